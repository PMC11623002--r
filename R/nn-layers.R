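# Minimal layer framework backing the split classifier and the conditional
# GAN. A layer is an environment holding parameters, gradients, optimizer
# state and the forward cache; models are lists of layers. Tensors are R
# double arrays laid out (H, W, C, N); dense activations are (features, N)
# matrices. Convolution/pooling/batch-norm kernels are C++ (see src/).

new_layer <- function(type, par = list(), cfg = list(), state = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- par
  e$grad <- list()
  e$opt <- list()
  e$state <- state
  e$cfg <- cfg
  e$cache <- NULL
  class(e) <- "sf_layer"
  e
}

# TensorFlow-style 'same' padding: output = ceiling(input / stride), with the
# extra pad row/column on the bottom/right.
pad_same <- function(input, k, stride) {
  out <- ceiling(input / stride)
  total <- max((out - 1L) * stride + k - input, 0L)
  c(total %/% 2L, total - total %/% 2L)
}

init_normal <- function(dims, sd) {
  array(stats::rnorm(prod(dims), 0, sd), dim = dims)
}

act_code <- function(act)
  switch(act, none = 0L, relu = 1L, lrelu = 1L, tanh = 2L)

layer_conv <- function(k, c_in, c_out, stride = 1L, pad = "same",
                       input_size = NULL, init_sd = NULL, act = "none",
                       slope = 0.2) {
  if (identical(pad, "same")) {
    stopifnot(!is.null(input_size))
    p <- pad_same(input_size, k, stride)
    pads <- c(p[1], p[2], p[1], p[2])
  } else {
    pads <- rep(as.integer(pad), length.out = 4L)
  }
  if (is.null(init_sd)) init_sd <- sqrt(2 / (k * k * c_in))
  new_layer("conv",
            par = list(w = init_normal(c(k, k, c_in, c_out), init_sd),
                       b = numeric(c_out)),
            cfg = list(k = as.integer(k), stride = as.integer(stride),
                       pads = as.integer(pads), act = act_code(act),
                       slope = slope))
}

# Transposed convolution; weight layout (k, k, c_out, c_in) mirrors the
# adjoint convolution mapping output space back to input space.
layer_tconv <- function(k, c_in, c_out, stride = 1L, output_size,
                        init_sd = 0.02, act = "none", slope = 0.2) {
  total <- k - stride  # 'same' transposed padding: output = input * stride
  stopifnot(total >= 0)
  pt <- total %/% 2L
  pads <- c(pt, total - pt, pt, total - pt)
  new_layer("tconv",
            par = list(w = init_normal(c(k, k, c_out, c_in), init_sd),
                       b = numeric(c_out)),
            cfg = list(k = as.integer(k), stride = as.integer(stride),
                       pads = as.integer(pads),
                       output_size = as.integer(output_size),
                       act = act_code(act), slope = slope,
                       small = k * k * c_in * c_out <= 65536L))
}

layer_bn <- function(c_in, eps = 1e-5, momentum = 0.1, act = "none") {
  new_layer("bn",
            par = list(gamma = rep(1, c_in), beta = numeric(c_in)),
            state = list(rmean = numeric(c_in), rvar = rep(1, c_in)),
            cfg = list(eps = eps, momentum = momentum,
                       act = act_code(act),
                       slope = if (identical(act, "lrelu")) 0.2 else 0))
}

layer_relu <- function() new_layer("relu")
layer_lrelu <- function(slope = 0.2) new_layer("lrelu", cfg = list(slope = slope))
layer_tanh <- function() new_layer("tanh")
layer_sigmoid <- function() new_layer("sigmoid")
layer_maxpool <- function(k = 3L, stride = 2L, pad = 1L)
  new_layer("maxpool", cfg = list(k = as.integer(k), stride = as.integer(stride),
                                  pad = as.integer(pad)))
layer_dropout <- function(p) new_layer("dropout", cfg = list(p = p))
layer_flatten <- function() new_layer("flatten")
layer_reshape <- function(dims) new_layer("reshape", cfg = list(dims = as.integer(dims)))
layer_upsample <- function() new_layer("upsample")
layer_gap <- function() new_layer("gap")

layer_dense <- function(d_in, d_out, init_sd = NULL) {
  if (is.null(init_sd)) init_sd <- sqrt(2 / d_in)
  new_layer("dense",
            par = list(w = init_normal(c(d_in, d_out), init_sd),
                       b = numeric(d_out)))
}

layer_embedding <- function(n_classes, dim, init_sd = 0.05) {
  new_layer("embedding",
            par = list(w = init_normal(c(n_classes, dim), init_sd)),
            cfg = list(n_classes = as.integer(n_classes)))
}

# ResNet basic block: conv-BN-ReLU-conv-BN plus an identity or projection
# shortcut, joined by addition and a final ReLU.
layer_block <- function(c_in, c_out, stride = 1L) {
  main <- list(layer_conv(3L, c_in, c_out, stride, pad = 1L),
               layer_bn(c_out, act = "relu"),
               layer_conv(3L, c_out, c_out, 1L, pad = 1L),
               layer_bn(c_out))
  shortcut <- if (stride != 1L || c_in != c_out) {
    list(layer_conv(1L, c_in, c_out, stride, pad = 0L), layer_bn(c_out))
  } else list()
  l <- new_layer("block")
  l$sub <- list(main = main, shortcut = shortcut)
  l
}

# flat list of elementary layers, recursing into composite blocks
all_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "block") {
      out <- c(out, all_layers(l$sub$main), all_layers(l$sub$shortcut))
    } else {
      out <- c(out, list(l))
    }
  }
  out
}

layer_forward <- function(l, x, training = FALSE) {
  switch(l$type,
    conv = {
      y <- cpp_conv_fw(x, dim(x), l$par$w, dim(l$par$w), l$par$b,
                       l$cfg$stride, l$cfg$pads[1], l$cfg$pads[2],
                       l$cfg$pads[3], l$cfg$pads[4], l$cfg$act, l$cfg$slope)
      l$cache <- list(x = x, xdim = dim(x),
                      y = if (l$cfg$act != 0L) y)
      y
    },
    tconv = {
      s <- l$cfg$output_size
      y <- if (isTRUE(l$cfg$small)) {
        cpp_tconv_small_fw(x, dim(x), l$par$w, dim(l$par$w), l$par$b,
                           l$cfg$stride, l$cfg$pads[1], l$cfg$pads[3], s,
                           l$cfg$act, l$cfg$slope)
      } else {
        y0 <- cpp_conv_bw_data(x, dim(x), l$par$w, dim(l$par$w),
                               l$cfg$stride, l$cfg$pads[1], l$cfg$pads[2],
                               l$cfg$pads[3], l$cfg$pads[4], s, s, l$par$b)
        if (l$cfg$act == 1L) cpp_lrelu_fw(y0, l$cfg$slope)
        else if (l$cfg$act == 2L) tanh(y0)
        else y0
      }
      l$cache <- list(x = x, xdim = dim(x),
                      y = if (l$cfg$act != 0L) y)
      y
    },
    bn = {
      r <- cpp_bn_fw(x, dim(x), l$par$gamma, l$par$beta,
                     l$state$rmean, l$state$rvar,
                     l$cfg$eps, l$cfg$momentum, training,
                     l$cfg$act, l$cfg$slope)
      if (training) {
        l$state$rmean <- r$rmean
        l$state$rvar <- r$rvar
      }
      l$cache <- list(x = x, xdim = dim(x), mean = r$mean, var = r$var,
                      y = if (l$cfg$act != 0L) r$y)
      r$y
    },
    relu = { l$cache <- x; cpp_lrelu_fw(x, 0) },
    lrelu = { l$cache <- x; cpp_lrelu_fw(x, l$cfg$slope) },
    tanh = { y <- tanh(x); l$cache <- y; y },
    sigmoid = { y <- 1 / (1 + exp(-x)); l$cache <- y; y },
    maxpool = {
      r <- cpp_maxpool_fw(x, dim(x), l$cfg$k, l$cfg$stride, l$cfg$pad)
      l$cache <- list(idx = r$idx, xdim = dim(x))
      r$y
    },
    dropout = {
      if (training && l$cfg$p > 0) {
        mask <- (stats::runif(length(x)) >= l$cfg$p) / (1 - l$cfg$p)
        l$cache <- mask
        x * mask
      } else {
        l$cache <- NULL
        x
      }
    },
    flatten = {
      l$cache <- dim(x)
      d <- dim(x)
      matrix(x, prod(d[-length(d)]), d[length(d)])
    },
    reshape = {
      l$cache <- dim(x)
      array(x, dim = c(l$cfg$dims, ncol(x)))
    },
    upsample = {
      d <- dim(x)
      l$cache <- d
      x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
        drop = FALSE]
    },
    gap = {
      d <- dim(x)
      l$cache <- d
      matrix(colMeans(matrix(x, d[1] * d[2])), d[3], d[4])
    },
    dense = {
      l$cache <- x
      crossprod(l$par$w, x) + l$par$b
    },
    embedding = {
      l$cache <- x  # integer 0-based labels
      t(l$par$w[x + 1L, , drop = FALSE])
    },
    block = {
      a <- seq_forward(l$sub$main, x, training)
      b <- if (length(l$sub$shortcut))
        seq_forward(l$sub$shortcut, x, training) else x
      s <- a + b
      l$cache <- s
      cpp_lrelu_fw(s, 0)
    },
    stop("unknown layer type: ", l$type)
  )
}

undo_act <- function(l, dy) {
  if (is.null(l$cfg$act) || l$cfg$act == 0L) return(dy)
  if (l$cfg$act == 1L) cpp_lrelu_bw(l$cache$y, dy, l$cfg$slope)
  else dy * (1 - l$cache$y^2)
}

layer_backward <- function(l, dy, need_param = TRUE) {
  switch(l$type,
    conv = {
      cc <- l$cache
      dy <- undo_act(l, dy)
      if (need_param) {
        g <- cpp_conv_bw_filter(cc$x, cc$xdim, dy, dim(dy), l$cfg$k,
                                l$cfg$stride, l$cfg$pads[1], l$cfg$pads[2],
                                l$cfg$pads[3], l$cfg$pads[4])
        l$grad <- list(w = g$dw, b = g$db)
      }
      cpp_conv_bw_data(dy, dim(dy), l$par$w, dim(l$par$w), l$cfg$stride,
                       l$cfg$pads[1], l$cfg$pads[2], l$cfg$pads[3],
                       l$cfg$pads[4], cc$xdim[1], cc$xdim[2], numeric(0))
    },
    tconv = {
      cc <- l$cache
      dy <- undo_act(l, dy)
      g <- cpp_tconv_bw(cc$x, cc$xdim, l$par$w, dim(l$par$w),
                        dy, dim(dy), l$cfg$stride,
                        l$cfg$pads[1], l$cfg$pads[2],
                        l$cfg$pads[3], l$cfg$pads[4])
      l$grad <- list(w = g$dw, b = g$db)
      g$dx
    },
    bn = {
      cc <- l$cache
      g <- cpp_bn_bw(cc$x, dy, cc$xdim, l$par$gamma, cc$mean, cc$var,
                     l$cfg$eps,
                     if (l$cfg$act != 0L) cc$y else numeric(0),
                     l$cfg$act, l$cfg$slope)
      l$grad <- list(gamma = g$dgamma, beta = g$dbeta)
      g$dx
    },
    relu = cpp_lrelu_bw(l$cache, dy, 0),
    lrelu = cpp_lrelu_bw(l$cache, dy, l$cfg$slope),
    tanh = dy * (1 - l$cache^2),
    sigmoid = dy * l$cache * (1 - l$cache),
    maxpool = cpp_maxpool_bw(dy, l$cache$idx, l$cache$xdim),
    dropout = if (is.null(l$cache)) dy else dy * l$cache,
    flatten = array(dy, dim = l$cache),
    reshape = matrix(dy, prod(l$cfg$dims), dim(dy)[4]),
    upsample = {
      d <- l$cache
      dy[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , , drop = FALSE] +
        dy[seq(2, 2 * d[1], 2), seq(1, 2 * d[2], 2), , , drop = FALSE] +
        dy[seq(1, 2 * d[1], 2), seq(2, 2 * d[2], 2), , , drop = FALSE] +
        dy[seq(2, 2 * d[1], 2), seq(2, 2 * d[2], 2), , , drop = FALSE]
    },
    gap = {
      d <- l$cache
      hw <- d[1] * d[2]
      array(rep(dy, each = hw) / hw, dim = d)
    },
    dense = {
      if (need_param) l$grad <- list(w = l$cache %*% t(dy), b = rowSums(dy))
      l$par$w %*% dy
    },
    embedding = {
      if (need_param) {
        dw <- array(0, dim = dim(l$par$w))
        lab <- l$cache + 1L
        for (i in seq_along(lab)) dw[lab[i], ] <- dw[lab[i], ] + dy[, i]
        l$grad <- list(w = dw)
      }
      NULL  # labels carry no gradient
    },
    block = {
      ds <- cpp_lrelu_bw(l$cache, dy, 0)
      da <- seq_backward(l$sub$main, ds)
      db <- if (length(l$sub$shortcut))
        seq_backward(l$sub$shortcut, ds) else ds
      da + db
    },
    stop("unknown layer type: ", l$type)
  )
}

seq_forward <- function(layers, x, training = FALSE) {
  for (l in layers) x <- layer_forward(l, x, training)
  x
}

seq_backward <- function(layers, dy, need_param = TRUE) {
  for (l in rev(layers)) dy <- layer_backward(l, dy, need_param)
  dy
}

# ---- weights as plain lists (used by FedAvg, checkpoints, deep copies) ----
# Weight collections include batch-norm running statistics so aggregation
# and checkpointing cover the full model state.

get_weights <- function(layers) {
  lapply(all_layers(layers), function(l) c(l$par, l$state))
}

set_weights <- function(layers, w) {
  fl <- all_layers(layers)
  stopifnot(length(fl) == length(w))
  for (i in seq_along(fl)) {
    l <- fl[[i]]
    for (nm in names(l$par)) l$par[[nm]] <- w[[i]][[nm]]
    for (nm in names(l$state)) l$state[[nm]] <- w[[i]][[nm]]
  }
  invisible(layers)
}

# drop forward caches (activations can dwarf the parameters in memory)
clear_caches <- function(layers) {
  for (l in all_layers(layers)) l$cache <- NULL
  invisible(layers)
}

reset_opt_state <- function(layers) {
  for (l in all_layers(layers)) l$opt <- list()
  invisible(layers)
}

clone_layers <- function(layers) {
  lapply(layers, function(l) {
    e <- new_layer(l$type, l$par, l$cfg, l$state)
    e$opt <- l$opt
    if (l$type == "block")
      e$sub <- list(main = clone_layers(l$sub$main),
                    shortcut = clone_layers(l$sub$shortcut))
    e
  })
}

# ---- Adam ----

new_adam <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$t <- 0L
  class(e) <- "sf_adam"
  e
}

adam_step <- function(opt, layers) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (l in all_layers(layers)) {
    if (!length(l$grad)) next
    for (nm in names(l$grad)) {
      st <- l$opt[[nm]]
      r <- cpp_adam_step(l$par[[nm]], l$grad[[nm]],
                         if (is.null(st)) numeric(0) else st$m,
                         if (is.null(st)) numeric(0) else st$v,
                         opt$lr, opt$beta1, opt$beta2, opt$eps, c1, c2)
      l$opt[[nm]] <- list(m = r$m, v = r$v)
      l$par[[nm]] <- r$par
    }
    l$grad <- list()
  }
  invisible(layers)
}

# ---- losses ----

# Multinomial cross-entropy on logits (K, N); labels are 0-based integers.
softmax_ce <- function(logits, labels) {
  k <- nrow(logits)
  n <- ncol(logits)
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  probs <- sweep(ex, 2, colSums(ex), "/")
  picked <- probs[cbind(labels + 1L, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- probs
  dlogits[cbind(labels + 1L, seq_len(n))] <-
    dlogits[cbind(labels + 1L, seq_len(n))] - 1
  list(loss = loss, probs = probs, dlogits = dlogits / n)
}

# Binary cross-entropy on probabilities (1, N) against scalar/vector targets.
binary_ce <- function(p, target) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  loss <- -mean(target * log(p) + (1 - target) * log(1 - p))
  dp <- (p - target) / (p * (1 - p)) / length(p)
  list(loss = loss, dp = dp)
}

# run a block with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
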