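# Conditional GAN for minority-class image synthesis. The generator maps a
# latent draw plus a class label to a tanh-range image; the discriminator
# scores (image, label) pairs. Architectures follow the reference model
# summaries: at image size 256 the parameterized layers count 413,696 /
# 208,896 / 2,112 / 1,025 (generator) and 3,342,336 / 2,432 / 147,584 x 4 /
# 8,193 (discriminator).

#' Conditional GAN architecture specification
#'
#' @param latent_dim latent-space dimension (default 100).
#' @param embed_dim label-embedding dimension (default 50).
#' @param n_classes number of condition classes (default 3).
#' @param image_size output side length; must be divisible by 4 (the
#'   generator reaches it from an `image_size/4` map by one 2x upsampling
#'   and one stride-2 transposed convolution).
#' @param base_channels filters of the first transposed convolution.
#' @export
gan_spec <- function(latent_dim = 100L, embed_dim = 50L, n_classes = 3L,
                     image_size = 256L, base_channels = 64L) {
  image_size <- as.integer(image_size)
  if (image_size %% 4L != 0L)
    stop("image_size must be divisible by 4")
  stopifnot(latent_dim >= 1, embed_dim >= 1, n_classes >= 2,
            base_channels >= 1)
  structure(list(latent_dim = as.integer(latent_dim),
                 embed_dim = as.integer(embed_dim),
                 n_classes = as.integer(n_classes),
                 image_size = image_size,
                 base_channels = as.integer(base_channels)),
            class = "gan_spec")
}

#' Build the conditional generator
#'
#' Structure: the latent vector feeds a dense layer of `(s/4)^2` units with
#' leaky-ReLU; the label feeds an embedding and a dense layer of the same
#' width; both are reshaped to `(s/4, s/4, 1)` maps and concatenated to a
#' 2-channel map, then 2x nearest-neighbour upsampling, a stride-2 4x4
#' transposed convolution (`base_channels` filters, leaky-ReLU) and a final
#' stride-1 4x4 transposed convolution to one channel with tanh output in
#' \[-1, 1\].
#'
#' @param spec a [gan_spec()].
#' @return An object of class `sf_generator`.
#' @export
build_generator <- function(spec = gan_spec()) {
  stopifnot(inherits(spec, "gan_spec"))
  q <- spec$image_size %/% 4L
  structure(list(
    spec = spec,
    latent_path = list(layer_dense(spec$latent_dim, q * q, init_sd = 0.02),
                       layer_lrelu(0.2)),
    label_path = list(layer_embedding(spec$n_classes, spec$embed_dim),
                      layer_dense(spec$embed_dim, q * q, init_sd = 0.02)),
    trunk = list(layer_upsample(),
                 layer_tconv(4L, 2L, spec$base_channels, stride = 2L,
                             output_size = spec$image_size, act = "lrelu"),
                 layer_tconv(4L, spec$base_channels, 1L, stride = 1L,
                             output_size = spec$image_size, act = "tanh"))
  ), class = "sf_generator")
}

generator_layers <- function(g) c(g$latent_path, g$label_path, g$trunk)

generator_forward <- function(g, z, labels, training = FALSE) {
  q <- g$spec$image_size %/% 4L
  n <- nrow(z)
  a <- seq_forward(g$latent_path, t(z), training)       # (q^2, n)
  b <- seq_forward(g$label_path, as.integer(labels), training)
  x <- array(0, dim = c(q, q, 2L, n))
  x[, , 1L, ] <- a
  x[, , 2L, ] <- b
  seq_forward(g$trunk, x, training)
}

generator_backward <- function(g, dy) {
  dcat <- seq_backward(g$trunk, dy)
  q <- dim(dcat)[1]; n <- dim(dcat)[4]
  da <- matrix(dcat[, , 1L, ], q * q, n)
  db <- matrix(dcat[, , 2L, ], q * q, n)
  seq_backward(g$latent_path, da)
  seq_backward(g$label_path, db)
  invisible(g)
}

#' Build the conditional discriminator
#'
#' Structure: the label feeds an embedding and a dense layer of `s^2`
#' units, reshaped to an `(s, s, 1)` map and concatenated with the input
#' image; then five stride-2 3x3 convolutions of 128 filters with
#' leaky-ReLU, flatten, dropout (0.4) and a single sigmoid unit scoring
#' the pair as real.
#'
#' @param spec a [gan_spec()].
#' @return An object of class `sf_discriminator`.
#' @export
build_discriminator <- function(spec = gan_spec()) {
  stopifnot(inherits(spec, "gan_spec"))
  s <- spec$image_size
  trunk <- list()
  sz <- s
  c_in <- 2L
  for (i in 1:5) {
    trunk <- c(trunk, list(
      layer_conv(3L, c_in, 128L, stride = 2L, pad = "same",
                 input_size = sz, init_sd = 0.02, act = "lrelu")))
    sz <- as.integer(ceiling(sz / 2))
    c_in <- 128L
  }
  trunk <- c(trunk, list(layer_flatten(), layer_dropout(0.4),
                         layer_dense(sz * sz * 128L, 1L, init_sd = 0.02),
                         layer_sigmoid()))
  structure(list(
    spec = spec,
    label_path = list(layer_embedding(spec$n_classes, spec$embed_dim),
                      layer_dense(spec$embed_dim, s * s, init_sd = 0.02)),
    trunk = trunk
  ), class = "sf_discriminator")
}

discriminator_layers <- function(d) c(d$label_path, d$trunk)

discriminator_forward <- function(d, images, labels, training = FALSE) {
  s <- d$spec$image_size
  n <- dim(images)[4]
  lab_map <- seq_forward(d$label_path, as.integer(labels), training)
  x <- array(0, dim = c(s, s, 2L, n))
  x[, , 1L, ] <- images
  x[, , 2L, ] <- lab_map
  as.vector(seq_forward(d$trunk, x, training))
}

# returns the gradient with respect to the image channel (for generator
# training); discriminator layer gradients are left in place unless
# need_params = FALSE (frozen discriminator during a generator step)
discriminator_backward <- function(d, dp, need_params = TRUE) {
  dcat <- seq_backward(d$trunk, matrix(dp, 1L), need_param = need_params)
  if (need_params) {
    s <- dim(dcat)[1]; n <- dim(dcat)[4]
    dlab <- matrix(dcat[, , 2L, ], s * s, n)
    seq_backward(d$label_path, dlab)
  }
  dcat[, , 1L, , drop = FALSE]
}

clear_grads <- function(layers) {
  for (l in all_layers(layers)) l$grad <- list()
  invisible(layers)
}

#' Per-layer trainable parameter counts
#'
#' @param model an `sf_generator`, `sf_discriminator`, `client_net` or
#'   `server_net`.
#' @return A data frame with columns `layer` and `params`; layer names
#'   identify the parameterized layers in forward order.
#' @export
param_table <- function(model) {
  count <- function(l) sum(vapply(l$par, length, integer(1)))
  if (inherits(model, "sf_generator")) {
    data.frame(
      layer = c("dense_latent", "embedding", "dense_label",
                "tconv_1", "tconv_2"),
      params = c(count(model$latent_path[[1]]),
                 count(model$label_path[[1]]),
                 count(model$label_path[[2]]),
                 count(model$trunk[[2]]),
                 count(model$trunk[[3]])))
  } else if (inherits(model, "sf_discriminator")) {
    convs <- model$trunk[vapply(model$trunk, function(l) l$type == "conv",
                                logical(1))]
    dense_out <- model$trunk[[length(model$trunk) - 1L]]
    data.frame(
      layer = c("embedding", "dense_label", paste0("conv_", 1:5),
                "dense_out"),
      params = c(count(model$label_path[[1]]),
                 count(model$label_path[[2]]),
                 vapply(convs, count, integer(1)),
                 count(dense_out)))
  } else if (!is.null(model$layers)) {
    ls <- all_layers(model$layers)
    keep <- vapply(ls, function(l) length(l$par) > 0, logical(1))
    ls <- ls[keep]
    data.frame(layer = paste0(vapply(ls, `[[`, "", "type"),
                              "_", seq_along(ls)),
               params = vapply(ls, count, integer(1)))
  } else stop("unsupported model")
}

#' Adversarial value function
#'
#' The discriminator's objective `mean(log d_real) + mean(log(1 - d_fake))`,
#' maximized by the discriminator and minimized by the generator.
#' Probabilities are clamped away from 0/1 at machine epsilon. Equals the
#' negative binary cross-entropy of the discriminator (up to the factor 2
#' from averaging the real and fake halves separately).
#'
#' @param d_real,d_fake discriminator probabilities on real and generated
#'   samples, in (0, 1).
#' @return The scalar objective value.
#' @seealso [generator_loss()] for the generator-side loss actually
#'   optimized during training.
#' @export
gan_objective <- function(d_real, d_fake) {
  if (!length(d_real) || !length(d_fake)) stop("empty probability vector")
  eps <- .Machine$double.eps
  d_real <- pmin(pmax(d_real, eps), 1 - eps)
  d_fake <- pmin(pmax(d_fake, eps), 1 - eps)
  mean(log(d_real)) + mean(log(1 - d_fake))
}

#' Generator loss
#'
#' The non-saturating form `-mean(log d_fake)` used during training (the
#' standard substitution for minimizing `log(1 - D(G(z)))`, which has
#' vanishing gradients early on); `saturating = TRUE` gives the literal
#' minimax term `mean(log(1 - d_fake))`.
#'
#' @param d_fake discriminator probabilities on generated samples.
#' @param saturating use the saturating minimax form.
#' @export
generator_loss <- function(d_fake, saturating = FALSE) {
  if (!length(d_fake)) stop("empty probability vector")
  eps <- .Machine$double.eps
  d_fake <- pmin(pmax(d_fake, eps), 1 - eps)
  if (saturating) mean(log(1 - d_fake)) else -mean(log(d_fake))
}

#' Draw latent points with matching labels
#'
#' @param latent_dim latent dimension.
#' @param n number of draws.
#' @param n_classes number of classes labels are drawn from (uniformly),
#'   unless `class_label` fixes one class.
#' @param seed integer seed.
#' @param class_label optional fixed 0-based class for every draw.
#' @return A list with `z` (an `n x latent_dim` matrix of standard-normal
#'   draws) and `labels` (`n` integers).
#' @export
generate_latent_points <- function(latent_dim, n, n_classes, seed,
                                   class_label = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, latent_points_rng(latent_dim, n, n_classes, class_label))
}

latent_points_rng <- function(latent_dim, n, n_classes, class_label = NULL) {
  z <- matrix(stats::rnorm(n * latent_dim), n, latent_dim)
  labels <- if (is.null(class_label)) {
    sample.int(n_classes, n, replace = TRUE) - 1L
  } else {
    if (class_label < 0 || class_label >= n_classes)
      stop("class_label out of range")
    rep(as.integer(class_label), n)
  }
  list(z = z, labels = labels)
}

# one discriminator update on a labeled batch with a common real/fake target
disc_train_batch <- function(d, opt, images, labels, target) {
  p <- discriminator_forward(d, images, labels, training = TRUE)
  b <- binary_ce(p, target)
  discriminator_backward(d, b$dp)
  adam_step(opt, discriminator_layers(d))
  list(loss = b$loss, p = p)
}

# one generator update through the frozen discriminator
gen_train_batch <- function(g, d, opt, n_batch) {
  lp <- latent_points_rng(g$spec$latent_dim, n_batch, g$spec$n_classes)
  imgs <- generator_forward(g, lp$z, lp$labels, training = TRUE)
  p <- discriminator_forward(d, imgs, lp$labels, training = TRUE)
  b <- binary_ce(p, 1)                       # non-saturating: target "real"
  dimg <- discriminator_backward(d, b$dp, need_params = FALSE)  # frozen D
  generator_backward(g, dimg)
  adam_step(opt, generator_layers(g))
  generator_loss(p)
}

#' Train a conditional GAN
#'
#' Adversarial training: per batch the discriminator is updated on a real
#' half-batch (target 1) and a generated half-batch (target 0) separately,
#' then the generator is updated through the frozen discriminator with the
#' non-saturating loss. Real images are mapped from \[0, 1\] to the
#' generator's tanh range \[-1, 1\]. Adam with step size 2e-4 and beta1 0.5
#' (the customary GAN setting) drives both players.
#'
#' @param dataset an `image_set` whose images match `spec$image_size`.
#' @param spec a [gan_spec()].
#' @param n_epochs training epochs (default 100).
#' @param n_batch batch size (default 128; at most the dataset size).
#' @param seed integer seed; identical inputs and seed give an identical
#'   training log.
#' @param lr,beta1 Adam settings for both players.
#' @param checkpoint_dir if non-`NULL`, generator weights are saved there
#'   every `checkpoint_every` epochs.
#' @param checkpoint_every checkpoint cadence in epochs.
#' @param verbose print one line per 10 epochs.
#' @return An object of class `cgan` with elements `generator`,
#'   `discriminator`, `spec`, `log` (one row per epoch: discriminator loss
#'   and accuracy on real and fake samples, generator loss) and
#'   `class_names`.
#' @export
train_cgan <- function(dataset, spec = gan_spec(image_size = 64L),
                       n_epochs = 100L, n_batch = 128L, seed = 1L,
                       lr = 2e-4, beta1 = 0.5,
                       checkpoint_dir = NULL, checkpoint_every = 10L,
                       verbose = FALSE) {
  n <- length(dataset)
  d1 <- dim(dataset$images[[1]])
  if (d1[1] != spec$image_size || d1[2] != spec$image_size)
    stop("image size ", d1[1], "x", d1[2], " does not match spec image_size ",
         spec$image_size)
  if (n_batch > n) stop("n_batch exceeds dataset size")
  s <- spec$image_size
  X <- array(unlist(dataset$images), dim = c(s, s, 1L, n)) * 2 - 1
  y <- dataset$labels
  if (max(y) >= spec$n_classes) stop("labels exceed spec n_classes")

  with_seed(seed, {
    g <- build_generator(spec)
    d <- build_discriminator(spec)
    opt_g <- new_adam(lr, beta1)
    opt_d <- new_adam(lr, beta1)
    bat_per_epo <- max(1L, n %/% n_batch)
    half <- max(1L, n_batch %/% 2L)
    log <- vector("list", n_epochs)
    for (ep in seq_len(n_epochs)) {
      st <- c(d_loss_real = 0, d_loss_fake = 0, acc_real = 0, acc_fake = 0,
              g_loss = 0)
      for (b in seq_len(bat_per_epo)) {
        ridx <- sample.int(n, half)
        r <- disc_train_batch(d, opt_d, X[, , , ridx, drop = FALSE],
                              y[ridx], 1)
        lp <- latent_points_rng(spec$latent_dim, half, spec$n_classes)
        fake <- generator_forward(g, lp$z, lp$labels)
        f <- disc_train_batch(d, opt_d, fake, lp$labels, 0)
        gl <- gen_train_batch(g, d, opt_g, n_batch)
        st <- st + c(r$loss, f$loss, mean(r$p > 0.5), mean(f$p < 0.5), gl)
      }
      log[[ep]] <- as.data.frame(as.list(st / bat_per_epo))
      if (!is.null(checkpoint_dir) && ep %% checkpoint_every == 0L) {
        dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(get_weights(generator_layers(g)),
                file.path(checkpoint_dir, sprintf("generator_ep%04d.rds", ep)))
      }
      if (verbose && ep %% 10L == 0L)
        message(sprintf(
          "epoch %d: d_real %.3f d_fake %.3f acc_r %.2f acc_f %.2f g %.3f",
          ep, st[1] / bat_per_epo, st[2] / bat_per_epo, st[3] / bat_per_epo,
          st[4] / bat_per_epo, st[5] / bat_per_epo))
    }
    clear_caches(generator_layers(g))
    clear_caches(discriminator_layers(d))
    structure(list(spec = spec, generator = g, discriminator = d,
                   log = do.call(rbind, log),
                   class_names = dataset$class_names),
              class = "cgan")
  })
}

#' Synthesize images of one class from a trained GAN
#'
#' Draws latent points, runs the generator conditioned on `class_label`,
#' and rescales outputs from tanh range to \[0, 1\]. All returned images
#' carry provenance `"synthetic"`.
#'
#' @param gan a trained `cgan` object.
#' @param class_label 0-based class to synthesize.
#' @param n number of images.
#' @param seed integer seed.
#' @return An `image_set`.
#' @export
synthesize <- function(gan, class_label, n, seed = 1L) {
  stopifnot(inherits(gan, "cgan"))
  spec <- gan$spec
  if (class_label < 0 || class_label >= spec$n_classes)
    stop("class_label out of range")
  with_seed(seed, {
    lp <- latent_points_rng(spec$latent_dim, n, spec$n_classes, class_label)
    imgs <- generator_forward(gan$generator, lp$z, lp$labels)
    imgs <- (imgs + 1) / 2
    imgs <- pmin(pmax(imgs, 0), 1)
    clear_caches(generator_layers(gan$generator))
    image_set(lapply(seq_len(n), function(i) imgs[, , 1L, i]),
              lp$labels, gan$class_names, provenance = "synthetic")
  })
}

#' @export
print.cgan <- function(x, ...) {
  cat("<cgan> image size ", x$spec$image_size, ", ", x$spec$n_classes,
      " classes, latent dim ", x$spec$latent_dim, "\n", sep = "")
  cat("  trained for", nrow(x$log), "epochs\n")
  if (nrow(x$log)) {
    f <- x$log[nrow(x$log), ]
    cat(sprintf("  final: D acc real %.2f / fake %.2f, G loss %.3f\n",
                f$acc_real, f$acc_fake, f$g_loss))
  }
  invisible(x)
}

#' @export
summary.cgan <- function(object, ...) {
  cat("Generator parameters:\n")
  print(param_table(object$generator))
  cat("\nDiscriminator parameters:\n")
  print(param_table(object$discriminator))
  cat("\nFinal epoch:\n")
  print(object$log[nrow(object$log), ])
  invisible(object)
}

#' Simulate (synthesize) images from a fitted conditional GAN
#'
#' @param object a `cgan` fit.
#' @param nsim number of images.
#' @param seed integer seed.
#' @param class_label 0-based class to condition on.
#' @param ... unused.
#' @return An `image_set` of synthetic images.
#' @export
simulate.cgan <- function(object, nsim = 1, seed = 1L, class_label = 0L, ...) {
  synthesize(object, class_label, nsim, seed)
}

#' Save / load GAN weights as a single-file checkpoint
#'
#' @param gan a `cgan` object.
#' @param path checkpoint file path.
#' @export
save_gan <- function(gan, path) {
  saveRDS(list(spec = gan$spec,
               generator = get_weights(generator_layers(gan$generator)),
               discriminator = get_weights(discriminator_layers(gan$discriminator)),
               log = gan$log, class_names = gan$class_names),
          path)
  invisible(path)
}

#' @rdname save_gan
#' @export
load_gan <- function(path) {
  x <- readRDS(path)
  g <- build_generator(x$spec)
  d <- build_discriminator(x$spec)
  set_weights(generator_layers(g), x$generator)
  set_weights(discriminator_layers(d), x$discriminator)
  structure(list(spec = x$spec, generator = g, discriminator = d,
                 log = x$log, class_names = x$class_names),
            class = "cgan")
}
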