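# Independent oracles used across test files.

# direct quadruple-loop 2-D convolution on (H, W, C, N) arrays
naive_conv <- function(x, w, b, stride, pt, pb, pl, pr) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  K <- dim(w)[1]; Cout <- dim(w)[4]
  xp <- array(0, c(H + pt + pb, W + pl + pr, C, N))
  xp[pt + seq_len(H), pl + seq_len(W), , ] <- x
  Ho <- (H + pt + pb - K) %/% stride + 1
  Wo <- (W + pl + pr - K) %/% stride + 1
  y <- array(0, c(Ho, Wo, Cout, N))
  for (n in seq_len(N)) for (co in seq_len(Cout))
    for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) {
      patch <- xp[(ho - 1) * stride + seq_len(K),
                  (wo - 1) * stride + seq_len(K), , n]
      y[ho, wo, co, n] <- sum(patch * w[, , , co]) + b[co]
    }
  y
}

# central finite difference of f at element i of v
fd_grad <- function(f, v, i, eps = 1e-3) {
  v1 <- v; v1[i] <- v1[i] + eps
  v2 <- v; v2[i] <- v2[i] - eps
  (f(v1) - f(v2)) / (2 * eps)
}

# small deterministic image set: k classes with distinct mean intensities
tiny_image_set <- function(n_per_class = c(6, 4, 2), size = 8L, seed = 1L) {
  set.seed(seed)
  imgs <- list(); labels <- integer(0)
  for (k in seq_along(n_per_class) - 1L) {
    for (j in seq_len(n_per_class[k + 1L])) {
      imgs[[length(imgs) + 1L]] <-
        matrix(pmin(pmax(0.2 + 0.25 * k + rnorm(size^2, 0, 0.05), 0), 1),
               size, size)
      labels <- c(labels, k)
    }
  }
  image_set(imgs, labels, class_names = paste0("c", seq_along(n_per_class)))
}

max_rel_err <- function(a, b) {
  stopifnot(length(a) == length(b))
  max(abs(a - b)) / max(1e-12, max(abs(b)))
}

# deep comparison of two weight collections
weights_max_diff <- function(w1, w2) {
  m <- 0
  for (i in seq_along(w1))
    for (nm in names(w1[[i]]))
      m <- max(m, max(abs(w1[[i]][[nm]] - w2[[i]][[nm]])))
  m
}
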