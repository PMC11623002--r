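sf <- asNamespace("splitfed")

make_batch <- function(n = 4L, size = 32L, seed = 1L) {
  set.seed(seed)
  list(x = array(runif(size * size * n), c(size, size, 1L, n)) * 2 - 1,
       labels = sample(0:2, n, replace = TRUE))
}

test_that("client forward emits 64-channel smashed data at a quarter resolution", {
  set.seed(10)
  cn <- client_net()
  b <- make_batch(2L, 32L)
  sb <- forward_client(cn, b, training = FALSE)
  expect_s3_class(sb, "smashed_batch")
  expect_equal(dim(sb$activations), c(8L, 8L, 64L, 2L))
  expect_identical(sb$labels, as.integer(b$labels))
  # 224x224 input maps to the canonical 56x56x64 cut
  b224 <- make_batch(1L, 224L)
  expect_equal(dim(forward_client(cn, b224, FALSE)$activations),
               c(56L, 56L, 64L, 1L))
  # eval-mode determinism
  expect_identical(forward_client(cn, b, FALSE)$activations, sb$activations)
  expect_error(forward_client(cn, list(x = array(0, c(30, 30, 1, 1)),
                                       labels = 0L), FALSE), "divisible")
})

test_that("server step computes cross-entropy, predictions and the cut gradient", {
  set.seed(11)
  cn <- client_net()
  sv <- server_net()
  sb <- forward_client(cn, make_batch(3L, 32L), training = TRUE)
  pk <- server_step(sv, sb, training = TRUE)
  expect_s3_class(pk, "gradient_packet")
  expect_true(is.finite(pk$loss))
  expect_equal(dim(pk$grad), dim(sb$activations))
  expect_equal(dim(pk$probs), c(3L, 3L))
  expect_equal(colSums(pk$probs), rep(1, 3), tolerance = 1e-9)
  # eval mode: no gradient, no weight change
  w0 <- get_weights(sv$layers)
  pk2 <- server_step(sv, sb, training = FALSE)
  expect_null(pk2$grad)
  expect_equal(weights_max_diff(w0, get_weights(sv$layers)), 0)
  bad <- sb; bad$labels <- c(0L, 1L, 9L)
  expect_error(server_step(sv, bad), "label out of range")
})

test_that("uniform predictions give the analytic ln(3) cross-entropy", {
  sm <- sf$softmax_ce(matrix(0, 3, 5), rep(0L, 5))
  expect_equal(sm$loss, log(3), tolerance = 1e-12)
  expect_true(all(abs(sm$probs - 1 / 3) < 1e-12))
})

test_that("client backward updates weights from the received packet", {
  set.seed(12)
  cn <- client_net()
  sv <- server_net()
  b <- make_batch(3L, 32L)
  sb <- forward_client(cn, b, training = TRUE)
  pk <- server_step(sv, sb, training = TRUE)
  w0 <- get_weights(cn$layers)
  client_backward(cn, sb, pk)
  expect_gt(weights_max_diff(w0, get_weights(cn$layers)), 0)
  # shape guard
  pk$grad <- pk$grad[, , , 1, drop = FALSE]
  expect_error(client_backward(cn, sb, pk), "shape")
  ev <- server_step(sv, sb, training = FALSE)
  expect_error(client_backward(cn, sb, ev), "no gradient")
})

test_that("repeated split steps on one fixed batch drive the loss down", {
  set.seed(13)
  cn <- client_net(dropout = 0)   # deterministic descent check
  sv <- server_net()
  b <- make_batch(8L, 32L)
  losses <- numeric(8)
  for (i in 1:8) {
    sb <- forward_client(cn, b, training = TRUE)
    pk <- server_step(sv, sb, training = TRUE)
    client_backward(cn, sb, pk)
    losses[i] <- pk$loss
  }
  expect_true(all(diff(losses[1:6]) < 0))
})

test_that("composed model shares weights with its halves and matches the two-stage path", {
  set.seed(14)
  cn <- client_net()
  sv <- server_net()
  full <- compose(cn, sv)
  expect_equal(param_count(full), param_count(cn) + param_count(sv))
  b <- make_batch(2L, 32L)
  logits_full <- sf$composed_forward(full, b$x, training = FALSE)
  sb <- forward_client(cn, b, training = FALSE)
  logits_split <- sf$seq_forward(sv$layers, sb$activations, FALSE)
  expect_identical(logits_full, logits_split)   # same arithmetic path
  # weights are shared, not copied: updating a half moves the composed model
  sb <- forward_client(cn, b, training = TRUE)
  invisible(server_step(sv, sb, training = TRUE))
  logits2 <- sf$composed_forward(full, b$x, training = FALSE)
  expect_false(identical(logits_full, logits2))
})

test_that("split-path gradients equal continuous composed-model backpropagation", {
  # the module's core property: with shared initial weights the gradient of
  # every parameter from (forward_client -> server_step -> client_backward)
  # equals the gradient from one continuous backward through the composed
  # model, to within 32-bit relative error 1e-5
  set.seed(15)
  cn <- client_net(dropout = 0)
  sv <- server_net()
  cn2 <- sf$clone_layers(cn$layers)
  sv2 <- sf$clone_layers(sv$layers)
  b <- make_batch(4L, 32L)

  sb <- forward_client(cn, b, training = TRUE)
  logits <- sf$seq_forward(sv$layers, sb$activations, TRUE)
  smx <- sf$softmax_ce(logits, b$labels)
  dcut <- sf$seq_backward(sv$layers, smx$dlogits)
  invisible(sf$seq_backward(cn$layers, dcut))
  split_grads <- lapply(sf$all_layers(c(cn$layers, sv$layers)),
                        function(l) l$grad)

  all2 <- c(cn2, sv2)
  logits2 <- sf$seq_forward(all2, b$x, TRUE)
  invisible(sf$seq_backward(all2, sf$softmax_ce(logits2, b$labels)$dlogits))
  comp_grads <- lapply(sf$all_layers(all2), function(l) l$grad)

  worst <- 0
  for (i in seq_along(split_grads))
    for (nm in names(split_grads[[i]]))
      worst <- max(worst, max_rel_err(split_grads[[i]][[nm]],
                                      comp_grads[[i]][[nm]]))
  expect_lte(worst, 1e-5)
  # batch-norm batch statistics also agree between the two paths
  bns <- which(vapply(sf$all_layers(c(cn$layers, sv$layers)),
                      function(l) l$type == "bn", logical(1)))
  fl1 <- sf$all_layers(c(cn$layers, sv$layers))
  fl2 <- sf$all_layers(all2)
  for (i in bns) {
    expect_equal(fl1[[i]]$state$rmean, fl2[[i]]$state$rmean)
    expect_equal(fl1[[i]]$state$rvar, fl2[[i]]$state$rvar)
  }
})
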