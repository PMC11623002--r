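# The ResNet18-style classifier partitioned at its cut layer. The client
# holds the stem (7x7 stride-2 convolution, batch norm, ReLU, 3x3 stride-2
# max pool) plus one 3x3 refinement convolution with batch norm, ReLU and
# dropout; its output -- the "smashed data", a (size/4, size/4, 64) map --
# travels to the server together with the batch labels. The server holds a
# conv-BN-ReLU-conv-BN refinement stage, three basic residual blocks
# (128/256/512 channels, stride 2 each), global average pooling and the
# 3-way classifier head.

#' Build the client-side network half
#'
#' @param dropout dropout probability applied at the cut layer (train mode
#'   only).
#' @param lr Adam step size for the client-side optimizer.
#' @return An object of class `client_net` holding layers and optimizer.
#' @export
client_net <- function(dropout = 0.5, lr = 1e-4) {
  structure(list(
    layers = list(layer_conv(7L, 1L, 64L, stride = 2L, pad = 3L),
                  layer_bn(64L, act = "relu"),
                  layer_maxpool(3L, 2L, 1L),
                  layer_conv(3L, 64L, 64L, stride = 1L, pad = 1L),
                  layer_bn(64L, act = "relu"),
                  layer_dropout(dropout)),
    opt = new_adam(lr)
  ), class = "client_net")
}

#' Build the server-side network half
#'
#' @param n_classes number of output classes.
#' @param lr Adam step size for the server-side optimizer.
#' @return An object of class `server_net`.
#' @export
server_net <- function(n_classes = 3L, lr = 1e-4) {
  structure(list(
    layers = list(layer_conv(3L, 64L, 64L, 1L, pad = 1L),
                  layer_bn(64L, act = "relu"),
                  layer_conv(3L, 64L, 64L, 1L, pad = 1L),
                  layer_bn(64L),
                  layer_block(64L, 128L, 2L),
                  layer_block(128L, 256L, 2L),
                  layer_block(256L, 512L, 2L),
                  layer_gap(),
                  layer_dense(512L, as.integer(n_classes))),
    n_classes = as.integer(n_classes),
    opt = new_adam(lr)
  ), class = "server_net")
}

#' Client forward pass: produce smashed data
#'
#' Runs the client half on a batch and returns the cut-layer activations
#' together with the (shared) true labels, the payload a client transmits
#' to the server under the label-sharing protocol.
#'
#' @param net a `client_net`.
#' @param batch list with `x`, an `(H, W, 1, N)` array (H and W divisible
#'   by 4), and `labels`, `N` 0-based integers.
#' @param training logical; enables batch-norm batch statistics and
#'   dropout.
#' @return An object of class `smashed_batch`: `activations` of shape
#'   `(H/4, W/4, 64, N)` plus the pass-through `labels`.
#' @export
forward_client <- function(net, batch, training = FALSE) {
  d <- dim(batch$x)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    stop("input size must be divisible by 4")
  if (length(batch$labels) != d[4])
    stop("batch size of images and labels differ")
  structure(list(activations = seq_forward(net$layers, batch$x, training),
                 labels = as.integer(batch$labels)),
            class = "smashed_batch")
}

#' Server step: loss, prediction and the gradient at the cut
#'
#' Forward pass of the server half on received smashed data, categorical
#' cross-entropy against the shared labels and, in training mode, one Adam
#' update of the server weights plus the loss gradient with respect to the
#' smashed activations (sent back to the client). In evaluation mode no
#' gradient is computed and no weights change.
#'
#' @param net a `server_net`.
#' @param smashed a `smashed_batch`.
#' @param training logical.
#' @return An object of class `gradient_packet`: `grad` (same shape as the
#'   smashed activations; `NULL` in eval mode), scalar `loss`, and `probs`
#'   (`n_classes x N` predicted probabilities).
#' @export
server_step <- function(net, smashed, training = TRUE) {
  labels <- smashed$labels
  if (any(labels < 0L) || any(labels >= net$n_classes))
    stop("label out of range")
  logits <- seq_forward(net$layers, smashed$activations, training)
  sm <- softmax_ce(logits, labels)
  grad <- NULL
  if (training) {
    grad <- seq_backward(net$layers, sm$dlogits)
    adam_step(net$opt, net$layers)
  }
  structure(list(grad = grad, loss = sm$loss, probs = sm$probs),
            class = "gradient_packet")
}

#' Client backward pass from a received gradient packet
#'
#' Continues backpropagation from the cut-layer gradient through the
#' client half (using the caches of the most recent forward of this batch)
#' and applies one Adam update to the client weights.
#'
#' @param net a `client_net`.
#' @param smashed the `smashed_batch` produced by the matching
#'   [forward_client()] call.
#' @param packet the `gradient_packet` returned by [server_step()].
#' @return The updated `client_net`, invisibly.
#' @export
client_backward <- function(net, smashed, packet) {
  if (is.null(packet$grad))
    stop("gradient packet carries no gradient (eval-mode server step?)")
  if (!identical(dim(packet$grad), dim(smashed$activations)))
    stop("gradient shape does not match smashed activations")
  seq_backward(net$layers, packet$grad)
  adam_step(net$opt, net$layers)
  invisible(net)
}

#' Compose the two halves into one full model
#'
#' The composed model shares the halves' weights (not copies): training or
#' updating either view changes the same parameters. Its forward pass is
#' exactly the client forward followed by the server forward.
#'
#' @param client a `client_net`.
#' @param server a `server_net`.
#' @return An object of class `composed_net`.
#' @export
compose <- function(client, server) {
  stopifnot(inherits(client, "client_net"), inherits(server, "server_net"))
  structure(list(client = client, server = server), class = "composed_net")
}

composed_layers <- function(model) c(model$client$layers, model$server$layers)

composed_forward <- function(model, x, training = FALSE) {
  seq_forward(composed_layers(model), x, training)
}

# one centralized training step: continuous backward through both halves,
# then one Adam update per half (each half keeps its own optimizer state)
composed_train_step <- function(model, x, labels) {
  logits <- composed_forward(model, x, training = TRUE)
  sm <- softmax_ce(logits, labels)
  seq_backward(composed_layers(model), sm$dlogits)
  adam_step(model$server$opt, model$server$layers)
  adam_step(model$client$opt, model$client$layers)
  sm
}

#' Total trainable parameter count of a model or model half
#'
#' @param model a `client_net`, `server_net`, `composed_net`,
#'   `sf_generator` or `sf_discriminator`.
#' @export
param_count <- function(model) {
  layers <- if (inherits(model, "composed_net")) composed_layers(model)
  else if (inherits(model, "sf_generator")) generator_layers(model)
  else if (inherits(model, "sf_discriminator")) discriminator_layers(model)
  else model$layers
  sum(vapply(all_layers(layers),
             function(l) sum(vapply(l$par, length, integer(1))), integer(1)))
}

#' Predict class probabilities with a composed model
#'
#' @param object a `composed_net`.
#' @param newdata an `image_set` or an `(H, W, 1, N)` array already
#'   normalized for the network.
#' @param type `"prob"` for an `N x n_classes` probability matrix,
#'   `"class"` for 0-based class indices.
#' @param ... unused.
#' @export
predict.composed_net <- function(object, newdata, type = c("prob", "class"),
                                 ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "image_set")) {
    to_tensor(newdata)$x
  } else newdata
  logits <- composed_forward(object, x, training = FALSE)
  probs <- t(softmax_ce(logits, integer(dim(x)[4]))$probs)
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

# image_set -> network input tensor, with fixed [-1, 1] normalization
to_tensor <- function(dataset, mean = 0.5, sd = 0.5) {
  n <- length(dataset)
  d <- dim(dataset$images[[1]])
  x <- array(unlist(dataset$images), dim = c(d[1], d[2], 1L, n))
  list(x = (x - mean) / sd, labels = dataset$labels)
}
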