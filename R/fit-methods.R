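#' @export
print.fed_fit <- function(x, ...) {
  cat("<fed_fit> mode:", x$mode, "\n")
  cat("  clients:", x$config$n_clients, " epochs:", x$config$epochs,
      " batch:", x$config$batch_size, " lr:", x$config$learning_rate, "\n")
  cat(sprintf("  final test: accuracy %.4f  loss %.4f\n",
              x$test_metrics$accuracy, x$test_metrics$loss))
  invisible(x)
}

#' @export
summary.fed_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  macro precision %.4f  macro recall %.4f\n",
              object$test_metrics$precision, object$test_metrics$recall))
  cat("\nFinal-epoch history:\n")
  h <- object$history
  print(h[h$epoch == max(h$epoch), ], row.names = FALSE)
  invisible(object)
}

#' Accuracy/loss curves of a fitted run
#'
#' @param x a `fed_fit`.
#' @param ... unused.
#' @export
plot.fed_fit <- function(x, ...) {
  plot_history(x$history[x$history$scope == "global", ])
  invisible(x)
}

#' Predict with the trained global model of a run
#'
#' Applies the global client half plus server half to new images.
#'
#' @param object a `fed_fit`.
#' @param newdata an `image_set` with the run's training image size.
#' @param type `"prob"` (an `N x n_classes` matrix) or `"class"` (0-based
#'   indices).
#' @param ... unused.
#' @export
predict.fed_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  predict(compose(object$client, object$server), newdata, type = type)
}

#' Extract the per-epoch training history
#'
#' @param fit a `fed_fit`.
#' @param scope `"global"`, `"clients"` or `"all"`.
#' @export
fit_history <- function(fit, scope = c("all", "global", "clients")) {
  scope <- match.arg(scope)
  h <- fit$history
  switch(scope,
         all = h,
         global = h[h$scope == "global", ],
         clients = h[h$scope != "global", ])
}
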