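#' Classification metrics from predicted probabilities
#'
#' Predicted class is the row-wise argmax (ties break to the lowest
#' index). Precision and recall per class come from the confusion matrix
#' with 0/0 defined as 0; macro values are unweighted means over classes.
#' Loss is mean categorical cross-entropy of the true-class probability.
#'
#' @param pred_probs `batch x n_classes` matrix of nonnegative row scores
#'   (rows need not be normalized for the argmax, but the cross-entropy
#'   assumes probabilities).
#' @param labels 0-based integer labels, one per row.
#' @param n_classes number of classes; defaults to `ncol(pred_probs)`.
#' @return An object of class `metrics_report`: `accuracy`, `loss`,
#'   per-class and macro `precision`/`recall`, and the `confusion` matrix
#'   (rows = true class, columns = predicted, so row sums equal per-class
#'   support and accuracy is trace over total).
#' @examples
#' p <- matrix(c(0.9, 0.05, 0.05, 0.1, 0.8, 0.1), 2, 3, byrow = TRUE)
#' compute_metrics(p, c(0, 1))
#' @export
compute_metrics <- function(pred_probs, labels, n_classes = ncol(pred_probs)) {
  pred_probs <- as.matrix(pred_probs)
  labels <- as.integer(labels)
  if (nrow(pred_probs) < 1) stop("empty batch")
  if (length(labels) != nrow(pred_probs))
    stop("labels and pred_probs sizes differ")
  if (any(labels < 0L) || any(labels >= n_classes))
    stop("label out of range")
  if (any(pred_probs < 0)) stop("negative prediction scores")
  pred <- max.col(pred_probs, ties.method = "first") - 1L
  conf <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(labels))
    conf[labels[i] + 1L, pred[i] + 1L] <- conf[labels[i] + 1L, pred[i] + 1L] + 1L
  diagv <- diag(conf)
  rs <- rowSums(conf); cs <- colSums(conf)
  precision <- ifelse(cs > 0, diagv / cs, 0)
  recall <- ifelse(rs > 0, diagv / rs, 0)
  picked <- pred_probs[cbind(seq_along(labels), labels + 1L)]
  structure(list(
    accuracy = sum(diagv) / length(labels),
    loss = -mean(log(pmax(picked, 1e-12))),
    precision = precision, recall = recall,
    macro_precision = mean(precision), macro_recall = mean(recall),
    confusion = conf, support = rs
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  loss %.4f  macro precision %.4f  macro recall %.4f\n",
              x$accuracy, x$loss, x$macro_precision, x$macro_recall))
  cat("confusion (rows = true, cols = predicted):\n")
  print(x$confusion)
  invisible(x)
}

# numbers are serialized at full precision so a reload is exact and two
# runs with the same seed produce byte-identical files
format_history <- function(history) {
  out <- history
  for (nm in c("loss", "accuracy", "precision", "recall"))
    out[[nm]] <- sprintf("%.17g", history[[nm]])
  out
}

#' Write a training history to CSV files
#'
#' Writes `history.csv` (per-epoch global train/test metrics) and
#' `clients.csv` (per-client per-epoch rows) under `out_dir`, and
#' optionally a PNG of the accuracy and loss curves. Values are written at
#' full precision: reloading with [read_history()] reproduces them
#' exactly.
#'
#' @param history a `fed_fit` or its `history` data frame.
#' @param out_dir output directory (created if needed).
#' @param plots also write `curves.png`.
#' @return Paths of the files written, invisibly.
#' @export
report <- function(history, out_dir, plots = FALSE) {
  if (inherits(history, "fed_fit")) history <- history$history
  if (is.null(history) || !nrow(history)) stop("empty history")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  glob <- history[history$scope == "global", ]
  cli <- history[history$scope != "global", ]
  f1 <- file.path(out_dir, "history.csv")
  f2 <- file.path(out_dir, "clients.csv")
  utils::write.csv(format_history(glob), f1, row.names = FALSE)
  utils::write.csv(format_history(cli), f2, row.names = FALSE)
  files <- c(f1, f2)
  if (plots) {
    f3 <- file.path(out_dir, "curves.png")
    grDevices::png(f3, width = 900, height = 450)
    plot_history(glob)
    grDevices::dev.off()
    files <- c(files, f3)
  }
  invisible(files)
}

#' Reload a history CSV written by [report()]
#'
#' @param path path to `history.csv` or `clients.csv`.
#' @export
read_history <- function(path) {
  h <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("loss", "accuracy", "precision", "recall"))
    h[[nm]] <- as.numeric(h[[nm]])
  h
}

plot_history <- function(glob) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  tr <- glob[glob$split == "train", ]
  te <- glob[glob$split == "test", ]
  graphics::plot(tr$epoch, tr$accuracy, type = "l", col = "steelblue",
                 ylim = range(c(tr$accuracy, te$accuracy)),
                 xlab = "epoch", ylab = "accuracy", main = "Accuracy")
  graphics::lines(te$epoch, te$accuracy, col = "firebrick")
  graphics::legend("bottomright", c("train", "test"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::plot(tr$epoch, tr$loss, type = "l", col = "steelblue",
                 ylim = range(c(tr$loss, te$loss)),
                 xlab = "epoch", ylab = "loss", main = "Loss")
  graphics::lines(te$epoch, te$loss, col = "firebrick")
}
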