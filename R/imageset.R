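#' Labeled grayscale image set
#'
#' The universal dataset container of the package: a list of 2-D grayscale
#' matrices with pixel intensities in \[0, 1\], integer class labels, an
#' ordered vector of class names, and a per-image provenance flag
#' (`"real"` or `"synthetic"`).
#'
#' Labels are 0-based class indices into `class_names` (label `k` means
#' `class_names[k + 1]`), the convention used throughout for GAN
#' conditioning and the classifier output. The default class map for the
#' dementia MRI setting is `0 = "Mild Dementia"`, `1 = "Moderate Dementia"`,
#' `2 = "Non Dementia"`.
#'
#' @param images list of numeric matrices with values in \[0, 1\].
#' @param labels integer vector of 0-based class indices, one per image.
#' @param class_names character vector of class names, ordered by index.
#' @param provenance character vector (`"real"` or `"synthetic"`), recycled.
#' @return An object of class `image_set`.
#' @export
image_set <- function(images, labels,
                      class_names = c("Mild Dementia", "Moderate Dementia",
                                      "Non Dementia"),
                      provenance = "real") {
  labels <- as.integer(labels)
  if (length(images) != length(labels))
    stop("images and labels must have the same length")
  if (length(labels) && (min(labels) < 0L || max(labels) >= length(class_names)))
    stop("labels must be 0-based indices into class_names")
  rng <- range(unlist(lapply(images, range), use.names = FALSE), 0, 1)
  if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
    stop("pixel intensities must lie in [0, 1]")
  provenance <- rep(provenance, length.out = length(images))
  if (!all(provenance %in% c("real", "synthetic")))
    stop("provenance must be 'real' or 'synthetic'")
  structure(list(images = images, labels = labels,
                 class_names = class_names, provenance = provenance),
            class = "image_set")
}

#' @export
length.image_set <- function(x) length(x$images)

#' @export
print.image_set <- function(x, ...) {
  cd <- if (length(x)) class_distribution(x)
  cat("<image_set> ", length(x), " images, ",
      length(x$class_names), " classes\n", sep = "")
  if (length(x)) {
    d <- dim(x$images[[1]])
    cat("  size: ", d[1], "x", d[2],
        "  synthetic: ", sum(x$provenance == "synthetic"), "\n", sep = "")
    for (i in seq_along(x$class_names))
      cat(sprintf("  [%d] %-20s n = %5d  ratio = %.3f\n", i - 1L,
                  x$class_names[i], cd$counts[i], cd$ratios[i]))
  }
  invisible(x)
}

#' Subset an image set by index
#' @param x an `image_set`.
#' @param i integer indices.
#' @param ... unused.
#' @export
subset_images <- function(x, i, ...) {
  image_set(x$images[i], x$labels[i], x$class_names, x$provenance[i])
}

#' Combine image sets sharing one class map
#' @param ... `image_set` objects.
#' @export
bind_images <- function(...) {
  xs <- list(...)
  cn <- xs[[1]]$class_names
  for (x in xs) stopifnot(identical(x$class_names, cn))
  image_set(do.call(c, lapply(xs, `[[`, "images")),
            do.call(c, lapply(xs, `[[`, "labels")),
            cn,
            do.call(c, lapply(xs, `[[`, "provenance")))
}

#' Class imbalance ratio
#'
#' Ratio of minority-class to majority-class sample counts. 1 means balanced;
#' values near 0 indicate severe imbalance. For the 3-class dementia MRI
#' counts (896 Mild, 64 Moderate, 3200 Non) the ratios are 0.28 and 0.02.
#'
#' @param minority_count nonnegative integer.
#' @param majority_count positive integer, at least `minority_count`.
#' @return The ratio, a number in \[0, 1\].
#' @examples
#' imbalance_ratio(896, 3200)  # 0.28
#' imbalance_ratio(64, 3200)   # 0.02
#' @export
imbalance_ratio <- function(minority_count, majority_count) {
  if (majority_count == 0)
    stop("imbalance ratio undefined: majority_count is 0")
  if (minority_count < 0)
    stop("minority_count must be nonnegative")
  if (minority_count > majority_count)
    stop("argument order error: minority_count exceeds majority_count")
  minority_count / majority_count
}

#' Per-class counts and imbalance ratios
#'
#' @param dataset an `image_set`.
#' @return A list of class `class_distribution` with `counts` (named
#'   per-class sample counts) and `ratios` (each class's count divided by
#'   the majority class's count; the majority class has ratio 1).
#' @export
class_distribution <- function(dataset) {
  if (!length(dataset)) stop("empty dataset")
  k <- length(dataset$class_names)
  counts <- tabulate(dataset$labels + 1L, nbins = k)
  names(counts) <- dataset$class_names
  ratios <- counts / max(counts)
  structure(list(counts = counts, ratios = ratios),
            class = "class_distribution")
}

#' @export
print.class_distribution <- function(x, ...) {
  print(data.frame(count = x$counts, ratio = x$ratios))
  invisible(x)
}

#' Subsample a dataset, preserving the class imbalance ratio
#'
#' Draws `floor(fraction * n_c)` images uniformly without replacement within
#' each class `c`, so the between-class imbalance ratios are preserved up to
#' integer flooring. Flooring (rather than rounding) guarantees no minority
#' class is ever inflated.
#'
#' @param dataset an `image_set`.
#' @param fraction sampling fraction in (0, 1\].
#' @param seed integer seed; the same seed reproduces the same selection.
#' @export
subsample_preserving_ratio <- function(dataset, fraction, seed) {
  stopifnot(fraction > 0, fraction <= 1)
  cd <- class_distribution(dataset)
  keep <- floor(fraction * cd$counts)
  if (any(keep < 1)) {
    bad <- names(cd$counts)[keep < 1][1]
    stop("subsampling would empty class '", bad, "'")
  }
  with_seed(seed, {
    idx <- unlist(lapply(seq_along(cd$counts), function(i) {
      pool <- which(dataset$labels == i - 1L)
      sort(sample(pool, keep[i]))
    }))
    subset_images(dataset, idx)
  })
}

#' Stratified train/test split
#'
#' Per class, `round(train_fraction * n_c)` images go to the training set
#' and the rest to the test set; the two parts are disjoint and their union
#' is the input.
#'
#' @param dataset an `image_set`; every class needs at least 2 samples.
#' @param train_fraction fraction in (0, 1), default 0.8.
#' @param seed integer seed.
#' @return A list with elements `train` and `test`.
#' @export
stratified_split <- function(dataset, train_fraction = 0.8, seed) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  cd <- class_distribution(dataset)
  if (any(cd$counts < 2))
    stop("class '", names(cd$counts)[cd$counts < 2][1],
         "' has fewer than 2 samples")
  with_seed(seed, {
    tr <- logical(length(dataset))
    for (i in seq_along(cd$counts)) {
      pool <- which(dataset$labels == i - 1L)
      n_tr <- round(train_fraction * length(pool))
      tr[sample(pool, n_tr)] <- TRUE
    }
    list(train = subset_images(dataset, which(tr)),
         test = subset_images(dataset, which(!tr)))
  })
}

#' Partition a dataset into IID client shards
#'
#' Class-stratified partition: within each class, images are shuffled and
#' dealt round-robin to clients (a single dealing pointer runs across
#' classes, so total shard sizes differ by at most one). Shards are disjoint
#' and their union is the input; each shard's class proportions match the
#' global ones within one sample per class.
#'
#' @param dataset an `image_set` with at least `n_clients` images.
#' @param n_clients positive integer.
#' @param seed integer seed.
#' @return List of `n_clients` `image_set` shards.
#' @export
partition_clients <- function(dataset, n_clients, seed) {
  n_clients <- as.integer(n_clients)
  stopifnot(n_clients >= 1)
  if (n_clients > length(dataset))
    stop("more clients than samples")
  with_seed(seed, {
    assign_to <- integer(length(dataset))
    ptr <- 0L
    for (i in seq_along(dataset$class_names)) {
      pool <- which(dataset$labels == i - 1L)
      if (!length(pool)) next
      pool <- sample(pool)
      assign_to[pool] <- (ptr + seq_along(pool) - 1L) %% n_clients + 1L
      ptr <- (ptr + length(pool)) %% n_clients
    }
    lapply(seq_len(n_clients),
           function(k) subset_images(dataset, which(assign_to == k)))
  })
}

#' Read a class-per-folder image tree
#'
#' Expects `path/<class name>/*.png` (JPEG also accepted when EBImage can
#' decode it). Images are converted to grayscale by channel averaging and
#' clamped to \[0, 1\].
#'
#' @param path root directory; one subdirectory per class.
#' @param class_names optional explicit class ordering; defaults to sorted
#'   subdirectory names.
#' @export
read_image_dir <- function(path, class_names = NULL) {
  if (is.null(class_names))
    class_names <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  if (!length(class_names)) stop("no class subdirectories under ", path)
  images <- list(); labels <- integer(0)
  for (i in seq_along(class_names)) {
    files <- sort(list.files(file.path(path, class_names[i]),
                             pattern = "\\.(png|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE))
    for (f in files) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
        png::readPNG(f)
      } else {
        as.array(EBImage::readImage(f))
      }
      if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
      images[[length(images) + 1L]] <- pmin(pmax(img, 0), 1)
      labels <- c(labels, i - 1L)
    }
  }
  image_set(images, labels, class_names)
}

#' Write an image set as a class-per-folder PNG tree
#'
#' @param dataset an `image_set`.
#' @param path output root; class subdirectories are created.
#' @param manifest if `TRUE`, also writes `manifest.csv` (columns `path`,
#'   `label`, `provenance`) at the root.
#' @export
write_image_dir <- function(dataset, path, manifest = TRUE) {
  rows <- vector("list", length(dataset))
  for (i in seq_along(dataset$class_names)) {
    dir.create(file.path(path, dataset$class_names[i]),
               recursive = TRUE, showWarnings = FALSE)
  }
  for (j in seq_len(length(dataset))) {
    cls <- dataset$class_names[dataset$labels[j] + 1L]
    fn <- file.path(path, cls, sprintf("img_%05d.png", j))
    png::writePNG(dataset$images[[j]], fn)
    rows[[j]] <- data.frame(path = file.path(cls, basename(fn)),
                            label = dataset$labels[j],
                            provenance = dataset$provenance[j])
  }
  if (manifest)
    utils::write.csv(do.call(rbind, rows),
                     file.path(path, "manifest.csv"), row.names = FALSE)
  invisible(path)
}
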