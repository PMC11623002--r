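#' Augmentation configuration
#'
#' Controls the stochastic training-time transform chain: random resized
#' crop, horizontal/vertical flips, rotation, color jitter
#' (brightness/contrast for grayscale), random grayscale conversion (an
#' identity for already-grayscale input, kept as an explicit flag), and a
#' final fixed normalization. The transform kinds follow standard image
#' classification practice; magnitudes are configurable with moderate
#' defaults (rotation +/- 15 degrees, jitter 0.2, crop scale \[0.8, 1\]).
#'
#' @param output_size output side length in pixels (default 224).
#' @param random_resized_crop,horizontal_flip,vertical_flip,random_grayscale
#'   enable flags.
#' @param crop_scale area fraction range sampled by the random resized crop.
#' @param rotation_degrees maximal absolute rotation (>= 0).
#' @param color_jitter brightness/contrast jitter magnitude (0 disables).
#' @param normalize_mean,normalize_sd normalization constants applied last;
#'   the defaults 0.5/0.5 map \[0, 1\] grayscale onto \[-1, 1\].
#' @export
augmentation_config <- function(output_size = 224L,
                                random_resized_crop = TRUE,
                                crop_scale = c(0.8, 1.0),
                                horizontal_flip = TRUE,
                                vertical_flip = TRUE,
                                rotation_degrees = 15,
                                color_jitter = 0.2,
                                random_grayscale = TRUE,
                                normalize_mean = 0.5,
                                normalize_sd = 0.5) {
  stopifnot(output_size > 0, rotation_degrees >= 0, normalize_sd > 0)
  structure(list(output_size = as.integer(output_size),
                 random_resized_crop = random_resized_crop,
                 crop_scale = crop_scale,
                 horizontal_flip = horizontal_flip,
                 vertical_flip = vertical_flip,
                 rotation_degrees = rotation_degrees,
                 color_jitter = color_jitter,
                 random_grayscale = random_grayscale,
                 normalize_mean = normalize_mean,
                 normalize_sd = normalize_sd),
            class = "augmentation_config")
}

#' Build a seeded augmentation transform
#'
#' Returns a callable `function(image)` applying the configured chain with
#' its own private random stream: transforms built with the same seed
#' produce the same sequence of random decisions, and applying the
#' transform never disturbs the caller's RNG state.
#'
#' @param config an [augmentation_config()].
#' @param seed integer seed for the private stream.
#' @return A function mapping a grayscale matrix to an
#'   `output_size` x `output_size` matrix (normalized, so values may lie
#'   outside \[0, 1\]).
#' @export
build_augmentation <- function(config = augmentation_config(), seed = 1L) {
  stopifnot(inherits(config, "augmentation_config"))
  state <- with_seed(seed, get(".Random.seed", envir = globalenv()))
  function(image) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    apply_augmentation(image, config)
  }
}

apply_augmentation <- function(img, cfg) {
  h <- nrow(img); w <- ncol(img)
  if (cfg$random_resized_crop) {
    area <- stats::runif(1, cfg$crop_scale[1], cfg$crop_scale[2]) * h * w
    aspect <- stats::runif(1, 3 / 4, 4 / 3)
    ch <- min(h, max(8L, round(sqrt(area / aspect))))
    cw <- min(w, max(8L, round(sqrt(area * aspect))))
    top <- sample.int(h - ch + 1L, 1L)
    left <- sample.int(w - cw + 1L, 1L)
    img <- img[top:(top + ch - 1L), left:(left + cw - 1L)]
  }
  img <- resize_image(img, cfg$output_size)
  if (cfg$horizontal_flip && stats::runif(1) < 0.5)
    img <- img[, rev(seq_len(ncol(img)))]
  if (cfg$vertical_flip && stats::runif(1) < 0.5)
    img <- img[rev(seq_len(nrow(img))), ]
  if (cfg$rotation_degrees > 0) {
    ang <- stats::runif(1, -cfg$rotation_degrees, cfg$rotation_degrees)
    rot <- EBImage::rotate(EBImage::Image(img), ang, bg.col = 0,
                           output.dim = dim(img))
    img <- as.array(rot)
  }
  if (cfg$color_jitter > 0) {
    j <- cfg$color_jitter
    img <- img * stats::runif(1, 1 - j, 1 + j)                   # brightness
    m <- mean(img)
    img <- (img - m) * stats::runif(1, 1 - j, 1 + j) + m         # contrast
    img <- pmin(pmax(img, 0), 1)
  }
  if (cfg$random_grayscale && stats::runif(1) < 0.1) {
    img <- img  # input is single-channel; conversion is the identity
  }
  (img - cfg$normalize_mean) / cfg$normalize_sd
}
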