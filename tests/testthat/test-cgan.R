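sf <- asNamespace("splitfed")

test_that("generator and discriminator parameter tables match the reference architecture", {
  set.seed(1)
  pt_g <- param_table(build_generator(gan_spec()))
  counts <- setNames(pt_g$params, pt_g$layer)
  expect_identical(counts[["dense_latent"]], 413696L)
  expect_identical(counts[["dense_label"]], 208896L)
  expect_identical(counts[["tconv_1"]], 2112L)
  expect_identical(counts[["tconv_2"]], 1025L)

  pt_d <- param_table(build_discriminator(gan_spec()))
  counts <- setNames(pt_d$params, pt_d$layer)
  expect_identical(counts[["dense_label"]], 3342336L)
  expect_identical(counts[["conv_1"]], 2432L)
  for (i in 2:5) expect_identical(counts[[paste0("conv_", i)]], 147584L)
  expect_identical(counts[["dense_out"]], 8193L)
  # counts are reproducible from the spec alone
  set.seed(99)
  expect_identical(param_table(build_generator(gan_spec())), pt_g)
})

test_that("generator and discriminator forwards have the contracted shapes and ranges", {
  spec <- gan_spec(image_size = 32L)
  set.seed(2)
  g <- build_generator(spec)
  d <- build_discriminator(spec)
  lp <- generate_latent_points(100, 5, 3, seed = 3)
  expect_equal(dim(lp$z), c(5L, 100L))
  expect_true(all(lp$labels >= 0 & lp$labels < 3))
  img <- sf$generator_forward(g, lp$z, lp$labels)
  expect_equal(dim(img), c(32L, 32L, 1L, 5L))
  expect_lte(max(abs(img)), 1)              # tanh range
  p <- sf$discriminator_forward(d, img, lp$labels)
  expect_length(p, 5L)
  expect_true(all(p >= 0 & p <= 1))         # sigmoid range
  expect_error(gan_spec(image_size = 30L), "divisible by 4")
})

test_that("latent draws are seeded and class conditioning is honored", {
  a <- generate_latent_points(16, 10, 3, seed = 7)
  b <- generate_latent_points(16, 10, 3, seed = 7)
  expect_identical(a, b)
  fixed <- generate_latent_points(16, 6, 3, seed = 1, class_label = 2)
  expect_true(all(fixed$labels == 2L))
  expect_error(generate_latent_points(16, 2, 3, seed = 1, class_label = 5),
               "out of range")
})

test_that("adversarial objective has its analytic values and optima", {
  expect_equal(gan_objective(0.5, 0.5), 2 * log(0.5), tolerance = 1e-12)
  eps <- 1e-9
  expect_lt(gan_objective(1 - eps, eps), 0)
  expect_gt(gan_objective(1 - eps, eps), -1e-6)   # approaches 0 from below
  # equals negative binary cross-entropy with labels 1 (real) / 0 (fake)
  set.seed(5)
  pr <- runif(20, 0.05, 0.95); pf <- runif(20, 0.05, 0.95)
  bce <- -(mean(log(pr)) + mean(log(1 - pf)))
  expect_equal(gan_objective(pr, pf), -bce)
  # monotone: maximized over d_real at 1, over d_fake at 0
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(vapply(grid, gan_objective, numeric(1),
                              d_fake = 0.3)) > 0))
  expect_true(all(diff(vapply(grid, gan_objective, numeric(1),
                              d_real = 0.7)) < 0))
  expect_error(gan_objective(numeric(0), 0.5), "empty")
  # generator losses: non-saturating vs saturating forms
  expect_equal(generator_loss(c(0.5, 0.5)), -log(0.5))
  expect_equal(generator_loss(c(0.5, 0.5), saturating = TRUE), log(0.5))
})

test_that("training runs to schedule, is seeded, and freezes the discriminator in generator steps", {
  x <- generate_phantom_dataset(
    phantom_spec(image_size = 16L, n_per_class = c(4, 4), seed = 1))
  spec <- gan_spec(image_size = 16L, n_classes = 2L, base_channels = 8L)
  fit <- train_cgan(x, spec, n_epochs = 2, n_batch = 8, seed = 11)
  expect_s3_class(fit, "cgan")
  expect_equal(nrow(fit$log), 2L)
  expect_true(all(is.finite(unlist(fit$log))))
  expect_true(all(fit$log$acc_real >= 0 & fit$log$acc_real <= 1))
  # identical call, identical log
  fit2 <- train_cgan(x, spec, n_epochs = 2, n_batch = 8, seed = 11)
  expect_identical(fit$log, fit2$log)
  expect_error(train_cgan(x, spec, n_batch = 99, seed = 1), "exceeds")
  expect_error(train_cgan(x, gan_spec(image_size = 32L, n_classes = 2L),
                          seed = 1), "does not match")

  # a generator-only step must leave discriminator weights untouched
  set.seed(3)
  g <- build_generator(spec)
  d <- build_discriminator(spec)
  before <- get_weights(sf$discriminator_layers(d))
  sf$gen_train_batch(g, d, sf$new_adam(2e-4, 0.5), 8L)
  after <- get_weights(sf$discriminator_layers(d))
  expect_equal(weights_max_diff(before, after), 0)
})

test_that("synthesis returns rescaled, provenance-flagged images of the requested class", {
  x <- generate_phantom_dataset(
    phantom_spec(image_size = 16L, n_per_class = c(4, 4), seed = 1))
  spec <- gan_spec(image_size = 16L, n_classes = 2L, base_channels = 8L)
  gan <- train_cgan(x, spec, n_epochs = 1, n_batch = 8, seed = 11)
  syn <- synthesize(gan, 1L, 10, seed = 5)
  expect_equal(length(syn), 10L)
  expect_true(all(syn$labels == 1L))
  expect_true(all(syn$provenance == "synthetic"))
  expect_equal(dim(syn$images[[1]]), c(16L, 16L))
  rng <- range(unlist(syn$images))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
  # rescaling is the affine inverse of the tanh mapping
  expect_true(all(abs(unlist(syn$images) * 2 - 1) <= 1))
  expect_error(synthesize(gan, 7L, 1, seed = 1), "out of range")
  # simulate() is the S3 face of synthesize()
  sim <- simulate(gan, nsim = 3, seed = 5, class_label = 1L)
  expect_identical(sim$images, synthesize(gan, 1L, 3, seed = 5)$images)

  # checkpoint round trip
  path <- withr::local_tempfile(fileext = ".rds")
  save_gan(gan, path)
  gan2 <- load_gan(path)
  expect_identical(synthesize(gan2, 1L, 2, seed = 9)$images,
                   synthesize(gan, 1L, 2, seed = 9)$images)
})
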