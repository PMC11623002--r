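# Scaled-down study conditions used by the end-to-end pipeline checks:
# phantom dataset of 800/224/16 images per class at 64x64, an 80/20
# stratified split, two IID client shards, 5 global epochs of SFL
# (batch 64, Adam 1e-4), cGAN rebalancing to target ratio 0.5 with the
# GAN pre-trained on the training split's minority classes.
PIPE_SEED <- 2024L
PIPE_EPOCHS <- 5L
GAN_EPOCHS <- 60L
AUG_SEEDS <- c(101L, 102L, 103L)

# recall over the two minority classes (unweighted mean), the quantity the
# augmentation is meant to move
minority_recall <- function(fit, test) {
  pred <- predict(fit, test, type = "class")
  mean(vapply(1:2, function(k) {
    idx <- test$labels == k
    mean(pred[idx] == k)
  }, numeric(1)))
}

pipeline_env <- new.env()

pipeline_data <- function() {
  if (is.null(pipeline_env$data)) {
    ph <- generate_phantom_dataset(phantom_spec(seed = PIPE_SEED))
    sp <- stratified_split(ph, 0.8, seed = PIPE_SEED)
    shards <- partition_clients(sp$train, 2, seed = PIPE_SEED)
    pipeline_env$data <- list(split = sp, shards = shards)
  }
  pipeline_env$data
}

pipeline_unaug <- function() {
  if (is.null(pipeline_env$unaug)) {
    d <- pipeline_data()
    cfg <- training_config("sfl", epochs = PIPE_EPOCHS, seed = AUG_SEEDS[1])
    pipeline_env$unaug <- run_sfl(cfg, d$shards, d$split$test)
  }
  pipeline_env$unaug
}

pipeline_gan <- function() {
  if (is.null(pipeline_env$gan)) {
    d <- pipeline_data()
    minority <- subset_images(d$split$train,
                              which(d$split$train$labels > 0L))
    pipeline_env$gan <- train_cgan(minority, gan_spec(image_size = 64L),
                                   n_epochs = GAN_EPOCHS, n_batch = 128L,
                                   seed = PIPE_SEED)
  }
  pipeline_env$gan
}

pipeline_aug_fits <- function() {
  if (is.null(pipeline_env$aug)) {
    d <- pipeline_data()
    gan <- pipeline_gan()
    pipeline_env$aug <- lapply(AUG_SEEDS, function(s) {
      sh <- augment_minority(d$shards, gan, target_ratio = 0.5, seed = s)
      run_sfl(training_config("sfl", epochs = PIPE_EPOCHS, seed = s),
              sh, d$split$test)
    })
  }
  pipeline_env$aug
}
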