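# Collaborative training protocols over client data shards:
#   SFL -- each client trains its half of the split network against a
#          shared server half (smashed-data / gradient exchange), and the
#          client halves are federally averaged each round;
#   FL  -- each client trains a full local copy of the composed model for
#          one local epoch, and all weights are federally averaged;
#   SL  -- clients are processed sequentially against a shared server half,
#          with the client half relayed from client to client (no
#          averaging);
#   centralized -- the composed model trained on pooled data, the reference
#          all three protocols collapse to when there is a single client.

#' Training configuration
#'
#' Defaults mirror the study configuration: Adam, batch size 64, learning
#' rate 1e-4, 50 epochs, 3 classes, 2 clients, ResNet18-style model,
#' categorical cross-entropy.
#'
#' @param mode one of `"sfl"`, `"fl"`, `"sl"`.
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size for all model parts.
#' @param epochs global training rounds.
#' @param n_classes number of classes.
#' @param n_clients number of simulated clients.
#' @param frac fraction of clients participating per round (in (0, 1\];
#'   `frac * n_clients >= 1`); with `frac = 1` every client participates
#'   and selection consumes no randomness.
#' @param dropout dropout probability at the cut layer.
#' @param seed integer seed governing every random choice of the run.
#' @param augment optional [augmentation_config()] applied to training
#'   images each epoch (test data are only resized/normalized); `NULL`
#'   disables augmentation.
#' @param optimizer,model,loss descriptive fields (only the defaults —
#'   `"adam"`, `"resnet18"`, categorical cross-entropy — are implemented).
#' @export
training_config <- function(mode = c("sfl", "fl", "sl"),
                            batch_size = 64L, learning_rate = 1e-4,
                            epochs = 50L, n_classes = 3L, n_clients = 2L,
                            frac = 1.0, dropout = 0.5, seed = 1L,
                            augment = NULL,
                            optimizer = "adam", model = "resnet18",
                            loss = "categorical cross entropy") {
  mode <- match.arg(mode)
  stopifnot(frac > 0, frac <= 1, frac * n_clients >= 1,
            batch_size >= 1, epochs >= 1)
  structure(list(mode = mode, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 n_classes = as.integer(n_classes),
                 n_clients = as.integer(n_clients), frac = frac,
                 dropout = dropout, seed = as.integer(seed),
                 augment = augment, optimizer = optimizer, model = model,
                 loss = loss),
            class = "training_config")
}

#' Federated averaging of weight collections
#'
#' Unweighted element-wise arithmetic mean of every parameter array
#' (including batch-norm running statistics) across clients.
#'
#' @param weight_sets nonempty list of weight collections as returned by
#'   the package's internal `get_weights()`; all must have congruent
#'   shapes.
#' @return The averaged weight collection.
#' @export
fedavg <- function(weight_sets) {
  if (!length(weight_sets)) stop("fedavg needs at least one weight set")
  k <- length(weight_sets)
  out <- weight_sets[[1]]
  for (i in seq_along(out)) {
    for (nm in names(out[[i]])) {
      arrs <- lapply(weight_sets, function(w) w[[i]][[nm]])
      ref <- dim(arrs[[1]])
      for (a in arrs)
        if (!identical(dim(a), ref) || length(a) != length(arrs[[1]]))
          stop("shape mismatch in fedavg")
      out[[i]][[nm]] <- Reduce(`+`, arrs) / k
    }
  }
  out
}

#' Randomly select participating clients
#'
#' Selects `m = max(1, round(frac * n_clients))` distinct client indices
#' uniformly without replacement. With `frac = 1` all clients are returned
#' deterministically.
#'
#' @param n_clients number of clients.
#' @param frac participation fraction in (0, 1\].
#' @param seed integer seed.
#' @return Sorted integer vector of client indices (1-based).
#' @export
select_clients <- function(n_clients, frac, seed) {
  with_seed(seed, select_clients_rng(n_clients, frac))
}

select_clients_rng <- function(n_clients, frac) {
  stopifnot(frac > 0, frac <= 1)
  m <- max(1L, as.integer(round(frac * n_clients)))
  if (m >= n_clients) return(seq_len(n_clients))
  sort(sample.int(n_clients, m))
}

# one pass over a shard: shuffle, iterate mini-batches through step_fn,
# accumulate loss and the confusion matrix from the returned predictions
local_pass <- function(step_fn, x, labels, batch_size, n_classes) {
  n <- dim(x)[4]
  idx <- sample.int(n)
  batches <- split(idx, ceiling(seq_along(idx) / batch_size))
  loss <- 0
  conf <- matrix(0, n_classes, n_classes)
  for (b in batches) {
    r <- step_fn(x[, , , b, drop = FALSE], labels[b])
    loss <- loss + r$loss * length(b)
    pred <- max.col(t(r$probs), ties.method = "first") - 1L
    for (i in seq_along(b))
      conf[labels[b[i]] + 1L, pred[i] + 1L] <-
        conf[labels[b[i]] + 1L, pred[i] + 1L] + 1L
  }
  summarize_confusion(conf, loss / n)
}

summarize_confusion <- function(conf, loss) {
  diagv <- diag(conf)
  rs <- rowSums(conf); cs <- colSums(conf)
  prec <- ifelse(cs > 0, diagv / cs, 0)
  rec <- ifelse(rs > 0, diagv / rs, 0)
  list(loss = loss, accuracy = sum(diagv) / sum(conf),
       precision = mean(prec), recall = mean(rec), confusion = conf)
}

# batched eval of a client/server pair on a tensor
evaluate_split <- function(cnet, snet, tensor, batch_size, n_classes) {
  n <- dim(tensor$x)[4]
  batches <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  loss <- 0
  conf <- matrix(0, n_classes, n_classes)
  for (b in batches) {
    sb <- forward_client(cnet, list(x = tensor$x[, , , b, drop = FALSE],
                                    labels = tensor$labels[b]),
                         training = FALSE)
    pk <- server_step(snet, sb, training = FALSE)
    loss <- loss + pk$loss * length(b)
    pred <- max.col(t(pk$probs), ties.method = "first") - 1L
    for (i in seq_along(b))
      conf[tensor$labels[b[i]] + 1L, pred[i] + 1L] <-
        conf[tensor$labels[b[i]] + 1L, pred[i] + 1L] + 1L
  }
  summarize_confusion(conf, loss / n)
}

history_row <- function(epoch, scope, split, m) {
  data.frame(epoch = epoch, scope = scope, split = split, loss = m$loss,
             accuracy = m$accuracy, precision = m$precision,
             recall = m$recall)
}

# build per-epoch augmented tensors, or fixed tensors when augment is NULL
shard_tensor <- function(shard, augment_fn, cfg) {
  if (is.null(augment_fn)) return(to_tensor(shard))
  imgs <- lapply(shard$images, augment_fn)
  d <- dim(imgs[[1]])
  list(x = array(unlist(imgs), dim = c(d[1], d[2], 1L, length(imgs))),
       labels = shard$labels)
}

prepare_test_tensor <- function(test, config) {
  if (is.null(config$augment)) return(to_tensor(test))
  sz <- config$augment$output_size
  imgs <- lapply(test$images, function(im)
    (resize_image(im, sz) - config$augment$normalize_mean) /
      config$augment$normalize_sd)
  list(x = array(unlist(imgs), dim = c(sz, sz, 1L, length(imgs))),
       labels = test$labels)
}

new_fit <- function(mode, config, history, client, server, test_metrics,
                    class_names) {
  structure(list(mode = mode, config = config,
                 history = do.call(rbind, history),
                 client = client, server = server,
                 test_metrics = test_metrics, class_names = class_names),
            class = "fed_fit")
}

#' Split federated learning
#'
#' The SFL loop: per global round, participating clients are selected and
#' each trains its client half locally (client forward, shared-server step,
#' client backward from the returned cut gradient, batch by batch); the
#' server half is shared and updated sequentially across clients within the
#' round; after all clients finish, their client-half weights are federally
#' averaged and installed as the new global client model, which is then
#' evaluated with the server half on the test set.
#'
#' A client's optimizer state persists across rounds unless aggregation
#' actually replaced its weights (more than one participant), in which case
#' stale Adam moments are discarded.
#'
#' @param config a [training_config()].
#' @param shards list of `n_clients` training `image_set` shards.
#' @param test test `image_set` (never augmented or rebalanced).
#' @return An object of class `fed_fit`.
#' @export
run_sfl <- function(config, shards, test) {
  stopifnot(inherits(config, "training_config"),
            length(shards) == config$n_clients)
  for (s in shards) if (!length(s)) stop("empty client shard")
  with_seed(config$seed, {
    cglob <- client_net(config$dropout, config$learning_rate)
    serv <- server_net(config$n_classes, config$learning_rate)
    aug <- if (!is.null(config$augment))
      build_augmentation(config$augment, seed = sample.int(2^31 - 1, 1))
    # clones, not fresh builds: copying weights must not consume RNG
    clients <- lapply(seq_len(config$n_clients), function(k) {
      structure(list(layers = clone_layers(cglob$layers),
                     opt = new_adam(config$learning_rate)),
                class = "client_net")
    })
    fixed <- if (is.null(aug)) lapply(shards, to_tensor)
    test_tensor <- prepare_test_tensor(test, config)
    history <- list()
    m_prev <- 1L
    for (ep in seq_len(config$epochs)) {
      sel <- select_clients_rng(config$n_clients, config$frac)
      w_locals <- list()
      train_loss <- 0; train_n <- 0
      conf <- matrix(0, config$n_classes, config$n_classes)
      for (k in sel) {
        cnet <- clients[[k]]
        set_weights(cnet$layers, get_weights(cglob$layers))
        if (m_prev > 1L) reset_opt_state(cnet$layers)
        tens <- if (is.null(aug)) fixed[[k]]
        else shard_tensor(shards[[k]], aug, config)
        m <- local_pass(function(xb, yb) {
          sb <- forward_client(cnet, list(x = xb, labels = yb), TRUE)
          pk <- server_step(serv, sb, TRUE)
          client_backward(cnet, sb, pk)
          pk
        }, tens$x, tens$labels, config$batch_size, config$n_classes)
        history[[length(history) + 1L]] <-
          history_row(ep, paste0("client_", k), "train", m)
        nk <- length(tens$labels)
        train_loss <- train_loss + m$loss * nk
        train_n <- train_n + nk
        conf <- conf + m$confusion
        w_locals[[length(w_locals) + 1L]] <- get_weights(cnet$layers)
      }
      set_weights(cglob$layers, fedavg(w_locals))
      m_prev <- length(w_locals)
      history[[length(history) + 1L]] <-
        history_row(ep, "global", "train",
                    summarize_confusion(conf, train_loss / train_n))
      te <- evaluate_split(cglob, serv, test_tensor, config$batch_size,
                           config$n_classes)
      history[[length(history) + 1L]] <- history_row(ep, "global", "test", te)
    }
    clear_caches(cglob$layers); clear_caches(serv$layers)
    for (cl in clients) clear_caches(cl$layers)
    new_fit("sfl", config, history, cglob, serv, te, test$class_names)
  })
}

#' Federated learning baseline
#'
#' Each participating client trains a full local copy of the composed
#' model for one local epoch; all local weights (both halves) are
#' federally averaged into the global model each round.
#'
#' @inheritParams run_sfl
#' @return A `fed_fit`.
#' @export
run_fl <- function(config, shards, test) {
  stopifnot(inherits(config, "training_config"),
            length(shards) == config$n_clients)
  for (s in shards) if (!length(s)) stop("empty client shard")
  with_seed(config$seed, {
    cglob <- client_net(config$dropout, config$learning_rate)
    serv <- server_net(config$n_classes, config$learning_rate)
    glob <- compose(cglob, serv)
    aug <- if (!is.null(config$augment))
      build_augmentation(config$augment, seed = sample.int(2^31 - 1, 1))
    locals <- lapply(seq_len(config$n_clients), function(k) {
      compose(structure(list(layers = clone_layers(cglob$layers),
                             opt = new_adam(config$learning_rate)),
                        class = "client_net"),
              structure(list(layers = clone_layers(serv$layers),
                             n_classes = serv$n_classes,
                             opt = new_adam(config$learning_rate)),
                        class = "server_net"))
    })
    fixed <- if (is.null(aug)) lapply(shards, to_tensor)
    test_tensor <- prepare_test_tensor(test, config)
    history <- list()
    m_prev <- 1L
    for (ep in seq_len(config$epochs)) {
      sel <- select_clients_rng(config$n_clients, config$frac)
      w_locals <- list()
      train_loss <- 0; train_n <- 0
      conf <- matrix(0, config$n_classes, config$n_classes)
      for (k in sel) {
        loc <- locals[[k]]
        set_weights(composed_layers(loc), get_weights(composed_layers(glob)))
        if (m_prev > 1L) {
          reset_opt_state(loc$client$layers)
          reset_opt_state(loc$server$layers)
        }
        tens <- if (is.null(aug)) fixed[[k]]
        else shard_tensor(shards[[k]], aug, config)
        m <- local_pass(function(xb, yb) composed_train_step(loc, xb, yb),
                        tens$x, tens$labels, config$batch_size,
                        config$n_classes)
        history[[length(history) + 1L]] <-
          history_row(ep, paste0("client_", k), "train", m)
        nk <- length(tens$labels)
        train_loss <- train_loss + m$loss * nk
        train_n <- train_n + nk
        conf <- conf + m$confusion
        w_locals[[length(w_locals) + 1L]] <- get_weights(composed_layers(loc))
      }
      set_weights(composed_layers(glob), fedavg(w_locals))
      m_prev <- length(w_locals)
      history[[length(history) + 1L]] <-
        history_row(ep, "global", "train",
                    summarize_confusion(conf, train_loss / train_n))
      te <- evaluate_split(cglob, serv, test_tensor, config$batch_size,
                           config$n_classes)
      history[[length(history) + 1L]] <- history_row(ep, "global", "test", te)
    }
    clear_caches(composed_layers(glob))
    for (loc in locals) clear_caches(composed_layers(loc))
    new_fit("fl", config, history, cglob, serv, te, test$class_names)
  })
}

#' Split learning baseline
#'
#' Clients are processed sequentially against the shared server half; the
#' single client half (with its optimizer state) is relayed from client to
#' client, with no averaging.
#'
#' @inheritParams run_sfl
#' @return A `fed_fit`.
#' @export
run_sl <- function(config, shards, test) {
  stopifnot(inherits(config, "training_config"),
            length(shards) == config$n_clients)
  for (s in shards) if (!length(s)) stop("empty client shard")
  with_seed(config$seed, {
    cnet <- client_net(config$dropout, config$learning_rate)
    serv <- server_net(config$n_classes, config$learning_rate)
    aug <- if (!is.null(config$augment))
      build_augmentation(config$augment, seed = sample.int(2^31 - 1, 1))
    fixed <- if (is.null(aug)) lapply(shards, to_tensor)
    test_tensor <- prepare_test_tensor(test, config)
    history <- list()
    for (ep in seq_len(config$epochs)) {
      sel <- select_clients_rng(config$n_clients, config$frac)
      train_loss <- 0; train_n <- 0
      conf <- matrix(0, config$n_classes, config$n_classes)
      for (k in sel) {
        tens <- if (is.null(aug)) fixed[[k]]
        else shard_tensor(shards[[k]], aug, config)
        m <- local_pass(function(xb, yb) {
          sb <- forward_client(cnet, list(x = xb, labels = yb), TRUE)
          pk <- server_step(serv, sb, TRUE)
          client_backward(cnet, sb, pk)
          pk
        }, tens$x, tens$labels, config$batch_size, config$n_classes)
        history[[length(history) + 1L]] <-
          history_row(ep, paste0("client_", k), "train", m)
        nk <- length(tens$labels)
        train_loss <- train_loss + m$loss * nk
        train_n <- train_n + nk
        conf <- conf + m$confusion
      }
      history[[length(history) + 1L]] <-
        history_row(ep, "global", "train",
                    summarize_confusion(conf, train_loss / train_n))
      te <- evaluate_split(cnet, serv, test_tensor, config$batch_size,
                           config$n_classes)
      history[[length(history) + 1L]] <- history_row(ep, "global", "test", te)
    }
    clear_caches(cnet$layers); clear_caches(serv$layers)
    new_fit("sl", config, history, cnet, serv, te, test$class_names)
  })
}

#' Centralized reference training of the composed model
#'
#' Trains the full (composed) network on pooled data with the same inner
#' loop as the collaborative protocols; all three protocols collapse to
#' this when run with a single client holding all data.
#'
#' @param config a [training_config()] (mode is ignored).
#' @param train,test training and test `image_set`s.
#' @return A `fed_fit` with mode `"centralized"`.
#' @export
centralized_train <- function(config, train, test) {
  stopifnot(inherits(config, "training_config"))
  with_seed(config$seed, {
    cnet <- client_net(config$dropout, config$learning_rate)
    serv <- server_net(config$n_classes, config$learning_rate)
    model <- compose(cnet, serv)
    aug <- if (!is.null(config$augment))
      build_augmentation(config$augment, seed = sample.int(2^31 - 1, 1))
    fixed <- if (is.null(aug)) to_tensor(train)
    test_tensor <- prepare_test_tensor(test, config)
    history <- list()
    for (ep in seq_len(config$epochs)) {
      tens <- if (is.null(aug)) fixed else shard_tensor(train, aug, config)
      m <- local_pass(function(xb, yb) composed_train_step(model, xb, yb),
                      tens$x, tens$labels, config$batch_size,
                      config$n_classes)
      history[[length(history) + 1L]] <- history_row(ep, "global", "train", m)
      te <- evaluate_split(cnet, serv, test_tensor, config$batch_size,
                           config$n_classes)
      history[[length(history) + 1L]] <- history_row(ep, "global", "test", te)
    }
    clear_caches(cnet$layers); clear_caches(serv$layers)
    new_fit("centralized", config, history, cnet, serv, te,
            test$class_names)
  })
}

#' Train under a collaborative protocol
#'
#' Front end dispatching on `config$mode` to [run_sfl()], [run_fl()] or
#' [run_sl()].
#'
#' @inheritParams run_sfl
#' @return A `fed_fit`.
#' @export
fed_train <- function(config, shards, test) {
  switch(config$mode,
         sfl = run_sfl(config, shards, test),
         fl = run_fl(config, shards, test),
         sl = run_sl(config, shards, test))
}

#' Rebalance client shards with GAN-synthesized minority images
#'
#' Per client and per minority class, synthesizes enough images to raise
#' that client's class imbalance ratio to `min(target_ratio, 1)` (target
#' count `ceiling(target_ratio x majority count)`), passes them through
#' the enhancement chain (CLAHE, then resizing to the shard's image size),
#' and appends them with provenance `"synthetic"`. Test data must never be
#' augmented; only pass training shards.
#'
#' @param shards list of training `image_set` shards.
#' @param gan a trained `cgan` whose image size matches the shards after
#'   enhancement resizing.
#' @param target_ratio desired minority-to-majority ratio (default 0.5;
#'   full balance at 1 risks overfitting to synthetic data).
#' @param seed integer seed.
#' @param config an [enhance_config()]; its `target_size` defaults to the
#'   shards' image size.
#' @return The augmented list of shards.
#' @export
augment_minority <- function(shards, gan, target_ratio = 0.5, seed = 1L,
                             config = NULL) {
  stopifnot(inherits(gan, "cgan"), target_ratio > 0)
  target_ratio <- min(target_ratio, 1)
  if (is.null(config))
    config <- enhance_config(target_size = nrow(shards[[1]]$images[[1]]))
  with_seed(seed, {
    out <- vector("list", length(shards))
    for (k in seq_along(shards)) {
      shard <- shards[[k]]
      cd <- class_distribution(shard)
      target <- ceiling(target_ratio * max(cd$counts))
      changed <- FALSE
      for (cls in which(cd$counts < target)) {
        n_new <- target - cd$counts[cls]
        syn <- synthesize(gan, cls - 1L, n_new,
                          seed = sample.int(2^31 - 1, 1))
        syn$class_names <- shard$class_names
        shard <- bind_images(shard, enhance_batch(syn, config))
        changed <- TRUE
      }
      if (!changed)
        warning("shard ", k, ": target_ratio not above current ratios; ",
                "no images added")
      out[[k]] <- shard
    }
    out
  })
}
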