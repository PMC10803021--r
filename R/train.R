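# Training protocol: focal-loss optimisation with AdamW at initial learning
# rate 1e-3, plateau-based learning-rate decay monitoring validation mIoU,
# 100 epochs with validation every 2 epochs, the 5 best parameter snapshots
# retained, and test metrics averaged over the retained checkpoints'
# predictions.

#' Training configuration
#'
#' @param epochs training epochs (default 100).
#' @param lr initial AdamW learning rate (default 1e-3).
#' @param weight_decay AdamW decoupled weight decay (default 1e-2).
#' @param betas,eps AdamW moment coefficients and stabiliser.
#' @param batch_size images per optimisation step.
#' @param val_every validate every this many epochs (default 2).
#' @param top_k_checkpoints parameter snapshots retained, ranked by
#'   validation mIoU (default 5).
#' @param plateau_factor,plateau_patience,min_lr plateau scheduler: multiply
#'   the learning rate by `plateau_factor` after `plateau_patience`
#'   validations without mIoU improvement, never below `min_lr`.
#' @param gamma,alpha focal-loss parameters (defaults 2 and 0.25).
#' @param max_steps optional cap on total optimisation steps (useful for
#'   smoke runs); `Inf` trains for the full epoch budget.
#' @param mixed_precision accepted for protocol compatibility; computation
#'   is double precision regardless.
#' @param reader_threads accepted for protocol compatibility; reading is
#'   sequential.
#' @param seed seed for shuffling and any stochastic component.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100L, lr = 1e-3, weight_decay = 1e-2,
                         betas = c(0.9, 0.999), eps = 1e-8,
                         batch_size = 8L, val_every = 2L,
                         top_k_checkpoints = 5L,
                         plateau_factor = 0.5, plateau_patience = 5L,
                         min_lr = 1e-6, gamma = 2, alpha = 0.25,
                         max_steps = Inf, mixed_precision = FALSE,
                         reader_threads = 16L, seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), lr = lr, weight_decay = weight_decay,
              betas = betas, eps = eps, batch_size = as.integer(batch_size),
              val_every = as.integer(val_every),
              top_k_checkpoints = as.integer(top_k_checkpoints),
              plateau_factor = plateau_factor,
              plateau_patience = as.integer(plateau_patience),
              min_lr = min_lr, gamma = gamma, alpha = alpha,
              max_steps = max_steps, mixed_precision = isTRUE(mixed_precision),
              reader_threads = as.integer(reader_threads),
              seed = as.integer(seed))
  if (cfg$epochs < 1L) stop("epochs must be >= 1")
  if (cfg$val_every < 1L) stop("val_every must be >= 1")
  if (cfg$top_k_checkpoints < 1L) stop("top_k_checkpoints must be >= 1")
  structure(cfg, class = "train_config")
}

# ---- AdamW ----

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, cfg) {
  b1 <- cfg$betas[1L]; b2 <- cfg$betas[2L]
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      lr * (mh / (sqrt(vh) + cfg$eps) + cfg$weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

# ---- ReduceLROnPlateau (mode "max") ----

plateau_init <- function(lr, factor, patience, min_lr) {
  list(lr = lr, factor = factor, patience = patience, min_lr = min_lr,
       best = -Inf, bad = 0L)
}

plateau_update <- function(st, metric) {
  if (metric > st$best + 1e-8) {
    st$best <- metric
    st$bad <- 0L
  } else {
    st$bad <- st$bad + 1L
    if (st$bad > st$patience) {
      st$lr <- max(st$lr * st$factor, st$min_lr)
      st$bad <- 0L
    }
  }
  st
}

# ---- top-k checkpoint set, ranked by validation mIoU ----

#' Insert a snapshot into a top-k checkpoint set
#'
#' Keeps at most `k` entries sorted by decreasing validation mIoU; an
#' incoming snapshot displaces the worst retained one only if it scores
#' higher, so the set never holds a snapshot worse than one it discarded.
#'
#' @param set list of checkpoint entries (possibly empty).
#' @param entry list with at least `miou` and `epoch` fields.
#' @param k maximum number of retained snapshots.
#' @return The updated list.
#' @export
checkpoint_insert <- function(set, entry, k) {
  set <- c(set, list(entry))
  ord <- order(vapply(set, `[[`, numeric(1L), "miou"), decreasing = TRUE)
  set[ord][seq_len(min(length(set), k))]
}

# ---- data access ----

load_batch <- function(manifest, rows, cache = NULL) {
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    r <- rows[i]
    out[[i]] <- if (!is.null(cache)) cache[[r]] else
      load_pair(manifest$image_path[r], manifest$mask_path[r])
  }
  out
}

batch_matrices <- function(pairs) {
  st <- stack_images(lapply(pairs, `[[`, "image"))
  st$target <- unlist(lapply(pairs, function(p) as.integer(p$mask)), use.names = FALSE)
  st
}

# confusion over a set of manifest rows, eval mode
eval_confusion <- function(model, manifest, rows, k, cache = NULL, batch = 4L) {
  cm <- matrix(0L, k + 1L, k + 1L)
  for (chunk in split(rows, ceiling(seq_along(rows) / batch))) {
    pairs <- load_batch(manifest, chunk, cache)
    preds <- predict_masks(model, lapply(pairs, `[[`, "image"))
    for (i in seq_along(pairs)) {
      cm <- cm + confusion_matrix(preds[[i]], pairs[[i]]$mask, k)
    }
  }
  dimnames(cm) <- list(truth = 0:k, pred = 0:k)
  cm
}

#' Train the segmentation model
#'
#' Runs focal-loss optimisation with AdamW over the training split,
#' validates mean IoU on the validation split every `val_every` epochs,
#' keeps the `top_k_checkpoints` best parameter snapshots, and decays the
#' learning rate on validation plateaus. Aborts with a diagnostic if the
#' loss turns non-finite.
#'
#' @param model an `endoseg_model` from [build_model()].
#' @param manifest dataset manifest (data.frame with `image_path`,
#'   `mask_path`), or a list of in-memory `list(image, mask)` pairs.
#' @param split an [split_dataset()] result; `NULL` trains on everything and
#'   validates on the training images (smoke-run mode).
#' @param config a [train_config()].
#' @param rundir optional directory for the training log, checkpoints and
#'   config copy.
#' @param quiet suppress per-validation progress lines.
#' @return An `endoseg_run`: list with the trained `model`, `checkpoints`
#'   (top-k snapshots with `miou` and `epoch`), and `log` (data.frame per
#'   logged event: epoch, step, loss, lr, val_miou).
#' @export
train <- function(model, manifest, split = NULL, config = train_config(),
                  rundir = NULL, quiet = TRUE) {
  stopifnot(inherits(model, "endoseg_model"), inherits(config, "train_config"))
  in_memory <- is.list(manifest) && !is.data.frame(manifest)
  cache <- NULL
  if (in_memory) {
    cache <- manifest
    manifest <- data.frame(image_path = sprintf("mem:%d", seq_along(cache)),
                           mask_path = sprintf("mem:%d", seq_along(cache)))
  } else if (nrow(manifest) <= 64L) {
    cache <- lapply(seq_len(nrow(manifest)), function(i) {
      load_pair(manifest$image_path[i], manifest$mask_path[i])
    })
  }
  n <- nrow(manifest)
  if (n == 0L) stop("empty manifest")
  train_rows <- if (is.null(split)) seq_len(n) else split$train
  val_rows <- if (is.null(split)) seq_len(n) else split$val
  if (length(train_rows) == 0L || length(val_rows) == 0L) stop("empty split")
  k <- model$config$num_classes - 1L
  loss_cfg <- focal_config(gamma = config$gamma, alpha = config$alpha)
  opt <- adamw_init(model$params)
  sched <- plateau_init(config$lr, config$plateau_factor,
                        config$plateau_patience, config$min_lr)
  checkpoints <- list()
  log <- list()
  old <- rng_snapshot(); on.exit(rng_restore(old))
  set.seed(config$seed)
  step <- 0L
  if (!is.null(rundir)) {
    dir.create(rundir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(unclass(config), file.path(rundir, "train_config.yaml"))
    yaml::write_yaml(unclass(model$config), file.path(rundir, "model_config.yaml"))
  }
  for (epoch in seq_len(config$epochs)) {
    perm <- sample(train_rows)
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    epoch_loss <- 0; nb <- 0L
    for (bt in batches) {
      if (step >= config$max_steps) break
      pairs <- load_batch(manifest, bt, cache)
      bm <- batch_matrices(pairs)
      lg <- net_loss_grads(model, bm$x, bm$b, bm$h, bm$w, bm$target, loss_cfg)
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite loss (%g) at epoch %d step %d", lg$loss, epoch, step))
      }
      upd <- adamw_step(model$params, lg$grads, opt, sched$lr, config)
      model$params <- upd$params
      opt <- upd$state
      step <- step + 1L
      epoch_loss <- epoch_loss + lg$loss; nb <- nb + 1L
      log[[length(log) + 1L]] <- data.frame(epoch = epoch, step = step,
                                            loss = lg$loss, lr = sched$lr,
                                            val_miou = NA_real_)
    }
    do_val <- epoch %% config$val_every == 0L || step >= config$max_steps ||
      epoch == config$epochs
    if (do_val) {
      cm <- eval_confusion(model, manifest, val_rows, k, cache)
      miou <- mean_iou(cm)
      checkpoints <- checkpoint_insert(
        checkpoints,
        list(state = model_state(model), miou = miou, epoch = epoch),
        config$top_k_checkpoints)
      sched <- plateau_update(sched, miou)
      log[[length(log) + 1L]] <- data.frame(epoch = epoch, step = step,
                                            loss = if (nb) epoch_loss / nb else NA_real_,
                                            lr = sched$lr, val_miou = miou)
      if (!quiet) {
        message(sprintf("epoch %3d step %5d loss %.4f lr %.2e val mIoU %.4f",
                        epoch, step, if (nb) epoch_loss / nb else NA, sched$lr, miou))
      }
    }
    if (step >= config$max_steps) break
  }
  log <- do.call(rbind, log)
  run <- structure(list(model = model, checkpoints = checkpoints, log = log,
                        config = config), class = "endoseg_run")
  if (!is.null(rundir)) {
    utils::write.csv(log, file.path(rundir, "log.csv"), row.names = FALSE)
    for (i in seq_along(checkpoints)) {
      saveRDS(checkpoints[[i]], file.path(rundir, sprintf("checkpoint_%02d.rds", i)))
    }
  }
  run
}

#' @export
print.endoseg_run <- function(x, ...) {
  best <- if (length(x$checkpoints)) x$checkpoints[[1L]]$miou else NA
  cat(sprintf("<endoseg_run> %d steps, %d checkpoints, best val mIoU %.4f\n",
              max(x$log$step), length(x$checkpoints), best))
  invisible(x)
}

#' Evaluate retained checkpoints on a split
#'
#' For each retained checkpoint, predicts the requested split, accumulates
#' one global confusion matrix, and computes precision/recall/F1/mIoU; the
#' reported figures are the per-checkpoint metrics and their arithmetic
#' mean (the protocol's 5-checkpoint average).
#'
#' @param run an `endoseg_run` from [train()] (or a list of checkpoints plus
#'   a model via `model =`).
#' @param manifest dataset manifest or in-memory pair list, as in [train()].
#' @param rows manifest row indices to evaluate (e.g. `split$test`).
#' @param model optional `endoseg_model` template when `run` is a bare
#'   checkpoint list.
#' @return An `endoseg_evaluation`: `per_checkpoint` data.frame (epoch,
#'   val_miou, precision, recall, f1, miou) and `mean` named vector.
#' @export
evaluate <- function(run, manifest, rows, model = NULL) {
  checkpoints <- if (inherits(run, "endoseg_run")) run$checkpoints else run
  if (length(checkpoints) == 0L) stop("no checkpoints to evaluate")
  model <- if (inherits(run, "endoseg_run")) run$model else model
  stopifnot(inherits(model, "endoseg_model"))
  cache <- NULL
  if (is.list(manifest) && !is.data.frame(manifest)) {
    cache <- manifest
    manifest <- data.frame(image_path = sprintf("mem:%d", seq_along(cache)),
                           mask_path = sprintf("mem:%d", seq_along(cache)))
  }
  k <- model$config$num_classes - 1L
  res <- vector("list", length(checkpoints))
  for (i in seq_along(checkpoints)) {
    ck <- checkpoints[[i]]
    m <- model_load_state(model, ck$state)
    cm <- eval_confusion(m, manifest, rows, k, cache)
    mac <- precision_recall_f1(cm)$macro
    res[[i]] <- data.frame(checkpoint = i, epoch = ck$epoch,
                           val_miou = ck$miou,
                           precision = mac["precision"], recall = mac["recall"],
                           f1 = mac["f1"], miou = mac["miou"], row.names = NULL)
  }
  per <- do.call(rbind, res)
  structure(list(per_checkpoint = per,
                 mean = colMeans(per[, c("precision", "recall", "f1", "miou")])),
            class = "endoseg_evaluation")
}

#' @export
print.endoseg_evaluation <- function(x, ...) {
  cat("<endoseg_evaluation> mean over", nrow(x$per_checkpoint), "checkpoints:\n")
  print(round(x$mean, 4))
  invisible(x)
}
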