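# Training harness: AdamW with decoupled weight decay, cosine annealing with
# warm restarts stepped per epoch, early stopping on validation loss,
# best-epoch checkpointing, K-fold cross-validation, and the ablation runner.

#' Training configuration
#'
#' @param lr0 initial learning rate.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param batch_size minibatch size.
#' @param max_epochs epoch budget.
#' @param T0,Tmult warm-restart schedule: cycle c has length T0 * Tmult^c
#'   epochs.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement); must be < max_epochs.
#' @param seed base seed; per-fold seed is seed + fold.
#' @param augment enable training-time augmentation.
#' @export
train_config <- function(lr0 = 1e-4, weight_decay = 1e-4, batch_size = 16L,
                         max_epochs = 100L, T0 = 20L, Tmult = 2L,
                         patience = 30L, seed = 1L, augment = TRUE) {
  if (lr0 <= 0) stop("lr0 must be positive")
  if (patience >= max_epochs) stop("patience must be < max_epochs")
  structure(list(lr0 = lr0, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), T0 = as.integer(T0),
                 Tmult = as.integer(Tmult), patience = as.integer(patience),
                 seed = as.integer(seed), augment = isTRUE(augment)),
            class = "busseg_train_config")
}

#' Cosine-annealing-with-warm-restarts learning rate at an epoch
#'
#' Within cycle c (length \code{T0 * Tmult^c}, starting at cumulative epoch
#' S_c): \code{lr = lr0 * (1 + cos(pi * (epoch - S_c) / T_c)) / 2} with zero
#' floor.
#'
#' @param epoch zero-based epoch index.
#' @param lr0 initial learning rate.
#' @param T0 first cycle length in epochs.
#' @param Tmult cycle-length multiplier at each restart.
#' @export
lr_at <- function(epoch, lr0 = 1e-4, T0 = 20L, Tmult = 2L) {
  vapply(epoch, function(e) {
    Tc <- T0
    start <- 0
    while (e >= start + Tc) {
      start <- start + Tc
      Tc <- Tc * Tmult
    }
    lr0 * (1 + cos(pi * (e - start) / Tc)) / 2
  }, numeric(1))
}

# Early-stopping semantics shared with train_fold: best epoch is the argmin
# of the validation losses; training stops after the first epoch at which
# the loss has not improved for `patience` consecutive epochs.
best_and_stop <- function(val_losses, patience) {
  best <- Inf
  best_epoch <- NA_integer_
  since <- 0L
  stop_epoch <- length(val_losses)
  for (i in seq_along(val_losses)) {
    if (val_losses[i] < best) {
      best <- val_losses[i]
      best_epoch <- i
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience) {
        stop_epoch <- i
        break
      }
    }
  }
  list(best_epoch = best_epoch, stop_epoch = stop_epoch)
}

adamw_new <- function(params) {
  list(m = lapply(params, function(p) p$v * 0),
       v = lapply(params, function(p) p$v * 0),
       t = 0L)
}

adamw_step <- function(params, state, lr, weight_decay, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$g
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    p$v <- p$v - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p$v)
  }
  state
}

samples_to_batch <- function(samples, ids) {
  S <- nrow(samples[[ids[1]]]$image)
  n <- length(ids)
  x <- array(0, c(S, S, 1L, n))
  y <- array(0, c(S, S, 1L, n))
  for (i in seq_len(n)) {
    s <- samples[[ids[i]]]
    x[, , 1L, i] <- s$image
    y[, , 1L, i] <- s$mask
  }
  list(x = x, y = y)
}

eval_loss_dsc <- function(model, samples, ids, loss_cfg, batch_size = 8L) {
  tot <- 0; dscs <- numeric(0)
  for (chunk in split(ids, ceiling(seq_along(ids) / batch_size))) {
    b <- samples_to_batch(samples, chunk)
    fw <- model_forward(model, b$x, training = FALSE)
    l <- dbr_loss_ag(fw$logits, b$y, loss_cfg)
    tot <- tot + ag_val(l$total) * length(chunk)
    for (i in seq_along(chunk)) {
      dscs <- c(dscs, overlap_metrics(fw$prob[, , i] >= 0.5, b$y[, , 1, i])$dsc)
    }
  }
  list(loss = tot / length(ids), dsc = mean(dscs))
}

#' Train on all folds except one, validating on the held-out fold
#'
#' Standard protocol: AdamW, cosine warm restarts stepped per epoch, early
#' stopping on validation loss with the configured patience, and selection of
#' the parameters with the lowest validation loss. All randomness (shuffling,
#' augmentation, dropout) derives from \code{train_config$seed + fold}.
#'
#' @param samples named list of "image_sample" objects (ids as names).
#' @param manifest data.frame with id and fold columns.
#' @param fold held-out fold id.
#' @param model_config a \code{\link{model_config}} (or a prebuilt model via
#'   \code{model}).
#' @param train_cfg a \code{\link{train_config}}.
#' @param loss_cfg a \code{\link{loss_config}}.
#' @param model optional prebuilt model (overrides model_config; used by the
#'   ablation runner so all variants share the per-fold init seed).
#' @param verbose print one line per epoch.
#' @return list with \code{model} (best-validation parameters),
#'   \code{history} (per-epoch data.frame: epoch, lr, train_loss, val_loss,
#'   val_dsc), \code{best_epoch}.
#' @export
train_fold <- function(samples, manifest, fold, model_config = NULL,
                       train_cfg = train_config(), loss_cfg = loss_config(),
                       model = NULL, verbose = FALSE) {
  train_ids <- manifest$id[manifest$fold != fold]
  val_ids <- manifest$id[manifest$fold == fold]
  if (length(val_ids) == 0L) stop("fold ", fold, " is empty")
  if (length(train_ids) == 0L) stop("no training images outside fold ", fold)
  fold_seed <- train_cfg$seed + fold
  if (is.null(model)) {
    stopifnot(inherits(model_config, "busseg_config"))
    model <- build_model(model_config, seed = fold_seed)
  }
  params <- collect_params(model)
  opt <- adamw_new(params)
  history <- list()
  best_val <- Inf
  best_epoch <- NA_integer_
  best_params <- NULL
  since_best <- 0L
  for (epoch in seq_len(train_cfg$max_epochs) - 1L) {
    lr <- lr_at(epoch, train_cfg$lr0, train_cfg$T0, train_cfg$Tmult)
    set.seed(fold_seed * 10000L + epoch)
    order_ids <- sample(train_ids)
    batches <- split(order_ids, ceiling(seq_along(order_ids) / train_cfg$batch_size))
    ep_loss <- 0
    for (bids in batches) {
      bs <- samples[bids]
      if (train_cfg$augment) bs <- lapply(bs, augment_sample)
      b <- samples_to_batch(bs, bids)
      with_tape({
        fw <- model_forward(model, b$x, training = TRUE)
        l <- dbr_loss_ag(fw$logits, b$y, loss_cfg)
        if (!is.finite(ag_val(l$total))) {
          stop(sprintf("non-finite training loss at epoch %d (components: %s)",
                       epoch, paste(sprintf("%.4g", unlist(l$breakdown)),
                                    collapse = ", ")))
        }
        ag_backward(l$total)
      })
      opt <- adamw_step(params, opt, lr, train_cfg$weight_decay)
      ag_zero_grad(params)
      ep_loss <- ep_loss + ag_val(l$total) * length(bids)
    }
    ep_loss <- ep_loss / length(train_ids)
    ev <- eval_loss_dsc(model, samples, val_ids, loss_cfg)
    history[[epoch + 1L]] <- data.frame(epoch = epoch, lr = lr,
                                        train_loss = ep_loss,
                                        val_loss = ev$loss, val_dsc = ev$dsc)
    if (verbose) {
      message(sprintf("fold %d epoch %3d lr %.2e train %.4f val %.4f dsc %.4f",
                      fold, epoch, lr, ep_loss, ev$loss, ev$dsc))
    }
    if (ev$loss < best_val) {
      best_val <- ev$loss
      best_epoch <- epoch
      best_params <- param_values(model)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= train_cfg$patience) break
    }
  }
  set_param_values(model, best_params)
  list(model = model, history = do.call(rbind, history), best_epoch = best_epoch,
       best_val_loss = best_val)
}

#' K-fold cross-validation
#'
#' Trains one model per fold (each validated and evaluated on its held-out
#' fold only, so no image is ever evaluated by a model that trained on it)
#' and aggregates per-image metrics into a fold summary.
#'
#' @inheritParams train_fold
#' @return list with \code{records} (per-image metrics data.frame including
#'   fold), \code{summary} (a \code{\link{fold_aggregate}} result),
#'   \code{fold_models}, \code{histories}.
#' @export
run_cv <- function(samples, manifest, model_config, train_cfg = train_config(),
                   loss_cfg = loss_config(), verbose = FALSE) {
  folds <- sort(unique(manifest$fold))
  if (length(folds) < 2L) stop("need >= 2 folds")
  records <- list()
  fold_models <- list()
  histories <- list()
  for (f in folds) {
    tr <- train_fold(samples, manifest, f, model_config, train_cfg, loss_cfg,
                     verbose = verbose)
    fold_models[[as.character(f)]] <- tr$model
    histories[[as.character(f)]] <- tr$history
    val_ids <- manifest$id[manifest$fold == f]
    for (chunk in split(val_ids, ceiling(seq_along(val_ids) / 8L))) {
      b <- samples_to_batch(samples, chunk)
      prob <- predict_prob(tr$model, b$x)
      for (i in seq_along(chunk)) {
        rec <- metrics_record(prob[, , i], b$y[, , 1, i], id = chunk[i])
        rec$fold <- f
        records[[chunk[i]]] <- rec
      }
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  list(records = records,
       summary = fold_aggregate(records[setdiff(names(records), "fold")],
                                manifest),
       fold_models = fold_models, histories = histories)
}

#' Run the ablation battery
#'
#' Trains each requested variant with identical per-fold seeds and folds and
#' tabulates DSC (mean +/- SD across folds), boundary IoU, HD95 and
#' parameter count.
#'
#' @param samples,manifest,train_cfg as in \code{\link{run_cv}}.
#' @param variants character vector of \code{\link{variant_names}}.
#' @param base_config configuration the variants are derived from.
#' @return list with \code{table} (one row per variant) and \code{runs}
#'   (full run_cv results by variant).
#' @export
run_ablation <- function(samples, manifest, variants = variant_names(),
                         base_config = model_config(),
                         train_cfg = train_config()) {
  runs <- list()
  rows <- list()
  for (vn in variants) {
    v <- build_variant(vn, base_config, seed = train_cfg$seed)
    cvfun <- function(f) {
      # identical init seeds across variants: rebuild per fold
      build_variant(vn, base_config, seed = train_cfg$seed + f)$model
    }
    folds <- sort(unique(manifest$fold))
    records <- list()
    fold_dsc <- numeric(0)
    for (f in folds) {
      tr <- train_fold(samples, manifest, f, model_config = NULL,
                       train_cfg = train_cfg, loss_cfg = v$loss_config,
                       model = cvfun(f))
      val_ids <- manifest$id[manifest$fold == f]
      b <- samples_to_batch(samples, val_ids)
      prob <- predict_prob(tr$model, b$x)
      for (i in seq_along(val_ids)) {
        rec <- metrics_record(prob[, , i], b$y[, , 1, i], id = val_ids[i])
        rec$fold <- f
        records[[val_ids[i]]] <- rec
      }
      fold_dsc <- c(fold_dsc,
                    mean(vapply(records[val_ids], `[[`, numeric(1), "dsc")))
    }
    records <- do.call(rbind, records)
    runs[[vn]] <- list(records = records)
    rows[[vn]] <- data.frame(
      variant = vn,
      dsc_mean = mean(fold_dsc), dsc_sd = sd(fold_dsc),
      b_iou = mean(records$b_iou), hd95 = mean(records$hd95),
      params = n_params(v$model))
  }
  list(table = do.call(rbind, rows), runs = runs)
}

#' Training preset for the miniature desk-scale protocol
#'
#' The configuration used with \code{\link{mini_model_config}} for the
#' phantom end-to-end experiments: a higher initial learning rate and a
#' short cosine cycle suited to a small model on a small dataset, batch 16,
#' five epochs.
#' @param ... overrides passed to \code{\link{train_config}}.
#' @export
mini_train_config <- function(...) {
  args <- list(lr0 = 1e-3, batch_size = 16L, max_epochs = 5L, T0 = 15L,
               Tmult = 2L, patience = 3L, seed = 7L, augment = TRUE)
  args[names(list(...))] <- list(...)
  do.call(train_config, args)
}
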