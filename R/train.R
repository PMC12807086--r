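#' Training configuration
#'
#' Defaults follow the model's hyperparameter table: batch size in
#' \[256, 512\] (default 256), learning rate in \[0.001, 0.01\] (default
#' 0.001), 50 epochs. The validation split is grouped by genomic site: all
#' windows of a site land on the same side, so validation sites are never
#' seen in training (the evaluation analogue of training on one genome and
#' testing on another).
#'
#' @param batch_size Minibatch size (>= 1).
#' @param learning_rate Peak Adam learning rate (> 0).
#' @param epochs Number of training epochs.
#' @param seed Seed for the split, per-epoch shuffling and dropout.
#' @param validation_fraction Fraction of sites held out for validation.
#' @param schedule Learning-rate schedule: `"warmup_cosine"` (default;
#'   linear warmup over the first `warmup_frac` of steps, then cosine decay
#'   to `min_lr_frac * learning_rate` -- the standard stabilizer for short
#'   transformer training runs) or `"constant"`.
#' @param warmup_frac Fraction of total steps used for warmup.
#' @param min_lr_frac Final learning rate as a fraction of the peak.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 256L, learning_rate = 0.001,
                         epochs = 50L, seed = 1L, validation_fraction = 0.2,
                         schedule = c("warmup_cosine", "constant"),
                         warmup_frac = 0.1, min_lr_frac = 0.1) {
  schedule <- match.arg(schedule)
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must lie in (0, 1)")
  }
  if (warmup_frac < 0 || warmup_frac >= 1) stop("warmup_frac must lie in [0, 1)")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 schedule = schedule, warmup_frac = warmup_frac,
                 min_lr_frac = min_lr_frac),
            class = "train_config")
}

.lr_at <- function(step, total, tcfg) {
  if (tcfg$schedule == "constant") return(tcfg$learning_rate)
  warm <- max(1, floor(tcfg$warmup_frac * total))
  if (step <= warm) return(tcfg$learning_rate * step / warm)
  frac <- (step - warm) / max(1, total - warm)
  floor_lr <- tcfg$min_lr_frac
  tcfg$learning_rate * (floor_lr + (1 - floor_lr) * 0.5 * (1 + cos(pi * frac)))
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

# Clip gradients to a global L2 norm; tames the occasional saturated-softmax
# spike that would otherwise poison Adam's moment estimates.
.clip_global <- function(grads, max_norm) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(nrm) && nrm > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / nrm))
  }
  grads
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.98,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gn <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gn
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gn * gn
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Train the transformer methylation classifier
#'
#' Minimizes two-class cross-entropy with Adam over labeled feature windows.
#' Windows are split into training and validation sets by genomic site
#' (grouped split; see [train_config()]), shuffled with the seed every
#' epoch, and the checkpoint with the best validation F1 is returned
#' together with a per-epoch trace of losses and validation metrics.
#'
#' @param windows A labeled `meth_windows` object.
#' @param cfg A [model_config()]; its `window` must match the windows.
#' @param tcfg A [train_config()].
#' @param quiet Suppress the per-epoch log line.
#' @return A list of class `methformer_fit`: `model` (best checkpoint),
#'   `trace` (per-epoch data frame), `validation` (metrics of the best
#'   checkpoint on the held-out windows), `val_idx`.
#' @export
train_transformer <- function(windows, cfg = model_config(),
                              tcfg = train_config(), quiet = FALSE) {
  stopifnot(inherits(windows, "meth_windows"))
  y <- windows$label
  if (is.null(y)) stop("training requires labeled windows")
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class; both labels are required")
  }
  if (windows$window != cfg$window) {
    stop(sprintf("window size mismatch: data %d vs config %d",
                 windows$window, cfg$window))
  }
  n <- length(y)
  w <- cfg$window
  F_all <- .flatten_windows(windows)

  set.seed(tcfg$seed)
  site <- paste(windows$meta$chrom, windows$meta$ref_pos, windows$meta$strand)
  usite <- unique(site)
  n_val <- max(1L, round(tcfg$validation_fraction * length(usite)))
  if (n_val >= length(usite)) stop("validation fraction leaves no training sites")
  val_sites <- sample(usite, n_val)
  val_idx <- which(site %in% val_sites)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(y[tr_idx])) < 2L) {
    stop("training split contains a single class; increase data or change seed")
  }

  model <- build_model(cfg)
  params <- model$params
  # column statistics of the numeric features, from training rows only
  tr_rows <- .batch_rows(tr_idx, w)
  stats <- list(mu = colMeans(F_all[tr_rows, 1:3, drop = FALSE]),
                sd = pmax(apply(F_all[tr_rows, 1:3, drop = FALSE], 2L, stats::sd),
                          1e-8))
  model$feat_stats <- stats
  state <- .adam_init(params)
  set.seed(tcfg$seed + 1L)

  n_batches <- ceiling(length(tr_idx) / tcfg$batch_size)
  total_steps <- tcfg$epochs * n_batches
  step <- 0L
  best <- list(f1 = -Inf, params = params, epoch = 0L)
  trace <- vector("list", tcfg$epochs)
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / tcfg$batch_size))
    tl <- 0
    for (bi in batches) {
      step <- step + 1L
      lg <- .mf_loss_grads(params, cfg, F_all[.batch_rows(bi, w), , drop = FALSE],
                           y[bi], train = TRUE, stats = stats)
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite training loss at epoch %d; try a lower learning rate", ep))
      }
      upd <- .adam_step(params, .clip_global(lg$grads, 1.0), state,
                        .lr_at(step, total_steps, tcfg))
      params <- upd$params
      state <- upd$state
      tl <- tl + lg$loss * length(bi)
    }
    tl <- tl / length(tr_idx)

    ev <- .eval_split(params, cfg, F_all, y, val_idx, w, tcfg$batch_size, stats)
    trace[[ep]] <- data.frame(
      epoch = ep, train_loss = tl, val_loss = ev$loss,
      val_accuracy = ev$metrics$accuracy, val_f1 = ev$metrics$f1,
      val_auc = ev$auc
    )
    if (!quiet) {
      message(sprintf("epoch %3d  train_loss %.4f  val_loss %.4f  val_f1 %.4f  val_auc %.4f",
                      ep, tl, ev$loss, ev$metrics$f1, ev$auc))
    }
    if (ev$metrics$f1 > best$f1) {
      best <- list(f1 = ev$metrics$f1, params = params, epoch = ep)
    }
  }
  trace <- do.call(rbind, trace)

  model$params <- best$params
  model$meta <- list(epochs = tcfg$epochs, best_epoch = best$epoch,
                     final_train_loss = trace$train_loss[tcfg$epochs],
                     train_config = unclass(tcfg))
  ev <- .eval_split(best$params, cfg, F_all, y, val_idx, w, tcfg$batch_size, stats)
  structure(list(model = model, trace = trace,
                 validation = list(metrics = ev$metrics, auc = ev$auc,
                                   loss = ev$loss, n = length(val_idx),
                                   probs = ev$probs, labels = y[val_idx]),
                 val_idx = val_idx),
            class = "methformer_fit")
}

.eval_split <- function(params, cfg, F_all, y, idx, w, batch_size, stats = NULL) {
  probs <- numeric(length(idx))
  loss <- 0
  for (bi in split(idx, ceiling(seq_along(idx) / batch_size))) {
    M <- .mf_embed(params, cfg, F_all[.batch_rows(bi, w), , drop = FALSE],
                   length(bi), stats)
    p <- .mf_forward_core(params, cfg, M, length(bi), train = FALSE)$probs
    probs[match(bi, idx)] <- p[, 2L]
    loss <- loss - sum(log(pmax(p[cbind(seq_along(bi), y[bi] + 1L)], 1e-300)))
  }
  calls <- call_methylation(probs)
  mr <- metrics_report(confusion(y[idx], calls))
  auc <- if (length(unique(y[idx])) == 2L) roc_auc(y[idx], probs) else NA_real_
  list(loss = loss / length(idx), metrics = mr, auc = auc, probs = probs)
}

#' @export
print.methformer_fit <- function(x, ...) {
  v <- x$validation
  cat(sprintf(
    "methformer_fit: best epoch %d/%d | held-out F1 %.4f, AUC %.4f (n = %d site-grouped windows)\n",
    x$model$meta$best_epoch, x$model$meta$epochs, v$metrics$f1, v$auc, v$n))
  invisible(x)
}

#' Predict methylation for feature windows
#'
#' @param model A trained `methformer_model`.
#' @param windows A `meth_windows` object.
#' @param batch_size Windows per forward batch.
#' @return Data frame: `read_id`, `chrom`, `strand`, `ref_pos`, `prob`
#'   (methylation probability), `call` (1 iff prob > 0.5).
#' @export
predict_windows <- function(model, windows, batch_size = 512L) {
  stopifnot(inherits(windows, "meth_windows"))
  cfg <- model$config
  n <- dim(windows$x)[3L]
  F_all <- .flatten_windows(windows)
  prob <- numeric(n)
  for (bi in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    M <- .mf_embed(model$params, cfg, F_all[.batch_rows(bi, cfg$window), , drop = FALSE],
                   length(bi), model$feat_stats)
    prob[bi] <- .mf_forward_core(model$params, cfg, M, length(bi), train = FALSE)$probs[, 2L]
  }
  out <- windows$meta
  out$prob <- prob
  out$call <- call_methylation(prob)
  out
}

#' Position-embedding and window-size ablation harness
#'
#' Trains the same data under a grid of settings and returns the combined
#' per-epoch trace in a stable schema: `mode_or_param`, `seed`, `epoch`,
#' `train_loss`, `val_loss`, `val_f1`, `val_auc`. `ablate_pe` compares
#' summation against concatenation of the position embedding at fixed
#' `d_model`; `ablate_window` compares window sizes by centrally cropping
#' one set of windows extracted at the largest size, so every run scores the
#' identical candidate set.
#'
#' @param windows A labeled `meth_windows` object.
#' @param modes Character vector of PE modes (subset of `"sum"`, `"concat"`).
#' @param seeds Integer vector; each seed reinitializes model and split.
#' @param d_model Model width used for every run.
#' @param epochs,batch_size,learning_rate Training settings for every run.
#' @return Data frame with one row per (run, epoch).
#' @export
ablate_pe <- function(windows, modes = c("sum", "concat"), seeds = 1:3,
                      d_model = 16L, epochs = 10L, batch_size = 256L,
                      learning_rate = 0.001) {
  grid <- expand.grid(mode = modes, seed = seeds, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- model_config(d_model = d_model, window = windows$window,
                        pe_mode = grid$mode[i], seed = grid$seed[i])
    fit <- train_transformer(windows, cfg,
                             train_config(batch_size = batch_size,
                                          learning_rate = learning_rate,
                                          epochs = epochs, seed = grid$seed[i]),
                             quiet = TRUE)
    cbind(mode_or_param = grid$mode[i], seed = grid$seed[i],
          fit$trace[, c("epoch", "train_loss", "val_loss", "val_f1", "val_auc")])
  })
  do.call(rbind, out)
}

#' @rdname ablate_pe
#' @param sizes Odd window sizes, each at most `windows$window`.
#' @export
ablate_window <- function(windows, sizes = c(11L, 21L, 31L), seeds = 1L,
                          d_model = 16L, epochs = 10L, batch_size = 256L,
                          learning_rate = 0.001) {
  if (max(sizes) > windows$window) {
    stop("extract windows at the largest ablation size first")
  }
  grid <- expand.grid(size = sizes, seed = seeds)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    wd <- crop_windows(windows, grid$size[i])
    cfg <- model_config(d_model = d_model, window = grid$size[i],
                        seed = grid$seed[i])
    fit <- train_transformer(wd, cfg,
                             train_config(batch_size = batch_size,
                                          learning_rate = learning_rate,
                                          epochs = epochs, seed = grid$seed[i]),
                             quiet = TRUE)
    cbind(mode_or_param = paste0("w", grid$size[i]), seed = grid$seed[i],
          fit$trace[, c("epoch", "train_loss", "val_loss", "val_f1", "val_auc")])
  })
  do.call(rbind, out)
}
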