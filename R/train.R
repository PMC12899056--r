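## AdamW optimization, lambda schedule, training loop with early stopping on
## validation AUC, and checkpoint save/restore.

#' Training configuration
#'
#' Defaults follow the published setup: AdamW with initial learning rate
#' 1e-4, weight decay 1e-5, mini-batch size 32, at most 100 epochs with early
#' stopping on validation AUC.
#'
#' @param lr learning rate.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum training epochs.
#' @param patience epochs without validation-AUC improvement before stopping.
#' @param seed seed controlling initialization, shuffling and dropout.
#' @param lambda_mode `"schedule"` (ramp `2/(1+exp(-10 p)) - 1`) or
#'   `"constant"`.
#' @param lambda_constant constant lambda value (constant mode).
#' @param domain_loss_weight weight on the domain loss in the total loss.
#' @param val_fraction when no explicit validation window set is supplied,
#'   fraction of training subjects held out for early stopping.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-5, batch_size = 32L,
                         max_epochs = 100L, patience = 10L, seed = 1L,
                         lambda_mode = c("schedule", "constant"),
                         lambda_constant = 1.0, domain_loss_weight = 1.0,
                         val_fraction = 0.2) {
  lambda_mode <- match.arg(lambda_mode)
  stopifnot(lr > 0, weight_decay >= 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, patience <= max_epochs, domain_loss_weight >= 0)
  structure(
    list(lr = lr, weight_decay = weight_decay,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         seed = as.integer(seed), lambda_mode = lambda_mode,
         lambda_constant = lambda_constant,
         domain_loss_weight = domain_loss_weight,
         val_fraction = val_fraction),
    class = "train_config"
  )
}

#' Gradient-reversal coefficient schedule
#'
#' Constant mode returns the constant; schedule mode returns the standard
#' domain-adversarial warm-up ramp `2/(1 + exp(-10 p)) - 1` over training
#' progress `p` in `[0, 1]`.
#'
#' @param progress training progress fraction; values outside `[0, 1]` are
#'   clamped with a warning.
#' @param mode `"schedule"` or `"constant"`.
#' @param constant value returned in constant mode.
#' @return scalar lambda.
#' @export
lambda_schedule <- function(progress, mode = c("schedule", "constant"),
                            constant = 1.0) {
  mode <- match.arg(mode)
  if (progress < 0 || progress > 1) {
    warning("progress outside [0, 1]; clamping")
    progress <- min(max(progress, 0), 1)
  }
  if (mode == "constant") constant else 2 / (1 + exp(-10 * progress)) - 1
}

## ---- AdamW over nested parameter lists ------------------------------------

# Leaves eligible for optimization (numeric arrays except layer geometry and
# batch-norm running statistics, which are state, not parameters).
.skip_leaves <- c("kh", "kw", "stride", "pad", "hidden",
                  "run_mean", "run_var")

adamw_init <- function(params) {
  walk <- function(p) {
    if (is.list(p)) return(lapply(p, walk))
    list(m = p * 0, v = p * 0)
  }
  list(state = walk(params), t = 0L)
}

# One AdamW step; returns list(params, opt). Walks params and grads in
# parallel; grads may omit branches (e.g. frozen or absent heads).
adamw_step <- function(params, grads, opt, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  t_ <- opt$t
  step_leaf <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t_)
    vhat <- s$v / (1 - beta2^t_)
    p <- p - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p)
    list(p = p, s = s)
  }
  walk <- function(p, g, s) {
    if (!is.list(p)) {
      r <- step_leaf(p, g, s)
      return(list(p = r$p, s = r$s))
    }
    keys <- names(p) %||% seq_along(p)
    for (nm in keys) {
      if (is.character(nm) && nm %in% .skip_leaves) next
      if (is.null(g[[nm]])) next
      r <- walk(p[[nm]], g[[nm]], s[[nm]])
      p[[nm]] <- r$p
      s[[nm]] <- r$s
    }
    list(p = p, s = s)
  }
  r <- walk(params, grads, opt$state)
  list(params = r$p, opt = list(state = r$s, t = t_))
}

## ---- training -------------------------------------------------------------

prepare_domains <- function(subject_ids) {
  lev <- sort(unique(subject_ids))
  list(index = match(subject_ids, lev), levels = lev)
}

#' Train the network
#'
#' Trains with AdamW on the combined loss `L_y + domain_loss_weight * L_d`
#' (the domain gradient reaching the backbone is reversed and scaled by
#' `-lambda`). Validation AUC is monitored each epoch; training stops when it
#' fails to improve for `patience` epochs and the best-AUC weights are
#' returned. Train and validation subject sets must be disjoint.
#'
#' @param train_windows a training-role `window_set`.
#' @param val_windows an eval-role `window_set` from different subjects, or
#'   NULL to train for `max_epochs` with no early stopping.
#' @param mcfg a [model_config()]; `n_domains` is overridden by the number of
#'   distinct training subjects.
#' @param tcfg a [train_config()].
#' @param adversarial enable the domain branch (lambda > 0).
#' @param verbose print per-epoch progress.
#' @return list with `checkpoint` (see [save_checkpoint()]) and `log`
#'   (per-epoch data.frame: epoch, loss_label, loss_domain, val_auc, lambda,
#'   stopped_early, best_epoch).
#' @export
train_model <- function(train_windows, val_windows = NULL, mcfg, tcfg,
                        adversarial = TRUE, verbose = FALSE) {
  train_subjects <- unique(train_windows$subject_ids)
  if (!is.null(val_windows)) {
    overlap <- intersect(train_subjects, unique(val_windows$subject_ids))
    if (length(overlap) > 0) {
      stop_eegdann(
        sprintf("subject leakage between train and validation: %s",
                paste(overlap, collapse = ", ")),
        "eegdann_leakage_error"
      )
    }
  }
  dom <- prepare_domains(train_windows$subject_ids)
  n_domains <- if (adversarial) length(dom$levels) else 0L
  if (adversarial && n_domains < 2) {
    stop_eegdann("adversarial training needs >= 2 training subjects",
                 "eegdann_config_error")
  }
  mcfg$n_domains <- as.integer(n_domains)

  sp_train <- zscore_normalize(stft_logmag(train_windows))
  stats <- sp_train$norm_stats
  sp_val <- NULL
  if (!is.null(val_windows)) {
    sp_val <- apply_zscore(stft_logmag(val_windows), stats)
  }

  params <- init_model(mcfg, seed = tcfg$seed)
  opt <- adamw_init(params)
  n <- dim(sp_train$tensor)[1]
  labels <- sp_train$labels
  n_batches <- ceiling(n / tcfg$batch_size)
  best_auc <- -Inf
  best_params <- params
  best_epoch <- 0L
  bad_epochs <- 0L
  log_rows <- list()
  stopped_early <- FALSE

  set.seed(derive_seed(tcfg$seed, 1))
  for (epoch in seq_len(tcfg$max_epochs)) {
    idx <- sample.int(n)
    ep_ly <- 0
    ep_ld <- 0
    ld_count <- 0
    for (b in seq_len(n_batches)) {
      rows <- idx[((b - 1) * tcfg$batch_size + 1):min(b * tcfg$batch_size, n)]
      progress <- ((epoch - 1) + (b - 1) / n_batches) / tcfg$max_epochs
      lam <- if (adversarial) {
        lambda_schedule(progress, tcfg$lambda_mode, tcfg$lambda_constant)
      } else 0
      xb <- sp_train$tensor[rows, , , , drop = FALSE]
      fwd <- model_forward(params, mcfg, xb, training = TRUE, lambda = lam,
                           keep_cache = TRUE)
      params <- fwd$params # batch-norm running statistics
      bwd <- model_backward(params, mcfg, fwd, labels[rows],
                            domains = if (adversarial) dom$index[rows],
                            domain_loss_weight = tcfg$domain_loss_weight)
      st <- adamw_step(params, bwd$grads, opt, tcfg$lr, tcfg$weight_decay)
      params <- st$params
      opt <- st$opt
      ep_ly <- ep_ly + bwd$loss_label * length(rows)
      if (!is.na(bwd$loss_domain)) {
        ep_ld <- ep_ld + bwd$loss_domain * length(rows)
        ld_count <- ld_count + length(rows)
      }
    }
    val_auc <- NA_real_
    if (!is.null(sp_val)) {
      probs <- predict_spectrograms(params, mcfg, sp_val$tensor,
                                    batch_size = tcfg$batch_size)
      val_auc <- auc_score(probs, sp_val$labels)
    }
    lam_end <- if (adversarial) {
      lambda_schedule(epoch / tcfg$max_epochs, tcfg$lambda_mode,
                      tcfg$lambda_constant)
    } else 0
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, loss_label = ep_ly / n,
      loss_domain = if (ld_count > 0) ep_ld / ld_count else NA_real_,
      val_auc = val_auc, lambda = lam_end
    )
    if (verbose) {
      message(sprintf("epoch %d: L_y=%.4f L_d=%.4f val AUC=%.4f", epoch,
                      ep_ly / n, ifelse(ld_count > 0, ep_ld / ld_count, NA),
                      val_auc))
    }
    if (!is.null(sp_val)) {
      if (val_auc > best_auc) {
        best_auc <- val_auc
        best_params <- params
        best_epoch <- epoch
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= tcfg$patience) {
          stopped_early <- TRUE
          break
        }
      }
    } else {
      best_params <- params
      best_epoch <- epoch
    }
  }
  log <- do.call(rbind, log_rows)
  log$stopped_early <- stopped_early
  log$best_epoch <- best_epoch
  ckpt <- structure(
    list(params = best_params, config = mcfg, norm_stats = stats,
         montage = bipolar_channel_names(), domain_levels = dom$levels,
         train_config = tcfg, best_epoch = best_epoch,
         best_val_auc = if (is.finite(best_auc)) best_auc else NA_real_),
    class = "eegdann_checkpoint"
  )
  list(checkpoint = ckpt, log = log)
}

# Batched eval-mode forward returning seizure probabilities.
predict_spectrograms <- function(params, cfg, tensor, batch_size = 64L) {
  n <- dim(tensor)[1]
  probs <- numeric(n)
  b0 <- 1L
  while (b0 <= n) {
    b1 <- min(b0 + batch_size - 1L, n)
    fwd <- model_forward(params, cfg,
                         tensor[b0:b1, , , , drop = FALSE],
                         training = FALSE)
    probs[b0:b1] <- fwd$seizure_prob
    b0 <- b1 + 1L
  }
  probs
}

#' Seizure probabilities for a window set, using a trained checkpoint
#'
#' Applies the checkpoint's stored normalization statistics (leakage-checked)
#' and runs the network in evaluation mode.
#'
#' @param ckpt an `eegdann_checkpoint`.
#' @param windows a `window_set`.
#' @param check_leakage verify eval subjects were not in the normalization
#'   fit.
#' @return vector of seizure probabilities.
#' @export
predict_windows <- function(ckpt, windows, check_leakage = TRUE) {
  sp <- apply_zscore(stft_logmag(windows), ckpt$norm_stats,
                     check_leakage = check_leakage)
  predict_spectrograms(ckpt$params, ckpt$config, sp$tensor)
}

#' Save a checkpoint: weights blob plus JSON sidecar
#'
#' Writes `<path>.rds` (parameters and optimizer-free state) and
#' `<path>.json` (model configuration, normalization statistics, montage
#' order, domain index map).
#'
#' @param ckpt an `eegdann_checkpoint`.
#' @param path path prefix (without extension).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(ckpt, path) {
  # weights blob carries the exact binary parameters and normalization
  # statistics; the JSON sidecar duplicates the metadata human-readably
  saveRDS(list(params = ckpt$params, norm_stats = ckpt$norm_stats),
          paste0(path, ".rds"))
  sidecar <- list(
    config = unclass(ckpt$config),
    norm_stats = list(mean = ckpt$norm_stats$mean, sd = ckpt$norm_stats$sd,
                      fitted_subjects = ckpt$norm_stats$fitted_subjects),
    montage = ckpt$montage,
    domain_levels = ckpt$domain_levels,
    best_epoch = ckpt$best_epoch,
    best_val_auc = ckpt$best_val_auc
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path path prefix used at save time.
#' @return an `eegdann_checkpoint`.
#' @export
load_checkpoint <- function(path) {
  blob <- readRDS(paste0(path, ".rds"))
  params <- blob$params
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- structure(as.list(sc$config), class = "model_config")
  for (nm in c("n_channels", "n_freq", "n_frames", "n_domains", "base_width",
               "blocks_per_stage", "cnn_out_dim", "lstm_hidden", "pooled_dim",
               "attention_hidden", "head_hidden")) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  stats <- blob$norm_stats
  structure(
    list(params = params, config = cfg, norm_stats = stats,
         montage = sc$montage, domain_levels = sc$domain_levels,
         best_epoch = sc$best_epoch, best_val_auc = sc$best_val_auc),
    class = "eegdann_checkpoint"
  )
}
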