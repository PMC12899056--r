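## Cross-validation, the source-data scaling experiment, the four-variant
## ablation, attention-map export, and the linear domain probe used to
## diagnose domain-invariant features.

# Per-subject window cache: train-role and eval-role windows for a cohort.
preprocess_cohort_cached <- function(cohort) {
  lapply(cohort, function(rec) {
    list(train = preprocess_recording(rec, "train"),
         eval = preprocess_recording(rec, "eval"),
         group = rec$group, subject_id = rec$subject_id)
  })
}

subsample_per_subject <- function(ws, n_keep, seed) {
  n <- length(ws$labels)
  if (is.null(n_keep) || n <= n_keep) return(ws)
  idx <- with_seed(seed, sort(sample.int(n, n_keep)))
  subset_window_set(ws, idx)
}

gather_windows <- function(cache, subjects, role, per_subject_cap = NULL,
                           seed = 1L) {
  sets <- lapply(subjects, function(s) {
    subsample_per_subject(cache[[s]][[role]], per_subject_cap,
                          derive_seed(seed, match(s, subjects)))
  })
  bind_window_sets(sets)
}

#' Subject-wise cross-validation of the detector
#'
#' For each fold: train on the other folds' subjects (training-role windows,
#' 50% overlap), evaluate on the held-out subjects' eval-role windows.
#' Early stopping uses a subject-held-out sub-split of the training subjects
#' (never the test fold). Subject disjointness is asserted and recorded in
#' the returned manifest.
#'
#' @param cohort list of `eeg_recording`s.
#' @param mcfg a [model_config()].
#' @param tcfg a [train_config()].
#' @param plan a [make_group_folds()] plan covering the cohort.
#' @param folds fold indices to run (default all; subsets support
#'   desk-scale experiments).
#' @param adversarial enable domain-adversarial training.
#' @param train_cap optional cap on training windows per subject
#'   (seeded subsample; used to scale experiments down).
#' @param eval_cap optional cap on evaluation windows per subject.
#' @param use_val_split hold out a fraction of training subjects for early
#'   stopping (else train for `max_epochs`).
#' @param keep_checkpoints retain each fold's checkpoint in the result.
#' @param cache optional precomputed [preprocess_cohort_cached()] result.
#' @param verbose print progress.
#' @return list with `report` (a `metrics_report`), `folds` (per-fold
#'   details: metrics, scores, labels, subjects, checkpoint if kept) and
#'   `manifest` (per-fold train/test subject sets).
#' @export
run_cross_validation <- function(cohort, mcfg, tcfg, plan,
                                 folds = seq_len(plan$k),
                                 adversarial = TRUE,
                                 train_cap = NULL, eval_cap = NULL,
                                 use_val_split = TRUE,
                                 keep_checkpoints = FALSE,
                                 cache = NULL, verbose = FALSE) {
  if (is.null(cache)) cache <- preprocess_cohort_cached(cohort)
  all_subjects <- names(plan$assignments)
  missing <- setdiff(all_subjects, names(cache))
  if (length(missing) > 0) {
    stop_eegdann("fold plan names subjects absent from the cohort",
                 "eegdann_fold_error")
  }
  groups <- vapply(cache[all_subjects], function(x) x$group, "")
  per_fold <- list()
  fold_details <- list()
  manifest <- list()
  for (f in folds) {
    test_subjects <- all_subjects[plan$assignments[all_subjects] == f]
    train_subjects <- setdiff(all_subjects, test_subjects)
    stopifnot(length(intersect(train_subjects, test_subjects)) == 0)
    val_subjects <- character(0)
    if (use_val_split && tcfg$val_fraction > 0) {
      # stratified subject-level sub-split for early stopping
      for (g in unique(groups[train_subjects])) {
        gs <- train_subjects[groups[train_subjects] == g]
        n_val <- max(1L, floor(tcfg$val_fraction * length(gs)))
        val_subjects <- c(val_subjects,
                          with_seed(derive_seed(tcfg$seed, f, 7),
                                    sample(gs, n_val)))
      }
      train_subjects <- setdiff(train_subjects, val_subjects)
    }
    tw <- gather_windows(cache, train_subjects, "train", train_cap,
                         derive_seed(tcfg$seed, f, 1))
    vw <- if (length(val_subjects) > 0) {
      gather_windows(cache, val_subjects, "eval", eval_cap,
                     derive_seed(tcfg$seed, f, 2))
    }
    ew <- gather_windows(cache, test_subjects, "eval", eval_cap,
                         derive_seed(tcfg$seed, f, 3))
    if (verbose) {
      message(sprintf("fold %d: train %d windows / %d subjects, test %d windows",
                      f, length(tw$labels), length(train_subjects),
                      length(ew$labels)))
    }
    fit <- train_model(tw, vw, mcfg, tcfg, adversarial = adversarial,
                       verbose = verbose)
    scores <- predict_windows(fit$checkpoint, ew)
    m <- compute_metrics(scores, ew$labels)
    per_fold[[length(per_fold) + 1]] <- m$metrics
    fold_details[[length(fold_details) + 1]] <- list(
      fold = f, metrics = m$metrics, counts = m$counts, scores = scores,
      labels = ew$labels, train_subjects = train_subjects,
      val_subjects = val_subjects, test_subjects = test_subjects,
      log = fit$log,
      checkpoint = if (keep_checkpoints) fit$checkpoint
    )
    manifest[[length(manifest) + 1]] <- list(
      fold = f, train = sort(c(train_subjects, val_subjects)),
      test = sort(test_subjects),
      disjoint = length(intersect(c(train_subjects, val_subjects),
                                  test_subjects)) == 0
    )
  }
  list(report = metrics_report(per_fold), folds = fold_details,
       manifest = manifest)
}

#' Source-data scaling experiment
#'
#' Holds one target fold fixed and retrains from scratch on a stratified
#' (by window class) random fraction `gamma` of the source-domain training
#' windows, tracing the generalization trajectory.
#'
#' @param cohort list of `eeg_recording`s.
#' @param mcfg,tcfg,plan as in [run_cross_validation()].
#' @param gamma_values fractions of source windows (default 0.6 ... 1.0).
#' @param fold the fixed target fold.
#' @param adversarial enable domain-adversarial training.
#' @param train_cap,eval_cap optional per-subject window caps.
#' @param use_val_split early-stopping sub-split flag.
#' @param cache optional preprocessed cohort cache.
#' @return list per gamma: `gamma`, `n_windows`, `metrics`.
#' @export
run_data_scaling <- function(cohort, mcfg, tcfg, plan,
                             gamma_values = c(0.6, 0.7, 0.8, 0.9, 1.0),
                             fold = 1L, adversarial = TRUE,
                             train_cap = NULL, eval_cap = NULL,
                             use_val_split = FALSE, cache = NULL) {
  stopifnot(all(gamma_values > 0 & gamma_values <= 1))
  if (is.null(cache)) cache <- preprocess_cohort_cached(cohort)
  all_subjects <- names(plan$assignments)
  test_subjects <- all_subjects[plan$assignments[all_subjects] == fold]
  train_subjects <- setdiff(all_subjects, test_subjects)
  tw_full <- gather_windows(cache, train_subjects, "train", train_cap,
                            derive_seed(tcfg$seed, fold, 1))
  ew <- gather_windows(cache, test_subjects, "eval", eval_cap,
                       derive_seed(tcfg$seed, fold, 3))
  out <- list()
  for (g in gamma_values) {
    tw <- subsample_windows_stratified(tw_full, g, derive_seed(tcfg$seed, 11))
    if (length(unique(tw$labels)) < 2) {
      stop_eegdann("gamma subset contains a single class",
                   "eegdann_config_error")
    }
    fit <- train_model(tw, NULL, mcfg, tcfg, adversarial = adversarial)
    scores <- predict_windows(fit$checkpoint, ew)
    m <- compute_metrics(scores, ew$labels)
    out[[length(out) + 1]] <- list(gamma = g, n_windows = length(tw$labels),
                                   metrics = m$metrics)
  }
  out
}

#' Stratified random subset of a window set
#'
#' Keeps `round(gamma * n_class)` windows of each label class; `gamma = 1`
#' returns the input unchanged.
#'
#' @param ws a `window_set`.
#' @param gamma fraction in (0, 1].
#' @param seed sampling seed.
#' @return a `window_set`.
#' @export
subsample_windows_stratified <- function(ws, gamma, seed = 1L) {
  if (gamma >= 1) return(ws)
  keep <- with_seed(seed, {
    unlist(lapply(unique(ws$labels), function(cl) {
      idx <- which(ws$labels == cl)
      sample(idx, round(gamma * length(idx)))
    }))
  })
  subset_window_set(ws, sort(keep))
}

ablation_variants <- list(
  baseline = list(pooling = "mean", adversarial = FALSE),
  att = list(pooling = "attention", adversarial = FALSE),
  da = list(pooling = "mean", adversarial = TRUE),
  full = list(pooling = "attention", adversarial = TRUE)
)

#' Four-variant ablation
#'
#' `baseline` = mean pooling, lambda 0; `att` = attention pooling, lambda 0;
#' `da` = mean pooling, adversarial; `full` = attention pooling,
#' adversarial. All variants share seeds and every other configuration
#' field, giving paired comparisons.
#'
#' @param cohort list of `eeg_recording`s.
#' @param mcfg,tcfg,plan as in [run_cross_validation()].
#' @param variants subset of `c("baseline", "att", "da", "full")`.
#' @param seeds integer seeds; each variant is run once per seed.
#' @param folds fold indices to evaluate.
#' @param ... passed to [run_cross_validation()] (caps, cache, ...).
#' @return list per variant: `runs` (per-seed CV results), `mean_auc`
#'   (mean over seeds and folds), plus `seeds`.
#' @export
run_ablation <- function(cohort, mcfg, tcfg, plan,
                         variants = c("baseline", "att", "da", "full"),
                         seeds = tcfg$seed, folds = seq_len(plan$k), ...) {
  variants <- match.arg(variants, names(ablation_variants), several.ok = TRUE)
  cache <- preprocess_cohort_cached(cohort)
  out <- list()
  for (v in variants) {
    spec_v <- ablation_variants[[v]]
    mcfg_v <- mcfg
    mcfg_v$pooling <- spec_v$pooling
    runs <- list()
    for (s in seeds) {
      tcfg_s <- tcfg
      tcfg_s$seed <- as.integer(s)
      runs[[as.character(s)]] <- run_cross_validation(
        cohort, mcfg_v, tcfg_s, plan, folds = folds,
        adversarial = spec_v$adversarial, cache = cache, ...
      )
    }
    aucs <- unlist(lapply(runs, function(r) r$report$per_fold$auc))
    out[[v]] <- list(runs = runs, mean_auc = mean(aucs), aucs = aucs)
  }
  out$seeds <- seeds
  out
}

#' Export per-window attention weights from a trained checkpoint
#'
#' @param ckpt an `eegdann_checkpoint` trained with attention pooling.
#' @param windows a `window_set`.
#' @param check_leakage passed to the normalization step.
#' @return list with `attention` (N x 18 matrix, rows sum to 1), `uniform`
#'   (the 1/18 reference), `channel_names`.
#' @export
export_attention_map <- function(ckpt, windows, check_leakage = FALSE) {
  if (ckpt$config$pooling != "attention") {
    stop_eegdann("checkpoint was trained with mean pooling; no attention weights",
                 "eegdann_variant_error")
  }
  sp <- apply_zscore(stft_logmag(windows), ckpt$norm_stats,
                     check_leakage = check_leakage)
  n <- dim(sp$tensor)[1]
  att <- matrix(0, n, 18)
  b0 <- 1L
  while (b0 <= n) {
    b1 <- min(b0 + 63L, n)
    fwd <- model_forward(ckpt$params, ckpt$config,
                         sp$tensor[b0:b1, , , , drop = FALSE],
                         training = FALSE)
    att[b0:b1, ] <- fwd$attention
    b0 <- b1 + 1L
  }
  colnames(att) <- bipolar_channel_names()
  list(attention = att, uniform = 1 / 18,
       channel_names = bipolar_channel_names())
}

#' Pooled backbone features of a window set (evaluation mode)
#'
#' @param params model parameters.
#' @param cfg the [model_config()].
#' @param tensor normalized spectrogram tensor (N x 18 x 33 x 17).
#' @return N x pooled_dim feature matrix.
#' @export
extract_pooled_features <- function(params, cfg, tensor) {
  n <- dim(tensor)[1]
  z <- matrix(0, n, cfg$pooled_dim)
  b0 <- 1L
  while (b0 <= n) {
    b1 <- min(b0 + 63L, n)
    fwd <- model_forward(params, cfg, tensor[b0:b1, , , , drop = FALSE],
                         training = FALSE)
    z[b0:b1, ] <- fwd$pooled
    b0 <- b1 + 1L
  }
  z
}

#' Linear domain probe: how much subject identity remains in the features?
#'
#' Trains a multinomial logistic probe on pooled features to predict the
#' subject (domain) label, and reports held-out accuracy. Run against the
#' backbone at initialization versus after adversarial training, a drop
#' toward chance (1 / n_domains) indicates domain-invariant features.
#'
#' @param features N x D pooled feature matrix.
#' @param domains integer domain labels in `1..K`.
#' @param train_idx indices used to fit the probe; the rest are the held-out
#'   evaluation set.
#' @param seed probe initialization seed.
#' @param epochs full-batch gradient steps.
#' @param lr learning rate.
#' @return list with `accuracy` (held-out), `chance` (= 1/K).
#' @export
domain_probe_accuracy <- function(features, domains, train_idx,
                                  seed = 1L, epochs = 300L, lr = 0.05) {
  k <- max(domains)
  d <- ncol(features)
  # standardize features for a well-conditioned probe
  mu <- colMeans(features[train_idx, , drop = FALSE])
  sdv <- pmax(apply(features[train_idx, , drop = FALSE], 2, sd), 1e-6)
  x <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  xtr <- x[train_idx, , drop = FALSE]
  ytr <- domains[train_idx]
  xte <- x[-train_idx, , drop = FALSE]
  yte <- domains[-train_idx]
  p <- with_seed(seed, init_linear(d, k))
  opt <- adamw_init(p)
  onehot <- matrix(0, length(ytr), k)
  onehot[cbind(seq_along(ytr), ytr)] <- 1
  for (e in seq_len(epochs)) {
    lf <- linear_fwd(xtr, p)
    probs <- softmax_rows(lf$out)
    g <- softmax_ce_grad(probs, onehot)
    lb <- linear_bwd(g, p, lf$cache)
    st <- adamw_step(p, lb[c("W", "b")], opt, lr, 0)
    p <- st$params
    opt <- st$opt
  }
  pred <- max.col(linear_fwd(xte, p)$out)
  list(accuracy = mean(pred == yte), chance = 1 / k)
}
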