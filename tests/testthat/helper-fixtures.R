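# Shared fixtures, memoised so expensive objects are built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Minimal cohort: 2 seizure + 2 non-seizure subjects, 60 s recordings.
tiny_cohort <- function() {
  memo("tiny_cohort", function() {
    generate_cohort(cohort_config(n_subjects_per_group = 2, duration_s = 60,
                                  burst_rate = 4, seed = 424))
  })
}

tiny_cohort_cache <- function() {
  memo("tiny_cohort_cache", function() {
    eegdann:::preprocess_cohort_cached(tiny_cohort())
  })
}

# Micro model: exercises every layer at trivial cost.
micro_model_config <- function(n_domains = 0L, pooling = "attention") {
  model_config(n_domains = n_domains, base_width = 4L, blocks_per_stage = 1L,
               lstm_hidden = 6L, attention_hidden = 5L, head_hidden = 7L,
               dropout_p = 0, pooling = pooling)
}

micro_train_config <- function(...) {
  train_config(lr = 1e-3, batch_size = 16, max_epochs = 2, patience = 2,
               seed = 11, val_fraction = 0, ...)
}

# A labeled micro window set derived from the tiny cohort.
tiny_window_set <- function(role = "train") {
  cache <- tiny_cohort_cache()
  bind_window_sets(lapply(cache, function(x) x[[role]]))
}

random_window_set <- function(n = 6, seed = 1, role = "train",
                              subject_ids = rep("s1", n)) {
  set.seed(seed)
  structure(
    list(windows = array(rnorm(n * 18 * 256), dim = c(n, 18, 256)),
         labels = rep_len(c(0L, 1L), n),
         subject_ids = subject_ids,
         start_times_s = seq_len(n) - 1,
         split_role = role),
    class = "window_set"
  )
}

# Numeric gradient of a scalar-valued function of one parameter leaf element.
numeric_grad <- function(params, path, idx, fn, eps = 1e-5) {
  get_leaf <- function(P) Reduce(function(a, b) a[[b]], path, P)
  set_leaf <- function(P, path, leaf) {
    if (length(path) == 1) {
      P[[path[[1]]]] <- leaf
      return(P)
    }
    P[[path[[1]]]] <- set_leaf(P[[path[[1]]]], path[-1], leaf)
    P
  }
  leaf <- get_leaf(params)
  if (length(idx) > 1) idx <- matrix(idx, 1)
  lp <- leaf; lp[idx] <- lp[idx] + eps
  lm <- leaf; lm[idx] <- lm[idx] - eps
  (fn(set_leaf(params, path, lp)) - fn(set_leaf(params, path, lm))) / (2 * eps)
}

get_grad_leaf <- function(grads, path, idx) {
  if (length(idx) > 1) idx <- matrix(idx, 1)
  Reduce(function(a, b) a[[b]], path, grads)[idx]
}

# Micro cross-validation run shared by the experiments and acceptance suites.
micro_cv <- function() {
  memo("micro_cv", function() {
    cohort <- tiny_cohort()
    plan <- make_group_folds(eegdann:::cohort_selection_frame(cohort),
                             k = 2, seed = 1)
    run_cross_validation(cohort, micro_model_config(), micro_train_config(),
                         plan, use_val_split = FALSE,
                         keep_checkpoints = TRUE,
                         cache = tiny_cohort_cache())
  })
}
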