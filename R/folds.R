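## Stratified group-wise (subject-level) fold construction.

#' Stratified subject-level k-fold plan
#'
#' Subjects (never windows) are partitioned into `k` folds. Within each group
#' the subjects are shuffled by seed and dealt round-robin into the folds, so
#' every fold receives subjects from both clinical groups (stratification)
#' and all windows of a subject follow its fold.
#'
#' @param selection a data.frame with columns `subject_id` and `group` (a
#'   `subject_selection` works; only `selected` rows are used when that
#'   column is present).
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @return a `fold_plan`: list with `k`, `assignments` (named integer vector
#'   subject -> fold), `stratified = TRUE`.
#' @export
make_group_folds <- function(selection, k = 5L, seed = 1L) {
  df <- as.data.frame(selection)
  if ("selected" %in% names(df)) df <- df[df$selected, ]
  stopifnot(all(c("subject_id", "group") %in% names(df)))
  assignments <- integer(0)
  for (g in unique(df$group)) {
    subs <- df$subject_id[df$group == g]
    if (length(subs) < k) {
      stop_eegdann(
        sprintf("group '%s' has %d subjects, fewer than k = %d folds",
                g, length(subs), k),
        "eegdann_fold_error"
      )
    }
    subs <- with_seed(derive_seed(seed, match(g, unique(df$group))),
                      sample(subs))
    f <- rep(seq_len(k), length.out = length(subs))
    assignments[subs] <- f
  }
  structure(list(k = as.integer(k), assignments = assignments,
                 stratified = TRUE),
            class = "fold_plan")
}

cohort_selection_frame <- function(cohort) {
  data.frame(
    subject_id = vapply(cohort, function(r) r$subject_id, ""),
    group = vapply(cohort, function(r) r$group, "")
  )
}
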