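## Majority-vote consensus labeling, annotation disagreement rate (ADR),
## and ADR-ranked subject selection.

#' Construct a three-expert annotation set
#'
#' @param annotations 3 x T_seconds 0/1 matrix, one row per expert.
#' @param subject_id character identifier.
#' @return an `annotation_set`.
#' @export
annotation_set <- function(annotations, subject_id = "unknown") {
  annotations <- as.matrix(annotations)
  if (nrow(annotations) != 3) {
    stop_eegdann("annotation set must have exactly 3 expert rows",
                 "eegdann_validation_error")
  }
  if (!is_binary(annotations)) {
    stop_eegdann("annotations must be binary (0/1)",
                 "eegdann_validation_error")
  }
  storage.mode(annotations) <- "integer"
  structure(list(annotations = annotations, subject_id = subject_id),
            class = "annotation_set")
}

as_annotation_set <- function(x) {
  if (inherits(x, "annotation_set")) return(x)
  if (inherits(x, "eeg_recording")) {
    return(annotation_set(x$annotations, x$subject_id))
  }
  annotation_set(x)
}

#' Per-second majority consensus and disagreement tracks
#'
#' For each second, the consensus label is 1 when at least two of the three
#' experts mark seizure; the disagreement flag is 1 when the experts are not
#' unanimous (expert sum in `{1, 2}`).
#'
#' @param ann an [annotation_set()] (or a 3 x T 0/1 matrix, or an
#'   `eeg_recording`).
#' @return a `consensus_track`: list with integer vectors `consensus` and
#'   `disagreement`.
#' @export
consensus_per_second <- function(ann) {
  ann <- as_annotation_set(ann)
  s <- colSums(ann$annotations)
  structure(
    list(consensus = as.integer(s >= 2),
         disagreement = as.integer(s == 1 | s == 2),
         subject_id = ann$subject_id),
    class = "consensus_track"
  )
}

#' Annotation disagreement rate (ADR), in percent
#'
#' `ADR = 100 * T_disagreement / T_total`, where `T_disagreement` is the
#' number of seconds on which the three experts are not unanimous and
#' `T_total` the number of annotated seconds.
#'
#' @inheritParams consensus_per_second
#' @return ADR as a percentage (full precision; round for display).
#' @export
compute_adr <- function(ann) {
  ann <- as_annotation_set(ann)
  t_total <- ncol(ann$annotations)
  if (t_total == 0) {
    stop_eegdann("ADR is undefined for an empty annotation set",
                 "eegdann_validation_error")
  }
  ct <- consensus_per_second(ann)
  100 * sum(ct$disagreement) / t_total
}

#' Select the lowest-ADR subjects per group
#'
#' Ranks subjects within each group in ascending order of ADR (ties broken by
#' lexicographic subject id) and marks the `k_per_group` lowest-ADR subjects
#' of each group as selected.
#'
#' @param selection_input list of entries, each a list with elements `ann`
#'   (an [annotation_set()] or `eeg_recording`) and `group` (`"seizure"` /
#'   `"non_seizure"`); a plain list of `eeg_recording`s (with `$group`) also
#'   works.
#' @param k_per_group number of subjects to keep per group.
#' @return a `subject_selection` data.frame with columns `subject_id`,
#'   `group`, `t_total`, `t_disagreement`, `adr`, `selected`.
#' @export
select_subjects <- function(selection_input, k_per_group) {
  rows <- lapply(selection_input, function(entry) {
    if (inherits(entry, "eeg_recording")) {
      ann <- as_annotation_set(entry)
      group <- entry$group
    } else {
      ann <- as_annotation_set(entry$ann)
      group <- entry$group
    }
    ct <- consensus_per_second(ann)
    data.frame(subject_id = ann$subject_id, group = group,
               t_total = ncol(ann$annotations),
               t_disagreement = sum(ct$disagreement),
               adr = compute_adr(ann))
  })
  df <- do.call(rbind, rows)
  df$selected <- FALSE
  for (g in unique(df$group)) {
    in_g <- which(df$group == g)
    if (length(in_g) < k_per_group) {
      stop_eegdann(
        sprintf("group '%s' has %d subjects, fewer than k_per_group = %d",
                g, length(in_g), k_per_group),
        "eegdann_selection_error"
      )
    }
    ord <- in_g[order(df$adr[in_g], df$subject_id[in_g])]
    df$selected[ord[seq_len(k_per_group)]] <- TRUE
  }
  rownames(df) <- NULL
  class(df) <- c("subject_selection", "data.frame")
  df
}

#' Read an annotations.csv table into per-subject annotation sets
#'
#' Expects columns `subject_id`, `second_index` (0-based), `expert1`,
#' `expert2`, `expert3`.
#'
#' @param path CSV file path.
#' @return named list of [annotation_set()]s.
#' @export
read_annotations_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "second_index", "expert1", "expert2", "expert3")
  if (!all(need %in% names(df))) {
    stop_eegdann("annotations.csv missing required columns",
                 "eegdann_validation_error")
  }
  out <- list()
  for (sid in unique(df$subject_id)) {
    sub <- df[df$subject_id == sid, ]
    sub <- sub[order(sub$second_index), ]
    out[[as.character(sid)]] <- annotation_set(
      rbind(sub$expert1, sub$expert2, sub$expert3), as.character(sid)
    )
  }
  out
}

#' Write a subject-selection report CSV
#'
#' Columns mirror the annotation-quality table: `SampleID`, `Ttotal`,
#' `Tdisagreement`, `ADR` (percent, 2 decimals), plus `group` and `selected`.
#'
#' @param selection a `subject_selection` from [select_subjects()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(selection, path) {
  out <- data.frame(
    SampleID = selection$subject_id,
    Ttotal = selection$t_total,
    Tdisagreement = selection$t_disagreement,
    ADR = sprintf("%.2f", selection$adr),
    group = selection$group,
    selected = selection$selected
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
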