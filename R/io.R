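trial_cols <- c("subject_id", "modality", "pairing", "auditory_snr",
                "visual_snr", "soa", "n_B", "n_D", "n_G")

#' Read and write long-format trial-count tables
#'
#' The on-disk format is a long CSV with one row per (subject, condition):
#' columns `subject_id`, `modality`, `pairing`, `auditory_snr`, `visual_snr`,
#' `soa`, `n_B`, `n_D`, `n_G`. Condition labels must match the enumerated
#' design vocabulary; duplicate (subject, condition) rows and negative counts
#' are rejected with the offending row number. Rows whose counts do not sum
#' to the design's repetition number are accepted with a warning (real data
#' can have dropped trials). An empty file yields an empty cohort with a
#' warning.
#'
#' @param path CSV file path.
#' @param design The `"av_design"` defining the condition vocabulary.
#' @return `read_trials()`: a list of `"av_subject"` objects, in order of
#'   first appearance. `write_trials()`: `path`, invisibly.
#' @export
read_trials <- function(path, design = av_design()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("no trial rows in ", path, "; returning an empty cohort",
            call. = FALSE)
    return(list())
  }
  missing_cols <- setdiff(trial_cols, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  key_design <- condition_key(design$conditions)
  key_rows <- condition_key(df)
  bad <- which(!key_rows %in% key_design)
  if (length(bad)) {
    stop("row ", bad[1], ": condition labels not in the design vocabulary (",
         key_rows[bad[1]], ")", call. = FALSE)
  }
  neg <- which(df$n_B < 0 | df$n_D < 0 | df$n_G < 0)
  if (length(neg)) {
    stop("row ", neg[1], ": negative response count", call. = FALSE)
  }
  dup <- which(duplicated(paste(df$subject_id, key_rows)))
  if (length(dup)) {
    stop("row ", dup[1], ": duplicate (subject, condition) row",
         call. = FALSE)
  }
  off <- df$n_B + df$n_D + df$n_G != design$n_reps
  if (any(off)) {
    warning(sum(off), " row(s) with counts not summing to ", design$n_reps,
            " repetitions (kept)", call. = FALSE)
  }
  lapply(unique(df$subject_id), function(s) {
    av_subject(s, df[df$subject_id == s,
                     setdiff(trial_cols, "subject_id")])
  })
}

#' @rdname read_trials
#' @param cohort List of `"av_subject"` objects (an `"av_cohort"` is
#'   accepted).
#' @export
write_trials <- function(cohort, path, design = av_design()) {
  if (inherits(cohort, "av_cohort")) cohort <- cohort$subjects
  key_design <- condition_key(design$conditions)
  rows <- do.call(rbind, lapply(cohort, function(s) {
    stopifnot(inherits(s, "av_subject"))
    counts <- s$counts[order(match(condition_key(s$counts), key_design)), ]
    cbind(subject_id = s$subject_id, counts[, setdiff(trial_cols,
                                                      "subject_id")])
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate trial-level responses into the count format
#'
#' Converts a trial-by-trial table (one row per presentation with a single
#' `response` column coded B/D/G) into the long count format used by the
#' fitting functions. Column names can be remapped for externally deposited
#' data.
#'
#' @param df Data frame with the condition columns, `subject_id`, and a
#'   response column.
#' @param response Name of the response column (values `"B"`, `"D"`, `"G"`).
#' @param columns Optional named character vector remapping
#'   `c(<internal> = <external>)` column names.
#' @return Data frame in the long count format accepted by [write_trials()].
#' @export
aggregate_trials <- function(df, response = "response", columns = NULL) {
  if (!is.null(columns)) {
    for (internal in names(columns)) {
      names(df)[names(df) == columns[[internal]]] <- internal
    }
  }
  need <- c(setdiff(trial_cols, c("n_B", "n_D", "n_G")), response)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df[[response]] %in% c("B", "D", "G"))) {
    stop("responses must be coded B, D or G", call. = FALSE)
  }
  grp <- setdiff(trial_cols, c("n_B", "n_D", "n_G"))
  agg <- stats::aggregate(df[[response]], by = df[grp], FUN = function(r) {
    c(n_B = sum(r == "B"), n_D = sum(r == "D"), n_G = sum(r == "G"))
  })
  out <- cbind(agg[grp], as.data.frame(agg$x))
  out[order(out$subject_id), ]
}
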