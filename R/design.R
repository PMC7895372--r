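#' Enumerate the audiovisual identification design
#'
#' Builds the full 42-condition design of the B/D/G identification paradigm:
#' auditory-only and visual-only presentations of B and G at three SNR levels
#' (12 unimodal conditions), and audiovisual presentations of three stimulus
#' pairings (congruent B, congruent G, and the McGurk pairing of auditory B
#' with visual G) at five SNR combinations -- clear audio crossed with the
#' three visual SNR levels and clear video crossed with the three auditory
#' SNR levels, deduplicated at clear-clear -- each shown in synchrony and
#' with a 500 ms audio-lead asynchrony (30 audiovisual conditions).
#'
#' Conditions are returned in a fixed canonical order (unimodal auditory,
#' unimodal visual, then audiovisual by pairing, SNR combination, SOA) so that
#' cross-validation folds index the same condition across runs.
#'
#' @param n_reps Number of presentations per condition (default 25, giving
#'   1050 trials in total).
#' @return An object of class `"av_design"`: a list with `conditions`
#'   (a data frame with columns `modality`, `pairing`, `auditory_snr`,
#'   `visual_snr`, `soa`) and `n_reps`.
#' @examples
#' d <- av_design()
#' nrow(d$conditions)   # 42
#' total_trials(d)      # 1050
#' @export
av_design <- function(n_reps = 25) {
  stopifnot(is.numeric(n_reps), length(n_reps) == 1, n_reps >= 0)
  snr <- c("high", "mid", "low")

  aud <- data.frame(
    modality = "auditory_only",
    pairing = rep(c("congruent_B", "congruent_G"), each = 3),
    auditory_snr = rep(snr, 2),
    visual_snr = "n/a",
    soa = "n/a",
    stringsAsFactors = FALSE
  )
  vis <- data.frame(
    modality = "visual_only",
    pairing = rep(c("congruent_B", "congruent_G"), each = 3),
    auditory_snr = "n/a",
    visual_snr = rep(snr, 2),
    soa = "n/a",
    stringsAsFactors = FALSE
  )
  # five SNR combinations: clear audio x 3 visual SNRs, clear video x 3
  # auditory SNRs, with the clear-clear cell counted once
  combos <- data.frame(
    auditory_snr = c("high", "high", "high", "mid", "low"),
    visual_snr   = c("high", "mid", "low", "high", "high"),
    stringsAsFactors = FALSE
  )
  av <- do.call(rbind, lapply(c("congruent_B", "congruent_G", "mcgurk"),
    function(p) {
      do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
        data.frame(
          modality = "audiovisual",
          pairing = p,
          auditory_snr = combos$auditory_snr[i],
          visual_snr = combos$visual_snr[i],
          soa = c("sync", "async"),
          stringsAsFactors = FALSE
        )
      }))
    }))

  conditions <- rbind(aud, vis, av)
  rownames(conditions) <- NULL
  structure(list(conditions = conditions, n_reps = n_reps),
            class = "av_design")
}

#' Total number of trials in a design
#'
#' @param design An `"av_design"` object.
#' @return `nrow(conditions) * n_reps`.
#' @export
total_trials <- function(design) {
  stopifnot(inherits(design, "av_design"))
  nrow(design$conditions) * design$n_reps
}

#' @export
print.av_design <- function(x, ...) {
  cat("Audiovisual identification design:", nrow(x$conditions),
      "conditions x", x$n_reps, "repetitions =", total_trials(x),
      "trials\n")
  tab <- table(x$conditions$modality)
  cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

# Key identifying a condition row; used to match data rows to design rows.
condition_key <- function(df) {
  paste(df$modality, df$pairing, df$auditory_snr, df$visual_snr, df$soa,
        sep = "|")
}
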