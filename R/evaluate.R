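#' Cross-validation RMSE table for a cohort
#'
#' Convenience wrapper: runs [cross_validate()] for every subject and variant
#' and collects the RMSEs into the long-format table [compare_models()]
#' expects.
#'
#' @param cohort List of `"av_subject"` objects (an `"av_cohort"` is
#'   accepted).
#' @param variants Character vector of model variants.
#' @param design The `"av_design"`.
#' @param config A [fit_config()].
#' @return Data frame with columns `subject`, `variant`, `rmse`, plus a
#'   `"cv_results"` attribute holding the `"av_cv"` objects.
#' @export
cv_table <- function(cohort, variants = c("MLE", "ReducedJP"),
                     design = av_design(), config = fit_config()) {
  if (inherits(cohort, "av_cohort")) cohort <- cohort$subjects
  variants <- vapply(variants, match.arg, "", choices = variant_names)
  rows <- expand.grid(subject = vapply(cohort, `[[`, "", "subject_id"),
                      variant = variants, stringsAsFactors = FALSE)
  cvs <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    subj <- cohort[[match(rows$subject[i],
                          vapply(cohort, `[[`, "", "subject_id"))]]
    cvs[[i]] <- cross_validate(subj, rows$variant[i], design, config)
  }
  rows$rmse <- vapply(cvs, `[[`, numeric(1), "rmse")
  attr(rows, "cv_results") <- cvs
  rows
}

#' Compare model variants by cross-validation error
#'
#' Builds the per-subject RMSE table, the improvement of every variant over
#' the MLE strong-fusion baseline (`RMSE_MLE - RMSE_variant`, positive =
#' better than forced fusion), and paired Wilcoxon signed-rank tests for the
#' standard contrasts among the fitted variants: each Bayesian variant vs MLE
#' (one-sided: Bayesian error lower), Full vs Reduced within each family
#' (two-sided), and Joint Prior vs BCI within Reduced and Full
#' implementations (two-sided; no direction is hypothesised between the two
#' Bayesian families).
#'
#' Signed-rank tests use the exact distribution for n <= 25 without ties and
#' drop zero differences (standard Wilcoxon handling).
#'
#' @param cv A data frame with columns `subject`, `variant`, `rmse` (as from
#'   [cv_table()]); every subject must have a result for every variant.
#' @return An `"av_comparison"`: `rmse` (subjects x variants matrix),
#'   `improvement` (same shape, relative to MLE if fitted), and `tests`
#'   (data frame with `contrast`, `alternative`, `statistic`, `p_value`,
#'   `mean_diff`).
#' @export
compare_models <- function(cv) {
  need <- c("subject", "variant", "rmse")
  if (!all(need %in% names(cv))) {
    stop("cv must have columns subject, variant, rmse", call. = FALSE)
  }
  subjects <- unique(cv$subject)
  variants <- unique(cv$variant)
  counts <- table(cv$subject, cv$variant)
  if (!all(counts == 1)) {
    stop("every subject needs exactly one RMSE per variant", call. = FALSE)
  }
  rmse <- matrix(NA_real_, length(subjects), length(variants),
                 dimnames = list(subjects, variants))
  rmse[cbind(match(cv$subject, subjects), match(cv$variant, variants))] <-
    cv$rmse

  improvement <- NULL
  if ("MLE" %in% variants) improvement <- rmse[, "MLE"] - rmse

  contrasts <- list(
    list(a = "ReducedJP", b = "MLE", alt = "less"),
    list(a = "ReducedBCI", b = "MLE", alt = "less"),
    list(a = "FullJP", b = "MLE", alt = "less"),
    list(a = "FullBCI", b = "MLE", alt = "less"),
    list(a = "FullJP", b = "ReducedJP", alt = "two.sided"),
    list(a = "FullBCI", b = "ReducedBCI", alt = "two.sided"),
    list(a = "ReducedJP", b = "ReducedBCI", alt = "two.sided"),
    list(a = "FullJP", b = "FullBCI", alt = "two.sided")
  )
  tests <- do.call(rbind, lapply(contrasts, function(ct) {
    if (!all(c(ct$a, ct$b) %in% variants)) return(NULL)
    x <- rmse[, ct$a]
    y <- rmse[, ct$b]
    wt <- signed_rank_test(x, y, alternative = ct$alt)
    data.frame(contrast = paste(ct$a, "vs", ct$b),
               alternative = ct$alt,
               statistic = wt$statistic, p_value = wt$p_value,
               mean_diff = mean(x - y), stringsAsFactors = FALSE)
  }))
  structure(list(rmse = rmse, improvement = improvement, tests = tests),
            class = "av_comparison")
}

# Paired Wilcoxon signed-rank via stats::wilcox.test, with the degenerate
# all-zero-differences case reported as non-significant rather than an error.
signed_rank_test <- function(x, y, alternative = "two.sided") {
  d <- x - y
  if (all(d == 0)) {
    return(list(statistic = 0, p_value = 1))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, alternative = alternative))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' @export
print.av_comparison <- function(x, ...) {
  cat("Model comparison over", nrow(x$rmse), "subjects\n")
  cat("Mean CV RMSE by variant:\n")
  print(round(colMeans(x$rmse), 4))
  if (!is.null(x$improvement)) {
    cat("Mean improvement over MLE baseline:\n")
    print(round(colMeans(x$improvement), 4))
  }
  if (!is.null(x$tests)) {
    cat("Pairwise signed-rank tests:\n")
    print(x$tests, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Test binding-prior parameters against complete binding
#'
#' One-sided one-sample t-tests of the fitted binding parameters against zero
#' (complete binding), asynchronous and synchronous conditions separately:
#' under the causal-inference account the asynchronous binding parameter
#' should exceed zero while the synchronous one should not. Constant
#' parameter vectors (zero variance across subjects) make the t statistic
#' undefined; such cases are flagged and reported as non-significant with an
#' `NA` statistic.
#'
#' @param fits List of `"av_fit"` objects (one per subject), all of the same
#'   Full variant (Reduced variants pin the synchronous value, leaving
#'   nothing to test there; they are accepted and the sync row is then
#'   degenerate at 0).
#' @return Data frame with one row per synchrony condition: `n`, `mean`,
#'   `sd`, `statistic`, `p_value`, `degenerate`.
#' @export
prior_parameter_tests <- function(fits) {
  if (length(fits) < 2) {
    stop("prior parameter tests need at least 2 subjects", call. = FALSE)
  }
  kinds <- vapply(fits, function(f) f$params$prior$kind, "")
  if (length(unique(kinds)) != 1 || kinds[1] == "mle") {
    stop("fits must share one Bayesian prior family", call. = FALSE)
  }
  vals <- vapply(fits, function(f) {
    c(sync = f$params$prior$value_sync, async = f$params$prior$value_async)
  }, numeric(2))
  out <- do.call(rbind, lapply(c("sync", "async"), function(cnd) {
    v <- vals[cnd, ]
    degenerate <- stats::sd(v) == 0
    if (degenerate) {
      stat <- NA_real_
      p <- 1
    } else {
      tt <- stats::t.test(v, mu = 0, alternative = "greater")
      stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    data.frame(condition = cnd, n = length(v), mean = mean(v),
               sd = stats::sd(v), statistic = stat, p_value = p,
               degenerate = degenerate, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Test the SNR ordering of fitted sensory precisions
#'
#' One-sided paired Wilcoxon signed-rank tests that fitted precision
#' (\eqn{1/\sigma^2}) decreases with the SNR level, separately per modality:
#' high > mid and mid > low.
#'
#' @param fits List of `"av_fit"` objects, one per subject.
#' @return Data frame with columns `modality`, `contrast`, `statistic`,
#'   `p_value`, `mean_diff` (mean paired precision difference).
#' @export
precision_ordering_tests <- function(fits) {
  if (length(fits) < 2) {
    stop("precision ordering tests need at least 2 subjects", call. = FALSE)
  }
  prec <- function(f, mod) 1 / f$params$likelihood[[paste0("sigma2_", mod)]]
  out <- do.call(rbind, lapply(c("A", "V"), function(mod) {
    m <- t(vapply(fits, prec, numeric(3), mod = mod))
    do.call(rbind, lapply(list(c("high", "mid"), c("mid", "low")),
      function(pair) {
        wt <- signed_rank_test(m[, pair[1]], m[, pair[2]],
                               alternative = "greater")
        data.frame(modality = mod,
                   contrast = paste(pair[1], ">", pair[2]),
                   statistic = wt$statistic, p_value = wt$p_value,
                   mean_diff = mean(m[, pair[1]] - m[, pair[2]]),
                   stringsAsFactors = FALSE)
      }))
  }))
  rownames(out) <- NULL
  out
}

#' Auditory weights implied by a fitted Joint Prior model
#'
#' For every audiovisual condition, the weight of the auditory cue in the
#' fused estimate, computed from the fitted binding variance
#' (synchrony-appropriate) and the SNR-appropriate sensory variances via
#' [auditory_weight()]. Only defined for the Joint Prior family (the MLE
#' baseline is the `sigma_o2 = 0` member and is accepted).
#'
#' @param fit An `"av_fit"` of variant MLE, ReducedJP or FullJP.
#' @param design The `"av_design"`.
#' @return Data frame of the audiovisual conditions with a `w_A` column.
#' @export
extract_auditory_weights <- function(fit, design = av_design()) {
  stopifnot(inherits(fit, "av_fit"))
  if (!fit$variant %in% c("MLE", "ReducedJP", "FullJP")) {
    stop("auditory weights are defined for the Joint Prior family, not ",
         fit$variant, call. = FALSE)
  }
  cond <- design$conditions
  av <- cond[cond$modality == "audiovisual", , drop = FALSE]
  lk <- fit$params$likelihood
  pr <- fit$params$prior
  so2 <- ifelse(av$soa == "async", pr$value_async, pr$value_sync)
  w <- auditory_weight(so2, lk$sigma2_A[av$auditory_snr],
                       lk$sigma2_V[av$visual_snr])
  out <- cbind(av, w_A = as.numeric(w))
  rownames(out) <- NULL
  out
}
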