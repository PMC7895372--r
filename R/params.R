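#' Observer parameter objects
#'
#' An observer is specified by (i) likelihood parameters -- category means for
#' B and G on the one-dimensional place-of-articulation axis in each modality,
#' and one variance per SNR level and modality; (ii) a binding prior, whose
#' form depends on the model family; and (iii) a response map: two boundaries
#' cutting the finite representation interval into the B, D and G response
#' regions.
#'
#' Five variants are supported. `"MLE"` is the strong-fusion baseline (binding
#' forced to be complete in all conditions). `"ReducedJP"` and `"FullJP"` are
#' Joint Prior observers whose binding prior is a Gaussian ridge along the
#' audiovisual diagonal with cross-diagonal variance `sigma_o2` (0 = complete
#' binding); the Reduced variant pins the synchronous value at 0 and fits only
#' the asynchronous one. `"ReducedBCI"` and `"FullBCI"` are causal-inference
#' observers parameterized by the prior probability of separate causes
#' `p_separate` (0 = complete binding), again with the synchronous value
#' pinned at 0 in the Reduced variant. Free-parameter counts are 12 (MLE),
#' 13 (Reduced) and 14 (Full).
#'
#' @param mu_A_B,mu_A_G Auditory category means for B and G, inside the
#'   representation interval.
#' @param mu_V_B,mu_V_G Visual category means for B and G.
#' @param sigma2_A,sigma2_V Named numeric vectors of length 3
#'   (`high`, `mid`, `low`): likelihood variance per SNR level, all > 0.
#' @param kind Prior family: `"mle"`, `"joint_prior"` or `"bci"`.
#' @param value_sync,value_async Binding parameter per synchrony condition:
#'   `sigma_o2 >= 0` for `joint_prior`, `p_separate` in `[0, 1]` for `bci`,
#'   both 0 for `mle`.
#' @param b1,b2 Response boundaries, `lo < b1 < b2 < hi`.
#' @param interval_lo,interval_hi Bounds of the finite representation
#'   interval; fixed constants, not fitted (default `[0, 1]`).
#' @return `likelihood_params()`, `prior_params()` and `response_map()` return
#'   validated lists of the respective class; `observer_params()` returns an
#'   `"av_observer"` combining them with a `variant` label.
#' @name observer_params
NULL

snr_levels <- c("high", "mid", "low")

#' @rdname observer_params
#' @export
likelihood_params <- function(mu_A_B, mu_A_G, mu_V_B, mu_V_G,
                              sigma2_A, sigma2_V) {
  mus <- c(mu_A_B, mu_A_G, mu_V_B, mu_V_G)
  if (!all(is.finite(mus))) {
    stop("category means must be finite", call. = FALSE)
  }
  for (s2 in list(A = sigma2_A, V = sigma2_V)) {
    if (length(s2) != 3 || !all(is.finite(s2)) || any(s2 <= 0)) {
      stop("sigma2_A and sigma2_V must each give 3 finite positive variances",
           call. = FALSE)
    }
  }
  sigma2_A <- stats::setNames(as.numeric(sigma2_A), snr_levels)
  sigma2_V <- stats::setNames(as.numeric(sigma2_V), snr_levels)
  structure(list(mu_A_B = mu_A_B, mu_A_G = mu_A_G,
                 mu_V_B = mu_V_B, mu_V_G = mu_V_G,
                 sigma2_A = sigma2_A, sigma2_V = sigma2_V),
            class = "likelihood_params")
}

#' @rdname observer_params
#' @export
prior_params <- function(kind = c("mle", "joint_prior", "bci"),
                         value_sync = 0, value_async = 0) {
  kind <- match.arg(kind)
  vals <- c(value_sync, value_async)
  if (!all(is.finite(vals))) stop("prior values must be finite", call. = FALSE)
  if (kind == "mle" && any(vals != 0)) {
    stop("the MLE prior has both binding values fixed at 0", call. = FALSE)
  }
  if (kind == "joint_prior" && any(vals < 0)) {
    stop("sigma_o2 must be >= 0", call. = FALSE)
  }
  if (kind == "bci" && (any(vals < 0) || any(vals > 1))) {
    stop("p_separate must lie in [0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, value_sync = value_sync,
                 value_async = value_async),
            class = "prior_params")
}

#' @rdname observer_params
#' @export
response_map <- function(b1, b2, interval_lo = 0, interval_hi = 1) {
  if (!(is.finite(interval_lo) && is.finite(interval_hi) &&
        is.finite(b1) && is.finite(b2) &&
        interval_lo < b1 && b1 < b2 && b2 < interval_hi)) {
    stop("response map requires interval_lo < b1 < b2 < interval_hi",
         call. = FALSE)
  }
  structure(list(interval_lo = interval_lo, interval_hi = interval_hi,
                 b1 = b1, b2 = b2),
            class = "response_map")
}

variant_names <- c("MLE", "ReducedJP", "FullJP", "ReducedBCI", "FullBCI")

variant_prior_kind <- function(variant) {
  switch(variant,
         MLE = "mle",
         ReducedJP = , FullJP = "joint_prior",
         ReducedBCI = , FullBCI = "bci",
         stop("unknown variant: ", variant, call. = FALSE))
}

#' @rdname observer_params
#' @param likelihood A `likelihood_params` object.
#' @param prior A `prior_params` object.
#' @param rmap A `response_map` object.
#' @param variant One of `"MLE"`, `"ReducedJP"`, `"FullJP"`, `"ReducedBCI"`,
#'   `"FullBCI"`.
#' @export
observer_params <- function(likelihood, prior, rmap,
                            variant = c("MLE", "ReducedJP", "FullJP",
                                        "ReducedBCI", "FullBCI")) {
  variant <- match.arg(variant)
  stopifnot(inherits(likelihood, "likelihood_params"),
            inherits(prior, "prior_params"),
            inherits(rmap, "response_map"))
  if (prior$kind != variant_prior_kind(variant)) {
    stop("prior kind '", prior$kind, "' does not match variant '", variant,
         "'", call. = FALSE)
  }
  if (variant %in% c("MLE", "ReducedJP", "ReducedBCI") &&
      prior$value_sync != 0) {
    stop("variant ", variant, " pins the synchronous binding value at 0",
         call. = FALSE)
  }
  lo <- rmap$interval_lo
  hi <- rmap$interval_hi
  mus <- c(likelihood$mu_A_B, likelihood$mu_A_G,
           likelihood$mu_V_B, likelihood$mu_V_G)
  if (any(mus <= lo) || any(mus >= hi)) {
    stop("category means must lie strictly inside the representation interval",
         call. = FALSE)
  }
  structure(list(likelihood = likelihood, prior = prior,
                 response_map = rmap, variant = variant),
            class = "av_observer")
}

#' Number of free parameters of a model variant
#'
#' 12 shared parameters (4 category means, 6 SNR variances, 2 response
#' boundaries) plus 0 (MLE), 1 (Reduced: asynchronous binding value) or
#' 2 (Full: one binding value per synchrony condition).
#'
#' @param variant Variant name.
#' @return Integer count.
#' @export
n_free_params <- function(variant) {
  variant <- match.arg(variant, variant_names)
  12L + switch(variant, MLE = 0L, ReducedJP = , ReducedBCI = 1L,
               FullJP = , FullBCI = 2L)
}

#' @export
print.av_observer <- function(x, ...) {
  cat("Observer model (", x$variant, ", ", n_free_params(x$variant),
      " free parameters)\n", sep = "")
  lk <- x$likelihood
  cat(sprintf("  means: mu_A = (B %.3f, G %.3f), mu_V = (B %.3f, G %.3f)\n",
              lk$mu_A_B, lk$mu_A_G, lk$mu_V_B, lk$mu_V_G))
  cat("  sigma2_A (high/mid/low):",
      paste(signif(lk$sigma2_A, 4), collapse = " / "), "\n")
  cat("  sigma2_V (high/mid/low):",
      paste(signif(lk$sigma2_V, 4), collapse = " / "), "\n")
  lab <- switch(x$prior$kind, mle = "binding fixed (MLE)",
                joint_prior = "sigma_o2", bci = "P(separate causes)")
  cat(sprintf("  prior [%s]: sync = %.4g, async = %.4g\n", lab,
              x$prior$value_sync, x$prior$value_async))
  rm <- x$response_map
  cat(sprintf("  boundaries: %.3f / %.3f on [%g, %g]\n", rm$b1, rm$b2,
              rm$interval_lo, rm$interval_hi))
  invisible(x)
}
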