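#' Auditory weight of the fused estimate
#'
#' The weight of the auditory mean in the marginal audiovisual posterior of
#' the Joint Prior observer,
#' \deqn{w_A = (2\sigma_o^2 + \sigma_V^2) / (2\sigma_o^2 + \sigma_V^2 +
#'   \sigma_A^2),}
#' where \eqn{\sigma_o^2} is the cross-diagonal variance of the binding prior
#' and \eqn{\sigma_A^2, \sigma_V^2} the sensory variances. At
#' \eqn{\sigma_o^2 = 0} this is inverse-variance (MLE) weighting; as
#' \eqn{\sigma_o^2 \to \infty} the weight goes to 1 and the cues are
#' segregated. All arguments are recycled to a common length.
#'
#' @param sigma_o2 Binding-prior variance, `>= 0`.
#' @param sigma2_A,sigma2_V Auditory and visual likelihood variances, `> 0`.
#' @return Weight(s) in `[0, 1]`.
#' @examples
#' auditory_weight(0, 1, 1)    # 0.5: symmetric MLE case
#' auditory_weight(0, 1, 3)    # 0.75
#' auditory_weight(1e12, 1, 1) # ~1: full segregation
#' @export
auditory_weight <- function(sigma_o2, sigma2_A, sigma2_V) {
  if (any(!is.finite(sigma2_A)) || any(sigma2_A <= 0) ||
      any(!is.finite(sigma2_V)) || any(sigma2_V <= 0)) {
    stop("sensory variances must be finite and > 0", call. = FALSE)
  }
  if (any(sigma_o2 < 0)) stop("sigma_o2 must be >= 0", call. = FALSE)
  (2 * sigma_o2 + sigma2_V) / (2 * sigma_o2 + sigma2_V + sigma2_A)
}

#' Marginal auditory posteriors of the observer models
#'
#' `joint_prior_posterior()` returns the auditory marginal of the Joint Prior
#' observer's audiovisual posterior: a Gaussian with mean
#' \eqn{\mu_{AV} = w_A \mu_A + (1 - w_A)\mu_V} and variance
#' \eqn{\sigma_{AV}^2 = w_A \sigma_A^2}, with \eqn{w_A} from
#' [auditory_weight()]. `mle_posterior()` is the strong-fusion special case
#' \eqn{\sigma_o^2 = 0} (inverse-variance weighting; variance
#' \eqn{\sigma_A^2\sigma_V^2 / (\sigma_A^2 + \sigma_V^2)}).
#' `bci_posterior()` returns the causal-inference posterior for an auditory
#' report: a two-component mixture of the fused MLE posterior (weight
#' `1 - p_separate`) and the auditory likelihood alone (weight `p_separate`).
#'
#' @param mu_A,mu_V Auditory and visual likelihood means.
#' @param sigma2_A,sigma2_V Auditory and visual likelihood variances, `> 0`.
#' @param sigma_o2 Binding-prior variance, `>= 0`.
#' @param p_separate Prior probability of separate causes, in `[0, 1]`.
#' @return `joint_prior_posterior()` and `mle_posterior()` return a
#'   `"gaussian1d"` list (`mean`, `variance`); `bci_posterior()` returns a
#'   `"gaussian_mixture1d"` list (`means`, `variances`, `weights`).
#' @examples
#' mle_posterior(0, 1, 1, 1)                        # mean 0.5, variance 0.5
#' joint_prior_posterior(0.2, 0.04, 0.8, 0.04, 0.01) # mean 0.44, var 0.024
#' bci_posterior(0.2, 0.04, 0.8, 0.04, 0.3)
#' @export
joint_prior_posterior <- function(mu_A, sigma2_A, mu_V, sigma2_V, sigma_o2) {
  w <- auditory_weight(sigma_o2, sigma2_A, sigma2_V)
  gaussian1d(w * mu_A + (1 - w) * mu_V, w * sigma2_A)
}

#' @rdname joint_prior_posterior
#' @export
mle_posterior <- function(mu_A, sigma2_A, mu_V, sigma2_V) {
  joint_prior_posterior(mu_A, sigma2_A, mu_V, sigma2_V, 0)
}

#' @rdname joint_prior_posterior
#' @export
bci_posterior <- function(mu_A, sigma2_A, mu_V, sigma2_V, p_separate) {
  if (!is.finite(p_separate) || p_separate < 0 || p_separate > 1) {
    stop("p_separate must lie in [0, 1]", call. = FALSE)
  }
  fused <- mle_posterior(mu_A, sigma2_A, mu_V, sigma2_V)
  gaussian_mixture1d(means = c(fused$mean, mu_A),
                     variances = c(fused$variance, sigma2_A),
                     weights = c(1 - p_separate, p_separate))
}

#' One-dimensional Gaussian and Gaussian-mixture posteriors
#'
#' Light containers for posteriors on the place-of-articulation axis before
#' category read-out. Mixture weights must be non-negative and sum to 1.
#'
#' @param mean,variance Mean and (strictly positive) variance.
#' @param means,variances,weights Parallel vectors of component parameters.
#' @return A `"gaussian1d"` or `"gaussian_mixture1d"` list.
#' @export
gaussian1d <- function(mean, variance) {
  if (any(!is.finite(variance)) || any(variance <= 0)) {
    stop("variance must be finite and > 0", call. = FALSE)
  }
  structure(list(mean = mean, variance = variance), class = "gaussian1d")
}

#' @rdname gaussian1d
#' @export
gaussian_mixture1d <- function(means, variances, weights) {
  if (length(means) != length(variances) ||
      length(means) != length(weights)) {
    stop("means, variances and weights must have equal length", call. = FALSE)
  }
  if (any(!is.finite(variances)) || any(variances <= 0)) {
    stop("variances must be finite and > 0", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(means = means, variances = variances, weights = weights),
            class = "gaussian_mixture1d")
}

#' Response-category probabilities of a posterior
#'
#' Restricts the posterior to the finite representation interval and reads out
#' the three response categories: the probabilities of B, D and G are the
#' masses of the posterior on `[lo, b1]`, `[b1, b2]` and `[b2, hi]`, each
#' divided by the total mass on `[lo, hi]` (the tails outside the interval are
#' discarded, not lumped into the end categories). Mixtures are truncated as a
#' whole: interval masses are weight-averaged over components before
#' renormalization.
#'
#' @param dist A `"gaussian1d"` or `"gaussian_mixture1d"` object.
#' @param rmap A [response_map()].
#' @return Named numeric vector `c(B = , D = , G = )` summing to 1.
#' @examples
#' post <- joint_prior_posterior(0.2, 0.04, 0.8, 0.04, 0.01)
#' category_probabilities(post, response_map(1/3, 2/3))
#' @export
category_probabilities <- function(dist, rmap) {
  stopifnot(inherits(rmap, "response_map"))
  cuts <- c(rmap$interval_lo, rmap$b1, rmap$b2, rmap$interval_hi)
  if (inherits(dist, "gaussian1d")) {
    means <- dist$mean
    variances <- dist$variance
    weights <- 1
  } else if (inherits(dist, "gaussian_mixture1d")) {
    means <- dist$means
    variances <- dist$variances
    weights <- dist$weights
  } else {
    stop("dist must be a gaussian1d or gaussian_mixture1d", call. = FALSE)
  }
  sds <- sqrt(variances)
  # rows: the 4 cut points, cols: components
  cdf <- stats::pnorm(outer(cuts, means, "-") / rep(sds, each = 4))
  mass <- (cdf[2:4, , drop = FALSE] - cdf[1:3, , drop = FALSE]) %*% weights
  total <- sum(mass)
  if (!is.finite(total) || total < 1e-300) {
    stop("degenerate posterior: no probability mass on the representation ",
         "interval", call. = FALSE)
  }
  stats::setNames(as.numeric(mass) / total, c("B", "D", "G"))
}

# --- vectorized prediction over a whole design -----------------------------

# Precomputed integer plan for fast repeated prediction of all conditions.
# For each condition: modality code (1 aud-only, 2 vis-only, 3 AV), indices
# into the mean/variance parameter vectors, and SOA code (1 sync, 2 async).
# McGurk pairs auditory B with visual G.
design_plan <- function(design) {
  cond <- design$conditions
  snr_idx <- function(x) match(x, snr_levels)
  aud_cons <- ifelse(cond$pairing == "congruent_G", 2L, 1L) # B=1, G=2; mcgurk -> A is B
  vis_cons <- ifelse(cond$pairing == "congruent_B", 1L, 2L) # mcgurk -> V is G
  list(
    modality = match(cond$modality,
                     c("auditory_only", "visual_only", "audiovisual")),
    aud_cons = aud_cons,
    vis_cons = vis_cons,
    a_snr = snr_idx(cond$auditory_snr),
    v_snr = snr_idx(cond$visual_snr),
    soa = match(cond$soa, c("sync", "async")),
    n = nrow(cond)
  )
}

# Category probabilities for every condition in the plan; returns an n x 3
# matrix. Works on the raw parameter pieces so the optimizer can call it
# without rebuilding av_observer objects.
predict_plan <- function(plan, mu_A, mu_V, sigma2_A, sigma2_V,
                         prior_kind, prior_vals, cuts) {
  n <- plan$n
  m1 <- numeric(n); v1 <- numeric(n)        # first (or only) component
  m2 <- numeric(n); v2 <- numeric(n)        # BCI segregation component
  w1 <- rep(1, n)

  ia <- plan$modality == 1L
  iv <- plan$modality == 2L
  iav <- plan$modality == 3L

  if (any(ia)) {
    m1[ia] <- mu_A[plan$aud_cons[ia]]
    v1[ia] <- sigma2_A[plan$a_snr[ia]]
  }
  if (any(iv)) {
    m1[iv] <- mu_V[plan$vis_cons[iv]]
    v1[iv] <- sigma2_V[plan$v_snr[iv]]
  }
  if (any(iav)) {
    mA <- mu_A[plan$aud_cons[iav]]
    mV <- mu_V[plan$vis_cons[iav]]
    s2A <- sigma2_A[plan$a_snr[iav]]
    s2V <- sigma2_V[plan$v_snr[iav]]
    pv <- prior_vals[plan$soa[iav]]
    if (prior_kind == "bci") {
      w <- s2V / (s2V + s2A)
      m1[iav] <- w * mA + (1 - w) * mV
      v1[iav] <- w * s2A
      m2[iav] <- mA
      v2[iav] <- s2A
      w1[iav] <- 1 - pv
    } else {
      so2 <- if (prior_kind == "mle") 0 else pv
      w <- (2 * so2 + s2V) / (2 * so2 + s2V + s2A)
      m1[iav] <- w * mA + (1 - w) * mV
      v1[iav] <- w * s2A
    }
  }

  p <- interval_masses(m1, v1, cuts)
  mix <- w1 < 1
  if (any(mix)) {
    p2 <- interval_masses(m2[mix], v2[mix], cuts)
    p[mix, ] <- w1[mix] * p[mix, ] + (1 - w1[mix]) * p2
  }
  tot <- rowSums(p)
  if (any(!is.finite(tot)) || any(tot < 1e-300)) {
    stop("degenerate posterior: no probability mass on the representation ",
         "interval", call. = FALSE)
  }
  p / tot
}

# n x 3 matrix of Gaussian masses on [lo,b1], [b1,b2], [b2,hi] (unnormalized)
interval_masses <- function(means, variances, cuts) {
  sd <- sqrt(variances)
  c1 <- stats::pnorm((cuts[1] - means) / sd)
  c2 <- stats::pnorm((cuts[2] - means) / sd)
  c3 <- stats::pnorm((cuts[3] - means) / sd)
  c4 <- stats::pnorm((cuts[4] - means) / sd)
  cbind(c2 - c1, c3 - c2, c4 - c3)
}

observer_pieces <- function(params) {
  lk <- params$likelihood
  rm <- params$response_map
  list(mu_A = c(lk$mu_A_B, lk$mu_A_G),
       mu_V = c(lk$mu_V_B, lk$mu_V_G),
       sigma2_A = as.numeric(lk$sigma2_A),
       sigma2_V = as.numeric(lk$sigma2_V),
       prior_kind = params$prior$kind,
       prior_vals = c(params$prior$value_sync, params$prior$value_async),
       cuts = c(rm$interval_lo, rm$b1, rm$b2, rm$interval_hi))
}

#' Predicted response probabilities for the design conditions
#'
#' Maps an observer's parameters to the predicted B/D/G response probabilities
#' for each condition. Auditory-only conditions read out the auditory
#' likelihood of the presented consonant at its SNR; visual-only conditions
#' read out the visual likelihood on the same axis with the same boundaries
#' (the lipreading report); audiovisual conditions read out the variant's
#' marginal posterior, using the synchrony-appropriate binding value. McGurk
#' conditions combine auditory B with visual G.
#'
#' @param params An `"av_observer"` object.
#' @param design An `"av_design"`; predictions are returned for all its
#'   conditions.
#' @param conditions Optional integer vector of design row indices to predict
#'   (default: all).
#' @return A numeric matrix, one row per requested condition, columns
#'   `B`, `D`, `G`, each row summing to 1.
#' @export
predict_conditions <- function(params, design, conditions = NULL) {
  stopifnot(inherits(params, "av_observer"), inherits(design, "av_design"))
  plan <- design_plan(design)
  pc <- observer_pieces(params)
  p <- predict_plan(plan, pc$mu_A, pc$mu_V, pc$sigma2_A, pc$sigma2_V,
                    pc$prior_kind, pc$prior_vals, pc$cuts)
  colnames(p) <- c("B", "D", "G")
  if (!is.null(conditions)) p <- p[conditions, , drop = FALSE]
  p
}

#' @rdname predict_conditions
#' @param cond A single-row data frame (or list) with the condition fields
#'   `modality`, `pairing`, `auditory_snr`, `visual_snr`, `soa`.
#' @export
predict_condition <- function(params, cond) {
  stopifnot(inherits(params, "av_observer"))
  cond <- as.data.frame(cond, stringsAsFactors = FALSE)
  if (nrow(cond) != 1) stop("cond must be a single condition", call. = FALSE)
  if (!cond$modality %in% c("auditory_only", "visual_only", "audiovisual")) {
    stop("unknown modality: ", cond$modality, call. = FALSE)
  }
  if (cond$modality == "audiovisual" && !cond$soa %in% c("sync", "async")) {
    stop("unknown soa: ", cond$soa, call. = FALSE)
  }
  snr_of <- function(x) {
    if (!x %in% snr_levels) stop("unknown SNR level: ", x, call. = FALSE)
    x
  }
  if (cond$modality != "visual_only") snr_of(cond$auditory_snr)
  if (cond$modality != "auditory_only") snr_of(cond$visual_snr)
  fake <- list(conditions = cond, n_reps = 1)
  class(fake) <- "av_design"
  drop(predict_conditions(params, fake))
}
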