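# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: category probabilities by adaptive quadrature of
# the truncated density, the multinomial log-likelihood via dmultinom, and
# the signed-rank distribution by exhaustive enumeration of sign assignments.

# Truncated-density category probabilities by numeric quadrature.
quad_category_probs <- function(means, variances, weights, rmap) {
  dens <- function(x) {
    rowSums(vapply(seq_along(means), function(i) {
      weights[i] * stats::dnorm(x, means[i], sqrt(variances[i]))
    }, numeric(length(x))))
  }
  piece <- function(a, b) {
    stats::integrate(dens, a, b, rel.tol = 1e-10, abs.tol = 1e-12)$value
  }
  cuts <- c(rmap$interval_lo, rmap$b1, rmap$b2, rmap$interval_hi)
  m <- c(piece(cuts[1], cuts[2]), piece(cuts[2], cuts[3]),
         piece(cuts[3], cuts[4]))
  m / sum(m)
}

# Multinomial NLL (coefficient removed) via dmultinom.
dmultinom_nll <- function(counts, probs) {
  -sum(vapply(seq_len(nrow(counts)), function(i) {
    n <- counts[i, ]
    coef_log <- lgamma(sum(n) + 1) - sum(lgamma(n + 1))
    stats::dmultinom(n, prob = probs[i, ], log = TRUE) - coef_log
  }, numeric(1)))
}

# Exact signed-rank test by enumerating all 2^n sign assignments.
# Returns the W+ statistic (sum of positive ranks) and the p-value, using
# the same two-sided doubling rule as stats::wilcox.test. Assumes no zero
# differences and no tied absolute values.
enum_signed_rank <- function(x, y, alternative = "two.sided") {
  d <- x - y
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  n <- length(d)
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  list(statistic = w_obs, p_value = p)
}

# Random posterior (Gaussian or 2-component mixture) and response map.
random_dist_rmap <- function() {
  lo <- 0
  hi <- 1
  b1 <- runif(1, 0.1, 0.5)
  b2 <- runif(1, b1 + 0.05, 0.95)
  rmap <- response_map(b1, b2, lo, hi)
  # means near (or slightly outside) the interval, variances bounded below
  # so the truncated mass stays well above the degeneracy guard
  if (runif(1) < 0.5) {
    dist <- gaussian1d(runif(1, -0.1, 1.1), exp(runif(1, log(1e-3), log(4))))
  } else {
    w <- runif(1, 0.05, 0.95)
    dist <- gaussian_mixture1d(
      means = runif(2, -0.1, 1.1),
      variances = exp(runif(2, log(1e-3), log(4))),
      weights = c(w, 1 - w))
  }
  list(dist = dist, rmap = rmap)
}

# Random likelihood evaluation (one audiovisual stimulus).
random_likelihood <- function() {
  list(mu_A = runif(1, 0.05, 0.95), sigma2_A = exp(runif(1, log(1e-3), 0)),
       mu_V = runif(1, 0.05, 0.95), sigma2_V = exp(runif(1, log(1e-3), 0)))
}

# Internal transform helpers, re-exported for the suite.
pack_observer <- bindfuse:::pack_observer
unpack_theta <- bindfuse:::unpack_theta
draw_inits <- bindfuse:::draw_inits
theta_length <- bindfuse:::theta_length

# Natural-scale coefficient vector of an observer (no fit required).
coef_from_params <- function(params) {
  coef(structure(list(params = params), class = "av_fit"))
}

# Auditory weights implied by a true observer (bypasses av_fit).
true_weights <- function(params, design) {
  fake <- structure(list(params = params, variant = params$variant),
                    class = "av_fit")
  extract_auditory_weights(fake, design)$w_A
}
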