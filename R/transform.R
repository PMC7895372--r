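# Unconstrained parameterization used by the optimizer and by between-subject
# perturbation. The representation interval is the fixed constant [0, 1]
# (fixing the axis scale removes the affine non-identifiability of means,
# variances and boundaries). Layout of theta:
#   1-4   qlogis(mu_A_B), qlogis(mu_A_G), qlogis(mu_V_B), qlogis(mu_V_G)
#   5-10  log sigma2_A (high, mid, low), log sigma2_V (high, mid, low)
#   11    t1: b1 = plogis(t1)
#   12    t2: b2 = b1 + (1 - b1) * plogis(t2)   (enforces 0 < b1 < b2 < 1)
#   13    Reduced: async binding value; Full: sync binding value
#   14    Full: async binding value
# Binding values are log(sigma_o2) for the Joint Prior family and
# qlogis(p_separate) for the BCI family; MLE has no binding entries.

theta_length <- function(variant) n_free_params(variant)

theta_names <- function(variant) {
  base <- c("mu_A_B", "mu_A_G", "mu_V_B", "mu_V_G",
            paste0("sigma2_A_", snr_levels), paste0("sigma2_V_", snr_levels),
            "b1", "b2")
  extra <- switch(variant,
                  MLE = character(),
                  ReducedJP = "sigma_o2_async",
                  FullJP = c("sigma_o2_sync", "sigma_o2_async"),
                  ReducedBCI = "p_separate_async",
                  FullBCI = c("p_separate_sync", "p_separate_async"))
  c(base, extra)
}

unpack_theta <- function(theta, variant) {
  if (length(theta) != theta_length(variant)) {
    stop("theta has length ", length(theta), " but variant ", variant,
         " has ", theta_length(variant), " free parameters", call. = FALSE)
  }
  theta <- unname(theta)
  # clamp away from the interval endpoints: a saturated logit (|theta| above
  # ~37) is numerically 0 or 1, which the validated constructors reject
  eps <- 1e-12
  squash <- function(x) pmin(pmax(stats::plogis(x), eps), 1 - eps)
  mus <- squash(theta[1:4])
  s2 <- exp(theta[5:10])
  b1 <- squash(theta[11])
  b2 <- b1 + (1 - b1) * squash(theta[12])
  kind <- variant_prior_kind(variant)
  inv <- if (kind == "bci") stats::plogis else exp
  vals <- switch(variant,
                 MLE = c(0, 0),
                 ReducedJP = , ReducedBCI = c(0, inv(theta[13])),
                 FullJP = , FullBCI = c(inv(theta[13]), inv(theta[14])))
  observer_params(
    likelihood = likelihood_params(mus[1], mus[2], mus[3], mus[4],
                                   s2[1:3], s2[4:6]),
    prior = prior_params(kind, vals[1], vals[2]),
    rmap = response_map(b1, b2),
    variant = variant
  )
}

pack_observer <- function(params) {
  lk <- params$likelihood
  rm <- params$response_map
  pr <- params$prior
  b1 <- rm$b1
  b2 <- rm$b2
  theta <- c(stats::qlogis(c(lk$mu_A_B, lk$mu_A_G, lk$mu_V_B, lk$mu_V_G)),
             log(c(lk$sigma2_A, lk$sigma2_V)),
             stats::qlogis(b1),
             stats::qlogis((b2 - b1) / (1 - b1)))
  fwd <- if (pr$kind == "bci") stats::qlogis else log
  theta <- c(theta, switch(params$variant,
                           MLE = numeric(),
                           ReducedJP = , ReducedBCI = fwd(pr$value_async),
                           FullJP = , FullBCI = fwd(c(pr$value_sync,
                                                      pr$value_async))))
  stats::setNames(theta, theta_names(params$variant))
}

# Random starting points on the unconstrained scale, drawn as natural-scale
# values on documented ranges and transformed. B means start in the lower half
# of the axis and G means in the upper half (the axis orientation is fixed by
# the response-category order B < D < G); variances are log-uniform on
# [1e-3, 1]; sigma_o2 log-uniform on [1e-3, 10]; p_separate uniform on
# [0.05, 0.95].
draw_inits <- function(n, variant) {
  k <- theta_length(variant)
  t(vapply(seq_len(n), function(i) {
    mus <- c(stats::runif(1, 0.02, 0.48), stats::runif(1, 0.52, 0.98),
             stats::runif(1, 0.02, 0.48), stats::runif(1, 0.52, 0.98))
    s2 <- exp(stats::runif(6, log(1e-3), log(1)))
    b1 <- stats::runif(1, 0.10, 0.45)
    b2 <- stats::runif(1, b1 + 0.05, 0.90)
    pars <- c(stats::qlogis(mus), log(s2), stats::qlogis(b1),
              stats::qlogis((b2 - b1) / (1 - b1)))
    n_extra <- k - 12L
    if (n_extra > 0) {
      extra <- if (variant_prior_kind(variant) == "bci") {
        stats::qlogis(stats::runif(n_extra, 0.05, 0.95))
      } else {
        stats::runif(n_extra, log(1e-3), log(10))
      }
      pars <- c(pars, extra)
    }
    pars
  }, numeric(k)))
}
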