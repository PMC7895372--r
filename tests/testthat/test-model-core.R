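test_that("auditory weight follows the closed form and its limits", {
  expect_equal(auditory_weight(0, 1, 1), 0.5)
  expect_equal(auditory_weight(0, 1, 3), 0.75)
  expect_gt(auditory_weight(1e12, 1, 1), 1 - 1e-6)
  expect_error(auditory_weight(0, -1, 1), "variance")
  expect_error(auditory_weight(0, 1, 0), "variance")
  expect_error(auditory_weight(-0.1, 1, 1), "sigma_o2")
})

test_that("auditory weight is monotone in each variance argument", {
  set.seed(101)
  for (i in 1:50) {
    so2 <- exp(runif(1, -5, 2))
    s2A <- exp(runif(1, -5, 1))
    s2V <- exp(runif(1, -5, 1))
    eps <- 1e-4
    w <- auditory_weight(so2, s2A, s2V)
    expect_gt(auditory_weight(so2 + eps, s2A, s2V), w)
    expect_gt(auditory_weight(so2, s2A, s2V + eps), w)
    expect_lt(auditory_weight(so2, s2A + eps, s2V), w)
    expect_true(w >= 0 && w <= 1)
  }
})

test_that("joint prior posterior matches hand-computed arithmetic", {
  g <- joint_prior_posterior(0.2, 0.04, 0.8, 0.04, 0.01)
  # w_A = (0.02 + 0.04) / (0.02 + 0.04 + 0.04) = 0.6
  expect_equal(g$mean, 0.6 * 0.2 + 0.4 * 0.8)
  expect_equal(g$variance, 0.6 * 0.04)
  # full segregation limit
  seg <- joint_prior_posterior(0.2, 0.04, 0.8, 0.04, 1e12)
  expect_equal(seg$mean, 0.2, tolerance = 1e-9)
  expect_equal(seg$variance, 0.04, tolerance = 1e-9)
})

test_that("the MLE posterior is inverse-variance weighting", {
  g <- mle_posterior(0, 1, 1, 1)
  expect_equal(g$mean, 0.5)
  expect_equal(g$variance, 0.5)
  expect_equal(mle_posterior(0.3, 2, 0.3, 5)$mean, 0.3)
  # uninformative visual cue
  expect_equal(mle_posterior(0.2, 0.5, 0.9, 1e12)$mean, 0.2,
               tolerance = 1e-9)
  # zero binding variance reduces the joint prior to the MLE
  set.seed(7)
  for (i in 1:10) {
    lk <- random_likelihood()
    a <- joint_prior_posterior(lk$mu_A, lk$sigma2_A, lk$mu_V, lk$sigma2_V, 0)
    b <- mle_posterior(lk$mu_A, lk$sigma2_A, lk$mu_V, lk$sigma2_V)
    expect_equal(a, b)
  }
})

test_that("the BCI posterior mixes fusion and segregation components", {
  m <- bci_posterior(0.2, 0.04, 0.8, 0.04, 0.3)
  expect_equal(m$weights, c(0.7, 0.3))
  expect_equal(m$means, c(0.5, 0.2))  # fused component via equal variances
  expect_equal(m$variances[2], 0.04)
  expect_error(bci_posterior(0, 1, 0, 1, 1.2), "p_separate")
  expect_error(bci_posterior(0, 1, 0, 1, -0.1), "p_separate")
})

test_that("category probabilities agree with the quadrature oracle", {
  set.seed(2024)
  rmap <- response_map(1/3, 2/3)
  for (i in 1:100) {
    inst <- random_dist_rmap()
    p <- category_probabilities(inst$dist, inst$rmap)
    q <- quad_category_probs(
      if (inherits(inst$dist, "gaussian1d")) inst$dist$mean else inst$dist$means,
      if (inherits(inst$dist, "gaussian1d")) inst$dist$variance else inst$dist$variances,
      if (inherits(inst$dist, "gaussian1d")) 1 else inst$dist$weights,
      inst$rmap)
    expect_equal(unname(p), q, tolerance = 1e-6)
    expect_equal(sum(p), 1, tolerance = 1e-10)
  }
})

test_that("category probabilities handle flat, symmetric and degenerate
           posteriors", {
  rmap <- response_map(1/3, 2/3)
  # near-flat truncated density
  p <- category_probabilities(gaussian1d(0.5, 100), rmap)
  expect_equal(unname(p), rep(1/3, 3), tolerance = 1e-3)
  # symmetry about the interval midpoint
  p2 <- category_probabilities(gaussian1d(0.5, 0.02), rmap)
  expect_equal(p2[["B"]], p2[["G"]], tolerance = 1e-12)
  # concentrated mass in the first interval
  p3 <- category_probabilities(gaussian1d(0.05, 1e-6), rmap)
  expect_gt(p3[["B"]], 1 - 1e-9)
  # no mass on the interval at all
  expect_error(category_probabilities(gaussian1d(50, 1e-4), rmap),
               "degenerate")
})

test_that("JP at zero binding variance, BCI at zero separation probability,
           and MLE give identical predictions", {
  design <- av_design()
  set.seed(99)
  for (i in 1:10) {
    base <- default_observer("MLE")
    theta <- pack_observer(base) + rnorm(12, 0, 0.3)
    mle <- unpack_theta(theta, "MLE")
    jp <- unpack_theta(c(theta, -60), "ReducedJP")     # sigma_o2 = e^-60
    bci <- unpack_theta(c(theta, -60), "ReducedBCI")   # p_sep ~ 1e-26
    p_mle <- predict_conditions(mle, design)
    expect_equal(predict_conditions(jp, design), p_mle, tolerance = 1e-10)
    expect_equal(predict_conditions(bci, design), p_mle, tolerance = 1e-10)
  }
})

test_that("full segregation recovers the auditory-only prediction", {
  design <- av_design()
  lk <- default_observer()$likelihood
  rmap <- default_observer()$response_map
  jp_seg <- observer_params(lk, prior_params("joint_prior", 1e12, 1e12),
                            rmap, "FullJP")
  bci_seg <- observer_params(lk, prior_params("bci", 1, 1), rmap, "FullBCI")
  av_rows <- which(design$conditions$modality == "audiovisual")
  for (j in av_rows) {
    cond <- design$conditions[j, ]
    aud_only <- cond
    aud_only$modality <- "auditory_only"
    aud_only$visual_snr <- "n/a"
    aud_only$soa <- "n/a"
    aud_only$pairing <- if (cond$pairing == "congruent_G") "congruent_G" else
      "congruent_B"  # McGurk auditory component is B
    p_aud <- predict_condition(jp_seg, aud_only)
    expect_equal(predict_condition(jp_seg, cond), p_aud, tolerance = 1e-6)
    expect_equal(predict_condition(bci_seg, cond), p_aud, tolerance = 1e-6)
  }
})

test_that("condition prediction dispatches on modality and validates input", {
  design <- av_design()
  obs <- default_observer("ReducedJP")
  p <- predict_conditions(obs, design)
  expect_equal(dim(p), c(42, 3))
  expect_equal(unname(rowSums(p)), rep(1, 42), tolerance = 1e-10)

  # Reduced variants predict synchronous AV conditions exactly as MLE does
  mle <- default_observer("MLE")
  sync <- which(design$conditions$soa == "sync")
  expect_equal(predict_conditions(obs, design)[sync, ],
               predict_conditions(mle, design)[sync, ], tolerance = 1e-12)

  # visual-only predictions ignore the auditory parameters
  obs2 <- obs
  obs2$likelihood$sigma2_A <- obs$likelihood$sigma2_A * 5
  obs2$likelihood$mu_A_B <- 0.4
  vis <- which(design$conditions$modality == "visual_only")
  expect_equal(predict_conditions(obs2, design)[vis, ],
               predict_conditions(obs, design)[vis, ])

  expect_error(predict_condition(obs, data.frame(
    modality = "audiovisual", pairing = "mcgurk", auditory_snr = "ultra",
    visual_snr = "high", soa = "sync")), "SNR")
  expect_error(predict_condition(obs, data.frame(
    modality = "tactile", pairing = "mcgurk", auditory_snr = "high",
    visual_snr = "high", soa = "sync")), "modality")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(likelihood_params(0.1, 0.9, 0.1, 0.9, c(1, 1), c(1, 1, 1)),
               "3 finite positive")
  expect_error(likelihood_params(0.1, 0.9, 0.1, 0.9, c(1, -1, 1), c(1, 1, 1)),
               "positive")
  expect_error(prior_params("joint_prior", -1, 0), "sigma_o2")
  expect_error(prior_params("bci", 0, 2), "p_separate")
  expect_error(prior_params("mle", 0.5, 0), "fixed at 0")
  expect_error(response_map(0.7, 0.3), "b1 < b2")
  expect_error(response_map(0, 0.5), "b1")
  lk <- default_observer()$likelihood
  expect_error(observer_params(lk, prior_params("bci", 0, 0.5),
                               response_map(1/3, 2/3), "ReducedJP"),
               "does not match")
  expect_error(observer_params(lk, prior_params("joint_prior", 0.2, 0.2),
                               response_map(1/3, 2/3), "ReducedJP"),
               "pins")
  expect_error(gaussian_mixture1d(c(0, 1), c(1, 1), c(0.6, 0.6)), "sum to 1")
  expect_error(gaussian1d(0, 0), "variance")
})
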