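make_subject <- function(seed = 11, variant = "ReducedJP",
                         design = av_design()) {
  simulate_subject(default_observer(variant), design, seed = seed)
}

test_that("the multinomial NLL matches the dmultinom oracle and its closed
           cases", {
  design <- av_design()
  obs <- default_observer("ReducedJP")
  subj <- make_subject(21)

  # three-condition fixture against the independent multinomial oracle
  incl <- c(1, 17, 40)
  counts <- as.matrix(subj$counts[incl, c("n_B", "n_D", "n_G")])
  probs <- predict_conditions(obs, design, conditions = incl)
  expect_equal(negative_log_likelihood(obs, subj, design, included = incl),
               dmultinom_nll(counts, probs), tolerance = 1e-9)

  # near-uniform predictions: one 25-trial condition gives ~ 25 log 3
  flat <- observer_params(
    likelihood_params(0.45, 0.55, 0.45, 0.55,
                      sigma2_A = rep(100, 3), sigma2_V = rep(100, 3)),
    prior_params("mle"), response_map(1/3, 2/3), "MLE")
  expect_equal(negative_log_likelihood(flat, subj, design, included = 1),
               25 * log(3), tolerance = 0.05)

  # predicted probability ~1 for every observed response gives NLL ~ 0
  sharp <- observer_params(
    likelihood_params(0.05, 0.95, 0.05, 0.95,
                      sigma2_A = rep(1e-8, 3), sigma2_V = rep(1e-8, 3)),
    prior_params("mle"), response_map(1/3, 2/3), "MLE")
  s3 <- simulate_subject(sharp, design, seed = 3)
  aud <- which(design$conditions$modality == "auditory_only")
  expect_equal(negative_log_likelihood(sharp, s3, design, included = aud), 0,
               tolerance = 1e-6)

  expect_error(negative_log_likelihood(obs, subj, design,
                                       included = integer()), "non-empty")
})

test_that("the penalized objective adds lambda times the precision sum", {
  design <- av_design()
  subj <- make_subject(22)
  unit <- observer_params(
    likelihood_params(0.2, 0.8, 0.2, 0.8, sigma2_A = rep(1, 3),
                      sigma2_V = rep(1, 3)),
    prior_params("mle"), response_map(1/3, 2/3), "MLE")
  nll <- negative_log_likelihood(unit, subj, design)
  expect_equal(penalized_objective(unit, subj, design, lambda_reg = 0), nll)
  expect_equal(penalized_objective(unit, subj, design, lambda_reg = 7),
               nll + 42)
  # penalty strictly decreasing in each variance
  shrunk <- unit
  shrunk$likelihood$sigma2_A[1] <- 0.5
  expect_gt(penalized_objective(shrunk, subj, design, lambda_reg = 7) -
              negative_log_likelihood(shrunk, subj, design),
            42)
  expect_error(penalized_objective(unit, subj, design, lambda_reg = -1),
               ">= 0")
})

test_that("free-parameter counts are 12/13/14 and match the optimized
           dimension", {
  expected <- c(MLE = 12L, ReducedJP = 13L, FullJP = 14L,
                ReducedBCI = 13L, FullBCI = 14L)
  for (v in names(expected)) {
    expect_identical(n_free_params(v), expected[[v]])
    expect_identical(theta_length(v), expected[[v]])
    expect_identical(ncol(draw_inits(2, v)), as.integer(expected[[v]]))
    obs <- default_observer(v)
    expect_length(pack_observer(obs), expected[[v]])
  }
})

test_that("the transform round-trips and enforces constraints", {
  for (v in c("MLE", "ReducedJP", "FullJP", "ReducedBCI", "FullBCI")) {
    obs <- default_observer(v)
    back <- unpack_theta(pack_observer(obs), v)
    expect_equal(coef_from_params(back), coef_from_params(obs),
                 tolerance = 1e-10)
  }
  set.seed(14)
  for (i in 1:20) {
    theta <- rnorm(13, 0, 5)
    obs <- unpack_theta(theta, "ReducedJP")
    co <- coef_from_params(obs)
    expect_true(all(co[c("mu_A_B", "mu_A_G", "mu_V_B", "mu_V_G")] > 0))
    expect_true(all(co[c("mu_A_B", "mu_A_G", "mu_V_B", "mu_V_G")] < 1))
    expect_true(co[["b1"]] < co[["b2"]])
    expect_true(all(co[grepl("sigma2", names(co))] > 0))
  }
})

test_that("multi-start fitting selects the best restart and never worsens
           with more restarts", {
  design <- av_design()
  subj <- make_subject(31, "MLE")
  cfg3 <- fit_config("test", n_restarts = 3, seed = 5)
  cfg6 <- fit_config("test", n_restarts = 6, seed = 5)
  f3 <- fit_observer(subj, "MLE", design, cfg3)
  f6 <- fit_observer(subj, "MLE", design, cfg6)
  expect_equal(f3$penalized_nll, min(f3$restart_trace, na.rm = TRUE))
  expect_lte(f6$penalized_nll, f3$penalized_nll + 1e-8)
  expect_equal(f3$penalized_nll,
               f3$nll + 7 * sum(1 / coef(f3)[grepl("sigma2", names(coef(f3)))]),
               tolerance = 1e-8)

  # optimality spot-check against random probe parameters
  set.seed(77)
  probes <- draw_inits(50, "MLE")
  probe_obj <- apply(probes, 1, function(th) {
    penalized_objective(unpack_theta(th, "MLE"), subj, design, lambda_reg = 7)
  })
  expect_lte(f6$penalized_nll, min(probe_obj))
})

test_that("the Full search space contains the Reduced one", {
  design <- av_design()
  subj <- make_subject(32)
  cfg <- fit_config("test", n_restarts = 6, seed = 9)
  red <- fit_observer(subj, "ReducedJP", design, cfg)
  # seed the Full fit with the Reduced optimum (sync binding ~ 0)
  full_init <- c(red$theta[1:12], -30, red$theta[13])
  full <- fit_observer(subj, "FullJP", design, cfg, init = full_init)
  expect_lte(full$penalized_nll, red$penalized_nll + 1e-3)
})

test_that("fitted parameters recover the generating observer's auditory
           weights", {
  design <- av_design(n_reps = 500)
  truth <- default_observer("ReducedJP")
  subj <- simulate_subject(truth, design, seed = 51)
  fit <- fit_observer(subj, "ReducedJP", design,
                      fit_config("test", n_restarts = 10, seed = 12))
  w_err <- abs(extract_auditory_weights(fit, design)$w_A -
                 true_weights(truth, design))
  expect_lt(median(w_err), 0.05)
  expect_gt(coef(fit)[["sigma_o2_async"]], 0)
  # fitted variances preserve the SNR ordering of the truth
  co <- coef(fit)
  expect_true(co[["sigma2_A_high"]] < co[["sigma2_A_mid"]])
  expect_true(co[["sigma2_A_mid"]] < co[["sigma2_A_low"]])
  expect_true(co[["sigma2_V_high"]] < co[["sigma2_V_mid"]])
  expect_true(co[["sigma2_V_mid"]] < co[["sigma2_V_low"]])
})

test_that("cross-validation leaves out one condition per fold and reports
           cell RMSE", {
  design <- av_design()
  subj <- make_subject(41, "MLE")
  cv <- cross_validate(subj, "MLE", design,
                       fit_config("test", n_restarts = 3,
                                  n_restarts_fold = 1, seed = 2))
  expect_equal(nrow(cv$predictions), 42)
  expect_equal(nrow(cv$per_fold_params), 42)
  preds <- as.matrix(cv$predictions[, c("pred_B", "pred_D", "pred_G")])
  obs <- as.matrix(cv$predictions[, c("obs_B", "obs_D", "obs_G")])
  expect_equal(unname(rowSums(preds)), rep(1, 42), tolerance = 1e-8)
  expect_equal(cv$rmse, sqrt(mean((preds - obs)^2)))
  expect_gt(cv$rmse, 0)
})

test_that("the lambda sweep returns the minimizer of its own curve", {
  design <- av_design(n_reps = 5)  # tiny data invites precision overfitting
  subj <- simulate_subject(default_observer("MLE"), design, seed = 61)
  cfg <- fit_config("test", n_restarts = 2, n_restarts_fold = 1, seed = 3)
  sw1 <- sweep_lambda(list(subj), "MLE", design, grid = 7, config = cfg)
  expect_equal(sw1$lambda, 7)
  sw <- sweep_lambda(list(subj), "MLE", design, grid = 10^seq(-3, 1, 1),
                     config = cfg)
  expect_equal(sw$lambda, sw$curve$lambda[which.min(sw$curve$rmse)])
  # with 5 repetitions per condition the near-unregularized fit overfits:
  # the CV curve has an interior minimum, not at the smallest grid value
  expect_gt(sw$lambda, min(sw$curve$lambda))
  expect_lt(sw$lambda, max(sw$curve$lambda))
  expect_error(sweep_lambda(list(subj), "MLE", design, grid = numeric()),
               "non-empty")
  expect_error(sweep_lambda(list(subj), "MLE", design, grid = c(-1, 7)),
               ">= 0")
})
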