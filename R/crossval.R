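#' Leave-one-condition-out cross-validation
#'
#' One fold per design condition: the model is refitted with all trials of
#' that condition held out, and the held-out condition's response
#' probabilities are predicted from the fold's parameters. The reported error
#' is the RMSE over all (condition x category) cells between predicted
#' probabilities and observed response proportions — RMSE rather than held-out
#' log-likelihood, because a fold can predict probability exactly 0 or 1 for
#' a response that was nonetheless (not) observed, making log undefined.
#'
#' A full-data fit is run first (with `config$n_restarts` restarts); each fold
#' is then optimized from that optimum as a warm start plus
#' `config$n_restarts_fold - 1` random restarts.
#'
#' @param data An `"av_subject"` (or counts data frame).
#' @param variant Model variant.
#' @param design The `"av_design"`.
#' @param config A [fit_config()].
#' @return An `"av_cv"`: `predictions` (data frame of condition columns,
#'   observed proportions and held-out predicted probabilities), `rmse`,
#'   `per_fold_params` (matrix of unconstrained fold optima), `variant`,
#'   and the `full_fit`.
#' @export
cross_validate <- function(data, variant = "ReducedJP", design = av_design(),
                           config = fit_config()) {
  variant <- match.arg(variant, variant_names)
  counts <- align_counts(data, design)
  n_cond <- nrow(design$conditions)
  full_fit <- fit_observer(data, variant, design, config)

  preds <- matrix(NA_real_, n_cond, 3)
  fold_params <- matrix(NA_real_, n_cond, theta_length(variant))
  for (j in seq_len(n_cond)) {
    fold_config <- config
    fold_config$seed <- config$seed + j
    fit_j <- fit_observer(data, variant, design, fold_config,
                          included = setdiff(seq_len(n_cond), j),
                          init = full_fit$theta,
                          n_restarts = max(config$n_restarts_fold - 1L, 0L))
    preds[j, ] <- predict_conditions(fit_j$params, design, conditions = j)
    fold_params[j, ] <- fit_j$theta
  }
  obs <- counts / rowSums(counts)
  rmse <- sqrt(mean((preds - obs)^2))
  predictions <- cbind(design$conditions,
                       obs_B = obs[, 1], obs_D = obs[, 2], obs_G = obs[, 3],
                       pred_B = preds[, 1], pred_D = preds[, 2],
                       pred_G = preds[, 3])
  rownames(predictions) <- NULL
  colnames(fold_params) <- theta_names(variant)
  structure(list(predictions = predictions, rmse = rmse,
                 per_fold_params = fold_params, variant = variant,
                 full_fit = full_fit),
            class = "av_cv")
}

#' @export
print.av_cv <- function(x, ...) {
  cat("Leave-one-condition-out CV:", x$variant, "-",
      nrow(x$predictions), "folds, RMSE", sprintf("%.4f", x$rmse), "\n")
  invisible(x)
}

#' Cross-validated sweep of the regularization constant
#'
#' Evaluates a grid of regularization constants by mean leave-one-condition-
#' out RMSE over subjects and model variants, and selects the minimizer. The
#' reference analysis swept \eqn{[10^{-3}, 10^2]} over the MLE, Joint Prior
#' and BCI models and selected \eqn{\lambda = 7}.
#'
#' @param cohort List of `"av_subject"` objects (an `"av_cohort"` is
#'   accepted).
#' @param variants Character vector of model variants entering the mean.
#' @param design The `"av_design"`.
#' @param grid Numeric vector of candidate `lambda_reg` values, all `>= 0`.
#' @param config A [fit_config()]; its `lambda_reg` is replaced by each grid
#'   value in turn.
#' @return An `"av_lambda_sweep"`: `lambda` (the selected value), `curve`
#'   (data frame of `lambda` and mean CV `rmse`), and the per-subject/variant
#'   RMSE table.
#' @export
sweep_lambda <- function(cohort, variants = c("MLE", "ReducedJP",
                                              "ReducedBCI"),
                         design = av_design(),
                         grid = 10^seq(-3, 2, length.out = 6),
                         config = fit_config()) {
  if (inherits(cohort, "av_cohort")) cohort <- cohort$subjects
  if (length(grid) == 0) stop("grid must be non-empty", call. = FALSE)
  if (any(grid < 0)) stop("grid values must be >= 0", call. = FALSE)
  variants <- vapply(variants, match.arg, "", choices = variant_names)

  cells <- expand.grid(subject = seq_along(cohort), variant = variants,
                       lambda = grid, stringsAsFactors = FALSE)
  cells$rmse <- vapply(seq_len(nrow(cells)), function(i) {
    cfg <- config
    cfg$lambda_reg <- cells$lambda[i]
    cross_validate(cohort[[cells$subject[i]]], cells$variant[i], design,
                   cfg)$rmse
  }, numeric(1))
  curve <- stats::aggregate(rmse ~ lambda, data = cells, FUN = mean)
  best <- curve$lambda[which.min(curve$rmse)]
  structure(list(lambda = best, curve = curve, cells = cells),
            class = "av_lambda_sweep")
}

#' @export
print.av_lambda_sweep <- function(x, ...) {
  cat("Regularization sweep over", nrow(x$curve), "values: selected lambda =",
      x$lambda, "\n")
  print(x$curve)
  invisible(x)
}
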