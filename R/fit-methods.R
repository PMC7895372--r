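#' @export
print.av_fit <- function(x, ...) {
  cat("Fitted observer model:", x$variant, "(",
      n_free_params(x$variant), "free parameters )\n")
  cat(sprintf("  penalized NLL: %.3f  (NLL %.3f, lambda = %g)\n",
              x$penalized_nll, x$nll, x$config$lambda_reg))
  cat("  restarts:", sum(is.finite(x$restart_trace)), "finite of",
      length(x$restart_trace), "\n")
  invisible(x)
}

#' @export
coef.av_fit <- function(object, transformed = FALSE, ...) {
  if (transformed) return(object$theta)
  lk <- object$params$likelihood
  pr <- object$params$prior
  rm <- object$params$response_map
  out <- c(mu_A_B = lk$mu_A_B, mu_A_G = lk$mu_A_G,
           mu_V_B = lk$mu_V_B, mu_V_G = lk$mu_V_G,
           stats::setNames(as.numeric(lk$sigma2_A),
                           paste0("sigma2_A_", snr_levels)),
           stats::setNames(as.numeric(lk$sigma2_V),
                           paste0("sigma2_V_", snr_levels)),
           b1 = rm$b1, b2 = rm$b2)
  if (pr$kind == "joint_prior") {
    out <- c(out, sigma_o2_sync = pr$value_sync,
             sigma_o2_async = pr$value_async)
  } else if (pr$kind == "bci") {
    out <- c(out, p_separate_sync = pr$value_sync,
             p_separate_async = pr$value_async)
  }
  out
}

#' @export
logLik.av_fit <- function(object, ...) {
  structure(-object$nll, df = n_free_params(object$variant),
            class = "logLik")
}

#' Predicted response probabilities from a fitted model
#'
#' @param object An `"av_fit"`.
#' @param design Design to predict for; defaults to the one used in fitting.
#' @param ... Unused.
#' @return Data frame of condition columns plus predicted `p_B`, `p_D`, `p_G`.
#' @export
predict.av_fit <- function(object, design = object$design, ...) {
  p <- predict_conditions(object$params, design)
  out <- cbind(design$conditions, p_B = p[, 1], p_D = p[, 2], p_G = p[, 3])
  rownames(out) <- NULL
  out
}

#' @export
residuals.av_fit <- function(object, ...) {
  p <- predict_conditions(object$params, object$design)
  n <- rowSums(object$data)
  obs <- object$data / n
  res <- obs - p
  colnames(res) <- c("B", "D", "G")
  cbind(object$design$conditions, as.data.frame(res))
}

#' @export
simulate.av_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$config$seed
  out <- lapply(seq_len(nsim), function(i) {
    simulate_subject(object$params, object$design,
                     seed = as.integer(seed) + i - 1L,
                     subject_id = sprintf("sim%02d", i))
  })
  if (nsim == 1) out[[1]] else out
}

#' @export
summary.av_fit <- function(object, ...) {
  res <- residuals.av_fit(object)
  rmse <- sqrt(mean(as.matrix(res[, c("B", "D", "G")])^2))
  structure(list(fit = object, coef = coef.av_fit(object),
                 training_rmse = rmse), class = "summary.av_fit")
}

#' @export
print.summary.av_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  training RMSE (42 x 3 cells): %.4f\n", x$training_rmse))
  cat("  coefficients:\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' Observed vs predicted response probabilities
#'
#' Simple base-graphics summary: one panel per response category, observed
#' proportions against fitted probabilities across conditions.
#'
#' @param x An `"av_fit"`.
#' @param ... Passed to [plot()].
#' @export
plot.av_fit <- function(x, ...) {
  p <- predict_conditions(x$params, x$design)
  obs <- x$data / rowSums(x$data)
  op <- graphics::par(mfrow = c(1, 3), pty = "s")
  on.exit(graphics::par(op))
  for (k in 1:3) {
    graphics::plot(p[, k], obs[, k], xlim = 0:1, ylim = 0:1,
                   xlab = "predicted", ylab = "observed",
                   main = c("B", "D", "G")[k], ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
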