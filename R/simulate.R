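#' Default group-level observer parameters
#'
#' A plausible ground-truth observer for simulation, expressed on the `[0, 1]`
#' place-of-articulation axis. Category means put B near the front of the axis
#' and G near the back in both modalities; sensory variances increase as SNR
#' decreases, with clear video the most reliable cue and noisy video nearly
#' uninformative; response boundaries sit at 1/3 and 2/3. The binding prior is
#' complete for synchronous stimuli and markedly relaxed for the 500 ms
#' audio-lead asynchrony. With these settings the expected response patterns
#' show the classic signatures: a strong McGurk effect for synchronous
#' incongruent stimuli that weakens with asynchrony, fewer auditory (B)
#' responses at lower auditory SNR, and more at lower visual SNR.
#'
#' @param variant Model variant to instantiate. Reduced/MLE variants pin the
#'   synchronous binding value at 0.
#' @param sigma_o2_async Asynchronous binding-prior variance (Joint Prior
#'   family).
#' @param p_separate_async Asynchronous probability of separate causes (BCI
#'   family).
#' @param sigma_o2_sync,p_separate_sync Synchronous values, used only by the
#'   Full variants.
#' @return An `"av_observer"`.
#' @export
default_observer <- function(variant = "ReducedJP",
                             sigma_o2_async = 0.15,
                             p_separate_async = 0.6,
                             sigma_o2_sync = 0,
                             p_separate_sync = 0) {
  variant <- match.arg(variant, variant_names)
  kind <- variant_prior_kind(variant)
  prior <- switch(kind,
    mle = prior_params("mle", 0, 0),
    joint_prior = prior_params("joint_prior",
                               if (variant == "FullJP") sigma_o2_sync else 0,
                               sigma_o2_async),
    bci = prior_params("bci",
                       if (variant == "FullBCI") p_separate_sync else 0,
                       p_separate_async))
  observer_params(
    likelihood = likelihood_params(
      mu_A_B = 0.15, mu_A_G = 0.85, mu_V_B = 0.10, mu_V_G = 0.90,
      sigma2_A = c(high = 0.008, mid = 0.03, low = 0.09),
      sigma2_V = c(high = 0.005, mid = 0.04, low = 0.20)),
    prior = prior,
    rmap = response_map(b1 = 1/3, b2 = 2/3),
    variant = variant
  )
}

#' Simulate one subject's response counts
#'
#' Draws, for every condition in the design, a multinomial sample of size
#' `n_reps` from the observer's predicted B/D/G response probabilities.
#'
#' @param params An `"av_observer"`: the subject's true parameters.
#' @param design An `"av_design"`.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param subject_id Label stored with the data.
#' @return An `"av_subject"`: a list with `subject_id` and `counts`, a data
#'   frame of the design's condition columns plus integer columns
#'   `n_B`, `n_D`, `n_G` (each row summing to `n_reps`).
#' @export
simulate_subject <- function(params, design, seed = 1L, subject_id = "S1") {
  stopifnot(inherits(params, "av_observer"), inherits(design, "av_design"))
  probs <- predict_conditions(params, design)
  set.seed(as.integer(seed))
  counts <- t(apply(probs, 1, function(p) {
    stats::rmultinom(1, size = design$n_reps, prob = p)[, 1]
  }))
  colnames(counts) <- c("n_B", "n_D", "n_G")
  av_subject(subject_id, cbind(design$conditions, as.data.frame(counts)))
}

av_subject <- function(subject_id, counts) {
  stopifnot(all(c("modality", "pairing", "auditory_snr", "visual_snr", "soa",
                  "n_B", "n_D", "n_G") %in% names(counts)))
  if (any(counts[, c("n_B", "n_D", "n_G")] < 0)) {
    stop("response counts must be non-negative", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), counts = counts),
            class = "av_subject")
}

#' @export
print.av_subject <- function(x, ...) {
  cat("Subject", x$subject_id, "-", nrow(x$counts), "conditions,",
      sum(x$counts[, c("n_B", "n_D", "n_G")]), "trials\n")
  invisible(x)
}

#' Cohort specification for simulation
#'
#' @param n_subjects Number of simulated subjects (the behavioural study this
#'   design emulates tested 16).
#' @param group_params Population-level `"av_observer"`; per-subject
#'   parameters are Gaussian perturbations of it on the unconstrained scale
#'   (logit means and boundaries, log variances, log `sigma_o2` / logit
#'   `p_separate`), which keeps every subject's parameters valid without
#'   clipping.
#' @param between_subject_sd Standard deviation of the perturbation, either a
#'   single value applied to all free parameters or a vector of one value per
#'   free parameter of the variant.
#' @param seed Integer seed.
#' @return A `"cohort_spec"` list.
#' @export
cohort_spec <- function(n_subjects = 16L,
                        group_params = default_observer(),
                        between_subject_sd = 0.25,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, all(between_subject_sd >= 0))
  k <- theta_length(group_params$variant)
  if (!length(between_subject_sd) %in% c(1L, k)) {
    stop("between_subject_sd must have length 1 or ", k, call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 group_params = group_params,
                 between_subject_sd = between_subject_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of subjects
#'
#' Perturbs the group-level parameters independently per subject on the
#' unconstrained scale and simulates each subject's response counts. The true
#' per-subject parameters are returned alongside the data for recovery
#' studies.
#'
#' @param spec A [cohort_spec()].
#' @param design An `"av_design"`.
#' @return An `"av_cohort"`: list with `subjects` (list of `"av_subject"`),
#'   `true_params` (list of `"av_observer"`), and the `spec`.
#' @export
simulate_cohort <- function(spec, design = av_design()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(design, "av_design"))
  theta0 <- pack_observer(spec$group_params)
  variant <- spec$group_params$variant
  set.seed(spec$seed)
  thetas <- lapply(seq_len(spec$n_subjects), function(i) {
    theta0 + stats::rnorm(length(theta0), 0, spec$between_subject_sd)
  })
  subject_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_subjects)
  true_params <- lapply(thetas, unpack_theta, variant = variant)
  subjects <- lapply(seq_len(spec$n_subjects), function(i) {
    simulate_subject(true_params[[i]], design, seed = subject_seeds[i],
                     subject_id = sprintf("S%02d", i))
  })
  structure(list(subjects = subjects, true_params = true_params, spec = spec),
            class = "av_cohort")
}

#' @export
print.av_cohort <- function(x, ...) {
  cat("Simulated cohort:", length(x$subjects), "subjects, generating variant",
      x$spec$group_params$variant, "\n")
  invisible(x)
}
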