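#' Run the full analysis pipeline
#'
#' End-to-end driver: obtain a cohort (simulate one, or read a trial-count
#' CSV), cross-validate each requested model variant for each subject,
#' compare variants against the MLE baseline, and write all outputs to a run
#' directory. Every source of randomness derives from the single `seed` in
#' the config, which is echoed (with the resolved configuration) to
#' `config.json` in the run directory.
#'
#' `config` is a list (or path to a JSON file holding one) with elements:
#' \describe{
#'   \item{input}{path to a trial-count CSV, or `NULL` to simulate}
#'   \item{n_subjects, generating_variant, between_subject_sd}{simulation
#'     settings used when `input` is `NULL` (defaults 16, `"ReducedJP"`,
#'     0.25)}
#'   \item{variants}{variants to fit (default `c("MLE", "ReducedJP")`)}
#'   \item{lambda, n_restarts, n_restarts_fold, profile, seed}{fitting
#'     settings forwarded to [fit_config()]}
#' }
#'
#' Per-subject/variant failures are caught, logged, and excluded from the
#' comparison rather than aborting the run.
#'
#' @param config List or JSON path, see Details.
#' @param out_dir Run directory (created if needed).
#' @param quiet Suppress per-fit progress messages.
#' @return An `"av_run"` list: `comparison` (an `"av_comparison"` or `NULL`
#'   if fewer than two variants succeeded), `cv` (the RMSE table),
#'   `failures`, and the resolved `config`; files `cv_rmse.csv`,
#'   `comparison_tests.csv`, `weights.csv` (Joint Prior variants only),
#'   `trials.csv` (simulated cohorts) and `config.json` under `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("avrun"),
                         quiet = FALSE) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- list(input = NULL, n_subjects = 16L,
                   generating_variant = "ReducedJP",
                   between_subject_sd = 0.25,
                   variants = c("MLE", "ReducedJP"),
                   lambda = 7, profile = "test",
                   n_restarts = NULL, n_restarts_fold = NULL, seed = 1L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  config <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- av_design()
  fcfg <- fit_config(profile = config$profile,
                     n_restarts = config$n_restarts,
                     n_restarts_fold = config$n_restarts_fold,
                     lambda_reg = config$lambda, seed = config$seed)

  if (is.null(config$input)) {
    spec <- cohort_spec(n_subjects = config$n_subjects,
                        group_params = default_observer(
                          config$generating_variant),
                        between_subject_sd = config$between_subject_sd,
                        seed = config$seed)
    cohort <- simulate_cohort(spec, design)$subjects
    write_trials(cohort, file.path(out_dir, "trials.csv"), design)
  } else {
    cohort <- read_trials(config$input, design)
  }

  say <- function(...) if (!quiet) message(...)
  cells <- expand.grid(subject = seq_along(cohort),
                       variant = config$variants, stringsAsFactors = FALSE)
  results <- vector("list", nrow(cells))
  failures <- character()
  for (i in seq_len(nrow(cells))) {
    subj <- cohort[[cells$subject[i]]]
    say("cross-validating ", subj$subject_id, " / ", cells$variant[i],
        " (lambda = ", fcfg$lambda_reg, ", ", fcfg$n_restarts, " restarts)")
    results[[i]] <- tryCatch(
      cross_validate(subj, cells$variant[i], design, fcfg),
      error = function(e) {
        failures <<- c(failures, paste0(subj$subject_id, "/",
                                        cells$variant[i], ": ",
                                        conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(results, is.null, logical(1))
  cv <- data.frame(
    subject = vapply(cells$subject[ok],
                     function(j) cohort[[j]]$subject_id, ""),
    variant = cells$variant[ok],
    rmse = vapply(results[ok], `[[`, numeric(1), "rmse"),
    stringsAsFactors = FALSE)
  utils::write.csv(cv, file.path(out_dir, "cv_rmse.csv"), row.names = FALSE)

  comparison <- NULL
  complete <- names(which(table(cv$variant) == length(cohort)))
  if (length(complete) >= 2) {
    comparison <- compare_models(cv[cv$variant %in% complete, ])
    utils::write.csv(comparison$tests,
                     file.path(out_dir, "comparison_tests.csv"),
                     row.names = FALSE)
  }

  jp <- intersect(config$variants, c("ReducedJP", "FullJP"))
  if (length(jp)) {
    wtab <- do.call(rbind, lapply(which(ok & cells$variant == jp[1]),
      function(i) {
        w <- extract_auditory_weights(results[[i]]$full_fit, design)
        cbind(subject = cohort[[cells$subject[i]]]$subject_id, w)
      }))
    if (!is.null(wtab)) {
      utils::write.csv(wtab, file.path(out_dir, "weights.csv"),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (length(failures)) warning(length(failures), " fit(s) failed: ",
                                paste(failures, collapse = "; "),
                                call. = FALSE)
  structure(list(comparison = comparison, cv = cv, failures = failures,
                 config = config, out_dir = out_dir),
            class = "av_run")
}

#' @export
print.av_run <- function(x, ...) {
  cat("Pipeline run (", nrow(x$cv), " subject/variant fits; outputs in ",
      x$out_dir, ")\n", sep = "")
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
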