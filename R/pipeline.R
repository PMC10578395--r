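#' Run the full screening analysis pipeline
#'
#' Orchestrates score -> exclude -> fit full model -> classify -> fit
#' parsimonious model -> screen -> predict. Input is either a participant
#' table (data frame or CSV path) or a printed coefficient table (via
#' `fits`), in which case the fitting stages are skipped and the decision
#' engine runs directly on the supplied estimates.
#'
#' @param cohort Participant table or path to its CSV; ignored when `fits`
#'   is supplied.
#' @param design A `factorial_design`.
#' @param fits Optional list with elements `full` and `parsimonious`
#'   (`screening_fit` objects, e.g. from [aet_screening_fit()]) for
#'   coefficient-table input mode.
#' @param exclusion_rules Passed to [apply_exclusions()] (default
#'   `"under_18"`; use `character(0)` for none).
#' @param threshold Importance threshold (default 0.1).
#' @param level Confidence level (default 0.90).
#' @param mode Prediction/resolution scale: `"standardized"` (published-table
#'   compatible) or `"unstandardized"`.
#' @param output_dir Optional directory; when given, writes
#'   `coefficients.csv`, `predictions.csv`, `decision_log.json`,
#'   `exclusion_log.json` and `run_log.json` (seed and config fingerprint).
#' @param seed Seed recorded in the run log (generation happens upstream).
#' @return List with `scored`, `exclusion_log`, `full_fit`,
#'   `parsimonious_fit`, `important`, `screening`, `predictions` (a
#'   `prediction_table` over the screened-in components with screened-out
#'   components fixed low), and `optimized_condition_id`.
#' @export
run_pipeline <- function(cohort = NULL, design, fits = NULL,
                         exclusion_rules = "under_18", threshold = 0.1,
                         level = 0.90,
                         mode = c("standardized", "unstandardized"),
                         output_dir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  scored <- NULL
  exclusion_log <- NULL
  if (is.null(fits)) {
    if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
    scored <- score_cohort(cohort)
    excl <- apply_exclusions(scored, exclusion_rules)
    scored <- excl$cohort
    exclusion_log <- excl$log
    full_fit <- fit_full_model(scored, design, level = level)
    important <- classify_effects(full_fit, threshold)
    pars_fit <- fit_parsimonious(scored, important$term, design,
                                 level = level)
  } else {
    stopifnot(all(c("full", "parsimonious") %in% names(fits)))
    full_fit <- fits$full
    pars_fit <- fits$parsimonious
    important <- classify_effects(full_fit, threshold)
  }
  screening <- run_screening(full_fit, pars_fit, threshold, mode = mode)
  fixed <- screening$decisions[screening$screened_out]
  pred_mode <- if (mode == "standardized") "table_compatible" else
    "unstandardized"
  predictions <- build_prediction_table(pars_fit, design, fixed = fixed,
                                        mode = pred_mode)
  out <- list(scored = scored, exclusion_log = exclusion_log,
              full_fit = full_fit, parsimonious_fit = pars_fit,
              important = important, screening = screening,
              predictions = predictions,
              optimized_condition_id = attr(predictions, "argmax_id"))
  if (!is.null(output_dir)) {
    write_pipeline_artifacts(out, output_dir, threshold = threshold,
                             mode = mode, seed = seed)
  }
  out
}

#' Monte-Carlo power of a main-effect test in the factorial regression
#'
#' Simulates replicates of an effect-coded 2^k experiment in which a single
#' component carries a standardized mean difference `d` between its levels
#' (coefficient d/2 on the ±1 code) and the noise is unit-variance Gaussian,
#' fits the full factorial model each time, and records the fraction of
#' replicates with the target term's two-sided p below `alpha`. With `d = 0`
#' the same routine estimates the per-term type-I error rate.
#'
#' @param design A `factorial_design`.
#' @param d Standardized difference between the two levels of the target
#'   component (0 for a null simulation).
#' @param n Participants per replicate.
#' @param alpha Two-sided significance level.
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @param target Factor name carrying the effect (default: first factor).
#' @param allocation `"balanced"` (near-equal per-condition counts, the
#'   design assumption of the power formula) or `"simple"` randomization.
#' @return A `simulation_summary` list: `estimate` (power or type-I rate for
#'   the target term), `mc_se`, `per_term_rates` (rejection rate of every
#'   factorial term), `reps`, `n`, `d`, `alpha`.
#' @export
simulate_power <- function(design, d, n, alpha = 0.1, reps = 1000,
                           seed = 1L, target = NULL,
                           allocation = c("balanced", "simple")) {
  allocation <- match.arg(allocation)
  stopifnot(reps >= 1, n > 2^design$k)
  target <- target %||% design$factors$name[1]
  stopifnot(target %in% design$factors$name)
  terms <- all_terms(design)
  n_cond <- nrow(design$conditions)

  assign_balanced <- function() {
    base <- rep(seq_len(n_cond), n %/% n_cond)
    extra <- seq_len(n %% n_cond)
    c(base, extra)
  }

  with_seed(seed, {
    if (allocation == "balanced") {
      cond <- assign_balanced()
      codes <- design_codes(design)[cond, , drop = FALSE]
      X <- cbind(`(Intercept)` = 1, build_model_matrix(codes, terms))
      qx <- qr(X)  # fixed design: one decomposition reused across reps
    }
    rej <- matrix(FALSE, reps, length(terms),
                  dimnames = list(NULL, terms))
    for (r in seq_len(reps)) {
      if (allocation == "simple") {
        cond <- sample.int(n_cond, n, replace = TRUE)
        codes <- design_codes(design)[cond, , drop = FALSE]
        X <- cbind(`(Intercept)` = 1, build_model_matrix(codes, terms))
        qx <- qr(X)
      }
      y <- (d / 2) * X[, target] + stats::rnorm(n)
      fit <- fit_ols(y, X, qr_x = qx)
      se <- sqrt(diag(fit$cov))[terms]
      tstat <- fit$coefficients[terms] / se
      p <- 2 * stats::pt(-abs(tstat), fit$df)
      rej[r, ] <- p < alpha
    }
    rates <- colMeans(rej)
    est <- unname(rates[target])
    structure(list(scenario = if (d == 0) "type_I" else "power",
                   estimate = est,
                   mc_se = sqrt(est * (1 - est) / reps),
                   per_term_rates = rates,
                   reps = reps, n = n, d = d, alpha = alpha,
                   target = target, allocation = allocation),
              class = "simulation_summary")
  })
}

#' Monte-Carlo accuracy of the screening decision engine
#'
#' Repeatedly generates synthetic cohorts under a known truth model, runs
#' the full pipeline, and scores whether the selected optimized condition
#' attains the truth-optimal expected outcome. Because components with truly
#' null effects make both of their levels optimal, accuracy is defined as
#' membership of the selected condition in the argmax set of the true linear
#' predictor over all conditions.
#'
#' @param design A `factorial_design`.
#' @param truth A [truth_model()] designating the data-generating effects.
#' @param n Participants per replicate.
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @param threshold Importance threshold passed to the pipeline.
#' @param config Optional [cohort_config()] template; `n` and per-replicate
#'   seeds are overridden.
#' @return A `simulation_summary` list: `estimate` (accuracy), `mc_se`,
#'   `optimal_ids` (truth-optimal condition ids), `selected_ids` (per
#'   replicate), `modal_configuration` (most frequent screened-in set).
#' @export
simulate_screening_accuracy <- function(design, truth, n, reps = 50,
                                        seed = 1L, threshold = 0.1,
                                        config = NULL) {
  stopifnot(reps >= 1)
  codes <- design_codes(design)
  lp <- rep(truth$intercept, nrow(codes))
  if (length(truth$term_effects)) {
    lp <- lp + as.vector(build_model_matrix(codes, names(truth$term_effects))
                         %*% truth$term_effects)
  }
  optimal_ids <- design$conditions$condition_id[lp >= max(lp) - 1e-12]

  template <- config %||% cohort_config(n = n, seed = 1L)
  selected <- integer(reps)
  configs <- character(reps)
  for (r in seq_len(reps)) {
    cfg <- template
    cfg$n <- as.integer(n)
    cfg$seed <- child_seed(seed, r)
    cohort <- generate_cohort(design, truth, cfg)
    res <- run_pipeline(cohort, design, exclusion_rules = character(0),
                        threshold = threshold, mode = "unstandardized")
    selected[r] <- res$optimized_condition_id
    configs[r] <- paste(sort(res$screening$screened_in), collapse = "+")
  }
  acc <- mean(selected %in% optimal_ids)
  modal <- names(which.max(table(configs)))
  structure(list(scenario = "screening_accuracy", estimate = acc,
                 mc_se = sqrt(acc * (1 - acc) / reps),
                 optimal_ids = optimal_ids, selected_ids = selected,
                 modal_configuration = if (identical(modal, "")) "(none)"
                 else modal,
                 reps = reps, n = n, threshold = threshold),
            class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat(sprintf("%s: estimate %.4f (MC SE %.4f) over %d replicates\n",
              x$scenario, x$estimate, x$mc_se, x$reps))
  invisible(x)
}
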