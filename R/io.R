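# CSV / JSON / YAML interfaces for designs, cohorts and run artifacts.

#' Export and import a factorial design as CSV
#'
#' The CSV carries `condition_id`, one level-label column per factor and one
#' `<name>_code` column per factor.
#'
#' @param design A `factorial_design`.
#' @param path File path.
#' @return `write_design_csv` returns `path` invisibly; `read_design_csv`
#'   returns the condition table as a data frame.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(design$conditions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Read / write a participant table
#'
#' @param cohort Participant table.
#' @param path File path.
#' @return `read_cohort_csv` returns the table; required columns are
#'   checked and diagnosed by name.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("participant_id", "age", "condition_id",
            paste0("pre_item_", 1:10), paste0("post_item_", 1:10),
            "completion_minutes")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("cohort CSV lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized fields mirror the arguments of [run_pipeline()],
#' [cohort_config()] and [required_sample_size()]; unknown fields are kept
#' as-is for the caller.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Write the artifact bundle of a pipeline run
#'
#' Writes the coefficient table (full and parsimonious stacked, unselected
#' parsimonious terms reported as zero), the prediction table, the decision
#' log, the exclusion log, and a run log holding the seed and a
#' configuration fingerprint.
#'
#' @param result List returned by [run_pipeline()].
#' @param output_dir Directory (created if needed).
#' @param threshold,mode,seed Run settings recorded in the run log.
#' @return `output_dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(result, output_dir, threshold = 0.1,
                                     mode = "standardized", seed = NULL) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  coef_tab <- rbind(effect_table(result$full_fit),
                    effect_table(result$parsimonious_fit,
                                 zero_unselected = TRUE))
  utils::write.csv(coef_tab, file.path(output_dir, "coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$predictions),
                   file.path(output_dir, "predictions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(screened_in = result$screening$screened_in,
         screened_out = result$screening$screened_out,
         threshold = result$screening$threshold,
         optimized_condition_id = result$optimized_condition_id,
         log = result$screening$decision_log),
    file.path(output_dir, "decision_log.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(result$exclusion_log)) {
    lg <- result$exclusion_log
    jsonlite::write_json(
      list(rules = lg$rules, n_before = lg$n_before, n_after = lg$n_after,
           n_removed = lg$n_removed, counts = lg$counts),
      file.path(output_dir, "exclusion_log.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }
  settings <- list(threshold = threshold, mode = mode, seed = seed,
                   n = if (!is.null(result$scored)) nrow(result$scored))
  jsonlite::write_json(
    list(settings = settings,
         config_fingerprint = config_fingerprint(settings),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(output_dir, "run_log.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(output_dir)
}
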