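#' Classify factorial effects as important
#'
#' An effect (main or interaction) is important when its two-sided p-value
#' is strictly below the importance threshold. The threshold is set a priori
#' under a decision-priority perspective (incorrectly screening a component
#' in and incorrectly screening it out are equally costly), conventionally
#' 0.1 rather than 0.05. Covariates are never classified.
#'
#' @param fit A `screening_fit` (full model, or a printed table wrapped via
#'   [as_screening_fit()]).
#' @param threshold Importance threshold on p (strict; default 0.1).
#' @return Data frame of important factorial terms with `term`, `order`,
#'   `b_weight`, `beta`, `p`, and `direction` (`"synergistic"` for positive
#'   interaction coefficients, `"antagonistic"` for negative; main effects
#'   `"positive"` / `"negative"`).
#' @export
classify_effects <- function(fit, threshold = 0.1) {
  stopifnot(threshold > 0, threshold < 1)
  est <- fit$estimates
  fac <- est[est$type == "factorial" & !is.na(est$p) & est$p < threshold,
             c("term", "order", "b_weight", "beta", "p"), drop = FALSE]
  fac$direction <- ifelse(fac$order == 1L,
                          ifelse(fac$beta >= 0, "positive", "negative"),
                          ifelse(fac$beta >= 0, "synergistic", "antagonistic"))
  fac <- fac[order(fac$order, match(fac$term, est$term)), , drop = FALSE]
  rownames(fac) <- NULL
  fac
}

#' Order important interactions for stepped decision-making
#'
#' Effect-hierarchy processing order: first the interactions containing any
#' component that has an important main effect, in ascending interaction
#' order; then the remaining interactions, again ascending by order. Ties
#' are broken by canonical (design) component order.
#'
#' @param important Data frame from [classify_effects()].
#' @param design A `factorial_design` (for canonical order tie-breaks).
#' @return Character vector of interaction terms in processing order.
#' @export
order_interactions <- function(important, design) {
  inter <- important[important$order >= 2L, , drop = FALSE]
  if (!nrow(inter)) return(character(0))
  main_comps <- important$term[important$order == 1L]
  has_main <- vapply(inter$term, function(tm) {
    any(term_components(tm) %in% main_comps)
  }, logical(1))
  # canonical rank: position of the term in the full enumeration
  canon <- match(inter$term, all_terms(design))
  ord <- order(!has_main, inter$order, canon)
  inter$term[ord]
}

# Enumerate candidate ±1 assignments for `comps` (canonical order), high
# levels first with the last component varying fastest, i.e. condition-id
# order restricted to those components.
candidate_grid <- function(comps) {
  m <- length(comps)
  g <- matrix(0, 2^m, m, dimnames = list(NULL, comps))
  for (j in seq_len(m)) {
    bit <- bitwAnd(bitwShiftR(seq_len(2^m) - 1L, m - j), 1L)
    g[, j] <- ifelse(bit == 1L, -1, 1)
  }
  g
}

# Linear predictor over a restricted set of factorial terms.
predict_terms <- function(intercept, coefs, terms, codes) {
  y <- intercept
  for (i in seq_along(terms)) {
    y <- y + coefs[i] * prod(codes[term_components(terms[i])])
  }
  y
}

#' Resolve one important interaction into component-level decisions
#'
#' For the components of the interaction not yet resolved, chooses the level
#' combination maximizing the parsimonious-model predicted outcome,
#' restricted — per the effect-hierarchy principle — to important terms
#' whose components all lie within the already-resolved set plus the
#' interaction's own components. Already-resolved components are held fixed
#' and are never flipped; if the interaction would favor flipping one, the
#' conflict is recorded in the log entry. Ties go to the candidate earliest
#' in condition-id order (high levels first).
#'
#' @param term Canonical interaction term string.
#' @param decisions Named numeric vector of ±1 levels fixed so far.
#' @param parsimonious A `screening_fit` holding the parsimonious
#'   coefficients.
#' @param mode `"standardized"` to compare predictions on the beta scale
#'   (as when driven by a printed table), `"unstandardized"` for b-weights.
#' @return List with `decisions` (updated) and `log` (one decision-log
#'   entry).
#' @export
resolve_interaction <- function(term, decisions, parsimonious,
                                mode = c("standardized", "unstandardized")) {
  mode <- match.arg(mode)
  comps <- term_components(term)
  est <- parsimonious$estimates
  fac <- est[est$type == "factorial", , drop = FALSE]
  coef_col <- if (mode == "standardized") "beta" else "b_weight"
  unresolved <- setdiff(comps, names(decisions))

  if (!length(unresolved)) {
    return(list(decisions = decisions, log = list(
      step = "interaction", effect = term, confirmatory = TRUE,
      resolved = character(0),
      note = "all components already resolved; decision unchanged")))
  }

  scope <- union(names(decisions), comps)
  in_scope <- vapply(fac$term, function(tm) {
    all(term_components(tm) %in% scope)
  }, logical(1))
  use_terms <- fac$term[in_scope]
  use_coefs <- fac[[coef_col]][in_scope]

  grid <- candidate_grid(unresolved)
  preds <- vapply(seq_len(nrow(grid)), function(i) {
    codes <- c(decisions, stats::setNames(grid[i, ], colnames(grid)))
    predict_terms(parsimonious$intercept, use_coefs, use_terms, codes)
  }, numeric(1))
  best <- which.max(preds)  # first maximum: high levels win ties
  chosen <- stats::setNames(grid[best, ], colnames(grid))

  decisions <- c(decisions, chosen)
  list(decisions = decisions, log = list(
    step = "interaction", effect = term, confirmatory = FALSE,
    resolved = unresolved,
    chosen_levels = as.list(chosen),
    held_fixed = as.list(decisions[setdiff(names(decisions),
                                           names(chosen))]),
    terms_compared = use_terms,
    candidate_predictions = stats::setNames(
      as.list(round(preds, 6)),
      apply(grid, 1, function(r) paste(sprintf("%s=%+d", colnames(grid), r),
                                       collapse = ","))
    )))
}

#' Predict the outcome for one candidate condition
#'
#' Evaluates the parsimonious prediction model at a signed code vector. In
#' `"table_compatible"` mode the linear predictor uses the raw intercept
#' with the standardized coefficients and no covariates, the convention
#' used for published condition-level predictions in this literature; in
#' `"unstandardized"` mode it uses the b-weights, optionally adding a
#' covariate offset in outcome units.
#'
#' @param parsimonious A `screening_fit`.
#' @param codes Named ±1 vector covering every component appearing in the
#'   parsimonious terms.
#' @param mode `"table_compatible"` or `"unstandardized"`.
#' @param covariate_offset Optional constant added to the prediction
#'   (outcome units).
#' @return Predicted outcome (scalar).
#' @export
predict_condition <- function(parsimonious, codes,
                              mode = c("table_compatible", "unstandardized"),
                              covariate_offset = NULL) {
  mode <- match.arg(mode)
  est <- parsimonious$estimates
  fac <- est[est$type == "factorial", , drop = FALSE]
  needed <- unique(unlist(lapply(fac$term, term_components)))
  missing <- setdiff(needed, names(codes))
  if (length(missing)) {
    stop("codes missing for component(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  coefs <- if (mode == "table_compatible") fac$beta else fac$b_weight
  y <- predict_terms(parsimonious$intercept, coefs, fac$term, codes)
  y + (covariate_offset %||% 0)
}

#' Predicted outcomes for every candidate condition
#'
#' Enumerates the 2^m level combinations of the free components (screened-in
#' or undecided), holding the screened-out components fixed at their
#' assigned levels, and predicts the outcome for each. Condition ids are
#' mapped back to the full-design numbering. The argmax is reported with a
#' deterministic tie-break (first in condition-id order).
#'
#' @param parsimonious A `screening_fit`.
#' @param design A `factorial_design`.
#' @param fixed Named ±1 vector of levels for the fixed (screened-out)
#'   components; may be empty to enumerate the full design.
#' @param free Character vector of the remaining component names; defaults
#'   to all factors not in `fixed`.
#' @param mode,covariate_offset Passed to [predict_condition()].
#' @return A `prediction_table` data frame: `condition_id`, one level-label
#'   column per factor, `y_hat`; attribute `argmax_id` holds the selected
#'   condition id.
#' @export
build_prediction_table <- function(parsimonious, design, fixed = numeric(0),
                                   free = NULL,
                                   mode = c("table_compatible",
                                            "unstandardized"),
                                   covariate_offset = NULL) {
  mode <- match.arg(mode)
  nm <- design$factors$name
  free <- free %||% setdiff(nm, names(fixed))
  stopifnot(setequal(c(free, names(fixed)), nm),
            !anyDuplicated(c(free, names(fixed))))
  free <- nm[nm %in% free]  # canonical order
  grid <- candidate_grid(free)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cand <- stats::setNames(grid[i, ], colnames(grid))
    codes <- c(cand, fixed)[nm]
    names(codes) <- nm
    id <- condition_id_from_codes(design, codes)
    y <- predict_condition(parsimonious, codes, mode, covariate_offset)
    c(list(condition_id = id),
      stats::setNames(as.list(ifelse(codes == 1, design$factors$high_label,
                                     design$factors$low_label)), nm),
      list(y_hat = y))
  })
  tab <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  tab <- tab[order(tab$condition_id), , drop = FALSE]
  rownames(tab) <- NULL
  argmax <- tab$condition_id[which.max(tab$y_hat)]
  structure(tab, argmax_id = argmax, mode = mode,
            class = c("prediction_table", "data.frame"))
}

#' Stepped component-screening decision algorithm
#'
#' Formalizes the stepped, effect-hierarchy decision process of a factorial
#' screening analysis as three stages: (1) components with an important
#' positive main effect are screened in, with an important negative main
#' effect screened out; (2) important interactions are processed in
#' [order_interactions()] order, each resolved by
#' [resolve_interaction()] — earlier decisions are never flipped; (3) any
#' component untouched by an important effect is screened out (set to its
#' low level), reflecting the resource-management principle. The whole
#' procedure is deterministic.
#'
#' @param full_fit `screening_fit` whose p-values classify importance
#'   (typically the full model).
#' @param parsimonious_fit `screening_fit` whose coefficients drive
#'   interaction resolution and prediction.
#' @param threshold Importance threshold (default 0.1, strict).
#' @param mode Coefficient scale for interaction resolution (see
#'   [resolve_interaction()]).
#' @param default_level Level assigned to untouched components: `"low"`
#'   (default) or `"high"`.
#' @return A `screening_result`: `screened_in`, `screened_out` (component
#'   name vectors), `decisions` (named ±1 vector), `important` (the
#'   classification table), and `decision_log` (ordered list with one entry
#'   for the main-effect stage, one per processed interaction, and one for
#'   the defaulting stage).
#' @export
run_screening <- function(full_fit, parsimonious_fit = full_fit,
                          threshold = 0.1,
                          mode = c("standardized", "unstandardized"),
                          default_level = c("low", "high")) {
  mode <- match.arg(mode)
  default_level <- match.arg(default_level)
  design <- full_fit$design
  nm <- design$factors$name
  important <- classify_effects(full_fit, threshold)

  decisions <- numeric(0)
  log <- list()

  mains <- important[important$order == 1L, , drop = FALSE]
  if (nrow(mains)) {
    lv <- ifelse(mains$beta >= 0, 1, -1)
    decisions <- stats::setNames(lv, mains$term)
  }
  log[[length(log) + 1L]] <- list(
    step = "main_effects",
    screened_in = mains$term[mains$beta >= 0],
    screened_out = mains$term[mains$beta < 0])

  for (tm in order_interactions(important, design)) {
    res <- resolve_interaction(tm, decisions, parsimonious_fit, mode)
    decisions <- res$decisions
    log[[length(log) + 1L]] <- res$log
  }

  untouched <- setdiff(nm, names(decisions))
  if (length(untouched)) {
    decisions <- c(decisions,
                   stats::setNames(rep(if (default_level == "low") -1 else 1,
                                       length(untouched)), untouched))
  }
  log[[length(log) + 1L]] <- list(step = "default",
                                  components = untouched,
                                  level = default_level)
  decisions <- decisions[nm]
  names(decisions) <- nm
  structure(list(
    screened_in = nm[decisions == 1],
    screened_out = nm[decisions == -1],
    decisions = decisions,
    important = important,
    threshold = threshold,
    decision_log = log
  ), class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Component screening result\n")
  cat("  screened in : ", paste(x$screened_in, collapse = ", "), "\n")
  cat("  screened out: ", paste(x$screened_out, collapse = ", "), "\n")
  cat(sprintf("  %d important effect(s) at p < %g\n",
              nrow(x$important), x$threshold))
  invisible(x)
}
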