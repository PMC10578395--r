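#' Ordinary least squares with explicit coefficient covariance
#'
#' QR-based least squares. Exposed separately so that design-level tools
#' (power simulation, oracle tests) can reuse one decomposition of a fixed
#' design matrix across many outcome vectors.
#'
#' @param y Outcome vector.
#' @param X Model matrix including the intercept column; must have more rows
#'   than columns and full column rank.
#' @param qr_x Optional precomputed `qr(X)` to reuse across calls with the
#'   same `X`.
#' @return List with `coefficients`, `sigma2` (residual variance), `cov`
#'   (coefficient covariance), `df` (residual degrees of freedom),
#'   `fitted`, `residuals`.
#' @export
fit_ols <- function(y, X, qr_x = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n > p)
  qx <- qr_x %||% qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[setdiff(seq_len(p), qx$pivot[seq_len(qx$rank)])]
    stop("model matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qx, y)
  fitted <- as.vector(X %*% coef)
  res <- y - fitted
  df <- n - p
  sigma2 <- sum(res^2) / df
  # (X'X)^{-1} from the R factor, undoing the pivot
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  piv <- qx$pivot
  xtx_inv[piv, piv] <- xtx_inv
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  list(coefficients = coef, sigma2 = sigma2, cov = sigma2 * xtx_inv,
       df = df, fitted = fitted, residuals = res)
}

#' Standardize a regression coefficient
#'
#' beta = b * sd(predictor) / sd(outcome). For balanced ±1 effect-code
#' columns the predictor SD is approximately 1, so the standardized and raw
#' coefficients differ essentially by the outcome SD.
#'
#' @param b_weight Unstandardized coefficient (outcome units per unit code).
#' @param predictor_sd Sample SD of the predictor column.
#' @param outcome_sd Sample SD of the outcome (> 0).
#' @return Standardized coefficient.
#' @examples
#' standardize_coef(0.362, 1, 5.72)  # 0.063
#' @export
standardize_coef <- function(b_weight, predictor_sd, outcome_sd) {
  if (any(outcome_sd <= 0)) stop("outcome SD must be positive", call. = FALSE)
  b_weight * predictor_sd / outcome_sd
}

#' t statistics, p-values and confidence intervals for a fitted model
#'
#' Two-sided p-values from the t distribution at the residual degrees of
#' freedom; confidence intervals computed on the standardized (beta) scale,
#' `beta +/- t_{(1+level)/2, df} * se_beta`.
#'
#' @param b Coefficient vector.
#' @param se Standard errors of `b`.
#' @param df Residual degrees of freedom (>= 1).
#' @param predictor_sds,outcome_sd SDs used for standardization.
#' @param level Confidence level (default 0.90).
#' @return Data frame with `b_weight`, `se_b`, `beta`, `se_beta`, `ci_low`,
#'   `ci_high`, `t`, `p`.
#' @export
coefficient_inference <- function(b, se, df, predictor_sds, outcome_sd,
                                  level = 0.90) {
  if (df < 1) stop("no residual degrees of freedom; inference unavailable",
                   call. = FALSE)
  beta <- standardize_coef(b, predictor_sds, outcome_sd)
  se_beta <- standardize_coef(se, predictor_sds, outcome_sd)
  tcrit <- stats::qt((1 + level) / 2, df)
  tstat <- b / se
  data.frame(b_weight = b, se_b = se, beta = beta, se_beta = se_beta,
             ci_low = beta - tcrit * se_beta, ci_high = beta + tcrit * se_beta,
             t = tstat, p = 2 * stats::pt(-abs(tstat), df))
}

# Shared fitting core for full and parsimonious models.
fit_factorial <- function(scored, design, terms,
                          covariates = c("pre_differential", "age"),
                          level = 0.90, model_label = "full") {
  need <- c("condition_id", "post_differential", covariates)
  missing <- setdiff(need, names(scored))
  if (length(missing)) {
    stop("scored table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  y <- scored$post_differential
  codes <- design_codes(design)[scored$condition_id, , drop = FALSE]
  Xf <- if (length(terms)) build_model_matrix(codes, terms) else
    matrix(numeric(0), nrow(scored), 0)
  # covariates centered at their sample means so the intercept is the
  # covariate-adjusted grand mean of the outcome
  Xc <- vapply(covariates, function(v) scored[[v]] - mean(scored[[v]]),
               numeric(nrow(scored)))
  if (length(covariates)) colnames(Xc) <- covariates
  X <- cbind(`(Intercept)` = 1, Xf, Xc)
  ols <- fit_ols(y, X)
  se <- sqrt(diag(ols$cov))
  outcome_sd <- stats::sd(y)
  idx <- setdiff(colnames(X), "(Intercept)")
  predictor_sds <- vapply(idx, function(cn) stats::sd(X[, cn]), numeric(1))
  inf <- coefficient_inference(ols$coefficients[idx], se[idx], ols$df,
                               predictor_sds, outcome_sd, level)
  est <- cbind(
    data.frame(term = idx,
               type = ifelse(idx %in% covariates, "covariate", "factorial"),
               order = ifelse(idx %in% covariates, NA_integer_,
                              term_order(idx)),
               stringsAsFactors = FALSE),
    inf
  )
  rownames(est) <- NULL
  structure(list(
    model = model_label,
    estimates = est,
    intercept = unname(ols$coefficients["(Intercept)"]),
    intercept_se = unname(se["(Intercept)"]),
    intercept_t = unname(ols$coefficients["(Intercept)"] / se["(Intercept)"]),
    residual_df = ols$df,
    sigma = sqrt(ols$sigma2),
    outcome_sd = outcome_sd,
    n = nrow(scored),
    terms = terms,
    covariates = covariates,
    level = level,
    design = design
  ), class = "screening_fit")
}

#' Fit the full effect-coded factorial model
#'
#' Multiple linear regression of the post-intervention differential on all
#' 2^k - 1 factorial terms (every main effect and every interaction, coded
#' -1/+1) plus covariates. Coefficients follow the half-difference
#' convention: with effect coding each factorial coefficient is half the
#' difference between the two level means.
#'
#' @param scored Scored cohort (see [score_cohort()]); needs
#'   `condition_id`, `post_differential` and the covariate columns.
#' @param design A `factorial_design`.
#' @param covariates Covariate column names (default baseline differential
#'   and age), entered as deviations from their sample means.
#' @param level Confidence level for intervals (default 0.90).
#' @return A `screening_fit`: coefficient table with b-weights, standardized
#'   betas, CIs, t and p, plus fit metadata.
#' @export
fit_full_model <- function(scored, design,
                           covariates = c("pre_differential", "age"),
                           level = 0.90) {
  fit_factorial(scored, design, all_terms(design), covariates, level, "full")
}

#' Fit the parsimonious prediction model
#'
#' Refits the factorial regression with only the selected (important) terms
#' plus covariates. Terms not selected are reported with coefficients of
#' exactly zero in [effect_table()] exports.
#'
#' @param scored Scored cohort.
#' @param selected_terms Character vector of canonical term strings (subset
#'   of `all_terms(design)`); may be empty for a covariates-only fit.
#' @param design A `factorial_design`.
#' @inheritParams fit_full_model
#' @return A `screening_fit` with `model = "parsimonious"`.
#' @export
fit_parsimonious <- function(scored, selected_terms, design,
                             covariates = c("pre_differential", "age"),
                             level = 0.90) {
  selected_terms <- vapply(selected_terms, term_spec, character(1),
                           design = design, USE.NAMES = FALSE)
  extra <- setdiff(selected_terms, all_terms(design))
  if (length(extra)) {
    stop("selected term(s) not in the design: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  fit_factorial(scored, design, selected_terms, covariates, level,
                "parsimonious")
}

#' @export
print.screening_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Effect-coded factorial regression (%s model), n = %d\n",
              x$model, x$n))
  cat(sprintf("Intercept %.3f; residual SD %.3f; outcome SD %.3f\n",
              x$intercept, x$sigma, x$outcome_sd))
  shown <- x$estimates[c("term", "b_weight", "beta", "ci_low", "ci_high",
                         "t", "p")]
  print(format(shown, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Coefficient table of one or two fitted models
#'
#' Flat table mirroring the reporting layout of a screening analysis: one
#' row per term with b-weight, standardized beta, CI bounds, t and p, and a
#' `model` column. For a parsimonious fit, unselected factorial terms are
#' included with coefficients of exactly zero when `zero_unselected = TRUE`.
#'
#' @param fit A `screening_fit`.
#' @param zero_unselected Include zero rows for unselected factorial terms.
#' @return Data frame.
#' @export
effect_table <- function(fit, zero_unselected = FALSE) {
  est <- fit$estimates
  t_int <- fit$intercept_t %||% NA_real_
  p_int <- if (is.finite(t_int) && isTRUE(fit$residual_df >= 1)) {
    2 * stats::pt(-abs(t_int), fit$residual_df)
  } else NA_real_
  if (!"ci_low" %in% names(est)) est$ci_low <- NA_real_
  if (!"ci_high" %in% names(est)) est$ci_high <- NA_real_
  if (!"t" %in% names(est)) est$t <- NA_real_
  out <- data.frame(term = c("(Intercept)", est$term),
                    type = c("intercept", est$type),
                    b_weight = c(fit$intercept, est$b_weight),
                    beta = c(NA, est$beta),
                    ci_low = c(NA, est$ci_low),
                    ci_high = c(NA, est$ci_high),
                    t = c(t_int, est$t),
                    p = c(p_int, est$p),
                    model = fit$model,
                    stringsAsFactors = FALSE)
  if (zero_unselected) {
    absent <- setdiff(all_terms(fit$design), fit$terms)
    if (length(absent)) {
      zero <- data.frame(term = absent, type = "factorial", b_weight = 0,
                         beta = 0, ci_low = NA, ci_high = NA, t = NA, p = NA,
                         model = fit$model, stringsAsFactors = FALSE)
      out <- rbind(out, zero)
    }
  }
  out
}

#' Build a fit-like object from a printed coefficient table
#'
#' Coefficient-table input mode: when the raw participant data are not
#' available but a published effect table is, the screening decision engine
#' can be driven directly from the table. The object carries the same
#' `estimates` and `intercept` slots the engine reads from a
#' `screening_fit`.
#'
#' @param estimates Data frame with at least `term`, `b_weight`, `beta`,
#'   `p` columns for the factorial terms (covariate rows are identified by
#'   `type == "covariate"` or by `term` matching `covariates`).
#' @param intercept Model intercept (outcome units).
#' @param design A `factorial_design` whose factor names the terms use.
#' @param model Label, e.g. `"full"` or `"parsimonious"`.
#' @param covariates Covariate term names present in `estimates`.
#' @return A `screening_fit` (without residual information).
#' @export
as_screening_fit <- function(estimates, intercept, design,
                             model = "full",
                             covariates = c("pre_differential", "age")) {
  stopifnot(all(c("term", "b_weight", "beta", "p") %in% names(estimates)))
  est <- estimates[estimates$term != "(Intercept)", , drop = FALSE]
  if (!"type" %in% names(est)) {
    est$type <- ifelse(est$term %in% covariates, "covariate", "factorial")
  }
  fac <- est$type == "factorial"
  est$term[fac] <- vapply(est$term[fac], term_spec, character(1),
                          design = design, USE.NAMES = FALSE)
  est$order <- ifelse(fac, term_order(est$term), NA_integer_)
  rownames(est) <- NULL
  structure(list(model = model, estimates = est, intercept = intercept,
                 residual_df = NA_integer_, n = NA_integer_,
                 terms = est$term[fac], covariates = covariates,
                 design = design),
            class = "screening_fit")
}
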