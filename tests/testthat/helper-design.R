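# Shared fixtures, built in code.

aet_design <- function() enumerate_conditions(aet_leaflet_factors())

abc_design <- function(k = 3) {
  enumerate_conditions(lapply(letters[seq_len(k)], factor_def))
}

# Small scored cohort with a hand-set linear outcome (no rounding), one
# participant per condition replicated `reps` times: perfectly balanced.
balanced_scored <- function(design, coef = numeric(0), reps = 4,
                            noise_sd = 0, seed = 1, baseline = NULL) {
  n_cond <- nrow(design$conditions)
  condition_id <- rep(design$conditions$condition_id, reps)
  n <- length(condition_id)
  codes <- design_codes(design)[condition_id, , drop = FALSE]
  y <- rep(0, n)
  if (length(coef)) {
    y <- as.vector(build_model_matrix(codes, names(coef)) %*% coef)
  }
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed({
    if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
    data.frame(participant_id = seq_len(n), condition_id = condition_id,
               post_differential = y,
               pre_differential = baseline %||% rnorm(n, 0, 1),
               age = runif(n, 20, 70))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Factorial fit without covariates (exactly orthogonal design matrix).
fit_factorial_for_test <- function(scored, design,
                                   terms = all_terms(design)) {
  fit_parsimonious(scored, terms, design, covariates = character(0))
}
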