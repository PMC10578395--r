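test_that("least squares agrees with a normal-equations oracle", {
  set.seed(10)
  for (r in 1:10) {
    n <- 40; p <- 5
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    colnames(X) <- c("(Intercept)", paste0("x", 1:(p - 1)))
    y <- rnorm(n)
    fit <- fit_ols(y, X)
    beta_oracle <- solve(crossprod(X), crossprod(X, y))
    expect_lt(max(abs(fit$coefficients - beta_oracle)), 1e-10)
    s2_oracle <- sum((y - X %*% beta_oracle)^2) / (n - p)
    expect_equal(fit$sigma2, s2_oracle, tolerance = 1e-12)
    expect_lt(max(abs(fit$cov - s2_oracle * solve(crossprod(X)))), 1e-10)
  }
})

test_that("intercept-only fit returns the sample mean", {
  y <- c(1.5, 2, 4, -3, 0.5)
  fit <- fit_ols(y, matrix(1, 5, 1, dimnames = list(NULL, "(Intercept)")))
  expect_equal(unname(fit$coefficients), mean(y))
})

test_that("rank deficiency is reported with the offending column", {
  X <- cbind(`(Intercept)` = 1, a = c(1, -1, 1, -1, 1, -1),
             a_copy = c(1, -1, 1, -1, 1, -1))
  expect_error(fit_ols(rnorm(6), X), "rank deficient.*a_copy")
})

test_that("balanced-design coefficients are half the level-mean difference", {
  des <- abc_design(3)
  truth <- c(a = 0.4, "a:b" = -0.25)
  scored <- balanced_scored(des, coef = truth, reps = 8, noise_sd = 1,
                            seed = 2)
  fit <- fit_factorial_for_test(scored, des)
  codes <- design_codes(des)[scored$condition_id, ]
  for (tm in c("a", "b", "a:b", "a:b:c")) {
    col <- build_model_matrix(codes, tm)[, 1]
    half_diff <- (mean(scored$post_differential[col == 1]) -
                  mean(scored$post_differential[col == -1])) / 2
    b <- fit$estimates$b_weight[fit$estimates$term == tm]
    expect_equal(b, half_diff, tolerance = 1e-10)
  }
})

test_that("inference behaves at the reference points", {
  inf <- coefficient_inference(b = c(0, 0.5), se = c(0.1, 0.25), df = 50,
                               predictor_sds = c(1, 1), outcome_sd = 2)
  expect_equal(inf$t[1], 0)
  expect_equal(inf$p[1], 1)
  # CI symmetric about beta
  expect_equal(inf$beta - inf$ci_low, inf$ci_high - inf$beta)
  expect_error(coefficient_inference(1, 1, 0, 1, 1), "degrees of freedom")
})

test_that("standardization reproduces the published coefficient pair", {
  expect_equal(round(standardize_coef(0.362, 1, 5.72), 3), 0.063)
  expect_equal(standardize_coef(0, 1, 5.72), 0)
  expect_error(standardize_coef(1, 1, 0), "positive")
})

test_that("rescaling the outcome scales b but leaves beta unchanged", {
  des <- abc_design(3)
  scored <- balanced_scored(des, coef = c(a = 0.4), reps = 10, noise_sd = 1,
                            seed = 3)
  f1 <- fit_full_model(scored, des)
  scored2 <- scored
  scored2$post_differential <- 3 * scored2$post_differential
  f2 <- fit_full_model(scored2, des)
  i <- which(f1$estimates$term == "a")
  expect_equal(f2$estimates$b_weight[i], 3 * f1$estimates$b_weight[i],
               tolerance = 1e-10)
  expect_equal(f2$estimates$beta[i], f1$estimates$beta[i], tolerance = 1e-10)
})

test_that("the full model carries all 31 factorial terms plus covariates", {
  des <- aet_design()
  expect_length(all_terms(des), 31L)
  expect_equal(as.vector(table(term_order(all_terms(des)))[as.character(1:5)]),
               choose(5, 1:5))
  scored <- balanced_scored(des, reps = 2, noise_sd = 1, seed = 4)
  fit <- fit_full_model(scored, des)
  expect_equal(sum(fit$estimates$type == "factorial"), 31L)
  expect_equal(sum(fit$estimates$type == "covariate"), 2L)
  expect_equal(fit$residual_df, nrow(scored) - 34L)
})

test_that("selecting all terms reproduces the full fit; none gives covariates only", {
  des <- abc_design(3)
  scored <- balanced_scored(des, coef = c(a = 0.5, "b:c" = 0.3), reps = 10,
                            noise_sd = 1, seed = 6)
  full <- fit_full_model(scored, des)
  same <- fit_parsimonious(scored, all_terms(des), des)
  expect_equal(same$estimates$b_weight, full$estimates$b_weight,
               tolerance = 1e-12)
  none <- fit_parsimonious(scored, character(0), des)
  expect_equal(sum(none$estimates$type == "factorial"), 0L)
  tab <- effect_table(none, zero_unselected = TRUE)
  expect_equal(sum(tab$type == "factorial" & tab$b_weight == 0), 7L)
  expect_error(fit_parsimonious(scored, "a:z", des), "unknown factor")
})

test_that("dropping orthogonal terms leaves remaining coefficients unchanged", {
  des <- abc_design(3)
  scored <- balanced_scored(des, coef = c(a = 0.5, "a:b" = 0.3), reps = 6,
                            noise_sd = 1, seed = 7)
  full <- fit_factorial_for_test(scored, des)
  sub <- fit_factorial_for_test(scored, des, terms = c("a", "a:b"))
  for (tm in c("a", "a:b")) {
    expect_equal(sub$estimates$b_weight[sub$estimates$term == tm],
                 full$estimates$b_weight[full$estimates$term == tm],
                 tolerance = 1e-10)
  }
})

test_that("parsimonious refits change selected coefficients by less than one SE", {
  des <- aet_design()
  truth <- aet_truth_model()
  for (s in 1:5) {
    coh <- generate_cohort(des, truth, cohort_config(n = 1600, seed = 200 + s))
    scored <- score_cohort(coh)
    full <- fit_full_model(scored, des)
    sel <- names(truth$term_effects)
    pars <- fit_parsimonious(scored, sel, des)
    for (tm in sel) {
      b_full <- full$estimates$b_weight[full$estimates$term == tm]
      b_pars <- pars$estimates$b_weight[pars$estimates$term == tm]
      se <- full$estimates$se_b[full$estimates$term == tm]
      expect_lt(abs(b_full - b_pars), se)
    }
  }
})

test_that("fitted coefficients recover the generating model at large n", {
  des <- aet_design()
  truth <- aet_truth_model()
  coh <- generate_cohort(des, truth, cohort_config(n = 20000, seed = 314))
  fit <- fit_full_model(score_cohort(coh), des)
  est <- fit$estimates
  for (tm in names(truth$term_effects)) {
    i <- which(est$term == tm)
    expect_lt(abs(est$b_weight[i] - truth$term_effects[[tm]]),
              4 * est$se_b[i])
  }
  i <- which(est$term == "pre_differential")
  expect_lt(abs(est$b_weight[i] - truth$baseline_coef), 4 * est$se_b[i])
})
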