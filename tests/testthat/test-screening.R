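published_fits <- function() {
  list(full = aet_screening_fit("full"),
       parsimonious = aet_screening_fit("parsimonious"))
}

fake_fit <- function(terms, betas, ps, design = aet_design(),
                     intercept = 2, b = betas) {
  as_screening_fit(
    data.frame(term = terms, b_weight = b, beta = betas, p = ps,
               type = "factorial", stringsAsFactors = FALSE),
    intercept = intercept, design = design)
}

test_that("importance classification is strict at the threshold", {
  imp <- classify_effects(aet_screening_fit("full"), 0.1)
  expect_setequal(imp$term,
                  c("patient_input", "diagrams:benefits",
                    "diagrams:side_effects",
                    "diagrams:concerns:patient_input",
                    "diagrams:benefits:side_effects:concerns"))
  expect_equal(imp$direction[imp$term == "diagrams:benefits"], "synergistic")
  expect_equal(imp$direction[imp$term == "diagrams:side_effects"],
               "antagonistic")

  at_thr <- fake_fit(c("diagrams", "benefits"), c(0.05, 0.04), c(0.1, 0.2))
  expect_equal(nrow(classify_effects(at_thr, 0.1)), 0L)  # p = .1 is out
  expect_equal(nrow(classify_effects(at_thr, 0.2)), 1L)
})

test_that("interactions are ordered by main-effect overlap then order", {
  des <- aet_design()
  imp <- classify_effects(aet_screening_fit("full"), 0.1)
  expect_equal(order_interactions(imp, des),
               c("diagrams:concerns:patient_input",
                 "diagrams:benefits",
                 "diagrams:side_effects",
                 "diagrams:benefits:side_effects:concerns"))
  # no important main effect: pure ascending interaction order
  no_main <- imp[imp$order > 1, ]
  expect_equal(order_interactions(no_main, des),
               c("diagrams:benefits", "diagrams:side_effects",
                 "diagrams:concerns:patient_input",
                 "diagrams:benefits:side_effects:concerns"))
  # same-order tie without main-effect overlap: canonical design order
  tie <- fake_fit(c("concerns:patient_input", "diagrams:benefits"),
                  c(0.03, 0.03), c(0.01, 0.01))
  expect_equal(order_interactions(classify_effects(tie), des),
               c("diagrams:benefits", "concerns:patient_input"))
})

test_that("interaction resolution follows the effect hierarchy and never flips", {
  pfit <- aet_screening_fit("parsimonious")
  # synergistic three-way with patient input already high: both others high
  r1 <- resolve_interaction("diagrams:concerns:patient_input",
                            c(patient_input = 1), pfit)
  expect_equal(r1$decisions[c("diagrams", "concerns")],
               c(diagrams = 1, concerns = 1))
  # antagonistic two-way with diagrams already high: side effects low
  r2 <- resolve_interaction("diagrams:side_effects",
                            c(patient_input = 1, diagrams = 1, concerns = 1,
                              benefits = 1), pfit)
  expect_equal(unname(r2$decisions["side_effects"]), -1)
  # fully resolved effect: confirmatory, decisions unchanged
  dec <- c(diagrams = 1, benefits = 1, side_effects = -1, concerns = 1,
           patient_input = 1)
  r3 <- resolve_interaction("diagrams:benefits:side_effects:concerns",
                            dec, pfit)
  expect_true(r3$log$confirmatory)
  expect_identical(r3$decisions, dec)
})

test_that("condition predictions reproduce the published values", {
  des <- aet_design()
  pfit <- aet_screening_fit("parsimonious")
  cond5 <- c(diagrams = 1, benefits = 1, side_effects = -1, concerns = 1,
             patient_input = 1)
  expect_equal(round(predict_condition(pfit, cond5), 3), 2.524)
  cond16 <- c(diagrams = 1, benefits = -1, side_effects = -1, concerns = -1,
              patient_input = -1)
  expect_equal(round(predict_condition(pfit, cond16), 3), 2.304)
  cond29 <- c(diagrams = -1, benefits = -1, side_effects = -1, concerns = 1,
              patient_input = 1)
  expect_equal(round(predict_condition(pfit, cond29), 3), 2.412)
  # degenerate model: intercept everywhere
  zero <- fake_fit("diagrams", 0, 0.5, intercept = 2.319)
  expect_equal(predict_condition(zero, cond5), 2.319)
  expect_error(predict_condition(pfit, cond5[-1]), "missing")
  # offset shifts the prediction additively
  expect_equal(predict_condition(pfit, cond5, covariate_offset = 1.791),
               predict_condition(pfit, cond5) + 1.791)
})

test_that("the prediction table enumerates candidates and finds the argmax", {
  des <- aet_design()
  pfit <- aet_screening_fit("parsimonious")
  tab <- build_prediction_table(pfit, des, fixed = c(side_effects = -1))
  expect_equal(nrow(tab), 16L)
  published <- c(`5` = 2.524, `6` = 2.342, `7` = 2.390, `8` = 2.320,
                 `13` = 2.352, `14` = 2.170, `15` = 2.374, `16` = 2.304,
                 `21` = 2.240, `22` = 2.170, `23` = 2.374, `24` = 2.192,
                 `29` = 2.412, `30` = 2.342, `31` = 2.390, `32` = 2.208)
  expect_equal(tab$condition_id, as.integer(names(published)))
  expect_equal(round(tab$y_hat, 3), unname(published))
  expect_equal(attr(tab, "argmax_id"), 5L)
  # all-zero coefficients: flat table, argmax ties to the lowest id
  zero <- fake_fit("diagrams", 0, 0.5, intercept = 1)
  flat <- build_prediction_table(zero, des)
  expect_equal(nrow(flat), 32L)
  expect_true(all(flat$y_hat == 1))
  expect_equal(attr(flat, "argmax_id"), 1L)
})

test_that("the stepped screening reproduces the published decision trail", {
  fits <- published_fits()
  scr <- run_screening(fits$full, fits$parsimonious, threshold = 0.1)
  expect_setequal(scr$screened_in,
                  c("diagrams", "benefits", "concerns", "patient_input"))
  expect_equal(scr$screened_out, "side_effects")
  steps <- vapply(scr$decision_log,
                  function(e) e$effect %||% e$step, character(1))
  expect_equal(steps, c("main_effects",
                        "diagrams:concerns:patient_input",
                        "diagrams:benefits",
                        "diagrams:side_effects",
                        "diagrams:benefits:side_effects:concerns",
                        "default"))
  # the four-way is confirmatory at that point
  expect_true(scr$decision_log[[5]]$confirmatory)
  # determinism
  scr2 <- run_screening(fits$full, fits$parsimonious, threshold = 0.1)
  expect_identical(scr, scr2)
})

test_that("screening defaults untouched components to the low level", {
  # nothing important: everything screened out
  fits <- published_fits()
  none <- run_screening(fits$full, fits$parsimonious, threshold = 1e-6)
  expect_length(none$screened_in, 0L)
  expect_length(none$screened_out, 5L)
  # one negative main effect only: that component out, rest out
  neg <- fake_fit(c("benefits", "diagrams"), c(-0.05, 0.01), c(0.01, 0.9))
  scr <- run_screening(neg, neg)
  expect_length(scr$screened_in, 0L)
  expect_equal(unname(scr$decisions["benefits"]), -1)
})

test_that("the screening result matches the prediction-table argmax", {
  des <- aet_design()
  fits <- published_fits()
  scr <- run_screening(fits$full, fits$parsimonious)
  tab <- build_prediction_table(fits$parsimonious, des,
                                fixed = scr$decisions[scr$screened_out])
  expect_equal(condition_id_from_codes(des, scr$decisions),
               attr(tab, "argmax_id"))
})

test_that("strengthening a screened-in main effect never screens it out", {
  fits <- published_fits()
  base <- run_screening(fits$full, fits$parsimonious)
  expect_true("patient_input" %in% base$screened_in)
  for (delta in c(0.01, 0.05, 0.2)) {
    full <- fits$full
    i <- which(full$estimates$term == "patient_input")
    full$estimates$beta[i] <- full$estimates$beta[i] + delta
    full$estimates$b_weight[i] <- full$estimates$b_weight[i] + delta * 5.72
    scr <- run_screening(full, fits$parsimonious)
    expect_true("patient_input" %in% scr$screened_in)
  }
})
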