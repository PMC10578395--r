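# Published coefficient tables of the AET information-leaflet screening
# experiment, transcribed so the decision engine can be driven without the
# (undeposited) raw participant data.

#' Coefficient table of the AET leaflet screening experiment
#'
#' Effect estimates from the 2^5 factorial screening experiment on the AET
#' information leaflet (n = 1,603): b-weights (half-difference convention),
#' standardized betas, 90% CIs, t and two-sided p for the full model (all 31
#' factorial terms plus baseline-differential and age covariates) and for
#' the parsimonious prediction model (important terms only, p < .1).
#' P-values published as "< .001" are stored as 0.0005 and betas published
#' as "< 0.001" as signed 0.001/0.000; neither affects any screening
#' decision.
#'
#' @param model `"full"`, `"parsimonious"`, or `"both"`.
#' @return Data frame with `term`, `type`, `b_weight`, `beta`, `ci_low`,
#'   `ci_high`, `t`, `p`, `model`. Intercept rows carry `type =
#'   "intercept"`.
#' @export
aet_screening_effects <- function(model = c("both", "full", "parsimonious")) {
  model <- match.arg(model)
  full <- data.frame(
    term = c("(Intercept)",
             "diagrams", "benefits", "side_effects", "concerns",
             "patient_input",
             "diagrams:benefits", "diagrams:side_effects",
             "benefits:side_effects", "diagrams:concerns",
             "benefits:concerns", "side_effects:concerns",
             "diagrams:patient_input", "benefits:patient_input",
             "side_effects:patient_input", "concerns:patient_input",
             "diagrams:benefits:side_effects", "diagrams:benefits:concerns",
             "diagrams:side_effects:concerns",
             "benefits:side_effects:concerns",
             "diagrams:benefits:patient_input",
             "diagrams:side_effects:patient_input",
             "benefits:side_effects:patient_input",
             "diagrams:concerns:patient_input",
             "benefits:concerns:patient_input",
             "side_effects:concerns:patient_input",
             "diagrams:benefits:side_effects:concerns",
             "diagrams:benefits:side_effects:patient_input",
             "diagrams:benefits:concerns:patient_input",
             "diagrams:side_effects:concerns:patient_input",
             "benefits:side_effects:concerns:patient_input",
             "diagrams:benefits:side_effects:concerns:patient_input",
             "pre_differential", "age"),
    type = c("intercept", rep("factorial", 31), "covariate", "covariate"),
    b_weight = c(2.322,
                 0.028, -0.047, 0.018, -0.005, 0.362,
                 0.267, -0.163, -0.102, 0.031, -0.080, -0.072,
                 0.134, 0.002, -0.121, -0.035,
                 -0.045, -0.042, 0.144, 0.032, 0.086, 0.130, 0.061,
                 0.167, 0.047, -0.002,
                 -0.219, -0.096, -0.157, 0.070, 0.107,
                 0.095,
                 0.784, 0.003),
    beta = c(NA,
             0.005, -0.008, 0.003, -0.001, 0.063,
             0.047, -0.029, -0.018, 0.005, -0.014, -0.013,
             0.023, 0.000, -0.021, -0.006,
             -0.008, -0.007, 0.025, 0.006, 0.015, 0.023, 0.011,
             0.029, 0.008, 0.000,
             -0.038, -0.017, -0.027, 0.012, 0.019,
             0.017,
             0.735, 0.010),
    ci_low = c(NA,
               -0.023, -0.036, -0.025, -0.029, 0.035,
               0.019, -0.056, -0.046, -0.022, -0.042, -0.040,
               -0.005, -0.028, -0.049, -0.034,
               -0.036, -0.035, -0.003, -0.022, -0.013, -0.005, -0.017,
               0.001, -0.020, -0.028,
               -0.066, -0.045, -0.055, -0.016, -0.009,
               -0.011,
               0.707, -0.018),
    ci_high = c(NA,
                0.033, 0.020, 0.031, 0.027, 0.091,
                0.075, -0.001, 0.010, 0.033, 0.014, 0.015,
                0.051, 0.028, 0.007, 0.022,
                0.020, 0.021, 0.053, 0.033, 0.043, 0.051, 0.039,
                0.057, 0.036, 0.027,
                -0.010, 0.011, 0.001, 0.040, 0.047,
                0.045,
                0.763, 0.038),
    t = c(23.989,
          0.293, -0.486, 0.185, -0.055, 3.740,
          2.757, -1.683, -1.051, 0.324, -0.826, -0.745,
          1.380, 0.022, -1.253, -0.357,
          -0.462, -0.437, 1.484, 0.327, 0.888, 1.344, 0.632,
          1.726, 0.481, -0.025,
          -2.261, -0.987, -1.614, 0.724, 1.105,
          0.980,
          42.842, 0.575),
    p = c(0.0005,
          0.770, 0.627, 0.853, 0.956, 0.0005,
          0.006, 0.093, 0.293, 0.746, 0.409, 0.456,
          0.168, 0.983, 0.210, 0.721,
          0.644, 0.663, 0.138, 0.744, 0.375, 0.179, 0.527,
          0.085, 0.630, 0.980,
          0.024, 0.324, 0.107, 0.469, 0.269,
          0.327,
          0.0005, 0.566),
    model = "full",
    stringsAsFactors = FALSE
  )
  pars <- data.frame(
    term = c("(Intercept)", "patient_input", "diagrams:benefits",
             "diagrams:side_effects", "diagrams:concerns:patient_input",
             "diagrams:benefits:side_effects:concerns",
             "pre_differential", "age"),
    type = c("intercept", rep("factorial", 5), "covariate", "covariate"),
    b_weight = c(2.319, 0.361, 0.266, -0.163, 0.160, -0.224, 0.785, 0.005),
    beta = c(NA, 0.063, 0.047, -0.028, 0.028, -0.039, 0.736, 0.014),
    ci_low = c(NA, 0.036, 0.019, -0.056, 0.000, -0.067, 0.708, -0.014),
    ci_high = c(NA, 0.091, 0.074, -0.001, 0.056, -0.012, 0.764, 0.042),
    t = c(24.219, 3.773, 2.770, -1.693, 1.664, -2.332, 43.291, 0.846),
    p = c(0.0005, 0.0005, 0.006, 0.091, 0.096, 0.020, 0.0005, 0.397),
    model = "parsimonious",
    stringsAsFactors = FALSE
  )
  switch(model, full = full, parsimonious = pars, both = rbind(full, pars))
}

#' Published AET screening fits for the decision engine
#'
#' Wraps [aet_screening_effects()] into `screening_fit` objects (via
#' [as_screening_fit()]) so the stepped screening algorithm and the
#' prediction table can be reproduced without raw data.
#'
#' @param model `"full"` or `"parsimonious"`.
#' @return A `screening_fit`.
#' @export
aet_screening_fit <- function(model = c("full", "parsimonious")) {
  model <- match.arg(model)
  tab <- aet_screening_effects(model)
  design <- enumerate_conditions(aet_leaflet_factors())
  as_screening_fit(tab[tab$type != "intercept", ],
                   intercept = tab$b_weight[tab$type == "intercept"],
                   design = design, model = model)
}
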