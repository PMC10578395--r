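# mostscreen

Factorial screening analysis for intervention optimization.

In the optimization phase of the multiphase optimization strategy (MOST), a
multicomponent intervention is taken apart into candidate components and a
single randomized 2^k factorial experiment decides, component by component,
what the optimized intervention should contain. `mostscreen` implements
that analysis as a tested, reusable pipeline for biostatisticians and
trialists running component screening experiments:

* **Design**: full 2^k condition enumeration with stable condition ids,
  −1/+1 effect coding, exactly orthogonal model matrices, the screening
  sample-size formula, and simple randomization.
* **Measurement**: scoring of the 10-item Beliefs about Medicines
  Questionnaire (necessity and concerns subscales, 5–25 each; differential
  = necessity − concerns, −20 to +20), speed-responder data-quality flags,
  and configurable exclusion rules.
* **Model**: multiple linear regression of the post-intervention
  differential on all 2^k − 1 effect-coded factorial terms plus baseline
  and age covariates, then a parsimonious refit keeping only the important
  terms (p < .1). With effect coding every coefficient is *half* the
  difference between level means.
* **Decision engine**: a deterministic, stepped, effect-hierarchy screening
  algorithm — main effects first, then important interactions in a
  principled order, then low-level defaults — plus condition-level outcome
  prediction over all candidate configurations and an argmax selection.
* **Validation tooling**: a synthetic-cohort generator with a configurable
  truth model and contamination, and Monte-Carlo power, type-I and
  decision-accuracy simulations.

The worked example throughout is a five-component information leaflet for
women prescribed adjuvant endocrine therapy (AET) after breast cancer;
its published coefficient table ships with the package
(`aet_screening_effects()`) so the decision trail is reproducible without
raw participant data.

## Worked example

```r
library(mostscreen)
design <- enumerate_conditions(aet_leaflet_factors())

required_sample_size(0.15, 0.9, 0.1, attrition_rate = 0.05)
#> $n_per_level  762
#> $n_analysis  1524
#> $n_recruit   1604
```

To detect a standardized main-effect difference of 0.15 with power 0.9 at
two-sided α = 0.1, 1,524 analyzable participants are needed — 1,604
recruited if 5% of responses are unusable.

```r
res <- run_pipeline(design = design,
                    fits = list(full = aet_screening_fit("full"),
                                parsimonious = aet_screening_fit("parsimonious")))
res$screening
#> Component screening result
#>   screened in :  diagrams, benefits, concerns, patient_input
#>   screened out:  side_effects
#>   5 important effect(s) at p < 0.1
res$optimized_condition_id
#> [1] 5
head(as.data.frame(res$predictions)[c("condition_id", "y_hat")], 3)
#>   condition_id y_hat
#> 1            5 2.524
#> 2            6 2.342
#> 3            7 2.390
```

Driven by the published effect table, the engine screens in four of the
five components and screens out the side-effects component: its main
effect is null and it interacts antagonistically with the others. The
prediction table evaluates the parsimonious model (intercept 2.319 plus
the five important standardized coefficients) over all 16 candidate
conditions with side effects fixed at its basic level; condition 5 — every
remaining component at its high level — has the greatest predicted
belief differential, 2.524 points.

The same pipeline runs end to end from participant-level data
(`run_pipeline(cohort_csv_or_data_frame, design, ...)`), and
`generate_cohort()` produces fully synthetic cohorts for method validation:

```r
coh <- generate_cohort(design, aet_truth_model(), cohort_config(n = 1524, seed = 7))
res <- run_pipeline(coh, design)   # score -> exclude -> fit -> screen -> predict
```

See the methods vignette (`vignettes/factorial-screening.Rmd`) for the
model, the decision rules and their rationale, and what the synthetic
generator does and does not emulate.

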