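---
title: "Factorial screening of intervention components: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factorial screening of intervention components: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mostscreen)
```

## The problem

In the optimization phase of the multiphase optimization strategy (MOST), a
multicomponent behavioural intervention is decomposed into candidate
components, and a single randomized factorial experiment estimates the
effect of every component — and of their combinations — at once. The worked
example throughout this package is an information leaflet for women
prescribed adjuvant endocrine therapy (AET) after breast cancer, with five
two-level components: mechanism diagrams (on/off), benefit infographics
(enhanced/basic), side-effect prevalence information (enhanced/basic),
answers to common concerns (on/off), and patient input from breast cancer
survivors (on/off). The outcome is the Beliefs about Medicines Questionnaire
differential — the necessity subscale total (5–25) minus the concerns
subscale total (5–25), range −20 to +20 — measured before and after viewing
the leaflet.

The analytic question is not "does the leaflet work" but "which components
should the optimized leaflet contain". `mostscreen` implements that
screening analysis end to end: the design, the sample size, the regression,
and a deterministic decision engine.

## Design and coding

A full 2^5 design has 32 conditions. `enumerate_conditions()` numbers them
deterministically: condition 1 has every component at its high level and the
last factor varies fastest, so condition ids are stable and citable.
Components are effect-coded −1/+1 (low/high). Under a balanced design the
±1 coding makes every pair of the 31 factorial contrast columns (5 main
effects, 10 two-way, 10 three-way, 5 four-way, 1 five-way) exactly
orthogonal: with one replicate per condition the cross-product matrix of the
intercept plus all 31 columns is `32 * I`.

A consequence of effect coding worth stating explicitly: a regression
coefficient on a ±1 column is *half* the difference between the two level
means. All coefficients in this package are reported in that
half-difference convention, as they come out of the model.

## Sample size

`required_sample_size()` uses the two-group normal approximation for a main
effect in a balanced factorial: per level
$n = \lceil 2 (z_{1-\alpha/2} + z_{1-\beta})^2 / d^2 \rceil$, analysis
$n = 2 n_{\text{level}}$, and a recruitment target inflated by
nearest-integer division by $(1 - \text{attrition})$. With $d = 0.15$,
power 0.9 and two-sided $\alpha = 0.1$ this gives 1,524 analyzable
participants, and 1,604 recruited at 5% expected unusable responses. An
$\alpha$ of 0.1 is deliberate: in a screening context, wrongly discarding a
useful component and wrongly retaining a useless one are comparably costly,
so type-I and type-II rates are balanced rather than minimizing type-I
alone.

```{r}
required_sample_size(0.15, 0.9, 0.1, attrition_rate = 0.05)
```

## Measurement and data quality

`score_bmq()`/`score_cohort()` sum the two 5-item subscales (no reverse
coding) and form the differential. `flag_speed_responders()` implements
three data-quality rules: completion time strictly below one third of the
sample median (the median is computed on the full pre-exclusion sample),
and straight-lining — one identical response to all ten items — within the
pre or the post administration, each evaluated separately.
`apply_exclusions()` applies any subset of `{under_18, speed,
bc_diagnosis}`; the primary analysis excludes only under-18s, the other
rules mirror sensitivity analyses.

## The regression

`fit_full_model()` regresses the post differential on all 31 factorial
terms plus two covariates: the baseline differential and age. Covariates
enter as deviations from their sample means, so the intercept is the
covariate-adjusted grand mean of the outcome — directly comparable with the
raw outcome scale. Inference is classical OLS: $t$ at the residual degrees
of freedom, two-sided $p$, and 90% confidence intervals reported on the
standardized scale, where $\beta = b \cdot \mathrm{sd}(x) /
\mathrm{sd}(y)$ (for balanced ±1 columns $\mathrm{sd}(x) \approx 1$, so
$b/\beta$ is essentially the outcome SD). Rank deficiency is detected by
the QR decomposition and reported with the offending columns named.

`fit_parsimonious()` refits with only the terms meeting the importance
threshold (plus the covariates); every other factorial coefficient is set
to exactly zero in exported tables. On a perfectly balanced design the
factorial columns are orthogonal, so dropping terms leaves the remaining
coefficients unchanged; under simple randomization the change is small —
bounded in our tests by one standard error.

## The screening decision engine

`run_screening()` formalizes a stepped, effect-hierarchy decision process
into three deterministic stages:

1. **Main effects.** Every component with an important (p strictly below
   the threshold, default 0.1) positive main effect is screened in;
   important negative main effects screen out.
2. **Interactions**, processed in `order_interactions()` order: first those
   containing a component with an important main effect, ascending by
   interaction order; then the rest, ascending by order; ties broken by
   canonical component order. Each interaction is resolved by
   `resolve_interaction()`: the still-undecided components in the
   interaction take the level combination that maximizes the
   parsimonious-model prediction, *restricted to important terms whose
   components all lie within the already-resolved set plus the
   interaction's own components*. Components resolved earlier are held
   fixed and never flipped; an interaction whose components are all
   resolved is logged as confirmatory.
3. **Defaults.** Components never touched by an important effect are set to
   their low level, reflecting the resource-management principle (the
   cheaper level wins absent evidence); this default is configurable.

Two design choices here were genuinely open and deserve their rationale.

*Why restrict the predictor in stage 2?* The effect-hierarchy principle
holds that lower-order effects are the scientifically trustworthy ones.
When the engine examines, say, a three-way interaction right after the main
effects, conditioning its decision on higher-order terms involving
components it has not yet examined would let poorly-understood corners of
the model drive early decisions — and can actively contradict the stepwise
logic, because reference levels assumed for unexamined components inject
their cross-terms into the comparison. Restricting each step to the terms
spanned by the components under consideration (plus those already decided)
makes each decision depend only on evidence already on the table. The final
prediction table then evaluates the *full* parsimonious model over all
remaining candidate conditions, so nothing is ignored at the end.

*Why do ties go to the high level?* A synergistic interaction among
otherwise-null components is maximized equally by "all high" and "all low".
The engine prefers the candidate earliest in condition-id order — high
levels first — i.e. it retains components that participate in a positive
synergy rather than discarding them. This is the all-active-components
perspective: the best expected outcome irrespective of cost. A consequence,
visible in null simulations, is that false-positive synergistic
interactions tend to pull their components in; at the default threshold of
0.1 roughly three of the 31 terms will be falsely important in any null
data set, so screened-in sets under pure noise are frequently non-empty.
That is a property of the decision rules at this threshold, not of the
implementation.

`build_prediction_table()` enumerates the 2^m candidate conditions over the
free components (screened-out components held at their assigned level),
predicts each, and selects the argmax, with ties again to the lowest
condition id. Two prediction modes exist: `"table_compatible"` applies the
standardized coefficients to the raw intercept without covariates — the
convention used for published condition-level predictions in this
literature, and the mode that reproduces them to three decimals — and
`"unstandardized"`, the default for new analyses, which uses the b-weights
and accepts a covariate offset in outcome units.

```{r}
fits <- list(full = aet_screening_fit("full"),
             parsimonious = aet_screening_fit("parsimonious"))
scr <- run_screening(fits$full, fits$parsimonious)
scr
```

## The synthetic cohort generator

The study's raw data are not deposited, so the generator is the package's
test bed. It emulates: balanced ±1 condition assignment by simple
randomization; a baseline differential drawn Normal(1.52, 5.36) — the
observed baseline mean and SD — rounded to the attainable integer grid and
clipped to [−20, 20]; ages from a truncated Normal(47.9, 16.3) on [18, 83];
a post differential from a configurable linear truth model (default:
`aet_truth_model()`, the parsimonious b-weights with intercept 2.319,
baseline slope 0.785, age slope 0.005) plus Gaussian noise, again rounded
and clipped; and log-normal completion times with median 9.45 minutes
(sdlog 0.4, a right-skew consistent with the observed range). The default
residual SD of 3.87 makes the marginal follow-up SD about 5.7 once the
baseline effect is added, matching the observed outcome spread.

Score totals are decomposed into items deterministically: each of the five
subscale items gets `floor(total/5)` and the remainder goes one unit each
to the first items. A differential is decomposed by anchoring the concerns
total (at 16 at baseline; at its baseline value at follow-up) and moving
necessity, spilling into concerns only when a bound forces it. Items 1–5
are the necessity subscale by convention. Speed-responder contamination is
injected on demand (`inject_speed_responders()`), with truth flags returned
so filter recovery is testable.

What the generator does **not** emulate: item-level measurement structure
(no IRT; items within a subscale are near-interchangeable by construction),
realistic demographic joint distributions, missing data (the emulated
survey made all fields mandatory), or any relationship between speed
responding and the outcome. Tests passing on this generator therefore
validate the *pipeline arithmetic and statistical calibration*, not the
psychometrics of any real instrument.

Two numerical notes. Rounding the continuous model outcome to the integer
grid adds discretization noise of variance 1/12, which the convergence and
recovery tests account for; clipping at ±20 is a >3 SD event at the default
parameters and negligible. And every stochastic operation draws from an
injected seed through a save/restore wrapper, so nothing mutates the
session's RNG state and identical seeds give byte-identical tables.

## Simulation tooling and problem sizes

`simulate_power()` works at the linear-model level: balanced effect-coded
assignment, a single main effect of standardized size $d$ (coefficient
$d/2$ on the ±1 code), unit Gaussian noise, full 31-term fit per replicate,
reusing one QR decomposition of the fixed design matrix. At $d = 0.15$,
$n = 1{,}524$, $\alpha = 0.1$ the simulated power is ≈ 0.90, matching the
closed form; at $d = 0$ it recovers the nominal per-term type-I rate of
0.10. `simulate_screening_accuracy()` runs the full generator-to-decision
pipeline and scores whether the selected condition attains the
truth-optimal expected outcome (membership in the argmax set of the true
predictor — components with truly null effects make both of their levels
optimal).

Default problem sizes were chosen so the whole validation suite runs in
well under a minute on a single core: 1,000 replicates for power and type-I
rates, 20 cohorts of n = 20,000 for parameter recovery, 200 cohorts of
n = 400 for interval coverage, and 40-replicate grids for decision
accuracy. All are package choices and scale linearly if more precision is
wanted.

## Known limitations

* The decision engine never revisits a resolved component; an important
  interaction that would favor flipping one is logged as a conflict but
  cannot override earlier, lower-order evidence. This is intentional but
  means the result can depend on processing order in pathological patterns.
* The engine optimizes a single outcome with the all-active-components
  criterion; cost-constrained or multi-outcome optimization is out of
  scope.
* Only full 2^k designs with two-level factors are supported — no
  fractional designs, blocking, or stratified randomization.
* The published-table prediction mode inherits the rounding of the printed
  coefficients; predictions agree with published values to three decimals,
  not beyond.
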