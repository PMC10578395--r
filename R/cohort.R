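#' Truth model for synthetic-cohort generation
#'
#' Specifies the data-generating linear model for the post-intervention
#' belief differential. Factorial coefficients follow the half-difference
#' convention of effect coding: a coefficient is the change in outcome per
#' unit of the ±1 code, i.e. half the difference between the two level means.
#' Covariates enter as deviations from their centers, so `intercept` is the
#' covariate-adjusted grand mean of the outcome.
#'
#' @param intercept Outcome units (belief differential points).
#' @param term_effects Named numeric vector: canonical term string ->
#'   coefficient (outcome units per unit code).
#' @param baseline_coef Slope on the baseline differential deviation.
#' @param age_coef Slope on the age deviation (per year).
#' @param noise_sd Residual standard deviation (>= 0).
#' @param baseline_center,age_center Centers subtracted from the covariates
#'   before applying the slopes; `NULL` (default) means the population means
#'   configured in [cohort_config()].
#' @return A `truth_model` object.
#' @export
truth_model <- function(intercept = 0, term_effects = numeric(0),
                        baseline_coef = 0, age_coef = 0, noise_sd = 1,
                        baseline_center = NULL, age_center = NULL) {
  stopifnot(noise_sd >= 0)
  structure(list(intercept = intercept, term_effects = term_effects,
                 baseline_coef = baseline_coef, age_coef = age_coef,
                 noise_sd = noise_sd, baseline_center = baseline_center,
                 age_center = age_center),
            class = "truth_model")
}

#' Truth model echoing the AET leaflet screening study
#'
#' Default data-generating model with the parsimonious unstandardized
#' coefficients estimated in the AET information-leaflet screening
#' experiment: patient input 0.361, diagrams x benefits 0.266, diagrams x
#' side effects -0.163, diagrams x concerns x patient input 0.160, diagrams x
#' benefits x side effects x concerns -0.224, baseline slope 0.785, age slope
#' 0.005, intercept 2.319. The residual SD defaults to 3.87, consistent with
#' a follow-up outcome SD of 5.72 of which the baseline covariate explains
#' beta ~ 0.74.
#'
#' @param noise_sd Residual standard deviation.
#' @return A `truth_model`.
#' @export
aet_truth_model <- function(noise_sd = 3.87) {
  truth_model(
    intercept = 2.319,
    term_effects = c(
      "patient_input" = 0.361,
      "diagrams:benefits" = 0.266,
      "diagrams:side_effects" = -0.163,
      "diagrams:concerns:patient_input" = 0.160,
      "diagrams:benefits:side_effects:concerns" = -0.224
    ),
    baseline_coef = 0.785,
    age_coef = 0.005,
    noise_sd = noise_sd
  )
}

#' Cohort configuration
#'
#' Population parameters of the synthetic cohort. Defaults emulate the AET
#' leaflet screening sample: baseline differential mean 1.52 (SD 5.36), age
#' mean 47.9 (SD 16.3) truncated to 18-83 years, median survey completion
#' time 9.45 minutes, 4.9% with a breast-cancer diagnosis.
#'
#' @param n Number of participants (>= 1).
#' @param baseline_mean,baseline_sd Baseline belief-differential distribution.
#' @param age_mean,age_sd,age_range Age distribution (truncated normal).
#' @param time_median,time_sdlog Log-normal completion-time parameters
#'   (minutes; `time_median` is the distribution median).
#' @param speed_fraction Fraction of rows to contaminate when
#'   [inject_speed_responders()] is asked to use the configured rate.
#' @param bc_fraction Breast-cancer subgroup rate.
#' @param seed Integer seed for all generation.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n, baseline_mean = 1.52, baseline_sd = 5.36,
                          age_mean = 47.9, age_sd = 16.3,
                          age_range = c(18, 83),
                          time_median = 9.45, time_sdlog = 0.4,
                          speed_fraction = 0, bc_fraction = 0.049,
                          seed = 1L) {
  stopifnot(n >= 1, baseline_sd >= 0, age_sd >= 0,
            speed_fraction >= 0, speed_fraction <= 1,
            bc_fraction >= 0, bc_fraction <= 1,
            length(age_range) == 2L, age_range[1] <= age_range[2])
  structure(list(n = as.integer(n), baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 time_median = time_median, time_sdlog = time_sdlog,
                 speed_fraction = speed_fraction, bc_fraction = bc_fraction,
                 seed = seed),
            class = "cohort_config")
}

#' Deterministically allocate a subscale total to five Likert items
#'
#' Every item receives `floor(total / 5)`; the remainder (`total mod 5`) is
#' distributed one unit each to the first items. The allocation inverts
#' subscale scoring exactly: summing the returned items recovers `total`.
#'
#' @param subscale_total Integer in [5, 25].
#' @return Integer vector of 5 item responses in [1, 5].
#' @examples
#' items_from_score(25)  # 5 5 5 5 5
#' items_from_score(7)   # 2 2 1 1 1
#' @export
items_from_score <- function(subscale_total) {
  stopifnot(length(subscale_total) == 1L)
  if (subscale_total != round(subscale_total) ||
      subscale_total < 5 || subscale_total > 25) {
    stop("subscale total must be an integer in [5, 25], got ", subscale_total,
         call. = FALSE)
  }
  as.integer(items_matrix(as.integer(subscale_total))[1L, ])
}

# Vectorized allocator: one row of 5 items per total.
items_matrix <- function(totals) {
  base <- totals %/% 5L
  rem <- totals %% 5L
  m <- matrix(base, length(totals), 5L)
  m + outer(rem, 1:5, ">=")
}

# Represent an integer differential d in [-20, 20] as (necessity, concerns)
# totals in [5, 25] with necessity - concerns = d, anchoring concerns near
# `anchor` and shifting only when a bound forces it.
split_differential <- function(d, anchor = 16L) {
  stopifnot(all(d >= -20), all(d <= 20))
  con <- rep(as.integer(anchor), length(d))
  nec <- con + as.integer(d)
  over <- nec > 25L
  con[over] <- con[over] - (nec[over] - 25L)
  nec[over] <- 25L
  under <- nec < 5L
  con[under] <- con[under] + (5L - nec[under])
  nec[under] <- 5L
  cbind(necessity = nec, concerns = con)
}

# Move a baseline (necessity, concerns) pair to realize a new differential:
# concerns held at baseline, necessity shifted, residual spilled into
# concerns when a necessity bound is hit.
shift_differential <- function(pre_nec, pre_con, new_diff) {
  nec <- pre_con + as.integer(new_diff)
  con <- pre_con
  over <- nec > 25L
  con[over] <- con[over] - (nec[over] - 25L)
  nec[over] <- 25L
  under <- nec < 5L
  con[under] <- con[under] + (5L - nec[under])
  nec[under] <- 5L
  cbind(necessity = nec, concerns = con)
}

#' Generate a synthetic participant cohort
#'
#' Draws ages (truncated normal), baseline belief differentials (normal,
#' rounded to the attainable integer grid and clipped to [-20, 20]),
#' decomposes them into necessity/concern subscale totals and item responses,
#' assigns conditions by simple randomization, generates the
#' post-intervention differential from the truth model plus Gaussian noise
#' (again rounded and clipped), and draws log-normal completion times.
#' Fully reproducible given `config$seed`.
#'
#' @param design A `factorial_design`.
#' @param truth A [truth_model()].
#' @param config A [cohort_config()].
#' @return Data frame with columns `participant_id`, `age`, `bc_flag`,
#'   `condition_id`, `pre_item_1..10`, `post_item_1..10`,
#'   `completion_minutes`. Items 1-5 of each administration are the necessity
#'   subscale, items 6-10 the concerns subscale.
#' @export
generate_cohort <- function(design, truth, config) {
  stopifnot(inherits(design, "factorial_design"),
            inherits(truth, "truth_model"),
            inherits(config, "cohort_config"))
  n <- config$n
  with_seed(config$seed, {
    # age: inverse-CDF truncated normal
    lo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
    hi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
    age <- stats::qnorm(stats::runif(n, lo, hi), config$age_mean,
                        config$age_sd)

    base_cont <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    base_diff <- as.integer(clip(round(base_cont), -20, 20))
    pre <- split_differential(base_diff)

    condition_id <- sample.int(nrow(design$conditions), n, replace = TRUE)
    codes <- design_codes(design)[condition_id, , drop = FALSE]

    b_center <- truth$baseline_center %||% config$baseline_mean
    a_center <- truth$age_center %||% config$age_mean
    lp <- rep(truth$intercept, n)
    if (length(truth$term_effects)) {
      tm <- build_model_matrix(codes, names(truth$term_effects))
      lp <- lp + as.vector(tm %*% truth$term_effects)
    }
    lp <- lp + truth$baseline_coef * (base_diff - b_center) +
      truth$age_coef * (age - a_center)
    post_cont <- lp + stats::rnorm(n, 0, truth$noise_sd)
    post_diff <- as.integer(clip(round(post_cont), -20, 20))
    post <- shift_differential(pre[, "necessity"], pre[, "concerns"],
                               post_diff)

    completion <- stats::rlnorm(n, meanlog = log(config$time_median),
                                sdlog = config$time_sdlog)
    bc_flag <- stats::runif(n) < config$bc_fraction

    pre_items <- cbind(items_matrix(pre[, "necessity"]),
                       items_matrix(pre[, "concerns"]))
    post_items <- cbind(items_matrix(post[, "necessity"]),
                        items_matrix(post[, "concerns"]))
    colnames(pre_items) <- paste0("pre_item_", 1:10)
    colnames(post_items) <- paste0("post_item_", 1:10)

    cbind(
      data.frame(participant_id = seq_len(n), age = age, bc_flag = bc_flag,
                 condition_id = condition_id),
      as.data.frame(pre_items), as.data.frame(post_items),
      data.frame(completion_minutes = completion)
    )
  })
}

#' Contaminate a cohort with speed responders
#'
#' Alters a seeded random subset of rows to mimic low-quality responding:
#' `fast_time` sets the completion time below one third of the current median
#' time; `straightline_pre` / `straightline_post` set all ten items of the
#' corresponding administration to one common value; `mixed` picks one of the
#' three modes per contaminated row.
#'
#' @param cohort Participant table from [generate_cohort()].
#' @param fraction Fraction of rows to contaminate, in [0, 1]; the subset has
#'   size `round(fraction * n)`.
#' @param mode One of `"fast_time"`, `"straightline_pre"`,
#'   `"straightline_post"`, `"mixed"`.
#' @param seed Integer seed.
#' @return List with `cohort` (contaminated copy) and `flags` (data frame
#'   `participant_id`, `injected`, `mode`) for filter-validation tests.
#' @export
inject_speed_responders <- function(cohort, fraction,
                                    mode = c("mixed", "fast_time",
                                             "straightline_pre",
                                             "straightline_post"),
                                    seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(fraction >= 0, fraction <= 1)
  n <- nrow(cohort)
  m <- round(fraction * n)
  flags <- data.frame(participant_id = cohort$participant_id,
                      injected = FALSE, mode = NA_character_)
  if (m == 0) return(list(cohort = cohort, flags = flags))
  with_seed(seed, {
    idx <- sample.int(n, m)
    modes <- if (mode == "mixed") {
      sample(c("fast_time", "straightline_pre", "straightline_post"), m,
             replace = TRUE)
    } else rep(mode, m)
    med <- stats::median(cohort$completion_minutes)
    for (j in seq_len(m)) {
      i <- idx[j]
      switch(modes[j],
        fast_time = {
          # well below a third of the median, so the flag threshold still
          # catches the row after contamination itself shifts the median
          cohort$completion_minutes[i] <- med / 3 * stats::runif(1, 0.2, 0.8)
        },
        straightline_pre = {
          cohort[i, paste0("pre_item_", 1:10)] <- sample.int(5L, 1L)
        },
        straightline_post = {
          cohort[i, paste0("post_item_", 1:10)] <- sample.int(5L, 1L)
        })
    }
    flags$injected[idx] <- TRUE
    flags$mode[idx] <- modes
    list(cohort = cohort, flags = flags)
  })
}
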