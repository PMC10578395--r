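#' Score the 10-item beliefs-about-medicines instrument
#'
#' Sums the five necessity items and the five concern items (each subscale
#' ranging 5-25) and forms the differential = necessity - concerns (range
#' -20 to +20). No items are reverse-coded.
#'
#' @param items Integer vector of 10 responses, each in [1, 5].
#' @param necessity_index Positions of the five necessity items (default
#'   1:5; the remaining five are the concerns subscale).
#' @return List with `necessity`, `concerns`, `differential`.
#' @export
score_bmq <- function(items, necessity_index = 1:5) {
  items <- as.integer(items)
  if (length(items) != 10L || anyNA(items) ||
      any(items < 1L | items > 5L)) {
    stop("items must be 10 integer responses in [1, 5]", call. = FALSE)
  }
  stopifnot(length(necessity_index) == 5L,
            all(necessity_index %in% 1:10))
  necessity <- sum(items[necessity_index])
  concerns <- sum(items[-necessity_index])
  list(necessity = necessity, concerns = concerns,
       differential = necessity - concerns)
}

#' Score every participant in a cohort table
#'
#' Adds `pre_necessity`, `pre_concerns`, `pre_differential`,
#' `post_necessity`, `post_concerns`, `post_differential` columns.
#'
#' @param cohort Participant table with `pre_item_1..10` and
#'   `post_item_1..10` columns.
#' @param necessity_index Positions of the necessity items within each
#'   10-item administration.
#' @return The table with six score columns appended.
#' @export
score_cohort <- function(cohort, necessity_index = 1:5) {
  pre <- as.matrix(cohort[paste0("pre_item_", 1:10)])
  post <- as.matrix(cohort[paste0("post_item_", 1:10)])
  if (anyNA(pre) || anyNA(post) || any(pre < 1 | pre > 5) ||
      any(post < 1 | post > 5)) {
    stop("item responses must be integers in [1, 5]", call. = FALSE)
  }
  cohort$pre_necessity <- rowSums(pre[, necessity_index, drop = FALSE])
  cohort$pre_concerns <- rowSums(pre[, -necessity_index, drop = FALSE])
  cohort$pre_differential <- cohort$pre_necessity - cohort$pre_concerns
  cohort$post_necessity <- rowSums(post[, necessity_index, drop = FALSE])
  cohort$post_concerns <- rowSums(post[, -necessity_index, drop = FALSE])
  cohort$post_differential <- cohort$post_necessity - cohort$post_concerns
  cohort
}

#' Flag speed responders
#'
#' A respondent is flagged when any of three data-quality criteria holds:
#' (i) the survey was completed in strictly less than one third of the
#' median completion time of the full (pre-exclusion) sample; (ii) all ten
#' pre-intervention items received one identical response (straight-lining);
#' (iii) all ten post-intervention items did.
#'
#' @param cohort Participant table with `completion_minutes` and item
#'   columns.
#' @return Data frame with logical columns `fast_time`, `straightline_pre`,
#'   `straightline_post`, and their union `speed`.
#' @export
flag_speed_responders <- function(cohort) {
  stopifnot(all(cohort$completion_minutes > 0))
  med <- stats::median(cohort$completion_minutes)
  pre <- as.matrix(cohort[paste0("pre_item_", 1:10)])
  post <- as.matrix(cohort[paste0("post_item_", 1:10)])
  fast_time <- cohort$completion_minutes < med / 3
  straightline_pre <- apply(pre, 1, function(r) length(unique(r)) == 1L)
  straightline_post <- apply(post, 1, function(r) length(unique(r)) == 1L)
  data.frame(fast_time = fast_time,
             straightline_pre = straightline_pre,
             straightline_post = straightline_post,
             speed = fast_time | straightline_pre | straightline_post)
}

#' Apply exclusion rules to a cohort
#'
#' Removes participants failing any selected rule and returns an exclusion
#' log. The primary analysis typically excludes only under-18s; the speed
#' and breast-cancer-diagnosis rules mirror sensitivity analyses.
#'
#' @param cohort Participant table (needs `age` for `under_18`, item/time
#'   columns for `speed`, `bc_flag` for `bc_diagnosis`).
#' @param rules Character subset of `c("under_18", "speed", "bc_diagnosis")`;
#'   empty means no exclusion.
#' @return List with `cohort` (filtered copy; the input is untouched) and
#'   `log`, an `exclusion_log` with per-rule flags, per-rule counts and
#'   `n_before` / `n_after`.
#' @export
apply_exclusions <- function(cohort, rules = "under_18") {
  known <- c("under_18", "speed", "bc_diagnosis")
  if (length(rules) && !all(rules %in% known)) {
    stop("unknown exclusion rule(s): ",
         paste(setdiff(rules, known), collapse = ", "), call. = FALSE)
  }
  n <- nrow(cohort)
  sp <- flag_speed_responders(cohort)
  flags <- data.frame(participant_id = cohort$participant_id,
                      under_18 = cohort$age < 18,
                      fast_time = sp$fast_time,
                      straightline_pre = sp$straightline_pre,
                      straightline_post = sp$straightline_post,
                      bc_diagnosis = as.logical(cohort$bc_flag))
  drop <- rep(FALSE, n)
  if ("under_18" %in% rules) drop <- drop | flags$under_18
  if ("speed" %in% rules) drop <- drop | sp$speed
  if ("bc_diagnosis" %in% rules) drop <- drop | flags$bc_diagnosis
  log <- structure(list(
    rules = rules,
    n_before = n,
    n_after = n - sum(drop),
    n_removed = sum(drop),
    counts = list(under_18 = sum(flags$under_18),
                  fast_time = sum(flags$fast_time),
                  straightline_pre = sum(flags$straightline_pre),
                  straightline_post = sum(flags$straightline_post),
                  speed = sum(sp$speed),
                  bc_diagnosis = sum(flags$bc_diagnosis)),
    flags = flags
  ), class = "exclusion_log")
  list(cohort = cohort[!drop, , drop = FALSE], log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat(sprintf("Exclusions [%s]: %d -> %d participants (%d removed)\n",
              paste(x$rules, collapse = ", "), x$n_before, x$n_after,
              x$n_removed))
  invisible(x)
}

#' Two-sample comparison of a score between subgroups
#'
#' Convenience report: Welch or pooled-variance t-test of a scored column
#' between participants with and without a flag (e.g. breast-cancer
#' diagnosis). Not part of the screening decision pipeline.
#'
#' @param scored Scored cohort table.
#' @param column Name of the numeric column to compare.
#' @param group Logical vector or name of a logical column splitting the
#'   sample.
#' @param var.equal Passed to [stats::t.test()] (default pooled variance).
#' @return The `htest` object.
#' @export
subgroup_t_test <- function(scored, column, group = "bc_flag",
                            var.equal = TRUE) {
  g <- if (is.character(group)) as.logical(scored[[group]]) else group
  stats::t.test(scored[[column]][g], scored[[column]][!g],
                var.equal = var.equal)
}
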