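#' Define a two-level factor (candidate intervention component)
#'
#' Each candidate component of the intervention is a two-level experimental
#' factor: an "on/enhanced" level (coded +1) and an "off/basic" level
#' (coded -1).
#'
#' @param name Short unique label, e.g. `"diagrams"`.
#' @param low_label Text label for the -1 (off/basic) level.
#' @param high_label Text label for the +1 (on/enhanced) level.
#' @return A `factor_def` object (named list).
#' @export
factor_def <- function(name, low_label = "off", high_label = "on") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, low_label = low_label, high_label = high_label),
            class = "factor_def")
}

#' Candidate components of the AET information leaflet
#'
#' The five two-level components screened in the worked examples: diagrams
#' explaining the medication mechanism (on/off), benefit infographics
#' (enhanced/basic), side-effect prevalence information (enhanced/basic),
#' answers to common concerns (on/off), and patient input from breast cancer
#' survivors (on/off).
#'
#' @return A list of five [factor_def()] objects, in canonical order.
#' @export
aet_leaflet_factors <- function() {
  list(
    factor_def("diagrams",      "No",    "Yes"),
    factor_def("benefits",      "Basic", "Enhanced"),
    factor_def("side_effects",  "Basic", "Enhanced"),
    factor_def("concerns",      "No",    "Yes"),
    factor_def("patient_input", "No",    "Yes")
  )
}

#' Enumerate all conditions of a full two-level factorial design
#'
#' Builds the 2^k condition table. Condition 1 has every factor at its high
#' level; the last factor varies fastest, from high to low, so the numbering
#' is deterministic given the factor order.
#'
#' @param factors Ordered list of [factor_def()] objects (length k >= 1).
#' @return A `factorial_design` object: list with `factors` (data frame of
#'   name/low_label/high_label), `k`, and `conditions` (data frame with
#'   `condition_id`, one level-label column per factor, and one `<name>_code`
#'   column per factor holding the ±1 effect codes).
#' @export
enumerate_conditions <- function(factors) {
  if (inherits(factors, "factor_def")) factors <- list(factors)
  stopifnot(length(factors) >= 1L)
  stopifnot(all(vapply(factors, inherits, logical(1), "factor_def")))
  names <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(names)) {
    stop("duplicate factor names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "),
         call. = FALSE)
  }
  k <- length(factors)
  n_cond <- 2L^k
  # id - 1 in binary, most significant bit = first factor; bit 1 = low level.
  codes <- matrix(0L, n_cond, k, dimnames = list(NULL, names))
  for (j in seq_len(k)) {
    bit <- bitwAnd(bitwShiftR(seq_len(n_cond) - 1L, k - j), 1L)
    codes[, j] <- ifelse(bit == 1L, -1L, 1L)
  }
  fac_df <- data.frame(
    name = names,
    low_label = vapply(factors, `[[`, character(1), "low_label"),
    high_label = vapply(factors, `[[`, character(1), "high_label"),
    stringsAsFactors = FALSE
  )
  conditions <- data.frame(condition_id = seq_len(n_cond))
  for (j in seq_len(k)) {
    conditions[[names[j]]] <- ifelse(codes[, j] == 1L,
                                     fac_df$high_label[j], fac_df$low_label[j])
  }
  for (j in seq_len(k)) {
    conditions[[paste0(names[j], "_code")]] <- codes[, j]
  }
  structure(list(factors = fac_df, k = k, conditions = conditions),
            class = "factorial_design")
}

#' @export
print.factorial_design <- function(x, ...) {
  cat(sprintf("Full 2^%d factorial design: %d conditions, factors %s\n",
              x$k, nrow(x$conditions), paste(x$factors$name, collapse = ", ")))
  invisible(x)
}

#' Effect-code matrix of a design
#'
#' @param design A `factorial_design`.
#' @return Integer matrix (2^k x k) of ±1 codes, columns in factor order,
#'   rows in condition-id order.
#' @export
design_codes <- function(design) {
  stopifnot(inherits(design, "factorial_design"))
  m <- as.matrix(design$conditions[paste0(design$factors$name, "_code")])
  colnames(m) <- design$factors$name
  m
}

#' Effect-code a single condition
#'
#' Maps level labels to signed codes: +1 for the high (on/enhanced) level,
#' -1 for the low (off/basic) level.
#'
#' @param design A `factorial_design`.
#' @param condition Named character vector or list assigning a level label to
#'   every factor, or a single condition id.
#' @return Named numeric vector of ±1 codes in canonical factor order.
#' @export
effect_code <- function(design, condition) {
  stopifnot(inherits(design, "factorial_design"))
  fac <- design$factors
  if (is.numeric(condition) && length(condition) == 1L) {
    stopifnot(condition %in% design$conditions$condition_id)
    codes <- design_codes(design)[condition, ]
    return(codes)
  }
  condition <- unlist(condition)
  missing <- setdiff(fac$name, names(condition))
  if (length(missing)) {
    stop("condition does not assign a level to: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  codes <- vapply(seq_len(nrow(fac)), function(j) {
    lev <- condition[[fac$name[j]]]
    if (identical(lev, fac$high_label[j])) 1
    else if (identical(lev, fac$low_label[j])) -1
    else stop(sprintf("unknown level '%s' for factor '%s'", lev, fac$name[j]),
              call. = FALSE)
  }, numeric(1))
  stats::setNames(codes, fac$name)
}

#' Map effect codes back to a condition id
#'
#' Inverse of the condition numbering: the all-high condition is 1 and the
#' last factor varies fastest.
#'
#' @param design A `factorial_design`.
#' @param codes Named ±1 vector covering every factor (or a matrix with one
#'   row per condition).
#' @return Integer condition id(s).
#' @export
condition_id_from_codes <- function(design, codes) {
  if (is.null(dim(codes))) codes <- matrix(codes, 1L,
                                           dimnames = list(NULL, names(codes)))
  nm <- design$factors$name
  stopifnot(all(nm %in% colnames(codes)))
  codes <- codes[, nm, drop = FALSE]
  k <- design$k
  ids <- rep(1L, nrow(codes))
  for (j in seq_len(k)) {
    ids <- ids + as.integer(codes[, j] == -1) * 2L^(k - j)
  }
  ids
}

# ---- factorial terms -------------------------------------------------------

#' Canonicalize a factorial term
#'
#' A term is a set of component names: a single name is a main effect, two or
#' more names an interaction. Terms are represented as strings joining the
#' components with `":"` in canonical (design) factor order.
#'
#' @param components Character vector of factor names, or a `"a:b"` string.
#' @param design A `factorial_design`.
#' @return Canonical term string.
#' @export
term_spec <- function(components, design) {
  if (length(components) == 1L && grepl(":", components, fixed = TRUE)) {
    components <- strsplit(components, ":", fixed = TRUE)[[1]]
  }
  components <- unique(components)
  unknown <- setdiff(components, design$factors$name)
  if (length(unknown)) {
    stop("unknown factor(s) in term: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  idx <- sort(match(components, design$factors$name))
  paste(design$factors$name[idx], collapse = ":")
}

#' @rdname term_spec
#' @param term Canonical term string.
#' @export
term_components <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

#' @rdname term_spec
#' @export
term_order <- function(term) lengths(strsplit(term, ":", fixed = TRUE))

#' All factorial terms of a design up to a given interaction order
#'
#' @param design A `factorial_design`.
#' @param max_order Highest interaction order to include (default: k, i.e.
#'   all 2^k - 1 terms).
#' @return Character vector of canonical term strings, ordered by interaction
#'   order, then lexicographically by component position.
#' @export
all_terms <- function(design, max_order = design$k) {
  nm <- design$factors$name
  unlist(lapply(seq_len(min(max_order, design$k)), function(m) {
    apply(utils::combn(nm, m), 2, paste, collapse = ":")
  }), use.names = FALSE)
}

#' Build the effect-coded model matrix for a list of terms
#'
#' Interaction columns are elementwise products of their components' main
#' effect code columns.
#'
#' @param codes Matrix of ±1 main-effect codes, one column per factor, with
#'   column names.
#' @param terms Character vector of term strings (see [term_spec()]).
#' @return Numeric matrix with one column per term, in the supplied order.
#' @export
build_model_matrix <- function(codes, terms) {
  codes <- as.matrix(codes)
  out <- matrix(NA_real_, nrow(codes), length(terms),
                dimnames = list(NULL, terms))
  for (i in seq_along(terms)) {
    comps <- term_components(terms[i])
    unknown <- setdiff(comps, colnames(codes))
    if (length(unknown)) {
      stop("term '", terms[i], "' references unknown factor(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    col <- rep(1, nrow(codes))
    for (cm in comps) col <- col * codes[, cm]
    out[, i] <- col
  }
  out
}

# ---- sample size and randomization ----------------------------------------

#' Screening-experiment sample size
#'
#' Normal-approximation sample size for detecting a standardized main-effect
#' difference `d` between the two levels of a component in a balanced
#' two-level factorial screening experiment: per-level
#' n = ceil(2 (z_{1-alpha/2} + z_{power})^2 / d^2), analysis n = 2 x per-level
#' n, and a recruitment n inflated for expected unusable responses by
#' nearest-integer division by (1 - attrition_rate).
#'
#' @param effect_size_d Standardized mean difference to detect (> 0).
#' @param power Target power (0, 1).
#' @param alpha Two-sided significance level (0, 1).
#' @param attrition_rate Expected fraction of unusable responses [0, 1).
#' @return List with `n_per_level`, `n_analysis`, `n_recruit`.
#' @examples
#' required_sample_size(0.15, 0.9, 0.1)            # n_analysis 1524
#' required_sample_size(0.15, 0.9, 0.1, 0.05)      # n_recruit 1604
#' @export
required_sample_size <- function(effect_size_d, power, alpha,
                                 attrition_rate = 0) {
  stopifnot(effect_size_d > 0, power > 0, power < 1, alpha > 0, alpha < 1,
            attrition_rate >= 0, attrition_rate < 1)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n_per_level <- ceiling(2 * z^2 / effect_size_d^2)
  n_analysis <- 2L * as.integer(n_per_level)
  n_recruit <- as.integer(round(n_analysis / (1 - attrition_rate)))
  list(n_per_level = as.integer(n_per_level), n_analysis = n_analysis,
       n_recruit = n_recruit)
}

#' Simple randomization to experimental conditions
#'
#' Each participant is independently assigned a uniform draw over the
#' condition ids; per-condition counts are not constrained (simple, not
#' blocked, randomization).
#'
#' @param n_participants Number of participants (>= 1).
#' @param n_conditions Number of conditions (>= 1).
#' @param seed Integer seed; the same seed reproduces the same assignment.
#' @return Integer vector of condition ids, length `n_participants`.
#' @export
randomize <- function(n_participants, n_conditions, seed) {
  stopifnot(n_participants >= 1, n_conditions >= 1)
  with_seed(seed, sample.int(n_conditions, n_participants, replace = TRUE))
}
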