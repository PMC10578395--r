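test_that("condition enumeration covers every level combination exactly once", {
  expect_equal(nrow(abc_design(1)$conditions), 2L)
  expect_equal(abc_design(1)$conditions$a, c("on", "off"))

  des3 <- abc_design(3)
  expect_equal(nrow(des3$conditions), 8L)
  combos <- unique(des3$conditions[c("a", "b", "c")])
  expect_equal(nrow(combos), 8L)  # exhaustive, no duplicates

  expect_equal(nrow(aet_design()$conditions), 32L)
  expect_error(enumerate_conditions(list(factor_def("x"), factor_def("x"))),
               "duplicate")
})

test_that("condition numbering puts all-high first with the last factor varying fastest", {
  des <- aet_design()
  codes <- design_codes(des)
  # independent oracle: digit j of (id - 1) in base 2, most significant
  # digit = first factor, digit 1 -> low level
  for (id in c(1, 2, 5, 16, 21, 29, 32)) {
    q <- id - 1
    expected <- integer(5)
    for (j in 5:1) {
      expected[j] <- if (q %% 2 == 1) -1L else 1L
      q <- q %/% 2
    }
    expect_equal(unname(codes[id, ]), expected)
  }
  # printed condition table patterns
  cond <- des$conditions
  expect_equal(unname(unlist(cond[1, 2:6])),
               c("Yes", "Enhanced", "Enhanced", "Yes", "Yes"))
  expect_equal(unname(unlist(cond[16, 2:6])),
               c("Yes", "Basic", "Basic", "No", "No"))
  expect_equal(unname(unlist(cond[21, 2:6])),
               c("No", "Enhanced", "Basic", "Yes", "Yes"))
  expect_equal(unname(unlist(cond[32, 2:6])),
               c("No", "Basic", "Basic", "No", "No"))
  # numbering round-trips through the codes
  expect_equal(condition_id_from_codes(des, codes), 1:32)
})

test_that("effect coding maps high to +1, low to -1, and is balanced", {
  des <- aet_design()
  all_high <- setNames(des$factors$high_label, des$factors$name)
  expect_equal(unname(effect_code(des, all_high)), rep(1, 5))
  expect_equal(unname(effect_code(des, 16)), c(1, -1, -1, -1, -1))
  bad <- all_high
  bad["diagrams"] <- "Maybe"
  expect_error(effect_code(des, bad), "unknown level")
  expect_equal(unname(colSums(design_codes(des))), rep(0, 5))
})

test_that("model matrix columns are term products and mutually orthogonal", {
  des <- aet_design()
  codes <- design_codes(des)
  M <- build_model_matrix(codes, all_terms(des))
  expect_equal(ncol(M), 31L)
  # interaction = product of main-effect columns at every row
  expect_equal(M[, "diagrams:benefits"],
               codes[, "diagrams"] * codes[, "benefits"])
  expect_equal(
    M[, "diagrams:benefits:side_effects:concerns:patient_input"],
    apply(codes, 1, prod))
  X <- cbind(1, M)
  expect_equal(unname(crossprod(X)), 32 * diag(32))
  expect_error(build_model_matrix(codes, "diagrams:nonexistent"),
               "unknown factor")
})

test_that("screening sample size reproduces the planned study numbers", {
  ss <- required_sample_size(0.15, 0.9, 0.1)
  expect_identical(ss$n_analysis, 1524L)
  expect_identical(required_sample_size(0.15, 0.9, 0.1, 0.05)$n_recruit,
                   1604L)
  # doubling d quarters the unrounded per-level n
  unrounded <- 2 * (qnorm(0.95) + qnorm(0.9))^2 / 0.15^2
  expect_identical(required_sample_size(0.30, 0.9, 0.1)$n_per_level,
                   as.integer(ceiling(unrounded / 4)))
  expect_error(required_sample_size(0, 0.9, 0.1))
})

test_that("sample size is monotone in effect size, alpha and power", {
  grid <- expand.grid(d = c(0.1, 0.15, 0.2), alpha = c(0.05, 0.1),
                      power = c(0.8, 0.9))
  n_of <- function(g) required_sample_size(g$d, g$power, g$alpha)$n_analysis
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_gte(n_of(g), n_of(transform(g, d = d * 1.5)))
    expect_gte(n_of(g), n_of(transform(g, alpha = alpha * 1.5)))
    expect_lte(n_of(g), n_of(transform(g, power = power + 0.05)))
  }
})

test_that("simple randomization is reproducible, unconstrained, and uniform", {
  expect_identical(randomize(100, 32, seed = 11), randomize(100, 32, seed = 11))
  expect_false(identical(randomize(1000, 32, 1), randomize(1000, 32, 2)))
  # simple (not blocked): with n = k the counts need not all be one
  counts <- table(randomize(32, 32, seed = 3))
  expect_true(length(counts) < 32 || any(counts != 1))
  # goodness of fit: uniformity rejected in roughly alpha of seeded draws
  reps <- 1000
  rejected <- vapply(seq_len(reps), function(s) {
    cond <- randomize(1603, 32, seed = s)
    obs <- tabulate(cond, nbins = 32)
    suppressWarnings(chisq.test(obs)$p.value) < 0.05
  }, logical(1))
  rate <- mean(rejected)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})
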