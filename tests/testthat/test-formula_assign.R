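test_that("enumeration finds the known composition and nothing spurious at tiny bounds", {
  b <- element_bounds(C = c(0, 20), H = c(0, 30), N = c(0, 6), O = c(0, 10),
                      S = NULL, P = NULL)
  cand <- enumerate_formulas(194.080376, 2, b)
  expect_true("C8H10N4O2" %in% cand$formula)
  tiny <- enumerate_formulas(18.010565, 2,
                             element_bounds(C = c(0, 2), H = c(0, 6), N = c(0, 2),
                                            O = c(0, 2), S = NULL, P = NULL))
  expect_equal(tiny$formula, "H2O")
  expect_error(enumerate_formulas(-5.0, 2), "positive")
  expect_error(enumerate_formulas(100, 2, max_combinations = 10), "combinations")
})

test_that("enumeration matches the exhaustive oracle on random small instances", {
  set.seed(31)
  for (i in 1:100) {
    bounds <- element_bounds(C = c(0, sample(5:14, 1)), H = c(0, sample(8:24, 1)),
                             N = c(0, sample(0:3, 1)), O = c(0, sample(0:5, 1)),
                             S = NULL, P = NULL)
    mass <- stats::runif(1, 40, 250)
    tol <- sample(c(2, 5, 50, 500), 1)
    got <- sort(enumerate_formulas(mass, tol, bounds)$formula)
    want <- oracle_enumerate(mass, tol, bounds)
    expect_identical(got, want, label = sprintf("mass %.4f tol %g", mass, tol))
  }
})

test_that("every candidate satisfies the tolerance, recomputed independently", {
  set.seed(37)
  for (i in 1:20) {
    comp <- random_composition()
    target <- monoisotopic_mass(comp) * (1 + stats::runif(1, -1.5e-6, 1.5e-6))
    cand <- enumerate_formulas(target, 2)
    expect_gt(nrow(cand), 0)
    for (j in seq_len(nrow(cand))) {
      err <- abs(monoisotopic_mass(cand$formula[j]) - target) / target * 1e6
      expect_lte(err, 2 + 1e-9)
    }
    expect_equal(cand$rank, seq_len(nrow(cand)))
    expect_true(!is.unsorted(abs(cand$ppm_error)))
  }
})

test_that("self-recovery: each composition is found at its own mass", {
  set.seed(41)
  for (i in 1:150) {
    comp <- random_composition()
    cand <- enumerate_formulas(monoisotopic_mass(comp), 2)
    expect_true(format_formula(comp) %in% cand$formula, label = format_formula(comp))
  }
})

test_that("the candidate set grows monotonically with tolerance", {
  set.seed(43)
  for (i in 1:10) {
    comp <- random_composition()
    mass <- monoisotopic_mass(comp)
    s1 <- enumerate_formulas(mass, 2)$formula
    s2 <- enumerate_formulas(mass, 10)$formula
    expect_true(all(s1 %in% s2))
  }
})

test_that("peak assignment converts m/z through the adduct and flags failures", {
  b <- element_bounds(C = c(0, 20), H = c(0, 30), N = c(0, 6), O = c(0, 10),
                      S = NULL, P = NULL)
  res <- assign_peaks(tibble::tibble(mz = 195.087652), bounds = b)
  expect_equal(res$formula, "C8H10N4O2")
  expect_true(res$assigned)
  expect_equal(res$theoretical_mz, 195.087652, tolerance = 1e-8)

  expect_error(assign_peaks(tibble::tibble(mz = 0.5)), "below the mass")
  expect_error(assign_peaks(tibble::tibble(mz = -1)), "positive")
  expect_error(assign_peaks(tibble::tibble(mz = 100), adduct = "[M+2H]2+"),
               "unsupported adduct")

  empty <- assign_peaks(tibble::tibble(mz = numeric()), bounds = b)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("formula", "ppm_error", "n_candidates") %in% names(empty)))

  # no candidate in a deliberately impossible window: flagged, not dropped
  none <- assign_peaks(tibble::tibble(mz = 195.087652),
                       bounds = element_bounds(C = c(1, 2), H = c(0, 4), N = NULL,
                                               O = NULL, S = NULL, P = NULL))
  expect_false(none$assigned)
  expect_equal(none$n_candidates, 0L)
})

test_that("bounds strings parse into element bounds", {
  b <- parse_bounds("C0-70H0-120N0-6O0-35")
  expect_equal(b$C, c(0L, 70L))
  expect_equal(b$O, c(0L, 35L))
  expect_null(b$S)
  expect_error(parse_bounds("C0-70 junk"), "cannot parse")
  expect_error(element_bounds(C = c(5, 2)), "min <= max")
})
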