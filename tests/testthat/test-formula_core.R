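test_that("formula parsing transcribes stoichiometry and rejects bad input", {
  expect_equal(parse_formula("C15H10O7"), c(C = 15L, H = 10L, O = 7L))
  expect_equal(parse_formula("C8H10N4O2"), c(C = 8L, H = 10L, N = 4L, O = 2L))
  expect_equal(parse_formula("H2O"), c(H = 2L, O = 1L))
  # order-insensitive
  expect_equal(parse_formula("O7C15H10"), parse_formula("C15H10O7"))
  expect_error(parse_formula("C15H10O7X"), "unknown element")
  expect_error(parse_formula("C0H4"), "zero count")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("c6h6"), "cannot parse|unknown")
})

test_that("Hill formatting puts C then H then alphabetical, omitting count 1", {
  expect_equal(format_formula(c(C = 8, H = 10, N = 4, O = 2)), "C8H10N4O2")
  expect_equal(format_formula(c(H = 2, O = 1)), "H2O")
  expect_equal(format_formula(c(C = 30, H = 50, O = 1)), "C30H50O")
  expect_equal(format_formula(c(O = 2, N = 4, H = 10, C = 8)), "C8H10N4O2")
})

test_that("parse/format round-trips on random compositions", {
  set.seed(101)
  for (i in 1:1000) {
    comp <- random_composition()
    expect_identical(parse_formula(format_formula(comp)), element_composition(comp))
  }
})

test_that("monoisotopic masses match independent summation", {
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-5 / 18)
  expect_equal(monoisotopic_mass("C8H10N4O2"), 194.080376, tolerance = 1e-5 / 194)
  # protonated caffeine m/z, electron mass included
  expect_equal(monoisotopic_mass("C8H11N4O2", charge = 1), 195.087652,
               tolerance = 1e-5 / 195)
  expect_error(element_composition(integer(0)), "non-empty|at least one")
})

test_that("mass is additive over compositions", {
  set.seed(7)
  for (i in 1:50) {
    a <- random_composition()
    b <- random_composition()
    ab <- tapply(c(a, b), names(c(a, b)), sum)
    expect_equal(monoisotopic_mass(element_composition(ab)),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-9 / 100)
  }
})

test_that("neutralize inverts every supported adduct", {
  m <- parse_formula("C8H10N4O2")
  for (adduct in supported_adducts()) {
    ion <- ion_species(m, adduct)
    expect_identical(neutralize(ion), m, label = adduct)
  }
  # spec'd cases
  expect_equal(neutralize(list(composition = c(C = 8L, H = 16L, N = 1L),
                               adduct_label = "[M+H]+")),
               c(C = 8L, H = 15L, N = 1L))
  expect_equal(neutralize(list(composition = c(C = 5L, H = 11L, N = 1L),
                               adduct_label = "[M]")),
               c(C = 5L, H = 11L, N = 1L))
  expect_error(neutralize(list(composition = c(C = 1L), adduct_label = "[M+H]+")),
               "no H to remove")
  expect_error(ion_species("C8H10N4O2", "[M+2H]2+"), "unsupported adduct")
})

test_that("m/z round-trips through adduct application", {
  for (adduct in setdiff(supported_adducts(), "[M]")) {
    mz <- adduct_mz("C15H10O7", adduct)
    expect_equal(neutral_mass_from_mz(mz, adduct), monoisotopic_mass("C15H10O7"),
                 tolerance = 1e-12, label = adduct)
  }
  expect_error(adduct_mz("C15H10O7", "[M]"), "no m/z")
})
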