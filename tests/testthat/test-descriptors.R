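test_that("elemental ratios match hand arithmetic and guard against C == 0", {
  expect_equal(elemental_ratios("C15H10O7"), c(hc = 10 / 15, oc = 7 / 15),
               tolerance = 1e-3)
  expect_equal(elemental_ratios("C30H50O"), c(hc = 50 / 30, oc = 1 / 30),
               tolerance = 1e-3)
  expect_error(elemental_ratios("H2O"), "without carbon")
})

test_that("DBE reproduces canonical scaffold values", {
  cases <- list(
    list("C8H15N", 2),    # tropane bicyclic core
    list("C5H11N", 1),    # piperidine
    list("C14H12", 9),    # trans-stilbene
    list("C9H6O2", 7),    # coumarin
    list("C15H10O7", 11), # quercetin
    list("C7H6O5", 5),    # gallic acid
    list("C8H10N4O2", 6), # caffeine
    list("C14H8O2", 11),  # anthraquinone
    list("C30H50O", 6),   # lupeol
    list("C1H4", 0)       # methane
  )
  for (case in cases) expect_equal(dbe(case[[1]]), case[[2]], label = case[[1]])
  # protonated single-nitrogen ion composition gives a half-integer
  expect_equal(dbe("C8H16N"), 1.5)
})

test_that("DBE responds to structural increments as unsaturation bookkeeping demands", {
  set.seed(11)
  for (i in 1:100) {
    comp <- random_composition()
    d <- dbe(comp)
    expect_true(d >= 0 && abs(2 * d - round(2 * d)) < 1e-9)
    add <- function(delta) {
      v <- tapply(c(comp, delta), names(c(comp, delta)), sum)
      element_composition(v[v > 0])
    }
    # O and S neutral
    expect_equal(dbe(add(c(O = 1))), d)
    expect_equal(dbe(add(c(S = 1))), d)
    # +C2H2 ring/double-bond unit: +1; +H2 saturation: -1
    expect_equal(dbe(add(c(C = 2, H = 2))), d + 1)
    expect_equal(dbe(add(c(H = 2))), d - 1)
    # one glycosyl unit adds exactly one ring
    expect_equal(dbe(add(c(C = 6, H = 10, O = 5))), d + 1)
  }
})

test_that("modified aromaticity index is clamped and hits known anchors", {
  expect_equal(ai_mod("C6H6"), 2 / 3, tolerance = 1e-3)
  expect_equal(ai_mod("C6H14"), 0)
  expect_equal(ai_mod("H2O"), 0)  # non-positive denominator guard
  set.seed(13)
  for (i in 1:200) {
    comp <- random_composition()
    v <- ai_mod(comp)
    expect_true(v >= 0 && v <= 1)
  }
  # fully saturated acyclic CH chains
  for (nc in c(1, 4, 10)) {
    expect_equal(ai_mod(c(C = nc, H = 2 * nc + 2)), 0)
  }
})

test_that("descriptor profile bundles all fields and records the convention", {
  p <- descriptor_profile("C15H10O7")
  expect_equal(p$dbe, 11)
  expect_equal(p$hc, 2 / 3, tolerance = 1e-3)
  expect_equal(p$oc, 7 / 15, tolerance = 1e-3)
  expect_equal(p$c, 15)
  expect_equal(p$dbe_convention, "neutral")
  p2 <- descriptor_profile("C8H10N4O2")
  expect_equal(p2$dbe, 6)
  expect_equal(p2$n, 4)
  p3 <- descriptor_profile("C8H16N", convention = "ion")
  expect_equal(p3$dbe, 1.5)
  expect_equal(p3$dbe_convention, "ion")
})

test_that("table descriptor computation isolates per-row parse failures", {
  tab <- compute_descriptors(tibble::tibble(formula = c("C15H10O7", "notaformula", "CH4")))
  expect_equal(tab$parse_ok, c(TRUE, FALSE, TRUE))
  expect_equal(tab$dbe, c(11, NA, 0))
  empty <- compute_descriptors(tibble::tibble(formula = character()))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("hc", "oc", "dbe", "ai_mod") %in% names(empty)))
})
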