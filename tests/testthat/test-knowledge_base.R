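test_that("built-in KB carries the printed range windows verbatim", {
  kb <- default_kb()
  get <- function(name) kb[kb$name == name, ]
  fl <- get("flavonoid")
  expect_equal(c(fl$oc_min, fl$oc_max), c(0.133, 0.750))
  expect_equal(c(fl$hc_min, fl$hc_max), c(0.600, 1.692))
  expect_equal(c(fl$dbe_min, fl$dbe_max), c(7, 20))
  ta <- get("tannin")
  expect_equal(c(ta$hc_min, ta$hc_max), c(0.519, 0.917))
  expect_equal(c(ta$oc_min, ta$oc_max), c(0.370, 0.500))
  expect_equal(c(ta$dbe_min, ta$dbe_max), c(14, 37))
  sa <- get("saponin")
  expect_equal(c(sa$oc_min, sa$oc_max), c(0.074, 0.518))
  tr <- get("triterpene")
  expect_equal(c(tr$c_min, tr$c_max), c(30, 30))
  iq <- get("isoquinoline")
  expect_equal(c(iq$hc_min, iq$hc_max), c(0.44, 1.38))
  expect_equal(c(iq$oc_min, iq$oc_max), c(0.00, 0.33))
})

test_that("KB invariants hold: unique names, three groups, nitrogen flags, min <= max", {
  kb <- default_kb()
  expect_equal(anyDuplicated(kb$name), 0)
  expect_setequal(unique(kb$group), c("phenolic", "nitrogenous", "isoprenoid"))
  expect_true(all(kb$requires_nitrogen == (kb$group == "nitrogenous")))
  for (ax in c("hc", "oc", "dbe", "c")) {
    lo <- kb[[paste0(ax, "_min")]]; hi <- kb[[paste0(ax, "_max")]]
    expect_true(all(is.na(lo) | lo <= hi))
    expect_identical(is.na(lo), is.na(hi))
  }
  # derived windows exist for classes with no printed ratios
  expect_equal(kb$hc_prov[kb$name == "coumarin"], "derived")
  expect_false(anyNA(kb$hc_min))
  expect_false(anyNA(kb$oc_min))
})

test_that("JSON serialization round-trips losslessly including provenance", {
  kb <- default_kb()
  path <- withr::local_tempfile(fileext = ".json")
  save_kb(kb, path)
  kb2 <- load_kb(path)
  expect_equal(tibble::as_tibble(kb2), tibble::as_tibble(kb))
  expect_equal(attr(kb2, "version"), attr(kb, "version"))
  expect_equal(kb2$dbe_prov, kb$dbe_prov)
  expect_equal(kb2$hc_prov, kb$hc_prov)
})

test_that("loading rejects schema violations with field paths", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"version": "1", "classes": [
    {"name": "x", "group": "phenolic",
     "bounds": {"dbe": {"min": 10, "max": 9}}, "requires_nitrogen": false}
  ]}', path)
  expect_error(load_kb(path), "min 10 > max 9")

  writeLines('{"version": "1", "source": "t"}', path)
  expect_error(load_kb(path), "missing top-level 'classes'")

  writeLines('{"version": "1", "classes": [
    {"name": "a", "group": "phenolic", "bounds": {"dbe": {"min": 1, "max": 2}},
     "requires_nitrogen": false},
    {"name": "a", "group": "phenolic", "bounds": {"dbe": {"min": 1, "max": 2}},
     "requires_nitrogen": false}
  ]}', path)
  expect_error(load_kb(path), "duplicate class name")

  writeLines("{not json", path)
  expect_error(load_kb(path), "malformed JSON")
})

test_that("overlap diagnostics flag converging windows within groups", {
  diag <- validate_kb(default_kb())
  fl_li <- diag[diag$axis == "dbe" &
                ((diag$class_a == "flavonoid" & diag$class_b == "lignan") |
                 (diag$class_a == "lignan" & diag$class_b == "flavonoid")), ]
  expect_equal(nrow(fl_li), 1)
  expect_equal(c(fl_li$overlap_min, fl_li$overlap_max), c(8, 17))
  expect_equal(fl_li$overlap_fraction, 1)  # lignan window nested in flavonoid's
  tr_st <- diag[diag$axis == "hc" &
                ((diag$class_a == "triterpene" & diag$class_b == "steroid") |
                 (diag$class_a == "steroid" & diag$class_b == "triterpene")), ]
  expect_equal(nrow(tr_st), 1)
  expect_equal(c(tr_st$overlap_min, tr_st$overlap_max), c(1.154, 1.704))
  # cross-group pairs are never reported
  expect_true(all(diag$group %in% c("phenolic", "nitrogenous", "isoprenoid")))
})

test_that("single-class KB yields no overlap warnings", {
  kb <- default_kb()
  one <- kb[kb$name == "flavonoid", ]
  expect_equal(nrow(validate_kb(one)), 0)
})

test_that("tidy and glance summarise the KB", {
  kb <- default_kb()
  long <- tidy(kb)
  expect_setequal(unique(long$axis), c("hc", "oc", "dbe", "c"))
  expect_true(all(long$provenance %in% c("paper", "derived")))
  g <- glance(kb)
  expect_equal(g$n_classes, 20)
  expect_equal(g$n_bounds, nrow(long))
})
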