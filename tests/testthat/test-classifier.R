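kb <- default_kb()

test_that("membership score is 1 inside all windows and decays outside", {
  quercetin <- descriptor_profile("C15H10O7")
  fl <- kb[kb$name == "flavonoid", ]
  expect_equal(membership_score(quercetin, fl), 1.0)
  tr <- kb[kb$name == "triterpene", ]
  # hard membership: only DBE (11 in 5-12) inside of the four axes
  hard <- classifier_options(sigma_ratio = 0, sigma_dbe = 0, sigma_carbon = 0)
  expect_equal(membership_score(quercetin, tr, hard), 0.25)
  expect_lt(membership_score(quercetin, tr), 0.5)
  lupeol <- descriptor_profile("C30H50O")
  expect_equal(membership_score(lupeol, tr), 1.0)
  # scores bounded in [0, 1]
  for (i in seq_len(nrow(kb))) {
    s <- membership_score(quercetin, kb[i, ])
    expect_true(s >= 0 && s <= 1)
  }
})

test_that("classify ranks the expected top candidates for canonical compounds", {
  expect_equal(classify(descriptor_profile("C8H10N4O2"), kb)$candidates$class[1], "purine")
  expect_equal(classify(descriptor_profile("C30H50O"), kb)$candidates$class[1], "triterpene")
  expect_equal(classify(descriptor_profile("C15H10O7"), kb)$candidates$class[1], "flavonoid")
  a <- classify(descriptor_profile("C1H4"), kb)
  expect_equal(nrow(a$candidates), 0)
  expect_false(is.na(a$unclassified_reason))
  expect_equal(a$msi_level, "3")
})

test_that("half-integer DBE under the ion convention restricts to alkaloid classes", {
  ion <- descriptor_profile("C8H16N", convention = "ion")  # protonated tropane
  a <- classify(ion, kb, classifier_options(min_score = 0))
  expect_true(all(a$candidates$group == "nitrogenous"))
  # same arithmetic under the neutral convention carries no such restriction
  neut <- descriptor_profile("C8H16N", convention = "neutral")
  b <- classify(neut, kb, classifier_options(min_score = 0, strict_nitrogen = FALSE))
  expect_true(length(unique(b$candidates$group)) >= 1)
})

test_that("nitrogen gate blocks cross-group annotation in strict mode", {
  set.seed(23)
  for (i in 1:50) {
    comp <- random_composition()
    ann <- classify(descriptor_profile(comp), kb)
    if (nrow(ann$candidates) == 0) next
    if ("N" %in% names(comp)) {
      expect_true(all(ann$candidates$group == "nitrogenous"),
                  label = format_formula(comp))
    } else {
      expect_true(all(ann$candidates$group != "nitrogenous"),
                  label = format_formula(comp))
    }
  }
})

test_that("classify_table annotates canonical fixtures and isolates failures", {
  tab <- classify_table(tibble::tibble(formula = c("C15H10O7", "C30H50O", "C8H10N4O2")))
  expect_equal(tab$top1_class, c("flavonoid", "triterpene", "purine"))
  expect_equal(tab$top1_score, rep(1, 3))
  expect_equal(unique(tab$msi_level), "3")

  mixed <- classify_table(tibble::tibble(formula = c("C15H10O7", "notaformula")))
  expect_equal(mixed$parse_ok, c(TRUE, FALSE))
  expect_equal(mixed$top1_class, c("flavonoid", NA))
  expect_match(mixed$flags[2], "parse_error")

  empty <- classify_table(tibble::tibble(formula = character()))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("top1_class", "candidates", "msi_level") %in% names(empty)))

  expect_error(classify_table(tibble::tibble(formula = c("bad1", "bad2"))),
               "no input row could be parsed")
})

test_that("classification is deterministic", {
  tab <- tibble::tibble(formula = c("C15H10O7", "C30H50O", "C8H10N4O2", "C9H6O2",
                                    "C20H24N2O2", "C27H46O"))
  a <- classify_table(tab, kb)
  b <- classify_table(tab, kb)
  expect_identical(a, b)
})

test_that("window-sampled synthetic formulas always score 1 for their true class", {
  classes <- c("flavonoid", "tannin", "isoquinoline", "steroid", "saponin")
  for (cl in classes) {
    recs <- generate_class_formulas(cl, 10, seed = 99, kb = kb)
    ann <- classify_table(recs, kb, opts = classifier_options(top_k = 20, min_score = 0.999))
    for (i in seq_len(nrow(ann))) {
      expect_match(ann$candidates[i], cl, label = paste(cl, ann$formula[i]))
    }
  }
})
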