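# Range-membership classifier: scores a descriptor profile against every
# class window in the knowledge base, applies nitrogen gating and the
# half-integer-DBE alkaloid diagnostic, and ranks candidates with
# DBE-midpoint tie-breaking (DBE is the primary discriminator).

#' Classifier options
#'
#' @param top_k Maximum number of candidate classes to report.
#' @param min_score Minimum membership score for a candidate to be reported.
#' @param strict_nitrogen When `TRUE` (default), nitrogen-free profiles can
#'   never match an alkaloid class and nitrogen-containing profiles can never
#'   match a non-nitrogenous class. When `FALSE`, such matches are demoted
#'   (score halved) rather than excluded, reflecting that plant extracts
#'   contain nitrogenous primary metabolites.
#' @param sigma_ratio Softness (in ratio units) of the boundary for H/C and
#'   O/C axes: outside a window, per-axis membership decays as
#'   `exp(-distance/sigma)`.
#' @param sigma_dbe Softness for the DBE axis, in DBE units.
#' @param sigma_carbon Softness for the carbon-count axis, in atoms.
#'   Set all three sigmas to 0 for hard interval membership.
#' @return A list of options for [classify()].
#' @export
classifier_options <- function(top_k = 3L, min_score = 0.5, strict_nitrogen = TRUE,
                               sigma_ratio = 0.1, sigma_dbe = 1.0, sigma_carbon = 2.0) {
  stopifnot(top_k >= 1, min_score >= 0, min_score <= 1,
            sigma_ratio >= 0, sigma_dbe >= 0, sigma_carbon >= 0)
  list(top_k = as.integer(top_k), min_score = min_score,
       strict_nitrogen = isTRUE(strict_nitrogen),
       sigma_ratio = sigma_ratio, sigma_dbe = sigma_dbe, sigma_carbon = sigma_carbon)
}

# per-axis membership: 1 inside the window, exp(-d/sigma) outside
# (0 outside when sigma == 0)
.axis_membership <- function(value, lo, hi, sigma) {
  if (value >= lo && value <= hi) return(1)
  d <- if (value < lo) lo - value else value - hi
  if (sigma <= 0) 0 else exp(-d / sigma)
}

#' Membership score of a profile in one class window
#'
#' The mean, over the class's defined axes (H/C, O/C, DBE, carbon count),
#' of per-axis membership: 1 inside the window, decaying exponentially with
#' distance outside it. The score is forced to 0 (strict mode) when the
#' nitrogen gate fails: the class requires nitrogen but the profile has
#' none, or the profile contains nitrogen and the class is not nitrogenous.
#'
#' @param desc One-row descriptor tibble from [descriptor_profile()] (or any
#'   list with `hc, oc, dbe, c, n`).
#' @param cdef One row of a `vk_kb` knowledge base.
#' @param opts Options from [classifier_options()].
#' @return Score in \[0, 1\]; exactly 1 iff inside every defined window.
#' @export
#' @examples
#' membership_score(descriptor_profile("C15H10O7"),
#'                  dplyr::filter(default_kb(), name == "flavonoid"))
membership_score <- function(desc, cdef, opts = classifier_options()) {
  values <- c(hc = desc$hc, oc = desc$oc, dbe = desc$dbe, c = desc$c)
  sigmas <- c(hc = opts$sigma_ratio, oc = opts$sigma_ratio,
              dbe = opts$sigma_dbe, c = opts$sigma_carbon)
  memb <- numeric(0)
  for (ax in .kb_axes) {
    lo <- cdef[[paste0(ax, "_min")]]; hi <- cdef[[paste0(ax, "_max")]]
    if (is.na(lo)) next
    memb[ax] <- .axis_membership(values[[ax]], lo, hi, sigmas[[ax]])
  }
  if (length(memb) == 0) {
    stop("class '", cdef$name, "' defines no axes; cannot score", call. = FALSE)
  }
  score <- mean(memb)
  gate_fails <- (isTRUE(cdef$requires_nitrogen) && desc$n == 0) ||
    (desc$n >= 1 && cdef$group != "nitrogenous")
  if (gate_fails) score <- if (opts$strict_nitrogen) 0 else score / 2
  score
}

#' Classify one descriptor profile
#'
#' Scores the profile against every class, ranks candidates by score with
#' deterministic tie-breaking (smaller distance of the profile's DBE to the
#' class DBE midpoint, then smaller distance of the carbon count to the
#' class carbon midpoint, then class name), and reports up to `top_k`
#' candidates at or above `min_score`. A half-integer DBE under the ion
#' convention restricts eligibility to the nitrogenous group, since
#' noninteger DBE values of protonated single-nitrogen species are not
#' observed in any other compound class. Annotation confidence is MSI
#' Level 3 (compound class, not identity) by construction.
#'
#' @param desc One-row descriptor tibble from [descriptor_profile()].
#' @param kb A `vk_kb` knowledge base.
#' @param opts Options from [classifier_options()].
#' @return A `vk_annotation` list: `candidates` (tibble with `class, score,
#'   rank` and per-axis membership flags), `msi_level` (always `"3"`),
#'   `rationale` (character lines), `unclassified_reason` (`NA` when
#'   classified).
#' @export
#' @examples
#' classify(descriptor_profile("C8H10N4O2"), default_kb())
classify <- function(desc, kb, opts = classifier_options()) {
  stopifnot(inherits(kb, "vk_kb"))
  if (nrow(kb) == 0) stop("empty knowledge base", call. = FALSE)
  half_integer <- is.finite(desc$dbe) && abs(desc$dbe %% 1 - 0.5) < 1e-9
  ion_half <- half_integer && identical(desc$dbe_convention, "ion")
  rationale <- character(0)
  if (ion_half) {
    rationale <- c(rationale,
                   "half-integer DBE under the ion convention: eligibility restricted to alkaloid classes")
  }
  rows <- list()
  for (i in seq_len(nrow(kb))) {
    cdef <- kb[i, ]
    if (ion_half && cdef$group != "nitrogenous") next
    score <- membership_score(desc, cdef, opts)
    inside <- vapply(.kb_axes, function(ax) {
      lo <- cdef[[paste0(ax, "_min")]]
      if (is.na(lo)) return(NA)
      desc[[ax]] >= lo && desc[[ax]] <= cdef[[paste0(ax, "_max")]]
    }, logical(1))
    mid_dbe <- if (is.na(cdef$dbe_min)) Inf else abs(desc$dbe - (cdef$dbe_min + cdef$dbe_max) / 2)
    mid_c <- if (is.na(cdef$c_min)) Inf else abs(desc$c - (cdef$c_min + cdef$c_max) / 2)
    rows[[length(rows) + 1]] <- tibble::tibble(
      class = cdef$name, group = cdef$group, score = score,
      in_hc = inside[["hc"]], in_oc = inside[["oc"]],
      in_dbe = inside[["dbe"]], in_c = inside[["c"]],
      dbe_mid_dist = mid_dbe, c_mid_dist = mid_c
    )
  }
  scored <- dplyr::bind_rows(rows)
  scored <- scored[order(-scored$score, scored$dbe_mid_dist, scored$c_mid_dist, scored$class), ]
  cand <- scored[scored$score >= opts$min_score, , drop = FALSE]
  cand <- utils::head(cand, opts$top_k)
  unclassified_reason <- NA_character_
  if (nrow(cand) == 0) {
    unclassified_reason <- if (desc$n >= 1) {
      "nitrogenous, no alkaloid window matched (possibly an amino acid or other primary metabolite)"
    } else {
      "no class window matched at the requested minimum score"
    }
    rationale <- c(rationale, unclassified_reason)
  } else {
    rationale <- c(rationale, sprintf(
      "%s: score %.3f (axes inside: %s)", cand$class[1], cand$score[1],
      paste(stats::na.omit(c(
        if (isTRUE(cand$in_hc[1])) "H/C", if (isTRUE(cand$in_oc[1])) "O/C",
        if (isTRUE(cand$in_dbe[1])) "DBE", if (isTRUE(cand$in_c[1])) "C"
      )), collapse = ", ")))
  }
  cand$rank <- seq_len(nrow(cand))
  structure(
    list(
      candidates = cand[, c("class", "group", "score", "rank",
                            "in_hc", "in_oc", "in_dbe", "in_c")],
      msi_level = "3",
      rationale = rationale,
      unclassified_reason = unclassified_reason
    ),
    class = "vk_annotation"
  )
}

#' @export
print.vk_annotation <- function(x, ...) {
  cat("<class annotation, MSI level", x$msi_level, ">\n")
  if (nrow(x$candidates) == 0) {
    cat("unclassified:", x$unclassified_reason, "\n")
  } else {
    print(x$candidates)
  }
  invisible(x)
}

#' Annotate a table of molecular formulas with candidate classes
#'
#' The main batch entry point: parses each formula, computes the full
#' descriptor set, classifies against the knowledge base and returns one
#' annotated row per input row. Rows that fail to parse are flagged
#' (`parse_ok == FALSE`) and carry `NA` annotations; only an all-rows-failed
#' input is an error. Output is deterministic given identical input, KB and
#' options.
#'
#' @param data Data frame with a formula column.
#' @param kb A `vk_kb` knowledge base (default [default_kb()]).
#' @param formula_col Name of the formula column.
#' @param convention DBE convention, `"neutral"` (default) or `"ion"`.
#' @param opts Options from [classifier_options()].
#' @return A tibble: input columns plus `mass, hc, oc, dbe, ai_mod, c, n,
#'   dbe_convention, parse_ok, parse_error, top1_class, top1_score,
#'   candidates` (packed `"class:score"` strings separated by `";"`),
#'   `msi_level` and `flags`.
#' @export
#' @examples
#' classify_table(tibble::tibble(formula = c("C15H10O7", "C30H50O", "C8H10N4O2")))
classify_table <- function(data, kb = default_kb(), formula_col = "formula",
                           convention = c("neutral", "ion"),
                           opts = classifier_options()) {
  convention <- match.arg(convention)
  desc <- compute_descriptors(data, formula_col = formula_col, convention = convention)
  if (nrow(desc) > 0 && !any(desc$parse_ok)) {
    stop("no input row could be parsed:\n  ",
         paste(sprintf("row %d (%s): %s",
                       which(!desc$parse_ok),
                       desc[[formula_col]][!desc$parse_ok],
                       desc$parse_error[!desc$parse_ok]),
               collapse = "\n  "),
         call. = FALSE)
  }
  if (nrow(desc) == 0) {
    return(dplyr::bind_cols(desc, tibble::tibble(
      top1_class = character(), top1_score = numeric(), candidates = character(),
      msi_level = character(), flags = character()
    )))
  }
  ann <- purrr::map(seq_len(nrow(desc)), function(i) {
    row <- desc[i, ]
    if (!row$parse_ok) {
      return(tibble::tibble(top1_class = NA_character_, top1_score = NA_real_,
                            candidates = NA_character_, msi_level = "3",
                            flags = paste0("parse_error: ", row$parse_error)))
    }
    a <- classify(row, kb, opts)
    flags <- character(0)
    if (row$dbe < 0) flags <- c(flags, "negative_dbe")
    if (nrow(a$candidates) == 0) {
      tibble::tibble(top1_class = NA_character_, top1_score = NA_real_,
                     candidates = "", msi_level = a$msi_level,
                     flags = paste(c(flags, paste0("unclassified: ", a$unclassified_reason)),
                                   collapse = "; "))
    } else {
      tibble::tibble(
        top1_class = a$candidates$class[1],
        top1_score = a$candidates$score[1],
        candidates = paste(sprintf("%s:%.4f", a$candidates$class, a$candidates$score),
                           collapse = ";"),
        msi_level = a$msi_level,
        flags = paste(flags, collapse = "; ")
      )
    }
  })
  dplyr::bind_cols(desc, dplyr::bind_rows(ann))
}
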