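# Formula-derived descriptors: H/C and O/C atomic ratios, double bond
# equivalents (DBE), the modified aromaticity index of Koch & Dittmar,
# carbon and nitrogen counts, monoisotopic mass.

.count_of <- function(comp, el) if (el %in% names(comp)) unname(comp[[el]]) else 0L

#' H/C and O/C atomic ratios
#'
#' The two axes of the Van Krevelen diagram. Requires at least one carbon;
#' absent hydrogen or oxygen gives a ratio of 0.
#'
#' @param comp Composition (named integer vector) or formula string.
#' @return Named numeric vector `c(hc, oc)`.
#' @export
#' @examples
#' elemental_ratios("C15H10O7")
elemental_ratios <- function(comp) {
  if (is.character(comp)) comp <- parse_formula(comp)
  comp <- element_composition(comp)
  nc <- .count_of(comp, "C")
  if (nc == 0) stop("H/C and O/C ratios are undefined without carbon", call. = FALSE)
  c(hc = .count_of(comp, "H") / nc, oc = .count_of(comp, "O") / nc)
}

#' Double bond equivalents
#'
#' Rings-plus-pi-bonds count from the elemental composition:
#' \deqn{DBE = C - (H + X)/2 + N/2 + 1}
#' where X counts halogens (F, Cl, Br, I), and O, S and P are neutral.
#' Valid neutral CHNO molecules give integer DBE; even-electron
#' single-nitrogen cations (e.g. protonated alkaloids) give half-integer
#' values such as 5.5 or 9.5, a diagnostic the classifier exploits.
#'
#' @param comp Composition (named integer vector) or formula string.
#' @return DBE value (may be negative for impossible compositions; such
#'   values are flagged downstream, not rejected here).
#' @export
#' @examples
#' dbe("C8H15N")  # tropane bicyclic core: 2
#' dbe("C14H12")  # trans-stilbene: 9
dbe <- function(comp) {
  if (is.character(comp)) comp <- parse_formula(comp)
  comp <- element_composition(comp)
  x <- sum(vapply(.halogens, function(el) .count_of(comp, el), numeric(1)))
  .count_of(comp, "C") - (.count_of(comp, "H") + x) / 2 + .count_of(comp, "N") / 2 + 1
}

#' Modified aromaticity index
#'
#' The heteroatom-corrected aromaticity index of Koch & Dittmar,
#' \deqn{AI_{mod} = \frac{1 + C - 0.5\,O - S - 0.5\,(N + P + H)}
#'                       {C - 0.5\,O - S - N - P}}
#' clamped to \[0, 1\]; returns 0 when the denominator is non-positive or
#' the numerator negative. Values near 1 indicate condensed aromatic
#' structures; fully saturated acyclic molecules give 0.
#'
#' @param comp Composition (named integer vector) or formula string.
#' @return AI_mod in \[0, 1\].
#' @export
#' @examples
#' ai_mod("C6H6")   # benzene: 2/3
#' ai_mod("C6H14")  # hexane: 0
ai_mod <- function(comp) {
  if (is.character(comp)) comp <- parse_formula(comp)
  comp <- element_composition(comp)
  C <- .count_of(comp, "C"); H <- .count_of(comp, "H"); N <- .count_of(comp, "N")
  O <- .count_of(comp, "O"); S <- .count_of(comp, "S"); P <- .count_of(comp, "P")
  num <- 1 + C - 0.5 * O - S - 0.5 * (N + P + H)
  den <- C - 0.5 * O - S - N - P
  if (den <= 0 || num < 0) return(0)
  min(num / den, 1)
}

#' Full descriptor profile of one composition
#'
#' Bundles every descriptor the annotation framework uses into a one-row
#' tibble. `dbe_convention` records whether the composition is the neutral
#' molecule or the intact ion: the arithmetic is identical but half-integer
#' DBE values only arise (and are only diagnostic) under the ion convention.
#'
#' @param comp Composition (named integer vector) or formula string.
#' @param convention `"neutral"` (default) or `"ion"`.
#' @return One-row tibble with columns `formula, mass, hc, oc, dbe, ai_mod,
#'   c, n, dbe_convention`.
#' @export
#' @examples
#' descriptor_profile("C15H10O7")
descriptor_profile <- function(comp, convention = c("neutral", "ion")) {
  convention <- match.arg(convention)
  if (is.character(comp)) comp <- parse_formula(comp)
  comp <- element_composition(comp)
  ratios <- elemental_ratios(comp)
  tibble::tibble(
    formula = format_formula(comp),
    mass = monoisotopic_mass(comp),
    hc = unname(ratios["hc"]),
    oc = unname(ratios["oc"]),
    dbe = dbe(comp),
    ai_mod = ai_mod(comp),
    c = .count_of(comp, "C"),
    n = .count_of(comp, "N"),
    dbe_convention = convention
  )
}

#' Compute descriptors for a table of formulas
#'
#' Adds the descriptor columns (`mass, hc, oc, dbe, ai_mod, c, n,
#' dbe_convention, parse_ok, parse_error`) to a data frame holding a
#' formula column. Rows that fail to parse are kept and flagged rather
#' than dropped, so a single bad row never aborts a batch.
#'
#' @param data A data frame with a column of formula strings.
#' @param formula_col Name of the formula column (default `"formula"`).
#' @param convention `"neutral"` or `"ion"` (see [descriptor_profile()]).
#' @return A tibble: the input columns plus descriptor columns.
#' @export
#' @examples
#' compute_descriptors(tibble::tibble(formula = c("C15H10O7", "C30H50O")))
compute_descriptors <- function(data, formula_col = "formula",
                                convention = c("neutral", "ion")) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(data))
  if (!formula_col %in% names(data)) {
    stop("column '", formula_col, "' not found in input", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) {
    return(dplyr::bind_cols(data, tibble::tibble(
      mass = numeric(), hc = numeric(), oc = numeric(), dbe = numeric(),
      ai_mod = numeric(), c = integer(), n = integer(),
      dbe_convention = character(), parse_ok = logical(), parse_error = character()
    )))
  }
  desc <- purrr::map(data[[formula_col]], function(f) {
    tryCatch({
      p <- descriptor_profile(f, convention = convention)
      p$parse_ok <- TRUE
      p$parse_error <- NA_character_
      p[setdiff(names(p), "formula")]
    }, error = function(e) {
      tibble::tibble(
        mass = NA_real_, hc = NA_real_, oc = NA_real_, dbe = NA_real_,
        ai_mod = NA_real_, c = NA_integer_, n = NA_integer_,
        dbe_convention = convention, parse_ok = FALSE,
        parse_error = conditionMessage(e)
      )
    })
  })
  dplyr::bind_cols(data, dplyr::bind_rows(desc))
}
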