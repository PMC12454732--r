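# Molecular-formula parsing, Hill formatting, monoisotopic mass and
# ion <-> neutral conversion. Compositions are named integer vectors
# (element symbol -> count), the atomic bookkeeping unit for the package.

#' Monoisotopic masses of the supported elements
#'
#' Masses of the most abundant isotope of each supported element, in Da,
#' plus the electron mass under the name `"e"`. Embedded as a single
#' source of truth so every mass in the package traces to one table.
#'
#' @return A named numeric vector of masses in Da.
#' @export
#' @examples
#' element_masses()[["C"]]
element_masses <- function() {
  c(
    C  = 12,
    H  = 1.0078250319,
    N  = 14.0030740052,
    O  = 15.9949146221,
    S  = 31.97207069,
    P  = 30.97376151,
    Na = 22.98976928,
    K  = 38.96370649,
    F  = 18.9984031627,
    Cl = 34.96885268,
    Br = 78.9183376,
    I  = 126.9044719,
    e  = 0.00054858
  )
}

.supported_elements <- function() setdiff(names(element_masses()), "e")

.halogens <- c("F", "Cl", "Br", "I")

#' Construct an element composition
#'
#' @param counts Named integer vector or list, element symbol to count.
#' @return A named integer vector with all counts > 0, validated.
#' @export
#' @examples
#' element_composition(c(C = 15, H = 10, O = 7))
element_composition <- function(counts) {
  counts <- unlist(counts)
  if (length(counts) == 0 || is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("composition must be a non-empty named vector of element counts", call. = FALSE)
  }
  unknown <- setdiff(names(counts), .supported_elements())
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    stop("composition must contain at least one atom", call. = FALSE)
  }
  # collapse duplicated symbols, keep stable Hill order for printing
  counts <- tapply(counts, names(counts), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out[hill_order(names(out))]
}

# Hill convention: C first, then H, then remaining elements alphabetically;
# when no carbon is present, everything alphabetical.
hill_order <- function(symbols) {
  if ("C" %in% symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    match(intersect(c("C", "H", rest), symbols), symbols)
  } else {
    order(symbols)
  }
}

#' Parse a molecular formula string
#'
#' Parses plain Hill-style formulas such as `"C15H10O7"`. Element symbols
#' are a capital letter plus optional lowercase letter, each followed by
#' an optional integer count (omitted count means 1). No parentheses,
#' hydrates or isotope labels.
#'
#' @param text A single formula string.
#' @return A named integer vector (element -> count).
#' @export
#' @examples
#' parse_formula("C8H10N4O2")
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text)) {
    stop("formula must be a non-empty string", call. = FALSE)
  }
  tokens <- stringr::str_match_all(text, "([A-Z][a-z]?)(\\d*)")[[1]]
  consumed <- paste0(tokens[, 1], collapse = "")
  if (!identical(consumed, text)) {
    stop("cannot parse formula '", text, "': unexpected characters", call. = FALSE)
  }
  symbols <- tokens[, 2]
  unknown <- setdiff(symbols, .supported_elements())
  if (length(unknown) > 0) {
    stop("unknown element symbol '", unknown[1], "' in formula '", text, "'", call. = FALSE)
  }
  counts <- ifelse(nzchar(tokens[, 3]), suppressWarnings(as.integer(tokens[, 3])), 1L)
  if (any(counts == 0L)) {
    stop("zero count for element '", symbols[which(counts == 0L)[1]],
         "' in formula '", text, "'", call. = FALSE)
  }
  names(counts) <- symbols
  element_composition(counts)
}

#' Format a composition as a Hill-notation formula string
#'
#' @param comp Named integer vector as returned by [parse_formula()].
#' @return A formula string; `parse_formula(format_formula(x))` equals `x`.
#' @export
#' @examples
#' format_formula(c(C = 8, H = 10, N = 4, O = 2))
format_formula <- function(comp) {
  comp <- element_composition(comp)
  paste0(names(comp), ifelse(comp > 1, comp, ""), collapse = "")
}

#' Monoisotopic mass of a composition
#'
#' Sums most-abundant-isotope masses; for charged species subtracts
#' `charge` electron masses and divides by `|charge|`, i.e. returns m/z.
#'
#' @param comp Composition (named integer vector) or formula string.
#' @param charge Integer charge of the species (0 for a neutral molecule).
#' @return Mass in Da (m/z when `charge != 0`).
#' @export
#' @examples
#' monoisotopic_mass("H2O")
#' monoisotopic_mass("C8H11N4O2", charge = 1) # protonated caffeine m/z
monoisotopic_mass <- function(comp, charge = 0L) {
  if (is.character(comp)) comp <- parse_formula(comp)
  comp <- element_composition(comp)
  m <- element_masses()
  total <- sum(m[names(comp)] * comp)
  if (charge == 0) return(total)
  (total - charge * m[["e"]]) / abs(charge)
}

# ---- adducts ---------------------------------------------------------------

# delta: atoms the adduct adds to the neutral molecule M.
.adduct_table <- function() {
  list(
    "[M]"     = list(delta = integer(0),            charge = 0L),
    "[M+H]+"  = list(delta = c(H = 1L),             charge = 1L),
    "[M+Na]+" = list(delta = c(Na = 1L),            charge = 1L),
    "[M+K]+"  = list(delta = c(K = 1L),             charge = 1L),
    "[M+NH4]+" = list(delta = c(N = 1L, H = 4L),    charge = 1L),
    "[M-H]-"  = list(delta = c(H = -1L),            charge = -1L)
  )
}

#' Supported adduct labels
#' @return Character vector of adduct labels.
#' @export
supported_adducts <- function() names(.adduct_table())

.adduct_info <- function(adduct) {
  tab <- .adduct_table()
  if (!adduct %in% names(tab)) {
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  tab[[adduct]]
}

# signed mass of the adduct's atom delta
.adduct_delta_mass <- function(adduct) {
  info <- .adduct_info(adduct)
  if (length(info$delta) == 0) return(0)
  m <- element_masses()
  sum(m[names(info$delta)] * info$delta)
}

#' Build an ion species from a neutral molecule
#'
#' Applies an adduct's atom delta to a neutral composition, returning the
#' intact-ion composition together with its label and charge.
#'
#' @param comp Neutral composition or formula string.
#' @param adduct One of [supported_adducts()].
#' @return A list with `composition`, `adduct_label`, `charge`, `polarity`.
#' @export
#' @examples
#' ion_species("C8H10N4O2", "[M+H]+")
ion_species <- function(comp, adduct = "[M+H]+") {
  if (is.character(comp)) comp <- parse_formula(comp)
  comp <- element_composition(comp)
  info <- .adduct_info(adduct)
  counts <- comp
  for (el in names(info$delta)) {
    counts[el] <- (if (el %in% names(counts)) counts[el] else 0L) + info$delta[[el]]
    if (counts[el] < 0) {
      stop("adduct ", adduct, " removes more ", el, " than the molecule has", call. = FALSE)
    }
  }
  list(
    composition = element_composition(counts),
    adduct_label = adduct,
    charge = info$charge,
    polarity = if (info$charge > 0) "positive" else if (info$charge < 0) "negative" else "neutral"
  )
}

#' Recover the neutral molecule from an ion species
#'
#' Inverts [ion_species()]: subtracts the adduct atoms from the intact-ion
#' composition. `[M]` is the identity.
#'
#' @param ion A list as returned by [ion_species()], or a composition plus
#'   an `adduct` label.
#' @param adduct Adduct label when `ion` is a bare composition.
#' @return The neutral composition (named integer vector).
#' @export
#' @examples
#' neutralize(ion_species("C8H10N4O2", "[M+H]+"))
neutralize <- function(ion, adduct = NULL) {
  if (is.list(ion) && !is.null(ion$composition)) {
    comp <- ion$composition
    adduct <- ion$adduct_label
  } else {
    comp <- if (is.character(ion)) parse_formula(ion) else element_composition(ion)
    if (is.null(adduct)) stop("adduct label required", call. = FALSE)
  }
  info <- .adduct_info(adduct)
  counts <- comp
  for (el in names(info$delta)) {
    have <- if (el %in% names(counts)) counts[el] else 0L
    counts[el] <- have - info$delta[[el]]
    if (counts[el] < 0) {
      stop("cannot neutralize ", adduct, ": no ", el, " to remove", call. = FALSE)
    }
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("neutralization left an empty composition", call. = FALSE)
  element_composition(counts)
}

#' m/z of a neutral molecule observed as a given adduct
#'
#' @param comp Neutral composition or formula string.
#' @param adduct One of [supported_adducts()] with non-zero charge.
#' @return Theoretical m/z in Da, electron mass included.
#' @export
#' @examples
#' adduct_mz("C8H10N4O2", "[M+H]+")
adduct_mz <- function(comp, adduct = "[M+H]+") {
  info <- .adduct_info(adduct)
  if (info$charge == 0L) stop("adduct [M] carries no charge; no m/z defined", call. = FALSE)
  if (is.character(comp)) comp <- parse_formula(comp)
  m_neutral <- monoisotopic_mass(comp)
  (m_neutral + .adduct_delta_mass(adduct) - info$charge * element_masses()[["e"]]) /
    abs(info$charge)
}

#' Neutral monoisotopic mass implied by an observed m/z
#'
#' Inverse of [adduct_mz()]: subtracts the adduct mass and restores the
#' electron mass so the ppm budget is preserved even at low m/z.
#'
#' @param mz Observed m/z values (numeric vector).
#' @param adduct One of [supported_adducts()] with non-zero charge.
#' @return Neutral monoisotopic masses in Da.
#' @export
neutral_mass_from_mz <- function(mz, adduct = "[M+H]+") {
  info <- .adduct_info(adduct)
  if (info$charge == 0L) stop("adduct [M] carries no charge; m/z undefined", call. = FALSE)
  mz * abs(info$charge) - .adduct_delta_mass(adduct) + info$charge * element_masses()[["e"]]
}
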