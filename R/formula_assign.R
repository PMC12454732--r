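# Elemental-composition enumeration for accurate MS1 masses under a ppm
# tolerance, and peak-list assignment via adduct neutralization.
# Enumeration is a descending-mass recursive search with residual-mass
# interval pruning; the lightest element is solved analytically at the leaf.

#' Element count bounds for formula enumeration
#'
#' @param C,H,N,O,S,P Two-element `c(min, max)` integer vectors. The
#'   defaults cover the specialized-metabolite space the annotation
#'   framework targets. Pass `NULL` to drop an element entirely.
#' @return A named list of `c(min, max)` bounds, class `vk_bounds`.
#' @export
#' @examples
#' element_bounds(C = c(0, 20), H = c(0, 30), N = c(0, 6), O = c(0, 10),
#'                S = NULL, P = NULL)
element_bounds <- function(C = c(0, 70), H = c(0, 120), N = c(0, 6),
                           O = c(0, 35), S = c(0, 2), P = c(0, 2)) {
  bounds <- list(C = C, H = H, N = N, O = O, S = S, P = P)
  bounds <- bounds[!vapply(bounds, is.null, logical(1))]
  for (el in names(bounds)) {
    b <- bounds[[el]]
    if (length(b) != 2 || anyNA(b) || b[1] < 0 || b[1] > b[2] || any(b != floor(b))) {
      stop("bounds for ", el, " must be c(min, max) with 0 <= min <= max", call. = FALSE)
    }
    bounds[[el]] <- as.integer(b)
  }
  structure(bounds, class = "vk_bounds")
}

#' Parse a compact bounds string
#'
#' Accepts the command-line syntax `"C0-70H0-120N0-6O0-35"`.
#'
#' @param text Bounds specification string.
#' @return A `vk_bounds` object.
#' @export
parse_bounds <- function(text) {
  m <- stringr::str_match_all(text, "([A-Z][a-z]?)(\\d+)-(\\d+)")[[1]]
  if (nrow(m) == 0 || !identical(paste0(m[, 1], collapse = ""), text)) {
    stop("cannot parse bounds '", text, "'; expected e.g. \"C0-70H0-120N0-6O0-35\"",
         call. = FALSE)
  }
  args <- stats::setNames(
    lapply(seq_len(nrow(m)), function(i) c(as.integer(m[i, 3]), as.integer(m[i, 4]))),
    m[, 2]
  )
  full <- stats::setNames(vector("list", 6), c("C", "H", "N", "O", "S", "P"))
  for (el in names(args)) {
    if (!el %in% names(full)) stop("unsupported element in bounds: ", el, call. = FALSE)
    full[[el]] <- args[[el]]
  }
  do.call(element_bounds, full)
}

.bounds_volume <- function(bounds) {
  prod(vapply(bounds, function(b) b[2] - b[1] + 1, numeric(1)))
}

#' Enumerate candidate molecular formulas for a neutral mass
#'
#' Returns exactly the compositions within the element bounds whose neutral
#' monoisotopic mass lies within `tolerance_ppm` of `neutral_mass` (ppm
#' measured against the target neutral mass), ranked by absolute ppm error
#' with deterministic tie-breaking (fewer heteroatoms, then formula string).
#' Chemical filters mirror common practice: integer DBE only and DBE >= 0
#' are on by default; H/C and O/C plausibility windows are off by default.
#'
#' @param neutral_mass Target neutral monoisotopic mass in Da.
#' @param tolerance_ppm Mass tolerance in ppm (default 2, the acceptance
#'   cut-off of the case-study workflow).
#' @param bounds [element_bounds()] object.
#' @param integer_dbe_only Drop compositions with non-integer DBE.
#' @param min_dbe Minimum DBE (default 0); `-Inf` disables.
#' @param hc_range,oc_range Optional `c(min, max)` ratio filters (`NULL`
#'   disables; conventional windows are `c(0.2, 3.2)` and `c(0, 1.5)`).
#' @param max_combinations Guard on the bounds lattice volume; larger
#'   search spaces are refused with guidance rather than attempted.
#' @return Tibble with `formula, theoretical_mass, ppm_error, rank` and the
#'   element count columns.
#' @export
#' @examples
#' enumerate_formulas(194.080376, 2,
#'   element_bounds(C = c(0, 20), H = c(0, 30), N = c(0, 6), O = c(0, 10),
#'                  S = NULL, P = NULL))
enumerate_formulas <- function(neutral_mass, tolerance_ppm = 2,
                               bounds = element_bounds(),
                               integer_dbe_only = TRUE, min_dbe = 0,
                               hc_range = NULL, oc_range = NULL,
                               max_combinations = 5e8) {
  if (!is.numeric(neutral_mass) || length(neutral_mass) != 1 || neutral_mass <= 0) {
    stop("neutral_mass must be a single positive number", call. = FALSE)
  }
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be positive", call. = FALSE)
  if (!inherits(bounds, "vk_bounds")) bounds <- do.call(element_bounds, as.list(bounds))
  if (.bounds_volume(bounds) > max_combinations) {
    stop("element bounds span ", format(.bounds_volume(bounds), big.mark = ","),
         " combinations (guard: ", format(max_combinations, big.mark = ","),
         "); narrow the bounds or raise max_combinations", call. = FALSE)
  }
  tol_da <- tolerance_ppm * neutral_mass * 1e-6
  masses <- element_masses()
  els <- names(bounds)[order(masses[names(bounds)], decreasing = TRUE)]
  lo <- vapply(els, function(e) bounds[[e]][1], integer(1))
  hi <- vapply(els, function(e) bounds[[e]][2], integer(1))
  m <- masses[els]
  n <- length(els)
  # suffix sums: min/max mass attainable from elements k..n
  min_rest <- rev(cumsum(rev(lo * m)))
  max_rest <- rev(cumsum(rev(hi * m)))
  min_rest <- c(min_rest[-1], 0)
  max_rest <- c(max_rest[-1], 0)
  hits <- list()
  counts <- integer(n)
  recurse <- function(k, residual) {
    if (k == n) {
      # solve the lightest element analytically
      c_est <- round(residual / m[k])
      for (ck in unique(pmax(lo[k], pmin(hi[k], c_est + (-1:1))))) {
        if (ck < lo[k] || ck > hi[k]) next
        if (abs(residual - ck * m[k]) <= tol_da) {
          counts[k] <<- ck
          hits[[length(hits) + 1]] <<- counts
        }
      }
      return(invisible())
    }
    c_min <- max(lo[k], ceiling((residual - tol_da - max_rest[k]) / m[k]))
    c_max <- min(hi[k], floor((residual + tol_da - min_rest[k]) / m[k]))
    if (c_min > c_max) return(invisible())
    for (ck in c_min:c_max) {
      counts[k] <<- ck
      recurse(k + 1, residual - ck * m[k])
    }
  }
  recurse(1, neutral_mass)
  empty <- tibble::tibble(formula = character(), theoretical_mass = numeric(),
                          ppm_error = numeric(), rank = integer())
  if (length(hits) == 0) return(empty)
  mat <- do.call(rbind, hits)
  colnames(mat) <- els
  keep <- rowSums(mat) > 0
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) == 0) return(empty)
  th_mass <- as.numeric(mat %*% m)
  getc <- function(e) if (e %in% els) mat[, e] else rep(0L, nrow(mat))
  dbe_v <- getc("C") - getc("H") / 2 + getc("N") / 2 + 1
  ok <- rep(TRUE, nrow(mat))
  if (integer_dbe_only) ok <- ok & abs(dbe_v - round(dbe_v)) < 1e-9
  if (is.finite(min_dbe)) ok <- ok & dbe_v >= min_dbe
  if (!is.null(hc_range)) {
    hc_v <- ifelse(getc("C") > 0, getc("H") / getc("C"), Inf)
    ok <- ok & hc_v >= hc_range[1] & hc_v <= hc_range[2]
  }
  if (!is.null(oc_range)) {
    oc_v <- ifelse(getc("C") > 0, getc("O") / getc("C"), Inf)
    ok <- ok & oc_v >= oc_range[1] & oc_v <= oc_range[2]
  }
  mat <- mat[ok, , drop = FALSE]
  if (nrow(mat) == 0) return(empty)
  th_mass <- th_mass[ok]
  ppm <- (th_mass - neutral_mass) / neutral_mass * 1e6
  formulas <- vapply(seq_len(nrow(mat)), function(i) {
    v <- mat[i, ]
    format_formula(v[v > 0])
  }, character(1))
  hetero <- rowSums(mat[, setdiff(els, c("C", "H")), drop = FALSE])
  ord <- order(abs(ppm), hetero, formulas)
  out <- tibble::as_tibble(as.data.frame(mat[ord, , drop = FALSE]))
  names(out) <- els
  dplyr::bind_cols(
    tibble::tibble(formula = formulas[ord],
                   theoretical_mass = th_mass[ord],
                   ppm_error = ppm[ord],
                   rank = seq_along(ord)),
    out
  )
}

#' Assign molecular formulas to an MS1 peak list
#'
#' Converts each observed m/z to a neutral monoisotopic mass via the
#' declared adduct (adduct mass subtracted, electron mass restored),
#' enumerates candidate formulas within the ppm tolerance and stores the
#' best (rank 1) candidate. Peaks with no candidate are flagged, never
#' dropped.
#'
#' @param peaks Data frame with an `mz` column (and optionally `intensity`).
#' @param adduct One of [supported_adducts()] with non-zero charge.
#' @param tolerance_ppm Mass tolerance in ppm (default 2).
#' @param bounds [element_bounds()] object.
#' @param ... Further filters passed to [enumerate_formulas()].
#' @return Tibble: input columns plus `neutral_mass, formula,
#'   theoretical_mz, ppm_error, n_candidates, assigned`.
#' @export
#' @examples
#' assign_peaks(tibble::tibble(mz = 195.087652),
#'              bounds = element_bounds(C = c(0, 20), H = c(0, 30), N = c(0, 6),
#'                                      O = c(0, 10), S = NULL, P = NULL))
assign_peaks <- function(peaks, adduct = "[M+H]+", tolerance_ppm = 2,
                         bounds = element_bounds(), ...) {
  stopifnot(is.data.frame(peaks))
  if (!"mz" %in% names(peaks)) stop("peak list must have an 'mz' column", call. = FALSE)
  peaks <- tibble::as_tibble(peaks)
  if (nrow(peaks) > 0 && (anyNA(peaks$mz) || any(peaks$mz <= 0))) {
    stop("all m/z values must be positive and non-missing", call. = FALSE)
  }
  info <- .adduct_info(adduct)
  if (info$charge == 0L) stop("adduct [M] carries no charge; use a charged adduct", call. = FALSE)
  res <- purrr::map(peaks$mz, function(mz) {
    nm <- neutral_mass_from_mz(mz, adduct)
    if (nm <= 0) {
      stop("m/z ", mz, " lies below the mass of the ", adduct,
           " adduct; no neutral molecule is possible", call. = FALSE)
    }
    cand <- enumerate_formulas(nm, tolerance_ppm = tolerance_ppm, bounds = bounds, ...)
    if (nrow(cand) == 0) {
      tibble::tibble(neutral_mass = nm, formula = NA_character_,
                     theoretical_mz = NA_real_, ppm_error = NA_real_,
                     n_candidates = 0L, assigned = FALSE)
    } else {
      tibble::tibble(neutral_mass = nm,
                     formula = cand$formula[1],
                     theoretical_mz = adduct_mz(cand$formula[1], adduct),
                     ppm_error = cand$ppm_error[1],
                     n_candidates = nrow(cand),
                     assigned = TRUE)
    }
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(neutral_mass = numeric(), formula = character(),
                          theoretical_mz = numeric(), ppm_error = numeric(),
                          n_candidates = integer(), assigned = logical())
  }
  dplyr::bind_cols(peaks, out)
}
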