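# Class-consistent synthetic molecular formulas and peak lists, emulating a
# curated natural-product reference set so the whole pipeline is testable
# without external data. Two generation modes: integer-lattice rejection
# sampling inside a class's descriptor windows, and scaffold-plus-substituent
# construction from per-class core structures.

# Per-class core scaffolds for scaffold_built mode (neutral molecules).
.class_scaffolds <- function() {
  c(
    flavonoid = "C15H10O2",      # flavone core
    phenolic_acid = "C7H6O2",    # benzoic acid
    tannin = "C27H24O18",        # trigalloyl glucose
    coumarin = "C9H6O2",
    stilbene = "C14H12",
    lignan = "C20H22O6",         # pinoresinol
    anthraquinone = "C14H8O2",
    isoquinoline = "C9H7N",
    indole = "C8H7N",
    quinolizidine = "C9H17N",
    tropane = "C8H15N",
    quinoline = "C9H7N",
    protoalkaloid = "C8H11N",    # phenethylamine
    purine = "C5H4N4",
    pyrrolizidine = "C8H13NO2",  # retronecine
    piperidine = "C5H11N",
    pyrrolidine = "C4H9N",
    steroid = "C27H46O",         # cholesterol
    triterpene = "C30H50O",      # lupeol
    saponin = "C36H60O6"         # lupeol monoglucoside
  )
}

# substituent vocabulary: atoms added per unit (methylenedioxy bridge
# replaces two hydrogens with an O-CH2-O bridge: net +C +O2)
.substituents <- function() {
  list(
    hydroxyl = c(O = 1L),
    methoxyl = c(C = 1L, H = 2L, O = 1L),
    methyl = c(C = 1L, H = 2L),
    prenyl = c(C = 5L, H = 8L),
    methylenedioxy = c(C = 1L, O = 2L),
    glycosyl = c(C = 6L, H = 10L, O = 5L)
  )
}

# run code under a local RNG state, leaving the caller's stream untouched
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.class_def <- function(kb, class_name) {
  if (!class_name %in% kb$name) {
    stop("class '", class_name, "' is not in the knowledge base", call. = FALSE)
  }
  kb[kb$name == class_name, ]
}

# one window-sampled composition, or NULL if the draw fails the windows
.sample_window_formula <- function(cdef) {
  c_lo <- if (is.na(cdef$c_min)) 5L else as.integer(ceiling(cdef$c_min))
  c_hi <- if (is.na(cdef$c_max)) 60L else as.integer(floor(cdef$c_max))
  C <- if (c_lo == c_hi) c_lo else sample(c_lo:c_hi, 1)
  N <- if (cdef$group == "nitrogenous") sample(1:2, 1) else 0L
  h_lo <- if (is.na(cdef$hc_min)) 0L else as.integer(ceiling(cdef$hc_min * C))
  h_hi <- if (is.na(cdef$hc_max)) 2L * C + 2L else as.integer(floor(cdef$hc_max * C))
  if (h_lo > h_hi) return(NULL)
  H <- if (h_lo == h_hi) h_lo else sample(h_lo:h_hi, 1)
  # hydrogen parity: neutral CHNO DBE is integer iff H and N share parity
  if ((H + N) %% 2 != 0) {
    H <- if (H + 1 <= h_hi) H + 1L else H - 1L
    if (H < h_lo || H > h_hi) return(NULL)
  }
  o_lo <- if (is.na(cdef$oc_min)) 0L else as.integer(ceiling(cdef$oc_min * C))
  o_hi <- if (is.na(cdef$oc_max)) as.integer(ceiling(0.8 * C)) else as.integer(floor(cdef$oc_max * C))
  if (o_lo > o_hi) return(NULL)
  O <- if (o_lo == o_hi) o_lo else sample(o_lo:o_hi, 1)
  counts <- c(C = C, H = H, N = N, O = O)
  counts <- counts[counts > 0]
  d <- dbe(counts)
  if (d < 0 || abs(d - round(d)) > 1e-9) return(NULL)
  if (!is.na(cdef$dbe_min) && (d < cdef$dbe_min || d > cdef$dbe_max)) return(NULL)
  r <- elemental_ratios(counts)
  if (!is.na(cdef$hc_min) && (r["hc"] < cdef$hc_min || r["hc"] > cdef$hc_max)) return(NULL)
  if (!is.na(cdef$oc_min) && (r["oc"] < cdef$oc_min || r["oc"] > cdef$oc_max)) return(NULL)
  counts
}

.build_scaffold_formula <- function(class_name, n_subst) {
  comp <- parse_formula(.class_scaffolds()[[class_name]])
  vocab <- .substituents()
  if (n_subst > 0) {
    picks <- sample(names(vocab), n_subst, replace = TRUE)
    for (p in picks) {
      add <- vocab[[p]]
      for (el in names(add)) {
        comp[el] <- (if (el %in% names(comp)) comp[el] else 0L) + add[[el]]
      }
    }
  }
  element_composition(comp[comp > 0])
}

#' Generate class-consistent synthetic molecular formulas
#'
#' `window_sampled` mode draws integer compositions by rejection sampling
#' until H/C, O/C, DBE and carbon count all fall inside the named class's
#' knowledge-base windows, with hydrogen parity corrected so every formula
#' is a valid neutral molecule (integer DBE >= 0). `scaffold_built` mode
#' starts from a per-class core structure (e.g. the bare coumarin scaffold
#' C9H6O2 or lupeol C30H50O) and attaches 0 to `max_substituents` random
#' substituents from the natural-product vocabulary (hydroxyl, methoxyl,
#' methyl, prenyl, methylenedioxy, glycosyl); scaffold products are
#' chemically sensible but need not stay inside the windows.
#'
#' @param class_name A class present in `kb`.
#' @param n Number of records (>= 1).
#' @param seed Integer seed; identical seeds give identical records.
#' @param kb Knowledge base (default [default_kb()]).
#' @param mode `"window_sampled"` (default) or `"scaffold_built"`.
#' @param max_substituents Maximum substituent count in scaffold mode.
#' @param max_attempts Rejection-sampling bound per record.
#' @return Tibble with `true_class, formula, generation_mode, seed`.
#' @export
#' @examples
#' generate_class_formulas("triterpene", 5, seed = 42)
generate_class_formulas <- function(class_name, n, seed, kb = default_kb(),
                                    mode = c("window_sampled", "scaffold_built"),
                                    max_substituents = 3L, max_attempts = 1e5) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  cdef <- .class_def(kb, class_name)
  formulas <- .with_seed(seed, {
    if (mode == "window_sampled") {
      out <- character(n)
      for (i in seq_len(n)) {
        comp <- NULL
        attempts <- 0
        while (is.null(comp)) {
          attempts <- attempts + 1
          if (attempts > max_attempts) {
            stop("could not sample a formula inside the windows of class '",
                 class_name, "' after ", max_attempts,
                 " attempts; the integer lattice may be empty", call. = FALSE)
          }
          comp <- .sample_window_formula(cdef)
        }
        out[i] <- format_formula(comp)
      }
      out
    } else {
      vapply(seq_len(n), function(i) {
        format_formula(.build_scaffold_formula(class_name,
                                               sample(0:max_substituents, 1)))
      }, character(1))
    }
  })
  tibble::tibble(true_class = class_name, formula = formulas,
                 generation_mode = mode, seed = as.integer(seed))
}

#' Simulate an MS1 peak list from synthetic records
#'
#' Ionizes each record's neutral formula as the declared adduct and
#' perturbs the theoretical m/z with multiplicative Gaussian noise of the
#' given ppm standard deviation; intensities are log-uniform over four
#' decades. Reproducible from the seed.
#'
#' @param records Tibble from [generate_class_formulas()] (needs `formula`;
#'   `true_class` carried through when present).
#' @param adduct One of [supported_adducts()] with non-zero charge.
#' @param ppm_noise_sd Mass-noise standard deviation in ppm (>= 0).
#' @param seed Integer seed.
#' @return Tibble with `mz, intensity, true_formula, true_class, adduct`.
#' @export
#' @examples
#' recs <- generate_class_formulas("purine", 3, seed = 1)
#' generate_peaklist(recs, ppm_noise_sd = 0.5, seed = 2)
generate_peaklist <- function(records, adduct = "[M+H]+", ppm_noise_sd = 0.5, seed = 1L) {
  stopifnot(is.data.frame(records), ppm_noise_sd >= 0)
  if (nrow(records) == 0) {
    return(tibble::tibble(mz = numeric(), intensity = numeric(),
                          true_formula = character(), true_class = character(),
                          adduct = character()))
  }
  if (!"formula" %in% names(records)) {
    stop("records must contain a 'formula' column", call. = FALSE)
  }
  mz0 <- unname(vapply(records$formula, adduct_mz, numeric(1), adduct = adduct))
  .with_seed(seed, {
    eps <- stats::rnorm(length(mz0), 0, ppm_noise_sd * 1e-6)
    tibble::tibble(
      mz = mz0 * (1 + eps),
      intensity = 10^stats::runif(length(mz0), 4, 8),
      true_formula = records$formula,
      true_class = if ("true_class" %in% names(records)) records$true_class else NA_character_,
      adduct = adduct
    )
  })
}
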