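---
title: "MS1-level metabolite class annotation with Van Krevelen ratios and DBE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MS1-level metabolite class annotation with Van Krevelen ratios and DBE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vkdbe)
library(tibble)
```

## The problem and the model

In untargeted LC-MS metabolomics most detected features carry only an MS1
accurate mass: fragmentation spectra are acquired for a minority of ions, so
library matching and in-silico fragmentation leave the bulk of the metabolome
unannotated. High-resolution MS1 data do, however, support confident
molecular-formula assignment, and a molecular formula alone constrains
compound class surprisingly well. `vkdbe` formalizes that constraint as a
small set of formula-derived descriptors and per-class numeric windows.

For a composition with `c` carbons, `h` hydrogens, `n` nitrogens, `o`
oxygens, `s` sulfurs and `p` phosphorus atoms:

* H/C = h/c and O/C = o/c are the Van Krevelen coordinates. Aromatic,
  hydroxylated phenolics sit at low H/C and mid-to-high O/C; aliphatic
  isoprenoids at high H/C and low O/C; glycosylation pushes O/C upward.
* DBE = c − (h + x)/2 + n/2 + 1 (x = halogen count) counts rings plus
  π-bonds. O and S do not change DBE; each added H₂ lowers it by 1; each
  glycosyl unit (C₆H₁₀O₅) adds exactly 1 (the pyranose ring).
* AI_mod = (1 + c − 0.5o − s − 0.5(n + p + h)) / (c − 0.5o − s − n − p),
  clamped to [0, 1] and set to 0 for a non-positive denominator or negative
  numerator, estimates condensed-aromatic character with all π-equivalents
  that heteroatoms can plausibly absorb discounted. Benzene scores 2/3,
  saturated acyclic chains 0.
* The carbon count discriminates classes whose ratio and DBE windows
  converge: triterpenes have exactly 30 carbons, steroids at most 28,
  saponins 35–60 from their sugar load, phenolic acids 7–11.

Annotation confidence is MSI Level 3 by construction — the output is a
ranked list of candidate compound *classes*, never an identity — and every
result row records it.

### DBE conventions

DBE arithmetic is identical for neutral molecules and intact ions, but its
interpretation differs. A valid neutral CHNO molecule has integer DBE; a
protonated even-electron ion with one nitrogen (the typical ESI⁺ alkaloid)
has a half-integer DBE such as 5.5 or 9.5. Published alkaloid DBE ranges mix
the two conventions without comment, so the package supports both: the
default is the neutral convention (tropane core 2, piperidine 1, purines
6–7), an explicit `convention = "ion"` reproduces half-integer values, and
every descriptor row records which was used. Under the ion convention a
half-integer DBE additionally restricts classifier eligibility to the
alkaloid group, since no other class produces it.

## The knowledge base

Twenty classes across three biosynthetic groups (seven phenolic, ten
alkaloid, three isoprenoid), each with up to four windows (H/C, O/C, DBE,
carbon). Every numerically published window is embedded verbatim and tagged
`provenance = "paper"`. Two published DBE ranges existed for flavonoids
(9–20 and 7–17) and phenolic acids (5–11 and 5–7); the defaults use the
unions (7–20, 5–11) with the narrower sources kept in the entry notes. Two
carbon endpoints are implementer choices: the tannin maximum (stated as "30
to over 100") defaults to 120, and the steroid window (stated as "fewer than
29 carbons") defaults to 10–28, the lower endpoint excluding trivially small
molecules; both are tagged `derived`.

Classes whose elemental-ratio ranges were described only qualitatively get
windows computed at `default_kb()` call time from ≥ 10 canonical member
compounds each (e.g. gallic through sinapic acid for phenolic acids,
tropane/atropine/scopolamine/cocaine for tropanes), rounded outward to three
decimals and tagged `derived`. Protoalkaloid members are restricted to
phenylethylamine-derived amines — the textbook definition of a protoalkaloid
(nitrogen outside any ring, derived from an aromatic amino acid) — so
colchicine-type outliers and non-plant amphetamines are deliberately
excluded. Derived windows are a package construction, never presented as
published values; `tidy(default_kb())` exposes every bound with its
provenance, and users can override everything via a JSON file
(`load_kb()`/`save_kb()`, schema in `inst/extdata/kb-schema.json`).

`validate_kb()` reports window overlaps between classes of the same group
(flavonoid/lignan DBE, triterpene/steroid H/C, and others). Overlap is real
chemistry, not an error; it is why DBE boundaries and carbon counts matter.

## The classifier

No published numeric scoring rule exists for "falls inside the class's
windows", so the score is this package's own formalization of interval
membership across axes:

* per defined axis, membership is 1 inside the window and `exp(-d/σ)` at
  distance `d` outside it, with σ = 0.1 for ratios, 1.0 for DBE, 2.0 for
  carbons (σ = 0 gives hard membership);
* the class score is the mean over its defined axes, so score 1 means
  "inside every window the class defines";
* candidates at or above `min_score` (default 0.5) are ranked by score;
  exact ties are broken by smaller |DBE − window midpoint| first (DBE is the
  primary discriminator), then |C − carbon-window midpoint|, then class name
  — fully deterministic.

The σ defaults were chosen once, on the scale of each axis (0.1 in ratio
units is roughly the spacing of one hydroxyl on a C15 skeleton; 1 DBE is one
ring; 2 carbons is one homologue step), and are exposed as options rather
than tuned.

Nitrogen gating defaults to strict: a nitrogen-free profile scores 0 against
every alkaloid class and a nitrogen-containing profile scores 0 against
non-nitrogenous classes. Plant extracts are full of nitrogenous primary
metabolites (amino acids, nucleosides); with `strict_nitrogen = FALSE` such
cross-group matches are halved instead of excluded. Unclassified nitrogenous
profiles carry a reason string pointing at the primary-metabolite
explanation. AI_mod is computed and exported on every row but does not gate
the default classifier — no published threshold exists — so it remains an
optional user-side filter.

## Formula enumeration

`enumerate_formulas()` returns exactly the CHNOPS compositions within the
bounds whose monoisotopic mass lies within the ppm tolerance of the target
neutral mass. The search orders elements by descending mass, prunes each
branch by the residual-mass interval attainable from the remaining elements,
and solves the lightest element analytically at the leaf; completeness is
tested against a naive exhaustive oracle on random small instances. Default
bounds are C 0–70, H 0–120, N 0–6, O 0–35, S 0–2, P 0–2 — wide enough for
specialized metabolites to ~1300 Da — with a lattice-volume guard (5×10⁸)
refusing pathological requests. ppm is defined against the neutral
monoisotopic mass (vendor convention); ion↔neutral conversion handles the
electron mass explicitly, which matters below m/z 300 at 2 ppm. Candidates
are ranked by |ppm error|, ties by fewer heteroatoms then formula string.
Chemical filters (integer DBE, DBE ≥ 0 on by default; H/C and O/C
plausibility windows available but off) are individually switchable.
Isotopic-pattern scoring is out of scope: ranking is by mass error alone,
which is the main reason a wrong near-isobaric candidate can outrank the
true formula at high mass.

## Synthetic data: what it emulates and what it does not

`generate_class_formulas()` emulates a curated per-class formula collection.
`window_sampled` mode rejection-samples integer compositions (bounded at
10⁵ attempts, seeded, hydrogen parity corrected so every formula is a valid
neutral molecule) until all of the class's windows are satisfied; carbon
falls back to 5–60 where a class defines no carbon window, and alkaloid
records carry 1–2 nitrogens. `scaffold_built` mode starts from a per-class
core (coumarin C9H6O2, trans-stilbene C14H12, tropane C8H15N, lupeol
C30H50O, …) and adds random substituents from the natural-product vocabulary
(hydroxyl, methoxyl, methyl, prenyl, methylenedioxy, glycosyl); it exists
precisely for windows too narrow to sample (triterpene carbon is exactly
30). `generate_peaklist()` ionizes the records under one adduct and applies
multiplicative Gaussian ppm noise (default sd 0.5 ppm, a realistic Orbitrap
calibration residual) with log-uniform intensities.

What passing tests on these data show: the enumerator, adduct arithmetic,
windows and classifier are mutually consistent, and the pipeline recovers
what it generated. What they do not show: performance on real extracts —
synthetic records have no isotope patterns, no adduct mixtures, no in-source
fragments, no co-eluting isomers, and their class distribution inside each
window is uniform rather than biological. Window-sampled records score 1.0
for their true class *by construction*; the end-to-end test is a consistency
check, not a validation of the windows against nature.

## Numerical and design choices

* Monoisotopic masses are an embedded constants table (C 12 exact,
  H 1.0078250319, N 14.0030740052, O 15.9949146221, S 31.97207069,
  P 30.97376151, Na 22.98976928, K 38.96370649, electron 0.00054858, plus
  halogens), unit-tested; one source of truth for every mass in the package.
* Supported adducts: [M], [M+H]⁺, [M+Na]⁺, [M+K]⁺, [M+NH₄]⁺, [M−H]⁻;
  |z| = 1 only. Neutralization followed by re-adduction is tested as the
  identity.
* Formula syntax is plain Hill-style text; no parentheses, hydrates or
  isotope labels. Parsing failures in batch input flag the row and never
  abort the batch (an all-failed batch is an error).
* Degenerate inputs: ratios are an error without carbon; negative DBE is
  computed but flagged (`negative_dbe`), since it signals an impossible
  neutral composition; the [M] adduct has no m/z.
* Van Krevelen axes are fixed to x = O/C, y = H/C, the conventional
  orientation. DBE histograms default to 0.5-wide bins so half-integer
  alkaloid values get their own bin; at width 1.0 values bin by the floor
  rule. Boxplot quartiles use type-7 linear interpolation. The 20-class
  color palette is fixed so figures reproduce byte-for-byte.
* Problem sizes in the test suite were chosen to exercise each property at
  desk scale: 1000 parse/format round-trips, 100 enumerator-vs-oracle
  instances, 150 self-recovery enumerations, and one 200-record end-to-end
  run (10 classes × 20 records, 0.5 ppm noise, 2 ppm filter).

## Known limitations

* Class windows come from curated literature ranges and canonical members,
  not from a learned model; a compound class absent from the knowledge base
  is invisible, and exotic substitution can leave a true member outside its
  windows.
* Candidate ranking ignores isotope patterns, so formula assignment degrades
  above ~700 Da where 2 ppm admits many CHNOPS compositions.
* Multiply charged ions, adduct deconvolution across peaks, and
  structure-level identifiers (SMILES/InChI) are out of scope.
* AI_mod is reported, not thresholded; users wanting a condensed-aromatics
  cut must choose their own.
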