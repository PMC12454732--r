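# vkdbe

Class-level annotation of specialized plant metabolites from MS1
high-resolution mass spectrometry data alone.

Untargeted metabolomics studies acquire MS/MS spectra for only a fraction of
the features detected in full-scan (MS1) mode, so most features never reach a
library match. `vkdbe` targets that gap: given accurate MS1 masses (or
molecular formulas directly), it assigns candidate compound **classes** —
flavonoids, phenolic acids, tannins, alkaloid subclasses, triterpenes,
steroids, saponins and more — at MSI confidence Level 3 (putatively
characterized compound class), without any fragmentation data. It is aimed at
natural-product and plant-metabolomics researchers profiling complex,
under-characterized extracts.

## The method

Everything is computed from the elemental composition
C<sub>c</sub>H<sub>h</sub>N<sub>n</sub>O<sub>o</sub>S<sub>s</sub>P<sub>p</sub>:

- **Van Krevelen ratios** H/C = h/c and O/C = o/c, the two axes of the Van
  Krevelen diagram, tracking hydrogenation degree and oxidation state;
- **double bond equivalents** DBE = c − (h + halogens)/2 + n/2 + 1, the
  ring-plus-π-bond count. Valid neutral CHNO molecules have integer DBE;
  protonated even-electron single-nitrogen ions give half-integer values
  (5.5, 9.5, …), a diagnostic that is essentially unique to alkaloids;
- **modified aromaticity index**
  AI<sub>mod</sub> = (1 + c − 0.5o − s − 0.5(n + p + h)) / (c − 0.5o − s − n − p),
  clamped to [0, 1], separating condensed aromatic from aliphatic space;
- **carbon count**, decisive where DBE windows overlap (e.g. C30 triterpenes
  vs. C ≤ 28 steroids vs. C35–60 saponins).

A built-in knowledge base stores, for 20 metabolite classes in three
biosynthetic groups, the characteristic windows of H/C, O/C, DBE and carbon
count. A profile's membership score for a class is the mean per-axis
membership over the class's defined windows (1 inside, exponential decay
outside); candidates are ranked by score with DBE-midpoint tie-breaking, and
nitrogen gating keeps nitrogen-free formulas out of alkaloid classes and vice
versa. For raw m/z input, a branch-and-bound enumerator generates all CHNOPS
compositions within a ppm tolerance (default 2 ppm) of the adduct-corrected
neutral mass.

## Worked example

```r
library(vkdbe)
library(tibble)

# quercetin, lupeol, caffeine
ann <- classify_table(tibble(formula = c("C15H10O7", "C30H50O", "C8H10N4O2")))
ann[, c("formula", "hc", "oc", "dbe", "c", "top1_class", "top1_score")]
#> # A tibble: 3 × 7
#>   formula      hc     oc   dbe     c top1_class top1_score
#>   <chr>     <dbl>  <dbl> <dbl> <int> <chr>           <dbl>
#> 1 C15H10O7  0.667 0.467     11    15 flavonoid           1
#> 2 C30H50O   1.67  0.0333     6    30 triterpene          1
#> 3 C8H10N4O2 1.25  0.25       6     8 purine              1
```

Quercetin's H/C 0.667, O/C 0.467, DBE 11 and 15 carbons all fall inside the
flavonoid windows, so the flavonoid score is exactly 1; lupeol is the only
class whose four windows all contain its profile; caffeine (DBE 6, four
nitrogens) passes the nitrogen gate and lands in the purine DBE window 6–7,
which out-ranks wider alkaloid windows via the DBE-midpoint tie-break.

Starting from raw peaks instead of formulas:

```r
peaks <- tibble(mz = 195.087652)               # protonated caffeine
assign_peaks(peaks, adduct = "[M+H]+", tolerance_ppm = 2)[, c("mz", "formula", "ppm_error")]
#> # A tibble: 1 × 3
#>      mz formula   ppm_error
#>   <dbl> <chr>         <dbl>
#> 1  195. C8H10N4O2  0.000185
```

Figures: `plot_van_krevelen(ann)`, `plot_dbe_distribution(ann)`,
`autoplot(default_kb())` (class range bars), `plot_dbe_box(ann)`, and
`render(ann, "vk3d", "fig.png")` for the 3D H/C–O/C–DBE view.

A command-line interface wrapping the same functions ships at
`inst/cli/vkdbe.R` with subcommands `describe`, `assign`, `classify`, `plot`,
`simulate` and `kb`.

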