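# nucleograde

Quantitative-histology pipeline for clear cell renal cell carcinoma
(ccRCC), built around one cell-level feature: **nucleolar prominence**.
WHO/ISUP grading of ccRCC is driven largely by how visible nucleoli are
at a given magnification, but expert application of that rule is
subject to interobserver variability. `nucleograde` implements, as
fully tested desk-scale code, the analysis chain that turns an H&E tile
into prognostic tissue statistics:

1. **Synthetic data** (`make_tile`, `make_pattern_tile`,
   `make_cohort`) — seeded H&E-like tiles with star-convex nuclei,
   planted nucleoli and full ground truth; survival cohorts with
   quadrant-dependent exponential hazards. Every downstream stage is
   testable with no external data.
2. **Segmentation** (`compute_maps`, `candidates`, `nms`,
   `rasterize`) — star-convex polygon instance segmentation: per-pixel
   object probability d and radial distances r along n fixed rays,
   polygon candidates, greedy IoU non-maximum suppression, label-mask
   rasterisation. The probability/distance predictor is a deterministic
   classical stage (stain-darkness rescaling + ray casting) standing in
   for a trained network.
3. **Classification** (`assign_grade`, `classify_cells`) — a
   deterministic rule encoding of the grading criteria: a cell is G3
   when its largest nucleolus is at least `D100` = 1.5 µm across with
   darkness contrast ≥ `C_hi` = 0.25 ("clearly visible at ×100"); G2
   for ≥ `D400` = 0.7 µm with contrast ≥ `C_lo` = 0.10 ("noticeable at
   ×400"); G1 for small plain nuclei; Other for the rest. The primary
   output is the binary task **G3 vs Other**.
4. **ROI metrics** (`roi_from_perimeter`, `profile_roi`) — square ROI
   of perimeter 4000 µm (1 mm²); G3 cells/mm², Other cells/mm², %G3.
5. **Grade statistics** (`roc_auc`, `youden_threshold`,
   `grade_binary_eval`, `anova_tukey`) — low (G1/G2) vs high (G3/G4)
   discrimination: AUC as pairwise concordance, Youden's
   J = sensitivity + specificity − 1 cutpoint, one-way ANOVA with Tukey
   HSD.
6. **Survival** (`assign_quadrant`, `km_fit`, `logrank_test`,
   `fisher_exact`, `cohort_analysis`) — the four prognostic tissue
   quadrants from dual density cut-offs (G3 > 533, Other > 4133
   cells/mm²), Kaplan–Meier product-limit curves and medians, k-sample
   log-rank (Mantel–Cox) test, Fisher's exact test of quadrant × grade.

The statistic at the core of the survival model: with S(t) the
product-limit estimate Π_{t_i ≤ t} (1 − d_i/n_i), each quadrant's
median is the smallest event time with S(t) ≤ 0.5, and the k-sample
log-rank statistic is (O − E)ᵀ V⁻¹ (O − E) with hypergeometric
variance–covariance summed over distinct event times, referred to
χ²(k−1).

## Worked example

```r
library(nucleograde)

tile <- make_tile(tile_spec(width_px = 1000, height_px = 1000,
                            pixel_size = 0.5, n_cells = 250,
                            class_mix = c(G1 = 0.4, G2 = 0.2,
                                          G3 = 0.15, Other = 0.25),
                            seed = 42))
seg   <- segment_tile(tile$image)
cells <- classify_cells(tile$image, seg$mask, pixel_size = 0.5)
class_distribution(cells$label)
#>   class count  pct
#> 1    G1   100 40.0
#> 2    G2    49 19.6
#> 3    G3    38 15.2
#> 4 Other    63 25.2

prof <- profile_roi(cells, roi_from_perimeter(2000, center = c(250, 250)))
prof[, c("n_total", "dens_g3", "dens_other", "pct_g3")]
#>   n_total dens_g3 dens_other pct_g3
#> 1     250     152        848   15.2
flag_high_grade(prof$pct_g3)   # >= 11.4% of cells have prominent nucleoli
#> [1] TRUE
```

All 250 planted nuclei are recovered by the segmentation, the class
percentages match the planted mix (15.2% G3 realised vs 15% planted),
and the ROI is flagged high grade by the one-in-ten criterion.

Grade discrimination and survival on synthetic cohorts:

```r
gc_df <- make_grade_cohort(seed = 1)
grade_binary_eval(gc_df, gc_df$grade)
#> threshold 11.74 | J = 0.943 (sens 1.000, spec 0.943) | AUC = 0.997

co <- make_cohort(cohort_spec(n_samples = 70, seed = 1))
cohort_analysis(co)
#> cohort_report: cuts G3 > 533, Other > 4133 cells/mm^2
#> G3+/O- G3+/O+ G3-/O- G3-/O+
#>     18     18     17     17
#> medians (days):
#> G3+/O- G3+/O+ G3-/O- G3-/O+
#>  536.7 2597.3 1129.5 2605.0
#> overall median: 1261.245
#> log-rank (Mantel-Cox): chi2 = 21.32 on 3 df, p = 9.038e-05
#> Fisher quadrant x grade: p = 0.0001022 (exact network (r x c))
```

The Youden cutpoint on the synthetic grade cohort (11.74 %G3) lands
next to the 11.4% high-grade criterion the package exposes as its
default, and the low-Other-density quadrants show the short medians
the generator encodes. Note the AUC of 0.997 is a synthetic-world
statement (well-separated pattern presets), not a claim about real
slides.

A command-line driver mirrors the stages
(`inst/cli/nucleograde simulate|segment|classify|profile|grade|survive|pipeline`),
and `run_pipeline()` chains all of them into a checksummed run
directory.

## Vignette

`vignettes/nucleograde-methods.Rmd` documents the model and its
assumptions, every tunable threshold with units and defaults, what the
synthetic generator does and does not emulate, numerical conventions
(boundary rules, tie-breaks, degenerate inputs), and known limitations
— including two acceptance checks that are deliberately left failing
with a statistical analysis of why.
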