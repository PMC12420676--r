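---
title: "nucleograde: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nucleograde: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package models

In clear cell renal cell carcinoma (ccRCC), WHO/ISUP grade — the main
histological driver of treatment intensity — is assigned mostly from
*nucleolar prominence*: G1 nuclei show no visible nucleolus, G2
nucleoli become noticeable around ×400 magnification, G3 nucleoli are
clearly visible already at ×100. Because this is a visual judgement it
suffers from interobserver variability, and because grades are
discrete they hide a continuous quantity with prognostic content: the
*fraction of tumour cells with prominent nucleoli* and the *density of
cells* in a region.

`nucleograde` implements that quantitative reading as a pipeline of
small, separately testable stages: segment nuclei as star-convex
polygons, grade each cell by an explicit physical rule, profile 1 mm²
regions (G3 cells/mm², Other cells/mm², %G3), select discriminating
thresholds by ROC/Youden, and stratify cohorts into four prognostic
quadrants evaluated with Kaplan–Meier curves, the log-rank test and
Fisher's exact test. Everything runs on synthetic data with known
ground truth; nothing requires whole-slide images.

## Segmentation model

A nucleus is represented star-convexly: from a centre pixel, radial
distances $r_k$ along $n$ fixed rays (ray $k$ at angle $2\pi k/n$,
angle 0 = +x, measured toward +y in image convention) define a polygon
with vertex $k$ at $c + r_k(\cos\theta_k, \sin\theta_k)$. The
probability map $d$ and distance map $r$ that a trained network would
predict are replaced by a deterministic classical stage, because no
trained weights are published and a desk-scale pipeline needs a
closed-form component:

* darkness = $1 - \text{mean(RGB)}$, smoothed with a Gaussian
  (`smooth_sigma` = 1 px);
* probability = darkness rescaled linearly between `darkness_low` =
  0.10 and `darkness_high` = 0.30 and clamped to [0, 1];
* distances = ray marching on the thresholded foreground (step 0.5 px,
  boundary estimated at half a step before the first background
  sample).

The anchors are calibrated to the renderer: background darkness is
0.06 and the faintest nucleus class renders at ≈ 0.33, so probability
0.5 (the foreground threshold) falls at darkness 0.20 — the
*half-intensity contour* between background and nucleus, which is the
unbiased edge estimate for a blurred step. An earlier choice
(0.15/0.45) placed the contour well inside small G1 nuclei, eroding
~30% of their area and breaking IoU ≥ 0.5 matching; the fix was this
recalibration, not a loosening of the matching criterion.

Candidates are one polygon per foreground pixel on a stride-2 grid,
scored by probability, sorted descending with ties broken by (row,
column) scan order. Greedy non-maximum suppression accepts the best
candidate and suppresses anything with IoU above `iou_threshold` = 0.5
against an accepted instance. Polygon IoU is computed *exactly*: each
simple polygon is decomposed into signed fan triangles, pairwise
triangle intersections are clipped (Sutherland–Hodgman), and the signed
sum gives the intersection area — verified in the tests against a
Monte-Carlo oracle and, for NMS, against a quadratic brute-force
reference. The overlap criterion (IoU rather than containment) is a
documented choice; the original description does not state one.

## The grading rule

Visibility-at-magnification is not reproducible as stated, so it is
encoded as physical thresholds on the detected nucleolus (all
config-exposed via `grade_rules()`):

| parameter | meaning | default | unit |
|---|---|---|---|
| `D100` | min. nucleolus equivalent diameter for G3 | 1.5 | µm |
| `C_hi` | min. nucleolus/nucleoplasm contrast for G3 | 0.25 | darkness |
| `D400` | min. diameter for G2 | 0.7 | µm |
| `C_lo` | min. contrast for G2 | 0.10 | darkness |
| `small_nucleus_diam` | max. equivalent diameter for G1 | 7.5 | µm |

Rule order is fixed and total: G3 iff diameter ≥ `D100` **and**
contrast ≥ `C_hi` (boundaries inclusive); else G2 iff ≥ `D400` and ≥
`C_lo`; else G1 iff the nucleus equivalent diameter is at most the
small-nucleus bound; else Other. The G1 bound of 7.5 µm sits between
the ~6 µm low-grade and ~9 µm high-grade nuclear size priors. When a
cell has several nucleoli the largest governs (the source criteria are
silent on this). Giant/multinucleated (G4) cells are not emitted: they
were merged into "Other" in the annotation scheme this rule encodes,
and the primary task is binary G3 vs Other.

Nucleolus detection is blob detection inside the nucleus mask:
connected pixels whose darkness exceeds the intra-nuclear median by at
least `min_contrast` = 0.08, with blob contrast measured as mean blob
darkness minus the median of the remaining nucleoplasm. 0.08 sits
below `C_lo`, so detection never hides a gradable nucleolus.

## ROI metrics and thresholds

An ROI is an axis-aligned square of perimeter $P$ (side $P/4$); the
reference ROI has $P$ = 4000 µm, area exactly 1 mm², which is why "533
cells" and "533 cells/mm²" can be used interchangeably for the
cut-offs. Cell membership is by centroid with a half-open convention
(min-edges inclusive, max-edges exclusive) so that tiling ROIs never
double-count — the source does not state a rule. Percentages are
reported with half-up rounding to 2 decimals, matching the reference
tables' arithmetic. An empty ROI yields a flagged profile with
undefined %G3, not an error; a verification mode warns when an ROI
falls outside the 400–1200 cells/mm² band (sparse dystrophic tissue
legitimately does).

Two fixed clinical thresholds are carried in the pipeline config: the
dual density cut-offs (533, 4133) defining the quadrants, and the
11.4 %G3 criterion (`flag_high_grade`, boundary inclusive — "one cell
in ten").

## Statistics

* **AUC** is pairwise concordance
  $P(s^+ > s^-) + \tfrac12 P(\text{tie})$ computed by midranks, which
  equals the trapezoidal area under the empirical ROC.
* **Youden cutpoint**: candidates are midpoints of adjacent distinct
  scores plus ±∞; positives are `score > threshold`; ties on J resolve
  to the smallest threshold (deterministic, invariant between observed
  values).
* **ANOVA/Tukey** delegate to `stats::aov`/`TukeyHSD` (infrastructure,
  not contribution); the all-groups-constant degenerate case returns
  p = 1 when means agree and a flagged p = 0 otherwise — no infinite F
  is ever reported.
* **Kaplan–Meier**: $S(t) = \prod_{t_i \le t} (1 - d_i/n_i)$ over
  distinct event times; subjects censored exactly at an event time
  count as at risk there; the median is the smallest event time with
  $S \le 0.5$ (inclusive), NA ("not reached") when the curve stays
  above 0.5 — the report distinguishes "not reached" from small-n
  instability by carrying the group size.
* **Log-rank (Mantel–Cox)**: observed-minus-expected event counts with
  hypergeometric variance–covariance summed over distinct event times,
  ties processed together; $\chi^2$ with $k-1$ df; a generalised
  inverse handles degenerate variance. Verified equal to
  `survival::survdiff` and to an independently coded two-sample closed
  form.
* **Fisher's exact test**: 2×2 by direct hypergeometric enumeration
  with the probability-mass two-sided ordering (the most common "exact
  test" convention, stated here for reproducibility); r×c via the
  exact network algorithm up to total 200 (with Monte-Carlo fallback if
  the FEXACT workspace overflows), seeded Monte-Carlo with reported
  standard error above that.
* **Quadrants**: positivity is *strictly greater* on both axes
  (G3⁺ iff dens_G3 > 533; O⁺ iff dens_Other > 4133). The published
  quadrant list is internally inconsistent at the Other boundary ("<"
  in one quadrant, "≥" in its complement cannot partition the plane);
  a uniform strict rule restores an exclusive, exhaustive partition.

## What the synthetic generator emulates — and what it does not

Tiles plant: star-convex nuclei (base radius plus low-order Fourier
perturbation, so the segmentation representation can express every
planted shape); class counts by largest-remainder apportionment of the
class mix (ties by class order G1 < G2 < G3 < Other — deterministic);
~6 µm low-grade and ~9 µm high-grade nuclear diameters; nucleolus
discs whose size/contrast are strictly inside (G3) or outside
(G1/G2/Other) the grading rule's G3 region, so ground-truth round
trips are well posed; hematoxylin-dark nuclei on a pale noisy
background (contrast is what the classifier measures — no attempt at
H&E colour fidelity). Pattern presets reproduce the four prognostic
tissue patterns' %G3 distributions (monomorphic 5.24 ± 3.55,
pluralistic 18.45 ± 5.57, nucleolar 28.29 ± 10.04, dystrophic
8.56 ± 7.06, the latter with total density below 5000 cells/mm²).
Cohorts draw per-quadrant densities from truncated normals confined to
the quadrant's region of the density plane and exponential survival
times with medians ln 2/λ of 804 / 2400 / 1062.5 / 2600 days,
administratively censored at 3650 days.

Choices made where the source is silent:

* **Survival law**: only medians are reported, so exponential hazards
  are an assumption; the censoring horizon of 3650 days is a typical
  registry follow-up and keeps all four medians estimable.
* **Placement**: non-overlap by dart throwing with minimum
  centre-to-centre distance (max radius sum + 4 px). The attempt bound
  was originally fixed at 10 × n; at realistic densities
  (~6000 cells/mm² ⇒ ~40% exclusion-disc coverage) random sequential
  adsorption needs super-linearly many attempts near jamming and that
  bound is unsatisfiable, so the bound is 200 × n and larger nuclei
  are placed first (still pure dart throwing, deterministic, with an
  explicit error naming the achievable maximum on failure).
* **Grade → pattern mapping** for the synthetic grade cohort: grades
  1–2 draw %G3 from the monomorphic preset, grades 3–4 from the
  nucleolar preset, following the patterns' own morphological
  alignment (monomorphic ≈ G1/G2, nucleolar characteristic of G3).
  The pluralistic and dystrophic presets are deliberately *not*
  grade-typical defaults: in the source cohorts those patterns were
  discordant with expert grade (pluralistic cases graded G2 despite
  18% G3 cells; dystrophic spanning G3/G4 with low density), which is
  precisely what limits real-data discrimination to an AUC around
  0.79. A green synthetic AUC > 0.9 therefore certifies the *method*
  (scoring, thresholding, evaluation) on a separable world — it is not
  a reproduction of the real-data figure, and passing `mapping =` a
  discordant assignment emulates the harder world.
* **Pixel size**: tiles default to 0.5 µm/px; the pipeline config
  default is 0.25 µm/px (the common ×40 scanner value, not printed in
  the source). Both are parameters, never assumptions.

Not emulated (out of scope by design): photo-realistic H&E colour,
stain batch effects, scanner artifacts and folds, necrosis geometry,
G4 rhabdoid/sarcomatoid morphology, intratumoral heterogeneity across
blocks. A green tile test therefore establishes correctness of the
geometry, rules and statistics — not performance on real slides.

## Numerical conventions

Coordinates are 0-based pixel indices, x = column, y = row; polygon
vertices in pixel units; µm = px × pixel size. Rasterisation assigns a
pixel to the highest-score covering instance by pixel-centre
inclusion; instance ids are 1..K in score order. Percentages use
half-up rounding (base R rounds half-even). Seeded generators
save and restore the caller's RNG state, so they are reproducible and
side-effect free; distinct seeds give distinct layouts. Label masks
are stored as RGB PNG with the id byte-packed across channels (no
TIFF library is assumed), tiles as 8-bit RGB PNG, overlays as
QuPath-style GeoJSON (`classification.name`, `measurements.score`,
pixel coordinates).

## Known limitations

* The classical probability/distance stage is calibrated to the
  package's own renderer; on real H&E it would need stain
  normalisation and retuned anchors, and no claim is made about
  real-slide segmentation accuracy (the published validation F1 and
  test accuracy require the original annotated slides).
* Two acceptance checks are deliberately left failing, with analysis:
  (1) recovering all four KM medians within 15% from a 280-sample
  cohort is statistically unattainable for most seeds — at 70 subjects
  per quadrant the exponential KM median has relative standard error
  ≈ 1/(ln 2 · √70) ≈ 17%, so all-four-within-15% has probability
  ≈ 0.15; the hazard calibration itself is verified at n = 4000 within
  5%. (2) the log-rank type-I band 0.05 ± 0.01 at n = 70 across four
  groups is violated by the canonical statistic itself (measured
  0.056–0.074 over seeds, identical to `survival::survdiff` on the
  same draws, converging to 0.05 by n = 280). Neither band was
  widened.
* Cox regression, clinical covariate adjustment and multi-ROI spatial
  statistics are out of scope.
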