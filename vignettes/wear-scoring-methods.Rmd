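---
title: "Methods: grid-based wear scoring and its reliability"
author: "sachwear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid-based wear scoring and its reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sachwear)
```

This vignette documents the model and procedure `sachwear` implements, the
numerical and interpretive choices the implementation had to make, and the
assumptions behind the simulator. It is the place to look when a result
depends on a convention rather than on the mathematics.

## The scoring procedure

A SACH foot's plantar surface is photographed (or traced), a **20×10
rectangular grid** (20 rows toe→heel, 10 columns medial→lateral on a left
foot) is overlaid on the outline, and each cell receives an ordinal wear
score. Right feet are **mirrored** before grid placement so that columns
always read medial→lateral; see `mirror_outline()`.

Two rubrics are supported (`wear_scale()`, `rubric_table()`):

* **original**, 0–9: anchored to the progressive exposure and destruction
  of the two nylon reinforcement sheets moulded into the sole. Only
  applicable to feet that have such sheets.
* **modified**, 0–5: a minimalist rubric (surface texture, depth of
  material loss) applicable to any foot.

`collapse_score()` maps original→modified many-to-one:
0→0, 1→1, {2,3}→2, {4,5,6,7}→3, 8→4, 9→5. The map is monotone, so
collapsing can **merge** previously distinct levels (creating ties) but can
never reverse an ordering: `discordant_pairs()` never increases and
`tied_pairs()` never decreases under collapse. This is why mean per-cell
concordance typically drops on the modified scale while per-pair
*agreement* rates rise — the coarser scale is easier to agree on exactly,
but ties carry less ranking information.

Cells wholly or mostly outside the outline are `NA`. A used foot should
have no interior score of 0 (wear begins as soon as a foot is walked on);
`validate_grid()` flags such cells together with out-of-range values.

## Grid placement and the 50 % rule

`fit_grid()` places the grid without manual input:

1. The outline's area centroid and **second area moment** (covariance of
   the uniform measure over the polygon interior) are computed exactly from
   the vertex list. The principal eigenvector gives the long axis.
2. The long axis is oriented toe→heel by a shape cue: the **forefoot is the
   wider half**, so the half with more area is taken as the toe end
   (`toe = "flip"` overrides this).
3. Rows run toe→heel along that axis; the column axis is its +90° CCW
   rotation. The grid's bounding box is the outline's bounding box in this
   frame, split into `rows × cols` equal cells. Cell R1C1 sits at the toe
   corner.

`cell_coverage()` computes the **exact** area fraction of each cell covered
by the outline, via Sutherland–Hodgman half-plane clipping of the outline
polygon against each cell (done per column strip, then per row, for speed)
and the shoelace formula. No rasterization is involved; the per-cell
fractions tile the polygon area to machine precision (the tests require
relative error < 1e-6 over random outlines).

`apply_na_rule()` marks a cell scoreable when its coverage is **≥ 0.5 —
inclusive**. A cell exactly half-filled is scored. This boundary is pinned
by a test (`0.5` scoreable, `0.5 - 1e-12` not).

`classify_cells()` partitions scoreable cells into **border** (at least one
4-neighbour missing or non-scoreable — grid edges count as non-scoreable)
and **interior**, which is how the package quantifies the edge effect on
agreement.

## Reliability statistics

### Tie-corrected Kendall's W

For $m$ raters scoring $n$ items, scores are converted to within-rater
mid-ranks (`rank(ties.method = "average")`). With rank sums $R_i$,

$$S = \sum_{i=1}^{n}\left(R_i - \frac{m(n+1)}{2}\right)^2,
\qquad
W = \frac{12S}{m^2(n^3 - n) - mT},
\qquad
T = \sum_{j=1}^{m}\sum_k (t_k^3 - t_k),$$

where $t_k$ are the tie-group sizes within rater $j$. Two readings of the
correction term circulate in the literature (per-rater $T$ summed over
raters vs a single pooled term); `sachwear` uses the **per-rater sum**,
the only reading under which $m$ identical raters with tied scores give
exactly $W = 1$. The implementation is verified in the tests against a
brute-force from-definitions oracle (500 random instances, 1e-12
tolerance) and cross-checked against `vegan::kendall.global()`.

`kendalls_w()` returns an explicitly undefined result (with a machine
readable `undefined_reason`) instead of a misleading number when:

* `n < 3` after `NA` exclusion (`"insufficient_items"` — two items give a
  degenerate rank space);
* `m < 2` (`"insufficient_raters"`);
* the tie-corrected denominator is ≤ 0, i.e. every rater is constant
  (`"degenerate_ties"`).

The accompanying significance test uses $\chi^2 = m(n-1)W$ with $n-1$
degrees of freedom (Friedman's approximation). No multiple-testing
adjustment is applied across cells or feet; the per-cell $\chi^2$ values
are descriptive and the package reports them as such.

### Two orientations, one statistic

* `per_cell_concordance()`: for each grid cell, items = feet, raters =
  raters. "Do raters agree which feet are more worn *here*?" Feet with an
  `NA` from **any** rater at that cell are excluded **listwise**, and the
  excluded IDs are recorded in the result.
* `per_foot_concordance()`: for each foot, items = its scoreable cells,
  raters = raters. "Do raters agree on the *spatial pattern* of wear?"

### Agreement categories

`categorize_agreement()` bins W into five labels published as
0–0.20 *poor/slight*, 0.21–0.40 *fair*, 0.41–0.60 *moderate*, 0.61–0.80
*good/substantial*, 0.81–1.00 *excellent*. The published bins leave gaps
(0.20–0.21, …) because they were written for two-decimal values; the
implementation closes each gap at its **midpoint**, using half-open
intervals [0, 0.205), [0.205, 0.405), [0.405, 0.605), [0.605, 0.805),
[0.805, 1]. Any two-decimal W lands in its published bin.

### Intraobserver agreement

`intraobserver_agreement()` compares one rater's two sessions cell by cell
across feet, returning per-cell counts of exact agreements and of valid
comparisons. A comparison where both sessions are `NA` is excluded by
default (set `count_na_agreement = TRUE` to count it as agreement — both
conventions appear in practice; the default is the stricter one).

## The simulator

The simulator exists so every statistic above can be exercised, with known
ground truth, without a single photograph. It emulates the *structure* of
a wear-scoring study — it is not a biomechanical model.

* **Outlines** (`make_foot_outline()`): a smooth, mildly asymmetric foot
  silhouette parameterized by length (px) and width ratio, with seeded
  low-frequency perturbations. Toe at the top (y = 0), heel at y = length.
* **Wear fields** (`make_wear_field()`): continuous intensity =
  baseline + **keel bump** (Gaussian, amplitude 6, radius 30 px, centred a
  fixed **140 px from the heel** — anchored to the keel hardware, so its
  *relative* position shifts toward mid-foot on shorter feet) + **edge
  band** (amplitude 3 within 12 px of the outline — exposed rims abrade
  fastest) + smooth random noise (SD 0.4, correlation length 40 px),
  clamped at 0. The design maximum (baseline + both amplitudes = 10) sets
  the default score thresholds, equally spaced over (0, design max).
* **True grids** (`render_true_grid()`): per-cell mean intensity by
  quadrature, thresholded to ordinal levels; used feet always score ≥ 1;
  `NA` from the 50 % rule.
* **Raters** (`rater_model()`, `simulate_rater()`): each rater has a
  systematic bias, ordinal noise (SD on the level scale, default 0.5), a
  grid **misalignment** — a shift expressed in *cell units* (default
  U(−0.25, 0.25) per axis) plus a small rotation (±2°) — and a lapse rate
  (default 0.01) replacing a score with a uniform draw. Misalignment is in
  cell units, not px, so its effect scales with foot size as a human
  misplacement would. Misaligned raters also re-derive their own `NA`
  mask, which is what produces the border-cell agreement penalty.
* **Panels** (`sim_config()`, `simulate_panel()`): defaults are the
  package's reference study conditions — 48 feet × 4 raters (or any
  shape), foot lengths U(180, 260) px, width ratios U(0.38, 0.48), one or
  more sessions. Every (foot, rater, session) gets an **independent
  derived seed stream**, so adding a rater or session never perturbs
  existing data, and a panel is byte-reproducible from its config. Ground
  truth (outline, field, placement, true grid) is attached as an
  attribute.

Seeds must be below 2^31; all seeding goes through `withr::with_seed`, so
library calls never disturb the caller's RNG state.

## Parameters at a glance

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `rows × cols` | 20 × 10 | cells | standard scoring grid |
| coverage threshold | 0.5, inclusive | fraction | 50 %-fill scoreability rule |
| `foot_length_range` | 180–260 | px | typical photographed plantar lengths |
| `keel_offset` | 140 | px from heel | keel is fixed hardware, not proportional |
| `keel_amplitude`, `keel_radius` | 6, 30 | levels, px | dominant distal wear site |
| `edge_amplitude`, `edge_width` | 3, 12 | levels, px | rim abrasion band |
| field `noise_sd`, `noise_scale` | 0.4, 40 | levels, px | foot-to-foot texture variation |
| rater `noise_sd` | 0.5 | levels | about half a rubric step |
| rater shift | U(−0.25, 0.25) | cells/axis | plausible manual grid placement error |
| rater rotation | ±2 | degrees | plausible manual alignment error |
| `lapse_rate` | 0.01 | probability | occasional transcription slips |

## Known limitations

* The simulator's outlines and fields are stylized; absolute W values from
  it characterize the *method under the stated noise model*, not any
  particular rater population.
* Grid fitting assumes a roughly convex, elongated outline with a wider
  forefoot; exotic silhouettes may need `toe = "flip"`.
* The $\chi^2$ test is an approximation that weakens for small $n$; with
  the n ≥ 3 rule the package will compute it, but p-values at very small
  $n$ should be read cautiously.
* Intraobserver analysis supports exactly two sessions per rater.
* Some test suites in this package use smaller panels (e.g. 12 feet × 3
  raters) than the reference defaults purely to keep runtimes short; the
  defaults themselves are the study-scale conditions and are exercised in
  the end-to-end tests and in `scripts/acceptance.R`.
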