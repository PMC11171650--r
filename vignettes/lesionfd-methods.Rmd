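---
title: "Methods: box-counting fractal dimension for lesion screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: box-counting fractal dimension for lesion screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionfd)
```

## The model

`lesionfd` treats the silhouette complexity of a pigmented skin lesion as
a one-number feature: the Minkowski–Bouligand (box-counting) dimension of
its binary mask,

$$D_b = \lim_{\varepsilon \to 0} \frac{\log N(\varepsilon)}{\log(1/\varepsilon)},$$

where $N(\varepsilon)$ is the number of grid boxes of side $\varepsilon$
containing at least one foreground pixel. On a raster the limit is
unreachable, so $D_b$ is the ordinary least-squares slope of
$\log N(\varepsilon)$ against $\log(1/\varepsilon)$ over a finite schedule
of box sides. The assumption doing the work downstream is that malignant —
and especially melanocytic — lesions have more space-filling, irregular
masks than benign ones, so their $D_b$ distribution is shifted upward.
Everything after the estimator (rank tests, ROC screening, the two-stage
decision rule, clustering) consumes only the `(id, diagnosis, fd)` record
table.

## Imaging parameters

* `target_side = 512` px: every image is resized (bilinear, aspect
  deliberately not preserved) to a common lattice before binarization, so
  box schedules are comparable across images.
* Binarization defaults to Otsu's between-class-variance threshold with
  the lesion as the *darker* class; `invert = TRUE` handles light-on-dark
  inputs and `method = "fixed"` pins the threshold for reproducibility
  experiments. Otsu was chosen because it is parameter-free and standard
  for dermoscopy masks; the upstream acquisition protocol is not something
  this package can reconstruct, so the threshold used is always recorded
  on the mask and in batch output.
* Background elimination keeps the largest 8-connected component
  (removing hair/bubble speckle) and fills interior holes by default so
  area-style counting is stable. Equal-area ties resolve to the component
  whose first foreground pixel comes earliest in row-major order — an
  arbitrary but deterministic rule.

## Estimator parameters

* Schedules: `dyadic` ($2, 4, \dots, s/2$, the default), `ternary`
  (powers of 3, natural for the Sierpinski fixtures), or `custom`. The
  smallest default box is 2 px, below which pixel noise saturates the
  counts. $D_b$ depends on the schedule, so the series is retained in
  every `fd_estimate` and the scale count is exported per image.
* The grid is anchored at the mask origin. Offset averaging is available
  through `grid_offset` but off by default. Note a subtlety the test
  suite documents: for exactly self-similar fixtures the origin-aligned
  grid is the *special* case (it attains the analytic counts), while
  random offsets land on a nearby, slightly lower slope; the spread
  across random offsets is small (< 0.05 for the level-5 carpet).
* Counting modes: the default counts all foreground pixels of the
  (hole-filled) mask — area or "mass" box counting, consistent with
  covering the lesion itself. `margin_only = TRUE` instead counts the
  mask's morphological gradient, i.e. the boundary curve, for workflows
  that define complexity on the margin. The two modes genuinely measure
  different quantities (a filled square gives 2.0 vs ~1.0) and the choice
  is surfaced rather than hidden.
* A degenerate series with all counts equal yields $D_b = 0$ with
  $R^2$ reported, not an error: single-pixel masks are legal input.

## What the synthetic module emulates

Two generators stand in for an image archive:

* **Analytic rasters** (`make_fractal_mask()`): Sierpinski carpet
  ($\log 8/\log 3$), Sierpinski triangle ($\log 3/\log 2$), Koch curve
  ($\log 4/\log 3$, rasterized at 1-px stroke on a 729-px canvas), filled
  squares/disks (2), axis-aligned lines (1) and seeded random blobs.
  These validate the estimator against closed-form values.
  `render_lesion_photo()` closes the loop through the imaging module:
  dark lesion on a light field plus Gaussian noise, with the precondition
  $|fg - bg| > 4\sigma$ guaranteeing reliable recovery. End-to-end tests
  run with `fill_holes = FALSE` — the carpet's lacunae are the structure
  being measured, and filling them (the right default for real lesions)
  would collapse the fixture to a filled square. The Koch fixture is
  ingested at its native 729-px canvas; resampling a 1-px stroke to 512
  px breaks the curve and biases the slope low.
* **Cohorts** (`make_cohort()`): per class, FD values are drawn from a
  normal centred on the target median, truncated to (1, 2) by
  inverse-CDF sampling (exact, vectorized, bitwise reproducible per
  seed). Only medians and confidence intervals are available for the
  reference cohort, so the distributional shape is an assumption; the
  default spread of 0.08 FD units places the melanoma/non-melanoma
  overlap in a moderately separable regime. `default_cohort_spec()`
  mirrors the 39,270-lesion reference composition at 1/10 scale
  (ceiling-rounded so the 4-image metastatic class survives as one
  record). The five published per-class medians are used verbatim
  (melanoma-family 1.755, Breslow 3 1.859, atypical melanocytic
  proliferation 1.636, and the 1.74/1.651 group aggregates); the seven
  unpublished classes get fixed plausible values consistent with those
  aggregates (nevus 1.645; verrucous, vascular and neurofibroma 1.66;
  squamous and basal cell carcinoma 1.70; Breslow 1/2 1.76/1.80).

What passing tests on these cohorts do **not** show: real dermoscopy FD
distributions are not truncated normals, real masks carry hair, rulers
and gel-bubble artifacts the renderer does not model, and the reference
archive's operating characteristics (AUC 0.67, sensitivity ≈ 72%,
specificity ≈ 50%) are properties of that data, not of this simulation —
the synthetic cohorts are more separable than the real archive.

## Grouping and screening choices

* The benign/malignant mapping includes squamous cell carcinoma in the
  malignant group: the reference cohort's printed totals
  (29,050/10,220) are reproducible only under that assignment, and
  integer arithmetic beats prose; `scc_malignant = FALSE` overrides.
  Breslow-graded lesions sit in the melanoma group for the same reason
  (6,035 = 5,858 + 4 + 150 + 14 + 9).
* Both decision thresholds use a strict `fd > t` rule. The melanoma
  cutoff defaults to 1.755, the reference melanoma-group median. No
  benign/malignant cutoff was ever published, so `t_malignant` is an
  explicit parameter defaulting to 1.74 (the malignant-group median,
  mirroring the same construction).
* Median confidence intervals use the distribution-free binomial
  order-statistic construction. Dunn's post hoc z-tests (with tie
  correction, Holm adjustment) follow the Kruskal–Wallis test when more
  than two groups are compared; with two groups a Mann–Whitney U test is
  run. ROC AUC is computed by trapezoid and is asserted (to $10^{-9}$)
  against the Mann–Whitney $U/(n_1 n_2)$ identity on every call.

## Clustering choices

* "Iterated" K-means is interpreted as 100 random-initialization
  restarts keeping the lowest inertia, with Lloyd sweeps run to
  convergence (max 300) inside each restart — the stronger reading, and
  the default semantics of the common tooling. Initialization is greedy
  farthest-point seeding from a seeded random first centre, which
  reduces restart variance at small k.
* Feature scaling defaults to standardizing both columns, because the
  encoded diagnosis (0–11) and FD (≈1.6–1.9) are incommensurate.
  `scaling = "none"` reproduces the behaviour of running K-means straight
  on a label-encoded spreadsheet — the configuration in which silhouette
  values near 0.8–0.9 arise, since the integer label gap then dominates
  every distance. The quality metrics are only comparable within one
  scaling choice, which is why it is recorded in `glance()` output.
* Clustering on an encoded *diagnosis* leaks label information into an
  unsupervised method; the print method says so and `fd_only = TRUE`
  clusters on FD alone.
* Silhouette uses the standard $(b - a)/\max(a, b)$ with Euclidean
  distances; singletons score 0. PCA standardizes columns and
  decomposes the correlation structure; a zero-variance column is a
  typed error rather than a silent drop.

## Numerical and testing notes

Problem sizes were chosen for desk-scale runs: the 1/10-scale cohort
(3,930 records) for classification and clustering checks, n = 5000 per
class for median-recovery checks (median SE ≈ 0.0014), 200 random 64×64
masks for the box-count oracle sweep, and 2000 decorrelated seeded
replicates for the type-I calibration of the rank test (binomial SE
≈ 0.5%; replicate seeds are drawn once from a frozen stream because
consecutive-integer seeding correlates adjacent cohorts). Grid-offset
draws in the stability test exclude the origin-aligned grid, which is the
one special offset.

## Known limitations

* $D_b$ is schedule- and resolution-dependent; values are comparable only
  within one configuration, which the batch output records per image.
* The imaging front end assumes a single dominant lesion darker than the
  surrounding skin; multi-focal lesions lose all but the largest
  component.
* The renderer does not model dermoscopy artifacts, so imaging-stage
  robustness claims extend only to additive Gaussian noise.
* The metastatic/non-metastatic contrast is structurally data-starved
  (4 metastatic records in the reference composition, 1 in the default
  simulation) and is exposed but not asserted on.
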