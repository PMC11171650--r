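# lesionfd

Box-counting fractal dimension analysis and classification of
dermatological lesion images.

Pigmented skin lesions differ in the irregularity of their silhouette:
melanocytic malignancies tend to produce more complex, space-filling
outlines than benign nevi. `lesionfd` quantifies that irregularity with a
single per-lesion feature — the Minkowski–Bouligand (box-counting) fractal
dimension of the binarized lesion mask — and carries it through a complete
screening pipeline: rank-based group comparisons, ROC threshold screening,
a two-stage decision rule (benign/malignant, then melanoma/non-melanoma),
and unsupervised structure discovery with PCA and iterated K-means. It is
aimed at researchers evaluating fractal-dimension screens on dermatoscopic
archives such as ISIC, and it ships a synthetic-data module so every stage
is testable without any image archive.

## The statistic

For a binary lesion mask, cover the plane with a grid of boxes of side
*ε* and let *N(ε)* be the number of boxes containing at least one
foreground pixel. The box-counting dimension is

```
D_b = lim_{ε→0} log N(ε) / log(1/ε)
```

estimated at finite scales as the least-squares slope of log *N(ε)*
against log(1/*ε*) over a schedule of box sizes (dyadic by default). A
filled region gives *D_b* = 2, a smooth curve 1, and fractal boundaries
fall in between; the level-5 Sierpinski carpet's analytic value
log 8 / log 3 ≈ 1.8928 is recovered exactly.

Images enter the estimator through a fixed preprocessing chain: decode →
8-bit grayscale at 512×512 (luminance weighting, bilinear resize) → Otsu
binarization (lesion is the darker class) → background elimination
(largest 8-connected component, optional hole filling).

## Worked example

```r
library(lesionfd)

# 1. validate the estimator on an analytic fractal
carpet <- make_fractal_mask("sierpinski_carpet", 5)   # 243 x 243, 8^5 px
estimate_fd(carpet, box_schedule(243, "ternary"))
#> <fd_estimate> D_b = 1.8928 (R^2 = 1.0000, 4 scales, sierpinski_carpet_5)

# 2. simulate a diagnosis-labelled cohort (1/10-scale ISIC composition)
cohort <- make_cohort(default_cohort_spec(), seed = 1)   # 3,930 records

# 3. compare melanoma vs non-melanoma FD distributions
compare_groups(cohort, "melanoma_nonmelanoma")
#> <lesion_group_test> Mann-Whitney U on 'melanoma_nonmelanoma' grouping:
#>   statistic 1656585.000, p = 8.77e-142
#>   melanoma      n =  605  median 1.75 [1.75, 1.76]
#>   non-melanoma  n = 3325  median 1.65 [1.65, 1.65]

# 4. ROC screen with the strict fd > t rule
roc <- roc_curve(cohort, "melanoma_nonmelanoma", positive = "melanoma")
roc$auc                                   # 0.8235
roc_operating_point(roc, 1.755)           # sens 0.476, spec 0.889

# 5. two-stage decision screen and clustering
screen_cohort(cohort)                     # per-stage confusion table
grouped <- assign_groups(cohort, "benign_malignant")
km <- kmeans_stage(encode_labels(grouped, "group"), k = 2,
                   restarts = 100, seed = 2, scaling = "none")
glance(km)
#>   k inertia silhouette restarts seed scaling
#>   2    27.4      0.907      100    2 none
```

The Mann–Whitney p-value and the median gap (1.75 vs 1.65) show the
simulated melanoma group carries systematically higher FD; the AUC of 0.82
is the separability implied by the simulation's class medians and spread.
At the melanoma cutoff 1.755 (the melanoma-group median), the strict
greater-than rule trades sensitivity (0.48) for specificity (0.89) on this
cohort. With raw label codes alongside FD — the configuration in which
published silhouette values near 0.8 arise — K-means at k = 2 recovers the
benign/malignant split with silhouette 0.91 and perfect cluster purity.

Every fitted object has `tidy()`/`glance()` methods and an `autoplot()`;
`run_pipeline()` orchestrates simulate → classify → cluster with a JSON
manifest, and `inst/cli/lesionfd.R` exposes the same stages as shell
subcommands (`simulate`, `compute-fd`, `classify`, `cluster`).

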