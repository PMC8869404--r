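---
title: "Profiling microglia: morphometry, clustering and transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling microglia: morphometry, clustering and transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaProfiler)
```

## The problem

Microglia change shape with their activation state: surveillant cells are
highly ramified, with long thin processes covering a wide territory, while
activated and reactive cells retract their processes, enlarge the soma and
drift towards amoeboid outlines. Because morphology tracks state, a
quantitative morphometric profile of Iba-1-labelled cells — together with a
transcriptomic readout of sorted microglia — is a standard way to ask
whether a disease model carries an altered microglial compartment.

gliaProfiler implements that workflow end to end for 2D binary single-cell
masks and bulk count matrices:

1. **Morphometry** — 25 named per-cell features: 10 from the skeletonised
   cell (branch counts, voxel classes, path lengths, the Euclidean chord of
   the longest branch, triple/quadruple points) and 15 from the full mask
   (fractal dimension, lacunarity, density, convex-hull geometry, bounding
   circle, radii, area, perimeter, circularity).
2. **Statistical learning** — per-feature Student t screening, PCA,
   k-means with elbow selection of the cluster number, and nested
   cross-validated gradient boosted trees with gain importance.
3. **Transcriptomics** — reads-per-million normalisation, moderated
   differential expression with the joint |FC| / p / FDR filter,
   directional gene-set overlap (Fisher's exact test with a Baptista–Pike
   odds-ratio interval), marker-panel purity and qPCR ΔΔCt fold changes.
4. **Synthetic generators** — seeded simulators for masks, feature tables,
   count matrices and direction-annotated gene sets, so that every stage is
   testable without imaging or sequencing data.

## Morphometric conventions

Several quantities on a pixel raster admit more than one convention; the
package fixes them as follows and exposes flags where alternatives are
common.

**Skeleton.** Masks are thinned with a Zhang–Suen-style two-subcycle
scheme under 8-connectivity. Skeleton pixels are classified by their
neighbour count — endpoint (≤ 1), slab (2), junction (≥ 3) — after a
*triangle reduction*: a diagonal adjacency is ignored when the two pixels
are also connected through an orthogonal common neighbour. Without this
reduction every sharp right-angle corner of a one-pixel path would read as
a spurious junction. Branch path length uses the 1/√2 step metric times
the calibration (default 0.31 µm/px, a 40× confocal field of
624.39 × 624.39 µm at 1024 × 1024 px). Per cell, the "Euclidean distance"
feature is the endpoint-to-endpoint chord of the *longest* branch — the
path/chord contrast indexes tortuosity; the chord can never exceed the
path length, which is asserted as an invariant. Junction pixels are
grouped into 8-connected clusters, and triple/quadruple points are
clusters with exactly 3 or 4 incident branches.

**Perimeter and circularity.** The cell perimeter is measured on the
Moore-traced outer boundary. The raw chain-code length (1 per orthogonal,
√2 per diagonal step) systematically overestimates smooth outlines by
about 5 %, which would push a disc's circularity (4πA/P²) down to ≈ 0.90.
The default is therefore the Vossepoel–Smeulders corrected chain length
(0.980·N_even + 1.406·N_odd − 0.091·N_corner), which brings a digital
disc to circularity 1.00 ± 0.02; the raw chain and a 4-direction Crofton
estimate remain available via `perimeter_method`. The transformation
index is the exact reciprocal of circularity; the identity
TI × circularity = 1 is tested to 10⁻⁹. The corrected estimator trades a
small bias on axis-aligned rectangles (a 100 × 2 bar reads ≈ 196 against
the 200 of its pixel-centre polygon) for near-unbiasedness on curved
outlines, the relevant regime for cells.

**Hull metrics.** The convex hull is taken over foreground *pixel
centres* (monotone chain via `grDevices::chull`). A consequence worth
knowing: density (foreground pixels / hull area) can exceed 1 for convex
blobs, because the pixel-count numerator measures pixel squares while the
denominator is the vertex polygon; we deliberately do not assert
`cell_area ≤ convex_hull_area`. The bounding circle is the exact minimum
enclosing circle (Welzl's algorithm) of the hull vertices, so its
diameter always dominates the maximum span. Radii statistics are measured
from the hull's area centroid; the span ratio is the maximum span divided
by the hull width perpendicular to the span direction.

**Fractal dimension.** Box counting over a ladder of sizes (default
powers of two up to half the image side) with several grid offsets per
size. At each size we take the *minimal* cover across offsets — the box
count is defined as the smallest number of boxes covering the set, and a
fixed origin systematically overcounts; offset-averaging would bias a
filled square's dimension down to ≈ 1.8, while the minimal cover
recovers 2.0 exactly, 1.0 for a line, and log 8/log 3 for the depth-4
Sierpinski carpet on its natural ladder {3, 9, 27, 81}.

**Lacunarity.** Sliding-box (σ/μ)² of foreground mass, stride 1, averaged
over sizes, computed over the cell's *bounding box*. Restricting the
window domain matters: over a full canvas the measure is dominated by how
much empty background surrounds the cell, not by the cell's own gappiness;
within the bounding box a ramified cell is strictly more lacunar than a
filled disc of equal area in every seeded draw we test. Some lacunarity
implementations report Λ + 1; ours reports the bare (σ/μ)² (0 for any
homogeneous mass).

## The statistical-learning stage

Features are z-scored before PCA and k-means — they span µm, µm² and
dimensionless ratios, so unstandardised Euclidean distances would be
dominated by the large-magnitude features. Screening uses the classical
pooled-variance two-tailed t-test at α = 0.05.

**Elbow rule.** The historical "largest drop" reading of the MSE-vs-k
plot is degenerate: for any convex decreasing curve the largest drop is
always at k = 2. It is kept (`rule = "largest_drop"`) because it is what
elbow plots are usually read as, but the default is a knee rule on the
*log* MSE curve: the k maximising
log MSE(k−1) − 2·log MSE(k) + log MSE(k+1). On the log scale a
structureless geometric decay is exactly flat (the rule then falls back
to k = 2 with a low-confidence warning), and proportional-drop collapse
is scale-free, so the rule also recovers k = 4 on four well-separated
blobs, where the raw second difference would stay glued to k = 2. On
two-population morphology tables at the study's group sizes (310 + 389,
3-SD shifts on the 14 affected features) both rules select k = 2 in
100/100 seeded replicates.

**Boosted trees.** The classifier is gradient boosting with logistic
loss, depth-limited trees and per-tree column subsampling (xgboost), with
hyperparameters chosen by 5 × 5 nested stratified cross-validation; the
default grid includes the configuration that wins on this problem (100
estimators, depth 2, learning rate 0.1, 1/5 of columns per tree). Inner
selection uses accuracy with ties broken towards fewer rounds and
shallower trees. Gain importance is normalised per outer-fold model and
averaged; on label-permuted data the outer accuracy stays within binomial
noise of 0.5 (the leakage guard), and a single informative feature takes
at least 80 % of the total gain.

## The transcriptomics stage

Counts are scaled to reads per million per sample. Differential
expression is tested on log2(RPM + 1). The default test is a moderated
t: per-gene pooled variances are shrunk towards a prior estimated from
the ensemble of variances by matching the moments of log s² (scaled-F
theory, trigamma inversion), and the statistic is referred to a t
distribution with the summed degrees of freedom. The choice is forced by
the design: at 3–4 replicates per group an unmoderated Welch test cannot
jointly satisfy p < 0.05 and FDR < 0.1 for most 4-fold effects (measured
sensitivity ≈ 0.4), while moderation restores near-complete power — the
same reason empirical-Bayes pipelines are the field standard at this
sample size. `method = "welch"` is available, and the moderated p-values
are cross-checked in the test suite against an independent
empirical-Bayes implementation (limma) on a common fixture.

Fold changes use the signed linear convention: |FC| ≥ 1 always, the sign
encodes direction. The DEG filter is the literal
|FC| > 1 ∧ p < 0.05 ∧ FDR < 0.1; the fold-change threshold is a config
knob because the literal value of 1 excludes only exactly-equal means.
One consequence the reader should expect: with Benjamini–Hochberg control
at FDR < 0.1, roughly 10 % of the passing list are nulls *by design* —
on the synthetic study-scale simulation (20,000 genes, 4 vs 4, 83 up and
18 down planted at |log2FC| = 2, dispersion 0.05) the filter recovers a
median of 101/83/18 of the planted genes while passing ≈ 112 genes in
total, with the observed false-discovery proportion at the nominal 0.1.

Overlap statistics condition on the 2 × 2 table of two gene lists over a
stated universe (default 23,930, a targeted mouse transcriptome panel of
20,767 RefSeq plus 3,163 XM/XR models). The two-sided Fisher p uses the
point-probability rule and is verified against exhaustive hypergeometric
enumeration for all tables with margins ≤ 12 (|Δp| < 10⁻¹⁰). The
Baptista–Pike odds-ratio interval inverts the point-probability test of
the noncentral hypergeometric likelihood by bisection on the log odds
ratio; zero marginal cells yield explicit one-sided bounds (0 or ∞), and
the interval's coverage is conservative (≥ 95 %) in simulation.
Direction concordance counts shared genes with equal direction labels;
gene symbols are matched case-insensitively after whitespace stripping,
with mouse-style capitalisation preserved on output.

## What the synthetic generators emulate — and what they do not

The mask generator grows a soma disc plus persistent random-walk
processes (heading jitter ~ N(0, tortuosity), optional one-level
secondary branching) and stamps them at a chosen thickness. Its two
presets bracket the biology — "ramified" (6 primaries, 60 ± 10 px,
thickness 1) vs "activated" (2 primaries, 15 ± 5 px, thickness 3, larger
soma) — and reproduce the direction of every reported group effect:
activated cells have higher median density and circularity and lower
total branch length, hull area, span and lacunarity across seeds. The
feature-table generator is a fast multivariate-normal surrogate whose
default plants 3-SD shifts on the 14 affected features (all decreased in
the disease phenotype except density and circularity); baseline means are
plausible wild-type values, but since effects are specified in SD units
the absolute scale is immaterial to the downstream statistics. The count
generator is gamma-Poisson with log-normal baselines
(meanlog = log 500, sdlog = 1 — the moderate spread of a targeted
amplicon panel; dispersion is a user knob, default 0.05).

None of these emulate staining artefacts, intensity variation,
point-spread blur, touching cells, 3D structure, or correlated feature
noise; passing tests demonstrate that the *computations* are correct and
that effects of the stated size are recoverable, not that real images of
real tissue would yield the same numbers. The study's real-data
quantities that depend on the unavailable images (per-feature p-values,
the 91.7 % first principal component, the ≈ 70 % classifier accuracy)
are therefore not reproduced, only the procedures that computed them.

## Numerical choices and degenerate inputs

* Deterministic generators: every simulator is a pure function of its
  parameters and an explicit seed (`withr::with_seed`); identical calls
  are bit-identical.
* Empty masks, multi-component masks, degenerate hulls (< 3 non-collinear
  pixels), zero-total library columns, overlapping planted gene sets,
  undersized canvases and missing direction annotations all raise classed
  errors with explicit messages rather than propagating NaNs.
* Constant features report p = 1 with a warning; all-zero genes are
  flagged `tested = FALSE` and excluded from the multiplicity correction.
* k-means at the extremes bypasses Lloyd iterations (k = 1 and k = n have
  closed forms); MSE is total within-cluster sum of squares divided by n,
  and is non-increasing in k at 10 restarts on the scales we test.
* The problem sizes used by the test-suite simulations (100 seeds for the
  elbow recovery, 20 for DEG recovery, 25–100 for the mask Monte-Carlo
  checks, 800 tables for interval coverage) were chosen so the whole
  suite completes in a few minutes while keeping Monte-Carlo error well
  inside the asserted margins.

## Known limitations

* 2D only; images are assumed Z-projected before masking.
* The skeleton voxel-class counts follow the reduced-adjacency
  convention above; tools that count raw 8-neighbours will report more
  junction voxels on the same skeleton.
* The per-branch Euclidean distance is summarised per cell by the chord
  of the longest branch (the mean across branches is available in the
  `skeleton_graph`); other summaries exist in the literature.
* FracLac-style grid sampling details (number of grid positions,
  box-size ladders, the optional +1 in lacunarity) vary between tools;
  ours are documented above and configurable, so absolute fractal
  dimension and lacunarity values should only be compared within one
  convention.
* The DEG stage models two unpaired groups with a single contrast; no
  covariates, pairing or batch terms.

## A worked example

```{r, eval = FALSE}
library(gliaProfiler)

# morphology arm on a synthetic two-phenotype table
sim <- simulate_morphology_table(seed = 1)
rep <- run_morphology_arm(sim$table)
rep$elbow$chosen_k          # 2
rep$gbt$accuracy            # ~1 on 3-SD synthetic effects
head(gain_importance(rep$gbt))

# transcriptomics arm at the study scale
cs  <- simulate_count_matrix(seed = 1)
rna <- run_rnaseq_arm(cs$counts,
                      setNames(as.character(cs$groups), colnames(cs$counts)))
rna$degs$n_up; rna$degs$n_down

# directional overlap of two published-model DEG lists
a <- read_gene_set_csv(system.file("extdata",
  "overlap_mjd_vs_als_mjd_directions.csv", package = "gliaProfiler"))
b <- read_gene_set_csv(system.file("extdata",
  "overlap_mjd_vs_als_als_directions.csv", package = "gliaProfiler"))
direction_concordance(a, b)[c("concordant", "discordant", "overlap")]
```
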