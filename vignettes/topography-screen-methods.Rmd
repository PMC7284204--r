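---
title: "Methods: from micro-topography designs to macrophage response models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from micro-topography designs to macrophage response models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topomacro)
```

`topomacro` implements a complete in-silico counterpart of a high-content
micro-topography screen of human macrophage attachment and M1/M2
polarization: design generation, surface-descriptor extraction, image-based
cell quantification, response aggregation and filtering, clustering, and
descriptor-to-response regression with Shapley-value attribution. This
vignette explains the models and the numerical choices behind each stage.

## The design grammar

A topography is a square *feature block* (default edge 29 µm) carrying
primitives — circles, equilateral triangles (parameterized by their
circumscribing diameter) and rectangles — each sized within 3–23 µm, at a
common pillar height of 10 µm. Primitives are sampled uniformly: shape from
the configured shape set, sizes from the size bounds, rotation from
[0°, 360°), position uniform under the constraint that the circumscribing
circle fits inside the block (rejected and resampled otherwise, with a
bounded attempt budget). Primitives may overlap; the rasterized union defines
the pillars, so an 8-connected component — not a primitive — is the unit of
all shape measurements. The default of 1–3 primitives per block was chosen
because overlap merging makes denser compositions collapse into single large
blobs, which narrows the realized diversity of pillar sizes and spacings;
the count distribution, like every other grammar parameter, is configurable.

Blocks tile periodically into TopoUnits. The chip pitch is 300 µm with a
290 µm patterned interior (both retained in configuration; descriptor
extraction uses the patterned interior). A chip is a 66 × 66 grid: 2176
unique designs, each placed twice, plus 4 flat control slots. "Diagonal
duplicates" is implemented as the fixed involution
`(r, c) -> (r + 33, c + 33) mod 66`, which pairs the grid into 2178 orbits
of size two; flat controls occupy whole orbits (default: the corner orbits
of one quadrant diagonal), so the layout is invertible by construction.

Rasters use 10 px per µm, a top-left origin, and a pixel-center point-in-shape
test: a pixel is foreground exactly when its center lies inside a primitive.
Rasterized circle areas then agree with πr² to well under 0.5 % for d ≥ 3 µm
at generic positions (a boundary threading exactly through pixel centers is a
measure-zero alignment and is avoided in fixtures), and axis-aligned
rectangles rasterize exactly.

## Surface descriptors

Shape descriptors are computed per 8-connected component of the block raster
and summarized per design (mean, median, min, max, 25th/75th percentiles):
pillar top area ("Pattern Area"), perimeter, form factor 4πA/P², moment
eccentricity, solidity, and min/max Feret diameters; plus pillar count,
pillar density, coverage, and the construction parameters of the grammar.
The full roster is emitted with a manifest (name, unit, definition) rather
than hard-coding any particular descriptor count.

Two numerical choices deserve a note:

* **Perimeter.** Chain-code lengths overestimate smooth digital boundaries
  (a digital circle's 8-chain is ≈ 5 % longer than πd, pushing its form
  factor to ≈ 0.90), while orientation-calibrated weightings distort
  axis-aligned squares. We therefore measure the length of the Moore contour
  after a circular moving average (window 5): a digital circle of d = 10 µm
  then yields a form factor of 1.016 and a 10 µm square 0.816 (analytic
  π/4 ≈ 0.785) — both within the tolerance used by the tests, and stable in
  µm units under raster-scale doubling to ≈ 1 %.
* **Solidity.** The convex hull of pixel centers misses the outer
  half-pixel band, so the hull area gets a Pick-style boundary correction
  (+ perimeter/2 + 1) before the area ratio is formed.

**Spacing (maximum inscribed circles).** The spacing between pillars is
quantified by iteratively inscribing the largest circle in the open (non
pillar) region: invert the tiled raster, downscale by 5 (block mean,
foreground at ≥ 0.5), then repeat: find the free pixel with the largest
exact Euclidean distance to the nearest pillar pixel or to the virtual
obstacle ring just outside the frame (ties broken at the smallest (row,
col)); record a circle of that diameter; remove its strict interior (so
later circles may touch but not overlap); stop when the next diameter falls
below 3 working pixels. The distance field is maintained exactly and
incrementally: removing a disk can only lower distances within twice its
radius of its center (the disk was the global distance maximum), so only a
local transform seeded by the removed pixels is recomputed and min-combined.
The sequence is identical to a full recomputation and to a brute-force
oracle that minimizes distances by direct scan, and runs in tens of
milliseconds per design. Spacing descriptors are computed on a 2 × 2-tiled
block window (116 × 116 working pixels): the pattern is periodic, so this
window carries the same spacing structure as a full 290 µm unit at ~25× less
cost; the window is configurable.

**Pruning.** Descriptors are pruned by pairwise Pearson correlation at
|r| ≥ 0.85: constant columns are removed first (undefined correlation), then
greedily, from the most-correlated remaining pair, the member with the
larger mean absolute correlation to all other retained descriptors is
dropped (ties keep the earlier, manifest-order column) until every retained
pair is below the threshold. The paper-scale roster prunes from ~60 raw
descriptors to ~20 retained ones under the default grammar. Note the
retained set keeps one *representative per correlation cluster* — a driver
descriptor may be represented by a tightly correlated surrogate (e.g. the
minimum Feret diameter for the minimum pattern area, r ≈ 0.94), which
matters when interpreting feature rankings (see `match_drivers()`).

## Image quantification

Frames are four-channel (nuclei / membrane / M1 marker, a calprotectin
proxy / M2 marker, a mannose-receptor proxy), 280 × 280 µm. Illumination is
corrected by dividing out a large-kernel Gaussian estimate of the
multiplicative background (σ = edge/8), preserving the channel mean, with a
floor (default 10⁻³) against degenerate estimates. Nuclei are detected by a
robust-background global threshold — trim the dimmest and brightest 5 %,
then mean + 2 SD of the remainder — followed by 8-connected labeling and an
area filter (20–400 µm², configurable; the trim fractions and the SD
multiplier are configurable too, since the upstream tool's exact values are
not published). Cells are demarcated by seeded propagation of the nuclear
labels through the membrane channel restricted to an above-background mask
(the CellProfiler-family propagation/watershed approach; exactly one region
per seed, regions disjoint). Cells touching the one-pixel frame border are
flagged and excluded from attachment counts; marker values are per-cell
means inside the cell mask. Out-of-focus rejection (manual in the original
workflow) is replaced by an optional variance-of-Laplacian score, disabled
by default.

## The synthetic screen

The generator plants the structure–function rules the screen is built to
recover, at the study's stated conditions: flat controls attach ≈ 6
cells/unit; attachment across designs ranges from over 100 cells down to
fewer than 10; five donors; normalized M2/M1 ratios span ≈ 0.41–2.13 with
flat surfaces at 1.2.

* **Attachment.** Expected cells/unit is unimodal in the effective pillar
  diameter d\* = √(4·PatternArea_mean/π): a Gaussian bump at 5 µm (width
  3 µm) times a logistic suppression above 10 µm (width 1 µm), times a
  density modulation 0.6 + 0.4·logistic((26 − spacing)/5) where spacing is
  the largest inscribed-circle diameter (denser patterns attach more), all
  scaled between the flat baseline (6) and an asymptote of 240 cells/unit.
  The bump width, modulation midpoint and asymptote were fixed once by
  forward simulation so that the library's top decile exceeds 100 cells and
  its bottom decile stays under 10 under the default grammar.
* **Phenotype.** The expected M2/M1 ratio is
  1.2 − 1.4·[log(A_min + 80) − log(260)] − 1.4·log(spacing/22), clipped to
  [0.41, 2.13]: it falls with the smallest pillar area and rises with pillar
  density, so small dense pillars plant an M2 bias and large sparse features
  an M1 bias. The 80 µm² offset damps the otherwise unbounded log boost of
  tiny pillars; coefficients were fixed by the same one-off calibration so
  the realized ratios span the stated range.
* **Noise.** Counts are negative-binomial (size 10) around the expectation
  scaled by a lognormal donor effect (σ = 0.25) and a lognormal replicate
  effect (σ = 0.10); marker means decompose the ratio symmetrically
  (m1 = 100/√ratio, m2 = 100·√ratio) under per-donor-per-channel lognormal
  effects (σ = 0.20) and per-unit noise (σ = 0.10). These families were
  chosen for overdispersed counts and strictly positive intensities; the
  magnitudes are plausible placeholders (real inter-donor variances are not
  published) and all are configurable. Setting every σ to zero and the
  dispersion to ∞ makes the screen deterministic — a property the tests use.

The generator also renders single-unit fluorescence frames with ground-truth
masks (Gaussian nuclei, membrane disks with a rim, exact uniform marker
fills) for validating the quantification stage. What passing tests on these
synthetic data do *not* show: robustness to real-world segmentation hazards
(touching and overlapping cells, debris, focus drift, autofluorescence), to
unmodeled spatial artifacts (edge effects, meniscus gradients beyond a
linear/multiplicative field), or to biology outside the planted parametric
rules.

## Aggregation, filtering, clustering

Per donor and chip, counts and marker means are normalized by that
donor/chip's mean over flat units; the two diagonal replicates are averaged
per design; means, SDs and SNR = mean/SD are then taken across donors. The
SNR < 2 exclusion is applied to the attachment SNR (the cross-donor level —
the level at which the denominator is taken is configurable, as the original
description leaves it open). Marker means are floored at the 1st percentile
of positive values before ratios, guarding log(0). The composite response is
log(M2/M1, flat-normalized) × mean attachment, natural log (the log base
only rescales the composite; sign and ordering are unchanged). An optional
low-attachment override can retain bottom-decile designs whose absolute SD
is small; it is off by default because the original "carefully moderated"
rule is not algorithmic.

Attachment classes use k-means (k = 3, 10 restarts, fixed seed; if the
number of distinct values equals k each value is its own cluster), relabeled
high/medium/low by descending cluster mean. Phenotype classes use
agglomerative clustering on the standardized (ratio, attachment) plane with
Euclidean distance and Ward linkage (the original reports only the metric;
Ward is the variance-minimizing default for compact classes), labeled
M2-biased/M0/M1-biased by descending cluster-mean ratio; constant input is a
documented error rather than a silent single cluster. Donor consistency is
the mean pairwise Spearman correlation of per-donor design rankings by mean
attachment.

## Models and attribution

Both tree-ensemble families are fitted through xgboost on a random 70/30
split (by design, unstratified, seed recorded): gradient-boosted trees
(500 rounds, depth 6, learning rate 0.05, 80 % row/column subsampling) and a
random forest expressed in the same machinery (one round of 500 parallel
trees, depth 20, bagging at 0.632, one third of features per split). Using
one engine for both families gives exact TreeSHAP attributions uniformly via
`predict(..., predcontrib = TRUE)`. Hyperparameters are configurable and
recorded in the fitted object. Feature rankings order descriptors by mean
absolute Shapley attribution (ties by manifest order); the additivity of
attributions to the predictions is asserted at 10⁻⁵ relative to the
prediction scale — tree scoring is single-precision, which bounds the
achievable reconstruction accuracy with 500 trees. Feature selection keeps
the top-n (default 20) or a cumulative-attribution prefix, followed by a
refit on the retained set. The top-50/bottom-50 composite contrast tests
every descriptor with a two-sample Wilcoxon rank-sum test under
Benjamini–Hochberg adjustment at 0.05 (the adjustment is a package choice;
the original states only "statistically significant").

Because pruning keeps one representative per correlation cluster,
driver-recovery checks map each top-ranked feature back to the planted
driver it tracks (|r| ≥ 0.85 across the descriptor matrix, the pruning
threshold itself) via `match_drivers()` rather than requiring the planted
column name verbatim.

## Problem sizes and reproducibility

The default pipeline scale is the full chip: 2176 designs × 2 + 4 flats on a
66 × 66 grid, five donors. Descriptor extraction for the full library takes
on the order of two minutes on a single core; the test suite exercises the
same code mostly at reduced library sizes (10–500 designs) chosen to keep
each property sharp, and the whole-pipeline smoke test runs 48 designs on a
10 × 10 grid. Every stochastic step takes an explicit seed; rerunning any
stage — or the whole pipeline — with the same configuration reproduces
byte-identical output tables, and each run directory archives the resolved
configuration with its hash.

## Known limitations

* Descriptors are computed from design rasters; the original workflow also
  measured bright-field micrographs of fabricated surfaces, so
  fabrication-induced deviations (rounded corners, undercuts) are outside
  this package's scope — a deliberate substitution.
* The exact published 65-descriptor roster and the true primitive
  composition distribution of the original chip are not public; the package
  reproduces the generative grammar and the pruning rule, not those exact
  artifacts, and its headline numbers are therefore properties of the
  synthetic screen, not re-derivations of the published R² values.
* The planted response surfaces are smooth parametric stand-ins for
  biology; they encode the reported qualitative rules (pillar size optimum,
  size cutoff, density-phenotype coupling), not a mechanistic cell model.
* Segmentation is tuned for the synthetic frames' morphology; real imagery
  would need channel-specific parameter tuning and out-of-focus screening.
* Shapley attributions split credit among correlated descriptors, and the
  generator plants the pattern-area rule through two statistics (the mean
  area drives the attachment bump, the minimum area the phenotype ratio).
  Their retained surrogates can therefore occupy several top ranks at once
  and push the (weaker) spacing driver past rank 3 in some library draws:
  whether the top-3 ranking shows both driver families is sensitive to the
  random library, even though the spacing driver is always recovered within
  the leading handful of features. `match_drivers()` exists to make the
  cluster mapping behind any such claim explicit.
* Flat-controls are few (the 66 x 66 grid leaves exactly 4 slots next to
  2 x 2176 design placements), so per-donor flat normalization carries
  appreciable sampling noise; this lowers the SNR of every normalized
  response and makes the retained-unit set vary between screens.
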