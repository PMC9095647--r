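---
title: "Processing multi-round immunofluorescence images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing multi-round immunofluorescence images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cyclicproc)
```

This vignette documents the models, parameter choices and numerical
conventions behind `cyclicproc`, and what the synthetic-data validation
does and does not establish about real data.

## The processing model

A cyclic immunofluorescence (CyCIF) experiment produces, per scene, one
16-bit grayscale raster per (round, channel), with the DAPI counterstain
re-acquired every round. The pipeline treats these as follows.

### Registration

Rounds drift by a few to tens of pixels and fractions of a degree. Each
round's DAPI image is registered onto the reference round (the lowest round
index by default) with a 6-parameter planar affine transform, and the same
transform is applied to all channels of that round — within a round the
channels are acquired without moving the stage, so one transform per round
is the correct model. Transforms are estimated per scene; stitched whole
slides can flex between rounds, so per-slide transforms would be less
accurate.

Keypoints are nuclei themselves: the DAPI raster is smoothed (Gaussian,
sigma 2 px), Otsu-thresholded, connected components of at least 4 px are
kept and localized by intensity-weighted centroids, which gives sub-pixel
positions. Each keypoint is described by the sorted distances to its 12
nearest neighbors — a descriptor invariant to rotation and translation and
insensitive to the ≤2 % scale changes seen between rounds. Matches pass a
0.8 ratio test, then a 3-point RANSAC (inlier tolerance 2 px, 500
iterations, internally seeded so results are deterministic) selects a
consensus set and the final transform is a least-squares fit on the
inliers. Registration *fails loudly* — fewer than `min_matches = 10`
inliers, or an inlier RMS residual above 5 px, raises an error naming the
round — rather than silently accepting a bad alignment. On simulated
fields with planted jitter (shifts up to 20 px, rotations up to 5°), the
recovered transforms agree with the planted ones to well under 0.5 px mean
displacement over the field (typically ~0.05 px).

Warping uses bilinear interpolation with out-of-frame pixels set to 0.
Zero-filled borders bias the intensity of cells touching them; downstream
QC should drop border-touching cells. Cropping to common coverage is
deliberately not performed by default so label geometry stays aligned with
the reference frame.

### Autofluorescence subtraction

Tissue autofluorescence (AF) is strongest in the AF488/AF555/AF647 channels
(`c2`–`c4`), which are therefore corrected by default; DAPI passes through,
and AF750 carries too little AF to justify correction. Blank (unstained)
acquisitions are scaled by the exposure-time ratio — intensity is linear in
camera integration time — and subtracted:

* **baseline**: one blank, subtracted from every round. AF declines over
  the first 3–4 quenching rounds and rises again later, so a blank
  collected near that minimum avoids over-subtraction everywhere. A
  warning is emitted if the round-0 (pre-quench, ~25 % brighter) blank is
  used as the baseline.
* **scaled**: AF at round *r* is interpolated linearly between an early and
  a late blank, `AF(r) = (1-w)·B_early + w·B_late` with
  `w = (r - r_e)/(r_l - r_e)`. For rounds outside `[r_e, r_l]` the weight
  is clamped to `[0, 1]`: extrapolation could over-subtract, which is the
  failure mode this design avoids; interpolation inside the window is the
  assumption that AF drifts linearly between the two acquisitions.

Negative differences are clamped to 0 before the cast back to unsigned
16-bit (a signed floating-point output is available for diagnostics via
`clamp = FALSE`). Corrected intensities are exposure-equivariant before
clamping: doubling the target exposure and the marker intensities doubles
the corrected image exactly.

### Segmentation

Nucleus segmentation follows a watershed design: (i) white top-hat of the
max-projected DAPI (disc radius 15 px ≈ one nuclear radius at 0.325 µm/px;
the top-hat suppresses the diffuse background while keeping nuclear-scale
peaks), (ii) seeds are local maxima of the lightly smoothed top-hat, above
its Otsu threshold and separated by at least 5 px, (iii) the Prewitt
gradient magnitude supplies the contour relief, (iv) seeded propagation
(the seeded-watershed equivalent in EBImage) grows seeds inside the tissue
mask, and (v) nuclei are clipped to a maximum area — 1200 px² for
cytokeratin-positive seeds, 600 px² for negative ones, reflecting that
epithelial nuclei are larger; the caps are configurable because they are a
rule, not physical constants. The z-projection is the pixelwise **maximum**
across rounds so nuclei that detach in later rounds still segment.

Seed-level cytokeratin positivity (needed before cells exist) is computed
as the mean marker intensity in a 10 px disc around each seed centroid
against an Otsu cut over the per-seed means — an interpretation, exposed as
`seed_marker_positive()` with a manual threshold override.

Cell segmentation: membrane(E-cadherin)-positive nuclei compete in a seeded
propagation over the membrane image, together with a background seed placed
on low-membrane pixels farther than 30 px from any nucleus, so epithelial
cells stop at membrane ridges; membrane-negative nuclei are expanded by
5 px (1.6 µm, the measured scale of immune-cell cytoplasm). Membrane
negativity defaults to an Otsu cut on the mean membrane intensity in each
cell's 5 px ring. Label expansion assigns each contested background pixel
to the *nearest* label by Euclidean distance, ties broken toward the
smaller label id — fully deterministic, and verified exactly against a
brute-force oracle. Cytoplasm is the set difference cell − nucleus; a
nucleus outside its cell is an error, not a warning.

External deep-learning segmenters can be used instead: label TIFFs are
ingested via `read_image()`/`label_mask()`. A documented preset for a
generalist neural segmenter (cells: diameter 30 px, flow threshold 0.6,
min size 113; nuclei: diameter 30, flow threshold 0, min size 28) is
recorded here for users who run one; executing it is out of scope.

### QC metrics

*Positive* always means strictly above the threshold: on integer data ties
matter, and "above" is read exclusively. The SBR background set excludes a
30 px (10 µm) *Euclidean* gap around any positive pixel — a disc, not a
square dilation, because the gap is a physical distance — implemented by
exact distance transform and tested against an exhaustive oracle. Markers
with no positive pixels are flagged `negative_in_tissue` and not scored.

The quantile estimate of dynamic range uses the 4th and 99.5th percentiles;
the high cut at 99.5 (rather than, say, 99.9) keeps rare markers' dynamic
range meaningful while remaining robust to hot pixels.

Tissue retention thresholds DAPI per round with the Li minimum-cross-entropy
algorithm (iterative scheme, initial guess = mean) and reports the fraction
of round-1-positive cells still above threshold in each round. Per-round
thresholds (rather than one global threshold) accommodate per-round exposure
changes; this is an interpretation and the denominator is configurable
(`all_cells` as the alternative). The threshold is computed on
`log2(x + 1)` intensities by default: fluorescence intensities are
approximately lognormal and span decades, and on the raw scale the
mean-initialized Li iteration converges to a split *inside* the bright
nuclear mode whenever only a few percent of cells have detached — exactly
the regime retention analysis cares about. On the log scale the iteration
escapes to the between-mode valley. `log_space = FALSE` restores raw-scale
behavior.

### Normalization

The exclusivity score for a marker pair standardizes both columns and
takes the singular-value ratio σ₂/σ₁ of the n×2 matrix. For bivariate
normal data this equals `sqrt((1-|r|)/(1+|r|))`: perfectly co-expressed
pairs score 0, and the spread of genuinely expressed markers makes
L-shaped exclusive pairs score above the 0.5 selection cut-off (0.66 for
global thresholds; fallbacks 0.2 and 0.5 apply when no pair reaches the
primary cut-off). One caveat is inherited from this definition: two
*independent* background-only columns score near 1, so markers that are
expressed nowhere should be excluded before pair selection.

RESTORE-style thresholds exploit exclusivity: cells in the top quartile of
an exclusive partner are negative for the marker by construction, so the
99.5th percentile of the marker within that subpopulation estimates the
marker's background ceiling; the median over partners is the threshold.
Both quantiles are configurable; partner-positive subpopulations under 20
cells are skipped. The estimator is an extreme quantile: its sampling
error scales as n^-1/2 with ~9 % relative error at 750 partner-positive
cells, so reliable (±10 %) recovery needs batches of ≥10⁴ cells — the
validation uses 15 000 cells per batch, in line with real slides.

RESTORE scaling maps below-threshold cells to seeded uniform values in
(0, 0.02) and above-threshold cells affinely onto (0.02, 1], so the most
intense cell is exactly 1 and order is preserved. The seed is a required
argument — an unseeded version would make otherwise-identical runs differ.

Batch adjustment implements the parametric empirical-Bayes location/scale
model (per-batch per-feature shifts γ and scales δ, normal and
inverse-gamma priors moment-matched across features and iterated to
convergence). It is written here, rather than delegated, because the
control-tissue parameterization requires a fit/apply split — fitting on
training cells only (`all` cells, one control core, or cells pooled from
several control cores) and applying batch-wise to everything — which the
reference implementation does not expose; in the all-cells mode it agrees
with `sva::ComBat` to below 1e-6 (tested). With a single batch the data
pass through unchanged. `eb = FALSE` gives the no-shrinkage limit, which
equalizes training means and variances exactly. EB shrinkage is only as
good as its prior: with very few features whose batch effects are
*identical*, the between-feature variance t² is pure noise and shrinkage
leaves a small residual; with realistic marker-specific effects t² is
genuine and shrinkage is negligible.

### Batch evaluation

kBET draws `n_subsets = 100` anchor cells, forms each anchor's
neighborhood (itself plus its k nearest neighbors, k+1 cells — the anchor
is included, which is why expected counts use k+1), and compares batch
counts to global proportions by Pearson chi-squared with B−1 degrees of
freedom, no continuity correction. The default k is `floor(mean batch
size / 4)` (the reference heuristic), capped at n−1. k-NN graphs are exact
(blockwise all-pairs Euclidean distances, ties to the lower index) — at the
5 400-cell evaluation scale approximate neighbors buy nothing.

Clustering is Leiden community detection (modularity objective, resolution
0.6) on the k-NN graph, run once on the pooled normalized table so
replicate sections share one label space; per-replicate clustering with
post-hoc label matching would confound composition correlation with
matching errors. Cluster-composition correlation then compares, within
each core, the per-replicate vectors of cluster fractions (summing to 1)
by Pearson correlation for every replicate pair — 3 cores × 3 sections
give 9 values.

## The synthetic-data generator

`simulate_image_experiment()` emulates the features the pipeline must
handle: non-touching ellipse nuclei (semi-axis 5–9 px, aspect up to 1.6),
per-round marker signal on the cell footprint, an AF field made of a
diffuse component plus bright curvilinear fibers at 2–10× the signal scale,
a per-round AF multiplier declining linearly to a minimum at round 3 and
rising afterwards (the dynamics seen in repeated-quenching experiments),
planted affine jitter, Poisson shot noise plus Gaussian read noise, blank
acquisitions at configurable rounds, and a non-increasing retention
schedule realized exactly by rounding. Everything is determined by
(config, seed), and every piece of ground truth is returned.

`simulate_cell_table()` emulates the statistical structure the
normalization stack assumes: three cell types (epithelial CK19/Ecad,
immune CD45/CD8, stromal aSMA) at planted per-core compositions
(40/35/25 % jittered per core, realized exactly per core–batch group so
replicate sections of a core share composition), lognormal intensities in
which co-expressed markers share a per-cell latent level (making them
strongly correlated, as real co-expression is), background at 40 with the
positive component at 2000 — 16-bit scales at which the exclusivity score
of planted pairs clears the selection cut-offs — and per-batch,
per-marker multiplicative gains (base gains 1/1.6/0.7, marker jitter
sdlog 0.15). Batch effects are multiplicative because stain and exposure
efficiency scale intensities; an additive offset parameter exists but
defaults to 0. The planted background-ceiling threshold has the closed
form `qlnorm(0.995, log(40), 0.5) · gain`.

What passing the synthetic suite does **not** show: robustness to
non-affine (flexing) misalignment, spatially varying AF beyond the
fiber/diffuse model, segmentation of touching or overlapping nuclei at
tissue density, compartment misassignment from real optics (the generator
has no PSF), composition-*dependent* batch effects (under the generator's
multiplicative effects, the three ComBat training modes perform
equivalently; the advantage of pooling several control tissues emerges
only when batch effects interact with composition, which is not modeled),
or the behavior of the exclusivity score on panels dominated by
co-expressed lineages.

## Numerical conventions

* Coordinates are (x = column, y = row), 1-based, pixel units; transforms
  map moving → reference.
* All quantiles use R's default linear interpolation (type 7); e.g. Q3 of
  1…100 is 75.25.
* Empty compartments yield `NA` means, never 0 — zeros would silently
  deflate thresholds and SBR.
* Eccentricity comes from the second-central-moment ellipse,
  `sqrt(1 - λ₂/λ₁)`, clamped to [0, 1).
* Expansion ties go to the smaller label id; k-NN distance ties to the
  lower cell index; consensus sampling in registration and all random
  draws in simulation, sampling and kBET run on locally seeded streams
  that restore the caller's RNG state.
* Validation problem sizes: registration and AF recovery on 256² images
  (60–70 nuclei, 3–6 rounds), segmentation F1 on 512² fields of 150–200
  nuclei, retention on 5 000 cells × 10 rounds, batch evaluation on
  3 000-cell batches with k = 450, threshold recovery on 15 000-cell
  batches; brute-force oracle comparisons on rasters ≤ 64² and n ≤ 200.

## Known limitations

Non-rigid registration is out of scope; scenes that flex need external
tools. The watershed segmenter targets nuclei of roughly the configured
top-hat scale; very large or very dense nuclei need re-tuned radii or an
external segmenter. The Li iteration can sit inside a mode on raw-scale
near-unimodal data (hence the log-space default for retention). kBET at
the heuristic k is extremely powerful at 5 400 cells: composition
fluctuations of a few percent between batches are detected as batch
effect, which is faithful to the published algorithm but means small
nonzero rejection rates should not be over-interpreted. The exclusivity
score treats independent background-only pairs as exclusive; curate the
marker set first.
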