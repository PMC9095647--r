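# cyclicproc

Image processing and single-cell analytics for cyclic immunofluorescence
(CyCIF) and related multi-round multiplex imaging experiments.

CyCIF multiplexes 40–60 protein markers on one tissue section by iterating
stain → image → quench rounds with a handful of fluorophores. Turning the
resulting pile of single-channel TIFFs into a trustworthy single-cell table
requires a chain of processing steps, each with its own failure modes:
rounds drift out of alignment, residual tissue autofluorescence (AF) can
outshine real staining in the blue/green channels, tissue detaches as rounds
accumulate, and staining intensity shifts between experimental batches.
`cyclicproc` implements this chain as a tested R library plus a thin
command-line entry point, and ships a synthetic-experiment generator so the
whole pipeline can be exercised, end to end, against known ground truth —
no microscope required.

Intended users: imaging platform developers validating a multiplex protocol,
and analysts who need reproducible QC and normalization for multi-round
imaging data.

## What it computes

- **Registration** — every round's channels are mapped onto the first
  round's frame by an affine transform (scaling, rotation, translation)
  estimated from DAPI keypoints with robust consensus fitting.
- **Autofluorescence subtraction** — blank (unstained) acquisitions, scaled
  linearly by exposure time, are subtracted from the AF488/AF555/AF647
  channels. Two algorithms: *baseline* (one blank, ideally collected after
  3–4 quenching rounds, near the AF minimum) and *scaled*
  (linear interpolation between early and late blanks,
  `AF(r) = (1-w)·B_early + w·B_late`, `w = (r-r_e)/(r_l-r_e)`).
- **Segmentation** — white top-hat seeding, Prewitt-gradient relief, seeded
  watershed for nuclei (with cytokeratin-dependent size caps); cells by
  watershed on the membrane (E-cadherin) image or by 5-pixel (1.6 µm)
  nuclear expansion for membrane-negative cells; cytoplasm = cell − nucleus.
- **Feature extraction** — per-cell mean intensity for every marker in every
  compartment, plus each marker's biologically relevant compartment
  (cytoplasm for CK19, nucleus for Ki67, ...).
- **QC** — signal-to-background ratio `SBR = (mean FG − mean BG)/mean BG`
  with a 30 px (10 µm) Euclidean exclusion gap around positive pixels
  against lateral bleed-through; quantile dynamic range (4th/99.5th
  percentile); percent-positive; Li-threshold tissue retention across
  rounds; precision/recall/F1 against manual annotation.
- **Normalization** — raw/log2/arcsinh transforms; standard, min-max,
  max-abs, robust, quantile and power scalers; RESTORE-style background
  thresholds from mutually exclusive marker pairs (truncated-SVD
  exclusivity score, 0.5/0.2 per-core and 0.66/0.5 global cut-offs,
  median threshold over partners) with 0.02–1 rescaling; reverse-compartment
  Q3 thresholds; empirical-Bayes ComBat-style batch adjustment with
  control-tissue training modes; mean-only batch regression.
- **Batch evaluation** — exact k-NN graphs, kBET rejection rate (chi-squared
  on neighborhood batch counts vs global proportions; 0 = perfect mixing,
  1 = no mixing), stratified sampling (600 cells per core per batch),
  Leiden clustering, and replicate cluster-composition correlation.

## Worked example

```r
library(cyclicproc)

# simulate a 3-round, one-marker-channel experiment with registration jitter
cfg <- sim_image_config(shape = c(256, 256), n_cells = 70, rounds = 3,
                        channels = "c2", jitter_shift_px = 10,
                        jitter_rot_deg = 3, blank_rounds = c(1, 3), seed = 7)
sim <- simulate_image_experiment(cfg)

# register every round onto round 1 via DAPI
reg <- register_stack(sim$stack)
reg$transforms[["2"]]
#> <affine_transform> [+1.0003 -0.0257; +0.0258 +0.9999] t=(10.95, -5.21) rms=0.175 px, 70 inliers

# subtract autofluorescence with the interpolated ("scaled") algorithm
corr <- correct_stack(reg, sim$blanks, algorithm = "scaled", channels = "c2")

# segment nuclei from the DAPI projection, expand to cells, derive cytoplasm
nuc  <- segment_nuclei(project_dapi(corr))
cell <- expand_labels(nuc, distance_px = 5)
cyt  <- derive_cytoplasm(cell, nuc)
nuc
#> <label_mask> nucleus, 256x256 px, 70 objects

# per-cell feature table and a quantile SBR estimate for one marker
tab <- build_cell_table(corr, list(nucleus = nuc, cell = cell, cytoplasm = cyt),
                        marker_compartments = c(M1c2 = "cell"))
q <- sbr_from_quantiles(tab$M1c2)
#> cells: 70; M1c2 dynamic range 9-663, SBR estimate 72.6
```

The recovered transform matches the planted jitter to ~0.2 px, all 70
simulated nuclei are found, and the marker's quantile SBR reflects the
simulated positive fraction (negative cells sit at the AF-subtracted floor).

Batch evaluation on a simulated 3-core × 3-batch table:

```r
simt <- simulate_cell_table(sim_table_config(seed = 7))
tabn <- simt$table
markers <- marker_columns(tabn)
tabn[, markers] <- combat_adjust(log2(as.matrix(tabn[, markers])), tabn$batch_id)
samp <- stratified_sample(tabn, 600, seed = 7)      # 5400 cells
g <- build_knn(as.matrix(samp[, markers]), k = kbet_default_k(samp$batch_id))
kbet_rejection_rate(g, samp$batch_id, seed = 7)
#> <kbet_result> rejection rate 0.000 (k=450, alpha=0.05, 100 subsets)
```

The planted per-marker batch gains (up to 1.6× between batches) drive the
raw-data kBET rejection rate to ~1; location/scale adjustment on log
intensities brings it to the nominal test level.

## Command line

A thin Rscript front end wraps the library:

```sh
Rscript inst/cli/cyclicproc.R simulate --out scene/ --seed 1 --rounds 3
Rscript inst/cli/cyclicproc.R register --scene scene/ --out registered/
Rscript inst/cli/cyclicproc.R segment  --scene registered/ --out masks/
Rscript inst/cli/cyclicproc.R run      --config pipeline.yaml
```

`run` executes the full stage chain (register → afsub → segment → extract →
qc → normalize → eval) from a YAML configuration and writes a JSON manifest
with parameters, seeds and MD5 checksums of every artifact; identical
configurations reproduce identical checksums.

Images follow the naming convention
`{slide}_{scene}_R{round}_{marker}_{channel}_{exposure}ms.tif`
(`channel` ∈ DAPI, c2 = AF488, c3 = AF555, c4 = AF647, c5 = AF750;
`marker = "blank"` marks unstained AF acquisitions; round 0 is the
pre-staining baseline). The convention is configurable via a template
string in `parse_filename()`.

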