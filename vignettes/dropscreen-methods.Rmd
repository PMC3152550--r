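---
title: "Methods: simulating and analysing a lipid-droplet high-content screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a lipid-droplet high-content screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(dropscreen)
library(dplyr)
```

## The assay this package models

Cells grown in delipidated serum lose their lipid droplets (LDs); loading
the medium with free fatty acid (oleic acid) drives triglyceride synthesis
and LDs reappear as small bright puncta under a neutral-lipid dye. A
plate-based screen exploits this switch: each well receives a candidate
treatment, fields are imaged in two channels (a DNA stain marking nuclei and
a neutral-lipid dye marking LDs), and the readouts per well are the mean
number of LDs per cell and the number of nuclei per field, the latter a
surrogate for cytotoxicity. Treatments whose well values fall outside the
plate's normal range — mean ± k·SD over all extracts on that plate — are
flagged as LD increasers, LD decreasers, or cytotoxic.

`dropscreen` implements the full chain as composable, pipe-friendly
functions: a synthetic-field generator with per-cell ground truth
(`render_scene()`, `render_plate()`), the image-analysis chain
(`segment_nuclei()`, `delineate_cytoplasm()`, `detect_droplets()`,
`assign_droplets()`), per-cell and per-well quantification
(`per_cell_measurements()`, `summarize_well()`), and plate analytics
(`screen_plate()`, `dose_response()`, `fit_uptake()`, `assay_window()`).
Because no public image set accompanies the assay, the generator is a
first-class, tested component: it is what makes every downstream claim
falsifiable against known truth.

## The synthetic-field generator

A field is rendered in five steps:

1. **Cell placement.** Nucleus centres are rejection-sampled uniformly with
   a minimum pairwise spacing (default 5 nucleus radii) and a border margin.
   If the field cannot host the requested cells within a bounded retry
   budget, a capacity error is raised rather than silently overcrowding.
2. **LD counts.** Each cell draws its LD count from a Poisson distribution
   with rate lambda set by the treatment. The assay literature reports means
   and left/right distribution shifts but no count distribution; Poisson is
   the minimal choice for unclumped event counts and is exposed per
   treatment in `scenario_config()`.
3. **LD placement.** Spots are placed uniformly in the cytoplasmic annulus
   between the nucleus edge and the cytoplasm radius, clipped to the cell's
   own side of every neighbour bisector, with a minimum centre-to-centre
   separation (default 8 px) so planted spots are optically resolvable.
   Spots that cannot be placed after bounded retries are dropped *and the
   truth records what was actually planted*, so truth and image never
   disagree. The wide default cell spacing exists for the same reason: with
   crowded territories the annulus jams geometrically below high lambda and
   the empirical rate would fall more than 10% under the nominal one.
4. **Rendering.** Nuclei are Gaussian-shaded ellipses (sd = semi-axis/2,
   eccentricity 0.75–1), LDs are Gaussian spots with FWHM equal to their
   diameter (default 3–6 px) and ±20% amplitude jitter.
5. **Optics and camera.** A single Gaussian PSF blur (default sigma 1 px)
   then additive Gaussian read noise (default SD 100 on a 16-bit scale with
   background 400 and spot peak 6000, i.e. SNR well above 5), quantised to
   integers in [0, 65535].

Defaults describe a 512 × 512 px field with 30 cells — a desk-scale
stand-in for a montage field at 40×. Plate-scale work uses
`plate_scene_params()`: 320 × 320 px, 40 nominal cells, compact spacing.
That density choice trades per-well statistics against render time so that
a full 96-well plate (42 extracts in duplicate plus 12 controls) renders
and segments in under half a minute.

**What the generator does not emulate:** uneven illumination,
photobleaching, 3-D structure (the z-collapse operator `collapse_stack()`
exists for real stacks, but synthetic fields are born collapsed), cell-shape
heterogeneity beyond radius jitter, and any correlation between a cell's
size and its LD count. Tests passing on this generator therefore certify
the *analysis logic* — thresholding, declumping, assignment, plate
statistics — not performance on real micrographs, where illumination
correction and empirically tuned gates would come first.

### Scenarios

`scenario_library()` ships the regimes the screen is calibrated against,
with rates chosen once to match the assay's reference behaviour:

- delipidated baseline lambda = 3.5 (< 5 LDs/cell) and oleic loading
  lambda = 35 (ten-fold induction);
- a triacsin C ladder scaling the loaded rate by 1, 0.8, 0.5, 0.2, 0.05
  across increasing concentrations;
- an inhibitor ladder reaching ~60% inhibition at 20 µM;
- a cytotoxic-extract concentration series acting on survival, not on
  lambda;
- a screening-plate scenario at lambda = 10 with planted actives
  (increaser ×3, decreasers ×0.4, cytotoxic survival 0.3). The reduced
  plate baseline keeps a ×3 increaser resolvable inside compact plate
  territories; effects are multiplicative on the rate, so hit calling — a
  purely relative rule — is unaffected by the absolute level;
- an uptake time course with I_max = 100 au and tau = 10/3 min, placing the
  95% plateau (3·tau) at 10 minutes.

## The image-analysis chain

**Nuclei.** Global Otsu threshold (or a fixed level), connected components,
optional watershed declumping on the distance transform (tolerance 2 px),
an 80–2000 px² area gate, and exclusion of border-touching nuclei (standard
HCS practice, so partially imaged cells never contribute fractional
counts). All gates are parameters of `segmentation_params()` because the
original analysis settings are not published in a reusable form; the
defaults here are reasoned substitutes validated against the generator.

**Cytoplasm.** Each nucleus claims the pixels within
`cytoplasm_radius_px` (default 40 px) of its mask, partitioned between
nuclei by nearest nucleus centroid. This distance-limited Voronoi
construction was chosen over iterative geodesic dilation because it is
exact, order-independent and fast, and it mirrors the generator's own
bisector clipping; for round, similar-sized nuclei the two constructions
coincide to the pixel. Territories are disjoint by construction, include
their nucleus, and meet at perpendicular bisectors (verified against a
brute-force per-pixel oracle in the tests).

**LD spots.** The default detector applies a white top-hat (disc radius =
the upper spot-radius gate) to remove cell-scale structure, thresholds at
`median(response) + k·sigma` with k = 5, splits merged spots by an
intensity watershed (tolerance k·sigma), and gates detections on their
diameter at half maximum (default 3–10 px). Two numerical choices matter
and were forced by dense wells:

- *Noise scale.* sigma is estimated from the median absolute difference of
  adjacent pixels of the raw image (scaled for Gaussian noise), not from
  the spread of the response. In heavily loaded cells, spots and their
  halos cover enough of the field that any statistic of the response
  distribution (MAD included) inflates several-fold and the threshold
  climbs into the spot peaks; the pixel-difference estimator is indifferent
  to how much of the field is structure.
- *Diameter at half maximum.* When the threshold sits above a spot's
  half-max level only the core is visible, so the half-max area is
  extrapolated from the Gaussian profile identity A(L) = 2π·sigma²·ln(peak/L);
  near-threshold speckle (cores under 4 px) is measured directly so the
  extrapolation cannot inflate noise into the gate.

A multi-scale difference-of-Gaussians blob detector (`ld_detector = "log"`)
is available as an alternative; it shares the thresholding and gating
logic.

**Assignment.** A spot belongs to the territory containing its rounded
centroid; a centroid on a boundary pixel goes to the territory labelled at
that pixel; spots on background are reported as unassigned. The identity
`sum(per-cell counts) + unassigned = detections` holds exactly and is
asserted on every fixture. Coordinates throughout are R-native 1-based
(row, col) at pixel centres — the natural convention for R matrices and
EBImage — rather than 0-based.

## Quantification

Per cell: LD count, territory area, and integrated cytoplasmic intensity —
the background-corrected sum over the territory, clipped at zero, with the
image median as the default background estimate (robust, parameter-free;
exposed in case a field has structure covering most pixels). Per well:
cells are pooled across fields at the cell level (the screen reports one
value per well; pooling is the simplest choice consistent with that),
nuclei per field = pooled cells / fields, and the LD-count histogram uses
unit bins with an open-ended top bin. A well with no cells reports an
explicit `NA` mean, never a silent zero. `distribution_shift()` is the
difference of histogram means — positive for a right shift — which makes it
exactly translation-consistent with `mean_lds_per_cell`.

## Plate analytics

Replicate wells are averaged arithmetically per extract. The normal range
is mean ± k·SD over the extract-level values with k = 1 (the screen's rule
names no multiplier; k is a parameter) and population SD (divide by n; the
convention is pinned for reproducibility and configurable, the difference
being immaterial at n = 42). Control wells are excluded from the range:
they are intentionally extreme, and their inclusion would widen the band
the extracts are judged against. Cytotoxicity is flagged only below the
lower nuclei bound — losing cells is evidence of toxicity, gaining them is
not — and the co-occurrence of cytotoxicity with LD flags is reported as a
table rather than folded into the calls. `assay_window()` quantifies
control separation as Z' = 1 − 3(sd₊ + sd₋)/|mu₋ − mu₊|.

`dose_response()` summarises replicates per concentration, computes percent
inhibition 100·(1 − (treated − baseline)/(loaded − baseline)) against the
delipidated baseline and oleic-loaded positive control, tests monotone
trend by Spearman rank correlation (robust, assumption-free at 3–8 doses),
and optionally fits a four-parameter logistic, reporting the midpoint only
when the optimiser converges and the midpoint lies within the positive
concentration range — extrapolated midpoints are withheld rather than
reported with spurious precision. `fit_uptake()` fits the saturating
exponential I(t) = I_max·(1 − exp(−t/tau)) by Levenberg–Marquardt least
squares and reports the time to plateau as 3·tau (95% of I_max); degenerate
inputs return an explicit failure object.

## Determinism and problem sizes

Every stochastic function takes a seed; plate rendering derives per-well
substreams from the top-level seed, so wells are reproducible
independently of one another, and the RNG state of the calling session is
never disturbed. Re-running `run_pipeline()` with the same config
reproduces every table bit for bit.

The shipped validation workloads use: 20 fields of 512 × 512 px at
lambda = 20 for count recovery; 20 seed pairs of delipidated/oleic fields
for the regime check; a 5-dose ladder × 20 seeds on 384 × 384 px fields;
and 20 full 96-well plates for the screen end-to-end. These sizes give
roughly 600 cells per condition — enough that Poisson sampling error on a
mean is ~2% — while keeping a complete run in the minutes range on one
core.

## Known limitations

- The normal-range rule is plate-wise; no multi-plate batch correction
  (B-score, median polish) and no FDR control are provided, matching the
  screen's own design.
- No confidence intervals on the 4PL midpoint.
- Segmentation defaults are validated on the generator's optics; real
  micrographs need illumination correction upstream and empirical gate
  tuning.
- Visual rescoring of flagged extracts — part of the original workflow — is
  inherently manual and out of scope.

## A worked example

```{r example, eval = FALSE}
res <- run_pipeline(run_config(
  scenario = "screen-plate", seed = 1, n_extracts = 42,
  n_increasers = 1, n_decreasers = 2, n_cytotoxic = 2
))
res$screen
autoplot(res$screen)
```
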