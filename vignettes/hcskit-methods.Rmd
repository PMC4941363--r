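---
title: "hcskit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hcskit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcskit)
```

# Overview

`hcskit` implements a high-content screening analysis chain — nuclei
segmentation, per-cell receptor and S-phase readouts, dose-response fitting,
and profile clustering — together with a synthetic microscopy simulator that
carries per-cell ground truth. The simulator is not decoration: it is what
makes every stage of the chain testable. At zero noise the rendered pixel
values equal the generative values exactly, so the measurement layer is
checked to machine precision; at realistic noise, recovery is checked
statistically against the known truth.

# Segmentation

The DAPI channel is processed as:

1. **Rolling-ball background subtraction.** Grayscale opening with a flat
   disc (radius 50 px by default), subtracted from the image and clamped at
   zero. The opening is computed exactly with the van Herk/Gil-Werman
   running min/max along each disc chord, giving O(1) work per pixel
   independent of radius. Borders are padded with ±Inf, the standard
   convention for flat morphology; on a sloped background this means the
   estimate under-tracks a ramp within one radius of the border, which is
   inherent to any truncated structuring element.
2. **Adaptive mean threshold.** A pixel is foreground when it exceeds the
   local mean over a `window × window` neighborhood (default 51, odd
   required) by `offset`. The local mean uses symmetric mirror reflection at
   the borders and a separable running sum. The default `offset = 100` is
   set from the noise model, not tuned on outcomes: with read noise around
   `sd = 40`, an offset of a few counts would admit roughly a third of all
   background pixels as foreground speckle, whereas 2.5 standard deviations
   keeps the false-positive rate per pixel well under 1% while nuclei
   (thousands of counts above background) are unaffected. The residual
   speckle that does pass is removed by the area filter.
3. **Minimum-area filter.** Objects with *strictly fewer than* 20 pixels are
   discarded (area 20 survives). The boundary semantics are pinned by tests.
4. **Watershed splitting of touching nuclei.** The Euclidean distance
   transform (exact, via Felzenszwalb's algorithm) of the foreground is
   seeded with its h-maxima (grayscale reconstruction of `dst - h` under
   `dst`, then regional maxima) and flooded with Meyer's priority-queue
   watershed with FIFO tie-breaking. The default `h = 1.2` follows from
   geometry: for two discs of radius `r` at center distance `d`, the saddle
   of the distance transform sits `r - sqrt(r^2 - (d/2)^2)` below the two
   maxima. With `r = 8` and the simulator's pair distances of
   `1.3–1.8 × r`, the shallowest saddle is ≈1.8 px deep, so `h = 1.2`
   suppresses single-nucleus plateau noise while preserving both seeds of
   every touching pair. An `h` of 2 or more would merge the closest pairs by
   construction.
5. **Cell masks by contested dilation.** Each pixel within the dilation
   radius (default 10 px) of any nucleus is assigned to its *nearest*
   nucleus, ties to the lower label — so adjacent cells partition the
   contested zone instead of overwriting each other. Implemented as a
   per-label distance transform cropped to the label's padded bounding box.
6. **Edge removal.** A cell is removed when its *cell mask* (not just the
   nucleus) touches the field border, since its cytoplasmic measurement
   would be truncated.

Every operator is tested for exact agreement with an independent brute-force
oracle (full shift-and-min/max opening, explicit padded local mean,
exhaustive nearest-seed assignment), so the fast implementations cannot
drift from their definitions.

# Simulator geometry

Nuclei are discs (radius 8 px) and cytoplasm concentric discs of radius 19.
The cytoplasm radius is chosen as `nuclear radius + dilation radius + 1` so
that the default cell mask (radius 18) lies strictly inside the rendered
cytoplasm: at zero noise the measured cytoplasmic mean then equals the
generative value exactly, which is what the 1e-9 measurement-recovery
checks rely on. Singles are placed by rejection sampling with disjoint
cytoplasmic discs; a configurable fraction of cells is placed as touching
nuclear pairs at center distance `U(1.3, 1.8) × r` — close enough to merge
into one foreground component, far enough that the watershed split is
well-posed (see the `h` discussion above). Channels get a flat background, a
linear gradient, Gaussian read noise, and `sqrt(signal)`-scaled shot noise,
then clip to the 16-bit range with clip events counted in field metadata.
Each well/field derives its own RNG stream from the plate seed, so fields
are reproducible in isolation.

# Per-cell features

The translocation readout is the ratio of nuclear mean to cytoplasmic mean
of the receptor channel; a ratio of means is size-invariant and undefined
(flagged, not dropped) for cells with no cytoplasm pixels. EdU S-phase calls
use a two-class split (1-D 2-means) of log10 nuclear EdU means pooled over
*vehicle wells only*; the threshold is the log-midpoint of the two class
centers and is then frozen for the whole plate, so treatments that change
the S-phase fraction cannot drift the classifier. When bimodality is not
detectable (class centers closer than 0.5 log units) or fewer than 50
vehicle cells exist, the classifier falls back to `median + 3·MAD` with a
warning. The fraction-recovery tests run the classifier on cell populations
drawn from the generative model (thousands of cells in seconds) rather than
on millions of rendered pixels; rendering fidelity is established separately
by the zero-noise exactness and segmentation-recovery tests, so compositing
the two wouldn't test anything new and would push the suite past its runtime
budget.

# Screen-level analysis

Well summaries are medians (plus means/MADs) over cells. Normalization is
either fold-change over the vehicle median or percent-of-agonist
(`100 · (x - vehicle) / (agonist - vehicle)`). Dose-response uses the 4PL in
log10-dose space fitted by bounded Levenberg–Marquardt (`minpack.lm::nlsLM`)
from a small multi-start grid (slope × midpoint candidates); the reported
IC50 is the relative IC50 (the fitted midpoint). "No activity" is declared
by an extra-sum-of-squares F-test against the constant model at α = 0.05 —
a flat curve is a *result*, not an error. Profiles (conditions × cell lines)
are clustered with Euclidean distance and average linkage (UPGMA); merge
heights are verified against exhaustive enumeration, and trees export to
Newick via `ape`. Biolog phenotype plates are corrected by subtracting each
plate's negative-control mean, then Z-scored per carbon source across all
corrected replicates (zero-variance rows set to 0 and flagged).

# Files and interfaces

All I/O uses lowest-common-denominator formats: one 16-bit grayscale TIFF
per channel per field named `r{row:02d}c{col:02d}f{field:02d}_{channel}.tif`
(with a manifest-CSV escape hatch), CSV for layout/cells/wells/fits, Newick
for dendrograms, and a flat key/value text file recording each run's
resolved configuration. The "command line" is the exported function layer —
`simulatePlate()`, `segmentField()`, `runPipeline()`, etc. — which is the
idiomatic entry point for an R analysis package; `runPipeline()` accepts
either an in-memory plate or a directory and chains every stage, skipping
unreadable fields with a message and degrading gracefully (normalization
refusal on a plate without controls still leaves the upstream outputs
intact).

# Limitations

- Nuclei are discs: segmentation accuracy numbers from the simulator do not
  transfer to irregular real nuclei; they validate the algorithmic chain,
  not biology.
- The shot-noise model is Gaussian with `sqrt(signal)` scale, not true
  Poisson photon statistics.
- Single-plane 2-D analysis only; no 3-D stacks, no vendor microscope
  formats, no illumination-correction modeling beyond the linear gradient.
- The Monte-Carlo IC50 spread reflects the simulated noise model, not
  plate-to-plate biological variability.

```{r example, eval = FALSE}
# End-to-end demo (see README for printed output)
conds <- rbind(
  controlCondition(replicates = 4L),
  doseResponseConditions("BPAP", c(1, 5, 10, 15, 30, 60) * 1e-6, unit = "M",
                         nucModel = effectModel(800, 320, 15e-6, 1.2),
                         replicates = 2L))
plate <- simulatePlate(plateSimConfig(conds, seed = 7))
run <- runPipeline(plate)
run$fits
```
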