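---
title: "Quantifying epithelial detachment in kidney organoid images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epithelial detachment in kidney organoid images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The phenotype and the measurement model

Human kidney organoids exposed to stressors such as high glucose or
inflammatory cytokines shed epithelial cells — most visibly podocytes —
from the main organoid body. In fluorescence microscopy this appears as
small, isolated specks of marker signal (PODXL for podocytes, ECAD for
distal tubule, LTL for proximal tubule) scattered around a large contiguous
marker-positive structure. `organoidquant` turns that visual into numbers:

1. **Background**: for each channel, the background of an acquisition set
   is the arithmetic mean over images of each image's minimum pixel
   intensity. A set-level (rather than per-image) background keeps the
   threshold comparable across the conditions being contrasted.
2. **Threshold**: a pixel is foreground when its intensity exceeds
   `background + threshold_offset`. The offset is one global value per
   experiment. When not supplied explicitly it is derived per image as
   `auto_k` (default 3) times the median absolute deviation of the
   below-median pixels — a robust spread of the non-signal population — but
   an explicit offset is recommended for exact reproducibility and is what
   all shipped configurations use.
3. **Components**: foreground pixels are grouped into connected components
   (default 8-connectivity), components smaller than `min_object_px`
   (default 4 px) are discarded as shot noise.
4. **Intact vs detached**: a component of area at least `main_body_min_px`
   is *intact* (a main organoid body); every other surviving component is
   *detached*. If no component reaches the cut, the largest one is taken as
   the body, because an analyzable image must contain an organoid. The
   headline statistic is the intact/detached area ratio; when a well has no
   detached signal the denominator is floored at `ratio_epsilon_px` and the
   result flagged, so control wells stay finite and plottable.
5. **Intensity**: the mean background-subtracted intensity over the union
   mask, clipped at zero, optionally normalized to the control-condition
   mean.

Whole-well organoid **census** counts a region as an organoid iff a
connected component of the union of the marker masks is at least
`min_organoid_px` and contains above-background pixels of *every* required
marker (ECAD, PODXL, LTL by default) — the automatable reading of "a
structure showing all three nephron markers simultaneously". Counts on
later days are reported as percent of day 0. **Time-lapse** tracking
matches day-0 organoid positions to later detections greedily by ascending
centroid distance (ties to the lower region label), with unmatched
positions recorded as gaps, and collates per-day body area, detached area
and detached-object count.

The statistical layer mirrors standard practice for this kind of
experiment: group summaries as mean ± SEM (sample SD, n − 1), one-way
fixed-effects ANOVA, Fisher's LSD pairwise comparisons on the pooled error
term without multiplicity correction, ratio-of-means fold changes, and
relative qPCR quantification by 2^−ΔΔCt against a housekeeping gene.
The transcriptomics module implements the cell-QC rules (keep a cell iff
UMI < 40,000, detected genes < 8,500, mitochondrial fraction < 10%,
ribosomal fraction < 40% — all strict inequalities), inclusive
differential-expression thresholds (adjusted p ≤ 0.05, |log2FC| ≥ 0.8),
and the overlap/directionality arithmetic between two DE tables.

## Why the boundary conventions differ

QC keeps cells under strict `<` bounds while DE filtering keeps rows under
inclusive `≤`/`≥` bounds. Each follows the letter of the procedure it
implements; the package does not harmonize them, and tests pin the
boundary behavior on both sides.

Two referents exist for "overlap as a fraction": the fraction of either
input table's significant genes. The concordance report carries both,
explicitly labeled, rather than guessing which one a reader means.

## The synthetic-data generator

Because the raw microscope images and sequencing data behind this kind of
study are rarely publicly deposited, the package ships a generator that
produces every input with exact ground truth:

- **Organoid bodies** are unions of overlapping discs (a main disc plus
  three satellites at 0.55 r with radius 0.6 r) — lobed shapes that
  preserve the connectivity structure the segmentation relies on. Each
  marker occupies a configurable fraction of the body
  (`marker_overlap_fraction`, default 0.6), PODXL anchored centrally and
  ECAD/LTL peripherally, all overlapping near the body center so the
  three-marker census rule is satisfiable.
- **Detached cells** are single discs placed in an annular band
  (`detached_ring_px`, default 4–30 px from the body's reach) with a
  guaranteed > 1 px gap to the body and to each other, so ground-truth
  object counts are exact under 8-connectivity. Counts can be set per
  channel.
- **Noise** is additive Gaussian (clipped at zero) over a uniform
  background offset. This stresses thresholding without modeling camera
  physics (no PSF, no bleaching, no illumination gradients).
- **Ground truth** is exactly the noiseless object support: per-channel
  intact and detached masks (disjoint by construction), intact fractions,
  organoid counts and centroids.
- **Condition effects** scale the body radius by the square root of the
  requested intact-area multiplier — the default treated condition carries
  the 3-fold intact-area reduction that motivates the package — and scale
  the detached-cell count by a separate multiplier (default 2; the
  magnitude of the detached-burden increase is a generator choice, as the
  area reduction is the quantity the phenotype is reported by).
- **Time-lapse series** shrink the body area by `shrink_rate` per day and
  add `shed_rate` detached cells per day at evenly spaced angles
  (collision-free by construction) in the PODXL channel only, mirroring a
  PODXL–GFP live-imaging experiment; the centroid drifts by at most
  `max_drift_px` per day so position-based tracking is solvable.
- **Count matrices** plant cells that violate exactly one named QC rule
  while passing the other three; **DE-table pairs** realize an exact
  overlap and up/down concordance composition (default 56 shared genes,
  15 up- and 21 down-concordant) with every row passing the cutoffs.

Everything is driven by explicit integer seeds through `withr::with_seed`,
so identical specifications give bit-identical outputs and the caller's
RNG state is never disturbed.

What passing tests on these images shows is that the *quantification
arithmetic* is correct and robust to additive noise at realistic
signal-to-noise ratios. It does not show robustness to the failure modes
of real microscopy — uneven illumination, out-of-focus organoids, staining
artifacts, touching organoids, debris — which is why the thresholds remain
configuration, not constants.

## Numerical and design choices

- **Connectivity** defaults to 8: diagonal pixels of one cell should not
  split an object. The labeling kernel (compiled, two-pass union-find)
  assigns labels 1..K in row-major order of each component's first pixel,
  so label maps are deterministic and testable against an independent
  flood-fill oracle.
- **Intact vs detached by component area**, not by distance to the body:
  "geometrically isolated" is operationalized as "not part of a component
  large enough to be a main body", which matches the visual of tiny
  outlying specks without inventing a distance parameter.
- **min_object_px = 4** suppresses single-pixel noise while keeping small
  detached cells (a 2-px-radius cell covers ~13 px).
- **z-projection** defaults to per-pixel maximum, the common reading of
  "collapsed" confocal stacks; mean and sum are selectable.
- **Negative background-subtracted intensities are clipped to 0**: they
  are subtraction artifacts, not signal.
- **No automatic outlier exclusion**: visually failed stainings are a
  judgment call; the statistics accept data as given, and any exclusion
  must happen upstream, explicitly.
- **Greedy nearest-neighbor tracking** rather than globally optimal
  assignment: organoids are sparse and sessile, displacement is small
  relative to spacing, and the greedy rule is deterministic and cheap. The
  recommended `max_displacement_px` is twice the body radius.
- ROI delineation is automated through components; there is no manual
  circling step, trading fidelity to a manual workflow for
  reproducibility.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script exercise, per run: 100 random
32×32 masks against the flood-fill oracle (both connectivities); a
16-image demo experiment for exact area conservation and byte-identical
pipeline re-runs; 60 single-organoid images (144×144 px, signal-to-noise
5) for intact-fraction recovery at targets 0.5/0.8/0.95; 50 replicate
two-condition experiments (30 organoids per condition, 112×112 px images)
for fold-change recovery and LSD power; 40 whole-well censuses (288×288
px, 8–16 organoids); and 20 seeded count matrices for the QC filter.
These sizes were chosen as the smallest at which the recovery claims are
meaningful at their stated thresholds.

## Known limitations

- Pixel units only: no magnification-to-µm conversion is applied anywhere,
  as acquisition metadata is not modeled.
- The detached ring band must physically fit in the well image; crowded
  configurations (many cells per channel in a narrow band) are rejected
  with an error rather than silently overlapped.
- The time-lapse generator spaces detached cells at distinct angles, which
  caps the collision-free shed total at roughly the number of cells whose
  arc spacing exceeds a cell diameter.
- Whether the source workflow's intensities were means or integrated
  densities is not stated there; the package reports means (integrated
  density is area × mean, both of which are in the output).
- No volumetric (3-D) quantification; z-stacks are always projected first.
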