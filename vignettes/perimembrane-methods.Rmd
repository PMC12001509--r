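---
title: "Quantifying membrane-protein trafficking from two-channel immunofluorescence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-protein trafficking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perimembrane)
```

## The measurement problem

When a tagged membrane protein (for example a SNAP-tagged aquaporin in
salivary acinar cells) is stimulated to traffic to the plasma membrane,
the readout in fixed-cell immunofluorescence is an increase of signal in
the *perimembrane area*: thin, bright fragments at the cell periphery.
Quantifying this automatically has two difficulties. First, perinuclear
fluorescence (ER/Golgi pools, which are bright and compact) must not
contaminate the measurement. Second, absolute intensities vary between
stainings and sessions, so only intensities normalized within an
experiment are comparable.

The pipeline in this package addresses both:

1. **Nuclei segmentation** on a dedicated nuclei channel (Otsu
   threshold, hole filling, 8-connected components, minimum-area
   filter).
2. **Exclusion mask** -- the nuclear mask expanded by a Euclidean
   distance (default 10 px, about 0.8 µm at 0.082 µm/px). Everything
   inside is removed from fragment detection, which eliminates
   perinuclear fluorescence.
3. **Fragment detection** -- thresholding of the signal channel outside
   the exclusion mask, 8-connected labeling.
4. **Shape selection** -- only long, thin objects are retained:
   area within `[50, 50000]` px and circularity (form factor
   $4\pi A / P^2$) at most 0.3. Compact blobs (vesicle clusters,
   debris, residual perinuclear signal) score near 1 and are dropped.
5. **Scoring** -- each retained fragment is scored with its
   **upper-quartile (UpQ) intensity**, the 75th percentile of its pixel
   values. The upper quartile is robust to the dim tail a fragment
   inevitably drags along its borders, unlike a mean.
6. **Normalization** -- fragments are pooled across images per
   condition and every score is divided by the *control condition's
   median*, so the control median is exactly 1 and all condition
   medians are unitless fold changes.
7. **Statistics** -- conditions are compared with the tie-corrected
   Kruskal-Wallis test; individual conditions are compared to the
   control with Dunn's rank-based many-to-one post-hoc tests
   (Bonferroni-adjusted by default) and coded with the conventional
   star map (`*` p < 0.05 through `****` p < 0.0001, strict
   inequalities).

## Conventions that had to be pinned down

Several quantities have more than one common definition; the package
fixes one and uses it everywhere.

**Percentiles.** The UpQ score and all reported quartiles use linear
interpolation between order statistics at 0-based rank position
$p\,(n-1)$ (the common scientific-computing default, R's `type = 7`).
A verbal definition like "the value below which 75% of pixels lie" is
ambiguous for small $n$; the interpolating convention is exact,
permutation-invariant, and matches an independent sort-and-interpolate
oracle to 1e-12 in the test suite.

**Circularity.** The form factor $4\pi A/P^2$ with $A$ the pixel count
and $P$ from a border-configuration perimeter estimator with diagonal
correction (straight border runs count 1, diagonal runs $\sqrt 2$,
corner transitions $(1+\sqrt 2)/2$). This estimator reproduces
scikit-image's `measure.perimeter` exactly on shared shapes, scores
rasterized disks near 1 (0.906 at radius 30) and a 3×100 px bar at
0.092, so the 0.3 cut cleanly separates "long and thin" from compact.

**Connectivity.** 8-connected components for both channels; thin
diagonal structures stay connected.

**Thresholding.** The fragment threshold is, by default, a
**three-class Otsu** computed on the non-excluded signal pixels, keeping
the top class. Two-class Otsu is offered but is the wrong default here:
fluorescence fields are dominated by dark background, so the two-class
criterion splits background from cells and merges cytoplasm with
membrane into one foreground -- the fragment measurement then collapses.
Assigning the middle Otsu class to background is the standard choice in
CellProfiler-style pipelines for exactly this situation. Fixed and
quantile thresholds are also available; all are logged in the run
configuration. Our implementations agree with
`skimage.filters.threshold_otsu` / `threshold_multiotsu` to about 1% on
identical samples.

**Exact vs. asymptotic Kruskal-Wallis p.** The chi-square approximation
is used for realistic sample sizes. For very small pooled samples
(where the number of distinct group assignments is at most 1e5) the
package enumerates the exact permutation null instead, because the
chi-square approximation can be off by far more than the discreteness
of the exact distribution at, say, $N = 8$. The statistic itself is
always the tie-corrected $H_c = H / (1 - \sum(t^3-t)/(N^3-N))$ on
pooled mid-ranks.

**Dunn, not Dunnett.** The post-hoc comparisons are Dunn's rank-based
many-to-one z tests,
$z = (\bar R_i - \bar R_r) / \sqrt{(N(N+1)/12 - \sum(t^3-t)/(12(N-1)))
(1/n_i + 1/n_r)}$, which is the coherent follow-up to a Kruskal-Wallis
omnibus; the parametric Dunnett test assumes normal within-group errors
and would contradict the nonparametric omnibus choice. Comparisons are
many-to-one against the control (the hypothesis the experiment
addresses); Bonferroni adjustment over the $k-1$ performed comparisons
is the default, Holm is available.

**Sampling unit.** The observation is the *fragment* (that is what the
measurement database contains). Per-image fragment counts are also
reported so users can judge clustering; no nesting correction is
applied (documented limitation below).

**Normalization order.** Pooling across images happens first, then a
single control-median normalization per analysis batch. Normalizing per
independent experiment and pooling afterwards is arithmetically
available to users (run batches separately) but is not the default, so
a batch is always interpretable against one control unit.

## The synthetic-scene generator

Real acquisitions of this kind are rarely publicly deposited, so the
package ships a generator that produces two-channel 16-bit scenes with
full ground truth, used by every validation test.

Each cell is a disk with four painted regions (nucleus on the nuclei
channel; cytoplasm, perinuclear halo, membrane annulus on the signal
channel). Key modeling choices:

* **Broken annulus.** The membrane ring is interrupted by 3 angular
  gaps (evenly spaced with ±10° jitter, widths 10-25°), so detected
  objects are arcs -- long and thin -- as in real images, where the
  membrane signal is fragmented.
* **Perinuclear halo.** A bright annulus (default 6000 counts, twice
  the cytoplasm) hugging the nucleus. The generator deliberately
  creates the artifact the exclusion mask exists to remove; tests
  verify zero retained pixels fall in it.
* **Cell brightness variability.** Each cell carries a log-normal
  brightness factor (median 1, CV 0.2) multiplying all its
  signal-channel paints. This reproduces the spread seen in real
  normalized violin plots (IQRs of roughly 0.8-1.3 around a median of
  1); without it, synthetic fragments would be implausibly
  homogeneous and every statistical test trivial.
* **Noise model.** Poisson (shot) noise on the painted mean, then
  additive Gaussian read noise (SD 50 counts), then clipping and
  quantization to 16 bits -- the standard camera chain, applied in
  that order.
* **Enrichment as ground truth.** The membrane paint equals
  cytoplasm × enrichment × condition multiplier, per cell, before
  noise -- so the membrane/cytoplasm ratio is *exact* in the noise-free
  image and every recovery test has an analytic target. The default
  condition presets (1, 1.347, 1.331, 1.331 for CTRL / FK / TH /
  FK+TH) mirror the normalized medians a sensitized secretagogue
  experiment produces, making the default synthetic experiment a
  structural analogue of that design.
* **Scaled-down geometry.** Cells are 35-55 px in radius -- several
  times smaller than a real acinar cell at 0.082 µm/px -- purely to
  keep test runtimes in seconds. All pipeline statistics (ratios of
  medians, rank tests) are invariant to this scaling. Absolute
  intensity levels are free parameters (the source protocol reports
  none), with defaults (cytoplasm 3000, membrane enrichment 2.5)
  placed well inside the 16-bit range.

**What a green test establishes -- and what it does not.** The
generator omits point-spread blur, z-structure, touching cells,
non-disk morphologies and photobleaching. Passing tests establish that
the measurement chain is *internally correct* (segmentation respects
ground truth, enrichment ratios are recovered within 10%, the test
statistics are calibrated); they do not certify performance on real
confocal images, where threshold and expansion parameters must be
inspected per dataset (`run_config()` exposes and logs all of them).

## Numerical and degenerate-input behavior

* All randomness flows from one top-level seed through named
  substreams (`substream_seed()`), so any image or stage can be
  regenerated in isolation; identical seeds give byte-identical TIFFs.
* File writes are atomic (temp + rename); interrupted runs never leave
  truncated tables.
* An all-zero nuclei channel yields an empty label map, not an error;
  an empty exclusion mask excludes nothing; an all-identical sample is
  a hard error in `kruskal_wallis()` (the statistic is undefined).
* The generator's rejection placement is bounded; crowded fields emit
  fewer cells with a warning and the count recorded.
* TIFF support is deliberately minimal (uncompressed grayscale
  baseline TIFF, 8/16-bit, multi-page, both byte orders), implemented
  in-package because no TIFF library is available in the target
  environment; it is cross-validated against Python `tifffile` in both
  directions. Proprietary microscope formats are out of scope.
* Spreadsheet (xlsx) export is not provided -- no xlsx writer exists in
  the target environment -- and CSV is the canonical, fully tested
  export format.

## Known limitations

* Fragments from the same cell or image are treated as independent
  observations by the rank tests; with strong per-image effects this
  overstates confidence. Per-image counts are reported so users can
  aggregate first if they prefer.
* Touching nuclei are not split (no watershed); in dense fields the
  exclusion mask is conservative rather than precise.
* The 2D analysis treats z-slices as independent images; no 3D
  reconstruction is attempted.
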