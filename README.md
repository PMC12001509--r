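# perimembrane

Automated quantification of how much of a fluorescently tagged membrane
protein reaches the **cell perimembrane area**, from two-channel
(nuclei + signal) 16-bit fluorescence microscopy images — together with
the nonparametric group statistics used to compare experimental
conditions. The motivating application is stimulus-induced trafficking
of tagged water channels (e.g. SNAP-tagged AQP5 in salivary acinar
cells), but the pipeline applies to any protein whose translocation
shows up as thin bright fragments at the cell periphery.

## What it computes

For each image the pipeline:

1. segments **nuclei** on the nuclei channel (Otsu threshold, hole
   filling, 8-connected components, minimum area);
2. expands the nuclear mask by a Euclidean distance *d* (default 10 px)
   into an **exclusion mask** that removes perinuclear fluorescence;
3. thresholds the signal channel outside the mask (three-class Otsu by
   default) and labels candidate **membrane fragments**;
4. keeps only *long, thin* objects: area in [50, 50000] px and
   circularity 4πA/P² ≤ 0.3;
5. scores each retained fragment with its **upper-quartile (UpQ)
   intensity** — the 75th percentile of its pixel values, robust to dim
   border pixels.

Fragments are pooled per condition, every score is divided by the
**control condition's median** (so the control median is exactly 1),
and conditions are compared with a tie-corrected **Kruskal-Wallis**
test plus **Dunn's many-to-one post-hoc tests** against the control
(Bonferroni-adjusted, star-coded: `*` p < 0.05 … `****` p < 0.0001).

A seeded synthetic-scene generator produces two-channel scenes with
ground-truth label maps (nucleus, perinuclear halo, cytoplasm, broken
membrane annulus per cell, Poisson + Gaussian noise), so the whole
chain is validated against known truth. See
`vignettes/perimembrane-methods.Rmd` for every convention and design
choice.

## Worked example

```r
library(perimembrane)

report <- run_synthetic_experiment(
  config  = run_config(seed = 42),          # all parameters logged
  spec    = scene_spec(seed = 42),          # 640x640 px, 10 cells/image
  presets = condition_presets_default(),    # CTRL 1, FK 1.347, TH 1.331, FK+TH 1.331
  images_per_condition = 3,
  out_dir = "demo")
print(report)
```

```
perimembrane run: 12 images, 356 retained fragments

 condition   median       q25      q75  n
      CTRL 1.000000 0.8975052 1.131318 89
        FK 1.305693 1.1821750 1.493331 90
        TH 1.395909 1.2485018 1.610035 87
     FK+TH 1.272603 1.0726860 1.388028 90

Kruskal-Wallis: H = 126.0360, df = 3, p = 3.866e-27 (chi-square approximation, N = 356)
 group reference n_group n_reference mean_rank         z        p_raw   p_adjusted stars
    FK      CTRL      90          89  214.6000  8.910570 5.077105e-19 1.523132e-18  ****
    TH      CTRL      87          89  237.8333 10.332564 5.020023e-25 1.506007e-24  ****
 FK+TH      CTRL      90          89  184.9056  6.980395 2.943514e-12 8.830543e-12  ****
```

Reading the output: the control's normalized median is 1 by
construction; the treated conditions' medians (1.31, 1.40, 1.27 here)
estimate their true fold enrichments (1.347, 1.331, 1.331 in the
presets) from only ~90 fragments per condition. The omnibus H rejects
equality of the four distributions, and each Dunn comparison against
CTRL is significant at the `****` level. `demo/` now contains the
images, `manifest.csv`, `measurements.csv` (one row per fragment),
`summary.csv`, `stats.csv`, `violin.png` and a `run_log.txt` recording
every parameter.

To analyze your own TIFFs, provide a manifest (`file`, `condition`
columns) and call

```r
run_ingest_experiment("manifest.csv", run_config(control_label = "CTRL"),
                      out_dir = "results")
```

or use the CLI (`inst/cli/perimembrane.R`) with subcommands
`simulate`, `segment`, `quantify`, `stats`, `all`.

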