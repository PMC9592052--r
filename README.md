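# tpmquant

Ratiometric quantification of tropomyosin decoration on actin structures in
two-channel fluorescence microscopy of rod-shaped (fission-yeast-like)
cells.

Tropomyosin binds along actin filaments, and a single cellular pool of it
decorates three very different F-actin assemblies: endocytic patches,
interphase cables, and the cytokinetic actomyosin ring. Given a two-channel
image — a tropomyosin reporter and an F-actin reporter (LifeAct fusion) —
`tpmquant` measures how much tropomyosin each structure carries *per unit of
F-actin signal*, normalized so that reporter brightness and expression
differences cancel. The package is aimed at quantitative cell biologists
analysing such stacks, and at anyone needing a tested reference
implementation of this class of two-channel structure-decoration
measurement.

## The statistic

For a structure ROI, with `T` the tropomyosin channel and `F` the F-actin
channel:

    r = [ (T_roi − T_cyt) / (F_roi − F_cyt) ] × [ (F_cell − F_out) / (T_cell − T_out) ]

where `X_roi` is the ROI mean with the 10% darkest pixels discarded (cable
ROIs are first shrunk by 1 px), `X_cyt` the parent cell's cytoplasm mean
with the 10% brightest pixels discarded, `X_cell` the untrimmed mean over
the whole cell instance, and `X_out` the untrimmed mean over extracellular
pixels. The first factor is decoration above the cytoplasmic pools; the
second cancels expression/brightness differences between the channels.
Results are aggregated per class as mean ± s.e.m. with n.

The package provides the full workflow around the statistic: calibrated
16-bit TIFF stack I/O with JSON sidecars, z-projection (average/maximum),
photobleaching correction (`simple_ratio` / exponential fit), two-channel
translation registration (FFT cross-correlation, optional subpixel),
trainable per-pixel segmentation (random forest over a standard feature
bank) plus a deterministic rule-based fallback, per-cell instance detection
with clump rejection, kymographs along the cell long axis, and a
ground-truthed synthetic microscopy simulator (capsule cells, Gaussian PSF,
Poisson + read noise) used to validate the whole chain.

## Worked example

Simulate a small field of cells whose structures carry known decoration
ratios (patch 0.14, cable 0.97, ring 0.95), then quantify it with the
simulator's ground-truth masks:

```r
library(tpmquant)

cfg <- scene_config(n_cells = 4, fov_um = c(28, 28),
                    decoration_ratio = c(patch = 0.14, cable = 0.97,
                                         ring = 0.95),
                    patch_decorated_fraction = 1, ring_fraction = 0.3)
opt <- optics_model(n_zplanes = 1)      # single-plane (projected-image) mode

tab <- NULL
for (i in 1:8) {
  rendered <- render_scene(sample_scene(cfg, seed = i), opt)
  ch1 <- rendered$stack$data[1, 1, 1, , ]; dim(ch1) <- dim(rendered$labels)
  ch2 <- rendered$stack$data[1, 2, 1, , ]; dim(ch2) <- dim(rendered$labels)
  cells <- detect_cells(rendered$labels)
  tab <- rbind(tab, quantify_image(rendered$labels, cells, ch1, ch2,
                                   pixel_size_nm = 69))
}
aggregate_ratios(tab)
#>   class   n      mean         sem
#> 2 patch 115 0.2085407 0.008861355
#> 1 cable  85 1.0014379 0.002932810
#> 3  ring  11 0.9502170 0.011097685
```

Cables and rings are recovered at their configured values. The patch class
mean exceeds its configured 0.14 for two documented reasons — light from
strongly decorated cables underneath cable-riding patches, and the
trim–noise bias that grows as ROI signal drops — both quantified in the
methods vignette (`vignettes/decoration-ratio-methods.Rmd`).

The full pipeline (simulation → projection → trained segmentation → cell
detection → quantification → per-class tables, with a provenance manifest)
is one call:

```r
res <- run_pipeline(pipeline_config(
  generator = list(config = cfg, optics = opt, n_images = 12),
  segmentation = "classifier", seed = 1))
res$summary
```

A thin command-line interface over the same functions is installed at
`inst/scripts/tpmquant.R`
(`simulate | project | bleach-correct | register | segment | quantify |
kymograph | pipeline`).

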