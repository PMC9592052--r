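---
title: "Quantifying tropomyosin decoration of actin structures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tropomyosin decoration of actin structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmquant)
```

## The measurement problem

Tropomyosin is a coiled-coil dimer that binds along actin filaments. In
fission yeast a single gene (*cdc8*) supplies the tropomyosin for three very
different F-actin assemblies: endocytic patches, interphase cables, and the
cytokinetic actomyosin ring (CAR). A two-channel live-cell experiment — a
tropomyosin reporter in one channel, an F-actin reporter (a LifeAct fusion)
in the other — can ask *how much tropomyosin sits on each structure class,
per unit of actin*. The answer cannot be read off raw intensities: the two
fluorophores differ in brightness and expression level, both channels sit on
cytoplasmic pools of unbound reporter, and the camera adds background.

`tpmquant` implements the normalized **decoration ratio** that answers this
question, together with every supporting image operation the workflow needs,
and a ground-truthed simulator used to validate the whole chain.

## The decoration-ratio statistic

For one structure ROI the statistic is

$$
r \;=\; \frac{\overline{T}_{\mathrm{roi}} - \overline{T}_{\mathrm{cyt}}}
             {\overline{F}_{\mathrm{roi}} - \overline{F}_{\mathrm{cyt}}}
     \;\times\;
     \frac{\overline{F}_{\mathrm{cell}} - \overline{F}_{\mathrm{out}}}
          {\overline{T}_{\mathrm{cell}} - \overline{T}_{\mathrm{out}}}
$$

where $T$ is the tropomyosin channel, $F$ the F-actin channel, and the four
reference means per channel are: the ROI mean with the lowest 10% of pixels
discarded; the parent cell's cytoplasm mean with the highest 10% discarded;
the untrimmed mean over all pixels of the cell instance; and the untrimmed
mean over all extracellular pixels of the image. Cable ROIs are additionally
shrunk by one pixel (3×3 erosion) before measurement so that their dim rim
does not dilute the cable signal; if erosion empties a cable ROI the original
pixel set is kept and flagged.

The first factor is the structure's tropomyosin-per-actin signal above the
cytoplasmic pools. The second normalizes away the difference in overall
expression/brightness between the two reporters: if the tropomyosin channel
were globally twice as bright, both its numerator and its cell-level signal
would double and $r$ would not move. Two properties follow directly and are
enforced by tests: multiplying either whole channel by a positive constant
leaves every $r$ unchanged, and adding a constant offset to a whole channel
(which shifts its measured outside level equally) also leaves $r$ unchanged.

ROIs whose above-cytoplasm F-actin signal, or whose cell-level tropomyosin
signal above background, is not positive cannot be normalized; they are
excluded with an explicit reason in the output table, never silently zeroed.
Per class the pipeline reports the mean, the standard error of the mean
(sample SD over $\sqrt{n}$; undefined at $n = 1$, never reported as 0), and
$n$.

### Known biases of the estimator

The statistic is simple and robust, but not unbiased, and the simulator makes
the biases measurable:

* **Normalization bias.** The cell-level means include the structures
  themselves. If structures carry a fraction $s$ of the cell's
  above-background F-actin signal, the normalization factor is inflated by
  $(1+s)/(1+\rho s)$ for true ratio $\rho$ — exact at $\rho = 1$, a few
  percent upward at low $\rho$ for $s \approx 0.1$. The statistic therefore
  presumes that most reporter signal is cytoplasmic, which holds for
  diffuse-pool reporters such as LifeAct and tropomyosin fusions.
* **Trim–noise bias.** Discarding the darkest 10% of a noisy ROI raises its
  mean by about $0.195\,\sigma$; discarding the brightest 10% of the noisy
  cytoplasm lowers that reference likewise. Both inflate both numerators by
  the same additive amount $b$, biasing $r$ from $\rho$ toward
  $(\rho N + b)/(N + b)$ where $N$ is the F-actin numerator. The effect
  vanishes at $\rho = 1$ and grows as structures get dimmer; it is the main
  reason the dimmest simulated conditions recover ratios a few hundredths
  high. The same trims exist to remove real contamination (dim ROI rims,
  bright cytoplasmic specks), which the flat simulated cytoplasm does not
  contain, so the simulation shows the worst case of this bias.
* **Cross-class contamination.** A pixel belongs to exactly one class, but
  the light does not: a patch footprint overlapping a strongly decorated
  cable inherits some of the cable's channel-2 signal. With patches at 0.14
  and cables at 0.97 this inflates the patch class mean by roughly +0.07
  with ground-truth masks (more with trained masks, whose patch footprints
  have a wider halo). In real cells, patches at the tip cortex and cables
  along the shaft are largely disjoint; the residual overlap of
  cable-riding patches is a real feature of the system.

## Reference sets and the cell edge

The cytoplasm and outside reference means exclude pixels within a small
margin (default 2 px) of the cell boundary. The point-spread function rolls
intensity off across the edge over about two pixels; generative ground-truth
labels assign those transitional pixels to cytoplasm or outside, but their
values estimate neither reference level, and appearance-based segmentation —
the instrument the measurement is defined on — never labels them as either
class. Without the margin, the cytoplasm reference drops several counts below
the cytoplasmic level and every ratio numerator inflates additively. ROI
pixels are never excluded by the margin.

Components smaller than the PSF support area
($\pi (2\sigma_{\mathrm{psf}})^2 \approx 16$ px at $\sigma = 1.1$ px) are
dropped before measurement (`min_roi_px`): a "structure" smaller than the
instrument's resolution element is segmentation speckle, and its near-0/0
ratio is noise.

## Segmentation

Following the two-channel design of the experiment, patches (and cytoplasm
and outside) are detected in the F-actin channel and cables and rings in the
tropomyosin channel; the merged label map resolves overlaps with precedence
ring > patch > cable > cytoplasm > outside (the rarest, brightest class
wins). A consequence worth noting: cable and ring detection *requires* their
tropomyosin decoration. In simulations where cables carry almost no
channel-2 signal (uniform ratio 0.1), tropomyosin-channel cable segmentation
is unidentifiable in principle — trained classifiers return speckle and the
cable class mean from trained masks is meaningless there. The experiment's
own design premise is that cable and ring decoration is high.

The trainable classifier is a probability random forest over a standard
trainable-segmentation feature bank: raw intensity; Gaussian-smoothed
intensity at sigma 1, 2, 4, 8 px; gradient magnitude and Laplacian at each
scale; difference-of-Gaussians between consecutive scales. Training pixels
come from sparse annotations; the helper that emulates an annotator spends
half of each non-structure class budget on pixels bordering structures,
where the class boundary is hardest. Training and prediction are
deterministic for a fixed seed (fixed forest seed, single thread, first-max
tie-breaking). A deterministic rule-based fallback (`threshold_segment`)
covers data with no annotations: Otsu cell mask, per-channel thresholds
referenced to the in-cell median and bright-structure quantile, and
thickness-based ring/cable separation.

Cell instances are 8-connected components of non-outside pixels. A touching
mother–daughter pair is deliberately one instance. Components larger than
2.5× the median instance area are flagged as clumps and excluded from
quantification (the area factor is configurable); components below
`min_area` are dropped.

## The synthetic scene generator

No raw images from the original experiments are public, so validation runs
on simulated scenes with known ground truth. The generator emulates:

* **Cells**: capsules (rectangle plus hemispherical caps) of radius 1.75 µm
  and length 7–14 µm — typical fission-yeast dimensions — placed without
  overlap (0.5 µm clearance) except for deliberately placed clumps of
  touching cells, which exist so clump rejection is testable.
* **Structures**: Gaussian-profile spots (patches, sigma 0.15 µm, biased
  toward the tip caps), Gaussian-profile tubes along jittered polylines
  spanning the shaft (cables, sigma 0.09 µm), and a medial band (ring,
  sigma 0.2 µm) in a configurable fraction of cells. Cables end before the
  tip domes where the patches live, as in the real cell; a configurable
  fraction of patches rides on cables in the interior. Ground-truth labels
  record each pixel's generating class within the profile's 2-sigma
  effective extent (86% encircled energy), with ring > patch > cable
  precedence.
* **Channels**: channel 2 carries `decoration_ratio[class] ×` the channel-1
  structure amplitude, times a global `expression_scale_ch2`. Only a
  configurable fraction of patches (default 0.5) carries channel-2 signal at
  all, mirroring the observation that only a subset of patches contains
  tropomyosin. Channel 2 is expressed in expression-normalized units — its
  cytoplasmic excess above background equals channel 1's — so that the
  configured decoration ratio is exactly the quantity the statistic
  estimates; a true expression difference is the single global factor the
  normalization cancels.
* **Optics and camera**: Gaussian PSF (sigma 1.1 px laterally ≈ 76 nm at
  the default 69 nm/px, 1 plane axially), Poisson shot noise, Gaussian read
  noise (3 counts), offset 100 counts. Defaults: 16 z-planes at 0.4 µm.

Intensity scales are free parameters of the simulation (the imaging
parameters that set them are not published). The defaults — outside 10,
cytoplasm 300, patch 400 / cable 180 / ring 350 photons above cytoplasm —
were chosen so that structures carry roughly 10% of a cell's
above-background signal, consistent with diffuse-pool reporters and with the
statistic's validity domain discussed above.

**Single-plane versus multi-plane mode.** The single-plane mode
(`n_zplanes = 1`) treats the structure amplitudes as contrasts of the
*projected* image and is the mode used for validation and for the
acceptance run. The multi-plane mode renders the cell body across the
z-planes it occupies with structures in the focal plane; an average
z-projection then dilutes point and line structures several-fold relative to
the volumetric cytoplasm — as real projections do — so at the same per-plane
amplitudes its readouts carry larger small-numerator biases. The multi-plane
path (render → 16-bit TIFF → read → projection → quantification) is covered
by the pipeline tests.

What the simulator does **not** model: cytoplasmic texture and organelle
exclusion zones, bright cytoplasmic specks (so the 10% trims only ever pay
their bias cost, never their contamination benefit), depth-dependent PSF
width, uneven illumination, camera fixed-pattern noise, and structure
dynamics beyond a constant-velocity mode used by kymograph tests. Passing
validation here shows the measurement chain is correct and calibrated on
data satisfying its assumptions; it does not certify accuracy on real images
that violate them.

## Preprocessing

* **Projection**: pixelwise mean or maximum over z. Quantification always
  uses the average projection; maximum projection is for display and
  kymographs.
* **Bleach correction**: per channel, `simple_ratio` (each frame rescaled to
  the first frame's mean — the common default) or `exponential_fit`
  ($I(t) = a e^{-kt} + c$ fitted to frame means by Levenberg–Marquardt,
  frames divided by the normalized fitted decay; a non-convergent fit falls
  back to `simple_ratio` with a warning). For a time series the pipeline
  order is bleach correction before projection, configurable.
* **Registration**: dual-camera misalignment is modeled as a pure
  translation, estimated by FFT cross-correlation with a bounded search
  window (integer pixels by default; optional subpixel refinement evaluates
  the correlation surface on a 0.05 px grid around the integer peak by
  matrix DFT). The aligned image's unfilled edge pixels are masked and
  excluded from all downstream statistics.

## Kymographs

The cell long axis is the principal direction of the mask's second-moment
matrix through its centroid, clipped to the mask extent, with a fixed
orientation convention (angle in $[0, \pi)$, first endpoint at smaller x).
Masks with aspect ratio below 1.2 warn that the axis is ill-defined.
Kymographs sample each time frame by bilinear interpolation at unit steps
along the line, averaging over an odd perpendicular width (default 5 px —
the display width is not published, so it is configurable). A ridge helper
(per-column argmax with parabolic sub-pixel refinement, linear fit of
position on frame) supports the velocity-recovery tests; recovered
velocities are within 5% at 0.5–2 px/frame.

## Reproducibility

Every stochastic step is seeded: scene sampling, noise draws, annotation
subsampling, the classifier's forest, and the holdout split. Dataset and
pipeline runs write JSON manifests recording every parameter and seed;
re-running from a manifest reproduces byte-identical images and tables
(`regenerate_dataset()`, `rerun_from_manifest()`). Prediction uses one
thread and first-maximum tie-breaking so results do not depend on thread
scheduling.

## Validation summary and problem sizes

The test suite validates each operation against independent oracles
(sort-discard-average for the trimmed mean, a brute-force 3×3 neighborhood
check for erosion, constructed shifts for registration, known decay rates
for bleach correction, known velocities for kymographs) and the whole chain
by parameter recovery: scenes at decoration ratios 0.1–1.0 and at the
mixed condition (patch 0.14 / cable 0.97 / ring 0.95), 30+ cells per
condition rendered at default noise in single-plane mode, quantified with
ground-truth masks and with trained segmentation. Recovery is within ±0.05
(ground-truth masks) for patches and rings across conditions; cable means at
the dimmest conditions run ~0.05–0.06 high (the trim–noise bias quantified
above), and the mixed condition's patch mean runs ~0.07 high
(cross-class contamination). The trained-segmentation route matches the
ground-truth route within its wider tolerance wherever the segmented channel
actually carries signal. These residuals are properties of the estimator
under the stated conditions, documented rather than tuned away.

Test problem sizes (2–4 cells per ~26–28 µm field, 8 images per condition,
single-plane rendering) keep the default suite fast while meeting the
30-cells-per-condition design of the recovery experiments.
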