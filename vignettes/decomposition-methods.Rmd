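---
title: "Decomposition-based CT-free PET correction: model, simulator and evaluation"
author: "petdecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposition-based CT-free PET correction: model, simulator and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petdecomp)
```

## The problem and the decomposition

PET images reconstructed without attenuation and scatter correction
(NASC-PET) underestimate activity wherever annihilation photons traverse
dense tissue, and carry a smooth scattered-background haze. The clinically
established fix divides out attenuation-correction factors computed from a
CT-derived $\mu$-map — at the cost of additional ionizing radiation. A
CT-free alternative is to learn the correction from data. Learning the
corrected image *directly* from the uncorrected one forces a network to
reproduce tracer- and disease-dependent texture, which transfers poorly to
scanners and tracers not seen in training.

This package implements the decomposition alternative. Define the
anatomy-dependent correction map (ADCM) voxel-wise from a paired
acquisition:

$$
I^{\mathrm{ADCM}}[x,y,z] =
\begin{cases}
\dfrac{I^{\mathrm{ASC}}[x,y,z]}{I^{\mathrm{NASC}}[x,y,z]} &
  I^{\mathrm{NASC}}[x,y,z] > \varepsilon\\[2ex]
I^{\mathrm{ASC}}[x,y,z] & \text{otherwise,}
\end{cases}
$$

with $\varepsilon = 1$ in stored intensity units by default. Correction of
a new uncorrected volume multiplies by a (predicted) map wherever
$I^{\mathrm{NASC}} > \varepsilon$ and passes the voxel through unchanged
otherwise, so the full-resolution texture of the input survives
multiplication by a slowly varying field. The two branches are
deliberately asymmetric: below $\varepsilon$ the map *stores* the
corrected intensity — giving the regression a meaningful target in
low-count voxels — while application *ignores* the map there. Both
branches are implemented verbatim; `applyADCM(nasc, computeADCM(nasc,
asc))` restores `asc` exactly on every voxel above threshold and `nasc`
below it, which the test suite asserts bitwise on exact-arithmetic inputs.

Because attenuation factors and scatter vary on the scale of anatomy (tens
of millimetres), the ratio map is dominated by low spatial frequencies.
That is what makes the learning problem easy and transferable: the package
quantifies it as the fraction of spectral energy above one quarter of the
Nyquist frequency (`highFreqEnergyFraction`), which is consistently
smaller for the true map than for the corrected image itself across seeded
phantoms.

## The estimator

A conditional adversarial pair estimates the map from the uncorrected
volume alone. The generator is a volumetric U-Net (encoder–decoder with
skip connections, two 3³ convolutions per level, instance normalization,
leaky rectifier activations, nearest-neighbour upsampling, linear 1³
output head). The discriminator scores the channel-stacked pair
(condition, candidate) through a strided conv/pool stack, global average
pooling and a sigmoid head. Losses follow the conditional minimax game
with an L2 regression term weighted by $\lambda$:

$$
\min_G \max_D \; \sum_i \log D(x_i, t_i) + \log\big(1 - D(x_i, G(x_i))\big)
  \;+\; \lambda\,\| G(x_i) - t_i \|^2 ,
$$

with $\lambda = 10^4$ by default, so the regression term dominates and the
adversarial term acts as a refinement; a `pureL2` flag drops the
adversarial terms entirely for debugging and ablation. The squared-error
form is used for the penalty (mean squared error over voxels), the
conventional choice for conditional image translation. Optimization is
Adam (generator $2\times10^{-3}$ to $10^{-3}$, discriminator $10^{-4}$),
batch size 1, alternating discriminator/generator updates. All stochastic
sources — initialization and shuffling — derive from the config seed, so
identical configs reproduce identical loss traces bitwise. Training aborts
with the epoch index if any loss becomes non-finite.

Three modes share the same backbone so comparisons isolate the
decomposition itself:

* **decomposition** — target is the true ADCM at the working resolution;
  prediction is upsampled to the native grid and applied through the
  $\varepsilon$-branch. Wherever the input is at or below $\varepsilon$
  the end-to-end output equals the input *regardless of the network
  state* — a texture-preservation guarantee the direct baselines cannot
  make.
* **direct3d** — target is the corrected volume itself.
* **direct2d** — axial slices are independent samples; in-plane working
  resolution only, per-slice normalization, so each output slice depends
  only on its input slice (asserted by perturbation in the tests).

Inputs are normalized per volume (per slice in direct2d) by the robust
99th-percentile intensity, undone on output; per-volume normalization is
what lets one trained model face scanners with different count scales.
Predicted ratios are clipped to $[0, r_{\max}]$ ($r_{\max} = 100$) before
application, guarding against blow-ups in air voxels. The working
resolution is a config choice: 112³ reflects the full-scale design and its
insensitivity to matrix size; the desk-scale defaults used throughout the
tests are 32³ and 16³. Where the map is applied is likewise explicit: the
predicted map is trilinearly upsampled to the native grid and applied
there, preserving full-resolution texture.

## The phantom simulator

Clinical paired volumes are replaced by an image-space forward model that
preserves exactly the structure the method exploits:

* **Geometry.** A soft-tissue body ellipsoid with two lungs, liver, heart,
  kidneys, a spine column and two hot spherical lesions, rasterized by
  voxel-centre membership (background level everywhere, organ value =
  background × multiplier, later entries overwriting earlier), then
  smoothed by the scanner PSF (Gaussian, FWHM 5 mm default). Attenuation
  is piecewise constant at 511 keV values: soft tissue 0.0096/mm, lung
  0.003/mm, bone 0.017/mm, air 0.
* **Attenuation.** For every voxel the full line integral of $\mu$ is
  accumulated along in-plane directions (both emission directions, as for
  a coincidence line of response) by fixed-step ray marching with step =
  half the smallest voxel spacing, and $e^{-\int\mu}$ is averaged over 8
  equally spaced transaxial angles. Oblique rays are omitted: they add
  cost without changing any tested property. The marcher is verified
  against an independent per-voxel loop and against the analytic chord
  $e^{-2\mu_0 R}$ at a uniform sphere's centre.
* **Scatter.** A Gaussian-blurred copy (FWHM 40 mm) of the attenuated
  image, scaled so the stated scatter fraction (0.25 default) is exactly
  the scattered share of total counts — capturing scatter's low-frequency
  character, which is all the decomposition needs.
* **Noise.** Poisson count statistics applied *once* to the measured
  (attenuated + scattered) image at a count scale of 4 counts per
  intensity unit; the corrected reference is then reconstructed from the
  same noisy measurement as $(\mathrm{NASC} - \mathrm{scatter})/
  \mathrm{AF}$, clipped at zero. This mirrors the clinical situation —
  uncorrected and corrected images are reconstructions of one acquisition,
  so their noise is strongly correlated — and it is what keeps the true
  ratio map anatomy-dependent rather than noise-dominated. With scatter
  and noise disabled the identity $\mathrm{NASC} = \mathrm{ASC}\times
  \mathrm{AF}$ holds to machine precision and the true map equals
  $1/\mathrm{AF}$ above threshold.
* **Families and shifts.** `makeDataset` draws subjects by jittering organ
  centres (±1.5% of extent), semi-axes (±8%) and uptake (±10%) from named
  sub-stream seeds; the first pair is the canonical unjittered subject. A
  *scanner* shift widens the PSF ×1.5, halves the count scale and adds
  0.10 scatter fraction; a *tracer* shift swaps the organ-multiplier
  profile (e.g. the liver-avid profile with 5× hepatic uptake emulating
  receptor-targeted agents). Activity units are arbitrary concentration
  units with soft tissue near 100, so $\varepsilon = 1$ is a low-count
  threshold as it is for Bq/mL-scale clinical images; SUV conversion is a
  scale factor applied at evaluation time.

What the simulator does *not* emulate: sinogram-domain reconstruction and
its correlated artifacts, time-of-flight, randoms, respiratory motion,
inter-vendor calibration offsets, and real tracer pharmacokinetics.
Passing tests therefore demonstrate that the implementation realizes the
decomposition's claimed mechanisms under controlled physics — not clinical
performance.

## Evaluation protocol

`globalMetrics` returns NRMSE, PSNR and SSIM together. Design choices the
definitions leave open are fixed as: NRMSE normalizer = reference range
(max − min); PSNR peak = reference maximum (PET intensities are
unbounded); SSIM = volumetric 3D computation over a 7³ uniform window with
constants $(0.01L)^2, (0.03L)^2$ on the *joint* dynamic range $L$ of the
two inputs, which makes the index exactly symmetric. A constant reference
is reported as an explicit error, and a perfect prediction as an infinite
PSNR sentinel.

Local metrics use spherical VOIs — placed automatically at organ centres
with radius 40% of the smallest semi-axis (floored at half a voxel
diagonal on coarse grids) — yielding SUV$_\mathrm{mean}$,
SUV$_\mathrm{max}$ and total lesion metabolism (SUV$_\mathrm{mean}$ ×
VOI volume in mL; one definition, one name). A configurable first-order
feature set (mean, max, entropy, skewness, kurtosis, energy) feeds the
feature-level mean absolute percentage error; zero-reference features are
excluded with a logged count. Joint-histogram analysis fits ordinary least
squares of predicted on reference intensities over a reference-masked
voxel set; a slope near 1 indicates voxel-wise agreement. Mode comparisons
use the classical paired two-tailed t-test with Bonferroni-corrected
significance ($p < 0.05/m$; $0.025$ for two comparisons), with exact ties
reported as such rather than as division errors.

## Numerical and reproducibility choices

* Resampling is separable linear (or nearest) interpolation under the
  coordinate convention position = index × spacing; spacing is rescaled so
  physical extent is preserved; constants resample exactly, and
  boundary samples clamp to the last voxel.
* One global seed fans out to every phantom, dataset and model through a
  named-substream hash, so adding components never perturbs existing
  streams; every experiment writes a manifest of the derived seeds and a
  config hash, and reruns reproduce all outputs byte-for-byte.
* Problem sizes in the test suite are deliberate desk-scale choices:
  phantoms of 64³ × 4 mm (simulator properties) and 32³ × 8 mm (learning),
  working grids of 32³ and 16³, 12–60 training subjects, 10–12 epochs.
  The reference calibration runs for the two learning checks (a
  constant-unity-map baseline for map prediction; the
  decomposition/direct3d ordering on shifted families) were performed once
  with these configurations and their margins frozen into the tests.

## Known limitations

The generator's native-resolution application assumes the uncorrected
input and the predicted map share physical extent; anisotropic grids are
supported but not rotated/oblique geometries. The discriminator is
intentionally small; at desk scale the adversarial term contributes little
beyond the L2 term (by design, $\lambda = 10^4$). The image-space forward
model cannot validate sinogram-domain claims, and no clinical performance
figure should be read off the synthetic families.
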