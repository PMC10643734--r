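# spinesynth

Paired MR-to-CT translation of sagittal spine imaging with conditional
denoising diffusion implicit models (DDIM), in R.

Spine MRI shows soft tissue and marrow; CT shows cortical bone. CT-trained
segmentation models therefore cannot run on MR directly — but a synthetic CT
translated *from* the MR is perfectly aligned with it by construction, so
segmenting the synthetic CT segments the MR. Two obstacles dominate:
building aligned MR/CT training pairs, and translating the thin posterior
structures (especially the spinous process) correctly. `spinesynth`
implements the whole pipeline:

* **Vertebra-landmark rigid registration** — per-vertebra centre-of-mass
  landmarks, in 1-point (vertebral body) and 2-point (body + spinous
  process) modes, solved in closed form (Kabsch/SVD), with an iterative
  translate-and-segment refinement loop. The 1-point mode leaves rotation
  about the craniocaudal axis unconstrained (the body centroids are nearly
  collinear); the 2-point mode pins it down.
* **Conditional DDIM translation** — noise- and image-prediction modes with
  algebraic inter-conversion, DDIM stepping with stochasticity η, few-step
  inference (t = 20 in 2D, t = 25 in 3D), classifier-free guidance (w), a
  2D self-attention U-Net and a 3D attention-free, additive-skip,
  fully-convolutional variant with position-ramp inputs (any side divisible
  by 8). Networks, backprop and Adam are implemented in the package (Rcpp
  conv kernel); gradients are verified against finite differences.
* **Preprocessing** — HU normalisation (`clamp(v/1000, -1, 1)`), MR
  `[0, max] → [-1, 1]`, brightness/contrast jitter (0.2), tenfold elastic
  augmentation with a shared displacement field, sagittal slicing with
  random/centred 256×256 cropping, 1 mm isotropic resampling and
  128×128×32 patching with position ramps.
* **Evaluation** — L1 / MSE / PSNR / SSIM / VIFp restricted to within 10
  pixels of segmented spine (exact Euclidean distance transform), and Dice
  overlap globally, per vertebra, and posterior-only (vertebral bodies
  removed).
* **A spine phantom** — paired MR/CT volumes with per-vertebra body and
  spinous-process labels, a known non-monotonic MR↔CT intensity map,
  anisotropic (1×1×3 mm) voxels and configurable rigid misalignment, so
  everything above is testable without any clinical data.

The model core: a denoiser `f(x_t, MR, t)` is trained on
`x_t = √ᾱ_t·CT + √(1−ᾱ_t)·ε` to predict either `CT` (image mode) or `ε`
(noise mode) under MSE; inference iterates the DDIM update
`x_{t'} = √ᾱ_{t'}·x̂₀ + √(1−ᾱ_{t'}−σ²)·ε̂ + σz` with
`σ = η·√((1−ᾱ_{t'})/(1−ᾱ_t))·√(1−ᾱ_t/ᾱ_{t'})` from pure noise, conditioned
on the MR.

## Worked example

Generate a misaligned phantom, register it with one and two landmarks per
vertebra, and compare the posterior-structure overlap:

```r
library(spinesynth)

case <- generate_phantom(phantom_config(
  seed = 7,
  misalignment = list(angle_deg = 10, axis = "craniocaudal",
                      translation_mm = c(2, 1, 0))))
case
#> <paired_case> 5 vertebrae, grid 64 x 96 x 20, spacing 1 x 1 x 3 mm
#>   CT misaligned: 10.00 deg rotation, |t| = 6.48 mm

for (pts in 1:2) {
  st <- if (pts == 1) "body" else c("body", "spinous_process")
  fit <- fit_rigid(extract_centroids(phantom_segmenter(case$ct), st),
                   extract_centroids(case$mask, st))
  reg <- resample_onto(case$ct_mask, fit, grid_of(case$mask))
  d <- dice(case$mask, reg, protocol = "posterior_only")
  cat(sprintf("%d-point: posterior DSC %.3f\n",
              pts, d$posterior_only$per_volume))
}
#> 1-point: posterior DSC 0.033
#> 2-point: posterior DSC 0.890
```

The single-landmark fit leaves the 10° craniocaudal rotation in place —
the body centroids lie along that axis, so the rotation about it is
essentially unconstrained and the fit reduces to a translation — and the
spinous processes miss almost completely; the second landmark recovers the
rotation to a fraction of a degree and the posterior overlap jumps
accordingly.

Translating with the phantom's analytic MR→CT oracle and scoring it:

```r
cfg <- phantom_config(seed = 7)
case <- generate_phantom(cfg)
synth <- phantom_oracle_translator(cfg)(case$mr)
quality(normalize_ct(synth), normalize_ct(case$meta$ct_clean),
        seg = case$mask)
#> <quality_report (spine-masked)> L1 0.0015 | MSE 0.00261 | PSNR 31.85 dB | SSIM 0.9759 | VIFp 0.9796
```

A PSNR above 30 dB means the synthetic CT is essentially indistinguishable
from the reference inside the spine neighbourhood; the residual error here
is entirely MR-noise misclassification at compartment boundaries. Training
a small conditional DDIM instead of using the oracle is exercised in
`tests/testthat/test-acceptance.R` (2000 Adam steps at learning rate 2e-5
on 32×32 crops) and must beat the best linear rescaling of the MR — which
it does by a wide margin, because the MR→CT intensity map is non-monotonic.

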