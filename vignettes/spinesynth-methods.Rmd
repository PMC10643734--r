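---
title: "Methods: paired MR-to-CT spine translation with conditional DDIMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired MR-to-CT spine translation with conditional DDIMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spinesynth)
```

## The problem

Sagittal spine MRI shows bone marrow, discs and cord beautifully, but the
cortical bone that CT-based segmentation models rely on is nearly invisible:
bone is dark on MR while soft tissue is bright, the *opposite* of the CT
contrast. Translating an MR volume into a CT-like volume lets pretrained CT
segmentation tooling run on MR studies, with the synthetic CT perfectly
aligned to the source MR by construction. Two things make the spine hard:

1. **Paired training data requires registration.** MR and CT are acquired in
   different sessions and positions. A rigid alignment driven by one landmark
   per vertebra (the vertebral-body centre of mass) pins down translation and
   two rotations, but leaves rotation about the craniocaudal axis
   unconstrained — the vertebral bodies form an almost collinear chain. That
   residual rotation misplaces exactly the structures that are hardest to
   translate: the posterior elements. Adding a second landmark per vertebra
   (the spinous-process centre of mass) removes the degeneracy.
2. **Thin structures versus thick slices.** The spinous process is thinner
   than two sagittal slices at clinical slice spacing, so slice-wise 2D
   translation suffers partial-volume loss there; a 3D translator operating
   on 1 mm isotropic volumes does not.

The package implements the full pipeline — phantom data generation, landmark
registration, preprocessing, conditional diffusion translation in 2D and 3D,
and masked image-quality plus Dice evaluation — so both effects are
measurable end to end on synthetic data.

## The spine phantom

Because clinical volumes cannot ship with a package, every stage is testable
against a generated phantom (`generate_phantom()`): a stack of vertebrae
(ellipsoidal body, thin posterior arch, rectangular spinous-process block)
inside a soft-tissue cylinder, rendered into both modalities from one tissue
map. Key properties, chosen once and fixed:

* **Grid and spacing.** 64 x 96 x 20 voxels at 1 x 1 x 3 mm — fine in the
  sagittal plane, coarse left-right, emulating thin-slice sagittal
  acquisitions. The spinous process is 5 mm wide left-right, i.e. thinner
  than two slices, which is the regime where 2D translation degrades.
* **Intensities.** CT: air -1000 HU, soft tissue +40 HU, bone +700 HU.
  MR (arbitrary units): air 0, soft tissue 800, bone 150. The MR-to-CT map
  is deliberately non-monotonic in intensity — bright MR soft tissue maps to
  mid CT, dark MR bone maps to bright CT — so no global intensity rescaling
  can solve the task. This is exactly the property that defeats
  intensity-only translation and makes the learned conditional model
  necessary.
* **Noise.** Additive Gaussian, SD 30 (MR) and 20 HU (CT) by default. CT
  reconstruction noise in the wild is scanner- and kernel-dependent; the
  phantom's noise is a free parameter, not a claim of realism.
* **Ground truth.** The case stores the aligned noiseless CT, per-structure
  centroids and the applied misalignment, so registration and translation
  errors are measurable analytically. `phantom_oracle_translator()` is the
  exact MR-to-CT map implied by the generator and serves as a drop-in for a
  trained network in pipeline tests.
* **Reference segmenter.** `phantom_segmenter()` plays the role of an
  external CT segmentation model: bone threshold 150 HU (well above soft
  tissue plus noise, but below partial-volume-diluted bone, so the thin
  arch survives linear resampling), 6-connected components merged by
  overlapping craniocaudal extent (a process severed from its body by
  partial volume shares its body's extent; neighbouring vertebrae do not),
  and a body/process split where the anterior-posterior area profile
  collapses below 20% of its peak — the thin-arch waist.
* All randomness flows from the single `seed` in `phantom_config()`.

What the phantom does **not** emulate: anatomical shape variation,
pathology, multi-contrast MR, bias fields, inter-vertebra articulation.
Green tests on the phantom demonstrate the pipeline's mechanics and the
geometric/registration claims, not clinical image quality.

## Registration

Landmarks are unweighted centres of mass of labelled structures, computed in
world millimetres (voxel-centred, right-handed; anisotropic spacing is
handled by doing all landmark math in mm). `fit_rigid()` solves the
least-squares rigid problem in closed form (centering, SVD of the
cross-covariance, sign correction of the smallest singular vector to force a
proper rotation). One global transform is fitted jointly over all
vertebrae's landmarks — inter-vertebra motion is treated as a limitation of
the rigid model, not something it fits — and all vertebrae are weighted
equally.

Degenerate configurations are handled explicitly: with fewer than three
matched landmarks the fit errors; with collinear landmarks the rotation
about the common line is unconstrained, and the fit warns and returns the
*minimal-rotation* solution (the smallest rotation mapping one line
direction onto the other). That choice is what produces the textbook
single-landmark failure: under a craniocaudal rotation the body centroids
stay collinear, the minimal-rotation fit reduces to a pure translation, and
the posterior structures stay misaligned — measurable here as a posterior
Dice gap between 1-point and 2-point registration on every phantom seed.

`refine_registration()` closes the bootstrap loop for unregistered pairs:
translate the MR, segment the synthetic CT, extract centroids, fit the real
CT onto them, resample, repeat. Convergence is declared when the mean
landmark displacement of a round falls below 0.5 mm — half the finest
default voxel — or after a fixed round budget.

## Preprocessing

* CT normalisation: `v -> clamp(v / 1000, -1, 1)` (HU). MR normalisation:
  volume-wise `[0, max] -> [-1, 1]`.
* Intensity jitter: brightness and contrast factors drawn from
  U(0.8, 1.2), applied as `clamp(c * (b * v - m) + m, -1, 1)` with `m` the
  input mean. The exact operator is a package choice; mean-anchoring keeps
  the jitter from drifting the air level. In 2D pipelines jitter is applied
  per volume before slicing.
* Elastic augmentation: ten deformed copies per case, a 5x5x5 control grid
  of Gaussian displacements (SD 4 mm) upsampled trilinearly; the identical
  field warps MR, CT and mask (mask nearest-neighbour), so labels never
  migrate relative to the images. Grid size and SD are configurable; the
  defaults produce mild, scoliosis-like bending without tearing structures.
* Slicing and cropping: sagittal slices whose mask plane is empty are
  dropped; training crops are random within bounds (retried until they
  contain segmentation), evaluation uses one deterministic crop centred on
  the mask's in-plane bounding box. Padding uses -1 (air) for images, 0 for
  masks.
* 3D patches carry three ramp channels giving each voxel's normalized
  position over the *full* volume (affine 0 to 1 per axis, computed before
  cropping), so the fully-convolutional 3D model retains coarse anatomical
  position despite seeing only patches.

## The diffusion core

Training uses the standard forward process
`x_t = sqrt(ab_t) x0 + sqrt(1 - ab_t) eps` over a T = 1000 linear beta
schedule (1e-4 to 0.02; a cosine schedule is available). The denoiser
predicts either the clean image or the noise — `convert_prediction()`
computes the other algebraically, and the two parameterisations produce
identical sampling trajectories (tested to 1e-5). Inference runs the DDIM
update over `n_steps` uniformly spaced timesteps (20 in 2D, 25 in 3D by
default), with stochasticity `eta` (default 1) and optional classifier-free
guidance: with probability 0.1 the condition is dropped during training
(replaced by an all-air image), and at inference the prediction is
extrapolated `(1 + w) cond - w uncond`. Predicted clean images are clamped
to [-1, 1] by default during sampling (`clip_x0`), which stabilises image
mode; it can be disabled.

**A note on few-step sampling bias.** With the *exact* posterior-mean
denoiser of a Gaussian toy distribution, DDIM sampling converges to the
correct distribution as the step count approaches T (the suite verifies
unbiased moments at full step count), but at 20 steps it provably
under-disperses: each strided update treats the predicted clean image as
fixed across the jump, and for any distribution with posterior spread this
contracts variance (by Cauchy-Schwarz, each step multiplies the variance by
a factor < 1 unless consecutive alphabars coincide). At 20 steps the
contraction is 15-40% depending on the data SD. This is a property of
few-step DDIM itself, not of this implementation; for image translation the
conditioning concentrates the posterior enough that the effect is benign,
but moment-matching tests must either use full-step sampling or tolerate
the known bias.

## Denoiser architectures

* **2D (SA-UNet).** U-shaped encoder/decoder, kernel-3 convolutions, group
  normalisation, SiLU, sinusoidal timestep embedding passed through a
  two-layer MLP and injected additively (per channel) in every block after
  the first normalisation — injecting before normalisation would cancel the
  embedding whenever a group contains a single channel. Convolutional
  self-attention (single-head, 1x1 projections, residual) at the two
  coarsest levels. Skips are channel concatenations. Defaults: base width
  64, depth 4 (five resolution levels); the condition enters by channel
  concatenation at the input.
* **3D.** Attention removed, concatenation skips replaced by additions
  (with a 1x1x1 reduction after upsampling), three ramp channels appended
  to the input. Depth 3 means sides must be divisible by 8; the network is
  fully convolutional and its parameter count is independent of input size.
  Defaults: base width 32.

Exact widths and depths are package choices — the architecture family, the
attention-free 3D simplifications, the additive skips and the ramp
embedding are the load-bearing decisions. All weights are randomly
initialised under a stated seed; the final convolution and the attention
output projections start at zero (identity residual), a standard
stabilisation.

The networks, backpropagation and Adam are implemented in the package
itself (an Rcpp im2col kernel carries the 2D convolutions); every layer's
analytic gradient is verified against finite differences in the test suite
to below 1e-5 relative error.

## Training

Adam at learning rate 2e-5, batch 8, MSE on the mode's target. The
translator object records the loss curve and optional held-out validation
losses, and exposes `predict()` (slice or stack translation) and
`simulate()` (repeated eta = 1 draws). An optional weighted (1 - SSIM) term
exists in the loss-reporting interface (`training_step()`) but the gradient
trainer deliberately supports the plain MSE objective only.

## Whole-volume translation and evaluation

`translate_volume()` stitches: in 2D, square tiles matching the training
size with 32-pixel overlap, blended with linear feathering (a constant
image through an identity oracle comes back constant to 1e-6 — no seams);
in 3D, padding to divisible-by-8, one fully-convolutional pass, cropping,
and optional resampling from 1 mm isotropic back to the native grid.

Image quality (L1, MSE, PSNR, SSIM with an 11x11 Gaussian window, and
pixel-domain VIFp over four Gaussian scales) is computed on the normalized
[-1, 1] scale (PSNR range 2) after masking voxels farther than 10 pixels
from segmented spine — soft tissue correspondence is deliberately not
scored. The distance is an exact Euclidean distance transform (separable
parabola scan), configurable to chessboard. On images smaller than a VIFp
window the window shrinks to the largest odd size that fits. Dice supports
global, per-vertebra (unweighted mean over vertebrae present in both
masks) and posterior-only protocols (vertebral-body labels removed), with
explicit exclusions and NA (not 0) for undefined units.

## Problem sizes in the shipped tests

The suite runs on one CPU: phantoms at 64 x 96 x 20 voxels; the trained
acceptance model is a base-16, depth-2 SA-UNet on 32 x 32 crops for 2000
Adam steps (about twelve minutes); registration properties use 20 phantom
seeds; sampler moment checks use 1e4 draws. The acceptance script trains a
shorter 600-step variant of the same configuration. These sizes are the
package's own smoke-scale choices; the defaults encoded in the functions
(256 x 256 crops, base 64, 128 x 128 x 32 patches) are the intended
full-scale settings.

## Known limitations

* The rigid model ignores inter-vertebra motion; deformable refinement is
  out of scope.
* The phantom cannot certify clinical image quality; it certifies geometry,
  contracts and learning signal.
* The pure-R/Rcpp network stack is CPU-bound and meant for smoke-scale
  models; the architectures and contracts translate directly to GPU
  frameworks.
* 3D training is exercised at toy scale only; the 3D path's full-scale
  value is in fully-convolutional inference.
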