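---
title: "Attenuation and high-resolution correction for brain PET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attenuation and high-resolution correction for brain PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Annihilation photons at 511 keV are attenuated along each line of response,
so an uncorrected ("non-AC") brain FDG-PET reconstruction underestimates
activity, most severely at the centre of the head. The clinical standard is
CT-based attenuation correction (CTAC): the CT volume is segmented into a
511-keV linear-attenuation map (mu-map), the map is projected, and the
resulting survival factors `exp(-integral mu dl)` enter the reconstruction.
CT, however, costs radiation dose and can mis-register.

`petac` implements and evaluates three learned alternatives on synthetic
digital head phantoms:

* **indirect** — a U-net translates T1-like MRI into a synthetic CT (SCT);
  the SCT is segmented into a mu-map and CTAC proceeds as usual;
* **direct** — a U-net translates the non-AC reconstruction directly into
  an AC image, trained against CTAC references;
* **direct+HRC** — the same single forward pass, but trained against CTAC
  references that were additionally resolution-corrected by Richardson-Lucy
  deconvolution of the scanner point-spread function (PSF), so attenuation
  and resolution correction are learned jointly.

## The phantom generator

Clinical triplets (MRI, CT, PET) are private; the package generates its own
co-registered 2-D head slices. Geometry is nested ellipses with randomized
axes and offsets: a soft-tissue scalp, a closed high-HU skull ring, a
gray-matter rim, a white-matter core, paired ventricles and striata. Tissue
values are drawn per region: background -1000 HU; soft tissues normal
around 8-40 HU, clipped to [0, 80]; skull normal around 1000 HU, clipped at
700. Activity defaults are white 1.0, gray 4.0 (the typical 4:1 FDG
contrast), striatum 5.0, ventricle 0.2, with 3% multiplicative texture. The
MRI channel receives per-region T1-like intensities with per-case
multiplicative jitter, so the MRI scale is deliberately *not* a fixed
function of HU — the premise that makes MRI-to-CT translation a learning
problem rather than a lookup.

What the phantoms do **not** emulate: real cortical folding and anatomical
variability, MRI sequence physics and bias fields, scatter and randoms,
bone marrow heterogeneity, and 3-D out-of-plane effects. Passing tests on
phantoms therefore demonstrate that the pipeline's mathematics and learning
machinery work, not that clinical accuracy transfers.

Slices are 2-D by design: every comparison the toolkit makes is a per-slice
image metric, and 2-D keeps the physics desk-scale. The default field of
view is fixed at 256 mm, so the pixel size adapts to the grid (1 mm at
256 px, 4 mm at 64 px).

## Acquisition physics

The scanner is reduced to 2-D parallel-beam geometry. The forward projector
takes length-weighted line integrals (cm) by bilinear sampling at
pixel-size steps — exactly linear in the image, which the test suite
exploits. The PSF (Gaussian, FWHM 5 mm by default) is applied in the image
domain *before* projection; this makes the HRC target well-defined as image
-domain deconvolution of the reconstruction. Poisson noise is drawn on the
attenuated projections after scaling the expected total to `total_counts`
(default 5e5 per slice); `total_counts = 0` is the noise-free sentinel.

Two reconstructions are provided. Filtered back-projection (Ram-Lak kernel
evaluated in the spatial domain, pixel-driven back-projection) is the
default for references and tests because it is deterministic, linear and
fast. Ordered-subsets EM (default 3 iterations, 15 subsets, mirroring a
clinical brain protocol) folds the attenuation factors into the system
model, with the back-projector implemented as the exact adjoint of the
forward sampler so the EM fixed-point property holds to machine precision.

### The mu-map rule

The three-class segmentation (air / soft tissue / bone at 0, 0.096 and
0.151 cm^-1, standard 511-keV values) uses thresholds `air below -200 HU`
and `bone at or above +250 HU` by default. The clinical rule this mirrors
is printed with the air/soft boundary at *+200* HU, which would classify
all brain tissue (~0-60 HU) as air and cannot produce working AC images;
we treat that as a sign typo and default to -200, while
`mu_map_thresholds(printed_rule = TRUE)` reproduces the printed rule
verbatim for anyone who wants it.

## Preprocessing

Counts are normalized per case — never pooled across cases — by min-max
scaling to [0, 255]; the `(x_min, x_max)` record makes the mapping exactly
invertible, and an 8-bit PNG round trip is accurate to half a quantization
step in native units. CT display uses window width 2500 / level 250 (a
bone-emphasis window). Augmentation expands each training pair 32-fold:
four 90-degree rotations (lossless by construction; arbitrary angles are
deliberately rejected), four integer translations including the identity
(default offsets (0,0), (+8,0), (0,+8), (+8,+8) px — any identity-containing
four-element set satisfies the 32-fold count), and an optional horizontal
flip, applied in that order. Augmentation operates on the normalized 8-bit
images, matching the pipeline order conversion -> PNG -> expansion.

## The U-net and its training

Thirteen convolutional layers over five depth levels: one 3x3 conv per
encoder level (4), two bottleneck convs, one conv per decoder level after
2x nearest-neighbour upsampling and skip concatenation (4), two refinement
convs, and a final linear 1x1 conv. ReLU and batch normalization sit on
every layer except the last. Channel widths double per level from
`base_channels` (default 16; the toy experiments use 8 for speed). This is
one concrete, shape-sound assignment of the 13-layer/5-depth census; the
exact layout of the original figure is not legible from its text, so the
layout here is a declared package default, fully configurable.

Training minimizes mean squared error with Adam at alpha 0.001, beta1 0.9,
beta2 0.999, epsilon 1e-8. Images are scaled from [0, 255] to [0, 1] inside
the trainer for conditioning and rescaled on output. Everything is seeded:
He-normal initialization, minibatch shuffling, and the Poisson draws of the
training acquisitions, so identical configurations reproduce identical loss
curves bit-for-bit on a fixed single-threaded BLAS.

Two choices matter in the few-epoch regimes the test suite uses:

* **Batch-norm inference statistics** are cumulative (debiased) averages of
  the batch statistics rather than momentum-decayed ones, and are
  **recalibrated** by one extra pass over the training set under the final
  weights. With only a few hundred updates, momentum-0.9 running statistics
  still carry their (0, 1) initialization and wreck eval-mode inference;
  recalibration makes inference consistent with the trained weights at the
  cost of one forward epoch.
* **Batch size** defaults to 8; the toy cross-validation runs use 2. With
  epochs fixed and only ~200 training slices, the number of Adam updates —
  not the data volume — limits what the network can learn, and smaller
  batches buy updates at no gradient-quality cost at this scale.

Cross-validation splits by *case*, never by augmented slice: all 32 copies
of a case share its fold, so no model is ever evaluated on a case whose
augmentations it trained on. The protocol defaults are 6 folds / 50 epochs
(indirect) and 7 or 10 folds / 30 epochs (direct, direct+HRC); the test
suite uses 3 folds / 5 epochs at 64x64.

## High-resolution correction

Richardson-Lucy deconvolution, the multiplicative EM update
`f <- f * H(g / H(f))` with the normalized symmetric Gaussian PSF (so
`H^T = H`), initialized at the observed image (fewer iterations to useful
sharpening; both this and a constant start are RL-valid), reflective
boundary padding (avoids edge ringing on head-centred images), divisions
guarded by 1e-12, and optional RL-TV regularization (`1 - lambda div(grad
f/|grad f|)` in the denominator). The iteration count of the clinical HRC
product is unpublished; the default 10 is a typical clinical range, and
tests pin the *behaviour* — strict RMSE decrease against truth over
iterations 1-10 on noise-free data, nonnegativity, flux conservation for
interior objects — rather than a magic number.

## Metrics

NMSE follows the literal printed definition: the target is rescaled so its
maximum matches the reference maximum, and the denominator sums the
*target* squared (`denominator = "reference"` switches to the conventional
form; the two agree exactly when target = reference). PSNR is
`10 log10(max(K)^2 / MSE)` — the only reading consistent with values in the
tens of dB — with identical images reported as `Inf`. SSIM uses the
standard constants k1 = 0.01, k2 = 0.03, L = 255 and defaults to an 8x8
sliding window (stride 1, population moments, mean over windows) with a
global-window option; clinical SSIM windowing conventions vary, and results
in the 0.96-0.998 range are windowing-sensitive, so both modes are exposed
and the choice is logged in every report. Cohort evaluation first brings
each prediction/reference pair onto a common display scale anchored at the
reference maximum, then compares methods pairwise with a two-sided Wilcoxon
rank-sum test (midranks; exhaustive enumeration up to combined n = 20,
normal approximation with tie and continuity correction beyond).

All three metrics are validated against brute-force double-loop oracles to
1e-10, and the Wilcoxon enumeration against closed combinatorial cases
(e.g. {1,2,3} vs {4,5,6} gives exactly 2/20 = 0.1).

## Numerical choices and degenerate inputs

Constant images cannot be count-normalized (zero denominator) and raise an
error rather than a silent NaN. Attenuation factors are validated into
(0, 1]; CTAC refuses nonpositive factors. OSEM and RL guard divisions with
1e-12 and preserve nonnegativity exactly. Max-pooling breaks ties toward
the first element in column-major order — fixed, so reproducible. FBP clips
negative pixels by default but exposes the linear pre-clipping operator for
property tests. Seeds are derived, never shared: case seeds from
`(cohort seed, index)`, acquisition seeds from `(case id, global seed)`,
fold-model seeds from `(global seed, fold)`, keeping every stage
independently reproducible and below 2^31.

## Problem sizes

The test suite and the reproduction script run: phantom checks at 64-128
px; physics round trips at 128 px with 180 angles; and the cross-validated
direct method on nine 64-px cases (3 folds, 192 augmented slices per fold,
5 epochs, batch 2, base width 8). These sizes were chosen so the full suite
completes in minutes on one CPU core while every property remains sharply
testable; they are an order of magnitude below clinical resolution, and the
reported metric magnitudes scale accordingly (toy NMSE ~5e-2 against noisy
references versus ~1e-3 clinically).

## Known limitations

Scatter, randoms, detector normalization and time-of-flight are out of
scope; the projector pair is parallel-beam; phantoms are 2-D and
anatomically schematic; the learned models here are small and trained for
minutes, so their absolute image quality is illustrative of the pipeline,
not of what the architecture achieves at clinical scale; and the clinical
method ordering (indirect best, direct+HRC worst in NMSE) is a property of
clinical data and training scale that the harness reports but does not
assert on phantoms.
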