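---
title: "Conditional-GAN slice-thickness reduction: models, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional-GAN slice-thickness reduction: models, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctthinslice)
```

## The problem

Clinical CT is often acquired or archived at 3 mm slice thickness, while
surgical planning — for example of distal radius fractures — benefits from
1 mm slices. Going from 3 mm to 1 mm involves two couplings: *thickness
reduction* (each 3 mm slice is the through-plane average of roughly three
1 mm slices, so the central 1 mm slice must be deblurred out of it) and
*interpolation* (the adjacent 1 mm slices above and below must be
synthesised). `ctthinslice` performs both in one step with conditional
generative adversarial networks (cGANs), and ships a fully synthetic
paired-volume phantom generator so that the whole pipeline — training,
inference, evaluation — runs and is testable without any clinical data.

## The five-position scheme

For a thickness ratio $k = 3$, thick slice $j$ (0-based) covers thin
slices $3j, 3j+1, 3j+2$; its geometric center is $C = 3j + 1$. Five
independent generators are trained, one per target position relative to
that center: `2P`, `1P` (two/one before), `C` (corresponding), `1N`, `2N`
(one/two after), with offsets $-2, -1, 0, +1, +2$. `build_mapping()`
materialises this thick-to-thin correspondence; positions whose thin index
would fall outside the volume are absent, and boundary rows are left short
rather than padded, so nothing is fabricated at the volume ends.

```{r}
build_mapping(9, 3)
```

At inference (`enhance_volume()`), every thick slice is pushed through all
five generators and the per-position predictions are assembled by thin
index. Adjacent thick slices overlap at exactly two thin indices; the
default rule averages the contributors (symmetric, variance-reducing), and
`overlap = "nearest"` instead lets the smaller-offset position win. The
five-position scheme itself does not dictate a reconciliation rule, so
this is a package decision, surfaced as an argument.

## Scales and the two training targets

Stored values are 12-bit integers in $[0, 4095]$. Generators consume and
emit the signed scale $x' = x / 2047.5 - 1 \in [-1, 1]$ (endpoints map to
endpoints exactly; the affine map is a package decision since only the
ranges are standard). Metrics and the residual construction live on the
unit scale $x / 4095 \in [0, 1]$.

Two training-target constructions are implemented and compared:

* **Method 1 (raw learning)** — the generator maps the signed thick slice
  directly to the signed thin slice; output is rescaled to stored values.
* **Method 2 (residual/difference learning)** — the generator predicts
  the *difference* `to_unit(thin) - to_unit(thick)`; at inference the
  residual is added to the unit-scaled input, clipped to $[0,1]$
  (the sum can leave the range), and rescaled.

## Architecture and objective

The generator is a U-Net: 4×4 stride-2 convolutions with leaky-ReLU in
the encoder, nearest-neighbour-upsample + 3×3 convolution with ReLU in
the decoder, skip concatenations between mirrored levels, plus a
full-resolution skip of the raw input into the 1-channel output
convolution. Three choices deserve explanation:

* **Hard-tanh output.** The output activation must be a bounded odd map
  onto $[-1,1]$. We use `clip(x, -1, 1)` rather than `tanh` because it can
  represent the identity exactly: with the input skip, the generator can
  be *initialized at the copy-thick baseline* (passthrough initialization
  for Method 1, zero-output initialization for Method 2), so optimisation
  starts from the trivial solution instead of noise. A `tanh` cannot pass
  a full-range image through unchanged at any finite weight.
* **Instance normalization** on all hidden convolutions (not the first
  encoder layer, not the output). The canonical image-to-image recipe
  trains with batch size 1, where batch normalization degenerates to
  instance normalization; without it, a normalisation-free network of
  this depth barely trains at small step counts. Weights use He (fan-in)
  initialization for the same reason.
* **Upsample + convolution** instead of transposed convolution in the
  decoder: equivalent capacity here, no checkerboard artifacts, simpler
  adjoint.

The discriminator is a conditional PatchGAN: condition and candidate are
channel-concatenated and reduced by three 4×4 stride-2 convolutions, one
stride-1 convolution and a 1-channel stride-1 head, producing a grid of
patch logits (30×30 for a 256 px input — the classic ~70 px receptive
field).

The objective is the standard conditional-GAN compound: the discriminator
minimises the mean binary cross-entropy of real pairs toward label 1 and
fake pairs toward label 0; the generator minimises the non-saturating
adversarial term plus $\lambda \cdot \mathrm{mean}|y - G(x)|$ with
$\lambda = 100$ and adversarial weight 1 (the published defaults, kept).
`cgan_losses()` computes exactly these quantities.

### Optimisation details

Adam with $\beta_1 = 0.5$, $\beta_2 = 0.999$. One numerical choice
matters: the descent direction for the L1 term uses the Charbonnier
smoothing $e / \sqrt{e^2 + \varepsilon^2}$ in place of the
non-differentiable $\mathrm{sign}(e)$ (`l1_smooth`, in normalized-image
units). Because training starts at the copy baseline, a large fraction of
target pixels are matched *exactly* at initialization; the raw sign
subgradient is zero there while any parameter movement still incurs
first-order loss, so exact-L1 descent stalls in the kink. The smoothing
makes small errors contribute proportionally small gradients and restores
a usable descent direction; all *reported* losses remain exact mean
absolute error.

After training, the returned generator is the best checkpoint by
training-set mean squared reconstruction error among the initialization,
the best epoch and the final state. This is ordinary best-model
selection, with one welcome consequence: a position whose baseline is
already at the phantom's noise floor (typically `C`, where the thick
slice nearly equals the central thin slice) keeps its baseline instead of
being perturbed by adversarial gradients, while the adjacent positions
keep their trained weights. Selection uses the squared-error family
because that is the family (PSNR/MSE) in which enhanced volumes are
scored; selection by exact L1 would discard models that trade tiny,
invisible flat-region perturbations for large edge improvements.

### Profiles

`training_config()` defaults are the published full-scale recipe (depth
6, width 64, step size 2e-4). `training_profile("smoke")` is the
desk-scale profile used by the package's own experiments and tests: 64 px
inputs, depth 3, width 8, 6 epochs, step size 1e-3, `l1_smooth = 0.05`.
The step size is larger than the full-scale recipe because a desk-scale
run takes a few hundred optimisation steps rather than hundreds of
thousands; the profile was calibrated once on held-out residual error of
the phantom family and then frozen.

## The phantom family

`phantom_config()` / `generate_phantom_volume()` build wrist-like
thin-slice volumes: an air background (stored value ~24), a soft-tissue
ellipse (~1064), cortical shells (~2600) with trabecular interior (~1400
plus band-limited texture), an optional oblique fracture plane rendered
at soft-tissue intensity through the first shell, and additive Gaussian
noise, clipped to $[0, 4095]$ and rounded. `degrade_to_thick()` derives
the paired thick volume as the unweighted mean of $k$ consecutive thin
slices (the standard partial-volume model; the virtual-thickening
procedure is otherwise unspecified upstream), rounding half away from
zero.

Two rendering decisions are essential for the method to have anything to
learn, and are worth stating because they were diagnosed, not assumed:

* **Partial-volume (anti-aliased) edges.** Boundary voxels take
  fractional-occupancy values over a ~1.2-voxel transition, as real CT
  point-spread and slice averaging produce. With hard binary edges, the
  sub-voxel drift of structures between adjacent slices turns into
  aliased single-pixel flips that carry *no recoverable signal*: even an
  oracle regression cannot beat the copy baseline on such data.
* **Monotone taper along z.** The body outline and shells shrink
  steadily along the slice axis (as a distal limb does) with only a small
  superimposed wobble. A symmetric drift is fundamentally ambiguous from
  a single thick slice — the average of shifted edge ramps looks the same
  whether the structure is growing or shrinking — so position-specific
  models rely on a stereotyped through-plane progression, exactly as they
  do on real anatomy. The predictable part of the adjacent-slice residual
  is then approximately (drift speed) × (local gradient magnitude), a
  function a one-hidden-layer convolution network can represent.

`phantom_suite()` freezes the evaluation family used by the package's
experiments: 4 cases, 64×64 in-plane, 60 thin slices, $k = 3$, two
tapering shells, no trabecular texture, noise sd 2 stored values. Texture
is omitted there deliberately: with slice-wise sampling, trabecular
texture behaves as unpredictable noise for interpolation (the thick slice
already contains each thin slice's best linear texture predictor), so
including it would only shrink the measurable learning signal without
changing the ranking of methods.

What passing on this family does and does not show: it demonstrates that
the implementation trains, that both target constructions extract real
through-plane signal, and that every pipeline contract holds end to end.
It does not certify clinical image quality — real CT has scanner noise
spectra, beam hardening, motion, and anatomical variability far beyond
this family, and the published clinical results are not reproducible
without the original patient data and trained weights.

## Evaluation

All metrics operate on unit-scaled images with peak 1: MSE; PSNR
$= 10\log_{10}(1/\mathrm{MSE})$ in dB, reported as `Inf` (never capped)
for identical images and excluded from means with a count; SSIM with the
original defaults (11×11 Gaussian window, $\sigma = 1.5$, $K_1 = 0.01$,
$K_2 = 0.03$, $L = 1$). The peak-1 convention is the one consistent with
published MSE↔PSNR pairs of this method family (e.g. MSE 1.23e-5 pairing
with ≈49 dB). Per-slice method comparisons count a merged "PSNR, MSE"
winner (the relation is strictly monotone, so both metrics always agree)
and an SSIM winner; strict ties are excluded from both tallies and
reported separately, since nothing upstream states a tie rule.

Training-reproduction checks and cross-validation score *per generated
slice*: every (thick slice, position) prediction is compared against its
paired thin slice, so each thick input contributes up to five scored
1 mm slices. This is the protocol behind published per-slice tables of
this method family (slice counts there equal the number of paired thin
images, not of assembled volume slices), and it is also the protocol
under which the copy-thick baseline is scored. Assembled volumes can be
scored separately through the command-line `evaluate` subcommand.
`metric_report()` aggregates per case and grand means both over slices
and over case means (they differ by case-size weighting; both are
labelled). Signed difference images render positive differences red and
negative blue with symmetric scaling. `cohen_kappa()` implements plain
chance-corrected two-rater agreement for the qualitative-grading
workflow.

## Reproducing the desk-scale study

`scripts/acceptance.R` regenerates the suite, runs leave-one-case-out
cross-validation for both methods (each fold trains five fresh position
models on three cases and scores the held-out case), scores the
copy-thick baseline, and writes held-out PSNR/SSIM/MSE plus method-2
winner shares as JSON. On one CPU the whole study takes on the order of
ten minutes; problem sizes (4 cases, 60 slices, 64² pixels, 6 epochs) are
the package's desk-scale study conditions. Every random draw derives from
the single `--seed` via `derive_seed()`, and a fixed seed reproduces
phantoms, trained bundles and reports bit for bit on one platform.

One observation the script's winner shares make visible: on this easy,
texture-free family, raw learning tends to win the per-slice PSNR/MSE
comparison more often while residual learning wins SSIM more often.
Which construction is preferable is a property of the data family and
the training scale, not of the implementation; desk-scale phantom
results should not be read as a clinical ranking of the two methods.

## Known limitations

* 2-D, per-slice modelling only (as specified); no 3-D convolutions.
* Integer thickness ratios with odd $k$ only; non-integer ratios are
  rejected rather than resampled.
* The phantom family is deliberately easy; no scanner physics.
* Adversarial training at desk scale is dominated by the reconstruction
  term; the perceptual benefits of the GAN term emerge only at full
  scale, which is configuration (`training_config()`), not code.
* DICOM support is a minimal Explicit-VR-Little-Endian geometry +
  pixel-module subset, cross-checked against an independent reader in the
  test suite; it is not a general DICOM implementation.
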