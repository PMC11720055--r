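---
title: "Slice-thickness super-resolution and volumetric lung-nodule assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-thickness super-resolution and volumetric lung-nodule assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsr)
```

## The problem

Volume-based lung-cancer screening assigns each nodule to a management
category from its measured volume, with hard cut-offs (113, 268, 1767 mm³ for
solid nodules in the simplified volume rules used here). Nodule volumetry is
only as good as the through-plane resolution of the scan: on a 4 mm-thick
reconstruction, a 6 mm nodule spans one or two slices and its segmented
volume can be off by half. Many archived scans exist only at thick slice
spacing, so a method that reconstructs thin slices from thick ones — slice
super-resolution along the scanner z axis — directly improves the
consistency of categorization.

`ctsr` implements such a method end to end, in a form where every stage is
testable on synthetic data with no external scans or pretrained weights:

1. a seeded **phantom generator** producing thin-slice chest-CT-like volumes
   with nodules of known analytic volume and type;
2. the **degradation model**: every `r` consecutive thin slices averaged into
   one thick slice (the self-supervised training signal — no paired
   acquisitions are needed);
3. the **3D generator network**: residual-in-residual dense blocks (RRDBs)
   with a voxel-shuffle slice-generation head, trained with pixel, perceptual
   and adversarial losses against a 3D convolutional discriminator;
4. **volumetry**: voxel-count volumes from binary masks, nodule typing at the
   −450 HU threshold, repeatability statistics;
5. **categorization**: the simplified volume-based Lung-RADS v2022 rules,
   confusion matrices between image sources, and agreement metrics.

## The model

### Degradation

`simulate_thick(vol, r)` replaces each group of `r` consecutive slices along
the stack axis with its arithmetic mean and multiplies the stack spacing by
`r`; a 300-slice 1.0 mm series becomes a 75-slice 4.0 mm series at `r = 4`.
Training pairs are made by degrading thin-slice volumes, so the ground truth
is the volume itself. Depths not divisible by `r` are trimmed (averaging a
partial group would change the effective slice thickness).

### Generator

The generator follows the ESRGAN lineage, with all convolutions 3D
(3×3×3, stride 1, padding 1) and no batch normalization:

* a head convolution lifts the single-channel volume to `base_channels`
  features;
* `n_rrdb` RRDBs follow. Each RRDB holds three residual dense blocks (RDBs);
  an RDB is five convolutions with dense connections (every convolution sees
  the concatenation of the block input and all previous outputs) and four
  leaky rectifiers, and its output is scaled by β and added to the block
  input. The RRDB adds its own skip, also scaled by β (default 0.2);
* a trunk convolution and a global residual re-join the head features;
* a channel-expansion convolution widens to `base_channels × r`, and
  **voxel shuffle** rearranges those channels into the depth axis:
  `out[b, c, h, w, d·r + k] = in[b, c·r + k, h, w, d]`. This is a pure,
  invertible element rearrangement — the 3D slice-generation analogue of 2D
  sub-pixel convolution — so the slice count multiplies by `r` without
  arithmetic on values;
* two output convolutions produce the generated thin-slice volume.

Intensities are mapped from the HU window [−1024, 600] to [0, 1] before the
network and back after. Initialization is small scaled-Gaussian plus an
ICNR-style identity component in the head, expansion and output layers, so
an untrained generator approximates nearest-neighbour slice repetition — the
standard stable starting point for sub-pixel upsampling heads.

The full-scale configuration is 23 RRDBs at 64/32 channels; the package's
desk-scale experiments use 1 RRDB at 8/4 channels, which trains on a single
CPU in minutes.

### Discriminator and losses

The discriminator is eight 3D convolution + LReLU pairs (strides alternating
1 and 2), a dense layer of width 1024, an LReLU, a dense layer to one unit
and a sigmoid; output 1 means "judged real thin-slice". Three losses drive
the generator:

* **MSE**: mean squared voxel difference on the normalized scale,
  `1/(rDHW) Σ (I^GT − G(I^LR))²`;
* **perceptual**: volumes are split into 2D slices, each slice is passed
  through a feature extractor, and the mean squared feature difference is
  averaged over slices;
* **adversarial**: `Σ −log D(G(I^LR))` over the batch, with probabilities
  clamped at 10⁻⁷ inside the log.

The combination weights default to (1, 1, 5·10⁻³); the small adversarial
weight is the convention of this architecture family. The adversarial form
is the standard (non-relativistic) negative-log objective. Training uses
Adam with β₁ = 0, β₂ = 0.9 and learning rate 10⁻⁴ by default, alternating
one discriminator and one generator update, and stops when the validation
loss fails to improve by `min_delta` over `patience` evaluations.

**On the perceptual feature extractor.** The classical choice is a VGG19
classification network pretrained on natural images. This package ships no
pretrained weights; its extractor is a fixed, internally seeded random
convolutional network (three 3×3 stages, the deeper two with stride 2,
single-channel slices replicated to three channels and standardized with
fixed constants). Random convolutional features are a well-studied distance
for structural comparison; the term retains the defining properties of a
perceptual loss (zero at identity, translation-equivariant deep features,
multi-scale support) but is not a learned semantic feature space, and
results with it should be read accordingly.

### Chunking and stitching

Volumes are processed in segments of 16 slices along the stack axis (a
memory constraint at full scale, kept as the default contract here).
Consecutive segments overlap by 2 slices by default and are blended with
linear cross-fade weights at stitching; at `overlap = 0` this reduces to the
disjoint-segment scheme. Tail segments are edge-replicated and the padding
discarded on reassembly. Re-slicing between axial and coronal stacking is a
lossless transpose (`reslice()`); the super-resolved axis is always the
array's third (stack) axis, so both readings of the processing orientation
are available by tagging.

## Volumetry and categorization

`nodule_volume()` is exact voxel-count arithmetic: set voxels × voxel
volume. Typing applies the −450 HU rule within the mask: all voxels strictly
above → solid, all at or below → ground-glass (GGN), mixed → subsolid; a
voxel at exactly −450 counts to the ground-glass side, following the rule's
wording ("above" vs "equal to or below"). The solid component of a
part-solid nodule is measured with the same voxel-wise threshold — the rule
is not spelled out in the source description, and this is the minimal choice
consistent with the type definitions.

`repeatability_stats()` uses the **population** (divide-by-n) standard
deviation. This is a deliberate, documented choice: it is the only
convention under which the published five-measurement worked example
(137, 140, 133, 125, 148 mm³) reproduces its printed mean 136.6, SD 7.61 and
CV 5.57% exactly (the sample convention gives SD 8.50). For the companion
series (133, 121, 146, 142, 144 mm³) the recomputed SD is 9.24 at two
decimals where 9.23 is printed; the mean (137.2) and CV (6.73%) recompute
exactly.

`lungrads_category()` implements the simplified volume rules: solid nodules
cut at 113/268/1767 mm³; part-solid nodules cut at 113 mm³ total volume with
solid-component cut-offs 113/268 mm³. Two boundary decisions make the rule
set total: the exactly-1767 mm³ case (left uncovered by the printed table,
"<1767" vs ">1767") maps to 4B, and pure ground-glass nodules — which the
volume table does not address — default to category 2, with a configuration
hook to supply a different rule. Categories are ordered 2 < 3 < 4A < 4B and
the mapping is monotone in the deciding volume.

Agreement between two sources is the diagonal sum of the category confusion
matrix over the nodule count. From misclassification counts m_a and m_b the
package reports the relative reduction `100·(m_a − m_b)/m_a` and the fold
ratio `m_a/m_b`; with the published counts (31 and 8 among 304 nodules)
these round to 74% and 3.9.

## The phantom: what it emulates and what it does not

`make_phantom()` builds a thin-slice (default 0.7 × 0.7 × 1.0 mm) volume
containing:

* a parenchyma background: mean −850 HU plus a smooth random field (SD
  20 HU) emulating low-frequency tissue heterogeneity;
* vessel-like bright tubes (30 HU) running along the stack axis with a small
  random tilt. Tubes keep a clearance from every nodule: a manual
  segmentation would exclude crossing vessels, so the phantom does not
  create them;
* ellipsoidal nodules with exact analytic volume `4/3·π·a·b·c`. Solid
  nodules are homogeneous at −100 HU, ground-glass at −700 HU, and
  part-solid nodules are a concentric solid core inside a ground-glass
  shell, which guarantees the mixed-attenuation condition by construction;
* additive Gaussian voxel noise (SD 10 HU), applied **before** degradation
  and typing so the −450 HU threshold is exercised under noise. The default
  is small against the ≈ 400 HU margin between the default attenuations and
  the threshold, mimicking the high contrast-to-noise of screening CT.

Mask membership is voxel-center-inside-ellipsoid, matching a binary manual
segmentation and giving an unambiguous count. World coordinates are mm from
the first voxel center, 0-based on all axes.

The phantom does **not** emulate airways, lobar anatomy, attenuation
physics, reconstruction kernels, or scanner noise spectra, and no intensity
statistics were fitted to real scans (none are published in the source
description; the values above are stipulated). Passing tests on phantoms
therefore demonstrate the correctness of the pipeline's arithmetic and the
trainability of the network under the stated degradation model — not
clinical performance on real CT.

## Desk-scale study conditions

The package's experiments run on one CPU at sizes chosen once:

* 4 phantom volumes of 24 × 24 × 64 voxels at 0.7 × 0.7 × 1.0 mm, three
  nodules each (one solid, one GGN, one part-solid; radii 2.0–2.6 mm);
* generator: 1 RRDB, 8 base / 4 growth channels, `r = 4`;
* MSE-only objective, learning rate 10⁻³ (the full-scale default of 10⁻⁴
  is kept as the package default; the higher rate is this experiment's
  choice for its short 300-step budget), 300 steps, batch 1, chunks of 16
  thick slices, validation split by whole volume (1 of 4 held out, never by
  chunk, to avoid leakage);
* evaluation on the held-out volume: voxel MSE / PSNR / SSIM of the
  generated thin volume against the true thin volume, and nodule volumes
  re-measured by ROI threshold segmentation (the window (−600, ∞] for solid,
  (−775, −450] for ground-glass — the upper bound emulating manual
  separation from vessels — and (−775, ∞] for part-solid nodules) compared
  with the same measurement on the true thin volume.

Under these conditions the trained generator beats trilinear interpolation
of the same 4×-degraded input on held-out voxel MSE and on mean nodule
volume error; this is the package's stand-in for the full-scale result,
which required tens of thousands of series and GPU training. The full-scale
outcome figures (52.2% → 15.7% volume difference; the specific 31-vs-8
confusion matrices; observer scores) are data outcomes on a clinical corpus
and are not reproducible at this scale; the package reproduces their
arithmetic exactly from the published counts.

## Numerical choices and degenerate inputs

* SSIM uses a uniform 7×7 in-plane window on valid (unpadded) pixels with
  K₁ = 0.01, K₂ = 0.03 on the normalized unit range; PSNR is
  `10·log₁₀(1/MSE)` on the same range, reported as `Inf` for identical
  volumes.
* The linear baseline (`trilinear_upsample()`) maps output slice k to source
  coordinate k/r (aligned endpoints, edge replication past the last slice).
  This convention shifts a degrade-then-upsample round trip by 0.375 slices;
  it affects only the baseline, not the method.
* Chunk starts step by `chunk_len − overlap` until a chunk reaches the last
  slice; the final chunk may extend past the end and is edge-padded. The
  cross-fade weight of slice j in a chunk is
  `min(1, j/(o+1), (len−j+1)/(o+1))`, which makes overlapping weights sum
  to one exactly; weights are renormalized per output slice after padding
  is dropped.
* Probabilities entering logarithms are clamped at 10⁻⁷, so `p = 1` gives
  exactly zero adversarial loss and `p = 0` a finite one.
* An empty mask measures 0 mm³ with a note (not an error); classifying an
  empty mask is an error.
* Degenerate chunk plans (`overlap ≥ chunk_len`), non-positive spacings,
  radii or learning rates, and mismatched shapes are rejected at
  construction time with named errors.

## Known limitations

* The perceptual term uses fixed random features, not a pretrained
  classification network (none can be bundled).
* DICOM reading supports uncompressed explicit-VR little-endian single-frame
  series only; NIfTI is the primary format.
* The discriminator's dense layer ties its parameters to the training chunk
  shape; inference is chunk-shape-free but a trained discriminator is not.
* Training at full scale (23 RRDBs, 512 × 512 slices, tens of thousands of
  series) is out of reach of this implementation's CPU-bound kernels; the
  architecture is the same, the widths and budgets are not.
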