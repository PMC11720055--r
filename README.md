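# ctsr — slice-thickness super-resolution and lung-nodule volumetry for chest CT

Volume-based lung-cancer screening categorizes nodules by hard volume
cut-offs (Lung-RADS v2022: 113 / 268 / 1767 mm³ for solid nodules), but much
archived CT exists only at thick slice spacing, where through-plane partial
volume makes nodule volumetry — and hence categorization — unreliable.
`ctsr` implements a deep-learning slice super-resolution pipeline that
reconstructs thin slices (×4 along the stack axis) from thick-slice volumes,
together with the downstream volumetric assessment, for researchers studying
slice-thickness normalization and its effect on nodule categorization.

The core is a 3D ESRGAN-style generator: `n` residual-in-residual dense
blocks (RRDBs; three dense blocks each, residual scaling β = 0.2), a global
residual, and a voxel-shuffle slice-generation head that moves channels into
the depth axis,

    out[b, c, h, w, d·r + k] = in[b, c·r + k, h, w, d],   k = 0 … r − 1,

trained self-supervised against an adversarial 3D discriminator: thin-slice
volumes are degraded by averaging every r = 4 consecutive slices
(I^LR = mean-pool_z(I^GT)), and the generator G minimizes

    L = w_mse · 1/(rDHW) Σ (I^GT − G(I^LR))²  +  w_perc · L_feat  +
        w_adv · Σ −log D(G(I^LR)),

with Adam (β₁ = 0, β₂ = 0.9, lr 10⁻⁴). Everything is testable on seeded
synthetic chest phantoms with nodules of known analytic volume — no scans
and no pretrained weights are required (the perceptual term uses a fixed,
seeded random convolutional feature extractor; see the vignette).

The whole pipeline is also runnable at desk scale: a reduced generator
(1 RRDB, 8 channels) trained for 300 CPU steps on four phantom volumes beats
trilinear interpolation on held-out voxel MSE and nodule-volume error.

## Worked example

```r
library(ctsr)

## repeatability of five repeated measurements of one reference nodule (mm^3)
repeatability_stats(c(137, 140, 133, 125, 148))
#> repeatability over 5 measurements: mean 136.60 mm^3, SD 7.61 mm^3, CV 5.57%

## degrade a 300-slice 1.0 mm phantom series 4:1
thin  <- make_phantom(phantom_spec(c(24, 24, 300), c(0.7, 0.7, 1.0), seed = 1))$volume
thick <- simulate_thick(thin, 4)
thick
#> ct_volume: 24 x 24 x 75 voxels (axial-stack)
#>   spacing: 0.7 x 0.7 x 4 mm
#>   HU range: [-908.8, 51.9]  provenance: thick

## categorize a measured nodule under the simplified volume rules
rec <- nodule_record("n1", "solid", total_volume_mm3 = 113, solid_component_mm3 = 113)
lungrads_category(rec)
#> [1] 3
#> Levels: 2 3 4A 4B

## agreement arithmetic from misclassification counts (31 vs 8 of 304 nodules)
agreement_from_counts(31, 8, 304)
#> agreement: 89.8% -> 97.4% (31 -> 8 misclassified of 304)
#> misclassification reduction: 74%; fold ratio: 3.9
```

The numbers mean: the five repeated measurements scatter with a coefficient
of variation of 5.57% around 136.6 mm³ (population-SD convention, the choice
that reproduces this printed triple exactly); a 300-slice 1.0 mm series
becomes 75 slices at 4.0 mm; a solid nodule of exactly 113 mm³ falls in
category 3 (the cut-off is inclusive); and reducing misclassifications from
31 to 8 among 304 nodules is a 74% reduction, a 3.9-fold ratio.

Training and applying the model:

```r
study <- phantom_study_set(4, seed = 1)            # 4 thin-slice phantoms
fit <- ctsr_fit(lapply(study, `[[`, "volume"),
                train_config(r = 4, plan = chunk_plan(16, 0),
                             generator = generator_config(r = 4, n_rrdb = 1,
                                                          base_channels = 8,
                                                          growth_channels = 4),
                             losses = loss_config(1, 0, 0),
                             lr = 1e-3, steps = 300, seed = 1))
gen <- predict(fit, simulate_thick(study[[1]]$volume, 4))
evaluate_sr(gen, study[[1]]$volume)                # MSE / PSNR / SSIM
```

`print(fit)`, `plot(fit)` (loss history), `coef(fit)` (flattened generator
parameters) and `save_ctsr()`/`load_ctsr()` round out the fitted-model
interface.

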