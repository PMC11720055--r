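tiny_cfg <- function(steps = 0L, chunk_len = 4L, r = 4L, seed = 5L,
                     losses = loss_config(1, 0, 0), eval_every = 5L, ...) {
  train_config(r = r, plan = chunk_plan(chunk_len, 0),
               generator = generator_config(r = r, n_rrdb = 1,
                                            base_channels = 4,
                                            growth_channels = 2),
               discriminator = discriminator_config(n_conv_pairs = 3,
                                                    base_channels = 4,
                                                    dense_width = 8),
               losses = losses, steps = steps, eval_every = eval_every,
               seed = seed, ...)
}

tiny_vols <- function(n = 3, depth = 32, hw = 12, seed = 1) {
  lapply(seq_len(n), function(i) {
    ph <- make_phantom(phantom_spec(c(hw, hw, depth), c(0.7, 0.7, 1.0),
                                    vessel_count = 2, seed = seed + i))
    ph$volume
  })
}

test_that("training pairs are aligned thick/thin chunks in seeded order", {
  vols <- tiny_vols(2)
  cfg <- tiny_cfg(chunk_len = 4)
  pairs <- make_training_pairs(vols, cfg)
  expect_gt(length(pairs), 1)
  for (p in pairs) {
    expect_equal(dim(p$gt)[3], 16)            # chunk_len * r thin slices
    expect_equal(dim(p$lr)[3], 4)
    # definitional: LR is the 4:1 average of GT
    gtv <- ct_volume(array(p$gt, dim(p$gt)[1:3]), c(0.7, 0.7, 1.0))
    expect_equal(p$lr, ctsr:::as_sample_array(simulate_thick(gtv, 4)$voxels),
                 tolerance = 1e-12)
  }
  # fixed seed: identical order across runs
  pairs2 <- make_training_pairs(vols, cfg)
  expect_identical(lapply(pairs, `[[`, "start"), lapply(pairs2, `[[`, "start"))
  expect_identical(lapply(pairs, `[[`, "volume"), lapply(pairs2, `[[`, "volume"))
})

test_that("volumes thinner than one chunk are skipped with a warning", {
  vols <- c(tiny_vols(2, depth = 32), tiny_vols(1, depth = 8, seed = 9))
  expect_warning(pairs <- make_training_pairs(vols, tiny_cfg(chunk_len = 4)),
                 "thinner")
  expect_true(all(vapply(pairs, `[[`, numeric(1), "volume") <= 2))
})

test_that("a zero-step fit equals its initialization", {
  vols <- tiny_vols(3)
  cfg <- tiny_cfg(steps = 0)
  fit <- ctsr_fit(vols, cfg)
  expect_s3_class(fit, "ctsr_fit")
  expect_equal(fit$steps_run, 0)
  expect_identical(fit$params, init_generator(cfg$generator, seed = cfg$seed))
  expect_equal(nrow(fit$history), 0)
})

test_that("training is reproducible for identical config and seed", {
  vols <- tiny_vols(3)
  cfg <- tiny_cfg(steps = 10, lr = 1e-3)
  f1 <- ctsr_fit(vols, cfg)
  f2 <- ctsr_fit(vols, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$val_ids, f2$val_ids)
})

test_that("a short MSE-only fit reduces validation MSE", {
  vols <- tiny_vols(3, depth = 32, hw = 16)
  cfg <- tiny_cfg(steps = 60, chunk_len = 8, lr = 1e-3)
  fit <- ctsr_fit(vols, cfg)
  h <- fit$history
  expect_gt(nrow(h), 2)
  expect_lt(h$val_mse[nrow(h)], h$val_mse[1])
})

test_that("adversarial and perceptual terms train without error and are logged", {
  vols <- tiny_vols(3, depth = 16, hw = 8)
  cfg <- tiny_cfg(steps = 4, chunk_len = 4, lr = 1e-4, eval_every = 2L,
                  losses = loss_config(1, 0.1, 1e-3, perc_layer = 1))
  fit <- ctsr_fit(vols, cfg)
  h <- fit$history[fit$history$step > 0, ]
  expect_true(all(h$loss_perc > 0))
  expect_true(all(h$loss_adv > 0))
  expect_true(all(is.finite(h$loss_total)))
  expect_false(is.null(fit$disc_params))
})

test_that("a warm-up phase defers the adversarial and perceptual terms", {
  vols <- tiny_vols(3, depth = 16, hw = 8)
  cfg <- tiny_cfg(steps = 4, chunk_len = 4, lr = 1e-4, eval_every = 1L,
                  losses = loss_config(1, 0.1, 1e-3, perc_layer = 1),
                  warmup_steps = 2L)
  fit <- ctsr_fit(vols, cfg)
  h <- fit$history[fit$history$step > 0, ]
  expect_equal(h$loss_adv[h$step <= 2], c(0, 0))
  expect_true(all(h$loss_adv[h$step > 2] > 0))
})

test_that("prediction applies the full chunk-forward-stitch pipeline shape contract", {
  vols <- tiny_vols(3)
  fit <- ctsr_fit(vols, tiny_cfg(steps = 0))
  thick <- simulate_thick(vols[[1]], 4)
  gen <- predict(fit, thick)
  expect_equal(dim(gen$voxels)[3], dim(thick$voxels)[3] * 4)
  expect_equal(gen$spacing_mm[3], thick$spacing_mm[3] / 4)
  expect_equal(dim(gen$voxels)[1:2], dim(thick$voxels)[1:2])
  expect_equal(gen$provenance, "generated")
})

test_that("checkpoints restore bit-compatible inference", {
  vols <- tiny_vols(3)
  fit <- ctsr_fit(vols, tiny_cfg(steps = 5, lr = 1e-3))
  path <- withr::local_tempfile(fileext = ".rds")
  save_ctsr(fit, path)
  fit2 <- load_ctsr(path)
  thick <- simulate_thick(vols[[1]], 4)
  expect_identical(predict(fit, thick)$voxels, predict(fit2, thick)$voxels)
})

test_that("SR metrics have their closed forms and symmetries", {
  v <- ct_volume(array(hu_denormalize(0.5), c(8, 8, 4)), c(1, 1, 1))
  expect_equal(evaluate_sr(v, v), list(mse = 0, psnr = Inf, ssim = 1))
  # a pair with normalized MSE 0.01 on the unit range: PSNR = 20 dB
  w <- ct_volume(array(hu_denormalize(0.6), c(8, 8, 4)), c(1, 1, 1))
  m <- evaluate_sr(w, v)
  expect_equal(m$mse, 0.01, tolerance = 1e-10)
  expect_equal(m$psnr, 20, tolerance = 1e-8)
  # SSIM is symmetric
  set.seed(2)
  a <- ct_volume(array(rnorm(10 * 10 * 3, -800, 100), c(10, 10, 3)), c(1, 1, 1))
  b <- ct_volume(array(rnorm(10 * 10 * 3, -800, 100), c(10, 10, 3)), c(1, 1, 1))
  expect_equal(evaluate_sr(a, b)$ssim, evaluate_sr(b, a)$ssim, tolerance = 1e-12)
  expect_error(evaluate_sr(a, ct_volume(array(0, c(4, 4, 4)), c(1, 1, 1))),
               "mismatch")
})
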