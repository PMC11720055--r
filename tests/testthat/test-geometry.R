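test_that("4:1 averaging turns 300 slices at 1.0 mm into 75 at 4.0 mm", {
  vol <- ct_volume(array(rnorm(4 * 4 * 300, -800, 50), c(4, 4, 300)),
                   c(0.7, 0.7, 1.0))
  th <- simulate_thick(vol, 4)
  expect_equal(dim(th$voxels)[3], 75)
  expect_equal(th$spacing_mm, c(0.7, 0.7, 4.0))
  expect_equal(dim(th$voxels)[1:2], c(4, 4))
})

test_that("slice averaging is the arithmetic group mean", {
  vol <- ct_volume(array(rep(0:7, each = 4), c(2, 2, 8)), c(1, 1, 1))
  th <- simulate_thick(vol, 4)
  expect_equal(as.numeric(th$voxels[1, 1, ]), c(1.5, 5.5))
  const <- ct_volume(array(-500, c(3, 3, 12)), c(1, 1, 1))
  expect_true(all(simulate_thick(const, 4)$voxels == -500))
  # global mean conserved when depth divides r
  v <- ct_volume(array(rnorm(2 * 2 * 16), c(2, 2, 16)), c(1, 1, 1))
  expect_equal(mean(simulate_thick(v, 4)$voxels), mean(v$voxels))
})

test_that("non-divisible depth follows the remainder policy", {
  vol <- ct_volume(array(seq_len(2 * 2 * 10), c(2, 2, 10)), c(1, 1, 1))
  th <- simulate_thick(vol, 4)                  # trim: keep 8 slices -> 2
  expect_equal(dim(th$voxels)[3], 2)
  expect_error(simulate_thick(vol, 4, remainder = "error"), "not divisible")
})

test_that("reslicing is a lossless spacing-consistent transpose", {
  set.seed(3)
  vol <- ct_volume(array(rnorm(5 * 4 * 3), c(5, 4, 3)), c(0.7, 0.8, 4.0),
                   "axial-stack")
  cor <- reslice(vol, "coronal-stack")
  expect_equal(dim(cor$voxels), c(5, 3, 4))
  expect_equal(cor$spacing_mm, c(0.7, 4.0, 0.8))
  expect_equal(cor$voxels[2, 3, 1], vol$voxels[2, 1, 3])
  back <- reslice(cor, "axial-stack")
  expect_identical(back$voxels, vol$voxels)
  expect_identical(back$spacing_mm, vol$spacing_mm)
  one <- ct_volume(array(1, c(1, 1, 1)), c(1, 1, 1))
  expect_equal(reslice(one, "coronal-stack")$voxels, one$voxels)
})

test_that("chunking enumerates the expected windows and covers every slice", {
  v75 <- ct_volume(array(0, c(2, 2, 75)), c(1, 1, 1))
  starts0 <- vapply(chunk_volume(v75, chunk_plan(16, 0)), attr, numeric(1), "start")
  expect_equal(starts0, c(0, 16, 32, 48, 64))
  last <- chunk_volume(v75, chunk_plan(16, 0))[[5]]
  expect_equal(attr(last, "n_pad"), 5)
  starts2 <- vapply(chunk_volume(v75, chunk_plan(16, 2)), attr, numeric(1), "start")
  expect_equal(starts2, c(0, 14, 28, 42, 56, 70))
  v16 <- ct_volume(array(0, c(2, 2, 16)), c(1, 1, 1))
  ch16 <- chunk_volume(v16, chunk_plan(16, 2))
  expect_length(ch16, 1)
  expect_equal(attr(ch16[[1]], "n_pad"), 0)
  # property: union of source ranges covers the full depth
  for (d in c(5, 16, 17, 31, 75)) for (ov in c(0, 2, 5)) {
    plan <- chunk_plan(16, ov)
    chs <- chunk_volume(ct_volume(array(0, c(1, 1, d)), c(1, 1, 1)), plan)
    covered <- sort(unique(unlist(lapply(chs, function(ch)
      attr(ch, "start") + seq_len(plan$chunk_len)))))
    expect_true(all(seq_len(d) %in% covered),
                label = sprintf("coverage d=%d overlap=%d", d, ov))
  }
})

test_that("chunk tail is edge-replicated", {
  v <- ct_volume(array(rep(1:5, each = 1), c(1, 1, 5)), c(1, 1, 1))
  ch <- chunk_volume(v, chunk_plan(8, 0))[[1]]
  expect_equal(as.numeric(ch$voxels[1, 1, ]), c(1:5, 5, 5, 5))
})

test_that("stitching inverts chunking under an identity repeat upsampler", {
  set.seed(4)
  for (ov in c(0, 2)) {
    v <- ct_volume(array(rnorm(3 * 3 * 21), c(3, 3, 21)), c(1, 1, 1))
    plan <- chunk_plan(8, ov)
    chs <- chunk_volume(v, plan)
    r <- 3
    up <- lapply(chs, function(ch) {
      o <- ct_volume(ch$voxels[, , rep(seq_len(8), each = r)],
                     ch$spacing_mm * c(1, 1, 1 / r), ch$orientation)
      attr(o, "start") <- attr(ch, "start")
      o
    })
    st <- stitch_chunks(up, plan, r, 21)
    expect_equal(dim(st$voxels)[3], 63)
    expect_equal(st$voxels, v$voxels[, , rep(seq_len(21), each = r)],
                 tolerance = 1e-12)
    expect_equal(st$spacing_mm[3], 1 / r)
  }
})

test_that("overlap cross-fade interpolates linearly between chunks", {
  # two 8-slice chunks with constant values a and b, overlap 2:
  # blended slices must be (2a+b)/3 and (a+2b)/3
  a <- 10; b <- 40
  plan <- chunk_plan(8, 2)
  mk <- function(val, start) {
    o <- ct_volume(array(val, c(2, 2, 8)), c(1, 1, 1))
    attr(o, "start") <- start
    o
  }
  st <- stitch_chunks(list(mk(a, 0), mk(b, 6)), plan, 1, 14)
  prof <- st$voxels[1, 1, ]
  expect_equal(prof[1:6], rep(a, 6))
  expect_equal(prof[7], (2 * a + b) / 3)
  expect_equal(prof[8], (a + 2 * b) / 3)
  expect_equal(prof[9:14], rep(b, 6))
})

test_that("stitch validates chunk count and shape against the plan", {
  plan <- chunk_plan(8, 0)
  v <- ct_volume(array(0, c(2, 2, 16)), c(1, 1, 1))
  chs <- chunk_volume(v, plan)
  expect_error(stitch_chunks(chs[1], plan, 1, 16), "expected 2 chunks")
  bad <- chs
  bad[[1]]$voxels <- bad[[1]]$voxels[, , 1:4, drop = FALSE]
  expect_error(stitch_chunks(bad, plan, 1, 16), "chunk depth")
})

test_that("trilinear upsampling interpolates slice centers with endpoint alignment", {
  v <- ct_volume(array(c(0, 4), c(1, 1, 2)), c(1, 1, 4))
  up <- trilinear_upsample(v, 4)
  expect_equal(as.numeric(up$voxels[1, 1, ]), c(0, 1, 2, 3, 4, 4, 4, 4))
  expect_equal(up$spacing_mm[3], 1)
  const <- ct_volume(array(7, c(2, 2, 5)), c(1, 1, 1))
  expect_true(all(trilinear_upsample(const, 3)$voxels == 7))
  expect_identical(trilinear_upsample(const, 1), const)
  expect_error(trilinear_upsample(const, 0), ">= 1")
})

test_that("degrading a linearly upsampled smooth volume approximately recovers it", {
  # the aligned-endpoint convention shifts each averaged group by 0.375 of a
  # slice, so the round-trip error is bounded by that shift times the local
  # slope of the (smooth) profile
  z <- seq(0, 2 * pi, length.out = 24)
  profile <- 100 * sin(z / 3)
  smooth <- ct_volume(outer(matrix(1, 4, 4), profile), c(1, 1, 4))
  rt <- simulate_thick(trilinear_upsample(smooth, 4), 4)
  bound <- 0.375 * max(abs(diff(profile))) * 1.05
  expect_lt(max(abs(rt$voxels - smooth$voxels)), bound)
  expect_gt(stats::cor(as.numeric(rt$voxels), as.numeric(smooth$voxels)), 0.995)
})
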