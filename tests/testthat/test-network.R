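test_that("compiled 3D convolution matches direct summation, forward and backward", {
  set.seed(1)
  x <- array(rnorm(5 * 4 * 6 * 2), c(5, 4, 6, 2))
  w <- array(rnorm(27 * 2 * 3), c(3, 3, 3, 2, 3))
  b <- rnorm(3)
  expect_equal(ctsr:::conv3(x, w, b), naive_conv3(x, w, b), tolerance = 1e-12)
  s <- c(2, 2, 2)
  y <- ctsr:::conv3(x, w, b, stride = s)
  expect_equal(y, naive_conv3(x, w, b, s = s), tolerance = 1e-12)
  # gradients against central finite differences
  gy <- array(rnorm(length(y)), dim(y))
  bw <- ctsr:::conv3_bw(x, w, gy, stride = s)
  eps <- 1e-6
  for (i in c(1, 17, 100)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (sum(ctsr:::conv3(xp, w, b, stride = s) * gy) -
             sum(ctsr:::conv3(xm, w, b, stride = s) * gy)) / (2 * eps)
    expect_equal(bw$gx[i], fd, tolerance = 1e-5)
  }
  wp <- w; wp[33] <- wp[33] + eps
  wm <- w; wm[33] <- wm[33] - eps
  fd <- (sum(ctsr:::conv3(x, wp, b, stride = s) * gy) -
           sum(ctsr:::conv3(x, wm, b, stride = s) * gy)) / (2 * eps)
  expect_equal(bw$gw[33], fd, tolerance = 1e-5)
})

test_that("voxel shuffle obeys the channel-to-depth shape rule", {
  x <- array(rnorm(1 * 4 * 2 * 2 * 3), c(1, 4, 2, 2, 3))
  y <- voxel_shuffle_sg(x, 4)
  expect_equal(dim(y), c(1, 1, 2, 2, 12))
  expect_identical(voxel_shuffle_sg(x, 1), x)
  expect_error(voxel_shuffle_sg(x, 3), "not divisible")
})

test_that("voxel shuffle matches the brute-force index map and is invertible", {
  # full enumeration on a 4-element array: channel c*r+k -> depth d*r+k
  x <- array(seq_len(4), c(1, 2, 1, 1, 2))
  y <- voxel_shuffle_sg(x, 2)
  for (d in 0:1) for (k in 0:1)
    expect_equal(y[1, 1, 1, 1, d * 2 + k + 1], x[1, k + 1, 1, 1, d + 1])
  expect_equal(as.numeric(y[1, 1, 1, 1, ]), c(1, 2, 3, 4))
  # larger random case: brute-force oracle plus bit-exact inversion
  set.seed(2)
  x <- array(rnorm(2 * 6 * 3 * 4 * 5), c(2, 6, 3, 4, 5))
  r <- 3
  y <- voxel_shuffle_sg(x, r)
  for (probe in list(c(1, 1, 1, 1, 1), c(2, 2, 3, 4, 5), c(1, 2, 2, 1, 13))) {
    b <- probe[1]; c0 <- probe[2] - 1; h <- probe[3]; w <- probe[4]
    dr <- probe[5] - 1
    d0 <- dr %/% r; k <- dr %% r
    expect_equal(y[b, c0 + 1, h, w, dr + 1],
                 x[b, c0 * r + k + 1, h, w, d0 + 1])
  }
  expect_identical(voxel_unshuffle_sg(y, r), x)
  expect_equal(sort(as.numeric(y)), sort(as.numeric(x)))  # multiset conserved
})

test_that("generator output shape is input shape with depth scaled by r", {
  cfg <- generator_config(r = 4, n_rrdb = 1, base_channels = 4,
                          growth_channels = 2)
  params <- init_generator(cfg, seed = 1)
  x <- array(runif(8 * 8 * 6), c(8, 8, 6))
  out <- generator_forward(x, cfg, params)
  expect_equal(dim(out), c(8, 8, 24, 1))
})

test_that("a zero-weight generator outputs exactly zero", {
  cfg <- generator_config(r = 2, n_rrdb = 2, base_channels = 4,
                          growth_channels = 2, beta = 0.7)
  params <- lapply(init_generator(cfg, seed = 1), function(p) p * 0)
  out <- generator_forward(array(runif(5 * 5 * 4), c(5, 5, 4)), cfg, params)
  expect_true(all(out == 0))
})

test_that("generator parameter count matches the layer-by-layer closed form", {
  cfg <- generator_config(r = 4, n_rrdb = 1, base_channels = 4,
                          growth_channels = 2)
  params <- init_generator(cfg)
  conv_p <- function(cin, cout) 27 * cin * cout + cout
  nf <- 4; gc <- 2
  rdb <- conv_p(nf, gc) + conv_p(nf + gc, gc) + conv_p(nf + 2 * gc, gc) +
    conv_p(nf + 3 * gc, gc) + conv_p(nf + 4 * gc, nf)
  expected <- conv_p(1, nf) + 3 * rdb + conv_p(nf, nf) +
    conv_p(nf, nf * 4) + conv_p(nf, nf) + conv_p(nf, 1)
  expect_equal(n_params(params), expected)
})

test_that("zeroing the dense blocks reduces the generator to its residual skips", {
  # with every RDB conv zero, each RDB is its skip connection, so each RRDB
  # scales its input by (1 + beta): out = tail(fea0 + trunk((1+beta)^n fea0))
  cfg <- generator_config(r = 2, n_rrdb = 2, base_channels = 4,
                          growth_channels = 2)
  params <- init_generator(cfg, seed = 9)
  for (nm in grep("^rrdb", names(params), value = TRUE)) params[[nm]] <- params[[nm]] * 0
  x <- array(runif(6 * 6 * 4), c(6, 6, 4, 1))
  out <- generator_forward(x, cfg, params)
  fea0 <- ctsr:::conv3(x, params$head.w, params$head.b)
  t <- (1 + cfg$beta)^cfg$n_rrdb * fea0
  fea <- fea0 + ctsr:::conv3(t, params$trunk.w, params$trunk.b)
  up <- ctsr:::conv3(fea, params$up.w, params$up.b)
  hr <- ctsr:::lrelu(ctsr:::conv3(ctsr:::shuffle4(up, 2), params$hr.w, params$hr.b),
                     cfg$lrelu_slope)
  manual <- ctsr:::conv3(hr, params$last.w, params$last.b)
  expect_equal(out, manual, tolerance = 1e-12)
})

test_that("generator backward matches finite differences through the whole network", {
  cfg <- generator_config(r = 2, n_rrdb = 1, base_channels = 4,
                          growth_channels = 2)
  params <- init_generator(cfg, seed = 3)
  set.seed(5)
  x <- array(runif(6 * 5 * 4), c(6, 5, 4, 1))
  gt <- array(runif(6 * 5 * 8), c(6, 5, 8, 1))
  fw <- ctsr:::gen_forward_sample(x, cfg, params, want_cache = TRUE)
  gout <- 2 * (fw$out - gt) / length(fw$out)
  bw <- ctsr:::gen_backward_sample(gout, cfg, params, fw$cache)
  loss <- function(p) mean((ctsr:::gen_forward_sample(x, cfg, p)$out - gt)^2)
  eps <- 1e-6
  for (nm in c("head.w", "rrdb1.rdb2.c3.w", "rrdb1.rdb1.c5.w", "trunk.w",
               "up.w", "last.w", "rrdb1.rdb3.c1.b")) {
    i <- 5 %% length(params[[nm]]) + 1
    pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
    fd <- (loss(pp) - loss(pm)) / (2 * eps)
    expect_equal(bw$grads[[nm]][i], fd, tolerance = 1e-3,
                 label = sprintf("grad of %s", nm))
  }
})

test_that("discriminator outputs calibrated probabilities", {
  cfg <- discriminator_config(n_conv_pairs = 4, base_channels = 4,
                              dense_width = 8)
  params <- init_discriminator(cfg, c(8, 8, 8), seed = 2)
  x <- array(runif(512), c(8, 8, 8))
  p <- discriminator_forward(x, cfg, params)
  expect_true(p > 0 && p < 1)
  zero <- lapply(params, function(p) p * 0)
  attr(zero, "input_shape") <- attr(params, "input_shape")
  expect_equal(discriminator_forward(x, cfg, zero), 0.5)
  # monotone in the final dense bias
  lo <- params; lo$dense2.b <- -1
  hi <- params; hi$dense2.b <- 1
  expect_lt(discriminator_forward(x, cfg, lo),
            discriminator_forward(x, cfg, hi))
  expect_error(discriminator_forward(array(0, c(4, 4, 4)), cfg, params),
               "shape")
})
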