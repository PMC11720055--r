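#' Generator configuration
#'
#' Architecture hyperparameters of the slice-generation network: an
#' ESRGAN-lineage 3D generator of residual-in-residual dense blocks (RRDBs)
#' followed by a voxel-shuffle head that multiplies the stack-axis slice count
#' by `r`. Defaults are the full-scale settings (23 RRDBs, residual scaling
#' 0.2, x4 depth upsampling); desk-scale experiments shrink `n_rrdb` and the
#' channel widths. All convolutions are 3x3x3, stride 1, padding 1, with no
#' batch normalization anywhere.
#'
#' @param r depth scaling factor (>= 1; default 4).
#' @param n_rrdb number of RRDBs (>= 1; default 23).
#' @param base_channels trunk feature width (default 64).
#' @param growth_channels dense-connection growth width (default 32).
#' @param beta residual scaling in (0, 1] applied to every dense-block output
#'   and to the RRDB stack (default 0.2).
#' @param lrelu_slope negative slope of the leaky rectifier (default 0.2).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(r = 4L, n_rrdb = 23L, base_channels = 64L,
                             growth_channels = 32L, beta = 0.2,
                             lrelu_slope = 0.2) {
  r <- as.integer(r); n_rrdb <- as.integer(n_rrdb)
  if (r < 1L) stop("'r' must be >= 1")
  if (n_rrdb < 1L) stop("'n_rrdb' must be >= 1")
  if (!(beta > 0 && beta <= 1)) stop("'beta' must be in (0, 1]")
  structure(list(r = r, n_rrdb = n_rrdb,
                 base_channels = as.integer(base_channels),
                 growth_channels = as.integer(growth_channels),
                 beta = beta, lrelu_slope = lrelu_slope),
            class = "generator_config")
}

#' Discriminator configuration
#'
#' Eight 3D convolution + LReLU pairs (strides alternating 1 and 2 to shrink
#' the receptive field to the dense layers), one dense layer of width
#' `dense_width`, an LReLU, a final dense layer to one unit and a sigmoid.
#' An output of 1 means "judged ground-truth thin-slice", 0 "judged generated".
#'
#' @param n_conv_pairs conv+LReLU pairs (default 8).
#' @param base_channels width of the first pair; doubled every second pair,
#'   capped at 8x (default 64).
#' @param dense_width first dense layer width (default 1024).
#' @param lrelu_slope leaky rectifier slope (default 0.2).
#' @return an object of class `discriminator_config`.
#' @export
discriminator_config <- function(n_conv_pairs = 8L, base_channels = 64L,
                                 dense_width = 1024L, lrelu_slope = 0.2) {
  n_conv_pairs <- as.integer(n_conv_pairs)
  if (n_conv_pairs < 1L) stop("'n_conv_pairs' must be >= 1")
  if (dense_width < 1L) stop("'dense_width' must be >= 1")
  structure(list(n_conv_pairs = n_conv_pairs,
                 base_channels = as.integer(base_channels),
                 dense_width = as.integer(dense_width),
                 lrelu_slope = lrelu_slope),
            class = "discriminator_config")
}

#' Voxel shuffle: move channels into the depth axis
#'
#' A pure rearrangement (bijection on elements, no arithmetic) taking a
#' 5-axis array of shape `(batch, channel * r, H, W, D)` to
#' `(batch, channel, H, W, D * r)` with, in 0-based indices,
#' `out[b, c, h, w, d*r + k] = in[b, c*r + k, h, w, d]` for `k` in `0..r-1`.
#' This is the slice-generation analogue of 2D sub-pixel (pixel-shuffle)
#' upsampling: each group of `r` consecutive channels becomes `r` consecutive
#' output slices.
#'
#' @param x 5-axis array `(batch, channel * r, H, W, D)`.
#' @param r integer scaling factor; the channel count must be divisible by it.
#' @return 5-axis array `(batch, channel, H, W, D * r)`.
#' @export
voxel_shuffle_sg <- function(x, r) {
  d <- dim(x)
  if (length(d) != 5L) stop("'x' must be a 5-axis array (batch, channel, H, W, D)")
  r <- as.integer(r)
  if (r < 1L) stop("'r' must be >= 1")
  if (d[2] %% r != 0L)
    stop(sprintf("channel axis (%d) not divisible by r = %d", d[2], r))
  if (r == 1L) return(x)
  cn <- d[2] %/% r
  dim(x) <- c(d[1], r, cn, d[3], d[4], d[5])   # channel c*r+k splits as (k fast, c)
  x <- aperm(x, c(1L, 3L, 4L, 5L, 2L, 6L))     # (b, c, H, W, r, D): k fast in depth
  dim(x) <- c(d[1], cn, d[3], d[4], r * d[5])
  x
}

#' @rdname voxel_shuffle_sg
#' @details `voxel_unshuffle_sg()` is the exact inverse map; composing the two
#'   recovers the input bit-exactly.
#' @export
voxel_unshuffle_sg <- function(x, r) {
  d <- dim(x)
  if (length(d) != 5L) stop("'x' must be a 5-axis array (batch, channel, H, W, D)")
  r <- as.integer(r)
  if (r < 1L) stop("'r' must be >= 1")
  if (d[5] %% r != 0L)
    stop(sprintf("depth axis (%d) not divisible by r = %d", d[5], r))
  if (r == 1L) return(x)
  dn <- d[5] %/% r
  dim(x) <- c(d[1], d[2], d[3], d[4], r, dn)
  x <- aperm(x, c(1L, 5L, 2L, 3L, 4L, 6L))     # (b, r, c, H, W, D)
  dim(x) <- c(d[1], d[2] * r, d[3], d[4], dn)
  x
}

## ---- internal numerics: layout (H, W, D, C), flat named parameter lists ----

conv3 <- function(x, w, b, stride = c(1L, 1L, 1L), pad = c(1L, 1L, 1L)) {
  conv3d_forward_cpp(x, dim(x), w, dim(w), b,
                     as.integer(stride), as.integer(pad))
}

conv3_bw <- function(x, w, gy, stride = c(1L, 1L, 1L), pad = c(1L, 1L, 1L)) {
  conv3d_backward_cpp(x, dim(x), w, dim(w), gy,
                      as.integer(stride), as.integer(pad))
}

lrelu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}

lrelu_bw <- function(g, pre, slope) {
  neg <- pre < 0
  g[neg] <- g[neg] * slope
  g
}

cat_c <- function(...) {
  args <- list(...)
  d <- dim(args[[1]])
  array(unlist(args, use.names = FALSE),
        c(d[1:3], sum(vapply(args, function(a) dim(a)[4], numeric(1)))))
}

# shuffle on the internal (H, W, D, C) layout, same index semantics as
# voxel_shuffle_sg: out[h, w, d*r+k, c] = in[h, w, d, c*r+k]
shuffle4 <- function(x, r) {
  d <- dim(x)
  cn <- d[4] %/% r
  dim(x) <- c(d[1], d[2], d[3], r, cn)
  x <- aperm(x, c(1L, 2L, 4L, 3L, 5L))
  dim(x) <- c(d[1], d[2], r * d[3], cn)
  x
}

unshuffle4 <- function(x, r) {
  d <- dim(x)
  dn <- d[3] %/% r
  dim(x) <- c(d[1], d[2], r, dn, d[4])
  x <- aperm(x, c(1L, 2L, 4L, 3L, 5L))
  dim(x) <- c(d[1], d[2], dn, r * d[4])
  x
}

# conv layer names and shapes of the generator, in forward order
gen_layer_table <- function(cfg) {
  nf <- cfg$base_channels; gc <- cfg$growth_channels
  layers <- list(head = c(1L, nf))
  for (i in seq_len(cfg$n_rrdb)) for (j in 1:3) {
    cin <- nf
    for (k in 1:4) {
      layers[[sprintf("rrdb%d.rdb%d.c%d", i, j, k)]] <- c(cin, gc)
      cin <- cin + gc
    }
    layers[[sprintf("rrdb%d.rdb%d.c5", i, j)]] <- c(cin, nf)
  }
  layers$trunk <- c(nf, nf)
  layers$up <- c(nf, nf * cfg$r)
  layers$hr <- c(nf, nf)
  layers$last <- c(nf, 1L)
  layers
}

#' Initialize generator parameters
#'
#' Weights are small scaled-Gaussian (Kaiming-style, scaled down by 0.1 as is
#' customary for this architecture family) plus an ICNR-style near-identity
#' component in the head, expansion, HR and output convolutions so that the
#' freshly initialized generator approximates nearest-neighbour slice
#' repetition — the standard stable starting point for sub-pixel upsampling
#' heads.
#'
#' @param cfg a [generator_config()].
#' @param seed RNG seed for the random component.
#' @param identity_gain weight of the identity component (default 1; 0 gives a
#'   purely random small init).
#' @return named list of parameter arrays (`<layer>.w` of shape
#'   `(3, 3, 3, Cin, Cout)` and `<layer>.b`).
#' @export
init_generator <- function(cfg, seed = 1L, identity_gain = 1) {
  rng_state <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(rng_state)) assign(".Random.seed", rng_state, .GlobalEnv))
  set.seed(seed)
  layers <- gen_layer_table(cfg)
  params <- list()
  for (nm in names(layers)) {
    cin <- layers[[nm]][1]; cout <- layers[[nm]][2]
    sd <- 0.1 * sqrt(2 / (27 * cin))
    w <- array(stats::rnorm(27 * cin * cout, 0, sd), c(3L, 3L, 3L, cin, cout))
    params[[paste0(nm, ".w")]] <- w
    params[[paste0(nm, ".b")]] <- numeric(cout)
  }
  if (identity_gain != 0) {
    add_id <- function(nm, cin, couts) {
      w <- params[[paste0(nm, ".w")]]
      for (co in couts) w[2, 2, 2, cin, co] <- w[2, 2, 2, cin, co] + identity_gain
      params[[paste0(nm, ".w")]] <<- w
    }
    add_id("head", 1L, 1L)                     # image into feature channel 1
    add_id("up", 1L, seq_len(cfg$r))           # channels (1..r) -> r repeats of ch 1
    add_id("hr", 1L, 1L)
    add_id("last", 1L, 1L)
  }
  params
}

#' Total parameter count
#' @param params a named parameter list.
#' @return integer count of scalar parameters.
#' @export
n_params <- function(params) sum(vapply(params, length, numeric(1)))

rdb_forward <- function(x, params, prefix, cfg, cache = NULL) {
  slope <- cfg$lrelu_slope
  feats <- list(x)
  pres <- list()
  for (k in 1:4) {
    xin <- do.call(cat_c, feats)
    pre <- conv3(xin, params[[sprintf("%s.c%d.w", prefix, k)]],
                 params[[sprintf("%s.c%d.b", prefix, k)]])
    pres[[k]] <- pre
    feats[[k + 1]] <- lrelu(pre, slope)
  }
  xin <- do.call(cat_c, feats)
  x5 <- conv3(xin, params[[paste0(prefix, ".c5.w")]],
              params[[paste0(prefix, ".c5.b")]])
  out <- x + cfg$beta * x5
  if (!is.null(cache)) cache[[prefix]] <- list(feats = feats, pres = pres)
  list(out = out, cache = cache)
}

rdb_backward <- function(gout, params, prefix, cfg, cache, grads) {
  slope <- cfg$lrelu_slope
  st <- cache[[prefix]]
  feats <- st$feats; pres <- st$pres
  nf <- dim(feats[[1]])[4]; gcw <- dim(feats[[2]])[4]
  gx <- gout                                  # through the residual skip
  g5 <- cfg$beta * gout
  xin5 <- do.call(cat_c, feats)
  bw <- conv3_bw(xin5, params[[paste0(prefix, ".c5.w")]], g5)
  grads[[paste0(prefix, ".c5.w")]] <- grads[[paste0(prefix, ".c5.w")]] + bw$gw
  grads[[paste0(prefix, ".c5.b")]] <- grads[[paste0(prefix, ".c5.b")]] + bw$gb
  # split the concat gradient into per-feature gradients
  gfeats <- vector("list", 5)
  ofs <- 0L
  for (m in 1:5) {
    cm <- dim(feats[[m]])[4]
    gfeats[[m]] <- bw$gx[, , , ofs + seq_len(cm), drop = FALSE]
    ofs <- ofs + cm
  }
  for (k in 4:1) {
    gpre <- lrelu_bw(gfeats[[k + 1]], pres[[k]], slope)
    xin <- do.call(cat_c, feats[seq_len(k)])
    bw <- conv3_bw(xin, params[[sprintf("%s.c%d.w", prefix, k)]], gpre)
    grads[[sprintf("%s.c%d.w", prefix, k)]] <-
      grads[[sprintf("%s.c%d.w", prefix, k)]] + bw$gw
    grads[[sprintf("%s.c%d.b", prefix, k)]] <-
      grads[[sprintf("%s.c%d.b", prefix, k)]] + bw$gb
    ofs <- 0L
    for (m in seq_len(k)) {
      cm <- dim(feats[[m]])[4]
      gfeats[[m]] <- gfeats[[m]] + bw$gx[, , , ofs + seq_len(cm), drop = FALSE]
      ofs <- ofs + cm
    }
  }
  list(gx = gx + gfeats[[1]], grads = grads)
}

gen_forward_sample <- function(x, cfg, params, want_cache = FALSE) {
  cache <- if (want_cache) list() else NULL
  fea0 <- conv3(x, params$head.w, params$head.b)
  t <- fea0
  rrdb_in <- if (want_cache) vector("list", cfg$n_rrdb) else NULL
  for (i in seq_len(cfg$n_rrdb)) {
    x_in <- t
    for (j in 1:3) {
      res <- rdb_forward(t, params, sprintf("rrdb%d.rdb%d", i, j), cfg, cache)
      t <- res$out
      cache <- res$cache
    }
    t <- x_in + cfg$beta * t
    if (want_cache) rrdb_in[[i]] <- x_in
  }
  trunk <- conv3(t, params$trunk.w, params$trunk.b)
  fea <- fea0 + trunk
  up <- conv3(fea, params$up.w, params$up.b)
  shuf <- shuffle4(up, cfg$r)
  hr_pre <- conv3(shuf, params$hr.w, params$hr.b)
  hr <- lrelu(hr_pre, cfg$lrelu_slope)
  out <- conv3(hr, params$last.w, params$last.b)
  if (want_cache) {
    cache$x <- x; cache$fea0 <- fea0; cache$rrdb_in <- rrdb_in
    cache$rrdb_out <- t
    cache$fea <- fea; cache$shuf <- shuf; cache$hr_pre <- hr_pre; cache$hr <- hr
  }
  list(out = out, cache = cache)
}

gen_backward_sample <- function(gout, cfg, params, cache) {
  grads <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  bw <- conv3_bw(cache$hr, params$last.w, gout)
  grads$last.w <- bw$gw; grads$last.b <- bw$gb
  g <- lrelu_bw(bw$gx, cache$hr_pre, cfg$lrelu_slope)
  bw <- conv3_bw(cache$shuf, params$hr.w, g)
  grads$hr.w <- bw$gw; grads$hr.b <- bw$gb
  g <- unshuffle4(bw$gx, cfg$r)
  bw <- conv3_bw(cache$fea, params$up.w, g)
  grads$up.w <- bw$gw; grads$up.b <- bw$gb
  gfea <- bw$gx
  bw <- conv3_bw(cache$rrdb_out, params$trunk.w, gfea)
  grads$trunk.w <- bw$gw; grads$trunk.b <- bw$gb
  g <- bw$gx
  for (i in rev(seq_len(cfg$n_rrdb))) {
    g_skip <- g
    g <- cfg$beta * g
    for (j in 3:1) {
      res <- rdb_backward(g, params, sprintf("rrdb%d.rdb%d", i, j), cfg,
                          cache, grads)
      g <- res$gx
      grads <- res$grads
    }
    g <- g + g_skip
  }
  gfea0 <- g + gfea                           # global residual joins head output
  bw <- conv3_bw(cache$x, params$head.w, gfea0)
  grads$head.w <- bw$gw; grads$head.b <- bw$gb
  list(gx = bw$gx, grads = grads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_sample_array <- function(x) {
  # accept a ct_volume, a 3D array, or an internal (H, W, D, 1) array
  if (is_ct_volume(x)) x <- x$voxels
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  if (length(dim(x)) != 4L) stop("expected a 3D volume or (H, W, D, C) array")
  x
}

#' Run the generator on one chunk
#'
#' Applies the full generator pipeline — head convolution, RRDB stack with
#' global residual, trunk convolution, channel expansion to `base * r`,
#' voxel shuffle, and two output convolutions — to a single-channel chunk.
#' Input intensities are expected on the normalized \[0, 1\] scale
#' (see [hu_normalize()]).
#'
#' @param x a [ct_volume()] chunk or 3D/`(H, W, D, 1)` array.
#' @param cfg a [generator_config()].
#' @param params parameters from [init_generator()] or a fitted model.
#' @return array of shape `(H, W, D * r, 1)`.
#' @export
generator_forward <- function(x, cfg, params) {
  x <- as_sample_array(x)
  d <- dim(x)
  if (d[4] != 1L) stop("generator input must be single-channel")
  if (any(d[1:3] < 3L)) stop("spatial extent smaller than the kernel size")
  gen_forward_sample(x, cfg, params, want_cache = FALSE)$out
}

## ---- discriminator ----

disc_channel_schedule <- function(cfg) {
  i <- seq_len(cfg$n_conv_pairs) - 1L
  pmin(cfg$base_channels * 2^(i %/% 2L), cfg$base_channels * 8L)
}

disc_strides <- function(cfg) {
  ifelse(seq_len(cfg$n_conv_pairs) %% 2L == 0L, 2L, 1L)
}

#' Initialize discriminator parameters
#'
#' The dense layers' sizes depend on the training chunk shape, so the input
#' spatial shape (at thin-slice resolution) is fixed at initialization.
#'
#' @param cfg a [discriminator_config()].
#' @param input_shape length-3 spatial shape `(H, W, D)` of discriminator inputs.
#' @param seed RNG seed.
#' @return named parameter list (convs, `dense1.*`, `dense2.*`), with the
#'   input shape recorded in attribute `input_shape`.
#' @export
init_discriminator <- function(cfg, input_shape, seed = 1L) {
  rng_state <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(rng_state)) assign(".Random.seed", rng_state, .GlobalEnv))
  set.seed(seed)
  chans <- disc_channel_schedule(cfg)
  strides <- disc_strides(cfg)
  params <- list()
  cin <- 1L
  sh <- as.integer(input_shape)
  for (i in seq_len(cfg$n_conv_pairs)) {
    cout <- chans[i]
    sd <- sqrt(2 / (27 * cin))
    params[[sprintf("conv%d.w", i)]] <-
      array(stats::rnorm(27 * cin * cout, 0, sd), c(3L, 3L, 3L, cin, cout))
    params[[sprintf("conv%d.b", i)]] <- numeric(cout)
    sh <- (sh + 2L - 3L) %/% strides[i] + 1L
    if (any(sh < 1L)) stop("input shape too small for the conv stack")
    cin <- cout
  }
  flat <- prod(sh) * cin
  params$dense1.w <- matrix(stats::rnorm(flat * cfg$dense_width, 0, sqrt(2 / flat)),
                            flat, cfg$dense_width)
  params$dense1.b <- numeric(cfg$dense_width)
  params$dense2.w <- matrix(stats::rnorm(cfg$dense_width, 0, sqrt(1 / cfg$dense_width)),
                            cfg$dense_width, 1L)
  params$dense2.b <- 0
  attr(params, "input_shape") <- as.integer(input_shape)
  params
}

disc_forward_sample <- function(x, cfg, params, want_cache = FALSE) {
  strides <- disc_strides(cfg)
  cache <- if (want_cache) list(inputs = list(), pres = list()) else NULL
  t <- x
  for (i in seq_len(cfg$n_conv_pairs)) {
    if (want_cache) cache$inputs[[i]] <- t
    pre <- conv3(t, params[[sprintf("conv%d.w", i)]],
                 params[[sprintf("conv%d.b", i)]],
                 stride = rep(strides[i], 3L))
    if (want_cache) cache$pres[[i]] <- pre
    t <- lrelu(pre, cfg$lrelu_slope)
  }
  flat <- as.numeric(t)
  z1 <- as.numeric(flat %*% params$dense1.w) + params$dense1.b
  a1 <- lrelu(z1, cfg$lrelu_slope)
  z2 <- sum(a1 * params$dense2.w[, 1]) + params$dense2.b
  p <- 1 / (1 + exp(-z2))
  if (want_cache) {
    cache$flat <- flat; cache$flat_dim <- dim(t)
    cache$z1 <- z1; cache$a1 <- a1; cache$p <- p
  }
  list(p = p, cache = cache)
}

disc_backward_sample <- function(gp, cfg, params, cache) {
  # gp: dLoss/dp at the sigmoid output
  p <- cache$p
  gz2 <- gp * p * (1 - p)
  grads <- list()
  grads$dense2.w <- matrix(gz2 * cache$a1, ncol = 1L)
  grads$dense2.b <- gz2
  ga1 <- gz2 * params$dense2.w[, 1]
  gz1 <- lrelu_bw(ga1, cache$z1, cfg$lrelu_slope)
  grads$dense1.w <- outer(cache$flat, gz1)
  grads$dense1.b <- gz1
  gflat <- as.numeric(params$dense1.w %*% gz1)
  g <- array(gflat, cache$flat_dim)
  strides <- disc_strides(cfg)
  for (i in rev(seq_len(cfg$n_conv_pairs))) {
    g <- lrelu_bw(g, cache$pres[[i]], cfg$lrelu_slope)
    bw <- conv3_bw(cache$inputs[[i]], params[[sprintf("conv%d.w", i)]], g,
                   stride = rep(strides[i], 3L))
    grads[[sprintf("conv%d.w", i)]] <- bw$gw
    grads[[sprintf("conv%d.b", i)]] <- bw$gb
    g <- bw$gx
  }
  list(gx = g, grads = grads)
}

#' Run the discriminator
#'
#' @param x one chunk (3D array / `ct_volume` on the normalized scale) or a
#'   list of them (a batch).
#' @param cfg a [discriminator_config()].
#' @param params parameters from [init_discriminator()].
#' @return numeric vector of probabilities in (0, 1), one per batch item;
#'   1 means "judged ground-truth thin-slice".
#' @export
discriminator_forward <- function(x, cfg, params) {
  if (!is.list(x) || is_ct_volume(x)) x <- list(x)
  vapply(x, function(xi) {
    xi <- as_sample_array(xi)
    expected <- attr(params, "input_shape")
    if (!is.null(expected) && !all(dim(xi)[1:3] == expected))
      stop(sprintf("discriminator input shape (%s) != initialized shape (%s)",
                   paste(dim(xi)[1:3], collapse = "x"),
                   paste(expected, collapse = "x")))
    disc_forward_sample(xi, cfg, params)$p
  }, numeric(1))
}
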