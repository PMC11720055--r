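#' Loss configuration
#'
#' Weights and settings of the three-term generator objective:
#' pixel-wise mean squared error, a perceptual (feature-space) distance
#' computed slice by slice, and the adversarial term `sum(-log D(G(x)))`.
#' Defaults weight the terms (1, 1, 5e-3); the small adversarial weight is
#' the convention of this architecture family.
#'
#' @param w_mse,w_perc,w_adv non-negative weights; at least one must be > 0.
#' @param perc_layer which stage of the feature extractor supplies the
#'   feature maps (1-3; default 3, the deepest).
#' @param perc_plane axis (1-3) along which volumes are split into 2D slices
#'   for the perceptual term (default 3, the stack axis of the processing
#'   orientation).
#' @param batch_size nominal batch size `N` of the adversarial sum (default 1).
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(w_mse = 1, w_perc = 1, w_adv = 5e-3,
                        perc_layer = 3L, perc_plane = 3L, batch_size = 1L) {
  if (w_mse < 0 || w_perc < 0 || w_adv < 0) stop("loss weights must be >= 0")
  if (w_mse + w_perc + w_adv == 0) stop("at least one loss weight must be > 0")
  perc_layer <- as.integer(perc_layer)
  if (!perc_layer %in% 1:3) stop("'perc_layer' must be 1, 2 or 3")
  perc_plane <- as.integer(perc_plane)
  if (!perc_plane %in% 1:3) stop("'perc_plane' must be 1, 2 or 3")
  structure(list(w_mse = w_mse, w_perc = w_perc, w_adv = w_adv,
                 perc_layer = perc_layer, perc_plane = perc_plane,
                 batch_size = as.integer(batch_size)),
            class = "loss_config")
}

#' Pixel-wise mean squared error
#'
#' The mean over all voxels of squared intensity differences between a
#' generated and a ground-truth volume (both on the same intensity scale):
#' for a `(H, W, r*D)` pair this is `1/(r*D*H*W) * sum((gt - gen)^2)`.
#'
#' @param gen,gt arrays (or [ct_volume()]s) of identical shape.
#' @return non-negative scalar; 0 iff the inputs are identical.
#' @export
mse_loss <- function(gen, gt) {
  if (is_ct_volume(gen)) gen <- gen$voxels
  if (is_ct_volume(gt)) gt <- gt$voxels
  if (!all(dim(gen) == dim(gt))) stop("shape mismatch between 'gen' and 'gt'")
  mean((gen - gt)^2)
}

LOG_CLAMP_EPS <- 1e-7

check_probs <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop(sprintf("'%s' must be probabilities in [0, 1]", what))
  p
}

#' Adversarial generator loss
#'
#' `sum(-log p_n)` over the batch of discriminator probabilities assigned to
#' generated volumes. Probabilities are clamped below at 1e-7 before the log,
#' so the loss is finite at p = 0 and exactly 0 at p = 1.
#'
#' @param disc_probs numeric vector of probabilities in \[0, 1\].
#' @return non-negative scalar, strictly decreasing in each probability.
#' @export
adversarial_gen_loss <- function(disc_probs) {
  p <- check_probs(disc_probs, "disc_probs")
  sum(-log(pmax(p, LOG_CLAMP_EPS)))
}

#' Discriminator loss
#'
#' Binary cross-entropy with target 1 for ground-truth thin-slice inputs and
#' 0 for generated inputs: `sum(-log p_real) + sum(-log(1 - p_fake))`, with
#' the same 1e-7 clamp inside the logs.
#'
#' @param p_real,p_fake probability vectors in \[0, 1\].
#' @return non-negative scalar, minimized when real scores 1 and fake 0.
#' @export
discriminator_loss <- function(p_real, p_fake) {
  p_real <- check_probs(p_real, "p_real")
  p_fake <- check_probs(p_fake, "p_fake")
  sum(-log(pmax(p_real, LOG_CLAMP_EPS))) +
    sum(-log(pmax(1 - p_fake, LOG_CLAMP_EPS)))
}

## ---- perceptual feature extractor ----
# A fixed convolutional feature network with internally seeded random weights
# (three 3x3 stages, the deeper two with stride 2). No pretrained weights are
# bundled with this package, so the perceptual term measures distance in the
# feature space of this fixed random network rather than of a classification
# network; it retains the structural properties of a perceptual loss (deep,
# translation-equivariant, multi-channel features compared by squared error).

PERC_CHANNELS <- c(8L, 16L, 32L)
PERC_STRIDES <- c(1L, 2L, 2L)
PERC_INPUT_MEAN <- 0.45
PERC_INPUT_SD <- 0.225

perc_env <- new.env(parent = emptyenv())

perc_params <- function() {
  if (is.null(perc_env$params)) {
    rng_state <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(rng_state)) assign(".Random.seed", rng_state, .GlobalEnv))
    set.seed(20240107L)                        # fixed: the extractor never changes
    cin <- 3L
    params <- list()
    for (s in seq_along(PERC_CHANNELS)) {
      cout <- PERC_CHANNELS[s]
      params[[s]] <- list(
        w = array(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                  c(3L, 3L, 1L, cin, cout)),
        b = numeric(cout))
      cin <- cout
    }
    perc_env$params <- params
  }
  perc_env$params
}

# slice (H, W) -> features of stage `layer`; optionally keep a backward cache
perc_features <- function(slice, layer, want_cache = FALSE) {
  x <- (slice - PERC_INPUT_MEAN) / PERC_INPUT_SD
  x <- array(rep(x, 3L), c(dim(slice), 1L, 3L))  # replicate to three channels
  pp <- perc_params()
  cache <- if (want_cache) list(inputs = list(), pres = list()) else NULL
  for (s in seq_len(layer)) {
    if (want_cache) cache$inputs[[s]] <- x
    pre <- conv3(x, pp[[s]]$w, pp[[s]]$b,
                 stride = c(PERC_STRIDES[s], PERC_STRIDES[s], 1L),
                 pad = c(1L, 1L, 0L))
    if (want_cache) cache$pres[[s]] <- pre
    x <- lrelu(pre, 0.2)
  }
  list(feat = x, cache = cache)
}

# gradient of mean((f(a) - f(b))^2) wrt the slice `a`
perc_slice_grad <- function(a_slice, b_feat, layer) {
  fa <- perc_features(a_slice, layer, want_cache = TRUE)
  diff <- fa$feat - b_feat
  g <- 2 * diff / length(diff)
  pp <- perc_params()
  for (s in rev(seq_len(layer))) {
    g <- lrelu_bw(g, fa$cache$pres[[s]], 0.2)
    bw <- conv3_bw(fa$cache$inputs[[s]], pp[[s]]$w, g,
                   stride = c(PERC_STRIDES[s], PERC_STRIDES[s], 1L),
                   pad = c(1L, 1L, 0L))
    g <- bw$gx
  }
  # collapse the channel replication and undo input standardization
  (g[, , 1, 1] + g[, , 1, 2] + g[, , 1, 3]) / PERC_INPUT_SD
}

slice_along <- function(x, axis, k) {
  switch(axis,
         `1` = x[k, , ],
         `2` = x[, k, ],
         `3` = x[, , k])
}

#' Perceptual (feature-space) loss
#'
#' Volumes are split into 2D slices along `cfg$perc_plane`; each slice pair is
#' passed through the package's fixed convolutional feature extractor and the
#' mean squared feature difference (normalized by the feature-map size) is
#' averaged over all slices. Inputs are expected on the normalized \[0, 1\]
#' intensity scale.
#'
#' @param gen,gt arrays or [ct_volume()]s of identical shape.
#' @param cfg a [loss_config()] (uses `perc_layer` and `perc_plane`).
#' @return non-negative scalar; 0 for identical inputs.
#' @export
perceptual_loss <- function(gen, gt, cfg = loss_config()) {
  if (is_ct_volume(gen)) gen <- gen$voxels
  if (is_ct_volume(gt)) gt <- gt$voxels
  if (!all(dim(gen) == dim(gt))) stop("shape mismatch between 'gen' and 'gt'")
  d <- dim(gen)
  if (length(d) == 4L && d[4] == 1L) { dim(gen) <- d[1:3]; dim(gt) <- d[1:3]; d <- d[1:3] }
  n <- d[cfg$perc_plane]
  if (n < 1L) stop("volume has no slices along 'perc_plane'")
  total <- 0
  for (k in seq_len(n)) {
    fa <- perc_features(slice_along(gen, cfg$perc_plane, k), cfg$perc_layer)$feat
    fb <- perc_features(slice_along(gt, cfg$perc_plane, k), cfg$perc_layer)$feat
    total <- total + mean((fa - fb)^2)
  }
  total / n
}

# gradient of perceptual_loss wrt `gen` (same shape as gen)
perceptual_loss_grad <- function(gen, gt, cfg) {
  d3 <- dim(gen)[1:3]
  g <- array(0, dim(gen))
  dim_gen <- dim(gen)
  gen3 <- gen; gt3 <- gt
  if (length(dim_gen) == 4L) { dim(gen3) <- d3; dim(gt3) <- d3 }
  n <- d3[cfg$perc_plane]
  for (k in seq_len(n)) {
    fb <- perc_features(slice_along(gt3, cfg$perc_plane, k), cfg$perc_layer)$feat
    gs <- perc_slice_grad(slice_along(gen3, cfg$perc_plane, k), fb, cfg$perc_layer) / n
    if (cfg$perc_plane == 1L) g[k, , , 1] <- gs
    else if (cfg$perc_plane == 2L) g[, k, , 1] <- gs
    else g[, , k, 1] <- gs
  }
  g
}

#' Combined generator objective
#'
#' `w_mse * mse + w_perc * perceptual + w_adv * adversarial`, linear in each
#' component.
#'
#' @param gen,gt volumes on the normalized scale.
#' @param disc_probs discriminator probabilities for the generated batch
#'   (ignored when `w_adv` is 0).
#' @param cfg a [loss_config()].
#' @return list with `total` and the raw components `mse`, `perc`, `adv`.
#' @export
total_generator_loss <- function(gen, gt, disc_probs = NULL, cfg = loss_config()) {
  if (cfg$w_mse + cfg$w_perc + cfg$w_adv == 0) stop("all loss weights are zero")
  mse <- if (cfg$w_mse > 0 || TRUE) mse_loss(gen, gt)
  perc <- if (cfg$w_perc > 0) perceptual_loss(gen, gt, cfg) else 0
  adv <- if (cfg$w_adv > 0) {
    if (is.null(disc_probs)) stop("'disc_probs' needed when w_adv > 0")
    adversarial_gen_loss(disc_probs)
  } else 0
  list(total = cfg$w_mse * mse + cfg$w_perc * perc + cfg$w_adv * adv,
       mse = mse, perc = perc, adv = adv)
}
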