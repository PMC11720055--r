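#' Training configuration
#'
#' Settings of the self-supervised adversarial training loop. Thin-slice
#' volumes are degraded 4:1 by consecutive-slice averaging to form aligned
#' (thick, thin) chunk pairs; the generator and discriminator are updated
#' alternately (1:1) with Adam. Optimizer defaults are beta1 = 0, beta2 = 0.9
#' and learning rate 1e-4. Training stops at the step budget or earlier when
#' the validation loss saturates (no improvement of at least `min_delta` over
#' `patience` evaluations).
#'
#' @param r depth upsampling factor (default 4).
#' @param plan a [chunk_plan()]; chunk lengths are in thick-slice slices, so
#'   ground-truth chunks span `chunk_len * r` thin slices.
#' @param generator a [generator_config()] (its `r` must equal `r`).
#' @param discriminator a [discriminator_config()].
#' @param losses a [loss_config()]; set `w_perc = w_adv = 0` for MSE-only
#'   training.
#' @param lr,beta1,beta2 Adam settings.
#' @param steps maximum optimizer steps.
#' @param batch_size chunk pairs per step (>= 1).
#' @param val_fraction fraction of whole volumes held out for validation
#'   (split by volume, never by chunk, to avoid leakage).
#' @param eval_every validation cadence in steps.
#' @param patience,min_delta loss-saturation stopping rule.
#' @param warmup_steps optional MSE-only warm-up steps before the perceptual
#'   and adversarial terms switch on (0 = off).
#' @param seed seed governing pair shuffling, initialization and batching.
#' @return an object of class `train_config`.
#' @export
train_config <- function(r = 4L, plan = chunk_plan(16L, 2L),
                         generator = generator_config(r = r),
                         discriminator = discriminator_config(),
                         losses = loss_config(),
                         lr = 1e-4, beta1 = 0, beta2 = 0.9,
                         steps = 1000L, batch_size = 1L,
                         val_fraction = 0.2, eval_every = 25L,
                         patience = 10L, min_delta = 1e-4,
                         warmup_steps = 0L, seed = 1L) {
  if (lr <= 0) stop("'lr' must be > 0")
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1)
    stop("Adam betas must be in [0, 1)")
  if (batch_size < 1L) stop("'batch_size' must be >= 1")
  if (generator$r != r) stop("generator config 'r' must match training 'r'")
  if (val_fraction < 0 || val_fraction >= 1) stop("'val_fraction' must be in [0, 1)")
  structure(list(r = as.integer(r), plan = plan, generator = generator,
                 discriminator = discriminator, losses = losses,
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 steps = as.integer(steps), batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, eval_every = as.integer(eval_every),
                 patience = as.integer(patience), min_delta = min_delta,
                 warmup_steps = as.integer(warmup_steps), seed = as.integer(seed)),
            class = "train_config")
}

#' Build aligned (thick, thin) training chunk pairs
#'
#' Each thin volume is normalized to \[0, 1\], chunked along the stack axis
#' into ground-truth chunks of `chunk_len * r` thin slices, and each chunk is
#' degraded by `r`-fold slice averaging to make its low-resolution partner, so
#' LR slice `k` covers GT slices `k*r .. k*r + r - 1` by construction. The
#' pair order is shuffled with the config seed. Volumes thinner than one
#' ground-truth chunk are skipped with a warning.
#'
#' @param thin_vols list of thin-slice [ct_volume()]s.
#' @param cfg a [train_config()].
#' @return list of pairs, each `list(lr, gt, volume, start)` with arrays on
#'   the normalized scale, in seeded shuffled order.
#' @export
make_training_pairs <- function(thin_vols, cfg) {
  r <- cfg$r
  gt_len <- cfg$plan$chunk_len * r
  gt_plan <- chunk_plan(gt_len, cfg$plan$overlap * r, cfg$plan$pad_mode)
  pairs <- list()
  for (v in seq_along(thin_vols)) {
    vol <- thin_vols[[v]]
    stopifnot_volume(vol)
    if (dim(vol$voxels)[3] < gt_len) {
      warning(sprintf("volume %d is thinner than one chunk (%d < %d); skipped",
                      v, dim(vol$voxels)[3], gt_len))
      next
    }
    nv <- ct_volume(hu_normalize(vol$voxels), vol$spacing_mm, vol$orientation)
    for (ch in chunk_volume(nv, gt_plan)) {
      gt <- as_sample_array(ch$voxels)
      lr <- as_sample_array(simulate_thick(ch, r)$voxels)
      pairs[[length(pairs) + 1L]] <-
        list(lr = lr, gt = gt, volume = v, start = attr(ch, "start"))
    }
  }
  if (length(pairs) == 0L) stop("no usable training pairs")
  rng_state <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(rng_state)) assign(".Random.seed", rng_state, .GlobalEnv))
  set.seed(cfg$seed)
  pairs[sample.int(length(pairs))]
}

## ---- Adam ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

## ---- the fitting function ----

#' Fit the slice-generation model
#'
#' Self-supervised training: the supplied thin-slice volumes are split by
#' whole volume into training and validation sets, degraded `r`-fold by slice
#' averaging, and the generator is trained to invert the degradation, with an
#' adversarial discriminator and perceptual term when their loss weights are
#' nonzero. Returns a fitted-model object with the usual methods:
#' [predict.ctsr_fit()] super-resolves a volume, `plot()` draws the loss
#' history, `coef()` returns the flattened generator parameters.
#'
#' Training is deterministic for a fixed config and seed. If the generator
#' loss becomes non-finite the fit aborts, reporting the step.
#'
#' @param thin_vols list of thin-slice [ct_volume()]s (at least 1 training
#'   and 1 validation volume after the split).
#' @param config a [train_config()].
#' @return an object of class `ctsr_fit`.
#' @export
ctsr_fit <- function(thin_vols, config = train_config()) {
  if (!inherits(config, "train_config")) stop("expected a 'train_config'")
  n_vol <- length(thin_vols)
  n_val <- max(1L, round(config$val_fraction * n_vol))
  if (n_vol - n_val < 1L)
    stop("need at least 1 training and 1 validation volume")

  rng_state <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(rng_state)) assign(".Random.seed", rng_state, .GlobalEnv))
  set.seed(config$seed)
  val_ids <- sort(sample.int(n_vol, n_val))
  train_ids <- setdiff(seq_len(n_vol), val_ids)

  pairs <- make_training_pairs(thin_vols[train_ids], config)
  val_pairs <- make_training_pairs(thin_vols[val_ids], config)

  gcfg <- config$generator
  lcfg <- config$losses
  params <- init_generator(gcfg, seed = config$seed)
  gstate <- adam_init(params)

  use_adv <- lcfg$w_adv > 0
  dparams <- dstate <- NULL
  if (use_adv) {
    gt_shape <- dim(pairs[[1]]$gt)[1:3]
    dparams <- init_discriminator(config$discriminator, gt_shape,
                                  seed = config$seed + 1L)
    dstate <- adam_init(dparams)
  }

  val_mse <- function() {
    mean(vapply(val_pairs, function(p) {
      out <- gen_forward_sample(p$lr, gcfg, params, want_cache = FALSE)$out
      mean((out - p$gt)^2)
    }, numeric(1)))
  }

  history <- list()
  if (config$steps > 0L) {
    history[[1L]] <- data.frame(step = 0L, loss_mse = NA_real_,
                                loss_perc = NA_real_, loss_adv = NA_real_,
                                loss_total = NA_real_, val_mse = val_mse())
  }
  best <- Inf; since_best <- 0L
  set.seed(config$seed + 2L)
  order_idx <- sample.int(length(pairs))
  cursor <- 0L
  stopped_at <- config$steps

  step <- 0L
  while (step < config$steps) {
    step <- step + 1L
    batch <- lapply(seq_len(config$batch_size), function(i) {
      cursor <<- cursor + 1L
      if (cursor > length(order_idx)) {
        order_idx <<- sample.int(length(pairs))
        cursor <<- 1L
      }
      pairs[[order_idx[cursor]]]
    })
    warm <- step <= config$warmup_steps
    adv_on <- use_adv && !warm
    perc_on <- lcfg$w_perc > 0 && !warm

    # ---- discriminator update (1:1 with the generator) ----
    gen_outs <- vector("list", length(batch))
    if (adv_on) {
      dgrads_tot <- NULL
      for (bi in seq_along(batch)) {
        p <- batch[[bi]]
        gen_outs[[bi]] <- gen_forward_sample(p$lr, gcfg, params)$out
        fr <- disc_forward_sample(p$gt, config$discriminator, dparams, TRUE)
        ff <- disc_forward_sample(gen_outs[[bi]], config$discriminator, dparams, TRUE)
        # d/dp of -log p and of -log(1 - p), with the documented clamp
        gpr <- -1 / pmax(fr$p, LOG_CLAMP_EPS)
        gpf <- 1 / pmax(1 - ff$p, LOG_CLAMP_EPS)
        br <- disc_backward_sample(gpr, config$discriminator, dparams, fr$cache)
        bf <- disc_backward_sample(gpf, config$discriminator, dparams, ff$cache)
        g <- Map(`+`, br$grads, bf$grads[names(br$grads)])
        dgrads_tot <- if (is.null(dgrads_tot)) g else Map(`+`, dgrads_tot, g)
      }
      upd <- adam_step(dparams, dgrads_tot[names(dparams)], dstate,
                       config$lr, config$beta1, config$beta2)
      att <- attributes(dparams)
      dparams <- upd$params; attributes(dparams) <- att
      dstate <- upd$state
    }

    # ---- generator update ----
    ggrads_tot <- NULL
    comp <- c(mse = 0, perc = 0, adv = 0)
    for (bi in seq_along(batch)) {
      p <- batch[[bi]]
      fw <- gen_forward_sample(p$lr, gcfg, params, want_cache = TRUE)
      out <- fw$out
      gout <- array(0, dim(out))
      l_mse <- mean((out - p$gt)^2)
      comp["mse"] <- comp["mse"] + l_mse
      if (lcfg$w_mse > 0)
        gout <- gout + lcfg$w_mse * 2 * (out - p$gt) / length(out)
      if (perc_on) {
        comp["perc"] <- comp["perc"] + perceptual_loss(out, p$gt, lcfg)
        gout <- gout + lcfg$w_perc * perceptual_loss_grad(out, p$gt, lcfg)
      }
      if (adv_on) {
        ff <- disc_forward_sample(out, config$discriminator, dparams, TRUE)
        comp["adv"] <- comp["adv"] + adversarial_gen_loss(ff$p)
        gp <- -1 / pmax(ff$p, LOG_CLAMP_EPS)
        bd <- disc_backward_sample(gp, config$discriminator, dparams, ff$cache)
        gout <- gout + lcfg$w_adv * bd$gx
      }
      bw <- gen_backward_sample(gout, gcfg, params, fw$cache)
      ggrads_tot <- if (is.null(ggrads_tot)) bw$grads else
        Map(`+`, ggrads_tot, bw$grads[names(ggrads_tot)])
    }
    comp <- comp / length(batch)
    gen_total <- lcfg$w_mse * comp["mse"] + lcfg$w_perc * comp["perc"] +
      lcfg$w_adv * comp["adv"]
    if (!is.finite(gen_total))
      stop(sprintf("generator loss diverged (non-finite) at step %d", step))
    upd <- adam_step(params, ggrads_tot[names(params)], gstate,
                     config$lr, config$beta1, config$beta2)
    params <- upd$params; gstate <- upd$state

    if (step %% config$eval_every == 0L || step == config$steps) {
      vm <- val_mse()
      history[[length(history) + 1L]] <-
        data.frame(step = step, loss_mse = comp[["mse"]],
                   loss_perc = comp[["perc"]], loss_adv = comp[["adv"]],
                   loss_total = as.numeric(gen_total), val_mse = vm)
      if (vm < best - config$min_delta) {
        best <- vm; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) { stopped_at <- step; break }
      }
      stopped_at <- step
    }
  }

  history <- if (length(history)) do.call(rbind, history) else
    data.frame(step = integer(), loss_mse = numeric(), loss_perc = numeric(),
               loss_adv = numeric(), loss_total = numeric(), val_mse = numeric())
  structure(list(params = params, disc_params = dparams, config = config,
                 history = history, val_ids = val_ids, train_ids = train_ids,
                 steps_run = if (config$steps == 0L) 0L else stopped_at),
            class = "ctsr_fit")
}

#' @export
print.ctsr_fit <- function(x, ...) {
  g <- x$config$generator
  cat(sprintf("ctsr_fit: 3D slice-generation model (x%d depth)\n", g$r))
  cat(sprintf("  generator: %d RRDBs, %d base / %d growth channels, beta = %g (%s parameters)\n",
              g$n_rrdb, g$base_channels, g$growth_channels, g$beta,
              format(n_params(x$params), big.mark = ",")))
  cat(sprintf("  trained %d steps on %d volume(s), %d held out\n",
              x$steps_run, length(x$train_ids), length(x$val_ids)))
  if (nrow(x$history))
    cat(sprintf("  final validation MSE: %.3g\n",
                x$history$val_mse[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.ctsr_fit <- function(object, ...) {
  print(object)
  if (nrow(object$history)) {
    cat("\nloss history (last 5 evaluations):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.ctsr_fit <- function(object, ...) {
  unlist(object$params, use.names = TRUE)
}

#' @export
plot.ctsr_fit <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) { warning("no history to plot"); return(invisible(x)) }
  graphics::matplot(h$step, cbind(h$loss_total, h$val_mse), type = "l",
                    lty = 1, col = c("black", "red3"),
                    xlab = "step", ylab = "loss", log = "y", ...)
  graphics::legend("topright", c("training total", "validation MSE"),
                   lty = 1, col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Super-resolve a volume with a fitted model
#'
#' Runs the full inference pipeline on a thick-slice volume: normalize to
#' \[0, 1\], chunk along the stack axis per the training chunk plan, run the
#' generator on each chunk, stitch with cross-fade blending, and de-normalize.
#' The output has `r` times the input depth and the stack spacing divided by
#' `r`.
#'
#' @param object a `ctsr_fit`.
#' @param newdata a thick-slice [ct_volume()].
#' @param ... unused.
#' @return a [ct_volume()] with provenance `"generated"`.
#' @export
predict.ctsr_fit <- function(object, newdata, ...) {
  stopifnot_volume(newdata)
  cfg <- object$config
  nv <- ct_volume(hu_normalize(newdata$voxels), newdata$spacing_mm,
                  newdata$orientation)
  chunks <- chunk_volume(nv, cfg$plan)
  up <- lapply(chunks, function(ch) {
    out <- gen_forward_sample(as_sample_array(ch$voxels), cfg$generator,
                              object$params)$out
    oc <- ct_volume(array(out, dim(out)[1:3]), ch$spacing_mm * c(1, 1, 1 / cfg$r),
                    ch$orientation)
    attr(oc, "start") <- attr(ch, "start")
    oc
  })
  st <- stitch_chunks(up, cfg$plan, cfg$r, dim(newdata$voxels)[3])
  ct_volume(hu_denormalize(st$voxels), newdata$spacing_mm * c(1, 1, 1 / cfg$r),
            newdata$orientation, provenance = "generated")
}

#' Save / load a fitted model
#'
#' Checkpoints are written in R's standard serialized format with the full
#' config embedded, so a reloaded model restores bit-compatible inference.
#'
#' @param object a `ctsr_fit`.
#' @param path file path.
#' @return `load_ctsr` returns the `ctsr_fit`.
#' @export
save_ctsr <- function(object, path) {
  if (!inherits(object, "ctsr_fit")) stop("expected a 'ctsr_fit'")
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_ctsr
#' @export
load_ctsr <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "ctsr_fit")) stop("file does not contain a 'ctsr_fit'")
  obj
}

#' Image-quality metrics for a super-resolved volume
#'
#' MSE on the normalized \[0, 1\] intensity scale, PSNR as
#' `10 * log10(range^2 / MSE)` over that unit range (`Inf` for identical
#' volumes, the documented sentinel), and mean SSIM computed slice-wise along
#' the stack axis with a uniform 7x7 window on valid (unpadded) pixels and
#' the standard constants `K1 = 0.01`, `K2 = 0.03`.
#'
#' @param gen_vol,gt_vol [ct_volume()]s of identical shape and spacing.
#' @return list with elements `mse`, `psnr`, `ssim`.
#' @export
evaluate_sr <- function(gen_vol, gt_vol) {
  stopifnot_volume(gen_vol); stopifnot_volume(gt_vol)
  if (!all(dim(gen_vol$voxels) == dim(gt_vol$voxels)))
    stop("shape mismatch")
  if (!isTRUE(all.equal(gen_vol$spacing_mm, gt_vol$spacing_mm)))
    stop("spacing mismatch")
  a <- hu_normalize(gen_vol$voxels)
  b <- hu_normalize(gt_vol$voxels)
  mse <- mean((a - b)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(1 / mse)
  list(mse = mse, psnr = psnr, ssim = ssim_volume(a, b))
}

ssim_volume <- function(a, b, win = 7L, K1 = 0.01, K2 = 0.03) {
  d <- dim(a)
  if (any(d[1:2] < win)) stop("in-plane extent smaller than the SSIM window")
  kern <- array(1 / (win * win), c(win, win, 1L, 1L, 1L))
  filt <- function(x) {
    dim(x) <- c(d, 1L)
    y <- conv3d_forward_cpp(x, dim(x), kern, dim(kern), 0,
                            c(1L, 1L, 1L), c(0L, 0L, 0L))
    array(y, dim(y)[1:3])
  }
  mu_a <- filt(a); mu_b <- filt(b)
  va <- filt(a * a) - mu_a^2
  vb <- filt(b * b) - mu_b^2
  vab <- filt(a * b) - mu_a * mu_b
  C1 <- K1^2; C2 <- K2^2
  s <- ((2 * mu_a * mu_b + C1) * (2 * vab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}
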