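#' Nodule specification for the synthetic chest phantom
#'
#' Describes one ellipsoidal nodule by its center and semi-axes in mm (world
#' coordinates are mm from the center of the volume's first voxel, all axes
#' 0-based) and its Hounsfield composition. A nodule with only `core_hu` is
#' homogeneous (solid when `core_hu` is above the -450 HU typing threshold,
#' ground-glass when at or below it). Supplying `shell_hu` builds a part-solid
#' nodule: a concentric solid core (`core_radii_mm`, default 60% of
#' `radii_mm`) surrounded by a ground-glass shell, which guarantees the
#' mixed-attenuation condition by construction.
#'
#' @param center_mm numeric length-3 center in mm.
#' @param radii_mm numeric length-3 ellipsoid semi-axes in mm (> 0).
#' @param core_hu HU of the interior (or of the core when `shell_hu` is given).
#' @param shell_hu optional HU of the outer shell; must be <= -450 with
#'   `core_hu` > -450.
#' @param core_radii_mm optional semi-axes of the solid core of a part-solid
#'   nodule.
#' @param intended_type optional; one of `"solid"`, `"GGN"`, `"subsolid"`.
#'   Derived from the HU fields when omitted; validated against them when given.
#' @return an object of class `nodule_spec`.
#' @export
nodule_spec <- function(center_mm, radii_mm, core_hu, shell_hu = NULL,
                        core_radii_mm = NULL, intended_type = NULL) {
  center_mm <- as.numeric(center_mm); radii_mm <- as.numeric(radii_mm)
  if (length(center_mm) != 3L || length(radii_mm) != 3L)
    stop("'center_mm' and 'radii_mm' must have length 3")
  if (any(!is.finite(radii_mm)) || any(radii_mm <= 0))
    stop("'radii_mm' must all be > 0")
  thr <- -450
  if (is.null(shell_hu)) {
    derived <- if (core_hu > thr) "solid" else "GGN"
    core_radii_mm <- radii_mm
  } else {
    if (core_hu <= thr || shell_hu > thr)
      stop("part-solid nodule needs core_hu > -450 and shell_hu <= -450")
    if (is.null(core_radii_mm)) core_radii_mm <- 0.6 * radii_mm
    core_radii_mm <- as.numeric(core_radii_mm)
    if (any(core_radii_mm <= 0) || any(core_radii_mm >= radii_mm))
      stop("'core_radii_mm' must be positive and strictly inside 'radii_mm'")
    derived <- "subsolid"
  }
  if (is.null(intended_type)) intended_type <- derived
  intended_type <- match.arg(intended_type, c("solid", "GGN", "subsolid"))
  if (!identical(intended_type, derived))
    stop(sprintf("intended_type '%s' inconsistent with HU fields (derived '%s')",
                 intended_type, derived))
  structure(list(center_mm = center_mm, radii_mm = radii_mm, core_hu = core_hu,
                 shell_hu = shell_hu, core_radii_mm = core_radii_mm,
                 intended_type = intended_type),
            class = "nodule_spec")
}

#' Analytic ellipsoid nodule volume
#'
#' Ground truth for volumetry tests: the exact ellipsoid volume
#' `4/3 * pi * a * b * c` in mm^3.
#'
#' @param spec a [nodule_spec()] (or a length-3 vector of semi-axes in mm).
#' @return volume in mm^3.
#' @export
analytic_nodule_volume <- function(spec) {
  radii <- if (inherits(spec, "nodule_spec")) spec$radii_mm else as.numeric(spec)
  if (length(radii) != 3L || any(!is.finite(radii)) || any(radii <= 0))
    stop("need 3 positive semi-axes")
  4 / 3 * pi * prod(radii)
}

#' Phantom specification
#'
#' Parameters of a seeded synthetic thin-slice chest-CT-like volume: low-HU
#' parenchyma background (a smooth random field), bright vessel-like tubes
#' running along the stack axis, embedded ellipsoidal nodules, and additive
#' Gaussian HU noise applied before any degradation so that threshold-based
#' nodule typing is exercised under noise.
#'
#' @param grid_shape integer length-3 voxels per axis (all >= 8).
#' @param spacing_mm voxel size in mm per axis (default 0.7 x 0.7 x 1.0, the
#'   thin-slice acquisition geometry being emulated).
#' @param background_mean_hu,background_sd_hu parenchyma HU field parameters
#'   (defaults -850 and 20).
#' @param vessel_count number of vessel-like tubes (default 3).
#' @param vessel_hu tube attenuation (default 30, blood-like).
#' @param nodule_specs list of [nodule_spec()] objects.
#' @param noise_sd additive voxel noise SD in HU (>= 0; default 10, small
#'   against the 400 HU margin between the default nodule attenuations and the
#'   -450 typing threshold).
#' @param seed RNG seed; identical spec + seed gives bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, spacing_mm = c(0.7, 0.7, 1.0),
                         background_mean_hu = -850, background_sd_hu = 20,
                         vessel_count = 3L, vessel_hu = 30,
                         nodule_specs = list(), noise_sd = 10, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("'grid_shape' must be 3 integers, all >= 8")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 positive numbers")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (background_sd_hu < 0) stop("'background_sd_hu' must be >= 0")
  if (!all(vapply(nodule_specs, inherits, logical(1), "nodule_spec")))
    stop("'nodule_specs' must be a list of nodule_spec objects")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 background_mean_hu = background_mean_hu,
                 background_sd_hu = background_sd_hu,
                 vessel_count = as.integer(vessel_count), vessel_hu = vessel_hu,
                 nodule_specs = nodule_specs, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Binary nodule mask on a volume grid
#'
#' @param mask logical 3D array, same shape as the parent volume.
#' @param volume_ref identifier of the parent volume.
#' @return an object of class `nodule_mask`.
#' @export
nodule_mask <- function(mask, volume_ref = "") {
  if (!is.array(mask) || length(dim(mask)) != 3L) stop("'mask' must be a 3D array")
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, volume_ref = as.character(volume_ref)),
            class = "nodule_mask")
}

# logical array: voxel centers inside (<= 1) the ellipsoid
ellipsoid_mask <- function(grid_shape, spacing_mm, center_mm, radii_mm) {
  ax <- lapply(1:3, function(i) ((seq_len(grid_shape[i]) - 1) * spacing_mm[i] -
                                   center_mm[i]) / radii_mm[i])
  q <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  array(q <= 1, grid_shape)
}

# smooth Gaussian random field: coarse grid linearly interpolated to full size
smooth_field <- function(grid_shape, sd, coarse = 8L) {
  nc <- pmax(2L, ceiling(grid_shape / coarse) + 1L)
  f <- array(stats::rnorm(prod(nc), 0, sd), nc)
  for (axis in 1:3) {
    dn <- dim(f)
    xin <- seq(0, 1, length.out = dn[axis])
    xout <- seq(0, 1, length.out = grid_shape[axis])
    f <- apply(f, setdiff(1:3, axis), function(v)
      stats::approx(xin, v, xout)$y)
    # apply returns axis-first; rotate back into place
    f <- aperm(array(f, c(grid_shape[axis], dn[setdiff(1:3, axis)])),
               order(c(axis, setdiff(1:3, axis))))
  }
  f
}

#' Generate a seeded synthetic thin-slice chest phantom
#'
#' Builds the HU volume described by a [phantom_spec()]: smooth parenchyma
#' background, vessel-like tubes along the stack axis (carved around nodules
#' so nodule composition stays as specified), nodules painted per their specs,
#' then additive Gaussian noise. Mask membership is voxel-center-inside-
#' ellipsoid, matching a binary manual segmentation.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `volume` (a [ct_volume()]) and `masks` (one
#'   [nodule_mask()] per nodule spec, in order).
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("expected a 'phantom_spec'")
  gs <- spec$grid_shape; sp <- spec$spacing_mm
  extent <- (gs - 1) * sp
  for (i in seq_along(spec$nodule_specs)) {
    ns <- spec$nodule_specs[[i]]
    if (any(ns$center_mm - ns$radii_mm < 0) ||
        any(ns$center_mm + ns$radii_mm > extent))
      stop(sprintf("nodule %d extends outside the grid", i))
  }
  masks <- lapply(spec$nodule_specs, function(ns)
    ellipsoid_mask(gs, sp, ns$center_mm, ns$radii_mm))
  if (length(masks) > 1) {
    for (i in seq_len(length(masks) - 1)) for (j in seq((i + 1), length(masks)))
      if (any(masks[[i]] & masks[[j]]))
        stop(sprintf("nodules %d and %d overlap", i, j))
  }

  rng_state <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(rng_state)) assign(".Random.seed", rng_state, .GlobalEnv))
  set.seed(spec$seed)

  vox <- array(spec$background_mean_hu, gs)
  if (spec$background_sd_hu > 0)
    vox <- vox + smooth_field(gs, spec$background_sd_hu)

  # vessel-like tubes: tilted lines along the stack axis
  in_any_nodule <- Reduce(`|`, masks, array(FALSE, gs))
  if (spec$vessel_count > 0) {
    xs <- (seq_len(gs[1]) - 1) * sp[1]
    ys <- (seq_len(gs[2]) - 1) * sp[2]
    for (v in seq_len(spec$vessel_count)) {
      # keep tubes clear of every nodule (plus margin): a manual segmentation
      # would exclude crossing vessels, so the phantom does not create them
      radius <- stats::runif(1, 0.8, 1.5)
      for (try in 1:50) {
        x0 <- stats::runif(1, 0.1, 0.9) * extent[1]
        y0 <- stats::runif(1, 0.1, 0.9) * extent[2]
        slope <- stats::runif(2, -0.05, 0.05)  # mm drift per mm of depth
        clear <- all(vapply(spec$nodule_specs, function(ns) {
          zr <- seq(max(0, ns$center_mm[3] - ns$radii_mm[3] - 2),
                    min(extent[3], ns$center_mm[3] + ns$radii_mm[3] + 2),
                    length.out = 9)
          dmin <- min(sqrt((x0 + slope[1] * zr - ns$center_mm[1])^2 +
                             (y0 + slope[2] * zr - ns$center_mm[2])^2))
          dmin > max(ns$radii_mm[1:2]) + radius + 2.5
        }, logical(1)))
        if (clear) break
      }
      for (k in seq_len(gs[3])) {
        z <- (k - 1) * sp[3]
        d2 <- outer((xs - (x0 + slope[1] * z))^2, (ys - (y0 + slope[2] * z))^2, "+")
        tube <- d2 <= radius^2 & !in_any_nodule[, , k]
        sl <- vox[, , k]; sl[tube] <- spec$vessel_hu; vox[, , k] <- sl
      }
    }
  }

  for (i in seq_along(spec$nodule_specs)) {
    ns <- spec$nodule_specs[[i]]
    vox[masks[[i]]] <- if (is.null(ns$shell_hu)) ns$core_hu else ns$shell_hu
    if (!is.null(ns$shell_hu)) {
      core <- ellipsoid_mask(gs, sp, ns$center_mm, ns$core_radii_mm)
      vox[core] <- ns$core_hu
    }
  }

  if (spec$noise_sd > 0)
    vox <- vox + array(stats::rnorm(prod(gs), 0, spec$noise_sd), gs)

  vol <- ct_volume(vox, sp, "axial-stack", provenance = "phantom")
  list(volume = vol,
       masks = lapply(seq_along(masks), function(i)
         nodule_mask(masks[[i]], volume_ref = sprintf("phantom-seed%d", spec$seed))))
}

#' A standard set of phantom volumes for desk-scale experiments
#'
#' Generates `n_volumes` thin-slice phantoms (1.0 mm stack spacing), each with
#' a solid, a ground-glass and a part-solid nodule of varying size, suitable
#' as a self-contained stand-in for a thin-slice training/evaluation corpus.
#'
#' @param n_volumes number of phantoms (default 4).
#' @param seed base seed; phantom `i` uses `seed + i - 1`.
#' @param grid_shape per-volume grid (default `c(24, 24, 64)`).
#' @param spacing_mm voxel spacing (default `c(0.7, 0.7, 1.0)`).
#' @return list of `list(volume, masks, specs)` entries.
#' @export
phantom_study_set <- function(n_volumes = 4L, seed = 1L,
                              grid_shape = c(24L, 24L, 64L),
                              spacing_mm = c(0.7, 0.7, 1.0)) {
  extent <- (grid_shape - 1) * spacing_mm
  lapply(seq_len(n_volumes), function(i) {
    s <- seed + i - 1L
    zs <- extent[3] * c(0.2, 0.5, 0.8)
    ctr <- extent[1:2] / 2
    rad <- 2.0 + 0.4 * ((i - 1) %% 3)
    specs <- list(
      nodule_spec(c(ctr * 0.6, zs[1]), rep(rad, 3), core_hu = -100),
      nodule_spec(c(ctr * 1.4, zs[2]), rep(rad + 0.3, 3), core_hu = -700),
      nodule_spec(c(ctr, zs[3]), rep(rad + 0.6, 3), core_hu = -100,
                  shell_hu = -700)
    )
    ph <- make_phantom(phantom_spec(grid_shape, spacing_mm,
                                    nodule_specs = specs, seed = s))
    ph$specs <- specs
    ph
  })
}
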