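#' CT volume container
#'
#' A `ct_volume` carries a 3D array of Hounsfield units together with the
#' voxel spacing in mm per axis and an orientation tag naming which anatomical
#' stacking the third array axis represents. The third axis is always the
#' stack ("depth") axis: the axis along which slices are counted, degraded and
#' super-resolved. [reslice()] moves a different anatomical axis into that
#' position by a lossless transpose.
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing_mm numeric length-3, voxel size in mm per array axis (all > 0).
#' @param orientation `"axial-stack"` or `"coronal-stack"`: which anatomical
#'   plane the in-plane axes span, equivalently which anatomical direction is
#'   stacked along axis 3.
#' @param provenance free-text label recording where the volume came from
#'   (e.g. `"phantom"`, `"thick"`, `"generated"`).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing_mm, orientation = "axial-stack",
                      provenance = "") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 positive finite numbers")
  orientation <- match.arg(orientation, c("axial-stack", "coronal-stack"))
  if (any(!is.finite(voxels))) stop("voxel values must be finite HU")
  structure(list(voxels = voxels, spacing_mm = spacing_mm,
                 orientation = orientation, provenance = as.character(provenance)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d x %d x %d voxels (%s)\n", d[1], d[2], d[3], x$orientation))
  cat(sprintf("  spacing: %.3g x %.3g x %.3g mm\n",
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  HU range: [%.1f, %.1f]", min(x$voxels), max(x$voxels)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance)
  cat("\n")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

is_ct_volume <- function(x) inherits(x, "ct_volume")

stopifnot_volume <- function(vol) {
  if (!is_ct_volume(vol)) stop("expected a 'ct_volume' object")
  invisible(vol)
}

# Fixed display/normalization window covering lung parenchyma through soft
# tissue; the network operates on intensities mapped from this window to [0,1].
HU_WINDOW <- c(-1024, 600)

#' Map HU to the network's normalized [0,1] intensity scale
#'
#' Intensities are clamped to a fixed window (-1024 to 600 HU) and rescaled to
#' \[0, 1\]. The same window is used for de-normalization and for PSNR's
#' intensity range.
#'
#' @param hu numeric array of HU values.
#' @return array of the same shape on \[0, 1\].
#' @export
hu_normalize <- function(hu) {
  pmin(pmax((hu - HU_WINDOW[1]) / diff(HU_WINDOW), 0), 1)
}

#' @rdname hu_normalize
#' @param x numeric array on \[0, 1\].
#' @export
hu_denormalize <- function(x) {
  x * diff(HU_WINDOW) + HU_WINDOW[1]
}
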