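#' Simulate thick-slice CT by consecutive-slice averaging
#'
#' Degrades a thin-slice volume along the stack axis by replacing every `r`
#' consecutive slices with their arithmetic mean, the standard self-supervised
#' degradation for slice-thickness super-resolution: a 300-slice 1.0 mm series
#' with `r = 4` becomes a 75-slice 4.0 mm series.
#'
#' @param vol a [ct_volume()].
#' @param r integer averaging factor (>= 2).
#' @param remainder what to do when the depth is not divisible by `r`:
#'   `"trim"` (default) drops the trailing remainder slices, `"error"` aborts.
#' @return a `ct_volume` with depth `floor(depth / r)` and stack spacing
#'   multiplied by `r`; in-plane axes untouched.
#' @export
simulate_thick <- function(vol, r, remainder = c("trim", "error")) {
  stopifnot_volume(vol)
  remainder <- match.arg(remainder)
  r <- as.integer(r)
  if (is.na(r) || r < 2L) stop("'r' must be an integer >= 2")
  d <- dim(vol$voxels)
  if (d[3] %% r != 0L) {
    if (remainder == "error")
      stop(sprintf("depth %d is not divisible by r = %d", d[3], r))
    keep <- (d[3] %/% r) * r
    if (keep == 0L) stop("volume thinner than one averaging group")
    vol$voxels <- vol$voxels[, , seq_len(keep), drop = FALSE]
    d <- dim(vol$voxels)
  }
  dn <- d[3] %/% r
  # group-mean along axis 3: reshape (H, W, r, dn) and average axis 3
  v <- vol$voxels
  dim(v) <- c(d[1], d[2], r, dn)
  out <- colMeans(aperm(v, c(3, 1, 2, 4)))
  dim(out) <- c(d[1], d[2], dn)
  ct_volume(out, vol$spacing_mm * c(1, 1, r), vol$orientation,
            provenance = "thick")
}

#' Reslice a volume between axial and coronal stacking
#'
#' A lossless axis transpose: the requested anatomical axis becomes the stack
#' (third) axis and the spacing vector is permuted accordingly. Reslicing back
#' to the source orientation restores the voxel array bit-exactly.
#'
#' @param vol a [ct_volume()].
#' @param target_orientation `"axial-stack"` or `"coronal-stack"`.
#' @return a `ct_volume` in the target orientation.
#' @export
reslice <- function(vol, target_orientation) {
  stopifnot_volume(vol)
  target_orientation <- match.arg(target_orientation,
                                  c("axial-stack", "coronal-stack"))
  if (identical(vol$orientation, target_orientation)) return(vol)
  # axial (x, y, z) <-> coronal (x, z, y): swap axes 2 and 3 (an involution)
  perm <- c(1L, 3L, 2L)
  ct_volume(aperm(vol$voxels, perm), vol$spacing_mm[perm], target_orientation,
            provenance = vol$provenance)
}

#' Chunking plan for segment-wise processing
#'
#' The network processes fixed-length segments along the stack axis (16 slices
#' at thick-slice resolution). Consecutive segments may overlap; overlapping
#' super-resolved output is blended by a linear cross-fade; `overlap = 0`
#' recovers plain disjoint-segment processing.
#'
#' @param chunk_len slices per segment (>= 2; default 16).
#' @param overlap slices shared by consecutive segments (0 <= overlap < chunk_len).
#' @param pad_mode tail policy; only `"edge"` (replicate the last slice) is
#'   provided.
#' @return an object of class `chunk_plan`.
#' @export
chunk_plan <- function(chunk_len = 16L, overlap = 2L, pad_mode = "edge") {
  chunk_len <- as.integer(chunk_len); overlap <- as.integer(overlap)
  if (chunk_len < 2L) stop("'chunk_len' must be >= 2")
  if (overlap < 0L || overlap >= chunk_len) stop("need 0 <= overlap < chunk_len")
  pad_mode <- match.arg(pad_mode, "edge")
  structure(list(chunk_len = chunk_len, overlap = overlap, pad_mode = pad_mode),
            class = "chunk_plan")
}

# 0-based chunk start indices covering depth d under a plan: step by
# chunk_len - overlap until the last chunk reaches the final slice; the last
# chunk may extend past the end and is edge-padded.
chunk_starts <- function(d, plan) {
  step <- plan$chunk_len - plan$overlap
  starts <- 0L
  while (starts[length(starts)] + plan$chunk_len < d)
    starts <- c(starts, starts[length(starts)] + step)
  starts
}

#' Split a volume into fixed-length stack-axis segments
#'
#' @param vol a [ct_volume()].
#' @param plan a [chunk_plan()].
#' @return a list of `ct_volume` chunks, each carrying attributes
#'   `start` (0-based source slice of its first slice) and `n_pad`
#'   (replicated tail slices). The union of source ranges covers every slice.
#' @export
chunk_volume <- function(vol, plan = chunk_plan()) {
  stopifnot_volume(vol)
  d <- dim(vol$voxels)[3]
  starts <- chunk_starts(d, plan)
  lapply(starts, function(s) {
    idx <- s + seq_len(plan$chunk_len)     # 1-based source slices
    n_pad <- sum(idx > d)
    idx[idx > d] <- d                      # edge replication
    ch <- ct_volume(vol$voxels[, , idx, drop = FALSE], vol$spacing_mm,
                    vol$orientation, provenance = vol$provenance)
    attr(ch, "start") <- s
    attr(ch, "n_pad") <- n_pad
    ch
  })
}

# trapezoidal cross-fade weight profile over the chunk_len source slices
fade_profile <- function(chunk_len, overlap) {
  j <- seq_len(chunk_len)
  pmin(1, j / (overlap + 1), (chunk_len - j + 1) / (overlap + 1))
}

#' Reassemble super-resolved chunks into a full volume
#'
#' Inverse of [chunk_volume()] after each chunk has been upsampled by `r`
#' along the stack axis. Overlapping slices are blended with linear cross-fade
#' weights (normalized to sum to one per slice); slices that were edge-padding
#' are discarded.
#'
#' @param chunks list of upsampled chunks (each of depth `chunk_len * r`),
#'   with the `start` attributes produced by [chunk_volume()].
#' @param plan the [chunk_plan()] used to create them.
#' @param r the upsampling factor applied to each chunk.
#' @param original_depth stack depth of the volume that was chunked.
#' @return a `ct_volume` of depth `original_depth * r`.
#' @export
stitch_chunks <- function(chunks, plan, r, original_depth) {
  r <- as.integer(r)
  if (length(chunks) == 0L) stop("no chunks to stitch")
  starts <- chunk_starts(original_depth, plan)
  if (length(chunks) != length(starts))
    stop(sprintf("expected %d chunks for depth %d under this plan, got %d",
                 length(starts), original_depth, length(chunks)))
  d1 <- dim(chunks[[1]]$voxels)
  if (d1[3] != plan$chunk_len * r)
    stop(sprintf("chunk depth %d != chunk_len * r = %d", d1[3], plan$chunk_len * r))
  Dout <- original_depth * r
  num <- array(0, c(d1[1], d1[2], Dout))
  den <- numeric(Dout)
  wsrc <- fade_profile(plan$chunk_len, plan$overlap)
  for (i in seq_along(chunks)) {
    ch <- chunks[[i]]
    if (!all(dim(ch$voxels) == d1)) stop("chunk shapes differ")
    s <- starts[i]
    for (j in seq_len(plan$chunk_len)) {
      src <- s + j                         # 1-based source slice
      if (src > original_depth) next       # padded tail: discard
      out_idx <- (src - 1L) * r + seq_len(r)
      in_idx <- (j - 1L) * r + seq_len(r)
      num[, , out_idx] <- num[, , out_idx] + wsrc[j] * ch$voxels[, , in_idx]
      den[out_idx] <- den[out_idx] + wsrc[j]
    }
  }
  if (any(den == 0)) stop("stitching left uncovered slices")
  num <- sweep(num, 3, den, "/")
  ref <- chunks[[1]]          # chunks are already upsampled: spacing is final
  ct_volume(num, ref$spacing_mm, ref$orientation, provenance = "generated")
}

#' Linear-interpolation baseline upsampler
#'
#' The classical non-learned baseline: the stack axis is upsampled `r`-fold by
#' linear interpolation between slice centers, with output slice `k` (0-based)
#' mapped to source coordinate `k / r` and edge replication past the last
#' slice. In-plane axes are untouched, so on an already-thin in-plane grid
#' this is the trilinear resampling a viewer would apply.
#'
#' @param vol a [ct_volume()].
#' @param r integer upsampling factor (>= 1); `r = 1` is the identity.
#' @return a `ct_volume` with depth `depth * r` and stack spacing divided by `r`.
#' @export
trilinear_upsample <- function(vol, r) {
  stopifnot_volume(vol)
  r <- as.integer(r)
  if (is.na(r) || r < 1L) stop("'r' must be an integer >= 1")
  if (r == 1L) return(vol)
  d <- dim(vol$voxels)
  coord <- (seq_len(d[3] * r) - 1) / r     # source coordinate of each output slice
  lo <- pmin(floor(coord), d[3] - 1)
  frac <- coord - lo
  lo <- lo + 1                             # 1-based lower slice
  hi <- pmin(lo + 1, d[3])
  out <- array(0, c(d[1], d[2], d[3] * r))
  for (k in seq_along(coord)) {
    out[, , k] <- (1 - frac[k]) * vol$voxels[, , lo[k]] + frac[k] * vol$voxels[, , hi[k]]
  }
  ct_volume(out, vol$spacing_mm * c(1, 1, 1 / r), vol$orientation,
            provenance = "trilinear")
}
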