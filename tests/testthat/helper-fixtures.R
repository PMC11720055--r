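# Shared fixtures: everything is generated in code at test time.

# naive direct-summation 3D convolution, the oracle for the compiled kernel
naive_conv3 <- function(x, w, b, s = c(1, 1, 1), p = c(1, 1, 1)) {
  xd <- dim(x); wd <- dim(w)
  Ho <- (xd[1] + 2 * p[1] - wd[1]) %/% s[1] + 1
  Wo <- (xd[2] + 2 * p[2] - wd[2]) %/% s[2] + 1
  Do <- (xd[3] + 2 * p[3] - wd[3]) %/% s[3] + 1
  y <- array(0, c(Ho, Wo, Do, wd[5]))
  for (co in seq_len(wd[5])) for (d in seq_len(Do)) for (ww in seq_len(Wo))
    for (h in seq_len(Ho)) {
      acc <- b[co]
      for (ci in seq_len(xd[4])) for (kd in seq_len(wd[3]))
        for (kw in seq_len(wd[2])) for (kh in seq_len(wd[1])) {
          hh <- (h - 1) * s[1] - p[1] + kh
          w2 <- (ww - 1) * s[2] - p[2] + kw
          dd <- (d - 1) * s[3] - p[3] + kd
          if (hh >= 1 && hh <= xd[1] && w2 >= 1 && w2 <= xd[2] &&
              dd >= 1 && dd <= xd[3])
            acc <- acc + x[hh, w2, dd, ci] * w[kh, kw, kd, ci, co]
        }
      y[h, ww, d, co] <- acc
    }
  y
}

# a small single-nodule phantom centered in the grid
centered_sphere_phantom <- function(radius_mm = 3, spacing = 0.5, n = 24,
                                    core_hu = -100, seed = 7, noise_sd = 10) {
  gs <- rep(n, 3); sp <- rep(spacing, 3)
  ctr <- (gs - 1) * sp / 2
  ns <- nodule_spec(ctr, rep(radius_mm, 3), core_hu = core_hu)
  list(spec = ns,
       phantom = make_phantom(phantom_spec(gs, sp, nodule_specs = list(ns),
                                           seed = seed, noise_sd = noise_sd)))
}

# segmentation window used when re-measuring phantom nodules on any source
phantom_roi_window <- function(intended_type) {
  switch(intended_type,
         GGN = c(-775, -450),
         subsolid = c(-775, Inf),
         c(-600, Inf))
}

# ---- minimal DICOM writer (explicit VR little endian) for reader tests ----

dcm_raw_uint <- function(x, bytes) {
  writeBin(as.integer(x), raw(), size = bytes, endian = "little")
}

dcm_element <- function(group, elem, vr, value) {
  if (is.character(value)) value <- charToRaw(value)
  if (length(value) %% 2L == 1L)
    value <- c(value, if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" "))
  hdr <- c(dcm_raw_uint(group, 2), dcm_raw_uint(elem, 2), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, as.raw(c(0, 0)), dcm_raw_uint(length(value), 4), value)
  } else {
    c(hdr, dcm_raw_uint(length(value), 2), value)
  }
}

write_test_dicom_slice <- function(path, pixels, z, series_uid = "1.2.3.4",
                                   spacing = c(0.7, 0.6), slope = 1,
                                   intercept = -1024) {
  rows <- nrow(pixels); cols <- ncol(pixels)
  # PixelData row-major: first image row left to right; pixels[i, j] is
  # row i, column j of the image
  px <- writeBin(as.integer(t(pixels)), raw(), size = 2, endian = "little")
  body <- c(
    dcm_element(0x0008, 0x0018, "UI", paste0(series_uid, ".", z)),
    dcm_element(0x0020, 0x000E, "UI", series_uid),
    dcm_element(0x0020, 0x0032, "DS", sprintf("0\\0\\%g", z)),
    dcm_element(0x0028, 0x0010, "US", dcm_raw_uint(rows, 2)),
    dcm_element(0x0028, 0x0011, "US", dcm_raw_uint(cols, 2)),
    dcm_element(0x0028, 0x0030, "DS", sprintf("%g\\%g", spacing[1], spacing[2])),
    dcm_element(0x0028, 0x0100, "US", dcm_raw_uint(16, 2)),
    dcm_element(0x0028, 0x0103, "US", dcm_raw_uint(1, 2)),
    dcm_element(0x0028, 0x1052, "DS", sprintf("%g", intercept)),
    dcm_element(0x0028, 0x1053, "DS", sprintf("%g", slope)),
    dcm_element(0x7FE0, 0x0010, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
}
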