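#' Read a CT volume
#'
#' Reads a NIfTI file (voxel spacing from the header) or a directory holding
#' one DICOM series of single-frame slices (slices sorted by position along
#' the normal, rescale slope/intercept applied to obtain HU). The DICOM path
#' supports uncompressed explicit-VR little-endian files only.
#'
#' @param path a NIfTI file or a directory of DICOM slices.
#' @param orientation orientation tag to attach (default `"axial-stack"`).
#' @return a [ct_volume()].
#' @export
read_volume <- function(path, orientation = "axial-stack") {
  if (dir.exists(path)) return(read_dicom_series(path, orientation))
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  pd <- RNifti::pixdim(img)
  vox <- as.array(img)
  attributes(vox) <- list(dim = dim(vox))   # strip image-header attributes
  d <- dim(vox)
  if (length(d) == 4L && d[4] == 1L) { vox <- vox[, , , 1]; d <- dim(vox) }
  if (length(d) != 3L) stop("expected a 3D volume, got ", length(d), " axes")
  if (length(pd) < 3L || any(pd[1:3] <= 0))
    stop("volume is missing positive voxel spacing in its header")
  ct_volume(vox, pd[1:3], orientation, provenance = path)
}

#' Write a CT volume as NIfTI
#'
#' Spacing is encoded in the header. `datatype = "float"` (32-bit) round-trips
#' HU losslessly at single precision; `datatype = "int16"` stores rounded HU
#' (maximum absolute round-trip error 0.5 HU).
#'
#' @param vol a [ct_volume()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @param datatype `"float"` or `"int16"`.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, datatype = c("float", "int16")) {
  stopifnot_volume(vol)
  datatype <- match.arg(datatype)
  vox <- vol$voxels
  if (datatype == "int16") vox <- round(vox)
  attr(vox, "pixdim") <- vol$spacing_mm
  img <- RNifti::asNifti(vox, datatype = datatype)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

## ---- minimal DICOM series reader (explicit VR little endian) ----

dcm_uint <- function(raw) sum(as.integer(raw) * 256^(seq_along(raw) - 1))

# parse one file's needed elements; returns a list of tag values
parse_dicom_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", 132L)
  if (length(preamble) < 132L || rawToChar(preamble[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  out <- list()
  repeat {
    hdr <- readBin(con, "raw", 8L)
    if (length(hdr) < 8L) break
    group <- dcm_uint(hdr[1:2]); elem <- dcm_uint(hdr[3:4])
    vr <- rawToChar(hdr[5:6])
    if (vr %in% long_vrs) {
      len <- dcm_uint(readBin(con, "raw", 4L))
    } else {
      len <- dcm_uint(hdr[7:8])
    }
    tag <- sprintf("%04x,%04x", group, elem)
    wanted <- c("0008,0018", "0020,000e", "0020,0032", "0028,0010",
                "0028,0011", "0028,0030", "0028,0100", "0028,0103",
                "0028,1052", "0028,1053", "7fe0,0010")
    if (tag %in% wanted) {
      val <- readBin(con, "raw", len)
      out[[tag]] <- list(vr = vr, raw = val)
      if (tag == "7fe0,0010") break
    } else {
      seek(con, len, origin = "current")
    }
  }
  out
}

dcm_str <- function(el) trimws(rawToChar(el$raw))
dcm_ds <- function(el) as.numeric(strsplit(dcm_str(el), "\\\\")[[1]])
dcm_us <- function(el) dcm_uint(el$raw[1:2])

read_dicom_series <- function(dir, orientation = "axial-stack") {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory: ", dir)
  parsed <- lapply(files, parse_dicom_file)
  uids <- vapply(parsed, function(p) dcm_str(p[["0020,000e"]]), character(1))
  if (length(unique(uids)) > 1L)
    stop("directory mixes ", length(unique(uids)), " DICOM series")
  need <- c("0028,0010", "0028,0011", "0028,0030", "0020,0032", "7fe0,0010")
  for (p in parsed) if (!all(need %in% names(p)))
    stop("DICOM slice missing required elements (rows/columns/spacing/position/pixels)")
  pos_z <- vapply(parsed, function(p) dcm_ds(p[["0020,0032"]])[3], numeric(1))
  ord <- order(pos_z)
  parsed <- parsed[ord]; pos_z <- pos_z[ord]
  rows <- dcm_us(parsed[[1]][["0028,0010"]])
  cols <- dcm_us(parsed[[1]][["0028,0011"]])
  ps <- dcm_ds(parsed[[1]][["0028,0030"]])   # (row spacing, column spacing)
  dz <- if (length(parsed) > 1L) diff(pos_z) else 1
  if (length(parsed) > 1L && any(abs(dz - dz[1]) > 1e-6 * max(abs(dz))))
    stop("non-uniform slice positions in DICOM series")
  slope <- if (!is.null(parsed[[1]][["0028,1053"]]))
    dcm_ds(parsed[[1]][["0028,1053"]]) else 1
  inter <- if (!is.null(parsed[[1]][["0028,1052"]]))
    dcm_ds(parsed[[1]][["0028,1052"]]) else 0
  vox <- array(0, c(cols, rows, length(parsed)))
  for (k in seq_along(parsed)) {
    el <- parsed[[k]][["7fe0,0010"]]
    px <- readBin(el$raw, "integer", n = rows * cols, size = 2L,
                  signed = TRUE, endian = "little")
    # PixelData is row-major: first image row left to right
    vox[, , k] <- matrix(px, nrow = cols)
  }
  vox <- vox * slope + inter
  spacing <- c(ps[2], ps[1], if (length(parsed) > 1L) abs(dz[1]) else 1)
  ct_volume(vox, spacing, orientation, provenance = dir)
}

## ---- record tables ----

#' Read and write nodule record tables
#'
#' CSV with columns `nodule_id, source, type, total_mm3, solid_mm3`.
#'
#' @param records a record data.frame (from [measure_nodules()]).
#' @param path CSV file path.
#' @return `read_nodule_records` returns the data.frame.
#' @export
write_nodule_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nodule_records
#' @export
read_nodule_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("nodule_id", "source", "type", "total_mm3", "solid_mm3")
  if (!all(need %in% names(df)))
    stop("record table must have columns: ", paste(need, collapse = ", "))
  df$nodule_id <- as.character(df$nodule_id)
  df
}

#' Write a phantom to disk
#'
#' Writes the phantom volume and each nodule mask as NIfTI files plus a CSV
#' sidecar of ground truth (center, semi-axes, analytic volume, intended
#' type).
#'
#' @param phantom result of [make_phantom()].
#' @param specs the list of [nodule_spec()]s used to build it.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_phantom <- function(phantom, specs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$volume, file.path(dir, "phantom.nii.gz"))
  for (i in seq_along(phantom$masks)) {
    m <- phantom$masks[[i]]$mask
    storage.mode(m) <- "integer"
    write_volume(ct_volume(m, phantom$volume$spacing_mm,
                           phantom$volume$orientation),
                 file.path(dir, sprintf("mask_n%d.nii.gz", i)),
                 datatype = "int16")
  }
  gt <- do.call(rbind, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    data.frame(nodule_id = paste0("n", i),
               center_x_mm = s$center_mm[1], center_y_mm = s$center_mm[2],
               center_z_mm = s$center_mm[3],
               radius_x_mm = s$radii_mm[1], radius_y_mm = s$radii_mm[2],
               radius_z_mm = s$radii_mm[3],
               analytic_volume_mm3 = analytic_nodule_volume(s),
               intended_type = s$intended_type)
  }))
  utils::write.csv(gt, file.path(dir, "nodules.csv"), row.names = FALSE)
  invisible(dir)
}
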