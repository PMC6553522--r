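# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# No NIfTI package ships with this stack, so the subset of NIfTI-1 the
# pipeline needs is implemented directly: a 348-byte header followed by a
# float32 (or integer) data block, magic "n+1", vox_offset 352. Gzip is
# handled transparently by gzfile(). Only 3D volumes with isotropic spacing
# are supported downstream; the reader enforces this because the texture
# analysis assumes isotropic voxels.

NIFTI_DT <- list(`2` = list(what = "integer", size = 1L, signed = FALSE),
                 `4` = list(what = "integer", size = 2L, signed = TRUE),
                 `8` = list(what = "integer", size = 4L, signed = TRUE),
                 `16` = list(what = "double", size = 4L, signed = TRUE),
                 `64` = list(what = "double", size = 8L, signed = TRUE))

#' Read a NIfTI-1 image into a voxel_grid
#'
#' Supports uncompressed `.nii` and gzipped `.nii.gz` single-file NIfTI-1
#' volumes with scalar datatypes. Anisotropic voxel spacing is an error:
#' every downstream texture computation assumes an isotropic lattice.
#'
#' @param path file path.
#' @return a [voxel_grid()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L)
  swap <- FALSE
  if (sizeof_hdr != 348L) {
    swap <- TRUE
    sizeof_hdr_sw <- .swap32(sizeof_hdr)
    if (sizeof_hdr_sw != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  endian <- if (swap) "swap" else .Platform$endian
  readBin(con, "raw", 36L)                       # unused header fields
  dims <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  ndim <- dims[1]
  extra <- dims[5:8]
  if (ndim < 3L || any(extra[extra > 0] > 1L))
    stop("only 3D volumes are supported: ", path)
  nx <- dims[2]; ny <- dims[3]; nz <- dims[4]
  readBin(con, "raw", 14L)                       # intent fields
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)  # bitpix
  readBin(con, "raw", 2L)                        # slice_start
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 348L - 120L - 4L)          # rest of header up to magic
  magic <- readBin(con, "raw", 4L)
  magic_str <- rawToChar(magic[magic != as.raw(0)])
  if (!magic_str %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path)

  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  n <- as.numeric(nx) * ny * nz
  vals <- readBin(con, dt$what, as.integer(n), size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data block: ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  sp <- pixdim[2:4]
  if (max(sp) - min(sp) > 1e-6 * max(sp))
    stop(sprintf("anisotropic voxel spacing (%.4g, %.4g, %.4g) mm is not supported",
                 sp[1], sp[2], sp[3]))
  voxel_grid(array(vals, c(nx, ny, nz)), spacing = sp[1])
}

.swap32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4L)
  readBin(rev(b), "integer", 1L, size = 4L)
}

#' Write a voxel_grid (or mask array) as NIfTI-1
#'
#' Writes a single-file NIfTI-1 volume, float32, gzipped when the path ends
#' in `.gz`.
#'
#' @param grid a [voxel_grid()], or a 3D array (then `spacing` must be given).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing in mm, required when `grid` is a bare array.
#' @return `path`, invisibly.
#' @export
write_image <- function(grid, path, spacing = NULL) {
  if (inherits(grid, "voxel_grid")) {
    arr <- grid$values; sp <- grid$spacing
  } else {
    if (is.null(spacing)) stop("`spacing` required when writing a bare array")
    arr <- grid; sp <- spacing
  }
  stopifnot(length(dim(arr)) == 3L)
  d <- dim(arr)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4L)
  writeBin(raw(36L), con)
  writeBin(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), con, size = 2L)
  writeBin(raw(14L), con)
  writeBin(16L, con, size = 2L)                  # datatype float32
  writeBin(32L, con, size = 2L)                  # bitpix
  writeBin(raw(2L), con)
  writeBin(c(1, sp, sp, sp, 1, 1, 1, 1), con, size = 4L)  # pixdim
  writeBin(352, con, size = 4L)                  # vox_offset
  writeBin(c(1, 0), con, size = 4L)              # scl_slope, scl_inter
  writeBin(raw(224L), con)                       # zeroed fields, offsets 120..343
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  writeBin(raw(4L), con)                         # extension flag
  writeBin(as.numeric(arr), con, size = 4L)
  invisible(path)
}
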