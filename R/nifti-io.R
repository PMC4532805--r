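# Minimal NIfTI-1 I/O (uncompressed single-file .nii).
#
# Only the subset of the format this pipeline needs: 3D volumes, little-endian,
# datatypes uint8/int16/int32/float32/float64, scl_slope/scl_inter honoured on
# read. Deliberately no dependency: no NIfTI package is assumed available.

NIFTI_DTYPES <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4` = list(what = "integer", size = 2L, signed = TRUE), # int16
  `8` = list(what = "integer", size = 4L, signed = TRUE), # int32
  `16` = list(what = "double", size = 4L, signed = TRUE), # float32
  `64` = list(what = "double", size = 8L, signed = TRUE) # float64
)

#' Read a NIfTI-1 volume
#'
#' Reads an uncompressed single-file `.nii` volume (NIfTI-1, magic `n+1`).
#' Supports uint8, int16, int32, float32 and float64 data; `scl_slope` and
#' `scl_inter` are applied when `scl_slope` is non-zero.
#'
#' @param path Path to a `.nii` file.
#' @return A numeric array with attributes `pixdim` (voxel size per spatial
#'   dimension, mm) and `voxel_volume` (mm^3).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) input_error(sprintf("NIfTI file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- "little"
  if (sizeof_hdr != 348L) {
    # header written on a big-endian machine
    seek(con, 0L)
    sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    if (sizeof_hdr != 348L) input_error("not a NIfTI-1 file (bad sizeof_hdr)")
    endian <- "big"
  }
  seek(con, 40L)
  dim <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  seek(con, 70L)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  seek(con, 76L)
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  seek(con, 344L)
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic[1:3]), "n+1")) {
    input_error("not a single-file NIfTI-1 image (magic != 'n+1')")
  }
  spec <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(spec)) {
    input_error(sprintf("unsupported NIfTI datatype code %d", datatype))
  }
  ndim <- dim[1L]
  if (ndim < 1L || ndim > 7L) input_error("invalid NIfTI dim[0]")
  shape <- dim[seq_len(ndim) + 1L]
  shape[shape == 0L] <- 1L
  n <- prod(shape)
  seek(con, as.integer(vox_offset))
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) != n) input_error("truncated NIfTI data section")
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0) {
    vals <- vals * scl_slope + scl_inter
  }
  out <- array(vals, dim = shape)
  attr(out, "pixdim") <- pixdim[seq_len(min(ndim, 3L)) + 1L]
  attr(out, "voxel_volume") <- prod(abs(pixdim[2:4])[seq_len(min(ndim, 3L))])
  out
}

#' Write a NIfTI-1 volume
#'
#' Writes a numeric array as an uncompressed single-file `.nii` (little-endian).
#' Integer-valued arrays (atlas labels, masks) are stored as int32, everything
#' else as float64.
#'
#' @param x Numeric array (up to 3 dimensions).
#' @param path Output path (conventionally ending in `.nii`).
#' @param pixdim Voxel size per spatial dimension in mm; recycled to length 3.
#' @param datatype `"auto"`, `"int32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, pixdim = c(1, 1, 1), datatype = "auto") {
  if (!is.array(x)) x <- array(x, dim = c(length(x), 1L, 1L))
  if (length(dim(x)) > 3L) input_error("write_nifti supports up to 3 dimensions")
  shape <- c(dim(x), rep(1L, 3L - length(dim(x))))
  pixdim <- rep_len(as.double(pixdim), 3L)
  if (identical(datatype, "auto")) {
    datatype <- if (is.integer(x) ||
                    all(x == round(x) & abs(x) < 2^31, na.rm = TRUE)) {
      "int32"
    } else {
      "float64"
    }
  }
  code <- switch(datatype, int32 = 8L, float64 = 64L,
                 input_error("datatype must be 'auto', 'int32' or 'float64'"))
  bitpix <- switch(datatype, int32 = 32L, float64 = 64L)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  wf <- function(v, size) writeBin(as.double(v), con, size = size,
                                   endian = "little")
  wi(348L, 4L) # sizeof_hdr
  writeBin(raw(36L), con) # data_type, db_name, extents, session_error, regular, dim_info
  wi(c(3L, shape, 1L, 1L, 1L, 1L), 2L) # dim[8]
  wf(c(0, 0, 0), 4L) # intent_p1..p3
  wi(0L, 2L) # intent_code
  wi(code, 2L) # datatype
  wi(bitpix, 2L) # bitpix
  wi(0L, 2L) # slice_start
  wf(c(1, pixdim, 1, 1, 1, 1), 4L) # pixdim[8] (qfac = 1)
  wf(352, 4L) # vox_offset
  wf(1, 4L) # scl_slope
  wf(0, 4L) # scl_inter
  wi(0L, 2L) # slice_end
  writeBin(raw(2L), con) # slice_code, xyzt_units
  wf(c(0, 0, 0, 0), 4L) # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4L) # glmax, glmin
  writeBin(raw(104L), con) # descrip[80] + aux_file[24]
  wi(c(0L, 1L), 2L) # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0), 4L) # quatern b,c,d + qoffset x,y,z
  wf(c(pixdim[1], 0, 0, 0), 4L) # srow_x
  wf(c(0, pixdim[2], 0, 0), 4L) # srow_y
  wf(c(0, 0, pixdim[3], 0), 4L) # srow_z
  writeBin(raw(16L), con) # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4L), con) # extension flag
  if (datatype == "int32") {
    wi(as.vector(x), 4L)
  } else {
    wf(as.vector(x), 8L)
  }
  invisible(path)
}
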