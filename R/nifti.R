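# Minimal NIfTI-1 I/O.
#
# No NIfTI reader ships with the supported R stack, so the small subset
# of the format needed here (single-file .nii / .nii.gz, little-endian,
# datatypes uint8/int16/int32/float32/float64, no extensions) is
# implemented directly against the NIfTI-1 header layout and verified in
# the test suite against the Python nibabel implementation.

#' Write an array as a NIfTI-1 image
#'
#' @param arr numeric or integer array (3-D or 4-D).
#' @param path output path; a `.gz` suffix gzips the stream.
#' @param pixdim voxel dimensions (mm / s), recycled to the array rank.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(arr, path, pixdim = c(1, 1, 1, 1)) {
  nd <- length(dim(arr))
  stopifnot(nd >= 2, nd <= 4)
  integer_data <- is.integer(arr)
  datatype <- if (integer_data) 8L else 16L      # int32 / float32
  bitpix <- 32L
  dims <- c(nd, dim(arr), rep(1L, 7 - nd))
  pd <- c(1, rep(as.numeric(pixdim), length.out = nd), rep(1, 7 - nd))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, len) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(len - length(raw_s))), con)
  }
  wi(348L, 4)                    # sizeof_hdr
  wc("", 10); wc("", 18)         # data_type, db_name
  wi(0L, 4); wi(0L, 2)           # extents, session_error
  wc("r", 1); wc("", 1)          # regular, dim_info
  wi(dims, 2)                    # dim[8]
  wf(c(0, 0, 0))                 # intent_p1..p3
  wi(0L, 2)                      # intent_code
  wi(datatype, 2); wi(bitpix, 2) # datatype, bitpix
  wi(0L, 2)                      # slice_start
  wf(pd)                         # pixdim[8]
  wf(352)                        # vox_offset
  wf(1); wf(0)                   # scl_slope, scl_inter
  wi(0L, 2); wc("", 1); wc("", 1) # slice_end, slice_code, xyzt_units
  wf(0); wf(0); wf(0); wf(0)     # cal_max, cal_min, slice_duration, toffset
  wi(0L, 4); wi(0L, 4)           # glmax, glmin
  wc("sapmnet", 80); wc("", 24)  # descrip, aux_file
  wi(0L, 2); wi(2L, 2)           # qform_code, sform_code (aligned)
  wf(c(0, 0, 0)); wf(c(0, 0, 0)) # quaterns, qoffsets
  wf(c(pd[2], 0, 0, 0))          # srow_x
  wf(c(0, pd[3], 0, 0))          # srow_y
  wf(c(0, 0, pd[4], 0))          # srow_z
  wc("", 16)                     # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(raw(4), con)          # no extensions
  if (integer_data) wi(as.vector(arr), 4) else wf(as.vector(arr))
  invisible(path)
}

#' Read a NIfTI-1 image
#'
#' Supports single-file little-endian images with datatypes uint8,
#' int16, int32, float32 and float64, optionally gzipped.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return array with attribute `pixdim`; integer storage for integer
#'   datatypes.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header", call. = FALSE)
  ri <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = "little")
  sizeof_hdr <- ri(0, 4)
  if (sizeof_hdr != 348) stop("not a little-endian NIfTI-1 file",
                              call. = FALSE)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic: ", magic,
                                        call. = FALSE)
  dims <- ri(40, 2, 8)
  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  datatype <- ri(70, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  scl_slope <- rf(112); scl_inter <- rf(116)
  if (is.na(scl_slope) || scl_slope == 0) scl_slope <- 1
  n_vox <- prod(shape)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  data <- switch(as.character(datatype),
    "2"  = as.integer(readBin(con, "integer", n = n_vox, size = 1,
                              signed = FALSE)),
    "4"  = readBin(con, "integer", n = n_vox, size = 2, endian = "little"),
    "8"  = readBin(con, "integer", n = n_vox, size = 4, endian = "little"),
    "16" = readBin(con, "numeric", n = n_vox, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n = n_vox, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code: ", datatype, call. = FALSE))
  if (length(data) < n_vox) stop("truncated NIfTI data", call. = FALSE)
  if (scl_slope != 1 || scl_inter != 0)
    data <- data * scl_slope + scl_inter
  out <- array(data, dim = shape)
  attr(out, "pixdim") <- pixdim[2:(1 + nd)]
  out
}
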