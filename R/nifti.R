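# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# No NIfTI reader is available among the package's allowed dependencies, so
# the small subset of the format this pipeline needs is implemented here:
# single-file volumes, datatypes uint8 / int16 / int32 / float32 / float64,
# no scaling slope, no extensions. Headers are written little-endian; the
# reader detects byte order from sizeof_hdr. Validated against nibabel
# round-trips during development.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                 float64 = 64L)
NIFTI_BITPIX <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D array as a NIfTI-1 volume
#'
#' @param x A 3D numeric array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size Numeric length-3 voxel dimensions in mm.
#' @param datatype One of `"float32"`, `"float64"`, `"uint8"`, `"int16"`,
#'   `"int32"`.
#' @return `path`, invisibly.
#' @export
nifti_write <- function(x, path, voxel_size = c(1, 1, 1),
                        datatype = "float32") {
  stopifnot(length(dim(x)) == 3L, length(voxel_size) == 3L)
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype, call. = FALSE)
  bitpix <- NIFTI_BITPIX[[as.character(dt)]]

  con <- nifti_connection(path, "wb")
  on.exit(close(con), add = TRUE)
  w_i32 <- function(v) writeBin(as.integer(v), con, size = 4L,
                                endian = "little")
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2L,
                                endian = "little")
  w_f32 <- function(v) writeBin(as.double(v), con, size = 4L,
                                endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                              # sizeof_hdr
  w_raw(36L)                               # data_type..dim_info (unused)
  w_i16(c(3L, dim(x), 1L, 1L, 1L, 1L))     # dim[8]
  w_raw(14L)                               # intent_p1..intent_code
  w_i16(c(dt, bitpix, 0L))                 # datatype, bitpix, slice_start
  w_f32(c(0, voxel_size, 1, 1, 1, 1))      # pixdim[8] (qfac 0 -> analyze-like)
  w_f32(352)                               # vox_offset
  w_f32(c(0, 0))                           # scl_slope, scl_inter (none)
  w_raw(3L)                                # slice_end..xyzt_units
  w_raw(1L)                                # xyzt_units = 0
  w_f32(c(0, 0, 0))                        # cal_max, cal_min, slice_duration
  w_f32(0)                                 # toffset
  w_i32(c(0L, 0L))                         # glmax, glmin
  w_raw(80L + 24L)                         # descrip, aux_file
  w_i16(c(0L, 1L))                         # qform_code 0, sform_code 1
  w_f32(c(0, 0, 0, 0, 0, 0))               # quatern b,c,d, qoffset x,y,z
  w_f32(c(voxel_size[1], 0, 0, 0))         # srow_x
  w_f32(c(0, voxel_size[2], 0, 0))         # srow_y
  w_f32(c(0, 0, voxel_size[3], 0))         # srow_z
  w_raw(16L)                               # intent_name
  writeChar("n+1", con, nchars = 3L, eos = NULL)
  w_raw(1L)                                # magic terminator
  w_raw(4L)                                # extension flag (none)

  if (datatype %in% c("float32", "float64")) {
    writeBin(as.double(x), con, size = bitpix / 8L, endian = "little")
  } else {
    writeBin(as.integer(x), con, size = bitpix / 8L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package (or any plain single-file
#' NIfTI-1 with a supported datatype and no scaling)
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (3D array), `voxel_size` (length-3 numeric).
#' @export
nifti_read <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- nifti_connection(path, "rb")
  on.exit(close(con), add = TRUE)

  hdr <- readBin(con, "raw", n = 352L)
  if (length(hdr) < 348L) stop("truncated NIfTI header: ", path, call. = FALSE)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path, call. = FALSE)
  }
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian)
  }
  dims <- rd(40L, "integer", 8L, 2L)
  ndim <- dims[1]
  shape <- dims[2:(1 + max(ndim, 3L))]
  if (ndim > 3L && any(dims[(2 + 3):(1 + ndim)] > 1L)) {
    stop("only 3D volumes supported: ", path, call. = FALSE)
  }
  shape <- dims[2:4]
  datatype <- rd(70L, "integer", 1L, 2L)
  pixdim <- rd(76L, "numeric", 8L, 4L)
  vox_offset <- rd(108L, "numeric", 1L, 4L)
  scl_slope <- rd(112L, "numeric", 1L, 4L)
  scl_inter <- rd(116L, "numeric", 1L, 4L)

  n <- prod(shape)
  skip <- vox_offset - 352L
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- switch(as.character(datatype),
    `2`  = as.double(readBin(con, "integer", n = n, size = 1L, signed = FALSE)),
    `4`  = as.double(readBin(con, "integer", n = n, size = 2L, endian = endian)),
    `8`  = as.double(readBin(con, "integer", n = n, size = 4L, endian = endian)),
    `16` = readBin(con, "numeric", n = n, size = 4L, endian = endian),
    `64` = readBin(con, "numeric", n = n, size = 8L, endian = endian),
    stop("unsupported NIfTI datatype code ", datatype, call. = FALSE))
  if (length(vals) < n) stop("truncated NIfTI data: ", path, call. = FALSE)
  if (!is.na(scl_slope) && scl_slope != 0 && scl_slope != 1) {
    vals <- vals * scl_slope + scl_inter
  }
  list(data = array(vals, dim = shape), voxel_size = pixdim[2:4])
}
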