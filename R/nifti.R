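# Minimal NIfTI-1 reader/writer.
#
# The environment provides no NIfTI package, so the subset of NIfTI-1 this
# pipeline needs is implemented here: single-file .nii (optionally .nii.gz),
# 3D or 4D, datatypes uint8/int16/int32/float32/float64, no extensions,
# voxel sizes carried in pixdim. Doubles are stored as FLOAT64 so image
# round-trips are bitwise exact; label volumes are stored as INT32.

nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "numeric", size = 4L, signed = TRUE),
  `64` = list(what = "numeric", size = 8L, signed = TRUE)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D/4D array as NIfTI-1
#'
#' @param vol numeric or integer array (3D or 4D).
#' @param path output file, `.nii` or `.nii.gz`.
#' @param voxel_size voxel edge lengths in mm (length 3).
#' @param datatype `"float64"` (default) or `"int32"`.
#' @keywords internal
write_nifti <- function(vol, path, voxel_size = c(1, 1, 1),
                        datatype = c("float64", "int32")) {
  datatype <- match.arg(datatype)
  d <- dim(vol)
  assert_that(length(d) %in% c(3L, 4L), "volume must be 3D or 4D",
              "petidif_format_error")
  assert_that(all(is.finite(vol)), "volume contains non-finite values")
  code <- if (datatype == "float64") 64L else 8L
  bitpix <- if (datatype == "float64") 64L else 32L
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i32(348L)                      # sizeof_hdr
  w_raw(36L)                       # data_type..dim_info (unused)
  dim8 <- c(length(d), d, rep(1L, 7L - length(d)))
  w_i16(dim8)                      # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)     # intent
  w_i16(code); w_i16(bitpix); w_i16(0L)  # datatype, bitpix, slice_start
  pixdim <- c(1, voxel_size, if (length(d) == 4L) 1 else 1, rep(0, 3))
  w_f32(pixdim)                    # pixdim[8]
  w_f32(352); w_f32(1); w_f32(0)   # vox_offset, scl_slope, scl_inter
  w_i16(0L); w_raw(2L)             # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))             # cal_max..toffset
  w_i32(c(0L, 0L))                 # glmax, glmin
  w_raw(80L + 24L)                 # descrip, aux_file
  w_i16(c(0L, 1L))                 # qform_code, sform_code
  w_f32(rep(0, 6))                 # quaternion
  w_f32(c(voxel_size[1], 0, 0, 0)) # srow_x
  w_f32(c(0, voxel_size[2], 0, 0)) # srow_y
  w_f32(c(0, 0, voxel_size[3], 0)) # srow_z
  w_raw(16L)                       # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL); w_raw(1L)  # magic
  w_raw(4L)                        # extension flag
  if (datatype == "float64") {
    writeBin(as.numeric(vol), con, size = 8L, endian = "little")
  } else {
    writeBin(as.integer(vol), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package (or any plain single-file
#' NIfTI-1 with a supported datatype)
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `vol` (array) and `voxel_size` (mm, length 3).
#' @keywords internal
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352L)
  assert_that(length(hdr) == 352L, "truncated NIfTI header", "petidif_format_error")
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = "little", signed = TRUE)
  }
  assert_that(rd(0L, "integer", 1L, 4L) == 348L,
              "not a little-endian NIfTI-1 file", "petidif_format_error")
  dim8 <- rd(40L, "integer", 8L, 2L)
  nd <- dim8[1]
  assert_that(nd %in% c(3L, 4L), "only 3D/4D NIfTI supported", "petidif_format_error")
  d <- dim8[2:(1 + nd)]
  code <- rd(70L, "integer", 1L, 2L)
  dt <- nifti_datatypes[[as.character(code)]]
  assert_that(!is.null(dt), sprintf("unsupported NIfTI datatype %d", code),
              "petidif_format_error")
  pixdim <- rd(76L, "numeric", 8L, 4L)
  vox_offset <- rd(108L, "numeric", 1L, 4L)
  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(d)
  vol <- readBin(con, dt$what, n = n, size = dt$size, endian = "little",
                 signed = dt$signed)
  assert_that(length(vol) == n, "truncated NIfTI data", "petidif_format_error")
  dim(vol) <- d
  list(vol = vol, voxel_size = pixdim[2:4])
}
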