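# Minimal NIfTI-1 I/O.
#
# The installed R stack has no NIfTI package, so the small subset of the
# NIfTI-1 format this package needs is implemented here directly: single-file
# .nii / .nii.gz, 3-D volumes, data types uint8/int16/int32/uint16/float32/
# float64, scl_slope/scl_inter scaling, both endiannesses on read; writing is
# always little-endian float32. Interoperability with an independent reader
# (nibabel) is exercised in the test suite.

nifti_dtypes <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE),
  `4` = list(what = "integer", size = 2L, signed = TRUE),
  `8` = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "numeric", size = 4L, signed = TRUE),
  `64` = list(what = "numeric", size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (numeric array), `pixdim` (voxel sizes, mm, one
#'   per data dimension) and `dim`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_io("cannot read NIfTI file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop_io("truncated NIfTI header: ", path)
  endian <- "little"
  szof <- readBin(hdr[1:4], "integer", 1L, 4L, endian = endian)
  if (szof != 348L) {
    endian <- "big"
    szof <- readBin(hdr[1:4], "integer", 1L, 4L, endian = endian)
    if (szof != 348L) stop_io("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  rd <- function(off, what, n, size) readBin(hdr[(off + 1L):(off + n * size)], what, n, size, endian = endian)
  dims <- rd(40L, "integer", 8L, 2L)
  ndim <- dims[1]
  datatype <- rd(70L, "integer", 1L, 2L)
  pixdim <- rd(76L, "numeric", 8L, 4L)
  vox_offset <- rd(108L, "numeric", 1L, 4L)
  scl_slope <- rd(112L, "numeric", 1L, 4L)
  scl_inter <- rd(116L, "numeric", 1L, 4L)
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop_io("unsupported NIfTI datatype ", datatype, " in ", path)
  shape <- dims[2:(1 + max(1, ndim))]
  shape <- shape[shape > 0]
  if (length(shape) > 3 && prod(shape[-(1:3)]) > 1) {
    stop_io("only 3-D volumes are supported (", path, " is ", length(shape), "-D)")
  }
  shape <- shape[1:min(3, length(shape))]
  n_vox <- prod(shape)
  skip <- as.integer(vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  vals <- readBin(con, dt$what, n_vox, dt$size, signed = dt$signed, endian = endian)
  if (length(vals) < n_vox) stop_io("truncated NIfTI data: ", path)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(data = array(vals, dim = shape), pixdim = pixdim[2:(1 + length(shape))],
       dim = shape)
}

#' Write a NIfTI-1 volume (little-endian float32)
#'
#' @param data numeric 2-D or 3-D array.
#' @param path output `.nii` or `.nii.gz` path.
#' @param pixdim voxel sizes in mm (recycled to the data dimensionality).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = 1) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  d <- dim(data)
  if (length(d) != 3) stop_contract("data must be a 2-D or 3-D array")
  if (!all(is.finite(data))) stop_contract("data must be finite")
  pixdim <- rep_len(as.numeric(pixdim), 3L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, 4L, endian = "little")
  wi(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(35L), con)                        # data_type, db_name, extents, session_error, regular
  writeBin(as.raw(0L), con)                      # dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)              # dim[8]
  wf(c(0, 0, 0))                                 # intent_p1..p3
  wi(0L, 2L)                                     # intent_code
  wi(16L, 2L)                                    # datatype = float32
  wi(32L, 2L)                                    # bitpix
  wi(0L, 2L)                                     # slice_start
  wf(c(1, pixdim, 1, 1, 1, 1))                   # pixdim[8] (qfac = 1)
  wf(352)                                        # vox_offset
  wf(1); wf(0)                                   # scl_slope, scl_inter
  wi(0L, 2L); writeBin(as.raw(c(0L, 0L)), con)  # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                                 # cal_max, cal_min, slice_duration
  wf(0)                                          # toffset
  wi(c(0L, 0L), 4L)                              # glmax, glmin
  writeBin(raw(104L), con)                       # descrip[80] + aux_file[24]
  wi(c(0L, 1L), 2L)                              # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))                        # quaternions
  wf(c(pixdim[1], 0, 0, 0))                      # srow_x
  wf(c(0, pixdim[2], 0, 0))                      # srow_y
  wf(c(0, 0, pixdim[3], 0))                      # srow_z
  writeBin(raw(16L), con)                        # intent_name[16]
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4L), con)                         # extension flag -> vox_offset 352
  writeBin(as.numeric(data), con, 4L, endian = "little")
  invisible(path)
}
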