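# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# No NIfTI package is available in this environment, so the small subset of
# the format the package needs is implemented directly: the fixed 348-byte
# NIfTI-1 header, uncompressed or gzip streams, datatypes uint8 / int16 /
# int32 / float32 / float64, scl_slope/scl_inter rescaling, and both
# endiannesses on read. Data are always written as float32, little-endian.

NIFTI_DT <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),  # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)   # float64
)

#' Write an array as a NIfTI-1 file
#'
#' @param x numeric matrix (2D slice) or 3D array.
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @param pixdim voxel dimensions, recycled to the array rank.
#' @return invisibly, `path`.
#' @export
write_nifti <- function(x, path, pixdim = 1) {
  stopifnot(is.numeric(x), length(dim(x)) %in% c(2L, 3L))
  dims <- dim(x)
  if (length(dims) == 2L) dims <- c(dims, 1L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wc <- function(n) writeBin(raw(n), con)
  wi(348L, 4L)                      # sizeof_hdr
  wc(36L)                           # unused through dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L)[1:8], 2L)  # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)        # intent_p1..3, intent_code
  wi(16L, 2L); wi(32L, 2L)          # datatype float32, bitpix
  wi(0L, 2L)                        # slice_start
  pd <- rep_len(pixdim, 3L)
  wf(c(1, pd, 1, 1, 1, 1))          # pixdim[8]
  wf(352)                           # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0L, 2L); wc(2L)                # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4L)                 # glmax, glmin
  wc(104L)                          # descrip, aux_file
  wi(c(0L, 1L), 2L)                 # qform_code = 0, sform_code = 1
  wf(rep(0, 6))                     # quaternion fields
  wf(c(pd[1], 0, 0, 0,  0, pd[2], 0, 0,  0, 0, pd[3], 0))  # srow
  wc(16L)                           # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)            # magic
  wc(4L)                            # extension indicator
  writeBin(as.numeric(x), con, size = 4L, endian = "little")
  invisible(path)
}

read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- gzfile(path, "rb")         # reads plain files too
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("corrupt NIfTI (truncated header): ", path,
                               call. = FALSE)
  rd <- function(off, what, n, size, endian, signed = TRUE) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L, "little") != 348L) {
    if (rd(0L, "integer", 1L, 4L, "big") == 348L) endian <- "big"
    else stop("not a NIfTI-1 file (bad sizeof_hdr): ", path, call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop("not a NIfTI-1 file (bad magic): ", path, call. = FALSE)
  }
  dim8 <- rd(40L, "integer", 8L, 2L, endian)
  ndim <- dim8[1]
  if (ndim < 1L || ndim > 7L) stop("corrupt NIfTI (dim[0]=", ndim, "): ",
                                   path, call. = FALSE)
  dims <- dim8[2:(1 + ndim)]
  datatype <- rd(70L, "integer", 1L, 2L, endian)
  spec <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code ", datatype, ": ",
                          path, call. = FALSE)
  vox_offset <- rd(108L, "double", 1L, 4L, endian)
  scl_slope <- rd(112L, "double", 1L, 4L, endian)
  scl_inter <- rd(116L, "double", 1L, 4L, endian)
  srow <- matrix(rd(280L, "double", 12L, 4L, endian), 3L, 4L, byrow = TRUE)
  skip <- vox_offset - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vox <- readBin(con, spec$what, n = n, size = spec$size, endian = endian,
                 signed = spec$signed)
  if (length(vox) < n) stop("corrupt NIfTI (truncated data): ", path,
                            call. = FALSE)
  vox <- as.numeric(vox)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vox <- vox * scl_slope + scl_inter
  }
  dim(vox) <- dims
  list(voxels = vox, affine = srow, path = path)
}
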