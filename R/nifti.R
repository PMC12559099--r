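# Minimal self-contained NIfTI-1 I/O. Single-file .nii / .nii.gz only;
# enough of the format for ROI-statistics work: dim, datatype, pixdim,
# vox_offset, scl_slope/scl_inter, either endianness. Writing always emits
# little-endian float32 with an identity scaling.

NIFTI_DATATYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into a
#' [volumetric_image()]. Supports the common scalar datatypes (uint8, int8,
#' int16, uint16, int32, float32, float64), both endiannesses, and applies
#' `scl_slope`/`scl_inter` intensity scaling when set. Only the first three
#' dimensions are kept; higher dimensions must be singleton.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volumetric_image()] whose `voxel_dims` are `pixdim[1:3]` in mm.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con), add = TRUE)

  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unsupported NIfTI magic '", magic, "' in ", path)
  if (magic == "ni1")
    stop("two-file NIfTI (.hdr/.img) is not supported: ", path)

  dims <- readBin(hdr_raw[41:56], "integer", n = 8L, size = 2L, endian = endian)
  datatype <- readBin(hdr_raw[71:72], "integer", n = 1L, size = 2L, endian = endian)
  pixdim <- readBin(hdr_raw[77:108], "double", n = 8L, size = 4L, endian = endian)
  vox_offset <- readBin(hdr_raw[109:112], "double", n = 1L, size = 4L, endian = endian)
  scl_slope <- readBin(hdr_raw[113:116], "double", n = 1L, size = 4L, endian = endian)
  scl_inter <- readBin(hdr_raw[117:120], "double", n = 1L, size = 4L, endian = endian)

  ndim <- dims[1]
  higher <- if (ndim > 3L) dims[5:(1 + ndim)] else integer(0)
  if (ndim < 3L || any(higher > 1L))
    stop("only 3-D volumes are supported (dim = ",
         paste(dims[2:(1 + max(ndim, 1))], collapse = "x"), ")")
  shape <- pmax(dims[2:4], 1L)

  dt <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)

  # skip from byte 348 to vox_offset (gz connections cannot seek reliably)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip < 0L) stop("invalid vox_offset ", vox_offset)
  if (skip > 0L) readBin(con, "raw", n = skip)

  n_vox <- prod(shape)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size, endian = endian,
                  signed = if (dt$what == "integer") dt$signed else TRUE)
  if (length(vals) != n_vox) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  voxel_dims <- abs(pixdim[2:4])
  if (any(voxel_dims <= 0)) voxel_dims[voxel_dims <= 0] <- 1
  volumetric_image(array(vals, dim = shape), voxel_dims)
}

#' Write a NIfTI-1 volume
#'
#' Writes a [volumetric_image()] (or plain 3-D array) as a little-endian
#' float32 single-file NIfTI-1 image. Gzip compression is chosen by the
#' `.gz` file extension.
#'
#' @param image a [volumetric_image()] or 3-D array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel_dims spacings in mm; defaults to the image's own, or 1 mm
#'   isotropic for a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(image, path, voxel_dims = NULL) {
  if (inherits(image, "volumetric_image")) {
    if (is.null(voxel_dims)) voxel_dims <- image$voxel_dims
    data <- image$data
  } else {
    data <- as_image_array(image)
    if (is.null(voxel_dims)) voxel_dims <- c(1, 1, 1)
  }
  shape <- dim(data)

  con <- nifti_connection(path, "wb")
  on.exit(close(con), add = TRUE)
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw0 <- function(n) writeBin(raw(n), con)

  w_i32(348L)                                   # sizeof_hdr
  w_raw0(36L)                                   # data_type..dim_info
  w_i16(c(3L, shape, 1L, 1L, 1L, 1L))           # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)                  # intent_p1..3, intent_code
  w_i16(16L); w_i16(32L)                        # datatype float32, bitpix
  w_i16(0L)                                     # slice_start
  w_f32(c(0, voxel_dims, 1, 1, 1, 1))           # pixdim[8] (qfac 0)
  w_f32(352)                                    # vox_offset
  w_f32(1); w_f32(0)                            # scl_slope, scl_inter
  w_i16(0L); writeBin(as.raw(c(0L, 0L)), con)   # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                          # cal_max..toffset
  w_i32(c(0L, 0L))                              # glmax, glmin
  w_raw0(80L + 24L)                             # descrip, aux_file
  w_i16(c(0L, 0L))                              # qform_code, sform_code (none)
  w_f32(rep(0, 6))                              # quatern b,c,d + qoffset x,y,z
  w_f32(rep(0, 12))                             # srow_x/y/z
  w_raw0(16L)                                   # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  w_raw0(4L)                                    # pad to vox_offset 352
  writeBin(as.double(as.vector(data)), con, size = 4L, endian = "little")
  invisible(path)
}
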