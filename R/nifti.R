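# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# Implements only what the package needs: 3D/4D volumes, datatypes
# uint8/int16/int32/float32/float64, scl_slope/inter scaling, and the
# sform/qform affine (sform preferred). Written against the public NIfTI-1
# header layout because no NIfTI package is available in the target R
# library set.

.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

.open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

.quatern_to_mat <- function(b, c, d, qfac, pixdim, qoffset) {
  a2 <- 1 - b * b - c * c - d * d
  a <- if (a2 < 1e-7) 0 else sqrt(a2)
  R <- matrix(c(
    a * a + b * b - c * c - d * d, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a * a + c * c - b * b - d * d, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a * a + d * d - b * b - c * c),
    3, 3, byrow = TRUE)
  if (qfac < 0) R[, 3] <- -R[, 3]
  m <- diag(4)
  m[1:3, 1:3] <- R %*% diag(pixdim[1:3])
  m[1:3, 4] <- qoffset
  m
}

#' Read a NIfTI-1 image
#'
#' Reads a single-file NIfTI-1 volume (`.nii` or `.nii.gz`), applying
#' `scl_slope`/`scl_inter` and resolving the affine from the sform (or
#' qform, or pixdim as a last resort).
#'
#' @param path file path.
#' @return List with `data` (numeric array), `affine` (4x4, voxel index
#'   0-based to mm) and `pixdim`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_nifti: no such file: %s", path))
  con <- .open_maybe_gz(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L) stop("read_nifti: truncated header")
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("read_nifti: not a NIfTI-1 file (bad sizeof_hdr)")
  }
  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2 * n)],
                                     "integer", n, 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                     "double", n, 4L, endian = endian)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("read_nifti: missing NIfTI magic string")
  dim_field <- rd_i16(40L, 8L)
  ndim <- dim_field[1L]
  if (ndim < 3L || ndim > 4L)
    stop(sprintf("read_nifti: only 3D/4D images supported (ndim=%d)", ndim))
  shape <- dim_field[2:(1 + ndim)]
  datatype <- rd_i16(70L, 1L)
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt))
    stop(sprintf("read_nifti: unsupported datatype code %d", datatype))
  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  qform_code <- rd_i16(252L, 1L)
  sform_code <- rd_i16(254L, 1L)
  n <- prod(shape)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  data <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (length(data) < n) stop("read_nifti: truncated data section")
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  affine <- if (sform_code > 0L) {
    rbind(rd_f32(280L, 4L), rd_f32(296L, 4L), rd_f32(312L, 4L), c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    .quatern_to_mat(rd_f32(256L, 1L), rd_f32(260L, 1L), rd_f32(264L, 1L),
                    if (pixdim[1L] < 0) -1 else 1,
                    pixdim[2:4], rd_f32(268L, 3L))
  } else {
    diag(c(pixdim[2:4], 1))
  }
  list(data = array(data, dim = shape), affine = affine, pixdim = pixdim[2:4])
}

#' Write a NIfTI-1 image
#'
#' Writes a single-file NIfTI-1 volume with the affine stored as sform
#' (code 1, scanner anatomical); gzip-compressed when the path ends in
#' `.gz`.
#'
#' @param data 3D or 4D numeric array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype `"float32"`, `"uint8"`, `"int16"` or `"int32"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, affine, path, datatype = "float32") {
  ndim <- length(dim(data))
  if (!ndim %in% c(3L, 4L)) stop("write_nifti: data must be 3D or 4D")
  affine <- .check_affine(affine)
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop("write_nifti: unsupported datatype ", datatype))
  size <- switch(datatype, uint8 = 1L, int16 = 2L, int32 = 4L,
                 float32 = 4L, float64 = 8L)
  pixdim_sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  dim_field <- integer(8)
  dim_field[1L] <- ndim
  dim_field[2:(1 + ndim)] <- dim(data)
  if (ndim == 3L) dim_field[5:8] <- c(1L, 1L, 1L, 1L) else dim_field[6:8] <- 1L
  dim_field[dim_field == 0L] <- 1L

  con <- .open_maybe_gz(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, 2L, endian = "little")
  w_i8  <- function(x) writeBin(as.integer(x), con, 1L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                       # sizeof_hdr
  w_raw(36L)                        # data_type, db_name, extents, session_error, regular, dim_info
  w_i16(dim_field)                  # dim[8]
  w_raw(14L)                        # intent_p1..3, intent_code
  w_i16(code); w_i16(size * 8L)     # datatype, bitpix
  w_i16(0L)                         # slice_start
  w_f32(c(1, pixdim_sp, 0, 0, 0, 0))  # pixdim[8] (qfac=1)
  w_f32(352)                        # vox_offset
  w_f32(1); w_f32(0)                # scl_slope, scl_inter
  w_i16(0L); w_i8(0L); w_i8(0L)     # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0))                 # cal_max, cal_min, slice_duration
  w_f32(0)                          # toffset
  w_i32(c(0L, 0L))                  # glmax, glmin
  w_raw(80L); w_raw(24L)            # descrip, aux_file
  w_i16(0L); w_i16(1L)              # qform_code=0, sform_code=1
  w_f32(rep(0, 6))                  # quatern_b,c,d, qoffset_x,y,z
  w_f32(affine[1L, ]); w_f32(affine[2L, ]); w_f32(affine[3L, ])
  w_raw(16L)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)   # magic
  w_raw(4L)                         # extension flag

  vals <- as.vector(data)
  if (datatype %in% c("uint8", "int16", "int32")) {
    writeBin(as.integer(round(vals)), con, size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size, endian = "little")
  }
  invisible(path)
}
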