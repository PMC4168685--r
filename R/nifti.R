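# Minimal NIfTI-1 reader/writer.
#
# Only the subset of the format needed by this package is supported:
# single-file .nii / .nii.gz, datatypes uint8, int16, int32, float32,
# float64, and the standard 348-byte header.  scl_slope / scl_inter are
# applied on read so values have physical semantics.  Written files use
# float64, sform == qform-free affine, little-endian byte order.

NIFTI_DATATYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)    # float64
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

# Read the full header + data of a NIfTI-1 file.  Returns a list with
# elements data (array, scaling applied), dim, pixdim, affine, datatype.
nifti_read <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", n = 348L)
  if (length(raw_hdr) < 348L) {
    stop("not a NIfTI-1 file (truncated header): ", path, call. = FALSE)
  }
  endian <- "little"
  sizeof_hdr <- readBin(raw_hdr[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(raw_hdr[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) {
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path, call. = FALSE)
    }
  }
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop("not a NIfTI-1 file (bad magic): ", path, call. = FALSE)
  }
  i16 <- function(off, n = 1L) {
    readBin(raw_hdr[(off + 1):(off + 2L * n)], "integer",
            n = n, size = 2L, endian = endian)
  }
  f32 <- function(off, n = 1L) {
    readBin(raw_hdr[(off + 1):(off + 4L * n)], "double",
            n = n, size = 4L, endian = endian)
  }
  dim0 <- i16(40L, 8L)
  ndim <- dim0[1]
  if (ndim < 1L || ndim > 7L) {
    stop("invalid NIfTI dim[0] = ", ndim, call. = FALSE)
  }
  dims <- dim0[2:(1 + ndim)]
  datatype <- i16(70L)
  dt <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(dt)) {
    stop("unsupported NIfTI datatype code: ", datatype, call. = FALSE)
  }
  pixdim <- f32(76L, 8L)
  vox_offset <- f32(108L)
  scl_slope <- f32(112L)
  scl_inter <- f32(116L)
  sform_code <- i16(254L)
  qform_code <- i16(252L)
  srow <- rbind(f32(280L, 4L), f32(296L, 4L), f32(312L, 4L))

  n_vals <- prod(dims)
  # skip from end of header to vox_offset
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = n_vals, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < n_vals) {
    stop("truncated NIfTI data in ", path, call. = FALSE)
  }
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  data <- array(vals, dim = dims)

  affine <- if (sform_code > 0L && any(srow != 0)) {
    rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    nifti_qform_affine(raw_hdr, pixdim, endian)
  } else {
    # fall back to a scaled identity (analyze-style)
    diag(c(pixdim[2:4], 1))
  }

  list(data = data, dim = dims, pixdim = pixdim, affine = affine,
       datatype = datatype)
}

nifti_qform_affine <- function(raw_hdr, pixdim, endian) {
  f32 <- function(off, n = 1L) {
    readBin(raw_hdr[(off + 1):(off + 4L * n)], "double",
            n = n, size = 4L, endian = endian)
  }
  b <- f32(256L); c_ <- f32(260L); d <- f32(264L)
  a2 <- 1 - b^2 - c_^2 - d^2
  a <- if (a2 < 0) 0 else sqrt(a2)
  R <- matrix(c(
    a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),   2 * (b * d + a * c_),
    2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
    2 * (b * d - a * c_),   2 * (c_ * d + a * b),   a^2 + d^2 - b^2 - c_^2
  ), nrow = 3, byrow = TRUE)
  qfac <- if (pixdim[1] < 0) -1 else 1
  S <- diag(c(pixdim[2], pixdim[3], pixdim[4] * qfac))
  off <- c(f32(268L), f32(272L), f32(276L))
  rbind(cbind(R %*% S, off), c(0, 0, 0, 1))
}

# Write an array as a single-file NIfTI-1 (float64, little-endian).
nifti_write <- function(path, data, pixdim_spatial = c(1, 1, 1), tr = 0,
                        affine = NULL) {
  dims <- dim(data)
  if (is.null(dims)) dims <- length(data)
  ndim <- length(dims)
  if (ndim > 7L) stop("too many dimensions for NIfTI", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(pixdim_spatial[seq_len(min(3L, ndim))],
                     rep(1, 4 - min(3L, ndim))))
  }
  dim_field <- integer(8L)
  dim_field[1] <- ndim
  dim_field[2:(1 + ndim)] <- as.integer(dims)
  if (ndim < 7L) dim_field[(2 + ndim):8] <- 1L
  pixdim_field <- numeric(8L)
  pixdim_field[1] <- 1
  pixdim_field[2:4] <- c(pixdim_spatial, 1, 1)[1:3]
  pixdim_field[5] <- tr

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_chr <- function(s, n) {
    b <- charToRaw(s)
    b <- c(b[seq_len(min(length(b), n))], raw(max(0L, n - length(b))))
    writeBin(b[1:n], con)
  }

  w_i32(348L)                       # sizeof_hdr
  w_raw(10L); w_raw(18L)            # data_type, db_name
  w_i32(0L); w_i16(0L); w_raw(2L)   # extents, session_error, regular+dim_info
  w_i16(dim_field)                  # dim
  w_f32(c(0, 0, 0)); w_i16(0L)      # intent_p*, intent_code
  w_i16(64L); w_i16(64L)            # datatype float64, bitpix
  w_i16(0L)                         # slice_start
  w_f32(pixdim_field)               # pixdim
  w_f32(352)                        # vox_offset
  w_f32(1); w_f32(0)                # scl_slope, scl_inter
  w_i16(0L); w_raw(1L)              # slice_end, slice_code
  w_raw(1L)                         # xyzt_units (0 = unspecified)
  w_f32(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                  # glmax, glmin
  w_chr("sockeica", 80L)            # descrip
  w_raw(24L)                        # aux_file
  w_i16(0L)                         # qform_code
  w_i16(1L)                         # sform_code
  w_f32(c(0, 0, 0))                 # quatern b,c,d
  w_f32(c(0, 0, 0))                 # qoffset x,y,z
  w_f32(affine[1, ]); w_f32(affine[2, ]); w_f32(affine[3, ])
  w_raw(16L)                        # intent_name
  w_chr("n+1", 4L)                  # magic (includes trailing NUL)
  w_raw(4L)                         # extension flag bytes
  writeBin(as.double(data), con, size = 8L, endian = "little")
  invisible(path)
}
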