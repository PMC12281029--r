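# NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Header layout follows the published NIfTI-1 standard (348-byte header,
# magic "n+1\0" at offset 344, voxel data at vox_offset).  Both byte orders
# are supported on read (sizeof_hdr == 348 checked under each); the writer
# emits native little-endian with sform and qform both set.

.nifti_dt_code <- c(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L)
.nifti_dt_name <- c(`2` = "uint8", `4` = "int16", `8` = "int32",
                    `16` = "float32", `64` = "float64")
.nifti_bitpix <- c(uint8 = 8L, int16 = 16L, int32 = 32L, float32 = 32L, float64 = 64L)

# ---- quaternion <-> rotation, per the NIfTI-1 standard ---------------------

quatern_to_mat <- function(b, c_, d, qoffset, pixdim, qfac) {
  a2 <- 1 - b * b - c_ * c_ - d * d
  a <- sqrt(max(a2, 0))
  R <- matrix(c(
    a * a + b * b - c_ * c_ - d * d, 2 * b * c_ - 2 * a * d, 2 * b * d + 2 * a * c_,
    2 * b * c_ + 2 * a * d, a * a + c_ * c_ - b * b - d * d, 2 * c_ * d - 2 * a * b,
    2 * b * d - 2 * a * c_, 2 * c_ * d + 2 * a * b, a * a + d * d - b * b - c_ * c_
  ), nrow = 3, byrow = TRUE)
  S <- R %*% diag(c(pixdim[1], pixdim[2], pixdim[3] * qfac))
  aff <- diag(4)
  aff[1:3, 1:3] <- S
  aff[1:3, 4] <- qoffset
  aff
}

mat_to_quatern <- function(aff) {
  M <- aff[1:3, 1:3]
  pixdim <- sqrt(colSums(M^2))
  R <- sweep(M, 2, pixdim, "/")
  qfac <- 1
  if (det3(R) < 0) {
    qfac <- -1
    R[, 3] <- -R[, 3]
  }
  r <- function(i, j) R[i, j]
  a2 <- 1 + r(1, 1) + r(2, 2) + r(3, 3)
  if (a2 > 0.5) {
    a <- 0.5 * sqrt(a2)
    b <- 0.25 * (r(3, 2) - r(2, 3)) / a
    cc <- 0.25 * (r(1, 3) - r(3, 1)) / a
    d <- 0.25 * (r(2, 1) - r(1, 2)) / a
  } else {
    xd <- 1 + r(1, 1) - r(2, 2) - r(3, 3)
    yd <- 1 + r(2, 2) - r(1, 1) - r(3, 3)
    zd <- 1 + r(3, 3) - r(1, 1) - r(2, 2)
    if (xd > 1) {
      b <- 0.5 * sqrt(xd)
      a <- 0.25 * (r(3, 2) - r(2, 3)) / b
      cc <- 0.25 * (r(2, 1) + r(1, 2)) / b
      d <- 0.25 * (r(3, 1) + r(1, 3)) / b
    } else if (yd > 1) {
      cc <- 0.5 * sqrt(yd)
      a <- 0.25 * (r(1, 3) - r(3, 1)) / cc
      b <- 0.25 * (r(2, 1) + r(1, 2)) / cc
      d <- 0.25 * (r(3, 2) + r(2, 3)) / cc
    } else {
      d <- 0.5 * sqrt(zd)
      a <- 0.25 * (r(2, 1) - r(1, 2)) / d
      b <- 0.25 * (r(3, 1) + r(1, 3)) / d
      cc <- 0.25 * (r(3, 2) + r(2, 3)) / d
    }
    if (a < 0) { a <- -a; b <- -b; cc <- -cc; d <- -d }
  }
  list(b = b, c = cc, d = d, qoffset = aff[1:3, 4], pixdim = pixdim, qfac = qfac)
}

# ---- reading ---------------------------------------------------------------

parse_nifti_header <- function(hdr_raw) {
  rd <- function(offset, what, n, size, endian, signed = TRUE) {
    con <- rawConnection(hdr_raw[(offset + 1):length(hdr_raw)])
    on.exit(close(con))
    readBin(con, what, n = n, size = size, endian = endian, signed = signed)
  }
  endian <- "little"
  if (rd(0, "integer", 1, 4, "little") != 348L) {
    if (rd(0, "integer", 1, 4, "big") == 348L) endian <- "big"
    else vv_corrupt_error("not a NIfTI-1 header (sizeof_hdr != 348 in both byte orders)")
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    vv_corrupt_error(paste("bad NIfTI magic:", magic))
  dim_ <- rd(40, "integer", 8, 2, endian)
  datatype_code <- rd(70, "integer", 1, 2, endian)
  pixdim <- rd(76, "double", 8, 4, endian)
  vox_offset <- rd(108, "double", 1, 4, endian)
  scl_slope <- rd(112, "double", 1, 4, endian)
  scl_inter <- rd(116, "double", 1, 4, endian)
  dbytes <- hdr_raw[149:228]
  z <- which(dbytes == as.raw(0))
  descrip <- rawToChar(dbytes[seq_len(if (length(z)) z[1] - 1L else length(dbytes))])
  qform_code <- rd(252, "integer", 1, 2, endian)
  sform_code <- rd(254, "integer", 1, 2, endian)
  quat <- rd(256, "double", 6, 4, endian)   # b, c, d, qoffset x/y/z
  srow <- rd(280, "double", 12, 4, endian)
  dtname <- .nifti_dt_name[[as.character(datatype_code)]]
  if (is.null(dtname))
    vv_format_error(paste("unsupported NIfTI datatype code:", datatype_code))
  list(endian = endian, dim = dim_, datatype = dtname, pixdim = pixdim,
       vox_offset = vox_offset, scl_slope = scl_slope, scl_inter = scl_inter,
       descrip = descrip, qform_code = qform_code, sform_code = sform_code,
       quat = quat, srow = srow)
}

read_nifti <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  gz <- inherits(con, "gzfile")
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L)
    vv_corrupt_error(sprintf("truncated NIfTI header: expected 348 bytes, got %d",
                             length(hdr_raw)))
  h <- parse_nifti_header(hdr_raw)
  ndim <- h$dim[1]
  shape <- pmax(h$dim[2:4], 1L)
  nvols <- if (ndim >= 4) max(h$dim[5], 1L) else 1L
  skip <- h$vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  dt <- .vv_datatypes[[h$datatype]]
  nvox <- prod(shape)
  raw_data <- read_exact(con, dt$what, nvox, dt$size, h$endian, dt$signed)
  if (nvols > 1L)
    warning("4D input: keeping only the first volume", call. = FALSE)
  slope <- if (is.na(h$scl_slope) || h$scl_slope == 0) 1 else h$scl_slope
  inter <- if (is.na(h$scl_inter)) 0 else h$scl_inter
  data <- array(raw_data * slope + inter, dim = shape)
  if (h$sform_code > 0) {
    aff <- rbind(matrix(h$srow, nrow = 3, byrow = TRUE), c(0, 0, 0, 1))
  } else if (h$qform_code > 0) {
    qfac <- if (h$pixdim[1] < 0) -1 else 1
    aff <- quatern_to_mat(h$quat[1], h$quat[2], h$quat[3], h$quat[4:6],
                          abs(h$pixdim[2:4]), qfac)
  } else {
    warning("NIfTI with qform_code = sform_code = 0: using pixdim diagonal affine",
            call. = FALSE)
    aff <- diag(c(abs(h$pixdim[2:4]), 1))
  }
  fmt <- if (gz) {
    if (grepl("\\.voi$", path, ignore.case = TRUE)) "voi" else "nifti1_gz"
  } else "nifti1"
  new_volume(data, affine = aff, datatype = h$datatype, source_format = fmt,
             description = h$descrip)
}

# ---- writing ---------------------------------------------------------------

# Serialize data for an integer target datatype: round and clamp to range.
quantize_for <- function(data, datatype) {
  rng <- switch(datatype,
    uint8 = c(0, 255), int16 = c(-32768, 32767),
    int32 = c(-2147483648, 2147483647), NULL)
  if (is.null(rng)) return(as.double(data))
  as.integer(clamp(round_half_away(data), rng[1], rng[2]))
}

#' Write a volume as NIfTI-1
#'
#' Single-file NIfTI-1 (`.nii`, or gzipped `.nii.gz`).  The volume's affine is
#' written to both the sform (exact) and the qform (quaternion-encoded), with
#' both codes set to 1 (scanner space).  Integer datatypes are rounded and
#' clamped to the datatype range at serialization; floats are written as-is.
#'
#' @param vol a `vv_volume`.
#' @param path output path.
#' @param gzipped write gzip-compressed output (`.nii.gz` convention).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, gzipped = grepl("\\.gz$|\\.voi$", path)) {
  check_that(is_volume(vol), "vol must be a vv_volume")
  con <- tryCatch(if (gzipped) gzfile(path, "wb") else file(path, "wb"),
                  error = function(e) vv_io_error(paste("cannot open", path)))
  on.exit(close(con))
  shape <- dim(vol$data)
  dt <- vol$datatype
  q <- mat_to_quatern(vol$affine)
  w <- function(x, size, what = "integer") writeBin(x, con, size = size, endian = "little")
  pad <- function(s, n) {
    b <- charToRaw(s)
    writeBin(c(b[seq_len(min(length(b), n))], raw(max(0, n - length(b)))), con)
  }
  w(348L, 4)                                   # sizeof_hdr
  pad("", 10); pad("", 18)                     # data_type, db_name
  w(0L, 4); w(0L, 2); pad("r", 1); pad("", 1)  # extents, session_error, regular, dim_info
  w(as.integer(c(3L, shape, 1L, 1L, 1L, 1L)), 2)           # dim[8]
  w(numeric(3), 4)                             # intent_p1..p3
  w(0L, 2)                                     # intent_code
  w(.nifti_dt_code[[dt]], 2)                   # datatype
  w(.nifti_bitpix[[dt]], 2)                    # bitpix
  w(0L, 2)                                     # slice_start
  w(c(q$qfac, q$pixdim, 1, 1, 1, 1), 4)        # pixdim[8]
  w(352, 4)                                    # vox_offset
  w(c(1, 0), 4)                                # scl_slope, scl_inter
  w(0L, 2); pad("", 1); pad(rawToChar(as.raw(10L)), 1)  # slice_end, slice_code, xyzt_units (mm|sec)
  w(numeric(4), 4)                             # cal_max, cal_min, slice_duration, toffset
  w(c(0L, 0L), 4)                              # glmax, glmin
  pad(vol$description, 80)                     # descrip
  pad("", 24)                                  # aux_file
  w(1L, 2); w(1L, 2)                           # qform_code, sform_code
  w(c(q$b, q$c, q$d, q$qoffset), 4)            # quaterns + qoffsets
  w(as.numeric(t(vol$affine[1:3, ])), 4)       # srow_x/y/z
  pad("", 16)                                  # intent_name
  pad("n+1", 4)                                # magic (NUL-padded)
  writeBin(raw(4), con)                        # extension flag: none
  payload <- quantize_for(vol$data, dt)
  writeBin(payload, con, size = .vv_datatypes[[dt]]$size, endian = "little")
  invisible(path)
}
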