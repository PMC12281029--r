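# FreeSurfer MGH / MGZ reader and writer.
#
# MGH is always big-endian: a 284-byte header (version, dims, type, dof,
# goodRASFlag, voxel sizes, direction-cosine matrix Mdc, RAS center Pxyz_c)
# followed by the voxel data.  MGZ is the same stream gzip-compressed.
# The affine is reconstructed from Mdc / Pxyz_c with the volume center at
# voxel (dims/2), matching FreeSurfer's convention.

.mgh_type_code <- c(uint8 = 0L, int32 = 1L, float32 = 3L, int16 = 4L)
.mgh_type_name <- c(`0` = "uint8", `1` = "int32", `3` = "float32", `4` = "int16")

read_mgh <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  gz <- inherits(con, "gzfile")
  rd_i <- function(n, size = 4L) read_exact(con, "integer", n, size, "big")
  rd_f <- function(n) read_exact(con, "double", n, 4L, "big")
  version <- rd_i(1)
  if (version != 1L) vv_corrupt_error(paste("unsupported MGH version:", version))
  dims <- rd_i(4)                       # width height depth nframes
  type_code <- rd_i(1)
  rd_i(1)                               # dof (unused)
  good_ras <- read_exact(con, "integer", 1, 2L, "big")
  dtname <- .mgh_type_name[[as.character(type_code)]]
  if (is.null(dtname)) vv_format_error(paste("unsupported MGH type code:", type_code))
  if (good_ras == 1L) {
    spacing <- rd_f(3)
    mdc <- matrix(rd_f(9), nrow = 3)    # columns = x/y/z direction cosines
    pxyz_c <- rd_f(3)
  } else {
    spacing <- c(1, 1, 1)
    mdc <- diag(3); mdc[1, 1] <- -1     # FreeSurfer default LIA-ish fallback
    pxyz_c <- c(0, 0, 0)
  }
  # skip remaining header padding up to byte 284
  consumed <- 4L * 7L + 2L + if (good_ras == 1L) 60L else 0L
  readBin(con, "raw", n = 284L - consumed)
  shape <- dims[1:3]
  if (dims[4] > 1L) warning("4D input: keeping only the first volume", call. = FALSE)
  dt <- .vv_datatypes[[dtname]]
  data <- read_exact(con, dt$what, prod(shape), dt$size, "big", dt$signed)
  M <- mdc %*% diag(spacing)
  aff <- diag(4)
  aff[1:3, 1:3] <- M
  aff[1:3, 4] <- pxyz_c - M %*% (shape / 2)
  new_volume(array(data, dim = shape), affine = aff, datatype = dtname,
             source_format = if (gz) "mgz" else "mgh")
}

#' Write a volume as FreeSurfer MGH/MGZ
#'
#' @param vol a `vv_volume`; `float64` data are stored as MGH `float`
#'   (single precision), other datatypes map directly.
#' @param path output path.
#' @param gzipped write MGZ (gzip-compressed MGH).
#' @return `path`, invisibly.
#' @export
write_mgh <- function(vol, path, gzipped = grepl("\\.mgz$", path)) {
  check_that(is_volume(vol), "vol must be a vv_volume")
  dtname <- if (vol$datatype == "float64") "float32" else vol$datatype
  con <- tryCatch(if (gzipped) gzfile(path, "wb") else file(path, "wb"),
                  error = function(e) vv_io_error(paste("cannot open", path)))
  on.exit(close(con))
  shape <- dim(vol$data)
  M <- vol$affine[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  mdc <- sweep(M, 2, spacing, "/")
  pxyz_c <- M %*% (shape / 2) + vol$affine[1:3, 4]
  wi <- function(x, size = 4L) writeBin(as.integer(x), con, size = size, endian = "big")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "big")
  wi(1L)                                # version
  wi(c(shape, 1L))                      # dims + nframes
  wi(.mgh_type_code[[dtname]])
  wi(0L)                                # dof
  wi(1L, size = 2L)                     # goodRASFlag
  wf(spacing)
  wf(as.numeric(mdc))                   # column-major = x_r x_a x_s y_r ...
  wf(as.numeric(pxyz_c))
  writeBin(raw(284L - (4L * 7L + 2L + 60L)), con)
  dt <- .vv_datatypes[[dtname]]
  writeBin(quantize_for(vol$data, dtname), con, size = dt$size, endian = "big")
  invisible(path)
}
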