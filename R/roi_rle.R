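# Legacy run-length ROI codec.
#
# A faithful-capacity reconstruction of the original memory-lean ROI store:
# each slice is a list of (start_offset, length) runs of set pixels over the
# flattened in-plane raster order, with both fields held in 16 bits.  That
# field width is exactly what limits the codec to 65536 in-plane pixels —
# planes larger than that are refused.  The on-disk dialect (magic "MRO1")
# is documented below; bit-compatibility with historical archives is not
# claimed, but the capacity behavior is.
#
# File layout (all integers little-endian uint16 unless noted):
#   bytes 0-3  magic "MRO1"
#   nx, ny, nz
#   n_slices                      number of slices that carry runs
#   per slice: slice_index, n_runs, then n_runs x (start_offset, length-1)
# The length field stores (run length - 1) so a single run spanning a full
# 65536-pixel plane is representable in 16 bits; empty runs never occur.

.rle_max_pixels <- 65536L

check_rle_capacity <- function(npix) {
  if (npix > .rle_max_pixels)
    vv_capacity_error(sprintf(
      "plane has %d in-plane pixels; the 16-bit RLE codec is limited to %d",
      npix, .rle_max_pixels))
  invisible(npix)
}

#' Run-length encode / decode one binary slice
#'
#' `rle_encode_slice` scans the plane in raster order (first in-plane axis
#' fastest) and returns the sorted, non-overlapping runs of set pixels as
#' 0-based `(start, length)` pairs.  Planes with more than 65536 in-plane
#' pixels are refused — the capacity ceiling imposed by the codec's 16-bit
#' fields.  `rle_decode_slice` inverts it exactly.
#'
#' @param plane 2D 0/1 matrix (or any numeric matrix; nonzero = set).
#' @param runs a `legacy_roi_slice` from `rle_encode_slice`.
#' @param shape length-2 plane dimensions for decoding.
#' @return `rle_encode_slice`: a `legacy_roi_slice` (fields `runs`, an n x 2
#'   matrix of start/length, and `n_pixels`); `rle_decode_slice`: the 0/1
#'   integer matrix.
#' @export
rle_encode_slice <- function(plane) {
  npix <- length(plane)
  check_rle_capacity(npix)
  v <- as.integer(as.vector(plane) != 0)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths          # 0-based start of each run
  keep <- r$values == 1L
  runs <- cbind(start = starts[keep], length = r$lengths[keep])
  structure(list(runs = runs, n_pixels = npix), class = "legacy_roi_slice")
}

#' @rdname rle_encode_slice
#' @export
rle_decode_slice <- function(runs, shape) {
  check_that(inherits(runs, "legacy_roi_slice"), "runs must be a legacy_roi_slice")
  npix <- prod(shape)
  check_rle_capacity(npix)
  v <- integer(npix)
  if (nrow(runs$runs)) {
    for (r in seq_len(nrow(runs$runs))) {
      s <- runs$runs[r, 1]; l <- runs$runs[r, 2]
      if (s + l > npix)
        vv_corrupt_error(sprintf("run (%d, %d) exceeds plane size %d", s, l, npix))
      v[(s + 1):(s + l)] <- 1L
    }
  }
  matrix(v, nrow = shape[1], ncol = shape[2])
}

#' Save / load a VOI in the legacy run-length ROI dialect
#'
#' Encodes every slice of the VOI with [rle_encode_slice()] into the "MRO1"
#' container.  The format stores only grid dimensions, so `load_roi` takes
#' an optional reference volume to restore the affine (identity otherwise).
#'
#' @param voi a `vv_voi` whose in-plane pixel count is at most 65536.
#' @param path output path (conventionally `.roi`).
#' @param reference optional `vv_volume`/`vv_voi` supplying the affine on
#'   load.
#' @return `path` (`load_roi` returns the `vv_voi`).
#' @export
save_roi <- function(voi, path) {
  check_that(is_voi(voi), "voi must be a vv_voi")
  d <- dim(voi$mask)
  check_rle_capacity(d[1] * d[2])
  slices <- list()
  for (k in seq_len(d[3])) {
    enc <- rle_encode_slice(voi$mask[, , k])
    if (nrow(enc$runs)) slices[[length(slices) + 1L]] <- list(index = k - 1L, enc = enc)
  }
  con <- tryCatch(file(path, "wb"),
                  error = function(e) vv_io_error(paste("cannot open", path)))
  on.exit(close(con))
  writeBin(charToRaw("MRO1"), con)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w16(d); w16(length(slices))
  for (s in slices) {
    w16(s$index); w16(nrow(s$enc$runs))
    for (r in seq_len(nrow(s$enc$runs)))
      w16(c(s$enc$runs[r, 1], s$enc$runs[r, 2] - 1L))
  }
  invisible(path)
}

#' @rdname save_roi
#' @export
load_roi <- function(path, reference = NULL) {
  con <- tryCatch(file(path, "rb"),
                  error = function(e) vv_io_error(paste("cannot open", path)))
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(rawToChar(magic), "MRO1"))
    vv_corrupt_error("not a legacy ROI file (missing MRO1 magic)")
  r16 <- function(n) read_exact(con, "integer", n, 2L, "little", signed = FALSE)
  d <- r16(3)
  nslices <- r16(1)
  mask <- array(0L, dim = d)
  for (s in seq_len(nslices)) {
    idx <- r16(1); nruns <- r16(1)
    runs <- if (nruns > 0) matrix(r16(2L * nruns), ncol = 2, byrow = TRUE)
            else matrix(integer(0), ncol = 2)
    runs[, 2] <- runs[, 2] + 1L
    obj <- structure(list(runs = runs, n_pixels = d[1] * d[2]),
                     class = "legacy_roi_slice")
    mask[, , idx + 1L] <- rle_decode_slice(obj, d[1:2])
  }
  if (!is.null(reference)) new_voi(mask, reference = reference)
  else new_voi(mask, affine = diag(4))
}
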