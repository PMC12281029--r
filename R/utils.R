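# Internal helpers shared across modules.

#' @keywords internal
vv_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "vv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

vv_validation_error <- function(msg, ...) vv_error(msg, "vv_validation_error", ...)
vv_io_error <- function(msg, ...) vv_error(msg, "vv_io_error", ...)
vv_format_error <- function(msg, ...) vv_error(msg, "vv_format_error", ...)
vv_corrupt_error <- function(msg, ...) vv_error(msg, "vv_corrupt_error", ...)
vv_capacity_error <- function(msg, ...) vv_error(msg, "vv_capacity_error", ...)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round half away from zero: the tie rule used by every nearest-neighbor
# lookup in the package (documented; base round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# stopifnot-style scalar check with a validation condition class
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) vv_validation_error(msg)
  invisible(TRUE)
}

# 3x3 determinant (affines are small; avoids Matrix dependency)
det3 <- function(m) {
  m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) -
    m[1, 2] * (m[2, 1] * m[3, 3] - m[2, 3] * m[3, 1]) +
    m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
}

# Open a connection suited to `path`, transparently gunzipping.
open_maybe_gz <- function(path, mode = "rb") {
  two <- readBin(path, "raw", n = 2L)
  if (length(two) == 2L && two[1] == as.raw(0x1f) && two[2] == as.raw(0x8b)) {
    gzfile(path, mode)
  } else {
    file(path, mode)
  }
}

# readBin wrapper that errors (with byte accounting) on short reads
read_exact <- function(con, what, n, size, endian, signed = TRUE) {
  x <- readBin(con, what = what, n = n, size = size, endian = endian,
               signed = signed)
  if (length(x) < n) {
    vv_corrupt_error(sprintf(
      "truncated data section: expected %d values of %d byte(s), got %d",
      n, size, length(x)))
  }
  x
}

fmt_num <- function(x, digits = 6) vapply(x, function(v)
  as.character(signif(v, digits)), character(1))

# Snap doubles to their nearest float32-representable value (via a byte
# round-trip), so volumes serialized with 4-byte floats re-read bit-exact.
float32_snap <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.double(x), raw(), size = 4L), "double",
               n = length(x), size = 4L)
  if (!is.null(d)) dim(y) <- d
  y
}
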