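#' Volumetric image container
#'
#' A `vv_volume` bundles a 3D numeric voxel array with the geometry needed to
#' place each voxel in world space: a 4x4 voxel-to-world affine (RAS+
#' millimetres, mapping the 0-based index of a voxel *center*), the voxel
#' dimensions, and format bookkeeping.  All readers produce this container and
#' every other module consumes it.  Voxel data are stored *after* any on-disk
#' scale/intercept has been applied, so `vol$data` is always in physical units.
#'
#' @param data 3D numeric array (a 4D array is truncated to its first volume
#'   with a warning).
#' @param affine 4x4 voxel-to-world matrix; if `NULL` a diagonal affine is
#'   built from `voxel_size`.
#' @param voxel_size length-3 positive numeric, voxel edge lengths in mm.
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"` — the datatype used when the volume is serialized.
#' @param source_format provenance tag (`"synthetic"` for in-memory volumes).
#' @param description free-text header description.
#' @return An object of class `vv_volume`.
#' @export
new_volume <- function(data, affine = NULL, voxel_size = c(1, 1, 1),
                       datatype = "float32", source_format = "synthetic",
                       description = "") {
  if (length(dim(data)) == 4L) {
    if (dim(data)[4] > 1L)
      warning("4D input: keeping only the first volume", call. = FALSE)
    data <- array(data[, , , 1L], dim = dim(data)[1:3])
  }
  check_that(length(dim(data)) == 3L, "volume data must be a 3D array")
  check_that(all(dim(data) >= 1L), "volume dims must be positive")
  if (is.null(affine)) {
    check_that(length(voxel_size) == 3L && all(voxel_size > 0),
               "voxel_size must be 3 positive reals")
    affine <- diag(c(voxel_size, 1))
  }
  affine <- unname(as.matrix(affine))
  check_that(all(dim(affine) == c(4L, 4L)), "affine must be 4x4")
  check_that(abs(det3(affine[1:3, 1:3])) > .Machine$double.eps,
             "affine 3x3 part must be nonsingular")
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  check_that(datatype %in% names(.vv_datatypes), paste("unknown datatype:", datatype))
  if (anyNA(data) || any(!is.finite(data)))
    vv_validation_error("volume data must be finite everywhere")
  structure(
    list(data = data, affine = affine, voxel_size = voxel_size,
         datatype = datatype, source_format = source_format,
         description = description),
    class = "vv_volume")
}

# datatype -> (size bytes, what, signed) used by all binary readers/writers
.vv_datatypes <- list(
  uint8   = list(size = 1L, what = "integer", signed = FALSE),
  int16   = list(size = 2L, what = "integer", signed = TRUE),
  int32   = list(size = 4L, what = "integer", signed = TRUE),
  float32 = list(size = 4L, what = "double",  signed = TRUE),
  float64 = list(size = 8L, what = "double",  signed = TRUE)
)

#' @export
print.vv_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<vv_volume> ", paste(d, collapse = " x "),
      " [", x$datatype, ", ", x$source_format, "]\n", sep = "")
  cat("  voxel size (mm): ", paste(fmt_num(x$voxel_size), collapse = " x "), "\n", sep = "")
  cat("  intensity range: ", fmt_num(min(x$data)), " .. ", fmt_num(max(x$data)), "\n", sep = "")
  cat("  affine:\n")
  print(round(x$affine, 6))
  invisible(x)
}

#' @export
dim.vv_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "vv_volume")

#' Binary volume of interest (VOI)
#'
#' A `vv_voi` is a binary mask (0/1) sharing a reference volume's grid: same
#' array shape and the same voxel-to-world affine.  Lesion drawing, the
#' run-length ROI codec and incidence mapping all operate on this type.
#'
#' @param mask 3D array coercible to 0/1.
#' @param reference a `vv_volume` (or another `vv_voi`) providing the
#'   geometry; alternatively pass `affine` directly.
#' @param affine 4x4 voxel-to-world matrix, used when `reference` is `NULL`.
#' @return An object of class `vv_voi`.
#' @export
new_voi <- function(mask = NULL, reference = NULL, affine = NULL) {
  if (is.null(mask)) {
    check_that(!is.null(reference), "need a mask or a reference grid")
    mask <- array(0L, dim = dim(reference$data %||% reference$mask))
  }
  mask <- array(as.integer(mask != 0), dim = dim(mask))
  check_that(length(dim(mask)) == 3L, "VOI mask must be 3D")
  if (!is.null(reference)) {
    ref_dim <- dim(reference$data %||% reference$mask)
    check_that(all(dim(mask) == ref_dim),
               "VOI mask shape must equal the reference grid shape")
    affine <- reference$affine
  }
  if (is.null(affine)) affine <- diag(4)
  structure(list(mask = mask, affine = unname(as.matrix(affine))),
            class = "vv_voi")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vv_voi <- function(x, ...) {
  cat("<vv_voi> ", paste(dim(x$mask), collapse = " x "),
      ", ", sum(x$mask), " voxel(s) set\n", sep = "")
  invisible(x)
}

#' @export
dim.vv_voi <- function(x) dim(x$mask)

is_voi <- function(x) inherits(x, "vv_voi")

# VOI as a uint8 volume (for writing through the NIfTI writer)
voi_as_volume <- function(voi) {
  new_volume(voi$mask, affine = voi$affine, datatype = "uint8",
             source_format = "voi")
}
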