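# Group lesion incidence maps and per-VOI descriptive statistics.

#' Per-voxel lesion incidence across subjects
#'
#' The voxelwise mean of the binary masks: fraction of subjects whose lesion
#' includes each voxel.  Inputs must share a grid (shapes equal, affines
#' within 1e-3 elementwise); mismatched inputs are rejected rather than
#' silently resliced — reslice binary masks explicitly (nearest-neighbor)
#' first.
#'
#' @param vois list of `vv_voi` on a common grid.
#' @return A `vv_incidence` list: `fraction` (3D array in `[0, 1]`),
#'   `n_subjects`, `affine`.
#' @export
incidence_map <- function(vois) {
  check_that(length(vois) >= 1, "need at least one VOI")
  for (q in seq_along(vois))
    check_that(is_voi(vois[[q]]), sprintf("input %d is not a vv_voi", q))
  ref <- vois[[1]]
  for (q in seq_along(vois)) {
    if (!all(dim(vois[[q]]$mask) == dim(ref$mask)) ||
        max(abs(vois[[q]]$affine - ref$affine)) > 1e-3)
      vv_validation_error(sprintf(
        "VOI %d is on a different grid than VOI 1; reslice it explicitly first", q))
  }
  count <- Reduce(`+`, lapply(vois, `[[`, "mask"))
  structure(list(fraction = count / length(vois), n_subjects = length(vois),
                 affine = ref$affine),
            class = "vv_incidence")
}

#' @export
print.vv_incidence <- function(x, ...) {
  cat("<vv_incidence> ", paste(dim(x$fraction), collapse = " x "),
      ", n = ", x$n_subjects,
      ", max fraction = ", fmt_num(max(x$fraction)), "\n", sep = "")
  invisible(x)
}

#' Display layer for an incidence map
#'
#' Windows the fraction between `low_threshold` and `high_threshold` through
#' a cold-to-warm LUT: fractions below the low threshold are fully
#' transparent, the low threshold maps to the cold (blue) end and fractions
#' at or above the high threshold saturate at the warm (red) end.  The
#' defaults reproduce the classic 1% blue / 10% red incidence display.
#'
#' @param map a [incidence_map()] result.
#' @param low_threshold lower fraction bound (default 0.01).
#' @param high_threshold upper fraction bound (default 0.10).
#' @param lut a cold-to-warm 256 x 4 LUT (default [color_lut]`("warm")`).
#' @param opacity overlay opacity.
#' @return A [windowed_layer()] carrying the fraction volume.
#' @export
incidence_overlay <- function(map, low_threshold = 0.01, high_threshold = 0.10,
                              lut = color_lut("warm"), opacity = 1) {
  check_that(inherits(map, "vv_incidence"), "map must be an incidence map")
  check_that(low_threshold >= 0 && low_threshold < high_threshold &&
               high_threshold <= 1,
             "need 0 <= low_threshold < high_threshold <= 1")
  vol <- new_volume(map$fraction, affine = map$affine, datatype = "float32",
                    source_format = "synthetic",
                    description = sprintf("lesion incidence n=%d", map$n_subjects))
  windowed_layer(vol, display_min = low_threshold, display_max = high_threshold,
                 lut = lut, opacity = opacity)
}

#' Descriptive statistics for a VOI
#'
#' Voxel count, physical volume (`n_voxels` times the voxel volume, the
#' absolute determinant of the affine's 3x3 part), world center of mass and
#' world bounding box of the set voxels.  An empty VOI yields zero volume
#' and `NA` centroid/bounds with `empty = TRUE`.
#'
#' @param voi a `vv_voi`.
#' @param label optional identifier recorded in the output row.
#' @return One-row data frame.
#' @export
voi_descriptives <- function(voi, label = NA_character_) {
  check_that(is_voi(voi), "voi must be a vv_voi")
  n <- sum(voi$mask)
  vox_mm3 <- abs(det3(voi$affine[1:3, 1:3]))
  if (n == 0) {
    return(data.frame(label = label, n_voxels = 0L, volume_mm3 = 0,
                      com_x = NA_real_, com_y = NA_real_, com_z = NA_real_,
                      min_x = NA_real_, min_y = NA_real_, min_z = NA_real_,
                      max_x = NA_real_, max_y = NA_real_, max_z = NA_real_,
                      empty = TRUE, stringsAsFactors = FALSE))
  }
  idx <- which(voi$mask != 0L, arr.ind = TRUE) - 1L
  w <- voxel_to_world(voi, idx)
  com <- colMeans(w)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  data.frame(label = label, n_voxels = as.integer(n), volume_mm3 = n * vox_mm3,
             com_x = com[1], com_y = com[2], com_z = com[3],
             min_x = lo[1], min_y = lo[2], min_z = lo[3],
             max_x = hi[1], max_y = hi[2], max_z = hi[3],
             empty = FALSE, stringsAsFactors = FALSE, row.names = NULL)
}

#' Write VOI descriptives to CSV
#'
#' One row per record, fixed column order, headered; an empty record list
#' writes a header-only file.
#'
#' @param records list of [voi_descriptives()] rows (or a data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptives_csv <- function(records, path) {
  cols <- c("label", "n_voxels", "volume_mm3", "com_x", "com_y", "com_z",
            "min_x", "min_y", "min_z", "max_x", "max_y", "max_z", "empty")
  df <- if (is.data.frame(records)) records else do.call(rbind, records)
  if (is.null(df) || nrow(df) == 0)
    df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols))
  utils::write.csv(df[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Save an incidence map as float32 NIfTI
#'
#' @param map a [incidence_map()] result.
#' @param path output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_incidence <- function(map, path) {
  check_that(inherits(map, "vv_incidence"), "map must be an incidence map")
  vol <- new_volume(float32_snap(map$fraction), affine = map$affine,
                    datatype = "float32",
                    description = sprintf("lesion incidence n=%d", map$n_subjects))
  write_nifti(vol, path)
}
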