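# Voxel/world geometry, canonical reorientation and reslicing.
#
# Convention used everywhere in the package: voxel indices are 0-based,
# world space is RAS+ millimetres, and the affine maps the homogeneous index
# (i, j, k, 1) of a voxel CENTER to world coordinates.

#' Target grid specification for reslicing
#'
#' @param shape 3 positive integers.
#' @param affine 4x4 voxel-to-world matrix with a nonsingular 3x3 part.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(shape, affine) {
  check_that(length(shape) == 3L && all(shape >= 1), "shape must be 3 positive integers")
  affine <- unname(as.matrix(affine))
  check_that(all(dim(affine) == c(4, 4)), "affine must be 4x4")
  check_that(abs(det3(affine[1:3, 1:3])) > .Machine$double.eps,
             "affine 3x3 part must be nonsingular")
  structure(list(shape = as.integer(shape), affine = affine), class = "grid_spec")
}

#' Map voxel indices to world coordinates
#'
#' @param vol a `vv_volume`, `vv_voi` or `grid_spec` (anything with an
#'   `$affine`).
#' @param ijk numeric length-3 vector, or an n x 3 matrix of 0-based
#'   (possibly fractional, possibly out-of-grid) voxel indices.
#' @return World RAS+ mm coordinates, same shape as the input.
#' @export
voxel_to_world <- function(vol, ijk) {
  A <- vol$affine
  if (is.matrix(ijk)) {
    t(A[1:3, 1:3] %*% t(ijk) + A[1:3, 4])
  } else {
    as.numeric(A[1:3, 1:3] %*% ijk + A[1:3, 4])
  }
}

#' Map world coordinates to (fractional) voxel indices
#'
#' Exact inverse of [voxel_to_world()].
#'
#' @param vol as in [voxel_to_world()].
#' @param xyz numeric length-3 vector or n x 3 matrix of world mm positions.
#' @return 0-based fractional voxel indices, same shape as the input.
#' @export
world_to_voxel <- function(vol, xyz) {
  A <- vol$affine
  Minv <- solve(A[1:3, 1:3])
  if (is.matrix(xyz)) {
    t(Minv %*% (t(xyz) - A[1:3, 4]))
  } else {
    as.numeric(Minv %*% (xyz - A[1:3, 4]))
  }
}

# Vectorized array lookup with 0 fill outside the grid; pts is n x 3 of
# 0-based integer indices.
lookup0 <- function(data, pts) {
  d <- dim(data)
  inside <- pts[, 1] >= 0 & pts[, 1] <= d[1] - 1 &
            pts[, 2] >= 0 & pts[, 2] <= d[2] - 1 &
            pts[, 3] >= 0 & pts[, 3] <= d[3] - 1
  out <- numeric(nrow(pts))
  if (any(inside)) {
    p <- pts[inside, , drop = FALSE]
    idx <- 1 + p[, 1] + d[1] * (p[, 2] + d[2] * p[, 3])
    out[inside] <- data[idx]
  }
  out
}

#' Sample a volume at continuous voxel coordinates
#'
#' `nearest` rounds each component half-away-from-zero and returns the stored
#' value; `trilinear` is the weighted average of the 8 surrounding grid
#' values.  Coordinates outside the grid return 0 (background fill) — edge
#' values are never smeared outward.
#'
#' @param vol a `vv_volume` (or any object with `$data`), or a bare 3D array.
#' @param ijk length-3 vector or n x 3 matrix of continuous 0-based indices.
#' @param interp `"nearest"` or `"trilinear"`.
#' @return Numeric vector of sampled intensities.
#' @export
sample_volume <- function(vol, ijk, interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  data <- if (is.array(vol)) vol else (vol$data %||% vol$mask)
  if (!is.matrix(ijk)) ijk <- matrix(ijk, ncol = 3)
  if (interp == "nearest") {
    return(lookup0(data, round_half_away(ijk)))
  }
  f <- floor(ijk)
  w <- ijk - f
  out <- numeric(nrow(ijk))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    wt <- (if (di) w[, 1] else 1 - w[, 1]) *
          (if (dj) w[, 2] else 1 - w[, 2]) *
          (if (dk) w[, 3] else 1 - w[, 3])
    nz <- wt != 0
    if (any(nz)) {
      pts <- cbind(f[nz, 1] + di, f[nz, 2] + dj, f[nz, 3] + dk)
      out[nz] <- out[nz] + wt[nz] * lookup0(data, pts)
    }
  }
  out
}

#' Reorient a volume to canonical RAS axis order
#'
#' Losslessly permutes and flips the voxel axes (no interpolation) so that
#' the affine's 3x3 part is maximally diagonal with a positive diagonal:
#' axis 1 runs left-to-Right, axis 2 posterior-to-Anterior, axis 3
#' inferior-to-Superior.  Every voxel keeps its world position; the multiset
#' of intensities is untouched.  Idempotent.
#'
#' @param vol a `vv_volume`.
#' @return The reoriented `vv_volume`.
#' @export
canonical_ras <- function(vol) {
  A <- vol$affine
  M <- A[1:3, 1:3]
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  score <- vapply(perms, function(p) sum(abs(M[cbind(1:3, p)])), numeric(1))
  perm <- perms[[which.max(score)]]       # perm[world axis] = source voxel axis
  flip <- M[cbind(1:3, perm)] < 0
  shape <- dim(vol$data)
  # array: new axis r = source axis perm[r], reversed when flipped
  data <- aperm(vol$data, perm)
  for (r in which(flip)) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[r]] <- dim(data)[r]:1
    data <- do.call(`[`, c(list(data), idx, list(drop = FALSE)))
  }
  # T maps new homogeneous index to old: old = P.new + t
  Tm <- matrix(0, 4, 4); Tm[4, 4] <- 1
  for (r in 1:3) {
    if (flip[r]) {
      Tm[perm[r], r] <- -1
      Tm[perm[r], 4] <- shape[perm[r]] - 1
    } else {
      Tm[perm[r], r] <- 1
    }
  }
  new_volume(data, affine = A %*% Tm, datatype = vol$datatype,
             source_format = vol$source_format, description = vol$description)
}

#' Reslice a volume onto a target grid through world space
#'
#' Each target voxel takes the value of `vol` sampled (with the chosen
#' interpolation) at the source-grid position of the target voxel's world
#' coordinate; out-of-field positions fill with 0.  The result carries the
#' target's affine.
#'
#' @param vol a `vv_volume`.
#' @param target a [grid_spec()] (or another volume, whose grid is used).
#' @param interp `"trilinear"` or `"nearest"`.
#' @return A `vv_volume` on the target grid.
#' @export
reslice_world <- function(vol, target, interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  if (is_volume(target)) target <- grid_spec(dim(target$data), target$affine)
  check_that(inherits(target, "grid_spec"), "target must be a grid_spec or vv_volume")
  shape <- target$shape
  g <- index_grids(shape)
  tgt_ijk <- cbind(as.numeric(g$i), as.numeric(g$j), as.numeric(g$k))
  xyz <- voxel_to_world(target, tgt_ijk)
  src_ijk <- world_to_voxel(vol, xyz)
  vals <- sample_volume(vol, src_ijk, interp)
  new_volume(array(vals, dim = shape), affine = target$affine,
             datatype = vol$datatype, source_format = vol$source_format,
             description = vol$description)
}

# Isotropic world-space grid covering a volume, spacing = smallest voxel dim.
# Used by world-space display (slices and mosaics).
world_grid_for <- function(vol, spacing = NULL) {
  shape <- dim(vol$data)
  if (is.null(spacing)) spacing <- min(vol$voxel_size)
  corners <- as.matrix(expand.grid(c(0, shape[1] - 1), c(0, shape[2] - 1),
                                   c(0, shape[3] - 1)))
  w <- voxel_to_world(vol, corners)
  lo <- apply(w, 2, min)
  hi <- apply(w, 2, max)
  n <- pmax(1L, as.integer(floor((hi - lo) / spacing)) + 1L)
  aff <- diag(c(rep(spacing, 3), 1))
  aff[1:3, 4] <- lo
  grid_spec(n, aff)
}
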