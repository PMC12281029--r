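# Lesion drawing operators on binary VOIs.
#
# All 2D operators address one slice (fixed third voxel axis, 0-based index)
# and leave every other slice untouched.  In-plane coordinates are 0-based
# (i, j) voxel indices; drawing happens in image space only, so traced
# lesions are never interpolated.

check_slice <- function(voi, slice_index) {
  nz <- dim(voi$mask)[3]
  if (slice_index < 0 || slice_index > nz - 1)
    vv_validation_error(sprintf("slice %d out of range: valid range is 0..%d",
                                slice_index, nz - 1))
  as.integer(slice_index)
}

plane_of <- function(voi, k) voi$mask[, , k + 1L]

with_plane <- function(voi, k, plane) {
  m <- voi$mask
  m[, , k + 1L] <- as.integer(plane != 0)
  new_voi(m, affine = voi$affine)
}

# in-plane voxel-center coordinate grids (0-based)
plane_grids <- function(shape2) {
  list(x = matrix(rep(seq_len(shape2[1]) - 1, shape2[2]), shape2[1], shape2[2]),
       y = matrix(rep(seq_len(shape2[2]) - 1, each = shape2[1]), shape2[1], shape2[2]))
}

#' Draw or erase a pen stroke on one slice
#'
#' Sets (or, with `erase`, clears) every voxel whose center lies within
#' `thickness / 2` (Euclidean, in-plane) of any segment of the polyline.
#' A single-point polyline stamps a disc.
#'
#' @param voi a `vv_voi`.
#' @param slice_index 0-based slice (third axis).
#' @param polyline n x 2 matrix of 0-based in-plane (i, j) points.
#' @param thickness stroke thickness in voxels (>= 1).
#' @param erase clear instead of set.
#' @return The modified `vv_voi`.
#' @export
pen_stroke <- function(voi, slice_index, polyline, thickness = 1, erase = FALSE) {
  check_that(is_voi(voi), "voi must be a vv_voi")
  k <- check_slice(voi, slice_index)
  check_that(thickness >= 1, "thickness must be >= 1")
  polyline <- matrix(as.numeric(polyline), ncol = 2)
  plane <- plane_of(voi, k)
  g <- plane_grids(dim(plane))
  r <- thickness / 2
  hit <- matrix(FALSE, nrow(plane), ncol(plane))
  nseg <- max(1L, nrow(polyline) - 1L)
  for (s in seq_len(nseg)) {
    p1 <- polyline[s, ]
    p2 <- polyline[min(s + 1L, nrow(polyline)), ]
    d <- p2 - p1
    len2 <- sum(d^2)
    if (len2 == 0) {
      dist2 <- (g$x - p1[1])^2 + (g$y - p1[2])^2
    } else {
      tt <- clamp(((g$x - p1[1]) * d[1] + (g$y - p1[2]) * d[2]) / len2, 0, 1)
      dist2 <- (g$x - (p1[1] + tt * d[1]))^2 + (g$y - (p1[2] + tt * d[2]))^2
    }
    hit <- hit | dist2 <= r^2
  }
  plane[hit] <- if (erase) 0L else 1L
  with_plane(voi, k, plane)
}

#' Draw or erase an ellipse on one slice
#'
#' The ellipse inscribed in `bounding_box` (inclusive 0-based in-plane voxel
#' corners).  `filled` paints the interior; otherwise only the 1-voxel-thick
#' boundary (the filled disc minus its 4-connected erosion) is drawn.
#'
#' @param voi a `vv_voi`.
#' @param slice_index 0-based slice.
#' @param bounding_box `list(min = c(i, j), max = c(i, j))`, nonzero extent.
#' @param filled paint the interior.
#' @param erase clear instead of set.
#' @return The modified `vv_voi`.
#' @export
draw_ellipse <- function(voi, slice_index, bounding_box, filled = TRUE,
                         erase = FALSE) {
  check_that(is_voi(voi), "voi must be a vv_voi")
  k <- check_slice(voi, slice_index)
  bb_min <- as.numeric(bounding_box$min)
  bb_max <- as.numeric(bounding_box$max)
  if (any(bb_max <= bb_min))
    vv_validation_error("degenerate bounding box: both extents must be nonzero")
  ctr <- (bb_min + bb_max) / 2
  ax <- (bb_max - bb_min) / 2
  plane <- plane_of(voi, k)
  g <- plane_grids(dim(plane))
  disc <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 <= 1
  sel <- if (filled) disc else disc & !erode4_plane(disc)
  plane[sel] <- if (erase) 0L else 1L
  with_plane(voi, k, plane)
}

# 4-connected in-plane binary erosion (border treated as background)
erode4_plane <- function(b) {
  n <- nrow(b); m <- ncol(b)
  up <- rbind(b[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, b[-n, , drop = FALSE])
  lf <- cbind(b[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, b[, -m, drop = FALSE])
  b & up & dn & lf & rt
}

#' Flood-fill an enclosed area on one slice
#'
#' 4-connected flood of the 0-valued region containing `seed_point`, bounded
#' by 1-valued voxels and the slice border; the region is set to 1.
#' 4-connectivity makes 8-connected drawn contours watertight.  A seed on an
#' already-set voxel is a no-op (with a notice).
#'
#' @param voi a `vv_voi`.
#' @param slice_index 0-based slice.
#' @param seed_point length-2 0-based in-plane (i, j) voxel.
#' @return The modified `vv_voi`.
#' @export
bucket_fill <- function(voi, slice_index, seed_point) {
  check_that(is_voi(voi), "voi must be a vv_voi")
  k <- check_slice(voi, slice_index)
  plane <- plane_of(voi, k)
  n <- nrow(plane); m <- ncol(plane)
  si <- as.integer(seed_point[1]) + 1L
  sj <- as.integer(seed_point[2]) + 1L
  check_that(si >= 1 && si <= n && sj >= 1 && sj <= m, "seed point outside the slice")
  if (plane[si, sj] != 0L) {
    message("bucket_fill: seed voxel already set; nothing to fill")
    return(voi)
  }
  filled <- matrix(FALSE, n, m)
  frontier <- (sj - 1L) * n + si          # linear indices
  filled[frontier] <- TRUE
  while (length(frontier)) {
    i <- (frontier - 1L) %% n + 1L
    j <- (frontier - 1L) %/% n + 1L
    cand <- c((j - 1L) * n + (i - 1L), (j - 1L) * n + (i + 1L),
              (j - 2L) * n + i, j * n + i)
    ok <- c(i > 1L, i < n, j > 1L, j < m)
    cand <- unique(cand[ok])
    cand <- cand[!filled[cand] & plane[cand] == 0L]
    filled[cand] <- TRUE
    frontier <- cand
  }
  plane[filled] <- 1L
  with_plane(voi, k, plane)
}

#' Grow a region from a seed by intensity
#'
#' The 3D connected component (6- or 26-connectivity) of voxels whose source
#' intensity lies in `[low, high]`, containing the seed.
#'
#' @param source a `vv_volume`.
#' @param seed_voxel length-3 0-based (i, j, k).
#' @param low,high inclusive intensity bounds; must bracket the seed value.
#' @param connectivity 6 or 26.
#' @return A `vv_voi` on the source grid.
#' @export
intensity_grow <- function(source, seed_voxel, low, high, connectivity = 6) {
  check_that(is_volume(source), "source must be a vv_volume")
  check_that(connectivity %in% c(6, 26), "connectivity must be 6 or 26")
  d <- dim(source$data)
  s <- as.integer(seed_voxel) + 1L
  check_that(all(s >= 1L) && all(s <= d), "seed voxel outside the volume")
  sval <- source$data[s[1], s[2], s[3]]
  if (sval < low || sval > high)
    vv_validation_error(sprintf(
      "seed intensity %s outside [%s, %s]", fmt_num(sval), fmt_num(low), fmt_num(high)))
  inside <- source$data >= low & source$data <= high
  offs <- if (connectivity == 6) {
    matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1),
           ncol = 3, byrow = TRUE)
  } else {
    as.matrix(expand.grid(-1:1, -1:1, -1:1))[-14, ]   # drop (0,0,0)
  }
  visited <- array(FALSE, dim = d)
  visited[s[1], s[2], s[3]] <- TRUE
  frontier <- cbind(s[1], s[2], s[3])
  while (nrow(frontier)) {
    cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o)
      sweep(frontier, 2, as.numeric(offs[o, ]), "+")))
    keep <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[keep, , drop = FALSE]
    if (!nrow(cand)) break
    lin <- cand[, 1] + d[1] * (cand[, 2] - 1) + d[1] * d[2] * (cand[, 3] - 1)
    take <- !visited[lin] & inside[lin]
    lin <- unique(lin[take])
    if (!length(lin)) break
    visited[lin] <- TRUE
    l0 <- lin - 1
    frontier <- cbind(l0 %% d[1] + 1, (l0 %/% d[1]) %% d[2] + 1,
                      l0 %/% (d[1] * d[2]) + 1)
  }
  new_voi(visited, affine = source$affine)
}

#' Binary morphology with a discrete spherical element
#'
#' `dilate`, `erode`, `open` (erode then dilate) or `close` (dilate then
#' erode) with the structuring element of all offsets with squared norm
#' `<= radius^2` (radius 1 gives the 6-connected ball).  Outside the grid is
#' background.
#'
#' @param voi a `vv_voi`.
#' @param operation `"dilate"`, `"erode"`, `"open"` or `"close"`.
#' @param radius_voxels structuring-element radius (>= 1).
#' @return The transformed `vv_voi`.
#' @export
morph_voi <- function(voi, operation = c("dilate", "erode", "open", "close"),
                      radius_voxels = 1) {
  operation <- match.arg(operation)
  check_that(is_voi(voi), "voi must be a vv_voi")
  check_that(radius_voxels >= 1, "radius must be >= 1")
  r <- floor(radius_voxels)
  offs <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  offs <- offs[rowSums(offs^2) <= radius_voxels^2, , drop = FALSE]
  mask <- voi$mask != 0L
  out <- switch(operation,
    dilate = shift_reduce(mask, offs, `|`),
    erode = shift_reduce(mask, offs, `&`),
    open = shift_reduce(shift_reduce(mask, offs, `&`), offs, `|`),
    close = shift_reduce(shift_reduce(mask, offs, `|`), offs, `&`))
  new_voi(out, affine = voi$affine)
}

# fold a logical array over all shifted copies of itself
shift_reduce <- function(mask, offs, op) {
  out <- NULL
  for (o in seq_len(nrow(offs))) {
    sh <- shift3(mask, offs[o, ])
    out <- if (is.null(out)) sh else op(out, sh)
  }
  out
}

# shift a logical 3D array by an integer offset, padding with FALSE
shift3 <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  src <- dst <- list()
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) {
      if (o >= d[a]) return(out)
      dst[[a]] <- (1 + o):d[a]; src[[a]] <- 1:(d[a] - o)
    } else {
      if (-o >= d[a]) return(out)
      dst[[a]] <- 1:(d[a] + o); src[[a]] <- (1 - o):d[a]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Copy and paste slice masks
#'
#' `copy_slice` returns the slice's mask as an independent buffer;
#' `paste_slice` replaces the target slice with a buffered mask.
#'
#' @param voi a `vv_voi`.
#' @param from_index,to_index 0-based slice indices.
#' @param buffer a 2D 0/1 matrix from `copy_slice`.
#' @return `copy_slice`: the buffer matrix; `paste_slice`: the modified VOI.
#' @export
copy_slice <- function(voi, from_index) {
  check_that(is_voi(voi), "voi must be a vv_voi")
  k <- check_slice(voi, from_index)
  plane_of(voi, k)
}

#' @rdname copy_slice
#' @export
paste_slice <- function(voi, to_index, buffer) {
  check_that(is_voi(voi), "voi must be a vv_voi")
  k <- check_slice(voi, to_index)
  check_that(all(dim(buffer) == dim(voi$mask)[1:2]),
             "buffer shape does not match the in-plane grid")
  with_plane(voi, k, buffer)
}

#' Persist a VOI as a gzipped NIfTI (.voi)
#'
#' The `.voi` file is a standard gzipped NIfTI-1 with uint8 datatype and the
#' reference affine — renamed to `.nii.gz` it opens in any NIfTI reader.
#'
#' @param voi a `vv_voi`.
#' @param path output path (conventionally `.voi`).
#' @return `path` (`load_voi` returns the `vv_voi`).
#' @export
save_voi <- function(voi, path) {
  check_that(is_voi(voi), "voi must be a vv_voi")
  write_nifti(voi_as_volume(voi), path, gzipped = TRUE)
  invisible(path)
}

#' @rdname save_voi
#' @export
load_voi <- function(path) {
  vol <- read_volume(path)
  new_voi(vol$data != 0, affine = vol$affine)
}
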