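# Slice extraction and mosaic composition.
#
# Orientation conventions: axial/coronal/sagittal are defined on the
# canonical RAS volume (fixed third/second/first voxel axis respectively).
# Display planes put the first remaining axis along the columns and the
# second along the rows, with the top row at the maximum of the vertical
# axis (anterior up for axial, superior up for coronal/sagittal).  In image
# space every voxel is an equal-sized square of `scale` screen pixels —
# anisotropy stays visible.  In world space the scene is first resliced
# (trilinear) onto an isotropic grid whose spacing is the smallest source
# voxel dimension.

.axis_num <- c(sagittal = 1L, coronal = 2L, axial = 3L)

#' Mosaic layout specification
#'
#' @param axis `"axial"`, `"coronal"` or `"sagittal"`.
#' @param slices ordered vector of slice positions — 0-based indices in image
#'   space, world mm along the axis in world space.  Need not be equidistant.
#' @param columns tiles per row.
#' @param overlap_fraction horizontal overlap between adjacent tiles, in
#'   `[0, 0.9]`: placement advances by `tile_width * (1 - overlap_fraction)`.
#' @param space `"image"` or `"world"`.
#' @param crosshair optional world xyz to mark.
#' @param scale screen pixels per voxel (positive integer).
#' @return A `mosaic_spec` list.
#' @export
mosaic_spec <- function(axis = "axial", slices, columns = length(slices),
                        overlap_fraction = 0, space = "image",
                        crosshair = NULL, scale = 1L) {
  check_that(axis %in% names(.axis_num), "axis must be axial, coronal or sagittal")
  check_that(length(slices) >= 1, "slices must be nonempty")
  check_that(is_scalar_number(columns) && columns >= 1, "columns must be positive")
  check_that(is_scalar_number(overlap_fraction) &&
               overlap_fraction >= 0 && overlap_fraction <= 0.9,
             "overlap_fraction must be in [0, 0.9]")
  check_that(space %in% c("image", "world"), "space must be image or world")
  check_that(is_scalar_number(scale) && scale >= 1 && scale == floor(scale),
             "scale must be a positive integer")
  structure(list(axis = axis, slices = slices, columns = as.integer(columns),
                 overlap_fraction = overlap_fraction, space = space,
                 crosshair = crosshair, scale = as.integer(scale)),
            class = "mosaic_spec")
}

# Canonicalize all scene layers; in world space additionally reslice onto a
# common isotropic grid.  Returns list(base_vol, overlay list(vol, layer)).
scene_grids <- function(sc, space) {
  base_vol <- canonical_ras(sc$base$volume)
  ovs <- lapply(sc$overlays, function(ov) canonical_ras(ov$volume))
  if (space == "world") {
    grid <- world_grid_for(base_vol)
    base_vol <- reslice_world(base_vol, grid, "trilinear")
    ovs <- lapply(ovs, reslice_world, target = grid, interp = "trilinear")
  } else {
    for (ov in ovs)
      check_that(all(dim(ov$data) == dim(base_vol$data)),
                 "image-space overlays must share the base volume grid")
  }
  list(base = base_vol, overlays = ovs)
}

# value plane of one canonical volume: rows/cols per the display convention
value_plane <- function(data, axis, index) {
  d <- dim(data)
  if (index < 0 || index > d[axis] - 1)
    vv_validation_error(sprintf("slice %d out of range: valid range is 0..%d",
                                index, d[axis] - 1))
  pl <- switch(axis,
               data[index + 1L, , , drop = TRUE],      # sagittal: cols y, rows z
               data[, index + 1L, , drop = TRUE],      # coronal:  cols x, rows z
               data[, , index + 1L, drop = TRUE])      # axial:    cols x, rows y
  dim(pl) <- switch(axis, d[2:3], d[c(1, 3)], d[1:2])
  m <- t(pl)
  m[rev(seq_len(nrow(m))), , drop = FALSE]
}

# color one layer's value plane: base -> RGB, overlay -> RGBA w/ threshold
layer_plane <- function(layer, vals, overlay) {
  norm <- window_intensity(vals, layer$display_min, layer$display_max)
  rgba <- apply_lut(norm, layer$lut)
  if (overlay) {
    alpha <- rgba[, , 4]
    alpha[vals < layer$display_min] <- 0L   # sub-threshold voxels invisible
    rgba[, , 4] <- alpha
    rgba
  } else {
    rgba[, , 1:3, drop = FALSE]
  }
}

#' Extract one windowed, colored, blended slice of a scene
#'
#' @param sc a [scene()] (a bare [windowed_layer()] or `vv_volume` is
#'   promoted to a single-layer scene).
#' @param axis `"axial"`, `"coronal"` or `"sagittal"`.
#' @param position 0-based slice index (image space) or world mm along the
#'   axis (world space).
#' @param space `"image"` (raw grid, no resampling) or `"world"` (isotropic
#'   trilinear reslice).
#' @param scale screen pixels per voxel.
#' @return RGB integer array (rows x cols x 3, 0..255).
#' @export
extract_slice <- function(sc, axis = "axial", position = 0, space = "image",
                          scale = 1L) {
  sc <- as_scene(sc)
  ax <- .axis_num[[axis]]
  g <- scene_grids(sc, space)
  index <- if (space == "world") {
    # the world grid is diagonal: invert the axis in isolation
    aff <- g$base$affine
    as.integer(round_half_away((position - aff[ax, 4]) / aff[ax, ax]))
  } else {
    as.integer(round_half_away(position))
  }
  base_rgb <- layer_plane(sc$base, value_plane(g$base$data, ax, index), overlay = FALSE)
  ovs <- list()
  for (q in seq_along(g$overlays)) {
    vals <- value_plane(g$overlays[[q]]$data, ax, index)
    ovs[[q]] <- list(rgba = layer_plane(sc$overlays[[q]], vals, overlay = TRUE),
                     opacity = sc$overlays[[q]]$opacity)
  }
  img <- blend_layers(base_rgb, ovs)
  if (scale > 1L) img <- upscale_rgb(img, scale)
  img
}

as_scene <- function(x) {
  if (inherits(x, "vv_scene")) return(x)
  if (inherits(x, "vv_layer")) return(scene(x))
  if (is_volume(x)) return(scene(windowed_layer(x)))
  vv_validation_error("expected a vv_scene, windowed_layer or vv_volume")
}

upscale_rgb <- function(img, scale) {
  d <- dim(img)
  out <- array(0, dim = c(d[1] * scale, d[2] * scale, 3L))
  for (ch in 1:3)
    out[, , ch] <- kronecker(img[, , ch], matrix(1L, scale, scale))
  storage.mode(out) <- "integer"
  out
}

#' Compose a slice mosaic
#'
#' Tiles are laid row-major into `ceil(n / columns)` rows; horizontal
#' placement advances by `tile_width * (1 - overlap_fraction)` so adjacent
#' tiles can partially overlap.  Later tiles paint over earlier ones where
#' they overlap, with zero-intensity (black) pixels treated as transparent —
#' reproducing the look of overlapping brain slices on a black background.
#'
#' @param sc a [scene()] (or layer/volume, promoted).
#' @param spec a [mosaic_spec()].
#' @return RGB integer array (0..255).
#' @export
compose_mosaic <- function(sc, spec) {
  check_that(inherits(spec, "mosaic_spec"), "spec must be a mosaic_spec")
  sc <- as_scene(sc)
  tiles <- lapply(spec$slices, function(pos)
    extract_slice(sc, spec$axis, pos, spec$space, spec$scale))
  if (!is.null(spec$crosshair))
    tiles <- mark_crosshair(tiles, sc, spec)
  th <- dim(tiles[[1]])[1]; tw <- dim(tiles[[1]])[2]
  n <- length(tiles)
  ncol_ <- min(spec$columns, n)
  nrow_ <- ceiling(n / ncol_)
  step <- tw * (1 - spec$overlap_fraction)
  width <- as.integer(round((ncol_ - 1) * step)) + tw
  canvas <- array(0L, dim = c(nrow_ * th, width, 3L))
  for (t_i in seq_len(n)) {
    row <- (t_i - 1L) %/% ncol_
    col <- (t_i - 1L) %% ncol_
    r0 <- row * th
    c0 <- as.integer(round(col * step))
    tile <- tiles[[t_i]]
    region <- canvas[r0 + seq_len(th), c0 + seq_len(tw), , drop = FALSE]
    nonbg <- tile[, , 1] > 0L | tile[, , 2] > 0L | tile[, , 3] > 0L
    for (ch in 1:3) {
      rc <- region[, , ch]
      tc <- tile[, , ch]
      rc[nonbg] <- tc[nonbg]
      region[, , ch] <- rc
    }
    canvas[r0 + seq_len(th), c0 + seq_len(tw), ] <- region
  }
  canvas
}

# draw a 1-pixel crosshair on the tile whose slice contains the world point
mark_crosshair <- function(tiles, sc, spec) {
  ax <- .axis_num[[spec$axis]]
  base <- canonical_ras(sc$base$volume)
  if (spec$space == "world") base <- reslice_world(base, world_grid_for(base), "nearest")
  ijk <- round_half_away(world_to_voxel(base, spec$crosshair))
  d <- dim(base$data)
  inplane <- setdiff(1:3, ax)
  for (t_i in seq_along(spec$slices)) {
    pos <- spec$slices[t_i]
    index <- if (spec$space == "world") {
      p <- spec$crosshair; p[ax] <- pos
      round_half_away(world_to_voxel(base, p)[ax])
    } else round_half_away(pos)
    if (index != ijk[ax]) next
    tile <- tiles[[t_i]]
    s <- spec$scale
    colpix <- (ijk[inplane[1]] + 0.5) * s          # column position
    rowpix <- (d[inplane[2]] - 1 - ijk[inplane[2]] + 0.5) * s
    rr <- clamp(as.integer(ceiling(rowpix)), 1L, dim(tile)[1])
    cc <- clamp(as.integer(ceiling(colpix)), 1L, dim(tile)[2])
    tile[rr, , ] <- 255L
    tile[, cc, ] <- 255L
    tiles[[t_i]] <- tile
  }
  tiles
}

#' Save / load an 8-bit RGB image as PNG
#'
#' Lossless round trip: the reread pixel array equals the written one.
#' Only 8-bit images are accepted; higher bit depths are refused.
#'
#' @param image RGB (or gray) integer array with values in 0..255.
#' @param path output path.
#' @return `path`, invisibly (`read_png` returns the integer image).
#' @export
save_png <- function(image, path) {
  if (max(image) > 255 || min(image) < 0)
    vv_validation_error("save_png expects 8-bit values in 0..255; 16-bit images are not supported")
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' @rdname save_png
#' @export
read_png <- function(path) {
  img <- png::readPNG(path)
  out <- round_half_away(img * 255)
  storage.mode(out) <- "integer"
  out
}
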