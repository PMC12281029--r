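# Intensity windowing, color lookup tables, translucent blending,
# legacy 8-bit palette emulation, and colorbars.
#
# Images flowing through this module are integer arrays in 0..255:
# RGB planes are H x W x 3, RGBA planes H x W x 4.  Compositing happens in
# floating point and is rounded to 8 bits once, at the end.

#' Built-in color lookup tables
#'
#' Returns a 256 x 4 integer matrix (columns R, G, B, A in 0..255).  The
#' ramps shipped here are documented replacements for a desktop viewer's
#' scheme menu: `grayscale`, `red`, `blue`, `hot` (black-red-yellow-white),
#' `cool` (black-blue-cyan), `warm` (blue-to-red diverging ramp used for
#' incidence overlays) and `viridis` (a perceptually ordered ramp).
#'
#' @param name LUT name.
#' @return 256 x 4 integer matrix of class `vv_lut`.
#' @export
color_lut <- function(name = c("grayscale", "red", "blue", "hot", "cool",
                               "warm", "viridis")) {
  name <- match.arg(name)
  t01 <- seq(0, 1, length.out = 256)
  ramp <- function(r, g, b) cbind(r, g, b)
  rgb01 <- switch(name,
    grayscale = ramp(t01, t01, t01),
    red = ramp(t01, 0 * t01, 0 * t01),
    blue = ramp(0 * t01, 0 * t01, t01),
    hot = ramp(clamp(3 * t01, 0, 1), clamp(3 * t01 - 1, 0, 1), clamp(3 * t01 - 2, 0, 1)),
    cool = ramp(0 * t01, clamp(2 * t01 - 1, 0, 1), clamp(2 * t01, 0, 1)),
    warm = ramp(clamp(2 * t01, 0, 1), 0.2 + 0.3 * sin(pi * t01)^2, clamp(2 - 2 * t01, 0, 1)),
    viridis = {
      # compact piecewise-linear approximation of a perceptual ramp
      anchors <- matrix(c(
        0.267, 0.005, 0.329,
        0.283, 0.141, 0.458,
        0.254, 0.265, 0.530,
        0.207, 0.372, 0.553,
        0.164, 0.471, 0.558,
        0.128, 0.567, 0.551,
        0.135, 0.659, 0.518,
        0.267, 0.749, 0.441,
        0.478, 0.821, 0.318,
        0.741, 0.873, 0.150,
        0.993, 0.906, 0.144), ncol = 3, byrow = TRUE)
      tt <- seq(0, 1, length.out = nrow(anchors))
      cbind(stats::approx(tt, anchors[, 1], t01)$y,
            stats::approx(tt, anchors[, 2], t01)$y,
            stats::approx(tt, anchors[, 3], t01)$y)
    })
  lut <- cbind(round_half_away(rgb01 * 255), 255L)
  storage.mode(lut) <- "integer"
  dimnames(lut) <- list(NULL, c("R", "G", "B", "A"))
  structure(lut, class = "vv_lut", lut_name = name)
}

#' Read/write a LUT as 256-line CSV (index,R,G,B,A)
#' @param lut a 256 x 4 LUT matrix.
#' @param path CSV path.
#' @return `path` (write) or the LUT (read).
#' @export
write_lut_csv <- function(lut, path) {
  df <- data.frame(index = 0:255, R = lut[, 1], G = lut[, 2], B = lut[, 3], A = lut[, 4])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lut_csv
#' @export
read_lut_csv <- function(path) {
  df <- utils::read.csv(path)
  check_that(nrow(df) == 256L, "a LUT CSV must have exactly 256 entries")
  lut <- as.matrix(df[order(df$index), c("R", "G", "B", "A")])
  storage.mode(lut) <- "integer"
  structure(unname(lut), class = "vv_lut", dimnames = list(NULL, c("R", "G", "B", "A")))
}

#' Window an intensity into [0, 1]
#'
#' Linear contrast/brightness rescale with clamping:
#' `clamp((value - display_min) / (display_max - display_min), 0, 1)`.
#'
#' @param value numeric vector/array of intensities.
#' @param display_min,display_max window bounds, `display_min < display_max`.
#' @return Values in `[0, 1]`, same shape as `value`.
#' @export
window_intensity <- function(value, display_min, display_max) {
  check_that(display_min < display_max, "display_min must be < display_max")
  out <- clamp((value - display_min) / (display_max - display_min), 0, 1)
  if (!is.null(dim(value))) dim(out) <- dim(value)
  out
}

#' Apply a color LUT to a normalized plane
#'
#' Index = `round(normalized * 255)` (half away from zero), then a per-pixel
#' table lookup.
#'
#' @param normalized numeric plane (values in `[0, 1]`).
#' @param lut 256 x 4 LUT.
#' @return RGBA integer array of shape `dim(normalized) x 4`.
#' @export
apply_lut <- function(normalized, lut) {
  check_that(all(normalized >= 0 & normalized <= 1), "normalized values must be in [0, 1]")
  d <- dim(normalized) %||% length(normalized)
  idx <- as.integer(round_half_away(as.numeric(normalized) * 255)) + 1L
  out <- array(0L, dim = c(d, 4L))
  flat <- lut[idx, , drop = FALSE]
  npix <- prod(d)
  for (ch in 1:4) out[npix * (ch - 1L) + seq_len(npix)] <- flat[, ch]
  out
}

#' A windowed, colored, stackable display layer
#'
#' @param volume a `vv_volume`.
#' @param display_min,display_max window bounds (default: data range).
#' @param lut a 256 x 4 LUT matrix (see [color_lut()]).
#' @param opacity layer opacity in `[0, 1]`.
#' @return A `vv_layer` list.
#' @export
windowed_layer <- function(volume, display_min = NULL, display_max = NULL,
                           lut = color_lut("grayscale"), opacity = 1) {
  check_that(is_volume(volume), "volume must be a vv_volume")
  rng <- range(volume$data)
  if (is.null(display_min)) display_min <- rng[1]
  if (is.null(display_max)) display_max <- if (rng[2] > display_min) rng[2] else display_min + 1
  check_that(display_min < display_max, "display_min must be < display_max")
  check_that(is_scalar_number(opacity) && opacity >= 0 && opacity <= 1,
             "opacity must be in [0, 1]")
  structure(list(volume = volume, display_min = display_min,
                 display_max = display_max, lut = lut, opacity = opacity),
            class = "vv_layer")
}

#' A display scene: one base layer plus ordered overlays
#'
#' Overlay voxels whose value falls below the overlay's `display_min` are
#' fully transparent, so statistical maps show only supra-threshold voxels
#' over the anatomy.
#'
#' @param base a [windowed_layer()].
#' @param overlays list of [windowed_layer()]s, composited in order.
#' @return A `vv_scene` list.
#' @export
scene <- function(base, overlays = list()) {
  check_that(inherits(base, "vv_layer"), "base must be a windowed_layer")
  for (ov in overlays)
    check_that(inherits(ov, "vv_layer"), "overlays must be windowed_layers")
  structure(list(base = base, overlays = overlays), class = "vv_scene")
}

#' Composite overlay planes onto a base plane
#'
#' Source-over compositing in list order, in floating point, rounded to
#' 8 bits once at the end: `out = src * a + dst * (1 - a)` with
#' `a = (pixel_alpha / 255) * opacity`.
#'
#' @param base RGB integer array (H x W x 3, 0..255).
#' @param overlays list of `list(rgba = <H x W x 4 plane>, opacity = <[0,1]>)`.
#' @return RGB integer array, same shape as `base`.
#' @export
blend_layers <- function(base, overlays = list()) {
  out <- array(as.numeric(base), dim = dim(base))
  for (ov in overlays) {
    rgba <- ov$rgba
    check_that(all(dim(rgba)[1:2] == dim(base)[1:2]),
               "overlay plane shape must match the base plane")
    a <- (rgba[, , 4] / 255) * ov$opacity
    for (ch in 1:3)
      out[, , ch] <- rgba[, , ch] * a + out[, , ch] * (1 - a)
  }
  out <- round_half_away(out)
  storage.mode(out) <- "integer"
  out
}

#' Legacy 8-bit palette emulation
#'
#' Reproduces the original memory-constrained display model: a 256-entry
#' palette holding 255 gray levels (indices 0..254) for the anatomy and one
#' reserved opaque entry (index 255) for the lesion.  Lesion voxels always
#' take the reserved color — there is no translucency in this mode, by
#' construction.
#'
#' @param base_layer a [windowed_layer()] for the anatomy.
#' @param lesion a `vv_voi` on the same grid (or `NULL`).
#' @param lesion_color length-3 RGB in 0..255 (default opaque red).
#' @return List with `index` (array of palette indices, same shape as the
#'   volume) and `palette` (256 x 3 RGB matrix).
#' @export
legacy_palette <- function(base_layer, lesion = NULL, lesion_color = c(255L, 0L, 0L)) {
  check_that(inherits(base_layer, "vv_layer"), "base_layer must be a windowed_layer")
  vol <- base_layer$volume
  if (!is.null(lesion)) {
    check_that(is_voi(lesion), "lesion must be a vv_voi")
    check_that(all(dim(lesion$mask) == dim(vol$data)),
               "lesion grid does not match the base volume grid")
  }
  norm <- window_intensity(vol$data, base_layer$display_min, base_layer$display_max)
  index <- round_half_away(norm * 254)           # 255 gray levels: 0..254
  if (!is.null(lesion)) index[lesion$mask == 1L] <- 255
  storage.mode(index) <- "integer"
  gray <- as.integer(round_half_away(seq(0, 254) * 255 / 254))
  palette <- rbind(cbind(gray, gray, gray), as.integer(lesion_color))
  dimnames(palette) <- list(NULL, c("R", "G", "B"))
  list(index = index, palette = unname(palette))
}

#' Render a colorbar image
#'
#' A vertical gradient sampling the LUT monotonically from `display_min`
#' (bottom row) to `display_max` (top row).  When the requested size leaves
#' room (width >= 16, height >= 64), the two endpoint values are printed
#' beside the bar with a built-in 3x5 pixel font; the bar itself occupies
#' the columns reported in the `"bar_cols"` attribute.
#'
#' @param lut a 256 x 4 LUT.
#' @param display_min,display_max window endpoints (labels).
#' @param size `c(width, height)` in pixels.
#' @return RGB integer array (height x width x 3) with attribute `bar_cols`.
#' @export
colorbar <- function(lut, display_min, display_max, size = c(24L, 128L)) {
  check_that(display_min < display_max, "display_min must be < display_max")
  w <- as.integer(size[1]); h <- as.integer(size[2])
  check_that(w >= 1 && h >= 1, "colorbar size must be positive")
  labeled <- w >= 16L && h >= 64L
  bar_w <- if (labeled) max(4L, w %/% 3L) else w
  img <- array(0L, dim = c(h, w, 3L))
  # row 1 is the top of the image; bottom row samples entry 0
  idx <- if (h == 1L) 255L else as.integer(round_half_away((h:1 - 1) / (h - 1) * 255))
  for (ch in 1:3) img[, seq_len(bar_w), ch] <- matrix(lut[idx + 1L, ch], h, bar_w)
  if (labeled) {
    img <- draw_label(img, fmt_num(display_max, 4), row = 2L, col = bar_w + 2L)
    img <- draw_label(img, fmt_num(display_min, 4), row = h - 6L, col = bar_w + 2L)
  }
  attr(img, "bar_cols") <- seq_len(bar_w)
  img
}

# 3x5 bitmap glyphs for colorbar labels (digits and numeric punctuation)
.vv_font <- list(
  "0" = c("111","101","101","101","111"), "1" = c("010","110","010","010","111"),
  "2" = c("111","001","111","100","111"), "3" = c("111","001","111","001","111"),
  "4" = c("101","101","111","001","001"), "5" = c("111","100","111","001","111"),
  "6" = c("111","100","111","101","111"), "7" = c("111","001","010","010","010"),
  "8" = c("111","101","111","101","111"), "9" = c("111","101","111","001","111"),
  "." = c("000","000","000","000","010"), "-" = c("000","000","111","000","000"),
  "e" = c("000","111","110","100","111"), "+" = c("000","010","111","010","000"))

draw_label <- function(img, text, row, col, color = c(255L, 255L, 255L)) {
  h <- dim(img)[1]; w <- dim(img)[2]
  for (chr in strsplit(text, "")[[1]]) {
    glyph <- .vv_font[[chr]]
    if (!is.null(glyph)) {
      for (gr in 1:5) {
        bits <- strsplit(glyph[gr], "")[[1]] == "1"
        for (gc in 1:3) {
          r <- row + gr - 1L; cc <- col + gc - 1L
          if (bits[gc] && r >= 1 && r <= h && cc >= 1 && cc <= w)
            img[r, cc, ] <- color
        }
      }
    }
    col <- col + 4L
  }
  img
}
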