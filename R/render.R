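# CPU orthographic ray-cast volume rendering with optional slice cut-outs.
#
# Rays are cast through the canonical RAS volume at the requested view
# angles; samples are trilinear at `step_mm` spacing.  Ray/volume
# intersection uses the slab method in voxel coordinates and sampling starts
# at the entry face plus half a step.  The transfer function is deliberately
# simple (windowed intensity, and for composite mode per-sample alpha =
# windowed intensity x opacity_gain): a rudimentary renderer by design.

#' Rendering specification
#'
#' @param azimuth view azimuth in degrees (rotation about the world z axis).
#' @param elevation view elevation in degrees above the axial plane.
#' @param mode `"mip"` (maximum intensity projection) or `"composite"`
#'   (front-to-back alpha accumulation, terminating at alpha >= 0.99).
#' @param step_mm sampling step along each ray, in mm (> 0).
#' @param opacity_gain per-sample alpha multiplier in (0, 1] (composite mode).
#' @param cutout optional axis-aligned box in voxel coords,
#'   `list(min = c(i,j,k), max = c(i,j,k))` (inclusive voxel index bounds);
#'   voxels inside are treated as empty.  A box with any `max < min` is
#'   empty (zero extent).
#' @param image_size `c(width, height)` in pixels.
#' @return A `render_spec` list.
#' @export
render_spec <- function(azimuth = 45, elevation = 20, mode = c("mip", "composite"),
                        step_mm = 1, opacity_gain = 0.5, cutout = NULL,
                        image_size = c(96L, 96L)) {
  mode <- match.arg(mode)
  check_that(is_scalar_number(step_mm) && step_mm > 0, "step_mm must be > 0")
  check_that(is_scalar_number(opacity_gain) && opacity_gain > 0 && opacity_gain <= 1,
             "opacity_gain must be in (0, 1]")
  check_that(length(image_size) == 2L && all(image_size >= 1),
             "image_size must be two positive integers")
  structure(list(azimuth = azimuth, elevation = elevation, mode = mode,
                 step_mm = step_mm, opacity_gain = opacity_gain,
                 cutout = cutout, image_size = as.integer(image_size)),
            class = "render_spec")
}

# orthonormal view basis from azimuth/elevation (degrees)
view_basis <- function(azimuth, elevation) {
  az <- azimuth * pi / 180
  el <- elevation * pi / 180
  f <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))  # scene -> camera
  up0 <- if (abs(f[3]) > 0.999) c(0, 1, 0) else c(0, 0, 1)
  right <- c(f[2] * up0[3] - f[3] * up0[2],
             f[3] * up0[1] - f[1] * up0[3],
             f[1] * up0[2] - f[2] * up0[1])
  right <- right / sqrt(sum(right^2))
  up <- c(right[2] * f[3] - right[3] * f[2],
          right[3] * f[1] - right[1] * f[3],
          right[1] * f[2] - right[2] * f[1])
  list(f = f, right = right, up = up)
}

# per-point scene color (nearest-neighbor), used for cut-out face texturing;
# pts are base-grid voxel indices (n x 3)
scene_color_at <- function(sc, base_vol, ov_vols, pts) {
  vals <- sample_volume(base_vol, pts, "nearest")
  norm <- window_intensity(vals, sc$base$display_min, sc$base$display_max)
  rgba <- apply_lut(matrix(norm, ncol = 1), sc$base$lut)
  col <- matrix(as.numeric(rgba[, 1, 1:3]), ncol = 3)
  if (length(ov_vols)) {
    xyz <- voxel_to_world(base_vol, pts)
    for (q in seq_along(ov_vols)) {
      layer <- sc$overlays[[q]]
      ov_pts <- world_to_voxel(ov_vols[[q]], xyz)
      v <- sample_volume(ov_vols[[q]], ov_pts, "nearest")
      nrm <- window_intensity(v, layer$display_min, layer$display_max)
      orgba <- apply_lut(matrix(nrm, ncol = 1), layer$lut)
      a <- (orgba[, 1, 4] / 255) * layer$opacity
      a[v < layer$display_min] <- 0
      for (ch in 1:3)
        col[, ch] <- orgba[, 1, ch] * a + col[, ch] * (1 - a)
    }
  }
  col
}

#' Ray-cast a scene to an RGB image
#'
#' Orthographic projection.  `mip` keeps each ray's maximum windowed base
#' intensity and colors it through the base LUT; `composite` accumulates
#' front-to-back with per-sample alpha = windowed intensity x
#' `opacity_gain`, stopping a ray once its accumulated alpha reaches 0.99.
#' Overlay layers are composited onto each sample's color where
#' supra-threshold.  Voxels inside the cut-out box are skipped.
#'
#' @param sc a [scene()] (or layer/volume, promoted).
#' @param spec a [render_spec()].
#' @return RGB integer array (height x width x 3, 0..255).
#' @export
raycast <- function(sc, spec) {
  sc <- as_scene(sc)
  check_that(inherits(spec, "render_spec"), "spec must be a render_spec")
  base_vol <- canonical_ras(sc$base$volume)
  ov_vols <- lapply(sc$overlays, function(ov) canonical_ras(ov$volume))
  st <- raymarch_setup(sc, spec, base_vol)
  raymarch(sc, spec, base_vol, ov_vols, st, hybrid = FALSE)
}

#' Hybrid rendering: ray casting with textured cut-out faces
#'
#' As [raycast()], but rays leaving the cut-out box strike an opaque surface
#' textured with the scene's windowed/blended orthogonal slice at the exposed
#' face plane, combining the 3D context with exact 2D slices.
#'
#' @param sc a [scene()].
#' @param spec a [render_spec()]; `cutout` must be present.
#' @param reveal_layers_in_cutout texture the exposed faces with the full
#'   layered scene (`TRUE`) or the base layer only.
#' @return RGB integer array.
#' @export
hybrid_render <- function(sc, spec, reveal_layers_in_cutout = TRUE) {
  sc <- as_scene(sc)
  check_that(inherits(spec, "render_spec"), "spec must be a render_spec")
  check_that(!is.null(spec$cutout), "hybrid_render requires a cutout box")
  base_vol <- canonical_ras(sc$base$volume)
  ov_vols <- lapply(sc$overlays, function(ov) canonical_ras(ov$volume))
  if (!reveal_layers_in_cutout) ov_vols <- list()
  st <- raymarch_setup(sc, spec, base_vol)
  raymarch(sc, spec, base_vol, ov_vols, st, hybrid = TRUE)
}

raymarch_setup <- function(sc, spec, base_vol) {
  shape <- dim(base_vol$data)
  W <- spec$image_size[1]; H <- spec$image_size[2]
  corners <- as.matrix(expand.grid(c(-0.5, shape[1] - 0.5),
                                   c(-0.5, shape[2] - 0.5),
                                   c(-0.5, shape[3] - 0.5)))
  wc <- voxel_to_world(base_vol, corners)
  center <- colMeans(wc)
  radius <- max(sqrt(rowSums(sweep(wc, 2, center)^2)))
  vb <- view_basis(spec$azimuth %% 360, spec$elevation)
  pix <- 2 * radius / min(W, H)
  px <- rep(seq_len(W), each = H)
  py <- rep(seq_len(H), times = W)
  sx <- (px - (W + 1) / 2) * pix
  sy <- ((H + 1) / 2 - py) * pix
  O <- cbind(center[1] + vb$right[1] * sx + vb$up[1] * sy + vb$f[1] * radius,
             center[2] + vb$right[2] * sx + vb$up[2] * sy + vb$f[2] * radius,
             center[3] + vb$right[3] * sx + vb$up[3] * sy + vb$f[3] * radius)
  Minv <- solve(base_vol$affine[1:3, 1:3])
  Ov <- world_to_voxel(base_vol, O)
  dv <- as.numeric(Minv %*% (-vb$f))      # voxel-space direction per world mm
  slab <- function(lo, hi, o, d) {
    if (abs(d) < 1e-12) {
      t0 <- ifelse(o >= lo & o <= hi, -Inf, Inf)
      t1 <- ifelse(o >= lo & o <= hi, Inf, -Inf)
    } else {
      ta <- (lo - o) / d; tb <- (hi - o) / d
      t0 <- pmin(ta, tb); t1 <- pmax(ta, tb)
    }
    cbind(t0, t1)
  }
  t_lo <- rep(-Inf, W * H); t_hi <- rep(Inf, W * H)
  for (a in 1:3) {
    s <- slab(-0.5, shape[a] - 0.5, Ov[, a], dv[a])
    t_lo <- pmax(t_lo, s[, 1]); t_hi <- pmin(t_hi, s[, 2])
  }
  box <- spec$cutout
  bt <- NULL
  if (!is.null(box) && all(box$max >= box$min)) {
    b_lo <- rep(-Inf, W * H); b_hi <- rep(Inf, W * H)
    for (a in 1:3) {
      s <- slab(box$min[a] - 0.5, box$max[a] + 0.5, Ov[, a], dv[a])
      b_lo <- pmax(b_lo, s[, 1]); b_hi <- pmin(b_hi, s[, 2])
    }
    bt <- list(lo = b_lo, hi = b_hi, hit = b_hi > b_lo)
  }
  list(W = W, H = H, Ov = Ov, dv = dv, t_lo = t_lo, t_hi = t_hi, bt = bt,
       px = px, py = py)
}

raymarch <- function(sc, spec, base_vol, ov_vols, st, hybrid) {
  N <- st$W * st$H
  valid <- st$t_hi > st$t_lo
  t0 <- ifelse(valid, st$t_lo, 0) + spec$step_mm / 2
  nsteps <- if (any(valid))
    max(0L, ceiling((max(st$t_hi[valid] - st$t_lo[valid])) / spec$step_mm)) else 0L
  mip_val <- numeric(N)
  accA <- numeric(N)
  accC <- matrix(0, N, 3)
  face_pending <- if (hybrid && !is.null(st$bt)) st$bt$hit & valid else rep(FALSE, N)
  shape <- dim(base_vol$data)
  in_box <- function(P) {
    b <- spec$cutout
    if (is.null(st$bt)) return(rep(FALSE, nrow(P)))
    P[, 1] >= b$min[1] - 0.5 & P[, 1] <= b$max[1] + 0.5 &
    P[, 2] >= b$min[2] - 0.5 & P[, 2] <= b$max[2] + 0.5 &
    P[, 3] >= b$min[3] - 0.5 & P[, 3] <= b$max[3] + 0.5
  }
  xyz_cache <- NULL
  for (k in seq_len(nsteps)) {
    tv <- t0 + (k - 1L) * spec$step_mm      # per-ray: entry + half step + k steps
    active <- valid & tv <= st$t_hi & accA < 0.99
    if (!any(active)) break
    # hybrid: rays crossing the box exit face strike the textured surface
    if (hybrid && any(face_pending)) {
      hitting <- face_pending & active & tv >= st$bt$hi & st$bt$hi >= st$t_lo
      if (any(hitting)) {
        Pf <- st$Ov[hitting, , drop = FALSE] +
          outer(st$bt$hi[hitting], st$dv)
        fcol <- scene_color_at(sc, base_vol, ov_vols,
                               clamp_to_grid(Pf, shape))
        w <- 1 - accA[hitting]
        accC[hitting, ] <- accC[hitting, ] + w * fcol
        accA[hitting] <- 1
        face_pending[hitting] <- FALSE
        mip_val[hitting] <- NA          # face replaces MIP for these rays
      }
    }
    active <- active & accA < 0.99
    if (!any(active)) next
    P <- st$Ov[active, , drop = FALSE] + outer(tv[active], st$dv)
    skip <- in_box(P)
    use <- which(active)[!skip]
    if (!length(use)) next
    Pu <- P[!skip, , drop = FALSE]
    v <- sample_volume(base_vol, Pu, "trilinear")
    w <- window_intensity(v, sc$base$display_min, sc$base$display_max)
    if (spec$mode == "mip") {
      mip_val[use] <- pmax(mip_val[use], w, na.rm = FALSE)
    } else {
      rgba <- apply_lut(matrix(w, ncol = 1), sc$base$lut)
      col <- matrix(as.numeric(rgba[, 1, 1:3]), ncol = 3)
      if (length(ov_vols)) {
        xyz <- voxel_to_world(base_vol, Pu)
        for (q in seq_along(ov_vols)) {
          layer <- sc$overlays[[q]]
          ovv <- sample_volume(ov_vols[[q]], world_to_voxel(ov_vols[[q]], xyz),
                               "trilinear")
          onrm <- window_intensity(ovv, layer$display_min, layer$display_max)
          orgba <- apply_lut(matrix(onrm, ncol = 1), layer$lut)
          a <- (orgba[, 1, 4] / 255) * layer$opacity
          a[ovv < layer$display_min] <- 0
          for (ch in 1:3)
            col[, ch] <- orgba[, 1, ch] * a + col[, ch] * (1 - a)
        }
      }
      a <- clamp(w * spec$opacity_gain, 0, 1)
      wgt <- (1 - accA[use]) * a
      accC[use, ] <- accC[use, ] + wgt * col
      accA[use] <- accA[use] + wgt
    }
  }
  img <- array(0L, dim = c(st$H, st$W, 3L))
  if (spec$mode == "mip") {
    mv <- mip_val
    face_rays <- is.na(mv)
    mv[face_rays] <- 0
    rgba <- apply_lut(matrix(mv, ncol = 1), sc$base$lut)
    col <- matrix(as.numeric(rgba[, 1, 1:3]), ncol = 3)
    if (any(face_rays)) col[face_rays, ] <- accC[face_rays, ]
  } else {
    col <- accC
  }
  col <- round_half_away(clamp(col, 0, 255))
  for (ch in 1:3)
    img[cbind(st$py, st$px, ch)] <- as.integer(col[, ch])
  img
}

clamp_to_grid <- function(P, shape) {
  cbind(clamp(P[, 1], 0, shape[1] - 1),
        clamp(P[, 2], 0, shape[2] - 1),
        clamp(P[, 3], 0, shape[3] - 1))
}
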