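#' Phantom specification
#'
#' Describes a deterministic synthetic volume: grid shape, voxel size, a list
#' of painted primitives and additive Gaussian noise.  The same spec and seed
#' always produce bit-identical voxel data (Mersenne-Twister via
#' `set.seed(seed, kind = "Mersenne-Twister")`, so seeds are portable across
#' releases).
#'
#' @param shape 3 positive integers (voxels).
#' @param voxel_size 3 positive reals (mm).
#' @param primitives list of primitives, each a list with `kind` one of
#'   `"sphere"` (`center`, `radius`, `intensity`), `"box"` (`min`, `max`
#'   inclusive voxel corners, `intensity`) or `"linear_gradient"` (`direction`
#'   length-3, `intensity` = value per voxel step at unit direction).
#'   Coordinates are 0-based voxel indices.
#' @param noise_sigma nonnegative standard deviation of additive Gaussian
#'   noise.
#' @param seed integer PRNG seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(24L, 24L, 24L), voxel_size = c(1, 1, 1),
                         primitives = list(), noise_sigma = 0, seed = 1L) {
  check_that(length(shape) == 3L && all(shape >= 1) && all(shape == floor(shape)),
             "shape must be 3 positive integers")
  check_that(length(voxel_size) == 3L && all(voxel_size > 0),
             "voxel_size must be 3 positive reals")
  check_that(is_scalar_number(noise_sigma) && noise_sigma >= 0,
             "noise_sigma must be a nonnegative real")
  structure(list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
                 primitives = primitives, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Demonstration phantom specification
#'
#' A structured phantom used by the `fixtures` CLI command and the example
#' pipeline: an axial intensity gradient, a bright central sphere and an
#' off-center box, plus mild Gaussian noise.  Purely geometric — it emulates
#' contrast and structure, not anatomy.
#'
#' @param seed integer PRNG seed.
#' @param noise_sigma noise standard deviation (default 1).
#' @return A [phantom_spec()].
#' @export
demo_phantom_spec <- function(seed = 1L, noise_sigma = 1) {
  phantom_spec(
    shape = c(24L, 24L, 24L), voxel_size = c(1, 1, 1),
    primitives = list(
      list(kind = "linear_gradient", direction = c(0, 0, 1), intensity = 2),
      list(kind = "box", min = c(3, 3, 3), max = c(20, 20, 20), intensity = 30),
      list(kind = "sphere", center = c(12, 12, 12), radius = 7, intensity = 90),
      list(kind = "sphere", center = c(6, 16, 15), radius = 3, intensity = 60)),
    noise_sigma = noise_sigma, seed = seed)
}

# 0-based voxel index grids for a shape, as three conforming arrays
index_grids <- function(shape) {
  list(
    i = array(rep(seq_len(shape[1]) - 1, times = shape[2] * shape[3]), dim = shape),
    j = array(rep(rep(seq_len(shape[2]) - 1, each = shape[1]), times = shape[3]), dim = shape),
    k = array(rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2]), dim = shape)
  )
}

#' Generate a phantom volume
#'
#' Paints the spec's primitives in order (later primitives overwrite earlier
#' ones where they overlap), then adds seeded Gaussian noise.  Sphere
#' membership is inclusive: a voxel belongs if its center is within `radius`
#' (Euclidean, voxel units) of the sphere center.  Noise is kept at full float
#' precision in memory; clamping to the datatype range happens only when a
#' writer serializes the volume.
#'
#' @param spec a [phantom_spec()].
#' @return A [new_volume()] with a diagonal affine scaled by `voxel_size`.
#' @export
make_phantom <- function(spec) {
  check_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  shape <- spec$shape
  data <- array(0, dim = shape)
  g <- index_grids(shape)
  for (p in spec$primitives) {
    kind <- p$kind %||% "sphere"
    if (kind == "sphere") {
      d2 <- (g$i - p$center[1])^2 + (g$j - p$center[2])^2 + (g$k - p$center[3])^2
      data[d2 <= p$radius^2] <- p$intensity
    } else if (kind == "box") {
      sel <- g$i >= p$min[1] & g$i <= p$max[1] &
             g$j >= p$min[2] & g$j <= p$max[2] &
             g$k >= p$min[3] & g$k <= p$max[3]
      data[sel] <- p$intensity
    } else if (kind == "linear_gradient") {
      dirn <- p$direction / sqrt(sum(p$direction^2))
      data <- data + p$intensity * (g$i * dirn[1] + g$j * dirn[2] + g$k * dirn[3])
    } else {
      vv_validation_error(paste("unknown primitive kind:", kind))
    }
  }
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed, kind = "Mersenne-Twister")
    data <- data + array(stats::rnorm(prod(shape), sd = spec$noise_sigma), dim = shape)
  }
  new_volume(float32_snap(data), voxel_size = spec$voxel_size, datatype = "float32",
             source_format = "synthetic",
             description = sprintf("voxview phantom seed=%d", spec$seed))
}

#' Generate a reproducible set of spherical lesions
#'
#' Draws `n` random spheres on `grid`'s geometry and returns them as binary
#' VOIs.  Centers are uniform over positions where the whole sphere fits
#' inside the grid; radii are uniform in `radius_range` (voxel units).
#'
#' @param n number of lesions (>= 1).
#' @param grid a `vv_volume` providing shape and affine.
#' @param seed integer seed.
#' @param radius_range length-2 numeric, min/max sphere radius in voxels.
#' @return List of `n` [new_voi()] objects.
#' @export
make_lesion_set <- function(n, grid, seed = 1L, radius_range = c(2, 4)) {
  check_that(is_scalar_number(n) && n >= 1, "n must be >= 1")
  check_that(is_volume(grid), "grid must be a vv_volume")
  shape <- dim(grid$data)
  rmax <- max(radius_range)
  if (any(2 * rmax + 1 > shape))
    vv_validation_error(sprintf(
      "radius %s does not fit inside grid of shape %s",
      fmt_num(rmax), paste(shape, collapse = "x")))
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  g <- index_grids(shape)
  out <- vector("list", n)
  for (s in seq_len(n)) {
    r <- stats::runif(1, radius_range[1], radius_range[2])
    ctr <- vapply(shape, function(nn) stats::runif(1, r, nn - 1 - r), numeric(1))
    d2 <- (g$i - ctr[1])^2 + (g$j - ctr[2])^2 + (g$k - ctr[3])^2
    out[[s]] <- new_voi(d2 <= r^2, reference = grid)
  }
  out
}

#' Serialize one phantom in every supported format
#'
#' Writes the identical phantom as `.nii`, `.nii.gz`, `.mgh`, `.mgz`,
#' AFNI `.HEAD`/`.BRIK`, `.nrrd` and legacy `.vtk`, and a JSON-lines manifest
#' (`manifest.jsonl`, one `{"path": ..., "format": ...}` record per file).
#' Every file re-reads to a voxel-identical array with an equivalent affine —
#' the cross-format consistency contract the format sniffing tests rely on.
#'
#' @param dir output directory (created if absent).
#' @param spec a [phantom_spec()].
#' @return Data frame with columns `path` and `format` (the manifest).
#' @export
write_fixture_suite <- function(dir, spec = phantom_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) vv_io_error(paste("cannot create directory:", dir))
  vol <- make_phantom(spec)
  entries <- list(
    list(path = file.path(dir, "phantom.nii"),
         format = "nifti1",    write = function(p) write_nifti(vol, p, gzipped = FALSE)),
    list(path = file.path(dir, "phantom.nii.gz"),
         format = "nifti1_gz", write = function(p) write_nifti(vol, p, gzipped = TRUE)),
    list(path = file.path(dir, "phantom.mgh"),
         format = "mgh",       write = function(p) write_mgh(vol, p, gzipped = FALSE)),
    list(path = file.path(dir, "phantom.mgz"),
         format = "mgz",       write = function(p) write_mgh(vol, p, gzipped = TRUE)),
    list(path = file.path(dir, "phantom+orig.HEAD"),
         format = "afni",      write = function(p) write_afni(vol, p)),
    list(path = file.path(dir, "phantom.nrrd"),
         format = "nrrd",      write = function(p) write_nrrd(vol, p)),
    list(path = file.path(dir, "phantom.vtk"),
         format = "vtk_legacy", write = function(p) write_vtk(vol, p))
  )
  for (e in entries) e$write(e$path)
  manifest <- data.frame(path = vapply(entries, `[[`, "", "path"),
                         format = vapply(entries, `[[`, "", "format"),
                         stringsAsFactors = FALSE)
  con <- file(file.path(dir, "manifest.jsonl"), "w")
  on.exit(close(con))
  for (r in seq_len(nrow(manifest))) {
    writeLines(jsonlite::toJSON(as.list(manifest[r, ]), auto_unbox = TRUE), con)
  }
  manifest
}
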