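# Shared builders and independent brute-force oracles used across tests.
# The oracles deliberately re-derive results by direct enumeration, never by
# calling the code path they check.

tiny_phantom <- function(shape = c(10, 12, 14), voxel_size = c(1, 1, 1),
                         seed = 1L, noise = 0) {
  make_phantom(phantom_spec(
    shape = shape, voxel_size = voxel_size,
    primitives = list(
      list(kind = "linear_gradient", direction = c(1, 0, 0), intensity = 1),
      list(kind = "sphere", center = (shape - 1) / 2, radius = min(shape) / 4,
           intensity = 50)),
    noise_sigma = noise, seed = seed))
}

empty_voi_on <- function(shape = c(16, 16, 6)) {
  new_voi(reference = make_phantom(phantom_spec(shape = shape)))
}

# brute-force sphere membership count (voxel centers, inclusive radius)
oracle_sphere_count <- function(shape, center, radius) {
  n <- 0L
  for (i in seq_len(shape[1]) - 1) for (j in seq_len(shape[2]) - 1)
    for (k in seq_len(shape[3]) - 1)
      if ((i - center[1])^2 + (j - center[2])^2 + (k - center[3])^2 <= radius^2)
        n <- n + 1L
  n
}

# brute-force min distance from every in-plane voxel center to a polyline
oracle_stroke_mask <- function(shape2, polyline, thickness) {
  hit <- matrix(FALSE, shape2[1], shape2[2])
  r <- thickness / 2
  nseg <- max(1L, nrow(polyline) - 1L)
  for (i in seq_len(shape2[1]) - 1) for (j in seq_len(shape2[2]) - 1) {
    dmin <- Inf
    for (s in seq_len(nseg)) {
      p1 <- polyline[s, ]; p2 <- polyline[min(s + 1, nrow(polyline)), ]
      d <- p2 - p1; len2 <- sum(d^2)
      tt <- if (len2 == 0) 0 else max(0, min(1, ((i - p1[1]) * d[1] + (j - p1[2]) * d[2]) / len2))
      q <- p1 + tt * d
      dmin <- min(dmin, sqrt((i - q[1])^2 + (j - q[2])^2))
    }
    if (dmin <= r) hit[i + 1, j + 1] <- TRUE
  }
  hit
}

# independent queue-based flood fill (one pixel popped at a time)
oracle_flood <- function(plane, seed_ij) {
  n <- nrow(plane); m <- ncol(plane)
  filled <- matrix(FALSE, n, m)
  queue <- list(seed_ij + 1L)
  if (plane[seed_ij[1] + 1L, seed_ij[2] + 1L] != 0) return(filled)
  filled[seed_ij[1] + 1L, seed_ij[2] + 1L] <- TRUE
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= n && q[2] >= 1 && q[2] <= m &&
          !filled[q[1], q[2]] && plane[q[1], q[2]] == 0) {
        filled[q[1], q[2]] <- TRUE
        queue[[length(queue) + 1L]] <- q
      }
    }
  }
  filled
}

# independent 3D region growth over a thresholded volume
oracle_grow <- function(data, seed, low, high, connectivity = 6) {
  d <- dim(data)
  inside <- data >= low & data <= high
  vis <- array(FALSE, dim = d)
  s <- seed + 1L
  if (!inside[s[1], s[2], s[3]]) return(vis)
  vis[s[1], s[2], s[3]] <- TRUE
  queue <- list(s)
  offs <- if (connectivity == 6) {
    list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    lapply(setdiff(seq_len(27), 14), function(r) as.numeric(g[r, ]))
  }
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (o in offs) {
      q <- p + o
      if (all(q >= 1) && all(q <= d) && !vis[q[1], q[2], q[3]] &&
          inside[q[1], q[2], q[3]]) {
        vis[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1L]] <- q
      }
    }
  }
  vis
}

# random binary mask with clustered structure
random_mask <- function(n, m, p = 0.3) {
  matrix(as.integer(stats::runif(n * m) < p), n, m)
}

digest_slice <- function(m) paste(as.integer(m), collapse = "")

# 0-based index grids, independent of the package's internal helper
index_grids_for_test <- function(shape) {
  list(i = array(rep(seq_len(shape[1]) - 1, times = shape[2] * shape[3]), dim = shape),
       j = array(rep(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[3]), dim = shape),
       k = array(rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2]), dim = shape))
}

expect_vv_error <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
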