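#' @useDynLib tissuecanvas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# A canvas is a triangulated two-surface growing sheet.  Internally it is a
# list with:
#   vertices   N x 3 matrix of midplane positions (micrometres)
#   thickness  length-N vector (micrometres, > 0)
#   triangles  M x 3 integer matrix (1-based, counterclockwise seen from +z
#              at construction time)
#   factors    named list of per-vertex levels
#   rest_A, rest_B  M x 3 matrices holding the rest Gram tensor of each
#              triangle's edge pair (d1 = v2-v1, d2 = v3-v1) for the A
#              (adaxial, +z) and B (abaxial) surface: columns g11, g12, g22.
#   polarity_A, polarity_B  M x 2 material coordinates (a, b) of the polarity
#              direction in the edge basis, or NA when undefined
#   frozen_A, frozen_B  logical M: TRUE where polarity is a frozen material
#              direction rather than recomputed from the polariser gradient
#   clone_id   integer M (0 = not in a clone); clone membership is material
#   pol        per-vertex polariser concentration (or NULL)
#   time       simulation time in hours (1 DAI = 24 h)
#   meta       construction parameters (target edge length etc.)

new_canvas <- function(vertices, triangles, thickness, meta = list()) {
  vertices <- unname(as.matrix(vertices))
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  m <- nrow(triangles)
  cv <- structure(list(
    vertices = vertices,
    thickness = rep_len(thickness, nrow(vertices)),
    triangles = triangles,
    factors = list(),
    rest_A = NULL, rest_B = NULL,
    polarity_A = matrix(NA_real_, m, 2),
    polarity_B = matrix(NA_real_, m, 2),
    frozen_A = rep(FALSE, m), frozen_B = rep(FALSE, m),
    clone_id = integer(m),
    pol = NULL,
    time = 0,
    meta = meta
  ), class = "canvas")
  g <- tri_gram(cv)
  cv$rest_A <- g
  cv$rest_B <- g
  validate_canvas(cv)
  cv
}

validate_canvas <- function(cv) {
  if (any(cv$thickness <= 0)) abort("canvas thickness must be positive everywhere")
  a <- tri_areas(cv)
  if (any(a <= 0)) abort("degenerate triangle (zero area) in canvas")
  for (g in list(cv$rest_A, cv$rest_B)) {
    det <- g[, 1] * g[, 3] - g[, 2]^2
    if (any(g[, 1] <= 0) || any(det <= 0)) {
      abort("rest metrics must be symmetric positive definite")
    }
  }
  invisible(cv)
}

# edge vectors d1 = v2 - v1, d2 = v3 - v1 for every triangle
tri_edges <- function(cv) {
  v <- cv$vertices; t <- cv$triangles
  list(d1 = v[t[, 2], , drop = FALSE] - v[t[, 1], , drop = FALSE],
       d2 = v[t[, 3], , drop = FALSE] - v[t[, 1], , drop = FALSE])
}

# current Gram tensors (g11, g12, g22) per triangle
tri_gram <- function(cv) {
  e <- tri_edges(cv)
  cbind(rowSums(e$d1 * e$d1), rowSums(e$d1 * e$d2), rowSums(e$d2 * e$d2))
}

tri_areas <- function(cv) {
  e <- tri_edges(cv)
  n <- cross3(e$d1, e$d2)
  0.5 * sqrt(rowSums(n * n))
}

rest_areas <- function(g) 0.5 * sqrt(pmax(g[, 1] * g[, 3] - g[, 2]^2, 0))

tri_normals <- function(cv) {
  e <- tri_edges(cv)
  n <- cross3(e$d1, e$d2)
  n / sqrt(rowSums(n * n))
}

tri_centroids <- function(cv) {
  v <- cv$vertices; t <- cv$triangles
  (v[t[, 1], , drop = FALSE] + v[t[, 2], , drop = FALSE] +
     v[t[, 3], , drop = FALSE]) / 3
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Total canvas area
#' @param canvas a canvas object.
#' @return total mesh area in square micrometres.
#' @export
canvas_area <- function(canvas) sum(tri_areas(canvas))

#' Construct a square starting canvas
#'
#' Builds a triangulated square sheet centred on the origin in the xy plane
#' (x mediolateral, y proximodistal, z adaxial-up), optionally bowed into a
#' shallow cap and/or perturbed with seeded per-vertex height noise.  The cap
#' profile is the paraboloid `z = sagitta * (1 - rho^2 / rho_max^2)` with
#' `rho` the distance from the centre and `rho_max` the half-diagonal, so the
#' apex deviation equals `curvature_sagitta` and the corners stay at z = 0.
#'
#' @param side side length (micrometres).
#' @param resolution target edge length (micrometres); default `side / 30`.
#' @param curvature_sagitta apex height of the initial cap (micrometres).
#' @param z_noise_amplitude half-range of uniform per-vertex z noise
#'   (micrometres).
#' @param seed integer seed for the noise (identical seed, identical canvas).
#' @param thickness initial sheet thickness (micrometres, default 10, the
#'   scale of one cell).
#' @return a canvas object.
#' @export
make_square_canvas <- function(side, resolution = side / 30,
                               curvature_sagitta = 0, z_noise_amplitude = 0,
                               seed = 1, thickness = 10) {
  if (side <= 0 || resolution <= 0) abort("side and resolution must be positive")
  if (resolution >= side) abort("resolution must be smaller than side")
  grid_sheet(side, side, resolution, curvature_sagitta, z_noise_amplitude,
             seed, thickness, cap = "radial")
}

#' Construct a rectangular strip canvas
#'
#' Builds the initial strip used by the dome/wedge models: a `width` x
#' `height` rectangle (long side along x, the mediolateral axis), slightly
#' bowed along its length so the abaxial (-z) side is convex when
#' `curvature_sagitta > 0`; the mid-strip deviates by the sagitta below the
#' ends (`z = -sagitta * (1 - (2x/width)^2)`).
#'
#' @param width long side (micrometres).
#' @param height short side (micrometres).
#' @param curvature_sagitta mid-strip z deviation (micrometres); default 1%
#'   of the short side.
#' @param resolution target edge length; default `height / 6` (coarse) so the
#'   1060 x 120 strip stays tractable; pass a smaller value for production
#'   runs.
#' @param thickness initial thickness (micrometres).
#' @return a canvas object.
#' @export
make_strip_canvas <- function(width, height,
                              curvature_sagitta = 0.01 * height,
                              resolution = height / 6, thickness = 10) {
  if (width <= 0 || height <= 0) abort("width and height must be positive")
  if (resolution <= 0) abort("resolution must be positive")
  grid_sheet(width, height, resolution, curvature_sagitta, 0, 1, thickness,
             cap = "cylindrical")
}

grid_sheet <- function(wx, wy, resolution, sagitta, noise, seed, thickness,
                       cap = c("radial", "cylindrical")) {
  cap <- match.arg(cap)
  nx <- max(2L, as.integer(round(wx / resolution)))
  ny <- max(2L, as.integer(round(wy / resolution)))
  xs <- seq(-wx / 2, wx / 2, length.out = nx + 1L)
  ys <- seq(-wy / 2, wy / 2, length.out = ny + 1L)
  g <- expand.grid(x = xs, y = ys)  # x varies fastest
  z <- if (sagitta != 0) {
    if (cap == "radial") {
      rho2 <- g$x^2 + g$y^2
      sagitta * (1 - rho2 / ((wx / 2)^2 + (wy / 2)^2))
    } else {
      -sagitta * (1 - (2 * g$x / wx)^2)
    }
  } else rep(0, nrow(g))
  if (noise > 0) {
    z <- z + with_seed(seed, stats::runif(nrow(g), -noise, noise))
  }
  idx <- function(i, j) (j - 1L) * (nx + 1L) + i
  tris <- vector("list", nx * ny)
  k <- 1L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      v00 <- idx(i, j); v10 <- idx(i + 1L, j)
      v01 <- idx(i, j + 1L); v11 <- idx(i + 1L, j + 1L)
      # alternate the diagonal for a symmetric union-jack-like pattern
      if ((i + j) %% 2L == 0L) {
        tris[[k]] <- rbind(c(v00, v10, v11), c(v00, v11, v01))
      } else {
        tris[[k]] <- rbind(c(v00, v10, v01), c(v10, v11, v01))
      }
      k <- k + 1L
    }
  }
  cv <- new_canvas(cbind(g$x, g$y, z), do.call(rbind, tris), thickness,
                   meta = list(target_edge = resolution, seed = seed,
                               size = c(wx, wy), sagitta = sagitta,
                               z_noise = noise))
  cv
}

#' Bounding box of a canvas
#' @param canvas a canvas object.
#' @return 2 x 3 matrix with min/max of x, y, z.
#' @export
canvas_bbox <- function(canvas) {
  apply(canvas$vertices, 2, range)
}

#' Set a per-vertex factor
#' @param canvas a canvas.
#' @param name factor name.
#' @param levels per-vertex numeric vector (recycled if scalar).
#' @return the modified canvas.
#' @export
set_factor <- function(canvas, name, levels) {
  canvas$factors[[name]] <- rep_len(as.numeric(levels), nrow(canvas$vertices))
  canvas
}

# factor levels averaged onto triangles
factors_on_triangles <- function(cv) {
  t <- cv$triangles
  lapply(cv$factors, function(f) (f[t[, 1]] + f[t[, 2]] + f[t[, 3]]) / 3)
}
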