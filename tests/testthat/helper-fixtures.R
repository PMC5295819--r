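# shared fixtures and small independent oracles

# flat canvas with no curvature or noise
flat_square <- function(side = 100, resolution = 10, thickness = 2) {
  make_square_canvas(side, resolution = resolution, curvature_sagitta = 0,
                     z_noise_amplitude = 0, thickness = thickness)
}

# absolute angular difference in degrees, wrapped to [0, 180]
ang_diff_deg <- function(a, b) abs(((a - b + pi) %% (2 * pi)) - pi) * 180 / pi

# axial (mod pi) angular difference in degrees, in [0, 90]
axial_diff_deg <- function(a, b) abs(((a - b + pi / 2) %% pi) - pi / 2) * 180 / pi

# independent chord-length oracle: length of the centroid chord of a CONVEX
# polygon at angle phi, via full-line/edge intersections
oracle_chord_len <- function(poly, phi) {
  cen <- colMeans(poly)  # not the area centroid: recompute properly
  n <- nrow(poly); j <- c(2:n, 1)
  cr <- poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2]
  A <- sum(cr) / 2
  cen <- c(sum((poly[, 1] + poly[j, 1]) * cr), sum((poly[, 2] + poly[j, 2]) * cr)) / (6 * A)
  d <- c(cos(phi), sin(phi))
  ts <- c()
  for (e in seq_len(n)) {
    a <- poly[e, ]; b <- poly[j[e], ]
    M <- cbind(d, a - b)
    if (abs(det(M)) < 1e-13) next
    sol <- solve(M, a - cen)
    if (sol[2] >= -1e-9 && sol[2] <= 1 + 1e-9) ts <- c(ts, sol[1])
  }
  if (length(ts) < 2) return(NA_real_)
  max(ts) - min(ts)
}

# seeded random convex polygon (convex hull of random points)
random_convex_polygon <- function(k = 8, scale = 1) {
  pts <- matrix(stats::runif(2 * (k + 4), 0, scale), ncol = 2)
  h <- grDevices::chull(pts)
  pts[rev(h), , drop = FALSE]  # counterclockwise
}
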