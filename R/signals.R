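# Diffusion-decay fields on the canvas.  Signals (sRAD, sRIM, sLAT, ...)
# are modelled at steady state: D lap(u) = k u away from the source, i.e.
# u ~ exp(-d / l) with diffusion length l = sqrt(D / k) on a homogeneous 1D
# sheet.  Discretised with the cotangent stiffness matrix and lumped mass;
# the source region is clamped at 1 (Dirichlet).

cotan_stiffness <- function(cv) {
  t <- cv$triangles; v <- cv$vertices
  i <- t[, 1]; j <- t[, 2]; k <- t[, 3]
  cot_at <- function(a, b, c) {
    # cotangent of the angle at vertex a in triangle (a, b, c)
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    d <- rowSums(u * w)
    n <- cross3(u, w)
    d / pmax(sqrt(rowSums(n * n)), 1e-300)
  }
  ci <- cot_at(i, j, k); cj <- cot_at(j, k, i); ck <- cot_at(k, i, j)
  # edge (j,k) gets weight cot_i / 2, etc.
  ii <- c(j, k, i); jj <- c(k, i, j); ww <- c(ci, cj, ck) / 2
  n <- nrow(v)
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(W)) - W
}

lumped_mass <- function(cv) {
  a <- tri_areas(cv)
  n <- nrow(cv$vertices)
  m <- numeric(n)
  for (c in 1:3) {
    idx <- cv$triangles[, c]
    acc <- tapply(a / 3, idx, sum)
    at <- as.integer(names(acc))
    m[at] <- m[at] + as.numeric(acc)
  }
  Matrix::Diagonal(n, m)
}

#' Steady-state diffusible signal from a source region
#'
#' Solves the steady diffusion-decay equation on the mesh with the source
#' region clamped at level 1, giving a field that decays approximately as
#' `exp(-d / diffusion_length)` with distance `d` from the source.
#'
#' @param canvas a canvas.
#' @param source_factor name of a factor marking the producing region
#'   (vertices with level > 0.5 are clamped at 1), or a numeric/logical
#'   per-vertex vector.
#' @param diffusion_length decay length in micrometres (`Inf` gives a
#'   uniform field of 1).
#' @param mode only `"steady"` is implemented (the models fix their signals
#'   after set-up).
#' @return per-vertex signal level in [0, 1].
#' @export
diffuse_signal <- function(canvas, source_factor, diffusion_length,
                           mode = "steady") {
  stopifnot(mode == "steady")
  src <- if (is.character(source_factor)) {
    f <- canvas$factors[[source_factor]]
    if (is.null(f)) abort("source factor `%s` not present", source_factor)
    f > 0.5
  } else as.logical(rep_len(source_factor, nrow(canvas$vertices)) > 0.5)
  n <- nrow(canvas$vertices)
  if (!any(src)) {
    warning("diffuse_signal: empty source region; returning all-zero field")
    return(numeric(n))
  }
  if (is.infinite(diffusion_length)) return(rep(1, n))
  K <- cotan_stiffness(canvas)
  M <- lumped_mass(canvas)
  A <- diffusion_length^2 * K + M
  u <- numeric(n)
  u[src] <- 1
  free <- which(!src)
  if (length(free)) {
    rhs <- -A[free, src, drop = FALSE] %*% u[src]
    u[free] <- as.numeric(Matrix::solve(A[free, free, drop = FALSE], rhs))
  }
  clamp(u, 0, 1)
}
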