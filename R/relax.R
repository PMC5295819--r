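# Elastic relaxation of the canvas.  The energy is a two-layer discrete
# shell: per-triangle St-Venant-Kirchhoff membrane terms against the A and B
# rest metrics plus hinge bending with a spontaneous dihedral angle derived
# from the A/B rest-length differential across each hinge (so differential
# surface growth produces spontaneous curvature: the faster-growing surface
# ends on the convex side).  Moduli are uniform (unit Young modulus,
# Poisson coupling nu = 0.3); only energy ratios matter for the
# quasi-static shapes.

# interior-edge table: columns i, j (directed edge as it appears in the
# first triangle's winding), k (opposite vertex, first triangle), l
# (opposite vertex, second triangle), t1, t2 (triangle indices)
build_hinges <- function(cv) {
  t <- cv$triangles
  m <- nrow(t)
  from <- c(t[, 1], t[, 2], t[, 3])
  to <- c(t[, 2], t[, 3], t[, 1])
  opp <- c(t[, 3], t[, 1], t[, 2])
  tri <- rep(seq_len(m), 3)
  key <- paste(pmin(from, to), pmax(from, to))
  first <- !duplicated(key)
  match2 <- match(key, key[first])
  tab <- table(match2)
  interior <- as.integer(names(tab)[tab == 2L])
  if (!length(interior)) {
    return(matrix(integer(0), 0, 6,
                  dimnames = list(NULL, c("i", "j", "k", "l", "t1", "t2"))))
  }
  idx1 <- which(first)[interior]
  # partner half-edge: the other occurrence of the same key
  out <- matrix(0L, length(interior), 6)
  colnames(out) <- c("i", "j", "k", "l", "t1", "t2")
  occ <- split(seq_along(key), match2)
  for (r in seq_along(interior)) {
    pair <- occ[[as.character(interior[r])]]
    a <- pair[1]; b <- pair[2]
    out[r, ] <- c(from[a], to[a], opp[a], opp[b], tri[a], tri[b])
  }
  out
}

# spontaneous dihedral angles and bending stiffness per hinge
hinge_rest <- function(cv, hinges, nu = 0.3) {
  nh <- nrow(hinges)
  if (!nh) return(list(theta0 = numeric(0), kb = numeric(0)))
  theta0 <- numeric(nh)
  kb <- numeric(nh)
  t <- cv$triangles
  h_tri <- (cv$thickness[t[, 1]] + cv$thickness[t[, 2]] + cv$thickness[t[, 3]]) / 3
  aA <- rest_areas(cv$rest_A)
  aB <- rest_areas(cv$rest_B)
  a0 <- (aA + aB) / 2
  for (r in seq_len(nh)) {
    i <- hinges[r, 1]; j <- hinges[r, 2]
    t1 <- hinges[r, 5]; t2 <- hinges[r, 6]
    deltas <- numeric(2); l0s <- numeric(2)
    for (s in 1:2) {
      tt <- if (s == 1) t1 else t2
      tr <- t[tt, ]
      base <- rbind(c(0, 0), c(1, 0), c(0, 1))
      wi <- base[match(i, tr), ]; wj <- base[match(j, tr), ]
      w <- wj - wi  # hinge edge in this triangle's edge basis
      GA <- matrix(c(cv$rest_A[tt, 1], cv$rest_A[tt, 2],
                     cv$rest_A[tt, 2], cv$rest_A[tt, 3]), 2, 2)
      GB <- matrix(c(cv$rest_B[tt, 1], cv$rest_B[tt, 2],
                     cv$rest_B[tt, 2], cv$rest_B[tt, 3]), 2, 2)
      Gm <- (GA + GB) / 2
      # direction across the hinge: Gm-orthogonal complement of w
      gw <- Gm %*% w
      q <- c(-gw[2], gw[1])
      lA <- sqrt(max(drop(t(q) %*% GA %*% q), 0))
      lB <- sqrt(max(drop(t(q) %*% GB %*% q), 0))
      deltas[s] <- 2 * (lA - lB) / max(lA + lB, 1e-300)
      l0s[s] <- sqrt(max(drop(t(w) %*% Gm %*% w), 0))
    }
    l0 <- mean(l0s)
    h <- (h_tri[t1] + h_tri[t2]) / 2
    arc <- (2 * a0[t1] / l0 + 2 * a0[t2] / l0) / 3
    theta0[r] <- mean(deltas) / h * arc
    kb[r] <- (h^3 / 12) / (1 - nu^2) * 3 * l0^2 / max(a0[t1] + a0[t2], 1e-300)
  }
  list(theta0 = theta0, kb = kb)
}

shell_args <- function(cv, nu = 0.3) {
  t <- cv$triangles
  htri <- (cv$thickness[t[, 1]] + cv$thickness[t[, 2]] + cv$thickness[t[, 3]]) / 3
  hinges <- attr(cv, "hinges")
  if (is.null(hinges)) hinges <- build_hinges(cv)
  hr <- hinge_rest(cv, hinges, nu)
  list(verts = cv$vertices, tris = cv$triangles,
       restA = cv$rest_A, restB = cv$rest_B, htri = htri,
       hinges = hinges[, 1:4, drop = FALSE],
       theta0 = hr$theta0, kb = hr$kb, nu = nu)
}

#' Elastic energy of a canvas
#'
#' @param canvas a canvas.
#' @param nu Poisson-type coupling (default 0.3).
#' @return total elastic energy (arbitrary units; zero when the realised
#'   geometry matches both rest metrics and all spontaneous angles).
#' @export
canvas_energy <- function(canvas, nu = 0.3) {
  a <- shell_args(canvas, nu)
  .shell_energy(a$verts, a$tris, a$restA, a$restB, a$htri,
                a$hinges, a$theta0, a$kb, a$nu)
}

#' Relax a canvas to elastic equilibrium
#'
#' Minimises the two-layer shell energy over vertex positions by conjugate
#' gradients with a monotone (Armijo) line search.  The solver injects no
#' randomness: buckling direction is selected by the initial curvature or
#' seeded height noise of the canvas.
#'
#' @param canvas a canvas (with rest metrics set).
#' @param tol relative energy-change convergence tolerance (default 1e-6).
#' @param max_iter maximum iterations (default 2000).
#' @param nu Poisson coupling.
#' @return the canvas with updated vertex positions; attributes
#'   `relax_energy`, `relax_iterations`, `relax_converged`,
#'   `relax_trace` record the solve.  Warns on non-convergence and returns
#'   the best state found.
#' @export
relax <- function(canvas, tol = 1e-6, max_iter = 2000L, nu = 0.3) {
  a <- shell_args(canvas, nu)
  scale <- sqrt(mean(rest_areas(canvas$rest_A)))
  res <- .shell_relax(a$verts, a$tris, a$restA, a$restB, a$htri,
                      a$hinges, a$theta0, a$kb, a$nu,
                      tol, as.integer(max_iter), 1e-5 * scale)
  if (!res$converged && res$iterations >= max_iter) {
    warning(sprintf("relax: not converged after %d iterations (energy %.3g)",
                    res$iterations, res$energy))
  }
  canvas$vertices <- res$vertices
  attr(canvas, "relax_energy") <- res$energy
  attr(canvas, "relax_iterations") <- res$iterations
  attr(canvas, "relax_converged") <- res$converged
  attr(canvas, "relax_trace") <- res$trace
  canvas
}
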