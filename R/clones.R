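#' Induce circular clones on a canvas
#'
#' Marks disjoint, approximately circular material sectors centred on a
#' regular grid.  Membership is stored per triangle (`clone_id`), so clones
#' advect passively with the mesh as it grows.
#'
#' @param canvas a canvas.
#' @param time induction time in hours (recorded on each clone).
#' @param radius clone radius at induction (micrometres).
#' @param spacing centre-to-centre grid spacing (micrometres); must exceed
#'   `radius` (in fact `2 * radius` is required for disjoint clones).
#' @return the canvas, with `clone_id` set and a `clones` attribute: a list
#'   of clone records (id, centre, induction_time, initial_radius, elements).
#' @export
induce_clones <- function(canvas, time = canvas$time, radius = 10,
                          spacing = 50) {
  if (radius >= spacing) abort("clone radius (%g) must be smaller than spacing (%g)", radius, spacing)
  if (radius <= 0) abort("clone radius must be positive")
  bb <- canvas_bbox(canvas)
  cx <- seq(bb[1, 1] + spacing / 2, bb[2, 1] - spacing / 2 + 1e-9, by = spacing)
  cy <- seq(bb[1, 2] + spacing / 2, bb[2, 2] - spacing / 2 + 1e-9, by = spacing)
  if (!length(cx)) cx <- mean(bb[, 1])
  if (!length(cy)) cy <- mean(bb[, 2])
  centres <- as.matrix(expand.grid(x = cx, y = cy))
  cen <- tri_centroids(canvas)
  canvas$clone_id <- integer(nrow(canvas$triangles))
  clones <- vector("list", nrow(centres))
  for (k in seq_len(nrow(centres))) {
    d2 <- (cen[, 1] - centres[k, 1])^2 + (cen[, 2] - centres[k, 2])^2
    mem <- which(d2 <= radius^2 & canvas$clone_id == 0L)
    canvas$clone_id[mem] <- k
    clones[[k]] <- list(id = k, centre = c(centres[k, ], 0),
                        induction_time = time, initial_radius = radius,
                        elements = mem)
  }
  keep <- vapply(clones, function(cl) length(cl$elements) > 0L, logical(1))
  attr(canvas, "clones") <- clones[keep]
  canvas
}

clone_elements <- function(canvas, id) which(canvas$clone_id == id)

#' Shape statistics of a clone
#'
#' Area and principal-axis statistics of a marked clone, computed from the
#' exact second area moments of its member triangles (so the result is the
#' statistics of the equivalent uniform ellipse).
#'
#' @param canvas a canvas with induced clones.
#' @param clone clone id (integer) or a clone record from
#'   `attr(canvas, "clones")`.
#' @return list with `area` (square micrometres), `major_axis`, `minor_axis`
#'   (full axis lengths of the equivalent ellipse), `orientation` (angle of
#'   the major axis to the x axis, in `[0, pi)`, measured in the xy
#'   projection) and `anisotropy` (major/minor ratio).
#' @export
clone_stats <- function(canvas, clone) {
  id <- if (is.list(clone)) clone$id else clone
  el <- clone_elements(canvas, id)
  if (!length(el)) abort("clone %s is empty", as.character(id))
  v <- canvas$vertices; t <- canvas$triangles[el, , drop = FALSE]
  p1 <- v[t[, 1], , drop = FALSE]; p2 <- v[t[, 2], , drop = FALSE]
  p3 <- v[t[, 3], , drop = FALSE]
  n <- cross3(p2 - p1, p3 - p1)
  a <- 0.5 * sqrt(rowSums(n * n))
  A <- sum(a)
  mu <- colSums((p1 + p2 + p3) / 3 * a) / A
  # exact covariance of the uniform measure on the triangle set:
  # for one triangle, E[x x^T] = (1/12) (sum_i sum_j<=i pi pj^T + sym) ...
  # use the standard formula Cov_t = (1/12) sum_i (pi-mu)(pi-mu)^T +
  #                                 (1/12)*3*(c-mu)(c-mu)^T  with c centroid
  S <- matrix(0, 3, 3)
  for (k in seq_along(a)) {
    q <- rbind(p1[k, ], p2[k, ], p3[k, ])
    c_k <- colMeans(q)
    qc <- sweep(q, 2, mu)
    cc <- c_k - mu
    S_k <- (crossprod(qc) + 9 * tcrossprod(cc)) / 12
    S <- S + a[k] * S_k
  }
  S <- S / A
  ev <- eigen(S, symmetric = TRUE)
  # uniform ellipse with semi-axes (sa, sb): second moments sa^2/4, sb^2/4
  sa <- 2 * sqrt(max(ev$values[1], 0))
  sb <- 2 * sqrt(max(ev$values[2], 0))
  dir <- ev$vectors[, 1]
  ang <- atan2(dir[2], dir[1]) %% pi
  list(area = A, major_axis = 2 * sa, minor_axis = 2 * sb,
       orientation = ang, anisotropy = sa / max(sb, .Machine$double.eps))
}

#' Shape statistics for every clone
#' @param canvas a canvas with induced clones.
#' @return data frame of per-clone statistics plus clone centre coordinates.
#' @export
all_clone_stats <- function(canvas) {
  clones <- attr(canvas, "clones")
  if (is.null(clones)) abort("no clones induced on this canvas")
  cen <- tri_centroids(canvas)
  do.call(rbind, lapply(clones, function(cl) {
    el <- clone_elements(canvas, cl$id)
    if (!length(el)) return(NULL)
    st <- clone_stats(canvas, cl$id)
    pos <- colMeans(cen[el, , drop = FALSE])
    data.frame(id = cl$id, x = pos[1], y = pos[2], z = pos[3],
               area = st$area, major = st$major_axis, minor = st$minor_axis,
               orientation = st$orientation, anisotropy = st$anisotropy)
  }))
}
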