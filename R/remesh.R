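# Remeshing by longest-edge bisection.  A triangle whose longest edge
# exceeds `max_edge` is split at that edge's midpoint; the neighbour sharing
# the edge is split too so the mesh stays conforming.  Vertex fields
# (factors, thickness, polariser) are interpolated linearly; per-triangle
# rest metrics are inherited exactly by expressing each child's edge pair as
# a linear image of the parent's (G_child = B^T G_parent B), so refinement
# introduces no spurious elastic energy; clone ids, polarity material
# coordinates and frozen flags are inherited from the parent.

#' Refine a canvas until no edge exceeds a length bound
#'
#' @param canvas a canvas.
#' @param max_edge maximum allowed edge length (micrometres).
#' @param max_pass safety bound on bisection sweeps.
#' @return the refined canvas (returned unchanged if already fine enough).
#' @export
remesh <- function(canvas, max_edge, max_pass = 30L) {
  if (max_edge <= 0) abort("max_edge must be positive")
  for (pass in seq_len(max_pass)) {
    if (!any(edge_lengths_exceed(canvas, max_edge))) break
    canvas <- bisect_pass(canvas, max_edge)
  }
  canvas
}

edge_lengths_exceed <- function(cv, max_edge) {
  e <- tri_edges(cv)
  d3 <- e$d2 - e$d1  # v3 - v2
  l2 <- cbind(rowSums(e$d1^2), rowSums(d3^2), rowSums(e$d2^2))
  sqrt(apply(l2, 1, max)) > max_edge
}

# one sweep: split every triangle whose longest edge is over the bound at
# that edge's midpoint (2 children); conformity is restored on the
# neighbouring triangle by splitting it at the same midpoint.
bisect_pass <- function(cv, max_edge) {
  t <- cv$triangles
  v <- cv$vertices
  m <- nrow(t)
  # per-triangle edges as vertex pairs in local order:
  # edge 1: (v1,v2), edge 2: (v2,v3), edge 3: (v3,v1)
  epair <- function(tr, k) switch(k, tr[c(1, 2)], tr[c(2, 3)], tr[c(3, 1)])
  elen2 <- function(p) sum((v[p[1], ] - v[p[2], ])^2)
  # collect the set of edges to split: longest edge of each oversized triangle
  keys <- character(0)
  split_edges <- list()
  for (i in seq_len(m)) {
    tr <- t[i, ]
    l2 <- c(elen2(tr[c(1, 2)]), elen2(tr[c(2, 3)]), elen2(tr[c(3, 1)]))
    if (sqrt(max(l2)) > max_edge) {
      k <- which.max(l2)
      p <- sort(epair(tr, k))
      key <- paste(p, collapse = "-")
      if (!key %in% keys) {
        keys <- c(keys, key)
        split_edges[[key]] <- p
      }
    }
  }
  if (!length(split_edges)) return(cv)
  # create midpoints
  nv0 <- nrow(v)
  mid_id <- setNames(nv0 + seq_along(split_edges), names(split_edges))
  mids <- do.call(rbind, lapply(split_edges, function(p) (v[p[1], ] + v[p[2], ]) / 2))
  newv <- rbind(v, mids)
  interp <- function(f) {
    c(f, vapply(split_edges, function(p) (f[p[1]] + f[p[2]]) / 2, numeric(1)))
  }
  new_thick <- interp(cv$thickness)
  new_factors <- lapply(cv$factors, interp)
  new_pol <- if (!is.null(cv$pol)) interp(cv$pol) else NULL

  out_tri <- list(); out_restA <- list(); out_restB <- list()
  out_polA <- list(); out_polB <- list()
  out_frozA <- logical(0); out_frozB <- logical(0); out_clone <- integer(0)
  push <- function(parent, tri_new, B) {
    # child rest gram: edges of child = parent edges %*% B (columns a,b with
    # child d = a*parent_d1 + b*parent_d2)
    Gp <- function(g) matrix(c(g[1], g[2], g[2], g[3]), 2, 2)
    flat <- function(G) c(G[1, 1], G[1, 2], G[2, 2])
    gA <- flat(t(B) %*% Gp(cv$rest_A[parent, ]) %*% B)
    gB <- flat(t(B) %*% Gp(cv$rest_B[parent, ]) %*% B)
    # polarity material coords transform contravariantly: u_child = B^{-1} u
    Binv <- solve(B)
    pA <- cv$polarity_A[parent, ]; pB <- cv$polarity_B[parent, ]
    out_tri[[length(out_tri) + 1L]] <<- tri_new
    out_restA[[length(out_restA) + 1L]] <<- gA
    out_restB[[length(out_restB) + 1L]] <<- gB
    out_polA[[length(out_polA) + 1L]] <<- if (all(is.finite(pA))) as.numeric(Binv %*% pA) else c(NA_real_, NA_real_)
    out_polB[[length(out_polB) + 1L]] <<- if (all(is.finite(pB))) as.numeric(Binv %*% pB) else c(NA_real_, NA_real_)
    out_frozA <<- c(out_frozA, cv$frozen_A[parent])
    out_frozB <<- c(out_frozB, cv$frozen_B[parent])
    out_clone <<- c(out_clone, cv$clone_id[parent])
  }
  base <- rbind(c(0, 0), c(1, 0), c(0, 1))
  for (i in seq_len(m)) {
    tr <- t[i, ]
    mids <- integer(3)  # midpoint vertex id per local edge, 0 if unsplit
    for (k in 1:3) {
      key <- paste(sort(epair(tr, k)), collapse = "-")
      if (key %in% names(mid_id)) mids[k] <- mid_id[[key]]
    }
    nmark <- sum(mids > 0L)
    if (nmark == 0L) {
      push(i, tr, diag(2))
      next
    }
    # edge-basis coordinates of any involved vertex relative to tr
    loc <- function(vid) {
      j <- match(vid, tr)
      if (!is.na(j)) return(base[j, ])
      k <- match(vid, mids)
      p <- epair(tr, k)
      (base[match(p[1], tr), ] + base[match(p[2], tr), ]) / 2
    }
    emit <- function(v1, v2, v3) {
      c1 <- loc(v1); c2 <- loc(v2); c3 <- loc(v3)
      push(i, c(v1, v2, v3), cbind(c2 - c1, c3 - c1))
    }
    if (nmark == 3L) {
      emit(tr[1], mids[1], mids[3])
      emit(mids[1], tr[2], mids[2])
      emit(mids[3], mids[2], tr[3])
      emit(mids[1], mids[2], mids[3])
    } else if (nmark == 1L) {
      k <- which(mids > 0L)
      ab <- epair(tr, k); opp <- setdiff(tr, ab)
      emit(ab[1], mids[k], opp)
      emit(mids[k], ab[2], opp)
    } else {
      # two marked edges; rotate the triangle (winding-preserving) so the
      # marked edges are local edges 1 and 2, sharing local vertex 2
      ks <- sort(which(mids > 0L))
      rot <- if (identical(ks, c(1L, 2L))) c(1L, 2L, 3L)
             else if (identical(ks, c(2L, 3L))) c(2L, 3L, 1L)
             else c(3L, 1L, 2L)
      tv <- tr[rot]
      ma <- mids[rot[1]]; mb <- mids[rot[2]]
      emit(ma, tv[2], mb)
      emit(tv[1], ma, mb)
      emit(tv[1], mb, tv[3])
    }
  }
  cv2 <- structure(list(
    vertices = newv,
    thickness = new_thick,
    triangles = do.call(rbind, out_tri),
    factors = new_factors,
    rest_A = do.call(rbind, out_restA),
    rest_B = do.call(rbind, out_restB),
    polarity_A = do.call(rbind, out_polA),
    polarity_B = do.call(rbind, out_polB),
    frozen_A = out_frozA, frozen_B = out_frozB,
    clone_id = out_clone,
    pol = new_pol,
    time = cv$time,
    meta = cv$meta
  ), class = "canvas")
  cl <- attr(cv, "clones")
  if (!is.null(cl)) {
    cl <- lapply(cl, function(x) { x$elements <- which(out_clone == x$id); x })
    attr(cv2, "clones") <- cl
  }
  storage.mode(cv2$triangles) <- "integer"
  cv2
}
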