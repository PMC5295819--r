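# Cell divisions on the growing canvas.  Cells are passive polygonal
# markers drawn on the tissue: their vertices move with the material, and
# when a cell's area exceeds a threshold it divides along the shortest wall
# through its centroid (slightly shortened to give more realistic wall
# angles).  Wall birth times record the history, so wall-age classes (T0
# original walls, T1 and T2 for the two growth phases) reproduce the
# calcofluor-like staining patterns used to infer growth orientation.

#' Create a cell complex
#'
#' @param vertices V x 2 matrix of vertex positions.
#' @param cells list of integer vectors (counterclockwise vertex loops).
#' @param birth named or unnamed numeric vector of wall birth times
#'   (default 0 for all initial walls).
#' @param threshold division area threshold; default 2x the initial mean
#'   cell area.
#' @return a `cell_complex` object.
#' @export
cell_complex <- function(vertices, cells, birth = NULL, threshold = NULL) {
  vertices <- as.matrix(vertices)
  walls <- list()
  wall_key <- character(0)
  add_wall <- function(i, j, t) {
    k <- paste(min(i, j), max(i, j))
    if (!k %in% wall_key) {
      walls[[length(walls) + 1L]] <<- c(min(i, j), max(i, j), t)
      wall_key <<- c(wall_key, k)
    }
  }
  for (cl in cells) {
    for (e in seq_along(cl)) {
      add_wall(cl[e], cl[e %% length(cl) + 1L], 0)
    }
  }
  w <- do.call(rbind, walls)
  cc <- structure(list(vertices = vertices,
                       walls = data.frame(v1 = w[, 1], v2 = w[, 2],
                                          birth = if (is.null(birth)) w[, 3] else rep_len(birth, nrow(w))),
                       cells = cells,
                       time = 0), class = "cell_complex")
  cc$threshold <- threshold %||% (2 * mean(cell_areas(cc)))
  cc
}

cell_polygon <- function(cc, i) cc$vertices[cc$cells[[i]], , drop = FALSE]

polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

polygon_centroid <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- sum(cr) / 2
  cx <- sum((p[, 1] + p[j, 1]) * cr) / (6 * a)
  cy <- sum((p[, 2] + p[j, 2]) * cr) / (6 * a)
  c(cx, cy)
}

#' Cell areas of a complex
#' @param cc a `cell_complex`.
#' @return numeric vector of polygon areas.
#' @export
cell_areas <- function(cc) {
  vapply(seq_along(cc$cells), function(i) polygon_area(cell_polygon(cc, i)),
         numeric(1))
}

point_in_polygon <- function(pt, p) {
  n <- nrow(p); j <- c(2:n, 1)
  inside <- FALSE
  for (e in seq_len(n)) {
    a <- p[e, ]; b <- p[j[e], ]
    if ((a[2] > pt[2]) != (b[2] > pt[2])) {
      xint <- a[1] + (pt[2] - a[2]) / (b[2] - a[2]) * (b[1] - a[1])
      if (pt[1] < xint) inside <- !inside
    }
  }
  inside
}

# chord of polygon `p` through point `c` at angle `phi`: returns the two
# boundary intersection points nearest to c on each side (with their edge
# indices and edge parameters), or NULL if degenerate
centroid_chord <- function(p, cen, phi) {
  d <- c(cos(phi), sin(phi))
  n <- nrow(p); j <- c(2:n, 1)
  hits <- list()
  for (e in seq_len(n)) {
    a <- p[e, ]; b <- p[j[e], ]
    eb <- b - a
    det <- d[1] * (-eb[2]) - d[2] * (-eb[1])
    if (abs(det) < 1e-14) next
    rhs <- a - cen
    tt <- (rhs[1] * (-eb[2]) - rhs[2] * (-eb[1])) / det   # along the ray
    ss <- (d[1] * rhs[2] - d[2] * rhs[1]) / det           # along the edge
    if (ss >= -1e-9 && ss <= 1 + 1e-9) {
      hits[[length(hits) + 1L]] <- c(t = tt, edge = e, s = clamp(ss, 0, 1))
    }
  }
  if (length(hits) < 2L) return(NULL)
  h <- do.call(rbind, hits)
  pos <- h[h[, 1] > 1e-12, , drop = FALSE]
  neg <- h[h[, 1] < -1e-12, , drop = FALSE]
  if (!nrow(pos) || !nrow(neg)) return(NULL)
  hp <- pos[which.min(pos[, 1]), ]
  hn <- neg[which.max(neg[, 1]), ]
  p1 <- cen + hp[1] * d
  p2 <- cen + hn[1] * d
  list(p1 = p1, p2 = p2, e1 = as.integer(hp[2]), e2 = as.integer(hn[2]),
       s1 = hp[3], s2 = hn[3], length = hp[1] - hn[1])
}

chord_interior_ok <- function(p, ch, cen) {
  # for non-convex polygons: chord midpoints must lie inside
  for (f in c(0.25, 0.5, 0.75)) {
    q1 <- cen + f * (ch$p1 - cen)
    q2 <- cen + f * (ch$p2 - cen)
    if (!point_in_polygon(q1, p) || !point_in_polygon(q2, p)) return(FALSE)
  }
  TRUE
}

# shortest centroid chord: coarse angle scan + local golden-section refine;
# equal-length ties break deterministically toward the smallest angle
shortest_chord <- function(p, step_deg = 0.5) {
  cen <- polygon_centroid(p)
  angles <- seq(0, pi - 1e-9, by = step_deg * pi / 180)
  best <- NULL; best_len <- Inf; best_phi <- 0
  for (phi in angles) {
    ch <- centroid_chord(p, cen, phi)
    if (is.null(ch)) next
    if (!chord_interior_ok(p, ch, cen)) next
    if (ch$length < best_len - 1e-12) {
      best <- ch; best_len <- ch$length; best_phi <- phi
    }
  }
  if (is.null(best)) abort("no admissible division chord found")
  # refine around the best angle
  f <- function(phi) {
    ch <- centroid_chord(p, cen, phi %% pi)
    if (is.null(ch) || !chord_interior_ok(p, ch, cen)) return(Inf)
    ch$length
  }
  opt <- stats::optimize(f, c(best_phi - 2 * step_deg * pi / 180,
                              best_phi + 2 * step_deg * pi / 180))
  if (is.finite(opt$objective) && opt$objective < best_len) {
    best <- centroid_chord(p, cen, opt$minimum %% pi)
    best_phi <- opt$minimum %% pi
  }
  best$angle <- best_phi
  best$centroid <- cen
  best
}

# shorten the new wall slightly by sliding each endpoint a short, bounded
# distance along its parent edge in the length-reducing direction (the
# angle-regularisation convention); travel is capped so the adjustment
# stays local and daughter areas stay balanced
shorten_wall <- function(p, ch, shorten = 0.1) {
  if (shorten <= 0) {
    return(list(p1 = ch$p1, p2 = ch$p2, e1 = ch$e1, e2 = ch$e2,
                angle = ch$angle))
  }
  n <- nrow(p); j <- c(2:n, 1)
  seg <- function(e) {
    a <- p[e, ]; b <- p[j[e], ]
    list(a = a, d = b - a, len = sqrt(sum((b - a)^2)))
  }
  s1 <- seg(ch$e1); s2 <- seg(ch$e2)
  t1 <- sum((ch$p1 - s1$a) * s1$d) / sum(s1$d^2)
  t2 <- sum((ch$p2 - s2$a) * s2$d) / sum(s2$d^2)
  t1_0 <- t1; t2_0 <- t2
  L0 <- ch$length
  target <- (1 - shorten) * L0
  # endpoint travel is bounded in absolute terms (12% of the wall length)
  # so the adjustment stays slight and local; when the wall already meets
  # its parent edges near-perpendicularly, sliding cannot shorten it and
  # the wall is left as found
  cap1 <- 0.12 * L0 / s1$len
  cap2 <- 0.12 * L0 / s2$len
  for (iter in 1:6) {
    q1 <- s1$a + t1 * s1$d
    q2 <- s2$a + t2 * s2$d
    L <- sqrt(sum((q1 - q2)^2))
    if (L <= target + 1e-12 * L0) break
    w <- (q1 - q2) / L
    g1 <- sum(s1$d * w)    # dL/dt1
    g2 <- -sum(s2$d * w)   # dL/dt2 (note sign)
    gn2 <- (g1 / s1$len)^2 + (g2 / s2$len)^2
    if (gn2 < 0.01) break  # wall ~ perpendicular to its parent edges
    step <- (L - target) / (g1^2 + g2^2)
    t1 <- clamp(clamp(t1 - step * g1, t1_0 - cap1, t1_0 + cap1), 0.05, 0.95)
    t2 <- clamp(clamp(t2 - step * g2, t2_0 - cap2, t2_0 + cap2), 0.05, 0.95)
  }
  list(p1 = s1$a + t1 * s1$d, p2 = s2$a + t2 * s2$d,
       e1 = ch$e1, e2 = ch$e2, angle = ch$angle)
}

#' Divide one cell along its shortest centroid wall
#'
#' The division wall is the minimal-length chord through the cell centroid
#' (over all wall orientations, interior chords only for non-convex cells),
#' then shortened slightly by sliding its endpoints along the parent walls
#' (default 10% length reduction) to give more realistic angles.  Ties
#' between equal-minimal chords break deterministically toward the smallest
#' angle to the x axis.
#'
#' @param cc a `cell_complex`.
#' @param cell index of the cell to divide.
#' @param time birth time stamped on the new wall.
#' @param shorten fractional length reduction of the new wall.
#' @return the complex with the cell replaced by its two daughters.
#' @export
divide_cell <- function(cc, cell, time = cc$time, shorten = 0.1) {
  p <- cell_polygon(cc, cell)
  loop <- cc$cells[[cell]]
  n <- length(loop)
  ch <- shortest_chord(p)
  ch <- shorten_wall(p, ch, shorten)
  nv <- nrow(cc$vertices)
  cc$vertices <- rbind(cc$vertices, ch$p1, ch$p2)
  i1 <- nv + 1L; i2 <- nv + 2L
  # walk the loop inserting the new vertices on their edges
  # edge e of the polygon joins loop[e] -> loop[e %% n + 1]
  ins <- list()
  for (e in seq_len(n)) {
    ins[[e]] <- integer(0)
  }
  place <- function(e, vid, pos) {
    a <- p[e, ]; b <- p[e %% n + 1, ]
    tt <- sum((cc$vertices[vid, ] - a) * (b - a)) / sum((b - a)^2)
    rbind(c(vid, tt))
  }
  put <- function(lst, e, vid) {
    lst[[e]] <- rbind(lst[[e]], place(e, vid)[1, ])
    lst
  }
  ins <- list()
  for (e in seq_len(n)) ins[[e]] <- matrix(numeric(0), 0, 2)
  ins <- put(ins, ch$e1, i1)
  ins <- put(ins, ch$e2, i2)
  newloop <- integer(0)
  for (e in seq_len(n)) {
    newloop <- c(newloop, loop[e])
    if (nrow(ins[[e]])) {
      ord <- order(ins[[e]][, 2])
      newloop <- c(newloop, as.integer(ins[[e]][ord, 1]))
    }
  }
  # split the augmented loop at i1 and i2
  k1 <- match(i1, newloop); k2 <- match(i2, newloop)
  if (k1 > k2) { tmp <- k1; k1 <- k2; k2 <- tmp }
  loopA <- newloop[k1:k2]
  loopB <- c(newloop[k2:length(newloop)], newloop[seq_len(k1)])
  # rebuild walls: the split parent edges inherit the parent's birth time
  splits <- c(ch$e1, ch$e2)
  wl <- cc$walls
  for (e in splits) {
    a <- loop[e]; b <- loop[e %% n + 1]
    vid <- if (e == ch$e1) i1 else i2
    hit <- which((wl$v1 == min(a, b)) & (wl$v2 == max(a, b)))
    if (length(hit)) {
      bt <- wl$birth[hit[1]]
      wl <- wl[-hit[1], ]
      wl <- rbind(wl, data.frame(v1 = min(a, vid), v2 = max(a, vid), birth = bt),
                  data.frame(v1 = min(vid, b), v2 = max(vid, b), birth = bt))
    }
  }
  wl <- rbind(wl, data.frame(v1 = min(i1, i2), v2 = max(i1, i2), birth = time))
  cc$walls <- wl
  cc$cells[[cell]] <- loopA
  cc$cells[[length(cc$cells) + 1L]] <- loopB
  cc
}

#' Sweep all cells, dividing any over the threshold
#' @param cc a `cell_complex`.
#' @param time birth time for new walls.
#' @param shorten wall shortening fraction.
#' @return the complex after repeated division sweeps (no cell left above
#'   the threshold).
#' @export
divide_sweep <- function(cc, time = cc$time, shorten = 0.1) {
  repeat {
    a <- cell_areas(cc)
    over <- which(a > cc$threshold)
    if (!length(over)) break
    for (i in over) cc <- divide_cell(cc, i, time = time, shorten = shorten)
  }
  cc
}

#' Advect a cell complex with a canvas deformation
#'
#' Maps every cell vertex through the deformation between two canvas
#' configurations with identical topology: each vertex is located in a
#' triangle of the old canvas (barycentric coordinates, projected to the
#' nearest triangle with a warning if outside) and re-emitted from the new
#' canvas.  Cell topology is unchanged.
#'
#' @param cc a `cell_complex` (vertices in canvas xy coordinates).
#' @param canvas_before,canvas_after canvases before and after deformation.
#' @return the advected complex.
#' @export
advect_cells <- function(cc, canvas_before, canvas_after) {
  t <- canvas_before$triangles
  vb <- canvas_before$vertices
  va <- canvas_after$vertices
  out <- cc$vertices
  for (k in seq_len(nrow(cc$vertices))) {
    pt <- cc$vertices[k, ]
    found <- FALSE
    best_d <- Inf; best <- NULL
    for (i in seq_len(nrow(t))) {
      a <- vb[t[i, 1], 1:2]; b <- vb[t[i, 2], 1:2]; cpt <- vb[t[i, 3], 1:2]
      M <- cbind(b - a, cpt - a)
      dt <- det(M)
      if (abs(dt) < 1e-14) next
      lam <- solve(M, pt - a)
      l <- c(1 - sum(lam), lam)
      miss <- -min(l)
      if (miss <= 1e-9) {
        bc <- l; tri <- i; found <- TRUE; break
      } else if (miss < best_d) {
        best_d <- miss; best <- list(l = clamp(l, 0, 1), tri = i)
      }
    }
    if (!found) {
      warning("cell vertex outside canvas: projected to nearest element")
      bc <- best$l / sum(best$l); tri <- best$tri
    }
    q <- bc[1] * va[t[tri, 1], 1:2] + bc[2] * va[t[tri, 2], 1:2] +
      bc[3] * va[t[tri, 3], 1:2]
    out[k, ] <- q
  }
  cc$vertices <- out
  cc
}

#' Classify walls by age
#'
#' @param cc a `cell_complex`.
#' @param t1_end end of phase T1 (walls born in (0, t1_end] are T1; born
#'   later are T2; walls with birth 0 or earlier are the original T0 walls).
#' @return factor vector over walls with levels T0, T1, T2 (the rendering
#'   convention is T0 thick blue, T1 green, T2 thin white).
#' @export
wall_age_class <- function(cc, t1_end) {
  b <- cc$walls$birth
  factor(ifelse(b <= 0, "T0", ifelse(b <= t1_end, "T1", "T2")),
         levels = c("T0", "T1", "T2"))
}

#' Wall orientation angles
#' @param cc a `cell_complex`.
#' @return per-wall angle to the x axis, in `[0, pi)`.
#' @export
wall_angles <- function(cc) {
  d <- cc$vertices[cc$walls$v2, , drop = FALSE] -
    cc$vertices[cc$walls$v1, , drop = FALSE]
  atan2(d[, 2], d[, 1]) %% pi
}

#' Growth-orientation lines from recent walls
#'
#' A line perpendicular to each recent division wall indicates the local
#' growth orientation; lines are classified by their angle to the reference
#' axis: parallel (<= 30 degrees, rendered red), perpendicular (>= 60
#' degrees, yellow) or diagonal (orange).
#'
#' @param cc a `cell_complex`.
#' @param axis reference axis angle in radians (default `pi/2`, the
#'   proximodistal y axis).
#' @param since only walls born after this time (default all non-original).
#' @return data frame with wall index, wall angle, line angle, and class.
#' @export
orientation_lines <- function(cc, axis = pi / 2, since = 0) {
  sel <- which(cc$walls$birth > since)
  if (!length(sel)) abort("no recent walls to classify")
  wa <- wall_angles(cc)[sel]
  line <- (wa + pi / 2) %% pi
  dang <- abs(((line - axis + pi / 2) %% pi) - pi / 2) * 180 / pi
  cls <- ifelse(dang <= 30, "parallel", ifelse(dang >= 60, "perpendicular", "diagonal"))
  data.frame(wall = sel, wall_angle = wa, line_angle = line,
             angle_to_axis = dang,
             class = factor(cls, levels = c("parallel", "perpendicular", "diagonal")))
}

#' Run a cell-file growth pattern
#'
#' Simulates the three printed cell-file growth patterns on an initial cell
#' grid under a proximodistal (+y) polarity: pattern 1 uniform isotropic
#' (Kpar = Kper = 0.05), pattern 2 proximodistal (Kpar = 0.08, Kper = 0),
#' pattern 3 proximodistal then mediolateral (T1: Kpar = 0.1, Kper = 0;
#' T2: Kpar = 0, Kper = 0.1).  Specified growth is uniform, hence
#' conflict-free, and the deformation is the exact affine map
#' `diag(exp(Kper dt), exp(Kpar dt))` per step.
#'
#' @param pattern 1, 2 or 3.
#' @param phases length of phases T1 and T2 in hours.
#' @param shape initial cell geometry 1..4 (see [gen_cell_grid()]).
#' @param n number of initial cells.
#' @param dt step (hours).
#' @param seed seed for the initial grid jitter.
#' @return list with the final `cells` complex, `t1_end`, and the phase
#'   rate table.
#' @export
run_cellfile_model <- function(pattern, phases = c(24, 24), shape = 1,
                               n = 9, dt = 1, seed = 1) {
  rates <- switch(as.character(pattern),
    "1" = list(T1 = c(kpar = 0.05, kper = 0.05), T2 = c(kpar = 0.05, kper = 0.05)),
    "2" = list(T1 = c(kpar = 0.08, kper = 0), T2 = c(kpar = 0.08, kper = 0)),
    "3" = list(T1 = c(kpar = 0.1, kper = 0), T2 = c(kpar = 0, kper = 0.1)),
    abort("pattern must be 1, 2 or 3"))
  cc <- gen_cell_grid(shape, n, seed = seed)
  t <- 0
  for (ph in c("T1", "T2")) {
    r <- rates[[ph]]
    dur <- phases[[if (ph == "T1") 1 else 2]]
    nstep <- ceiling(dur / dt)
    for (s in seq_len(nstep)) {
      sx <- exp(r["kper"] * dt); sy <- exp(r["kpar"] * dt)
      cc$vertices <- cc$vertices %*% diag(c(sx, sy))
      t <- t + dt
      cc$time <- t
      cc <- divide_sweep(cc, time = t)
    }
  }
  list(cells = cc, t1_end = phases[1], rates = rates)
}

#' Plot a cell complex with the wall-age colour code
#'
#' Renders walls on a dark background with the calcofluor-like convention:
#' original T0 walls thick blue, T1 walls green, T2 walls thin white.
#'
#' @param cc a `cell_complex`.
#' @param t1_end end of phase T1 for age classing.
#' @param ... passed to `plot`.
#' @export
plot_cell_complex <- function(cc, t1_end = Inf, ...) {
  cls <- wall_age_class(cc, t1_end)
  cols <- c(T0 = "#4060ff", T1 = "#30c030", T2 = "#ffffff")
  lwds <- c(T0 = 3, T1 = 1.8, T2 = 0.8)
  op <- graphics::par(bg = "black")
  on.exit(graphics::par(op))
  plot(cc$vertices, type = "n", asp = 1, axes = FALSE, xlab = "", ylab = "", ...)
  graphics::segments(cc$vertices[cc$walls$v1, 1], cc$vertices[cc$walls$v1, 2],
                     cc$vertices[cc$walls$v2, 1], cc$vertices[cc$walls$v2, 2],
                     col = cols[as.character(cls)], lwd = lwds[as.character(cls)])
  invisible(cc)
}

#' Write the wall table as CSV
#' @param cc a `cell_complex`.
#' @param path output path.
#' @param t1_end phase boundary for age classes.
#' @export
write_wall_csv <- function(cc, path, t1_end = Inf) {
  wa <- wall_angles(cc)
  df <- data.frame(v1 = cc$walls$v1, v2 = cc$walls$v2,
                   x1 = cc$vertices[cc$walls$v1, 1],
                   y1 = cc$vertices[cc$walls$v1, 2],
                   x2 = cc$vertices[cc$walls$v2, 1],
                   y2 = cc$vertices[cc$walls$v2, 2],
                   birth = cc$walls$birth,
                   angle = wa,
                   age_class = wall_age_class(cc, t1_end))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
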