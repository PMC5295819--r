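# Time stepping and conflict quantification.
#
# Growth of a region is described by a growth tensor with a strain
# (symmetric) and a rotational (skew-symmetric) component.  Specified
# growth has no rotational component; the resultant growth measured from
# the realised deformation may have both.  The difference between resultant
# and specified strain is the residual strain; nonzero local rotations and
# residual strain diagnose tissue conflict.

# orthonormal in-plane basis for a triangle (rows p1,p2,p3)
tri_frame <- function(p1, p2, p3) {
  d1 <- p2 - p1; d2 <- p3 - p1
  e1 <- d1 / sqrt(sum(d1^2))
  n <- c(d1[2] * d2[3] - d1[3] * d2[2],
         d1[3] * d2[1] - d1[1] * d2[3],
         d1[1] * d2[2] - d1[2] * d2[1])
  n <- n / sqrt(sum(n^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2, n = n)
}

logm2 <- function(S) {
  # matrix log of a symmetric positive-definite 2x2 matrix
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ev$vectors %*% diag(log(pmax(ev$values, 1e-300))) %*% t(ev$vectors)
}

#' Resultant growth tensor of one element over a step
#'
#' Decomposes the in-plane deformation gradient of a triangle between two
#' configurations (polar decomposition F = R U) into a rotation and a
#' symmetric stretch; the strain rate is `log(U) / dt` and the rotation
#' rate combines the in-plane rotation angle with the tilt of the element
#' normal.
#'
#' @param verts_before,verts_after 3 x 3 matrices of the element's vertex
#'   positions (rows) in the two configurations.
#' @param dt time elapsed between the configurations (hours).
#' @return list with `strain_rate` (2 x 2 symmetric, in the before-frame),
#'   `rotation_inplane` and `rotation_outofplane` (radians per hour),
#'   `rotation` (their Euclidean combination), `F` and `R`.
#' @export
resultant_tensor <- function(verts_before, verts_after, dt = 1) {
  degen <- function(v) {
    n <- cross3(rbind(v[2, ] - v[1, ]), rbind(v[3, ] - v[1, ]))
    sqrt(sum(n^2)) < 1e-12 * max(sum((v[2, ] - v[1, ])^2), 1e-300)
  }
  if (degen(verts_before) || degen(verts_after)) abort("degenerate element")
  fb <- tri_frame(verts_before[1, ], verts_before[2, ], verts_before[3, ])
  fa <- tri_frame(verts_after[1, ], verts_after[2, ], verts_after[3, ])
  # parallel-transport the deformed element back into the before-plane by
  # the minimal rotation aligning the normals, so the in-plane rotation of
  # the deformation is measured rather than absorbed into the frame
  axis <- c(fa$n[2] * fb$n[3] - fa$n[3] * fb$n[2],
            fa$n[3] * fb$n[1] - fa$n[1] * fb$n[3],
            fa$n[1] * fb$n[2] - fa$n[2] * fb$n[1])
  s <- sqrt(sum(axis^2)); cth <- clamp(sum(fa$n * fb$n), -1, 1)
  rot_to_before <- if (s < 1e-14) {
    function(x) x
  } else {
    k <- axis / s
    th <- atan2(s, cth)
    function(x) {
      x * cos(th) + c(k[2] * x[3] - k[3] * x[2],
                      k[3] * x[1] - k[1] * x[3],
                      k[1] * x[2] - k[2] * x[1]) * sin(th) +
        k * sum(k * x) * (1 - cos(th))
    }
  }
  proj <- function(x) c(sum(x * fb$e1), sum(x * fb$e2))
  D0 <- cbind(proj(verts_before[2, ] - verts_before[1, ]),
              proj(verts_before[3, ] - verts_before[1, ]))
  D1 <- cbind(proj(rot_to_before(verts_after[2, ] - verts_after[1, ])),
              proj(rot_to_before(verts_after[3, ] - verts_after[1, ])))
  if (abs(det(D0)) < 1e-300) abort("degenerate element")
  F <- D1 %*% solve(D0)
  sv <- svd(F)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {  # keep a proper rotation
    sv$u[, 2] <- -sv$u[, 2]; sv$d[2] <- -sv$d[2]
    R <- sv$u %*% t(sv$v)
  }
  U <- sv$v %*% diag(sv$d) %*% t(sv$v)
  ang <- atan2(R[2, 1], R[1, 1])
  tilt <- acos(clamp(sum(fb$n * fa$n), -1, 1))
  list(strain_rate = logm2(U) / dt,
       rotation_inplane = ang / dt,
       rotation_outofplane = tilt / dt,
       rotation = sqrt((ang / dt)^2 + (tilt / dt)^2),
       F = F, R = R)
}

# specified mid-surface strain-rate tensor of element i, in the element's
# in-plane orthonormal frame
specified_strain <- function(cv, i, rates) {
  kp <- (rep_len(rates$kpar_a, nrow(cv$triangles))[i] +
           rep_len(rates$kpar_b, nrow(cv$triangles))[i]) / 2
  kq <- (rep_len(rates$kper_a, nrow(cv$triangles))[i] +
           rep_len(rates$kper_b, nrow(cv$triangles))[i]) / 2
  if (kp == kq) return(diag(c(kp, kp)))
  pm <- cv$polarity_A[i, ]
  pmB <- cv$polarity_B[i, ]
  if (!all(is.finite(pm))) pm <- pmB
  if (!all(is.finite(pm))) return(diag(c((kp + kq) / 2, (kp + kq) / 2)))
  t <- cv$triangles[i, ]
  v <- cv$vertices
  f <- tri_frame(v[t[1], ], v[t[2], ], v[t[3], ])
  d1 <- v[t[2], ] - v[t[1], ]; d2 <- v[t[3], ] - v[t[1], ]
  p3 <- pm[1] * d1 + pm[2] * d2
  p2 <- c(sum(p3 * f$e1), sum(p3 * f$e2))
  p2 <- p2 / sqrt(sum(p2^2))
  q2 <- c(-p2[2], p2[1])
  kp * tcrossprod(p2) + kq * tcrossprod(q2)
}

#' Advance a canvas by one growth/relaxation step
#'
#' Evaluates the growth spec on the canvas factors, grows the rest metrics,
#' relaxes to elastic equilibrium, re-derives polarity from the advected
#' polariser field, and records the per-element conflict diagnostics of the
#' step.
#'
#' @param canvas a canvas.
#' @param spec a [growth_spec()].
#' @param dt step length (hours).
#' @param relax_tol,relax_max_iter solver controls.
#' @return the advanced canvas; the last step's diagnostics are available
#'   via [conflict_report()].
#' @export
advance_canvas <- function(canvas, spec, dt = 1, relax_tol = 1e-6,
                           relax_max_iter = 2000L) {
  target <- canvas$meta$target_edge
  if (!is.null(target) && any(edge_lengths_exceed(canvas, 2 * target))) {
    canvas <- remesh(canvas, 2 * target)
  }
  ftri <- factors_on_triangles(canvas)
  rates <- eval_growth(spec, ftri)
  fvert <- canvas$factors
  knor_v <- eval_expr(spec$knor, fvert)
  rates$knor <- knor_v
  # elements whose polarity is undefined (degenerate POL gradient) are
  # grown isotropically at the same areal rate for this step
  m0 <- nrow(canvas$triangles)
  for (s in c("a", "b")) {
    polm <- canvas[[if (s == "a") "polarity_A" else "polarity_B"]]
    kp <- rep_len(rates[[paste0("kpar_", s)]], m0)
    kq <- rep_len(rates[[paste0("kper_", s)]], m0)
    und <- !is.finite(polm[, 1]) & kp != kq
    if (any(und)) {
      mean_k <- (kp[und] + kq[und]) / 2
      kp[und] <- mean_k; kq[und] <- mean_k
      rates[[paste0("kpar_", s)]] <- kp
      rates[[paste0("kper_", s)]] <- kq
    }
  }
  before <- canvas$vertices
  tris <- canvas$triangles
  canvas <- grow_rest_metrics(canvas, rates, dt)
  canvas <- relax(canvas, tol = relax_tol, max_iter = relax_max_iter)
  canvas <- refresh_polarity(canvas)
  # per-element diagnostics
  m <- nrow(tris)
  res_strain <- numeric(m); rot <- numeric(m)
  kp_m <- (rep_len(rates$kpar_a, m) + rep_len(rates$kpar_b, m)) / 2
  kq_m <- (rep_len(rates$kper_a, m) + rep_len(rates$kper_b, m)) / 2
  old_cv <- list(vertices = before, triangles = tris,
                 polarity_A = canvas$polarity_A, polarity_B = canvas$polarity_B)
  for (i in seq_len(m)) {
    t <- tris[i, ]
    rt <- resultant_tensor(before[t, , drop = FALSE],
                           canvas$vertices[t, , drop = FALSE], dt)
    sp <- specified_strain(old_cv, i, rates)
    res_strain[i] <- sqrt(sum((rt$strain_rate - sp)^2))
    rot[i] <- rt$rotation
  }
  dr <- derived_rates(kp_m, kq_m)
  canvas$report <- data.frame(element = seq_len(m),
                              residual_strain_norm = res_strain,
                              rotation_magnitude = rot,
                              Kaniso = dr$Kaniso, Karea = dr$Karea)
  canvas$time <- canvas$time + dt
  canvas
}

#' Per-element conflict report of the last completed step
#'
#' @param canvas a canvas that has been advanced at least one step.
#' @param window ignored for now (single-step reporting).
#' @return data frame with per-element `residual_strain_norm`,
#'   `rotation_magnitude` (radians per hour), `Kaniso` and `Karea`.
#' @export
conflict_report <- function(canvas, window = 1L) {
  if (is.null(canvas$report)) abort("no completed step: advance the canvas first")
  canvas$report
}

#' Advance a canvas under a full model configuration
#'
#' Applies any events scheduled in `(time, time + dt]`, selects the phase
#' covering the current time, and advances one step.
#'
#' @param canvas a canvas.
#' @param model a model configuration (see [get_model()]).
#' @param dt step length (hours).
#' @param ... passed to [advance_canvas()].
#' @return the advanced canvas.
#' @export
step_canvas <- function(canvas, model, dt = 1, ...) {
  done <- canvas$meta$events_done %||% character(0)
  for (ev in model$events %||% list()) {
    if (!is.null(ev$id) && ev$id %in% done) next
    if (ev$time <= canvas$time + 1e-9) {
      canvas <- ev$action(canvas)
      done <- c(done, ev$id)
    }
  }
  canvas$meta$events_done <- done
  ph <- NULL
  for (p in model$phases) {
    if (canvas$time >= p$t0 - 1e-9 && canvas$time < p$t1 - 1e-9) { ph <- p; break }
  }
  if (is.null(ph)) {
    abort("model `%s` has no phase covering time %.2f h", model$name, canvas$time)
  }
  advance_canvas(canvas, ph$spec, dt, ...)
}
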