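test_that("derived_rates: anisotropy and areal rate", {
  r <- derived_rates(0.05, 0.05)
  expect_equal(r$Kaniso, 0)
  expect_equal(r$Karea, 0.1)
  expect_equal(derived_rates(0.05, 0.02)$Kaniso, log(2.5), tolerance = 1e-12)
  expect_equal(derived_rates(0.01, -0.01)$Karea, 0)
  # display clamp to [-1, 1] and contraction handling
  expect_equal(derived_rates(1, 0.01)$Kaniso, 1)
  expect_equal(derived_rates(0.01, -0.01)$Kaniso, 1)
  expect_equal(derived_rates(-0.01, 0.01)$Kaniso, -1)
})

test_that("grow_rest_metrics: exponential compounding, perpendicular, thickness", {
  cv <- flat_square(50, 10)
  g0 <- cv$rest_A
  rates <- list(kpar_a = 0.03, kpar_b = 0.03, kper_a = 0.03, kper_b = 0.03,
                knor = 0.044)
  cv2 <- grow_rest_metrics(cv, rates, dt = 1)
  expect_equal(cv2$rest_A, g0 * exp(0.03)^2, tolerance = 1e-12)
  expect_equal(cv2$thickness, cv$thickness * exp(0.044), tolerance = 1e-12)

  # anisotropic: rest lengths along polarity scale, perpendicular unchanged
  cvp <- cv
  cvp$polarity_A <- matrix(NA_real_, nrow(cv$triangles), 2)
  # polarity along +y expressed in edge coordinates per triangle
  e <- tissuecanvas:::tri_edges(cv)
  for (i in seq_len(nrow(cv$triangles))) {
    C <- matrix(c(sum(e$d1[i, ]^2), sum(e$d1[i, ] * e$d2[i, ]),
                  sum(e$d1[i, ] * e$d2[i, ]), sum(e$d2[i, ]^2)), 2, 2)
    u <- solve(C, c(e$d1[i, 2], e$d2[i, 2]))  # coords of (0,1,0)
    cvp$polarity_A[i, ] <- u / sqrt(drop(t(u) %*% C %*% u))
  }
  cvp$polarity_B <- cvp$polarity_A
  rates <- list(kpar_a = 0.1, kpar_b = 0.1, kper_a = 0, kper_b = 0, knor = 0)
  cvg <- grow_rest_metrics(cvp, rates, dt = 1)
  # rest length of a horizontal unit vector (perpendicular to polarity):
  # use an element whose d1 is horizontal
  horiz <- which(abs(e$d1[, 2]) < 1e-9 & abs(e$d1[, 3]) < 1e-9)[1]
  expect_equal(cvg$rest_A[horiz, 1], cvp$rest_A[horiz, 1], tolerance = 1e-9)
  # rest area scales by exp(Kpar + Kper)
  expect_equal(tissuecanvas:::rest_areas(cvg$rest_A),
               tissuecanvas:::rest_areas(cvp$rest_A) * exp(0.1),
               tolerance = 1e-9)
  # anisotropic growth without polarity is an error naming the element
  expect_error(grow_rest_metrics(cv, rates, 1), "polarity")
})

test_that("relax: equilibrium at rest, free scaling, energy monotone", {
  cv <- flat_square(60, 12)
  v0 <- cv$vertices
  cvr <- relax(cv)
  expect_equal(cvr$vertices, v0, tolerance = 1e-9)

  # all rest lengths doubled: free sheet scales x2 with ~zero energy
  cv2 <- cv
  cv2$rest_A <- cv$rest_A * 4
  cv2$rest_B <- cv$rest_B * 4
  cvr2 <- relax(cv2, tol = 1e-10, max_iter = 10000)
  expect_equal(canvas_area(cvr2) / canvas_area(cv), 4, tolerance = 0.001)
  e_scale <- canvas_energy(cv2)  # energy before relaxing, for scale
  expect_lt(attr(cvr2, "relax_energy"), 1e-6 * e_scale)
  expect_true(all(diff(attr(cvr2, "relax_trace")) <= 1e-12))
})

test_that("small-mesh equilibria match brute-force energy minimisation", {
  set.seed(42)
  # 2-triangle and 4-triangle instances with incompatible rest metrics
  make_case <- function(n_tri) {
    if (n_tri == 2) {
      v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
      tr <- rbind(c(1, 2, 3), c(1, 3, 4))
    } else {
      v <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                 c(0.5, 1, 0), c(1.5, 1, 0), c(1, 2, 0))
      tr <- rbind(c(1, 2, 4), c(2, 5, 4), c(2, 3, 5), c(4, 5, 6))
    }
    cv <- tissuecanvas:::new_canvas(v, tr, thickness = 0.2)
    for (i in seq_len(nrow(tr))) {
      f <- exp(stats::runif(1, -0.2, 0.25))
      cv$rest_A[i, ] <- cv$rest_A[i, ] * f
      cv$rest_B[i, ] <- cv$rest_A[i, ]
    }
    cv
  }
  for (n_tri in c(2, 4)) {
    cv <- make_case(n_tri)
    cvr <- relax(cv, tol = 1e-12, max_iter = 50000)
    f <- function(x) {
      c2 <- cv; c2$vertices <- matrix(x, ncol = 3); canvas_energy(c2)
    }
    o <- stats::optim(as.vector(cv$vertices) + stats::rnorm(length(cv$vertices), 0, 0.01),
                      f, method = "BFGS",
                      control = list(maxit = 10000, reltol = 1e-15))
    expect_lt(abs(attr(cvr, "relax_energy") - o$value) /
                max(abs(o$value), 1e-12), 1e-6)
  }
})

test_that("step: conflict-free growth laws (area, planarity, aspect ratio)", {
  # uniform isotropic: area ratio e^(Karea t), stays planar from a flat start
  cv <- flat_square(100, 10)
  spec <- growth_spec("0.03", "0.03", "0.044")
  a0 <- canvas_area(cv)
  for (i in 1:6) cv <- advance_canvas(cv, spec, dt = 1)
  expect_equal(canvas_area(cv) / a0, exp(0.06 * 6), tolerance = 0.01)
  expect_lt(max(abs(cv$vertices[, 3])), 0.001 * diff(canvas_bbox(cv)[, 1]))
  rep <- conflict_report(cv)
  expect_lt(max(rep$residual_strain_norm), 1e-3)
  expect_lt(max(rep$rotation_magnitude), 1e-3)

  # uniform anisotropic: aspect ratio e^((Kpar-Kper) t)
  cv <- flat_square(100, 10)
  cv <- setup_square_factors(cv)
  cv <- update_polariser(cv, pol_config(production = "BOTTOM",
                                        fixed = list(TOP = 0.01)))
  spec <- growth_spec("0.03", "0.02", "0")
  bb0 <- canvas_bbox(cv)
  for (i in 1:6) cv <- advance_canvas(cv, spec, dt = 1)
  bb1 <- canvas_bbox(cv)
  ar <- (diff(bb1[, 2]) / diff(bb1[, 1])) / (diff(bb0[, 2]) / diff(bb0[, 1]))
  expect_equal(ar, exp(0.01 * 6), tolerance = 0.02)
})

test_that("resultant_tensor: rigid rotation, conflict-free, SVD oracle", {
  vb <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.3, 1, 0))
  th <- pi / 6
  Rz <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  va <- cbind(t(Rz %*% t(vb[, 1:2])), 0)
  rt <- resultant_tensor(vb, va, dt = 1)
  expect_lt(sqrt(sum(rt$strain_rate^2)), 1e-12)
  expect_equal(rt$rotation_inplane, th, tolerance = 1e-12)

  # conflict-free uniform growth: resultant strain equals specified strain
  cv <- flat_square(80, 10)
  spec <- growth_spec("0.04", "0.04", "0")
  cv <- advance_canvas(cv, spec, dt = 1)
  rep <- conflict_report(cv)
  expect_lt(max(rep$residual_strain_norm), 1e-6)

  # random positive-determinant maps against an independent SVD oracle
  set.seed(11)
  for (k in 1:20) {
    F <- matrix(stats::rnorm(4), 2, 2)
    if (det(F) < 0) F[, 1] <- -F[, 1]
    va <- cbind(t(F %*% t(vb[, 1:2])), 0)
    rt <- resultant_tensor(vb, va, dt = 1)
    sv <- svd(F)
    R <- sv$u %*% t(sv$v)
    if (det(R) < 0) { sv$u[, 2] <- -sv$u[, 2]; R <- sv$u %*% t(sv$v) }
    U <- sv$v %*% diag(sv$d) %*% t(sv$v)
    expect_lt(max(abs(rt$F - F)), 1e-9)
    expect_lt(ang_diff_deg(rt$rotation_inplane, atan2(R[2, 1], R[1, 1])) * pi / 180,
              1e-9)
    ev <- eigen(U, symmetric = TRUE)
    logU <- ev$vectors %*% diag(log(ev$values)) %*% t(ev$vectors)
    expect_lt(max(abs(rt$strain_rate - logU)), 1e-9)
  }
  expect_error(resultant_tensor(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                                vb), "degenerate")
})

test_that("conflict diagnosis: areal rotation, surface curvature sign flip", {
  # areal conflict generates local rotations well above the conflict-free bound
  m <- get_model("fig1_areal")
  res <- suppressWarnings(run_model(m, resolution = 12, t_end = 6))
  expect_gt(stats::quantile(res$report$rotation_magnitude, 0.9), 1e-2 * 1e-1)
  expect_gt(max(res$report$rotation_magnitude), 10 * 1e-3)

  # surface conflict: swapping the A/B rates flips the curvature sign
  m1 <- get_model("fig1_surface")
  r1 <- suppressWarnings(run_model(m1, resolution = 14, t_end = 6))
  m2 <- m1
  m2$phases[[1]]$spec <- growth_spec(knor = "0.044",
                                     kpar_a = "0.05", kper_a = "0.05",
                                     kpar_b = "0.06", kper_b = "0.06")
  r2 <- suppressWarnings(run_model(m2, resolution = 14, t_end = 6))
  centre_z <- function(r) {
    v <- r$canvas$vertices
    mean(v[abs(v[, 1]) < 25 & abs(v[, 2]) < 25, 3])
  }
  expect_gt(centre_z(r1), 1)    # faster A (adaxial, +z): dome up
  expect_lt(centre_z(r2), -1)   # swapped: dome down
})
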