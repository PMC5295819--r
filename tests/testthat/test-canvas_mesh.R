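test_that("square canvas construction: flatness, area, determinism", {
  cv <- flat_square(100, 10)
  expect_equal(max(abs(cv$vertices[, 3])), 0)
  expect_equal(canvas_area(cv), 10000, tolerance = 1e-3)
  bb <- canvas_bbox(cv)
  expect_equal(diff(bb[, 1]), 100)
  expect_equal(diff(bb[, 2]), 100)

  a <- make_square_canvas(100, 10, z_noise_amplitude = 0.5, seed = 7)
  b <- make_square_canvas(100, 10, z_noise_amplitude = 0.5, seed = 7)
  expect_identical(a$vertices, b$vertices)
  c2 <- make_square_canvas(100, 10, z_noise_amplitude = 0.5, seed = 8)
  expect_false(identical(a$vertices, c2$vertices))

  expect_error(make_square_canvas(-1, 1), "positive")
  expect_error(make_square_canvas(100, 200), "smaller")
})

test_that("strip canvas: bounding box, curvature profile", {
  cv <- make_strip_canvas(1060, 120)
  bb <- canvas_bbox(cv)
  expect_equal(diff(bb[, 1]), 1060)
  expect_equal(diff(bb[, 2]), 120)

  flat <- make_strip_canvas(200, 40, curvature_sagitta = 0)
  expect_equal(max(abs(flat$vertices[, 3])), 0)

  bent <- make_strip_canvas(200, 40, curvature_sagitta = 6)
  # mid-strip deviation equals the sagitta of the analytic cap profile
  expect_equal(max(abs(bent$vertices[, 3])), 6, tolerance = 0.05 * 6)
  # abaxially convex: centre below the ends
  mid <- abs(bent$vertices[, 1]) < 1e-6
  expect_lt(mean(bent$vertices[mid, 3]), 0)
  expect_error(make_strip_canvas(0, 10), "positive")
})

test_that("clones: disjoint grid, induction area, passivity under growth", {
  # grid disjointness + induction area on a finely meshed strip
  cv <- make_strip_canvas(1060, 120, curvature_sagitta = 0, resolution = 3)
  cv <- induce_clones(cv, radius = 10, spacing = 50)
  clones <- attr(cv, "clones")
  cen <- do.call(rbind, lapply(clones, `[[`, "centre"))
  expect_gte(min(dist(cen)), 50 - 1e-9)
  expect_error(induce_clones(cv, radius = 60, spacing = 50), "smaller")

  # clone area at induction ~ pi r^2 (mesh discretisation tolerance)
  areas <- vapply(clones, function(cl) clone_stats(cv, cl$id)$area, numeric(1))
  expect_lt(abs(mean(areas) / (pi * 100) - 1), 0.15)

  # uniform isotropic growth: clone area ratio tracks canvas area ratio
  cv <- flat_square(100, 8)
  cv <- induce_clones(cv, radius = 8, spacing = 30)
  clones <- attr(cv, "clones")
  spec <- growth_spec("0.04", "0.04", "0")
  a0 <- canvas_area(cv)
  c0 <- sum(vapply(clones, function(cl) clone_stats(cv, cl$id)$area, numeric(1)))
  cv2 <- cv
  for (i in 1:4) cv2 <- advance_canvas(cv2, spec, dt = 1)
  c1 <- sum(vapply(clones, function(cl) clone_stats(cv2, cl$id)$area, numeric(1)))
  expect_equal(c1 / c0, canvas_area(cv2) / a0, tolerance = 0.02)
})

test_that("clone_stats: isotropy of a disc, affine image anisotropy", {
  cv <- flat_square(100, 4)
  cv <- induce_clones(cv, radius = 15, spacing = 60)
  st <- clone_stats(cv, attr(cv, "clones")[[1]]$id)
  expect_gt(st$major_axis, 0)
  expect_gte(st$major_axis, st$minor_axis)
  expect_true(st$orientation >= 0 && st$orientation < pi)
  expect_equal(st$anisotropy, 1, tolerance = 0.1)

  # pure Kpar growth exp(0.5) along y: the clone becomes the affine image of
  # a disc with axis ratio e^0.5 oriented at pi/2
  cv2 <- cv
  cv2$vertices[, 2] <- cv2$vertices[, 2] * exp(0.5)
  st2 <- clone_stats(cv2, attr(cv, "clones")[[1]]$id)
  expect_equal(st2$anisotropy, exp(0.5), tolerance = 0.1)
  expect_lt(axial_diff_deg(st2$orientation, pi / 2), 10)
  expect_error(clone_stats(cv, 999), "empty")
})

test_that("remesh: no-op when fine, preserves area and linear fields, quality", {
  cv <- flat_square(100, 10)
  same <- remesh(cv, 50)
  expect_equal(nrow(same$triangles), nrow(cv$triangles))

  cv <- set_factor(cv, "lin", 0.3 + 0.004 * cv$vertices[, 1])
  a0 <- canvas_area(cv)
  fine <- remesh(cv, 7)
  expect_gt(nrow(fine$triangles), nrow(cv$triangles))
  expect_equal(canvas_area(fine) / a0, 1, tolerance = 0.005)
  expect_equal(fine$factors$lin, 0.3 + 0.004 * fine$vertices[, 1],
               tolerance = 0.01)
  # no edge above the bound; min angle stays decent
  expect_false(any(tissuecanvas:::edge_lengths_exceed(fine, 7)))
  e <- tissuecanvas:::tri_edges(fine)
  d3 <- e$d2 - e$d1
  ang <- function(u, w) acos(pmax(pmin(rowSums(u * w) /
    sqrt(rowSums(u * u) * rowSums(w * w)), 1), -1))
  angles <- c(ang(e$d1, e$d2), ang(-e$d1, d3), ang(-e$d2, -d3))
  expect_gte(min(angles) * 180 / pi, 15)
  expect_error(remesh(cv, -1), "positive")
})

test_that("remesh preserves rest metrics exactly (no spurious energy)", {
  cv <- flat_square(100, 10)
  e0 <- canvas_energy(cv)
  fine <- remesh(cv, 6)
  expect_lt(canvas_energy(fine), 1e-9 + e0)
})

test_that("mesh I/O round-trips through OBJ and PLY with factor sidecars", {
  cv <- make_square_canvas(50, 10, curvature_sagitta = 2)
  cv <- set_factor(cv, "f1", seq_len(nrow(cv$vertices)) / nrow(cv$vertices))
  d <- withr::local_tempdir()
  write_obj(cv, file.path(d, "m.obj"))
  back <- read_obj(file.path(d, "m.obj"))
  expect_equal(back$vertices, unname(cv$vertices), tolerance = 1e-6)
  expect_equal(back$triangles, cv$triangles, ignore_attr = TRUE)

  write_ply(cv, file.path(d, "m.ply"))
  back2 <- read_ply(file.path(d, "m.ply"))
  expect_equal(back2$vertices, unname(cv$vertices), tolerance = 1e-6)
  expect_equal(back2$triangles, cv$triangles, ignore_attr = TRUE)

  write_factor_csv(cv, file.path(d, "f.csv"))
  cv2 <- read_factor_csv(back, file.path(d, "f.csv"))
  expect_equal(cv2$factors$f1, cv$factors$f1)
})
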