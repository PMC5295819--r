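test_that("advect_cells: identity, uniform scaling, anisotropic stretch", {
  cv0 <- flat_square(60, 10)
  cc <- gen_cell_grid(1, n = 4, cell_size = 8, seed = 2)
  cc$vertices <- sweep(cc$vertices, 2, c(12, 12))  # inside the canvas
  same <- advect_cells(cc, cv0, cv0)
  expect_equal(same$vertices, cc$vertices, tolerance = 1e-9)
  expect_identical(same$cells, cc$cells)

  cv1 <- cv0; cv1$vertices <- cv0$vertices * 1.5
  sc <- advect_cells(cc, cv0, cv1)
  expect_equal(cell_areas(sc), cell_areas(cc) * 1.5^2, tolerance = 1e-9)

  cv2 <- cv0; cv2$vertices[, 2] <- cv0$vertices[, 2] * exp(0.1)
  an <- advect_cells(cc, cv0, cv2)
  aspect <- function(c1) {
    vapply(seq_along(c1$cells), function(i) {
      p <- c1$vertices[c1$cells[[i]], ]
      diff(range(p[, 2])) / diff(range(p[, 1]))
    }, numeric(1))
  }
  expect_equal(aspect(an) / aspect(cc), rep(exp(0.1), 4), tolerance = 0.01)
})

test_that("divide_cell: rectangle bisector, square tie-break, exact partition", {
  # 2x1 rectangle: the division wall is the vertical bisector of length 1
  cc <- cell_complex(rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)), list(1:4),
                     threshold = 1)
  d <- divide_cell(cc, 1, time = 1, shorten = 0)
  expect_equal(sort(cell_areas(d)), c(1, 1), tolerance = 1e-9)
  wall <- d$walls[d$walls$birth == 1, ]
  p1 <- d$vertices[wall$v1, ]; p2 <- d$vertices[wall$v2, ]
  expect_equal(sqrt(sum((p1 - p2)^2)), 1, tolerance = 1e-6)
  expect_lt(axial_diff_deg(atan2(p2[2] - p1[2], p2[1] - p1[1]), pi / 2), 0.1)

  # unit square: equal-minimal chords tie-break deterministically to angle 0
  sq <- cell_complex(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), list(1:4),
                     threshold = 0.4)
  ch <- tissuecanvas:::shortest_chord(sq$vertices[sq$cells[[1]], ])
  expect_lt(abs(ch$angle), 1e-6)

  # daughters partition the parent exactly and each is a balanced share
  set.seed(5)
  for (k in 1:10) {
    poly <- random_convex_polygon(8, scale = 3)
    cc <- cell_complex(poly, list(seq_len(nrow(poly))), threshold = 0.1)
    a0 <- cell_areas(cc)
    d <- divide_cell(cc, 1, time = 1)
    a <- cell_areas(d)
    expect_equal(sum(a), a0, tolerance = 1e-9)
    expect_true(all(a / a0 >= 0.35 & a / a0 <= 0.65))
  }
})

test_that("shortest chord matches a dense-angle brute-force oracle", {
  set.seed(9)
  for (k in 1:15) {
    poly <- random_convex_polygon(sample(5:9, 1), scale = 2)
    ch <- tissuecanvas:::shortest_chord(poly)
    lens <- vapply(seq(0, pi, by = 0.1 * pi / 180), function(phi) {
      oracle_chord_len(poly, phi)
    }, numeric(1))
    expect_lte(ch$length, min(lens, na.rm = TRUE) * 1.005)
  }
})

test_that("division sweep: area bound and topology preservation", {
  cc <- gen_cell_grid(1, n = 4, cell_size = 10, seed = 1)
  thr <- cc$threshold
  # grow until divisions happen, checking the invariants
  nwall0 <- nrow(cc$walls)
  for (i in 1:30) {
    cc$vertices <- cc$vertices * exp(0.05)
    cc$time <- i
    cc <- divide_sweep(cc, time = i)
    expect_true(all(cell_areas(cc) <= 2 * thr))
  }
  expect_gt(length(cc$cells), 4)       # divisions occurred
  expect_gt(nrow(cc$walls), nwall0)    # walls only ever inserted
  # every wall endpoint referenced by cells; daughters share the new walls
  expect_true(all(unlist(cc$cells) <= nrow(cc$vertices)))
})

test_that("orientation_lines classifies by the printed angle bands", {
  # angles are measured between the wall and the proximodistal (y) axis:
  # a wall at 90 deg to the axis (horizontal) gives a parallel (red) line,
  # a wall at 0 deg (vertical) gives a perpendicular (yellow) line
  v <- rbind(c(2, 0), c(3, 0),      # horizontal wall: 90 deg to the axis
             c(0, 0), c(0, 1),      # vertical wall: 0 deg to the axis
             c(5, 0), c(6, 1))      # 45 deg: diagonal
  cc <- structure(list(vertices = v,
                       walls = data.frame(v1 = c(1, 3, 5), v2 = c(2, 4, 6),
                                          birth = c(1, 1, 1)),
                       cells = list(), time = 1, threshold = 1),
                  class = "cell_complex")
  ol <- orientation_lines(cc, axis = pi / 2)
  expect_equal(as.character(ol$class),
               c("parallel", "perpendicular", "diagonal"))
  expect_error(orientation_lines(cc, since = 2), "no recent walls")
})

test_that("cell-file growth patterns reproduce the printed wall statistics", {
  # pattern 2: proximodistal growth -> new walls perpendicular to growth
  r2 <- run_cellfile_model(2, phases = c(18, 18), n = 9, seed = 2)
  ol <- orientation_lines(r2$cells)
  expect_gte(mean(ol$angle_to_axis <= 30), 0.7)

  # pattern 1: isotropic growth -> randomly oriented walls
  r1 <- run_cellfile_model(1, phases = c(18, 18), n = 9, seed = 2)
  wa <- orientation_lines(r1$cells)$line_angle
  circ_var <- 1 - sqrt(mean(cos(2 * wa))^2 + mean(sin(2 * wa))^2)
  expect_gt(circ_var, 0.5)

  # pattern 3: T1 walls mainly horizontal, T2 walls mainly vertical
  r3 <- run_cellfile_model(3, phases = c(14, 14), n = 9, seed = 2)
  cls <- wall_age_class(r3$cells, r3$t1_end)
  ang <- wall_angles(r3$cells)
  horiz <- axial_diff_deg(ang, 0) < 30
  vert <- axial_diff_deg(ang, pi / 2) < 30
  expect_gt(mean(horiz[cls == "T1"]), 0.5)
  expect_gt(mean(vert[cls == "T2"]), 0.5)
  expect_setequal(levels(cls), c("T0", "T1", "T2"))
})
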