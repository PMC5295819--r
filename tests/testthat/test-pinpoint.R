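test_that("boundary band: radius 0, straight-edge thickness, set difference", {
  mask <- matrix(FALSE, 120, 120)
  mask[11:110, 11:110] <- TRUE

  expect_equal(sum(boundary_band(mask, 0)), 0)

  band <- boundary_band(mask, 5)
  expect_true(all(mask[band]))
  # thickness along a straight edge equals the radius
  col <- band[, 60]
  runs <- rle(col)
  expect_equal(runs$lengths[runs$values], c(5, 5))
  # band count is exactly mask minus eroded
  er <- erode_mask(mask, 5)
  expect_equal(sum(band), sum(mask) - sum(er))

  # over-large radius: whole mask with a warning
  tiny <- matrix(FALSE, 12, 12); tiny[5:8, 5:8] <- TRUE
  expect_warning(b2 <- boundary_band(tiny, 10), "whole mask")
  expect_equal(b2, tiny)
  expect_error(boundary_band(matrix(FALSE, 5, 5), 1), "empty")
})

test_that("cell_polarity: symmetry cancellation and single-pixel geometry", {
  mask <- matrix(FALSE, 41, 41)
  mask[6:36, 6:36] <- TRUE
  band <- boundary_band(mask, 3)
  # uniform intensity on a centro-symmetric band cancels
  img <- matrix(0, 41, 41); img[band] <- 7
  pv <- cell_polarity(img, mask, band)
  expect_lt(pv$magnitude, 1e-6 * sum(img))

  # single band pixel directly +x of the centroid
  img2 <- matrix(0, 41, 41)
  img2[21, 34] <- 200   # row = centroid row, col right of centre
  pv2 <- cell_polarity(img2, mask, band)
  expect_equal(pv2$vx, 200)
  expect_equal(pv2$vy, 0)
  expect_equal(pv2$angle, 0)

  # two opposite pixels cancel
  img3 <- img2; img3[21, 8] <- 200
  pv3 <- cell_polarity(img3, mask, band)
  expect_lt(pv3$magnitude, 1e-9)
  # all-zero intensity is a zero vector, not an error
  pv4 <- cell_polarity(matrix(0, 41, 41), mask, band)
  expect_equal(pv4$magnitude, 0)
})

test_that("window_average: per-tile sums and empty tiles", {
  vecs <- data.frame(vx = c(1, 0, 2), vy = c(0, 1, 0))
  pos <- rbind(c(10, 10), c(20, 15), c(70, 70))
  f <- window_average(vecs, pos, window = 30)
  t00 <- f[f$tile_x == 0 & f$tile_y == 0, ]
  expect_equal(c(t00$vx, t00$vy), c(1, 1))   # two cells summed
  expect_equal(t00$n, 2L)
  t22 <- f[f$tile_x == 2 & f$tile_y == 2, ]
  expect_equal(c(t22$vx, t22$vy), c(2, 0))   # single cell: its own vector
  expect_equal(nrow(f), 2)                   # empty tiles are absent (zero)
  fm <- window_average(vecs, pos, window = 30, mode = "mean")
  expect_equal(fm[fm$tile_x == 0, ]$vx, 0.5)
  expect_error(window_average(vecs, pos, window = 0), "positive")
})

test_that("quantify_stack: defaults, linearity, translation equivariance", {
  # the procedure's printed defaults
  expect_equal(formals(quantify_stack)$radius, 5)
  expect_equal(formals(quantify_stack)$window, 30)
  expect_equal(formals(boundary_band)$radius, 5)

  st <- gen_pin_stack(pin_spec(n_cells = 9, angle = pi / 3, noise_sd = 0,
                               background = 0, seed = 6))
  q <- quantify_stack(st, st$segmentations)
  expect_equal(nrow(q$cells), length(st$segmentations))

  # linearity: doubling intensities doubles magnitudes, angles unchanged
  st2 <- st; st2$pin <- st$pin * 2
  q2 <- quantify_stack(st2, st2$segmentations)
  expect_equal(q2$cells$magnitude, 2 * q$cells$magnitude, tolerance = 1e-9)
  expect_equal(q2$cells$angle, q$cells$angle, tolerance = 1e-9)

  # translation: shifting image and masks leaves the vectors unchanged
  sh <- 12L
  n <- nrow(st$pin)
  big <- matrix(0, n + sh, n + sh)
  big[(sh + 1):(sh + n), (sh + 1):(sh + n)] <- st$pin
  segs_sh <- lapply(st$segmentations, function(s) {
    m2 <- matrix(FALSE, n + sh, n + sh)
    m2[(sh + 1):(sh + n), (sh + 1):(sh + n)] <- s$mask
    list(id = s$id, mask = m2, plane = 1L)
  })
  q3 <- quantify_stack(big, segs_sh)
  expect_equal(q3$cells$vx, q$cells$vx, tolerance = 1e-6)
  expect_equal(q3$cells$vy, q$cells$vy, tolerance = 1e-6)
})

test_that("rotation equivariance: rotating a cell rotates its angle by 90 deg", {
  st <- gen_pin_stack(pin_spec(n_cells = 9, angle = pi / 6, noise_sd = 0,
                               background = 0, seed = 8))
  q <- quantify_stack(st, st$segmentations)
  # rotate image 90 deg counterclockwise in (x, y): (x, y) -> (-y, x);
  # built directly as out[y', x'] with x' = n+1-y, y' = x
  rot <- function(m) {
    n <- nrow(m)
    out <- matrix(0, ncol(m), n)
    for (y in seq_len(n)) out[, n + 1 - y] <- m[y, ]
    out
  }
  st2pin <- rot(st$pin)
  segs2 <- lapply(st$segmentations, function(s) {
    list(id = s$id, mask = rot(s$mask) != 0, plane = 1L)
  })
  q2 <- quantify_stack(st2pin, segs2)
  dd <- ang_diff_deg(q2$cells$angle, q$cells$angle + pi / 2)
  expect_lt(max(dd), 2)
})

test_that("PGM image I/O round-trips", {
  img <- matrix(sample(0:255, 30 * 20, replace = TRUE), 20, 30)
  path <- tempfile(fileext = ".pgm")
  write_pgm(img, path, maxval = 255)
  back <- read_pgm(path)
  expect_equal(back, img, ignore_attr = TRUE)
  unlink(path)
})
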