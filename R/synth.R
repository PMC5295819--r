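# Synthetic ground-truth generators.  These emulate (a) two-channel
# microscopy-like images of polygonal cells with PIN signal concentrated on
# the boundary segment facing a known angle, plus Poisson shot noise and
# Gaussian read noise; (b) flat perturbed starting canvases; (c) initial
# cell grids for the cell-file simulations.  Every generator is
# deterministic given its seed.

#' Specification for a synthetic PIN image stack
#'
#' @param n_cells number of cells (>= 3).
#' @param cell_size approximate cell diameter in pixels.
#' @param angle polarity angle field: a single angle in radians (constant
#'   field), the string `"convergent"` (all cells point at the image
#'   centre), or a function `(x, y) -> angle` of centroid position.
#' @param edge_frac fraction of the PIN signal concentrated on the facing
#'   boundary arc (the rest is spread uniformly around the band).
#' @param arc_halfwidth half-width of the facing arc in radians.
#' @param intensity mean PIN intensity on the polarised arc (counts).
#' @param background additive background level (counts).
#' @param noise_sd Gaussian read-noise standard deviation; Poisson shot
#'   noise is always applied to the signal.  SNR is `intensity / noise_sd`.
#' @param pixel_size micrometres per pixel (metadata only).
#' @param seed integer seed.
#' @return a `pin_spec` list.
#' @export
pin_spec <- function(n_cells = 25, cell_size = 40, angle = 0,
                     edge_frac = 0.8, arc_halfwidth = pi / 4,
                     intensity = 200, background = 10, noise_sd = 5,
                     pixel_size = 0.3, seed = 1) {
  if (n_cells < 3) abort("n_cells must be at least 3 (degenerate Voronoi)")
  if (edge_frac < 0 || edge_frac > 1) abort("edge_frac must be in [0, 1]")
  structure(as.list(environment()), class = "pin_spec")
}

#' Generate a synthetic PIN stack with known polarity
#'
#' Cells are Voronoi polygons of a jittered grid; the wall channel marks
#' all cell boundaries; the PIN channel carries, per cell, `edge_frac` of
#' the signal on the boundary-band pixels whose direction from the cell
#' centroid lies within `arc_halfwidth` of that cell's true angle, and the
#' remainder uniformly around the band.  Poisson shot noise and Gaussian
#' read noise are added.  Ground-truth segmentations and angles are
#' returned, so recovery error can be computed without any manual input.
#'
#' @param spec a [pin_spec()].
#' @return list with `pin` and `wall` image matrices, `segmentations`
#'   (list of `id`, `polygon`, `mask`, `centroid`), `truth` (data frame of
#'   id and true angle) and the generating `spec`.
#' @export
gen_pin_stack <- function(spec) {
  stopifnot(inherits(spec, "pin_spec"))
  with_seed(spec$seed, {
    k <- ceiling(sqrt(spec$n_cells))
    img_size <- as.integer(k * spec$cell_size)
    gx <- (rep(seq_len(k), k) - 0.5) * spec$cell_size
    gy <- (rep(seq_len(k), each = k) - 0.5) * spec$cell_size
    keep <- seq_len(spec$n_cells)
    jit <- 0.25 * spec$cell_size
    px <- clamp(gx[keep] + stats::runif(spec$n_cells, -jit, jit), 2, img_size - 1)
    py <- clamp(gy[keep] + stats::runif(spec$n_cells, -jit, jit), 2, img_size - 1)
    dd <- deldir::deldir(px, py, rw = c(0, img_size + 1, 0, img_size + 1))
    tiles <- deldir::tile.list(dd)
    pin <- matrix(0, img_size, img_size)
    wall <- matrix(0, img_size, img_size)
    segs <- list()
    truths <- list()
    for (i in seq_along(tiles)) {
      tl <- tiles[[i]]
      poly <- cbind(tl$x, tl$y)
      mask <- polygon_mask(poly, img_size, img_size)
      if (!any(mask)) next
      band <- boundary_band(mask, 2)
      cen <- mask_centroid(mask)
      ang <- if (is.function(spec$angle)) {
        spec$angle(cen["x"], cen["y"])
      } else if (identical(spec$angle, "convergent")) {
        atan2(img_size / 2 - cen["y"], img_size / 2 - cen["x"])
      } else spec$angle
      idx <- which(band, arr.ind = TRUE)
      dx <- idx[, 2] - cen["x"]; dy <- idx[, 1] - cen["y"]
      pang <- atan2(dy, dx)
      dphi <- ((pang - ang + pi) %% (2 * pi)) - pi
      on_arc <- abs(dphi) <= spec$arc_halfwidth
      lvl <- numeric(nrow(idx))
      # the polarised share is distributed per angular bin (equal intensity
      # at +phi and -phi about the target direction) so the generated
      # vector sum points at the specified angle irrespective of cell shape
      total <- spec$intensity * nrow(idx)
      if (any(on_arc)) {
        nb <- 24L
        bin <- pmin(pmax(ceiling(abs(dphi[on_arc]) / spec$arc_halfwidth * nb), 1L), nb)
        side <- sign(dphi[on_arc] + 1e-12)
        key <- paste(bin, side)
        cnt <- table(key)
        # per-bin intensity shared between the two sides; a side missing its
        # mirror gets dropped to preserve the direction of the sum
        per_bin <- spec$edge_frac * total / nb
        for (bnum in unique(bin)) {
          kp <- paste(bnum, 1); kn <- paste(bnum, -1)
          np <- if (kp %in% names(cnt)) cnt[[kp]] else 0L
          nn <- if (kn %in% names(cnt)) cnt[[kn]] else 0L
          if (np > 0L && nn > 0L) {
            lvl[on_arc][key == kp] <- lvl[on_arc][key == kp] + per_bin / 2 / np
            lvl[on_arc][key == kn] <- lvl[on_arc][key == kn] + per_bin / 2 / nn
          } else if (np + nn > 0L) {
            # unpaired bin: assign at reduced weight (counts toward the
            # uniform background instead of the oriented arc)
            k1 <- if (np > 0L) kp else kn
            lvl[on_arc][key == k1] <- lvl[on_arc][key == k1] + 0
          }
        }
      }
      lvl <- lvl + (1 - spec$edge_frac) * total / nrow(idx)
      pin[idx] <- pin[idx] + lvl
      wall[band] <- pmax(wall[band], 0.6 * spec$intensity)
      segs[[length(segs) + 1L]] <- list(id = i, polygon = poly, mask = mask,
                                        centroid = cen, plane = 1L)
      truths[[length(truths) + 1L]] <- data.frame(id = i, angle = ang,
                                                  x = cen["x"], y = cen["y"])
    }
    # shot noise on signal + background, then read noise
    noisy <- function(img) {
      img <- img + spec$background
      img[] <- stats::rpois(length(img), lambda = pmax(img, 0))
      img[] <- img + stats::rnorm(length(img), 0, spec$noise_sd)
      pmax(img, 0)
    }
    truth <- do.call(rbind, truths)
    rownames(truth) <- NULL
    list(pin = noisy(pin), wall = noisy(wall), segmentations = segs,
         truth = truth, spec = spec)
  })
}

#' Flat perturbed starting sheet
#'
#' Convenience wrapper for the flat-start conflict models: a flat square
#' canvas with seeded uniform z-noise (delegates to
#' [make_square_canvas()]).
#'
#' @param side side length (micrometres).
#' @param amplitude z-noise half-range (micrometres).
#' @param seed integer seed.
#' @param ... passed to [make_square_canvas()].
#' @return a canvas.
#' @export
gen_perturbed_sheet <- function(side, amplitude, seed = 1, ...) {
  if (amplitude < 0) abort("amplitude must be non-negative")
  make_square_canvas(side, curvature_sagitta = 0,
                     z_noise_amplitude = amplitude, seed = seed, ...)
}

#' Generate an initial cell grid
#'
#' The four starting cell geometries of the cell-file simulations,
#' parameterised: 1 = near-square cells, 2 = elongated (2:1), 3 = oblique
#' (sheared parallelograms), 4 = irregular quadrilaterals.  Shapes 1-3
#' carry a small seeded vertex jitter (real initial cells are never exact
#' polygons; it also breaks division-orientation ties), shape 4 a strong
#' one.
#'
#' @param shape 1..4.
#' @param n number of cells (arranged near-squarely).
#' @param cell_size nominal cell width (micrometres).
#' @param jitter vertex jitter as a fraction of cell size (default 0.05
#'   for shapes 1-3, 0.25 for shape 4).
#' @param seed integer seed.
#' @return a `cell_complex`.
#' @export
gen_cell_grid <- function(shape, n = 9, cell_size = 10, jitter = NULL,
                          seed = 1) {
  if (!shape %in% 1:4) abort("shape must be 1, 2, 3 or 4")
  jitter <- jitter %||% if (shape == 4) 0.25 else 0.05
  nx <- ceiling(sqrt(n)); ny <- ceiling(n / nx)
  asp <- if (shape == 2) 2 else 1        # elongated along y
  shear <- if (shape == 3) 0.4 else 0
  with_seed(seed, {
    vid <- function(i, j) (j - 1L) * (nx + 1L) + i
    xs <- (0:nx) * cell_size
    ys <- (0:ny) * cell_size * asp
    g <- expand.grid(i = 0:nx, j = 0:ny)
    vx <- xs[g$i + 1L] + shear * g$j * cell_size
    vy <- ys[g$j + 1L]
    v <- cbind(vx, vy)
    v <- v + matrix(stats::runif(length(v), -jitter, jitter) * cell_size,
                    ncol = 2)
    cells <- list()
    for (j in seq_len(ny)) {
      for (i in seq_len(nx)) {
        if (length(cells) >= n) break
        cells[[length(cells) + 1L]] <-
          c(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
      }
    }
    cell_complex(v, cells)
  })
}
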