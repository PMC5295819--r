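# PinPoint: per-cell PIN polarity from two-channel images.  For each
# segmented cell, a boundary band is extracted by eroding the cell mask
# with a disk (default radius 5 px, roughly 1.5 um) and subtracting; each
# band pixel contributes a vector of magnitude equal to its PIN intensity,
# directed from the (binary) mask centroid to the pixel; the vector sum is
# the cell's polarity.  Windowed fields sum cell vectors per image tile
# (default 30 x 30 px).
#
# Image convention: matrices indexed [row, col]; x = column index, y = row
# index (both 1-based), angles measured from the +x axis toward +y.

disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2 + 1e-9, , drop = FALSE]
}

#' Binary erosion with a disk structuring element
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels (0 returns the mask unchanged).
#' @return eroded logical matrix (pixels beyond the border count as
#'   background).
#' @export
erode_mask <- function(mask, radius) {
  mask <- mask != 0
  if (radius <= 0) return(mask)
  off <- disk_offsets(radius)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (k in seq_len(nrow(off))) {
    dx <- off$dx[k]; dy <- off$dy[k]
    shifted <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 - dy):min(nr, nr - dy)
    cs <- max(1, 1 - dx):min(nc, nc - dx)
    shifted[rs, cs] <- mask[rs + dy, cs + dx]
    out <- out & shifted
    if (!any(out)) break
  }
  out
}

#' Boundary band of a cell mask
#'
#' The band is the mask minus its erosion by a disk of the given radius
#' (default 5 px).  If the erosion empties the mask entirely the whole mask
#' is returned as the band, with a warning.
#'
#' @param mask logical (or 0/1) matrix marking the cell.
#' @param radius erosion radius in pixels.
#' @return logical matrix: the boundary band (subset of the mask).
#' @export
boundary_band <- function(mask, radius = 5) {
  mask <- mask != 0
  if (!any(mask)) abort("boundary_band: empty mask")
  if (radius < 0) abort("boundary_band: radius must be non-negative")
  er <- erode_mask(mask, radius)
  if (!any(er) && radius > 0) {
    warning("boundary_band: erosion emptied the mask; using the whole mask")
    return(mask)
  }
  mask & !er
}

mask_centroid <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  c(x = mean(idx[, 2]), y = mean(idx[, 1]))
}

#' Polarity vector of one cell
#'
#' @param pin_image numeric matrix of PIN intensities.
#' @param mask cell mask (logical/0-1 matrix).
#' @param band boundary band mask; computed with the default radius when
#'   omitted.
#' @return list with `vx`, `vy` (intensity-weighted vector sum over band
#'   pixels, unit direction from the mask centroid to each pixel),
#'   `magnitude` and `angle` (radians in (-pi, pi], from the +x axis).
#' @export
cell_polarity <- function(pin_image, mask, band = NULL) {
  if (is.null(band)) band <- boundary_band(mask)
  cen <- mask_centroid(mask)
  idx <- which(band != 0, arr.ind = TRUE)
  if (!nrow(idx)) return(list(vx = 0, vy = 0, magnitude = 0, angle = 0))
  dx <- idx[, 2] - cen["x"]
  dy <- idx[, 1] - cen["y"]
  nrm <- sqrt(dx^2 + dy^2)
  keep <- nrm > 0   # pixels exactly at the centroid have no direction
  ii <- pin_image[idx[keep, , drop = FALSE]]
  vx <- sum(ii * dx[keep] / nrm[keep])
  vy <- sum(ii * dy[keep] / nrm[keep])
  list(vx = unname(vx), vy = unname(vy),
       magnitude = sqrt(vx^2 + vy^2), angle = atan2(vy, vx))
}

#' Windowed average of cell polarity vectors
#'
#' Sums (default, as in the procedure's description) or averages the
#' vectors of all cells whose centroids fall in each `window` x `window`
#' pixel tile, tiling anchored at the image origin.
#'
#' @param vectors data frame with columns `vx`, `vy`.
#' @param positions matrix/data frame of cell centroid positions (x, y in
#'   pixels).
#' @param window tile size in pixels (default 30).
#' @param mode `"sum"` or `"mean"`.
#' @return data frame with tile indices, tile-centre coordinates, summed
#'   (or averaged) vector components and the cell count per tile.
#' @export
window_average <- function(vectors, positions, window = 30,
                           mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (window <= 0) abort("window must be positive")
  positions <- as.matrix(positions)
  tx <- floor((positions[, 1] - 1e-9) / window)
  ty <- floor((positions[, 2] - 1e-9) / window)
  key <- paste(tx, ty)
  agg <- function(v) tapply(v, key, sum)
  sx <- agg(vectors$vx); sy <- agg(vectors$vy)
  n <- tapply(rep(1, length(key)), key, sum)
  ks <- names(sx)
  t2 <- do.call(rbind, strsplit(ks, " "))
  out <- data.frame(tile_x = as.integer(t2[, 1]), tile_y = as.integer(t2[, 2]),
                    vx = as.numeric(sx), vy = as.numeric(sy),
                    n = as.integer(n))
  if (mode == "mean") {
    out$vx <- out$vx / out$n
    out$vy <- out$vy / out$n
  }
  out$x <- (out$tile_x + 0.5) * window
  out$y <- (out$tile_y + 0.5) * window
  out
}

# rasterise a polygon (x, y columns, pixel coordinates) to a mask
polygon_mask <- function(poly, nrow_img, ncol_img) {
  xs <- poly[, 1]; ys <- poly[, 2]
  mask <- matrix(FALSE, nrow_img, ncol_img)
  rr <- clamp(floor(min(ys)), 1, nrow_img):clamp(ceiling(max(ys)), 1, nrow_img)
  cc <- clamp(floor(min(xs)), 1, ncol_img):clamp(ceiling(max(xs)), 1, ncol_img)
  n <- length(xs); j <- c(2:n, 1)
  for (r in rr) {
    # crossing test per row at pixel-centre height
    crossings <- numeric(0)
    for (e in seq_len(n)) {
      y1 <- ys[e]; y2 <- ys[j[e]]
      if ((y1 > r) != (y2 > r)) {
        crossings <- c(crossings, xs[e] + (r - y1) / (y2 - y1) * (xs[j[e]] - xs[e]))
      }
    }
    if (!length(crossings)) next
    crossings <- sort(crossings)
    for (k in seq(1, length(crossings) - 1, by = 2)) {
      c0 <- clamp(ceiling(crossings[k]), 1, ncol_img)
      c1 <- clamp(floor(crossings[k + 1]), 1, ncol_img)
      if (c0 <= c1) mask[r, c0:c1] <- TRUE
    }
  }
  mask
}

#' Quantify PIN polarity for all cells of a stack
#'
#' Runs the full per-cell pipeline (mask, boundary band, intensity-weighted
#' vector sum) on the representative plane of each segmentation, then
#' computes the windowed vector field.
#'
#' @param stack list with `pin` (matrix or list of matrices per z-plane)
#'   and optionally `wall`; or a single matrix.
#' @param segmentations list of segmentations, each a list with `id`,
#'   `polygon` (k x 2 matrix of pixel coordinates) or `mask`, and optional
#'   `plane` (z index, default 1).
#' @param radius boundary-band erosion radius in pixels (default 5).
#' @param window field window in pixels (default 30).
#' @return list with `cells` (per-cell data frame: id, plane, centroid,
#'   vx, vy, magnitude, angle) and `field` (windowed sums).  Per-cell
#'   failures are logged as warnings and skipped.
#' @export
quantify_stack <- function(stack, segmentations, radius = 5, window = 30) {
  pin <- if (is.matrix(stack)) list(stack) else if (!is.null(stack$pin)) {
    if (is.matrix(stack$pin)) list(stack$pin) else stack$pin
  } else abort("stack must contain a `pin` channel")
  rows <- list()
  for (seg in segmentations) {
    res <- tryCatch({
      plane <- seg$plane %||% 1L
      img <- pin[[plane]]
      mask <- if (!is.null(seg$mask)) seg$mask != 0
              else polygon_mask(seg$polygon, nrow(img), ncol(img))
      band <- boundary_band(mask, radius)
      pv <- cell_polarity(img, mask, band)
      cen <- mask_centroid(mask)
      data.frame(id = seg$id, plane = plane, x = cen["x"], y = cen["y"],
                 vx = pv$vx, vy = pv$vy, magnitude = pv$magnitude,
                 angle = pv$angle)
    }, error = function(e) {
      warning(sprintf("cell %s skipped: %s", as.character(seg$id),
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  field <- if (!is.null(cells) && nrow(cells)) {
    window_average(cells, cells[, c("x", "y")], window)
  } else NULL
  list(cells = cells, field = field)
}

# ---- plain-text image I/O (ASCII PGM, P2) -------------------------------

#' Write a matrix as an ASCII PGM image
#' @param img numeric matrix (values scaled to 0..maxval).
#' @param path output path.
#' @param maxval maximum grey value (default 65535).
#' @export
write_pgm <- function(img, path, maxval = 65535) {
  img <- round(clamp(img, 0, maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)),
               sprintf("%d", maxval)), con)
  writeLines(apply(img, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ASCII PGM image
#' @param path PGM (P2) file path.
#' @return numeric matrix.
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") abort("%s is not an ASCII PGM (P2) file", path)
  nc <- as.integer(toks[2]); nr <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  matrix(vals, nr, nc, byrow = TRUE)
}

#' Quiver plot of a windowed polarity field
#' @param field data frame from [window_average()].
#' @param scale arrow length scale.
#' @param ... passed to `plot`.
#' @export
plot_polarity_field <- function(field, scale = NULL, ...) {
  mag <- sqrt(field$vx^2 + field$vy^2)
  scale <- scale %||% (0.4 * min(diff(range(field$x)), diff(range(field$y))) /
                         (max(mag) + 1e-12) / max(1, sqrt(nrow(field))))
  plot(field$x, field$y, asp = 1, pch = 16, cex = 0.3,
       xlab = "x (px)", ylab = "y (px)", ...)
  graphics::arrows(field$x, field$y,
                   field$x + scale * field$vx, field$y + scale * field$vy,
                   length = 0.05, col = "red")
  invisible(field)
}
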