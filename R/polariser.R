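# The polariser (POL) is a phenomenological diffusible scalar whose
# gradient orients growth.  Polarity per element is the unit tangent along
# the down-gradient direction (from producing "+" organisers toward
# degrading "-" organisers).  Polarity can be frozen per surface, in which
# case the element keeps its stored MATERIAL direction (edge-basis
# coordinates) and simply advects with the deformation.

#' Polariser configuration
#'
#' @param production factor name(s) marking POL-producing regions.
#' @param degradation factor name(s) marking strongly degrading regions
#'   (treated as near-zero sinks).
#' @param fixed named list `factor -> level` of regions clamped at a fixed
#'   POL concentration.
#' @param diffusion_length POL diffusion length in micrometres; defaults,
#'   per canvas, to its largest dimension so gradients span the tissue.
#' @return a `pol_config` object.
#' @export
pol_config <- function(production = character(0), degradation = character(0),
                       fixed = list(), diffusion_length = NULL) {
  structure(list(production = production, degradation = degradation,
                 fixed = fixed, diffusion_length = diffusion_length),
            class = "pol_config")
}

#' Update the polariser field and element polarity
#'
#' Solves the steady polariser profile for the configured organisers
#' (production clamped high, degradation clamped low, fixed sites at their
#' level) and re-derives polarity on every unfrozen element as the
#' down-gradient tangent direction.  Elements whose POL gradient is
#' degenerate (below 1e-9 of the canvas mean) get undefined polarity and are
#' treated as isotropic by the growth engine.
#'
#' @param canvas a canvas whose factors include the organiser regions.
#' @param config a [pol_config()].
#' @return the canvas with `pol` and per-surface polarity updated.
#' @export
update_polariser <- function(canvas, config) {
  n <- nrow(canvas$vertices)
  lvl <- function(nms) {
    out <- rep(0, n)
    for (nm in nms) {
      f <- canvas$factors[[nm]]
      if (is.null(f)) abort("polariser organiser factor `%s` not present", nm)
      out <- pmax(out, f)
    }
    out
  }
  prod <- lvl(config$production)
  degr <- lvl(config$degradation)
  clampv <- rep(NA_real_, n)
  clampv[prod > 0.5] <- 1
  clampv[degr > 0.5] <- 0
  for (nm in names(config$fixed)) {
    f <- canvas$factors[[nm]]
    if (is.null(f)) abort("polariser fixed-site factor `%s` not present", nm)
    clampv[f > 0.5] <- config$fixed[[nm]]
  }
  if (!any(is.finite(clampv)) &&
      !(all(canvas$frozen_A) && all(canvas$frozen_B))) {
    # no organiser at all: POL never established, polarity undefined
    canvas$pol <- rep(0, n)
    canvas$polarity_A[!canvas$frozen_A, ] <- NA_real_
    canvas$polarity_B[!canvas$frozen_B, ] <- NA_real_
    return(canvas)
  }
  ell <- config$diffusion_length %||% max(apply(canvas$vertices, 2, function(x) diff(range(x))))
  K <- cotan_stiffness(canvas)
  M <- lumped_mass(canvas)
  A <- ell^2 * K + 0.01 * M  # weak background turnover sets the far field
  u <- numeric(n)
  fixed <- which(is.finite(clampv))
  u[fixed] <- clampv[fixed]
  free <- setdiff(seq_len(n), fixed)
  if (length(free)) {
    rhs <- -A[free, fixed, drop = FALSE] %*% u[fixed]
    u[free] <- as.numeric(Matrix::solve(A[free, free, drop = FALSE], rhs))
  }
  canvas$pol <- u
  refresh_polarity(canvas)
}

# recompute unfrozen polarity (both surfaces) from the POL gradient
refresh_polarity <- function(canvas) {
  u <- canvas$pol
  if (is.null(u)) return(canvas)
  t <- canvas$triangles
  e <- tri_edges(canvas)
  g <- tri_gram(canvas)
  du1 <- u[t[, 2]] - u[t[, 1]]
  du2 <- u[t[, 3]] - u[t[, 1]]
  det <- g[, 1] * g[, 3] - g[, 2]^2
  # gradient vector in edge-basis (contravariant) coords: Ginv %*% du
  a <- (g[, 3] * du1 - g[, 2] * du2) / det
  b <- (-g[, 2] * du1 + g[, 1] * du2) / det
  # spatial |grad|^2 = du . Ginv du
  gn2 <- a * du1 + b * du2
  thresh <- 1e-9 * sqrt(mean(pmax(gn2, 0)))
  # down-gradient direction, normalised to unit spatial length
  gn <- sqrt(pmax(gn2, .Machine$double.xmin))
  ma <- -a / gn
  mb <- -b / gn
  undef <- gn < thresh | gn2 <= 0
  ma[undef] <- NA_real_; mb[undef] <- NA_real_
  coords <- cbind(ma, mb)
  canvas$polarity_A[!canvas$frozen_A, ] <- coords[!canvas$frozen_A, ]
  canvas$polarity_B[!canvas$frozen_B, ] <- coords[!canvas$frozen_B, ]
  canvas
}

#' Spatial polarity vectors of a canvas surface
#'
#' @param canvas a canvas.
#' @param surface `"A"` or `"B"`.
#' @return M x 3 matrix of unit tangent vectors (rows NA where undefined).
#' @export
polarity_vectors <- function(canvas, surface = c("A", "B")) {
  surface <- match.arg(surface)
  pm <- canvas[[paste0("polarity_", surface)]]
  e <- tri_edges(canvas)
  v <- pm[, 1] * e$d1 + pm[, 2] * e$d2
  nv <- sqrt(rowSums(v * v))
  v / nv
}

#' Freeze polarity on a surface
#'
#' Frozen elements keep their current material polarity direction through
#' subsequent deformation instead of tracking the POL gradient.
#'
#' @param canvas a canvas.
#' @param surface `"A"` or `"B"`.
#' @param elements triangle indices (default all).
#' @return the modified canvas.
#' @export
freeze_polarity <- function(canvas, surface = c("A", "B"),
                            elements = seq_len(nrow(canvas$triangles))) {
  surface <- match.arg(surface)
  canvas[[paste0("frozen_", surface)]][elements] <- TRUE
  canvas
}

#' Lock a polarity channel
#'
#' Freezes the current polarity of the region's elements on both surfaces
#' (creating a polarity channel) and optionally marks the region as a weak
#' POL sink for the flanking tissue by setting a `CHANNELSINK` factor.
#'
#' @param canvas a canvas.
#' @param region triangle indices of the channel (empty region is a no-op).
#' @param weak_sink logical; mark the channel region as a weak POL sink.
#' @return the modified canvas.
#' @export
lock_polarity_channel <- function(canvas, region, weak_sink = TRUE) {
  if (!length(region)) return(canvas)
  canvas <- freeze_polarity(canvas, "A", region)
  canvas <- freeze_polarity(canvas, "B", region)
  if (weak_sink) {
    f <- rep(0, nrow(canvas$vertices))
    f[unique(as.vector(canvas$triangles[region, ]))] <- 1
    canvas <- set_factor(canvas, "CHANNELSINK", f)
  }
  canvas
}

#' Unlock frozen polarity
#' @param canvas a canvas.
#' @param surface `"A"`, `"B"` or `"both"`.
#' @param elements triangle indices (default all).
#' @return the canvas with polarity re-derived from the current POL field.
#' @export
unlock_polarity <- function(canvas, surface = "both",
                            elements = seq_len(nrow(canvas$triangles))) {
  if (surface %in% c("A", "both")) canvas$frozen_A[elements] <- FALSE
  if (surface %in% c("B", "both")) canvas$frozen_B[elements] <- FALSE
  refresh_polarity(canvas)
}
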