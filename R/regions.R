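# Region recipes: factor spatial domains for the catalogue models.  The
# source figures show these domains graphically; here they are parameterised
# conventions (stripe widths default to 10% of the canvas, signal diffusion
# lengths to a few cell widths), all overridable through the recipe
# arguments.

# --- square-canvas factors (conflict and orthogonal-conflict models) -----

#' Set up the standard square-model factors
#'
#' Installs the identity factors used by the square conflict models:
#' `icentre` (1 at the centre, declining radially to 0 at the corners),
#' `iedge` (its complement), `FOCI`, `EDGE`, `BOTTOM`, `TOP`, `JUN` and
#' `RIM` stripes (default width 10% of the side) with diffused signals
#' `sjun`, `srim`, plus `ihalfside` (left half), `idistalhalf` (upper half)
#' and `imargins` (bands flanking the JUN stripe).
#'
#' @param canvas a square canvas.
#' @param stripe_frac stripe width as fraction of the side.
#' @param signal_length diffusion length of `sjun`/`srim` as a fraction of
#'   the side.
#' @param icentre_radius radius (micrometres) at which `icentre` reaches 0;
#'   default the half-diagonal.
#' @return the canvas with factors installed.
#' @export
setup_square_factors <- function(canvas, stripe_frac = 0.1,
                                 signal_length = 0.05,
                                 icentre_radius = NULL) {
  v <- canvas$vertices
  side <- diff(range(v[, 1]))
  rho <- sqrt(v[, 1]^2 + v[, 2]^2)
  r0 <- icentre_radius %||% sqrt(2) * side / 2
  eps <- 1e-6 * side
  onedge <- v[, 1] < min(v[, 1]) + eps | v[, 1] > max(v[, 1]) - eps |
    v[, 2] < min(v[, 2]) + eps | v[, 2] > max(v[, 2]) - eps
  canvas <- set_factor(canvas, "icentre", pmax(1 - rho / r0, 0))
  canvas <- set_factor(canvas, "iedge", 1 - pmax(1 - rho / r0, 0))
  canvas <- set_factor(canvas, "FOCI", as.numeric(rho < 0.15 * side))
  canvas <- set_factor(canvas, "EDGE", as.numeric(onedge))
  canvas <- set_factor(canvas, "BOTTOM", as.numeric(v[, 2] < min(v[, 2]) + eps))
  canvas <- set_factor(canvas, "TOP", as.numeric(v[, 2] > max(v[, 2]) - eps))
  canvas <- set_factor(canvas, "TOPMID",
                       as.numeric(v[, 2] > max(v[, 2]) - eps &
                                    abs(v[, 1]) < 0.1 * side))
  w <- stripe_frac * side / 2
  jun <- as.numeric(abs(v[, 1]) <= w)
  rim <- as.numeric(abs(v[, 2]) <= w)
  canvas <- set_factor(canvas, "JUN", jun)
  canvas <- set_factor(canvas, "RIM", rim)
  canvas <- set_factor(canvas, "ihalfside", as.numeric(v[, 1] < 0))
  canvas <- set_factor(canvas, "idistalhalf", as.numeric(v[, 2] > 0))
  canvas <- set_factor(canvas, "imargins",
                       as.numeric(abs(v[, 1]) > w & abs(v[, 1]) <= 3.5 * w))
  ell <- signal_length * side
  canvas <- set_factor(canvas, "sjun", diffuse_signal(canvas, "JUN", ell))
  canvas <- set_factor(canvas, "srim", diffuse_signal(canvas, "RIM", ell))
  canvas
}

# calibrated icentre/iedge pair for the size-preserving areal model: the
# profile radius is chosen so the area-weighted mean of iedge matches the
# printed rate ratio (the source model states its parameters were chosen to
# keep overall canvas size constant)
setup_size_preserving_edge <- function(canvas, target_mean = 0.019 / 0.032) {
  v <- canvas$vertices
  a <- tri_areas(canvas)
  t <- canvas$triangles
  rho <- sqrt(v[, 1]^2 + v[, 2]^2)
  mean_iedge <- function(r0) {
    ie <- pmin(rho / r0, 1)
    ie_t <- (ie[t[, 1]] + ie[t[, 2]] + ie[t[, 3]]) / 3
    sum(ie_t * a) / sum(a)
  }
  side <- diff(range(v[, 1]))
  r0 <- stats::uniroot(function(r) mean_iedge(r) - target_mean,
                       c(0.2 * side, 2 * side))$root
  canvas <- set_factor(canvas, "iedge", pmin(rho / r0, 1))
  canvas <- set_factor(canvas, "icentre", 1 - pmin(rho / r0, 1))
  canvas
}

# --- strip-canvas (wedge/dome) factors -----------------------------------

#' Set up the wedge-model factors on a strip canvas
#'
#' Installs the regional identities of the dome/wedge models on a
#' mediolateral (x) by proximodistal (y) strip: proximodistal zones PLT,
#' PLX, RIM, LIP (split into LIF and LIF-distal LIS), organisers SOURCE and
#' SINK, lateral RAD with its diffusing signal sRAD (defining the hinge and
#' the DIV gradient), mediolateral vein/junction signals sMED, sSEC, sLAT,
#' and derived factors ibrim (sRIM > 0.01) and ihinge.  Domain fractions are
#' conventions read qualitatively from the source patterns; all are
#' configurable.
#'
#' @param canvas a strip canvas.
#' @param plt_frac proximodistal extent of PLT (fraction of height).
#' @param rim_frac RIM stripe height fraction.
#' @param lif_frac LIP-proximal (cliff) fraction.
#' @param srad_length,srim_length,vein_length diffusion lengths
#'   (micrometres).
#' @param div_grade mediolateral fraction over which DIV rises from 0 at
#'   the lateral edge to 1.
#' @return the canvas with factors installed.
#' @export
setup_wedge_factors <- function(canvas, plt_frac = 0.5, rim_frac = 0.1,
                                lif_frac = 0.2, srad_length = 100,
                                srim_length = 12, vein_length = 40,
                                div_grade = 0.4) {
  v <- canvas$vertices
  xr <- range(v[, 1]); yr <- range(v[, 2])
  W <- diff(xr); H <- diff(yr)
  yf <- (v[, 2] - yr[1]) / H   # 0 proximal -> 1 distal
  xf <- (v[, 1] - mean(xr)) / W  # -0.5 .. 0.5
  eps <- 1e-6 * H
  # regions stay non-empty at coarse resolution: membership extends half an
  # edge length beyond the nominal band
  tol <- 0.55 * (canvas$meta$target_edge %||% (H / 30))
  near <- function(x0, hw) as.numeric(abs(v[, 1] - x0) <= max(hw, tol))
  band_y <- function(lo, hi) {
    as.numeric(v[, 2] >= yr[1] + lo * H - tol & v[, 2] <= yr[1] + hi * H + tol)
  }
  canvas <- set_factor(canvas, "isource", as.numeric(v[, 2] < yr[1] + eps))
  canvas <- set_factor(canvas, "isink", as.numeric(v[, 2] > yr[2] - eps))
  canvas <- set_factor(canvas, "iplt", as.numeric(yf <= plt_frac))
  canvas <- set_factor(canvas, "iplx", band_y(0, 0.1))
  canvas <- set_factor(canvas, "irim", band_y(plt_frac, plt_frac + rim_frac))
  lip0 <- plt_frac + rim_frac
  canvas <- set_factor(canvas, "ilip", as.numeric(yf > lip0))
  canvas <- set_factor(canvas, "ilif",
                       as.numeric(yf > lip0 & yf <= lip0 + lif_frac))
  canvas <- set_factor(canvas, "ilis", as.numeric(yf > lip0 + lif_frac))
  canvas <- set_factor(canvas, "irad",
                       as.numeric(abs(xf) > 0.5 - 0.02))
  srad <- diffuse_signal(canvas, "irad", srad_length)
  canvas <- set_factor(canvas, "srad", srad)
  canvas <- set_factor(canvas, "ihinge", as.numeric(srad > 0.4))
  canvas <- set_factor(canvas, "idiv",
                       clamp((1 - abs(xf) * 2) / div_grade, 0, 1))
  srim <- diffuse_signal(canvas, "irim", srim_length)
  canvas <- set_factor(canvas, "srim", srim)
  canvas <- set_factor(canvas, "ibrim", as.numeric(srim > 0.01))
  # petal junctions at the third boundaries; midveins at the petal centres;
  # secondary veins midway between midvein and junction
  jx <- c(-W / 6, W / 6)
  mx <- c(-W / 3, 0, W / 3)
  sx <- c(-W / 4, -W / 12, W / 12, W / 4)
  hw <- 0.01 * W
  lat_src <- pmax(near(jx[1], hw), near(jx[2], hw))
  med_src <- pmax(near(mx[1], hw), pmax(near(mx[2], hw), near(mx[3], hw)))
  sec_src <- Reduce(pmax, lapply(sx, near, hw = hw))
  canvas <- set_factor(canvas, "ilat_src", lat_src)
  canvas <- set_factor(canvas, "imed_src", med_src)
  canvas <- set_factor(canvas, "isec_src", sec_src)
  canvas <- set_factor(canvas, "slat", diffuse_signal(canvas, "ilat_src", vein_length))
  canvas <- set_factor(canvas, "smed", diffuse_signal(canvas, "imed_src", vein_length))
  canvas <- set_factor(canvas, "ssec", diffuse_signal(canvas, "isec_src", 0.75 * vein_length))
  # sinus: intersection of the petal junctions with the distal lip
  canvas <- set_factor(canvas, "isinus",
                       as.numeric((near(jx[1], 2 * hw) | near(jx[2], 2 * hw)) &
                                    yf > 0.9))
  canvas
}
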