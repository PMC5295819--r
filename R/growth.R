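# Specified growth.  A growth spec holds KRN expressions for the in-plane
# rates parallel (Kpar) and perpendicular (Kper) to the local polarity, per
# surface (A = adaxial, B = abaxial; single-surface models use the same
# expression for both), plus the thickness rate Knor.  All rates are
# fractional rates per hour and compound exponentially.

#' Create a growth specification
#'
#' @param kpar,kper KRN expressions (strings or `krn_expr`) for both
#'   surfaces; ignored when per-surface forms are given.
#' @param knor thickness growth-rate expression (default "0").
#' @param kpar_a,kpar_b,kper_a,kper_b optional per-surface expressions
#'   (surface conflict); any not given falls back to `kpar` / `kper`.
#' @param normalise optional constant c: evaluated rates are rescaled per
#'   surface to `Kpar' = c*Kpar/(Kpar+Kper)`, `Kper' = c*Kper/(Kpar+Kper)`
#'   (the no-areal-conflict normalisation); points where `Kpar+Kper = 0` get
#'   `c/2` each and are flagged.
#' @return a `growth_spec` object.
#' @export
growth_spec <- function(kpar = NULL, kper = NULL, knor = "0",
                        kpar_a = NULL, kpar_b = NULL,
                        kper_a = NULL, kper_b = NULL,
                        normalise = NULL, isotropise = FALSE) {
  pick <- function(spec, fallback) krn(spec %||% fallback %||% "0")
  spec <- structure(list(
    kpar_a = pick(kpar_a, kpar), kpar_b = pick(kpar_b, kpar),
    kper_a = pick(kper_a, kper), kper_b = pick(kper_b, kper),
    knor = krn(knor), normalise = normalise, isotropise = isotropise
  ), class = "growth_spec")
  spec
}

#' @export
print.growth_spec <- function(x, ...) {
  same_a <- identical(x$kpar_a$text, x$kpar_b$text) &&
    identical(x$kper_a$text, x$kper_b$text)
  if (same_a) {
    cat("Kpar  =", x$kpar_b$text, "\nKper  =", x$kper_b$text, "\n")
  } else {
    cat("Kpara =", x$kpar_a$text, "\nKparb =", x$kpar_b$text,
        "\nKpera =", x$kper_a$text, "\nKperb =", x$kper_b$text, "\n")
  }
  cat("Knor  =", x$knor$text, "\n")
  if (!is.null(x$normalise)) {
    cat("areal normalisation: Karea rescaled to", x$normalise, "\n")
  }
  invisible(x)
}

#' Derived rate summaries: specified anisotropy and areal rate
#'
#' `Kaniso = ln(Kpar / Kper)` (clamped to the display range [-1, 1]; the
#' sign of `Kpar - Kper` is used where the ratio is undefined, e.g. under
#' contraction) and `Karea = Kpar + Kper`.
#'
#' @param kpar,kper numeric vectors of specified rates.
#' @return list with `Kaniso` and `Karea`.
#' @export
derived_rates <- function(kpar, kper) {
  ratio <- kpar / kper
  kaniso <- ifelse(is.finite(ratio) & ratio > 0, log(ratio),
                   sign(kpar - kper))
  kaniso[kpar == kper] <- 0
  list(Kaniso = clamp(kaniso, -1, 1), Karea = kpar + kper)
}

#' Evaluate a growth spec over factor levels
#'
#' @param spec a `growth_spec`.
#' @param factors named list/data frame of factor levels.
#' @return list of numeric vectors `kpar_a`, `kpar_b`, `kper_a`, `kper_b`,
#'   `knor`, plus logical `normalise_degenerate` flagging points where the
#'   areal normalisation divided by zero.
#' @export
eval_growth <- function(spec, factors) {
  r <- list(kpar_a = eval_expr(spec$kpar_a, factors),
            kpar_b = eval_expr(spec$kpar_b, factors),
            kper_a = eval_expr(spec$kper_a, factors),
            kper_b = eval_expr(spec$kper_b, factors),
            knor = eval_expr(spec$knor, factors))
  n <- max(lengths(r))
  r <- lapply(r, rep_len, n)
  r$normalise_degenerate <- rep(FALSE, n)
  if (isTRUE(spec$isotropise)) {
    # no-directional-conflict ablation: no polarity field is established,
    # growth is applied isotropically at the same areal rate
    for (s in c("a", "b")) {
      m <- (r[[paste0("kpar_", s)]] + r[[paste0("kper_", s)]]) / 2
      r[[paste0("kpar_", s)]] <- m
      r[[paste0("kper_", s)]] <- m
    }
  }
  if (!is.null(spec$normalise)) {
    cc <- spec$normalise
    for (s in c("a", "b")) {
      kp <- r[[paste0("kpar_", s)]]; kq <- r[[paste0("kper_", s)]]
      tot <- kp + kq
      bad <- tot == 0
      r$normalise_degenerate <- r$normalise_degenerate | bad
      kp2 <- ifelse(bad, cc / 2, cc * kp / ifelse(bad, 1, tot))
      kq2 <- ifelse(bad, cc / 2, cc * kq / ifelse(bad, 1, tot))
      r[[paste0("kpar_", s)]] <- kp2
      r[[paste0("kper_", s)]] <- kq2
    }
  }
  r
}

# G-orthonormal frame along the polarity material direction u (edge-basis
# coords) for Gram G: returns 2x2 matrix with columns (u_hat, v_hat)
g_frame <- function(G, u) {
  nu <- sqrt(max(drop(t(u) %*% G %*% u), .Machine$double.xmin))
  uh <- u / nu
  gu <- G %*% uh
  w <- c(-gu[2], gu[1])
  nw <- sqrt(max(drop(t(w) %*% G %*% w), .Machine$double.xmin))
  cbind(uh, w / nw)
}

# apply an anisotropic stretch (s_par along polarity, s_per across) to one
# rest Gram; isotropic when u is NULL
stretch_gram <- function(g, s_par, s_per, u) {
  if (s_par == s_per) return(g * s_par^2)
  G <- matrix(c(g[1], g[2], g[2], g[3]), 2, 2)
  F <- g_frame(G, u)
  gu <- G %*% F[, 1]; gv <- G %*% F[, 2]
  Gn <- s_par^2 * tcrossprod(gu) + s_per^2 * tcrossprod(gv)
  c(Gn[1, 1], Gn[1, 2], Gn[2, 2])
}

#' Grow the rest metrics of a canvas
#'
#' Updates each element's per-surface rest metric by the stretch
#' `exp(dt * K)` applied along the local polarity (Kpar) and perpendicular
#' to it (Kper), and the thickness by `exp(Knor * dt)`.  Where the specified
#' growth is anisotropic, a polarity direction must be defined for the
#' element (error otherwise); isotropic growth needs no polarity.
#'
#' @param canvas a canvas (with polarity set where needed).
#' @param rates list as returned by [eval_growth()] evaluated per triangle;
#'   `knor` may be per vertex.
#' @param dt time step (hours).
#' @return the canvas with updated rest metrics and thickness.
#' @export
grow_rest_metrics <- function(canvas, rates, dt) {
  m <- nrow(canvas$triangles)
  for (s in c("A", "B")) {
    kp <- rep_len(rates[[paste0("kpar_", tolower(s))]], m)
    kq <- rep_len(rates[[paste0("kper_", tolower(s))]], m)
    rest <- canvas[[paste0("rest_", s)]]
    polm <- canvas[[paste0("polarity_", s)]]
    for (i in seq_len(m)) {
      s_par <- exp(kp[i] * dt); s_per <- exp(kq[i] * dt)
      if (s_par == s_per) {
        rest[i, ] <- rest[i, ] * s_par^2
      } else {
        u <- polm[i, ]
        if (!all(is.finite(u))) {
          abort("element %d has anisotropic specified growth but no polarity", i)
        }
        rest[i, ] <- stretch_gram(rest[i, ], s_par, s_per, u)
      }
    }
    canvas[[paste0("rest_", s)]] <- rest
  }
  knor <- rep_len(rates$knor, nrow(canvas$vertices))
  canvas$thickness <- canvas$thickness * exp(knor * dt)
  canvas
}
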