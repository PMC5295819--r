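# Growth-regulatory-network (KRN) expression DSL.
#
# Growth rates are declared as arithmetic over regional factor levels using
# the multiplicative regulatory primitives
#   pro(x, f) = 1 + x * f      (promotion by amount x: 1 when f is absent)
#   inh(x, f) = 1 / (1 + x*f)  (inhibition by amount x: 1 when f is absent)
# together with +, -, *, /, parentheses, numeric constants, threshold
# indicators `(f > c)` (0/1 valued), logical AND `&` on indicators, and
# `pos(expr)` clipping to non-negative.  Expressions are stored as parsed
# R language objects and evaluated in a sealed environment that exposes
# only these primitives and the factor levels, so evaluation is pure.

#' Promotion primitive
#'
#' `pro(x, v)` multiplies a rate by `1 + x * v`: a factor at level 0 leaves
#' the rate unchanged, a factor at level 1 boosts it by the amount `x`.
#'
#' @param x promotion amount (non-negative scalar).
#' @param v factor level(s), non-negative.
#' @return multiplier `1 + x * v` (vectorised over `v`).
#' @export
pro <- function(x, v) {
  if (any(x < 0)) abort("pro(): promotion amount must be non-negative")
  1 + x * v
}

#' Inhibition primitive
#'
#' `inh(x, v)` multiplies a rate by `1 / (1 + x * v)`: 1 when the factor is
#' absent, approaching 0 under strong inhibition.
#'
#' @param x inhibition amount (non-negative scalar).
#' @param v factor level(s), non-negative.
#' @return multiplier in (0, 1], vectorised over `v`.
#' @export
inh <- function(x, v) {
  if (any(x < 0)) abort("inh(): inhibition amount must be non-negative")
  1 / (1 + x * v)
}

.krn_calls <- c("+", "-", "*", "/", "(", ">", "<", "&", "pro", "inh", "pos")

#' Parse a KRN expression
#'
#' Parses an expression string in the KRN grammar into a `krn_expr` object.
#' Only the grammar's primitives are admitted; any other function call or
#' syntax is rejected at parse time.
#'
#' @param text expression string, e.g.
#'   `"0.05 + 0.05*sjun + 0.05*srim - 0.2*sjun*srim"` or
#'   `"0.02 * inh(5, srad) * pro(0.8, ilis)"`.
#' @return a `krn_expr` object.
#' @export
krn <- function(text) {
  if (inherits(text, "krn_expr")) return(text)
  e <- tryCatch(str2lang(text), error = function(err) {
    abort("cannot parse KRN expression: %s", conditionMessage(err))
  })
  check_krn_ast(e)
  structure(list(expr = e, text = krn_deparse(e)), class = "krn_expr")
}

check_krn_ast <- function(e) {
  if (is.numeric(e) || is.name(e)) return(invisible(TRUE))
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (!fn %in% .krn_calls) {
      abort("KRN grammar does not allow `%s`", fn)
    }
    for (arg in as.list(e)[-1]) check_krn_ast(arg)
    return(invisible(TRUE))
  }
  if (is.logical(e)) return(invisible(TRUE))
  abort("KRN grammar does not allow element of type %s", typeof(e))
}

krn_deparse <- function(e) paste(deparse(e, width.cutoff = 500L), collapse = " ")

#' @export
format.krn_expr <- function(x, ...) x$text

#' @export
print.krn_expr <- function(x, ...) {
  cat("<krn> ", x$text, "\n", sep = "")
  invisible(x)
}

#' @export
as.character.krn_expr <- function(x, ...) x$text

#' Factors referenced by a KRN expression
#' @param expr a `krn_expr` (or string).
#' @return character vector of factor names.
#' @export
krn_factors <- function(expr) {
  expr <- krn(expr)
  out <- character(0)
  walk <- function(e) {
    if (is.name(e)) out <<- union(out, as.character(e))
    else if (is.call(e)) for (arg in as.list(e)[-1]) walk(arg)
  }
  walk(expr$expr)
  out
}

# sealed evaluation environment: comparison returns numeric 0/1 so indicator
# products like (f > 0.4) * g work; & is numeric AND on indicators
krn_env <- function(factors) {
  env <- new.env(parent = baseenv())
  env$pro <- pro
  env$inh <- inh
  env$pos <- function(x) pmax(x, 0)
  env$`>` <- function(a, b) as.numeric(a > b)
  env$`<` <- function(a, b) as.numeric(a < b)
  env$`&` <- function(a, b) as.numeric((a != 0) & (b != 0))
  for (nm in names(factors)) assign(nm, factors[[nm]], envir = env)
  env
}

#' Evaluate a KRN expression over factor levels
#'
#' @param expr a `krn_expr` object or expression string.
#' @param factors named list (or data frame) of factor levels; vectors are
#'   evaluated pointwise.
#' @return numeric vector of the expression value at each point.
#' @export
eval_expr <- function(expr, factors) {
  expr <- krn(expr)
  missing <- setdiff(krn_factors(expr), names(factors))
  if (length(missing)) {
    abort("KRN expression references undefined factor(s): %s",
          paste(missing, collapse = ", "))
  }
  eval(expr$expr, krn_env(as.list(factors)))
}

#' Evaluate a KRN expression on a canvas
#'
#' @param expr a `krn_expr` or string.
#' @param canvas a canvas whose factors supply the levels.
#' @param where `"vertices"` (default) or `"triangles"` (factor levels
#'   averaged per element first).
#' @return numeric vector over vertices or triangles.
#' @export
eval_expr_canvas <- function(expr, canvas, where = c("vertices", "triangles")) {
  where <- match.arg(where)
  f <- if (where == "vertices") canvas$factors else factors_on_triangles(canvas)
  eval_expr(expr, f)
}
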