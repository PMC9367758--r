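#' Paired condition/outcome observations
#'
#' Bundles one condition variable `x` and one outcome variable `y` into the
#' basic unit every ceiling fit consumes. Values must be finite and pairs
#' complete; run [impute_mean()] / [remove_outliers()] first if the raw data
#' contain missing values or implausible records.
#'
#' @param x Numeric vector of condition values (native units).
#' @param y Numeric vector of outcome values (native units), same length as
#'   `x`.
#' @param condition,outcome Variable labels used in printing and reports.
#' @return An object of class `nca_observations`: a list with elements `x`,
#'   `y`, `condition`, `outcome` and `n`.
#' @examples
#' obs <- nca_observations(c(0, 1, 2), c(0, 1, 2))
#' obs$n
#' @export
nca_observations <- function(x, y, condition = "x", outcome = "y") {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length (got ", length(x), " and ",
         length(y), ")", call. = FALSE)
  }
  if (length(x) < 2L) {
    stop("at least 2 observation pairs are required", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("all condition and outcome values must be finite; impute or drop ",
         "missing values first", call. = FALSE)
  }
  structure(
    list(x = x, y = y, condition = as.character(condition)[1],
         outcome = as.character(outcome)[1], n = length(x)),
    class = "nca_observations"
  )
}

#' @export
print.nca_observations <- function(x, ...) {
  cat(sprintf("NCA observations: %s (condition) vs %s (outcome), n = %d\n",
              x$condition, x$outcome, x$n))
  cat(sprintf("  x range: [%g, %g]   y range: [%g, %g]\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Analysis scope
#'
#' The rectangle over which necessity is evaluated. The effect size d is the
#' ceiling-zone area divided by the area of this rectangle, so the scope is
#' the denominator of every result. By default it is empirical: the observed
#' minima and maxima of condition and outcome. A theoretical scope may be
#' supplied instead (e.g. the full range of a rating scale); it must contain
#' all observations.
#'
#' @param obs An [nca_observations()] object, or `NULL` when all four bounds
#'   are given explicitly.
#' @param x_min,x_max,y_min,y_max Optional explicit bounds. Supplying any of
#'   them marks the scope as theoretical.
#' @return An object of class `nca_scope` with fields `x_min`, `x_max`,
#'   `y_min`, `y_max`, `source` (`"empirical"` or `"theoretical"`) and
#'   `area`.
#' @examples
#' obs <- nca_observations(c(0, 1, 2), c(0, 1, 2))
#' nca_scope(obs)                       # empirical: [0,2] x [0,2]
#' nca_scope(obs, y_min = 0, y_max = 4) # theoretical in y
#' @export
nca_scope <- function(obs = NULL, x_min = NULL, x_max = NULL,
                      y_min = NULL, y_max = NULL) {
  explicit <- !vapply(list(x_min, x_max, y_min, y_max), is.null, logical(1))
  if (is.null(obs) && !all(explicit)) {
    stop("without `obs`, all four scope bounds must be given", call. = FALSE)
  }
  if (!is.null(obs) && !inherits(obs, "nca_observations")) {
    stop("`obs` must be an nca_observations object", call. = FALSE)
  }
  b <- list(
    x_min = if (is.null(x_min)) min(obs$x) else as.numeric(x_min),
    x_max = if (is.null(x_max)) max(obs$x) else as.numeric(x_max),
    y_min = if (is.null(y_min)) min(obs$y) else as.numeric(y_min),
    y_max = if (is.null(y_max)) max(obs$y) else as.numeric(y_max)
  )
  if (!(b$x_max > b$x_min) || !(b$y_max > b$y_min)) {
    stop("degenerate scope: need x_max > x_min and y_max > y_min ",
         "(a zero-width scope has no area)", call. = FALSE)
  }
  if (!is.null(obs)) {
    if (any(obs$x < b$x_min) || any(obs$x > b$x_max) ||
        any(obs$y < b$y_min) || any(obs$y > b$y_max)) {
      stop("scope must contain all observations", call. = FALSE)
    }
  }
  b$source <- if (any(explicit)) "theoretical" else "empirical"
  b$area <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  structure(b, class = "nca_scope")
}

#' @export
print.nca_scope <- function(x, ...) {
  cat(sprintf("NCA scope (%s): [%g, %g] x [%g, %g], area S = %g\n",
              x$source, x$x_min, x$x_max, x$y_min, x$y_max, x$area))
  invisible(x)
}

# numeric tolerance tied to the outcome range; used for "on the line" and
# boundary comparisons throughout
.y_tol <- function(scope) 1e-9 * (scope$y_max - scope$y_min)
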