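# Ceiling-line estimation.
#
# CE-FDH: the free-disposal-hull step ceiling c(x) = max{ y_i : x_i <= x },
# right-continuous and non-decreasing; every observation lies on or below it.
# CR-FDH: the OLS line through the step's upper-left corner vertices (the
# peers' own (x, y) points), a straight-line smoothing of the step that may
# leave a few observations above it.
#
# The zone area C is the area between the ceiling (clipped to the scope
# rectangle) and the scope top y_max; d = C / S.

# Step profile of the data within a scope: distinct x breakpoints and the
# running-max ceiling value on [x_k, x_{k+1}). First breakpoint is at x_min
# (value y_min when the scope extends left of the data).
.step_profile <- function(x, y, scope) {
  ord <- order(x, -y)
  xs <- x[ord]
  ys <- y[ord]
  cm <- cummax(ys)
  last <- !duplicated(xs, fromLast = TRUE)
  ux <- xs[last]
  vals <- cm[last]
  # peers: leftmost point attaining each strict increase of the running max;
  # ties in x resolved to the highest y, ties in y to the smallest x
  peer <- c(TRUE, diff(vals) > 0)
  peers <- data.frame(x = ux[peer], y = vals[peer])
  if (ux[1] > scope$x_min) {
    ux <- c(scope$x_min, ux)
    vals <- c(scope$y_min, vals)
  }
  # compress: keep only the x where the ceiling value changes, so dominated
  # points leave the breakpoint list untouched
  keep <- c(TRUE, diff(vals) > 0)
  list(x = ux[keep], value = vals[keep], peers = peers)
}

.step_zone_area <- function(ux, vals, scope) {
  widths <- diff(c(ux, scope$x_max))
  sum(widths * (scope$y_max - pmin(pmax(vals, scope$y_min), scope$y_max)))
}

# Exact area between y_max and the line a + b*x clipped to the scope
# rectangle: the clipped line is piecewise linear with kinks only where it
# crosses y_min / y_max, so a trapezoid sum over those segments is exact.
.line_zone_area <- function(a, b, scope) {
  xs <- c(scope$x_min, scope$x_max)
  if (b != 0) {
    for (yy in c(scope$y_min, scope$y_max)) {
      xc <- (yy - a) / b
      if (xc > scope$x_min && xc < scope$x_max) xs <- c(xs, xc)
    }
  }
  xs <- sort(xs)
  clip <- function(x) pmin(pmax(a + b * x, scope$y_min), scope$y_max)
  lo <- xs[-length(xs)]
  hi <- xs[-1]
  sum((hi - lo) * (scope$y_max - (clip(lo) + clip(hi)) / 2))
}

#' Fit a CE-FDH step ceiling
#'
#' Envelops the scatterplot from above with the free-disposal-hull step
#' function `c(x) = max{ y_i : x_i <= x }`. The step passes through the
#' peers — observations not dominated by any point with smaller-or-equal x
#' and greater-or-equal y — and leaves every observation on or below it, so
#' its accuracy is 100% by construction.
#'
#' @param obs An [nca_observations()] object.
#' @param scope An [nca_scope()]; defaults to the empirical scope of `obs`.
#' @return An `nca_fit` with fields `method` (`"ce_fdh"`), `breakpoints`
#'   (data.frame `x`, `value`), `peers`, `zone_area`, `scope_area`, `d`,
#'   `accuracy` (always 100) and `scope`.
#' @examples
#' obs <- nca_observations(c(0, 1, 2), c(0, 1, 2))
#' fit <- fit_ce_fdh(obs)
#' fit$zone_area   # 3: the empty staircase above the diagonal in [0,2]^2
#' fit$d           # 0.75
#' @export
fit_ce_fdh <- function(obs, scope = nca_scope(obs)) {
  stopifnot(inherits(obs, "nca_observations"), inherits(scope, "nca_scope"))
  .check_in_scope(obs, scope)
  sp <- .step_profile(obs$x, obs$y, scope)
  C <- .step_zone_area(sp$x, sp$value, scope)
  fit <- structure(
    list(method = "ce_fdh",
         breakpoints = data.frame(x = sp$x, value = sp$value),
         peers = sp$peers, zone_area = C, scope_area = scope$area,
         d = C / scope$area, accuracy = 100, scope = scope, obs = obs),
    class = "nca_fit")
  # the ceiling zone must be empty: no observation strictly above the step
  stopifnot(all(obs$y <= ceiling_value(fit, obs$x) + .y_tol(scope)))
  fit
}

#' Fit a CR-FDH straight-line ceiling
#'
#' Fits an ordinary-least-squares line through the upper-left corner points
#' of the CE-FDH step (the peers), giving a straight ceiling suited to
#' continuous data. Unlike CE-FDH the line may leave some observations above
#' it; the share on or below it is the fit's accuracy, and fits below 95%
#' accuracy are flagged as not appropriate for interpretation. The line is
#' clipped to the scope rectangle for all area and bottleneck computations,
#' so `d` stays in `[0, 1]`.
#'
#' @inheritParams fit_ce_fdh
#' @return An `nca_fit` with fields `method` (`"cr_fdh"`), `slope`,
#'   `intercept`, `peers`, `zone_area`, `scope_area`, `d`, `accuracy`
#'   (percent of observations on or below the line) and `interpretable`
#'   (`accuracy >= 95`).
#' @examples
#' obs <- nca_observations(c(0, 1, 2), c(0, 1, 2))
#' fit <- fit_cr_fdh(obs)
#' c(fit$slope, fit$intercept)   # the diagonal y = x
#' fit$d                         # 0.5
#' @export
fit_cr_fdh <- function(obs, scope = nca_scope(obs)) {
  stopifnot(inherits(obs, "nca_observations"), inherits(scope, "nca_scope"))
  .check_in_scope(obs, scope)
  sp <- .step_profile(obs$x, obs$y, scope)
  p <- sp$peers
  if (nrow(p) < 2L) {
    stop("CR-FDH needs at least 2 distinct ceiling corner points; this ",
         "dataset has ", nrow(p), " (the upper-left corner is occupied). ",
         "Use CE-FDH instead.", call. = FALSE)
  }
  b <- stats::cov(p$x, p$y) / stats::var(p$x)
  a <- mean(p$y) - b * mean(p$x)
  C <- .line_zone_area(a, b, scope)
  tol <- .y_tol(scope)
  acc <- 100 * mean(obs$y <= a + b * obs$x + tol)
  structure(
    list(method = "cr_fdh", slope = b, intercept = a, peers = p,
         zone_area = C, scope_area = scope$area, d = C / scope$area,
         accuracy = acc, interpretable = acc >= 95, scope = scope,
         obs = obs),
    class = "nca_fit")
}

#' Fit a ceiling line
#'
#' Dispatcher over the two ceiling techniques.
#'
#' @inheritParams fit_ce_fdh
#' @param method `"ce_fdh"` (step function) or `"cr_fdh"` (straight line).
#' @return An `nca_fit`; see [fit_ce_fdh()] and [fit_cr_fdh()].
#' @export
fit_ceiling <- function(obs, scope = nca_scope(obs),
                        method = c("ce_fdh", "cr_fdh")) {
  method <- match.arg(method)
  switch(method, ce_fdh = fit_ce_fdh(obs, scope), cr_fdh = fit_cr_fdh(obs, scope))
}

.check_in_scope <- function(obs, scope) {
  if (any(obs$x < scope$x_min) || any(obs$x > scope$x_max) ||
      any(obs$y < scope$y_min) || any(obs$y > scope$y_max)) {
    stop("observations fall outside the scope rectangle", call. = FALSE)
  }
  invisible(TRUE)
}

#' Evaluate a ceiling line at condition values
#'
#' @param fit An `nca_fit` from [fit_ce_fdh()] / [fit_cr_fdh()].
#' @param x Numeric vector of condition values inside the scope.
#' @param clip Clip the value to the scope's `[y_min, y_max]`? Clipping is
#'   what zone areas and bottlenecks use; the raw line value may leave the
#'   rectangle for CR-FDH. Default `FALSE`.
#' @return Ceiling value(s) at `x`.
#' @examples
#' obs <- nca_observations(c(0, 1, 2), c(0, 1, 2))
#' ceiling_value(fit_ce_fdh(obs), 1.5)   # 1: step holds its value until x=2
#' @export
ceiling_value <- function(fit, x, clip = FALSE) {
  stopifnot(inherits(fit, "nca_fit"))
  sc <- fit$scope
  if (any(x < sc$x_min - 1e-12 * (sc$x_max - sc$x_min)) ||
      any(x > sc$x_max + 1e-12 * (sc$x_max - sc$x_min))) {
    stop("x outside the scope [", sc$x_min, ", ", sc$x_max, "]", call. = FALSE)
  }
  v <- if (fit$method == "ce_fdh") {
    bp <- fit$breakpoints
    bp$value[findInterval(x, bp$x)]
  } else {
    fit$intercept + fit$slope * x
  }
  if (clip) v <- pmin(pmax(v, sc$y_min), sc$y_max)
  v
}

#' @export
print.nca_fit <- function(x, ...) {
  lab <- if (x$method == "ce_fdh") "CE-FDH (step ceiling)" else
    sprintf("CR-FDH (line y = %.4gx + %.4g)", x$slope, x$intercept)
  cat(sprintf("%s, %s vs %s, n = %d\n", lab, x$obs$condition, x$obs$outcome,
              x$obs$n))
  cat(sprintf("  ceiling zone C = %.6g, scope S = %.6g, d = C/S = %.4f\n",
              x$zone_area, x$scope_area, x$d))
  cat(sprintf("  accuracy = %.2f%%%s\n", x$accuracy,
              if (x$method == "cr_fdh" && !x$interpretable)
                " (< 95%: not appropriate for interpretation)" else ""))
  invisible(x)
}

#' Plot observations with their ceiling line
#'
#' Scatterplot of the observations with the scope rectangle, the fitted
#' ceiling line and the (shaded) ceiling zone.
#'
#' @param x An `nca_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.nca_fit <- function(x, ...) {
  sc <- x$scope
  graphics::plot(x$obs$x, x$obs$y, xlim = c(sc$x_min, sc$x_max),
                 ylim = c(sc$y_min, sc$y_max), xlab = x$obs$condition,
                 ylab = x$obs$outcome, pch = 19,
                 col = grDevices::adjustcolor("grey30", 0.7), ...)
  graphics::rect(sc$x_min, sc$y_min, sc$x_max, sc$y_max, border = "grey60",
                 lty = 3)
  xx <- seq(sc$x_min, sc$x_max, length.out = 400)
  cv <- ceiling_value(x, xx, clip = TRUE)
  graphics::polygon(c(xx, rev(xx)), c(cv, rep(sc$y_max, length(xx))),
                    col = grDevices::adjustcolor("firebrick", 0.15),
                    border = NA)
  if (x$method == "ce_fdh") {
    bp <- x$breakpoints
    graphics::lines(stats::stepfun(bp$x[-1], bp$value), do.points = FALSE,
                    col = "firebrick", lwd = 2)
  } else {
    graphics::abline(x$intercept, x$slope, col = "firebrick", lwd = 2)
  }
  graphics::points(x$peers$x, x$peers$y, pch = 21, bg = "gold", cex = 1.2)
  invisible(x)
}
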