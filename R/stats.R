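# Necessity effect size, inefficiencies and the permutation test.

#' Necessity effect size and companion statistics
#'
#' Summarises a ceiling fit into the effect size `d = C/S` (ceiling-zone
#' area over scope area), the ceiling accuracy, and the outcome/condition
#' inefficiencies. A p-value can be attached by [permutation_test()].
#'
#' @param fit An `nca_fit` from [fit_ce_fdh()] / [fit_cr_fdh()].
#' @return An `nca_result`: a list with `d`, `zone_area`, `scope_area`,
#'   `accuracy`, `outcome_inefficiency`, `condition_inefficiency`,
#'   `ceiling_kind`, `interpretable`, `effect_label` (see [interpret_d()]),
#'   and `p_value`/`n_permutations` slots (`NA` until a test is run).
#' @examples
#' obs <- nca_observations(c(0, 1, 2), c(0, 1, 2))
#' effect_size(fit_ce_fdh(obs))$d   # 0.75
#' @export
effect_size <- function(fit) {
  stopifnot(inherits(fit, "nca_fit"))
  if (fit$scope_area <= 0) stop("scope area is zero", call. = FALSE)
  d <- fit$zone_area / fit$scope_area
  structure(
    list(d = d, zone_area = fit$zone_area, scope_area = fit$scope_area,
         accuracy = fit$accuracy,
         outcome_inefficiency = outcome_inefficiency(fit),
         condition_inefficiency = condition_inefficiency(fit),
         ceiling_kind = fit$method,
         interpretable = if (fit$method == "cr_fdh") fit$interpretable else TRUE,
         effect_label = interpret_d(d),
         p_value = NA_real_, n_permutations = NA_integer_),
    class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("NCA result (%s): d = %.2f (%s)%s\n",
              toupper(gsub("_", "-", x$ceiling_kind)), x$d, x$effect_label,
              if (is.na(x$p_value)) "" else
                sprintf(", p = %.3f (%d permutations)", x$p_value,
                        x$n_permutations)))
  cat(sprintf("  accuracy %.2f%%, outcome inefficiency %.2f%%, condition inefficiency %.2f%%\n",
              x$accuracy, x$outcome_inefficiency, x$condition_inefficiency))
  if (!x$interpretable)
    cat("  accuracy < 95%: not appropriate for interpretation\n")
  invisible(x)
}

#' Interpret a necessity effect size d
#'
#' Conventional thresholds for the ceiling-zone effect size: small below
#' 0.1, medium from 0.1 to 0.3 (inclusive at both ends), large above 0.3.
#'
#' @param d Effect size in `[0, 1]`.
#' @return `"small"`, `"medium"` or `"large"`.
#' @export
interpret_d <- function(d) {
  stopifnot(all(d >= 0 & d <= 1))
  ifelse(d < 0.1, "small", ifelse(d <= 0.3, "medium", "large"))
}

#' Outcome inefficiency
#'
#' The share of the outcome range that is reachable with no condition
#' requirement at all: the (clipped) ceiling height at the scope's left
#' edge, as a percentage of the outcome range. 0% means the condition
#' constrains every outcome level; 100% means no level is constrained.
#'
#' @param fit An `nca_fit`.
#' @return Percentage in `[0, 100]`.
#' @export
outcome_inefficiency <- function(fit) {
  stopifnot(inherits(fit, "nca_fit"))
  sc <- fit$scope
  y_cmin <- ceiling_value(fit, sc$x_min, clip = TRUE)
  100 * (y_cmin - sc$y_min) / (sc$y_max - sc$y_min)
}

#' Condition inefficiency
#'
#' The share of the condition range that is not needed even for the highest
#' outcome: everything to the right of the smallest x at which the (clipped)
#' ceiling reaches the scope's `y_max`. If the ceiling never reaches
#' `y_max`, every condition level matters and the inefficiency is 0%.
#'
#' @param fit An `nca_fit`.
#' @return Percentage in `[0, 100]`.
#' @export
condition_inefficiency <- function(fit) {
  stopifnot(inherits(fit, "nca_fit"))
  sc <- fit$scope
  x_cmax <- .x_reaching(fit, sc$y_max)
  if (is.na(x_cmax)) x_cmax <- sc$x_max
  100 * (sc$x_max - x_cmax) / (sc$x_max - sc$x_min)
}

# smallest x in scope at which the clipped ceiling is >= target (NA if never)
.x_reaching <- function(fit, target) {
  sc <- fit$scope
  tol <- .y_tol(sc)
  target <- min(target, sc$y_max)
  if (fit$method == "ce_fdh") {
    bp <- fit$breakpoints
    v <- pmin(pmax(bp$value, sc$y_min), sc$y_max)
    hit <- which(v >= target - tol)
    if (length(hit) == 0L) return(NA_real_)
    bp$x[hit[1]]
  } else {
    a <- fit$intercept
    b <- fit$slope
    clipv <- function(x) min(max(a + b * x, sc$y_min), sc$y_max)
    if (clipv(sc$x_min) >= target - tol) return(sc$x_min)
    if (clipv(sc$x_max) < target - tol) return(NA_real_)
    # b > 0 here: the clipped line is non-decreasing and crosses the target
    min(max((target - a) / b, sc$x_min), sc$x_max)
  }
}

# ---- permutation test -------------------------------------------------------

# Tight d computation reused across permutation replicates: x order and
# distinct-x segmentation are fixed, only y changes.
.perm_prep <- function(x, scope) {
  ord <- order(x)
  xs <- x[ord]
  last <- !duplicated(xs, fromLast = TRUE)
  ux <- xs[last]
  widths <- diff(c(ux, scope$x_max))
  # scope extending left of the data: constant floor strip for the step area
  extra <- (ux[1] - scope$x_min) * (scope$y_max - scope$y_min)
  list(ord = ord, last = last, ux = ux, widths = widths, extra = extra)
}

.perm_d <- function(y, prep, scope, method) {
  vals <- cummax(y[prep$ord])[prep$last]
  if (method == "ce_fdh") {
    return((prep$extra + sum(prep$widths * (scope$y_max - vals))) / scope$area)
  }
  keep <- c(TRUE, diff(vals) > 0)
  if (sum(keep) < 2L) return(0)   # corner occupied: flat ceiling, no zone
  px <- prep$ux[keep]
  py <- vals[keep]
  mx <- mean(px)
  b <- sum((px - mx) * (py - mean(py))) / sum((px - mx)^2)
  a <- mean(py) - b * mx
  .line_zone_area(a, b, scope) / scope$area
}

#' Approximate permutation test for the necessity effect size
#'
#' Tests whether the observed effect size d could have arisen from unrelated
#' variables: the outcome values are randomly re-paired with the condition
#' values (a permutation, preserving both marginals and hence the empirical
#' scope), the effect size is recomputed with the same ceiling technique,
#' and the p-value is the share of permuted effect sizes greater than or
#' equal to the observed one. With `plus_one = TRUE` the
#' `(count + 1)/(N + 1)` variant is used, which cannot return exactly 0.
#'
#' @param obs An [nca_observations()] object.
#' @param method Ceiling technique, `"ce_fdh"` or `"cr_fdh"`.
#' @param scope Scope rectangle (held fixed across permutations; permuting y
#'   leaves the marginals, and hence the empirical scope, unchanged).
#' @param n_permutations Number of random re-pairings (default 10000).
#' @param seed Integer seed making the null reproducible bit-for-bit.
#' @param plus_one Use the `(count + 1)/(N + 1)` estimator? Default `FALSE`.
#' @return An `nca_permutation`: list with `p_value`, `d_observed`,
#'   `d_null` (vector of permuted effect sizes), `n_permutations`, `seed`,
#'   `method`.
#' @examples
#' obs <- nca_observations(c(0, 1, 2, 3), c(0, 1, 2, 3))
#' permutation_test(obs, "ce_fdh", n_permutations = 50, seed = 1)$p_value
#' @export
permutation_test <- function(obs, method = c("ce_fdh", "cr_fdh"),
                             scope = nca_scope(obs), n_permutations = 10000,
                             seed = NULL, plus_one = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(obs, "nca_observations"))
  if (obs$n < 3L) stop("permutation test needs n >= 3", call. = FALSE)
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L) {
    stop("n_permutations must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  prep <- .perm_prep(obs$x, scope)
  d_obs <- .perm_d(obs$y, prep, scope, method)
  d_null <- vapply(seq_len(n_permutations), function(i) {
    .perm_d(sample(obs$y), prep, scope, method)
  }, numeric(1))
  tol <- 1e-12 * max(1, abs(d_obs))
  count <- sum(d_null >= d_obs - tol)
  p <- if (plus_one) (count + 1) / (n_permutations + 1) else
    count / n_permutations
  structure(
    list(p_value = p, d_observed = d_obs, d_null = d_null,
         n_permutations = n_permutations, seed = seed, method = method,
         plus_one = plus_one),
    class = "nca_permutation")
}

#' @export
print.nca_permutation <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %d permutations%s): d = %.4f, p = %.4f\n",
              toupper(gsub("_", "-", x$method)), x$n_permutations,
              if (is.null(x$seed)) "" else paste0(", seed ", x$seed),
              x$d_observed, x$p_value))
  invisible(x)
}

#' Significance decision
#'
#' `TRUE` iff `p < alpha` (strict): an effect size this large would rarely be
#' obtained by randomly re-pairing unrelated variables.
#'
#' @param p p-value in `[0, 1]`.
#' @param alpha Significance level (default 0.05).
#' @return Logical.
#' @export
is_significant <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1), alpha > 0, alpha < 1)
  p < alpha
}
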