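# Synthetic data generators: ceiling-constrained fills, independence nulls,
# and survey-like student data matching printed summary profiles. All
# generators are pure functions of (parameters, seed).

#' Generate data under a known linear ceiling
#'
#' Draws `n` points filling the region under the ceiling
#' `y = min(slope * x + intercept, y_max)` within a scope rectangle:
#' x uniform on `[x_min, x_max]`, then y uniform on
#' `[y_min, min(slope * x + intercept, y_max)]`. The fraction of the scope
#' above the true ceiling is the analytic effect size the estimators should
#' recover as n grows.
#'
#' @param n Number of points.
#' @param slope,intercept True ceiling line.
#' @param scope An [nca_scope()] (explicit bounds; defaults to the unit
#'   square).
#' @param seed Integer seed.
#' @return An [nca_observations()] object.
#' @examples
#' obs <- gen_ceiling_data(200, slope = 1, intercept = 0, seed = 1)
#' fit_ce_fdh(obs)$d   # near 0.5: the empty triangle above y = x
#' @export
gen_ceiling_data <- function(n, slope, intercept,
                             scope = nca_scope(x_min = 0, x_max = 1,
                                               y_min = 0, y_max = 1),
                             seed = NULL) {
  stopifnot(inherits(scope, "nca_scope"), n >= 2)
  top <- function(x) pmin(slope * x + intercept, scope$y_max)
  if (all(top(c(scope$x_min, scope$x_max)) <= scope$y_min)) {
    stop("the ceiling lies entirely below the scope floor; nothing to fill",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- numeric(0)
  while (length(x) < n) {
    cand <- stats::runif(n, scope$x_min, scope$x_max)
    cand <- cand[top(cand) > scope$y_min]   # no room under the ceiling there
    x <- c(x, cand)
  }
  x <- x[seq_len(n)]
  y <- stats::runif(n, scope$y_min, top(x))
  nca_observations(x, y, condition = "x", outcome = "y")
}

#' Analytic effect size of a linear-ceiling scenario
#'
#' The fraction of the scope rectangle lying strictly above the true ceiling
#' `y = min(slope * x + intercept, y_max)` — the value `d` estimated on data
#' from [gen_ceiling_data()] converges to.
#'
#' @inheritParams gen_ceiling_data
#' @return A number in `[0, 1]`.
#' @export
true_ceiling_d <- function(slope, intercept, scope) {
  stopifnot(inherits(scope, "nca_scope"))
  .line_zone_area(intercept, slope, scope) / scope$area
}

#' Generate an independence null dataset
#'
#' x and y independent uniforms on the scope rectangle: the configuration
#' the permutation test's null hypothesis describes. Used for type-I-error
#' simulations.
#'
#' @param n Number of points (`>= 3`).
#' @param scope An [nca_scope()] with explicit bounds (default unit square).
#' @param seed Integer seed.
#' @return An [nca_observations()] object.
#' @export
gen_null_data <- function(n, scope = nca_scope(x_min = 0, x_max = 1,
                                               y_min = 0, y_max = 1),
                          seed = NULL) {
  stopifnot(inherits(scope, "nca_scope"), n >= 3)
  if (!is.null(seed)) set.seed(as.integer(seed))
  nca_observations(stats::runif(n, scope$x_min, scope$x_max),
                   stats::runif(n, scope$y_min, scope$y_max))
}

# ---- survey-like student data ----------------------------------------------

# Closed-form mean/SD of a normal(mu, sigma) truncated to [lo, hi].
.truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Underlying (mu, sigma) such that the [lo, hi]-truncated normal has the
# target mean and SD. Truncation shifts moments, so using the targets
# directly as (mu, sigma) can miss the printed mean by >10% when a bound sits
# close to it; matching moments honours the printed summaries.
.truncnorm_params <- function(mean, sd, lo, hi) {
  obj <- function(p) {
    mo <- .truncnorm_moments(p[1], exp(p[2]), lo, hi)
    (mo["mean"] - mean)^2 / sd^2 + (mo["sd"] - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Group profile for survey-like generation
#'
#' Per-variable summary targets (mean, SD, min, max) defining one group of a
#' survey-like dataset, as printed in descriptive-statistics tables.
#'
#' @param variables Character vector of variable names.
#' @param mean,sd,min,max Numeric vectors aligned with `variables`.
#' @param n Default number of rows to generate for this group.
#' @return An `nca_group_profile` data.frame.
#' @export
group_profile <- function(variables, mean, sd, min, max, n) {
  stopifnot(length(variables) == length(mean), length(mean) == length(sd),
            length(sd) == length(min), length(min) == length(max))
  if (any(min >= max)) stop("profile requires min < max", call. = FALSE)
  if (any(sd < 0)) stop("profile requires sd >= 0", call. = FALSE)
  structure(
    data.frame(variable = variables, mean = mean, sd = sd, min = min,
               max = max, stringsAsFactors = FALSE),
    n = as.integer(n), class = c("nca_group_profile", "data.frame"))
}

#' Illustrative student-cohort profiles
#'
#' Summary profiles (mean, SD, range per variable) for two cohorts of
#' psychology undergraduates — one at a face-to-face university (n = 159),
#' one at an online university (n = 76) — covering grade point average
#' (0-10 scale), university admission grade (0-10), weekly study hours, and
#' a conscientiousness questionnaire score. Useful as realistic inputs for
#' end-to-end pipeline tests via [gen_student_like()].
#'
#' @return Named list of two [group_profile()] objects, `face_to_face` and
#'   `online`.
#' @export
student_profiles <- function() {
  vars <- c("gpa", "admission_grade", "study_time", "conscientiousness")
  list(
    face_to_face = group_profile(
      vars,
      mean = c(6.80, 7.80, 12.65, 31.87),
      sd   = c(0.72, 0.71, 8.62, 5.54),
      min  = c(5.50, 6.00, 1, 17),
      max  = c(9.20, 9.36, 40, 44),
      n = 159),
    online = group_profile(
      vars,
      mean = c(7.29, 6.90, 18.59, 35.17),
      sd   = c(0.79, 0.96, 10.76, 4.93),
      min  = c(5.00, 5.00, 2, 24),
      max  = c(8.76, 9.60, 100, 45),
      n = 76)
  )
}

#' Generate survey-like data from a group profile
#'
#' Draws each variable independently from a truncated normal on
#' `[min, max]` whose underlying parameters are moment-matched so the
#' truncated distribution has the profile's mean and SD (sample moments land
#' within ~10% of the targets by n = 500). Columns are independent: no
#' attempt is made to reproduce a correlation structure, so these data are
#' for pipeline/shape testing, not for reproducing published effect sizes.
#'
#' @param profile An [group_profile()] object.
#' @param n Number of rows (defaults to the profile's `n`).
#' @param seed Integer seed.
#' @return A data.frame with one column per profile variable.
#' @examples
#' head(gen_student_like(student_profiles()$online, n = 10, seed = 1))
#' @export
gen_student_like <- function(profile, n = attr(profile, "n"), seed = NULL) {
  stopifnot(inherits(profile, "nca_group_profile"), n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- lapply(seq_len(nrow(profile)), function(i) {
    p <- profile[i, ]
    if (p$sd == 0) return(rep(p$mean, n))
    th <- .truncnorm_params(p$mean, p$sd, p$min, p$max)
    plo <- stats::pnorm((p$min - th["mu"]) / th["sigma"])
    phi <- stats::pnorm((p$max - th["mu"]) / th["sigma"])
    # inverse-CDF sampling: exactly truncated, one draw per row
    th["mu"] + th["sigma"] * stats::qnorm(stats::runif(n, plo, phi))
  })
  names(out) <- profile$variable
  as.data.frame(out)
}

#' Generate a two-group student-like dataset
#'
#' Convenience wrapper stacking [gen_student_like()] draws for several
#' profiles into one table with a group column — the shape a grouped
#' necessity analysis ingests.
#'
#' @param profiles Named list of [group_profile()] objects (default
#'   [student_profiles()]).
#' @param n Optional vector of group sizes (defaults to each profile's `n`).
#' @param seed Integer seed.
#' @param group_col Name of the group column (default `"setting"`).
#' @return A data.frame.
#' @export
gen_student_groups <- function(profiles = student_profiles(), n = NULL,
                               seed = NULL, group_col = "setting") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  parts <- lapply(seq_along(profiles), function(i) {
    ni <- if (is.null(n)) attr(profiles[[i]], "n") else n[i]
    df <- gen_student_like(profiles[[i]], n = ni, seed = NULL)
    df[[group_col]] <- names(profiles)[i]
    df
  })
  do.call(rbind, parts)
}
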