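# Independent oracles used across the suite. These deliberately avoid the
# package's analytic area code paths: areas come from fine-grid numerical
# integration and ceiling values from the definitional max-scan.

# Definitional CE-FDH ceiling at grid points: max{ y_i : x_i <= g } (y_min
# when no observation lies at or left of g). Chunked to bound memory.
oracle_step_value <- function(gx, x, y, y_min) {
  out <- numeric(length(gx))
  chunk <- 20000L
  for (s in seq(1, length(gx), by = chunk)) {
    idx <- s:min(s + chunk - 1L, length(gx))
    m <- outer(gx[idx], x, ">=")            # grid point sees observation?
    yy <- matrix(y, nrow = length(idx), ncol = length(y), byrow = TRUE)
    yy[!m] <- -Inf
    v <- apply(yy, 1, max)
    v[!is.finite(v)] <- y_min
    out[idx] <- v
  }
  out
}

# Fine-grid numerical integration of the empty zone above a fitted ceiling,
# clipped to the scope rectangle. `cells` midpoints across the x range.
oracle_zone_area <- function(fit, cells = 1e6) {
  sc <- fit$scope
  w <- sc$x_max - sc$x_min
  gx <- sc$x_min + w * (seq_len(cells) - 0.5) / cells
  cv <- if (fit$method == "ce_fdh") {
    oracle_step_value(gx, fit$obs$x, fit$obs$y, sc$y_min)
  } else {
    fit$intercept + fit$slope * gx
  }
  cv <- pmin(pmax(cv, sc$y_min), sc$y_max)
  mean(sc$y_max - cv) * w
}

# Random bivariate dataset with an arbitrary (affinely shifted) scale.
random_obs <- function(n, seed) {
  set.seed(seed)
  a <- runif(1, -5, 5)
  b <- runif(1, 0.1, 10)
  nca_observations(a + b * runif(n), a / 2 + 2 * b * runif(n))
}
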