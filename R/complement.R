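# Benchmark-based interpretation of Pearson correlations: the "sufficiency"
# complement reported next to the necessity results.

#' Interpret a Pearson correlation against benchmarks
#'
#' Two interpretation schemes:
#' * `"cohen"` — the classic thresholds: `|r| < 0.10` below-small,
#'   0.10-0.29 small, 0.30-0.49 medium, `>= 0.50` large.
#' * `"empirical_quartiles"` — quartile bands of the distribution of
#'   published individual-differences correlations, whose 25th/50th/75th
#'   percentiles sit at 0.11/0.19/0.29; a coefficient is placed in the
#'   quartile band its magnitude falls into, giving a field-relative reading
#'   (most published effects are far below Cohen's "large").
#'
#' @param r Correlation coefficient(s), `|r| <= 1`.
#' @param scheme `"cohen"` or `"empirical_quartiles"`.
#' @return Character label(s).
#' @examples
#' interpret_r(0.18, "cohen")                 # "small"
#' interpret_r(0.18, "empirical_quartiles")   # "second quartile (0.11-0.19)"
#' @export
interpret_r <- function(r, scheme = c("cohen", "empirical_quartiles")) {
  scheme <- match.arg(scheme)
  stopifnot(all(abs(r) <= 1))
  a <- abs(r)
  if (scheme == "cohen") {
    ifelse(a < 0.10, "below-small",
           ifelse(a < 0.30, "small",
                  ifelse(a < 0.50, "medium", "large")))
  } else {
    ifelse(a < 0.11, "first quartile (< 0.11)",
           ifelse(a < 0.19, "second quartile (0.11-0.19)",
                  ifelse(a < 0.29, "third quartile (0.19-0.29)",
                         "fourth quartile (>= 0.29)")))
  }
}

#' Pearson correlation with benchmark labels
#'
#' Computes the product-moment correlation between each condition and the
#' outcome and attaches both interpretation schemes, contextualising the
#' usual sufficiency-logic effect size alongside the necessity results.
#'
#' @param nd An `nca_data` object from [read_nca_data()] (already
#'   preprocessed), or a plain data.frame plus explicit column names.
#' @param outcome,conditions Column names (taken from `nd` when it is an
#'   `nca_data`).
#' @return An `nca_complement` data.frame: one row per condition with `r`,
#'   `cohen_label`, `quartile_label`, `n`.
#' @export
complement_report <- function(nd, outcome = NULL, conditions = NULL) {
  if (inherits(nd, "nca_data")) {
    df <- nd$data
    outcome <- nd$outcome
    conditions <- nd$conditions
  } else {
    df <- as.data.frame(nd)
  }
  rows <- lapply(conditions, function(cl) {
    x <- df[[cl]]
    y <- df[[outcome]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]
    y <- y[ok]
    if (length(x) < 3L) stop("correlation needs n >= 3 for ", cl, call. = FALSE)
    if (stats::var(x) == 0 || stats::var(y) == 0) {
      stop("zero variance in '", cl, "' or '", outcome,
           "': correlation undefined", call. = FALSE)
    }
    r <- stats::cor(x, y)
    data.frame(condition = cl, r = r,
               cohen_label = interpret_r(r, "cohen"),
               quartile_label = interpret_r(r, "empirical_quartiles"),
               n = length(x), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            outcome = outcome,
            class = c("nca_complement", "data.frame"))
}

#' @export
print.nca_complement <- function(x, ...) {
  cat(sprintf("Pearson-r complement (outcome '%s'):\n", attr(x, "outcome")))
  y <- as.data.frame(x)
  y$r <- round(y$r, 2)
  print(y, row.names = FALSE)
  invisible(x)
}
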