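# Bottleneck tables: invert a ceiling line into the minimum condition level
# required for each outcome level.

#' Bottleneck column for one condition
#'
#' For each requested outcome level (a percentage of the outcome range,
#' `0% = y_min`, `100% = y_max`), finds the smallest condition value whose
#' (clipped) ceiling reaches that outcome level. Levels already reachable at
#' the scope's left edge need no condition at all and get the sentinel
#' `"NN"` (not necessary); levels the ceiling never reaches within the scope
#' get `"NA"` (not attainable).
#'
#' For a step ceiling the requirement is exact (a breakpoint x-coordinate);
#' for a straight-line ceiling it is the analytic inversion of the line,
#' clipped to the scope.
#'
#' @param fit An `nca_fit`.
#' @param levels Outcome levels as percentages of the outcome range
#'   (default `seq(0, 100, 10)`).
#' @param units `"actual"` (condition's native units, default) or
#'   `"percentage_range"` (percent of the condition range).
#' @return An `nca_bottleneck`: data.frame with columns `level` (outcome %)
#'   and `required` (numeric; `NA` with attribute-level sentinels resolved
#'   by `format()`), plus attributes `sentinel` (character `""`/`"NN"`/
#'   `"NA"` per row), `condition`, `outcome`, `units`.
#' @examples
#' obs <- nca_observations(c(0, 5, 10), c(0, 5, 10))
#' bottleneck(fit_cr_fdh(obs), levels = c(0, 50, 100))
#' @export
bottleneck <- function(fit, levels = seq(0, 100, 10),
                       units = c("actual", "percentage_range")) {
  stopifnot(inherits(fit, "nca_fit"))
  units <- match.arg(units)
  if (any(levels < 0 | levels > 100)) {
    stop("outcome levels must be percentages in [0, 100]", call. = FALSE)
  }
  sc <- fit$scope
  tol <- .y_tol(sc)
  y_at_min <- ceiling_value(fit, sc$x_min, clip = TRUE)
  required <- numeric(length(levels))
  sentinel <- character(length(levels))
  for (i in seq_along(levels)) {
    target <- sc$y_min + levels[i] / 100 * (sc$y_max - sc$y_min)
    if (y_at_min >= target - tol) {
      required[i] <- NA_real_
      sentinel[i] <- "NN"
      next
    }
    xr <- .x_reaching(fit, target)
    if (is.na(xr)) {
      required[i] <- NA_real_
      sentinel[i] <- "NA"
      next
    }
    required[i] <- if (units == "percentage_range") {
      100 * (xr - sc$x_min) / (sc$x_max - sc$x_min)
    } else xr
    sentinel[i] <- ""
  }
  structure(
    data.frame(level = levels, required = required),
    sentinel = sentinel, condition = fit$obs$condition,
    outcome = fit$obs$outcome, units = units, method = fit$method,
    class = c("nca_bottleneck", "data.frame"))
}

#' Assemble bottleneck columns into one table
#'
#' Aligns per-condition bottleneck columns (which must share the same
#' outcome-level grid) into a single table: one row per outcome level, one
#' column per condition, with `"NN"`/`"NA"` sentinels as strings.
#'
#' @param columns A (optionally named) list of `nca_bottleneck` objects.
#' @return An `nca_bottleneck_table`: a data.frame whose first column is the
#'   outcome level (labelled `"<outcome> (%)"`) followed by one character
#'   column per condition.
#' @export
bottleneck_table <- function(columns) {
  if (inherits(columns, "nca_bottleneck")) columns <- list(columns)
  stopifnot(length(columns) >= 1L,
            all(vapply(columns, inherits, logical(1), "nca_bottleneck")))
  lv <- columns[[1]]$level
  for (cl in columns) {
    if (!isTRUE(all.equal(cl$level, lv))) {
      stop("bottleneck columns use different outcome-level grids",
           call. = FALSE)
    }
  }
  out <- data.frame(level = lv, check.names = FALSE)
  names(out) <- paste0(attr(columns[[1]], "outcome"), " (%)")
  for (i in seq_along(columns)) {
    cl <- columns[[i]]
    nm <- names(columns)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- attr(cl, "condition")
    s <- attr(cl, "sentinel")
    v <- ifelse(s != "", s, formatC(cl$required, format = "fg", digits = 6))
    out[[nm]] <- v
  }
  structure(out, units = attr(columns[[1]], "units"),
            class = c("nca_bottleneck_table", "data.frame"))
}

#' @export
print.nca_bottleneck <- function(x, ...) {
  cat(sprintf("Bottleneck column: %s required for %s levels (%s units, %s)\n",
              attr(x, "condition"), attr(x, "outcome"), attr(x, "units"),
              toupper(gsub("_", "-", attr(x, "method")))))
  s <- attr(x, "sentinel")
  shown <- ifelse(s != "", s, format(round(x$required, 2)))
  print(data.frame(level = x$level, required = shown), row.names = FALSE)
  invisible(x)
}

#' @export
print.nca_bottleneck_table <- function(x, ...) {
  cat(sprintf("Bottleneck table (%s units):\n", attr(x, "units")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Write a bottleneck table to CSV
#'
#' @param table An `nca_bottleneck_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_bottlenecks <- function(table, path) {
  stopifnot(inherits(table, "nca_bottleneck_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
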