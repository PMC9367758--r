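#' Read a rectangular dataset for necessity analysis
#'
#' Reads a CSV file (RFC-4180, header row, "." decimal separator) and checks
#' that the outcome, condition and optional grouping columns exist and are
#' numeric. Empty cells and the tokens `"NA"` / `"NaN"` (case-insensitive)
#' are treated as missing; any other non-numeric cell in an analysis column
#' is an error reported with its row number.
#'
#' @param path Path to a CSV file, or a `data.frame` to validate in place.
#' @param outcome Name of the outcome column.
#' @param conditions Character vector of condition column names.
#' @param group Optional name of a grouping column; its levels define
#'   subsamples that are analysed independently.
#' @return An object of class `nca_data`: a list with the parsed `data`
#'   (analysis columns numeric), and the `outcome`, `conditions`, `group`
#'   column names.
#' @seealso [preprocess_nca()] for imputation/outlier handling,
#'   [run_nca()] for the full pipeline.
#' @export
read_nca_data <- function(path, outcome, conditions, group = NULL) {
  df <- if (is.data.frame(path)) {
    as.data.frame(path)
  } else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  cols <- c(outcome, conditions, group)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("column(s) not found in input: ",
         paste(sQuote(missing_cols), collapse = ", "), call. = FALSE)
  }
  for (cl in c(outcome, conditions)) {
    df[[cl]] <- .coerce_numeric_column(df[[cl]], cl)
  }
  if (!is.null(group)) df[[group]] <- as.character(df[[group]])
  structure(list(data = df, outcome = outcome, conditions = conditions,
                 group = group),
            class = "nca_data")
}

# missing-value tokens accepted in CSV cells
.is_missing_token <- function(v) {
  is.na(v) | trimws(tolower(as.character(v))) %in% c("", "na", "nan")
}

.coerce_numeric_column <- function(v, name) {
  if (is.numeric(v)) return(as.numeric(v))
  ch <- trimws(as.character(v))
  out <- rep(NA_real_, length(ch))
  miss <- .is_missing_token(ch)
  num <- suppressWarnings(as.numeric(ch[!miss]))
  bad <- which(!miss)[is.na(num)]
  if (length(bad) > 0L) {
    stop(sprintf("column '%s': non-numeric value %s at row %d",
                 name, sQuote(ch[bad[1]]), bad[1]), call. = FALSE)
  }
  out[!miss] <- num
  out
}

#' @export
print.nca_data <- function(x, ...) {
  cat(sprintf("NCA dataset: %d rows; outcome '%s'; condition(s) %s%s\n",
              nrow(x$data), x$outcome,
              paste(sQuote(x$conditions), collapse = ", "),
              if (is.null(x$group)) "" else
                sprintf("; grouped by '%s'", x$group)))
  invisible(x)
}

#' Mean imputation of missing values
#'
#' Replaces every missing entry of a numeric vector by the mean of its
#' non-missing entries. This preserves the column mean exactly and is the
#' conventional simple treatment when missingness is low (around 1%);
#' it is not suitable for heavily incomplete columns.
#'
#' @param column Numeric vector, possibly with `NA` entries.
#' @return A list with `values` (the imputed vector) and `n_imputed`.
#' @examples
#' impute_mean(c(1, 2, NA, 3))   # NA -> 2
#' @export
impute_mean <- function(column) {
  column <- as.numeric(column)
  miss <- is.na(column)
  if (all(miss)) {
    stop("cannot impute an all-missing column", call. = FALSE)
  }
  column[miss] <- mean(column[!miss])
  list(values = column, n_imputed = sum(miss))
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' Bias-corrected sample skewness
#' \eqn{G_1 = g_1 \sqrt{n(n-1)}/(n-2)} with
#' \eqn{g_1 = m_3 / m_2^{3/2}} (central moments with 1/n weights), the
#' estimator reported by default in common statistics software. Absolute
#' values above 2.0 are conventionally read as a highly skewed distribution
#' and flagged.
#'
#' @param column Numeric vector, `n >= 3`, non-constant.
#' @param threshold Flagging threshold on `|skewness|` (default 2.0).
#' @return A number with attribute `flagged` (`TRUE` when
#'   `|skewness| > threshold`).
#' @examples
#' sample_skewness(c(1, 2, 3, 4, 5))   # 0, symmetric
#' @export
sample_skewness <- function(column, threshold = 2) {
  column <- as.numeric(column)
  column <- column[!is.na(column)]
  n <- length(column)
  if (n < 3L) stop("skewness needs at least 3 values", call. = FALSE)
  m <- mean(column)
  m2 <- mean((column - m)^2)
  if (m2 == 0) {
    stop("skewness is undefined for a constant vector", call. = FALSE)
  }
  g1 <- mean((column - m)^3) / m2^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  structure(G1, flagged = abs(G1) > threshold)
}

#' Remove outliers beyond k standard deviations
#'
#' Flags values at least `k` standard deviations away from the mean, with
#' mean and SD computed once on the full input (single pass; no iterative
#' re-screening — re-invoking on the kept values may remove more rows). The
#' SD is the population (1/n) standard deviation and the boundary is
#' inclusive: a value exactly `k` SD from the mean is removed. Row removal is
#' intended to apply to whole records, so the kept/removed indices are
#' returned rather than a shortened vector.
#'
#' @param column Numeric vector, `n >= 3`.
#' @param k SD multiplier (default 3).
#' @return A list with integer vectors `kept` and `removed` (indices into
#'   `column`), plus `mean` and `sd` used for the screen.
#' @examples
#' remove_outliers(c(rep(1, 9), 100))$removed   # 10
#' @export
remove_outliers <- function(column, k = 3) {
  column <- as.numeric(column)
  n <- length(column)
  if (n < 3L) stop("outlier screen needs at least 3 values", call. = FALSE)
  idx <- which(!is.na(column))
  m <- mean(column[idx])
  s <- sqrt(mean((column[idx] - m)^2))
  if (s == 0) {
    warning("zero standard deviation; no outliers removed")
    return(list(kept = seq_len(n), removed = integer(0), mean = m, sd = s))
  }
  # inclusive boundary with a tiny relative tolerance so that values placed
  # exactly k SDs out are removed despite floating-point rounding
  out <- idx[abs(column[idx] - m) >= k * s * (1 - 1e-12)]
  list(kept = setdiff(seq_len(n), out), removed = out, mean = m, sd = s)
}

#' Preprocess a dataset for necessity analysis
#'
#' Applies, in order: mean imputation of every analysis column, a skewness
#' screen on every analysis column, and single-pass outlier removal
#' (whole-record) on the selected columns. Grouped analyses preprocess the
#' full sample before splitting, so imputation means and outlier screens use
#' all rows.
#'
#' @param nd An `nca_data` object from [read_nca_data()].
#' @param impute Impute missing values by column means? (default `TRUE`)
#' @param outlier_cols Columns to screen for outliers: a character vector of
#'   column names, `"flagged"` (default) to screen only columns whose
#'   `|skewness|` exceeds `skew_threshold`, or `NULL` for none.
#' @param outlier_k SD multiplier for the outlier screen (default 3).
#' @param skew_threshold Skewness flag threshold (default 2.0).
#' @return A list with `data` (the cleaned `nca_data`) and `report`, an
#'   `nca_preprocess` object recording imputation counts, per-column
#'   skewness, removed rows and sample sizes before/after. Serialize the
#'   report with [preprocess_json()].
#' @export
preprocess_nca <- function(nd, impute = TRUE, outlier_cols = "flagged",
                           outlier_k = 3, skew_threshold = 2) {
  stopifnot(inherits(nd, "nca_data"))
  df <- nd$data
  cols <- c(nd$outcome, nd$conditions)
  n_before <- nrow(df)

  n_imputed <- stats::setNames(integer(length(cols)), cols)
  if (impute) {
    for (cl in cols) {
      im <- impute_mean(df[[cl]])
      df[[cl]] <- im$values
      n_imputed[cl] <- im$n_imputed
    }
  }

  skew <- stats::setNames(numeric(length(cols)), cols)
  flagged <- character(0)
  for (cl in cols) {
    s <- tryCatch(sample_skewness(df[[cl]], threshold = skew_threshold),
                  error = function(e) structure(NA_real_, flagged = FALSE))
    skew[cl] <- as.numeric(s)
    if (isTRUE(attr(s, "flagged"))) flagged <- c(flagged, cl)
  }

  screen <- if (identical(outlier_cols, "flagged")) flagged else outlier_cols
  screen <- intersect(screen, cols)
  removed <- data.frame(row = integer(0), column = character(0),
                        value = numeric(0), stringsAsFactors = FALSE)
  for (cl in screen) {
    ro <- remove_outliers(df[[cl]], k = outlier_k)
    if (length(ro$removed) > 0L) {
      removed <- rbind(removed, data.frame(
        row = ro$removed, column = cl, value = df[[cl]][ro$removed],
        stringsAsFactors = FALSE))
    }
  }
  drop_rows <- sort(unique(removed$row))
  if (length(drop_rows) > 0L) df <- df[-drop_rows, , drop = FALSE]
  rownames(df) <- NULL

  nd$data <- df
  report <- structure(
    list(n_before = n_before, n_after = nrow(df), n_imputed = as.list(n_imputed),
         skewness = as.list(skew), skew_threshold = skew_threshold,
         flagged_columns = flagged, outlier_columns = screen,
         outlier_k = outlier_k, outlier_rows_removed = removed),
    class = "nca_preprocess")
  list(data = nd, report = report)
}

#' @export
print.nca_preprocess <- function(x, ...) {
  cat(sprintf("Preprocessing: n %d -> %d\n", x$n_before, x$n_after))
  cat("  imputed:", paste(sprintf("%s=%d", names(x$n_imputed),
                                  unlist(x$n_imputed)), collapse = ", "), "\n")
  cat("  skewness:", paste(sprintf("%s=%.2f", names(x$skewness),
                                   unlist(x$skewness)), collapse = ", "), "\n")
  if (length(x$flagged_columns) > 0L)
    cat("  flagged |skew| >", x$skew_threshold, ":",
        paste(x$flagged_columns, collapse = ", "), "\n")
  if (nrow(x$outlier_rows_removed) > 0L)
    cat(sprintf("  removed %d row(s) beyond %g SD in: %s\n",
                length(unique(x$outlier_rows_removed$row)), x$outlier_k,
                paste(unique(x$outlier_rows_removed$column), collapse = ", ")))
  invisible(x)
}

#' Serialize a preprocessing report to JSON
#'
#' @param report An `nca_preprocess` object from [preprocess_nca()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
preprocess_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "nca_preprocess"))
  x <- unclass(report)
  x$outlier_rows_removed <- report$outlier_rows_removed
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
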