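# End-to-end analysis: preprocessing, per-group per-condition ceiling fits,
# effect sizes with permutation p-values, bottlenecks for significant
# conditions, and the Pearson-r complement.

#' Run a full necessity analysis
#'
#' The whole pipeline in one call: read/validate the table, preprocess the
#' full sample (mean imputation, skewness screen, outlier removal), split by
#' group, and for every group x condition x ceiling technique compute the
#' effect size d, its permutation p-value, accuracy and inefficiencies.
#' CR-FDH fits with accuracy below 95% are flagged as not interpretable and
#' the step ceiling is marked as the line to read instead. Bottleneck tables
#' are emitted only for conditions whose effect size is significant
#' (`p < alpha`) for at least one ceiling technique, and a Pearson-r
#' complement with benchmark labels is attached per group.
#'
#' Per-condition failures (e.g. a constant column) are caught and recorded
#' in `$failures` without aborting the other conditions.
#'
#' @param data CSV path or data.frame.
#' @param outcome,conditions,group Column names (see [read_nca_data()]).
#' @param methods Ceiling techniques to fit (default both).
#' @param n_permutations Permutations for the significance test (default
#'   10000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer master seed; each group x condition x method test
#'   derives its own sub-seed deterministically from it.
#' @param impute,outlier_cols,outlier_k,skew_threshold Preprocessing
#'   switches, see [preprocess_nca()].
#' @param bottleneck_levels,bottleneck_units Bottleneck grid and units, see
#'   [bottleneck()].
#' @return An `nca_analysis`: list with `results` (one data.frame row per
#'   group x condition x method: `ES`, `p`, `A`, `OI`, `CI`,
#'   `interpretable`, `significant`), `bottlenecks` (nested list
#'   group -> condition -> `nca_bottleneck_table`), `complement` (per
#'   group), `preprocess` report, `failures`, and the `config`.
#' @examples
#' df <- gen_student_like(student_profiles()$online, n = 60, seed = 7)
#' ana <- run_nca(df, outcome = "gpa", conditions = "study_time",
#'                n_permutations = 200, seed = 1)
#' ana$results
#' @export
run_nca <- function(data, outcome, conditions, group = NULL,
                    methods = c("ce_fdh", "cr_fdh"), n_permutations = 10000,
                    alpha = 0.05, seed = 1, impute = TRUE,
                    outlier_cols = "flagged", outlier_k = 3,
                    skew_threshold = 2, bottleneck_levels = seq(0, 100, 10),
                    bottleneck_units = "actual") {
  stopifnot(alpha > 0, alpha < 1)
  methods <- match.arg(methods, c("ce_fdh", "cr_fdh"), several.ok = TRUE)
  nd <- read_nca_data(data, outcome, conditions, group)
  pp <- preprocess_nca(nd, impute = impute, outlier_cols = outlier_cols,
                       outlier_k = outlier_k, skew_threshold = skew_threshold)
  df <- pp$data$data

  groups <- if (is.null(group)) list(all = df) else split(df, df[[group]])
  results <- list()
  bottlenecks <- list()
  complement <- list()
  failures <- list()

  for (gi in seq_along(groups)) {
    gname <- names(groups)[gi]
    gdf <- groups[[gi]]
    # per-condition isolation: a degenerate column must not suppress the
    # other conditions' correlations
    cc_rows <- lapply(conditions, function(cl) tryCatch(
      complement_report(gdf, outcome = outcome, conditions = cl),
      error = function(e) NULL))
    cc_rows <- cc_rows[!vapply(cc_rows, is.null, logical(1))]
    complement[[gname]] <- if (length(cc_rows) > 0L) {
      structure(do.call(rbind, cc_rows), outcome = outcome,
                class = c("nca_complement", "data.frame"))
    } else NULL
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      res <- tryCatch({
        obs <- nca_observations(gdf[[cond]], gdf[[outcome]],
                                condition = cond, outcome = outcome)
        scope <- nca_scope(obs)
        rows <- list()
        signif_any <- FALSE
        fits <- list()
        for (mi in seq_along(methods)) {
          m <- methods[mi]
          fit <- fit_ceiling(obs, scope, method = m)
          fits[[m]] <- fit
          es <- effect_size(fit)
          sub_seed <- (as.integer(seed) + 7919L * gi + 101L * ci + mi) %% .Machine$integer.max
          pt <- permutation_test(obs, m, scope = scope,
                                 n_permutations = n_permutations,
                                 seed = sub_seed)
          sig <- is_significant(pt$p_value, alpha)
          signif_any <- signif_any || sig
          rows[[m]] <- data.frame(
            group = gname, condition = cond, ceiling = m, n = obs$n,
            ES = es$d, p = pt$p_value, A = es$accuracy,
            OI = es$outcome_inefficiency, CI = es$condition_inefficiency,
            interpretable = es$interpretable, significant = sig,
            effect_label = es$effect_label, stringsAsFactors = FALSE)
        }
        # bottlenecks only for significant conditions (per reporting rule);
        # both ceilings are tabled, the interpretable one is the one to read
        if (signif_any) {
          cols <- lapply(fits, bottleneck, levels = bottleneck_levels,
                         units = bottleneck_units)
          names(cols) <- paste0(cond, " (", toupper(gsub("_", "-",
                                                         names(fits))), ")")
          bottlenecks[[gname]][[cond]] <- bottleneck_table(cols)
        }
        do.call(rbind, rows)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[paste(gname, cond, sep = "/")]] <- conditionMessage(res)
      } else {
        results[[paste(gname, cond, sep = "/")]] <- res
      }
    }
  }

  structure(
    list(results = if (length(results) > 0L)
           do.call(rbind, c(results, list(make.row.names = FALSE))) else NULL,
         bottlenecks = bottlenecks, complement = complement,
         preprocess = pp$report, failures = failures,
         config = list(outcome = outcome, conditions = conditions,
                       group = group, methods = methods,
                       n_permutations = n_permutations, alpha = alpha,
                       seed = seed, impute = impute,
                       outlier_cols = outlier_cols, outlier_k = outlier_k,
                       skew_threshold = skew_threshold,
                       bottleneck_levels = bottleneck_levels,
                       bottleneck_units = bottleneck_units)),
    class = "nca_analysis")
}

#' @export
print.nca_analysis <- function(x, ...) {
  cat("Necessity analysis\n")
  print(x$preprocess)
  r <- x$results
  if (!is.null(r) && nrow(r) > 0L) {
    r$ES <- round(r$ES, 2)          # presentation rounding only: 2 decimals
    r$p <- round(r$p, 3)            # for effect sizes, 3 for p-values
    r$A <- round(r$A, 2)
    r$OI <- round(r$OI, 2)
    r$CI <- round(r$CI, 2)
    cat("\nEffect sizes (ES = d, A = accuracy %, OI/CI = inefficiency %):\n")
    print(r, row.names = FALSE)
  }
  for (g in names(x$complement)) {
    cat("\nGroup", g, "-- ")
    print(x$complement[[g]])
  }
  if (length(x$bottlenecks) > 0L) {
    for (g in names(x$bottlenecks)) for (cond in names(x$bottlenecks[[g]])) {
      cat(sprintf("\nGroup %s, condition %s -- ", g, cond))
      print(x$bottlenecks[[g]][[cond]])
    }
  } else {
    cat("\nNo significant conditions: no bottleneck tables emitted.\n")
  }
  if (length(x$failures) > 0L) {
    cat("\nFailures:\n")
    for (nm in names(x$failures)) cat("  ", nm, ": ", x$failures[[nm]], "\n",
                                      sep = "")
  }
  invisible(x)
}

#' Write an analysis report bundle to disk
#'
#' Writes `report.json` (full precision), `table2.csv` (one row per group x
#' condition x ceiling with ES/p/A/OI/CI columns), `bottlenecks.csv` (long
#' format) and `preprocess.json` into a directory.
#'
#' @param ana An `nca_analysis` from [run_nca()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_nca_report <- function(ana, dir) {
  stopifnot(inherits(ana, "nca_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(report = file.path(dir, "report.json"),
             table2 = file.path(dir, "table2.csv"),
             bottlenecks = file.path(dir, "bottlenecks.csv"),
             preprocess = file.path(dir, "preprocess.json"))

  utils::write.csv(ana$results, paths["table2"], row.names = FALSE)

  bn_long <- list()
  for (g in names(ana$bottlenecks)) for (cond in names(ana$bottlenecks[[g]])) {
    tb <- as.data.frame(ana$bottlenecks[[g]][[cond]])
    long <- utils::stack(tb[-1])
    bn_long[[paste(g, cond)]] <- data.frame(
      group = g, condition = cond, outcome_level = tb[[1]],
      ceiling_column = as.character(long$ind), required = long$values,
      stringsAsFactors = FALSE)
  }
  bn <- if (length(bn_long) > 0L) do.call(rbind, bn_long) else
    data.frame(group = character(0), condition = character(0),
               outcome_level = numeric(0), ceiling_column = character(0),
               required = character(0))
  utils::write.csv(bn, paths["bottlenecks"], row.names = FALSE)

  preprocess_json(ana$preprocess, paths["preprocess"])

  report <- list(
    config = ana$config,
    results = ana$results,
    complement = lapply(ana$complement, function(cc)
      if (is.data.frame(cc)) cc else list(error = cc)),
    bottlenecks = lapply(ana$bottlenecks, function(g)
      lapply(g, as.data.frame)),
    preprocess = c(unclass(ana$preprocess)),
    failures = ana$failures)
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paths)
}
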