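# The correlation complement and the end-to-end analysis/report assembly.

test_that("Pearson r basics and error paths", {
  df <- data.frame(y = c(1, 2, 3, 4), up = c(2, 4, 6, 8), down = -c(1, 2, 3, 4))
  cc <- complement_report(df, outcome = "y", conditions = c("up", "down"))
  expect_equal(cc$r, c(1, -1))
  expect_error(
    complement_report(data.frame(y = 1:4, k = rep(2, 4)), outcome = "y",
                      conditions = "k"),
    "zero variance")
})

test_that("correlation benchmarks: Cohen bands and empirical quartiles", {
  expect_equal(interpret_r(c(0.09, 0.18, 0.299, 0.30, 0.499, 0.50), "cohen"),
               c("below-small", "small", "small", "medium", "medium", "large"))
  expect_equal(interpret_r(-0.35, "cohen"), "medium")   # magnitude-based

  expect_match(interpret_r(0.18, "empirical_quartiles"), "second quartile")
  expect_match(interpret_r(0.05, "empirical_quartiles"), "first quartile")
  expect_match(interpret_r(0.21, "empirical_quartiles"), "third quartile")
  expect_match(interpret_r(0.40, "empirical_quartiles"), "fourth quartile")
})

test_that("run_nca produces one result block per group and isolates failures", {
  df <- gen_student_groups(seed = 17)
  df$broken <- 1                      # constant column: per-condition failure
  ana <- run_nca(df, outcome = "gpa",
                 conditions = c("study_time", "conscientiousness", "broken"),
                 group = "setting", n_permutations = 100, seed = 2)

  r <- ana$results
  expect_setequal(unique(r$group), c("face_to_face", "online"))
  # 2 groups x 2 working conditions x 2 ceilings
  expect_equal(nrow(r), 8)
  expect_true(all(r$ES >= 0 & r$ES <= 1))
  expect_true(all(r$p >= 0 & r$p <= 1))
  expect_true(all(r$A[r$ceiling == "ce_fdh"] == 100))
  expect_length(ana$failures, 2)      # 'broken' fails in both groups
  expect_match(ana$failures[[1]], "degenerate|corner|variance")
})

test_that("CR-FDH below 95% accuracy is flagged; the step line is the one to read", {
  # concave corners force a low-accuracy regression line
  x <- c(0, 1, 2, seq(0.1, 1.9, length.out = 30))
  y <- c(0, 0.9, 1, rep(0.85, 30))
  df <- data.frame(y = y, x = x)
  ana <- run_nca(df, outcome = "y", conditions = "x", n_permutations = 50,
                 seed = 3)
  r <- ana$results
  expect_true(all(r$interpretable[r$ceiling == "ce_fdh"]))
  expect_false(any(r$interpretable[r$ceiling == "cr_fdh"]))
})

test_that("bottlenecks are emitted only for significant conditions", {
  set.seed(9)
  strong <- gen_ceiling_data(120, slope = 1, intercept = 0, seed = 10)
  null_y <- runif(120)
  df <- data.frame(y = strong$y, ceiling_x = strong$x, noise_x = null_y)
  ana <- run_nca(df, outcome = "y", conditions = c("ceiling_x", "noise_x"),
                 n_permutations = 300, seed = 6)
  r <- ana$results
  expect_true(all(r$significant[r$condition == "ceiling_x"]))
  sig_conditions <- names(ana$bottlenecks$all)
  expect_true("ceiling_x" %in% sig_conditions)
  insig <- unique(r$condition[!r$significant])
  for (cond in setdiff(insig, unique(r$condition[r$significant]))) {
    expect_false(cond %in% sig_conditions)
  }
})

test_that("reports are byte-identical across runs and serialize fully", {
  df <- gen_student_groups(seed = 20)
  d1 <- file.path(tempdir(), "rep1")
  d2 <- file.path(tempdir(), "rep2")
  for (d in c(d1, d2)) {
    ana <- run_nca(df, outcome = "gpa", conditions = "conscientiousness",
                   group = "setting", n_permutations = 100, seed = 44)
    write_nca_report(ana, d)
  }
  for (f in c("report.json", "table2.csv", "bottlenecks.csv",
              "preprocess.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  }
  rep <- jsonlite::fromJSON(file.path(d1, "report.json"))
  expect_equal(rep$config$seed, 44)
  expect_true(is.data.frame(rep$results))
  # full precision retained in JSON (values not rounded to 2 decimals)
  expect_false(all(rep$results$ES == round(rep$results$ES, 2)))
})

test_that("the CLI script runs end to end", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "nca.R", package = "necessity")
  skip_if(cli == "")
  csv <- tempfile(fileext = ".csv")
  out <- tempfile()
  write.csv(gen_student_like(student_profiles()$online, n = 80, seed = 12),
            csv, row.names = FALSE)
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = ":"))
  res <- system2("Rscript", c(cli, "run", "--input", csv, "--outcome", "gpa",
                              "--conditions", "study_time,conscientiousness",
                              "--permutations", "100", "--seed", "7",
                              "--out", out),
                 stdout = TRUE, stderr = TRUE, env = libs)
  expect_equal(attr(res, "status"), NULL)   # exit code 0
  expect_true(file.exists(file.path(out, "report.json")))

  sim <- tempfile(fileext = ".csv")
  res2 <- system2("Rscript", c(cli, "simulate", "null", "--n", "50",
                               "--seed", "1", "--out", sim),
                  stdout = TRUE, stderr = TRUE, env = libs)
  expect_equal(attr(res2, "status"), NULL)
  expect_equal(nrow(read.csv(sim)), 50)
})
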