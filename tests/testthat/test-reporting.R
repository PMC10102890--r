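make_synthetic_curve <- function(t, est, lo = est - 0.05, label = "CS_c/CS_g",
                                 delta = 5) {
  survode:::new_prognosis_curve(
    tibble::tibble(t = t, delta = delta, estimate = est,
                   variance = 0.001, se = sqrt(0.001), lo = lo, hi = est + 0.05,
                   defined = TRUE),
    label = label, delta = delta
  )
}

test_that("crossing times are read off with linear interpolation", {
  # linear rise 0.5 -> 1.0 over [0, 10]: level 0.75 crossed at t = 5
  tt <- seq(0, 10, by = 0.5)
  cv <- make_synthetic_curve(tt, 0.5 + 0.05 * tt)
  rep <- time_to_level(cv, levels = c(0.4, 0.75, 0.99))
  expect_equal(rep$status, c("achieved_at_zero", "achieved", "achieved"))
  expect_equal(rep$t_estimate, c(0, 5, 9.8))
  # pessimistic curve (0.05 lower) crosses later (level 0.75: at t = 6)
  expect_equal(rep$t_pessimistic[2], 6)
  expect_true(is.na(rep$t_pessimistic[3])) # lower band never reaches 0.99

  # a curve identically 1 achieves every level at zero
  cv1 <- make_synthetic_curve(tt, rep(1, length(tt)))
  rep1 <- time_to_level(cv1, levels = c(0.6, 0.9, 1))
  expect_true(all(rep1$status == "achieved_at_zero"))

  # a flat low curve never achieves a high level
  cv2 <- make_synthetic_curve(tt, rep(0.5, length(tt)))
  rep2 <- time_to_level(cv2, levels = 0.9)
  expect_equal(rep2$status, "never_achieved")
  expect_true(is.na(rep2$t_estimate))
})

test_that("crossing times are nondecreasing in the level for monotone curves", {
  tt <- seq(0, 15, by = 0.1)
  est <- 1 - 0.6 * exp(-0.2 * tt)
  cv <- make_synthetic_curve(tt, est)
  levels <- seq(0.45, 0.99, by = 0.01)
  rep <- time_to_level(cv, levels)
  tc <- rep$t_estimate[rep$status == "achieved"]
  expect_true(all(diff(tc) >= 0))
  # brute-force oracle on a dense grid
  dense_t <- seq(0, 15, by = 0.0005)
  dense <- stats::approx(tt, est, xout = dense_t)$y
  for (i in which(rep$status == "achieved")) {
    brute <- dense_t[which(dense >= levels[i])[1]]
    expect_lt(abs(rep$t_estimate[i] - brute), 0.001)
  }
})

test_that("report rendering follows the table conventions", {
  tt <- seq(0, 10, by = 0.5)
  cv <- make_synthetic_curve(tt, 0.5 + 0.05 * tt)
  rep <- time_to_level(cv, levels = c(0.4, 0.75, 2))
  cells <- format_crossing_report(rep)
  expect_equal(unname(cells[1]), "")             # achieved at t = 0
  expect_match(unname(cells[2]), "^5 \\(.*\\)$") # "est (pessimistic)"
  expect_equal(unname(cells[3]), "-")            # never achieved
})

test_that("non-monotone estimates warn and report the first crossing", {
  tt <- 0:6
  cv <- make_synthetic_curve(tt, c(0.5, 0.8, 0.6, 0.9, 0.85, 0.95, 1))
  expect_warning(rep <- time_to_level(cv, levels = 0.75), "monotone")
  expect_lt(rep$t_estimate, 1) # first crossing is in (0, 1)
})

test_that("run_estimate writes the expected toy curve files deterministically", {
  dir <- withr::local_tempdir()
  cf <- file.path(dir, "cohort.csv")
  write_cohort(toy_cohort(), cf)
  out1 <- file.path(dir, "out1")
  files <- run_estimate(cf, out1, parameters = "CS", delta = 2)
  expect_true(file.exists(files[["CS"]]))
  curve <- read_curve(files[["CS"]])
  row <- curve[curve$t == 1, ]
  expect_equal(row$estimate, 0.5)
  # rerunning yields byte-identical outputs
  out2 <- file.path(dir, "out2")
  files2 <- run_estimate(cf, out2, parameters = "CS", delta = 2)
  expect_identical(readLines(files[["CS"]]), readLines(files2[["CS"]]))
  # curve files round-trip to identical in-memory curves
  f3 <- file.path(dir, "roundtrip.csv")
  write_curve(curve, f3)
  expect_identical(readLines(files[["CS"]]), readLines(f3))
  expect_error(run_estimate(cf, out1, parameters = character(0)), "no parameters")
})

test_that("run_contrast writes contrast curves and a crossing report", {
  dir <- withr::local_tempdir()
  sp <- scenario(n = 300, lambda_cancer = 0.1, lambda_other = 0.05,
                 censoring_rate = 0.1, admin_censor_time = 12, seed = 31)
  cf <- file.path(dir, "cohort.csv")
  write_cohort(generate_cohort(sp), cf)
  tf <- file.path(dir, "rates.csv")
  write_ratetable(generate_ratetable("constant", list(lambda = 0.02),
                                     ages = 0:110, years = 1990:2045), tf)
  out <- file.path(dir, "out")
  files <- suppressWarnings(
    run_contrast(cf, tf, out, delta = 3, t_grid = c(0, 1, 2))
  )
  expect_setequal(names(files),
                  c("CS_ratio", "CS_difference", "RMRL_ratio",
                    "RMRL_difference", "report"))
  for (f in files) expect_true(file.exists(f))
  rat <- read_curve(files[["CS_ratio"]])
  expect_true(all(rat$estimate > 0 & rat$estimate <= 1.2))
  rep <- readr::read_csv(files[["report"]], show_col_types = FALSE)
  expect_named(rep, c("level", "t_estimate", "t_pessimistic", "status"))

  # a zero-rate table reduces contrasts to the cohort curves themselves
  tf0 <- file.path(dir, "rates0.csv")
  write_ratetable(generate_ratetable("constant", list(lambda = 0),
                                     ages = 0:110, years = 1990:2045), tf0)
  out0 <- file.path(dir, "out0")
  files0 <- suppressWarnings(
    run_contrast(cf, tf0, out0, delta = 3, t_grid = c(0, 1, 2))
  )
  rat0 <- read_curve(files0[["CS_ratio"]])
  cc <- prognosis_curves(read_cohort(cf), "CS", delta = 3, t_grid = c(0, 1, 2))
  expect_equal(rat0$estimate, cc$CS$estimate, tolerance = 1e-12)
})

test_that("the command-line interface runs end to end on a tiny scenario", {
  cli <- system.file("cli", "survode.R", package = "survode")
  skip_if(cli == "", "CLI script not installed")
  dir <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")
  st <- system2(rscript, c(cli, "simulate", "--n", "60", "--seed", "5",
                           "--out-dir", shQuote(dir)),
                stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  st2 <- system2(rscript, c(cli, "estimate", "--cohort",
                            shQuote(file.path(dir, "cohort.csv")),
                            "--params", "CS", "--delta", "3",
                            "--out-dir", shQuote(file.path(dir, "est"))),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "est", "curve_CS.csv")))
  expect_true(file.exists(file.path(dir, "est", "run_log.txt")))
})

test_that("tidiers and plots expose curves and paths as tidy objects", {
  coh <- random_cohort(80, 3)
  h <- nelson_aalen(coh)
  p <- solve_path(survival_system(), h)
  td <- generics::tidy(p)
  expect_named(td, c("time", "state", "estimate", "variance"))
  expect_equal(nrow(td), length(p$time))
  gl <- generics::glance(p)
  expect_equal(gl$n, 80)
  expect_true(gl$has_covariance)
  cs <- conditional_survival(p, max(h$time) / 4)
  expect_s3_class(ggplot2::autoplot(cs), "ggplot")
  expect_s3_class(ggplot2::autoplot(p), "ggplot")
  expect_equal(generics::glance(cs)$label, "CS_c")
})
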