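#' Estimate all cohort prognosis curves in one call
#'
#' Convenience pipeline from a cohort data frame to the cohort-internal
#' prognosis curves: fits the Nelson-Aalen hazards, solves the relevant
#' plug-in systems with covariances, and assembles the requested curves.
#'
#' @param cohort A cohort data frame.
#' @param parameters Character vector among `"CS"`, `"RMRL"`, `"CRMTL"`,
#'   `"risk"`, `"ratio"`, `"difference"`, `"proportion"`.
#' @param delta Horizon width in years (default 5).
#' @param horizon Solve horizon; defaults to the last event time.
#' @param t_grid Base times for the curves (default: event grid restricted
#'   to `[0, horizon - delta]`).
#' @param mesh_step Mesh for the time component feeding RMRL (years).
#' @param conf_level,ci_scale Passed to the curve constructors.
#' @return A named list of `prognosis_curve` tibbles.
#' @examples
#' coh <- generate_cohort(scenario(n = 400, seed = 7))
#' curves <- prognosis_curves(coh, c("CS", "risk"), delta = 5, t_grid = 0:2)
#' curves$CS
#' @export
prognosis_curves <- function(cohort, parameters = c("CS", "RMRL"), delta = 5,
                             horizon = NULL, t_grid = NULL, mesh_step = 0.01,
                             conf_level = 0.95, ci_scale = "plain") {
  cohort <- as_cohort(cohort)
  ok <- c("CS", "RMRL", "CRMTL", "risk", "ratio", "difference", "proportion")
  bad <- setdiff(parameters, ok)
  if (length(bad) > 0) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  if (length(parameters) == 0) stop("no parameters requested.", call. = FALSE)
  out <- list()
  if (any(parameters %in% c("CS"))) {
    haz <- nelson_aalen(cohort, "all")
    path <- solve_path(survival_system(), haz)
    out$CS <- conditional_survival(path, delta, t_grid, conf_level, ci_scale)
  }
  if (any(parameters %in% c("RMRL", "CRMTL"))) {
    haz <- nelson_aalen(cohort, "all")
    hz <- if (is.null(horizon)) {
      if (length(haz$time) > 0) max(haz$time) else stop(
        "cohort has no events; give `horizon` explicitly.", call. = FALSE)
    } else horizon
    haz_t <- augment_time_component(haz, mesh_step, hz)
    path <- solve_path(rmrl_system(), haz_t)
    rm_curve <- rmrl(path, delta, t_grid, conf_level, ci_scale)
    if ("RMRL" %in% parameters) out$RMRL <- rm_curve
    if ("CRMTL" %in% parameters) out$CRMTL <- crmtl(rm_curve)
  }
  cause_params <- intersect(parameters, c("risk", "ratio", "difference", "proportion"))
  if (length(cause_params) > 0) {
    haz <- nelson_aalen(cohort, c(1, 2))
    path <- solve_path(cif_system(), haz)
    for (p in cause_params) {
      out[[p]] <- cause_specific_curves(path, delta, p, t_grid,
                                        conf_level, ci_scale)
    }
  }
  out[parameters]
}

#' Time until a desired prognosis level is reached
#'
#' For each level `delta_level` the report gives the first base time at
#' which the curve's point estimate reaches the level (linear
#' interpolation between adjacent grid points), and the same reading off
#' the lower 95% confidence curve as a pessimistic ("95th percentile")
#' crossing time: on a rising curve the lower band crosses later.
#' Statuses follow the conventions of registry prognosis tables:
#' `achieved_at_zero` when the curve already starts at or above the level,
#' `achieved` with a time pair otherwise, `never_achieved` when the level
#' is not reached within follow-up.  A non-monotone estimate still reports
#' the first crossing, with a warning.
#'
#' @param curve A `prognosis_curve`.
#' @param levels Prognosis levels in `(0, 1]` (fractions; default the
#'   conventional `c(0.6, 0.7, 0.8, 0.9, 0.95, 1)`).
#' @return A `crossing_report` tibble: `level`, `t_estimate`,
#'   `t_pessimistic`, `status`.
#' @export
time_to_level <- function(curve, levels = c(0.6, 0.7, 0.8, 0.9, 0.95, 1)) {
  stopifnot(inherits(curve, "prognosis_curve"))
  if (any(levels <= 0)) stop("`levels` must be positive fractions.", call. = FALSE)
  keep <- curve$defined & is.finite(curve$estimate)
  if (any(!keep)) {
    warning("skipping ", sum(!keep), " undefined/non-finite curve point(s).",
            call. = FALSE)
  }
  tt <- curve$t[keep]
  est <- curve$estimate[keep]
  lo <- curve$lo[keep]
  if (length(tt) == 0) stop("curve has no defined points.", call. = FALSE)
  if (any(diff(est) < -1e-12)) {
    warning("estimated curve is not monotone; reporting first crossings.",
            call. = FALSE)
  }
  first_crossing <- function(y, level) {
    if (y[1] >= level) return(0)
    idx <- which(y >= level)
    if (length(idx) == 0) return(NA_real_)
    i <- idx[1]
    # linear interpolation on [t_{i-1}, t_i]
    t0 <- tt[i - 1]; t1 <- tt[i]; y0 <- y[i - 1]; y1 <- y[i]
    if (y1 == y0) t1 else t0 + (level - y0) / (y1 - y0) * (t1 - t0)
  }
  rows <- purrr::map_dfr(levels, function(lv) {
    te <- first_crossing(est, lv)
    tp <- first_crossing(lo, lv)
    status <- if (!is.na(te) && te == 0) "achieved_at_zero"
      else if (is.na(te)) "never_achieved" else "achieved"
    tibble::tibble(level = lv, t_estimate = te, t_pessimistic = tp,
                   status = status)
  })
  class(rows) <- c("crossing_report", class(rows))
  attr(rows, "label") <- attr(curve, "label")
  rows
}

#' Render a crossing report in registry-table conventions
#'
#' One cell per level: empty when the prognosis holds at diagnosis
#' (`t = 0`), `"est (pessimistic)"` when reached later, and `"-"` when
#' never reached within follow-up.
#'
#' @param report A `crossing_report` from [time_to_level()].
#' @param digits Rounding for displayed times.
#' @return A named character vector, one cell per level.
#' @export
format_crossing_report <- function(report, digits = 1) {
  stopifnot(inherits(report, "crossing_report"))
  cells <- vapply(seq_len(nrow(report)), function(i) {
    switch(report$status[i],
      achieved_at_zero = "",
      never_achieved = "-",
      achieved = {
        pe <- report$t_pessimistic[i]
        pe_txt <- if (is.na(pe)) "-" else format(round(pe, digits))
        paste0(format(round(report$t_estimate[i], digits)), " (", pe_txt, ")")
      }
    )
  }, character(1))
  stats::setNames(cells, paste0("delta=", report$level))
}

#' Write a crossing report to delimited text
#'
#' @param report A `crossing_report`.
#' @param file Output path.
#' @param delim Field delimiter.
#' @return `file`, invisibly.
#' @export
write_crossing_report <- function(report, file, delim = ",") {
  readr::write_delim(tibble::as_tibble(report), file, delim = delim)
  invisible(file)
}

#' Run the cohort estimation pipeline on files
#'
#' Reads a cohort file, computes the requested prognosis curves and writes
#' one delimited curve file per parameter (named `curve_<parameter>.csv`)
#' plus a plain-text run log recording the configuration, event counts and
#' any undefined regions.  Deterministic: rerunning on identical input
#' reproduces identical bytes.
#'
#' @param cohort_file Path to a cohort file (see [read_cohort()]).
#' @param out_dir Output directory (created if needed).
#' @param parameters,delta,horizon,t_grid,mesh_step,conf_level,ci_scale
#'   Passed to [prognosis_curves()].
#' @param delim Field delimiter for inputs and outputs.
#' @return Invisibly, the named vector of files written.
#' @export
run_estimate <- function(cohort_file, out_dir, parameters = c("CS", "RMRL"),
                         delta = 5, horizon = NULL, t_grid = NULL,
                         mesh_step = 0.01, conf_level = 0.95,
                         ci_scale = "plain", delim = ",") {
  if (length(parameters) == 0) {
    stop("no parameters requested; nothing to do.", call. = FALSE)
  }
  cohort <- read_cohort(cohort_file, delim)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  curves <- prognosis_curves(cohort, parameters, delta, horizon, t_grid,
                             mesh_step, conf_level, ci_scale)
  files <- character(0)
  for (p in names(curves)) {
    f <- file.path(out_dir, paste0("curve_", p, ".csv"))
    write_curve(curves[[p]], f, delim)
    files[p] <- f
  }
  log_lines <- c(
    "survode run_estimate",
    paste0("cohort_file: ", basename(cohort_file)),
    paste0("n: ", nrow(cohort)),
    paste0("events_cancer: ", sum(cohort$event == 1)),
    paste0("events_other: ", sum(cohort$event == 2)),
    paste0("censored: ", sum(cohort$event == 0)),
    paste0("parameters: ", paste(parameters, collapse = ",")),
    paste0("delta: ", delta),
    paste0("mesh_step: ", mesh_step),
    paste0("ci_scale: ", ci_scale),
    paste0("undefined_points: ",
           paste(vapply(names(curves), function(p) {
             paste0(p, "=", sum(!curves[[p]]$defined))
           }, character(1)), collapse = " "))
  )
  logf <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, logf)
  files["log"] <- logf
  invisible(files)
}

#' Run the population-contrast pipeline on files
#'
#' Reads a cohort and a rate table, computes the conditional survival and
#' RMRL contrasts (ratio and difference) between the cohort and its
#' Ederer I matched population, writes one curve file per contrast, and a
#' crossing-time report read off the conditional-survival ratio curve.
#'
#' @param cohort_file,ratetable_file Input paths.
#' @param out_dir Output directory.
#' @param delta Horizon width (default 5).
#' @param horizon Solve horizon; defaults to the last event time.
#' @param t_grid Base times (default: regular grid of step 0.5 over
#'   `[0, horizon - delta]`).
#' @param levels Prognosis levels for the crossing report.
#' @param mesh_step,conf_level,ci_scale,delim As in [run_estimate()].
#' @return Invisibly, the named vector of files written.
#' @export
run_contrast <- function(cohort_file, ratetable_file, out_dir, delta = 5,
                         horizon = NULL, t_grid = NULL,
                         levels = c(0.6, 0.7, 0.8, 0.9, 0.95, 1),
                         mesh_step = 0.01, conf_level = 0.95,
                         ci_scale = "plain", delim = ",") {
  cohort <- read_cohort(cohort_file, delim)
  table <- read_ratetable(ratetable_file, delim)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ev <- cohort$time[cohort$event > 0]
  hz <- horizon %||% if (length(ev) > 0) max(ev) else
    stop("cohort has no events; give `horizon` explicitly.", call. = FALSE)
  if (is.null(t_grid)) t_grid <- seq(0, max(hz - delta, 0), by = 0.5)
  cc <- prognosis_curves(cohort, c("CS", "RMRL"), delta, hz, t_grid,
                         mesh_step, conf_level, ci_scale)
  es <- ederer1(cohort, table, sort(unique(c(t_grid, t_grid + delta))))
  pc <- population_curves(es, delta, t_grid)
  curves <- list(
    CS_ratio = contrast(cc$CS, pc$cs, "ratio", conf_level),
    CS_difference = contrast(cc$CS, pc$cs, "difference", conf_level),
    RMRL_ratio = contrast(cc$RMRL, pc$rmrl, "ratio", conf_level),
    RMRL_difference = contrast(cc$RMRL, pc$rmrl, "difference", conf_level)
  )
  files <- character(0)
  for (p in names(curves)) {
    f <- file.path(out_dir, paste0("curve_", p, ".csv"))
    write_curve(curves[[p]], f, delim)
    files[p] <- f
  }
  report <- time_to_level(curves$CS_ratio, levels)
  repf <- file.path(out_dir, "crossing_report.csv")
  write_crossing_report(report, repf, delim)
  files["report"] <- repf
  invisible(files)
}
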