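#' Construct a population mortality rate table
#'
#' Yearly all-cause mortality hazards (deaths per person-year) on a grid of
#' attained age x calendar year x sex.  Stored as a long tibble with an
#' internal lookup array.
#'
#' @param df Data frame with columns `age` (integer years), `year`
#'   (integer calendar year), `sex` (`"F"`/`"M"`), `rate` (nonnegative
#'   hazard per person-year).  Every (age, year, sex) cell in the crossed
#'   contiguous ranges must be present.
#' @return A `rate_table` object.
#' @export
rate_table <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("age", "year", "sex", "rate")
  if (!all(need %in% names(df))) {
    stop("rate table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(df$rate < 0)) stop("rates must be nonnegative.", call. = FALSE)
  ages <- sort(unique(as.integer(df$age)))
  years <- sort(unique(as.integer(df$year)))
  sexes <- sort(unique(as.character(df$sex)))
  if (!all(sexes %in% c("F", "M"))) stop("`sex` must be \"F\"/\"M\".", call. = FALSE)
  if (!identical(ages, seq(min(ages), max(ages))) ||
      !identical(years, seq(min(years), max(years)))) {
    stop("age and year axes must be contiguous integer ranges.", call. = FALSE)
  }
  arr <- array(NA_real_, dim = c(length(ages), length(years), length(sexes)),
               dimnames = list(ages, years, sexes))
  arr[cbind(match(df$age, ages), match(df$year, years), match(df$sex, sexes))] <- df$rate
  if (any(is.na(arr))) stop("rate table has missing cells.", call. = FALSE)
  structure(list(ages = ages, years = years, sexes = sexes, rate = arr,
                 data = df[order(df$sex, df$age, df$year), need]),
            class = "rate_table")
}

#' @export
print.rate_table <- function(x, ...) {
  cat("<rate_table> ages ", min(x$ages), "-", max(x$ages), ", years ",
      min(x$years), "-", max(x$years), ", sexes ",
      paste(x$sexes, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Read a rate table from delimited text
#'
#' Header columns `age`, `year`, `sex`, `rate` with rate in deaths per
#' person-year.  Standard relative-survival rate-table layouts (age x year
#' matrices per sex with yearly death *probabilities* q) map onto this
#' schema by pivoting to long form and converting probabilities to hazards
#' via `rate = -log(1 - q)`; daily probabilities are first annualised.
#'
#' @param file Path.
#' @param delim Field delimiter.
#' @return A `rate_table`.
#' @export
read_ratetable <- function(file, delim = ",") {
  rate_table(readr::read_delim(file, delim = delim, show_col_types = FALSE,
                               progress = FALSE))
}

#' Write a rate table to delimited text
#'
#' @param table A `rate_table`.
#' @param file Output path.
#' @param delim Field delimiter.
#' @return `file`, invisibly.
#' @export
write_ratetable <- function(table, file, delim = ",") {
  stopifnot(inherits(table, "rate_table"))
  readr::write_delim(table$data, file, delim = delim)
  invisible(file)
}

#' @keywords internal
#' Piecewise-constant population hazard along one subject's trajectory:
#' cumulative hazard and exact integral of survival at the requested times.
#' Returns list(surv, rsurv) at `times`.
subject_expected <- function(age_dx, year_dx, sex, table, times,
                             carry_forward = TRUE, warn_env = NULL) {
  tmax <- max(times)
  # cell boundaries: age crossings and calendar-year crossings
  a_off <- ceiling(age_dx + 1e-12) - age_dx
  y_off <- ceiling(year_dx + 1e-12) - year_dx
  brks <- sort(unique(c(0, times,
                        if (a_off <= tmax) seq(a_off, tmax, by = 1),
                        if (y_off <= tmax) seq(y_off, tmax, by = 1))))
  brks <- brks[brks >= 0 & brks <= tmax]
  if (brks[length(brks)] < tmax) brks <- c(brks, tmax)
  lo <- brks[-length(brks)]
  hi <- brks[-1]
  mid <- (lo + hi) / 2
  age_cell <- floor(age_dx + mid)
  year_cell <- floor(year_dx + mid)
  oob <- age_cell < min(table$ages) | age_cell > max(table$ages) |
    year_cell < min(table$years) | year_cell > max(table$years)
  if (any(oob)) {
    if (!carry_forward) {
      i <- which(oob)[1]
      stop("rate lookup outside table bounds at (age ", age_cell[i],
           ", year ", year_cell[i], ", sex ", sex, ").", call. = FALSE)
    }
    if (!is.null(warn_env)) warn_env$clamped <- TRUE
    age_cell <- pmin(pmax(age_cell, min(table$ages)), max(table$ages))
    year_cell <- pmin(pmax(year_cell, min(table$years)), max(table$years))
  }
  lam <- table$rate[cbind(age_cell - min(table$ages) + 1,
                          year_cell - min(table$years) + 1,
                          match(sex, table$sexes))]
  len <- hi - lo
  Lam <- c(0, cumsum(lam * len))          # cumulative hazard at brks
  S <- exp(-Lam)
  # exact integral of exp(-Lambda(u)) over each cell
  seg <- ifelse(lam > 0, (S[-length(S)] - S[-1]) / lam, len * S[-length(S)])
  Rcum <- c(0, cumsum(seg))
  idx <- match(times, brks)
  list(surv = S[idx], rsurv = Rcum[idx])
}

#' Ederer I expected survival for a cohort
#'
#' For each subject, a matched general-population survival curve
#' \eqn{S_i^*(t) = \exp(-\int_0^t \lambda_{pop}(a_i+u,\, y_i+u,\,
#' sex_i)\,du)} is built from the rate table, with the hazard piecewise
#' constant on attained-age x calendar-year unit cells (the applicable
#' cell is the floor of the attained age and year).  The Ederer I expected
#' survival is the cohort average \eqn{S_g(t) = n^{-1}\sum_i S_i^*(t)};
#' its running integral is accumulated exactly cell by cell.
#'
#' Trajectories leaving the table (very old attained ages, years beyond
#' the last tabulated one) carry the boundary cell's rate forward, with a
#' single warning; set `carry_forward = FALSE` to make this an error.
#'
#' @param cohort A cohort with columns `age_dx`, `sex`, `year_dx`.
#' @param table A `rate_table`.
#' @param times Evaluation grid (years since diagnosis, nonnegative).
#' @param carry_forward Clamp out-of-range lookups to the boundary cell?
#' @return An `expected_survival` object: `grid`, `s_exp` (\eqn{S_g}) and
#'   `r_exp` (\eqn{\int_0^t S_g}).
#' @export
ederer1 <- function(cohort, table, times, carry_forward = TRUE) {
  cohort <- as_cohort(cohort)
  stopifnot(inherits(table, "rate_table"))
  need <- c("age_dx", "sex", "year_dx")
  if (!all(need %in% names(cohort))) {
    stop("Ederer I needs demographic columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  times <- sort(unique(c(0, as.numeric(times))))
  if (any(times < 0)) stop("`times` must be nonnegative.", call. = FALSE)
  warn_env <- new.env()
  warn_env$clamped <- FALSE
  n <- nrow(cohort)
  s_sum <- r_sum <- numeric(length(times))
  for (i in seq_len(n)) {
    ei <- subject_expected(cohort$age_dx[i], cohort$year_dx[i], cohort$sex[i],
                           table, times, carry_forward, warn_env)
    s_sum <- s_sum + ei$surv
    r_sum <- r_sum + ei$rsurv
  }
  if (warn_env$clamped) {
    warning("some attained (age, year) cells fell outside the rate table; ",
            "boundary rates were carried forward.", call. = FALSE)
  }
  structure(list(grid = times, s_exp = s_sum / n, r_exp = r_sum / n, n = n),
            class = "expected_survival")
}

#' @export
print.expected_survival <- function(x, ...) {
  cat("<expected_survival> Ederer I over [0, ", max(x$grid), "] from n = ",
      x$n, " matched subjects\n", sep = "")
  invisible(x)
}

#' @keywords internal
lookup_exp <- function(exp_surv, t, what = c("s", "r")) {
  what <- match.arg(what)
  i <- match(TRUE, abs(exp_surv$grid - t) < 1e-9)
  if (is.na(i)) {
    stop("time ", t, " is not on the expected-survival grid; include it in ",
         "`times` when calling ederer1().", call. = FALSE)
  }
  if (what == "s") exp_surv$s_exp[i] else exp_surv$r_exp[i]
}

#' Conditional population prognosis curves
#'
#' The population analogues of conditional Delta-year survival and
#' restricted mean residual lifetime, computed from the Ederer I marginal
#' expected survival: \eqn{CS_g(t+\Delta\mid t) = S_g(t+\Delta)/S_g(t)}
#' and \eqn{RMRL_g(t+\Delta\mid t) = (r(t+\Delta) - r(t))/S_g(t)} with
#' \eqn{r = \int S_g}.  Rate tables are treated as known population
#' quantities, so both curves carry zero sampling variance.
#'
#' @param exp_surv An `expected_survival` whose grid contains every `t`
#'   and `t + delta` requested.
#' @param delta Horizon width in years.
#' @param t_grid Base times (default: all grid times `t` with `t + delta`
#'   on the grid).
#' @return A list with `prognosis_curve` elements `cs` (label `CS_g`) and
#'   `rmrl` (label `RMRL_g`).
#' @export
population_curves <- function(exp_surv, delta, t_grid = NULL) {
  stopifnot(inherits(exp_surv, "expected_survival"))
  g <- exp_surv$grid
  if (is.null(t_grid)) {
    t_grid <- g[vapply(g, function(t) any(abs(g - (t + delta)) < 1e-9), logical(1))]
  }
  m <- length(t_grid)
  cs <- rm <- rep(NA_real_, m)
  defined <- rep(TRUE, m)
  for (i in seq_len(m)) {
    St <- lookup_exp(exp_surv, t_grid[i], "s")
    Std <- lookup_exp(exp_surv, t_grid[i] + delta, "s")
    if (St == 0) { defined[i] <- FALSE; next }
    cs[i] <- Std / St
    rm[i] <- (lookup_exp(exp_surv, t_grid[i] + delta, "r") -
                lookup_exp(exp_surv, t_grid[i], "r")) / St
  }
  zero_var_curve <- function(est, label, delta) {
    new_prognosis_curve(
      tibble::tibble(t = t_grid, delta = delta, estimate = est,
                     variance = 0, se = 0, lo = est, hi = est,
                     defined = defined),
      label = label, delta = delta
    )
  }
  list(cs = zero_var_curve(cs, "CS_g", delta),
       rmrl = zero_var_curve(rm, "RMRL_g", delta))
}

#' Contrast a cohort curve against its population analogue
#'
#' Pointwise ratio or difference of a cohort prognosis curve and the
#' matched-population curve on a shared base-time grid.  The population
#' curve is treated as a known constant, so the contrast inherits only the
#' cohort curve's sampling variance: `var(ratio) = var_c / pop^2`,
#' `var(difference) = var_c`.
#'
#' @param cohort_curve A `prognosis_curve` (e.g. `CS_c` or `RMRL_c`).
#' @param pop_curve The matching population `prognosis_curve` (`CS_g` or
#'   `RMRL_g`) on the same `t` grid and `delta`.
#' @param scale `"ratio"` or `"difference"`.
#' @param conf_level Confidence level for the Wald interval.
#' @return A `prognosis_curve` labelled e.g. `CS_c/CS_g` or
#'   `RMRL_c - RMRL_g`.
#' @export
contrast <- function(cohort_curve, pop_curve, scale = c("ratio", "difference"),
                     conf_level = 0.95) {
  scale <- match.arg(scale)
  stopifnot(inherits(cohort_curve, "prognosis_curve"),
            inherits(pop_curve, "prognosis_curve"))
  if (!isTRUE(all.equal(attr(cohort_curve, "delta"), attr(pop_curve, "delta")))) {
    stop("curves have different Delta.", call. = FALSE)
  }
  if (nrow(cohort_curve) != nrow(pop_curve) ||
      max(abs(cohort_curve$t - pop_curve$t)) > 1e-9) {
    stop("curves must share the same base-time grid.", call. = FALSE)
  }
  delta <- attr(cohort_curve, "delta")
  g <- pop_curve$estimate
  est_c <- cohort_curve$estimate
  var_c <- cohort_curve$variance
  defined <- cohort_curve$defined & pop_curve$defined
  if (scale == "ratio") {
    defined <- defined & is.finite(g) & g != 0
    est <- ifelse(defined, est_c / g, NA_real_)
    v <- ifelse(defined, var_c / g^2, NA_real_)
    range <- c(0, Inf)
  } else {
    est <- ifelse(defined, est_c - g, NA_real_)
    v <- ifelse(defined, var_c, NA_real_)
    rng_w <- if (grepl("RMRL", attr(cohort_curve, "label"))) delta else 1
    range <- c(-rng_w, rng_w)
  }
  se <- sqrt(v)
  ci <- wald_ci(est, se, range, conf_level, "plain")
  lab <- paste0(attr(cohort_curve, "label"),
                if (scale == "ratio") "/" else " - ",
                attr(pop_curve, "label"))
  new_prognosis_curve(
    tibble::tibble(t = cohort_curve$t, delta = delta, estimate = est,
                   variance = v, se = se, lo = ci$lo, hi = ci$hi,
                   defined = defined),
    label = lab, delta = delta
  )
}
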