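#' Piecewise-constant hazard specification
#'
#' A constant hazard is a single nonnegative number; a piecewise-constant
#' hazard is `pw_hazard(rates, breaks)` with `length(breaks) ==
#' length(rates) - 1` change-points.
#'
#' @param rates Nonnegative hazard rates per year, one per piece.
#' @param breaks Strictly increasing change-points (years); the first
#'   piece runs over `[0, breaks[1])`.
#' @return A `pw_hazard` object.
#' @export
pw_hazard <- function(rates, breaks = numeric(0)) {
  rates <- as.numeric(rates)
  breaks <- as.numeric(breaks)
  stopifnot(length(rates) == length(breaks) + 1, all(rates >= 0),
            all(breaks > 0), !is.unsorted(breaks, strictly = TRUE))
  structure(list(rates = rates, breaks = breaks), class = "pw_hazard")
}

#' @keywords internal
as_pw <- function(x) {
  if (inherits(x, "pw_hazard")) return(x)
  stopifnot(is.numeric(x), length(x) == 1, x >= 0)
  pw_hazard(x)
}

#' @keywords internal
#' Cumulative hazard of a piecewise-constant hazard at times t (vectorized).
pw_cumhaz <- function(pw, t) {
  edges <- c(0, pw$breaks, Inf)
  vapply(t, function(ti) {
    lo <- edges[-length(edges)]
    hi <- pmin(edges[-1], ti)
    sum(pw$rates * pmax(hi - lo, 0))
  }, numeric(1))
}

#' @keywords internal
#' Hazard value at times t.
pw_rate <- function(pw, t) {
  pw$rates[findInterval(t, c(0, pw$breaks))]
}

#' @keywords internal
#' Robust sampler for a piecewise-constant hazard: inverse transform on
#' Exp(1) draws, piece by piece.
pw_sample <- function(pw, u) {
  e <- -log(u)
  edges <- c(0, pw$breaks)
  k <- length(pw$rates)
  cum <- pw_cumhaz(pw, c(pw$breaks, Inf))
  cum_lo <- c(0, cum[-length(cum)])
  out <- rep(Inf, length(e))
  for (i in seq_len(k)) {
    hi <- if (i < k) cum[i] else Inf
    sel <- e > cum_lo[i] & e <= hi
    if (any(sel)) {
      if (pw$rates[i] > 0) {
        out[sel] <- edges[i] + (e[sel] - cum_lo[i]) / pw$rates[i]
      } # rate 0 with e inside the piece cannot happen (cum flat)
    }
  }
  out
}

#' Define a synthetic cohort scenario
#'
#' Latent cause-specific death times are piecewise-exponential with the
#' stated cause-specific hazards, censoring is independent with constant
#' hazard plus administrative censoring at a fixed time, and demographics
#' are drawn independently of survival.  Defaults emulate a registry-style
#' cohort of younger patients (ages 30-59 at diagnosis, diagnoses
#' 2001-2018, administrative censoring 15 years after diagnosis).
#'
#' @param n Cohort size.
#' @param lambda_cancer,lambda_other Cause-specific hazards per year:
#'   scalars or [pw_hazard()] objects.
#' @param censoring_rate Constant hazard of independent censoring.
#' @param admin_censor_time Administrative censoring time in years.
#' @param age_range Uniform range for age at diagnosis.
#' @param year_range Integer range for calendar year of diagnosis.
#' @param prob_male Probability of sex `"M"`.
#' @param seed Integer seed; generation is reproducible.
#' @return A `scenario` object.
#' @export
scenario <- function(n, lambda_cancer = 0.1, lambda_other = 0.05,
                     censoring_rate = 0.1, admin_censor_time = 15,
                     age_range = c(30, 60), year_range = c(2001L, 2018L),
                     prob_male = 0.5, seed = 1L) {
  stopifnot(n >= 1, censoring_rate >= 0, admin_censor_time > 0)
  structure(
    list(n = as.integer(n), lambda_cancer = as_pw(lambda_cancer),
         lambda_other = as_pw(lambda_other),
         censoring_rate = censoring_rate,
         admin_censor_time = admin_censor_time,
         age_range = age_range, year_range = as.integer(year_range),
         prob_male = prob_male, seed = as.integer(seed)),
    class = "scenario"
  )
}

#' Generate a synthetic cohort from a scenario
#'
#' Observed time is the minimum of the two latent death times, the random
#' censoring time and the administrative censoring time; the event code
#' records which was attained, with exact ties broken deterministically
#' toward the smaller event code (cancer before other causes before
#' censoring).
#'
#' @param spec A [scenario()].
#' @return A cohort tibble with columns `id`, `time`, `event`, `age_dx`,
#'   `sex`, `year_dx`; identical seeds yield identical cohorts.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "scenario"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$n
  t1 <- pw_sample(spec$lambda_cancer, stats::runif(n))
  t2 <- pw_sample(spec$lambda_other, stats::runif(n))
  cens <- if (spec$censoring_rate > 0) stats::rexp(n, spec$censoring_rate) else rep(Inf, n)
  cens <- pmin(cens, spec$admin_censor_time)
  time <- pmin(t1, t2, cens)
  event <- ifelse(t1 <= time, 1L, ifelse(t2 <= time, 2L, 0L))
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  sex <- ifelse(stats::runif(n) < spec$prob_male, "M", "F")
  year <- sample(seq(spec$year_range[1], spec$year_range[2]), n, replace = TRUE)
  as_cohort(tibble::tibble(
    id = seq_len(n), time = time, event = event,
    age_dx = age, sex = sex, year_dx = year
  ))
}

#' @keywords internal
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' @keywords internal
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Closed-form truth of a prognosis parameter under a scenario
#'
#' Analytic values of the prognosis parameters under the scenario's
#' (piecewise-)constant cause-specific hazards, by exact piecewise
#' composition of \eqn{S}, \eqn{C^c}, \eqn{C^o} and \eqn{R = \int S}.
#' Under constant hazards these reduce to the familiar forms, e.g.
#' \eqn{CS = e^{-(\lambda_1+\lambda_2)\Delta}},
#' \eqn{RMRL = (1 - e^{-\lambda\Delta})/\lambda},
#' ratio \eqn{= \lambda_1/\lambda_2}, proportion
#' \eqn{= \lambda_1/(\lambda_1+\lambda_2)}.
#'
#' @param spec A [scenario()].
#' @param parameter One of `"CS"`, `"RMRL"`, `"CRMTL"`, `"risk"`,
#'   `"ratio"`, `"difference"`, `"proportion"`.
#' @param t Base time.
#' @param delta Horizon width.
#' @return The analytic parameter value.
#' @export
scenario_truth <- function(spec, parameter = c("CS", "RMRL", "CRMTL", "risk",
                                               "ratio", "difference", "proportion"),
                           t, delta) {
  stopifnot(inherits(spec, "scenario"))
  parameter <- match.arg(parameter)
  l1 <- spec$lambda_cancer
  l2 <- spec$lambda_other
  Surv <- function(u) exp(-(pw_cumhaz(l1, u) + pw_cumhaz(l2, u)))
  # exact piecewise integrals of S and of the cause-1/2 subdensities
  pieces <- function(a, b) sort(unique(c(a, b, l1$breaks[l1$breaks > a & l1$breaks < b],
                                         l2$breaks[l2$breaks > a & l2$breaks < b])))
  integrate_S <- function(a, b) {
    if (b <= a) return(0)
    ed <- pieces(a, b)
    tot <- 0
    for (i in seq_len(length(ed) - 1)) {
      lo <- ed[i]; hi <- ed[i + 1]
      lam <- pw_rate(l1, lo) + pw_rate(l2, lo)
      tot <- tot + if (lam > 0) (Surv(lo) - Surv(hi)) / lam else (hi - lo) * Surv(lo)
    }
    tot
  }
  integrate_sub <- function(a, b, cause) {
    if (b <= a) return(0)
    ed <- pieces(a, b)
    tot <- 0
    for (i in seq_len(length(ed) - 1)) {
      lo <- ed[i]; hi <- ed[i + 1]
      r1 <- pw_rate(l1, lo); r2 <- pw_rate(l2, lo)
      lam <- r1 + r2
      rc <- if (cause == 1) r1 else r2
      tot <- tot + if (lam > 0) rc / lam * (Surv(lo) - Surv(hi)) else 0
    }
    tot
  }
  St <- Surv(t); Std <- Surv(t + delta)
  switch(parameter,
    CS = Std / St,
    RMRL = integrate_S(t, t + delta) / St,
    CRMTL = delta - integrate_S(t, t + delta) / St,
    risk = integrate_sub(t, t + delta, 1) / St,
    ratio = integrate_sub(t, t + delta, 1) / integrate_sub(t, t + delta, 2),
    difference = (integrate_sub(t, t + delta, 1) - integrate_sub(t, t + delta, 2)) / St,
    proportion = integrate_sub(t, t + delta, 1) / (St - Std)
  )
}

#' Generate a synthetic population rate table
#'
#' @param kind `"constant"` (every cell the same rate) or `"gompertz"`
#'   (rate `a * exp(b * age)`).
#' @param params For `"constant"`: `list(lambda = )`; for `"gompertz"`:
#'   `list(a = , b = )`.
#' @param ages,years Contiguous integer axes.
#' @param sex_multiplier Multiplier applied to male cells (default 1).
#' @return A `rate_table`; deterministic.
#' @export
generate_ratetable <- function(kind = c("constant", "gompertz"), params,
                               ages = 0:110, years = 1990:2030,
                               sex_multiplier = 1) {
  kind <- match.arg(kind)
  grid <- tidyr::expand_grid(age = ages, year = years, sex = c("F", "M"))
  base <- switch(kind,
    constant = rep(params$lambda, nrow(grid)),
    gompertz = params$a * exp(params$b * grid$age)
  )
  grid$rate <- base * ifelse(grid$sex == "M", sex_multiplier, 1)
  rate_table(grid)
}
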