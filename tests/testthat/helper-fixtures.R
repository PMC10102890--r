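# Shared fixtures: everything is generated in code, no stored data.

# The worked 4-subject cohort: deaths at 1 (cancer), 3 (other), 4 (cancer),
# censoring at 2.  All hand-computed expectations in the tests derive from it.
toy_cohort <- function() {
  tibble::tibble(time = c(1, 2, 3, 4), event = c(1L, 0L, 2L, 1L))
}

# Random right-censored competing-risks cohort with continuous (tie-free)
# times unless `round_digits` is given.
random_cohort <- function(n, seed, rate = 0.3, censor_rate = 0.15,
                          p_cause1 = 0.6, round_digits = NULL) {
  withr::with_seed(seed, {
    tt <- stats::rexp(n, rate)
    cc <- stats::rexp(n, censor_rate)
    time <- pmin(tt, cc)
    dead <- tt <= cc
    cause <- ifelse(stats::runif(n) < p_cause1, 1L, 2L)
    if (!is.null(round_digits)) time <- round(time, round_digits)
    tibble::tibble(time = time, event = ifelse(dead, cause, 0L))
  })
}

# Independent Kaplan-Meier / Nelson-Aalen / Greenwood oracle.
km_oracle <- function(cohort, times) {
  fit <- survival::survfit(survival::Surv(time, event > 0) ~ 1,
                           data = cohort, ctype = 1)
  s <- summary(fit, times = times, extend = TRUE)
  list(surv = s$surv, cumhaz = s$cumhaz, std_err = s$std.err)
}

# Bare single-component ("all") step hazard at given jump times/increments,
# with a nominal risk set, for grid-plumbing tests.
new_test_hazard <- function(times, incs, n = 10) {
  survode:::new_step_hazard(
    times, matrix(incs, ncol = 1, dimnames = list(NULL, "all")),
    at_risk = seq(n, by = -1, length.out = length(times)), n = n
  )
}

expect_curve_defined <- function(curve) {
  expect_true(all(curve$defined))
  expect_true(all(is.finite(curve$estimate)))
}
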