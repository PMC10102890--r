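test_that("the survival plug-in reproduces Kaplan-Meier exactly, ties included", {
  skip_if_not_installed("survival")
  # toy cohort, hand values
  p <- solve_plugin(survival_system(), nelson_aalen(toy_cohort()))
  expect_equal(p$x[, 1], c(1, 0.75, 0.375, 0))
  # random cohorts, against the independent product-limit implementation
  for (seed in 1:15) {
    coh <- random_cohort(30 + seed * 10, seed,
                         round_digits = if (seed %% 2 == 0) 1 else NULL)
    h <- nelson_aalen(coh)
    if (length(h$time) == 0) next
    p <- solve_plugin(survival_system(), h)
    o <- km_oracle(coh, h$time)
    expect_lt(max(abs(p$x[-1, 1] - o$surv)), 1e-12)
  }
})

test_that("a zero hazard leaves state and covariance at their initial values", {
  h <- nelson_aalen(tibble::tibble(time = c(2, 5), event = c(0L, 0L)))
  p <- solve_path(survival_system(), h)
  expect_equal(nrow(p$x), 1)
  expect_equal(unname(p$x[1, 1]), 1)
  expect_equal(p$v[1, 1, 1], 0)
  expect_equal(eval_state(p, 0)[1], 1)
})

test_that("quadratic covariation follows the per-jump product rule", {
  # tie-free single component: [B](t) = sum (dA)^2 = int 1/Y dA
  coh <- random_cohort(60, 3)
  h <- nelson_aalen(coh)
  B <- quadratic_covariation(h)
  expect_equal(drop(B[1, 1, ]), h$inc[, 1]^2)
  expect_equal(sum(B[1, 1, ]), sum(h$inc[, 1] / h$at_risk), tolerance = 1e-14)

  # two cause components never jump together on tie-free data
  hc <- nelson_aalen(coh, causes = c(1, 2))
  Bc <- quadratic_covariation(hc)
  expect_true(all(Bc[1, 2, ] == 0))

  # anything involving the time component is zero
  ht <- augment_time_component(h, 0.5, horizon = max(h$time))
  Bt <- quadratic_covariation(ht)
  expect_true(all(Bt["time", , ] == 0))
  expect_true(all(Bt[, "time", ] == 0))
})

test_that("generic covariance equals direct evaluation of the scalar survival recursion", {
  for (seed in 1:10) {
    coh <- random_cohort(40 + 15 * seed, seed)
    h <- nelson_aalen(coh)
    p <- solve_path(survival_system(), h)
    # direct recursion: V_k = V_{k-1} - 2 V_{k-1} dA_k + n S_{k-1}^2 / Y_k dA_k
    V <- 0
    worst <- 0
    for (k in seq_along(h$time)) {
      dA <- h$inc[k, 1]
      V <- V - 2 * V * dA + h$n * p$x[k, 1]^2 / h$at_risk[k] * dA
      worst <- max(worst, abs(V - p$v[1, 1, k + 1]))
    }
    expect_lt(worst, 1e-12)
  }
})

test_that("cross-covariance anchors at V(t) and simplifies for the survival system", {
  coh <- random_cohort(120, 9)
  h <- nelson_aalen(coh)
  p <- solve_path(survival_system(), h)
  t <- unname(stats::quantile(h$time, 0.3))
  # delta = 0: anchor exactly
  cc0 <- cross_covariance(p, t, 0)
  expect_identical(cc0$vt_delta, eval_cov(p, t))
  # no events in the window: unchanged
  gaps <- diff(h$time)
  g <- which.max(gaps)
  t1 <- h$time[g] + 1e-6
  cc_gap <- cross_covariance(p, t1, gaps[g] / 2)
  expect_equal(cc_gap$vt_delta, eval_cov(p, t1))
  # product-form simplification V(t, t+d) = V(t) S(t+d)/S(t)
  for (d in c(0.5, 2, 5)) {
    cc <- cross_covariance(p, t, d)
    St <- eval_state(p, t)[1]
    Std <- eval_state(p, t + d)[1]
    expect_lt(abs(cc$vt_delta[1, 1] - eval_cov(p, t)[1, 1] * Std / St), 1e-12)
  }
  expect_error(cross_covariance(p, max(p$time) + 1, 0), "horizon")
})

test_that("transform covariance reproduces the conditional-survival closed form", {
  for (seed in c(2, 11)) {
    coh <- random_cohort(150, seed)
    h <- nelson_aalen(coh)
    p <- solve_path(survival_system(), h)
    t <- unname(stats::quantile(h$time, 0.25))
    d <- unname(stats::quantile(h$time, 0.6)) - t
    cc <- cross_covariance(p, t, d)
    tr <- make_transform(function(x, y) y[1] / x[1],
                         function(x, y) matrix(c(-y[1] / x[1]^2, 1 / x[1]), 1, 2))
    tc <- transform_covariance(tr, p, cc, t, d)
    St <- eval_state(p, t)[1]; Std <- eval_state(p, t + d)[1]
    Vt <- eval_cov(p, t)[1, 1]; Vtd <- eval_cov(p, t + d)[1, 1]
    closed <- (Vtd - Vt * Std^2 / St^2) / (p$n * St^2)
    expect_lt(abs(tc$cov[1, 1] - closed), 1e-12)
    expect_equal(tc$estimate, Std / St)

    # identity on the first block: covariance V(t)/n
    tr_id <- make_transform(function(x, y) x[1],
                            function(x, y) matrix(c(1, 0), 1, 2))
    tc_id <- transform_covariance(tr_id, p, cc, t, d)
    expect_equal(tc_id$cov[1, 1], Vt / p$n)

    # degenerate window (delta = 0) with H constant in its second argument
    cc0 <- cross_covariance(p, t, 0)
    tc0 <- transform_covariance(tr_id, p, cc0, t, 0)
    expect_equal(tc0$cov[1, 1], Vt / p$n)
  }
})

test_that("covariance paths are symmetric with nonnegative diagonals", {
  for (seed in 1:8) {
    coh <- random_cohort(100, seed, round_digits = if (seed > 4) 1 else NULL)
    hc <- nelson_aalen(coh, causes = c(1, 2))
    p <- solve_path(cif_system(), hc)
    for (k in seq_along(p$time)) {
      V <- p$v[, , k]
      expect_identical(V, t(V))
      expect_true(all(diag(V) >= -1e-10))
    }
  }
})

test_that("halving the time mesh leaves the R path and its variance unchanged", {
  coh <- random_cohort(100, 21)
  h <- nelson_aalen(coh)
  hz <- unname(stats::quantile(h$time, 0.9))
  p1 <- solve_path(rmrl_system(), augment_time_component(h, 0.02, hz))
  p2 <- solve_path(rmrl_system(), augment_time_component(h, 0.01, hz))
  for (t in c(hz / 4, hz / 2, hz * 0.85)) {
    r1 <- eval_state(p1, t)[2]; r2 <- eval_state(p2, t)[2]
    expect_lt(abs(r1 - r2) / max(1, abs(r2)), 1e-6)
    v1 <- eval_cov(p1, t); v2 <- eval_cov(p2, t)
    expect_lt(max(abs(v1 - v2)) / max(1, max(abs(v2))), 1e-6)
  }
})

test_that("shipped systems pass the finite-difference gradient check", {
  states <- list(c(1, 0, 0), c(0.5, 0.3, 0.2), c(0.2, 0.5, 0.3))
  expect_lt(check_gradients(cif_system()$system, states), 1e-6)
  expect_lt(check_gradients(survival_system()$system,
                            list(1, 0.5, 0.1)), 1e-6)
  expect_lt(check_gradients(rmrl_system()$system,
                            list(c(1, 0), c(0.4, 2.5))), 1e-6)
})

test_that("dimension mismatches and undefined transforms are reported", {
  coh <- random_cohort(30, 1)
  h <- nelson_aalen(coh) # single "all" component
  expect_error(solve_plugin(cif_system(), h), "lacks component")
  # transform undefined at S(t)=0: flagged, not raised
  p <- solve_path(survival_system(), nelson_aalen(toy_cohort()))
  cc <- cross_covariance(p, 4, 0)
  tr <- make_transform(function(x, y) y[1] / x[1],
                       function(x, y) matrix(c(-y[1] / x[1]^2, 1 / x[1]), 1, 2))
  tc <- transform_covariance(tr, p, cc, 4, 0)
  expect_false(tc$defined)
  expect_true(is.na(tc$estimate))
})

test_that("Wald intervals from the plug-in variance attain nominal coverage", {
  # exponential truth S(2) = exp(-0.4); rate 0.2, censoring 0.1, n = 300
  B <- 1000
  n <- 300
  truth <- exp(-0.4)
  hits <- 0
  withr::with_seed(2024, {
    for (b in seq_len(B)) {
      tt <- stats::rexp(n, 0.2)
      cc <- stats::rexp(n, 0.1)
      coh <- tibble::tibble(time = pmin(tt, cc),
                            event = as.integer(tt <= cc))
      p <- solve_path(survival_system(), nelson_aalen(coh))
      S2 <- eval_state(p, 2)[1]
      se <- sqrt(eval_cov(p, 2)[1, 1] / n)
      hits <- hits + (abs(S2 - truth) <= stats::qnorm(0.975) * se)
    }
  })
  expect_gte(hits / B, 0.93)
  expect_lte(hits / B, 0.97)
})
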