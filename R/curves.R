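#' @keywords internal
new_prognosis_curve <- function(df, label, delta) {
  df <- tibble::as_tibble(df)
  attr(df, "label") <- label
  attr(df, "delta") <- delta
  class(df) <- c("prognosis_curve", class(df))
  df
}

#' @export
print.prognosis_curve <- function(x, ...) {
  cat("<prognosis_curve> ", attr(x, "label"), " with Delta = ",
      attr(x, "delta"), " years\n", sep = "")
  NextMethod()
}

#' @keywords internal
#' Wald interval on the requested scale, clipped to the parameter's
#' logical range.
wald_ci <- function(est, se, range, conf_level = 0.95, ci_scale = "plain") {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- hi <- rep(NA_real_, length(est))
  ok <- is.finite(est) & is.finite(se)
  if (ci_scale == "plain") {
    lo[ok] <- est[ok] - z * se[ok]
    hi[ok] <- est[ok] + z * se[ok]
  } else if (ci_scale == "log") {
    pos <- ok & est > 0
    lo[pos] <- est[pos] * exp(-z * se[pos] / est[pos])
    hi[pos] <- est[pos] * exp(z * se[pos] / est[pos])
    lo[ok & !pos] <- est[ok & !pos]
    hi[ok & !pos] <- est[ok & !pos]
  } else if (ci_scale == "loglog") {
    # for probabilities in (0, 1); falls back to plain at the boundary
    inr <- ok & est > 0 & est < 1
    th <- log(-log(est[inr]))
    se_th <- se[inr] / abs(est[inr] * log(est[inr]))
    lo[inr] <- exp(-exp(th + z * se_th))
    hi[inr] <- exp(-exp(th - z * se_th))
    bd <- ok & !inr
    lo[bd] <- est[bd] - z * se[bd]
    hi[bd] <- est[bd] + z * se[bd]
  } else {
    stop("unknown `ci_scale`: ", ci_scale, call. = FALSE)
  }
  lo <- pmax(lo, range[1]); lo <- pmin(lo, est, na.rm = FALSE)
  hi <- pmin(hi, range[2]); hi <- pmax(hi, est, na.rm = FALSE)
  list(lo = lo, hi = hi)
}

#' @keywords internal
#' Default base-time grid for a curve: solved event/grid times (excluding
#' mesh-only points when a time component is present) restricted to
#' [0, horizon - delta].
default_t_grid <- function(path, delta) {
  horizon <- max(path$time)
  tt <- path$time
  tcol <- path$align$time_col
  if (!is.na(tcol)) {
    jumps <- rowSums(abs(path$align$inc[, !path$align$is_time, drop = FALSE])) > 0
    tt <- c(0, path$hazard$time[jumps])
  }
  sort(unique(tt[tt <= horizon - delta + 1e-9]))
}

#' @keywords internal
#' Shared curve assembly: generic delta-method variance with an always-on
#' assertion against the closed-form variance expression.
build_curve <- function(path, delta, t_grid, transform, closed_form,
                        label, range, conf_level, ci_scale,
                        agree_tol = 1e-10) {
  if (is.null(t_grid)) t_grid <- default_t_grid(path, delta)
  m <- length(t_grid)
  est <- var_gen <- rep(NA_real_, m)
  defined <- rep(FALSE, m)
  for (i in seq_len(m)) {
    t <- t_grid[i]
    cc <- cross_covariance(path, t, delta)
    tc <- transform_covariance(transform, path, cc, t, delta)
    if (!tc$defined) next
    est[i] <- tc$estimate
    var_gen[i] <- tc$cov[1, 1]
    defined[i] <- TRUE
    if (!is.null(closed_form)) {
      vcf <- closed_form(path, cc, t, delta)
      if (is.finite(vcf) &&
          abs(vcf - var_gen[i]) > agree_tol * max(1, abs(vcf))) {
        stop("internal check failed: generic and closed-form variances ",
             "disagree at t = ", t, " (", var_gen[i], " vs ", vcf, ")",
             call. = FALSE)
      }
    }
  }
  var_gen[defined] <- pmax(var_gen[defined], 0)
  se <- sqrt(var_gen)
  ci <- wald_ci(est, se, range, conf_level, ci_scale)
  new_prognosis_curve(
    tibble::tibble(t = t_grid, delta = delta, estimate = est,
                   variance = var_gen, se = se,
                   lo = ci$lo, hi = ci$hi, defined = defined),
    label = label, delta = delta
  )
}

#' Conditional Delta-year survival curve
#'
#' \eqn{\hat{CS}_c(t+\Delta\mid t) = \hat S(t+\Delta)/\hat S(t)}, the ratio
#' of Kaplan-Meier values, with pointwise variance from the generic
#' delta-method engine.  The closed-form expression
#' \eqn{\{\hat V(t+\Delta) - \hat V(t)\hat S(t+\Delta)^2/\hat S(t)^2\}/
#' (n\hat S(t)^2)} is evaluated alongside and must agree (internal
#' assertion); base times where \eqn{\hat S(t) = 0} are flagged undefined.
#'
#' @param path A `plugin_path` of the [survival_system()] with covariance,
#'   solved to horizon at least `max(t_grid) + delta`.
#' @param delta Horizon width in years.
#' @param t_grid Base times; defaults to the event grid restricted to
#'   `[0, horizon - delta]`.
#' @param conf_level Confidence level (default 0.95).
#' @param ci_scale `"plain"` (default), `"log"` or `"loglog"`.
#' @return A `prognosis_curve` tibble: columns `t`, `delta`, `estimate`,
#'   `variance`, `se`, `lo`, `hi`, `defined`.
#' @export
conditional_survival <- function(path, delta, t_grid = NULL,
                                 conf_level = 0.95, ci_scale = "plain") {
  stopifnot(inherits(path, "plugin_path"))
  tr <- make_transform(
    H = function(x, y) y[1] / x[1],
    gradH = function(x, y) matrix(c(-y[1] / x[1]^2, 1 / x[1]), 1, 2)
  )
  cf <- function(path, cc, t, delta) {
    St <- eval_state(path, t)[1]
    Std <- eval_state(path, t + delta)[1]
    Vt <- eval_cov(path, t)[1, 1]
    Vtd <- eval_cov(path, t + delta)[1, 1]
    if (St == 0) return(NA_real_)
    (Vtd - Vt * Std^2 / St^2) / (path$n * St^2)
  }
  build_curve(path, delta, t_grid, tr, cf, label = "CS_c",
              range = c(0, 1), conf_level = conf_level, ci_scale = ci_scale,
              agree_tol = 1e-12)
}

#' Restricted mean residual lifetime curve
#'
#' \eqn{\widehat{RMRL}_c(t+\Delta\mid t) = (\hat R(t+\Delta) - \hat R(t))/
#' \hat S(t)} where \eqn{\hat R} integrates the Kaplan-Meier step function
#' exactly.  The generic delta-method variance is cross-checked against the
#' explicit block quadratic form in \eqn{\hat V(t)}, \eqn{\hat
#' V(t,t+\Delta)} and \eqn{\hat V(t+\Delta)}.
#'
#' @param path A `plugin_path` of the [rmrl_system()] with covariance
#'   (drive it with [augment_time_component()]).
#' @inheritParams conditional_survival
#' @return A `prognosis_curve` with estimates in years, bounded by
#'   `[0, delta]`.
#' @export
rmrl <- function(path, delta, t_grid = NULL,
                 conf_level = 0.95, ci_scale = "plain") {
  stopifnot(inherits(path, "plugin_path"))
  tr <- make_transform(
    H = function(x, y) (y[2] - x[2]) / x[1],
    gradH = function(x, y) matrix(c(-(y[2] - x[2]) / x[1]^2, -1 / x[1],
                                    0, 1 / x[1]), 1, 4)
  )
  cf <- function(path, cc, t, delta) {
    x <- eval_state(path, t); y <- eval_state(path, t + delta)
    St <- x[1]
    if (St == 0) return(NA_real_)
    dR <- y[2] - x[2]
    a <- c(dR / St^2, 1 / St)
    b <- c(0, 1 / St)
    Vt <- eval_cov(path, t)
    Vtd <- eval_cov(path, t + delta)
    C <- cc$vt_delta
    (drop(a %*% Vt %*% a) - drop(a %*% t(C) %*% b) -
        drop(b %*% C %*% a) + drop(b %*% Vtd %*% b)) / path$n
  }
  build_curve(path, delta, t_grid, tr, cf, label = "RMRL_c",
              range = c(0, delta), conf_level = conf_level,
              ci_scale = ci_scale, agree_tol = 1e-10)
}

#' Conditional restricted mean time lost
#'
#' \eqn{CRMTL(t+\Delta\mid t) = \Delta - RMRL_c(t+\Delta\mid t)}: the
#' expected years of life lost over the horizon.  Being an affine map, the
#' variance is carried over unchanged and the interval bounds swap.
#'
#' @param curve A `prognosis_curve` produced by [rmrl()].
#' @return A `prognosis_curve` labelled `CRMTL`.
#' @export
crmtl <- function(curve) {
  stopifnot(inherits(curve, "prognosis_curve"))
  if (!identical(attr(curve, "label"), "RMRL_c")) {
    stop("`crmtl()` expects an RMRL curve.", call. = FALSE)
  }
  delta <- attr(curve, "delta")
  out <- tibble::as_tibble(curve)
  old_lo <- out$lo
  out$estimate <- delta - out$estimate
  out$lo <- delta - out$hi
  out$hi <- delta - old_lo
  new_prognosis_curve(out, label = "CRMTL", delta = delta)
}

#' Cause-specific prognosis curves
#'
#' Transforms of the cumulative-incidence path \eqn{(\hat S, \hat C^c,
#' \hat C^o)} among survivors at `t`, over the window \eqn{(t, t+\Delta]}:
#' \describe{
#'   \item{`risk`}{\eqn{(\hat C^c(t+\Delta) - \hat C^c(t))/\hat S(t)} —
#'     conditional risk of death from the target cancer.}
#'   \item{`ratio`}{\eqn{(\hat C^c(t+\Delta) - \hat C^c(t))/(\hat
#'     C^o(t+\Delta) - \hat C^o(t))} — cancer vs other-cause risk ratio.}
#'   \item{`difference`}{conditional risk difference, cancer minus other.}
#'   \item{`proportion`}{share of deaths in the window attributable to the
#'     cancer, \eqn{(\hat C^c(t+\Delta) - \hat C^c(t))/(\hat S(t) - \hat
#'     S(t+\Delta))}.}
#' }
#' Variances come from the generic engine and are cross-checked against
#' the explicit gradient quadratic forms \eqn{a(t)^\top\hat V(t)a(t) +
#' a(t)^\top\hat V(t,t+\Delta)^\top b(t) + b(t)^\top\hat
#' V(t,t+\Delta)a(t) + b(t)^\top\hat V(t+\Delta)b(t)} of each transform.
#' Undefined base times (zero denominators) are flagged, not raised.
#'
#' @param path A `plugin_path` of the [cif_system()] with covariance.
#' @param which One of `"risk"`, `"ratio"`, `"difference"`, `"proportion"`.
#' @inheritParams conditional_survival
#' @return A `prognosis_curve`.
#' @export
cause_specific_curves <- function(path, delta, which = c("risk", "ratio",
                                                         "difference", "proportion"),
                                  t_grid = NULL, conf_level = 0.95,
                                  ci_scale = "plain") {
  stopifnot(inherits(path, "plugin_path"))
  which <- match.arg(which)
  spec <- switch(which,
    risk = list(
      H = function(x, y) (y[2] - x[2]) / x[1],
      ab = function(x, y) {
        S <- x[1]; dCc <- y[2] - x[2]
        list(a = c(-dCc / S, -1, 0) / S, b = c(0, 1, 0) / S)
      },
      label = "risk_c", range = c(0, 1)
    ),
    ratio = list(
      H = function(x, y) (y[2] - x[2]) / (y[3] - x[3]),
      ab = function(x, y) {
        dCc <- y[2] - x[2]; dCo <- y[3] - x[3]; J1 <- 1 / dCo
        list(a = J1 * c(0, -1, dCc / dCo), b = J1 * c(0, 1, -dCc / dCo))
      },
      label = "risk_ratio", range = c(0, Inf)
    ),
    difference = list(
      H = function(x, y) (y[2] - x[2] - y[3] + x[3]) / x[1],
      ab = function(x, y) {
        S <- x[1]; d <- (y[2] - x[2]) - (y[3] - x[3])
        list(a = c(-d / S, -1, 1) / S, b = c(0, 1, -1) / S)
      },
      label = "risk_difference", range = c(-1, 1)
    ),
    proportion = list(
      H = function(x, y) (y[2] - x[2]) / (x[1] - y[1]),
      ab = function(x, y) {
        dCc <- y[2] - x[2]; dS <- x[1] - y[1]; J2 <- 1 / dS
        list(a = J2 * c(-dCc / dS, -1, 0), b = J2 * c(dCc / dS, 1, 0))
      },
      label = "death_proportion", range = c(0, 1)
    )
  )
  tr <- make_transform(
    H = spec$H,
    gradH = function(x, y) {
      ab <- spec$ab(x, y)
      matrix(c(ab$a, ab$b), 1, 6)
    }
  )
  cf <- function(path, cc, t, delta) {
    x <- eval_state(path, t); y <- eval_state(path, t + delta)
    ab <- spec$ab(x, y)
    if (any(!is.finite(ab$a)) || any(!is.finite(ab$b))) return(NA_real_)
    Vt <- eval_cov(path, t)
    Vtd <- eval_cov(path, t + delta)
    C <- cc$vt_delta
    (drop(ab$a %*% Vt %*% ab$a) + drop(ab$a %*% t(C) %*% ab$b) +
        drop(ab$b %*% C %*% ab$a) + drop(ab$b %*% Vtd %*% ab$b)) / path$n
  }
  build_curve(path, delta, t_grid, tr, cf, label = spec$label,
              range = spec$range, conf_level = conf_level,
              ci_scale = ci_scale, agree_tol = 1e-10)
}

#' Write a prognosis curve to delimited text
#'
#' One file per parameter; a `# label:` comment line preserves the curve's
#' identity for [read_curve()].  Columns: `t`, `delta`, `estimate`, `se`,
#' `lo95`, `hi95`, `defined`.
#'
#' @param curve A `prognosis_curve`.
#' @param file Output path.
#' @param delim Field delimiter.
#' @return `file`, invisibly.
#' @export
write_curve <- function(curve, file, delim = ",") {
  stopifnot(inherits(curve, "prognosis_curve"))
  out <- tibble::tibble(
    t = curve$t, delta = curve$delta, estimate = curve$estimate,
    se = curve$se, lo95 = curve$lo, hi95 = curve$hi, defined = curve$defined
  )
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeLines(paste0("# label: ", attr(curve, "label")), con)
  readr::write_delim(out, con, delim = delim)
  invisible(file)
}

#' Read a prognosis curve written by [write_curve()]
#'
#' @param file Path to a curve file.
#' @param delim Field delimiter.
#' @return A `prognosis_curve`.
#' @export
read_curve <- function(file, delim = ",") {
  first <- readLines(file, n = 1)
  label <- sub("^# label: ", "", first)
  x <- readr::read_delim(file, delim = delim, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  df <- tibble::tibble(
    t = x$t, delta = x$delta, estimate = x$estimate,
    variance = x$se^2, se = x$se, lo = x$lo95, hi = x$hi95,
    defined = x$defined
  )
  new_prognosis_curve(df, label = label, delta = x$delta[1])
}
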