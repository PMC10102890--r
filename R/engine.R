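#' @keywords internal
#' Align a hazard's increment matrix with a system's components.
#' Returns list(inc, is_time, time_col).
align_hazard <- function(system, hazard) {
  missing <- setdiff(system$components, colnames(hazard$inc))
  if (length(missing) > 0) {
    stop("hazard lacks component(s) required by the system: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  inc <- hazard$inc[, system$components, drop = FALSE]
  is_time <- system$components == "time"
  if (sum(is_time) > 1) stop("at most one time component is allowed.", call. = FALSE)
  list(inc = inc, is_time = is_time, time_col = if (any(is_time)) which(is_time) else NA_integer_)
}

#' Solve the plug-in difference equation
#'
#' Forward recursion over the hazard grid:
#' \deqn{\hat X(s_k) = \hat X(s_{k-1}) + F(\hat X(s_{k-1}))\,\Delta\hat A(s_k),}
#' the plug-in estimator of the system's ODE with the cumulative hazard
#' replaced by its step-function estimate.  Coefficients are always
#' evaluated at the left limit (previous grid point), so for pure-jump
#' integrators the path is exact.  With the survival system this recursion
#' reproduces the Kaplan-Meier estimator jump for jump.
#'
#' @param system An [ode_system()] (or a bundle from e.g.
#'   [survival_system()], whose `$system` is used).
#' @param hazard A `step_hazard` carrying all components the system needs.
#' @return A `plugin_path`: `time` (grid with 0 prepended), `x` (matrix of
#'   states, one row per grid time), `n`, plus the system and hazard for
#'   downstream variance work.
#' @export
solve_plugin <- function(system, hazard) {
  if (!inherits(system, "ode_system") && is.list(system) && inherits(system$system, "ode_system")) {
    system <- system$system
  }
  stopifnot(inherits(system, "ode_system"), inherits(hazard, "step_hazard"))
  al <- align_hazard(system, hazard)
  K <- length(hazard$time)
  p <- system$p
  x <- matrix(NA_real_, K + 1, p, dimnames = list(NULL, system$state_names))
  x[1, ] <- system$x0
  xk <- system$x0
  for (k in seq_len(K)) {
    xk <- xk + drop(system$F(xk) %*% al$inc[k, ])
    if (any(!is.finite(xk))) {
      stop("non-finite state at grid time ", hazard$time[k], call. = FALSE)
    }
    x[k + 1, ] <- xk
  }
  structure(
    list(time = c(0, hazard$time), x = x, v = NULL, n = hazard$n,
         system = system, hazard = hazard, align = al),
    class = "plugin_path"
  )
}

#' @export
print.plugin_path <- function(x, ...) {
  cat("<plugin_path> ", length(x$time), " grid times over [0, ",
      format(max(x$time)), "], states: ",
      paste(x$system$state_names, collapse = ", "),
      if (!is.null(x$v)) " (with covariance path)" else "", "\n", sep = "")
  invisible(x)
}

#' Per-jump quadratic covariation of the driving hazard
#'
#' At each grid point the optional matrix \eqn{\Delta[B]_{ij} =
#' \Delta\hat A^i \Delta\hat A^j} for hazard components; every entry
#' involving the reserved `"time"` component is zero.
#'
#' @param hazard A `step_hazard`.
#' @return A `q x q x K` array of per-jump increments (named by component).
#' @export
quadratic_covariation <- function(hazard) {
  stopifnot(inherits(hazard, "step_hazard"))
  inc <- hazard$inc
  q <- ncol(inc)
  K <- nrow(inc)
  comps <- colnames(inc)
  keep <- comps != "time"
  out <- array(0, dim = c(q, q, max(K, 0)), dimnames = list(comps, comps, NULL))
  for (k in seq_len(K)) {
    d <- inc[k, ] * keep
    out[, , k] <- tcrossprod(d)
  }
  out
}

#' @keywords internal
#' One-interval exact propagation of a covariance through the time
#' component: V <- (I + G dt) V (I + G dt)^T.  Exact between event atoms
#' when grad F_time does not depend on the state (true for all shipped
#' systems); composes exactly under mesh refinement for nilpotent G.
propagate_time_cov <- function(V, G, dt) {
  M <- diag(nrow(V)) + G * dt
  M %*% V %*% t(M)
}

#' Solve the plug-in covariance recursion
#'
#' Propagates the covariance path \eqn{\hat V(t)} of the root-n residual
#' process along the hazard grid:
#' jump components contribute
#' \eqn{\{\hat V \nabla F_j^\top + \nabla F_j \hat V\}\,\Delta\hat A^j
#'  + n\,F\,\Delta[B]\,F^\top}
#' with everything evaluated at the left limit, while the reserved time
#' component is propagated exactly through
#' \eqn{\hat V \mapsto (I + \nabla F_{time}\,dt)\,\hat V\,(I + \nabla
#' F_{time}\,dt)^\top} over each grid spacing (which makes the result
#' independent of the mesh used for the time component).  Output is
#' symmetrized at every step.
#'
#' @param system An [ode_system()] or bundle.
#' @param hazard The driving `step_hazard`.
#' @param path The `plugin_path` from [solve_plugin()] on the same hazard.
#' @return The `plugin_path` with `v` filled in: a `p x p x (K+1)` array of
#'   covariance matrices along `path$time`.
#' @export
solve_variance <- function(system, hazard, path) {
  if (!inherits(system, "ode_system") && is.list(system)) system <- system$system
  stopifnot(inherits(path, "plugin_path"))
  if (!identical(path$time, c(0, hazard$time))) {
    stop("`path` was not solved on this hazard grid.", call. = FALSE)
  }
  al <- align_hazard(system, hazard)
  K <- length(hazard$time)
  p <- system$p
  n <- hazard$n
  v <- array(0, dim = c(p, p, K + 1))
  V <- system$v0
  v[, , 1] <- V
  haz_idx <- which(!al$is_time)
  tcol <- al$time_col
  for (k in seq_len(K)) {
    xk <- path$x[k, ]
    dA <- al$inc[k, ]
    if (!is.na(tcol) && dA[tcol] > 0) {
      V <- propagate_time_cov(V, system$gradF[[tcol]](xk), dA[tcol])
    }
    upd <- matrix(0, p, p)
    dB <- rep(0, length(dA))
    for (j in haz_idx) {
      if (dA[j] != 0) {
        G <- system$gradF[[j]](xk)
        upd <- upd + (V %*% t(G) + G %*% V) * dA[j]
        dB[j] <- dA[j]
      }
    }
    if (any(dB != 0)) {
      Fx <- system$F(xk)
      upd <- upd + n * (Fx %*% tcrossprod(dB) %*% t(Fx))
    }
    V <- V + upd
    V <- (V + t(V)) / 2
    if (any(!is.finite(V))) {
      stop("non-finite covariance at grid time ", hazard$time[k], call. = FALSE)
    }
    v[, , k + 1] <- V
  }
  path$v <- v
  path
}

#' Solve the plug-in path together with its covariance
#'
#' Convenience wrapper: [solve_plugin()] followed by [solve_variance()].
#'
#' @inheritParams solve_variance
#' @return A `plugin_path` with both `x` and `v`.
#' @export
solve_path <- function(system, hazard) {
  if (!inherits(system, "ode_system") && is.list(system)) system <- system$system
  path <- solve_plugin(system, hazard)
  solve_variance(system, hazard, path)
}

#' @keywords internal
#' Index of the last grid time <= t (right-continuous step convention).
path_index <- function(path, t) {
  i <- findInterval(t, path$time)
  if (i < 1) stop("time ", t, " precedes the solved grid.", call. = FALSE)
  i
}

#' Evaluate the solved state at an arbitrary time
#'
#' Step interpolation (right-continuous) for jump-driven components; for
#' systems with a time component the dt-driven part of the state advances
#' linearly between grid points, which is exact because the coefficient is
#' a step function.
#'
#' @param path A `plugin_path`.
#' @param t A single time within the solved horizon.
#' @return The state vector \eqn{\hat X(t)}.
#' @export
eval_state <- function(path, t) {
  if (t > max(path$time) + 1e-9) {
    stop("time ", t, " lies beyond the solved horizon ", max(path$time),
         call. = FALSE)
  }
  i <- path_index(path, t)
  x <- path$x[i, ]
  tcol <- path$align$time_col
  dt <- t - path$time[i]
  if (!is.na(tcol) && dt > 0) {
    x <- x + path$system$F(x)[, tcol] * dt
  }
  unname(x)
}

#' Evaluate the covariance path at an arbitrary time
#'
#' @param path A `plugin_path` with `v` (see [solve_variance()]).
#' @param t A single time within the solved horizon.
#' @return The `p x p` matrix \eqn{\hat V(t)}.
#' @export
eval_cov <- function(path, t) {
  if (is.null(path$v)) stop("path has no covariance; run solve_variance().", call. = FALSE)
  if (t > max(path$time) + 1e-9) {
    stop("time ", t, " lies beyond the solved horizon ", max(path$time),
         call. = FALSE)
  }
  i <- path_index(path, t)
  V <- path$v[, , i, drop = FALSE]
  dim(V) <- dim(path$v)[1:2]
  tcol <- path$align$time_col
  dt <- t - path$time[i]
  if (!is.na(tcol) && dt > 0) {
    V <- propagate_time_cov(V, path$system$gradF[[tcol]](path$x[i, ]), dt)
  }
  V
}

#' Cross-covariance between the path at t and at later times
#'
#' Propagates \eqn{\hat V(t, s)} from the anchor \eqn{\hat V(t,t) =
#' \hat V(t)} over the grid points in \eqn{(t, t+\Delta]}:
#' \deqn{\hat V(t,s) = \hat V(t,s-) + \sum_j \nabla F_j(\hat X(s-))\,
#' \hat V(t,s-)\,\Delta\hat A^j(s),}
#' with the time component applied as exact left multiplication by
#' \eqn{(I + \nabla F_{time}\,dt)}.
#'
#' @param path A `plugin_path` with covariance.
#' @param t Base time.
#' @param delta Nonnegative horizon offset; `t + delta` must lie within the
#'   solved grid.
#' @return A `cross_cov` object: the anchor `t`, `delta`, the horizon times
#'   `s` in `(t, t+delta]`, the array `v` of matrices \eqn{\hat V(t,s)},
#'   and `vt_delta`, the final matrix \eqn{\hat V(t, t+\Delta)}.
#' @export
cross_covariance <- function(path, t, delta) {
  stopifnot(inherits(path, "plugin_path"), delta >= 0)
  if (is.null(path$v)) stop("path has no covariance; run solve_variance().", call. = FALSE)
  horizon <- max(path$time)
  if (t > horizon + 1e-9 || t + delta > horizon + 1e-9) {
    stop("window [", t, ", ", t + delta, "] exceeds the solved horizon ",
         horizon, call. = FALSE)
  }
  C <- eval_cov(path, t)
  tcol <- path$align$time_col
  haz_idx <- which(!path$align$is_time)
  ks <- which(path$time > t & path$time <= t + delta)
  m <- length(ks)
  p <- path$system$p
  out <- array(NA_real_, dim = c(p, p, m))
  prev_time <- t
  for (ii in seq_along(ks)) {
    k <- ks[ii]
    xk <- path$x[k - 1, ]
    if (!is.na(tcol)) {
      dt <- path$time[k] - prev_time
      if (dt > 0) {
        C <- (diag(p) + path$system$gradF[[tcol]](xk) * dt) %*% C
      }
    }
    dAk <- path$align$inc[k - 1, ]
    for (j in haz_idx) {
      if (dAk[j] != 0) {
        C <- C + path$system$gradF[[j]](xk) %*% C * dAk[j]
      }
    }
    out[, , ii] <- C
    prev_time <- path$time[k]
  }
  # partial time propagation up to exactly t + delta
  if (!is.na(tcol)) {
    dt <- t + delta - prev_time
    if (dt > 0) {
      i <- path_index(path, t + delta)
      C <- (diag(p) + path$system$gradF[[tcol]](path$x[i, ]) * dt) %*% C
    }
  }
  structure(
    list(t = t, delta = delta, s = path$time[ks], v = out, vt_delta = C),
    class = "cross_cov"
  )
}

#' Define a smooth transform of the path at two time points
#'
#' @param H Function of two state vectors `(x, y)` (the path at `t` and at
#'   `t + delta`) returning a length-`m` numeric vector.
#' @param gradH Function returning the `m x 2p` Jacobian of `H` at
#'   `(x, y)` (columns ordered: derivatives in `x`, then in `y`).
#' @param m Output dimension (default 1).
#' @return A `transform` object for [transform_covariance()].
#' @export
make_transform <- function(H, gradH, m = 1L) {
  stopifnot(is.function(H), is.function(gradH))
  structure(list(H = H, gradH = gradH, m = as.integer(m)), class = "transform")
}

#' Delta-method estimate and covariance of a two-time-point transform
#'
#' Computes \eqn{H(\hat X(t), \hat X(t+\Delta))} and its covariance
#' \deqn{\frac{1}{n}\,\nabla H \begin{pmatrix}\hat V(t) & \hat
#' V(t,t+\Delta)^\top\\ \hat V(t,t+\Delta) & \hat V(t+\Delta)\end{pmatrix}
#' \nabla H^\top.}
#' A non-finite value or gradient (for example division by
#' \eqn{\hat S(t) = 0}) yields `defined = FALSE` with `NA` outputs rather
#' than an error, so whole curves survive late-time degeneracy.
#'
#' @param transform A [make_transform()] object.
#' @param path A `plugin_path` with covariance.
#' @param crosscov A `cross_cov` from [cross_covariance()] for the same
#'   `(t, delta)`.
#' @param t Base time.
#' @param delta Horizon offset.
#' @return A list: `estimate` (length `m`), `cov` (`m x m`, symmetric),
#'   `defined` (logical).
#' @export
transform_covariance <- function(transform, path, crosscov, t, delta) {
  stopifnot(inherits(transform, "transform"), inherits(crosscov, "cross_cov"))
  if (abs(crosscov$t - t) > 1e-9 || abs(crosscov$delta - delta) > 1e-9) {
    stop("`crosscov` was computed for a different (t, delta).", call. = FALSE)
  }
  x <- eval_state(path, t)
  y <- eval_state(path, t + delta)
  est <- transform$H(x, y)
  J <- transform$gradH(x, y)
  if (any(!is.finite(est)) || any(!is.finite(J))) {
    return(list(estimate = rep(NA_real_, transform$m),
                cov = matrix(NA_real_, transform$m, transform$m),
                defined = FALSE))
  }
  Vt <- eval_cov(path, t)
  Vtd <- eval_cov(path, t + delta)
  C <- crosscov$vt_delta
  Sigma <- rbind(cbind(Vt, t(C)), cbind(C, Vtd))
  J <- matrix(J, nrow = transform$m)
  cov <- (J %*% Sigma %*% t(J)) / path$n
  cov <- (cov + t(cov)) / 2
  list(estimate = unname(est), cov = unname(cov), defined = TRUE)
}
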