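#' Define a hazard-driven ODE system
#'
#' A parameter vector \eqn{X(t)} of dimension `p` solving
#' \deqn{X(t) = X(0) + \int_0^t F(X(s))\,dA(s)}
#' where \eqn{A} is a `q`-dimensional vector of integrator components
#' (cumulative hazards, and optionally the reserved `"time"` component with
#' \eqn{dA = dt}).
#'
#' @param x0 Numeric initial value \eqn{X(0)} (length `p`).
#' @param F Function mapping a state vector to the `p x q` coefficient
#'   matrix.
#' @param gradF List of `q` functions, each mapping a state vector to the
#'   `p x p` gradient \eqn{\nabla F_j} of column `j`.
#' @param components Character vector of length `q` naming the integrator
#'   components the system consumes; must match column labels of the
#'   driving `step_hazard` (`"time"` is reserved for the dt component).
#' @param v0 Initial covariance \eqn{\hat V(0)}, `p x p`; defaults to the
#'   zero matrix (deterministic initial value).
#' @param state_names Optional names for the state entries.
#' @return An `ode_system` object.
#' @seealso [survival_system()], [cif_system()], [rmrl_system()] for the
#'   predefined prognosis systems.
#' @export
ode_system <- function(x0, F, gradF, components, v0 = NULL, state_names = NULL) {
  p <- length(x0)
  q <- length(components)
  stopifnot(is.function(F), is.list(gradF), length(gradF) == q)
  if (is.null(v0)) v0 <- matrix(0, p, p)
  stopifnot(is.matrix(v0), all(dim(v0) == p))
  if (max(abs(v0 - t(v0))) > 1e-12) stop("`v0` must be symmetric.", call. = FALSE)
  if (min(eigen(v0, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("`v0` must be positive semidefinite.", call. = FALSE)
  }
  if (!is.null(state_names)) stopifnot(length(state_names) == p)
  structure(
    list(p = p, q = q, x0 = as.numeric(x0), F = F, gradF = gradF,
         components = components, v0 = v0,
         state_names = state_names %||% paste0("x", seq_len(p))),
    class = "ode_system"
  )
}

#' @export
print.ode_system <- function(x, ...) {
  cat("<ode_system> p = ", x$p, ", driven by: ",
      paste(x$components, collapse = ", "),
      "; states: ", paste(x$state_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Check F / gradF consistency by finite differences
#'
#' Compares each analytic gradient \eqn{\nabla F_j} against central finite
#' differences of column `j` of `F` at the supplied states.
#'
#' @param system An `ode_system`.
#' @param states A list of state vectors to test at.
#' @param h Finite-difference step.
#' @return The maximum absolute discrepancy over all states, columns and
#'   entries.
#' @export
check_gradients <- function(system, states, h = 1e-6) {
  worst <- 0
  for (x in states) {
    for (j in seq_len(system$q)) {
      G <- system$gradF[[j]](x)
      num <- matrix(0, system$p, system$p)
      for (k in seq_len(system$p)) {
        e <- rep(0, system$p); e[k] <- h
        num[, k] <- (system$F(x + e)[, j] - system$F(x - e)[, j]) / (2 * h)
      }
      worst <- max(worst, max(abs(G - num)))
    }
  }
  worst
}

#' Predefined system: all-cause survival
#'
#' \eqn{S(t) = 1 - \int_0^t S(s)\,dA(s)} with the all-cause cumulative
#' hazard as the single integrator; the plug-in solution driven by the
#' Nelson-Aalen estimate is exactly the Kaplan-Meier estimator.
#'
#' @return A list with elements `system` (an [ode_system()]),
#'   `component_roles` naming the state entries, and `required_hazards`
#'   (here `"all"`, no time component).
#' @export
survival_system <- function() {
  sys <- ode_system(
    x0 = 1,
    F = function(x) matrix(-x[1], 1, 1),
    gradF = list(function(x) matrix(-1, 1, 1)),
    components = "all",
    state_names = "S"
  )
  list(system = sys, component_roles = c(S = 1L),
       required_hazards = "all", needs_time = FALSE)
}

#' Predefined system: cumulative incidence functions
#'
#' State \eqn{(S, C^c, C^o)} driven by the cause-specific cumulative
#' hazards: \eqn{dS = -S\,dA^c - S\,dA^o}, \eqn{dC^c = S\,dA^c},
#' \eqn{dC^o = S\,dA^o}, with \eqn{X(0) = (1, 0, 0)}.  The plug-in
#' solution gives the Aalen-Johansen-type estimators
#' \eqn{\hat C(t) = \int_0^t \hat S(s-)\,d\hat A(s)} and conserves
#' \eqn{S + C^c + C^o = 1}.
#'
#' @return A bundle as in [survival_system()].
#' @export
cif_system <- function() {
  sys <- ode_system(
    x0 = c(1, 0, 0),
    F = function(x) matrix(c(-x[1], x[1], 0,
                             -x[1], 0, x[1]), nrow = 3, ncol = 2),
    gradF = list(
      function(x) matrix(c(-1, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3),
      function(x) matrix(c(-1, 0, 1, 0, 0, 0, 0, 0, 0), 3, 3)
    ),
    components = c("cancer", "other"),
    state_names = c("S", "Cc", "Co")
  )
  list(system = sys, component_roles = c(S = 1L, Cc = 2L, Co = 3L),
       required_hazards = c("cancer", "other"), needs_time = FALSE)
}

#' Predefined system: survival and its running integral
#'
#' State \eqn{(S, R)} with \eqn{R(t) = \int_0^t S(s)\,ds}: \eqn{dS = -S\,dA}
#' (all-cause hazard) and \eqn{dR = S\,dt} (reserved time component).
#' Feeds restricted mean residual lifetime
#' \eqn{(R(t+\Delta)-R(t))/S(t)}.
#'
#' @return A bundle as in [survival_system()]; `required_hazards` is
#'   `c("all", "time")`, so drive it with [augment_time_component()].
#' @export
rmrl_system <- function() {
  sys <- ode_system(
    x0 = c(1, 0),
    F = function(x) matrix(c(-x[1], 0,
                             0, x[1]), nrow = 2, ncol = 2),
    gradF = list(
      function(x) matrix(c(-1, 0, 0, 0), 2, 2),
      function(x) matrix(c(0, 1, 0, 0), 2, 2)
    ),
    components = c("all", "time"),
    state_names = c("S", "R")
  )
  list(system = sys, component_roles = c(S = 1L, R = 2L),
       required_hazards = c("all", "time"), needs_time = TRUE)
}
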