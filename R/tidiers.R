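#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a solved plug-in path
#'
#' @param x A `plugin_path`.
#' @param ... Unused.
#' @return A long tibble with columns `time`, `state`, `estimate` and
#'   (when the covariance path has been solved) `variance`, the diagonal
#'   of \eqn{\hat V(t)/n}.
#' @method tidy plugin_path
#' @export
tidy.plugin_path <- function(x, ...) {
  states <- x$system$state_names
  out <- purrr::map_dfr(seq_along(states), function(j) {
    tibble::tibble(
      time = x$time, state = states[j], estimate = x$x[, j],
      variance = if (!is.null(x$v)) x$v[j, j, ] / x$n else NA_real_
    )
  })
  out
}

#' One-row summary of a solved plug-in path
#'
#' @param x A `plugin_path`.
#' @param ... Unused.
#' @return A tibble with the cohort size, state dimension, number of
#'   integrator components, number of grid times and horizon.
#' @method glance plugin_path
#' @export
glance.plugin_path <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = x$system$p, q = x$system$q,
    n_grid = length(x$time), horizon = max(x$time),
    has_covariance = !is.null(x$v)
  )
}

#' Tidy a prognosis curve
#'
#' @param x A `prognosis_curve`.
#' @param ... Unused.
#' @return A plain tibble with the curve columns plus `label`.
#' @method tidy prognosis_curve
#' @export
tidy.prognosis_curve <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$label <- attr(x, "label")
  out
}

#' One-row summary of a prognosis curve
#'
#' @param x A `prognosis_curve`.
#' @param ... Unused.
#' @return A tibble with the label, `delta`, grid size, number of defined
#'   points and the estimate range.
#' @method glance prognosis_curve
#' @export
glance.prognosis_curve <- function(x, ...) {
  ok <- x$defined & is.finite(x$estimate)
  tibble::tibble(
    label = attr(x, "label"), delta = attr(x, "delta"),
    n_points = nrow(x), n_defined = sum(ok),
    min_estimate = if (any(ok)) min(x$estimate[ok]) else NA_real_,
    max_estimate = if (any(ok)) max(x$estimate[ok]) else NA_real_
  )
}
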