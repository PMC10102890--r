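#' @keywords internal
new_step_hazard <- function(time, inc, at_risk, n, time_component = NA_character_) {
  stopifnot(is.matrix(inc), nrow(inc) == length(time),
            length(at_risk) == length(time))
  if (length(time) > 1 && any(diff(time) <= 0)) {
    stop("jump times must be strictly increasing.", call. = FALSE)
  }
  structure(
    list(time = as.numeric(time), inc = inc, at_risk = as.numeric(at_risk),
         n = as.integer(n), time_component = time_component),
    class = "step_hazard"
  )
}

#' Nelson-Aalen cumulative hazard estimation
#'
#' Computes the Nelson-Aalen step-function estimate
#' \eqn{\hat A^j(t) = \sum_{s \le t} dN^j(s) / Y(s)} for the requested
#' cause(s) on the pooled grid of event times.  Simultaneous events at a
#' time are pooled (\eqn{dN > 1} allowed); subjects censored exactly at an
#' event time are still counted in the risk set \eqn{Y(s)} (events are
#' processed before censorings).
#'
#' @param cohort A cohort data frame (see [as_cohort()]).
#' @param causes Either `"all"` (codes 1 and 2 pooled into a single
#'   all-cause component labelled `"all"`) or a subset of `c(1, 2)`
#'   yielding cause-specific components labelled `"cancer"` and `"other"`.
#' @return A `step_hazard`: jump times, per-component increments, at-risk
#'   counts and the cohort size. A cohort with no qualifying events yields
#'   a valid hazard with zero jumps.
#' @examples
#' toy <- data.frame(time = c(1, 2, 3, 4), event = c(1, 0, 2, 1))
#' nelson_aalen(toy)                  # all-cause
#' nelson_aalen(toy, causes = c(1, 2))  # cause-specific
#' @export
nelson_aalen <- function(cohort, causes = "all") {
  cohort <- as_cohort(cohort)
  n <- nrow(cohort)
  if (identical(causes, "all")) {
    comp <- list(all = c(1L, 2L))
  } else {
    causes <- sort(unique(as.integer(causes)))
    if (!all(causes %in% c(1L, 2L)) || length(causes) == 0) {
      stop("`causes` must be \"all\" or a subset of c(1, 2).", call. = FALSE)
    }
    comp <- stats::setNames(as.list(causes),
                            c("cancer", "other")[causes])
  }
  pooled <- unique(unlist(comp))
  ev_times <- sort(unique(cohort$time[cohort$event %in% pooled]))
  K <- length(ev_times)
  inc <- matrix(0, nrow = K, ncol = length(comp),
                dimnames = list(NULL, names(comp)))
  if (K > 0) {
    # Y(s) = number with follow-up >= s (censoring ties stay at risk)
    at_risk <- vapply(ev_times, function(s) sum(cohort$time >= s), numeric(1))
    for (j in seq_along(comp)) {
      dn <- vapply(ev_times, function(s) {
        sum(cohort$time == s & cohort$event %in% comp[[j]])
      }, numeric(1))
      inc[, j] <- dn / at_risk
    }
  } else {
    at_risk <- numeric(0)
  }
  new_step_hazard(ev_times, inc, at_risk, n)
}

#' Add a time-driven integrator component on an augmented grid
#'
#' Parameters that integrate against `dt` (for example the running integral
#' of survival feeding restricted mean residual lifetime) need the driving
#' step function to carry a reserved `"time"` component whose increment at
#' each grid point equals the elapsed time since the previous grid point.
#' The event grid is united with a regular mesh so that the time component
#' advances even where no events occur.
#'
#' @param hazard A `step_hazard`.
#' @param mesh_step Regular mesh spacing in years (default 0.01).
#' @param horizon Final grid time; defaults to the last jump time.
#' @return A `step_hazard` on the union grid with the extra `"time"`
#'   column; original hazard components keep their jumps and are zero at
#'   mesh-only points.
#' @export
augment_time_component <- function(hazard, mesh_step = 0.01, horizon = NULL) {
  stopifnot(inherits(hazard, "step_hazard"))
  if (!is.na(hazard$time_component)) {
    stop("hazard already carries a time component.", call. = FALSE)
  }
  if (!is.numeric(mesh_step) || mesh_step <= 0) {
    stop("`mesh_step` must be a positive number of years.", call. = FALSE)
  }
  if (is.null(horizon)) {
    horizon <- if (length(hazard$time) > 0) max(hazard$time) else
      stop("`horizon` must be given for a hazard with no jumps.", call. = FALSE)
  }
  mesh <- seq(0, horizon, by = mesh_step)[-1]
  keep <- hazard$time <= horizon
  grid <- sort(unique(c(hazard$time[keep], mesh, horizon)))
  K <- length(grid)
  q0 <- ncol(hazard$inc)
  inc <- matrix(0, nrow = K, ncol = q0 + 1,
                dimnames = list(NULL, c(colnames(hazard$inc), "time")))
  idx <- match(hazard$time[keep], grid)
  if (length(idx) > 0) inc[idx, seq_len(q0)] <- hazard$inc[keep, , drop = FALSE]
  inc[, q0 + 1] <- diff(c(0, grid))
  # at-risk carried forward from the last event time (cosmetic between jumps)
  at_risk <- rep(hazard$n, K)
  if (length(hazard$time) > 0) {
    pos <- findInterval(grid, hazard$time)
    at_risk[pos > 0] <- hazard$at_risk[pos[pos > 0]]
  }
  new_step_hazard(grid, inc, at_risk, hazard$n, time_component = "time")
}

#' @export
print.step_hazard <- function(x, ...) {
  comps <- colnames(x$inc)
  cat("<step_hazard> ", length(x$time), " grid points, components: ",
      paste(comps, collapse = ", "), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Tidy a step hazard into a long tibble
#'
#' @param x A `step_hazard`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `component`, `increment`,
#'   `cumulative` and `at_risk`.
#' @method tidy step_hazard
#' @export
tidy.step_hazard <- function(x, ...) {
  comps <- colnames(x$inc)
  purrr::map_dfr(comps, function(cmp) {
    tibble::tibble(
      time = x$time,
      component = cmp,
      increment = x$inc[, cmp],
      cumulative = cumsum(x$inc[, cmp]),
      at_risk = x$at_risk
    )
  })
}

#' Write a step hazard to delimited text
#'
#' Long format, one row per (time, component): columns `time`, `component`,
#' `increment`, `at_risk`.
#'
#' @param hazard A `step_hazard`.
#' @param file Output path.
#' @param delim Field delimiter.
#' @return `file`, invisibly.
#' @export
write_step_hazard <- function(hazard, file, delim = ",") {
  out <- tidy.step_hazard(hazard)[, c("time", "component", "increment", "at_risk")]
  readr::write_delim(out, file, delim = delim)
  invisible(file)
}
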