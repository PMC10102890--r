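#' Validate a cohort of right-censored competing-risks records
#'
#' A cohort is an ordinary data frame with one row per subject.  Required
#' columns are `time` (years since diagnosis, nonnegative) and `event`
#' (0 = censored, 1 = death from the target cancer, 2 = death from other
#' causes).  Demographic columns `age_dx` (age at diagnosis in years),
#' `sex` (`"F"`/`"M"`) and `year_dx` (calendar year of diagnosis) are
#' required only by population-matching functions and are passed through
#' untouched here.
#'
#' @param x A data frame with at least columns `time` and `event`.
#' @return A tibble with the validated columns, invisibly classed as a
#'   cohort. Throws an error on an empty cohort or malformed codes.
#' @examples
#' as_cohort(data.frame(time = c(1, 2, 3, 4), event = c(1, 0, 1, 1)))
#' @export
as_cohort <- function(x) {
  if (!is.data.frame(x)) {
    stop("`x` must be a data frame with columns `time` and `event`.", call. = FALSE)
  }
  missing_cols <- setdiff(c("time", "event"), names(x))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) stop("cohort is empty: at least one record is required.", call. = FALSE)
  if (any(!is.finite(x$time)) || any(x$time < 0)) {
    stop("`time` must be finite and nonnegative for every record.", call. = FALSE)
  }
  if (!all(x$event %in% c(0L, 1L, 2L))) {
    stop("`event` must be coded 0 (censored), 1 (cancer death) or 2 (other death).",
         call. = FALSE)
  }
  x$event <- as.integer(x$event)
  if ("sex" %in% names(x)) {
    sx <- as.character(x$sex)
    if (!all(sx %in% c("F", "M"))) {
      stop("`sex` must be coded \"F\"/\"M\".", call. = FALSE)
    }
    x$sex <- sx
  }
  x
}

#' Read a cohort from delimited text
#'
#' Expects header columns `id`, `time`, `event`, `age_dx`, `sex`, `year_dx`
#' (the demographic columns may be absent when only cohort-internal
#' parameters are needed); `event` is coded 0/1/2 and `sex` M/F.
#'
#' @param file Path to a delimited text file.
#' @param delim Field delimiter (default comma).
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(file, delim = ",") {
  x <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  bad <- setdiff(c("time", "event"), names(x))
  if (length(bad) > 0) {
    stop("cohort file ", file, " is missing column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  as_cohort(x)
}

#' Write a cohort to delimited text
#'
#' @param cohort A cohort data frame.
#' @param file Output path.
#' @param delim Field delimiter.
#' @return `file`, invisibly.
#' @export
write_cohort <- function(cohort, file, delim = ",") {
  cohort <- as_cohort(cohort)
  if (!"id" %in% names(cohort)) {
    cohort <- dplyr::mutate(cohort, id = dplyr::row_number(), .before = 1)
  }
  readr::write_delim(cohort, file, delim = delim)
  invisible(file)
}
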