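#' Sampling design of a time-series expression experiment
#'
#' A sampling design records the time grid on which every profile of an
#' experiment was measured, together with the single specified oscillation
#' period of interest (the cell-cycle or circadian period, typically estimated
#' upstream or taken from the source study) and the nominal sampling interval.
#'
#' @param times Numeric vector of sample times, strictly increasing. Units are
#'   whatever `unit` says (minutes for cell-cycle designs, hours for circadian
#'   designs); all downstream arithmetic only requires that `times`, `period`
#'   and `interval` share the unit.
#' @param period Specified oscillation period, same unit as `times`. Must be
#'   positive.
#' @param interval Nominal spacing between consecutive samples. Defaults to
#'   the median of `diff(times)`, which equals the true spacing for the
#'   regular grids used in practice.
#' @param unit Time unit label, recorded for printing only.
#'
#' @return An object of class `sampling_design`: a list with elements
#'   `times`, `period`, `interval`, `duration` (last time minus first) and
#'   `unit`.
#' @examples
#' sampling_design(seq(0, 240, by = 16), period = 94, unit = "min")
#' @export
sampling_design <- function(times, period, interval = NULL, unit = "min") {
  if (!is.numeric(times) || length(times) < 2L) {
    stop("`times` must be a numeric vector with at least two sample times.", call. = FALSE)
  }
  if (anyNA(times) || is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing and free of missing values.", call. = FALSE)
  }
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) || period <= 0) {
    stop("`period` must be a single positive number.", call. = FALSE)
  }
  if (is.null(interval)) interval <- stats::median(diff(times))
  if (!is.numeric(interval) || length(interval) != 1L || !is.finite(interval) || interval <= 0) {
    stop("`interval` must be a single positive number.", call. = FALSE)
  }
  structure(
    list(
      times = as.numeric(times),
      period = as.numeric(period),
      interval = as.numeric(interval),
      duration = as.numeric(times[length(times)] - times[1L]),
      unit = unit
    ),
    class = "sampling_design"
  )
}

#' @export
print.sampling_design <- function(x, ...) {
  cat(
    sprintf(
      "<sampling_design> %d timepoints over %g %s (interval %g, period %g, %.4g timepoints/cycle)\n",
      length(x$times), x$duration, x$unit, x$interval, x$period,
      timepoints_per_cycle(x)
    )
  )
  invisible(x)
}

#' Timepoints per oscillation cycle
#'
#' The ratio of the specified period to the sampling interval: how many
#' samples fall within one full cycle. Returned as the exact ratio, never
#' rounded, because non-integer designs (e.g. a 94-minute period sampled
#' every 16 minutes gives 5.875) are common and must be carried exactly.
#' The ratio is invariant to rescaling period and interval by a common
#' unit-conversion factor.
#'
#' @param design A [sampling_design()].
#' @return A single number, `period / interval`.
#' @examples
#' timepoints_per_cycle(sampling_design(seq(0, 240, 16), period = 94))
#' @export
timepoints_per_cycle <- function(design) {
  stopifnot(inherits(design, "sampling_design"))
  design$period / design$interval
}
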