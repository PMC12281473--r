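#' Breathing-gas schedule for a gas-challenge experiment
#'
#' Describes the ordered sequence of breathing (or flow) gases during a
#' scan as contiguous, non-overlapping time intervals. The canonical
#' paradigm is air for an initial baseline, a hyperoxic challenge
#' (carbogen, 95% O2 + 5% CO2, or 100% O2), and optionally a return to
#' air. A frame whose start time falls in an interval is assigned that
#' interval's gas (left-closed intervals).
#'
#' @param start_min,end_min numeric vectors of interval bounds (minutes).
#' @param gas character gas names (e.g. "air", "carbogen", "oxygen",
#'   "nitrogen").
#' @param o2_fraction dry-gas O2 fractions in `[0, 1]`.
#' @param total_pressure_mmHg total pressure, default 760 mmHg.
#' @return An object of class `gas_schedule` (a data.frame).
#' @examples
#' sched <- gas_schedule(c(0, 5, 10), c(5, 10, 15),
#'                       c("air", "carbogen", "air"),
#'                       c(0.21, 0.95, 0.21))
#' gas_at(sched, 5)   # left-closed: the switch frame is carbogen
#' @export
gas_schedule <- function(start_min, end_min, gas, o2_fraction,
                         total_pressure_mmHg = 760) {
  n <- length(start_min)
  if (n == 0) stop("a gas schedule needs at least one interval")
  stopifnot(length(end_min) == n, length(gas) == n,
            length(o2_fraction) == n)
  if (any(end_min <= start_min))
    stop("each interval must have end > start")
  if (n > 1 && any(abs(start_min[-1] - end_min[-n]) > 1e-9))
    stop("intervals must be contiguous and non-overlapping")
  if (any(o2_fraction < 0 | o2_fraction > 1))
    stop("O2 fractions must lie in [0, 1]")
  if (any(total_pressure_mmHg <= 0))
    stop("total pressure must be positive")
  structure(
    data.frame(start_min = as.numeric(start_min),
               end_min = as.numeric(end_min),
               gas = as.character(gas),
               o2_fraction = as.numeric(o2_fraction),
               total_pressure_mmHg = rep_len(total_pressure_mmHg, n),
               stringsAsFactors = FALSE),
    class = c("gas_schedule", "data.frame"))
}

#' Index of the schedule interval active at given times
#'
#' Intervals are left-closed: a time equal to a switch belongs to the
#' interval that starts there. Times at or beyond the final end time map
#' to the last interval.
#'
#' @param schedule a `gas_schedule`.
#' @param time_min numeric times in minutes.
#' @return Integer interval indices.
#' @export
interval_at <- function(schedule, time_min) {
  stopifnot(inherits(schedule, "gas_schedule"))
  idx <- findInterval(time_min, schedule$start_min)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(schedule)] <- nrow(schedule)
  idx
}

#' Gas name active at given times
#' @inheritParams interval_at
#' @return Character gas names.
#' @export
gas_at <- function(schedule, time_min)
  schedule$gas[interval_at(schedule, time_min)]

#' Partial pressure of O2 in a dry breathing gas
#'
#' pO2 = O2 fraction x total pressure; no water-vapour correction is
#' applied (dry-gas convention, which reproduces the phantom calibration
#' slopes from tabulated R1 values).
#'
#' @param o2_fraction O2 fraction(s) in `[0, 1]`.
#' @param total_pressure_mmHg total pressure, default 760 mmHg.
#' @return pO2 in mmHg.
#' @examples
#' gas_po2(0.21)  # air: 159.6 mmHg
#' gas_po2(0.95)  # carbogen: 722 mmHg
#' @export
gas_po2 <- function(o2_fraction, total_pressure_mmHg = 760) {
  if (any(!is.finite(o2_fraction)) ||
      any(o2_fraction < 0 | o2_fraction > 1))
    stop("O2 fraction must lie in [0, 1]")
  if (any(total_pressure_mmHg <= 0))
    stop("total pressure must be positive")
  o2_fraction * total_pressure_mmHg
}

#' @export
print.gas_schedule <- function(x, ...) {
  cat(sprintf("<gas_schedule> %d interval(s), %.3g-%.3g min\n",
              nrow(x), min(x$start_min), max(x$end_min)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
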