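#' Event sequences of foragers crossing the nest boundary
#'
#' An event sequence is the basic observational unit of colony foraging
#' activity: the ordered times (seconds) at which foragers cross a reference
#' line near the nest entrance, either inward (`"in"`) or outward (`"out"`).
#' It is stored as a tibble with a single `time_s` column plus a `label`
#' attribute, so it composes with dplyr verbs while retaining its identity.
#'
#' Simultaneous events are permitted (multiplicity is meaningful: merged or
#' thinned point processes can collide timestamps).
#'
#' @param times Numeric vector of event times in seconds, finite and
#'   nonnegative. Sorted on construction; a warning is issued if the input
#'   was out of order.
#' @param label Direction of the events, `"in"` or `"out"`.
#' @return A tibble of class `event_sequence` with column `time_s`.
#' @examples
#' ev <- event_sequence(c(3, 1, 2), label = "in")
#' ev$time_s
#' @export
event_sequence <- function(times = numeric(), label = c("in", "out")) {
  label <- match.arg(label)
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) {
    abort("event times must be finite")
  }
  if (any(times < 0)) {
    abort("event times must be nonnegative")
  }
  if (is.unsorted(times)) {
    warn("event times were not sorted; sorting")
    times <- sort(times)
  }
  out <- tibble(time_s = times)
  class(out) <- c("event_sequence", class(out))
  attr(out, "label") <- label
  out
}

#' @export
print.event_sequence <- function(x, ...) {
  cat(sprintf("<event_sequence '%s': %d events", attr(x, "label"), nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf(" over [%.6g, %.6g] s", min(x$time_s), max(x$time_s)))
  }
  cat(">\n")
  invisible(x)
}

event_times <- function(x) {
  if (inherits(x, "event_sequence") || is.data.frame(x)) {
    return(as.numeric(x$time_s))
  }
  as.numeric(x)
}

#' Sliding-window estimate of an instantaneous foraging rate
#'
#' Estimates the instantaneous event rate (ants/sec) by counting events in a
#' boxcar window of width `window` centred on each grid time and dividing by
#' the covered window length. Near the edges of the record the window is
#' truncated to the observed span and the actual covered length is used as
#' the denominator, which avoids the artificial ramp a fixed denominator
#' would create at the ends of a recording.
#'
#' @param events An [event_sequence()] (or data frame with `time_s`).
#' @param grid Numeric vector of times (seconds) at which to evaluate the
#'   rate; must be sorted.
#' @param window Window width in seconds (default 300, the standard
#'   field-analysis choice).
#' @param t_start,t_end Extent of the record used for edge truncation;
#'   default to the range of `grid`.
#' @return A tibble of class `rate_series` with columns `time_s` and `rate`,
#'   and a `window` attribute.
#' @examples
#' ev <- generate_poisson_events(0.5, 3600)
#' rs <- estimate_rate(ev, grid = seq(0, 3600, by = 60))
#' mean(rs$rate)
#' @export
estimate_rate <- function(events, grid, window = 300,
                          t_start = NULL, t_end = NULL) {
  if (!is.numeric(window) || length(window) != 1 || window <= 0) {
    abort("`window` must be a single positive number")
  }
  grid <- as.numeric(grid)
  if (is.unsorted(grid)) abort("`grid` must be sorted")
  if (is.null(t_start)) t_start <- min(grid)
  if (is.null(t_end)) t_end <- max(grid)
  times <- sort(event_times(events))
  h <- window / 2
  lo <- pmax(grid - h, t_start)
  hi <- pmin(grid + h, t_end)
  covered <- pmax(hi - lo, .Machine$double.eps)
  # count events with lo <= t <= hi (left.open makes the second term #{t < lo})
  n <- findInterval(hi, times) - findInterval(lo, times, left.open = TRUE)
  out <- tibble(time_s = grid, rate = n / covered)
  class(out) <- c("rate_series", class(out))
  attr(out, "window") <- window
  out
}

#' Cumulative count of foragers currently outside the nest
#'
#' Running difference between the number of outgoing and incoming events up
#' to each grid time, `(#out <= t) - (#in <= t)`. With this sign convention
#' the series equals the number of foragers currently outside the nest in a
#' closed-loop run in which every simulated departure is matched by a later
#' return (field analyses often plot the same quantity up to sign).
#'
#' @param in_events,out_events Incoming and outgoing [event_sequence()]s.
#' @param grid Times (seconds) at which to evaluate the count.
#' @return A tibble with columns `time_s` and `n_outside` (integer-valued).
#' @export
cumulative_outside <- function(in_events, out_events, grid) {
  grid <- as.numeric(grid)
  t_in <- event_times(in_events)
  t_out <- event_times(out_events)
  tibble(time_s = grid,
         n_outside = findInterval(grid, t_out) - findInterval(grid, t_in))
}

#' Generate a homogeneous Poisson event sequence
#'
#' Fixture generator for synthetic incoming streams: exponential inter-event
#' times with mean `1/rate`, truncated to `duration` seconds. Uses the
#' current R random-number state; call `set.seed()` first for
#' reproducibility.
#'
#' @param rate Event rate in ants/sec (`rate >= 0`; 0 gives an empty
#'   sequence).
#' @param duration Length of the generated record in seconds.
#' @param label Direction label for the resulting sequence.
#' @return An [event_sequence()].
#' @examples
#' set.seed(1)
#' ev <- generate_poisson_events(1, 100)
#' @export
generate_poisson_events <- function(rate, duration, label = "in") {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0) {
    abort("`rate` must be a single nonnegative number")
  }
  if (!is.numeric(duration) || length(duration) != 1 || duration < 0) {
    abort("`duration` must be a single nonnegative number")
  }
  if (rate == 0 || duration == 0) {
    return(event_sequence(numeric(), label = label))
  }
  # draw with headroom, extend in the rare case the record is not covered
  times <- numeric(0)
  t_last <- 0
  repeat {
    n_draw <- max(16, ceiling((duration - t_last) * rate * 1.2 + 10))
    times <- c(times, t_last + cumsum(rexp(n_draw, rate)))
    t_last <- times[length(times)]
    if (t_last > duration) break
  }
  event_sequence(times[times <= duration], label = label)
}
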