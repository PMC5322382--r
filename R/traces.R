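#' Uniformly sampled force trace
#'
#' The basic substrate for all onset detection: a single-channel force
#' series sampled at a fixed rate.  No per-sample timestamps are stored;
#' sample \code{i} (1-based) lies at \code{t0 + (i - 1) / rate_hz} seconds
#' from run start.
#'
#' @param samples numeric vector of force values.
#' @param rate_hz sampling frequency in Hz (> 0).
#' @param channel one of \code{"left_foot"}, \code{"right_foot"},
#'   \code{"touch"}, \code{"f_ml"}.
#' @param t0 time of the first sample, seconds from run start.
#' @param units unit tag, by default newtons.
#' @return an object of class \code{force_trace}.
#' @export
force_trace <- function(samples, rate_hz, channel, t0 = 0, units = "N") {
  channel <- match.arg(channel, c("left_foot", "right_foot", "touch", "f_ml"))
  stopifnot(is.numeric(samples), length(samples) >= 1L,
            is.numeric(rate_hz), length(rate_hz) == 1L, rate_hz > 0,
            is.numeric(t0), length(t0) == 1L, is.finite(t0))
  if (anyNA(samples)) stop("force_trace: samples contain NA")
  structure(
    list(samples = as.numeric(samples), rate_hz = as.numeric(rate_hz),
         channel = channel, t0 = as.numeric(t0), units = units),
    class = "force_trace"
  )
}

#' Antero-posterior marker displacement trace
#'
#' Displacement of the reflective marker on the right malleolus, in mm,
#' conventionally sampled at 200 Hz.
#'
#' @param displacement numeric vector, mm.
#' @param rate_hz sampling frequency in Hz.
#' @param t0 time of the first sample (s from run start).
#' @return an object of class \code{marker_trace}.
#' @export
marker_trace <- function(displacement, rate_hz = 200, t0 = 0) {
  stopifnot(is.numeric(displacement), length(displacement) >= 1L,
            is.numeric(rate_hz), length(rate_hz) == 1L, rate_hz > 0)
  if (anyNA(displacement)) stop("marker_trace: displacement contains NA")
  structure(
    list(samples = as.numeric(displacement), rate_hz = as.numeric(rate_hz),
         channel = "marker_ap", t0 = as.numeric(t0), units = "mm"),
    class = "marker_trace"
  )
}

#' Sample times of a trace
#' @param trace a \code{force_trace} or \code{marker_trace}.
#' @return numeric vector of times (s from run start), one per sample.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$rate_hz
}

#' End time of a trace (time just past the last sample)
#' @param trace a trace object.
#' @return numeric scalar, seconds.
#' @export
trace_end <- function(trace) {
  trace$t0 + length(trace$samples) / trace$rate_hz
}

# indices of samples with t in [start, end)
.window_idx <- function(trace, window) {
  stopifnot(is.numeric(window), length(window) == 2L, window[1] < window[2])
  tt <- trace_times(trace)
  which(tt >= window[1] & tt < window[2])
}

# closed variant [start, end] (with half-sample tolerance) used for
# integration, where both endpoint samples must contribute
.window_idx_closed <- function(trace, window) {
  stopifnot(is.numeric(window), length(window) == 2L, window[1] < window[2])
  tt <- trace_times(trace)
  eps <- 1e-9 / trace$rate_hz
  which(tt >= window[1] - eps & tt <= window[2] + eps)
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> channel=%s  %d samples @ %g Hz  t0=%.3f s  [%s]\n",
              x$channel, length(x$samples), x$rate_hz, x$t0, x$units))
  invisible(x)
}

#' @export
print.marker_trace <- function(x, ...) {
  cat(sprintf("<marker_trace> %d samples @ %g Hz  t0=%.3f s  [mm]\n",
              length(x$samples), x$rate_hz, x$t0))
  invisible(x)
}

#' Baseline/movement analysis windows for one trial
#'
#' Closed-open intervals \code{[start, end)} in seconds from run start.
#' The baseline window (the instructed relax period) must precede the
#' movement window.
#'
#' @param baseline numeric length-2, \code{c(start, end)}.
#' @param movement numeric length-2, \code{c(start, end)}.
#' @return an object of class \code{trial_window}.
#' @export
trial_window <- function(baseline, movement) {
  stopifnot(is.numeric(baseline), length(baseline) == 2L,
            is.numeric(movement), length(movement) == 2L)
  if (baseline[1] >= baseline[2] || movement[1] >= movement[2])
    stop("trial_window: windows must be non-empty [start, end)")
  if (baseline[2] > movement[1])
    stop("trial_window: baseline must precede movement")
  structure(list(baseline = as.numeric(baseline),
                 movement = as.numeric(movement)),
            class = "trial_window")
}

#' One trial's synchronized recording
#'
#' Bundles the traces of one trial (or a full run), the cue/trigger event
#' table, and — for simulated data — the ground-truth metadata enabling
#' parameter-recovery tests.
#'
#' @param traces named list of \code{force_trace}/\code{marker_trace}
#'   objects, named by channel.
#' @param events an \code{event_table} (may have zero rows).
#' @param ground_truth optional list of true onsets/parameters.
#' @param meta optional free-form metadata list.
#' @return an object of class \code{trial_recording}.
#' @export
trial_recording <- function(traces, events = empty_events(),
                            ground_truth = NULL, meta = list()) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  ok <- vapply(traces, function(x)
    inherits(x, "force_trace") || inherits(x, "marker_trace"), logical(1))
  if (!all(ok)) stop("trial_recording: traces must be force/marker traces")
  if (is.null(names(traces)) || any(names(traces) == ""))
    names(traces) <- vapply(traces, `[[`, character(1), "channel")
  structure(list(traces = traces, events = as_event_table(events),
                 ground_truth = ground_truth, meta = meta),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %d trace(s): %s; %d event(s)%s\n",
              length(x$traces), paste(names(x$traces), collapse = ", "),
              nrow(x$events),
              if (is.null(x$ground_truth)) "" else "; ground truth attached"))
  invisible(x)
}
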