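#' Emulate the real-time acquisition loop and force-drop trigger
#'
#' Replays the control box's online rule on a recorded (or simulated)
#' trial: the mean \code{m} and standard deviation \code{s} of the
#' moving-leg force are taken over a calibration window preceding the go
#' cue; scanning sample by sample from the go cue, the first sample with
#' force below \code{m - k_sd * s} raises a \code{trigger} event, and the
#' relax command is displayed \code{relax_delay} seconds later
#' (\code{relax_cmd} event).  If no sample crosses before the scheduled
#' go window ends, no events are emitted.
#'
#' A noise-free sensor would make the threshold unreachable (\code{s =
#' 0}); \code{s} is therefore floored at \code{sd_floor_frac} times the
#' absolute calibration mean.
#'
#' @param recording a \code{trial_recording} whose events contain the
#'   trial's \code{go_circle} row.
#' @param calibration_window length-2 numeric \code{[start, end)}, s;
#'   must precede the go cue and contain at least 5 samples.
#' @param channel moving-leg channel name (default \code{"right_foot"}).
#' @param k_sd threshold depth in calibration SDs (default 20).
#' @param relax_delay seconds from trigger to relax command.
#' @param sd_floor_frac SD floor as a fraction of |calibration mean|.
#' @return an \code{event_table} with 0 or 2 rows (\code{trigger},
#'   \code{relax_cmd}).
#' @export
run_acquisition_loop <- function(recording, calibration_window,
                                 channel = "right_foot", k_sd = 20,
                                 relax_delay = 0.5, sd_floor_frac = 0.005) {
  stopifnot(inherits(recording, "trial_recording"))
  tr <- recording$traces[[channel]]
  if (is.null(tr))
    stop("run_acquisition_loop: recording has no '", channel, "' channel")
  ev <- recording$events
  go <- ev[ev$trial_type == "go_circle", ]
  if (nrow(go) < 1) stop("run_acquisition_loop: no go_circle event")
  go_onset <- go$onset[1]
  go_end <- go_onset + go$duration[1]
  if (calibration_window[2] > go_onset)
    stop("run_acquisition_loop: calibration window must precede the go cue")

  cal_idx <- .window_idx(tr, calibration_window)
  if (length(cal_idx) < 5L)
    stop("run_acquisition_loop: calibration window has fewer than 5 samples")
  m <- mean(tr$samples[cal_idx])
  s <- stats::sd(tr$samples[cal_idx])
  s <- max(s, sd_floor_frac * abs(m))
  threshold <- m - k_sd * s

  tt <- trace_times(tr)
  scan_idx <- which(tt >= go_onset & tt < go_end)
  trigger_t <- NA_real_
  for (i in scan_idx) {          # sample-by-sample, as the online loop runs
    if (tr$samples[i] < threshold) {
      trigger_t <- tt[i]
      break
    }
  }
  if (is.na(trigger_t)) return(empty_events())
  idx <- go$trial_index[1]
  event_table(onset = c(trigger_t, trigger_t + relax_delay),
              duration = c(0, 0),
              trial_type = c("trigger", "relax_cmd"),
              trial_index = c(idx, idx))
}
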