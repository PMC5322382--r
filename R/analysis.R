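#' Baseline mean and SD of a trace window
#'
#' @param trace a \code{force_trace} or \code{marker_trace}.
#' @param window length-2 numeric \code{[start, end)}, s; must contain
#'   at least 5 samples and lie within the trace extent.
#' @return list with \code{mean}, \code{sd} (n-1 denominator) and
#'   \code{n}.
#' @export
baseline_stats <- function(trace, window) {
  if (window[1] < trace$t0 - 1e-9 || window[2] > trace_end(trace) + 1e-9)
    stop("baseline_stats: window outside trace extent")
  idx <- .window_idx(trace, window)
  if (length(idx) < 5L)
    stop("baseline_stats: window contains fewer than 5 samples")
  x <- trace$samples[idx]
  list(mean = mean(x), sd = stats::sd(x), n = length(idx))
}

#' Threshold-crossing onset detection
#'
#' First time within the window at which the signal stays beyond
#' \code{mean + k_sd * sd} (direction \code{"above"}) or
#' \code{mean - k_sd * sd} (\code{"below"}) for \code{hold} consecutive
#' samples.  Absence of a crossing is a value (\code{NA}), not an error.
#'
#' @param trace a trace object.
#' @param window length-2 numeric search window \code{[start, end)}, s.
#' @param mean,sd baseline statistics (from \code{\link{baseline_stats}}).
#' @param k_sd threshold in baseline SDs (default 2).
#' @param direction \code{"above"} or \code{"below"}.
#' @param hold required consecutive supra-threshold samples (>= 1);
#'   debounces spurious single-sample crossings on high-rate noisy
#'   signals.
#' @return onset time in seconds (time of the first sample of the run),
#'   or \code{NA_real_} if the signal never crosses.
#' @export
detect_crossing <- function(trace, window, mean, sd, k_sd = 2,
                            direction = c("above", "below"), hold = 1L) {
  direction <- match.arg(direction)
  stopifnot(sd >= 0, hold >= 1L)
  idx <- .window_idx(trace, window)
  if (length(idx) == 0) return(NA_real_)
  x <- trace$samples[idx]
  beyond <- if (direction == "above") x > mean + k_sd * sd
            else x < mean - k_sd * sd
  if (hold == 1L) {
    hit <- which(beyond)
    if (length(hit) == 0) return(NA_real_)
    first <- hit[1]
  } else {
    run <- 0L
    first <- NA_integer_
    for (i in seq_along(beyond)) {
      run <- if (beyond[i]) run + 1L else 0L
      if (run >= hold) { first <- i - hold + 1L; break }
    }
    if (is.na(first)) return(NA_real_)
  }
  trace_times(trace)[idx[first]]
}

# default debounce: ~100 ms of sustained crossing.  A fixed small sample
# count does not debounce band-limited noise, whose 2-SD excursions last
# tens of ms at any sampling rate; a duration-based hold does.
.default_hold <- function(rate_hz) max(1L, as.integer(round(0.1 * rate_hz)))

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) filtering so that onsets are not
#' delayed; the 10 Hz default matches the conventional treatment of
#' motion-capture marker trajectories.
#'
#' @param trace a \code{force_trace} or \code{marker_trace}.
#' @param cutoff_hz cutoff frequency, Hz; must be below Nyquist.
#' @param order filter order (default 4).
#' @return a trace of the same class, band-limited.
#' @export
lowpass_filter <- function(trace, cutoff_hz = 10, order = 4) {
  if (cutoff_hz >= trace$rate_hz / 2)
    stop("lowpass_filter: cutoff must be below the Nyquist frequency (",
         trace$rate_hz / 2, " Hz)")
  bf <- signal::butter(order, cutoff_hz / (trace$rate_hz / 2), type = "low")
  x <- trace$samples
  n <- length(x)
  # odd-reflection padding suppresses the start/end transients that
  # plain forward-backward filtering leaves on finite records
  np <- min(n - 1, ceiling(9 * trace$rate_hz / cutoff_hz))
  pre <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
  out <- trace
  out$samples <- y[(np + 1):(np + n)]
  out
}

#' APA quantification for one step-initiation trial
#'
#' APA onset is the first crossing of the medio-lateral force 2 SD above
#' its baseline mean; step onset is the first crossing of the marker's
#' antero-posterior displacement 2 SD above its baseline mean.  The APA
#' amplitude is the peak absolute deviation of the force from the
#' baseline mean within the APA interval, normalized by foot length
#' (N/cm).  Trials whose onsets cannot be detected, or where the step
#' does not follow the APA, are flagged invalid — never silently
#' dropped.
#'
#' @param fml medio-lateral \code{force_trace}.
#' @param marker antero-posterior \code{marker_trace}.
#' @param windows a \code{trial_window}.
#' @param foot_length_cm subject foot length, cm (> 0).
#' @param k_sd onset threshold in baseline SDs.
#' @param hold_force,hold_marker debounce holds in samples; default
#'   about 100 ms of sustained crossing at each trace's rate.
#' @param search_window window scanned for onsets, s; defaults to the
#'   movement window.  Restricting the search to start at the go cue
#'   avoids false crossings during the preparation period.
#' @return list of class \code{step_apa_result}: \code{apa_onset},
#'   \code{step_onset}, \code{apa_interval}, \code{fml_amplitude_norm}
#'   (N/cm), \code{valid}, \code{reason}.
#' @export
compute_step_apa <- function(fml, marker, windows, foot_length_cm,
                             k_sd = 2,
                             hold_force = .default_hold(fml$rate_hz),
                             hold_marker = .default_hold(marker$rate_hz),
                             search_window = windows$movement) {
  stopifnot(inherits(windows, "trial_window"))
  if (!is.numeric(foot_length_cm) || is.na(foot_length_cm) ||
      foot_length_cm <= 0)
    stop("compute_step_apa: foot_length_cm must be positive ",
         "(amplitude is normalized by the size of the foot)")
  bf <- baseline_stats(fml, windows$baseline)
  bm <- baseline_stats(marker, windows$baseline)
  apa_onset <- detect_crossing(fml, search_window, bf$mean, bf$sd,
                               k_sd, "above", hold_force)
  # the step can only follow the APA: once the APA onset is known, the
  # marker search starts there, which keeps noise-driven false step
  # onsets rare
  marker_window <- search_window
  if (!is.na(apa_onset))
    marker_window <- c(max(search_window[1], apa_onset), search_window[2])
  step_onset <- detect_crossing(marker, marker_window, bm$mean, bm$sd,
                                k_sd, "above", hold_marker)
  res <- list(apa_onset = apa_onset, step_onset = step_onset,
              apa_interval = NA_real_, fml_amplitude_norm = NA_real_,
              valid = FALSE, reason = NA_character_)
  class(res) <- "step_apa_result"
  if (is.na(apa_onset)) { res$reason <- "no APA onset detected"; return(res) }
  if (is.na(step_onset)) { res$reason <- "no step onset detected"; return(res) }
  if (step_onset <= apa_onset) {
    res$reason <- "step onset does not follow APA onset"
    return(res)
  }
  idx <- .window_idx(fml, c(apa_onset, step_onset + 0.5 / fml$rate_hz))
  res$apa_interval <- step_onset - apa_onset
  res$fml_amplitude_norm <-
    max(abs(fml$samples[idx] - bf$mean)) / foot_length_cm
  res$valid <- TRUE
  res
}

#' Force-magnitude percentage of a sub-interval
#'
#' Trapezoidal integral of the trace over \code{numer_window} divided by
#' its trapezoidal integral over \code{denom_window}, times 100.  For a
#' nonnegative trace with \code{numer_window} inside \code{denom_window}
#' the result lies in [0, 100] and is invariant under positive rescaling
#' of the force.  Unlike the closed-open slicing convention used for
#' detection, integration windows are closed \code{[start, end]}: both
#' endpoint samples contribute, so a sub-window covering a given
#' fraction of a constant trace yields exactly that fraction.
#'
#' @param trace a \code{force_trace}.
#' @param numer_window,denom_window length-2 numeric windows, s.
#' @return percentage (numeric scalar).
#' @export
force_magnitude_pct <- function(trace, numer_window, denom_window) {
  tt <- trace_times(trace)
  den_idx <- .window_idx_closed(trace, denom_window)
  num_idx <- .window_idx_closed(trace, numer_window)
  if (length(den_idx) < 2L)
    stop("force_magnitude_pct: denominator window has fewer than 2 samples")
  den <- pracma::trapz(tt[den_idx], trace$samples[den_idx])
  if (den <= 0)
    stop("force_magnitude_pct: whole-curve integral is not positive")
  num <- if (length(num_idx) < 2L) 0
         else pracma::trapz(tt[num_idx], trace$samples[num_idx])
  100 * num / den
}

#' APA quantification for one supine (scanner) trial
#'
#' APA onset is the crossing of the support (left) foot force 2 SD above
#' its baseline mean; leg-lift onset is the crossing of the moving
#' (right) foot force 2 SD below its baseline mean.  The force magnitude
#' is the trapezoidal integral of the left-foot force between the two
#' onsets, divided by the integral over the whole movement epoch, times
#' 100.  Raw (not baseline-subtracted) force enters both integrals.
#'
#' @param left support-foot \code{force_trace} (32 Hz).
#' @param right moving-foot \code{force_trace} (32 Hz).
#' @param windows a \code{trial_window}; the movement window doubles as
#'   the whole-curve epoch of the magnitude denominator.
#' @param k_sd onset threshold in baseline SDs.
#' @param hold debounce hold in samples (about 100 ms by default).
#' @param search_window window scanned for onsets, s; defaults to the
#'   movement window (start it at the go cue to exclude the preparation
#'   period from the search).
#' @return list of class \code{scanner_apa_result}: \code{apa_onset},
#'   \code{leglift_onset}, \code{force_magnitude_pct} (in [0, 100]),
#'   \code{apa_peak} (peak support-force deviation within the APA
#'   interval, N), \code{valid}, \code{reason}.
#' @export
compute_scanner_apa <- function(left, right, windows, k_sd = 2,
                                hold = .default_hold(left$rate_hz),
                                search_window = windows$movement) {
  stopifnot(inherits(windows, "trial_window"))
  bl <- baseline_stats(left, windows$baseline)
  br <- baseline_stats(right, windows$baseline)
  apa_onset <- detect_crossing(left, search_window, bl$mean, bl$sd,
                               k_sd, "above", hold)
  lift_onset <- detect_crossing(right, search_window, br$mean, br$sd,
                                k_sd, "below", hold)
  res <- list(apa_onset = apa_onset, leglift_onset = lift_onset,
              force_magnitude_pct = NA_real_, apa_peak = NA_real_,
              valid = FALSE, reason = NA_character_)
  class(res) <- "scanner_apa_result"
  if (is.na(apa_onset)) { res$reason <- "no APA onset detected"; return(res) }
  if (is.na(lift_onset)) {
    res$reason <- "no leg-lift onset detected"
    return(res)
  }
  if (lift_onset <= apa_onset) {
    res$reason <- "leg lift does not follow APA onset"
    return(res)
  }
  res$force_magnitude_pct <-
    force_magnitude_pct(left, c(apa_onset, lift_onset), windows$movement)
  # peak taken on a 3-sample moving average: the raw-sample maximum of a
  # noisy trace overestimates the peak by the expected extreme of the
  # sensor noise
  sm <- stats::filter(left$samples, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- left$samples[is.na(sm)]
  idx <- .window_idx(left, c(apa_onset, lift_onset + 0.5 / left$rate_hz))
  res$apa_peak <- max(sm[idx]) - bl$mean
  res$valid <- TRUE
  res
}

#' @export
print.step_apa_result <- function(x, ...) {
  if (x$valid)
    cat(sprintf(
      "<step_apa_result> APA %.3f s, step %.3f s (interval %.3f s), amplitude %.3f N/cm\n",
      x$apa_onset, x$step_onset, x$apa_interval, x$fml_amplitude_norm))
  else cat(sprintf("<step_apa_result> invalid trial: %s\n", x$reason))
  invisible(x)
}

#' @export
print.scanner_apa_result <- function(x, ...) {
  if (x$valid)
    cat(sprintf(
      "<scanner_apa_result> APA %.3f s, leg lift %.3f s, magnitude %.2f%%\n",
      x$apa_onset, x$leglift_onset, x$force_magnitude_pct))
  else cat(sprintf("<scanner_apa_result> invalid trial: %s\n", x$reason))
  invisible(x)
}
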