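#' @title Synthetic trial simulators
#' @description
#' The simulators generate recordings with the geometry of the two tasks
#' the force measurement system (FMS) is used for: supine leg raises in
#' the scanner (32 Hz foot sensors, touch bar) and upright step
#' initiation on a force platform (medio-lateral force plus an
#' antero-posterior malleolus marker).  Each trial carries ground truth
#' so detectors can be validated by parameter recovery.
#' @name simulate
NULL

# cubic smoothstep: 0 below 0, 1 above 1, C1-smooth in between
.smoothstep <- function(x) {
  y <- pmin(pmax(x, 0), 1)
  y * y * (3 - 2 * y)
}

# saturating exponential ramp starting at 0 with unit asymptote;
# nonzero initial slope gives the abrupt onset seen in force records
.expramp <- function(t, tau) {
  ifelse(t <= 0, 0, 1 - exp(-t / tau))
}

# piecewise-linear biphasic deflection, unit first lobe:
# linear rise to +1 (abrupt onset), plateau, reversal to -away, return to 0
.biphasic <- function(t, rise = 0.12, plateau = 0.08, cross = 0.18,
                      away = 0.5, away_plateau = 0.06, back = 0.18) {
  b1 <- rise; b2 <- b1 + plateau; b3 <- b2 + cross
  b4 <- b3 + away_plateau; b5 <- b4 + back
  w <- numeric(length(t))
  i <- t > 0 & t < b1;  w[i] <- t[i] / rise
  i <- t >= b1 & t < b2; w[i] <- 1
  i <- t >= b2 & t < b3; w[i] <- 1 - (1 + away) * (t[i] - b2) / cross
  i <- t >= b3 & t < b4; w[i] <- -away
  i <- t >= b4 & t < b5; w[i] <- -away * (1 - (t[i] - b4) / back)
  w
}

#' Supine leg-raise trial parameters
#'
#' Defaults describe a light heel contact on the thin-film foot sensors
#' (about 10 N per heel at rest), an anticipatory loading of the support
#' (left) foot of about 10 N developing with a 60 ms time constant, a
#' 250 ms lead of the APA over the leg lift, and an 80 percent force
#' drop under the moving (right) foot at lift.  In the supported
#' condition the anticipatory component is scaled by
#' \code{1 - suppression_factor}.
#'
#' @param baseline_left,baseline_right resting heel forces, N.
#' @param apa_amplitude peak anticipatory force increase on the support
#'   sensor, N.
#' @param apa_lead seconds between APA onset and leg-lift onset.
#' @param lift_drop_fraction fraction of moving-foot force lost at lift.
#' @param ramp_tau time constant of the force ramps, s.
#' @param noise_sd sensor noise SD, N.
#' @param condition \code{"unsupported"} (APA required) or
#'   \code{"supported"} (knee pad, APA suppressed).
#' @param suppression_factor fraction of the APA removed when supported,
#'   in [0, 1].
#' @param latency_range go-cue-to-APA reaction latency range, s
#'   (jittered uniformly per trial).
#' @param touch_delay seconds from lift onset to the foot reaching the
#'   restraint bar.
#' @param rate_hz sensor sampling rate, Hz.
#' @return a list of class \code{supine_trial_params}.
#' @export
supine_trial_params <- function(baseline_left = 10, baseline_right = 10,
                                apa_amplitude = 10, apa_lead = 0.25,
                                lift_drop_fraction = 0.8, ramp_tau = 0.06,
                                noise_sd = 0.2,
                                condition = c("unsupported", "supported"),
                                suppression_factor = 0.5,
                                latency_range = c(0.15, 0.40),
                                touch_delay = 0.12, rate_hz = 32) {
  condition <- match.arg(condition)
  stopifnot(baseline_left >= 0, baseline_right >= 0, apa_amplitude >= 0,
            apa_lead > 0, lift_drop_fraction >= 0, lift_drop_fraction <= 1,
            ramp_tau > 0, noise_sd >= 0,
            suppression_factor >= 0, suppression_factor <= 1,
            latency_range[1] <= latency_range[2], rate_hz > 0)
  structure(as.list(environment()), class = "supine_trial_params")
}

#' Simulate one supine leg-raise trial
#'
#' Produces the three FMS channels (left foot, right foot, touch) at the
#' sensor rate, the cue events of the trial, and ground truth.  The
#' support-foot trace rises by the (possibly suppressed) APA amplitude
#' from the true APA onset; the moving-foot trace drops by
#' \code{lift_drop_fraction} from the lift onset (APA onset plus
#' \code{apa_lead}); the touch channel switches on when the foot reaches
#' the bar.  Gaussian sensor noise is added to the force channels.
#'
#' @param params a \code{supine_trial_params}.
#' @param slice trial cue times, as returned by
#'   \code{\link{schedule_slice}}.
#' @param seed optional integer seed (fixes both the reaction-latency
#'   jitter and the noise).
#' @param tail_s extra recording time after the scheduled go window, s.
#' @return a \code{trial_recording} with \code{ground_truth}.
#' @export
simulate_supine_trial <- function(params, slice, seed = NULL, tail_s = 1.0) {
  stopifnot(inherits(params, "supine_trial_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  if (p$apa_lead < 2 / p$rate_hz)
    stop("simulate_supine_trial: apa_lead shorter than 2 sample periods; ",
         "the lift would be indistinguishable from the APA at this rate")
  latency <- stats::runif(1, p$latency_range[1], p$latency_range[2])
  apa_onset <- slice$go_onset + latency
  lift_onset <- apa_onset + p$apa_lead
  supp <- if (p$condition == "supported") p$suppression_factor else 0
  amp_eff <- p$apa_amplitude * (1 - supp)

  t0 <- slice$cross_onset
  t_end <- slice$trial_end + tail_s
  n <- ceiling((t_end - t0) * p$rate_hz)
  tt <- t0 + (seq_len(n) - 1) / p$rate_hz

  left <- p$baseline_left + amp_eff * .expramp(tt - apa_onset, p$ramp_tau)
  right <- p$baseline_right *
    (1 - p$lift_drop_fraction * .expramp(tt - lift_onset, p$ramp_tau))
  touch <- as.numeric(tt >= lift_onset + p$touch_delay)
  if (p$noise_sd > 0) {
    left <- left + stats::rnorm(n, 0, p$noise_sd)
    right <- right + stats::rnorm(n, 0, p$noise_sd)
  }

  events <- event_table(
    onset = c(slice$cross_onset, slice$prepare_onset, slice$go_onset),
    duration = c(slice$prepare_onset - slice$cross_onset,
                 slice$go_onset - slice$prepare_onset, slice$go_max),
    trial_type = c("cross", "prepare_circle", "go_circle"),
    trial_index = rep(1L, 3L))

  # noiseless peak of the anticipatory component realized inside the
  # APA interval (the quantity the peak detector can see)
  apa_window_peak <- amp_eff * .expramp(p$apa_lead, p$ramp_tau)

  trial_recording(
    traces = list(
      left_foot = force_trace(left, p$rate_hz, "left_foot", t0),
      right_foot = force_trace(right, p$rate_hz, "right_foot", t0),
      touch = force_trace(touch, p$rate_hz, "touch", t0, units = "bool")),
    events = events,
    ground_truth = list(task = "supine", condition = p$condition,
                        true_apa_onset = apa_onset,
                        true_lift_onset = lift_onset,
                        apa_amplitude_effective = amp_eff,
                        apa_window_peak = apa_window_peak,
                        baseline_left = p$baseline_left,
                        baseline_right = p$baseline_right),
    meta = list(params = p))
}

#' Step-initiation trial parameters
#'
#' Defaults describe a biphasic medio-lateral APA of 20 N peak, a 350 ms
#' lead over step onset, a 30 cm antero-posterior foot excursion, force
#' synthesized at 1000 Hz then band-limited at 100 Hz to emulate the
#' platform's internal analog filter, and the marker sampled at 200 Hz.
#' Holding a walker (supported condition) scales the APA by
#' \code{1 - suppression_factor}.
#'
#' @param fml_amplitude peak medio-lateral APA force, N.
#' @param apa_lead seconds between APA onset and step onset.
#' @param step_sigmoid_scale duration of the sigmoid marker excursion, s.
#' @param marker_excursion antero-posterior step amplitude, mm.
#' @param noise_sd_force platform noise SD before filtering, N.
#' @param noise_sd_marker marker noise SD, mm.
#' @param condition \code{"unsupported"} or \code{"supported"} (walker).
#' @param suppression_factor fraction of the APA removed when supported.
#' @param latency_range go-cue-to-APA latency range, s.
#' @param rate_force_hz force synthesis/sampling rate, Hz.
#' @param analog_cutoff_hz platform analog low-pass cutoff, Hz.
#' @param rate_marker_hz marker sampling rate, Hz.
#' @return a list of class \code{step_trial_params}.
#' @export
step_trial_params <- function(fml_amplitude = 20, apa_lead = 0.35,
                              step_sigmoid_scale = 0.3,
                              marker_excursion = 300,
                              noise_sd_force = 0.1, noise_sd_marker = 1.0,
                              condition = c("unsupported", "supported"),
                              suppression_factor = 0.5,
                              latency_range = c(0.15, 0.40),
                              rate_force_hz = 1000, analog_cutoff_hz = 100,
                              rate_marker_hz = 200) {
  condition <- match.arg(condition)
  stopifnot(fml_amplitude >= 0, apa_lead > 0, step_sigmoid_scale > 0,
            marker_excursion >= 0, noise_sd_force >= 0, noise_sd_marker >= 0,
            suppression_factor >= 0, suppression_factor <= 1,
            rate_force_hz > 0, rate_marker_hz > 0,
            analog_cutoff_hz < rate_force_hz / 2)
  structure(as.list(environment()), class = "step_trial_params")
}

#' Simulate one step-initiation trial
#'
#' Produces the medio-lateral force channel (biphasic toward-then-away
#' APA deflection, band-limited by the emulated analog filter) and the
#' antero-posterior marker trace (sigmoid excursion starting at the step
#' onset), with cue events and ground truth.
#'
#' @inheritParams simulate_supine_trial
#' @param params a \code{step_trial_params}.
#' @return a \code{trial_recording} with channels \code{f_ml} and
#'   \code{marker_ap} and attached \code{ground_truth}.
#' @export
simulate_step_trial <- function(params, slice, seed = NULL, tail_s = 1.0) {
  stopifnot(inherits(params, "step_trial_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  if (p$apa_lead < 2 / p$rate_force_hz)
    stop("simulate_step_trial: apa_lead shorter than 2 sample periods")
  latency <- stats::runif(1, p$latency_range[1], p$latency_range[2])
  apa_onset <- slice$go_onset + latency
  step_onset <- apa_onset + p$apa_lead
  supp <- if (p$condition == "supported") p$suppression_factor else 0
  amp_eff <- p$fml_amplitude * (1 - supp)

  t0 <- slice$cross_onset
  t_end <- slice$trial_end + tail_s

  nf <- ceiling((t_end - t0) * p$rate_force_hz)
  tf <- t0 + (seq_len(nf) - 1) / p$rate_force_hz
  fml <- amp_eff * .biphasic(tf - apa_onset)
  if (p$noise_sd_force > 0)
    fml <- fml + stats::rnorm(nf, 0, p$noise_sd_force)
  fml_tr <- force_trace(fml, p$rate_force_hz, "f_ml", t0)
  fml_tr <- lowpass_filter(fml_tr, cutoff_hz = p$analog_cutoff_hz)

  nm <- ceiling((t_end - t0) * p$rate_marker_hz)
  tm <- t0 + (seq_len(nm) - 1) / p$rate_marker_hz
  disp <- p$marker_excursion *
    .smoothstep((tm - step_onset) / p$step_sigmoid_scale)
  if (p$noise_sd_marker > 0)
    disp <- disp + stats::rnorm(nm, 0, p$noise_sd_marker)

  events <- event_table(
    onset = c(slice$cross_onset, slice$prepare_onset, slice$go_onset),
    duration = c(slice$prepare_onset - slice$cross_onset,
                 slice$go_onset - slice$prepare_onset, slice$go_max),
    trial_type = c("cross", "prepare_circle", "go_circle"),
    trial_index = rep(1L, 3L))

  trial_recording(
    traces = list(f_ml = fml_tr,
                  marker_ap = marker_trace(disp, p$rate_marker_hz, t0)),
    events = events,
    ground_truth = list(task = "step", condition = p$condition,
                        true_apa_onset = apa_onset,
                        true_step_onset = step_onset,
                        fml_amplitude_effective = amp_eff,
                        marker_excursion = p$marker_excursion),
    meta = list(params = p))
}

#' Default analysis windows for a simulated trial
#'
#' Baseline is the instructed relax period (cross display to preparation
#' cue); the movement/whole-curve epoch runs from the preparation cue to
#' \code{end} (by default the end of the scheduled go window; pass the
#' relax-command time from \code{\link{run_acquisition_loop}} to use the
#' realized trial end).
#'
#' @param slice trial cue times (\code{\link{schedule_slice}}).
#' @param end end of the movement epoch, s; default
#'   \code{slice$trial_end}.
#' @return a \code{trial_window}.
#' @export
default_trial_window <- function(slice, end = NULL) {
  if (is.null(end)) end <- slice$trial_end
  trial_window(baseline = c(slice$cross_onset, slice$prepare_onset),
               movement = c(slice$prepare_onset, end))
}
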