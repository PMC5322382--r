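#' Event-related paradigm configuration
#'
#' One run consists of \code{n_trials} trials, each showing a cross
#' (relax; its duration is the inter-stimulus interval), a preparation
#' circle, and a go circle.  Stimulus durations are randomized on 0.5 s
#' grids — preparation on [1, 3] s, ISI on [5.5, 8.5] s — with grid
#' indices drawn from a truncated Poisson law, a jitter scheme that
#' improves hemodynamic-response sampling in event-related designs.
#' The go stimulus is scheduled at its 5 s maximum; at acquisition time
#' it ends as soon as the force under the movement leg drops.
#'
#' @param n_trials trials per run (default 30).
#' @param prepare_range preparation-circle duration range, s.
#' @param go_max maximum go-stimulus duration, s.
#' @param isi_range cross (inter-stimulus interval) range, s.
#' @param grid_step duration grid step, s.
#' @param poisson_rate rate (lambda) of the truncated Poisson over grid
#'   indices.
#' @param cue_mapping which circle is the ready cue for this subject.
#' @return an object of class \code{paradigm_config}.
#' @export
paradigm_config <- function(n_trials = 30L,
                            prepare_range = c(1.0, 3.0),
                            go_max = 5.0,
                            isi_range = c(5.5, 8.5),
                            grid_step = 0.5,
                            poisson_rate = 1.5,
                            cue_mapping = c("open_is_prepare",
                                            "closed_is_prepare")) {
  cue_mapping <- match.arg(cue_mapping)
  stopifnot(n_trials >= 1, grid_step > 0, poisson_rate > 0, go_max > 0,
            length(prepare_range) == 2L, length(isi_range) == 2L,
            prepare_range[1] < prepare_range[2], isi_range[1] < isi_range[2])
  for (rg in list(prepare_range, isi_range)) {
    k <- (rg[2] - rg[1]) / grid_step
    if (abs(k - round(k)) > 1e-9)
      stop("paradigm_config: grid_step must divide the range width")
  }
  structure(list(n_trials = as.integer(n_trials),
                 prepare_range = prepare_range, go_max = go_max,
                 isi_range = isi_range, grid_step = grid_step,
                 poisson_rate = poisson_rate, cue_mapping = cue_mapping),
            class = "paradigm_config")
}

#' Draw one stimulus duration from a truncated-Poisson grid
#'
#' The admissible durations are \code{range[1] + grid_step * j} for
#' \code{j = 0..k}; the index \code{j} is drawn from a Poisson(lambda)
#' distribution truncated (renormalized) to \code{{0, ..., k}}.  As
#' lambda tends to 0 all mass collapses onto \code{range[1]}.
#'
#' Uses the current RNG state; seed with \code{set.seed()} for
#' reproducibility.
#'
#' @param range length-2 duration range, s.
#' @param grid_step grid step, s.
#' @param lambda Poisson rate (> 0).
#' @param n number of draws.
#' @return numeric vector of durations on the grid.
#' @export
sample_grid_duration <- function(range, grid_step, lambda, n = 1L) {
  stopifnot(length(range) == 2L, range[1] <= range[2], grid_step > 0,
            lambda > 0, n >= 1)
  k <- round((range[2] - range[1]) / grid_step)
  if (abs((range[2] - range[1]) / grid_step - k) > 1e-9)
    stop("sample_grid_duration: grid_step must divide the range width")
  j <- 0:k
  if (length(j) == 0) stop("sample_grid_duration: empty grid")
  p <- stats::dpois(j, lambda)
  if (sum(p) <= 0) stop("sample_grid_duration: degenerate truncation")
  idx <- sample(j, n, replace = TRUE, prob = p)
  range[1] + grid_step * idx
}

#' Truncated-Poisson probability mass over a duration grid
#'
#' The distribution \code{\link{sample_grid_duration}} draws from;
#' exposed for calibration checks.
#'
#' @inheritParams sample_grid_duration
#' @return data.frame with \code{duration} and \code{prob}.
#' @export
grid_duration_pmf <- function(range, grid_step, lambda) {
  k <- round((range[2] - range[1]) / grid_step)
  j <- 0:k
  p <- stats::dpois(j, lambda)
  data.frame(duration = range[1] + grid_step * j, prob = p / sum(p))
}

#' Build a full run schedule
#'
#' Generates the ordered cross/prepare/go event sequence for one run.
#' Deterministic given the RNG seed (\code{seed} argument or prior
#' \code{set.seed()}).
#'
#' @param config a \code{paradigm_config}.
#' @param seed optional integer seed applied before sampling.
#' @return an object of class \code{paradigm_schedule}: an
#'   \code{event_table} plus the total planned run duration.
#' @export
build_schedule <- function(config = paradigm_config(), seed = NULL) {
  stopifnot(inherits(config, "paradigm_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  isi <- sample_grid_duration(config$isi_range, config$grid_step,
                              config$poisson_rate, n)
  prep <- sample_grid_duration(config$prepare_range, config$grid_step,
                               config$poisson_rate, n)
  go <- rep(config$go_max, n)
  onset <- numeric(0); dur <- numeric(0); typ <- character(0); idx <- integer(0)
  t <- 0
  for (i in seq_len(n)) {
    onset <- c(onset, t, t + isi[i], t + isi[i] + prep[i])
    dur <- c(dur, isi[i], prep[i], go[i])
    typ <- c(typ, "cross", "prepare_circle", "go_circle")
    idx <- c(idx, rep(i, 3L))
    t <- t + isi[i] + prep[i] + go[i]
  }
  structure(list(events = event_table(onset, dur, typ, idx),
                 total_duration = t, config = config),
            class = "paradigm_schedule")
}

#' @export
print.paradigm_schedule <- function(x, ...) {
  cat(sprintf("<paradigm_schedule> %d trials, planned run %.1f s, cue mapping %s\n",
              x$config$n_trials, x$total_duration, x$config$cue_mapping))
  invisible(x)
}

#' Extract one trial's cue times from a schedule
#'
#' @param schedule a \code{paradigm_schedule}.
#' @param trial trial index.
#' @return list with \code{cross_onset}, \code{prepare_onset},
#'   \code{go_onset}, \code{go_max} and \code{trial_end} (s from run
#'   start).
#' @export
schedule_slice <- function(schedule, trial) {
  ev <- schedule$events
  tr <- ev[ev$trial_index == trial, ]
  if (nrow(tr) != 3L) stop("schedule_slice: trial not found: ", trial)
  g <- tr[tr$trial_type == "go_circle", ]
  list(cross_onset = tr$onset[tr$trial_type == "cross"],
       prepare_onset = tr$onset[tr$trial_type == "prepare_circle"],
       go_onset = g$onset, go_max = g$duration,
       trial_end = g$onset + g$duration)
}

#' Counterbalanced cue (or condition-order) assignment
#'
#' Splits subjects as evenly as possible between the two cue mappings
#' (half see the open circle as the ready cue, half the closed circle),
#' deterministically given the seed.  The same rule serves to
#' counterbalance supported/unsupported condition order.
#'
#' @param subjects vector of subject identifiers.
#' @param labels the two assignment labels.
#' @param seed optional integer seed.
#' @return data.frame with \code{subject} and \code{assignment}.
#' @export
counterbalance <- function(subjects,
                           labels = c("open_is_prepare", "closed_is_prepare"),
                           seed = NULL) {
  stopifnot(length(subjects) >= 1L, length(labels) == 2L)
  if (!is.null(seed)) set.seed(seed)
  n <- length(subjects)
  ord <- sample.int(n)
  assignment <- character(n)
  assignment[ord <= ceiling(n / 2)] <- labels[1]
  assignment[ord > ceiling(n / 2)] <- labels[2]
  data.frame(subject = subjects, assignment = assignment,
             stringsAsFactors = FALSE)
}
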