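#' FMS run log: write
#'
#' Serializes a \code{trial_recording} to the versioned plain-text run-log
#' format of the control box.  The file is self-describing and
#' diff-friendly: a format-version line, one section per channel (each
#' with its own \code{rate_hz}, \code{t0} and \code{units}, so channels
#' with different sampling rates coexist in one file), then an
#' \code{# events} section holding the event table.  Forces are written
#' with 6 significant digits and times at 1 ms resolution.
#'
#' @param recording a \code{trial_recording}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_fms_log <- function(recording, path) {
  stopifnot(inherits(recording, "trial_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# FMS-LOG v1", con)
  for (nm in names(recording$traces)) {
    tr <- recording$traces[[nm]]
    writeLines(c(sprintf("# channel: %s", nm),
                 sprintf("# rate_hz: %.6g", tr$rate_hz),
                 sprintf("# t0: %.3f", tr$t0),
                 sprintf("# units: %s", tr$units),
                 sprintf("%.6g", tr$samples)), con)
  }
  writeLines("# events", con)
  ev <- recording$events
  writeLines("onset\tduration\ttrial_type\ttrial_index", con)
  if (nrow(ev) > 0)
    writeLines(sprintf("%.3f\t%.3f\t%s\t%d", ev$onset, ev$duration,
                       ev$trial_type, ev$trial_index), con)
  invisible(path)
}

.log_err <- function(line, msg) {
  stop(sprintf("FMS log parse error at line %d: %s", line, msg), call. = FALSE)
}

.header_val <- function(lines, i, key) {
  pat <- paste0("^# ", key, ": *(.*)$")
  if (i > length(lines) || !grepl(pat, lines[i]))
    .log_err(i, sprintf("expected '# %s:' header", key))
  sub(pat, "\\1", lines[i])
}

#' FMS run log: read
#'
#' Parses a run log written by \code{\link{write_fms_log}}.  Malformed
#' headers, unknown channel tags and rows with the wrong number of fields
#' raise errors that name the offending line.
#'
#' @param path file path.
#' @return a \code{trial_recording} (ground truth is not stored in the
#'   log; see the ground-truth sidecar written by the simulator CLI).
#' @export
read_fms_log <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "# FMS-LOG v1")
    .log_err(1, "missing 'FMS-LOG v1' magic header")
  i <- 2L
  traces <- list()
  marker_channels <- "marker_ap"
  known <- c("left_foot", "right_foot", "touch", "f_ml", marker_channels)
  while (i <= length(lines) && grepl("^# channel:", lines[i])) {
    ch <- .header_val(lines, i, "channel")
    if (!ch %in% known) .log_err(i, paste("unknown channel tag:", ch))
    rate <- suppressWarnings(as.numeric(.header_val(lines, i + 1L, "rate_hz")))
    if (is.na(rate) || rate <= 0) .log_err(i + 1L, "invalid rate_hz")
    t0 <- suppressWarnings(as.numeric(.header_val(lines, i + 2L, "t0")))
    if (is.na(t0)) .log_err(i + 2L, "invalid t0")
    units <- .header_val(lines, i + 3L, "units")
    i <- i + 4L
    first <- i
    while (i <= length(lines) && !startsWith(lines[i], "#")) i <- i + 1L
    if (i == first) .log_err(first, paste("channel", ch, "has no samples"))
    vals <- suppressWarnings(as.numeric(lines[first:(i - 1L)]))
    if (anyNA(vals))
      .log_err(first - 1L + which(is.na(vals))[1], "non-numeric sample value")
    traces[[ch]] <- if (ch %in% marker_channels)
      marker_trace(vals, rate_hz = rate, t0 = t0)
    else
      force_trace(vals, rate_hz = rate, channel = ch, t0 = t0, units = units)
  }
  if (length(traces) == 0) .log_err(i, "no channel sections found")
  if (i > length(lines) || lines[i] != "# events")
    .log_err(i, "expected '# events' section")
  i <- i + 1L
  if (i > length(lines) || lines[i] != "onset\tduration\ttrial_type\ttrial_index")
    .log_err(i, "expected events header row")
  ev_first <- i + 1L
  ev_lines <- if (ev_first > length(lines)) character(0) else lines[ev_first:length(lines)]
  ev_lines <- ev_lines[nzchar(ev_lines)]
  if (length(ev_lines) == 0) {
    events <- empty_events()
  } else {
    parts <- strsplit(ev_lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 4L))
      .log_err(ev_first - 1L + which(nf != 4L)[1],
               sprintf("expected 4 tab-separated fields, got %d",
                       nf[which(nf != 4L)[1]]))
    m <- do.call(rbind, parts)
    onset <- suppressWarnings(as.numeric(m[, 1]))
    dur <- suppressWarnings(as.numeric(m[, 2]))
    idx <- suppressWarnings(as.integer(m[, 4]))
    if (anyNA(onset) || anyNA(dur) || anyNA(idx))
      .log_err(ev_first - 1L + which(is.na(onset) | is.na(dur) | is.na(idx))[1],
               "non-numeric event field")
    events <- event_table(onset, dur, m[, 3], idx)
  }
  trial_recording(traces, events)
}
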