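#' Stimulus/trigger event tables
#'
#' A BIDS-events-like table with columns \code{onset} (s from run start),
#' \code{duration} (s), \code{trial_type} and \code{trial_index}.  Onsets
#' must be non-decreasing and durations non-negative.
#'
#' @param onset numeric, seconds from run start.
#' @param duration numeric, seconds (>= 0).
#' @param trial_type character, one of the known event labels.
#' @param trial_index integer trial number.
#' @return a \code{data.frame} of class \code{event_table}.
#' @export
event_table <- function(onset, duration, trial_type, trial_index) {
  df <- data.frame(onset = as.numeric(onset),
                   duration = as.numeric(duration),
                   trial_type = as.character(trial_type),
                   trial_index = as.integer(trial_index),
                   stringsAsFactors = FALSE)
  validate_event_table(df)
}

.event_types <- c("cross", "prepare_circle", "go_circle",
                  "relax_cmd", "trigger", "touch_bar")

validate_event_table <- function(df) {
  need <- c("onset", "duration", "trial_type", "trial_index")
  if (!all(need %in% names(df)))
    stop("event_table: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[need]
  if (nrow(df) > 0) {
    if (anyNA(df$onset) || any(!is.finite(df$onset)))
      stop("event_table: non-finite onset")
    if (is.unsorted(df$onset))
      stop("event_table: onsets must be non-decreasing")
    if (any(df$duration < 0)) stop("event_table: negative duration")
    bad <- setdiff(unique(df$trial_type), .event_types)
    if (length(bad) > 0)
      stop("event_table: unknown trial_type: ", paste(bad, collapse = ", "))
  }
  class(df) <- c("event_table", "data.frame")
  df
}

#' Coerce to an event table
#' @param x a data.frame with the event-table columns.
#' @return a validated \code{event_table}.
#' @export
as_event_table <- function(x) {
  if (inherits(x, "event_table")) return(x)
  validate_event_table(as.data.frame(x))
}

#' Empty event table
#' @return an \code{event_table} with zero rows.
#' @export
empty_events <- function() {
  event_table(numeric(0), numeric(0), character(0), integer(0))
}

#' Read an events TSV
#'
#' Tab-separated with header \code{onset duration trial_type trial_index}.
#' Onset ordering and non-negative durations are enforced.
#'
#' @param path file path.
#' @return an \code{event_table}.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_event_table(df)
}

#' Write an events TSV
#'
#' Times are serialized at 1 ms resolution.
#'
#' @param events an \code{event_table}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_events <- function(events, path) {
  events <- as_event_table(events)
  out <- data.frame(onset = sprintf("%.3f", events$onset),
                    duration = sprintf("%.3f", events$duration),
                    trial_type = events$trial_type,
                    trial_index = events$trial_index)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
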