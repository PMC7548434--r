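#' Construct a continuous multichannel EEG recording
#'
#' A recording holds a time-by-channel sample matrix in microvolts, its
#' sampling rate, and an event table of stimulus onsets and responses.
#' Channel labels follow the 10-10 system (plus `M1`/`M2` mastoids and
#' `IO1`/`IO2` infraorbitals).
#'
#' @param data Numeric matrix, time samples in rows, channels in columns.
#'   Column names are the channel labels and must be unique.
#' @param sampling_rate Sampling rate in Hz.
#' @param events Optional event table, see [event_table()].
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, sampling_rate, events = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("recording data must be numeric")
  labels <- colnames(data)
  if (is.null(labels) || anyDuplicated(labels))
    stop("recording requires unique channel labels as column names")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  if (!is.null(events)) events <- event_table(events)
  structure(
    list(data = data, sampling_rate = sampling_rate, events = events),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
    ncol(x$data), nrow(x$data), x$sampling_rate,
    nrow(x$data) / x$sampling_rate,
    if (is.null(x$events)) 0L else nrow(x$events)
  ))
  cat("channels:", paste(colnames(x$data), collapse = ", "), "\n")
  invisible(x)
}

#' Validate an event table
#'
#' Events are a data frame with columns `onset` (seconds from recording
#' start, non-decreasing), `type` (one of `upper`, `lower`, `flash`,
#' `response`), and optionally `observed` (logical, defined only for
#' `flash` events, TRUE when a key press followed within the response
#' window) and `response_s` (response latency in seconds, NA if missed).
#'
#' @param x A data frame.
#' @return The validated data frame.
#' @export
event_table <- function(x) {
  x <- as.data.frame(x)
  if (!all(c("onset", "type") %in% names(x)))
    stop("event table needs 'onset' and 'type' columns")
  if (is.unsorted(x$onset)) stop("event onsets must be non-decreasing")
  bad <- setdiff(unique(as.character(x$type)),
                 c("upper", "lower", "flash", "response"))
  if (length(bad))
    stop("unknown event type(s): ", paste(bad, collapse = ", "))
  if (!"observed" %in% names(x)) x$observed <- NA
  if (any(!is.na(x$observed) & x$type != "flash"))
    stop("'observed' is defined only for flash events")
  x
}

#' Extract one channel from a recording
#'
#' @param rec An [recording()].
#' @param label Channel label.
#' @return Numeric vector of samples.
#' @export
get_channel <- function(rec, label) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!label %in% colnames(rec$data))
    stop("channel not present in recording: ", label)
  rec$data[, label]
}

# Sample index (1-based) of an absolute time in seconds; sample 1 is t = 0.
time_to_sample <- function(t_s, fs) as.integer(round(t_s * fs)) + 1L

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, window [%g, %g) ms, %d rejected\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sampling_rate,
    x$window_ms[1], x$window_ms[2], sum(x$rejected)
  ))
  invisible(x)
}

# Logical mask of accepted trials in an eeg_epochs object.
accepted_trials <- function(epochs) !epochs$rejected
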