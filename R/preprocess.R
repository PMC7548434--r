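#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel of a continuous recording with a second-order
#' IIR Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), giving a zero-phase response.  The band is
#' realized as a high-pass/low-pass cascade, which is numerically robust
#' for the very low default high-pass edge (0.01 Hz).  Each single pass
#' is -3 dB at the stated edges, so the combined two-pass response is
#' -6 dB there.
#'
#' Filtering is applied to the continuous recording, before epoching, so
#' that filter transients never fall inside short epochs.
#'
#' @param rec An [recording()].
#' @param low,high Band edges in Hz; must satisfy `0 < low < high <
#'   Nyquist`.
#' @param order Filter order of each Butterworth section (default 2).
#' @return The filtered recording.
#' @export
bandpass_zero_phase <- function(rec, low = 0.01, high = 50, order = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist")
  out <- rec
  for (j in seq_len(ncol(rec$data)))
    out$data[, j] <- bandpass_series(rec$data[, j], rec$sampling_rate,
                                     low, high, order)
  out
}

# The single-series band-pass behind bandpass_zero_phase().
bandpass_series <- function(x, fs, low = 0.01, high = 50, order = 2) {
  nyq <- fs / 2
  bh <- signal::butter(order, low / nyq, type = "high")
  bl <- signal::butter(order, high / nyq, type = "low")
  signal::filtfilt(bl, signal::filtfilt(bh, x))
}

#' Re-reference a recording to averaged mastoids
#'
#' Subtracts the mean of the two mastoid channels from every channel.
#'
#' @param rec An [recording()].
#' @param mastoids Labels of the two mastoid channels.
#' @return The re-referenced recording.
#' @export
rereference_mastoids <- function(rec, mastoids = c("M1", "M2")) {
  stopifnot(inherits(rec, "eeg_recording"))
  miss <- setdiff(mastoids, colnames(rec$data))
  if (length(miss)) stop("missing mastoid channel(s): ",
                         paste(miss, collapse = ", "))
  ref <- rowMeans(rec$data[, mastoids, drop = FALSE])
  rec$data <- rec$data - ref
  rec
}

#' Derive the bipolar vertical EOG signal
#'
#' vEOG(t) = mean(Fp1, Fp2)(t) - mean(left, right infraorbital)(t); large
#' deflections in this channel mark blinks.
#'
#' @param rec An [recording()].
#' @param frontal Labels of the two frontopolar channels.
#' @param infraorbital Labels of the two infraorbital channels.
#' @return Numeric vector, the vEOG time series in microvolts.
#' @export
derive_veog <- function(rec, frontal = c("Fp1", "Fp2"),
                        infraorbital = c("IO1", "IO2")) {
  stopifnot(inherits(rec, "eeg_recording"))
  need <- c(frontal, infraorbital)
  miss <- setdiff(need, colnames(rec$data))
  if (length(miss)) stop("missing channel(s) for vEOG: ",
                         paste(miss, collapse = ", "))
  rowMeans(rec$data[, frontal, drop = FALSE]) -
    rowMeans(rec$data[, infraorbital, drop = FALSE])
}

#' Down-sample a recording by an integer factor
#'
#' Decimates after a protective zero-phase anti-alias low-pass (4th-order
#' Butterworth at 0.45 x target rate, applied forward-backward).  Event
#' onsets are stored in seconds and therefore carry over unchanged; the
#' nearest-sample re-expression happens at epoching time.
#'
#' @param rec An [recording()].
#' @param target_rate Target sampling rate in Hz; must divide the current
#'   rate.
#' @return The down-sampled recording.
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (target_rate > fs) stop("target_rate exceeds current sampling rate")
  if (target_rate == fs) return(rec)
  fac <- fs / target_rate
  if (abs(fac - round(fac)) > 1e-9)
    stop("target_rate must divide the sampling rate (integer decimation)")
  fac <- as.integer(round(fac))
  bl <- signal::butter(4, (0.45 * target_rate) / (fs / 2), type = "low")
  keep <- seq(1L, nrow(rec$data), by = fac)
  dat <- matrix(0, length(keep), ncol(rec$data),
                dimnames = list(NULL, colnames(rec$data)))
  for (j in seq_len(ncol(rec$data)))
    dat[, j] <- signal::filtfilt(bl, rec$data[, j])[keep]
  rec$data <- dat
  rec$sampling_rate <- target_rate
  rec
}

# Epoch a single series into a trial x time matrix.  Windows are
# half-open in samples, [onset + lo, onset + hi): a (-50, 200) ms window
# at 2048 Hz is 512 samples.  Trials extending past the series edges are
# returned as NA rows and flagged by the caller.
epoch_series <- function(x, fs, onsets_s, window_ms) {
  lo <- as.integer(round(window_ms[1] * fs / 1000))
  hi <- as.integer(round(window_ms[2] * fs / 1000))
  if (hi <= lo) stop("empty epoch window")
  rel <- lo:(hi - 1L)
  n <- length(x)
  out <- matrix(NA_real_, length(onsets_s), length(rel))
  edge <- logical(length(onsets_s))
  for (i in seq_along(onsets_s)) {
    idx <- time_to_sample(onsets_s[i], fs) + rel
    if (idx[1] < 1L || idx[length(idx)] > n) {
      edge[i] <- TRUE
    } else {
      out[i, ] <- x[idx]
    }
  }
  list(data = out, time_ms = rel / fs * 1000, edge = edge)
}

#' Cut stimulus-locked epochs from a recording
#'
#' Windows are half-open in samples, `[onset + lo, onset + hi)`, with
#' `lo`/`hi` the window edges rounded to samples, so epoch length is
#' proportional to the sampling rate.  Trials too close to the recording
#' edge are flagged `rejected` with reason `"edge"`.
#'
#' @param rec An [recording()].
#' @param events Event table subset to epoch (must be non-empty); its
#'   `onset` column is used.
#' @param window_ms Length-2 numeric, window in ms relative to onset,
#'   e.g. `c(-50, 200)`.
#' @param channels Channel labels to include (default: all).
#' @return An `eeg_epochs` object: `data` is a trial x channel x time
#'   array, plus `time_ms`, `sampling_rate`, `events`, `rejected`,
#'   `reject_reason`.
#' @export
epoch_recording <- function(rec, events, window_ms, channels = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  events <- event_table(events)
  if (!nrow(events)) stop("empty event selection")
  if (is.null(channels)) channels <- colnames(rec$data)
  miss <- setdiff(channels, colnames(rec$data))
  if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))
  first <- epoch_series(rec$data[, channels[1]], rec$sampling_rate,
                        events$onset, window_ms)
  nt <- nrow(events); nc <- length(channels); ns <- length(first$time_ms)
  arr <- array(NA_real_, c(nt, nc, ns),
               dimnames = list(NULL, channels, NULL))
  arr[, 1, ] <- first$data
  if (nc > 1) for (j in 2:nc) {
    arr[, j, ] <- epoch_series(rec$data[, channels[j]], rec$sampling_rate,
                               events$onset, window_ms)$data
  }
  structure(list(
    data = arr,
    time_ms = first$time_ms,
    window_ms = window_ms,
    sampling_rate = rec$sampling_rate,
    events = events,
    rejected = first$edge,
    reject_reason = ifelse(first$edge, "edge", NA_character_)
  ), class = "eeg_epochs")
}

#' Reject epochs containing blinks in the vEOG signal
#'
#' Slides a window (default 150 ms, 75-ms steps) over each trial's vEOG
#' epoch; a trial is rejected iff any window's peak-to-peak amplitude
#' (max - min) reaches the threshold (default 100 uV).  Windows start at
#' the epoch's first sample; a final partial window is evaluated iff at
#' least half the window length remains.
#'
#' @param epochs An `eeg_epochs` object to annotate.
#' @param veog_epochs Trial x time numeric matrix of the vEOG signal,
#'   aligned with `epochs` (same trials and sampling).
#' @param win_ms Sliding window length in ms.
#' @param step_ms Step between window onsets in ms.
#' @param threshold_uv Peak-to-peak rejection threshold in uV.
#' @return `epochs` with blink trials flagged `rejected`, reason
#'   `"blink"` (existing rejections are kept).
#' @export
reject_blinks <- function(epochs, veog_epochs, win_ms = 150, step_ms = 75,
                          threshold_uv = 100) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  veog_epochs <- as.matrix(veog_epochs)
  if (nrow(veog_epochs) != dim(epochs$data)[1])
    stop("vEOG epochs not aligned with data epochs")
  ns <- ncol(veog_epochs)
  fs <- epochs$sampling_rate
  win <- as.integer(round(win_ms * fs / 1000))
  step <- as.integer(round(step_ms * fs / 1000))
  if (win > ns) stop("blink window longer than epoch")
  starts <- seq(1L, ns, by = step)
  keep_start <- (starts + win - 1L <= ns) | (ns - starts + 1L >= win / 2)
  starts <- starts[keep_start]
  blink <- vapply(seq_len(nrow(veog_epochs)), function(i) {
    x <- veog_epochs[i, ]
    if (anyNA(x)) return(FALSE)
    for (s in starts) {
      w <- x[s:min(s + win - 1L, ns)]
      if (max(w) - min(w) >= threshold_uv) return(TRUE)
    }
    FALSE
  }, logical(1))
  newly <- blink & !epochs$rejected
  epochs$rejected <- epochs$rejected | blink
  epochs$reject_reason[newly] <- "blink"
  epochs
}

#' Pool occipital channels into LO and RO signals
#'
#' Left-occipital (LO) is the arithmetic mean of O1, PO3, PO7;
#' right-occipital (RO) of O2, PO4, PO8.
#'
#' @param rec An [recording()].
#' @param left,right Channel labels to average per hemisphere.
#' @return List with numeric vectors `lo` and `ro`.
#' @export
pool_occipital <- function(rec, left = c("O1", "PO3", "PO7"),
                           right = c("O2", "PO4", "PO8")) {
  stopifnot(inherits(rec, "eeg_recording"))
  miss <- setdiff(c(left, right), colnames(rec$data))
  if (length(miss)) stop("missing occipital channel(s): ",
                         paste(miss, collapse = ", "))
  list(lo = rowMeans(rec$data[, left, drop = FALSE]),
       ro = rowMeans(rec$data[, right, drop = FALSE]))
}
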