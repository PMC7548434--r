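#' Probability of observing a flash for a logistic observer
#'
#' Psychometric stand-in for a participant: the probability of reporting
#' a flash of a given greyscale intensity is
#' `plogis(slope * (intensity - threshold))`, exactly 0.5 at the
#' threshold.
#'
#' @param intensity Stimulus intensity, greyscale 0-255.
#' @param threshold The 50%-observation intensity.
#' @param slope Psychometric slope in 1/greyscale units; must be
#'   positive.  As `slope -> Inf` the observer becomes a step function
#'   at threshold.
#' @return Observation probability.
#' @export
psychometric_p <- function(intensity, threshold, slope) {
  if (slope <= 0) stop("slope must be positive")
  stats::plogis(slope * (intensity - threshold))
}

#' Create a simulated logistic observer
#'
#' Returns a function of intensity that draws a Bernoulli observation
#' from [psychometric_p()] using the ambient RNG stream (seed it with
#' `set.seed()` or pass `seed` to [run_staircase()]).
#'
#' @inheritParams psychometric_p
#' @return `function(intensity) -> logical` observation flag.
#' @export
simulated_observer <- function(threshold, slope) {
  if (slope <= 0) stop("slope must be positive")
  function(intensity) {
    stats::runif(1) < psychometric_p(intensity, threshold, slope)
  }
}

#' Run a 1-up/1-down staircase
#'
#' Each observed flash decreases the next trial's intensity by `step`;
#' each miss increases it by `step` (fixed step, no halving).
#' Intensities are clamped to the greyscale range `[0, 255]`; the number
#' of clamped updates is recorded.  Reversals are trials at which the
#' trial-intensity slope changes sign (clamp-flattened slopes carry the
#' preceding sign).
#'
#' @param observer A function of intensity returning a logical
#'   observation flag, e.g. [simulated_observer()].
#' @param start_intensity First trial's intensity.
#' @param step Intensity change per trial.
#' @param n_trials Number of trials (at least 4).
#' @param seed Optional RNG seed for reproducibility.
#' @return An object of class `staircase_trace`: data frame
#'   `trials(trial, intensity, observed)`, `reversal_indices`,
#'   `n_clamped`, and `threshold` (NA until 3 reversals occurred; see
#'   [staircase_threshold()]).
#' @export
run_staircase <- function(observer, start_intensity = 128, step = 4,
                          n_trials = 40, seed = NULL) {
  if (n_trials < 4) stop("staircase needs at least 4 trials")
  if (!is.null(seed)) set.seed(seed)
  intensity <- numeric(n_trials)
  observed <- logical(n_trials)
  slope_sign <- integer(n_trials)   # sign of intensity change after trial i
  n_clamped <- 0L
  cur <- start_intensity
  for (i in seq_len(n_trials)) {
    intensity[i] <- cur
    observed[i] <- isTRUE(observer(cur))
    nxt <- cur + if (observed[i]) -step else step
    clamped <- min(max(nxt, 0), 255)
    if (clamped != nxt) n_clamped <- n_clamped + 1L
    slope_sign[i] <- sign(clamped - cur)
    cur <- clamped
  }
  # reversal at trial i when the post-trial slope sign flips relative to
  # the last non-zero sign seen before it
  reversals <- integer(0)
  last <- 0L
  for (i in seq_len(n_trials)) {
    s <- slope_sign[i]
    if (s == 0L) next
    if (last != 0L && s != last) reversals <- c(reversals, i)
    last <- s
  }
  trace <- structure(list(
    trials = data.frame(trial = seq_len(n_trials), intensity = intensity,
                        observed = observed),
    reversal_indices = reversals,
    step = step,
    n_clamped = n_clamped,
    threshold = NA_real_
  ), class = "staircase_trace")
  if (length(reversals) >= 3)
    trace$threshold <- staircase_threshold(trace)
  trace
}

#' @export
print.staircase_trace <- function(x, ...) {
  cat(sprintf(
    "<staircase_trace> %d trials, %d reversals, threshold %s\n",
    nrow(x$trials), length(x$reversal_indices),
    if (is.na(x$threshold)) "undefined" else sprintf("%.2f", x$threshold)))
  invisible(x)
}

#' Threshold intensity from a staircase trace
#'
#' The threshold is the arithmetic mean of the intensities of all trials
#' strictly after the trial of the third reversal in the trial-intensity
#' slope, through the final trial (e.g. third reversal at trial 5 in a
#' 40-trial run: mean of trials 6-40).
#'
#' @param trace A `staircase_trace`.
#' @return Threshold intensity (greyscale value).
#' @export
staircase_threshold <- function(trace) {
  stopifnot(inherits(trace, "staircase_trace"))
  if (length(trace$reversal_indices) < 3)
    stop("threshold undefined: fewer than 3 reversals")
  r3 <- trace$reversal_indices[3]
  n <- nrow(trace$trials)
  if (r3 >= n) stop("threshold undefined: no trials after third reversal")
  mean(trace$trials$intensity[(r3 + 1):n])
}
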