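#' Circular mean of angles in degrees
#'
#' Averages angles as unit vectors (optionally weighted) and returns the
#' direction of the resultant together with the mean resultant length.
#' Used wherever phases are averaged: the LO/RO per-trial combination and
#' group-level preferred-phase summaries.
#'
#' @param angles_deg Numeric vector of angles in degrees.
#' @param weights Optional non-negative weights, recycled to length.
#' @return List with `angle` (degrees in `[0, 360)`) and `r`, the mean
#'   resultant length in `[0, 1]` (weighted mean of unit vectors).
#' @export
circ_mean <- function(angles_deg, weights = NULL) {
  if (!length(angles_deg)) stop("circ_mean needs at least one angle")
  if (is.null(weights)) weights <- rep(1, length(angles_deg))
  if (any(weights < 0)) stop("weights must be non-negative")
  rad <- angles_deg * pi / 180
  x <- sum(weights * cos(rad)) / sum(weights)
  y <- sum(weights * sin(rad)) / sum(weights)
  r <- sqrt(x^2 + y^2)
  if (r < 1e-12)
    stop("circular mean undefined: zero resultant vector")
  list(angle = wrap_deg(atan2(y, x) * 180 / pi), r = r)
}

#' Signed circular difference a - b in degrees
#'
#' @param a,b Angles in degrees (vectors recycle).
#' @return Signed difference wrapped to `(-180, 180]`.
#' @export
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

#' Wrap angles into `[0, 360)` degrees
#' @param x Angles in degrees.
#' @return Wrapped angles (values within numerical noise of 360 map
#'   to 0).
#' @export
wrap_deg <- function(x) {
  w <- x %% 360
  w[w >= 360 - 1e-9] <- 0
  w
}
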