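#' Tukey HSD pairwise comparisons from means and an error term
#'
#' Studentized-range test for all pairs among k cell means sharing one
#' error term: `q = |m_i - m_j| / sqrt(MSE / n)` with adjusted p from
#' `ptukey(q, k, df_error)`.
#'
#' @param cell_means Named numeric vector of k >= 2 means.
#' @param error_ms Mean-square error of the shared error term.
#' @param df_error Error degrees of freedom (>= 1).
#' @param n_per_cell Observations per mean.
#' @return Data frame: `level_1, level_2, diff, q, p_adj`.
#' @export
tukey_hsd <- function(cell_means, error_ms, df_error, n_per_cell) {
  k <- length(cell_means)
  if (k < 2) stop("need at least 2 means")
  if (df_error < 1) stop("df_error must be at least 1")
  nm <- names(cell_means)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  se <- sqrt(error_ms / n_per_cell)
  out <- data.frame(
    level_1 = nm[pairs[1, ]], level_2 = nm[pairs[2, ]],
    diff = cell_means[pairs[2, ]] - cell_means[pairs[1, ]]
  )
  out$q <- abs(out$diff) / se
  out$p_adj <- stats::ptukey(out$q, k, df_error, lower.tail = FALSE)
  rownames(out) <- NULL
  out
}

#' Tukey HSD between phase bins within one amplitude level
#'
#' Compares the four phase-bin delta-OR means within one amplitude
#' level of a subjects x amplitude x phase table.  The error term comes
#' from the phase-by-subject decomposition refit within that level
#' (df = (k-1)(n-1), e.g. 57 for 20 participants and 4 bins); set
#' `error = "omnibus"` to pool the omnibus two-way phase-by-subject
#' error instead.
#'
#' @param Y Numeric array, subjects x amplitude(2) x phase levels, with
#'   `dimnames` on the factor dimensions (defaults are supplied).
#' @param amplitude Which amplitude level to test (index or name into
#'   the second dimension).
#' @param error `"within_level"` (default) or `"omnibus"`.
#' @return The [tukey_hsd()] table, with the error term recorded in
#'   attributes `error_ms` and `df_error`.
#' @export
tukey_phase_bins <- function(Y, amplitude = "high",
                             error = c("within_level", "omnibus")) {
  error <- match.arg(error)
  Y <- unclass(Y)
  stopifnot(length(dim(Y)) == 3)
  if (is.character(amplitude)) {
    if (is.null(dimnames(Y)[[2]])) dimnames(Y)[[2]] <- c("low", "high")
    amplitude <- match(amplitude, dimnames(Y)[[2]])
  }
  n <- dim(Y)[1]; b <- dim(Y)[3]
  sub <- Y[, amplitude, ]                   # n x b
  centers <- dimnames(Y)[[3]]
  if (is.null(centers)) centers <- c("0", "90", "180", "270")[seq_len(b)]
  means <- colMeans(sub)
  names(means) <- centers
  if (error == "within_level") {
    m_s <- rowMeans(sub); m_b <- colMeans(sub); g <- mean(sub)
    ss_err <- sum((sub - outer(m_s, m_b, `+`) + g)^2)
    df_err <- (b - 1) * (n - 1)
  } else {
    fit <- rm_anova(Y)
    row <- fit$effects[fit$effects$effect == fit$factor_names[2], ]
    ss_err <- row$ss_err; df_err <- row$df_den
  }
  out <- tukey_hsd(means, ss_err / df_err, df_err, n_per_cell = n)
  attr(out, "error_ms") <- ss_err / df_err
  attr(out, "df_error") <- df_err
  out
}

#' Bonferroni-corrected one-sample t tests of delta-OR against zero
#'
#' One-sample t test (df = n - 1) per cell of a subjects x cells matrix,
#' with p values multiplied by the number of comparisons `m` (default:
#' the number of cells, 8 for the 2 x 4 design) and capped at 1.  A
#' zero-variance cell yields an infinite t and adjusted p of 0 with a
#' warning.
#'
#' @param samples Numeric matrix, subjects x cells (named columns
#'   recommended).
#' @param m Number of comparisons for the Bonferroni correction.
#' @return Data frame: `cell, mean, t, df, p, p_adj`.
#' @export
one_sample_t_bonferroni <- function(samples, m = ncol(samples)) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < 2) stop("need at least 2 participants per cell")
  nm <- colnames(samples)
  if (is.null(nm)) nm <- as.character(seq_len(ncol(samples)))
  mu <- colMeans(samples)
  s <- apply(samples, 2, stats::sd)
  tval <- mu / (s / sqrt(n))
  deg <- s == 0
  if (any(deg)) {
    # zero spread: t is 0 for a zero mean, +/-Inf (p_adj -> 0) otherwise
    tval[deg] <- sign(mu[deg]) * Inf
    tval[deg & mu == 0] <- 0
    if (any(deg & mu != 0))
      warning("zero-variance cell(s): infinite t, adjusted p -> 0")
  }
  p <- 2 * stats::pt(abs(tval), n - 1, lower.tail = FALSE)
  data.frame(cell = nm, mean = mu, t = tval, df = n - 1, p = p,
             p_adj = pmin(1, m * p), row.names = NULL)
}
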