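# Normalized (orthonormal) Helmert contrasts for a k-level factor,
# k x (k-1), columns orthonormal and orthogonal to the unit vector.
orthonormal_contrasts <- function(k) {
  m <- stats::contr.helmert(k)
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

#' Mauchly's test of sphericity for a within-subject effect
#'
#' Given the n x k matrix of per-subject effect scores (cell means for a
#' main effect, or interaction scores), the covariance S of the k-1
#' orthonormal contrast variables is formed;
#' `W = det(S) / (tr(S)/(k-1))^(k-1)`, and the chi-square approximation
#' is `-(n-1) * d * log W` with the standard correction
#' `d = 1 - (2p^2 + p + 2) / (6p(n-1))`, `p = k - 1`, on
#' `p(p+1)/2 - 1` degrees of freedom.
#'
#' @param scores Numeric matrix, subjects x levels (k >= 3); or, with
#'   `contrasts_applied = TRUE`, subjects x contrast scores (p >= 2,
#'   e.g. interaction scores that already live in contrast space).
#' @param contrasts_applied If TRUE, `scores` are already orthonormal
#'   contrast variables and are used as-is.
#' @return List: `W`, `chi2`, `df`, `p`.
#' @export
mauchly_test <- function(scores, contrasts_applied = FALSE) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  if (contrasts_applied) {
    if (k < 2) stop("need at least 2 contrast variables")
    d <- scores
    p <- k
  } else {
    if (k < 3) stop("Mauchly test needs a factor with at least 3 levels")
    d <- scores %*% orthonormal_contrasts(k)
    p <- k - 1
  }
  if (n <= p) stop("Mauchly test needs n > p subjects")
  S <- stats::cov(d)
  detS <- det(S)
  if (detS <= 0) stop("singular contrast covariance")
  W <- detS / (sum(diag(S)) / p)^p
  dd <- 1 - (2 * p^2 + p + 2) / (6 * p * (n - 1))
  chi2 <- -(n - 1) * dd * log(W)
  df <- p * (p + 1) / 2 - 1
  list(W = W, chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# Interaction scores: for each subject, apply the kronecker product of
# the two factors' orthonormal contrasts to the vectorized cell means.
interaction_scores <- function(Y) {
  n <- dim(Y)[1]; a <- dim(Y)[2]; b <- dim(Y)[3]
  C <- kronecker(orthonormal_contrasts(a), orthonormal_contrasts(b))
  cells <- matrix(aperm(Y, c(1, 3, 2)), n, a * b)  # b fastest, then a
  # aperm gives subject x b x a flattened with b fastest: reorder to
  # match kronecker (a slow, b fast) = as.vector over (b within a)
  cells %*% C
}

#' Two-way within-subjects repeated-measures ANOVA
#'
#' Full within-subject decomposition for an n x a x b complete balanced
#' table (subjects by factor A by factor B), with each effect tested
#' against its own effect-by-subject error term.  Reports F, degrees of
#' freedom, p, partial eta squared, observed power (noncentral-F
#' convention, see [observed_power()]), and Mauchly sphericity tests for
#' every within effect with at least 3 levels (including the
#' interaction).
#'
#' In the alpha-shutter design A is amplitude (low/high), B is the phase
#' bin (0/90/180/270), and the responses are per-participant delta-OR
#' values, giving the df pattern (1, n-1) for amplitude and (3, 3(n-1))
#' for phase and the interaction.
#'
#' @param Y Numeric array, subjects x A-levels x B-levels, no missing
#'   cells.
#' @param factor_names Length-2 character, names of A and B.
#' @param alpha Significance level used for the observed power.
#' @return Object of class `rm_anova`: data frame `effects` with
#'   columns `effect, df_num, df_den, F, p, partial_eta_sq,
#'   observed_power`, and `mauchly`, a named list of [mauchly_test()]
#'   results.
#' @export
rm_anova <- function(Y, factor_names = c("amplitude", "phase"),
                     alpha = 0.05) {
  Y <- unclass(Y)
  if (length(dim(Y)) != 3) stop("Y must be a subjects x A x B array")
  if (anyNA(Y)) stop("missing cells: exclude incomplete subjects upstream")
  n <- dim(Y)[1]; a <- dim(Y)[2]; b <- dim(Y)[3]
  if (n < 2 || a < 2 || b < 2) stop("need >= 2 subjects and levels")
  g <- mean(Y)
  m_s <- apply(Y, 1, mean)
  m_a <- apply(Y, 2, mean)
  m_b <- apply(Y, 3, mean)
  m_sa <- apply(Y, c(1, 2), mean)
  m_sb <- apply(Y, c(1, 3), mean)
  m_ab <- apply(Y, c(2, 3), mean)

  ss_a <- n * b * sum((m_a - g)^2)
  ss_b <- n * a * sum((m_b - g)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, m_b, `+`) + g)^2)
  ss_as <- b * sum((m_sa - outer(m_s, m_a, `+`) + g)^2)
  ss_bs <- a * sum((m_sb - outer(m_s, m_b, `+`) + g)^2)
  resid <- Y
  for (i in seq_len(n)) for (j in seq_len(a)) for (k in seq_len(b))
    resid[i, j, k] <- Y[i, j, k] - m_sa[i, j] - m_sb[i, k] -
      m_ab[j, k] + m_s[i] + m_a[j] + m_b[k] - g
  ss_abs <- sum(resid^2)

  eff <- data.frame(
    effect = c(factor_names[1], factor_names[2],
               paste(factor_names, collapse = " x ")),
    df_num = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df_den = c((a - 1) * (n - 1), (b - 1) * (n - 1),
               (a - 1) * (b - 1) * (n - 1)),
    ss = c(ss_a, ss_b, ss_ab),
    ss_err = c(ss_as, ss_bs, ss_abs)
  )
  eff$ms_err <- eff$ss_err / eff$df_den
  eff$F <- (eff$ss / eff$df_num) / eff$ms_err
  eff$F[eff$ss == 0] <- 0          # no effect variance at all -> F = 0
  eff$p <- stats::pf(eff$F, eff$df_num, eff$df_den, lower.tail = FALSE)
  eff$partial_eta_sq <- partial_eta_sq(eff$F, eff$df_num, eff$df_den)
  eff$observed_power <- observed_power(eff$F, eff$df_num, eff$df_den,
                                       alpha)
  mau <- list()
  try_mauchly <- function(...) tryCatch(mauchly_test(...),
                                        error = function(e) NULL)
  if (a >= 3) mau[[factor_names[1]]] <- try_mauchly(m_sa)
  if (b >= 3) mau[[factor_names[2]]] <- try_mauchly(m_sb)
  if (a >= 2 && b >= 2 && (a - 1) * (b - 1) >= 2)
    mau[[paste(factor_names, collapse = " x ")]] <-
      try_mauchly(interaction_scores(Y), contrasts_applied = TRUE)
  mau <- Filter(Negate(is.null), mau)
  structure(list(effects = eff, mauchly = mau, n = n,
                 factor_names = factor_names),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Two-way within-subjects ANOVA (n = %d)\n", x$n))
  e <- x$effects
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-20s F(%d,%d) = %.3f, p = %.4f, eta_p^2 = %.4f, power = %.3f\n",
                e$effect[i], e$df_num[i], e$df_den[i], e$F[i],
                max(e$p[i], 1e-4), e$partial_eta_sq[i],
                e$observed_power[i]))
  for (nm in names(x$mauchly)) {
    m <- x$mauchly[[nm]]
    cat(sprintf("  Mauchly %-12s chi2(%d) = %.3f, p = %.4f\n",
                nm, m$df, m$chi2, max(m$p, 1e-4)))
  }
  invisible(x)
}

#' Partial eta squared from F and its degrees of freedom
#'
#' `F * df_num / (F * df_num + df_den)`.
#'
#' @param F,df_num,df_den F statistic and its degrees of freedom
#'   (vectorized).
#' @return Effect size in `[0, 1)`.
#' @export
partial_eta_sq <- function(F, df_num, df_den) {
  if (any(F < 0)) stop("F must be non-negative")
  F * df_num / (F * df_num + df_den)
}

#' Post hoc observed power of an F test
#'
#' `P(F' > F_crit(alpha, df_num, df_den))` where `F'` is noncentral F
#' with noncentrality `lambda = F * df_num` (the convention used by
#' standard statistical packages); equals `alpha` at `F = 0` and is
#' strictly increasing in F.
#'
#' @param F,df_num,df_den Observed F statistic and degrees of freedom
#'   (vectorized).
#' @param alpha Test level.
#' @return Power estimate in `[alpha, 1)`.
#' @export
observed_power <- function(F, df_num, df_den, alpha = 0.05) {
  if (any(F < 0)) stop("F must be non-negative")
  fcrit <- stats::qf(1 - alpha, df_num, df_den)
  stats::pf(fcrit, df_num, df_den, ncp = F * df_num, lower.tail = FALSE)
}
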