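test_that("trial measures read phase/amplitude at the snapped sample", {
  fs <- 512
  n <- 4 * fs
  # series with a known per-sample phase ramp (10 Hz) and amplitude
  t <- (0:(n - 1)) / fs
  lo <- make_analytic(wrap_deg(90 + 360 * 10 * t), p2p = 8, fs = fs)
  ro <- make_analytic(wrap_deg(90 + 360 * 10 * t), p2p = 6, fs = fs)
  ev <- data.frame(onset = c(1, 2), type = "flash",
                   observed = c(TRUE, FALSE))
  tm <- trial_measures(lo, ro, ev, t_measure_ms = 75)
  idx <- round(ev$onset * fs) + round(0.075 * fs) + 1
  expect_equal(tm$lo_phase, wrap_deg(90 + 360 * 10 * t[idx]))
  expect_equal(tm$combined_amp, c(7, 7))
  expect_identical(tm$observed, c(TRUE, FALSE))
  expect_error(trial_measures(lo, ro,
                              data.frame(onset = 10, type = "flash",
                                         observed = TRUE), 75),
               "beyond")
})

test_that("asynchrony rejection is strict at 90 degrees", {
  fs <- 512
  ev <- data.frame(onset = c(0.5, 1, 1.5), type = "flash", observed = TRUE)
  lo <- make_analytic(rep(0, 2 * fs), p2p = 4, fs = fs)
  ro <- make_analytic(rep(c(120, 45, 90), each = ceiling(2 * fs / 3))[1:(2 * fs)],
                      p2p = 4, fs = fs)
  tm <- trial_measures(lo, ro, ev, t_measure_ms = 0)
  expect_identical(tm$rejected_asynchrony, c(TRUE, FALSE, FALSE))
  # two-point circular mean halves the separation
  expect_equal(tm$combined_phase[2], 22.5)
  expect_equal(tm$combined_phase[3], 45)   # boundary trial retained
  expect_true(is.na(tm$combined_phase[1]))
})

test_that("the median amplitude split balances levels", {
  tr <- make_trials(phase = c(10, 20, 30, 40), amp = c(1, 2, 3, 4),
                    observed = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(as.character(amplitude_split(tr)),
               c("low", "low", "high", "high"))

  tr2 <- make_trials(phase = 1:4 * 10, amp = rep(5, 4),
                     observed = rep(TRUE, 4))
  expect_warning(lab2 <- amplitude_split(tr2), "degenerate")
  expect_true(all(lab2 == "low"))

  # even-count random amplitudes: the split is exact when the median is
  # not an observed value; otherwise the imbalance is bounded by the
  # tie count (at most 2*ties - 2, by counting the <=-median side)
  set.seed(11)
  for (rep in 1:5) {
    amp <- sample(1:20, 40, replace = TRUE)
    tr3 <- make_trials(phase = runif(40, 0, 360), amp = amp,
                       observed = runif(40) < 0.5)
    lab3 <- amplitude_split(tr3)
    ties <- sum(amp == median(amp))
    imbalance <- abs(sum(lab3 == "high") - sum(lab3 == "low"))
    expect_lte(imbalance, max(0, 2 * ties - 2))
  }
})

test_that("the bin grid partitions trials and centers delta-OR", {
  # all observed: every delta_or is zero
  tr <- make_trials(phase = runif(50, 0, 360), amp = runif(50, 1, 10),
                    observed = rep(TRUE, 50))
  g <- bin_grid(tr, amplitude_split(tr))
  expect_true(all(g$delta_or[!g$empty] == 0))

  # explicit arithmetic: a 3/4 cell against a 50% overall rate
  tr2 <- make_trials(phase = c(0, 0, 1, 359, 170, 180, 181, 175),
                     amp = rep(c(1, 9), 4),
                     observed = c(TRUE, TRUE, TRUE, FALSE,
                                  TRUE, FALSE, FALSE, FALSE))
  lab2 <- factor(rep(c("low", "high"), 4), levels = c("low", "high"))
  g2 <- bin_grid(tr2, lab2)
  expect_equal(attr(g2, "overall_or"), 50)
  cell <- g2[g2$amplitude == "low" & g2$phase_center == 0, ]
  # low-amplitude 0-deg cell: trials 1,3 observed ... construct recount
  expect_equal(cell$n_trials,
               sum(lab2 == "low" &
                     alphashutter:::phase_bin_center(tr2$combined_phase) == 0))
})

test_that("bin grid and rotating profile match an exhaustive recount", {
  set.seed(12)
  for (rep in 1:3) {
    n <- 120
    phase <- runif(n, 0, 360)
    amp <- rlnorm(n, 2, 0.4)
    obs <- runif(n) < 0.5 + 0.2 * cos((phase - 270) * pi / 180)
    tr <- make_trials(phase, amp, obs)
    lab <- amplitude_split(tr)
    g <- bin_grid(tr, lab)
    overall <- 100 * mean(obs)
    expect_equal(sum(g$n_trials), n)   # cells partition retained trials
    for (r in seq_len(nrow(g))) {
      inbin <- ((phase - (g$phase_center[r] - 45)) %% 360) < 90 &
        lab == g$amplitude[r]
      expect_equal(g$n_trials[r], sum(inbin))
      if (any(inbin))
        expect_equal(g$delta_or[r], 100 * mean(obs[inbin]) - overall)
    }
    prof <- rotating_profile(tr, lab)
    for (c0 in seq(0, 355, by = 5)) {    # recount a systematic subset
      for (lev in c("low", "high")) {
        inbin <- ((phase - (c0 - 45)) %% 360) < 90 & lab == lev
        if (any(inbin))
          expect_equal(prof[[lev]][c0 + 1],
                       100 * mean(obs[inbin]) - overall)
      }
    }
    # profile agrees with the grid at the four cardinal centers
    for (r in seq_len(nrow(g))) {
      if (!g$empty[r])
        expect_equal(prof[[as.character(g$amplitude[r])]][g$phase_center[r] + 1],
                     g$delta_or[r])
    }
  }
})

test_that("dense cosine-gated trials produce a cosine-like profile", {
  set.seed(13)
  n <- 6000
  phase <- runif(n, 0, 360)
  obs <- runif(n) < 0.5 + 0.3 * cos((phase - 270) * pi / 180)
  tr <- make_trials(phase, rlnorm(n, 2, 0.3), obs)
  lab <- amplitude_split(tr)
  prof <- rotating_profile(tr, lab)
  for (lev in c("low", "high")) {
    pp <- preferred_phase(prof, lev)
    expect_lt(abs(circ_diff(pp$angle, 270)), 12)
  }
})

test_that("small rotating-bin gaps interpolate, large ones flag", {
  vals <- sin((0:359) * pi / 180)
  vals[100:103] <- NA
  filled <- alphashutter:::interp_circular_gaps(vals, 5)
  expect_false(anyNA(filled))
  expect_lt(max(abs(filled[100:103] - sin((99:102) * pi / 180))), 0.01)
  vals[200:220] <- NA
  part <- alphashutter:::interp_circular_gaps(vals, 5)
  expect_true(anyNA(part[200:220]))
})

test_that("preferred phase recovers cosine profiles analytically", {
  cc <- 0:359
  prof <- 3 * cos((cc - 270) * pi / 180)
  pp <- preferred_phase(prof)
  expect_equal(pp$angle, 270, tolerance = 1e-8)
  expect_equal(pp$magnitude, 1.5, tolerance = 1e-8)
  expect_equal(pp$ppe, 6, tolerance = 1e-6)
  expect_equal(pp$pessimal_angle, 90, tolerance = 1e-8)
  # PPE = 4 x magnitude for cosine-shaped profiles
  expect_equal(pp$ppe, 4 * pp$magnitude, tolerance = 1e-6)
  expect_error(preferred_phase(rep(2, 360)), "zero")
})

test_that("preferred phase matches a brute-force vector sum", {
  set.seed(14)
  for (rep in 1:5) {
    prof <- as.numeric(arima.sim(list(ar = 0.9), 360)) + runif(1, -2, 2)
    x <- 0; y <- 0
    for (c0 in 0:359) {
      x <- x + prof[c0 + 1] * cos(c0 * pi / 180)
      y <- y + prof[c0 + 1] * sin(c0 * pi / 180)
    }
    x <- x / 360; y <- y / 360
    pp <- preferred_phase(prof)
    expect_equal(pp$angle, wrap_deg(atan2(y, x) * 180 / pi))
    expect_equal(pp$magnitude, sqrt(x^2 + y^2))
  }
})

test_that("group preferred phase equals the mean-profile preferred phase", {
  set.seed(15)
  profs <- lapply(1:8, function(i)
    rnorm(1, 5, 1) * cos(((0:359) - rnorm(1, 270, 20)) * pi / 180) +
      rnorm(360, 0, 0.5))
  pps <- lapply(profs, preferred_phase)
  grp <- group_preferred_phase(pps, profs)
  direct <- preferred_phase(Reduce(`+`, profs) / length(profs))
  # linearity identity, machine precision
  expect_equal(grp$angle, direct$angle, tolerance = 1e-10)
  expect_equal(grp$magnitude, direct$magnitude, tolerance = 1e-10)
  expect_equal(grp$ppe, direct$ppe, tolerance = 1e-10)

  same <- group_preferred_phase(list(make_pp(120, 2), make_pp(120, 2)))
  expect_equal(same$angle, 120)
  expect_equal(same$magnitude, 2)
  expect_error(group_preferred_phase(list(make_pp(0, 1),
                                          make_pp(180, 1))),
               "zero resultant")
})

test_that("angular CIs match a dense rectangle-sampling oracle", {
  set.seed(16)
  for (rep in 1:4) {
    ang <- runif(10, 220, 320); mag <- runif(10, 2, 8)
    pps <- mapply(make_pp, ang, mag, SIMPLIFY = FALSE)
    ci <- preferred_phase_ci(pps)
    expect_false(ci$full_circle)
    xs <- mag * cos(ang * pi / 180); ys <- mag * sin(ang * pi / 180)
    tc <- qt(0.975, 9)
    xci <- mean(xs) + c(-1, 1) * tc * sd(xs) / sqrt(10)
    yci <- mean(ys) + c(-1, 1) * tc * sd(ys) / sqrt(10)
    pts <- expand.grid(x = seq(xci[1], xci[2], length.out = 100),
                       y = seq(yci[1], yci[2], length.out = 100))
    ga <- atan2(mean(ys), mean(xs)) * 180 / pi
    offs <- circ_diff(atan2(pts$y, pts$x) * 180 / pi, ga)
    expect_equal(ci$ci_deg[1], wrap_deg(ga + min(offs)), tolerance = 0.2)
    expect_equal(ci$ci_deg[2], wrap_deg(ga + max(offs)), tolerance = 0.2)
  }
})

test_that("CI width shrinks for concordant vectors and widens to the full
           circle when the rectangle spans the origin", {
  tight <- lapply(rep(250, 20), make_pp, magnitude = 5)
  # identical vectors: sd 0 -> degenerate point interval
  ci <- preferred_phase_ci(tight)
  expect_lt(abs(circ_diff(ci$ci_deg[1], 250)), 1e-6)
  expect_lt(abs(circ_diff(ci$ci_deg[2], 250)), 1e-6)

  spread <- mapply(make_pp, c(0, 90, 180, 270, 45), rep(3, 5),
                   SIMPLIFY = FALSE)
  expect_warning(full <- preferred_phase_ci(spread), "full-circle")
  expect_true(full$full_circle)
  expect_equal(full$ci_deg, c(0, 360))
  expect_error(preferred_phase_ci(tight[1:2]), "3 individuals")
})
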