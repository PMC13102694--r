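test_that("peak features reproduce analytic pulse shapes", {
  # Gaussian pulse, sigma = 1 h: FWHM = 2.3548 h
  dt <- 0.01
  tt <- seq(0, 24, by = dt)
  y <- exp(-(tt - 12)^2 / 2)
  ts <- time_series(tt, list(sig = y))
  pf <- peak_features(ts, "sig", threshold_sd = 2, reference_time = 5)
  expect_equal(nrow(pf), 1L)
  expect_equal(pf$fwhm, 2 * sqrt(2 * log(2)), tolerance = 0.01)
  expect_equal(pf$peak_time, 12, tolerance = 2 * dt)

  # symmetric triangle of amplitude 2 over [8, 12]: FWHM exactly 2
  ytri <- pmax(0, 2 * (1 - abs(tt - 10) / 2))
  ts2 <- time_series(tt, list(sig = ytri))
  pf2 <- peak_features(ts2, "sig", reference_time = 5)
  expect_equal(pf2$fwhm, 2, tolerance = 1e-6)
  expect_equal(pf2$amplitude, 2, tolerance = 1e-9)
  expect_equal(pf2$time_to_peak, 5, tolerance = 2 * dt)
  expect_lte(pf2$onset_time, pf2$peak_time)

  # flat series: no peaks
  ts3 <- time_series(tt, list(sig = rep(0, length(tt))))
  expect_equal(nrow(peak_features(ts3, "sig", reference_time = 5)), 0L)

  expect_error(peak_features(ts, "sig", reference_time = 0), "pre-reference")
})

test_that("line length is the total variation within the window", {
  ts <- time_series(1:4, list(a = c(0, 1, 0, 1), b = rep(2, 4)))
  expect_equal(line_length(ts, "a"), 3)
  expect_equal(line_length(ts, "b"), 0)

  # sine over one period on a dense grid -> total variation 4
  n <- 1000
  tt <- seq(0, 1, length.out = n)
  tsin <- time_series(tt, list(s = sin(2 * pi * tt)))
  expect_equal(line_length(tsin, "s"), 4, tolerance = 0.01)

  expect_error(line_length(ts, "a", 10, 11), "window")
})

test_that("post-stimulation mean behaves on simple signals", {
  tt <- seq(0, 10, by = 0.01)
  ts <- time_series(tt, list(
    const = ifelse(tt >= 5, 0.5, 0),
    ramp = ifelse(tt >= 5 & tt <= 7, (tt - 5) / 2, 0)))
  expect_equal(post_stim_mean(ts, "const", 5, 3), 0.5, tolerance = 1e-9)
  expect_equal(post_stim_mean(ts, "ramp", 5, 2), 0.5, tolerance = 0.01)
  # a pulse entirely outside the window leaves the baseline mean
  expect_equal(post_stim_mean(ts, "ramp", 0, 2), 0, tolerance = 1e-9)
  expect_error(post_stim_mean(ts, "ramp", 50, 1), "window")
})

test_that("lag correlation recovers planted shifts and is symmetric", {
  dt <- 0.01
  n <- 400
  set.seed(51)
  base <- moving_avg_oracle(rnorm(n + 50), 7)
  a <- base[1:n]
  tsA <- time_series(seq(0, by = dt, length.out = n), list(x = a))
  # identical series: r(0) = 1 at zero lag
  lp0 <- lag_correlation(tsA, tsA, "x", "x", max_lag = 0.1)
  expect_equal(lp0$correlations[lp0$lags == 0], 1)
  expect_equal(lp0$lags[which.max(lp0$correlations)], 0)
  # grid is symmetric about zero
  expect_equal(lp0$lags, -rev(lp0$lags))

  # planted shift of 3 lag steps: B(t) = A(t - 3 dt)
  b <- c(rep(NA, 3), a[1:(n - 3)])
  b[1:3] <- a[1]
  tsB <- time_series(seq(0, by = dt, length.out = n), list(y = b))
  lp <- lag_correlation(tsA, tsB, "x", "y", max_lag = 0.1)
  expect_equal(lp$lags[which.max(lp$correlations)], 3 * dt)

  # antisymmetry between the two orderings
  lp_ab <- lag_correlation(tsA, tsB, "x", "y", max_lag = 0.08)
  lp_ba <- lag_correlation(tsB, tsA, "y", "x", max_lag = 0.08)
  expect_equal(lp_ab$correlations, rev(lp_ba$correlations),
               tolerance = 1e-9)

  # independent white noise stays weakly correlated at all lags
  set.seed(52)
  hits <- 0
  for (i in 1:100) {
    u <- rnorm(200)
    v <- rnorm(200)
    tu <- time_series(seq(0, by = dt, length.out = 200), list(x = u))
    tv <- time_series(seq(0, by = dt, length.out = 200), list(y = v))
    lpn <- lag_correlation(tu, tv, "x", "y", max_lag = 0.05)
    if (max(abs(lpn$correlations), na.rm = TRUE) < 0.3) hits <- hits + 1
  }
  expect_gte(hits, 95)

  # zero-variance segments are masked, not errors
  flat <- time_series(seq(0, by = dt, length.out = n),
                      list(y = rep(1, n)))
  lpf <- lag_correlation(tsA, flat, "x", "y", max_lag = 0.05)
  expect_true(all(is.na(lpf$correlations)))
})

test_that("coupling classification separates coupled and decoupled cells", {
  # clean archetypes: perfect near-zero correlation vs flat
  lags <- seq(-0.5, 0.5, by = 0.05)
  arch_c <- list(lags = lags,
                 correlations = exp(-abs(lags) / 0.08))
  arch_d <- list(lags = lags, correlations = rep(0.02, length(lags)))
  class(arch_c) <- class(arch_d) <- "lag_profile"
  profs <- c(rep(list(arch_c), 5), rep(list(arch_d), 5))
  res <- classify_coupling(profs)
  expect_equal(res$label,
               c(rep("type2_coupled", 5), rep("type1_decoupled", 5)))

  # scaling every profile uniformly leaves the partition unchanged
  profs_scaled <- lapply(profs, function(p) {
    p$correlations <- 0.5 * p$correlations
    p
  })
  expect_equal(classify_coupling(profs_scaled)$label, res$label)

  # degenerate input: identical profiles labelled by the threshold rule
  dup <- rep(list(arch_c), 6)
  resd <- classify_coupling(dup)
  expect_true(attr(resd, "degenerate"))
  expect_true(all(resd$label == "type2_coupled"))

  expect_error(classify_coupling(profs[1:3]), "at least 4")
})

test_that("synthetic coupled/decoupled cohorts are classified correctly", {
  for (sd in 0:4) {
    cohort <- simulate_coupling_cohort(n_coupled = 20, n_decoupled = 20,
                                       seed = sd)
    profs <- lapply(cohort$series, function(s)
      lag_correlation(s$up, s$down, "pcreb", "fos", max_lag = 0.15))
    res <- classify_coupling(profs)
    agreement <- mean(res$label == cohort$truth)
    agreement <- max(agreement, 1 - agreement) # labels are exchangeable
    expect_gte(agreement, 0.9)
  }
})

test_that("fibers are assigned to the soma holding their majority", {
  sp <- c(0.4, 0.2, 0.2)
  labs <- array(0L, c(20, 40, 60))
  labs[, , 1:30] <- 3L
  labs[, , 31:60] <- 5L
  soma <- label_volume(labs, sp, "soma")

  mk <- function(x0, x1, n = 100)
    centerline(cbind(2, 2, seq(x0, x1, length.out = n)), method = "manual")

  # fully inside label 3
  r1 <- assign_fibers_to_cells(list(f1 = mk(0.5, 4)), soma)
  expect_equal(r1$assignments$cell, 3L)

  # 60% in label 3 / 40% in label 5 -> label 3
  r2 <- assign_fibers_to_cells(list(f2 = mk(2, 7.95)), soma)
  expect_equal(r2$assignments$cell, 3L)

  # two fibers in one cell: the longer one is the representative
  r3 <- assign_fibers_to_cells(list(short = mk(0.5, 4), long = mk(0.2, 5)),
                               soma)
  expect_equal(unname(r3$representatives["3"]), "long")
  expect_true(r3$assignments$representative[r3$assignments$fiber == "long"])

  # an exact 50/50 tie leaves the fiber unassigned
  r4 <- assign_fibers_to_cells(list(tie = mk(5.9, 6.1, n = 100)), soma)
  expect_true(is.na(r4$assignments$cell) ||
                r4$assignments$geodesic_length > 0)
})
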