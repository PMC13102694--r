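make_profile <- function(y, L = 10, extra = list()) {
  arc <- seq(0, L, length.out = length(y))
  fiber_profile(arc, c(list(ref = y), extra))
}

test_that("mirror-symmetric profiles split at the geometric center", {
  set.seed(41)
  h <- cumsum(rnorm(400))
  h <- h - min(h) + 1
  y <- c(rev(h), h[-1])   # palindrome sharing the center sample
  prof <- make_profile(y)
  sp <- find_split(prof, "ref", window_frac = 0.2)
  expect_equal(sp$pearson_r, 1, tolerance = 1e-9)
  expect_equal(sp$split_arclength, 5, tolerance = 0.02)
})

test_that("planted off-center splits are recovered exactly", {
  # profile built as reversed(H) then H, with the junction inside the
  # search window; brute-force correlation scan is the oracle
  set.seed(42)
  for (rep in 1:5) {
    h <- moving_avg_oracle(rnorm(300), 15)
    nl <- sample(260:340, 1)
    left <- approx(seq_along(h), h, xout = seq(1, length(h),
                                               length.out = nl))$y
    y <- c(rev(left), h)
    prof <- make_profile(y, L = length(y) / 60)
    sp <- find_split(prof, "ref", window_frac = 0.2)
    oracle <- brute_force_split(prof$arclength, y, window_frac = 0.2)
    expect_equal(sp$split_index, oracle)
  }
})

test_that("split search rejects degenerate reference channels", {
  prof <- make_profile(rep(3, 200))
  expect_error(find_split(prof, "ref"), "zero variance")
  expect_error(find_split(make_profile(rnorm(30)), "ref"), "short")
  expect_error(find_split(make_profile(rnorm(200)), "nope"), "not present")
})

test_that("mode presets fix the split window fraction", {
  expect_equal(run_config(mode = "cultured")$window_frac, 0.2)
  expect_equal(run_config(mode = "in_vivo")$window_frac, 0.05)
  expect_equal(run_config(mode = "cultured")$transfer_model, "quadratic")
  expect_equal(run_config(mode = "in_vivo")$transfer_model,
               "piecewise_linear")
})

test_that("baseline normalization produces relative changes", {
  y <- rep(2, 100)
  y[60] <- 3
  prof <- make_profile(rep(1, 100), extra = list(sig = y))
  out <- normalize_baseline(prof, 50)
  expect_equal(out$channels$sig[60], 0.5)
  expect_true(all(abs(out$channels$sig[-60]) < 1e-12))
  # constant channel -> all zeros
  expect_true(all(abs(out$channels$ref) < 1e-12))
  # zero baseline -> division-unsafe error naming the channel
  prof0 <- make_profile(rep(1, 100), extra = list(bad = rep(0, 100)))
  expect_error(normalize_baseline(prof0, 50), "bad")
})

test_that("changepoint detection locates steps and pulse onsets", {
  # noise-free step at sample 600 of 1000, encoded as a dye pair
  y <- c(rep(0, 600), rep(1, 400))
  prof2 <- make_profile(1 - y, extra = list(d2 = y))
  h2 <- split_profile(prof2, 1L)$right
  names(h2$channels) <- c("d1", "d2")
  ts2 <- detect_timestamps(h2, c("d1", "d2"), 2, 4, mode = "dye_switch")
  expect_true(ts2$detected)
  expect_equal(ts2$anchors$fraction[1], 0.600, tolerance = 0.002)
  expect_equal(ts2$anchors$fraction[nrow(ts2$anchors)], 1)
  expect_equal(ts2$anchors$time, c(2, 4))

  # noise-free trapezoid: rise onset at 0.40, decay onset at 0.70,
  # cross-checked against the exhaustive two-changepoint oracle
  n <- 250
  x <- seq(0, 1, length.out = n)
  trap <- ifelse(x < 0.4, 0, ifelse(x < 0.7, (x - 0.4) / 0.3,
                                    1 - (x - 0.7) / 0.3))
  hp <- split_profile(make_profile(trap), 1L)$right
  names(hp$channels) <- "flag"
  ts3 <- detect_timestamps(hp, "flag", c(10, 12), 14, mode = "dox_pulse",
                           smooth_frac = 0)
  expect_true(ts3$detected)
  expect_equal(ts3$anchors$fraction[1:2], c(0.40, 0.70), tolerance = 0.01)
  oracle <- oracle_two_changepoints(trap)
  expect_equal(oracle$k / n, c(0.40, 0.70), tolerance = 0.012)

  # flat channel -> detection failure flag
  hflat <- split_profile(make_profile(rep(1, 200),
                                      extra = list(d2 = rep(1, 200))),
                         1L)$right
  ts4 <- detect_timestamps(hflat, c("ref", "d2"), 2, 4,
                           mode = "dye_switch")
  expect_false(ts4$detected)
})

test_that("transfer fits pass through anchors and stay monotone", {
  # quadratic through the worked anchors, against the 3x3 solve oracle
  anch <- timestamp_set(c(0.5, 0.7, 1.0), c(2, 5.5, 11))
  tf <- fit_transfer(anch, "quadratic")
  A <- cbind(1, c(0.5, 0.7, 1.0), c(0.5, 0.7, 1.0)^2)
  coef_oracle <- solve(A, c(2, 5.5, 11))
  expect_lt(max(abs(unlist(tf$coefficients) - coef_oracle)), 1e-9)
  expect_equal(predict(tf, 0.85),
               sum(coef_oracle * c(1, 0.85, 0.85^2)), tolerance = 1e-12)
  expect_equal(predict(tf, 0.85), 8.2125, tolerance = 1e-9)

  # linear through two anchors
  tf2 <- fit_transfer(timestamp_set(c(0.5, 1), c(5, 10)), "linear")
  expect_equal(predict(tf2, 0.25), 2.5, tolerance = 1e-12)

  # piecewise linear hits every anchor and extrapolates end slopes
  tf3 <- fit_transfer(timestamp_set(c(0.55, 0.82, 1), c(10, 12, 14)),
                      "piecewise_linear")
  expect_lt(max(abs(predict(tf3, c(0.55, 0.82, 1)) - c(10, 12, 14))),
            1e-12)
  slope_hi <- (14 - 12) / (1 - 0.82)
  expect_equal(predict(tf3, 1.05), 14 + 0.05 * slope_hi)

  # anchor exactness across families with #anchors <= dof
  for (model in c("linear", "quadratic", "piecewise_linear",
                  "monotone_spline")) {
    a <- timestamp_set(c(0.4, 0.7, 1), c(3, 6, 11))
    a2 <- if (model == "linear") timestamp_set(c(0.5, 1), c(4, 9)) else a
    tfm <- fit_transfer(a2, model)
    expect_lt(max(abs(predict(tfm, a2$anchors$fraction) -
                        a2$anchors$time)), 1e-9)
  }
  # power-law fit is near-exact for three anchors and monotone
  tfp <- fit_transfer(timestamp_set(c(0.5, 0.7, 1), c(2, 5.5, 11)),
                      "power")
  expect_lt(max(abs(predict(tfp, c(0.5, 0.7, 1)) - c(2, 5.5, 11))), 1e-5)
  expect_true(all(diff(predict(tfp, seq(0.5, 1, length.out = 200))) > 0))

  # decreasing anchor times are invalid
  expect_error(fit_transfer(timestamp_set(c(0.5, 1), c(5, 3))), "invalid")

  # a non-monotone fit falls back to piecewise linear with a flag
  wavy <- timestamp_set(c(0.1, 0.2, 0.9, 1), c(1, 8, 8.5, 9))
  tfw <- fit_transfer(wavy, "quadratic")
  expect_equal(tfw$model, "piecewise_linear")
  expect_true("nonmonotone_fallback" %in% tfw$flags)
})

test_that("warping maps fractions to a uniform time axis", {
  n <- 200
  y <- sin(seq(0, 2 * pi, length.out = n))
  prof <- make_profile(y, L = 8)
  halves <- split_profile(prof, 1L)
  h <- halves$right
  tf <- fit_transfer(timestamp_set(c(0.5, 1), c(4, 8)), "linear") # t = 8f
  ts <- warp_to_time(h, tf, dt = 0.05)
  expect_true(all(abs(diff(ts$time) - 0.05) < 1e-9))
  # identity-like transfer preserves the values
  expect_equal(approx(ts$time / 8, ts$channels$ref,
                      xout = h$fraction[10:190])$y,
               y[10:190], tolerance = 0.01)
  # samples before the first anchor are flagged as extrapolated
  expect_true(all(ts$extrapolated[ts$time < 4 - 1e-9]))
  expect_false(any(ts$extrapolated[ts$time >= 4]))

  # a convex (quadratic) transfer stretches later fractions
  tfq <- fit_transfer(timestamp_set(c(0.2, 0.6, 1), c(1, 2.6, 9)),
                      "quadratic")
  mapped <- predict(tfq, seq(0.2, 1, length.out = 50))
  expect_true(all(diff(diff(mapped)) > -1e-9))

  expect_error(warp_to_time(h, tf, dt = -1), "positive")
})

test_that("round trip recovers scheduled switch times for all growth laws", {
  # simulate -> render noise-free -> full pipeline -> compare the detected
  # switch position, mapped through the true growth law, with the schedule
  pulse <- promoter_waveform(baseline = 0.5, amplitude = 1.5,
                             stim_time = 2.5, tau_rise = 0.2,
                             tau_decay = 0.45)
  cfg <- run_config(schedule_times = 2, fixation = 4, signals = "fos",
                    sampling = "cylindrical")
  for (b in c(0.5, 0.75, 1)) {
    # pick the rate so every growth law yields the same 12.8 um fiber
    a_b <- 12.8 / (2 * 4^b)
    sim <- simulate_tape_cell(a = a_b, b = b,
                              signal_waveforms = list(fos = pulse),
                              seed = 30 + round(100 * b), noise = FALSE)
    run <- decode_volume(sim$volume, cfg)
    expect_length(run$fibers, 1)
    f <- run$fibers[[1]]
    traj <- simulate_growth(sim$model, 100)
    # detected switch arclength on each half, mapped through the true law
    prof <- sample_cylindrical(sim$volume, f$centerline)
    sp <- f$split
    halves <- split_profile(prof, sp)
    for (h in c("left", "right")) {
      anch <- detect_timestamps(halves[[h]], cfg$dyes, 2, 4,
                                mode = "dye_switch")
      s_hat <- anch$anchors$fraction[1] * halves[[h]]$length_um
      t_hat <- traj$time_of_length(s_hat)
      expect_lt(abs(t_hat - 2), 0.02 * 4 + 1e-9)
    }
    # half-consistency: the two warped halves agree on every channel
    ha <- f$halves$left$series
    hb <- f$halves$right$series
    grid <- seq(max(min(ha$time), min(hb$time)),
                min(max(ha$time), max(hb$time)), length.out = 300)
    for (ch in names(ha$channels)) {
      va <- approx(ha$time, ha$channels[[ch]], grid)$y
      vb <- approx(hb$time, hb$channels[[ch]], grid)$y
      expect_gt(cor(va, vb), 0.95)
    }
  }
})
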