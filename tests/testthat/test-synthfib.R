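test_that("growth law matches closed forms and is invertible", {
  m1 <- growth_model(a = 2, b = 1, t0 = 1, duration = 4)
  tr1 <- simulate_growth(m1, 50)
  expect_equal(tr1$length_of_time(3), 4)

  m2 <- growth_model(a = 4, b = 0.5, t0 = 0, duration = 5)
  tr2 <- simulate_growth(m2, 50)
  expect_equal(tr2$length_of_time(4), 8)

  expect_true(all(diff(tr1$half_length) > 0))
  expect_true(all(diff(tr1$time) > 0))
  set.seed(7)
  tt <- runif(100, 1.001, 5)
  expect_lt(max(abs(tr1$time_of_length(tr1$length_of_time(tt)) - tt) /
                  tt), 1e-9)

  expect_error(growth_model(a = -1), "invalid")
  expect_error(growth_model(a = 1, b = 0), "invalid")
  expect_error(growth_model(a = 1, duration = -2), "invalid")
  expect_error(simulate_growth(m1, 1), "n_samples")
})

test_that("promoter and Dox waveforms behave as specified", {
  w <- promoter_waveform(baseline = 0.2, amplitude = 1.3, stim_time = 2,
                         delay = 0.1, tau_rise = 0.05, tau_decay = 0.3)
  tt <- seq(0, 6, by = 0.001)
  v <- waveform_value(w, tt)
  expect_true(all(v >= 0))
  expect_true(all(v[tt < 2.1] == 0.2))
  expect_equal(max(v), 0.2 + 1.3, tolerance = 1e-4)

  d <- dox_waveform(t_on = 10, t_off = 12, amplitude = 2)
  vd <- waveform_value(d, c(9, 10.5, 12, 13))
  expect_equal(vd[1], 0)
  expect_true(vd[2] > 0 && vd[3] > vd[2] && vd[4] < vd[3])

  cw <- composite_waveform(list(
    promoter_waveform(baseline = 0.5, amplitude = 1, stim_time = 1),
    promoter_waveform(baseline = 0.5, amplitude = 1, stim_time = 3)),
    baseline = 0.5)
  vc <- waveform_value(cw, tt)
  expect_equal(vc[tt < 1.05][1], 0.5)
  expect_gt(waveform_fwhm(cw), 0)
})

test_that("fiber records encode dye switches and signals along arclength", {
  traj <- simulate_growth(growth_model(a = 5, b = 1, duration = 4), 400)
  sch <- dye_schedule(data.frame(switch_time = c(0, 2),
                                 channel = c("dye1", "dye2")), 4)
  rec <- compose_fiber_record(traj, schedule = sch, structural_level = 3)
  expect_equal(rec$L, 20)
  # exact encoding fidelity: switch fraction = s(switch)/s(fixation)
  expect_identical(rec$dye_switch_fraction, 0.5)
  expect_true(all(rec$channels$structural == 3))

  # mirror symmetry of the full record
  fr <- full_record(rec)
  for (ch in names(fr$channels))
    if (stats::sd(fr$channels[[ch]]) > 0)
      expect_equal(cor(fr$channels[[ch]], rev(fr$channels[[ch]])), 1)

  # signal pulse deposits its maximum at s(t*) within one sample step
  pw <- promoter_waveform(baseline = 0.1, amplitude = 1, stim_time = 2.5,
                          delay = 0.1, tau_rise = 0.05, tau_decay = 0.3)
  rec2 <- compose_fiber_record(traj, waveforms = list(sig = pw),
                               schedule = sch, structural_level = 1)
  tgrid <- rec2$time
  t_star <- tgrid[which.max(waveform_value(pw, tgrid))]
  s_star <- traj$length_of_time(t_star)
  s_hat <- rec2$arclength[which.max(rec2$channels$sig)]
  expect_lt(abs(s_hat - s_star), 2 * rec2$ds)

  # a waveform colliding with a dye channel id is a configuration error
  expect_error(
    compose_fiber_record(traj, waveforms = list(dye2 = pw), schedule = sch),
    "configuration error")
})

test_that("encoding fidelity holds across random growth models", {
  set.seed(11)
  for (i in 1:10) {
    a <- runif(1, 0.5, 3)
    b <- sample(c(0.5, 0.75, 1), 1)
    dur <- runif(1, 3, 10)
    sw <- sort(runif(2, 0.2 * dur, 0.8 * dur))
    traj <- simulate_growth(growth_model(a = a, b = b, duration = dur), 300)
    sch <- dye_schedule(data.frame(switch_time = c(0, sw),
                                   channel = c("d1", "d2", "d3")), dur)
    rec <- compose_fiber_record(traj, schedule = sch)
    expect_equal(rec$dye_switch_fraction,
                 traj$length_of_time(sw) / traj$length_of_time(dur),
                 tolerance = 1e-12)
  }
})

test_that("confined centerline generation is deterministic and bounded", {
  p0 <- generate_centerline_curve(10, max_curvature = 0, soma_radius = 8,
                                  seed = 1)
  expect_equal(sqrt(sum((p0[1, ] - p0[nrow(p0), ])^2)), 10,
               tolerance = 1e-9)
  expect_lt(max(discrete_curvature_for_test(p0)), 1e-9)

  p1 <- generate_centerline_curve(14, 0.2, 7.5, seed = 5, z_scale = 0.4)
  p2 <- generate_centerline_curve(14, 0.2, 7.5, seed = 5, z_scale = 0.4)
  expect_identical(p1, p2)

  for (sd in 1:8) {
    L <- runif(1, 9, 16)
    p <- generate_centerline_curve(L, 0.2, 7.5, seed = sd, z_scale = 0.4)
    arclen <- sum(sqrt(rowSums(diff(p)^2)))
    expect_lt(abs(arclen - L) / L, 0.01)
    expect_lte(max(discrete_curvature_for_test(p)), 0.2 * 1.05)
    expect_lte(max(sqrt(rowSums(p^2))), 7.5)
  }

  expect_error(generate_centerline_curve(40, 0.05, 5, seed = 1),
               "infeasible")
})

test_that("rendering is deterministic, background-exact and mass-linear", {
  cfg <- render_config(seed = 42)
  empty <- render_volume(list(), list(), config = cfg,
                         shape = c(16L, 24L, 24L), noise = FALSE)
  expect_true(all(empty$volume$data$nissl == cfg$background))

  rec <- standard_record(a = 1.2, config = cfg)
  r1 <- render_straight_fiber(rec, cfg, noise = TRUE)
  r2 <- render_straight_fiber(rec, cfg, noise = TRUE)
  expect_identical(r1$volume$data, r2$volume$data)

  # doubling length doubles the summed noise-free intensity above background
  rec_long <- standard_record(a = 2.4, config = cfg)
  s1 <- render_straight_fiber(rec, cfg, noise = FALSE)
  s2 <- render_straight_fiber(rec_long, cfg, noise = FALSE)
  tot <- function(r) sum(r$volume$data$structural - cfg$background)
  expect_equal(tot(s2) / tot(s1), 2, tolerance = 0.02)

  # a fiber breaking the margin is rejected with its index
  sp <- cfg$voxel_spacing
  bad_poly <- cbind(rep(0.1, 40), rep(3, 40), seq(1, 5, length.out = 40))
  expect_error(render_volume(list(list(record = rec, polyline = bad_poly)),
                             config = cfg, shape = c(24L, 48L, 48L)),
               "fiber 1 exits")
})

test_that("ground truth of a simulated cell is fully populated", {
  pulse <- promoter_waveform(baseline = 0.5, amplitude = 1.5,
                             stim_time = 2.5)
  sim <- simulate_tape_cell(a = 1.1, signal_waveforms = list(fos = pulse),
                            shape = c(64L, 100L, 100L), soma_radius = 5.5,
                            seed = 2, noise = FALSE)
  gt <- sim$ground_truth$fibers[[1]]
  expect_equal(gt$split_arclength, sim$record$L)
  expect_equal(gt$total_length, 2 * sim$record$L)
  expect_equal(gt$dye_switch_arclength, sim$model$a * 2)
  expect_equal(gt$cell, 1L)
  expect_s3_class(sim$volume, "image_volume")
  expect_true(all(c("structural", "dye1", "dye2", "fos", "nissl") %in%
                    sim$volume$channels))
})
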