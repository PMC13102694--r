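## Ground-truthed single-cell experiments: one soma + one tape fiber per
## 128^3 volume, used for end-to-end parameter-recovery studies.

#' Sum of promoter pulses sharing one baseline
#' @param pulses list of [promoter_waveform()]s.
#' @param baseline common baseline (a.u.).
#' @return a `composite_waveform`.
#' @export
composite_waveform <- function(pulses, baseline = 0) {
  stopifnot(length(pulses) >= 1)
  structure(list(pulses = pulses, baseline = baseline),
            class = c("composite_waveform", "tape_waveform"))
}

#' @export
waveform_value.composite_waveform <- function(w, t) {
  out <- rep(w$baseline, length(t))
  for (p in w$pulses) out <- out + waveform_value(p, t) - p$baseline
  out
}

#' Numeric full width at half maximum of a waveform pulse
#' @param w a waveform object.
#' @param span time range to scan (days).
#' @param n grid resolution.
#' @return FWHM in days.
#' @export
waveform_fwhm <- function(w, span = c(0, 20), n = 20001L) {
  tt <- seq(span[1], span[2], length.out = n)
  y <- waveform_value(w, tt) - w$baseline
  pk <- which.max(y)
  half <- y[pk] / 2
  above <- which(y >= half)
  tt[max(above)] - tt[min(above)]
}

#' Simulate one cell: growth, record composition and confocal rendering
#'
#' Builds a single soma with one bidirectionally grown tape fiber, deposits
#' the dye-timestamp and signal records along it, and renders the stack
#' with the configured PSF and noise model. The defaults state a 4-day
#' cultured-cell recording: linear growth, one dye switch at day 2, a
#' promoter pulse, 128^3 voxels at (0.4, 0.13, 0.13) um spacing, and
#' deposition levels calibrated for a peak SNR of 5.
#'
#' @param a elongation rate (um/day per half-fiber).
#' @param b growth exponent.
#' @param duration recording span (days); fixation at `t0 + duration`.
#' @param t0 nucleation time (days).
#' @param switch_times dye-switch times (days); `NULL` for no dye channels.
#' @param signal_waveforms named list of waveform objects for signal
#'   channels (levels in deposition units; see `snr`).
#' @param dox_channel optional name of a Dox-dependent timestamp channel
#'   rendered from `dox` (a [dox_waveform()]).
#' @param dox a [dox_waveform()] (required with `dox_channel`).
#' @param snr peak structural-channel signal-to-noise ratio.
#' @param config a [render_config()].
#' @param shape volume dimensions.
#' @param max_curvature,soma_radius fiber geometry (um^-1, um).
#' @param z_scale flattening of the cell along the optical axis (adherent
#'   cultured cells are oblate, so fibers lie mostly in-plane).
#' @param seed integer seed (geometry + noise).
#' @param noise render with the noise model.
#' @return list with `volume`, `ground_truth`, `record`, `model`.
#' @export
simulate_tape_cell <- function(a = 1.6, b = 1, duration = 4, t0 = 0,
                               switch_times = 2,
                               signal_waveforms = NULL,
                               dox_channel = NULL, dox = NULL,
                               snr = 5, config = render_config(),
                               shape = c(128L, 128L, 128L),
                               max_curvature = 0.2, soma_radius = 7.5,
                               z_scale = 0.4, seed = 1L, noise = TRUE) {
  model <- growth_model(a = a, b = b, t0 = t0, duration = duration)
  traj <- simulate_growth(model, n_samples = 500)
  fixation <- t0 + duration
  level <- level_for_snr(config, snr)
  schedule <- NULL
  if (!is.null(switch_times) && length(switch_times)) {
    dye_names <- paste0("dye", seq_len(length(switch_times) + 1L))
    schedule <- dye_schedule(
      data.frame(switch_time = c(t0, switch_times), channel = dye_names),
      fixation_time = fixation)
  }
  waveforms <- list()
  if (!is.null(signal_waveforms)) {
    # signal deposition scaled to the calibrated structural level
    waveforms <- lapply(signal_waveforms, function(w) {
      w$baseline <- w$baseline * level
      if (!is.null(w$amplitude)) w$amplitude <- w$amplitude * level
      if (!is.null(w$pulses))
        w$pulses <- lapply(w$pulses, function(p) {
          p$baseline <- p$baseline * level
          p$amplitude <- p$amplitude * level
          p
        })
      w
    })
  }
  if (!is.null(dox_channel)) {
    stopifnot(inherits(dox, "dox_waveform"))
    dox$amplitude <- dox$amplitude * level
    dox$baseline <- dox$baseline * level
    waveforms[[dox_channel]] <- dox
  }
  record <- compose_fiber_record(traj, waveforms = waveforms,
                                 schedule = schedule,
                                 structural_level = level)
  # dye channels also carry monomer at the calibrated level
  if (!is.null(schedule))
    for (ch in schedule$events$channel)
      record$channels[[ch]] <- record$channels[[ch]] * level
  cfg <- config
  cfg$seed <- as.integer(seed)
  extent <- (shape - 1) * cfg$voxel_spacing
  center <- extent / 2
  poly <- generate_centerline_curve(2 * record$L, max_curvature,
                                    soma_radius, seed = seed,
                                    z_scale = z_scale)
  poly <- sweep(poly, 2, center, "+")
  soma <- list(center = center, radius = soma_radius, z_scale = z_scale,
               level = 2 * level_for_snr(cfg, 3))
  rendered <- render_volume(list(list(record = record, polyline = poly)),
                            somata = list(soma), config = cfg,
                            shape = shape, noise = noise)
  c(rendered, list(record = record, model = model, level = level))
}

#' Simulate a cohort of single-cell recordings
#'
#' Per-cell elongation rates are drawn lognormally (20% coefficient of
#' variation by default); everything else follows [simulate_tape_cell()].
#'
#' @param n_cells number of cells (one volume each).
#' @param seed cohort seed; cell `i` uses `seed * 1000 + i` for geometry
#'   and noise.
#' @param rate_mean mean elongation rate (um/day).
#' @param rate_cv lognormal coefficient of variation of the rate.
#' @param ... forwarded to [simulate_tape_cell()].
#' @return list of per-cell simulation results.
#' @export
simulate_tape_cohort <- function(n_cells = 20, seed = 1L, rate_mean = 1.6,
                                 rate_cv = 0.2, ...) {
  sdlog <- sqrt(log(1 + rate_cv^2))
  rates <- with_seed(seed,
    rlnorm(n_cells, meanlog = log(rate_mean) - sdlog^2 / 2, sdlog = sdlog))
  lapply(seq_len(n_cells), function(i)
    simulate_tape_cell(a = rates[i], seed = seed * 1000L + i, ...))
}

#' Recover signal peak times from a decoded run
#'
#' For each decoded fiber, the recovered peak time of `channel` is the mean
#' over the two half-records of the time at the maximum relative change.
#'
#' @param run a `tape_run` from [decode_volume()].
#' @param channel signal channel name.
#' @return named numeric vector (fiber id -> recovered peak time, days).
#' @export
recover_peak_times <- function(run, channel) {
  out <- c()
  for (f in run$fibers) {
    tims <- vapply(f$halves, function(h) {
      ts <- h$series
      ts$time[which.max(ts$channels[[channel]])]
    }, 1)
    out[f$fiber] <- mean(tims)
  }
  out
}

#' Synthetic coupled/decoupled signalling cohort
#'
#' Generates per-cell pairs of upstream/downstream time series: coupled
#' cells carry a noisy, delayed copy of the upstream signal in the
#' downstream channel; decoupled cells carry independent noise. Used to
#' exercise [lag_correlation()] and [classify_coupling()].
#'
#' @param n_coupled,n_decoupled cell counts.
#' @param n_samples samples per series.
#' @param dt sampling interval (days).
#' @param delay coupling delay (days).
#' @param noise_sd additive noise sd (signals have unit scale).
#' @param seed integer seed.
#' @return list with `series` (per-cell list of upstream/downstream
#'   [time_series()]) and `truth` (character labels).
#' @export
simulate_coupling_cohort <- function(n_coupled = 20, n_decoupled = 20,
                                     n_samples = 200L, dt = 0.01,
                                     delay = 0.05, noise_sd = 0.3,
                                     seed = 0L) {
  lag_samp <- round(delay / dt)
  with_seed(seed, {
    tt <- seq(0, by = dt, length.out = n_samples)
    mk_cell <- function(coupled) {
      # smooth upstream fluctuation: low-pass filtered white noise
      up <- moving_average(rnorm(n_samples + lag_samp), 9L)
      a <- up[seq_len(n_samples) + lag_samp]       # upstream A(t)
      b <- if (coupled) {
        # downstream lags upstream by `delay`: B(t) = A(t - delay) + noise
        up[seq_len(n_samples)] + rnorm(n_samples, sd = noise_sd)
      } else {
        moving_average(rnorm(n_samples), 9L) + rnorm(n_samples,
                                                     sd = noise_sd)
      }
      list(up = time_series(tt, list(pcreb = a)),
           down = time_series(tt, list(fos = b)))
    }
    series <- c(lapply(seq_len(n_coupled), function(i) mk_cell(TRUE)),
                lapply(seq_len(n_decoupled), function(i) mk_cell(FALSE)))
    truth <- c(rep("type2_coupled", n_coupled),
               rep("type1_decoupled", n_decoupled))
    list(series = series, truth = truth)
  })
}

#' Average the two decoded half-records of a fiber
#'
#' Both halves of a bidirectionally grown fiber carry the same record, so
#' averaging their warped series on a common time grid halves the noise
#' variance and suppresses half-specific decoding artifacts.
#'
#' @param fiber one element of `tape_run$fibers`.
#' @return A [time_series()] (the single available half if only one was
#'   decoded).
#' @export
average_halves <- function(fiber) {
  hs <- fiber$halves
  if (length(hs) == 1L) return(hs[[1]]$series)
  a <- hs[[1]]$series; b <- hs[[2]]$series
  t0 <- max(min(a$time), min(b$time))
  t1 <- min(max(a$time), max(b$time))
  grid <- seq(t0, t1, by = a$dt)
  ch <- lapply(names(a$channels), function(nm) {
    (approx(a$time, a$channels[[nm]], grid, rule = 2)$y +
     approx(b$time, b$channels[[nm]], grid, rule = 2)$y) / 2
  })
  names(ch) <- names(a$channels)
  ext <- approx(a$time, as.numeric(a$extrapolated), grid, rule = 2)$y > 0 |
         approx(b$time, as.numeric(b$extrapolated), grid, rule = 2)$y > 0
  time_series(grid, ch, extrapolated = ext)
}

#' Recover the time of a promoter pulse by template fitting
#'
#' Fits the characterized reporter pulse shape (free shift, amplitude,
#' width and offset) to a recovered relative-change series by least
#' squares. Because the fitted template absorbs symmetric broadening into
#' its width, the location estimate is unbiased under the symmetric
#' arclength smear of the imaging model, unlike the argmax of the smeared
#' waveform.
#'
#' @param ts a [time_series()].
#' @param channel channel name.
#' @param pulse the [promoter_waveform()] whose kinetics (tau ratio) are
#'   known; its absolute timing is not used.
#' @param width_range multiplicative width scales searched.
#' @return fitted pulse peak time (days).
#' @export
recover_pulse_time <- function(ts, channel, pulse,
                               width_range = seq(0.7, 1.8, by = 0.05)) {
  y <- ts$channels[[channel]]
  if (is.null(y)) stop("unknown channel: ", channel)
  tt <- ts$time
  # unit template with peak at 0
  upk <- log(pulse$tau_decay / pulse$tau_rise) /
    (1 / pulse$tau_rise - 1 / pulse$tau_decay)
  template <- function(u, w) {
    x <- (tt - u) / w + upk
    v <- ifelse(x > 0, exp(-x / pulse$tau_decay) - exp(-x / pulse$tau_rise),
                0)
    v / (exp(-upk / pulse$tau_decay) - exp(-upk / pulse$tau_rise))
  }
  best <- list(sse = Inf, u = tt[which.max(y)])
  for (w in width_range) {
    for (u in tt[seq(1, length(tt), by = 2L)]) {
      X <- cbind(1, template(u, w))
      if (all(abs(X[, 2]) < 1e-12)) next
      fit <- lm.fit(X, y)
      sse <- sum(fit$residuals^2)
      if (sse < best$sse && fit$coefficients[2] > 0)
        best <- list(sse = sse, u = u, w = w)
    }
  }
  best$u
}
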