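## Forward simulator: tape growth, dye timestamping, signal deposition and
## confocal-style rendering, with full ground truth for parameter recovery.

#' Tape growth model
#'
#' Bidirectional tape growth is parameterized per half-fiber as
#' `s(t) = a * (t - t0)^b` for `t > t0`: `s` is the half-fiber arclength in
#' um deposited by time `t` (days). `b = 1` gives linear elongation; `b < 1`
#' gives decelerating (power-law) kinetics matching the sublinear regime that
#' quadratic/power transfer functions are fitted to.
#'
#' @param a elongation-rate coefficient (um/day^b), per half-fiber; > 0.
#' @param b growth exponent, 0 < b <= 1.
#' @param t0 nucleation time (days).
#' @param duration recording span (days); fiber is observed on
#'   `(t0, t0 + duration]`.
#' @return A `growth_model` object.
#' @export
growth_model <- function(a, b = 1, t0 = 0, duration = 6) {
  if (!is.numeric(a) || a <= 0) stop("invalid model: `a` must be positive")
  if (!is.numeric(b) || b <= 0 || b > 1)
    stop("invalid model: `b` must be in (0, 1]")
  if (!is.numeric(duration) || duration <= 0)
    stop("invalid model: `duration` must be positive")
  structure(list(a = a, b = b, t0 = t0, duration = duration),
            class = "growth_model")
}

#' Sample a growth trajectory and its inverse map
#'
#' @param model a [growth_model()].
#' @param n_samples number of time samples (>= 2).
#' @return list with `time` (strictly increasing), `half_length` (strictly
#'   increasing, um), `time_of_length(s)` (inverse map, days) and
#'   `length_of_time(t)`, plus the model.
#' @export
simulate_growth <- function(model, n_samples = 500) {
  stopifnot(inherits(model, "growth_model"))
  if (n_samples < 2) stop("`n_samples` must be >= 2")
  tt <- seq(model$t0, model$t0 + model$duration, length.out = n_samples)
  s_of_t <- function(t) model$a * pmax(t - model$t0, 0)^model$b
  t_of_s <- function(s) model$t0 + (pmax(s, 0) / model$a)^(1 / model$b)
  list(time = tt, half_length = s_of_t(tt),
       length_of_time = s_of_t, time_of_length = t_of_s, model = model)
}

#' Promoter-activity pulse waveform
#'
#' Bi-exponential pulse: baseline before `stim_time + delay`, then
#' `baseline + amplitude * (exp(-u/tau_decay) - exp(-u/tau_rise))` with
#' `u = t - stim_time - delay`, normalized so the pulse peak equals
#' `amplitude`.
#'
#' @param baseline,amplitude intensities (a.u., >= 0).
#' @param stim_time stimulation time (days).
#' @param delay onset delay after stimulation (days).
#' @param tau_rise,tau_decay rise/decay time constants (days),
#'   `tau_rise < tau_decay`.
#' @return A `promoter_waveform` object.
#' @export
promoter_waveform <- function(baseline = 0, amplitude = 1, stim_time = 0,
                              delay = 0.1, tau_rise = 0.05, tau_decay = 0.3) {
  stopifnot(baseline >= 0, amplitude >= 0, tau_rise > 0,
            tau_decay > tau_rise)
  structure(list(baseline = baseline, amplitude = amplitude,
                 stim_time = stim_time, delay = delay, tau_rise = tau_rise,
                 tau_decay = tau_decay),
            class = c("promoter_waveform", "tape_waveform"))
}

#' Doxycycline-controlled (Tet-On) timestamp waveform
#'
#' Expression of the Dox-dependent monomer rises toward saturation with time
#' constant `tau_on` while Dox is present (`t_on <= t < t_off`) and decays
#' with `tau_off` after withdrawal. Slow accumulation/turnover (days) makes
#' the ON and OFF phases quasi-linear, so the rise onset and decay onset are
#' clean changepoints along the fiber.
#'
#' @param t_on,t_off Dox administration and withdrawal times (days).
#' @param amplitude saturation level (a.u.).
#' @param baseline leaky expression level (a.u.).
#' @param tau_on,tau_off accumulation / decay time constants (days).
#' @return A `dox_waveform` object.
#' @export
dox_waveform <- function(t_on, t_off, amplitude = 1, baseline = 0,
                         tau_on = 3, tau_off = 3) {
  stopifnot(t_off > t_on, amplitude > 0, tau_on > 0, tau_off > 0)
  structure(list(t_on = t_on, t_off = t_off, amplitude = amplitude,
                 baseline = baseline, tau_on = tau_on, tau_off = tau_off),
            class = c("dox_waveform", "tape_waveform"))
}

#' Evaluate a waveform at given times
#' @param w a waveform object.
#' @param t numeric vector of times (days).
#' @return numeric vector of activities (a.u., >= 0).
#' @export
waveform_value <- function(w, t) UseMethod("waveform_value")

#' @export
waveform_value.promoter_waveform <- function(w, t) {
  u <- t - w$stim_time - w$delay
  pulse <- ifelse(u > 0, exp(-u / w$tau_decay) - exp(-u / w$tau_rise), 0)
  # peak of the unnormalized bi-exponential
  upk <- log(w$tau_decay / w$tau_rise) / (1 / w$tau_rise - 1 / w$tau_decay)
  pk <- exp(-upk / w$tau_decay) - exp(-upk / w$tau_rise)
  w$baseline + w$amplitude * pulse / pk
}

#' @export
waveform_value.dox_waveform <- function(w, t) {
  on <- 1 - exp(-pmax(t - w$t_on, 0) / w$tau_on)
  level_off <- 1 - exp(-(w$t_off - w$t_on) / w$tau_on)
  val <- ifelse(t < w$t_on, 0,
         ifelse(t < w$t_off, on,
                level_off * exp(-(t - w$t_off) / w$tau_off)))
  w$baseline + w$amplitude * val
}

#' Dye-switch schedule for self-labeling-tag timestamps
#'
#' @param events data.frame with columns `switch_time` (days, strictly
#'   increasing) and `channel` (dye channel name). The first event defines
#'   the initial dye; subsequent rows are dye switches.
#' @param fixation_time fixation (end of recording), days; all switch times
#'   must precede it.
#' @return A `dye_schedule` object.
#' @export
dye_schedule <- function(events, fixation_time) {
  events <- as.data.frame(events)
  stopifnot(all(c("switch_time", "channel") %in% names(events)))
  if (is.unsorted(events$switch_time, strictly = TRUE))
    stop("switch times must be strictly increasing")
  if (any(events$switch_time >= fixation_time))
    stop("all switch times must precede `fixation_time`")
  structure(list(events = events, fixation_time = fixation_time),
            class = "dye_schedule")
}

# Gaussian smoothing along an equispaced 1D grid, kernel renormalized at the
# edges so plateaus are preserved
smooth_gaussian_1d <- function(y, sigma, ds) {
  if (sigma <= 0 || length(y) < 3) return(y)
  r <- max(1L, ceiling(3 * sigma / ds))
  k <- exp(-0.5 * ((-r:r) * ds / sigma)^2)
  n <- length(y)
  ypad <- c(rep(y[1], r), y, rep(y[n], r))
  num <- stats::filter(ypad, k / sum(k), sides = 2)
  as.numeric(num[(r + 1):(r + n)])
}

#' Compose the deposited intensity record of one fiber
#'
#' Evaluates every channel's activity over the growth trajectory and maps it
#' onto arclength via the inverse growth map, producing the per-channel
#' deposition profile of one half-fiber. Both halves are mirror images
#' (symmetric bidirectional growth), so a single half record plus the
#' mirroring accessor [full_record()] describes the fiber.
#'
#' @param trajectory result of [simulate_growth()]; must cover
#'   `[t0, fixation_time]`.
#' @param waveforms named list of waveform objects (signal and/or Dox
#'   channels); names are channel names.
#' @param schedule a [dye_schedule()] or `NULL`.
#' @param structural_level constitutive structural-monomer level (a.u.).
#' @param structural_channel name for the structural channel.
#' @param ds arclength sampling interval (um).
#' @param dye_sigma_s Gaussian smoothing of dye transitions along arclength
#'   (um), mimicking finite labeling kinetics.
#' @return A `fiber_record`: half-fiber arclength grid, deposition time at
#'   each arclength, per-channel profiles, half length `L`, and exact
#'   dye-switch arclengths/fractions.
#' @export
compose_fiber_record <- function(trajectory, waveforms = list(),
                                 schedule = NULL, structural_level = 1,
                                 structural_channel = "structural",
                                 ds = 0.06, dye_sigma_s = 0.3) {
  model <- trajectory$model
  fix <- if (!is.null(schedule)) schedule$fixation_time else
    model$t0 + model$duration
  if (fix > model$t0 + model$duration + 1e-9)
    stop("trajectory does not cover [t0, fixation_time]")
  if (!is.null(schedule)) {
    clash <- intersect(names(waveforms), schedule$events$channel)
    if (length(clash))
      stop("configuration error: channel(s) used for both dye and waveform: ",
           paste(clash, collapse = ", "))
  }
  L <- trajectory$length_of_time(fix)
  s <- seq(0, L, by = ds)
  if (s[length(s)] < L) s <- c(s, L)
  t_of_s <- trajectory$time_of_length
  tt <- t_of_s(s)
  channels <- list()
  channels[[structural_channel]] <- rep(structural_level, length(s))
  if (!is.null(schedule)) {
    ev <- schedule$events
    bounds <- c(ev$switch_time, fix)
    for (i in seq_len(nrow(ev))) {
      lo <- max(bounds[i], model$t0)
      hi <- bounds[i + 1]
      ind <- as.numeric(tt >= lo & tt < hi)
      if (i == nrow(ev)) ind <- as.numeric(tt >= lo & tt <= hi)
      channels[[ev$channel[i]]] <- smooth_gaussian_1d(ind, dye_sigma_s, ds)
    }
  }
  for (nm in names(waveforms))
    channels[[nm]] <- waveform_value(waveforms[[nm]], tt)
  switch_s <- if (!is.null(schedule) && nrow(schedule$events) > 1)
    trajectory$length_of_time(schedule$events$switch_time[-1]) else numeric()
  structure(list(arclength = s, time = tt, channels = channels, L = L,
                 ds = ds, fixation_time = fix, model = model,
                 schedule = schedule,
                 dye_switch_arclength = switch_s,
                 dye_switch_fraction = switch_s / L),
            class = "fiber_record")
}

#' Mirror a half record into the full bidirectional fiber profile
#'
#' @param record a `fiber_record`.
#' @return list with full `arclength` grid (0..2L), per-channel profiles
#'   (reversed half followed by forward half) and `split_arclength = L`.
#' @export
full_record <- function(record) {
  stopifnot(inherits(record, "fiber_record"))
  n <- length(record$arclength)
  full_s <- c(record$L - rev(record$arclength),
              record$L + record$arclength[-1])
  ch <- lapply(record$channels, function(v) c(rev(v), v[-1]))
  list(arclength = full_s, channels = ch, split_arclength = record$L,
       total_length = 2 * record$L)
}

# evaluate and restore RNG state around seeded simulation code
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rotate_towards <- function(d, target, max_angle) {
  # rotate unit vector d towards unit vector target by at most max_angle
  cosang <- max(-1, min(1, sum(d * target)))
  ang <- acos(cosang)
  if (ang < 1e-12) return(d)
  th <- min(ang, max_angle)
  # orthonormal component of target relative to d
  perp <- target - cosang * d
  np <- sqrt(sum(perp^2))
  if (np < 1e-12) { # antiparallel: pick any perpendicular
    ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- ref - sum(ref * d) * d
    np <- sqrt(sum(perp^2))
  }
  perp <- perp / np
  d * cos(th) + perp * sin(th)
}

#' Generate a confined random fiber centerline
#'
#' Emits a 3D polyline of prescribed arclength whose discrete (three-point
#' circumradius) curvature never exceeds `max_curvature` and which stays
#' within `soma_radius` of the origin. Because the maximal turn radius is
#' comparable to the cell radius, confinement cannot be improvised locally:
#' the curve is planned globally as a chord (when the length fits straight)
#' or a circular arc of the smallest curvature whose enclosing circle fits
#' the cell, plus a smooth bounded heading wander and a gentle axial (z)
#' undulation, each drawing on a fixed share of the curvature budget.
#' Adherent cultured cells are flat, so the fiber lies mostly in-plane.
#'
#' @param total_length target arclength (um).
#' @param max_curvature curvature bound (um^-1, >= 0).
#' @param soma_radius confinement radius (um).
#' @param seed integer seed (`NULL` = use current RNG state).
#' @param step polyline step (um).
#' @param z_scale flattening of the cell along z; bounds the amplitude of
#'   the axial undulation.
#' @return n x 3 matrix of `(z, y, x)` coordinates in um, centered on the
#'   origin.
#' @export
generate_centerline_curve <- function(total_length, max_curvature = 0.2,
                                      soma_radius = 8, seed = NULL,
                                      step = 0.2, z_scale = 1) {
  stopifnot(z_scale > 0, z_scale <= 1)
  stopifnot(total_length > 0, max_curvature >= 0, soma_radius > 0)
  if (total_length > 2 * soma_radius * 0.95 &&
      max_curvature * soma_radius < 1.2)
    stop("infeasible geometry: soma too small to confine the fiber at this ",
         "maximum curvature")
  n_steps <- max(2L, ceiling(total_length / step))
  h <- total_length / n_steps
  L <- total_length
  confine <- soma_radius * 0.92
  wander_allow <- min(1, 0.08 * L)       # lateral room reserved for wander
  Ceff <- confine - wander_allow
  # base curvature: 0 if a straight chord fits, else the smallest constant
  # curvature whose arc (enclosing-circle radius R*sin(min(alpha,pi)/2),
  # alpha = L*kappa) fits inside Ceff
  kap_base <- 0
  if (max_curvature > 0 && L / 2 > Ceff) {
    kgrid <- seq(0.01 * max_curvature, 0.85 * max_curvature,
                 length.out = 200L)
    enc <- (1 / kgrid) * sin(pmin(L * kgrid, pi) / 2)
    fit <- which(enc <= Ceff)
    if (!length(fit))
      stop("infeasible geometry: soma too small to confine the fiber at ",
           "this maximum curvature")
    kap_base <- kgrid[fit[1]]
  } else if (L / 2 > Ceff) {
    stop("infeasible geometry: soma too small to confine the fiber at ",
         "this maximum curvature")
  }
  # wander and axial undulation draw on the remaining curvature budget
  theta_amp <- if (max_curvature > 0) 0.15 else 0
  kap_wander <- 0.1 * max_curvature
  zamp <- if (max_curvature > 0)
    min(0.2, z_scale * soma_radius / 10) else 0
  kap_z <- 0.3 * max_curvature
  s <- seq(0, by = h, length.out = n_steps + 1L)
  with_seed(seed, {
    for (attempt in seq_len(50L)) {
      base_ang <- runif(1, 0, 2 * pi)
      turn_sign <- sample(c(-1, 1), 1)
      wav <- if (theta_amp > 0 && kap_wander > 0)
        max(L, 2 * pi * theta_amp / kap_wander) else Inf
      psi <- runif(1, 0, 2 * pi)
      theta <- if (is.finite(wav))
        theta_amp * sin(2 * pi * s / wav + psi) else rep(0, length(s))
      heading <- base_ang + turn_sign * kap_base * s + theta
      # integrate the planar path (midpoint headings keep curvature exact)
      hm <- (heading[-1] + heading[-length(heading)]) / 2
      xy <- rbind(c(0, 0),
                  cbind(cumsum(h * cos(hm)), cumsum(h * sin(hm))))
      # center, then offset chords randomly within the remaining room
      ctr <- (apply(xy, 2, max) + apply(xy, 2, min)) / 2
      xy <- sweep(xy, 2, ctr)
      rmax <- sqrt(max(rowSums(xy^2)))
      room <- confine - rmax
      if (room > 0) {
        ang <- runif(1, 0, 2 * pi)
        off <- runif(1, 0, room)
        xy <- sweep(xy, 2, off * c(cos(ang), sin(ang)), "+")
      }
      if (max(sqrt(rowSums(xy^2))) > soma_radius * 0.98) next
      lam_z <- if (kap_z > 0 && zamp > 0)
        max(2 * pi * sqrt(zamp / kap_z), 1e-9) else Inf
      z <- if (is.finite(lam_z))
        zamp * sin(2 * pi * s / lam_z + runif(1, 0, 2 * pi)) else
        rep(0, length(s))
      return(cbind(z, xy[, 2], xy[, 1]))
    }
    stop("infeasible geometry: could not confine the fiber in 50 attempts")
  })
}

#' Confocal rendering configuration
#'
#' Defaults emulate spinning-disk confocal stacks acquired at 0.4 um per
#' z-step with sub-resolution lateral sampling, an anisotropic Gaussian PSF
#' and a Poisson + Gaussian (sCMOS-style) noise model.
#'
#' @param voxel_spacing `(dz, dy, dx)` um.
#' @param psf_sigma Gaussian PSF sigma `(sz, sy, sx)` um.
#' @param fiber_radius rendered tube radius (um).
#' @param background offset (a.u.).
#' @param read_noise_sd Gaussian read-noise sd (a.u.).
#' @param photon_scale photons per intensity unit for shot noise.
#' @param soma_radius default soma radius (um).
#' @param seed integer noise seed.
#' @return A `render_config` object.
#' @export
render_config <- function(voxel_spacing = c(0.4, 0.13, 0.13),
                          psf_sigma = c(0.6, 0.15, 0.15),
                          fiber_radius = 0.25, background = 20,
                          read_noise_sd = 2, photon_scale = 1,
                          soma_radius = 8, seed = 1L) {
  stopifnot(all(voxel_spacing > 0), all(psf_sigma >= 0), fiber_radius > 0,
            background >= 0, read_noise_sd >= 0, photon_scale > 0)
  structure(list(voxel_spacing = voxel_spacing, psf_sigma = psf_sigma,
                 fiber_radius = fiber_radius, background = background,
                 read_noise_sd = read_noise_sd, photon_scale = photon_scale,
                 soma_radius = soma_radius, seed = as.integer(seed)),
            class = "render_config")
}

#' Background noise standard deviation implied by a render configuration
#' @param config a [render_config()].
#' @return sd (a.u.) of the Poisson + Gaussian noise at background level.
#' @export
background_noise_sd <- function(config) {
  sqrt(config$background / config$photon_scale + config$read_noise_sd^2)
}

#' Deposition level needed to reach a target peak signal-to-noise ratio
#'
#' SNR is defined as the noise-free peak tube intensity above background,
#' divided by the background noise sd. The peak response per unit deposition
#' density is measured by rendering a short straight probe tube, so the
#' returned level is exact for the configured PSF, radius and spacing.
#'
#' @param config a [render_config()].
#' @param snr target ratio.
#' @return deposition level (a.u. per um of fiber).
#' @export
level_for_snr <- function(config, snr) {
  sp <- config$voxel_spacing
  shape <- c(max(8L, ceiling(4 / sp[1])), ceiling(6 / sp[2]),
             ceiling(6 / sp[3]))
  ext <- (shape - 1) * sp
  n <- 81L
  pts <- cbind(rep(ext[1] / 2, n), rep(ext[2] / 2, n),
               seq(ext[3] / 2 - 2, ext[3] / 2 + 2, length.out = n))
  ds <- 4 / (n - 1)
  vol <- array(0, shape)
  vol <- cpp_splat(vol, dim(vol), sp, pts, rep(ds, n),
                   0.6 * config$fiber_radius)
  vol <- cpp_gauss_blur(vol, dim(vol), config$psf_sigma / sp)
  peak_unit <- max(vol)
  snr * background_noise_sd(config) / peak_unit
}

#' Render fibers and somata into a multi-channel volume with ground truth
#'
#' Each fiber's mirrored deposition record is painted along its polyline as
#' a Gaussian tube (sigma `0.6 * config$fiber_radius`, so deposition mass
#' stays concentrated on the axis), all channels are blurred
#' with the anisotropic PSF, somata are rendered as blurred spheres into the
#' Nissl channel, and Poisson + Gaussian noise is applied under
#' `config$seed`. The noise-free intermediate is deterministic.
#'
#' @param fibers list of `list(record = fiber_record, polyline = n x 3
#'   matrix)` with polylines in absolute volume coordinates (um). Each
#'   polyline's arclength should equal the record's full (mirrored) length.
#' @param somata list of `list(center = c(z, y, x) um, radius = um,
#'   level = a.u.)`.
#' @param config a [render_config()].
#' @param shape volume dimensions `(nz, ny, nx)`.
#' @param nissl_channel channel name for the soma stain.
#' @param noise apply the noise model (`FALSE` = return the noise-free
#'   volume).
#' @param ds tube painting step along arclength (um).
#' @return list with `volume` (an [image_volume()]) and `ground_truth`
#'   (per-fiber polylines, records, split position, arclength-time map and
#'   dye-switch positions; per-soma geometry).
#' @export
render_volume <- function(fibers, somata = list(), config = render_config(),
                          shape = c(128L, 128L, 128L),
                          nissl_channel = "nissl", noise = TRUE, ds = 0.05) {
  sp <- config$voxel_spacing
  extent <- (shape - 1) * sp
  margin <- 3 * config$psf_sigma
  ch_names <- unique(c(unlist(lapply(fibers, function(f)
    names(f$record$channels))), nissl_channel))
  vols <- lapply(ch_names, function(ch) array(0, shape))
  names(vols) <- ch_names
  gt_fibers <- list()
  for (i in seq_along(fibers)) {
    rec <- fibers[[i]]$record
    poly <- as.matrix(fibers[[i]]$polyline)
    lo <- apply(poly, 2, min); hi <- apply(poly, 2, max)
    if (any(lo < margin - 1e-9) || any(hi > extent - margin + 1e-9))
      stop("fiber ", i, " exits the volume bounds (margin 3*psf_sigma)")
    fr <- full_record(rec)
    npt <- max(2L, ceiling(fr$total_length / ds))
    pts <- resample_polyline(poly, npt)
    ds_i <- fr$total_length / (npt - 1)
    sfull <- seq(0, fr$total_length, length.out = npt)
    for (ch in names(fr$channels)) {
      vals <- approx(fr$arclength, fr$channels[[ch]], xout = sfull,
                     rule = 2)$y
      vols[[ch]] <- cpp_splat(vols[[ch]], shape, sp, pts, vals * ds_i,
                              0.6 * config$fiber_radius)
    }
    cell <- NA_integer_
    if (length(somata)) {
      mid <- pts[ceiling(npt / 2), ]
      dists <- vapply(somata, function(s)
        sqrt(sum((mid - s$center)^2)), 1)
      inside <- which(dists <= vapply(somata, function(s) s$radius, 1))
      if (length(inside)) cell <- inside[which.min(dists[inside])]
    }
    gt_fibers[[i]] <- list(
      polyline = pts, arclength = sfull, record = rec,
      split_arclength = rec$L, total_length = fr$total_length,
      time_of_length = rec$model, # model parameters define the map
      arclength_time = data.frame(arclength_um = rec$arclength,
                                  time_days = rec$time),
      dye_switch_arclength = rec$dye_switch_arclength,
      dye_switch_fraction = rec$dye_switch_fraction,
      cell = cell)
  }
  # somata: blurred spheres in the Nissl channel
  if (length(somata)) {
    zg <- (seq_len(shape[1]) - 1) * sp[1]
    yg <- (seq_len(shape[2]) - 1) * sp[2]
    xg <- (seq_len(shape[3]) - 1) * sp[3]
    for (s in somata) {
      lvl <- s$level %||% 30
      zs <- s$z_scale %||% 1
      d2 <- outer(outer(((zg - s$center[1]) / zs)^2,
                        (yg - s$center[2])^2, "+"),
                  (xg - s$center[3])^2, "+")
      vols[[nissl_channel]] <- vols[[nissl_channel]] +
        lvl * (d2 <= s$radius^2)
    }
  }
  sig_vox <- config$psf_sigma / sp
  for (ch in ch_names) {
    vols[[ch]] <- cpp_gauss_blur(vols[[ch]], shape, sig_vox)
    vols[[ch]] <- vols[[ch]] + config$background
  }
  if (noise) {
    vols <- with_seed(config$seed, {
      lapply(vols, function(v) {
        counts <- rpois(length(v), lambda = config$photon_scale * pmax(v, 0))
        nv <- counts / config$photon_scale +
          rnorm(length(v), sd = config$read_noise_sd)
        array(nv, dim(v))
      })
    })
  }
  vol <- image_volume(vols, spacing = sp, channels = ch_names)
  gt <- list(fibers = gt_fibers, somata = somata, config = config,
             shape = shape)
  list(volume = vol, ground_truth = gt)
}
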