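# Shared fixtures: everything is generated in code at test time.

# pure-R 8-corner trilinear interpolation, independent of the C++ sampler
trilinear_oracle <- function(vol, pts) {
  dims <- dim(vol)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- pmin(pmax(pts[i, ], 0), dims - 1)
    lo <- floor(p)
    hi <- pmin(lo + 1, dims - 1)
    f <- p - lo
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dz) f[1] else 1 - f[1]) *
           (if (dy) f[2] else 1 - f[2]) *
           (if (dx) f[3] else 1 - f[3])
      z <- if (dz) hi[1] else lo[1]
      y <- if (dy) hi[2] else lo[2]
      x <- if (dx) hi[3] else lo[3]
      acc <- acc + w * vol[z + 1, y + 1, x + 1]
    }
    out[i] <- acc
  }
  out
}

# analytic solid cylinder mask along the x axis, centered in the volume
cylinder_mask <- function(length_um, radius_um, spacing,
                          pad_um = c(2, 2, 2)) {
  dims <- ceiling((c(2 * pad_um[1], 2 * pad_um[2],
                     length_um + 2 * pad_um[3])) / spacing) + 1
  zg <- (seq_len(dims[1]) - 1) * spacing[1]
  yg <- (seq_len(dims[2]) - 1) * spacing[2]
  xg <- (seq_len(dims[3]) - 1) * spacing[3]
  cz <- max(zg) / 2; cy <- max(yg) / 2
  x0 <- pad_um[3]; x1 <- pad_um[3] + length_um
  r2 <- outer((zg - cz)^2, (yg - cy)^2, "+")
  mask <- array(FALSE, dims)
  inx <- xg >= x0 & xg <= x1
  core <- r2 <= radius_um^2
  for (k in which(inx)) mask[, , k] <- core
  list(mask = mask, spacing = spacing,
       start = c(cz, cy, x0), end = c(cz, cy, x1))
}

# analytic circular-arc centerline of given radius in the yx plane
arc_centerline <- function(radius, angle, n = 600) {
  th <- seq(0, angle, length.out = n)
  pts <- cbind(0, radius * sin(th), radius * (1 - cos(th)))
  centerline(pts, method = "manual")
}

# render one straight fiber (record along x) in a compact volume
render_straight_fiber <- function(record, config = render_config(),
                                  somata = list(), noise = TRUE,
                                  pad_um = c(2.5, 2.5, 3)) {
  L2 <- 2 * record$L
  sp <- config$voxel_spacing
  shape <- as.integer(ceiling(c(2 * pad_um[1], 2 * pad_um[2],
                                L2 + 2 * pad_um[3]) / sp) + 1)
  extent <- (shape - 1) * sp
  n <- max(50L, ceiling(L2 / 0.1))
  poly <- cbind(rep(extent[1] / 2, n), rep(extent[2] / 2, n),
                seq(extent[3] / 2 - L2 / 2, extent[3] / 2 + L2 / 2,
                    length.out = n))
  render_volume(list(list(record = record, polyline = poly)),
                somata = somata, config = config, shape = shape,
                noise = noise)
}

# standard 4-day single-switch record at a given SNR level
standard_record <- function(a = 1.6, duration = 4, switch_time = 2,
                            config = render_config(), snr = 5,
                            waveforms = list()) {
  lvl <- level_for_snr(config, snr)
  traj <- simulate_growth(growth_model(a = a, duration = duration), 400)
  sch <- dye_schedule(data.frame(switch_time = c(0, switch_time),
                                 channel = c("dye1", "dye2")),
                      fixation_time = duration)
  wf <- lapply(waveforms, function(w) {
    w$baseline <- w$baseline * lvl
    if (!is.null(w$amplitude)) w$amplitude <- w$amplitude * lvl
    w
  })
  rec <- compose_fiber_record(traj, waveforms = wf, schedule = sch,
                              structural_level = lvl)
  rec$channels$dye1 <- rec$channels$dye1 * lvl
  rec$channels$dye2 <- rec$channels$dye2 * lvl
  rec
}

# exhaustive discontinuous-segment least-squares changepoint oracles
segment_sse_oracle <- function(y, i, j) {
  x <- i:j
  yy <- y[i:j]
  if (length(x) < 3) return(sum((yy - mean(yy))^2))
  fit <- stats::lm.fit(cbind(1, x), yy)
  sum(fit$residuals^2)
}

oracle_one_changepoint <- function(y, min_seg = 3L) {
  n <- length(y)
  best <- list(sse = Inf, k = NA)
  for (k in min_seg:(n - min_seg)) {
    sse <- segment_sse_oracle(y, 1, k) + segment_sse_oracle(y, k + 1, n)
    if (sse < best$sse) best <- list(sse = sse, k = k)
  }
  best
}

oracle_two_changepoints <- function(y, min_seg = 3L) {
  n <- length(y)
  best <- list(sse = Inf, k = c(NA, NA))
  for (c1 in min_seg:(n - 2 * min_seg))
    for (c2 in (c1 + min_seg):(n - min_seg)) {
      sse <- segment_sse_oracle(y, 1, c1) +
        segment_sse_oracle(y, c1 + 1, c2) +
        segment_sse_oracle(y, c2 + 1, n)
      if (sse < best$sse) best <- list(sse = sse, k = c(c1, c2))
    }
  best
}

# independent three-point circumradius curvature (Heron's formula)
discrete_curvature_for_test <- function(points) {
  n <- nrow(points)
  k <- numeric(n - 2)
  for (i in 2:(n - 1)) {
    A <- points[i - 1, ]; B <- points[i, ]; C <- points[i + 1, ]
    a <- sqrt(sum((B - C)^2))
    b <- sqrt(sum((A - C)^2))
    cc <- sqrt(sum((A - B)^2))
    s <- (a + b + cc) / 2
    area <- sqrt(max(s * (s - a) * (s - b) * (s - cc), 0))
    k[i - 1] <- if (a * b * cc > 0) 4 * area / (a * b * cc) else 0
  }
  k
}

voxels_to_um_for_test <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(idx - 1, 2, spacing, "*")
}

# simple centered moving average (independent of the package internal)
moving_avg_oracle <- function(y, k) {
  n <- length(y)
  out <- numeric(n)
  half <- k %/% 2
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    out[i] <- mean(y[lo:hi])
  }
  out
}

# brute-force optimal split: maximize the Pearson correlation of the two
# outward-parameterized halves compared on a common absolute-distance grid
brute_force_split <- function(arc, y, window_frac = 0.2, n_grid = 500) {
  n <- length(arc)
  L <- arc[n]
  cand <- which(abs(arc - L / 2) <= window_frac * L / 2 + 1e-12)
  cand <- cand[cand >= 3 & cand <= n - 2]
  best <- list(r = -Inf, k = NA)
  for (k in cand) {
    dl <- arc[k] - arc[k:1]
    dr <- arc[k:n] - arc[k]
    lmin <- min(max(dl), max(dr))
    g <- seq(0, lmin, length.out = n_grid)
    li <- approx(dl, y[k:1], xout = g)$y
    ri <- approx(dr, y[k:n], xout = g)$y
    if (sd(li) < 1e-12 || sd(ri) < 1e-12) next
    r <- cor(li, ri)
    if (r > best$r + 1e-12) best <- list(r = r, k = k)
  }
  best$k
}

smooth_series <- function(y, k) moving_avg_oracle(y, max(1L, as.integer(k)))
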