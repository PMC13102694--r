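## Space-to-time decoding: split search, baseline normalization, timestamp
## detection, transfer-function fitting and warping onto a real-time axis.

#' Find the optimal split point of a bidirectional fiber profile
#'
#' Exhaustively scans candidate split positions within a window centered on
#' the geometric midpoint (`window_frac` of the total length). At each
#' candidate the two halves, parameterized outward from the split, are
#' resampled onto a common 500-point fractional grid and Pearson-correlated
#' on the reference channel; the argmax is returned, ties broken toward the
#' geometric center.
#'
#' @param profile a [fiber_profile()] with at least 50 samples.
#' @param ref_channel reference channel(s) (typically the timestamp/dye
#'   channels); with several, the Pearson correlation is averaged across
#'   channels, which sharpens the optimum.
#' @param window_frac searched window as a fraction of total length
#'   (0.2 for cultured-cell mode, 0.05 for in vivo mode).
#' @param n_resample points of the common fractional grid.
#' @return `split_result`: `split_index`, `split_arclength` (um),
#'   `pearson_r`, `window_frac`.
#' @export
find_split <- function(profile, ref_channel, window_frac = 0.2,
                       n_resample = 500L) {
  stopifnot(inherits(profile, "fiber_profile"))
  arc <- profile$arclength
  n <- length(arc)
  if (n < 50) stop("profile too short for split search (< 50 samples)")
  ys <- profile$channels[ref_channel]
  if (any(vapply(ys, is.null, TRUE)))
    stop("reference channel not present: ",
         paste(ref_channel[vapply(ys, is.null, TRUE)], collapse = ", "))
  if (all(vapply(ys, sd, 1) < 1e-12))
    stop("undefined correlation: reference channel has zero variance")
  L <- arc[n]
  half_win <- window_frac * L / 2
  cand <- which(abs(arc - L / 2) <= half_win + 1e-12)
  cand <- cand[cand >= 3 & cand <= n - 2]
  if (!length(cand)) cand <- which.min(abs(arc - L / 2))
  # bidirectional growth copies the record symmetrically in absolute
  # arclength, so the halves are compared on a common outward-distance grid
  # truncated to the shorter half; this keeps the optimum sharp even when
  # one terminus is imperfectly recovered
  rvals <- vapply(cand, function(k) {
    dl <- arc[k] - arc[k:1]
    dr <- arc[k:n] - arc[k]
    lmin <- min(dl[length(dl)], dr[length(dr)])
    if (lmin <= 0) return(-Inf)
    grid <- seq(0, lmin, length.out = n_resample)
    rs <- vapply(ys, function(y) {
      li <- approx(dl, y[k:1], xout = grid)$y
      ri <- approx(dr, y[k:n], xout = grid)$y
      if (sd(li) < 1e-12 || sd(ri) < 1e-12) return(NA_real_)
      cor(li, ri)
    }, 1)
    if (all(is.na(rs))) return(-Inf)
    mean(rs, na.rm = TRUE)
  }, 1)
  best_r <- max(rvals)
  ties <- cand[rvals >= best_r - 1e-12]
  k <- ties[which.min(abs(arc[ties] - L / 2))]
  structure(list(split_index = k, split_arclength = arc[k],
                 pearson_r = best_r, window_frac = window_frac),
            class = "split_result")
}

#' Normalize a profile to relative change from its split-point baseline
#'
#' The baseline of each channel is the mean intensity within a
#' `window_frac`-of-length radius around the split point; the channel is
#' then transformed to `(I - B) / B`.
#'
#' @param profile a [fiber_profile()].
#' @param split a `split_result` (or split sample index).
#' @param window_frac baseline window radius as a fraction of total length.
#' @param eps baselines at or below this value raise a division-unsafe
#'   error naming the channel.
#' @return A [fiber_profile()] of relative changes, with a `baselines`
#'   attribute.
#' @export
normalize_baseline <- function(profile, split, window_frac = 0.05,
                               eps = 1e-8) {
  k <- if (inherits(split, "split_result")) split$split_index else
    as.integer(split)
  arc <- profile$arclength
  L <- arc[length(arc)]
  win <- abs(arc - arc[k]) <= window_frac * L + 1e-12
  if (sum(win) < 3) stop("baseline window contains fewer than 3 samples")
  baselines <- vapply(profile$channels, function(y) mean(y[win]), 1)
  bad <- names(baselines)[baselines <= eps]
  if (length(bad))
    stop("division-unsafe baseline (<= ", eps, ") in channel(s): ",
         paste(bad, collapse = ", "))
  out <- mapply(function(y, b) (y - b) / b, profile$channels, baselines,
                SIMPLIFY = FALSE)
  res <- fiber_profile(arc, out, sampling = profile$sampling,
                       step = profile$step, flags = profile$flags)
  attr(res, "baselines") <- baselines
  res
}

#' Split a profile into two outward-parameterized half-records
#'
#' @param profile a [fiber_profile()].
#' @param split a `split_result` or sample index.
#' @return list of two `half_profile` objects (`left`, `right`), each with
#'   outward arclength, fraction-of-length grid and channels.
#' @export
split_profile <- function(profile, split) {
  k <- if (inherits(split, "split_result")) split$split_index else
    as.integer(split)
  arc <- profile$arclength
  n <- length(arc)
  mk <- function(idx, half) {
    d <- abs(arc[idx] - arc[k])
    Lh <- d[length(d)]
    structure(list(arclength_out = d, fraction = d / Lh,
                   channels = lapply(profile$channels, function(y) y[idx]),
                   length_um = Lh, half = half),
              class = "half_profile")
  }
  list(left = mk(seq(k, 1), "left"), right = mk(seq(k, n), "right"))
}

## --- changepoint machinery --------------------------------------------
## Discontinuous piecewise-linear least squares: each segment is fitted by
## its own line; breakpoints minimize the total SSE. Prefix sums give O(1)
## per-interval SSE.

interval_sse_fun <- function(y, model = c("linear", "step")) {
  model <- match.arg(model)
  n <- length(y)
  x <- seq_len(n)
  cx <- cumsum(x); cxx <- cumsum(x * x)
  cy <- cumsum(y); cyy <- cumsum(y * y); cxy <- cumsum(x * y)
  pre <- function(c, i) ifelse(i > 1, c[i - 1], 0)
  function(i, j) {
    nn <- j - i + 1
    sy <- cy[j] - pre(cy, i); syy <- cyy[j] - pre(cyy, i)
    vy <- syy - sy^2 / nn
    if (model == "step") return(pmax(vy, 0))
    sx <- cx[j] - pre(cx, i); sxx <- cxx[j] - pre(cxx, i)
    sxy <- cxy[j] - pre(cxy, i)
    vx <- sxx - sx^2 / nn
    cv <- sxy - sx * sy / nn
    pmax(vy - ifelse(vx > 1e-12, cv^2 / vx, 0), 0)
  }
}

# best single breakpoint: segments [1..k], [k+1..n]. The "step" model fits
# a constant per segment (mean shift): on a blurred monotone transition its
# breakpoint sits at the transition midpoint, where the sloped-segment
# variant would latch onto the top of the ramp.
two_segment_changepoint <- function(y, min_seg = 3L,
                                    model = c("linear", "step")) {
  n <- length(y)
  f <- interval_sse_fun(y, model)
  ks <- seq.int(min_seg, n - min_seg)
  sse <- f(rep(1L, length(ks)), ks) + f(ks + 1L, rep(n, length(ks)))
  k <- ks[which.min(sse)]
  sse_null <- f(1L, n)
  gain <- if (sse_null > 1e-12) 1 - min(sse) / sse_null else 0
  list(breaks = k, sse = min(sse), gain = gain)
}

# best pair of breakpoints: segments [1..k1], [k1+1..k2], [k2+1..n]
three_segment_changepoint <- function(y, min_seg = 3L) {
  n <- length(y)
  f <- interval_sse_fun(y)
  search <- function(c1s, c2lo, c2hi, stride) {
    best <- list(sse = Inf)
    for (c1 in c1s) {
      c2s <- seq.int(max(c1 + min_seg, c2lo), c2hi, by = stride)
      if (!length(c2s)) next
      m <- length(c2s)
      sse <- f(rep(1L, m), rep(c1, m)) + f(rep(c1 + 1L, m), c2s) +
        f(c2s + 1L, rep(n, m))
      i <- which.min(sse)
      if (sse[i] < best$sse)
        best <- list(sse = sse[i], c1 = c1, c2 = c2s[i])
    }
    best
  }
  stride <- max(1L, n %/% 150L)
  coarse <- search(seq.int(min_seg, n - 2L * min_seg, by = stride),
                   2L * min_seg, n - min_seg, stride)
  if (!is.finite(coarse$sse)) stop("profile too short for two changepoints")
  fine <- search(seq.int(max(min_seg, coarse$c1 - stride),
                         min(n - 2L * min_seg, coarse$c1 + stride)),
                 max(2L * min_seg, coarse$c2 - stride),
                 min(n - min_seg, coarse$c2 + stride), 1L)
  sse_null <- f(1L, n)
  gain <- if (sse_null > 1e-12) 1 - fine$sse / sse_null else 0
  list(breaks = c(fine$c1, fine$c2), sse = fine$sse, gain = gain)
}

#' Detect timestamp anchors on a half-fiber profile
#'
#' In `dye_switch` mode, the rise onset of each later dye relative to its
#' predecessor is located by a two-segment piecewise-linear least-squares
#' changepoint on the smoothed dye profile. In `dox_pulse` mode, the rise
#' onset and decay onset of the single Dox-dependent channel are located by
#' a three-segment changepoint. The fiber terminus (fraction 1, fixation
#' time) is always appended, and event times are assigned from
#' `schedule_times` in order.
#'
#' @param half a `half_profile` (see [split_profile()]).
#' @param dye_channels ordered dye channel names (`dye_switch`: first dye
#'   first; `dox_pulse`: the single pulse channel).
#' @param schedule_times wall-clock event times (days): one per dye switch,
#'   or `c(rise, decay)` for a Dox pulse.
#' @param fixation fixation time (days).
#' @param mode `"dye_switch"` or `"dox_pulse"`.
#' @param smooth_frac moving-average window as a fraction of profile
#'   length applied before changepoint detection.
#' @param min_gain minimum SSE improvement over a single-line fit for a
#'   changepoint to count as detected.
#' @return A `timestamp_set` (`anchors` data.frame with `fraction`, `time`,
#'   `kind`; `detected` flag with a `reason` when detection failed).
#' @export
detect_timestamps <- function(half, dye_channels, schedule_times, fixation,
                              mode = c("dye_switch", "dox_pulse"),
                              smooth_frac = 0.02, min_gain = 0.25) {
  mode <- match.arg(mode)
  stopifnot(inherits(half, "half_profile"))
  fr <- half$fraction
  n <- length(fr)
  kwin <- max(1L, round(smooth_frac * n))
  fail <- function(reason)
    structure(list(anchors = NULL, detected = FALSE, reason = reason,
                   mode = mode), class = "timestamp_set")
  mid_fraction <- function(k) (fr[k] + fr[min(k + 1L, n)]) / 2
  anchors <- NULL
  if (mode == "dye_switch") {
    if (length(dye_channels) < 2)
      stop("dye_switch mode needs at least two dye channels")
    if (length(schedule_times) != length(dye_channels) - 1L)
      stop("number of events must match length(schedule_times)")
    rows <- list()
    for (i in seq.int(2L, length(dye_channels))) {
      y2 <- half$channels[[dye_channels[i]]]
      y1 <- half$channels[[dye_channels[i - 1L]]]
      if (is.null(y2) || is.null(y1))
        stop("missing dye channel: ", dye_channels[i])
      # rise of the later dye relative to its predecessor: their normalized
      # difference crosses zero at the switch regardless of what later dyes
      # do, and is invariant to brightness variation along the fiber
      tot <- y2 + y1
      floor_tot <- 0.2 * stats::median(tot)
      ys <- moving_average((y2 - y1) / pmax(tot, floor_tot, 1e-12), kwin)
      if (sd(ys) < 1e-12) return(fail("flat dye channel"))
      cp <- two_segment_changepoint(ys, model = "step")
      k <- cp$breaks
      rising <- mean(ys[(k + 1):n]) > mean(ys[1:k])
      if (cp$gain < min_gain || !rising)
        return(fail(paste0("undetectable switch for ", dye_channels[i])))
      rows[[i - 1L]] <- data.frame(fraction = mid_fraction(k),
                                   time = schedule_times[i - 1L],
                                   kind = "rise_onset")
    }
    anchors <- do.call(rbind, rows)
  } else {
    if (length(schedule_times) != 2L)
      stop("dox_pulse mode needs schedule_times = c(rise, decay)")
    y <- half$channels[[dye_channels[1]]]
    if (is.null(y)) stop("missing pulse channel: ", dye_channels[1])
    ys <- moving_average(y, kwin)
    if (sd(ys) < 1e-12) return(fail("flat pulse channel"))
    cp <- three_segment_changepoint(ys)
    if (cp$gain < min_gain) return(fail("undetectable pulse"))
    k1 <- cp$breaks[1]; k2 <- cp$breaks[2]
    # refine each onset with a local two-segment fit: within a short
    # window the exponential phases are nearly straight, removing the
    # curvature bias of the global linear segments
    refine <- function(k, lo, hi) {
      w <- max(10L, round(0.08 * n))
      lo <- max(lo, k - w)
      hi <- min(hi, k + w)
      if (hi - lo < 12L) return(k)
      cpl <- two_segment_changepoint(ys[lo:hi], model = "linear")
      lo + cpl$breaks - 1L
    }
    k1 <- refine(k1, 1L, k2 - 3L)
    k2 <- refine(k2, k1 + 3L, n)
    mid_rise <- mean(ys[(k1 + 1):k2])
    if (!(mid_rise > mean(ys[1:k1]))) return(fail("pulse not rising"))
    anchors <- data.frame(
      fraction = c(mid_fraction(k1), mid_fraction(k2)),
      time = schedule_times,
      kind = c("rise_onset", "decay_onset"))
  }
  anchors <- rbind(anchors,
                   data.frame(fraction = 1, time = fixation,
                              kind = "terminus"))
  if (is.unsorted(anchors$fraction, strictly = TRUE))
    return(fail("anchor fractions not strictly increasing"))
  structure(list(anchors = anchors, detected = TRUE, reason = NULL,
                 mode = mode), class = "timestamp_set")
}

#' Construct a timestamp set directly from known anchors
#' @param fraction,time,kind anchor columns (fractions strictly increasing
#'   in (0, 1]; last anchor should be the terminus at fraction 1).
#' @return A `timestamp_set`.
#' @export
timestamp_set <- function(fraction, time,
                          kind = rep("rise_onset", length(fraction))) {
  stopifnot(length(fraction) == length(time), length(fraction) >= 2,
            all(fraction > 0), all(fraction <= 1),
            !is.unsorted(fraction, strictly = TRUE))
  structure(list(anchors = data.frame(fraction = fraction, time = time,
                                      kind = kind),
                 detected = TRUE, reason = NULL, mode = "manual"),
            class = "timestamp_set")
}

## --- transfer functions ------------------------------------------------

piecewise_linear_fun <- function(f, t) {
  n <- length(f)
  slope_lo <- (t[2] - t[1]) / (f[2] - f[1])
  slope_hi <- (t[n] - t[n - 1]) / (f[n] - f[n - 1])
  function(x) {
    y <- approx(f, t, xout = x, rule = 2)$y
    lo <- x < f[1]
    hi <- x > f[n]
    y[lo] <- t[1] + slope_lo * (x[lo] - f[1])
    y[hi] <- t[n] + slope_hi * (x[hi] - f[n])
    y
  }
}

fit_power <- function(f, t) {
  # t = alpha * f^beta + gamma, fitted by profiling beta (linear solve for
  # alpha, gamma at fixed beta); deterministic
  sse_beta <- function(beta) {
    X <- cbind(1, f^beta)
    fit <- lm.fit(X, t)
    sum(fit$residuals^2)
  }
  opt <- optimize(sse_beta, interval = c(0.05, 10), tol = 1e-10)
  beta <- opt$minimum
  X <- cbind(1, f^beta)
  cf <- lm.fit(X, t)$coefficients
  list(alpha = cf[2], beta = beta, gamma = cf[1])
}

#' Fit a space-to-time transfer function through timestamp anchors
#'
#' With two anchors the mapping is linear; with three or more, a quadratic
#' polynomial, a power law `t = alpha * f^beta + gamma`, a piecewise-linear
#' interpolant, or a monotone (Hyman-filtered) cubic spline can be fitted.
#' Monotonicity is verified on the anchor span; a violating fit falls back
#' to piecewise-linear and is flagged.
#'
#' @param anchors a `timestamp_set` (fractions in (0, 1], strictly
#'   increasing times).
#' @param model transfer family.
#' @return A `transfer_function` with a `predict()` method mapping
#'   fraction-of-length to days.
#' @export
fit_transfer <- function(anchors,
                         model = c("linear", "quadratic", "power",
                                   "piecewise_linear", "monotone_spline")) {
  model <- match.arg(model)
  stopifnot(inherits(anchors, "timestamp_set"), isTRUE(anchors$detected))
  a <- anchors$anchors
  f <- a$fraction
  t <- a$time
  if (length(f) < 2) stop("need at least 2 anchors")
  if (is.unsorted(t, strictly = TRUE))
    stop("invalid anchors: times must be strictly increasing")
  if (model %in% c("quadratic", "power", "monotone_spline") &&
      length(f) < 3) model <- "linear"
  flags <- character()
  mk <- function(model) {
    switch(model,
      linear = {
        cf <- lm.fit(cbind(1, f), t)$coefficients
        list(coef = c(intercept = cf[[1]], slope = cf[[2]]),
             fn = function(x) cf[[1]] + cf[[2]] * x)
      },
      quadratic = {
        cf <- lm.fit(cbind(1, f, f^2), t)$coefficients
        list(coef = c(c0 = cf[[1]], c1 = cf[[2]], c2 = cf[[3]]),
             fn = function(x) cf[[1]] + cf[[2]] * x + cf[[3]] * x^2)
      },
      power = {
        p <- fit_power(f, t)
        list(coef = c(alpha = unname(p$alpha), beta = unname(p$beta),
                      gamma = unname(p$gamma)),
             fn = function(x) p$gamma + p$alpha * x^p$beta)
      },
      piecewise_linear = {
        fn <- piecewise_linear_fun(f, t)
        list(coef = list(fraction = f, time = t), fn = fn)
      },
      monotone_spline = {
        fn <- splinefun(f, t, method = "hyman")
        list(coef = list(fraction = f, time = t), fn = fn)
      })
  }
  built <- mk(model)
  # monotonicity on the anchor span
  grid <- seq(min(f), 1, length.out = 500)
  if (any(diff(built$fn(grid)) < -1e-12)) {
    flags <- c(flags, "nonmonotone_fallback")
    model <- "piecewise_linear"
    built <- mk(model)
  }
  structure(list(model = model, coefficients = built$coef, fn = built$fn,
                 anchors = a, flags = flags),
            class = "transfer_function")
}

#' @export
predict.transfer_function <- function(object, f, ...) object$fn(f)

#' @export
print.transfer_function <- function(x, ...) {
  cat("transfer_function:", x$model, "\n")
  if (is.numeric(x$coefficients))
    cat("  coefficients:",
        paste(names(x$coefficients), signif(x$coefficients, 6),
              sep = " = ", collapse = ", "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Warp a half-fiber profile onto a uniform real-time axis
#'
#' Maps each sample's fraction-of-length to time through the transfer
#' function and resamples all channels onto a uniform grid of spacing `dt`
#' by linear interpolation. Samples earlier than the first anchor are
#' reached only by model extrapolation and are flagged.
#'
#' @param half a `half_profile`.
#' @param transfer a `transfer_function`.
#' @param dt output sampling interval (days).
#' @param channels channels to carry (default: all).
#' @return A [time_series()].
#' @export
warp_to_time <- function(half, transfer, dt, channels = NULL) {
  stopifnot(inherits(half, "half_profile"),
            inherits(transfer, "transfer_function"))
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive")
  channels <- channels %||% names(half$channels)
  tt <- predict(transfer, half$fraction)
  if (is.unsorted(tt)) stop("transfer function not monotone on the profile")
  grid <- seq(tt[1], tt[length(tt)], by = dt)
  ch <- lapply(half$channels[channels], function(y)
    approx(tt, y, xout = grid, rule = 2)$y)
  first_anchor_t <- min(transfer$anchors$time)
  time_series(grid, ch, extrapolated = grid < first_anchor_t)
}
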