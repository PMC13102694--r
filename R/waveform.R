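## Per-cell analytics on recovered time series: peak features, fluctuation
## statistic, time-lagged correlation, coupling-mode classification and
## fiber-to-cell assignment.

#' Extract peak features from a recovered time series channel
#'
#' Peaks are strict local maxima whose surrounding threshold exceedance
#' (`threshold_sd` pre-reference standard deviations above the zero
#' relative-change baseline) is sustained for at least `min_sustain`
#' samples. Each peak reports its amplitude, time to peak from the
#' reference, full width at half maximum (linear interpolation of the
#' half-height crossings) and onset time (start of the sustained
#' threshold crossing preceding the peak).
#'
#' @param ts a [time_series()].
#' @param channel channel name.
#' @param threshold_sd detection threshold in units of the pre-reference
#'   (pre-stimulus) standard deviation.
#' @param min_sustain minimum number of consecutive supra-threshold
#'   samples.
#' @param reference_time reference (e.g. stimulation) time, days; the
#'   pre-reference window estimates the noise sd.
#' @return data.frame with one row per peak: `amplitude`, `peak_time`,
#'   `time_to_peak`, `fwhm`, `onset_time`.
#' @export
peak_features <- function(ts, channel, threshold_sd = 2, min_sustain = 3L,
                          reference_time) {
  stopifnot(inherits(ts, "time_series"))
  y <- ts$channels[[channel]]
  if (is.null(y)) stop("unknown channel: ", channel)
  tt <- ts$time
  pre <- tt < reference_time
  if (sum(pre) < 3)
    stop("no pre-reference window to estimate the baseline sd")
  thr <- threshold_sd * sd(y[pre])
  n <- length(y)
  above <- y > thr
  empty <- data.frame(amplitude = numeric(), peak_time = numeric(),
                      time_to_peak = numeric(), fwhm = numeric(),
                      onset_time = numeric())
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_sustain)
  rows <- list()
  for (ri in runs) {
    lo <- starts[ri]; hi <- ends[ri]
    seg <- y[lo:hi]
    # strict interior local maxima within the run (run edges count if the
    # neighbouring sample outside the run is lower)
    peaks <- integer()
    for (j in lo:hi) {
      left <- if (j > 1) y[j - 1] else -Inf
      right <- if (j < n) y[j + 1] else -Inf
      if (y[j] >= left && y[j] > right) peaks <- c(peaks, j)
      else if (y[j] > left && y[j] >= right) peaks <- c(peaks, j)
    }
    if (!length(peaks)) peaks <- lo + which.max(seg) - 1L
    # keep peaks separated by >= min_sustain samples (tallest first)
    peaks <- peaks[order(-y[peaks])]
    kept <- integer()
    for (p in peaks)
      if (!length(kept) || all(abs(kept - p) >= min_sustain))
        kept <- c(kept, p)
    for (p in sort(kept)) {
      amp <- y[p]
      half <- amp / 2
      # half-height crossings, searched outward from the peak
      tl <- NA_real_
      if (p >= 2) for (j in p:2) {
        if (y[j - 1] <= half && y[j] > half) {
          tl <- tt[j - 1] + (tt[j] - tt[j - 1]) *
            (half - y[j - 1]) / (y[j] - y[j - 1])
          break
        }
      }
      tr <- NA_real_
      if (p <= n - 1) for (j in p:(n - 1)) {
        if (y[j] > half && y[j + 1] <= half) {
          tr <- tt[j] + (tt[j + 1] - tt[j]) *
            (y[j] - half) / (y[j] - y[j + 1])
          break
        }
      }
      if (is.na(tl)) tl <- tt[1]
      if (is.na(tr)) tr <- tt[n]
      rows[[length(rows) + 1L]] <- data.frame(
        amplitude = amp, peak_time = tt[p],
        time_to_peak = tt[p] - reference_time,
        fwhm = tr - tl, onset_time = tt[lo])
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Line-length (total-variation) fluctuation statistic
#'
#' Sum of absolute differences between consecutive samples within a time
#' window; used to quantify baseline fluctuations.
#'
#' @param ts a [time_series()].
#' @param channel channel name.
#' @param t_start,t_end window bounds (days), inclusive.
#' @return numeric line length.
#' @export
line_length <- function(ts, channel, t_start = min(ts$time),
                        t_end = max(ts$time)) {
  stopifnot(inherits(ts, "time_series"))
  y <- ts$channels[[channel]]
  if (is.null(y)) stop("unknown channel: ", channel)
  sel <- ts$time >= t_start - 1e-12 & ts$time <= t_end + 1e-12
  if (sum(sel) < 2) stop("empty or single-sample window")
  sum(abs(diff(y[sel])))
}

#' Mean post-stimulation signal
#' @param ts a [time_series()].
#' @param channel channel name.
#' @param t_stim stimulation time (days).
#' @param window averaging window length after `t_stim` (days).
#' @return mean relative change over `[t_stim, t_stim + window]`.
#' @export
post_stim_mean <- function(ts, channel, t_stim, window) {
  stopifnot(inherits(ts, "time_series"))
  y <- ts$channels[[channel]]
  if (is.null(y)) stop("unknown channel: ", channel)
  sel <- ts$time >= t_stim - 1e-12 & ts$time <= t_stim + window + 1e-12
  if (!any(sel)) stop("empty post-stimulation window")
  mean(y[sel])
}

#' Time-lagged Pearson correlation between two channels
#'
#' `r(tau) = cor(A(t), B(t + tau))` over the overlapping window, for `tau`
#' on a symmetric grid. Lags with a zero-variance segment are masked (NA).
#'
#' @param tsA,tsB [time_series()] objects on a common uniform grid (or the
#'   same object).
#' @param channelA,channelB channel names.
#' @param max_lag maximum |lag| (days).
#' @param lag_step lag grid step (days); defaults to the sampling interval.
#' @param min_overlap minimum overlapping samples per lag.
#' @return `lag_profile`: data.frame-like list with `lags` (days) and
#'   `correlations`.
#' @export
lag_correlation <- function(tsA, tsB, channelA, channelB, max_lag,
                            lag_step = NULL, min_overlap = 10L) {
  stopifnot(inherits(tsA, "time_series"), inherits(tsB, "time_series"))
  if (abs(tsA$dt - tsB$dt) > 1e-9)
    stop("series must share a common uniform grid")
  dt <- tsA$dt
  lag_step <- lag_step %||% dt
  step_samp <- max(1L, round(lag_step / dt))
  max_samp <- round(max_lag / dt)
  a <- tsA$channels[[channelA]]
  b <- tsB$channels[[channelB]]
  if (is.null(a) || is.null(b)) stop("unknown channel")
  # align the two series on the common absolute time axis
  offset <- round((tsB$time[1] - tsA$time[1]) / dt)
  ks <- seq.int(-max_samp, max_samp, by = step_samp)
  rs <- vapply(ks, function(k) {
    # pair a[i] with b[j] where timeB[j] = timeA[i] + k*dt
    shift <- k - offset
    ia <- seq_along(a)
    ib <- ia + shift
    ok <- ib >= 1 & ib <= length(b)
    if (sum(ok) < min_overlap) return(NA_real_)
    av <- a[ia[ok]]; bv <- b[ib[ok]]
    if (sd(av) < 1e-12 || sd(bv) < 1e-12) return(NA_real_)
    cor(av, bv)
  }, 1)
  structure(list(lags = ks * dt, correlations = rs),
            class = "lag_profile")
}

#' Classify cells into coupled and decoupled signalling modes
#'
#' Two-cluster partition of per-cell lag-correlation vectors with a
#' deterministic k-means (farthest-pair initialization, Lloyd iterations).
#' The cluster with the higher mean correlation within
#' `near_zero_frac * max_lag` of zero lag is labelled `type2_coupled`; the
#' other `type1_decoupled`. If all profiles are identical the partition is
#' degenerate and cells are labelled by a fixed threshold
#' (`max_r_near_zero >= 0.5` = coupled).
#'
#' @param lag_profiles list of `lag_profile` objects on a common lag grid
#'   (>= 4 cells).
#' @param near_zero_frac half-width of the near-zero-lag window as a
#'   fraction of the maximum lag.
#' @param max_iter Lloyd iteration cap.
#' @return data.frame with `cell`, `label`, `max_r_near_zero`.
#' @export
classify_coupling <- function(lag_profiles, near_zero_frac = 0.1,
                              max_iter = 100L) {
  n <- length(lag_profiles)
  if (n < 4) stop("need at least 4 cells to classify")
  lags <- lag_profiles[[1]]$lags
  X <- t(vapply(lag_profiles, function(p) {
    if (length(p$lags) != length(lags) || any(abs(p$lags - lags) > 1e-9))
      stop("lag profiles must share a common lag grid")
    v <- p$correlations
    v[is.na(v)] <- 0
    v
  }, numeric(length(lags))))
  near <- abs(lags) <= near_zero_frac * max(abs(lags)) + 1e-12
  r_near <- apply(X[, near, drop = FALSE], 1, max)
  d2 <- as.matrix(dist(X))^2
  degenerate <- max(d2) < 1e-12
  if (degenerate) {
    label <- ifelse(r_near >= 0.5, "type2_coupled", "type1_decoupled")
    res <- data.frame(cell = seq_len(n), label = label,
                      max_r_near_zero = r_near)
    attr(res, "degenerate") <- TRUE
    return(res)
  }
  # farthest-pair initialization
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  centers <- X[c(ij[1], ij[2]), , drop = FALSE]
  assign_old <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    dc <- cbind(rowSums(sweep(X, 2, centers[1, ])^2),
                rowSums(sweep(X, 2, centers[2, ])^2))
    cl <- max.col(-dc, ties.method = "first")
    if (all(cl == assign_old)) break
    assign_old <- cl
    for (g in 1:2)
      if (any(cl == g))
        centers[g, ] <- colMeans(X[cl == g, , drop = FALSE])
  }
  mean_near <- vapply(1:2, function(g)
    mean(X[cl == g, near, drop = FALSE]), 1)
  coupled_cluster <- which.max(mean_near)
  label <- ifelse(cl == coupled_cluster, "type2_coupled", "type1_decoupled")
  res <- data.frame(cell = seq_len(n), label = label,
                    max_r_near_zero = r_near)
  attr(res, "degenerate") <- FALSE
  res
}

#' Assign fibers to cells and pick per-cell representative fibers
#'
#' Each fiber is assigned to the soma label containing the strict majority
#' of its centerline points (ties or background majority leave it
#' unassigned). When a cell owns several fibers, the one with the longest
#' geodesic length is its representative.
#'
#' @param centerlines named list of [centerline()] objects (names = fiber
#'   ids).
#' @param soma_labels a [label_volume()] of kind `"soma"`.
#' @return list with `assignments` (data.frame: fiber, cell, geodesic_length,
#'   representative) and `representatives` (named vector cell -> fiber id).
#' @export
assign_fibers_to_cells <- function(centerlines, soma_labels) {
  stopifnot(inherits(soma_labels, "label_volume"))
  if (is.null(names(centerlines)))
    names(centerlines) <- as.character(seq_along(centerlines))
  rows <- lapply(names(centerlines), function(nm) {
    cl <- centerlines[[nm]]
    soma <- soma_majority(cl, soma_labels)
    data.frame(fiber = nm,
               cell = if (soma > 0) soma else NA_integer_,
               geodesic_length = geodesic_length(cl),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$representative <- FALSE
  reps <- c()
  for (cell in unique(tab$cell[!is.na(tab$cell)])) {
    sub <- tab[!is.na(tab$cell) & tab$cell == cell, ]
    best <- sub$fiber[which.max(sub$geodesic_length)]
    tab$representative[tab$fiber == best] <- TRUE
    reps[as.character(cell)] <- best
  }
  list(assignments = tab, representatives = reps)
}
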