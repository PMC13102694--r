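#' @useDynLib tapetrace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor cov dist lm.fit mad median prcomp quantile
#'   rlnorm rnorm rpois runif sd smooth.spline predict splinefun coef
#'   optimize var
#' @importFrom utils write.csv read.csv head tail
NULL

#' Multi-channel 3D image volume
#'
#' Container for a confocal-style z-stack with named channels and physical
#' voxel spacing. Arrays are indexed `(z, y, x)`; the physical position of
#' voxel `(z, y, x)` (0-based) is `(z*dz, y*dy, x*dx)` micrometres.
#'
#' @param data named list of 3D numeric arrays, one per channel, all of the
#'   same dimension.
#' @param spacing numeric length-3, voxel spacing `(dz, dy, dx)` in um.
#' @param channels optional channel names; defaults to `names(data)`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, channels = names(data)) {
  if (!is.list(data) || length(data) == 0L)
    stop("`data` must be a non-empty list of 3D arrays")
  dims <- lapply(data, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("each channel must be a 3D array")
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must share the same dimensions")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (dz, dy, dx)")
  if (is.null(channels)) {
    channels <- paste0("ch", seq_along(data) - 1L)
    warning("missing channel names; auto-naming ch0..ch", length(data) - 1L)
  }
  names(data) <- channels
  structure(list(data = data, spacing = as.numeric(spacing),
                 channels = channels, dim = dims[[1]]),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume:", paste(x$dim, collapse = " x "),
      "voxels,", length(x$channels), "channel(s)\n")
  cat("  spacing (dz,dy,dx):", paste(signif(x$spacing, 4), collapse = ", "),
      "um\n")
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

get_channel <- function(vol, channel) {
  stopifnot(inherits(vol, "image_volume"))
  if (!channel %in% vol$channels)
    stop("unknown channel: ", channel)
  vol$data[[channel]]
}

#' Integer label volume
#'
#' @param labels 3D integer array, 0 = background.
#' @param spacing voxel spacing `(dz, dy, dx)` in um.
#' @param kind `"fiber"` or `"soma"`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing, kind = c("fiber", "soma")) {
  kind <- match.arg(kind)
  stopifnot(length(dim(labels)) == 3L, length(spacing) == 3L)
  structure(list(labels = labels, spacing = as.numeric(spacing), kind = kind,
                 n = max(0L, max(labels))),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume (", x$kind, "): ", x$n, " instance(s), ",
      paste(dim(x$labels), collapse = " x "), " voxels\n", sep = "")
  invisible(x)
}

#' Ordered 3D centerline
#'
#' @param points n x 3 matrix of `(z, y, x)` physical coordinates in um.
#' @param method how the centerline was obtained.
#' @param flags character vector of quality flags.
#' @return `centerline` object with cumulative `arclength` in um.
#' @export
centerline <- function(points, method = c("pca_spline", "morph_skeleton",
                                          "manual"),
                       flags = character()) {
  method <- match.arg(method)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, nrow(points) >= 2L)
  seg <- sqrt(rowSums(diff(points)^2))
  structure(list(points = points, arclength = c(0, cumsum(seg)),
                 n_points = nrow(points), method = method, flags = flags),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat("centerline:", x$n_points, "points,",
      sprintf("%.2f um", geodesic_length(x)), "geodesic length,",
      "method =", x$method, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Geodesic (arclength) length of a centerline
#' @param cl a `centerline`.
#' @return length in um.
#' @export
geodesic_length <- function(cl) {
  stopifnot(inherits(cl, "centerline"))
  cl$arclength[length(cl$arclength)]
}

#' Per-channel intensity profile along a fiber
#'
#' @param arclength numeric grid in um.
#' @param channels named list of numeric vectors, one per channel, each the
#'   same length as `arclength`.
#' @param sampling `"trilinear"` or `"cylindrical"`.
#' @param step sampling interval in um (for cylindrical sampling).
#' @param flags character quality flags.
#' @return `fiber_profile` object.
#' @export
fiber_profile <- function(arclength, channels,
                          sampling = c("trilinear", "cylindrical"),
                          step = NA_real_, flags = character()) {
  sampling <- match.arg(sampling)
  lens <- vapply(channels, length, 1L)
  if (any(lens != length(arclength)))
    stop("all channel sequences must match the arclength grid")
  structure(list(arclength = as.numeric(arclength), channels = channels,
                 sampling = sampling, step = step, flags = flags),
            class = "fiber_profile")
}

#' @export
print.fiber_profile <- function(x, ...) {
  cat("fiber_profile:", length(x$arclength), "samples over",
      sprintf("%.2f um;", max(x$arclength)), "channels:",
      paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Uniformly sampled time series of relative-change signals
#'
#' @param time numeric, strictly increasing uniform grid (days).
#' @param channels named list of numeric vectors.
#' @param extrapolated logical mask marking samples below the first timestamp
#'   anchor (times reached only by model extrapolation).
#' @return `time_series` object.
#' @export
time_series <- function(time, channels, extrapolated = NULL) {
  stopifnot(all(diff(time) > 0))
  lens <- vapply(channels, length, 1L)
  if (any(lens != length(time)))
    stop("channel lengths must match the time grid")
  if (is.null(extrapolated)) extrapolated <- rep(FALSE, length(time))
  structure(list(time = as.numeric(time), channels = channels,
                 dt = if (length(time) > 1) diff(time)[1] else NA_real_,
                 extrapolated = extrapolated),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat("time_series:", length(x$time), "samples,",
      sprintf("t in [%.3g, %.3g] days, dt = %.4g;", min(x$time), max(x$time),
              x$dt),
      "channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

## --- small shared numeric helpers -------------------------------------

# centered moving average with edge shrinkage; k forced odd
moving_average <- function(y, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(y)
  n <- length(y)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# resample an ordered point matrix to n points equidistant in arclength
resample_polyline <- function(points, n) {
  seg <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seg))
  keep <- c(TRUE, diff(s) > 0)
  s <- s[keep]
  points <- points[keep, , drop = FALSE]
  grid <- seq(0, s[length(s)], length.out = n)
  out <- sapply(seq_len(3), function(j)
    approx(s, points[, j], xout = grid, rule = 2)$y)
  out
}

# three-point discrete curvature (1/circumradius) for consecutive triples
discrete_curvature <- function(points) {
  n <- nrow(points)
  if (n < 3) return(numeric(0))
  a <- points[1:(n - 2), , drop = FALSE]
  b <- points[2:(n - 1), , drop = FALSE]
  cc <- points[3:n, , drop = FALSE]
  ab <- b - a; bc <- cc - b; ac <- cc - a
  la <- sqrt(rowSums(ab^2)); lb <- sqrt(rowSums(bc^2)); lc <- sqrt(rowSums(ac^2))
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  area2 <- sqrt(rowSums(cr^2))            # 2 * triangle area
  denom <- la * lb * lc
  kappa <- ifelse(denom > 0, 2 * area2 / denom, 0)
  kappa
}

`%||%` <- function(a, b) if (is.null(a)) b else a
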