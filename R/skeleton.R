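## Centerline extraction, extrapolation to fiber termini, and geometry.

# voxel (z,y,x) 1-based index matrix -> physical um coordinates
voxels_to_um <- function(idx, spacing) {
  sweep(idx - 1, 2, spacing, "*")
}

mask_indices <- function(mask) {
  which(mask, arr.ind = TRUE)
}

#' Explained variance of the first principal component of a point cloud
#'
#' The fraction of total coordinate variance captured by the first
#' principal axis, `lambda1 / (lambda1 + lambda2 + lambda3)`; used as a
#' straightness / fiber-likeness score (1 for collinear points, about 1/3
#' for an isotropic 3D cloud).
#'
#' @param points n x 3 coordinate matrix (n >= 3, not all identical).
#' @return fraction in (0, 1].
#' @export
pc1_explained_variance <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3)
    stop("undefined geometry: need at least 3 points")
  cv <- stats::cov(points)
  tot <- sum(diag(cv))
  if (tot <= 0)
    stop("undefined geometry: zero variance point cloud")
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev[1] / tot
}

#' Extract a fiber centerline from a binary mask
#'
#' `pca_spline` projects the mask voxels onto the first principal axis,
#' trims to the central 80% of points by projection quantile, fits a
#' coordinate-wise smoothing cubic spline against the projection parameter
#' and resamples the curve at `n_points` equidistant arclength positions.
#' `morph_skeleton` (fallback for low-straightness geometries) extracts the
#' longest geodesic path through the mask's 26-connected voxel graph,
#' smooths it and resamples identically.
#'
#' @param mask 3D logical array selecting one fiber's voxels (>= 20 voxels).
#' @param spacing voxel spacing `(dz, dy, dx)` um.
#' @param method `"pca_spline"` or `"morph_skeleton"`.
#' @param n_points number of equidistant output points.
#' @param trim_frac fraction of points trimmed from each end of the
#'   projection before spline fitting (0.1 each end = central 80%).
#' @param spar optional smoothing parameter passed to
#'   [stats::smooth.spline()] (default: generalized cross-validation).
#' @return A [centerline()].
#' @export
extract_centerline <- function(mask, spacing,
                               method = c("pca_spline", "morph_skeleton"),
                               n_points = 1000L, trim_frac = 0.1,
                               spar = NULL) {
  method <- match.arg(method)
  idx <- mask_indices(mask)
  if (nrow(idx) < 20)
    stop("mask too small for centerline extraction (< 20 voxels)")
  pts <- voxels_to_um(idx, spacing)
  flags <- character()
  if (method == "pca_spline") {
    pc <- prcomp(pts, center = TRUE, scale. = FALSE)
    u <- pc$x[, 1]
    qs <- quantile(u, c(trim_frac, 1 - trim_frac))
    keep <- u >= qs[1] & u <= qs[2]
    u <- u[keep]
    sub <- pts[keep, , drop = FALSE]
    # bin-average the cloud along the projection (~1 voxel-diagonal bins)
    # before the spline fit: averages out the tube cross-section and keeps
    # the fit from chasing interleaved projections of curved geometries
    vdiag <- sqrt(sum(spacing^2))
    nbins <- max(10L, min(500L, ceiling(diff(range(u)) / (vdiag / 2))))
    bin <- findInterval(u, seq(min(u), max(u), length.out = nbins + 1L),
                        all.inside = TRUE)
    ub <- tapply(u, bin, mean)
    wb <- tabulate(bin, nbins)[as.integer(names(ub))]
    ugrid <- seq(min(u), max(u), length.out = max(200L, n_points %/% 2L))
    # flexibility capped at ~one degree of freedom per 1.5 um: ample for
    # biological curvatures while refusing to chase residual mask noise
    dfmax <- min(length(ub) - 1L, max(4L, ceiling(diff(range(u)) / 1.5)))
    curve <- sapply(1:3, function(j) {
      cb <- tapply(sub[, j], bin, mean)
      fit <- if (is.null(spar))
        smooth.spline(ub, cb, w = wb, df = dfmax)
      else smooth.spline(ub, cb, w = wb, spar = spar)
      predict(fit, ugrid)$y
    })
    proj_span <- diff(range(u))
  } else {
    sw1 <- cpp_geodesic_sweep(as.logical(mask), dim(mask), spacing, -1L)
    sw2 <- cpp_geodesic_sweep(as.logical(mask), dim(mask), spacing,
                              sw1$farthest - 1L)
    # walk predecessors back from the farthest voxel
    path <- integer(0)
    cur <- sw2$farthest
    while (cur > 0) {
      path <- c(path, cur)
      cur <- sw2$pred[cur]
    }
    # count skeleton-graph endpoints to flag branched geometries
    nd <- dim(mask)
    arr <- arrayInd(path, nd)
    curve <- voxels_to_um(arr, spacing)
    # smooth voxel staircase (~1 um window)
    step_um <- mean(sqrt(rowSums((diff(curve))^2)))
    k <- max(3L, round(1 / max(step_um, 1e-6)))
    curve <- apply(curve, 2, moving_average, k = k)
    if (nrow(curve) < 2)
      stop("degenerate geodesic path")
    # trim to the central 80% by arclength, mirroring the pca_spline trim;
    # the trimmed tips (and mask-corner artifacts at the path ends) are
    # recovered by extrapolation against the structural channel
    seg <- c(0, cumsum(sqrt(rowSums(diff(curve)^2))))
    Lp <- seg[length(seg)]
    keep <- seg >= trim_frac * Lp & seg <= (1 - trim_frac) * Lp
    if (sum(keep) >= 2) curve <- curve[keep, , drop = FALSE]
    proj_span <- NA_real_
    flags <- c(flags, "morph_skeleton")
  }
  out <- resample_polyline(curve, n_points)
  cl <- centerline(out, method = method, flags = flags)
  cl$proj_span <- proj_span
  cl
}

#' Resample a centerline at equidistant arclength positions
#' @param cl a [centerline()].
#' @param n_points number of output points.
#' @return resampled [centerline()].
#' @export
resample_centerline <- function(cl, n_points = 1000L) {
  out <- resample_polyline(cl$points, n_points)
  centerline(out, method = cl$method, flags = cl$flags)
}

# local tangent at a centerline end, averaged over ~`span` um
end_tangent <- function(cl, end = c("last", "first"), span = 1) {
  end <- match.arg(end)
  s <- cl$arclength
  L <- s[length(s)]
  if (end == "last") {
    k <- which(s >= L - span)[1]
    d <- cl$points[nrow(cl$points), ] - cl$points[k, ]
  } else {
    k <- tail(which(s <= span), 1)
    d <- cl$points[1, ] - cl$points[k, ]
  }
  n <- sqrt(sum(d^2))
  if (n < 1e-12) stop("degenerate end tangent")
  d / n
}

# positions continuing a centerline end along its osculating circle (the
# straight tangent when the end is nearly straight), at arclength steps
end_extension_points <- function(cl, end = c("last", "first"), n_ext, step,
                                 span = 2) {
  end <- match.arg(end)
  s <- cl$arclength
  L <- s[length(s)]
  pick <- function(target) {
    if (end == "last") cl$points[which(s >= L - target)[1], ]
    else cl$points[tail(which(s <= target), 1), ]
  }
  C <- if (end == "last") cl$points[nrow(cl$points), ] else cl$points[1, ]
  A <- pick(span)
  B <- pick(span / 2)
  tangent <- end_tangent(cl, end)
  straight <- function() sweep(outer(seq_len(n_ext) * step, tangent), 2,
                               C, "+")
  a <- A - C
  b <- B - C
  cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  cr2 <- sum(cr^2)
  if (cr2 < 1e-12) return(straight())
  # circumcenter: C + ((|a|^2 b - |b|^2 a) x (a x b)) / (2 |a x b|^2)
  v <- sum(a^2) * b - sum(b^2) * a
  off <- c(v[2] * cr[3] - v[3] * cr[2], v[3] * cr[1] - v[1] * cr[3],
           v[1] * cr[2] - v[2] * cr[1]) / (2 * cr2)
  O <- C + off
  R <- sqrt(sum((C - O)^2))
  if (!is.finite(R) || R > 50) return(straight())
  axis <- cr / sqrt(cr2)
  # choose the rotation sense that continues the A -> B -> C motion
  vel <- c(axis[2] * (C - O)[3] - axis[3] * (C - O)[2],
           axis[3] * (C - O)[1] - axis[1] * (C - O)[3],
           axis[1] * (C - O)[2] - axis[2] * (C - O)[1])
  sgn <- if (sum(vel * tangent) >= 0) 1 else -1
  r0 <- C - O
  t(vapply(seq_len(n_ext), function(i) {
    th <- sgn * i * step / R
    ct <- cos(th); st <- sin(th)
    O + r0 * ct + c(axis[2] * r0[3] - axis[3] * r0[2],
                    axis[3] * r0[1] - axis[1] * r0[3],
                    axis[1] * r0[2] - axis[2] * r0[1]) * st +
      axis * sum(axis * r0) * (1 - ct)
  }, numeric(3)))
}

#' Extrapolate a centerline to the true fiber termini
#'
#' Extends each end of the centerline along its osculating circle (the
#' straight tangent for near-straight ends) in steps of the sampling
#' interval, sampling the structural-monomer channel by trilinear
#' interpolation. The extension stops at the minimum of the smoothed
#' sampled profile -- located as the mean-shift changepoint of the falling
#' intensity transition, i.e. the midpoint of the blurred tube edge -- or
#' after `cap_frac` of the geodesic length, whichever comes first. The
#' probe looks beyond the cap so the transition has background context,
#' but the accepted extension never exceeds the cap.
#'
#' @param cl a [centerline()].
#' @param structure_channel 3D array of the structural channel.
#' @param spacing voxel spacing um.
#' @param cap_frac maximum extension per end, as a fraction of the geodesic
#'   length (0.2 = up to 20% each way).
#' @param step extension step (um); default the centerline sampling
#'   interval.
#' @param smooth_um moving-average window for the sampled profile (um).
#' @return extended, re-resampled [centerline()]; flags record ends that hit
#'   the cap (`"capped_start"`, `"capped_end"`) or the volume boundary
#'   (`"truncated"`).
#' @export
extrapolate_centerline <- function(cl, structure_channel, spacing,
                                   cap_frac = 0.2, step = NULL,
                                   smooth_um = 0.5) {
  if (cap_frac <= 0) return(cl)
  L <- geodesic_length(cl)
  if (is.null(step)) step <- mean(diff(cl$arclength))
  m <- floor(cap_frac * L / step)
  if (m < 1) return(cl)
  dims <- dim(structure_channel)
  extent <- (dims - 1) * spacing
  flags <- cl$flags
  extend_one <- function(end, label) {
    # probe twice as far as the cap so the tip transition has background
    # context on both sides; the accepted extension is still capped at m.
    # The probe follows the end's osculating circle so that curved fiber
    # ends are tracked instead of left tangentially.
    pos <- end_extension_points(cl, end, 2L * m, step)
    inb <- pos[, 1] >= 0 & pos[, 1] <= extent[1] &
           pos[, 2] >= 0 & pos[, 2] <= extent[2] &
           pos[, 3] >= 0 & pos[, 3] <= extent[3]
    if (!all(inb)) {
      pos <- pos[seq_len(max(0L, which(!inb)[1] - 1L)), , drop = FALSE]
      flags <<- c(flags, "truncated")
    }
    if (nrow(pos) == 0) return(NULL)
    prof <- cpp_trilinear(structure_channel, dims,
                          sweep(pos, 2, spacing, "/"))
    sm <- moving_average(prof, max(1L, round(smooth_um / step)))
    # the fiber tip is the falling intensity transition of the extension
    # profile; its midpoint is located by a two-segment mean-shift
    # changepoint, which averages noise on both sides and is unbiased for
    # the symmetric PSF-blurred edge. A flat profile (no minimum to find)
    # extends to the cap.
    stop_at <- min(nrow(pos), m)
    found <- FALSE
    if (length(sm) >= 7) {
      cp <- two_segment_changepoint(sm, min_seg = 3L, model = "step")
      k <- cp$breaks
      falling <- mean(sm[(k + 1):length(sm)]) < mean(sm[seq_len(k)])
      if (cp$gain >= 0.2 && falling) {
        stop_at <- min(k, m)
        found <- k <= m
      }
    }
    if (!found) flags <<- c(flags, paste0("capped_", label))
    pos[seq_len(stop_at), , drop = FALSE]
  }
  ext_end <- extend_one("last", "end")
  ext_start <- extend_one("first", "start")
  pts <- rbind(
    if (!is.null(ext_start)) ext_start[rev(seq_len(nrow(ext_start))), ,
                                       drop = FALSE],
    cl$points,
    ext_end)
  out <- resample_polyline(pts, cl$n_points)
  centerline(out, method = cl$method, flags = unique(flags))
}

#' Fiber geometry: geodesic length, mean width, maximum curvature
#'
#' Length is the centerline arclength. Width is twice the mean Euclidean
#' distance-transform value of the mask sampled at the centerline points
#' (a morphology-based definition). Maximum curvature is the largest
#' three-point circumradius reciprocal over a smoothed (default 1 um moving
#' average) centerline resampled at a quarter of the smoothing window, which
#' suppresses voxel-noise blow-up.
#'
#' @param cl a [centerline()].
#' @param mask optional 3D logical mask of the fiber (needed for width).
#' @param spacing voxel spacing um (needed for width).
#' @param smooth_um curvature smoothing window (um).
#' @return list with `geodesic_length`, `mean_width` (NA without a mask)
#'   and `max_curvature`.
#' @export
fiber_geometry <- function(cl, mask = NULL, spacing = NULL, smooth_um = 1) {
  L <- geodesic_length(cl)
  width <- NA_real_
  if (!is.null(mask)) {
    stopifnot(!is.null(spacing))
    edt <- cpp_edt(as.logical(mask), dim(mask), spacing)
    vals <- cpp_trilinear(edt, dim(mask),
                          sweep(cl$points, 2, spacing, "/"))
    width <- 2 * mean(vals)
  }
  ds <- mean(diff(cl$arclength))
  k <- max(1L, round(smooth_um / ds))
  sm <- apply(cl$points, 2, moving_average, k = k)
  n_res <- max(8L, round(L / (smooth_um / 4)))
  res <- resample_polyline(sm, n_res)
  kappa <- discrete_curvature(res)
  list(geodesic_length = L, mean_width = width,
       max_curvature = if (length(kappa)) max(kappa) else 0)
}
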