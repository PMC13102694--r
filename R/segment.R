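## Classical instance segmentation of fibers and somata, and QC filters.

otsu_threshold <- function(v, nbins = 256L) {
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- as.numeric(tabulate(findInterval(v, breaks, all.inside = TRUE),
                                nbins))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  tot <- w[length(w)]
  mtot <- m[length(m)]
  between <- (mtot * w - m * tot)^2 / (w * (tot - w))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Marker-based watershed split of touching instances. Markers are the
# connected components of the region where the distance transform exceeds
# `marker_frac` of its per-component maximum: robust to the distance-ridge
# plateaus of elongated or flattened objects, while overlapping near-convex
# bodies (whose neck distance falls below the threshold) still separate.
watershed_split <- function(mask, spacing, marker_frac = 0.5) {
  dims <- dim(mask)
  comp <- cpp_label(as.logical(mask), dims)
  edt <- cpp_edt(as.logical(mask), dims, spacing)
  ncomp <- max(comp)
  if (ncomp == 0) return(comp)
  maxed <- vapply(seq_len(ncomp), function(l) max(edt[comp == l]), 1)
  marker_mask <- edt > marker_frac * maxed[pmax(comp, 1L)] & comp > 0
  markers <- cpp_label(as.logical(marker_mask), dims)
  if (max(markers) <= ncomp) return(comp)
  cpp_watershed(-edt, as.logical(mask), markers, dims)
}

relabel_components <- function(lab, min_voxels) {
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab >= min_voxels)
  map <- integer(length(tab))
  map[keep] <- seq_along(keep)
  out <- array(0L, dim(lab))
  nz <- lab > 0
  out[nz] <- map[lab[nz]]
  out
}

#' Segment fibers from a structural-monomer channel
#'
#' Adaptive local-mean thresholding (Gaussian local mean with a physical
#' block size, plus `k_sigma` robust background standard deviations),
#' 26-connected component labelling, optional marker-based watershed
#' splitting at distance-transform maxima, and removal of components below
#' `min_voxels`.
#'
#' @param channel 3D numeric array (the structural channel).
#' @param spacing voxel spacing `(dz, dy, dx)` um.
#' @param block_size local-mean window (um).
#' @param k_sigma detection threshold offset in background-noise sd units.
#' @param k_weak extent (hysteresis) threshold: voxels above
#'   `local mean + k_weak * sd` join the mask when within `grow_um` of a
#'   detection-threshold voxel.
#' @param grow_um maximum hysteresis growth distance (um).
#' @param min_voxels minimum component size.
#' @param watershed split touching fibers by a distance-transform
#'   marker-based watershed.
#' @param marker_frac watershed marker threshold (fraction of the
#'   per-component distance maximum).
#' @return A [label_volume()] of kind `"fiber"` (empty if the volume is all
#'   background).
#' @export
segment_fibers <- function(channel, spacing, block_size = 4, k_sigma = 3,
                           k_weak = 1.5, grow_um = 0.5, min_voxels = 30L,
                           watershed = FALSE, marker_frac = 0.5) {
  dims <- dim(channel)
  stopifnot(length(dims) == 3L)
  sigma_bg <- mad(channel)
  local_mean <- cpp_box_mean(channel, dims,
                             as.integer(ceiling((block_size / 2) / spacing)))
  strong <- channel > local_mean + k_sigma * sigma_bg
  if (!any(strong))
    return(label_volume(array(0L, dims), spacing, "fiber"))
  # bounded hysteresis: weak-threshold voxels within `grow_um` of a strong
  # voxel join the mask, recovering the dim tube shell without letting
  # noise clusters percolate
  mask <- strong
  if (k_weak < k_sigma) {
    weak <- channel > local_mean + k_weak * sigma_bg
    dist_to_strong <- cpp_edt(as.logical(!strong), dims, spacing)
    mask <- strong | (weak & dist_to_strong <= grow_um)
  }
  lab <- if (watershed) {
    watershed_split(mask, spacing, marker_frac)
  } else {
    cpp_label(as.logical(mask), dims)
  }
  lab <- relabel_components(lab, min_voxels)
  label_volume(lab, spacing, "fiber")
}

# fill background cavities: background components not touching the border
fill_holes <- function(mask) {
  dims <- dim(mask)
  bg <- cpp_label(as.logical(!mask), dims)
  border_labels <- unique(c(bg[1, , ], bg[dims[1], , ], bg[, 1, ],
                            bg[, dims[2], ], bg[, , 1], bg[, , dims[3]]))
  border_labels <- border_labels[border_labels > 0]
  mask | (bg > 0 & !(bg %in% border_labels))
}

#' Segment somata from a Nissl channel
#'
#' Global (Otsu) or offset thresholding of the blurred Nissl channel,
#' 3D hole filling, and a distance-transform watershed to split touching
#' somata.
#'
#' @param channel 3D numeric array (Nissl channel).
#' @param spacing voxel spacing um.
#' @param threshold `"otsu"` or a numeric absolute threshold.
#' @param min_voxels minimum soma size in voxels.
#' @param marker_frac watershed marker threshold (fraction of the
#'   per-component distance maximum).
#' @param presmooth Gaussian presmoothing sigma (um).
#' @return A [label_volume()] of kind `"soma"`.
#' @export
segment_somata <- function(channel, spacing, threshold = "otsu",
                           min_voxels = 500L, marker_frac = 0.5,
                           presmooth = 0.5) {
  dims <- dim(channel)
  stopifnot(length(dims) == 3L)
  sm <- if (presmooth > 0)
    cpp_gauss_blur(channel, dims, presmooth / spacing) else channel
  thr <- if (identical(threshold, "otsu")) otsu_threshold(sm) else threshold
  mask <- sm > thr
  if (!any(mask))
    return(label_volume(array(0L, dims), spacing, "soma"))
  mask <- fill_holes(mask)
  lab <- watershed_split(mask, spacing, marker_frac)
  lab <- relabel_components(lab, min_voxels)
  label_volume(lab, spacing, "soma")
}

# fraction of centerline points falling in each soma label; returns the
# majority label (0 if background holds the majority or on a tie)
soma_majority <- function(cl, soma_labels) {
  idx <- round(sweep(cl$points, 2, soma_labels$spacing, "/")) + 1
  dims <- dim(soma_labels$labels)
  idx[, 1] <- pmin(pmax(idx[, 1], 1), dims[1])
  idx[, 2] <- pmin(pmax(idx[, 2], 1), dims[2])
  idx[, 3] <- pmin(pmax(idx[, 3], 1), dims[3])
  labs <- soma_labels$labels[cbind(idx[, 1], idx[, 2], idx[, 3])]
  tab <- table(labs)
  top <- names(tab)[which.max(tab)]
  n <- length(labs)
  best <- as.integer(top)
  if (best == 0L) return(0L)
  if (tab[[top]] <= n / 2) return(0L)   # strict majority required
  best
}

#' Quality-control filter for segmented fibers
#'
#' A fiber survives when (i) its geodesic length is at least `min_length`
#' (default 8 um), (ii) the explained variance of the first principal
#' component of its skeleton is at least `min_ev` (default 0.8), and
#' (iii) the majority of its centerline points lie inside a segmented soma.
#'
#' @param skeletons named list of [centerline()] objects, one per fiber
#'   label (names are the label ids).
#' @param soma_labels a [label_volume()] of kind `"soma"`, or `NULL` to
#'   skip the containment criterion.
#' @param min_length minimum geodesic length (um).
#' @param min_ev minimum PC1 explained variance.
#' @return list with `report` (data.frame: label, geodesic_length, pc1_ev,
#'   inside_soma, soma_label, passed, failure_reasons) and `survivors`
#'   (character vector of surviving labels).
#' @export
qc_filter <- function(skeletons, soma_labels = NULL, min_length = 8,
                      min_ev = 0.8) {
  if (length(skeletons) == 0)
    return(list(report = data.frame(label = character(),
                                    geodesic_length = numeric(),
                                    pc1_ev = numeric(),
                                    inside_soma = logical(),
                                    soma_label = integer(),
                                    passed = logical(),
                                    failure_reasons = character()),
                survivors = character()))
  if (is.null(names(skeletons)))
    names(skeletons) <- as.character(seq_along(skeletons))
  rows <- lapply(names(skeletons), function(nm) {
    cl <- skeletons[[nm]]
    if (is.null(cl)) stop("missing skeleton for fiber label ", nm)
    len <- geodesic_length(cl)
    ev <- pc1_explained_variance(cl$points)
    soma <- if (is.null(soma_labels)) NA_integer_ else
      soma_majority(cl, soma_labels)
    inside <- if (is.null(soma_labels)) TRUE else soma > 0L
    reasons <- character()
    if (len < min_length) reasons <- c(reasons, "geodesic_length")
    if (ev < min_ev) reasons <- c(reasons, "pc1_explained_variance")
    if (!inside) reasons <- c(reasons, "outside_soma")
    data.frame(label = nm, geodesic_length = len, pc1_ev = ev,
               inside_soma = inside, soma_label = soma,
               passed = length(reasons) == 0L,
               failure_reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(report = report, survivors = report$label[report$passed])
}
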