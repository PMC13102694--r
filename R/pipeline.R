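## Run configuration and end-to-end pipeline orchestration:
## segment -> skeletonize -> QC -> profile -> split -> decode -> analyze.

# deterministic polynomial rolling hash of a deparsed object, for output
# provenance
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline run configuration
#'
#' Collects channel mapping, experiment timing and all stage parameters.
#' The analysis mode fixes defaults: cultured-cell mode searches the split
#' within a window spanning 20% of the fiber length and fits a quadratic
#' transfer (for 3+ anchors); in vivo mode searches within 5% and connects
#' anchors piecewise-linearly. Two anchors always yield a linear transfer.
#'
#' @param structural,nissl structural-monomer / Nissl channel names.
#' @param dyes ordered timestamp channel names (first dye first; in
#'   `dox_pulse` mode the single Dox-dependent channel).
#' @param signals signal (epitope) channel names.
#' @param schedule_times wall-clock event times (days): dye-switch times,
#'   or `c(rise, decay)` for a Dox pulse.
#' @param fixation fixation time (days).
#' @param mode `"cultured"` or `"in_vivo"`.
#' @param timestamp_mode `"dye_switch"` or `"dox_pulse"` (default by mode).
#' @param ref_channel split-search reference channel (default: last dye).
#' @param window_frac split-search window fraction (default by mode).
#' @param transfer_model transfer family for 3+ anchors (default by mode).
#' @param baseline_frac baseline window radius (fraction of length).
#' @param min_length,min_ev QC thresholds (um, fraction).
#' @param n_points centerline sampling points.
#' @param cap_frac maximum centerline extrapolation per end.
#' @param dt output time-series step (days); default `fixation / 500`.
#' @param seed integer seed for any stochastic stage.
#' @param sampling intensity sampling along the centerline: `"trilinear"`
#'   (point interpolation) or `"cylindrical"` (disc-averaged at
#'   `sampling_step` um intervals; lower profile noise).
#' @param sampling_radius,sampling_step cylinder radius and interval (um).
#' @param structural_norm divide background-subtracted signal channels by
#'   the background-subtracted structural channel before baseline
#'   normalization, cancelling position-dependent rendering efficiency.
#' @param segmentation,soma_segmentation parameter lists forwarded to
#'   [segment_fibers()] / [segment_somata()].
#' @return A `run_config` list.
#' @export
run_config <- function(structural = "structural", dyes = c("dye1", "dye2"),
                       signals = "fos", nissl = "nissl",
                       schedule_times = 2, fixation = 4,
                       mode = c("cultured", "in_vivo"),
                       timestamp_mode = NULL, ref_channel = NULL,
                       window_frac = NULL, transfer_model = NULL,
                       baseline_frac = 0.05, min_length = 8, min_ev = 0.8,
                       n_points = 1000L, cap_frac = 0.2, dt = NULL,
                       seed = 1L, sampling = c("trilinear", "cylindrical"),
                       sampling_radius = 0.25, sampling_step = 0.06,
                       structural_norm = TRUE,
                       segmentation = list(), soma_segmentation = list()) {
  sampling <- match.arg(sampling)
  mode <- match.arg(mode)
  cfg <- list(
    structural = structural, dyes = dyes, signals = signals, nissl = nissl,
    schedule_times = schedule_times, fixation = fixation, mode = mode,
    timestamp_mode = timestamp_mode %||%
      if (mode == "cultured") "dye_switch" else "dox_pulse",
    ref_channel = ref_channel %||% dyes[length(dyes)],
    window_frac = window_frac %||% if (mode == "cultured") 0.2 else 0.05,
    transfer_model = transfer_model %||%
      if (mode == "cultured") "quadratic" else "piecewise_linear",
    baseline_frac = baseline_frac, min_length = min_length,
    min_ev = min_ev, n_points = as.integer(n_points), cap_frac = cap_frac,
    dt = dt %||% (fixation / 500), seed = as.integer(seed),
    sampling = sampling, sampling_radius = sampling_radius,
    sampling_step = sampling_step, structural_norm = structural_norm,
    segmentation = segmentation, soma_segmentation = soma_segmentation)
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "hash")])
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  args <- yaml::read_yaml(path)
  bad <- setdiff(names(args), names(formals(run_config)))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, args)
}

#' Decode a multi-channel volume into per-cell time series
#'
#' Runs the full readout chain on one volume: fiber and soma instance
#' segmentation, centerline extraction (PCA + smoothing spline, with a
#' geodesic-path fallback for low-straightness masks), terminus
#' extrapolation, quality control (length of at least 8 um, PC1 explained
#' variance of at least 0.8, soma containment), fiber-to-cell assignment with the
#' longest-fiber-per-cell rule, trilinear profiling, optimal split search,
#' baseline normalization, timestamp detection, transfer-function fitting
#' and warping of the signal channels onto the real-time axis. Excluded
#' fibers are logged with reasons; the run is deterministic given the
#' configuration.
#'
#' @param vol an [image_volume()].
#' @param config a [run_config()].
#' @param fiber_labels,soma_labels optional precomputed [label_volume()]s.
#' @return A `tape_run`: QC report, assignments, per-fiber decodings
#'   (`split`, `anchors`, `transfer`, `series$left/right`), labels and log.
#' @export
decode_volume <- function(vol, config, fiber_labels = NULL,
                          soma_labels = NULL) {
  stopifnot(inherits(vol, "image_volume"), inherits(config, "run_config"))
  for (ch in c(config$structural, config$dyes, config$signals, config$nissl))
    if (!ch %in% vol$channels)
      stop("configuration error: channel not in volume: ", ch)
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  sp <- vol$spacing
  if (is.null(fiber_labels)) {
    fiber_labels <- do.call(segment_fibers,
      c(list(channel = get_channel(vol, config$structural), spacing = sp),
        config$segmentation))
  }
  if (is.null(soma_labels)) {
    soma_labels <- do.call(segment_somata,
      c(list(channel = get_channel(vol, config$nissl), spacing = sp),
        config$soma_segmentation))
  }
  note("segmented ", fiber_labels$n, " fiber candidate(s), ",
       soma_labels$n, " soma(ta)")
  struct_ch <- get_channel(vol, config$structural)
  # per-channel background level: fibers and somata occupy a small volume
  # fraction, so the channel median is a robust background estimate
  bg_level <- lapply(vol$data[c(config$structural, config$signals)], median)
  skeletons <- list()
  for (l in seq_len(fiber_labels$n)) {
    mask <- fiber_labels$labels == l
    cl <- tryCatch({
      cl0 <- extract_centerline(mask, sp, "pca_spline",
                                n_points = config$n_points)
      # a PCA-ordered spline of a strongly curved mask interleaves limbs
      # and zigzags, inflating arclength far beyond the projection span;
      # fall back to the geodesic path in that case
      zigzag <- is.finite(cl0$proj_span) &&
        geodesic_length(cl0) > 1.8 * cl0$proj_span
      if (zigzag || pc1_explained_variance(cl0$points) < config$min_ev)
        cl0 <- extract_centerline(mask, sp, "morph_skeleton",
                                  n_points = config$n_points)
      extrapolate_centerline(cl0, struct_ch, sp,
                             cap_frac = config$cap_frac)
    }, error = function(e) {
      note("fiber ", l, ": centerline failed (", conditionMessage(e), ")")
      NULL
    })
    if (!is.null(cl)) skeletons[[as.character(l)]] <- cl
  }
  qc <- qc_filter(skeletons, soma_labels, min_length = config$min_length,
                  min_ev = config$min_ev)
  for (i in seq_len(nrow(qc$report)))
    if (!qc$report$passed[i])
      note("fiber ", qc$report$label[i], ": QC excluded (",
           qc$report$failure_reasons[i], ")")
  survivors <- skeletons[qc$survivors]
  assign <- assign_fibers_to_cells(survivors, soma_labels)
  fibers <- list()
  reps <- assign$representatives
  for (cell in names(reps)) {
    fid <- reps[[cell]]
    cl <- survivors[[fid]]
    res <- tryCatch({
      prof <- if (identical(config$sampling, "cylindrical"))
        sample_cylindrical(vol, cl, radius = config$sampling_radius,
                           step = config$sampling_step)
      else sample_trilinear(vol, cl)
      if (isTRUE(config$structural_norm)) {
        # rendering efficiency (tube-end falloff, off-axis sampling, local
        # blur) multiplies every channel alike; dividing the background-
        # subtracted signal by the background-subtracted structural channel
        # cancels it, leaving the deposited signal fraction
        st <- prof$channels[[config$structural]] - bg_level[[config$structural]]
        floor_st <- pmax(0.2 * median(st), 1e-12)
        for (sg in config$signals)
          prof$channels[[sg]] <-
            pmax(prof$channels[[sg]] - bg_level[[sg]], 0) / pmax(st, floor_st)
      }
      split <- find_split(prof, config$ref_channel,
                          window_frac = config$window_frac)
      norm <- normalize_baseline(prof, split,
                                 window_frac = config$baseline_frac)
      halves_raw <- split_profile(prof, split)
      halves_norm <- split_profile(norm, split)
      out <- list(cell = as.integer(cell), fiber = fid, split = split,
                  centerline = cl, halves = list())
      for (h in c("left", "right")) {
        anch <- detect_timestamps(halves_raw[[h]], config$dyes,
                                  config$schedule_times, config$fixation,
                                  mode = config$timestamp_mode)
        if (!isTRUE(anch$detected)) {
          note("cell ", cell, " fiber ", fid, " ", h,
               ": timestamp detection failed (", anch$reason, ")")
          next
        }
        model <- if (nrow(anch$anchors) == 2) "linear" else
          config$transfer_model
        tf <- fit_transfer(anch, model)
        ts <- warp_to_time(halves_norm[[h]], tf, dt = config$dt,
                           channels = config$signals)
        out$halves[[h]] <- list(anchors = anch, transfer = tf, series = ts)
      }
      if (!length(out$halves)) NULL else out
    }, error = function(e) {
      note("cell ", cell, " fiber ", fid, ": decoding failed (",
           conditionMessage(e), ")")
      NULL
    })
    if (!is.null(res)) fibers[[fid]] <- res
  }
  structure(list(fiber_labels = fiber_labels, soma_labels = soma_labels,
                 skeletons = skeletons, qc = qc, assignments = assign,
                 fibers = fibers, config = config, log = log),
            class = "tape_run")
}

#' @export
print.tape_run <- function(x, ...) {
  cat("tape_run:", x$fiber_labels$n, "fiber candidate(s),",
      length(x$qc$survivors), "passing QC,",
      length(x$fibers), "decoded cell(s)\n")
  invisible(x)
}

#' Long-format table of the decoded time series of a run
#' @param run a `tape_run`.
#' @return data.frame: cell_id, fiber_id, half, time_days, channel,
#'   rel_change, extrapolated, config_hash.
#' @export
time_series_table <- function(run) {
  rows <- list()
  for (f in run$fibers)
    for (h in names(f$halves)) {
      ts <- f$halves[[h]]$series
      for (ch in names(ts$channels))
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = f$cell, fiber_id = f$fiber, half = h,
          time_days = ts$time, channel = ch,
          rel_change = ts$channels[[ch]],
          extrapolated = ts$extrapolated,
          config_hash = run$config$hash)
    }
  if (!length(rows))
    return(data.frame(cell_id = integer(), fiber_id = character(),
                      half = character(), time_days = numeric(),
                      channel = character(), rel_change = numeric(),
                      extrapolated = logical(), config_hash = character()))
  do.call(rbind, rows)
}

#' Run the full pipeline on a volume file and write result tables
#'
#' @param input path to a volume readable by [read_volume()].
#' @param config a [run_config()] (or YAML path).
#' @param out output directory.
#' @return the `tape_run`, invisibly.
#' @export
run_pipeline <- function(input, config, out) {
  if (is.character(config)) config <- read_run_config(config)
  vol <- read_volume(input)
  run <- decode_volume(vol, config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  tab <- time_series_table(run)
  write.csv(tab, file.path(out, "time_series.csv"), row.names = FALSE)
  qc <- run$qc$report
  if (nrow(qc)) qc$config_hash <- run$config$hash
  write.csv(qc, file.path(out, "qc_report.csv"), row.names = FALSE)
  write.csv(run$assignments$assignments,
            file.path(out, "assignments.csv"), row.names = FALSE)
  transfers <- lapply(run$fibers, function(f)
    lapply(f$halves, function(h) list(
      model = h$transfer$model,
      coefficients = h$transfer$coefficients,
      anchors = h$anchors$anchors)))
  jsonlite::write_json(transfers, file.path(out, "transfers.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(run$log, file.path(out, "log.txt"))
  invisible(run)
}
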