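---
title: "Decoding time from protein tape recordings: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding time from protein tape recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The recording principle

An intracellular protein tape is a thread-like self-assembly that elongates
from a central nucleation point symmetrically in both directions. Monomers
are deposited only at the growing tips, so position along the fiber encodes
deposition time, twice over: each half-fiber is an independent copy of the
same record. Three kinds of monomer write onto this spatial tape:

* a **structural** monomer, expressed constitutively, forms the backbone and
  provides a constant reference density;
* **timestamp** monomers carry a self-labeling tag; switching the applied
  dye (or pulsing a doxycycline-inducible monomer in vivo) writes a
  transition at a known wall-clock time;
* **signal** monomers are expressed from activity-dependent promoters; their
  local density reports promoter activity at the time that stretch of fiber
  grew.

Reading the tape back means: find the fibers in a confocal stack, extract
their centerlines, read intensity profiles along them, locate the split
point between the two halves, detect the timestamp transitions, fit a
monotone transfer function from fraction-of-length to real time, and warp
the signal profiles onto that time axis.

`tapetrace` implements this full readout chain, together with a forward
simulator of growth, deposition and imaging, so that every stage can be
validated by parameter recovery against a known ground truth.

## Growth model and transfer functions

Half-fiber arclength follows a power law, `s(t) = a (t - t0)^b` with
`b = 1` (linear elongation) as default and `0 < b < 1` for decelerating
kinetics. The inverse map `t(s)` exists on the recording span, which is what
makes decoding possible at all.

The decoded time axis is anchored at the timestamp positions (expressed as
fraction of half-fiber length, `f`) and at the fiber terminus (`f = 1`,
fixation time). Transfer families:

* **linear** — two anchors (one dye switch plus terminus); exact.
* **quadratic** — three anchors; exact; the cultured-cell default.
* **power** — `t = alpha f^beta + gamma`, fitted by profiling `beta`
  deterministically over (0.05, 10].
* **piecewise linear** — connects anchors exactly, extrapolates each end
  with the terminal segment slope; the in vivo default.
* **monotone spline** — Hyman-filtered cubic through the anchors.

Every fit is checked for monotonicity on a dense grid; a violating fit falls
back to the piecewise-linear interpolant and is flagged. With anchor count
at or below the family's degrees of freedom the fit passes through the
anchors to machine precision, which the test suite asserts at 1e-9.

## Timestamp detection

The package replaces manual critical-point picking with deterministic
changepoint estimators built on exact interval least squares (prefix sums,
discontinuous segments):

* **Dye switches.** The detection signal for switch *k* is the *normalized
  difference* of the later and earlier dye channel,
  `(d2 - d1) / max(d2 + d1, floor)`. It crosses zero at the switch, is
  invariant to brightness variation along the fiber, and is unaffected by
  later dyes. A two-segment **mean-shift** changepoint locates the
  transition midpoint. The mean-shift (piecewise-constant) model was chosen
  over sloped segments deliberately: on a PSF-blurred transition a sloped
  two-segment fit latches onto the *top* of the ramp, whereas the mean-shift
  breakpoint sits at the transition midpoint, which for a symmetric blur is
  the true switch position.
* **Dox (Tet-On) pulses.** The in vivo timestamp channel rises while Dox is
  present and decays after withdrawal; the rise onset and decay onset are
  slope changes. A three-segment piecewise-linear changepoint finds them,
  followed by a local two-segment refinement in a short window around each
  knot — within the window the exponential phases are nearly straight, which
  removes the curvature bias of the global linear segments (this is what
  brings noise-free onset errors below 1% of fiber length).

Detection failure (SSE improvement over a single line below `min_gain`, or
a non-rising "rise") flags the half-fiber and it is excluded downstream,
never silently decoded.

## Split search and normalization

The split point maximizes the Pearson correlation between the two halves of
the profile over a window centered on the geometric midpoint (a window
spanning 20% of the length in cultured-cell mode, 5% in vivo). One detail
matters: the halves are compared on a common **absolute** outward-arclength
grid truncated to the shorter half, not on per-half fractional grids.
Bidirectional growth copies the record symmetrically in micrometres, so the
absolute comparison stays sharp even when one terminus is imperfectly
recovered; fractional comparison smears the optimum in exactly that case.
Several reference channels can be averaged to sharpen the objective.

Baseline normalization follows the split: for each channel the mean within
a 5%-of-length radius around the split is the baseline `B`, and the profile
becomes `(I - B)/B`. Before that, the pipeline optionally (and by default)
divides background-subtracted signal channels by the background-subtracted
structural channel. The structural monomer is deposited uniformly, so this
ratio cancels position-dependent rendering efficiency — tube-end falloff,
off-axis sampling error, local blur — which baseline normalization alone
cannot. Background per channel is estimated as the volume median (fibers
and somata occupy a tiny volume fraction).

## Segmentation, skeletonization and QC

* **Fibers**: adaptive local-mean threshold (box mean over a 4 um window
  plus `k_sigma = 3` robust background standard deviations) with *bounded
  hysteresis* — voxels above 1.5 sigma join the mask when within 0.5 um of
  a detection voxel. The hysteresis recovers the dim tube shell without
  letting noise percolate. Components below 30 voxels are dropped; an
  optional marker-based watershed splits touching fibers.
* **Somata**: Otsu threshold of the smoothed Nissl channel, 3D hole
  filling, then a watershed whose markers are connected components of the
  region where the distance transform exceeds half its per-component
  maximum. Point-maxima markers were rejected: the distance ridge of a
  flattened or elongated soma is a plateau that fragments into many maxima,
  while the threshold-region markers stay connected yet still separate
  overlapping near-convex somata whose neck distance dips below the
  threshold.
* **Centerlines**: the primary extractor projects mask voxels on the first
  principal axis, trims to the central 80%, bin-averages the cloud along
  the projection (half a voxel diagonal per bin) and fits coordinate-wise
  smoothing splines whose flexibility is capped at about one degree of
  freedom per 1.5 um; the curve is resampled at 1,000 equidistant points.
  The fallback for low-straightness masks is the longest geodesic path
  through the 26-connected voxel graph (with anisotropic edge lengths),
  smoothed and trimmed by the same 80% convention. The fallback triggers
  when the skeleton's PC1 explained variance is below 0.8 or when the
  spline's arclength exceeds 1.8 times the projection span, which is the
  signature of interleaved projections on strongly folded masks.
* **Terminus extrapolation**: each end is extended along its osculating
  circle (not the straight tangent — a curved end leaves a straight probe
  within about a micrometre), sampling the structural channel. The probe
  reaches twice the 20% cap so the tip transition has background context;
  the stop position is the mean-shift changepoint of the smoothed extension
  profile, i.e. the midpoint of the falling edge, which for a symmetric PSF
  is the tip. A profile with no material drop extends to the cap and is
  flagged. The accepted extension never exceeds 20% of the geodesic length
  per end.
* **QC**: geodesic length >= 8 um, skeleton PC1 explained variance >= 0.8,
  and strict-majority soma containment of the centerline points. Raising
  either threshold can only remove survivors (tested as a property).

## The forward simulator

The simulator is a first-class module; its defaults state the world used by
the recovery studies and are not tuned per experiment:

* **Recording**: 4-day cultured-cell recordings (6-day for the two-pulse
  study), nucleation at day 0, one dye switch at day 2 (days 1 and 3 for
  two-pulse), fixation at the end.
* **Rates**: per-cell elongation rates lognormal with 20% coefficient of
  variation around 1.6 um/day per half-fiber (1.07 um/day for the 6-day
  study, keeping fiber length inside the field of view).
* **Geometry**: adherent cultured cells are flat, so fibers are generated
  as guided planar random walks with a gentle axial undulation, confined to
  an oblate soma (radius 7.5 um, z-flattening 0.4). Because the maximal
  turn radius (1/max_curvature = 5 um) is comparable to the cell radius,
  confinement cannot be improvised step by step; the walk plans a base
  chord or minimal-curvature arc globally and adds bounded heading wander,
  each drawing a fixed share of the curvature budget. Discrete curvature
  never exceeds the bound and the arclength error stays below 1%.
* **Deposition**: dye indicators are smoothed along arclength with a 0.3 um
  Gaussian (finite labeling kinetics); promoter pulses are bi-exponential
  with rise/decay constants 0.2/0.45 days — deliberately broader than the
  transcriptional burst itself, because the deposited profile reflects
  promoter activity convolved with monomer synthesis and incorporation;
  the Dox timestamp accumulates and decays with 3-day time constants, which
  matches rise-over-days profiles and keeps the ON/OFF phases quasi-linear.
* **Imaging**: voxels (0.4, 0.13, 0.13) um (0.4 um per z-step), Gaussian
  PSF sigma (0.6, 0.15, 0.15) um, tube painted with a Gaussian cross
  section of sigma 0.6 x radius so deposition mass stays on the axis,
  Poisson shot noise plus Gaussian read noise. Deposition levels are
  calibrated by rendering a unit probe tube, so "SNR 5" means the noise-free
  peak tube intensity sits five background noise standard deviations above
  background — exactly, for the configured PSF and spacing.

What the generator does **not** emulate: fiber-fiber steric interactions,
photobleaching, depth-dependent aberrations, non-Gaussian PSF tails,
chromatic shifts between channels, and segmentation clutter from
neighbouring cells. A green recovery test therefore establishes that the
readout chain is correct and robust to shot/read noise and to the geometric
variability the generator produces — not that it would survive every
artifact of real tissue.

## Estimators used in the recovery studies

The recovered time of a known promoter pulse is estimated by fitting the
characterized pulse template (free shift, amplitude, width, offset) to the
decoded waveform. The template's width absorbs the symmetric arclength
smear of the imaging model, so the location estimate is unbiased where a
plain argmax of the smeared waveform is systematically late — the smear
pushes the mode toward the pulse's decay tail. When two pulses must be
resolved, peaks are picked from the half-averaged series after smoothing at
half the pulse FWHM, with maxima closer than one FWHM merged: features
below the FWHM scale are not resolvable pulses. Averaging the two decoded
halves before feature extraction halves the noise variance; the halves are
duplicate copies of one record, so this loses nothing.

## Numerical choices

* Disc sampling for cylindrical profiles uses a 19-point concentric-ring
  quadrature (center + 6 + 12 points) with area weights and rings at
  annulus-centroid radii; it integrates smooth fields to well under 1%,
  where the naive equal-weight lattice is biased by several percent.
* Changepoint searches are exact at profile resolution (prefix-sum interval
  SSE); the two-changepoint search decimates to ~150 candidates per break
  and refines locally at full resolution.
* Distance transforms and geodesic paths use physical voxel spacing, never
  voxel counts; all lengths are micrometres, all times days.
* Curvature is measured by the three-point circumradius on a centerline
  smoothed with a 1 um moving average and resampled at a quarter of that
  window; this keeps voxel noise from exploding the estimate while biasing
  a 0.2 um^-1 arc by less than 0.2%.
* The time-series step defaults to recording duration / 500.
* All randomness (geometry, noise, rate draws) flows from a single integer
  seed; reruns are bit-identical.

## Known limitations

* Branched fibers are not modelled; the geodesic fallback returns the
  longest path and flags the geometry.
* The PCA-projection extractor assumes the projection is monotone along the
  fiber, which holds for arcs up to a half-turn; beyond that the geodesic
  fallback carries the load and slightly undershoots length on strongly
  curved tubes.
* The minimal TIFF reader handles the files the package writes (baseline,
  uncompressed, little-endian, 8/16-bit unsigned or 32-bit float) — not the
  full TIFF zoo; compressed or big-endian stacks must be converted first.
* In vivo mode is exercised at record level and on noise-free renders; a
  full tissue-clutter simulation (many touching cells, partial fibers) is
  out of scope.

## A worked example

```{r}
library(tapetrace)

pulse <- promoter_waveform(baseline = 0.5, amplitude = 1.5,
                           stim_time = 2.5, tau_rise = 0.2,
                           tau_decay = 0.45)
sim <- simulate_tape_cell(a = 1.6, signal_waveforms = list(fos = pulse),
                          seed = 7)
cfg <- run_config(schedule_times = 2, fixation = 4, signals = "fos",
                  sampling = "cylindrical")
run <- decode_volume(sim$volume, cfg)
run$qc$report
recover_pulse_time(average_halves(run$fibers[[1]]), "fos", pulse)
```
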