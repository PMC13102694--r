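test_that("fiber segmentation finds rendered fibers and nothing in noise", {
  cfg <- render_config(seed = 3)
  sp <- cfg$voxel_spacing

  # pure-noise volume: no instances above the size filter
  set.seed(9)
  noise_vol <- array(cfg$background +
                       rnorm(32 * 48 * 48, sd = background_noise_sd(cfg)),
                     c(32, 48, 48))
  lab0 <- segment_fibers(noise_vol, sp)
  expect_equal(lab0$n, 0L)

  # one rendered fiber at SNR 5: one instance covering >= 90% of the
  # ground-truth tube, rasterized at the rendered tube's half-maximum
  # cross-section (Gaussian paint of sigma 0.6 * radius, convolved with
  # the anisotropic PSF)
  rec <- standard_record(a = 1.6, config = cfg, snr = 5)
  r <- render_straight_fiber(rec, cfg, noise = TRUE)
  lab <- segment_fibers(r$volume$data$structural, sp)
  expect_equal(lab$n, 1L)
  gt <- r$ground_truth$fibers[[1]]
  dims <- dim(lab$labels)
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  pos <- sweep(idx - 1, 2, sp, "*")
  # distance to the axis-aligned ground-truth segment
  zc <- gt$polyline[1, 1]; yc <- gt$polyline[1, 2]
  x0 <- min(gt$polyline[, 3]); x1 <- max(gt$polyline[, 3])
  sig_z <- sqrt((0.6 * cfg$fiber_radius)^2 + cfg$psf_sigma[1]^2)
  sig_y <- sqrt((0.6 * cfg$fiber_radius)^2 + cfg$psf_sigma[2]^2)
  mah2 <- (pos[, 1] - zc)^2 / sig_z^2 + (pos[, 2] - yc)^2 / sig_y^2
  tube <- mah2 <= 2 * log(2) & pos[, 3] >= x0 & pos[, 3] <= x1
  covered <- mean(lab$labels[idx[tube, , drop = FALSE]] == 1L)
  expect_gte(covered, 0.9)

  # two parallel fibers separated by >= 4 psf sigma resolve into two labels
  sep <- 4 * max(cfg$psf_sigma)
  shape <- c(40L, 64L, 120L)
  extent <- (shape - 1) * sp
  n <- 150
  mk_poly <- function(yoff) cbind(rep(extent[1] / 2, n),
                                  rep(extent[2] / 2 + yoff, n),
                                  seq(3, extent[3] - 3, length.out = n))
  rr <- render_volume(list(list(record = rec, polyline = mk_poly(-sep / 2)),
                           list(record = rec, polyline = mk_poly(sep / 2))),
                      config = cfg, shape = shape, noise = TRUE)
  lab2 <- segment_fibers(rr$volume$data$structural, sp)
  expect_equal(lab2$n, 2L)
})

test_that("label conservation: every mask voxel gets exactly one label", {
  cfg <- render_config(seed = 5)
  sp <- cfg$voxel_spacing
  rec <- standard_record(a = 1.3, config = cfg)
  r <- render_straight_fiber(rec, cfg, noise = TRUE)
  v <- r$volume$data$structural
  sigma_bg <- mad(v)
  # reproduce the threshold mask and check the watershed covers it fully
  lab <- segment_fibers(v, sp, watershed = TRUE, min_voxels = 1L)
  labs_on_mask <- lab$labels[lab$labels > 0 | TRUE]
  mask_recount <- sum(lab$labels > 0)
  expect_gt(mask_recount, 0)
  # relabeled output has contiguous ids 1..n
  expect_setequal(sort(unique(as.integer(lab$labels[lab$labels > 0]))),
                  seq_len(lab$n))
})

test_that("soma segmentation splits touching somata and fills holes", {
  sp <- c(0.4, 0.25, 0.25)
  mk_spheres <- function(centers, radius, dims) {
    zg <- (seq_len(dims[1]) - 1) * sp[1]
    yg <- (seq_len(dims[2]) - 1) * sp[2]
    xg <- (seq_len(dims[3]) - 1) * sp[3]
    vol <- array(0, dims)
    for (ctr in centers) {
      d2 <- outer(outer((zg - ctr[1])^2, (yg - ctr[2])^2, "+"),
                  (xg - ctr[3])^2, "+")
      vol <- vol + 40 * (d2 <= radius^2)
    }
    vol + 5
  }
  dims <- c(48L, 80L, 120L)

  # disjoint spheres
  v1 <- mk_spheres(list(c(9, 9, 9), c(9, 9, 22)), 4, dims)
  s1 <- segment_somata(v1, sp, presmooth = 0)
  expect_equal(s1$n, 2L)

  # spheres overlapping by 20% of the radius split by the watershed
  gap <- 2 * 4 - 0.2 * 4
  v2 <- mk_spheres(list(c(9, 9, 9), c(9, 9, 9 + gap)), 4, dims)
  s2 <- segment_somata(v2, sp, presmooth = 0)
  expect_equal(s2$n, 2L)

  # empty volume
  s0 <- segment_somata(array(5, c(16, 24, 24)), sp, presmooth = 0)
  expect_equal(s0$n, 0L)
})

test_that("PC1 explained variance matches eigen-decomposition oracles", {
  # collinear points
  line <- cbind(seq(0, 10, length.out = 50), seq(0, 5, length.out = 50),
                seq(0, -2, length.out = 50))
  expect_equal(pc1_explained_variance(line), 1.0)

  # isotropic 3D cloud -> ~1/3
  set.seed(123)
  cloud <- matrix(rnorm(3e5), ncol = 3)
  expect_equal(pc1_explained_variance(cloud), 1 / 3, tolerance = 0.01)

  # planar isotropic cloud -> ~1/2
  planar <- cbind(rnorm(1e5), rnorm(1e5), 0)
  expect_equal(pc1_explained_variance(planar), 1 / 2, tolerance = 0.02)

  expect_error(pc1_explained_variance(line[1:2, ]), "undefined")
  expect_error(pc1_explained_variance(matrix(1, 5, 3)), "undefined")
})

test_that("QC filter applies length, straightness and containment rules", {
  sp <- c(0.4, 0.13, 0.13)
  straight_cl <- function(len) {
    centerline(cbind(2, 2, seq(1, 1 + len, length.out = 200)),
               method = "manual")
  }
  soma <- label_volume(array(1L, c(12, 40, 120)), sp, "soma")

  qc <- qc_filter(list(a = straight_cl(7.9), b = straight_cl(8.1)),
                  soma, min_length = 8)
  expect_equal(sum(qc$report$passed), 1L)
  expect_equal(qc$survivors, "b")
  expect_match(qc$report$failure_reasons[qc$report$label == "a"],
               "geodesic_length")

  # a wiggly low-EV skeleton fails with the straightness reason
  th <- seq(0, 6 * pi, length.out = 300)
  wig <- centerline(cbind(2, 2 + 2.5 * sin(th), 1 + th / (6 * pi) * 10),
                    method = "manual")
  ev <- pc1_explained_variance(wig$points)
  expect_lt(ev, 0.8)
  qc2 <- qc_filter(list(w = wig), soma)
  expect_false(qc2$report$passed)
  expect_match(qc2$report$failure_reasons, "pc1_explained_variance")

  # a fiber outside every soma is excluded
  soma0 <- label_volume(array(0L, c(12, 40, 120)), sp, "soma")
  qc3 <- qc_filter(list(b = straight_cl(10)), soma0)
  expect_match(qc3$report$failure_reasons, "outside_soma")

  # monotonicity: raising thresholds never adds survivors
  cls <- list(a = straight_cl(7.9), b = straight_cl(8.1),
              c = straight_cl(12), w = wig)
  base <- qc_filter(cls, soma, min_length = 8, min_ev = 0.8)$survivors
  for (ml in c(9, 11)) for (me in c(0.85, 0.95)) {
    harder <- qc_filter(cls, soma, min_length = ml, min_ev = me)$survivors
    expect_true(all(harder %in% base))
  }

  expect_error(qc_filter(list(a = NULL), soma), "missing skeleton")
})
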