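# 3D feature extraction and population statistics.

test_that("segmentation labels well-separated objects and filters specks", {
  flow <- flow_config(core_width = 20)
  a <- lfcyto:::new_phantom_object(
    "bead", c(-3, 0, 0),
    list(lfcyto:::component("bead", "sphere", 1L, 1, d = 2)), list())
  b <- lfcyto:::new_phantom_object(
    "bead", c(3, 1, 0.4),
    list(lfcyto:::component("bead", "sphere", 1L, 1, d = 1)), list())
  vol <- voxelize(a, 0.2, c(61, 61, 11))[[1]] +
    voxelize(b, 0.2, c(61, 61, 11))[[1]]
  vol[2, 2, 2] <- 2   # single-voxel speck
  seg <- segment_objects(vol, method = "fraction", fraction = 0.4,
                         voxel = c(0.2, 0.2, 0.2))
  expect_identical(nrow(seg$records), 2L)   # speck removed by size filter
  rec <- seg$records[order(seg$records$volume_um3, decreasing = TRUE), ]
  expect_equal(rec$volume_um3[1], pi / 6 * 8, tolerance = 0.15)
  expect_equal(rec$centroid_x_um, c(-3, 3), tolerance = 0.1)
  # empty volume: empty record set
  seg0 <- segment_objects(array(0, c(8, 8, 3)))
  expect_identical(nrow(seg0$records), 0L)
})

test_that("point pairs at sub-micron spacing are resolved after RL", {
  psf <- test_psf_small()
  d <- dim(psf); iz0 <- which(attr(psf, "z") == 0)
  vol <- array(0, d)
  # two points 4 px apart laterally (~0.6 um): segmented as two objects
  vol[49, 46, iz0] <- 100
  vol[49, 50, iz0] <- 100
  y <- lfcyto:::lf_forward(vol, psf)
  rv <- richardson_lucy_3d(y, psf, 30)
  seg <- segment_objects(rv, method = "fraction", fraction = 0.3,
                         min_size = 1)
  expect_identical(nrow(seg$records), 2L)
  # at 3 px (~0.46 um) the profile still dips well below half maximum
  v2 <- array(0, d)
  v2[49, 47, iz0] <- 100
  v2[49, 50, iz0] <- 100
  rv2 <- richardson_lucy_3d(lfcyto:::lf_forward(v2, psf), psf, 30)
  prof <- rv2[49, , iz0]
  expect_lt(min(prof[47:50]) / max(prof), 0.5)
})

test_that("FWHM measurement matches the Gaussian closed form", {
  # isotropic Gaussian blob, sigma 200 nm on a 50 nm grid
  n <- 41; vx <- 0.05
  ax <- (seq_len(n) - 21) * vx
  g1 <- exp(-ax^2 / (2 * 0.2^2))
  vol <- outer(outer(g1, g1), g1)
  vol <- array(vol, c(n, n, n))
  attr(vol, "voxel") <- c(vx, vx, vx)
  for (axis in c("x", "y", "z")) {
    expect_equal(measure_fwhm(vol, c(21, 21, 21), axis),
                 1000 * 2 * sqrt(2 * log(2)) * 0.2, tolerance = 0.02)
  }
  # invariant to intensity scaling
  expect_identical(measure_fwhm(vol * 7.3, c(21, 21, 21), "x"),
                   measure_fwhm(vol, c(21, 21, 21), "x"))
  # profile that never drops below half max is flagged unbounded
  flat <- array(1, c(9, 9, 3))
  w <- measure_fwhm(flat, c(5, 5, 2), "x")
  expect_true(is.na(w))
  expect_true(attr(w, "unbounded"))
})

test_that("equivalent diameter inverts the sphere volume", {
  expect_equal(equivalent_diameter(4.18879), 2, tolerance = 1e-5)
  expect_equal(equivalent_diameter(pi / 6), 1)
  v <- seq(0.1, 10, length.out = 20)
  expect_true(all(diff(equivalent_diameter(v)) > 0))
  expect_error(equivalent_diameter(0), "positive")
})

test_that("ellipsoid moments recover radii and respect rotations", {
  ball <- ellipsoid_volume(c(2, 2, 2), voxel = 0.1)
  seg <- segment_objects(ball, method = "fraction", fraction = 0.5,
                         voxel = attr(ball, "voxel"))
  r <- fit_ellipsoid(seg$labels, ball, 1, voxel = attr(ball, "voxel"))
  expect_equal(unname(r), c(2, 2, 2), tolerance = 0.03)
  ell <- ellipsoid_volume(c(3, 2, 1), voxel = 0.1)
  segl <- segment_objects(ell, method = "fraction", fraction = 0.5,
                          voxel = attr(ell, "voxel"))
  re <- fit_ellipsoid(segl$labels, ell, 1, voxel = attr(ell, "voxel"))
  expect_equal(unname(re), c(3, 2, 1), tolerance = 0.03)
  expect_true(re[1] >= re[2] && re[2] >= re[3])
  # rotation invariance of the radius set
  rot <- ellipsoid_volume(c(3, 2, 1), voxel = 0.1, angle = pi / 6)
  segr <- segment_objects(rot, method = "fraction", fraction = 0.5,
                          voxel = attr(rot, "voxel"))
  rr <- fit_ellipsoid(segr$labels, rot, 1, voxel = attr(rot, "voxel"))
  expect_equal(unname(rr), unname(re), tolerance = 0.03)
})

test_that("N:C ratio reproduces the printed worked example", {
  cell <- data.frame(volume_um3 = pi / 6 * 7.99^3)
  nuc <- data.frame(volume_um3 = pi / 6 * 6.57^3)
  r <- nc_ratio(cell, nuc)
  expect_equal(r, (6.57 / 7.99)^3, tolerance = 1e-12)
  expect_equal(signif(r, 3), 0.556)
  expect_equal(nc_ratio(cell, cell), 1)
  flagged <- nc_ratio(nuc, cell)
  expect_gt(flagged, 1)
  expect_true(attr(flagged, "flagged"))
})

test_that("micronuclei metrics quantify dispersion", {
  one <- data.frame(volume_um3 = 5, centroid_x_um = 1, centroid_y_um = 2,
                    centroid_z_um = 0)
  m1 <- micronuclei_metrics(one)
  expect_identical(m1$count, 1L)
  expect_identical(m1$mean_centroid_distance_um, 0)
  # two equal components 4 um apart: distance 2 by symmetry
  two <- data.frame(volume_um3 = c(3, 3),
                    centroid_x_um = c(-2, 2), centroid_y_um = 0,
                    centroid_z_um = 0)
  expect_equal(micronuclei_metrics(two)$mean_centroid_distance_um, 2)
  # ground-truth sidecar oracle: segment a fragmented phantom and recover
  # the generator dispersion within a voxel
  frag <- make_cell_phantom("apoptotic",
                            params = list(k_micronuclei = 3, dispersion = 3,
                                          d_cell = 14, d_nuc = 3,
                                          n_mito = 0),
                            seed = 31)
  vol <- voxelize(frag, 0.2, c(81, 81, 41))[["2"]]
  seg <- segment_objects(vol, method = "fraction", fraction = 0.3,
                         voxel = c(0.2, 0.2, 0.2))
  expect_identical(nrow(seg$records), 3L)
  mm <- micronuclei_metrics(seg$records)
  expect_equal(mm$mean_centroid_distance_um,
               frag$truth$micronuclei$mean_centroid_distance,
               tolerance = 0.15)
})

test_that("mitochondrial enclosure matches an analytic-hull oracle", {
  dims <- c(41, 41, 41)
  vx <- c(0.2, 0.2, 0.2)
  micro <- array(0, dims)
  # eight corner voxels: the convex hull is exactly the cube spanned by
  # their centers
  a <- 8   # voxel offset from the center
  for (sx in c(-a, a)) for (sy in c(-a, a)) for (sz in c(-a, a))
    micro[21 + sy, 21 + sx, 21 + sz] <- 1
  set.seed(12)
  mito <- array(0, dims)
  pts <- cbind(sample(5:37, 400, TRUE), sample(5:37, 400, TRUE),
               sample(5:37, 400, TRUE))
  mito[pts] <- 1
  fr <- mito_enclosure_fraction(mito, micro, voxel = vx)
  # brute-force point-in-cube oracle (half-voxel tolerance as in the
  # support-function test)
  idx <- which(mito > 0)
  ai <- arrayInd(idx, dims)
  tol <- sqrt(sum((vx / 2)^2))
  inside <- abs(ai[, 2] - 21) * vx[1] <= a * vx[1] + tol &
    abs(ai[, 1] - 21) * vx[2] <= a * vx[2] + tol &
    abs(ai[, 3] - 21) * vx[3] <= a * vx[3] + tol
  v_enc <- sum(inside) * prod(vx)
  v_all <- (sum(micro) + sum(mito)) * prod(vx)
  expect_equal(fr, v_enc / v_all, tolerance = 0.02)
  # bounds
  far <- array(0, dims); far[3, 3, 3] <- 1
  expect_equal(mito_enclosure_fraction(far, micro, vx), 0)
  inside_only <- array(0, dims); inside_only[21, 21, 21] <- 1
  expect_equal(mito_enclosure_fraction(inside_only, micro, vx),
               1 / (8 + 1))
  none <- array(0, dims)
  fr0 <- mito_enclosure_fraction(mito, none, vx)
  expect_identical(as.numeric(fr0), 0)
  expect_true(!is.null(attr(fr0, "flagged")))
})

test_that("mixture models recover the bead population structure", {
  gen_records <- function(seed) {
    withr::with_seed(seed, {
      d <- rep(c(0.45, 1, 2, 4), each = 12)   # smallest class at the
      # resolution-broadened size
      vol <- pi / 6 * d^3 * rlnorm(length(d), 0, 0.08)
      inten <- 2e6 * pi / 6 * d^3 * rlnorm(length(d), 0, 0.1)
      data.frame(volume_um3 = vol, eq_diameter_um = equivalent_diameter(vol),
                 total_intensity = inten)
    })
  }
  # four-population recovery is stable across seeds
  for (seed in 1:5) {
    pop <- population_count(gen_records(seed))
    expect_identical(pop$n_clusters, 4L)
    ord <- pop$clusters[order(pop$clusters$mean_volume_um3), ]
    expect_equal(ord$mean_diameter_um, c(0.45, 1, 2, 4), tolerance = 0.15)
    expect_identical(sum(pop$clusters$n), 48L)
  }
  # a single class collapses to one cluster
  one <- do.call(rbind, lapply(1:3, function(s) gen_records(s)[1:12, ]))
  expect_identical(population_count(one)$n_clusters, 1L)
})

test_that("Gaussian histogram fits recover cohort diameters", {
  set.seed(6)
  d <- rnorm(300, 7.99, 0.5)
  fit <- gaussian_fit_diameter(d)
  expect_true(fit$converged)
  expect_equal(fit$mean, 7.99, tolerance = 0.02)
  expect_equal(fit$sd, 0.5, tolerance = 0.15)
  # insensitive to the histogram binning within 2%
  alt <- gaussian_fit_diameter(d, breaks = seq(min(d) - 0.1, max(d) + 0.1,
                                               length.out = 40))
  expect_equal(alt$mean, fit$mean, tolerance = 0.02)
  # zero-variance cohort: fallback to the exact sample mean
  z <- gaussian_fit_diameter(rep(5, 20))
  expect_equal(z$mean, 5)
  expect_error(gaussian_fit_diameter(1:5), "at least 10")
})

test_that("reporter gating recovers generated positive fractions", {
  gen <- function(seed, frac = 0.8, n = 200) {
    withr::with_seed(seed, {
      pos <- runif(n) < frac
      data.frame(total_intensity = ifelse(pos, 1e4, 1e3) *
                   rlnorm(n, 0, 0.2))
    })
  }
  for (seed in 1:3) {
    pf <- positive_fraction(gen(seed))
    expect_equal(pf, 80, tolerance = 0.12)  # ~3 binomial SE at n = 200
  }
  # no positives under an explicit threshold
  low <- data.frame(total_intensity = rep(100, 20))
  expect_equal(as.numeric(positive_fraction(low, threshold = 500)), 0)
  # degenerate all-equal intensities are flagged
  dg <- positive_fraction(low)
  expect_true(!is.null(attr(dg, "flagged")))
  # monotonicity: raising the threshold never raises the fraction
  r <- gen(9)
  ths <- quantile(r$total_intensity, c(0.1, 0.3, 0.5, 0.7, 0.9))
  fr <- vapply(ths, function(t) positive_fraction(r, threshold = t),
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("shape features are invariant to global intensity scaling", {
  ball <- ellipsoid_volume(c(1.5, 1.5, 1.5), voxel = 0.15)
  v2 <- ball * 37
  attr(v2, "voxel") <- attr(ball, "voxel")
  s1 <- segment_objects(ball, method = "fraction",
                        voxel = attr(ball, "voxel"))
  s2 <- segment_objects(v2, method = "fraction", voxel = attr(ball, "voxel"))
  expect_equal(s1$records$volume_um3, s2$records$volume_um3)
  expect_equal(s1$records$eq_diameter_um, s2$records$eq_diameter_um)
  # total intensity is linear in the scale
  expect_equal(s2$records$total_intensity, 37 * s1$records$total_intensity)
})
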