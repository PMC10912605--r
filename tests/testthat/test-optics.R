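# Wave-optics train: configuration, pupil, microlens array and PSF stack.

test_that("effective magnification follows the objective/MLA relay", {
  expect_equal(signif(effective_magnification(
    optical_config(m_obj = 100, f_ml = 117, f_fl = 275)), 3), 42.5)
  # unit relay: equal focal lengths leave the objective magnification
  expect_equal(effective_magnification(
    optical_config(m_obj = 100, f_ml = 117, f_fl = 117)), 100)
  # direct-arithmetic oracle at a different objective
  expect_equal(effective_magnification(
    optical_config(m_obj = 10, f_ml = 117, f_fl = 275)),
    10 * 117 / 275, tolerance = 1e-12)
  # the scaled twin preserves the effective magnification
  expect_equal(effective_magnification(test_config()),
               effective_magnification(optical_config()))
})

test_that("configuration invariants are enforced", {
  expect_error(optical_config(na = 1.6), "na < n_imm")
  expect_error(optical_config(f_fl = -1), "positive")
  expect_error(optical_config(z_range = 1, z_step = 0.3), "multiple")
  cfg <- optical_config()
  expect_identical(n_axial_planes(cfg), 101L)
  expect_true(n_axial_planes(cfg) %% 2 == 1)
  expect_identical(n_axial_planes(test_config(z_range = 2, z_step = 0.2)), 21L)
})

test_that("pupil field is a defocus-phase disc", {
  cfg <- test_config()
  u0 <- pupil_field(cfg, z = 0, channel = 3)
  m <- Mod(u0) > 0
  # support confined to na/lambda and constant phase in focus
  expect_true(all(Arg(u0[m]) == 0))
  rho_step <- attr(u0, "rho_step")
  nf <- nrow(u0)
  k <- (0:(nf - 1)) - floor(nf / 2)
  rho <- sqrt(outer(k^2, k^2, "+")) * rho_step
  expect_true(all(Mod(u0)[rho > cfg$na / (cfg$wavelengths[3] * 1e-3) +
                            2 * rho_step] == 0))
  # +z and -z fields are complex conjugates
  up <- pupil_field(cfg, z = 1, channel = 3)
  un <- pupil_field(cfg, z = -1, channel = 3)
  expect_equal(unclass(up), Conj(unclass(un)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # numeric-integration oracle: defocus redistributes phase, not energy
  energies <- vapply(c(-2, -1, 0, 0.7, 2), function(z)
    sum(Mod(pupil_field(cfg, z, channel = 3))^2), numeric(1))
  expect_equal(max(energies) / min(energies), 1, tolerance = 1e-12)
  expect_error(pupil_field(cfg, z = 5, channel = 3), "outside")
})

test_that("microlens array partitions the pupil into three lenslets", {
  cfg <- test_config()
  tr <- mla_transmittance(cfg, channel = 3)
  cc <- attr(tr, "centers_in_pupil")
  expect_identical(nrow(cc), 3L)
  # hexagonal-lattice oracle: the three centers form an equilateral
  # triangle of side = pitch
  dists <- as.numeric(stats::dist(cc))
  expect_equal(dists, rep(cfg$mla_pitch, 3), tolerance = 1e-9)
  # transmittance is unity phase at each lenslet vertex region center
  expect_equal(Mod(tr[1, 1]), 1)
  # consistency with the merged linear factor used by the PSF builder:
  # T * exp(i pi r^2 / (lambda f)) must be the per-cell tilt
  # exp(i pi (2 r.c - c^2) / (lambda f))
  g <- lfcyto:::lf_grid(cfg, channel = 3, crop = NULL, oversample = 2L)
  xmat <- outer(rep(1, g$nf), g$xm)
  ymat <- outer(g$xm, rep(1, g$nf))
  q <- exp(1i * pi * (xmat^2 + ymat^2) / (g$lam_mm * cfg$f_ml))
  idx <- cbind(sample(g$nf, 50), sample(g$nf, 50))
  cc3 <- attr(tr, "centers")
  for (k in seq_len(nrow(idx))) {
    x <- xmat[idx[k, , drop = FALSE]]; y <- ymat[idx[k, , drop = FALSE]]
    d2 <- (cc3[, 1] - x)^2 + (cc3[, 2] - y)^2
    c_near <- cc3[which.min(d2), ]
    want <- exp(1i * pi * (2 * (x * c_near[1] + y * c_near[2]) -
                             sum(c_near^2)) / (g$lam_mm * cfg$f_ml))
    expect_equal((tr * q)[idx[k, , drop = FALSE]], unname(want),
                 tolerance = 1e-8)
  }
  # breaking the exactly-3 geometry warns
  bad <- test_config()
  bad$mla_pitch <- bad$mla_pitch * 0.7
  expect_warning(mla_transmittance(bad, channel = 3), "lenslet centers")
})

test_that("huge centered lenslet degenerates to plain Fourier imaging", {
  cfg <- scaled_optical_config(scale = 0.125, sensor_shape = c(96, 96),
                               z_range = 1, z_step = 0.5,
                               mla_centering = "centered")
  cfg$mla_pitch <- 50 * 0.125
  expect_warning(ec <- elemental_centers(cfg), "expected 3")
  expect_identical(nrow(ec), 1L)
  expect_equal(c(ec$x_mm, ec$y_mm), c(0, 0))
})

test_that("elemental centers match the lattice and the PSF peaks", {
  cfg <- test_config()
  ec <- elemental_centers(cfg, crop = 160)
  expect_identical(nrow(ec), 3L)
  # pairwise pixel distances equal pitch / camera pixel
  pd <- as.numeric(stats::dist(ec[, c("row", "col")]))
  expect_equal(pd, rep(1e3 * cfg$mla_pitch / cfg$pixel_cam, 3),
               tolerance = 1e-9)
  # 120 degree rotation maps the hexagonal center set onto itself
  rot <- test_config()
  rot$mla_rotation <- 2 * pi / 3
  ec_rot <- elemental_centers(rot, crop = 160)
  ord <- function(df) df[order(round(df$row, 6), round(df$col, 6)), ]
  expect_equal(ord(ec_rot)$row, ord(ec)$row, tolerance = 1e-6)
  expect_equal(ord(ec_rot)$col, ord(ec)$col, tolerance = 1e-6)
  # PSF-peak oracle: each in-focus elemental spot peaks within 1 px of its
  # predicted center
  psf <- test_psf()
  p0 <- psf[, , which(attr(psf, "z") == 0)]
  for (i in 1:3) {
    r <- round(ec$row[i]); c <- round(ec$col[i])
    win <- p0[(r - 5):(r + 5), (c - 5):(c + 5)]
    pk <- which(win == max(win), arr.ind = TRUE)[1, ]
    expect_lt(max(abs(pk - 6)), 2)  # peak within 1 px of the center
  }
})

test_that("PSF stack conserves energy and is axially symmetric", {
  psf <- test_psf()
  zs <- attr(psf, "z")
  expect_identical(dim(psf)[3], 21L)
  sums <- apply(psf, 3, sum)
  expect_true(all(sums > 0))
  # energy bookkeeping: light redistributes but is not lost across defocus
  i0 <- which(zs == 0)
  expect_true(all(abs(sums / sums[i0] - 1) < 0.05))
  # plane-to-plane smoothness
  expect_true(all(abs(diff(sums) / sums[-1]) < 0.5))
  # the three-lens geometry intentionally breaks +/-z symmetry: opposite
  # parallax at opposite defocus is what encodes the depth sign
  expect_lt(stats::cor(as.numeric(psf[, , i0 + 5]),
                       as.numeric(psf[, , i0 - 5])), 0.9)
})

test_that("inversion-symmetric aperture gives point-symmetric +/-z planes", {
  # a single axis-centered lenslet covering the pupil (plain Fourier
  # imaging) has an inversion-symmetric aperture, so the aberration-free
  # -z plane is the point reflection of the +z plane
  cfg <- scaled_optical_config(scale = 0.125, sensor_shape = c(96, 96),
                               z_range = 1, z_step = 0.25,
                               mla_centering = "centered")
  cfg$mla_pitch <- 50 * 0.125
  # oversample 1: pixel binning would offset the grid by half a sample and
  # mask the exact symmetry
  suppressWarnings(psf <- build_psf_stack(cfg, channel = 3, oversample = 1))
  zs <- attr(psf, "z")
  i0 <- which(zs == 0)
  n <- dim(psf)[1]
  for (dz in c(2, 4)) {
    a <- psf[2:n, 2:n, i0 + dz]
    b <- psf[n:2, n:2, i0 - dz]       # point reflection about the axis
    expect_gt(stats::cor(as.numeric(a), as.numeric(b)), 0.99)
  }
})

test_that("all-zero aberration map reproduces the ideal PSF exactly", {
  cfg <- test_config(z_range = 1, z_step = 0.5, crop = 96)
  ideal <- build_psf_stack(cfg, channel = 3)
  withab <- build_psf_stack(cfg, channel = 3,
                            aberration = aberration_map(zernike = rep(0, 11)))
  expect_identical(unclass(ideal), unclass(withab))
  # a real aberration changes the stack
  astig <- build_psf_stack(cfg, channel = 3,
                           aberration = aberration_map(zernike = c(0, 0, 0, 0, 0.2)))
  expect_gt(max(abs(astig - ideal)), 1e-6 * max(ideal))
})

test_that("undersampled grids raise a sampling error", {
  # large defocus range on a coarse grid: the defocus phase would alias at
  # the pupil edge
  cfg <- test_config(z_range = 4, z_step = 0.5, crop = 96)
  expect_error(build_psf_stack(cfg, channel = 3, oversample = 1),
               "sampling error")
})

test_that("single-lenslet sub-aperture matches the diffraction limit", {
  # centered lenslet smaller than the pupil: the on-axis elemental spot
  # should have the Airy-like width of the equivalent sub-aperture
  cfg <- scaled_optical_config(scale = 0.125, sensor_shape = c(96, 96),
                               z_range = 0.5, z_step = 0.25,
                               mla_centering = "centered")
  suppressWarnings(psf <- build_psf_stack(cfg, channel = 3))
  p0 <- psf[, , which(attr(psf, "z") == 0)]
  c0 <- 49
  vx <- sample_pixel(cfg)
  fw_x <- fwhm_1d(p0[c0, ], vx)
  fw_y <- fwhm_1d(p0[, c0], vx)
  # equivalent-area circular aperture of the hexagonal cell
  r_eq <- cfg$mla_pitch * sqrt(sqrt(3) / (2 * pi))
  na_sub <- r_eq * cfg$m_obj / cfg$f_fl
  fw_theory <- 0.514 * (cfg$wavelengths[3] * 1e-3) / na_sub
  expect_equal(fw_x, fw_theory, tolerance = 0.15)
  expect_equal(fw_y, fw_theory, tolerance = 0.15)
})

test_that("PSF stacks round-trip through float TIFF with metadata", {
  psf <- test_psf_small()
  path <- withr::local_tempfile(fileext = ".tif")
  write_psf_stack(psf, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_psf_stack(path)
  expect_equal(dim(back), dim(psf))
  expect_lt(max(abs(back - psf)) / max(psf), 1e-6)
  expect_equal(attr(back, "voxel"), as.numeric(attr(psf, "voxel")))
  expect_equal(attr(back, "z"), as.numeric(attr(psf, "z")))
  expect_equal(attr(back, "wavelength"), attr(psf, "wavelength"))
})
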