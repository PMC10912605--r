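# Wave-optics forward model of the Fourier light-field train.
#
# The microscope is an epi-fluorescence platform (objective + tube lens)
# whose native image plane is Fourier-transformed by a Fourier lens of focal
# length f_fl. A hexagonal microlens array (MLA, focal length f_ml) sits in
# that Fourier plane and partitions the relayed objective pupil; the camera
# sits one MLA focal length behind it, so each lenslet forms one elemental
# perspective image. Scalar diffraction is used throughout: the field in the
# MLA plane for a point emitter at defocus z is the (scaled) objective pupil
# carrying the defocus phase exp(i 2 pi z sqrt((n/lambda)^2 - rho^2)).
#
# Units: focal lengths, MLA pitch and MLA-plane coordinates in mm;
# wavelengths in nm; camera pixel pitch in um; sample-space coordinates and
# axial positions in um.

#' Optical configuration of the light-field train
#'
#' Collects every optical parameter of the system in one validated record.
#' Defaults describe a 100x/NA 1.45 oil objective, a 275 mm Fourier lens, a
#' 117 mm hexagonal microlens array and a 6.5 um sCMOS camera, i.e. an
#' effective magnification of 42.5x and a pupil partitioned by exactly three
#' lenslets.
#'
#' @param na objective numerical aperture (must be below `n_imm`)
#' @param m_obj objective magnification
#' @param f_tube tube lens focal length (mm); manufacturer convention 200 mm
#' @param f_fl Fourier lens focal length (mm)
#' @param f_ml microlens focal length (mm)
#' @param mla_pitch lenslet center-to-center distance (mm)
#' @param mla_rotation lattice rotation (radians)
#' @param mla_centering `"deephole"` places the optical axis at a deep hole
#'   of the hexagonal lattice (three nearest lenslets, the three-elemental
#'   image geometry); `"centered"` puts a lenslet center on the axis.
#' @param n_imm immersion refractive index
#' @param wavelengths per-channel emission wavelengths (nm)
#' @param pixel_cam camera pixel pitch (um)
#' @param sensor_shape sensor size in pixels, `c(rows, cols)`
#' @param z_range axial half-extent of the PSF stack (um)
#' @param z_step axial step (um)
#' @return an object of class `optical_config`
#' @export
optical_config <- function(na = 1.45, m_obj = 100, f_tube = 200,
                           f_fl = 275, f_ml = 117,
                           mla_pitch = 3.5, mla_rotation = 0,
                           mla_centering = c("deephole", "centered"),
                           n_imm = 1.515,
                           wavelengths = c(515, 580, 680),
                           pixel_cam = 6.5,
                           sensor_shape = c(1024L, 1024L),
                           z_range = 5, z_step = 0.1) {
  cfg <- list(na = na, m_obj = m_obj, f_tube = f_tube, f_fl = f_fl,
              f_ml = f_ml, mla_pitch = mla_pitch,
              mla_rotation = mla_rotation,
              mla_centering = match.arg(mla_centering),
              n_imm = n_imm, wavelengths = wavelengths,
              pixel_cam = pixel_cam,
              sensor_shape = as.integer(sensor_shape),
              z_range = z_range, z_step = z_step)
  class(cfg) <- "optical_config"
  validate_optical_config(cfg)
  cfg
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  %gx / NA %.2f (n_imm %.3f), f_tube %g mm\n",
              x$m_obj, x$na, x$n_imm, x$f_tube))
  cat(sprintf("  Fourier lens %g mm, MLA f %g mm pitch %g mm (%s)\n",
              x$f_fl, x$f_ml, x$mla_pitch, x$mla_centering))
  cat(sprintf("  effective magnification %.3fx, sample pixel %.1f nm\n",
              effective_magnification(x), 1000 * sample_pixel(x)))
  cat(sprintf("  sensor %d x %d px @ %g um, z +/- %g um step %g um (%d planes)\n",
              x$sensor_shape[1], x$sensor_shape[2], x$pixel_cam,
              x$z_range, x$z_step, n_axial_planes(x)))
  invisible(x)
}

validate_optical_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid optical configuration: ", msg,
                                 call. = FALSE)
  if (!(cfg$na > 0 && cfg$na < cfg$n_imm))
    stop_cfg("need 0 < na < n_imm")
  for (f in c("f_tube", "f_fl", "f_ml", "mla_pitch", "pixel_cam", "z_step"))
    if (!(is.numeric(cfg[[f]]) && cfg[[f]] > 0))
      stop_cfg(paste(f, "must be positive"))
  if (any(cfg$wavelengths <= 0)) stop_cfg("wavelengths must be positive")
  if (cfg$z_range <= 0) stop_cfg("z_range must be positive")
  np <- 2 * cfg$z_range / cfg$z_step
  if (abs(np - round(np)) > 1e-8)
    stop_cfg("z_range must be an integer multiple of z_step (odd plane count
              with a plane at z = 0)")
  if (any(cfg$sensor_shape < 16))
    stop_cfg("sensor_shape too small")
  invisible(cfg)
}

#' Number of axial planes of the PSF stack
#' @param config an [optical_config()]
#' @return integer plane count, always odd (a plane sits at z = 0)
#' @export
n_axial_planes <- function(config) {
  as.integer(round(2 * config$z_range / config$z_step)) + 1L
}

#' Effective magnification of the light-field system
#'
#' The objective magnification rescaled by the microlens/Fourier-lens relay,
#' `m_obj * f_ml / f_fl`. With the default optics this is 42.5x: the system
#' trades the raw 100x sampling for a wider field while the three-perspective
#' reconstruction restores near-diffraction-limited resolution.
#'
#' @param config an [optical_config()]
#' @return scalar magnification
#' @export
effective_magnification <- function(config) {
  validate_optical_config(config)
  config$m_obj * config$f_ml / config$f_fl
}

#' Sample-referred camera pixel size (um)
#' @param config an [optical_config()]
#' @export
sample_pixel <- function(config) {
  config$pixel_cam / effective_magnification(config)
}

# radius of the relayed objective pupil in the MLA plane (mm)
pupil_radius_mm <- function(config) {
  config$na * config$f_fl / config$m_obj
}

#' Maximum elemental field of view at the sample (um)
#'
#' Elemental images are spaced by the lenslet pitch on the sensor, so the
#' non-overlapping field of view of one perspective is
#' `pitch / effective magnification`.
#' @param config an [optical_config()]
#' @export
elemental_fov <- function(config) {
  1000 * config$mla_pitch / effective_magnification(config)
}

#' Geometrically scaled configuration for desk-scale runs
#'
#' Scales the Fourier-lens and microlens focal lengths and the MLA pitch by
#' a common factor while keeping the objective, immersion, camera pixel and
#' axial sampling unchanged. This preserves the effective magnification, the
#' numerical aperture and the way the lenslets partition the pupil (still
#' exactly three elemental images), so resolution-relevant quantities are
#' unchanged while the elemental images pack onto a small sensor crop.
#'
#' @param scale common focal-length/pitch factor (default 0.125)
#' @param sensor_shape sensor crop in pixels
#' @param ... further arguments passed to [optical_config()]
#' @export
scaled_optical_config <- function(scale = 0.125,
                                  sensor_shape = c(160L, 160L), ...) {
  optical_config(f_fl = 275 * scale, f_ml = 117 * scale,
                 mla_pitch = 3.5 * scale, sensor_shape = sensor_shape, ...)
}

# ---------------------------------------------------------------------------
# frequency/MLA-plane grid shared by the pupil, MLA and PSF builders

lf_grid <- function(config, channel = 1L, crop = NULL, oversample = 2L) {
  validate_optical_config(config)
  wl <- config$wavelengths[channel]
  if (is.na(wl)) stop("no wavelength defined for channel ", channel,
                      call. = FALSE)
  n <- if (is.null(crop)) min(config$sensor_shape) else as.integer(crop)
  q <- as.integer(oversample)
  nf <- n * q
  lam_mm <- wl * 1e-6
  lam_um <- wl * 1e-3
  ds_mm <- config$pixel_cam * 1e-3 / q          # sensor sampling (mm)
  dm <- lam_mm * config$f_ml / (nf * ds_mm)     # MLA-plane sampling (mm)
  k <- (0:(nf - 1)) - floor(nf / 2)
  xm <- k * dm
  # sample-side spatial frequency (1/um) per mm of MLA-plane coordinate
  rho_per_mm <- config$m_obj / (lam_mm * config$f_fl) * 1e-3
  rho_x <- outer(rep(1, nf), xm * rho_per_mm)
  rho_y <- outer(xm * rho_per_mm, rep(1, nf))
  rho2 <- rho_x^2 + rho_y^2
  rho_max <- config$na / lam_um
  list(n = n, q = q, nf = nf, wavelength = wl,
       lam_mm = lam_mm, lam_um = lam_um,
       ds_mm = ds_mm, dm = dm, xm = xm,
       rho_per_mm = rho_per_mm, rho2 = rho2, rho_max = rho_max,
       mask = rho2 <= rho_max^2,
       kz = sqrt(pmax((config$n_imm / lam_um)^2 - rho2, 0)))
}

# ---------------------------------------------------------------------------
# aberration maps

#' Aberration map for the hybrid PSF
#'
#' The hybrid PSF combines the ideal wave-optics model with a calibration
#' term for real-system deviations. The calibration is expressed either as
#' Zernike coefficients (Noll indexing, waves RMS) or as a measured phase
#' map sampled on the pupil grid. An all-zero map reproduces the ideal PSF
#' exactly.
#'
#' @param zernike named or plain numeric vector of Noll coefficients
#'   (waves RMS), index 1 = piston
#' @param phase optional measured pupil phase map (radians) matching the
#'   simulation grid; added to the Zernike expansion
#' @export
aberration_map <- function(zernike = numeric(0), phase = NULL) {
  structure(list(zernike = zernike, phase = phase),
            class = "aberration_map")
}

# Noll-indexed Zernike polynomial j on unit-disc coordinates
zernike_noll <- function(j, rho, theta) {
  # unrank Noll index -> (n, m)
  n <- 0
  while (j > (n + 1) * (n + 2) / 2) n <- n + 1
  jrem <- j - n * (n + 1) / 2
  ms <- if (n %% 2 == 0) seq(0, n, by = 2) else seq(1, n, by = 2)
  mabs <- rep(ms, each = 2)
  if (ms[1] == 0) mabs <- c(0, rep(ms[-1], each = 2))
  m <- mabs[jrem]
  # radial polynomial
  R <- 0
  for (k in 0:((n - m) / 2)) {
    R <- R + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k)) *
      rho^(n - 2 * k)
  }
  if (m == 0) return(sqrt(n + 1) * R)
  # Noll: even j -> cos, odd j -> sin
  if (j %% 2 == 0) sqrt(2 * (n + 1)) * R * cos(m * theta)
  else             sqrt(2 * (n + 1)) * R * sin(m * theta)
}

aberration_phase <- function(aberration, grid) {
  if (is.null(aberration)) return(0)
  stopifnot(inherits(aberration, "aberration_map"))
  ph <- 0
  cz <- aberration$zernike
  if (length(cz) && any(cz != 0)) {
    rho <- sqrt(grid$rho2) / grid$rho_max
    theta <- atan2(outer(grid$xm, rep(1, grid$nf)),
                   outer(rep(1, grid$nf), grid$xm))
    for (j in seq_along(cz)) {
      if (cz[j] != 0)
        ph <- ph + 2 * pi * cz[j] * zernike_noll(j, pmin(rho, 1), theta)
    }
  }
  if (!is.null(aberration$phase)) ph <- ph + aberration$phase
  ph
}

# ---------------------------------------------------------------------------
# pupil field

#' Defocused pupil field in the MLA (Fourier) plane
#'
#' Scalar-diffraction pupil of the objective relayed into the microlens
#' plane: a uniform disc of radius `na / lambda` in sample-side spatial
#' frequency, carrying the angular-spectrum defocus phase
#' `exp(i 2 pi z sqrt((n_imm/lambda)^2 - rho^2))` for an emitter at axial
#' position `z`, plus any calibration aberration phase.
#'
#' @param config an [optical_config()]
#' @param z axial emitter position (um); must satisfy `|z| <= z_range`
#' @param channel emission channel index into `config$wavelengths`
#' @param aberration optional [aberration_map()]
#' @param crop lateral grid size in camera pixels (default: sensor)
#' @param oversample sub-pixel sampling factor of the camera grid
#' @return complex matrix of class `pupil_field` with attributes
#'   `rho_step` (cycles/um per sample), `wavelength` (nm) and `z` (um)
#' @export
pupil_field <- function(config, z, channel = 1L, aberration = NULL,
                        crop = NULL, oversample = 2L) {
  if (abs(z) > config$z_range + 1e-9)
    stop("defocus z = ", z, " um outside the configured axial range +/- ",
         config$z_range, " um", call. = FALSE)
  g <- lf_grid(config, channel, crop, oversample)
  ph <- 2 * pi * z * g$kz + aberration_phase(aberration, g)
  u <- g$mask * exp(1i * ph)
  structure(u, class = c("pupil_field", class(u)),
            rho_step = g$dm * g$rho_per_mm,
            wavelength = g$wavelength, z = z)
}

# ---------------------------------------------------------------------------
# microlens array

# lenslet centers (mm, MLA plane) of the hexagonal lattice, restricted to a
# neighborhood large enough to cover the simulation grid
mla_centers <- function(config, extent_mm) {
  p <- config$mla_pitch
  th <- config$mla_rotation
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  a1 <- rot %*% c(p, 0)
  a2 <- rot %*% c(p / 2, p * sqrt(3) / 2)
  off <- if (config$mla_centering == "deephole") (a1 + a2) / 3 else c(0, 0)
  nmax <- max(3L, ceiling(extent_mm / p) + 2L)
  ij <- expand.grid(i = -nmax:nmax, j = -nmax:nmax)
  cx <- ij$i * a1[1] + ij$j * a2[1] - off[1]
  cy <- ij$i * a1[2] + ij$j * a2[2] - off[2]
  keep <- sqrt(cx^2 + cy^2) <= extent_mm * sqrt(2)
  cbind(x = cx[keep], y = cy[keep])
}

# nearest-center (Voronoi, i.e. full-fill hexagonal aperture) assignment of
# every grid sample to a lenslet
mla_assignment <- function(grid, centers) {
  nf <- grid$nf
  xmat <- outer(rep(1, nf), grid$xm)
  ymat <- outer(grid$xm, rep(1, nf))
  best <- matrix(1L, nf, nf)
  bestd <- (xmat - centers[1, 1])^2 + (ymat - centers[1, 2])^2
  for (t in seq_len(nrow(centers))[-1]) {
    d <- (xmat - centers[t, 1])^2 + (ymat - centers[t, 2])^2
    w <- d < bestd
    best[w] <- t
    bestd[w] <- d[w]
  }
  list(index = best, x = xmat, y = ymat,
       cx = matrix(centers[best, 1], nf, nf),
       cy = matrix(centers[best, 2], nf, nf))
}

#' Complex transmittance of the microlens array
#'
#' Hexagonally packed, full-fill lenslets: every point of the MLA plane is
#' assigned to its nearest lenslet center (a hexagonal Voronoi aperture) and
#' receives the thin-lens quadratic phase of that lenslet,
#' `exp(-i pi |r - c_j|^2 / (lambda f_ml))`.
#'
#' @inheritParams pupil_field
#' @return complex matrix with attributes `centers` (all lattice centers on
#'   the grid, mm), `centers_in_pupil` (those inside the relayed pupil disc)
#'   and `pitch` (mm). A warning is emitted when the number of lenslets
#'   intersecting the pupil differs from three.
#' @export
mla_transmittance <- function(config, channel = 1L, crop = NULL,
                              oversample = 2L) {
  g <- lf_grid(config, channel, crop, oversample)
  centers <- mla_centers(config, extent_mm = max(abs(g$xm)))
  a <- mla_assignment(g, centers)
  r2 <- (a$x - a$cx)^2 + (a$y - a$cy)^2
  tr <- exp(-1i * pi * r2 / (g$lam_mm * config$f_ml))
  rp <- pupil_radius_mm(config)
  inside <- sqrt(centers[, 1]^2 + centers[, 2]^2) <= rp
  if (sum(inside) != 3L)
    warning(sprintf(
      "%d lenslet centers intersect the relayed pupil disc (expected 3 for the default geometry)",
      sum(inside)), call. = FALSE)
  structure(tr, centers = centers, centers_in_pupil = centers[inside, , drop = FALSE],
            pitch = config$mla_pitch)
}

#' Sensor positions of the elemental images
#'
#' Each lenslet whose center lies inside the relayed pupil disc forms one
#' elemental image centered at the projection of that lenslet onto the
#' camera; pairwise center distances equal the lenslet pitch divided by the
#' camera pixel pitch. For the default geometry the three centers form an
#' equilateral triangle around the sensor center.
#'
#' @param config an [optical_config()]
#' @param crop lateral grid size in camera pixels used as the coordinate
#'   frame (default: sensor); centers are reported in this frame with the
#'   optical axis at pixel `floor(crop/2) + 1`
#' @return data.frame with columns `row`, `col` (pixel coordinates) and
#'   `x_mm`, `y_mm` (MLA-plane coordinates); a warning is issued (and all
#'   intersecting centers returned) when the count differs from three
#' @export
elemental_centers <- function(config, crop = NULL) {
  validate_optical_config(config)
  n <- if (is.null(crop)) min(config$sensor_shape) else as.integer(crop)
  centers <- mla_centers(config, extent_mm = pupil_radius_mm(config) +
                           2 * config$mla_pitch)
  rp <- pupil_radius_mm(config)
  inside <- sqrt(centers[, 1]^2 + centers[, 2]^2) <= rp
  cc <- centers[inside, , drop = FALSE]
  if (nrow(cc) != 3L)
    warning(sprintf("%d lenslet centers intersect the pupil (expected 3); returning all of them",
                    nrow(cc)), call. = FALSE)
  px <- 1e3 * cc / config$pixel_cam     # mm -> camera px offsets
  c0 <- grid_center(n)
  data.frame(row = c0 + px[, 2], col = c0 + px[, 1],
             x_mm = cc[, 1], y_mm = cc[, 2])
}

# ---------------------------------------------------------------------------
# PSF stack

#' Build the hybrid point-spread-function stack
#'
#' For each axial plane the defocused pupil field is relayed to the MLA
#' plane, multiplied by the microlens transmittance, Fresnel-propagated one
#' microlens focal length to the sensor, squared and integrated over camera
#' pixel footprints (by `oversample`-fold supersampling and binning).
#'
#' Numerically, the Fresnel quadratic phase at the MLA plane is merged
#' analytically with the lenslet quadratic phase: within each hexagonal
#' Voronoi cell with center `c` the product reduces to the exactly linear
#' phase `exp(i pi (2 r.c - |c|^2) / (lambda f_ml))`, which steers that
#' cell's light to the elemental image centered at `c`. This avoids sampling
#' two large canceling quadratics on the grid. Lenslets whose elemental
#' image would fall outside the computed sensor crop are masked (finite
#' sensor). The stack is normalized so that the z = 0 plane sums to one.
#'
#' @inheritParams pupil_field
#' @param crop lateral output size in camera pixels; defaults to the full
#'   sensor (use a small crop plus [scaled_optical_config()] for desk-scale
#'   work)
#' @param normalize `"z0"` (in-focus plane sums to 1), `"max"`, or `"none"`
#' @return 3D array (rows x cols x z) of class `psf_stack` with attributes
#'   `z` (plane positions, um), `voxel` (dx, dy, dz in um at sample scale),
#'   `wavelength`, `channel`, `normalization`
#' @export
build_psf_stack <- function(config, channel = 1L, aberration = NULL,
                            crop = NULL, oversample = 2L,
                            normalize = c("z0", "max", "none")) {
  normalize <- match.arg(normalize)
  g <- lf_grid(config, channel, crop, oversample)
  check_sampling(config, g)
  centers <- mla_centers(config, extent_mm = max(abs(g$xm)))
  a <- mla_assignment(g, centers)
  # finite sensor: drop cells whose elemental image misses the computed crop
  half_extent_mm <- g$n / 2 * config$pixel_cam * 1e-3
  visible <- abs(a$cx) <= half_extent_mm & abs(a$cy) <= half_extent_mm
  tilt <- visible *
    exp(1i * pi * (2 * (a$x * a$cx + a$y * a$cy) - (a$cx^2 + a$cy^2)) /
          (g$lam_mm * config$f_ml))
  zs <- seq(-config$z_range, config$z_range, by = config$z_step)
  zs[which.min(abs(zs))] <- 0
  ab <- aberration_phase(aberration, g)
  base <- g$mask * exp(1i * ab) * tilt
  out <- array(0, c(g$n, g$n, length(zs)))
  for (iz in seq_along(zs)) {
    u <- base * exp(2i * pi * zs[iz] * g$kz)
    f <- fftshift2(stats::fft(ifftshift2(u)))
    inten <- Mod(f)^2
    if (g$q > 1L) inten <- bin2(inten, g$q)
    out[, , iz] <- inten
  }
  sc <- switch(normalize,
               z0 = sum(out[, , which(zs == 0)]),
               max = max(out),
               none = 1)
  out <- out / sc
  vx <- sample_pixel(config)
  structure(out, class = "psf_stack",
            z = zs, voxel = c(dx = vx, dy = vx, dz = config$z_step),
            wavelength = g$wavelength, channel = as.integer(channel),
            normalization = normalize,
            otf_env = new.env(parent = emptyenv()))
}

# q x q pixel binning (area integration over camera pixel footprints)
bin2 <- function(m, q) {
  # sum q adjacent columns, then q adjacent rows
  cm <- m[, seq(1, ncol(m), by = q), drop = FALSE]
  if (q > 1) for (k in 2:q) cm <- cm + m[, seq(k, ncol(m), by = q), drop = FALSE]
  rm <- cm[seq(1, nrow(cm), by = q), , drop = FALSE]
  if (q > 1) for (k in 2:q) rm <- rm + cm[seq(k, nrow(cm), by = q), , drop = FALSE]
  rm
}

# band-limit / phase-sampling guards for the reduced grids
check_sampling <- function(config, g) {
  pupil_samples <- g$rho_max / (g$dm * g$rho_per_mm)
  if (pupil_samples < 12)
    stop("sampling error: pupil radius covered by only ",
         round(pupil_samples, 1),
         " grid samples; increase crop or oversample", call. = FALSE)
  # defocus phase increment at the pupil edge, in cycles per sample
  kz_edge <- sqrt((config$n_imm / g$lam_um)^2 - g$rho_max^2)
  dphi <- config$z_range * g$rho_max / kz_edge * (g$dm * g$rho_per_mm)
  if (dphi > 0.5)
    stop("sampling error: defocus phase aliases at the pupil edge (",
         signif(dphi, 3),
         " cycles/sample at z_range); increase crop/oversample or reduce z_range",
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.psf_stack <- function(x, ...) {
  d <- dim(x)
  v <- attr(x, "voxel")
  cat(sprintf("<psf_stack> %d x %d x %d, voxel %.1f x %.1f x %.0f nm, %g nm emission\n",
              d[1], d[2], d[3], 1000 * v[1], 1000 * v[2], 1000 * v[3],
              attr(x, "wavelength")))
  invisible(x)
}
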