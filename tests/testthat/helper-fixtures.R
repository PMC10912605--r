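# Shared fixtures. PSF stacks are expensive to build, so they are memoized
# per test run. All optical fixtures use the geometrically scaled twin of
# the full instrument (same NA, magnification and pupil partition, small
# sensor crop).

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# standard test configuration: scale 0.125, 160 px crop
test_config <- function(z_range = 2, z_step = 0.2, crop = 160) {
  scaled_optical_config(scale = 0.125, sensor_shape = c(crop, crop),
                        z_range = z_range, z_step = z_step)
}

# 21-plane PSF on the 160 px crop (deep-red channel)
test_psf <- function() {
  memo("psf160", function() build_psf_stack(test_config(), channel = 3))
}

# cheaper 9-plane PSF on a 96 px crop for reconstruction unit tests
test_psf_small <- function() {
  memo("psf96", function()
    build_psf_stack(test_config(z_range = 1, z_step = 0.25, crop = 96),
                    channel = 3))
}

# tiny synthetic separable-Gaussian PSF stack, independent of the optics
# module (for Richardson-Lucy and segmentation unit tests)
gauss_psf <- function(n = 7, nz = 3, sigma = 1, voxel = c(0.1, 0.1, 0.2)) {
  g <- exp(-((seq_len(n) - grid_center(n))^2) / (2 * sigma^2))
  plane <- outer(g, g)
  arr <- array(0, c(n, n, nz))
  wz <- exp(-((seq_len(nz) - grid_center(nz))^2) / 2)
  for (k in seq_len(nz)) arr[, , k] <- plane * wz[k]
  arr <- arr / sum(arr[, , grid_center(nz)])
  structure(arr, class = "psf_stack", z = (seq_len(nz) - grid_center(nz)) * voxel[3],
            voxel = c(dx = voxel[1], dy = voxel[2], dz = voxel[3]),
            wavelength = 680, channel = 1L, normalization = "z0",
            otf_env = new.env(parent = emptyenv()))
}

grid_center <- function(n) floor(n / 2) + 1L

# dense-matrix forward operator: independent brute-force implementation of
# "convolve every z plane with its PSF plane and sum" (explicit loops, no
# FFT), used as the oracle for the Richardson-Lucy path
dense_forward_matrix <- function(psf, nr, nc) {
  d <- dim(psf)
  npx <- nr * nc
  nvox <- npx * d[3]
  A <- matrix(0, npx, nvox)
  c0r <- grid_center(d[1]); c0c <- grid_center(d[2])
  for (z in seq_len(d[3])) {
    for (vr in seq_len(nr)) for (vc in seq_len(nc)) {
      vidx <- (z - 1) * npx + (vc - 1) * nr + vr
      for (kr in seq_len(d[1])) for (kc in seq_len(d[2])) {
        ir <- vr + (kr - c0r); ic <- vc + (kc - c0c)
        if (ir >= 1 && ir <= nr && ic >= 1 && ic <= nc)
          A[(ic - 1) * nr + ir, vidx] <- A[(ic - 1) * nr + ir, vidx] +
            psf[kr, kc, z]
      }
    }
  }
  A
}

# dense Richardson-Lucy updates from the matrix operator
dense_rl <- function(y, A, nz, iterations) {
  npx <- length(y)
  x <- rep(sum(y) / (npx * nz), npx * nz)
  eps <- 1e-12 * max(y)
  for (i in seq_len(iterations)) {
    f <- as.numeric(A %*% x)
    x <- x * as.numeric(t(A) %*% (as.numeric(y) / (f + eps)))
  }
  x
}

# voxelized axis-aligned ellipsoid mask (optionally rotated about z)
ellipsoid_volume <- function(radii, voxel = 0.1, margin = 1, angle = 0) {
  n <- ceiling(2 * (max(radii) + margin) / voxel)
  n <- n + (1 - n %% 2)      # odd grid, center voxel on the origin
  ax <- (seq_len(n) - grid_center(n)) * voxel
  arr <- array(0, c(n, n, n))
  for (k in seq_len(n)) {
    x <- outer(rep(1, n), ax); y <- outer(ax, rep(1, n))
    xr <- cos(angle) * x + sin(angle) * y
    yr <- -sin(angle) * x + cos(angle) * y
    arr[, , k] <- (xr / radii[1])^2 + (yr / radii[2])^2 +
      (ax[k] / radii[3])^2 <= 1
  }
  structure(arr, voxel = c(voxel, voxel, voxel))
}

expect_no_failure <- function(expr) expect_error(expr, NA)
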