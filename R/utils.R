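# Shared numerical helpers: centered FFT grids, padding, 1D FWHM, Otsu.

# quadrant swap putting the grid center (floor(n/2)+1) at [1,1] and back.
# For even n the operation is its own inverse; both directions are provided
# for readability at call sites.
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c((floor(nr / 2) + 1):nr, seq_len(floor(nr / 2))),
    c((floor(nc / 2) + 1):nc, seq_len(floor(nc / 2))), drop = FALSE]
}

ifftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c((nr - floor(nr / 2) + 1):nr, seq_len(nr - floor(nr / 2))),
    c((nc - floor(nc / 2) + 1):nc, seq_len(nc - floor(nc / 2))), drop = FALSE]
}

# center index of an fft-convention grid
grid_center <- function(n) floor(n / 2) + 1L

# smallest 5-smooth integer >= n (keeps base R's mixed-radix FFT fast)
next_fast_size <- function(n) {
  while (TRUE) {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(as.integer(n))
    n <- n + 1
  }
}

pad_matrix <- function(m, nr, nc = nr, row0 = 1L, col0 = 1L) {
  out <- matrix(0, nr, nc)
  out[row0:(row0 + nrow(m) - 1L), col0:(col0 + ncol(m) - 1L)] <- m
  out
}

# embed a centered convolution kernel into an np x np grid with its center
# wrapped to [1,1] (circular-shift convention used with fft-based convolution)
kernel_to_origin <- function(k, np) {
  p <- pad_matrix(k, np, np)
  c0r <- grid_center(nrow(k)); c0c <- grid_center(ncol(k))
  p[c(c0r:np, seq_len(c0r - 1L)), c(c0c:np, seq_len(c0c - 1L))]
}

#' Full width at half maximum of a 1D profile
#'
#' Locates the half-maximum crossings on either side of the profile peak by
#' linear interpolation and returns their distance in the units of `step`.
#'
#' @param profile numeric vector of intensities (not necessarily normalized)
#' @param step sample spacing (physical units per sample)
#' @return width in the units of `step`; `NA` with attribute
#'   `unbounded = TRUE` when the profile does not fall below half maximum
#'   on both sides inside the vector.
#' @export
fwhm_1d <- function(profile, step = 1) {
  stopifnot(length(profile) >= 3)
  i <- which.max(profile)
  h <- profile[i] / 2
  left <- NA_real_
  if (i > 1) for (a in seq(i, 2L)) {
    if (profile[a - 1] < h) {
      left <- (a - 1) + (h - profile[a - 1]) / (profile[a] - profile[a - 1])
      break
    }
  }
  right <- NA_real_
  if (i < length(profile)) for (a in seq(i, length(profile) - 1L)) {
    if (profile[a + 1] < h) {
      right <- a + (profile[a] - h) / (profile[a] - profile[a + 1])
      break
    }
  }
  if (is.na(left) || is.na(right)) {
    return(structure(NA_real_, unbounded = TRUE))
  }
  (right - left) * step
}

# Otsu threshold of a numeric vector, delegating the histogram split to
# EBImage after rescaling to [0, 1].
otsu_split <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) {
    return(structure(r[1], degenerate = TRUE))
  }
  u <- (x - r[1]) / diff(r)
  thr <- EBImage::otsu(EBImage::Image(matrix(u, ncol = 1)),
                       range = c(0, 1), levels = levels)
  thr * diff(r) + r[1]
}

# evaluate a deterministic block under an optional seed
with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
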