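# Rendering of light-field camera frames from voxelized phantoms, and
# stroboscopic flow sequences.

# cached padded-plane OTFs of a PSF stack (shared by rendering and
# Richardson-Lucy deconvolution: both apply the same forward operator)
psf_otfs <- function(psf, np) {
  env <- attr(psf, "otf_env")
  if (is.null(env)) env <- new.env(parent = emptyenv())
  key <- paste0("np", np)
  if (!is.null(env[[key]])) return(env[[key]])
  nz <- dim(psf)[3]
  otfs <- vector("list", nz)
  for (iz in seq_len(nz))
    otfs[[iz]] <- stats::fft(kernel_to_origin(psf[, , iz], np))
  env[[key]] <- otfs
  otfs
}

# forward light-field operator: per-plane 2D convolution with the matching
# PSF plane, summed over z. Returns the noise-free sensor image, same size
# as the lateral volume grid.
lf_forward <- function(volume, psf, np = NULL) {
  dv <- dim(volume)
  dp <- dim(psf)
  if (dv[3] != dp[3])
    stop("shape error: volume has ", dv[3], " planes but the PSF stack has ",
         dp[3], call. = FALSE)
  if (is.null(np)) np <- next_fast_size(max(dv[1:2]) + max(dp[1:2]) - 1L)
  otfs <- psf_otfs(psf, np)
  acc <- matrix(0i, np, np)
  for (iz in seq_len(dv[3])) {
    pl <- volume[, , iz]
    if (any(pl != 0)) acc <- acc + stats::fft(pad_matrix(pl, np)) * otfs[[iz]]
  }
  out <- Re(stats::fft(acc, inverse = TRUE)) / np^2
  out[seq_len(dv[1]), seq_len(dv[2])]
}

# adjoint of lf_forward (per-plane correlation with the PSF planes)
lf_adjoint <- function(image, psf, nz, np = NULL) {
  di <- dim(image)
  dp <- dim(psf)
  if (is.null(np)) np <- next_fast_size(max(di) + max(dp[1:2]) - 1L)
  otfs <- psf_otfs(psf, np)
  fr <- stats::fft(pad_matrix(image, np))
  out <- array(0, c(di[1], di[2], nz))
  for (iz in seq_len(nz)) {
    b <- Re(stats::fft(fr * Conj(otfs[[iz]]), inverse = TRUE)) / np^2
    out[, , iz] <- b[seq_len(di[1]), seq_len(di[2])]
  }
  out
}

# 1D motion-blur kernel (box of physical length len_um along the flow axis,
# fractional ends, unit sum)
motion_kernel <- function(len_um, voxel_um) {
  L <- len_um / voxel_um
  if (L <= 1) return(1)   # streak contained in one voxel
  jmax <- ceiling((L - 1) / 2)
  j <- -jmax:jmax
  w <- pmax(0, pmin(j + 0.5, L / 2) - pmax(j - 0.5, -L / 2))
  w <- w[w > 0]
  w / sum(w)
}

# convolve each volume plane along the flow axis (columns = x) with a 1D
# kernel, by shifted weighted sums
blur_along_flow <- function(volume, kern) {
  if (length(kern) == 1) return(volume)
  nk <- length(kern)
  c0 <- (nk + 1) / 2
  out <- array(0, dim(volume))
  nx <- dim(volume)[2]
  for (k in seq_len(nk)) {
    sh <- round(k - c0)
    src <- seq_len(nx) - sh
    ok <- src >= 1 & src <= nx
    out[, which(ok), ] <- out[, which(ok), ] + kern[k] * volume[, src[ok], ]
  }
  out
}

#' Apply the sCMOS noise model to a noise-free image
#'
#' @param signal noise-free expected signal (intensity units)
#' @param noise a [noise_model()]; `NULL` returns the signal unchanged
#' @param seed optional seed overriding the model's own
#' @return numeric matrix of camera counts; 16-bit saturation is flagged via
#'   attribute `saturated` rather than wrapped
#' @export
apply_noise <- function(signal, noise = noise_model(), seed = NULL) {
  if (is.null(noise)) return(signal)
  stopifnot(inherits(noise, "noise_model"))
  if (is.null(seed)) seed <- noise$seed
  with_opt_seed(seed, {
    s <- pmax(signal, 0)
    out <- if (is.finite(noise$photon_scale)) {
      matrix(stats::rpois(length(s), s * noise$photon_scale),
             nrow(s), ncol(s)) / noise$photon_scale
    } else s
    out <- out + noise$offset
    if (noise$read_sigma > 0)
      out <- out + matrix(stats::rnorm(length(s), 0, noise$read_sigma),
                          nrow(s), ncol(s))
    out <- round(pmax(out, 0))
    sat <- any(out > 65535)
    out[out > 65535] <- 65535
    structure(out, saturated = sat)
  })
}

#' Render one light-field camera frame
#'
#' Applies, in order: motion blur (a line kernel of physical length
#' `flow_speed * strobe_duration` along the flow axis), the light-field
#' optical blur (per-plane 2D convolution with the matching PSF plane,
#' summed over depth), and the sCMOS noise model.
#'
#' @param volumes a single 3D density array or a named per-channel list as
#'   returned by [voxelize()]; lateral grid must match the PSF planes
#' @param psf a [build_psf_stack()] result for the rendered channel
#' @param flow a [flow_config()]; `NULL` disables motion blur
#' @param noise a [noise_model()]; `NULL` renders noise-free
#' @param channel channel to render when `volumes` is a per-channel list
#' @param seed optional RNG seed for the noise
#' @return matrix of camera counts with attributes `channel` and
#'   `saturated`
#' @export
render_lightfield_frame <- function(volumes, psf, flow = flow_config(),
                                    noise = noise_model(), channel = 1L,
                                    seed = NULL) {
  vol <- if (is.list(volumes)) volumes[[as.character(channel)]] else volumes
  if (is.null(vol)) {
    d <- dim(psf)
    vol <- array(0, c(d[1], d[2], d[3]))
  }
  if (!all(dim(vol)[1:2] == dim(psf)[1:2]))
    stop("shape error: volume lateral grid ", paste(dim(vol)[1:2], collapse = "x"),
         " does not match PSF ", paste(dim(psf)[1:2], collapse = "x"),
         call. = FALSE)
  if (!is.null(flow)) {
    len <- flow$flow_speed * flow$strobe_duration * 1e-3  # mm/s * us -> um
    vol <- blur_along_flow(vol, motion_kernel(len, attr(psf, "voxel")[1]))
  }
  # densities (photons/um^3) -> expected photons per voxel
  img <- lf_forward(vol * prod(attr(psf, "voxel")), psf)
  out <- apply_noise(img, noise, seed)
  attr(out, "channel") <- as.integer(channel)
  out
}

#' Simulate a stroboscopic light-field frame sequence
#'
#' Objects traverse the field of view at the configured flow speed; each
#' strobe samples their positions at its timestamp and renders one frame.
#' In two-color mode frames strictly alternate channels, the second strobe
#' of each pair firing `t2` microseconds after the first so that both
#' colors see (almost) the same object positions. Frames with no object in
#' the field occur naturally and are labeled blank in the ground truth.
#'
#' @param objects list of [phantom_object]s; each object is assigned an
#'   arrival time uniform over the sequence duration
#' @param psf a [build_psf_stack()] result, or a per-channel named list
#' @param flow a [flow_config()]
#' @param noise a [noise_model()]; `NULL` for noise-free frames
#' @param n_frames number of camera frames
#' @param two_color alternate two emission channels
#' @param seed RNG seed controlling arrivals and noise (bit-reproducible)
#' @return object of class `frame_sequence`: list with `frames` (16-bit
#'   count matrices), `info` (frame, channel, time_ms, n_objects), `truth`
#'   (frame, object, channel, x/y/z position at strobe time, plus the
#'   generator feature record index), `voxel`, `fov_um`, `flow`
#' @export
simulate_sequence <- function(objects, psf, flow = flow_config(),
                              noise = noise_model(), n_frames = 20,
                              two_color = FALSE, seed = 1) {
  stopifnot(n_frames >= 1)
  psfs <- if (inherits(psf, "psf_stack")) list(`1` = psf) else psf
  p1 <- psfs[[1]]
  d <- dim(p1)
  voxel <- attr(p1, "voxel")
  fov_x <- d[2] * voxel[1]
  if (flow$core_width > elemental_fov_from_psf(p1))
    warning("flow core is wider than the elemental field of view",
            call. = FALSE)
  v_um_ms <- flow$flow_speed                       # mm/s == um/ms
  dur_ms <- if (two_color) ceiling(n_frames / 2) * 2 * flow$t1
            else n_frames * flow$t1
  with_opt_seed(seed, {
    arrivals <- if (length(objects))
      stats::runif(length(objects), 0, dur_ms) else numeric(0)
    frame_time <- function(f) {
      if (!two_color) (f - 1) * flow$t1
      else (ceiling(f / 2) - 1) * 2 * flow$t1 +
        (1 - f %% 2) * flow$t2 * 1e-3
    }
    # acquisition channels (indices into the phantom components and the
    # psf list), distinct from the wavelength index stored in the PSF
    channels <- if (two_color) rep(c(1L, 2L), length.out = n_frames)
                else rep(1L, n_frames)
    frames <- vector("list", n_frames)
    info <- data.frame(frame = seq_len(n_frames), channel = channels,
                       time_ms = vapply(seq_len(n_frames), frame_time,
                                        numeric(1)),
                       n_objects = 0L)
    truth <- list()
    noise_seeds <- if (!is.null(noise))
      sample.int(.Machine$integer.max, n_frames) else rep(NA_integer_, n_frames)
    for (f in seq_len(n_frames)) {
      t <- info$time_ms[f]
      ch <- info$channel[f]
      pk <- psfs[[as.character(ch)]] %||% psfs[[1]]
      acc <- NULL
      for (oi in seq_along(objects)) {
        x <- (t - arrivals[oi]) * v_um_ms
        if (abs(x) > fov_x / 2) next
        ob <- objects[[oi]]
        ob$center <- ob$center + c(x, 0, 0)
        vv <- voxelize(ob, voxel, c(d[1], d[2], d[3]), clip = TRUE)
        vch <- vv[[as.character(ch)]]
        if (!is.null(vch)) acc <- if (is.null(acc)) vch else acc + vch
        truth[[length(truth) + 1L]] <-
          data.frame(frame = f, object = oi, channel = ch,
                     x_um = ob$center[1], y_um = ob$center[2],
                     z_um = ob$center[3], kind = ob$kind,
                     in_channel = !is.null(vch))
        info$n_objects[f] <- info$n_objects[f] + 1L
      }
      if (is.null(acc)) acc <- array(0, d)
      frames[[f]] <- render_lightfield_frame(acc, pk, flow, noise,
                                             channel = ch,
                                             seed = noise_seeds[f])
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(frame = integer(0), object = integer(0),
                             channel = integer(0), x_um = numeric(0),
                             y_um = numeric(0), z_um = numeric(0),
                             kind = character(0), in_channel = logical(0))
    structure(list(frames = frames, info = info, truth = truth,
                   objects = objects, voxel = voxel, fov_um = fov_x,
                   flow = flow, two_color = two_color, seed = seed),
              class = "frame_sequence")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample-side field of view implied by a PSF stack's lateral grid
elemental_fov_from_psf <- function(psf) {
  dim(psf)[2] * attr(psf, "voxel")[1]
}

#' @export
print.frame_sequence <- function(x, ...) {
  occ <- length(unique(x$truth$frame))
  cat(sprintf("<frame_sequence> %d frames (%d occupied), %s, %d x %d px\n",
              length(x$frames), occ,
              if (isTRUE(x$two_color)) "two-color" else "single color",
              nrow(x$frames[[1]]), ncol(x$frames[[1]])))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)
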