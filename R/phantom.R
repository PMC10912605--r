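# Ground-truth phantom objects: fluorescent microspheres and synthetic
# cells (membrane/nucleus shells, organelle puncta, apoptotic micronuclei,
# reporter expression), with partial-volume voxelization.

#' Flow and stroboscopic timing configuration
#'
#' Describes the hydrodynamically focused flow and the stroboscopic
#' illumination timing: a global camera exposure `t0` within which strobes
#' of `strobe_duration` fire, the frame period `t1 = 1/frame_rate`, and the
#' inter-strobe interval `t2` separating the two color strobes of a
#' two-color pair.
#'
#' @param flow_speed flow speed along the flow axis (mm/s)
#' @param strobe_duration strobe length (us)
#' @param frame_rate camera frame rate (fps)
#' @param t0 global camera exposure (ms)
#' @param t2 inter-strobe interval between the two colors of a pair (us)
#' @param core_width width of the hydrodynamically focused sample core (um)
#' @param channel_depth depth of the microfluidic channel (um)
#' @param objects_per_second arrival rate of objects through the field
#' @return object of class `flow_config`; `t1` (ms) is derived from
#'   `frame_rate`
#' @export
flow_config <- function(flow_speed = 4.5, strobe_duration = 100,
                        frame_rate = 200, t0 = 5, t2 = 200,
                        core_width = 75, channel_depth = 30,
                        objects_per_second = 2000) {
  t1 <- 1000 / frame_rate
  if (strobe_duration * 1e-3 > t0)
    stop("strobe_duration exceeds the global exposure t0", call. = FALSE)
  if (any(c(flow_speed, frame_rate, t0, core_width, channel_depth) <= 0) ||
      strobe_duration <= 0 || t2 < 0)
    stop("flow_config parameters must be positive", call. = FALSE)
  structure(list(flow_speed = flow_speed, strobe_duration = strobe_duration,
                 frame_rate = frame_rate, t0 = t0, t1 = t1, t2 = t2,
                 core_width = core_width, channel_depth = channel_depth,
                 objects_per_second = objects_per_second),
            class = "flow_config")
}

#' sCMOS noise model
#'
#' Shot noise plus pixel read noise: the noise-free expected signal `s`
#' (intensity units) is converted to photons with `photon_scale` expected
#' photons per intensity unit, Poisson-sampled, scaled back, then offset and
#' Gaussian read noise are added:
#' `counts = Pois(s * photon_scale) / photon_scale + offset + N(0, sigma)`.
#' As `photon_scale -> Inf` with `read_sigma = 0` the model becomes
#' deterministic (noise-free rendering).
#'
#' @param photon_scale expected photons per intensity unit (`Inf` disables
#'   shot noise)
#' @param read_sigma read noise standard deviation (counts)
#' @param offset camera baseline offset (counts)
#' @param seed optional RNG seed applied when the model is used
#' @export
noise_model <- function(photon_scale = 1, read_sigma = 2, offset = 100,
                        seed = NULL) {
  stopifnot(photon_scale > 0, read_sigma >= 0, offset >= 0)
  structure(list(photon_scale = photon_scale, read_sigma = read_sigma,
                 offset = offset, seed = seed),
            class = "noise_model")
}

# a phantom component: one labeled geometric piece in one channel
component <- function(label, shape, channel, density, d = NULL,
                      thickness = NULL, centers = NULL, d_each = NULL) {
  stopifnot(shape %in% c("sphere", "shell", "puncta"), density >= 0)
  list(label = label, shape = shape, channel = as.integer(channel),
       density = density, d = d, thickness = thickness,
       centers = centers, d_each = d_each)
}

new_phantom_object <- function(kind, center, components, truth) {
  structure(list(kind = kind, center = center, components = components,
                 truth = truth),
            class = "phantom_object")
}

#' @export
print.phantom_object <- function(x, ...) {
  cat(sprintf("<phantom_object> %s at (%.1f, %.1f, %.1f) um, %d component(s)\n",
              x$kind, x$center[1], x$center[2], x$center[3],
              length(x$components)))
  invisible(x)
}

# analytic volume of one component (um^3)
component_volume <- function(comp) {
  vol_sphere <- function(d) pi / 6 * d^3
  switch(comp$shape,
         sphere = vol_sphere(comp$d),
         shell = vol_sphere(comp$d) - vol_sphere(comp$d - 2 * comp$thickness),
         puncta = sum(vol_sphere(comp$d_each)))
}

#' Mixture of fluorescent microspheres in the flow core
#'
#' Emulates a bead mixture (e.g. diameters 0.2, 1, 2 and 4 um) flowing in
#' the hydrodynamically focused core. Lateral positions are uniform within
#' the core, axial positions uniform over the channel depth truncated to
#' `z_limit` (the axial capture range of the point-spread function stack).
#' Bead fluorescence is proportional to volume: intensity density is
#' constant across diameters.
#'
#' @param diameters bead diameters (um)
#' @param counts number of beads per diameter class
#' @param intensity_scale fluorophore density (expected photons per um^3 at
#'   unit photon scale)
#' @param flow a [flow_config()]
#' @param channel emission channel of the beads
#' @param z_limit axial placement half-range (um); beads are placed within
#'   `+/- min(z_limit, channel_depth/2)`
#' @param lateral_limit optional half-width (um) overriding
#'   `core_width / 2` for small simulated fields
#' @param seed RNG seed
#' @return list of [phantom_object]s with ground-truth class labels
#' @export
make_bead_mixture <- function(diameters = c(0.2, 1, 2, 4),
                              counts = c(10, 10, 10, 10),
                              intensity_scale = 2e6,
                              flow = flow_config(),
                              channel = 1L, z_limit = 2,
                              lateral_limit = NULL, seed = NULL) {
  stopifnot(length(diameters) == length(counts), all(diameters > 0),
            all(counts >= 0))
  half_y <- if (is.null(lateral_limit)) flow$core_width / 2 else lateral_limit
  if (any(diameters > 2 * half_y) || any(diameters > flow$core_width))
    stop("bead diameter exceeds the flow core width", call. = FALSE)
  half_z <- min(z_limit, flow$channel_depth / 2)
  with_opt_seed(seed, {
    objs <- list()
    for (k in seq_along(diameters)) {
      if (counts[k] == 0) next
      for (i in seq_len(counts[k])) {
        ctr <- c(0, stats::runif(1, -half_y, half_y),
                 stats::runif(1, -half_z, half_z))
        d <- diameters[k]
        comp <- component("bead", "sphere", channel, intensity_scale, d = d)
        truth <- list(class = k, diameter = d,
                      volume = component_volume(comp),
                      total_photons = component_volume(comp) * intensity_scale)
        objs[[length(objs) + 1L]] <-
          new_phantom_object("bead", ctr, list(comp), truth)
      }
    }
    objs
  })
}

#' Synthetic cell phantom
#'
#' Generates one cell with per-channel components and a ground-truth feature
#' record. Kinds:
#' \describe{
#'   \item{peroxisome}{GFP-like puncta scattered in the cell body
#'     (channel 1).}
#'   \item{membrane_nucleus}{a membrane shell (channel 1) around a solid
#'     nucleus (channel 2); ground truth carries the nuclear-to-cell volume
#'     ratio `(d_nuc/d_cell)^3`.}
#'   \item{two_color_organelle}{mitochondria puncta (channel 1) and
#'     peroxisome puncta (channel 2).}
#'   \item{apoptotic}{`k_micronuclei` nuclear fragments (channel 2) whose
#'     mean distance to their common centroid equals `dispersion` exactly,
#'     plus mitochondria puncta (channel 1); `k_micronuclei = 1` with
#'     `dispersion = 0` is an intact nucleus.}
#'   \item{reporter}{a cell body (channel 1) and a reporter fill
#'     (channel 2) whose density is `positive_ratio`-fold higher when
#'     `positive = TRUE`.}
#' }
#'
#' @param kind one of `"peroxisome"`, `"membrane_nucleus"`,
#'   `"two_color_organelle"`, `"apoptotic"`, `"reporter"`
#' @param params named list overriding kind-specific defaults (see Details
#'   in the package vignette); common entries: `d_cell`, `d_nuc`,
#'   `thickness`, `n_puncta`, `d_punctum`, `k_micronuclei`, `dispersion`,
#'   `positive`, `density`
#' @param center object center in the field (um)
#' @param seed RNG seed
#' @return a [phantom_object] whose `truth` element holds the generator's
#'   feature record (volumes, N:C ratio, micronuclei metrics, reporter flag)
#' @export
make_cell_phantom <- function(kind = c("peroxisome", "membrane_nucleus",
                                       "two_color_organelle", "apoptotic",
                                       "reporter"),
                              params = list(), center = c(0, 0, 0),
                              seed = NULL) {
  kind <- match.arg(kind)
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  with_opt_seed(seed, {
    comps <- list()
    truth <- list(kind = kind)
    d_cell <- p("d_cell", switch(kind, membrane_nucleus = 7.99,
                                 apoptotic = 9, 8))
    if (d_cell <= 0) stop("cell diameter must be positive", call. = FALSE)
    truth$d_cell <- d_cell

    scatter_in_ball <- function(n, r_max) {
      # uniform positions in a ball of radius r_max
      u <- matrix(stats::rnorm(3 * n), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      u * r_max * stats::runif(n)^(1 / 3)
    }

    if (kind == "peroxisome") {
      n <- p("n_puncta", 30); dp <- p("d_punctum", 0.4)
      ctrs <- scatter_in_ball(n, d_cell / 2 - dp / 2)
      comps <- list(component("peroxisome", "puncta", 1L,
                              p("density", 2e5), centers = ctrs,
                              d_each = rep(dp, n)))
    } else if (kind == "membrane_nucleus") {
      d_nuc <- p("d_nuc", 6.57); th <- p("thickness", 0.55)
      if (d_nuc > d_cell)
        stop("geometry error: nucleus larger than cell", call. = FALSE)
      comps <- list(
        component("membrane", "shell", 1L, p("density", 2e4),
                  d = d_cell, thickness = th),
        component("nucleus", "sphere", 2L, p("density", 2e4), d = d_nuc))
      truth$d_nuc <- d_nuc
      truth$nc_ratio <- (d_nuc / d_cell)^3
    } else if (kind == "two_color_organelle") {
      nm <- p("n_mito", 40); dm <- p("d_mito", 0.6)
      np <- p("n_puncta", 30); dp <- p("d_punctum", 0.4)
      comps <- list(
        component("mitochondria", "puncta", 1L, p("density", 2e5),
                  centers = scatter_in_ball(nm, d_cell / 2 - dm / 2),
                  d_each = rep(dm, nm)),
        component("peroxisome", "puncta", 2L, p("density", 2e5),
                  centers = scatter_in_ball(np, d_cell / 2 - dp / 2),
                  d_each = rep(dp, np)))
    } else if (kind == "apoptotic") {
      k <- p("k_micronuclei", 1L)
      disp <- p("dispersion", 0)
      d_nuc <- p("d_nuc", 6)
      if (k < 1) stop("need at least one nuclear component", call. = FALSE)
      # fragmented nuclei condense: total nuclear volume shrinks
      vol_total <- pi / 6 * d_nuc^3 * if (k > 1) p("condensation", 0.7) else 1
      vols <- rep(vol_total / k, k)
      if (k > 1) {
        vols <- vols * stats::runif(k, 0.8, 1.2)
        vols <- vols / sum(vols) * vol_total
      }
      d_each <- (6 * vols / pi)^(1 / 3)
      if (k == 1 || disp == 0) {
        offs <- matrix(0, k, 3)
        disp_true <- 0
      } else {
        offs <- matrix(stats::rnorm(3 * k), ncol = 3)
        offs <- sweep(offs, 2, colMeans(offs))       # centroid at origin
        dmean <- mean(sqrt(rowSums(offs^2)))
        if (dmean == 0) stop("degenerate micronuclei offsets", call. = FALSE)
        offs <- offs * disp / dmean                  # mean distance == disp
        disp_true <- disp
      }
      if (max(sqrt(rowSums(offs^2)) + d_each / 2) > d_cell / 2)
        stop("micronuclei do not fit inside the cell; reduce dispersion",
             call. = FALSE)
      nm <- p("n_mito", 30); dm <- p("d_mito", 0.6)
      comps <- list(
        component("mitochondria", "puncta", 1L, p("density", 2e5),
                  centers = scatter_in_ball(nm, d_cell / 2 - dm / 2),
                  d_each = rep(dm, nm)),
        component("micronuclei", "puncta", 2L, p("density", 2e4),
                  centers = offs, d_each = d_each))
      truth$micronuclei <- list(count = as.integer(k),
                                mean_volume = mean(vols),
                                mean_centroid_distance = disp_true)
    } else if (kind == "reporter") {
      pos <- isTRUE(p("positive", FALSE))
      base <- p("density", 2e3)
      ratio <- p("positive_ratio", 10)
      comps <- list(
        component("body", "sphere", 1L, p("body_density", 1e4), d = d_cell),
        component("reporter", "sphere", 2L, base * if (pos) ratio else 1,
                  d = d_cell))
      truth$positive <- pos
    }
    truth$volumes <- vapply(comps, component_volume, numeric(1))
    names(truth$volumes) <- vapply(comps, `[[`, "", "label")
    new_phantom_object(kind, center, comps, truth)
  })
}

# ---------------------------------------------------------------------------
# voxelization

# partial-volume fraction of voxels covered by a sphere; voxel centers given
# as coordinate vectors, anisotropic voxels supported
sphere_fractions <- function(xs, ys, zs, center, radius, voxel, super = 4L) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  dx2 <- (xs - center[1])^2
  dy2 <- (ys - center[2])^2
  dz2 <- (zs - center[3])^2
  # distance from sphere surface classifies voxels inside / outside / boundary
  half_diag <- sqrt(sum((voxel / 2)^2))
  dist <- sqrt(outer(outer(dy2, dx2, "+"), dz2, "+"))  # [y, x, z]
  frac <- array(0, c(ny, nx, nz))
  frac[dist <= radius - half_diag] <- 1
  bnd <- which(abs(dist - radius) < half_diag)
  if (length(bnd)) {
    s <- as.integer(super)
    offs1 <- ((seq_len(s) - 0.5) / s - 0.5)
    og <- expand.grid(oy = offs1 * voxel[2], ox = offs1 * voxel[1],
                      oz = offs1 * voxel[3])
    idx <- arrayInd(bnd, c(ny, nx, nz))
    bx <- xs[idx[, 2]] - center[1]
    by <- ys[idx[, 1]] - center[2]
    bz <- zs[idx[, 3]] - center[3]
    inside <- integer(length(bnd))
    for (o in seq_len(nrow(og))) {
      inside <- inside +
        ((bx + og$ox[o])^2 + (by + og$oy[o])^2 + (bz + og$oz[o])^2 <= radius^2)
    }
    frac[bnd] <- inside / nrow(og)
  }
  frac
}

#' Rasterize a phantom object into per-channel density volumes
#'
#' Converts the analytic geometry into voxel densities with partial-volume
#' handling: boundary voxels are supersampled so that the integrated density
#' matches the analytic component volume to better than 1%.
#'
#' @param object a [phantom_object]
#' @param voxel_size voxel edge lengths in um, scalar or `c(dx, dy, dz)`
#' @param grid_shape `c(rows, cols, planes)` of the output volumes; the
#'   field center (optical axis) sits at voxel `floor(n/2) + 1` along each
#'   axis
#' @param super supersampling factor per axis for boundary voxels
#' @param clip allow geometry extending beyond the grid (rasterizing only
#'   the inside part); the default raises a clipping error instead, so the
#'   integrated density always matches the analytic volume
#' @return named list of 3D arrays (one per channel index present), each
#'   with attribute `voxel`
#' @export
voxelize <- function(object, voxel_size, grid_shape, super = 4L,
                     clip = FALSE) {
  stopifnot(inherits(object, "phantom_object"))
  voxel <- if (length(voxel_size) == 1) rep(voxel_size, 3) else voxel_size
  stopifnot(length(voxel) == 3, all(voxel > 0), length(grid_shape) == 3)
  ny <- grid_shape[1]; nx <- grid_shape[2]; nz <- grid_shape[3]
  xs <- ((1:nx) - grid_center(nx)) * voxel[1]
  ys <- ((1:ny) - grid_center(ny)) * voxel[2]
  zs <- ((1:nz) - grid_center(nz)) * voxel[3]
  extent <- c(range(xs), range(ys), range(zs))
  vols <- list()
  vol_voxel <- prod(voxel)
  add <- function(ch, arr) {
    key <- as.character(ch)
    if (is.null(vols[[key]])) vols[[key]] <<- array(0, c(ny, nx, nz))
    vols[[key]] <<- vols[[key]] + arr
  }
  for (comp in object$components) {
    spheres <- switch(comp$shape,
      sphere = list(list(c = object$center, r = comp$d / 2, w = 1)),
      shell = list(list(c = object$center, r = comp$d / 2, w = 1),
                   list(c = object$center, r = comp$d / 2 - comp$thickness,
                        w = -1)),
      puncta = lapply(seq_len(nrow(comp$centers)), function(i)
        list(c = object$center + comp$centers[i, ],
             r = comp$d_each[i] / 2, w = 1)))
    for (sp in spheres) {
      if (!clip &&
          (sp$c[1] - sp$r < extent[1] - voxel[1] / 2 ||
          sp$c[1] + sp$r > extent[2] + voxel[1] / 2 ||
          sp$c[2] - sp$r < extent[3] - voxel[2] / 2 ||
          sp$c[2] + sp$r > extent[4] + voxel[2] / 2 ||
          sp$c[3] - sp$r < extent[5] - voxel[3] / 2 ||
          sp$c[3] + sp$r > extent[6] + voxel[3] / 2))
        stop("clipping error: object extends beyond the voxel grid",
             call. = FALSE)
      fr <- sphere_fractions(xs, ys, zs, sp$c, sp$r, voxel, super)
      add(comp$channel, sp$w * comp$density * fr)
    }
  }
  lapply(vols, function(v) structure(pmax(v, 0), voxel = voxel))
}
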