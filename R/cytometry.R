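# 3D single-object feature extraction and population statistics:
# segmentation, FWHM and volume measures, ellipsoid moment fits, N:C
# ratios, micronuclei dispersion, enclosure fractions, mixture-model
# population counts and gating.

#' Segment objects in a reconstructed volume
#'
#' Global threshold (Otsu by default, or a fraction of the maximum),
#' 26-connectivity 3D connected components (via the voxel adjacency graph),
#' and a minimum-size filter. Each component yields one feature record.
#'
#' @param volume a `recon_volume` or plain nonnegative 3D array
#' @param method `"otsu"` or `"fraction"` (threshold at
#'   `fraction * max(volume)`, the parameter-light choice for beads)
#' @param fraction fraction of the maximum for `method = "fraction"`
#' @param min_size minimum component size (voxels)
#' @param exclude_border drop objects touching the first/last column along
#'   the flow axis (partial transits with truncated volume and intensity,
#'   the usual border-object exclusion of imaging cytometry)
#' @param voxel voxel sizes in um (taken from the `recon_volume` attribute
#'   when present)
#' @param channel channel label stored in the records
#' @return list with `labels` (integer array, 0 = background) and `records`
#'   (data.frame, one row per object: id, channel, n_voxels, volume_um3,
#'   eq_diameter_um, total_intensity, centroid_x/y/z_um, ra/rb/rc_um)
#' @export
segment_objects <- function(volume, method = c("otsu", "fraction"),
                            fraction = 0.2, min_size = 5L,
                            exclude_border = FALSE,
                            voxel = NULL, channel = NA_integer_) {
  method <- match.arg(method)
  if (is.null(voxel)) voxel <- attr(volume, "voxel")
  if (is.null(voxel)) voxel <- c(1, 1, 1)
  if (is.null(channel) || length(channel) == 0) channel <- NA_integer_
  if (!is.na(attr(volume, "channel") %||% NA) && is.na(channel))
    channel <- attr(volume, "channel")
  v <- unclass(volume)
  attributes(v) <- list(dim = dim(volume))
  empty <- list(labels = array(0L, dim(v)), records = empty_records())
  if (all(v <= 0)) return(empty)
  thr <- switch(method,
                otsu = otsu_split(as.numeric(v[v > 0])),
                fraction = fraction * max(v))
  fg <- which(v > thr)
  if (!length(fg)) return(empty)
  labs_fg <- label_components_26(fg, dim(v))
  labels <- array(0L, dim(v))
  labels[fg] <- labs_fg
  # minimum-size filter, relabeled consecutively
  sizes <- tabulate(labs_fg)
  keep <- which(sizes >= min_size)
  if (exclude_border) {
    cols <- arrayInd(fg, dim(v))[, 2]
    at_border <- unique(labs_fg[cols == 1L | cols == dim(v)[2]])
    keep <- setdiff(keep, at_border)
  }
  if (!length(keep)) return(empty)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  labels[fg] <- remap[labs_fg]
  records <- do.call(rbind, lapply(seq_along(keep), function(newid) {
    idx <- fg[labels[fg] == newid]
    object_record(idx, v, dim(v), voxel, newid, channel)
  }))
  list(labels = labels, records = records)
}

empty_records <- function() {
  data.frame(id = integer(0), channel = integer(0), n_voxels = integer(0),
             volume_um3 = numeric(0), eq_diameter_um = numeric(0),
             total_intensity = numeric(0),
             centroid_x_um = numeric(0), centroid_y_um = numeric(0),
             centroid_z_um = numeric(0),
             ra_um = numeric(0), rb_um = numeric(0), rc_um = numeric(0))
}

# 26-connectivity connected components of foreground voxels, via igraph on
# the voxel adjacency graph
label_components_26 <- function(fg, dims) {
  pos <- integer(prod(dims))
  pos[fg] <- seq_along(fg)
  ai <- arrayInd(fg, dims)
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & (offs$dx > 0 |
            (offs$dx == 0 & offs$dy > 0))), ]   # half-space: each pair once
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    y2 <- ai[, 1] + offs$dy[k]
    x2 <- ai[, 2] + offs$dx[k]
    z2 <- ai[, 3] + offs$dz[k]
    ok <- y2 >= 1 & y2 <= dims[1] & x2 >= 1 & x2 <= dims[2] &
      z2 >= 1 & z2 <= dims[3]
    if (!any(ok)) next
    lin2 <- y2[ok] + (x2[ok] - 1L) * dims[1] + (z2[ok] - 1L) * dims[1] * dims[2]
    nb <- pos[lin2]
    hit <- nb > 0
    if (any(hit))
      edges[[length(edges) + 1L]] <-
        cbind(which(ok)[hit], nb[hit])
  }
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  } else {
    g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  }
  igraph::components(g)$membership
}

object_record <- function(idx, v, dims, voxel, id, channel) {
  ai <- arrayInd(idx, dims)
  w <- v[idx]
  # physical coordinates of voxel centers (x = cols, y = rows, z = planes)
  xyz <- cbind((ai[, 2] - grid_center(dims[2])) * voxel[1],
               (ai[, 1] - grid_center(dims[1])) * voxel[2],
               (ai[, 3] - grid_center(dims[3])) * voxel[3])
  ctr <- colSums(xyz * w) / sum(w)
  vol <- length(idx) * prod(voxel)
  radii <- if (length(idx) >= 10) ellipsoid_radii(xyz, w)
           else rep(NA_real_, 3)
  data.frame(id = id, channel = channel, n_voxels = length(idx),
             volume_um3 = vol, eq_diameter_um = equivalent_diameter(vol),
             total_intensity = sum(w),
             centroid_x_um = ctr[1], centroid_y_um = ctr[2],
             centroid_z_um = ctr[3],
             ra_um = radii[1], rb_um = radii[2], rc_um = radii[3])
}

#' Equivalent spherical diameter from a volume
#'
#' @param volume_um3 object volume(s) in um^3
#' @return diameter(s) `(6 V / pi)^(1/3)` in um
#' @export
equivalent_diameter <- function(volume_um3) {
  if (any(volume_um3 <= 0)) stop("volume must be positive", call. = FALSE)
  (6 * volume_um3 / pi)^(1 / 3)
}

# intensity-weighted second-moment ellipsoid radii (sorted descending); a
# uniform ball of radius R has position covariance R^2/5 per axis, hence
# radius = sqrt(5 * eigenvalue)
ellipsoid_radii <- function(xyz, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(xyz))
  ctr <- colSums(xyz * w) / sum(w)
  cc <- sweep(xyz, 2, ctr)
  cov <- crossprod(cc * sqrt(w / sum(w)))
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  r <- sqrt(5 * pmax(ev, 0))
  sort(r, decreasing = TRUE)
}

#' Ellipsoid fit of a segmented object
#'
#' Intensity-weighted second-moment fit: the radii are
#' `sqrt(5 * eigenvalues)` of the voxel-position covariance, sorted
#' `Ra >= Rb >= Rc` (the scaling under which a uniform ball of radius R
#' returns R on all axes).
#'
#' @param labels integer label array from [segment_objects()]
#' @param volume the intensity volume the labels came from
#' @param id object label to fit
#' @param voxel voxel sizes (um)
#' @return named vector `c(ra, rb, rc)` in um; `rc = 0` objects are
#'   degenerate (planar) and flagged with attribute `degenerate`
#' @export
fit_ellipsoid <- function(labels, volume, id = 1L, voxel = NULL) {
  if (is.null(voxel)) voxel <- attr(volume, "voxel") %||% c(1, 1, 1)
  idx <- which(labels == id)
  if (length(idx) < 10)
    stop("object must span at least 10 voxels", call. = FALSE)
  dims <- dim(labels)
  ai <- arrayInd(idx, dims)
  xyz <- cbind((ai[, 2] - grid_center(dims[2])) * voxel[1],
               (ai[, 1] - grid_center(dims[1])) * voxel[2],
               (ai[, 3] - grid_center(dims[3])) * voxel[3])
  r <- ellipsoid_radii(xyz, as.numeric(volume)[idx])
  names(r) <- c("ra", "rb", "rc")
  if (r[3] <= 0) attr(r, "degenerate") <- TRUE
  r
}

#' FWHM of a volume profile along one axis
#'
#' Extracts the 1D intensity profile through `point` along `axis` and
#' measures the half-maximum crossing distance by linear interpolation.
#'
#' @param volume 3D array (a `recon_volume` or plain array)
#' @param point voxel index `c(row, col, plane)` the profile passes through
#'   (e.g. the object maximum)
#' @param axis `"x"` (columns), `"y"` (rows) or `"z"` (planes)
#' @param voxel voxel sizes in um (from the volume attribute when present)
#' @return FWHM in nm; `NA` flagged `unbounded` when the profile does not
#'   fall below half maximum inside the volume
#' @export
measure_fwhm <- function(volume, point, axis = c("x", "y", "z"),
                         voxel = NULL) {
  axis <- match.arg(axis)
  if (is.null(voxel)) voxel <- attr(volume, "voxel") %||% c(1, 1, 1)
  d <- dim(volume)
  stopifnot(all(point >= 1), all(point <= d))
  prof <- switch(axis,
                 x = volume[point[1], , point[3]],
                 y = volume[, point[2], point[3]],
                 z = volume[point[1], point[2], ])
  step <- switch(axis, x = voxel[1], y = voxel[2], z = voxel[3])
  w <- fwhm_1d(as.numeric(prof), step)
  if (is.na(w)) return(structure(NA_real_, unbounded = TRUE))
  1000 * w
}

#' Nuclear-to-cytoplasmic volume ratio
#'
#' `V_nucleus / V_cell` from co-registered two-channel records. Records
#' with nuclear volume exceeding the cell volume are kept but flagged.
#'
#' @param cell_record,nucleus_record single rows of a
#'   [segment_objects()] record table (or any list with `volume_um3`)
#' @return ratio, with attribute `flagged = TRUE` when it exceeds 1
#' @export
nc_ratio <- function(cell_record, nucleus_record) {
  vc <- cell_record$volume_um3
  vn <- nucleus_record$volume_um3
  stopifnot(length(vc) == 1, length(vn) == 1, vc > 0, vn > 0)
  r <- vn / vc
  if (r > 1) structure(r, flagged = TRUE) else r
}

#' Micronuclei count, volume and dispersion
#'
#' For the nuclear-channel components of one cell: the component count,
#' the mean component volume, and the mean Euclidean distance between the
#' component centroids and their common (unweighted) centroid. An intact
#' nucleus is a single component and has distance exactly 0.
#'
#' @param records data.frame of nuclear-channel components of one cell
#'   (rows from [segment_objects()])
#' @return list `count`, `mean_volume_um3`, `mean_centroid_distance_um`
#' @export
micronuclei_metrics <- function(records) {
  if (nrow(records) < 1) stop("need at least one nuclear component",
                              call. = FALSE)
  ctrs <- as.matrix(records[, c("centroid_x_um", "centroid_y_um",
                                "centroid_z_um")])
  if (nrow(ctrs) == 1) {
    return(list(count = 1L, mean_volume_um3 = records$volume_um3,
                mean_centroid_distance_um = 0))
  }
  all_ctr <- colMeans(ctrs)
  dists <- sqrt(rowSums(sweep(ctrs, 2, all_ctr)^2))
  list(count = nrow(records), mean_volume_um3 = mean(records$volume_um3),
       mean_centroid_distance_um = mean(dists))
}

# Fibonacci-sphere directions plus the coordinate axes; used as the support
# directions of the hull-membership test
support_directions <- function(n = 362L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  rbind(dirs, diag(3), -diag(3))
}

# membership of query points in the convex hull of a point set, as an outer
# approximation by support-function half-spaces over fixed directions
in_hull_support <- function(query, hull_points, tol = 0) {
  dirs <- support_directions()
  ok <- rep(TRUE, nrow(query))
  for (i in seq_len(nrow(dirs))) {
    d <- dirs[i, ]
    h <- max(hull_points %*% d)                    # support value
    ok <- ok & (drop(query %*% d) <= h + tol)
  }
  ok
}

#' Fraction of mitochondrial volume enclosed by the micronuclei hull
#'
#' Operationalizes "enclosed within the micronuclei" as lying inside the 3D
#' convex hull of the micronuclei voxel set (evaluated as an intersection
#' of support half-spaces over a fixed set of directions, with half-voxel
#' tolerance). Returns
#' `V_enclosed / (V_micronuclei + V_mitochondria_total)`.
#'
#' @param mito_mask logical/numeric 3D array of mitochondria voxels
#' @param micronuclei_mask logical/numeric 3D array of micronuclei voxels
#' @param voxel voxel sizes in um
#' @return dimensionless fraction; 0 with attribute `flagged` when the
#'   micronuclei set is empty
#' @export
mito_enclosure_fraction <- function(mito_mask, micronuclei_mask,
                                    voxel = c(1, 1, 1)) {
  stopifnot(all(dim(mito_mask) == dim(micronuclei_mask)))
  dims <- dim(mito_mask)
  mito_idx <- which(mito_mask > 0)
  micro_idx <- which(micronuclei_mask > 0)
  if (!length(micro_idx))
    return(structure(0, flagged = "empty micronuclei set"))
  to_xyz <- function(idx) {
    ai <- arrayInd(idx, dims)
    cbind((ai[, 2] - grid_center(dims[2])) * voxel[1],
          (ai[, 1] - grid_center(dims[1])) * voxel[2],
          (ai[, 3] - grid_center(dims[3])) * voxel[3])
  }
  v_micro <- length(micro_idx) * prod(voxel)
  v_mito <- length(mito_idx) * prod(voxel)
  if (!length(mito_idx)) return(0)
  inside <- in_hull_support(to_xyz(mito_idx), to_xyz(micro_idx),
                            tol = sqrt(sum((voxel / 2)^2)))
  v_enc <- sum(inside) * prod(voxel)
  v_enc / (v_micro + v_mito)
}

#' Population structure of object features
#'
#' Gaussian-mixture fit (full covariance, BIC model selection over 1..6
#' components) on log10 volume and log10 total intensity; reports the
#' cluster count and per-cluster mean equivalent diameter, mean intensity
#' and size.
#'
#' @param records a [segment_objects()] record table (>= 2 rows)
#' @param max_components upper bound of the BIC search; additionally capped
#'   so that each candidate component keeps at least five records (small
#'   cohorts otherwise admit degenerate single-point components)
#' @return object of class `population_summary`: list with `n_clusters`,
#'   `clusters` (data.frame: cluster, n, mean_diameter_um,
#'   mean_volume_um3, mean_intensity), `bic`, `classification`
#' @export
population_count <- function(records, max_components = 6L) {
  stopifnot(nrow(records) >= 2)
  g_max <- max(1L, min(max_components, nrow(records) - 1L,
                       nrow(records) %/% 5L))
  x <- cbind(log10(records$volume_um3), log10(records$total_intensity))
  fit <- Mclust(x, G = seq_len(g_max), verbose = FALSE)
  cl <- fit$classification
  clusters <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    data.frame(cluster = k, n = sum(cl == k),
               mean_volume_um3 = mean(records$volume_um3[cl == k]),
               mean_diameter_um = mean(records$eq_diameter_um[cl == k]),
               mean_intensity = mean(records$total_intensity[cl == k]))
  }))
  structure(list(n_clusters = as.integer(fit$G), clusters = clusters,
                 bic = fit$BIC,
                 classification = cl),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> %d cluster(s)\n", x$n_clusters))
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Gaussian fit of an equivalent-diameter histogram
#'
#' Histograms the diameters with Freedman-Diaconis bins and least-squares
#' fits a Gaussian to the bin counts; falls back to the sample mean and
#' standard deviation (flagged) when the fit does not converge.
#'
#' @param diameters equivalent diameters (um), at least 10 values
#' @param breaks histogram rule or explicit breaks (default
#'   Freedman-Diaconis)
#' @return list `mean`, `sd`, `converged`
#' @export
gaussian_fit_diameter <- function(diameters, breaks = "FD") {
  if (length(diameters) < 10)
    stop("need at least 10 records for a histogram fit", call. = FALSE)
  h <- graphics::hist(diameters, breaks = breaks, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  start <- list(a = max(h$counts), mu = mean(diameters),
                s = max(stats::sd(diameters), 1e-3))
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * s^2)), data = df,
                        start = start,
                        lower = c(0, min(h$mids), 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(mean = mean(diameters), sd = stats::sd(diameters),
                converged = FALSE))
  cf <- stats::coef(fit)
  list(mean = unname(cf["mu"]), sd = abs(unname(cf["s"])), converged = TRUE)
}

#' Fraction of reporter-positive objects
#'
#' Gates object records on total reporter intensity. The default threshold
#' is an Otsu split of log10 intensity; an explicit threshold (on the raw
#' intensity scale) can be supplied instead.
#'
#' @param records record table with a `total_intensity` column
#' @param threshold optional explicit intensity threshold
#' @return percentage (0-100) of records above threshold; degenerate
#'   all-equal intensities are flagged
#' @export
positive_fraction <- function(records, threshold = NULL) {
  x <- records$total_intensity
  stopifnot(length(x) >= 1, all(x > 0))
  if (is.null(threshold)) {
    if (diff(range(x)) == 0)
      return(structure(0, flagged = "degenerate threshold: all intensities equal"))
    thr_log <- otsu_split(log10(x))
    threshold <- 10^thr_log
  }
  100 * mean(x > threshold)
}
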