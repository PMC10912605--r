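# File formats: multipage TIFF frames and volumes (16-bit raw counts,
# 32-bit float), JSON sidecar metadata and provenance logs, flat YAML-style
# run configuration.
#
# The TIFF library in use cannot write free-form description tags, so voxel
# sizes, scale factors and ground-truth tables travel in a JSON sidecar
# named `<file>.json` next to each TIFF.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a frame sequence as multipage 16-bit TIFF
#'
#' Frames are stored as 16-bit grayscale pages; channels, timestamps and
#' the ground-truth object table go to the JSON sidecar.
#'
#' @param seq a `frame_sequence`
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_frames <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  pages <- lapply(seq$frames, function(f) {
    m <- pmin(pmax(round(as.matrix(f)), 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  write_sidecar(path, list(type = "frame_sequence",
                           info = seq$info, truth = seq$truth,
                           voxel = as.numeric(seq$voxel),
                           fov_um = seq$fov_um,
                           two_color = isTRUE(seq$two_color),
                           seed = seq$seed))
  invisible(path)
}

#' Read a multipage TIFF frame sequence
#'
#' Accepts 8- or 16-bit grayscale multipage TIFFs in both native sensor
#' dialects (square frames, or 1024 x 900-style rectangular frames, which
#' are flagged for padding). When a JSON sidecar written by
#' [write_frames()] is present, channel labels, timestamps and ground truth
#' are restored.
#'
#' @param path TIFF file path
#' @return a `frame_sequence`; rectangular frames carry
#'   `needs_padding = TRUE` in the sequence
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path,
                               call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("I/O error reading ", path, ": ",
                           conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) != 2)
      stop("format error: expected single-channel grayscale pages",
           call. = FALSE)
    if (is.double(p) && any(p != round(p)))
      stop("format error: expected 8/16-bit integer grayscale data",
           call. = FALSE)
  }
  meta <- read_sidecar(path)
  n <- length(pages)
  info <- if (!is.null(meta$info)) as.data.frame(meta$info)
          else data.frame(frame = seq_len(n), channel = 1L,
                          time_ms = NA_real_, n_objects = NA_integer_)
  truth <- if (!is.null(meta$truth)) as.data.frame(meta$truth)
           else data.frame()
  rect <- nrow(pages[[1]]) != ncol(pages[[1]])
  structure(list(frames = lapply(pages, function(p) {
                   storage.mode(p) <- "numeric"; p
                 }),
                 info = info, truth = truth,
                 voxel = meta$voxel, fov_um = meta$fov_um,
                 flow = NULL, two_color = isTRUE(meta$two_color),
                 seed = meta$seed, needs_padding = rect),
            class = "frame_sequence")
}

#' Write a PSF stack or reconstructed volume as 32-bit float TIFF
#'
#' Pages are the axial planes, scaled to `[0, 1]` by the stack maximum; the
#' scale factor, voxel sizes, axial positions and channel metadata go to
#' the JSON sidecar so that [read_psf_stack()] restores the array exactly
#' (to float precision).
#'
#' @param x a `psf_stack` or `recon_volume` (any 3D array with `voxel`
#'   attribute)
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_psf_stack <- function(x, path) {
  stopifnot(length(dim(x)) == 3)
  mx <- max(x)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  write_sidecar(path, list(type = class(x)[1], scale = mx,
                           voxel = as.numeric(attr(x, "voxel")),
                           z = as.numeric(attr(x, "z")),
                           wavelength = attr(x, "wavelength"),
                           channel = attr(x, "channel"),
                           normalization = attr(x, "normalization")))
  invisible(path)
}

#' @rdname write_psf_stack
#' @export
write_volume <- write_psf_stack

#' Read a PSF stack or volume written by [write_psf_stack()]
#'
#' @param path TIFF file path
#' @return `psf_stack` or `recon_volume` with metadata restored from the
#'   sidecar
#' @export
read_psf_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- read_sidecar(path)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  if (!is.null(meta$scale)) arr <- arr * meta$scale
  structure(arr,
            class = if (identical(meta$type, "recon_volume")) "recon_volume"
                    else "psf_stack",
            voxel = meta$voxel, z = meta$z,
            wavelength = meta$wavelength, channel = meta$channel,
            normalization = meta$normalization,
            otf_env = new.env(parent = emptyenv()))
}

#' @rdname read_psf_stack
#' @export
read_volume <- read_psf_stack

#' Write / read a flat run configuration
#'
#' Flat key-value text with dotted namespaces (YAML semantics), e.g.
#' `optics.f_fl: 34.375`. Every pipeline run writes its resolved
#' configuration next to its outputs.
#'
#' @param config named list (possibly nested one level via dotted keys)
#' @param path file path
#' @export
write_run_config <- function(config, path) {
  flat <- unlist(config)
  yaml::write_yaml(as.list(flat), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such file: ", path,
                               call. = FALSE)
  flat <- yaml::read_yaml(path)
  out <- list()
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) out[[key]] <- flat[[key]]
    else {
      if (is.null(out[[parts[1]]])) out[[parts[1]]] <- list()
      out[[parts[1]]][[paste(parts[-1], collapse = ".")]] <- flat[[key]]
    }
  }
  out
}

#' Provenance log
#'
#' Accumulates per-stage entries (stage name, parameters, input/output
#' identifiers, timestamp, package version) so every output artifact has a
#' complete chain back to raw input or generator seed.
#'
#' @param entries optional initial list of entries
#' @return object of class `provenance_log`
#' @export
provenance_log <- function(entries = list()) {
  structure(list(entries = entries), class = "provenance_log")
}

#' @rdname provenance_log
#' @param log a `provenance_log`
#' @param stage stage name
#' @param ... named parameters / identifiers recorded with the entry
#' @export
log_stage <- function(log, stage, ...) {
  e <- list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
            version = as.character(utils::packageVersion("lfcyto")), ...)
  log$entries[[length(log$entries) + 1L]] <- e
  log
}

#' @rdname provenance_log
#' @param path JSON output path
#' @export
write_provenance <- function(log, path) {
  jsonlite::write_json(log$entries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Feature table output
#'
#' @param records a [segment_objects()] record table
#' @param path CSV path (one row per object-channel)
#' @export
write_features <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
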