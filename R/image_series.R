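#' Construct a calibrated fluorescence image time series
#'
#' The central container of the package: a 3D intensity lattice indexed
#' `[row, col, frame]` together with its physical calibration. Row 1 is the
#' top of the image; columns increase rightward. Intensities are in arbitrary
#' linear units (photons for simulated data).
#'
#' Raw, simulated, registered and Gaussian-filtered series must be
#' nonnegative; only heterogeneity maps (see [heterogeneity_map()]) may carry
#' negative values, because they encode signed local contrast.
#'
#' @param frames Numeric 3D array `[row, col, frame]` (a matrix is promoted to
#'   a single-frame series). All values must be finite.
#' @param pixel_size Pixel size in micrometres (> 0).
#' @param frame_interval Time between consecutive frames in seconds (> 0).
#' @param provenance One of `"raw"`, `"registered"`, `"gaussian"`,
#'   `"heterogeneity"`, `"simulated"`.
#' @return An object of class `image_series`: a list with elements `frames`,
#'   `pixel_size`, `frame_interval`, `provenance`.
#' @examples
#' s <- image_series(array(1, c(8, 8, 3)), pixel_size = 0.14,
#'                   frame_interval = 15)
#' n_frames(s)
#' @export
image_series <- function(frames, pixel_size, frame_interval,
                         provenance = "raw") {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be a [row, col, frame] 3D array")
  storage.mode(frames) <- "double"
  if (!all(is.finite(frames)))
    stop("image series contains non-finite values")
  provenance <- match.arg(provenance,
    c("raw", "registered", "gaussian", "heterogeneity", "simulated"))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (um/pixel)")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0)
    stop("'frame_interval' must be a single positive number (s/frame)")
  if (provenance != "heterogeneity" && any(frames < 0))
    stop("negative intensities are only allowed for provenance 'heterogeneity'")
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval, provenance = provenance),
    class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "image_series: %d frame(s) of %d x %d px | %.4g um/px, %.4g s/frame | %s\n",
    d[3], d[1], d[2], x$pixel_size, x$frame_interval, x$provenance))
  invisible(x)
}

#' Number of frames in an image series
#' @param series An [image_series()].
#' @return Integer frame count.
#' @export
n_frames <- function(series) {
  stopifnot(inherits(series, "image_series"))
  dim(series$frames)[3]
}

#' Frame dimensions of an image series
#' @param series An [image_series()].
#' @return Integer vector `c(rows, cols)`.
#' @export
frame_dims <- function(series) {
  stopifnot(inherits(series, "image_series"))
  dim(series$frames)[1:2]
}

#' Extract a spatial sub-series (region of interest)
#'
#' @param series An [image_series()].
#' @param origin `c(row, col)` of the top-left corner of the window, 1-based.
#' @param size `c(rows, cols)` of the window. The window must lie fully
#'   inside the frame.
#' @return An `image_series` with identical calibration and provenance.
#' @export
crop_roi <- function(series, origin, size) {
  stopifnot(inherits(series, "image_series"),
            length(origin) == 2L, length(size) == 2L)
  origin <- as.integer(origin); size <- as.integer(size)
  d <- frame_dims(series)
  if (any(origin < 1L) || any(size < 1L) || any(origin + size - 1L > d))
    stop(sprintf("ROI [%d:%d, %d:%d] exceeds the %d x %d frame",
                 origin[1], origin[1] + size[1] - 1L,
                 origin[2], origin[2] + size[2] - 1L, d[1], d[2]))
  out <- series
  out$frames <- series$frames[origin[1]:(origin[1] + size[1] - 1L),
                              origin[2]:(origin[2] + size[2] - 1L), ,
                              drop = FALSE]
  out
}

#' Read a single-channel multi-page TIFF as an image series
#'
#' Calibration always comes from the arguments (or the JSON sidecar written by
#' [write_tiff_series()]); TIFF tags are not trusted. Float series written by
#' this package are stored affinely rescaled to `[0, 1]`; the sidecar's
#' `scale`/`offset` entries are applied to undo the rescaling.
#'
#' @param path Path to the TIFF file.
#' @param pixel_size,frame_interval Calibration overrides; if `NULL`, taken
#'   from the sidecar `<path>.json` when present, otherwise required.
#' @return An [image_series()].
#' @export
read_tiff_series <- function(path, pixel_size = NULL, frame_interval = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
  if (is.null(frame_interval)) frame_interval <- meta$frame_interval_s
  if (is.null(pixel_size) || is.null(frame_interval))
    stop("pixel_size and frame_interval must be supplied ",
         "(no sidecar metadata found)")
  as_is <- identical(meta$encoding, "uint16")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (any(vapply(dims, length, 1L) != 2L))
    stop("multi-channel / RGB TIFF pages are not supported")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("TIFF pages have non-uniform dimensions")
  frames <- array(unlist(pages), c(dims[[1]], length(pages)))
  if (!is.null(meta$scale))
    frames <- frames * meta$scale + meta$offset
  prov <- if (is.null(meta$provenance)) "raw" else meta$provenance
  image_series(frames, pixel_size, frame_interval, provenance = prov)
}

#' Write an image series as a multi-page TIFF with a JSON sidecar
#'
#' Nonnegative integer-valued series within the 16-bit range are stored as
#' uint16 pages (bit-exact round trip). Anything else -- including signed
#' heterogeneity maps -- is stored as 32-bit float after affine rescaling to
#' `[0, 1]`; the scale and offset are recorded in the sidecar
#' (`<path>.json`) together with the calibration and provenance, and
#' [read_tiff_series()] inverts them.
#'
#' @param series An [image_series()] with at least one frame.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_tiff_series <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  fr <- series$frames
  if (dim(fr)[3] < 1L) stop("cannot write an empty series")
  meta <- list(pixel_size_um = series$pixel_size,
               frame_interval_s = series$frame_interval,
               provenance = series$provenance,
               n_frames = dim(fr)[3])
  is_int <- all(fr >= 0) && all(fr <= 65535) && all(fr == round(fr))
  pages <- vector("list", dim(fr)[3])
  if (is_int) {
    meta$encoding <- "uint16"
    for (t in seq_along(pages)) pages[[t]] <- fr[, , t] / 65535
    bits <- 16L
  } else {
    meta$encoding <- "float32"
    lo <- min(fr); hi <- max(fr)
    span <- if (hi > lo) hi - lo else 1
    meta$scale <- span; meta$offset <- lo
    for (t in seq_along(pages)) pages[[t]] <- (fr[, , t] - lo) / span
    bits <- 32L
  }
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits),
                 error = function(e) stop("cannot write TIFF: ",
                                          conditionMessage(e)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
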