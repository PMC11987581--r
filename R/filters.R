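#' Normalized circular averaging kernel
#'
#' Builds the disk kernel used by the heterogeneity map to compute local mean
#' intensities. The kernel lattice is the smallest odd square that contains
#' the disk; a pixel belongs to the disk iff the Euclidean distance from its
#' center to the kernel center is at most `diameter / 2`, and all disk pixels
#' share the same weight so that the weights sum to 1.
#'
#' @param diameter Disk diameter in pixels (positive integer). This is the
#'   "kernel size" a user tunes to the size of the structures of interest
#'   (e.g. 8 px for myosin puncta, 16 px for podosomes at 0.14 um/px).
#' @return An object of class `disk_kernel`: list with `diameter` and the
#'   `weights` matrix.
#' @examples
#' make_disk_kernel(3)$weights   # a 3x3 block of 1/9
#' @export
make_disk_kernel <- function(diameter) {
  if (!is.numeric(diameter) || length(diameter) != 1L ||
      diameter < 1 || diameter != round(diameter))
    stop("'diameter' must be a positive integer number of pixels")
  diameter <- as.integer(diameter)
  side <- if (diameter %% 2L == 1L) diameter else diameter + 1L
  ctr <- (side + 1L) / 2
  dist <- sqrt(outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, "+"))
  w <- (dist <= diameter / 2) * 1
  w <- w / sum(w)
  structure(list(diameter = diameter, weights = w), class = "disk_kernel")
}

# replicate-pad a matrix by (pr, pc) pixels on each side
.pad_replicate <- function(m, pr, pc) {
  d <- dim(m)
  ri <- pmin(pmax(seq_len(d[1] + 2L * pr) - pr, 1L), d[1])
  ci <- pmin(pmax(seq_len(d[2] + 2L * pc) - pc, 1L), d[2])
  m[ri, ci, drop = FALSE]
}

# 2D convolution with replicate boundary handling; kernel side must be odd.
# Explicit replicate padding followed by a circular filter guarantees edge
# semantics independent of kernel/image size ratios.
.convolve_replicate <- function(frame, weights) {
  side <- dim(weights)
  d <- dim(frame)
  if (any(side > 2L * d))
    stop("kernel (", side[1], " px) larger than twice the frame")
  r <- (side - 1L) %/% 2L
  padded <- .pad_replicate(frame, r[1], r[2])
  out <- EBImage::filter2(padded, weights, boundary = "circular")
  out[(r[1] + 1L):(r[1] + d[1]), (r[2] + 1L):(r[2] + d[2]), drop = FALSE]
}

#' Local mean map of a single frame
#'
#' Convolves one frame with a normalizing disk kernel using replicate
#' (edge-extend) boundary handling, yielding the average intensity of each
#' pixel's circular neighborhood.
#'
#' @param frame Numeric matrix of finite intensities.
#' @param kernel A [make_disk_kernel()] object.
#' @return Matrix of the same dimensions.
#' @export
local_mean <- function(frame, kernel) {
  stopifnot(is.matrix(frame), inherits(kernel, "disk_kernel"))
  if (!all(is.finite(frame))) stop("frame contains non-finite values")
  .convolve_replicate(frame, kernel$weights)
}

#' Heterogeneity map: accentuate local intensity contrast
#'
#' For every frame, computes `HM = (I - mu) / mu`, where `mu` is the local
#' mean under a circular kernel of the given diameter: each pixel's intensity
#' normalized to the average of its neighborhood. Pixels brighter than their
#' surroundings get positive values and dimmer pixels negative values,
#' regardless of absolute brightness -- `HM(c * I) = HM(I)` for any `c > 0` --
#' which suppresses large-scale intensity waves while preserving the local
#' texture that tracks structure displacement. This is the filter to apply
#' before STICS when the contiguous (structure-movement) flow component is of
#' interest.
#'
#' Pixels whose local mean does not exceed `epsilon` are set to 0 instead of
#' dividing by (near) zero; their count is available as
#' `attr(result, "n_guarded")`.
#'
#' @param series A nonnegative [image_series()].
#' @param kernel_diameter Disk diameter in pixels; ideally encompasses one
#'   structure of interest plus the space separating it from its neighbors.
#' @param epsilon Division guard; default `1e-12 * max(series)`.
#' @return An `image_series` with provenance `"heterogeneity"` (the only
#'   provenance allowed to carry negative values).
#' @export
heterogeneity_map <- function(series, kernel_diameter, epsilon = NULL) {
  stopifnot(inherits(series, "image_series"))
  if (any(series$frames < 0))
    stop("heterogeneity_map expects a nonnegative series")
  kernel <- make_disk_kernel(kernel_diameter)
  if (is.null(epsilon)) epsilon <- 1e-12 * max(series$frames)
  out <- series$frames
  n_guarded <- 0L
  for (t in seq_len(dim(out)[3])) {
    mu <- local_mean(series$frames[, , t], kernel)
    hm <- (series$frames[, , t] - mu) / mu
    guard <- mu <= epsilon
    n_guarded <- n_guarded + sum(guard)
    hm[guard] <- 0
    out[, , t] <- hm
  }
  res <- image_series(out, series$pixel_size, series$frame_interval,
                      provenance = "heterogeneity")
  attr(res, "n_guarded") <- n_guarded
  res
}

# sampled, normalized 2D Gaussian kernel truncated at 4 sigma
.gaussian_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  x <- -r:r
  g1 <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

#' Gaussian filter: attenuate local intensity contrast
#'
#' Per-frame 2D Gaussian convolution (replicate boundary, kernel truncated at
#' 4 sigma). Blurring computationally enlarges the effective point spread
#' function so that intensities of adjacent structures are interpolated into a
#' smooth envelope: structure-scale texture is removed while large-scale
#' intensity waves survive. This is the filter to apply before STICS when the
#' noncontiguous (intensity-propagation) flow component is of interest; sigma
#' should exceed the spacing between adjacent structures.
#'
#' @param series An [image_series()].
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return An `image_series` with provenance `"gaussian"`.
#' @export
gaussian_filter <- function(series, sigma) {
  stopifnot(inherits(series, "image_series"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a single positive number of pixels")
  k <- .gaussian_kernel(sigma)
  out <- series$frames
  for (t in seq_len(dim(out)[3]))
    out[, , t] <- .convolve_replicate(series$frames[, , t], k)
  # FFT round-off can leave tiny negatives on a nonnegative input
  out[out < 0 & out > -1e-9 * max(abs(out))] <- 0
  image_series(out, series$pixel_size, series$frame_interval,
               provenance = "gaussian")
}

#' Apply a named filter branch to a series
#'
#' Convenience dispatcher used by the pipeline: `"original"` returns the input
#' unchanged, `"gaussian"` calls [gaussian_filter()], `"heterogeneity"` calls
#' [heterogeneity_map()].
#'
#' @param series An [image_series()].
#' @param mode `"original"`, `"gaussian"` or `"heterogeneity"`.
#' @param gaussian_sigma Sigma (px) for the Gaussian branch (default 7).
#' @param hm_kernel_diameter Disk diameter (px) for the heterogeneity branch
#'   (default 16).
#' @param hm_epsilon Optional division guard passed to [heterogeneity_map()].
#' @return The filtered `image_series`.
#' @export
apply_filter <- function(series, mode = c("original", "gaussian",
                                          "heterogeneity"),
                         gaussian_sigma = 7, hm_kernel_diameter = 16,
                         hm_epsilon = NULL) {
  mode <- match.arg(mode)
  switch(mode,
    original = series,
    gaussian = gaussian_filter(series, gaussian_sigma),
    heterogeneity = heterogeneity_map(series, hm_kernel_diameter, hm_epsilon))
}
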