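#' STICS analysis parameters
#'
#' Parameters controlling ROI/TOI tiling, the correlation computation, peak
#' tracking and vector rejection. The defaults are the simulation settings
#' used throughout this package: 32 px ROIs shifted by 4 px, 5-frame TOIs
#' shifted by 1 frame, time lags 1..4. For small structures (e.g. podosomes
#' or myosin puncta analyzed on heterogeneity maps) a 16 px ROI with 2 px
#' shift resolves the vector field more finely.
#'
#' @param roi_size Square ROI side, pixels.
#' @param roi_shift Offset between ROI origins, pixels (>= 1).
#' @param toi_size Frames per TOI (>= 2).
#' @param toi_shift Offset between TOI starts, frames (>= 1).
#' @param max_lag Largest time lag correlated (1 <= max_lag <= toi_size - 1).
#' @param immobile_subtraction Subtract each pixel's temporal mean before
#'   correlating, so static structures do not dominate the correlation.
#' @param whole_series_subtraction If `TRUE` (default), the temporal mean is
#'   taken over the whole series (the standard DC-removal immobile filter);
#'   if `FALSE`, per TOI. A mean taken over only `toi_size` frames is itself
#'   strongly correlated with the moving signal and biases recovered speeds
#'   upward (roughly twofold at the default TOI of 5 frames), so the
#'   whole-series scope is the default.
#' @param normalize Normalize each correlation by
#'   `N_pix * mean(i_t) * mean(i_(t+tau))` (the scale-free STICS convention);
#'   automatically falls back to the unnormalized cross-covariance when a
#'   spatial mean is at or below the guard (peak position, hence velocity, is
#'   unaffected by this scale choice).
#' @param min_lags_for_fit Minimum number of tracked peaks required for the
#'   velocity regression (>= 2).
#' @param r2_threshold Minimum mean R^2 of the displacement-vs-lag
#'   regressions for a vector to be valid.
#' @param peak_search_radius Half-width (px) of the window searched and
#'   fitted around the previous peak; defaults to `roi_size / 4` to stay clear
#'   of cyclic wrap ambiguity.
#' @return A `stics_params` list.
#' @export
stics_params <- function(roi_size = 32L, roi_shift = 4L, toi_size = 5L,
                         toi_shift = 1L, max_lag = toi_size - 1L,
                         immobile_subtraction = TRUE,
                         whole_series_subtraction = TRUE,
                         normalize = TRUE, min_lags_for_fit = 3L,
                         r2_threshold = 0.8,
                         peak_search_radius = roi_size / 4) {
  p <- list(roi_size = as.integer(roi_size),
            roi_shift = as.integer(roi_shift),
            toi_size = as.integer(toi_size),
            toi_shift = as.integer(toi_shift),
            max_lag = as.integer(max_lag),
            immobile_subtraction = isTRUE(immobile_subtraction),
            whole_series_subtraction = isTRUE(whole_series_subtraction),
            normalize = isTRUE(normalize),
            min_lags_for_fit = as.integer(min_lags_for_fit),
            r2_threshold = r2_threshold,
            peak_search_radius = peak_search_radius)
  if (p$roi_size < 2L || p$roi_shift < 1L || p$toi_shift < 1L)
    stop("roi_size >= 2, roi_shift >= 1 and toi_shift >= 1 required")
  if (p$toi_size < 2L) stop("toi_size must be >= 2 frames")
  if (p$max_lag < 1L || p$max_lag > p$toi_size - 1L)
    stop("max_lag must satisfy 1 <= max_lag <= toi_size - 1")
  if (p$min_lags_for_fit < 2L) stop("min_lags_for_fit must be >= 2")
  structure(p, class = "stics_params")
}

#' Tile a frame with regularly shifted ROI origins
#'
#' Origins start at (1, 1) and advance by `roi_shift` per axis as long as the
#' ROI fits inside the frame; they are returned in row-major order (rows
#' outer, columns inner). Per axis this yields
#' `floor((dim - roi_size) / roi_shift) + 1` positions.
#'
#' @param frame_dims `c(rows, cols)`.
#' @param roi_size Square ROI side (<= both dims).
#' @param roi_shift Offset between origins (>= 1).
#' @return Integer matrix with columns `row`, `col` of 1-based origins.
#' @export
tile_rois <- function(frame_dims, roi_size, roi_shift) {
  frame_dims <- as.integer(frame_dims)
  roi_size <- as.integer(roi_size); roi_shift <- as.integer(roi_shift)
  if (any(roi_size > frame_dims))
    stop("roi_size exceeds the frame dimensions")
  rows <- seq.int(1L, frame_dims[1] - roi_size + 1L, by = roi_shift)
  cols <- seq.int(1L, frame_dims[2] - roi_size + 1L, by = roi_shift)
  cbind(row = rep(rows, each = length(cols)),
        col = rep(cols, times = length(rows)))
}

#' Remove the immobile fraction from a ROI stack
#'
#' Subtracts each pixel's temporal mean over the stack, leaving fluctuations
#' whose per-pixel temporal mean is exactly zero. Without this step, bright
#' static structures dominate the correlation function and pin its peak at
#' zero lag.
#'
#' @param roi_stack 3D array `[row, col, frame]` with >= 2 frames.
#' @return Centered array of the same shape.
#' @export
subtract_immobile <- function(roi_stack) {
  stopifnot(is.array(roi_stack), length(dim(roi_stack)) == 3L)
  if (dim(roi_stack)[3] < 2L) stop("need at least 2 frames")
  roi_stack - c(rowMeans(roi_stack, dims = 2L))
}

# lag value of each FFT-layout index: k maps to (k - 1) wrapped into
# [-floor(n/2), ceiling(n/2) - 1]
.index_lags <- function(n) {
  l <- seq_len(n) - 1L
  l[l >= ceiling(n / 2)] <- l[l >= ceiling(n / 2)] - n
  l
}

# centered (sorted) lag values for an axis of length n
.centered_lags <- function(n) sort(.index_lags(n))

# reorder an FFT-layout matrix so lag 0 sits at the center (fftshift)
.fftshift2 <- function(m) {
  d <- dim(m)
  m[order(.index_lags(d[1])), order(.index_lags(d[2])), drop = FALSE]
}

#' Spatiotemporal correlation function of one ROI stack
#'
#' For each time lag `tau = 0..max_lag`, computes the cyclic spatial
#' cross-correlation of the intensity fluctuations of every frame pair
#' `(t, t + tau)`, averaged over pairs:
#' `r(xi, eta, tau) = < sum_xy di_t(x, y) di_(t+tau)(x+xi, y+eta) /
#' (N_pix * <i>_t * <i>_(t+tau)) >_t`, evaluated with forward/inverse FFTs.
#' Positive `xi` (column lag) means the pattern moved rightward between the
#' two frames; positive `eta` (row lag) means it moved down the image. The
#' lag lattice is centered on zero lag.
#'
#' The spatial means `<i>` are those of the *intensity* stack; pass them via
#' `means` when `roi_stack` has already been fluctuation-centered. When a
#' mean is at or below `1e-9 * intensity_max` (possible for
#' heterogeneity-filtered data, whose spatial mean is near zero), the
#' unnormalized cross-covariance `C / N_pix` is used for that lag and
#' `normalization_used` records it; this rescaling never moves the peak.
#'
#' @param roi_stack 3D array `[row, col, frame]`, typically the output of
#'   [subtract_immobile()].
#' @param max_lag Largest lag (< number of frames).
#' @param normalize Apply the mean normalization (default `TRUE`).
#' @param means Per-frame spatial means of the intensity stack; defaults to
#'   the per-frame means of `roi_stack`.
#' @param intensity_max Reference intensity scale for the normalization
#'   guard; defaults to `max(abs(roi_stack))`.
#' @return A `stics_corr` object: list with `values` (array
#'   `[eta, xi, tau + 1]`, lag-centered), `lags_row`, `lags_col`,
#'   `normalization_used` (logical per tau), `empty` flag.
#' @export
correlation_function <- function(roi_stack, max_lag, normalize = TRUE,
                                 means = NULL, intensity_max = NULL) {
  stopifnot(is.array(roi_stack), length(dim(roi_stack)) == 3L)
  d <- dim(roi_stack)
  nt <- d[3]
  if (max_lag < 0L || max_lag >= nt)
    stop("max_lag must satisfy 0 <= max_lag < n_frames")
  npix <- d[1] * d[2]
  empty <- max(abs(roi_stack)) == 0
  if (is.null(means)) means <- colMeans(roi_stack, dims = 2L)
  if (is.null(intensity_max)) intensity_max <- max(abs(roi_stack))
  guard <- 1e-9 * intensity_max
  ft <- vector("list", nt)
  for (t in seq_len(nt)) ft[[t]] <- fft(roi_stack[, , t])
  values <- array(0, c(d[1], d[2], max_lag + 1L))
  norm_used <- logical(max_lag + 1L)
  for (tau in 0:max_lag) {
    acc <- matrix(0, d[1], d[2])
    pairs <- nt - tau
    can_norm <- normalize && all(means[seq_len(pairs)] > guard) &&
      all(means[seq_len(pairs) + tau] > guard)
    for (t in seq_len(pairs)) {
      cc <- Re(fft(Conj(ft[[t]]) * ft[[t + tau]], inverse = TRUE)) / npix
      denom <- if (can_norm) npix * means[t] * means[t + tau] else npix
      acc <- acc + cc / denom
    }
    values[, , tau + 1L] <- .fftshift2(acc / pairs)
    norm_used[tau + 1L] <- can_norm
  }
  structure(list(values = values,
                 lags_row = .centered_lags(d[1]),
                 lags_col = .centered_lags(d[2]),
                 normalization_used = norm_used,
                 empty = empty),
            class = "stics_corr")
}

# residuals and jacobian of the 2D Gaussian peak model
# A * exp(-((xi - xi0)^2 + (eta - eta0)^2) / w^2) + c
.peak_residual <- function(par, xi, eta, z) {
  e <- exp(-((xi - par[2])^2 + (eta - par[3])^2) / par[4]^2)
  par[1] * e + par[5] - z
}
.peak_jacobian <- function(par, xi, eta, z) {
  dx <- xi - par[2]; dy <- eta - par[3]
  e <- exp(-(dx^2 + dy^2) / par[4]^2)
  cbind(e,
        par[1] * e * 2 * dx / par[4]^2,
        par[1] * e * 2 * dy / par[4]^2,
        par[1] * e * 2 * (dx^2 + dy^2) / par[4]^3,
        1)
}

#' Fit a 2D Gaussian to a correlation-function peak
#'
#' Levenberg-Marquardt least-squares fit of
#' `A * exp(-((xi - xi0)^2 + (eta - eta0)^2) / w^2) + c` over the square
#' window of half-width `search_radius` centered on `init_center` (in lag
#' units). The fit is initialized at the discrete argmax within the window
#' (ties broken toward the smallest `(eta, xi)` in lexicographic order).
#'
#' @param corr_slice 2D matrix `[eta, xi]` of correlation values, lag-centered
#'   as produced by [correlation_function()].
#' @param init_center `c(xi, eta)` lag coordinates of the window center.
#' @param search_radius Window half-width, pixels.
#' @param lags_row,lags_col Lag coordinate vectors of the slice axes;
#'   defaults to centered lags for the slice dimensions.
#' @return A `peak_fit` list: `center` (`c(xi, eta)`, subpixel), `amplitude`,
#'   `width`, `offset`, `residual_norm`, `converged`.
#' @export
fit_gaussian_peak <- function(corr_slice, init_center = c(0, 0),
                              search_radius,
                              lags_row = NULL, lags_col = NULL) {
  stopifnot(is.matrix(corr_slice))
  if (!all(is.finite(corr_slice))) stop("correlation slice not finite")
  d <- dim(corr_slice)
  if (is.null(lags_row)) lags_row <- .centered_lags(d[1])
  if (is.null(lags_col)) lags_col <- .centered_lags(d[2])
  fail <- list(center = c(NA_real_, NA_real_), amplitude = NA_real_,
               width = NA_real_, offset = NA_real_,
               residual_norm = NA_real_, converged = FALSE)
  class(fail) <- "peak_fit"
  keep_r <- which(abs(lags_row - init_center[2]) <= search_radius)
  keep_c <- which(abs(lags_col - init_center[1]) <= search_radius)
  if (length(keep_r) < 3L || length(keep_c) < 3L) return(fail)
  win <- corr_slice[keep_r, keep_c, drop = FALSE]
  if (max(win) - min(win) <= 0) return(fail)   # constant window: degenerate
  wr <- lags_row[keep_r]; wc <- lags_col[keep_c]
  # argmax with lexicographic (eta, xi) tie-break
  mx <- which(win == max(win), arr.ind = TRUE)
  mx <- mx[order(wr[mx[, 1]], wc[mx[, 2]])[1], , drop = TRUE]
  pk <- c(wc[mx[2]], wr[mx[1]])
  # re-center the fit window on the argmax: an asymmetric window around a
  # broad correlation dome otherwise biases the fitted center outward
  keep_r <- which(abs(lags_row - pk[2]) <= search_radius)
  keep_c <- which(abs(lags_col - pk[1]) <= search_radius)
  win <- corr_slice[keep_r, keep_c, drop = FALSE]
  wr <- lags_row[keep_r]; wc <- lags_col[keep_c]
  eta <- rep(wr, times = length(wc))
  xi <- rep(wc, each = length(wr))
  z <- as.vector(win)
  c0 <- min(z)
  zp <- z - c0
  d2 <- (xi - pk[1])^2 + (eta - pk[2])^2
  # moment-based width: broad correlation domes (structures comparable to the
  # ROI) need w near the window size, sharp particle peaks need a few px
  w0 <- sqrt(max(2, sum(d2 * zp) / sum(zp)))
  par0 <- c(A = max(z) - c0, xi0 = pk[1], eta0 = pk[2], w = w0, c = c0)
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = par0, fn = .peak_residual,
                         jac = .peak_jacobian, xi = xi, eta = eta, z = z,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100, ftol = 1e-6, ptol = 1e-4))),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(fail)
  p <- fit$par
  p[4] <- abs(p[4])
  in_lattice <- p[2] >= min(lags_col) && p[2] <= max(lags_col) &&
    p[3] >= min(lags_row) && p[3] <= max(lags_row)
  if (p[1] <= 0 || p[4] <= 0 || !in_lattice) return(fail)
  structure(list(center = c(xi = unname(p[2]), eta = unname(p[3])),
                 amplitude = unname(p[1]), width = unname(p[4]),
                 offset = unname(p[5]),
                 residual_norm = sqrt(sum(fit$fvec^2)),
                 converged = TRUE),
            class = "peak_fit")
}

#' Track the correlation peak across time lags
#'
#' The lag-1 peak is searched around zero lag; each subsequent lag is searched
#' within `peak_search_radius` of the previously found center (a continuity
#' constraint that rejects jumps to cyclic aliases or secondary peaks). Lags
#' whose fit fails, or whose fitted center leaves the continuity window, are
#' dropped.
#'
#' @param corr A `stics_corr` from [correlation_function()].
#' @param params A [stics_params()].
#' @return Data frame with columns `tau`, `xi`, `eta` of surviving peak
#'   centers; `attr(, "insufficient")` is `TRUE` when fewer than
#'   `min_lags_for_fit` survive.
#' @export
track_peaks <- function(corr, params) {
  stopifnot(inherits(corr, "stics_corr"), inherits(params, "stics_params"))
  max_lag <- dim(corr$values)[3] - 1L
  prev <- c(0, 0)
  taus <- integer(0); xis <- numeric(0); etas <- numeric(0)
  for (tau in seq_len(max_lag)) {
    fit <- fit_gaussian_peak(corr$values[, , tau + 1L], init_center = prev,
                             search_radius = params$peak_search_radius,
                             lags_row = corr$lags_row,
                             lags_col = corr$lags_col)
    if (!fit$converged) next
    if (max(abs(fit$center - prev)) > params$peak_search_radius) next
    taus <- c(taus, tau)
    xis <- c(xis, fit$center[["xi"]])
    etas <- c(etas, fit$center[["eta"]])
    prev <- fit$center
  }
  out <- data.frame(tau = taus, xi = xis, eta = etas)
  attr(out, "insufficient") <- nrow(out) < params$min_lags_for_fit
  out
}

# closed-form OLS of y ~ tau with intercept; returns slope and R^2
.ols_slope_r2 <- function(tau, y) {
  mt <- mean(tau); my <- mean(y)
  sxx <- sum((tau - mt)^2)
  slope <- sum((tau - mt) * (y - my)) / sxx
  res <- y - (my + slope * (tau - mt))
  ss_res <- sum(res^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_res <= 1e-20) 1 else 1 - ss_res / ss_tot
  c(slope = slope, r2 = r2)
}

#' Velocity from tracked peak displacements
#'
#' Ordinary least-squares lines (with intercept) of the peak's column lag and
#' row lag versus time lag give the displacement rate in px/frame, converted
#' to um/min with the calibration. `vy` is reported up-positive (mathematical
#' convention), so a pattern moving toward the top of the image has positive
#' `vy` and angle +90 degrees. `r2` is the mean of the two regressions' R^2
#' (defined as 1 when the residuals are exactly zero).
#'
#' @param peaks Data frame `tau`, `xi`, `eta` from [track_peaks()] (>= 2
#'   rows).
#' @param pixel_size um per pixel.
#' @param frame_interval s per frame.
#' @return List with `vx`, `vy` (um/min), `r2`.
#' @export
velocity_from_peaks <- function(peaks, pixel_size, frame_interval) {
  if (nrow(peaks) < 2L) stop("need at least 2 tracked peaks")
  conv <- pixel_size * 60 / frame_interval     # px/frame -> um/min
  fx <- .ols_slope_r2(peaks$tau, peaks$xi)
  fy <- .ols_slope_r2(peaks$tau, peaks$eta)
  list(vx = unname(fx["slope"]) * conv,
       vy = -unname(fy["slope"]) * conv,      # row lag grows downward
       r2 = unname(mean(c(fx["r2"], fy["r2"]))))
}

#' Full STICS analysis of an image series
#'
#' Tiles the series into TOIs and square ROIs, and for every (TOI, ROI) pair
#' runs immobile-fraction subtraction, the spatiotemporal correlation
#' function, Gaussian peak tracking across lags 1..`max_lag`, and the
#' displacement-versus-lag velocity regression. Every ROI position yields
#' exactly one flow vector per TOI; vectors that cannot be estimated are kept
#' with `valid = FALSE` and a `rejection_reason` of `empty_roi` (all-zero
#' ROI), `fit_failed` (fewer than `min_lags_for_fit` tracked peaks),
#' `peak_out_of_range` (tracked displacement beyond `roi_size / 4`, where
#' cyclic correlation becomes ambiguous), or `low_r2`.
#'
#' @param series An [image_series()] with more than `toi_size` frames.
#' @param params A [stics_params()].
#' @return An object of class `stics_result`: a list of per-TOI vector
#'   fields, each a data frame with columns `toi_index`, `time_s`, `x_um`,
#'   `y_um`, `vx_um_min`, `vy_um_min`, `speed_um_min`, `angle_deg`, `r2`,
#'   `valid`, `rejection_reason`; `params` and the series calibration are
#'   attached as attributes. Positions are ROI centers (x from the left edge,
#'   y down from the top edge); angles are mathematical (0 = +x, +90 = up).
#' @export
stics_analyze <- function(series, params = stics_params()) {
  stopifnot(inherits(series, "image_series"), inherits(params, "stics_params"))
  d <- frame_dims(series)
  nt <- n_frames(series)
  if (nt < params$toi_size) stop("series shorter than toi_size")
  if (any(params$roi_size > d)) stop("roi_size exceeds frame dimensions")
  origins <- tile_rois(d, params$roi_size, params$roi_shift)
  toi_starts <- seq.int(1L, nt - params$toi_size + 1L, by = params$toi_shift)
  rs <- params$roi_size
  half_roi <- rs / 2
  series_max <- max(abs(series$frames))
  conv_reason <- c("none", "empty_roi", "fit_failed", "peak_out_of_range",
                   "low_r2")
  global_mean <- if (params$whole_series_subtraction)
    c(rowMeans(series$frames, dims = 2L)) else NULL
  fields <- vector("list", length(toi_starts))
  for (k in seq_along(toi_starts)) {
    t0 <- toi_starts[k]
    toi <- series$frames[, , t0:(t0 + params$toi_size - 1L), drop = FALSE]
    fluct <- if (!params$immobile_subtraction) toi
      else if (params$whole_series_subtraction) toi - global_mean
      else subtract_immobile(toi)
    n_roi <- nrow(origins)
    vx <- vy <- r2 <- rep(NA_real_, n_roi)
    reason <- rep("none", n_roi)
    for (j in seq_len(n_roi)) {
      r0 <- origins[j, 1]; c0 <- origins[j, 2]
      stack <- toi[r0:(r0 + rs - 1L), c0:(c0 + rs - 1L), , drop = FALSE]
      if (max(abs(stack)) == 0) { reason[j] <- "empty_roi"; next }
      fstack <- fluct[r0:(r0 + rs - 1L), c0:(c0 + rs - 1L), , drop = FALSE]
      corr <- correlation_function(
        fstack, params$max_lag, normalize = params$normalize,
        means = colMeans(stack, dims = 2L), intensity_max = series_max)
      peaks <- track_peaks(corr, params)
      if (attr(peaks, "insufficient")) { reason[j] <- "fit_failed"; next }
      if (max(abs(c(peaks$xi, peaks$eta))) > rs / 4) {
        reason[j] <- "peak_out_of_range"; next
      }
      vel <- velocity_from_peaks(peaks, series$pixel_size,
                                 series$frame_interval)
      vx[j] <- vel$vx; vy[j] <- vel$vy; r2[j] <- vel$r2
      if (vel$r2 < params$r2_threshold) reason[j] <- "low_r2"
    }
    valid <- reason == "none" & !is.na(vx)
    fields[[k]] <- data.frame(
      toi_index = k,
      time_s = (t0 - 1 + (params$toi_size - 1) / 2) * series$frame_interval,
      x_um = (origins[, 2] - 1 + half_roi) * series$pixel_size,
      y_um = (origins[, 1] - 1 + half_roi) * series$pixel_size,
      vx_um_min = vx, vy_um_min = vy,
      speed_um_min = sqrt(vx^2 + vy^2),
      angle_deg = atan2(vy, vx) * 180 / pi,
      r2 = r2,
      valid = valid,
      rejection_reason = factor(reason, levels = conv_reason))
  }
  structure(fields, class = "stics_result", params = params,
            pixel_size = series$pixel_size,
            frame_interval = series$frame_interval,
            provenance = series$provenance)
}

#' Bind the per-TOI vector fields of a STICS result into one data frame
#'
#' @param result A `stics_result` from [stics_analyze()].
#' @return A single data frame of all flow vectors.
#' @export
bind_fields <- function(result) {
  stopifnot(inherits(result, "stics_result"))
  do.call(rbind, c(unclass(result), make.row.names = FALSE))
}

#' @export
print.stics_result <- function(x, ...) {
  all <- bind_fields(x)
  cat(sprintf(
    "stics_result: %d TOI(s) x %d ROI(s); %d/%d valid vectors\n",
    length(x), nrow(x[[1]]), sum(all$valid), nrow(all)))
  if (any(all$valid))
    cat(sprintf("  mean valid speed %.4g um/min, mean angle %.3g deg\n",
                mean(all$speed_um_min[all$valid]),
                atan2(mean(all$vy_um_min[all$valid]),
                      mean(all$vx_um_min[all$valid])) * 180 / pi))
  invisible(x)
}
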