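#' Fourier-based translational registration of an image series
#'
#' Aligns every frame to a single reference frame by phase correlation: the
#' normalized cross-power spectrum of reference and frame is inverted and the
#' location of its peak gives the integer-pixel translation. Frames are then
#' shifted back by a cyclic roll. Intended to remove stage drift or whole-cell
#' translation before filtering and STICS; cells suitable for STICS are
#' typically nonmigratory over the acquisition, so integer precision is the
#' default. An optional subpixel refinement takes the intensity centroid of
#' the 3-by-3 neighborhood around the correlation peak (the applied shift is
#' still the rounded value; the refined estimate is reported).
#'
#' A constant (e.g. all-zero) frame has an undefined cross-power spectrum; such
#' frames are left unshifted, assigned shift (0, 0), and flagged.
#'
#' @param series An [image_series()] with at least 2 frames.
#' @param reference_index Frame that defines the common coordinate system
#'   (default 1, the first frame).
#' @param subpixel If `TRUE`, also report centroid-refined subpixel shifts.
#' @return A list with elements:
#'   \describe{
#'     \item{series}{the registered `image_series` (provenance `"registered"`)}
#'     \item{registration}{a data frame with one row per frame: `frame`,
#'       `shift_row`, `shift_col` (pixels of displacement of the frame
#'       relative to the reference; the frame is rolled by the negated shift),
#'       `flagged`; plus `shift_row_sub`, `shift_col_sub` when
#'       `subpixel = TRUE`. The reference index is stored in
#'       `attr(, "reference_index")`.}
#'   }
#' @examples
#' f0 <- matrix(stats::runif(64 * 64), 64, 64)
#' s <- image_series(array(c(f0, roll_matrix(f0, 3, -2)), c(64, 64, 2)),
#'                   0.14, 15)
#' register_series(s)$registration
#' @export
register_series <- function(series, reference_index = 1L, subpixel = FALSE) {
  stopifnot(inherits(series, "image_series"))
  nt <- n_frames(series)
  if (nt < 2L) stop("registration needs at least 2 frames")
  if (reference_index < 1L || reference_index > nt)
    stop("reference_index out of range")
  ref <- series$frames[, , reference_index]
  fr <- fft(ref - mean(ref))
  d <- dim(ref)
  shifts <- matrix(0, nt, 2L)
  subs <- matrix(0, nt, 2L)
  flagged <- logical(nt)
  out <- series$frames
  for (t in seq_len(nt)) {
    if (t == reference_index) next
    g <- series$frames[, , t]
    if (stats::sd(g) == 0 || stats::sd(ref) == 0) {
      flagged[t] <- TRUE
      next
    }
    cp <- Conj(fr) * fft(g - mean(g))
    mag <- Mod(cp)
    # regularized whitening: full normalization amplifies the noise-dominated
    # high frequencies of smooth images
    pc <- Re(fft(cp / (mag + 0.01 * max(mag)), inverse = TRUE)) / length(cp)
    pk <- arrayInd(which.max(pc), d)
    # index k corresponds to the frame being the reference shifted by k-1,
    # wrapped into (-n/2, n/2]
    sh <- .wrap_lag(pk - 1L, d)
    shifts[t, ] <- sh
    if (subpixel) {
      nb <- expand.grid(dr = -1:1, dc = -1:1)
      idx <- cbind((pk[1] - 1L + nb$dr) %% d[1] + 1L,
                   (pk[2] - 1L + nb$dc) %% d[2] + 1L)
      w <- pmax(pc[idx], 0)
      subs[t, ] <- if (sum(w) > 0)
        sh + c(sum(nb$dr * w), sum(nb$dc * w)) / sum(w) else sh
    }
    out[, , t] <- roll_matrix(g, -sh[1], -sh[2])
  }
  if (subpixel) subs[reference_index, ] <- 0
  reg <- data.frame(frame = seq_len(nt),
                    shift_row = shifts[, 1], shift_col = shifts[, 2],
                    flagged = flagged)
  if (subpixel) {
    reg$shift_row_sub <- ifelse(seq_len(nt) == reference_index, 0, subs[, 1])
    reg$shift_col_sub <- ifelse(seq_len(nt) == reference_index, 0, subs[, 2])
  }
  attr(reg, "reference_index") <- as.integer(reference_index)
  res <- image_series(out, series$pixel_size, series$frame_interval,
                      provenance = "registered")
  list(series = res, registration = reg)
}

#' Cyclically shift a matrix
#'
#' Rolls the contents of a matrix down by `by_row` rows and right by `by_col`
#' columns, wrapping around the edges (negative values roll up / left).
#'
#' @param m A matrix.
#' @param by_row,by_col Integer shifts in rows / columns.
#' @return The rolled matrix.
#' @export
roll_matrix <- function(m, by_row, by_col) {
  d <- dim(m)
  ri <- ((seq_len(d[1]) - 1L - as.integer(by_row)) %% d[1]) + 1L
  ci <- ((seq_len(d[2]) - 1L - as.integer(by_col)) %% d[2]) + 1L
  m[ri, ci, drop = FALSE]
}

# wrap a nonnegative cyclic lag vector into (-n/2, n/2]
.wrap_lag <- function(lag, dims) {
  ifelse(lag > dims / 2, lag - dims, lag)
}
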