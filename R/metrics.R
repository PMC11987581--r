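#' Alignment percentage of a vector field with a reference axis
#'
#' `100 * median(cos(angle - reference_angle))` over the valid vectors:
#' 100 means perfect alignment with the reference direction, 0 no alignment
#' (orthogonal), and -100 perfect anti-alignment. The median of an even count
#' is the midpoint of the two central values. Horizontal flow is scored
#' against 0 degrees, vertical flow against 90 degrees.
#'
#' @param field A vector-field data frame (one element of a
#'   [stics_analyze()] result, or their [bind_fields()] combination).
#' @param reference_angle Reference direction, degrees (0 = +x, +90 = up).
#' @return Signed percentage in [-100, 100].
#' @export
alignment_percentage <- function(field, reference_angle) {
  v <- field[field$valid, , drop = FALSE]
  if (nrow(v) == 0L) stop("no valid vectors")
  100 * stats::median(cos((v$angle_deg - reference_angle) * pi / 180))
}

#' Summary statistics of a vector field
#'
#' Statistics are computed over valid vectors only. An empty field (no valid
#' vectors) yields `n_valid = 0` with the remaining statistics `NA`.
#'
#' @param field A vector-field data frame.
#' @return One-row data frame: `n_valid`, `mean_speed`, `median_speed`,
#'   `max_speed` (um/min), `alignment_pct_horizontal`,
#'   `alignment_pct_vertical`.
#' @export
summarize_field <- function(field) {
  v <- field[field$valid, , drop = FALSE]
  if (nrow(v) == 0L)
    return(data.frame(n_valid = 0L, mean_speed = NA_real_,
                      median_speed = NA_real_, max_speed = NA_real_,
                      alignment_pct_horizontal = NA_real_,
                      alignment_pct_vertical = NA_real_))
  data.frame(n_valid = nrow(v),
             mean_speed = mean(v$speed_um_min),
             median_speed = stats::median(v$speed_um_min),
             max_speed = max(v$speed_um_min),
             alignment_pct_horizontal = alignment_percentage(field, 0),
             alignment_pct_vertical = alignment_percentage(field, 90))
}
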