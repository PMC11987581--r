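#' Configuration for the two-layer flow simulator
#'
#' Describes a synthetic fluorescence video made of up to two layers:
#' a "main" layer of point emitters drifting rigidly (contiguous,
#' structure-displacement flow) and a "wave" layer of wide-PSF emitters
#' seeded on a horizontal line and translating as a whole (which, superimposed
#' on the main layer, appears as a noncontiguous traveling intensity wave).
#' Layers are combined by addition or multiplication; no photon noise,
#' bleaching or blinking is simulated, so every departure from ground truth
#' downstream is attributable to the analysis itself.
#'
#' Angles use the mathematical convention: 0 degrees = rightward (+x),
#' counter-clockwise positive, so +90 degrees points toward the top of the
#' image.
#'
#' The defaults of [default_sim_config()] freeze the study conditions of the
#' `"two_layer"` preset: a 100 x 100 px canvas at 0.14 um/px; 200 main-layer
#' particles with a 0.5 um 1/e^2 PSF radius, each emitting 400 photons/s,
#' drifting rightward at 0.5 um/min; 100 wave-layer particles with a 2 um PSF
#' radius on a horizontal line one third of the canvas height from the bottom,
#' translating upward at 0.5 um/min; 30 frames at 15 s intervals with 1 s
#' exposure.
#'
#' @param canvas `c(rows, cols)` in pixels.
#' @param pixel_size um per pixel.
#' @param n_particles Main-layer particle count.
#' @param psf_e2_radius Main-layer PSF 1/e^2 intensity radius, um
#'   (Gaussian sigma = radius / 2).
#' @param photon_rate Photons emitted per second per particle (the integral
#'   of its PSF).
#' @param drift_speed,drift_direction Main-layer speed (um/min) and direction
#'   (degrees).
#' @param wave_n_particles Wave-layer particle count.
#' @param wave_psf_radius Wave-layer PSF 1/e^2 radius, um.
#' @param wave_line_fraction Height of the seeding line as a fraction of the
#'   canvas measured from the bottom (in (0, 1)).
#' @param wave_speed,wave_direction Wave-layer speed (um/min) and direction
#'   (degrees; 90 = upward).
#' @param combine_mode `"none"` (single enabled layer), `"add"` or
#'   `"multiply"`.
#' @param main_enabled,wave_enabled Which layers are rendered.
#' @param n_frames Number of frames.
#' @param frame_interval Seconds between frames.
#' @param exposure Exposure time per frame, s (pure intensity scale; motion
#'   blur is not simulated).
#' @param boundary `"wrap"` (cyclic; particle density and total intensity stay
#'   stationary, the clean setting for correlation analysis) or `"open"`
#'   (particles leaving the canvas disappear).
#' @param seed RNG seed making the video reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(canvas = c(100L, 100L), pixel_size = 0.14,
                       n_particles = 200L, psf_e2_radius = 0.5,
                       photon_rate = 400, drift_speed = 0.5,
                       drift_direction = 0, wave_n_particles = 100L,
                       wave_psf_radius = 2, wave_line_fraction = 1 / 3,
                       wave_speed = 0.5, wave_direction = 90,
                       combine_mode = c("none", "add", "multiply"),
                       main_enabled = TRUE, wave_enabled = FALSE,
                       n_frames = 30L, frame_interval = 15, exposure = 1,
                       boundary = c("wrap", "open"), seed = 1L) {
  combine_mode <- match.arg(combine_mode)
  boundary <- match.arg(boundary)
  cfg <- list(canvas = as.integer(canvas), pixel_size = pixel_size,
              n_particles = as.integer(n_particles),
              psf_e2_radius = psf_e2_radius, photon_rate = photon_rate,
              drift_speed = drift_speed, drift_direction = drift_direction,
              wave_n_particles = as.integer(wave_n_particles),
              wave_psf_radius = wave_psf_radius,
              wave_line_fraction = wave_line_fraction,
              wave_speed = wave_speed, wave_direction = wave_direction,
              combine_mode = combine_mode, main_enabled = main_enabled,
              wave_enabled = wave_enabled, n_frames = as.integer(n_frames),
              frame_interval = frame_interval, exposure = exposure,
              boundary = boundary, seed = as.integer(seed))
  pos <- c("pixel_size", "psf_e2_radius", "photon_rate", "wave_psf_radius",
           "frame_interval", "exposure")
  for (f in pos) if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
    stop("'", f, "' must be positive")
  if (any(cfg$canvas < 1L) || cfg$n_frames < 1L)
    stop("canvas and n_frames must be positive")
  if (cfg$drift_speed < 0 || cfg$wave_speed < 0) stop("speeds must be >= 0")
  if (cfg$wave_line_fraction <= 0 || cfg$wave_line_fraction >= 1)
    stop("'wave_line_fraction' must lie in (0, 1)")
  if (combine_mode == "multiply" && !(main_enabled && wave_enabled))
    stop("combine_mode 'multiply' requires both layers enabled")
  if (combine_mode == "add" && !(main_enabled && wave_enabled))
    stop("combine_mode 'add' requires both layers enabled")
  if (combine_mode == "none" && main_enabled && wave_enabled)
    stop("combine_mode 'none' allows only one enabled layer")
  if (!main_enabled && !wave_enabled) stop("no layer enabled")
  structure(cfg, class = "sim_config")
}

#' Frozen study-condition presets for the simulator
#'
#' `"contiguous"`: drifting point emitters only. `"noncontiguous"`: traveling
#' wide-PSF wave only. `"mixed_multiply"` / `"mixed_add"`: both layers,
#' combined multiplicatively (structures that move while modulating in
#' brightness, the podosome-like case) or additively (a dense molecular flow
#' superimposed on moving complexes). All numeric values are the
#' `"two_layer"` defaults documented in [sim_config()].
#'
#' @param preset One of `"contiguous"`, `"noncontiguous"`, `"mixed_multiply"`,
#'   `"mixed_add"`.
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
default_sim_config <- function(preset = c("contiguous", "noncontiguous",
                                          "mixed_multiply", "mixed_add"),
                               ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    contiguous = list(main_enabled = TRUE, wave_enabled = FALSE),
    noncontiguous = list(main_enabled = FALSE, wave_enabled = TRUE),
    mixed_multiply = list(main_enabled = TRUE, wave_enabled = TRUE,
                          combine_mode = "multiply"),
    mixed_add = list(main_enabled = TRUE, wave_enabled = TRUE,
                     combine_mode = "add"))
  do.call(sim_config, utils::modifyList(args, list(...)))
}

#' Initialize a particle layer
#'
#' Main-layer positions are sampled uniformly over the canvas area; wave-layer
#' positions have uniform x and a fixed y on the horizontal seeding line
#' `wave_line_fraction` of the canvas height above the bottom edge. Positions
#' are continuous (um, x rightward from the left edge, y downward from the top
#' edge) and are never snapped to pixels. Draws come from the current RNG
#' stream; [simulate_series()] seeds it once per simulation.
#'
#' @param config A [sim_config()].
#' @param layer `"main"` or `"wave"`.
#' @return A `particle_layer`: list with `x`, `y` (um), `photon_rate`,
#'   `psf_radius` (um).
#' @export
init_particles <- function(config, layer = c("main", "wave")) {
  layer <- match.arg(layer)
  stopifnot(inherits(config, "sim_config"))
  w_um <- config$canvas[2] * config$pixel_size
  h_um <- config$canvas[1] * config$pixel_size
  if (layer == "main") {
    n <- config$n_particles
    x <- stats::runif(n, 0, w_um)
    y <- stats::runif(n, 0, h_um)
    r <- config$psf_e2_radius
  } else {
    n <- config$wave_n_particles
    x <- stats::runif(n, 0, w_um)
    y <- rep((1 - config$wave_line_fraction) * h_um, n)
    r <- config$wave_psf_radius
  }
  structure(list(x = x, y = y, photon_rate = config$photon_rate,
                 psf_radius = r),
            class = "particle_layer")
}

#' Advance a particle layer by one time step
#'
#' Displaces every particle by `speed * dt / 60` um along `direction`
#' (0 degrees = +x; +90 degrees = toward the top of the image, i.e.
#' decreasing y).
#'
#' @param layer A `particle_layer`.
#' @param speed um/min.
#' @param direction Degrees.
#' @param dt Time step, s (> 0).
#' @param config The [sim_config()] (for canvas size and boundary mode).
#' @return The advanced `particle_layer`.
#' @export
advance_particles <- function(layer, speed, direction, dt, config) {
  stopifnot(inherits(layer, "particle_layer"), dt > 0)
  step <- speed * dt / 60
  th <- direction * pi / 180
  layer$x <- layer$x + step * cos(th)
  layer$y <- layer$y - step * sin(th)     # y is measured downward
  w_um <- config$canvas[2] * config$pixel_size
  h_um <- config$canvas[1] * config$pixel_size
  if (config$boundary == "wrap") {
    layer$x <- layer$x %% w_um
    layer$y <- layer$y %% h_um
  }
  layer
}

#' Render one frame of a particle layer
#'
#' Each particle contributes a 2D Gaussian intensity profile
#' `A * exp(-2 d^2 / r^2)` sampled at pixel centers, where `r` is the 1/e^2
#' radius and the amplitude `A` is set so that the continuous integral of the
#' profile equals `photon_rate * exposure` photons (so a frame's pixel sum for
#' one interior particle approximates its photon budget to discretization
#' accuracy). Contributions add linearly; profiles are truncated at `2 r`
#' (4 sigma, < 0.04% mass loss). With `boundary = "wrap"` the tails wrap
#' around the canvas edges, conserving total photons exactly; with `"open"`
#' they are clipped. No noise is added.
#'
#' @param layer A `particle_layer`.
#' @param config A [sim_config()].
#' @return Numeric `canvas` matrix of photons per pixel.
#' @export
render_frame <- function(layer, config) {
  stopifnot(inherits(layer, "particle_layer"), inherits(config, "sim_config"))
  nr <- config$canvas[1]; nc <- config$canvas[2]
  px <- config$pixel_size
  frame <- matrix(0, nr, nc)
  n <- length(layer$x)
  if (n == 0L) return(frame)
  r <- layer$psf_radius
  amp <- 2 * layer$photon_rate * config$exposure / (pi * r^2)  # photons/um^2
  half <- ceiling(2 * r / px)               # truncation radius, px
  off <- -half:half
  wrap <- config$boundary == "wrap"
  for (p in seq_len(n)) {
    # pixel whose center is nearest the particle
    ic <- floor(layer$y[p] / px - 0.5) + 1
    jc <- floor(layer$x[p] / px - 0.5) + 1
    ii <- ic + off
    jj <- jc + off
    dy <- (ii - 0.5) * px - layer$y[p]
    dx <- (jj - 0.5) * px - layer$x[p]
    prof <- amp * px^2 * outer(exp(-2 * dy^2 / r^2), exp(-2 * dx^2 / r^2))
    if (wrap) {
      ii <- (ii - 1L) %% nr + 1L
      jj <- (jj - 1L) %% nc + 1L
      frame[ii, jj] <- frame[ii, jj] + prof
    } else {
      keep_i <- ii >= 1L & ii <= nr
      keep_j <- jj >= 1L & jj <= nc
      if (any(keep_i) && any(keep_j))
        frame[ii[keep_i], jj[keep_j]] <-
          frame[ii[keep_i], jj[keep_j]] + prof[keep_i, keep_j]
    }
  }
  frame
}

#' Combine two rendered layers
#'
#' `"add"` sums the series frame-wise. `"multiply"` multiplies them and
#' divides each frame by the spatial mean of the corresponding `b` frame so
#' the result stays on `a`'s intensity scale (the raw product would carry
#' photons-squared units; only relative fluctuations matter to STICS).
#'
#' @param a,b Two [image_series()] with identical shape and calibration.
#' @param mode `"add"` or `"multiply"`.
#' @return The combined `image_series`.
#' @export
combine_layers <- function(a, b, mode = c("add", "multiply")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "image_series"), inherits(b, "image_series"))
  if (!identical(dim(a$frames), dim(b$frames)))
    stop("layer shapes differ")
  if (a$pixel_size != b$pixel_size || a$frame_interval != b$frame_interval)
    stop("layer calibrations differ")
  out <- a
  if (mode == "add") {
    out$frames <- a$frames + b$frames
  } else {
    fr <- a$frames * b$frames
    for (t in seq_len(dim(fr)[3])) {
      mb <- mean(b$frames[, , t])
      fr[, , t] <- if (mb > 0) fr[, , t] / mb else fr[, , t]
    }
    out$frames <- fr
  }
  out
}

#' Simulate a two-layer fluorescence video with ground truth
#'
#' Seeds the RNG from `config$seed`, initializes the enabled layers (main
#' first, then wave, so a given seed always yields the same video), then for
#' each frame renders the layers, combines them per `combine_mode`, and
#' advances the layers by one frame interval. The returned ground truth
#' records the full configuration and the exact cumulative displacement of
#' each layer at every frame, which downstream tests compare against
#' STICS-recovered velocities.
#'
#' @param config A [sim_config()].
#' @param keep_positions If `TRUE`, per-frame particle positions are stored in
#'   the ground truth (as a list of data frames).
#' @return A list: `series` (an [image_series()], provenance `"simulated"`)
#'   and `truth` (list with `config`, `displacement_um` -- a data frame of
#'   per-frame cumulative (dx, dy) per layer, y up-positive -- and optionally
#'   `positions`).
#' @export
simulate_series <- function(config, keep_positions = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  main <- if (config$main_enabled) init_particles(config, "main") else NULL
  wave <- if (config$wave_enabled) init_particles(config, "wave") else NULL
  nt <- config$n_frames
  dt <- config$frame_interval
  frames_main <- if (config$main_enabled)
    array(0, c(config$canvas, nt)) else NULL
  frames_wave <- if (config$wave_enabled)
    array(0, c(config$canvas, nt)) else NULL
  positions <- if (keep_positions) vector("list", nt) else NULL
  for (t in seq_len(nt)) {
    if (config$main_enabled) frames_main[, , t] <- render_frame(main, config)
    if (config$wave_enabled) frames_wave[, , t] <- render_frame(wave, config)
    if (keep_positions)
      positions[[t]] <- list(
        main = if (config$main_enabled) data.frame(x = main$x, y = main$y),
        wave = if (config$wave_enabled) data.frame(x = wave$x, y = wave$y))
    if (t < nt) {
      if (config$main_enabled)
        main <- advance_particles(main, config$drift_speed,
                                  config$drift_direction, dt, config)
      if (config$wave_enabled)
        wave <- advance_particles(wave, config$wave_speed,
                                  config$wave_direction, dt, config)
    }
  }
  mk <- function(fr) image_series(fr, config$pixel_size,
                                  config$frame_interval,
                                  provenance = "simulated")
  series <- if (config$combine_mode == "none") {
    if (config$main_enabled) mk(frames_main) else mk(frames_wave)
  } else {
    combine_layers(mk(frames_main), mk(frames_wave),
                   mode = config$combine_mode)
  }
  tgrid <- seq_len(nt) - 1L
  step_um <- function(speed, dir) {
    s <- speed * dt / 60
    c(dx = s * cos(dir * pi / 180), dy = s * sin(dir * pi / 180))
  }
  dm <- step_um(config$drift_speed, config$drift_direction)
  dw <- step_um(config$wave_speed, config$wave_direction)
  truth <- list(
    config = config,
    displacement_um = data.frame(
      frame = tgrid + 1L,
      main_dx = if (config$main_enabled) tgrid * dm["dx"] else NA_real_,
      main_dy = if (config$main_enabled) tgrid * dm["dy"] else NA_real_,
      wave_dx = if (config$wave_enabled) tgrid * dw["dx"] else NA_real_,
      wave_dy = if (config$wave_enabled) tgrid * dw["dy"] else NA_real_))
  if (keep_positions) truth$positions <- positions
  list(series = series, truth = truth)
}
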