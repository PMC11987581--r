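test_that("ROI tiling follows floor((dim - size)/shift) + 1 per axis", {
  t1 <- tile_rois(c(100, 100), 32, 4)
  expect_equal(nrow(t1), 18 * 18)
  expect_equal(max(t1[, "row"]), 69L)   # last origin: 1 + 17 * 4
  t2 <- tile_rois(c(32, 32), 32, 4)
  expect_equal(nrow(t2), 1)
  expect_equal(unname(t2[1, ]), c(1L, 1L))
  t3 <- tile_rois(c(100, 100), 16, 2)
  expect_equal(nrow(t3), 43 * 43)
  # row-major ordering: columns advance fastest
  expect_equal(t1[2, "row"], t1[1, "row"])
  expect_equal(t1[2, "col"], t1[1, "col"] + 4L)
  expect_error(tile_rois(c(30, 30), 32, 4), "exceeds")
})

test_that("immobile subtraction centers every pixel's time trace", {
  expect_equal(subtract_immobile(array(1:5, c(1, 1, 5)))[1, 1, ],
               c(-2, -1, 0, 1, 2))
  static <- array(7, c(4, 4, 3))
  expect_equal(max(abs(subtract_immobile(static))), 0)
  set.seed(8)
  st <- array(stats::runif(6 * 6 * 5), c(6, 6, 5))
  expect_lt(max(abs(rowMeans(subtract_immobile(st), dims = 2))), 1e-12)
})

test_that("FFT correlation equals the direct-sum oracle on random stacks", {
  set.seed(13)
  for (rep in 1:3) {
    st <- array(stats::runif(8 * 8 * 4, 0.5, 1.5), c(8, 8, 4))
    dst <- subtract_immobile(st)
    m <- colMeans(st, dims = 2)
    co <- correlation_function(dst, 3, means = m)
    for (tau in 0:3) {
      o <- oracle_correlation(dst, tau, m, co$lags_row, co$lags_col)
      expect_lt(max(abs(o - co$values[, , tau + 1])) / max(abs(o)), 1e-10)
    }
  }
})

test_that("zero-lag correlation is point-symmetric", {
  set.seed(14)
  st <- array(stats::runif(16 * 16 * 5), c(16, 16, 5))
  co <- correlation_function(subtract_immobile(st), 2,
                             means = colMeans(st, dims = 2))
  v0 <- co$values[, , 1]
  n <- 16
  # lag grid is -8..7; the symmetric partner of index i is the index of -lag
  for (ei in 2:n) for (xj in 2:n)
    expect_equal(v0[ei, xj], v0[n + 2 - ei, n + 2 - xj], tolerance = 1e-12)
})

test_that("correlation handles degenerate stacks", {
  # identical frames + immobile subtraction -> identically zero correlation
  st <- array(rep(matrix(stats::runif(64), 8, 8), 4), c(8, 8, 4))
  co <- correlation_function(subtract_immobile(st), 3,
                             means = colMeans(st, dims = 2))
  expect_equal(max(abs(co$values)), 0)
  # all-zero stack is flagged empty
  expect_true(correlation_function(array(0, c(8, 8, 3)), 2)$empty)
})

test_that("a translating spot produces correlation peaks at (tau, 0)", {
  st <- spot_series(32, centers = cbind(16, 8), sigma = 2, n_frames = 5,
                    shift_per_frame = c(0, 1), background = 0)
  co <- correlation_function(st, 3)
  for (tau in 1:3) {
    sl <- co$values[, , tau + 1]
    pk <- arrayInd(which.max(sl), dim(sl))
    expect_equal(co$lags_col[pk[2]], tau)    # xi = tau
    expect_equal(co$lags_row[pk[1]], 0)      # eta = 0
  }
  p <- stics_params()
  tr <- track_peaks(co, p)
  expect_equal(tr$tau, 1:3)
  expect_lt(max(abs(tr$xi - 1:3)), 0.1)
  expect_lt(max(abs(tr$eta)), 0.1)
})

test_that("gaussian peak fitting recovers noiseless parameters", {
  lags <- -16:15
  mk <- function(cx, cy, w, A, c0) {
    outer(lags, lags, function(eta, xi)
      A * exp(-((xi - cx)^2 + (eta - cy)^2) / w^2) + c0)
  }
  sl <- mk(1.3, -0.7, 3, 2, 0.1)
  f <- fit_gaussian_peak(sl, c(0, 0), 8)
  expect_true(f$converged)
  expect_equal(unname(f$center), c(1.3, -0.7), tolerance = 1e-6)
  expect_equal(f$width, 3, tolerance = 1e-6)
  expect_equal(f$amplitude, 2, tolerance = 1e-6)
  expect_equal(f$offset, 0.1, tolerance = 1e-5)

  # constant slice: no peak to fit
  expect_false(fit_gaussian_peak(matrix(1, 32, 32), c(0, 0), 8)$converged)

  # Gaussian on a linear ramp: center within 0.2 px of a dense grid search
  ramp <- outer(lags, lags, function(eta, xi) 0.02 * xi + 0.01 * eta)
  sl2 <- mk(2.2, 1.1, 3, 1, 0) + ramp
  f2 <- fit_gaussian_peak(sl2, c(0, 0), 8)
  expect_true(f2$converged)
  grid <- expand.grid(cx = seq(1.0, 3.4, by = 0.05),
                      cy = seq(-0.1, 2.3, by = 0.05))
  sse <- mapply(function(cx, cy) {
    mdl <- outer(lags, lags, function(eta, xi)
      exp(-((xi - cx)^2 + (eta - cy)^2) / 9))
    win <- abs(row(sl2) - 17) <= 8 & abs(col(sl2) - 17) <= 8
    z <- sl2[win]; m <- mdl[win]
    ls <- stats::lm.fit(cbind(m, 1), z)
    sum(ls$residuals^2)
  }, grid$cx, grid$cy)
  best <- grid[which.min(sse), ]
  expect_lt(max(abs(unname(f2$center) - c(best$cx, best$cy))), 0.2)
})

test_that("peak tracking enforces continuity and drop semantics", {
  # build a correlation object with a clean moving peak for tau 1..2 and a
  # flat slice at tau 3: the flat lag is dropped, two centers survive
  lags <- -16:15
  vals <- array(0, c(32, 32, 4))
  for (tau in 1:2)
    vals[, , tau + 1] <- outer(lags, lags, function(eta, xi)
      exp(-((xi - tau)^2 + eta^2) / 4))
  co <- structure(list(values = vals, lags_row = lags, lags_col = lags,
                       normalization_used = rep(TRUE, 4), empty = FALSE),
                  class = "stics_corr")
  p <- stics_params(min_lags_for_fit = 2)
  tr <- track_peaks(co, p)
  expect_equal(tr$tau, 1:2)
  expect_false(attr(tr, "insufficient"))
  p3 <- stics_params(min_lags_for_fit = 3)
  expect_true(attr(track_peaks(co, p3), "insufficient"))

  # static structure: peaks pinned at zero lag
  stv <- array(rep(outer(lags, lags, function(eta, xi)
    exp(-(xi^2 + eta^2) / 9)), 4), c(32, 32, 4))
  co0 <- structure(list(values = stv, lags_row = lags, lags_col = lags,
                        normalization_used = rep(TRUE, 4), empty = FALSE),
                   class = "stics_corr")
  tr0 <- track_peaks(co0, stics_params())
  expect_equal(tr0$tau, 1:3)
  expect_lt(max(abs(c(tr0$xi, tr0$eta))), 0.05)
})

test_that("velocities convert peak slopes with the calibration", {
  pk <- data.frame(tau = 1:3, xi = 1:3, eta = 0)
  v <- velocity_from_peaks(pk, 0.14, 15)
  expect_equal(v$vx, 0.56)       # 1 px/frame * 0.14 um * 4 frames/min
  expect_equal(v$vy, 0)
  expect_equal(v$r2, 1)

  pk0 <- data.frame(tau = 1:3, xi = 0, eta = 0)
  v0 <- velocity_from_peaks(pk0, 0.14, 15)
  expect_equal(c(v0$vx, v0$vy), c(0, 0))

  # diagonal 0.5 px/frame in both axes; eta grows downward so vy < 0
  pkd <- data.frame(tau = 1:4, xi = 0.5 * 1:4, eta = 0.5 * 1:4)
  vd <- velocity_from_peaks(pkd, 0.14, 15)
  expect_equal(vd$vx, 0.28)
  expect_equal(vd$vy, -0.28)
  expect_error(velocity_from_peaks(pk[1, ], 0.14, 15), "at least 2")
})

test_that("full analysis recovers a rigid integer-pixel translation", {
  # noiseless pattern rolled cyclically by exactly 1 px/frame rightward;
  # the ROI spans the whole (periodic) frame so the cyclic correlation is an
  # exact model of the motion. Nothing is immobile in a rigidly rolled
  # pattern, so the temporal-mean subtraction is disabled: it would
  # reintroduce a correlated streak.
  set.seed(17)
  centers <- cbind(sample(5:28, 10, replace = TRUE),
                   sample(5:28, 10, replace = TRUE))
  fr <- spot_series(32, centers, sigma = 2, n_frames = 8, background = 0)
  for (t in 2:8) fr[, , t] <- roll_matrix(fr[, , 1], 0, t - 1)
  s <- image_series(fr, 0.14, 15, provenance = "simulated")
  p <- stics_params(roi_size = 32, roi_shift = 4,
                    immobile_subtraction = FALSE)
  res <- suppressWarnings(stics_analyze(s, p))
  v <- bind_fields(res)
  v <- v[v$valid, ]
  expect_gt(nrow(v), 0)
  true_speed <- 1 * 0.14 * 60 / 15
  expect_lt(max(abs(v$speed_um_min - true_speed)) / true_speed, 0.02)
  expect_lt(max(abs(v$angle_deg)), 2)
})

test_that("every ROI yields exactly one vector and reasons are recorded", {
  cfg <- default_sim_config("contiguous", n_frames = 6, canvas = c(60, 60),
                            n_particles = 60, seed = 3)
  sim <- simulate_series(cfg)
  p <- stics_params(roi_size = 32, roi_shift = 8)
  res <- suppressWarnings(stics_analyze(sim$series, p))
  expect_length(res, 2)  # (6 - 5)/1 + 1 TOIs
  tiling <- tile_rois(c(60, 60), 32, 8)
  for (f in res) expect_equal(nrow(f), nrow(tiling))
  expect_true(all(bind_fields(res)$rejection_reason[
    !bind_fields(res)$valid] != "none"))
  expect_error(stics_analyze(crop_roi(sim$series, c(1, 1), c(20, 20)), p),
               "roi_size")
})

test_that("a static noiseless series produces no spurious flow", {
  cfg <- default_sim_config("contiguous", drift_speed = 0, n_frames = 8,
                            canvas = c(64, 64), n_particles = 80, seed = 6)
  sim <- simulate_series(cfg)
  res <- suppressWarnings(
    stics_analyze(sim$series, stics_params(roi_size = 32, roi_shift = 16)))
  v <- bind_fields(res)
  expect_true(all(v$speed_um_min[v$valid] < 0.02, na.rm = TRUE))
})

test_that("doubling all intensities changes no vector", {
  cfg <- default_sim_config("contiguous", n_frames = 7, canvas = c(64, 64),
                            n_particles = 60, seed = 12)
  sim <- simulate_series(cfg)
  p <- stics_params(roi_size = 32, roi_shift = 16)
  r1 <- bind_fields(suppressWarnings(stics_analyze(sim$series, p)))
  doubled <- image_series(2 * sim$series$frames, 0.14, 15, "simulated")
  r2 <- bind_fields(suppressWarnings(stics_analyze(doubled, p)))
  expect_equal(r1$vx_um_min, r2$vx_um_min, tolerance = 1e-8)
  expect_equal(r1$vy_um_min, r2$vy_um_min, tolerance = 1e-8)
  expect_identical(r1$valid, r2$valid)
})
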