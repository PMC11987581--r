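test_that("image_series validates shape, calibration and sign", {
  fr <- array(1, c(8, 8, 3))
  s <- image_series(fr, 0.14, 15)
  expect_s3_class(s, "image_series")
  expect_equal(n_frames(s), 3)
  expect_equal(frame_dims(s), c(8L, 8L))

  expect_error(image_series(fr, -0.1, 15), "pixel_size")
  expect_error(image_series(fr, 0.14, 0), "frame_interval")
  fr[1, 1, 1] <- NA
  expect_error(image_series(fr, 0.14, 15), "finite")
  fr[1, 1, 1] <- -2
  expect_error(image_series(fr, 0.14, 15), "negative")
  expect_silent(image_series(fr, 0.14, 15, provenance = "heterogeneity"))
})

test_that("TIFF round trip is bit-exact for integers and float-accurate for signed data", {
  tmp <- withr::local_tempfile(fileext = ".tif")
  fr <- array(sample(0:65535, 10 * 64 * 64, replace = TRUE), c(64, 64, 10))
  s <- image_series(fr, 0.2146, 15, provenance = "simulated")
  write_tiff_series(s, tmp)
  r <- read_tiff_series(tmp)
  expect_identical(dim(r$frames), c(64L, 64L, 10L))
  expect_identical(r$frames, s$frames)          # bit-exact
  expect_equal(r$pixel_size, 0.2146)            # sidecar calibration
  expect_equal(r$frame_interval, 15)
  expect_equal(r$provenance, "simulated")

  # signed (heterogeneity-like) data survives to 32-bit float precision
  fr2 <- array(stats::rnorm(3 * 16 * 16), c(16, 16, 3))
  s2 <- image_series(fr2, 0.14, 15, provenance = "heterogeneity")
  tmp2 <- withr::local_tempfile(fileext = ".tif")
  write_tiff_series(s2, tmp2)
  r2 <- read_tiff_series(tmp2)
  expect_lt(max(abs(r2$frames - fr2)), diff(range(fr2)) * 2^-23)
  expect_true(any(r2$frames < 0))

  # empty series cannot be written
  empty <- image_series(array(0, c(4, 4, 0)), 1, 1)
  expect_error(write_tiff_series(empty, tmp2), "empty")
})

test_that("reading rejects missing files and mismatched pages", {
  expect_error(read_tiff_series("no/such/file.tif", 0.14, 15), "not found")
  # pages of different sizes
  tmp <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.5, 32, 64), matrix(0.5, 64, 64)), tmp,
                  bits.per.sample = 16)
  expect_error(read_tiff_series(tmp, 0.14, 15), "non-uniform")
  # calibration required when no sidecar exists
  tmp2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 8, 8), tmp2)
  expect_error(read_tiff_series(tmp2), "pixel_size")
})

test_that("crop_roi extracts windows and rejects out-of-bounds requests", {
  fr <- array(seq_len(100 * 100 * 2), c(100, 100, 2))
  s <- image_series(fr / max(fr), 0.14, 15)
  full <- crop_roi(s, c(1, 1), c(100, 100))
  expect_identical(full$frames, s$frames)
  sub <- crop_roi(s, c(11, 11), c(32, 32))
  expect_identical(dim(sub$frames), c(32L, 32L, 2L))
  expect_identical(sub$frames[1, 1, 1], s$frames[11, 11, 1])
  expect_equal(sub$pixel_size, s$pixel_size)
  expect_error(crop_roi(s, c(91, 91), c(32, 32)), "exceeds")
})

test_that("phase correlation recovers cyclic shifts exactly and is idempotent", {
  set.seed(42)
  f0 <- matrix(stats::runif(64 * 64), 64, 64)
  shifts <- list(c(3, -2), c(-10, 10), c(10, -10), c(0, 7), c(31, 0))
  frames <- array(0, c(64, 64, length(shifts) + 1))
  frames[, , 1] <- f0
  for (k in seq_along(shifts))
    frames[, , k + 1] <- roll_matrix(f0, shifts[[k]][1], shifts[[k]][2])
  s <- image_series(frames, 0.14, 15)
  reg <- register_series(s)
  for (k in seq_along(shifts))
    expect_equal(unlist(reg$registration[k + 1, c("shift_row", "shift_col")],
                        use.names = FALSE), shifts[[k]])
  # registered frames coincide with the reference
  expect_equal(max(abs(reg$series$frames[, , 2] - f0)), 0)
  # idempotence: a second pass finds nothing to correct
  reg2 <- register_series(reg$series)
  expect_true(all(reg2$registration$shift_row == 0))
  expect_true(all(reg2$registration$shift_col == 0))
})

test_that("registration matches a direct cross-correlation argmax for a pad shift", {
  # a non-cyclic (pad-and-crop) translation of smooth content
  set.seed(7)
  big <- matrix(0, 80, 80)
  for (k in 1:12) {
    cy <- sample(20:60, 1); cx <- sample(20:60, 1)
    big <- big + outer(exp(-(1:80 - cy)^2 / 8), exp(-(1:80 - cx)^2 / 8))
  }
  a <- big[11:50, 11:50]
  b <- big[11 - 5 + 0:39, 11 - 4 + 0:39]   # content appears shifted by (5, 4)
  # oracle: argmax of direct (non-FFT) cross-correlation over candidate shifts
  best <- c(0, 0); bestv <- -Inf
  for (dr in -8:8) for (dc in -8:8) {
    v <- sum(a * roll_matrix(b, -dr, -dc))
    if (v > bestv) { bestv <- v; best <- c(dr, dc) }
  }
  s <- image_series(array(c(a, b), c(40, 40, 2)), 0.14, 15)
  reg <- register_series(s)$registration
  got <- c(reg$shift_row[2], reg$shift_col[2])
  expect_lte(max(abs(got - best)), 1)
  expect_lte(max(abs(got - c(5, 4))), 1)
})

test_that("constant frames are flagged and left in place", {
  fr <- array(0, c(16, 16, 3))
  fr[, , 1] <- matrix(stats::runif(256), 16, 16)
  fr[, , 3] <- roll_matrix(fr[, , 1], 2, 2)
  s <- image_series(fr, 0.14, 15)
  reg <- register_series(s)
  expect_true(reg$registration$flagged[2])
  expect_equal(unlist(reg$registration[2, c("shift_row", "shift_col")],
                      use.names = FALSE), c(0, 0))
  expect_false(reg$registration$flagged[3])
})
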