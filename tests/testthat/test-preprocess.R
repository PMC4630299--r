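test_that("spatial binning averages blocks exactly", {
  m <- make_flat_movie(7, c(16, 16, 3), cal = calibration(0.108, 3.5))
  out <- bin_spatial(m, 4)
  expect_equal(dim(out$data), c(4, 4, 3))
  expect_true(all(out$data == 7))
  expect_equal(out$calibration$bin_factor, 4L)
  expect_equal(effective_pixel_um(out$calibration), 0.432)

  # 4x4 block of 0..15 averages to 7.5
  m2 <- movie(array(matrix(0:15, 4, 4, byrow = TRUE), c(4, 4, 2)), ref_cal())
  expect_equal(as.vector(bin_spatial(m2, 4)$data[1, 1, ]), c(7.5, 7.5))

  # random frame equals a loop-based block-mean oracle
  set.seed(1)
  x <- array(runif(24 * 24 * 2), c(24, 24, 2))
  m3 <- movie(x, ref_cal())
  out3 <- bin_spatial(m3, 4)
  oracle <- array(0, c(6, 6, 2))
  for (t in 1:2) for (i in 1:6) for (j in 1:6)
    oracle[i, j, t] <- mean(x[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j), t])
  expect_equal(out3$data, oracle, tolerance = 1e-12)
})

test_that("binning trims non-divisible trailing rows and columns", {
  m <- movie(array(1, c(10, 11, 2)), ref_cal())
  out <- bin_spatial(m, 4)
  expect_equal(dim(out$data)[1:2], c(2, 2))
})

test_that("temporal stretching doubles length and reproduces simple series", {
  m <- make_flat_movie(3, c(8, 8, 6), cal = calibration(0.108, 3.5))
  out <- stretch_time(m, 2)
  expect_equal(dim(out$data)[3], 12)
  expect_equal(max(abs(out$data - 3)), 0, tolerance = 1e-9)
  expect_equal(out$calibration$time_stretch, 2L)
  expect_equal(effective_interval_s(out$calibration), 1.75)

  # per-pixel linear ramp: inserted frames are arithmetic midpoints
  x <- array(0, c(4, 4, 8))
  for (t in 1:8) x[, , t] <- t * 2 + 5
  ms <- stretch_time(movie(x, ref_cal()), 2)
  expect_equal(ms$data[1, 1, 2], (x[1, 1, 1] + x[1, 1, 2]) / 2, tolerance = 1e-6)
  expect_equal(ms$data[2, 3, 8], (x[2, 3, 4] + x[2, 3, 5]) / 2, tolerance = 1e-6)
  # original frames are reproduced at odd output indices
  expect_equal(ms$data[, , 7], x[, , 4], tolerance = 1e-8)

  # sinusoid: quintic interpolation beats linear interpolation
  tt <- 1:30
  y <- 2 + sin(tt / 3)
  xs <- array(rep(y, each = 4), c(2, 2, 30))
  st <- stretch_time(movie(xs, ref_cal()), 2)
  xq <- pmin(1 + (seq_len(60) - 1) / 2, 30)
  err_q <- max(abs(st$data[1, 1, ] - (2 + sin(xq / 3))))
  err_lin <- max(abs(approx(tt, y, xq)$y - (2 + sin(xq / 3))))
  expect_lt(err_q, err_lin)

  # factor 1 is an identity
  expect_equal(stretch_time(m, 1)$data, m$data, tolerance = 1e-9)
})

test_that("centered crop bookkeeping is exact", {
  set.seed(2)
  x <- array(runif(64 * 64 * 2), c(64, 64, 2))
  m <- movie(x, ref_cal())
  expect_identical(crop_center(m, c(64, 64))$data, x)
  out <- crop_center(m, c(50, 50))
  expect_equal(out$data[1, 1, 1], x[8, 8, 1])   # offset floor((64-50)/2) = 7
  expect_equal(out$data[50, 50, 2], x[57, 57, 2])
  expect_error(crop_center(m, 100), "exceeds")
  # odd remainder: extra pixel removed from the right/bottom
  out2 <- crop_center(m, c(63, 63))
  expect_equal(out2$data[1, 1, 1], x[1, 1, 1])
})

test_that("contrast enhancement stretches, equalizes and converts to 8-bit", {
  x <- array(0, c(10, 10, 2)); x[, 6:10, ] <- 100
  m <- movie(x, ref_cal())
  out <- enhance_contrast_8bit(m, 0, equalize = FALSE)
  expect_setequal(unique(as.vector(out$data)), c(0, 255))
  expect_equal(out$bit_depth, 8L)

  # equalization flattens the histogram of a skewed random stack
  set.seed(3)
  sk <- array(rexp(32 * 32 * 3, rate = 1 / 50), c(32, 32, 3))
  msk <- movie(sk, ref_cal())
  eq <- enhance_contrast_8bit(msk, 0.02, equalize = TRUE)
  st <- enhance_contrast_8bit(msk, 0.02, equalize = FALSE)
  cv <- function(v) { h <- tabulate(findInterval(v, seq(0, 256, by = 16)), 16); sd(h) / mean(h) }
  expect_lt(cv(as.vector(eq$data)), cv(as.vector(st$data)))
  # equalization is a monotone map of the input intensities
  o <- order(as.vector(msk$data))
  expect_true(all(diff(as.vector(eq$data)[o]) >= 0))

  # constant movie: mid-gray with a warning, not an error
  expect_warning(cm <- enhance_contrast_8bit(make_flat_movie(5)), "constant")
  expect_true(all(cm$data == 128))
})

test_that("mean-projection background subtraction removes static structure", {
  sc <- mixed_scene(n_stationary = 15, n_moving = 0, n_frames = 8, size = c(64, 64),
                    noise_gaussian_sd = 0, noise_poisson_scale = 0, jitter_sd = 0)
  out <- subtract_mean_projection(sc$movie)
  expect_equal(max(abs(out$data)), 0, tolerance = 1e-9)

  # adding a constant to every frame leaves the output unchanged
  m2 <- sc$movie; m2$data <- m2$data + 37
  expect_equal(subtract_mean_projection(m2)$data, out$data, tolerance = 1e-9)

  # a mover retains a positive transient over a ~zero background
  mv <- single_mover_scene(0.4, n_frames = 12, size = c(48, 80),
                           noise_gaussian_sd = 0, noise_poisson_scale = 0)
  sub <- subtract_mean_projection(mv$movie)
  tr <- mv$truth$trajectories[[1]]
  expect_gt(sub$data[round(tr[12, "y"]), round(tr[12, "x"]), 12], 100)
  corner <- sub$data[1:10, 1:10, ]
  expect_lt(mean(corner), 1e-9)
})

test_that("velocity unit conversion follows the effective calibration", {
  cal <- ref_cal()
  expect_equal(effective_pixel_um(cal), 0.432)
  expect_equal(effective_interval_s(cal), 1.75)
  expect_equal(velocity_umps(1, cal), 0.432 / 1.75)
  expect_equal(velocity_umps(0, cal), 0)
  expect_equal(umps_to_pf(velocity_umps(3.7, cal), cal), 3.7, tolerance = 1e-12)
})

test_that("count_maxima counts prominent peaks only", {
  expect_equal(count_maxima(matrix(0, 20, 20), 1, 10), 0)
  fr <- matrix(0, 40, 40)
  pos <- cbind(c(8, 8, 20, 32, 32), c(8, 32, 20, 8, 32))
  for (i in 1:5) fr <- add_spot(fr, pos[i, 1], pos[i, 2], 100, 1.5)
  expect_equal(count_maxima(fr, 2, 30), 5)
  expect_equal(count_maxima(fr, 1, 30), 5)
  expect_equal(count_maxima(fr, 2, 150), 0)   # tolerance above amplitude
  # a connected plateau counts once
  pl <- matrix(0, 12, 12); pl[5:7, 5:7] <- 50
  expect_equal(count_maxima(pl, 1, 10), 1)
})

test_that("rigid registration recovers translation and rotation", {
  sc <- mixed_scene(n_stationary = 30, n_moving = 0, n_frames = 4, size = c(96, 96),
                    jitter_sd = 0, seed = 3)
  inj <- inject_artifacts(sc$movie, artifact_spec(
    drift = data.frame(frame = 2, dx = 2.0, dy = -1.0)))
  reg <- register_rigid(inj$movie)
  expect_equal(reg$transforms$dx[1], 0)
  expect_lt(max(abs(reg$transforms$dx[2:4] - 2.0)), 0.25)
  expect_lt(max(abs(reg$transforms$dy[2:4] + 1.0)), 0.25)
  # residual shift between consecutive registered frames
  ph <- mitomotion:::phase_shift_estimate(reg$movie$data[, , 2], reg$movie$data[, , 3])
  expect_lt(max(abs(ph)), 0.25 + 1e-9)

  # rotation by 2 degrees about the center
  m2 <- sc$movie
  th <- 2 * pi / 180
  m2$data[, , 2] <- mitomotion:::rigid_resample(sc$movie$data[, , 2], 0, 0, th)
  reg2 <- register_rigid(m2)
  expect_lt(abs(abs(reg2$transforms$theta[2]) - th), 0.2 * pi / 180)

  # identical frames give identity transforms
  mi <- make_flat_movie(100, c(32, 32, 3))
  mi$data[5:10, 5:10, ] <- 200
  regi <- register_rigid(mi)
  expect_lt(max(abs(as.matrix(regi$transforms[, c("dx", "dy", "theta")]))), 1e-3)

  # registration barely changes per-frame mean intensity
  scj <- mixed_scene(n_stationary = 30, n_moving = 0, n_frames = 4, size = c(96, 96),
                     seed = 4)
  regj <- register_rigid(scj$movie)
  mu0 <- apply(scj$movie$data, 3, mean); mu1 <- apply(regj$movie$data, 3, mean)
  expect_lt(max(abs(mu1 / mu0 - 1)), 0.01)

  expect_error(register_rigid(movie(array(0, c(8, 8, 3)), ref_cal())), "zero")
})

test_that("kymographs turn constant-velocity runs into straight ridges", {
  sc <- single_mover_scene(0.394, n_frames = 40, size = c(64, 200), seed = 4,
                           noise_gaussian_sd = 2, noise_poisson_scale = 0)
  tr <- sc$truth$trajectories[[1]]
  path <- cbind(c(tr[1, "x"] - 2, tr[40, "x"] + 2), c(tr[1, "y"], tr[40, "y"]))
  ky <- kymograph(sc$movie, path, width = 3)
  ridge <- apply(ky, 2, which.max)
  slope_pf <- unname(coef(lm(ridge ~ seq_along(ridge)))[2])
  v_est <- slope_pf * 0.432 / 3.5
  expect_lt(abs(v_est - 0.394) / 0.394, 0.10)

  # static movie: every column identical
  st <- mixed_scene(n_stationary = 10, n_moving = 0, n_frames = 5, size = c(48, 48),
                    noise_gaussian_sd = 0, noise_poisson_scale = 0, jitter_sd = 0)
  ky2 <- kymograph(st$movie, cbind(c(5, 40), c(24, 24)), width = 3)
  expect_equal(max(apply(ky2, 1, function(r) diff(range(r)))), 0, tolerance = 1e-9)
})

test_that("every operation appends exactly one replayable history entry", {
  m <- mixed_scene(n_stationary = 5, n_moving = 0, n_frames = 6, size = c(48, 48))$movie
  n0 <- length(m$history)
  steps <- list(function(x) bin_spatial(x, 2),
                function(x) stretch_time(x, 2),
                function(x) crop_center(x, c(20, 20)),
                function(x) subtract_mean_projection(x))
  for (i in seq_along(steps)) {
    m <- steps[[i]](m)
    expect_length(m$history, n0 + i)
  }
  ops <- vapply(m$history, `[[`, character(1), "op")
  expect_equal(ops[(n0 + 1):(n0 + 4)],
               c("bin_spatial", "stretch_time", "crop_center", "subtract_mean_projection"))
  expect_equal(m$history[[n0 + 1]]$factor, 2L)
})

test_that("movies round-trip through multi-page TIFF with a YAML sidecar", {
  sc <- mixed_scene(n_stationary = 8, n_moving = 0, n_frames = 4, size = c(32, 32))
  path <- tempfile(fileext = ".tif")
  write_movie_tiff(sc$movie, path)
  back <- read_movie_tiff(path)
  expect_equal(dim(back$data), dim(sc$movie$data))
  expect_lt(max(abs(back$data - sc$movie$data)), 65535 / 65535 + 0.51)
  expect_equal(back$calibration$pixel_size_um, sc$movie$calibration$pixel_size_um)
})
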