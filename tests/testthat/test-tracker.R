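# Build an 8-bit movie directly from an array (bypassing contrast
# enhancement) for controlled difference-filter scenarios.
movie8 <- function(x, cal = ref_cal()) movie(x, cal, bit_depth = 8L)

# A dim 8-bit spot movie with one mover at v px/frame along +x.
spot_movie8 <- function(v_pf = 1.5, n_frames = 16, size = c(40, 80),
                        amplitude = 120, y0 = 20, x0 = 10) {
  x <- array(0, c(size[1], size[2], n_frames))
  for (t in 1:n_frames)
    x[, , t] <- add_spot(matrix(0, size[1], size[2]), y0, x0 + (t - 1) * v_pf,
                         amplitude, 1.5)
  movie8(round(x))
}

test_that("the difference filter isolates moving pixels", {
  st <- movie8(array(100, c(16, 16, 10)))
  out <- difference_filter(st, dt_params())
  expect_equal(out$stats$moving_intensity, 0)
  expect_equal(max(out$movie$data), 0)

  mv <- spot_movie8(2)
  res <- difference_filter(mv, dt_params())
  expect_gt(res$stats$moving_intensity, 0)
  expect_gt(res$stats$moving_count, 0)
  # moving pixels keep their original intensity
  w <- which(res$movie$data > 0)
  expect_equal(res$movie$data[w], mv$data[w])

  expect_error(difference_filter(make_flat_movie(1), dt_params()), "8-bit")
})

test_that("raising min_difference never increases moving intensity", {
  mv <- spot_movie8(1.5)
  mi <- sapply(c(10, 20, 40, 80), function(md)
    difference_filter(mv, dt_params(min_difference = md))$stats$moving_intensity)
  expect_true(all(diff(mi) <= 0))
})

test_that("movers slower than the offset speed floor are invisible", {
  # floor: 1 px per (offset * interval); here 4 frames. A mover at 0.05
  # px/frame moves 0.2 px per offset window: sub-threshold for a dim spot.
  slow <- spot_movie8(0.05, n_frames = 20, amplitude = 60)
  fast <- spot_movie8(1.2, n_frames = 20, amplitude = 60)
  rs <- difference_filter(slow, dt_params())
  rf <- difference_filter(fast, dt_params())
  expect_equal(rs$stats$moving_count, 0)
  expect_gt(rf$stats$moving_count, 0)
})

test_that("feature detection matches a flood-fill oracle", {
  p <- dt_params()
  expect_equal(nrow(detect_features(matrix(0, 10, 10), p)), 0)

  fr <- matrix(0, 20, 20); fr[5:7, 5:7] <- 30
  f <- detect_features(fr, p)
  expect_equal(nrow(f), 1)
  expect_equal(f$area, 9)
  expect_equal(c(f$x, f$y), c(6, 6))
  expect_equal(f$total_intensity, 270)

  # random blocks against an independent flood-fill labeling
  flood_label <- function(mask) {
    H <- nrow(mask); W <- ncol(mask); lab <- matrix(0L, H, W); k <- 0L
    for (j in 1:W) for (i in 1:H) {
      if (mask[i, j] && lab[i, j] == 0L) {
        k <- k + 1L; st <- list(c(i, j)); lab[i, j] <- k
        while (length(st)) {
          q <- st[[length(st)]]; st[[length(st)]] <- NULL
          for (dy in -1:1) for (dx in -1:1) {
            r <- q[1] + dy; c <- q[2] + dx
            if (r >= 1 && r <= H && c >= 1 && c <= W && mask[r, c] && lab[r, c] == 0L) {
              lab[r, c] <- k; st[[length(st) + 1L]] <- c(r, c)
            }
          }
        }
      }
    }
    lab
  }
  set.seed(11)
  for (rep in 1:5) {
    fr2 <- matrix(0, 30, 30)
    for (b in 1:6) {
      i <- sample(1:26, 1); j <- sample(1:26, 1)
      fr2[i:(i + sample(2:4, 1)), j:(j + sample(2:4, 1))] <- sample(20:80, 1)
    }
    f2 <- detect_features(fr2, dt_params(min_tracked_intensity = 0,
                                         min_feature_size = 1))
    lab <- flood_label(fr2 > 0)
    expect_equal(nrow(f2), max(lab))
    # per-component area and intensity-weighted centroid agree
    ord <- order(f2$x, f2$y)
    oc <- t(sapply(seq_len(max(lab)), function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      w <- fr2[idx]
      c(x = sum(w * idx[, 2]) / sum(w), y = sum(w * idx[, 1]) / sum(w),
        area = nrow(idx))
    }))
    oo <- order(oc[, "x"], oc[, "y"])
    expect_equal(f2$x[ord], unname(oc[oo, "x"]))
    expect_equal(f2$area[ord], unname(as.integer(oc[oo, "area"])))
  }
})

test_that("a single constant-velocity mover yields one accurate track", {
  v_pf <- 1.5
  mv <- spot_movie8(v_pf, n_frames = 14)
  res <- difference_tracker(mv, dt_params())
  expect_equal(res$report$total_track_count, 1)
  tr <- res$tracks[[1]]
  expect_gte(tr$duration, 8)
  truth_umps <- v_pf * effective_pixel_um(mv$calibration) /
    effective_interval_s(mv$calibration)
  expect_lt(abs(tr$mean_speed_umps - truth_umps) / truth_umps, 0.15)
  expect_equal(tr$direction, 1)   # moving left to right
})

test_that("linking matches a brute-force global assignment on parallel movers", {
  # two well-separated movers
  n <- 12
  x <- array(0, c(60, 80, n))
  for (t in 1:n) {
    fr <- matrix(0, 60, 80)
    fr <- add_spot(fr, 15, 10 + (t - 1) * 1.5, 120, 1.5)
    fr <- add_spot(fr, 45, 10 + (t - 1) * 1.8, 120, 1.5)
    x[, , t] <- round(fr)
  }
  m <- movie8(x)
  res <- difference_tracker(m, dt_params())
  expect_equal(length(res$tracks), 2)

  # brute-force per-frame optimal assignment oracle on the same features
  feats <- res$features
  oracle_tracks <- list()
  prev <- NULL
  for (t in seq_along(feats)) {
    f <- feats[[t]]
    if (is.null(prev)) {
      prev <- lapply(seq_len(nrow(f)), function(i) list(xs = f$x[i], ys = f$y[i], fr = t))
    } else {
      stopifnot(nrow(f) == length(prev))
      perms <- if (nrow(f) == 2) list(1:2, 2:1) else list(1)
      costs <- sapply(perms, function(p)
        sum((sapply(prev, function(tr) tail(tr$xs, 1)) - f$x[p])^2 +
            (sapply(prev, function(tr) tail(tr$ys, 1)) - f$y[p])^2))
      p <- perms[[which.min(costs)]]
      prev <- lapply(seq_along(prev), function(i) {
        tr <- prev[[i]]
        tr$xs <- c(tr$xs, f$x[p[i]]); tr$ys <- c(tr$ys, f$y[p[i]]); tr
      })
    }
  }
  # the greedy linker's trajectories equal the optimal assignment's
  got <- lapply(res$tracks, function(tr) cbind(tr$x, tr$y))
  want <- lapply(prev, function(tr) cbind(tr$xs, tr$ys))
  ord_g <- order(sapply(got, function(g) g[1, 2]))
  ord_w <- order(sapply(want, function(g) g[1, 2]))
  for (i in 1:2)
    expect_equal(got[[ord_g[i]]], want[[ord_w[i]]], tolerance = 1e-9)
})

test_that("tracks never share features and respect the length floor", {
  mv <- mixed_scene(n_stationary = 40, n_moving = 2, n_frames = 30,
                    size = c(128, 128), seed = 13)
  pre <- stretch_time(mv$movie, 2)
  m8 <- enhance_contrast_8bit(pre, 0.05, equalize = FALSE)
  res <- difference_tracker(m8, dt_params())
  # exclusivity: features identified by (frame, x, y) appear in one track
  keys <- unlist(lapply(res$tracks, function(tr)
    paste(tr$frames, round(tr$x, 6), round(tr$y, 6))))
  expect_equal(anyDuplicated(keys), 0)
  for (tr in res$tracks) {
    expect_true(all(diff(tr$frames) == 1))
    expect_gte(tr$duration, dt_params()$min_track_length)
  }
  # a stricter length floor never yields more tracks
  res8 <- difference_tracker(m8, dt_params(min_track_length = 8))
  expect_lte(length(res8$tracks), length(res$tracks))
})

test_that("empty feature streams produce no tracks and a zeroed report", {
  empty <- lapply(1:10, function(t)
    data.frame(x = numeric(0), y = numeric(0), area = integer(0),
               total_intensity = numeric(0)))
  tracks <- link_tracks(empty, dt_params(), ref_cal())
  expect_length(tracks, 0)
  rep <- track_statistics(tracks, list(static_intensity = 0, moving_intensity = 0,
                                       static_count = 0, moving_count = 0),
                          empty, 10)
  expect_equal(rep$total_track_count, 0)
  expect_true(is.na(rep$average_speed_per_track))
})

test_that("track statistics summarize durations and speeds", {
  feats <- lapply(1:6, function(t)
    data.frame(x = 2 * t, y = 5, area = 4L, total_intensity = 80))
  tracks <- link_tracks(feats, dt_params(), ref_cal())
  expect_length(tracks, 1)
  rep <- track_statistics(tracks, list(static_intensity = 100, moving_intensity = 50,
                                       static_count = 10, moving_count = 2),
                          feats, 6)
  expect_equal(rep$average_track_duration, 6)
  expect_equal(rep$average_particle_count_per_frame, 1)
  expect_equal(rep$average_volume_per_particle, 4)
  expect_equal(rep$intensity_percentage_moving, 100 * 50 / 150)
  expect_equal(rep$count_percentage_moving, 100 * 2 / 12)
  # speed: 2 px/frame at the reference calibration
  expect_equal(rep$average_speed_per_track, 2 * 0.432 / 1.75, tolerance = 1e-9)
})

test_that("treated/control ratio reports divide field by field", {
  a <- list(x = 10, y = 4)
  expect_equal(treatment_ratio_report(a, a)$ratio, c(1, 1))
  expect_warning(r0 <- treatment_ratio_report(list(x = 0), list(x = 5)), "denominator")
  expect_true(is.na(r0$ratio))
})
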