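#' Difference-tracker parameters
#'
#' Parameters of the two-stage tracker: the temporal difference filter
#' (\code{min_difference}, \code{frame_offset}) isolating moving pixels, and
#' the mass particle tracker (feature thresholds, search flexibilities and
#' the minimum surviving track length). Defaults are the published
#' operating point for 8-bit movies: minimum difference 20, frame offset 4,
#' minimum tracked intensity 20, minimum feature size 2 px, initial
#' flexibility 10 px, subsequent flexibility 5 px, minimum track length 4.
#'
#' @param min_difference Intensity change threshold.
#' @param frame_offset Temporal offset (frames) for the difference.
#' @param min_tracked_intensity Minimum total feature intensity.
#' @param min_feature_size Minimum feature area (px).
#' @param initial_flexibility Search radius (px) for a 1-frame-old track.
#' @param subsequent_flexibility Search radius (px) around the
#'   constant-velocity prediction of an established track.
#' @param min_track_length Minimum number of frames for a surviving track.
#' @return A \code{DTParams}.
#' @export
dt_params <- function(min_difference = 20, frame_offset = 4L,
                      min_tracked_intensity = 20, min_feature_size = 2L,
                      initial_flexibility = 10, subsequent_flexibility = 5,
                      min_track_length = 4L) {
  stopifnot(min_difference >= 0, frame_offset >= 1, min_tracked_intensity >= 0,
            min_feature_size >= 0, initial_flexibility >= 0,
            subsequent_flexibility >= 0, min_track_length >= 1)
  structure(list(min_difference = min_difference, frame_offset = as.integer(frame_offset),
                 min_tracked_intensity = min_tracked_intensity,
                 min_feature_size = as.integer(min_feature_size),
                 initial_flexibility = initial_flexibility,
                 subsequent_flexibility = subsequent_flexibility,
                 min_track_length = as.integer(min_track_length)),
            class = "DTParams")
}

#' Temporal difference filter
#'
#' Classifies pixel (t, y, x) as moving iff the absolute intensity
#' difference to the frame \code{frame_offset} earlier or later (the
#' maximum over the offsets that exist; one-sided at the sequence ends) is
#' at least \code{min_difference}. The returned movie keeps the original
#' intensity at moving pixels and is 0 elsewhere. Per-movie statistics
#' accumulate static/moving intensity sums and static/moving object counts
#' (8-connected components with total intensity at or above
#' \code{min_tracked_intensity}) over all frames. The implied speed floor
#' is one pixel per \code{frame_offset} frames.
#'
#' @param m An 8-bit \code{\link{movie}} (run
#'   \code{\link{enhance_contrast_8bit}} first).
#' @param params A \code{\link{dt_params}}.
#' @return List with \code{movie} (moving-only) and \code{stats} (list:
#'   \code{static_intensity}, \code{moving_intensity}, \code{static_count},
#'   \code{moving_count}).
#' @export
difference_filter <- function(m, params = dt_params()) {
  stopifnot(inherits(m, "Movie"))
  if (m$bit_depth != 8L)
    stop("difference_filter requires an 8-bit movie; run enhance_contrast_8bit first")
  Tn <- n_frames(m); off <- params$frame_offset
  if (Tn <= off) stop("movie shorter than the difference frame offset")
  out <- array(0, dim(m$data))
  static_intensity <- 0; moving_intensity <- 0
  static_count <- 0L; moving_count <- 0L
  for (t in seq_len(Tn)) {
    fr <- m$data[, , t]
    diffmax <- matrix(0, nrow(fr), ncol(fr))
    if (t - off >= 1L) diffmax <- pmax(diffmax, abs(fr - m$data[, , t - off]))
    if (t + off <= Tn) diffmax <- pmax(diffmax, abs(fr - m$data[, , t + off]))
    moving <- diffmax >= params$min_difference
    out[, , t][moving] <- fr[moving]
    moving_intensity <- moving_intensity + sum(fr[moving])
    static_intensity <- static_intensity + sum(fr[!moving])
    # Object counts: 8-connected components of pixels at or above the
    # intensity floor within each partition, with the minimum feature area.
    bright <- fr >= params$min_tracked_intensity
    for (part in list(list(mask = moving & bright, which = "moving"),
                      list(mask = !moving & bright, which = "static"))) {
      lab <- label_components8(part$mask)
      if (max(lab) > 0L) {
        nc <- sum(tabulate(lab[lab > 0L], max(lab)) >= params$min_feature_size)
        if (part$which == "moving") moving_count <- moving_count + nc
        else static_count <- static_count + nc
      }
    }
  }
  mm <- movie(out, m$calibration, m$history, 8L)
  mm <- record_op(mm, "difference_filter", min_difference = params$min_difference,
                  frame_offset = off)
  list(movie = mm,
       stats = list(static_intensity = static_intensity,
                    moving_intensity = moving_intensity,
                    static_count = static_count, moving_count = moving_count))
}

#' Detect bright features in a moving-only frame
#'
#' 8-connected components of nonzero pixels with area at least
#' \code{min_feature_size} and total intensity at least
#' \code{min_tracked_intensity}; centroids are intensity-weighted.
#'
#' @param frame 2-D matrix (a frame of the difference-filtered movie).
#' @param params A \code{\link{dt_params}}.
#' @return Data frame with columns \code{x}, \code{y}, \code{area},
#'   \code{total_intensity} (possibly 0 rows).
#' @export
detect_features <- function(frame, params = dt_params()) {
  lab <- label_components8(frame > 0)
  n <- max(lab)
  if (n == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      area = integer(0), total_intensity = numeric(0)))
  idx <- which(lab > 0)
  l <- lab[idx]; v <- frame[idx]
  rr <- (idx - 1L) %% nrow(frame) + 1L
  cc <- (idx - 1L) %/% nrow(frame) + 1L
  area <- tabulate(l, n)
  tot <- as.vector(tapply(v, l, sum))
  cx <- as.vector(tapply(v * cc, l, sum)) / tot
  cy <- as.vector(tapply(v * rr, l, sum)) / tot
  keep <- area >= params$min_feature_size & tot >= params$min_tracked_intensity
  data.frame(x = cx[keep], y = cy[keep], area = area[keep],
             total_intensity = tot[keep])
}

#' Link per-frame features into tracks
#'
#' Greedy priority linking: at each frame, existing tracks claim features
#' in descending track-length order (ties broken by lower track id). An
#' established track (2+ features) searches within
#' \code{subsequent_flexibility} px of its constant-velocity prediction
#' (velocity = the last observed step); a 1-frame-old track searches within
#' \code{initial_flexibility} px of its seed. Each feature joins at most
#' one track; unclaimed features seed new tracks; a track that claims
#' nothing terminates. Tracks shorter than \code{min_track_length} are
#' discarded.
#'
#' @param features_by_frame List (one element per frame) of feature data
#'   frames from \code{\link{detect_features}}.
#' @param params A \code{\link{dt_params}}.
#' @param cal A \code{\link{calibration}} for speed conversion.
#' @return List of \code{Track}s: each a list with \code{frames},
#'   \code{x}, \code{y}, \code{area}, \code{total_intensity},
#'   \code{duration}, \code{step_px}, \code{mean_speed_umps},
#'   \code{max_speed_umps}, \code{direction} (sign of net x displacement).
#' @export
link_tracks <- function(features_by_frame, params = dt_params(), cal) {
  active <- list()    # each: list(id, frames, x, y, area, tot, vx, vy, len)
  done <- list()
  next_id <- 1L
  for (t in seq_along(features_by_frame)) {
    feats <- features_by_frame[[t]]
    claimed <- rep(FALSE, nrow(feats))
    if (length(active)) {
      ord <- order(-vapply(active, `[[`, integer(1), "len"),
                   vapply(active, `[[`, integer(1), "id"))
      keep_active <- logical(length(active))
      for (ai in ord) {
        tr <- active[[ai]]
        if (tr$len >= 2L) {
          px <- tr$x[tr$len] + tr$vx; py <- tr$y[tr$len] + tr$vy
          radius <- params$subsequent_flexibility
        } else {
          px <- tr$x[tr$len]; py <- tr$y[tr$len]
          radius <- params$initial_flexibility
        }
        cand <- which(!claimed)
        if (length(cand)) {
          d <- sqrt((feats$x[cand] - px)^2 + (feats$y[cand] - py)^2)
          j <- cand[which.min(d)]
          if (min(d) <= radius) {
            claimed[j] <- TRUE
            tr$vx <- feats$x[j] - tr$x[tr$len]
            tr$vy <- feats$y[j] - tr$y[tr$len]
            tr$frames <- c(tr$frames, t)
            tr$x <- c(tr$x, feats$x[j]); tr$y <- c(tr$y, feats$y[j])
            tr$area <- c(tr$area, feats$area[j])
            tr$tot <- c(tr$tot, feats$total_intensity[j])
            tr$len <- tr$len + 1L
            active[[ai]] <- tr
            keep_active[ai] <- TRUE
          }
        }
      }
      done <- c(done, active[!keep_active])
      active <- active[keep_active]
    }
    for (j in which(!claimed)) {
      active[[length(active) + 1L]] <- list(
        id = next_id, frames = t, x = feats$x[j], y = feats$y[j],
        area = feats$area[j], tot = feats$total_intensity[j],
        vx = 0, vy = 0, len = 1L)
      next_id <- next_id + 1L
    }
  }
  done <- c(done, active)
  done <- Filter(function(tr) tr$len >= params$min_track_length, done)
  pxum <- effective_pixel_um(cal); dt <- effective_interval_s(cal)
  lapply(done, function(tr) {
    step <- if (tr$len >= 2L) sqrt(diff(tr$x)^2 + diff(tr$y)^2) else numeric(0)
    sp <- step * pxum / dt
    structure(list(id = tr$id, frames = tr$frames, x = tr$x, y = tr$y,
                   area = tr$area, total_intensity = tr$tot,
                   duration = tr$len, step_px = step,
                   mean_speed_umps = if (length(sp)) mean(sp) else NA_real_,
                   max_speed_umps = if (length(sp)) max(sp) else NA_real_,
                   direction = sign(tr$x[tr$len] - tr$x[1])),
              class = "Track")
  })
}

#' Motion report (combined difference-filter and tracker summary)
#'
#' Combines the difference-filter statistics and the linked tracks into the
#' standard per-movie summary: static/moving intensity and component
#' counts with percentage-moving figures, track counts, mean particle
#' count per frame, mean track duration (frames), mean particle area
#' ("volume", px), and mean and max track speeds (um/s).
#'
#' @param tracks Output of \code{\link{link_tracks}}.
#' @param filter_stats \code{stats} element from
#'   \code{\link{difference_filter}}.
#' @param features_by_frame Per-frame feature data frames (for the particle
#'   counts and areas).
#' @param n_frames_total Number of frames in the tracked movie.
#' @return A \code{MotionReport} (named list).
#' @export
track_statistics <- function(tracks, filter_stats, features_by_frame, n_frames_total) {
  fs <- filter_stats
  n_feat <- sum(vapply(features_by_frame, nrow, integer(1)))
  areas <- unlist(lapply(features_by_frame, `[[`, "area"))
  rep <- list(
    static_intensity = fs$static_intensity,
    moving_intensity = fs$moving_intensity,
    intensity_percentage_moving =
      100 * fs$moving_intensity / max(fs$static_intensity + fs$moving_intensity, 1e-12),
    static_count = fs$static_count,
    moving_count = fs$moving_count,
    count_percentage_moving =
      100 * fs$moving_count / max(fs$static_count + fs$moving_count, 1e-12),
    total_track_count = length(tracks),
    average_particle_count_per_frame = n_feat / n_frames_total,
    average_track_duration =
      if (length(tracks)) mean(vapply(tracks, `[[`, numeric(1), "duration")) else NA_real_,
    average_volume_per_particle = if (length(areas)) mean(areas) else NA_real_,
    average_speed_per_track =
      if (length(tracks)) mean(vapply(tracks, `[[`, numeric(1), "mean_speed_umps")) else NA_real_,
    average_max_speed_per_track =
      if (length(tracks)) mean(vapply(tracks, `[[`, numeric(1), "max_speed_umps")) else NA_real_)
  structure(rep, class = "MotionReport")
}

#' Run the full difference-tracker chain on an 8-bit movie
#'
#' Convenience wrapper: difference filter, per-frame feature detection,
#' track linking, and the motion report.
#'
#' @param m An 8-bit \code{\link{movie}}.
#' @param params A \code{\link{dt_params}}.
#' @return List with \code{report}, \code{tracks}, \code{features},
#'   \code{moving_movie}, \code{filter_stats}.
#' @export
difference_tracker <- function(m, params = dt_params()) {
  df <- difference_filter(m, params)
  feats <- lapply(seq_len(n_frames(df$movie)), function(t)
    detect_features(df$movie$data[, , t], params))
  tracks <- link_tracks(feats, params, m$calibration)
  report <- track_statistics(tracks, df$stats, feats, n_frames(m))
  list(report = report, tracks = tracks, features = feats,
       moving_movie = df$movie, filter_stats = df$stats)
}

#' Treated/control ratio report
#'
#' Elementwise treated / control for every numeric field of two
#' \code{MotionReport}s, rendered to 2 decimals in the printed table.
#' Zero control denominators give \code{NA} with a warning.
#'
#' @param control,treated \code{MotionReport}s (or named numeric lists with
#'   the same fields).
#' @return Data frame with columns \code{field}, \code{control},
#'   \code{treated}, \code{ratio}.
#' @export
treatment_ratio_report <- function(control, treated) {
  fields <- intersect(names(control), names(treated))
  ctl <- vapply(fields, function(f) as.numeric(control[[f]]), numeric(1))
  trt <- vapply(fields, function(f) as.numeric(treated[[f]]), numeric(1))
  ratio <- rep(NA_real_, length(fields))
  ok <- !is.na(ctl) & ctl != 0 & !is.na(trt)
  ratio[ok] <- trt[ok] / ctl[ok]
  if (any(!ok & !is.na(trt)))
    warning("zero or missing control denominators: ratios set to NA")
  data.frame(field = fields, control = ctl, treated = trt,
             ratio = round(ratio, 2), row.names = NULL)
}

#' Write tracks as CSV
#' @param tracks Output of \code{\link{link_tracks}}.
#' @param path Output path.
#' @export
write_tracks_csv <- function(tracks, path) {
  rows <- lapply(tracks, function(tr)
    data.frame(track_id = tr$id, frame = tr$frames, x = tr$x, y = tr$y,
               area = tr$area, intensity = tr$total_intensity))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(0), frame = integer(0), x = numeric(0),
               y = numeric(0), area = integer(0), intensity = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
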