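#' Screen processing configuration
#'
#' Default end-to-end parameters: spatial bin 4, rigid registration to
#' frame 1, temporal stretch 2, centered crops removing the same border
#' fraction as 512 -> 450 (flow branch) and 512 -> 400 (tracker branch),
#' LK parameters (2, 2, 0.3, 0.02), the 140-bin log histogram over -10..4,
#' a 0.25 um/s flow threshold, and the published difference-tracker
#' defaults. All values are overridable and echoed into outputs.
#'
#' @param bin_factor Spatial binning factor.
#' @param stretch_factor Temporal stretch factor.
#' @param crop_fraction_lk,crop_fraction_dt Fraction of the (binned) frame
#'   kept by the centered crop in each branch.
#' @param lk An \code{\link{lk_params}}.
#' @param hist A \code{\link{histogram_spec}}.
#' @param v_threshold Flow-ratio speed threshold (um/s).
#' @param dt A \code{\link{dt_params}}.
#' @param mask_k,mask_max_reject Artifact-mask rule parameters.
#' @param register Run rigid registration (TRUE by default).
#' @return A \code{ScreenConfig} list.
#' @export
screen_config <- function(bin_factor = 4L, stretch_factor = 2L,
                          crop_fraction_lk = 450 / 512, crop_fraction_dt = 400 / 512,
                          lk = lk_params(), hist = histogram_spec(),
                          v_threshold = 0.25, dt = dt_params(),
                          mask_k = 3, mask_max_reject = 0.4, register = TRUE) {
  structure(list(bin_factor = as.integer(bin_factor),
                 stretch_factor = as.integer(stretch_factor),
                 crop_fraction_lk = crop_fraction_lk,
                 crop_fraction_dt = crop_fraction_dt,
                 lk = lk, hist = hist, v_threshold = v_threshold, dt = dt,
                 mask_k = mask_k, mask_max_reject = mask_max_reject,
                 register = isTRUE(register)),
            class = "ScreenConfig")
}

#' Preprocess a raw movie for analysis
#'
#' The standard conditioning chain: spatial binning, rigid-body
#' registration, quintic B-spline temporal stretching.
#'
#' @param m A raw \code{\link{movie}}.
#' @param config A \code{\link{screen_config}}.
#' @return The preprocessed \code{Movie}.
#' @export
preprocess_movie <- function(m, config = screen_config()) {
  m <- bin_spatial(m, config$bin_factor)
  if (config$register) m <- register_rigid(m)$movie
  stretch_time(m, config$stretch_factor)
}

#' Flow-branch analysis of one preprocessed movie
#'
#' Centered crop, dense LK flow, absolute-velocity maps, log-speed
#' montage, per-time normalization, running-SD artifact mask, and the
#' above-threshold flow-ratio series.
#'
#' @param m A preprocessed \code{\link{movie}}.
#' @param config A \code{\link{screen_config}}.
#' @param sample_id Label for the montage.
#' @return List: \code{montage} (normalized, masked), \code{raw_montage},
#'   \code{scores}, \code{mask}, \code{ratios}, \code{maps},
#'   \code{percent_moving} (mean percentage of above-gate measurements
#'   faster than the threshold).
#' @export
analyze_flow <- function(m, config = screen_config(), sample_id = NA_character_) {
  d <- dim(m$data)
  crop <- round(d[1:2] * config$crop_fraction_lk)
  mc <- crop_center(m, crop)
  fields <- flow_movie(mc, config$lk)
  maps <- lapply(fields, absolute_velocity)
  raw <- build_montage(maps, config$hist, mc$calibration, sample_id)
  norm <- normalize_montage(raw)
  scores <- running_sd_scores(norm)
  mask <- build_frame_mask(scores, k = config$mask_k,
                           max_reject_fraction = config$mask_max_reject)
  norm <- apply_frame_mask(norm, mask)
  ratios <- flow_ratio_series(norm, v_threshold = config$v_threshold)
  list(montage = norm, raw_montage = raw, scores = scores, mask = mask,
       ratios = ratios, maps = maps,
       percent_moving = 100 * mean(ratios, na.rm = TRUE))
}

#' Tracker-branch analysis of one preprocessed movie
#'
#' Centered crop, stack-wide contrast normalization to 8-bit, and the full
#' difference-filter + mass-particle-tracker chain. The 8-bit conversion
#' uses the percentile stretch without histogram equalization: on
#' spot-on-plain-background scenes equalization spreads the dominant
#' background mode across the output range and pushes pure noise over the
#' difference threshold.
#'
#' @param m A preprocessed \code{\link{movie}}.
#' @param config A \code{\link{screen_config}}.
#' @return \code{\link{difference_tracker}} output.
#' @export
analyze_tracks <- function(m, config = screen_config()) {
  d <- dim(m$data)
  crop <- round(d[1:2] * config$crop_fraction_dt)
  mc <- crop_center(m, crop)
  m8 <- enhance_contrast_8bit(mc, saturated_fraction = 0.05, equalize = FALSE)
  difference_tracker(m8, config$dt)
}

#' Run a full screen over a plate manifest
#'
#' For every manifest row, reads the movie, runs the flow branch and the
#' tracker branch, and writes per-movie intermediates (montage, mask,
#' ratio series, track CSV, motion report). Screen-level outputs are the
#' flow table, the per-sample summary, pooled-control Dunnett results per
#' cell type, and a JSON provenance log (input hashes and the full
#' configuration). Per-movie failures are isolated and logged; the screen
#' completes for the remaining movies.
#'
#' @param manifest Data frame with columns \code{file}, \code{sample},
#'   \code{group} (\code{control}/\code{treated}) and optionally
#'   \code{cell_type}, \code{well}, \code{phase}. Each (sample, phase) must
#'   be unique.
#' @param config A \code{\link{screen_config}}.
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with \code{flow_table}, \code{summary},
#'   \code{dunnett} (per cell type), \code{reports}, \code{failures}.
#' @export
run_screen <- function(manifest, config = screen_config(), out_dir) {
  stopifnot(all(c("file", "sample", "group") %in% names(manifest)))
  if (anyDuplicated(manifest[c("sample", if ("phase" %in% names(manifest)) "phase")]))
    stop("manifest has duplicate (sample, phase) rows")
  if (!"cell_type" %in% names(manifest)) manifest$cell_type <- "all"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  montages <- list(); reports <- list(); failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      m <- read_movie_tiff(row$file)
      pre <- preprocess_movie(m, config)
      fl <- analyze_flow(pre, config, sample_id = row$sample)
      tr <- analyze_tracks(pre, config)
      write_montage_csv(fl$montage, file.path(out_dir, paste0(row$sample, "_montage.csv")))
      utils::write.csv(data.frame(time = seq_along(fl$scores), score = fl$scores,
                                  retained = as.logical(fl$mask)),
                       file.path(out_dir, paste0(row$sample, "_mask.csv")),
                       row.names = FALSE)
      write_tracks_csv(tr$tracks, file.path(out_dir, paste0(row$sample, "_tracks.csv")))
      jsonlite::write_json(unclass(tr$report), file.path(out_dir, paste0(row$sample, "_report.json")),
                           auto_unbox = TRUE, digits = NA)
      list(montage = fl$montage, report = tr$report)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", row$sample, conditionMessage(res)))
      next
    }
    montages[[row$sample]] <- res$montage
    reports[[row$sample]] <- res$report
  }
  if (length(failures))
    writeLines(failures, file.path(out_dir, "failures.log"))
  if (length(montages) == 0L) stop("no movie processed successfully")
  ft <- build_flow_table(montages, config$v_threshold)
  write_montage_csv(ft, file.path(out_dir, "flow_table.csv"))
  ok <- manifest$sample %in% names(montages)
  summ <- summarize_screen(ft, manifest[ok, ])
  utils::write.csv(summ$per_sample, file.path(out_dir, "per_sample_summary.csv"),
                   row.names = FALSE)
  dunnett <- list()
  for (ct in unique(manifest$cell_type[ok])) {
    sub <- manifest[ok & manifest$cell_type == ct, ]
    mk <- function(g) lapply(sub$sample[sub$group == g], function(s)
      sample_series(s, ft[, s], group = if (g == "control") "control" else "treated",
                    cell_type = ct))
    ctl <- mk("control"); trt <- mk("treated")
    if (length(ctl) >= 2 && length(trt) >= 1) {
      dres <- tryCatch(pooled_dunnett(ctl, trt), error = function(e) e)
      if (!inherits(dres, "error")) {
        dunnett[[ct]] <- dres
        utils::write.csv(dres, file.path(out_dir, paste0("dunnett_", ct, ".csv")),
                         row.names = FALSE)
      } else failures <- c(failures, sprintf("dunnett[%s]: %s", ct, conditionMessage(dres)))
    }
  }
  prov <- list(
    inputs = data.frame(file = manifest$file,
                        md5 = unname(tools::md5sum(manifest$file))),
    config = rapply(unclass(config), unclass, how = "list"),
    n_processed = length(montages), failures = failures)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(flow_table = ft, summary = summ, dunnett = dunnett,
                 reports = reports, failures = failures))
}
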