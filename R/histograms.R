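#' Log-speed histogram specification
#'
#' Speeds in px/frame are natural-log transformed and binned into
#' \code{n_bins} uniform bins on \code{[log_min, log_max)}. The defaults
#' (140 bins over -10..4, bin width 0.1) cover speeds from
#' \code{exp(-10)} to \code{exp(4)} px/frame, i.e. 0.000045-54.6 p/f.
#'
#' @param n_bins Number of bins.
#' @param log_min,log_max Natural-log speed bounds (px/frame).
#' @return A \code{HistogramSpec}.
#' @export
histogram_spec <- function(n_bins = 140L, log_min = -10, log_max = 4) {
  stopifnot(n_bins >= 1, log_min < log_max)
  structure(list(n_bins = as.integer(n_bins), log_min = log_min, log_max = log_max,
                 edges = seq(log_min, log_max, length.out = n_bins + 1L)),
            class = "HistogramSpec")
}

#' Log-speed histogram of one absolute-velocity map
#'
#' Zero (gated) speeds are treated as missing and never binned; the
#' remaining speeds are natural-log transformed, values outside the range
#' are dropped, and counts per bin are returned (last bin right-closed).
#'
#' @param map An \code{AbsVelocityMap}.
#' @param spec A \code{\link{histogram_spec}}.
#' @return Integer vector of length \code{n_bins}.
#' @export
log_speed_histogram <- function(map, spec = histogram_spec()) {
  s <- map$speed[map$valid & map$speed > 0]
  if (length(s) == 0L) return(numeric(spec$n_bins))
  ls <- log(s)
  w <- (ls - spec$log_min) / (spec$log_max - spec$log_min) * spec$n_bins
  idx <- floor(w) + 1L
  idx[ls == spec$log_max] <- spec$n_bins   # right-close the last bin
  keep <- idx >= 1L & idx <= spec$n_bins
  tabulate(idx[keep], spec$n_bins)
}

#' Build a velocity-histogram montage
#'
#' Stacks the per-frame log-speed histograms of a movie's absolute-velocity
#' maps into a T x n_bins count matrix (rows = time points ordered by frame
#' index): the velocity histogram montage.
#'
#' @param maps List of \code{AbsVelocityMap}s.
#' @param spec A \code{\link{histogram_spec}}.
#' @param cal The movie's \code{\link{calibration}}.
#' @param sample_id Optional label.
#' @return A \code{VelocityMontage}: list with \code{counts},
#'   \code{bin_edges}, \code{calibration}, \code{normalized}, \code{mask}
#'   (per-row retention, initially all TRUE), \code{frame_index},
#'   \code{sample_id}.
#' @export
build_montage <- function(maps, spec = histogram_spec(), cal, sample_id = NA_character_) {
  stopifnot(length(maps) >= 1)
  dims <- vapply(maps, function(m) dim(m$speed), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent map shapes")
  ord <- order(vapply(maps, `[[`, integer(1), "frame_index"))
  maps <- maps[ord]
  counts <- t(vapply(maps, function(m) log_speed_histogram(m, spec),
                     numeric(spec$n_bins)))
  structure(list(counts = counts, bin_edges = spec$edges, calibration = cal,
                 normalized = FALSE, mask = rep(TRUE, nrow(counts)),
                 frame_index = vapply(maps, `[[`, integer(1), "frame_index"),
                 sample_id = sample_id),
            class = "VelocityMontage")
}

#' Normalize a montage by its per-time-point mean
#'
#' Divides each row (time point) by its own mean bin count, so the area
#' under every histogram is identical and the total number of mitochondria
#' is factored out. Rows with zero mean are flagged missing in the mask.
#'
#' @param m A \code{VelocityMontage} (not already normalized).
#' @return Normalized \code{VelocityMontage}.
#' @export
normalize_montage <- function(m) {
  stopifnot(inherits(m, "VelocityMontage"))
  if (m$normalized) stop("montage is already normalized")
  mu <- rowMeans(m$counts)
  zero <- mu == 0
  mu[zero] <- 1
  m$counts <- m$counts / mu
  m$mask <- m$mask & !zero
  m$normalized <- TRUE
  m
}

#' Running-standard-deviation artifact scores
#'
#' The per-time-point artifact score: the population standard deviation of
#' each bin over the three adjacent rows (t-1, t, t+1), summed over bins.
#' The first and last rows use the available 2-row window. Transient
#' imaging artifacts (flicker, residual stage drift) perturb the whole
#' velocity distribution for a frame or two and produce large scores.
#'
#' @param m A normalized \code{VelocityMontage}.
#' @return Numeric score per time point.
#' @export
running_sd_scores <- function(m) {
  stopifnot(inherits(m, "VelocityMontage"), m$normalized)
  Tn <- nrow(m$counts)
  if (Tn < 3) {
    warning("fewer than 3 time points: running-SD scores set to 0")
    return(numeric(Tn))
  }
  pop_sd_rows <- function(rows) {
    x <- m$counts[rows, , drop = FALSE]
    mu <- colMeans(x)
    sum(sqrt(colMeans(sweep(x, 2, mu)^2)))
  }
  vapply(seq_len(Tn), function(t) {
    rows <- intersect((t - 1L):(t + 1L), seq_len(Tn))
    pop_sd_rows(rows)
  }, numeric(1))
}

#' Build a frame-retention mask from artifact scores
#'
#' Rejects time points whose running-SD score exceeds
#' \code{median + k * MAD} (MAD scaled to be SD-consistent). If more than
#' \code{max_reject_fraction} of rows would be rejected the sample is
#' flagged failed (attribute \code{failed}) rather than silently masked.
#'
#' @param scores Output of \code{\link{running_sd_scores}}.
#' @param k Threshold multiplier (default 3).
#' @param max_reject_fraction Cap on the rejected fraction (default 0.4).
#' @return Logical retention mask (TRUE = keep) with attributes
#'   \code{threshold} and \code{failed}.
#' @export
build_frame_mask <- function(scores, k = 3, max_reject_fraction = 0.4) {
  stopifnot(all(is.finite(scores)))
  thr <- stats::median(scores) + k * stats::mad(scores)   # mad() is SD-consistent
  keep <- scores <= thr
  failed <- mean(!keep) > max_reject_fraction
  if (failed) {
    warning(sprintf("mask rejects %.0f%% of time points (> %.0f%% cap): sample flagged failed",
                    100 * mean(!keep), 100 * max_reject_fraction))
    keep <- rep(TRUE, length(scores))
  }
  structure(keep, threshold = thr, failed = failed)
}

#' Apply a retention mask to a montage
#' @param m A \code{VelocityMontage}.
#' @param mask Logical vector from \code{\link{build_frame_mask}}.
#' @return The montage with its mask intersected.
#' @export
apply_frame_mask <- function(m, mask) {
  stopifnot(inherits(m, "VelocityMontage"), length(mask) == nrow(m$counts))
  m$mask <- m$mask & as.logical(mask)
  m
}

# Index of the first bin at/above a um/s threshold: the threshold is mapped
# to the nearest bin edge not below it, so 0.25 um/s lands on a reproducible
# edge across calibrations.
threshold_bin <- function(m, v_threshold_umps) {
  v_pf <- umps_to_pf(v_threshold_umps, m$calibration)
  lv <- log(v_pf)
  edges <- m$bin_edges
  if (lv > edges[length(edges) - 1L]) return(NA_integer_)
  which(edges >= lv - 1e-12)[1]
}

#' Above-threshold flow-ratio series
#'
#' For each retained time point, the fraction of above-gate flow
#' measurements with speed at or above \code{v_threshold} (um/s, mapped to
#' the nearest histogram bin edge not below it): \code{sum(counts in bins
#' >= threshold) / sum(all counts)}. Masked rows are \code{NA}. The ratio
#' is invariant to row normalization.
#'
#' @param m A \code{VelocityMontage}.
#' @param mask Optional logical retention mask (defaults to the montage's).
#' @param v_threshold Speed threshold in um/s (default 0.25).
#' @return Numeric vector (one entry per time point, \code{NA} where
#'   masked).
#' @export
flow_ratio_series <- function(m, mask = NULL, v_threshold = 0.25) {
  stopifnot(inherits(m, "VelocityMontage"))
  if (is.null(mask)) mask <- m$mask
  stopifnot(length(mask) == nrow(m$counts))
  b0 <- threshold_bin(m, v_threshold)
  if (is.na(b0)) {
    warning("threshold above histogram range: all ratios 0")
    out <- numeric(nrow(m$counts)); out[!mask] <- NA_real_
    return(out)
  }
  tot <- rowSums(m$counts)
  hi <- rowSums(m$counts[, b0:ncol(m$counts), drop = FALSE])
  out <- ifelse(tot > 0, hi / tot, 0)
  out[!mask] <- NA_real_
  out
}

#' Build a flow table across samples
#'
#' Columns are samples, rows are time points; entries are above-threshold
#' flow ratios with \code{NA} where the artifact mask rejected the time
#' point. Samples of unequal length are padded with \code{NA} (with a
#' warning).
#'
#' @param samples Named list of \code{VelocityMontage}s (masks already
#'   applied).
#' @param v_threshold Speed threshold in um/s.
#' @return A \code{FlowTable}: matrix with a \code{summary} attribute (per
#'   sample: mean, SD and n over retained rows).
#' @export
build_flow_table <- function(samples, v_threshold = 0.25) {
  stopifnot(length(samples) >= 1)
  series <- lapply(samples, flow_ratio_series, v_threshold = v_threshold)
  lens <- lengths(series)
  if (length(unique(lens)) > 1) {
    warning("samples have unequal time lengths: padding with NA")
    series <- lapply(series, function(s) c(s, rep(NA_real_, max(lens) - length(s))))
  }
  tab <- do.call(cbind, series)
  colnames(tab) <- if (!is.null(names(samples))) names(samples) else
    paste0("sample", seq_along(samples))
  summ <- data.frame(
    sample = colnames(tab),
    mean = apply(tab, 2, mean, na.rm = TRUE),
    sd = apply(tab, 2, stats::sd, na.rm = TRUE),
    n = apply(tab, 2, function(x) sum(!is.na(x))),
    row.names = NULL)
  structure(tab, summary = summ, v_threshold = v_threshold, class = c("FlowTable", "matrix"))
}

#' Write a montage or flow table as CSV
#' @param x A \code{VelocityMontage} or \code{FlowTable}.
#' @param path Output path.
#' @export
write_montage_csv <- function(x, path) {
  if (inherits(x, "VelocityMontage")) {
    df <- as.data.frame(x$counts)
    names(df) <- sprintf("logv_%.2f", (x$bin_edges[-length(x$bin_edges)] +
                                         x$bin_edges[-1]) / 2)
    df <- cbind(frame = x$frame_index, retained = x$mask, df)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    utils::write.csv(as.data.frame(unclass(x)), path, row.names = FALSE, na = "NaN")
  }
  invisible(path)
}
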