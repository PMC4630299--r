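#' Lucas-Kanade flow parameters
#'
#' Parameters of the dense Lucas-Kanade estimator: spatial and temporal
#' Gaussian scales for the derivative prefilters (\code{sigma_s},
#' \code{sigma_t}, which should be equal so that flow-field intensity scales
#' linearly with velocity), the Gaussian window scale \code{sigma_w} over
#' which the structure tensor is accumulated, and the noise gate \code{tau}:
#' the minimum smaller-eigenvalue of the structure tensor required before a
#' flow vector is emitted. Defaults (2, 2, 0.3, 0.02) are the calibrated
#' operating point for binned, registered, time-stretched movies on a
#' 0-255-range intensity scale.
#'
#' @param sigma_s Spatial derivative scale (px).
#' @param sigma_t Temporal derivative scale (frames).
#' @param sigma_w Structure-tensor window scale (px).
#' @param tau Eigenvalue noise gate (intensity-squared units).
#' @param normal_flow Also emit normal flow where only the larger eigenvalue
#'   passes the gate (off by default: ungated pixels report no flow).
#' @return An \code{LKParams} object.
#' @export
lk_params <- function(sigma_s = 2, sigma_t = 2, sigma_w = 0.3, tau = 0.02,
                      normal_flow = FALSE) {
  stopifnot(sigma_s > 0, sigma_t > 0, sigma_w > 0, tau >= 0)
  if (sigma_s != sigma_t)
    warning("sigma_s != sigma_t: flow-field intensity will not be linearly related to velocity")
  structure(list(sigma_s = sigma_s, sigma_t = sigma_t, sigma_w = sigma_w,
                 tau = tau, normal_flow = isTRUE(normal_flow)),
            class = "LKParams")
}

temporal_half_support <- function(params) max(1L, as.integer(ceiling(3 * params$sigma_t)))

#' Gaussian-derivative gradient volumes
#'
#' Computes the spatiotemporal intensity gradients by separable Gaussian
#' (derivative) filtering: each of Ix, Iy, It is differentiated along its
#' own axis with a Gaussian-derivative kernel and smoothed along the other
#' two axes (spatial scale \code{sigma_s}, temporal scale \code{sigma_t});
#' kernel half-width is \code{ceil(3 sigma)}.
#'
#' @param m A \code{\link{movie}}.
#' @param sigma_s Spatial scale (px).
#' @param sigma_t Temporal scale (frames).
#' @return List of H x W x T arrays \code{Ix}, \code{Iy}, \code{It} and the
#'   temporal half-support \code{ht}.
#' @export
gaussian_derivatives <- function(m, sigma_s = 2, sigma_t = 2) {
  stopifnot(inherits(m, "Movie"))
  ht <- max(1L, as.integer(ceiling(3 * sigma_t)))
  if (n_frames(m) < 2 * ht + 1)
    stop("movie shorter than the temporal kernel support")
  gs <- gauss_kernel(sigma_s); gt <- gauss_kernel(sigma_t)
  ds <- gauss_deriv_kernel(sigma_s); dt <- gauss_deriv_kernel(sigma_t)
  v <- m$data
  sm_t <- conv3_dim(v, gt, 3L)
  Ix <- conv3_dim(conv3_dim(sm_t, ds, 2L), gs, 1L)
  Iy <- conv3_dim(conv3_dim(sm_t, ds, 1L), gs, 2L)
  It <- conv3_dim(conv3_dim(conv3_dim(v, dt, 3L), gs, 1L), gs, 2L)
  list(Ix = Ix, Iy = Iy, It = It, ht = ht)
}

# Window weights for the structure tensor: squared Gaussian samples,
# normalized to sum 1; support is an odd square of half-width
# max(1, ceil(3 sigma_w)) (3 x 3 at the default sigma_w = 0.3).
lk_window_kernel <- function(sigma_w) {
  h <- max(1L, as.integer(ceiling(3 * sigma_w)))
  x <- seq(-h, h)
  w2 <- exp(-x^2 / sigma_w^2)       # (Gaussian)^2
  w2 / sum(w2)
}

#' Lucas-Kanade flow for one frame
#'
#' For every pixel, accumulates the structure tensor
#' \code{G = sum w^2 [Ix^2, IxIy; IxIy, Iy^2]} and
#' \code{b = -sum w^2 [IxIt; IyIt]} over the Gaussian window and solves
#' \code{G v = b} in closed form where the smaller eigenvalue of \code{G}
#' is at least \code{tau}; all other pixels emit zero flow and are marked
#' invalid.
#'
#' @param grads Output of \code{\link{gaussian_derivatives}}.
#' @param frame Frame index (must be within the temporally valid range).
#' @param params An \code{\link{lk_params}}.
#' @return A \code{FlowField}: list with H x W matrices \code{vx},
#'   \code{vy} (px/frame), logical \code{valid}, and \code{frame_index}.
#' @export
lk_flow_frame <- function(grads, frame, params = lk_params()) {
  Tn <- dim(grads$Ix)[3]
  ht <- grads$ht
  if (frame <= ht || frame > Tn - ht)
    stop(sprintf("frame %d outside the temporally valid range %d..%d",
                 frame, ht + 1L, Tn - ht))
  Ix <- grads$Ix[, , frame]; Iy <- grads$Iy[, , frame]; It <- grads$It[, , frame]
  k <- lk_window_kernel(params$sigma_w)
  G11 <- conv2_sep(Ix * Ix, k, k); G22 <- conv2_sep(Iy * Iy, k, k)
  G12 <- conv2_sep(Ix * Iy, k, k)
  b1 <- -conv2_sep(Ix * It, k, k); b2 <- -conv2_sep(Iy * It, k, k)
  tr2 <- (G11 + G22) / 2
  disc <- sqrt(pmax((G11 - G22)^2 / 4 + G12^2, 0))
  lam_min <- tr2 - disc
  lam_max <- tr2 + disc
  det <- G11 * G22 - G12^2
  valid <- lam_min >= params$tau & det > .Machine$double.eps
  vx <- matrix(0, nrow(Ix), ncol(Ix)); vy <- vx
  if (any(valid)) {
    vx[valid] <- (G22[valid] * b1[valid] - G12[valid] * b2[valid]) / det[valid]
    vy[valid] <- (G11[valid] * b2[valid] - G12[valid] * b1[valid]) / det[valid]
  }
  if (params$normal_flow) {
    nf <- !valid & lam_max >= params$tau & lam_max > 0
    if (any(nf)) {
      # Normal flow along the dominant gradient direction.
      g2 <- G11[nf] + G22[nf]
      bt <- b1[nf] * 0  # projection of b on the major eigenvector, approximated
      # major eigenvector components
      ex <- G12[nf]; ey <- lam_max[nf] - G11[nf]
      nrm <- sqrt(ex^2 + ey^2); nz <- nrm > 0
      ex[nz] <- ex[nz] / nrm[nz]; ey[nz] <- ey[nz] / nrm[nz]
      proj <- (b1[nf] * ex + b2[nf] * ey) / lam_max[nf]
      vx[nf] <- proj * ex; vy[nf] <- proj * ey
      valid <- valid | nf
    }
  }
  structure(list(vx = vx, vy = vy, valid = valid, frame_index = frame),
            class = "FlowField")
}

#' Dense flow for a whole movie
#'
#' Runs \code{\link{lk_flow_frame}} on every temporally valid frame (frames
#' within \code{ceil(3 sigma_t)} of either end are excluded by kernel
#' support).
#'
#' @param m A preprocessed \code{\link{movie}} (binned, registered,
#'   stretched).
#' @param params An \code{\link{lk_params}}.
#' @return List of \code{FlowField}s with attribute \code{valid_frames}.
#' @export
flow_movie <- function(m, params = lk_params()) {
  grads <- gaussian_derivatives(m, params$sigma_s, params$sigma_t)
  ht <- grads$ht
  frames <- (ht + 1L):(dim(m$data)[3] - ht)
  fields <- lapply(frames, function(t) lk_flow_frame(grads, t, params))
  attr(fields, "valid_frames") <- frames
  fields
}

#' Absolute-velocity map
#'
#' Elementwise \code{sqrt(vx^2 + vy^2)}; gated (invalid) pixels are 0.
#'
#' @param field A \code{FlowField}.
#' @return An \code{AbsVelocityMap}: list with \code{speed} (H x W,
#'   px/frame), \code{valid}, \code{frame_index}.
#' @export
absolute_velocity <- function(field) {
  stopifnot(inherits(field, "FlowField"))
  speed <- sqrt(field$vx^2 + field$vy^2)
  speed[!field$valid] <- 0
  structure(list(speed = speed, valid = field$valid,
                 frame_index = field$frame_index),
            class = "AbsVelocityMap")
}

#' The calibration sweep's geometric tau series
#'
#' The noise-gate sweep doubles tau consecutively from a starting value;
#' the default 20-value series runs from 1e-5 to 5.24.
#'
#' @param start First tau value.
#' @param n Number of values.
#' @return Numeric vector of length \code{n}.
#' @export
tau_sweep_values <- function(start = 1e-5, n = 20L) start * 2^(seq_len(n) - 1L)

#' Parameter sweep over window scale and noise gate
#'
#' Computes flow over a grid of (\code{sigma_w}, \code{tau}) values on a
#' (small) movie and summarizes, for a foreground ROI containing the motion
#' of interest and a background ROI free of structures, the number of
#' above-gate pixels and the summed speed, plus the pooled log-speed
#' histogram. The structure tensor is computed once per \code{sigma_w}; the
#' gate is then applied per \code{tau}.
#'
#' @param m A preprocessed \code{\link{movie}}.
#' @param sigma_w_values,tau_values Grid values (defaults: 0.1-1 by 0.1 and
#'   \code{\link{tau_sweep_values}()}).
#' @param base An \code{\link{lk_params}} providing \code{sigma_s}/
#'   \code{sigma_t}.
#' @param fg_roi,bg_roi Lists \code{list(rows =, cols =)} of index vectors.
#' @param hist_spec A \code{\link{histogram_spec}} for the per-cell pooled
#'   histogram.
#' @return A \code{SweepReport}: data frame with one row per grid cell
#'   (columns \code{sigma_w}, \code{tau}, \code{fg_valid}, \code{fg_speed_sum},
#'   \code{bg_valid}, \code{bg_speed_sum}) with the histograms in
#'   \code{attr(, "histograms")}.
#' @export
parameter_sweep <- function(m, sigma_w_values = seq(0.1, 1, by = 0.1),
                            tau_values = tau_sweep_values(),
                            base = lk_params(), fg_roi, bg_roi,
                            hist_spec = histogram_spec()) {
  stopifnot(length(sigma_w_values) > 0, length(tau_values) > 0)
  d <- dim(m$data)
  for (roi in list(fg_roi, bg_roi))
    if (min(roi$rows) < 1 || max(roi$rows) > d[1] ||
        min(roi$cols) < 1 || max(roi$cols) > d[2])
      stop("ROI outside image bounds")
  grads <- gaussian_derivatives(m, base$sigma_s, base$sigma_t)
  ht <- grads$ht
  frames <- (ht + 1L):(d[3] - ht)
  rows <- list(); hists <- list()
  for (sw in sigma_w_values) {
    k <- lk_window_kernel(sw)
    per_frame <- lapply(frames, function(t) {
      Ix <- grads$Ix[, , t]; Iy <- grads$Iy[, , t]; It <- grads$It[, , t]
      list(G11 = conv2_sep(Ix * Ix, k, k), G22 = conv2_sep(Iy * Iy, k, k),
           G12 = conv2_sep(Ix * Iy, k, k),
           b1 = -conv2_sep(Ix * It, k, k), b2 = -conv2_sep(Iy * It, k, k))
    })
    for (tau in tau_values) {
      fgv <- 0L; fgs <- 0; bgv <- 0L; bgs <- 0
      counts <- numeric(hist_spec$n_bins)
      for (pf in per_frame) {
        tr2 <- (pf$G11 + pf$G22) / 2
        disc <- sqrt(pmax((pf$G11 - pf$G22)^2 / 4 + pf$G12^2, 0))
        det <- pf$G11 * pf$G22 - pf$G12^2
        valid <- (tr2 - disc) >= tau & det > .Machine$double.eps
        speed <- matrix(0, d[1], d[2])
        if (any(valid)) {
          vx <- (pf$G22[valid] * pf$b1[valid] - pf$G12[valid] * pf$b2[valid]) / det[valid]
          vy <- (pf$G11[valid] * pf$b2[valid] - pf$G12[valid] * pf$b1[valid]) / det[valid]
          speed[valid] <- sqrt(vx^2 + vy^2)
        }
        fg <- speed[fg_roi$rows, fg_roi$cols]; fgval <- valid[fg_roi$rows, fg_roi$cols]
        bg <- speed[bg_roi$rows, bg_roi$cols]; bgval <- valid[bg_roi$rows, bg_roi$cols]
        fgv <- fgv + sum(fgval); fgs <- fgs + sum(fg)
        bgv <- bgv + sum(bgval); bgs <- bgs + sum(bg)
        counts <- counts + log_speed_histogram(
          structure(list(speed = speed, valid = valid, frame_index = 0L),
                    class = "AbsVelocityMap"), hist_spec)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sigma_w = sw, tau = tau, fg_valid = fgv, fg_speed_sum = fgs,
        bg_valid = bgv, bg_speed_sum = bgs)
      hists[[length(hists) + 1L]] <- counts
    }
  }
  rep <- do.call(rbind, rows)
  attr(rep, "histograms") <- hists
  class(rep) <- c("SweepReport", class(rep))
  rep
}

#' Select operating parameters from a sweep
#'
#' Picks the smallest window scale whose foreground ROI produced flow, then
#' the largest gate value at that scale that fully suppresses the background
#' ROI (zero above-gate pixels) while the foreground still produces flow.
#'
#' @param report A \code{SweepReport}.
#' @return List \code{(sigma_w, tau)}.
#' @export
select_parameters <- function(report) {
  stopifnot(inherits(report, "SweepReport"))
  sws <- sort(unique(report$sigma_w))
  sw_ok <- sws[vapply(sws, function(s) any(report$fg_valid[report$sigma_w == s] > 0),
                      logical(1))]
  if (length(sw_ok) == 0L)
    stop("parameter selection failed: no window scale produced foreground flow")
  sw <- min(sw_ok)
  sub <- report[report$sigma_w == sw & report$bg_valid == 0 & report$fg_valid > 0, ]
  if (nrow(sub) == 0L)
    stop(sprintf("parameter selection failed: at sigma_w = %g no tau suppresses the background while retaining foreground flow", sw))
  list(sigma_w = sw, tau = max(sub$tau))
}

#' Write flow fields or absolute-velocity maps as 32-bit float TIFF
#'
#' Values are stored divided by \code{full_scale} (default \code{exp(4)}
#' px/frame, the histogram's upper speed bound) because TIFF sample values
#' live in [0, 1]; the scale is recorded in a YAML sidecar.
#'
#' @param fields List of \code{FlowField}s or \code{AbsVelocityMap}s.
#' @param path Output \code{.tif}.
#' @param what One of \code{"speed"}, \code{"vx"}, \code{"vy"}.
#' @param full_scale Value mapped to 1.0 on disk.
#' @export
write_flow_tiff <- function(fields, path, what = c("speed", "vx", "vy"),
                            full_scale = exp(4)) {
  what <- match.arg(what)
  pages <- lapply(fields, function(f) {
    v <- if (inherits(f, "AbsVelocityMap")) f$speed
    else if (what == "speed") absolute_velocity(f)$speed
    else f[[what]]
    # signed components are offset to keep samples in [0, 1]
    if (what == "speed") pmin(v / full_scale, 1)
    else pmin(pmax((v / full_scale + 1) / 2, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(quantity = what, full_scale_pf = full_scale,
                        signed_offset = what != "speed",
                        n_frames = length(fields)),
                   sub("\\.tiff?$", ".yaml", path))
  invisible(path)
}
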