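#' Spatial binning by block averaging
#'
#' Downsizes each frame by averaging non-overlapping \code{factor} x
#' \code{factor} blocks ("average when downsizing"). If the frame size is
#' not divisible by \code{factor}, trailing rows/columns are trimmed first.
#' The calibration's \code{bin_factor} is multiplied accordingly.
#'
#' @param m A \code{\link{movie}}.
#' @param factor Integer binning factor (>= 1).
#' @return Binned \code{Movie}.
#' @export
bin_spatial <- function(m, factor = 4L) {
  stopifnot(inherits(m, "Movie"), factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(record_op(m, "bin_spatial", factor = 1L))
  d <- dim(m$data)
  H <- (d[1] %/% factor) * factor; W <- (d[2] %/% factor) * factor
  x <- m$data[seq_len(H), seq_len(W), , drop = FALSE]
  # Block mean via two reshapes.
  dim(x) <- c(factor, H %/% factor, W, d[3])
  x <- colMeans(x)                               # (H/f) x W x T
  x <- aperm(x, c(2, 1, 3))
  dim(x) <- c(factor, W %/% factor, H %/% factor, d[3])
  x <- aperm(colMeans(x), c(2, 1, 3))            # (H/f) x (W/f) x T
  cal <- m$calibration
  cal$bin_factor <- cal$bin_factor * factor
  out <- movie(x, cal, m$history, m$bit_depth)
  record_op(out, "bin_spatial", factor = factor)
}

# Resample one frame under a rigid transform (dx, dy, theta about center):
# the transform maps reference coordinates to frame coordinates, so the
# output (registered) frame is the input sampled at the transformed grid.
rigid_resample <- function(img, dx, dy, theta) {
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gr <- matrix(seq_len(H), H, W); gc <- matrix(rep(seq_len(W), each = H), H, W)
  ct <- cos(theta); st <- sin(theta)
  src_c <- ct * (gc - cx) - st * (gr - cy) + cx + dx
  src_r <- st * (gc - cx) + ct * (gr - cy) + cy + dy
  matrix(bilinear_sample(img, as.vector(src_r), as.vector(src_c)), H, W)
}

# Integer-pixel translation estimate by FFT cross-correlation.
phase_shift_estimate <- function(ref, img) {
  F1 <- stats::fft(ref); F2 <- stats::fft(img)
  cc <- Re(stats::fft(F1 * Conj(F2), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  H <- nrow(ref); W <- ncol(ref)
  dy <- unname(pk[1]) - 1L; dx <- unname(pk[2]) - 1L
  if (dy > H / 2) dy <- dy - H
  if (dx > W / 2) dx <- dx - W
  c(dx = dx, dy = dy)
}

#' Rigid-body registration of a movie
#'
#' Removes global stage motion by registering every frame to a reference
#' frame with a rigid-body model (translation + rotation). Translation is
#' initialized by FFT cross-correlation; (dx, dy, theta) are then refined by
#' Nelder-Mead minimization of the mean-squared intensity difference on a
#' centrally cropped region, and the frame is resampled bilinearly.
#'
#' @param m A \code{\link{movie}}.
#' @param reference Reference frame index (default 1).
#' @return List with \code{movie} (registered) and \code{transforms} (data
#'   frame of per-frame \code{dx}, \code{dy}, \code{theta}; the reference row
#'   is the identity).
#' @export
register_rigid <- function(m, reference = 1L) {
  stopifnot(inherits(m, "Movie"), n_frames(m) >= 2)
  Tn <- n_frames(m)
  ref <- m$data[, , reference]
  if (all(ref == 0)) stop(sprintf("registration failure: reference frame %d is all zero", reference))
  H <- nrow(ref); W <- ncol(ref)
  mrg <- max(2L, round(min(H, W) * 0.1))
  rows <- (mrg + 1):(H - mrg); cols <- (mrg + 1):(W - mrg)
  out <- m$data
  tf <- data.frame(frame = seq_len(Tn), dx = 0, dy = 0, theta = 0)
  for (t in seq_len(Tn)) {
    if (t == reference) next
    img <- m$data[, , t]
    if (all(img == 0)) stop(sprintf("registration failure: frame %d is all zero", t))
    init <- phase_shift_estimate(ref, img)
    cost <- function(p) {
      mean((rigid_resample(img, p[1], p[2], p[3])[rows, cols] - ref[rows, cols])^2)
    }
    fit <- stats::optim(c(init["dx"], init["dy"], 0), cost, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-10))
    p <- fit$par
    out[, , t] <- rigid_resample(img, p[1], p[2], p[3])
    tf[t, c("dx", "dy", "theta")] <- p
  }
  mm <- movie(pmax(out, 0), m$calibration, m$history, m$bit_depth)
  mm <- record_op(mm, "register_rigid", reference = reference)
  list(movie = mm, transforms = tf)
}

#' Temporal stretching by quintic B-spline interpolation
#'
#' Resamples each pixel's time series with a degree-5 B-spline, producing
#' \code{factor * T} frames. Output frame \code{j} samples input time
#' \code{1 + (j - 1)/factor} (clamped to the original range at the end), so
#' for \code{factor = 2} every second output frame is an original frame and
#' the inserted frames are spline midpoints. The calibration's
#' \code{time_stretch} is multiplied accordingly.
#'
#' @param m A \code{\link{movie}}.
#' @param factor Integer stretch factor (>= 1).
#' @return Stretched \code{Movie}.
#' @export
stretch_time <- function(m, factor = 2L) {
  stopifnot(inherits(m, "Movie"), factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(record_op(m, "stretch_time", factor = 1L))
  d <- dim(m$data)
  x_new <- 1 + (seq_len(factor * d[3]) - 1) / factor
  Bm <- bspline_interp_matrix(d[3], x_new, degree = 5L)
  flat <- matrix(m$data, d[1] * d[2], d[3])
  out <- array(flat %*% t(Bm), c(d[1], d[2], length(x_new)))
  cal <- m$calibration
  cal$time_stretch <- cal$time_stretch * factor
  mm <- movie(pmax(out, 0), cal, m$history, m$bit_depth)
  record_op(mm, "stretch_time", factor = factor)
}

#' Centered crop
#'
#' Crops every frame to \code{out_size}, centered; with an odd size
#' difference the extra removed pixel comes from the right/bottom so that
#' output pixel (1,1) maps to input pixel
#' (\code{floor((H-h)/2)+1}, \code{floor((W-w)/2)+1}).
#'
#' @param m A \code{\link{movie}}.
#' @param out_size Integer (height, width) or a single size.
#' @return Cropped \code{Movie}; calibration unchanged.
#' @export
crop_center <- function(m, out_size) {
  stopifnot(inherits(m, "Movie"))
  out_size <- rep_len(as.integer(out_size), 2L)
  d <- dim(m$data)
  if (any(out_size > d[1:2])) stop("crop size exceeds movie size")
  off <- (d[1:2] - out_size) %/% 2L
  out <- m$data[off[1] + seq_len(out_size[1]), off[2] + seq_len(out_size[2]), , drop = FALSE]
  mm <- movie(out, m$calibration, m$history, m$bit_depth)
  record_op(mm, "crop_center", out_size = out_size)
}

#' Contrast enhancement and 8-bit conversion
#'
#' Stack-wide percentile stretch that saturates the stated fraction of
#' pixels (split between the low and high tails), followed by stack-wide
#' histogram equalization and linear rescale to 0-255 integers. Percentiles
#' and the equalization map are computed over the whole stack, not per
#' frame, so global flicker survives for the artifact filter to catch.
#'
#' @param m A \code{\link{movie}}.
#' @param saturated_fraction Fraction of pixels to saturate, in [0, 0.5).
#' @param equalize Apply histogram equalization after the stretch.
#' @return 8-bit \code{Movie} (with a \code{constant_input} flag in the
#'   history when the input had no dynamic range).
#' @export
enhance_contrast_8bit <- function(m, saturated_fraction = 0.05, equalize = TRUE) {
  stopifnot(inherits(m, "Movie"),
            saturated_fraction >= 0, saturated_fraction < 0.5)
  x <- m$data
  if (max(x) == min(x)) {
    out <- array(128, dim(x))
    warning("constant movie: contrast enhancement returns mid-gray")
    mm <- movie(out, m$calibration, m$history, 8L)
    return(record_op(mm, "enhance_contrast_8bit", constant_input = TRUE))
  }
  qs <- stats::quantile(x, c(saturated_fraction / 2, 1 - saturated_fraction / 2),
                        names = FALSE)
  if (qs[1] == qs[2]) qs <- range(x)
  x <- pmin(pmax((x - qs[1]) / (qs[2] - qs[1]), 0), 1)
  if (equalize) {
    # Stack-wide histogram equalization on 256 levels (monotone rank map).
    # Counts enter through their square root, which damps the otherwise
    # overwhelming background mode so that equalization does not blow
    # background noise across the full output range.
    lev <- pmin(floor(x * 255), 255)
    cdf <- cumsum(sqrt(tabulate(lev + 1L, 256L)))
    cdf0 <- cdf[which(cdf > 0)[1]]
    map <- (cdf - cdf0) / max(cdf[256] - cdf0, .Machine$double.eps)
    x <- array(map[lev + 1L], dim(x))
  }
  out <- array(as.numeric(round(x * 255)), dim(x))
  mm <- movie(out, m$calibration, m$history, 8L)
  record_op(mm, "enhance_contrast_8bit", saturated_fraction = saturated_fraction,
            equalize = equalize)
}

#' Background subtraction by mean projection
#'
#' Subtracts the temporal mean projection from every frame (clipped at 0),
#' suppressing stationary structures and highlighting moving objects.
#'
#' @param m A \code{\link{movie}}.
#' @return Background-subtracted \code{Movie}.
#' @export
subtract_mean_projection <- function(m) {
  stopifnot(inherits(m, "Movie"), n_frames(m) >= 2)
  mp <- rowMeans(m$data, dims = 2)
  out <- pmax(sweep(m$data, c(1, 2), mp, "-"), 0)
  mm <- movie(out, m$calibration, m$history, m$bit_depth)
  record_op(mm, "subtract_mean_projection")
}

#' Count intensity maxima with a prominence tolerance
#'
#' Upscales a frame by quintic B-spline interpolation, then counts local
#' maxima whose prominence over the saddle toward any higher region exceeds
#' \code{noise_tolerance} (ImageJ Find-Maxima-style). Connected plateaus
#' count once. Used to estimate the total number of labeled mitochondria.
#'
#' @param frame 2-D numeric matrix.
#' @param upscale_factor Integer B-spline upscaling factor (>= 1).
#' @param noise_tolerance Minimum prominence (intensity units).
#' @return Integer count of accepted maxima.
#' @export
count_maxima <- function(frame, upscale_factor = 1L, noise_tolerance = 0) {
  stopifnot(is.matrix(frame), upscale_factor >= 1)
  if (upscale_factor > 1L) {
    xr <- 1 + (seq_len(upscale_factor * nrow(frame)) - 1) / upscale_factor
    xc <- 1 + (seq_len(upscale_factor * ncol(frame)) - 1) / upscale_factor
    xr <- xr[xr <= nrow(frame)]; xc <- xc[xc <= ncol(frame)]
    frame <- bspline_interp_matrix(nrow(frame), xr) %*% frame %*%
      t(bspline_interp_matrix(ncol(frame), xc))
  }
  H <- nrow(frame); W <- ncol(frame)
  gmin <- min(frame)
  if (max(frame) == gmin) return(0L)
  # Candidate maxima: pixels >= all 8 neighbors.
  pad <- matrix(-Inf, H + 2, W + 2); pad[2:(H + 1), 2:(W + 1)] <- frame
  is_max <- matrix(TRUE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & (frame >= pad[2:(H + 1) + dy, 2:(W + 1) + dx])
  }
  cand <- which(is_max)
  cand <- cand[order(frame[cand], decreasing = TRUE)]
  owner <- matrix(0L, H, W)   # pixels claimed by an accepted or flooded maximum
  count <- 0L
  for (p in cand) {
    if (owner[p] != 0L) next  # on a plateau / within a higher maximum's flood
    v0 <- frame[p]
    # Flood the region of pixels > v0 - tolerance reachable from p. Meeting
    # higher ground (or a previously claimed region) means the candidate's
    # prominence over its saddle is below the tolerance: subsumed.
    vis <- matrix(FALSE, H, W)
    queue <- p; head <- 1L; vis[p] <- TRUE
    subsumed <- v0 - noise_tolerance <= gmin  # prominence over the image floor
    while (head <= length(queue) && !subsumed) {
      q <- queue[head]; head <- head + 1L
      r <- (q - 1L) %% H + 1L; c <- (q - 1L) %/% H + 1L
      for (dy in -1:1) for (dx in -1:1) {
        rr <- r + dy; cc <- c + dx
        if (rr < 1L || rr > H || cc < 1L || cc > W) next
        qq <- (cc - 1L) * H + rr
        if (frame[qq] > v0) { subsumed <- TRUE; break }
        if (frame[qq] > v0 - noise_tolerance && !vis[qq]) {
          if (owner[qq] != 0L) { subsumed <- TRUE; break }
          vis[qq] <- TRUE
          queue <- c(queue, qq)
        }
      }
    }
    owner[vis] <- 1L          # claim the flood so lower plateaus/bumps merge
    if (!subsumed) count <- count + 1L
  }
  count
}

#' Convert between pixels/frame and micrometers/second
#'
#' Flow and track speeds are computed natively in pixels per frame; these
#' helpers convert through the movie's effective calibration
#' (\code{um/px * bin_factor}, \code{s / time_stretch}).
#'
#' @param v_pf Speed in pixels/frame.
#' @param v_umps Speed in micrometers/second.
#' @param cal A \code{\link{calibration}}.
#' @return Converted speed.
#' @examples
#' cal <- calibration(0.108, 3.5, bin_factor = 4, time_stretch = 2)
#' velocity_umps(1, cal)     # ~0.247 um/s per px/frame
#' @export
velocity_umps <- function(v_pf, cal) v_pf * effective_pixel_um(cal) / effective_interval_s(cal)

#' @rdname velocity_umps
#' @export
umps_to_pf <- function(v_umps, cal) v_umps * effective_interval_s(cal) / effective_pixel_um(cal)

#' Rayleigh lateral resolution limit
#'
#' \code{0.61 * lambda / NA}, in nanometers; the conservative diffraction
#' limit used to relate camera sampling to optical resolution.
#'
#' @param wavelength_nm Emission wavelength in nm.
#' @param na Objective numerical aperture.
#' @return Resolution in nm.
#' @export
rayleigh_limit_nm <- function(wavelength_nm, na) 0.61 * wavelength_nm / na

#' Kymograph along a polyline path
#'
#' Samples the movie along a polyline (columns of the result are time
#' points; rows are positions along the path, ~1 px apart) taking the
#' maximum intensity across a perpendicular band of the given width.
#'
#' @param m A \code{\link{movie}}.
#' @param path Two-column matrix of (x, y) vertices in pixels.
#' @param width Band width in pixels (odd integer effective).
#' @return Matrix (position along path) x (time).
#' @export
kymograph <- function(m, path, width = 3) {
  stopifnot(inherits(m, "Movie"), is.matrix(path), ncol(path) == 2)
  if (nrow(path) < 2) stop("kymograph path needs at least 2 vertices")
  # Resample the polyline at ~1 px spacing.
  pts <- NULL; dirs <- NULL
  for (i in seq_len(nrow(path) - 1)) {
    a <- path[i, ]; b <- path[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, length.out = max(2, ceiling(len) + 1))
    if (i > 1) tt <- tt[-1]
    seg <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
    dir <- (b - a) / len
    pts <- rbind(pts, seg)
    dirs <- rbind(dirs, matrix(dir, nrow(seg), 2, byrow = TRUE))
  }
  normal <- cbind(-dirs[, 2], dirs[, 1])
  offsets <- seq(-(width - 1) / 2, (width - 1) / 2)
  Tn <- n_frames(m)
  out <- matrix(0, nrow(pts), Tn)
  for (t in seq_len(Tn)) {
    fr <- m$data[, , t]
    prof <- matrix(-Inf, nrow(pts), length(offsets))
    for (j in seq_along(offsets)) {
      px <- pts[, 1] + offsets[j] * normal[, 1]
      py <- pts[, 2] + offsets[j] * normal[, 2]
      prof[, j] <- bilinear_sample(fr, py, px)
    }
    out[, t] <- apply(prof, 1, max)
  }
  out
}
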