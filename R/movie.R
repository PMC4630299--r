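#' Acquisition calibration
#'
#' Holds the spatial and temporal calibration of a movie. The raw
#' acquisition scale (micrometers per pixel, seconds per frame) is fixed at
#' construction; spatial binning and temporal stretching update the
#' \code{bin_factor} and \code{time_stretch} bookkeeping so that the
#' effective scales are always \code{pixel_size_um * bin_factor} and
#' \code{frame_interval_s / time_stretch}.
#'
#' @param pixel_size_um Raw pixel size in micrometers per pixel.
#' @param frame_interval_s Raw frame interval in seconds.
#' @param bin_factor Integer spatial binning already applied (default 1).
#' @param time_stretch Integer temporal stretch already applied (default 1).
#' @return An object of class \code{Calibration}.
#' @examples
#' cal <- calibration(0.108, 3.5, bin_factor = 4, time_stretch = 2)
#' effective_pixel_um(cal)      # 0.432
#' effective_interval_s(cal)    # 1.75
#' @export
calibration <- function(pixel_size_um, frame_interval_s,
                        bin_factor = 1L, time_stretch = 1L) {
  stopifnot(pixel_size_um > 0, frame_interval_s > 0,
            bin_factor >= 1, time_stretch >= 1)
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 bin_factor = as.integer(bin_factor),
                 time_stretch = as.integer(time_stretch)),
            class = "Calibration")
}

#' @rdname calibration
#' @export
effective_pixel_um <- function(cal) cal$pixel_size_um * cal$bin_factor

#' @rdname calibration
#' @export
effective_interval_s <- function(cal) cal$frame_interval_s / cal$time_stretch

#' Time-lapse movie container
#'
#' A single-channel time-lapse movie stored as an H x W x T numeric array
#' (rows = y increasing downward, columns = x increasing rightward, both
#' 1-based) together with its \code{\link{calibration}} and an ordered
#' history of applied operations sufficient to replay the processing chain.
#'
#' @param data H x W x T numeric array of intensities.
#' @param cal A \code{Calibration}.
#' @param history List of operation descriptors (each a named list with at
#'   least an \code{op} element).
#' @param bit_depth Nominal bit depth of \code{data} (16 for raw camera
#'   counts, 8 after \code{\link{enhance_contrast_8bit}}).
#' @return An object of class \code{Movie}.
#' @export
movie <- function(data, cal, history = list(list(op = "create")), bit_depth = 16L) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] >= 2,
            all(is.finite(data)), inherits(cal, "Calibration"))
  structure(list(data = data, calibration = cal, history = history,
                 bit_depth = as.integer(bit_depth)),
            class = "Movie")
}

n_frames <- function(m) dim(m$data)[3]

record_op <- function(m, op, ...) {
  m$history[[length(m$history) + 1L]] <- c(list(op = op), list(...))
  m
}

#' @export
print.Movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Movie: %d x %d px, %d frames, %.3f um/px (effective), %.3f s/frame (effective)\n",
              d[1], d[2], d[3],
              effective_pixel_um(x$calibration), effective_interval_s(x$calibration)))
  cat("history:", paste(vapply(x$history, function(h) h$op, character(1)),
                        collapse = " -> "), "\n")
  invisible(x)
}

#' @export
print.Calibration <- function(x, ...) {
  cat(sprintf("Calibration: %.4f um/px x bin %d = %.4f um/px; %.3f s / stretch %d = %.3f s\n",
              x$pixel_size_um, x$bin_factor, effective_pixel_um(x),
              x$frame_interval_s, x$time_stretch, effective_interval_s(x)))
  invisible(x)
}

#' Read and write movies as multi-page TIFF with a YAML calibration sidecar
#'
#' Movies are written as 16-bit (or 8-bit) multi-page TIFF; intensities are
#' scaled by the bit depth's full range on disk. The calibration and history
#' are stored in a \code{.yaml} sidecar next to the TIFF.
#'
#' @param m A \code{Movie}.
#' @param path Path to the \code{.tif} file.
#' @return \code{write_movie_tiff} returns \code{path} invisibly;
#'   \code{read_movie_tiff} returns a \code{Movie}.
#' @export
write_movie_tiff <- function(m, path) {
  maxval <- 2^m$bit_depth - 1
  pages <- lapply(seq_len(n_frames(m)), function(t)
    pmin(pmax(m$data[, , t] / maxval, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = if (m$bit_depth <= 8) 8L else 16L)
  sidecar <- sub("\\.tiff?$", ".yaml", path)
  yaml::write_yaml(list(
    pixel_size_um = m$calibration$pixel_size_um,
    frame_interval_s = m$calibration$frame_interval_s,
    bin_factor = m$calibration$bin_factor,
    time_stretch = m$calibration$time_stretch,
    bit_depth = m$bit_depth,
    history = m$history), sidecar)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- sub("\\.tiff?$", ".yaml", path)
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else
    list(pixel_size_um = 0.108, frame_interval_s = 3.5,
         bin_factor = 1L, time_stretch = 1L, bit_depth = 16L,
         history = list(list(op = "read")))
  bit_depth <- as.integer(meta$bit_depth %||% 16L)
  maxval <- 2^bit_depth - 1
  d <- dim(pages[[1]])
  data <- array(0, c(d[1], d[2], length(pages)))
  for (t in seq_along(pages)) data[, , t] <- pages[[t]] * maxval
  movie(data,
        calibration(meta$pixel_size_um, meta$frame_interval_s,
                    meta$bin_factor %||% 1L, meta$time_stretch %||% 1L),
        history = meta$history %||% list(list(op = "read")),
        bit_depth = bit_depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
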