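#' Kymograph container
#'
#' A kymograph is a time-by-position raster of fluorescence intensity along a
#' single tethered DNA molecule. Rows are frames (time increasing downward),
#' columns are position pixels; indices are 0-based in all file formats and
#' 1-based inside R, as usual. All channels share the shape and calibration.
#'
#' @param channels named list of numeric matrices (frames x position pixels),
#'   e.g. `list(rad51 = ..., rpa = ...)`.
#' @param frame_interval_s time per frame, seconds (> 0).
#' @param pixel_size_nm spatial calibration, nm per pixel (> 0).
#' @return an object of class `kymograph`.
#' @examples
#' k <- kymograph(list(g = matrix(0, 4, 10)), frame_interval_s = 1,
#'                pixel_size_nm = 100)
#' dim(k)
#' @export
kymograph <- function(channels, frame_interval_s, pixel_size_nm = 100) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop_param("'channels' must be a named list of matrices")
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m),
                 logical(1))))
    stop_param("every channel must be a numeric matrix")
  if (length(unique(dims)) != 1L)
    stop_param("all channels must share the same dimensions")
  check_scalar(frame_interval_s, "frame_interval_s", 0, strict_min = TRUE)
  check_scalar(pixel_size_nm, "pixel_size_nm", 0, strict_min = TRUE)
  structure(list(channels = channels,
                 frame_interval_s = frame_interval_s,
                 pixel_size_nm = pixel_size_nm),
            class = "kymograph")
}

#' @export
dim.kymograph <- function(x) dim(x$channels[[1L]])

#' @export
print.kymograph <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<kymograph> %d frames x %d px | %.3g s/frame, %.3g nm/px | channels: %s\n",
    d[1L], d[2L], x$frame_interval_s, x$pixel_size_nm,
    paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Frame times of a kymograph
#'
#' Frame `i` holds the state at time `(i - 1) * frame_interval_s`; the first
#' frame is the initial state.
#' @param kymo a [kymograph].
#' @return numeric vector of frame times in seconds.
#' @export
frame_times <- function(kymo) {
  stopifnot(inherits(kymo, "kymograph"))
  (seq_len(nrow(kymo$channels[[1L]])) - 1) * kymo$frame_interval_s
}

#' @export
plot.kymograph <- function(x, channel = names(x$channels)[1L], ...) {
  m <- x$channels[[channel]]
  tt <- frame_times(x)
  pos <- (seq_len(ncol(m)) - 0.5) * x$pixel_size_nm / 1000
  graphics::image(pos, tt, t(m)[, rev(seq_along(tt)), drop = FALSE],
                  xlab = "position (µm)", ylab = "time (s, downward)",
                  yaxt = "n", col = grDevices::hcl.colors(64, "viridis"), ...)
  at <- pretty(tt)
  graphics::axis(2, at = rev(range(tt))[1] - at + min(tt), labels = at)
  invisible(x)
}
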