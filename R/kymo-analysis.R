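## Kymograph kinetics: normalized assembly signal, apparent nucleation rate,
## filament boundary growth/disassembly slopes, binding events, FRET phases,
## force-trace downsampling.

#' Normalized assembly signal
#'
#' Per-frame mean channel intensity divided by the per-frame mean intensity
#' of a user-chosen background pixel region, emulating normalization of the
#' assembly fluorescence to the background signal. A uniform image therefore
#' yields a constant series of 1.
#'
#' @param kymo a [kymograph].
#' @param channel channel name.
#' @param background_region integer vector of background pixel columns, or
#'   `c(lo, hi)` range.
#' @param signal_region pixel columns of the signal region (default: the
#'   whole width).
#' @return data.frame `time_s`, `normalized`.
#' @export
normalize_assembly_signal <- function(kymo, channel,
                                      background_region,
                                      signal_region = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  m <- kymo$channels[[channel]]
  if (is.null(m)) stop_param(sprintf("no channel '%s'", channel))
  bg <- if (length(background_region) == 2L)
    seq.int(background_region[1L], background_region[2L])
  else as.integer(background_region)
  if (!length(bg) || any(bg < 1L) || any(bg > ncol(m)))
    stop_param("'background_region' empty or outside the image")
  sig <- signal_region %||% seq_len(ncol(m))
  bg_mean <- rowMeans(m[, bg, drop = FALSE])
  if (any(bg_mean == 0))
    stop("background mean is zero in at least one frame; cannot normalize")
  data.frame(time_s = frame_times(kymo),
             normalized = rowMeans(m[, sig, drop = FALSE]) / bg_mean)
}

# Local maxima of x with topographic prominence >= min_prom; maxima closer
# than min_sep keep only the highest. Returns indices.
find_peaks <- function(x, min_prom, min_sep = 3L) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) {
    h <- x[i]
    # walk left until a higher point; key saddle = min en route
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) { lmin <- min(lmin, x[j]); j <- j - 1L }
    if (j < 1L) lmin <- min(lmin, min(x[1:i]))
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) { rmin <- min(rmin, x[j]); j <- j + 1L }
    if (j > n) rmin <- min(rmin, min(x[i:n]))
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prom & prom > 0]
  if (length(keep) < 2L || min_sep <= 1L) return(keep)
  o <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer()
  for (i in o) if (!length(sel) || all(abs(sel - i) >= min_sep))
    sel <- c(sel, i)
  sort(sel)
}

#' Apparent nucleation rate from a kymograph
#'
#' Each frame's spatial intensity profile is smoothed with a Savitzky-Golay
#' filter (default 5-pixel window, polynomial order 2), local intensity peaks
#' with topographic prominence of at least `prominence_sigmas` robust
#' background SDs are counted, and the per-frame peak counts are fitted with
#' the saturating exponential `y = a_max (1 - exp(-k t))`. The fitted `k`
#' (1/s) is the apparent nucleation rate.
#'
#' @param kymo a [kymograph].
#' @param channel channel name.
#' @param smooth_window_px Savitzky-Golay window, pixels (odd, default 5).
#' @param sg_order Savitzky-Golay polynomial order (default 2; must be
#'   smaller than the window).
#' @param prominence_sigmas peak prominence threshold in units of the robust
#'   (MAD-based) SD of the smoothed image (default 3).
#' @param min_separation_px minimum distance between counted peaks (default
#'   3, about one PSF, to avoid double-counting).
#' @return a `nucleation_estimate`: list with `peak_counts`, `time_s`, `fit`
#'   ([exp_fit][fit_saturating_exponential]), `apparent_rate` (1/s) and the
#'   thresholds used.
#' @export
estimate_nucleation_rate <- function(kymo, channel = names(kymo$channels)[1L],
                                     smooth_window_px = 5L, sg_order = 2L,
                                     prominence_sigmas = 3,
                                     min_separation_px = 3L) {
  stopifnot(inherits(kymo, "kymograph"))
  m <- kymo$channels[[channel]]
  if (is.null(m)) stop_param(sprintf("no channel '%s'", channel))
  if (nrow(m) == 0L) stop_param("kymograph has zero frames")
  if (ncol(m) < smooth_window_px)
    stop_param("image narrower than the smoothing window")
  if (sg_order >= smooth_window_px)
    stop_param("'sg_order' must be smaller than the window")
  sm <- t(apply(m, 1L, function(r)
    signal::sgolayfilt(r, p = sg_order, n = smooth_window_px)))
  # background noise SD estimated from horizontal first differences of the
  # raw image (robust to the covered/uncovered structure; smoothing shrinks
  # noise prominences below this scale, so 3 sigma suppresses false peaks)
  sigma <- robust_sd(as.vector(t(diff(t(m))))) / sqrt(2)
  thr <- if (sigma > 0) prominence_sigmas * sigma else .Machine$double.eps
  counts <- apply(sm, 1L, function(r)
    length(find_peaks(r, min_prom = thr, min_sep = min_separation_px)))
  tt <- frame_times(kymo)
  fit <- fit_saturating_exponential(tt, counts)
  structure(list(peak_counts = as.integer(counts), time_s = tt, fit = fit,
                 apparent_rate = if (fit$converged) fit$k else 0,
                 prominence_threshold = thr,
                 smooth_window_px = smooth_window_px, sg_order = sg_order),
            class = "nucleation_estimate")
}

#' @export
print.nucleation_estimate <- function(x, ...) {
  cat(sprintf(
    "<nucleation_estimate> apparent rate k = %.4g 1/s (plateau %.3g peaks, %s)\n",
    x$apparent_rate, x$fit$a_max,
    if (x$fit$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Filament boundary growth or disassembly rate
#'
#' Tracks one border of a bright connected segment across frames and regresses
#' its position (nm) on time: the slope is the growth rate (positive when the
#' chosen edge moves outward, i.e. the filament grows) in nm/s. The boundary
#' is the outermost pixel of the connected run whose intensity is at least
#' `threshold_fraction` of the segment plateau (half-max by default).
#'
#' @param kymo a [kymograph].
#' @param channel channel name.
#' @param segment_seed `c(frame, px)`: a pixel inside the segment in a frame
#'   where it is present.
#' @param threshold_fraction boundary definition, fraction of the plateau.
#' @param side which border to track: `"right"` or `"left"`.
#' @param max_gap_frames frames the segment may go missing before the track
#'   is truncated (with a warning).
#' @return an `edge_rate`: list with `boundary` (data.frame `time_s`,
#'   `position_nm`), `rate_nm_per_s` (signed: positive = outward growth),
#'   `r_squared`, `side`.
#' @export
measure_edge_rate <- function(kymo, channel = names(kymo$channels)[1L],
                              segment_seed, threshold_fraction = 0.5,
                              side = c("right", "left"),
                              max_gap_frames = 2L) {
  stopifnot(inherits(kymo, "kymograph"))
  side <- match.arg(side)
  m <- kymo$channels[[channel]]
  if (is.null(m)) stop_param(sprintf("no channel '%s'", channel))
  f0 <- segment_seed[1L]; p0 <- segment_seed[2L]
  if (f0 < 1L || f0 > nrow(m) || p0 < 1L || p0 > ncol(m))
    stop_param("'segment_seed' outside the kymograph")

  run_around <- function(row, j, thr) {
    if (row[j] < thr) return(NULL)
    lo <- j; while (lo > 1L && row[lo - 1L] >= thr) lo <- lo - 1L
    hi <- j; while (hi < length(row) && row[hi + 1L] >= thr) hi <- hi + 1L
    c(lo, hi)
  }
  seed_row <- m[f0, ]
  # plateau: median intensity of the half-max run around the seed pixel
  provisional <- run_around(seed_row, p0, 0.5 * max(seed_row))
  if (is.null(provisional))
    stop_param("seed pixel is not above the provisional threshold")
  plateau <- stats::median(seed_row[provisional[1L]:provisional[2L]])
  thr <- threshold_fraction * plateau

  track_j <- p0
  gap <- 0L
  tt <- frame_times(kymo)
  out_t <- numeric(); out_px <- numeric()
  for (f in f0:nrow(m)) {
    run <- run_around(m[f, ], track_j, thr)
    if (is.null(run)) {
      # segment may have shrunk past the tracked point; search the nearest
      # above-threshold pixel within a small neighbourhood
      near <- which(m[f, ] >= thr)
      if (length(near)) {
        j2 <- near[which.min(abs(near - track_j))]
        if (abs(j2 - track_j) <= 5L) run <- run_around(m[f, ], j2, thr)
      }
    }
    if (is.null(run)) {
      gap <- gap + 1L
      if (gap > max_gap_frames) {
        warning(sprintf("segment lost after frame %d; track truncated", f))
        break
      }
      next
    }
    gap <- 0L
    track_j <- as.integer(round(mean(run)))
    edge_px <- if (side == "right") run[2L] else run[1L]
    out_t <- c(out_t, tt[f])
    out_px <- c(out_px, edge_px)
  }
  if (length(out_t) < 3L)
    stop_param("fewer than 3 boundary samples; cannot fit a rate")
  pos_nm <- (out_px - 0.5) * kymo$pixel_size_nm
  fit <- stats::lm(pos_nm ~ out_t)
  slope <- unname(stats::coef(fit)[2L])
  r2 <- if (stats::var(pos_nm) == 0) 0 else summary(fit)$r.squared
  # sign convention: positive = edge moving outward (growth)
  rate <- if (side == "right") slope else -slope
  structure(list(boundary = data.frame(time_s = out_t, position_nm = pos_nm),
                 rate_nm_per_s = rate, r_squared = r2, side = side,
                 threshold = thr),
            class = "edge_rate")
}

#' @export
print.edge_rate <- function(x, ...) {
  cat(sprintf("<edge_rate> %s edge: %.4g nm/s (R^2 = %.3f, %d samples)\n",
              x$side, x$rate_nm_per_s, x$r_squared, nrow(x$boundary)))
  invisible(x)
}

#' Detect binding events in a kymograph
#'
#' Thresholds a channel at `median + intensity_sigmas * MAD`, labels
#' 8-connected spatiotemporal regions, and keeps those lasting at least
#' `min_duration_frames`. Event frequency is reported per time window
#' (default 30 s, the window used for binding-frequency comparisons).
#'
#' @param kymo a [kymograph].
#' @param channel channel name.
#' @param intensity_sigmas detection threshold in robust SDs (default 5).
#' @param min_duration_frames minimum event duration, frames (default 2).
#' @param window_s frequency window, seconds (default 30).
#' @return list with `events` (data.frame: `start_s`, `end_s`,
#'   `position_lo_px`, `position_hi_px`, one `mean_<channel>` column per
#'   channel) and `frequency` (data.frame `window_start_s`, `count` of
#'   events starting in each window).
#' @export
detect_binding_events <- function(kymo, channel = names(kymo$channels)[1L],
                                  intensity_sigmas = 5,
                                  min_duration_frames = 2L, window_s = 30) {
  stopifnot(inherits(kymo, "kymograph"))
  m <- kymo$channels[[channel]]
  if (is.null(m)) stop_param(sprintf("no channel '%s'", channel))
  dt <- kymo$frame_interval_s
  bg <- stats::median(m)
  sigma <- robust_sd(as.vector(m))
  thr <- bg + intensity_sigmas * max(sigma, .Machine$double.eps)
  lab <- label_components8(m >= thr)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  ev <- list()
  for (id in ids) {
    px <- which(lab == id, arr.ind = TRUE)
    frames <- range(px[, 1L])
    if (diff(frames) + 1L < min_duration_frames) next
    means <- vapply(kymo$channels, function(ch)
      mean(ch[px]), numeric(1))
    names(means) <- paste0("mean_", names(kymo$channels))
    ev[[length(ev) + 1L]] <- data.frame(
      start_s = (frames[1L] - 1L) * dt, end_s = frames[2L] * dt,
      position_lo_px = min(px[, 2L]) - 1L,  # 0-based, as documented
      position_hi_px = max(px[, 2L]) - 1L,
      as.list(means))
  }
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(start_s = numeric(), end_s = numeric(),
                            position_lo_px = integer(),
                            position_hi_px = integer())
  events <- events[order(events$start_s), , drop = FALSE]
  total_s <- nrow(m) * dt
  starts <- seq(0, max(total_s - 1e-9, 0), by = window_s)
  freq <- data.frame(window_start_s = starts,
                     count = vapply(starts, function(w)
                       sum(events$start_s >= w &
                           events$start_s < w + window_s), integer(1)))
  list(events = events, frequency = freq, threshold = thr)
}

#' Segment a FRET event trace into phases
#'
#' Averages both channels in a running 3-sample window, thresholds the
#' acceptor against donor bleed-through, and labels contiguous phases:
#' `fret` (acceptor above bleed-through), `donor_only` (donor present,
#' acceptor at bleed-through) and `dark` (both at background). The Pearson
#' correlation of the two channels over the non-dark portion quantifies the
#' anti-correlation expected of genuine energy transfer.
#'
#' @param trace an `event_trace` (see [simulate_fret_trace()]) or a list with
#'   `time_s`, `donor`, `acceptor` of equal length.
#' @param bleedthrough_level acceptor intensity expected from donor
#'   bleed-through alone (measured on donor-only molecules).
#' @param step_sigmas threshold margin in units of the estimated channel
#'   noise SD (default 3).
#' @param donor_background donor intensity in the dark phase (default 0).
#' @param smooth_window running-mean window, samples (default 3).
#' @return a `fret_event`: list with `phases` (data.frame `label`,
#'   `start_s`, `end_s`), `donor_trace`, `acceptor_trace` (smoothed),
#'   `anticorrelation`.
#' @export
analyze_fret_event <- function(trace, bleedthrough_level, step_sigmas = 3,
                               donor_background = 0, smooth_window = 3L) {
  if (length(trace$donor) != length(trace$acceptor))
    stop_param("donor and acceptor traces have unequal length")
  n <- length(trace$donor)
  if (n < 2L) stop_param("trace too short")
  don <- running_mean(trace$donor, smooth_window)
  acc <- running_mean(trace$acceptor, smooth_window)
  # noise estimated from first differences of the raw traces (robust to
  # steps); smoothing only shrinks the noise, so this margin is conservative
  sd_a <- robust_sd(diff(trace$acceptor)) / sqrt(2)
  sd_d <- robust_sd(diff(trace$donor)) / sqrt(2)
  thr_a <- bleedthrough_level + step_sigmas * max(sd_a, .Machine$double.eps)
  thr_d <- donor_background + step_sigmas * max(sd_d, .Machine$double.eps)
  lab <- ifelse(acc > thr_a, "fret",
                ifelse(don > thr_d, "donor_only", "dark"))
  r <- rle(lab)
  # suppress sub-resolution flicker: runs shorter than 3 samples are merged
  # into the preceding phase (or the following one at the trace start)
  while (length(r$lengths) > 1L && any(r$lengths < 3L)) {
    i <- which.min(r$lengths)
    if (r$lengths[i] >= 3L) break
    r$values[i] <- if (i > 1L) r$values[i - 1L] else r$values[i + 1L]
    keep <- rle(inverse.rle(r))
    r <- keep
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  tt <- trace$time_s
  dt <- if (n > 1L) tt[2L] - tt[1L] else 1
  phases <- data.frame(label = r$values,
                       start_s = tt[starts] - dt / 2,
                       end_s = tt[ends] + dt / 2)
  nd <- lab != "dark"
  anticor <- if (sum(nd) >= 3L && stats::sd(don[nd]) > 0 &&
                 stats::sd(acc[nd]) > 0)
    stats::cor(don[nd], acc[nd]) else NA_real_
  structure(list(phases = phases, donor_trace = don, acceptor_trace = acc,
                 time_s = tt, anticorrelation = anticor,
                 thresholds = c(acceptor = thr_a, donor = thr_d)),
            class = "fret_event")
}

#' @export
print.fret_event <- function(x, ...) {
  cat("<fret_event> phases:\n")
  print(x$phases)
  cat(sprintf("anticorrelation r = %.3f\n", x$anticorrelation))
  invisible(x)
}

#' Downsample a force trace by block averaging
#'
#' Non-overlapping block means over half-open windows `[t, t + 1/target_hz)`,
#' the standard reduction of high-rate optical-trap force data for plotting
#' (default 3 Hz).
#'
#' @param trace a `force_trace` (data.frame `time_s`, `force_pN` with
#'   attribute `sample_rate_hz`) or any such data.frame.
#' @param target_hz output rate, Hz.
#' @return a `force_trace` at `target_hz`; the number of output samples is
#'   `floor(duration * target_hz)`.
#' @export
downsample_force <- function(trace, target_hz = 3) {
  check_scalar(target_hz, "target_hz", 0, strict_min = TRUE)
  tt <- trace$time_s
  if (is.unsorted(tt, strictly = TRUE))
    stop_param("time must be strictly increasing")
  rate <- attr(trace, "sample_rate_hz") %||%
    (1 / stats::median(diff(tt)))
  if (rate < target_hz) stop_param("input rate below the target rate")
  duration <- length(tt) / rate
  n_out <- floor(duration * target_hz)
  if (n_out < 1L) stop_param("trace shorter than one output block")
  block <- floor((tt - tt[1L]) * target_hz)
  keep <- block < n_out
  f <- tapply(trace$force_pN[keep], block[keep], mean)
  b <- as.integer(names(f))
  structure(data.frame(time_s = tt[1L] + (b + 0.5) / target_hz,
                       force_pN = as.numeric(f)),
            sample_rate_hz = target_hz,
            class = c("force_trace", "data.frame"))
}
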