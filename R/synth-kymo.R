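## Forward simulation of RAD51 filament assembly/disassembly kymographs.
##
## Process model: filament assembly follows a nucleation-extension mechanism.
## Nucleation is a spatial Poisson process with intensity k_nuc (events per um
## of *uncovered* substrate per second); each nucleus is a short covered
## segment that extends at both ends until it collides with a neighbour or the
## substrate end. Disassembly (no ATP) shrinks segments from both ends at
## k_off. The camera model is Gaussian-PSF blur of the expected photon flux,
## Poisson shot noise, then additive Gaussian read noise.

#' Parameters for kymograph simulation
#'
#' Collects and validates the generative parameters of the
#' nucleation-extension-disassembly process and of the camera model.
#'
#' @param length_um substrate (ssDNA) length, micrometres.
#' @param duration_s total imaged time, seconds.
#' @param frame_interval_s time per frame, seconds.
#' @param pixel_size_nm spatial calibration, nm per pixel (default 100, the
#'   confocal scan calibration typical of C-trap kymographs).
#' @param k_nuc nucleation rate density, events per um of uncovered substrate
#'   per second.
#' @param v_grow total extension speed of one filament cluster, nm/s, split
#'   between its two ends by `polarity`.
#' @param k_off per-end disassembly speed, nm/s, used when simulating the
#'   ATP-free channel.
#' @param polarity fraction of `v_grow` assigned to the right-moving end
#'   (0.5 = symmetric growth; filament growth polarity can be emulated by
#'   moving it toward 0 or 1).
#' @param nucleus_nm initial footprint of a nucleus, nm.
#' @param psf_sigma_px Gaussian point-spread-function width, pixels.
#' @param photon_rate expected counts per fully covered pixel per frame.
#' @param read_noise_sd Gaussian camera read noise, counts.
#' @param bleach_rate per-fluorophore photobleaching rate, 1/s.
#' @param shot_noise logical; disable to render the noise-free expectation
#'   (used by recovery tests at zero noise).
#' @param seed integer RNG seed; identical parameters and seed give
#'   bit-identical output.
#' @return a validated list of class `sim_kymo_params`.
#' @seealso [simulate_kymograph()], [simulate_disassembly_kymograph()]
#' @export
sim_kymo_params <- function(length_um = 20, duration_s = 240,
                            frame_interval_s = 2, pixel_size_nm = 100,
                            k_nuc = 0.02, v_grow = 0.5, k_off = 0,
                            polarity = 0.5, nucleus_nm = 100,
                            psf_sigma_px = 1.2, photon_rate = 120,
                            read_noise_sd = 3, bleach_rate = 0,
                            shot_noise = TRUE, seed = 1L) {
  check_scalar(length_um, "length_um", 0, strict_min = TRUE)
  check_scalar(duration_s, "duration_s", 0, strict_min = TRUE)
  check_scalar(frame_interval_s, "frame_interval_s", 0, strict_min = TRUE)
  check_scalar(pixel_size_nm, "pixel_size_nm", 0, strict_min = TRUE)
  for (nm in c("k_nuc", "v_grow", "k_off", "nucleus_nm", "psf_sigma_px",
               "photon_rate", "read_noise_sd", "bleach_rate"))
    check_scalar(get(nm), nm, 0)
  check_scalar(polarity, "polarity", 0)
  if (polarity > 1) stop_param("'polarity' must be in [0, 1]")
  check_scalar(seed, "seed")
  structure(list(length_um = length_um, duration_s = duration_s,
                 frame_interval_s = frame_interval_s,
                 pixel_size_nm = pixel_size_nm, k_nuc = k_nuc,
                 v_grow = v_grow, k_off = k_off, polarity = polarity,
                 nucleus_nm = nucleus_nm, psf_sigma_px = psf_sigma_px,
                 photon_rate = photon_rate, read_noise_sd = read_noise_sd,
                 bleach_rate = bleach_rate, shot_noise = isTRUE(shot_noise),
                 seed = as.integer(seed)),
            class = "sim_kymo_params")
}

# Merge a sorted segment table (columns left, right in um) after growth;
# segments are clipped to [0, L]. `id` keeps the oldest contributing nucleus.
merge_segments <- function(seg, L) {
  if (!nrow(seg)) return(seg)
  seg$left <- pmax(seg$left, 0)
  seg$right <- pmin(seg$right, L)
  seg <- seg[seg$right > seg$left, , drop = FALSE]
  if (nrow(seg) < 2L) return(seg)
  seg <- seg[order(seg$left), , drop = FALSE]
  out <- seg[1L, , drop = FALSE]
  for (i in 2:nrow(seg)) {
    j <- nrow(out)
    if (seg$left[i] <= out$right[j]) {
      out$right[j] <- max(out$right[j], seg$right[i])
      out$id[j] <- min(out$id[j], seg$id[i])
    } else {
      out <- rbind(out, seg[i, , drop = FALSE])
    }
  }
  out
}

# Uncovered intervals of [0, L] given a merged, sorted segment table.
gap_intervals <- function(seg, L) {
  if (!nrow(seg)) return(data.frame(lo = 0, hi = L))
  lo <- c(0, seg$right)
  hi <- c(seg$left, L)
  keep <- hi > lo
  data.frame(lo = lo[keep], hi = hi[keep])
}

# Per-pixel covered fraction (length n_px) for segments in um.
pixel_coverage <- function(seg, n_px, px_um) {
  cov <- numeric(n_px)
  if (!nrow(seg)) return(cov)
  for (i in seq_len(nrow(seg))) {
    j0 <- floor(seg$left[i] / px_um) + 1
    j1 <- ceiling(seg$right[i] / px_um)
    j0 <- max(1, min(n_px, j0)); j1 <- max(1, min(n_px, j1))
    for (j in j0:j1) {
      o <- min(seg$right[i], j * px_um) - max(seg$left[i], (j - 1) * px_um)
      if (o > 0) cov[j] <- cov[j] + o / px_um
    }
  }
  pmin(cov, 1)
}

# Gaussian blur of each row along the position axis, reflective boundaries.
blur_rows <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3.5 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  nc <- ncol(m)
  idx <- c(pmin(r:1 + 1L, nc), seq_len(nc), nc - pmin(1:r, nc - 1L))
  pad <- m[, idx, drop = FALSE]
  out <- matrix(0, nrow(m), nc)
  for (o in seq_along(k))
    out <- out + k[o] * pad[, (o - 1L) + seq_len(nc), drop = FALSE]
  out
}

# Core engine shared by the assembly and disassembly simulators.
run_kymo_process <- function(p, initial = NULL, disassembly = FALSE,
                             rpa_channel = FALSE) {
  dt <- p$frame_interval_s
  n_frames <- max(2L, round(p$duration_s / dt) + 1L)
  n_px <- max(1L, round(p$length_um * 1000 / p$pixel_size_nm))
  px_um <- p$pixel_size_nm / 1000
  L <- p$length_um
  vR <- p$polarity * p$v_grow / 1000          # um/s
  vL <- (1 - p$polarity) * p$v_grow / 1000
  koff_um <- p$k_off / 1000

  seg <- if (is.null(initial)) {
    data.frame(id = integer(), left = numeric(), right = numeric())
  } else {
    data.frame(id = seq_len(nrow(initial)), left = initial[, 1L],
               right = initial[, 2L])
  }
  next_id <- nrow(seg) + 1L

  events <- list()
  traj <- vector("list", n_frames)
  coverage <- numeric(n_frames)
  nseg <- integer(n_frames)
  cov_px <- matrix(0, n_frames, n_px)
  t_on <- rep(NA_real_, n_px)

  with_seed(p$seed, {
    for (i in seq_len(n_frames)) {
      t_now <- (i - 1) * dt
      if (i > 1L) {
        if (disassembly) {
          if (nrow(seg)) {
            seg$left <- seg$left + koff_um * dt
            seg$right <- seg$right - koff_um * dt
            # tolerance absorbs accumulated floating-point drift so a segment
            # shrunk to zero length vanishes on the exact frame
            seg <- seg[seg$right - seg$left > 1e-9, , drop = FALSE]
          }
        } else {
          if (nrow(seg)) {
            seg$left <- seg$left - vL * dt
            seg$right <- seg$right + vR * dt
          }
          seg <- merge_segments(seg, L)
          gaps <- gap_intervals(seg, L)
          l_unc <- sum(gaps$hi - gaps$lo)
          n_new <- stats::rpois(1L, p$k_nuc * l_unc * dt)
          if (n_new > 0L) {
            u <- stats::runif(n_new) * l_unc
            cum <- cumsum(gaps$hi - gaps$lo)
            gi <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
            gi <- pmin(pmax(gi, 1L), nrow(gaps))
            pos <- gaps$lo[gi] + (u - c(0, cum)[gi])
            tev <- t_now - dt + stats::runif(n_new) * dt
            events[[length(events) + 1L]] <-
              data.frame(time_s = tev, position_um = pos)
            h <- p$nucleus_nm / 2000
            seg <- rbind(seg, data.frame(id = next_id + seq_len(n_new) - 1L,
                                         left = pos - h, right = pos + h))
            next_id <- next_id + n_new
          }
        }
        seg <- merge_segments(seg, L)
      } else {
        seg <- merge_segments(seg, L)
      }
      coverage[i] <- if (nrow(seg)) sum(seg$right - seg$left) / L else 0
      nseg[i] <- nrow(seg)
      if (nrow(seg))
        traj[[i]] <- data.frame(frame = i, time_s = t_now, id = seg$id,
                                left_um = seg$left, right_um = seg$right)
      cv <- pixel_coverage(seg, n_px, px_um)
      newly <- is.na(t_on) & cv > 0
      t_on[newly] <- t_now
      cov_px[i, ] <- cv
    }

    surv <- matrix(1, n_frames, n_px)
    if (p$bleach_rate > 0) {
      tt <- (seq_len(n_frames) - 1) * dt
      for (j in seq_len(n_px)) {
        if (!is.na(t_on[j])) {
          on <- tt >= t_on[j]
          surv[on, j] <- exp(-p$bleach_rate * (tt[on] - t_on[j]))
        }
      }
    }
    mean_sig <- blur_rows(p$photon_rate * cov_px * surv, p$psf_sigma_px)
    render <- function(mu) {
      x <- if (p$shot_noise) {
        matrix(stats::rpois(length(mu), pmax(mu, 0)), nrow(mu), ncol(mu))
      } else mu
      if (p$read_noise_sd > 0)
        x <- x + matrix(stats::rnorm(length(mu), 0, p$read_noise_sd),
                        nrow(mu), ncol(mu))
      x
    }
    ch <- list(rad51 = render(mean_sig))
    if (rpa_channel) {
      mean_rpa <- blur_rows(p$photon_rate * (1 - cov_px), p$psf_sigma_px)
      ch$rpa <- render(mean_rpa)
    }
    list(
      kymo = kymograph(ch, frame_interval_s = dt,
                       pixel_size_nm = p$pixel_size_nm),
      truth = structure(list(
        nucleation_events = if (length(events)) do.call(rbind, events)
                            else data.frame(time_s = numeric(),
                                            position_um = numeric()),
        boundary_trajectories = if (any(!vapply(traj, is.null, logical(1))))
          do.call(rbind, traj[!vapply(traj, is.null, logical(1))])
          else data.frame(frame = integer(), time_s = numeric(),
                          id = integer(), left_um = numeric(),
                          right_um = numeric()),
        coverage_fraction = coverage,
        segments_per_frame = nseg,
        true_rates = list(k_nuc = p$k_nuc, v_grow = p$v_grow,
                          k_off = p$k_off),
        params = p), class = "sim_truth"))
  })
}

#' Simulate an assembly kymograph
#'
#' Forward-simulates RAD51 filament assembly on ssDNA under the
#' nucleation-extension model and renders it as a kymograph with a Gaussian
#' PSF, Poisson shot noise and Gaussian read noise. Optionally renders a
#' second, anti-correlated channel emulating RPA being displaced wherever
#' RAD51 covers the substrate.
#'
#' @param params a [sim_kymo_params()] object.
#' @param rpa_channel logical; add the complementary RPA channel.
#' @return a list with elements `kymo` ([kymograph]) and `truth`
#'   (`sim_truth`: nucleation events, per-frame boundary trajectories,
#'   coverage fraction, distinct-segment census, generating rates).
#' @examples
#' sim <- simulate_kymograph(sim_kymo_params(duration_s = 60, seed = 7))
#' sim$truth$coverage_fraction[1:5]
#' @export
simulate_kymograph <- function(params, rpa_channel = FALSE) {
  stopifnot(inherits(params, "sim_kymo_params"))
  run_kymo_process(params, initial = NULL, disassembly = FALSE,
                   rpa_channel = rpa_channel)
}

#' Simulate a disassembly kymograph
#'
#' Starts from pre-covered segments (filaments grown with ATP, then moved to
#' an ATP-free channel) and shrinks every segment bidirectionally at `k_off`
#' nm/s per end. No new nucleation occurs.
#'
#' @param params a [sim_kymo_params()] object; `k_nuc` is ignored (forced 0).
#' @param initial_coverage a list of `c(lo_um, hi_um)` intervals, or a
#'   two-column matrix; intervals must not overlap.
#' @return as [simulate_kymograph()].
#' @examples
#' p <- sim_kymo_params(duration_s = 120, frame_interval_s = 2, k_off = 10,
#'                      seed = 3)
#' sim <- simulate_disassembly_kymograph(p, list(c(9, 11)))
#' @export
simulate_disassembly_kymograph <- function(params, initial_coverage) {
  stopifnot(inherits(params, "sim_kymo_params"))
  iv <- if (is.matrix(initial_coverage)) initial_coverage
        else do.call(rbind, initial_coverage)
  if (is.null(iv) || ncol(iv) != 2L || !nrow(iv))
    stop_param("'initial_coverage' must give at least one (lo, hi) interval")
  if (any(iv[, 2L] <= iv[, 1L]))
    stop_param("initial intervals must have hi > lo")
  o <- order(iv[, 1L])
  iv <- iv[o, , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
    stop_param("initial coverage intervals overlap")
  p <- params
  p$k_nuc <- 0
  run_kymo_process(p, initial = iv, disassembly = TRUE, rpa_channel = FALSE)
}

#' Simulate a two-colour single-molecule FRET event trace
#'
#' Builds a donor/acceptor intensity trace with three phases: (1) FRET —
#' acceptor emits, donor is suppressed; (2) acceptor-labelled partner
#' dissociates — donor recovers, acceptor falls to bleed-through; (3) donor
#' dissociates — both at background.
#'
#' @param phase_durations numeric length 3: durations (s) of the fret,
#'   donor-only and dark phases; zeros allowed.
#' @param donor_level donor emission in the donor-only phase (counts).
#' @param acceptor_fret_level acceptor emission during FRET (counts).
#' @param bleedthrough_level acceptor signal from donor bleed-through in the
#'   donor-only phase (counts).
#' @param donor_fret_fraction fraction of `donor_level` remaining during FRET
#'   (donor quenched by energy transfer).
#' @param background level of both channels in the dark phase.
#' @param noise_sd Gaussian noise on both channels.
#' @param sample_interval_s trace sampling interval, seconds.
#' @param seed RNG seed.
#' @return an `event_trace`: list with `time_s`, `donor`, `acceptor`, and
#'   `truth` (phase boundary times in seconds).
#' @export
simulate_fret_trace <- function(phase_durations, donor_level = 100,
                                acceptor_fret_level = 80,
                                bleedthrough_level = 8,
                                donor_fret_fraction = 0.3, background = 0,
                                noise_sd = 2, sample_interval_s = 0.1,
                                seed = 1L) {
  if (length(phase_durations) != 3L || any(!is.finite(phase_durations)) ||
      any(phase_durations < 0))
    stop_param("'phase_durations' must be 3 non-negative durations")
  check_scalar(sample_interval_s, "sample_interval_s", 0, strict_min = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  n <- pmax(0L, round(phase_durations / sample_interval_s))
  don <- c(rep(donor_level * donor_fret_fraction, n[1L]),
           rep(donor_level, n[2L]), rep(background, n[3L]))
  acc <- c(rep(acceptor_fret_level, n[1L]),
           rep(bleedthrough_level, n[2L]), rep(background, n[3L]))
  ntot <- length(don)
  if (!ntot) stop_param("all phases have zero duration")
  with_seed(seed, {
    don <- don + stats::rnorm(ntot, 0, noise_sd)
    acc <- acc + stats::rnorm(ntot, 0, noise_sd)
  })
  structure(list(time_s = (seq_len(ntot) - 0.5) * sample_interval_s,
                 donor = don, acceptor = acc,
                 truth = list(boundaries_s = cumsum(phase_durations)[1:2],
                              n_samples = n)),
            class = "event_trace")
}

#' Simulate a kymograph with planted transient binding events
#'
#' Plants short-lived fluorescent binding events (e.g. transient BCDX2 visits
#' to ssDNA) at known times and positions over a dark background, for
#' validating event detection. Ground truth is the planted event table.
#'
#' @param events data.frame with columns `start_s`, `end_s`, `position_um`.
#' @param params a [sim_kymo_params()] object (camera fields are used;
#'   kinetic fields are ignored).
#' @return list of `kymo` and `truth` (the event table).
#' @export
simulate_binding_kymograph <- function(events, params) {
  stopifnot(inherits(params, "sim_kymo_params"), is.data.frame(events))
  need <- c("start_s", "end_s", "position_um")
  if (!all(need %in% names(events)))
    stop_param("'events' needs columns start_s, end_s, position_um")
  if (any(events$end_s < events$start_s))
    stop_param("event end_s must be >= start_s")
  p <- params
  dt <- p$frame_interval_s
  n_frames <- max(2L, round(p$duration_s / dt) + 1L)
  n_px <- max(1L, round(p$length_um * 1000 / p$pixel_size_nm))
  mu <- matrix(0, n_frames, n_px)
  tt <- (seq_len(n_frames) - 1) * dt
  for (i in seq_len(nrow(events))) {
    rows <- which(tt >= events$start_s[i] & tt <= events$end_s[i])
    j <- max(1L, min(n_px,
                     floor(events$position_um[i] * 1000 / p$pixel_size_nm) + 1L))
    mu[rows, j] <- mu[rows, j] + p$photon_rate
  }
  mu <- blur_rows(mu, p$psf_sigma_px)
  with_seed(p$seed, {
    x <- if (p$shot_noise)
      matrix(stats::rpois(length(mu), pmax(mu, 0)), n_frames, n_px) else mu
    if (p$read_noise_sd > 0)
      x <- x + matrix(stats::rnorm(length(mu), 0, p$read_noise_sd),
                      n_frames, n_px)
    list(kymo = kymograph(list(bcdx2 = x), frame_interval_s = dt,
                          pixel_size_nm = p$pixel_size_nm),
         truth = structure(list(events = events, params = p),
                           class = "sim_truth"))
  })
}

#' Deterministic force proxy from filament coverage
#'
#' Emits a force-versus-time trace as a monotone decreasing function of
#' filament coverage: RAD51 binding lengthens and stiffens ssDNA, so the
#' force between the traps falls as filaments assemble. This is a proxy, not
#' a polymer-mechanics model.
#'
#' @param coverage_fraction per-frame coverage in `[0, 1]`.
#' @param frame_interval_s frame interval of the coverage series, seconds.
#' @param f_high force at zero coverage, pN.
#' @param f_low force at full coverage, pN.
#' @param sample_rate_hz output sampling rate (linear interpolation).
#' @param noise_sd Gaussian noise, pN.
#' @param seed RNG seed.
#' @return a `force_trace`: data.frame `time_s`, `force_pN`, with attribute
#'   `sample_rate_hz`.
#' @export
simulate_force_trace <- function(coverage_fraction, frame_interval_s,
                                 f_high = 55, f_low = 25,
                                 sample_rate_hz = 30, noise_sd = 0,
                                 seed = 1L) {
  stopifnot(all(coverage_fraction >= 0), all(coverage_fraction <= 1))
  check_scalar(sample_rate_hz, "sample_rate_hz", 0, strict_min = TRUE)
  t_frames <- (seq_along(coverage_fraction) - 1) * frame_interval_s
  tmax <- max(t_frames)
  tt <- seq(0, tmax, by = 1 / sample_rate_hz)
  f <- f_high - (f_high - f_low) *
    stats::approx(t_frames, coverage_fraction, xout = tt)$y
  if (noise_sd > 0)
    f <- with_seed(seed, f + stats::rnorm(length(f), 0, noise_sd))
  structure(data.frame(time_s = tt, force_pN = f),
            sample_rate_hz = sample_rate_hz,
            class = c("force_trace", "data.frame"))
}
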