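test_that("normalized assembly signal is 1 for a uniform image and tracks coverage", {
  k <- kymograph(list(g = matrix(7, 10, 40)), frame_interval_s = 1)
  s <- normalize_assembly_signal(k, "g", background_region = c(1, 5))
  expect_equal(s$normalized, rep(1, 10))
  expect_error(normalize_assembly_signal(k, "g", integer()), "background")
  k0 <- kymograph(list(g = matrix(0, 4, 10)), frame_interval_s = 1)
  expect_error(normalize_assembly_signal(k0, "g", c(1, 3)), "zero")

  # noise-free assembly + constant offset: series is affine in coverage
  p <- sim_kymo_params(duration_s = 120, shot_noise = FALSE,
                       read_noise_sd = 0, seed = 6)
  sim <- simulate_kymograph(p)
  koff <- kymograph(list(rad51 = sim$kymo$channels$rad51 + 10),
                    frame_interval_s = p$frame_interval_s,
                    pixel_size_nm = p$pixel_size_nm)
  s <- normalize_assembly_signal(koff, "rad51", background_region = c(1, 5))
  expect_gt(cor(s$normalized, sim$truth$coverage_fraction), 0.99)
})

test_that("an all-zero kymograph yields zero peaks and a non-converged rate", {
  k <- kymograph(list(g = matrix(0, 12, 50)), frame_interval_s = 1)
  est <- estimate_nucleation_rate(k, "g")
  expect_true(all(est$peak_counts == 0))
  expect_identical(est$apparent_rate, 0)
  expect_false(est$fit$converged)
  expect_error(estimate_nucleation_rate(
    kymograph(list(g = matrix(0, 3, 4)), 1), "g"), "window")
})

test_that("noise-free well-separated segments are counted exactly", {
  sim <- static_segments_kymo(list(c(2, 3), c(8, 9.5), c(15, 16)))
  est <- estimate_nucleation_rate(sim$kymo, "rad51")
  expect_true(all(est$peak_counts == 3))
})

test_that("peak counting is invariant to circular position shifts (noise-free)", {
  sim <- static_segments_kymo(list(c(4, 5), c(10, 11), c(16, 17)))
  m <- sim$kymo$channels$rad51
  base <- estimate_nucleation_rate(sim$kymo, "rad51")$peak_counts
  for (shift in c(7, 23)) {
    ms <- m[, c((shift + 1):ncol(m), 1:shift)]
    ks <- kymograph(list(rad51 = ms),
                    frame_interval_s = sim$kymo$frame_interval_s,
                    pixel_size_nm = sim$kymo$pixel_size_nm)
    expect_identical(estimate_nucleation_rate(ks, "rad51")$peak_counts, base)
  }
})

test_that("a boundary advancing 2 px per frame measures 40 nm/s", {
  n_frames <- 20; n_px <- 120
  m <- matrix(0, n_frames, n_px)
  for (f in seq_len(n_frames)) m[f, 10:(20 + 2 * (f - 1))] <- 100
  k <- kymograph(list(g = m), frame_interval_s = 5, pixel_size_nm = 100)
  er <- measure_edge_rate(k, "g", segment_seed = c(1, 15), side = "right")
  expect_equal(er$rate_nm_per_s, 2 * 100 / 5, tolerance = 1e-9)
  expect_gt(er$r_squared, 0.999)
})

test_that("a static segment has zero rate and zero R^2", {
  m <- matrix(0, 15, 80); m[, 30:40] <- 50
  k <- kymograph(list(g = m), frame_interval_s = 2, pixel_size_nm = 100)
  er <- measure_edge_rate(k, "g", segment_seed = c(1, 35))
  expect_equal(er$rate_nm_per_s, 0, tolerance = 1e-9)
  expect_identical(er$r_squared, 0)
})

test_that("disassembly rate recovery matches the generating k_off within 15%", {
  rates <- vapply(1:8, function(s) {
    p <- sim_kymo_params(length_um = 10, duration_s = 150,
                         frame_interval_s = 5, k_off = 10,
                         psf_sigma_px = 0.8, photon_rate = 200,
                         read_noise_sd = 2, seed = s)
    sim <- simulate_disassembly_kymograph(p, list(c(3, 7)))
    abs(measure_edge_rate(sim$kymo, segment_seed = c(1, 50),
                          side = "right")$rate_nm_per_s)
  }, numeric(1))
  expect_lt(abs(median(rates) - 10) / 10, 0.15)
})

test_that("planted transient binding events are detected with correct frequency", {
  p <- sim_kymo_params(length_um = 10, duration_s = 100,
                       frame_interval_s = 2, shot_noise = FALSE,
                       read_noise_sd = 0, seed = 1)
  ev_true <- data.frame(start_s = c(4, 10, 14, 20, 26, 60),
                        end_s = c(8, 16, 18, 24, 30, 70),
                        position_um = c(1, 3, 5, 7, 9, 4))
  sim <- simulate_binding_kymograph(ev_true, p)
  det <- detect_binding_events(sim$kymo, "bcdx2", intensity_sigmas = 5,
                               min_duration_frames = 2, window_s = 30)
  expect_equal(nrow(det$events), 6)
  # five of the six events start within the first 30 s window
  expect_equal(det$frequency$count[1], 5L)
  # durations match planted durations within one frame interval
  dt <- sim$kymo$frame_interval_s
  det_sorted <- det$events[order(det$events$start_s), ]
  dur_det <- det_sorted$end_s - det_sorted$start_s
  dur_true <- ev_true$end_s - ev_true$start_s
  expect_true(all(abs(dur_det - dur_true) <= dt + 1e-9))
})

test_that("a blank kymograph has no binding events", {
  k <- kymograph(list(g = matrix(0, 20, 50)), frame_interval_s = 1)
  det <- detect_binding_events(k, "g")
  expect_equal(nrow(det$events), 0)
  expect_true(all(det$frequency$count == 0))
})

test_that("fret phases are recovered at the generated boundaries", {
  tr <- simulate_fret_trace(c(5, 5, 5), noise_sd = 0.5, seed = 3)
  ev <- analyze_fret_event(tr, bleedthrough_level = 8)
  expect_identical(ev$phases$label, c("fret", "donor_only", "dark"))
  dt <- tr$time_s[2] - tr$time_s[1]
  expect_lt(abs(ev$phases$end_s[1] - 5), dt + 1e-9)
  expect_lt(abs(ev$phases$end_s[2] - 10), dt + 1e-9)
  expect_lt(ev$anticorrelation, 0)

  donly <- simulate_fret_trace(c(0, 10, 0), noise_sd = 0.5, seed = 4)
  ev2 <- analyze_fret_event(donly, bleedthrough_level = 8)
  expect_false("fret" %in% ev2$phases$label)
  expect_true("donor_only" %in% ev2$phases$label)

  bad <- tr; bad$donor <- bad$donor[-1]
  expect_error(analyze_fret_event(bad, 8), "unequal")
})

test_that("force downsampling produces exact block means", {
  # constant force stays constant
  ft <- structure(data.frame(time_s = (0:299) / 30, force_pN = rep(10, 300)),
                  sample_rate_hz = 30,
                  class = c("force_trace", "data.frame"))
  d <- downsample_force(ft, 3)
  expect_true(all(abs(d$force_pN - 10) < 1e-12))
  expect_equal(nrow(d), floor(300 / 30 * 3))

  # alternating 9/11 at 30 Hz averages to 10 in every 3 Hz block
  ft2 <- structure(data.frame(time_s = (0:299) / 30,
                              force_pN = rep(c(9, 11), 150)),
                   sample_rate_hz = 30,
                   class = c("force_trace", "data.frame"))
  d2 <- downsample_force(ft2, 3)
  expect_true(all(abs(d2$force_pN - 10) < 1e-12))

  # block means preserve the overall mean for exact partitions
  set.seed(8)
  ft3 <- structure(data.frame(time_s = (0:599) / 30,
                              force_pN = rnorm(600, 40, 5)),
                   sample_rate_hz = 30,
                   class = c("force_trace", "data.frame"))
  d3 <- downsample_force(ft3, 3)
  expect_lt(abs(mean(d3$force_pN) - mean(ft3$force_pN)), 1e-6 * 40)
  expect_error(downsample_force(ft3, 100), "below")
})
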