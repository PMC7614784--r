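test_that("identical parameters and seed give bit-identical output", {
  p <- sim_kymo_params(duration_s = 40, seed = 42)
  a <- simulate_kymograph(p, rpa_channel = TRUE)
  b <- simulate_kymograph(p, rpa_channel = TRUE)
  expect_identical(a$kymo$channels, b$kymo$channels)
  expect_identical(a$truth$nucleation_events, b$truth$nucleation_events)

  d1 <- simulate_disassembly_kymograph(
    sim_kymo_params(duration_s = 40, k_off = 5, seed = 9),
    list(c(2, 4), c(8, 10)))
  d2 <- simulate_disassembly_kymograph(
    sim_kymo_params(duration_s = 40, k_off = 5, seed = 9),
    list(c(2, 4), c(8, 10)))
  expect_identical(d1$kymo$channels, d2$kymo$channels)
  expect_identical(d1$truth$boundary_trajectories,
                   d2$truth$boundary_trajectories)

  f1 <- simulate_fret_trace(c(3, 3, 3), seed = 5)
  f2 <- simulate_fret_trace(c(3, 3, 3), seed = 5)
  expect_identical(f1$donor, f2$donor)
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_kymograph(sim_kymo_params(duration_s = 10, seed = 1)))
  expect_identical(runif(1), before)
})

test_that("no nucleation means zero coverage and noise-only raster", {
  p <- sim_kymo_params(k_nuc = 0, duration_s = 60, seed = 3)
  sim <- simulate_kymograph(p)
  expect_true(all(sim$truth$coverage_fraction == 0))
  expect_equal(nrow(sim$truth$nucleation_events), 0)
  # raster is pure camera noise around zero
  expect_lt(abs(mean(sim$kymo$channels$rad51)), 1)
})

test_that("nucleation counts follow the analytic Poisson mean and dispersion", {
  # lambda = k_nuc * L * t = 0.01 * 20 * 10 = 2.0 with point-like nuclei
  counts <- vapply(1:500, function(s) {
    p <- sim_kymo_params(length_um = 20, duration_s = 10,
                         frame_interval_s = 2, k_nuc = 0.01, v_grow = 0,
                         nucleus_nm = 1, photon_rate = 0,
                         read_noise_sd = 0, seed = s)
    sum(simulate_kymograph(p)$truth$nucleation_events$time_s <= 10)
  }, numeric(1))
  lambda <- 2.0
  se <- sqrt(lambda / 500)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.2)
})

test_that("coverage is non-decreasing while disassembly is off", {
  for (s in 1:5) {
    sim <- simulate_kymograph(sim_kymo_params(duration_s = 120, seed = s))
    expect_true(all(diff(sim$truth$coverage_fraction) >= -1e-12))
  }
})

test_that("disassembly shrinks segments at k_off per end and conserves none", {
  # 2 um segment, k_off = 10 nm/s per end -> gone at t = 1000 nm / 10 nm/s
  p <- sim_kymo_params(length_um = 10, duration_s = 120,
                       frame_interval_s = 1, k_off = 10, seed = 2)
  sim <- simulate_disassembly_kymograph(p, list(c(4, 6)))
  cov <- sim$truth$coverage_fraction
  tt <- (seq_along(cov) - 1) * 1
  expect_true(all(cov[tt < 100] > 0))
  expect_true(all(cov[tt >= 100] == 0))
  # k_off = 0 keeps coverage constant
  p0 <- sim_kymo_params(length_um = 10, duration_s = 60, k_off = 0, seed = 2)
  sim0 <- simulate_disassembly_kymograph(p0, list(c(4, 6)))
  expect_true(all(abs(sim0$truth$coverage_fraction - 0.2) < 1e-12))
})

test_that("overlapping initial intervals are rejected", {
  p <- sim_kymo_params(k_off = 5)
  expect_error(simulate_disassembly_kymograph(p, list(c(1, 3), c(2, 4))),
               "overlap")
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_kymo_params(k_nuc = -1), "k_nuc")
  expect_error(sim_kymo_params(frame_interval_s = 0), "frame_interval_s")
  expect_error(sim_kymo_params(photon_rate = NaN), "photon_rate")
  expect_error(sim_kymo_params(polarity = 1.5), "polarity")
})

test_that("fret trace phases are built as specified", {
  # noise-free (5, 5, 5): boundaries exactly at 5 and 10 s
  tr <- simulate_fret_trace(c(5, 5, 5), noise_sd = 0, seed = 1)
  expect_equal(tr$truth$boundaries_s, c(5, 10))
  n <- tr$truth$n_samples
  expect_equal(n, c(50L, 50L, 50L))
  # anti-correlation at the 1 -> 2 transition: acceptor steps down, donor up
  expect_gt(tr$donor[n[1] + 1] - tr$donor[n[1]], 0)
  expect_lt(tr$acceptor[n[1] + 1] - tr$acceptor[n[1]], 0)
  # donor-only trace: acceptor never exceeds bleed-through
  d <- simulate_fret_trace(c(0, 8, 0), noise_sd = 0, bleedthrough_level = 8)
  expect_true(all(d$acceptor == 8))
  expect_true(all(d$donor == 100))
  expect_error(simulate_fret_trace(c(-1, 5, 5)), "non-negative")
})

test_that("force proxy is monotone in coverage and reproducible", {
  cov <- seq(0, 1, length.out = 61)
  ft <- simulate_force_trace(cov, frame_interval_s = 1, noise_sd = 0)
  expect_true(all(diff(ft$force_pN) <= 1e-12))
  expect_equal(ft$force_pN[1], 55)
  expect_equal(ft$force_pN[nrow(ft)], 25)
})
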