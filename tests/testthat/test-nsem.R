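test_that("difference of Gaussians annihilates constants and is linear", {
  const <- matrix(5, 64, 64)
  expect_lt(max(abs(dog_filter(const, 2, 6))), 1e-10)

  set.seed(2)
  a <- matrix(rnorm(64 * 64), 64, 64)
  b <- matrix(rnorm(64 * 64), 64, 64)
  expect_lt(max(abs(dog_filter(a + b, 2, 6) -
                    (dog_filter(a, 2, 6) + dog_filter(b, 2, 6)))), 1e-10)
  expect_error(dog_filter(a, 6, 2), "smaller")
})

test_that("impulse response equals the analytic difference of kernels", {
  n <- 81
  img <- matrix(0, n, n); img[41, 41] <- 1
  out <- dog_filter(img, 1.5, 4)
  kern <- function(sigma) {
    r <- max(1L, ceiling(3.5 * sigma))
    k <- dnorm(-r:r, sd = sigma); k / sum(k)
  }
  k1 <- kern(1.5); k2 <- kern(4)
  pad <- function(k, half) {
    out <- numeric(2 * half + 1)
    r <- (length(k) - 1) / 2
    out[(half - r + 1):(half + r + 1)] <- k
    out
  }
  half <- 20
  expected <- outer(pad(k1, half), pad(k1, half)) -
              outer(pad(k2, half), pad(k2, half))
  expect_equal(out[(41 - half):(41 + half), (41 - half):(41 + half)],
               expected, tolerance = 1e-12)
})

test_that("a blank image yields zero filaments", {
  blank <- micrograph(matrix(0, 64, 64), 5.85)
  expect_length(trace_filaments(blank), 0)
})

test_that("a straight 200 px filament measures 117 nm within 5%", {
  p <- sim_micrograph_params(image_size_px = c(64, 256), pixel_size_A = 5.85,
                             persistence_px = 1e9, noise_sd = 0.02,
                             background_particles_per_um2 = 0, seed = 3)
  sim <- simulate_micrograph(
    p, filaments = data.frame(row = 32, col = 25, theta = 0,
                              length_px = 200))
  tr <- trace_filaments(dog_filter(sim$image))
  expect_length(tr, 1)
  expect_lt(abs(filament_lengths(tr) - 117) / 117, 0.05)
})

test_that("measured length is rotation-robust (0, 45, 90 degrees)", {
  lens <- vapply(c(0, pi / 4, pi / 2), function(th) {
    p <- sim_micrograph_params(image_size_px = c(256, 256),
                               pixel_size_A = 5.85, persistence_px = 1e9,
                               noise_sd = 0.01,
                               background_particles_per_um2 = 0, seed = 5)
    sim <- simulate_micrograph(
      p, filaments = data.frame(row = 60, col = 60, theta = th,
                                length_px = 150))
    lt <- filament_lengths(trace_filaments(dog_filter(sim$image)))
    expect_length(lt, 1)
    lt
  }, numeric(1))
  expect_lt((max(lens) - min(lens)) / min(lens), 0.05)
})

test_that("raising the threshold never increases the filament count", {
  p <- sim_micrograph_params(image_size_px = c(256, 256), n_filaments = 8,
                             noise_sd = 0.06, seed = 9)
  filt <- dog_filter(simulate_micrograph(p)$image)
  counts <- vapply(c(2, 3, 4, 5), function(th)
    length(trace_filaments(filt, threshold_sigmas = th)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("tracer recall and length accuracy hold on gridded synthetic filaments", {
  # 16 filaments in a 4x4 grid of 160 px cells, random orientation, moderate
  # noise; every filament should be found within 10% of its true length
  cell <- 160; ngrid <- 4
  centres <- expand.grid(r = cell * (seq_len(ngrid) - 0.5),
                         c = cell * (seq_len(ngrid) - 0.5))
  found <- 0L; err_ok <- 0L; n_tot <- 0L
  for (s in 1:2) {
    set.seed(100 + s)
    fil <- data.frame(row = centres$r, col = centres$c,
                      theta = runif(nrow(centres), 0, 2 * pi),
                      length_px = runif(nrow(centres), 70, 120))
    p <- sim_micrograph_params(image_size_px = c(cell * ngrid, cell * ngrid),
                               pixel_size_A = 5.85, persistence_px = 2000,
                               noise_sd = 0.08, filament_amplitude = 1,
                               background_particles_per_um2 = 20, seed = s)
    sim <- simulate_micrograph(p, filaments = fil)
    tr <- trace_filaments(dog_filter(sim$image))
    mids <- t(vapply(tr, function(x) colMeans(x$path), numeric(2)))
    lens <- filament_lengths(tr)
    for (i in seq_len(nrow(fil))) {
      n_tot <- n_tot + 1L
      near <- which(abs(mids[, 1] - fil$row[i]) < cell / 2 &
                    abs(mids[, 2] - fil$col[i]) < cell / 2)
      if (!length(near)) next
      found <- found + 1L
      best <- near[which.max(lens[near])]
      truth_nm <- sim$truth$lengths_nm[i]
      if (abs(lens[best] - truth_nm) / truth_nm <= 0.10)
        err_ok <- err_ok + 1L
    }
  }
  expect_gte(found / n_tot, 0.9)
  expect_gte(err_ok / found, 0.9)
})

test_that("Mann-Whitney exact enumeration matches theory and wilcox.test", {
  # {1,2} vs {3,4}: U = 0, exact two-sided p = 2/6
  r <- mann_whitney_test(c(1, 2), c(3, 4))
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_match(r$method, "exact")

  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    mine <- mann_whitney_test(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  # normal approximation agrees with wilcox.test at moderate n
  x <- rnorm(30); y <- rnorm(30, 0.5)
  mine <- mann_whitney_test(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("condition comparison reports the prescribed statistics", {
  # identical per-micrograph counts: t = 0, p = 1
  st <- compare_conditions(list(c(1, 2), c(3, 4, 5)),
                           list(c(6, 7), c(8, 9, 10)))
  expect_equal(st$count_test$t, 0)
  expect_equal(st$count_test$p_value, 1)
  expect_equal(st$length_test$u, 0)

  # 2x length difference, n = 200 per arm: decisive Mann-Whitney
  set.seed(3)
  rej <- mean(vapply(1:100, function(i) {
    a <- rlnorm(200, log(60), 0.35)
    b <- rlnorm(200, log(120), 0.35)
    mann_whitney_test(a, b)$p_value < 0.001
  }, logical(1)))
  expect_gte(rej, 0.95)

  expect_warning(compare_conditions(list(c(1, 2, 3)), list(c(2, 3), c(4))),
                 "t-test disabled")
})

test_that("overlay masks round-trip to identical lengths", {
  p <- sim_micrograph_params(image_size_px = c(256, 256), n_filaments = 4,
                             noise_sd = 0.02, seed = 12)
  sim <- simulate_micrograph(p)
  tr <- trace_filaments(dog_filter(sim$image))
  expect_gt(length(tr), 0)
  path <- file.path(tempdir(), "overlay.png")
  mask <- write_overlay(sim$image, tr, path)
  expect_equal(sum(mask), sum(vapply(tr, `[[`, integer(1), "n_points")))
  reread <- png::readPNG(path) > 0.5
  tr2 <- traces_from_mask(reread, sim$image$pixel_size_A, min_length_px = 2,
                          path_smooth_px = 7)  # same metric as the tracer
  expect_equal(sort(filament_lengths(tr2)), sort(filament_lengths(tr)),
               tolerance = 1e-9)
})
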