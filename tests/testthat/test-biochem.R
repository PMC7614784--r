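test_that("quadratic isotherm matches its closed-form anchors", {
  expect_equal(quadratic_binding_model(0, L = 0.05, kd = 0.5,
                                       a_min = 0.04, a_max = 0.2), 0.04)
  # stoichiometric limit: kd = 0, x = L saturates the probe
  expect_equal(quadratic_binding_model(0.05, L = 0.05, kd = 0,
                                       a_min = 0, a_max = 1), 1)
  # independent numeric solve of the 1:1 mass balance
  y <- quadratic_binding_model(0.16, L = 0.05, kd = 0.16,
                               a_min = 0, a_max = 1)
  expect_equal(y, 0.4612, tolerance = 5e-4)
  expect_equal(y, bound_fraction_numeric(0.16, 0.05, 0.16),
               tolerance = 1e-9)
  # continuity / monotonicity in x
  x <- seq(0, 5, by = 0.01)
  yy <- quadratic_binding_model(x, 0.05, 0.3, 0.05, 0.25)
  expect_true(all(diff(yy) >= -1e-12))
  expect_true(all(yy >= 0.05 - 1e-12 & yy <= 0.25 + 1e-12))
})

test_that("quadratic isotherm converges to the hyperbola when L << K_D", {
  kd <- 1; L <- kd / 100
  x <- 10^seq(-2, 1, length.out = 30)
  quad <- quadratic_binding_model(x, L, kd, 0, 1)
  hyper <- x / (x + kd)
  expect_lt(max(abs(quad - hyper) / hyper), 0.01)
})

test_that("noise-free isotherm fit recovers the generating constant exactly", {
  tt <- simulate_titration(0.5, noise_sd = 0, seed = 1)
  f <- fit_binding_isotherm(tt)
  expect_true(f$converged)
  expect_lt(abs(f$kd - 0.5) / 0.5, 1e-6)
  expect_lt(abs(f$a_min - 0.05), 1e-6)
  expect_lt(abs(f$a_max - 0.20), 1e-6)
})

test_that("isotherm fit beats the grid-search oracle and flags flat data", {
  tt <- simulate_titration(0.3, noise_sd = 0.005, seed = 7)
  f <- fit_binding_isotherm(tt)
  expect_lte(f$residual_sse,
             grid_sse_isotherm(tt$data$protein_uM, tt$data$anisotropy,
                               0.05) + 1e-12)
  flat <- data.frame(protein_uM = 10^seq(-3, 1, length.out = 10),
                     anisotropy = rep(0.05, 10))
  expect_false(fit_binding_isotherm(flat, probe_conc = 0.05)$converged)
})

test_that("95% CI coverage of the fitted K_D is calibrated", {
  hits <- vapply(1:200, function(s) {
    f <- fit_binding_isotherm(simulate_titration(0.16, seed = s))
    f$converged && f$ci95_kd[1] <= 0.16 && 0.16 <= f$ci95_kd[2]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("fret emission ratio uses nearest-grid lookup and guards zero donor", {
  sp <- data.frame(wavelength_nm = 550:800, intensity = 1)
  sp$intensity[sp$wavelength_nm == 555] <- 100
  sp$intensity[sp$wavelength_nm == 647] <- 30
  expect_equal(fret_emission_ratio(sp), 0.30)
  # doubled acceptor emission doubles the ratio
  s1 <- simulate_emission_spectrum(acceptor_intensity = 30, baseline = 0)
  s2 <- simulate_emission_spectrum(acceptor_intensity = 60, baseline = 0)
  expect_equal(fret_emission_ratio(s2) / fret_emission_ratio(s1), 2,
               tolerance = 1e-4)
  sp0 <- data.frame(wavelength_nm = 550:800, intensity = 0)
  expect_error(fret_emission_ratio(sp0), "zero")
  expect_error(fret_emission_ratio(sp, donor_nm = 500), "outside")
})

test_that("Beer-Lambert concentration with nucleotide-adjusted extinction", {
  expect_equal(protein_concentration(0, 4), 0)
  expect_equal(protein_concentration(0.08978, n_nt = 4), 1.000,
               tolerance = 1e-3)
  expect_gt(protein_concentration(0.1, 3), protein_concentration(0.1, 4))
})

test_that("peak integration matches the Gaussian area and standards", {
  # flat trace integrates to zero
  flat <- data.frame(time_min = seq(0, 12, 0.005), absorbance = 0.02)
  pk <- integrate_nucleotide_peaks(
    flat, list(ATP = c(6, 7)), list(ATP = cbind(c(1, 2), c(1, 2))))
  expect_equal(pk$area, 0)
  # amplitude-1, sigma 0.1 Gaussian has area sigma * sqrt(2 pi) = 0.2507
  tg <- seq(0, 12, by = 0.002)
  g <- data.frame(time_min = tg,
                  absorbance = exp(-(tg - 6.5)^2 / (2 * 0.1^2)))
  pk2 <- integrate_nucleotide_peaks(
    g, list(ATP = c(6, 7)), list(ATP = cbind(c(1, 2), c(1, 2))))
  expect_equal(pk2$area, 0.1 * sqrt(2 * pi), tolerance = 1e-3)
  expect_error(integrate_nucleotide_peaks(
    g, list(ATP = c(11, 13)), list(ATP = cbind(c(1, 2), c(1, 2)))),
    "outside")
  expect_error(integrate_nucleotide_peaks(
    g, list(ATP = c(6, 7), ADP = c(6.5, 8)),
    list(ATP = cbind(c(1, 2), c(1, 2)), ADP = cbind(c(1, 2), c(1, 2)))),
    "disjoint")
})

test_that("stoichiometry pipeline inverts the chromatogram generator", {
  wins <- list(ATP = c(6, 7), ADP = c(4, 5))
  run_std <- function(conc) {
    s <- simulate_chromatogram(c(ATP = conc, ADP = conc))
    dummy <- list(ATP = cbind(c(1, 2), c(1, 2)),
                  ADP = cbind(c(1, 2), c(1, 2)))
    integrate_nucleotide_peaks(s, wins, dummy)$area
  }
  a1 <- run_std(1); a5 <- run_std(5)
  stds <- list(ATP = cbind(c(a1[1], a5[1]), c(1, 5)),
               ADP = cbind(c(a1[2], a5[2]), c(1, 5)))

  wt <- simulate_chromatogram(c(ATP = 2.1, ADP = 1.9))
  res <- nucleotide_stoichiometry(
    integrate_nucleotide_peaks(wt, wins, stds), protein_conc = 1.0)
  expect_equal(unname(res$nt_per_complex["ATP"]), 2.1, tolerance = 1e-3)
  expect_equal(unname(res$nt_per_complex["ADP"]), 1.9, tolerance = 1e-3)
  expect_equal(res$total_nt, 4.0, tolerance = 1e-3)

  mut <- simulate_chromatogram(c(ATP = 1.8, ADP = 1.2))
  res_m <- nucleotide_stoichiometry(
    integrate_nucleotide_peaks(mut, wins, stds), protein_conc = 1.0)
  expect_equal(res_m$total_nt, 3.0, tolerance = 1e-3)
})

test_that("overlapping chromatogram peaks raise a warning flag", {
  expect_warning(
    simulate_chromatogram(c(ATP = 1, ADP = 1),
                          retention_centers = c(ATP = 5, ADP = 5.2),
                          peak_sigma = 0.1),
    "overlap")
})

test_that("TLC conservation and ATPase arithmetic", {
  tl <- simulate_tlc(c(0, 0.5, 0.8), total_signal = 1000, noise_sd = 0)
  expect_true(all(abs(tl$adp + tl$atp - 1000) < 1e-9))
  res <- atpase_hydrolysis(tl)
  expect_equal(res$percent_hydrolysis, c(0, 50, 80))
  # rate: percent/100 * 15 uM / (30 min * 1 uM)
  expect_equal(res$rate_uM_per_min_per_uM[2], 0.5 * 15 / 30)
  # invariance to common rescaling of both spots
  tl2 <- tl; tl2$adp <- tl2$adp * 7; tl2$atp <- tl2$atp * 7
  expect_equal(atpase_hydrolysis(tl2)$percent_hydrolysis,
               res$percent_hydrolysis)
  expect_error(atpase_hydrolysis(data.frame(adp = 0, atp = 0)), "zero")
  expect_error(simulate_tlc(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("group comparison matches hand-computed Welch and exact MW", {
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  # Welch by hand: t = (2 - 4) / sqrt(1/3 + 4/3), df = (5/3)^2 /
  #   ((1/3)^2/2 + (4/3)^2/2)
  t_hand <- -2 / sqrt(5 / 3)
  df_hand <- (5 / 3)^2 / ((1 / 3)^2 / 2 + (4 / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  r <- compare_groups(a, b, test = "t")
  expect_equal(r$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r$p_value, p_hand, tolerance = 1e-12)

  r2 <- compare_groups(c(1, 2), c(3, 4), test = "mannwhitney")
  expect_equal(r2$p_value, 1 / 3, tolerance = 1e-12)

  same <- compare_groups(c(1, 2, 3), c(1, 2, 3), test = "t")
  expect_equal(same$p_value, 1)

  auto <- compare_groups(rnorm(10), rnorm(10), test = "auto")
  expect_named(auto$normality_p, c("a", "b"))
  expect_equal(auto$test_used, "welch_t")
  expect_warning(compare_groups(c(1, 1), c(2, 2)), "Mann-Whitney")
})
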