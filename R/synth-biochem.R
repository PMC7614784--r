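## Forward simulators for the biochemical assays: fluorescence-anisotropy
## titrations, HPLC nucleotide chromatograms and TLC ATPase spot pairs.

#' Simulate a fluorescence-anisotropy titration
#'
#' Forward-simulates anisotropy as a function of protein concentration from
#' the tight-binding quadratic isotherm (see [quadratic_binding_model()]),
#' with additive Gaussian noise.
#'
#' @param true_kd generating dissociation constant, uM.
#' @param a_min,a_max anisotropy of free and fully bound probe.
#' @param probe_conc labelled-oligonucleotide concentration, uM (default
#'   0.05, i.e. 50 nM probe).
#' @param protein_concs protein concentrations, uM. Default: 14 half-log
#'   points spanning 0.001-10 uM.
#' @param noise_sd Gaussian anisotropy noise (default 0.005).
#' @param condition free-text nucleotide-condition label (e.g. "ATP").
#' @param seed RNG seed.
#' @return a `binding_titration`: list with `data` (data.frame `protein_uM`,
#'   `anisotropy`), `probe_uM`, `condition`, and `truth` carrying `true_kd`.
#' @examples
#' tt <- simulate_titration(0.16, seed = 1)
#' head(tt$data)
#' @export
simulate_titration <- function(true_kd, a_min = 0.05, a_max = 0.20,
                               probe_conc = 0.05,
                               protein_concs = 10^seq(-3, 1,
                                                      length.out = 14),
                               noise_sd = 0.005, condition = "ATP",
                               seed = 1L) {
  check_scalar(true_kd, "true_kd", 0)
  check_scalar(probe_conc, "probe_conc", 0, strict_min = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  if (any(!is.finite(protein_concs)) || any(protein_concs < 0))
    stop_param("'protein_concs' must be non-negative and finite")
  y0 <- quadratic_binding_model(protein_concs, probe_conc, true_kd,
                                a_min, a_max)
  y <- if (noise_sd > 0)
    with_seed(seed, y0 + stats::rnorm(length(y0), 0, noise_sd)) else y0
  structure(list(data = data.frame(protein_uM = protein_concs,
                                   anisotropy = y),
                 probe_uM = probe_conc, condition = condition,
                 truth = list(true_kd = true_kd, a_min = a_min,
                              a_max = a_max, noise_sd = noise_sd)),
            class = "binding_titration")
}

#' @export
print.binding_titration <- function(x, ...) {
  cat(sprintf("<binding_titration> %d points, probe %.3g uM, condition %s\n",
              nrow(x$data), x$probe_uM, x$condition))
  invisible(x)
}

#' Simulate an HPLC nucleotide chromatogram
#'
#' Gaussian peaks on a flat baseline; each species' peak area equals
#' `response_factor * concentration`, emulating a 260 nm absorbance channel
#' whose response is linear in amount injected.
#'
#' @param nt_concs named numeric vector of species concentrations in uM;
#'   names must be among `"ATP"`, `"ADP"`, `"ATPgS"`.
#' @param retention_centers named numeric vector, retention time (min) per
#'   species.
#' @param peak_sigma Gaussian peak width (min).
#' @param response_factors named numeric vector, area units per uM.
#' @param baseline flat baseline level.
#' @param noise_sd additive Gaussian noise.
#' @param time_grid retention axis (min).
#' @param seed RNG seed.
#' @return a `chromatogram`: list with `data` (data.frame `time_min`,
#'   `absorbance`) and `truth` (the generating concentrations). A warning is
#'   attached when two peaks are closer than 4 sigma (`truth$overlap`).
#' @export
simulate_chromatogram <- function(nt_concs,
                                  retention_centers = c(ADP = 4.5, ATP = 6.5,
                                                        ATPgS = 8.5),
                                  peak_sigma = 0.1,
                                  response_factors = c(ADP = 1, ATP = 1,
                                                       ATPgS = 1),
                                  baseline = 0.01, noise_sd = 0,
                                  time_grid = seq(0, 12, by = 0.005),
                                  seed = 1L) {
  allowed <- c("ATP", "ADP", "ATPgS")
  if (is.null(names(nt_concs)) || !all(names(nt_concs) %in% allowed))
    stop_param("'nt_concs' must be named with species among ATP, ADP, ATPgS")
  if (any(nt_concs < 0)) stop_param("concentrations must be >= 0")
  check_scalar(peak_sigma, "peak_sigma", 0, strict_min = TRUE)
  sp <- names(nt_concs)
  cen <- retention_centers[sp]
  if (any(is.na(cen))) stop_param("missing retention center for a species")
  overlap <- FALSE
  if (length(cen) > 1L) {
    d <- diff(sort(cen))
    if (any(d < 4 * peak_sigma)) {
      overlap <- TRUE
      warning("peaks closer than 4 sigma; integration windows may overlap")
    }
  }
  y <- rep(baseline, length(time_grid))
  for (s in sp) {
    area <- response_factors[[s]] * nt_concs[[s]]
    amp <- area / (peak_sigma * sqrt(2 * pi))
    y <- y + amp * exp(-(time_grid - cen[[s]])^2 / (2 * peak_sigma^2))
  }
  if (noise_sd > 0)
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  structure(list(data = data.frame(time_min = time_grid, absorbance = y),
                 truth = list(nt_concs = nt_concs,
                              retention_centers = cen,
                              peak_sigma = peak_sigma,
                              response_factors = response_factors[sp],
                              baseline = baseline, overlap = overlap)),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %d points, %.3g-%.3g min\n",
              nrow(x$data), min(x$data$time_min), max(x$data$time_min)))
  invisible(x)
}

#' Simulate a TLC ATPase assay
#'
#' Each lane carries an ATP spot and an ADP spot whose noise-free intensities
#' sum to `total_signal`; the ADP fraction is the fraction of ATP hydrolysed.
#'
#' @param fraction_hydrolysed per-lane hydrolysed fraction, each in `[0, 1]`.
#' @param total_signal total radiolabel signal per lane.
#' @param noise_sd Gaussian noise per spot.
#' @param lane_names optional lane labels.
#' @param seed RNG seed.
#' @return a `tlc_assay`: data.frame with columns `lane`, `adp`, `atp`, plus
#'   attribute `truth` (the generating fractions).
#' @export
simulate_tlc <- function(fraction_hydrolysed, total_signal = 1000,
                         noise_sd = 0, lane_names = NULL, seed = 1L) {
  if (any(!is.finite(fraction_hydrolysed)) ||
      any(fraction_hydrolysed < 0) || any(fraction_hydrolysed > 1))
    stop_param("'fraction_hydrolysed' values must lie in [0, 1]")
  check_scalar(total_signal, "total_signal", 0, strict_min = TRUE)
  n <- length(fraction_hydrolysed)
  adp <- fraction_hydrolysed * total_signal
  atp <- (1 - fraction_hydrolysed) * total_signal
  if (noise_sd > 0) {
    with_seed(seed, {
      adp <- pmax(0, adp + stats::rnorm(n, 0, noise_sd))
      atp <- pmax(0, atp + stats::rnorm(n, 0, noise_sd))
    })
  }
  structure(data.frame(lane = lane_names %||% paste0("lane", seq_len(n)),
                       adp = adp, atp = atp),
            truth = list(fraction_hydrolysed = fraction_hydrolysed,
                         total_signal = total_signal),
            class = c("tlc_assay", "data.frame"))
}

#' Simulate a bulk FRET emission spectrum
#'
#' Donor and acceptor emission rendered as Gaussian bands on a 1 nm grid,
#' for exercising [fret_emission_ratio()].
#'
#' @param donor_peak,acceptor_peak band centres, nm.
#' @param donor_intensity,acceptor_intensity band amplitudes.
#' @param band_sd band width, nm.
#' @param baseline flat offset.
#' @param wavelength_nm grid (default 550-800 nm).
#' @param excitation_nm excitation wavelength recorded in the object.
#' @return an `emission_spectrum`: data.frame `wavelength_nm`, `intensity`,
#'   with attribute `excitation_nm`.
#' @export
simulate_emission_spectrum <- function(donor_peak = 555, acceptor_peak = 647,
                                       donor_intensity = 100,
                                       acceptor_intensity = 30,
                                       band_sd = 18, baseline = 1,
                                       wavelength_nm = 550:800,
                                       excitation_nm = 500) {
  if (is.unsorted(wavelength_nm, strictly = TRUE))
    stop_param("'wavelength_nm' must be strictly increasing")
  y <- baseline +
    donor_intensity * exp(-(wavelength_nm - donor_peak)^2 / (2 * band_sd^2)) +
    acceptor_intensity *
      exp(-(wavelength_nm - acceptor_peak)^2 / (2 * band_sd^2))
  structure(data.frame(wavelength_nm = wavelength_nm, intensity = y),
            excitation_nm = excitation_nm,
            class = c("emission_spectrum", "data.frame"))
}
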