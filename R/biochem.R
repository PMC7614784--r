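## Equilibrium ssDNA-binding fits, bulk FRET ratios, nucleotide stoichiometry
## from HPLC chromatograms, and TLC ATPase quantification.

#' Tight-binding quadratic isotherm
#'
#' Anisotropy of a labelled probe at total probe concentration `L` and total
#' protein concentration `x` for 1:1 binding with dissociation constant `kd`:
#'
#' \deqn{Y = A_{min} + (A_{max}-A_{min})\,
#'   \frac{(x + L + K_D) - \sqrt{(x + L + K_D)^2 - 4 x L}}{2L}}
#'
#' This is the exact solution of the 1:1 mass-balance quadratic and must be
#' used (rather than the hyperbolic isotherm) when the probe concentration is
#' comparable to \eqn{K_D}; it reduces to the hyperbola when \eqn{L \ll K_D}.
#'
#' @param x total protein concentration(s), uM.
#' @param L total probe (ligand) concentration, uM (> 0).
#' @param kd dissociation constant, uM.
#' @param a_min,a_max anisotropy of free and fully bound probe.
#' @return anisotropy value(s), bounded in `[a_min, a_max]`, non-decreasing
#'   in `x`.
#' @examples
#' quadratic_binding_model(0.16, L = 0.05, kd = 0.16, a_min = 0, a_max = 1)
#' @export
quadratic_binding_model <- function(x, L, kd, a_min, a_max) {
  check_scalar(L, "L", 0, strict_min = TRUE)
  if (any(!is.finite(x)) || any(x < 0)) stop_param("'x' must be >= 0")
  if (!is.finite(kd) || kd < 0) stop_param("'kd' must be >= 0")
  s <- x + L + kd
  disc <- pmax(s^2 - 4 * x * L, 0)  # guard: exact arithmetic keeps it >= 0
  frac <- (s - sqrt(disc)) / (2 * L)
  a_min + (a_max - a_min) * pmin(pmax(frac, 0), 1)
}

#' Fit the quadratic binding isotherm to a titration
#'
#' Least-squares fit of [quadratic_binding_model()] to anisotropy versus
#' protein concentration, estimating `kd`, `a_min` and `a_max`, with an
#' asymptotic 95% confidence interval on `kd` from the Jacobian. Starting
#' values come from a log-spaced `kd` grid search.
#'
#' @param titration a `binding_titration` (see [simulate_titration()]) or a
#'   data.frame with columns `protein_uM` and `anisotropy`.
#' @param probe_conc probe concentration, uM; taken from the titration object
#'   when omitted.
#' @return a `binding_fit`: `kd` (uM), `a_min`, `a_max`, `ci95_kd`,
#'   `residual_sse`, `converged`, plus the data for the methods.
#' @examples
#' tt <- simulate_titration(0.5, noise_sd = 0, seed = 1)
#' fit_binding_isotherm(tt)
#' @export
fit_binding_isotherm <- function(titration, probe_conc = NULL) {
  if (inherits(titration, "binding_titration")) {
    df <- titration$data
    probe_conc <- probe_conc %||% titration$probe_uM
  } else {
    df <- as.data.frame(titration)
  }
  if (is.null(probe_conc)) stop_param("'probe_conc' required")
  check_scalar(probe_conc, "probe_conc", 0, strict_min = TRUE)
  if (!all(c("protein_uM", "anisotropy") %in% names(df)))
    stop_param("titration needs columns protein_uM, anisotropy")
  x <- df$protein_uM; y <- df$anisotropy
  if (length(x) < 5L) stop_param("need at least 5 concentrations")

  failed <- function() structure(
    list(kd = NA_real_, a_min = NA_real_, a_max = NA_real_,
         ci95_kd = c(NA_real_, NA_real_), residual_sse = NA_real_,
         converged = FALSE, probe_uM = probe_conc,
         data = data.frame(protein_uM = x, anisotropy = y)),
    class = "binding_fit")
  if (diff(range(y)) <= .Machine$double.eps) return(failed())

  lo <- min(y); hi <- max(y)
  kd_grid <- 10^seq(-3, 2, length.out = 40)
  sse <- vapply(kd_grid, function(k)
    sum((y - quadratic_binding_model(x, probe_conc, k, lo, hi))^2),
    numeric(1))
  k0 <- kd_grid[which.min(sse)]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ quadratic_binding_model(x, probe_conc, kd, amin, amax),
      data = data.frame(x = x, y = y),
      start = list(kd = k0, amin = lo, amax = hi),
      lower = c(1e-9, -Inf, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf[["kd"]] <= 0 || cf[["amax"]] <= cf[["amin"]])
    return(failed())
  se_kd <- tryCatch(sqrt(stats::vcov(fit)["kd", "kd"]),
                    error = function(e) NA_real_)
  structure(list(kd = unname(cf[["kd"]]), a_min = unname(cf[["amin"]]),
                 a_max = unname(cf[["amax"]]),
                 ci95_kd = unname(cf[["kd"]] + c(-1.96, 1.96) * se_kd),
                 residual_sse = sum(stats::resid(fit)^2), converged = TRUE,
                 probe_uM = probe_conc,
                 data = data.frame(protein_uM = x, anisotropy = y)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<binding_fit> not converged\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<binding_fit> K_D = %.4g uM (95%% CI %.4g-%.4g), Amin = %.4g, Amax = %.4g\n",
    x$kd, x$ci95_kd[1L], x$ci95_kd[2L], x$a_min, x$a_max))
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...)
  c(kd = object$kd, a_min = object$a_min, a_max = object$a_max)

#' @export
predict.binding_fit <- function(object, protein_uM = object$data$protein_uM,
                                ...)
  quadratic_binding_model(protein_uM, object$probe_uM, object$kd,
                          object$a_min, object$a_max)

#' @export
confint.binding_fit <- function(object, ...)
  matrix(object$ci95_kd, 1, 2,
         dimnames = list("kd", c("2.5 %", "97.5 %")))

#' @export
plot.binding_fit <- function(x, ...) {
  graphics::plot(x$data$protein_uM, x$data$anisotropy, log = "x",
                 xlab = "protein (µM)", ylab = "anisotropy", ...)
  xx <- 10^seq(log10(max(min(x$data$protein_uM[x$data$protein_uM > 0]),
                         1e-4)),
               log10(max(x$data$protein_uM)), length.out = 200)
  graphics::lines(xx, predict(x, xx), col = 2, lwd = 2)
  invisible(x)
}

#' Bulk FRET emission ratio
#'
#' Ratio of acceptor to donor fluorescence intensity \eqn{I_A/I_D} read from
#' an emission spectrum at the acceptor and donor emission wavelengths
#' (defaults 647 and 555 nm), with nearest-grid-point lookup.
#'
#' @param spectrum an `emission_spectrum` or data.frame with
#'   `wavelength_nm`, `intensity`.
#' @param donor_nm,acceptor_nm lookup wavelengths.
#' @return the ratio (numeric scalar).
#' @export
fret_emission_ratio <- function(spectrum, donor_nm = 555, acceptor_nm = 647) {
  w <- spectrum$wavelength_nm; y <- spectrum$intensity
  if (is.unsorted(w, strictly = TRUE))
    stop_param("wavelengths must be strictly increasing")
  if (donor_nm < min(w) || donor_nm > max(w) ||
      acceptor_nm < min(w) || acceptor_nm > max(w))
    stop_param("lookup wavelength outside the spectrum range")
  id <- which.min(abs(w - donor_nm))
  ia <- which.min(abs(w - acceptor_nm))
  if (y[id] == 0) stop("donor intensity is zero; ratio undefined")
  y[ia] / y[id]
}

#' Protein concentration by Beer-Lambert with nucleotide-adjusted extinction
#'
#' Concentration of the BCDX2 complex from A280, with the complex extinction
#' coefficient (80,220 1/(M cm)) adjusted for `n_nt` co-purifying nucleotides
#' (2,390 1/(M cm) each at 280 nm).
#'
#' @param a280 absorbance at 280 nm.
#' @param n_nt bound nucleotides per complex included in the extinction
#'   adjustment (3-4 for wild type).
#' @param path_cm path length, cm.
#' @param eps_protein,eps_nt extinction coefficients, 1/(M cm).
#' @return concentration in uM.
#' @examples
#' protein_concentration(0.08978, n_nt = 4)  # 1.000 uM
#' @export
protein_concentration <- function(a280, n_nt = 4, path_cm = 1,
                                  eps_protein = 80220, eps_nt = 2390) {
  check_scalar(a280, "a280", 0)
  check_scalar(n_nt, "n_nt", 0)
  check_scalar(path_cm, "path_cm", 0, strict_min = TRUE)
  a280 / ((eps_protein + n_nt * eps_nt) * path_cm) * 1e6
}

#' Integrate nucleotide peaks and convert to concentrations
#'
#' For each species window a linear baseline is drawn between the window
#' edges and subtracted, the remaining signal is integrated by the
#' trapezoidal rule, and the area is converted to concentration with a
#' standard curve fitted through the origin (response proportional to
#' amount).
#'
#' @param chrom a `chromatogram` or data.frame `time_min`, `absorbance`.
#' @param windows named list: species -> `c(lo, hi)` retention window (min);
#'   windows must be disjoint and inside the retention axis.
#' @param standards named list: species -> two-column matrix/data.frame of
#'   (area, concentration_uM) pairs, at least 2 per species.
#' @return a `peak_table` data.frame: `species`, `window_lo`, `window_hi`,
#'   `area`, `concentration_uM`.
#' @export
integrate_nucleotide_peaks <- function(chrom, windows, standards) {
  df <- if (inherits(chrom, "chromatogram")) chrom$data else
    as.data.frame(chrom)
  if (!all(c("time_min", "absorbance") %in% names(df)))
    stop_param("chromatogram needs columns time_min, absorbance")
  tt <- df$time_min; y <- df$absorbance
  sp <- names(windows)
  if (is.null(sp)) stop_param("'windows' must be a named list")
  iv <- do.call(rbind, windows)
  if (any(iv[, 1L] < min(tt)) || any(iv[, 2L] > max(tt)))
    stop_param("integration window outside the retention axis")
  o <- order(iv[, 1L])
  if (nrow(iv) > 1L && any(iv[o, 1L][-1L] < iv[o, 2L][-nrow(iv)]))
    stop_param("integration windows must be disjoint")
  rows <- lapply(sp, function(s) {
    w <- windows[[s]]
    sel <- tt >= w[1L] & tt <= w[2L]
    if (sum(sel) < 3L) stop_param("window contains fewer than 3 points")
    ts <- tt[sel]; ys <- y[sel]
    base <- ys[1L] + (ys[length(ys)] - ys[1L]) *
      (ts - ts[1L]) / (ts[length(ts)] - ts[1L])
    area <- max(0, pracma::trapz(ts, ys - base))
    std <- standards[[s]]
    if (is.null(std) || nrow(std) < 2L)
      stop_param(sprintf("need >= 2 standard points for %s", s))
    a <- std[, 1L]; cc <- std[, 2L]
    slope <- sum(a * cc) / sum(cc^2)  # through-origin: area = slope * conc
    data.frame(species = s, window_lo = w[1L], window_hi = w[2L],
               area = area, concentration_uM = area / slope)
  })
  structure(do.call(rbind, rows), class = c("peak_table", "data.frame"))
}

#' Nucleotides per protein complex
#'
#' Converts peak concentrations to a per-complex stoichiometry given the
#' protein concentration of the extracted sample.
#'
#' @param peaks a `peak_table` from [integrate_nucleotide_peaks()].
#' @param protein_conc protein (complex) concentration, uM (> 0).
#' @return a `stoichiometry_result`: list with `protein_uM`,
#'   `nt_per_complex` (named per species), `total_nt`.
#' @export
nucleotide_stoichiometry <- function(peaks, protein_conc) {
  check_scalar(protein_conc, "protein_conc", 0, strict_min = TRUE)
  per <- stats::setNames(peaks$concentration_uM / protein_conc,
                         peaks$species)
  structure(list(protein_uM = protein_conc, nt_per_complex = per,
                 total_nt = sum(per)),
            class = "stoichiometry_result")
}

#' @export
print.stoichiometry_result <- function(x, ...) {
  cat("<stoichiometry_result>",
      paste(sprintf("%s = %.2f", names(x$nt_per_complex), x$nt_per_complex),
            collapse = ", "),
      sprintf("| total %.2f nt per complex\n", x$total_nt))
  invisible(x)
}

#' ATPase activity from TLC spot intensities
#'
#' Percent hydrolysis per lane is `100 * ADP / (ADP + ATP)`; the hydrolysis
#' rate follows from the assay composition (defaults: 15 uM ATP, 1 uM enzyme,
#' 30 min at 37 C).
#'
#' @param assay a `tlc_assay` or data.frame with columns `adp` and `atp`
#'   (and optionally `lane`).
#' @param atp_total_uM total ATP in the reaction, uM.
#' @param enzyme_uM enzyme concentration, uM.
#' @param time_min incubation time, minutes.
#' @return an `atpase_result` data.frame: `lane`, `percent_hydrolysis`,
#'   `rate_uM_per_min_per_uM` (uM ATP consumed per minute per uM enzyme).
#' @export
atpase_hydrolysis <- function(assay, atp_total_uM = 15, enzyme_uM = 1,
                              time_min = 30) {
  df <- as.data.frame(assay)
  if (!all(c("adp", "atp") %in% names(df)))
    stop_param("assay needs columns adp, atp")
  if (any(df$adp < 0) || any(df$atp < 0))
    stop_param("spot intensities must be >= 0")
  if (any(df$adp + df$atp == 0))
    stop("both spots zero in at least one lane; percent undefined")
  check_scalar(atp_total_uM, "atp_total_uM", 0, strict_min = TRUE)
  check_scalar(enzyme_uM, "enzyme_uM", 0, strict_min = TRUE)
  check_scalar(time_min, "time_min", 0, strict_min = TRUE)
  pct <- 100 * df$adp / (df$adp + df$atp)
  structure(data.frame(lane = df$lane %||% paste0("lane", seq_len(nrow(df))),
                       percent_hydrolysis = pct,
                       rate_uM_per_min_per_uM =
                         pct / 100 * atp_total_uM / (time_min * enzyme_uM)),
            class = c("atpase_result", "data.frame"))
}

#' Compare two groups of measurements
#'
#' Two-sided Welch t-test or Mann-Whitney test. In `"auto"` mode a
#' Shapiro-Wilk normality screen is run on both groups and reported as an
#' annotation only; the test actually used is the Welch t-test unless
#' explicitly selected otherwise (the screen never switches the test
#' silently). With degenerate (zero) variance in both groups the t statistic
#' is undefined and an exact Mann-Whitney comparison is used instead, with a
#' warning.
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @param test `"auto"`, `"t"` or `"mannwhitney"`.
#' @return list with `statistic`, `p_value`, `test_used`, and (auto mode)
#'   `normality_p` for both groups.
#' @export
compare_groups <- function(a, b, test = c("auto", "t", "mannwhitney")) {
  test <- match.arg(test)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop_param("each group needs at least 2 values")
  normality <- NULL
  if (test == "auto") {
    shap <- function(v) if (length(unique(v)) >= 3L && length(v) >= 3L &&
                            length(v) <= 5000L)
      tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
    else NA_real_
    normality <- c(a = shap(a), b = shap(b))
    test <- "t"
  }
  if (test == "t") {
    if (stats::var(a) + stats::var(b) == 0) {
      if (length(unique(c(a, b))) == 1L)
        return(list(statistic = 0, p_value = 1, test_used = "degenerate",
                    normality_p = normality))
      warning("zero variance in both groups; using exact Mann-Whitney")
      mw <- mann_whitney_test(a, b)
      return(list(statistic = mw$u, p_value = mw$p_value,
                  test_used = "mannwhitney (degenerate variance)",
                  normality_p = normality))
    }
    tt <- stats::t.test(a, b)
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         test_used = "welch_t", normality_p = normality)
  } else {
    mw <- mann_whitney_test(a, b)
    list(statistic = mw$u, p_value = mw$p_value,
         test_used = paste0("mannwhitney (", mw$method, ")"),
         normality_p = normality)
  }
}
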