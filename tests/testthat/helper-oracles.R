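# Independent oracles used by several test files.

# Brute-force grid search for the saturating exponential: best SSE over an
# (a_max, k) grid. Deliberately independent of fit_saturating_exponential.
grid_sse_exponential <- function(t, y, n_grid = 100) {
  a_grid <- seq(max(y) * 0.5, max(y) * 1.5, length.out = n_grid)
  k_grid <- seq(1e-4, 2 / stats::median(t[t > 0]), length.out = n_grid)
  best <- Inf
  for (a in a_grid) for (k in k_grid) {
    sse <- sum((y - a * (1 - exp(-k * t)))^2)
    if (sse < best) best <- sse
  }
  best
}

# Brute-force grid search for the binding isotherm over log-spaced kd with
# a_min/a_max profiled on a small grid around the data range.
grid_sse_isotherm <- function(x, y, L) {
  kd_grid <- 10^seq(-3, 2, length.out = 100)
  amin_grid <- seq(min(y) - 0.02, min(y) + 0.02, length.out = 11)
  amax_grid <- seq(max(y) - 0.02, max(y) + 0.02, length.out = 11)
  best <- Inf
  for (kd in kd_grid) for (am in amin_grid) for (ax in amax_grid) {
    sse <- sum((y - quadratic_binding_model(x, L, kd, am, ax))^2)
    if (sse < best) best <- sse
  }
  best
}

# Exact 1:1 equilibrium bound-probe fraction found numerically from the
# mass-balance equations (independent of the closed-form quadratic).
bound_fraction_numeric <- function(x_tot, L_tot, kd) {
  if (x_tot == 0) return(0)
  f <- function(c_free) {
    bound <- L_tot * c_free / (kd + c_free)
    c_free + bound - x_tot
  }
  if (kd == 0) return(min(x_tot, L_tot) / L_tot)
  c_free <- stats::uniroot(f, c(0, x_tot), tol = 1e-14)$root
  (c_free / (kd + c_free))
}

# A noise-free kymograph with constant, well-separated covered segments.
static_segments_kymo <- function(intervals_um, n_frames = 20,
                                 frame_interval_s = 2) {
  p <- sim_kymo_params(length_um = 20,
                       duration_s = (n_frames - 1) * frame_interval_s,
                       frame_interval_s = frame_interval_s, k_off = 0,
                       shot_noise = FALSE, read_noise_sd = 0, seed = 1)
  simulate_disassembly_kymograph(p, intervals_um)
}
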