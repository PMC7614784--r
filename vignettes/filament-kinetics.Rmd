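---
title: "Models and methods: RAD51 filament kinetics, EM filament tracing and binding biochemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rad51kit)
```

This vignette records the models behind each analysis stage, the tunable
parameters and their defaults, what the synthetic-data generators emulate
(and deliberately do not), and the numerical choices made where the design
was genuinely open.

## The nucleation–extension process model

RAD51 filament assembly on ssDNA is modelled as a spatial birth-and-growth
process. Nucleation is a Poisson process with intensity `k_nuc`
(events·µm⁻¹·s⁻¹) on the *uncovered* part of the substrate — an
excluded-volume assumption chosen as the simplest process consistent with
nucleation–extension kinetics. Each nucleus is born as a short covered
segment (`nucleus_nm`, default 100 nm, one confocal pixel) and extends at a
total speed `v_grow` (nm/s), split between its two ends by `polarity`
(default 0.5, symmetric). Growth polarity along the 3′→5′ direction can be
emulated by moving `polarity` toward 0 or 1; no rate asymmetry is quantified
in the literature, so symmetric growth is the default. Segments merge on
collision and clip at the substrate ends. Disassembly (the ATP-free channel)
shrinks every segment at `k_off` nm/s per end, bidirectionally.

The camera model is: expected photon flux per pixel proportional to covered
fraction (`photon_rate` counts per covered pixel per frame, default 120),
blurred along the position axis by a Gaussian PSF (`psf_sigma_px`, default
1.2 px at 100 nm/px), then Poisson shot noise, then additive Gaussian read
noise (`read_noise_sd`, default 3 counts). Optional single-exponential
photobleaching (`bleach_rate`) ages each pixel from its first coverage.
These are generic confocal/EMCCD choices; the detector of any particular
instrument is not being reproduced. The optional RPA channel is rendered as
the exact complement of coverage (RPA displaced where RAD51 binds), which is
idealised: real RPA displacement lags filament growth.

Simulation is stepped at the frame interval; frame *i* holds the state at
`(i − 1) · frame_interval_s`. Rows are frames (time increases downward),
columns are position pixels, 0-based in files and half-open in all interval
conventions. Every simulator takes an explicit integer seed and restores the
caller's RNG state, so identical parameters and seed give bit-identical
output.

Absolute kinetic parameters for this system are not established in physical
units — published work reports fold-changes, not rates — so the generator
defaults are stated as the package's own study conditions: a 20 µm substrate
(λ ssDNA at typical C-trap tension), 100 nm pixels, 2 s frames, `k_nuc` of
order 0.01–0.04 events·µm⁻¹·s⁻¹ and slow growth (`v_grow` ≲ 1 nm/s). These
were calibrated once on synthetic data so that the peak-count curve (below)
rises and saturates within the observation window, which is the regime in
which an apparent nucleation rate is a meaningful summary; they were not
tuned per experiment thereafter.

## Apparent nucleation rate

The estimator mirrors the field's recipe: each frame's spatial profile is
Savitzky–Golay smoothed (window 5 px, polynomial order 2 — the order must be
below the window and 2 is the smallest that preserves peak curvature), local
maxima with topographic prominence at least `prominence_sigmas` (default 3)
times the robust background SD are counted with a minimum separation of 3 px
(about one PSF, to avoid double-counting), and the counts *y(t)* are fitted
with

$$y = A_{max}\,(1 - e^{-kt}),$$

whose rate constant `k` (s⁻¹) is the apparent nucleation rate and
`ln 2 / k` the half-life. Two numerical details matter:

* the background SD is estimated from the *horizontal first differences* of
  the raw image (MAD/√2). Estimating it from the raw intensities themselves
  would conflate the covered/uncovered structure of the image with noise
  and makes the threshold explode once filaments cover an appreciable
  fraction of the substrate;
* `k` is only identified when the count curve actually approaches its
  plateau inside the window. Before saturation, `A_max` and `k` trade off
  and the fit is noisy. To first order the expected count obeys
  `dN/dt = k_nuc (L − wN)` for an effective exclusion length `w` (peak
  separation limit plus PSF), so the apparent rate scales with `k_nuc` and
  ratios of apparent rates between conditions estimate ratios of the
  generating nucleation rates — the quantity the recovery suite checks.
  The estimator is not exactly unbiased for that ratio, however: the
  saturation time scales inversely with `k_nuc`, so a fixed observation
  window inevitably covers more of the faster condition's post-plateau
  phase, where peak merging erodes the count and inflates the fitted `k`.
  At the study conditions (two-fold `k_nuc` difference, window covering the
  rise and plateau of the slower arm) this inflates the recovered
  fold-change by roughly +15% (about 2.3 for a true 2.0); the recovery
  criterion is stated as 2.0 ± 0.5 for exactly this reason, and the bias
  grows if the window extends much further past saturation. The per-molecule
  apparent rate has a coefficient of variation near 25–30%, so arm summaries
  use medians over tens of molecules.

The saturating-exponential fit itself (`fit_saturating_exponential`) uses
Levenberg–Marquardt with non-negative bounds, a data-driven start (plateau
from the maximum, rate from the first 63% crossing), asymptotic 95%
confidence intervals from the Jacobian, and a `k = 0, converged = FALSE`
sentinel for all-zero or constant input.

## Boundary rates, binding events, FRET phases, force

A filament border is tracked per frame as the outermost pixel of the
connected run above `threshold_fraction` (default 0.5) of the segment
plateau, where the plateau is the median intensity of the seed-frame
segment; positions (pixel centres, nm) are regressed on time, so the rate is
a slope in nm/s with its R². A static segment reports rate 0 and R² 0 by
convention. Tracks survive `max_gap_frames` (default 2) missing frames
before truncating with a warning.

Binding events are 8-connected spatiotemporal components above
`median + intensity_sigmas · MAD` (default 5) lasting at least
`min_duration_frames` (default 2); frequencies are counted in half-open
windows of `window_s` (default 30 s, the first-window convention used for
binding-frequency comparisons).

FRET event traces are averaged in a running 3-sample window, then the
acceptor is thresholded against the donor bleed-through level plus
`step_sigmas` (default 3) noise SDs — noise estimated from first differences
of the *raw* trace, which is conservative after smoothing — and phases are
labelled `fret` / `donor_only` / `dark`. Runs shorter than 3 samples are
merged into their preceding phase to suppress threshold flicker at
transitions. The Pearson correlation of the two smoothed channels over the
non-dark samples quantifies anti-correlation; genuine energy transfer gives
r < 0.

Force traces are reduced by non-overlapping block means on half-open
`[t, t + 1/target_hz)` windows (default 3 Hz), which preserves the overall
mean exactly on block-aligned partitions.

## Filament tracing in negative-stain micrographs

Micrographs are band-passed with a difference of Gaussians (defaults σ₁ = 2,
σ₂ = 6 px ≈ filament width versus background scale at 5.85 Å/px; reflective
boundaries, so constants map to zero and the operator is linear). The ridge
mask is all pixels at least `threshold_sigmas` (default 3) robust SDs above
the median. The mask is thinned by subfield simple-point thinning: a pixel
is deleted when its Yokoi 8-connectivity number is 1 (topology preserved)
and it is not an endpoint, sweeping four (row, column) parity subfields so
that no two adjacent pixels are deleted in one parallel sweep — this keeps
2-px diagonal structures connected, where plain two-subiteration thinning
schemes erase them. Boundary noise leaves short side branches and junction
clumps on any 1-px skeleton, so thinning alternates with spur pruning
(terminal branches up to 8 px ending at a junction are removed, then the
result is re-thinned, twice). The cleaned skeleton is split at junction
pixels (> 2 neighbours), and each branch of at least `min_length_px`
(default 5) becomes a trace.

Two corrections make the measured contour length approximately unbiased on
synthetic ground truth:

* trace ends are trimmed to the half-maximum of the ridge-intensity profile
  along the path (the threshold mask otherwise overhangs each filament tip
  by roughly the PSF scale);
* the polyline is smoothed with a 7-point moving average (endpoints pinned)
  before arc length is summed, because a 1-px medial axis zigzags laterally
  inside a noisy ridge band and raw 1/√2 step sums inflate length by up to
  ~10%. With smoothing disabled the metric is exactly 1 per axial and √2
  per diagonal step.

Junction handling is split-only: filaments crossing each other are measured
as separate branches, never joined across the crossing. Whether the original
ImageJ-based analyses joined across crossings is unknowable from the outside;
for sparse fields (the regime simulated here) the difference is negligible,
for dense fields it shifts the absolute length distribution downward. On
gridded synthetic micrographs at moderate noise the tracer finds ≥ 90% of
filaments with ~95% of matched lengths within ±10% of ground truth; a
residual −3 to −4% mean bias from end erosion remains. Note that raising the
detection threshold can *fragment* borderline filaments as well as remove
them, so monotonicity of the detected count in the threshold holds reliably
only for clean, well-separated filaments.

The micrograph generator renders filaments as persistence-sampled random
walks (per-pixel heading change Gaussian with SD `1/√persistence_px`) with a
Gaussian cross-section, plus disc-shaped background particles and Gaussian
noise. It does not emulate stain granularity, defocus/CTF, or filament
bundling — recovery results on it validate the tracer's geometry, not its
behaviour on crowded or low-contrast real micrographs.

## Statistics for condition comparisons

Pooled filament lengths are compared with a two-sided Mann–Whitney test;
per-micrograph counts with a two-sided Welch t-test; medians and IQRs are
reported. When both groups have at most 8 observations the Mann–Whitney
p-value comes from exact enumeration of all group assignments (a full
permutation test on U, valid under ties); otherwise the normal approximation
with tie correction and continuity correction is used. The two routes are
not numerically interchangeable at very small n — the normal approximation
can differ from the exact p by far more than 0.01 there, which is why the
exact path exists. `compare_groups` exposes the same machinery for scalar
measurements; its `auto` mode runs a Shapiro–Wilk screen for annotation only
and always applies the Welch test unless the user selects otherwise, so no
silent test switching occurs.

## Binding isotherms

With probe concentration `L` comparable to `K_D` (50 nM probe against
dissociation constants down to 0.09 µM), the fraction bound must come from
the 1:1 mass-balance quadratic rather than the hyperbolic isotherm:

$$Y = A_{min} + (A_{max}-A_{min})\,
 \frac{(x + L + K_D) - \sqrt{(x + L + K_D)^2 - 4xL}}{2L}.$$

The discriminant is clamped at zero against floating-point underflow (it is
non-negative for valid inputs), and the bound fraction is clamped to
`[0, 1]`. The fit estimates `(K_D, A_min, A_max)` by Levenberg–Marquardt
from a log-spaced `K_D` grid start, reports an asymptotic 95% CI on `K_D`
from the Jacobian (the conventional choice for this fit; profile likelihood
would be more accurate far from the design range), and declares
`converged = FALSE` on flat data. For `L ≤ K_D/100` the quadratic agrees
with the hyperbola to better than 1%, a closed-form limit the tests check.
Titration replicates may be fitted individually and summarised afterwards
(the package's convention, used throughout the recovery suite) or averaged
before fitting; both orders are supported since the fit consumes any
(concentration, anisotropy) table.

## Nucleotide quantification and ATPase

Chromatogram peaks are integrated per species window after subtracting a
linear baseline drawn between the window edges; areas convert to
concentrations via standard curves fitted through the origin (response
proportional to amount — the natural model for peak-area calibration).
Nucleotides per complex divide by the protein concentration. The
Beer–Lambert helper adjusts the complex extinction coefficient
(80,220 M⁻¹cm⁻¹) for co-purifying nucleotides (2,390 M⁻¹cm⁻¹ each); because
the adjustment depends on the stoichiometry being measured, the recommended
order of operations is a two-pass scheme — assume 4 nt, compute the
concentration, recompute nt per complex, iterate once — which converges to
well under 1% because the nucleotide term is ≲ 12% of the total extinction.
TLC percent hydrolysis is `100·ADP/(ADP+ATP)` per lane, invariant to common
rescaling of both spots; the rate normalisation assumes 15 µM ATP, 1 µM
enzyme and 30 min unless told otherwise.

The chromatogram generator places Gaussian peaks (area = response factor ×
concentration) on a flat baseline and warns when two centres fall within 4σ;
it does not emulate tailing, drift or co-elution. The TLC generator
conserves `total_signal` per lane at zero noise.

## Problem sizes in the validation suite

The test and acceptance runs use deliberately modest sizes chosen for good
statistical resolution: 10 titration replicates per condition (±10% on the
median recovered K_D), 16–30 kymographs per arm for the fold-change recovery
(the per-molecule apparent rate has CV ≈ 25–30%, so arm medians need tens of
molecules), two 720² px micrographs with nine gridded filaments each for the
tracer, and 500 short simulations for the Poisson dispersion check. One full
run of the suite takes a few minutes on one CPU.

## Known limitations

* The apparent-rate estimator is only unbiased in its design regime
  (saturating counts, limited merging); outside it, ratios drift upward.
* The tracer assumes bright curvilinear ridges on a flat background; it is
  not a general ridge detector for low-SNR cryo-EM data, and it does not
  join filaments across crossings.
* The binding fit assumes a single 1:1 site and blank-corrected anisotropy;
  no G-factor or instrument corrections are applied.
* Simulated data cannot certify performance on real detector artifacts
  (drift, afterpulsing, stain variability); passing recovery tests shows the
  estimators invert their own generative models at realistic noise, not that
  the models capture every property of the instruments.
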