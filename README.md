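# rad51kit

Quantitative analysis of RAD51 nucleoprotein-filament assembly on
single-stranded DNA, and of its stimulation by the RAD51-paralog complex
BCDX2 (RAD51B–RAD51C–RAD51D–XRCC2), for researchers working with
single-molecule C-trap kymographs, negative-stain electron micrographs and
the standard accompanying biochemistry (fluorescence anisotropy, HPLC
nucleotide analysis, TLC ATPase assays).

RAD51 filaments assemble by a nucleation–extension mechanism: rare nucleation
events seed clusters on ssDNA that then grow at their ends. The package
implements the bespoke quantitative procedures this kind of study relies on,
plus forward simulators for every input modality so that each analysis stage
can be validated by parameter recovery against known ground truth.

## What it computes

**Kymograph kinetics** (`estimate_nucleation_rate`, `measure_edge_rate`,
`normalize_assembly_signal`, `detect_binding_events`, `analyze_fret_event`,
`downsample_force`). The apparent nucleation rate follows the
smoothing/peak-counting recipe: each frame's spatial profile is
Savitzky–Golay smoothed (5 px window), intensity peaks are counted, and the
per-frame counts *y* are fitted with the saturating exponential

    y = A_max (1 − exp(−k t))

where `k` (s⁻¹) is the apparent nucleation rate and `ln 2 / k` the assembly
half-life. Filament growth and disassembly rates are the slope of a filament
border (nm/s) tracked at half-maximal intensity.

**Negative-stain EM filaments** (`dog_filter`, `trace_filaments`,
`compare_conditions`, `write_overlay`). Micrographs are band-passed with a
difference of Gaussians, the ridge mask is thinned to a one-pixel skeleton,
spurs are pruned, branches are split at junctions and measured as
calibrated contour lengths. Conditions are compared with a two-sided
Mann–Whitney test on pooled lengths (exact enumeration when both n ≤ 8) and
a Welch t-test on per-micrograph counts.

**Equilibrium ssDNA binding** (`quadratic_binding_model`,
`fit_binding_isotherm`). Anisotropy titrations are fitted with the
tight-binding quadratic isotherm

    Y = A_min + (A_max − A_min) · [(x + L + K_D) − √((x + L + K_D)² − 4xL)] / (2L)

which is exact when the probe concentration `L` is comparable to `K_D`
(here `L = 0.05 µM`).

**Nucleotide stoichiometry and ATPase activity**
(`integrate_nucleotide_peaks`, `nucleotide_stoichiometry`,
`protein_concentration`, `atpase_hydrolysis`, `fret_emission_ratio`,
`compare_groups`). HPLC peaks at 260 nm are baseline-corrected, integrated
and converted with standard curves; hydrolysis is `100 · ADP/(ADP + ATP)`
per TLC lane.

**Simulators** (`simulate_kymograph`, `simulate_disassembly_kymograph`,
`simulate_fret_trace`, `simulate_binding_kymograph`, `simulate_micrograph`,
`simulate_titration`, `simulate_chromatogram`, `simulate_tlc`,
`simulate_emission_spectrum`, `simulate_force_trace`). All take an explicit
integer seed, never touch the global RNG, and return the hidden ground truth
(event lists, boundary trajectories, true lengths, true K_D) alongside the
rendered data.

## Worked example

```r
library(rad51kit)

# simulate an assembly kymograph and recover the nucleation kinetics
p   <- sim_kymo_params(k_nuc = 0.02, seed = 11)
sim <- simulate_kymograph(p)
est <- estimate_nucleation_rate(sim$kymo, "rad51")
est
#> <nucleation_estimate> apparent rate k = 0.0159 1/s (plateau 19.7 peaks, converged)

# fit a synthetic anisotropy titration at the ATP-condition affinity
fit <- fit_binding_isotherm(simulate_titration(0.16, seed = 1))
fit
#> <binding_fit> K_D = 0.1347 uM (95% CI 0.1027-0.1667), Amin = 0.04917, Amax = 0.1964
```

The apparent rate is the exponential rate constant of peak-count saturation
(s⁻¹): on this molecule, detected nuclei approach a plateau of ~20 resolvable
peaks with rate 0.016 s⁻¹. The binding fit reports the dissociation constant
in µM with its asymptotic 95% confidence interval; this single noisy
replicate fits 0.135 µM and its CI covers the generating 0.16 µM — the
recovery suite checks the median over replicates.

A unified driver, `run_pipeline()`, executes any stage from a YAML or list
configuration and writes CSV outputs plus a `summary.json` echoing every
threshold used; `inst/cli/rad51kit` is a thin command-line wrapper around it.

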