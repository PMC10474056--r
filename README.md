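# whiskervib

Modal analysis of whisker vibrations and dispersive tactile transduction.

Rodents sense object texture through their whiskers: every micro-collision
of a sweeping whisker with a surface feature launches a vibrational
shockwave down the shaft toward the follicle, where mechanoreceptors turn
force into spikes. That shockwave is not a single pulse. It decomposes
into the transverse eigenmodes of the whisker — a tapered, truncated,
clamped-free Euler–Bernoulli beam — whose natural frequencies follow

    f_j = R_b / (4 pi l S_tot) * sqrt(E / rho) * gamma_j
        = R_b / (4 pi S_tot^2)  * sqrt(E / rho) * beta_j

with base radius `R_b`, total arc length `S_tot`, truncated length `l`,
Young's modulus `E`, density `rho`, and dimensionless mode coefficients
`beta_j` (`gamma_j` for the truncated form). Because flexural waves are
dispersive — group velocity `v_g = 2 sqrt(omega) (E R^2 / 4 rho)^(1/4)` —
and damping ratios fall roughly as `1/f`, high-order modes (up to 10 kHz)
arrive at the follicle first, fast and lightly damped, while the heavily
damped fundamental straggles in milliseconds later. A single collision is
thereby transformed into a time-sequenced series of energy bursts: a
temporal "bar code" with kilobit-per-second information capacity, ready
for threshold-crossing spike encoding by rapidly adapting
mechanoreceptors.

`whiskervib` implements the full analysis chain for this picture, plus a
ground-truth-labeled synthetic data generator so every stage is testable
without recordings:

- **Beam model** — eigenfrequencies and mode shapes of the truncated
  conical clamped-free beam (`solve_eigenmodes`), static deflections
  (`static_deflection`), and damped free-vibration simulation of the base
  shear force after a pole slip-off (`simulate_base_shear`).
- **Spectral analysis** — complex Morlet wavelet spectrograms
  (`cmw_spectrogram`), minima-based per-mode FFT filter banks
  (`band_partition`, `bandpass_mode`), analytic-signal power envelopes
  and modal energy partitions (`mode_power_envelope`, `modal_energy`).
- **Modal estimation** — resonant peak detection (`detect_modal_peaks`),
  two-regime damping estimation (time-domain `fit_damped_sinusoid` below
  200 Hz, wavelet-ridge slope `damping_from_wavelet_slope` above),
  damping-corrected natural frequencies (`correct_natural_frequency`),
  envelope-peak group delays (`group_delay_and_velocity`), and
  one-parameter Young's-modulus fits to trimming series
  (`fit_youngs_modulus`).
- **Kinematics & energetics** — curvature and contact-angle kinematics
  from traced shapes (`whisker_curvature`, `tip_kinematics`),
  pinned/unpinned/collision segmentation (`segment_phases`), contact
  force and the elastic/kinetic/impact energy budget (`contact_force`,
  `strain_energy`, `rotational_impact_energy`), impedance reflection and
  dB attenuation accounting (`power_reflection`, `attenuate_db`).
- **Spike encoding & information** — threshold-crossing population spike
  trains (`upsample_trace`, `threshold_spikes`), raster/PSTH/ISI
  summaries (`trial_statistics`), and direct-method mutual information
  with a jackknife cross-check (`binarize`, `direct_information`,
  `jackknife_information`, `info_vs_binsize`).
- **Synthetic data** — slip-off traces, texture sweeps with dispersive
  collision wave packets, trial ensembles, and traced whisker shapes,
  each carrying its injected ground truth (`generate_slipoff_trace`,
  `generate_texture_sweep`, `generate_trial_ensemble`,
  `generate_whisker_shapes`).

## Worked example

Simulate the base shear of a rat-like whisker (40 mm cone trimmed to
29 mm, `R_b` = 60 µm, `E` = 2 GPa, damping 430 rad/s) slipping off a pole
2 mm from its tip, then recover the whisker's physics from the trace
alone:

```r
library(whiskervib)

geom <- whisker_geometry(S_tot = 40, R_b = 60e-3, r_t = 0, l = 29,
                         E = 2e9, rho = 1000, unit = "mm")
modes <- solve_eigenmodes(geom, n_modes = 12, check = FALSE)
head(modes$table)
#>  j        f_j   omega_j    beta_j    gamma_j
#>  1   45.44169  285.5185  10.76758   7.806494
#>  2  148.96953  936.0032  35.29889  25.591695
#>  3  337.74069 2122.0874  80.02893  58.020971
#>  4  616.15337 3871.4058 145.99986 105.849896
#>  5  985.67388 6193.1716 233.55913 169.330368
#>  6 1446.72564 9090.0453 342.80708 248.535130

shear <- simulate_base_shear(geom,
  simulator_config(pole_arc_position = 2e-3, alpha = 430,
                   n_points = 30000, n_modes = 12), modes = modes)

sp <- cmw_spectrogram(shear, f_min = 1500, f_max = 7000, n_freq = 400)
peaks <- detect_modal_peaks(sp, delay = 5e-3)
round(as.numeric(peaks), 1)
#> [1] 2003.8 2635.7 3374.4 4205.1
zeta <- sapply(peaks, function(f) damping_from_wavelet_slope(sp, f)$zeta)
round(zeta, 4)
#> [1] 0.0340 0.0259 0.0203 0.0163

f_n <- correct_natural_frequency(as.numeric(peaks), zeta)
fit <- fit_youngs_modulus(data.frame(l = geom$l, j = 7:10, f_n = f_n), geom)
sprintf("E = %.3f GPa (r = %.4f)", fit$E / 1e9, fit$pearson_r)
#> "E = 1.998 GPa (r = 1.0000)"

group_velocity(geom$E, geom$R_b, geom$rho, 2 * pi * f_n[3])
#> [1] 60 m/s (mode 9, ~3.4 kHz; the 45 Hz fundamental travels at ~7 m/s)
```

The detected spectral peaks are the damped resonances of the underdamped
modes (the heavily damped modes 1–3 have no usable peak at this damping);
the wavelet-ridge slopes return each mode's damping ratio — all
consistent with the single 430 rad/s decay rate — and after the
`f_R / sqrt(1 - zeta^2)` correction, a single-parameter fit of the beam
model recovers the simulator's Young's modulus to 0.1%.

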