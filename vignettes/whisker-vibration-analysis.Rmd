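---
title: "Dispersive modal analysis of whisker vibrations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dispersive modal analysis of whisker vibrations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whiskervib)
```

# The physical model

A whisker is modeled as a linearly tapered circular Euler–Bernoulli beam,
clamped at the base (as when glued to a microphone membrane) and free at
the distal end. The untrimmed cone has total arc length $S_{tot}$, base
radius $R_b$ and tip radius $r_t$; trimming truncates it at arc length
$l$, and the free-end conditions move to the cut. Transverse eigenmodes
obey

$$(E I(s)\, w'')'' = \rho A(s)\, \omega^2 w, \qquad
  I(s) = \tfrac{\pi}{4} r(s)^4,\; A(s) = \pi r(s)^2,\;
  r(s) = R_b - \tfrac{R_b - r_t}{S_{tot}} s,$$

with $w(0) = w'(0) = 0$ and natural boundary conditions at $s = l$.
Natural frequencies are conventionally reported through dimensionless
coefficients,

$$f_j \;=\; \frac{R_b}{4\pi l S_{tot}} \sqrt{E/\rho}\;\gamma_j
      \;=\; \frac{R_b}{4\pi S_{tot}^2} \sqrt{E/\rho}\;\beta_j ,$$

which depend only on the truncation ratio $l/S_{tot}$ and the taper. For
a cylinder $\sqrt{\beta_j}$ reduces to the classical cantilever roots
(1.8751, 4.6941, ...). Frequencies scale as $R_b$, $\sqrt{E}$,
$1/\sqrt{\rho}$ and $1/S_{tot}^2$; these scalings, the cylinder limit,
and agreement with an independent finite-element discretization are
asserted by the test suite.

Three further ingredients complete the physical picture:

* **Damping.** Each mode decays exponentially. We use the standard
  damping ratio $\zeta = 1/(\omega_n \tau)$, where $\tau$ is the
  *amplitude* decay time, so the quality factor is $Q = 1/(2\zeta)$ and
  the resonant (spectral-peak) frequency relates to the natural one by
  $f_n = f_R/\sqrt{1-\zeta^2}$. Measured whisker damping falls roughly
  as $1/f$: the fundamental can be heavily damped ($\zeta \sim 0.3$)
  while kilohertz modes ring for hundreds of cycles.
* **Dispersion.** Flexural wave packets in a uniform rod of radius $R$
  travel at the group velocity
  $v_g = 2\sqrt{\omega}\,(E R^2/4\rho)^{1/4}$: a 3–4 kHz mode moves an
  order of magnitude faster than the fundamental, so a collision
  shockwave arrives at the base high-frequency-first.
* **Energy.** Eigenmodes remain orthogonal under this damping model, so
  the instantaneous signal power splits additively across modes; modal
  energies are integrals of per-mode power envelopes.

# Numerical methods

**Eigenproblem.** The variable-coefficient operator is discretized by a
Rayleigh–Ritz finite-difference scheme: strain energy
$\int EI (w'')^2\,ds$ with second-difference curvature (one-sided at the
clamped base), trapezoidal quadrature, and a diagonal (lumped) mass
matrix. The generalized symmetric eigenproblem is reduced by a Cholesky
factorization of the stiffness matrix, which tolerates the vanishing
mass density at an ideal cone tip. Free-end conditions are natural in
the variational form — the scheme stays well behaved for strong taper
where strong-form stencils at the free end are fragile. Convergence is
certified by grid doubling (`solve_eigenmodes(check = TRUE)` errors if
any requested frequency moves by more than `tol`, default $10^{-3}$
relative); the default grid of 400 intervals resolves the first 20 modes
of realistic geometries well inside that tolerance. The test suite
cross-checks frequencies and static deflections against an independent
Hermite-cubic finite-element discretization to 1%.

**Slip-off simulation.** The initial condition is the static deflection
under a point load at the pole contact; at $t = 0$ the load is released
and each mass-normalized modal coordinate evolves as a damped oscillator
with amplitude envelope $e^{-\alpha t}$ and damped frequency
$\omega_d = \sqrt{\omega_n^2 - \alpha^2}$ (modes with
$\omega_n \le \alpha$ follow the overdamped branch). With the default
$\alpha = 430\ \mathrm{rad/s}$ — the frequency-independent damping used
for the reference configuration — low-order modes of a 29 mm whisker are
over- or heavily damped, which matters for what a spectral readout can
recover (below). Base shear is $E I(0) w'''(0)$, assembled per mode from
a one-sided third-derivative stencil consistent with the clamped
constraints. With $\alpha = 0$ the per-mode energies
$(\dot q^2 + \omega^2 q^2)/2$ are conserved to machine precision; with
$\alpha > 0$ their envelopes decay at $2\alpha$ — both asserted in
tests, pinning the damping convention that the estimators are validated
against.

**Wavelet spectrogram.** The complex Morlet mother is
$\psi(t) = \exp(2\pi i f_c t - t^2/f_b)$ with center frequency
$f_c = 3$ Hz and bandwidth coefficient $f_b = 3$ Hz by default, a
balanced time–bandwidth compromise for 20 kS/s whisker traces. Because
Morlet parameter conventions differ across toolkits, the convention here
is pinned by regression tests on damped-tone fixtures: daughters are
L1-normalized, so a unit-amplitude tone yields a ridge of magnitude 1/2
located exactly at the tone frequency at every scale, and the ridge's
log-magnitude slope equals the amplitude decay rate. The analysis grid
is log-spaced (2 Hz–10 kHz in 5000 steps by default; tests and the
acceptance script use coarser grids sized to their bands). The transform
runs on a zero-padded domain (0.1 s per side, trimmed afterwards);
remaining edge effects are delimited by the reported cone-of-influence
margin $\sqrt{2}\sigma_t(f)$, where $\sigma_t(f) = \sqrt{f_b/2}\, f_c/f$
is the daughter envelope SD.

**Band partition.** Modal peaks are local maxima of a magnitude slice
rising at least 10 dB above a robust floor (lower-half median plus MAD —
the modal skirts inflate whole-slice statistics) with at least 6 dB
prominence. Band edges sit at the deepest amplitude minimum between
adjacent detected peaks, hard-edged, with the outermost edges at guard
margins; for a single detected peak the band spans the analyzed range.
Slice-local statistics cannot, however, reject a pure-noise input:
Rayleigh magnitude fluctuations produce bumps with up to ~20 dB of
prominence (measured while designing the detector). `detect_modal_peaks`
therefore adds a pre-onset baseline screen when the trace has one: under
the noise-only null the squared coefficient magnitude is exponentially
distributed about the per-frequency baseline mean, so candidates must
exceed a Bonferroni-corrected exponential-tail quantile
(`alpha = 0.01` familywise). Noise-only traces then return empty lists
while genuine modal peaks, far above the microphone floor, pass
untouched.

**Filtering and envelopes.** Mode traces are obtained by zero-phase FFT
mask filtering of the offset-corrected signal (hard edges, matching the
band table; an optional raised-cosine taper suppresses ringing if
needed). The power envelope is the squared magnitude of the analytic
signal of the bandpassed trace — for a tone of amplitude $A$ this gives
$A^2$ with no rectifier ripple, and a damped tone's power envelope
decays at twice its amplitude rate. Modal energies are trapezoidal
integrals of these envelopes over a window (5 ms is the conventional
integration window for collision events), reported as fractions together
with the split above/below 1 kHz.

**Two-regime damping estimation.** Below ~200 Hz the scaled wavelet is
tens of milliseconds wide and cannot follow the decay, so damping comes
from a Levenberg–Marquardt fit of
$A e^{-t/\tau}\sin(\omega t + \varphi)$ to the bandpassed trace; the
reported $\tau$ is the amplitude decay time, so
$\zeta = 1/(\omega\tau)$ reproduces the standard worked example (82 Hz,
$\tau = 12.7$ ms $\to \zeta = 0.153$). Above 200 Hz, $\zeta$ comes from
the slope of $\ln|W|$ at the mode's central frequency; the default fit
window opens $\max(1\ \mathrm{ms}, 2.5\sigma_t(f))$ after the onset
(clear of the onset transient smeared by the wavelet), closes where the
ridge has dropped 30 dB, and is refused if it touches the
cone-of-influence margins. The two regimes agree within 10% on tones
near the boundary, which the suite asserts.

**Group delay.** Modal arrival is the power-envelope peak time relative
to the event onset, refined by parabolic interpolation through the three
samples around the maximum (sub-sample precision matters: kilohertz
modes of a 21 mm propagation path arrive within a few hundred
microseconds). The onset must be supplied explicitly — for synthetic
data it is the ground-truth collision time; for measured data the
first threshold crossing of broadband power at 3 times the noise floor
is the recommended convention.

**Young's modulus fit.** All $(l, j, f_n)$ observations of a trimming
series are fitted simultaneously with $E$ as the single adjustable
parameter: frequencies scale as $\sqrt{E}$, with the dimensionless
coefficients recomputed per truncated length by the eigensolver.
Levenberg–Marquardt supplies the estimate, its standard error, and the
Pearson correlation between model and data.

**Spike encoding and information.** Power traces are upsampled 5-fold
(20 to 100 kS/s) by linear interpolation before thresholding; a spike is
emitted at every crossing, up and down, with linearly interpolated
crossing times — the deterministic population-code abstraction of
rapidly adapting mechanoreceptors. Words are single bits per time bin
(spike present/absent). The direct method computes
$S_{total} = -\sum_i p(i)\log_2 p(i)$ over word values,
$S_{noise} = \langle -\sum_i p(i|t)\log_2 p(i|t)\rangle_t$, and
$I = S_{total} - S_{noise}$ (with $0\log 0 = 0$), plus rates per second
and per spike. The jackknife cross-check combines leave-one-out
estimates into $N I - (N-1)\overline{I_{(-j)}}$ and reports the relative
deviation from the direct value as a sampling-bias diagnostic; the two
agree exactly on deterministic ensembles and to a few percent on
low-variability synthetic ensembles. The inter-spike-interval summary
follows the all-pairs-of-spike-bins convention (a consecutive-interval
option exists behind a flag). Bin sizes are interpreted in microseconds
where the sub-millisecond regime is meant: the finest admissible bin is
the 10 µs upsampled sample period, and the plateau of information rate
below the jitter scale is what the bar-code capacity argument rests on.

# The synthetic data generator

The generator produces every input the estimators consume, with the
injected truth attached, under a single root seed (per-trial streams are
derived by fixed offsets; outputs are bit-reproducible and never disturb
the caller's RNG state).

* **Slip-off traces** are sums of damped modal sinusoids plus offset and
  Gaussian noise floor — the free-vibration signal after a pole release.
  Defaults emulate the reference configuration (20 kS/s, modal ladders
  from the eigensolver, $\zeta \propto 1/f$).
* **Texture sweeps** are Poisson point processes of collision events;
  each event excites all modes with a random (or supplied) energy
  partition, as Gaussian-envelope wave packets centered at the
  dispersive arrival time $L/v_g(\omega_j)$, so the envelope-peak delay
  equals the propagation delay by construction. Packet envelope SDs are
  $\max(0.5\ \mathrm{ms}, n_{cyc}/f_j)$; the dispersion-recovery
  fixtures use $n_{cyc} = 4$ so that dense high-order modes stay inside
  their own filter bands (chosen once from the band-spacing/bandwidth
  tradeoff). Sandpaper grit maps monotonically to event rate and
  impulse-magnitude scale — a modeling convention, not a calibration.
* **Trial ensembles** replicate a base trace with Gaussian timing jitter
  (default SD 30 µs, the sub-100 µs PSTH-jitter regime), multiplicative
  amplitude scatter (CV 2%) and fresh noise. No quantitative
  trial-to-trial variability is available to match, so these defaults
  are fixed to the qualitative regime and not tuned further.
* **Traced shapes** integrate a tangent-angle model: intrinsic parabolic
  curvature ($A_{curv} x^2$) plus a contact-induced bending term
  localized in a Gaussian bump (SD 4 mm) at the curvature evaluation
  point. Curvature ramps linearly while pinned, drops through a
  $C^2$ quintic step over the unpinned phase, and relaxes after the
  collision. The whole-frame rotation is defined so the *contact angle*
  follows the pinned/unpinned/collision profile exactly (the
  bending-induced tip rotation is compensated, which a rigid rotation
  permits exactly); the unpinned release then has a closed-form interior
  acceleration peak $5.7735\,\Delta\theta/d^2$, and the velocity kink at
  the collision is the deceleration transient. Companion broadband
  power traces place sharp transients at the collision times.

What passing tests on these fixtures do **not** show: real whiskers have
intrinsic curvature out of the sweep plane, non-ideal taper, medulla
density gradients, follicle (non-clamped) boundary conditions, and
acquisition nonlinearity near the rails — none of which the generator
emulates beyond optional rail clipping and 16-bit quantization. Recovery
accuracy on synthetic data is an upper bound, demonstrating correctness
of the estimators rather than robustness to un-modeled physics.

# Design decisions on open points

* **Units.** Whisker dimensions are conventionally quoted in mm and µm,
  and unit slips are an easy mistake in this domain; constructors
  require an explicit `unit` and keep everything SI internally.
* **Strain-energy convention.** The cantilever strain energy
  $U = F^2 S_{tot}^3/(6EI)$ is evaluated with the area moment at the
  curvature evaluation point $p$, making it algebraically identical to
  the combined form
  $U = \tfrac{\pi}{24}\kappa_p^2 S_{tot}^3 E a_p^4 /
  (r_p^2\cos^2(\theta_p - \theta_{contact}))$; the identity is asserted
  to $10^{-12}$. The area moment $I_p$ [m^4] and the rotational inertia
  $I_{rot}$ [kg m^2] of the impact energy $K = I_{rot}\omega^2/2$ are
  deliberately distinct quantities; $I_{rot}$ is integrated from the
  geometry ($\int \rho\,\pi r(s)^2 s^2\,ds$) when not supplied. The
  formulas' outputs are reported as computed; published walk-through
  energy magnitudes in this field are not force-matched, only the
  dimensionless ratios (conversion efficiency, dB attenuation) are.
* **Spectral readout under heavy damping.** With frequency-independent
  $\alpha = 430$ rad/s, modes 1–3 of the 29 mm reference whisker are
  overdamped or heavily damped; they contribute no usable resonant peak
  and their broad Lorentzians overlap. The simulate–analyze round trip
  therefore reads out the underdamped ladder ($\zeta < 0.05$, a 1.5–7
  kHz band), corrects $f_R \to f_n$, and fits $E$ — a physical
  limitation of spectral peak readout, not of the estimators; the
  time-domain fit route exists precisely for the heavily damped low
  modes.
* **Segmentation thresholds.** Collision = upward crossing of 10x the
  power-trace median (merged within a 15 ms refractory); unpinned =
  start of the last fast curvature drop (rate below -500 m^-1 s^-1)
  before the collision; pinned = start of the contiguous slow-tip
  curvature ramp (rate above +200 m^-1 s^-1, tip speed below 50 deg/s)
  ending at the unpinned transition. All are exposed parameters;
  defaults are calibrated on the synthetic grating fixture, where
  segmentation achieves exact precision/recall with sub-frame timing.
* **Problem sizes.** Tests and the acceptance script use eigensolver
  grids of 250–400 intervals, 0.3–1 s traces at 20 kS/s, spectrograms of
  150–700 log-spaced frequencies, 10-trial ensembles and 200-trial
  independence checks — sizes at which every quantity is converged well
  inside its asserted tolerance while the whole suite runs in well under
  a minute.

# Known limitations

* Euler–Bernoulli only: no shear/rotary-inertia (Timoshenko)
  corrections, no large-deflection nonlinearity, no follicle boundary
  compliance.
* The spectral band partition assumes well-separated resonances;
  closely spaced or overlapping modes (heavy damping, near-degenerate
  geometries) need the time-domain route or are unrecoverable.
* Group velocity uses the uniform-rod dispersion law with the base
  radius; on a strong taper this is the same approximation the field's
  comparison curves make, good to the tens-of-percent level, and the
  synthetic fixtures inject and recover the same convention.
* The spike encoder is deterministic thresholding: information estimates
  are upper bounds that ignore stochastic channel gating, refractoriness
  and spike failures.
* The beating of reflected wave packets visible in measured envelopes is
  reported only through the multi-peak flag of the group-delay routine;
  no velocity estimate is derived from beating periods.
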