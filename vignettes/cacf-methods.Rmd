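---
title: "Coherence-adaptive clutter filtering: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherence-adaptive clutter filtering: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
signal model behind coherence-adaptive clutter filtering (CACF), the
synthetic data that validates it, and the decisions taken where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The problem

Color flow imaging estimates axial blood velocity from the slow-time phase
progression of echoes over an ensemble of K transmissions at the pulse
repetition frequency (PRF). Tissue echoes are roughly 40 dB stronger than
blood, so a slow-time high-pass ("wall") filter must precede velocity
estimation. Any fixed cutoff is a compromise: clutter energy left in a low
cutoff's passband biases velocity toward the clutter velocity, while a
high cutoff removes slow blood signal and biases velocity upward as the
filter reshapes the slow-time spectrum. CACF resolves the compromise per
pixel: channel data are run through a bank of filters, the short-lag
spatial coherence (SLSC) of each output is measured, and the velocity of
the coherence-maximizing filter is emitted. The premise is physical:
diffuse blood scatter at the focus is coherent across the receive aperture
(the van Cittert–Zernike prediction for a uniform transmit aperture of M
elements is the triangle `1 - m/M` in element lag `m`), whereas thermal
noise and reverberation-like clutter are not, so aperture coherence ranks
filter outputs by how much of what remains is blood.

## 2. Acquisition model and analytic relations

The reference configuration (`make_c52v_config()`) is a 128-element convex
array (pitch 0.508 mm, radius 49.57 mm — public transducer values; the
element count, 4-cycle 3.5 MHz pulse, 6 cm focus, F/2 geometry, 3 kHz PRF
and K = 14 are the study conditions). F/2 at 6 cm gives a 3 cm aperture,
i.e. a 60-element transmit aperture; the receive aperture used for
coherence matches it, so lag fractions quoted against the transmit
aperture carry over. Sound speed defaults to 1540 m/s; it is not a
reported quantity but reproduces every printed velocity conversion:
Nyquist velocity `c·PRF/(4 f0)` = 33 cm/s, and cutoff-to-velocity
`c·fc·PRF/(2 f0)` maps 0.03 and 0.34 · PRF to 2.0 and 22.4 cm/s. The RF
sampling rate defaults to 4·f0 (14 MHz), sufficient for the 4-cycle pulse.
Line positions default to 21 beams spanning ±1.2 cm at the focal depth;
all desk-scale studies below use the center line only.

## 3. The synthetic-data generator and its fidelity boundary

`simulate_rf_ensemble()` replaces a full spatial-impulse-response simulator
with first-order point-scatterer superposition: the focused transmit field
at each scatterer is summarized by a narrowband complex weight (sum over
transmit elements of `cos θ / r · exp(-j2πf0 τ)` with focusing delays) and
an amplitude-weighted group delay; each receive element then records the
pulse delayed by the two-way travel time with 1/r spreading and a cosine
obliquity factor. This preserves what the method depends on — focusing,
fully developed speckle statistics, the aperture-coherence triangle,
off-axis sidelobe clutter, and round-trip Doppler phase (`-4π f0 Δz / c`
per axial displacement `Δz`) — at desk scale. It deliberately omits
attenuation, nonlinear propagation, elevation focusing, element directivity
beyond the obliquity cosine, and true multi-path reverberation physics
(reverberation is modeled statistically, below). Passing tests therefore
validate the method's signal-processing claims, not the absolute echo
amplitudes of any particular scanner.

Phantoms (`seed_scatterers()`) fill a block with uniformly placed
scatterers at 15 per focal resolution cell, where the cell is
`(λ·F#)² · (n_cycles·λ/2)`; amplitudes are i.i.d. Gaussian with blood set
40 dB below tissue. Flow (`velocity_field()`) is 0° plug or 50° parabolic
inside a cylindrical vessel (no-slip parabolic profile `1 - (ρ/R)²`),
plus an axial bulk velocity applied to every scatterer. Two readings of
"peak velocity" are possible for angled parabolic flow; the package takes
v0 as the *axial component* on the vessel axis (the along-axis speed is
`v0/cos 50°`), matching how axial-velocity profiles are plotted.
Scatterers are displaced kinematically between emissions
(`position + v·Δt`, Δt = 1/PRF) and are not recycled within one ensemble
(max displacement ≈ 0.8 mm, far below block size); independent
realizations reseed the field.

Two noise models are referenced to the *blood channel power*, the mean
squared RF over the vessel gate of a blood-only simulation (the package
simulates blood and tissue separately and sums them — the simulator is
linear — precisely so this reference is measurable). Thermal noise is
i.i.d. Gaussian across fast time, channel, and slow time with power
`blood_power·10^(-SNR/10)`. Spatially incoherent clutter draws one
band-limited trace per channel (white noise convolved with the transmit
pulse), scaled to `blood_power·10^(level/10)` — the level argument is the
clutter power in dB relative to blood — and adds it to every emission;
clutter motion is a per-emission two-way fast-time delay
(`2·v/c / PRF`, FFT-based band-limited shift), so at zero velocity the
slow-time correlation is exactly 1 and the inter-channel correlation is 0
by construction. One consequence worth knowing: channel-incoherent clutter
is suppressed by the coherent beamsum by a factor M relative to blood, so
at levels near the blood channel power it strongly suppresses *channel
coherence* (and hence drives filter selection) while perturbing the
*beamsum velocity* only mildly; visible velocity bias from clutter
requires either much stronger incoherent clutter or partially coherent
off-axis clutter from bulk motion.

## 4. PI-IIR clutter filters for short ensembles

A conventional IIR high-pass started from rest rings for much of a
14-sample ensemble. The bank (`design_pi_iir()`, `default_bank()`) builds
each filter as an explicit K × K operator `A = F + Z·S·C`: `F` is
zero-state filtering (Toeplitz of the impulse response), `Z` holds the
zero-input responses of the internal states, `C` projects the input onto
polynomials of degree < `proj_degree`, and `S` maps polynomial
coefficients to the steady tracking state the filter would carry had that
polynomial been applied since the infinite past (computed by running the
filter over a long backward extension). A constant input then produces the
steady-state DC response exactly — zero, since the high-pass zeros sit at
z = 1 — with no transient; measured annihilation is below −260 dB against
the −40 dB contract.

Design choices here were genuinely open:

* **Family/order.** Order-4 Chebyshev type I with 0.5 dB ripple, the
  standard choice in the clutter-filter literature; Butterworth is
  available. The passband edge is calibrated by root finding so the −3 dB
  point lands exactly on the quoted cutoff (the design routines take the
  ripple edge, not the −3 dB point).
* **Cutoff set.** Only the range (0.03–0.34 · PRF) and a handful of values
  (0.03, 0.06, 0.09, 0.12, 0.17, 0.26) are fixed by the study; the
  remaining cutoffs fill the range approximately log-uniformly:
  {0.03, 0.045, 0.06, 0.075, 0.09, 0.12, 0.14, 0.17, 0.20, 0.26, 0.30,
  0.34}.
* **Projection degree.** The default is 2 (DC + linear trend), *not* the
  filter order. Each added degree deepens the effective stopband of the
  short-ensemble operator but also captures more of any slow blood tone:
  with degree 4 the operator attenuates the 3 cm/s Doppler line
  (0.0455 · PRF, 0.64 cycles per ensemble) by ≈ 28 dB and distorts its
  lag-one phase upward by tens of percent — it annihilates the slowest
  study velocity outright, which would defeat the low-cutoff members'
  role of preserving slow flow. Degree 2 keeps DC annihilation exact and
  linear-trend suppression while leaving 3 cm/s measurable (≈ −8 dB).
  `proj_degree` is exposed for users who want the minimum-output-energy
  behavior (degree = order).

An intrinsic limit worth stating: *any* linear operator on 14 samples that
annihilates DC distorts the lag-one phase of a 0.64-cycle tone upward (a
pure DC-subtraction already by ≈ +4%, the PI-IIR designs by ≈ +11–16%).
Slow flow near the lowest cutoff is therefore measured with a positive
bias of order 10–20% at K = 14; this is a property of short-ensemble
clutter filtering, not of a particular implementation, and it is why the
slowest plug-flow closure check sits at the edge of its tolerance while
6–18 cm/s recover within a few percent.

## 5. Focusing, coherence, and velocity estimation

`focus_and_demodulate()` forms complex baseband per channel
(`exp(-j2πf0 t)` followed by a zero-phase 49-tap FIR low-pass at f0, which
rejects the 2f0 image) and applies per-pixel dynamic-receive delays
`(|r - beam origin| + |r - element|)/c` by interpolation, rotating by
`exp(+j2πf0 τ)` to keep baseband phases aligned. Pixels outside the
acquisition window are flagged invalid rather than silently extrapolated.

`coherence_function()` offers two estimators of the slow-time-averaged
spatial coherence:

* **point** (default): every pairwise product is normalized to a unit
  phasor before averaging over channel pairs and the ensemble — the
  single-sample-per-pixel form. It is kept as the default because it is
  the canonical written form, but it has a known statistical bias for
  speckle: for jointly circular Gaussian channels the expected phasor mean
  is `(πρ/4)·₂F₁(½,½;2;ρ²)`, which sits 0.06–0.11 *below* the true
  correlation for ρ between 0.65 and 0.97. It is also noisy, since
  low-amplitude (noise-dominated) samples enter with full weight.
* **kernel**: per channel pair and emission, a normalized correlation over
  a small axial gate (default ±2 pixels), averaged afterwards — the
  standard amplitude-weighted SLSC estimator, asymptotically unbiased.

Physics checks against the van Cittert–Zernike triangle (±0.05 over lags
up to 20, 50 seeded speckle realizations) and the noise-scaling law
(independent channel noise at linear SNR `s` scales lag > 0 coherence by
`s/(1+s)`) use the kernel estimator with a wide gate, since the point
form's intrinsic bias exceeds those tolerances by construction. The
experiment runners also select filters with the kernel estimator: with the
point form, per-pixel SLSC noise lets a noticeable fraction of in-vessel
pixels select aggressive cutoffs whose distorted velocities inflate the
adaptive method's absolute-deviation bias by 2–3 percentage points —
selection stability is exactly what the amplitude weighting buys.
`run_cacf(..., coherence_method = "point")` reproduces the literal form
throughout. `slsc()` sums lags 1..Q; Q defaults to 10 (≈ 16% of the
60-element aperture), with Q = 1 the lag-one coherence.

`estimate_velocity()` implements the 2-D autocorrelation estimator on
beam-summed IQ over a 1λ axial kernel (no lateral averaging). The sign
convention is fixed by simulation: motion away from the transducer
increases the round-trip delay, giving a negative slow-time phase
increment, and the leading minus sign in the velocity conversion makes
away-flow positive; a directed test asserts it. Filtering and beam
summation commute (both are linear; a test verifies commutation to 1e-10),
and the package filters before summing.

## 6. The adaptive core and the quality metrics

`run_cacf()` demodulates once, then per bank member filters the channel
IQ, computes per-pixel SLSC and velocity, and selects the argmax member
per pixel; the output velocity is copied bit-exact from the winner. Exact
ties (within 1e-12) break toward the lower cutoff — when coherence cannot
discriminate, the member that preserves more signal is preferred — with
the identity ranked lowest; a tie flag is set. Pixels whose coherence is
undefined everywhere (all-zero data) are flagged invalid, not defaulted.
Frames and pixels are processed independently; no spatial regularization
is applied to the selection map.

`velocity_bias()` and `velocity_sd()` are normalized mean *absolute*
deviations (from truth, and from the across-realization mean profile),
scaled by the peak true speed; `combined_error()` takes their maximum.
The written S.D. form carries a per-term square root that reduces each
summand to an absolute deviation; the package implements that literal
reading as the default and provides `mode = "rms"` for the conventional
root-mean-square definition, without attempting to adjudicate between
them. Both metrics are scale-equivariant (a property test asserts it).
Because the metrics are absolute deviations, *any* estimator variance —
including speckle realization noise on a small ROI — enters "bias"; at
desk scale this sets a floor of a few percent for every method, shared by
all of them.

## 7. Desk-scale study geometry

The experiment runners reproduce the study designs at a reduced size
chosen so a full condition grid runs in minutes on one core:

* block 14 × 10 × 1 mm centered on the 6 cm focus (tests use 10 × 8 × 1
  mm), 15 scatterers per resolution cell (≈ 3000 scatterers);
* one imaging line through the vessel center; pixels every 0.11 mm
  (λ/4) over ±2.5 mm; ROI = ±1 mm about the vessel center (the reduced
  analogue of the 5 × 2 mm ROI, axial extent preserved);
* vessel diameter 1 cm (6 mm at test scale) with the axis along the beam
  for 0° plug flow and at 50° in-plane for parabolic flow;
* N_p = 5 independent seeded realizations per condition ("number of
  profiles" is realized as independent realizations of the center-line
  profile); condition grids use the study ranges — clutter velocity −3..3
  cm/s, clutter level −10..10 dB re blood, bulk 0..3 cm/s, v0 3..18 cm/s,
  thermal SNR 10 dB unless stated.

The uniform-motion texture study (velocity spread versus Q at high SNR)
references its thermal noise to the translating slab's own channel power;
the slab contains no blood, and referencing 40 dB below it would make the
noise invisible to every filter output, leaving coherence unable to rank
filters at all.

## 8. Numerical choices and degenerate inputs

Seeds: every stochastic component takes an explicit seed and restores the
caller's RNG state; experiment runners derive per-condition,
per-realization child seeds (kept below 2^31) from one base seed, so runs
are bit-reproducible. Fast-time windows are derived from the scatterer
geometry with three pulse-length margins and can be pinned explicitly so
separately simulated components sum sample-exact. Stability of every IIR
design is checked against the unit circle (1e-10 margin); the steady
tracking state is computed over a 2000-sample pre-roll, comfortably beyond
the slowest pole's decay. Zero-magnitude channel samples are excluded from
coherence averages; all-zero pixels yield NA and an invalid flag that
propagates through selection. Velocity on an all-zero kernel is NA. The
DC-annihilation contract is asserted at −40 dB though the construction
achieves ≈ −260 dB.

## 9. Known limitations

* The simulator's narrowband transmit summary slightly misplaces pulse
  envelopes away from the focus; off-axis round-trip geometry biases
  plug-flow velocity low by a few percent across the 1 cm vessel — a real
  physical effect, but one the desk-scale ROI cannot average away.
* Short-ensemble clutter filtering distorts sub-cycle tones upward (see
  §4); slow-flow accuracy at the lowest cutoffs is limited by K, not by
  implementation.
* Incoherent clutter at levels near the blood channel power drives filter
  *selection* but barely moves beamsum velocity (see §3); bulk-motion
  off-axis clutter is the mechanism that visibly biases low-cutoff
  velocity estimates.
* Aliased, turbulent, pulsatile, or out-of-plane flow, wall compliance,
  eigen-/SVD-based filtering, and alternative coherence factors are out of
  scope.
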