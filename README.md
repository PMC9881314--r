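# cacf: Coherence-Adaptive Clutter Filtering for Ultrasound Color Flow Imaging

Color flow Doppler estimates blood velocity from the slow-time phase of
echoes collected over an ensemble of K transmissions at the pulse
repetition frequency (PRF). Before the velocity is estimated, a high-pass
*clutter filter* must remove echoes from tissue — typically 40 dB stronger
than blood — together with reverberation and bulk-motion artifact. A fixed
filter cutoff is always a compromise: too low, and slow-moving clutter
biases the estimate downward; too high, and slow blood flow is removed,
biasing it upward. `cacf` implements **coherence-adaptive clutter
filtering**: at every imaging pixel, the channel data are passed through a
bank of clutter filters and the filter whose output maximizes the local
*short-lag spatial coherence* (SLSC) is selected; that filter's velocity
estimate becomes the output pixel. Spatial coherence acts as a per-pixel
image-quality feedback signal, because clutter and noise decorrelate the
receive aperture while blood echoes do not.

The package is aimed at ultrasound signal-processing researchers. It is
self-contained: a point-scatterer channel simulator generates all inputs
(flow phantoms, thermal noise, spatially incoherent moving clutter, bulk
motion), so every result can be regenerated from a seed.

## The method

For time-delayed complex IQ channel signals `u_i[r, k]` at receive element
`i`, pixel `r`, and slow-time sample `k`, the slow-time-averaged spatial
coherence at element lag `m` is

    R[m; r] = Re{ 1/(K (M - m)) * sum_k sum_i
                  u_i[r,k] conj(u_{i+m}[r,k]) / (|u_i[r,k]| |u_{i+m}[r,k]|) }

and its short-lag integral is `SLSC[r] = sum_{m=1..Q} R[m; r]` (Q = 1 is
the lag-one coherence). Velocities come from the 2-D autocorrelation
(Kasai) estimator on beam-summed IQ with a one-wavelength axial kernel:

    phi[r] = Arg sum_{k=1..K-1} sum_{r' in kernel} u[r', k+1] conj(u[r', k])
    v[r]   = -(c * PRF / (4 * pi * f0)) * phi[r]

Clutter filters are projection-initialized IIR (PI-IIR) high-pass filters:
order-4 Chebyshev type I designs applied as K x K matrix operators whose
internal states are initialized from the input's projection onto low-degree
polynomials, so stationary clutter is annihilated (≤ −40 dB; in practice
≈ −260 dB) without the start-up transient that makes plain IIR filters
unusable on 14-sample ensembles. The default bank holds 12 filters with
−3 dB cutoffs from 0.03 to 0.34 · PRF (90 Hz to 1.02 kHz; velocity cutoffs
2.0 to 22.4 cm/s) plus a "no filter" identity member. The coherence-adaptive
output selects, per pixel, the bank member maximizing SLSC (ties go to the
lower cutoff) and copies its velocity.

Image quality is summarized by the normalized mean absolute deviation from
the ground truth (`Bias`), the spread about the across-realization mean
profile (`S.D.`), and `Error = max(Bias, S.D.)`.

## Worked example

Simulate a tiny plug-flow vessel phantom (6 cm/s axial flow, tissue 40 dB
above blood, 10 dB thermal channel SNR) and run the adaptive filter:

```r
library(cacf)
cfg  <- make_c52v_config()   # C5-2v array, 3.5 MHz, 6 cm focus, K = 14
bank <- default_bank(cfg$ensemble_length)
fx   <- make_fixture("plug_vessel", scale = "tiny", seed = 1, v0 = 0.06)
ens  <- add_thermal_noise(fx$ensemble, 10, fx$blood_power, rng_seed = 2)
res  <- run_cacf(ens, bank, fx$depths, Q = 10, coherence_method = "kernel")

roi <- fx$depths >= 0.059 & fx$depths <= 0.061
round(100 * c(cacf      = mean(res$velocity[roi]),
              no_filter = mean(res$velocity_by_filter[roi, 1]),
              fc003     = mean(res$velocity_by_filter[roi, 2])), 2)
#>      cacf no_filter     fc003
#>      5.67      3.90      5.67
```

Without filtering, stationary tissue drags the estimate down to 3.9 cm/s;
the adaptive filter selects the 0.03 · PRF member at every in-vessel pixel
(slow flow must not be over-filtered) and recovers 5.67 cm/s of the
programmed 6 cm/s. `run_experiment()` scales this up to condition grids
(clutter velocity, bulk motion, peak velocity, SNR) with seeded
realizations and tidy CSV output, and `simulate_condition()` exposes a
single seeded realization with all per-filter diagnostics.

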