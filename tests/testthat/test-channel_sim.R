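test_that("simulator is linear and symmetric", {
  cfg <- two_element_cfg()
  # single on-axis scatterer, two elements symmetric about the beam axis:
  # identical delayed pulses on both channels
  f <- single_scatterer_field(c(0, 0, 0.06))
  ens <- simulate_rf_ensemble(f, cfg)
  expect_equal(ens$samples[, 1, 1], ens$samples[, 2, 1])
  expect_equal(ens$samples[, , 1], ens$samples[, , 2])  # static: identical
  expect_gt(max(abs(ens$samples)), 0)
  # doubling amplitude doubles the RF exactly
  f2 <- single_scatterer_field(c(0, 0, 0.06), amp = 2)
  ens2 <- simulate_rf_ensemble(f2, cfg,
                               time_window = c(ens$t0, ens$t0 +
                                 (dim(ens$samples)[1] - 1) / ens$fs))
  expect_equal(ens2$samples, 2 * ens$samples, tolerance = 1e-12)
  # superposition: simulate(a) + simulate(b) == simulate(a + b)
  fa <- single_scatterer_field(c(-0.001, 0, 0.059), amp = 0.7)
  fb <- single_scatterer_field(c(0.001, 0, 0.061), amp = -1.2)
  fab <- single_scatterer_field(rbind(c(-0.001, 0, 0.059),
                                      c(0.001, 0, 0.061)),
                                amp = c(0.7, -1.2))
  win <- c(7e-5, 8.4e-5)
  sa <- simulate_rf_ensemble(fa, cfg, time_window = win)$samples
  sb <- simulate_rf_ensemble(fb, cfg, time_window = win)$samples
  sab <- simulate_rf_ensemble(fab, cfg, time_window = win)$samples
  expect_equal(sa + sb, sab, tolerance = 1e-12)
})

test_that("empty scatterer fields yield a zero ensemble with a warning", {
  cfg <- two_element_cfg()
  empty <- single_scatterer_field(matrix(numeric(0), 0, 3),
                                  amp = numeric(0))
  expect_warning(ens <- simulate_rf_ensemble(empty, cfg), "empty")
  expect_true(all(ens$samples == 0))
})

test_that("axial motion produces the round-trip Doppler phase", {
  cfg <- make_c52v_config()
  lam <- cfg$pulse$wavelength
  f <- single_scatterer_field(c(0, 0, cfg$focal_depth))
  flds <- lapply(seq_len(cfg$ensemble_length), function(k) {
    g <- f
    g$positions[, 3] <- g$positions[, 3] + (k - 1) * lam / 8
    g
  })
  ens <- simulate_rf_ensemble(flds, cfg)
  depths <- seq(0.0594, 0.0606, by = 1.1e-4)
  bs <- beamsum(focus_and_demodulate(ens, depths))
  p <- which.min(abs(depths - 0.06))
  step <- Arg(sum(bs$iq[p, 2:4] * Conj(bs$iq[p, 1:3])))
  expect_equal(step, -pi / 2, tolerance = 0.05 * pi / 2)
})

test_that("blood channel power measurement scales and validates", {
  cfg <- two_element_cfg()
  f <- single_scatterer_field(c(0, 0, 0.06))
  ens <- simulate_rf_ensemble(f, cfg)
  p1 <- measure_blood_channel_power(ens, c(0.055, 0.065))
  expect_gt(p1, 0)
  ens3 <- ens
  ens3$samples <- 3 * ens$samples
  expect_equal(measure_blood_channel_power(ens3, c(0.055, 0.065)), 9 * p1)
  ens0 <- ens
  ens0$samples[] <- 0
  expect_equal(measure_blood_channel_power(ens0, c(0.055, 0.065)), 0)
  expect_error(measure_blood_channel_power(ens, c(0.5, 0.6)), "outside")
})

test_that("thermal noise has the requested power and no channel correlation", {
  cfg <- make_c52v_config()
  fx <- make_fixture("noise_only", seed = 4, snr_t_db = 0)
  ens <- fx$ensemble  # unit reference power, 0 dB SNR
  n <- length(ens$samples)
  expect_gt(n, 1e5)
  expect_equal(mean(ens$samples^2), 1, tolerance = 0.01)
  # channel pairs uncorrelated: |rho| < 3/sqrt(n_samples)
  x <- ens$samples[, 1, 1]
  y <- ens$samples[, 2, 1]
  expect_lt(abs(cor(x, y)), 3 / sqrt(length(x)))
  # +Inf SNR leaves the ensemble untouched
  expect_identical(add_thermal_noise(ens, Inf, 1, 1), ens)
  # determinism
  z0 <- single_scatterer_field(matrix(numeric(0), 0, 3), amp = numeric(0))
  e1 <- suppressWarnings(simulate_rf_ensemble(z0, cfg))
  expect_identical(add_thermal_noise(e1, 10, 1, 77)$samples,
                   add_thermal_noise(e1, 10, 1, 77)$samples)
})

test_that("incoherent clutter is channel-incoherent and slow-time coherent", {
  cfg <- make_c52v_config()
  fx <- make_fixture("clutter_only", seed = 5, clutter_db = 0,
                     clutter_velocity = 0)
  s <- fx$ensemble$samples
  k <- dim(s)[3]
  # static clutter: slow-time correlation exactly 1 (identical traces)
  for (ki in 2:k) expect_identical(s[, 3, ki], s[, 3, 1])
  # channel incoherence: mean |correlation| over many pairs is small
  m <- dim(s)[2]
  set.seed(1)
  pairs <- cbind(sample(m, 100, replace = TRUE),
                 sample(m, 100, replace = TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  rho <- apply(pairs, 1, function(ij) cor(s[, ij[1], 1], s[, ij[2], 1]))
  expect_lt(mean(abs(rho)), 0.05)
  # requested power is delivered per channel
  expect_equal(mean(s^2), 1, tolerance = 0.05)
  expect_error(make_incoherent_clutter(fx$ensemble, 0, 0.4, 1, cfg, 1),
               "Nyquist")
})

test_that("moving clutter carries its programmed Doppler velocity", {
  cfg <- make_c52v_config()
  fx <- make_fixture("clutter_only", seed = 6, clutter_db = 0,
                     clutter_velocity = -0.02)
  depths <- seq(0.0585, 0.0615, by = 1.1e-4)
  vm <- estimate_velocity(beamsum(focus_and_demodulate(fx$ensemble, depths)),
                          cfg)
  expect_equal(mean(vm$velocity, na.rm = TRUE), -0.02, tolerance = 0.1)
})
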