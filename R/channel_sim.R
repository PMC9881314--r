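# Point-scatterer RF channel simulator.
#
# First-order model: a focused transmit is formed by summing spherical waves
# from each transmit element (1/r spreading, cosine obliquity, focusing
# delays to the focal point). The narrowband transmit field at scatterer s is
# summarized by a complex weight W(s) at f0 and an amplitude-weighted group
# delay; each receive element then records a delayed, scaled replica of the
# pulse. This preserves focusing, speckle statistics and off-axis clutter
# phenomenology without spatial-impulse-response integration.

# Narrowband transmit field summary at scatterer positions for one beam.
tx_field <- function(pos, cfg, beam) {
  geom <- cfg$geometry
  f0 <- cfg$pulse$f0
  c0 <- cfg$pulse$c
  els <- beam$tx_elements
  epos <- geom$element_positions[els, , drop = FALSE]
  enrm <- geom$element_normals[els, , drop = FALSE]
  # focusing delays aligning arrivals at the focal point
  d_focus <- sqrt(rowSums(sweep(epos, 2, beam$focus)^2))
  delay <- (cfg$focal_depth - d_focus) / c0
  n <- nrow(pos)
  w_re <- numeric(n); w_im <- numeric(n)
  tw <- numeric(n); wsum <- numeric(n)
  for (j in seq_along(els)) {
    dx <- pos[, 1] - epos[j, 1]
    dy <- pos[, 2] - epos[j, 2]
    dz <- pos[, 3] - epos[j, 3]
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    obl <- pmax(0, (dx * enrm[j, 1] + dy * enrm[j, 2] + dz * enrm[j, 3]) / d)
    w <- obl / pmax(d, 1e-6)
    tj <- d / c0 + delay[j]
    phase <- -2 * pi * f0 * tj
    w_re <- w_re + w * cos(phase)
    w_im <- w_im + w * sin(phase)
    tw <- tw + w * tj
    wsum <- wsum + w
  }
  list(amp = sqrt(w_re^2 + w_im^2), phase = atan2(w_im, w_re),
       group_delay = tw / pmax(wsum, 1e-300))
}

#' Simulate an RF channel ensemble for one imaging line
#'
#' Synthesizes per-element RF echoes from point scatterers for each of the K
#' slow-time emissions of a color flow ensemble. Each scatterer contributes
#' `a_s * |W_tx(s)| * cos(theta_i) / r_i` times the transmit pulse delayed by
#' the two-way travel time, where `W_tx` is the focused narrowband transmit
#' field and `cos(theta_i)` a receive obliquity factor. The simulator is
#' linear in scatterer amplitude.
#'
#' @param fields List of K `cacf_scatterers`, one per emission (see
#'   [flow_ensemble_fields()]); a single field is replicated K times
#'   (stationary medium).
#' @param cfg A `cacf_config`.
#' @param line_index Index into `cfg$line_angles` (default: center line).
#' @param time_window Optional `c(t0, t1)` fast-time window in seconds;
#'   derived from the scatterer depth span when omitted.
#' @return An object of class `cacf_ensemble`: `samples` (fast-time x channel
#'   x slow-time RF array), `fs`, `t0`, `prf`, `f0`, `cfg`, `line_index`,
#'   `beam`.
#' @export
simulate_rf_ensemble <- function(fields, cfg, line_index = NULL,
                                 time_window = NULL) {
  if (inherits(fields, "cacf_scatterers")) {
    fields <- rep(list(fields), cfg$ensemble_length)
  }
  k <- cfg$ensemble_length
  if (length(fields) != k) stop("need one scatterer field per emission")
  if (is.null(line_index)) line_index <- (length(cfg$line_angles) + 1L) %/% 2L
  beam <- line_beam(cfg, line_index)
  fs <- cfg$pulse$fs
  tp <- cfg$pulse$duration
  c0 <- cfg$pulse$c
  m <- length(beam$rx_elements)
  epos <- cfg$geometry$element_positions[beam$rx_elements, , drop = FALSE]
  enrm <- cfg$geometry$element_normals[beam$rx_elements, , drop = FALSE]
  n_sc <- nrow(fields[[1]]$positions)

  if (is.null(time_window)) {
    if (n_sc > 0) {
      zr <- range(vapply(fields, function(f) range(f$positions[, 3]),
                         numeric(2)))
      # conservative two-way span: shortest on-axis path to longest
      # oblique path across the receive aperture
      pmax_xy <- max(abs(fields[[1]]$positions[, 1] - beam$origin[1])) +
        max(abs(epos[, 1])) + 0.002
      time_window <- c(2 * max(0, zr[1] - 0.002) / c0 - 3 * tp,
                       (zr[2] + sqrt(zr[2]^2 + pmax_xy^2)) / c0 + 3 * tp)
    } else {
      time_window <- c(0, 2 * (cfg$focal_depth + 0.01) / c0)
    }
  }
  t0 <- time_window[1]
  nt <- as.integer(floor((time_window[2] - t0) * fs + 1e-6)) + 1L
  rf <- array(0, dim = c(nt, m, k))
  env_type <- if (cfg$pulse$envelope == "hann") 0L else 1L

  if (n_sc == 0) {
    warning("empty scatterer field: returning all-zero ensemble")
  } else {
    f0 <- cfg$pulse$f0
    for (ki in seq_len(k)) {
      pos <- fields[[ki]]$positions
      a <- fields[[ki]]$amplitudes
      tx <- tx_field(pos, cfg, beam)
      psi <- 2 * pi * f0 * tx$group_delay + tx$phase
      amp_tx <- a * tx$amp
      for (i in seq_len(m)) {
        dx <- pos[, 1] - epos[i, 1]
        dy <- pos[, 2] - epos[i, 2]
        dz <- pos[, 3] - epos[i, 3]
        d <- sqrt(dx * dx + dy * dy + dz * dz)
        obl <- pmax(0, (dx * enrm[i, 1] + dy * enrm[i, 2] + dz * enrm[i, 3]) / d)
        rf[, i, ki] <- rf_deposit(tx$group_delay + d / c0,
                                  amp_tx * obl / pmax(d, 1e-6), psi,
                                  t0, 1 / fs, nt, f0, tp, env_type,
                                  rf[, i, ki])
      }
    }
  }
  structure(list(samples = rf, fs = fs, t0 = t0, prf = cfg$prf,
                 f0 = cfg$pulse$f0, cfg = cfg, line_index = line_index,
                 beam = beam),
            class = "cacf_ensemble")
}

#' @export
print.cacf_ensemble <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<cacf_ensemble> %d fast-time x %d channels x %d slow-time, fs=%.1f MHz\n",
              d[1], d[2], d[3], x$fs / 1e6))
  invisible(x)
}

#' Mean channel signal power over a depth gate
#'
#' Mean squared RF amplitude over the fast-time gate spanning the two-way
#' travel times of `depth_range`, across all channels and emissions. Run on
#' an ensemble simulated from blood-only scatterers this gives the blood
#' channel power that noise and clutter levels are referenced to.
#'
#' @param ens A `cacf_ensemble`.
#' @param depth_range `c(zmin, zmax)` in metres.
#' @return Mean power (linear units).
#' @export
measure_blood_channel_power <- function(ens, depth_range) {
  c0 <- ens$cfg$pulse$c
  t <- ens$t0 + (seq_len(dim(ens$samples)[1]) - 1L) / ens$fs
  gate <- t >= 2 * depth_range[1] / c0 & t <= 2 * depth_range[2] / c0
  if (!any(gate)) stop("ROI depth gate lies outside the acquisition window")
  mean(ens$samples[gate, , , drop = FALSE]^2)
}

#' Add thermal channel noise
#'
#' Adds i.i.d. zero-mean Gaussian samples, independent across fast-time,
#' channel and slow-time, with variance `blood_power * 10^(-snr_db/10)`.
#' `snr_db` is the thermal channel SNR relative to the blood channel signal
#' power; `Inf` leaves the ensemble unchanged.
#'
#' @param ens A `cacf_ensemble`.
#' @param snr_db Channel SNR in dB relative to blood signal power.
#' @param blood_power Blood channel power (see
#'   [measure_blood_channel_power()]).
#' @param rng_seed Integer seed.
#' @return The noisy `cacf_ensemble`.
#' @export
add_thermal_noise <- function(ens, snr_db, blood_power, rng_seed) {
  if (is.infinite(snr_db) && snr_db > 0) return(ens)
  stopifnot(blood_power > 0)
  sdv <- sqrt(blood_power * 10^(-snr_db / 10))
  with_seed(rng_seed, {
    ens$samples <- ens$samples + array(rnorm(length(ens$samples), sd = sdv),
                                       dim = dim(ens$samples))
  })
  ens
}

#' Add spatially incoherent, slow-time coherent clutter
#'
#' Models reverberation-like clutter: for each channel independently, one
#' band-limited Gaussian noise trace (white noise convolved with the transmit
#' pulse) is drawn and added to every emission; motion at `clutter_velocity`
#' is realized as a per-emission two-way fast-time delay of that trace
#' (FFT-based band-limited shift). The clutter is therefore uncorrelated
#' between channels (rho_c = 0) and, at zero velocity, perfectly correlated
#' across slow-time (rho_t = 1). Per-channel clutter power is
#' `blood_power * 10^(snr_db/10)`, i.e. `snr_db` is the clutter level in dB
#' relative to the blood channel signal power (the SNR_c,s convention).
#'
#' @param ens A `cacf_ensemble`.
#' @param snr_db Clutter level in dB relative to blood channel power.
#' @param clutter_velocity Axial clutter velocity in m/s; must be below the
#'   Nyquist velocity in magnitude.
#' @param blood_power Blood channel power.
#' @param cfg A `cacf_config`.
#' @param rng_seed Integer seed.
#' @return The cluttered `cacf_ensemble`.
#' @export
make_incoherent_clutter <- function(ens, snr_db, clutter_velocity, blood_power,
                                    cfg, rng_seed) {
  if (abs(clutter_velocity) >= nyquist_velocity(cfg)) {
    stop("clutter velocity must be below the Nyquist velocity")
  }
  stopifnot(blood_power > 0)
  d <- dim(ens$samples)
  nt <- d[1]; m <- d[2]; k <- d[3]
  target <- blood_power * 10^(snr_db / 10)
  # transmit pulse for band-limiting
  tp <- cfg$pulse$duration
  fs <- ens$fs
  tpul <- seq(-tp / 2, tp / 2, by = 1 / fs)
  env <- if (cfg$pulse$envelope == "hann") {
    0.5 * (1 + cos(2 * pi * tpul / tp))
  } else {
    exp(-0.5 * (tpul / (tp / 4))^2)
  }
  pul <- env * cos(2 * pi * cfg$pulse$f0 * tpul)
  pw <- c(pul, rep(0, nt - length(pul)))
  pf <- fft(pw)
  freqs <- (seq_len(nt) - 1L) / nt * fs
  freqs[freqs > fs / 2] <- freqs[freqs > fs / 2] - fs  # signed frequencies
  dtau <- (2 * clutter_velocity / cfg$pulse$c) / cfg$prf
  with_seed(rng_seed, {
    for (i in seq_len(m)) {
      w <- rnorm(nt)
      nf <- fft(w) * pf  # circular band-limited noise, stationary
      base <- Re(fft(nf, inverse = TRUE)) / nt
      base <- base * sqrt(target / mean(base^2))
      bf <- fft(base)
      for (ki in seq_len(k)) {
        shift <- (ki - 1L) * dtau
        tr <- if (shift == 0) base else {
          Re(fft(bf * exp(-2i * pi * freqs * shift), inverse = TRUE)) / nt
        }
        ens$samples[, i, ki] <- ens$samples[, i, ki] + tr
      }
    }
  })
  ens
}
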