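# Beamsum and 2-D autocorrelation (Kasai) axial velocity estimation.

#' Coherent beamsum of focused channel IQ
#'
#' Unweighted complex sum across the receive channels, per pixel and
#' emission.
#'
#' @param iq A `cacf_iq`.
#' @return An object of class `cacf_beamsum`: `iq` (pixel x slow-time
#'   complex matrix), `depths`, `cfg`, `valid`.
#' @export
beamsum <- function(iq) {
  u <- iq$iq
  bs <- apply(u, c(1, 3), sum)
  structure(list(iq = bs, depths = iq$depths, cfg = iq$cfg,
                 valid = iq$valid, pixel_pitch = iq$pixel_pitch),
            class = "cacf_beamsum")
}

#' Axial kernel extent from a wavelength count
#'
#' @param n_lambda Kernel length in wavelengths (> 0).
#' @param cfg A `cacf_config`.
#' @return Axial extent in metres (`n_lambda * c / f0`).
#' @export
kernel_from_wavelengths <- function(n_lambda, cfg) {
  if (n_lambda <= 0) stop("n_lambda must be > 0")
  n_lambda * cfg$pulse$c / cfg$pulse$f0
}

#' 2-D autocorrelation (Kasai) velocity estimate
#'
#' Estimates per-pixel axial velocity from the phase of the lag-one
#' slow-time autocorrelation of beam-summed IQ, averaged over the K - 1
#' slow-time pairs and an axial kernel:
#' `phi[r] = Arg sum_k sum_{r' in kernel} u[r', k+1] u*[r', k]`,
#' `v = -(c * PRF / (4 pi f0)) * phi`. With this sign convention motion away
#' from the transducer (increasing depth) yields positive velocity.
#'
#' @param bs A `cacf_beamsum`.
#' @param cfg A `cacf_config` (defaults to the one carried by `bs`).
#' @param kernel Axial kernel extent in metres (default one wavelength, see
#'   [kernel_from_wavelengths()]).
#' @return An object of class `cacf_velocity_map`: `velocity` (m/s),
#'   `phase` (rad), `depths`, `kernel`, `valid`.
#' @export
estimate_velocity <- function(bs, cfg = NULL, kernel = NULL) {
  cfg <- cfg %||% bs$cfg
  u <- bs$iq
  np <- nrow(u); k <- ncol(u)
  if (k < 2) stop("need at least two slow-time samples")
  if (is.null(kernel)) kernel <- kernel_from_wavelengths(1, cfg)
  lag1 <- rowSums(u[, 2:k, drop = FALSE] * Conj(u[, 1:(k - 1), drop = FALSE]))
  if (!is.na(bs$pixel_pitch) && np > 1) {
    half_px <- floor((kernel / 2) / bs$pixel_pitch)
    width <- 2L * half_px + 1L
    lag1 <- running_sum(Re(lag1), width)[, 1] +
      1i * running_sum(Im(lag1), width)[, 1]
  }
  phase <- Arg(lag1)
  undefined <- Mod(lag1) == 0 | is.na(lag1)
  phase[undefined] <- NA_real_
  v <- -(cfg$pulse$c * cfg$prf / (4 * pi * cfg$pulse$f0)) * phase
  structure(list(velocity = v, phase = phase, depths = bs$depths,
                 kernel = kernel, valid = bs$valid & !undefined),
            class = "cacf_velocity_map")
}
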