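# Receive focusing, baseband demodulation, and spatial coherence.

#' Focus and demodulate a channel ensemble to per-pixel IQ
#'
#' Converts RF channel data to complex baseband (multiplication by
#' `exp(-j 2 pi f0 t)` followed by a low-pass FIR at the carrier frequency)
#' and applies per-pixel dynamic-receive delays
#' `tau_i(r) = (|r - beam origin| + |r - element_i|) / c`, sampling each
#' channel's baseband at the delayed time and phase-rotating by
#' `exp(+j 2 pi f0 tau_i)` so focused channels are phase aligned.
#'
#' Pixels are placed on the beam axis at the requested depths (one line per
#' ensemble); pixels whose delays fall outside the acquisition window are
#' flagged invalid (all-NA channels).
#'
#' @param ens A `cacf_ensemble`.
#' @param depths Axial pixel depths along the beam in metres.
#' @param lpf_taps Length of the baseband low-pass FIR (odd; default 49).
#' @return An object of class `cacf_iq`: `iq` (pixel x channel x slow-time
#'   complex array), `depths`, `pixel_positions`, `cfg`, `beam`, `valid`.
#' @export
focus_and_demodulate <- function(ens, depths, lpf_taps = 49) {
  d <- dim(ens$samples)
  nt <- d[1]; m <- d[2]; k <- d[3]
  cfg <- ens$cfg
  f0 <- ens$f0
  fs <- ens$fs
  c0 <- cfg$pulse$c
  t <- ens$t0 + (seq_len(nt) - 1L) / fs
  carrier <- exp(-2i * pi * f0 * t)

  # complex baseband, zero-phase FIR low-pass at f0 (keeps the pulse band,
  # rejects the 2*f0 image)
  h <- signal::fir1(lpf_taps - 1, f0 / (fs / 2))
  bb <- matrix(complex(real = as.vector(ens$samples)), nt, m * k)
  bb <- bb * carrier
  bbf <- stats::filter(Re(bb), h, sides = 2) +
    1i * stats::filter(Im(bb), h, sides = 2)
  bbf[is.na(bbf)] <- 0
  bbf <- matrix(bbf, nt, m * k)

  beam <- ens$beam
  pix <- t(vapply(depths, function(z) beam$origin + z * beam$dir, numeric(3)))
  epos <- cfg$geometry$element_positions[beam$rx_elements, , drop = FALSE]
  np <- length(depths)
  iq <- array(NA_complex_, dim = c(np, m, k))
  trange <- range(t)
  valid <- rep(TRUE, np)
  for (i in seq_len(m)) {
    di <- dist_to_point(pix, epos[i, ])
    tau <- (depths + di) / c0
    out_of_window <- tau < trange[1] | tau > trange[2]
    valid <- valid & !out_of_window
    rot <- exp(2i * pi * f0 * tau)
    for (ki in seq_len(k)) {
      col <- bbf[, (ki - 1L) * m + i]
      re <- approx(t, Re(col), xout = tau, rule = 1)$y
      im <- approx(t, Im(col), xout = tau, rule = 1)$y
      iq[, i, ki] <- complex(real = re, imaginary = im) * rot
    }
  }
  structure(list(iq = iq, depths = depths, pixel_positions = pix, cfg = cfg,
                 beam = beam, valid = valid,
                 pixel_pitch = if (np > 1) mean(diff(depths)) else NA_real_),
            class = "cacf_iq")
}

#' @export
print.cacf_iq <- function(x, ...) {
  d <- dim(x$iq)
  cat(sprintf("<cacf_iq> %d pixels x %d channels x %d slow-time\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Slow-time-averaged spatial coherence function
#'
#' Normalized cross-correlation of focused channel signals as a function of
#' element lag m, averaged over channel pairs and the slow-time ensemble;
#' the real part is reported.
#'
#' Two estimators are available. `"point"` (the default) normalizes each
#' pairwise product to a unit phasor before averaging:
#' `R[m] = Re mean_{k,i} u_i u*_{i+m} / (|u_i| |u_{i+m}|)`, a single sample
#' per pixel. `"kernel"` computes, per channel pair and emission, a
#' normalized correlation over an axial gate around the pixel
#' (`sum u_i u*_{i+m} / sqrt(sum |u_i|^2 sum |u_{i+m}|^2)`) and averages its
#' real part; this is the standard short-lag spatial coherence kernel
#' estimator and, unlike the point form, is asymptotically unbiased for
#' speckle statistics checks.
#'
#' Zero-magnitude samples are excluded from the average; pixels with no
#' valid terms at a lag get `NA` there.
#'
#' @param iq A `cacf_iq`.
#' @param lags Integer lags (default `0:(M-1)`).
#' @param method `"point"` or `"kernel"`.
#' @param kernel_halfwidth Axial gate half-width in pixels for the kernel
#'   estimator (default 2).
#' @return Matrix of class `cacf_coherence`, pixels x lags, with attributes
#'   `lags` and `method`. `R[, m = 0] = 1` for any nonzero input.
#' @export
coherence_function <- function(iq, lags = NULL,
                               method = c("point", "kernel"),
                               kernel_halfwidth = 2) {
  method <- match.arg(method)
  u <- iq$iq
  d <- dim(u)
  np <- d[1]; m <- d[2]; k <- d[3]
  if (m < 2) stop("need at least two channels")
  if (is.null(lags)) lags <- 0:(m - 1)
  stopifnot(all(lags >= 0), all(lags <= m - 1))
  R <- matrix(NA_real_, np, length(lags))

  if (method == "point") {
    mag <- Mod(u)
    ph <- u / ifelse(mag > 0, mag, 1)
    ph[mag == 0 | is.na(mag)] <- NA_complex_
    for (li in seq_along(lags)) {
      mm <- lags[li]
      a1 <- ph[, seq_len(m - mm), , drop = FALSE]
      a2 <- Conj(ph[, seq_len(m - mm) + mm, , drop = FALSE])
      pr <- Re(a1 * a2)
      dim(pr) <- c(np, (m - mm) * k)
      R[, li] <- rowMeans(pr, na.rm = TRUE)
      R[rowSums(!is.na(pr)) == 0, li] <- NA_real_
    }
  } else {
    width <- 2L * as.integer(kernel_halfwidth) + 1L
    pw <- Mod(u)^2
    dim(pw) <- c(np, m * k)
    pw_s <- running_sum(pw, width)
    dim(pw_s) <- c(np, m, k)
    for (li in seq_along(lags)) {
      mm <- lags[li]
      idx1 <- seq_len(m - mm)
      a1 <- u[, idx1, , drop = FALSE]
      a2 <- Conj(u[, idx1 + mm, , drop = FALSE])
      num <- a1 * a2
      dim(num) <- c(np, (m - mm) * k)
      num_re <- running_sum(Re(num), width)
      num_im <- running_sum(Im(num), width)
      den <- sqrt(pw_s[, idx1, , drop = FALSE] *
                    pw_s[, idx1 + mm, , drop = FALSE])
      dim(den) <- c(np, (m - mm) * k)
      rho <- num_re / den
      rho[den == 0] <- NA_real_
      R[, li] <- rowMeans(rho, na.rm = TRUE)
      R[rowSums(!is.na(rho)) == 0, li] <- NA_real_
      rm(num_im)
    }
  }
  structure(R, class = "cacf_coherence", lags = lags, method = method)
}

#' Short-lag spatial coherence (SLSC)
#'
#' Sum of the coherence function over lags 1..Q. `Q = 1` is the lag-one
#' coherence (LOC).
#'
#' @param coh A `cacf_coherence` matrix containing lags 1..Q.
#' @param Q Maximum short-lag (>= 1, <= M - 1).
#' @return Numeric vector of per-pixel SLSC values.
#' @export
slsc <- function(coh, Q) {
  lags <- attr(coh, "lags")
  if (Q < 1 || !all(seq_len(Q) %in% lags)) {
    stop("Q out of range for the computed lags")
  }
  cols <- match(seq_len(Q), lags)
  rowSums(coh[, cols, drop = FALSE])
}
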