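#' Transducer array geometry
#'
#' Describes a linear or convex (curvilinear) array in a right-handed frame
#' with x lateral, y elevational, and z axial (depth, pointing into the
#' medium). For convex arrays the elements lie on a circular arc of radius
#' `convex_radius` whose apex element sits at the origin; element normals
#' point radially outward (into the medium).
#'
#' @param n_elements Number of elements (>= 2).
#' @param pitch Element spacing in metres (arc length for convex arrays).
#' @param convex_radius Radius of curvature in metres; `Inf` gives a linear
#'   array.
#' @param name Label for the geometry.
#' @return An object of class `cacf_array` with fields `n_elements`, `pitch`,
#'   `convex_radius`, `element_positions` (n x 3, metres), `element_normals`
#'   (n x 3 unit vectors) and `name`.
#' @export
array_geometry <- function(n_elements, pitch, convex_radius = Inf,
                           name = "array") {
  stopifnot(n_elements >= 2, pitch > 0, convex_radius > 0)
  idx <- seq_len(n_elements) - (n_elements + 1) / 2
  if (is.finite(convex_radius)) {
    theta <- idx * pitch / convex_radius
    pos <- cbind(convex_radius * sin(theta), 0,
                 convex_radius * cos(theta) - convex_radius)
    nrm <- cbind(sin(theta), 0, cos(theta))
  } else {
    theta <- rep(0, n_elements)
    pos <- cbind(idx * pitch, 0, 0)
    nrm <- cbind(0, 0, 1)[rep(1, n_elements), , drop = FALSE]
  }
  structure(list(n_elements = as.integer(n_elements), pitch = pitch,
                 convex_radius = convex_radius, element_angles = theta,
                 element_positions = pos, element_normals = nrm, name = name),
            class = "cacf_array")
}

#' Transmit pulse description
#'
#' @param f0 Center frequency in Hz.
#' @param n_cycles Number of carrier cycles in the pulse (>= 1).
#' @param envelope Pulse envelope, `"hann"` or `"gaussian"`.
#' @param fs RF sampling frequency in Hz; must be at least `4 * f0`.
#' @param c Speed of sound in m/s (default 1540, soft tissue).
#' @return An object of class `cacf_pulse` with a derived `wavelength` field.
#' @export
pulse_spec <- function(f0, n_cycles, envelope = c("hann", "gaussian"),
                       fs = 4 * f0, c = 1540) {
  envelope <- match.arg(envelope)
  stopifnot(f0 > 0, n_cycles >= 1, c > 0)
  if (fs < 4 * f0) stop("fs must be >= 4 * f0 for adequate RF sampling")
  structure(list(f0 = f0, n_cycles = n_cycles, envelope = envelope, fs = fs,
                 c = c, wavelength = c / f0, duration = n_cycles / f0),
            class = "cacf_pulse")
}

#' Color flow acquisition configuration
#'
#' Bundles the array, pulse, and color-flow ensemble parameters. Beam lines
#' radiate radially from the array surface (normal to it); `line_angles`
#' holds the steering angle of each line relative to the array axis.
#'
#' @param geometry A [array_geometry()] object.
#' @param pulse A [pulse_spec()] object.
#' @param prf Pulse repetition frequency in Hz.
#' @param ensemble_length Number of slow-time samples K per estimate (>= 2).
#' @param focal_depth Transmit focal depth in metres.
#' @param f_number Transmit focal F-number (depth / aperture width).
#' @param m_tx Transmit aperture size in elements.
#' @param m_rx Receive aperture (coherence channel count) in elements.
#' @param line_angles Steering angles (radians) of the imaging lines; default
#'   21 beams whose lateral positions at the focal depth span +/- 1.2 cm.
#' @return An object of class `cacf_config`.
#' @export
acquisition_config <- function(geometry, pulse, prf, ensemble_length,
                               focal_depth, f_number, m_tx = NULL,
                               m_rx = NULL, line_angles = NULL) {
  stopifnot(inherits(geometry, "cacf_array"), inherits(pulse, "cacf_pulse"),
            prf > 0, ensemble_length >= 2, focal_depth > 0, f_number > 0)
  aperture_width <- focal_depth / f_number
  if (is.null(m_tx)) m_tx <- round(aperture_width / geometry$pitch)
  if (is.null(m_rx)) m_rx <- m_tx
  if (m_tx > geometry$n_elements || m_rx > geometry$n_elements) {
    stop("aperture exceeds element count")
  }
  if (is.null(line_angles)) {
    r_eff <- if (is.finite(geometry$convex_radius)) {
      geometry$convex_radius + focal_depth
    } else {
      focal_depth
    }
    span <- asin(min(1, 0.012 / r_eff))
    line_angles <- seq(-span, span, length.out = 21)
  }
  structure(list(geometry = geometry, pulse = pulse, prf = prf,
                 ensemble_length = as.integer(ensemble_length),
                 focal_depth = focal_depth, f_number = f_number,
                 m_tx = as.integer(m_tx), m_rx = as.integer(m_rx),
                 line_angles = line_angles),
            class = "cacf_config")
}

#' Reference C5-2v color flow configuration
#'
#' Builds the default acquisition used throughout: a 128-element C5-2v
#' curvilinear array (0.508 mm pitch, 49.57 mm radius) transmitting 4-cycle
#' pulses at 3.5 MHz focused at 6 cm with F/2 geometry, a 3 kHz PRF and a
#' 14-sample slow-time ensemble. The 60-element transmit aperture follows
#' from the F/2 focal geometry; the receive aperture used for coherence
#' matches it.
#'
#' @param ... Overrides passed to [acquisition_config()] (`prf`,
#'   `ensemble_length`, `m_rx`, `line_angles`, ...).
#' @return A `cacf_config`.
#' @examples
#' cfg <- make_c52v_config()
#' cfg$ensemble_length  # 14
#' nyquist_velocity(cfg)  # 0.33 m/s
#' @export
make_c52v_config <- function(...) {
  geom <- array_geometry(128, pitch = 0.508e-3, convex_radius = 49.57e-3,
                         name = "C5-2v")
  pls <- pulse_spec(f0 = 3.5e6, n_cycles = 4)
  defaults <- list(geometry = geom, pulse = pls, prf = 3000,
                   ensemble_length = 14, focal_depth = 0.06, f_number = 2,
                   m_tx = 60L, m_rx = 60L)
  args <- utils::modifyList(defaults, list(...))
  do.call(acquisition_config, args)
}

#' Nyquist velocity of a color flow acquisition
#'
#' The maximum unambiguous axial velocity, `c * PRF / (4 * f0)`.
#'
#' @param cfg A `cacf_config`.
#' @return Axial velocity in m/s.
#' @export
nyquist_velocity <- function(cfg) {
  cfg$pulse$c * cfg$prf / (4 * cfg$pulse$f0)
}

#' Convert a normalized filter cutoff to an axial velocity cutoff
#'
#' A slow-time frequency `fc_norm * PRF` corresponds to axial velocity
#' `c * fc_norm * PRF / (2 * f0)`; a cutoff of 0.5 equals the Nyquist
#' velocity.
#'
#' @param fc_norm Cutoff as a fraction of the PRF, in `[0, 0.5]`.
#' @param cfg A `cacf_config`.
#' @return Axial velocity cutoff in m/s.
#' @export
cutoff_to_velocity <- function(fc_norm, cfg) {
  if (any(fc_norm < 0 | fc_norm > 0.5)) {
    stop("invalid cutoff: fc_norm must lie in [0, 0.5]")
  }
  cfg$pulse$c * (fc_norm * cfg$prf) / (2 * cfg$pulse$f0)
}

#' Resolution cell volume at the focus
#'
#' Nominal focal resolution cell used to convert a scatterer density given in
#' scatterers per resolution cell into an absolute count: lateral and
#' elevational extents `lambda * f_number` and axial extent
#' `n_cycles * lambda / 2`.
#'
#' @param cfg A `cacf_config`.
#' @return Volume in cubic metres.
#' @export
resolution_cell_volume <- function(cfg) {
  lam <- cfg$pulse$wavelength
  (lam * cfg$f_number)^2 * (cfg$pulse$n_cycles * lam / 2)
}

#' @export
print.cacf_config <- function(x, ...) {
  cat(sprintf("<cacf_config> %s: %d el, f0=%.2f MHz, %d cycles\n",
              x$geometry$name, x$geometry$n_elements, x$pulse$f0 / 1e6,
              x$pulse$n_cycles))
  cat(sprintf("  focus %.1f cm F/%.1f, PRF %.0f Hz, K=%d, M_tx=%d, M_rx=%d\n",
              x$focal_depth * 100, x$f_number, x$prf, x$ensemble_length,
              x$m_tx, x$m_rx))
  cat(sprintf("  Nyquist velocity %.1f cm/s, %d lines\n",
              100 * nyquist_velocity(x), length(x$line_angles)))
  invisible(x)
}

# Beam description for one imaging line: origin on the array surface,
# unit direction, and centered transmit/receive aperture element indices.
line_beam <- function(cfg, line_index) {
  geom <- cfg$geometry
  th <- cfg$line_angles[line_index]
  if (is.finite(geom$convex_radius)) {
    o <- c(geom$convex_radius * sin(th), 0,
           geom$convex_radius * cos(th) - geom$convex_radius)
    u <- c(sin(th), 0, cos(th))
  } else {
    o <- c(th, 0, 0)  # linear arrays: line_angles store lateral origins
    u <- c(0, 0, 1)
  }
  center <- which.min(abs(geom$element_angles - th))
  pick <- function(m) {
    i0 <- center - (m %/% 2) + 1L
    idx <- i0:(i0 + m - 1L)
    idx[idx >= 1L & idx <= geom$n_elements]
  }
  list(origin = o, dir = u, theta = th,
       tx_elements = pick(cfg$m_tx), rx_elements = pick(cfg$m_rx),
       focus = o + cfg$focal_depth * u)
}
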