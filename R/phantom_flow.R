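#' Prescribed vessel velocity field
#'
#' Describes the motion imposed on scatterers: plug or parabolic flow inside
#' a cylindrical vessel whose axis lies in the x-z plane at
#' `beam_to_flow_angle` from the beam (z) axis, plus an optional axial bulk
#' velocity applied to every scatterer (tissue and blood alike). For
#' parabolic flow the profile is `(1 - (rho/R)^2)` in the distance `rho`
#' from the vessel axis, scaled so that the peak *axial* velocity component
#' on the axis equals `peak_velocity`.
#'
#' @param kind `"plug"` or `"parabolic"`.
#' @param beam_to_flow_angle Angle between beam axis and flow, in degrees
#'   (< 89).
#' @param peak_velocity Peak axial velocity v0 in m/s.
#' @param vessel_center Vessel axis reference point (x, y, z) in metres.
#' @param vessel_diameter Vessel diameter in metres (0 disables the vessel,
#'   leaving bulk motion only).
#' @param bulk_velocity Axial bulk velocity in m/s applied everywhere.
#' @return An object of class `cacf_velocity_field`.
#' @export
velocity_field <- function(kind = c("plug", "parabolic"),
                           beam_to_flow_angle = 0, peak_velocity = 0,
                           vessel_center = c(0, 0, 0.06),
                           vessel_diameter = 0.01, bulk_velocity = 0) {
  kind <- match.arg(kind)
  stopifnot(vessel_diameter >= 0, abs(beam_to_flow_angle) < 89)
  structure(list(kind = kind, beam_to_flow_angle = beam_to_flow_angle,
                 peak_velocity = peak_velocity, vessel_center = vessel_center,
                 vessel_diameter = vessel_diameter,
                 bulk_velocity = bulk_velocity),
            class = "cacf_velocity_field")
}

vessel_axis_dir <- function(vfield) {
  th <- vfield$beam_to_flow_angle * pi / 180
  c(sin(th), 0, cos(th))
}

# rho: perpendicular distance from each position to the vessel axis.
vessel_rho <- function(vfield, positions) {
  a <- vessel_axis_dir(vfield)
  rel <- sweep(positions, 2, vfield$vessel_center)
  along <- rel %*% a
  perp <- rel - along %*% t(a)
  sqrt(rowSums(perp^2))
}

#' Evaluate the prescribed velocity at positions
#'
#' @param vfield A [velocity_field()].
#' @param positions N x 3 matrix of positions in metres (a length-3 vector is
#'   treated as one position).
#' @return N x 3 matrix of velocities in m/s (flow along the vessel axis for
#'   points inside the vessel, zero outside, plus axial bulk velocity
#'   everywhere).
#' @export
velocity_at <- function(vfield, positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1)
  n <- nrow(positions)
  v <- matrix(0, n, 3)
  if (vfield$vessel_diameter > 0 && vfield$peak_velocity != 0) {
    a <- vessel_axis_dir(vfield)
    r_v <- vfield$vessel_diameter / 2
    rho <- vessel_rho(vfield, positions)
    inside <- rho < r_v
    # speed along the vessel axis whose axial component peaks at v0
    speed_peak <- vfield$peak_velocity / cos(vfield$beam_to_flow_angle * pi / 180)
    prof <- if (vfield$kind == "plug") {
      as.numeric(inside)
    } else {
      ifelse(inside, 1 - (rho / r_v)^2, 0)
    }
    v <- v + (speed_peak * prof) %*% t(a)
  }
  v[, 3] <- v[, 3] + vfield$bulk_velocity
  v
}

#' Axial component of the prescribed velocity (ground truth)
#'
#' @inheritParams velocity_at
#' @return Vector of axial (z) velocities in m/s.
#' @export
truth_axial_velocity <- function(vfield, positions) {
  velocity_at(vfield, positions)[, 3]
}

#' Seed a random scatterer field
#'
#' Populates a rectangular block with uniformly distributed point scatterers
#' at a density given in scatterers per focal resolution cell. Scatterers
#' inside the vessel are labelled blood and drawn with backscatter amplitude
#' 40 dB below tissue (i.i.d. Gaussian amplitudes, tissue sd 1, blood sd
#' 10^(-40/20)).
#'
#' @param block_extents List with numeric `x`, `y`, `z` ranges (metres), e.g.
#'   `list(x = c(-0.02, 0.02), y = c(-5e-4, 5e-4), z = c(0.04, 0.08))`.
#' @param density Scatterers per resolution cell (> 0).
#' @param vessel A [velocity_field()] defining the blood region (may have
#'   `vessel_diameter = 0` for pure tissue).
#' @param cfg A `cacf_config` (sets the resolution cell volume).
#' @param rng_seed Integer seed; fields are deterministic given the seed.
#' @param blood_rel_db Blood backscatter level relative to tissue in dB
#'   (default -40).
#' @return An object of class `cacf_scatterers` with `positions` (N x 3),
#'   `amplitudes`, `labels` (factor tissue/blood), `block_extents`,
#'   `rng_seed`.
#' @export
seed_scatterers <- function(block_extents, density, vessel, cfg, rng_seed,
                            blood_rel_db = -40) {
  ext <- block_extents
  sizes <- vapply(ext[c("x", "y", "z")], function(r) diff(range(r)),
                  numeric(1))
  if (any(sizes <= 0)) stop("block extents must be positive in x, y and z")
  if (density <= 0) stop("density must be > 0")
  v_block <- prod(sizes)
  n <- max(1L, round(density * v_block / resolution_cell_volume(cfg)))
  with_seed(rng_seed, {
    pos <- cbind(runif(n, ext$x[1], ext$x[2]),
                 runif(n, ext$y[1], ext$y[2]),
                 runif(n, ext$z[1], ext$z[2]))
    blood <- if (vessel$vessel_diameter > 0) {
      vessel_rho(vessel, pos) < vessel$vessel_diameter / 2
    } else {
      rep(FALSE, n)
    }
    amp <- rnorm(n, sd = ifelse(blood, 10^(blood_rel_db / 20), 1))
    structure(list(positions = pos, amplitudes = amp,
                   labels = factor(ifelse(blood, "blood", "tissue"),
                                   levels = c("tissue", "blood")),
                   block_extents = ext, rng_seed = rng_seed),
              class = "cacf_scatterers")
  })
}

#' Displace scatterers by the prescribed motion over one interval
#'
#' Pure kinematic translation: `position + velocity_at(position) * dt`.
#' Amplitudes and labels are unchanged; scatterers leaving the block are not
#' recycled (displacements over one ensemble are far smaller than the block).
#'
#' @param field A `cacf_scatterers`.
#' @param vfield A [velocity_field()].
#' @param dt Time step in seconds (1/PRF between emissions).
#' @return The displaced `cacf_scatterers`.
#' @export
displace_scatterers <- function(field, vfield, dt) {
  stopifnot(dt > 0)
  field$positions <- field$positions + velocity_at(vfield, field$positions) * dt
  field
}

#' Scatterer fields for each emission of an ensemble
#'
#' Applies [displace_scatterers()] repeatedly at the pulse repetition
#' interval to produce the K per-emission scatterer fields of one slow-time
#' ensemble.
#'
#' @param field Initial `cacf_scatterers`.
#' @param vfield A [velocity_field()].
#' @param cfg A `cacf_config` (provides K and the PRF).
#' @return List of K `cacf_scatterers`.
#' @export
flow_ensemble_fields <- function(field, vfield, cfg) {
  k <- cfg$ensemble_length
  out <- vector("list", k)
  out[[1]] <- field
  for (i in seq_len(k - 1)) {
    out[[i + 1]] <- displace_scatterers(out[[i]], vfield, 1 / cfg$prf)
  }
  out
}

#' @export
print.cacf_scatterers <- function(x, ...) {
  cat(sprintf("<cacf_scatterers> %d scatterers (%d blood), seed %s\n",
              nrow(x$positions), sum(x$labels == "blood"),
              format(x$rng_seed)))
  invisible(x)
}
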