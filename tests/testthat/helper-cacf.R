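# Shared helpers: tiny configs and hand-built IQ containers.

c52 <- make_c52v_config()

# Wrap a complex pixel x channel x slow-time array as a cacf_iq object on a
# uniform axial grid, for estimator unit tests that need controlled inputs.
synthetic_iq <- function(arr, pitch = 1.1e-4, cfg = c52) {
  np <- dim(arr)[1]
  depths <- 0.06 + (seq_len(np) - (np + 1) / 2) * pitch
  structure(list(iq = arr, depths = depths,
                 pixel_positions = cbind(0, 0, depths), cfg = cfg,
                 beam = NULL, valid = rep(TRUE, np), pixel_pitch = pitch),
            class = "cacf_iq")
}

synthetic_beamsum <- function(mat, pitch = 1.1e-4, cfg = c52) {
  np <- nrow(mat)
  depths <- 0.06 + (seq_len(np) - (np + 1) / 2) * pitch
  structure(list(iq = mat, depths = depths, cfg = cfg,
                 valid = rep(TRUE, np), pixel_pitch = pitch),
            class = "cacf_beamsum")
}

# Tiny two-element linear probe for symmetry checks.
two_element_cfg <- function() {
  geom <- array_geometry(2, pitch = 5e-3, convex_radius = Inf)
  pls <- pulse_spec(3.5e6, 4)
  acquisition_config(geom, pls, prf = 3000, ensemble_length = 2,
                     focal_depth = 0.06, f_number = 2, m_tx = 2, m_rx = 2,
                     line_angles = 0)
}

single_scatterer_field <- function(pos, amp = 1) {
  structure(list(positions = matrix(pos, ncol = 3), amplitudes = amp,
                 labels = factor(rep("tissue", length(amp)),
                                 levels = c("tissue", "blood")),
                 block_extents = NULL, rng_seed = 0L),
            class = "cacf_scatterers")
}
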