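test_that("scatterer seeding honors density, determinism and amplitudes", {
  cfg <- make_c52v_config()
  vf <- velocity_field("plug", 0, 0.06, vessel_center = c(0, 0, 0.06),
                       vessel_diameter = 0.01)
  block <- list(x = c(-0.02, 0.02), y = c(-5e-4, 5e-4), z = c(0.04, 0.08))
  f <- seed_scatterers(block, 15, vf, cfg, rng_seed = 3)
  n_expect <- round(15 * (0.04 * 0.001 * 0.04) / resolution_cell_volume(cfg))
  expect_equal(nrow(f$positions), n_expect)
  expect_gt(n_expect, 3e4)  # full-block density is ~35k scatterers
  # identical fields under the same seed
  f2 <- seed_scatterers(block, 15, vf, cfg, rng_seed = 3)
  expect_identical(f, f2)
  expect_error(seed_scatterers(block, 0, vf, cfg, 1), "density")
  bad <- block
  bad$z <- c(0.05, 0.05)
  expect_error(seed_scatterers(bad, 15, vf, cfg, 1), "extents")
  # -40 dB blood-to-tissue amplitude ratio within sampling tolerance
  blood <- f$labels == "blood"
  expect_gt(sum(blood), 1000)
  rms_ratio <- sqrt(mean(f$amplitudes[blood]^2) /
                      mean(f$amplitudes[!blood]^2))
  expect_equal(rms_ratio, 10^(-40 / 20), tolerance = 0.05)
  # all scatterers inside the block
  expect_true(all(f$positions[, 3] >= 0.04 & f$positions[, 3] <= 0.08))
})

test_that("velocity fields evaluate plug and parabolic profiles exactly", {
  plug <- velocity_field("plug", 0, 0.06, vessel_center = c(0, 0, 0.06),
                         vessel_diameter = 0.01)
  expect_equal(velocity_at(plug, c(0.002, 0, 0.055)), cbind(0, 0, 0.06))
  expect_equal(velocity_at(plug, c(0.008, 0, 0.06)), cbind(0, 0, 0))
  para <- velocity_field("parabolic", 50, 0.12,
                         vessel_center = c(0, 0, 0.06),
                         vessel_diameter = 0.01, bulk_velocity = 0.01)
  a <- c(sin(50 * pi / 180), 0, cos(50 * pi / 180))
  # on the axis the axial component equals v0 (plus bulk)
  v_axis <- velocity_at(para, c(0, 0, 0.06))
  expect_equal(v_axis[3], 0.12 + 0.01)
  # no-slip at the wall: bulk only
  wall <- c(0, 0, 0.06) + 0.005 * c(cos(50 * pi / 180), 0,
                                    -sin(50 * pi / 180))
  expect_equal(velocity_at(para, wall), cbind(0, 0, 0.01))
  # profile along a diameter matches v0*(1 - (rho/R)^2) to machine precision
  rho <- seq(-0.005, 0.005, length.out = 21)
  perp <- c(cos(50 * pi / 180), 0, -sin(50 * pi / 180))
  pts <- t(sapply(rho, function(r) c(0, 0, 0.06) + r * perp))
  vax <- truth_axial_velocity(para, pts) - 0.01
  expect_equal(vax, 0.12 * (1 - (rho / 0.005)^2), tolerance = 1e-12)
})

test_that("displacement is the prescribed kinematic translation", {
  cfg <- make_c52v_config()
  plug <- velocity_field("plug", 0, 0.06, vessel_center = c(0, 0, 0.06),
                         vessel_diameter = 0.01)
  f <- single_scatterer_field(c(0.001, 0, 0.058))
  g <- displace_scatterers(f, plug, 1 / 3000)
  expect_equal(g$positions[1, 3] - f$positions[1, 3], 0.06 / 3000)  # 20 um
  expect_equal(g$positions[1, 1:2], f$positions[1, 1:2])
  # zero velocity field: identity
  still <- velocity_field("plug", 0, 0, vessel_diameter = 0)
  expect_identical(displace_scatterers(f, still, 1 / 3000)$positions,
                   f$positions)
  # bulk motion translates tissue by v_bulk / PRF
  bulk <- velocity_field("plug", 0, 0, vessel_diameter = 0,
                         bulk_velocity = 0.02)
  h <- displace_scatterers(f, bulk, 1 / 3000)
  expect_equal(h$positions[1, 3] - f$positions[1, 3], 0.02 / 3000,
               tolerance = 1e-12)
  # plug displacement over the ensemble is exactly (K-1) v0 / PRF
  fields <- flow_ensemble_fields(f, plug, cfg)
  expect_length(fields, 14)
  expect_equal(fields[[14]]$positions[1, 3] - f$positions[1, 3],
               13 * 0.06 / 3000)
  # scatterer count conserved
  expect_equal(nrow(fields[[14]]$positions), nrow(f$positions))
})
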