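test_that("bias follows the normalized mean-absolute-deviation definition", {
  expect_equal(velocity_bias(matrix(c(1, 2), 1), c(1, 2)), 0)
  # constant offset delta against peak speed V gives delta/V
  truth <- c(0.5, 1, 2)
  expect_equal(velocity_bias(rbind(truth + 0.4, truth + 0.4), truth),
               0.4 / 2)
  # hand-computed: profiles [1,2] and [3,4] vs truth [2,2], max 2
  expect_equal(velocity_bias(rbind(c(1, 2), c(3, 4)), c(2, 2)),
               (1 + 0 + 1 + 2) / (2 * 2 * 2))
  expect_error(velocity_bias(rbind(c(1, 2)), c(0, 0)), "all zero")
  expect_error(velocity_bias(matrix(1, 2, 3), c(1, 1)), "mismatch")
})

test_that("spread about the profile mean matches hand computations", {
  expect_equal(velocity_sd(rbind(c(1, 2), c(1, 2)), c(1, 2)), 0)
  # two profiles [0] and [2], truth max 2: mean |dev| = 1, result 0.5
  expect_equal(velocity_sd(rbind(0, 2), 2), 0.5)
  # permutation invariance
  p <- rbind(c(1, 5), c(2, 3), c(0, 4))
  expect_equal(velocity_sd(p, c(5, 5)), velocity_sd(p[c(3, 1, 2), ], c(5, 5)))
  # rms mode: sqrt of the mean squared deviation
  q <- rbind(c(0, 0), c(2, 4))
  expect_equal(velocity_sd(q, c(4, 4), mode = "rms"),
               sqrt(mean(c(1, 1, 4, 4))) / 4)
  expect_equal(velocity_sd(q, c(4, 4)), mean(c(1, 1, 2, 2)) / 4)
  expect_error(velocity_sd(rbind(c(1, 2)), c(1, 2)), "Np >= 2")
})

test_that("the combined error is the max of bias and spread", {
  expect_equal(combined_error(0.1, 0.3), 0.3)
  expect_equal(combined_error(0.3, 0.1), 0.3)
  expect_equal(combined_error(0, 0), 0)
  expect_equal(combined_error(c(0.1, 0.4), c(0.2, 0.2)), c(0.2, 0.4))
  expect_error(combined_error(-0.1, 0.2))
})

test_that("bias and spread are invariant to a common velocity scale", {
  set.seed(6)
  prof <- matrix(rnorm(40, 0.1, 0.02), 4, 10)
  truth <- runif(10, 0.05, 0.15)
  for (g in c(2, 17)) {
    expect_equal(velocity_bias(g * prof, g * truth),
                 velocity_bias(prof, truth))
    expect_equal(velocity_sd(g * prof, g * truth),
                 velocity_sd(prof, truth))
  }
})

test_that("ROI summaries average the stored diagnostics", {
  fx <- make_fixture("plug_vessel", scale = "tiny", seed = 4, v0 = 0.06)
  bank <- default_bank(14)
  res <- lapply(1:2, function(s) {
    ens <- add_thermal_noise(fx$ensemble, 10, fx$blood_power, 100 + s)
    run_cacf(ens, bank, fx$depths, Q = 10, coherence_method = "kernel")
  })
  sc <- experiment_scale("tiny")
  summ <- roi_summary(res, sc$roi, fx$truth)
  idx <- summ$roi_index
  expect_equal(dim(summ$coherence), c(13, 21))
  expect_equal(summ$error, combined_error(summ$bias, summ$sd))
  # single-pixel ROI reduces to the pixel values
  one <- roi_summary(res[[1]], fx$depths[idx[1]] + c(-1e-9, 1e-9), fx$truth)
  expect_equal(one$slsc, res[[1]]$slsc_by_filter[idx[1], ])
  expect_error(roi_summary(res, c(0.2, 0.3), fx$truth), "outside")
  # bank_statistics exposes the same numbers per member
  bs <- bank_statistics(res, sc$roi, fx$truth)
  expect_equal(nrow(bs), 14)
  expect_equal(bs$bias[14], unname(summ$bias[14]))
})

test_that("experiment runs are deterministic and correctly shaped", {
  conds <- data.frame(flow = "plug", v0 = 0.06, clutter_velocity = NA,
                      clutter_db = NA, bulk_velocity = 0, snr_t_db = 10)
  r1 <- run_experiment(conds, n_realizations = 2, seed = 9, scale = "tiny")
  expect_equal(nrow(r1), 4)  # CACF + three conventional references
  expect_setequal(r1$method, c("none", "fc003", "fc009", "cacf"))
  expect_true(all(r1$error == pmax(r1$bias, r1$sd)))
  r2 <- run_experiment(conds, n_realizations = 2, seed = 9, scale = "tiny")
  expect_identical(r1, r2)
  path <- tempfile(fileext = ".csv")
  write_report_csv(r1, path)
  back <- read.csv(path)
  expect_equal(back$bias, r1$bias)
  expect_error(run_experiment(conds[0, ]), "empty")
})
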