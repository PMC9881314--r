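bank14 <- default_bank(14)

test_that("default bank has the documented structure", {
  expect_length(bank14, 13)
  fc <- bank_cutoffs(bank14)
  expect_true(bank14[[1]]$is_identity)
  expect_equal(min(fc[-1]), 0.03)
  expect_equal(max(fc[-1]), 0.34)
  expect_false(is.unsorted(fc))
  expect_equal(fc[-1] * 3000, c(90, 135, 180, 225, 270, 360, 420, 510, 600,
                                780, 900, 1020))
  expect_true(all(vapply(bank14, function(f) all(dim(f$matrix) == c(14, 14)),
                         logical(1))))
  expect_identical(bank14[[1]]$matrix, diag(14))
})

test_that("every PI-IIR member annihilates constant slow-time vectors", {
  x <- rep(1, 14)
  for (f in bank14[-1]) {
    y <- apply_filter(x, f)
    expect_lt(sum(y^2) / sum(x^2), 1e-4)
  }
})

test_that("steady-state responses anchor the -3 dB cutoff and stopband", {
  for (f in bank14[-1]) {
    g_fc <- 20 * log10(Mod(frequency_response(f, f$fc_norm)))
    expect_lt(abs(g_fc + 3), 0.1)
    expect_lt(Mod(frequency_response(f, 1e-9)), 1e-2)
  }
  expect_equal(frequency_response(bank14[[1]], c(0, 0.1, 0.5)),
               rep(1 + 0i, 3))
})

test_that("design validates inputs and rejects unstable requests", {
  expect_error(design_pi_iir(0.6, 14), "fc_norm")
  expect_error(design_pi_iir(0.1, 4, order = 4), "K >= order")
  b <- design_pi_iir(0.2, 14, order = 2, family = "butterworth")
  expect_lt(abs(20 * log10(Mod(frequency_response(b, 0.2))) + 3), 0.1)
})

test_that("passband tones pass near their steady-state gain at K = 14", {
  # oracle: steady-state filtering of a long tone, center 14 samples
  f3 <- bank14[[2]]  # fc = 0.03
  for (freq in c(0.25, 0.35, 0.45)) {
    n <- 1000
    x_long <- cos(2 * pi * freq * (0:(n - 1)))
    y_long <- as.numeric(signal::filter(f3$b, f3$a, x_long))
    mid <- 501:514
    e_ss <- sum(y_long[mid]^2)
    y_blk <- apply_filter(x_long[mid], f3)
    gain_db <- 10 * log10(sum(y_blk^2) / e_ss)
    expect_gt(gain_db, -3)
    expect_lt(gain_db, 1)
  }
})

test_that("stopband suppression is monotone in the cutoff", {
  k <- 0:13
  for (freq in c(0.01, 0.02)) {
    x <- cos(2 * pi * freq * k + 0.4)
    p <- vapply(bank14[-1], function(f) sum(apply_filter(x, f)^2),
                numeric(1))
    expect_true(all(diff(p) < 1e-12))
  }
})

test_that("filter application is linear, shape-preserving and validated", {
  f9 <- bank14[[6]]
  x <- matrix(rnorm(5 * 14), 5, 14)
  y <- matrix(rnorm(5 * 14), 5, 14)
  expect_equal(apply_filter(2 * x - 3 * y, f9),
               2 * apply_filter(x, f9) - 3 * apply_filter(y, f9),
               tolerance = 1e-12)
  # identity is bit-exact
  expect_identical(apply_filter(x, bank14[[1]]), x)
  # complex inputs: real matrix acts on I and Q identically
  z <- x + 1i * y
  expect_equal(apply_filter(z, f9),
               apply_filter(x, f9) + 1i * apply_filter(y, f9))
  # filtering commutes with channel summation
  arr <- array(rnorm(4 * 6 * 14), dim = c(4, 6, 14))
  sum_then <- apply_filter(apply(arr, c(1, 3), sum), f9)
  then_sum <- apply(apply_filter(arr, f9), c(1, 3), sum)
  expect_equal(sum_then, then_sum, tolerance = 1e-10)
  expect_error(apply_filter(rnorm(10), f9), "slow-time length")
})
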