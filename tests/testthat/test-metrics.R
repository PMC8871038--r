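test_that("gated peak obeys homogeneity and rejects empty gates", {
  tr <- two_pulse_trace(5e-6, 6e-6, span = 1e-5)
  gate <- c(4e-6, 7e-6)
  m <- gated_peak(tr, gate)
  expect_gte(m$peak, 0)
  expect_true(m$t_peak >= gate[1] && m$t_peak <= gate[2])

  trk <- us_trace(-3 * tr$samples, tr$dt, "scaled")
  expect_equal(gated_peak(trk, gate)$peak, 3 * m$peak)

  z <- us_trace(rep(0, 100), 1e-8)
  expect_identical(gated_peak(z, c(0, 1e-7))$peak, 0)
  expect_error(gated_peak(tr, c(2e-5, 3e-5)), "empty gate")
})

test_that("phase relation classifies sign and symmetry correctly", {
  tr <- two_pulse_trace(5e-6, 6e-6)
  neg <- us_trace(-tr$samples, tr$dt, "neg")
  gate <- c(4e-6, 7e-6)
  expect_identical(phase_relation(tr, tr, gate), "in_phase")
  expect_identical(phase_relation(tr, neg, gate), "anti_phase")
  # symmetry in the arguments
  expect_identical(phase_relation(neg, tr, gate), "anti_phase")
  # flipping one trace flips the relation
  expect_identical(phase_relation(neg, neg, gate), "in_phase")
  # zero-variance input is indeterminate
  z <- us_trace(rep(0, length(tr$samples)), tr$dt)
  expect_identical(phase_relation(tr, z, gate), "indeterminate")
  # uncorrelated noise is indeterminate
  set.seed(42)
  a <- us_trace(rnorm(2000), 1e-8)
  b <- us_trace(rnorm(2000), 1e-8)
  expect_identical(phase_relation(a, b, c(0, 1.9e-5), max_lag = 2e-7),
                   "indeterminate")
})

test_that("peak-pair separation recovers a constructed 1 us gap", {
  tr <- two_pulse_trace(5e-6, 6e-6)
  expect_equal(peak_pair_separation(tr, c(4e-6, 7e-6)), 1e-6,
               tolerance = 1e-2)
  onesign <- us_trace(abs(tr$samples), tr$dt)
  expect_error(peak_pair_separation(onesign, c(4e-6, 7e-6)),
               "opposite-sign")
})

test_that("amplitude ratio is scale-invariant and guards the denominator", {
  tr <- two_pulse_trace(5e-6, 6e-6)
  gate <- c(4e-6, 7e-6)
  m <- gated_peak(tr, gate)
  expect_equal(amplitude_ratio(m, m), 100)
  mk <- gated_peak(us_trace(5 * tr$samples, tr$dt), gate)
  expect_equal(amplitude_ratio(mk, m), 500)
  # common rescaling of both traces leaves the ratio exactly invariant
  expect_identical(amplitude_ratio(mk, mk), 100)
  expect_error(amplitude_ratio(m, gated_peak(us_trace(rep(0, 10), 1e-8),
                                             c(0, 1e-7))), "denominator")
})

test_that("echo gate brackets the round-trip time and avoids breakthrough", {
  g <- echo_gate(6e-3)
  expect_lt(g[1], 2 * 6e-3 / 1500)
  expect_gt(g[2], 2 * 6e-3 / 1500)
  expect_gte(g[1], 1.5 * 2 / 7e6)
})
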