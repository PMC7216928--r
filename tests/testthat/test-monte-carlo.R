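test_that("ensembles are reproducible and match the target distribution", {
  g <- cc_gamma()
  e1 <- make_ensemble(1e4, g = g, seed = 7)
  e2 <- make_ensemble(1e4, g = g, seed = 7)
  expect_identical(e1, e2)
  e3 <- make_ensemble(1e4, g = g, seed = 8)
  expect_false(identical(e1$d, e3$d))

  ec <- make_ensemble(5000, d = 3.5e-4, seed = 1)
  expect_true(all(ec$d == 3.5e-4))
  expect_true(all(ec$u >= 0 & ec$u <= 1))

  big <- make_ensemble(4e5, g = g, seed = 2)
  expect_equal(mean(big$d), g$dm, tolerance = 3 * g$ds / sqrt(4e5) / g$dm)
  expect_equal(sd(big$d), g$ds, tolerance = 0.02)

  # phase replicas: positions remain uniform, walkers shared across groups
  er <- make_ensemble(8000, g = g, seed = 3, phase_groups = 8)
  expect_equal(er$n_walkers, 1000L)
  expect_equal(er$d[1:1000], er$d[1001:2000])
  expect_gt(ks.test(er$u, "punif")$p.value, 1e-6)
  expect_error(make_ensemble(1001, g = g, phase_groups = 8),
               class = "dwssfp_error_data")
})

test_that("DW-SE Monte-Carlo reproduces closed-form attenuation", {
  se <- se_protocol(13.56, 40)
  b <- c(0, 1000, 4000, 10000)

  ens <- make_ensemble(2e4, d = 3.5e-4, seed = 21)
  mc <- simulate_dwse_mc(ens, se, b_values = b, seed = 22)
  expect_equal(mc$signal[mc$b == 0], 1, tolerance = 1e-12)  # G = 0
  for (i in 2:4) {
    expect_lt(abs(mc$signal[i] - exp(-b[i] * 3.5e-4)),
              3 * mc$stderr[i] + 1e-3)
  }

  g <- cc_gamma()
  eg <- make_ensemble(2e4, g = g, seed = 23)
  mg <- simulate_dwse_mc(eg, se, b_values = b, seed = 24)
  truth <- dwse_signal_gamma(b, g)
  for (i in 2:4) {
    expect_lt(abs(mg$signal[i] - truth[i]), 3 * mg$stderr[i] + 2e-3)
  }
  # determinism
  mg2 <- simulate_dwse_mc(eg, se, b_values = b, seed = 24)
  expect_identical(mg$signal, mg2$signal)
})

test_that("DW-SSFP Monte-Carlo matches the exact narrow-pulse steady state", {
  p <- paper_protocol(c(20, 90, 150))
  tis <- cc_tissue()

  # relaxation-plus-dephasing only: the frozen reference run is deterministic
  # and must equal the exact D = 0 steady state
  ens0 <- make_ensemble(2e4, d = 3.5e-4, seed = 31, phase_groups = 4)
  mc0 <- simulate_dwssfp_mc(ens0, p, tis, n_tr = 400, seed = 32)
  ref_exact <- ssfp_freed_signal(p, tis, d = 0)
  expect_equal(mc0$signal_ref, ref_exact, tolerance = 1e-3)

  # Gaussian D: attenuation within 3 SE of the exact narrow-pulse model
  att_exact <- ssfp_attenuation(p, cc_tissue(3.5e-4), model = "freed",
                                pulse = "narrow")
  expect_true(all(abs(mc0$attenuation - att_exact) <
                    3 * mc0$stderr + 2e-3))

  # gamma ensemble: attenuation within 3 SE of the gamma-integrated model
  g <- cc_gamma()
  eg <- make_ensemble(2e4, g = g, seed = 33, phase_groups = 4)
  mcg <- simulate_dwssfp_mc(eg, p, tis, n_tr = 250, seed = 34)
  att_gamma <- ssfp_attenuation(p, tis, g = g, model = "freed",
                                pulse = "narrow")
  expect_true(all(abs(mcg$attenuation - att_gamma) < 3 * mcg$stderr + 2e-3))

  # determinism and q = 0 rejection
  mcg2 <- simulate_dwssfp_mc(eg, p, tis, n_tr = 250, seed = 34)
  expect_identical(mcg$attenuation, mcg2$attenuation)
  p0 <- p; p0$q <- 0
  expect_error(simulate_dwssfp_mc(eg, p0, tis), class = "dwssfp_error_data")
})

test_that("reflecting barriers preserve uniformity and restrict diffusion", {
  # wide barriers: identical to a free step under the same seed
  ens <- make_ensemble(5000, d = 3.5e-4, seed = 41)
  a_wide <- 1e3
  set.seed(99); stepped <- reflecting_barrier_step(ens, a_wide, dt = 1e-3)
  set.seed(99); free <- ens$u + rnorm(5000, 0, sqrt(2 * ens$d * 1e-3))
  expect_equal(stepped$u, free, tolerance = 1e-12)

  # stationary distribution stays uniform on (0, a)
  a <- 0.005
  ens2 <- make_ensemble(5000, d = 3.5e-4, seed = 42)
  ens2$u <- ens2$u * a
  set.seed(43)
  for (i in 1:2000) ens2 <- reflecting_barrier_step(ens2, a, dt = 1e-3)
  expect_true(all(ens2$u >= 0 & ens2$u <= a))
  expect_gt(ks.test(ens2$u / a, "punif")$p.value, 0.01)

  # long-time apparent D from mean-squared displacement falls with spacing
  apparent_d <- sapply(c(0.02, 0.005, 0.002), function(aa) {
    e <- make_ensemble(4000, d = 3.5e-4, seed = 44)
    e$u <- e$u * aa
    x0 <- e$u
    set.seed(45)
    n_steps <- 200
    for (i in seq_len(n_steps)) e <- reflecting_barrier_step(e, aa, dt = 1e-3)
    mean((e$u - x0)^2) / (2 * n_steps * 1e-3)
  })
  expect_true(all(diff(apparent_d) < 0))
  expect_lt(apparent_d[3], 3.5e-4 / 3)
})
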