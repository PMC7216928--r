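test_that("ADC inversion round-trips the forward models exactly", {
  p <- paper_protocol(c(15, 60, 120))
  tis <- cc_tissue()
  for (model in c("two_period", "buxton")) {
    for (d_true in c(1e-4, 3.5e-4, 2e-3)) {
      att <- ssfp_attenuation(p, cc_tissue(d = d_true), model = model)
      adc <- adc_from_attenuation(att, p$flip_deg, p, tis, model = model)
      expect_equal(adc, rep(d_true, 3), tolerance = 1e-8)
    }
  }
  expect_equal(adc_from_attenuation(1, 60, p, tis), 0)
  expect_error(adc_from_attenuation(1.2, 60, p, tis),
               class = "dwssfp_error_data")
  expect_error(adc_from_attenuation(1e-6, 60, p, tis),
               class = "dwssfp_error_bracket")
})

test_that("ADC rises with flip angle under a gamma distribution", {
  p <- paper_protocol()
  tis <- tissue(600, 20)
  for (ds in c(1e-4, 2e-4, 3e-4)) {
    g <- gamma_diffusivity(3e-4, ds)
    curve <- predicted_adc_curve(g, p, tis, model = "buxton",
                                 flip_deg = seq(5, 175, 10))
    expect_true(all(diff(curve$adc) > 0))
    expect_true(all(curve$adc < g$dm))
  }
  # larger Ds at fixed Dm gives lower ADC at low flip angle
  adc10 <- sapply(c(1e-4, 2e-4, 3e-4), function(ds) {
    predicted_adc_curve(gamma_diffusivity(3e-4, ds), p, tis,
                        flip_deg = 10)$adc
  })
  expect_true(all(diff(adc10) < 0))
  # degenerate Ds -> flat curve at Dm
  flat <- predicted_adc_curve(gamma_diffusivity(3e-4, 1e-9), p, tis,
                              flip_deg = c(10, 90, 170))
  expect_equal(flat$adc, rep(3e-4, 3), tolerance = 1e-3)
})

test_that("DW-SE gamma ADC: closed form, limits, convexity, inverse", {
  g <- cc_gamma()
  expect_equal(adc_se_gamma(0, g), g$dm)
  expect_equal(adc_se_gamma(1000, g), 1.314990796e-4, tolerance = 1e-8)
  # independent oracle: ADC(b) = -log(S(b)/S0)/b from the closed-form signal
  for (b in c(250, 1000, 5000, 14000)) {
    expect_equal(adc_se_gamma(b, g), -log(dwse_signal_gamma(b, g)) / b,
                 tolerance = 1e-10)
  }
  b_grid <- seq(0, 14000, 500)
  adc <- adc_se_gamma(b_grid, g)
  expect_true(all(diff(adc) < 0))                 # strictly decreasing
  expect_true(all(diff(diff(adc)) > 0))           # convex
  # Ds -> 0 pins the ADC at Dm for all b
  g0 <- gamma_diffusivity(1.5e-4, 1e-12)
  expect_equal(adc_se_gamma(c(0, 1000, 14000), g0), rep(1.5e-4, 3),
               tolerance = 1e-10)

  # effective_bvalue is the exact inverse on [0, b_max]
  for (b in c(0, 12.5, 1000, 9000, 19000)) {
    expect_equal(effective_bvalue(adc_se_gamma(b, g), g), b,
                 tolerance = 1e-4)
  }
  expect_equal(effective_bvalue(g$dm, g), 0)
  expect_error(effective_bvalue(2e-4, g), class = "dwssfp_error_nosolution")
  expect_error(effective_bvalue(adc_se_gamma(30000, g), g),
               class = "dwssfp_error_bracket")
  expect_error(effective_bvalue(1e-4, gamma_diffusivity(1.5e-4, 1e-13)),
               class = "dwssfp_error_degenerate")
})

test_that("gamma fit recovers noise-free truth and flags degenerate data", {
  p <- paper_protocol(seq(10, 170, 20))
  tis <- cc_tissue()
  g <- cc_gamma()
  att <- ssfp_attenuation(p, tis, g = g, model = "buxton")
  adc <- adc_from_attenuation(att, p$flip_deg, p, tis, model = "buxton")
  fit <- fit_gamma(tibble::tibble(flip_deg = p$flip_deg, adc = adc), p, tis,
                   model = "buxton", fit_target = "adc")
  expect_equal(fit$dm, g$dm, tolerance = 1e-3)
  expect_equal(fit$ds, g$ds, tolerance = 1e-3)
  expect_false(fit$degenerate)

  # signal-target route recovers the same truth
  fit2 <- fit_gamma(tibble::tibble(flip_deg = p$flip_deg, attenuation = att),
                    p, tis, model = "buxton", fit_target = "signal")
  expect_equal(fit2$dm, g$dm, tolerance = 1e-3)
  expect_equal(fit2$ds, g$ds, tolerance = 1e-3)

  # Gaussian (flat) data pin Ds near zero and are flagged
  att_g <- ssfp_attenuation(p, cc_tissue(d = 2e-4), model = "buxton")
  adc_g <- adc_from_attenuation(att_g, p$flip_deg, p, tis, model = "buxton")
  fit_g <- fit_gamma(tibble::tibble(flip_deg = p$flip_deg, adc = adc_g),
                     p, tis, model = "buxton", fit_target = "adc")
  expect_true(fit_g$degenerate)
  expect_lt(fit_g$ds, 1e-6)

  # design validation
  expect_error(fit_gamma(tibble::tibble(flip_deg = c(10, 10, 40),
                                        adc = adc[1:3]), p, tis),
               class = "dwssfp_error_data")
  expect_error(fit_gamma(tibble::tibble(flip_deg = c(10, 20), adc = adc[1:2]),
                         p, tis),
               class = "dwssfp_error_data")
})

test_that("translation pipeline round-trips and b_eff falls with flip angle", {
  p <- paper_protocol()
  tis <- cc_tissue()
  g <- cc_gamma()
  res <- acc_roundtrip()
  expect_s3_class(res, "dwssfp_beff")
  expect_equal(res$fit$dm, g$dm, tolerance = 1e-3)
  expect_equal(res$fit$ds, g$ds, tolerance = 1e-3)
  expect_true(all(diff(res$per_flip$adc) > 0))
  expect_true(all(diff(res$per_flip$b_eff) < 0))
  # self-consistency: ADC at b_eff reproduces the measured ADC
  g_fit <- gamma_diffusivity(res$fit$dm, res$fit$ds)
  expect_equal(adc_se_gamma(res$per_flip$b_eff, g_fit), res$per_flip$adc,
               tolerance = 1e-6)

  # tidiers
  td <- tidy(res)
  expect_named(td, c("flip_deg", "attenuation", "adc", "b_eff"))
  gl <- glance(res)
  expect_equal(gl$dm, res$fit$dm)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(res$fit), "ggplot")
})

test_that("samples differing only in T1 share one ADC-vs-b_eff curve", {
  # different T1 reweights the coherence pathways (different ADC-vs-flip
  # curves) but the translation to effective b-values aligns them
  p <- paper_protocol(seq(10, 170, 20))
  g <- cc_gamma()
  res_a <- run_translation_pipeline(
    generate_multiflip_dataset(g, p, tissue(568, 19.8)), p, tissue(568, 19.8))
  res_b <- run_translation_pipeline(
    generate_multiflip_dataset(g, p, tissue(1200, 19.8)), p,
    tissue(1200, 19.8))
  # ADC-vs-flip curves differ appreciably...
  expect_gt(max(abs(res_a$per_flip$adc / res_b$per_flip$adc - 1)), 0.01)
  # ...but both recover the same distribution, so ADC(b) curves coincide
  b_grid <- seq(0, 6000, 500)
  adc_a <- adc_se_gamma(b_grid, gamma_diffusivity(res_a$fit$dm, res_a$fit$ds))
  adc_b <- adc_se_gamma(b_grid, gamma_diffusivity(res_b$fit$dm, res_b$fit$ds))
  expect_equal(adc_a, adc_b, tolerance = 5e-3)
})

test_that("parameter recovery from Rician-noisy data at ROI-averaged SNR", {
  # the distribution fit amplifies attenuation noise ~100x, so recovery at
  # useful precision needs the effective SNR of region-averaged data; the
  # pipeline must survive single-acquisition noise (clipping / dropping
  # uninvertible flips) and recover the truth once the noise is at the
  # region-averaged level
  p <- paper_protocol()
  tis <- cc_tissue()
  g <- cc_gamma()
  errs <- sapply(1:5, function(s) {
    tbl <- generate_multiflip_dataset(g, p, tis, snr = 5000, seed = 3000 + s)
    res <- run_translation_pipeline(tbl, p, tis, model = "buxton",
                                    fit_target = "signal")
    c(abs(res$fit$dm / g$dm - 1), abs(res$fit$ds / g$ds - 1))
  })
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.20)
  # single-acquisition noise does not crash the pipeline
  p9 <- paper_protocol(seq(10, 170, 20))
  noisy <- generate_multiflip_dataset(g, p9, tis, snr = 50, seed = 3101)
  res50 <- run_translation_pipeline(noisy, p9, tis, model = "buxton")
  expect_s3_class(res50, "dwssfp_beff")
})
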