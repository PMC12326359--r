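test_that("sequential pH-series fit recovers generating parameters exactly", {
  ctx <- physical_context(303.15)
  p <- cr_ph_params(alpha = 2.4, beta = 1.7)
  pH <- seq(4.5, 10, 0.5)
  waves <- lapply(pH, ph_series_wave, p = p, ctx = ctx)
  d <- series_dataset(pH, waves, "pH", temperature = 303.15)
  fit <- fit_ph_series(d)
  expect_equal(fit$params$e2_0, p$e2_0, tolerance = 1e-8)
  expect_equal(fit$params$pK, p$pK, tolerance = 1e-8)
  expect_equal(fit$params$pK3, p$pK3, tolerance = 1e-8)
  expect_equal(fit$params$e1_0app, p$e1_0app, tolerance = 1e-8)
  expect_equal(fit$params$pK1, p$pK1, tolerance = 1e-6)
  expect_equal(fit$params$pK2, p$pK2, tolerance = 1e-6)
  # currents are normalized by ilim_ox at the anchor pH (7), so the fitted
  # model predicts unit oxidative limiting current there
  expect_equal(ph_series_wave(7, fit$params, ctx)$ilim_ox, 1,
               tolerance = 1e-6)
})

test_that("pK's outside the pH window are reported as bounds", {
  ctx <- physical_context(313.15)
  p <- tam_ph_params()
  pH <- seq(4.5, 9, 0.5)
  waves <- lapply(pH, ph_series_wave, p = p, ctx = ctx)
  fit <- fit_ph_series(series_dataset(pH, waves, "pH", temperature = 313.15))
  expect_identical(fit$params$bound_flags[["pK1"]], "upper_bound")
  expect_identical(fit$params$bound_flags[["pK2"]], "upper_bound")
  expect_identical(fit$params$bound_flags[["pK3"]], "fitted")
  expect_equal(fit$params$e2_0, p$e2_0, tolerance = 1e-6)
  expect_equal(fit$params$pK, p$pK, tolerance = 1e-4)
  expect_equal(fit$params$pK3, p$pK3, tolerance = 1e-6)
  # a pK inside the window is reported as fitted, not as a bound
  p_in <- pfewave:::apparent_ph_params_obj(1, 1, -0.466, -0.523, 8.3,
                                           pK1 = 6, pK2 = 4.0, pK3 = 7.9)
  waves_in <- lapply(pH, ph_series_wave, p = p_in, ctx = ctx)
  fit_in <- fit_ph_series(series_dataset(pH, waves_in, "pH",
                                         temperature = 313.15))
  expect_identical(fit_in$params$bound_flags[["pK1"]], "fitted")
  expect_equal(fit_in$params$pK1, 6, tolerance = 1e-4)
  # the constraint is honored in the returned parameter set
  expect_lte(fit$params$pK2, min(fit$params$pK1, fit$params$pK3) + 1e-9)
})

test_that("bound pK's are insensitive: moving them lower changes nothing", {
  ctx <- physical_context(313.15)
  p <- tam_ph_params()
  pH <- seq(4.5, 9, 0.5)
  waves <- lapply(pH, ph_series_wave, p = p, ctx = ctx)
  fit <- fit_ph_series(series_dataset(pH, waves, "pH", temperature = 313.15))
  # regenerate with the bound-flagged pK's one unit lower; the quotable
  # parameters must be unchanged within 1 mV / 0.01 pK
  p_low <- pfewave:::apparent_ph_params_obj(1, 1, p$e1_0app, p$e2_0, p$pK,
                                            p$pK1 - 1, p$pK2 - 1, p$pK3)
  waves_low <- lapply(pH, ph_series_wave, p = p_low, ctx = ctx)
  fit_low <- fit_ph_series(series_dataset(pH, waves_low, "pH",
                                          temperature = 313.15))
  expect_lt(abs(fit_low$params$e2_0 - fit$params$e2_0), 1e-3)
  expect_lt(abs(fit_low$params$e1_0app - fit$params$e1_0app), 2e-3)
  expect_lt(abs(fit_low$params$pK - fit$params$pK), 0.01)
  expect_lt(abs(fit_low$params$pK3 - fit$params$pK3), 0.01)
})

test_that("H2-series fit recovers KM, E1' and the constant reductive pair", {
  ctx <- physical_context(278.15)
  p <- cr_h2_params()
  h2 <- c(0.04, 0.09, 0.18, 0.36, 0.89)
  waves <- lapply(h2, h2_series_wave, p = p, ctx = ctx)
  d <- series_dataset(h2, waves, "h2_mM", temperature = 278.15)
  fit <- fit_h2_series(d)
  expect_equal(fit$params$km, 0.3, tolerance = 1e-6)
  expect_equal(fit$params$e1_0prime, -0.337, tolerance = 1e-8)
  expect_equal(fit$params$e2_0app, -0.458, tolerance = 1e-10)
  expect_equal(fit$params$ilim_red_const, 0.5, tolerance = 1e-10)
  expect_identical(fit$km_flag, "fitted")
  # sequential (non-joint) route agrees on noiseless data
  fit2 <- fit_h2_series(d, joint = FALSE)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-6)
  # H2-independent inputs: zero-slope fit returns the mean
  expect_equal(fit$params$e2_0app,
               mean(vapply(waves, function(w) w$ecat_red, numeric(1))))
})

test_that("series datasets validate their invariants", {
  ctx <- physical_context(298.15)
  p <- cr_h2_params()
  waves <- lapply(c(0.1, 0.2, 0.4, 0.8), h2_series_wave, p = p, ctx = ctx)
  expect_error(series_dataset(c(1, 2, 3), waves), "length")
  expect_error(series_dataset(c(1, 1, 2, 3), waves), "distinct")
  d_narrow <- series_dataset(c(0.2, 0.3, 0.4, 0.5), waves, "h2_mM")
  expect_error(fit_h2_series(d_narrow), "factor of 5")
  d_ph <- series_dataset(c(5, 6, 7, 8), waves, "pH")
  expect_error(fit_h2_series(d_ph), "H2 series")
})

test_that("global fit agrees with the sequential protocol", {
  ctx <- physical_context(303.15)
  p <- cr_ph_params()
  pH <- seq(4.5, 10, 0.5)
  waves <- lapply(pH, ph_series_wave, p = p, ctx = ctx)
  d <- series_dataset(pH, waves, "pH", temperature = 303.15)
  g <- global_fit(d)
  s <- fit_ph_series(d)
  for (nm in c("e1_0app", "e2_0", "pK", "pK3")) {
    expect_equal(g$params[[nm]], s$params[[nm]], tolerance = 1e-5)
  }
  expect_lte(g$params$pK2, min(g$params$pK1, g$params$pK3) + 1e-9)
  # noisy replicates: global and sequential estimates stay close
  set.seed(5)
  spread <- replicate(20, {
    waves_n <- lapply(pH, function(x) {
      w <- ph_series_wave(x, p, ctx)
      wave_params(w$ecat_ox + rnorm(1, 0, 0.002),
                  w$ecat_red + rnorm(1, 0, 0.002),
                  w$ilim_ox * (1 + rnorm(1, 0, 0.02)),
                  w$ilim_red_mag * (1 + rnorm(1, 0, 0.02)))
    })
    dn <- series_dataset(pH, waves_n, "pH", temperature = 303.15)
    c(global_fit(dn)$params$e2_0, fit_ph_series(dn)$params$e2_0)
  })
  expect_lt(abs(mean(spread[1, ]) - p$e2_0), 0.01)
  expect_lt(abs(mean(spread[2, ]) - p$e2_0), 0.01)
  expect_lt(max(abs(spread[1, ] - spread[2, ])), 0.02)
})

test_that("parameter tables render bounds in the conventional style", {
  ctx <- physical_context(313.15)
  p <- tam_ph_params()
  pH <- seq(4.5, 9, 0.5)
  waves <- lapply(pH, ph_series_wave, p = p, ctx = ctx)
  fit <- fit_ph_series(series_dataset(pH, waves, "pH", temperature = 313.15))
  tab <- parameter_table(fit, "Tam HydS")
  expect_identical(rownames(tab), "Tam HydS")
  expect_match(tab$pK1, "^<")
  expect_match(tab$pK2, "^<")
  expect_false(grepl("^<", tab$pK3))
})
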