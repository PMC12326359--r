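ctx <- physical_context(298.15)

test_that("steady-state waveform has the correct plateaus and zero crossing", {
  w <- wave_params(-0.30, -0.45, 1, 0.6)
  expect_equal(steady_state_current(10, w, ctx), w$ilim_ox)
  expect_equal(steady_state_current(-10, w, ctx), -w$ilim_red_mag)
  # overflow-safe far from the wave
  expect_true(is.finite(steady_state_current(50, w, ctx)))
  expect_true(is.finite(steady_state_current(-50, w, ctx)))
  # the current crosses zero exactly at the implied equilibrium potential
  eeq <- eq2_implied_eeq(w, ctx)
  expect_equal(steady_state_current(eeq, w, ctx), 0, tolerance = 1e-14)
})

test_that("waveshape/equilibrium relation and its algebraic inverse", {
  w <- wave_params(-0.4, -0.4, 1, 1)
  expect_equal(eq2_implied_eeq(w, ctx), -0.4)  # equal currents: midpoint
  w2 <- wave_params(-0.4, -0.4, exp(2), 1)
  expect_equal(eq2_implied_eeq(w2, ctx), -0.4 - 1 / ctx$f)
  # round trip: imposing the returned Eeq reproduces the current ratio
  eeq <- eq2_implied_eeq(wave_params(-0.32, -0.47, 2.3, 0.7), ctx)
  ratio <- exp(2 * ctx$f * ((-0.32 + -0.47) / 2 - eeq))
  expect_equal(ratio, 2.3 / 0.7)
  expect_error(eq2_implied_eeq(wave_params(-0.3, -0.4, 0, 1), ctx),
               "positive")
})

test_that("micro-rate expressions give the waveshape parameters", {
  w <- wave_from_rates(1, 1, 1, 1, e1_eff = -0.35, e2_eff = -0.5,
                       scale = 1, ctx = ctx)
  expect_equal(w$ilim_ox, 1 / 3)
  expect_equal(w$ilim_red_mag, 1 / 3)
  expect_equal(w$ecat_ox, -0.35 - log(3 / 2) / ctx$f)
  expect_equal(w$ecat_red, -0.5 + log(3 / 2) / ctx$f)
  # no H2 binding: no oxidative current, no shift of Ecat_ox
  w0 <- wave_from_rates(1, 1, 1, 0, -0.35, -0.5, 1, ctx)
  expect_equal(w0$ilim_ox, 0)
  expect_equal(w0$ecat_ox, -0.35)
  # no protonation: no reductive current
  expect_equal(wave_from_rates(0, 1, 1, 1, -0.35, -0.5, 1, ctx)$ilim_red_mag,
               0)
  expect_error(wave_from_rates(0, 0, 0, 0, -0.35, -0.5, 1, ctx),
               "degenerate")
})

test_that("pH-coupled step potentials have the right limits", {
  t <- thermo_params(-0.359, -0.405, 7.2)
  expect_equal(ph_coupled_potentials(t, 14, ctx)$e1_prime, t$e1_0,
               tolerance = 1e-6)
  expect_equal(ph_coupled_potentials(t, 7.2, ctx)$e1_prime,
               t$e1_0 + log(2) / ctx$f)
  expect_equal(ph_coupled_potentials(t, 0, ctx)$e2_prime, t$e2_0,
               tolerance = 1e-6)
})

test_that("relay protonation and H2 step laws", {
  r <- micro_rates(k1_max = 100, k_m1_max = 50, pK_relay = 7,
                   k2_0 = 10, k_m2_bi = 10)
  lo <- relay_protonation_rates(r, 1)
  expect_equal(lo$k1, 100, tolerance = 1e-5)
  expect_equal(lo$k_m1, 0, tolerance = 1e-3)
  hi <- relay_protonation_rates(r, 13)
  expect_equal(hi$k1, 0, tolerance = 1e-3)
  expect_equal(hi$k_m1, 50, tolerance = 1e-5)
  at_pk <- relay_protonation_rates(r, 7)
  expect_equal(at_pk$k1, 50)
  expect_equal(at_pk$k_m1, 25)
  expect_equal(h2_step_rates(r, 0)$k_m2, 0)
  expect_equal(h2_step_rates(r, 0.5)$k_m2, 5)
  expect_equal(h2_step_rates(r, 1)$k_m2, 2 * h2_step_rates(r, 0.5)$k_m2)
  expect_equal(h2_step_rates(r, 1)$k2, h2_step_rates(r, 2)$k2)
  expect_error(h2_step_rates(r, -1), "non-negative")
})

test_that("apparent pH parameters match hand substitution", {
  # k2 = k_m2 = k_m1_max = k1_max = 1, pK_relay = 7
  r <- micro_rates(k1_max = 1, k_m1_max = 1, pK_relay = 7, k2_0 = 1,
                   k_m2_bi = 2)
  ap <- apparent_ph_params(r, thermo_params(-0.3, -0.5, 7.2), h2 = 0.5, ctx)
  expect_equal(ap$pK1, 7 - log10(1.5))
  expect_equal(ap$pK2, 7 - log10(2))
  expect_equal(ap$pK3, 7)
  expect_equal(ap$alpha, 1 / 3)
  expect_equal(ap$beta_mag, 1 / 2)
  # no protonation of the reduced intermediate: K3 collapses onto K2
  r0 <- micro_rates(k1_max = 0, k_m1_max = 3, pK_relay = 7, k2_0 = 2,
                    k_m2_bi = 1)
  ap0 <- apparent_ph_params(r0, thermo_params(-0.3, -0.5, 7.2), 0.5, ctx)
  expect_equal(ap0$pK3, ap0$pK2)
})

test_that("pH-series waveshape limits", {
  p <- cr_ph_params()
  hi <- ph_series_wave(14, p, ctx)
  expect_equal(hi$ilim_ox, p$alpha, tolerance = 1e-4)
  expect_equal(hi$ilim_red_mag, 0, tolerance = 1e-4)
  lo <- ph_series_wave(-2, p, ctx)
  expect_equal(lo$ilim_red_mag, p$beta_mag, tolerance = 1e-4)
})

test_that("Michaelis constant from the micro-rates", {
  r <- micro_rates(k1_max = 1, k_m1_max = 2, pK_relay = 2, k2_0 = 1,
                   k_m2_bi = 10)
  # far above pK_relay, k_m1 = k_m1_max = 1 with these values scaled: use
  # explicit high pH so k_m1 -> k_m1_max
  expect_equal(km_from_micro(r, 14), (1 + 2) / 10)
  r2 <- micro_rates(k1_max = 1, k_m1_max = 0, pK_relay = 7, k2_0 = 3,
                    k_m2_bi = 6)
  expect_equal(km_from_micro(r2, 7), 3 / 6)
  expect_equal(km_from_micro(r, 14) / 2,
               km_from_micro(micro_rates(1, 2, 2, 1, 20), 14))
  expect_error(km_from_micro(micro_rates(1, 1, 7, 1, 0), 7), "undefined")
})

test_that("H2-series waveshape: saturation and H2-independent reductive pair", {
  p <- cr_h2_params()
  expect_equal(h2_series_wave(p$km, p, ctx)$ilim_ox, p$sat_ox / 2)
  expect_equal(h2_series_wave(1e-9, p, ctx)$ecat_ox, p$e1_0prime,
               tolerance = 1e-6)
  expect_equal(h2_series_wave(0, p, ctx)$ilim_ox, 0)
  w_lo <- h2_series_wave(0.04, p, ctx)
  w_hi <- h2_series_wave(0.89, p, ctx)
  expect_identical(w_lo$ecat_red, w_hi$ecat_red)
  expect_identical(w_lo$ilim_red_mag, w_hi$ilim_red_mag)
  # ilim_ox increasing and saturating, ecat_ox decreasing in H2
  h2s <- c(0.01, 0.1, 1, 10, 100)
  iox <- vapply(h2s, function(h) h2_series_wave(h, p, ctx)$ilim_ox,
                numeric(1))
  eox <- vapply(h2s, function(h) h2_series_wave(h, p, ctx)$ecat_ox,
                numeric(1))
  expect_true(all(diff(iox) > 0))
  expect_true(all(iox < p$sat_ox))
  expect_true(all(diff(eox) < 0))
})

test_that("step reassignment: default identity and H2-in-step-1 sign flip", {
  r <- micro_rates(k1_max = 40, k_m1_max = 30, pK_relay = 7, k2_0 = 20,
                   k_m2_bi = 15)
  t <- thermo_params(-0.35, -0.5, 7.5)
  for (pH in c(5, 7, 9)) {
    vw <- variant_wave("step1", "step2", r, t, pH, 0.5, ctx)
    pr <- relay_protonation_rates(r, pH)
    hr <- h2_step_rates(r, 0.5)
    pot <- ph_coupled_potentials(t, pH, ctx)
    ref <- wave_from_rates(pr$k1, pr$k_m1, hr$k2, hr$k_m2, pot$e1_prime,
                           pot$e2_prime, r$scale, ctx)
    expect_equal(unclass(vw), unclass(ref), tolerance = 1e-12)
  }
  # with H2 binding in step 1, Ecat_ox increases with H2 - the opposite of
  # the observed trend, which rejects that mechanism
  set.seed(4)
  for (k in 1:20) {
    r2 <- random_micro_rates()
    t2 <- random_thermo()
    e_lo <- variant_wave("step2", "step1", r2, t2, 7, 0.1, ctx)$ecat_ox
    e_hi <- variant_wave("step2", "step1", r2, t2, 7, 1.0, ctx)$ecat_ox
    expect_gt(e_hi, e_lo)
  }
  expect_error(variant_wave("step1", "step1", r, t, 7, 0.5, ctx),
               "distinct")
})

test_that("broadening preserves plateaus and the zero crossing", {
  w <- wave_params(-0.30, -0.45, 1, 0.6)
  E <- seq(-0.9, 0.1, by = 0.002)
  expect_identical(broadened_current(E, w, 0, ctx),
                   steady_state_current(E, w, ctx))
  for (width in c(0.02, 0.05, 0.1)) {
    ib <- broadened_current(c(-10, 10), w, width, ctx)
    expect_equal(ib, c(-w$ilim_red_mag, w$ilim_ox), tolerance = 1e-9)
  }
  # zero crossing moves by < 1 mV for widths up to 100 mV
  eeq <- eq2_implied_eeq(w, ctx)
  Efine <- seq(eeq - 0.01, eeq + 0.01, by = 1e-5)
  ib <- broadened_current(Efine, w, 0.1, ctx)
  crossing <- Efine[which.min(abs(ib))]
  expect_lt(abs(crossing - eeq), 1e-3)
  expect_error(broadened_current(E, w, -0.1, ctx), "non-negative")
})

test_that("waveform is non-decreasing in potential for random parameters", {
  set.seed(21)
  E <- seq(-1.2, 0.4, by = 5e-3)
  for (k in 1:50) {
    w <- wave_params(runif(1, -0.6, -0.1), runif(1, -0.9, -0.3),
                     10^runif(1, -2, 2), 10^runif(1, -2, 2))
    expect_true(all(diff(steady_state_current(E, w, ctx)) >= -1e-12))
  }
})
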