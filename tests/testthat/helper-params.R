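# shared fixtures: canonical generator parameter sets and small builders

# pH-series generating rows (bound-only entries instantiated at the
# generator defaults pK1/pK2 = 4.5/4.0 for Cr HydA1, 3.0/2.5 for Tam HydS)
cr_ph_params <- function(alpha = 1, beta = 1) {
  pfewave:::apparent_ph_params_obj(alpha, beta, e1_0app = -0.466,
                                   e2_0 = -0.523, pK = 8.3,
                                   pK1 = 4.5, pK2 = 4.0, pK3 = 7.9)
}
tam_ph_params <- function(alpha = 1, beta = 1) {
  pfewave:::apparent_ph_params_obj(alpha, beta, e1_0app = -0.332,
                                   e2_0 = -0.568, pK = 7.1,
                                   pK1 = 3.0, pK2 = 2.5, pK3 = 5.1)
}

# H2-series generating rows (arbitrary current scales)
cr_h2_params <- function() {
  h2_series_params(e1_0prime = -0.337, e2_0app = -0.458, km = 0.3,
                   sat_ox = 1, ilim_red_const = 0.5)
}
tam_h2_params <- function() {
  h2_series_params(e1_0prime = -0.283, e2_0app = -0.603, km = 0.6,
                   sat_ox = 1, ilim_red_const = 0.5)
}

# equilibrium-titration generating parameters
fig2_thermo <- function() thermo_params(-0.359, -0.405, 7.2)

random_micro_rates <- function() {
  micro_rates(k1_max = 10^stats::runif(1, -1, 3),
              k_m1_max = 10^stats::runif(1, -1, 3),
              pK_relay = stats::runif(1, 3, 11),
              k2_0 = 10^stats::runif(1, -1, 3),
              k_m2_bi = 10^stats::runif(1, -1, 2),
              scale = 10^stats::runif(1, -1, 1))
}
random_thermo <- function() {
  thermo_params(stats::runif(1, -0.5, -0.2), stats::runif(1, -0.7, -0.4),
                stats::runif(1, 4, 10))
}

# single noiseless triangular-sweep CV from wave parameters
make_cv <- function(w, ctx, vertices = c(-1.0, 0.05), n = 400,
                    meta = list(role = "sample", pH = 7, h2_mM = 1,
                                temperature_K = ctx$temperature,
                                scan_rate_V_s = 0.02, reference = "SHE",
                                sequence_index = 1)) {
  down <- seq(vertices[2], vertices[1], length.out = n)
  E <- c(down, rev(down)[-1])
  voltammogram(E, steady_state_current(E, w, ctx), meta)
}

# series of noiseless synthetic CV files; returns manifest path
make_series_dir <- function(params, mode, conditions, temperature,
                            seed = 42, ...) {
  cfg <- synthesis_config(mode = mode, params = params,
                          conditions = conditions,
                          temperature = temperature, noise_sd = 0,
                          seed = seed, ...)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  synthesize_series(cfg, dir)
}
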