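# Core algebra of the ordered EECC catalytic cycle: the four-parameter
# steady-state waveform, the micro-rate expressions for the limiting currents
# and catalytic potentials, the pH and H2 laws of the chemical steps, and the
# apparent-parameter forms used to fit pH and H2 series.

#' Waveshape descriptors of one steady-state catalytic voltammogram
#'
#' The steady-state response of a two-electron bidirectional ordered catalyst
#' is described by four parameters: the oxidative and reductive catalytic
#' potentials (inflection potentials above/below which H2 oxidation/evolution
#' is observed) and the two limiting currents. The reductive limiting current
#' is stored as a magnitude; the model's reductive current value is
#' \code{-ilim_red_mag}.
#'
#' @param ecat_ox,ecat_red Catalytic potentials, volts vs SHE.
#' @param ilim_ox,ilim_red_mag Limiting-current magnitudes (>= 0), arbitrary
#'   current units.
#' @return An object of class \code{"wave_params"}.
#' @export
wave_params <- function(ecat_ox, ecat_red, ilim_ox, ilim_red_mag) {
  stopifnot(is.finite(ecat_ox), is.finite(ecat_red),
            is.finite(ilim_ox), is.finite(ilim_red_mag))
  if (ilim_ox < 0 || ilim_red_mag < 0) {
    stop("limiting currents must be non-negative magnitudes")
  }
  structure(list(ecat_ox = ecat_ox, ecat_red = ecat_red,
                 ilim_ox = ilim_ox, ilim_red_mag = ilim_red_mag),
            class = "wave_params")
}

#' @export
print.wave_params <- function(x, ...) {
  cat(sprintf(
    "Catalytic wave: Ecat_ox = %.1f mV, Ecat_red = %.1f mV, ilim_ox = %.4g, ilim_red = %.4g\n",
    1000 * x$ecat_ox, 1000 * x$ecat_red, x$ilim_ox, x$ilim_red_mag))
  invisible(x)
}

#' Micro-rate constants of the EECC chemical steps
#'
#' Rate constants of the two reversible non-redox ("chemical") steps of the
#' catalytic cycle, together with their pH and H2 laws. In the default step
#' assignment, step 1 is (de)protonation through the proton relay
#' (\code{k1_max}, \code{k_m1_max}, \code{pK_relay}) and step 2 is H2
#' release/binding (\code{k2_0} unimolecular release, \code{k_m2_bi}
#' bimolecular binding per mM H2). \code{scale} is the lumped prefactor
#' \eqn{2FA\Gamma} relating turnover to current: the electrode area and
#' electroactive coverage are not separately identifiable.
#'
#' @param k1_max,k_m1_max Maximal protonation/deprotonation rates (1/s).
#' @param pK_relay Acidity constant of the proton relay (-log10 K).
#' @param k2_0 Unimolecular H2 release rate (1/s).
#' @param k_m2_bi Bimolecular H2 binding constant (1/(mM s)).
#' @param scale Lumped current prefactor 2FAGamma (> 0).
#' @return An object of class \code{"micro_rates"}.
#' @export
micro_rates <- function(k1_max, k_m1_max, pK_relay, k2_0, k_m2_bi, scale = 1) {
  vals <- c(k1_max, k_m1_max, k2_0, k_m2_bi)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("rate constants must be finite and non-negative")
  }
  if (!is.finite(scale) || scale <= 0) stop("'scale' must be positive")
  structure(list(k1_max = k1_max, k_m1_max = k_m1_max, pK_relay = pK_relay,
                 k2_0 = k2_0, k_m2_bi = k_m2_bi, scale = scale),
            class = "micro_rates")
}

#' Thermodynamic parameters of the two redox couples
#'
#' @param e1_0 Alkaline limit of the first couple's reduction potential
#'   (Hox/Hred), volts vs SHE.
#' @param e2_0 Acidic limit of the second couple's reduction potential
#'   (HredH+/HsredH+), volts vs SHE.
#' @param pK Acidity constant (-log10 K) of the one-electron-reduced state.
#' @return An object of class \code{"thermo_params"}.
#' @export
thermo_params <- function(e1_0, e2_0, pK) {
  stopifnot(is.finite(e1_0), is.finite(e2_0), is.finite(pK))
  structure(list(e1_0 = e1_0, e2_0 = e2_0, pK = pK), class = "thermo_params")
}

#' Steady-state catalytic current
#'
#' The generic four-parameter rate equation for the steady-state voltammetric
#' response of an ordered two-electron bidirectional catalytic cycle:
#' \deqn{i(E) = \frac{i_{lim}^{ox} e^{f(E-E_{cat}^{ox})} e^{f(E-E_{cat}^{red})}
#'   - i_{lim}^{red}}{(1+e^{f(E-E_{cat}^{red})})(1+e^{f(E-E_{cat}^{ox})})}}
#' evaluated overflow-safely via logistic factors:
#' \eqn{i = i_{lim}^{ox}\sigma(a)\sigma(b) - i_{lim}^{red}\sigma(-a)\sigma(-b)}
#' with \eqn{a = f(E-E_{cat}^{ox})}, \eqn{b = f(E-E_{cat}^{red})}.
#'
#' @param E Electrode potential, volts vs SHE (vectorized).
#' @param w A \code{\link{wave_params}} object (or list with its fields).
#' @param ctx A \code{\link{physical_context}}.
#' @return Current, same units as the limiting currents.
#' @export
steady_state_current <- function(E, w, ctx = physical_context()) {
  a <- ctx$f * (E - w$ecat_ox)
  b <- ctx$f * (E - w$ecat_red)
  w$ilim_ox * stats::plogis(a) * stats::plogis(b) -
    w$ilim_red_mag * stats::plogis(-a) * stats::plogis(-b)
}

#' Equilibrium potential implied by the waveshape
#'
#' For a reversible response the zero-crossing of the catalytic wave is the
#' equilibrium potential of the H+/H2 couple; the four waveshape parameters
#' are tied to it by
#' \eqn{i_{lim}^{ox}/i_{lim}^{red} =
#'   \exp[(2F/RT)((E_{cat}^{ox}+E_{cat}^{red})/2 - E_{eq})]}.
#' This returns the implied \eqn{E_{eq}}.
#'
#' @inheritParams steady_state_current
#' @return Potential in volts vs SHE.
#' @export
eq2_implied_eeq <- function(w, ctx = physical_context()) {
  if (w$ilim_ox <= 0 || w$ilim_red_mag <= 0) {
    stop("both limiting currents must be positive to define the ratio")
  }
  (w$ecat_ox + w$ecat_red) / 2 - log(w$ilim_ox / w$ilim_red_mag) / (2 * ctx$f)
}

#' Waveshape from the micro-rates of the chemical steps
#'
#' The limiting currents and catalytic potentials of the EECC cycle in terms
#' of the instantaneous rate constants of the two chemical steps and the
#' effective (possibly pH-adjusted) potentials of the two redox steps:
#' \deqn{i_{lim}^{ox} = 2FA\Gamma \frac{k_{-1}k_{-2}}{k_2+k_{-1}+k_{-2}},\quad
#'   i_{lim}^{red} = -2FA\Gamma \frac{k_1 k_2}{k_1+k_2+k_{-1}}}
#' \deqn{E_{cat}^{ox} = E_1^{0} - \frac{RT}{F}
#'   \ln\frac{k_2+k_{-1}+k_{-2}}{k_2+k_{-1}},\quad
#'   E_{cat}^{red} = E_2^{0} + \frac{RT}{F}
#'   \ln\frac{k_2+k_{-1}+k_1}{k_2+k_{-1}}}
#'
#' @param k1,k_m1,k2,k_m2 Instantaneous step rate constants (1/s, >= 0).
#' @param e1_eff,e2_eff Effective step potentials, volts.
#' @param scale Lumped prefactor 2FAGamma.
#' @param ctx A \code{\link{physical_context}}.
#' @return A \code{\link{wave_params}} object.
#' @export
wave_from_rates <- function(k1, k_m1, k2, k_m2, e1_eff, e2_eff,
                            scale = 1, ctx = physical_context()) {
  if (any(c(k1, k_m1, k2, k_m2) < 0)) stop("rates must be non-negative")
  d_ox <- k2 + k_m1 + k_m2
  d_red <- k1 + k2 + k_m1
  if (d_ox == 0 && d_red == 0) {
    stop("degenerate catalytic cycle: all step rates are zero")
  }
  ilim_ox <- if (d_ox > 0) scale * k_m1 * k_m2 / d_ox else 0
  ilim_red <- if (d_red > 0) scale * k1 * k2 / d_red else 0
  ecat_ox <- e1_eff -
    if (k2 + k_m1 > 0) log(d_ox / (k2 + k_m1)) / ctx$f else 0
  ecat_red <- e2_eff +
    if (k2 + k_m1 > 0) log(d_red / (k2 + k_m1)) / ctx$f else 0
  wave_params(ecat_ox, ecat_red, ilim_ox, ilim_red)
}

#' pH-dependent effective potentials of the two redox steps
#'
#' The first reduction is coupled to a fast protonation (pKa \code{pK} of the
#' one-electron-reduced state), which makes both step potentials pH dependent:
#' \deqn{E_1^{0\prime} = E_1^0 + \frac{RT}{F}\ln(1+[H^+]/K),\qquad
#'   E_2^{0\prime} = E_2^0 - \frac{RT}{F}\ln(1+K/[H^+])}
#' with \eqn{E_1^0} the alkaline limit and \eqn{E_2^0} the acidic limit.
#'
#' @param t A \code{\link{thermo_params}} object.
#' @param pH Solution pH (vectorized).
#' @param ctx A \code{\link{physical_context}}.
#' @return List with vectors \code{e1_prime} and \code{e2_prime} (volts).
#' @export
ph_coupled_potentials <- function(t, pH, ctx = physical_context()) {
  list(e1_prime = t$e1_0 + log1p(10^(t$pK - pH)) / ctx$f,
       e2_prime = t$e2_0 - log1p(10^(pH - t$pK)) / ctx$f)
}

#' Relay-limited protonation kinetics of chemical step 1
#'
#' The proton is delivered to the active site by the terminal proton relay
#' rather than directly from solution, so the protonation and deprotonation
#' rate constants saturate with pH according to the relay's acidity constant:
#' \deqn{k_1 = \frac{k_1^{max}}{1+K_{relay}/[H^+]},\qquad
#'   k_{-1} = \frac{k_{-1}^{max}}{1+[H^+]/K_{relay}}}
#'
#' @param r A \code{\link{micro_rates}} object.
#' @param pH Solution pH (vectorized).
#' @return List with vectors \code{k1} and \code{k_m1} (1/s).
#' @export
relay_protonation_rates <- function(r, pH) {
  list(k1 = r$k1_max / (1 + 10^(pH - r$pK_relay)),
       k_m1 = r$k_m1_max / (1 + 10^(r$pK_relay - pH)))
}

#' H2 dependence of chemical step 2
#'
#' H2 release is treated as unimolecular (\eqn{k_2} constant) and H2 binding
#' as bimolecular (\eqn{k_{-2} = k_{-2}'[H_2]}).
#'
#' @param r A \code{\link{micro_rates}} object.
#' @param h2 H2 concentration in mM (>= 0, vectorized).
#' @return List with vectors \code{k2} and \code{k_m2} (1/s).
#' @export
h2_step_rates <- function(r, h2) {
  if (any(!is.finite(h2)) || any(h2 < 0)) {
    stop("'h2' must be a non-negative concentration (mM)")
  }
  list(k2 = rep(r$k2_0, length(h2)), k_m2 = r$k_m2_bi * h2)
}

#' Apparent parameters of the pH-series model
#'
#' Substituting the relay protonation law into the micro-rate expressions
#' (with step-2 rates held at their fixed values for the series' constant H2)
#' collapses the pH dependence of the four waveshape parameters onto six
#' apparent parameters plus the thermodynamic pair (\eqn{E_2^0}, pK):
#' \deqn{\alpha = 2FA\Gamma\frac{k_{-2}k_{-1}^{max}}{k_2+k_{-2}+k_{-1}^{max}},
#'   \quad \beta = -2FA\Gamma\frac{k_2 k_1^{max}}{k_2+k_1^{max}}}
#' \deqn{E_1^{0app} = E_1^0 + \frac{RT}{F}
#'   \ln\frac{k_2+k_{-1}^{max}}{k_2+k_{-2}+k_{-1}^{max}}}
#' \deqn{K_1 = K_{relay}\frac{k_2+k_{-2}+k_{-1}^{max}}{k_2+k_{-2}},\quad
#'   K_2 = K_{relay}\frac{k_2+k_{-1}^{max}}{k_2},\quad
#'   K_3 = K_{relay}\frac{k_2+k_{-1}^{max}}{k_2+k_1^{max}}}
#' The catalytic pKa's pK1, pK2, pK3 are kinetic, not thermodynamic,
#' quantities; they always satisfy \eqn{pK_2 \le \min(pK_1, pK_3)}.
#'
#' @param r A \code{\link{micro_rates}} object. \code{k2} and \code{k_m2} are
#'   taken at the series' fixed H2 via \code{h2} below.
#' @param t A \code{\link{thermo_params}} object.
#' @param h2 The constant H2 concentration of the series (mM).
#' @param ctx A \code{\link{physical_context}}.
#' @return An object of class \code{"apparent_ph_params"}: list with fields
#'   \code{alpha}, \code{beta_mag}, \code{e1_0app}, \code{e2_0}, \code{pK},
#'   \code{pK1}, \code{pK2}, \code{pK3} and \code{bound_flags}.
#' @export
apparent_ph_params <- function(r, t, h2, ctx = physical_context()) {
  st2 <- h2_step_rates(r, h2)
  k2 <- st2$k2[1]
  k_m2 <- st2$k_m2[1]
  if (k2 + k_m2 + r$k_m1_max == 0 || k2 + r$k1_max == 0 || k2 == 0) {
    stop("degenerate catalytic cycle: zero denominator in apparent parameters")
  }
  alpha <- r$scale * k_m2 * r$k_m1_max / (k2 + k_m2 + r$k_m1_max)
  beta_mag <- r$scale * k2 * r$k1_max / (k2 + r$k1_max)
  e1_0app <- t$e1_0 +
    log((k2 + r$k_m1_max) / (k2 + k_m2 + r$k_m1_max)) / ctx$f
  # work on the log scale: pKi = pK_relay - log10(rate ratio)
  pK1 <- r$pK_relay - log10((k2 + k_m2 + r$k_m1_max) / (k2 + k_m2))
  pK2 <- r$pK_relay - log10((k2 + r$k_m1_max) / k2)
  pK3 <- r$pK_relay - log10((k2 + r$k_m1_max) / (k2 + r$k1_max))
  apparent_ph_params_obj(alpha, beta_mag, e1_0app, t$e2_0, t$pK,
                         pK1, pK2, pK3)
}

#' Assemble an apparent pH-parameter set directly
#'
#' Constructs an \code{\link{apparent_ph_params}} object from explicit
#' values (e.g. a published parameter table row used as a generator for
#' synthetic series) rather than from micro-rates. The catalytic-pKa
#' ordering \eqn{pK_2 \le \min(pK_1, pK_3)} is enforced.
#'
#' @param alpha Oxidative limiting-current plateau.
#' @param beta_mag Reductive limiting-current plateau (magnitude).
#' @param e1_0app Apparent first reduction potential (volts).
#' @param e2_0 Acidic-limit second reduction potential (volts).
#' @param pK pKa of the one-electron-reduced state.
#' @param pK1,pK2,pK3 Catalytic pKa's.
#' @param bound_flags Named character vector marking each pK as
#'   \code{"fitted"}, \code{"upper_bound"} or \code{"lower_bound"}.
#' @return An \code{\link{apparent_ph_params}} object.
#' @export
apparent_ph_params_set <- function(alpha, beta_mag, e1_0app, e2_0, pK,
                                   pK1, pK2, pK3,
                                   bound_flags = c(pK1 = "fitted",
                                                   pK2 = "fitted",
                                                   pK3 = "fitted")) {
  apparent_ph_params_obj(alpha, beta_mag, e1_0app, e2_0, pK, pK1, pK2, pK3,
                         bound_flags)
}

# internal constructor shared by apparent_ph_params() and fit_ph_series()
apparent_ph_params_obj <- function(alpha, beta_mag, e1_0app, e2_0, pK,
                                   pK1, pK2, pK3,
                                   bound_flags = c(pK1 = "fitted",
                                                   pK2 = "fitted",
                                                   pK3 = "fitted")) {
  if (pK2 > min(pK1, pK3) + 1e-9) {
    stop("invalid apparent parameters: pK2 must not exceed min(pK1, pK3)")
  }
  structure(list(alpha = alpha, beta_mag = beta_mag, e1_0app = e1_0app,
                 e2_0 = e2_0, pK = pK, pK1 = pK1, pK2 = pK2, pK3 = pK3,
                 bound_flags = bound_flags),
            class = "apparent_ph_params")
}

#' @export
print.apparent_ph_params <- function(x, ...) {
  fmt_pk <- function(v, flag) {
    switch(flag,
           upper_bound = sprintf("<%.2f", v),
           lower_bound = sprintf(">%.2f", v),
           sprintf("%.2f", v))
  }
  cat("Apparent pH-series parameters\n")
  cat(sprintf("  E1_0app = %.1f mV   E2_0 = %.1f mV   pK = %.2f\n",
              1000 * x$e1_0app, 1000 * x$e2_0, x$pK))
  cat(sprintf("  pK1 = %s   pK2 = %s   pK3 = %s\n",
              fmt_pk(x$pK1, x$bound_flags[["pK1"]]),
              fmt_pk(x$pK2, x$bound_flags[["pK2"]]),
              fmt_pk(x$pK3, x$bound_flags[["pK3"]])))
  cat(sprintf("  alpha = %.4g   |beta| = %.4g\n", x$alpha, x$beta_mag))
  invisible(x)
}

#' Waveshape parameters along a pH series (apparent-parameter model)
#'
#' The pH dependence of the four waveshape parameters at constant H2:
#' \deqn{i_{lim}^{ox} = \frac{\alpha}{1+[H^+]/K_1},\qquad
#'   i_{lim}^{red} = \frac{\beta}{1+K_3/[H^+]}}
#' \deqn{E_{cat}^{ox} = E_1^{0app} + \frac{RT}{F}\ln(1+[H^+]/K)
#'   + \frac{RT}{F}\ln\frac{1+[H^+]/K_2}{1+[H^+]/K_1}}
#' \deqn{E_{cat}^{red} = E_2^{0} - \frac{RT}{F}\ln(1+K/[H^+])
#'   + \frac{RT}{F}\ln\frac{1+[H^+]/K_3}{1+[H^+]/K_2}}
#'
#' @param pH Solution pH (scalar).
#' @param p An \code{\link{apparent_ph_params}} object.
#' @param ctx A \code{\link{physical_context}}.
#' @return A \code{\link{wave_params}} object.
#' @export
ph_series_wave <- function(pH, p, ctx = physical_context()) {
  rtf <- 1 / ctx$f
  ilim_ox <- p$alpha / (1 + 10^(p$pK1 - pH))
  ilim_red <- p$beta_mag / (1 + 10^(pH - p$pK3))
  ecat_ox <- p$e1_0app + rtf * log1p(10^(p$pK - pH)) +
    rtf * (log1p(10^(p$pK2 - pH)) - log1p(10^(p$pK1 - pH)))
  ecat_red <- p$e2_0 - rtf * log1p(10^(pH - p$pK)) +
    rtf * (log1p(10^(p$pK3 - pH)) - log1p(10^(p$pK2 - pH)))
  wave_params(ecat_ox, ecat_red, ilim_ox, ilim_red)
}

#' Michaelis constant from the micro-rates
#'
#' \eqn{K_M = (k_2 + k_{-1})/k_{-2}'} with the deprotonation rate
#' \eqn{k_{-1}} evaluated at the given pH.
#'
#' @param r A \code{\link{micro_rates}} object (needs \code{k_m2_bi > 0}).
#' @param pH Solution pH.
#' @return Michaelis constant in mM.
#' @export
km_from_micro <- function(r, pH) {
  if (r$k_m2_bi <= 0) stop("undefined KM: bimolecular binding constant is zero")
  k_m1 <- relay_protonation_rates(r, pH)$k_m1
  (r$k2_0 + k_m1) / r$k_m2_bi
}

#' H2-series apparent parameters
#'
#' The identifiable parameters of the waveshape's dependence on H2
#' concentration at constant pH: the saturating oxidative plateau
#' \eqn{2FA\Gamma k_{-1}}, the Michaelis constant, the pH-conditional first
#' potential \eqn{E_1^{0\prime}}, and the H2-independent reductive pair.
#'
#' @param e1_0prime First-couple potential at the series pH (volts).
#' @param e2_0app Apparent (offset) second potential = constant Ecat_red
#'   (volts).
#' @param km Michaelis constant (mM, > 0).
#' @param sat_ox Saturating oxidative limiting current (>= 0).
#' @param ilim_red_const H2-independent reductive limiting-current magnitude.
#' @return An object of class \code{"h2_series_params"}.
#' @export
h2_series_params <- function(e1_0prime, e2_0app, km, sat_ox, ilim_red_const) {
  if (!is.finite(km) || km <= 0) stop("'km' must be positive (mM)")
  if (sat_ox < 0 || ilim_red_const < 0) {
    stop("current magnitudes must be non-negative")
  }
  structure(list(e1_0prime = e1_0prime, e2_0app = e2_0app, km = km,
                 sat_ox = sat_ox, ilim_red_const = ilim_red_const),
            class = "h2_series_params")
}

#' @export
print.h2_series_params <- function(x, ...) {
  cat("H2-series parameters\n")
  cat(sprintf("  E1_0' = %.1f mV   E2_0app = %.1f mV   KM = %.3g mM\n",
              1000 * x$e1_0prime, 1000 * x$e2_0app, x$km))
  cat(sprintf("  saturating ilim_ox = %.4g   ilim_red = %.4g\n",
              x$sat_ox, x$ilim_red_const))
  invisible(x)
}

#' Waveshape parameters along an H2 series (apparent-parameter model)
#'
#' At constant pH, substituting the H2 laws of step 2 into the micro-rate
#' expressions gives
#' \deqn{i_{lim}^{ox} = \frac{2FA\Gamma k_{-1}}{1+K_M/[H_2]},\qquad
#'   E_{cat}^{ox} = E_1^{0\prime} - \frac{RT}{F}\ln(1+[H_2]/K_M)}
#' while \eqn{i_{lim}^{red}} and \eqn{E_{cat}^{red} = E_2^{0app}} are
#' independent of H2.
#'
#' @param h2 H2 concentration in mM (scalar, >= 0).
#' @param p An \code{\link{h2_series_params}} object.
#' @param ctx A \code{\link{physical_context}}.
#' @return A \code{\link{wave_params}} object. \code{h2 = 0} gives a zero
#'   oxidative limiting current (no substrate), not an error.
#' @export
h2_series_wave <- function(h2, p, ctx = physical_context()) {
  if (h2 < 0) stop("'h2' must be non-negative (mM)")
  ilim_ox <- if (h2 == 0) 0 else p$sat_ox / (1 + p$km / h2)
  ecat_ox <- p$e1_0prime - log1p(h2 / p$km) / ctx$f
  wave_params(ecat_ox, p$e2_0app, ilim_ox, p$ilim_red_const)
}

#' Waveshape under an alternative assignment of the chemical steps
#'
#' The default EECC assignment places protonation in chemical step 1 and H2
#' release/binding in step 2. This function re-routes the pH law and the H2
#' law onto the chosen steps and returns the resulting waveshape, allowing
#' the alternative mechanisms (protonation in step 2, or H2 release in
#' step 1) to be confronted with the observed trends; with H2 binding in
#' step 1 the oxidative catalytic potential increases with H2, opposite to
#' what is observed.
#'
#' @param protonation_step,h2_step \code{"step1"} or \code{"step2"}; must be
#'   distinct.
#' @param r A \code{\link{micro_rates}} object; the protonation law uses
#'   \code{k1_max}/\code{k_m1_max}/\code{pK_relay}, the H2 law uses
#'   \code{k2_0} (unimolecular release, forward) and \code{k_m2_bi}
#'   (bimolecular binding, reverse), whichever step they are routed to.
#' @param t A \code{\link{thermo_params}} object.
#' @param pH Solution pH.
#' @param h2 H2 concentration (mM).
#' @param ctx A \code{\link{physical_context}}.
#' @return A \code{\link{wave_params}} object.
#' @export
variant_wave <- function(protonation_step = c("step1", "step2"),
                         h2_step = c("step2", "step1"),
                         r, t, pH, h2, ctx = physical_context()) {
  protonation_step <- match.arg(protonation_step)
  h2_step <- match.arg(h2_step)
  if (protonation_step == h2_step) {
    stop("protonation and H2 must be assigned to distinct steps")
  }
  prot <- relay_protonation_rates(r, pH)
  h2r <- h2_step_rates(r, h2)
  if (protonation_step == "step1") {
    k1 <- prot$k1; k_m1 <- prot$k_m1
    k2 <- h2r$k2; k_m2 <- h2r$k_m2
  } else {
    k1 <- h2r$k2; k_m1 <- h2r$k_m2   # H2 release forward, binding reverse
    k2 <- prot$k1; k_m2 <- prot$k_m1
  }
  pot <- ph_coupled_potentials(t, pH, ctx)
  wave_from_rates(k1, k_m1, k2, k_m2, pot$e1_prime, pot$e2_prime,
                  scale = r$scale, ctx = ctx)
}

#' Broadened steady-state current
#'
#' Slow, dispersed interfacial electron transfer broadens the catalytic wave.
#' This is modeled phenomenologically as the average of the ideal waveform
#' over a uniform distribution of potential offsets in
#' \code{[-width/2, +width/2]} (midpoint quadrature); \code{width = 0}
#' reduces exactly to \code{\link{steady_state_current}} and plateau values
#' are preserved for any width.
#'
#' @inheritParams steady_state_current
#' @param width Full width of the offset distribution (volts, >= 0).
#' @param n_nodes Number of quadrature nodes.
#' @return Current (vectorized over \code{E}).
#' @export
broadened_current <- function(E, w, width, ctx = physical_context(),
                              n_nodes = 64) {
  if (width < 0) stop("'width' must be non-negative")
  if (width == 0) return(steady_state_current(E, w, ctx))
  offsets <- width * ((seq_len(n_nodes) - 0.5) / n_nodes - 0.5)
  out <- numeric(length(E))
  for (d in offsets) out <- out + steady_state_current(E + d, w, ctx)
  out / n_nodes
}
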