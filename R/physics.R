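#' Physical context for electrochemical calculations
#'
#' Bundles the temperature with the Faraday and gas constants and the derived
#' quantity \eqn{f = F/RT} (1/volt) that appears in every exponential of the
#' steady-state waveform model. All potentials in the package are volts vs
#' SHE and all temperatures kelvin; millivolts and Celsius are converted at
#' I/O boundaries only.
#'
#' @param temperature Temperature in kelvin (> 0).
#' @return An object of class \code{"physical_context"}: a list with elements
#'   \code{temperature}, \code{faraday} (C/mol), \code{gas_constant}
#'   (J/(mol K)) and \code{f} (1/V).
#' @examples
#' ctx <- physical_context(298.15)
#' 1 / ctx$f  # thermal voltage RT/F, about 25.7 mV
#' @export
physical_context <- function(temperature = 298.15) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("'temperature' must be a single positive number (kelvin)")
  }
  faraday <- 96485
  gas_constant <- 8.314
  structure(
    list(temperature = temperature,
         faraday = faraday,
         gas_constant = gas_constant,
         f = faraday / (gas_constant * temperature)),
    class = "physical_context")
}

#' @export
print.physical_context <- function(x, ...) {
  cat(sprintf("Physical context: T = %.2f K, RT/F = %.3f mV\n",
              x$temperature, 1000 / x$f))
  invisible(x)
}

#' Nernst potential of the H+/H2 couple
#'
#' Equilibrium potential of \eqn{2H^+ + 2e^- = H_2} at the given pH and
#' hydrogen partial pressure,
#' \eqn{E_{eq} = -(RT\ln 10/F)\,\mathrm{pH} - (RT/2F)\ln p_{H_2}}.
#'
#' @param pH Solution pH.
#' @param p_h2 H2 partial pressure in atm (> 0).
#' @param ctx A \code{\link{physical_context}}.
#' @return Equilibrium potential in volts vs SHE (vectorized over \code{pH}
#'   and \code{p_h2}).
#' @examples
#' ctx <- physical_context(298.15)
#' nernst_eeq(7, 1, ctx)     # about -0.414 V
#' nernst_eeq(7, 0.02, ctx)  # 2% H2: about -0.364 V
#' @export
nernst_eeq <- function(pH, p_h2, ctx = physical_context()) {
  if (any(!is.finite(p_h2)) || any(p_h2 <= 0)) {
    stop("'p_h2' must be positive (atm)")
  }
  -log(10) / ctx$f * pH - log(p_h2) / (2 * ctx$f)
}

#' Hydrogen solubility at 1 atm
#'
#' Aqueous H2 solubility used to convert partial pressures to concentrations:
#' 0.89 mM/atm at 5 degC and 0.64 mM/atm at 40 degC, with linear
#' interpolation in between (an approximation; flagged by a warning when an
#' intermediate temperature is requested).
#'
#' @param temperature_c Temperature in degrees Celsius.
#' @param warn Warn when the value is interpolated rather than tabulated.
#' @return Solubility in mM/atm.
#' @export
h2_solubility <- function(temperature_c, warn = TRUE) {
  t_ref <- c(5, 40)
  s_ref <- c(0.89, 0.64)
  if (warn && any(abs(outer(temperature_c, t_ref, "-")) > 1e-6 |
                  is.na(temperature_c))) {
    interp <- !temperature_c %in% t_ref
    if (any(interp)) {
      warning("H2 solubility linearly interpolated between 5 and 40 degC ",
              "(approximate)")
    }
  }
  stats::approx(t_ref, s_ref, xout = temperature_c, rule = 2)$y
}
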