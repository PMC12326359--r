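# Equilibrium four-state speciation of the H-cluster versus pH at fixed H2,
# and the three-parameter fit of FTIR titration data to it.

# default marker bands (cm^-1) of the four quantified H-cluster states
default_band_wavenumbers <- c(ox = 1939, red = 1933, redH = 1891, sredH = 1881)

#' Equilibrium fractions of the four H-cluster states
#'
#' Speciation of Hox, Hred, HredH+ and HsredH+ under equilibrium with the
#' H+/H2 couple: two one-electron reductions (potentials \code{e1_0},
#' \code{e2_0}) and one protonation (pKa \code{pK}) connect the states, and
#' the solution potential is the Nernst potential of H+/H2 at the given pH
#' and H2 pressure. Relative Boltzmann weights are
#' \eqn{w_{ox} = 1}, \eqn{w_{red} = e^{f(E_1^0 - E_{eq})}},
#' \eqn{w_{redH} = w_{red}10^{pK-pH}},
#' \eqn{w_{sredH} = w_{redH}e^{f(E_2^0 - E_{eq})}}, normalized to fractions.
#'
#' @param pH Solution pH (vectorized).
#' @param p_h2 H2 partial pressure, atm (> 0).
#' @param t A \code{\link{thermo_params}} object.
#' @param ctx A \code{\link{physical_context}}.
#' @return A data.frame with columns \code{pH}, \code{f_ox}, \code{f_red},
#'   \code{f_redH}, \code{f_sredH}; each row sums to 1.
#' @examples
#' ctx <- physical_context(298.15)
#' t <- thermo_params(-0.359, -0.405, 7.2)
#' equilibrium_fractions(seq(5, 10, 0.5), 0.02, t, ctx)
#' @export
equilibrium_fractions <- function(pH, p_h2, t, ctx = physical_context()) {
  eeq <- nernst_eeq(pH, p_h2, ctx)
  # log weights, stabilized by subtracting the maximum before exponentiating
  lw_ox <- rep(0, length(pH))
  lw_red <- ctx$f * (t$e1_0 - eeq)
  lw_redH <- lw_red + log(10) * (t$pK - pH)
  lw_sredH <- lw_redH + ctx$f * (t$e2_0 - eeq)
  lw <- cbind(lw_ox, lw_red, lw_redH, lw_sredH)
  lw <- lw - apply(lw, 1, max)
  w <- exp(lw)
  w <- w / rowSums(w)
  data.frame(pH = pH, f_ox = w[, 1], f_red = w[, 2],
             f_redH = w[, 3], f_sredH = w[, 4])
}

#' Fractions from FTIR marker-band amplitudes
#'
#' Converts amplitudes of the four marker bands into state fractions under
#' the equal-extinction assumption (supported by the observation that the
#' summed band intensity is conserved across the titration). Optional
#' per-state weights allow sensitivity analysis with unequal extinction
#' coefficients: amplitudes are divided by the weights before normalizing.
#'
#' @param amplitudes Numeric vector or matrix (rows = spectra) of band
#'   amplitudes in the order ox, red, redH, sredH; non-negative, at least
#'   one positive per spectrum.
#' @param extinction Relative extinction coefficients, same order; default
#'   all equal.
#' @return A vector (or matrix) of fractions summing to 1 per spectrum.
#' @export
fractions_from_bands <- function(amplitudes, extinction = rep(1, 4)) {
  a <- if (is.matrix(amplitudes)) amplitudes else matrix(amplitudes, nrow = 1)
  if (ncol(a) != 4) stop("expected four band amplitudes (ox, red, redH, sredH)")
  if (any(a < 0)) stop("band amplitudes must be non-negative")
  if (any(rowSums(a) == 0)) stop("all-zero band amplitudes")
  conc <- sweep(a, 2, extinction, "/")
  out <- conc / rowSums(conc)
  colnames(out) <- c("f_ox", "f_red", "f_redH", "f_sredH")
  if (is.matrix(amplitudes)) out else drop(out)
}

#' Constant-sum diagnostic for a band-amplitude series
#'
#' The equal-extinction conversion of band amplitudes to fractions relies on
#' the total band intensity being conserved across the series. This flags a
#' series whose summed amplitude varies by more than \code{tol} (relative
#' range about the mean; default 20%).
#'
#' @param amplitudes Matrix of band amplitudes, one row per spectrum.
#' @param tol Allowed relative variation of the summed amplitude.
#' @return Logical: \code{TRUE} when the series fails the diagnostic,
#'   with attribute \code{"relative_range"}.
#' @export
band_sum_varies <- function(amplitudes, tol = 0.2) {
  tot <- rowSums(amplitudes)
  rel <- (max(tot) - min(tot)) / mean(tot)
  structure(rel > tol, relative_range = rel)
}

#' Fit the equilibrium four-state model to a pH titration
#'
#' Least-squares fit of \code{\link{equilibrium_fractions}} to measured state
#' fractions over pH at fixed H2 pressure, adjusting the three parameters
#' (pK, \eqn{E_1^0}, \eqn{E_2^0}). The residual vector stacks all four state
#' fractions at every pH. Three starting points (the supplied \code{init}
#' and two perturbed copies) guard against the shallow \eqn{E_2^0}
#' direction; the best converged fit is returned.
#'
#' @param data A data.frame with columns \code{pH}, \code{f_ox},
#'   \code{f_red}, \code{f_redH}, \code{f_sredH} (at least 4 distinct pH
#'   values spanning the transition).
#' @param p_h2 H2 partial pressure, atm.
#' @param ctx A \code{\link{physical_context}}.
#' @param init A \code{\link{thermo_params}} starting point.
#' @return An object of class \code{"titration_fit"}: list with
#'   \code{params} (\code{thermo_params}), \code{stderr}, \code{residuals},
#'   \code{rms}, \code{converged}, \code{data}, \code{p_h2}, \code{ctx}.
#' @export
fit_titration <- function(data, p_h2, ctx = physical_context(),
                          init = thermo_params(-0.35, -0.45, 7)) {
  cols <- c("pH", "f_ox", "f_red", "f_redH", "f_sredH")
  if (!all(cols %in% names(data))) {
    stop("'data' must have columns ", paste(cols, collapse = ", "))
  }
  if (length(unique(data$pH)) < 4) {
    stop("underdetermined fit: need at least 4 distinct pH values")
  }
  obs <- as.matrix(data[, cols[-1]])
  if (max(obs[, "f_ox"]) - min(obs[, "f_ox"]) < 0.05 &&
      max(obs[, "f_sredH"]) - min(obs[, "f_sredH"]) < 0.05) {
    stop("underdetermined fit: no redox transition within the pH window")
  }
  resid_fn <- function(par) {
    t <- thermo_params(par[1], par[2], par[3])
    pred <- equilibrium_fractions(data$pH, p_h2, t, ctx)
    as.numeric(as.matrix(pred[, -1]) - obs)
  }
  starts <- list(
    c(init$e1_0, init$e2_0, init$pK),
    c(init$e1_0 + 0.03, init$e2_0 - 0.05, init$pK + 1),
    c(init$e1_0 - 0.03, init$e2_0 + 0.05, init$pK - 1))
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("titration fit failed from all starting points")
  par <- best$par
  cov <- try(solve(best$hessian) * best$deviance /
               max(1, length(best$fvec) - 3), silent = TRUE)
  stderr <- if (inherits(cov, "try-error")) rep(NA_real_, 3) else
    sqrt(pmax(diag(cov), 0))
  names(stderr) <- c("e1_0", "e2_0", "pK")
  structure(list(
    params = thermo_params(par[1], par[2], par[3]),
    stderr = stderr,
    residuals = best$fvec,
    rms = sqrt(mean(best$fvec^2)),
    converged = best$info %in% 1:4,
    data = data, p_h2 = p_h2, ctx = ctx),
    class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("Equilibrium four-state titration fit\n")
  cat(sprintf("  pK   = %.3f (se %.3g)\n", x$params$pK, x$stderr["pK"]))
  cat(sprintf("  E1_0 = %.1f mV (se %.2g mV)\n",
              1000 * x$params$e1_0, 1000 * x$stderr["e1_0"]))
  cat(sprintf("  E2_0 = %.1f mV (se %.2g mV)\n",
              1000 * x$params$e2_0, 1000 * x$stderr["e2_0"]))
  cat(sprintf("  rms residual %.3g; converged: %s\n", x$rms, x$converged))
  invisible(x)
}

#' @export
coef.titration_fit <- function(object, ...) {
  c(e1_0 = object$params$e1_0, e2_0 = object$params$e2_0,
    pK = object$params$pK)
}

#' @export
summary.titration_fit <- function(object, ...) {
  out <- data.frame(estimate = coef(object), stderr = object$stderr)
  cat(sprintf("Fit of the four-state equilibrium model at p(H2) = %g atm, T = %.1f K\n",
              object$p_h2, object$ctx$temperature))
  print(out)
  invisible(out)
}

#' @export
predict.titration_fit <- function(object, newdata = NULL, ...) {
  pH <- if (is.null(newdata)) object$data$pH else newdata$pH
  equilibrium_fractions(pH, object$p_h2, object$params, object$ctx)
}

#' @export
residuals.titration_fit <- function(object, ...) object$residuals

#' @export
plot.titration_fit <- function(x, ...) {
  cols <- c(f_ox = "red", f_red = "orange", f_redH = "skyblue",
            f_sredH = "blue")
  grid <- data.frame(pH = seq(min(x$data$pH), max(x$data$pH), length.out = 200))
  pred <- predict(x, grid)
  graphics::plot(NA, xlim = range(x$data$pH), ylim = c(0, 1),
                 xlab = "pH", ylab = "state fraction", ...)
  for (s in names(cols)) {
    graphics::points(x$data$pH, x$data[[s]], col = cols[[s]], pch = 16)
    graphics::lines(grid$pH, pred[[s]], col = cols[[s]])
  }
  graphics::legend("right", legend = c("Hox", "Hred", "HredH+", "HsredH+"),
                   col = cols, pch = 16, bty = "n")
  invisible(x)
}

#' Read / write a titration table
#'
#' Delimited-text titration tables with \code{# key: value} header lines and
#' columns \code{pH, f_ox, f_red, f_redH, f_sredH} (fractions) or
#' \code{pH, a_ox, a_red, a_redH, a_sredH} (band amplitudes, converted via
#' \code{\link{fractions_from_bands}} on read).
#'
#' @param path File path.
#' @return \code{read_titration}: data.frame of fractions with attribute
#'   \code{"meta"}.
#' @export
read_titration <- function(path) {
  parsed <- read_kv_table(path)
  tab <- parsed$table
  if (all(c("f_ox", "f_red", "f_redH", "f_sredH") %in% names(tab))) {
    out <- tab[, c("pH", "f_ox", "f_red", "f_redH", "f_sredH")]
  } else if (all(c("a_ox", "a_red", "a_redH", "a_sredH") %in% names(tab))) {
    fr <- fractions_from_bands(as.matrix(
      tab[, c("a_ox", "a_red", "a_redH", "a_sredH")]))
    out <- data.frame(pH = tab$pH, fr)
  } else {
    stop("titration table must carry fraction (f_*) or amplitude (a_*) columns")
  }
  attr(out, "meta") <- parsed$meta
  out
}

#' @rdname read_titration
#' @param data Data.frame of fractions (or amplitudes).
#' @param meta Named list written as \code{# key: value} header lines.
#' @export
write_titration <- function(data, path, meta = list()) {
  write_kv_table(data, path, meta)
}
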