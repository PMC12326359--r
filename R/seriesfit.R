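# Stage-2 inference: fit the apparent-parameter pH model to a series of
# waveshape parameters versus pH, and the H2 model to a series versus H2
# concentration, following the sequential, constraint-aware protocol.

#' Assemble a series dataset of waveshape parameters
#'
#' Collects stage-1 results (one \code{\link{wave_params}} or
#' \code{\link{fit_wave}} result per condition) into the table consumed by
#' \code{\link{fit_ph_series}} / \code{\link{fit_h2_series}}.
#'
#' @param condition Condition values (pH, or H2 concentration in mM),
#'   >= 4 distinct values.
#' @param waves List of \code{\link{wave_params}} or \code{"wave_fit"}
#'   objects, same length.
#' @param condition_type \code{"pH"} or \code{"h2_mM"}.
#' @param temperature Series temperature (kelvin).
#' @param anchor Condition value used as the current-normalization anchor
#'   (default: pH 7, or the largest H2 concentration).
#' @param fixed Value of the condition held constant across the series (the
#'   H2 concentration of a pH series, or the pH of an H2 series); optional
#'   metadata.
#' @return An object of class \code{"series_dataset"}: data.frame with
#'   columns \code{condition}, \code{ecat_ox}, \code{ecat_red},
#'   \code{ilim_ox}, \code{ilim_red_mag} and stage-1 standard errors
#'   (\code{se_*}, NA when unavailable), sorted by condition.
#' @export
series_dataset <- function(condition, waves,
                           condition_type = c("pH", "h2_mM"),
                           temperature = 298.15, anchor = NULL,
                           fixed = NULL) {
  condition_type <- match.arg(condition_type)
  if (length(condition) != length(waves)) {
    stop("'condition' and 'waves' lengths differ")
  }
  if (length(condition) < 4 || anyDuplicated(condition)) {
    stop("need at least 4 distinct condition values")
  }
  get_w <- function(x) if (inherits(x, "wave_fit")) x$params else x
  get_se <- function(x, nm) {
    if (inherits(x, "wave_fit") && nm %in% names(x$stderr)) {
      x$stderr[[nm]]
    } else NA_real_
  }
  df <- data.frame(
    condition = condition,
    ecat_ox = vapply(waves, function(x) get_w(x)$ecat_ox, numeric(1)),
    ecat_red = vapply(waves, function(x) get_w(x)$ecat_red, numeric(1)),
    ilim_ox = vapply(waves, function(x) get_w(x)$ilim_ox, numeric(1)),
    ilim_red_mag = vapply(waves, function(x) get_w(x)$ilim_red_mag,
                          numeric(1)),
    se_ecat_ox = vapply(waves, get_se, numeric(1), nm = "ecat_ox"),
    se_ecat_red = vapply(waves, get_se, numeric(1), nm = "ecat_red"),
    se_ilim_ox = vapply(waves, get_se, numeric(1), nm = "ilim_ox"),
    se_ilim_red_mag = vapply(waves, get_se, numeric(1),
                             nm = "ilim_red_mag"))
  df <- df[order(df$condition), ]
  rownames(df) <- NULL
  if (is.null(anchor)) {
    anchor <- if (condition_type == "pH") 7 else max(df$condition)
  }
  structure(df, condition_type = condition_type, temperature = temperature,
            anchor = anchor, fixed = fixed,
            class = c("series_dataset", "data.frame"))
}

# inverse-variance weights from stage-1 stderr, uniform fallback
series_weights <- function(se) {
  if (all(is.finite(se)) && all(se > 0)) 1 / se^2 else rep(1, length(se))
}

# Levenberg-Marquardt wrapper returning par, stderr, deviance
lm_fit <- function(par0, resid_fn, lower = NULL, upper = NULL) {
  n <- length(par0)
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid_fn,
    lower = if (is.null(lower)) rep(-Inf, n) else lower,
    upper = if (is.null(upper)) rep(Inf, n) else upper,
    control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-14,
                                         ptol = 1e-14))
  dof <- max(1, length(fit$fvec) - n)
  cov <- try(solve(fit$hessian) * fit$deviance / dof, silent = TRUE)
  stderr <- if (inherits(cov, "try-error")) rep(NA_real_, n) else
    sqrt(pmax(diag(cov), 0))
  list(par = fit$par, stderr = stderr, deviance = fit$deviance,
       converged = fit$info %in% 1:4)
}

# window-edge rule: a pK is only quotable inside the condition window
# (+/- 0.3 log units); outside it is reported as a bound
pk_bound_flag <- function(pk, wmin, wmax) {
  if (pk < wmin - 0.3) "upper_bound"
  else if (pk > wmax + 0.3) "lower_bound"
  else "fitted"
}

#' Sequential fit of the pH-series model
#'
#' Fits the apparent-parameter pH model to a series of waveshape parameters
#' following the sequential protocol:
#' (a) the oxidative limiting current versus pH gives pK1 (or only an upper
#' bound when the current is pH-independent within the window); (b) the
#' reductive limiting current gives pK3 and the plateau; (c) the reductive
#' catalytic potential, with pK3 fixed from (b) and the constraint
#' pK2 <= pK3, gives \eqn{E_2^0}, pK and pK2; (d) the oxidative catalytic
#' potential, with pK fixed from (c) and the constraint pK2 <= pK1, gives
#' \eqn{E_1^{0app}}. pK's whose fitted value falls outside the pH window
#' (+/- 0.3 units) are flagged as bounds: any value beyond the flagged one
#' fits the data equally well.
#'
#' @param d A \code{\link{series_dataset}} with \code{condition_type "pH"}.
#' @param ctx A \code{\link{physical_context}}; defaults to the dataset's
#'   temperature.
#' @param normalize Normalize the limiting currents by the oxidative
#'   limiting current at the anchor pH before fitting (the plateau
#'   parameters absorb the scale).
#' @return An object of class \code{"ph_series_fit"}: list with
#'   \code{params} (an \code{\link{apparent_ph_params}} with
#'   \code{bound_flags}), \code{stderr}, per-step diagnostics
#'   (\code{steps}), \code{data}, \code{ctx}.
#' @export
fit_ph_series <- function(d, ctx = NULL, normalize = TRUE) {
  stopifnot(inherits(d, "series_dataset"))
  if (attr(d, "condition_type") != "pH") stop("expected a pH series")
  if (is.null(ctx)) ctx <- physical_context(attr(d, "temperature"))
  pH <- d$condition
  if (is.unsorted(pH, strictly = TRUE)) {
    stop("conditions must be strictly increasing (duplicates not allowed)")
  }
  rtf <- 1 / ctx$f
  wmin <- min(pH); wmax <- max(pH)
  iox <- d$ilim_ox
  ired <- d$ilim_red_mag
  if (normalize) {
    anchor <- attr(d, "anchor")
    i_anchor <- stats::approx(pH, iox, xout = anchor, rule = 2)$y
    if (!is.finite(i_anchor) || i_anchor <= 0) {
      stop("cannot normalize: non-positive oxidative current at the anchor pH")
    }
    iox <- iox / i_anchor
    ired <- ired / i_anchor
  }
  steps <- list()

  # (a) ilim_ox = alpha / (1 + 10^(pK1 - pH))
  w_a <- series_weights(d$se_ilim_ox)
  fa <- lm_fit(c(max(iox), wmin),
               function(p) sqrt(w_a) * (p[1] / (1 + 10^(p[2] - pH)) - iox),
               lower = c(0, wmin - 6), upper = c(Inf, wmax + 6))
  alpha <- fa$par[1]
  pK1 <- fa$par[2]
  flag1 <- pk_bound_flag(pK1, wmin, wmax)
  steps$ilim_ox <- fa

  # (b) ilim_red = beta / (1 + 10^(pH - pK3))
  w_b <- series_weights(d$se_ilim_red_mag)
  fb <- lm_fit(c(max(ired), stats::median(pH)),
               function(p) sqrt(w_b) * (p[1] / (1 + 10^(pH - p[2])) - ired),
               lower = c(0, wmin - 6), upper = c(Inf, wmax + 6))
  if (!fb$converged) {
    stop("fit of the reductive limiting current failed; ",
         "downstream steps aborted (partial result: pK1 = ",
         signif(pK1, 4), ")")
  }
  beta_mag <- fb$par[1]
  pK3 <- fb$par[2]
  flag3 <- pk_bound_flag(pK3, wmin, wmax)
  steps$ilim_red <- fb

  # (c) Ecat_red with pK3 fixed, pK2 = pK3 - delta (delta >= 0)
  ecred_model <- function(e2, pK, pK2) {
    e2 - rtf * log1p(10^(pH - pK)) +
      rtf * (log1p(10^(pK3 - pH)) - log1p(10^(pK2 - pH)))
  }
  w_c <- series_weights(d$se_ecat_red)
  fc_best <- NULL
  delta_starts <- unique(pmax(c(0.5, pK3 - wmin + 0.5, 3, 6), 0))
  for (pk_start in c(stats::median(pH), wmin + 1, wmax - 1)) {
    for (delta_start in delta_starts) {
      fc <- lm_fit(c(max(d$ecat_red), pk_start, delta_start),
                   function(p) sqrt(w_c) *
                     (ecred_model(p[1], p[2], pK3 - p[3]) - d$ecat_red),
                   lower = c(-Inf, wmin - 6, 0),
                   upper = c(Inf, wmax + 6, 12))
      if (is.null(fc_best) || fc$deviance < fc_best$deviance) fc_best <- fc
    }
  }
  fc <- fc_best
  e2_0 <- fc$par[1]
  pK <- fc$par[2]
  pK2 <- pK3 - fc$par[3]
  flag2 <- pk_bound_flag(pK2, wmin, wmax)
  steps$ecat_red <- fc

  # (d) Ecat_ox with pK fixed from (c), pK2 = pK1 - delta (delta >= 0)
  ecox_model <- function(e1app, pK1d, pK2d) {
    e1app + rtf * log1p(10^(pK - pH)) +
      rtf * (log1p(10^(pK2d - pH)) - log1p(10^(pK1d - pH)))
  }
  w_d <- series_weights(d$se_ecat_ox)
  fd <- lm_fit(c(min(d$ecat_ox), pK1, max(pK1 - pK2, 0)),
               function(p) sqrt(w_d) *
                 (ecox_model(p[1], p[2], p[2] - p[3]) - d$ecat_ox),
               lower = c(-Inf, wmin - 6, 0),
               upper = c(Inf, wmax + 6, 12))
  e1_0app <- fd$par[1]
  steps$ecat_ox <- fd

  # assembled parameter set; the hard constraint pK2 <= min(pK1, pK3) is
  # enforced exactly at assembly (it can only be strained by noise)
  pK2 <- min(pK2, pK1, pK3)
  params <- apparent_ph_params_obj(
    alpha, beta_mag, e1_0app, e2_0, pK, pK1, pK2, pK3,
    bound_flags = c(pK1 = flag1, pK2 = flag2, pK3 = flag3))
  stderr <- c(alpha = fa$stderr[1], pK1 = fa$stderr[2],
              beta_mag = fb$stderr[1], pK3 = fb$stderr[2],
              e2_0 = fc$stderr[1], pK = fc$stderr[2],
              pK2 = fc$stderr[3],
              e1_0app = fd$stderr[1])
  structure(list(params = params, stderr = stderr, steps = steps,
                 normalized = normalize, data = d, ctx = ctx),
            class = "ph_series_fit")
}

#' @export
print.ph_series_fit <- function(x, ...) {
  cat("Sequential pH-series fit\n")
  print(x$params)
  invisible(x)
}

#' @export
coef.ph_series_fit <- function(object, ...) {
  p <- object$params
  c(e1_0app = p$e1_0app, e2_0 = p$e2_0, pK = p$pK,
    pK1 = p$pK1, pK2 = p$pK2, pK3 = p$pK3,
    alpha = p$alpha, beta_mag = p$beta_mag)
}

#' @export
summary.ph_series_fit <- function(object, ...) {
  print.ph_series_fit(object)
  cat("standard errors (covariance approximation):\n")
  print(signif(object$stderr, 3))
  invisible(coef(object))
}

#' @export
predict.ph_series_fit <- function(object, newdata = NULL, ...) {
  pH <- if (is.null(newdata)) object$data$condition else newdata$condition
  out <- t(vapply(pH, function(p) {
    unlist(ph_series_wave(p, object$params, object$ctx))
  }, numeric(4)))
  data.frame(condition = pH, out)
}

#' @export
plot.ph_series_fit <- function(x, ...) {
  d <- x$data
  grid <- data.frame(condition = seq(min(d$condition), max(d$condition),
                                     length.out = 200))
  pred <- predict(x, grid)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(d$condition, cbind(d$ecat_ox, d$ecat_red), pch = 16,
                    col = c("blue", "darkgreen"), xlab = "pH",
                    ylab = "Ecat (V)", ...)
  graphics::matlines(grid$condition, cbind(pred$ecat_ox, pred$ecat_red),
                     lty = 1, col = c("blue", "darkgreen"))
  graphics::matplot(d$condition, cbind(d$ilim_ox, d$ilim_red_mag), pch = 16,
                    col = c("darkgreen", "blue"), xlab = "pH",
                    ylab = "ilim", ...)
  graphics::matlines(grid$condition, cbind(pred$ilim_ox, pred$ilim_red_mag),
                     lty = 1, col = c("darkgreen", "blue"))
  invisible(x)
}

#' Fit the H2-series model
#'
#' Fits the saturating oxidative limiting current and the oxidative
#' catalytic potential versus H2 concentration, sharing the Michaelis
#' constant between the two (joint fit, the default) or fitting the current
#' alone first. The reductive pair is H2 independent and fitted as
#' constants.
#'
#' @param d A \code{\link{series_dataset}} with \code{condition_type
#'   "h2_mM"} whose conditions span at least a factor 5.
#' @param ctx A \code{\link{physical_context}}; defaults to the dataset's
#'   temperature.
#' @param joint Share KM between the current and potential fits (default
#'   TRUE).
#' @return An object of class \code{"h2_series_fit"}: list with
#'   \code{params} (an \code{\link{h2_series_params}}), \code{stderr},
#'   \code{km_flag} (\code{"fitted"} or a bound marker when the
#'   concentration window does not resolve the curvature), \code{data},
#'   \code{ctx}.
#' @export
fit_h2_series <- function(d, ctx = NULL, joint = TRUE) {
  stopifnot(inherits(d, "series_dataset"))
  if (attr(d, "condition_type") != "h2_mM") stop("expected an H2 series")
  if (is.null(ctx)) ctx <- physical_context(attr(d, "temperature"))
  h2 <- d$condition
  if (is.unsorted(h2, strictly = TRUE)) {
    stop("conditions must be strictly increasing (duplicates not allowed)")
  }
  if (max(h2) / min(h2) < 5) {
    stop("H2 concentrations must span at least a factor of 5")
  }
  rtf <- 1 / ctx$f
  i_scale <- max(d$ilim_ox)
  w_i <- series_weights(d$se_ilim_ox)
  w_e <- series_weights(d$se_ecat_ox)
  km0 <- stats::median(h2)
  if (joint) {
    fj <- lm_fit(
      c(i_scale, km0, max(d$ecat_ox)),
      function(p) {
        c(sqrt(w_i) * (p[1] / (1 + p[2] / h2) - d$ilim_ox) / i_scale,
          sqrt(w_e) * (p[3] - rtf * log1p(h2 / p[2]) - d$ecat_ox) / rtf)
      },
      lower = c(0, 1e-6, -Inf), upper = c(Inf, 1e3, Inf))
    sat_ox <- fj$par[1]; km <- fj$par[2]; e1p <- fj$par[3]
    stderr <- c(sat_ox = fj$stderr[1], km = fj$stderr[2],
                e1_0prime = fj$stderr[3])
    diag_fits <- list(joint = fj)
  } else {
    fi <- lm_fit(c(i_scale, km0),
                 function(p) sqrt(w_i) * (p[1] / (1 + p[2] / h2) - d$ilim_ox),
                 lower = c(0, 1e-6), upper = c(Inf, 1e3))
    sat_ox <- fi$par[1]; km <- fi$par[2]
    fe <- lm_fit(max(d$ecat_ox),
                 function(p) sqrt(w_e) *
                   (p[1] - rtf * log1p(h2 / km) - d$ecat_ox))
    e1p <- fe$par[1]
    stderr <- c(sat_ox = fi$stderr[1], km = fi$stderr[2],
                e1_0prime = fe$stderr[1])
    diag_fits <- list(ilim_ox = fi, ecat_ox = fe)
  }
  km_flag <- pk_bound_flag(log10(km), log10(min(h2)), log10(max(h2)))
  # horizontal fits of the H2-independent reductive pair
  w_er <- series_weights(d$se_ecat_red)
  e2_0app <- sum(w_er * d$ecat_red) / sum(w_er)
  w_ir <- series_weights(d$se_ilim_red_mag)
  ilim_red_const <- sum(w_ir * d$ilim_red_mag) / sum(w_ir)
  params <- h2_series_params(e1p, e2_0app, km, sat_ox, ilim_red_const)
  structure(list(params = params, stderr = stderr, km_flag = km_flag,
                 fits = diag_fits, data = d, ctx = ctx),
            class = "h2_series_fit")
}

#' @export
print.h2_series_fit <- function(x, ...) {
  cat("H2-series fit\n")
  print(x$params)
  if (x$km_flag != "fitted") {
    cat(sprintf("  note: KM outside the concentration window (%s)\n",
                sub("_bound", " bound", x$km_flag)))
  }
  invisible(x)
}

#' @export
coef.h2_series_fit <- function(object, ...) {
  p <- object$params
  c(e1_0prime = p$e1_0prime, e2_0app = p$e2_0app, km = p$km,
    sat_ox = p$sat_ox, ilim_red_const = p$ilim_red_const)
}

#' @export
predict.h2_series_fit <- function(object, newdata = NULL, ...) {
  h2 <- if (is.null(newdata)) object$data$condition else newdata$condition
  out <- t(vapply(h2, function(h) {
    unlist(h2_series_wave(h, object$params, object$ctx))
  }, numeric(4)))
  data.frame(condition = h2, out)
}

#' Global (simultaneous) fit of the pH-series model
#'
#' Single weighted least squares over all four observables of a pH series,
#' sharing the apparent acidity constants across them; a cross-check of the
#' sequential protocol (\code{\link{fit_ph_series}}), with which it agrees
#' on noiseless data. Potential residuals are scaled by RT/F and current
#' residuals by the largest plateau so that the blocks are commensurate.
#'
#' @inheritParams fit_ph_series
#' @param start Optional \code{\link{apparent_ph_params}} starting point
#'   (default: the sequential fit).
#' @return An object of class \code{"ph_series_fit"} (with element
#'   \code{global = TRUE}).
#' @export
global_fit <- function(d, ctx = NULL, normalize = TRUE, start = NULL) {
  stopifnot(inherits(d, "series_dataset"))
  if (nrow(d) < 4) stop("underdetermined: need at least 4 conditions")
  if (is.null(ctx)) ctx <- physical_context(attr(d, "temperature"))
  seq_fit <- fit_ph_series(d, ctx, normalize = normalize)
  if (is.null(start)) start <- seq_fit$params
  pH <- d$condition
  wmin <- min(pH); wmax <- max(pH)
  iox <- d$ilim_ox; ired <- d$ilim_red_mag
  if (normalize) {
    i_anchor <- stats::approx(pH, iox, xout = attr(d, "anchor"), rule = 2)$y
    iox <- iox / i_anchor
    ired <- ired / i_anchor
  }
  rtf <- 1 / ctx$f
  i_scale <- max(iox, ired)
  # theta: alpha, beta, e1app, e2, pK, pK1, pK3, delta (pK2 = min(pK1,pK3)-delta)
  to_params <- function(th) {
    apparent_ph_params_obj(th[1], th[2], th[3], th[4], th[5], th[6],
                           min(th[6], th[7]) - th[8], th[7])
  }
  resid_fn <- function(th) {
    p <- to_params(th)
    pred <- vapply(pH, function(x) unlist(ph_series_wave(x, p, ctx)),
                   numeric(4))
    c((pred["ilim_ox", ] - iox) / i_scale,
      (pred["ilim_red_mag", ] - ired) / i_scale,
      (pred["ecat_ox", ] - d$ecat_ox) / rtf,
      (pred["ecat_red", ] - d$ecat_red) / rtf)
  }
  th0 <- c(start$alpha, start$beta_mag, start$e1_0app, start$e2_0, start$pK,
           start$pK1, start$pK3,
           max(min(start$pK1, start$pK3) - start$pK2, 0))
  fg <- lm_fit(th0, resid_fn,
               lower = c(0, 0, -Inf, -Inf, wmin - 6, wmin - 6, wmin - 6, 0),
               upper = c(Inf, Inf, Inf, Inf, wmax + 6, wmax + 6, wmax + 6, 12))
  params <- to_params(fg$par)
  params$bound_flags <- c(pK1 = pk_bound_flag(params$pK1, wmin, wmax),
                          pK2 = pk_bound_flag(params$pK2, wmin, wmax),
                          pK3 = pk_bound_flag(params$pK3, wmin, wmax))
  stderr <- stats::setNames(fg$stderr,
                            c("alpha", "beta_mag", "e1_0app", "e2_0", "pK",
                              "pK1", "pK3", "delta_pK2"))
  structure(list(params = params, stderr = stderr,
                 steps = list(global = fg), sequential = seq_fit,
                 normalized = normalize, global = TRUE, data = d, ctx = ctx),
            class = "ph_series_fit")
}

#' Parameter table with bound flags
#'
#' Renders fitted series parameters in the conventional column order, with
#' pK's only known as bounds shown as \code{"<value"} (or \code{">value"}).
#'
#' @param fit A \code{"ph_series_fit"} or \code{"h2_series_fit"}.
#' @param label Row label (e.g. the enzyme name).
#' @return A one-row data.frame of character-rendered parameters (potentials
#'   in mV).
#' @export
parameter_table <- function(fit, label = "enzyme") {
  if (inherits(fit, "ph_series_fit")) {
    p <- fit$params
    fmt_pk <- function(v, flag) {
      switch(flag, upper_bound = sprintf("<%.1f", v),
             lower_bound = sprintf(">%.1f", v), sprintf("%.1f", v))
    }
    data.frame(row.names = label,
               E1_0app_mV = sprintf("%.0f", 1000 * p$e1_0app),
               E2_0_mV = sprintf("%.0f", 1000 * p$e2_0),
               pK = sprintf("%.1f", p$pK),
               pK1 = fmt_pk(p$pK1, p$bound_flags[["pK1"]]),
               pK2 = fmt_pk(p$pK2, p$bound_flags[["pK2"]]),
               pK3 = fmt_pk(p$pK3, p$bound_flags[["pK3"]]))
  } else if (inherits(fit, "h2_series_fit")) {
    p <- fit$params
    km_txt <- switch(fit$km_flag,
                     upper_bound = sprintf("<%.2g", p$km),
                     lower_bound = sprintf(">%.2g", p$km),
                     sprintf("%.2g", p$km))
    data.frame(row.names = label,
               E1_0prime_mV = sprintf("%.0f", 1000 * p$e1_0prime),
               E2_0app_mV = sprintf("%.0f", 1000 * p$e2_0app),
               KM_mM = km_txt)
  } else {
    stop("unsupported fit object")
  }
}
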