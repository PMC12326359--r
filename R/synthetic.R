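# Seeded, manifest-driven synthetic data: CV series over pH or [H2] with
# realistic nuisance structure (capacitive background, noise, interleaved
# reference scans, exponential film loss) and FTIR titration tables. The
# generator shares only the kinetic core with the fitting code, so
# closed-loop recovery tests cannot be confirmed by a shared bug in the
# nuisance model.

#' Synthesis configuration for a CV series
#'
#' @param mode \code{"ph_series"} or \code{"h2_series"}.
#' @param params Generator parameters: an \code{\link{apparent_ph_params}}
#'   (pH series) or \code{\link{h2_series_params}} (H2 series).
#' @param conditions Condition grid (pH values, or H2 in mM), length >= 4.
#' @param temperature Kelvin.
#' @param fixed The condition held constant (H2 in mM for a pH series, pH
#'   for an H2 series); recorded in metadata.
#' @param anchor Anchor condition for reference scans and normalization
#'   (default pH 7 / max H2).
#' @param noise_sd Gaussian current noise, as a fraction of the largest
#'   oxidative plateau of the series.
#' @param potential_jitter Gaussian potential jitter (volts; default 0).
#' @param background Quadratic background polynomial coefficients
#'   \code{c(b0, b1, b2)} in current units (current = b0 + b1 E + b2 E^2).
#' @param cap_offset Sweep-direction-antisymmetric offset mimicking
#'   capacitive current (added on the rising sweep, subtracted on the
#'   falling sweep).
#' @param film_loss_rate Exponential film-loss rate per scan (lambda;
#'   enzymatic current scaled by exp(-lambda * (sequence_index - 1))).
#' @param broadening_width Phenomenological broadening width (volts).
#' @param seed Integer seed (mandatory; all randomness flows from it).
#' @param vertices Sweep vertices \code{c(low, high)} in volts vs SHE.
#' @param points_per_sweep Points per half-sweep.
#' @param scan_rate_V_s Scan rate (metadata only; steady-state responses do
#'   not depend on it).
#' @param reference_every Interleave one reference scan (at the anchor
#'   condition) every this many sample scans; 0 disables them.
#' @param reference Reference electrode the files are written against
#'   (\code{"SHE"} or \code{"SCE"}; potentials are shifted accordingly so
#'   that conversion on read restores SHE values).
#' @return An object of class \code{"synthesis_config"}.
#' @export
synthesis_config <- function(mode = c("ph_series", "h2_series"),
                             params, conditions, temperature = 298.15,
                             fixed = NULL, anchor = NULL,
                             noise_sd = 0, potential_jitter = 0,
                             background = c(0, 0, 0), cap_offset = 0,
                             film_loss_rate = 0, broadening_width = 0,
                             seed, vertices = c(-1.0, 0.1),
                             points_per_sweep = 400, scan_rate_V_s = 0.02,
                             reference_every = 1,
                             reference = c("SHE", "SCE")) {
  mode <- match.arg(mode)
  reference <- match.arg(reference)
  if (length(conditions) < 4) stop("condition grid needs >= 4 values")
  if (missing(seed)) stop("'seed' is mandatory")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (is.null(anchor)) {
    anchor <- if (mode == "ph_series") 7 else max(conditions)
  }
  structure(list(mode = mode, params = params,
                 conditions = sort(conditions), temperature = temperature,
                 fixed = fixed, anchor = anchor, noise_sd = noise_sd,
                 potential_jitter = potential_jitter,
                 background = background, cap_offset = cap_offset,
                 film_loss_rate = film_loss_rate,
                 broadening_width = broadening_width, seed = as.integer(seed),
                 vertices = sort(vertices),
                 points_per_sweep = as.integer(points_per_sweep),
                 scan_rate_V_s = scan_rate_V_s,
                 reference_every = as.integer(reference_every),
                 reference = reference),
            class = "synthesis_config")
}

# triangular potential program: high -> low -> high, shared grid both ways
sweep_program <- function(vertices, n) {
  down <- seq(vertices[2], vertices[1], length.out = n)
  c(down, rev(down)[-1])
}

series_wave_at <- function(cfg, condition, ctx) {
  if (cfg$mode == "ph_series") {
    ph_series_wave(condition, cfg$params, ctx)
  } else {
    h2_series_wave(condition, cfg$params, ctx)
  }
}

#' Synthesize a CV series with nuisance structure
#'
#' For each condition, the waveshape parameters come from the pH or H2
#' apparent-parameter model; the emitted trace is the (optionally broadened)
#' steady-state waveform scaled by exponential film loss, plus a quadratic
#' capacitive background with a sweep-direction-antisymmetric offset and
#' seeded Gaussian noise. Matching blank files (background + noise only) and
#' interleaved reference scans at the anchor condition are emitted, and a
#' YAML manifest records the full generator parameter set, enabling
#' automatic recovery scoring. Two runs with the same seed produce identical
#' numeric content.
#'
#' @param cfg A \code{\link{synthesis_config}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path. The manifest lists every file with
#'   its role, condition and sequence index.
#' @export
synthesize_series <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synthesis_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  ctx <- physical_context(cfg$temperature)
  E <- sweep_program(cfg$vertices, cfg$points_per_sweep)
  direction <- c(rep(-1, cfg$points_per_sweep),
                 rep(1, cfg$points_per_sweep - 1))
  bg <- cfg$background[1] + cfg$background[2] * E + cfg$background[3] * E^2 +
    direction * cfg$cap_offset
  waves <- lapply(cfg$conditions, series_wave_at, cfg = cfg, ctx = ctx)
  anchor_wave <- series_wave_at(cfg, cfg$anchor, ctx)
  noise_scale <- cfg$noise_sd *
    max(vapply(c(waves, list(anchor_wave)),
               function(w) w$ilim_ox, numeric(1)))
  shift <- if (cfg$reference == "SCE") -0.241 else 0
  duration <- diff(range(cfg$vertices)) * 2 / cfg$scan_rate_V_s

  # scan schedule: bracketing reference scans around blocks of samples
  schedule <- list()
  add <- function(role, condition) {
    schedule[[length(schedule) + 1L]] <<- list(role = role,
                                               condition = condition)
  }
  if (cfg$reference_every > 0) add("reference_check", cfg$anchor)
  for (k in seq_along(cfg$conditions)) {
    add("sample", cfg$conditions[k])
    if (cfg$reference_every > 0 &&
        (k %% cfg$reference_every == 0 || k == length(cfg$conditions))) {
      add("reference_check", cfg$anchor)
    }
  }

  files <- list()
  emit <- function(pot, cur, meta, name) {
    path <- file.path(dir, name)
    write_cv(voltammogram(pot, cur, meta), path)
    files[[length(files) + 1L]] <<- list(
      path = name, role = meta$role, condition = meta$condition_value,
      sequence_index = meta$sequence_index)
  }
  seq_i <- 0L
  for (scan in schedule) {
    seq_i <- seq_i + 1L
    w <- series_wave_at(cfg, scan$condition, ctx)
    film <- exp(-cfg$film_loss_rate * (seq_i - 1L))
    i_enz <- film * broadened_current(E, w, cfg$broadening_width, ctx)
    new_jitter <- function() {
      if (cfg$potential_jitter > 0) {
        stats::rnorm(length(E), 0, cfg$potential_jitter)
      } else 0
    }
    meta_common <- list(
      temperature_K = cfg$temperature,
      scan_rate_V_s = cfg$scan_rate_V_s, rotation_rpm = 3000,
      reference = cfg$reference, sequence_index = seq_i,
      timestamp = (seq_i - 1L) * duration,
      condition_value = scan$condition)
    if (cfg$mode == "ph_series") {
      meta_common$pH <- scan$condition
      meta_common$h2_mM <- cfg$fixed %||% NA
    } else {
      meta_common$pH <- cfg$fixed %||% NA
      meta_common$h2_mM <- scan$condition
    }
    meta_s <- c(meta_common, list(role = scan$role))
    name_s <- sprintf("scan_%03d_%s.csv", seq_i,
                      if (scan$role == "sample") "sample" else "ref")
    emit(E + shift + new_jitter(),
         i_enz + bg + stats::rnorm(length(E), 0, noise_scale),
         meta_s, name_s)
    if (scan$role == "sample") {
      meta_b <- c(meta_common, list(role = "blank"))
      emit(E + shift + new_jitter(),
           bg + stats::rnorm(length(E), 0, noise_scale), meta_b,
           sprintf("scan_%03d_blank.csv", seq_i))
    }
  }

  manifest <- list(
    generator = c(list(mode = cfg$mode, temperature = cfg$temperature,
                       fixed = cfg$fixed, anchor = cfg$anchor,
                       noise_sd = cfg$noise_sd,
                       background = cfg$background,
                       cap_offset = cfg$cap_offset,
                       film_loss_rate = cfg$film_loss_rate,
                       broadening_width = cfg$broadening_width,
                       seed = cfg$seed, reference = cfg$reference),
                  list(params = unclass(cfg$params))),
    files = files)
  manifest_path <- file.path(dir, "manifest.yml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}

#' Synthesize an FTIR pH-titration table
#'
#' Equilibrium four-state fractions over a pH grid at fixed H2 pressure,
#' with optional seeded Gaussian noise and triplicate emission. With
#' \code{extinction} ratios different from 1 the table carries band
#' amplitudes instead of fractions (columns \code{a_*}), emulating
#' unequal extinction coefficients.
#'
#' @param params A \code{\link{thermo_params}} generator set.
#' @param pH_grid pH grid (length >= 4).
#' @param p_h2 H2 partial pressure, atm (default 0.02, i.e. 2% H2).
#' @param temperature Kelvin.
#' @param noise_sd Gaussian noise on each fraction (absolute).
#' @param replicates Number of replicate rows per pH (default 1).
#' @param extinction Relative extinction coefficients (ox, red, redH,
#'   sredH); when not all 1, amplitudes \code{a_* = extinction * fraction}
#'   are emitted.
#' @param seed Integer seed.
#' @param path Optional output file (written via
#'   \code{\link{write_titration}}).
#' @return The titration data.frame (invisibly when \code{path} is given).
#' @export
synthesize_ftir <- function(params, pH_grid, p_h2 = 0.02,
                            temperature = 298.15, noise_sd = 0,
                            replicates = 1, extinction = rep(1, 4),
                            seed, path = NULL) {
  if (length(pH_grid) < 4) stop("pH grid needs >= 4 values")
  if (missing(seed)) stop("'seed' is mandatory")
  set.seed(as.integer(seed))
  ctx <- physical_context(temperature)
  pH <- rep(sort(pH_grid), each = replicates)
  fr <- equilibrium_fractions(pH, p_h2, params, ctx)
  vals <- as.matrix(fr[, -1])
  if (noise_sd > 0) {
    vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd),
                          nrow = nrow(vals))
    vals <- pmax(vals, 0)
  }
  if (all(extinction == 1)) {
    out <- data.frame(pH = pH, vals)
  } else {
    amps <- sweep(vals, 2, extinction, "*")
    colnames(amps) <- c("a_ox", "a_red", "a_redH", "a_sredH")
    out <- data.frame(pH = pH, amps)
  }
  if (!is.null(path)) {
    write_titration(out, path, meta = list(
      p_h2_atm = p_h2, temperature_K = temperature, seed = seed,
      noise_sd = noise_sd,
      gen_pK = params$pK, gen_e1_0 = params$e1_0, gen_e2_0 = params$e2_0))
    return(invisible(out))
  }
  out
}
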