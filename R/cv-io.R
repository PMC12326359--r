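# Voltammogram container, the delimited-text CV dialect, and the
# Methods-level preprocessing: reference-electrode conversion, sweep
# splitting/averaging, blank subtraction, film-loss normalization.

#' Voltammogram container
#'
#' A potential/current trace with acquisition metadata. Potentials are stored
#' in volts; files carrying a \code{potential_unit: mV} tag are converted on
#' read.
#'
#' @param potential Potential vector (volts), length >= 16, spanning
#'   > 0.1 V.
#' @param current Current vector, same length.
#' @param meta Named list: \code{pH}, \code{temperature_K}, \code{h2_mM},
#'   \code{scan_rate_V_s}, \code{rotation_rpm}, \code{reference}
#'   (\code{"SCE"} or \code{"SHE"}), \code{role} (\code{"sample"},
#'   \code{"blank"} or \code{"reference_check"}), \code{sequence_index},
#'   \code{timestamp}. Completeness is enforced for \code{role = "sample"}.
#' @return An object of class \code{"voltammogram"}.
#' @export
voltammogram <- function(potential, current, meta = list()) {
  if (length(potential) != length(current)) {
    stop("'potential' and 'current' must have the same length")
  }
  if (length(potential) < 16) stop("trace too short (need >= 16 points)")
  if (diff(range(potential)) <= 0.1) {
    stop("potential range must span more than 0.1 V")
  }
  if (identical(meta$role, "sample")) {
    needed <- c("pH", "temperature_K", "h2_mM", "scan_rate_V_s",
                "reference", "sequence_index")
    missing <- setdiff(needed, names(meta))
    if (length(missing)) {
      stop("sample voltammogram metadata incomplete; missing: ",
           paste(missing, collapse = ", "))
    }
  }
  structure(list(potential = as.numeric(potential),
                 current = as.numeric(current), meta = meta),
            class = "voltammogram")
}

#' @export
print.voltammogram <- function(x, ...) {
  cat(sprintf("Voltammogram (%d points, %.3f to %.3f V vs %s)\n",
              length(x$potential), min(x$potential), max(x$potential),
              if (is.null(x$meta$reference)) "?" else x$meta$reference))
  m <- x$meta
  if (length(m)) {
    keys <- intersect(c("role", "pH", "h2_mM", "temperature_K",
                        "scan_rate_V_s", "sequence_index"), names(m))
    cat("  ", paste(sprintf("%s=%s", keys, unlist(m[keys])),
                    collapse = "  "), "\n")
  }
  invisible(x)
}

#' @export
plot.voltammogram <- function(x, ...) {
  graphics::plot(x$potential, x$current, type = "l",
                 xlab = "E (V)", ylab = "i", ...)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Read / write a CV file
#'
#' The file dialect is \code{# key: value} header lines carrying the
#' metadata followed by two delimited numeric columns (\code{potential},
#' \code{current}; tab or comma separated). Round trips are lossless. A
#' header tag \code{potential_unit: mV} triggers conversion to volts on
#' read.
#'
#' @param path File path.
#' @return \code{read_cv}: a \code{\link{voltammogram}}.
#' @export
read_cv <- function(path) {
  parsed <- read_kv_table(path)
  tab <- parsed$table
  if (!all(c("potential", "current") %in% names(tab))) {
    stop("CV file must have 'potential' and 'current' columns (got: ",
         paste(names(tab), collapse = ", "), ")")
  }
  if (!all(vapply(tab[c("potential", "current")], is.numeric, logical(1)))) {
    stop("non-numeric rows in CV columns")
  }
  meta <- parsed$meta
  pot <- tab$potential
  unit <- meta$potential_unit
  if (!is.null(unit)) {
    if (identical(tolower(unit), "mv")) {
      pot <- pot / 1000
    } else if (!identical(tolower(unit), "v")) {
      stop("unknown potential_unit: ", unit)
    }
    meta$potential_unit <- NULL
  }
  voltammogram(pot, tab$current, meta)
}

#' @rdname read_cv
#' @param v A \code{\link{voltammogram}}.
#' @export
write_cv <- function(v, path) {
  write_kv_table(
    data.frame(potential = sprintf("%.10g", v$potential),
               current = sprintf("%.10g", v$current)),
    path, v$meta)
}

#' Convert potentials to the SHE reference
#'
#' \eqn{E_{SHE} = E_{SCE} + 241\,\mathrm{mV}}. Idempotent for traces already
#' referenced to SHE.
#'
#' @param v A \code{\link{voltammogram}} with known \code{meta$reference}.
#' @return The voltammogram with potentials vs SHE.
#' @export
to_she <- function(v) {
  ref <- v$meta$reference
  if (is.null(ref)) stop("reference electrode unknown; cannot convert")
  if (identical(ref, "SHE")) return(v)
  if (!identical(ref, "SCE")) stop("unknown reference electrode: ", ref)
  v$potential <- v$potential + 0.241
  v$meta$reference <- "SHE"
  v
}

#' Split a triangular sweep and average the two half-sweeps
#'
#' Detects the sweep vertex as the sign change of the potential increment,
#' interpolates the forward and backward half-sweeps onto a common potential
#' grid and averages them, cancelling capacitive contributions that reverse
#' sign with scan direction.
#'
#' @param v A \code{\link{voltammogram}} containing at least one forward and
#'   one backward sweep.
#' @param n_grid Optional number of points for a uniform common grid;
#'   by default the first half-sweep's own potentials (restricted to the
#'   overlap) are reused.
#' @return A single-sweep \code{\link{voltammogram}} on an increasing grid.
#' @export
split_and_average_sweeps <- function(v, n_grid = NULL) {
  dE <- diff(v$potential)
  s <- sign(dE[dE != 0])
  turns <- which(diff(s) != 0)
  if (length(turns) == 0) {
    stop("no sweep vertex found: potential program is monotone")
  }
  # index (into the full trace) of the first vertex
  nz <- which(dE != 0)
  vertex <- nz[turns[1] + 1L]
  i1 <- seq_len(vertex)
  i2 <- seq(vertex, length(v$potential))
  lo <- max(min(v$potential[i1]), min(v$potential[i2]))
  hi <- min(max(v$potential[i1]), max(v$potential[i2]))
  if (hi - lo <= 0) stop("half-sweeps do not overlap")
  # reuse the first half-sweep's own sample points as the common grid (no
  # resampling error there; the second half-sweep usually shares the same
  # potentials on a symmetric program), unless a grid size is requested
  grid <- if (is.null(n_grid)) {
    sort(unique(v$potential[i1][v$potential[i1] >= lo &
                                  v$potential[i1] <= hi]))
  } else {
    seq(lo, hi, length.out = n_grid)
  }
  c1 <- stats::approx(v$potential[i1], v$current[i1], xout = grid,
                      ties = mean)$y
  c2 <- stats::approx(v$potential[i2], v$current[i2], xout = grid,
                      ties = mean)$y
  meta <- v$meta
  meta$sweeps_averaged <- TRUE
  voltammogram(grid, (c1 + c2) / 2, meta)
}

#' Subtract a blank (no-enzyme) voltammogram
#'
#' Removes the capacitive current by interpolating a blank trace onto the
#' sample grid and subtracting it. Sample points outside the blank's
#' potential range are trimmed.
#'
#' @param sample,blank \code{\link{voltammogram}} objects with overlapping
#'   potential ranges (>= 50% of the sample range).
#' @return The blank-subtracted sample.
#' @export
subtract_blank <- function(sample, blank) {
  lo <- max(min(sample$potential), min(blank$potential))
  hi <- min(max(sample$potential), max(blank$potential))
  overlap <- hi - lo
  if (overlap <= 0) stop("sample and blank potential ranges are disjoint")
  if (overlap < 0.5 * diff(range(sample$potential))) {
    stop("sample and blank overlap by less than 50% of the sample range")
  }
  keep <- sample$potential >= lo & sample$potential <= hi
  pot <- sample$potential[keep]
  bl <- stats::approx(blank$potential, blank$current, xout = pot,
                      ties = mean)$y
  meta <- sample$meta
  meta$blank_subtracted <- TRUE
  voltammogram(pot, sample$current[keep] - bl, meta)
}

# robust plateau statistic: median current over the top (or bottom) 5% of
# the potential window
plateau_current <- function(v, side = c("top", "bottom"), frac = 0.05) {
  side <- match.arg(side)
  rng <- range(v$potential)
  cut <- if (side == "top") rng[2] - frac * diff(rng) else
    rng[1] + frac * diff(rng)
  sel <- if (side == "top") v$potential >= cut else v$potential <= cut
  stats::median(v$current[sel])
}

#' Normalize a CV series for film loss
#'
#' Progressive enzyme desorption shrinks all currents over a series of
#' scans. Interleaved reference scans (\code{meta$role =
#' "reference_check"}), recorded at fixed conditions, track the loss: each
#' scan is rescaled by the reciprocal of the relative oxidative plateau of
#' the bracketing references, interpolated linearly in log scale versus
#' \code{sequence_index} (exponential-decay assumption). The first reference
#' defines scale 1. With references only at the ends the same log-linear
#' interpolation applies across the whole series.
#'
#' @param series List of \code{\link{voltammogram}} objects with
#'   \code{meta$role} and \code{meta$sequence_index}.
#' @return The series with currents rescaled. When no reference scans are
#'   present the series is returned unchanged with attribute
#'   \code{"film_loss_normalized" = FALSE} and a warning.
#' @export
film_loss_normalize <- function(series) {
  roles <- vapply(series, function(v) v$meta$role %||% "sample", character(1))
  idx <- vapply(series, function(v) as.numeric(v$meta$sequence_index %||% NA),
                numeric(1))
  is_ref <- roles == "reference_check"
  if (!any(is_ref)) {
    warning("no reference_check scans in series; film-loss normalization skipped")
    attr(series, "film_loss_normalized") <- FALSE
    return(series)
  }
  if (any(is.na(idx))) stop("every scan needs a sequence_index for normalization")
  ref_idx <- idx[is_ref]
  ref_plateau <- vapply(series[is_ref], plateau_current, numeric(1))
  ord <- order(ref_idx)
  ref_idx <- ref_idx[ord]
  rel <- ref_plateau[ord] / ref_plateau[ord][1]
  if (any(rel <= 0)) stop("non-positive reference plateau; cannot normalize")
  log_rel_at <- function(s) {
    if (length(ref_idx) == 1) return(log(rel))
    stats::approx(ref_idx, log(rel), xout = s, rule = 2)$y
  }
  out <- lapply(series, function(v) {
    fac <- exp(log_rel_at(as.numeric(v$meta$sequence_index)))
    v$current <- v$current / fac
    v$meta$film_loss_factor <- fac
    v
  })
  attr(out, "film_loss_normalized") <- TRUE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
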