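# End-to-end chain: read a synthetic (or measured) CV series manifest,
# apply the Methods-level preprocessing, extract waveshape parameters from
# every sample scan, and fit the pH or H2 series model. Recovery scoring
# compares the result against the generator parameters recorded in the
# manifest.

#' Read a CV-series manifest
#'
#' @param manifest_path Path to a YAML manifest written by
#'   \code{\link{synthesize_series}} (or hand-written in the same layout:
#'   a \code{files} list of \code{path}/\code{role}/\code{condition}/
#'   \code{sequence_index} entries, plus an optional \code{generator}
#'   block).
#' @return List with \code{generator} (or NULL), \code{files} (data.frame)
#'   and \code{dir}.
#' @export
read_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path)
  }
  m <- yaml::read_yaml(manifest_path)
  if (is.null(m$files) || length(m$files) == 0) {
    stop("manifest lists no files")
  }
  files <- do.call(rbind, lapply(m$files, function(f) {
    data.frame(path = f$path, role = f$role,
               condition = as.numeric(f$condition),
               sequence_index = as.integer(f$sequence_index))
  }))
  list(generator = m$generator, files = files,
       dir = dirname(manifest_path))
}

#' Preprocess a CV series
#'
#' Runs the standard preprocessing chain on every sample scan of a
#' manifest: read, convert to SHE, split and average the triangular sweep,
#' subtract the matching blank (same sequence index; fallback: nearest
#' blank), then normalize the whole series for film loss using the
#' interleaved reference scans.
#'
#' @param manifest A manifest path or the result of
#'   \code{\link{read_manifest}}.
#' @return List of processed sample \code{\link{voltammogram}}s (attribute
#'   \code{"conditions"} carries their condition values).
#' @export
preprocess_series <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  files <- manifest$files
  load_one <- function(row) to_she(read_cv(file.path(manifest$dir, row$path)))
  avg <- function(v) split_and_average_sweeps(v)
  blanks <- files[files$role == "blank", ]
  prep_sample <- function(row) {
    v <- avg(load_one(row))
    if (nrow(blanks)) {
      j <- which(blanks$sequence_index == row$sequence_index)
      if (!length(j)) {
        j <- which.min(abs(blanks$sequence_index - row$sequence_index))
      }
      b <- avg(load_one(blanks[j[1], ]))
      v <- subtract_blank(v, b)
    }
    v
  }
  keep <- files$role %in% c("sample", "reference_check")
  scans <- lapply(seq_len(nrow(files))[keep], function(i) {
    row <- files[i, ]
    if (row$role == "sample") prep_sample(row) else {
      # reference scans are blank-subtracted against the nearest blank too
      prep_sample(row)
    }
  })
  roles <- files$role[keep]
  normalized <- suppressWarnings(film_loss_normalize(scans))
  samples <- normalized[roles == "sample"]
  attr(samples, "conditions") <- files$condition[keep][roles == "sample"]
  samples
}

#' Fit a whole preprocessed series
#'
#' Stage-1 wave fits for every sample scan followed by the stage-2 series
#' fit.
#'
#' @param manifest Manifest path or \code{\link{read_manifest}} result.
#' @param mode \code{"ph_series"} or \code{"h2_series"}; default taken from
#'   the manifest's generator block.
#' @param constrain_eeq Optional equilibrium potential (volts) imposed on
#'   every stage-1 fit via the waveshape/equilibrium relation, or the
#'   string \code{"nernst"} to compute it per scan from the metadata.
#' @param broadening_width Broadening width passed to the stage-1 fits.
#' @return List with \code{series_fit} (a \code{ph_series_fit} or
#'   \code{h2_series_fit}), \code{wave_fits}, \code{dataset} and
#'   \code{manifest}.
#' @export
fit_series_pipeline <- function(manifest, mode = NULL, constrain_eeq = NULL,
                                broadening_width = 0) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(mode)) mode <- manifest$generator$mode
  if (is.null(mode)) stop("series mode not given and absent from manifest")
  samples <- preprocess_series(manifest)
  conditions <- attr(samples, "conditions")
  wave_fits <- lapply(samples, function(v) {
    ctx <- physical_context(v$meta$temperature_K %||% 298.15)
    ceeq <- constrain_eeq
    if (identical(ceeq, "nernst")) {
      sol <- h2_solubility(v$meta$temperature_K - 273.15, warn = FALSE)
      ceeq <- nernst_eeq(v$meta$pH, v$meta$h2_mM / sol, ctx)
    }
    fit_wave(v, ctx, constrain_eeq = ceeq,
             broadening_width = broadening_width)
  })
  temperature <- samples[[1]]$meta$temperature_K %||% 298.15
  ctype <- if (mode == "ph_series") "pH" else "h2_mM"
  d <- series_dataset(conditions, wave_fits, condition_type = ctype,
                      temperature = temperature,
                      anchor = manifest$generator$anchor %||% NULL)
  sfit <- if (mode == "ph_series") fit_ph_series(d) else fit_h2_series(d)
  list(series_fit = sfit, wave_fits = wave_fits, dataset = d,
       manifest = manifest)
}

#' Score parameter recovery against a manifest's generator block
#'
#' Runs \code{\link{fit_series_pipeline}} and compares the recovered
#' series parameters with the generator values recorded in the manifest.
#'
#' @inheritParams fit_series_pipeline
#' @return A data.frame with columns \code{parameter}, \code{generated},
#'   \code{recovered}, \code{delta} (attribute \code{"fit"} holds the full
#'   pipeline result).
#' @export
score_recovery <- function(manifest, constrain_eeq = NULL,
                           broadening_width = 0) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  gen <- manifest$generator
  if (is.null(gen) || is.null(gen$params)) {
    stop("manifest carries no generator parameters to score against")
  }
  res <- fit_series_pipeline(manifest, constrain_eeq = constrain_eeq,
                             broadening_width = broadening_width)
  rec <- coef(res$series_fit)
  keys <- if (gen$mode == "ph_series") {
    c("e1_0app", "e2_0", "pK", "pK1", "pK2", "pK3")
  } else {
    c("e1_0prime", "e2_0app", "km")
  }
  gen_par <- unlist(gen$params)
  keys <- intersect(keys, names(gen_par))
  out <- data.frame(parameter = keys,
                    generated = as.numeric(gen_par[keys]),
                    recovered = as.numeric(rec[keys]))
  out$delta <- out$recovered - out$generated
  attr(out, "fit") <- res
  out
}
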