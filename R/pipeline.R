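#' Pipeline configuration
#'
#' Collects all tunable parameters of the picking pipeline with their
#' defaults.  Only the significance threshold `threshold` genuinely depends
#' on experimental conditions and should always be reviewed by the user.
#'
#' @param charges Charge states to consider (default 1:4).
#' @param shape_kind `"gaussian"` or `"emg"`.
#' @param q Fit norm: 2 (non-negative least squares) or 1 (non-negative
#'   least absolute deviation, robust to model misfit).
#' @param window_h Sliding half-width for the local noise level and the
#'   goodness-of-fit windows (Th).
#' @param factor_place Placement gate: templates are placed where the
#'   intensity exceeds `factor_place` times the local noise level.
#' @param merge_ppm Adjacency tolerance for merging split templates (ppm).
#' @param threshold Signal-to-noise significance threshold t.
#' @param kappa Isotopic spacing constant (Da), in [1.002, 1.008].
#' @param mass_filter Apply the peptide-mass-center filter to the final
#'   list?
#' @param mass_filter_ppm Tolerance of that filter (ppm).
#' @param trim_rel Isotopic peaks below this fraction of the pattern maximum
#'   are dropped from templates.
#' @param shape_params Optional fixed peak-shape parameters, e.g.
#'   `list(kind = "gaussian", sigma = 0.05)`; bypasses automatic calibration
#'   (and is the fallback if calibration fails).
#' @param calibration List of arguments passed to [detect_peak_regions()].
#' @param trend_basis Basis for the shape-parameter trends (`"linear"` or
#'   `"constant"`).
#' @param gof_stride Stride for the single-peak design of the GOF map.
#' @param solver A [solver_config()].
#' @param log_level `"info"` (stage-level progress counts) or `"quiet"`.
#' @return A list of class `"pick_config"`.
#' @export
pick_config <- function(charges = 1:4, shape_kind = c("gaussian", "emg"),
                        q = 2, window_h = 2.5, factor_place = 1.5,
                        merge_ppm = 100, threshold = 5, kappa = 1.00235,
                        mass_filter = FALSE, mass_filter_ppm = 200,
                        trim_rel = 0.01, shape_params = NULL,
                        calibration = list(), trend_basis = "linear",
                        gof_stride = 1L, solver = solver_config(),
                        log_level = c("info", "quiet")) {
  shape_kind <- match.arg(shape_kind)
  log_level <- match.arg(log_level)
  stopifnot(q %in% c(1, 2), window_h > 0, factor_place > 0, merge_ppm > 0,
            threshold >= 0, kappa >= 1.002, kappa <= 1.008)
  structure(
    list(charges = as.integer(charges), shape_kind = shape_kind, q = q,
         window_h = window_h, factor_place = factor_place,
         merge_ppm = merge_ppm, threshold = threshold, kappa = kappa,
         mass_filter = mass_filter, mass_filter_ppm = mass_filter_ppm,
         trim_rel = trim_rel, shape_params = shape_params,
         calibration = calibration, trend_basis = trend_basis,
         gof_stride = as.integer(gof_stride), solver = solver,
         log_level = log_level),
    class = "pick_config"
  )
}

log_stage <- function(config, fmt, ...) {
  if (identical(config$log_level, "info")) inform(sprintf(fmt, ...))
}

#' Run the full template-matching pipeline on one spectrum
#'
#' Stages: peak-shape calibration (unless fixed parameters are supplied),
#' local noise level, template placement, sparse template-matrix assembly,
#' non-negative fit (interior point), goodness-of-fit map, merging of split
#' templates, signal-to-noise scoring, thresholding, and the optional
#' peptide-mass filter.  Deterministic given the spectrum and configuration.
#'
#' @param spectrum A spectrum data frame (see [as_spectrum()]).
#' @param config A [pick_config()].
#' @return A `"peaklist"` tibble: one row per reported feature with columns
#'   `monoisotopic_mz`, `charge`, `neutral_mass`, `beta` (apex intensity),
#'   `ratio`, `lnl_plus`, `gof_plus`, `anchor_mz`, `n_members`.  Attributes:
#'   `config`, `spectrum`, `scores` (all scored features before
#'   thresholding), `stage_counts`.
#' @examples
#' sim <- simulate_spectrum(
#'   data.frame(mass = 1200, charge = 1, height = 50),
#'   mz_range = c(1195, 1215), spacing = 0.02,
#'   shape = list(kind = "gaussian", sigma = 0.04)
#' )
#' cfg <- pick_config(charges = 1:2, threshold = 1, log_level = "quiet",
#'                    shape_params = list(kind = "gaussian", sigma = 0.04))
#' pick_peaks(sim$spectrum, cfg)
#' @export
pick_peaks <- function(spectrum, config = pick_config()) {
  stopifnot(inherits(config, "pick_config"))
  s <- as_spectrum(spectrum)

  shape_model <- if (!is.null(config$shape_params)) {
    sp <- config$shape_params
    sp$kind <- sp$kind %||% config$shape_kind
    sp
  } else {
    tryCatch(
      do.call(calibrate_peak_shape,
              c(list(s, kind = config$shape_kind, basis = config$trend_basis),
                config$calibration)),
      error = function(e) {
        abort(paste0("Stage `calibrate`: ", conditionMessage(e)), parent = e)
      }
    )
  }
  if (inherits(shape_model, "shape_param_model")) {
    log_stage(config, "calibrate: %d region fits", nrow(shape_model$fit_pairs))
  }

  noise <- local_noise_level(s, h = config$window_h)
  placements <- select_placements(s, noise, factor_place = config$factor_place,
                                  charges = config$charges)
  log_stage(config, "place: %d templates (%d positions x %d charges)",
            nrow(placements), nrow(placements) %/% max(1L, length(config$charges)),
            length(config$charges))
  empty <- tibble(
    monoisotopic_mz = numeric(), charge = integer(), neutral_mass = numeric(),
    beta = numeric(), ratio = numeric(), lnl_plus = numeric(),
    gof_plus = numeric(), anchor_mz = numeric(), n_members = integer()
  )
  finalize <- function(pl, scores = empty) {
    pl <- pl[, names(empty)]
    attr(pl, "config") <- config
    attr(pl, "spectrum") <- s
    attr(pl, "scores") <- scores
    class(pl) <- unique(c("peaklist", class(pl)))
    pl
  }
  if (nrow(placements) == 0L) {
    log_stage(config, "no placements above the noise gate; empty peaklist")
    return(finalize(empty))
  }

  tm <- assemble_template_matrix(s, placements, shape_model,
                                 kappa = config$kappa,
                                 trim_rel = config$trim_rel)
  fit <- tryCatch(
    if (config$q == 2) nnls_logbarrier(tm, s$intensity, config$solver)
    else nnlad_logbarrier(tm, s$intensity, config$solver),
    error = function(e) abort(paste0("Stage `fit`: ", conditionMessage(e)), parent = e)
  )
  log_stage(config, "fit (q = %d): %d of %d coefficients positive",
            config$q, sum(fit$beta > 0), length(fit$beta))

  gof <- goodness_of_fit_map(s, shape_model, q = config$q, h = config$window_h,
                             config = config$solver, stride = config$gof_stride)

  groups <- group_templates(fit, tm, ppm_tol = config$merge_ppm)
  if (nrow(groups) == 0L) {
    log_stage(config, "no positive templates; empty peaklist")
    return(finalize(empty))
  }
  spacing <- median(diff(s$mz))
  merged <- groups |>
    group_by(.data$charge, .data$group) |>
    dplyr::group_map(~ merge_group(.x |> mutate(charge = .y$charge),
                                   shape_model, data_spacing = spacing)) |>
    bind_rows()
  log_stage(config, "merge: %d groups -> %d features", nrow(merged), nrow(merged))

  scored <- score_features(merged, noise, gof, kappa = config$kappa)
  peaklist <- apply_threshold(scored, t = config$threshold)
  if (config$mass_filter) {
    peaklist <- peptide_mass_filter(peaklist, tol_ppm = config$mass_filter_ppm)
  }
  log_stage(config, "threshold t = %g: %d features reported", config$threshold,
            nrow(peaklist))
  finalize(peaklist, scores = scored)
}

#' Write a peaklist as CSV (with a config sidecar)
#'
#' Columns: `monoisotopic_mz`, `charge`, `neutral_mass`, `intensity`,
#' `ratio`, `lnl_plus`, `gof_plus`, `anchor_mz`; masses with 6 decimal
#' places.  The pipeline configuration snapshot, if attached to the
#' peaklist, is written to `<path>.config` as flat key = value pairs.
#'
#' @param peaklist A `"peaklist"` from [pick_peaks()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaklist, path) {
  df <- data.frame(
    monoisotopic_mz = sprintf("%.6f", peaklist$monoisotopic_mz),
    charge = peaklist$charge,
    neutral_mass = sprintf("%.6f", peaklist$neutral_mass),
    intensity = peaklist$beta,
    ratio = peaklist$ratio,
    lnl_plus = peaklist$lnl_plus,
    gof_plus = peaklist$gof_plus,
    anchor_mz = sprintf("%.6f", peaklist$anchor_mz)
  )
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) abort(paste0("Cannot write peaklist to ", path))
  )
  cfg <- attr(peaklist, "config")
  if (!is.null(cfg)) write_pick_config(cfg, paste0(path, ".config"))
  invisible(path)
}

#' Read a peaklist CSV written by [write_peaklist()]
#'
#' @param path CSV path.
#' @return A `"peaklist"` tibble.
#' @export
read_peaklist <- function(path) {
  df <- utils::read.csv(path)
  out <- as_tibble(df) |>
    dplyr::rename(beta = "intensity") |>
    mutate(charge = as.integer(.data$charge))
  class(out) <- unique(c("peaklist", class(out)))
  out
}

# --- flat key = value config serialization ---------------------------------

flatten_config <- function(config) {
  flat <- list()
  for (nm in names(config)) {
    v <- config[[nm]]
    if (nm %in% c("calibration", "solver", "shape_params")) {
      for (sub in names(v)) flat[[paste0(nm, ".", sub)]] <- v[[sub]]
    } else {
      flat[[nm]] <- v
    }
  }
  flat[vapply(flat, function(v) is.numeric(v) || is.character(v) || is.logical(v),
              logical(1))]
}

#' Serialize / parse a pipeline configuration
#'
#' Flat `key = value` text format; vector values are comma-separated and
#' nested solver/calibration/fixed-shape entries use dotted keys.  A
#' round trip through `write_pick_config()` and `read_pick_config()`
#' reproduces the configuration.
#'
#' @param config A [pick_config()].
#' @param path File path.
#' @return `write_pick_config()`: `path` invisibly; `read_pick_config()`:
#'   a `"pick_config"`.
#' @export
write_pick_config <- function(config, path) {
  flat <- flatten_config(config)
  lines <- vapply(names(flat), function(nm) {
    v <- flat[[nm]]
    val <- if (is.numeric(v)) paste(format(v, digits = 17), collapse = ",")
           else paste(as.character(v), collapse = ",")
    paste0(nm, " = ", val)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pick_config
#' @export
read_pick_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- list(); solver <- list(); calibration <- list(); shape <- list()
  for (pair in kv) {
    key <- trimws(pair[[1L]])
    raw <- strsplit(trimws(pair[[2L]]), ",")[[1L]]
    num <- suppressWarnings(as.numeric(raw))
    val <- if (!anyNA(num)) num
           else if (all(raw %in% c("TRUE", "FALSE"))) as.logical(raw)
           else raw
    if (startsWith(key, "solver.")) {
      solver[[sub("^solver\\.", "", key)]] <- val
    } else if (startsWith(key, "calibration.")) {
      calibration[[sub("^calibration\\.", "", key)]] <- val
    } else if (startsWith(key, "shape_params.")) {
      shape[[sub("^shape_params\\.", "", key)]] <- val
    } else {
      args[[key]] <- val
    }
  }
  args$solver <- do.call(solver_config, solver)
  args$calibration <- calibration
  if (length(shape) > 0L) args$shape_params <- shape
  do.call(pick_config, args)
}
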