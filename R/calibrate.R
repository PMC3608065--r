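#' Detect well-resolved peak regions
#'
#' Simple deterministic peak detection used to collect calibration material:
#' local maxima above an intensity quantile are grown into regions by
#' monotone descent (tolerating `max_violations` increases per side),
#' stopping at a valley or when the intensity drops below `stop_frac` of the
#' apex.  Apexes closer than `sep_window` to another retained apex are
#' discarded as not well resolved.
#'
#' @param spectrum A spectrum data frame.
#' @param quantile_gate Apex must exceed this intensity quantile of the
#'   spectrum (default 0.75).
#' @param stop_frac Region growth stops below this fraction of the apex.
#' @param min_points Minimum number of data points per region.
#' @param max_violations Tolerated monotonicity violations per side.
#' @param sep_window Minimum apex-to-apex distance (Th) for a peak to count
#'   as isolated.
#' @param min_regions Error if fewer regions are found.
#' @return A tibble with columns `start`, `end` (row indices into the
#'   spectrum), `apex_index`, `apex_mz`, `apex_intensity`, sorted by m/z.
#' @export
detect_peak_regions <- function(spectrum, quantile_gate = 0.75,
                                stop_frac = 0.05, min_points = 8L,
                                max_violations = 1L, sep_window = 0.5,
                                min_regions = 5L) {
  s <- as_spectrum(spectrum)
  y <- s$intensity
  n <- length(y)
  gate <- quantile(y, quantile_gate)
  # strict rise on the left, weak fall on the right: a flat-topped apex
  # (equal neighboring maxima) counts once
  apexes <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
  apexes <- apexes[y[apexes] > gate]
  regions <- lapply(apexes, function(a) {
    lo <- a; viol <- 0L
    while (lo > 1L && y[lo - 1L] >= stop_frac * y[a]) {
      if (y[lo - 1L] > y[lo]) {
        viol <- viol + 1L
        if (viol > max_violations) break
      }
      lo <- lo - 1L
    }
    hi <- a; viol <- 0L
    while (hi < n && y[hi + 1L] >= stop_frac * y[a]) {
      if (y[hi + 1L] > y[hi]) {
        viol <- viol + 1L
        if (viol > max_violations) break
      }
      hi <- hi + 1L
    }
    c(lo, hi, a)
  })
  out <- tibble(
    start = vapply(regions, `[`, integer(1), 1L) |> as.integer(),
    end = vapply(regions, `[`, integer(1), 2L) |> as.integer(),
    apex_index = vapply(regions, `[`, integer(1), 3L) |> as.integer()
  ) |>
    mutate(apex_mz = s$mz[.data$apex_index],
           apex_intensity = y[.data$apex_index]) |>
    filter(.data$end - .data$start + 1L >= min_points,
           .data$apex_index > .data$start, .data$apex_index < .data$end)
  if (nrow(out) > 1L) {
    d <- as.matrix(stats::dist(out$apex_mz))
    diag(d) <- Inf
    out <- out[apply(d, 1L, min) >= sep_window, , drop = FALSE]
  }
  out <- arrange(out, .data$apex_mz)
  if (nrow(out) < min_regions) {
    abort(paste0(
      "Only ", nrow(out), " well-resolved peak region(s) found (need ",
      min_regions, "); supply fixed peak-shape parameters via ",
      "`shape_params` instead of automatic calibration."
    ))
  }
  out
}

#' Fit a peak-shape model to one region
#'
#' Nonlinear least squares of the single-peak model (free height times the
#' Gaussian or EMG shape) to the data in a detected region.  Initialization
#' uses sample moments (sigma from an FWHM estimate, mu = 0, alpha =
#' sigma/2).  For the EMG, the characteristic location is fixed at the
#' detected apex and `mu` absorbs the residual shift, since a free location
#' and a free `mu` are jointly unidentifiable.
#'
#' @param spectrum A spectrum data frame.
#' @param region One row of [detect_peak_regions()] output.
#' @param kind `"gaussian"` or `"emg"`.
#' @return A list of class `"region_fit"`: `theta` (list with `sigma`,
#'   `alpha`, `mu`), `height`, `apex_mz` (refined to the fitted mode),
#'   `rss`, `rel_rss` (rss / sum(y^2) in the region), `converged`.
#' @export
fit_peak_region <- function(spectrum, region, kind = c("gaussian", "emg")) {
  kind <- match.arg(kind)
  s <- as_spectrum(spectrum)
  idx <- region$start:region$end
  x <- s$mz[idx]; y <- s$intensity[idx]
  apex <- region$apex_mz
  h0 <- region$apex_intensity
  half <- y >= h0 / 2
  fwhm <- if (sum(half) >= 2) diff(range(x[half])) else diff(range(x)) / 4
  sigma0 <- max(fwhm / 2.3548, diff(range(x)) / 50)

  failed <- function() {
    structure(list(theta = list(sigma = NA_real_, alpha = NA_real_, mu = NA_real_),
                   height = NA_real_, apex_mz = apex, center = apex,
                   rss = Inf, rel_rss = Inf, converged = FALSE, kind = kind),
              class = "region_fit")
  }
  if (kind == "gaussian") {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ h * exp(-(x - m)^2 / (2 * s2^2)),
        start = list(h = h0, m = apex, s2 = sigma0),
        lower = c(h = 0, m = min(x), s2 = 1e-6),
        upper = c(h = Inf, m = max(x), s2 = diff(range(x))),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) return(failed())
    cf <- coef(fit)
    rss <- sum(stats::resid(fit)^2)
    structure(list(
      theta = list(sigma = unname(cf[["s2"]]), alpha = NA_real_, mu = 0),
      height = unname(cf[["h"]]), apex_mz = unname(cf[["m"]]),
      center = unname(cf[["m"]]), rss = rss, rel_rss = rss / sum(y^2),
      converged = TRUE, kind = kind
    ), class = "region_fit")
  } else {
    alpha0 <- sigma0 / 2
    h0e <- h0 / max(eval_emg(x, apex, alpha0, sigma0, 0))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ h * eval_emg(x, apex, a, s2, m),
        start = list(h = h0e, a = alpha0, s2 = sigma0, m = 0),
        lower = c(h = 0, a = 1e-6, s2 = 1e-6, m = -diff(range(x))),
        upper = c(h = Inf, a = diff(range(x)), s2 = diff(range(x)), m = diff(range(x))),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) return(failed())
    cf <- coef(fit)
    rss <- sum(stats::resid(fit)^2)
    grid <- seq(min(x), max(x), length.out = 2000L)
    mode_mz <- grid[which.max(eval_emg(grid, apex, cf[["a"]], cf[["s2"]], cf[["m"]]))]
    structure(list(
      theta = list(sigma = unname(cf[["s2"]]), alpha = unname(cf[["a"]]),
                   mu = unname(cf[["m"]])),
      height = unname(cf[["h"]]), apex_mz = mode_mz, center = apex,
      rss = rss, rel_rss = rss / sum(y^2), converged = TRUE, kind = kind
    ), class = "region_fit")
  }
}

# Least absolute deviation fit of theta ~ G nu by iteratively reweighted
# least squares (weights 1/max(|resid|, delta)); the constant-basis special
# case is the exact median.
lad_fit <- function(G, theta, max_iter = 200L, tol = 1e-12) {
  G <- as.matrix(G)
  if (qr(G)$rank < ncol(G)) abort("Degenerate (collinear) trend basis.")
  if (ncol(G) == 1L && length(unique(G[, 1L])) == 1L) {
    return(median(theta) / G[1L, 1L])
  }
  nu <- qr.solve(G, theta)
  scale <- max(abs(theta), 1)
  for (it in seq_len(max_iter)) {
    r <- theta - as.numeric(G %*% nu)
    w <- 1 / pmax(abs(r), 1e-10 * scale)
    nu_new <- tryCatch(
      solve(crossprod(G, w * G), crossprod(G, w * theta)),
      error = function(e) NULL
    )
    if (is.null(nu_new)) break
    nu_new <- as.numeric(nu_new)
    if (max(abs(nu_new - nu)) < tol * (1 + max(abs(nu)))) {
      nu <- nu_new
      break
    }
    nu <- nu_new
  }
  lad_vertex_polish(G, theta, nu)
}

# IRLS approaches the LAD solution but stalls near it; an LAD optimum
# interpolates M = ncol(G) points, so finish with a single-swap local search
# over interpolation sets starting from the M smallest IRLS residuals.
lad_vertex_polish <- function(G, theta, nu) {
  n <- nrow(G); M <- ncol(G)
  if (n <= M) return(nu)
  obj <- function(v) sum(abs(theta - as.numeric(G %*% v)))
  solve_set <- function(idx) {
    sub <- G[idx, , drop = FALSE]
    if (abs(det(sub)) < 1e-14) return(NULL)
    tryCatch(as.numeric(solve(sub, theta[idx])), error = function(e) NULL)
  }
  cur_set <- order(abs(theta - as.numeric(G %*% nu)))[seq_len(M)]
  cand <- solve_set(cur_set)
  best <- if (!is.null(cand) && obj(cand) <= obj(nu)) cand else nu
  best_obj <- obj(best)
  repeat {
    improved <- FALSE
    for (pos in seq_len(M)) {
      for (j in setdiff(seq_len(n), cur_set)) {
        trial_set <- cur_set
        trial_set[pos] <- j
        v <- solve_set(trial_set)
        if (!is.null(v)) {
          o <- obj(v)
          if (o < best_obj - 1e-14 * (1 + best_obj)) {
            best <- v; best_obj <- o; cur_set <- trial_set
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  best
}

#' Fit m/z-dependent trends to peak-shape parameters
#'
#' Models each shape-parameter component as a linear combination of known
#' basis functions of m/z, \eqn{\theta_l(x) = \sum_m \nu_{l,m} g_{l,m}(x)},
#' fitted by least absolute deviation for robustness to poorly resolved or
#' overlapping calibration peaks.  With a constant basis this reduces to the
#' median of the per-region estimates.
#'
#' @param fits List of `"region_fit"` objects (converged fits are used;
#'   fits with `rel_rss > 0.2` are excluded as outliers).
#' @param basis `"linear"` (\{1, x\}), `"constant"`, or a named list of
#'   function lists per component (`sigma`, `alpha`, `mu`).
#' @param kind Peak-shape kind the model is for.
#' @return An object of class `"shape_param_model"`; evaluate with
#'   [eval_params()].
#' @export
fit_param_trend <- function(fits, basis = "linear", kind = NULL) {
  fits <- Filter(function(f) isTRUE(f$converged) && f$rel_rss <= 0.2, fits)
  if (length(fits) == 0L) abort("No usable region fits for trend estimation.")
  kind <- kind %||% fits[[1L]]$kind
  comps <- if (kind == "gaussian") "sigma" else c("sigma", "alpha", "mu")
  default_basis <- function(nm) {
    if (identical(basis, "constant")) list(function(x) rep(1, length(x)))
    else if (identical(basis, "linear")) list(function(x) rep(1, length(x)), function(x) x)
    else basis[[nm]]
  }
  xh <- vapply(fits, function(f) f$apex_mz, numeric(1))
  components <- list()
  for (nm in comps) {
    th <- vapply(fits, function(f) f$theta[[nm]], numeric(1))
    bs <- default_basis(nm)
    if (length(fits) < length(bs) + 1L) {
      abort(paste0("Need at least ", length(bs) + 1L,
                   " converged fits for the `", nm, "` trend."))
    }
    G <- vapply(bs, function(g) g(xh), numeric(length(xh)))
    G <- matrix(G, nrow = length(xh))
    components[[nm]] <- list(basis = bs, coef = lad_fit(G, th))
  }
  structure(
    list(kind = kind, components = components,
         fit_pairs = tibble(
           apex_mz = xh,
           sigma = vapply(fits, function(f) f$theta$sigma, numeric(1)),
           alpha = vapply(fits, function(f) f$theta$alpha, numeric(1)),
           mu = vapply(fits, function(f) f$theta$mu, numeric(1))
         )),
    class = "shape_param_model"
  )
}

#' Evaluate a shape-parameter model at an m/z position
#'
#' @param model A `"shape_param_model"` from [fit_param_trend()].
#' @param x m/z position (Th), scalar.
#' @param floor Positivity floor for `sigma` and `alpha` (Th); trend
#'   extrapolations below it are clipped.
#' @return A list with `kind`, `sigma`, `alpha`, `mu`.
#' @export
eval_params <- function(model, x, floor = 1e-4) {
  stopifnot(inherits(model, "shape_param_model"))
  out <- list(kind = model$kind)
  for (nm in names(model$components)) {
    comp <- model$components[[nm]]
    vals <- vapply(comp$basis, function(g) g(x)[[1L]], numeric(1))
    v <- sum(comp$coef * vals)
    if (nm %in% c("sigma", "alpha")) v <- max(v, floor)
    out[[nm]] <- v
  }
  if (model$kind == "gaussian") { out$alpha <- NA_real_; out$mu <- 0 }
  out
}

# Shape parameters at a position, from either a fitted model or a fixed
# parameter list (list(kind=, sigma=, alpha=, mu=)).
shape_params_at <- function(shape_model, x) {
  if (inherits(shape_model, "shape_param_model")) {
    eval_params(shape_model, x)
  } else if (is.list(shape_model) && !is.null(shape_model$sigma)) {
    list(kind = shape_model$kind %||% "gaussian",
         sigma = shape_model$sigma,
         alpha = shape_model$alpha %||% NA_real_,
         mu = shape_model$mu %||% 0)
  } else {
    abort("`shape_model` must be a shape_param_model or a list with `sigma`.")
  }
}

#' Calibrate peak-shape parameters from a spectrum
#'
#' Convenience wrapper: detect well-resolved regions, fit the peak model in
#' each, and fit robust m/z trends to the resulting parameter estimates.
#'
#' @param spectrum A spectrum data frame.
#' @param kind `"gaussian"` or `"emg"`.
#' @param basis Trend basis (see [fit_param_trend()]).
#' @param ... Passed to [detect_peak_regions()].
#' @return A `"shape_param_model"`.
#' @export
calibrate_peak_shape <- function(spectrum, kind = c("gaussian", "emg"),
                                 basis = "linear", ...) {
  kind <- match.arg(kind)
  s <- as_spectrum(spectrum)
  regions <- detect_peak_regions(s, ...)
  fits <- lapply(seq_len(nrow(regions)), function(i) {
    fit_peak_region(s, regions[i, ], kind)
  })
  fit_param_trend(fits, basis = basis, kind = kind)
}
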