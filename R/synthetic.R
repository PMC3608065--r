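#' Simulate a profile-mode spectrum with known ground truth
#'
#' Generates the sum of max-normalized isotope-pattern templates (one per
#' ground-truth pattern, height = intensity of its most intense peak) plus a
#' constant baseline, additive Gaussian noise (sd relative to the largest
#' pattern height) and optional multiplicative log-normal noise, clipped at
#' zero.  Deterministic for a fixed `seed`.
#'
#' @param patterns Data frame with columns `charge`, `height`, and either
#'   `mass` (neutral monoisotopic, Da) or `sequence` (peptide string).
#' @param mz_range Length-2 numeric: m/z range of the grid (Th).
#' @param spacing Grid spacing (Th, > 0); e.g. 0.06 for a low-resolution
#'   ion-trap line.
#' @param shape List with `kind` and parameters, e.g.
#'   `list(kind = "gaussian", sigma = 0.05)`.
#' @param noise List with `additive_sd` (relative to the max pattern
#'   height), `multiplicative_sd` (log-scale sd), `baseline` (absolute
#'   intensity).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param kappa Isotopic spacing constant (Da).
#' @param snap_anchors If `TRUE`, each pattern's mass is adjusted (by less
#'   than one grid spacing times the charge) so that its most intense peak
#'   falls exactly on a grid point.  Useful for noiseless exact-recovery
#'   studies where the signal should be exactly representable by templates
#'   placed at data positions; real anchors are generically off-grid.
#' @return A list with `spectrum` (tibble) and `truth` (tibble with
#'   `charge`, `height`, `mass`, `monoisotopic_mz`, `anchor_mz`).
#' @examples
#' sim <- simulate_spectrum(
#'   data.frame(mass = 1200, charge = 2, height = 100),
#'   mz_range = c(598, 605), spacing = 0.02,
#'   shape = list(kind = "gaussian", sigma = 0.04)
#' )
#' @export
simulate_spectrum <- function(patterns, mz_range, spacing = 0.02,
                              shape = list(kind = "gaussian", sigma = 0.05),
                              noise = list(additive_sd = 0,
                                           multiplicative_sd = 0,
                                           baseline = 0),
                              seed = NULL, kappa = 1.00235,
                              snap_anchors = FALSE) {
  if (spacing <= 0) abort("`spacing` must be > 0.")
  stopifnot(is.data.frame(patterns), nrow(patterns) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (!"mass" %in% names(patterns)) {
    if (!"sequence" %in% names(patterns)) {
      abort("`patterns` needs a `mass` or `sequence` column.")
    }
    patterns$mass <- vapply(seq_len(nrow(patterns)), function(i) {
      c0 <- patterns$charge[i]
      c0 * peptide_monoisotopic_mz(patterns$sequence[i], c0) - c0 * PROTON_MASS
    }, numeric(1))
  }
  grid <- seq(mz_range[1L], mz_range[2L], by = spacing)
  y <- rep(0, length(grid))
  truth <- vector("list", nrow(patterns))
  for (i in seq_len(nrow(patterns))) {
    chg <- as.integer(patterns$charge[i])
    mass_i <- patterns$mass[i]
    kmax <- averagine_distribution(mass_i)$most_intense_index
    if (snap_anchors) {
      for (pass in 1:2) {
        anchor0 <- (mass_i + chg * PROTON_MASS + kmax * kappa) / chg
        anchor_snap <- grid[nearest_index(grid, anchor0)]
        mass_i <- chg * anchor_snap - chg * PROTON_MASS - kmax * kappa
        k2 <- averagine_distribution(mass_i)$most_intense_index
        if (k2 == kmax) break
        kmax <- k2
      }
    }
    mono_mz <- (mass_i + chg * PROTON_MASS) / chg
    anchor <- mono_mz + kmax * kappa / chg
    if (anchor < mz_range[1L] || anchor > mz_range[2L]) {
      abort(sprintf("Pattern %d (anchor %.4f) lies outside mz_range.", i, anchor))
    }
    par <- shape_params_at(shape, anchor)
    tpl <- build_template(chg, anchor, par$kind, par, kappa = kappa)
    y <- y + patterns$height[i] * eval_template(tpl, grid)
    truth[[i]] <- tibble(charge = chg, height = patterns$height[i],
                         mass = mass_i, monoisotopic_mz = mono_mz,
                         anchor_mz = anchor)
  }
  max_height <- max(patterns$height)
  y <- y + (noise$baseline %||% 0)
  if ((noise$additive_sd %||% 0) > 0) {
    y <- y + rnorm(length(y), 0, noise$additive_sd * max_height)
  }
  if ((noise$multiplicative_sd %||% 0) > 0) {
    y <- y * rlnorm(length(y), 0, noise$multiplicative_sd)
  }
  y <- pmax(y, 0)
  list(spectrum = tibble(mz = grid, intensity = y),
       truth = bind_rows(truth))
}

#' Evaluate a peaklist against simulated ground truth
#'
#' Greedy one-to-one matching: candidate (feature, truth) pairs of the same
#' charge within `delta_ppm` on the monoisotopic m/z are accepted in order
#' of increasing relative distance, each feature and truth at most once.
#' Recall is matched truths over all truths; precision is matched features
#' over the list size (defined as 0 for an empty list).
#'
#' @param peaklist A peaklist tibble with `monoisotopic_mz` and `charge`.
#' @param truth Truth tibble from [simulate_spectrum()].
#' @param delta_ppm Match tolerance in ppm (> 0).
#' @return A list of class `"eval_result"`: `recall`, `precision`,
#'   `matched` (logical per peaklist entry), `n_list`, `n_truth`,
#'   `matches` (tibble of accepted pairs).
#' @export
evaluate_peaklist <- function(peaklist, truth, delta_ppm = 100) {
  if (delta_ppm <= 0) abort("`delta_ppm` must be > 0.")
  n_list <- nrow(peaklist)
  n_truth <- nrow(truth)
  pairs <- list()
  if (n_list > 0L && n_truth > 0L) {
    for (i in seq_len(n_list)) {
      for (j in seq_len(n_truth)) {
        if (peaklist$charge[i] != truth$charge[j]) next
        ppm <- abs(peaklist$monoisotopic_mz[i] - truth$monoisotopic_mz[j]) /
          truth$monoisotopic_mz[j] * 1e6
        if (ppm <= delta_ppm) pairs[[length(pairs) + 1L]] <- c(i, j, ppm)
      }
    }
  }
  matched <- logical(n_list)
  used_truth <- logical(n_truth)
  accepted <- list()
  if (length(pairs) > 0L) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(pm[, 3L]), , drop = FALSE]
    for (k in seq_len(nrow(pm))) {
      i <- pm[k, 1L]; j <- pm[k, 2L]
      if (!matched[i] && !used_truth[j]) {
        matched[i] <- TRUE
        used_truth[j] <- TRUE
        accepted[[length(accepted) + 1L]] <-
          tibble(list_index = i, truth_index = j, ppm = pm[k, 3L])
      }
    }
  }
  tp <- sum(matched)
  structure(
    list(
      recall = if (n_truth > 0L) tp / n_truth else NA_real_,
      precision = if (n_list > 0L) tp / n_list else 0,
      matched = matched, n_list = n_list, n_truth = n_truth,
      matches = if (length(accepted)) bind_rows(accepted)
                else tibble(list_index = integer(), truth_index = integer(),
                            ppm = numeric())
    ),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> recall = %.3f, precision = %.3f (%d/%d truths, list size %d)\n",
              x$recall, x$precision, sum(x$matched), x$n_truth, x$n_list))
  invisible(x)
}
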