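#' Unit-height Gaussian peak
#'
#' Template peaks are max-normalized downstream, so the Gaussian is used in
#' unit-height form without the density prefactor.
#'
#' @param x Numeric vector of m/z values (Th).
#' @param center Peak center (Th).
#' @param sigma Gaussian width (Th, > 0).
#' @return Intensities in (0, 1], with maximum 1 at `x = center`.
#' @examples
#' eval_gaussian(c(499.95, 500, 500.05), 500, 0.05)
#' @export
eval_gaussian <- function(x, center, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    abort("`sigma` must be a single positive number.")
  }
  exp(-((x - center)^2) / (2 * sigma^2))
}

#' Exponentially modified Gaussian peak
#'
#' Evaluates the EMG density
#' \deqn{\psi(x) = \frac{1}{\alpha}\exp\!\Big(\frac{\sigma^2}{2\alpha^2} +
#'   \frac{\mu - (x - m)}{\alpha}\Big)\Big(1 - F\big(\tfrac{\sigma}{\alpha} +
#'   \tfrac{\mu - (x - m)}{\sigma}\big)\Big)}
#' with \eqn{F} the standard normal CDF: a Gaussian of width `sigma`
#' convolved with an exponential tail of scale `alpha`, shifted by `mu`.
#' Models tailed peaks as produced e.g. by MALDI-TOF instruments.  The naive
#' formula overflows for small `alpha`; internally the scaled complementary
#' error function is used, which is stable for `sigma/alpha` up to at least
#' 1e4.  As `alpha` goes to 0 the EMG converges to a Gaussian density with
#' mean `center + mu` and sd `sigma`.
#'
#' @param x Numeric vector of m/z values (Th).
#' @param center Characteristic peak location m (Th).
#' @param alpha Exponential tailing scale (Th, > 0).
#' @param sigma Gaussian width (Th, > 0).
#' @param mu Shift parameter (Th, any sign).
#' @return Non-negative intensities (a density in x; integrates to 1).
#' @examples
#' eval_emg(seq(499.5, 501, by = 0.01), 500, alpha = 0.05, sigma = 0.1, mu = 0)
#' @export
eval_emg <- function(x, center, alpha, sigma, mu = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    abort("`alpha` must be a single positive number.")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    abort("`sigma` must be a single positive number.")
  }
  u <- mu - (x - center)
  t <- sigma / alpha + u / sigma
  out <- numeric(length(x))
  # For t >= 0: 1 - F(t) = erfc(t/sqrt(2))/2 = erfcx(t/sqrt(2)) exp(-t^2/2)/2,
  # and the exponent collapses to -u^2/(2 sigma^2) -- no overflow possible.
  pos <- t >= 0
  if (any(pos)) {
    out[pos] <- 0.5 / alpha * erfcx_safe(t[pos] / sqrt(2)) *
      exp(-u[pos]^2 / (2 * sigma^2))
  }
  if (any(!pos)) {
    # t < 0 implies the plain exponent is itself negative; direct formula.
    a <- sigma^2 / (2 * alpha^2) + u[!pos] / alpha
    out[!pos] <- 1 / alpha * exp(a) * stats::pnorm(t[!pos], lower.tail = FALSE)
  }
  if (!all(is.finite(out))) {
    abort("EMG evaluation produced non-finite values; check alpha/sigma.")
  }
  out
}

# Scaled complementary error function, stable for any non-negative z:
# pracma::erfcx overflows internally above z ~ 27, where the asymptotic
# expansion 1/(z sqrt(pi)) (1 - 1/(2z^2) + 3/(4z^4) - ...) is already
# accurate to machine precision.
erfcx_safe <- function(z) {
  out <- numeric(length(z))
  small <- z < 25
  if (any(small)) out[small] <- pracma::erfcx(z[small])
  if (any(!small)) {
    zz <- z[!small]
    iz2 <- 1 / (2 * zz^2)
    out[!small] <- (1 - iz2 + 3 * iz2^2 - 15 * iz2^3) / (zz * sqrt(pi))
  }
  out
}

# Evaluate the configured single-peak function (raw, not max-normalized).
eval_peak <- function(x, center, kind, params) {
  if (kind == "gaussian") {
    eval_gaussian(x, center, params$sigma)
  } else {
    eval_emg(x, center, alpha = params$alpha, sigma = params$sigma,
             mu = params$mu %||% 0)
  }
}

# Multiply two isotope-abundance polynomials (index = nucleon shift).
poly_mult <- function(a, b, trim = 1e-12) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    if (a[i] > 0) out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  keep <- max(which(out > trim * max(out)))
  out[seq_len(keep)]
}

# a^n by binary exponentiation.
poly_power <- function(a, n, trim = 1e-12) {
  result <- 1
  base <- a
  while (n > 0) {
    if (n %% 2 == 1) result <- poly_mult(result, base, trim)
    base <- poly_mult(base, base, trim)
    n <- n %/% 2
  }
  if (length(result) == 1L && identical(result, 1)) result <- c(1)
  result
}

#' Averagine isotope distribution for a given monoisotopic mass
#'
#' Predicts relative isotopic-peak heights for a peptide of the given
#' monoisotopic mass using the averagine pseudo-residue (average elemental
#' composition C 4.9384, H 7.7583, N 1.3577, O 1.4773, S 0.0417 per
#' 111.1254 Da).  The composition is scaled to the target mass, element
#' counts are rounded to integers with hydrogen adjusted to best match the
#' mass, and elemental isotope distributions are convolved.
#'
#' @param mass Neutral monoisotopic mass (Da, > 0).
#' @param max_peaks Optional cap on the number of isotopic peaks returned.
#' @param trim_rel Trailing peaks below `trim_rel` times the maximum weight
#'   are dropped (leading ones are kept so indices stay nucleon shifts).
#' @return An object of class `"isotope_distribution"`: a list with
#'   `weights` (relative abundances, max = 1; index k + 1 is the peak k
#'   nucleon shifts above monoisotopic) and `most_intense_index` (the k of
#'   the largest weight).
#' @examples
#' averagine_distribution(1000)
#' @export
averagine_distribution <- function(mass, max_peaks = NULL, trim_rel = 0.01) {
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0) {
    abort("`mass` must be a single positive number (Da).")
  }
  counts <- averagine_composition(mass)
  dist <- c(1)
  for (el in names(counts)) {
    if (counts[[el]] > 0) {
      dist <- poly_mult(dist, poly_power(ELEMENT_ISOTOPES[[el]], counts[[el]]))
    }
  }
  dist <- dist / max(dist)
  keep <- max(which(dist >= trim_rel))
  dist <- dist[seq_len(keep)]
  if (!is.null(max_peaks)) dist <- dist[seq_len(min(length(dist), max_peaks))]
  structure(
    list(weights = dist, most_intense_index = which.max(dist) - 1L),
    class = "isotope_distribution"
  )
}

# Integer element counts of the averagine pseudo-peptide of a given mass.
averagine_composition <- function(mass) {
  scale <- mass / AVERAGINE_MASS
  counts <- round(AVERAGINE_COMPOSITION[c("C", "N", "O", "S")] * scale)
  heavy <- sum(counts * ELEMENT_MONO_MASS[c("C", "N", "O", "S")])
  counts <- c(counts, H = max(0, round((mass - heavy) / ELEMENT_MONO_MASS[["H"]])))
  counts
}

#' Build an isotope-pattern template
#'
#' A template is the sum of single-peak functions at isotope positions
#' \eqn{m_{k} = m_0 + \kappa k / c} (k relative to the most intense peak, so
#' `anchor_mz` is the location of the pattern's tallest peak, not the
#' monoisotopic one) weighted by averagine abundances, and max-normalized to
#' height 1 so fitted coefficients read as apex intensities.
#'
#' @param charge Charge state c (integer >= 1).
#' @param anchor_mz Location of the most intense isotopic peak (Th).
#' @param shape_kind `"gaussian"` or `"emg"`.
#' @param shape_params List with `sigma` (and `alpha`, `mu` for EMG), Th.
#' @param kappa Isotopic spacing constant (Da); typically in [1.002, 1.008].
#' @param trim_rel Relative-abundance cutoff for isotopic peaks.
#' @return An object of class `"isotope_template"`; evaluate it on a grid
#'   with [eval_template()].
#' @examples
#' tpl <- build_template(2, 351.2, "gaussian", list(sigma = 0.05))
#' eval_template(tpl, seq(350.5, 353, by = 0.01))
#' @export
build_template <- function(charge, anchor_mz, shape_kind = c("gaussian", "emg"),
                           shape_params, kappa = 1.00235, trim_rel = 0.01) {
  shape_kind <- match.arg(shape_kind)
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 || charge != round(charge)) {
    abort("`charge` must be an integer >= 1.")
  }
  if (anchor_mz <= 0) abort("`anchor_mz` must be positive.")
  neutral_mass <- charge * anchor_mz - charge * PROTON_MASS
  if (neutral_mass <= 0) abort("`anchor_mz` implies a non-positive neutral mass.")
  dist <- averagine_distribution(neutral_mass, trim_rel = trim_rel)
  k_rel <- seq_along(dist$weights) - 1L - dist$most_intense_index
  centers <- anchor_mz + kappa * k_rel / charge
  tpl <- structure(
    list(
      charge = as.integer(charge), anchor_mz = anchor_mz,
      peak_centers = centers, weights = dist$weights,
      most_intense_index = dist$most_intense_index,
      shape_kind = shape_kind, shape_params = shape_params,
      kappa = kappa, neutral_mass = neutral_mass, norm = 1
    ),
    class = "isotope_template"
  )
  tpl$norm <- template_max(tpl)
  tpl
}

# Maximum of the un-normalized template over a fine grid (spacing sigma/50).
template_max <- function(tpl) {
  sigma <- tpl$shape_params$sigma
  pad <- 5 * sigma + 8 * alpha_or_zero(tpl$shape_params)
  grid <- seq(min(tpl$peak_centers) - pad, max(tpl$peak_centers) + pad, by = sigma / 50)
  max(eval_template_raw(tpl, grid))
}

eval_template_raw <- function(tpl, x) {
  out <- numeric(length(x))
  for (k in seq_along(tpl$peak_centers)) {
    out <- out + tpl$weights[k] *
      eval_peak(x, tpl$peak_centers[k], tpl$shape_kind, tpl$shape_params)
  }
  out
}

#' Evaluate a template on an m/z grid
#'
#' @param tpl An `"isotope_template"` from [build_template()].
#' @param x Numeric vector of m/z values.
#' @return Template intensities, max-normalized to 1.
#' @export
eval_template <- function(tpl, x) {
  eval_template_raw(tpl, x) / tpl$norm
}

# m/z half-width outside which a template is numerically negligible.
template_pad <- function(shape_params) {
  6 * shape_params$sigma + 10 * alpha_or_zero(shape_params)
}

# EMG tailing scale, or 0 when absent/NA (Gaussian shape).
alpha_or_zero <- function(par) {
  a <- par$alpha
  if (is.null(a) || is.na(a)) 0 else a
}

#' Assemble the sparse template matrix
#'
#' Builds one max-normalized template column per placement, sampled at the
#' spectrum's m/z grid and stored sparsely (entries below `floor_rel` times
#' the column maximum at the support edges are dropped; supports stay
#' contiguous, so with anchors sorted along m/z the Gram matrix is banded).
#'
#' @param spectrum A spectrum data frame.
#' @param placements Data frame with columns `charge` and `anchor_mz`
#'   (e.g. from [select_placements()]); anchors must lie inside the
#'   spectrum's m/z range.
#' @param shape_model A shape-parameter model from [calibrate_peak_shape()] /
#'   [fit_param_trend()], or a fixed parameter list such as
#'   `list(kind = "gaussian", sigma = 0.05)`.
#' @param kappa Isotopic spacing constant (Da).
#' @param trim_rel Relative-abundance cutoff for isotopic peaks.
#' @param floor_rel Sparse-storage floor relative to each column's maximum.
#' @return A list of class `"template_matrix"`: `phi` (sparse n x p
#'   `Matrix`), `blocks` (tibble: column, charge, anchor_mz), plus the
#'   construction parameters.
#' @export
assemble_template_matrix <- function(spectrum, placements, shape_model,
                                     kappa = 1.00235, trim_rel = 0.01,
                                     floor_rel = 1e-8) {
  s <- as_spectrum(spectrum)
  if (!is.data.frame(placements) || nrow(placements) == 0L) {
    abort("`placements` must be a non-empty data frame (charge, anchor_mz).")
  }
  bad <- placements$anchor_mz < min(s$mz) | placements$anchor_mz > max(s$mz)
  if (any(bad)) {
    abort(paste0("Placement anchor outside spectrum range: ",
                 paste(format(placements$anchor_mz[bad]), collapse = ", ")))
  }
  placements <- placements |>
    mutate(charge = as.integer(.data$charge)) |>
    arrange(.data$charge, .data$anchor_mz)
  n <- nrow(s)
  ii <- list(); xx <- list(); jj <- list()
  templates <- vector("list", nrow(placements))
  for (j in seq_len(nrow(placements))) {
    par <- shape_params_at(shape_model, placements$anchor_mz[j])
    tpl <- build_template(placements$charge[j], placements$anchor_mz[j],
                          par$kind, par, kappa = kappa, trim_rel = trim_rel)
    pad <- template_pad(par)
    lo <- findInterval(min(tpl$peak_centers) - pad, s$mz) + 1L
    hi <- findInterval(max(tpl$peak_centers) + pad, s$mz)
    lo <- max(lo, 1L); hi <- min(hi, n)
    if (hi < lo) { templates[[j]] <- tpl; next }
    idx <- lo:hi
    vals <- eval_template(tpl, s$mz[idx])
    keep <- which(vals >= floor_rel * max(vals))
    if (length(keep) > 0L) {
      idx <- idx[min(keep):max(keep)]           # contiguous support
      vals <- vals[min(keep):max(keep)]
      ii[[j]] <- idx; jj[[j]] <- rep(j, length(idx)); xx[[j]] <- vals
    }
    templates[[j]] <- tpl
  }
  phi <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(n, nrow(placements))
  )
  structure(
    list(
      phi = phi,
      blocks = tibble(
        column = seq_len(nrow(placements)),
        charge = placements$charge,
        anchor_mz = placements$anchor_mz
      ),
      templates = templates,
      kappa = kappa, trim_rel = trim_rel, shape_model = shape_model,
      mz = s$mz
    ),
    class = "template_matrix"
  )
}

#' Protonated monoisotopic m/z of a peptide sequence
#'
#' Sums monoisotopic residue masses, adds water for the termini and one
#' proton per charge: \eqn{(M + c\,m_p)/c}.
#'
#' @param sequence Amino-acid string over the 20 standard one-letter codes.
#' @param charge Charge state (integer >= 1).
#' @param carbamidomethyl If `TRUE`, adds the fixed carbamidomethyl
#'   modification (+57.021464 Da) per cysteine.
#' @return The m/z value (Th).
#' @examples
#' peptide_monoisotopic_mz("GACLLPK", 2)
#' @export
peptide_monoisotopic_mz <- function(sequence, charge, carbamidomethyl = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    abort("`sequence` must be a non-empty string.")
  }
  if (charge < 1 || charge != round(charge)) abort("`charge` must be an integer >= 1.")
  residues <- strsplit(toupper(sequence), "")[[1L]]
  unknown <- setdiff(residues, names(RESIDUE_MASS))
  if (length(unknown) > 0L) {
    abort(paste0("Unknown residue letter(s): ", paste(unique(unknown), collapse = ", ")))
  }
  mass <- sum(RESIDUE_MASS[residues]) + WATER_MASS
  if (carbamidomethyl) mass <- mass + CARBAMIDOMETHYL_MASS * sum(residues == "C")
  (mass + charge * PROTON_MASS) / charge
}
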