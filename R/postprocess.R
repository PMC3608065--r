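#' Group adjacent fitted templates
#'
#' Interior-point fits spread the weight of one true pattern over templates
#' at adjacent sampling positions ("peak splitting").  Per charge state,
#' templates with positive coefficients are chained into groups: consecutive
#' sorted anchors join a group while their gap is at most `ppm_tol` parts
#' per million.  Coefficients are considered positive above
#' `1e-10 * max(beta)` (solver crossover makes true zeros exact, but the
#' guard is kept for user-supplied coefficient vectors).
#'
#' @param fit An `"nn_fit"` from the solvers module.
#' @param matrix The `"template_matrix"` the fit was computed on.
#' @param ppm_tol Adjacency tolerance in ppm (> 0).
#' @return A tibble with columns `charge`, `anchor_mz`, `beta`, `column`,
#'   `group`; one row per retained template.
#' @export
group_templates <- function(fit, matrix, ppm_tol = 100) {
  stopifnot(inherits(fit, "nn_fit"), inherits(matrix, "template_matrix"))
  if (ppm_tol <= 0) abort("`ppm_tol` must be > 0.")
  beta <- fit$beta
  if (length(beta) != nrow(matrix$blocks)) {
    abort("Fit and template matrix have different numbers of columns.")
  }
  pos <- which(beta > 1e-10 * max(beta, 0))
  if (length(pos) == 0L) {
    return(tibble(charge = integer(), anchor_mz = numeric(),
                  beta = numeric(), column = integer(), group = integer()))
  }
  df <- matrix$blocks[pos, ] |>
    mutate(beta = beta[pos]) |>
    arrange(.data$charge, .data$anchor_mz)
  gid <- 0L
  groups <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    new_group <- i == 1L ||
      df$charge[i] != df$charge[i - 1L] ||
      (df$anchor_mz[i] - df$anchor_mz[i - 1L]) >
        ppm_tol * df$anchor_mz[i - 1L] / 1e6
    if (new_group) gid <- gid + 1L
    groups[i] <- gid
  }
  df |>
    mutate(group = groups) |>
    select("charge", "anchor_mz", "beta", "column", "group")
}

#' Merge one template group into a single feature
#'
#' Finds the continuous location \eqn{\tilde m} and weight \eqn{\tilde\beta}
#' whose single most-intense peak best approximates, in squared error over a
#' fine grid, the coefficient-weighted sum of the group's most-intense
#' peaks: \deqn{\min_{m, b} \int \Big(\sum_j \hat\beta_j \psi_{m_j}(x) -
#' b\,\psi_m(x)\Big)^2 dx.}  Because the optimal weight for a fixed
#' location has a closed form, the search reduces to a 1-D profile
#' optimization over the location (grid pre-scan plus local refinement),
#' which resolves locations well below the sampling rate.  Singleton groups
#' are returned unchanged.
#'
#' @param group Tibble rows of one group from [group_templates()].
#' @param shape_model A `"shape_param_model"` or fixed parameter list;
#'   evaluated at the group's coefficient-weighted mean anchor.
#' @param data_spacing Median m/z spacing of the spectrum (used for the
#'   integration grid: spacing `min(sigma/20, data_spacing/4)` over the
#'   support extended by 5 sigma).
#' @return A one-row tibble: `charge`, `anchor_mz` (merged location),
#'   `beta` (merged weight), `n_members`, `merge_objective`.
#' @export
merge_group <- function(group, shape_model, data_spacing = NULL) {
  stopifnot(nrow(group) >= 1L)
  charge <- group$charge[1L]
  if (nrow(group) == 1L) {
    return(tibble(charge = charge, anchor_mz = group$anchor_mz,
                  beta = group$beta, n_members = 1L, merge_objective = 0))
  }
  m_ref <- sum(group$anchor_mz * group$beta) / sum(group$beta)
  par <- shape_params_at(shape_model, m_ref)
  sigma <- par$sigma
  hpk <- peak_height(par)
  psi <- function(x, m) eval_peak(x, m, par$kind, par) / hpk
  dg <- min(sigma / 20, (data_spacing %||% Inf) / 4)
  lo <- min(group$anchor_mz) - 5 * sigma - 8 * alpha_or_zero(par)
  hi <- max(group$anchor_mz) + 5 * sigma + 8 * alpha_or_zero(par)
  grid <- seq(lo, hi, by = dg)
  target <- numeric(length(grid))
  for (j in seq_len(nrow(group))) {
    target <- target + group$beta[j] * psi(grid, group$anchor_mz[j])
  }
  profile_obj <- function(m) {
    pm <- psi(grid, m)
    b <- sum(target * pm) / sum(pm^2)
    sum((target - b * pm)^2)
  }
  span <- range(group$anchor_mz)
  pad <- max(diff(span), sigma) / 2
  cand <- seq(span[1L] - pad, span[2L] + pad, length.out = 41L)
  vals <- vapply(cand, profile_obj, numeric(1))
  k <- which.min(vals)
  bracket <- c(cand[max(1L, k - 1L)], cand[min(length(cand), k + 1L)])
  opt <- tryCatch(
    optimize(profile_obj, lower = bracket[1L], upper = bracket[2L],
             tol = dg / 100),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    warn("Merge optimization failed; keeping the largest-coefficient member.")
    jmax <- which.max(group$beta)
    return(tibble(charge = charge, anchor_mz = group$anchor_mz[jmax],
                  beta = group$beta[jmax], n_members = nrow(group),
                  merge_objective = NA_real_))
  }
  m_opt <- opt$minimum
  pm <- psi(grid, m_opt)
  b_opt <- sum(target * pm) / sum(pm^2)
  tibble(charge = charge, anchor_mz = m_opt, beta = b_opt,
         n_members = nrow(group), merge_objective = opt$objective * dg)
}

#' Score merged features with a goodness-of-fit-adjusted signal-to-noise ratio
#'
#' \deqn{\mathrm{ratio} = \frac{GOF_+(\tilde m)\,\tilde\beta}
#' {LNL_+(\tilde m)},} with \eqn{GOF_+} and \eqn{LNL_+} looked up at the
#' datum nearest each merged location (both are step-like window
#' statistics).  Also converts the most-intense-peak location to the
#' monoisotopic position, \eqn{\tilde m - k_{\max}\kappa/c}, where
#' \eqn{k_{\max}} is the averagine most-intense isotope index for the
#' feature's neutral mass.
#'
#' @param features Tibble of merged features (from [merge_group()] rows).
#' @param noise A `"noise_model"` on the same spectrum.
#' @param gof A `"gof_map"` on the same spectrum.
#' @param kappa Isotopic spacing constant (Da).
#' @return A tibble with columns `anchor_mz`, `charge`, `beta`, `ratio`,
#'   `gof_plus`, `lnl_plus`, `monoisotopic_mz`, `neutral_mass`,
#'   `n_members`.
#' @export
score_features <- function(features, noise, gof, kappa = 1.00235) {
  if (nrow(features) == 0L) {
    return(tibble(anchor_mz = numeric(), charge = integer(), beta = numeric(),
                  ratio = numeric(), gof_plus = numeric(), lnl_plus = numeric(),
                  monoisotopic_mz = numeric(), neutral_mass = numeric(),
                  n_members = integer()))
  }
  idx <- nearest_index(noise$mz, features$anchor_mz)
  lnlp <- noise$lnl_plus[idx]
  gofp <- gof$gof_plus[nearest_index(gof$mz, features$anchor_mz)]
  kmax <- vapply(seq_len(nrow(features)), function(i) {
    m0 <- features$charge[i] * features$anchor_mz[i] -
      features$charge[i] * PROTON_MASS
    averagine_distribution(m0)$most_intense_index
  }, integer(1))
  mono <- features$anchor_mz - kmax * kappa / features$charge
  tibble(
    anchor_mz = features$anchor_mz,
    charge = as.integer(features$charge),
    beta = features$beta,
    ratio = ifelse(lnlp > 0, gofp * features$beta / lnlp,
                   ifelse(features$beta > 0, Inf, 0)),
    gof_plus = gofp,
    lnl_plus = lnlp,
    monoisotopic_mz = mono,
    neutral_mass = features$charge * mono - features$charge * PROTON_MASS,
    n_members = as.integer(features$n_members %||% 1L)
  )
}

#' Threshold scored features into a peaklist
#'
#' Retains features whose signal-to-noise ratio is at least `t`; no
#' re-fitting occurs, so varying `t` simply walks along the ranking induced
#' by a single fit.
#'
#' @param features Scored features from [score_features()].
#' @param t Significance threshold (>= 0); platform- and sample-specific,
#'   so always worth reviewing against the score distribution.
#' @return The retained features sorted by m/z, classed `"peaklist"`.
#' @export
apply_threshold <- function(features, t = 5) {
  if (t < 0) abort("`t` must be >= 0.")
  out <- features |>
    filter(.data$ratio >= t) |>
    arrange(.data$monoisotopic_mz)
  attr(out, "threshold") <- t
  class(out) <- unique(c("peaklist", class(out)))
  out
}

#' Filter features by proximity to the peptide mass cluster centers
#'
#' Peptide monoisotopic masses cluster around \eqn{1.000485\,m_n + 0.029}
#' for integer nominal masses \eqn{m_n}; features whose neutral mass
#' deviates by `tol_ppm` or more from the nearest center are removed as
#' likely non-peptidic (matrix clusters, chemical noise).
#'
#' @param peaklist A peaklist with a `neutral_mass` column.
#' @param tol_ppm Tolerance in ppm (default 200).
#' @return The filtered peaklist.
#' @export
peptide_mass_filter <- function(peaklist, tol_ppm = 200) {
  if (nrow(peaklist) == 0L || is.infinite(tol_ppm)) return(peaklist)
  dev <- vapply(peaklist$neutral_mass, function(m) {
    mn <- floor((m - 0.029) / 1.000485) + c(0, 1)
    min(abs(m - (1.000485 * mn + 0.029))) / m * 1e6
  }, numeric(1))
  out <- peaklist[dev < tol_ppm, , drop = FALSE]
  class(out) <- unique(c("peaklist", class(out)))
  out
}
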