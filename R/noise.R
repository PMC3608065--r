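#' Local noise level by sliding-window median
#'
#' \eqn{LNL(x) = \mathrm{median}\{y_i : x_i \in [x - h, x + h]\}}, evaluated
#' at every datum; windows are truncated at the spectrum boundaries.  The
#' median makes the estimate robust and equivariant under monotone intensity
#' transforms.  The truncated version \eqn{LNL_+} floors the LNL at one
#' quarter of the median of all LNL values so that signal-to-noise ratios do
#' not blow up in low-intensity regions.
#'
#' @param spectrum A spectrum data frame.
#' @param h Sliding half-width on the m/z axis (Th, > 0).
#' @return A tibble of class `"noise_model"` with columns `mz`, `lnl`,
#'   `lnl_plus` and attributes `h`, `global_floor`.
#' @examples
#' s <- data.frame(mz = 1:5, intensity = 1:5)
#' local_noise_level(s, h = 1)
#' @export
local_noise_level <- function(spectrum, h = 2.5) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    abort("`h` must be a single positive number (Th).")
  }
  s <- as_spectrum(spectrum)
  lims <- window_bounds(s$mz, h)
  # the lower-median order statistic (not the midpoint average on even
  # windows) keeps the estimate exactly equivariant under monotone
  # intensity transforms
  lnl <- vapply(seq_len(nrow(s)), function(i) {
    w <- s$intensity[lims$lo[i]:lims$hi[i]]
    sort(w)[floor((length(w) + 1) / 2)]
  }, numeric(1))
  global_floor <- median(lnl) / 4
  out <- tibble(mz = s$mz, lnl = lnl, lnl_plus = pmax(lnl, global_floor))
  attr(out, "h") <- h
  attr(out, "global_floor") <- global_floor
  class(out) <- c("noise_model", class(out))
  out
}

# First/last spectrum index inside [x_i - h, x_i + h] for every i.
window_bounds <- function(mz, h) {
  lo <- findInterval(mz - h, mz, left.open = TRUE) + 1L
  hi <- findInterval(mz + h, mz)
  list(lo = pmax(lo, 1L), hi = pmin(hi, length(mz)))
}

#' Pre-select template placement positions
#'
#' Emits one template placement per charge state at every datum whose
#' intensity exceeds `factor_place` times the local noise level: isotope
#' patterns are sparse, so restricting candidate anchors to data above the
#' local noise keeps the template dictionary tractable.
#'
#' @param spectrum A spectrum data frame.
#' @param noise A `"noise_model"` from [local_noise_level()] on the same
#'   spectrum.
#' @param factor_place Multiplier of the LNL a datum must exceed (> 0).
#' @param charges Integer vector of charge states to consider.
#' @return A tibble with columns `charge`, `anchor_mz`, ordered by m/z then
#'   charge; may be empty.
#' @export
select_placements <- function(spectrum, noise, factor_place = 1.5,
                              charges = 1:4) {
  if (factor_place <= 0) abort("`factor_place` must be > 0.")
  if (length(charges) == 0L) abort("`charges` must be non-empty.")
  s <- as_spectrum(spectrum)
  stopifnot(nrow(noise) == nrow(s))
  idx <- which(s$intensity > factor_place * noise$lnl & s$intensity > 0)
  tidyr::crossing(anchor_mz = s$mz[idx], charge = as.integer(sort(charges))) |>
    arrange(.data$anchor_mz, .data$charge) |>
    select("charge", "anchor_mz")
}

#' Windowed goodness-of-fit map from a single-peak fit
#'
#' Fits the spectrum with max-normalized single peaks placed at every datum
#' (same peak model, parameters and fit norm as the template fit), then
#' summarizes the residuals over the same sliding windows as the local noise
#' level: \deqn{GOF_+(x) = \min\Big(1 - \frac{\sum_{i \in I_x} |r_i|^q}
#' {\sum_{i \in I_x} |y_i|^q},\; 0.5\Big).}  Noise regions fit poorly by
#' smooth peaks and receive low values, down-weighting spurious features;
#' the cap at 0.5 limits the influence of the correction (empty or all-zero
#' windows also get the neutral value 0.5).
#'
#' @param spectrum A spectrum data frame.
#' @param shape_model A `"shape_param_model"` or fixed parameter list.
#' @param q Fit norm, 1 or 2.
#' @param h Sliding half-width (Th), usually shared with
#'   [local_noise_level()].
#' @param config A [solver_config()].
#' @param stride Place single peaks at every `stride`-th datum (>= 1) to
#'   bound cost on very long spectra.
#' @param cap Truncation value (default 0.5).
#' @param cap_mode `"min"` (as defined above) or `"max"` (lower bound
#'   instead; exposed because either reading of "limiting the influence" is
#'   defensible).
#' @return A tibble of class `"gof_map"` with columns `mz`, `residual`,
#'   `gof_plus`; attributes `q`, `h`.
#' @export
goodness_of_fit_map <- function(spectrum, shape_model, q = 2, h = 2.5,
                                config = solver_config(), stride = 1L,
                                cap = 0.5, cap_mode = c("min", "max")) {
  cap_mode <- match.arg(cap_mode)
  if (!q %in% c(1, 2)) abort("`q` must be 1 or 2.")
  s <- as_spectrum(spectrum)
  n <- nrow(s)
  centers_idx <- seq(1L, n, by = as.integer(stride))
  ii <- list(); jj <- list(); xx <- list()
  for (j in seq_along(centers_idx)) {
    cx <- s$mz[centers_idx[j]]
    par <- shape_params_at(shape_model, cx)
    pad <- template_pad(par)
    lo <- max(findInterval(cx - pad, s$mz) + 1L, 1L)
    hi <- min(findInterval(cx + pad, s$mz), n)
    if (hi < lo) next
    idx <- lo:hi
    vals <- eval_peak(s$mz[idx], cx, par$kind, par) / peak_height(par)
    keep <- which(vals >= 1e-8 * max(vals))
    if (length(keep) == 0L) next
    idx <- idx[min(keep):max(keep)]
    vals <- vals[min(keep):max(keep)]
    ii[[j]] <- idx; jj[[j]] <- rep(j, length(idx)); xx[[j]] <- vals
  }
  design <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                                 dims = c(n, length(centers_idx)))
  fit <- if (q == 2) nnls_logbarrier(design, s$intensity, config)
         else nnlad_logbarrier(design, s$intensity, config)
  r <- fit$residuals
  lims <- window_bounds(s$mz, h)
  cr <- cumsum(abs(r)^q)
  cy <- cumsum(abs(s$intensity)^q)
  wsum <- function(cs, lo, hi) cs[hi] - ifelse(lo > 1L, cs[lo - 1L], 0)
  num <- wsum(cr, lims$lo, lims$hi)
  den <- wsum(cy, lims$lo, lims$hi)
  raw <- ifelse(den > 0, 1 - num / den, cap)
  gof <- if (cap_mode == "min") pmin(raw, cap) else pmax(raw, cap)
  gof[den == 0] <- cap
  out <- tibble(mz = s$mz, residual = r, gof_plus = gof)
  attr(out, "q") <- q
  attr(out, "h") <- h
  class(out) <- c("gof_map", class(out))
  out
}

# Height of the configured single-peak function (1 for the unit Gaussian;
# numeric mode height for the EMG).
peak_height <- function(par) {
  if (par$kind == "gaussian") return(1)
  opt <- optimize(function(u) eval_emg(u, 0, par$alpha, par$sigma, par$mu %||% 0),
                  lower = -(6 * par$sigma + 2 * par$alpha),
                  upper = 6 * par$sigma + 2 * par$alpha, maximum = TRUE)
  opt$objective
}
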