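#' Tidy a non-negative fit
#'
#' One row per design column with its fitted coefficient; when the fit was
#' computed on a template matrix, the charge and anchor of each template are
#' included.
#'
#' @param x An `"nn_fit"`.
#' @param positive_only Keep only columns with positive coefficients.
#' @param ... Unused.
#' @return A tibble with columns `column`, (`charge`, `anchor_mz`,)
#'   `estimate`.
#' @method tidy nn_fit
#' @export
tidy.nn_fit <- function(x, positive_only = FALSE, ...) {
  out <- if (!is.null(x$blocks)) {
    x$blocks |> mutate(estimate = x$beta)
  } else {
    tibble(column = seq_along(x$beta), estimate = x$beta)
  }
  if (positive_only) out <- filter(out, .data$estimate > 0)
  out
}

#' Glance at a non-negative fit
#'
#' @param x An `"nn_fit"`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `q`, `objective`, `kkt_residual`,
#'   `stages`, `converged`, `n`, `p`, `n_positive`.
#' @method glance nn_fit
#' @export
glance.nn_fit <- function(x, ...) {
  tibble(
    method = x$method, q = x$q, objective = x$objective,
    kkt_residual = x$kkt_residual, stages = x$stages,
    converged = x$converged, n = length(x$fitted), p = length(x$beta),
    n_positive = sum(x$beta > 0)
  )
}

#' Glance at an evaluation result
#'
#' @param x An `"eval_result"` from [evaluate_peaklist()].
#' @param ... Unused.
#' @return A one-row tibble: `recall`, `precision`, `n_matched`, `n_truth`,
#'   `n_list`.
#' @method glance eval_result
#' @export
glance.eval_result <- function(x, ...) {
  tibble(recall = x$recall, precision = x$precision,
         n_matched = sum(x$matched), n_truth = x$n_truth, n_list = x$n_list)
}
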