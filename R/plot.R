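#' Plot a peaklist over its source spectrum
#'
#' Raw signal as a line, reported features as labelled markers at their
#' most-intense-peak locations, sized by intensity.
#'
#' @param object A `"peaklist"` from [pick_peaks()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot peaklist
#' @export
autoplot.peaklist <- function(object, ...) {
  s <- attr(object, "spectrum")
  p <- ggplot2::ggplot()
  if (!is.null(s)) {
    p <- p + ggplot2::geom_line(
      data = s, ggplot2::aes(x = .data$mz, y = .data$intensity),
      colour = "grey40", linewidth = 0.3
    )
  }
  if (nrow(object) > 0L) {
    p <- p +
      ggplot2::geom_point(
        data = as_tibble(object),
        ggplot2::aes(x = .data$anchor_mz, y = .data$beta,
                     colour = factor(.data$charge)),
        shape = 17, size = 2
      ) +
      ggplot2::labs(colour = "charge")
  }
  p + ggplot2::labs(x = "m/z (Th)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a local-noise model
#'
#' @param object A `"noise_model"` from [local_noise_level()].
#' @param spectrum Optional spectrum to underlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot noise_model
#' @export
autoplot.noise_model <- function(object, spectrum = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(spectrum)) {
    s <- as_spectrum(spectrum)
    p <- p + ggplot2::geom_line(
      data = s, ggplot2::aes(x = .data$mz, y = .data$intensity),
      colour = "grey70", linewidth = 0.3
    )
  }
  p +
    ggplot2::geom_line(
      data = as_tibble(object),
      ggplot2::aes(x = .data$mz, y = .data$lnl_plus),
      colour = "firebrick", linewidth = 0.5
    ) +
    ggplot2::labs(x = "m/z (Th)", y = "intensity",
                  subtitle = "truncated local noise level") +
    ggplot2::theme_minimal()
}

#' Plot fitted templates over the data
#'
#' @param object An `"nn_fit"` computed on a template matrix.
#' @param matrix The `"template_matrix"` used for the fit.
#' @param y The fitted intensity vector.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nn_fit
#' @export
autoplot.nn_fit <- function(object, matrix = NULL, y = NULL, ...) {
  df <- tibble(
    mz = if (!is.null(matrix)) matrix$mz else seq_along(object$fitted),
    observed = if (!is.null(y)) y else object$fitted + object$residuals,
    fitted = object$fitted
  ) |>
    tidyr::pivot_longer(c("observed", "fitted"),
                        names_to = "series", values_to = "intensity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$intensity,
                                   colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(observed = "grey40",
                                            fitted = "steelblue")) +
    ggplot2::labs(x = "m/z (Th)", y = "intensity", colour = NULL) +
    ggplot2::theme_minimal()
}
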