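# ggplot2 views of the package's result types.

spectra_long <- function(x) {
  tidyr::pivot_longer(
    as_tibble(x), -"wavelength_nm",
    names_to = "series", values_to = "value"
  )
}

#' Plot spectral objects
#'
#' SPDs, sub-light sets and camera sensitivities are drawn as intensity
#' curves over wavelength, one line per light / channel.
#'
#' @param object The spectral object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spd <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$wavelength_nm, y = .data$value)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength [nm]", y = "Relative power")
}

#' @rdname autoplot.spd
#' @export
autoplot.sublight_set <- function(object, ...) {
  ggplot2::ggplot(
    spectra_long(object),
    ggplot2::aes(x = .data$wavelength_nm, y = .data$value,
                 color = .data$series)
  ) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(x = "Wavelength [nm]", y = "Relative power")
}

#' @rdname autoplot.spd
#' @export
autoplot.camera_sensitivity <- function(object, ...) {
  ggplot2::ggplot(
    spectra_long(object),
    ggplot2::aes(x = .data$wavelength_nm, y = .data$value,
                 color = .data$series)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength [nm]", y = "Quantum efficiency",
                  color = "Channel")
}

#' Plot an illuminant approximation
#'
#' Overlays the target illuminant and its least-squares reconstruction
#' from the sub-lights.
#'
#' @param object An [approximate_illuminant()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.illuminant_approx <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(object$target), series = "target"),
    dplyr::mutate(as_tibble(object$reconstructed), series = "reconstruction")
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$wavelength_nm, y = .data$value,
                 linetype = .data$series)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength [nm]", y = "Relative power",
                  linetype = NULL)
}

#' Plot a Mahalanobis distance report
#'
#' Histogram of the squared distances of 'rest' samples from the
#' target-class distribution.
#'
#' @param object A [mahalanobis_report()].
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mahalanobis_report <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object$distances, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::labs(
      x = if (object$squared) "Squared Mahalanobis distance" else
        "Mahalanobis distance",
      y = "Count"
    )
}

#' Plot per-fold metrics of a cross-validation table
#'
#' @param cv A [cross_validate()] or [compare_lighting()] tibble.
#' @param metric Column(s) to draw (default all F1/accuracy columns).
#' @return A ggplot with one bar per fold and metric.
#' @export
plot_cv_metrics <- function(cv, metric = NULL) {
  if (is.null(metric)) {
    metric <- intersect(
      c("f1", "accuracy", "f1_optimized", "f1_fixed",
        "accuracy_optimized", "accuracy_fixed"),
      names(cv)
    )
  }
  df <- tidyr::pivot_longer(
    cv[c("fold", metric)], -"fold",
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = factor(.data$fold), y = .data$value,
                 fill = .data$metric)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Fold", y = "Score", fill = NULL) +
    ggplot2::ylim(0, 1)
}
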