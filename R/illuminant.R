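#' Least-squares illuminant approximation
#'
#' Finds the lighting weights whose accumulated SPD best approximates a
#' target illuminant in the least-squares sense, `x_approx = Q^+ t` with
#' `Q^+` the Moore--Penrose pseudo-inverse — the minimum-norm solution of
#' `min_x ||Q x - t||_2`. Used to express the D65 reference with the
#' available sub-lights, both as a fixed-illuminant baseline and as an
#' initialization of the lighting weights.
#'
#' @param sublights A [sublight_set()].
#' @param target An [spd()]; resampled onto the sub-light grid if needed
#'   (0 outside its measured band).
#' @return Object of class `"illuminant_approx"`: list with `x_approx`
#'   (weights), `reconstructed` (the [spd()] `Q x_approx`), `target` (the
#'   resampled target) and `residual_l2 = ||Q x_approx - t||_2`.
#' @examples
#' sl <- simulated_sublights()
#' approx <- approximate_illuminant(sl, cie_d65())
#' approx$residual_l2
#' @export
approximate_illuminant <- function(sublights, target) {
  if (!same_grid(sublights, target)) {
    target <- resample_spectra(target, spectra_wavelength(sublights))
  }
  Q <- spectra_matrix(sublights)
  t_vec <- spectra_matrix(target)[, 1]
  x <- drop(MASS::ginv(Q) %*% t_vec)
  recon <- drop(Q %*% x)
  structure(
    list(
      x_approx = x,
      reconstructed = spd(spectra_wavelength(sublights), recon),
      target = target,
      residual_l2 = l2(recon - t_vec)
    ),
    class = "illuminant_approx"
  )
}

#' @export
print.illuminant_approx <- function(x, ...) {
  cat(sprintf(
    "<illuminant_approx> %d sub-lights, residual L2 = %.4g\n",
    length(x$x_approx), x$residual_l2
  ))
  invisible(x)
}

#' @rdname approximate_illuminant
#' @param x An `"illuminant_approx"` object.
#' @param ... Unused.
#' @export
tidy.illuminant_approx <- function(x, ...) {
  tibble(
    sublight = seq_along(x$x_approx),
    weight = x$x_approx
  )
}

#' @rdname approximate_illuminant
#' @export
glance.illuminant_approx <- function(x, ...) {
  t_vec <- spectra_matrix(x$target)[, 1]
  tibble(
    n_sublights = length(x$x_approx),
    residual_l2 = x$residual_l2,
    relative_residual = x$residual_l2 / l2(t_vec)
  )
}
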