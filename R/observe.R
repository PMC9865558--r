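#' Observe a reflectance under an illuminant
#'
#' The per-channel camera response is `o_j = integral c_j(lambda) l(lambda)
#' r(lambda) dlambda`, computed as a rectangle-rule sum with `dlambda` equal
#' to the grid step. All inputs must share one wavelength grid.
#'
#' @param camera A [camera_sensitivity()].
#' @param reflectance Numeric vector of reflectances in `[0, 1]`, one per
#'   grid wavelength.
#' @param illuminant An [spd()].
#' @return Named numeric vector of channel responses.
#' @export
observe <- function(camera, reflectance, illuminant) {
  assert_same_grid(camera, illuminant)
  wl <- spectra_wavelength(camera)
  if (length(reflectance) != length(wl)) {
    abort("`reflectance` length must match the wavelength grid.")
  }
  C <- spectra_matrix(camera)
  l <- spectra_matrix(illuminant)[, 1]
  drop(crossprod(C, reflectance * l)) * grid_step(wl)
}

#' Per-pixel A-matrix
#'
#' For one pixel with reflectance diagonal `R`, `A = C^T R Q * dlambda`: the
#' `Nch x NL` matrix of channel responses under each individual sub-light.
#' The grid step is folded into `A`, so the rendered response under mixing
#' weights `x` is exactly `A %*% x` — identical to observing under the
#' accumulated SPD `Q x`.
#'
#' @param camera A [camera_sensitivity()].
#' @param reflectance Reflectance vector on the shared grid.
#' @param sublights A [sublight_set()].
#' @return `Nch x NL` numeric matrix (channels x sub-lights).
#' @export
build_A <- function(camera, reflectance, sublights) {
  assert_same_grid(camera, sublights)
  wl <- spectra_wavelength(camera)
  if (length(reflectance) != length(wl)) {
    abort("`reflectance` length must match the wavelength grid.")
  }
  C <- spectra_matrix(camera)
  Q <- spectra_matrix(sublights)
  crossprod(C, reflectance * Q) * grid_step(wl)
}

#' A-matrix cube of a reflectance scene
#'
#' Applies [build_A()] to every pixel of an `H x W x Nlambda` reflectance
#' cube, yielding the `H x W x Nch x NL` stack of per-pixel A-matrices —
#' the "photograph the scene once under each sub-light" representation from
#' which any illuminant mixture can be rendered without re-imaging.
#'
#' @param scene A [generate_scene()] result (or list with `cube` and
#'   `wavelength_nm`).
#' @param camera A [camera_sensitivity()].
#' @param sublights A [sublight_set()].
#' @return Object of class `"a_cube"`: list with `A` (`H x W x Nch x NL`
#'   array), `channel_names`, `peak_nm`, `mask` (copied from the scene if
#'   present).
#' @export
build_A_cube <- function(scene, camera, sublights) {
  assert_same_grid(camera, sublights)
  wl <- spectra_wavelength(camera)
  cube <- scene$cube
  stopifnot(length(dim(cube)) == 3)
  if (dim(cube)[3] != length(wl)) {
    abort("Scene cube and camera/sub-lights are on different grids.")
  }
  if (!is.null(scene$wavelength_nm) &&
      any(abs(scene$wavelength_nm - wl) > 1e-6)) {
    abort("Scene cube and camera/sub-lights are on different grids.")
  }
  h <- dim(cube)[1]; w <- dim(cube)[2]
  C <- spectra_matrix(camera)
  Q <- spectra_matrix(sublights)
  step <- grid_step(wl)
  M <- matrix(cube, h * w, length(wl)) # pixels x wavelengths
  A <- array(0, c(h, w, ncol(C), ncol(Q)))
  for (i in seq_len(ncol(Q))) {
    A[, , , i] <- array(M %*% (C * Q[, i]) * step, c(h, w, ncol(C)))
  }
  structure(
    list(
      A = A,
      channel_names = colnames(C),
      peak_nm = attr(sublights, "peak_nm"),
      mask = scene$mask
    ),
    class = "a_cube"
  )
}

#' Render under lighting weights
#'
#' Linearly mixes the sub-light responses by the lighting weights `x`. This
#' is the single rendering definition shared by the observation model and
#' the neural network's rendering layer: for an `Nch x NL` matrix it returns
#' `A %*% x`; for an [build_A_cube()] stack it returns the `H x W x Nch`
#' rendered image.
#'
#' @param A An `Nch x NL` matrix, an `"a_cube"`, or an `H x W x Nch x NL`
#'   array.
#' @param x Lighting weights (length `NL`).
#' @return Channel vector, or rendered image array.
#' @export
render <- function(A, x) {
  if (inherits(A, "a_cube")) A <- A$A
  x <- as.numeric(x)
  d <- dim(A)
  if (is.null(d) || length(d) == 2) {
    A <- as.matrix(A)
    if (ncol(A) != length(x)) abort("`x` length must equal ncol(A).")
    return(drop(A %*% x))
  }
  if (length(d) == 4) {
    if (d[4] != length(x)) abort("`x` length must equal the sub-light count.")
    return(array(matrix(A, prod(d[1:3]), d[4]) %*% x, d[1:3]))
  }
  abort("`A` must be a matrix or a 4-d A-cube array.")
}

# Batch rendering for patch datasets: A is N x D x NL, returns N x D.
render_batch <- function(A, x) {
  d <- dim(A)
  matrix(matrix(A, d[1] * d[2], d[3]) %*% as.numeric(x), d[1], d[2])
}
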