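#' Construct a uniform wavelength grid
#'
#' All spectral objects in the package live on a uniform wavelength grid in
#' nanometres. The two bands used throughout are 400--830 nm (visible, the
#' range of the measured LED set) and 400--1000 nm (visible plus
#' near-infrared, the range of the simulated sub-light set); spectra sampled
#' at other resolutions are brought onto a common grid with
#' [resample_spectra()].
#'
#' @param start,stop Band limits in nm, `start < stop`.
#' @param step Grid spacing in nm; `(stop - start)` must be an integer
#'   multiple of `step`.
#' @return A numeric vector of wavelengths `start, start + step, ..., stop`.
#' @examples
#' wavelength_grid(400, 830, 5)   # 87 wavelengths
#' @export
wavelength_grid <- function(start, stop, step) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (!(start < stop)) abort("`start` must be smaller than `stop`.")
  if (step <= 0) abort("`step` must be positive.")
  n_steps <- (stop - start) / step
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    abort(sprintf(
      "Range %g--%g nm is not divisible by step %g nm.", start, stop, step
    ))
  }
  seq(start, stop, by = step)
}

# Spacing of a uniform grid; errors if the spacing is not uniform.
grid_step <- function(wl) {
  if (length(wl) < 2) abort("A wavelength grid needs at least 2 points.")
  d <- diff(wl)
  if (any(d <= 0) || diff(range(d)) > 1e-6 * mean(d)) {
    abort("Wavelength grid must be strictly increasing and uniformly spaced.")
  }
  mean(d)
}

new_spectra <- function(df, class, ...) {
  out <- as_tibble(df)
  attrs <- list(...)
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  class(out) <- c(class, class(out))
  out
}

#' Spectral power distribution (SPD)
#'
#' An SPD is a tibble with columns `wavelength_nm` and `value` (relative
#' radiant power, unitless). Mixed or optimized SPDs may carry negative
#' values; they are then interpretable as a post-capture linear combination
#' of sub-light images rather than a physical lamp.
#'
#' @param wavelength_nm Uniform wavelength grid (nm).
#' @param value Relative power at each wavelength; finite.
#' @return A tibble of class `"spd"`.
#' @export
spd <- function(wavelength_nm, value) {
  stopifnot(length(wavelength_nm) == length(value))
  if (!all(is.finite(value))) abort("SPD values must be finite.")
  grid_step(wavelength_nm)
  new_spectra(
    tibble(wavelength_nm = as.numeric(wavelength_nm), value = as.numeric(value)),
    "spd"
  )
}

#' Set of sub-light SPDs
#'
#' The columns of `Q` are the SPDs of the `NL` elementary light sources
#' ("sub-lights") whose weighted mixture forms the working illuminant.
#'
#' @param wavelength_nm Uniform wavelength grid (nm).
#' @param Q Numeric matrix, one nonnegative column per sub-light.
#' @param peak_nm Nominal peak wavelengths, one per column.
#' @return A wide tibble of class `"sublight_set"`: `wavelength_nm` plus one
#'   column per sub-light (`light_01`, ...), with attribute `peak_nm`.
#' @export
sublight_set <- function(wavelength_nm, Q, peak_nm = NULL) {
  Q <- as.matrix(Q)
  stopifnot(nrow(Q) == length(wavelength_nm), ncol(Q) >= 1)
  if (any(Q < 0)) abort("Sub-light SPDs must be nonnegative.")
  grid_step(wavelength_nm)
  if (is.null(peak_nm)) peak_nm <- wavelength_nm[apply(Q, 2, which.max)]
  stopifnot(length(peak_nm) == ncol(Q))
  colnames(Q) <- sprintf("light_%02d", seq_len(ncol(Q)))
  new_spectra(
    cbind(tibble(wavelength_nm = as.numeric(wavelength_nm)), as_tibble(Q)),
    "sublight_set",
    peak_nm = as.numeric(peak_nm)
  )
}

#' Camera spectral sensitivity
#'
#' Per-channel spectral response (quantum efficiency, unitless) of the
#' observing camera.
#'
#' @param wavelength_nm Uniform wavelength grid (nm).
#' @param C Numeric matrix, one nonnegative column per channel.
#' @param channel_names Channel labels (default `R`, `G`, `B`, ...).
#' @return A wide tibble of class `"camera_sensitivity"`.
#' @export
camera_sensitivity <- function(wavelength_nm, C,
                               channel_names = NULL) {
  C <- as.matrix(C)
  stopifnot(nrow(C) == length(wavelength_nm), ncol(C) >= 1)
  if (any(C < 0)) abort("Camera sensitivities must be nonnegative.")
  grid_step(wavelength_nm)
  if (is.null(channel_names)) {
    channel_names <- if (ncol(C) <= 3) {
      c("R", "G", "B")[seq_len(ncol(C))]
    } else {
      sprintf("ch_%02d", seq_len(ncol(C)))
    }
  }
  stopifnot(length(channel_names) == ncol(C))
  colnames(C) <- channel_names
  new_spectra(
    cbind(tibble(wavelength_nm = as.numeric(wavelength_nm)), as_tibble(C)),
    "camera_sensitivity"
  )
}

#' @rdname spectra_matrix
#' @export
spectra_wavelength <- function(x) x[["wavelength_nm"]]

#' Extract the numeric content of a spectral table
#'
#' `spectra_matrix()` returns the value columns of an [spd()],
#' [sublight_set()] or [camera_sensitivity()] as a plain matrix
#' (wavelengths in rows); `spectra_wavelength()` returns the grid.
#'
#' @param x A spectral tibble.
#' @return A numeric matrix / vector.
#' @export
spectra_matrix <- function(x) {
  as.matrix(x[setdiff(names(x), "wavelength_nm")])
}

same_grid <- function(a, b) {
  wa <- spectra_wavelength(a)
  wb <- spectra_wavelength(b)
  length(wa) == length(wb) && all(abs(wa - wb) < 1e-6)
}

assert_same_grid <- function(...) {
  objs <- list(...)
  for (i in seq_along(objs)[-1]) {
    if (!same_grid(objs[[1]], objs[[i]])) {
      abort("Spectral inputs must share one wavelength grid; resample first.")
    }
  }
  invisible(TRUE)
}

#' Resample spectra onto a new wavelength grid
#'
#' Linear interpolation at the target wavelengths; values outside the source
#' range are set to 0 (SPDs and sensitivities vanish outside their measured
#' band; no extrapolation is attempted).
#'
#' @param x An [spd()], [sublight_set()] or [camera_sensitivity()].
#' @param grid Target wavelength grid (numeric vector from
#'   [wavelength_grid()]).
#' @return The same kind of object on `grid`.
#' @export
resample_spectra <- function(x, grid) {
  grid_step(grid)
  wl <- spectra_wavelength(x)
  if (max(grid) < min(wl) || min(grid) > max(wl)) {
    abort("Target grid does not overlap the source wavelength range.")
  }
  vals <- spectra_matrix(x)
  out <- apply(vals, 2, function(v) {
    approx(wl, v, xout = grid, method = "linear", yleft = 0, yright = 0)$y
  })
  out <- matrix(out, nrow = length(grid), dimnames = list(NULL, colnames(vals)))
  if (inherits(x, "spd")) {
    spd(grid, out[, 1])
  } else if (inherits(x, "sublight_set")) {
    sublight_set(grid, out, peak_nm = attr(x, "peak_nm"))
  } else if (inherits(x, "camera_sensitivity")) {
    camera_sensitivity(grid, out, channel_names = colnames(vals))
  } else {
    new_spectra(cbind(tibble(wavelength_nm = grid), as_tibble(out)), character())
  }
}

#' @rdname resample_spectra
#' @export
resample_spd <- resample_spectra

#' Gaussian sub-light set
#'
#' Builds simulated sub-light SPDs as unit-height Gaussians
#' `exp(-(lambda - mu)^2 / (2 sigma^2))` with `sigma = fwhm / (2 sqrt(2 ln 2))`.
#'
#' @param peaks Peak (mean) wavelengths in nm, one per sub-light.
#' @param fwhm Full width at half maximum in nm (shared by all sub-lights).
#' @param grid Wavelength grid.
#' @return A [sublight_set()].
#' @export
gaussian_sublights <- function(peaks, fwhm, grid) {
  if (fwhm <= 0) abort("`fwhm` must be positive.")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  Q <- vapply(
    peaks,
    function(mu) exp(-(grid - mu)^2 / (2 * sigma^2)),
    numeric(length(grid))
  )
  sublight_set(grid, Q, peak_nm = peaks)
}

#' The 24 simulated sub-lights (400--1000 nm band)
#'
#' Gaussian sub-lights with peaks at 412, 437, ..., 987 nm (25-nm spacing)
#' and a 40-nm FWHM, spanning the visible and near-infrared band so that the
#' mixture can cover the full range of the D65 reference.
#'
#' @param grid Wavelength grid (default 400--1000 nm at 5 nm).
#' @return A [sublight_set()] with 24 columns.
#' @export
simulated_sublights <- function(grid = wavelength_grid(400, 1000, 5)) {
  gaussian_sublights(peaks = seq(412, 987, by = 25), fwhm = 40, grid = grid)
}

#' Synthetic stand-in for the 24-LED sub-light set (400--830 nm band)
#'
#' Gaussian SPDs placed at the nominal peak wavelengths of a 24-LED visible
#' panel (405--780 nm). This is a synthetic stand-in with a common 25-nm
#' FWHM, not a set of measured LED spectra; measured SPDs can be supplied
#' via [read_sublights_csv()].
#'
#' @param grid Wavelength grid (default 400--830 nm at 5 nm).
#' @param fwhm FWHM of each synthetic LED line, nm.
#' @return A [sublight_set()] with 24 columns.
#' @export
led_sublights <- function(grid = wavelength_grid(400, 830, 5), fwhm = 25) {
  peaks <- c(
    405, 420, 435, 450, 470, 490, 505, 525, 535, 555, 565, 570,
    590, 600, 610, 625, 630, 645, 660, 670, 680, 690, 700, 780
  )
  gaussian_sublights(peaks = peaks, fwhm = fwhm, grid = grid)
}

#' Synthetic RGB camera sensitivity
#'
#' A three-channel Gaussian quantum-efficiency model (blue ~460 nm, green
#' ~540 nm, red ~600 nm) standing in for a CMOS RGB sensor. With
#' `nir_tail = TRUE` all three channels share an identical flat response
#' above ~820 nm, reproducing the indistinct near-infrared behaviour of
#' consumer CMOS sensors: beyond the tail onset the channels carry no
#' differential spectral information.
#'
#' @param grid Wavelength grid.
#' @param nir_tail Add the shared NIR tail (default `TRUE`; irrelevant for
#'   grids that stop at 830 nm).
#' @return A [camera_sensitivity()] with channels `R`, `G`, `B`.
#' @export
synthetic_rgb_camera <- function(grid = wavelength_grid(400, 830, 5),
                                 nir_tail = TRUE) {
  gauss <- function(mu, sigma, amp) amp * exp(-(grid - mu)^2 / (2 * sigma^2))
  C <- cbind(
    R = gauss(600, 45, 0.50),
    G = gauss(540, 40, 0.60),
    B = gauss(460, 32, 0.55)
  )
  if (nir_tail) {
    tail <- 0.12 / (1 + exp(-(grid - 840) / 25))
    C <- C + tail # identical in all channels: indistinct NIR
  }
  camera_sensitivity(grid, C)
}

#' CIE D65 reference illuminant
#'
#' The relative SPD of the CIE standard daylight illuminant D65 (normalized
#' to 100 at 560 nm), packaged at 5-nm resolution over 300--830 nm. The
#' table is the canonical 10-nm tabulation linearly interpolated to 5 nm.
#'
#' @param grid Optional target grid; if given the table is resampled with
#'   [resample_spectra()] (0 outside 300--830 nm).
#' @return An [spd()].
#' @export
cie_d65 <- function(grid = NULL) {
  path <- system.file("extdata", "cie_d65_5nm.csv", package = "lightspd")
  out <- read_spd_csv(path)
  if (!is.null(grid)) out <- resample_spectra(out, grid)
  out
}

#' Mix sub-lights into one SPD
#'
#' The working illuminant is the weighted sum `l(lambda) = sum_i x_i
#' q_i(lambda)` of the sub-light SPDs — the accumulated SPD `Q x`.
#'
#' @param sublights A [sublight_set()].
#' @param x Lighting weights, length equal to the number of sub-lights.
#' @return An [spd()] on the same grid (possibly negative if `x` is).
#' @export
accumulate_spd <- function(sublights, x) {
  Q <- spectra_matrix(sublights)
  if (length(x) != ncol(Q)) {
    abort(sprintf(
      "`x` has length %d but there are %d sub-lights.", length(x), ncol(Q)
    ))
  }
  spd(spectra_wavelength(sublights), drop(Q %*% as.numeric(x)))
}

#' Read / write spectral CSV files
#'
#' Single SPDs use a two-column CSV `wavelength_nm,value`; sub-light sets
#' and camera sensitivities use one wide CSV with `wavelength_nm` followed
#' by one column per light / channel. Headers are required.
#'
#' @param path File path.
#' @param x Object to write.
#' @return The read object, or (invisibly) `path` for writers.
#' @name spectra_io
NULL

read_spectra_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- read.csv(path, check.names = FALSE)
  if (!"wavelength_nm" %in% names(df)) {
    abort(sprintf("%s: missing required `wavelength_nm` column.", path))
  }
  df
}

#' @rdname spectra_io
#' @export
read_spd_csv <- function(path) {
  df <- read_spectra_csv(path)
  if (ncol(df) != 2) abort("An SPD CSV must have exactly two columns.")
  spd(df$wavelength_nm, df[[setdiff(names(df), "wavelength_nm")]])
}

#' @rdname spectra_io
#' @export
read_sublights_csv <- function(path) {
  df <- read_spectra_csv(path)
  sublight_set(df$wavelength_nm, as.matrix(df[setdiff(names(df), "wavelength_nm")]))
}

#' @rdname spectra_io
#' @export
read_camera_csv <- function(path) {
  df <- read_spectra_csv(path)
  camera_sensitivity(
    df$wavelength_nm,
    as.matrix(df[setdiff(names(df), "wavelength_nm")]),
    channel_names = setdiff(names(df), "wavelength_nm")
  )
}

#' @rdname spectra_io
#' @export
write_spectra_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Numerically measure the full width at half maximum of an SPD
#'
#' Locates the two half-maximum crossings around the global peak by linear
#' interpolation between grid points and returns their wavelength
#' difference. For a Gaussian line this recovers `2 sqrt(2 ln 2) sigma`.
#'
#' @param x An [spd()], or a [sublight_set()] together with `light`.
#' @param light Column index of the sub-light to measure (for sets).
#' @return FWHM in nm.
#' @export
measure_fwhm <- function(x, light = 1) {
  wl <- spectra_wavelength(x)
  v <- spectra_matrix(x)[, light]
  ipk <- which.max(v)
  half <- v[ipk] / 2
  cross <- function(side) {
    idx <- if (side == "left") seq(ipk, 1) else seq(ipk, length(v))
    below <- which(v[idx] < half)
    if (!length(below)) {
      abort("SPD does not fall below half maximum on both sides of the peak.")
    }
    i2 <- idx[below[1]]         # first grid point below half-max
    i1 <- i2 + if (side == "left") 1L else -1L
    # linear interpolation of the crossing between i1 (above) and i2 (below)
    wl[i1] + (half - v[i1]) * (wl[i2] - wl[i1]) / (v[i2] - v[i1])
  }
  abs(cross("right") - cross("left"))
}
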