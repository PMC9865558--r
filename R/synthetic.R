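#' Class reflectance spectrum models
#'
#' Generates per-class reflectance models emulating the structure of oral
#' and dental spectral imagery: every class shares one smooth enamel-like
#' base curve, and each non-base class deviates from it by one (or more)
#' narrow Gaussian bump in its own wavelength band. Classes therefore
#' overlap under broadband illumination but are separable by spectral
#' weighting that concentrates on the discriminative band. The first class
#' (id 0, "enamel") is the unmodified base.
#'
#' @param n_classes Number of classes (>= 2; default 6: enamel + 5 lesions).
#' @param grid Wavelength grid.
#' @param seed Integer seed; the models are deterministic given it.
#' @param band_centers Optional bump centers in nm for classes `1..K-1`
#'   (default: evenly spread over the camera-sensitive 430--790 nm range,
#'   jittered).
#' @param band_fwhm Bump FWHM in nm (default 50, a narrow band relative to
#'   the camera channels).
#' @param band_amplitude Bump amplitude in reflectance units (default 0.15,
#'   alternating sign across classes).
#' @param noise_sd Per-pixel, per-band reflectance noise SD. The default
#'   0.08 emulates the substantial within-class variability of oral tissue
#'   reflectance and keeps the one-vs-rest task away from F1 saturation.
#' @return A tibble of class `"class_spectra"`, one row per class, with
#'   list-columns `spectrum` (mean reflectance on `grid`) and `bumps`;
#'   attribute `wavelength_nm` stores the grid.
#' @export
make_class_spectra <- function(n_classes = 6,
                               grid = wavelength_grid(400, 830, 5),
                               seed = 1,
                               band_centers = NULL,
                               band_fwhm = 50,
                               band_amplitude = 0.15,
                               noise_sd = 0.08) {
  if (n_classes < 2) abort("`n_classes` must be at least 2.")
  stopifnot(band_fwhm > 0, noise_sd >= 0)
  lesion_names <- c(
    "attrition_erosion", "calculus", "initial_caries", "microfracture", "root"
  )
  nm <- c("enamel", rep_len(c(lesion_names), n_classes - 1))
  if (n_classes > 6) nm <- c("enamel", sprintf("lesion_%02d", seq_len(n_classes - 1)))
  with_seed(seed, {
    # smooth enamel-like base: rising sigmoid plus gentle low-frequency ripple
    base <- 0.25 + 0.35 * stats::plogis((grid - 520) / 60) +
      0.03 * cos(2 * pi * (grid - min(grid)) / 400)
    if (is.null(band_centers)) {
      lo <- max(min(grid) + 30, 430)
      hi <- min(max(grid) - 40, 790)
      band_centers <- seq(lo, hi, length.out = n_classes - 1)
      if (n_classes > 2) band_centers <- band_centers + runif(n_classes - 1, -5, 5)
    }
    stopifnot(length(band_centers) == n_classes - 1)
    sig <- band_fwhm / (2 * sqrt(2 * log(2)))
    rows <- lapply(seq_len(n_classes) - 1L, function(k) {
      if (k == 0) {
        bumps <- tibble(
          center_nm = numeric(), fwhm_nm = numeric(), amplitude = numeric()
        )
        spec <- base
      } else {
        amp <- band_amplitude * if (k %% 2 == 0) -1 else 1
        bumps <- tibble(
          center_nm = band_centers[k], fwhm_nm = band_fwhm, amplitude = amp
        )
        spec <- base + amp * exp(-(grid - band_centers[k])^2 / (2 * sig^2))
      }
      tibble(
        class_id = k,
        name = nm[k + 1],
        noise_sd = noise_sd,
        spectrum = list(pmin(pmax(spec, 0), 1)),
        bumps = list(bumps)
      )
    })
    out <- dplyr::bind_rows(rows)
  })
  attr(out, "wavelength_nm") <- grid
  class(out) <- c("class_spectra", class(out))
  out
}

#' Striped class layout
#'
#' Default scene layout: vertical stripes of equal width, cycling through
#' the class ids.
#'
#' @param h,w Scene size in pixels.
#' @param n_classes Number of classes.
#' @return `h x w` integer matrix of class ids `0..n_classes-1`.
#' @export
stripe_layout <- function(h, w, n_classes) {
  matrix(
    rep(as.integer(floor((seq_len(w) - 1) * n_classes / w)), each = h),
    h, w
  )
}

#' Generate a labeled reflectance scene
#'
#' Builds an `H x W x Nlambda` reflectance cube: each pixel takes its
#' class's mean spectrum plus iid Gaussian noise, clipped to `[0, 1]`, with
#' the class mask mirroring the layout. Pixels labeled `-1` in the layout
#' are unlabeled background (their reflectance is the base-class spectrum).
#'
#' @param models A [make_class_spectra()] result.
#' @param h,w Scene size in pixels.
#' @param layout Optional `h x w` integer matrix of class ids (or -1);
#'   default [stripe_layout()].
#' @param seed Integer seed.
#' @return Object of class `"reflectance_cube"`: list with `cube`
#'   (`h x w x Nlambda` in `[0,1]`), `mask` (`h x w` integer), and
#'   `wavelength_nm`.
#' @export
generate_scene <- function(models, h, w, layout = NULL, seed = 1) {
  grid <- attr(models, "wavelength_nm")
  k <- nrow(models)
  if (is.null(layout)) layout <- stripe_layout(h, w, k)
  layout <- as.matrix(layout)
  storage.mode(layout) <- "integer"
  if (!all(dim(layout) == c(h, w))) {
    abort("`layout` dimensions must be h x w.")
  }
  if (!all(layout %in% c(-1, models$class_id))) {
    abort("`layout` contains class ids with no spectrum model.")
  }
  nl <- length(grid)
  spec_mat <- do.call(rbind, models$spectrum) # K x Nlambda
  sds <- models$noise_sd
  cube <- array(0, c(h, w, nl))
  with_seed(seed, {
    flat_class <- as.vector(layout)
    idx <- match(pmax(flat_class, 0), models$class_id)
    mean_px <- spec_mat[idx, , drop = FALSE] # (h*w) x Nlambda
    noise <- matrix(rnorm(h * w * nl), h * w, nl) * sds[idx]
    cube <- array(pmin(pmax(mean_px + noise, 0), 1), c(h, w, nl))
  })
  structure(
    list(cube = cube, mask = layout, wavelength_nm = grid),
    class = "reflectance_cube"
  )
}

#' Extract a labeled patch dataset from an A-cube
#'
#' Builds one sample per labeled pixel whose `p x p` window lies fully
#' inside the image (windows exiting the image are discarded; no padding).
#' The binary one-vs-rest label comes from the CENTRAL pixel of the patch:
#' `+1` if it belongs to `target_class`, `-1` otherwise. Patches may
#' overlap and may straddle class boundaries.
#'
#' @param a_cube A [build_A_cube()] result (carrying a mask) or an
#'   `H x W x Nch x NL` array plus `mask`.
#' @param mask Optional `H x W` integer label matrix (sentinel -1 =
#'   unlabeled) overriding the one stored in `a_cube`.
#' @param patch_size Odd patch edge length (1 or 5 in practice).
#' @param target_class Class id treated as the positive ("one") class.
#' @return Object of class `"patch_dataset"`: list with
#'   `A` (`N x D x NL` array, `D = p*p*Nch`, feature layout `(row, col,
#'   channel)` flattened column-major), `y` in `{-1, 1}`, `class_id` (the
#'   central-pixel class of each sample), `fold` (NA until
#'   [assign_folds()]), `patch_size`, `n_channels`, `target_class`,
#'   `peak_nm`.
#' @export
extract_patches <- function(a_cube, mask = NULL, patch_size = 1,
                            target_class = 0) {
  if (inherits(a_cube, "a_cube")) {
    if (is.null(mask)) mask <- a_cube$mask
    peak_nm <- a_cube$peak_nm
    A <- a_cube$A
  } else {
    A <- a_cube
    peak_nm <- NULL
  }
  stopifnot(length(dim(A)) == 4)
  if (is.null(mask)) abort("A label mask is required.")
  p <- as.integer(patch_size)
  if (p < 1 || p %% 2 == 0) abort("`patch_size` must be odd (e.g. 1 or 5).")
  d <- dim(A)
  h <- d[1]; w <- d[2]; nch <- d[3]; nl <- d[4]
  if (!all(dim(mask) == c(h, w))) abort("`mask` dimensions must match the cube.")
  half <- (p - 1L) %/% 2L
  centers <- which(mask >= 0, arr.ind = TRUE)
  ok <- centers[, 1] > half & centers[, 1] <= h - half &
    centers[, 2] > half & centers[, 2] <= w - half
  centers <- centers[ok, , drop = FALSE]
  n <- nrow(centers)
  if (n == 0) abort("No labeled pixel admits a full patch window.")
  D <- p * p * nch
  X <- array(0, c(n, D, nl))
  for (s in seq_len(n)) {
    ri <- (centers[s, 1] - half):(centers[s, 1] + half)
    ci <- (centers[s, 2] - half):(centers[s, 2] + half)
    X[s, , ] <- matrix(A[ri, ci, , , drop = FALSE], D, nl)
  }
  cls <- mask[centers]
  structure(
    list(
      A = X,
      y = ifelse(cls == target_class, 1, -1),
      class_id = as.integer(cls),
      fold = rep(NA_integer_, n),
      centers = centers,
      patch_size = p,
      n_channels = nch,
      target_class = as.integer(target_class),
      peak_nm = peak_nm
    ),
    class = "patch_dataset"
  )
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf(
    "<patch_dataset> %d samples (%d positive), patch %dx%d, %d channels x %d sub-lights\n",
    length(x$y), sum(x$y == 1), x$patch_size, x$patch_size,
    x$n_channels, dim(x$A)[3]
  ))
  invisible(x)
}

#' Stratified cross-validation folds
#'
#' Randomly partitions the samples into `k` folds, stratified by the binary
#' label so each fold's positive fraction stays within one sample of the
#' global fraction; deterministic given `seed`.
#'
#' @param dataset A [extract_patches()] dataset.
#' @param k Number of folds (>= 2; default 5).
#' @param seed Integer seed.
#' @return The dataset with its `fold` field filled with values `1..k`.
#' @export
assign_folds <- function(dataset, k = 5, seed = 1) {
  n <- length(dataset$y)
  if (k < 2) abort("`k` must be at least 2.")
  if (k > n) abort("More folds than samples.")
  fold <- integer(n)
  with_seed(seed, {
    cursor <- 0L
    for (lab in sort(unique(dataset$y))) {
      idx <- sample(which(dataset$y == lab))
      # continue one global 1..k cycle across strata: global and per-stratum
      # fold sizes both differ by at most 1
      fold[idx] <- ((cursor + seq_along(idx) - 1L) %% k) + 1L
      cursor <- cursor + length(idx)
    }
  })
  dataset$fold <- fold
  dataset
}

# Subset a patch dataset by sample index, keeping metadata.
subset_patches <- function(dataset, idx) {
  dataset$A <- dataset$A[idx, , , drop = FALSE]
  dataset$y <- dataset$y[idx]
  dataset$class_id <- dataset$class_id[idx]
  dataset$fold <- dataset$fold[idx]
  dataset$centers <- dataset$centers[idx, , drop = FALSE]
  dataset
}

# {0,1} one-hot view of the labels: column 1 = rest, column 2 = target.
one_hot <- function(y) {
  cbind(rest = as.numeric(y == -1), target = as.numeric(y == 1))
}
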