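# Shared fixtures: a small band-separable two-class task. Class 1 differs
# from the enamel-like base only inside a 50-nm band centered at 625 nm, so
# lighting weight mass on the sub-lights covering that band is the
# discriminative solution.

band_grid <- function() wavelength_grid(400, 830, 10)

band_sublights <- function() {
  gaussian_sublights(seq(420, 800, length.out = 12), fwhm = 50,
                     grid = band_grid())
}

band_camera <- function() synthetic_rgb_camera(band_grid())

band_scene <- function(h = 24, w = 24, noise_sd = NULL, seed = 4) {
  args <- list(
    n_classes = 2, grid = band_grid(), seed = 3,
    band_centers = 625, band_fwhm = 50, band_amplitude = 0.15
  )
  if (!is.null(noise_sd)) args$noise_sd <- noise_sd
  generate_scene(do.call(make_class_spectra, args), h, w, seed = seed)
}

# Sub-lights whose peak lies within one FWHM of the discriminative band
# center.
covering_lights <- function(sublights, center = 625, fwhm = 50) {
  which(abs(attr(sublights, "peak_nm") - center) <= fwhm)
}

band_dataset_env <- new.env()

# Memoised patch datasets of the band task (built once per test run).
# `noise_sd = NULL` uses the generator default; the "easy" variant is a
# nearly noiseless, linearly separable version of the same scene.
band_dataset <- function(patch_size = 1, noise_sd = NULL) {
  key <- paste0("p", patch_size, "n", noise_sd %||% "default")
  if (is.null(band_dataset_env[[key]])) {
    scene <- band_scene(noise_sd = noise_sd)
    ac <- build_A_cube(scene, band_camera(), band_sublights())
    ds <- extract_patches(ac, patch_size = patch_size, target_class = 1)
    band_dataset_env[[key]] <- assign_folds(ds, k = 5, seed = 5)
  }
  band_dataset_env[[key]]
}

easy_dataset <- function(patch_size = 1) {
  band_dataset(patch_size, noise_sd = 0.005)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Balanced thinning: every k-th sample across the whole index range (the
# sample order follows the scene's stripe layout, so prefix subsets would
# be class biased).
thin <- function(ds, k) {
  lightspd:::subset_patches(ds, seq(1, length(ds$y), by = k))
}

# Central finite-difference gradient of the training loss in the lighting
# weights (oracle for the backpropagated gradient).
fd_grad_x <- function(model, ds, idx, eps = 1e-5) {
  vapply(seq_along(model$x), function(i) {
    m1 <- model; m2 <- model
    m1$x[i] <- m1$x[i] + eps
    m2$x[i] <- m2$x[i] - eps
    (nn_gradients(m1, ds, idx)$loss - nn_gradients(m2, ds, idx)$loss) / (2 * eps)
  }, numeric(1))
}

# Independent brute-force observation: plain triple loop over wavelengths.
observe_brute <- function(camera, reflectance, illuminant) {
  wl <- spectra_wavelength(camera)
  C <- spectra_matrix(camera)
  l <- spectra_matrix(illuminant)[, 1]
  step <- wl[2] - wl[1]
  out <- numeric(ncol(C))
  for (j in seq_len(ncol(C))) {
    s <- 0
    for (k in seq_along(wl)) s <- s + C[k, j] * l[k] * reflectance[k]
    out[j] <- s * step
  }
  out
}

# Independent dual-QP oracle for the soft-margin linear SVM (kernlab::ipop):
# returns the primal weights and a KKT-derived bias.
svm_qp_oracle <- function(Z, y, cost = 1) {
  n <- nrow(Z)
  K <- tcrossprod(Z)
  H <- K * (y %o% y)
  fit <- kernlab::ipop(
    c = matrix(-1, n), H = H, A = matrix(y, 1), b = 0,
    l = matrix(0, n), u = matrix(cost, n), r = 0, sigf = 10, maxiter = 300
  )
  alpha <- kernlab::primal(fit)
  w <- drop(crossprod(Z, alpha * y))
  free <- which(alpha > 1e-6 * cost & alpha < cost * (1 - 1e-6))
  b <- mean(y[free] - Z[free, , drop = FALSE] %*% w)
  list(w = w, b = b, alpha = alpha)
}

# Random small patch-like dataset of raw A blocks (no spectra behind it).
random_qp_dataset <- function(n = 20, nch = 3, nl = 4, shift = 0.8) {
  A <- array(rnorm(n * nch * nl), c(n, nch, nl))
  y <- rep(c(-1, 1), length.out = n)
  A[y == 1, , ] <- A[y == 1, , ] + shift
  structure(
    list(A = A, y = y, fold = rep(NA_integer_, n), patch_size = 1L,
         n_channels = nch, target_class = 1L,
         class_id = as.integer(y == 1), centers = cbind(seq_len(n), 1L)),
    class = "patch_dataset"
  )
}
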