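test_that("wavelength grids have the right size and reject bad ranges", {
  expect_length(wavelength_grid(400, 830, 5), 87)
  expect_length(wavelength_grid(400, 1000, 1), 601)
  expect_error(wavelength_grid(400, 830, 7), "not divisible")
  expect_error(wavelength_grid(830, 400, 5), "smaller")
  expect_error(grid_step <- lightspd:::grid_step(c(400, 410, 425)), "uniform")
})

test_that("resampling interpolates linearly and zero-fills outside the band", {
  src <- wavelength_grid(400, 700, 10)
  fine <- wavelength_grid(400, 700, 5)
  expect_equal(resample_spd(spd(src, rep(1, length(src))), fine)$value,
               rep(1, length(fine)))
  ramp <- spd(src, seq(0, 30, length.out = length(src)))
  mid <- resample_spd(ramp, wavelength_grid(405, 695, 10))
  expect_equal(mid$value, approx(src, ramp$value, mid$wavelength_nm)$y)
  self <- resample_spd(ramp, src)
  expect_equal(self$value, ramp$value)
  wide <- resample_spd(ramp, wavelength_grid(300, 830, 10))
  expect_equal(wide$value[wide$wavelength_nm < 400], rep(0, 10))
  expect_equal(wide$value[wide$wavelength_nm > 700], rep(0, 13))
  expect_error(resample_spd(ramp, wavelength_grid(800, 900, 10)), "overlap")
})

test_that("gaussian sub-lights have the stated peaks, width and symmetry", {
  grid <- wavelength_grid(400, 1000, 1)
  sl <- simulated_sublights(grid)
  Q <- spectra_matrix(sl)
  expect_equal(ncol(Q), 24)
  expect_equal(grid[which.max(Q[, 1])], 412)
  expect_equal(attr(sl, "peak_nm"), seq(412, 987, by = 25))
  # closed-form sigma and the numeric half-max width agree
  sigma <- 40 / (2 * sqrt(2 * log(2)))
  expect_equal(sigma, 16.9865, tolerance = 1e-4)
  expect_equal(measure_fwhm(sl, light = 5), 40, tolerance = 1 / 40)
  # symmetry about a central peak on a symmetric grid
  g2 <- wavelength_grid(500, 700, 5)
  one <- spectra_matrix(gaussian_sublights(600, 40, g2))[, 1]
  expect_equal(one, rev(one))
  expect_error(gaussian_sublights(600, -1, g2), "positive")
})

test_that("accumulated SPD is the weighted sub-light sum", {
  sl <- band_sublights()
  Q <- spectra_matrix(sl)
  e3 <- replace(numeric(12), 3, 1)
  expect_equal(accumulate_spd(sl, e3)$value, unname(Q[, 3]))
  expect_equal(accumulate_spd(sl, numeric(12))$value, rep(0, nrow(Q)))
  expect_error(accumulate_spd(sl, numeric(5)), "length")
})

test_that("observation matches a brute-force rectangle-rule loop", {
  grid <- wavelength_grid(500, 560, 20)
  set.seed(1)
  cam <- camera_sensitivity(grid, matrix(runif(8), 4, 2))
  l <- spd(grid, runif(4))
  r <- runif(4)
  expect_equal(observe(cam, r, l), setNames(observe_brute(cam, r, l), c("R", "G")))
  # indicator channel picks out one summand
  ind <- camera_sensitivity(grid, matrix(c(0, 1, 0, 0), 4, 1))
  expect_equal(unname(observe(ind, rep(1, 4), l)), l$value[2] * 20)
  expect_equal(unname(observe(cam, rep(0, 4), l)), c(0, 0))
  expect_error(observe(cam, r, spd(wavelength_grid(400, 460, 20), runif(4))),
               "grid")
})

test_that("A-matrix rendering equals observation under the accumulated SPD", {
  grid <- wavelength_grid(600, 640, 20)
  set.seed(2)
  cam <- camera_sensitivity(grid, matrix(runif(6), 3, 2))
  sl <- sublight_set(grid, matrix(runif(9), 3, 3))
  r <- runif(3)
  A <- build_A(cam, r, sl)
  for (i in 1:3) {
    x <- replace(numeric(3), i, 1)
    expect_equal(drop(A %*% x),
                 observe(cam, r, accumulate_spd(sl, x)))
  }
  x <- rnorm(3)
  expect_equal(drop(A %*% x), observe(cam, r, accumulate_spd(sl, x)))
  expect_equal(unname(build_A(cam, rep(0, 3), sl)), matrix(0, 2, 3))
  # degenerate single-channel single-light case reduces to observe()
  cam1 <- camera_sensitivity(grid, matrix(runif(3), 3, 1))
  sl1 <- sublight_set(grid, matrix(runif(3), 3, 1))
  expect_equal(drop(build_A(cam1, r, sl1)),
               unname(observe(cam1, r, accumulate_spd(sl1, 1))))
})

test_that("rendering is linear in reflectance and lighting weights", {
  grid <- band_grid()
  cam <- band_camera()
  sl <- band_sublights()
  set.seed(3)
  r1 <- runif(length(grid)); r2 <- runif(length(grid))
  expect_equal(build_A(cam, 0.3 * r1 + 0.7 * r2, sl),
               0.3 * build_A(cam, r1, sl) + 0.7 * build_A(cam, r2, sl))
  A <- build_A(cam, r1, sl)
  x <- rnorm(12)
  expect_equal(render(A, 2.5 * x), 2.5 * render(A, x))
})

test_that("illuminant approximation is the least-squares minimizer", {
  sl <- band_sublights()
  Q <- spectra_matrix(sl)
  # target inside the column span is reproduced exactly
  set.seed(4)
  x_true <- rnorm(12)
  inside <- spd(band_grid(), drop(Q %*% x_true))
  ap <- approximate_illuminant(sl, inside)
  expect_lt(ap$residual_l2 / max(l2_norm <- sqrt(sum(inside$value^2)), 1), 1e-8)
  # D65 target: normal equations hold and no perturbation does better
  ap65 <- approximate_illuminant(sl, cie_d65())
  t_vec <- spectra_matrix(ap65$target)[, 1]
  grad <- crossprod(Q, drop(Q %*% ap65$x_approx) - t_vec)
  expect_lt(max(abs(grad)), 1e-8 * max(abs(crossprod(Q, t_vec))))
  for (i in 1:200) {
    x_pert <- ap65$x_approx + rnorm(12, sd = 0.05)
    expect_gte(sqrt(sum((drop(Q %*% x_pert) - t_vec)^2)), ap65$residual_l2)
  }
  expect_equal(ap65$reconstructed$value, drop(Q %*% ap65$x_approx))
})

test_that("approximation error concentrates where sub-lights have no coverage", {
  # sub-lights only below 700 nm; D65 lives on 400-830 nm
  grid <- wavelength_grid(400, 830, 5)
  sl_low <- gaussian_sublights(seq(410, 690, by = 20), fwhm = 40, grid = grid)
  ap <- approximate_illuminant(sl_low, cie_d65(grid))
  resid <- ap$reconstructed$value - spectra_matrix(ap$target)[, 1]
  above <- grid > 700
  expect_gt(sum(resid[above]^2), sum(resid[!above]^2))
})

test_that("packaged reference data load with the expected structure", {
  d65 <- cie_d65()
  expect_s3_class(d65, "spd")
  expect_equal(d65$value[d65$wavelength_nm == 560], 100)
  cam <- read_camera_csv(system.file("extdata", "camera_rgb_synthetic.csv",
                                     package = "lightspd"))
  expect_equal(setdiff(names(cam), "wavelength_nm"), c("R", "G", "B"))
  led <- read_sublights_csv(system.file(
    "extdata", "sublights_led24_synthetic.csv", package = "lightspd"
  ))
  expect_equal(ncol(spectra_matrix(led)), 24)
})
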