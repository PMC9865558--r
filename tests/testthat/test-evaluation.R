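test_that("binary metrics follow the confusion-count definitions", {
  expect_equal(binary_metrics(c(1, -1, 1), c(1, -1, 1))$f1, 1)
  expect_equal(binary_metrics(c(1, -1, 1), c(1, -1, 1))$accuracy, 1)
  # TP=2 FP=1 FN=1 TN=6 -> F1 = 2/3, accuracy = 0.8
  truth <- c(rep(1, 3), rep(-1, 7))
  pred <- c(1, 1, -1, 1, rep(-1, 6))
  m <- binary_metrics(truth, pred)
  expect_equal(unlist(m[c("tp", "fp", "fn", "tn")]),
               c(tp = 2, fp = 1, fn = 1, tn = 6))
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$accuracy, 0.8)
  # no positives anywhere -> F1 = 0 by convention
  expect_equal(binary_metrics(rep(-1, 4), rep(-1, 4))$f1, 0)
  expect_equal(binary_metrics(rep(-1, 4), rep(-1, 4))$accuracy, 1)
  expect_error(binary_metrics(numeric(), numeric()), "Empty")
  expect_error(binary_metrics(1, c(1, -1)), "mismatch")
})

test_that("metrics recomputed from stored confusion counts are consistent", {
  ds <- thin(band_dataset(1), 2)
  ds <- assign_folds(ds, 4, seed = 3)
  cv <- cross_validate(ds, "alt", n_trials = 2, seed = 1)
  expect_equal(nrow(cv), 4)
  expect_equal(sum(cv$n_test), length(ds$y)) # test sets partition the data
  expect_equal(cv$f1,
               ifelse(2 * cv$tp + cv$fp + cv$fn == 0, 0,
                      2 * cv$tp / (2 * cv$tp + cv$fp + cv$fn)))
  expect_equal(cv$accuracy, (cv$tp + cv$tn) / cv$n_test)
  expect_equal(lengths(cv$learned_x), rep(12L, 4))
  cv2 <- cross_validate(ds, "alt", n_trials = 2, seed = 1)
  expect_identical(cv$f1, cv2$f1)
  expect_identical(cv$learned_x, cv2$learned_x)
})

test_that("optimal-SPD reconstruction normalizes and flags negative lobes", {
  sl <- simulated_sublights()
  e7 <- replace(numeric(24), 7, 2)
  um <- reconstruct_optimal_spd(sl, e7, "unit_max")
  expect_equal(max(um$value), 1)
  q7 <- spectra_matrix(sl)[, 7]
  expect_equal(um$value, unname(q7 / max(q7)))
  ul <- reconstruct_optimal_spd(sl, rnorm(24), "unit_l2")
  expect_equal(sqrt(sum(ul$value^2)), 1)
  expect_error(reconstruct_optimal_spd(sl, numeric(24), "unit_max"), "zero")
  neg <- reconstruct_optimal_spd(sl, replace(numeric(24), 3, -1))
  expect_true(attr(neg, "has_negative"))
  # uniform weights over the simulated set give broadband 400-1000 coverage
  broad <- reconstruct_optimal_spd(sl, rep(1, 24), "unit_max")
  inside <- broad$value[broad$wavelength_nm >= 412 & broad$wavelength_nm <= 987]
  expect_gt(min(inside), 0.5)
})

test_that("Mahalanobis distances match closed forms and a dense-inverse oracle", {
  # target points whose sample covariance is exactly I and mean exactly 0
  Yc <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)) * sqrt(3 / 2)
  X <- rbind(Yc, c(3, 4), c(0, 0))
  labels <- c(rep(1, 4), -1, -1)
  rep_ <- mahalanobis_report(X, labels, ridge = 0)
  expect_equal(rep_$distances$distance, c(25, 0))
  expect_equal(sqrt(rep_$distances$distance),
               mahalanobis_report(X, labels, ridge = 0,
                                  squared = FALSE)$distances$distance)
  # random data: explicit inverse + quadratic-form loop oracle
  set.seed(51)
  Xr <- matrix(rnorm(60 * 3), 60, 3)
  lr <- rep(c(1, -1), c(40, 20))
  rr <- mahalanobis_report(Xr, lr, ridge = 0)
  Sinv <- solve(cov(Xr[lr == 1, ]))
  mu <- colMeans(Xr[lr == 1, ])
  oracle <- apply(Xr[lr == -1, ], 1, function(v) {
    drop(t(v - mu) %*% Sinv %*% (v - mu))
  })
  expect_equal(rr$distances$distance, unname(oracle), tolerance = 1e-8)
  # literal uncentered cross-product form
  ru <- mahalanobis_report(Xr, lr, ridge = 0, centered = FALSE)
  Su <- crossprod(Xr[lr == 1, ])
  ou <- apply(Xr[lr == -1, ], 1, function(v) {
    drop(t(v - mu) %*% solve(Su) %*% (v - mu))
  })
  expect_equal(ru$distances$distance, unname(ou), tolerance = 1e-8)
  # degenerate covariance demands a ridge
  Xd <- cbind(Xr[, 1], Xr[, 1], Xr[, 2])
  expect_error(mahalanobis_report(Xd, lr, ridge = 0), "singular|ridge")
  expect_s3_class(mahalanobis_report(Xd, lr), "mahalanobis_report")
})

test_that("Mahalanobis distance is affine invariant", {
  set.seed(52)
  X <- matrix(rnorm(80 * 4), 80, 4)
  labels <- rep(c(1, -1), each = 40)
  base <- mahalanobis_report(X, labels, ridge = 0)$distances$distance
  for (i in 1:5) {
    M <- matrix(rnorm(16), 4, 4) + diag(4)
    shift <- rnorm(4)
    Xt <- sweep(X %*% M, 2, shift, "+")
    tr <- mahalanobis_report(Xt, labels, ridge = 0)$distances$distance
    expect_equal(tr, base, tolerance = 1e-6)
  }
})

test_that("the 5x5 RGB feature space has 75 dimensions", {
  ds <- band_dataset(5)
  feats <- lightspd:::rendered_features(ds, rep(1, 12))
  expect_equal(ncol(feats), ds$patch_size^2 * ds$n_channels)
  expect_equal(ncol(feats), 75)
})

test_that("lighting comparison reports paired folds and a null control", {
  ds <- thin(band_dataset(1), 2)
  ds <- assign_folds(ds, 3, seed = 4)
  sl <- band_sublights()
  x_fix <- approximate_illuminant(sl, cie_d65())$x_approx
  # control: the same frozen lighting in both arms gives zero differences
  a <- cross_validate(ds, "alt", fixed_x = x_fix, seed = 2)
  b <- cross_validate(ds, "alt", fixed_x = x_fix, seed = 2)
  expect_identical(a$f1, b$f1)
  expect_identical(a$accuracy, b$accuracy)
  cmp <- compare_lighting(ds, sl, method = "alt", n_trials = 2, seed = 2)
  expect_equal(nrow(cmp), 3) # one row per fold
  expect_equal(cmp$f1_diff, cmp$f1_optimized - cmp$f1_fixed)
  expect_equal(cmp$f1_fixed, a$f1)
})

test_that("label-shuffled data scores near chance", {
  ds <- thin(band_dataset(1), 2)
  shuffled <- ds
  shuffled$y <- lightspd:::with_seed(77, sample(ds$y))
  shuffled <- assign_folds(shuffled, 4, seed = 5)
  cv <- cross_validate(shuffled, "alt", n_trials = 2, seed = 6)
  # positive prevalence is 0.5; F1 of any label-independent rule lies in a
  # band around 0.5 (0 is possible when the degenerate all-negative rule
  # wins) and accuracy cannot be much better than chance
  expect_lt(mean(cv$accuracy), 0.65)
  expect_lt(mean(cv$f1), 0.75)
})
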