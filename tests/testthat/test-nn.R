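test_that("the rendering layer shares the observation model's definition", {
  ds <- band_dataset(1)
  set.seed(41)
  x <- rnorm(12)
  R <- lightspd:::render_batch(ds$A, x)
  # per-sample agreement with the A-matrix product used everywhere else
  for (s in c(1, 17, 100)) {
    expect_equal(R[s, ], drop(matrix(ds$A[s, , ], 3, 12) %*% x))
  }
  # unit weight vector picks out one sub-light's image block
  e4 <- replace(numeric(12), 4, 1)
  expect_equal(lightspd:::render_batch(ds$A, e4), ds$A[, , 4])
})

test_that("lighting initialization schemes match their definitions", {
  sl <- band_sublights()
  expect_equal(init_lighting("uniform_ones", 12), rep(1, 12))
  expect_equal(init_lighting("d65_approx", 12, sl, cie_d65()),
               approximate_illuminant(sl, cie_d65())$x_approx)
  r1 <- init_lighting("random_pm1", 12, seed = 5)
  expect_identical(r1, init_lighting("random_pm1", 12, seed = 5))
  expect_true(all(r1 >= -1 & r1 <= 1))
  r2 <- init_lighting("random_01", 12, seed = 5)
  expect_true(all(r2 >= 0 & r2 <= 1))
  expect_error(init_lighting("d65_approx", 12), "sublights")
})

test_that("model architectures have the hand-computed parameter counts", {
  # FCL, 3 hidden layers of 10 units, Nch = 3, NL = 24:
  # x(24) + (3*10+10) + 2*(10*10+10) + (10*2+2)
  cfg <- nn_config("fcl", n_layers = 3, n_units = 10)
  mdl <- build_model(cfg, 1, 3, 24)
  expect_equal(n_params(mdl), 24 + 40 + 110 + 110 + 22)
  # CNN on 5x5 RGB, 10 filters 3x3 twice, then 1 FC layer and the output
  cfgc <- nn_config("cnn", n_layers = 3, n_units = 10, conv_filters = 10)
  mdlc <- build_model(cfgc, 5, 3, 24)
  expect_equal(
    n_params(mdlc),
    24 + (9 * 3 * 10 + 10) + (9 * 10 * 10 + 10) + (10 * 10 + 10) + (10 * 2 + 2)
  )
  expect_error(build_model(cfg, 5, 3, 24), "1x1")
  expect_error(build_model(cfgc, 1, 3, 24), "kernel")
  # zero weights and zero input give an indifferent softmax
  mdl0 <- mdl
  for (li in seq_along(mdl0$layers)) mdl0$layers[[li]]$W[] <- 0
  logits <- lightspd:::nn_forward_rendered(mdl0, matrix(0, 4, 3))$logits
  p <- exp(logits) / rowSums(exp(logits))
  expect_equal(unname(p), matrix(0.5, 4, 2))
})

test_that("the grid enumerates 18 architectures per model kind", {
  for (kind in c("fcl", "cnn")) {
    g <- hyperparameter_grid(kind)
    expect_length(g, 18)
    combos <- unique(t(sapply(g, function(cf) {
      c(cf$n_layers, cf$n_units, cf$activation)
    })))
    expect_equal(nrow(combos), 18)
  }
})

test_that("cross-entropy matches the direct softmax formula and is stable", {
  expect_equal(cross_entropy(c(0, 0), c(0, 1)), log(2))
  expect_lt(cross_entropy(c(-1000, 1000), c(0, 1)), 1e-10)
  expect_true(is.finite(cross_entropy(c(1000, -1000), c(0, 1))))
  set.seed(42)
  for (i in 1:20) {
    z <- rnorm(2, sd = 3)
    y <- sample(c(1, 0))
    direct <- -log(exp(z[y == 1]) / sum(exp(z))) # literal definition
    expect_equal(cross_entropy(z, y), direct)
  }
})

test_that("backpropagated gradients match central finite differences", {
  ds1 <- band_dataset(1)
  mdl <- build_model(nn_config("fcl", n_layers = 3, seed = 6), 1, 3, 12)
  g <- nn_gradients(mdl, ds1, 1:40)
  num <- fd_grad_x(mdl, ds1, 1:40)
  expect_lt(max(abs(num - g$dx)) / max(abs(num)), 1e-4)
  ds5 <- band_dataset(5)
  mdlc <- build_model(nn_config("cnn", n_layers = 3, seed = 6), 5, 3, 12)
  gc <- nn_gradients(mdlc, ds5, 1:30)
  numc <- fd_grad_x(mdlc, ds5, 1:30)
  expect_lt(max(abs(numc - gc$dx)) / max(abs(numc)), 1e-4)
  # spot-check classifier-weight gradients too
  for (li in c(1, length(mdlc$layers))) {
    for (j in 1:3) {
      eps <- 1e-5
      m1 <- mdlc; m2 <- mdlc
      m1$layers[[li]]$W[j] <- m1$layers[[li]]$W[j] + eps
      m2$layers[[li]]$W[j] <- m2$layers[[li]]$W[j] - eps
      num_w <- (nn_gradients(m1, ds5, 1:30)$loss -
                  nn_gradients(m2, ds5, 1:30)$loss) / (2 * eps)
      expect_equal(gc$dlayers[[li]]$W[j], num_w, tolerance = 1e-4)
    }
  }
})

test_that("explicit rendering and pre-rendered input give identical scores", {
  ds <- band_dataset(1)
  mdl <- build_model(nn_config("fcl", seed = 8), 1, 3, 12)
  via_A <- predict(mdl, ds, type = "prob")
  R <- lightspd:::render_batch(ds$A, mdl$x)
  via_R <- lightspd:::nn_forward_rendered(mdl, R)$logits
  p <- exp(via_R[, 2] - apply(via_R, 1, max)) /
    rowSums(exp(via_R - apply(via_R, 1, max)))
  expect_equal(via_A, p, tolerance = 1e-6)
})

test_that("training reduces the loss on a separable task, deterministically", {
  # near-noiseless separable scene; dropout off so the training loss can
  # actually approach zero on these 10-unit layers
  ds <- easy_dataset(1)
  cfg <- nn_config("fcl", n_layers = 3, n_units = 10, epochs = 120,
                   learning_rate = 1e-2, dropout_p = 0, seed = 9)
  mdl <- build_model(cfg, 1, 3, 12)
  tr1 <- train_nn(mdl, ds)
  expect_length(tr1$loss_history, 120)
  expect_lt(utils::tail(tr1$loss_history, 1), 0.1 * log(2))
  tr2 <- train_nn(build_model(cfg, 1, 3, 12), ds)
  expect_identical(tr1$x, tr2$x)
  expect_identical(tr1$loss_history, tr2$loss_history)
  # frozen lighting weights stay bit-identical through training
  frozen <- train_nn(build_model(cfg, 1, 3, 12), ds, epochs = 5,
                     freeze_x = TRUE)
  expect_identical(frozen$x, mdl$x)
  single <- lightspd:::subset_patches(ds, which(ds$y == 1))
  expect_error(train_nn(mdl, single), "both classes")
})

test_that("grid search scores every configuration and returns the argmax", {
  ds <- thin(band_dataset(1), 4)
  ds <- assign_folds(ds, k = 3, seed = 2)
  configs <- list(
    nn_config("fcl", n_layers = 3, n_units = 10, epochs = 25, seed = 3),
    nn_config("fcl", n_layers = 3, n_units = 10, activation = "none",
              epochs = 25, seed = 3)
  )
  gs <- grid_search(ds, configs)
  expect_equal(nrow(gs$table), 2)
  expect_equal(gs$table$mean_f1[gs$best_id], max(gs$table$mean_f1))
  expect_identical(gs$best_config, configs[[gs$best_id]])
  # singleton grid reduces to cross-validated training of that config
  gs1 <- grid_search(ds, configs[1])
  expect_equal(nrow(gs1$table), 1)
  expect_equal(gs1$table$mean_f1[1], gs$table$mean_f1[1])
})
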