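# Neural-network optimization of the light-source spectrum.
#
# The lighting weights x form the first, trainable "rendering" layer: each
# sample's A-matrix block is linearly combined into a single Nch-channel
# image (R = A x), which feeds an ordinary classifier — fully connected
# layers only (1x1 pixel input) or two valid 3x3 convolutions followed by
# fully connected layers (5x5 patch input). Because the rendered output is
# linear in x, the whole model is differentiable end-to-end and x is
# updated by backpropagation together with the classifier weights.

#' Neural-network configuration
#'
#' Hyperparameters of the rendering-layer classifier. The grid-searched
#' values are `n_layers` in `{3, 5, 7}`, `n_units` in `{10, 15, 20}` and
#' `activation` in `{"relu", "none"}`; the CNN uses 3x3 stride-1
#' convolutions with `conv_filters` filters (default 10) and dropout
#' probability 0.3 after each hidden fully connected layer. The optimizer
#' (Adam) settings are not grid-searched.
#'
#' @param model_kind `"fcl"` (1x1 pixel input) or `"cnn"` (patch input).
#' @param n_layers Total hidden-layer budget: for `"fcl"`, the number of
#'   hidden fully connected layers; for `"cnn"`, two convolution layers
#'   plus `n_layers - 2` hidden fully connected layers.
#' @param n_units Units per hidden fully connected layer.
#' @param activation `"relu"` or `"none"` (identity).
#' @param conv_filters,conv_kernel,conv_stride Convolution shape (CNN only).
#' @param dropout_p Dropout probability after each hidden FC layer, in
#'   `[0, 1)`.
#' @param init_scheme Initialization of the lighting weights: see
#'   [init_lighting()].
#' @param learning_rate,epochs,batch_size Adam optimizer settings.
#' @param seed Integer seed governing weight init, dropout and batching.
#' @return A list of class `"nn_config"`.
#' @export
nn_config <- function(model_kind = c("fcl", "cnn"),
                      n_layers = 3,
                      n_units = 10,
                      activation = c("relu", "none"),
                      conv_filters = 10,
                      conv_kernel = 3,
                      conv_stride = 1,
                      dropout_p = 0.3,
                      init_scheme = c("random_pm1", "random_01",
                                      "d65_approx", "uniform_ones"),
                      learning_rate = 1e-3,
                      epochs = 200,
                      batch_size = 64,
                      seed = 1) {
  model_kind <- match.arg(model_kind)
  activation <- match.arg(activation)
  init_scheme <- match.arg(init_scheme)
  if (dropout_p < 0 || dropout_p >= 1) abort("`dropout_p` must be in [0, 1).")
  if (conv_stride != 1) abort("Only stride-1 convolutions are supported.")
  if (model_kind == "cnn" && n_layers < 2) {
    abort("A CNN needs `n_layers` >= 2 (two of them are convolutions).")
  }
  structure(
    list(
      model_kind = model_kind, n_layers = n_layers, n_units = n_units,
      activation = activation, conv_filters = conv_filters,
      conv_kernel = conv_kernel, conv_stride = conv_stride,
      dropout_p = dropout_p, init_scheme = init_scheme,
      learning_rate = learning_rate, epochs = epochs,
      batch_size = batch_size, seed = seed
    ),
    class = "nn_config"
  )
}

#' Initial lighting weights
#'
#' The studied initialization schemes: `random_pm1` draws iid uniform on
#' `[-1, 1]` (the default scheme), `random_01` iid uniform on `[0, 1]`,
#' `d65_approx` the pseudo-inverse least-squares weights approximating the
#' reference illuminant ([approximate_illuminant()]), and `uniform_ones`
#' the all-ones vector.
#'
#' @param scheme Scheme name.
#' @param n_lights Number of sub-lights `NL`.
#' @param sublights,reference_spd Required for `d65_approx`.
#' @param seed Seed for the random schemes.
#' @return Numeric vector of length `n_lights`.
#' @export
init_lighting <- function(scheme = c("random_pm1", "random_01",
                                     "d65_approx", "uniform_ones"),
                          n_lights,
                          sublights = NULL,
                          reference_spd = NULL,
                          seed = 1) {
  scheme <- match.arg(scheme)
  switch(scheme,
    random_pm1 = with_seed(seed, runif(n_lights, -1, 1)),
    random_01 = with_seed(seed, runif(n_lights, 0, 1)),
    uniform_ones = rep(1, n_lights),
    d65_approx = {
      if (is.null(sublights) || is.null(reference_spd)) {
        abort("`d65_approx` initialization needs `sublights` and `reference_spd`.")
      }
      x <- approximate_illuminant(sublights, reference_spd)$x_approx
      if (length(x) != n_lights) abort("Sub-light count mismatch.")
      x
    }
  )
}

# Glorot-uniform weight matrix.
glorot <- function(fan_in, fan_out) {
  r <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -r, r), fan_in, fan_out)
}

# im2col gather index for a valid, stride-1 k x k convolution on a
# p x p x cin input flattened (row, col, channel) column-major.
# Returns an (s^2 x k^2*cin) matrix of input flat indices, s = p - k + 1.
im2col_index <- function(p, cin, k) {
  s <- p - k + 1
  op <- expand.grid(oi = seq_len(s), oj = seq_len(s)) # row fastest
  kk <- expand.grid(ki = 0:(k - 1), kj = 0:(k - 1), c = seq_len(cin))
  idx <- matrix(0L, s * s, k * k * cin)
  for (j in seq_len(nrow(kk))) {
    idx[, j] <- (op$oi + kk$ki[j]) +
      (op$oj + kk$kj[j] - 1L) * p +
      (kk$c[j] - 1L) * p * p
  }
  idx
}

#' Build an untrained rendering-layer model
#'
#' Assembles the trainable lighting weights plus classifier. The `"fcl"`
#' model (patch size 1) is: rendering layer, then `n_layers` hidden fully
#' connected layers of `n_units`, then a 2-unit output layer. The `"cnn"`
#' model (patch size >= 3) is: rendering layer, two valid 3x3 stride-1
#' convolution layers of `conv_filters` filters (a 5x5 patch collapses
#' 5 -> 3 -> 1 spatially), then `n_layers - 2` hidden fully connected
#' layers, then the 2-unit output. Class scores are softmax probabilities
#' of the 2-unit output; dropout follows each hidden FC layer during
#' training.
#'
#' @param config An [nn_config()].
#' @param patch_size Patch edge length (1 for `"fcl"`, >= 3 for `"cnn"`).
#' @param n_channels Camera channels `Nch`.
#' @param n_lights Sub-lights `NL`.
#' @param sublights,reference_spd Passed to [init_lighting()] when the
#'   init scheme is `d65_approx`.
#' @return Object of class `"nn_model"`.
#' @export
build_model <- function(config, patch_size, n_channels, n_lights,
                        sublights = NULL, reference_spd = NULL) {
  stopifnot(inherits(config, "nn_config"))
  p <- as.integer(patch_size)
  if (config$model_kind == "fcl" && p != 1) {
    abort("The FCL model takes 1x1 pixel input (`patch_size = 1`).")
  }
  if (config$model_kind == "cnn" && p < config$conv_kernel) {
    abort("The CNN model needs `patch_size` >= the convolution kernel.")
  }
  x <- init_lighting(
    config$init_scheme, n_lights,
    sublights = sublights, reference_spd = reference_spd,
    seed = config$seed
  )
  layers <- list()
  with_seed(config$seed + 1L, {
    if (config$model_kind == "cnn") {
      k <- config$conv_kernel
      f <- config$conv_filters
      s1 <- p - k + 1
      s2 <- s1 - k + 1
      if (s2 < 1) abort("Patch too small for two valid convolutions.")
      layers[[1]] <- list(
        type = "conv", W = glorot(k * k * n_channels, f), b = numeric(f),
        p = p, cin = n_channels, k = k,
        idx = im2col_index(p, n_channels, k), act = TRUE, dropout = FALSE
      )
      layers[[2]] <- list(
        type = "conv", W = glorot(k * k * f, f), b = numeric(f),
        p = s1, cin = f, k = k,
        idx = im2col_index(s1, f, k), act = TRUE, dropout = FALSE
      )
      in_dim <- s2 * s2 * f
      n_fc <- config$n_layers - 2L
    } else {
      in_dim <- n_channels
      n_fc <- config$n_layers
    }
    for (i in seq_len(n_fc)) {
      layers[[length(layers) + 1]] <- list(
        type = "fc", W = glorot(in_dim, config$n_units),
        b = numeric(config$n_units), act = TRUE, dropout = TRUE
      )
      in_dim <- config$n_units
    }
    layers[[length(layers) + 1]] <- list(
      type = "fc", W = glorot(in_dim, 2L), b = numeric(2L),
      act = FALSE, dropout = FALSE
    )
  })
  structure(
    list(
      x = x, layers = layers, config = config,
      patch_size = p, n_channels = n_channels, n_lights = n_lights,
      loss_history = numeric()
    ),
    class = "nn_model"
  )
}

#' Number of trainable parameters
#' @param model An `"nn_model"`.
#' @return Integer count, including the lighting weights.
#' @export
n_params <- function(model) {
  length(model$x) +
    sum(vapply(model$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

apply_act <- function(z, activation) {
  if (activation == "relu") pmax(z, 0) else z
}

# Forward pass from pre-rendered input (N x D). Returns logits and, when
# `keep = TRUE`, the caches needed for backprop. Dropout masks are drawn
# from the current RNG stream only when `training = TRUE`.
nn_forward_rendered <- function(model, R, training = FALSE, keep = FALSE) {
  cfg <- model$config
  cur <- R
  caches <- if (keep) vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$type == "conv") {
      n <- nrow(cur)
      s2 <- nrow(l$idx)
      K <- ncol(l$idx)
      xcol <- cur[, as.vector(l$idx), drop = FALSE]
      dim(xcol) <- c(n * s2, K)
      pre <- sweep(xcol %*% l$W, 2, l$b, "+")
      out <- if (l$act) apply_act(pre, cfg$activation) else pre
      f <- ncol(l$W)
      outflat <- out
      dim(outflat) <- c(n, s2 * f)
      if (keep) caches[[li]] <- list(xcol = xcol, pre = pre, n = n)
      cur <- outflat
    } else {
      pre <- sweep(cur %*% l$W, 2, l$b, "+")
      out <- if (l$act) apply_act(pre, cfg$activation) else pre
      mask <- NULL
      if (l$dropout && training && cfg$dropout_p > 0) {
        keep_p <- 1 - cfg$dropout_p
        mask <- matrix(
          stats::rbinom(length(out), 1, keep_p) / keep_p,
          nrow(out), ncol(out)
        )
        out <- out * mask
      }
      if (keep) caches[[li]] <- list(input = cur, pre = pre, mask = mask)
      cur <- out
    }
  }
  list(logits = cur, caches = caches)
}

# Backward pass: given d(loss)/d(logits), return gradients for every layer
# and for the rendered input.
nn_backward <- function(model, fw, dlogits) {
  cfg <- model$config
  grads <- vector("list", length(model$layers))
  dcur <- dlogits
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    cache <- fw$caches[[li]]
    if (l$type == "fc") {
      if (!is.null(cache$mask)) dcur <- dcur * cache$mask
      if (l$act && cfg$activation == "relu") dcur <- dcur * (cache$pre > 0)
      grads[[li]] <- list(
        W = crossprod(cache$input, dcur),
        b = colSums(dcur)
      )
      dcur <- tcrossprod(dcur, l$W)
    } else {
      n <- cache$n
      s2 <- nrow(l$idx)
      f <- ncol(l$W)
      dout <- dcur
      dim(dout) <- c(n * s2, f)
      if (l$act && cfg$activation == "relu") dout <- dout * (cache$pre > 0)
      grads[[li]] <- list(
        W = crossprod(cache$xcol, dout),
        b = colSums(dout)
      )
      dxcol <- tcrossprod(dout, l$W) # (n*s2) x K
      dflat <- matrix(0, n, l$p * l$p * l$cin)
      for (k in seq_len(ncol(l$idx))) {
        cols <- l$idx[, k]
        dflat[, cols] <- dflat[, cols] +
          matrix(dxcol[, k], n, s2)
      }
      dcur <- dflat
    }
  }
  list(layers = grads, d_rendered = dcur)
}

#' Softmax cross-entropy loss
#'
#' `cross_entropy()` evaluates the softmax negative log-likelihood of a
#' single 2-class score vector against a one-hot target, stabilized with
#' the log-sum-exp trick.
#'
#' @param scores Numeric logits (length C).
#' @param target One-hot vector of the same length.
#' @return Nonnegative loss scalar.
#' @examples
#' cross_entropy(c(0, 0), c(0, 1)) # log(2)
#' @export
cross_entropy <- function(scores, target) {
  stopifnot(length(scores) == length(target), sum(target) == 1,
            all(target %in% c(0, 1)))
  m <- max(scores)
  lse <- m + log(sum(exp(scores - m)))
  lse - sum(scores * target)
}

# Batch mean softmax cross-entropy with optional per-sample weights.
# Returns the loss and d(loss)/d(logits).
softmax_ce_batch <- function(logits, Y, sample_w = NULL) {
  n <- nrow(logits)
  if (is.null(sample_w)) sample_w <- rep(1, n)
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  p <- ex / rowSums(ex)
  li <- (m + log(rowSums(ex))) - rowSums(logits * Y)
  wsum <- sum(sample_w)
  list(
    loss = sum(sample_w * li) / wsum,
    dlogits = (p - Y) * (sample_w / wsum)
  )
}

# Loss and full gradient (x, all layers) on one batch of A-blocks.
nn_loss_grad <- function(model, Ab, Y, training = FALSE, sample_w = NULL) {
  R <- render_batch(Ab, model$x)
  fw <- nn_forward_rendered(model, R, training = training, keep = TRUE)
  ce <- softmax_ce_batch(fw$logits, Y, sample_w)
  bw <- nn_backward(model, fw, ce$dlogits)
  d <- dim(Ab)
  dx <- drop(crossprod(matrix(Ab, d[1] * d[2], d[3]), as.vector(bw$d_rendered)))
  list(loss = ce$loss, dx = dx, dlayers = bw$layers)
}

#' Evaluate the training loss and its gradients
#'
#' Computes the mean softmax cross-entropy of a batch and its exact
#' gradients with respect to the lighting weights and every classifier
#' parameter (no dropout). Exposed so the backpropagated gradients can be
#' verified against finite differences.
#'
#' @param model An [build_model()] model.
#' @param dataset A [extract_patches()] dataset.
#' @param idx Optional sample indices (default: all).
#' @return List with `loss`, `dx` (gradient in the lighting weights) and
#'   `dlayers` (per-layer `W`/`b` gradients).
#' @export
nn_gradients <- function(model, dataset, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(dataset$y)
  nn_loss_grad(
    model,
    dataset$A[idx, , , drop = FALSE],
    one_hot(dataset$y[idx]),
    training = FALSE
  )
}

adam_init <- function(par) list(m = par * 0, v = par * 0)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the rendering-layer model
#'
#' Minibatch Adam on the softmax cross-entropy, updating the classifier
#' weights and the lighting weights `x` jointly by backpropagation (or with
#' `x` frozen, for fixed-illuminant baselines). Deterministic given the
#' config seed.
#'
#' @param model An [build_model()] model.
#' @param dataset A [extract_patches()] dataset with both classes present.
#' @param epochs,learning_rate,batch_size Override the config values.
#' @param freeze_x Keep the lighting weights fixed at their initial value.
#' @param class_weights `NULL` (default, no imbalance handling) or
#'   `"balanced"` for inverse-frequency sample weights.
#' @return The trained `"nn_model"`, with `loss_history` (mean training
#'   loss per epoch) filled.
#' @export
train_nn <- function(model, dataset,
                     epochs = NULL, learning_rate = NULL, batch_size = NULL,
                     freeze_x = FALSE, class_weights = NULL) {
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  lr <- learning_rate %||% cfg$learning_rate
  bs <- batch_size %||% cfg$batch_size
  n <- length(dataset$y)
  if (length(unique(dataset$y)) < 2) {
    abort("Training data must contain both classes.")
  }
  Y <- one_hot(dataset$y)
  sw <- NULL
  if (identical(class_weights, "balanced")) {
    tab <- table(dataset$y)
    sw <- as.numeric(n / (2 * tab[as.character(dataset$y)]))
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  opt_x <- adam_init(model$x)
  opt_l <- lapply(model$layers, function(l) {
    list(W = adam_init(l$W), b = adam_init(l$b))
  })
  t_step <- 0
  loss_hist <- numeric(epochs)
  with_seed(cfg$seed + 2L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      ep_loss <- 0
      n_batch <- 0
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        g <- nn_loss_grad(
          model,
          dataset$A[idx, , , drop = FALSE],
          Y[idx, , drop = FALSE],
          training = TRUE,
          sample_w = sw[idx]
        )
        t_step <- t_step + 1
        corr <- sqrt(1 - b2^t_step) / (1 - b1^t_step)
        if (!freeze_x) {
          opt_x$m <- b1 * opt_x$m + (1 - b1) * g$dx
          opt_x$v <- b2 * opt_x$v + (1 - b2) * g$dx^2
          model$x <- model$x - lr * corr * opt_x$m / (sqrt(opt_x$v) + eps)
        }
        for (li in seq_along(model$layers)) {
          gl <- g$dlayers[[li]]
          opt_l[[li]]$W$m <- b1 * opt_l[[li]]$W$m + (1 - b1) * gl$W
          opt_l[[li]]$W$v <- b2 * opt_l[[li]]$W$v + (1 - b2) * gl$W^2
          model$layers[[li]]$W <- model$layers[[li]]$W -
            lr * corr * opt_l[[li]]$W$m / (sqrt(opt_l[[li]]$W$v) + eps)
          opt_l[[li]]$b$m <- b1 * opt_l[[li]]$b$m + (1 - b1) * gl$b
          opt_l[[li]]$b$v <- b2 * opt_l[[li]]$b$v + (1 - b2) * gl$b^2
          model$layers[[li]]$b <- model$layers[[li]]$b -
            lr * corr * opt_l[[li]]$b$m / (sqrt(opt_l[[li]]$b$v) + eps)
        }
        ep_loss <- ep_loss + g$loss
        n_batch <- n_batch + 1
      }
      loss_hist[ep] <- ep_loss / n_batch
    }
  })
  model$loss_history <- c(model$loss_history, loss_hist)
  model
}

#' Predict one-vs-rest labels from a trained model
#'
#' Renders each sample with the learned lighting weights, runs the
#' classifier (no dropout) and returns the softmax argmax, with the tie
#' resolved to class `+1`.
#'
#' @param object An `"nn_model"`.
#' @param dataset A [extract_patches()] dataset (or `N x D x NL` array).
#' @param type `"class"` for labels in `{-1, 1}` or `"prob"` for the
#'   positive-class softmax probability.
#' @param ... Unused.
#' @return Labels or probabilities.
#' @export
predict.nn_model <- function(object, dataset, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  A <- if (inherits(dataset, "patch_dataset")) dataset$A else dataset
  R <- render_batch(A, object$x)
  logits <- nn_forward_rendered(object, R, training = FALSE)$logits
  if (type == "prob") {
    m <- apply(logits, 1, max)
    ex <- exp(logits - m)
    return(ex[, 2] / rowSums(ex))
  }
  ifelse(logits[, 2] >= logits[, 1], 1L, -1L)
}

#' @export
print.nn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<nn_model> %s: %d layers x %d units (%s), %d params, %d sub-lights%s\n",
    cfg$model_kind, cfg$n_layers, cfg$n_units, cfg$activation,
    n_params(x), x$n_lights,
    if (length(x$loss_history)) {
      sprintf(", final loss %.4g", utils::tail(x$loss_history, 1))
    } else {
      " (untrained)"
    }
  ))
  invisible(x)
}

#' Tidiers for trained rendering-layer models
#'
#' `tidy()` returns the learned lighting weights (one row per sub-light);
#' `glance()` a one-row training summary.
#'
#' @param x An `"nn_model"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nn_model <- function(x, ...) {
  tibble(
    sublight = seq_along(x$x),
    weight = x$x
  )
}

#' @rdname tidy.nn_model
#' @export
glance.nn_model <- function(x, ...) {
  tibble(
    model_kind = x$config$model_kind,
    n_layers = x$config$n_layers,
    n_units = x$config$n_units,
    activation = x$config$activation,
    n_params = n_params(x),
    epochs_trained = length(x$loss_history),
    final_loss = if (length(x$loss_history)) utils::tail(x$loss_history, 1) else NA_real_
  )
}

#' The grid-searched hyperparameter set
#'
#' Enumerates the 18 architecture combinations per model kind: layers
#' `{3, 5, 7}` x units `{10, 15, 20}` x activation `{relu, none}`.
#'
#' @param model_kind `"fcl"` or `"cnn"`.
#' @param ... Overrides applied to every [nn_config()] (e.g. `epochs`,
#'   `seed`).
#' @return List of [nn_config()] objects.
#' @export
hyperparameter_grid <- function(model_kind = c("fcl", "cnn"), ...) {
  model_kind <- match.arg(model_kind)
  combos <- expand.grid(
    n_layers = c(3L, 5L, 7L),
    n_units = c(10L, 15L, 20L),
    activation = c("relu", "none"),
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(combos)), function(i) {
    nn_config(
      model_kind = model_kind,
      n_layers = combos$n_layers[i],
      n_units = combos$n_units[i],
      activation = combos$activation[i],
      ...
    )
  })
}

#' Grid search over architectures by cross-validated F1
#'
#' For each candidate configuration, runs k-fold cross-validation (folds
#' from [assign_folds()]), scores the held-out F1, and retrains the best
#' configuration (highest mean CV F1; ties keep the earliest) on the full
#' dataset.
#'
#' @param dataset A fold-assigned [extract_patches()] dataset.
#' @param configs List of [nn_config()] objects (e.g.
#'   [hyperparameter_grid()]).
#' @param sublights,reference_spd Passed to [build_model()].
#' @param ... Passed to [train_nn()] (e.g. `epochs`).
#' @return List of class `"grid_search"`: `best_model` (retrained),
#'   `best_config`, and `table` (one row per configuration with mean/sd CV
#'   F1).
#' @export
grid_search <- function(dataset, configs, sublights = NULL,
                        reference_spd = NULL, ...) {
  if (!length(configs)) abort("`configs` must be non-empty.")
  if (inherits(configs, "nn_config")) configs <- list(configs)
  folds <- sort(unique(dataset$fold))
  if (any(is.na(dataset$fold))) abort("Assign folds first (`assign_folds()`).")
  rows <- vector("list", length(configs))
  mean_f1 <- numeric(length(configs))
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    f1s <- vapply(folds, function(fo) {
      tr <- subset_patches(dataset, dataset$fold != fo)
      te <- subset_patches(dataset, dataset$fold == fo)
      mdl <- build_model(
        cfg, dataset$patch_size, dataset$n_channels, dim(dataset$A)[3],
        sublights = sublights, reference_spd = reference_spd
      )
      mdl <- train_nn(mdl, tr, ...)
      binary_metrics(te$y, predict(mdl, te))$f1
    }, numeric(1))
    mean_f1[ci] <- mean(f1s)
    rows[[ci]] <- tibble(
      config_id = ci,
      model_kind = cfg$model_kind,
      n_layers = cfg$n_layers,
      n_units = cfg$n_units,
      activation = cfg$activation,
      mean_f1 = mean(f1s),
      sd_f1 = sd(f1s)
    )
  }
  best <- which.max(mean_f1)
  best_model <- build_model(
    configs[[best]], dataset$patch_size, dataset$n_channels,
    dim(dataset$A)[3],
    sublights = sublights, reference_spd = reference_spd
  )
  best_model <- train_nn(best_model, dataset, ...)
  structure(
    list(
      best_model = best_model,
      best_config = configs[[best]],
      best_id = best,
      table = dplyr::bind_rows(rows)
    ),
    class = "grid_search"
  )
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf(
    "<grid_search> %d configurations; best: %d layers x %d units (%s), CV F1 = %.3f\n",
    nrow(x$table), x$best_config$n_layers, x$best_config$n_units,
    x$best_config$activation, x$table$mean_f1[x$best_id]
  ))
  invisible(x)
}
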