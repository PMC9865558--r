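#' Binary classification metrics
#'
#' F1 score and accuracy from confusion counts, with the positive class
#' `+1`: `F1 = 2 TP / (2 TP + FP + FN)` and `accuracy = (TP + TN) / N`.
#' When the F1 denominator is zero (no positives in either truth or
#' prediction) F1 is 0 by convention.
#'
#' @param truth,predicted Equal-length label vectors in `{-1, 1}` (or
#'   logical, `TRUE` = positive).
#' @return One-row tibble: `f1`, `accuracy`, `tp`, `fp`, `fn`, `tn`.
#' @export
binary_metrics <- function(truth, predicted) {
  if (!length(truth)) abort("Empty input.")
  if (length(truth) != length(predicted)) abort("Length mismatch.")
  tpos <- if (is.logical(truth)) truth else truth == 1
  ppos <- if (is.logical(predicted)) predicted else predicted == 1
  tp <- sum(tpos & ppos)
  fp <- sum(!tpos & ppos)
  fn <- sum(tpos & !ppos)
  tn <- sum(!tpos & !ppos)
  denom <- 2 * tp + fp + fn
  tibble(
    f1 = if (denom == 0) 0 else 2 * tp / denom,
    accuracy = (tp + tn) / length(truth),
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}

fit_and_score_fold <- function(dataset, fold_id, method,
                               sublights = NULL, reference_spd = NULL,
                               config = NULL,
                               n_trials = 10, seed = 1,
                               cost = 1, max_iter = 50, tol = 1e-4,
                               fixed_x = NULL, ...) {
  tr <- subset_patches(dataset, dataset$fold != fold_id)
  te <- subset_patches(dataset, dataset$fold == fold_id)
  nl <- dim(dataset$A)[3]
  if (method == "alt") {
    if (is.null(fixed_x)) {
      fit <- alt_restarts(tr, n_trials = n_trials, seed = seed + fold_id,
                          cost = cost, max_iter = max_iter, tol = tol)
      x_learned <- fit$x
    } else {
      wb <- fit_w_given_x(tr, fixed_x, cost = cost)
      fit <- structure(
        list(w = wb$w, b = wb$b, x = fixed_x, converged = TRUE,
             iterations = 1, cost = cost,
             history = tibble()),
        class = "alt_opt"
      )
      x_learned <- fixed_x
    }
    pred <- predict(fit, te)
  } else {
    cfg <- config %||% nn_config(
      model_kind = if (method == "cnn") "cnn" else "fcl"
    )
    cfg$seed <- cfg$seed + fold_id
    mdl <- build_model(
      cfg, dataset$patch_size, dataset$n_channels, nl,
      sublights = sublights, reference_spd = reference_spd
    )
    if (!is.null(fixed_x)) mdl$x <- fixed_x
    mdl <- train_nn(mdl, tr, freeze_x = !is.null(fixed_x), ...)
    x_learned <- mdl$x
    pred <- predict(mdl, te)
  }
  cbind(
    tibble(fold = fold_id),
    binary_metrics(te$y, pred),
    tibble(learned_x = list(x_learned), n_test = length(te$y))
  )
}

#' Cross-validated evaluation of a lighting optimizer
#'
#' Runs k-fold cross-validation (folds from [assign_folds()]): per fold,
#' the chosen optimizer is trained on the other folds and scored on the
#' held-out fold; the learned lighting weights are stored per fold (they
#' generally differ fold to fold — the optimization is not globally
#' stable).
#'
#' @param dataset A fold-assigned [extract_patches()] dataset.
#' @param method `"alt"` (alternating linear SVM, 1x1 input), `"fcl"` or
#'   `"cnn"`.
#' @param sublights,reference_spd Needed when the NN init scheme is
#'   `d65_approx` or when `fixed_x` baselines are derived.
#' @param config Optional [nn_config()] for the NN methods.
#' @param n_trials,seed,cost,max_iter,tol Alternating-optimizer settings
#'   ([alt_restarts()]).
#' @param fixed_x Optional lighting weights to freeze (fixed-illuminant
#'   baseline: classifier trained, lighting not).
#' @param ... Passed to [train_nn()].
#' @return A tibble with one row per fold: metrics, confusion counts and a
#'   `learned_x` list-column.
#' @export
cross_validate <- function(dataset, method = c("alt", "fcl", "cnn"),
                           sublights = NULL, reference_spd = NULL,
                           config = NULL, n_trials = 10, seed = 1,
                           cost = 1, max_iter = 50, tol = 1e-4,
                           fixed_x = NULL, ...) {
  method <- match.arg(method)
  if (any(is.na(dataset$fold))) abort("Assign folds first (`assign_folds()`).")
  folds <- sort(unique(dataset$fold))
  out <- lapply(folds, function(fo) {
    fit_and_score_fold(
      dataset, fo, method,
      sublights = sublights, reference_spd = reference_spd, config = config,
      n_trials = n_trials, seed = seed, cost = cost, max_iter = max_iter,
      tol = tol, fixed_x = fixed_x, ...
    )
  })
  dplyr::bind_rows(out)
}

#' Reconstruct the optimized SPD from learned lighting weights
#'
#' The optimized light source is the accumulated SPD `Q x`. Negative lobes
#' (possible because lighting weights are unconstrained) are preserved and
#' flagged via the `has_negative` attribute: such a "light" is a
#' post-capture linear combination, not a physical lamp.
#'
#' @param sublights A [sublight_set()].
#' @param x Learned lighting weights.
#' @param normalization `"none"`, `"unit_max"` (peak magnitude 1) or
#'   `"unit_l2"` (unit L2 norm).
#' @return An [spd()] with attribute `has_negative`.
#' @export
reconstruct_optimal_spd <- function(sublights, x,
                                    normalization = c("none", "unit_max",
                                                      "unit_l2")) {
  normalization <- match.arg(normalization)
  out <- accumulate_spd(sublights, x)
  v <- out$value
  if (normalization != "none") {
    scale <- switch(normalization,
      unit_max = max(abs(v)),
      unit_l2 = l2(v)
    )
    if (scale == 0) abort("Cannot normalize an identically zero SPD.")
    out$value <- v / scale
  }
  attr(out, "has_negative") <- any(out$value < 0)
  out
}

#' Mahalanobis interclass-distance report
#'
#' Measures how far the "rest" samples sit from the target-class
#' distribution in feature space: the squared Mahalanobis distance
#' `(x - mu_c)' Sigma_c^{-1} (x - mu_c)` of every non-target sample from
#' the target class's mean `mu_c` and covariance `Sigma_c`. Larger
#' distances mean the rendered features separate the classes more robustly
#' (e.g. against ambient-light noise). For 5x5 RGB patches the feature
#' space has `Nd = 75` dimensions.
#'
#' @param features `N x Nd` numeric matrix (rows = samples; e.g. flattened
#'   rendered patches).
#' @param labels Length-N labels in `{-1, 1}` (`+1` = target class).
#' @param target_class Label value treated as the target (default `1`).
#' @param ridge Ridge added to the covariance diagonal; default
#'   `1e-6 * trace(Sigma)/Nd`. Set `ridge = 0` to forbid regularization (a
#'   singular covariance is then an error).
#' @param centered Use the centered covariance with `1/(Nc - 1)` scaling
#'   (default); `FALSE` uses the raw uncentered, unscaled cross-product
#'   `Yc' Yc`.
#' @param squared Return squared distances (default); `FALSE` takes the
#'   square root.
#' @return Object of class `"mahalanobis_report"`: `mu_c`, `sigma_c` (as
#'   regularized), `distances` tibble (`sample`, `distance`), `nd`,
#'   `n_target`, `target_class`.
#' @export
mahalanobis_report <- function(features, labels, target_class = 1,
                               ridge = NULL, centered = TRUE,
                               squared = TRUE) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels)) abort("Length mismatch.")
  is_target <- labels == target_class
  if (sum(is_target) < 2) abort("Need at least 2 target-class samples.")
  Yc <- features[is_target, , drop = FALSE]
  nd <- ncol(features)
  if (centered) {
    mu <- colMeans(Yc)
    sigma <- cov(Yc)
  } else {
    mu <- colMeans(Yc)
    sigma <- crossprod(Yc) # literal uncentered, unscaled cross-product
  }
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(sigma)) / nd
  if (ridge < 0) abort("`ridge` must be nonnegative.")
  sigma_reg <- sigma + diag(ridge, nd)
  ev <- eigen(sigma_reg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    abort("Covariance is numerically singular; increase `ridge`.")
  }
  rest <- features[!is_target, , drop = FALSE]
  d2 <- mahalanobis(rest, mu, sigma_reg)
  structure(
    list(
      mu_c = mu,
      sigma_c = sigma_reg,
      distances = tibble(
        sample = which(!is_target),
        distance = if (squared) d2 else sqrt(d2)
      ),
      nd = nd,
      n_target = sum(is_target),
      target_class = target_class,
      squared = squared,
      ridge = ridge
    ),
    class = "mahalanobis_report"
  )
}

#' @export
print.mahalanobis_report <- function(x, ...) {
  cat(sprintf(
    "<mahalanobis_report> Nd = %d, %d target / %d rest samples, mean %sdistance = %.4g\n",
    x$nd, x$n_target, nrow(x$distances),
    if (x$squared) "squared " else "", mean(x$distances$distance)
  ))
  invisible(x)
}

#' @rdname mahalanobis_report
#' @param x A `"mahalanobis_report"`.
#' @param ... Unused.
#' @export
tidy.mahalanobis_report <- function(x, ...) x$distances

#' @rdname mahalanobis_report
#' @export
glance.mahalanobis_report <- function(x, ...) {
  tibble(
    nd = x$nd,
    n_target = x$n_target,
    n_rest = nrow(x$distances),
    mean_distance = mean(x$distances$distance),
    median_distance = stats::median(x$distances$distance),
    ridge = x$ridge
  )
}

#' Compare optimized lighting against a fixed reference illuminant
#'
#' Runs the same cross-validation twice: once with trainable/optimized
#' lighting weights and once with the weights frozen at the least-squares
#' approximation of `fixed_spd` (the D65 baseline), and reports the paired
#' per-fold differences.
#'
#' @param dataset A fold-assigned [extract_patches()] dataset.
#' @param sublights A [sublight_set()].
#' @param fixed_spd The reference illuminant [spd()] (default: packaged
#'   D65).
#' @param method `"alt"`, `"fcl"` or `"cnn"`.
#' @param ... Passed to [cross_validate()].
#' @return A tibble with one row per fold: `f1_optimized`, `f1_fixed`,
#'   `f1_diff`, the same for accuracy, and a `learned_x` list-column from
#'   the optimized arm.
#' @export
compare_lighting <- function(dataset, sublights, fixed_spd = cie_d65(),
                             method = c("alt", "fcl", "cnn"), ...) {
  method <- match.arg(method)
  x_fixed <- approximate_illuminant(sublights, fixed_spd)$x_approx
  opt <- cross_validate(
    dataset, method,
    sublights = sublights, reference_spd = fixed_spd, ...
  )
  fix <- cross_validate(
    dataset, method,
    sublights = sublights, reference_spd = fixed_spd, fixed_x = x_fixed, ...
  )
  tibble(
    fold = opt$fold,
    f1_optimized = opt$f1,
    f1_fixed = fix$f1,
    f1_diff = opt$f1 - fix$f1,
    accuracy_optimized = opt$accuracy,
    accuracy_fixed = fix$accuracy,
    accuracy_diff = opt$accuracy - fix$accuracy,
    learned_x = opt$learned_x
  )
}

#' Rendered feature matrix of a patch dataset
#'
#' Renders every sample of a patch dataset under the lighting weights `x`
#' and returns the flattened feature matrix (`N x p*p*Nch`) — the feature
#' space used for the Mahalanobis interclass analysis.
#'
#' @param dataset A [extract_patches()] dataset.
#' @param x Lighting weights.
#' @return Numeric matrix, one row per sample.
#' @export
rendered_features <- function(dataset, x) {
  render_batch(dataset$A, x)
}
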