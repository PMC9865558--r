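# Alternating linear-SVM optimization of lighting weights.
#
# The decision function is yhat = sign(w' A x + b): bilinear in the
# classifier weights w (per channel) and the lighting weights x (per
# sub-light). Each half is an ordinary soft-margin linear SVM:
#  * w-step: features o_i = A_i x   (channel responses under the mixture)
#  * x-step: features z_i = A_i' w  (per-sub-light responses through w)
# and the two are alternated to a fixed point.

# Soft-margin linear SVM returning primal (w, b) with the sign convention
# that positive decision values mean class +1.
linear_svm <- function(X, y, cost = 1, svm_tol = 1e-8) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) {
    abort("Both classes must be present to fit an SVM.")
  }
  yf <- factor(y, levels = c(-1, 1))
  m <- e1071::svm(
    X, yf,
    type = "C-classification", kernel = "linear",
    cost = cost, scale = FALSE, tolerance = svm_tol
  )
  w <- drop(crossprod(m$coefs, m$SV))
  b <- -m$rho
  # libsvm orients its decision value toward the first label it encounters;
  # flip if that label was -1 so that sign(w'z + b) = predicted class.
  dv <- attr(
    predict(m, X[1, , drop = FALSE], decision.values = TRUE),
    "decision.values"
  )
  if (!is.null(colnames(dv)) && startsWith(colnames(dv), "-1")) {
    w <- -w
    b <- -b
  }
  list(w = unname(w), b = unname(b))
}

# Per-sample hinge loss sum for decision values d and labels y.
hinge_sum <- function(d, y) sum(pmax(0, 1 - y * d))

# z_i = A_i' w for every sample: N x NL matrix.
project_w <- function(A, w) {
  d <- dim(A)
  Z <- matrix(0, d[1], d[3])
  for (l in seq_len(d[3])) Z[, l] <- matrix(A[, , l], d[1], d[2]) %*% w
  Z
}

#' Classifier step of the alternating optimization
#'
#' With the lighting weights `x` held fixed, fits the soft-margin linear
#' SVM on the rendered features `o_i = A_i x`, returning the classifier
#' weights `w` (one per rendered feature dimension) and bias `b`.
#'
#' @param dataset A [extract_patches()] dataset (its `A` array supplies the
#'   per-sample A-matrices, its `y` the one-vs-rest labels in `{-1, 1}`).
#' @param x Lighting weights, length `NL`.
#' @param cost Soft-margin penalty (shared by both subproblems).
#' @param svm_tol Termination tolerance of the SVM solver.
#' @return List with `w` and `b`.
#' @export
fit_w_given_x <- function(dataset, x, cost = 1, svm_tol = 1e-8) {
  O <- render_batch(dataset$A, x)
  linear_svm(O, dataset$y, cost = cost, svm_tol = svm_tol)
}

#' Lighting step of the alternating optimization
#'
#' With the classifier weights `w` held fixed, the margin problem in the
#' lighting weights is itself a linear SVM on the transformed features
#' `z_i = A_i' w`; its "classifier weights" are the new lighting weights
#' `x`, and the bias is refit.
#'
#' @inheritParams fit_w_given_x
#' @param w Classifier weights (nonzero).
#' @return List with `x` and `b`.
#' @export
fit_x_given_w <- function(dataset, w, cost = 1, svm_tol = 1e-8) {
  if (all(w == 0)) {
    abort("`w` must be nonzero: all transformed features would collapse to 0.")
  }
  Z <- project_w(dataset$A, w)
  fit <- linear_svm(Z, dataset$y, cost = cost, svm_tol = svm_tol)
  list(x = fit$w, b = fit$b)
}

#' Alternating optimization of lighting and classifier weights
#'
#' Repeats the [fit_w_given_x()] / [fit_x_given_w()] steps until the
#' relative change of both weight vectors falls below `tol` or `max_iter`
#' sweeps are reached.
#'
#' @inheritParams fit_w_given_x
#' @param x0 Initial lighting weights (length `NL`).
#' @param max_iter Maximum number of full sweeps.
#' @param tol Convergence tolerance on `max(|dx|/|x|, |dw|/|w|)`.
#' @return Object of class `"alt_opt"`: `w`, `b`, `x`, `converged`,
#'   `iterations`, `cost`, and a per-sweep `history` tibble with the
#'   soft-margin objectives of both subproblems
#'   (`0.5 ||.||^2 + cost * hinge`), the shared hinge loss, and step sizes.
#' @export
alternate <- function(dataset, x0, cost = 1, max_iter = 50, tol = 1e-4,
                      svm_tol = 1e-8) {
  d <- dim(dataset$A)
  if (length(x0) != d[3]) abort("`x0` length must equal the sub-light count.")
  x <- as.numeric(x0)
  w <- NULL
  hist <- vector("list", max_iter)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    w_fit <- fit_w_given_x(dataset, x, cost = cost, svm_tol = svm_tol)
    w_new <- w_fit$w
    x_fit <- fit_x_given_w(dataset, w_new, cost = cost, svm_tol = svm_tol)
    x_new <- x_fit$x
    b <- x_fit$b
    dec <- drop(render_batch(dataset$A, x_new) %*% w_new) + b
    hinge <- hinge_sum(dec, dataset$y)
    dx <- l2(x_new - x) / max(l2(x_new), .Machine$double.eps)
    dw <- if (is.null(w)) Inf else l2(w_new - w) / max(l2(w_new), .Machine$double.eps)
    hist[[it]] <- tibble(
      sweep = it,
      objective_w = 0.5 * sum(w_new^2) + cost * hinge,
      objective_x = 0.5 * sum(x_new^2) + cost * hinge,
      hinge = hinge,
      delta_x = dx,
      delta_w = dw
    )
    w <- w_new
    x <- x_new
    if (max(dx, dw) < tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(
      w = w, b = b, x = x,
      converged = converged, iterations = it, cost = cost,
      history = dplyr::bind_rows(hist[seq_len(it)])
    ),
    class = "alt_opt"
  )
}

#' Alternating optimization with random restarts
#'
#' Runs [alternate()] from `n_trials` random initial lighting weights drawn
#' iid uniform on `[-1, 1]`, and returns the trial with the best F1 score
#' (on `validation` if supplied, else on the training data). Ties keep the
#' earliest trial.
#'
#' @inheritParams alternate
#' @param n_trials Number of random restarts.
#' @param seed Integer seed (the whole procedure is deterministic given it).
#' @param validation Optional held-out [extract_patches()] dataset used for
#'   trial selection.
#' @return The best `"alt_opt"` state, with `trial_f1` (selection scores of
#'   all trials) and `trial` attached.
#' @export
alt_restarts <- function(dataset, n_trials = 10, seed = 1, validation = NULL,
                         cost = 1, max_iter = 50, tol = 1e-4, svm_tol = 1e-8) {
  if (n_trials < 1) abort("`n_trials` must be at least 1.")
  nl <- dim(dataset$A)[3]
  # one row per trial, filled trial-by-trial so trial t's init does not
  # depend on n_trials
  inits <- with_seed(
    seed,
    matrix(runif(n_trials * nl, -1, 1), n_trials, nl, byrow = TRUE)
  )
  score_on <- if (is.null(validation)) dataset else validation
  fits <- vector("list", n_trials)
  f1s <- numeric(n_trials)
  for (tr in seq_len(n_trials)) {
    fit <- alternate(dataset, inits[tr, ], cost = cost, max_iter = max_iter,
                     tol = tol, svm_tol = svm_tol)
    pred <- predict(fit, score_on)
    f1s[tr] <- binary_metrics(score_on$y, pred)$f1
    fits[[tr]] <- fit
  }
  best <- which.max(f1s)
  out <- fits[[best]]
  out$trial <- best
  out$trial_f1 <- f1s
  out
}

#' Predict one-vs-rest labels from a fitted alternating optimizer
#'
#' `yhat = sign(w' A x + b)`, with the tie at decision value 0 resolved to
#' class `+1`.
#'
#' @param object An `"alt_opt"` fit.
#' @param dataset A [extract_patches()] dataset (or `N x D x NL` array).
#' @param ... Unused.
#' @return Integer vector of labels in `{-1, 1}`.
#' @export
predict.alt_opt <- function(object, dataset, ...) {
  A <- if (inherits(dataset, "patch_dataset")) dataset$A else dataset
  dec <- drop(render_batch(A, object$x) %*% object$w) + object$b
  ifelse(dec >= 0, 1L, -1L)
}

#' @export
print.alt_opt <- function(x, ...) {
  cat(sprintf(
    "<alt_opt> %d sweeps (%s), %d sub-lights, hinge = %.4g\n",
    x$iterations, if (x$converged) "converged" else "max_iter",
    length(x$x), utils::tail(x$history$hinge, 1)
  ))
  invisible(x)
}

#' Tidiers for alternating-optimization fits
#'
#' `tidy()` returns one row per learned weight (lighting weights `x`,
#' classifier weights `w`, and the bias); `glance()` returns a one-row
#' convergence summary.
#'
#' @param x An `"alt_opt"` fit.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.alt_opt <- function(x, ...) {
  dplyr::bind_rows(
    tibble(
      term = sprintf("x[%02d]", seq_along(x$x)),
      role = "lighting",
      estimate = x$x
    ),
    tibble(
      term = sprintf("w[%02d]", seq_along(x$w)),
      role = "classifier",
      estimate = x$w
    ),
    tibble(term = "b", role = "bias", estimate = x$b)
  )
}

#' @rdname tidy.alt_opt
#' @export
glance.alt_opt <- function(x, ...) {
  last <- utils::tail(x$history, 1)
  tibble(
    iterations = x$iterations,
    converged = x$converged,
    hinge = last$hinge,
    objective_w = last$objective_w,
    objective_x = last$objective_x,
    cost = x$cost
  )
}
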