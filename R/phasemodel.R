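# Logistic-regression classifiers on pooled embeddings: standardization,
# class/dataset-balanced weights, a deterministic penalized Newton fit,
# L1-path feature selection, and the model artifact.

#' Fit per-feature standardization parameters
#'
#' Means and standard deviations are computed on the fitting rows only;
#' features with (numerically) zero variance are dropped and recorded.
#'
#' @param X Numeric n x D matrix, n >= 2.
#' @param strict Error on zero-variance features instead of dropping them.
#' @return An object of class `scaler_params`: list with `mean`, `sd`
#'   (length D), `keep` (indices of retained features), `dropped`, `dim_in`.
#' @export
standardize_fit <- function(X, strict = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("standardize_fit needs at least 2 rows")
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  zero <- which(!is.finite(sdv) | sdv <= 1e-12)
  if (strict && length(zero) > 0L) {
    stop("zero-variance feature(s): ", paste(zero, collapse = ", "))
  }
  structure(list(mean = mu, sd = sdv,
                 keep = setdiff(seq_len(ncol(X)), zero),
                 dropped = zero, dim_in = ncol(X)),
            class = "scaler_params")
}

#' Apply fitted standardization parameters
#'
#' @param X Numeric matrix with the same columns the scaler was fitted on.
#' @param scaler A `scaler_params` object from [standardize_fit()].
#' @return Matrix of standardized retained features.
#' @export
standardize_apply <- function(X, scaler) {
  X <- as.matrix(X)
  if (ncol(X) != scaler$dim_in) {
    stop("expected ", scaler$dim_in, " features, got ", ncol(X))
  }
  k <- scaler$keep
  sweep(sweep(X[, k, drop = FALSE], 2L, scaler$mean[k]), 2L,
        scaler$sd[k], "/")
}

#' Class- and dataset-balanced sample weights
#'
#' Weight of sample i is proportional to
#' `1 / (n_tag(i) * f_label(i)|tag(i))`, normalized so that weights sum to
#' n. Consequently every dataset contributes equal total weight, and within
#' each dataset each class contributes equal total weight.
#'
#' @param labels 0/1 labels.
#' @param dataset_tags Dataset tag per sample.
#' @return Numeric weight vector summing to `length(labels)`.
#' @export
balanced_weights <- function(labels, dataset_tags) {
  stopifnot(length(labels) == length(dataset_tags),
            !anyNA(labels), !anyNA(dataset_tags))
  cell <- table(dataset_tags, factor(labels, levels = c(0, 1)))
  if (any(cell == 0L)) {
    stop("empty (dataset, class) cell: every dataset needs both classes")
  }
  n_cell <- cell[cbind(as.character(dataset_tags), as.character(labels))]
  w <- 1 / as.numeric(n_cell)
  w * length(labels) / sum(w)
}

#' Default grid of inverse regularization strengths
#'
#' Logarithmic, `1e-4 ... 1e4`, 9 points.
#'
#' @return Numeric vector.
#' @export
default_C_grid <- function() 10^seq(-4, 4, length.out = 9L)

# Weighted penalized log-likelihood (L2 penalty excludes the intercept).
penalized_loglik <- function(eta, y, w, beta, pen) {
  sum(w * (y * stats::plogis(eta, log.p = TRUE) +
             (1 - y) * stats::plogis(-eta, log.p = TRUE))) -
    sum(pen * beta^2) / 2
}

# Damped Newton (IRLS) maximization of the L2-penalized weighted logistic
# log-likelihood. Deterministic; converges to the unique optimum of the
# strictly concave objective, so the result is independent of `init`.
irls_logistic <- function(X, y, w, lambda, tol = 1e-8, max_iter = 10000L,
                          init = NULL) {
  Xi <- cbind(1, X)
  p <- ncol(Xi)
  pen <- c(0, rep(lambda, p - 1L))
  beta <- if (!is.null(init) && length(init) == p) init else numeric(p)
  f0 <- penalized_loglik(drop(Xi %*% beta), y, w, beta, pen)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(Xi, w * (y - mu))) - pen * beta
    Wv <- pmax(w * mu * (1 - mu), 1e-12)
    H <- crossprod(Xi * sqrt(Wv))
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, g), error = function(e) {
      diag(H) <- diag(H) + 1e-8 * max(diag(H))
      solve(H, g)
    })
    t_sz <- 1
    repeat {
      cand <- beta + t_sz * step
      f1 <- penalized_loglik(drop(Xi %*% cand), y, w, cand, pen)
      if (f1 >= f0 - 1e-12 || t_sz < 1e-10) break
      t_sz <- t_sz / 2
    }
    beta <- cand
    moved <- max(abs(t_sz * step))
    f0 <- f1
    if (moved < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("logistic fit did not converge within ", iter, " iterations")
  }
  list(intercept = beta[1L], weights = beta[-1L], iterations = iter)
}

#' Train a penalized logistic classifier on (pooled-embedding) features
#'
#' Maximizes the weighted penalized log-likelihood
#' `sum_i w_i * loglik_i - (1 / (2C)) * ||beta||^2` (L2) to step tolerance
#' 1e-8 with a damped Newton method, after standardizing features on the
#' training rows. `penalty = "l1"` delegates to the glmnet lasso at the
#' matched penalty strength and is mainly useful for sparse final fits.
#'
#' @param X n x D feature matrix (raw pooled embeddings; standardization is
#'   part of the fit).
#' @param y 0/1 labels.
#' @param C Inverse regularization strength (> 0).
#' @param penalty `"l2"` (default) or `"l1"`.
#' @param sample_weights Optional nonnegative weights (default 1).
#' @param tol Newton step tolerance.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @param init Optional warm-start coefficient vector
#'   `c(intercept, weights)` in the standardized feature space; initialization
#'   cannot change the optimum, only the path to it.
#' @param meta Optional list of training metadata stored in the artifact.
#' @return An object of class `phase_classifier` with elements `weights`,
#'   `intercept`, `selected_features`, `scaler`, `penalty`, `C`,
#'   `iterations`, `meta`.
#' @export
train_logistic <- function(X, y, C = 1, penalty = c("l2", "l1"),
                           sample_weights = NULL, tol = 1e-8,
                           max_iter = 10000L, init = NULL, meta = list()) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(C > 0, all(y %in% c(0, 1)), nrow(X) == length(y))
  w <- if (is.null(sample_weights)) rep(1, length(y)) else as.numeric(sample_weights)
  stopifnot(length(w) == length(y), all(w >= 0))
  scaler <- standardize_fit(X)
  Xs <- standardize_apply(X, scaler)
  if (penalty == "l2") {
    fit <- irls_logistic(Xs, y, w, lambda = 1 / C, tol = tol,
                         max_iter = max_iter, init = init)
  } else {
    # glmnet objective: (1/n) sum w_i nll_i + lambda ||beta||_1 with weights
    # rescaled to sum to n, so lambda = 1 / (C * n) matches our convention.
    gfit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 1,
                           weights = w, standardize = FALSE,
                           lambda = 1 / (C * length(y)), thresh = 1e-12)
    fit <- list(intercept = as.numeric(gfit$a0),
                weights = as.numeric(gfit$beta),
                iterations = as.integer(gfit$npasses))
  }
  structure(list(weights = fit$weights, intercept = fit$intercept,
                 selected_features = seq_len(ncol(X)), scaler = scaler,
                 penalty = penalty, C = C, iterations = fit$iterations,
                 meta = meta),
            class = "phase_classifier")
}

#' Select features along the L1 regularization path
#'
#' Sweeps the lasso path from strong to weak penalty on standardized
#' features and returns the support of the first path point with at least
#' `target_k` nonzero weights, truncated to the `target_k` entries of
#' largest absolute weight. Deterministic.
#'
#' @param X n x D feature matrix.
#' @param y 0/1 labels.
#' @param target_k Number of features to retain (<= D).
#' @param weights Optional sample weights.
#' @param nlambda,lambda_min_ratio Discretization of the penalty path.
#' @return Sorted integer vector of `target_k` feature indices.
#' @export
select_features_l1 <- function(X, y, target_k, weights = NULL,
                               nlambda = 200L, lambda_min_ratio = 1e-4) {
  X <- as.matrix(X)
  stopifnot(target_k >= 1L, target_k <= ncol(X))
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  scaler <- standardize_fit(X)
  Xs <- standardize_apply(X, scaler)
  fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 1, weights = w,
                        standardize = FALSE, nlambda = nlambda,
                        lambda.min.ratio = lambda_min_ratio)
  j <- which(fit$df >= target_k)[1L]
  if (is.na(j)) {
    stop("L1 path never reaches ", target_k, " nonzero weights (max ",
         max(fit$df), ")")
  }
  beta <- as.numeric(fit$beta[, j])
  nz <- which(beta != 0)
  kept_in_scaled <- nz[order(-abs(beta[nz]))][seq_len(target_k)]
  sort(scaler$keep[kept_in_scaled])
}

#' Train a classifier with optional two-stage L1 -> L2 selection
#'
#' The protocol behind the reduced-feature amyloid models: select
#' `target_k` features on the L1 path, then refit an L2-penalized model on
#' the selected columns. Without `target_k` this is a plain [train_logistic()]
#' fit on all features.
#'
#' @inheritParams train_logistic
#' @param target_k Optional number of features to select before the final
#'   L2 fit.
#' @return A `phase_classifier`; `selected_features` indexes the original
#'   feature space.
#' @export
train_classifier <- function(X, y, C = 1, sample_weights = NULL,
                             target_k = NULL, meta = list()) {
  X <- as.matrix(X)
  if (is.null(target_k)) {
    return(train_logistic(X, y, C = C, sample_weights = sample_weights,
                          meta = meta))
  }
  sel <- select_features_l1(X, y, target_k, weights = sample_weights)
  model <- train_logistic(X[, sel, drop = FALSE], y, C = C,
                          sample_weights = sample_weights, meta = meta)
  model$selected_features <- sel
  model$dim_in <- ncol(X)
  model
}

#' @export
print.phase_classifier <- function(x, ...) {
  cat("<phase_classifier> ", x$penalty, " penalty, C = ", x$C, ", ",
      length(x$weights), " feature(s)\n", sep = "")
  invisible(x)
}

#' Predict probabilities or logits from a trained classifier
#'
#' @param object A `phase_classifier`.
#' @param newdata n x D matrix in the training feature space (or already
#'   subset to the selected features).
#' @param type `"prob"` (default) or `"logit"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.phase_classifier <- function(object, newdata,
                                     type = c("prob", "logit"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  full_d <- object$dim_in %||% object$scaler$dim_in
  if (ncol(X) == full_d && full_d != object$scaler$dim_in) {
    X <- X[, object$selected_features, drop = FALSE]
  }
  Xs <- standardize_apply(X, object$scaler)
  eta <- drop(object$intercept + Xs %*% object$weights)
  if (type == "logit") eta else stats::plogis(eta)
}

#' Serialize a classifier to portable JSON
#'
#' @param model A `phase_classifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "phase_classifier"))
  obj <- list(format = "idrphase_classifier", version = 1L,
              weights = model$weights, intercept = model$intercept,
              selected_features = model$selected_features,
              scaler = list(mean = model$scaler$mean, sd = model$scaler$sd,
                            keep = model$scaler$keep,
                            dim_in = model$scaler$dim_in),
              penalty = model$penalty, C = model$C,
              dim_in = model$dim_in %||% model$scaler$dim_in,
              meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a classifier serialized by [write_classifier()]
#'
#' @param path JSON path.
#' @return A `phase_classifier`.
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "idrphase_classifier")) {
    stop("'", path, "' is not an idrphase classifier artifact")
  }
  scaler <- structure(list(mean = as.numeric(obj$scaler$mean),
                           sd = as.numeric(obj$scaler$sd),
                           keep = as.integer(obj$scaler$keep),
                           dropped = setdiff(seq_len(obj$scaler$dim_in),
                                             as.integer(obj$scaler$keep)),
                           dim_in = as.integer(obj$scaler$dim_in)),
                      class = "scaler_params")
  structure(list(weights = as.numeric(obj$weights),
                 intercept = as.numeric(obj$intercept),
                 selected_features = as.integer(obj$selected_features),
                 scaler = scaler, penalty = obj$penalty, C = obj$C,
                 iterations = NA_integer_, dim_in = as.integer(obj$dim_in),
                 meta = obj$meta),
            class = "phase_classifier")
}
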