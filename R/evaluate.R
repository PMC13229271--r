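# Evaluation protocol: rank-based metrics, nested leave-one-out
# cross-validation, repeated stratified splits and leave-one-group-out
# harnesses.

#' ROC-AUC via the rank (Mann-Whitney) statistic
#'
#' Equals `P(score+ > score-) + 0.5 * P(tie)` computed with midranks.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  y <- as.numeric(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("roc_auc needs both classes")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (step-function convention)
#'
#' Sum over positives of precision at each positive's rank, divided by the
#' number of positives; ties are broken by descending score then stable
#' input order.
#'
#' @inheritParams roc_auc
#' @return Average precision in `(0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  y <- as.numeric(labels)
  if (sum(y == 1) == 0L) stop("average_precision needs at least one positive")
  ord <- order(-scores)
  ys <- y[ord]
  prec <- cumsum(ys) / seq_along(ys)
  sum(prec[ys == 1]) / sum(ys)
}

# Stratified index sample: for each class, round(frac * n_class) indices
# (at least 1). Returns the sampled ("test"/"validation") indices. Caller
# manages the RNG state.
stratified_holdout <- function(y, frac) {
  idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
    k <- max(1L, round(frac * length(ix)))
    if (k >= length(ix)) k <- length(ix) - 1L
    if (k < 1L) stop("a class is too small to split (n = ", length(ix), ")")
    sample(ix, k)
  }), use.names = FALSE)
  sort(idx)
}

#' Nested leave-one-out cross-validation
#'
#' Outer loop: each sample is held out once. Inner loop: a single seeded
#' stratified split of the remaining n - 1 samples selects the inverse
#' regularization strength `C` by validation AUC (ties favour the smallest,
#' i.e. most regularized, `C`); the fold model is then refit on all n - 1
#' samples at the chosen `C` and scores the held-out sample. With a length-1
#' grid this reduces to plain LOOCV. Standardization is refit inside every
#' fold on its training rows only.
#'
#' @param X n x D feature matrix.
#' @param y 0/1 labels (n >= 3, both classes).
#' @param C_grid Candidate `C` values (sorted internally).
#' @param weights Optional sample weights.
#' @param seed Seed controlling the per-fold inner splits.
#' @param inner_frac Fraction of the n - 1 samples used for inner
#'   validation.
#' @return List with `prob` (one out-of-fold probability per sample,
#'   never trained on itself), `chosen_C`, `auc`, `ap` and `y`.
#' @export
nested_loocv <- function(X, y, C_grid = default_C_grid(), weights = NULL,
                         seed = 1L, inner_frac = 0.2) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(n >= 3L, nrow(X) == n, length(C_grid) >= 1L,
            sum(y == 1) > 0L, sum(y == 0) > 0L)
  C_grid <- sort(as.numeric(C_grid))
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  fold_seeds <- spawn_seeds(seed, n)
  # Warm starts: the fold optima are near the full-data optimum, and the
  # objective is strictly concave, so warm starting changes speed only.
  full_fit <- lapply(C_grid, function(C)
    train_logistic(X, y, C = C, sample_weights = w))
  init_for <- function(ci) c(full_fit[[ci]]$intercept, full_fit[[ci]]$weights)
  prob <- numeric(n)
  chosen <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ci <- 1L
    if (length(C_grid) > 1L) {
      val <- with_seed(fold_seeds[i],
                       tr[stratified_holdout(y[tr], inner_frac)])
      itr <- setdiff(tr, val)
      if (length(unique(y[val])) < 2L || length(unique(y[itr])) < 2L) {
        stop("inner split of fold ", i, " lacks both classes")
      }
      inner_auc <- vapply(seq_along(C_grid), function(j) {
        m <- train_logistic(X[itr, , drop = FALSE], y[itr], C = C_grid[j],
                            sample_weights = w[itr], init = init_for(j))
        roc_auc(predict(m, X[val, , drop = FALSE]), y[val])
      }, numeric(1))
      ci <- which.max(inner_auc) # ties: first = smallest C
    }
    m <- train_logistic(X[tr, , drop = FALSE], y[tr], C = C_grid[ci],
                        sample_weights = w[tr], init = init_for(ci))
    prob[i] <- predict(m, X[i, , drop = FALSE])
    chosen[i] <- C_grid[ci]
  }
  list(prob = prob, chosen_C = chosen, auc = roc_auc(prob, y),
       ap = average_precision(prob, y), y = y)
}

#' Repeated stratified train/test evaluation
#'
#' @param X n x D feature matrix.
#' @param y 0/1 labels.
#' @param n_splits Number of random splits.
#' @param test_frac Fraction held out per split (stratified by class).
#' @param seed Seed; the whole report is reproducible from it.
#' @param train_fn Function `(X, y, weights) -> phase_classifier`; defaults
#'   to an L2 fit at `C`.
#' @param C Inverse regularization for the default `train_fn`.
#' @param weights Optional sample weights.
#' @return An `eval_report`: per-split ROC-AUC and average-precision lists
#'   with their medians and 16th/84th percentiles.
#' @export
repeated_split_eval <- function(X, y, n_splits = 30L, test_frac = 0.2,
                                seed = 1L, train_fn = NULL, C = 1,
                                weights = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(test_frac > 0, test_frac < 1, n_splits >= 1L)
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  if (is.null(train_fn)) {
    train_fn <- function(X, y, weights)
      train_logistic(X, y, C = C, sample_weights = weights)
  }
  split_seeds <- spawn_seeds(seed, n_splits)
  auc <- ap <- numeric(n_splits)
  for (s in seq_len(n_splits)) {
    test <- with_seed(split_seeds[s], stratified_holdout(y, test_frac))
    train <- setdiff(seq_along(y), test)
    if (length(unique(y[test])) < 2L || length(unique(y[train])) < 2L) {
      stop("split ", s, " lacks both classes")
    }
    m <- train_fn(X[train, , drop = FALSE], y[train], w[train])
    sc <- predict(m, X[test, , drop = FALSE])
    auc[s] <- roc_auc(sc, y[test])
    ap[s] <- average_precision(sc, y[test])
  }
  structure(list(auc = auc, ap = ap,
                 median_auc = stats::median(auc),
                 auc_p16 = unname(stats::quantile(auc, 0.16)),
                 auc_p84 = unname(stats::quantile(auc, 0.84)),
                 median_ap = stats::median(ap),
                 ap_p16 = unname(stats::quantile(ap, 0.16)),
                 ap_p84 = unname(stats::quantile(ap, 0.84)),
                 n_splits = n_splits, test_frac = test_frac, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d split(s), test fraction %.2f\n  ROC-AUC median %.3f (16th-84th pct: %.3f-%.3f)\n  AP      median %.3f (16th-84th pct: %.3f-%.3f)\n",
    x$n_splits, x$test_frac, x$median_auc, x$auc_p16, x$auc_p84,
    x$median_ap, x$ap_p16, x$ap_p84))
  invisible(x)
}

#' Leave-one-group-out evaluation
#'
#' For each group g (e.g. a dataset tag or a GO term), train on all samples
#' outside g and evaluate on g. Groups containing a single class get `NA`
#' metrics rather than an error.
#'
#' @param X n x D feature matrix.
#' @param y 0/1 labels.
#' @param groups Group label per sample (>= 2 distinct groups).
#' @param train_fn Function `(X, y, weights) -> phase_classifier`; defaults
#'   to an L2 fit at `C`.
#' @param C Inverse regularization for the default `train_fn`.
#' @param weights Optional sample weights.
#' @return Data frame with one row per group (`group`, `n`, `n_pos`, `auc`,
#'   `ap`); attribute `median_auc` is the median over groups with defined
#'   AUC.
#' @export
leave_one_group_out_eval <- function(X, y, groups, train_fn = NULL, C = 1,
                                     weights = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  groups <- as.character(groups)
  glev <- unique(groups)
  if (length(glev) < 2L) stop("need at least 2 groups")
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  if (is.null(train_fn)) {
    train_fn <- function(X, y, weights)
      train_logistic(X, y, C = C, sample_weights = weights)
  }
  rows <- lapply(glev, function(g) {
    test <- which(groups == g)
    train <- which(groups != g)
    if (length(unique(y[train])) < 2L) {
      stop("training portion lacks both classes when holding out '", g, "'")
    }
    m <- train_fn(X[train, , drop = FALSE], y[train], w[train])
    if (length(unique(y[test])) < 2L) {
      return(data.frame(group = g, n = length(test), n_pos = sum(y[test]),
                        auc = NA_real_, ap = NA_real_))
    }
    sc <- predict(m, X[test, , drop = FALSE])
    data.frame(group = g, n = length(test), n_pos = sum(y[test]),
               auc = roc_auc(sc, y[test]),
               ap = average_precision(sc, y[test]))
  })
  out <- do.call(rbind, rows)
  attr(out, "median_auc") <- stats::median(out$auc, na.rm = TRUE)
  out
}
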