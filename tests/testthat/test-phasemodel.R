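# Classifier training protocol: standardization, balanced weights, the
# penalized Newton fit, L1 feature selection, nested LOOCV.

test_that("standardization fits on training rows and matches a loop oracle", {
  set.seed(2)
  X <- cbind(matrix(rnorm(40, mean = 3, sd = 2), ncol = 4L), 7) # constant col
  sc <- standardize_fit(X)
  expect_equal(sc$dropped, 5L)
  Xs <- standardize_apply(X, sc)
  expect_lt(max(abs(colMeans(Xs))), 1e-10)
  expect_equal(unname(apply(Xs, 2L, sd)), rep(1, 4L))
  # new rows: element-wise oracle
  Xnew <- matrix(rnorm(20, 1, 3), ncol = 5L)
  got <- standardize_apply(Xnew, sc)
  for (j in 1:4) for (i in 1:4) {
    expect_equal(got[i, j], (Xnew[i, j] - sc$mean[j]) / sc$sd[j])
  }
  expect_error(standardize_fit(X, strict = TRUE), "zero-variance")
})

test_that("balanced weights equalize datasets and classes within datasets", {
  # one dataset, balanced classes -> all weights 1
  w <- balanced_weights(rep(c(0, 1), 10L), rep("a", 20L))
  expect_equal(w, rep(1, 20L))
  # two datasets of sizes 10 and 90 -> each dataset's weights sum to 50
  y <- c(rep(c(0, 1), 5L), rep(c(0, 0, 0, 1), length.out = 90L))
  tags <- c(rep("small", 10L), rep("big", 90L))
  w <- balanced_weights(y, tags)
  expect_equal(sum(w), 100)
  expect_equal(sum(w[tags == "small"]), 50)
  expect_equal(sum(w[tags == "big"]), 50)
  # within a tag, 1:3 positives:negatives -> positives weigh 3x negatives
  big_pos <- w[tags == "big" & y == 1][1L]
  big_neg <- w[tags == "big" & y == 0][1L]
  expect_equal(big_pos / big_neg, sum(tags == "big" & y == 0) /
                 sum(tags == "big" & y == 1))
  expect_error(balanced_weights(rep(0, 5L), rep("a", 5L)), "both classes")
})

test_that("the logistic fit separates separable data and matches glmnet ridge", {
  # separable 1-D data, weak penalty -> perfect training ranking
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1L)
  y <- c(0, 0, 0, 1, 1, 1)
  m <- train_logistic(x, y, C = 1e4)
  expect_equal(roc_auc(predict(m, x), y), 1.0)
  expect_gt(m$weights[1L], 0)
  # cross-check coefficients against glmnet ridge at matched penalty
  set.seed(4)
  X <- matrix(rnorm(600), ncol = 3L)
  yy <- rbinom(200, 1L, plogis(X %*% c(1, -0.5, 0.2)))
  w <- runif(200, 0.5, 1.5)
  C <- 0.7
  ours <- train_logistic(X, yy, C = C, sample_weights = w)
  Xs <- standardize_apply(X, ours$scaler)
  # glmnet rescales weights to sum to n; match that convention explicitly
  wn <- w / sum(w) * length(w)
  g <- glmnet::glmnet(Xs, yy, family = "binomial", alpha = 0,
                      weights = wn, standardize = FALSE,
                      lambda = 1 / (C * length(yy)), thresh = 1e-14)
  expect_equal(unname(ours$weights), as.numeric(g$beta), tolerance = 1e-3)
  expect_equal(ours$intercept, as.numeric(g$a0), tolerance = 1e-3)
})

test_that("held-out AUC on label-independent features stays near chance", {
  set.seed(10)
  aucs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(200 * 4L), ncol = 4L)
    y <- rbinom(200, 1L, 0.5)
    test <- sample(200, 60L)
    m <- train_logistic(X[-test, ], y[-test], C = 1)
    roc_auc(predict(m, X[test, ]), y[test])
  }, numeric(1))
  # single held-out splits of 60 samples have sd ~ 0.075 under the null
  expect_true(all(aucs >= 0.25 & aucs <= 0.75))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("planted logistic parameters are recovered (direction cosine >= 0.98)", {
  set.seed(42)
  d <- 5L
  w_star <- c(2, -1, 0.5, 1.5, -2)
  w_star <- w_star / sqrt(sum(w_star^2))
  X <- matrix(rnorm(5000 * d), ncol = d)
  y <- rbinom(5000, 1L, plogis(X %*% (3 * w_star)))
  m <- train_logistic(X, y, C = 10)
  cosine <- sum(m$weights * w_star) /
    sqrt(sum(m$weights^2) * sum(w_star^2))
  expect_gte(cosine, 0.98)
})

test_that("L1 path selection finds planted support and honours target_k", {
  set.seed(8)
  n <- 500L
  X <- matrix(rnorm(n * 50L), ncol = 50L)
  y <- rbinom(n, 1L, plogis(2 * X[, 7L] - 2 * X[, 31L]))
  sel <- select_features_l1(X, y, target_k = 2L)
  expect_setequal(sel, c(7L, 31L))
  # target_k = D with a weak penalty floor returns all features
  X2 <- matrix(rnorm(300 * 4L), ncol = 4L)
  y2 <- rbinom(300, 1L, plogis(X2 %*% c(1, -1, 0.5, -0.5)))
  expect_equal(select_features_l1(X2, y2, target_k = 4L), 1:4)
  expect_error(select_features_l1(X2, y2, target_k = 4L,
                                  nlambda = 3L, lambda_min_ratio = 0.9),
               "never reaches")
})

test_that("train_classifier with target_k predicts from the original feature space", {
  set.seed(12)
  X <- matrix(rnorm(400 * 30L), ncol = 30L)
  y <- rbinom(400, 1L, plogis(1.5 * X[, 3L] - 1.5 * X[, 17L]))
  m <- train_classifier(X, y, target_k = 2L)
  expect_length(m$weights, 2L)
  expect_length(predict(m, X), 400L)
  # round-trip through the JSON artifact
  f <- withr::local_tempfile(fileext = ".json")
  write_classifier(m, f)
  m2 <- read_classifier(f)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
  expect_equal(predict(m2, X, type = "logit"), predict(m, X, type = "logit"),
               tolerance = 1e-12)
})

test_that("nested LOOCV reduces to plain LOOCV for a singleton grid", {
  set.seed(14)
  X <- matrix(rnorm(20 * 2L), ncol = 2L)
  y <- rep(c(0, 1), 10L)
  cv1 <- nested_loocv(X, y, C_grid = 1, seed = 1L)
  # manual plain LOOCV
  manual <- vapply(1:20, function(i) {
    m <- train_logistic(X[-i, ], y[-i], C = 1)
    predict(m, X[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(cv1$prob, manual, tolerance = 1e-9)
  expect_true(all(cv1$chosen_C == 1))
})

test_that("nested LOOCV separates strong signal and never sees its own label", {
  set.seed(15)
  X <- matrix(rnorm(30), ncol = 1L)
  y <- as.numeric(X[, 1L] + rnorm(30, sd = 0.1) > 0)
  if (length(unique(y)) == 1L) y[1L] <- 1 - y[1L]
  cv <- nested_loocv(X, y, C_grid = c(0.1, 1, 10), seed = 2L)
  expect_gt(cv$auc, 0.9)
  # flipping sample i's label must not change its own out-of-fold score
  y2 <- y
  y2[5L] <- 1 - y2[5L]
  cv2 <- nested_loocv(X, y2, C_grid = c(0.1, 1, 10), seed = 2L)
  expect_equal(cv2$prob[5L], cv$prob[5L], tolerance = 1e-9)
})

test_that("rank AUC equals the O(n^2) pairwise oracle, ties included", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(1:10, c(rep(0, 5), rep(1, 5))), 1.0)
  expect_equal(roc_auc(rep(2, 10), c(rep(0, 5), rep(1, 5))), 0.5)
  set.seed(16)
  for (i in 1:40) {
    n <- sample(4:60, 1L)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # many ties
    labels <- rbinom(n, 1L, 0.5)
    if (length(unique(labels)) < 2L) labels[1:2] <- c(0L, 1L)
    expect_equal(roc_auc(scores, labels), roc_auc_oracle(scores, labels))
  }
  # negation symmetry without ties
  set.seed(17)
  s <- rnorm(30)
  l <- rbinom(30, 1L, 0.5); l[1:2] <- c(0L, 1L)
  expect_equal(roc_auc(-s, l), 1 - roc_auc(s, l))
  expect_error(roc_auc(s, rep(1, 30)), "both classes")
})

test_that("average precision follows the step convention and nulls to prevalence", {
  expect_equal(average_precision(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1.0)
  expect_equal(average_precision(c(4, 3, 2, 1), c(0, 1, 0, 0)), 0.5)
  set.seed(18)
  y <- rbinom(5000, 1L, 0.2)
  s <- runif(5000)
  expect_lt(abs(average_precision(s, y) - mean(y)), 0.03)
  expect_error(average_precision(1:3, c(0, 0, 0)), "positive")
})

test_that("rank metrics agree with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (i in 1:10) {
    s <- rnorm(50)
    y <- rbinom(50, 1L, 0.4); if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    ref <- suppressMessages(as.numeric(pROC::auc(y, s, direction = "<",
                                                 levels = c(0, 1))))
    expect_equal(roc_auc(s, y), ref)
  }
})

test_that("repeated-split reports are seeded and degenerate gracefully", {
  set.seed(20)
  X <- matrix(rnorm(120), ncol = 2L)
  y <- as.numeric(X[, 1L] > 0)
  r1 <- repeated_split_eval(X, y, n_splits = 5L, seed = 7L)
  r2 <- repeated_split_eval(X, y, n_splits = 5L, seed = 7L)
  expect_identical(r1$auc, r2$auc)
  one <- repeated_split_eval(X, y, n_splits = 1L, seed = 7L)
  expect_equal(one$median_auc, one$auc_p16)
  expect_equal(one$median_auc, one$auc_p84)
})

test_that("leave-one-group-out reports per-group metrics and handles one-class groups", {
  set.seed(22)
  X <- matrix(rnorm(300), ncol = 2L)
  y <- as.numeric(X[, 1L] + rnorm(150, sd = 0.5) > 0)
  groups <- rep(c("g1", "g2", "g3"), each = 50L)
  out <- leave_one_group_out_eval(X, y, groups, C = 1)
  expect_equal(nrow(out), 3L)
  # identically distributed groups: per-group AUC near the pooled AUC
  pooled <- roc_auc(X[, 1L], y)
  expect_true(all(abs(out$auc - pooled) < 0.2))
  # a group with only negatives gets NA metrics, not an error
  y2 <- y; y2[groups == "g2"] <- 0
  out2 <- leave_one_group_out_eval(X, y2, groups, C = 1)
  expect_true(is.na(out2$auc[out2$group == "g2"]))
  expect_false(anyNA(out2$auc[out2$group != "g2"]))
  expect_error(leave_one_group_out_eval(X, y, rep("g", 150L)), "2 groups")
})
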