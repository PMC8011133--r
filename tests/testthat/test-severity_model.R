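std <- function(x) scale(x)[, , drop = FALSE]

test_that("PCA reduction matches a brute-force eigendecomposition", {
  set.seed(51)
  x <- std(matrix(rnorm(30), 6, 5))
  pca <- pca_reduce(x, k = 4)
  ev <- eigen(crossprod(x) / (nrow(x) - 1), symmetric = TRUE)
  expect_equal(pca$explained_var[1:4], ev$values[1:4], tolerance = 1e-8)
  for (j in 1:4) {
    w <- ev$vectors[, j]
    if (w[which.max(abs(w))] < 0) w <- -w
    expect_equal(unname(pca$loadings[, j]), w, tolerance = 1e-8)
    expect_equal(unname(pca$scores[, j]), unname(as.numeric(x %*% w)),
                 tolerance = 1e-8)
  }
})

test_that("PCA explained variances satisfy the trace identity and ordering", {
  set.seed(52)
  x <- std(matrix(rnorm(41 * 30), 30, 41))
  pca <- pca_reduce(x, k = 4)
  expect_true(all(diff(pca$explained_var) <= 1e-12))
  expect_equal(sum(pca$explained_var), 41, tolerance = 1e-8)
})

test_that("PCA flags rank deficiency", {
  set.seed(53)
  base <- matrix(rnorm(20 * 2), 20, 2)
  x <- base %*% matrix(rnorm(2 * 41), 2, 41)   # rank 2 in 41 dims
  pca <- pca_reduce(std(x), k = 4)
  expect_true(pca$rank_deficient)
  expect_lte(pca$k, 2)
  expect_lt(sum(pca$explained_var[-(1:2)]) / sum(pca$explained_var), 1e-10)
})

test_that("the linear SVM separates separable classes deterministically", {
  set.seed(54)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 10), 20, 2))
  y <- rep(c("a", "b"), each = 20)
  m <- train_linear_svm(x, y)
  expect_identical(as.character(predict(m, x)), y)
  m2 <- train_linear_svm(x, y)
  expect_identical(predict(m, x), predict(m2, x))
  expect_error(train_linear_svm(x, rep("a", 40)), "2 classes")

  # 4 well-separated Gaussian classes: held-out accuracy >= 0.95
  centers <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5), 4, 2, byrow = TRUE) * 5
  xx <- do.call(rbind, lapply(1:4, function(k)
    matrix(rnorm(25 * 2, 0, 1), 25, 2) + rep(centers[k, ], each = 25)))
  yy <- factor(rep(letters[1:4], each = 25))
  train <- rep(c(TRUE, FALSE), 50)
  m4 <- train_linear_svm(xx[train, ], yy[train])
  acc <- mean(predict(m4, xx[!train, ]) == yy[!train])
  expect_gte(acc, 0.95)
})

test_that("ROC/AUC matches its printed examples and the pair-counting oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(c(0.9, 0.3, 0.6, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)

  set.seed(55)
  for (i in 1:20) {
    n <- sample(4:50, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)          # force ties
    got <- roc_auc(scores, labels)
    expect_equal(got$auc, brute_auc(scores, labels), tolerance = 1e-12)
    # curve contract
    expect_equal(got$roc[1, ], data.frame(fpr = 0, tpr = 0))
    expect_equal(unlist(got$roc[nrow(got$roc), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(got$roc$fpr) >= 0) && all(diff(got$roc$tpr) >= 0))
    # invariance under a strictly increasing transform
    expect_equal(roc_auc(exp(2 * scores), labels)$auc, got$auc)
  }

  # independent cross-check against pROC on one fixed case
  set.seed(58)
  labels <- rep(c(0, 1), each = 20)
  scores <- rnorm(40) + labels
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<",
                                              quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("repeated stratified CV is stratified, deterministic and leak-free", {
  set.seed(56)
  x <- matrix(rnorm(60 * 8), 60, 8)
  y <- factor(rep(c("a", "b", "c"), each = 20))
  cv1 <- repeated_stratified_cv(x, y, folds = 5, repeats = 3, seed = 7)
  cv2 <- repeated_stratified_cv(x, y, folds = 5, repeats = 3, seed = 7)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$per_fold, cv2$per_fold)

  # stratification: every fold holds 4 of each class
  for (r in 1:3) {
    tab <- table(cv1$folds[, r], y)
    expect_true(all(tab == 4))
  }

  # per-fold transforms genuinely differ from the whole-data transform:
  # means computed inside training folds change across folds
  means_by_fold <- sapply(1:5, function(f)
    colMeans(x[cv1$folds[, 1] != f, , drop = FALSE]))
  expect_gt(max(apply(means_by_fold, 1, sd)), 0)

  expect_error(repeated_stratified_cv(x[1:21, ], factor(c(rep("a", 20), "b")),
                                      seed = 1),
               "at least 2 members")
  expect_warning(
    repeated_stratified_cv(rbind(x, matrix(rnorm(24), 3, 8)),
                           factor(c(as.character(y), rep("d", 3))),
                           folds = 5, repeats = 1, seed = 1),
    "fewer members than folds")
})

test_that("CV recovers separable structure and stays null on noise", {
  set.seed(57)
  # one centre per coordinate axis so every class is linearly separable
  # from the rest (collinear centres would not be, one-vs-rest)
  x <- do.call(rbind, lapply(1:4, function(k) {
    m <- matrix(rnorm(15 * 6), 15, 6)
    m[, k] <- m[, k] + 20
    m
  }))
  y <- factor(rep(c("healthy", "mild", "moderate", "severe"), each = 15))
  cv <- repeated_stratified_cv(x, y, folds = 5, repeats = 2, seed = 3)
  expect_true(all(cv$summary$mean_auc >= 0.99))

  # permuted-label null: AUC near one half in both the fold-honest and the
  # whole-data ("paper literal") preprocessing modes -- the transforms are
  # unsupervised, so neither should find signal in noise
  xn <- matrix(rnorm(100 * 10), 100, 10)
  yn <- factor(rep(c("healthy", "mild", "moderate", "severe"), each = 25))
  aucs <- sapply(c(FALSE, TRUE), function(lit) {
    cvn <- repeated_stratified_cv(xn, sample(yn), folds = 5, repeats = 2,
                                  seed = 9, paper_literal = lit)
    mean(cvn$summary$mean_auc)
  })
  expect_true(all(abs(aucs - 0.5) < 0.12))
})
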