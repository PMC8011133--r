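# Severity classifier: z-scored features -> PCA (4 components) -> linear
# one-vs-rest SVM, evaluated with repeated stratified 5-fold CV and
# per-class ROC/AUC.

# Column-wise standardization fit on training data only.
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

# Median imputation with medians taken from the training portion.
fit_imputer <- function(x) {
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  med
}

apply_imputer <- function(x, med) {
  for (j in seq_len(ncol(x))) {
    miss <- !is.finite(x[, j])
    if (any(miss)) x[miss, j] <- med[j]
  }
  x
}

#' Reduce a standardized feature matrix with PCA
#'
#' Projects onto the top `k` eigenvectors of the covariance of the
#' (already standardized) columns, ordered by decreasing explained
#' variance, with a deterministic sign convention: the largest-magnitude
#' loading of each component is made positive. If the matrix has rank
#' below `k`, the available components are returned and flagged.
#'
#' @param x Numeric matrix (subjects x features), standardized columns.
#' @param k Number of components (default 4).
#' @return List: `scores` (n x k'), `loadings` (p x k'), `sdev`,
#'   `explained_var` (all components), `k` (components actually
#'   returned), `rank_deficient` flag.
#' @export
pca_reduce <- function(x, k = 4) {
  x <- as.matrix(x)
  assert_that(nrow(x) > k, "need more subjects than components")
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-9)
  k_eff <- min(k, rank)
  load <- pc$rotation[, seq_len(k_eff), drop = FALSE]
  for (j in seq_len(k_eff)) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  list(scores = x %*% load, loadings = load, sdev = pc$sdev,
       explained_var = ev, k = k_eff, rank_deficient = k_eff < k)
}

#' Train a one-vs-rest linear SVM
#'
#' One linear-kernel support vector machine per class against the rest
#' (regularization `C`, no class weighting), each exposing a continuous
#' decision score oriented so that larger means more like the class.
#' Prediction takes the class with the largest score.
#'
#' @param x Numeric matrix of predictors (e.g. PCA scores).
#' @param y Class labels (factor or character), at least 2 classes.
#' @param C SVM cost parameter (default 1).
#' @return An `ovr_svm` model object.
#' @export
train_linear_svm <- function(x, y, C = 1) {
  x <- as.matrix(x)
  y <- factor(y)
  assert_that(nlevels(droplevels(y)) >= 2, "need at least 2 classes")
  y <- droplevels(y)
  fits <- lapply(levels(y), function(cls) {
    yb <- factor(y == cls, levels = c(FALSE, TRUE))
    m <- e1071::svm(x, yb, kernel = "linear", cost = C, scale = FALSE)
    dv <- attr(stats::predict(m, x, decision.values = TRUE),
               "decision.values")[, 1]
    flip <- if (mean(dv[y == cls]) < mean(dv[y != cls])) -1 else 1
    list(svm = m, flip = flip)
  })
  names(fits) <- levels(y)
  structure(list(fits = fits, classes = levels(y), C = C),
            class = "ovr_svm")
}

#' Decision scores of a one-vs-rest SVM
#'
#' @param model An `ovr_svm` from [train_linear_svm()].
#' @param x Predictor matrix.
#' @return Matrix (n x classes) of decision scores.
#' @export
svm_scores <- function(model, x) {
  stopifnot(inherits(model, "ovr_svm"))
  x <- as.matrix(x)
  sc <- vapply(model$fits, function(f) {
    f$flip * attr(stats::predict(f$svm, x, decision.values = TRUE),
                  "decision.values")[, 1]
  }, numeric(nrow(x)))
  sc <- matrix(sc, nrow = nrow(x),
               dimnames = list(NULL, model$classes))
  sc
}

#' @export
predict.ovr_svm <- function(object, newdata, ...) {
  sc <- svm_scores(object, newdata)
  factor(object$classes[max.col(sc, ties.method = "first")],
         levels = object$classes)
}

#' ROC curve and AUC
#'
#' The AUC is the probability that a random positive outscores a random
#' negative, with ties counted one half — equal to the trapezoidal area
#' under the empirical ROC curve. The curve starts at (0, 0), ends at
#' (1, 1) and steps at each distinct score threshold.
#'
#' @param scores Numeric classifier scores (larger = more positive).
#' @param labels Binary labels (logical, 0/1, or two-level factor; the
#'   larger/`TRUE` level is positive).
#' @return List: `auc`, `roc` (data.frame with `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  assert_that(length(scores) == length(labels) && length(scores) > 0,
              "scores and labels must have equal positive length")
  assert_that(all(is.finite(scores)), "scores must be finite")
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  assert_that(np > 0 && nn > 0, "both classes must be present")

  rk <- rank(scores, ties.method = "average")
  auc <- (sum(rk[labels == 1L]) - np * (np + 1) / 2) / (np * nn)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  cut_idx <- which(!duplicated(s, fromLast = TRUE)[seq_along(s)] |
                     c(diff(s) != 0, TRUE))
  tp <- cumsum(l)[cut_idx]
  fp <- cumsum(1L - l)[cut_idx]
  roc <- data.frame(fpr = c(0, fp / nn), tpr = c(0, tp / np))
  list(auc = auc, roc = roc)
}

#' Repeated stratified k-fold cross-validation of the severity model
#'
#' For each repeat, the subjects are partitioned into `folds` stratified
#' folds (class proportions preserved). Within each fold split, median
#' imputation, z-score standardization and PCA are fit on the training
#' folds only and applied to the held-out fold — fitting them on the full
#' data before splitting leaks the held-out subjects into the feature
#' transform and inflates performance; `paper_literal = TRUE` reproduces
#' that leaking variant for comparison. A one-vs-rest linear SVM is
#' trained on the reduced training data and per-class ROC/AUC is computed
#' on the held-out fold.
#'
#' @param x Feature matrix (subjects x features); may contain NA.
#' @param y Class labels.
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeats (default 10).
#' @param k Number of principal components (default 4).
#' @param C SVM cost (default 1).
#' @param seed Integer seed controlling the fold partitions.
#' @param paper_literal Fit standardization and PCA once on the full data
#'   before splitting (leaky; default FALSE).
#' @return A `cv_report`: `per_fold` (repeat, fold, class, auc, n_test),
#'   `summary` (per-class mean and SD AUC), `roc` (per repeat x fold x
#'   class ROC points), `folds` (fold assignment matrix), `config`.
#' @export
repeated_stratified_cv <- function(x, y, folds = 5, repeats = 10, k = 4,
                                   C = 1, seed = 1L,
                                   paper_literal = FALSE) {
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  assert_that(nlevels(y) >= 2, "need at least 2 classes")
  tab <- table(y)
  assert_that(all(tab >= 2), "every class needs at least 2 members")
  if (any(tab < folds)) {
    warning(sprintf(
      "classes with fewer members than folds (%s): some folds will lack them",
      paste(names(tab)[tab < folds], collapse = ", ")), call. = FALSE)
  }

  if (paper_literal) {
    imp <- fit_imputer(x)
    xi <- apply_imputer(x, imp)
    scaler <- fit_scaler(xi)
    pca_all <- pca_reduce(apply_scaler(xi, scaler), k)
  }

  fold_matrix <- matrix(NA_integer_, nrow = length(y), ncol = repeats)
  per_fold <- list()
  rocs <- list()
  for (rep_i in seq_len(repeats)) {
    assign <- with_local_seed(derive_seed(seed, rep_i), {
      a <- integer(length(y))
      for (cls in levels(y)) {
        idx <- sample(which(y == cls))
        a[idx] <- rep_len(sample(folds), length(idx))
      }
      a
    })
    fold_matrix[, rep_i] <- assign
    for (fold_i in seq_len(folds)) {
      test <- assign == fold_i
      if (!any(test) || length(unique(y[!test])) < 2) next
      if (paper_literal) {
        red_train <- pca_all$scores[!test, , drop = FALSE]
        red_test <- pca_all$scores[test, , drop = FALSE]
      } else {
        imp <- fit_imputer(x[!test, , drop = FALSE])
        xtr <- apply_imputer(x[!test, , drop = FALSE], imp)
        xte <- apply_imputer(x[test, , drop = FALSE], imp)
        scaler <- fit_scaler(xtr)
        pca <- pca_reduce(apply_scaler(xtr, scaler), k)
        red_train <- pca$scores
        red_test <- apply_scaler(xte, scaler) %*% pca$loadings
      }
      model <- train_linear_svm(red_train, droplevels(y[!test]), C)
      sc <- svm_scores(model, red_test)
      for (cls in model$classes) {
        pos <- y[test] == cls
        if (!any(pos) || all(pos)) next
        ra <- roc_auc(sc[, cls], pos)
        per_fold[[length(per_fold) + 1L]] <- data.frame(
          rep = rep_i, fold = fold_i, class = cls, auc = ra$auc,
          n_test = sum(test), stringsAsFactors = FALSE)
        rocs[[sprintf("r%02d_f%d_%s", rep_i, fold_i, cls)]] <- ra$roc
      }
    }
  }
  per_fold <- do.call(rbind, per_fold)
  summary <- do.call(rbind, lapply(split(per_fold, per_fold$class),
                                   function(d) data.frame(
                                     class = d$class[1],
                                     mean_auc = mean(d$auc),
                                     sd_auc = sd_or_zero(d$auc),
                                     n_folds = nrow(d),
                                     stringsAsFactors = FALSE)))
  summary <- summary[order(match(summary$class, levels(y))), ]
  rownames(summary) <- NULL
  structure(list(per_fold = per_fold, summary = summary, roc = rocs,
                 folds = fold_matrix,
                 config = list(folds = folds, repeats = repeats, k = k,
                               C = C, seed = seed,
                               paper_literal = paper_literal)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<cv_report> %d-fold CV x %d repeats, PCA k = %d, linear SVM C = %g%s\n",
              cfg$folds, cfg$repeats, cfg$k, cfg$C,
              if (isTRUE(cfg$paper_literal)) " (leaky whole-data PCA)" else ""))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-10s AUC %.3f +/- %.3f (%d fold evaluations)\n",
                x$summary$class[i], x$summary$mean_auc[i],
                x$summary$sd_auc[i], x$summary$n_folds[i]))
  }
  invisible(x)
}

#' Fit the severity model on a full feature table
#'
#' Convenience wrapper for deployment-style use outside cross-validation:
#' median imputation, standardization and PCA are fit on all provided
#' subjects, then the one-vs-rest linear SVM is trained. For performance
#' estimates use [repeated_stratified_cv()].
#'
#' @inheritParams repeated_stratified_cv
#' @return A `severity_model` object with a `predict` method.
#' @export
fit_severity_model <- function(x, y, k = 4, C = 1) {
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  imp <- fit_imputer(x)
  xi <- apply_imputer(x, imp)
  scaler <- fit_scaler(xi)
  pca <- pca_reduce(apply_scaler(xi, scaler), k)
  svm <- train_linear_svm(pca$scores, y, C)
  structure(list(imputer = imp, scaler = scaler, pca = pca, svm = svm),
            class = "severity_model")
}

#' @export
predict.severity_model <- function(object, newdata, type = c("class", "score"),
                                   ...) {
  type <- match.arg(type)
  x <- apply_imputer(as.matrix(newdata), object$imputer)
  red <- apply_scaler(x, object$scaler) %*% object$pca$loadings
  if (type == "score") return(svm_scores(object$svm, red))
  stats::predict(object$svm, red)
}
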