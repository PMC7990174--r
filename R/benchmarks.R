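#' Relative abundance feature matrix
#'
#' The standard feature representation for the comparison classifiers:
#' \eqn{q_{ij} = n_{ij} / N_i}. Row sums are at most 1 (totals may exceed
#' the row sums of the retained OTUs).
#'
#' @param x an [otu_table] with positive totals.
#' @return Numeric matrix, samples in rows.
#' @export
relative_abundance_features <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  if (any(x$totals <= 0)) stop("relative abundance undefined: zero sample total")
  sweep(x$counts, 1L, x$totals, "/")
}

#' Baseline classifier methods
#'
#' @return Character vector of supported baseline method names.
#' @export
baseline_methods <- function() {
  c("kmeans-euclidean", "kmeans-manhattan", "knn-euclidean", "knn-manhattan",
    "nsc", "rf", "gb", "lasso", "rr", "svm")
}

#' Run a baseline classifier on OTU tables
#'
#' Trains one of the comparison classifiers on the relative-abundance
#' features of the training table and predicts labels for the test table.
#' Distance-based baselines are k-means (nearest class feature centroid)
#' and k-NN under Euclidean or Manhattan distance, and the nearest
#' (shrunken) centroid classifier; machine-learning baselines wrap
#' established implementations (ranger random forest, xgboost gradient
#' boosting, glmnet LASSO/ridge, e1071 RBF SVM) with small CV-tuned
#' hyperparameter grids.
#'
#' @param method one of [baseline_methods()].
#' @param train labelled [otu_table].
#' @param test [otu_table] with the same OTUs.
#' @param seed integer seed; given the seed predictions are deterministic.
#' @param tuning optional list of per-method tuning overrides (see
#'   [ml_fit_predict()]).
#' @return Factor of predicted labels for the test samples.
#' @export
baseline_classify <- function(method, train, test, seed = NULL, tuning = list()) {
  method <- match.arg(method, baseline_methods())
  stopifnot(inherits(train, "otu_table"), inherits(test, "otu_table"))
  if (is.null(train$labels)) stop("training table must be labelled")
  xtr <- relative_abundance_features(train)
  xte <- relative_abundance_features(test)[, colnames(xtr), drop = FALSE]
  y <- train$labels
  if (method %in% c("kmeans-euclidean", "kmeans-manhattan")) {
    metric <- sub("kmeans-", "", method)
    centroid_predict(xtr, y, xte, metric)
  } else if (method %in% c("knn-euclidean", "knn-manhattan")) {
    metric <- sub("knn-", "", method)
    if (!is.null(seed)) set.seed(seed)
    k <- feature_knn_cv(xtr, y, metric)
    knn_from_distances(feature_dist(xte, xtr, metric), y, k)
  } else if (method == "nsc") {
    nsc_fit_predict(xtr, y, xte, shrinkage = tuning$nsc$shrinkage %||% 0)
  } else {
    ml_fit_predict(method, xtr, y, xte, seed = seed, tuning = tuning[[method]])
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

feature_dist <- function(A, B, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    M <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    M[M < 0] <- 0
    M
  } else {
    M <- matrix(0, nrow(A), nrow(B))
    for (j in seq_len(ncol(A)))
      M <- M + abs(outer(A[, j], B[, j], "-"))
    M
  }
}

centroid_predict <- function(xtr, y, xte, metric) {
  mu <- t(vapply(levels(y),
                 function(cl) colMeans(xtr[y == cl, , drop = FALSE]),
                 numeric(ncol(xtr))))
  D <- feature_dist(xte, mu, metric)
  factor(levels(y)[apply(D, 1L, which.min)], levels = levels(y))
}

# CV choice of k for the feature-space k-NN baselines
feature_knn_cv <- function(xtr, y, metric, grid = seq(1L, 15L, 2L), folds = 5) {
  fold <- stratified_folds(y, folds)
  acc <- numeric(length(grid))
  for (f in sort(unique(fold))) {
    test <- fold == f
    D <- feature_dist(xtr[test, , drop = FALSE], xtr[!test, , drop = FALSE],
                      metric)
    for (g in seq_along(grid))
      acc[g] <- acc[g] + sum(knn_from_distances(D, y[!test], grid[g]) == y[test])
  }
  as.integer(grid[which.max(acc)])
}

#' Nearest (shrunken) centroid classifier
#'
#' Class centroids are the per-class means of the relative-abundance
#' features; a test sample is assigned to the class minimizing the
#' standardized squared distance
#' \eqn{\sum_j (x_j - \bar x_{kj})^2 / s_j^2}, where \eqn{s_j} is the
#' pooled within-class standard deviation of feature j (floored at a small
#' positive constant). Optionally the centroids are soft-thresholded
#' towards the overall centroid by `shrinkage` standardized units
#' (`shrinkage = 0`, the default, is the plain nearest-centroid rule;
#' `"auto"` chooses the amount by 5-fold cross-validation).
#'
#' @param xtr training feature matrix.
#' @param y training labels (factor, at least 2 classes).
#' @param xte test feature matrix.
#' @param shrinkage non-negative soft-threshold amount, or `"auto"`.
#' @return Factor of predicted labels.
#' @export
nsc_fit_predict <- function(xtr, y, xte, shrinkage = 0) {
  y <- factor(y)
  if (nlevels(y) < 2L) stop("nsc needs at least 2 classes")
  if (identical(shrinkage, "auto")) {
    grid <- c(0, 0.5, 1, 2, 4, 8)
    fold <- stratified_folds(y, 5)
    acc <- numeric(length(grid))
    for (f in sort(unique(fold))) {
      te <- fold == f
      for (g in seq_along(grid))
        acc[g] <- acc[g] + sum(nsc_fit_predict(xtr[!te, , drop = FALSE], y[!te],
                                               xtr[te, , drop = FALSE],
                                               grid[g]) == y[te])
    }
    shrinkage <- grid[which.max(acc)]
  }
  mu <- t(vapply(levels(y),
                 function(cl) colMeans(xtr[y == cl, , drop = FALSE]),
                 numeric(ncol(xtr))))
  nk <- as.numeric(table(y)[levels(y)])
  resid <- xtr - mu[as.integer(y), , drop = FALSE]
  s <- sqrt(colSums(resid^2) / (length(y) - nlevels(y)))
  s0 <- max(1e-8, stats::median(s) * 1e-6)
  s <- pmax(s, s0)
  if (shrinkage > 0) {
    overall <- colMeans(xtr)
    mk <- sqrt(1 / nk - 1 / length(y))
    for (ki in seq_len(nrow(mu))) {
      d <- (mu[ki, ] - overall) / (mk[ki] * s)
      d <- sign(d) * pmax(0, abs(d) - shrinkage)
      mu[ki, ] <- overall + mk[ki] * s * d
    }
  }
  scaled_te <- sweep(xte, 2L, s, "/")
  scaled_mu <- sweep(mu, 2L, s, "/")
  D <- feature_dist(scaled_te, scaled_mu, "euclidean")
  factor(levels(y)[apply(D, 1L, which.min)], levels = levels(y))
}

#' Machine-learning baselines on feature matrices
#'
#' Thin, seeded wrappers around the established implementations: random
#' forest (`ranger`, 500 trees, mtry tuned by out-of-bag error over
#' \eqn{\{\sqrt J, J/3, J\}}), gradient boosting (`xgboost`, depth
#' \eqn{\{1,2,3\}} x learning rate \eqn{\{0.01, 0.1\}} with rounds chosen by
#' early-stopped CV), LASSO and ridge logistic regression (`cv.glmnet`,
#' 10-fold CV over the default logarithmic penalty path) and an RBF SVM
#' (`e1071`, cost and gamma on logarithmic grids by 5-fold CV). Grids can
#' be overridden through `tuning`.
#'
#' @param method `"rf"`, `"gb"`, `"lasso"`, `"rr"` or `"svm"`.
#' @param xtr,xte numeric feature matrices (train / test).
#' @param y training labels.
#' @param seed integer seed making the fit deterministic.
#' @param tuning optional list of grids: `mtry` (rf); `depth`, `eta`,
#'   `nrounds`, `nfold` (gb); `nfolds` (lasso/rr); `cost`, `gamma`,
#'   `folds` (svm).
#' @return Factor of predicted test labels.
#' @export
ml_fit_predict <- function(method, xtr, y, xte, seed = NULL, tuning = NULL) {
  method <- match.arg(method, c("rf", "gb", "lasso", "rr", "svm"))
  y <- factor(y)
  if (!is.null(seed)) set.seed(seed)
  J <- ncol(xtr)
  switch(method,
    rf = {
      mtry_grid <- tuning$mtry %||%
        unique(pmax(1L, c(floor(sqrt(J)), floor(J / 3), J)))
      df <- data.frame(.y = y, xtr, check.names = FALSE)
      fits <- lapply(mtry_grid, function(m)
        ranger::ranger(dependent.variable.name = ".y", data = df,
                       num.trees = 500, mtry = m,
                       seed = seed %||% 1L, num.threads = 1L))
      best <- fits[[which.min(vapply(fits, function(f) f$prediction.error, 0))]]
      pred <- ranger::predictions(stats::predict(
        best, data = data.frame(xte, check.names = FALSE), num.threads = 1L))
      factor(as.character(pred), levels = levels(y))
    },
    gb = {
      K <- nlevels(y)
      params_grid <- expand.grid(depth = tuning$depth %||% c(1L, 2L, 3L),
                                 eta = tuning$eta %||% c(0.01, 0.1))
      nrounds <- tuning$nrounds %||% 300L
      nfold <- tuning$nfold %||% 5L
      ytr <- as.integer(y) - 1L
      dtr <- xgboost::xgb.DMatrix(as.matrix(xtr), label = ytr)
      mkparams <- function(depth, eta) {
        if (K == 2L)
          xgboost::xgb.params(max_depth = depth, eta = eta, nthread = 1L,
                              objective = "binary:logistic",
                              eval_metric = "error")
        else
          xgboost::xgb.params(max_depth = depth, eta = eta, nthread = 1L,
                              objective = "multi:softmax", num_class = K,
                              eval_metric = "merror")
      }
      best <- NULL
      for (r in seq_len(nrow(params_grid))) {
        p <- mkparams(params_grid$depth[r], params_grid$eta[r])
        cv <- xgboost::xgb.cv(params = p, data = dtr, nrounds = nrounds,
                              nfold = nfold, early_stopping_rounds = 20L,
                              verbose = 0L)
        log <- cv$evaluation_log
        col <- grep("^test_.*_mean$", names(log), value = TRUE)[1L]
        err <- min(log[[col]])
        if (is.null(best) || err < best$err)
          best <- list(err = err, params = p, nrounds = which.min(log[[col]]))
      }
      fit <- xgboost::xgb.train(params = best$params, data = dtr,
                                nrounds = best$nrounds, verbose = 0L)
      pr <- stats::predict(fit, as.matrix(xte))
      idx <- if (K == 2L) as.integer(pr > 0.5) else as.integer(pr)
      factor(levels(y)[idx + 1L], levels = levels(y))
    },
    lasso = ,
    rr = {
      alpha <- if (method == "lasso") 1 else 0
      fam <- if (nlevels(y) == 2L) "binomial" else "multinomial"
      cv <- glmnet::cv.glmnet(as.matrix(xtr), y, family = fam, alpha = alpha,
                              nfolds = tuning$nfolds %||% 10L)
      pred <- stats::predict(cv, newx = as.matrix(xte), s = "lambda.min",
                             type = "class")
      factor(as.character(pred), levels = levels(y))
    },
    svm = {
      cost_grid <- tuning$cost %||% 10^(-1:2)
      gamma_grid <- tuning$gamma %||% (1 / J) * c(0.25, 1, 4)
      folds <- tuning$folds %||% 5
      fold <- stratified_folds(y, folds)
      best <- NULL
      for (cst in cost_grid) for (gam in gamma_grid) {
        correct <- 0
        for (f in sort(unique(fold))) {
          te <- fold == f
          fit <- e1071::svm(xtr[!te, , drop = FALSE], y[!te], cost = cst,
                            gamma = gam, kernel = "radial", scale = FALSE)
          correct <- correct +
            sum(stats::predict(fit, xtr[te, , drop = FALSE]) == y[te])
        }
        if (is.null(best) || correct > best$correct)
          best <- list(correct = correct, cost = cst, gamma = gam)
      }
      fit <- e1071::svm(xtr, y, cost = best$cost, gamma = best$gamma,
                        kernel = "radial", scale = FALSE)
      stats::predict(fit, xte)
    })
}
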