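#' Distance-based classification using mixture distributions
#'
#' Fits the full distributional representation of a labelled OTU table:
#' per-OTU zero-inflated Poisson-Gamma mixtures estimated by constrained
#' least squares with bootstrap model averaging ([fit_mixture()]), posterior
#' component weights for every training sample ([component_posterior()]),
#' and the Gram matrices of both squared-L2 distributional metrics. The
#' returned object classifies new samples with [predict.dcmd()] under
#' either metric (`"d-l2"`, the discrete pmf norm, or `"cc-l2"`, the
#' continuous cumulative CDF norm) and either classifier (`"kmeans"`:
#' nearest class-mean distribution; `"knn"`: mode of the k nearest
#' training samples) — the arguments here only set the defaults.
#'
#' All-zero OTUs carry no distributional information and are skipped with a
#' warning. Test-sample resolutions are computed against the training mean
#' depth, so nothing about the test set enters the fit.
#'
#' @param x a labelled [otu_table] (training data).
#' @param labels optional label vector overriding `x$labels`.
#' @param metric default distance metric for prediction.
#' @param classifier default classification rule.
#' @param k neighbour count for `"knn"`; `NULL` chooses k by
#'   cross-validation on the training set ([choose_k_cv()]) at first use.
#' @param B bootstrap iterations per OTU (default 100).
#' @param seed integer seed governing all bootstrap resampling (per-OTU
#'   seeds are derived deterministically).
#' @param n_models,quantile_p,n_high,extra_low,c_min,bootstrap_refit passed
#'   to [fit_mixture()].
#' @param quadrature_step trapezoid step for the cc-l2 Gram matrices.
#' @return An object of class `dcmd` with `print`, `summary`, `coef` and
#'   `predict` methods.
#' @examples
#' sim <- simulate_dataset(scenario_config(class_sizes = c(30, 30), J = 4,
#'                                         seed = 1))
#' tab <- filter_samples_by_depth(sim$table, 1)
#' fit <- dcmd(tab, B = 10, seed = 1)
#' table(predict(fit, tab), tab$labels)
#' @export
dcmd <- function(x, labels = NULL, metric = c("d-l2", "cc-l2"),
                 classifier = c("kmeans", "knn"), k = NULL,
                 B = 100, seed = NULL, n_models = 5, quantile_p = 0.85,
                 n_high = 12, extra_low = list(c(1, 2)), c_min = 8,
                 quadrature_step = 0.01,
                 bootstrap_refit = c("original", "resample")) {
  metric <- match.arg(metric)
  classifier <- match.arg(classifier)
  bootstrap_refit <- match.arg(bootstrap_refit)
  stopifnot(inherits(x, "otu_table"))
  if (is.null(labels)) labels <- x$labels
  if (is.null(labels)) stop("dcmd needs class labels")
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("dcmd needs at least 2 classes")
  if (any(table(labels) == 0L)) stop("empty class in the training labels")

  res <- compute_resolutions(x)
  mix <- fit_mixtures(x, resolutions = res, seed = seed, B = B,
                      n_models = n_models,
                      bootstrap_refit = bootstrap_refit,
                      quantile_p = quantile_p, n_high = n_high,
                      extra_low = extra_low, c_min = c_min)
  otus <- names(mix)

  train_w <- vector("list", length(otus))
  names(train_w) <- otus
  P <- gram_d <- gram_cc <- train_w
  for (id in otus) {
    train_w[[id]] <- component_posterior(x$counts[, id], res$t, mix[[id]])
    P[[id]] <- component_pmf_matrix(mix[[id]])
    gram_d[[id]] <- d_l2_gram(P[[id]])
    gram_cc[[id]] <- cc_l2_gram(mix[[id]]$components, quadrature_step)
  }

  class_means <- lapply(train_w, function(W) {
    t(vapply(levels(labels),
             function(cl) colMeans(W[labels == cl, , drop = FALSE]),
             numeric(ncol(W))))
  })

  obj <- structure(
    list(mixtures = mix, otus = otus, labels = labels,
         train_w = train_w, class_means = class_means, P = P,
         gram = list(`d-l2` = gram_d, `cc-l2` = gram_cc),
         nbar = res$nbar, train_ids = rownames(x$counts),
         settings = list(metric = metric, classifier = classifier, k = k,
                         B = B, seed = seed, n_models = n_models,
                         quantile_p = quantile_p, n_high = n_high,
                         c_min = c_min, quadrature_step = quadrature_step,
                         bootstrap_refit = bootstrap_refit),
         call = match.call()),
    class = "dcmd")
  if (classifier == "knn" && is.null(k))
    obj$settings$k <- choose_k_cv(obj, metric = metric,
                                  seed = if (is.null(seed)) 1L else seed)
  obj
}

# posterior weight matrices for a new table, per OTU, using the training
# mean depth to place new samples on the training resolution scale
new_sample_weights <- function(object, newdata) {
  stopifnot(inherits(newdata, "otu_table"))
  if (!all(object$otus %in% colnames(newdata$counts)))
    stop("newdata is missing fitted OTUs")
  t_new <- newdata$totals / object$nbar
  if (any(t_new <= 0)) stop("new samples must have positive totals")
  lapply(stats::setNames(object$otus, object$otus), function(id)
    component_posterior(newdata$counts[, id], t_new, object$mixtures[[id]]))
}

#' Predict class labels for new samples
#'
#' Classifies new samples by their distributional distance to the training
#' data: each new count is converted into posterior component weights under
#' the OTU's fitted mixture (at the sample's own resolution), and total
#' distances (summed over OTUs) are computed in weight space via the
#' metric's Gram matrix.
#'
#' @param object a fitted [dcmd] model.
#' @param newdata an [otu_table] containing the fitted OTUs.
#' @param metric,classifier,k override the defaults stored in the fit.
#' @param type `"class"` for a factor of predicted labels, `"distance"`
#'   for the matrix of total distances (samples x classes for `"kmeans"`,
#'   samples x training samples for `"knn"`).
#' @param ... unused.
#' @return Factor of predicted labels (or a distance matrix).
#' @export
predict.dcmd <- function(object, newdata, metric = NULL, classifier = NULL,
                         k = NULL, type = c("class", "distance"), ...) {
  type <- match.arg(type)
  metric <- if (is.null(metric)) object$settings$metric else
    match.arg(metric, c("d-l2", "cc-l2"))
  classifier <- if (is.null(classifier)) object$settings$classifier else
    match.arg(classifier, c("kmeans", "knn"))
  W_new <- new_sample_weights(object, newdata)
  grams <- object$gram[[metric]]
  lv <- levels(object$labels)

  if (classifier == "kmeans") {
    D <- matrix(0, nrow(newdata$counts), length(lv),
                dimnames = list(rownames(newdata$counts), lv))
    for (id in object$otus) {
      G <- grams[[id]]
      mu <- object$class_means[[id]]
      for (ki in seq_along(lv))
        D[, ki] <- D[, ki] + quadform_rows(W_new[[id]], mu[ki, ], G)
    }
    if (type == "distance") return(D)
    # ties resolve to the lowest class index
    return(factor(lv[apply(D, 1L, which.min)], levels = lv))
  }

  # knn
  D <- 0
  for (id in object$otus)
    D <- D + cross_quadform(W_new[[id]], object$train_w[[id]], grams[[id]])
  dimnames(D) <- list(rownames(newdata$counts), object$train_ids)
  if (type == "distance") return(D)
  if (is.null(k)) k <- object$settings$k
  if (is.null(k))
    k <- choose_k_cv(object, metric = metric,
                     seed = if (is.null(object$settings$seed)) 1L
                            else object$settings$seed)
  knn_from_distances(D, object$labels, k)
}

# mode of the k nearest labels; a tied label-mode resolves to the label of
# the nearest neighbour among the tied classes
knn_from_distances <- function(D, labels, k) {
  lv <- levels(labels)
  k <- min(k, ncol(D))
  pred <- character(nrow(D))
  for (i in seq_len(nrow(D))) {
    ord <- order(D[i, ])[seq_len(k)]
    tab <- table(labels[ord])
    top <- names(tab)[tab == max(tab)]
    pred[i] <- if (length(top) == 1L) top else {
      first <- as.character(labels[ord])
      first[first %in% top][1L]
    }
  }
  factor(pred, levels = lv)
}

#' Choose the k-NN neighbour count by cross-validation
#'
#' Stratified `folds`-fold cross-validation on the training samples of a
#' fitted [dcmd] model, over a grid of odd k; returns the k with the
#' highest CV accuracy (ties resolve to the smallest k).
#'
#' @param object a fitted [dcmd] model.
#' @param metric distance metric (default: the fit's).
#' @param grid candidate k values (default odd 1..15).
#' @param folds number of CV folds (default 5).
#' @param seed seed for the fold assignment.
#' @return The selected k (integer).
#' @export
choose_k_cv <- function(object, metric = NULL, grid = seq(1L, 15L, 2L),
                        folds = 5, seed = NULL) {
  stopifnot(inherits(object, "dcmd"), length(grid) >= 1)
  metric <- if (is.null(metric)) object$settings$metric else
    match.arg(metric, c("d-l2", "cc-l2"))
  labels <- object$labels
  if (!is.null(seed)) set.seed(seed)
  fold <- stratified_folds(labels, folds)
  grams <- object$gram[[metric]]
  acc <- stats::setNames(numeric(length(grid)), grid)
  for (f in sort(unique(fold))) {
    test <- fold == f
    D <- 0
    for (id in object$otus)
      D <- D + cross_quadform(object$train_w[[id]][test, , drop = FALSE],
                              object$train_w[[id]][!test, , drop = FALSE],
                              grams[[id]])
    for (g in seq_along(grid)) {
      pred <- knn_from_distances(D, labels[!test], grid[g])
      acc[g] <- acc[g] + sum(pred == labels[test])
    }
  }
  as.integer(grid[which.max(acc)]) # first max = smallest k on ties
}

# fold ids balanced within each class
stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' @export
print.dcmd <- function(x, ...) {
  cat("dcmd model\n")
  cat(sprintf("  %d OTUs, %d training samples, %d classes (%s)\n",
              length(x$otus), length(x$labels), nlevels(x$labels),
              paste(levels(x$labels), collapse = ", ")))
  cat(sprintf("  default metric: %s, classifier: %s", x$settings$metric,
              x$settings$classifier))
  if (!is.null(x$settings$k)) cat(sprintf(" (k = %d)", x$settings$k))
  cat(sprintf("\n  bootstrap: B = %d, %d nested models\n",
              x$settings$B, x$settings$n_models))
  invisible(x)
}

#' @export
summary.dcmd <- function(object, ...) {
  zw <- vapply(object$mixtures, function(m)
    if (m$components$has_zero_mass) m$w[1L] else 0, 0)
  Cs <- vapply(object$mixtures, function(m) m$components$C, 0L)
  obj <- vapply(object$mixtures, function(m) m$objective, 0)
  out <- list(model = object,
              per_otu = data.frame(otu_id = object$otus, C = Cs,
                                   structural_zero_weight = zw,
                                   objective = obj, row.names = NULL))
  class(out) <- "summary.dcmd"
  out
}

#' @export
print.summary.dcmd <- function(x, ...) {
  print(x$model)
  cat("\nPer-OTU mixture fits:\n")
  df <- x$per_otu
  df$structural_zero_weight <- round(df$structural_zero_weight, 3)
  df$objective <- signif(df$objective, 3)
  print(utils::head(df, 15), row.names = FALSE)
  if (nrow(df) > 15) cat(sprintf("  ... and %d more OTUs\n", nrow(df) - 15))
  invisible(x)
}

#' Extract fitted mixture weights
#'
#' @param object a fitted [dcmd] model.
#' @param ... unused.
#' @return Long data.frame: one row per OTU and mixture component, with the
#'   component parameters and its joint bootstrap-averaged weight.
#' @export
coef.dcmd <- function(object, ...) {
  do.call(rbind, lapply(object$otus, function(id) {
    m <- object$mixtures[[id]]
    data.frame(otu_id = id, component = component_names(m$components),
               weight = unname(m$w), row.names = NULL)
  }))
}

#' Diagnostic plot of a fitted mixture
#'
#' Observed versus model-expected aggregate count frequencies for one OTU.
#'
#' @param x a `dcmd_mixture`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.dcmd_mixture <- function(x, ...) {
  h <- rbind(observed = x$y, expected = x$expected)
  graphics::barplot(h, beside = TRUE, legend.text = rownames(h),
                    xlab = "count category", ylab = "samples", ...)
  invisible(x)
}
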