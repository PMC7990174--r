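#' All classifier method names
#'
#' The four distributional-distance variants (`dcmd-<classifier>-<metric>`)
#' plus the baseline methods of [baseline_methods()].
#'
#' @return Character vector of method names.
#' @export
all_methods <- function() {
  c("dcmd-kmeans-d-l2", "dcmd-kmeans-cc-l2", "dcmd-knn-d-l2",
    "dcmd-knn-cc-l2", baseline_methods())
}

dcmd_variant <- function(method) {
  m <- regmatches(method, regexec("^dcmd-(kmeans|knn)-(d-l2|cc-l2)$", method))[[1L]]
  if (!length(m)) return(NULL)
  list(classifier = m[2L], metric = m[3L])
}

#' Stratified train/test split
#'
#' Splits a labelled table into training and test sets, stratified by
#' class so the split proportion holds within every class.
#'
#' @param x a labelled [otu_table].
#' @param prop training proportion (default 0.6).
#' @param seed optional seed.
#' @return List with `train` and `test` [otu_table]s.
#' @export
train_test_split <- function(x, prop = 0.6, seed = NULL) {
  stopifnot(inherits(x, "otu_table"), prop > 0, prop < 1)
  if (is.null(x$labels)) stop("split requires labels")
  if (!is.null(seed)) set.seed(seed)
  test_idx <- integer(0)
  for (cl in levels(x$labels)) {
    idx <- which(x$labels == cl)
    n_test <- round((1 - prop) * length(idx))
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  list(train = x[setdiff(seq_len(nrow(x$counts)), test_idx), ],
       test = x[sort(test_idx), ])
}

# run every requested method on one train/test split; the dcmd
# representation is fitted once and shared by all four variants
classify_split <- function(methods, train, test, B = 100, seed = NULL,
                           tuning = list(), k = NULL) {
  preds <- list()
  variants <- Filter(Negate(is.null), lapply(methods, dcmd_variant))
  if (length(variants)) {
    fit <- dcmd(train, B = B, seed = seed, k = k)
    for (m in methods) {
      v <- dcmd_variant(m)
      if (!is.null(v))
        preds[[m]] <- predict(fit, test, metric = v$metric,
                              classifier = v$classifier)
    }
  }
  for (m in setdiff(methods, names(preds)))
    preds[[m]] <- baseline_classify(m, train, test,
                                    seed = if (is.null(seed)) NULL
                                           else derive_seed(seed, match(m, all_methods())),
                                    tuning = tuning)
  preds
}

#' Run one simulation replicate
#'
#' Generates a dataset under `config`, splits it 60/40 (stratified), runs
#' the requested classifiers on the shared split, and scores them on the
#' test set. Mixture fitting, k selection and all tuning only ever see the
#' training portion.
#'
#' @param config a [scenario_config()].
#' @param methods classifier names from [all_methods()].
#' @param seed integer seed; the replicate is a deterministic function of
#'   config, methods and seed.
#' @param B bootstrap iterations for the mixture fits.
#' @param train_prop training proportion (default 0.6).
#' @param null_permute if `TRUE`, class labels are permuted after
#'   generation (the chance-level null).
#' @param tuning optional per-method tuning overrides.
#' @param positive positive class for binary metrics (default: second
#'   level).
#' @return data.frame with one row per method: accuracy, precision,
#'   recall, f1.
#' @export
run_replicate <- function(config, methods = c("dcmd-kmeans-d-l2", "dcmd-kmeans-cc-l2"),
                          seed = 1, B = 100, train_prop = 0.6,
                          null_permute = FALSE, tuning = list(),
                          positive = NULL) {
  methods <- match.arg(methods, all_methods(), several.ok = TRUE)
  sim <- simulate_dataset(config, seed = derive_seed(seed, 1L))
  # zero-depth samples carry no information and leave the resolution
  # t_i = N_i / Nbar undefined; drop them, as a minimal depth filter would
  tab <- filter_samples_by_depth(sim$table, 1L)
  if (null_permute) tab <- permute_null(tab, seed = derive_seed(seed, 2L))
  split <- train_test_split(tab, prop = train_prop,
                            seed = derive_seed(seed, 3L))
  preds <- classify_split(methods, split$train, split$test, B = B,
                          seed = derive_seed(seed, 4L), tuning = tuning)
  do.call(rbind, lapply(methods, function(m) {
    rep <- evaluate(split$test$labels, preds[[m]], positive = positive)
    data.frame(method = m, accuracy = rep$accuracy,
               precision = rep$precision %||% NA_real_,
               recall = rep$recall %||% NA_real_,
               f1 = rep$f1 %||% NA_real_)
  }))
}

#' Run a simulation study
#'
#' Repeats [run_replicate()] over independent replicates (replicate r uses
#' a seed derived from `seed` and r) and collects the per-replicate
#' metrics.
#'
#' @param config a [scenario_config()].
#' @param replicates number of replicates.
#' @param methods,B,train_prop,null_permute,tuning,positive passed to
#'   [run_replicate()].
#' @param seed master seed.
#' @param scenario optional scenario name recorded in the results.
#' @return An object of class `dcmd_study`: data.frame with columns
#'   scenario, replicate, method, accuracy, precision, recall, f1.
#' @export
run_simulation_study <- function(config, replicates = 20,
                                 methods = c("dcmd-kmeans-d-l2", "dcmd-kmeans-cc-l2"),
                                 B = 100, seed = 1, train_prop = 0.6,
                                 null_permute = FALSE, tuning = list(),
                                 positive = NULL, scenario = NA_character_) {
  out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    res <- run_replicate(config, methods, seed = derive_seed(seed, 101L + r),
                         B = B, train_prop = train_prop,
                         null_permute = null_permute, tuning = tuning,
                         positive = positive)
    cbind(scenario = scenario, replicate = r, res)
  }))
  class(out) <- c("dcmd_study", "data.frame")
  out
}

#' @export
summary.dcmd_study <- function(object, ...) {
  ag <- function(v) c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  sp <- split(seq_len(nrow(object)), object$method)
  out <- do.call(rbind, lapply(names(sp), function(m) {
    i <- sp[[m]]
    a <- ag(object$accuracy[i])
    f <- ag(object$f1[i])
    data.frame(method = m, replicates = length(i),
               mean_accuracy = a["mean"], sd_accuracy = a["sd"],
               mean_f1 = f["mean"], sd_f1 = f["sd"], row.names = NULL)
  }))
  out[order(-out$mean_accuracy), ]
}

#' Boxplot of per-replicate accuracy by method
#'
#' @param x a `dcmd_study`.
#' @param metric column to plot (default accuracy).
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.dcmd_study <- function(x, metric = "accuracy", ...) {
  graphics::boxplot(x[[metric]] ~ x$method, xlab = "", ylab = metric,
                    las = 2, ...)
  invisible(x)
}

#' Write study results as a tidy TSV
#'
#' @param study a `dcmd_study`.
#' @param path output file path.
#' @export
write_study_results <- function(study, path) {
  utils::write.table(study, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-validated evaluation on one dataset
#'
#' Stratified k-fold cross-validation of the requested classifiers on a
#' labelled table. Inside every fold, mixture estimation, hyperparameter
#' tuning and (optionally) OTU screening are redone on the training folds
#' only; out-of-fold predictions are pooled and scored once per method.
#'
#' @param x a labelled [otu_table].
#' @param methods classifier names from [all_methods()].
#' @param folds number of folds (default 10); `folds = nrow(x)` gives
#'   leave-one-out.
#' @param B bootstrap iterations for mixture fits.
#' @param seed integer seed (fold assignment and all fits).
#' @param screen if `TRUE`, distance-based methods use only the OTUs
#'   retained by [screen_otus()] on each training fold (machine-learning
#'   baselines always see all OTUs).
#' @param alpha_q screening q-value threshold.
#' @param pair_ids optional grouping vector; samples sharing a pair id are
#'   assigned to the same fold.
#' @param tuning,positive passed through.
#' @return Named list of `prediction_report`s, one per method, plus a
#'   `folds` attribute with the fold assignment.
#' @export
cv_evaluate <- function(x, methods = "dcmd-kmeans-d-l2", folds = 10, B = 100,
                        seed = 1, screen = FALSE, alpha_q = 0.05,
                        pair_ids = NULL, tuning = list(), positive = NULL) {
  stopifnot(inherits(x, "otu_table"))
  methods <- match.arg(methods, all_methods(), several.ok = TRUE)
  if (is.null(x$labels)) stop("cv_evaluate requires labels")
  I <- nrow(x$counts)
  set.seed(seed)
  if (is.null(pair_ids)) {
    fold <- stratified_folds(x$labels, folds)
  } else {
    stopifnot(length(pair_ids) == I)
    groups <- unique(pair_ids)
    gf <- sample(rep_len(seq_len(folds), length(groups)))
    fold <- gf[match(pair_ids, groups)]
  }
  # every training fold must contain every class; refold if not
  tries <- 0L
  while (is.null(pair_ids) &&
         any(vapply(seq_len(folds), function(f)
           nlevels(droplevels(x$labels[fold != f])) < nlevels(x$labels),
           TRUE))) {
    tries <- tries + 1L
    if (tries > 20L) stop("could not stratify folds with every class present")
    fold <- stratified_folds(x$labels, folds)
  }

  pred <- matrix(NA_character_, I, length(methods),
                 dimnames = list(rownames(x$counts), methods))
  dist_based <- c(grep("^dcmd-", methods, value = TRUE),
                  intersect(methods, c("kmeans-euclidean", "kmeans-manhattan",
                                       "knn-euclidean", "knn-manhattan", "nsc")))
  for (f in sort(unique(fold))) {
    tr <- x[which(fold != f), ]
    te <- x[which(fold == f), ]
    fold_seed <- derive_seed(seed, 1000L + f)
    tr_dist <- tr
    te_dist <- te
    if (screen && length(dist_based)) {
      keep <- screen_otus(tr, alpha_q = alpha_q)$retained
      if (length(keep)) {
        tr_dist <- tr[, match(keep, colnames(tr$counts))]
        te_dist <- te[, match(keep, colnames(te$counts))]
      }
    }
    p1 <- classify_split(intersect(methods, dist_based), tr_dist, te_dist,
                         B = B, seed = fold_seed, tuning = tuning)
    p2 <- classify_split(setdiff(methods, dist_based), tr, te,
                         B = B, seed = fold_seed, tuning = tuning)
    for (m in names(p1)) pred[fold == f, m] <- as.character(p1[[m]])
    for (m in names(p2)) pred[fold == f, m] <- as.character(p2[[m]])
  }
  out <- lapply(stats::setNames(methods, methods), function(m)
    evaluate(x$labels, factor(pred[, m], levels = levels(x$labels)),
             positive = positive))
  attr(out, "folds") <- fold
  out
}
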