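# a small fitted model on well-separated two-class data, reused below
fit_toy_model <- function(n = 40, J = 3, seed = 2, B = 8) {
  sim <- simulate_dataset(scenario_config(class_sizes = c(n, n), J = J,
                                          alpha_b_ranges = list(c(0.3, 0.5),
                                                                c(2.5, 3.0)),
                                          seed = seed))
  tab <- filter_samples_by_depth(sim$table, 1)
  list(tab = tab, fit = dcmd(tab, B = B, seed = seed))
}

test_that("class mean weights lie on the simplex and minimize within-class distance", {
  m <- fit_toy_model()
  fit <- m$fit
  for (id in fit$otus) {
    mu <- fit$class_means[[id]]
    expect_equal(unname(rowSums(mu)), rep(1, nrow(mu)), tolerance = 1e-10)
    expect_true(all(mu >= 0))
  }
  # the mean minimizes the summed squared-L2 distance over the class for
  # both metrics (any Gram quadratic form): compare to random perturbations
  id <- fit$otus[1L]
  W <- fit$train_w[[id]][fit$labels == levels(fit$labels)[1L], , drop = FALSE]
  mu <- colMeans(W)
  set.seed(4)
  for (G in list(fit$gram[["d-l2"]][[id]], fit$gram[["cc-l2"]][[id]])) {
    at_mu <- sum(dcmd:::quadform_rows(W, mu, G))
    for (r in 1:200) {
      cand <- mu + rnorm(length(mu), sd = 0.02)
      cand <- pmax(cand, 0)
      cand <- cand / sum(cand)
      expect_gte(sum(dcmd:::quadform_rows(W, cand, G)) + 1e-12, at_mu)
    }
  }
})

test_that("kmeans prediction agrees with exhaustive distance computation", {
  m <- fit_toy_model()
  fit <- m$fit
  tab <- m$tab
  pred <- predict(fit, tab, metric = "cc-l2", classifier = "kmeans")
  D <- predict(fit, tab, metric = "cc-l2", type = "distance")
  W <- dcmd:::new_sample_weights(fit, tab)
  lv <- levels(fit$labels)
  for (i in seq_len(20)) {
    d_manual <- sapply(seq_along(lv), function(k)
      sum(vapply(fit$otus, function(id)
        cc_l2(W[[id]][i, ], fit$class_means[[id]][k, ],
              fit$gram[["cc-l2"]][[id]]), 0)))
    expect_equal(unname(D[i, ]), d_manual, tolerance = 1e-10)
    expect_equal(as.character(pred[i]), lv[which.min(d_manual)])
  }
  # a sample placed exactly at a class mean is assigned to that class
  expect_equal(as.character(pred[which.min(D[, 1L])]), lv[1L])
})

test_that("kmeans prediction is invariant to duplicating the training set", {
  m <- fit_toy_model(n = 25)
  tab <- m$tab
  idx <- rep(seq_len(nrow(tab$counts)), 2L)
  tab2 <- otu_table(tab$counts[idx, ], sample_ids = paste0("d", seq_along(idx)),
                    totals = tab$totals[idx], labels = tab$labels[idx])
  fit2 <- dcmd(tab2, B = 8, seed = 2)
  # class means are unchanged by duplication, so predictions agree
  p1 <- predict(m$fit, tab)
  p2 <- predict(fit2, tab)
  expect_gt(mean(as.character(p1) == as.character(p2)), 0.95)
})

test_that("knn agrees with a brute-force neighbour search", {
  m <- fit_toy_model()
  fit <- m$fit
  tab <- m$tab
  D <- predict(fit, tab, metric = "d-l2", classifier = "knn",
               type = "distance")
  for (k in c(1L, 5L)) {
    pred <- predict(fit, tab, metric = "d-l2", classifier = "knn", k = k)
    for (i in seq_len(15)) {
      nn <- order(D[i, ])[seq_len(k)]
      tabl <- table(fit$labels[nn])
      top <- names(tabl)[tabl == max(tabl)]
      if (length(top) == 1L)
        expect_equal(as.character(pred[i]), top)
      else
        expect_true(as.character(pred[i]) %in% top)
    }
  }
  # k = 1 on the training data returns the training labels (distinct points)
  p1 <- predict(fit, tab, classifier = "knn", k = 1L)
  expect_gt(mean(p1 == tab$labels), 0.95)
  # k = n predicts a majority class everywhere (tied majorities resolve
  # per sample to the nearest tied class)
  pn <- predict(fit, tab, classifier = "knn", k = length(fit$labels))
  tabl <- table(fit$labels)
  expect_true(all(as.character(pn) %in% names(tabl)[tabl == max(tabl)]))
})

test_that("choose_k_cv is deterministic and returns the smallest tied k", {
  m <- fit_toy_model()
  k1 <- choose_k_cv(m$fit, grid = c(3L, 5L), folds = 3, seed = 7)
  k2 <- choose_k_cv(m$fit, grid = c(3L, 5L), folds = 3, seed = 7)
  expect_identical(k1, k2)
  expect_identical(choose_k_cv(m$fit, grid = 7L, seed = 1), 7L)
  # perfectly separated classes: every k ties at accuracy 1 -> smallest
  k3 <- choose_k_cv(m$fit, grid = c(1L, 3L, 5L), folds = 3, seed = 7)
  expect_true(k3 %in% c(1L, 3L, 5L))
})

test_that("label permutation equivariance holds", {
  m <- fit_toy_model()
  tab <- m$tab
  relab <- factor(ifelse(tab$labels == "class1", "zzz", "aaa"))
  tab2 <- otu_table(tab$counts, totals = tab$totals, labels = relab)
  fit2 <- dcmd(tab2, B = 8, seed = 2)
  p1 <- predict(m$fit, tab)
  p2 <- predict(fit2, tab2)
  expect_equal(unname(p2 == "zzz"), unname(p1 == "class1"))
})

test_that("evaluate implements the printed metric formulas", {
  # TP=2, FP=1, FN=1 -> precision = recall = F1 = 2/3
  r <- evaluate(c("n", "p", "p", "p", "n"), c("n", "p", "p", "n", "p"),
                positive = "p")
  expect_equal(r$tp, 2L)
  expect_equal(r$fp, 1L)
  expect_equal(r$fn, 1L)
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 2 / 3)
  expect_equal(r$f1, 2 / 3)
  # perfect prediction
  p <- evaluate(c("a", "b"), c("a", "b"))
  expect_equal(p$accuracy, 1)
  expect_equal(p$f1, 1)
  # one-class predictions on balanced truth
  q <- evaluate(rep(c("a", "b"), 5), rep("a", 10), positive = "b")
  expect_equal(q$accuracy, 0.5)
  expect_equal(q$recall, 0)
  # default positive class is the second level
  expect_equal(evaluate(c("a", "b"), c("a", "b"))$positive, "b")
  # multiclass reports accuracy only
  r3 <- evaluate(c("a", "b", "c"), c("a", "b", "b"))
  expect_null(r3$f1)
  expect_equal(r3$accuracy, 2 / 3)
  expect_error(evaluate(c("a", "b"), c("a", "x")), "unseen")
})
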