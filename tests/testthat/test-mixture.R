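test_that("aggregate counts tabulate onto the category axis", {
  y <- aggregate_counts(c(0, 0, 1, 3, 9, 12), C = 8)
  expect_equal(sum(y), 6)
  expect_equal(unname(y[c("0", "1", "3", "C+")]), c(2, 1, 1, 2))
  expect_named(y, c(as.character(0:8), "C+"))
})

test_that("expected aggregate conserves mass and honours point masses", {
  cs <- toy_components(alpha = c(1, 5), beta = c(1, 1), C = 8)
  t <- rep(1, 100)
  # all weight on the zero mass -> everything lands in category 0
  ye <- expected_aggregate(cs, c(1, 0, 0, 0), t)
  expect_equal(unname(ye["0"]), 100)
  expect_equal(sum(ye), 100)
  # single Gamma(1,1) at t=1: geometric, y^E_0 = I/2
  ye2 <- expected_aggregate(cs, c(0, 1, 0, 0), t)
  expect_equal(unname(ye2["0"]), 50)
  expect_equal(unname(ye2["1"]), 25)
  # conservation for random simplex weights at heterogeneous resolutions
  set.seed(3)
  t2 <- runif(50, 0.5, 2)
  for (i in 1:5) {
    w <- as.numeric(runif_simplex(1, 4))
    expect_equal(sum(expected_aggregate(cs, w, t2)), 50, tolerance = 1e-10)
  }
  expect_error(expected_aggregate(cs, c(1, 0), t), "length")
})

test_that("weight fitting recovers exact mixtures and matches the grid oracle", {
  cs <- toy_components(alpha = c(1, 5), beta = c(1, 1), C = 8,
                       has_zero = TRUE)
  t <- rep(1, 400)
  # data laid out exactly as I * pmf of Gamma(5,1) -> that weight -> 1
  p5 <- c(dnbinom(0:8, size = 5, prob = 0.5),
          pnbinom(8, size = 5, prob = 0.5, lower.tail = FALSE))
  counts <- rep(c(0:8, 9), round(400 * p5))
  fit <- fit_weights(cs, counts, rep(1, length(counts)))
  expect_gt(fit$w[["G(5,1)"]], 0.97)
  expect_equal(sum(fit$w), 1, tolerance = 1e-8)

  # brute-force simplex grid oracle on 3-component problems
  set.seed(11)
  for (rep in 1:4) {
    counts <- c(rpois(60, 1), rpois(40, 6))
    y <- aggregate_counts(counts, cs$C)
    arr <- dcmd:::component_prob_array(cs, rep(1, 100))
    A <- 100 * rowMeans(arr, dims = 2L)
    sub <- c(1, 2, 3) # z, Gamma(1,1), Gamma(5,1)
    fit <- dcmd:::simplex_lsq_cpp(A[, sub], y)
    best <- Inf
    for (w1 in seq(0, 1, by = 0.001)) for (w2 in seq(0, 1 - w1, by = 0.025)) {
      o <- sum((y - A[, sub] %*% c(w1, w2, 1 - w1 - w2))^2)
      if (o < best) best <- o
    }
    expect_lte(fit$objective, best + 1e-6)
    # never worse than the uniform-weight start
    expect_lte(fit$objective,
               sum((y - A[, sub] %*% rep(1 / 3, 3))^2) + 1e-9)
  }
})

test_that("structural-zero weight is recovered from zero-inflated data", {
  set.seed(5)
  n <- 2000
  z <- runif(n) < 0.3
  counts <- ifelse(z, 0L, rpois(n, rgamma(n, 5, 1)))
  fit <- fit_weights(specify_components(counts), counts, rep(1, n))
  expect_lt(abs(fit$w[["z"]] - 0.3), 0.05)
})

test_that("bootstrap model averaging returns coherent probabilities", {
  set.seed(9)
  counts <- c(rpois(150, 1.5), rpois(50, 10))
  t <- runif(200, 0.8, 1.2)
  m <- fit_mixture(counts, t, B = 30, seed = 4)
  expect_equal(sum(m$model_probs), 1)
  expect_equal(sum(m$w), 1, tolerance = 1e-8)
  expect_true(all(m$w >= 0))
  # joint weights are the v-weighted candidate average
  expect_equal(unname(m$w),
               unname(as.numeric(crossprod(m$per_model_w, m$model_probs))),
               tolerance = 1e-12)
  for (l in seq_len(nrow(m$per_model_w)))
    expect_equal(sum(m$per_model_w[l, ]), 1, tolerance = 1e-8)
  # a single candidate gets probability one and the plain fit
  m1 <- fit_mixture(counts, t, B = 10, n_models = 1, seed = 4)
  expect_equal(m1$model_probs, 1)
  f1 <- fit_weights(m1$components, counts, t)
  expect_equal(unname(m1$w), unname(f1$w), tolerance = 1e-10)
})

test_that("model probabilities respect which low-rate structure the data need", {
  set.seed(21)
  n <- 1500
  # data with substantial Gamma(1,2)-like near-zero mass: only the full
  # model carries that component, so it should win most resamples
  grp <- sample(3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  counts <- integer(n)
  counts[grp == 1] <- rpois(sum(grp == 1), rgamma(sum(grp == 1), 1, 2))
  counts[grp == 2] <- rpois(sum(grp == 2), rgamma(sum(grp == 2), 4, 1))
  counts[grp == 3] <- rpois(sum(grp == 3), rgamma(sum(grp == 3), 12, 1))
  m1 <- fit_mixture(counts, rep(1, n), B = 200, seed = 31)
  expect_gt(m1$model_probs[1L], 0.5)
  # data whose low counts need Gamma(2,1): the heavily pruned candidates
  # (which drop it) should almost never be selected
  counts2 <- integer(n)
  counts2[grp != 1] <- rpois(sum(grp != 1), rgamma(sum(grp != 1), 2, 1))
  counts2[grp == 1] <- rpois(sum(grp == 1), rgamma(sum(grp == 1), 9, 1))
  m2 <- fit_mixture(counts2, rep(1, n), B = 200, seed = 32)
  expect_lt(sum(m2$model_probs[4:5]), 0.2)
})

test_that("fits are invariant to rescaling all totals", {
  set.seed(13)
  counts <- rpois(120, 3)
  tot <- runif(120, 500, 2000)
  m1 <- fit_mixture(counts, compute_resolutions(tot), B = 20, seed = 2)
  m2 <- fit_mixture(counts, compute_resolutions(tot * 9), B = 20, seed = 2)
  expect_equal(m1$w, m2$w, tolerance = 1e-12)
})

test_that("fitted mixtures round-trip exactly through JSON", {
  set.seed(17)
  counts <- c(rpois(80, 2), rpois(20, 15))
  m <- fit_mixture(counts, rep(1, 100), B = 15, seed = 6)
  js <- mixture_to_json(m)
  m2 <- mixture_from_json(js)
  expect_identical(m$w, m2$w)
  expect_identical(m$per_model_w, m2$per_model_w)
  expect_identical(m$model_probs, m2$model_probs)
  expect_identical(m$objective, m2$objective)
  expect_identical(m$components$alpha, m2$components$alpha)
  expect_identical(m$components$C, m2$components$C)
  f <- tempfile(fileext = ".json")
  mixture_to_json(m, f)
  expect_identical(mixture_from_json(f)$w, m$w)
})

test_that("identical seeds give identical fits", {
  counts <- c(rpois(100, 2), rpois(30, 9))
  set.seed(99) # irrelevant outer state
  m1 <- fit_mixture(counts, rep(1, 130), B = 25, seed = 8)
  runif(3)
  m2 <- fit_mixture(counts, rep(1, 130), B = 25, seed = 8)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$model_probs, m2$model_probs)
})
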