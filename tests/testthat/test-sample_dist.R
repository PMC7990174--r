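test_that("posterior weights follow the hand computation", {
  # n=0 under 0.5 zero-mass + 0.5 Gamma(1,1), t=1:
  # p_z = 0.5, p_1 = 0.5 * 0.5 = 0.25 -> w_z = 2/3
  cs <- toy_components(alpha = 1, beta = 1, C = 8, has_high = TRUE)
  m <- toy_mixture(c(0.5, 0.5, 0), cs)
  w <- component_posterior(0, 1, m)
  expect_equal(unname(w[1, ]), c(2 / 3, 1 / 3, 0))

  # single Gamma component: posterior is 1 for any count
  m2 <- toy_mixture(c(0, 1, 0), cs)
  expect_equal(unname(component_posterior(c(0, 3, 20), 1, m2)[, 2]),
               c(1, 1, 1))

  # pure high mass and a count above C
  m3 <- toy_mixture(c(0, 0, 1), cs)
  expect_equal(unname(component_posterior(12, 1, m3)[1, ]), c(0, 0, 1))

  # inconsistent count errors with the sample index
  expect_error(component_posterior(3, 1, m3), "inconsistent")
})

test_that("zero separation holds for posterior weights", {
  set.seed(2)
  counts <- c(rpois(200, 2), rep(0, 60), 40, 55)
  m <- fit_mixture(counts, rep(1, length(counts)), B = 10, seed = 1)
  W <- component_posterior(counts, 1, m)
  nm <- colnames(W)
  expect_true(all(W[counts > 0, nm == "z"] == 0))
  expect_true(all(W[counts <= m$components$C, nm == "C+"] == 0))
  expect_equal(rowSums(W), rep(1, nrow(W)), tolerance = 1e-12)
})

test_that("higher resolution shifts the posterior to lower-rate components", {
  cs <- toy_components(alpha = c(1, 6), beta = c(1, 1), C = 10,
                       has_zero = FALSE, has_high = FALSE)
  m <- toy_mixture(c(0.5, 0.5), cs)
  post_mean <- sapply(c(0.5, 1, 2, 4), function(t) {
    w <- component_posterior(3, t, m)
    sum(w * c(1, 6))
  })
  expect_true(all(diff(post_mean) < 0))
})

test_that("component pmf matrix rows are proper distributions", {
  set.seed(4)
  counts <- c(rpois(150, 3), rpois(30, 20))
  m <- fit_mixture(counts, rep(1, 180), B = 10, seed = 2)
  P <- component_pmf_matrix(m)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-10)
  # z row is an indicator at the structural-zero category
  expect_equal(unname(P["z", ]), c(1, rep(0, ncol(P) - 1)))
  expect_equal(unname(P["C+", ncol(P)]), 1)
  # Gamma(1,1) row is geometric with tail mass at C+
  C <- m$components$C
  g11 <- P["G(1,1)", ]
  expect_equal(unname(g11[as.character(0:C)]), 0.5^(1:(C + 1)))
  expect_equal(unname(g11[["C+"]]), 0.5^(C + 1))
})

test_that("sample pmfs combine weights and the pmf matrix consistently", {
  cs <- toy_components(alpha = 1, beta = 1, C = 8)
  P <- component_pmf_matrix(cs)
  # pure structural zero
  expect_equal(unname(sample_pmf(c(1, 0, 0), P)[1, ]),
               c(1, rep(0, ncol(P) - 1)))
  # pure Gamma(1,1): geometric
  s <- sample_pmf(c(0, 1, 0), P)
  expect_equal(unname(s[1, c("0", "1")]), c(0.5, 0.25))
  # P_i(z) = w_z and total mass 1 for random weights
  W <- runif_simplex(20, 3)
  S <- sample_pmf(W, P)
  expect_equal(unname(S[, "z"]), W[, 1])
  expect_equal(rowSums(S), rep(1, 20), tolerance = 1e-8)
})

test_that("averaged sample pmfs converge to the mixture marginal", {
  # the identity E[w_i] = w is exact when every component has a proper
  # observation model, so test on a mixture without the high-count lump
  # (whose indicator posterior is not a pmf over specific counts)
  cs <- toy_components(alpha = c(2, 7), beta = c(1, 1), C = 40,
                       has_zero = TRUE, has_high = FALSE)
  m <- toy_mixture(c(0.3, 0.4, 0.3), cs)
  P <- component_pmf_matrix(m)
  marginal <- as.numeric(m$w %*% P)
  set.seed(8)
  n <- 20000
  comp <- sample(3, n, replace = TRUE, prob = m$w)
  draw <- integer(n)
  for (g in 1:2) {
    idx <- which(comp == g + 1L)
    draw[idx] <- rnbinom(length(idx), size = cs$alpha[g],
                         prob = cs$beta[g] / (1 + cs$beta[g]))
  }
  W <- component_posterior(draw, 1, m)
  avg <- colMeans(sample_pmf(W, P))
  expect_equal(unname(avg), unname(marginal), tolerance = 0.02)
})
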