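test_that("discrete L2 distance matches its weight-space quadratic form", {
  cs <- toy_components(alpha = c(1, 2, 5), beta = c(2, 1, 1), C = 8)
  P <- component_pmf_matrix(cs)
  G <- dcmd:::d_l2_gram(P)
  expect_equal(d_l2(c(1, 0, 0), c(1, 0, 0)), 0)
  # disjoint indicators: pure structural zero vs pure high mass
  nc <- nrow(P)
  a <- sample_pmf(c(1, 0, 0, 0, 0), P)
  b <- sample_pmf(c(0, 0, 0, 0, 1), P)
  expect_equal(d_l2(a, b), 2)
  # two independent evaluations agree to 1e-12
  set.seed(6)
  W <- runif_simplex(20, nc)
  for (i in 1:10) {
    wa <- W[2 * i - 1, ]
    wb <- W[2 * i, ]
    direct <- d_l2(sample_pmf(wa, P), sample_pmf(wb, P))
    quad <- as.numeric((wa - wb) %*% G %*% (wa - wb))
    expect_equal(direct, quad, tolerance = 1e-12)
    expect_gte(direct, 0)
  }
  expect_error(d_l2(a, b[, -1]), "category")
})

test_that("cc-l2 Gram entries match closed-form integrals", {
  cs <- toy_components(alpha = 1, beta = 1, C = 8)
  G <- cc_l2_gram(cs, quadrature_step = 0.005)
  # zero-mass CDF is identically 1: G_zz = C
  expect_equal(G["z", "z"], 8, tolerance = 1e-8)
  # anything with the high mass (CDF identically 0) is 0
  expect_equal(unname(G["C+", ]), rep(0, 3))
  # Gamma(1,1) with itself: int_0^8 (1 - e^-x)^2 dx
  closed <- 8 - 2 * (1 - exp(-8)) + (1 - exp(-16)) / 2
  expect_equal(G["G(1,1)", "G(1,1)"], closed, tolerance = 1e-6)
  # z with Gamma(1,1): int_0^8 (1 - e^-x) dx
  expect_equal(G["z", "G(1,1)"], 8 - (1 - exp(-8)), tolerance = 1e-6)
})

test_that("cc-l2 quadratic form equals direct CDF quadrature", {
  cs <- toy_components(alpha = c(1, 3, 7), beta = c(2, 1, 1), C = 10)
  G <- cc_l2_gram(cs)
  xs <- seq(0, 10, by = 0.002)
  Fm <- rbind(rep(1, length(xs)),
              pgamma(xs, 1, 2), pgamma(xs, 3, 1), pgamma(xs, 7, 1),
              rep(0, length(xs)))
  trap <- function(f) sum((f[-1] + f[-length(f)]) / 2 * diff(xs))
  set.seed(7)
  W <- runif_simplex(10, 5)
  for (i in 1:5) {
    wa <- W[2 * i - 1, ]
    wb <- W[2 * i, ]
    direct <- trap((as.numeric(wa %*% Fm) - as.numeric(wb %*% Fm))^2)
    expect_equal(cc_l2(wa, wb, G), direct, tolerance = 1e-5)
  }
  # pure structural zero vs pure high mass: int_0^C 1 dx = C
  expect_equal(cc_l2(c(1, 0, 0, 0, 0), c(0, 0, 0, 0, 1), G), 10,
               tolerance = 1e-8)
  expect_equal(cc_l2(W[1, ], W[1, ], G), 0)
})

test_that("Gram matrices are symmetric positive semidefinite", {
  set.seed(12)
  counts <- c(rpois(150, 2), rpois(50, 25))
  m <- fit_mixture(counts, rep(1, 200), B = 5, seed = 1)
  for (G in list(cc_l2_gram(m$components),
                 dcmd:::d_l2_gram(component_pmf_matrix(m)))) {
    expect_equal(G, t(G), tolerance = 1e-12)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9)
  }
})

test_that("total distance is additive over OTUs and order-invariant", {
  cs <- toy_components(alpha = 1, beta = 1, C = 8)
  P <- component_pmf_matrix(cs)
  wa <- c(0.6, 0.3, 0.1)
  wb <- c(0.1, 0.2, 0.7)
  pa <- as.numeric(sample_pmf(wa, P))
  pb <- as.numeric(sample_pmf(wb, P))
  single <- d_l2(pa, pb)
  J <- 5
  expect_equal(total_distance(rep(list(pa), J), rep(list(pb), J)),
               J * single)
  expect_equal(total_distance(list(pa, pa), list(pa, pa)), 0)
  # cc-l2 path with per-OTU Gram matrices, order permuted
  G <- cc_l2_gram(cs)
  d1 <- total_distance(list(a = wa, b = wb), list(a = wb, b = wa),
                       metric = "cc-l2", grams = list(G, G))
  d2 <- total_distance(list(b = wb, a = wa), list(b = wa, a = wb),
                       metric = "cc-l2", grams = list(G, G))
  expect_equal(d1, d2)
  expect_error(total_distance(list(a = wa), list(b = wb), metric = "cc-l2",
                              grams = list(G)), "disagree")
})

test_that("pairwise distance matrices are symmetric with zero diagonal", {
  set.seed(19)
  W <- list(runif_simplex(12, 3), runif_simplex(12, 3))
  cs <- toy_components(alpha = 1, beta = 1, C = 8)
  G <- cc_l2_gram(cs)
  D <- distance_matrix(W, list(G, G), ids = paste0("s", 1:12))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 12))
  expect_true(all(D >= 0))
  # spot-check one entry against the scalar form
  expect_equal(D[1, 5],
               cc_l2(W[[1]][1, ], W[[1]][5, ], G) +
                 cc_l2(W[[2]][1, ], W[[2]][5, ], G),
               tolerance = 1e-12)
})
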