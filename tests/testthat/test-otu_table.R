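test_that("constructor validates counts and computes totals", {
  x <- make_table(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(unname(x$totals), c(3, 7))
  expect_error(make_table(matrix(c(1, -1, 2, 4), 2, 2)), "non-negative")
  expect_error(make_table(matrix(c(1, 1.5, 2, 4), 2, 2)), "integer")
  expect_error(make_table(matrix(1:4, 2, 2), sample_ids = c("a", "a")),
               "duplicate")
})

test_that("reading both orientations yields identical tables", {
  counts <- matrix(c(0, 5, 2, 1, 7, 0), 2, 3,
                   dimnames = list(c("s1", "s2"), c("o1", "o2", "o3")))
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  write.table(cbind(id = rownames(counts), as.data.frame(counts)), f1,
              sep = "\t", quote = FALSE, row.names = FALSE)
  tc <- t(counts)
  write.table(cbind(id = rownames(tc), as.data.frame(tc)), f2,
              sep = "\t", quote = FALSE, row.names = FALSE)
  a <- read_otu_table(f1)
  b <- read_otu_table(f2, orientation = "otus-in-rows")
  expect_identical(a$counts, b$counts)
  expect_identical(a$totals, b$totals)

  # label column handling
  df <- cbind(id = rownames(counts), as.data.frame(counts),
              group = c("x", "y"))
  write.table(df, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- read_otu_table(f1, label_column = "group")
  expect_equal(as.character(lab$labels), c("x", "y"))
  expect_equal(ncol(lab$counts), 3L)
})

test_that("write/read round-trips totals and labels", {
  x <- make_table(rbind(c(1, 4), c(0, 2), c(5, 5)),
                  totals = c(100, 60, 80), labels = c("a", "b", "a"))
  f <- tempfile(fileext = ".tsv")
  write_otu_table(x, f)
  y <- read_otu_table(f, label_column = "label")
  expect_equal(unname(y$totals), unname(x$totals))
  expect_identical(unname(y$counts), unname(x$counts))
  expect_equal(as.character(y$labels), as.character(x$labels))
  # forcing row sums ignores the stored totals column... by dropping it
  z <- read_otu_table(f, totals_column = NA, drop_columns = "total",
                      label_column = "label")
  expect_equal(unname(z$totals), c(5, 2, 10))
})

test_that("read_otu_table reports the offending non-numeric cell", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\to1\to2", "s1\t1\tbad", "s2\t2\t3"), f)
  expect_error(read_otu_table(f), "bad")
})

test_that("depth filter keeps the boundary and errors when empty", {
  x <- make_table(rbind(c(50, 0), c(150, 0), c(100, 0)),
                  totals = c(50, 150, 100))
  f <- filter_samples_by_depth(x, 100)
  expect_equal(nrow(f$counts), 2L)
  expect_equal(unname(f$totals), c(150, 100))
  expect_equal(nrow(filter_samples_by_depth(x, 0)$counts), 3L)
  expect_error(filter_samples_by_depth(x, 1000), "every sample")
  # idempotence
  expect_identical(filter_samples_by_depth(f, 100), f)
})

test_that("OTU filter applies strict zero-proportion and abundance rules", {
  counts <- cbind(allzero = rep(0, 10), nine_zero = c(rep(0, 9), 5),
                  dense = rep(3, 10))
  x <- make_table(counts, totals = rep(100, 10))
  f <- filter_otus(x, 0, 0.9)
  # 9/10 zeros is not strictly below 0.9, so both sparse OTUs go
  expect_equal(colnames(f$counts), "dense")
  expect_identical(filter_otus(x, 0, 1)$counts, x$counts)
  expect_error(filter_otus(x, 0.99, 1), "every OTU")
  expect_identical(filter_otus(f, 0, 0.9), f)
  # mean relative abundance threshold
  f2 <- filter_otus(x, min_mean_rel_abundance = 0.02, max_zero_proportion = 1)
  expect_equal(colnames(f2$counts), "dense")
})

test_that("resolutions average to one and are depth-scale invariant", {
  x <- make_table(rbind(1:2, 3:4), totals = c(100, 300))
  r <- compute_resolutions(x)
  expect_equal(unname(r$t), c(0.5, 1.5))
  expect_equal(mean(r$t), 1, tolerance = 1e-12)
  r2 <- compute_resolutions(c(100, 300) * 17)
  expect_equal(unname(r$t), unname(r2$t))
  expect_error(compute_resolutions(c(0, 10)), "positive")
  set.seed(1)
  tot <- runif(20, 10, 1000)
  expect_equal(mean(compute_resolutions(tot)$t), 1, tolerance = 1e-12)
})

test_that("screening retains discriminative OTUs only", {
  set.seed(42)
  n <- 200
  labels <- rep(c("a", "b"), each = n)
  signal <- ifelse(labels == "b", 1000, 0) + rpois(2 * n, 20)
  flat <- rep(50, 2 * n) # identical in both classes
  noise <- rpois(2 * n, 10)
  x <- make_table(cbind(sig = signal, flat = flat, noise = noise),
                  totals = rep(2000, 2 * n), labels = labels)
  sc <- screen_otus(x, 0.05)
  expect_true("sig" %in% sc$retained)
  expect_false("flat" %in% sc$retained)
  expect_equal(sc$report$q[sc$report$otu_id == "flat"], 1)
  # alpha_q = 1 retains everything
  expect_equal(sort(screen_otus(x, 1)$retained), sort(colnames(x$counts)))
  # rank-based: invariant to monotone rescaling of the features
  x2 <- x
  x2$totals <- x$totals * 13
  expect_equal(screen_otus(x2, 0.05)$report$p, sc$report$p)
  # binary labels required
  x3 <- make_table(cbind(a = rpois(9, 5), b = rpois(9, 5)),
                   totals = rep(10, 9), labels = rep(c("a", "b", "c"), 3))
  expect_error(screen_otus(x3), "binary")
})
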