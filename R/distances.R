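#' Discrete L2 distance between sample distributions
#'
#' The squared discrete L2 norm
#' \eqn{\delta = \sum_x [P_a(x) - P_b(x)]^2} over the category axis
#' \eqn{x = z, 0, \ldots, C, C+} (the structural-zero category enters as its
#' own coordinate). Distances are used as squared norms throughout — no
#' square root is taken; classification is invariant to the monotone
#' transform.
#'
#' @param a,b sample pmf vectors over the same category axis
#'   ([sample_pmf()] rows).
#' @return Non-negative scalar.
#' @export
d_l2 <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("distributions live on different category axes")
  sum((a - b)^2)
}

# Gram matrix of the discrete metric in weight space: since P_i = w_i' P,
# sum_x [(w_a - w_b)' P(x)]^2 = (w_a - w_b)' (P P') (w_a - w_b).
d_l2_gram <- function(P) tcrossprod(P)

#' Gram matrix of the continuous cumulative L2 metric
#'
#' Entry \eqn{(m_1, m_2)} is \eqn{\int_0^C F_{m_1}(x) F_{m_2}(x) dx}, the
#' inner product of the component CDFs on \eqn{[0, C]}, so that
#' \eqn{\int_0^C [F_a - F_b]^2 dx} becomes the quadratic form
#' \eqn{(w_a - w_b) G (w_a - w_b)'}. CDF conventions: the zero-point mass
#' has \eqn{F \equiv 1} on \eqn{[0, C]}, the high-count mass
#' \eqn{F \equiv 0}, and Gamma components use their continuous
#' \eqn{\Gamma(\alpha_m, \beta_m)} CDF. Entries are computed by composite
#' trapezoid quadrature (the integrands are smooth).
#'
#' @param components a `component_set` (or `dcmd_mixture`).
#' @param quadrature_step grid step of the trapezoid rule (default 0.01).
#' @return Symmetric positive semidefinite matrix, components in model
#'   order.
#' @export
cc_l2_gram <- function(components, quadrature_step = 0.01) {
  cs <- if (inherits(components, "component_set")) components else components$components
  stopifnot(inherits(cs, "component_set"), quadrature_step > 0)
  C <- cs$C
  xs <- seq(0, C, by = quadrature_step)
  if (xs[length(xs)] < C) xs <- c(xs, C)
  nc <- n_components(cs)
  Fm <- matrix(0, nc, length(xs))
  j <- 0L
  if (cs$has_zero_mass) {
    j <- j + 1L
    Fm[j, ] <- 1
  }
  for (g in seq_along(cs$alpha)) {
    j <- j + 1L
    Fm[j, ] <- stats::pgamma(xs, shape = cs$alpha[g], rate = cs$beta[g])
  }
  if (cs$has_high_mass) j <- j + 1L # F == 0 on [0, C)
  wt <- diff(xs)
  wt <- c(wt / 2, 0) + c(0, wt / 2) # trapezoid weights
  G <- (Fm * rep(wt, each = nc)) %*% t(Fm)
  G <- (G + t(G)) / 2
  dimnames(G) <- list(component_names(cs), component_names(cs))
  G
}

#' Continuous cumulative L2 distance
#'
#' The squared continuous cumulative L2 norm
#' \eqn{\delta = \int_0^C [F_a(x) - F_b(x)]^2 dx}, evaluated as the
#' quadratic form \eqn{(w_a - w_b) G (w_a - w_b)'} with the Gram matrix
#' from [cc_l2_gram()].
#'
#' @param a,b sample component-weight vectors ([component_posterior()]
#'   rows).
#' @param G Gram matrix from [cc_l2_gram()].
#' @return Non-negative scalar.
#' @export
cc_l2 <- function(a, b, G) {
  d <- as.numeric(a) - as.numeric(b)
  if (length(d) != nrow(G)) stop("weight vector does not match the Gram matrix")
  max(0, as.numeric(d %*% G %*% d))
}

#' Total distance across OTUs
#'
#' The total distance between two samples is the sum of per-OTU
#' distributional distances.
#'
#' @param a,b per-OTU lists: pmf vectors for `metric = "d-l2"`, component
#'   weight vectors for `metric = "cc-l2"`.
#' @param metric `"d-l2"` or `"cc-l2"`.
#' @param grams per-OTU list of Gram matrices (required for `"cc-l2"`).
#' @return Non-negative scalar.
#' @export
total_distance <- function(a, b, metric = c("d-l2", "cc-l2"), grams = NULL) {
  metric <- match.arg(metric)
  if (length(a) != length(b)) stop("OTU lists differ in length")
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))
    stop("OTU lists disagree")
  if (metric == "d-l2")
    return(sum(vapply(seq_along(a), function(j) d_l2(a[[j]], b[[j]]), 0)))
  if (is.null(grams) || length(grams) != length(a))
    stop("cc-l2 requires one Gram matrix per OTU")
  sum(vapply(seq_along(a), function(j) cc_l2(a[[j]], b[[j]], grams[[j]]), 0))
}

# Row-wise quadratic forms d_i' G d_i for D = W - rep(mu): the workhorse of
# k-means prediction under either metric (both are Gram quadratic forms in
# weight space).
quadform_rows <- function(W, mu, G) {
  D <- sweep(W, 2L, mu, "-")
  rowSums((D %*% G) * D)
}

# Cross squared distances under Gram G between weight-row matrices:
# d(i, j) = (a_i - b_j)' G (a_i - b_j), returned as nrow(A) x nrow(B).
cross_quadform <- function(A, B, G) {
  AG <- A %*% G
  BG <- B %*% G
  ra <- rowSums(AG * A)
  rb <- rowSums(BG * B)
  M <- outer(ra, rb, "+") - 2 * tcrossprod(AG, B)
  M[M < 0] <- 0
  M
}

#' Pairwise distance matrix between samples
#'
#' Computes the full symmetric matrix of total distributional distances
#' \eqn{D(i_1, i_2) = \sum_j \delta_j} between all samples, given per-OTU
#' sample weight matrices and Gram matrices.
#'
#' @param W per-OTU list of sample weight matrices (rows = samples).
#' @param grams per-OTU list of Gram matrices matching the metric.
#' @param ids optional sample ids for the dimnames.
#' @return Symmetric non-negative matrix with zero diagonal.
#' @export
distance_matrix <- function(W, grams, ids = NULL) {
  stopifnot(length(W) == length(grams), length(W) >= 1)
  D <- 0
  for (j in seq_along(W)) D <- D + cross_quadform(W[[j]], W[[j]], grams[[j]])
  D <- (D + t(D)) / 2
  diag(D) <- 0
  if (!is.null(ids)) dimnames(D) <- list(ids, ids)
  D
}

#' Write a pairwise distance matrix as TSV
#'
#' @param D square distance matrix.
#' @param path output file path.
#' @export
write_distance_matrix <- function(D, path) {
  df <- cbind(sample_id = rownames(D), as.data.frame(D, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
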