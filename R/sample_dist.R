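#' Posterior component weights for observed counts
#'
#' Conditions the fitted mixture on each sample's observed count
#' \eqn{n_i} and resolution \eqn{t_i}: for a Gamma component,
#' \eqn{p_{im} = w_m \cdot P_{NB}(n_i \mid \alpha_m, \beta_m/(t_i+\beta_m))};
#' the zero-point mass contributes \eqn{w_z 1(n_i = 0)} and the high-count
#' mass \eqn{w_{C+} 1(n_i > C)}. The sample-specific weights are the
#' normalized \eqn{w_{im} = p_{im} / \sum_m p_{im}}.
#'
#' @param n observed count(s).
#' @param t resolution(s), recycled against `n`.
#' @param mixture a `dcmd_mixture` (or a list with `components` and `w`).
#' @return Matrix of sample weights, one row per sample, columns in model
#'   order; each row lies on the simplex.
#' @export
component_posterior <- function(n, t, mixture) {
  cs <- mixture$components
  w <- mixture$w
  stopifnot(inherits(cs, "component_set"), all(n >= 0), all(t > 0))
  ln <- max(length(n), length(t))
  n <- rep_len(n, ln)
  t <- rep_len(t, ln)
  nc <- n_components(cs)
  P <- matrix(0, ln, nc, dimnames = list(NULL, component_names(cs)))
  j <- 0L
  if (cs$has_zero_mass) {
    j <- j + 1L
    P[, j] <- w[j] * (n == 0)
  }
  for (g in seq_along(cs$alpha)) {
    j <- j + 1L
    P[, j] <- w[j] * stats::dnbinom(n, size = cs$alpha[g],
                                    prob = cs$beta[g] / (t + cs$beta[g]))
  }
  if (cs$has_high_mass) {
    j <- j + 1L
    P[, j] <- w[j] * (n > cs$C)
  }
  tot <- rowSums(P)
  bad <- which(tot <= 0)
  if (length(bad))
    stop(sprintf("count %s is inconsistent with every mixture component (sample %d)",
                 format(n[bad[1L]]), bad[1L]))
  P / tot
}

#' Component pmf matrix at unit resolution
#'
#' Precomputes, for each mixture component, the probability of every count
#' category \eqn{x = z, 0, \ldots, C, C+} at resolution 1. Gamma components
#' are \eqn{NB(\alpha_m, \beta_m/(1+\beta_m))} with their tail mass above
#' \eqn{C} in the `C+` column; the zero-point mass is an indicator at the
#' structural-zero column \eqn{z} (its own category, distinct from an
#' observed zero) and the high-count mass an indicator at `C+`. Every row
#' sums to 1.
#'
#' The asymmetry with [component_posterior()] — sample weights use each
#' sample's own \eqn{t_i}, the pmf matrix uses resolution 1 — is deliberate:
#' resolution adjustment enters once, through the posterior weights.
#'
#' @param mixture a `dcmd_mixture`, or a `component_set`.
#' @return Matrix with components in rows and categories
#'   `z, 0..C, C+` in columns.
#' @export
component_pmf_matrix <- function(mixture) {
  cs <- if (inherits(mixture, "component_set")) mixture else mixture$components
  stopifnot(inherits(cs, "component_set"))
  C <- cs$C
  nc <- n_components(cs)
  ncat <- C + 3L # z, 0..C, C+
  P <- matrix(0, nc, ncat,
              dimnames = list(component_names(cs),
                              c("z", as.character(0:C), "C+")))
  j <- 0L
  if (cs$has_zero_mass) {
    j <- j + 1L
    P[j, "z"] <- 1
  }
  for (g in seq_along(cs$alpha)) {
    j <- j + 1L
    p <- cs$beta[g] / (1 + cs$beta[g])
    P[j, 1L + seq_len(C + 1L)] <- stats::dnbinom(0:C, size = cs$alpha[g], prob = p)
    P[j, ncat] <- stats::pnbinom(C, size = cs$alpha[g], prob = p,
                                 lower.tail = FALSE)
  }
  if (cs$has_high_mass) {
    j <- j + 1L
    P[j, ncat] <- 1
  }
  P
}

#' Sample-specific discrete pmf
#'
#' The discrete probability density of a sample over the category axis
#' \eqn{x = z, 0, \ldots, C, C+}, obtained as \eqn{P_i = w_i' P} from its
#' posterior component weights and the component pmf matrix. By
#' construction \eqn{P_i(z) = w_{iz}} and
#' \eqn{P_i(C+) = 1 - [\sum_{x=0}^C P_i(x) + P_i(z)]}.
#'
#' @param w_i sample weight vector(s): a vector or a matrix with one row
#'   per sample (as returned by [component_posterior()]).
#' @param P component pmf matrix from [component_pmf_matrix()].
#' @return Matrix of sample pmfs (rows = samples, columns = categories);
#'   a vector input returns a single-row matrix.
#' @export
sample_pmf <- function(w_i, P) {
  if (is.null(dim(w_i))) w_i <- matrix(w_i, 1L)
  if (ncol(w_i) != nrow(P)) stop("weight / pmf matrix dimensions disagree")
  S <- w_i %*% P
  resid <- 1 - rowSums(S[, -ncol(S), drop = FALSE])
  if (any(resid < -1e-10))
    stop("negative residual high-count mass: inconsistent pmf matrix")
  S
}

#' Export sample distributions as a wide TSV
#'
#' @param pmf matrix of sample pmfs ([sample_pmf()]).
#' @param path output file path.
#' @param sample_ids optional row ids.
#' @export
write_sample_distributions <- function(pmf, path, sample_ids = rownames(pmf)) {
  df <- as.data.frame(pmf, check.names = FALSE)
  if (!is.null(sample_ids)) df <- cbind(sample_id = sample_ids, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
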