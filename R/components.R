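#' Specify mixture components for one OTU
#'
#' Builds the full component set used to model an OTU's count-rate
#' distribution: an optional structural-zero point mass, a ladder of Gamma
#' components covering the low and integer counts, a linear-log grid of
#' high-count Gamma components, and a high-count point mass at the
#' truncation point \eqn{C}.
#'
#' The component layout is:
#' \itemize{
#'   \item extra low-rate exponentials (default \eqn{\Gamma(1,2)}) adding
#'     mass near zero;
#'   \item Poisson-rate posteriors \eqn{\Gamma(x+1, 1)} for counts
#'     \eqn{x = 0..7} (i.e. \eqn{\Gamma(1,1)..\Gamma(8,1)});
#'   \item `n_high` shapes at uniform intervals on a linear-log scale from 8
#'     to \eqn{C}, all with rate 1 (collapsing duplicates when the grid is
#'     degenerate);
#'   \item a zero-point mass \eqn{G_z} iff the OTU has at least one observed
#'     zero, and a point mass \eqn{G_{C+}} absorbing counts above \eqn{C}.
#' }
#' \eqn{C} is the `quantile_p` quantile of the positive counts, floored at
#' `c_min` and rounded up.
#'
#' @param counts integer count vector for one OTU (all samples).
#' @param quantile_p quantile of the positive counts defining \eqn{C}
#'   (default 0.85).
#' @param n_high number of high-count grid components (default 12).
#' @param extra_low list of `c(shape, rate)` pairs of extra low-rate
#'   components (default a single \eqn{\Gamma(1,2)}).
#' @param c_min lower bound for the truncation point \eqn{C} (default 8).
#' @return An object of class `component_set`: list with `alpha`, `beta`
#'   (Gamma parameters, ordered by ascending mean), `C`, `has_zero_mass`,
#'   `has_high_mass`.
#' @examples
#' cs <- specify_components(c(0, 1, 0, 3, 12, 40, 2, 0))
#' cs$C
#' @export
specify_components <- function(counts, quantile_p = 0.85, n_high = 12,
                               extra_low = list(c(1, 2)), c_min = 8) {
  counts <- as.numeric(counts)
  pos <- counts[counts > 0]
  if (length(pos) == 0L) stop("all-zero OTU: no mixture to fit")
  C <- max(c_min, ceiling(stats::quantile(pos, quantile_p, names = FALSE)))

  alpha <- numeric(0)
  beta <- numeric(0)
  for (g in extra_low) {
    alpha <- c(alpha, g[[1L]])
    beta <- c(beta, g[[2L]])
  }
  alpha <- c(alpha, 1:8)
  beta <- c(beta, rep(1, 8))
  grid <- exp(seq(log(8), log(C), length.out = n_high))
  grid[1L] <- 8 # exact endpoints (exp/log round trip drifts in the last ulp)
  grid[length(grid)] <- C
  grid <- grid[!duplicated(signif(grid, 12))]
  alpha <- c(alpha, grid)
  beta <- c(beta, rep(1, length(grid)))

  ord <- order(alpha / beta, seq_along(alpha)) # stable, ascending mean
  structure(list(alpha = alpha[ord], beta = beta[ord], C = as.integer(C),
                 has_zero_mass = any(counts == 0), has_high_mass = TRUE),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("component_set: %d Gamma components, C = %d\n",
              length(x$alpha), x$C))
  cat(sprintf("  zero-point mass: %s, high-count mass: %s\n",
              x$has_zero_mass, x$has_high_mass))
  cat("  Gamma means:", paste(signif(x$alpha / x$beta, 3), collapse = " "), "\n")
  invisible(x)
}

# number of components including point masses
n_components <- function(cs) {
  length(cs$alpha) + as.integer(cs$has_zero_mass) + as.integer(cs$has_high_mass)
}

# component labels in model order: z, Gammas ascending by mean, C+
component_names <- function(cs) {
  g <- sprintf("G(%s,%s)", signif(cs$alpha, 4), signif(cs$beta, 4))
  c(if (cs$has_zero_mass) "z", g, if (cs$has_high_mass) "C+")
}

#' Nested candidate models
#'
#' Generates the nested candidate models over which the mixture weights are
#' averaged: model 1 is the full component set, and model \eqn{l} drops the
#' \eqn{l - 1} lowest-mean Gamma components (only components with mean below
#' 4 are droppable; point masses are never dropped).
#'
#' @param full a `component_set` from [specify_components()].
#' @param n_models number of nested models (default 5).
#' @return A list of candidate models; each is an integer vector of
#'   component indices into the full model order (zero mass, Gammas, high
#'   mass).
#' @export
build_nested_models <- function(full, n_models = 5) {
  stopifnot(inherits(full, "component_set"), n_models >= 1)
  nc <- n_components(full)
  means <- full$alpha / full$beta
  # positions of the gammas within the full component ordering
  off <- as.integer(full$has_zero_mass)
  droppable <- which(means < 4) + off
  droppable <- droppable[order(means[droppable - off])]
  if (n_models > length(droppable) + 1L)
    stop(sprintf("only %d low-rate components are droppable: at most %d nested models",
                 length(droppable), length(droppable) + 1L))
  lapply(seq_len(n_models), function(l) {
    drop <- if (l > 1L) droppable[seq_len(l - 1L)] else integer(0)
    setdiff(seq_len(nc), drop)
  })
}

#' Negative binomial count probability of a Poisson-Gamma component
#'
#' A Poisson count whose rate is \eqn{\Gamma(\alpha, \beta)}-distributed and
#' scaled by a resolution \eqn{t} is marginally negative binomial with size
#' \eqn{\alpha} and success probability \eqn{\beta / (t + \beta)}.
#'
#' @param x non-negative integer count(s).
#' @param alpha,beta Gamma shape and rate (positive).
#' @param t resolution(s), positive (default 1).
#' @return `P(X = x)`, vectorized over `x` and `t`.
#' @examples
#' nb_count_prob(0:3, 1, 1) # geometric: 0.5^(x+1)
#' @export
nb_count_prob <- function(x, alpha, beta, t = 1) {
  stopifnot(all(alpha > 0), all(beta > 0), all(t > 0))
  stats::dnbinom(x, size = alpha, prob = beta / (t + beta))
}
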