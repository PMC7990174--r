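#' Aggregate count frequencies for one OTU
#'
#' Tabulates the observed counts into the model's category axis
#' \eqn{x = 0, 1, \ldots, C, C+}: `y[x]` is the number of samples observed
#' with count `x`, and the final `C+` cell collects counts above the
#' truncation point. (Structural zeros are not observable; observed zeros
#' all land in the `0` cell.)
#'
#' @param counts integer count vector for one OTU.
#' @param C truncation point.
#' @return Named integer vector of length `C + 2` over categories
#'   `0..C, C+`; sums to `length(counts)`.
#' @export
aggregate_counts <- function(counts, C) {
  stopifnot(C >= 1, all(counts >= 0))
  cat_idx <- pmin(counts, C + 1) # C+1 encodes ">C"
  y <- tabulate(cat_idx + 1L, nbins = C + 2L)
  names(y) <- c(as.character(0:C), "C+")
  y
}

# resolutions argument: accept a `resolutions` object or a bare vector of t
resolve_t <- function(resolutions, n) {
  t <- if (inherits(resolutions, "resolutions")) resolutions$t else as.numeric(resolutions)
  if (length(t) != n) stop("resolutions do not match the number of samples")
  if (any(t <= 0)) stop("all resolutions must be positive")
  t
}

# Per-sample category probabilities for every component of a component_set:
# an array of dim (ncat, ncomp, nsamp) where ncat = C + 2 (categories
# 0..C, C+) and components follow the model order (z, Gammas, C+). Gamma
# components are NB(alpha, beta/(t_i + beta)) with the tail mass above C in
# the last cell; the zero mass puts all mass at x = 0 (a structural zero is
# *observed* as a zero count), the high mass all mass at C+.
component_prob_array <- function(cs, t) {
  C <- cs$C
  ncat <- C + 2L
  nsamp <- length(t)
  ncomp <- n_components(cs)
  arr <- array(0, dim = c(ncat, ncomp, nsamp))
  j <- 0L
  if (cs$has_zero_mass) {
    j <- j + 1L
    arr[1L, j, ] <- 1
  }
  xs <- 0:C
  for (g in seq_along(cs$alpha)) {
    j <- j + 1L
    p <- cs$beta[g] / (t + cs$beta[g])
    body <- stats::dnbinom(rep(xs, times = nsamp), size = cs$alpha[g],
                           prob = rep(p, each = C + 1L))
    arr[seq_len(C + 1L), j, ] <- body
    arr[ncat, j, ] <- stats::pnbinom(C, size = cs$alpha[g], prob = p,
                                     lower.tail = FALSE)
  }
  if (cs$has_high_mass) {
    j <- j + 1L
    arr[ncat, j, ] <- 1
  }
  arr
}

#' Expected aggregate counts under a weighted mixture
#'
#' The model-expected analogue of [aggregate_counts()]:
#' \eqn{y^E_x = I \sum_m w_m \bar p_{xm}} with
#' \eqn{\bar p_{xm} = \sum_i p_{xmi} / I}, where \eqn{p_{xmi}} is the
#' probability that component \eqn{m} produces count \eqn{x} at resolution
#' \eqn{t_i}. The zero-point mass contributes only to \eqn{x = 0} and the
#' `C+` cell takes each Gamma's tail mass above \eqn{C} plus the high-mass
#' weight, so \eqn{\sum_x y^E_x = I} for any weight vector on the simplex.
#'
#' @param components a `component_set`.
#' @param w weight vector on the simplex, in model order (zero mass,
#'   Gammas, high mass).
#' @param resolutions per-sample resolutions ([compute_resolutions()] object
#'   or bare vector).
#' @return Named numeric vector over categories `0..C, C+`.
#' @export
expected_aggregate <- function(components, w, resolutions) {
  stopifnot(inherits(components, "component_set"))
  t <- if (inherits(resolutions, "resolutions")) resolutions$t else as.numeric(resolutions)
  if (length(w) != n_components(components))
    stop("weight length does not match the component set")
  arr <- component_prob_array(components, t)
  A <- rowMeans(arr, dims = 2L)
  ye <- length(t) * as.numeric(A %*% w)
  names(ye) <- c(as.character(0:components$C), "C+")
  ye
}

#' Fit mixture weights by constrained least squares
#'
#' Estimates component weights for one OTU by minimizing
#' \eqn{\sum_x [y_x - y^E_x(w)]^2} over the probability simplex
#' (\eqn{\sum_m w_m = 1}, \eqn{w_m \ge 0}), where \eqn{y} are the observed
#' aggregate count frequencies and \eqn{y^E} the model-expected frequencies
#' of [expected_aggregate()]. The problem is a convex quadratic program and
#' is solved exactly by an active-set method.
#'
#' @param components a `component_set`.
#' @param counts integer counts for the OTU.
#' @param resolutions per-sample resolutions.
#' @param model optional integer vector of component indices defining a
#'   nested candidate model (default: the full set).
#' @return List with `w` (full-length weight vector, zeros on excluded
#'   components), `objective` (residual sum of squares) and `converged`.
#' @export
fit_weights <- function(components, counts, resolutions, model = NULL) {
  stopifnot(inherits(components, "component_set"))
  t <- resolve_t(resolutions, length(counts))
  nc <- n_components(components)
  if (is.null(model)) model <- seq_len(nc)
  arr <- component_prob_array(components, t)
  A <- rowMeans(arr, dims = 2L)
  y <- aggregate_counts(counts, components$C)
  fit <- simplex_lsq_cpp(length(counts) * A[, model, drop = FALSE], y)
  w <- numeric(nc)
  w[model] <- fit$w
  names(w) <- component_names(components)
  list(w = w, objective = fit$objective, converged = fit$converged)
}

#' Fit a bootstrap-averaged mixture distribution for one OTU
#'
#' The full workflow for a single OTU: specify the component set, build the
#' nested candidate models, estimate each candidate's weights by constrained
#' least squares, and average the candidates with nonparametric bootstrap
#' model probabilities. On each bootstrap iteration the samples (counts
#' jointly with their resolutions) are resampled with replacement, every
#' candidate is refit on the resample, and the candidate whose refit weights
#' best reproduce the *original* aggregate frequencies is selected; the
#' selection proportions over `B` iterations are the model probabilities
#' \eqn{v(l)}. The joint weights are \eqn{w = \sum_l v(l) w_l} with the
#' per-candidate weights \eqn{w_l} refit on the original data (or, with
#' `bootstrap_refit = "resample"`, averaged over the bootstrap refits).
#'
#' @param counts integer counts for one OTU.
#' @param resolutions per-sample resolutions ([compute_resolutions()] object
#'   or bare vector of \eqn{t_i}).
#' @param B number of bootstrap iterations (default 100).
#' @param n_models number of nested candidate models (default 5).
#' @param seed optional integer seed for the bootstrap resampling.
#' @param bootstrap_refit how the per-candidate weights entering the joint
#'   average are obtained: `"original"` (refit on the observed data,
#'   default) or `"resample"` (mean of the bootstrap refits).
#' @param quantile_p,n_high,extra_low,c_min passed to
#'   [specify_components()].
#' @return An object of class `dcmd_mixture`: list with `components`, `w`
#'   (joint weights), `model_probs` (\eqn{v(l)}), `per_model_w`
#'   (\eqn{L \times} components matrix), `objective` (of the joint weights)
#'   and `B`.
#' @examples
#' set.seed(1)
#' x <- rpois(200, 2)
#' m <- fit_mixture(x, rep(1, 200), B = 20, seed = 1)
#' round(m$w, 3)
#' @export
fit_mixture <- function(counts, resolutions, B = 100, n_models = 5,
                        seed = NULL,
                        bootstrap_refit = c("original", "resample"),
                        quantile_p = 0.85, n_high = 12,
                        extra_low = list(c(1, 2)), c_min = 8) {
  bootstrap_refit <- match.arg(bootstrap_refit)
  stopifnot(B >= 1)
  t <- resolve_t(resolutions, length(counts))
  cs <- specify_components(counts, quantile_p = quantile_p, n_high = n_high,
                           extra_low = extra_low, c_min = c_min)
  cands <- build_nested_models(cs, n_models)
  nc <- n_components(cs)
  nsamp <- length(counts)

  arr <- component_prob_array(cs, t)
  A <- rowMeans(arr, dims = 2L)
  y <- aggregate_counts(counts, cs$C)
  cat_idx <- pmin(counts, cs$C + 1L) # 0-based category per sample

  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(nsamp, nsamp * B, replace = TRUE), nsamp, B)
  if (any(counts > 0)) {
    # guard against degenerate (all-zero) resamples
    for (b in seq_len(B)) {
      tries <- 0L
      while (all(counts[idx[, b]] == 0)) {
        tries <- tries + 1L
        if (tries > 50L) stop("could not draw a non-degenerate bootstrap resample")
        idx[, b] <- sample.int(nsamp, nsamp, replace = TRUE)
      }
      if (tries > 0L)
        message(sprintf("bootstrap iteration %d: redrew %d degenerate resample(s)", b, tries))
    }
  }

  boot <- dcmd_bootstrap_cpp(arr, cat_idx, idx - 1L,
                             lapply(cands, function(i) i - 1L), A, y)
  L <- length(cands)
  v <- tabulate(boot$selected, nbins = L) / B

  per_model_w <- matrix(0, L, nc,
                        dimnames = list(paste0("model", seq_len(L)),
                                        component_names(cs)))
  objectives <- numeric(L)
  if (bootstrap_refit == "original") {
    for (l in seq_len(L)) {
      f <- simplex_lsq_cpp(nsamp * A[, cands[[l]], drop = FALSE], y)
      per_model_w[l, cands[[l]]] <- f$w
      objectives[l] <- f$objective
    }
  } else {
    per_model_w <- t(boot$wsum) / B
    dimnames(per_model_w) <- list(paste0("model", seq_len(L)),
                                  component_names(cs))
    for (l in seq_len(L)) {
      r <- y - nsamp * A %*% per_model_w[l, ]
      objectives[l] <- sum(r^2)
    }
  }

  w <- as.numeric(crossprod(per_model_w, v))
  names(w) <- component_names(cs)
  expected <- nsamp * as.numeric(A %*% w)
  names(expected) <- names(y)
  structure(list(components = cs, w = w, model_probs = v,
                 per_model_w = per_model_w, candidates = cands,
                 objective = sum((y - expected)^2),
                 candidate_objectives = objectives,
                 y = y, expected = expected,
                 B = B, bootstrap_refit = bootstrap_refit, n_samples = nsamp),
            class = "dcmd_mixture")
}

#' @export
print.dcmd_mixture <- function(x, ...) {
  cat(sprintf("dcmd_mixture: %d components (C = %d), fitted on %d samples\n",
              length(x$w), x$components$C, x$n_samples))
  cat("  model probabilities v(l):",
      paste(sprintf("%.2f", x$model_probs), collapse = " "), "\n")
  top <- sort(x$w[x$w > 1e-4], decreasing = TRUE)
  cat("  leading weights:\n")
  print(round(utils::head(top, 6), 4))
  cat(sprintf("  objective: %.4g\n", x$objective))
  invisible(x)
}

#' Fit mixtures for every OTU of a table
#'
#' Applies [fit_mixture()] to each OTU column. All-zero OTUs cannot be fit
#' and are skipped with a warning; the result carries the fitted OTU ids.
#' Per-OTU bootstrap seeds are derived deterministically from `seed`.
#'
#' @param x an [otu_table].
#' @param resolutions per-sample resolutions; default
#'   `compute_resolutions(x)`.
#' @param seed integer seed governing all bootstrap resampling.
#' @param ... passed to [fit_mixture()].
#' @return Named list of `dcmd_mixture` objects (class `dcmd_mixtures`).
#' @export
fit_mixtures <- function(x, resolutions = NULL, seed = NULL, ...) {
  stopifnot(inherits(x, "otu_table"))
  if (is.null(resolutions)) resolutions <- compute_resolutions(x)
  out <- list()
  for (j in seq_len(ncol(x$counts))) {
    id <- colnames(x$counts)[j]
    if (all(x$counts[, j] == 0)) {
      warning("skipping all-zero OTU: ", id, call. = FALSE)
      next
    }
    sj <- if (is.null(seed)) NULL else derive_seed(seed, j)
    out[[id]] <- fit_mixture(x$counts[, j], resolutions, seed = sj, ...)
  }
  if (!length(out)) stop("no OTU could be fit")
  class(out) <- "dcmd_mixtures"
  out
}

# deterministic per-stream seeds, kept inside 32-bit integer range
derive_seed <- function(seed, j) {
  as.integer((as.double(seed) + 7919 * as.double(j)) %% 2147483647)
}

#' Serialize a fitted mixture to JSON
#'
#' Round-trips exactly: numeric values are written at full precision.
#'
#' @param x a `dcmd_mixture`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
mixture_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "dcmd_mixture"))
  doc <- list(
    components = list(alpha = x$components$alpha, beta = x$components$beta,
                      C = x$components$C,
                      has_zero_mass = x$components$has_zero_mass,
                      has_high_mass = x$components$has_high_mass),
    w = x$w, model_probs = x$model_probs,
    per_model_w = x$per_model_w, candidates = x$candidates,
    objective = x$objective, candidate_objectives = x$candidate_objectives,
    y = x$y, expected = x$expected,
    B = x$B, bootstrap_refit = x$bootstrap_refit, n_samples = x$n_samples
  )
  js <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Restore a fitted mixture from JSON
#'
#' @param src a JSON string or file path produced by [mixture_to_json()].
#' @return A `dcmd_mixture`.
#' @export
mixture_from_json <- function(src) {
  doc <- jsonlite::fromJSON(src)
  cs <- structure(list(alpha = doc$components$alpha,
                       beta = doc$components$beta,
                       C = as.integer(doc$components$C),
                       has_zero_mass = doc$components$has_zero_mass,
                       has_high_mass = doc$components$has_high_mass),
                  class = "component_set")
  w <- as.numeric(doc$w)
  names(w) <- component_names(cs)
  pm <- as.matrix(doc$per_model_w)
  dimnames(pm) <- list(paste0("model", seq_len(nrow(pm))), component_names(cs))
  structure(list(components = cs, w = w,
                 model_probs = as.numeric(doc$model_probs),
                 per_model_w = pm,
                 candidates = lapply(seq_len(nrow(pm)), function(l) as.integer(doc$candidates[[l]])),
                 objective = doc$objective,
                 candidate_objectives = as.numeric(doc$candidate_objectives),
                 y = stats::setNames(as.numeric(doc$y), names(doc$y)),
                 expected = stats::setNames(as.numeric(doc$expected), names(doc$expected)),
                 B = doc$B, bootstrap_refit = doc$bootstrap_refit,
                 n_samples = doc$n_samples),
            class = "dcmd_mixture")
}
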