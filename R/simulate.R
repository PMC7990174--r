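# Calibrated bin -> rate map. Bin m of M (midpoint u = (m - 1/2)/M) maps to
# the Poisson rate lambda(u) = lambda_max * u^power: a power-law ladder
# spanning roughly 4 orders of magnitude from the near-zero rates of the
# bottom bins to lambda_max at the top. Each OTU additionally carries a
# log-normal abundance-level multiplier exp(level_sd * eps), eps ~ N(0,1),
# drawn once per OTU and shared across classes: OTUs differ in overall
# abundance, classes within an OTU only through alpha_b. The constants were
# calibrated once (scripts/calibrate_generator.R) so the generated
# scenarios reproduce the intended per-class zero proportions (0.14-0.84),
# their between-OTU SDs (0.07-0.13) and mean counts (1-15) across the
# benchmark alpha_b ranges; kappa = Inf makes the within-bin rate
# deterministic (the calibration drives kappa to that limit).
default_rate_map <- function() {
  list(lambda_max = 98.65, power = 2.841, level_sd = 0.568, kappa = Inf)
}

rate_map_lambdas <- function(M, rate_map) {
  u <- ((seq_len(M)) - 0.5) / M
  rate_map$lambda_max * u^rate_map$power
}

#' Simulation scenario configuration
#'
#' Describes one synthetic OTU-table generating process: per class, sample
#' counts are drawn from a mixture of M Poisson-rate components, where the
#' number of samples taken from each component is set by binning draws from
#' a `Beta(alpha_b, beta_b)` at M uniform intervals. `alpha_b` varies
#' between classes (it controls the class mean and sparsity), while
#' `beta_b` (dispersion) and M are drawn once per OTU and shared across
#' classes, so classes differ only through `alpha_b`. Observed counts are
#' `Poisson(r* t_i)` with the bin's rate `r*` and a per-sample resolution
#' `t_i ~ Unif(t_range)` shared across OTUs.
#'
#' @param n_classes number of classes (default 2).
#' @param class_sizes samples per class (default 400 each).
#' @param J number of OTUs (default 25).
#' @param alpha_b_ranges list of `c(lo, hi)` per class; `alpha_b` for a
#'   class and OTU is drawn uniformly from its range.
#' @param beta_b_range range of the per-OTU `beta_b` (default `(2, 6.5)`).
#' @param M_range integer range of the per-OTU component count (default
#'   `(5, 15)`, drawn uniformly on the integers).
#' @param t_range per-sample resolution range (default `(2/3, 5/4)`).
#' @param rate_map bin-to-rate mapping parameters; see Details in the
#'   package vignette. Defaults to the calibrated map.
#' @param seed optional default seed used by [simulate_dataset()].
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_classes = 2,
                            class_sizes = rep(400L, n_classes),
                            J = 25L,
                            alpha_b_ranges = list(c(1.5, 1.8), c(1.8, 2.1),
                                                  c(2.1, 2.4))[seq_len(n_classes)],
                            beta_b_range = c(2, 6.5),
                            M_range = c(5L, 15L),
                            t_range = c(2 / 3, 5 / 4),
                            rate_map = default_rate_map(),
                            seed = NULL) {
  stopifnot(n_classes >= 2, length(class_sizes) == n_classes,
            all(class_sizes >= 1), J >= 1,
            length(alpha_b_ranges) == n_classes,
            beta_b_range[2L] > beta_b_range[1L],
            M_range[2L] >= M_range[1L], M_range[1L] >= 1,
            t_range[1L] > 0, t_range[2L] > t_range[1L])
  structure(list(n_classes = as.integer(n_classes),
                 class_sizes = as.integer(class_sizes), J = as.integer(J),
                 alpha_b_ranges = alpha_b_ranges,
                 beta_b_range = beta_b_range,
                 M_range = as.integer(M_range), t_range = t_range,
                 rate_map = rate_map, seed = seed),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario_config: %d classes (%s samples), %d OTUs\n",
              x$n_classes, paste(x$class_sizes, collapse = "/"), x$J))
  for (k in seq_len(x$n_classes))
    cat(sprintf("  class %d: alpha_b in (%.2f, %.2f)\n", k,
                x$alpha_b_ranges[[k]][1L], x$alpha_b_ranges[[k]][2L]))
  cat(sprintf("  beta_b in (%.1f, %.1f), M in %d..%d, t in (%.3f, %.3f)\n",
              x$beta_b_range[1L], x$beta_b_range[2L], x$M_range[1L],
              x$M_range[2L], x$t_range[1L], x$t_range[2L]))
  invisible(x)
}

#' Preset two-class scenarios
#'
#' The four benchmark scenarios crossing signal strength (difference in
#' `alpha_b` between classes) with sparsity (overall `alpha_b` level):
#' 1 weak/low-sparsity, 2 strong/low-sparsity, 3 weak/high-sparsity,
#' 4 strong/high-sparsity.
#'
#' @param scenario integer 1-4.
#' @param ... overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
two_class_scenario <- function(scenario, ...) {
  ranges <- switch(as.character(scenario),
    "1" = list(c(1.5, 1.8), c(1.8, 2.1)),
    "2" = list(c(1.5, 1.8), c(2.7, 3.0)),
    "3" = list(c(0.2, 0.4), c(0.4, 0.6)),
    "4" = list(c(0.2, 0.4), c(0.8, 1.0)),
    stop("two-class scenarios are 1-4"))
  scenario_config(n_classes = 2, alpha_b_ranges = ranges, ...)
}

#' Preset three-class scenarios
#'
#' Three-class benchmarks with strongly differentiated classes at
#' decreasing abundance / increasing sparsity: scenario 1 low, 2 medium,
#' 3 high sparsity.
#'
#' @param scenario integer 1-3.
#' @param ... overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
three_class_scenario <- function(scenario, ...) {
  ranges <- switch(as.character(scenario),
    "1" = list(c(1.5, 1.8), c(2.1, 2.4), c(2.7, 3.0)),
    "2" = list(c(0.8, 1.0), c(1.5, 1.8), c(2.7, 3.0)),
    "3" = list(c(0.2, 0.4), c(0.8, 1.0), c(1.5, 1.8)),
    stop("three-class scenarios are 1-3"))
  scenario_config(n_classes = 3, alpha_b_ranges = ranges, ...)
}

#' Simulate counts for one OTU and one class
#'
#' Draws `n` values from `Beta(alpha_b, beta_b)`, bins them at M uniform
#' intervals on `[0, 1]`, maps each bin to its Poisson rate through the
#' rate map, and emits `Poisson(r* t)` counts.
#'
#' @param n number of samples.
#' @param alpha_b,beta_b Beta parameters (positive).
#' @param M number of mixture components.
#' @param rate_map rate-map parameters (see [scenario_config()]).
#' @param t per-sample resolutions (length `n` or recycled).
#' @return Integer vector of counts with attributes `bins` and `rates`.
#' @export
simulate_otu_class <- function(n, alpha_b, beta_b, M,
                               rate_map = default_rate_map(),
                               t = rep(1, n)) {
  stopifnot(n >= 1, alpha_b > 0, beta_b > 0, M >= 1)
  t <- rep_len(t, n)
  u <- stats::rbeta(n, alpha_b, beta_b)
  bins <- pmin(M, floor(u * M) + 1L)
  lam <- rate_map_lambdas(M, rate_map)
  r <- if (is.finite(rate_map$kappa))
    stats::rgamma(n, shape = rate_map$kappa, rate = rate_map$kappa / lam[bins])
  else lam[bins]
  counts <- stats::rpois(n, r * t)
  attr(counts, "bins") <- bins
  attr(counts, "rates") <- r
  counts
}

#' Simulate a labelled OTU dataset
#'
#' Generates a full class-structured OTU table under a
#' [scenario_config()]: resolutions are drawn once per sample; per OTU, the
#' component count M and `beta_b` are drawn once and shared across classes
#' while `alpha_b` is drawn per class from that class's range; counts
#' follow [simulate_otu_class()].
#'
#' @param config a `scenario_config`.
#' @param seed integer seed (default `config$seed`); the dataset is a
#'   deterministic function of config and seed.
#' @return An object of class `simulated_dataset`: list with `table` (a
#'   labelled [otu_table]), `truth` (per-OTU generating parameters and the
#'   true resolutions) and `config`.
#' @examples
#' sim <- simulate_dataset(scenario_config(class_sizes = c(20, 20), J = 3,
#'                                         seed = 42))
#' dim(sim$table)
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  I <- sum(config$class_sizes)
  K <- config$n_classes
  labels <- factor(rep(paste0("class", seq_len(K)), config$class_sizes))
  t <- stats::runif(I, config$t_range[1L], config$t_range[2L])
  counts <- matrix(0L, I, config$J,
                   dimnames = list(paste0("S", seq_len(I)),
                                   paste0("OTU", seq_len(config$J))))
  truth <- vector("list", config$J)
  class_idx <- split(seq_len(I), labels)
  for (j in seq_len(config$J)) {
    M <- sample(seq(config$M_range[1L], config$M_range[2L]), 1L)
    beta_b <- stats::runif(1, config$beta_b_range[1L], config$beta_b_range[2L])
    # per-OTU abundance level, shared across classes
    rm_j <- config$rate_map
    lsd <- rm_j$level_sd %||% 0
    if (lsd > 0) {
      rm_j$lambda_max <- rm_j$lambda_max * exp(lsd * stats::rnorm(1))
      rm_j$level_sd <- 0
    }
    alpha_b <- numeric(K)
    for (k in seq_len(K)) {
      rg <- config$alpha_b_ranges[[k]]
      alpha_b[k] <- stats::runif(1, rg[1L], rg[2L])
      idx <- class_idx[[k]]
      counts[idx, j] <- simulate_otu_class(length(idx), alpha_b[k], beta_b,
                                           M, rm_j, t[idx])
    }
    truth[[j]] <- list(M = M, beta_b = beta_b, alpha_b = alpha_b,
                       rates = rate_map_lambdas(M, rm_j))
  }
  # Totals represent the sample's total aligned reads -- the sequencing
  # depth of the whole community, of which the J modelled OTUs are a small
  # subset -- so they track the simulated resolution t_i directly (a
  # nominal mean depth of 1e4 reads). compute_resolutions() on the table
  # then recovers the generating resolutions up to mean-normalization,
  # exactly as N_i does for real data.
  totals <- round(1e4 * t)
  structure(list(table = otu_table(counts, totals = totals, labels = labels),
                 truth = list(otus = truth, t = t), config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset\n")
  print(x$table)
  invisible(x)
}

#' Permuted-label null dataset
#'
#' Uniformly permutes the class labels of a dataset, leaving the counts
#' untouched — the null case in which no classifier should beat the chance
#' accuracy 1/K.
#'
#' @param dataset a `simulated_dataset` or labelled [otu_table].
#' @param seed optional seed for the permutation.
#' @return Same type as the input, with permuted labels.
#' @export
permute_null <- function(dataset, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- if (inherits(dataset, "simulated_dataset")) dataset$table else dataset
  if (is.null(tab$labels)) stop("permutation null needs labels")
  perm <- sample(length(tab$labels))
  tab$labels <- stats::setNames(tab$labels[perm], names(tab$labels))
  if (inherits(dataset, "simulated_dataset")) {
    dataset$table <- tab
    dataset
  } else tab
}

#' Generator summary statistics for one class
#'
#' Mean per-OTU zero proportion and grand mean count of one class of a
#' scenario, averaged over independent replicate datasets — the summary by
#' which the generator is calibrated and checked.
#'
#' @param config a `scenario_config`.
#' @param class class index.
#' @param replicates number of replicate datasets (default 20).
#' @param seed integer seed; replicate r uses a seed derived from it.
#' @return List with `mean_zero_proportion`, `mean_count` and the
#'   per-replicate values.
#' @export
generator_class_stats <- function(config, class, replicates = 20, seed = 1) {
  stopifnot(class >= 1, class <= config$n_classes)
  zp <- mc <- numeric(replicates)
  for (r in seq_len(replicates)) {
    sim <- simulate_dataset(config, seed = derive_seed(seed, r))
    sub <- sim$table$counts[sim$table$labels == paste0("class", class), ,
                            drop = FALSE]
    zp[r] <- mean(colMeans(sub == 0))
    mc[r] <- mean(sub)
  }
  list(mean_zero_proportion = mean(zp), mean_count = mean(mc),
       zp = zp, count = mc)
}
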