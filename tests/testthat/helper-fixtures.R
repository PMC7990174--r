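# small in-code fixtures shared across test files

make_table <- function(counts, ...) otu_table(as.matrix(counts), ...)

# a component set built by hand (bypassing specify_components) so tests can
# control exactly which Gammas are present
toy_components <- function(alpha, beta = rep(1, length(alpha)), C = 8,
                           has_zero = TRUE, has_high = TRUE) {
  structure(list(alpha = alpha, beta = beta, C = as.integer(C),
                 has_zero_mass = has_zero, has_high_mass = has_high),
            class = "component_set")
}

# a minimal fitted-mixture stand-in with prescribed joint weights
toy_mixture <- function(w, components) {
  stopifnot(length(w) == dcmd:::n_components(components))
  structure(list(components = components, w = w / sum(w)),
            class = "dcmd_mixture")
}

# component means aligned with a mixture's weight vector (z -> 0, C+ -> Inf)
cs_means <- function(m) {
  cs <- m$components
  c(if (cs$has_zero_mass) 0, cs$alpha / cs$beta, if (cs$has_high_mass) Inf)
}

# random simplex points
runif_simplex <- function(n, k) {
  x <- matrix(stats::rexp(n * k), n, k)
  x / rowSums(x)
}
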