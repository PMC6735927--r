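# Small shared fixtures, built in code.

tiny_config <- function(seed = 42L, ...) {
  generator_config(
    species = "ath",
    n_block_pairs = 40L,
    n_tandem_pairs = 40L,
    n_unclassified_pairs = 8L,
    n_conditions = 40L,
    seed = seed,
    ...)
}

# fast single-species config for end-to-end runs
e2e_config <- function(seed, n_pairs = 150L, n_conditions = 40L) {
  generator_config(
    species = "ath",
    n_block_pairs = n_pairs,
    n_tandem_pairs = n_pairs,
    n_unclassified_pairs = 20L,
    n_conditions = n_conditions,
    seed = seed)
}

# simulate points directly from an origin-constrained saturation curve
sim_curve_points <- function(n, a, b, noise_sd, ks_rate = 0.8,
                             ks_range = c(0.05, 5)) {
  u <- runif(n)
  plo <- pexp(ks_range[1], ks_rate); phi <- pexp(ks_range[2], ks_rate)
  x <- qexp(plo + u * (phi - plo), ks_rate)
  data.frame(ks = x, value = a * x / (b + x) + rnorm(n, 0, noise_sd))
}

# dense exhaustive 2-D grid-search oracle for the saturation fit
grid_fit_oracle <- function(x, y, a_grid, b_grid) {
  syy <- sum(y * y)
  best <- list(sse = Inf, a = NA, b = NA)
  for (b in b_grid) {
    g <- x / (b + x)
    syg <- sum(y * g); sgg <- sum(g * g)
    sse <- syy - 2 * a_grid * syg + a_grid^2 * sgg
    i <- which.min(sse)
    if (sse[i] < best$sse) best <- list(sse = sse[i], a = a_grid[i], b = b)
  }
  best
}

# exhaustive enumeration over the b grid with exact per-b least-squares a;
# well-posed at the grid's own resolution (a full 2-D grid cannot localize b
# to its step size along the a-b ridge, see the methods vignette)
grid_fit_profiled <- function(x, y, b_grid, a_max = 1) {
  best <- list(sse = Inf, a = NA, b = NA)
  for (b in b_grid) {
    g <- x / (b + x)
    a <- min(max(sum(y * g) / sum(g * g), 0), a_max)
    sse <- sum((y - a * g)^2)
    if (sse < best$sse) best <- list(sse = sse, a = a, b = b)
  }
  best
}

# independent set-arithmetic Dice oracle
dice_oracle <- function(set_a, set_b) {
  if (length(set_a) + length(set_b) == 0) return(NA_real_)
  2 * length(intersect(set_a, set_b)) / (length(set_a) + length(set_b))
}

# build an igraph network from explicit partner sets for two genes
network_from_partner_sets <- function(gene_a, gene_b, pa, pb) {
  edges <- data.frame(
    protein_a = c(rep(gene_a, length(pa)), rep(gene_b, length(pb))),
    protein_b = c(pa, pb), stringsAsFactors = FALSE)
  merge_networks(edges, normalize_ids = FALSE)
}
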