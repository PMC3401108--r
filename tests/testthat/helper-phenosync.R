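# shared fixtures, built in code

# species tree + population mapping + grafted tree
make_grafted <- function(n_species, pops_per_species = 2, seed = 1) {
  tree <- simulateYuleTree(n_species, seed = seed)
  mapping <- do.call(rbind, lapply(tree$tip.label, function(s)
    data.frame(population_id = paste0(s, "_pop", seq_len(pops_per_species)),
               species_id = s, stringsAsFactors = FALSE)))
  list(tree = tree, mapping = mapping,
       grafted = graftPopulations(tree, mapping))
}

# direct multivariate-normal log-density, naive inverse: the independent
# likelihood oracle (never shares code with the fitting path)
mvn_loglik <- function(y, mu, Sigma) {
  n <- length(y)
  r <- y - mu
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(Sigma)$modulus[1] +
                     t(r) %*% solve(Sigma) %*% r))
}

# random non-negative frequency matrix (some zero cells)
random_freq_matrix <- function(s, t, lambda = 3) {
  matrix(stats::rpois(s * t, lambda), nrow = s)
}

# a pixel table with given per-pixel value vectors (one location)
pixel_table <- function(value_list, location_id = "loc1",
                        periods_per_year = 4) {
  do.call(rbind, lapply(seq_along(value_list), function(i) {
    v <- value_list[[i]]
    ny <- ceiling(length(v) / periods_per_year)
    data.frame(location_id = location_id,
               pixel_id = sprintf("px%02d", i),
               year = rep(seq_len(ny), each = periods_per_year)[seq_along(v)],
               period = rep(seq_len(periods_per_year), ny)[seq_along(v)],
               ndvi = v, stringsAsFactors = FALSE)
  }))
}
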