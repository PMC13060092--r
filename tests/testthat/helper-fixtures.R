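# Shared fixtures: tiny enumerable energy models, quartet builders, and a
# brute-force Boltzmann enumerator used as the sampler oracle.

# arbitrary (coupled) energy table over A^L states, as a custom model
toy_energy_model <- function(L = 3, A = 4, seed = 1) {
  tab <- dmscan::with_seed(seed, array(stats::rnorm(A^L), rep(A, L)))
  list(model = dmscan::custom_energy_model(
         function(s) tab[matrix(s, 1)], alphabet = LETTERS[seq_len(A)],
         L = L),
       table = tab)
}

# exact Boltzmann distribution by exhaustive enumeration (the oracle the
# Gibbs sampler is checked against)
boltzmann_exact <- function(tab, temperature = 1) {
  p <- exp(-as.vector(tab) / temperature)
  p / sum(p)
}

# state matrix -> linear index into as.vector(tab) (column-major)
state_index <- function(states, A) {
  idx <- states[, 1]
  if (ncol(states) > 1)
    for (j in 2:ncol(states)) idx <- idx + (states[, j] - 1L) * A^(j - 1L)
  idx
}

tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

# additive (identity-link) score table over random substitution tokens
additive_score_table <- function(n_singles = 30, n_doubles = 300,
                                 beta_sd = 0.3, noise_sd = 0.1,
                                 seed = 1) {
  tr <- dmscan::random_landscape(n_mutations = n_singles,
                                 effect_sd = beta_sd, effect_mean = 0,
                                 noise_sd = noise_sd, seed = seed)
  singles <- names(tr$beta)
  dmscan::with_seed(seed + 1, {
    pairs <- t(utils::combn(singles, 2))
    pairs <- pairs[sample(nrow(pairs), min(n_doubles, nrow(pairs))), ,
                   drop = FALSE]
    doubles <- apply(pairs, 1, function(r) dmscan::render_variant(
      dmscan::parse_variant_string(paste(r, collapse = "+"))))
    vs <- unique(c("WT", singles, doubles))
    z <- vapply(vs, function(v) if (v == "WT") 0 else
      sum(tr$beta[dmscan::variant_tokens(v)]), numeric(1))
    list(table = data.frame(variant = vs,
                            score = z + stats::rnorm(length(z), 0,
                                                     noise_sd),
                            se = noise_sd, stringsAsFactors = FALSE),
         beta = tr$beta, z = z)
  })
}
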