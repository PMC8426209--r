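# Shared fixtures and independent oracles used across the suite.

# A small, fast simulation configuration for tests that only need structure.
small_config <- function(seed = 1L, n_genes = 80L, planted_effects = NULL,
                         group_sizes = c(A = 6L, B = 6L, C = 8L, D = 8L)) {
  simulation_config(
    group_sizes = group_sizes, n_genes = n_genes, n_housekeeping = 8L,
    n_neg_controls = 6L, n_pos_controls = 6L,
    infiltration = list(hot_mean = 2, cold_mean = 0, sd = 1, hot_fraction = 0.5),
    planted_effects = planted_effects, seed = seed)
}

write_counts_fixture <- function(dir, counts, probes) {
  cp <- file.path(dir, "counts.tsv")
  pp <- file.path(dir, "probes.tsv")
  write_tsv(counts, cp)
  write_tsv(probes, pp)
  list(counts = cp, probes = pp)
}

# Brute-force two-sided Fisher exact p for a 2x2 table: enumerate every
# table with the observed margins and sum the hypergeometric probabilities
# not exceeding the observed table's (with the classical relative tolerance).
fisher_2x2_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)), numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force Benjamini-Hochberg step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

kw_p <- function(v, gf) stats::kruskal.test(v, gf)$p.value

# oracle variant tolerating degenerate margins (p = 1 by the package's rule)
fisher_2x2_oracle_safe <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1.0)
  fisher_2x2_oracle(tab)
}

random_2x2 <- function(max_n = 40) {
  repeat {
    cells <- as.vector(stats::rmultinom(1, sample(4:max_n, 1), rep(0.25, 4)))
    tab <- matrix(cells, 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}
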