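# Shared fixture builders for the test suite.

# small deterministic count table
toy_table <- function(counts, prefix_s = "S", prefix_o = "OTU") {
  m <- as.matrix(counts)
  rownames(m) <- paste0(prefix_s, seq_len(nrow(m)))
  colnames(m) <- paste0(prefix_o, seq_len(ncol(m)))
  count_table(m)
}

# i.i.d. multinomial communities from one metacommunity (pure sampling noise)
multinomial_table <- function(n_samples, meta, depth, seed) {
  set.seed(seed)
  tab <- t(stats::rmultinom(n_samples, depth, meta))
  rownames(tab) <- sprintf("S%03d", seq_len(n_samples))
  colnames(tab) <- sprintf("O%04d", seq_along(meta))
  count_table(tab)
}

# Moran-simulated sample set at a common m
moran_table <- function(n_samples, meta, m, N, generations, seed) {
  tab <- t(vapply(seq_len(n_samples), function(s)
    simulate_neutral_local(meta, m, N, generations,
                           seed = seed * 1000 + s),
    integer(length(meta))))
  rownames(tab) <- sprintf("S%03d", seq_len(n_samples))
  colnames(tab) <- sprintf("O%04d", seq_along(meta))
  count_table(tab)
}

# distance matrix with given pairwise values on ids
named_dist <- function(values, ids) {
  m <- as.matrix(values)
  dimnames(m) <- list(ids, ids)
  m
}
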