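# Independent brute-force oracle for the richness/reads-preserving null.
# Vectorized over draws and deliberately implemented with different
# primitives than the package: exponential-key weighted sampling without
# replacement and conditional-binomial multinomials.
oracle_null_bc <- function(m, n_draws, seed) {
  set.seed(seed)
  occ <- colSums(m > 0)
  ab <- colSums(m)
  S <- ncol(m)
  counts <- vector("list", nrow(m))
  for (j in seq_len(nrow(m))) {
    R <- sum(m[j, ] > 0)
    N <- sum(m[j, ])
    # weighted sampling w/o replacement: R smallest exponential keys
    keys <- matrix(stats::rexp(n_draws * S), n_draws, S)
    keys <- sweep(keys, 2, occ, "/")  # occ = 0 -> Inf key, never chosen
    sel <- matrix(FALSE, n_draws, S)
    for (r in seq_len(R)) {
      pick <- max.col(-keys)
      sel[cbind(seq_len(n_draws), pick)] <- TRUE
      keys[cbind(seq_len(n_draws), pick)] <- Inf
    }
    cnt <- matrix(0, n_draws, S)
    cnt[sel] <- 1
    # distribute remaining reads by conditional binomials over columns
    rem <- rep(N - R, n_draws)
    wmat <- sweep(sel, 2, ab, "*")
    tail_w <- t(apply(wmat[, S:1, drop = FALSE], 1, cumsum))[, S:1, drop = FALSE]
    for (k in seq_len(S)) {
      if (k < S) {
        pk <- ifelse(tail_w[, k] > 0, wmat[, k] / tail_w[, k], 0)
        x <- stats::rbinom(n_draws, rem, pk)
      } else {
        x <- rem
      }
      cnt[, k] <- cnt[, k] + x
      rem <- rem - x
    }
    counts[[j]] <- cnt
  }
  idx <- sizeassembly:::pair_index(nrow(m))
  sapply(seq_len(nrow(idx)), function(q) {
    A <- counts[[idx[q, "i"]]]
    B <- counts[[idx[q, "j"]]]
    bc <- rowSums(abs(A - B)) / rowSums(A + B)
    c(mean = mean(bc), sd = stats::sd(bc))
  })
}
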