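#' One richness- and depth-preserving null assembly of a count table
#'
#' Randomizes OTUs and reads in the total community matrix while preserving
#' each sample's observed richness R_j and read total N_j. For sample j:
#' (1) R_j distinct OTUs are drawn without replacement with probability
#' proportional to each OTU's occurrence count (number of samples occupied)
#' in the observed table; (2) each selected OTU receives one read, and the
#' remaining N_j - R_j reads are distributed multinomially with probabilities
#' proportional to the selected OTUs' total observed abundances.
#'
#' @param table a [count_table()].
#' @param seed optional seed; NULL draws from the current RNG stream.
#' @return a null [count_table()] with identical per-sample richness and
#'   read totals.
#' @export
null_assemble <- function(table, seed = NULL) {
  m <- as.matrix(count_table(as.matrix(table)))
  occ <- colSums(m > 0)
  abund <- colSums(m)
  with_seed(seed, null_assemble_impl(m, occ, abund))
}

# Core randomization, reusable inside the replicate loop without re-validating.
null_assemble_impl <- function(m, occ, abund) {
  n_otu <- ncol(m)
  out <- matrix(0L, nrow(m), n_otu, dimnames = dimnames(m))
  for (jj in seq_len(nrow(m))) {
    x <- m[jj, ]
    R <- sum(x > 0)
    N <- sum(x)
    if (R == 0L) next
    if (R > sum(occ > 0))
      stop("sample richness exceeds the occupied OTU pool", call. = FALSE)
    sel <- sample.int(n_otu, R, replace = FALSE, prob = occ)
    reads <- rep.int(1L, R)
    if (N > R) {
      w <- abund[sel]
      if (!any(w > 0)) w <- rep(1, R)
      reads <- reads + as.integer(stats::rmultinom(1, N - R, w))
    }
    out[jj, sel] <- reads
  }
  out
}

#' Beta-null deviation of a community table
#'
#' The null deviation value (NDV) of a sample pair is its observed
#' Bray-Curtis dissimilarity minus the mean Bray-Curtis of `n_reps`
#' independently null-assembled tables (see [null_assemble()]). NDV near 0
#' indicates assembly indistinguishable from the stochastic null; values
#' toward -1 or +1 indicate deterministic processes.
#'
#' @param table a [count_table()] with at least 2 samples.
#' @param n_reps number of null replicates (default 999).
#' @param seed integer seed.
#' @return object of class `ndv_result`: data.frame `pairs` (ids,
#'   `observed_bc`, `null_mean_bc`, `ndv`), plus `n_reps`, `mean_ndv` and
#'   `mean_abs_ndv`.
#' @export
ndv <- function(table, n_reps = 999, seed = 1L) {
  m <- as.matrix(count_table(as.matrix(table)))
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  observed <- bray_curtis(m)
  idx <- pair_index(nrow(m))
  obs_bc <- observed[idx]
  occ <- colSums(m > 0)
  abund <- colSums(m)
  null_sum <- numeric(nrow(idx))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      nm <- null_assemble_impl(m, occ, abund)
      null_sum <- null_sum + as.matrix(vegan::vegdist(nm, "bray"))[idx]
    }
  })
  null_mean <- null_sum / n_reps
  dev <- obs_bc - null_mean
  out <- list(pairs = data.frame(sample_i = rownames(m)[idx[, "i"]],
                                 sample_j = rownames(m)[idx[, "j"]],
                                 observed_bc = obs_bc,
                                 null_mean_bc = null_mean,
                                 ndv = dev),
              n_reps = as.integer(n_reps),
              mean_ndv = mean(dev),
              mean_abs_ndv = mean(abs(dev)))
  class(out) <- "ndv_result"
  out
}

#' @export
print.ndv_result <- function(x, digits = 4, ...) {
  cat(sprintf("Beta-null deviation over %d pairs (%d null replicates)\n",
              nrow(x$pairs), x$n_reps))
  cat(sprintf("  mean NDV      : %.*f\n", digits, x$mean_ndv))
  cat(sprintf("  mean |NDV|    : %.*f\n", digits, x$mean_abs_ndv))
  cat(sprintf("  NDV range     : [%.*f, %.*f]\n", digits, min(x$pairs$ndv),
              digits, max(x$pairs$ndv)))
  invisible(x)
}

#' Beta-null deviation per taxonomic group
#'
#' Runs [ndv()] independently on each group's sample x group-OTU sub-table.
#' Samples with zero reads for a group are dropped (with a message); groups
#' left with fewer than 2 non-empty samples are skipped with a warning.
#'
#' @param groups named list of per-group [count_table()] subsets, as returned
#'   by [filter_dominant_groups()].
#' @param n_reps null replicates per group (default 999).
#' @param seed master seed; each group gets a derived sub-seed.
#' @return named list of `ndv_result`, one per retained group.
#' @export
group_ndv <- function(groups, n_reps = 999, seed = 1L) {
  if (!length(groups)) stop("no groups supplied", call. = FALSE)
  out <- list()
  for (k in seq_along(groups)) {
    g <- names(groups)[k]
    sub <- as.matrix(groups[[k]])
    keep <- rowSums(sub) > 0
    if (any(!keep))
      message("group ", g, ": dropping ", sum(!keep), " empty sample(s)")
    sub <- sub[keep, , drop = FALSE]
    if (nrow(sub) < 2) {
      warning("group ", g, " skipped: fewer than 2 non-empty samples",
              call. = FALSE)
      next
    }
    out[[g]] <- ndv(count_table(sub), n_reps = n_reps,
                    seed = sub_seed(seed, k))
  }
  out
}
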