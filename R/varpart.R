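#' Moran's eigenvector map (PCNM) spatial predictors
#'
#' Classical PCNM construction: the geographic distance matrix is truncated
#' at the longest edge of its minimum spanning tree, beyond-threshold entries
#' are replaced by 4x the threshold, the transformed matrix is double-centered
#' and its positive-eigenvalue eigenvectors are returned, each column scaled
#' by the square root of its eigenvalue. Duplicate coordinates (zero
#' off-diagonal distances) are jittered by 1e-6 km with a warning.
#'
#' @param geo symmetric geographic distance matrix in km (>= 4 sites).
#' @return matrix, sites x MEM axes (columns `MEM1`, `MEM2`, ...), with an
#'   attribute `values` holding the eigenvalues.
#' @export
build_mem <- function(geo) {
  geo <- as.matrix(geo)
  if (nrow(geo) < 4) stop("need at least 4 sites for MEM construction",
                          call. = FALSE)
  off <- geo[upper.tri(geo)]
  if (any(off <= 0)) {
    warning("duplicate site coordinates: jittering zero distances by 1e-6 km",
            call. = FALSE)
    geo[geo <= 0] <- 1e-6
    diag(geo) <- 0
  }
  p <- vegan::pcnm(stats::as.dist(geo))
  vec <- sweep(p$vectors, 2, sqrt(p$values[seq_len(ncol(p$vectors))]), "*")
  colnames(vec) <- paste0("MEM", seq_len(ncol(vec)))
  rownames(vec) <- rownames(geo)
  attr(vec, "values") <- p$values[seq_len(ncol(vec))]
  vec
}

#' Forward selection of predictors for community composition
#'
#' Stepwise RDA predictor selection with the double stopping criterion:
#' a candidate enters only if its permutation p-value is below `alpha` and
#' the cumulative adjusted R-squared stays below that of the global
#' (all-candidates) model.
#'
#' @param response community table; Hellinger-transformed when
#'   `transform = "hellinger"` (default, appropriate for counts).
#' @param candidates data.frame or matrix of candidate predictors
#'   (standardized internally).
#' @param alpha entry threshold on the permutation p-value (default 0.05).
#' @param n_perm permutations (default 999).
#' @param seed integer seed (selection is deterministic given it).
#' @param transform `"hellinger"` or `"none"`.
#' @return character vector of selected predictor names (possibly empty).
#' @importFrom vegan rda
#' @export
forward_select <- function(response, candidates, alpha = 0.05, n_perm = 999,
                           seed = 1L, transform = c("hellinger", "none")) {
  transform <- match.arg(transform)
  Y <- as.matrix(response)
  if (transform == "hellinger") Y <- vegan::decostand(Y, "hellinger")
  X <- as.data.frame(scale(as.matrix(candidates)))
  with_seed(seed, {
    # global-model significance gate, then stepwise with double stopping
    m0 <- vegan::rda(Y ~ 1, data = X)
    m1 <- vegan::rda(Y ~ ., data = X)
    gp <- stats::anova(m1, permutations = n_perm)$`Pr(>F)`[1]
    if (is.na(gp) || gp > alpha) {
      character(0)
    } else {
      sel <- vegan::ordiR2step(m0, scope = stats::formula(m1),
                               direction = "forward", Pin = alpha,
                               R2scope = TRUE, permutations = n_perm,
                               trace = FALSE)
      attr(stats::terms(sel), "term.labels")
    }
  })
}

#' Partition community variation into environmental and spatial fractions
#'
#' Redundancy analysis (RDA) of the (Hellinger-transformed) community table
#' on two predictor blocks: environment and space (MEM eigenvectors).
#' Ezekiel-adjusted R-squared of the three models env, spatial, env+spatial
#' yields pure environmental = R2adj(both) - R2adj(spatial), pure spatial =
#' R2adj(both) - R2adj(env), shared = R2adj(env) + R2adj(spatial) -
#' R2adj(both), residual = 1 - R2adj(both). The two pure fractions are tested
#' by permutation on the corresponding partial RDA. Negative adjusted
#' fractions are reported as-is.
#'
#' @param response community table (counts or numeric matrix).
#' @param env environmental predictor block (may be NULL/empty).
#' @param mem spatial predictor block (may be NULL/empty); at least one block
#'   must be non-empty.
#' @param n_perm permutations for the pure-fraction tests (default 999).
#' @param seed integer seed.
#' @param transform `"hellinger"` (default) or `"none"`.
#' @return object of class `varpart_result`: adjusted fractions `pure_env`,
#'   `pure_spatial`, `shared`, `residual`; unadjusted counterparts in
#'   `unadjusted` (summing to 1 exactly); p-values `p_pure_env`,
#'   `p_pure_spatial`; and the block column names.
#' @export
variation_partition <- function(response, env, mem, n_perm = 999, seed = 1L,
                                transform = c("hellinger", "none")) {
  transform <- match.arg(transform)
  has_env <- !is.null(env) && NCOL(env) > 0
  has_mem <- !is.null(mem) && NCOL(mem) > 0
  if (!has_env && !has_mem)
    stop("both predictor blocks are empty", call. = FALSE)
  Y <- as.matrix(response)
  if (transform == "hellinger") Y <- vegan::decostand(Y, "hellinger")
  E <- if (has_env) as.matrix(env) else NULL
  M <- if (has_mem) as.matrix(mem) else NULL
  r2 <- function(X) {
    f <- vegan::rda(Y, X)
    adj <- vegan::RsquareAdj(f)
    c(raw = adj$r.squared, adj = adj$adj.r.squared)
  }
  zero <- c(raw = 0, adj = 0)
  r_env <- if (has_env) r2(E) else zero
  r_mem <- if (has_mem) r2(M) else zero
  r_both <- if (has_env && has_mem) r2(cbind(E, M)) else if (has_env) r_env else r_mem
  frac <- function(v) {
    c(pure_env = unname(r_both[v] - r_mem[v]),
      pure_spatial = unname(r_both[v] - r_env[v]),
      shared = unname(r_env[v] + r_mem[v] - r_both[v]),
      residual = unname(1 - r_both[v]))
  }
  adj <- frac("adj")
  raw <- frac("raw")
  p_env <- p_mem <- NA_real_
  with_seed(seed, {
    if (has_env) {
      f <- if (has_mem) vegan::rda(Y, E, M) else vegan::rda(Y, E)
      p_env <- stats::anova(f, permutations = n_perm)$`Pr(>F)`[1]
    }
    if (has_mem) {
      f <- if (has_env) vegan::rda(Y, M, E) else vegan::rda(Y, M)
      p_mem <- stats::anova(f, permutations = n_perm)$`Pr(>F)`[1]
    }
  })
  out <- list(pure_env = adj[["pure_env"]],
              pure_spatial = adj[["pure_spatial"]],
              shared = adj[["shared"]],
              residual = adj[["residual"]],
              unadjusted = raw,
              p_pure_env = p_env, p_pure_spatial = p_mem,
              selected_env = colnames(E), selected_mem = colnames(M))
  class(out) <- "varpart_result"
  out
}

#' @export
print.varpart_result <- function(x, digits = 4, ...) {
  cat("Variation partitioning (adjusted R2 fractions)\n")
  cat(sprintf("  pure environmental : %.*f  (p = %s)\n", digits, x$pure_env,
              format(x$p_pure_env, digits = 3)))
  cat(sprintf("  pure spatial       : %.*f  (p = %s)\n", digits,
              x$pure_spatial, format(x$p_pure_spatial, digits = 3)))
  cat(sprintf("  shared             : %.*f\n", digits, x$shared))
  cat(sprintf("  residual           : %.*f\n", digits, x$residual))
  invisible(x)
}
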