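#' Distance-decay relationship regression
#'
#' Fits the power-law decay of community similarity with geographic distance,
#' log10 S = a + b log10 D, by ordinary least squares over all unordered
#' sample pairs. Similarity is S = 1 - d for a dissimilarity matrix d (e.g.
#' Bray-Curtis). Pairs with S <= 0 or D < 1 km are excluded (log undefined /
#' below the 1 km floor used to define the initial similarity) and their
#' count is reported. Derived quantities: initial similarity s0 = 10^a
#' (similarity at D = 1 km) and the halving-distance d_h, the distance at
#' which similarity falls to s0 / 2 (see [halving_distance()]).
#'
#' @param community symmetric dissimilarity matrix (sample ids as dimnames).
#' @param geo symmetric geographic distance matrix in km, same ids.
#' @param mantel also run a Mantel permutation test (999 permutations) on the
#'   log-log matrices? Off by default; the headline statistics are the
#'   regression ones.
#' @param seed seed for the Mantel permutations.
#' @return object of class `ddr_fit` with elements `a`, `b`, `r_squared`,
#'   `p_value`, `s0`, `d_h`, `n_pairs`, `n_excluded`, the pairwise data, and
#'   optionally `mantel`.
#' @export
fit_ddr <- function(community, geo, mantel = FALSE, seed = 1L) {
  community <- as.matrix(community)
  geo <- as.matrix(geo)
  ids <- rownames(community)
  if (is.null(ids) || is.null(rownames(geo)))
    stop("both matrices need sample ids as dimnames", call. = FALSE)
  if (!setequal(ids, rownames(geo)))
    stop("sample ids of community and geographic matrices differ",
         call. = FALSE)
  geo <- geo[ids, ids]
  idx <- pair_index(length(ids))
  S <- 1 - community[idx]
  D <- geo[idx]
  usable <- S > 0 & D >= 1
  n_excluded <- sum(!usable)
  if (n_excluded > 0)
    message(n_excluded, " pair(s) excluded (similarity <= 0 or distance < 1 km)")
  if (sum(usable) < 3)
    stop("fewer than 3 usable pairs for the distance-decay regression",
         call. = FALSE)
  x <- log10(D[usable])
  y <- log10(S[usable])
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  if (!is.finite(b))
    stop("degenerate regression: no variation in usable log-distances",
         call. = FALSE)
  s0 <- 10^a
  if (s0 > 1)
    warning("extrapolated initial similarity exceeds 1 (steep fit); ",
            "s0 reported as computed", call. = FALSE)
  if (b < 0) {
    # with the defining relation s0 = 10^a the halving-distance reduces to
    # 10^(-log10(2)/b), valid even when the extrapolated s0 exceeds 1
    d_h <- 10^(-log10(2) / b)
  } else {
    d_h <- NA_real_
    warning("non-negative slope: halving-distance undefined", call. = FALSE)
  }
  out <- list(a = a, b = b,
              r_squared = sm$r.squared,
              p_value = sm$coefficients["x", "Pr(>|t|)"],
              s0 = s0, d_h = d_h,
              n_pairs = sum(usable), n_excluded = n_excluded,
              pairs = data.frame(sample_i = ids[idx[usable, "i"]],
                                 sample_j = ids[idx[usable, "j"]],
                                 distance_km = D[usable],
                                 similarity = S[usable]),
              lm = fit)
  if (mantel) {
    out$mantel <- with_seed(seed,
      vegan::mantel(stats::as.dist(community), stats::as.dist(geo),
                    permutations = 999))
  }
  class(out) <- "ddr_fit"
  out
}

#' @export
print.ddr_fit <- function(x, digits = 4, ...) {
  cat("Distance-decay relationship: log10 S = a + b log10 D\n")
  cat(sprintf("  a (intercept)     : %.*f\n", digits, x$a))
  cat(sprintf("  b (slope)         : %.*f  (p = %.3g)\n", digits, x$b,
              x$p_value))
  cat(sprintf("  R-squared         : %.*f\n", digits, x$r_squared))
  cat(sprintf("  S0 (at 1 km)      : %.*f\n", digits, x$s0))
  cat(sprintf("  halving-distance  : %s km\n",
              if (is.na(x$d_h)) "undefined" else format(x$d_h, digits = digits)))
  cat(sprintf("  pairs used        : %d (%d excluded)\n", x$n_pairs,
              x$n_excluded))
  invisible(x)
}

#' @export
coef.ddr_fit <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' @export
predict.ddr_fit <- function(object, distance_km, ...) {
  if (missing(distance_km)) distance_km <- object$pairs$distance_km
  10^(object$a + object$b * log10(distance_km))
}

#' @export
plot.ddr_fit <- function(x, ...) {
  graphics::plot(log10(x$pairs$distance_km), log10(x$pairs$similarity),
                 xlab = "log10 distance (km)", ylab = "log10 similarity",
                 pch = 16, col = "#00000055", ...)
  graphics::abline(x$a, x$b, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Halving-distance of a distance-decay relationship
#'
#' The distance at which community similarity falls to half the initial
#' similarity `s0`: d_H = 10^((log10(s0 / 2) - a) / b). With the defining
#' relation s0 = 10^a this reduces to 10^(-log10(2) / b).
#'
#' @param a DDR intercept (log10 similarity at 1 km).
#' @param b DDR slope; must be negative for the decay to halve.
#' @param s0 initial similarity in (0, 1]; defaults to 10^a.
#' @return halving-distance in km.
#' @export
halving_distance <- function(a, b, s0 = 10^a) {
  if (!is.finite(b) || b >= 0)
    stop("halving-distance undefined for non-negative slope", call. = FALSE)
  if (!is.finite(s0) || s0 <= 0 || s0 > 1)
    stop("s0 must lie in (0, 1]", call. = FALSE)
  10^((log10(s0 / 2) - a) / b)
}
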