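#' Neutral-model occurrence frequency
#'
#' The Sloan neutral community model predicts the probability that an OTU of
#' metacommunity relative abundance p is detected (>= 1 read in N) in a local
#' community of size N with immigration rate m:
#' Freq = 1 - I(1/N; N m p, N m (1 - p)), where I is the regularized
#' incomplete beta function (the beta cumulative distribution evaluated at
#' the detection threshold 1/N). Limits: p = 0 gives 0, p = 1 gives 1.
#'
#' @param p relative abundance(s) in \[0, 1\] (vectorized).
#' @param m dispersal (immigration) rate in (0, 1].
#' @param N community size, reads per sample (>= 1).
#' @return predicted occurrence frequencies in \[0, 1\].
#' @export
predicted_frequency <- function(p, m, N) {
  stopifnot_scalar_prob(m, "m")
  if (!is.numeric(N) || length(N) != 1L || N < 1)
    stop("`N` must be a single value >= 1", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  out <- numeric(length(p))
  mid <- p > 0 & p < 1
  out[p == 0] <- 0
  out[p == 1] <- 1
  if (any(mid))
    out[mid] <- 1 - stats::pbeta(1 / N, N * m * p[mid], N * m * (1 - p[mid]))
  out
}

#' Fit the Sloan neutral community model
#'
#' Estimates the dispersal rate m by least squares of observed occurrence
#' frequencies Freq_i (fraction of samples where OTU i is detected) on the
#' neutral prediction [predicted_frequency()] evaluated at each OTU's mean
#' relative abundance p_i, with N the common rarefaction depth. Fit quality
#' is the generalized R-squared 1 - SSerr/SStotal (not clipped; it can be
#' negative for poor fits). Wilson 95% score intervals around the predicted
#' frequencies partition OTUs into those above, within, or below the neutral
#' band.
#'
#' @param table a rarefied [count_table()] (equal row sums) with >= 10 OTUs
#'   of positive abundance.
#' @param ci_z normal quantile for the Wilson band (default 1.96).
#' @return object of class `sloan_fit` with `m`, `n_individuals`,
#'   `r_squared`, `n_samples`, and per-OTU data.frame `otus` (`p`, `freq`,
#'   `predicted`, `ci_lower`, `ci_upper`, `partition`).
#' @export
fit_sloan <- function(table, ci_z = 1.96) {
  mtab <- as.matrix(count_table(as.matrix(table)))
  rs <- rowSums(mtab)
  if (length(unique(rs)) != 1L)
    stop("row sums unequal: rarefy() the table to a common depth first",
         call. = FALSE)
  N <- rs[1]
  keep <- colSums(mtab) > 0
  mtab <- mtab[, keep, drop = FALSE]
  p <- colMeans(mtab) / N
  freq <- colMeans(mtab > 0)
  if (length(p) < 10)
    stop("need at least 10 OTUs with positive abundance", call. = FALSE)
  sse <- function(m) sum((freq - predicted_frequency(p, m, N))^2)
  starts <- c(0.01, 0.1, 0.5)
  fits <- lapply(starts, function(s)
    stats::nlminb(s, sse, lower = 1e-6, upper = 1))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  if (best$convergence != 0 && !is.finite(best$objective))
    stop("neutral-model fit failed to converge: ", best$message,
         call. = FALSE)
  m_hat <- best$par
  pred <- predicted_frequency(p, m_hat, N)
  ss_err <- sum((freq - pred)^2)
  ss_tot <- sum((freq - mean(freq))^2)
  ci <- wilson_ci(pred, nrow(mtab), z = ci_z)
  partition <- ifelse(freq > ci[, "upper"], "above",
                      ifelse(freq < ci[, "lower"], "below", "within"))
  out <- list(m = m_hat, n_individuals = as.integer(N),
              r_squared = 1 - ss_err / ss_tot,
              n_samples = nrow(mtab),
              otus = data.frame(otu_id = colnames(mtab), p = p, freq = freq,
                                predicted = pred,
                                ci_lower = ci[, "lower"],
                                ci_upper = ci[, "upper"],
                                partition = partition, row.names = NULL))
  class(out) <- "sloan_fit"
  out
}

#' @export
print.sloan_fit <- function(x, digits = 4, ...) {
  cat("Sloan neutral community model\n")
  cat(sprintf("  m (dispersal rate) : %.*f\n", digits, x$m))
  cat(sprintf("  N (reads/sample)   : %d\n", x$n_individuals))
  cat(sprintf("  generalized R2     : %.*f\n", digits, x$r_squared))
  tab <- table(x$otus$partition)
  cat("  OTU partition      :",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.sloan_fit <- function(object, ...) c(m = object$m)

#' @export
predict.sloan_fit <- function(object, p, ...) {
  if (missing(p)) p <- object$otus$p
  predicted_frequency(p, object$m, object$n_individuals)
}

#' @export
plot.sloan_fit <- function(x, ...) {
  o <- x$otus[order(x$otus$p), ]
  graphics::plot(log10(o$p), o$freq, pch = 16, col = "#00000055",
                 xlab = "log10 mean relative abundance",
                 ylab = "occurrence frequency", ylim = c(0, 1), ...)
  graphics::lines(log10(o$p), o$predicted, col = "firebrick", lwd = 2)
  graphics::lines(log10(o$p), o$ci_lower, col = "firebrick", lty = 2)
  graphics::lines(log10(o$p), o$ci_upper, col = "firebrick", lty = 2)
  invisible(x)
}

#' Wilson score confidence interval for a proportion
#'
#' @param freq_hat observed/predicted proportion(s) in \[0, 1\].
#' @param n number of trials (samples).
#' @param z normal quantile (default 1.96 for 95%).
#' @return matrix with columns `lower` and `upper`, always within \[0, 1\].
#' @export
wilson_ci <- function(freq_hat, n, z = 1.96) {
  if (any(freq_hat < 0 | freq_hat > 1)) stop("freq_hat must lie in [0, 1]",
                                             call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  denom <- 1 + z^2 / n
  center <- (freq_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(freq_hat * (1 - freq_hat) / n + z^2 / (4 * n^2)) / denom
  cbind(lower = pmax(0, center - half), upper = pmin(1, center + half))
}

#' Compare the neutral fit with a binomial random-sampling model
#'
#' The binomial model predicts detection under pure random subsampling of the
#' metacommunity, Freq_i = 1 - (1 - p_i)^N, i.e. no drift and no dispersal
#' limitation. Both models are scored by the least-squares AIC
#' n ln(SSerr/n) + 2k (k = 1 for the neutral model's fitted m, k = 0 for the
#' parameter-free binomial) on `n_boot` bootstrap resamples of the OTUs; the
#' neutral m is refit on every resample.
#'
#' @param table the rarefied [count_table()] used for `fit`.
#' @param fit a [fit_sloan()] result.
#' @param n_boot bootstrap replicates (default 1000); `n_boot = 1` scores the
#'   original OTU set once.
#' @param seed integer seed.
#' @return list with `aic_neutral`, `aic_binomial` (means over replicates),
#'   `delta_aic` (neutral - binomial, mean), `delta_ci` (2.5/97.5
#'   percentiles), `binomial_predicted` per OTU, and the per-replicate AICs.
#' @export
compare_binomial <- function(table, fit, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(fit, "sloan_fit"))
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  p <- fit$otus$p
  freq <- fit$otus$freq
  N <- fit$n_individuals
  n <- length(p)
  binom_pred_all <- 1 - (1 - p)^N
  aic_ls <- function(sse, k) n * log(sse / n) + 2 * k
  one_rep <- function(ii) {
    pp <- p[ii]; ff <- freq[ii]
    sse_n <- function(m) sum((ff - predicted_frequency(pp, m, N))^2)
    opt <- stats::nlminb(fit$m, sse_n, lower = 1e-6, upper = 1)
    c(neutral = aic_ls(opt$objective, 1),
      binomial = aic_ls(sum((ff - (1 - (1 - pp)^N))^2), 0))
  }
  reps <- with_seed(seed, {
    if (n_boot == 1L) {
      matrix(one_rep(seq_len(n)), nrow = 1,
             dimnames = list(NULL, c("neutral", "binomial")))
    } else {
      t(vapply(seq_len(n_boot),
               function(b) one_rep(sample.int(n, n, replace = TRUE)),
               c(neutral = 0, binomial = 0)))
    }
  })
  delta <- reps[, "neutral"] - reps[, "binomial"]
  list(aic_neutral = mean(reps[, "neutral"]),
       aic_binomial = mean(reps[, "binomial"]),
       delta_aic = mean(delta),
       delta_ci = stats::quantile(delta, c(0.025, 0.975), names = FALSE),
       binomial_predicted = binom_pred_all,
       replicates = reps)
}
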