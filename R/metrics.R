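#' Pairwise Bray-Curtis dissimilarity
#'
#' BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i) between the abundance vectors of
#' every sample pair.
#'
#' @param table a [count_table()] (or numeric matrix) with positive row sums.
#' @return symmetric matrix of dissimilarities in \[0, 1\] with zero diagonal,
#'   sample ids as dimnames.
#' @export
bray_curtis <- function(table) {
  m <- as.matrix(table)
  if (any(rowSums(m) <= 0))
    stop("all-zero sample(s): ",
         paste(rownames(m)[rowSums(m) <= 0], collapse = ", "), call. = FALSE)
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Observed richness and Chao1 per sample
#'
#' Richness is the number of OTUs with a positive count. Chao1 is
#' S_obs + F1^2 / (2 F2) where F1 and F2 are the numbers of singleton and
#' doubleton OTUs; when F2 = 0 the bias-corrected form
#' S_obs + F1 (F1 - 1) / (2 (F2 + 1)) is used instead.
#'
#' @param table a [count_table()] of integer counts (post-rarefaction).
#' @return data.frame with columns `sample_id`, `richness`, `chao1`.
#' @export
alpha_diversity <- function(table) {
  m <- as.matrix(count_table(as.matrix(table)))
  res <- t(apply(m, 1, function(x) {
    s <- sum(x > 0)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    chao <- if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / (2 * (f2 + 1))
    c(richness = s, chao1 = chao)
  }))
  data.frame(sample_id = rownames(m), richness = res[, "richness"],
             chao1 = res[, "chao1"], row.names = NULL)
}

#' Great-circle distances between sampling sites
#'
#' Haversine formula on a sphere of radius 6371 km.
#'
#' @param samples a [sample_info()] data.frame (needs `sample_id`,
#'   `latitude`, `longitude`).
#' @return symmetric matrix of distances in km, sample ids as dimnames.
#' @export
geographic_distance <- function(samples) {
  samples <- sample_info(as.data.frame(samples))
  lat <- samples$latitude * pi / 180
  lon <- samples$longitude * pi / 180
  n <- length(lat)
  R <- 6371
  d <- matrix(0, n, n, dimnames = list(samples$sample_id, samples$sample_id))
  for (i in seq_len(n)) {
    dlat <- lat - lat[i]
    dlon <- lon - lon[i]
    a <- sin(dlat / 2)^2 + cos(lat[i]) * cos(lat) * sin(dlon / 2)^2
    d[i, ] <- 2 * R * asin(pmin(1, sqrt(a)))
  }
  d
}
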