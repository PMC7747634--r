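#' Standardize environmental covariates (optionally rotating to PCA axes)
#'
#' Each selected variable is centered to mean 0 and scaled to population
#' (divide-by-n) standard deviation 1. With `pca = TRUE` the standardized
#' table is further rotated onto its principal axes, keeping every component
#' with non-null variance; the rotation is orthogonal, so total variance and
#' all OMI values are unchanged.
#'
#' @param samples a [sample_info()] data.frame.
#' @param variables covariate names; default all columns other than
#'   `sample_id`, `latitude`, `longitude`.
#' @param pca rotate onto principal axes? Default TRUE.
#' @return numeric matrix, sites x axes, sample ids as rownames.
#' @export
standardize_environment <- function(samples, variables = NULL, pca = TRUE) {
  samples <- sample_info(as.data.frame(samples))
  if (nrow(samples) < 2) stop("need at least 2 sites", call. = FALSE)
  if (is.null(variables))
    variables <- setdiff(names(samples), c("sample_id", "latitude", "longitude"))
  if (!length(variables)) stop("no environmental variables found", call. = FALSE)
  miss <- setdiff(variables, names(samples))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  x <- as.matrix(samples[, variables, drop = FALSE])
  n <- nrow(x)
  ctr <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  if (any(sdev == 0))
    stop("constant environmental variable(s): ",
         paste(variables[sdev == 0], collapse = ", "), call. = FALSE)
  z <- sweep(sweep(x, 2, ctr), 2, sdev, "/")
  rownames(z) <- samples$sample_id
  if (pca) {
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
    keep <- pc$sdev > 1e-10 * pc$sdev[1]
    z <- pc$x[, keep, drop = FALSE]
  }
  z
}

#' Outlying Mean Index per OTU
#'
#' An OTU's niche position is the abundance-weighted average of the site
#' coordinates in standardized environmental space; its OMI is the squared
#' Euclidean distance between that position and the unweighted mean condition
#' of the study area (the origin after centering). Low OMI = typical
#' conditions used = wide niche breadth; high OMI = marginal niche.
#'
#' @param table a [count_table()].
#' @param env standardized site x axis matrix from
#'   [standardize_environment()], same sample ids.
#' @return data.frame with `otu_id`, `omi`, `weight` (OTU total reads) and one
#'   `axis*` column per environmental axis (the niche position). OTUs absent
#'   everywhere are excluded.
#' @export
omi_per_otu <- function(table, env) {
  m <- as.matrix(count_table(as.matrix(table)))
  env <- as.matrix(env)
  if (is.null(rownames(env)) || !setequal(rownames(m), rownames(env)))
    stop("sample ids of table and environment differ", call. = FALSE)
  env <- env[rownames(m), , drop = FALSE]
  tot <- colSums(m)
  keep <- tot > 0
  m <- m[, keep, drop = FALSE]
  tot <- tot[keep]
  center <- colMeans(env)
  # niche positions: (t(counts) %*% env) / total, one row per OTU
  np <- crossprod(m, env) / tot
  dev <- sweep(np, 2, center)
  omi <- rowSums(dev^2)
  out <- data.frame(otu_id = colnames(m), omi = omi, weight = tot,
                    row.names = NULL)
  np_df <- as.data.frame(np)
  names(np_df) <- paste0("axis", seq_len(ncol(np)))
  cbind(out, np_df)
}

#' Group summaries of OMI
#'
#' @param records per-OTU data.frame from [omi_per_otu()].
#' @param taxa taxon map (columns `otu_id`, `group`).
#' @return data.frame with per-group OTU count, unweighted mean OMI and
#'   abundance-weighted mean OMI. Groups with no scored OTUs are skipped with
#'   a warning.
#' @export
group_omi <- function(records, taxa) {
  if (!nrow(records)) stop("no OMI records", call. = FALSE)
  taxa <- as_taxon_map(taxa)
  grp <- taxa$group[match(records$otu_id, taxa$otu_id)]
  if (anyNA(grp))
    stop("OTUs missing from the taxon map: ",
         paste(utils::head(records$otu_id[is.na(grp)], 5), collapse = ", "),
         call. = FALSE)
  empty <- setdiff(unique(taxa$group), unique(grp))
  if (length(empty))
    warning("group(s) with no scored OTUs skipped: ",
            paste(empty, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, lapply(split(records, grp), function(d) {
    data.frame(group = grp[match(d$otu_id[1], records$otu_id)],
               n_otus = nrow(d),
               mean_omi = mean(d$omi),
               weighted_mean_omi = sum(d$omi * d$weight) / sum(d$weight))
  }))
  rownames(out) <- NULL
  out
}
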