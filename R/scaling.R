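#' Regress an assembly metric on log10 body size
#'
#' Ordinary least squares of a chosen metric on log10(size_um), with Pearson
#' R-squared and a two-sided t test on the slope. `scope = "within-kingdom"`
#' fits one regression per kingdom (requires a `kingdom` column).
#'
#' @param metrics data.frame of per-group metrics with columns `size_um`, the
#'   response, and optionally `kingdom` (e.g. from [run_pipeline()]).
#' @param response name of the metric column to regress.
#' @param scope `"all"` (one fit) or `"within-kingdom"`.
#' @return data.frame of class `size_scaling` with columns `scope`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
regress_on_size <- function(metrics, response,
                            scope = c("all", "within-kingdom")) {
  scope <- match.arg(scope)
  if (!response %in% names(metrics))
    stop("no metric column '", response, "'", call. = FALSE)
  if (!"size_um" %in% names(metrics))
    stop("no 'size_um' column: body sizes unavailable for this study",
         call. = FALSE)
  fit_one <- function(d, label) {
    d <- d[is.finite(d[[response]]) & is.finite(d$size_um), ]
    if (nrow(d) < 3)
      stop("fewer than 3 groups with finite '", response, "' in scope ",
           label, call. = FALSE)
    f <- stats::lm(d[[response]] ~ log10(d$size_um))
    sm <- suppressWarnings(summary(f))
    data.frame(scope = label,
               slope = unname(stats::coef(f)[2]),
               intercept = unname(stats::coef(f)[1]),
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, "Pr(>|t|)"],
               n = nrow(d))
  }
  out <- if (scope == "all") {
    fit_one(metrics, "all")
  } else {
    if (!"kingdom" %in% names(metrics))
      stop("within-kingdom scope needs a 'kingdom' column", call. = FALSE)
    do.call(rbind, lapply(split(metrics, metrics$kingdom),
                          function(d) fit_one(d, d$kingdom[1])))
  }
  rownames(out) <- NULL
  class(out) <- c("size_scaling", class(out))
  out
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' @param values numeric metric values.
#' @param category grouping factor (>= 2 levels, >= 2 values each).
#' @return list with `f_statistic`, `p_value`, `tukey` (pairwise table) and
#'   `letters` (groups sharing a letter are not significantly different at
#'   0.05).
#' @export
compare_groups <- function(values, category) {
  category <- factor(category)
  if (nlevels(category) < 2) stop("need at least 2 categories", call. = FALSE)
  sizes <- table(category)
  if (any(sizes < 2))
    stop("categories with fewer than 2 values: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  fit <- stats::aov(values ~ category)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$category
  list(f_statistic = sm[["F value"]][1],
       p_value = sm[["Pr(>F)"]][1],
       tukey = tk,
       letters = cld_letters(levels(category), tk))
}

# Compact letter display by insert-and-absorb over the Tukey p-value matrix.
cld_letters <- function(lev, tukey, alpha = 0.05) {
  k <- length(lev)
  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  for (r in rownames(tukey)) {
    pr <- strsplit(r, "-", fixed = TRUE)[[1]]
    s <- tukey[r, "p adj"] < alpha
    sig[pr[1], pr[2]] <- sig[pr[2], pr[1]] <- s
  }
  groups <- list(lev[1])
  for (g in lev[-1]) {
    placed <- FALSE
    for (i in seq_along(groups)) {
      if (!any(sig[g, groups[[i]]])) {
        groups[[i]] <- c(groups[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- g
  }
  # absorb redundant letter groups
  keep <- rep(TRUE, length(groups))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i != j && keep[j] && all(groups[[i]] %in% groups[[j]]) &&
          length(groups[[i]]) < length(groups[[j]])) keep[i] <- FALSE
    }
  }
  groups <- groups[keep]
  out <- vapply(lev, function(g)
    paste(letters[which(vapply(groups, function(gr) g %in% gr, TRUE))],
          collapse = ""), "")
  out
}

#' Run the full assembly-analysis pipeline on a study
#'
#' Rarefies the table (when row sums are unequal), splits it into dominant
#' groups, and computes per group: alpha diversity, the distance-decay
#' regression, the beta-null deviation, the Sloan neutral fit, mean OMI, and
#' (optionally) variation partitioning with MEM forward selection. Failures
#' in one group/stage are caught and reported; the affected metrics are NA.
#'
#' @param study a `synthetic_study` (from [generate_study()]) or a study
#'   directory path readable by [read_study()].
#' @param depth rarefaction depth; default the minimum row sum.
#' @param n_reps null replicates for the NDV stage (default 999).
#' @param n_perm permutations for variation partitioning (default 999).
#' @param min_rel_abund,min_presence dominant-group thresholds (see
#'   [filter_dominant_groups()]).
#' @param stages subset of
#'   `c("alpha","ddr","ndv","neutral","omi","varpart")` to run.
#' @param seed master seed; every stochastic stage derives a sub-seed from it.
#' @param manifest_path optional path to write a JSON run manifest (seeds,
#'   parameters, group list).
#' @return data.frame of class `group_metrics`: one row per retained group
#'   with `group`, `size_um`, `kingdom` (if available), `mean_ndv`, `m`,
#'   `mean_omi`, `ddr_slope`, `d_h`, `s0`, `chao1_mean`, `richness_mean`,
#'   `pure_env`, `pure_spatial`. Stage objects are attached as attribute
#'   `details`.
#' @export
run_pipeline <- function(study, depth = NULL, n_reps = 999, n_perm = 999,
                         min_rel_abund = 0.01, min_presence = 0.80,
                         stages = c("alpha", "ddr", "ndv", "neutral", "omi",
                                    "varpart"),
                         seed = 1L, manifest_path = NULL) {
  if (is.character(study)) study <- read_study(study)
  stages <- match.arg(stages, several.ok = TRUE)
  table <- count_table(as.matrix(study$table))
  if (length(unique(rowSums(table))) > 1L) {
    if (is.null(depth)) depth <- min(rowSums(table))
    table <- rarefy(table, depth, seed = sub_seed(seed, 90L))
  }
  groups <- filter_dominant_groups(table, study$taxa, min_rel_abund,
                                   min_presence)
  if (!length(groups)) stop("no dominant groups retained", call. = FALSE)
  geo <- geographic_distance(study$samples)
  env <- standardize_environment(study$samples)
  mem <- if ("varpart" %in% stages) build_mem(geo) else NULL
  details <- list()
  rows <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    g <- names(groups)[k]
    sub <- groups[[k]]
    row <- list(group = g, mean_ndv = NA_real_, m = NA_real_,
                mean_omi = NA_real_, ddr_slope = NA_real_, d_h = NA_real_,
                s0 = NA_real_, chao1_mean = NA_real_,
                richness_mean = NA_real_, pure_env = NA_real_,
                pure_spatial = NA_real_)
    det <- list()
    try_stage <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        warning("group ", g, ", stage ", name, " failed: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    }
    if ("alpha" %in% stages) {
      ad <- try_stage("alpha", alpha_diversity(sub))
      if (!is.null(ad)) {
        row$chao1_mean <- mean(ad$chao1)
        row$richness_mean <- mean(ad$richness)
        det$alpha <- ad
      }
    }
    if ("ddr" %in% stages) {
      dd <- try_stage("ddr", {
        keep <- rowSums(as.matrix(sub)) > 0
        fit_ddr(bray_curtis(sub[keep, ]),
                geo[rownames(as.matrix(sub))[keep],
                    rownames(as.matrix(sub))[keep]])
      })
      if (!is.null(dd)) {
        row$ddr_slope <- dd$b
        row$d_h <- dd$d_h
        row$s0 <- dd$s0
        det$ddr <- dd
      }
    }
    if ("ndv" %in% stages) {
      nv <- try_stage("ndv", group_ndv(groups[k], n_reps = n_reps,
                                       seed = sub_seed(seed, 10L + k))[[g]])
      if (!is.null(nv)) {
        row$mean_ndv <- nv$mean_ndv
        det$ndv <- nv
      }
    }
    if ("neutral" %in% stages) {
      # group sub-tables have unequal per-sample group reads: rarefy the
      # sub-table to its minimum positive row sum so N is well defined
      sf <- try_stage("neutral", {
        subm <- as.matrix(sub)
        subm <- subm[rowSums(subm) > 0, , drop = FALSE]
        fit_sloan(rarefy(count_table(subm), min(rowSums(subm)),
                         seed = sub_seed(seed, 50L + k)))
      })
      if (!is.null(sf)) {
        row$m <- sf$m
        det$neutral <- sf
      }
    }
    if ("omi" %in% stages) {
      om <- try_stage("omi", omi_per_otu(sub, env))
      if (!is.null(om)) {
        row$mean_omi <- mean(om$omi)
        det$omi <- om
      }
    }
    if ("varpart" %in% stages) {
      vp <- try_stage("varpart", {
        sel_env <- forward_select(sub, as.data.frame(env),
                                  n_perm = n_perm,
                                  seed = sub_seed(seed, 20L + k))
        sel_mem <- forward_select(sub, as.data.frame(mem),
                                  n_perm = n_perm,
                                  seed = sub_seed(seed, 30L + k))
        if (!length(sel_env) && !length(sel_mem)) NULL
        else variation_partition(sub,
                                 env[, sel_env, drop = FALSE],
                                 mem[, sel_mem, drop = FALSE],
                                 n_perm = n_perm,
                                 seed = sub_seed(seed, 40L + k))
      })
      if (!is.null(vp)) {
        row$pure_env <- vp$pure_env
        row$pure_spatial <- vp$pure_spatial
        det$varpart <- vp
      }
    }
    details[[g]] <- det
    rows[[k]] <- as.data.frame(row)
  }
  out <- do.call(rbind, rows)
  if (!is.null(study$sizes)) {
    out$size_um <- study$sizes$size_um[match(out$group, study$sizes$group)]
    if ("kingdom" %in% names(study$sizes))
      out$kingdom <- study$sizes$kingdom[match(out$group, study$sizes$group)]
  }
  attr(out, "details") <- details
  attr(out, "manifest") <- list(seed = seed, n_reps = n_reps, n_perm = n_perm,
                                depth = if (is.null(depth))
                                  unique(rowSums(table))[1] else depth,
                                min_rel_abund = min_rel_abund,
                                min_presence = min_presence,
                                stages = stages, groups = names(groups),
                                timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(manifest_path))
    jsonlite::write_json(attr(out, "manifest"), manifest_path,
                         auto_unbox = TRUE, digits = NA)
  class(out) <- c("group_metrics", class(out))
  out
}

#' Pool beta-null deviations across many studies (meta-analysis harness)
#'
#' Computes per-group NDVs for each study independently and stacks the group
#' summaries with the study's ecosystem label, so size-scaling regressions
#' can be run within ecosystem strata. Malformed studies are skipped with a
#' message.
#'
#' @param studies list of study directories or `synthetic_study` objects.
#' @param ecosystems character vector of ecosystem labels, one per study.
#' @param n_reps null replicates per group (default 999).
#' @param seed master seed.
#' @param min_rel_abund,min_presence dominant-group thresholds.
#' @return data.frame with columns `study`, `ecosystem`, `group`, `size_um`
#'   (when available), `kingdom` (when available), `mean_ndv`, `n_pairs`.
#' @export
meta_batch <- function(studies, ecosystems = NULL, n_reps = 999, seed = 1L,
                       min_rel_abund = 0.01, min_presence = 0.80) {
  if (length(studies) < 2) stop("need at least 2 studies", call. = FALSE)
  if (is.null(ecosystems)) ecosystems <- rep("unlabelled", length(studies))
  stopifnot(length(ecosystems) == length(studies))
  rows <- list()
  for (s in seq_along(studies)) {
    study <- studies[[s]]
    res <- tryCatch({
      if (is.character(study)) study <- read_study(study)
      groups <- filter_dominant_groups(study$table, study$taxa,
                                       min_rel_abund, min_presence)
      # one shared seed so identical studies yield identical NDVs
      nd <- group_ndv(groups, n_reps = n_reps, seed = seed)
      do.call(rbind, lapply(names(nd), function(g) {
        size <- if (!is.null(study$sizes))
          study$sizes$size_um[match(g, study$sizes$group)] else NA_real_
        kingdom <- if (!is.null(study$sizes) &&
                       "kingdom" %in% names(study$sizes))
          study$sizes$kingdom[match(g, study$sizes$group)] else NA_character_
        data.frame(study = s, ecosystem = ecosystems[s], group = g,
                   size_um = size, kingdom = kingdom,
                   mean_ndv = nd[[g]]$mean_ndv,
                   n_pairs = nrow(nd[[g]]$pairs))
      }))
    }, error = function(e) {
      message("study ", s, " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
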