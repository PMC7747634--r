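#' Simulation configuration for a synthetic community-assembly study
#'
#' Defines the ground truth of a synthetic survey: a 1-D landscape with a
#' spatially autocorrelated environmental gradient, and per-group assembly
#' parameters — dispersal probability `m_true` (fraction of deaths replaced
#' by metacommunity immigrants) and Gaussian niche breadth `sigma_true` (in
#' environmental units; small sigma = strong selection).
#'
#' Defaults emulate a 45-site survey spanning 4165 km with eight organism
#' groups whose propagule sizes span 0.4-904 um. By default the assembly
#' parameters are coupled to body size — `m_true` strictly decreasing and
#' selection strength `1/sigma_true` strictly increasing in log10(size) — the
#' hypothesis that smaller organisms disperse more and are filtered less.
#' `size_coupling = FALSE` gives every group the middle parameter values, a
#' null world for calibration.
#'
#' @param n_sites number of sampling sites (default 45).
#' @param n_otus_per_group OTUs per group metacommunity (default 80).
#' @param depth rarefaction depth, reads per sample (default 2000).
#' @param n_individuals local community size N for the birth-death dynamics
#'   (default 5000; must be >= depth).
#' @param generations birth-death generations (N events each) per site
#'   (default 50).
#' @param groups data.frame with columns `label`, `size_um`, `m_true`,
#'   `sigma_true` and optionally `kingdom`; defaults built from
#'   `size_coupling`.
#' @param extent_km transect span in km (default 4165).
#' @param env_range numeric length-2, range of the environmental covariate
#'   (default c(0, 10), arbitrary units).
#' @param autocorr_length_km e-folding distance of environmental
#'   autocorrelation (default 1000 km).
#' @param size_coupling couple m_true and sigma_true to body size? Only used
#'   when `groups` is NULL.
#' @param seed master seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_sites = 45, n_otus_per_group = 80,
                              depth = 2000, n_individuals = 5000,
                              generations = 50, groups = NULL,
                              extent_km = 4165, env_range = c(0, 10),
                              autocorr_length_km = 1000,
                              size_coupling = TRUE, seed = 1L) {
  if (is.null(groups)) groups <- default_groups(env_range, size_coupling)
  stopifnot(n_sites >= 2, n_otus_per_group >= 2, depth >= 1,
            n_individuals >= depth, generations >= 1, extent_km > 0,
            length(env_range) == 2, autocorr_length_km > 0)
  if (!all(c("label", "size_um", "m_true", "sigma_true") %in% names(groups)))
    stop("groups needs columns label, size_um, m_true, sigma_true",
         call. = FALSE)
  if (any(groups$m_true <= 0 | groups$m_true > 1))
    stop("m_true must lie in (0, 1]", call. = FALSE)
  if (any(groups$sigma_true <= 0)) stop("sigma_true must be > 0", call. = FALSE)
  if (any(groups$size_um <= 0)) stop("size_um must be > 0", call. = FALSE)
  structure(list(n_sites = as.integer(n_sites),
                 n_otus_per_group = as.integer(n_otus_per_group),
                 depth = as.integer(depth),
                 n_individuals = as.integer(n_individuals),
                 generations = as.integer(generations),
                 groups = groups, extent_km = extent_km,
                 env_range = env_range,
                 autocorr_length_km = autocorr_length_km,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Eight groups, sizes log-spaced over the 0.4-904 um propagule range.
# Coupled world: m_true from 0.5 down to 0.02 (log-linear in log size),
# sigma_true from 8 down to 0.8 environmental units (1/sigma log-linear).
default_groups <- function(env_range, size_coupling) {
  sizes <- 10^seq(log10(0.4), log10(904), length.out = 8)
  kingdom <- c("bacteria", "bacteria", "fungi", "fungi",
               "protists", "protists", "nematodes", "nematodes")
  t01 <- (log10(sizes) - log10(0.4)) / (log10(904) - log10(0.4))
  if (size_coupling) {
    m <- 10^(log10(0.5) + t01 * (log10(0.02) - log10(0.5)))
    sig <- 10^(log10(8) + t01 * (log10(0.8) - log10(8)))
  } else {
    m <- rep(0.1, 8)
    sig <- rep(2.5, 8)
  }
  data.frame(label = sprintf("G%02d", 1:8), size_um = sizes, m_true = m,
             sigma_true = sig, kingdom = kingdom, stringsAsFactors = FALSE)
}

#' Generate a 1-D transect landscape with an autocorrelated environment
#'
#' Sites are evenly spaced on a north-south transect of length `extent_km`
#' along a fixed meridian. The environmental covariate `env` is a linear
#' trend across `env_range` plus zero-mean Gaussian noise whose correlation
#' decays as exp(-d / autocorr_length_km); as the autocorrelation length goes
#' to infinity the noise degenerates to a single shared offset and the field
#' is a pure linear trend.
#'
#' @param n_sites number of sites (>= 2).
#' @param extent_km transect length, km (> 0).
#' @param autocorr_length_km autocorrelation e-folding scale, km (may be Inf).
#' @param env_range length-2 numeric range spanned by the deterministic trend.
#' @param seed integer seed.
#' @param noise_sd standard deviation of the correlated noise, default 10% of
#'   the environmental range.
#' @return a [sample_info()] data.frame with one covariate column `env`.
#' @export
generate_landscape <- function(n_sites, extent_km = 4165,
                               autocorr_length_km = 1000,
                               env_range = c(0, 10), seed = 1L,
                               noise_sd = 0.1 * diff(range(env_range))) {
  if (n_sites < 2) stop("need at least 2 sites", call. = FALSE)
  if (extent_km <= 0) stop("extent_km must be positive", call. = FALSE)
  pos <- seq(0, extent_km, length.out = n_sites)
  km_per_deg <- 6371 * pi / 180
  lat0 <- -extent_km / (2 * km_per_deg)
  lat <- lat0 + pos / km_per_deg
  trend <- env_range[1] + (pos / extent_km) * diff(env_range)
  noise <- with_seed(seed, {
    if (is.infinite(autocorr_length_km)) {
      rep(stats::rnorm(1, 0, noise_sd), n_sites)
    } else {
      D <- abs(outer(pos, pos, "-"))
      K <- exp(-D / autocorr_length_km) + diag(1e-9, n_sites)
      drop(t(chol(K)) %*% stats::rnorm(n_sites, 0, noise_sd))
    }
  })
  sample_info(data.frame(sample_id = sprintf("S%03d", seq_len(n_sites)),
                         latitude = lat, longitude = 115,
                         env = trend + noise, stringsAsFactors = FALSE))
}

#' Draw a lognormal metacommunity rank-abundance vector
#'
#' @param n_otus number of OTUs (>= 2).
#' @param seed integer seed.
#' @param sdlog lognormal shape parameter (default 1.2).
#' @return relative abundances summing to 1, all positive.
#' @export
simulate_metacommunity <- function(n_otus, seed = 1L, sdlog = 1.2) {
  if (n_otus < 2) stop("need at least 2 OTUs", call. = FALSE)
  ab <- with_seed(seed, stats::rlnorm(n_otus, meanlog = 0, sdlog = sdlog))
  ab / sum(ab)
}

#' Simulate one local community under neutral birth-death-immigration dynamics
#'
#' Moran-type zero-sum update: at each step one random individual dies and is
#' replaced, with probability `m`, by an immigrant drawn from the
#' metacommunity relative abundances, otherwise by the offspring of a random
#' surviving local individual. The community starts as a multinomial draw
#' from `meta` and runs `N * generations` steps.
#'
#' @param meta metacommunity relative abundances (sums to 1).
#' @param m immigration (dispersal) probability in (0, 1].
#' @param N local community size (individuals).
#' @param generations number of generations (N events each), default 50.
#' @param seed integer seed.
#' @return integer count vector of length `length(meta)` summing to `N`.
#' @export
simulate_neutral_local <- function(meta, m, N, generations = 50, seed = 1L) {
  stopifnot_scalar_prob(m, "m")
  if (abs(sum(meta) - 1) > 1e-6) stop("meta must sum to 1", call. = FALSE)
  if (any(meta < 0)) stop("meta must be non-negative", call. = FALSE)
  if (N < 1 || generations < 1) stop("N and generations must be positive",
                                     call. = FALSE)
  with_seed(seed, {
    init <- as.integer(stats::rmultinom(1, N, meta))
    moran_sim(meta, init, m, as.numeric(N) * generations)
  })
}

#' Simulate one local community under Gaussian niche selection
#'
#' A multinomial draw with probabilities proportional to
#' meta_i * exp(-(env_site - mu_i)^2 / (2 sigma^2)): the metacommunity
#' filtered by how far each OTU's environmental optimum lies from the site's
#' condition. sigma -> Inf recovers plain multinomial sampling.
#'
#' @param meta metacommunity relative abundances.
#' @param env_site environmental value at the site.
#' @param mu per-OTU environmental optima (same length as `meta`).
#' @param sigma niche breadth (> 0), environmental units.
#' @param N reads/individuals to draw.
#' @param seed integer seed.
#' @return integer count vector summing to `N`.
#' @export
simulate_niche_local <- function(meta, env_site, mu, sigma, N, seed = 1L) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (length(mu) != length(meta)) stop("mu and meta lengths differ",
                                       call. = FALSE)
  w <- niche_weights(meta, env_site, mu, sigma)
  with_seed(seed, as.integer(stats::rmultinom(1, N, w)))
}

niche_weights <- function(meta, env_site, mu, sigma) {
  w <- meta * exp(-(env_site - mu)^2 / (2 * sigma^2))
  if (!any(w > 0))
    stop("all niche fitness weights underflowed to zero; increase sigma",
         call. = FALSE)
  w / sum(w)
}

#' Generate a full synthetic study
#'
#' For each group: a lognormal metacommunity is drawn, OTU environmental
#' optima are assigned uniformly over `env_range`, and each site's local
#' community is assembled by the neutral birth-death process whose immigrant
#' pool is the metacommunity filtered by the group's Gaussian niche weights
#' at that site (dispersal `m_true`, selection `sigma_true`). The assembled
#' table is rarefied to `depth`.
#'
#' @param config a [simulation_config()].
#' @return a `synthetic_study` list: `table` (rarefied [count_table()]),
#'   `samples` ([sample_info()]), `taxa` (taxon map), `sizes` (body sizes,
#'   with `kingdom` when configured), and `truth` (the input config).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  samples <- generate_landscape(config$n_sites, config$extent_km,
                                config$autocorr_length_km, config$env_range,
                                seed = sub_seed(config$seed, 1L))
  G <- nrow(config$groups)
  blocks <- vector("list", G)
  taxa <- vector("list", G)
  for (g in seq_len(G)) {
    gr <- config$groups[g, ]
    otu_ids <- sprintf("%s_OTU%04d", gr$label, seq_len(config$n_otus_per_group))
    meta <- simulate_metacommunity(config$n_otus_per_group,
                                   seed = sub_seed(config$seed, 100L + g))
    mu <- with_seed(sub_seed(config$seed, 200L + g),
                    stats::runif(config$n_otus_per_group,
                                 min(config$env_range), max(config$env_range)))
    block <- matrix(0L, config$n_sites, config$n_otus_per_group,
                    dimnames = list(samples$sample_id, otu_ids))
    for (s in seq_len(config$n_sites)) {
      pool <- niche_weights(meta, samples$env[s], mu, gr$sigma_true)
      block[s, ] <- simulate_neutral_local(
        pool, gr$m_true, config$n_individuals, config$generations,
        seed = sub_seed(config$seed, 1000L * g + s))
    }
    blocks[[g]] <- block
    taxa[[g]] <- data.frame(otu_id = otu_ids, group = gr$label,
                            stringsAsFactors = FALSE)
  }
  table <- count_table(do.call(cbind, blocks))
  table <- rarefy(table, config$depth, seed = sub_seed(config$seed, 2L))
  sizes <- config$groups[, intersect(c("group", "label", "size_um", "kingdom"),
                                     names(config$groups)), drop = FALSE]
  names(sizes)[names(sizes) == "label"] <- "group"
  structure(list(table = table, samples = samples,
                 taxa = do.call(rbind, taxa),
                 sizes = sizes, truth = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic_study: %d sites x %d OTUs (%d groups), ",
                     "depth %d\n"),
              nrow(x$table), ncol(x$table), nrow(x$truth$groups),
              x$truth$depth))
  invisible(x)
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Emits `counts.tsv`, `metadata.csv`, `taxa.tsv`, `sizes.csv` and
#' `truth.json` so a study can round-trip through [read_study()].
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(study$table, file.path(dir, "counts.tsv"))
  utils::write.csv(as.data.frame(study$samples),
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.table(study$taxa, file.path(dir, "taxa.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(study$sizes, file.path(dir, "sizes.csv"), row.names = FALSE)
  truth <- unclass(study$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' The sizes file is optional; a study without it supports every stage except
#' the body-size scaling regressions.
#'
#' @param dir study directory.
#' @return a `synthetic_study`-shaped list (`truth` is NULL when absent).
#' @export
read_study <- function(dir) {
  table <- read_count_table(file.path(dir, "counts.tsv"))
  samples <- read_metadata(file.path(dir, "metadata.csv"))
  taxa <- read_taxon_map(file.path(dir, "taxa.tsv"))
  sizes_path <- file.path(dir, "sizes.csv")
  sizes <- if (file.exists(sizes_path)) {
    df <- utils::read.csv(sizes_path, stringsAsFactors = FALSE)
    as_body_sizes(df)
  } else NULL
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path) else NULL
  structure(list(table = table, samples = samples, taxa = taxa,
                 sizes = sizes, truth = truth), class = "synthetic_study")
}
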