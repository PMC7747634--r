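#' Construct and validate a sample-by-OTU count table
#'
#' A count table is the universal currency of the pipeline: a samples x OTUs
#' matrix of non-negative integer read counts with unique sample ids as row
#' names and unique OTU ids as column names.
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns. Whole-number
#'   doubles are coerced to integer; fractional or negative entries are errors.
#' @return an integer matrix of class `count_table`.
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table needs sample ids (rownames) and OTU ids (colnames)",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  if (anyNA(counts)) stop("counts contain missing values", call. = FALSE)
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]),
         call. = FALSE)
  if (is.double(counts)) {
    frac <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
    if (nrow(frac) > 0)
      stop(sprintf("non-integer count at sample '%s', OTU '%s'",
                   rownames(counts)[frac[1, 1]], colnames(counts)[frac[1, 2]]),
           call. = FALSE)
    storage.mode(counts) <- "integer"
  }
  structure(counts, class = c("count_table", class(unclass(counts))))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d OTUs, %s reads total\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' @export
`[.count_table` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out)) class(out) <- c("count_table", class(out))
  out
}

#' Read a sample-by-OTU count table
#'
#' Two plain-text dialects are supported. `"tsv"`: samples in rows, first
#' column sample ids, header row of OTU ids. `"biom-text"`: classic BIOM
#' dense TSV with OTUs in rows (header line starting `#OTU ID`, samples in
#' columns); it is transposed on read.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"biom-text"`.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, dialect = c("tsv", "biom-text")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "biom-text") {
    lines <- readLines(path)
    keep <- !grepl("^#", lines) | grepl("^#OTU ID", lines)
    txt <- lines[keep]
    if (!length(txt) || !grepl("^#OTU ID", txt[1]))
      stop("biom-text table must carry a '#OTU ID' header line", call. = FALSE)
    txt[1] <- sub("^#OTU ID", "OTU_ID", txt[1])
    df <- utils::read.table(text = txt, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character")
    mat <- parse_count_cells(df, path)
    mat <- t(mat)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character")
    mat <- parse_count_cells(df, path)
  }
  count_table(mat)
}

# Shared cell parsing: first column ids, remaining columns numeric counts.
# Duplicate header names must be caught here: data.frame subsetting would
# silently uniquify them downstream.
parse_count_cells <- function(df, path) {
  hdr <- names(df)[-1]
  if (anyDuplicated(hdr))
    stop("duplicate OTU ids in ", path, ": ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "), call. = FALSE)
  ids <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric count '%s' at row '%s', column '%s' in %s",
                 body[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(body)[bad[1, 2]], path), call. = FALSE)
  neg <- which(num < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative count at row '%s', column '%s' in %s",
                 ids[neg[1, 1]], colnames(body)[neg[1, 2]], path),
         call. = FALSE)
  dimnames(num) <- list(ids, colnames(body))
  num
}

#' Write a count table as TSV
#'
#' Inverse of [read_count_table()] with `dialect = "tsv"`; round-trips
#' exactly, including all-zero OTU columns.
#'
#' @param table a [count_table()].
#' @param path output file path.
#' @export
write_count_table <- function(table, path) {
  table <- count_table(as.matrix(table))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write to ", path, ": no such directory",
                             call. = FALSE)
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata (coordinates plus environmental covariates)
#'
#' Expects a CSV with a header containing `sample_id`, `latitude` and
#' `longitude`; all remaining numeric columns are kept as environmental
#' covariates. Non-numeric extra columns are dropped with a warning.
#'
#' @param path CSV file path.
#' @return a data.frame of class `sample_info` with columns `sample_id`,
#'   `latitude`, `longitude`, then covariates.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("sample_id", "latitude", "longitude")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  env_cols <- setdiff(names(df), need)
  keep <- character(0)
  for (v in env_cols) {
    if (is.numeric(df[[v]])) {
      keep <- c(keep, v)
    } else {
      num <- suppressWarnings(as.numeric(df[[v]]))
      if (anyNA(num) && !all(is.na(df[[v]]))) {
        warning("ignoring non-numeric metadata column '", v, "'",
                call. = FALSE)
      } else {
        df[[v]] <- num
        keep <- c(keep, v)
      }
    }
  }
  out <- df[, c(need, keep), drop = FALSE]
  sample_info(out)
}

#' Construct and validate sample metadata
#'
#' @param df data.frame with columns `sample_id`, `latitude`, `longitude` and
#'   numeric environmental covariates.
#' @return the validated data.frame, classed `sample_info`.
#' @export
sample_info <- function(df) {
  need <- c("sample_id", "latitude", "longitude")
  if (!all(need %in% names(df)))
    stop("sample_info needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  if (any(!is.finite(df$latitude)) || any(df$latitude < -90 | df$latitude > 90))
    stop("latitude out of [-90, 90]", call. = FALSE)
  if (any(!is.finite(df$longitude)) ||
      any(df$longitude < -180 | df$longitude > 180))
    stop("longitude out of [-180, 180]", call. = FALSE)
  env <- setdiff(names(df), need)
  for (v in env) {
    if (!is.numeric(df[[v]]) || any(!is.finite(df[[v]])))
      stop("environmental covariate '", v, "' must be finite numeric",
           call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  class(df) <- unique(c("sample_info", class(df)))
  df
}

#' Rarefy every sample to a common depth
#'
#' Subsamples reads without replacement (hypergeometric) so that every row
#' sum equals `depth` exactly. Deterministic given `seed`.
#'
#' @param table a [count_table()].
#' @param depth target reads per sample; every sample must hold at least this
#'   many reads.
#' @param seed integer seed governing the subsampling.
#' @return a rarefied [count_table()].
#' @export
rarefy <- function(table, depth, seed = 1L) {
  table <- count_table(as.matrix(table))
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1)
    stop("`depth` must be a positive integer", call. = FALSE)
  depth <- as.integer(depth)
  rs <- rowSums(table)
  under <- rownames(table)[rs < depth]
  if (length(under))
    stop("samples below rarefaction depth ", depth, ": ",
         paste(under, collapse = ", "), call. = FALSE)
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(unclass(table), depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  storage.mode(out) <- "integer"
  count_table(out)
}

#' Split a count table into dominant taxonomic groups
#'
#' A group is retained when its pooled relative abundance over the whole
#' (rarefied) table is at least `min_rel_abund` AND it is present (>= 1 read
#' summed over its member OTUs) in at least `min_presence` of samples.
#'
#' @param table a [count_table()], typically rarefied.
#' @param taxa data.frame with columns `otu_id` and `group`; every OTU in
#'   `table` must be mapped.
#' @param min_rel_abund pooled relative-abundance threshold (default 0.01).
#' @param min_presence presence threshold as a fraction of samples
#'   (default 0.80).
#' @return named list of `count_table` subsets, one per retained group; each
#'   subset keeps all samples and only that group's OTUs.
#' @export
filter_dominant_groups <- function(table, taxa, min_rel_abund = 0.01,
                                   min_presence = 0.80) {
  table <- count_table(as.matrix(table))
  taxa <- as_taxon_map(taxa)
  unmapped <- setdiff(colnames(table), taxa$otu_id)
  if (length(unmapped))
    stop("OTUs missing from the taxon map: ",
         paste(utils::head(unmapped, 10), collapse = ", "),
         if (length(unmapped) > 10) ", ...", call. = FALSE)
  grp <- taxa$group[match(colnames(table), taxa$otu_id)]
  total <- sum(as.numeric(table))
  out <- list()
  for (g in unique(grp)) {
    sub <- table[, grp == g, drop = FALSE]
    pooled <- sum(as.numeric(sub)) / total
    presence <- mean(rowSums(sub) > 0)
    if (pooled >= min_rel_abund && presence >= min_presence)
      out[[g]] <- count_table(unclass(sub))
  }
  out
}

#' Validate an OTU-to-group taxon map
#'
#' @param taxa data.frame with columns `otu_id` and `group`.
#' @return validated data.frame; each OTU maps to exactly one group.
#' @export
as_taxon_map <- function(taxa) {
  if (!all(c("otu_id", "group") %in% names(taxa)))
    stop("taxon map needs columns otu_id and group", call. = FALSE)
  if (anyDuplicated(taxa$otu_id))
    stop("OTUs mapped to more than one group: ",
         paste(unique(taxa$otu_id[duplicated(taxa$otu_id)]), collapse = ", "),
         call. = FALSE)
  taxa$otu_id <- as.character(taxa$otu_id)
  taxa$group <- as.character(taxa$group)
  taxa
}

#' Read an OTU-to-group map (TSV with columns otu_id, group)
#' @param path TSV file path.
#' @return validated taxon map data.frame.
#' @export
read_taxon_map <- function(path) {
  as_taxon_map(utils::read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
}

#' Read a group body-size table (CSV with columns group, size_um)
#'
#' Body sizes are propagule lengths in micrometres; they must be positive and
#' groups unique.
#'
#' @param path CSV file path.
#' @return data.frame with columns `group` and `size_um`.
#' @export
read_body_sizes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_body_sizes(df)
}

#' Validate a group body-size table
#' @param df data.frame with columns `group`, `size_um` (micrometres, > 0).
#' @return validated data.frame.
#' @export
as_body_sizes <- function(df) {
  if (!all(c("group", "size_um") %in% names(df)))
    stop("body-size table needs columns group and size_um", call. = FALSE)
  if (anyDuplicated(df$group)) stop("duplicate groups in body-size table",
                                    call. = FALSE)
  if (any(!is.finite(df$size_um)) || any(df$size_um <= 0))
    stop("size_um must be positive and finite", call. = FALSE)
  df$group <- as.character(df$group)
  df
}
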