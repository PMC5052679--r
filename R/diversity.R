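# Rarefaction, Shannon diversity and the abundant-active-taxon census.

#' Rarefy a count table to a fixed depth
#'
#' Subsamples each library (column) to exactly `depth` reads without
#' replacement (multivariate hypergeometric draw). Samples whose total is
#' below the depth are dropped with a warning, never up-sampled.
#'
#' @param table Count matrix (taxa x samples).
#' @param depth Target depth (reads), >= 1.
#' @param seed Optional integer seed for reproducibility.
#' @return Count matrix with every column summing to `depth`.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  validate_count_table(table)
  if (!is.numeric(depth) || depth < 1) stop("depth must be >= 1", call. = FALSE)
  depth <- as.integer(round(depth))
  if (!is.null(seed)) set.seed(seed)
  totals <- colSums(table)
  drop <- totals < depth
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(colnames(table)[drop], collapse = ", "), call. = FALSE)
    table <- table[, !drop, drop = FALSE]
    if (!ncol(table)) stop("no samples at or above depth ", depth, call. = FALSE)
    totals <- totals[!drop]
  }
  out <- table
  for (j in seq_len(ncol(table))) {
    x <- table[, j]
    if (totals[j] == depth) next # exhaustive draw leaves the column unchanged
    picked <- sample.int(totals[j], depth)
    out[, j] <- tabulate(findInterval(picked - 1L, cumsum(x)) + 1L,
                         nbins = nrow(table))
  }
  out
}

#' Shannon diversity of a count vector
#'
#' `H = -sum p_i log_b p_i` over positive counts; base 2 (bits) by default.
#'
#' @param counts Non-negative numeric vector with at least one positive
#'   entry.
#' @param base Logarithm base (default 2).
#' @return Shannon diversity (scalar).
#' @export
shannon <- function(counts, base = 2) {
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and complete", call. = FALSE)
  counts <- counts[counts > 0]
  if (!length(counts)) stop("all-zero count vector", call. = FALSE)
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Mean Shannon diversity over repeated rarefactions
#'
#' Rarefies the table `restarts` times at a fixed depth and averages the
#' per-sample Shannon diversity over the restarts.
#'
#' @inheritParams rarefy
#' @param restarts Number of independent rarefactions (default 10).
#' @param base Logarithm base for Shannon (default 2).
#' @return Data frame: `sample_id`, `shannon` (mean over restarts),
#'   `shannon_sd`, `observed_taxa` (mean richness over restarts).
#' @export
mean_rarefied_shannon <- function(table, depth, restarts = 10, seed = NULL,
                                  base = 2) {
  if (restarts < 1) stop("restarts must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  keep <- colSums(table) >= depth
  if (!any(keep)) stop("no samples at or above depth ", depth, call. = FALSE)
  if (!all(keep))
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth,
            call. = FALSE)
  table <- table[, keep, drop = FALSE]
  h <- matrix(NA_real_, restarts, ncol(table))
  rich <- matrix(NA_real_, restarts, ncol(table))
  for (b in seq_len(restarts)) {
    rt <- suppressWarnings(rarefy(table, depth))
    h[b, ] <- apply(rt, 2L, shannon, base = base)
    rich[b, ] <- colSums(rt > 0)
  }
  data.frame(sample_id = colnames(table),
             shannon = colMeans(h),
             shannon_sd = if (restarts > 1) apply(h, 2L, stats::sd) else 0,
             observed_taxa = colMeans(rich),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Census of abundant active taxa per sample group
#'
#' Within each group, a taxon qualifies when its RNA reads summed over the
#' group's samples reach `min_count` and its mean activity ratio across the
#' group's samples (detected samples only) exceeds `theta`.
#'
#' @inheritParams activity_ratio
#' @param theta Dormancy threshold (default 1).
#' @param min_count Minimum summed RNA reads within the group (default 100).
#' @param group_col Metadata column defining the groups (default
#'   `"treatment"`).
#' @return Named list (one element per group) of character vectors of taxon
#'   ids; attribute `n` holds the per-group cardinalities.
#' @export
abundant_active_taxa <- function(paired, theta = 1, min_count = 100,
                                 group_col = "treatment", normalize = TRUE) {
  if (min_count < 1) stop("min_count must be >= 1", call. = FALSE)
  if (is.null(paired$metadata))
    stop("abundant_active_taxa requires sample metadata", call. = FALSE)
  groups <- paired$metadata[[group_col]]
  r <- activity_ratio(paired, normalize = normalize)
  out <- lapply(unique(groups), function(g) {
    cols <- paired$sample_ids[groups == g]
    rna_tot <- rowSums(paired$rna[, cols, drop = FALSE])
    mean_r <- rowMeans(r[, cols, drop = FALSE], na.rm = TRUE)
    sel <- rna_tot >= min_count & !is.nan(mean_r) & mean_r > theta
    paired$taxon_ids[sel]
  })
  names(out) <- unique(groups)
  attr(out, "n") <- vapply(out, length, integer(1L))
  out
}
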