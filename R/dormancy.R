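# Per-taxon RNA:DNA activity ratios, active/dormant classification,
# dormant-proportion estimation, threshold sensitivity sweep, order-level
# activity summaries and the dormancy-vs-fertilization ANOVA.

#' Depth-normalize paired count matrices
#'
#' Scales every library (each column of the DNA and RNA matrices) to a
#' common size, so the activity ratio is not dominated by sequencing-depth
#' imbalance between molecules. The common size defaults to the mean
#' library size over both matrices.
#'
#' @param paired A `paired_community`.
#' @param target Common library size; default mean of all column totals.
#' @return List with scaled `dna` and `rna` matrices (real-valued).
#' @keywords internal
normalize_depth <- function(paired, target = NULL) {
  tot_d <- colSums(paired$dna)
  tot_r <- colSums(paired$rna)
  if (is.null(target)) target <- mean(c(tot_d, tot_r))
  scale_cols <- function(m, tot) {
    tot[tot == 0] <- 1 # all-zero library stays all-zero
    sweep(m, 2L, target / tot, `*`)
  }
  list(dna = scale_cols(paired$dna, tot_d), rna = scale_cols(paired$rna, tot_r))
}

#' Per-taxon activity ratio (16S rRNA : 16S rRNA gene + 1)
#'
#' For every taxon i in a sample, the ratio `r_i = rna_i / (dna_i + 1)`.
#' The +1 on the gene (DNA) denominator encodes the assumption that a taxon
#' observed in the RNA pool must be present in the total community even if
#' its gene copy escaped sequencing, and keeps the ratio finite for
#' RNA-only taxa. Taxa with zero raw counts in both molecules are
#' undetected and returned as `NA`.
#'
#' @param paired A `paired_community`.
#' @param sample Optional sample id (or vector); default all samples.
#' @param normalize Compute ratios on depth-normalized counts (default) or
#'   raw counts.
#' @return Matrix of ratios (taxa x samples), `NA` for undetected taxa; a
#'   plain named vector if a single sample was requested.
#' @export
activity_ratio <- function(paired, sample = NULL, normalize = TRUE) {
  stopifnot(inherits(paired, "paired_community"))
  samples <- if (is.null(sample)) paired$sample_ids else sample
  unknown <- setdiff(samples, paired$sample_ids)
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  mats <- if (normalize) normalize_depth(paired) else paired[c("dna", "rna")]
  dna <- mats$dna[, samples, drop = FALSE]
  rna <- mats$rna[, samples, drop = FALSE]
  r <- rna / (dna + 1)
  undetected <- paired$dna[, samples, drop = FALSE] == 0 &
    paired$rna[, samples, drop = FALSE] == 0
  r[undetected] <- NA_real_
  if (length(samples) == 1L) r[, 1L] else r
}

#' Classify taxa as active or dormant
#'
#' A detected taxon is active iff its ratio strictly exceeds the threshold;
#' a ratio at or below the threshold is dormant (a ratio of exactly 1 is
#' dormant at the default threshold). `NA` ratios are `"undetected"`.
#'
#' @param ratios Numeric vector or matrix of activity ratios.
#' @param theta Dormancy threshold, >= 0 (default 1).
#' @return Character vector/matrix with values `"active"`, `"dormant"`,
#'   `"undetected"`.
#' @export
classify_activity <- function(ratios, theta = 1) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0)
    stop("theta must be a single non-negative number", call. = FALSE)
  out <- ifelse(is.na(ratios), "undetected",
                ifelse(ratios > theta, "active", "dormant"))
  if (is.matrix(ratios)) dimnames(out) <- dimnames(ratios)
  out
}

#' Per-sample dormant proportion
#'
#' Fraction of detected taxa classified dormant at threshold `theta`
#' (richness-based: every detected taxon counts once). The
#' abundance-weighted variant weights each taxon by its DNA relative
#' abundance instead.
#'
#' @inheritParams activity_ratio
#' @param theta Dormancy threshold (default 1).
#' @param weighted Abundance-weighted proportion instead of richness-based.
#' @return Named numeric vector of proportions in `[0, 1]`, one per sample.
#' @export
dormant_proportion <- function(paired, sample = NULL, theta = 1,
                               normalize = TRUE, weighted = FALSE) {
  samples <- if (is.null(sample)) paired$sample_ids else sample
  r <- activity_ratio(paired, samples, normalize = normalize)
  if (!is.matrix(r)) r <- matrix(r, ncol = 1L, dimnames = list(names(r), samples))
  lab <- classify_activity(r, theta)
  out <- vapply(seq_along(samples), function(j) {
    det <- lab[, j] != "undetected"
    if (!any(det))
      stop("sample ", samples[j], ": no detected taxa; dormant proportion undefined",
           call. = FALSE)
    if (weighted) {
      w <- paired$dna[, samples[j]][det]
      if (sum(w) == 0) w <- rep(1, sum(det))
      sum(w[lab[det, j] == "dormant"]) / sum(w)
    } else {
      mean(lab[det, j] == "dormant")
    }
  }, numeric(1L))
  names(out) <- samples
  out
}

#' Threshold sensitivity sweep of the dormant proportion
#'
#' Evaluates the per-sample dormant proportion over an ascending grid of
#' thresholds (default the integers 1..50). The resulting curves are
#' non-decreasing in the threshold by construction.
#'
#' @inheritParams dormant_proportion
#' @param thresholds Ascending numeric thresholds (default `1:50`).
#' @return A `threshold_sweep` object: samples x thresholds matrix of
#'   dormant proportions with attribute `thresholds`.
#' @export
threshold_sweep <- function(paired, thresholds = 1:50, normalize = TRUE,
                            weighted = FALSE) {
  if (!length(thresholds)) stop("empty threshold list", call. = FALSE)
  if (is.unsorted(thresholds, strictly = FALSE))
    stop("thresholds must be sorted ascending", call. = FALSE)
  r <- activity_ratio(paired, normalize = normalize)
  if (!is.matrix(r))
    r <- matrix(r, ncol = 1L, dimnames = list(names(r), paired$sample_ids))
  det <- !is.na(r)
  curve <- vapply(thresholds, function(th) {
    dormant <- det & r <= th
    if (weighted) {
      w <- paired$dna
      colSums(w * dormant) / pmax(colSums(w * det), 1)
    } else {
      colSums(dormant) / colSums(det)
    }
  }, numeric(ncol(r)))
  curve <- matrix(curve, nrow = ncol(r),
                  dimnames = list(paired$sample_ids, as.character(thresholds)))
  structure(curve, thresholds = thresholds, class = c("threshold_sweep", "matrix"))
}

#' Order-level activity summaries
#'
#' Aggregates counts to taxonomic orders, computes the display ratio
#' `(sum rna + 1) / (sum dna + 1)` per order per sample (the symmetric +1
#' keeps log10 finite when an order is absent from one molecule), and
#' summarises `log10` ratios as mean and s.e.m. per sample group. Orders
#' are ranked by total reads and retained until they jointly cover
#' `coverage` of all reads.
#'
#' @inheritParams activity_ratio
#' @param taxonomy Taxonomy data frame ([read_taxonomy()]).
#' @param coverage Cumulative read fraction the retained orders must cover
#'   (default 0.9).
#' @param group_col Metadata column defining the groups (default
#'   `"treatment"`).
#' @param strict Error (rather than warn) when more than half of all reads
#'   lack an order assignment.
#' @return Data frame: `order`, `group`, `mean_log10_ratio`, `sem`, `n`,
#'   `total_reads`.
#' @export
order_activity <- function(paired, taxonomy, coverage = 0.9,
                           group_col = "treatment", normalize = TRUE,
                           strict = FALSE) {
  if (!(coverage > 0 && coverage <= 1))
    stop("coverage must be in (0, 1]", call. = FALSE)
  if (is.null(paired$metadata))
    stop("order_activity requires sample metadata", call. = FALSE)
  orders <- taxonomy_rank(taxonomy, paired$taxon_ids, "order")
  uncl <- sum((rowSums(paired$dna) + rowSums(paired$rna))[orders == "unclassified"])
  if (uncl > 0.5 * (sum(paired$dna) + sum(paired$rna))) {
    msg <- "more than 50% of reads lack an order assignment"
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  mats <- if (normalize) normalize_depth(paired) else paired[c("dna", "rna")]
  agg <- function(m) rowsum(m, orders)
  dna_o <- agg(mats$dna); rna_o <- agg(mats$rna)
  total <- rowSums(agg(paired$dna)) + rowSums(agg(paired$rna))
  ord <- order(total, decreasing = TRUE)
  keep_n <- which(cumsum(total[ord]) / sum(total) >= coverage)[1L]
  keep <- rownames(dna_o)[ord[seq_len(keep_n)]]
  log_ratio <- log10((rna_o[keep, , drop = FALSE] + 1) /
                     (dna_o[keep, , drop = FALSE] + 1))
  groups <- paired$metadata[[group_col]]
  res <- do.call(rbind, lapply(unique(groups), function(g) {
    x <- log_ratio[, groups == g, drop = FALSE]
    n <- ncol(x)
    data.frame(order = rownames(x), group = g,
               mean_log10_ratio = rowMeans(x),
               sem = if (n > 1) apply(x, 1L, stats::sd) / sqrt(n) else 0,
               n = n,
               total_reads = total[rownames(x)],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  res[order(-res$total_reads, res$group), ]
}

#' One-way ANOVA of dormant proportions against a grouping factor
#'
#' Classical one-way (fixed-effects) ANOVA F test of per-sample dormant
#' proportions across fertilization groups. When every observation is
#' identical (zero between- and within-group variance) the test is
#' degenerate and `F = 0, p = 1` is returned by convention.
#'
#' @param proportions Numeric vector of per-sample dormant proportions.
#' @param groups Factor (or coercible) of the same length.
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
dormancy_anova <- function(proportions, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) stop("need >= 2 values per group", call. = FALSE)
  n <- length(proportions)
  a <- nlevels(groups)
  gm <- tapply(proportions, groups, mean)
  ssb <- sum(tabulate(groups) * (gm - mean(proportions))^2)
  ssw <- sum((proportions - gm[groups])^2)
  if (ssw == 0 && ssb == 0)
    return(list(F = 0, p = 1, df_between = a - 1L, df_within = n - a))
  if (ssw == 0)
    return(list(F = Inf, p = 0, df_between = a - 1L, df_within = n - a))
  f <- (ssb / (a - 1)) / (ssw / (n - a))
  list(F = f, p = stats::pf(f, a - 1, n - a, lower.tail = FALSE),
       df_between = a - 1L, df_within = n - a)
}
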