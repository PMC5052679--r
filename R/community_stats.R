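# Beta diversity (Bray-Curtis, weighted UniFrac), PCoA, permutation
# PERMANOVA, and per-taxon Kruskal-Wallis testing with multiplicity
# correction. Distances are returned as base `dist` objects labelled with
# sample ids.

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over taxa; bounded in
#' `[0, 1]`. By default columns are converted to relative abundance first.
#'
#' @param table Count matrix (taxa x samples), >= 2 samples.
#' @param normalize Convert columns to relative abundance first (default
#'   `TRUE`).
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(table, normalize = TRUE) {
  if (ncol(table) < 2L) stop("need >= 2 samples", call. = FALSE)
  tot <- colSums(table)
  if (any(tot == 0))
    stop("sample(s) with zero total: ",
         paste(colnames(table)[tot == 0], collapse = ", "), call. = FALSE)
  m <- if (normalize) sweep(table, 2L, tot, `/`) else table
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <- sum(abs(m[, i] - m[, j])) / sum(m[, i] + m[, j])
  }
  stats::as.dist(d)
}

#' Weighted UniFrac distance between samples
#'
#' Branch-length-weighted difference in phylogenetic placement of two
#' communities' relative-abundance mass: for each branch, the absolute
#' difference of the subtree mass of the two samples, weighted by branch
#' length and summed. The normalized variant divides by the maximal
#' attainable value (the abundance-weighted root-to-tip depth sum), so
#' distances lie in `[0, 1]`.
#'
#' @param table Count matrix (taxa x samples); every taxon must be a tree
#'   leaf.
#' @param tree Rooted `phylo` tree with non-negative branch lengths.
#' @param normalized Return the normalized variant (default `TRUE`).
#' @return A `dist` object over samples.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  if (ncol(table) < 2L) stop("need >= 2 samples", call. = FALSE)
  missing <- setdiff(rownames(table), tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) in tree", call. = FALSE)
  tot <- colSums(table)
  if (any(tot == 0))
    stop("sample(s) with zero total: ",
         paste(colnames(table)[tot == 0], collapse = ", "), call. = FALSE)
  p <- sweep(table, 2L, tot, `/`)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # per-sample mass under each node, accumulated tips-to-root (postorder)
  mass <- matrix(0, nnode, ncol(table))
  idx <- match(tree$tip.label, rownames(table))
  present <- !is.na(idx)
  mass[which(present), ] <- p[idx[present], , drop = FALSE]
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  elen <- tree$edge.length[match(paste(edge[, 1L], edge[, 2L]),
                                 paste(tree$edge[, 1L], tree$edge[, 2L]))]
  for (k in seq_len(nrow(edge)))
    mass[edge[k, 1L], ] <- mass[edge[k, 1L], ] + mass[edge[k, 2L], ]
  sub <- mass[edge[, 2L], , drop = FALSE] # subtree mass below each edge
  n <- ncol(table)
  d <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  if (normalized) {
    # abundance-weighted root-to-tip depth per sample
    depth_tip <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
    wdepth <- as.numeric(crossprod(mass[seq_len(ntip), , drop = FALSE], depth_tip))
  }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    raw <- sum(elen * abs(sub[, i] - sub[, j]))
    d[i, j] <- d[j, i] <- if (normalized) {
      den <- wdepth[i] + wdepth[j]
      if (den == 0) 0 else raw / den
    } else raw
  }
  stats::as.dist(d)
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centres the squared distance matrix and eigendecomposes it;
#' coordinates come from the positive eigenvalues, negative eigenvalues are
#' reported, and per-axis variance fractions are relative to the positive
#' eigenvalue total.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @return List with `points` (samples x axes), `eig` (all eigenvalues),
#'   `variance_explained` (per retained axis), `negative_eig` (sum of
#'   negative eigenvalues).
#' @export
pcoa <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 samples", call. = FALSE)
  a <- -0.5 * m^2
  g <- a - outer(rowMeans(a), rep(1, n)) - outer(rep(1, n), colMeans(a)) + mean(a)
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-9
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                 nrow = sum(pos))
  rownames(pts) <- rownames(m)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  list(points = pts,
       eig = e$values,
       variance_explained = e$values[pos] / sum(e$values[pos]),
       negative_eig = sum(e$values[e$values < 0]))
}

permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  sst <- sum(d2) / (2 * n)
  ssw <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  c(sst = sst, ssw = ssw)
}

#' Permutation PERMANOVA (single factor)
#'
#' Partitions the sum of squared distances between and within the levels of
#' a single factor; the pseudo-F statistic
#' `F = (SS_between / (a - 1)) / (SS_within / (N - a))` is referred to its
#' permutation distribution under random relabelling of samples. The
#' p-value uses the add-one correction
#' `p = (#[F_perm >= F_obs] + 1) / (n_perm + 1)`.
#'
#' @param d A `dist` object or symmetric distance matrix over samples.
#' @param groups Factor (or coercible) of group labels, one per sample;
#'   every level needs >= 2 samples.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for the permutation stream.
#' @return List with `factor_levels`, `pseudo_F`, `p`, `n_perm`, `df`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  m <- as.matrix(d)
  groups <- factor(groups)
  n <- nrow(m)
  if (length(groups) != n) stop("labels do not match distance matrix", call. = FALSE)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("singleton group(s): ",
         paste(names(which(table(groups) < 2L)), collapse = ", "), call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  d2 <- m^2
  a <- nlevels(groups)
  ss <- permanova_ss(d2, groups)
  f_obs <- ((ss["sst"] - ss["ssw"]) / (a - 1)) / (ss["ssw"] / (n - a))
  if (!is.null(seed)) set.seed(seed)
  f_perm <- vapply(seq_len(n_perm), function(b) {
    gp <- groups[sample.int(n)]
    ssp <- permanova_ss(d2, gp)
    ((ssp["sst"] - ssp["ssw"]) / (a - 1)) / (ssp["ssw"] / (n - a))
  }, numeric(1L))
  list(factor_levels = levels(groups),
       pseudo_F = unname(f_obs),
       p = (sum(f_perm >= f_obs) + 1) / (n_perm + 1),
       n_perm = n_perm,
       df = c(between = a - 1L, within = n - a))
}

#' Per-taxon Kruskal-Wallis tests across sample groups
#'
#' Rank-based H statistic with tie correction per taxon (row), with the
#' chi-square reference distribution. Rows that are constant across all
#' samples get `H = 0, p = 1` by convention.
#'
#' @param table Count matrix (taxa x samples).
#' @param groups Factor of group labels, one per sample.
#' @param normalize Convert columns to relative abundance first (default
#'   `TRUE`).
#' @return Data frame: `taxon`, `H`, `p`.
#' @export
kruskal_wallis_per_taxon <- function(table, groups, normalize = TRUE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  m <- if (normalize) sweep(table, 2L, colSums(table), `/`) else table
  res <- t(apply(m, 1L, function(x) {
    if (length(unique(x)) == 1L) return(c(0, 1))
    kt <- stats::kruskal.test(x, groups)
    c(unname(kt$statistic), kt$p.value)
  }))
  data.frame(taxon = rownames(table), H = res[, 1L], p = res[, 2L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multiple-testing correction
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up adjustment.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = c(bonferroni = "bonferroni", bh = "BH")[method])
}
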