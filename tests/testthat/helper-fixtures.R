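# Small in-code fixtures shared across test files.

# paired table built directly from matrices (skips file IO)
make_paired <- function(dna, rna, metadata = NULL) {
  stopifnot(identical(dimnames(dna), dimnames(rna)))
  structure(list(taxon_ids = rownames(dna), sample_ids = colnames(dna),
                 dna = dna, rna = rna, metadata = metadata),
            class = "paired_community")
}

random_count_matrix <- function(n_taxa, n_samples, lambda = 20) {
  matrix(stats::rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
         dimnames = list(sprintf("t%03d", seq_len(n_taxa)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# brute-force per-taxon dormancy re-computation used as the oracle against
# the vectorized implementation: loops taxa one at a time
brute_dormant_proportion <- function(paired, sample, theta,
                                     normalize = TRUE) {
  dn <- if (normalize) {
    target <- mean(c(colSums(paired$dna), colSums(paired$rna)))
    list(dna = paired$dna[, sample] * target / sum(paired$dna[, sample]),
         rna = paired$rna[, sample] * target / sum(paired$rna[, sample]))
  } else {
    list(dna = paired$dna[, sample], rna = paired$rna[, sample])
  }
  n_dormant <- 0L; n_detected <- 0L
  for (i in seq_along(paired$taxon_ids)) {
    raw_d <- paired$dna[i, sample]; raw_r <- paired$rna[i, sample]
    if (raw_d == 0 && raw_r == 0) next
    n_detected <- n_detected + 1L
    r <- dn$rna[i] / (dn$dna[i] + 1)
    if (r <= theta) n_dormant <- n_dormant + 1L
  }
  n_dormant / n_detected
}

# brute-force weighted UniFrac: explicit per-branch mass summation via tip
# descendant sets
brute_weighted_unifrac <- function(table, tree, normalized = FALSE) {
  p <- sweep(table, 2L, colSums(table), `/`)
  tips_below <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, tips_below))
  }
  n <- ncol(table)
  d <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  depths <- ape::node.depth.edgelength(tree)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    tot <- 0
    for (e in seq_len(nrow(tree$edge))) {
      tips <- tips_below(tree$edge[e, 2L])
      mi <- sum(p[tips, i]); mj <- sum(p[tips, j])
      tot <- tot + tree$edge.length[e] * abs(mi - mj)
    }
    if (normalized) {
      den <- sum(p[tree$tip.label, i] * depths[seq_along(tree$tip.label)]) +
        sum(p[tree$tip.label, j] * depths[seq_along(tree$tip.label)])
      tot <- tot / den
    }
    d[i, j] <- d[j, i] <- tot
  }
  stats::as.dist(d)
}
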