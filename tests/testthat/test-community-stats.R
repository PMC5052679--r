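test_that("Bray-Curtis matches hand values and its bounds", {
  tb <- matrix(c(6, 2, 2, 2), 2, dimnames = list(c("A", "B"), c("x", "y")))
  expect_equal(as.numeric(bray_curtis(tb, normalize = FALSE)), 1 / 3)
  same <- matrix(c(3, 7, 3, 7), 2, dimnames = list(c("A", "B"), c("x", "y")))
  expect_equal(as.numeric(bray_curtis(same)), 0)
  disj <- matrix(c(5, 0, 0, 8), 2, dimnames = list(c("A", "B"), c("x", "y")))
  expect_equal(as.numeric(bray_curtis(disj)), 1)
  zero <- matrix(c(1, 1, 0, 0), 2, dimnames = list(c("A", "B"), c("x", "y")))
  expect_error(bray_curtis(zero), "zero total")
  # agrees with vegan on relative-abundance input
  set.seed(4)
  tb2 <- random_count_matrix(15, 6)
  rel <- sweep(tb2, 2, colSums(tb2), `/`)
  expect_equal(as.matrix(bray_curtis(tb2)),
               as.matrix(vegan::vegdist(t(rel), method = "bray")),
               tolerance = 1e-12)
})

test_that("weighted UniFrac matches the closed form on a two-leaf star tree", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  tb <- matrix(c(10, 0, 0, 10), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(as.numeric(weighted_unifrac(tb, tr, normalized = FALSE)), 2)
  expect_equal(as.numeric(weighted_unifrac(tb, tr, normalized = TRUE)), 1)
  same <- matrix(c(4, 6, 4, 6), 2, dimnames = dimnames(tb))
  expect_equal(as.numeric(weighted_unifrac(same, tr)), 0)
  tb_bad <- rbind(tb, c = c(1, 1))
  expect_error(weighted_unifrac(tb_bad, tr), "absent from tree.*c")
})

test_that("weighted UniFrac agrees with per-branch brute force on random trees", {
  set.seed(77)
  for (i in 1:5) {
    tr <- ape::rcoal(6, tip.label = sprintf("t%d", 1:6))
    tb <- random_count_matrix(6, 4)
    rownames(tb) <- tr$tip.label
    expect_equal(as.matrix(weighted_unifrac(tb, tr, normalized = FALSE)),
                 as.matrix(brute_weighted_unifrac(tb, tr)),
                 tolerance = 1e-12)
    expect_equal(as.matrix(weighted_unifrac(tb, tr, normalized = TRUE)),
                 as.matrix(brute_weighted_unifrac(tb, tr, normalized = TRUE)),
                 tolerance = 1e-12)
    # collapsing a zero-length internal branch leaves distances unchanged
    tr0 <- tr
    internal <- which(tr0$edge[, 2] > ape::Ntip(tr0))
    tr0$edge.length[internal[1]] <- 0
    d0 <- weighted_unifrac(tb, tr0, normalized = FALSE)
    tr_col <- ape::di2multi(tr0, tol = 1e-12)
    expect_equal(as.matrix(weighted_unifrac(tb, tr_col, normalized = FALSE)),
                 as.matrix(d0), tolerance = 1e-12)
  }
})

test_that("weighted UniFrac agrees with phyloseq", {
  set.seed(12)
  tr <- ape::rcoal(8, tip.label = sprintf("t%d", 1:8))
  tb <- random_count_matrix(8, 5)
  rownames(tb) <- tr$tip.label
  ps <- phyloseq::phyloseq(phyloseq::otu_table(tb, taxa_are_rows = TRUE),
                           phyloseq::phy_tree(tr))
  for (norm in c(TRUE, FALSE)) {
    expect_equal(as.matrix(weighted_unifrac(tb, tr, normalized = norm)),
                 as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                             normalized = norm)),
                 tolerance = 1e-10)
  }
})

test_that("PCoA recovers Euclidean configurations and reports axis variance", {
  # three equidistant samples: the two axes carry equal variance
  d3 <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3,
                              dimnames = list(letters[1:3], letters[1:3])))
  pc3 <- pcoa(d3)
  expect_equal(pc3$variance_explained[1], pc3$variance_explained[2])
  # collinear points: one axis explains all positive variance
  x <- c(0, 1, 3, 7)
  dl <- stats::dist(x)
  pcl <- pcoa(dl)
  expect_equal(pcl$variance_explained[1], 1)
  expect_equal(sort(as.numeric(stats::dist(pcl$points[, 1]))),
               sort(as.numeric(dl)))
  # full-coordinate round trip for a random Euclidean cloud
  set.seed(6)
  pts <- matrix(rnorm(21), 7, 3)
  d <- stats::dist(pts)
  pc <- pcoa(d)
  expect_equal(as.matrix(stats::dist(pc$points)), as.matrix(d),
               tolerance = 1e-9)
  expect_lte(sum(pc$variance_explained), 1 + 1e-12)
  expect_error(pcoa(stats::dist(1)), ">= 2")
})

test_that("PERMANOVA pseudo-F matches vegan::adonis2 and is label-invariant", {
  set.seed(40)
  tb <- random_count_matrix(25, 12)
  g <- rep(c("a", "b", "c"), each = 4)
  d <- bray_curtis(tb)
  mine <- permanova(d, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-12)
  # renaming groups leaves F unchanged
  g2 <- c(a = "x", b = "y", c = "z")[g]
  expect_equal(permanova(d, g2, n_perm = 9, seed = 1)$pseudo_F, mine$pseudo_F)
  # consistent permutation of samples leaves F unchanged
  perm <- sample(12)
  m <- as.matrix(d)[perm, perm]
  expect_equal(permanova(stats::as.dist(m), g[perm], n_perm = 9,
                         seed = 1)$pseudo_F, mine$pseudo_F)
  # determinism under seed
  expect_identical(permanova(d, g, n_perm = 199, seed = 3),
                   permanova(d, g, n_perm = 199, seed = 3))
  expect_error(permanova(d, c(rep("a", 11), "b"), 99), "singleton")
})

test_that("PERMANOVA p-value: complete separation reaches the +1 floor", {
  # n = 20 so a random label permutation essentially never reproduces the
  # observed partition and the p-value reaches its +1 floor
  set.seed(55)
  pts <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 5, 0.1), 10))
  d <- stats::dist(pts)
  res <- permanova(d, rep(c("a", "b"), each = 10), n_perm = 999, seed = 2)
  expect_equal(res$p, 1 / 1000)
  expect_gte(res$p, 1 / (res$n_perm + 1))
})

test_that("PERMANOVA type-I error is calibrated on null Gaussian data", {
  set.seed(60)
  n_rep <- 400
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    d <- stats::dist(matrix(rnorm(24), 12, 2))
    rej[i] <- permanova(d, rep(c("a", "b"), each = 6), n_perm = 199)$p <= 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Kruskal-Wallis per taxon matches hand ranks and stats::kruskal.test", {
  tb <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
               dimnames = list("t1", sprintf("s%d", 1:6)))
  g <- rep(c("a", "b"), each = 3)
  res <- kruskal_wallis_per_taxon(tb, g, normalize = FALSE)
  expect_equal(res$H, 27 / 7) # 3.857...: no ties, complete separation of ranks
  # constant rows get H = 0, p = 1
  tb0 <- matrix(5, 2, 6, dimnames = list(c("t1", "t2"), sprintf("s%d", 1:6)))
  res0 <- kruskal_wallis_per_taxon(tb0, g, normalize = FALSE)
  expect_equal(res0$H, c(0, 0))
  expect_equal(res0$p, c(1, 1))
  # ties handled identically to stats::kruskal.test
  set.seed(70)
  tb2 <- random_count_matrix(10, 9, lambda = 3)
  g2 <- rep(c("a", "b", "c"), each = 3)
  res2 <- kruskal_wallis_per_taxon(tb2, g2, normalize = FALSE)
  for (i in c(1, 5, 10)) {
    ref <- stats::kruskal.test(tb2[i, ], factor(g2))
    expect_equal(res2$H[i], unname(ref$statistic))
    expect_equal(res2$p[i], unname(ref$p.value))
  }
})

test_that("Kruskal-Wallis raw p-values are calibrated under the null", {
  set.seed(80)
  tb <- matrix(rpois(200 * 12, 20), 200, 12,
               dimnames = list(sprintf("t%d", 1:200), sprintf("s%d", 1:12)))
  res <- kruskal_wallis_per_taxon(tb, rep(c("a", "b"), each = 6),
                                  normalize = FALSE)
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.045)
})

test_that("p-value adjustment follows Bonferroni and BH step-up", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(0.01, "bh"), 0.01)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.04), "bh"),
               c(0.03, 0.03, 0.04))
  p <- runif(20)
  expect_true(all(adjust_pvalues(p, "bonferroni") >= p))
  expect_true(all(adjust_pvalues(p, "bh") <= 1))
  # BH output is monotone after sorting by raw p
  adj <- adjust_pvalues(p, "bh")
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})
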