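#!/usr/bin/env Rscript
# Rarefied Shannon diversity of the total (DNA) and active (RNA)
# communities, and the abundant-active-taxon census per treatment.

library(saltmarsh)

sim <- "results/sim"
paired <- align_paired(read_count_table(file.path(sim, "dna.tsv")),
                       read_count_table(file.path(sim, "rna.tsv")),
                       read_metadata(file.path(sim, "map.tsv")))
md <- paired$metadata

depth <- min(colSums(paired$dna), colSums(paired$rna))
cat(sprintf("rarefying both molecules to the lowest depth (%d reads)\n", depth))
div <- rbind(cbind(molecule = "dna",
                   mean_rarefied_shannon(paired$dna, depth, restarts = 25,
                                         seed = 71)),
             cbind(molecule = "rna",
                   mean_rarefied_shannon(paired$rna, depth, restarts = 25,
                                         seed = 72)))
div <- merge(div, md, by = "sample_id")
utils::write.table(div, "results/diversity.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
for (mol in c("dna", "rna")) for (tr in unique(md$treatment)) {
  sel <- div$molecule == mol & div$treatment == tr
  cat(sprintf("%s %s: Shannon %.2f bits\n", tr,
              toupper(mol), mean(div$shannon[sel])))
}
aov_rna <- dormancy_anova(div$shannon[div$molecule == "rna"],
                          div$treatment[div$molecule == "rna"])
cat(sprintf("active (RNA) diversity ~ fertilization: F = %.2f, p = %.3g\n",
            aov_rna$F, aov_rna$p))

census <- abundant_active_taxa(paired, theta = 1, min_count = 100)
n <- attr(census, "n")
cat(sprintf("abundant active taxa (>=100 RNA reads, ratio > 1): %s\n",
            paste(sprintf("%s n=%d", names(n), n), collapse = ", ")))
utils::write.table(
  data.frame(group = rep(names(census), lengths(census)),
             taxon_id = unlist(census, use.names = FALSE)),
  "results/abundant_active_taxa.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
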