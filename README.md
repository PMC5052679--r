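# saltmarsh

Dormancy, active-community diversity and tidal-creek metabolism in
nutrient-enriched salt marsh sediments.

## The problem

Surveys of the 16S rRNA *gene* (DNA) count every cell — active, dormant,
dead — so a sediment community can look completely unresponsive to a
perturbation even while its *active* fraction reorganises. Sequencing the
gene's transcript (16S rRNA) alongside the gene gives a per-taxon activity
signal: a taxon transcribing far fewer ribosomes than its gene abundance
predicts is plausibly dormant. This package implements that paired
RNA/DNA analysis for a long-term salt marsh nitrogen-enrichment
experiment, together with a dissolved-oxygen metabolism estimator for the
adjacent tidal creeks, and synthetic-data generators with known ground
truth so every stage of the pipeline is testable.

It is written for microbial ecologists working with paired
amplicon libraries (QIIME-style OTU tables, mapping files, newick trees)
and for biogeochemists with creek sonde records.

## The model

For taxon *i* in a sample, the activity ratio is

    r_i = RNA_i / (DNA_i + 1)

computed on library-size-normalized counts. The +1 on the gene count
encodes the assumption that a taxon observed in the RNA pool must be
present in the total community even if its gene escaped sequencing. A
detected taxon (nonzero in either molecule) is **dormant** when
`r_i <= theta` (default threshold `theta = 1`, with a sensitivity sweep
over `theta = 1..50`), and the per-sample dormant proportion is the
fraction of detected taxa that are dormant. Downstream: rarefied Shannon
diversity of the total (DNA) and active (RNA) communities, Bray-Curtis and
weighted UniFrac distances with PCoA and permutation PERMANOVA, per-taxon
Kruskal-Wallis tests with Bonferroni/Benjamini-Hochberg correction, and a
one-way ANOVA of dormancy against fertilization.

For a tidal creek, net ecosystem metabolism (photosynthesis minus
respiration, positive = net autotrophy) is the residual of a
non-steady-state oxygen mass balance per unit creek length:

    NEM(t) = d(V C)/dt - Q_adv C - F_gas

with `V(h)` the wetted volume from the trapezoidal cross-section, `Q_adv =
dV/dt` the tidal volume flux, and `F_gas = k(wind, current, depth) (C_sat
- C) width(h)` the air-water exchange using the combined-fit oxygen
solubility function and a Schmidt-scaled transfer velocity. NEM is
summarised over the hour of each high tide; windows whose peak depth
floods the marsh platform are flagged and can receive a constant bias
correction.

## Worked example

The `analysis/` scripts run the whole workflow on a simulated experiment
(72 paired samples: 2 treatments x 2 habitats x 6 months x 3 replicates;
45% of taxa truly dormant in the reference arm, enrichment reassigning
activity into a small bloom) and two simulated creek deployments:

```sh
Rscript analysis/01_simulate_experiment.R
Rscript analysis/02_dormancy.R
Rscript analysis/03_diversity.R
Rscript analysis/04_community_stats.R
Rscript analysis/05_nem.R
```

Output from one run:

```
reference: 49.5% dormant taxa (mean over 36 samples)
enriched: 94.5% dormant taxa (mean over 36 samples)
dormancy ~ fertilization: F = 30803.64 (df 1,70), p = 2.64e-94
...
reference DNA: Shannon 6.38 bits
enriched DNA: Shannon 6.37 bits
reference RNA: Shannon 5.99 bits
enriched RNA: Shannon 3.40 bits
abundant active taxa (>=100 RNA reads, ratio > 1): reference n=82, enriched n=8
...
PERMANOVA (10,000 permutations):
  dna_bray      treatment F =   0.66  p = 0.6243
  dna_bray      habitat   F =  59.08  p = 9.999e-05
  rna_bray      treatment F = 266.12  p = 9.999e-05
...
enriched - reference NEM over high tide: day +0.14, night -0.43
```

Read: fertilization roughly doubles the dormant share of the community
and collapses active-community diversity while the total (DNA) community
is structured by habitat, not treatment — and the enriched creek is more
autotrophic by day and more heterotrophic by night. Per-sample tables land
under `results/`.

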