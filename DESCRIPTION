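Package: saltmarsh
Title: Dormancy, Active-Community Diversity and Tidal-Creek Metabolism in
    Nutrient-Enriched Salt Marshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for paired 16S rRNA / 16S rRNA gene (RNA/DNA)
    community surveys of salt marsh sediments under long-term nitrogen
    enrichment, together with a dissolved-oxygen net-ecosystem-metabolism
    (NEM) estimator for tidal creeks. Computes per-taxon RNA:DNA activity
    ratios, classifies taxa as active or dormant with threshold sensitivity
    sweeps, estimates per-sample dormant proportions, summarises activity at
    the taxonomic-order level, and tests dormancy against fertilization with
    one-way ANOVA. Provides rarefaction and Shannon diversity of total and
    active communities, Bray-Curtis and weighted UniFrac beta diversity,
    principal coordinate analysis, permutation PERMANOVA, and per-taxon
    Kruskal-Wallis tests with Bonferroni or Benjamini-Hochberg correction.
    The NEM module builds a non-steady-state oxygen mass balance for a tidal
    creek control volume from depth, geometry, gas exchange and solubility,
    and aggregates metabolism over high-tide windows. Synthetic-data
    generators with known ground truth (Dirichlet-multinomial paired
    community tables; forward-simulated tidal creek oxygen series) drive all
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    biomformat,
    phyloseq,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
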