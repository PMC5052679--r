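# Paired DNA/RNA community simulator with known activity ground truth.
#
# The community is a lognormal rank-abundance distribution; each taxon
# carries an activity multiplier (RNA transcripts per gene copy). Dormant
# taxa get multipliers below 1, active taxa multipliers above 1. Because
# sequencing fixes the RNA library size, only relative activity is
# observable: the generator therefore calibrates the abundance-weighted
# mean multiplier to 1, which makes the RNA:(DNA+1) ratio of a taxon equal
# to its multiplier in expectation and the ratio-1 classifier consistent
# with the truth labels. A side effect matching real paired libraries: the
# fewer taxa are active, the higher their apparent ratios.

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

#' Configuration for the paired community simulator
#'
#' @param n_taxa Number of taxa (default 200).
#' @param n_samples Number of biological samples (default 12).
#' @param dormant_fraction True fraction of dormant taxa, in `[0, 1]`
#'   (default 0.45).
#' @param dormant_meanlog,dormant_sdlog,dormant_max Lognormal law of
#'   dormant activity multipliers, truncated at `dormant_max` (< 1).
#' @param active_floor Minimum active multiplier (> 1); keeps active taxa
#'   clear of the classification boundary.
#' @param active_shape Gamma shape of the active multiplier excess above
#'   the floor; the mean is auto-calibrated so the abundance-weighted mean
#'   multiplier is 1.
#' @param rank_sdlog Lognormal shape of the rank-abundance law (default 1).
#' @param treatment `"reference"` or `"enriched"`; enrichment reassigns
#'   most active taxa to dormancy and concentrates activity in a small
#'   bloom.
#' @param bloom_fraction Fraction of active taxa that bloom under
#'   enrichment (default 0.1).
#' @param bloom_boost Multiplier applied to bloom taxa activity before
#'   recalibration (default 10).
#' @param depth_dna,depth_rna Library sizes (reads; >= 1000).
#' @param overdispersion Dirichlet concentration of per-sample community
#'   proportions around the base abundances (larger = closer to
#'   multinomial; default 1000).
#' @param habitat,month Metadata constants for the simulated samples.
#' @param seed Integer seed (mandatory).
#' @return A `community_sim_config` list.
#' @export
community_sim_config <- function(n_taxa = 200, n_samples = 12,
                                 dormant_fraction = 0.45,
                                 dormant_meanlog = log(0.12),
                                 dormant_sdlog = 0.6, dormant_max = 0.5,
                                 active_floor = 1.4, active_shape = 2,
                                 rank_sdlog = 1,
                                 treatment = c("reference", "enriched"),
                                 bloom_fraction = 0.1, bloom_boost = 10,
                                 depth_dna = 5e4, depth_rna = 5e4,
                                 overdispersion = 1000,
                                 habitat = "TSA", month = 1, seed) {
  treatment <- match.arg(treatment)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (dormant_fraction < 0 || dormant_fraction > 1)
    stop("dormant_fraction must be in [0, 1]", call. = FALSE)
  if (depth_dna < 1e3 || depth_rna < 1e3)
    stop("library depths must be >= 1000", call. = FALSE)
  if (dormant_max >= 1 || active_floor <= 1)
    stop("dormant_max must be < 1 and active_floor > 1", call. = FALSE)
  n_dormant <- round(dormant_fraction * n_taxa)
  if (dormant_fraction > 0 && n_dormant < 1)
    stop("dormant_fraction leaves no dormant taxon", call. = FALSE)
  if (dormant_fraction < 1 && n_taxa - n_dormant < 1)
    stop("dormant_fraction leaves no active taxon", call. = FALSE)
  structure(as.list(environment()), class = "community_sim_config")
}

draw_dormant_mult <- function(n, config) {
  pmin(stats::rlnorm(n, config$dormant_meanlog, config$dormant_sdlog),
       config$dormant_max)
}

# active multipliers = floor + Gamma excess, with the Gamma mean chosen so
# that sum(pi * m) = target over the whole community
draw_active_mult <- function(pi_active, target_mass, config) {
  mu <- target_mass / sum(pi_active)
  mu <- max(mu, config$active_floor * 1.05)
  excess_mean <- mu - config$active_floor
  config$active_floor +
    stats::rgamma(length(pi_active), shape = config$active_shape,
                  rate = config$active_shape / excess_mean)
}

# truth multipliers for one treatment arm; base_pi and the dormant label
# assignment are shared between arms so the DNA table is
# treatment-invariant by construction
build_multipliers <- function(base_pi, dormant, config, enriched = FALSE) {
  n <- length(base_pi)
  m <- numeric(n)
  m[dormant] <- draw_dormant_mult(sum(dormant), config)
  active <- which(!dormant)
  if (enriched && length(active) > 1L) {
    n_bloom <- max(1L, round(config$bloom_fraction * length(active)))
    bloom <- sample(active, n_bloom)
    demoted <- setdiff(active, bloom)
    dormant[demoted] <- TRUE
    m[demoted] <- draw_dormant_mult(length(demoted), config)
    m[bloom] <- (config$active_floor +
                   stats::rgamma(n_bloom, shape = config$active_shape,
                                 rate = config$active_shape)) *
      config$bloom_boost
    # recalibrate the bloom so the abundance-weighted mean multiplier is 1
    target <- 1 - sum(base_pi[dormant] * m[dormant])
    s <- target / sum(base_pi[bloom] * m[bloom])
    if (s > 0) m[bloom] <- pmax(m[bloom] * s, config$active_floor * 1.05)
    active <- bloom
  } else {
    target <- 1 - sum(base_pi[dormant] * m[dormant])
    m[active] <- draw_active_mult(base_pi[active], target, config)
  }
  list(multiplier = m, dormant = dormant)
}

#' Simulate a paired DNA/RNA community table with known activity truth
#'
#' Draws base taxon abundances from a lognormal rank-abundance law and,
#' per sample, a Dirichlet-perturbed community shared by both molecules;
#' DNA counts are multinomial on the perturbed proportions and RNA counts
#' multinomial on the proportions reweighted by the per-taxon activity
#' multipliers. Under `treatment = "enriched"`, all but a bloom fraction of
#' the active taxa are reassigned to dormancy and the bloom taxa absorb the
#' community's activity.
#'
#' @param config A [community_sim_config()].
#' @return List with `paired` (a `paired_community` including metadata) and
#'   `truth` (data frame: `taxon_id`, `dormant`, `multiplier`,
#'   `base_abundance`).
#' @export
simulate_paired_community <- function(config) {
  stopifnot(inherits(config, "community_sim_config"))
  set.seed(config$seed)
  n <- config$n_taxa
  taxa <- sprintf("OTU_%04d", seq_len(n))
  base_pi <- sort(stats::rlnorm(n, 0, config$rank_sdlog), decreasing = TRUE)
  base_pi <- base_pi / sum(base_pi)
  dormant0 <- rep(FALSE, n)
  if (config$n_dormant > 0) dormant0[sample.int(n, config$n_dormant)] <- TRUE
  tr <- build_multipliers(base_pi, dormant0, config,
                          enriched = config$treatment == "enriched")
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  dna <- rna <- matrix(0, n, config$n_samples, dimnames = list(taxa, samples))
  for (j in seq_len(config$n_samples)) {
    pi_s <- rdirichlet1(config$overdispersion * base_pi)
    q_s <- pi_s * tr$multiplier
    q_s <- q_s / sum(q_s)
    dna[, j] <- stats::rmultinom(1, config$depth_dna, pi_s)
    rna[, j] <- stats::rmultinom(1, config$depth_rna, q_s)
  }
  md <- data.frame(sample_id = samples, treatment = config$treatment,
                   habitat = config$habitat,
                   date = as.Date("2013-05-01") + 31 * (config$month - 1),
                   replicate = seq_len(config$n_samples),
                   stringsAsFactors = FALSE)
  paired <- structure(list(taxon_ids = taxa, sample_ids = samples,
                           dna = dna, rna = rna, metadata = md),
                      class = "paired_community")
  truth <- data.frame(taxon_id = taxa, dormant = tr$dormant,
                      multiplier = tr$multiplier, base_abundance = base_pi,
                      stringsAsFactors = FALSE)
  list(paired = paired, truth = truth)
}

FOCAL_ORDERS <- c("Desulfobacterales", "Oscillatoriales")
OTHER_ORDERS <- c("Chromatiales", "Rhizobiales", "Rhodocyclales",
                  "Chlorobiales", "Desulfuromonadales", "Flavobacteriales",
                  "Alteromonadales", "Bacteroidales", "Clostridiales",
                  "Campylobacterales", "Nitrosomonadales", "Anaerolineales")

#' Configuration for a full simulated enrichment experiment
#'
#' Factorial design: treatment (reference/enriched) x habitat (TSA/SP) x
#' month x replicate. Habitat tilts the base abundances (so habitat
#' structures the total community); month jitters the reference-arm active
#' multipliers (seasonality of the active community, suppressed under
#' enrichment); treatment changes activity only, so the DNA table is
#' treatment-invariant by construction.
#'
#' @inheritParams community_sim_config
#' @param months Number of monthly sampling dates (default 6, May-October).
#' @param replicates Replicates per cell (default 3).
#' @param habitats Habitat levels (default `c("TSA", "SP")`).
#' @param treatments Treatment levels.
#' @param habitat_tilt Lognormal s.d. of the per-habitat abundance tilt
#'   (default 0.5).
#' @param season_sd Lognormal s.d. of the monthly jitter on reference
#'   active multipliers (default 0.25).
#' @param treatment_effect Simulate the enrichment effect on activity;
#'   `FALSE` gives a null experiment (both arms share multipliers).
#' @return An `experiment_sim_config` list.
#' @export
experiment_sim_config <- function(n_taxa = 150, months = 1, replicates = 6,
                                  habitats = c("TSA", "SP"),
                                  treatments = c("reference", "enriched"),
                                  dormant_fraction = 0.45,
                                  dormant_meanlog = log(0.12),
                                  dormant_sdlog = 0.6, dormant_max = 0.5,
                                  active_floor = 1.4, active_shape = 2,
                                  rank_sdlog = 1,
                                  bloom_fraction = 0.1, bloom_boost = 10,
                                  depth_dna = 1e4, depth_rna = 1e4,
                                  overdispersion = 1000,
                                  habitat_tilt = 0.5, season_sd = 0.25,
                                  treatment_effect = TRUE, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  n_dormant <- round(dormant_fraction * n_taxa)
  structure(as.list(environment()), class = "experiment_sim_config")
}

#' Simulate a full enrichment experiment
#'
#' Generates the paired community table over the factorial design of
#' [experiment_sim_config()], plus taxonomy (order labels including the
#' focal orders Desulfobacterales and Oscillatoriales, with bloom taxa
#' placed preferentially in them), a random coalescent tree over the taxa,
#' and per-arm truth labels. Optionally writes every artefact to disk in
#' the package's IO dialects.
#'
#' @param config An [experiment_sim_config()].
#' @param out_dir Optional directory; when given, writes `dna.tsv`,
#'   `rna.tsv` (sample ids suffixed `_DNA` / `_cDNA`), `map.tsv`,
#'   `taxonomy.tsv` and `tree.nwk`.
#' @return List with `paired`, `truth` (per-arm list), `taxonomy`, `tree`,
#'   and `files` (paths, when written).
#' @export
simulate_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_sim_config"))
  set.seed(config$seed)
  n <- config$n_taxa
  taxa <- sprintf("OTU_%04d", seq_len(n))
  base_pi <- sort(stats::rlnorm(n, 0, config$rank_sdlog), decreasing = TRUE)
  base_pi <- base_pi / sum(base_pi)
  habitat_pi <- lapply(config$habitats, function(h) {
    p <- base_pi * stats::rlnorm(n, 0, config$habitat_tilt)
    p / sum(p)
  })
  names(habitat_pi) <- config$habitats

  dormant0 <- rep(FALSE, n)
  if (config$n_dormant > 0) dormant0[sample.int(n, config$n_dormant)] <- TRUE
  truth <- list()
  for (tr in config$treatments) {
    enr <- config$treatment_effect && tr == "enriched"
    truth[[tr]] <- build_multipliers(base_pi, dormant0, config, enriched = enr)
  }
  if (!config$treatment_effect)
    truth <- stats::setNames(rep(truth[1L], length(config$treatments)),
                             config$treatments)

  design <- expand.grid(replicate = seq_len(config$replicates),
                        month = seq_len(config$months),
                        habitat = config$habitats,
                        treatment = config$treatments,
                        stringsAsFactors = FALSE)
  samples <- sprintf("%s_%s_m%02d_r%d",
                     ifelse(design$treatment == "enriched", "enr", "ref"),
                     design$habitat, design$month, design$replicate)
  # monthly jitter of reference active multipliers (seasonality of the
  # active community); the enriched arm is spatiotemporally homogenized
  month_jitter <- lapply(seq_len(config$months), function(mo)
    stats::rlnorm(n, 0, config$season_sd))

  dna <- rna <- matrix(0, n, nrow(design), dimnames = list(taxa, samples))
  for (j in seq_len(nrow(design))) {
    tr <- truth[[design$treatment[j]]]
    m <- tr$multiplier
    if (design$treatment[j] == "reference" || !config$treatment_effect)
      m <- ifelse(tr$dormant, m, m * month_jitter[[design$month[j]]])
    pi_s <- rdirichlet1(config$overdispersion * habitat_pi[[design$habitat[j]]])
    q_s <- pi_s * m
    q_s <- q_s / sum(q_s)
    dna[, j] <- stats::rmultinom(1, config$depth_dna, pi_s)
    rna[, j] <- stats::rmultinom(1, config$depth_rna, q_s)
  }
  md <- data.frame(sample_id = samples, treatment = design$treatment,
                   habitat = design$habitat,
                   date = as.Date("2013-05-01") + 31 * (design$month - 1),
                   replicate = design$replicate, stringsAsFactors = FALSE)
  paired <- structure(list(taxon_ids = taxa, sample_ids = samples,
                           dna = dna, rna = rna, metadata = md),
                      class = "paired_community")

  # order labels: bloom taxa (enriched-arm actives) preferentially in the
  # focal bloom-forming orders
  orders <- sample(OTHER_ORDERS, n, replace = TRUE,
                   prob = stats::rlnorm(length(OTHER_ORDERS), 0, 0.5))
  bloom_taxa <- which(!truth[[length(truth)]]$dormant)
  orders[bloom_taxa] <- sample(FOCAL_ORDERS, length(bloom_taxa), replace = TRUE)
  lineage <- paste("Bacteria", "unclassified", "unclassified", orders,
                   sep = ";")
  taxonomy <- parse_lineage(lineage, taxa)
  tree <- ape::rcoal(n, tip.label = taxa)

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    dna_out <- dna; colnames(dna_out) <- paste0(samples, "_DNA")
    rna_out <- rna; colnames(rna_out) <- paste0(samples, "_cDNA")
    files <- list(dna = file.path(out_dir, "dna.tsv"),
                  rna = file.path(out_dir, "rna.tsv"),
                  map = file.path(out_dir, "map.tsv"),
                  taxonomy = file.path(out_dir, "taxonomy.tsv"),
                  tree = file.path(out_dir, "tree.nwk"))
    write_count_table(dna_out, files$dna)
    write_count_table(rna_out, files$rna)
    write_metadata(md, files$map)
    write_taxonomy(taxonomy, files$taxonomy)
    ape::write.tree(tree, files$tree)
  }
  list(paired = paired, truth = truth, taxonomy = taxonomy, tree = tree,
       files = files)
}
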