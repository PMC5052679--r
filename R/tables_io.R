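# IO for count tables, sample metadata, taxonomy, trees and creek sensor
# series. Count tables are plain numeric matrices, taxa in rows and samples
# in columns, with unique dimnames; all readers validate rather than coerce.

#' Validate a count table
#'
#' Checks the count-table contract used throughout the package: a
#' non-negative integer-valued matrix with unique taxon (row) and sample
#' (column) names.
#'
#' @param counts Numeric matrix, taxa in rows, samples in columns.
#' @param what Label used in error messages.
#' @return The validated matrix, invisibly classed as it came in.
#' @export
validate_count_table <- function(counts, what = "count table") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop(what, ": counts must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop(what, ": taxon and sample names are required", call. = FALSE)
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop(what, ": duplicate taxon id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    stop(what, ": duplicate sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (anyNA(counts))
    stop(what, ": missing values are not allowed", call. = FALSE)
  if (any(counts < 0))
    stop(what, ": negative counts at row(s) ",
         paste(utils::head(rownames(counts)[rowSums(counts < 0) > 0], 5),
               collapse = ", "), call. = FALSE)
  if (any(counts != round(counts)))
    stop(what, ": non-integer counts at row(s) ",
         paste(utils::head(rownames(counts)[rowSums(counts != round(counts)) > 0], 5),
               collapse = ", "), call. = FALSE)
  invisible(counts)
}

#' Read an OTU count table
#'
#' Reads a taxa-by-samples count table. The `tsv` dialect expects a header
#' row of sample ids with the first column holding taxon ids (a leading
#' `#OTU ID` comment header is accepted); `biom_json` reads the dense BIOM
#' JSON dialect via the biomformat package.
#'
#' @param path File path.
#' @param dialect One of `"tsv"` or `"biom_json"`.
#' @return Numeric matrix (taxa x samples) with integer counts.
#' @export
read_count_table <- function(path, dialect = c("tsv", "biom_json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "biom_json") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("biomformat is required for the biom_json dialect", call. = FALSE)
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    storage.mode(m) <- "double"
    validate_count_table(m, what = path)
    return(m)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#(?!OTU)", lines, perl = TRUE)]
  if (!length(lines)) stop(path, ": empty table", call. = FALSE)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) < 2L)
    stop(path, ": malformed header (need taxon id column plus >=1 sample)",
         call. = FALSE)
  dup <- hdr[-1L][duplicated(hdr[-1L])]
  if (length(dup))
    stop(path, ": duplicate sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(tab[, -1L, drop = FALSE], 2L,
                       function(x) any(is.na(suppressWarnings(as.numeric(x))))))
    stop(path, ": non-numeric cell(s) in column(s) ",
         paste(colnames(tab)[-1L][bad], collapse = ", "), call. = FALSE)
  }
  rownames(m) <- ids
  validate_count_table(m, what = path)
  m
}

#' Write an OTU count table
#'
#' @param counts Count matrix (taxa x samples).
#' @param path Output path.
#' @param dialect `"tsv"` or `"biom_json"`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, dialect = c("tsv", "biom_json")) {
  dialect <- match.arg(dialect)
  validate_count_table(counts)
  if (dialect == "biom_json") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("biomformat is required for the biom_json dialect", call. = FALSE)
    biomformat::write_biom(biomformat::make_biom(counts), path)
    return(invisible(path))
  }
  df <- data.frame(`#OTU ID` = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a QIIME-style sample mapping file
#'
#' Expects a TSV whose header starts with `#SampleID` and whose columns
#' include `Treatment` (enriched/reference), `Habitat` (TSA/SP), `Date`
#' (ISO date) and optionally `Replicate`.
#'
#' @param path File path.
#' @return `data.frame` with columns `sample_id`, `treatment`, `habitat`,
#'   `date`, `replicate`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#SampleID"))
    stop(path, ": mapping file must start with a #SampleID header", call. = FALSE)
  lines[1L] <- sub("^#", "", lines[1L])
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("sampleid", "treatment", "habitat", "date")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  md <- data.frame(sample_id = as.character(tab$sampleid),
                   treatment = as.character(tab$treatment),
                   habitat = as.character(tab$habitat),
                   date = as.Date(tab$date),
                   replicate = if ("replicate" %in% names(tab))
                     as.integer(tab$replicate) else NA_integer_,
                   stringsAsFactors = FALSE)
  validate_metadata(md, what = path)
  md
}

#' @rdname read_metadata
#' @param metadata Metadata data frame as returned by [read_metadata()].
#' @param what Label used in error messages.
#' @export
validate_metadata <- function(metadata, what = "metadata") {
  dup <- metadata$sample_id[duplicated(metadata$sample_id)]
  if (length(dup))
    stop(what, ": duplicate sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(metadata$treatment), c("enriched", "reference"))
  if (length(bad))
    stop(what, ": treatment must be enriched/reference, got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(metadata$habitat), c("TSA", "SP"))
  if (length(bad))
    stop(what, ": habitat must be TSA/SP, got: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyNA(metadata$date))
    stop(what, ": unparseable date(s)", call. = FALSE)
  invisible(metadata)
}

#' Write a QIIME-style mapping file
#'
#' @param metadata Metadata data frame.
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  validate_metadata(metadata)
  df <- data.frame(`#SampleID` = metadata$sample_id,
                   Treatment = metadata$treatment,
                   Habitat = metadata$habitat,
                   Date = format(metadata$date),
                   Replicate = metadata$replicate,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

#' Read a taxonomy map
#'
#' Two-column TSV (`taxon_id`, semicolon-delimited lineage, up to 7 ranks
#' kingdom..species). Unresolved ranks become `"unclassified"`.
#'
#' @param path File path.
#' @return `data.frame` with `taxon_id` plus one column per rank.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 2) stop(path, ": expected taxon_id<TAB>lineage", call. = FALSE)
  parse_lineage(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' @rdname read_taxonomy
#' @param lineage Character vector of semicolon-delimited lineages.
#' @param taxon_id Taxon identifiers, same length as `lineage`.
#' @export
parse_lineage <- function(lineage, taxon_id) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  if (any(lengths(parts) > 7L))
    stop("lineage with more than 7 ranks for taxon ",
         taxon_id[which(lengths(parts) > 7L)[1L]], call. = FALSE)
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    # strip greengenes-style prefixes ("o__Desulfobacterales")
    p <- sub("^[a-z]__", "", p)
    p[p == ""] <- "unclassified"
    c(p, rep("unclassified", 7L - length(p)))
  }, character(7L)))
  colnames(m) <- RANKS
  out <- data.frame(taxon_id = taxon_id, m, stringsAsFactors = FALSE)
  dup <- out$taxon_id[duplicated(out$taxon_id)]
  if (length(dup))
    stop("duplicate taxon id(s) in taxonomy: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  out
}

#' Look up a taxonomic rank for a set of taxa
#'
#' @param taxonomy Taxonomy data frame from [read_taxonomy()].
#' @param taxon_ids Taxa to look up; unknown taxa map to `"unclassified"`.
#' @param rank Rank name (default `"order"`).
#' @return Character vector of rank labels, one per taxon.
#' @export
taxonomy_rank <- function(taxonomy, taxon_ids, rank = "order") {
  rank <- match.arg(rank, RANKS)
  idx <- match(taxon_ids, taxonomy$taxon_id)
  out <- taxonomy[[rank]][idx]
  out[is.na(out)] <- "unclassified"
  out
}

#' Write a taxonomy map
#' @param taxonomy Taxonomy data frame.
#' @param path Output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  lin <- apply(as.matrix(taxonomy[RANKS]), 1L, paste, collapse = ";")
  utils::write.table(data.frame(taxonomy$taxon_id, lin),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree
#'
#' Newick reader (via ape) enforcing unique leaf labels and non-negative
#' branch lengths.
#'
#' @param path Newick file.
#' @return An ape `phylo` object.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop(path, ": could not parse newick", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop(path, ": duplicate leaf name(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop(path, ": negative branch length(s)", call. = FALSE)
  tree
}

#' Read a tidal-creek sensor series
#'
#' CSV with ISO `timestamp` plus `depth_m`, `temperature_c`, `salinity`,
#' `wind_m_s`, `current_m_s`, and exactly one of `o2_saturation_pct` or
#' `o2_mmol_m3`. Timestamps must be strictly increasing with a constant
#' step.
#'
#' @param path CSV path.
#' @return A `creek_series` data frame with attribute `dt_min` (step,
#'   minutes).
#' @export
read_creek_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  ts <- as.POSIXct(tab$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                  "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%d"))
  if (anyNA(ts)) stop(path, ": unparseable timestamp(s)", call. = FALSE)
  tab$timestamp <- ts
  as_creek_series(tab)
}

#' @rdname read_creek_series
#' @param x Data frame with the creek-series columns.
#' @export
as_creek_series <- function(x) {
  need <- c("timestamp", "depth_m", "temperature_c", "salinity",
            "wind_m_s", "current_m_s")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("creek series: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  has_sat <- "o2_saturation_pct" %in% names(x)
  has_conc <- "o2_mmol_m3" %in% names(x)
  if (has_sat == has_conc)
    stop("creek series: exactly one of o2_saturation_pct / o2_mmol_m3 required",
         call. = FALSE)
  dt <- diff(as.numeric(x$timestamp)) / 60
  if (any(dt <= 0))
    stop("creek series: timestamps must be strictly increasing", call. = FALSE)
  if (length(dt) && diff(range(dt)) > 1e-6)
    stop("creek series: non-uniform timestamp spacing", call. = FALSE)
  if (any(x$depth_m < 0)) stop("creek series: negative depth", call. = FALSE)
  if (any(x$salinity < 0)) stop("creek series: negative salinity", call. = FALSE)
  structure(as.data.frame(x), dt_min = if (length(dt)) dt[1L] else NA_real_,
            class = c("creek_series", "data.frame"))
}

#' Write a tidal-creek sensor series
#' @param series `creek_series` object.
#' @param path Output CSV path.
#' @export
write_creek_series <- function(series, path) {
  out <- as.data.frame(series)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align DNA and RNA count tables into a paired community table
#'
#' DNA (16S rRNA gene) and RNA (16S rRNA) libraries of one biological
#' sample are keyed by a shared base sample id carrying molecule suffixes
#' (default `"_DNA"` / `"_cDNA"`); the suffixes are stripped and the two
#' tables aligned on the base ids and on a harmonized taxon set.
#'
#' @param dna,rna Count matrices (taxa x samples).
#' @param metadata Metadata data frame keyed by base sample id, or `NULL`.
#' @param taxon_policy `"union"` (missing taxa zero-padded; default) or
#'   `"intersection"`.
#' @param suffixes Length-2 character: DNA suffix, RNA suffix. Use `c("","")`
#'   if the tables already share base ids.
#' @return A `paired_community` object: list with `taxon_ids`, `sample_ids`,
#'   `dna`, `rna`, `metadata`.
#' @export
align_paired <- function(dna, rna, metadata = NULL,
                         taxon_policy = c("union", "intersection"),
                         suffixes = c("_DNA", "_cDNA")) {
  taxon_policy <- match.arg(taxon_policy)
  validate_count_table(dna, "dna table")
  validate_count_table(rna, "rna table")
  strip <- function(ids, suf) if (nzchar(suf)) sub(paste0(suf, "$"), "", ids) else ids
  dna_ids <- strip(colnames(dna), suffixes[1L])
  rna_ids <- strip(colnames(rna), suffixes[2L])
  only_dna <- setdiff(dna_ids, rna_ids)
  only_rna <- setdiff(rna_ids, dna_ids)
  if (length(only_dna) || length(only_rna))
    stop("unmatched samples: ",
         if (length(only_dna)) paste0("DNA-only {", paste(only_dna, collapse = ", "), "} "),
         if (length(only_rna)) paste0("RNA-only {", paste(only_rna, collapse = ", "), "}"),
         call. = FALSE)
  samples <- dna_ids
  if (!is.null(metadata)) {
    validate_metadata(metadata)
    if (!setequal(samples, metadata$sample_id))
      stop("sample ids do not match metadata: missing {",
           paste(setdiff(samples, metadata$sample_id), collapse = ", "),
           "}, extra {",
           paste(setdiff(metadata$sample_id, samples), collapse = ", "), "}",
           call. = FALSE)
    samples <- metadata$sample_id[metadata$sample_id %in% samples]
    metadata <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
    rownames(metadata) <- NULL
  }
  taxa <- switch(taxon_policy,
                 union = union(rownames(dna), rownames(rna)),
                 intersection = intersect(rownames(dna), rownames(rna)))
  if (!length(taxa)) stop("no shared taxa under intersection policy", call. = FALSE)
  expand <- function(m, ids) {
    out <- matrix(0, length(taxa), length(samples),
                  dimnames = list(taxa, samples))
    keep <- intersect(taxa, rownames(m))
    out[keep, ] <- m[keep, match(samples, ids), drop = FALSE]
    out
  }
  structure(list(taxon_ids = taxa, sample_ids = samples,
                 dna = expand(dna, dna_ids), rna = expand(rna, rna_ids),
                 metadata = metadata),
            class = "paired_community")
}

#' @export
print.paired_community <- function(x, ...) {
  cat("paired_community:", length(x$taxon_ids), "taxa x",
      length(x$sample_ids), "samples\n")
  cat("  DNA reads:", sum(x$dna), " RNA reads:", sum(x$rna), "\n")
  if (!is.null(x$metadata))
    cat("  groups:", paste(names(table(x$metadata$treatment)),
                           table(x$metadata$treatment), collapse = ", "), "\n")
  invisible(x)
}
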