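#' Step-wise homology filtering to call lineage-specific genes
#'
#' Reproduces the cascade design: a gene survives as lineage-specific
#' (family level) if and only if it has no hit with e-value below
#' `lsg_evalue_cutoff` to any subject outside the lineage taxon list in any
#' database tier, and carries no domain flagged as occurring outside the
#' lineage. Self-hits and hits to within-lineage subjects never eliminate a
#' gene; the cascade - not the search engine - is the bespoke computation, so
#' position-specific results are just another tier table.
#'
#' @param gene_ids character vector of tested gene models.
#' @param hit_tables named list of HSP data.frames ([readHitTable()] layout),
#'   in tier order (e.g. peptide-db, nucleotide-db, est-db,
#'   position-specific).
#' @param subject_taxa data.frame with columns `subject_id`, `taxon` labelling
#'   every subject that appears in the tier tables.
#' @param lineage_taxa character vector of taxa inside the lineage; only
#'   subjects outside this list eliminate.
#' @param domain_annotations optional data.frame `gene_id`, `domain_id`,
#'   `cross_lineage` (logical): a gene with any `cross_lineage` domain is
#'   removed at the final tier.
#' @param thresholds a [ThresholdConfig-class].
#' @return data.frame with one row per tested gene: `gene_id`, `is_lsg`,
#'   `lineage_level` (`"family_specific"` for survivors, `NA` otherwise),
#'   `eliminating_tier` (`NA` for survivors) and a `filter_trace` list-column
#'   recording, per tier, the hits considered and the survived flag.
#' @export
stepwiseFilter <- function(gene_ids, hit_tables, subject_taxa, lineage_taxa,
                           domain_annotations = NULL,
                           thresholds = thresholdConfig()) {
    stopifnot(is.list(hit_tables), !is.null(names(hit_tables)))
    cutoff <- thresholds@lsg_evalue_cutoff
    taxon_of <- setNames(subject_taxa$taxon, subject_taxa$subject_id)

    eliminating_tier <- setNames(rep(NA_character_, length(gene_ids)),
                                 gene_ids)
    trace <- setNames(vector("list", length(gene_ids)), gene_ids)
    alive <- setNames(rep(TRUE, length(gene_ids)), gene_ids)

    for (tier in names(hit_tables)) {
        ht <- hit_tables[[tier]]
        unknown <- setdiff(unique(ht$query_id), gene_ids)
        if (length(unknown))
            stop("hit table '", tier, "' references unknown gene id(s): ",
                 paste(head(unknown, 5), collapse = ", "))
        tax <- taxon_of[ht$subject_id]
        if (anyNA(tax))
            stop("hit table '", tier, "' has subjects without taxon labels")
        eliminating <- ht$e_value < cutoff &
            !(tax %in% lineage_taxa) &
            ht$subject_id != ht$query_id
        n_hits <- table(factor(ht$query_id, levels = gene_ids))
        killed <- unique(ht$query_id[eliminating])
        for (g in gene_ids) {
            # once eliminated, later tiers are still recorded but moot
            trace[[g]] <- rbind(trace[[g]], data.frame(
                tier = tier,
                hits_considered = as.integer(n_hits[[g]]),
                survived = alive[[g]] && !(g %in% killed),
                stringsAsFactors = FALSE))
        }
        newly <- intersect(killed, names(alive)[alive])
        eliminating_tier[newly] <- tier
        alive[newly] <- FALSE
    }

    if (!is.null(domain_annotations) && nrow(domain_annotations)) {
        flagged <- unique(domain_annotations$gene_id[
            as.logical(domain_annotations$cross_lineage)])
        flagged <- intersect(flagged, gene_ids)
        for (g in gene_ids) {
            trace[[g]] <- rbind(trace[[g]], data.frame(
                tier = "domain-scan",
                hits_considered = sum(domain_annotations$gene_id == g),
                survived = alive[[g]] && !(g %in% flagged),
                stringsAsFactors = FALSE))
        }
        newly <- intersect(flagged, names(alive)[alive])
        eliminating_tier[newly] <- "domain-scan"
        alive[newly] <- FALSE
    }

    out <- data.frame(gene_id = gene_ids,
                      is_lsg = unname(alive),
                      lineage_level = ifelse(alive, "family_specific",
                                             NA_character_),
                      eliminating_tier = unname(eliminating_tier),
                      stringsAsFactors = FALSE)
    out$filter_trace <- unname(trace[gene_ids])
    out
}

#' Assign species-only status from outgroup peptide hits
#'
#' A family-level lineage-specific gene is narrowed to species-only when it
#' has no qualifying outgroup peptide hit: e-value below
#' `within_genome_evalue` and merged query coverage of at least
#' `min_query_coverage_pct`.
#'
#' @param records output of [stepwiseFilter()] (only `is_lsg` rows are
#'   updated).
#' @param outgroup_hits peptide-level HSP data.frame against outgroup gene
#'   models.
#' @param query_lengths named vector of query (peptide) lengths, needed for
#'   merged coverage.
#' @param thresholds a [ThresholdConfig-class].
#' @return `records` with `lineage_level` set to `"species_only"` where no
#'   qualifying hit exists.
#' @export
assignLineageLevel <- function(records, outgroup_hits, query_lengths,
                               thresholds = thresholdConfig()) {
    lsg <- records$gene_id[records$is_lsg]
    qualifying <- character()
    ht <- outgroup_hits[outgroup_hits$e_value <
                            thresholds@within_genome_evalue &
                        outgroup_hits$query_id %in% lsg, , drop = FALSE]
    if (nrow(ht)) {
        for (key in unique(paste(ht$query_id, ht$subject_id, sep = "\r"))) {
            ids <- strsplit(key, "\r", fixed = TRUE)[[1]]
            sub <- ht[ht$query_id == ids[1] & ht$subject_id == ids[2], ,
                      drop = FALSE]
            mc <- mergeHsps(sub, query_lengths[[ids[1]]], thresholds)
            if (!is.null(mc)) qualifying <- c(qualifying, ids[1])
        }
    }
    species_only <- setdiff(lsg, qualifying)
    records$lineage_level[records$gene_id %in% species_only] <- "species_only"
    records
}

#' Per-compartment and per-chromosome LSG proportions
#'
#' @param records [stepwiseFilter()] output.
#' @param gene_table gene table with `gene_id`, `chrom`, `compartment`
#'   (e.g. `geneModels(catalog)`).
#' @return data.frame with one row per compartment and per chromosome:
#'   group, tested gene-model count, LSG count, percentage (rounded half away
#'   from zero to 2 decimals; `NA`, not 0, for empty groups).
#' @examples
#' rec <- data.frame(gene_id = letters[1:4], is_lsg = c(TRUE, FALSE, TRUE, FALSE))
#' tab <- data.frame(gene_id = letters[1:4], chrom = "chr1", compartment = "nuclear")
#' compartmentSummary(rec, tab)
#' @export
compartmentSummary <- function(records, gene_table) {
    m <- merge(records[, c("gene_id", "is_lsg")],
               gene_table[, c("gene_id", "chrom", "compartment")],
               by = "gene_id")
    one <- function(label, values, group) {
        n <- as.integer(table(factor(values, levels = unique(values))))
        data.frame(group_type = label,
                   group = unique(values),
                   n_tested = n,
                   n_lsg = as.integer(tapply(m$is_lsg, factor(
                       values, levels = unique(values)), sum)),
                   stringsAsFactors = FALSE)
    }
    comp <- one("compartment", m$compartment)
    chrom <- one("chromosome", m$chrom)
    out <- rbind(comp, chrom)
    out$pct_lsg <- pctShare(out$n_lsg, out$n_tested)
    rownames(out) <- NULL
    out
}
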