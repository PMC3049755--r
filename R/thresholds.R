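#' Construct a ThresholdConfig
#'
#' Every numeric cutoff used by the pipeline, with the defaults used
#' throughout: cross-lineage elimination at e-value 1e-3, within-genome and
#' outgroup searches at 0.01, a 10 percent merged-coverage floor, 5 bp
#' intron-exon boundary tolerance, 4000 bp scaffold-hit chaining gap, 95
#' percent coverage for putative shared un-annotated ORFs, 100 bp flanks for
#' distant-genome reciprocal checks, differential expression at adjusted
#' p < 0.01 with |log2 fold change| > log2(1.5), and enrichment at p < 0.05.
#'
#' @param lsg_evalue_cutoff,within_genome_evalue,min_query_coverage_pct
#'   numeric scalars, see [ThresholdConfig-class].
#' @param boundary_tolerance_bp,scaffold_chain_gap_bp,intact_orf_coverage_pct
#'   numeric scalars.
#' @param distant_flank_bp,de_adj_p,de_min_abs_log2fc,enrichment_p numeric
#'   scalars.
#' @param tandem_max_intervening_genes numeric scalar.
#' @return validated [ThresholdConfig-class] object.
#' @examples
#' thresholdConfig()
#' thresholdConfig(lsg_evalue_cutoff = 1e-5)
#' @export
thresholdConfig <- function(lsg_evalue_cutoff = 1e-3,
                            within_genome_evalue = 0.01,
                            min_query_coverage_pct = 10.0,
                            boundary_tolerance_bp = 5,
                            scaffold_chain_gap_bp = 4000,
                            intact_orf_coverage_pct = 95.0,
                            distant_flank_bp = 100,
                            de_adj_p = 0.01,
                            de_min_abs_log2fc = log2(1.5),
                            enrichment_p = 0.05,
                            tandem_max_intervening_genes = 10) {
    new("ThresholdConfig",
        lsg_evalue_cutoff = lsg_evalue_cutoff,
        within_genome_evalue = within_genome_evalue,
        min_query_coverage_pct = min_query_coverage_pct,
        boundary_tolerance_bp = boundary_tolerance_bp,
        scaffold_chain_gap_bp = scaffold_chain_gap_bp,
        intact_orf_coverage_pct = intact_orf_coverage_pct,
        distant_flank_bp = distant_flank_bp,
        de_adj_p = de_adj_p,
        de_min_abs_log2fc = de_min_abs_log2fc,
        enrichment_p = enrichment_p,
        tandem_max_intervening_genes = tandem_max_intervening_genes)
}

setMethod("show", "ThresholdConfig", function(object) {
    cat("ThresholdConfig\n")
    for (s in slotNames(object))
        cat(sprintf("  %-28s %g\n", s, slot(object, s)))
})

# Coerce a ThresholdConfig to a named list (for provenance echoing).
thresholdsAsList <- function(th) {
    setNames(lapply(slotNames(th), function(s) slot(th, s)), slotNames(th))
}
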