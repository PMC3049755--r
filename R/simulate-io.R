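#' Run the full synthetic scenario and write its files
#'
#' Orchestrates [generateGenome()], [plantOriginEvents()],
#' [deriveOutgroup()], [generatePolymorphisms()], [generateExpression()] and
#' the tier-table synthesis, then writes every input the pipeline reads:
#' focal FASTA/GFF3/TE GFF3, outgroup FASTA/GFF3, tier hit tables
#' (12-column tabular), subject taxa, domain annotations, syntelog and WGD
#' tables, the accession SNP table, expression matrices with metadata, DE
#' contrast tables and the ground-truth tables. All output is deterministic
#' under the config seed (byte-identical files).
#'
#' @param config a [ScenarioConfig-class].
#' @param out_dir output directory (created if missing); `NULL` keeps
#'   everything in memory.
#' @return the simulation state (invisible file paths in
#'   `attr(sim, "paths")` when written).
#' @export
simulateScenario <- function(config, out_dir = NULL) {
    sim <- generateGenome(config)
    sim <- plantOriginEvents(sim)
    sim <- deriveOutgroup(sim)
    sim <- generatePolymorphisms(sim)
    sim <- simExpression(sim)
    sim <- simTierHits(sim)
    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        p <- function(...) file.path(out_dir, ...)
        writeGenomeAnnotation(sim$catalog, p("focal_genes.gff3"),
                              p("focal.fasta"), p("focal_te.gff3"))
        writeGenomeAnnotation(sim$outgroup, p("outgroup_genes.gff3"),
                              p("outgroup.fasta"))
        for (tier in names(sim$hit_tiers))
            writeHitTable(sim$hit_tiers[[tier]],
                          p(sprintf("hits_%s.tsv", tier)))
        writeTsv(sim$subject_taxa, p("subject_taxa.tsv"))
        writeTsv(sim$domains, p("domains.tsv"))
        writeTsv(sim$syntelog_pairs, p("syntelogs.tsv"))
        writeTsv(sim$wgd_pairs, p("wgd_blocks.tsv"))
        writeTsv(sim$snps, p("snps.tsv"))
        writeTsv(sim$expression$samples, p("samples.tsv"))
        writeTsv(data.frame(gene_id = rownames(sim$expression$expr),
                            round(sim$expression$expr, 4),
                            check.names = FALSE), p("expression.tsv"))
        writeTsv(data.frame(gene_id = rownames(sim$expression$calls),
                            sim$expression$calls * 1L, check.names = FALSE),
                 p("calls.tsv"))
        for (ct in names(sim$expression$de_tables))
            writeTsv(sim$expression$de_tables[[ct]],
                     p(sprintf("de_%s.tsv", ct)))
        writeTsv(sim$truth, p("ground_truth.tsv"))
        writeTsv(sim$acc_calls_truth, p("ground_truth_accession.tsv"))
        attr(sim, "paths") <- normalizePath(out_dir)
    }
    sim
}
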