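#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom IRanges IRanges reduce width start end
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand
NULL

#' Numeric thresholds shared across the pipeline
#'
#' One object carries every cutoff used by the filtering, merging, chaining,
#' projection and enrichment steps, so a run is fully described by its
#' thresholds plus its inputs.
#'
#' @slot lsg_evalue_cutoff e-value below which a cross-lineage hit eliminates a
#'   gene from the lineage-specific set (default 1e-3).
#' @slot within_genome_evalue e-value cutoff for within-genome paralog and
#'   outgroup searches (default 0.01).
#' @slot min_query_coverage_pct merged query coverage (percent) below which a
#'   query:subject pair or an ORF projection is discarded (default 10).
#' @slot boundary_tolerance_bp maximum distance (bp) between intron-exon
#'   boundaries still counted as matching, inclusive (default 5).
#' @slot scaffold_chain_gap_bp single-linkage gap for chaining scaffold hits
#'   (default 4000).
#' @slot intact_orf_coverage_pct coverage at or above which an intact
#'   projection is reported as a putative shared un-annotated ORF (default 95).
#' @slot distant_flank_bp flank added on both sides of a genomic hit before the
#'   reciprocal check (default 100).
#' @slot de_adj_p adjusted-p cutoff for differential expression (default 0.01).
#' @slot de_min_abs_log2fc minimum absolute log2 fold change (default
#'   log2(1.5)).
#' @slot enrichment_p p-value bound for calling a hypergeometric enrichment
#'   (default 0.05).
#' @slot tandem_max_intervening_genes maximum genes between a duplicate pair
#'   still called tandem (default 10).
#' @seealso [thresholdConfig()]
#' @export
setClass("ThresholdConfig", representation(
    lsg_evalue_cutoff = "numeric",
    within_genome_evalue = "numeric",
    min_query_coverage_pct = "numeric",
    boundary_tolerance_bp = "numeric",
    scaffold_chain_gap_bp = "numeric",
    intact_orf_coverage_pct = "numeric",
    distant_flank_bp = "numeric",
    de_adj_p = "numeric",
    de_min_abs_log2fc = "numeric",
    enrichment_p = "numeric",
    tandem_max_intervening_genes = "numeric"
))

setValidity("ThresholdConfig", function(object) {
    msg <- character()
    for (s in slotNames(object)) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v) || v <= 0)
            msg <- c(msg, sprintf("'%s' must be a single positive number", s))
    }
    for (s in c("min_query_coverage_pct", "intact_orf_coverage_pct")) {
        v <- slot(object, s)
        if (is.finite(v) && (v <= 0 || v > 100))
            msg <- c(msg, sprintf("'%s' must lie in (0, 100]", s))
    }
    if (length(msg)) msg else TRUE
})

#' Catalog of an annotated genome
#'
#' Holds the chromosome sequences, one representative gene model per locus
#' (exon and CDS structure as \code{GRangesList}), and transposable-element
#' fragments. All downstream operations consume this validated container; no
#' other module re-parses raw annotation text.
#'
#' @slot sequences \code{DNAStringSet} of chromosome/scaffold sequences.
#' @slot genes data.frame with one row per representative gene model:
#'   \code{gene_id}, \code{model_id}, \code{chrom}, \code{strand},
#'   \code{start}, \code{end} (1-based closed genomic span),
#'   \code{compartment} (nuclear/mitochondrial/chloroplast), \code{is_te_gene},
#'   \code{expression_support}, \code{n_exons}, \code{cds_length},
#'   \code{intact} (CDS length divisible by 3).
#' @slot exons \code{GRangesList}, one element per gene_id, exon intervals.
#' @slot cds \code{GRangesList}, one element per gene_id, CDS segments with a
#'   \code{phase} metadata column.
#' @slot te \code{GRanges} of transposable-element fragments with
#'   \code{te_id} and \code{superfamily} metadata columns.
#' @export
setClass("GenomeCatalog", representation(
    sequences = "DNAStringSet",
    genes = "data.frame",
    exons = "GRangesList",
    cds = "GRangesList",
    te = "GRanges"
))

setValidity("GenomeCatalog", function(object) {
    msg <- character()
    g <- object@genes
    need <- c("gene_id", "model_id", "chrom", "strand", "compartment")
    if (!all(need %in% names(g)))
        return(sprintf("genes table lacks columns: %s",
                       paste(setdiff(need, names(g)), collapse = ", ")))
    if (anyDuplicated(g$gene_id))
        msg <- c(msg, "more than one representative model per gene_id")
    if (!all(g$gene_id %in% names(object@cds)))
        msg <- c(msg, "every gene must have a CDS entry")
    if (!all(g$chrom %in% names(object@sequences)))
        msg <- c(msg, "gene chromosome absent from sequences")
    if (!all(g$compartment %in% c("nuclear", "mitochondrial", "chloroplast")))
        msg <- c(msg, "invalid compartment label")
    # CDS segments must fall inside the union of the model's exons
    common <- intersect(names(object@cds), names(object@exons))
    if (length(common)) {
        bad <- vapply(common, function(id) {
            cd <- IRanges::ranges(object@cds[[id]])
            ex <- IRanges::reduce(IRanges::ranges(object@exons[[id]]))
            ov <- IRanges::findOverlaps(cd, ex, type = "within")
            length(unique(S4Vectors::queryHits(ov))) != length(cd)
        }, logical(1))
        if (any(bad))
            msg <- c(msg, sprintf("CDS outside exons for model(s): %s",
                                  paste(common[bad], collapse = ", ")))
    }
    if (length(object@te) &&
        (is.null(object@te$superfamily) || any(!nzchar(object@te$superfamily))))
        msg <- c(msg, "TE fragments must carry a non-empty superfamily")
    if (length(msg)) msg else TRUE
})

#' Scenario configuration for the synthetic-genome simulator
#'
#' Defines the study conditions the simulator emulates: gene counts, planted
#' origin events of every class, outgroup divergence, accession panel and
#' expression signal. Defaults give a desk-scale genome (about 0.7 Mb, 200
#' genes, 60 planted events, 5 percent outgroup divergence) generated in under
#' a minute.
#'
#' @slot seed integer seed; a fixed seed reproduces byte-identical output.
#' @slot n_background_genes conserved background genes (nuclear).
#' @slot n_planted named integer vector of planted event counts with names
#'   overprint, dup_inframe, dup_frameshift, dup_inverted, retrocopy, te_exapt,
#'   chimera, de_novo, differential_loss, accession_isc, accession_msc.
#' @slot intergenic_fraction approximate fraction of the chromosome that is
#'   intergenic spacer.
#' @slot te_density named numeric vector, TE fragments per superfamily placed
#'   in intergenic space.
#' @slot outgroup_divergence per-site substitution probability applied when
#'   deriving the outgroup (must be < 0.5).
#' @slot n_accessions natural accessions genotyped in the SNP table.
#' @slot expression named numeric vector with elements n_tissues,
#'   n_replicates, lsg_breadth_mean, nonlsg_breadth_mean, lsg_expr_shift,
#'   n_stress_contrasts, planted_enrichment_odds.
#' @seealso [scenarioConfig()], [simulateScenario()]
#' @export
setClass("ScenarioConfig", representation(
    seed = "integer",
    n_background_genes = "integer",
    n_planted = "integer",
    intergenic_fraction = "numeric",
    te_density = "numeric",
    outgroup_divergence = "numeric",
    n_accessions = "integer",
    expression = "numeric"
))

.PLANT_CLASSES <- c("overprint", "dup_inframe", "dup_frameshift",
                    "dup_inverted", "retrocopy", "te_exapt", "chimera",
                    "de_novo", "differential_loss",
                    "accession_isc", "accession_msc")

.EXPR_FIELDS <- c("n_tissues", "n_replicates", "lsg_breadth_mean",
                  "nonlsg_breadth_mean", "lsg_expr_shift",
                  "n_stress_contrasts", "planted_enrichment_odds")

setValidity("ScenarioConfig", function(object) {
    msg <- character()
    if (!setequal(names(object@n_planted), .PLANT_CLASSES))
        msg <- c(msg, "n_planted must name every planted origin class")
    if (any(object@n_planted < 0) || object@n_background_genes < 0)
        msg <- c(msg, "counts must be non-negative")
    if (object@outgroup_divergence < 0 || object@outgroup_divergence >= 0.5)
        msg <- c(msg, "outgroup_divergence must lie in [0, 0.5): higher values break the alignability assumption")
    if (object@intergenic_fraction <= 0 || object@intergenic_fraction >= 1)
        msg <- c(msg, "intergenic_fraction must lie in (0, 1)")
    if (!all(.EXPR_FIELDS %in% names(object@expression)))
        msg <- c(msg, "expression must name all expression parameters")
    if (object@n_accessions < 1)
        msg <- c(msg, "need at least one accession")
    if (length(msg)) msg else TRUE
})
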