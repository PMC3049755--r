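# Shared simulation state, built once per test run. The default scenario is
# the study condition set (200 genes, 60 planted events, 5% divergence); the
# small scenario keeps end-to-end runs cheap.

.scenario_cache <- new.env(parent = emptyenv())

defaultSim <- function() {
    if (is.null(.scenario_cache$sim))
        .scenario_cache$sim <- simulateScenario(scenarioConfig(seed = 1L))
    .scenario_cache$sim
}

defaultBundle <- function() {
    if (is.null(.scenario_cache$bundle))
        .scenario_cache$bundle <- runPipeline(defaultSim())
    .scenario_cache$bundle
}

smallConfig <- function(seed = 7L)
    scenarioConfig(seed = seed, n_background_genes = 60L,
                   n_planted = c(overprint = 2L, dup_inframe = 2L,
                                 dup_frameshift = 1L, dup_inverted = 1L,
                                 retrocopy = 1L, te_exapt = 2L,
                                 chimera = 1L, de_novo = 2L,
                                 differential_loss = 1L,
                                 accession_isc = 2L, accession_msc = 2L),
                   n_accessions = 8L,
                   expression = c(n_tissues = 12, n_replicates = 2,
                                  n_stress_contrasts = 2))

# A hand-built two-chromosome catalog used by interval-level tests:
# gene gA (plus strand, 2 exons with an intron) and gB (minus strand,
# single exon) overlap gA's CDS; gC sits apart; one TE fragment overlaps
# gC's exon, another is intronic in gA.
testCatalog <- function() {
    seq1 <- strrep("ACGT", 500)   # chr1, 2000 bp
    seqs <- Biostrings::DNAStringSet(c(chr1 = seq1))
    mk <- function(chrom, s, e, strand) GenomicRanges::GRanges(
        chrom, IRanges::IRanges(s, e), strand = strand)
    exons <- GenomicRanges::GRangesList(
        gA = mk("chr1", c(101, 301), c(220, 460), "+"),
        gB = mk("chr1", 401, 580, "-"),
        gC = mk("chr1", 1001, 1180, "+"))
    cds <- GenomicRanges::GRangesList(
        gA = mk("chr1", c(121, 301), c(220, 421), "+"),
        gB = mk("chr1", 411, 560, "-"),
        gC = mk("chr1", 1021, 1140, "+"))
    te <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(1101, 241), c(1250, 290)),
        strand = "+", te_id = c("teX", "teY"),
        superfamily = c("LTR/Gypsy", "RC/Helitron"))
    genes <- data.frame(
        gene_id = c("gA", "gB", "gC"),
        model_id = c("gA.1", "gB.1", "gC.1"),
        chrom = "chr1", strand = c("+", "-", "+"),
        start = c(101, 401, 1001), end = c(460, 580, 1180),
        compartment = "nuclear", is_te_gene = FALSE,
        expression_support = "none", n_exons = c(2L, 1L, 1L),
        cds_length = c(221L, 150L, 120L), intact = c(FALSE, TRUE, TRUE),
        stringsAsFactors = FALSE)
    new("GenomeCatalog", sequences = seqs, genes = genes, exons = exons,
        cds = cds, te = te)
}
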