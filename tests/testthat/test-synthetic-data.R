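test_that("the scenario is byte-identical under a fixed seed", {
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    simulateScenario(smallConfig(), d1)
    simulateScenario(smallConfig(), d2)
    f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
    expect_equal(f1, f2)
    for (f in f1)
        expect_equal(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
    # a different seed changes the sequences
    d3 <- withr::local_tempdir()
    simulateScenario(smallConfig(seed = 8L), d3)
    expect_false(unname(tools::md5sum(file.path(d1, "focal.fasta"))) ==
                 unname(tools::md5sum(file.path(d3, "focal.fasta"))))
})

test_that("ground truth reconciles with the scenario configuration", {
    sim <- defaultSim()
    cfg <- sim$config
    counts <- table(sim$truth$class)
    for (cl in names(cfg@n_planted))
        expect_equal(unname(counts[[cl]]), unname(cfg@n_planted[[cl]]),
                     info = cl)
    expect_equal(unname(counts[["background"]]), cfg@n_background_genes)
    expect_true(all(sim$truth$gene_id %in% geneIds(sim$catalog)))
})

test_that("background ORFs are clean and planted structures verify", {
    sim <- defaultSim()
    truth <- sim$truth
    cds <- as.character(cdsSequences(sim$catalog))
    # translate-and-scan: the only stop is terminal, ORFs start with ATG
    for (g in names(cds)) {
        expect_equal(substr(cds[[g]], 1, 3), "ATG", info = g)
        stops <- translateScan(cds[[g]])
        expect_equal(stops, nchar(cds[[g]]) / 3, info = g)
    }
    # every te_exapt gene overlaps a TE fragment on an exon
    te <- detectTeExaptation(sim$catalog,
                             truth$gene_id[truth$class != "background"])
    planted_te <- truth$gene_id[truth$class == "te_exapt"]
    expect_true(all(planted_te %in% te$genes))
    # overprint CDS intersects the host CDS
    ov <- findOverlappingCds(sim$catalog,
                             truth$gene_id[truth$class != "background"])
    planted_ov <- truth$gene_id[truth$class == "overprint"]
    expect_true(all(planted_ov %in% c(ov$gene_a, ov$gene_b)))
    # chimeras share >= 30 bp exact substrings with both donors in
    # disjoint regions (substring-search oracle)
    chim <- truth[truth$class == "chimera", ]
    shared30 <- function(x, y) {
        n <- nchar(x)
        if (n < 30) return(integer())
        kmers <- substring(x, 1:(n - 29), 30:n)
        which(vapply(kmers, function(k) grepl(k, y, fixed = TRUE),
                     logical(1)))
    }
    for (i in seq_len(nrow(chim))) {
        donors <- strsplit(chim$donors[i], ",")[[1]]
        q <- cds[[chim$gene_id[i]]]
        posA <- shared30(q, cds[[donors[1]]])
        posB <- shared30(q, cds[[donors[2]]])
        expect_gt(length(posA), 0)
        expect_gt(length(posB), 0)
        expect_lt(max(posA), min(posB) + 1)   # disjoint query regions
    }
})

test_that("planted outgroup states are engineered as labelled", {
    sim <- defaultSim()
    truth <- sim$truth
    # an MSC-labelled gene: its outgroup locus no longer starts with ATG
    fine <- setNames(sim$truth_planted$outgroup_category,
                     sim$truth_planted$gene_id)
    msc_genes <- names(fine)[fine == "MSC"]
    expect_gt(length(msc_genes), 0)
    # differential-loss and de novo loci are absent from the outgroup
    lost <- truth$gene_id[truth$class %in% c("de_novo",
                                             "differential_loss")]
    og <- as.character(chromSequences(sim$outgroup))
    for (g in lost) {
        frag <- substr(as.character(cdsSequences(sim$catalog, g)), 1, 60)
        expect_false(any(vapply(og, function(s)
            grepl(frag, s, fixed = TRUE), logical(1))), info = g)
    }
    # zero divergence and no planted events: outgroup loci identical
    cfg0 <- scenarioConfig(seed = 3L, n_background_genes = 30L,
                           n_planted = c(overprint = 0L),
                           outgroup_divergence = 0)
    sim0 <- deriveOutgroup(plantOriginEvents(generateGenome(cfg0)))
    og0 <- as.character(chromSequences(sim0$outgroup))
    for (li in which(vapply(sim0$loci, function(l)
        l$chrom == "chr1" && length(l$genes) > 0, logical(1)))) {
        loc <- sim0$loci[[li]]
        expect_true(any(vapply(og0, function(s)
            grepl(loc$seq, s, fixed = TRUE), logical(1))), info = loc$id)
    }
    # divergence at or above 0.5 is refused
    expect_error(scenarioConfig(seed = 1, outgroup_divergence = 0.6),
                 "alignability")
})

test_that("SNP tables are consistent with the reference genome", {
    sim <- defaultSim()
    seqs <- chromSequences(sim$catalog)
    snps <- sim$snps
    idx <- seq(1, nrow(snps), length.out = min(200, nrow(snps)))
    for (i in as.integer(idx)) {
        base <- as.character(Biostrings::subseq(seqs[[snps$chrom[i]]],
                                                snps$pos[i], snps$pos[i]))
        expect_equal(base, snps$ref[i])
    }
    # every planted disruption is carried by at least one accession
    expect_true(all(table(sim$acc_calls_truth$gene_id) >= 1))
})
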