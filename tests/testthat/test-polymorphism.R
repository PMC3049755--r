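# A compact catalog for SNP calling: gPlus (+ strand) and gMinus (- strand),
# each a single-exon ORF embedded in a small chromosome.
polyCatalog <- function() {
    set.seed(41)
    codons <- setdiff(apply(expand.grid(c("A","C","G","T"),
                                        c("A","C","G","T"),
                                        c("A","C","G","T")), 1, paste,
                            collapse = ""), c("TAA", "TAG", "TGA"))
    mkcds <- function(n) paste0("ATG", paste(sample(codons, n - 2,
                                                    replace = TRUE),
                                             collapse = ""), "TAA")
    cds_p <- mkcds(80)
    # codon 40 set to TGG so a G->A SNP at its third base creates TGA
    cods <- substring(cds_p, 3 * (1:80) - 2, 3 * (1:80))
    cods[40] <- "TGG"; cods[50] <- "AAA"
    cds_p <- paste(cods, collapse = "")
    cds_m <- mkcds(60)
    chr <- paste0(strrep("ACGT", 25), cds_p, strrep("ACGT", 25),
                  paste(rev(strsplit(chartr("ACGT", "TGCA", cds_m),
                                     "")[[1]]), collapse = ""),
                  strrep("ACGT", 25))
    p_start <- 101L; p_end <- p_start + nchar(cds_p) - 1L
    m_start <- p_end + 101L; m_end <- m_start + nchar(cds_m) - 1L
    mk <- function(s, e, strand) GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(s, e), strand = strand)
    genes <- data.frame(gene_id = c("gPlus", "gMinus"),
                        model_id = c("gPlus.1", "gMinus.1"),
                        chrom = "chr1", strand = c("+", "-"),
                        start = c(p_start, m_start),
                        end = c(p_end, m_end),
                        compartment = "nuclear", is_te_gene = FALSE,
                        expression_support = c("gene_model_supported",
                                               "locus_supported"),
                        n_exons = 1L,
                        cds_length = c(nchar(cds_p), nchar(cds_m)),
                        intact = TRUE, stringsAsFactors = FALSE)
    new("GenomeCatalog",
        sequences = Biostrings::DNAStringSet(c(chr1 = chr)),
        genes = genes,
        exons = GenomicRanges::GRangesList(gPlus = mk(p_start, p_end, "+"),
                                           gMinus = mk(m_start, m_end,
                                                       "-")),
        cds = GenomicRanges::GRangesList(gPlus = mk(p_start, p_end, "+"),
                                         gMinus = mk(m_start, m_end, "-")),
        te = GenomicRanges::GRanges())
}

test_that("accession SNPs inside LSG CDS are translated into ISC/MSC calls", {
    cat <- polyCatalog()
    p_start <- 101L
    snps <- data.frame(
        accession = c("acc1", "acc1", "acc2", "acc3", "acc4"),
        chrom = "chr1",
        pos = c(p_start + 3 * 39 + 2,   # codon 40 TGG -> TGA
                p_start + 3 * 49 + 2,   # codon 50 AAA -> AAG, synonymous
                p_start,                # codon 1 ATG -> GTG
                p_start + 3 * 39 + 2,   # undetermined allele
                680),                   # intergenic
        ref = c("G", "A", "A", "G", substr(as.character(
            chromSequences(cat)$chr1), 680, 680)),
        alt = c("A", "G", "G", "N", "T"),
        stringsAsFactors = FALSE)
    snps$pos <- as.integer(snps$pos)
    out <- applySnpsAndCall(cat, c("gPlus", "gMinus"), snps)
    expect_equal(nrow(out$calls), 2)
    isc <- out$calls[out$calls$type == "ISC", ]
    expect_equal(isc$accession, "acc1")
    expect_equal(isc$codon_index, 40)
    msc <- out$calls[out$calls$type == "MSC", ]
    expect_equal(msc$accession, "acc2")
    expect_equal(msc$codon_index, 1)
    expect_equal(out$matrix["gPlus", "acc1"], "ISC")
    expect_equal(out$matrix["gPlus", "acc2"], "MSC")
    expect_equal(out$matrix["gPlus", "acc3"], "missing")
    expect_equal(out$matrix["gPlus", "acc4"], "ref")
    # row-order invariance
    out2 <- applySnpsAndCall(cat, c("gPlus", "gMinus"),
                             snps[sample(nrow(snps)), ])
    expect_equal(out2$calls[order(out2$calls$accession), ],
                 out$calls[order(out$calls$accession), ],
                 ignore_attr = TRUE)
    # applying zero SNPs changes nothing
    none <- applySnpsAndCall(cat, c("gPlus", "gMinus"), snps[0, ])
    expect_equal(nrow(none$calls), 0)
    expect_true(all(none$matrix == "ref"))
    # ref-mismatch and indel rows are rejected
    bad <- snps[1, ]; bad$ref <- "C"
    expect_error(applySnpsAndCall(cat, "gPlus", bad), "do not match")
    indel <- snps[1, ]; indel$alt <- "AT"
    expect_error(applySnpsAndCall(cat, "gPlus", indel), "substitution")
})

test_that("minus-strand SNPs are complemented before translation", {
    cat <- polyCatalog()
    g <- geneModels(cat)
    m_end <- g$end[g$gene_id == "gMinus"]
    # genomic base at m_end pairs with the A of the minus-strand ATG;
    # plus-strand T -> C makes the mRNA start G..: MSC
    snps <- data.frame(accession = "acc1", chrom = "chr1",
                       pos = as.integer(m_end), ref = "T", alt = "C",
                       stringsAsFactors = FALSE)
    out <- applySnpsAndCall(cat, "gMinus", snps)
    expect_equal(out$calls$type, "MSC")
})

test_that("outgroup cross-referencing distinguishes the four statuses", {
    cat <- polyCatalog()
    p_start <- 101L
    snps <- data.frame(accession = c("acc1", "acc2"), chrom = "chr1",
                       pos = as.integer(c(p_start + 3 * 39 + 2, p_start)),
                       ref = c("G", "A"), alt = c("A", "G"),
                       stringsAsFactors = FALSE)
    out <- applySnpsAndCall(cat, c("gPlus", "gMinus"), snps)
    cds <- as.character(cdsSequences(cat, "gPlus"))
    # outgroup carrying the disrupting allele at the site
    og_conserved <- cds; substr(og_conserved, 120, 120) <- "A"
    pr_c <- projectOrf(cds, og_conserved)
    # outgroup with a deletion spanning the site
    og_del <- paste0(substr(cds, 1, 110), substr(cds, 131, nchar(cds)))
    pr_d <- projectOrf(cds, og_del)
    # intact outgroup
    pr_i <- projectOrf(cds, cds)
    calls1 <- crossReferenceOutgroup(out$calls, cat,
                                     list(gPlus = pr_c))
    expect_equal(calls1$outgroup_status[calls1$type == "ISC"],
                 "CONSERVED_SNP")
    calls2 <- crossReferenceOutgroup(out$calls, cat, list(gPlus = pr_d))
    expect_equal(calls2$outgroup_status[calls2$type == "ISC"], "DELETION")
    calls3 <- crossReferenceOutgroup(out$calls, cat, list(gPlus = pr_i))
    expect_equal(calls3$outgroup_status[calls3$type == "ISC"],
                 "NOT_DISRUPTED")
    calls4 <- crossReferenceOutgroup(out$calls, cat, list(gPlus = NULL))
    expect_true(all(calls4$outgroup_status == "NOT_COVERED"))
})

test_that("parsimony separates gene birth from gene loss", {
    mkcalls <- function(status, accs) data.frame(
        gene_id = "g", accession = accs, type = "ISC", chrom = "chr1",
        pos = 1L, codon_index = 10L, ref = "G", alt = "A",
        outgroup_status = status, outgroup_disruptions = 0L,
        outgroup_coverage_pct = 100, stringsAsFactors = FALSE)
    intact <- list(g = list(category = "INTACT", coverage_pct = 100))
    # conserved disruption, 18 of 19 accessions: ancestral, birth
    b <- inferBirthVsLoss(mkcalls("CONSERVED_SNP", sprintf("a%02d", 1:18)),
                          intact, 19)
    expect_equal(b$scenario, "birth_in_focal")
    # intact outgroup, minority of accessions: loss
    l <- inferBirthVsLoss(mkcalls("NOT_DISRUPTED", sprintf("a%02d", 1:4)),
                          intact, 19)
    expect_equal(l$scenario, "loss_in_focal")
    # no outgroup coverage: ambiguous
    a <- inferBirthVsLoss(mkcalls("NOT_COVERED", "a01"), list(g = NULL), 19)
    expect_equal(a$scenario, "ambiguous")
    # majority disrupted without conservation: ambiguous, not loss
    m <- inferBirthVsLoss(mkcalls("NOT_DISRUPTED", sprintf("a%02d", 1:12)),
                          intact, 19)
    expect_equal(m$scenario, "ambiguous")
})

test_that("polymorphic LSG summary matches the lineage x type layout", {
    calls <- data.frame(
        gene_id = c(sprintf("b%02d", 1:32), sprintf("t%02d", 1:5), "b01"),
        accession = "acc1",
        type = c(rep("ISC", 32), rep("MSC", 5), "MSC"),
        stringsAsFactors = FALSE)
    records <- data.frame(gene_id = unique(calls$gene_id),
                          lineage_level = "family_specific",
                          stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = unique(calls$gene_id),
                        expression_support = c(
                            rep("gene_model_supported", 12),
                            rep("locus_supported", 10),
                            rep("none", 10), rep("gene_model_supported", 3),
                            rep("none", 2)),
                        stringsAsFactors = FALSE)
    out <- summarizePolymorphicLsgs(calls, records, genes)
    isc_row <- out$table[out$table$type == "ISC", ]
    expect_equal(isc_row$n_genes, 32)
    expect_equal(isc_row$gene_model_support, 12)
    expect_equal(isc_row$locus_support, 22)
    expect_equal(out$isc_msc_overlap, 1)
})
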