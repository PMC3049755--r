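test_that("interval union length matches set semantics", {
    expect_equal(intervalUnionLength(c(0, 30), c(40, 60)), 60)
    expect_equal(intervalUnionLength(integer(), integer()), 0)
    # half-open abutment merges
    expect_equal(intervalUnionLength(c(0, 10), c(10, 20)), 20)
    expect_error(intervalUnionLength(5, 5), "start < end")
    set.seed(11)
    for (i in 1:60) {
        n <- sample(1:12, 1)
        s <- sample(0:200, n, replace = TRUE)
        e <- s + sample(1:50, n, replace = TRUE)
        expect_equal(intervalUnionLength(s, e), bruteUnionLength(s, e))
    }
})

test_that("GFF3 parsing builds a validated catalog with coordinate round-trip", {
    dir <- withr::local_tempdir()
    fasta <- file.path(dir, "g.fa")
    gff <- file.path(dir, "g.gff3")
    seq <- paste(rep("ACGTACGTAC", 100), collapse = "")
    writeLines(c(">chr1", seq), fasta)
    writeLines(c(
        "##gff-version 3",
        "chr1\tx\tgene\t101\t400\t.\t+\t.\tID=g1",
        "chr1\tx\tmRNA\t101\t400\t.\t+\t.\tID=g1.1;Parent=g1",
        "chr1\tx\texon\t101\t200\t.\t+\t.\tParent=g1.1",
        "chr1\tx\texon\t301\t400\t.\t+\t.\tParent=g1.1",
        "chr1\tx\tCDS\t101\t200\t.\t+\t0\tParent=g1.1",
        "chr1\tx\tCDS\t301\t400\t.\t+\t2\tParent=g1.1",
        "chr1\tx\tgene\t501\t700\t.\t-\t.\tID=g2",
        "chr1\tx\tmRNA\t501\t700\t.\t-\t.\tID=g2.1;Parent=g2",
        "chr1\tx\texon\t501\t700\t.\t-\t.\tParent=g2.1",
        "chr1\tx\tCDS\t521\t640\t.\t-\t0\tParent=g2.1",
        "chr1\tx\ttransposable_element\t801\t950\t.\t+\t.\tID=te1;superfamily=RC/Helitron"
    ), gff)
    cat <- suppressWarnings(readGenomeAnnotation(gff, fasta))
    expect_equal(nrow(geneModels(cat)), 2)
    expect_equal(length(teFragments(cat)), 1)
    expect_equal(teFragments(cat)$superfamily, "RC/Helitron")
    # GFF3 1-based inclusive 101..200 kept as 1-based closed [101, 200]
    gr <- cdsRanges(cat)[["g1"]]
    expect_equal(GenomicRanges::start(gr), c(101, 301))
    expect_equal(GenomicRanges::end(gr), c(200, 400))
    # round trip through the writer reproduces intervals, strands and ids
    out_gff <- file.path(dir, "o.gff3"); out_fa <- file.path(dir, "o.fa")
    out_te <- file.path(dir, "o_te.gff3")
    writeGenomeAnnotation(cat, out_gff, out_fa, out_te)
    cat2 <- suppressWarnings(readGenomeAnnotation(out_gff, out_fa, out_te))
    expect_equal(geneModels(cat2)$gene_id, geneModels(cat)$gene_id)
    expect_equal(geneModels(cat2)$strand, geneModels(cat)$strand)
    for (g in geneIds(cat)) {
        expect_equal(IRanges::ranges(cdsRanges(cat2)[[g]]),
                     IRanges::ranges(cdsRanges(cat)[[g]]))
        expect_equal(IRanges::ranges(exonRanges(cat2)[[g]]),
                     IRanges::ranges(exonRanges(cat)[[g]]))
    }
    expect_equal(as.character(chromSequences(cat2)$chr1),
                 as.character(chromSequences(cat)$chr1))
})

test_that("annotation errors are specific", {
    dir <- withr::local_tempdir()
    fasta <- file.path(dir, "g.fa")
    writeLines(c(">chrZ", strrep("ACGT", 100)), fasta)
    gff <- file.path(dir, "g.gff3")
    writeLines(c("##gff-version 3",
                 "chr1\tx\tgene\t1\t90\t.\t+\t.\tID=g1",
                 "chr1\tx\tmRNA\t1\t90\t.\t+\t.\tID=g1.1;Parent=g1",
                 "chr1\tx\texon\t1\t90\t.\t+\t.\tParent=g1.1",
                 "chr1\tx\tCDS\t1\t90\t.\t+\t0\tParent=g1.1"), gff)
    expect_error(readGenomeAnnotation(gff, fasta), "absent from FASTA")
    # CDS escaping its exons is a malformed model
    fasta2 <- file.path(dir, "g2.fa")
    writeLines(c(">chr1", strrep("ACGT", 100)), fasta2)
    gff2 <- file.path(dir, "g2.gff3")
    writeLines(c("##gff-version 3",
                 "chr1\tx\tgene\t1\t200\t.\t+\t.\tID=g1",
                 "chr1\tx\tmRNA\t1\t200\t.\t+\t.\tID=g1.1;Parent=g1",
                 "chr1\tx\texon\t1\t90\t.\t+\t.\tParent=g1.1",
                 "chr1\tx\tCDS\t1\t120\t.\t+\t0\tParent=g1.1"), gff2)
    expect_error(readGenomeAnnotation(gff2, fasta2), "g1")
    # CDS length not divisible by three: parse succeeds with a warning
    gff3 <- file.path(dir, "g3.gff3")
    writeLines(c("##gff-version 3",
                 "chr1\tx\tgene\t1\t301\t.\t+\t.\tID=g1",
                 "chr1\tx\tmRNA\t1\t301\t.\t+\t.\tID=g1.1;Parent=g1",
                 "chr1\tx\texon\t1\t301\t.\t+\t.\tParent=g1.1",
                 "chr1\tx\tCDS\t1\t301\t.\t+\t0\tParent=g1.1"), gff3)
    expect_warning(cat3 <- readGenomeAnnotation(gff3, fasta2),
                   "non-intact")
    expect_false(geneModels(cat3)$intact)
})

test_that("hit tables normalise coordinates and orientation", {
    dir <- withr::local_tempdir()
    f <- file.path(dir, "hits.tsv")
    writeLines(c(
        "q1\ts1\t95.00\t100\t5\t0\t1\t100\t200\t101\t3e-40\t180.0",
        "q1\ts2\t90.00\t50\t5\t0\t11\t60\t1\t50\t0.002\t80.0",
        "bad\trow\tonly\tfour"), f)
    expect_error(readHitTable(f, "nucleotide"), "line 3")
    expect_warning(h <- readHitTable(f, "nucleotide", strict = FALSE),
                   "skipped 1")
    expect_equal(nrow(h), 2)
    expect_equal(h$q_start[1], 0); expect_equal(h$q_end[1], 100)
    expect_equal(h$s_start[1], 100); expect_equal(h$s_end[1], 200)
    expect_equal(h$orientation, c("inverted", "forward"))
    expect_equal(h$e_value[1], 3e-40)
    # write/read round trip preserves every field
    f2 <- file.path(dir, "hits2.tsv")
    writeHitTable(h, f2)
    h2 <- readHitTable(f2, "nucleotide")
    expect_equal(h2[, c("query_id", "subject_id", "q_start", "q_end",
                        "s_start", "s_end", "orientation")],
                 h[, c("query_id", "subject_id", "q_start", "q_end",
                       "s_start", "s_end", "orientation")])
})
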