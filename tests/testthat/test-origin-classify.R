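test_that("CDS overlap pairs ignore introns and UTRs", {
    cat <- testCatalog()
    ov <- findOverlappingCds(cat, lsg_ids = "gB")
    # gA CDS (301,421) vs gB CDS (411,560), opposite strands: 11 bp overlap
    expect_equal(nrow(ov), 1)
    expect_equal(ov$gene_a, "gA"); expect_equal(ov$gene_b, "gB")
    expect_equal(ov$overlap_bp, 11)
    expect_equal(ov$pair_type, "LSG:nonLSG")
    # exon-only overlap (no shared CDS) is not a pair: gA exon ends at 460,
    # gB CDS starts at 411 - shrink gA's second CDS to (301, 405)
    cat2 <- cat
    cat2@cds[["gA"]] <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(121, 301), c(220, 405)), strand = "+")
    expect_equal(nrow(findOverlappingCds(cat2, "gB")), 0)
})

test_that("HSP merging unions query intervals and applies the coverage floor", {
    h <- data.frame(query_id = "q", subject_id = "s",
                    percent_identity = 90, n_columns = c(40L, 30L),
                    mismatches = 0L, gap_opens = 0L,
                    q_start = c(0L, 30L), q_end = c(40L, 60L),
                    s_start = c(0L, 30L), s_end = c(40L, 60L),
                    orientation = "forward", e_value = 1e-10, score = 50,
                    stringsAsFactors = FALSE)
    m <- mergeHsps(h, 100)
    expect_equal(m$coverage_pct, 60)
    expect_equal(unname(m$intervals[, "start"]), 0)
    expect_equal(unname(m$intervals[, "end"]), 60)
    # single HSP covering 9 of 100 residues is discarded (strict < 10%)
    h9 <- h[1, ]; h9$q_end <- 9L; h9$n_columns <- 9L
    expect_null(mergeHsps(h9, 100))
    # full-length gap-free HSP
    hf <- h[1, ]; hf$q_end <- 100L; hf$n_columns <- 100L
    expect_equal(mergeHsps(hf, 100)$coverage_pct, 100)
    # gap columns can push coverage above 100
    hg <- h[1, ]; hg$q_end <- 100L; hg$n_columns <- 110L
    expect_equal(mergeHsps(hg, 100)$coverage_pct, 110)
    expect_error(mergeHsps(hf, 50), "beyond query length")
})

test_that("merged coverage equals brute-force union over random HSP sets", {
    set.seed(13)
    for (i in 1:50) {
        n <- sample(1:6, 1)
        qs <- sample(0:80, n, replace = TRUE)
        qe <- qs + sample(5:20, n, replace = TRUE)
        h <- data.frame(query_id = "q", subject_id = "s",
                        percent_identity = 90, n_columns = qe - qs,
                        mismatches = 0L, gap_opens = 0L, q_start = qs,
                        q_end = qe, s_start = qs, s_end = qe,
                        orientation = "forward", e_value = 1e-9, score = 30,
                        stringsAsFactors = FALSE)
        m <- mergeHsps(h, 200)
        expected <- 100 * bruteUnionLength(qs, qe) / 200
        if (expected < 10) expect_null(m) else
            expect_equal(m$coverage_pct, expected)
    }
})

test_that("raising the coverage floor never retains more pairs", {
    set.seed(14)
    hits <- do.call(rbind, lapply(1:40, function(i) {
        qs <- sample(0:50, 1); qe <- qs + sample(5:60, 1)
        data.frame(query_id = sprintf("q%02d", i), subject_id = "s",
                   percent_identity = 90, n_columns = qe - qs,
                   mismatches = 0L, gap_opens = 0L, q_start = qs,
                   q_end = qe, s_start = qs, s_end = qe,
                   orientation = "forward", e_value = 1e-9, score = 30,
                   stringsAsFactors = FALSE)
    }))
    kept <- vapply(c(5, 10, 20, 40), function(cov) {
        th <- thresholdConfig(min_query_coverage_pct = cov)
        merged <- lapply(split(hits, hits$query_id), mergeHsps, 120, th)
        sum(!vapply(merged, is.null, logical(1)))
    }, numeric(1))
    expect_true(all(diff(kept) <= 0))
})

test_that("frame comparison flags excess CDS coverage and subtracts intervals", {
    pep <- list(query_id = "q", subject_id = "s",
                intervals = cbind(start = 0L, end = 30L),
                coverage_pct = 74.40, n_hsps = 1,
                dominant_orientation = "forward")
    cds_same <- pep; cds_same$coverage_pct <- 74.40
    expect_equal(detectOutOfFrame(pep, cds_same)$frame, "in_frame")
    cds <- list(query_id = "q", subject_id = "s",
                intervals = cbind(start = c(0L, 300L), end = c(90L, 450L)),
                coverage_pct = 80, n_hsps = 2,
                dominant_orientation = "forward")
    oof <- detectOutOfFrame(pep, cds)
    expect_equal(oof$frame, "out_of_frame")
    expect_equal(unname(oof$out_of_frame_intervals[, "start"]), 300)
    expect_equal(unname(oof$out_of_frame_intervals[, "end"]), 450)
    # absent peptide hit counts as zero coverage: fully out-of-frame
    expect_equal(detectOutOfFrame(NULL, cds)$frame, "out_of_frame")
    expect_null(detectOutOfFrame(pep, NULL))
})

test_that("orientation follows the dominant HSP", {
    h <- data.frame(n_columns = c(300L, 40L),
                    orientation = c("forward", "inverted"))
    expect_equal(detectOrientation(h), "forward")
    expect_equal(detectOrientation(h[2, ]), "inverted")
})

test_that("duplication mechanism follows intron-exon boundary geometry", {
    # subject gS: 2 exons of 90 bp each; query copies either keep or lose
    # the intron
    seqs <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 400)))
    mk <- function(s, e, strand = "+") GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(s, e), strand = strand)
    cds <- GenomicRanges::GRangesList(
        gS = mk(c(101, 251), c(190, 340)),
        gUec = mk(c(601, 752), c(690, 841)),   # same split structure
        gRetro = mk(1001, 1180))               # intron-less copy
    exons <- cds
    genes <- data.frame(gene_id = c("gS", "gUec", "gRetro"),
                        model_id = paste0(c("gS", "gUec", "gRetro"), ".1"),
                        chrom = "chr1", strand = "+",
                        start = c(101, 601, 1001), end = c(340, 841, 1180),
                        compartment = "nuclear", is_te_gene = FALSE,
                        expression_support = "none",
                        n_exons = c(2L, 2L, 1L),
                        cds_length = 180L, intact = TRUE,
                        stringsAsFactors = FALSE)
    cat <- new("GenomeCatalog", sequences = seqs, genes = genes,
               exons = exons, cds = cds,
               te = GenomicRanges::GRanges())
    full_hit <- function(q) data.frame(
        query_id = q, subject_id = "gS", percent_identity = 95,
        n_columns = 180L, mismatches = 5L, gap_opens = 0L,
        q_start = 0L, q_end = 180L, s_start = 0L, s_end = 180L,
        orientation = "forward", e_value = 1e-40, score = 300,
        stringsAsFactors = FALSE)
    # boundaries coincide in spliced coordinates (offset 90 vs 90)
    expect_equal(classifyDuplicationMechanism(cat, "gUec", "gS",
                                              full_hit("gUec")),
                 "unequal_crossing_over")
    # intron-less query aligned across the subject boundary
    expect_equal(classifyDuplicationMechanism(cat, "gRetro", "gS",
                                              full_hit("gRetro")),
                 "retrotransposition")
    # alignment wholly inside one subject exon
    h <- full_hit("gRetro"); h$q_end <- 60L; h$s_end <- 60L
    h$n_columns <- 60L
    expect_equal(classifyDuplicationMechanism(cat, "gRetro", "gS", h),
                 "indeterminate")
    h_bad <- full_hit("gRetro"); h_bad$q_end <- 500L
    expect_error(classifyDuplicationMechanism(cat, "gRetro", "gS", h_bad),
                 "outside gene model")
})

test_that("duplication context separates tandem, distal and syntelog", {
    tab <- data.frame(gene_id = sprintf("g%02d", 1:20),
                      chrom = rep(c("chr1", "chr2"), each = 10),
                      start = rep(seq(1, 10000, length.out = 10), 2),
                      stringsAsFactors = FALSE)
    pairs <- data.frame(lsg_id = c("g01", "g01", "g02"),
                        subject_id = c("g02", "g11", "g15"),
                        stringsAsFactors = FALSE)
    syn <- data.frame(gene_a = "g02", gene_b = "g15",
                      stringsAsFactors = FALSE)
    out <- classifyDuplicationContext(pairs, tab, syn, syn)
    expect_equal(out$context, c("tandem", "distal", "syntelog"))
    expect_equal(out$wgd, c(FALSE, FALSE, TRUE))
    # more than the allowed intervening genes is distal
    p2 <- data.frame(lsg_id = "g01", subject_id = "g05")
    out2 <- classifyDuplicationContext(
        p2, tab, thresholds = thresholdConfig(
            tandem_max_intervening_genes = 2))
    expect_equal(out2$context, "distal")
})

test_that("TE exaptation is an exon-interval overlap", {
    cat <- testCatalog()
    te <- detectTeExaptation(cat, lsg_ids = "gC", level = "exon")
    # teX overlaps gC's exon by 80 bp; teY is intronic in gA
    expect_equal(te$genes, "gC")
    expect_equal(te$overlaps$overlap_bp, 80)
    expect_equal(te$tally$lsg_fragments[te$tally$superfamily ==
                                        "LTR/Gypsy"], 1)
    # at CDS level the same fragment overlaps by 40 bp
    te_cds <- detectTeExaptation(cat, lsg_ids = "gC", level = "cds")
    expect_equal(te_cds$overlaps$overlap_bp, 40)
})

test_that("chimerism needs near-disjoint regions and non-homologous parents", {
    ev <- data.frame(gene_id = "g",
                     type = c("parent", "parent"),
                     feature_id = c("A", "B"),
                     q_start = c(0L, 150L), q_end = c(100L, 300L),
                     stringsAsFactors = FALSE)
    out <- detectChimeric(ev)
    expect_equal(out$composition, "multi_parent")
    expect_equal(out$features, "A,B")
    # same region: not chimeric
    ev2 <- ev; ev2$q_start <- c(0L, 0L); ev2$q_end <- c(100L, 100L)
    expect_equal(nrow(detectChimeric(ev2)), 0)
    # homologous parents never jointly support chimerism
    hom <- data.frame(gene_a = "A", gene_b = "B")
    expect_equal(nrow(detectChimeric(ev, hom)), 0)
    # parent + disjoint TE overlap
    ev3 <- data.frame(gene_id = "g", type = c("parent", "te"),
                      feature_id = c("A", "te9"),
                      q_start = c(0L, 200L), q_end = c(60L, 300L),
                      stringsAsFactors = FALSE)
    expect_equal(detectChimeric(ev3)$composition, "parent_te")
})

test_that("hypergeometric tails match exhaustive enumeration", {
    expect_equal(hypergeometricEnrichment(3, 4, 5, 10), 66 / 252)
    expect_equal(hypergeometricEnrichment(0, 4, 5, 10), 1)
    expect_error(hypergeometricEnrichment(6, 4, 5, 10), "inconsistent")
    for (N in c(5, 9, 12)) for (K in 0:N) for (n in 0:N)
        for (k in 0:min(K, n))
            expect_equal(hypergeometricEnrichment(k, K, n, N),
                         enumHyperUpper(k, K, n, N), tolerance = 1e-12)
})

test_that("origin precedence and conservation hold in the rollup", {
    lsg <- sprintf("L%02d", 1:10)
    dup <- data.frame(gene_id = c("L01", "L02", "L03"),
                      detail = c("in_frame", "out_of_frame", "in_frame"),
                      stringsAsFactors = FALSE)
    res <- summarizeOrigins(lsg,
                            overprint_ids = c("L02", "L04"),
                            duplication = dup,
                            te_ids = c("L03", "L05"),
                            chimeric_ids = "L03",
                            outgroup_intergenic_ids = c("L06", "L07"))
    a <- setNames(res$assignments$primary_mechanism,
                  res$assignments$gene_id)
    expect_equal(unname(a["L03"]), "chimeric")      # beats duplication + TE
    expect_equal(unname(a["L02"]), "overprinting")  # beats duplication
    expect_equal(unname(a["L01"]), "duplication")
    expect_equal(unname(a["L05"]), "te_exaptation")
    expect_equal(unname(a["L08"]), "unknown")
    expect_equal(sum(res$rollup$count), 10)
    expect_error(summarizeOrigins(lsg, overprint_ids = "notLSG"),
                 "non-LSG")
    # printed-share arithmetic, duplication rollup style
    expect_equal(pctShare(225 + 173, 1789), 22.25)
})
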