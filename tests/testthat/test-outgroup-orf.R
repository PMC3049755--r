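mkScfHit <- function(s_start, s_end, score = 100, scf = "scf1", e = 1e-20)
    data.frame(query_id = "q", subject_id = scf, percent_identity = 90,
               n_columns = s_end - s_start, mismatches = 5L, gap_opens = 0L,
               q_start = 0L, q_end = s_end - s_start, s_start = s_start,
               s_end = s_end, orientation = "forward", e_value = e,
               score = score, stringsAsFactors = FALSE)

test_that("scaffold hits chain within the gap and follow the top hit", {
    # 3600 bp gap: one region spanning the extremes
    ch <- chainScaffoldHits(rbind(mkScfHit(1000, 1400),
                                  mkScfHit(5000, 5300, score = 80)))
    expect_equal(ch$region_start, 1000); expect_equal(ch$region_end, 5300)
    expect_equal(ch$n_hits, 2)
    # 4100 bp gap: two clusters, the best-scoring hit's cluster wins
    ch2 <- chainScaffoldHits(rbind(mkScfHit(1000, 1400, score = 60),
                                   mkScfHit(5500, 5800, score = 120)))
    expect_equal(ch2$region_start, 5500); expect_equal(ch2$region_end, 5800)
    expect_equal(ch2$n_hits, 1)
    # single hit: region equals the hit span; no hits: empty result
    ch3 <- chainScaffoldHits(mkScfHit(100, 400))
    expect_equal(c(ch3$region_start, ch3$region_end), c(100, 400))
    expect_null(chainScaffoldHits(mkScfHit(1, 50, e = 0.5)))
    # only the top hit's scaffold is considered; order of rows irrelevant
    hits <- rbind(mkScfHit(1000, 1300, score = 50, scf = "scfA"),
                  mkScfHit(2000, 2300, score = 200, scf = "scfB"),
                  mkScfHit(2500, 2800, score = 40, scf = "scfB"))
    ch4 <- chainScaffoldHits(hits)
    ch5 <- chainScaffoldHits(hits[c(3, 1, 2), ])
    expect_equal(ch4$scaffold, "scfB")
    expect_equal(ch4[c("region_start", "region_end", "n_hits")],
                 ch5[c("region_start", "region_end", "n_hits")])
})

test_that("ORF projection recovers planted disruption categories", {
    set.seed(21)
    cds <- paste0("ATG", paste(sample(setdiff(
        apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                          c("A","C","G","T")), 1, paste, collapse = ""),
        c("TAA", "TAG", "TGA")), 98, replace = TRUE), collapse = ""), "TAA")
    # identity
    pr <- projectOrf(cds, cds)
    expect_equal(pr$category, "INTACT")
    expect_equal(pr$coverage_pct, 100)
    expect_equal(pr$internal_stop_count, 0)
    expect_equal(pr$frameshift_indel_count, 0)
    # start codon mutated only
    msc <- cds; substr(msc, 3, 3) <- "A"
    pr2 <- projectOrf(cds, msc)
    expect_equal(pr2$category, "MSC")
    expect_false(pr2$start_codon_present)
    # verify with the translate-and-scan oracle: no stop gained
    expect_equal(translateScan(msc), translateScan(cds))
    # a 1-bp deletion at codon 50 is a frameshift indel
    del <- paste0(substr(cds, 1, 148), substr(cds, 150, nchar(cds)))
    pr3 <- projectOrf(cds, del)
    expect_equal(pr3$category, "ISC_OR_INDEL")
    expect_equal(pr3$frameshift_indel_count, 1)
    # an internal stop at codon 40
    isc <- cds; substr(isc, 118, 120) <- "TAA"
    pr4 <- projectOrf(cds, isc)
    expect_equal(pr4$category, "ISC_OR_INDEL")
    expect_equal(pr4$internal_stop_count, 1)
    expect_equal(pr4$stop_codon_positions, 39)  # 0-based codon index
    expect_equal(translateScan(isc)[1], 40)     # oracle agrees (1-based)
    # both
    both <- isc; substr(both, 3, 3) <- "A"
    expect_equal(projectOrf(cds, both)$category, "BOTH")
    # in-frame 30-bp insertion raises coverage above 100
    ins <- paste0(substr(cds, 1, 150),
                  paste(rep("GCA", 10), collapse = ""),
                  substr(cds, 151, nchar(cds)))
    pr5 <- projectOrf(cds, ins)
    expect_equal(pr5$coverage_pct, 110)
    expect_equal(pr5$frameshift_indel_count, 0)
    expect_error(projectOrf(cds, "AC"), "shorter than one codon")
})

test_that("projection on any sequence against itself is exactly INTACT 100", {
    set.seed(22)
    for (i in 1:5) {
        n <- sample(40:120, 1)
        cds <- paste0("ATG", paste(sample(setdiff(
            apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = ""),
            c("TAA", "TAG", "TGA")), n, replace = TRUE), collapse = ""),
            "TGA")
        pr <- projectOrf(cds, cds)
        expect_equal(pr$category, "INTACT")
        expect_equal(pr$coverage_pct, 100)
    }
})

test_that("projection sets summarise counts, coverage spread and intact list", {
    mkpr <- function(cat, cov) list(category = cat, coverage_pct = cov,
                                    start_codon_present = cat %in%
                                        c("INTACT", "ISC_OR_INDEL"),
                                    start_covered = TRUE,
                                    internal_stop_count = 0L,
                                    frameshift_indel_count = 0L,
                                    stop_codon_positions = integer(),
                                    aln_cds = "", aln_region = "")
    pr <- list(a = mkpr("MSC", 10), b = mkpr("MSC", 41.07),
               c = mkpr("INTACT", 96), d = mkpr("BOTH", 90),
               e = NULL)
    out <- classifyProjectionSet(pr)
    expect_equal(out$counts$denominator[1], 4)
    expect_equal(out$counts$share_pct[out$counts$category == "MSC"], 50)
    expect_equal(out$coverage$median[out$coverage$category == "MSC"],
                 (10 + 41.07) / 2)
    expect_equal(out$high_coverage_intact, "c")
    # SIQR definition: (Q3 - Q1) / 2
    pr2 <- list(a = mkpr("MSC", 10), b = mkpr("MSC", 41.07),
                c = mkpr("MSC", 90))
    out2 <- classifyProjectionSet(pr2)
    msc_i <- which(out2$coverage$category == "MSC")
    expect_equal(out2$coverage$median[msc_i], 41.07)
    expect_equal(out2$coverage$siqr[msc_i],
                 (stats::quantile(c(10, 41.07, 90), 0.75) -
                  stats::quantile(c(10, 41.07, 90), 0.25)) / 2,
                 ignore_attr = TRUE)
})

test_that("reciprocal best hits require agreement in both directions", {
    ab <- rbind(data.frame(query_id = "a", subject_id = "b", e_value = 1e-30,
                           score = 200),
                data.frame(query_id = "c", subject_id = "d", e_value = 1e-10,
                           score = 90))
    ba <- rbind(data.frame(query_id = "b", subject_id = "a", e_value = 1e-28,
                           score = 190),
                data.frame(query_id = "d", subject_id = "e", e_value = 1e-12,
                           score = 100))
    out <- reciprocalBestHits(ab, ba)
    expect_equal(out$gene_a, "a")
    expect_equal(out$gene_b, "b")
})

test_that("synthetic ortholog pairs at 5% divergence are recovered", {
    set.seed(23)
    n <- 40
    codons <- setdiff(apply(expand.grid(c("A","C","G","T"),
                                        c("A","C","G","T"),
                                        c("A","C","G","T")), 1, paste,
                            collapse = ""), c("TAA", "TAG", "TGA"))
    focal <- setNames(vapply(1:n, function(i)
        paste0("ATG", paste(sample(codons, 120, replace = TRUE),
                            collapse = ""), "TAA"), character(1)),
        sprintf("f%02d", 1:n))
    mut5 <- function(x) {
        v <- strsplit(x, "")[[1]]
        idx <- sample(length(v), round(0.05 * length(v)))
        v[idx] <- vapply(v[idx], function(b)
            sample(setdiff(c("A","C","G","T"), b), 1), character(1))
        paste(v, collapse = "")
    }
    og <- setNames(vapply(focal, mut5, character(1)), sprintf("o%02d", 1:n))
    fp <- Biostrings::AAStringSet(vapply(focal, function(x)
        sub("\\*.*$", "", lsgOrigins:::translateCds(x)), character(1)))
    op <- Biostrings::AAStringSet(vapply(og, function(x)
        sub("\\*.*$", "", lsgOrigins:::translateCds(x)), character(1)))
    rbh <- reciprocalBestHits(toySearch(fp, op, "peptide"),
                              toySearch(op, fp, "peptide"))
    correct <- sum(rbh$gene_b == sub("^f", "o", rbh$gene_a))
    expect_gte(correct, n - 1)
})

test_that("distant-genome evidence needs the reciprocal check", {
    set.seed(24)
    lsg_cds <- paste0("ATG", randomDnaStr(297))
    other <- setNames(randomDnaStr(300), "otherGene")
    focal_db <- Biostrings::DNAStringSet(c(L1 = lsg_cds, other))
    # species CDS database carries a diverged copy of the LSG
    sp_copy <- strsplit(lsg_cds, "")[[1]]
    idx <- sample(300, 20)
    sp_copy[idx] <- vapply(sp_copy[idx], function(b)
        sample(setdiff(c("A","C","G","T"), b), 1), character(1))
    sp_cds <- Biostrings::DNAStringSet(c(spT = paste(sp_copy,
                                                     collapse = "")))
    # genomic scaffold with the LSG-like segment at offset 5000
    scf <- paste0(randomDnaStr(5000), paste(sp_copy, collapse = ""),
                  randomDnaStr(3000))
    sp_gen <- Biostrings::DNAStringSet(c(scfX = scf))
    cds_hits <- toySearch(Biostrings::DNAStringSet(c(L1 = lsg_cds)), sp_cds,
                          "nucleotide")
    gen_hits <- toySearch(Biostrings::DNAStringSet(c(L1 = lsg_cds)), sp_gen,
                          "nucleotide")
    out <- scanDistantGenomes("L1", list(sp = cds_hits), list(sp = gen_hits),
                              list(sp = sp_cds), list(sp = sp_gen),
                              focal_db, c(L1 = 300))
    expect_equal(out$evidence, "distant_cds")
    # with no CDS hits, the genomic segment (plus 100 bp flanks) must hit
    # the LSG back
    out2 <- scanDistantGenomes("L1", list(sp = NULL), list(sp = gen_hits),
                               list(sp = sp_cds), list(sp = sp_gen),
                               focal_db, c(L1 = 300))
    expect_equal(out2$evidence, "distant_intergenic")
    # segment = hit span plus 100 bp on each side
    top_hit <- gen_hits[1, ]
    expect_equal(out2$partner, sprintf("scfX:%d-%d", top_hit$s_start - 100,
                                       top_hit$s_end + 100))
    # reciprocity failure: the segment matches another focal gene better
    focal_db2 <- Biostrings::DNAStringSet(
        c(L1 = randomDnaStr(300), better = paste(sp_copy, collapse = "")))
    out3 <- scanDistantGenomes("L1", list(sp = NULL), list(sp = gen_hits),
                               list(sp = sp_cds), list(sp = sp_gen),
                               focal_db2, c(L1 = 300))
    expect_equal(out3$evidence, "none")
})
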