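# Low-level builders for the synthetic genome: codon sampling, gene loci,
# frame-aware mutation. A "locus" is a self-contained stretch of sequence
# carrying zero or more genes with local 1-based coordinates; loci are later
# concatenated with intergenic spacers into chromosomes.

.NONSTOP_CODONS <- NULL

nonstopCodons <- function() {
    codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1, paste,
                    collapse = "")
    setdiff(codons, GENETIC_STOPS)
}

sampleCodons <- function(n) {
    paste(sample(nonstopCodons(), n, replace = TRUE), collapse = "")
}

# An intact ORF: ATG + (n_codons - 2) sense codons + stop.
makeOrf <- function(n_codons) {
    stopifnot(n_codons >= 3)
    paste0("ATG", sampleCodons(n_codons - 2L),
           sample(GENETIC_STOPS, 1))
}

# Replace any stop codon in frame 0 of `x` (length multiple of 3) with a
# sense codon differing by one base, leaving everything else untouched.
sanitizeStops <- function(x) {
    cods <- codonSplit(x)
    bad <- which(cods %in% GENETIC_STOPS)
    for (i in bad) {
        repl <- c(TAA = "CAA", TAG = "CAG", TGA = "TGG")[[cods[i]]]
        cods[i] <- repl
    }
    paste(cods, collapse = "")
}

# Build a gene locus. The spliced CDS is split over n_exons exons joined by
# introns; short UTRs extend the terminal exons. Coordinates are local,
# 1-based, on the plus strand of the locus; minus-strand genes store the
# reverse complement with flipped intervals.
makeGeneLocus <- function(gene_id, cds_seq, n_exons = 1L, strand = "+",
                          chrom = "chr1", utr5 = NULL, utr3 = NULL,
                          intron_len_range = c(70L, 200L),
                          expression_support = "locus_supported") {
    L <- nchar(cds_seq)
    stopifnot(L %% 3L == 0L, n_exons >= 1L)
    if (is.null(utr5)) utr5 <- sample(0:60, 1)
    if (is.null(utr3)) utr3 <- sample(0:80, 1)
    # cut the CDS into n_exons pieces, each at least 30 bp
    if (n_exons > 1L) {
        repeat {
            cuts <- sort(sample(seq(30L, L - 30L), n_exons - 1L))
            if (all(diff(c(0L, cuts, L)) >= 30L)) break
        }
    } else cuts <- integer()
    piece_bounds <- cbind(start = c(0L, cuts) + 1L, end = c(cuts, L))
    introns <- if (n_exons > 1L)
        vapply(seq_len(n_exons - 1L), function(i)
            randomDna(sample(seq(intron_len_range[1], intron_len_range[2]),
                             1)), character(1))
    else character()

    seq <- if (utr5 > 0) randomDna(utr5) else ""
    exons <- NULL; cds <- NULL
    pos <- nchar(seq)
    for (i in seq_len(n_exons)) {
        piece <- substr(cds_seq, piece_bounds[i, 1], piece_bounds[i, 2])
        ex_start <- if (i == 1L) 1L else pos + 1L
        cds_start <- pos + 1L
        seq <- paste0(seq, piece)
        pos <- nchar(seq)
        cds <- rbind(cds, c(cds_start, pos))
        if (i == n_exons && utr3 > 0) {
            seq <- paste0(seq, randomDna(utr3))
            pos <- nchar(seq)
        }
        exons <- rbind(exons, c(ex_start, pos))
        if (i < n_exons) {
            seq <- paste0(seq, introns[i])
            pos <- nchar(seq)
        }
    }
    gene <- list(gene_id = gene_id, strand = strand, chrom = chrom,
                 exons = exons, cds = cds,
                 expression_support = expression_support)
    if (strand == "-") {
        n <- nchar(seq)
        seq <- revcomp(seq)
        flip <- function(m) {
            out <- cbind(n - m[, 2] + 1L, n - m[, 1] + 1L)
            out[order(out[, 1]), , drop = FALSE]
        }
        gene$exons <- flip(gene$exons)
        gene$cds <- flip(gene$cds)
    }
    list(id = gene_id, chrom = chrom, seq = seq, genes = list(gene),
         te = list())
}

# Spliced CDS of a gene within its locus (local coordinates), 5'->3'.
locusCdsSeq <- function(locus, gene_idx = 1L) {
    g <- locus$genes[[gene_idx]]
    m <- g$cds[order(g$cds[, 1]), , drop = FALSE]
    s <- paste(vapply(seq_len(nrow(m)), function(i)
        substr(locus$seq, m[i, 1], m[i, 2]), character(1)), collapse = "")
    if (g$strand == "-") revcomp(s) else s
}

# Frame-aware substitution mutation of a locus. Positions inside any gene's
# CDS are mutated codon-aware in every covering gene's frame: proposals that
# create a stop, destroy a start codon or destroy a terminal stop in any
# covering gene are rejected; accepted nonsynonymous changes are thinned to
# probability `omega` (synonymous changes always accepted), giving planted
# rate classes. Positions in `protect` (local, 1-based) are never mutated.
mutateLocus <- function(locus, rate, omega = 1, protect = integer()) {
    n <- nchar(locus$seq)
    if (n == 0L || rate <= 0) return(locus)
    k <- rbinom(1, n, rate)
    if (k == 0L) return(locus)
    pos <- sample.int(n, k)
    pos <- setdiff(pos, protect)
    seqv <- strsplit(locus$seq, "")[[1]]
    cov <- coveringFrames(locus)
    # per-gene CDS base positions in transcription order, and codon counts
    gpos <- lapply(locus$genes, cdsLocalPositionsGene)
    ncod <- vapply(gpos, function(x) length(x) %/% 3L, integer(1))
    minus <- vapply(locus$genes, function(g) g$strand == "-", logical(1))
    bases <- c("A", "C", "G", "T")
    tbl <- codonTable()
    for (p in pos) {
        cur <- seqv[p]
        alt <- sample(setdiff(bases, cur), 1)
        entries <- cov[[p]]
        if (is.null(entries)) { seqv[p] <- alt; next }
        ok <- TRUE; any_nonsyn <- FALSE
        for (e in entries) {
            gi <- e$gene
            cpos <- gpos[[gi]][(e$codon * 3L - 2L):(e$codon * 3L)]
            triplet <- seqv[cpos]
            new_triplet <- triplet
            new_triplet[e$offset] <- alt
            if (minus[gi]) {
                triplet <- chartr("ACGT", "TGCA", triplet)
                new_triplet <- chartr("ACGT", "TGCA", new_triplet)
            }
            old_codon <- paste(triplet, collapse = "")
            new_codon <- paste(new_triplet, collapse = "")
            if (e$codon == 1L && new_codon != "ATG") { ok <- FALSE; break }
            if (e$codon == ncod[gi] &&
                !(new_codon %in% GENETIC_STOPS)) { ok <- FALSE; break }
            if (e$codon < ncod[gi] && new_codon %in% GENETIC_STOPS) {
                ok <- FALSE; break
            }
            if (tbl[[old_codon]] != tbl[[new_codon]]) any_nonsyn <- TRUE
        }
        if (!ok) next
        if (any_nonsyn && runif(1) > omega) next
        seqv[p] <- alt
    }
    locus$seq <- paste(seqv, collapse = "")
    locus
}

# Transcription-order CDS base positions for a gene definition (local,
# 1-based).
cdsLocalPositionsGene <- function(g) {
    m <- g$cds[order(g$cds[, 1]), , drop = FALSE]
    pos <- unlist(lapply(seq_len(nrow(m)), function(i) seq(m[i, 1], m[i, 2])),
                  use.names = FALSE)
    if (g$strand == "-") rev(pos) else pos
}

# For each local position covered by a CDS, the list of covering frames:
# gene index, codon index (1-based in the spliced CDS) and offset within the
# codon (1..3), strand-aware.
coveringFrames <- function(locus) {
    cov <- vector("list", nchar(locus$seq))
    for (gi in seq_along(locus$genes)) {
        g <- locus$genes[[gi]]
        m <- g$cds[order(g$cds[, 1]), , drop = FALSE]
        # spliced positions in transcription order
        plus_positions <- unlist(lapply(seq_len(nrow(m)), function(i)
            seq(m[i, 1], m[i, 2])))
        positions <- if (g$strand == "-") rev(plus_positions)
                     else plus_positions
        for (j in seq_along(positions)) {
            p <- positions[j]
            cov[[p]] <- c(cov[[p]], list(list(
                gene = gi, codon = (j - 1L) %/% 3L + 1L,
                offset = (j - 1L) %% 3L + 1L)))
        }
    }
    cov
}
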