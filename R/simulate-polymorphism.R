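#' Generate the accession SNP table
#'
#' Emits substitution SNPs for a panel of accessions: each planted
#' accession-ISC/MSC event places its disrupting allele in a majority of
#' accessions for gene-birth cases (the disruption is ancestral and shared)
#' or in one to three accessions for gene-loss cases; background SNPs are
#' placed at intergenic positions and at synonymous (fourfold degenerate)
#' coding sites, so only planted disruptions interrupt ORFs. A few
#' undetermined alleles (alt `N`) mark missing data.
#'
#' @param sim state from [deriveOutgroup()] (needs the assembled catalog).
#' @return sim with `sim$snps` (accession, chrom, pos, ref, alt) and
#'   `sim$acc_calls_truth` (gene_id, accession, type) listing every planted
#'   disruption call.
#' @export
generatePolymorphisms <- function(sim) {
    config <- sim$config
    stopifnot(config@n_accessions >= 1L)
    withSeed(childSeed(config@seed, "snps"), {
        accs <- sprintf("acc%02d", seq_len(config@n_accessions))
        catalog <- sim$catalog
        rows <- list(); truth_rows <- list()
        baseAt <- function(chrom, pos)
            as.character(Biostrings::subseq(catalog@sequences[[chrom]],
                                            pos, pos))
        # planted disruptions
        for (gid in names(sim$acc_truth)) {
            at <- sim$acc_truth[[gid]]
            gpos <- cdsPosToGenomic(catalog, gid,
                                    3L * (at$codon_index - 1L) +
                                        at$pos_in_codon - 1L)
            chrom <- catalog@genes$chrom[catalog@genes$gene_id == gid]
            ref <- baseAt(chrom, gpos)
            # birth cases: the disruption is ancestral, carried by a clear
            # majority; loss cases: confined to a small minority
            n_acc <- length(accs)
            n_carry <- if (at$birth) {
                lo <- max(2L, ceiling(n_acc * 0.6))
                hi <- max(lo, n_acc - 1L)
                sample(lo:hi, 1)
            } else sample(seq_len(max(1L, min(3L, (n_acc - 1L) %/% 2L))), 1)
            carriers <- sample(accs, n_carry)
            for (a in carriers) {
                rows[[length(rows) + 1L]] <- data.frame(
                    accession = a, chrom = chrom, pos = gpos, ref = ref,
                    alt = at$alt, stringsAsFactors = FALSE)
                truth_rows[[length(truth_rows) + 1L]] <- data.frame(
                    gene_id = gid, accession = a, type = at$type,
                    birth = at$birth, stringsAsFactors = FALSE)
            }
            # one undetermined genotype at the same site
            miss <- setdiff(accs, carriers)
            if (length(miss))
                rows[[length(rows) + 1L]] <- data.frame(
                    accession = miss[1], chrom = chrom, pos = gpos,
                    ref = ref, alt = "N", stringsAsFactors = FALSE)
        }
        # background SNPs: synonymous fourfold-degenerate third positions
        fourfold <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
        genes <- catalog@genes
        bg_genes <- sample(genes$gene_id, min(60L, nrow(genes)))
        for (gid in bg_genes) {
            cds <- as.character(cdsSequences(catalog, gid))
            cods <- codonSplit(cds)
            ok <- which(substr(cods, 1, 2) %in% fourfold)
            ok <- ok[ok > 1L & ok < length(cods)]
            if (!length(ok)) next
            ci <- sample(ok, 1)
            off <- 3L * ci - 1L  # 0-based offset of the third position
            gpos <- cdsPosToGenomic(catalog, gid, off)
            chrom <- genes$chrom[genes$gene_id == gid]
            strand <- genes$strand[genes$gene_id == gid]
            ref <- baseAt(chrom, gpos)
            alt_cds <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(cods[ci], 3, 3)), 1)
            alt <- if (strand == "-") chartr("ACGT", "TGCA", alt_cds)
                   else alt_cds
            for (a in sample(accs, max(1L, rbinom(1, length(accs), 0.25))))
                rows[[length(rows) + 1L]] <- data.frame(
                    accession = a, chrom = chrom, pos = gpos, ref = ref,
                    alt = alt, stringsAsFactors = FALSE)
        }
        # intergenic SNPs
        gene_cov <- GenomicRanges::reduce(GenomicRanges::GRanges(
            genes$chrom, IRanges::IRanges(genes$start, genes$end)))
        for (j in seq_len(120L)) {
            chrom <- "chr1"
            n <- length(catalog@sequences[[chrom]])
            pos <- sample.int(n, 1)
            hit <- GenomicRanges::countOverlaps(
                GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos)),
                gene_cov) > 0
            if (hit) next
            ref <- baseAt(chrom, pos)
            if (!ref %in% c("A", "C", "G", "T")) next
            alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
            for (a in sample(accs, max(1L, rbinom(1, length(accs), 0.2))))
                rows[[length(rows) + 1L]] <- data.frame(
                    accession = a, chrom = chrom, pos = pos, ref = ref,
                    alt = alt, stringsAsFactors = FALSE)
        }
        snps <- do.call(rbind, rows)
        snps <- snps[order(snps$accession, snps$chrom, snps$pos), ]
        rownames(snps) <- NULL
        sim$snps <- snps
        sim$acc_calls_truth <- if (length(truth_rows))
            do.call(rbind, truth_rows) else
            data.frame(gene_id = character(), accession = character(),
                       type = character(), birth = logical(),
                       stringsAsFactors = FALSE)
        sim
    })
}
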