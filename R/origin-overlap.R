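#' Find gene pairs with overlapping CDS
#'
#' Because lineage specificity is defined on the peptide, only CDS intervals
#' (not introns or UTRs) are compared: a pair is reported when the genomic
#' union of one model's CDS segments intersects the other's by at least one
#' base pair, on any strand. LSG members of LSG:non-LSG pairs are candidates
#' for an overprinting origin.
#'
#' @param catalog a [GenomeCatalog-class].
#' @param lsg_ids character vector of LSG gene ids.
#' @return data.frame of unordered pairs: `gene_a`, `gene_b`, `overlap_bp`,
#'   `pair_type` in `{"LSG:LSG", "LSG:nonLSG", "nonLSG:nonLSG"}`.
#' @export
findOverlappingCds <- function(catalog, lsg_ids = character()) {
    cds <- catalog@cds
    gr <- unlist(GenomicRanges::GRangesList(unname(lapply(cds, function(x) {
        GenomicRanges::GRanges(GenomeInfoDb::seqnames(x),
                               IRanges::ranges(x))
    }))))
    gene_of <- rep(names(cds), lengths(cds))
    ov <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    keep <- gene_of[qh] < gene_of[sh]
    qh <- qh[keep]; sh <- sh[keep]
    if (!length(qh))
        return(data.frame(gene_a = character(), gene_b = character(),
                          overlap_bp = integer(), pair_type = character(),
                          stringsAsFactors = FALSE))
    ovlap <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr)[qh],
                                                IRanges::ranges(gr)[sh]))
    df <- data.frame(gene_a = gene_of[qh], gene_b = gene_of[sh],
                     overlap_bp = ovlap, stringsAsFactors = FALSE)
    df <- stats::aggregate(overlap_bp ~ gene_a + gene_b, df, sum)
    a_lsg <- df$gene_a %in% lsg_ids
    b_lsg <- df$gene_b %in% lsg_ids
    df$pair_type <- ifelse(a_lsg & b_lsg, "LSG:LSG",
                    ifelse(a_lsg | b_lsg, "LSG:nonLSG", "nonLSG:nonLSG"))
    df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Detect transposable-element exaptation
#'
#' A gene has exapted TE DNA when at least one of its exons (or CDS segments,
#' per `level`) intersects a TE fragment by at least one base pair. The
#' per-superfamily tally counts exapted fragments split by LSG status; a gene
#' overlapped by fragments of several superfamilies contributes one case per
#' superfamily.
#'
#' @param catalog a [GenomeCatalog-class].
#' @param lsg_ids LSG gene ids.
#' @param level `"exon"` (default, exonic sequence comparison) or `"cds"`.
#' @return list with `overlaps` (gene_id, te_id, superfamily, overlap_bp,
#'   is_lsg), `genes` (distinct exapted genes) and `tally` (superfamily, LSG
#'   fragment count, non-LSG fragment count).
#' @export
detectTeExaptation <- function(catalog, lsg_ids = character(),
                               level = c("exon", "cds")) {
    level <- match.arg(level)
    feats <- if (level == "exon") catalog@exons else catalog@cds
    te <- catalog@te
    empty <- list(overlaps = data.frame(gene_id = character(),
                                        te_id = character(),
                                        superfamily = character(),
                                        overlap_bp = integer(),
                                        is_lsg = logical(),
                                        stringsAsFactors = FALSE),
                  genes = character(),
                  tally = data.frame(superfamily = character(),
                                     lsg_fragments = integer(),
                                     nonlsg_fragments = integer(),
                                     stringsAsFactors = FALSE))
    if (!length(te) || !length(feats)) return(empty)
    gr <- unlist(GenomicRanges::GRangesList(unname(lapply(feats, function(x)
        GenomicRanges::GRanges(GenomeInfoDb::seqnames(x),
                               IRanges::ranges(x))))))
    gene_of <- rep(names(feats), lengths(feats))
    ov <- GenomicRanges::findOverlaps(gr, te, ignore.strand = TRUE)
    if (!length(ov)) return(empty)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    ovlap <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(gr)[qh],
        IRanges::ranges(te)[sh]))
    df <- data.frame(gene_id = gene_of[qh],
                     te_id = te$te_id[sh],
                     superfamily = te$superfamily[sh],
                     overlap_bp = ovlap,
                     stringsAsFactors = FALSE)
    df <- stats::aggregate(overlap_bp ~ gene_id + te_id + superfamily, df,
                           sum)
    df$is_lsg <- df$gene_id %in% lsg_ids
    df <- df[order(df$gene_id, df$te_id), , drop = FALSE]
    rownames(df) <- NULL
    frag <- unique(df[, c("te_id", "superfamily", "is_lsg")])
    tally <- stats::aggregate(cbind(lsg_fragments = frag$is_lsg,
                                    nonlsg_fragments = !frag$is_lsg),
                              by = list(superfamily = frag$superfamily), sum)
    tally$lsg_fragments <- as.integer(tally$lsg_fragments)
    tally$nonlsg_fragments <- as.integer(tally$nonlsg_fragments)
    list(overlaps = df, genes = sort(unique(df$gene_id)), tally = tally)
}
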