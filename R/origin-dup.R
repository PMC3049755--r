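#' Merge overlapping HSPs of one query:subject pair
#'
#' All HSPs of the pair are concatenated: overlapping query intervals are
#' unioned, and the merged coverage is the union length plus any excess
#' alignment columns contributed by query-gap columns (so coverage can exceed
#' 100 only through gaps in the query). Pairs covering less than
#' `min_query_coverage_pct` of the query are discarded.
#'
#' @param hsps HSP data.frame rows sharing one `query_id` and one
#'   `subject_id`.
#' @param query_length query length on the HSP coordinate system (residues
#'   for peptide, nucleotides for CDS searches).
#' @param thresholds a [ThresholdConfig-class].
#' @return `NULL` when discarded, else a list with `query_id`, `subject_id`,
#'   `intervals` (matrix of merged 0-based half-open query intervals),
#'   `coverage_pct`, `n_hsps`, and the dominant (longest) HSP's orientation.
#' @export
mergeHsps <- function(hsps, query_length, thresholds = thresholdConfig()) {
    stopifnot(nrow(hsps) >= 1,
              length(unique(hsps$query_id)) == 1,
              length(unique(hsps$subject_id)) == 1)
    if (any(hsps$q_end > query_length))
        stop("HSP query end beyond query length for ", hsps$query_id[1])
    merged <- mergeIntervals(hsps$q_start, hsps$q_end)
    union_len <- sum(merged[, "end"] - merged[, "start"])
    excess <- sum(pmax(hsps$n_columns - (hsps$q_end - hsps$q_start), 0))
    coverage <- 100 * (union_len + excess) / query_length
    if (coverage < thresholds@min_query_coverage_pct) return(NULL)
    dom <- which.max(hsps$n_columns)
    list(query_id = hsps$query_id[1],
         subject_id = hsps$subject_id[1],
         intervals = merged,
         coverage_pct = coverage,
         n_hsps = nrow(hsps),
         dominant_orientation = hsps$orientation[dom])
}

# Merge every query:subject pair of a hit table at a given e-value cutoff;
# returns a list of mergeHsps results keyed "query\rsubject".
mergeAllPairs <- function(hits, query_lengths, thresholds,
                          evalue = thresholds@within_genome_evalue) {
    hits <- hits[hits$e_value < evalue, , drop = FALSE]
    out <- list()
    if (!nrow(hits)) return(out)
    key <- paste(hits$query_id, hits$subject_id, sep = "\r")
    for (k in unique(key)) {
        sub <- hits[key == k, , drop = FALSE]
        mc <- mergeHsps(sub, query_lengths[[sub$query_id[1]]], thresholds)
        if (!is.null(mc)) out[[k]] <- mc
    }
    out
}

#' Compare peptide and CDS merged coverage of a pair
#'
#' A pair has additional out-of-frame alignment segments when its CDS
#' (nucleotide) coverage exceeds its peptide coverage; an absent peptide hit
#' counts as coverage 0, so CDS-only pairs are fully out-of-frame. The
#' out-of-frame intervals are the CDS merged intervals minus the peptide
#' intervals mapped to nucleotide space.
#'
#' @param pep_merged,cds_merged [mergeHsps()] results for the same
#'   LSG:subject pair (either may be `NULL`).
#' @return `NULL` when no CDS evidence, else list with `frame`
#'   (`"in_frame"`/`"out_of_frame"`), `pep_coverage_pct`, `cds_coverage_pct`
#'   and `out_of_frame_intervals` (nucleotide space, 0-based half-open).
#' @export
detectOutOfFrame <- function(pep_merged, cds_merged) {
    if (is.null(cds_merged)) return(NULL)
    pep_cov <- if (is.null(pep_merged)) 0 else pep_merged$coverage_pct
    cds_cov <- cds_merged$coverage_pct
    if (cds_cov > pep_cov) {
        pep_nt <- if (is.null(pep_merged))
            cbind(start = integer(), end = integer())
        else cbind(start = 3L * pep_merged$intervals[, "start"],
                   end = 3L * pep_merged$intervals[, "end"])
        oof <- subtractIntervals(cds_merged$intervals[, "start"],
                                 cds_merged$intervals[, "end"],
                                 pep_nt[, "start"], pep_nt[, "end"])
        list(frame = "out_of_frame", pep_coverage_pct = pep_cov,
             cds_coverage_pct = cds_cov, out_of_frame_intervals = oof)
    } else {
        list(frame = "in_frame", pep_coverage_pct = pep_cov,
             cds_coverage_pct = cds_cov,
             out_of_frame_intervals = cbind(start = integer(),
                                            end = integer()))
    }
}

#' Orientation of a merged CDS pair
#'
#' Decided by the dominant (longest, by alignment columns) HSP rather than a
#' column majority; configurable by passing pre-filtered HSPs.
#'
#' @param cds_hsps nucleotide-level HSP rows for one pair.
#' @return `"forward"` or `"inverted"`.
#' @export
detectOrientation <- function(cds_hsps) {
    stopifnot(nrow(cds_hsps) >= 1)
    cds_hsps$orientation[which.max(cds_hsps$n_columns)]
}

#' Infer the duplication mechanism from intron-exon boundaries
#'
#' Within the aligned region: if any LSG intron-exon boundary lies within
#' `boundary_tolerance_bp` (inclusive) of a subject boundary, the pair is
#' consistent with segmental duplication / unequal crossing over; if the
#' alignment spans at least one subject boundary while the corresponding LSG
#' region is intron-free, it is consistent with retrotransposition; with no
#' boundaries in the alignments the mechanism is indeterminate. Boundary
#' positions are compared in the query's spliced-CDS coordinate space after
#' mapping subject boundaries through the HSPs.
#'
#' @param catalog a [GenomeCatalog-class].
#' @param lsg_id,subject_id gene ids of the duplicate pair.
#' @param cds_hsps nucleotide-level HSP rows for the pair (CDS coordinate
#'   space on both sides).
#' @param thresholds a [ThresholdConfig-class].
#' @return `"unequal_crossing_over"`, `"retrotransposition"` or
#'   `"indeterminate"`.
#' @export
classifyDuplicationMechanism <- function(catalog, lsg_id, subject_id,
                                         cds_hsps,
                                         thresholds = thresholdConfig()) {
    tol <- thresholds@boundary_tolerance_bp
    q_len <- sum(GenomicRanges::width(catalog@cds[[lsg_id]]))
    s_len <- sum(GenomicRanges::width(catalog@cds[[subject_id]]))
    if (any(cds_hsps$q_end > q_len) || any(cds_hsps$s_end > s_len))
        stop("alignment interval outside gene model for pair ",
             lsg_id, ":", subject_id)
    q_bounds <- cdsBoundaryPositions(catalog, lsg_id)
    s_bounds <- cdsBoundaryPositions(catalog, subject_id)

    # subject boundaries that fall inside an aligned segment, mapped to
    # query CDS coordinates through that segment (linear within an HSP)
    mapped <- numeric()
    for (i in seq_len(nrow(cds_hsps))) {
        h <- cds_hsps[i, ]
        inside <- s_bounds[s_bounds > h$s_start & s_bounds < h$s_end]
        if (!length(inside)) next
        if (h$orientation == "forward")
            mapped <- c(mapped, h$q_start + (inside - h$s_start))
        else
            mapped <- c(mapped, h$q_end - (inside - h$s_start))
    }
    q_in_aln <- q_bounds[vapply(q_bounds, function(b)
        any(b > cds_hsps$q_start & b < cds_hsps$q_end), logical(1))]

    if (length(mapped) && length(q_in_aln) &&
        any(vapply(q_in_aln, function(b) any(abs(b - mapped) <= tol),
                   logical(1))))
        return("unequal_crossing_over")
    if (length(mapped) && !length(q_in_aln))
        return("retrotransposition")
    "indeterminate"
}

#' Classify the genomic context of a duplicate pair
#'
#' Syntelog when the pair appears in the syntelog table (with a WGD flag when
#' it is also inside a listed WGD block); otherwise tandem when both genes sit
#' on one chromosome with at most `tandem_max_intervening_genes` annotated
#' genes between them (an approximation of a collinearity tool's
#' local-duplication call); otherwise distal.
#'
#' @param pairs data.frame with `lsg_id`, `subject_id`.
#' @param gene_table `geneModels(catalog)`-style table giving gene order.
#' @param syntelog_table optional data.frame `gene_a`, `gene_b`.
#' @param wgd_table optional data.frame `gene_a`, `gene_b` for pairs inside
#'   WGD blocks.
#' @param thresholds a [ThresholdConfig-class].
#' @return `pairs` with added `context` (`tandem`/`distal`/`syntelog`) and
#'   `wgd` (logical) columns.
#' @export
classifyDuplicationContext <- function(pairs, gene_table,
                                       syntelog_table = NULL,
                                       wgd_table = NULL,
                                       thresholds = thresholdConfig()) {
    ord <- gene_table[order(gene_table$chrom, gene_table$start), ]
    rank <- ave(seq_len(nrow(ord)), ord$chrom, FUN = seq_along)
    rank <- setNames(rank, ord$gene_id)
    chrom <- setNames(ord$chrom, ord$gene_id)
    pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    syn <- if (!is.null(syntelog_table) && nrow(syntelog_table))
        pairKey(syntelog_table$gene_a, syntelog_table$gene_b) else character()
    wgd <- if (!is.null(wgd_table) && nrow(wgd_table))
        pairKey(wgd_table$gene_a, wgd_table$gene_b) else character()
    key <- pairKey(pairs$lsg_id, pairs$subject_id)
    same_chrom <- chrom[pairs$lsg_id] == chrom[pairs$subject_id]
    intervening <- abs(rank[pairs$lsg_id] - rank[pairs$subject_id]) - 1L
    pairs$context <- ifelse(key %in% syn, "syntelog",
                     ifelse(same_chrom &
                            intervening <=
                                thresholds@tandem_max_intervening_genes,
                            "tandem", "distal"))
    pairs$wgd <- key %in% syn & key %in% wgd
    pairs
}
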