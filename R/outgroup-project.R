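#' Project an LSG CDS onto an outgroup region and classify disruptions
#'
#' Global-local affine-gap nucleotide alignment of the CDS (global) against
#' the chained outgroup region (local), followed by a codon walk: frameshift
#' indels are alignment gap runs whose length is not a multiple of three;
#' internal stop codons are counted by translating the region's aligned bases
#' in the reading frame projected from the CDS (frame tracked through gaps),
#' excluding the codon aligned to the CDS terminal stop; the start codon is
#' present when the region bases aligned to CDS codon 1 read ATG
#' (alternative start codons are not recognised). Coverage is alignment
#' columns over CDS length after trimming columns where the region is
#' exhausted, so it exceeds 100 only through insertions in the region
#' (query-gap columns). Terminal subject gaps therefore reduce coverage.
#'
#' Categories: INTACT (start present, no stops, no frameshifts), MSC (start
#' absent only), ISC_OR_INDEL (start present, stops and/or frameshifts),
#' BOTH. When the alignment does not reach codon 1 the start is not judged
#' absent; the projection carries `start_covered = FALSE` and the category is
#' computed from the covered portion.
#'
#' @param cds_seq LSG CDS sequence (character or `DNAString`), ATG..stop.
#' @param region_seq outgroup region sequence, already oriented to the hit
#'   strand.
#' @param thresholds a [ThresholdConfig-class].
#' @return `NULL` when coverage falls below `min_query_coverage_pct`, else a
#'   list with `category`, `coverage_pct`, `start_codon_present`,
#'   `start_covered`, `internal_stop_count`, `frameshift_indel_count`,
#'   `stop_codon_positions` (0-based CDS codon indices), and the aligned
#'   pattern/subject strings (`aln_cds`, `aln_region`) for site-level
#'   cross-referencing.
#' @export
projectOrf <- function(cds_seq, region_seq,
                       thresholds = thresholdConfig()) {
    cds_seq <- as.character(cds_seq); region_seq <- as.character(region_seq)
    if (nchar(region_seq) < 3)
        stop("outgroup region shorter than one codon")
    pars <- .SEARCH_PARS[["nucleotide"]]
    aln <- Biostrings::pairwiseAlignment(
        cds_seq, region_seq, type = "global-local",
        substitutionMatrix = searchMatrix("nucleotide"),
        gapOpening = pars$gap_open, gapExtension = pars$gap_ext)
    ap <- strsplit(as.character(Biostrings::alignedPattern(aln)[[1]]),
                   "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)[[1]]),
                    "")[[1]]
    # trim terminal columns where the region is exhausted
    sgap <- as_ == "-"
    keep <- rep(TRUE, length(ap))
    i <- 1L
    while (i <= length(ap) && sgap[i]) { keep[i] <- FALSE; i <- i + 1L }
    i <- length(ap)
    while (i >= 1L && sgap[i]) { keep[i] <- FALSE; i <- i - 1L }
    ap_t <- ap[keep]; as_t <- as_[keep]

    cds_len <- nchar(cds_seq)
    coverage <- 100 * length(ap_t) / cds_len
    if (coverage < thresholds@min_query_coverage_pct) return(NULL)

    # CDS position (0-based) of each trimmed column's pattern base
    pat_pos <- cumsum(ap != "-") - 1L
    pat_pos[ap == "-"] <- NA_integer_
    pat_pos_t <- pat_pos[keep]

    first_covered <- suppressWarnings(min(pat_pos_t, na.rm = TRUE))
    start_covered <- is.finite(first_covered) && first_covered <= 0L

    start_codon_present <- TRUE
    if (start_covered) {
        sc <- as_t[!is.na(pat_pos_t) & pat_pos_t <= 2L]
        sc <- sc[sc != "-"]
        start_codon_present <- length(sc) == 3L &&
            paste(sc, collapse = "") == "ATG"
    }

    # frameshift indels: gap runs (either side) with length % 3 != 0
    gapchar <- ifelse(ap_t == "-", "p", ifelse(as_t == "-", "s", "."))
    r <- rle(gapchar)
    frameshift <- sum(r$values != "." & r$lengths %% 3L != 0L)

    # internal stops: translate the region's bases straight through from the
    # base aligned to the first covered CDS codon boundary
    reg_bases <- as_t[as_t != "-"]
    # index (1-based, within reg_bases) of the region base aligned to each
    # covered CDS position
    reg_idx <- cumsum(as_t != "-")
    cds_of_col <- pat_pos_t
    ok <- !is.na(cds_of_col) & as_t != "-"
    # first column aligned at a codon boundary of the CDS
    boundary_cols <- which(ok & cds_of_col %% 3L == 0L)
    internal_stops <- 0L
    stop_positions <- integer()
    if (length(boundary_cols)) {
        from <- reg_idx[boundary_cols[1]]
        reg_str <- paste(reg_bases[from:length(reg_bases)], collapse = "")
        codons <- codonSplit(reg_str)
        cds_codon0 <- cds_of_col[boundary_cols[1]] %/% 3L
        terminal_codon <- cds_len %/% 3L - 1L
        codon_ids <- cds_codon0 + seq_along(codons) - 1L
        is_stop <- codons %in% GENETIC_STOPS
        internal <- is_stop & codon_ids < terminal_codon & codon_ids > 0L
        internal_stops <- sum(internal)
        stop_positions <- codon_ids[internal]
    }

    category <- if (start_codon_present && internal_stops == 0L &&
                    frameshift == 0L) "INTACT"
        else if (!start_codon_present && internal_stops == 0L &&
                 frameshift == 0L) "MSC"
        else if (start_codon_present) "ISC_OR_INDEL"
        else "BOTH"

    list(category = category,
         coverage_pct = coverage,
         start_codon_present = start_codon_present,
         start_covered = start_covered,
         internal_stop_count = internal_stops,
         frameshift_indel_count = frameshift,
         stop_codon_positions = stop_positions,
         aln_cds = paste(ap_t, collapse = ""),
         aln_region = paste(as_t, collapse = ""))
}

#' Summarise a set of ORF projections
#'
#' @param projections named list of [projectOrf()] results (discarded /
#'   `NULL` entries allowed; names are LSG ids).
#' @param thresholds a [ThresholdConfig-class].
#' @return list with `counts` (per category: count, share over the explicit
#'   denominator of non-discarded projections), `coverage` (per-category
#'   median and semi-interquartile range of coverage), and
#'   `high_coverage_intact` (ids with category INTACT and coverage at or
#'   above `intact_orf_coverage_pct`: putative shared un-annotated ORFs).
#' @export
classifyProjectionSet <- function(projections,
                                  thresholds = thresholdConfig()) {
    keep <- !vapply(projections, is.null, logical(1))
    pr <- projections[keep]
    cats <- c("INTACT", "MSC", "ISC_OR_INDEL", "BOTH")
    if (!length(pr))
        return(list(counts = data.frame(category = cats, count = 0L,
                                        denominator = 0L, share_pct = NA_real_,
                                        stringsAsFactors = FALSE),
                    coverage = data.frame(category = cats,
                                          median = NA_real_, siqr = NA_real_,
                                          stringsAsFactors = FALSE),
                    high_coverage_intact = character()))
    cat_v <- vapply(pr, `[[`, character(1), "category")
    cov_v <- vapply(pr, `[[`, numeric(1), "coverage_pct")
    counts <- data.frame(category = cats,
                         count = as.integer(table(factor(cat_v,
                                                         levels = cats))),
                         denominator = length(pr),
                         stringsAsFactors = FALSE)
    counts$share_pct <- pctShare(counts$count, counts$denominator)
    coverage <- do.call(rbind, lapply(cats, function(cc) {
        ms <- medianSiqr(cov_v[cat_v == cc])
        data.frame(category = cc, median = unname(ms["median"]),
                   siqr = unname(ms["siqr"]), stringsAsFactors = FALSE)
    }))
    hi <- names(pr)[cat_v == "INTACT" &
                    cov_v >= thresholds@intact_orf_coverage_pct]
    list(counts = counts, coverage = coverage,
         high_coverage_intact = sort(hi))
}
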