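#' @importFrom GenomicRanges GRanges GRangesList
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqnames
NULL

#' Accessors for GenomeCatalog
#'
#' @param x a [GenomeCatalog-class].
#' @return `chromSequences`: a `DNAStringSet`; `geneModels`: the gene table;
#'   `exonRanges`/`cdsRanges`: `GRangesList` keyed by gene id;
#'   `teFragments`: a `GRanges`; `geneIds`: character vector.
#' @name catalog-accessors
NULL

#' @rdname catalog-accessors
#' @export
chromSequences <- function(x) x@sequences

#' @rdname catalog-accessors
#' @export
geneModels <- function(x) x@genes

#' @rdname catalog-accessors
#' @export
exonRanges <- function(x) x@exons

#' @rdname catalog-accessors
#' @export
cdsRanges <- function(x) x@cds

#' @rdname catalog-accessors
#' @export
teFragments <- function(x) x@te

#' @rdname catalog-accessors
#' @export
geneIds <- function(x) x@genes$gene_id

setMethod("show", "GenomeCatalog", function(object) {
    g <- object@genes
    cat(sprintf("GenomeCatalog: %d sequence(s), %d gene model(s), %d TE fragment(s)\n",
                length(object@sequences), nrow(g), length(object@te)))
    tab <- table(g$compartment)
    cat("  compartments:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
})

#' Spliced CDS and peptide sequences for catalog genes
#'
#' CDS segments are concatenated in genomic order and reverse-complemented for
#' minus-strand models, so the returned sequence always reads 5' to 3' from
#' the start codon.
#'
#' @param catalog a [GenomeCatalog-class].
#' @param ids gene ids (default: all).
#' @return `cdsSequences`: named `DNAStringSet`; `peptideSequences`: named
#'   `AAStringSet` (terminal stop removed, translation stops at the annotated
#'   CDS end).
#' @export
cdsSequences <- function(catalog, ids = geneIds(catalog)) {
    stopifnot(all(ids %in% names(catalog@cds)))
    seqs <- vapply(ids, function(id) {
        gr <- catalog@cds[[id]]
        gr <- gr[order(GenomicRanges::start(gr))]
        chrom <- as.character(GenomeInfoDb::seqnames(gr))[1]
        s <- paste(vapply(seq_along(gr), function(i) {
            as.character(Biostrings::subseq(catalog@sequences[[chrom]],
                                            GenomicRanges::start(gr)[i],
                                            GenomicRanges::end(gr)[i]))
        }, character(1)), collapse = "")
        if (as.character(GenomicRanges::strand(gr))[1] == "-") revcomp(s) else s
    }, character(1))
    Biostrings::DNAStringSet(setNames(seqs, ids))
}

#' @rdname cdsSequences
#' @export
peptideSequences <- function(catalog, ids = geneIds(catalog)) {
    cds <- cdsSequences(catalog, ids)
    peps <- vapply(as.character(cds), function(s) {
        p <- translateCds(s)
        sub("\\*$", "", p)
    }, character(1))
    Biostrings::AAStringSet(setNames(peps, ids))
}

#' Total length of the union of a set of intervals
#'
#' Support routine for every coverage computation: the size of the set union
#' of (possibly overlapping, unordered) intervals on one coordinate system.
#' Accepts 0-based half-open `[start, end)` pairs, matching the alignment
#' coordinate convention used in hit tables.
#'
#' @param starts,ends integer vectors, `starts[i] < ends[i]`.
#' @return total number of covered bases (0 for empty input).
#' @examples
#' intervalUnionLength(c(0, 30), c(40, 60))   # 60
#' intervalUnionLength(c(0, 10), c(10, 20))   # 20, half-open abutment merges
#' @export
intervalUnionLength <- function(starts, ends) {
    if (length(starts) == 0L) return(0L)
    if (length(starts) != length(ends) || any(ends <= starts))
        stop("intervals must satisfy start < end")
    ir <- IRanges::IRanges(start = as.integer(starts) + 1L,
                           end = as.integer(ends))
    sum(IRanges::width(IRanges::reduce(ir)))
}

# Merge 0-based half-open intervals; returns matrix with columns start, end.
mergeIntervals <- function(starts, ends) {
    if (!length(starts)) return(cbind(start = integer(), end = integer()))
    ir <- IRanges::reduce(IRanges::IRanges(as.integer(starts) + 1L,
                                           as.integer(ends)))
    cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Set difference a \ b of 0-based half-open interval sets.
subtractIntervals <- function(a_starts, a_ends, b_starts, b_ends) {
    a <- IRanges::IRanges(as.integer(a_starts) + 1L, as.integer(a_ends))
    b <- IRanges::IRanges(as.integer(b_starts) + 1L, as.integer(b_ends))
    d <- IRanges::setdiff(a, b)
    cbind(start = IRanges::start(d) - 1L, end = IRanges::end(d))
}

# Map positions in spliced CDS coordinates (0-based) to genomic bases
# (1-based) for one gene; vectorised over pos.
cdsPosToGenomic <- function(catalog, gene_id, pos) {
    gr <- catalog@cds[[gene_id]]
    gr <- gr[order(GenomicRanges::start(gr))]
    starts <- GenomicRanges::start(gr)
    ends <- GenomicRanges::end(gr)
    minus <- as.character(GenomicRanges::strand(gr))[1] == "-"
    # genomic position of every CDS base, in transcription order
    gpos <- unlist(lapply(seq_along(starts), function(i)
        starts[i]:ends[i]), use.names = FALSE)
    if (minus) gpos <- rev(gpos)
    out <- rep(NA_integer_, length(pos))
    ok <- pos >= 0L & pos < length(gpos)
    out[ok] <- gpos[pos[ok] + 1L]
    out
}

# Positions (0-based, spliced CDS coordinates) of internal intron-exon
# boundaries of a gene, i.e. cumulative segment lengths short of the total.
cdsBoundaryPositions <- function(catalog, gene_id) {
    gr <- catalog@cds[[gene_id]]
    if (length(gr) < 2L) return(integer())
    gr <- gr[order(GenomicRanges::start(gr))]
    w <- GenomicRanges::width(gr)
    if (as.character(GenomicRanges::strand(gr))[1] == "-") w <- rev(w)
    cumsum(w)[-length(w)]
}
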