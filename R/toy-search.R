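#' @importFrom Biostrings pairwiseAlignment score pattern subject
#'   alignedPattern alignedSubject nmatch nmismatch PDict matchPDict
#'   vwhichPDict
NULL

# Scoring parameters and Karlin-Altschul constants for the default scoring
# schemes (nucleotide: match +2 / mismatch -3 / gap open 5 / extend 2, the
# classic megablast-style scheme; peptide: BLOSUM62 with gap open 11 /
# extend 1). Lambda/K are the published gapped constants for these schemes;
# e-values are indicative, monotone in score, and only compared against
# coarse cutoffs (1e-3, 0.01).
.SEARCH_PARS <- list(
    nucleotide = list(gap_open = 5, gap_ext = 2, lambda = 0.625, K = 0.41,
                      seed_k = 12L, mask = "N"),
    peptide = list(gap_open = 11, gap_ext = 1, lambda = 0.267, K = 0.041,
                   seed_k = 5L, mask = "X")
)

.matCache <- new.env(parent = emptyenv())

searchMatrix <- function(mode) {
    if (!is.null(.matCache[[mode]])) return(.matCache[[mode]])
    if (mode == "nucleotide") {
        letters <- c("A", "C", "G", "T", "N")
        m <- matrix(-3, 5, 5, dimnames = list(letters, letters))
        diag(m) <- 2
        m["N", ] <- -1000; m[, "N"] <- -1000
    } else {
        data("BLOSUM62", package = "Biostrings", envir = environment())
        m <- BLOSUM62
        m["X", ] <- -1000; m[, "X"] <- -1000
        m["*", ] <- -1000; m[, "*"] <- -1000
    }
    .matCache[[mode]] <- m
    m
}

# One optimal local alignment of character strings q vs s; NULL if below
# min_score. Returns 0-based half-open coordinates on both sides.
swOnce <- function(q, s, mode, min_score) {
    pars <- .SEARCH_PARS[[mode]]
    aln <- Biostrings::pairwiseAlignment(
        q, s, type = "local", substitutionMatrix = searchMatrix(mode),
        gapOpening = pars$gap_open, gapExtension = pars$gap_ext)
    sc <- Biostrings::score(aln)
    if (sc < min_score) return(NULL)
    ap <- as.character(Biostrings::alignedPattern(aln)[[1]])
    as_ <- as.character(Biostrings::alignedSubject(aln)[[1]])
    ncol <- nchar(ap)
    gap_opens <- countGapOpens(ap) + countGapOpens(as_)
    list(score = sc,
         q_start = IRanges::start(Biostrings::pattern(aln)) - 1L,
         q_end = IRanges::end(Biostrings::pattern(aln)),
         s_start = IRanges::start(Biostrings::subject(aln)) - 1L,
         s_end = IRanges::end(Biostrings::subject(aln)),
         n_columns = ncol,
         nmatch = Biostrings::nmatch(aln),
         mismatches = Biostrings::nmismatch(aln),
         gap_opens = gap_opens)
}

countGapOpens <- function(x) {
    r <- rle(strsplit(x, "")[[1]] == "-")
    sum(r$values)
}

# All local alignments of q against s above min_score, found by iteratively
# masking the subject span of the best alignment and re-aligning.
swIterate <- function(q, s, mode, min_score, max_hits = 6L) {
    pars <- .SEARCH_PARS[[mode]]
    hits <- list()
    s_work <- s
    while (length(hits) < max_hits) {
        h <- swOnce(q, s_work, mode, min_score)
        if (is.null(h)) break
        hits[[length(hits) + 1L]] <- h
        substr(s_work, h$s_start + 1L, h$s_end) <-
            strrep(pars$mask, h$s_end - h$s_start)
    }
    hits
}

# Candidate windows on a long subject sharing a k-mer with the query,
# returned as 0-based half-open [start, end) intervals. `s_kmer_vec` is the
# vector of all subject k-mers in position order (precomputed once per
# subject by the caller).
seedWindows <- function(q, s_kmer_vec, s_len, k, margin) {
    nq <- nchar(q)
    if (nq < k || !length(s_kmer_vec)) return(NULL)
    kmers <- unique(substring(q, seq_len(nq - k + 1L),
                              seq_len(nq - k + 1L) + k - 1L))
    pos <- which(s_kmer_vec %in% kmers)
    if (!length(pos)) return(NULL)
    ir <- IRanges::reduce(IRanges::IRanges(pmax(1L, pos - nq - margin),
                                           pmin(s_len, pos + k + nq +
                                                           margin)))
    cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Toy local-alignment search
#'
#' Smith-Waterman local alignment of each query against each subject, used as
#' the stand-in search engine on synthetic data (external search tools are out
#' of scope). Alignment is exact dynamic programming (via
#' \pkg{Biostrings}); for subjects longer than `direct_limit` the search is
#' restricted to windows around exact k-mer seed matches (k = 12 for
#' nucleotide, 5 for peptide), which is a documented heuristic for
#' genome-scale subjects. Nucleotide mode searches both strands and reports
#' minus-strand alignments with `orientation = "inverted"`. E-values follow
#' the Karlin-Altschul form K m n exp(-lambda S) with the constants of the
#' default scoring (nucleotide +2/-3, gaps 5/2: lambda 0.625, K 0.41; peptide
#' BLOSUM62, gaps 11/1: lambda 0.267, K 0.041), with n the total subject
#' database length.
#'
#' @param query,subjects named character vectors or `XStringSet`s.
#' @param mode `"nucleotide"` or `"peptide"` (fixes the alphabet and scoring).
#' @param min_score minimum raw alignment score reported (default 30
#'   nucleotide, 40 peptide). Lower it to study weak alignments.
#' @param max_evalue keep hits with e-value at or below this (default 10).
#' @param max_hits_per_pair maximum HSPs reported per query:subject pair.
#' @param direct_limit subjects up to this length are aligned whole; longer
#'   ones through seed windows.
#' @param seed_filter when `TRUE` (default), query:subject pairs whose product
#'   of lengths exceeds `exact_limit` are only aligned if they share an exact
#'   k-mer; pairs at or below `exact_limit` are always aligned exactly, so
#'   small instances are guaranteed optimal.
#' @param exact_limit see `seed_filter` (default 1.2e4, covering all pairs of
#'   sequences up to about 100 x 100).
#' @return HSP data.frame in the [readHitTable()] layout, sorted by query,
#'   then e-value; also valid [writeHitTable()] input.
#' @examples
#' s <- c(sub1 = paste(rep("ACGTTGCA", 40), collapse = ""))
#' toySearch(c(q1 = s[[1]]), s, "nucleotide")[, c("q_start", "q_end")]
#' @export
toySearch <- function(query, subjects, mode = c("nucleotide", "peptide"),
                      min_score = NULL, max_evalue = 10,
                      max_hits_per_pair = 6L, direct_limit = 2000L,
                      seed_filter = TRUE, exact_limit = 1.2e4) {
    mode <- match.arg(mode)
    pars <- .SEARCH_PARS[[mode]]
    if (is.null(min_score)) min_score <- if (mode == "nucleotide") 30 else 40
    # as.character() strips names from plain character vectors: keep them
    q_chr <- if (is.character(query)) query else as.character(query)
    s_chr <- if (is.character(subjects)) subjects else as.character(subjects)
    if (is.null(names(q_chr)) || is.null(names(s_chr)))
        stop("queries and subjects must be named")
    alpha_pat <- if (mode == "nucleotide") "[^ACGTN]" else
        "[^ARNDCQEGHILKMFPSTWYVBZX*]"
    if (any(grepl(alpha_pat, q_chr)) || any(grepl(alpha_pat, s_chr)))
        stop("sequence alphabet does not match mode '", mode, "'")
    n_db <- sum(nchar(s_chr))
    rows <- list()

    strands <- if (mode == "nucleotide") c("forward", "inverted")
               else "forward"
    # subject k-mer vectors per strand: position-ordered for seed windows on
    # long subjects, unique sets for the pair prefilter (computed once)
    k <- pars$seed_k
    kmerVec <- function(x) {
        n <- nchar(x)
        if (n < k) return(character())
        substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    }
    s_rc <- if (mode == "nucleotide")
        vapply(s_chr, revcomp, character(1)) else NULL
    long_or_filter <- seed_filter | nchar(s_chr) > direct_limit
    s_kvec <- lapply(seq_along(s_chr), function(i)
        if (long_or_filter[i]) kmerVec(s_chr[[i]]) else character())
    s_kvec_rc <- if (!is.null(s_rc))
        lapply(seq_along(s_rc), function(i)
            if (long_or_filter[i]) kmerVec(s_rc[[i]]) else character())
    else NULL
    s_kmers <- lapply(s_kvec, unique)
    s_kmers_rc <- if (!is.null(s_kvec_rc)) lapply(s_kvec_rc, unique)
                  else NULL
    for (qi in seq_along(q_chr)) {
        qname <- names(q_chr)[qi]
        q_kmers <- if (seed_filter) unique(kmerVec(q_chr[[qi]])) else NULL
        for (strand in strands) {
            qcur <- q_chr[[qi]]
            scur_all <- if (strand == "inverted") s_rc else s_chr
            sk_all <- if (strand == "inverted") s_kmers_rc else s_kmers
            skv_all <- if (strand == "inverted") s_kvec_rc else s_kvec
            for (si in seq_along(scur_all)) {
                sname <- names(s_chr)[si]
                scur <- scur_all[[si]]
                nq <- nchar(qcur); ns <- nchar(scur)
                small <- nq * ns <= exact_limit
                if (ns <= direct_limit || small) {
                    if (seed_filter && !small &&
                        !(length(q_kmers) == 0L || length(sk_all[[si]]) == 0L ||
                          any(q_kmers %in% sk_all[[si]]))) next
                    hits <- swIterate(qcur, scur, mode, min_score,
                                      max_hits_per_pair)
                    off <- 0L
                } else {
                    if (mode != "nucleotide")
                        stop("long-subject seeding implemented for nucleotide mode only")
                    win <- seedWindows(qcur, skv_all[[si]], ns,
                                       pars$seed_k, margin = 50L)
                    if (is.null(win)) next
                    hits <- list(); offs <- integer()
                    for (w in seq_len(nrow(win))) {
                        sub_s <- substr(scur, win[w, 1] + 1L, win[w, 2])
                        hw <- swIterate(qcur, sub_s, mode, min_score,
                                        max_hits_per_pair)
                        offs <- c(offs, rep(win[w, 1], length(hw)))
                        hits <- c(hits, hw)
                    }
                    off <- offs
                }
                if (!length(hits)) next
                if (length(off) == 1L) off <- rep(off, length(hits))
                for (hi in seq_along(hits)) {
                    h <- hits[[hi]]
                    ss <- h$s_start + off[hi]; se <- h$s_end + off[hi]
                    if (strand == "inverted") {
                        tmp <- ss
                        ss <- nchar(s_chr[[si]]) - se
                        se <- nchar(s_chr[[si]]) - tmp
                    }
                    ev <- pars$K * nq * n_db * exp(-pars$lambda * h$score)
                    if (ev > max_evalue) next
                    rows[[length(rows) + 1L]] <- data.frame(
                        query_id = qname, subject_id = sname,
                        percent_identity = roundHalfUp(
                            100 * h$nmatch / h$n_columns),
                        n_columns = h$n_columns,
                        mismatches = h$mismatches,
                        gap_opens = h$gap_opens,
                        q_start = h$q_start, q_end = h$q_end,
                        s_start = ss, s_end = se,
                        orientation = strand,
                        e_value = ev, score = h$score,
                        stringsAsFactors = FALSE)
                }
            }
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else emptyHitTable()
    out <- out[order(out$query_id, out$e_value, -out$score, out$subject_id), ,
               drop = FALSE]
    rownames(out) <- NULL
    attr(out, "query_kind") <- if (mode == "peptide") "peptide" else
        "nucleotide"
    out
}
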