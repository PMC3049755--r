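# Nei-Gojobori (1986) pathway-counting dN/dS with Jukes-Cantor correction.

.dndsCache <- new.env(parent = emptyenv())

codonTable <- function() {
    if (is.null(.dndsCache$aa)) {
        g <- expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                         c("T", "C", "A", "G"), stringsAsFactors = FALSE)
        codons <- paste0(g[[1]], g[[2]], g[[3]])
        aa <- vapply(codons, function(cc)
            as.character(Biostrings::translate(Biostrings::DNAString(cc),
                                               no.init.codon = TRUE)),
            character(1))
        .dndsCache$aa <- setNames(unname(aa), codons)
    }
    .dndsCache$aa
}

codonAa <- function(codon) unname(codonTable()[codon])

# Expected numbers of synonymous sites per codon (stop-creating changes
# count as nonsynonymous, keeping S + N = 3 per codon); cached for all 64.
synSites <- function(codon) {
    if (is.null(.dndsCache$syn)) {
        tbl <- codonTable()
        syn <- vapply(names(tbl), function(cc) {
            b <- strsplit(cc, "")[[1]]
            s <- 0
            for (pos in 1:3) for (nt in c("A", "C", "G", "T")) {
                if (nt == b[pos]) next
                alt <- b; alt[pos] <- nt
                if (tbl[[paste(alt, collapse = "")]] == tbl[[cc]])
                    s <- s + 1 / 3
            }
            s
        }, numeric(1))
        .dndsCache$syn <- syn
    }
    unname(.dndsCache$syn[codon])
}

# Observed synonymous/nonsynonymous differences between two codons, averaged
# over all single-step mutational pathways that avoid stop codons (all
# pathways used if every one passes through a stop). Cached per codon pair.
codonDiffs <- function(c1, c2) {
    key <- paste0(c1, c2)
    hit <- .dndsCache[[key]]
    if (!is.null(hit)) return(hit)
    out <- codonDiffsUncached(c1, c2)
    .dndsCache[[key]] <- out
    out
}

codonDiffsUncached <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) return(c(sd = 0, nd = 0))
    perms <- permute(pos)
    acc <- matrix(NA_real_, nrow = length(perms), ncol = 2)
    for (pi in seq_along(perms)) {
        ord <- perms[[pi]]
        cur <- strsplit(c1, "")[[1]]
        tgt <- strsplit(c2, "")[[1]]
        sd <- 0; nd <- 0; valid <- TRUE
        for (p in ord) {
            prev <- paste(cur, collapse = "")
            cur[p] <- tgt[p]
            nxt <- paste(cur, collapse = "")
            if (nxt %in% GENETIC_STOPS && nxt != c2) { valid <- FALSE; break }
            if (identical(unname(codonAa(prev)), unname(codonAa(nxt))))
                sd <- sd + 1 else nd <- nd + 1
        }
        acc[pi, ] <- if (valid) c(sd, nd) else c(NA, NA)
    }
    ok <- !is.na(acc[, 1])
    if (!any(ok)) ok <- rep(TRUE, nrow(acc))  # all paths blocked: use all
    if (any(is.na(acc[ok, ]))) {              # recompute blocked paths fully
        for (pi in which(is.na(acc[, 1]))) {
            ord <- perms[[pi]]
            cur <- strsplit(c1, "")[[1]]
            tgt <- strsplit(c2, "")[[1]]
            sd <- 0; nd <- 0
            for (p in ord) {
                prev <- paste(cur, collapse = "")
                cur[p] <- tgt[p]
                nxt <- paste(cur, collapse = "")
                if (identical(unname(codonAa(prev)), unname(codonAa(nxt))))
                    sd <- sd + 1 else nd <- nd + 1
            }
            acc[pi, ] <- c(sd, nd)
        }
    }
    c(sd = mean(acc[ok, 1]), nd = mean(acc[ok, 2]))
}

permute <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x))
        for (rest in permute(x[-i]))
            out[[length(out) + 1L]] <- c(x[i], rest)
    out
}

#' Pairwise dN/dS by Nei-Gojobori (1986) pathway counting
#'
#' Expected synonymous/nonsynonymous site counts are averaged over both
#' sequences (mutations to stop codons count as nonsynonymous so sites sum
#' to three per codon); observed differences in multi-hit codons are averaged
#' over all orderings of single-step paths, excluding paths through stop
#' codons; proportions are Jukes-Cantor corrected, d = -3/4 log(1 - 4p/3).
#'
#' @param cds1,cds2 gap-free codon-aligned coding sequences (characters of
#'   equal length, multiple of 3; alignment columns with gaps must already be
#'   dropped codon-wise, e.g. by [alignCodonPair()]).
#' @return list with `N_sites`, `S_sites`, `Nd`, `Sd`, `pN`, `pS`, `dN`,
#'   `dS`, `ratio` (`NA` when `dS` is 0) and `saturated` (`TRUE` when a
#'   proportion reaches the Jukes-Cantor limit of 3/4, leaving the corrected
#'   distance undefined).
#' @examples
#' computeDnds("ATGAAA", "ATGAAG")$ratio   # synonymous only: 0
#' @export
computeDnds <- function(cds1, cds2) {
    cds1 <- toupper(as.character(cds1)); cds2 <- toupper(as.character(cds2))
    stopifnot(nchar(cds1) == nchar(cds2), nchar(cds1) %% 3 == 0,
              nchar(cds1) >= 3)
    if (grepl("-", cds1, fixed = TRUE) || grepl("-", cds2, fixed = TRUE))
        stop("sequences must be gap-free (drop gapped codons first)")
    co1 <- codonSplit(cds1); co2 <- codonSplit(cds2)
    S <- (sum(vapply(co1, synSites, numeric(1))) +
          sum(vapply(co2, synSites, numeric(1)))) / 2
    N <- 3 * length(co1) - S
    diffs <- vapply(seq_along(co1), function(i) codonDiffs(co1[i], co2[i]),
                    numeric(2))
    Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
    pS <- if (S > 0) Sd / S else 0
    pN <- if (N > 0) Nd / N else 0
    jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
    dS <- jc(pS); dN <- jc(pN)
    saturated <- pS >= 0.75 || pN >= 0.75
    # no nonsynonymous change at all pins the ratio at 0 whenever any
    # synonymous change occurred, even with very few synonymous sites
    ratio <- if (Nd == 0 && Sd > 0) 0
             else if (!saturated && !is.na(dS) && dS > 0) dN / dS
             else NA_real_
    list(N_sites = N, S_sites = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
         dN = dN, dS = dS, ratio = ratio, saturated = saturated)
}

#' Codon-aware pairwise alignment of two coding sequences
#'
#' Aligns the peptides globally and back-maps the alignment onto codons;
#' codon columns containing a gap are dropped, giving valid
#' [computeDnds()] input.
#'
#' @param cds1,cds2 coding sequences (terminal stop allowed; trimmed).
#' @return list of two equal-length gap-free codon sequences.
#' @export
alignCodonPair <- function(cds1, cds2) {
    trim <- function(x) {
        x <- as.character(x)
        n <- nchar(x) %/% 3 * 3
        x <- substr(x, 1, n)
        cods <- codonSplit(x)
        if (length(cods) && cods[length(cods)] %in% GENETIC_STOPS)
            x <- substr(x, 1, n - 3)
        x
    }
    c1 <- trim(cds1); c2 <- trim(cds2)
    p1 <- translateCds(c1); p2 <- translateCds(c2)
    aln <- Biostrings::pairwiseAlignment(
        p1, p2, type = "global", substitutionMatrix = searchMatrix("peptide"),
        gapOpening = 11, gapExtension = 1)
    a1 <- strsplit(as.character(Biostrings::alignedPattern(aln)[[1]]),
                   "")[[1]]
    a2 <- strsplit(as.character(Biostrings::alignedSubject(aln)[[1]]),
                   "")[[1]]
    co1 <- codonSplit(c1); co2 <- codonSplit(c2)
    i1 <- 0L; i2 <- 0L; o1 <- character(); o2 <- character()
    for (k in seq_along(a1)) {
        g1 <- a1[k] == "-"; g2 <- a2[k] == "-"
        if (!g1) i1 <- i1 + 1L
        if (!g2) i2 <- i2 + 1L
        if (!g1 && !g2) { o1 <- c(o1, co1[i1]); o2 <- c(o2, co2[i2]) }
    }
    list(cds1 = paste(o1, collapse = ""), cds2 = paste(o2, collapse = ""))
}

#' Compare dN/dS distributions between groups
#'
#' @param results list of [computeDnds()] results (or a numeric vector of
#'   ratios).
#' @param labels character vector of group labels, parallel to `results`.
#' @return data.frame per group: n pairs with a defined ratio, median ratio
#'   and semi-interquartile range (`NA` for empty groups).
#' @export
compareDndsGroups <- function(results, labels) {
    ratios <- if (is.numeric(results)) results
              else vapply(results, `[[`, numeric(1), "ratio")
    stopifnot(length(ratios) == length(labels))
    if (!length(labels))
        return(data.frame(group = character(), n = integer(),
                          median_ratio = numeric(), siqr = numeric(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, lapply(sort(unique(labels)), function(g) {
        v <- ratios[labels == g]
        v <- v[is.finite(v)]
        ms <- medianSiqr(v)
        data.frame(group = g, n = length(v),
                   median_ratio = unname(ms["median"]),
                   siqr = unname(ms["siqr"]), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}
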