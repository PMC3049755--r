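#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges GRangesList
#' @importFrom Biostrings DNAStringSet DNAString AAStringSet translate
#'   reverseComplement readDNAStringSet writeXStringSet subseq
#' @importFrom stats phyper p.adjust t.test median quantile rbinom rnorm runif
#'   rexp setNames aggregate ave
#' @importFrom utils read.table write.table head tail
NULL

GENETIC_STOPS <- c("TAA", "TAG", "TGA")

#' Round half away from zero
#'
#' Percentages in reports are rounded half-away-from-zero to a fixed number of
#' decimals, matching the usual printed style, rather than using banker's
#' rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage share with explicit numerator and denominator
#'
#' @param k numerator count.
#' @param n denominator count.
#' @param digits decimal places.
#' @return percentage rounded half away from zero; `NA` when `n` is 0 (an
#'   empty group is not-applicable, never 0).
#' @export
pctShare <- function(k, n, digits = 2) {
    out <- rep(NA_real_, length(k))
    ok <- n > 0
    out[ok] <- roundHalfUp(100 * k[ok] / n[ok], digits)
    out
}

# Semi-interquartile range (Q3 - Q1) / 2, type-7 quantiles.
siqr <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(NA_real_)
    unname(diff(quantile(x, c(0.25, 0.75)))) / 2
}

# Median +/- SIQR as a two-element named vector; NA for empty groups.
medianSiqr <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(c(median = NA_real_, siqr = NA_real_))
    c(median = median(x), siqr = siqr(x))
}

# Evaluate `expr` under a local RNG state seeded from `seed`.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# Deterministic child seed for a named sub-generator, kept below 2^31.
childSeed <- function(seed, what) {
    h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
    (as.integer(seed) * 131L + as.integer(h %% 1000003L)) %% 2000000011L
}

# Translate a DNA character string (codon-complete prefix) to peptide.
# Codon-table lookup (standard code); unknown/ambiguous codons become X.
translateCds <- function(x) {
    n <- nchar(x) %/% 3L
    if (n == 0L) return("")
    aa <- codonTable()[substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
}

# Split a DNA character string into codon strings.
codonSplit <- function(x) {
    n <- nchar(x) %/% 3L
    if (n == 0L) return(character())
    substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Random DNA of length n.
randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Deterministic TSV writer (tab-separated, no quoting, unix newlines).
writeTsv <- function(df, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n")
    invisible(path)
}

readTsv <- function(path, ...) {
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               quote = "", comment.char = "", ...)
}
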