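# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force affine-gap Smith-Waterman score (gap of length L costs
# open + L * ext).
bruteSwScore <- function(q, s, mat = 2, mis = -3, open = 5, ext = 2) {
    qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
    n <- length(qv); m <- length(sv)
    M <- matrix(0, n + 1, m + 1)
    E <- matrix(-Inf, n + 1, m + 1)
    F <- matrix(-Inf, n + 1, m + 1)
    best <- 0
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
        E[i, j] <- max(M[i, j - 1] - open - ext, E[i, j - 1] - ext)
        F[i, j] <- max(M[i - 1, j] - open - ext, F[i - 1, j] - ext)
        sc <- if (qv[i - 1] == sv[j - 1]) mat else mis
        M[i, j] <- max(0, M[i - 1, j - 1] + sc, E[i, j], F[i, j])
        best <- max(best, M[i, j])
    }
    best
}

# Per-base membership count of an interval union (0-based half-open).
bruteUnionLength <- function(starts, ends) {
    if (!length(starts)) return(0L)
    covered <- logical(max(ends))
    for (i in seq_along(starts))
        covered[(starts[i] + 1):ends[i]] <- TRUE
    sum(covered)
}

# Exhaustive hypergeometric upper tail via combinatorial counting.
enumHyperUpper <- function(k, K, n, N) {
    j <- k:min(K, n)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Translate a DNA string and report 1-based codon indices of stop codons.
translateScan <- function(x) {
    n <- nchar(x) %/% 3
    cods <- substring(x, 3 * seq_len(n) - 2, 3 * seq_len(n))
    which(cods %in% c("TAA", "TAG", "TGA"))
}

randomDnaStr <- function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

rcStr <- function(x)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
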