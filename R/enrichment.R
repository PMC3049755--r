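#' Hypergeometric tail probability for set enrichment
#'
#' For a population of `N` genes of which `K` carry a property, and a drawn
#' set of `n` genes containing `k` carriers, the upper tail returns
#' P(X >= k) and the lower tail P(X <= k) for X ~ Hypergeometric(N, K, n).
#' Computed through the log-space-stable distribution function.
#'
#' @param k observed carriers in the drawn set.
#' @param K carriers in the population.
#' @param n drawn set size.
#' @param N population size.
#' @param tail `"upper"` (enrichment) or `"lower"` (depletion).
#' @return p-value in [0, 1].
#' @examples
#' hypergeometricEnrichment(3, 4, 5, 10)          # 66/252
#' hypergeometricEnrichment(0, 4, 5, 10)          # 1
#' @export
hypergeometricEnrichment <- function(k, K, n, N,
                                     tail = c("upper", "lower")) {
    tail <- match.arg(tail)
    if (K > N || n > N || k < 0 || k > min(K, n))
        stop("inconsistent counts: need 0 <= k <= min(K, n), K <= N, n <= N")
    if (tail == "upper")
        exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
    else
        exp(phyper(k, K, N - K, n, lower.tail = TRUE, log.p = TRUE))
}
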