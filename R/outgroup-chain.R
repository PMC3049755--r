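#' Chain scaffold hits of one LSG into a candidate outgroup region
#'
#' Significant hits (e-value below `within_genome_evalue`) on the same
#' scaffold as the top-scoring hit are clustered by single linkage with a gap
#' of at most `scaffold_chain_gap_bp`; the cluster containing the top hit is
#' returned, its region spanning the two most extreme coordinates of its
#' hits. No hits is an empty result (a candidate de novo / differential-loss
#' signal), not an error.
#'
#' @param hits nucleotide HSP data.frame of one LSG against outgroup
#'   scaffolds (`subject_id` = scaffold).
#' @param thresholds a [ThresholdConfig-class].
#' @return `NULL` when no significant hit, else a list with `scaffold`,
#'   `region_start`, `region_end` (0-based half-open), `orientation` (of the
#'   top hit), `n_hits` (hits in the chosen cluster) and `top_score`.
#' @export
chainScaffoldHits <- function(hits, thresholds = thresholdConfig()) {
    hits <- hits[hits$e_value < thresholds@within_genome_evalue, ,
                 drop = FALSE]
    if (!nrow(hits)) return(NULL)
    top <- hits[order(-hits$score, hits$e_value, hits$subject_id,
                      hits$s_start), ][1, ]
    same <- hits[hits$subject_id == top$subject_id, , drop = FALSE]
    same <- same[order(same$s_start, same$s_end), , drop = FALSE]
    gap <- thresholds@scaffold_chain_gap_bp
    cl <- integer(nrow(same)); cur <- 1L; max_end <- same$s_end[1]
    cl[1] <- 1L
    for (i in seq_len(nrow(same))[-1]) {
        if (same$s_start[i] - max_end > gap) {
            cur <- cur + 1L
            max_end <- same$s_end[i]
        } else {
            max_end <- max(max_end, same$s_end[i])
        }
        cl[i] <- cur
    }
    top_row <- which(same$s_start == top$s_start & same$s_end == top$s_end &
                     same$score == top$score)[1]
    chosen <- same[cl == cl[top_row], , drop = FALSE]
    list(scaffold = top$subject_id,
         region_start = min(chosen$s_start),
         region_end = max(chosen$s_end),
         orientation = top$orientation,
         n_hits = nrow(chosen),
         top_score = top$score)
}
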