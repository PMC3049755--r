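#' Detect chimeric gene structure from non-overlapping evidence
#'
#' A gene is chimeric when at least two evidence items - merged hits to
#' different parent genes, TE overlaps mapped to query coordinates, or a CDS
#' overlap - occupy query regions that overlap each other by at most 10
#' percent of the shorter region, and (for parent:parent combinations) the
#' parents are mutually non-homologous. The 10 percent bound quantifies
#' "non-overlapping": the evidence segments must concern different parts of
#' the gene.
#'
#' @param evidence data.frame with one row per evidence item: `gene_id`,
#'   `type` (`"parent"`, `"te"` or `"overlap"`), `feature_id` (parent gene,
#'   TE id or overlapping gene), `q_start`, `q_end` (0-based half-open query
#'   coordinates; nucleotide space).
#' @param parent_homology optional data.frame `gene_a`, `gene_b` listing
#'   parent candidates that hit each other (peptide level, e < 0.01); pairs
#'   present here never jointly support chimerism.
#' @param max_mutual_overlap maximum fraction of the shorter region that two
#'   supporting items may share (default 0.10).
#' @return data.frame with one row per chimeric gene: `gene_id`,
#'   `composition` (`multi_parent`, `parent_te`, `overlap_parent`,
#'   `overlap_te`, or combinations joined by `+`), `n_items`, `features`
#'   (comma-separated feature ids of the supporting disjoint items).
#' @export
detectChimeric <- function(evidence, parent_homology = NULL,
                           max_mutual_overlap = 0.10) {
    out <- list()
    hom <- if (!is.null(parent_homology) && nrow(parent_homology))
        paste(pmin(parent_homology$gene_a, parent_homology$gene_b),
              pmax(parent_homology$gene_a, parent_homology$gene_b),
              sep = "\r") else character()
    for (g in unique(evidence$gene_id)) {
        ev <- evidence[evidence$gene_id == g, , drop = FALSE]
        if (nrow(ev) < 2) next
        # collapse multiple items of the same feature to their merged span
        keyf <- paste(ev$type, ev$feature_id)
        ev <- do.call(rbind, lapply(unique(keyf), function(k) {
            sub <- ev[keyf == k, , drop = FALSE]
            sub$q_start[1] <- min(sub$q_start); sub$q_end[1] <- max(sub$q_end)
            sub[1, , drop = FALSE]
        }))
        if (nrow(ev) < 2) next
        supporting <- NULL
        for (i in seq_len(nrow(ev) - 1)) for (j in (i + 1):nrow(ev)) {
            ov <- min(ev$q_end[i], ev$q_end[j]) -
                  max(ev$q_start[i], ev$q_start[j])
            shorter <- min(ev$q_end[i] - ev$q_start[i],
                           ev$q_end[j] - ev$q_start[j])
            if (ov > max_mutual_overlap * shorter) next
            if (ev$type[i] == "parent" && ev$type[j] == "parent") {
                k <- paste(min(ev$feature_id[i], ev$feature_id[j]),
                           max(ev$feature_id[i], ev$feature_id[j]),
                           sep = "\r")
                if (k %in% hom) next
            }
            supporting <- rbind(supporting, ev[c(i, j), ])
        }
        if (is.null(supporting)) next
        supporting <- unique(supporting)
        types <- sort(unique(supporting$type))
        comp <- character()
        if (sum(supporting$type == "parent") >= 2)
            comp <- c(comp, "multi_parent")
        if (all(c("parent", "te") %in% types)) comp <- c(comp, "parent_te")
        if (all(c("overlap", "parent") %in% types))
            comp <- c(comp, "overlap_parent")
        if (all(c("overlap", "te") %in% types)) comp <- c(comp, "overlap_te")
        if (!length(comp)) next
        out[[g]] <- data.frame(
            gene_id = g,
            composition = paste(comp, collapse = "+"),
            n_items = nrow(supporting),
            features = paste(sort(unique(supporting$feature_id)),
                             collapse = ","),
            stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(gene_id = character(), composition = character(),
                          n_items = integer(), features = character(),
                          stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
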