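#' Collapse replicate present/absent calls to per-tissue presence
#'
#' A gene is present in a tissue/developmental stage when it is called
#' present in any replicate of that tissue; expression breadth is the number
#' of present tissues. The collapse is an OR, hence idempotent and
#' replicate-order invariant.
#'
#' @param calls logical matrix, genes x samples.
#' @param samples data.frame with `sample_id`, `tissue` (and optionally
#'   `replicate`) matching `colnames(calls)`.
#' @return list with `presence` (genes x tissues logical matrix) and
#'   `breadth` (named integer vector).
#' @export
collapseCalls <- function(calls, samples) {
    stopifnot(is.logical(calls), all(colnames(calls) %in% samples$sample_id))
    tissue <- samples$tissue[match(colnames(calls), samples$sample_id)]
    tissues <- unique(tissue)
    presence <- vapply(tissues, function(tt)
        rowSums(calls[, tissue == tt, drop = FALSE]) > 0,
        logical(nrow(calls)))
    colnames(presence) <- tissues
    list(presence = presence, breadth = rowSums(presence))
}

#' Compare expression breadth between LSGs and non-LSGs
#'
#' @param breadth named integer vector (genes).
#' @param lsg_labels logical vector parallel to `breadth` (`TRUE` = LSG).
#' @param low_breadth_at thresholds b at which the share expressed in at most
#'   b tissues is reported (default 0:8).
#' @return list with `summary` (per group: n, median breadth, SIQR) and
#'   `low_breadth` (group, b, share_pct expressed in <= b tissues).
#' @export
breadthComparison <- function(breadth, lsg_labels, low_breadth_at = 0:8) {
    stopifnot(length(breadth) == length(lsg_labels))
    groups <- list(LSG = breadth[lsg_labels], nonLSG = breadth[!lsg_labels])
    summary <- do.call(rbind, lapply(names(groups), function(g) {
        ms <- medianSiqr(groups[[g]])
        data.frame(group = g, n = length(groups[[g]]),
                   median_breadth = unname(ms["median"]),
                   siqr = unname(ms["siqr"]), stringsAsFactors = FALSE)
    }))
    low <- do.call(rbind, lapply(names(groups), function(g) {
        data.frame(group = g, b = low_breadth_at,
                   share_pct = pctShare(
                       vapply(low_breadth_at, function(b)
                           sum(groups[[g]] <= b), integer(1)),
                       rep(length(groups[[g]]), length(low_breadth_at))),
                   stringsAsFactors = FALSE)
    }))
    rownames(summary) <- rownames(low) <- NULL
    list(summary = summary, low_breadth = low)
}

#' Per-tissue expression level distributions of present genes
#'
#' For each tissue, the per-gene median (over replicates) log2 expression is
#' summarised per group, restricted to genes called present in that tissue.
#'
#' @param expr numeric matrix, genes x samples (log2 scale).
#' @param samples sample metadata as in [collapseCalls()].
#' @param presence genes x tissues logical matrix from [collapseCalls()].
#' @param lsg_labels logical vector per gene.
#' @return data.frame tissue, group, n present, median expression, SIQR
#'   (`NA` entries for tissues with no present genes in a group).
#' @export
expressionDistributions <- function(expr, samples, presence, lsg_labels) {
    tissue <- samples$tissue[match(colnames(expr), samples$sample_id)]
    rows <- list()
    for (tt in colnames(presence)) {
        med <- apply(expr[, tissue == tt, drop = FALSE], 1, median)
        for (g in c("LSG", "nonLSG")) {
            sel <- presence[, tt] & (if (g == "LSG") lsg_labels
                                     else !lsg_labels)
            ms <- medianSiqr(med[sel])
            rows[[length(rows) + 1L]] <- data.frame(
                tissue = tt, group = g, n_present = sum(sel),
                median_expression = unname(ms["median"]),
                siqr = unname(ms["siqr"]), stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Call differentially expressed gene sets for one contrast
#'
#' Table mode takes a supplied per-contrast table (gene, log2fc, adjusted p)
#' as produced by a moderated model; raw mode computes an unpaired two-sample
#' t statistic per gene from treatment/control replicate matrices with
#' Benjamini-Hochberg adjustment (an explicit stand-in; users with real data
#' should supply DE tables). "Fold change > log2(1.5)" is read as |log2 fold
#' change| above the threshold, sign giving direction, so up and down sets
#' are disjoint.
#'
#' @param de_table data.frame `gene_id`, `log2fc`, `adj_p` (table mode), or
#'   `NULL` for raw mode.
#' @param treatment,control numeric matrices (genes x replicates) for raw
#'   mode.
#' @param thresholds a [ThresholdConfig-class].
#' @return list with `up`, `down` (character vectors) and `table` (the
#'   thresholded table actually used).
#' @export
callDe <- function(de_table = NULL, treatment = NULL, control = NULL,
                   thresholds = thresholdConfig()) {
    if (is.null(de_table)) {
        stopifnot(!is.null(treatment), !is.null(control),
                  nrow(treatment) == nrow(control))
        p <- vapply(seq_len(nrow(treatment)), function(i)
            tryCatch(t.test(treatment[i, ], control[i, ])$p.value,
                     error = function(e) 1), numeric(1))
        de_table <- data.frame(
            gene_id = rownames(treatment),
            log2fc = rowMeans(treatment) - rowMeans(control),
            adj_p = p.adjust(p, method = "BH"),
            stringsAsFactors = FALSE)
    }
    if (!all(c("gene_id", "log2fc", "adj_p") %in% names(de_table)))
        stop("DE table must have columns gene_id, log2fc, adj_p")
    up <- de_table$gene_id[de_table$adj_p < thresholds@de_adj_p &
                           de_table$log2fc > thresholds@de_min_abs_log2fc]
    down <- de_table$gene_id[de_table$adj_p < thresholds@de_adj_p &
                             de_table$log2fc < -thresholds@de_min_abs_log2fc]
    list(up = up, down = down, table = de_table)
}

#' Hypergeometric enrichment of LSGs among responsive genes
#'
#' One result per (contrast, direction): with N tested genes of which K are
#' LSGs, and n differentially expressed genes containing k LSGs, the upper
#' hypergeometric tail is reported, flagged enriched below `enrichment_p`.
#' Raw p-values are reported (matching per-contrast threshold behaviour); a
#' BH-adjusted column across contrasts is added for reference.
#'
#' @param de_sets named list per contrast: list(up = ids, down = ids).
#' @param universe character vector of tested genes (or named list per
#'   contrast).
#' @param lsg_ids LSG gene ids.
#' @param thresholds a [ThresholdConfig-class].
#' @return data.frame contrast, direction, k, K, n, N, p_value, adj_p,
#'   enriched; attribute `lsg_de_overlap` gives the up/down/intersection
#'   counts of responsive LSGs across all contrasts.
#' @export
lsgStressEnrichment <- function(de_sets, universe, lsg_ids,
                                thresholds = thresholdConfig()) {
    rows <- list()
    for (ct in names(de_sets)) {
        uni <- if (is.list(universe)) universe[[ct]] else universe
        K <- length(intersect(lsg_ids, uni))
        N <- length(uni)
        for (dir in c("up", "down")) {
            if (length(de_sets[[ct]][[dir]]) > N)
                stop("DE set larger than tested universe")
            de <- intersect(de_sets[[ct]][[dir]], uni)
            k <- length(intersect(de, lsg_ids))
            p <- hypergeometricEnrichment(k, K, length(de), N, "upper")
            rows[[length(rows) + 1L]] <- data.frame(
                contrast = ct, direction = dir, k = k, K = K,
                n = length(de), N = N, p_value = p,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    out$adj_p <- p.adjust(out$p_value, method = "BH")
    out$enriched <- out$p_value < thresholds@enrichment_p
    rownames(out) <- NULL
    up_all <- unique(unlist(lapply(de_sets, function(x)
        intersect(x$up, lsg_ids))))
    down_all <- unique(unlist(lapply(de_sets, function(x)
        intersect(x$down, lsg_ids))))
    attr(out, "lsg_de_overlap") <- c(up = length(up_all),
                                     down = length(down_all),
                                     both = length(intersect(up_all,
                                                             down_all)))
    out
}
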