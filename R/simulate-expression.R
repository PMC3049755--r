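#' Generate expression matrices, presence calls and DE contrast tables
#'
#' Emulates the expression signatures of lineage-specific genes: LSG-like
#' genes are present in few tissues (breadth drawn binomially around
#' `lsg_breadth_mean`, versus `nonlsg_breadth_mean` for conserved genes, so
#' group medians match the configured means), expressed at a lower level
#' (log2 values shifted by `lsg_expr_shift`), and over-represented among
#' up-regulated genes of stress contrasts with odds
#' `planted_enrichment_odds` (odds 1 plants no signal). Per-contrast DE
#' tables (gene, log2 fold change, adjusted p) are emitted directly, the
#' moderated model that would produce them being out of scope.
#'
#' @param labels data.frame with `gene_id` and `class`
#'   (`lsg_like`/`conserved_like`).
#' @param expression named numeric vector of expression parameters (see
#'   [ScenarioConfig-class]).
#' @param seed integer seed.
#' @return list with `expr` (genes x samples log2 matrix), `calls` (logical
#'   matrix), `samples` (sample metadata), `de_tables` (named list per
#'   contrast), `de_truth` (planted DE membership per contrast).
#' @export
generateExpression <- function(labels, expression, seed = 1L) {
    pars <- expression
    n_rep <- as.integer(pars[["n_replicates"]])
    if (n_rep < 2L)
        stop("the present/absent call rule needs at least 2 replicates")
    n_tis <- as.integer(pars[["n_tissues"]])
    withSeed(childSeed(seed, "expression"), {
        genes <- labels$gene_id
        is_lsg <- labels$class == "lsg_like"
        n <- length(genes)
        tissues <- sprintf("tissue%02d", seq_len(n_tis))
        samples <- data.frame(
            sample_id = paste0(rep(tissues, each = n_rep), "_r",
                               rep(seq_len(n_rep), n_tis)),
            tissue = rep(tissues, each = n_rep),
            replicate = rep(seq_len(n_rep), n_tis),
            stringsAsFactors = FALSE)
        p_lsg <- min(1, pars[["lsg_breadth_mean"]] / n_tis)
        p_non <- min(1, pars[["nonlsg_breadth_mean"]] / n_tis)
        breadth <- ifelse(is_lsg, rbinom(n, n_tis, p_lsg),
                          rbinom(n, n_tis, p_non))
        present <- matrix(FALSE, n, n_tis, dimnames = list(genes, tissues))
        for (i in seq_len(n))
            if (breadth[i] > 0)
                present[i, sample(n_tis, breadth[i])] <- TRUE
        # replicate-level calls: present tissues have each replicate called
        # with probability 0.8, at least one guaranteed
        calls <- matrix(FALSE, n, nrow(samples),
                        dimnames = list(genes, samples$sample_id))
        for (tt in tissues) {
            cols <- samples$sample_id[samples$tissue == tt]
            rep_calls <- matrix(runif(n * n_rep) < 0.8, n, n_rep)
            none <- rowSums(rep_calls) == 0L
            rep_calls[cbind(which(none), sample(n_rep, sum(none),
                                                replace = TRUE))] <- TRUE
            rep_calls[!present[, tt], ] <- FALSE
            calls[, cols] <- rep_calls
        }
        base <- rnorm(n, 8, 0.8) + ifelse(is_lsg,
                                          pars[["lsg_expr_shift"]], 0)
        expr <- matrix(rnorm(n * nrow(samples), 0, 0.3), n, nrow(samples),
                       dimnames = list(genes, samples$sample_id)) + base
        expr[!calls] <- matrix(rnorm(sum(!calls), 3, 0.5))
        # stress contrasts: DE membership drawn with planted odds for LSGs
        n_ct <- as.integer(pars[["n_stress_contrasts"]])
        odds <- pars[["planted_enrichment_odds"]]
        de_tables <- list(); de_truth <- list()
        for (ct in seq_len(n_ct)) {
            ct_id <- sprintf("stress%02d", ct)
            n_de <- max(5L, round(0.08 * n))
            w <- ifelse(is_lsg, odds, 1)
            up <- sample(genes, n_de, prob = w)
            down <- sample(setdiff(genes, up), n_de)
            lfc <- rep(0, n); names(lfc) <- genes
            adjp <- runif(n, 0.05, 1); names(adjp) <- genes
            lfc[up] <- log2(1.5) + rexp(length(up), 2)
            lfc[down] <- -(log2(1.5) + rexp(length(down), 2))
            adjp[c(up, down)] <- runif(length(up) + length(down), 0, 0.009)
            de_tables[[ct_id]] <- data.frame(gene_id = genes,
                                             log2fc = unname(lfc[genes]),
                                             adj_p = unname(adjp[genes]),
                                             stringsAsFactors = FALSE)
            de_truth[[ct_id]] <- list(up = up, down = down)
        }
        list(expr = expr, calls = calls, samples = samples,
             de_tables = de_tables, de_truth = de_truth)
    })
}

# Scenario wrapper: expression for the assembled catalog's genes.
simExpression <- function(sim) {
    labels <- data.frame(gene_id = sim$truth$gene_id,
                         class = sim$truth$expression_class,
                         stringsAsFactors = FALSE)
    sim$expression <- generateExpression(labels, sim$config@expression,
                                         seed = sim$config@seed)
    sim
}
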