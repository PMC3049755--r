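# Synthesis of the cross-lineage database tier hit tables, taxon labels and
# domain annotations. Searching real out-of-lineage databases is out of
# scope, so the tier tables are constructed from ground truth: every
# conserved background gene is given eliminating hits at a chosen tier (most
# at the peptide tier, some only at later tiers, a couple only through a
# cross-lineage domain flag), planted lineage-specific genes get no
# out-of-lineage hits but may carry within-lineage decoy hits and borderline
# (non-significant) out-of-lineage hits.

.OUT_TAXA <- c("Distantia prima", "Distantia altera", "Remota tertia")
.LINEAGE_TAXA <- c("Focala focalis", "Focala soror")

simTierHits <- function(sim) {
    config <- sim$config
    withSeed(childSeed(config@seed, "tiers"), {
        truth <- sim$truth
        genes <- truth$gene_id
        conserved <- genes[truth$class == "background"]
        lsg <- genes[truth$class != "background"]
        tiers <- c("peptide-db", "nucleotide-db", "est-db",
                   "position-specific")
        rows <- setNames(lapply(tiers, function(x) list()), tiers)
        taxa_rows <- list()
        sid <- 0L
        addHit <- function(tier, g, taxon, evalue) {
            sid <<- sid + 1L
            subj <- sprintf("db|s%04d", sid)
            taxa_rows[[length(taxa_rows) + 1L]] <<- data.frame(
                subject_id = subj, taxon = taxon, stringsAsFactors = FALSE)
            qs <- sample(1:40, 1); qe <- qs + sample(60:200, 1)
            rows[[tier]][[length(rows[[tier]]) + 1L]] <<- data.frame(
                query_id = g, subject_id = subj,
                percent_identity = roundHalfUp(runif(1, 35, 95)),
                n_columns = qe - qs + 1L, mismatches = sample(0:30, 1),
                gap_opens = sample(0:3, 1),
                q_start = qs - 1L, q_end = qe,
                s_start = 0L, s_end = qe - qs + 1L,
                orientation = "forward",
                e_value = evalue, score = round(runif(1, 50, 300)),
                stringsAsFactors = FALSE)
        }
        # eliminating tier per conserved gene
        elim <- sample(c(tiers, "domain-scan"), length(conserved),
                       replace = TRUE,
                       prob = c(0.70, 0.15, 0.08, 0.04, 0.03))
        names(elim) <- conserved
        domain_rows <- list()
        for (g in conserved) {
            if (elim[[g]] == "domain-scan") {
                domain_rows[[length(domain_rows) + 1L]] <- data.frame(
                    gene_id = g, domain_id = "IPR_cross", cross_lineage = TRUE,
                    stringsAsFactors = FALSE)
                next
            }
            for (h in seq_len(sample(1:3, 1)))
                addHit(elim[[g]], g, sample(.OUT_TAXA, 1),
                       10^-runif(1, 4, 60))
            # borderline out-of-lineage hit in an earlier tier for some genes
            if (runif(1) < 0.15)
                addHit(tiers[1], g, sample(.OUT_TAXA, 1),
                       10^runif(1, -2.5, -0.5))
        }
        # within-lineage decoys and cross-lineage borderline hits for LSGs
        for (g in sample(lsg, ceiling(length(lsg) / 3))) {
            addHit(sample(tiers, 1), g, sample(.LINEAGE_TAXA, 1),
                   10^-runif(1, 5, 40))
            if (runif(1) < 0.3)
                addHit(tiers[1], g, sample(.OUT_TAXA, 1),
                       10^runif(1, -2.5, -0.5))
        }
        # lineage-restricted domains on a few LSGs (must not eliminate)
        for (g in sample(lsg, min(4L, length(lsg))))
            domain_rows[[length(domain_rows) + 1L]] <- data.frame(
                gene_id = g, domain_id = "IPR_lineage",
                cross_lineage = FALSE, stringsAsFactors = FALSE)
        sim$hit_tiers <- lapply(rows, function(r)
            if (length(r)) do.call(rbind, r) else emptyHitTable())
        sim$subject_taxa <- if (length(taxa_rows)) do.call(rbind, taxa_rows)
            else data.frame(subject_id = character(), taxon = character(),
                            stringsAsFactors = FALSE)
        sim$domains <- if (length(domain_rows)) do.call(rbind, domain_rows)
            else data.frame(gene_id = character(), domain_id = character(),
                            cross_lineage = logical(),
                            stringsAsFactors = FALSE)
        sim$lineage_taxa <- .LINEAGE_TAXA
        sim
    })
}
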