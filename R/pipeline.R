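# End-to-end orchestration: catalog -> origin -> outgroup -> polymorphism ->
# expression, with a machine-readable summary.

# Map a genomic interval to the spliced-CDS interval (0-based half-open) of
# one gene; NULL when it misses the CDS.
genomicToCdsInterval <- function(catalog, gene_id, gstart, gend) {
    n <- sum(GenomicRanges::width(catalog@cds[[gene_id]]))
    gp <- cdsPosToGenomic(catalog, gene_id, seq_len(n) - 1L)
    inside <- which(gp >= gstart & gp <= gend)
    if (!length(inside)) return(NULL)
    c(start = min(inside) - 1L, end = max(inside))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order on either a synthetic scenario
#' (pass a [ScenarioConfig-class]) or a prepared simulation state: step-wise
#' LSG filtering over the tier hit tables, lineage-level assignment against
#' the outgroup proteome, compartment summary, within-genome duplication
#' analysis (peptide + CDS searches, HSP merging, frame/orientation,
#' mechanism and context), TE exaptation, overlapping-CDS/overprinting,
#' chimera detection, outgroup scaffold chaining and ORF projection,
#' reciprocal-best-hit dN/dS, accession ISC/MSC calls with outgroup
#' cross-referencing, and expression breadth / stress enrichment. When
#' ground truth is available the summary carries recovery metrics.
#'
#' @param scenario a [ScenarioConfig-class] or the result of
#'   [simulateScenario()].
#' @param thresholds a [ThresholdConfig-class].
#' @param out_dir optional directory for reports (see [renderReports()]).
#' @param max_dnds_background cap on background RBH pairs used for the dN/dS
#'   comparison (keeps runtime proportionate).
#' @return a result bundle (list) with per-stage tables and `summary` (the
#'   machine-readable rollup).
#' @export
runPipeline <- function(scenario, thresholds = thresholdConfig(),
                        out_dir = NULL, max_dnds_background = 50L) {
    sim <- if (is(scenario, "ScenarioConfig")) simulateScenario(scenario)
           else scenario
    catalog <- sim$catalog
    genes <- geneModels(catalog)
    gene_ids <- genes$gene_id[!genes$is_te_gene]

    ## stage 1: LSG catalog ------------------------------------------------
    records <- stepwiseFilter(gene_ids, sim$hit_tiers, sim$subject_taxa,
                              sim$lineage_taxa, sim$domains, thresholds)
    lsg_ids <- records$gene_id[records$is_lsg]
    nonlsg_ids <- setdiff(gene_ids, lsg_ids)

    ## stage 2: lineage level against the outgroup proteome ----------------
    lsg_pep <- peptideSequences(catalog, lsg_ids)
    og_pep <- peptideSequences(sim$outgroup)
    og_pep_hits <- toySearch(lsg_pep, og_pep, mode = "peptide")
    pep_len <- setNames(nchar(as.character(lsg_pep)), lsg_ids)
    records <- assignLineageLevel(records, og_pep_hits, pep_len, thresholds)
    species_only <- records$gene_id[records$is_lsg &
                                    records$lineage_level == "species_only"]
    compartments <- compartmentSummary(records, genes)

    ## stage 3: overlapping CDS / overprinting ------------------------------
    overlaps <- findOverlappingCds(catalog, lsg_ids)
    lsg_nonlsg <- overlaps[overlaps$pair_type == "LSG:nonLSG", , drop = FALSE]
    overprint_ids <- intersect(unique(c(lsg_nonlsg$gene_a,
                                        lsg_nonlsg$gene_b)), lsg_ids)
    overlap_partner <- list()
    for (i in seq_len(nrow(overlaps))) {
        a <- overlaps$gene_a[i]; b <- overlaps$gene_b[i]
        overlap_partner[[a]] <- c(overlap_partner[[a]], b)
        overlap_partner[[b]] <- c(overlap_partner[[b]], a)
    }

    ## stage 4: within-genome duplication analysis --------------------------
    lsg_cds <- cdsSequences(catalog, lsg_ids)
    nonlsg_cds <- cdsSequences(catalog, nonlsg_ids)
    nonlsg_pep <- peptideSequences(catalog, nonlsg_ids)
    cds_len <- setNames(nchar(as.character(lsg_cds)), lsg_ids)
    pep_hits <- toySearch(lsg_pep, nonlsg_pep, mode = "peptide")
    cds_hits <- toySearch(lsg_cds, nonlsg_cds, mode = "nucleotide")
    dropPairs <- function(h) {
        keep <- vapply(seq_len(nrow(h)), function(i)
            !(h$subject_id[i] %in% overlap_partner[[h$query_id[i]]]) &&
                h$subject_id[i] != h$query_id[i], logical(1))
        h[keep, , drop = FALSE]
    }
    if (nrow(pep_hits)) pep_hits <- dropPairs(pep_hits)
    if (nrow(cds_hits)) cds_hits <- dropPairs(cds_hits)
    pep_merged <- mergeAllPairs(pep_hits, pep_len, thresholds)
    cds_merged <- mergeAllPairs(cds_hits, cds_len, thresholds)

    pair_keys <- union(names(pep_merged), names(cds_merged))
    dup_rows <- list(); dup_detail <- list()
    for (key in pair_keys) {
        ids <- strsplit(key, "\r", fixed = TRUE)[[1]]
        g <- ids[1]; s <- ids[2]
        pm <- pep_merged[[key]]; cm <- cds_merged[[key]]
        frame <- detectOutOfFrame(pm, cm)
        frame_lab <- if (is.null(frame)) "in_frame" else frame$frame
        orient <- "forward"; mech <- "indeterminate"
        if (!is.null(cm)) {
            hs <- cds_hits[cds_hits$query_id == g & cds_hits$subject_id == s &
                           cds_hits$e_value <
                               thresholds@within_genome_evalue, ,
                           drop = FALSE]
            if (nrow(hs)) {
                orient <- detectOrientation(hs)
                mech <- classifyDuplicationMechanism(catalog, g, s, hs,
                                                     thresholds)
            }
        } else if (!is.null(pm)) {
            mech <- "indeterminate"
        }
        dup_rows[[key]] <- data.frame(
            lsg_id = g, subject_id = s,
            pep_coverage_pct = if (is.null(pm)) 0 else
                roundHalfUp(pm$coverage_pct),
            cds_coverage_pct = if (is.null(cm)) 0 else
                roundHalfUp(cm$coverage_pct),
            frame = frame_lab, orientation = orient, mechanism = mech,
            stringsAsFactors = FALSE)
    }
    dup_pairs <- if (length(dup_rows)) do.call(rbind, dup_rows) else
        data.frame(lsg_id = character(), subject_id = character(),
                   pep_coverage_pct = numeric(), cds_coverage_pct = numeric(),
                   frame = character(), orientation = character(),
                   mechanism = character(), stringsAsFactors = FALSE)
    rownames(dup_pairs) <- NULL
    if (nrow(dup_pairs))
        dup_pairs <- classifyDuplicationContext(dup_pairs, genes,
                                                sim$syntelog_pairs,
                                                sim$wgd_pairs, thresholds)

    dup_detail <- do.call(rbind, lapply(seq_len(nrow(dup_pairs)),
                                        function(i) {
        d <- dup_pairs[i, ]
        details <- c(d$frame,
                     if (d$orientation == "inverted") "inverted",
                     if (d$mechanism != "indeterminate") d$mechanism,
                     d$context, if (isTRUE(d$wgd)) "wgd")
        data.frame(gene_id = d$lsg_id, detail = details,
                   stringsAsFactors = FALSE)
    }))

    ## stage 5: TE exaptation ------------------------------------------------
    te_res <- detectTeExaptation(catalog, lsg_ids, level = "exon")
    te_lsg_ids <- intersect(te_res$genes, lsg_ids)

    ## stage 6: chimera ------------------------------------------------------
    chim_ev <- list()
    addEv <- function(g, type, fid, qs, qe)
        chim_ev[[length(chim_ev) + 1L]] <<- data.frame(
            gene_id = g, type = type, feature_id = fid, q_start = qs,
            q_end = qe, stringsAsFactors = FALSE)
    for (key in pair_keys) {
        ids <- strsplit(key, "\r", fixed = TRUE)[[1]]
        m <- cds_merged[[key]]
        if (is.null(m) && !is.null(pep_merged[[key]])) {
            iv <- pep_merged[[key]]$intervals
            addEv(ids[1], "parent", ids[2], 3L * min(iv[, "start"]),
                  3L * max(iv[, "end"]))
        } else if (!is.null(m)) {
            addEv(ids[1], "parent", ids[2], min(m$intervals[, "start"]),
                  max(m$intervals[, "end"]))
        }
    }
    te_ov <- te_res$overlaps[te_res$overlaps$is_lsg, , drop = FALSE]
    te_gr <- catalog@te
    for (i in seq_len(nrow(te_ov))) {
        g <- te_ov$gene_id[i]
        t <- te_gr[te_gr$te_id == te_ov$te_id[i]][1]
        iv <- genomicToCdsInterval(catalog, g, GenomicRanges::start(t),
                                   GenomicRanges::end(t))
        if (!is.null(iv)) addEv(g, "te", te_ov$te_id[i], iv["start"],
                                iv["end"])
    }
    for (i in seq_len(nrow(lsg_nonlsg))) {
        g <- if (lsg_nonlsg$gene_a[i] %in% lsg_ids) lsg_nonlsg$gene_a[i]
             else lsg_nonlsg$gene_b[i]
        other <- setdiff(c(lsg_nonlsg$gene_a[i], lsg_nonlsg$gene_b[i]), g)
        og <- catalog@cds[[other]]
        iv <- genomicToCdsInterval(catalog, g,
                                   min(GenomicRanges::start(og)),
                                   max(GenomicRanges::end(og)))
        if (!is.null(iv)) addEv(g, "overlap", other, iv["start"], iv["end"])
    }
    chim_ev <- if (length(chim_ev)) do.call(rbind, chim_ev) else
        data.frame(gene_id = character(), type = character(),
                   feature_id = character(), q_start = integer(),
                   q_end = integer(), stringsAsFactors = FALSE)
    # mutual homology of parent candidates
    multi <- names(which(tapply(chim_ev$type == "parent", chim_ev$gene_id,
                                sum) >= 2))
    parents <- unique(chim_ev$feature_id[chim_ev$type == "parent" &
                                         chim_ev$gene_id %in% multi])
    parent_hom <- NULL
    if (length(parents) >= 2) {
        pp <- peptideSequences(catalog, parents)
        hh <- toySearch(pp, pp, mode = "peptide")
        hh <- hh[hh$query_id != hh$subject_id &
                 hh$e_value < thresholds@within_genome_evalue, ,
                 drop = FALSE]
        if (nrow(hh))
            parent_hom <- unique(data.frame(gene_a = hh$query_id,
                                            gene_b = hh$subject_id,
                                            stringsAsFactors = FALSE))
    }
    chimera <- detectChimeric(chim_ev, parent_hom)
    chimera_ids <- chimera$gene_id

    ## stage 7: outgroup tracing for species-only LSGs -----------------------
    og_seqs <- chromSequences(sim$outgroup)
    so_cds <- cdsSequences(catalog, species_only)
    scaffold_hits <- toySearch(so_cds, og_seqs, mode = "nucleotide")
    og_cds_db <- cdsSequences(sim$outgroup)
    og_cds_hits <- toySearch(so_cds, og_cds_db, mode = "nucleotide")
    outgroup_oof <- character()
    for (g in species_only) {
        sub <- og_cds_hits[og_cds_hits$query_id == g, , drop = FALSE]
        if (!is.null(qualifyingPairs(sub, g, cds_len[[g]], thresholds)))
            outgroup_oof <- c(outgroup_oof, g)
    }
    # projections are computed for every chained species-only LSG (also the
    # out-of-frame ones: their alignments back the polymorphism
    # cross-referencing); the rollup keeps the cascade order through
    # precedence
    projections <- setNames(vector("list", length(species_only)),
                            species_only)
    chains <- list()
    for (g in species_only) {
        hits <- scaffold_hits[scaffold_hits$query_id == g, , drop = FALSE]
        ch <- chainScaffoldHits(hits, thresholds)
        chains[[g]] <- ch
        if (is.null(ch)) next
        scf <- og_seqs[[ch$scaffold]]
        a <- max(0L, ch$region_start - 15L)
        b <- min(length(scf), ch$region_end + 15L)
        region <- as.character(Biostrings::subseq(scf, a + 1L, b))
        if (ch$orientation == "inverted") region <- revcomp(region)
        projections[[g]] <- projectOrf(as.character(so_cds[[g]]), region,
                                       thresholds)
    }
    chained_ids <- setdiff(names(chains)[!vapply(chains, is.null,
                                                 logical(1))],
                           outgroup_oof)
    no_match <- setdiff(species_only, c(outgroup_oof, chained_ids))
    proj_summary <- classifyProjectionSet(projections, thresholds)

    ## stage 8: origin rollup -------------------------------------------------
    nuclear_lsg <- intersect(lsg_ids,
                             genes$gene_id[genes$compartment == "nuclear"])
    origins <- summarizeOrigins(
        lsg_ids,
        overprint_ids = overprint_ids,
        duplication = dup_detail,
        te_ids = te_lsg_ids,
        chimeric_ids = chimera_ids,
        outgroup_oof_ids = outgroup_oof,
        outgroup_intergenic_ids = chained_ids,
        nuclear_ids = nuclear_lsg)

    ## stage 9: RBH + dN/dS ---------------------------------------------------
    rbh_query <- c(setdiff(nonlsg_ids,
                           genes$gene_id[genes$compartment != "nuclear"]),
                   intersect(lsg_ids, records$gene_id[
                       records$is_lsg &
                       records$lineage_level == "family_specific"]))
    focal_pep <- c(nonlsg_pep, lsg_pep)[rbh_query]
    ab <- toySearch(focal_pep, og_pep, mode = "peptide")
    ba <- toySearch(og_pep, focal_pep, mode = "peptide")
    rbh <- reciprocalBestHits(ab, ba)
    if (nrow(rbh)) {
        is_lsg_pair <- rbh$gene_a %in% lsg_ids
        keep_bg <- which(!is_lsg_pair)
        if (length(keep_bg) > max_dnds_background)
            keep_bg <- keep_bg[seq_len(max_dnds_background)]
        rbh_used <- rbh[sort(c(which(is_lsg_pair), keep_bg)), , drop = FALSE]
        focal_cds_all <- cdsSequences(catalog, unique(rbh_used$gene_a))
        dnds <- lapply(seq_len(nrow(rbh_used)), function(i) {
            al <- alignCodonPair(
                as.character(focal_cds_all[[rbh_used$gene_a[i]]]),
                as.character(og_cds_db[[rbh_used$gene_b[i]]]))
            computeDnds(al$cds1, al$cds2)
        })
        dnds_groups <- compareDndsGroups(
            dnds, ifelse(rbh_used$gene_a %in% lsg_ids, "LSG", "nonLSG"))
        dnds_table <- data.frame(
            gene_a = rbh_used$gene_a, gene_b = rbh_used$gene_b,
            dN = vapply(dnds, `[[`, numeric(1), "dN"),
            dS = vapply(dnds, `[[`, numeric(1), "dS"),
            ratio = vapply(dnds, `[[`, numeric(1), "ratio"),
            group = ifelse(rbh_used$gene_a %in% lsg_ids, "LSG", "nonLSG"),
            stringsAsFactors = FALSE)
    } else {
        dnds_groups <- NULL; dnds_table <- NULL
    }

    ## stage 10: polymorphism -------------------------------------------------
    poly <- applySnpsAndCall(catalog, lsg_ids, sim$snps)
    poly$calls <- crossReferenceOutgroup(poly$calls, catalog, projections)
    birth_loss <- if (nrow(poly$calls))
        inferBirthVsLoss(poly$calls, projections, sim$config@n_accessions)
    else NULL
    table1 <- summarizePolymorphicLsgs(poly$calls, records, genes)

    ## stage 11: expression ---------------------------------------------------
    ex <- sim$expression
    collapsed <- collapseCalls(ex$calls, ex$samples)
    lsg_flag <- rownames(ex$calls) %in% lsg_ids
    breadth <- breadthComparison(collapsed$breadth, lsg_flag)
    distr <- expressionDistributions(ex$expr, ex$samples,
                                     collapsed$presence, lsg_flag)
    de_sets <- lapply(ex$de_tables, function(tb)
        callDe(tb, thresholds = thresholds)[c("up", "down")])
    enrichment <- lsgStressEnrichment(de_sets, rownames(ex$calls), lsg_ids,
                                      thresholds)

    ## summary ---------------------------------------------------------------
    summary <- list(
        thresholds = thresholdsAsList(thresholds),
        n_genes_tested = length(gene_ids),
        n_lsg = length(lsg_ids),
        n_species_only = length(species_only),
        pct_species_only = pctShare(length(species_only), length(lsg_ids)),
        origin_rollup = origins$rollup,
        projection_counts = proj_summary$counts,
        n_no_outgroup_match = length(no_match),
        enrichment = enrichment[, c("contrast", "direction", "k", "K", "n",
                                    "N", "p_value", "enriched")],
        lsg_de_overlap = as.list(attr(enrichment, "lsg_de_overlap")))
    if (!is.null(sim$truth)) {
        truth <- sim$truth
        expected_lsg <- truth$gene_id[truth$class != "background"]
        mech_map <- c(overprint = "overprinting", dup_inframe = "duplication",
                      dup_frameshift = "duplication",
                      dup_inverted = "duplication", retrocopy = "duplication",
                      te_exapt = "te_exaptation", chimera = "chimeric")
        tr <- truth[truth$class %in% names(mech_map), ]
        assigned <- setNames(origins$assignments$primary_mechanism,
                             origins$assignments$gene_id)
        ok <- sum(assigned[tr$gene_id] == mech_map[tr$class], na.rm = TRUE)
        cat_truth <- setNames(truth$outgroup_category, truth$gene_id)
        cat_truth[cat_truth %in% c("ISC_STOP", "ISC_FS")] <- "ISC_OR_INDEL"
        proj_ok <- 0L; proj_tot <- 0L
        for (g in names(projections)) {
            expected <- cat_truth[[g]]
            if (is.null(expected) ||
                !expected %in% c("INTACT", "MSC", "ISC_OR_INDEL", "BOTH"))
                next
            proj_tot <- proj_tot + 1L
            if (!is.null(projections[[g]]) &&
                projections[[g]]$category == expected)
                proj_ok <- proj_ok + 1L
        }
        summary$recovery <- list(
            lsg_set_exact = setequal(lsg_ids, expected_lsg),
            mechanism_correct = ok, mechanism_total = nrow(tr),
            mechanism_rate = if (nrow(tr)) ok / nrow(tr) else NA,
            projection_correct = proj_ok, projection_total = proj_tot)
    }

    bundle <- list(records = records, compartments = compartments,
                   overlaps = overlaps, dup_pairs = dup_pairs,
                   te = te_res, chimera = chimera, origins = origins,
                   chains = chains, projections = projections,
                   projection_summary = proj_summary,
                   outgroup_oof = outgroup_oof, no_match = no_match,
                   rbh = rbh, dnds_table = dnds_table,
                   dnds_groups = dnds_groups,
                   polymorphism = poly, birth_loss = birth_loss,
                   table1 = table1, breadth = breadth,
                   expression_distributions = distr,
                   enrichment = enrichment, summary = summary,
                   truth = sim$truth)
    if (!is.null(out_dir)) renderReports(bundle, out_dir)
    bundle
}

#' Write the pipeline's report files
#'
#' Deterministic TSV/JSON reports: LSG catalog, origin assignments and
#' Figure-1-style rollup (every percentage printed with numerator and
#' denominator), TE tally, projection summary, polymorphism matrix and
#' Table-1-style summary, enrichment grid and the summary JSON.
#'
#' @param bundle result of [runPipeline()].
#' @param out_dir output directory.
#' @param overwrite overwrite existing outputs (default `FALSE`: refuses to
#'   clobber a non-empty directory).
#' @return invisibly, the output directory.
#' @export
renderReports <- function(bundle, out_dir, overwrite = FALSE) {
    if (dir.exists(out_dir) &&
        length(list.files(out_dir)) && !overwrite)
        stop("output directory not empty; pass overwrite = TRUE")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(out_dir, ...)
    rec <- bundle$records
    writeTsv(data.frame(gene_id = rec$gene_id, is_lsg = rec$is_lsg,
                        lineage_level = ifelse(is.na(rec$lineage_level),
                                               "none", rec$lineage_level),
                        eliminating_tier = ifelse(
                            is.na(rec$eliminating_tier), "none",
                            rec$eliminating_tier)),
             p("lsg_catalog.tsv"))
    writeTsv(bundle$origins$assignments, p("origin_assignments.tsv"))
    writeTsv(bundle$origins$rollup, p("origin_rollup.tsv"))
    writeTsv(bundle$te$tally, p("te_tally.tsv"))
    writeTsv(bundle$projection_summary$counts, p("projection_summary.tsv"))
    writeTsv(bundle$compartments, p("compartment_summary.tsv"))
    if (nrow(bundle$polymorphism$calls))
        writeTsv(bundle$polymorphism$calls, p("polymorphism_calls.tsv"))
    mat <- bundle$polymorphism$matrix
    writeTsv(data.frame(gene_id = rownames(mat), mat, check.names = FALSE),
             p("polymorphism_matrix.tsv"))
    writeTsv(bundle$table1$table, p("polymorphic_lsg_summary.tsv"))
    writeTsv(bundle$enrichment, p("enrichment.tsv"))
    if (!is.null(bundle$dnds_table))
        writeTsv(bundle$dnds_table, p("dnds.tsv"))
    jsonlite::write_json(bundle$summary, p("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns", na = "null")
    invisible(out_dir)
}
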