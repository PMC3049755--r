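# Derivation of the diverged outgroup genome with planted ORF disruptions.

# Transcription-order genomic (local) positions of a gene's CDS bases.
cdsLocalPositions <- function(g) {
    m <- g$cds[order(g$cds[, 1]), , drop = FALSE]
    pos <- unlist(lapply(seq_len(nrow(m)), function(i) seq(m[i, 1], m[i, 2])))
    if (g$strand == "-") rev(pos) else pos
}

# Overwrite codon `codon_index` (1-based, transcription order) of gene `gi`
# in a locus with `new_codon`, strand-aware.
editCdsCodonLocal <- function(locus, gi, codon_index, new_codon) {
    g <- locus$genes[[gi]]
    pos <- cdsLocalPositions(g)
    idx <- pos[(3L * codon_index - 2L):(3L * codon_index)]
    seqv <- strsplit(locus$seq, "")[[1]]
    bases <- strsplit(new_codon, "")[[1]]
    if (g$strand == "-") bases <- chartr("ACGT", "TGCA", bases)
    seqv[idx] <- bases
    locus$seq <- paste(seqv, collapse = "")
    locus
}

# Delete one base at CDS transcription position `p` (1-based) of gene `gi`.
# Only safe in loci whose other annotated features lie left of the site.
deleteCdsBaseLocal <- function(locus, gi, p) {
    g <- locus$genes[[gi]]
    pos <- cdsLocalPositions(g)[p]
    locus$seq <- paste0(substr(locus$seq, 1L, pos - 1L),
                        substr(locus$seq, pos + 1L, nchar(locus$seq)))
    locus
}

#' Derive the diverged outgroup genome
#'
#' The outgroup is the focal chromosome 1 with per-site substitutions at the
#' configured divergence: codon-aware inside every annotated CDS (changes
#' creating stops or destroying the start or terminal stop in any covering
#' frame are rejected; nonsynonymous changes are accepted with probability
#' 0.2 in background genes and 0.8 in lineage-specific loci, planting rate
#' classes for the dN/dS comparison), uniform elsewhere. Each species-only
#' planted gene then receives its assigned disruption (start-codon mutation,
#' internal stop, 1-bp frameshift deletion, or both); loci labelled de novo
#' or differential loss are deleted outright. Background genes and
#' family-level lineage-specific genes keep intact ORFs and are annotated as
#' outgroup gene models. The result is cut into five scaffolds at
#' inter-locus boundaries.
#'
#' @param sim state from [plantOriginEvents()].
#' @return sim with `sim$outgroup` (a [GenomeCatalog-class] of scaffolds and
#'   annotated outgroup models) and per-gene outgroup locations in
#'   `sim$outgroup_loci`.
#' @export
deriveOutgroup <- function(sim) {
    config <- sim$config
    div <- config@outgroup_divergence
    withSeed(childSeed(config@seed, "outgroup"), {
        truth <- sim$truth
        class_of <- setNames(truth$class, truth$gene_id)
        lin_of <- setNames(truth$lineage_level, truth$gene_id)
        cat_of <- setNames(truth$outgroup_category, truth$gene_id)
        # planted categories carry the finer ISC split from planting time
        fine <- setNames(sim$truth_planted$outgroup_category,
                         sim$truth_planted$gene_id)
        idx <- which(vapply(sim$loci, function(l) l$chrom == "chr1",
                            logical(1)))
        out_loci <- list()
        for (li in idx) {
            loc <- sim$loci[[li]]
            gene_ids <- vapply(loc$genes, function(g) g$gene_id,
                               character(1))
            dropped <- length(gene_ids) &&
                any(class_of[gene_ids] %in% c("de_novo",
                                              "differential_loss"))
            if (dropped) next
            has_bg <- any(class_of[gene_ids] == "background")
            omega <- if (!length(gene_ids) || has_bg) 0.2 else 0.8
            protect <- integer()
            for (gi in seq_along(loc$genes)) {
                gid <- gene_ids[gi]
                at <- sim$acc_truth[[gid]]
                if (!is.null(at)) {
                    pos <- cdsLocalPositions(loc$genes[[gi]])
                    protect <- c(protect,
                                 pos[3L * at$codon_index - 3L +
                                     at$pos_in_codon])
                }
            }
            loc <- mutateLocus(loc, div, omega = omega, protect = protect)
            for (gi in seq_along(loc$genes)) {
                gid <- gene_ids[gi]
                if (!identical(unname(lin_of[gid]), "species_only")) next
                at <- sim$acc_truth[[gid]]
                if (!is.null(at)) {
                    if (at$birth)
                        loc <- editCdsCodonLocal(loc, gi, at$codon_index,
                                                 at$disrupted_codon)
                    next
                }
                fc <- fine[[gid]]
                n_cod <- sum(loc$genes[[gi]]$cds[, 2] -
                             loc$genes[[gi]]$cds[, 1] + 1L) %/% 3L
                if (fc %in% c("MSC", "BOTH"))
                    loc <- editCdsCodonLocal(loc, gi, 1L, "CTG")
                if (fc %in% c("ISC_STOP", "BOTH"))
                    loc <- editCdsCodonLocal(loc, gi,
                                             max(3L, round(n_cod * 0.4)),
                                             "TAA")
                if (fc == "ISC_FS")
                    loc <- deleteCdsBaseLocal(loc, gi,
                                              3L * round(n_cod * 0.45))
            }
            out_loci[[length(out_loci) + 1L]] <- loc
        }

        # assemble into scaffolds, cutting between loci
        n_scf <- 5L
        per <- ceiling(length(out_loci) / n_scf)
        seqs <- character()
        gene_rows <- list(); exon_l <- list(); cds_l <- list()
        outgroup_loci <- list()
        for (s in seq_len(n_scf)) {
            take <- out_loci[((s - 1L) * per + 1L):min(s * per,
                                                       length(out_loci))]
            if ((s - 1L) * per + 1L > length(out_loci)) break
            scf <- sprintf("scf%d", s)
            parts <- character(); offset <- 0L
            for (loc in take) {
                spacer <- mutateString(sim$spacers[[loc$id]], div)
                parts <- c(parts, spacer)
                offset <- offset + nchar(spacer)
                outgroup_loci[[loc$id]] <- list(
                    scaffold = scf, start = offset + 1L,
                    end = offset + nchar(loc$seq))
                for (gi in seq_along(loc$genes)) {
                    g <- loc$genes[[gi]]
                    gid <- g$gene_id
                    annotate <- class_of[[gid]] == "background" ||
                        identical(unname(lin_of[gid]), "family_specific")
                    if (!annotate) next
                    og_id <- paste0("og_", gid)
                    ex <- g$exons + offset
                    cd <- g$cds + offset
                    exon_l[[og_id]] <- GenomicRanges::GRanges(
                        scf, IRanges::IRanges(ex[, 1], ex[, 2]),
                        strand = g$strand)
                    cdsgr <- GenomicRanges::GRanges(
                        scf, IRanges::IRanges(cd[, 1], cd[, 2]),
                        strand = g$strand)
                    cdsgr$phase <- cdsPhases(cdsgr, g$strand)
                    cds_l[[og_id]] <- cdsgr
                    gene_rows[[og_id]] <- data.frame(
                        gene_id = og_id, model_id = paste0(og_id, ".1"),
                        chrom = scf, strand = g$strand,
                        start = min(ex[, 1]), end = max(ex[, 2]),
                        compartment = "nuclear", is_te_gene = FALSE,
                        expression_support = "none",
                        n_exons = nrow(ex),
                        cds_length = sum(cd[, 2] - cd[, 1] + 1L),
                        intact = TRUE, stringsAsFactors = FALSE)
                }
                parts <- c(parts, loc$seq)
                offset <- offset + nchar(loc$seq)
            }
            parts <- c(parts, randomDna(200L))
            seqs[[scf]] <- paste(parts, collapse = "")
        }
        genes <- do.call(rbind, gene_rows)
        genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
        rownames(genes) <- NULL
        sim$outgroup <- new("GenomeCatalog",
                            sequences = Biostrings::DNAStringSet(seqs),
                            genes = genes,
                            exons = GenomicRanges::GRangesList(exon_l),
                            cds = GenomicRanges::GRangesList(cds_l),
                            te = GenomicRanges::GRanges())
        sim$outgroup_loci <- outgroup_loci
        sim
    })
}
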