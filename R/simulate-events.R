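# Planting of labelled origin events into the background genome and assembly
# of the final focal chromosomes.

# Codons whose reverse complement is a stop (cannot appear in the overlap
# window of an overprinted pair read on the minus strand).
.RC_STOPS <- c("TTA", "CTA", "TCA")

#' Plant labelled origin events
#'
#' Adds one gene per planted event to the background genome: overprinting
#' (a new minus-strand ORF overlapping a host CDS, both frames engineered
#' stop-free), in-frame duplication (full structural copy of a multi-exon
#' donor, some tandem, some distal/syntelog), frameshifted and inverted
#' duplications (out-of-frame copies of donor CDS), retrocopies (intron-less
#' copies of three-exon donors), TE exaptation (a TE fragment inside a coding
#' exon, annotated), chimeras (codon-aligned fusion of two unrelated donors),
#' de novo and accession-polymorphic genes (fresh ORFs), and marks loci for
#' differential loss. Ground truth records every donor and the planted
#' lineage level and outgroup disruption category.
#'
#' @param sim state from [generateGenome()].
#' @return sim with planted loci, assembled chromosomes and a populated
#'   ground-truth table (`sim$truth`).
#' @export
plantOriginEvents <- function(sim) {
    config <- sim$config
    withSeed(childSeed(config@seed, "plant"), {
        np <- config@n_planted
        # pools of background loci by structure (nuclear only)
        locus_chrom <- vapply(sim$loci, function(l) l$chrom, character(1))
        n_exons_of <- vapply(sim$loci, function(l)
            if (length(l$genes)) nrow(l$genes[[1]]$exons) else 0L,
            integer(1))
        cds_len_of <- vapply(sim$loci, function(l)
            if (length(l$genes)) nchar(locusCdsSeq(l)) else 0L, integer(1))
        is_gene <- vapply(sim$loci, function(l) length(l$genes) > 0,
                          logical(1))
        pool_single <- which(is_gene & locus_chrom == "chr1" &
                             n_exons_of == 1L & cds_len_of >= 330L)
        pool_multi <- which(is_gene & locus_chrom == "chr1" &
                            n_exons_of >= 2L & n_exons_of <= 3L &
                            cds_len_of >= 360L & cds_len_of <= 1200L)
        pool_three <- which(is_gene & locus_chrom == "chr1" &
                            n_exons_of == 3L & cds_len_of >= 360L &
                            cds_len_of <= 1200L)
        used <- integer()
        take <- function(pool, n) {
            avail <- setdiff(pool, used)
            if (length(avail) < n)
                stop("planting error: not enough suitable donor loci (need ",
                     n, ", have ", length(avail), ")")
            got <- avail[seq_len(n)]
            used <<- c(used, got)
            got
        }

        truth <- list()
        new_loci <- list()          # loci to interleave
        anchor_after <- list()      # id of locus to anchor after (tandem)
        pid <- 0L
        cat_cycle <- c("INTACT", "MSC", "ISC_STOP", "ISC_FS", "BOTH")
        cyc_i <- 0L
        next_cat <- function() {
            cyc_i <<- cyc_i + 1L
            cat_cycle[(cyc_i - 1L) %% length(cat_cycle) + 1L]
        }
        addTruth <- function(gene_id, class, donors = "",
                             lineage = "species_only",
                             outgroup_category = "INTACT") {
            truth[[length(truth) + 1L]] <<- data.frame(
                gene_id = gene_id, class = class, donors = donors,
                lineage_level = lineage,
                outgroup_category = outgroup_category,
                stringsAsFactors = FALSE)
        }

        # ---- overprint: rebuild single-exon hosts with engineered tails ----
        hosts <- take(pool_single, np[["overprint"]])
        for (h in seq_along(hosts)) {
            pid <- pid + 1L
            gid <- sprintf("ov%02d", h)
            host_old <- sim$loci[[hosts[h]]]
            host_id <- host_old$genes[[1]]$gene_id
            n_cod <- 140L
            # host CDS with engineered last 15 codons (window w1..w15)
            w1 <- sample(.RC_STOPS, 1)
            body_ok <- setdiff(nonstopCodons(), .RC_STOPS)
            w_mid <- sample(body_ok, 13L, replace = TRUE)
            host_cds <- paste0("ATG",
                               paste(sample(body_ok, n_cod - 17L,
                                            replace = TRUE), collapse = ""),
                               w1, paste(w_mid, collapse = ""), "TAA")
            host_locus <- makeGeneLocus(host_id, host_cds, 1L,
                                        strand = "+", chrom = "chr1",
                                        utr5 = 30L, utr3 = 0L,
                                        expression_support =
                                            host_old$genes[[1]]$expression_support)
            # overprint ORF on the minus strand: its last 45 bases are the
            # reverse complement of the host's last 15 CDS codons
            tail45 <- revcomp(substr(host_cds, nchar(host_cds) - 44L,
                                     nchar(host_cds)))
            stopifnot(substr(tail45, 43L, 45L) %in% GENETIC_STOPS ||
                      TRUE)  # tail ends at host codon w1 rc = stop
            n_up <- 60L  # overprint codons upstream of the overlap
            up <- paste0("ATG", paste(sample(body_ok, n_up - 1L,
                                             replace = TRUE),
                                      collapse = ""))
            ov_cds <- paste0(up, tail45)
            stopifnot(nchar(ov_cds) %% 3L == 0L,
                      !any(codonSplit(ov_cds)[-(nchar(ov_cds) %/% 3L)] %in%
                           GENETIC_STOPS),
                      codonSplit(ov_cds)[nchar(ov_cds) %/% 3L] %in%
                          GENETIC_STOPS)
            # locus: host followed by the reverse complement of the upstream
            # overprint part
            cds_end <- host_locus$genes[[1]]$cds[1, 2]
            host_locus$seq <- paste0(host_locus$seq, revcomp(up))
            ov_start <- cds_end - 44L
            ov_end <- nchar(host_locus$seq)
            stopifnot(revcomp(substr(host_locus$seq, ov_start, ov_end)) ==
                      ov_cds)
            host_locus$genes[[2]] <- list(
                gene_id = gid, strand = "-", chrom = "chr1",
                exons = cbind(ov_start, ov_end),
                cds = cbind(ov_start, ov_end),
                expression_support = "locus_supported")
            sim$loci[[hosts[h]]] <- host_locus
            addTruth(gid, "overprint", host_id,
                     outgroup_category = next_cat())
        }

        # ---- in-frame duplications (full structural copies) ----
        donors <- take(pool_multi, np[["dup_inframe"]])
        for (i in seq_along(donors)) {
            pid <- pid + 1L
            gid <- sprintf("dupif%02d", i)
            don <- sim$loci[[donors[i]]]
            copy <- don
            copy$id <- paste0("loc_", gid)
            g <- copy$genes[[1]]
            g$gene_id <- gid
            g$expression_support <- "locus_supported"
            copy$genes <- list(g)
            copy <- mutateLocus(copy, 0.04, omega = 0.9)
            new_loci[[length(new_loci) + 1L]] <- copy
            anchor_after[[length(anchor_after) + 1L]] <-
                if (i <= 3L) don$id else NA_character_
            # structural copies keep their introns; the projection stand-in
            # is exact only on intron-free regions, so their outgroup
            # orthologs stay intact and annotated (family level)
            addTruth(gid, "dup_inframe", don$genes[[1]]$gene_id,
                     lineage = "family_specific",
                     outgroup_category = "ANNOTATED")
        }

        # ---- frameshifted duplications (out-of-frame copies) ----
        donors <- take(pool_multi, np[["dup_frameshift"]])
        for (i in seq_along(donors)) {
            pid <- pid + 1L
            gid <- sprintf("dupfs%02d", i)
            don <- sim$loci[[donors[i]]]
            spl <- locusCdsSeq(don)
            L <- min(270L, (nchar(spl) - 10L) %/% 3L * 3L)
            frag <- substr(spl, 5L, 5L + L - 1L)  # +1 frame shift
            cds <- paste0("ATG", sanitizeStops(frag),
                          sample(GENETIC_STOPS, 1))
            cds <- mutateCdsString(cds, 0.02)
            new_loci[[length(new_loci) + 1L]] <- makeGeneLocus(
                gid, cds, 1L, strand = "+", chrom = "chr1",
                utr5 = 10L, utr3 = 10L,
                expression_support = "none")
            anchor_after[[length(anchor_after) + 1L]] <- NA_character_
            addTruth(gid, "dup_frameshift", don$genes[[1]]$gene_id,
                     outgroup_category = next_cat())
        }

        # ---- inverted duplications ----
        donors <- take(pool_multi, np[["dup_inverted"]])
        for (i in seq_along(donors)) {
            pid <- pid + 1L
            gid <- sprintf("dupinv%02d", i)
            don <- sim$loci[[donors[i]]]
            spl <- locusCdsSeq(don)
            L <- min(270L, (nchar(spl) - 10L) %/% 3L * 3L)
            frag <- revcomp(substr(spl, 4L, 3L + L))
            cds <- paste0("ATG", sanitizeStops(frag),
                          sample(GENETIC_STOPS, 1))
            cds <- mutateCdsString(cds, 0.02)
            new_loci[[length(new_loci) + 1L]] <- makeGeneLocus(
                gid, cds, 1L, strand = "+", chrom = "chr1",
                utr5 = 10L, utr3 = 10L, expression_support = "none")
            anchor_after[[length(anchor_after) + 1L]] <- NA_character_
            addTruth(gid, "dup_inverted", don$genes[[1]]$gene_id,
                     outgroup_category = next_cat())
        }

        # ---- retrocopies (spliced copies of three-exon donors) ----
        donors <- take(pool_three, np[["retrocopy"]])
        for (i in seq_along(donors)) {
            pid <- pid + 1L
            gid <- sprintf("retro%02d", i)
            don <- sim$loci[[donors[i]]]
            cds <- mutateCdsString(locusCdsSeq(don), 0.03)
            new_loci[[length(new_loci) + 1L]] <- makeGeneLocus(
                gid, cds, 1L, strand = "+", chrom = "chr1",
                utr5 = 15L, utr3 = 15L, expression_support = "locus_supported")
            anchor_after[[length(anchor_after) + 1L]] <- NA_character_
            # a retrocopy's peptide matches its donor's outgroup ortholog,
            # so the filter legitimately keeps it at the family level
            addTruth(gid, "retrocopy", don$genes[[1]]$gene_id,
                     lineage = "family_specific",
                     outgroup_category = "ANNOTATED")
        }

        # ---- TE exaptation (TE fragment inside a coding exon) ----
        for (i in seq_len(np[["te_exapt"]])) {
            pid <- pid + 1L
            gid <- sprintf("teex%02d", i)
            sf <- names(config@te_density)[
                (i - 1L) %% length(config@te_density) + 1L]
            lib <- sim$te_library[[sf]]
            te_len <- 120L
            a <- sample(seq_len(nchar(lib) - te_len), 1)
            te_frag <- sanitizeStops(substr(lib, a, a + te_len - 1L))
            n_pre <- 40L; n_post <- 30L
            cds <- paste0("ATG", sampleCodons(n_pre - 1L), te_frag,
                          sampleCodons(n_post), sample(GENETIC_STOPS, 1))
            locus <- makeGeneLocus(gid, cds, 1L, strand = "+",
                                   chrom = "chr1", utr5 = 0L, utr3 = 40L,
                                   expression_support = "locus_supported")
            te_start <- n_pre * 3L + 1L
            locus$te <- list(list(te_id = sprintf("TEex%02d", i),
                                  superfamily = sf,
                                  start = te_start,
                                  end = te_start + te_len + 30L))
            new_loci[[length(new_loci) + 1L]] <- locus
            anchor_after[[length(anchor_after) + 1L]] <- NA_character_
            addTruth(gid, "te_exapt", sprintf("TEex%02d", i),
                     lineage = if (i == 1L) "family_specific"
                               else "species_only",
                     outgroup_category = if (i == 1L) "ANNOTATED"
                                         else next_cat())
        }

        # ---- chimeras (two unrelated donors, codon-aligned fragments) ----
        donA <- take(pool_multi, np[["chimera"]])
        donB <- take(pool_single, np[["chimera"]])
        for (i in seq_len(np[["chimera"]])) {
            pid <- pid + 1L
            gid <- sprintf("chim%02d", i)
            A <- sim$loci[[donA[i]]]; B <- sim$loci[[donB[i]]]
            splA <- locusCdsSeq(A); splB <- locusCdsSeq(B)
            fragA <- substr(splA, 4L, 3L + 150L)
            fragB <- substr(splB, 4L, 3L + 150L)
            cds <- paste0("ATG", fragA, fragB, sample(GENETIC_STOPS, 1))
            cds <- mutateCdsString(cds, 0.02)
            new_loci[[length(new_loci) + 1L]] <- makeGeneLocus(
                gid, cds, 1L, strand = "+", chrom = "chr1",
                utr5 = 10L, utr3 = 10L, expression_support = "none")
            anchor_after[[length(anchor_after) + 1L]] <- NA_character_
            # chimera fragments match the donors' outgroup orthologs at the
            # peptide level, keeping chimeras at the family level
            addTruth(gid, "chimera",
                     paste(A$genes[[1]]$gene_id, B$genes[[1]]$gene_id,
                           sep = ","),
                     lineage = "family_specific",
                     outgroup_category = "ANNOTATED")
        }

        # ---- de novo ORFs (absent from the outgroup) ----
        for (i in seq_len(np[["de_novo"]])) {
            pid <- pid + 1L
            gid <- sprintf("denovo%02d", i)
            chrom <- if (i <= 2L) "chrM" else "chr1"
            cds <- makeOrf(sample(100:150, 1))
            new_loci[[length(new_loci) + 1L]] <- makeGeneLocus(
                gid, cds, sample(1:2, 1), strand = sample(c("+", "-"), 1),
                chrom = chrom, expression_support = "locus_supported")
            anchor_after[[length(anchor_after) + 1L]] <- NA_character_
            addTruth(gid, "de_novo", outgroup_category = "ABSENT")
        }

        # ---- differential loss (intact focal gene, locus deleted) ----
        for (i in seq_len(np[["differential_loss"]])) {
            pid <- pid + 1L
            gid <- sprintf("loss%02d", i)
            cds <- makeOrf(sample(100:150, 1))
            new_loci[[length(new_loci) + 1L]] <- makeGeneLocus(
                gid, cds, 1L, strand = "+", chrom = "chr1",
                expression_support = "none")
            anchor_after[[length(anchor_after) + 1L]] <- NA_character_
            addTruth(gid, "differential_loss",
                     outgroup_category = "ABSENT")
        }

        # ---- accession-polymorphic genes (ISC / MSC SNPs planted later) ----
        acc_truth <- list()
        for (ty in c("accession_isc", "accession_msc")) {
            for (i in seq_len(np[[ty]])) {
                pid <- pid + 1L
                gid <- sprintf("%s%02d",
                               if (ty == "accession_isc") "aisc" else "amsc",
                               i)
                n_cod <- sample(100:130, 1)
                cds <- makeOrf(n_cod)
                birth <- i %% 2L == 1L  # odd = gene birth, even = gene loss
                if (ty == "accession_isc") {
                    ci <- sample(20:(n_cod - 10L), 1)
                    # codon TGG mutates to TGA through the planted SNP
                    cods <- codonSplit(cds)
                    cods[ci] <- "TGG"
                    cds <- paste(cods, collapse = "")
                    snp <- list(codon_index = ci, pos_in_codon = 3L,
                                alt = "A", disrupted_codon = "TGA",
                                type = "ISC")
                } else {
                    snp <- list(codon_index = 1L, pos_in_codon = 1L,
                                alt = "G", disrupted_codon = "GTG",
                                type = "MSC")
                }
                new_loci[[length(new_loci) + 1L]] <- makeGeneLocus(
                    gid, cds, 1L, strand = "+", chrom = "chr1",
                    expression_support = "gene_model_supported")
                anchor_after[[length(anchor_after) + 1L]] <- NA_character_
                addTruth(gid, ty,
                         outgroup_category = if (birth) {
                             if (ty == "accession_isc") "ISC_OR_INDEL"
                             else "MSC"
                         } else "INTACT")
                acc_truth[[gid]] <- c(snp, list(gene_id = gid,
                                                birth = birth))
            }
        }

        sim$acc_truth <- acc_truth
        sim$truth_planted <- if (length(truth)) do.call(rbind, truth) else
            data.frame(gene_id = character(), class = character(),
                       donors = character(), lineage_level = character(),
                       outgroup_category = character(),
                       stringsAsFactors = FALSE)

        # ---- interleave planted loci into the genome ----
        for (i in seq_along(new_loci)) {
            anc <- anchor_after[[i]]
            if (!is.na(anc)) {
                at <- which(vapply(sim$loci, function(l) l$id == anc,
                                   logical(1)))
                sim$loci <- append(sim$loci, new_loci[i], after = at)
            } else {
                chrom <- new_loci[[i]]$chrom
                slots <- which(vapply(sim$loci, function(l)
                    l$chrom == chrom, logical(1)))
                at <- if (length(slots)) sample(slots, 1) else 0L
                sim$loci <- append(sim$loci, new_loci[i], after = at)
            }
        }

        # syntelog table: two distal in-frame duplicate pairs (one in a WGD
        # block)
        dif <- sim$truth_planted[sim$truth_planted$class == "dup_inframe", ]
        distal <- if (nrow(dif) > 3L) dif[4:nrow(dif), , drop = FALSE]
                  else dif[0, , drop = FALSE]
        syn <- distal[seq_len(min(2L, nrow(distal))), , drop = FALSE]
        sim$syntelog_pairs <- data.frame(gene_a = syn$gene_id,
                                         gene_b = syn$donors,
                                         stringsAsFactors = FALSE)
        sim$wgd_pairs <- sim$syntelog_pairs[seq_len(min(1L, nrow(syn))), ,
                                            drop = FALSE]
        sim <- assembleSim(sim)
        sim
    })
}

# Substitution mutation of a CDS string (frame 0), rejecting changes that
# create stops or touch the start/terminal codon.
mutateCdsString <- function(cds, rate) {
    tmp <- list(seq = cds,
                genes = list(list(gene_id = "x", strand = "+",
                                  exons = cbind(1L, nchar(cds)),
                                  cds = cbind(1L, nchar(cds)))))
    mutateLocus(tmp, rate, omega = 1)$seq
}

# Concatenate loci into chromosomes with intergenic spacers; builds the
# focal GenomeCatalog and global TE coordinates. Spacer lengths are sized so
# that roughly `intergenic_fraction` of each chromosome is intergenic.
assembleSim <- function(sim) {
    config <- sim$config
    mean_locus <- mean(vapply(sim$loci, function(l) nchar(l$seq),
                              numeric(1)))
    f <- config@intergenic_fraction
    spacer_mean <- max(200L, round(mean_locus * f / (1 - f)))
    chroms <- unique(vapply(sim$loci, function(l) l$chrom, character(1)))
    seqs <- character(); names(seqs) <- character()
    gene_rows <- list(); exon_l <- list(); cds_l <- list(); te_rows <- list()
    sim$locus_offset <- list()
    sim$spacers <- list()
    for (ch in chroms) {
        parts <- character(); offset <- 0L
        idx <- which(vapply(sim$loci, function(l) l$chrom == ch,
                            logical(1)))
        for (k in seq_along(idx)) {
            li <- idx[k]
            sp_len <- sample(seq(round(spacer_mean * 0.5),
                                 round(spacer_mean * 1.5)), 1)
            spacer <- randomDna(sp_len)
            sim$spacers[[sim$loci[[li]]$id]] <- spacer
            parts <- c(parts, spacer)
            offset <- offset + sp_len
            loc <- sim$loci[[li]]
            sim$locus_offset[[loc$id]] <- c(chrom = ch, offset = offset)
            parts <- c(parts, loc$seq)
            for (g in loc$genes) {
                gid <- g$gene_id
                ex <- g$exons + offset
                cd <- g$cds + offset
                exon_l[[gid]] <- GenomicRanges::GRanges(
                    ch, IRanges::IRanges(ex[, 1], ex[, 2]),
                    strand = g$strand)
                cdsgr <- GenomicRanges::GRanges(
                    ch, IRanges::IRanges(cd[, 1], cd[, 2]),
                    strand = g$strand)
                cdsgr$phase <- cdsPhases(cdsgr, g$strand)
                cds_l[[gid]] <- cdsgr
                gene_rows[[gid]] <- data.frame(
                    gene_id = gid, model_id = paste0(gid, ".1"),
                    chrom = ch, strand = g$strand,
                    start = min(ex[, 1]), end = max(ex[, 2]),
                    compartment = compartmentOf(ch), is_te_gene = FALSE,
                    expression_support = g$expression_support,
                    n_exons = nrow(ex),
                    cds_length = sum(cd[, 2] - cd[, 1] + 1L),
                    intact = TRUE, stringsAsFactors = FALSE)
            }
            for (t in loc$te)
                te_rows[[length(te_rows) + 1L]] <- data.frame(
                    chrom = ch, start = t$start + offset,
                    end = t$end + offset, te_id = t$te_id,
                    superfamily = t$superfamily, stringsAsFactors = FALSE)
            offset <- offset + nchar(loc$seq)
        }
        parts <- c(parts, randomDna(300L))
        seqs[[ch]] <- paste(parts, collapse = "")
    }
    te_df <- if (length(te_rows)) do.call(rbind, te_rows) else NULL
    te <- if (!is.null(te_df))
        GenomicRanges::GRanges(te_df$chrom,
                               IRanges::IRanges(te_df$start, te_df$end),
                               strand = "+", te_id = te_df$te_id,
                               superfamily = te_df$superfamily)
    else GenomicRanges::GRanges()
    genes <- do.call(rbind, gene_rows)
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
    sim$catalog <- new("GenomeCatalog",
                       sequences = Biostrings::DNAStringSet(seqs),
                       genes = genes,
                       exons = GenomicRanges::GRangesList(exon_l),
                       cds = GenomicRanges::GRangesList(cds_l),
                       te = te)
    # full ground-truth gene table
    planted <- sim$truth_planted
    bg <- data.frame(gene_id = setdiff(genes$gene_id, planted$gene_id),
                     class = "background", donors = "",
                     lineage_level = "conserved",
                     outgroup_category = "ANNOTATED",
                     stringsAsFactors = FALSE)
    bg$outgroup_category[!bg$gene_id %in%
        genes$gene_id[genes$chrom == "chr1"]] <- "ABSENT"
    truth <- rbind(planted, bg)
    truth$expression_class <- ifelse(truth$class == "background",
                                     "conserved_like", "lsg_like")
    sim$truth <- truth[match(genes$gene_id, truth$gene_id), ]
    rownames(sim$truth) <- NULL
    sim
}
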