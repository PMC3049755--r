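#' Scan distant (non-family) genomes for reciprocal LSG evidence
#'
#' For each LSG and distant species: when a qualifying transcript/CDS hit
#' exists (e-value below `within_genome_evalue`, merged coverage at least
#' `min_query_coverage_pct`), its top subject is searched back against the
#' focal CDS database and evidence class `distant_cds` is recorded when the
#' reciprocal top hit is the LSG itself. Otherwise a qualifying genomic hit
#' is followed up by extracting the hit span plus `distant_flank_bp` on both
#' sides (clamped to scaffold bounds with a warning) and searching the
#' segment back; reciprocity yields `distant_intergenic`. Everything else is
#' `none`.
#'
#' @param lsg_ids LSG ids scanned.
#' @param cds_hits,genomic_hits named lists (per species) of HSP data.frames
#'   of LSG CDS queries against the species' CDS set / genome scaffolds.
#' @param species_cds named list (per species) of `DNAStringSet` CDS
#'   databases.
#' @param species_genomes named list (per species) of `DNAStringSet`
#'   scaffolds.
#' @param focal_cds `DNAStringSet` of all focal CDS (reciprocal target).
#' @param query_lengths named vector of LSG CDS lengths.
#' @param thresholds a [ThresholdConfig-class].
#' @return data.frame `lsg_id`, `species`, `evidence`
#'   (`distant_cds`/`distant_intergenic`/`none`), `partner` (subject or
#'   scaffold segment id).
#' @export
scanDistantGenomes <- function(lsg_ids, cds_hits, genomic_hits, species_cds,
                               species_genomes, focal_cds, query_lengths,
                               thresholds = thresholdConfig()) {
    species <- union(names(cds_hits), names(genomic_hits))
    rows <- list()
    for (sp in species) {
        ch <- cds_hits[[sp]]
        gh <- genomic_hits[[sp]]
        for (g in lsg_ids) {
            ev <- "none"; partner <- NA_character_
            qlen <- query_lengths[[g]]
            qual <- qualifyingPairs(ch, g, qlen, thresholds)
            if (!is.null(qual)) {
                top <- qual$subject_id[1]
                back <- toySearch(
                    setNames(as.character(species_cds[[sp]][top]), top),
                    setNames(as.character(focal_cds), names(focal_cds)),
                    mode = "nucleotide")
                if (nrow(back) && back$subject_id[1] == g) {
                    ev <- "distant_cds"; partner <- top
                }
            }
            if (ev == "none" && !is.null(gh)) {
                qual <- qualifyingPairs(gh, g, qlen, thresholds)
                if (!is.null(qual)) {
                    hit <- gh[gh$query_id == g &
                              gh$subject_id == qual$subject_id[1], ][1, ]
                    scf <- species_genomes[[sp]][[hit$subject_id]]
                    fl <- thresholds@distant_flank_bp
                    a <- hit$s_start - fl; b <- hit$s_end + fl
                    if (a < 0 || b > length(scf)) {
                        warning("flank extraction clamped to scaffold bounds for ",
                                g, " on ", hit$subject_id)
                        a <- max(0, a); b <- min(length(scf), b)
                    }
                    seg <- as.character(Biostrings::subseq(scf, a + 1L, b))
                    seg_id <- sprintf("%s:%d-%d", hit$subject_id, a, b)
                    back <- toySearch(setNames(seg, seg_id),
                                      setNames(as.character(focal_cds),
                                               names(focal_cds)),
                                      mode = "nucleotide")
                    if (nrow(back) && back$subject_id[1] == g) {
                        ev <- "distant_intergenic"; partner <- seg_id
                    }
                }
            }
            rows[[length(rows) + 1L]] <- data.frame(
                lsg_id = g, species = sp, evidence = ev, partner = partner,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

# Best qualifying subject for one query in a hit table (e-value and merged
# coverage rules); NULL when none. Returns a one-row data.frame ordered by
# top-hit criteria.
qualifyingPairs <- function(hits, query, qlen, thresholds) {
    if (is.null(hits) || !nrow(hits)) return(NULL)
    sub <- hits[hits$query_id == query &
                hits$e_value < thresholds@within_genome_evalue, ,
                drop = FALSE]
    if (!nrow(sub)) return(NULL)
    good <- character()
    for (s in unique(sub$subject_id)) {
        mc <- mergeHsps(sub[sub$subject_id == s, , drop = FALSE], qlen,
                        thresholds)
        if (!is.null(mc)) good <- c(good, s)
    }
    if (!length(good)) return(NULL)
    sub <- sub[sub$subject_id %in% good, , drop = FALSE]
    sub <- sub[order(sub$e_value, -sub$score, sub$subject_id), , drop = FALSE]
    sub[1, , drop = FALSE]
}

#' Reciprocal best hits between two peptide sets
#'
#' A pair (a, b) is reported when b is a's top hit and a is b's top hit. Top
#' hits break ties by lower e-value, then higher score, then lexicographic
#' subject id.
#'
#' @param hits_ab,hits_ba HSP data.frames for the two search directions.
#' @return data.frame `gene_a`, `gene_b`, `evalue_ab`, `evalue_ba`.
#' @export
reciprocalBestHits <- function(hits_ab, hits_ba) {
    topOf <- function(h) {
        h <- h[order(h$query_id, h$e_value, -h$score, h$subject_id), ,
               drop = FALSE]
        h <- h[!duplicated(h$query_id), , drop = FALSE]
        setNames(h$subject_id, h$query_id)
    }
    ta <- topOf(hits_ab); tb <- topOf(hits_ba)
    rows <- list()
    for (a in names(ta)) {
        b <- ta[[a]]
        if (!is.null(tb[[b]]) && !is.na(tb[b]) && tb[[b]] == a) {
            ea <- min(hits_ab$e_value[hits_ab$query_id == a &
                                      hits_ab$subject_id == b])
            eb <- min(hits_ba$e_value[hits_ba$query_id == b &
                                      hits_ba$subject_id == a])
            rows[[a]] <- data.frame(gene_a = a, gene_b = b,
                                    evalue_ab = ea, evalue_ba = eb,
                                    stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(gene_a = character(), gene_b = character(),
                          evalue_ab = numeric(), evalue_ba = numeric(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$gene_a), , drop = FALSE]
}
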