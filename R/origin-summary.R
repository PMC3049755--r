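#' Roll up classifier evidence into one origin assignment per LSG
#'
#' Applies the documented precedence (configurable): chimeric > overprinting
#' > duplication > TE exaptation > outgroup out-of-frame > outgroup
#' intergenic > unknown. Category counts always sum to the LSG total, and the
#' rollup prints every percentage with its numerator and denominator (shares
#' are reported over both the full LSG set and the nuclear subset, since
#' printed denominators differ between the two).
#'
#' @param lsg_ids all LSG gene ids.
#' @param overprint_ids LSGs in LSG:nonLSG overlapping-CDS pairs.
#' @param duplication data.frame with `gene_id`, `detail` rows (details from
#'   `{in_frame, out_of_frame, inverted, retrotransposition,
#'   unequal_crossing_over, tandem, distal, syntelog, wgd}`), possibly several
#'   rows per gene.
#' @param te_ids TE-exapted LSGs.
#' @param chimeric_ids chimeric LSGs.
#' @param outgroup_oof_ids LSGs with out-of-frame CDS hits in the outgroup.
#' @param outgroup_intergenic_ids LSGs chained to outgroup intergenic
#'   regions.
#' @param nuclear_ids subset of `lsg_ids` in the nuclear compartment
#'   (defaults to all).
#' @param precedence character vector ordering the primary mechanisms.
#' @return list with `assignments` (gene_id, primary_mechanism,
#'   mechanism_detail comma-joined) and `rollup` (category, count, and
#'   percentage over each denominator).
#' @export
summarizeOrigins <- function(lsg_ids,
                             overprint_ids = character(),
                             duplication = NULL,
                             te_ids = character(),
                             chimeric_ids = character(),
                             outgroup_oof_ids = character(),
                             outgroup_intergenic_ids = character(),
                             nuclear_ids = lsg_ids,
                             precedence = c("chimeric", "overprinting",
                                            "duplication", "te_exaptation",
                                            "outgroup_out_of_frame",
                                            "outgroup_intergenic",
                                            "unknown")) {
    dup_ids <- if (!is.null(duplication)) unique(duplication$gene_id)
               else character()
    sets <- list(chimeric = chimeric_ids,
                 overprinting = overprint_ids,
                 duplication = dup_ids,
                 te_exaptation = te_ids,
                 outgroup_out_of_frame = outgroup_oof_ids,
                 outgroup_intergenic = outgroup_intergenic_ids)
    unknown_extra <- setdiff(unlist(sets), lsg_ids)
    if (length(unknown_extra))
        stop("classifier evidence for non-LSG gene(s): ",
             paste(head(unknown_extra, 5), collapse = ", "))
    primary <- setNames(rep("unknown", length(lsg_ids)), lsg_ids)
    for (mech in rev(setdiff(precedence, "unknown")))
        primary[intersect(sets[[mech]], lsg_ids)] <- mech
    detail <- setNames(rep("", length(lsg_ids)), lsg_ids)
    if (!is.null(duplication) && nrow(duplication)) {
        for (g in intersect(names(primary)[primary %in%
                                           c("duplication", "chimeric")],
                            duplication$gene_id)) {
            d <- sort(unique(duplication$detail[duplication$gene_id == g]))
            detail[g] <- paste(d, collapse = ",")
        }
    }
    assignments <- data.frame(gene_id = lsg_ids,
                              primary_mechanism = unname(primary[lsg_ids]),
                              mechanism_detail = unname(detail[lsg_ids]),
                              stringsAsFactors = FALSE)
    counts <- table(factor(assignments$primary_mechanism,
                           levels = precedence))
    rollup <- data.frame(category = names(counts),
                         count = as.integer(counts),
                         denominator_all = length(lsg_ids),
                         pct_all = pctShare(as.integer(counts),
                                            rep(length(lsg_ids),
                                                length(counts))),
                         denominator_nuclear = length(nuclear_ids),
                         stringsAsFactors = FALSE)
    nuc <- assignments[assignments$gene_id %in% nuclear_ids, ]
    nuc_counts <- table(factor(nuc$primary_mechanism, levels = precedence))
    rollup$count_nuclear <- as.integer(nuc_counts)
    rollup$pct_nuclear <- pctShare(rollup$count_nuclear,
                                   rep(length(nuclear_ids), nrow(rollup)))
    stopifnot(sum(rollup$count) == length(lsg_ids))
    list(assignments = assignments, rollup = rollup)
}
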