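#' Apply accession SNPs to LSG CDS and call ORF interruptions
#'
#' For each accession, substitution SNPs falling inside an LSG CDS are
#' applied strand-aware, the polymorphic CDS is translated, and SNPs
#' producing a missing start codon (MSC, codon 1 no longer ATG) or an
#' internal stop codon (ISC, a new stop strictly between codon 1 and the
#' terminal codon; a stop arising in the terminal codon is not internal) are
#' called. Undetermined alleles (alt `N`) are recorded as missing data, not
#' calls. Genes untouched in an accession produce no call.
#'
#' @param catalog a [GenomeCatalog-class] (reference accession).
#' @param lsg_ids LSG gene ids to scan.
#' @param snp_table data.frame `accession`, `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single bases; indel rows are rejected).
#' @return list with `calls` (gene_id, accession, type ISC/MSC, chrom, pos,
#'   codon_index 1-based, ref, alt) and `matrix` (gene x accession cells in
#'   `{ref, ISC, MSC, missing}`; ISC takes precedence over MSC in a cell for
#'   display, both calls are kept in `calls`).
#' @export
applySnpsAndCall <- function(catalog, lsg_ids, snp_table) {
    stopifnot(all(c("accession", "chrom", "pos", "ref", "alt") %in%
                  names(snp_table)))
    if (any(nchar(snp_table$ref) != 1L | nchar(snp_table$alt) != 1L))
        stop("only substitution SNPs are supported; indel row(s) present")
    accs <- sort(unique(snp_table$accession))
    cds_ref <- as.character(cdsSequences(catalog, lsg_ids))
    # genomic position -> CDS offset lookup per gene
    maps <- lapply(lsg_ids, function(g) {
        n <- nchar(cds_ref[[g]])
        gp <- cdsPosToGenomic(catalog, g, seq_len(n) - 1L)
        setNames(seq_len(n) - 1L, gp)
    })
    names(maps) <- lsg_ids
    chrom_of <- setNames(catalog@genes$chrom, catalog@genes$gene_id)
    strand_of <- setNames(catalog@genes$strand, catalog@genes$gene_id)

    # validate ref alleles against the reference genome
    bad <- character()
    for (i in seq_len(nrow(snp_table))) {
        base <- as.character(Biostrings::subseq(
            catalog@sequences[[snp_table$chrom[i]]],
            snp_table$pos[i], snp_table$pos[i]))
        if (base != snp_table$ref[i])
            bad <- c(bad, sprintf("%s:%d (ref %s, genome %s)",
                                  snp_table$chrom[i], snp_table$pos[i],
                                  snp_table$ref[i], base))
    }
    if (length(bad))
        stop("SNP ref allele(s) do not match the reference genome: ",
             paste(head(bad, 5), collapse = "; "))

    calls <- list()
    cellmat <- matrix("ref", nrow = length(lsg_ids), ncol = length(accs),
                      dimnames = list(lsg_ids, accs))
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    for (a in accs) {
        snps <- snp_table[snp_table$accession == a, , drop = FALSE]
        for (g in lsg_ids) {
            inside <- snps[snps$chrom == chrom_of[[g]] &
                           as.character(snps$pos) %in% names(maps[[g]]), ,
                           drop = FALSE]
            if (!nrow(inside)) next
            seq0 <- cds_ref[[g]]
            seqv <- strsplit(seq0, "")[[1]]
            touched <- FALSE; missing <- FALSE
            snp_at <- integer()
            for (i in seq_len(nrow(inside))) {
                off <- maps[[g]][[as.character(inside$pos[i])]]
                alt <- inside$alt[i]
                if (strand_of[[g]] == "-") alt <- comp[[alt]]
                if (alt == "N") { missing <- TRUE; next }
                seqv[off + 1L] <- alt
                touched <- TRUE
                snp_at <- c(snp_at, i)
            }
            if (missing && !touched) {
                cellmat[g, a] <- "missing"
                next
            }
            if (!touched) next
            ref_pep <- codonSplit(seq0)
            alt_pep <- codonSplit(paste(seqv, collapse = ""))
            n_codon <- length(ref_pep)
            for (i in snp_at) {
                off <- maps[[g]][[as.character(inside$pos[i])]]
                ci <- off %/% 3L + 1L
                ref_c <- ref_pep[ci]; alt_c <- alt_pep[ci]
                type <- NULL
                if (ci == 1L && ref_c == "ATG" && alt_c != "ATG")
                    type <- "MSC"
                else if (ci > 1L && ci < n_codon &&
                         !(ref_c %in% GENETIC_STOPS) &&
                         alt_c %in% GENETIC_STOPS)
                    type <- "ISC"
                if (is.null(type)) next
                calls[[length(calls) + 1L]] <- data.frame(
                    gene_id = g, accession = a, type = type,
                    chrom = inside$chrom[i], pos = inside$pos[i],
                    codon_index = ci, ref = inside$ref[i],
                    alt = inside$alt[i], stringsAsFactors = FALSE)
                cellmat[g, a] <- if (cellmat[g, a] == "ISC") "ISC" else type
            }
        }
    }
    calls <- if (length(calls)) do.call(rbind, calls) else
        data.frame(gene_id = character(), accession = character(),
                   type = character(), chrom = character(), pos = integer(),
                   codon_index = integer(), ref = character(),
                   alt = character(), stringsAsFactors = FALSE)
    rownames(calls) <- NULL
    list(calls = calls, matrix = cellmat)
}

#' Cross-reference disruption calls against the outgroup alignment
#'
#' For each call, the outgroup base aligned to the polymorphic CDS site is
#' looked up in the [projectOrf()] alignment of that LSG:
#' `CONSERVED_SNP` when it equals the disrupting allele (the outgroup carries
#' the same ISC/MSC), `DELETION` when the alignment has a gap at the site,
#' `NOT_COVERED` when no alignment exists or it does not span the site, else
#' `NOT_DISRUPTED`. Matrix-style side columns (outgroup disruption total,
#' outgroup coverage) are added per gene.
#'
#' @param calls `calls` from [applySnpsAndCall()].
#' @param catalog a [GenomeCatalog-class].
#' @param projections named list of [projectOrf()] results keyed by LSG id
#'   (`NULL` entries = no alignment).
#' @return `calls` with `outgroup_status` plus per-gene
#'   `outgroup_disruptions` (internal stops + frameshift indels in the
#'   outgroup alignment) and `outgroup_coverage_pct`.
#' @export
crossReferenceOutgroup <- function(calls, catalog, projections) {
    if (!nrow(calls)) {
        calls$outgroup_status <- character()
        calls$outgroup_disruptions <- integer()
        calls$outgroup_coverage_pct <- numeric()
        return(calls)
    }
    status <- character(nrow(calls))
    og_dis <- integer(nrow(calls)); og_cov <- rep(NA_real_, nrow(calls))
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    strand_of <- setNames(catalog@genes$strand, catalog@genes$gene_id)
    for (i in seq_len(nrow(calls))) {
        g <- calls$gene_id[i]
        pr <- projections[[g]]
        if (is.null(pr)) { status[i] <- "NOT_COVERED"; next }
        og_dis[i] <- pr$internal_stop_count + pr$frameshift_indel_count
        og_cov[i] <- pr$coverage_pct
        # CDS offset of the SNP
        n <- sum(GenomicRanges::width(catalog@cds[[g]]))
        gp <- cdsPosToGenomic(catalog, g, seq_len(n) - 1L)
        off <- which(gp == calls$pos[i]) - 1L
        if (!length(off)) { status[i] <- "NOT_COVERED"; next }
        ap <- strsplit(pr$aln_cds, "")[[1]]
        as_ <- strsplit(pr$aln_region, "")[[1]]
        pat_pos <- cumsum(ap != "-") - 1L
        col <- which(ap != "-" & pat_pos == off)
        if (!length(col)) { status[i] <- "NOT_COVERED"; next }
        og_base <- as_[col]
        alt <- calls$alt[i]
        if (strand_of[[g]] == "-") alt <- comp[[alt]]
        if (og_base == "-") status[i] <- "DELETION"
        else if (og_base == alt) status[i] <- "CONSERVED_SNP"
        else status[i] <- "NOT_DISRUPTED"
    }
    calls$outgroup_status <- status
    calls$outgroup_disruptions <- og_dis
    calls$outgroup_coverage_pct <- og_cov
    calls
}

#' Parsimony inference of gene birth vs gene loss
#'
#' A disruption conserved in the outgroup (the outgroup carries the same
#' disrupting allele) makes the disruption ancestral, so the intact ORF is
#' derived: gene birth in the focal lineage. An outgroup that is not
#' disrupted at the site, with an intact outgroup ORF, while the disruption
#' is confined to a minority (fewer than half) of genotyped accessions, makes
#' gene loss the most parsimonious explanation. Everything else is ambiguous.
#'
#' @param calls cross-referenced calls ([crossReferenceOutgroup()]).
#' @param projections named [projectOrf()] list (for outgroup ORF intactness).
#' @param n_accessions number of genotyped accessions (site denominators
#'   exclude accessions with missing data at the gene; pass the per-gene
#'   effective count via `genotyped` to override).
#' @param genotyped optional named vector of per-gene genotyped accession
#'   counts.
#' @return data.frame `gene_id`, `n_disrupted_accessions`, `n_genotyped`,
#'   `outgroup_status`, `scenario` in
#'   `{birth_in_focal, loss_in_focal, ambiguous}`.
#' @export
inferBirthVsLoss <- function(calls, projections, n_accessions,
                             genotyped = NULL) {
    genes <- unique(calls$gene_id)
    rows <- lapply(genes, function(g) {
        sub <- calls[calls$gene_id == g, , drop = FALSE]
        n_dis <- length(unique(sub$accession))
        n_gen <- if (!is.null(genotyped) && !is.null(genotyped[[g]]))
            genotyped[[g]] else n_accessions
        pr <- projections[[g]]
        og_intact <- !is.null(pr) && pr$category == "INTACT"
        status <- if (any(sub$outgroup_status == "CONSERVED_SNP"))
            "CONSERVED_SNP" else sub$outgroup_status[1]
        scenario <- if (status == "CONSERVED_SNP") "birth_in_focal"
            else if (status == "NOT_DISRUPTED" && og_intact &&
                     n_dis < n_gen / 2) "loss_in_focal"
            else "ambiguous"
        data.frame(gene_id = g, n_disrupted_accessions = n_dis,
                   n_genotyped = n_gen, outgroup_status = status,
                   scenario = scenario, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Summarise polymorphic LSGs by lineage level and SNP type
#'
#' Counts of distinct LSGs per (lineage level, SNP type) with
#' expression-support subtotals (gene-model support, locus support) and the
#' overlap between the ISC and MSC gene sets.
#'
#' @param calls [applySnpsAndCall()] calls.
#' @param records LSG records with `gene_id`, `lineage_level`.
#' @param gene_table gene table with `gene_id`, `expression_support`.
#' @return list with `table` (lineage_level, type, n_genes,
#'   gene_model_support, locus_support) and `isc_msc_overlap` (count of
#'   genes carrying both call types).
#' @export
summarizePolymorphicLsgs <- function(calls, records, gene_table) {
    supp <- setNames(gene_table$expression_support, gene_table$gene_id)
    lev <- setNames(records$lineage_level, records$gene_id)
    rows <- list()
    for (ll in sort(unique(lev[unique(calls$gene_id)]))) {
        for (ty in c("ISC", "MSC")) {
            genes <- unique(calls$gene_id[calls$type == ty &
                                          lev[calls$gene_id] == ll])
            if (!length(genes)) next
            rows[[length(rows) + 1L]] <- data.frame(
                lineage_level = ll, type = ty, n_genes = length(genes),
                gene_model_support = sum(supp[genes] ==
                                         "gene_model_supported"),
                locus_support = sum(supp[genes] %in%
                                    c("gene_model_supported",
                                      "locus_supported")),
                stringsAsFactors = FALSE)
        }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(lineage_level = character(), type = character(),
                   n_genes = integer(), gene_model_support = integer(),
                   locus_support = integer(), stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    isc <- unique(calls$gene_id[calls$type == "ISC"])
    msc <- unique(calls$gene_id[calls$type == "MSC"])
    list(table = tab, isc_msc_overlap = length(intersect(isc, msc)))
}
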