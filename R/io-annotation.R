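#' @importFrom rtracklayer import
NULL

# Compartment from a chromosome name: chrM*/mito* -> mitochondrial,
# chrC*/chloro*/Pt -> chloroplast, anything else nuclear.
compartmentOf <- function(chrom) {
    ifelse(grepl("^(chrM|mit)", chrom, ignore.case = TRUE), "mitochondrial",
    ifelse(grepl("^(chrC|chlo|Pt)", chrom, ignore.case = TRUE), "chloroplast",
           "nuclear"))
}

.firstChar <- function(x) {
    vapply(x, function(e) if (length(e)) as.character(e)[1] else NA_character_,
           character(1))
}

#' Read genome annotation into a GenomeCatalog
#'
#' Parses a GFF3 gene/TE annotation (via \pkg{rtracklayer}) and the matching
#' FASTA sequences into the validated [GenomeCatalog-class] container that all
#' downstream operations consume. GFF3 1-based inclusive coordinates are kept
#' as 1-based closed \code{GRanges}. When a locus carries several isoforms the
#' representative model is the one with the longest total CDS, ties broken by
#' lexicographic model id. Transposable-element features
#' (\code{transposable_element} / \code{repeat_region} types, or a separate
#' GFF3/BED file) are routed to the TE slot.
#'
#' @param gff3_source path to the gene (and optionally TE) GFF3 file.
#' @param fasta_source path to the genome FASTA.
#' @param te_source optional path to a separate TE annotation (GFF3 or BED;
#'   BED must carry the superfamily in the name column as `te_id|superfamily`).
#' @return a [GenomeCatalog-class]. Models whose CDS length is not a multiple
#'   of three are kept but flagged \code{intact = FALSE} with a warning.
#' @export
readGenomeAnnotation <- function(gff3_source, fasta_source, te_source = NULL) {
    seqs <- Biostrings::readDNAStringSet(fasta_source)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    gff <- rtracklayer::import(gff3_source, format = "gff3")

    chroms <- as.character(GenomeInfoDb::seqnames(gff))
    missing_seq <- setdiff(unique(chroms), names(seqs))
    if (length(missing_seq))
        stop("sequence id(s) in GFF3 absent from FASTA: ",
             paste(missing_seq, collapse = ", "))

    type <- as.character(gff$type)
    te_types <- c("transposable_element", "transposon_fragment",
                  "repeat_region")
    te <- gff[type %in% te_types]
    if (!is.null(te_source)) {
        ext <- tolower(tools::file_ext(te_source))
        if (ext == "bed") {
            bed <- rtracklayer::import(te_source, format = "bed")
            nm <- strsplit(as.character(bed$name), "|", fixed = TRUE)
            bed$te_id <- vapply(nm, `[`, character(1), 1L)
            bed$superfamily <- vapply(nm, function(x)
                if (length(x) > 1) x[2] else "", character(1))
            te2 <- bed
        } else {
            te2 <- rtracklayer::import(te_source, format = "gff3")
            te2 <- te2[as.character(te2$type) %in% te_types]
        }
        te <- c(granges_with_te_meta(te), granges_with_te_meta(te2))
    } else {
        te <- granges_with_te_meta(te)
    }

    mrna <- gff[type == "mRNA"]
    exon <- gff[type == "exon"]
    cds <- gff[type == "CDS"]
    gene <- gff[type == "gene"]

    mrna_parent <- .firstChar(mrna$Parent)
    exon_parent <- .firstChar(exon$Parent)
    cds_parent <- .firstChar(cds$Parent)
    mrna_id <- as.character(mrna$ID)

    # total CDS length per model
    cds_len <- tapply(GenomicRanges::width(cds), cds_parent, sum)
    # representative model per gene: longest CDS, ties lexicographic
    ord <- order(mrna_parent,
                 -as.numeric(cds_len[mrna_id]),
                 mrna_id)
    keep <- !duplicated(mrna_parent[ord])
    rep_models <- mrna_id[ord][keep]
    rep_gene <- mrna_parent[ord][keep]

    exons_l <- S4Vectors::split(exon[exon_parent %in% rep_models],
                                factor(exon_parent[exon_parent %in%
                                                   rep_models],
                                       levels = rep_models))
    cds_l <- S4Vectors::split(cds[cds_parent %in% rep_models],
                              factor(cds_parent[cds_parent %in% rep_models],
                                     levels = rep_models))

    gene_meta <- data.frame(
        gene_id = rep_gene,
        model_id = rep_models,
        stringsAsFactors = FALSE)
    gidx <- match(gene_meta$gene_id, as.character(gene$ID))
    if (anyNA(gidx))
        stop("mRNA Parent gene(s) missing from GFF3: ",
             paste(gene_meta$gene_id[is.na(gidx)], collapse = ", "))
    gene_meta$chrom <- as.character(GenomeInfoDb::seqnames(gene))[gidx]
    gene_meta$strand <- as.character(GenomicRanges::strand(gene))[gidx]
    gene_meta$start <- GenomicRanges::start(gene)[gidx]
    gene_meta$end <- GenomicRanges::end(gene)[gidx]
    gene_meta$compartment <- compartmentOf(gene_meta$chrom)
    gene_meta$is_te_gene <- type[match(gene_meta$gene_id,
                                       as.character(gff$ID))] ==
        "transposable_element_gene"
    gene_meta$is_te_gene[is.na(gene_meta$is_te_gene)] <- FALSE
    supp <- if (!is.null(gene$expression_support))
        as.character(gene$expression_support)[gidx] else NA_character_
    gene_meta$expression_support <- ifelse(is.na(supp), "none", supp)
    gene_meta$n_exons <- as.integer(lengths(exons_l)[gene_meta$model_id])
    gene_meta$cds_length <- as.integer(cds_len[gene_meta$model_id])
    gene_meta$intact <- gene_meta$cds_length %% 3L == 0L
    if (any(!gene_meta$intact))
        warning("CDS length not divisible by 3, model(s) flagged non-intact: ",
                paste(gene_meta$model_id[!gene_meta$intact], collapse = ", "))

    # key structure lists by gene_id (one representative model per gene)
    names(exons_l) <- gene_meta$gene_id[match(names(exons_l),
                                              gene_meta$model_id)]
    names(cds_l) <- gene_meta$gene_id[match(names(cds_l),
                                            gene_meta$model_id)]

    rownames(gene_meta) <- NULL
    new("GenomeCatalog",
        sequences = seqs,
        genes = gene_meta[order(gene_meta$chrom, gene_meta$start), ,
                          drop = FALSE],
        exons = exons_l,
        cds = cds_l,
        te = te)
}

granges_with_te_meta <- function(gr) {
    out <- GenomicRanges::granges(gr)
    out$te_id <- if (!is.null(gr$te_id)) as.character(gr$te_id)
                 else if (!is.null(gr$ID)) as.character(gr$ID)
                 else paste0("te", seq_along(gr))
    out$superfamily <- if (!is.null(gr$superfamily))
        as.character(gr$superfamily) else character(length(gr))
    out
}

#' Write a GenomeCatalog back to GFF3 + FASTA
#'
#' Deterministic writer (fixed attribute order, unix newlines) used by the
#' simulator and by round-trip tests. TE fragments go to a separate GFF3.
#'
#' @param catalog a [GenomeCatalog-class].
#' @param gff3_path,fasta_path,te_path output paths (`te_path` optional).
#' @return invisibly, the gff3 path.
#' @export
writeGenomeAnnotation <- function(catalog, gff3_path, fasta_path,
                                  te_path = NULL) {
    g <- catalog@genes
    lines <- c("##gff-version 3")
    for (i in seq_len(nrow(g))) {
        gid <- g$gene_id[i]; mid <- g$model_id[i]
        attrs <- sprintf("ID=%s;expression_support=%s", gid,
                         g$expression_support[i])
        lines <- c(lines, paste(g$chrom[i], "sim", "gene", g$start[i], g$end[i],
                                ".", g$strand[i], ".", attrs, sep = "\t"))
        lines <- c(lines, paste(g$chrom[i], "sim", "mRNA", g$start[i], g$end[i],
                                ".", g$strand[i], ".",
                                sprintf("ID=%s;Parent=%s", mid, gid),
                                sep = "\t"))
        ex <- catalog@exons[[gid]]
        ex <- ex[order(GenomicRanges::start(ex))]
        for (j in seq_along(ex))
            lines <- c(lines, paste(g$chrom[i], "sim", "exon",
                                    GenomicRanges::start(ex)[j],
                                    GenomicRanges::end(ex)[j], ".",
                                    g$strand[i], ".",
                                    sprintf("Parent=%s", mid), sep = "\t"))
        cd <- catalog@cds[[gid]]
        cd <- cd[order(GenomicRanges::start(cd))]
        ph <- if (!is.null(cd$phase)) cd$phase else cdsPhases(cd, g$strand[i])
        for (j in seq_along(cd))
            lines <- c(lines, paste(g$chrom[i], "sim", "CDS",
                                    GenomicRanges::start(cd)[j],
                                    GenomicRanges::end(cd)[j], ".",
                                    g$strand[i], ph[j],
                                    sprintf("Parent=%s", mid), sep = "\t"))
    }
    writeLines(lines, gff3_path, sep = "\n")
    Biostrings::writeXStringSet(catalog@sequences, fasta_path, width = 70)
    if (!is.null(te_path)) {
        te <- catalog@te
        tl <- c("##gff-version 3")
        for (j in seq_along(te))
            tl <- c(tl, paste(as.character(GenomeInfoDb::seqnames(te))[j],
                              "sim", "transposable_element",
                              GenomicRanges::start(te)[j],
                              GenomicRanges::end(te)[j], ".",
                              as.character(GenomicRanges::strand(te))[j], ".",
                              sprintf("ID=%s;superfamily=%s", te$te_id[j],
                                      te$superfamily[j]), sep = "\t"))
        writeLines(tl, te_path, sep = "\n")
    }
    invisible(gff3_path)
}

# GFF3 phases for CDS segments sorted in genomic order.
cdsPhases <- function(cd, strand) {
    w <- GenomicRanges::width(cd)
    if (strand == "-") w <- rev(w)
    ph <- (3L - (cumsum(c(0L, w[-length(w)])) %% 3L)) %% 3L
    if (strand == "-") rev(ph) else ph
}
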