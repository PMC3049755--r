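#' Construct a ScenarioConfig
#'
#' Default study conditions: 140 conserved background genes plus 60 planted
#' events (200 genes in total, a handful of them on small organellar
#' chromosomes), about 0.5 intergenic fraction, 5 percent outgroup
#' divergence, 19 accessions, 63 expression tissues/stages with three
#' replicates, breadth targets 4 (LSG-like) vs 51 (conserved), six stress
#' contrasts with planted enrichment odds 5.
#'
#' @param seed integer seed (drives every random draw).
#' @param n_background_genes conserved background genes.
#' @param n_planted named integer vector over the planted classes (defaults
#'   sum to 60).
#' @param intergenic_fraction,te_density,outgroup_divergence,n_accessions
#'   see [ScenarioConfig-class].
#' @param expression named numeric vector of expression parameters.
#' @return validated [ScenarioConfig-class].
#' @export
scenarioConfig <- function(seed = 1L,
                           n_background_genes = 140L,
                           n_planted = c(overprint = 6L, dup_inframe = 6L,
                                         dup_frameshift = 5L,
                                         dup_inverted = 5L, retrocopy = 5L,
                                         te_exapt = 6L, chimera = 5L,
                                         de_novo = 6L,
                                         differential_loss = 4L,
                                         accession_isc = 6L,
                                         accession_msc = 6L),
                           intergenic_fraction = 0.5,
                           te_density = c("RC/Helitron" = 10,
                                          "DNA/MuDR" = 8,
                                          "LTR/Gypsy" = 8,
                                          "LTR/Copia" = 6,
                                          "DNA/En-Spm" = 6),
                           outgroup_divergence = 0.05,
                           n_accessions = 19L,
                           expression = c(n_tissues = 63, n_replicates = 3,
                                          lsg_breadth_mean = 4,
                                          nonlsg_breadth_mean = 51,
                                          lsg_expr_shift = -1.5,
                                          n_stress_contrasts = 6,
                                          planted_enrichment_odds = 5)) {
    full <- setNames(rep(0L, length(.PLANT_CLASSES)), .PLANT_CLASSES)
    full[names(n_planted)] <- as.integer(n_planted)
    expr_full <- c(n_tissues = 63, n_replicates = 3, lsg_breadth_mean = 4,
                   nonlsg_breadth_mean = 51, lsg_expr_shift = -1.5,
                   n_stress_contrasts = 6, planted_enrichment_odds = 5)
    expr_full[names(expression)] <- expression
    new("ScenarioConfig", seed = as.integer(seed),
        n_background_genes = as.integer(n_background_genes),
        n_planted = full, intergenic_fraction = intergenic_fraction,
        te_density = te_density,
        outgroup_divergence = outgroup_divergence,
        n_accessions = as.integer(n_accessions),
        expression = expr_full)
}

setMethod("show", "ScenarioConfig", function(object) {
    cat(sprintf("ScenarioConfig: seed %d, %d background genes, %d planted events, divergence %.3f\n",
                object@seed, object@n_background_genes,
                sum(object@n_planted), object@outgroup_divergence))
})

#' Generate the background focal genome
#'
#' Builds the conserved background genes (1-6 exons, valid ORFs of 100-500
#' codons), small organellar chromosomes, the transposable-element library
#' and intergenic TE fragments. Deterministic under a fixed seed. Planted
#' origin events are added by [plantOriginEvents()].
#'
#' @param config a [ScenarioConfig-class].
#' @return a simulation state (list of class `lsg_sim`) carrying the locus
#'   blueprint and ground-truth skeleton.
#' @export
generateGenome <- function(config) {
    withSeed(childSeed(config@seed, "genome"), {
        sim <- list(config = config, loci = list(), truth = list(),
                    te_library = list())
        # TE library: one consensus per superfamily
        for (sf in names(config@te_density))
            sim$te_library[[sf]] <- randomDna(1200L)

        n_bg <- config@n_background_genes
        n_mito <- min(6L, n_bg); n_chloro <- min(4L, n_bg)
        n_nuc <- n_bg - n_mito - n_chloro
        if (n_nuc < 20L)
            stop("capacity error: too few background genes to host planted events; increase n_background_genes")
        mk_bg <- function(i, chrom) {
            n_ex <- sample(1:6, 1, prob = c(0.25, 0.2, 0.2, 0.15, 0.1, 0.1))
            n_cod <- sample(100:500, 1)
            makeGeneLocus(sprintf("bg%03d", i), makeOrf(n_cod), n_ex,
                          strand = sample(c("+", "-"), 1), chrom = chrom,
                          expression_support = sample(
                              c("gene_model_supported", "locus_supported",
                                "none"), 1, prob = c(0.5, 0.3, 0.2)))
        }
        idx <- 0L
        for (i in seq_len(n_nuc)) {
            idx <- idx + 1L
            sim$loci[[length(sim$loci) + 1L]] <- mk_bg(idx, "chr1")
        }
        for (i in seq_len(n_mito)) {
            idx <- idx + 1L
            sim$loci[[length(sim$loci) + 1L]] <- mk_bg(idx, "chrM")
        }
        for (i in seq_len(n_chloro)) {
            idx <- idx + 1L
            sim$loci[[length(sim$loci) + 1L]] <- mk_bg(idx, "chrC")
        }
        # intergenic TE fragments as their own loci
        ti <- 0L
        for (sf in names(config@te_density)) {
            for (j in seq_len(round(config@te_density[[sf]]))) {
                ti <- ti + 1L
                lib <- sim$te_library[[sf]]
                w <- sample(150:800, 1)
                a <- sample(seq_len(nchar(lib) - w), 1)
                frag <- mutateString(substr(lib, a, a + w - 1L), 0.10)
                sim$loci[[length(sim$loci) + 1L]] <- list(
                    id = sprintf("teloc%03d", ti), chrom = "chr1",
                    seq = frag, genes = list(),
                    te = list(list(te_id = sprintf("TE%03d", ti),
                                   superfamily = sf, start = 1L,
                                   end = nchar(frag))))
            }
        }
        # shuffle nuclear loci order
        is_nuc <- vapply(sim$loci, function(l) l$chrom == "chr1", logical(1))
        sim$loci[is_nuc] <- sim$loci[sample(which(is_nuc))]
        class(sim) <- "lsg_sim"
        sim
    })
}

# Uniform substitution mutation of a plain string.
mutateString <- function(x, rate) {
    n <- nchar(x)
    k <- rbinom(1, n, rate)
    if (k == 0L) return(x)
    pos <- sample.int(n, k)
    v <- strsplit(x, "")[[1]]
    bases <- c("A", "C", "G", "T")
    v[pos] <- vapply(v[pos], function(b) sample(setdiff(bases, b), 1),
                     character(1))
    paste(v, collapse = "")
}
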