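Package: lsgOrigins
Title: Classification of Lineage-Specific Genes and Their Evolutionary Origins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies lineage-specific (orphan) genes by step-wise filtering of
    homology-hit tables across database tiers and classifies their evolutionary
    origins: overprinting at overlapping coding sequences, duplication of
    conserved paralogs (in-frame, out-of-frame, inverted; retrotransposition
    versus unequal crossing over; tandem, distal or syntelog context),
    transposable-element exaptation and chimeric fusions. Species-only genes are
    traced into an outgroup genome by scaffold-hit chaining and frameshift-aware
    ORF projection into intact, missing-start, internal-stop/indel and combined
    disruption categories, complemented by Nei-Gojobori (1986) dN/dS for
    reciprocal-best-hit ortholog pairs, per-accession ORF-interrupting SNP calls
    with outgroup cross-referencing, and expression breadth and stress-response
    enrichment statistics. A synthetic-genome simulator plants labelled origin
    events, outgroup disruptions, accession SNPs and expression signal so every
    pipeline stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
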