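---
title: "Classifying lineage-specific genes and their origins with lsgOrigins"
author: "lsgOrigins authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying lineage-specific genes and their origins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Every sequenced genome carries protein-coding genes with no recognizable
homolog outside a narrow taxonomic lineage — lineage-specific genes (LSGs),
also called orphan genes or taxonomically restricted genes. Their existence
poses a concrete evolutionary question: where does a gene come from when no
relative exists to compare it with? `lsgOrigins` implements, as a tested and
reusable pipeline, the classical comparative-genomics answer: call LSGs by
step-wise homology filtering, then interrogate the genome itself (and a close
outgroup genome) for the footprints of the mechanisms known to create novel
genes:

* **overprinting** — a new reading frame arising inside or across an existing
  coding sequence, detected as CDS:CDS genomic overlap (introns and UTRs are
  ignored because lineage specificity is defined on the peptide);
* **duplication followed by divergence** — peptide-level in-frame paralogy,
  or nucleotide-only out-of-frame similarity (frameshifted or inverted
  copies), refined into retrotransposition versus unequal crossing over by
  intron–exon boundary geometry, and into tandem / distal / syntelog context
  by gene order and collinearity tables;
* **transposon exaptation** — coding exons overlapping annotated
  transposable-element fragments, tallied per TE superfamily;
* **chimeric origin** — near-disjoint query regions matching different,
  mutually non-homologous parents (including TE or overlap evidence);
* **de novo origination or differential loss** — species-only LSGs traced
  into the outgroup by scaffold-hit chaining and ORF projection, classifying
  the outgroup state as an intact ORF, a missing start codon (MSC), internal
  stop codons / frameshift indels (ISC), or both.

Two population-scale signatures complete the picture: accession-level SNPs
that interrupt an LSG's ORF (ISC/MSC per accession, with a parsimony
birth-versus-loss call against the outgroup), and expression signatures
(narrow tissue breadth, low expression level, enrichment among
stress-up-regulated genes, tested with the hypergeometric tail).

## Pipeline and thresholds

The analysis runs in dependency order: catalog → within-genome origin
classification → outgroup tracing → polymorphism → expression
(`runPipeline()`). Every numeric threshold lives in one `ThresholdConfig`
object and is echoed into the run summary:

| parameter | default | role |
|---|---|---|
| `lsg_evalue_cutoff` | 1e-3 | a cross-lineage hit below this eliminates a gene from the LSG set |
| `within_genome_evalue` | 0.01 | paralog, outgroup and distant-genome searches |
| `min_query_coverage_pct` | 10 | merged-HSP coverage below which a pair or projection is discarded |
| `boundary_tolerance_bp` | 5 | intron–exon boundaries this close (inclusive) count as matching |
| `scaffold_chain_gap_bp` | 4000 | single-linkage gap for chaining outgroup scaffold hits |
| `intact_orf_coverage_pct` | 95 | intact projections at or above this are putative shared un-annotated ORFs |
| `distant_flank_bp` | 100 | flank added to a genomic hit before the reciprocal check |
| `de_adj_p`, `de_min_abs_log2fc` | 0.01, log2(1.5) | differential-expression thresholds |
| `enrichment_p` | 0.05 | hypergeometric enrichment bound |
| `tandem_max_intervening_genes` | 10 | tandem-versus-distal cutoff |

The published shorthand "10e-3" for the LSG e-value cutoff is ambiguous
(10^-3 or 10 x 10^-3); it is read here as 1e-3, the conventional
interpretation, and is configurable. Survivor sets are monotonically
non-increasing in the cutoff, which the suite verifies.

A few genuinely open design points were fixed as follows, and are
configurable where they are judgement calls:

* *Overlap levels.* Gene:gene overlap uses CDS intervals; TE exaptation uses
  exon intervals by default (both levels selectable), since exonic TE DNA is
  exapted even when untranslated.
* *"Non-overlapping" evidence for chimeras* is quantified as at most 10%
  mutual overlap of the shorter query region; no published figure exists.
* *Orientation* of a merged nucleotide pair follows its dominant (longest)
  HSP rather than a column majority.
* *Self-hits, hits to other LSGs and to overlapping gene models* are removed
  before duplication analysis, so overlap evidence is not double-counted as
  paralogy.
* *Tandem* means at most 10 intervening annotated genes, an explicit
  approximation of a collinearity tool's local-duplication call.
* *Start codons.* Only ATG is recognized. When a projection's alignment does
  not reach codon 1 the start is not judged missing; the projection carries a
  `start_covered = FALSE` flag and is classified from the covered portion.
* *Representative models.* When an annotation carries several isoforms the
  longest-CDS model is representative, ties broken lexicographically.
* *Reported spreads* are median ± semi-interquartile range, (Q3 − Q1)/2;
  percentages are rounded half-away-from-zero to two decimals, and every
  printed percentage carries its numerator and denominator.

## The search stand-in and the projection stand-in

External search engines and spliced gene-prediction tools are inputs, not
dependencies. For synthetic data two stand-ins are provided:

* `toySearch()` performs exact Smith–Waterman local alignment (dynamic
  programming via Biostrings) with match +2 / mismatch −3, gap open 5 /
  extend 2 for nucleotides and BLOSUM62 11/1 for peptides, searching both
  strands and reporting minus-strand alignments as inverted. E-values use the
  Karlin–Altschul form K·m·n·exp(−λS) with the published gapped constants for
  these schemes (λ = 0.625, K = 0.41 nucleotide; λ = 0.267, K = 0.041
  peptide); they are indicative and only compared against coarse cutoffs.
  Subjects longer than 2 kb are searched through windows around exact k-mer
  seeds (k = 12 nucleotide, k = 5 peptide) — a documented heuristic; pairs
  with a length product up to about 100×100 are always aligned exactly, which
  is the regime the oracle-equivalence tests cover.
* `projectOrf()` replaces spliced gene prediction with a global–local
  affine-gap nucleotide alignment of the LSG CDS against the chained outgroup
  region, followed by a codon walk: frameshift indels are gap runs of length
  not divisible by three; internal stops are read in the frame projected from
  the CDS (tracked through gaps), excluding the terminal stop codon; coverage
  is alignment columns over CDS length, exceeding 100 only through insertions
  in the region. This is exact for intron-free regions — which the synthetic
  outgroup guarantees — and a declared limitation for real data, where
  intron-bearing outgroup loci would inflate the frameshift count.

dN/dS uses Nei–Gojobori (1986) pathway counting with Jukes–Cantor
correction: site counts average both sequences (stop-creating changes count
as nonsynonymous so sites sum to three per codon), multi-hit codons average
all single-step paths avoiding stops, and the ratio is undefined when dS = 0
(except the clean case of zero nonsynonymous differences with synonymous
differences present, which is reported as 0). Codon-model maximum-likelihood
estimators are out of scope; the estimator hook is a function argument away.

## What the simulator emulates — and what it does not

`simulateScenario()` builds a focal genome whose every gene carries a ground
truth label. The default configuration is the study condition set used by
the acceptance checks: 200 genes (140 conserved background genes, a few of
them on small mitochondrial and chloroplast chromosomes, plus 60 planted
events covering every origin class), about 0.4 Mb of chromosome 1 at roughly
half intergenic DNA, TE fragments from five superfamily consensus libraries,
a 5% diverged outgroup cut into five scaffolds, 19 accessions, and 63
expression tissues with three replicates where LSG-like genes have median
breadth 4 versus 51 for conserved genes (the published breadth medians),
are shifted down in log2 expression, and enter stress-contrast up-sets with
odds 5. These sizes keep generation under a minute and the full pipeline
within a few minutes on one core.

Construction details that matter for interpretation:

* Background ORFs are stop-free by construction, and all mutation processes
  (within-genome copies, outgroup divergence) are frame-aware in *every*
  annotated frame — in overprinted pairs both overlapping frames are
  respected — so only planted disruptions disrupt.
* Outgroup derivation accepts nonsynonymous changes with probability 0.2 in
  background genes and 0.8 in LSG loci, planting the rate classes that the
  reciprocal-best-hit dN/dS comparison recovers.
* Retrocopies and chimeras match their donors' outgroup orthologs at the
  peptide level, so the filter keeps them family-level — exactly as the
  operational species-only definition dictates; outgroup ORF-disruption
  categories are therefore planted on the intron-free classes that actually
  reach projection (overprints, frameshifted/inverted copies, TE exaptations
  and accession genes).
* Cross-lineage database tiers are synthesized from ground truth (with
  borderline e-values, later-tier eliminations, within-lineage decoys and
  domain flags) because no out-of-lineage database exists at desk scale;
  within-genome, outgroup-proteome and outgroup-scaffold searches are
  executed for real.

The simulator does not attempt realistic base composition, TE sequence
models, recombination, isoforms or sequencing noise. Passing recovery tests
therefore demonstrates that the classification logic is correct under its
stated assumptions — not that real-genome annotation noise, splice-form
ambiguity or deep divergence would leave accuracy untouched.

## A worked run

```{r}
library(lsgOrigins)
cfg <- scenarioConfig(seed = 1)
sim <- simulateScenario(cfg, out_dir = "scenario1")   # writes all inputs
bundle <- runPipeline(sim, out_dir = "reports1")
bundle$origins$rollup          # Figure-1-style origin counts
bundle$projection_summary      # outgroup ORF categories with coverage
bundle$summary$recovery        # ground-truth recovery metrics
```

Real data enter through the same surfaces: `readGenomeAnnotation()` for
FASTA + GFF3, `readHitTable()` for 12-column tabular alignment files (one
per database tier), TSV tables for syntelogs, SNPs, expression calls and DE
contrasts. Users with real microarray or RNA-seq data should supply
moderated DE tables; the built-in two-sample t test with
Benjamini–Hochberg adjustment is an explicit stand-in for synthetic data
only.

## Known limitations

* Projection is unspliced; intron-bearing outgroup loci are mis-counted as
  frameshifts (flagged above).
* E-values from `toySearch()` are calibrated for its fixed scoring schemes
  only; scores, not e-values, drive top-hit selection.
* The hypergeometric enrichment grid reports raw per-contrast p-values (with
  a BH-adjusted column for reference), mirroring per-contrast threshold
  practice rather than a family-wise correction.
* Mitochondrial and chloroplast genes are cataloged and counted but not
  traced into the outgroup, which contains nuclear sequence only.
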