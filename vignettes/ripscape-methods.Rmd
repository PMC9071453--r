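---
title: "Methods: intron-aware RIP-seq quantification and poly(A) tail statistics"
author: "ripscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intron-aware RIP-seq quantification and poly(A) tail statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripscape)
suppressPackageStartupMessages(library(GenomicRanges))
```

# The analysis problem

RNA immunoprecipitation sequencing (RIP-seq) against the nuclear and
cytoplasmic poly(A)-binding proteins (PABPN, PABPC) recovers transcript
populations in which splicing is often incomplete: polyadenylation can
finish before intron removal does, so a substantial fraction of bound
RNA is pre-mRNA. Standard RNA-seq quantification ignores intronic reads
and mis-handles two annotation pathologies that dominate intronic space:

1. **Overlapping gene annotations.** Reads falling where two genes'
   annotated space overlaps cannot be assigned to either gene, and any
   tie-breaking rule biases long genes or exonic features.
2. **Readthrough transcripts.** Annotation entries spanning two adjacent
   genes make large regions *appear* shared even though the readthrough
   isoform is a rare event.

A further artifact inflates gene-level signal: transcription that fails
to terminate at an upstream gene runs through the intergenic region into
the next gene's annotation (downstream-of-gene, DoG, readthrough), so a
gene can look bound when the reads actually belong to its upstream
neighbour's runaway transcript.

ripscape implements the bespoke computational steps of this analysis as
a reusable, tested pipeline: annotation sanitization, exon/intron-aware
quantification, the upstream-readthrough gene filter, enrichment
classification of a differential table, and per-gene poly(A) tail
statistics from nanopore direct-RNA long reads. A deterministic
synthetic-data generator with planted ground truth makes every stage
verifiable without any sequencing download.

# Annotation sanitization

`sanitizeAnnotation()` runs four steps:

* **Supplemental merge** (`mergeSupplementalGenes()`): genes present in
  one annotation source but missing from another are added verbatim,
  keyed on `gene_id` (optionally also gene symbol). Coordinate conflicts
  defer to the primary annotation and are logged. The specific gene list
  is data, not code; any second `GeneAnnotation` can be merged.
* **Readthrough removal** (`dropReadthroughTranscripts()`): every
  transcript tagged `readthrough_transcript` (the gencode convention) is
  removed, gene spans are recomputed as the hull of the surviving
  transcripts, and genes left without transcripts are dropped with a
  report.
* **De-overlap** (`removeSharedRegions()`): the set of bases covered by
  two or more gene *spans* is subtracted from every gene's annotated
  space and recorded as an audit trail. Span-level (rather than
  feature-level) overlap is used deliberately: the problem being solved
  is reads at genomic locations where multiple genes are annotated, and
  an exon of one gene inside an intron of another is exactly such a
  location, so it is removed from both genes.
* **Intron derivation** (`deriveIntronRegions()`): per gene, intronic
  space is the span minus the union of all surviving transcripts' exons
  minus the removed shared space. Genes with no intronic bases are
  flagged intronless; genes with no surviving annotated bases at all are
  dropped and reported.

**Strand mode.** Whether de-overlap should treat the two strands as one
genomic space is a genuinely open design choice: removing whole
"genomic space" argues for strand-blind removal, while a stranded
library could in principle resolve antisense overlaps. The default is
`strandMode = "blind"`; `"aware"` computes shared space per strand and
is exercised by the test suite. Both are available as a flag.

**Coordinate convention.** All interval arithmetic is delegated to
IRanges/GenomicRanges, whose native representation is 1-based closed
intervals; rtracklayer performs the GTF boundary conversion. The design
goal usually served by a 0-based half-open internal convention —
unambiguous, off-by-one-free interval algebra — is met here by using the
interval engine for every operation (coverage, subtraction,
intersection) rather than re-implementing any of it.

The two structural invariants — per-gene exonic/intronic disjointness
and total cross-gene disjointness — are enforced by the
`SanitizedAnnotation` validity method, and the test suite additionally
confirms them against a brute-force per-base ownership oracle on
synthetic genomes.

# Exon/intron-aware quantification

`assignReads()` re-implements featureCounts-style assignment under an
explicit contract: a fragment's aligned blocks are intersected with each
gene's exonic and intronic interval sets on the strand implied by the
library chemistry; a (gene, region) pair is a candidate when the total
overlap is at least `minOverlap = 20` bases; candidates in two or more
genes make the fragment ambiguous; within one gene the larger overlap
wins, with ties going to exonic. The 20-base floor and the
reverse-stranded default (`strandedness = "reverse"`, matching
dUTP-stranded chemistry) are the parameters a practitioner would pass to
featureCounts for such a library; both are flags. The exon-over-intron
tie-break is documented here because feature-level resolution inside a
gene is otherwise underdetermined. Cross-gene ambiguity cannot arise
from shared bases after sanitization, but two genes can still abut, so
ambiguous fragments are counted (`onAmbiguous = "count"`) rather than
treated as an error by default.

`combinedTpm()` computes TPM separately for exonic and intronic regions
and sums them. Using the full unspliced gene length would deflate every
value (introns are long), while using spliced length alone would inflate
genes with many intronic reads; normalizing each compartment by its own
length avoids both. Two normalization budgets are defensible and both
are implemented: **joint** (default), where one million is apportioned
across all exonic *and* intronic rates, and **split**, where each family
is normalized to one million independently. The joint table sums to 1e6
by construction (asserted to 1e-6 relative tolerance in the tests).

`splicingRatio()` is the per-gene intron/exon statistic: length-
normalized intronic read density over exonic density. Zero means fully
spliced; one means densities equal (unspliced-like); values above one
are reported as computed, not clamped. Genes qualify when they carry a
genomically encoded intron and reach `tpmMin = 1` combined TPM in both
samples being compared. Intronless genes and genes with zero exonic
counts have no defined ratio and are marked ineligible.

# The upstream-readthrough (DoG) filter

For each gene, `buildUpstreamRegions()` takes the 2 kb strand-aware
upstream flank (`bedtools flank -l 2000 -r 0 -s` semantics), subtracts
any base overlapping any gene's span, and records the remaining
effective length. `scoreUpstream()` then computes, from the alignments
that hit no annotated exonic or intronic region:

* **breadth** — the fraction of the effective flank covered by at least
  one retained alignment block (split-aware coverage), and
* **ratio** — upstream TPM over the gene's combined TPM, the upstream
  TPM using the effective flank length and the *same* per-sample
  normalization denominator as the gene TPMs.

A gene is flagged when ratio ≥ 0.20 **and** breadth ≥ 0.70. The
thresholds are read as inclusive and exposed as parameters. Flagging in
either the input or the IP condition removes the gene from that
IP-versus-input comparison (`applyUpstreamFilter()` takes the union).

Three sub-choices were open and are fixed as follows: the upstream TPM
uses the post-subtraction *effective* length (a flank half-consumed by a
neighbour should not halve its apparent density); the gene-side
denominator is the combined exonic+intronic TPM, consistent with the
quantification module; and flanks with zero effective length or genes
with zero TPM are "not evaluable" — kept, never flagged, and marked in
the output. The default strand policy, `antisense_of_flank`, retains
intergenic alignments whose strand is opposite the gene's: under
reverse-stranded chemistry that is exactly sense transcription running
toward the gene, mirroring `bedtools coverage -S -split`. The policy is
configurable because library chemistry varies.

# Enrichment classification and the histone background

`classifyGenes()` applies fixed cut-offs to an externally produced
differential-abundance table (`gene_id`, `baseMean`, `log2FoldChange`,
`padj`): enriched when log2FoldChange > 0.5, depleted when < −0.5, both
requiring padj ≤ 0.01 and baseMean > 50. The fold-change and baseMean
inequalities are strict, the adjusted-p cut non-strict, and rows with
missing padj — the signature of independent filtering in upstream
tools — are not significant. The differential model itself is never
fitted here; any table matching the schema is accepted.

`backgroundThresholdFilter()` implements the histone-gene background
rule: replication-dependent histone transcripts end in a stem-loop
rather than a poly(A) tail, so their IP/input ratio estimates
nonspecific pulldown. Each gene's ratio
(TPM_IP + 0.5)/(TPM_input + 0.5) is compared with a summary of the
histone genes' ratios; genes below it are removed. Whether "lower than
the histone genes" means their median or their maximum is not
determined by the rule itself, so the summary statistic is a parameter
(median by default, max available). The 0.5 pseudocount follows the
plotting convention used alongside the rule and keeps zero-TPM genes
continuous.

# Long-read poly(A) statistics

The long-read pipeline consumes spliced alignments and an external
tail-estimation table (`readname`, `qc_tag`, `polya_length` — the
standard nanopore output schema); raw-signal tail segmentation is out of
scope. The steps:

1. `filterLongAlignments()` — keep primary alignments with MAPQ ≥ 1
   (MAPQ 0 marks multi-mappers in spliced long-read alignment output),
   dropping supplementary and secondary records
   (`samtools view -bq 1 -F 2048` semantics).
2. `assignLongReads()` — largest-overlap gene assignment with the same
   20-base floor; mitochondrial reads (default chromosome names `chrM`,
   `MT`) are removed and counted, since mitochondrial transcripts are
   not products of the nuclear poly(A) machinery.
3. `flagIntronRetention()` — a read retains an intron when its blocks
   overlap a distinct intronic interval of its gene by at least 20
   bases. How many intronic bases make a read "intron-containing" is
   not fixed by the procedure being implemented; 20 bases (the
   assignment floor) is the default so that a read ending a few bases
   into an intron is not called retained, and the threshold is a
   parameter (`intronMinOverlap`) for users who want any-overlap calls.
4. `applyPolyaQc()` — discard estimates tagged `READ_FAILED_LOAD`,
   `SUFFCLIP` or `NOREGION`; idempotent.
5. `joinTailEstimates()` — inner join of surviving alignments and
   surviving estimates on read id; unmatched reads on either side are
   dropped and counted.
6. `geneTailStatistics()` — per gene and condition: read count, median
   and maximum tail. The median of an even count is the arithmetic
   midpoint of the two central values (documented because per-gene
   medians are the primary reported statistic). Genes with fewer than
   10 reads are omitted from the statistics table but remain in the
   per-read table. Optional stratification by intron-containing versus
   fully spliced reads or by gene biotype.
7. `tailLengthChange()` — per-gene difference of medians between two
   conditions, restricted to genes with at least 35 reads in each;
   negative values mean shorter tails in the second condition.

# The synthetic-data generator

`simConfig()` + `simulateAll()` produce a complete planted-truth data
set: a GTF with overlapping gene pairs (same- and opposite-strand),
readthrough-tagged transcripts, intronless genes and processed
pseudogenes; stranded short-read alignments with exonic, intronic and
upstream-readthrough components; long reads with per-condition tail
distributions, per-intron retention, QC-tag mixtures and MAPQ-0 /
supplementary / mitochondrial contaminants; and a differential table
with planted labels. Everything is written as plain text (GTF, SAM,
TSV), converted to indexed BAM on demand with `samToBam()`, and is
byte-identical under a fixed (seed, config).

Default parameters are the conditions the analysis assumes: tail modes
of 230 nt (nuclear IP) and 80 nt (cytoplasmic IP) with sd 40 nt,
truncated at a 12 nt floor for IP-like conditions (poly(A)-binding
proteins do not stably bind tails shorter than ~12 adenosines, so such
tails are essentially absent from IP samples); upstream-readthrough
genes planted at a 0.4 signal ratio across the full flank breadth;
reverse-stranded 75 nt short reads; log-normal expression; per-gene
unspliced fractions drawn from Beta(2, 5) (mean ≈ 0.29, reflecting that
most genes contribute modest pre-mRNA signal with a long tail of
poorly spliced genes) unless fixed explicitly.

Alignments are synthesized directly — blocks, CIGAR, flags, MAPQ and
strand — with no sequence content or error model, because every
downstream contract consumes alignments, not bases. Feature widths are
at least 150 bases so a 75 nt read never straddles three features,
which makes the expected splicing ratio under the generator's geometry
available in closed form by exhaustive enumeration of read start
positions (the calibration oracle in the tests). Intergenic gaps
default to 4.5–7 kb so that every nominal 2 kb upstream flank is
intergenic unless an overlap was planted.

**What passing tests do and do not show.** The generator emulates the
*structural* features the pipeline's rules act on (overlap, tags,
strand, retention, contaminant flags, tail distributions), not
sequencing realism: no base-call errors, no mappability structure, no
fragment-length or positional bias, no isoform diversity beyond one
skipped exon, and planted contaminants are independent Bernoulli draws.
Exact recovery on synthetic data therefore validates the *logic* of
each rule and its boundary behaviour; it does not certify performance
on real libraries, where alignment artifacts and annotation errors
outside these models dominate.

# Numerical choices and test scales

* Inclusive thresholds (≥) for the DoG ratio and breadth cuts; strict
  inequalities for fold-change and baseMean; non-strict for adjusted p.
* Tie-breaks: exonic over intronic at equal overlap; gene order breaks
  exact overlap ties in long-read assignment (deterministic).
* TPM tables carry their normalization denominator (`rate_sum`) so the
  upstream filter can reuse it exactly.
* Truncated-Normal tails are drawn by inverse-CDF, so outputs are
  deterministic under a seed; note that a Normal(80, 40) truncated at
  12 has median ≈ 82.3, which is what per-gene medians converge to.
* The test and acceptance suites run on genomes of 100–300 kb with
  14–50 genes, 5 000–20 000 short reads and 200 long reads per gene —
  sizes chosen so the whole suite completes in minutes on one core
  while keeping every per-gene statistic well inside its asymptotic
  regime.

# Known limitations

* Gene-level only: no isoform quantification or EM multimapper rescue.
* Paired-end support merges mates into one fragment; duplicate marking
  is out of scope.
* The upstream filter detects contamination of a gene's flank; it does
  not call DoG transcript 3′ ends or lengths.
* The per-gene median recovery band scales as 1.25·sd/√n: with 200
  reads per gene and sd 40 nt the sampling s.d. of a per-gene median is
  ≈ 3.5 nt, so roughly 84% (not more) of genes land within ±5 nt of
  the planted mode; ±10 nt captures >99%. Interpretation of per-gene
  medians at moderate depth should keep this width in mind.

# A compact end-to-end run

```{r pipeline, eval = TRUE}
cfg <- simConfig(seed = 1, n_genes = 15, chrom_length = 250000L)
sim <- simulateAnnotation(cfg)
sann <- sanitizeAnnotation(sim$annotation)
sann

sr <- simulateShortReads(sim, sampleId = "ip")
fc <- countSample(sr$alignments, sann, sampleId = "ip")
tpm <- combinedTpm(fc, sann)
sum(tpm$tpm_exonic) + sum(tpm$tpm_intronic)

sc <- scoreUpstream(buildUpstreamRegions(sann),
                    collectIntergenicAlignments(sr$alignments, sann), tpm)
table(flagged = sc$flagged,
      planted = sim$truth$genes$dog[match(sc$gene_id,
                                          sim$truth$genes$gene_id)])

lr <- simulateLongReads(sim)
stats <- lapply(names(lr), function(cond) {
  kept <- filterLongAlignments(lr[[cond]]$alignments)
  asg <- flagIntronRetention(kept, assignLongReads(kept, sann), sann)
  geneTailStatistics(joinTailEstimates(asg, applyPolyaQc(lr[[cond]]$tails)),
                     condition = cond)
})
delta <- tailLengthChange(stats[[1]], stats[[2]], minReadsEach = 35)
median(delta$delta_median)
```
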