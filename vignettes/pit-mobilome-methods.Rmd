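---
title: "Methods: TE-protein calling and annotation evaluation from PIT data"
author: "pitmobilome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE-protein calling and annotation evaluation from PIT data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

Proteomics informed by transcriptomics (PIT) identifies MS/MS peptides
against open reading frames translated from a *de novo* assembled
transcriptome of the same sample, instead of against a reference genome
annotation. This makes two downstream questions tractable in organisms with
incomplete annotation, such as the arbovirus vector *Aedes aegypti*:

1. **Which detected proteins derive from transposable elements (TEs)?**
   TE proteins are highly divergent between genomes and between copies of
   one element, are masked in reference annotation, and are therefore
   invisible to conventional proteomics.
2. **Where is the genome annotation incomplete?** Proteins with homology to
   related insects but not to the organism's own annotation point at genes
   the annotation has missed; mapping their transcripts back to the
   assembly localises the gaps.

`pitmobilome` implements the downstream analysis: six-frame ORF extraction,
peptide-evidence protein grouping, a tiered homology cascade, calibrated
TE-protein calling with enrichment normalisation, and the
annotation-completeness evaluation — plus a deterministic synthetic-data
generator that makes every step testable at desk scale.

## Sequence handling and protein groups

Transcripts are translated in all six frames; an ORF is a span from an ATG
through the last sense codon before the next in-frame stop, or through the
transcript edge when no stop follows (de novo transcripts are frequently
3'-truncated, so open 3' ends are retained). Only ORFs strictly longer than
200 nt (start codon through last sense codon, stop excluded) are kept, and
nested ATGs inside a retained ORF are not reported separately
(longest-per-stop). Codons containing N translate to `X`. Transcript-local
coordinates are 0-based half-open internally and 1-based inclusive in all
reported files; genomic features use the 1-based closed convention of the
Bioconductor containers that carry them.

Peptide evidence arrives as a table mapping peptides (minimum length 6) to
the ORFs they match. ORFs supported by an identical peptide set are
indistinguishable and merge into one protein group; the count of distinct
supporting peptides is kept per group so that summaries can be restricted
to two-or-more-peptide groups. Each group is represented downstream by its
longest ORF.

## Local alignment and E-values

All homology decisions rest on exhaustive Smith–Waterman local alignment
under BLOSUM62 with affine gaps (open 11, extend 1; a gap of length L costs
`11 + L`). There is no heuristic seeding: every query is aligned against
every database entry, which at the problem sizes this package targets is
exact and fast (the scoring kernel is compiled). The traceback is
deterministic — the first maximal cell in row-major order, ties resolved
preferring the diagonal, then a gap in the subject, then a gap in the query
— so identity and coverage are reproducible across platforms. Percent
identity is identities over alignment columns (the gapped-alignment
convention) and coverage is *query* coverage, the aligned fraction of the
query length.

Significance uses the Karlin–Altschul form `E = K·m·n·exp(−λS)` with the
summed residue length of the database as `n` and the standard gapped
BLOSUM62 parameters λ = 0.267, K = 0.041 by default; both are fields of
`scoring_scheme()` because thresholds calibrated under different search
spaces should be applied with the parameters they were calibrated under.
The test suite pins the closed form and checks the alignment engine against
an exhaustive enumeration oracle and against an independent implementation
(`Biostrings::pairwiseAlignment`).

## The tiered homology cascade

Each protein group is searched against reference proteomes in a fixed
order: the organism's own annotation, a congeneric mosquito, a distant
dipteran, and optionally a fallback database. The search stops at the first
tier whose best hit reaches 60% identity; a hit must also have E ≤ 1e-5 to
stop the cascade, because the identity of a five-residue spurious alignment
should not terminate the search. Stopping in the first tier classifies the
query as conspecific (`AEDES`), in the next two as `NON_AEDES_INSECT` — the
candidates for missing annotation — and anything else as `NON_INSECT`, the
candidate pool for TE and viral proteins. Percentages are reported
integer-rounded (half-up) and to one decimal, matching the reporting
convention of partition figures.

## TE-protein calling and its calibration

Calls are made against a metadata-tagged TE protein database (order, clade
and ORF type per entry). The **top hit by raw score** is the only hit
considered per query; it becomes a call only if it passes all thresholds
strictly: E < 1e-5, identity > 30%, query coverage > 45%. Calls above 95%
identity and 95% coverage are tiered as *exact matches* — a subset of the
calls, not a separate pool.

The coverage threshold is the calibrated quantity. The calibration
procedure computes, for a *target* set (expected to contain TE proteins)
and a *background* set (conspecific proteins, expected to contain
essentially none, since repeats are masked in the annotation), the
proportion of queries retaining a TE match as the coverage cutoff rises.
`select_coverage_threshold()` formalises the knee-picking: the smallest
cutoff where the background has collapsed to ≤ 20% of its baseline while
the target retains ≥ 80% of its baseline, falling back to the
maximum-difference point when no cutoff qualifies. Both tolerances are
arguments; the selection is advisory and never applied silently.

Two quality-control operations follow the calling. Single-peptide calls are
removed when their peptide also matches an ORF with a conflicting identity
(an uncalled, putatively host ORF; a call to an unrelated element; or a
different ORF type within the same clade) — sharing among copies of one
element, or same-type ORFs of one clade, is concordant and retained.
Dual-database concordance compares calls from two databases at the order
level and the clade level for the queries called in both, which quantifies
how much of the extra yield of a broader database is classification noise.

## Enrichment normalisation

Raw counts of TE calls per order or clade confound expression with genomic
abundance. Counts are therefore normalised by one of three measures of
representation — percent of the genome, genomic copy number, or number of
database entries — and expressed relative to a reference category:
`ratio_c = (count_c / norm_c) / (count_ref / norm_ref)`, so the reference
is 1 by construction and the ratios are invariant to uniform scaling of the
counts. Categories with an unknown normaliser (copy numbers are not known
for every clade) are flagged `NA`, never dropped; the non-autonomous orders
SINE and MITE, which do not encode their own proteins, are excluded from
the denominators by default (configurable). The per-ORF breakdown counts
*distinct elements* per clade and ORF type, not calls, so one element
detected through three gag peptidoforms contributes once.

Enrichment is computed on the post-QC call list — the final mobilome list
is the quantity of interest, and the handful of QC removals should not
inflate any category.

## Annotation evaluation

Transcripts of the `NON_AEDES_INSECT` groups are aligned to the assembly
with a built-in seed-and-extend spliced mapper (exact 16-mer seeds on an
Aho–Corasick dictionary scan, diagonal grouping, substitution-tolerant
extension that stops at two consecutive mismatches, and joining of
same-locus diagonals across genomic gaps up to 20 kb into multi-block
hits). The mapper targets near-exact placements — transcripts a few percent
diverged from the assembly — which is exactly the regime of this analysis;
externally computed alignments can be imported instead for harder cases.

Triage is a four-way partition with deterministic rules: `NO_MATCH` when no
alignment reaches 90% identity and 50% transcript coverage; `AMBIGUOUS`
when two or more loci score within 95% of the best locus (duplicated
placements are excluded from downstream use); `ALREADY_ANNOTATED` when the
best locus overlaps an annotated exon span on the same strand by at least
1 bp; `NEW_ANNOTATION` otherwise. The ambiguity margin and the same-strand
≥1 bp overlap rule are package decisions — the source analysis relied on
manual inspection and states no rule — and both are parameters of
`triage_params()`.

Three follow-ups characterise the new annotations. The **gap scan** counts
N characters in a window extending 5,000 nt up- and down-stream of each
alignment span (truncated and flagged at contig ends); presence of any N
marks the region as poor sequence, and the count is also reported. A
**length-matched control** set of conspecific transcripts is drawn by
greedy nearest-length matching without replacement (deterministic given a
seed) so the gap rate has a baseline. **Hotspots**: per chromosome, the
fraction of mapped supercontigs containing new annotation is divided by the
genome-wide fraction, so 1 means no enrichment; per cytological band, bands
are ranked by new-annotation count (ties by name) over all bands with a
mapped supercontig, and the top 20% (ceiling) are flagged enriched when
their count exceeds 2. Transcript-length differences between unmappable and
mapped candidates are tested with the pooled-variance two-tailed t-test
(`df = n1 + n2 − 2`); a zero pooled variance with equal means yields
`t = 0, p = 1`, with unequal means it is an error.

## The synthetic-data generator

`generate_fixtures()` emits an internally consistent bundle — genome,
annotation GFF3, chromosome map, transcripts, peptide evidence, TE
databases, genome TE statistics, tiered reference proteomes, a viral
database, and ground-truth tables — from a single seeded configuration. All
randomness flows through one Mersenne-Twister stream seeded once, so reruns
are byte-identical. What it emulates, and the defaults that constitute the
study conditions:

* **Annotation composition.** The evaluation subset comprises 215
  transcripts: 145 unannotated single-locus genes, 21 annotated genes, 11
  genes duplicated at two loci, and 38 genes absent from the assembly.
  Novel genes cluster on three bands (counts 5, 4, 3) with further mapped
  bands at ≤ 2 each, so the top-20%/>2 hotspot rule has an exact expected
  answer; 36% of novel genes (28% of expressed host genes) carry an N run
  of 60–250 nt planted 0.5–3 kb away.
* **TE families** with the field's ORF architectures: LTR retrotransposon
  families (Ty3/gypsy, BEL, Ty1/copia) encoding gag/pol/env, non-LTR
  families (Jockey, R4, L1) encoding ORF1/ORF2, and cut-and-paste DNA
  transposons (IS630-Tc1-mariner, Mutator) encoding a transposase. Each
  expressed copy diverges from its family consensus by a per-site
  BLOSUM62-weighted substitution rate drawn uniformly up to 0.25, and
  expression is gag-biased for LTR elements and ORF2-biased for non-LTR
  elements, mirroring the biology (gag is the structural protein of the
  virus-like particle; non-LTR copies are 5'-truncated). Mutator's
  clade-level copy number is deliberately unknown to exercise the
  flagged-cell path.
* **Layout.** Genes, TE copies and N runs are laid out along supercontigs
  with 6–12 kb random spacers — wider than the 5 kb scan flank, so each
  gene's gap-scan window is independent of its neighbours' planted N runs
  and the observed gap fraction estimates the planted rate. 200 host genes
  (160 expressed) provide the annotation and a control pool larger than
  the 145 targets. Half the supercontigs carry chromosome/band
  assignments.
* **Evidence.** Peptides per expressed protein follow a zero-truncated
  Poisson (mean 3); each peptide is a 9–18 residue substring of the
  *realized* protein (after transcript errors), matched back against every
  extracted ORF, so shared peptides arise naturally. Transcript errors are
  substitutions at rate 0.005, redrawn (up to 25 times) when they would
  destroy the encoded ORF — the planted composition is a study condition,
  not a random variable.

What the generator does **not** emulate: spectrum-level MS identification
(peptide evidence enters as counts and assignments), insertion-site
structure (target-site duplications, nesting), phylogenetically structured
divergence, and indel errors in transcripts (the mapper's
substitution-tolerant extension is exercised at its design point). Passing
the parameter-recovery suite therefore shows the *pipeline logic* is
correct under realistic compositions, not that the thresholds are optimal
for any particular real dataset.

## Numerical choices and degenerate inputs

* Rounding of reported percentages is half-up (`round_half_up()`), not
  banker's rounding, to reproduce printed summary values exactly.
* All thresholds are strict in the documented direction; a match at
  exactly 30% identity or 45% coverage is not a call.
* Search ranking ties break by E-value then subject id; traceback ties by
  the move order above; band ranking ties lexicographically — every
  ordering in the package is total.
* An empty database, a dangling ORF reference, a chromosome with no mapped
  supercontigs, and a zero-variance/unequal-means t-test are errors, not
  silent results; an unalignable transcript and a query with no positive
  alignment are ordinary outcomes, not errors.
* Pipeline problem sizes (a ~3.6 Mb toy genome, ~380 transcripts, tier
  databases of 40–310 proteins) were chosen so a full run takes well under
  a minute and the complete test suite under two minutes, while every
  partition in the default scenario is large enough for its expected
  answer to be exact.

## Worked example

```{r, eval = FALSE}
library(pitmobilome)

fx <- generate_fixtures(synth_config(seed = 1), "fixtures")
report <- run_pipeline(run_config_from_fixtures(fx, seed = 1,
                                                out_dir = "report"))

report$partition_all          # cascade partition with percentages
table(report$triage$category) # 38 / 21 / 11 / 145
report$band_hotspots          # enriched bands: 1p3, 1q4, 2p4
report$enrichment$order_genome_pct
```

The same run is scripted in `scripts/acceptance.R`, which regenerates the
fixtures, reruns the pipeline and the calibration and recovery scenarios,
and writes every headline quantity to JSON. The functions above are the
package's interface; `inst/scripts/run_pipeline.R` is a thin command-line
wrapper over them for shell use.

## Known limitations

* The built-in mapper is not a general spliced aligner: transcripts more
  than a few percent diverged from the assembly, or with many short exons,
  need an external aligner whose output is imported.
* E-values assume the default Karlin–Altschul parameters unless the caller
  supplies ones matched to their scoring scheme; they are not recomputed
  from the matrix.
* Concordance and QC reason over the metadata encoded in the TE database
  headers; inconsistently curated databases will propagate their
  inconsistencies into those summaries.
* The statistical treatment of enrichment ratios reports point estimates
  only, mirroring the source analysis; no confidence intervals are
  attached.
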