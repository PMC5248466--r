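# pitmobilome

Downstream analysis for **proteomics informed by transcriptomics (PIT)**
experiments in non-model organisms, built around two questions that
conventional, annotation-dependent proteomics cannot answer:

* **Which detected proteins come from transposable elements (TEs)?**
  TE proteins are divergent between copies and masked in reference
  annotations. `pitmobilome` calls TE proteins from translated de novo
  transcripts against metadata-tagged TE databases, using empirically
  calibrated thresholds, and normalises the calls against genomic
  representation to measure which element types are disproportionately
  active at the protein level.
* **Where is a genome's annotation incomplete?** Proteins homologous to
  related species but not to the organism's own annotation are mapped back
  to the assembly and triaged into no-match / already-annotated /
  ambiguous / new-annotation categories, with sequencing-gap scans,
  length-matched controls and chromosomal hotspot detection.

## The method in brief

Transcripts are translated in all six frames, keeping ORFs longer than
200 nt (ATG through last sense codon, longest-per-stop). Peptide evidence
groups ORFs with identical support into protein groups. Each group is
classified by a tiered homology cascade (own species → related mosquito →
distant dipteran → fallback) that stops at the first tier with a hit of
identity ≥ 60% and E ≤ 1e-5.

Homology uses exhaustive Smith–Waterman local alignment (BLOSUM62, affine
gaps 11/1; compiled kernel, deterministic traceback) with Karlin–Altschul
statistics,

    E = K · m · n · exp(−λS),    bits = (λS − ln K) / ln 2,

with λ = 0.267, K = 0.041 by default. A TE call is the top hit by raw
score, retained only if E < 1e-5, identity > 30% and query coverage > 45%
(all strict); calls above 95%/95% are tiered *exact matches*. The coverage
threshold is calibrated by comparing target and background retention
curves; relative enrichment of order/clade counts is
`(count_c / norm_c) / (count_ref / norm_ref)` under genome-percentage,
copy-number or database-entry normalisers.

A deterministic synthetic-data generator (`generate_fixtures()`) produces
genome, annotation, transcripts, peptide evidence, TE databases and
ground-truth tables for the whole pipeline, so every stage is tested by
parameter recovery on planted signal.

## Worked example

```r
library(pitmobilome)

fx <- generate_fixtures(synth_config(seed = 1), "fixtures")
report <- run_pipeline(run_config_from_fixtures(fx, seed = 1,
                                                out_dir = "report"))

report$partition_all
#>           category count pct_int pct_1dp
#> 1            AEDES   160      38    38.3
#> 2 NON_AEDES_INSECT   215      51    51.4
#> 3       NON_INSECT    43      10    10.3

table(report$triage$category)
#>          NO_MATCH ALREADY_ANNOTATED         AMBIGUOUS    NEW_ANNOTATION
#>                38                21                11               145

report$band_hotspots[report$band_hotspots$enriched, ]
#>   band new_annotation_count rank enriched
#> 1  1p3                    5    1     TRUE
#> 2  1q4                    4    2     TRUE
#> 3  2p4                    3    3     TRUE

report$enrichment$order_genome_pct
#>   category count     norm     ratio undefined
#> 1      LTR    18 5.237083 1.0000000     FALSE
#> 2  NON_LTR     5 2.725347 0.5337835     FALSE
#> 3  DNA_TIR     3 1.238350 0.7048468     FALSE
```

Reading the output: the cascade classified 160 protein groups as
conspecific, 215 as non-conspecific insect (the candidates for missing
annotation) and 43 as non-insect (the candidate TE/viral pool). Triage of
the 215 candidate transcripts found 145 new annotations, clustered on
bands 1p3, 1q4 and 2p4 — exactly the hotspots planted by the generator.
Of the non-insect pool, 26 proteins were called as TE-derived (4 exact
matches to known elements); LTR retrotransposons dominate the calls
(ratio 1 is the LTR reference; the other orders sit below it even after
normalising away genomic abundance).

`inst/scripts/run_pipeline.R` wraps the same functions for shell use, with
`--simulate` to emit the synthetic scenario and flags for every input file.

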