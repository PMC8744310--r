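# isoval

Validation and differential analysis of long-read transcriptome annotations.

## The problem

Long-read cDNA sequencing (e.g. Oxford Nanopore) recovers full-length
transcripts and therefore finds isoforms that short-read assemblies miss:
unannotated cassette exons, shifted donor/acceptor splice sites, novel
junctions between known sites, novel transcription start/termination sites.
But long reads are error-prone and shallow, so every putative novel feature
needs orthogonal support before it can be believed. `isoval` implements that
validation pipeline for people who already have a candidate annotation (e.g.
from a long-read transcript-model builder) and want to know *which candidate
transcripts survive scrutiny, what they change about the coding repertoire,
and how isoform usage shifts between conditions*.

## What it computes

- **Novelty classification.** Each candidate transcript is compared with the
  reference annotation's per-(chromosome, strand) sets of exons, donor sites,
  acceptor sites, junctions and TSS/TTS positions. Categories are disjoint:
  a *cassette exon* is an internal exon overlapping no reference exon; an
  exon overlapping a reference exon contributes *novel donor* (5′) / *novel
  acceptor* (3′) tallies, or a single *both-boundaries-novel* count; a
  junction pairing two annotated sites in an unannotated combination is a
  *novel junction between known sites*. Antisense transcripts exactly
  mirroring a reference exon chain are removed.
- **Orthogonal validation.** A novel exon passes short-read validation iff
  at least 75% of its bases have depth ≥ 15 (both inclusive); a transcript
  with any failing novel exon is removed. Junctions are checked against
  split-read counts (≥ 3 by default), transcripts against a minimum
  expression of N = 5 reads in K = 3 samples, and 3′ ends against A-rich
  internal-priming windows (20 bp, ≥ 50% A).
- **Coding status.** Decision tree: noncoding parent gene → noncoding;
  otherwise a frame-conservation test (net change in CDS-overlapping exonic
  length mod 3, against the reference isoform sharing the most junctions);
  otherwise a CPAT-style logistic model on ORF length, ORF coverage, Fickett
  TESTCODE score and hexamer usage bias, called coding at probability
  ≥ 0.364.
- **CAGE support.** Novel TSS ± 500 bp windows intersected with CAGE peaks.
- **Differential expression.** TMM-style normalization factors, gene-level
  aggregation, a two-group negative-binomial exact-style test with
  moment-estimated common dispersion, BH q-values, and the ±1.5 logFC /
  FDR < 0.05 filter.
- **Differential transcript usage.** Isoform fractions IF = count /
  gene count; per-gene switch score `sum(|dIF|)` (dIF = difference of
  condition-mean IFs) tested by exhaustive condition-label permutation
  (252 arrangements for 5 vs 5), plus an alternative-splicing event
  catalogue (ES, MES, IR, A5, A3, ATSS, ATTS, MEE) and functional-consequence
  flags for switches.
- **Spike-in sensitivity.** TPM, expected mix-B/mix-A logFC, broken-stick
  (two-segment least squares over a breakpoint grid) limit-of-quantification,
  and expected-vs-observed R².
- **Synthetic data.** A deterministic generator produces a genome, reference
  and candidate annotations with labelled injected features, designed
  coverage tracks, NB counts with planted DE/DTU, spike-in mixes with a known
  detection floor, and CAGE peaks — ground truth for every stage.

## Worked example

```r
library(isoval)
cfg <- sim_config(seed = 42, n_genes = 60, chrom_length = 6e5)
bundle <- simulate_bundle(cfg, out_dir = "bundle")
manifest <- run_pipeline(bundle$config)
```

Stage log (stderr) and summary, as printed by the run above:

```
[isoval] load: reference=78 candidates=51
[isoval] antisense_removal: removed=5
[isoval] novelty_classification: classified=46
[isoval] coverage_validation: removed=2 retained=44
[isoval] junction_validation: junctions=135 validated=99
[isoval] expression_filter: removed=0 retained=44
[isoval] merge: transcripts=122
[isoval] coding_assessment: coding=13 noncoding=31 unresolved=0
[isoval] cage_validation: n_novel_tss_transcripts=8 n_supported_transcripts=3 n_overlapping_peaks=3
[isoval] differential_expression: transcripts_tested=122 transcript_hits=43 genes_tested=60 gene_hits=25
[isoval] differential_usage: genes_tested=60 switches_q05=10
[isoval] as_events: events=177
[isoval] spikein: r_squared=0.8393 loq_mixA=0.16 loq_mixB=0.08

manifest$summary
#> n_candidates 51, antisense removed 5, coverage failed 2,
#> expression filtered 0  ->  n_validated 44 (86.3%)
#> coding 13 (29.5%) vs noncoding 31 (70.5%)
```

Reading it: of 51 candidate novel transcripts, 5 were exact antisense
duplicates of reference models and 2 contained a novel exon whose designed
coverage violated the 15-reads/75% rule, leaving 44 validated transcripts
(86.3%). Thirteen are putatively coding (frame-conserving cassette exons or
model-called), 31 noncoding (frameshifts, noncoding parent genes or
model-called). The usage test flags 10 genes at q < 0.05 — the generator
planted 10 isoform switches. The spike-in block recovers the planted
detection floor (0.08 attomol/μl) within one two-fold dilution step per mix,
and expected-vs-observed logFC correlate at R² = 0.84 under the default
noise model (sequins below the floor are flattened, which caps R² on the
small default ladder). All reports are TSVs under `bundle/out/`, with a
`manifest.json` recording counts and file checksums.

A command-line wrapper with `simulate`, `run` and `all` subcommands is in
`inst/scripts/isoval-pipeline.R`.

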