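---
title: "Validating long-read transcriptome annotations: models and methods"
author: "isoval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating long-read transcriptome annotations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
models and rules, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical choices, and the design
decisions taken where the problem itself left the design open. It states no
empirical result that the test suite or the acceptance script does not
compute.

## 1. The annotation model

All coordinates are internally 0-based half-open; GTF I/O converts at the
boundary. This makes interval arithmetic (overlap, subtraction, junction
extraction) unambiguous: an exon `[s, e)` has length `e - s`, and the intron
between consecutive exons is `[prev_end, next_start)`. Donor and acceptor
sites are strand-aware: on `+`, the donor is the intron start and the
acceptor the intron end; on `-`, reversed. This matters because novelty
tallies are reported as 5′ vs 3′ splice sites, which are transcript-relative
notions.

GTF reading is delegated to `rtracklayer` (the standard GENCODE-dialect
parser, gzip-transparent); GTF writing is done directly so that output
ordering — (chromosome, transcript start, transcript id) — is fully
deterministic and reruns are byte-identical, which the determinism tests
rely on. Gene biotype defaults to *coding iff any transcript of the gene
carries a CDS* when no `gene_type` attribute is present; the coding decision
tree needs a biotype for every gene.

## 2. Novelty classification

Candidate transcripts are compared against genome-wide per-(chromosome,
strand) indexes of the reference: exon intervals, donor/acceptor sets,
junction set, TSS/TTS positions. Comparison is global, not per-gene: a
boundary that coincides with *any* annotated site on the same chromosome and
strand is not novel.

The reported categories partition novel features disjointly:

* **cassette exon** — internal exon overlapping no reference exon. Its
  boundaries contribute nothing to the splice-site tallies (the exon is the
  finding, not its two sites).
* **novel donor / novel acceptor** — a boundary of an exon that overlaps a
  reference exon and is absent from the corresponding site set. Terminal
  exons contribute only their internal (splice-site) boundary; the outer
  boundaries are TSS/TTS and are judged separately.
* **both-boundaries novel** — an internal, reference-overlapping exon with
  both sites novel counts once here and not in the single-site tallies.
* **novel junction between known sites** — both sites annotated, pairing
  absent.
* **novel TSS / TTS** — strand-aware 5′/3′ end with no reference counterpart
  within `tolerance_bp` (default 0, i.e. exact; configurable because the
  underlying convention is not standardised).

Because published site counts do not state whether sites shared by several
novel transcripts are de-duplicated, the catalog reports both per-transcript
tallies and unique-site counts.

Antisense duplicates — candidate transcripts whose exon chain exactly equals
a reference transcript's on the opposite strand — are a recognised long-read
library artifact and are removed before classification. Matching is exact:
a 1 bp boundary difference is not a duplicate.

A transcript on a chromosome absent from the reference is classified with
empty site sets (everything novel) and flagged `no_reference_context` rather
than raising an error: incomplete references are a normal condition.

## 3. Orthogonal validation

**Exon coverage.** A novel exon passes iff
`#(bases with depth >= min_depth) / length >= min_fraction`, defaults 15
reads and 0.75, both inclusive — "at least 15 reads over at least 75%" reads
as closed thresholds, and the tests pin the boundary case (depth exactly 15
on exactly 75 of 100 bases passes). Coverage is per-base depth from a
BedGraph, held as run-length segments; correctness against a naive per-base
scan is property-tested. Only *novel* exons (cassette or both-novel) are
checked: transcripts reusing annotated exons are not punished for shallow
short-read coverage, and a transcript with any failing novel exon is removed
whole.

**Junctions.** A junction is validated by `>= junction_min_reads` exactly
matching split reads (default 3 — a conservative, common choice; the
evidence threshold is not standardised). Junction validation is report-only:
it does not remove transcripts, because only exon-level failure removal is a
stated rule of the pipeline this package models; the flag is available to
callers who want stricter behaviour.

**Expression.** Keep transcripts with `>= 5` counts in `>= 3` of the
samples (N = 5, K = 3 defaults: with five replicates per condition, K = 3
balances sensitivity for condition-specific isoforms against noise).

**Internal priming.** The 20 bp genomic window immediately 3′ of a
transcript end (sense strand; reverse-complemented on `-`) is flagged when
its A fraction is ≥ 0.5. The window size matches oligo-dT primer length; the
fraction is configurable since tools differ.

## 4. Coding status

The decision tree orders most-specific evidence first:

1. noncoding parent gene → `noncoding / noncoding_parent`;
2. frame-conservation test, where applicable → `noncoding / frameshift` or
   `coding / frame_conserving`;
3. otherwise the coding-potential model → `cpat_coding` / `cpat_noncoding`.

The frame test anchors on the CDS-bearing reference isoform of the same gene
sharing the most junctions with the candidate (ties → longest CDS; the
anchor choice is a documented convention, since several isoforms can share
junctions). It computes the net change in exonic length inside the anchor's
CDS genomic span; conservation means change ≡ 0 (mod 3). Changes wholly in
UTRs change nothing inside the span and conserve frame by construction. The
test is *not applicable* when the only novelty is a TSS/TTS change — there
is no splice-level alteration whose frame could be conserved — and such
transcripts go to the model. A brute-force translation oracle (compare the
amino-acid suffix downstream of the alteration) backs the test in the suite.

The coding-potential model is CPAT-style: logistic regression on ORF length,
ORF coverage, Fickett TESTCODE score (the published position/composition
lookup tables) and hexamer usage bias
(`log(freq_coding / freq_noncoding)`, pseudocount one occurrence per
hexamer class, scored over in-frame hexamers of the longest ORF). The
package ships no pre-trained human weights — training is on user-supplied or
synthetic labelled sequences, keeping the artifact self-contained — but the
decision threshold retains the conventional human cut-off CP ≥ 0.364
(inclusive). Both classes count hexamers identically (step 1), so identical
training sets give an exactly zero table; callers supply CDS/ORF sequences
as the coding class.

## 5. CAGE support

Novel-TSS transcripts get a window around the TSS — symmetric ± 500 bp by
default, upstream-only available — clamped at position 0, and are
intersected with CAGE peaks under half-open semantics (a peak ending exactly
at the window start does not overlap). The symmetric default follows the
headline convention of reporting "± 500 bp" support; the upstream-only mode
reflects the alternative description of the same window, and the discrepancy
between the two is not resolvable, hence both are implemented. Peak strand
is ignored by default (coordinate-BED CAGE releases); strand matching is a
flag.

## 6. Differential expression

`tmm_factors()` computes a doubly-trimmed (30% on M, 5% on A), precision-
weighted mean of gene-wise log2 count ratios against a reference sample (the
one whose upper quartile is closest to the mean upper quartile). The
returned factor deliberately **combines library size and composition** — a
sample with exactly twice another's counts gets factor √2 vs 1/√2 — and is
used as a divisor of raw counts; this is the contract the closed-form test
pins. (edgeR's convention divides library size out first; the two differ
only in bookkeeping, not in the normalized counts used downstream.)

`de_test()` is a defined replacement for an edgeR glm: common dispersion by
method of moments across features (pooled within-group variances,
`phi = (v - m) / m^2` averaged, floor 1e-4), then per feature an exact-style
conditional NB test on normalized group sums (group sums of n iid NB(μ, φ)
are treated as NB(nμ, φ/n); two-sided by probability-mass ordering). For
totals above 5·10⁴ the conditional distribution is effectively Gaussian and
a normal approximation replaces the enumeration. logFC is the log2 ratio of
normalized condition means with pseudo-count 0.5 (finite for zero counts).
Calibration — type-I error in [0.03, 0.07] at α = 0.05 over 2000 null
features — is an acceptance criterion, not a tuning target. The hit filter
is `|logFC| >= 1.5` (inclusive: "±1.5" states no open boundary) and
`q < 0.05`.

`downsample_counts()` is per-cell binomial thinning with a fixed seed —
the standard way to compare platforms at matched coverage.

## 7. Differential usage and splicing events

Isoform fraction `IF(i, s) = count(i, s) / gene_count(s)`, undefined when
the gene count is 0 (those samples drop out of that gene's means). dIF is
the difference of condition means of per-sample IFs — not pooled counts —
matching the replicate structure. The gene statistic is `sum(|dIF|)`; its
null distribution comes from condition-label permutations, exhaustive up to
10000 arrangements (252 for 5 vs 5, so the smallest attainable p is 2/252 ≈
0.0079 — the observed labelling and its mirror), Monte-Carlo with a fixed
seed beyond. BH across genes. A practical consequence, visible in the
pipeline reports: with ~100+ genes tested, the permutation-granular minimum
p can leave planted switches just above q = 0.05 even when they are all
top-ranked; the tests therefore assert recovery by ranking (AUC) and by the
exact minimal p, not by an arbitrary q cut.

Splicing events between isoform pairs follow the standard taxonomy. The
choices that needed fixing, since the class names alone do not define them:
ES/MES require the skipping isoform to bridge the skipped exon(s) with a
junction sharing both flanking sites; IR requires the retaining exon to
strictly contain the other isoform's intron; A5/A3 require a shared junction
partner *and* overlapping alternative exons (this excludes the spurious
donor/acceptor pairs that every ES event would otherwise generate); MEE
requires mutually non-overlapping exclusive internal exons sharing both
flanking partners — overlapping alternatives are A5/A3; ATSS/ATTS require a
differing terminal exon with the rest of the chain shared, and an
overlapping terminal exon whose *splice-site* boundary moved is handed to
A5/A3 instead (only the outer boundary moving, or disjoint terminal exons,
is an alternative start/end). Event usage per condition is the mean IF of
the inclusion isoform, a documented simplification of per-event isoform
attribution.

Functional consequences compare the dominant gaining and losing isoforms of
a switch: coding-status change, ORF length change ≥ 10%, and — only when a
feature table is supplied — domain or signal-peptide differences. The
package never runs domain/signal-peptide predictors; it consumes their
tabular outputs.

## 8. Spike-in sensitivity

Expected logFC between mixes defaults to `log2(MixB/MixA)`. The published
form of this quantity, `log2(MixB/MixA - 1) + 1`, is undefined for
MixB ≤ MixA and cannot produce the negative expected fold changes that
spike-in designs span; it is almost certainly a typographical rendering of
the plain ratio (the two coincide exactly at ratio 2). Both are
implemented — the literal form behind `formula = "literal"`, erroring on its
undefined domain — so the discrepancy is surfaced rather than silently
fixed.

The limit of quantification is the breakpoint of a two-segment least-squares
fit on (log2 concentration, log2(TPM + 0.01)): candidate breakpoints are the
observed concentrations; the left segment may be flat or free-slope
(whichever fits better), the right is free; the breakpoint minimising total
SSE wins, ties resolved to the smallest concentration (the earliest point
from which linearity holds). If a single line fits within 1e-9 of the best
two-segment fit, the LOQ is the minimum observed concentration — fully
linear data has no detection floor. The pseudo-abundance 0.01 makes zeros
representable and is configurable; note it bends perfectly linear data
slightly at the bottom of the range, which is why the exactness tests pass
`pseudo = 0`.

## 9. The synthetic world

The generator's defaults state the world the tests run in: 2 chromosomes ×
1 Mb, 150 genes of 2–10 exons (introns ≥ 600 bp, gaps ≥ 1.5 kb), ~20%
noncoding, 5 vs 5 samples, NB counts (dispersion 0.1) around a log-normal
baseline of mean ~100, injected novel features of every category, designed
coverage pass fraction 2567/3274 and coding fraction 929/2567 (the
proportions the modelled study reports), a 2-fold spike-in ladder with mix
ratios {¼, ½, 1, 2, 4} and detection floor 0.08 attomol/μl, and CAGE
support for 40% of novel-TSS transcripts. Planted DE (logFC 2) is split
half up / half down: real experiments show near-balanced directions, and a
one-sided design would be partly absorbed into any composition-aware
normalization. Planted DTU holds gene totals fixed, creating usage switches
without gene-level expression change.

Deliberate simplifications, hence what a green test does *not* establish:
no read-level error model (novelty calls are exact in the noise-free
setting, so precision = recall = 1 is a correctness check, not a
performance claim); coverage tracks are designed, not sampled from
alignments; designed coverage failures are only planted on cassette exons,
because both-boundary-novel exons overlap reference exons that carry
background depth — a designed failure there would contradict the background
model; CDS sequences plant start/stop codons but are not globally stop-free;
spike-in counts flatten *at* the floor level below the floor. Every
generator output is a pure function of (config, seed); sub-stages use fixed
seed offsets.

The acceptance suite's printed-percentage criterion constructs a run with
the published stage counts (3274 candidates, 2567 designed passes, 929
coding among them) and checks the pipeline's manifest arithmetic reproduces
78.41% / 36.19% / 63.81% — by computation, not by assignment.

## 10. Pipeline and configuration

`run_pipeline()` executes: antisense removal → novelty classification →
coverage validation → junction report → expression filter → merge →
coding assessment → CAGE → DE (transcript and gene) → DTU + consequences →
AS-event summary → spike-ins. Stages with absent inputs record a skip in
the manifest instead of failing. The manifest also records the arithmetic
identity `validated = candidates - antisense - coverage_failed -
expression_filtered` and md5 checksums of every report, which the
determinism criterion compares across reruns. The configuration is a
declarative JSON file (the environment provides no TOML parser; JSON keeps
the same single-file contract), and `inst/scripts/isoval-pipeline.R`
provides `simulate` / `run` / `all` subcommands.

## Known limitations

- The NB test uses a single common dispersion; tagwise/trended dispersion
  and covariate GLMs are out of scope.
- Event classification is pairwise; it does not build a gene-level splice
  graph, so complex events spanning three isoforms are reported as their
  pairwise projections.
- The coding model is only as good as its training sequences; with the
  synthetic trainer it separates long-ORF from ORF-free sequences but is not
  a substitute for a model trained on real labelled transcripts.
- GFF3, BAM parsing and liftover are out of scope by design; inputs must
  share an assembly.
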