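---
title: "Methods: variant triage, SV prioritization and run QC for rapid nanopore pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant triage, SV prioritization and run QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotriage)
```

# Scope and model

`nanotriage` implements the downstream analytic core of an ultra-rapid
nanopore whole-genome diagnostic workflow: once small variants and
structural variants (SVs) have been called, the bottleneck is manual
curation, and the package's job is to shrink the set of variants a
clinical analyst must look at — without losing clearly pathogenic,
actionable findings — and to quantify the quality of the sequencing run
itself. Everything operates on standard formats (VCF 4.2, BED3+, TSV) and
on deterministic synthetic fixtures, so every component is testable
without any external download.

Coordinates are 0-based half-open everywhere in memory; the VCF
ingestion/emission boundary is the only place the 1-based anchored
convention is converted. This makes interval arithmetic against BED
tracks uniform and keeps off-by-one reasoning in exactly one place.

# Homopolymer annotation

The dominant error mode of nanopore sequencing is indels in homopolymer
runs. Variants are therefore flagged against two interval tracks: long
homopolymers (>6 bp perfect, >10 bp imperfect, with slop — the
`"Homopolymer"` flag) and 4–6 bp runs (`"ShortHomopolymer"`). Because VCF
anchors an insertion at the base *before* the inserted sequence, a track
interval starting at position $x$ must also capture an insertion anchored
at $x-1$; the annotator therefore extends every track interval 1 bp to
the left before intersecting. The affected span of an insertion is its
single anchor base; for SNPs, MNPs and deletions it is the full reference
span. Partial overlap counts as overlap — the tracks do not say how much
of a deletion must sit inside a run for the error mode to apply, so any
intersection is treated as context (this is an interpretation, stated
here once). Annotation adds flags to a set and touches nothing else, so
it is idempotent and order-preserving; the test suite checks it against a
brute-force $O(n\,m)$ pairwise oracle.

Database annotation (ClinVar-like classifications, HGMD-like DM/DM?
labels, population allele frequencies) is an exact lookup keyed by
normalized `(contig, pos, ref, alt)`. Normalization trims shared
trailing then leading bases, advancing the position — the canonical
representation both the tables and the variants are reduced to. Full
left-alignment across repeat copies requires the reference sequence,
which no operation in this package otherwise needs; trimming is
sufficient to make keys canonical for any single consistent
representation source, and is applied identically on both sides of every
lookup. Lookups are allele-aware: a different alternate allele at the
same site never annotates.

# The two prioritization trees

Both systems first apply a rarity gate: variants with minor allele
frequency $\geq$ 1% (`maf_threshold`, configurable) are discarded from
scoring. A variant absent from the frequency table is treated as rare —
absence from population databases is evidence of rarity in clinical
filtration practice.

**The standard tree** is an any-criterion trigger system: a rare variant
is flagged for review if it meets *any* of, in order — (1) ClinVar P/LP;
(2) HGMD DM or DM? (both treated as pathogenic/likely pathogenic);
(3) membership in the patient-specific target gene list, evaluated only
for variants with protein-coding impact (LOF, missense or splice-region;
synonymous target-gene variants never trigger); (4) any rare biallelic
candidate, regardless of gene–disease annotation; (5) predicted
deleterious impact. `first_trigger` records the first satisfied
category, giving the ordered, exclusive groups used to compare the two
systems.

**The rapid tree** scores the same categories independently and reviews
only variants whose total meets the review threshold (default $\geq 4$).
Two criteria are deliberately tighter than in the standard system:
biallelic status earns points only in genes with an autosomal-recessive
OMIM annotation, and homopolymer-context indels receive a negative
adjustment, demoting the most error-prone nanopore call class. One is
looser: target-gene points are awarded *before* any coding-impact
restriction, so the rapid system scores (but usually does not review)
synonymous target-gene variants the standard system never sees.

The default point schema is a design choice of this package (the
clinically validated schema behind the original system is not public):

| criterion | points |
|---|---|
| ClinVar P/LP | 5 |
| HGMD DM | 4 |
| HGMD DM? | 2 |
| target-gene membership | 2 (intended per-case range 1–3) |
| biallelic in OMIM-AR gene | 2 |
| LOF | 1 |
| deleterious missense | 1 |
| homopolymer indel | −2 |

The weights were fixed by four requirements: a ClinVar P/LP
classification alone triggers review; a high-confidence DM alone
triggers review (DM is treated as P/LP); a low-confidence DM? alone does
not; and the maximum achievable total over mutually compatible criteria
(DM/DM? and LOF/deleterious-missense being exclusive within one variant)
is exactly 14, the documented top of the score scale
(`triage_config()$max_total`). Totals floor at zero: the homopolymer
penalty is clamped so that the recorded per-criterion points always sum
to the total *and* the total is never negative. Every weight, the gate
and the threshold are configurable (`triage_config()`, or a flat YAML
schema via `read_triage_config()`).

Compound heterozygotes are detected unphased — $\geq 2$ rare
heterozygous variants in one gene — since phasing is out of scope; such
variants are marked `unphased_biallelic` in the output so an analyst
knows the pair is a candidate, not a proven trans configuration. Rarity
is applied globally in both systems (whether the standard tree's
deleterious trigger is independently gated on rarity is not documented;
one global gate is the simpler and stricter reading).

# Rare-SV selection, tiering and evaluation

Two SVs of the same type match when the reciprocal overlap exceeds 50%
(deletions, duplications, inversions; strict `>`, both ratios), or for
insertions when the smaller size is at least 50% of the larger
(inclusive `>=`) and the anchor starts lie within 100 bp (strict `<`).
The strict/inclusive split mirrors the wording of the matching criteria
the selection scheme is modeled on ("overlap >50%", "50% similar");
both thresholds and the distance are exposed as arguments. Insertion
distance is measured between anchor starts, and insertion sequence
content is ignored. Duplications are matched as intervals like
deletions, with no DEL–DUP cross-type matching; BND records are carried
through readers but never match.

`select_rare()` removes a call iff it matches any catalog record with
allele frequency strictly above 1% (configurable); frequency exactly at
the threshold retains. Tiering then partitions the survivors: tier 1 —
the SV span intersects any CDS block (coding); tier 2 — it intersects a
UTR, promoter or intron of a protein-coding gene; tier 3 — it intersects
a conserved element or regulatory element. Tests are evaluated in that
order and are exclusive; SVs matching none are dropped from the report.
Within a tier, SVs touching a target-list gene are listed first. The
promoter is defined as 2,000 bp upstream of the transcription start
site, strand-aware — a conventional default (the tier definition names
promoters without defining them), exposed as `promoter_size`. The gene
TSV carries transcript spans and CDS blocks only, so UTRs are
approximated as the transcript termini flanking the CDS extent and
introns as gaps between CDS blocks; non-coding exons are not
distinguished.

`evaluate_sv()` benchmarks a callset against a truthset within
high-confidence regions (records not intersecting them are ignored on
both sides). Matching is greedy one-to-one: candidate pairs ranked by
best reciprocal overlap (size similarity for insertions), ties broken
leftmost, each record consumed at most once. The tie-breaking rule is
this package's defined behavior; the suite validates that the greedy
matching attains the exhaustive maximum-bipartite-matching size on
$\geq$ 99% of small random instances and can never overcount (any
matching is bounded by the maximum). Beyond precision/recall/F1 per
type and overall, `exact_matches` counts matched pairs with identical
start and size — the metric that quantifies what breakpoint refinement
by local assembly buys. The assembly step itself is out of scope; the
evaluator simply accepts a refined callset and recomputes the metric.

`coverage_windows()` computes mean depth in fixed 10-kb windows (last
window truncated) from unit-depth alignment spans, conserving coverage
mass exactly (window mean × window length sums to total aligned bases,
clipping aside). A contig whose mean depth deviates from the
autosome-wide mean by more than 25% is flagged for aneuploidy review.
The 25% is this package's choice — halfway between the ±33% a clean
trisomy/monosomy implies and the noise of a diploid baseline — and is a
flag for review, not a call.

# Run QC

**Carryover.** For a re-used flow cell, reads are filtered in order:
q-score failures (strictly below 7; a read at exactly 7.0 passes), then
unclassified reads; the carryover rate is the fraction of the remaining
reads whose barcode mismatches the expected one, with a per-barcode
breakdown (the report emits both because a per-run maximum and a
per-pair rate answer different contamination questions).

**In-silico contamination.** `mix_reads()` adds
`round(f × |primary|)` contaminant reads drawn without replacement under
a fixed seed. The fraction is defined relative to the *primary* read
count ("add 1% reads" is ambiguous between pools; relative-to-primary
matches the worked example of 100 reads added to 10,000). Consequently
the contaminant share of the mixed pool is $f/(1+f)$, not $f$ — at
$f = 1\%$ the distinction is negligible, at 5% it is visible — and the
recovery tests compare the estimator against the realized pool fraction
$m/(n+m)$, which is what the estimator estimates.

**Scheduling.** Per-contig variant-calling runtimes are distributed over
parallel instances by longest-processing-time (LPT) greedy assignment:
sort contigs by descending runtime (ties by name), give each to the
least-loaded worker (ties to the lowest index) — fully deterministic.
LPT guarantees makespan $\leq (4/3 - 1/(3k))\,\mathrm{OPT}$ for $k$
workers; the suite verifies the bound against branch-and-bound optima on
small instances. Inputs are whole contigs by construction, matching a
pipeline that does not parallelize below chromosome scale because the
caller uses long-range phasing information.

# Synthetic data

The generators exist so that every operation above has a ground truth.
`generate_cohort()` plants variants that each carry *exactly one*
criterion (ClinVar P/LP, HGMD DM, synonymous target-gene, biallelic in
an AR gene, LOF, homopolymer indel) inside gene CDS blocks or
homopolymer intervals, on a background of intergenic SNPs that carry
none — 80% common (MAF uniform on 1–50%) and 20% rare, chosen to
exercise both sides of the rarity gate. Because plants are
single-criterion and background is criterion-free, the manifest predicts
both systems' outputs exactly: expected totals per planted variant, the
rapid review set, the scored-not-reviewed set and the standard review
set. `generate_sv_benchmark()` perturbs a truthset within matching
tolerance (breakpoint shifts clamped at min(50 bp, 10% of size), size
jitter clamped at 10%), drops truths and adds spurious calls at
configured rates on a grid that keeps them unmatched by construction, so
tp/fp/fn/exact counts are knowable in advance and recorded in the
manifest. Defaults (400 variants, 30 genes, 80 SVs, shift sd 5 bp, size
jitter 3%, 10% FP and FN rates, two 1-Mb contigs) are fixed once as a
plausible desk-scale study; the read generator uses a 5% q-score failure
rate and 2% unclassified rate.

What the fixtures deliberately do **not** emulate: real sequence content
(alleles are literal placeholder bases), genotype-dependent error, linked
reads, caller-specific artifacts, overlapping genes, non-coding exon
structure, or population LD. Passing tests therefore demonstrate the
correctness of the *logic* — interval arithmetic, scoring, matching,
counting — not calling performance on real nanopore data.

# Numerical and degenerate-input choices

* Threshold sides are load-bearing and unit-tested: reciprocal overlap
  strict `>`, insertion similarity inclusive `>=`, insertion distance
  strict `<`, q-score failure strict `<`, catalog and cohort frequency
  gates strict `>` / `>=` respectively.
* Empty inputs: an empty cohort yields an empty report; an empty catalog
  list is the identity; an empty truthset reports recall 0 with a
  warning; zero evaluated reads is an error (the rate is undefined).
* Precision/recall are defined as 0 when their denominator is 0.
* Missing genotypes skip the record with a warning; an SV record lacking
  both `SVLEN` and `END` is rejected with a reason.
* All randomness flows through explicit seeds; generators restore the
  caller's RNG state.

# Problem sizes

The default test and reproduction runs use 400-variant cohorts, 80-SV
benchmarks, 100,000-read mixtures, 200 scheduling instances of at most
12 contigs × 4 workers, and 1,000-variant × 200-interval oracle
comparisons — sizes at which the brute-force oracles are exact and the
whole suite completes in about a minute on one core, while every code
path (both tree systems, all SV types, all filter boundaries) is
exercised.

# Known limitations

Consequence prediction is not implemented: consequences are read from
annotations (a VEP-class engine is out of scope), so scoring is only as
good as the annotation source. Compound-het detection is unphased and
will over-call pairs in cis. The UTR/intron approximation misassigns
non-coding exons to introns for genes where that distinction matters.
Carryover estimation assumes barcode calls themselves are correct;
misclassification would bias the estimate upward. The tier system
reports only SVs touching annotated features — a truly intergenic,
unconserved, unregulated SV is invisible to it by design.
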