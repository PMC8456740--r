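---
title: "CHG methylation as a gatekeeper of REF6 targeting in endosperm: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CHG methylation as a gatekeeper of REF6 targeting in endosperm: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the analysis chain

In *Arabidopsis* endosperm, genes repressed by Polycomb H3K27me3 alone
can be reactivated during germination by the H3K27me3 demethylase REF6,
which binds the 8-bp motif CTCTGYTY (Y = C or T).  Genes additionally
carrying H3K9me2 — a mark coupled to CHG DNA methylation through the
CMT3/SUVH feedback loop — tend to have CHG-methylated REF6-binding
sites, which repel REF6 and lock the genes in a silent, often
parentally biased state.  `epigerm` implements the analysis chain that
quantifies this model: motif scanning with cytosine-context resolution,
replicate-aware methylation calls, chromatin-state stratification,
germination-time-course and allelic-ratio statistics, and the
contingency tests that tie them together.

This vignette records the modelling assumptions, the tunable parameters
and why their defaults are what they are, and the decisions taken where
the analysis design was genuinely open.

# Coordinates and file formats

All internal coordinates are 1-based inclusive, matching GFF3 and
per-cytosine methylation reports.  BED input/output is converted at the
file boundary (`start_internal = start_bed + 1`).  Gene bodies are the
full annotated gene interval, introns and UTRs included; no transcript
isoform structure is modelled.  Promoters are the 1 kb (configurable)
immediately 5' of the *translation* start — the 5' gene end unless a
CDS feature specifies otherwise — and are truncated, never rejected, at
chromosome edges, because small genomes hit edges routinely.

# Motif scanning and cytosine context

`scan_motif()` reports every motif occurrence on both strands whose
full width lies inside a gene body, deduplicated per (gene, interval,
strand); a site inside two overlapping genes yields one record per
gene, and overlapping occurrences are all retained — no collapsing rule
is imposed.  Motif positions are always numbered in motif orientation
(position 1 is the first C of CTCTGYTY) so per-position statistics
aggregate across strands.  An N inside the match window never matches;
an N or a chromosome edge in the context flank makes the context
`undetermined`, which downstream aggregation treats as absent evidence,
never as methylation.

Context follows the standard bisulfite definition read 5'→3' on the
strand carrying the cytosine: CG if the next base is G, CHG if the next
base is H (A/C/T) followed by G, CHH otherwise.  A position whose
motif-orientation base is G carries the cytosine on the opposite
strand.  `chg_capable_positions()` answers, by constructive
enumeration, which motif positions could ever be CHG-methylated; for
CTCTGYTY these are positions 3, 5 and 8.  A subtlety worth noting: for
a motif like CAG *both* cytosines of the CAG/CTG palindromic pair are
in CHG context (positions 1 and 3), which the exhaustive-enumeration
oracle in the test suite confirms — intuition that "the C of CAG" is
the only CHG cytosine undercounts the antisense strand.

# Methylation calls

Two rules are implemented, both with `min_cov = 5` reads:

* **two-replicate** — a cytosine is *methylated* when each replicate
  has ≥ `min_cov` reads and each carries ≥ 1 methylated read;
  *undetermined* when either replicate is under-covered; *unmethylated*
  otherwise;
* **pooled** — counts are pooled across replicates before the same
  ≥ 1-methylated-among-≥ 5 test.

Both are three-state: low coverage yields `undetermined`, and a site's
CHG-methylation status is *methylated* if **any** CHG cytosine within
the 8 bp is methylated (the weakest aggregation consistent with
position-resolved reporting), *unmethylated* only when at least one
CHG cytosine is determinate and none is methylated.  Because the
denominator convention for "percent of sites methylated" is ambiguous
when undetermined sites exist, reports carry both variants: determinate
sites only (the default interpretation) and the alternative counting
undetermined as unmethylated.  In the recovery tests both variants give
the same group ordering.

Gene-body methylation levels are read-weighted
(Σ methylated / Σ total over covered cytosines), not mean-of-sites, and
a region with no covered cytosine is `undefined`, never 0.  The
presence cut for gene-body CHGm is level > 0.04 (the boundary value
counts as absent).  Flank profiles use fixed 2 kb flanks in genomic bp,
the gene body scaled to 20 bins, pooled-replicate counts per cytosine
with the same coverage floor, and strand-oriented bin order.

# Statistics

* Fisher tests are two-sided by the probability-mass criterion (sum of
  hypergeometric probabilities of tables no more probable than the
  observed one); the test suite verifies agreement with direct
  enumeration to < 1e-12.
* Wilcoxon rank-sum tests use exact null enumeration when both samples
  have ≤ 10 values and no ties, and the normal approximation with tie
  and continuity correction otherwise.
* Benjamini–Hochberg correction is the step-up formula; each test
  family is confined to one analysis invocation (one report), and the
  family is recorded by the report structure itself.
* Maternal ratios are m/(m+p); the neutral expectation in triploid
  endosperm is 2/3, but bias calls are made against the *empirical*
  all-genes background distribution (pairwise Wilcoxon + BH), matching
  how such comparisons are framed against "all genes".  The default
  minimum of 10 allele-resolved reads per gene is a pragmatic floor for
  ratio stability; upstream allele assignment is expected to have been
  done by dedicated tools.
* Expression classes: up (log2FC ≥ 1 and p < 0.05), down (log2FC ≤ −1
  and p < 0.05), non-expressed (below 1 RPKM in every sample,
  configurable), stable otherwise.  "Stable" is deliberately defined as
  *expressed but neither up nor down* — a literal reading that also
  demands p < 0.05 for stability would make the classes
  non-exhaustive.
* Relative expression profiles divide each gene by its mean across
  time points — a scale-free convention chosen for comparability
  across genes; all-zero genes are flagged undefined.  One caveat,
  verified empirically in the test suite: testing a later time point
  against the reference *across genes* after mean-scaling is mildly
  anticonservative under the null (the scaling couples the compared
  columns), so the tests assert the activated-versus-flat contrast
  (many orders of magnitude in p) rather than exact null calibration.
* Promoter k-mer overrepresentation uses presence/absence per promoter
  (an occurrence on either strand counts once, avoiding length
  confounding), a two-sided Fisher test per k-mer, and BH across the
  k-mers present in at least 3 target promoters.  Word sizes above 8
  are refused (4^k table guard).

# The synthetic-data generator

`simulate_study()` generates the full input suite with planted truth:

* **Genome/annotation** — uniform-random sequence, genes laid
  head-to-tail (500 bp genes, 200 bp spacers by default, random
  strand), each gene carrying 2 planted non-overlapping CTCTGYTY
  realisations on random strands.  After assembly the genome is
  re-scanned, so accidental motif occurrences enter the registry and
  keep the scanner honest.
* **Site methylation** — each CHG-capable site cytosine draws a
  Bernoulli methylation *state* from its gene's per-position
  probability; methylated cytosines then read at level 0.8 per read,
  unmethylated ones at 0.005 (a non-conversion-like error floor).
  This two-level model makes the observed per-position methylated
  fraction estimate the planted probability directly, while per-read
  background levels elsewhere (CG 0.20, CHG 0.02, CHH 0.02; gene-body
  CHG raised to 0.10 in H3K9me2-containing states, emulating the
  CHG/H3K9me2 coupling) govern region-level summaries such as the
  0.04 presence cut.
* **Coverage** — Poisson(depth) per cytosine and replicate with
  binomial methylated reads; depth 20 for methylomes (2 replicates),
  50 for allele-resolved counts.  Overdispersion is deliberately
  absent: the call rules' behaviour under Poisson–binomial sampling is
  what the analysis assumes, and a beta-binomial knob would blur the
  planted-parameter recovery the tests assert.
* **Defaults as study conditions** — group sizes 300/300/300/600
  (K27_only/K9_only/K27_K9/unmarked) give stable Fisher/Wilcoxon
  behaviour at desk scale; position-5 CHGm probability 0.7 in K27_K9
  (0.5 in K9_only) versus 0.05 in K27_only; maternal fraction 0.2 for
  K27_K9 genes with methylated sites (both conditions) and 0.85 for
  K27_only genes with unmethylated sites in dormant seeds, 2/3
  otherwise; germination time points 1–38 h of imbibition with a +3
  log2 activation of K27_only genes from 32 h (around endosperm
  rupture).
* **What is not emulated** — real *Arabidopsis* base composition,
  transposon landscapes, linked sites, read-level data (FASTQ), or
  allele-specific mapping bias.  Passing recovery tests therefore
  demonstrates the pipeline's correctness and sensitivity under the
  stated sampling model, not robustness to alignment artefacts or
  genomic confounders.

Everything is deterministic under (configuration, seed); stage seeds
are small fixed offsets of the master seed.

# Problem sizes in the tests

The validation suite runs the full pipeline at the default 1500-gene
configuration (a ~1 Mb genome, ~2 million cytosine records) for the
recovery checks, plus many small fixtures.  The k-mer fixtures use 40
genes with 300 bp promoters: with 4^6 hexamers and desk-scale gene
counts, 1 kb random promoters would contain any given hexamer ~40 % of
the time, making single-word detection a coin flip; 300 bp promoters
bring per-promoter presence to ~13 %, which is comparable to the
occupancy regime in which promoter-word statistics are informative.
Null calibration (a random target subset yielding no discovery) is
asserted over 20 seeded repetitions.

# Known limitations

* `simple_de_for_fixtures()` is a labelled stand-in used to fabricate
  differential-expression tables for synthetic runs; real DE tables
  should come from dedicated count-model tools and are consumed as
  input.
* Gene-body methylation scores inherited from prior studies may use
  slightly different weighting conventions; the read-weighted level
  used here is recorded in the outputs so downstream comparisons can
  account for it.
* The two-replicate call rule generalises to "every replicate" when
  more than two replicates are supplied.
* Chromatin-state assignment defaults to any-overlap (≥ 1 bp) between
  gene body and mark domain, with a configurable minimum overlap
  fraction, because the domain-to-gene assignment rule of upstream
  peak-calling pipelines varies; raising the threshold can only shrink
  the marked sets (a property the tests assert).
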