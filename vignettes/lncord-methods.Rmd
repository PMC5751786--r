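---
title: "Methods: identifying and annotating conserved lncRNAs with lncord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and annotating conserved lncRNAs with lncord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncord)
```

## The problem

Most long non-coding RNAs (lncRNAs) are unannotated: they are poorly
conserved as a class, tissue-specific, and rarely have experimentally
established functions. The small subset of lncRNAs whose genomic loci are
conserved between distant species (for instance human and rat, ~90 million
years diverged) is disproportionately likely to be functional, and the rat
side of such a pair makes the lncRNA experimentally accessible in a standard
animal model. `lncord` implements a coordinate-based workflow for this
setting: call high-confidence lncRNAs from assembled transcript models, pair
them across two genomes through a whole-genome alignment chain, and then
annotate the conserved pairs with three independent lines of functional
evidence — co-expression with protein-coding genes (PCGs), shared
bidirectional promoters, and monotone developmental expression trends.

Everything operates on genome coordinates and expression matrices; no
sequence alignment is performed. Internally all coordinates are 0-based
half-open (BED convention); GTF input/output converts at the boundary.

## LncRNA identification

Assembled transcripts are compared exon-to-exon against a reference
annotation and classified with a fixed precedence (PCG same-strand overlap,
then known-lncRNA same-strand overlap, then any opposite-strand overlap,
then novel single-/multi-exon). The filter cascade then keeps a transcript
iff

* spliced length ≥ 200 bp (the defining lncRNA length cutoff),
* coding-potential score ≤ 0.5 (scores are an input, e.g. from an external
  coding-potential classifier; the classifier itself is out of scope),
* maximum TPM across samples > 0 (expressed at all), and
* its class is `known_lncrna_match` or `multi_exon_novel`.

Boundary semantics are inclusive on the keep side: length exactly 200 and
score exactly 0.5 survive, because the removal rules are "less than 200 bp"
and "greater than 0.5". Length means spliced (exonic) length, the standard
reading for lncRNA definitions. Removal reasons are recorded in the order
length → coding → expression → class; membership of the kept set is
order-independent. Antisense-overlap and single-exon novel transcripts are
removed as likely assembly artifacts; transcripts whose intron wholly
contains a reference gene have no exonic overlap and therefore fall through
to the novel classes. Kept isoforms with identical exon chains are
deduplicated, preferring the annotated id.

Kept isoforms whose spans overlap by ≥ 1 base on the same chromosome and
strand are merged into families by single linkage; a family is the
locus-level unit of the final annotation table. Strand-restricting the
grouping is an assumption (divergent overlapping loci are biologically
distinct units).

## Orthology by chain liftover

Transcript spans are mapped through a UCSC chain file with liftOver's
default semantics, implemented from first principles: per-base mapping
through the blocks of the best chain, a minimum matched-base fraction of
0.95, the destination hull of mapped bases as output, reverse-strand query
coordinates converted only at output (`pos_fwd = q_size − 1 − pos_rev`),
and four statuses (`mapped`, `partial`, `ambiguous` when a second chain
also reaches the threshold, `unmapped`). Transcript spans — not per-exon
intervals — are lifted, consistent with comparing "genome coordinates" of
loci. The implementation is checked against a brute-force per-base mapper
and by round-tripping through programmatically inverted chains.

A destination-genome lncRNA whose span overlaps a lifted region by ≥ 1 base
(configurable) is a conserved partner; matching is strand-agnostic because
the lifted strand depends on chain orientation. Many-to-many pairs are kept
deliberately: a single source locus frequently maps onto several
destination isoforms of one family.

Cross-species expression similarity is summarized per transcript (median
TPM across that species' samples — the two species' sample sets do not
correspond, so no sample-wise statistic is possible) and compared by
Spearman rank correlation across pairs, separately for lncRNA pairs and PCG
orthologs.

## Sequence conservation

Per-base conservation scores (PhastCons-style, an input track) are averaged
over each transcript's exonic bases; unscored bases are excluded from both
numerator and denominator (conservation tracks are sparse), with a
missing-as-zero mode behind a flag. A random background is sampled uniformly
with lengths re-drawn from the lncRNA span-length distribution, rejecting
overlaps with annotated loci; matching is on length only. Groups are
compared by one-sided Wilcoxon rank-sum tests.

## Signed co-expression network

The network on conserved lncRNAs plus PCGs uses the signed weighted
adjacency

$$a_{ij} = \left(\frac{1 + \mathrm{cor}(x_i, x_j)}{2}\right)^{\beta},$$

which maps anticorrelation to 0 rather than to a strong edge, and the
topological overlap measure

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \neq i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}},$$

with modules from average-linkage clustering on $1-\mathrm{TOM}$ and a
static cut. Defaults and the reasoning behind them:

* `beta = 12`, the convention for signed networks. An automatic picker
  (`pick_soft_threshold`) returning the smallest power with scale-free fit
  R² ≥ 0.8 is provided, but planted-module synthetic data has no scale-free
  degree distribution for it to fit, so the pipeline uses the fixed
  convention.
* `cut_height = 0.9`. TOM dissimilarities concentrate near 1: between-module
  values sit at 0.97–1.0 while within-module merge heights are 0.3–0.9, so
  the static cut must sit just below the between-module plateau. (A cut at,
  say, 0.25 would shred every realistic module into singletons.) This is the
  static-cut convention of the reference WGCNA implementation. Dynamic tree
  cut is a non-goal.
* `min_module_size = 30`; smaller clusters become `unassigned`.
* Module labels are deterministic: ordered by size, ties broken by the
  lexicographically smallest member id.
* Expression is `log2(TPM + 1)`-transformed before Pearson correlation.

Node importance uses the module-normalized connectivity: an edge joins two
same-module nodes with TOM > 0.2 (a hard threshold; a TOM-weighted degree
mode exists behind a flag), and $c_i = \mathrm{degree}_i / \sum_{\text{module}}
\mathrm{degree}$, so connectivities sum to 1 within each module that has at
least one edge. LncRNAs are compared to PCGs with a one-sided Wilcoxon
rank-sum test on $c_i$ pooled across modules.

## GO enrichment and interaction support

Each module's PCGs are tested per GO term with the upper-tail
hypergeometric probability $P(X \ge k)$ against a universe of all expressed
PCGs (expressed-gene background avoids detection bias). The default
significance rule is raw $p < 0.05$, mirroring common practice for this
analysis; Benjamini–Hochberg correction is available and recommended when
many terms are tested. Module lncRNAs inherit their module's significant
terms. When lncRNA–protein interaction scores are supplied (0–100 scale,
e.g. from a sequence-based interaction predictor; the predictor is out of
scope), an inherited term is flagged interaction-supported if the lncRNA
scores > 50 with at least one module gene annotated to that term.

## Bidirectional pairs and temporal trends

A divergent (bidirectional) lncRNA–PCG pair shares a promoter region: the
two transcripts lie on opposite strands, head-to-head, with transcription
start sites (TSS = 5′ end of the span) at most 2000 bp apart (inclusive),
and no other TSS strictly between them (nearest-neighbor adjacency). TSS
distance — rather than gene-boundary distance — is the anchor because the
shared-promoter rationale concerns the start sites. Overlapping divergent
transcripts (negative distance) are excluded by default. A pair is
conserved-bidirectional when a conserved partner of the lncRNA forms a pair
(same rule) with the PCG's ortholog in the second genome; PCG orthology is
an input table, not computed.

Temporal trends over the four developmental stages (W2, W6, W21, W104) are
strict monotone runs on per-stage mean TPM: `up` iff every stage mean
strictly exceeds the previous one ("consistently increased" read literally;
ties break the trend), with an optional per-step fold-change margin
(`min_ratio`) for noise robustness. Calls are made per isoform on the
destination genome and mapped back to source lncRNAs through the conserved
pairs; conflicting partner trends are flagged `mixed`. Note that strict
monotonicity on noisy flat genes produces a predictable false-positive rate
(a flat 4-stage profile is strictly monotone by chance with probability
2/4! ≈ 8%); the margin parameter exists for exactly that reason.

Finally, evidence is OR-ed at family level (coexpression / bidirectional /
temporal flags), and coverage is the fraction of conserved families with at
least one flag, with exact Venn counts over the seven flag combinations.

## The synthetic study

`synthetic_config()` defines a fully self-contained two-genome study with
known ground truth, emulating a human/rat brain RNA-seq design at desk
scale. What it emulates, and the default conditions:

* **Genomes**: 2 chromosomes of 1 Mb per genome; 150 PCGs and 60 lncRNAs
  placed in non-overlapping slots; 30 conserved lncRNA loci, each mapped by
  one alignment chain (±500 bp flank), 30% of them on the reverse strand of
  genome B; non-conserved loci fall outside every chain block. A split-chain
  mode emits gapped two-block chains to exercise partial mapping.
* **Assembled set**: the planted lncRNAs (biotype unknown, as an assembler
  would emit) plus two distractors per filter rule (too short, coding,
  unexpressed, antisense, single-exon, PCG-overlap), so the filter's kept
  set can be compared to the plant exactly.
* **Expression**: a one-factor-per-module latent model, the simplest
  structure weighted co-expression methods provably recover. Gene $g$ in
  module $m$ draws $x_{gs} = \lambda_g f_{ms} + \varepsilon$; TPM is
  $\exp(\mu_g + 0.3\,x_{gs})$, which keeps values positive without changing
  rank structure. LncRNA members get the largest loadings (1.4 vs 0.8–1.0
  for PCGs), planting them as hubs. The default within-module correlation
  target is 0.75: the connectivity statistic thresholds TOM at 0.2, which at
  $\beta = 12$ corresponds to pairwise correlation ≈ 0.75, so the planted
  correlation must straddle that point for degree to be graded — denser
  modules saturate every degree and erase the hub signal, a property of the
  statistic, not of the data. 80 samples per species mirror the scale of
  the human brain cohort the design emulates.
* **Cross-species coupling**: conserved pairs and PCG orthologs share their
  log-baseline $\mu_g$ across genomes with jitter (SD 1.25 for lncRNAs,
  0.75 for PCGs), reproducing the empirical ordering that PCG expression is
  better conserved than lncRNA expression.
* **Temporal series**: 4 stages × 3 replicates; 5 genes planted strictly up
  and 5 strictly down (log-scale step 0.8 per stage), everything else flat;
  lognormal replicate noise (SD 0.1; 0 gives noiseless data for exactness
  tests).
* **GO map**: 30 terms at background rate 0.05 per gene, one fold-10 term
  planted per module.
* **Bidirectional plants**: divergent lncRNA–PCG pairs at TSS distances
  500/1000/2000/2001 bp in both genomes — 2001 sits just outside the
  threshold by design.
* **Conservation track**: interval scores with means 0.6 (PCG exons), 0.4
  (lncRNA exons), 0.2 (1 kb background bins), SD 0.05, clipped to [0, 1].

All generators are byte-deterministic under the config seed. What the
synthetic data does **not** emulate: read-level noise and assembly errors,
GC/mappability structure, overlapping gene models, correlated GO terms,
multi-chain paralogy, and batch effects. Passing tests therefore demonstrate
correctness of the computations and recoverability of planted structure,
not performance on real RNA-seq.

## Numerical and degenerate-input choices

Hypergeometric p-values use `phyper(k−1, K, N−K, n, lower.tail = FALSE)` and
are validated against exhaustive enumeration for all universes up to N = 12.
Wilcoxon tests use the normal approximation under ties (identical groups
give p ≈ 1 one-sided). Constant expression features are dropped with a
warning before correlation. Transcripts without any scored conservation base
yield `NA` with a warning rather than an error in batch mode. Empty pair
tables, empty modules, and chromosomes absent from a reference are all valid
inputs with documented degenerate outputs; the pipeline aborts with the
stage name on genuinely missing inputs.

Problem sizes used by the test-suite and the reproduction script (default
study: ~210 genes, 80 samples; module-recovery runs: 3 × 50-gene modules,
100 samples; liftover oracle: 1000 random intervals) keep a full run within
a few minutes on one CPU while leaving every planted effect comfortably
detectable.

## Known limitations

* Orthology is purely coordinate-based; paralogous chains are only handled
  through the ambiguity status, and no synteny inference is attempted.
* Module detection is a static cut; very unequal module sizes or nested
  correlation structure would favor dynamic tree cut, which is out of scope.
* The "significance" of a module is its size rule only; the GO stage then
  decides which modules carry functional signal.
* The default raw p < 0.05 enrichment rule is anti-conservative when many
  terms are tested; use `correction = "BH"` for real analyses.
* Family grouping by span overlap can chain distinct but overlapping loci
  on the same strand into one family (single-linkage behavior).
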