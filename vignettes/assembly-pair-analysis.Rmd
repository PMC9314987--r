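---
title: "Comparing assembly pairs: structural variants, segmental duplications and X-chromosome traffic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing assembly pairs: structural variants, segmental duplications and X-chromosome traffic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmpair)
```

## The scientific setting

When two high-quality assemblies of closely related genomes are available
— for instance a de novo assembly of a wild population and the curated
reference of its domesticated relative — their direct comparison gives
access to classes of variation that short-read mapping misses:

* **large intra-chromosomal structural variants** (deletions, insertions,
  duplications and inversions of a kilobase and more), whose
  per-chromosome counts can be tested against a neutral "longer
  chromosome, more events" expectation;
* **inter-chromosomal segmental duplications** (SDs), where two loci of
  one assembly align to a single locus of the other; once the parental
  and derived copies of each pair are told apart, SDs become a record of
  directional gene traffic between chromosomes, in particular between the
  X chromosome and the autosomes, where meiotic sex chromosome
  inactivation (MSCI) is expected to push gene copies off the X;
* **continuity differences**: runs of `N` in one assembly that the other
  assembly spans with real sequence, and per-chromosome gapless-length
  ratios.

`asmpair` implements this comparison end to end and, because real
assembly pairs are gigabase-scale, ships a first-class simulator that
generates desk-scale assembly pairs with planted ground truth, so that
every stage of the pipeline is testable and its operating
characteristics (precision, recall, direction accuracy) are measurable
rather than assumed.

## The simulated study system

`simulate_pair()` draws an ancestral genome of uniform random sequence,
then produces

* **assembly B** by applying background substitutions at rate
  `background_divergence` (default `0.001` per bp, a scale typical of
  within-species assembly comparisons) and planting events: deletions
  remove sequence, insertions add novel random sequence, duplications
  copy a segment in tandem, inversions reverse-complement in place, and
  segmental duplications insert a mutated copy of a parent segment on
  another chromosome;
* **assembly A** by overwriting `ngap_count` intervals with `N` — A plays
  the "reference-like" role, so gaps live only there, and the planted
  events are what B acquired relative to A's underlying sequence.

Derived SD copies are mutated at `derived_extra_divergence` (default
`0.02`): the derived copy has accumulated its own substitutions since
the duplication, which is exactly the signal the parental-resolution
rules exploit. The default SV intensity (10 events/Mb split 3:3:2:2 over
DEL:INS:DUP:INV) and 12 SDs split evenly over the three direction
categories give, on the 3-Mb and 1.6-Mb test genomes used throughout,
event densities high enough to measure recovery rates on a laptop while
keeping planted events resolvable.

Placement is rejection-sampled so that events never overlap each other
or an N-gap and keep `margin` (default 2,500 bp) of untouched sequence
between them and from chromosome ends; without such a margin two
adjacent events would merge into one alignment gap and no caller could
tell them apart, so the margin is part of the study conditions, not a
convenience. A single seed drives named substreams per event class, so
e.g. adding SDs to a configuration does not perturb where the SVs land.

What the simulator deliberately does **not** model: repeat families and
segmental low-complexity sequence (anchor uniqueness is nearly free on
random sequence, and much harder on real genomes), small indels
(< 50 bp), translocations, and read-level artifacts. Passing the test
suite therefore demonstrates the correctness of the *logic* — coordinate
arithmetic, classification rules, direction resolution, statistics — not
that the bundled anchor aligner would be competitive on a real pig-sized
genome; for real data the PAF import path exists precisely so that a
production aligner (minimap2, MashMap, LASTAL) can be substituted.

## Alignment

`anchor_chain_align()` is a unique-anchor chaining aligner: exact
`k`-mers (default `k = 21`) that occur once in the query genome and at
most `max_target_hits` (default 4) times in the target are chained
greedily while the diagonal drifts by at most `gap_tol` (default 100 bp)
and consecutive anchors are at most `max_anchor_gap` (default 500 bp)
apart. Chains end at strand flips, diagonal jumps and anchor deserts —
that is, exactly at rearrangement breakpoints and N-runs — and blocks
shorter than `min_block` (default 1,000 bp, the same unit as the SD
definition) are discarded. Identity is defined as matching columns over
all columns of the gap-free comparison along the chained span.

Allowing bounded target-side multiplicity is what lets duplications
surface: the parent locus of an SD aligns both to its ortholog and to
the derived copy, producing the "many-to-one" signature downstream
modules consume.

`pairwise_identity()` is a banded global aligner under unit
match/mismatch/gap scoring. Because several minimum-cost alignments of
the same pair can have different column counts, the implementation
resolves ties explicitly — minimize cost, then maximize matches, then
minimize columns — making the reported identity deterministic and
symmetric; the test suite checks it against an independent full-matrix
dynamic program on short sequences. Sequences up to 2 kb are aligned
with the full matrix; beyond that the band defaults to the length
difference plus 64, which is ample for the substitution-dominated
comparisons the pipeline makes.

## One-to-one synteny and continuity

`one_to_one_map()` discards blocks below `min_identity` (default 0.90,
the conventional orthology threshold for within-species comparisons),
resolves overlaps in score order, and chains the survivors. Two details
matter:

* **Trimming, not discarding.** When a lower-scoring block overlaps a
  retained one, only the overlapping part is removed; the residue
  survives if it keeps at least a few hundred base pairs. A block that
  competes for the same locus (a derived SD copy) loses everything and
  drops out, while a block that merely re-reads a tandem-duplicated
  interval keeps its unique part — dropping it whole would sever the
  chain and fabricate deletion/insertion calls.
* **Query rewinds.** Downstream of a tandem duplication the next block
  re-reads the duplicated query interval while the target continues
  forward. Chaining accepts this "rewind" (negative query gap with a
  continuous target) so the chain stays intact across duplications.

`chain_span` — the summed block length of a chain, robust to interleaved
insertions — is the "synteny length" used by the SD module.

`gap_fill_stats()` operationalizes "gap in an orthologous region" as: the
1 kb flanks on both sides of an N-run lie inside one-to-one blocks. A gap
counts as *filled* when both flanks map through blocks of the same chain
to the same chromosome of B and the implied spanning interval on B is
N-free. On simulated pairs every planted gap with intact flanks is
recovered (the test suite asserts recall 1.0), which validates the
accounting rather than any property of real gaps.
`gapless_length_ratio()` reports per-chromosome non-N length ratios
(B over A); chromosomes absent from one assembly or entirely N are
reported missing rather than erroring.

## Structural-variant classification

`classify_svs()` walks the junctions between consecutive blocks of each
name-matched chain: advance on A only is a deletion, advance on B only
an insertion, advance on both is split into one deletion plus one
insertion (the four counted types have no "substitution" class). A
minus-strand chain with plus-strand context on the same chromosome is an
inversion over its envelope. Duplications come from pairs of blocks
whose query intervals overlap by at least `dup_min_len` while their
projected target intervals are disjoint — two B copies of one A interval
— which covers both tandem copies (that surface as overlapping block
heads) and dispersed intra-chromosomal copies. Insertion calls whose B
interval is explained by a duplicated copy (tandem or an
inter-chromosomal SD) are suppressed so the categories stay disjoint.

Numerical tie-breaks and tolerances: coordinate advances below `min_gap`
(50 bp — the lower bound of what counts as structural here) are treated
as breakpoint jitter and ignored; both events of a junction share the
junction's A and B context for the `continuous` flag, so a gap junction
(N-run) marks its deletion *and* insertion discontinuous and the
continuity filter removes both. `filter_svs()` applies the `>= 1 kb`
length rule — a 999 bp event is removed, a 1,000 bp event kept — and the
continuity rule. Deletion/insertion polarity is expressed in A
("reference-like") coordinates: a deletion is present in A and absent in
B. Translocation-like chains (different chromosome names) are counted
and skipped with one warning; they are out of scope.

## Segmental duplications and direction resolution

`find_many_to_one()` pairs raw blocks that share an anchor locus
(reciprocal overlap at least 0.8 of the shorter block's anchor span,
each block at least 1 kb) while their projected copy loci are distinct;
families of n copies expand to all C(n,2) pairs under one family id. In
this package's orientation the anchor lives in assembly A and the copies
in assembly B, because the simulator inserts derived copies into B; the
`anchor_side` argument swaps the roles for comparisons run the other way
around. Copy loci are obtained by projecting the shared anchor interval
through each block, so a copy embedded in a long syntenic block gets its
actual locus, not the whole block.

`classify_sd()` assigns each pair to the boundary-derived (`bSD`) or
internal-derived (`iSD`) class: a copy is enclosed by the chain whose
blocks cover at least half of it; a pair is `bSD` when either copy has
no enclosing chain, extends beyond its chain envelope, or ends within
`boundary_tol` (1 kb) of it. A few base pairs of jittered contact with a
flanking block deliberately do not count as enclosure — a freshly
inserted copy has no syntenic context and must classify as boundary.

`resolve_parent()` applies the two rules: for `iSD`, the copy with the
longer enclosing `chain_span` is parental (a derived copy interrupts
pre-existing synteny, so its context is shorter); equal spans fall back
to the identity rule. For `bSD`, each copy is aligned to the anchor
sequence and the copy with the higher identity is parental, provided the
winner exceeds 0.90; ties and sub-threshold winners resolve to
`unresolved` rather than a guess — on simulations with no extra derived
divergence the resolver indeed reports unresolved rather than being
confidently wrong. The direction category (`A>A`, `A>X`, `X>A`) follows
from the parental copy's chromosome class, and `categorize_direction()`
tallies each resolved pair once on its derived copy's chromosome, with
unresolved pairs tallied separately so totals conserve exactly.
`genes_in_derived()` intersects derived copy intervals with a gene
annotation (one base pair of overlap suffices) for downstream enrichment
work, which is itself out of scope here.

## X-versus-autosome statistics

`fit_autosome_regression()` fits ordinary least squares of event count
on chromosome length over autosomes only. OLS on raw counts is used
(rather than a Poisson GLM) because the underlying null is a straight
line through the origin and the published comparisons in this field
report linear fits; a `mode = "poisson"` sensitivity fit is available.
`x_deviation()` predicts the X count from the fit, scales the
expectation by `ne_factor` (default 0.75: the X is carried in roughly
three quarters as many copies as an autosome, so its effective
population size is about three quarters of the autosomal one) and
reports the signed percentage deviation; because the adjustment weakens
deficiencies but strengthens excesses, the unadjusted deviation is
always co-reported. `outlier_test()` treats the X as a new observation
and computes the studentized prediction residual
$t = (y_X - \hat y_X)/\mathrm{SE}_{pred}$ with
$\mathrm{SE}_{pred} = s\sqrt{1 + 1/n + (x_X-\bar x)^2/S_{xx}}$ on
$n-2$ degrees of freedom, two-sided. Degenerate fits (zero residual
variance with an off-line X) report the p-value as not computable
rather than zero, and an observation exactly on the line returns
$t = 0$, $p = 1$ before any division. p-values across the four SV
categories and the SD directions are reported raw, without
multiple-testing correction, and flagged as such.

`simulate_count_table()` generates Poisson autosome counts on a pig-like
karyotype (18 autosomes of 40–274 Mb plus a 126 Mb X) and plants an X
count at a chosen fraction of the Ne-adjusted expectation; the test
suite uses it to show that a planted 50% deficiency is estimated at
−50% on average with p < 0.001 in essentially every replicate.

## Problem sizes and reproducibility

The bundled tests and the acceptance script run entirely on simulated
pairs: 3 × 1 Mb chromosomes with 30 planted SVs for variant recovery
(20 replicates), 4 × 0.4 Mb chromosomes with 12 planted SDs for
direction recovery (20 replicates), and 200 replicates of the count
regression. These sizes keep a full run in the minutes range on one CPU
while leaving dozens of events per replicate; all randomness descends
from one user-supplied seed, and identical configurations produce
byte-identical FASTA, truth tables and result TSVs (the pipeline
manifest records md5 checksums to make this checkable).

## Known limitations

* The anchor aligner assumes low divergence and unique sequence; on
  repeat-rich real genomes it will fragment and the PAF import path
  should be used instead.
* Duplication polarity (which assembly gained the copy) is not split
  into separate classes; DUP events carry the extra copy's B interval as
  an attribute.
* SV lengths at breakpoints carry up to tens of base pairs of jitter
  from breakpoint micro-homology; counts and length-scale statistics are
  unaffected.
* The gap-denominator counts maximal N-runs; assemblies that record
  inter-contig gaps as fixed-width runs will count each run once,
  which may differ from counting gap records.
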