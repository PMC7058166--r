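---
title: "Inferring ORC subunit duplication and loss on a species tree"
author: "orcEvo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ORC subunit duplication and loss on a species tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orcEvo)
```

## The model

The origin recognition complex marks DNA replication origins in
eukaryotes. Its AAA+ ATPase subunits — ORC1 through ORC5 plus CDC6 —
derive from one archaeal cdc6/orc1 gene, and because extant CDC6 and
ORC1 sequences are not always separable, the two are pooled into a
single `CDC6/ORC1` family throughout. The reconstructed ancestral state
is six subunits: two `CDC6/ORC1` copies and one each of ORC2–ORC5
(`ancestralProfile()`). Extant genomes deviate in both directions, and
the package's core task is to explain the observed per-taxon copy
numbers by duplication and loss events placed on a rooted species tree.

**Lineages.** Every node of the tree, root included, is one lineage
(the node plus the branch subtending it); a binary tree over $n$ taxa
has $2n-1$ lineages. A lineage is parasitic iff every descendant
species is parasitic (`propagateLifestyle`); WGD status is a per-branch
annotation with three levels (`none`, `reported`, `uncertain`), and the
`uncertain` branches are excluded from the WGD class unless explicitly
included, so the class only contains branches with positive evidence.

**Event inference.** For one family with leaf counts $c_\ell$ and root
count $r$, we seek ancestral copy numbers minimizing the total event
count, where a branch from state $s$ to state $t$ carries $|s-t|$
events ($t>s$: duplications, $t<s$: losses). Two constraints shape the
search space:

1. *Single origin (Dollo)*: the family originates at the root; a node
   may be assigned zero copies only if every leaf below it has zero.
   Losses therefore land at the stems of maximal extinct clades.
2. *Gene-tree constraints*: when paralogs are known to be
   species-specific, the terminal branch must carry the corresponding
   duplications (an ancestral duplication is disallowed as their
   origin); dually, a clade's stem can be barred from duplications.

Subject to these, a Sankoff dynamic program over states
$0,\dots,\max(c)+1$ finds the global minimum in polynomial time;
multifurcations are handled natively by summing child costs. Among
co-optimal assignments the backtrace picks the smallest child state,
which (i) delays duplications toward the tips — matching how
species-specific paralogs are treated — and (ii) places losses at the
roots of extinct clades; the output is therefore deterministic. The
test suite checks the optimum against exhaustive enumeration of all
Dollo-feasible assignments on hundreds of random small trees, and
checks on every run that replaying the inferred events from the root
reproduces the input counts exactly.

If the root count is zero while some leaf is positive the input is
rejected: under single origin the family cannot reappear. When a family
is absent from every leaf but present at the root, the losses are
reported on the root's child branches, since the root itself has no
subtending branch in the model.

## Enrichment statistics

The headline claims are branch-class enrichments: losses concentrate in
parasitic lineages, duplications in WGD lineages. `enrichmentTest`
builds the table

$$\begin{bmatrix} \text{events in class} & \text{events outside} \\
\text{lineages in class} & \text{lineages outside} \end{bmatrix}$$

and computes the one-tailed (upper) Fisher exact tail by summation of
the hypergeometric pmf in log-factorial space — with the printed study
tallies (41/69 losses, 83/263 lineages) this reproduces the reported
$P = 2.43\times10^{-5}$. This "margins" construction concatenates an
event margin with a lineage margin rather than cross-classifying one
set of units; it is kept as the default because it is the construction
under which the published number is recovered, and simulation shows it
is conservative under a uniform-placement null (empirical type-I error
about 0.026 at nominal 0.05 over 2000 draws). A conventional
alternative — hypergeometric placement of the event-bearing lineages
onto the lineage set — is available via `construction = "placement"`;
multiplicities collapse to presence there because a lineage cannot be
"drawn" twice. For the WGD-duplication tallies (11/39 on 20/263) the
two constructions give $5.4\times10^{-4}$ and $1.3\times10^{-5}$
respectively; neither matches the published $2.117\times10^{-5}$
exactly, so both are always reported and nothing downstream depends on
that value.

`mannWhitney` reports the U statistic for the first sample. With at
most 20 untied observations the exact null distribution of U is built
from the Mann–Whitney partition recurrence; otherwise a normal
approximation with midrank tie correction and continuity correction is
used, mirroring common statistical-package behaviour. A full
permutation mode (`method = "exact"`) enumerates all rank splits with
midranks and works with ties; it is the reference the other paths are
tested against. `spearmanRho` is defined as the Pearson correlation of
midranks — the definition itself handles ties, so no separate tie
correction is applied.

## Configuration classes, normalization and clustering

Relative to a reference profile, a taxon is `ancestral` (equal),
`expanded` (nowhere below, somewhere above), `reduced` (nowhere above,
somewhere below — note a taxon with a single `CDC6/ORC1` copy and all
else at reference is reduced), or `mixed`. For display alongside the
dendrogram, genome size is log10-transformed and scaled by the largest
genome's log10 (so the largest scores exactly 1), and gene content is
scaled linearly by the largest proteome. Clustering uses Euclidean
distance with complete linkage by default; both are configuration keys
because the choice shapes only the presentation — the tested artifact
is the ordered long-format table, and no downstream statistic depends
on the dendrogram's shape. Taxa are sorted by label before distance
computation so merge ties resolve deterministically and the result is
input-order invariant.

## PACT-region conservation

Each ORC1 ortholog is aligned globally to the human reference
(Needleman–Wunsch, affine gaps; BLOSUM62 with gap opening 10 and
extension 1 by default — a gap of length $L$ costs
$\mathrm{open} + L\cdot\mathrm{ext}$). Columns are split by reference
coordinate into the two PACT motifs versus background; columns where
the reference row is a gap carry no reference coordinate and fall to
the background. Per region, identity is the fraction of identical
pairs and similarity the fraction of pairs whose minimum-codon-change
distance (Fitch 1966; computed from the standard genetic code and
shipped as `fitchMatrix()`) is at most 1, both over columns with both
residues ungapped; identical pairs always count as similar, so
similarity ≥ identity by construction. The motif:background ratio of
each measure is the per-taxon statistic, compared between
centriole-bearing and centriole-lacking taxa by a two-tailed
Mann–Whitney test.

Two reconstruction caveats are deliberate: the exact PACT motif
coordinates are configuration input (`motifSpec`, `readMotifs`), not
hard-coded, because published coordinates live in cited work rather
than in a machine-readable form; and the identity/similarity
definitions above are this package's explicit reconstruction of the
measures — externally produced pairwise alignments can be ingested
(`alignmentPair`, `preAligned = TRUE`) when fidelity to another
aligner's gaps matters.

## Orthology assignment

Queries in a reference-labeled gene tree get the family of the smallest
enclosing clade whose reference leaves are family-pure (CDC6 and ORC1
pooled): `bona_fide` with ≥ 2 supporting references, `likely` with 1,
`uncertain`/`unassigned` when every enclosing clade mixes families.
These tiers are explicit, testable stand-ins for the bona-fide/likely
vocabulary whose full criteria are not published in the main text; the
same goes for false-paralog removal, which collapses same-species,
same-family sequences connected at ≥ 95% pairwise global identity
(single linkage, threshold configurable) to the longest representative
and logs every removal. The last member of a group is never removed.

## The synthetic-data generator

The generator exists so that every stage can be validated against known
truth without any external download. Its defaults describe the regimes
the analysis assumes:

- per-branch duplication and loss events are Poisson with means 0.03
  and 0.05 — rare enough that parsimony is near-exact while still
  exercising the machinery;
- parasitic lineages multiply the loss rate (streamlining); classes are
  assigned by marking whole random clades parasitic until a target
  fraction of lineages is reached, so the lifestyle-propagation
  invariant holds by construction (candidate clades that would
  overshoot the target by more than two lineages are skipped, keeping
  the realized fraction within a few points of the target);
- WGD branches double the incoming copy count — before that branch's
  stochastic events — and record the increment as duplications;
- losses drawn on a branch beyond the available copies are discarded
  and *not* recorded, so replaying the truth map always reproduces the
  matrix exactly (the censoring convention);
- sequences are drawn as a uniform random reference plus independent
  per-site substitutions at a background probability outside the motifs
  and a class-specific probability inside them; no indels by default,
  so simulated sequences remain reference-aligned and the conservation
  machinery can be exercised with and without the aligner.

What passing these simulations does and does not show: the generator
produces clean Poisson event histories on a known tree with exact
class labels — real data add gene-tree estimation error, annotation
noise, correlated rates and alignment uncertainty, none of which are
modeled. The simulations validate the algorithms, not the biological
conclusions.

**Problem sizes.** Three scales are used, chosen as the package's own
validation design. Parsimony recovery runs on 16-taxon trees with one
family per dataset at the default rates; per family this yields two or
three true events, the regime where "parsimony is consistent at low
rates" is a per-family statement (with five interacting families per
dataset the expected twelve events routinely admit cheaper explanations
than the truth — independent sibling losses merge into one ancestral
loss — and exact recovery is no longer the right yardstick). Enrichment
power runs at the study scale of 132 taxa / 263 lineages with 25%
parasitic lineages and a 5× loss multiplier, where the test detects
enrichment in ≈98% of replicates and stays below 5% rejections under
the null; at toy sizes too few events exist per dataset for any test to
be powerful. Sequence-comparison calibration uses 40 taxa (20 per
centriole class) and 200-residue references across 100 seeds.

## Numerical and degenerate-input choices

- Fisher tails are exact log-factorial sums; the pmf over the support
  is verified to sum to 1 within $10^{-12}$.
- Alignment traceback determinism is inherited from the alignment
  engine; scores are verified against an independent brute-force
  affine-gap DP.
- Single-leaf trees (`"(A);"`) and multifurcations parse and flow
  through every stage; no binarization is ever forced.
- Degenerate statistics error loudly rather than return NA: constant
  vectors for Spearman, empty samples for Mann–Whitney, all-zero
  tables for Fisher, empty lineage classes, zero background
  conservation (an undefined ratio), replay below zero copies.
- Generators take an explicit seed (or inherit the caller's RNG
  state); no hidden seeding.

## Known limitations

- The reconciliation is parsimony, not a birth–death likelihood: rate
  heterogeneity is expressible only through constraints, and event
  counts are lower bounds under high turnover.
- The published global tallies (69 losses, 47 duplications) drew on
  per-family gene-tree judgments that are not fully enumerable from
  text; the constraint file format carries such judgments, but exact
  reproduction of those tallies is not claimed — the DP's optimality is
  instead certified against exhaustive search.
- The per-species supplementary tables of the original study are not
  redistributed here; the summary-statistic recomputations
  (mean subunit count, configuration-class tallies, correlations,
  parasite shift) activate when those tables are placed under
  `inst/extdata/supplementary/`.
- Horizontal transfer, gene conversion and ILS are out of scope, as is
  multiple-sequence alignment: the conservation analysis is strictly
  pairwise against one reference.
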