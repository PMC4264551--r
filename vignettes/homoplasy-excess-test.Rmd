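---
title: "Detecting hybrid taxa in multilocus phylogenies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hybrid taxa in multilocus phylogenies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Hybridisation leaves two complementary signatures in multilocus DNA data.
First, because mitochondria are maternally inherited while nuclear alleles
sort between the parents, trees built from mitochondrial and nuclear
partitions can disagree — *cytonuclear discordance*.  Second, a hybrid
taxon whose genome is a mosaic of two parental lineages injects conflicting
phylogenetic signal into a concatenated nuclear matrix: at each locus it is
identical to one parent, so different loci vote for incompatible
placements.  That conflict expresses itself as homoplasy, and it depresses
bootstrap support precisely at the nodes that contain the parental
lineages.

`phyloHET` implements three linked analyses around these signatures:

1. the **homoplasy excess test (HET)**: a taxon-removal jack-knife that
   asks, for every candidate taxon (or small monophyletic group), whether
   its removal raises per-node bootstrap support *more than removing a
   random taxon would*;
2. **cytonuclear discordance detection**: an algorithmic comparison of the
   nuclear and mitochondrial consensus trees restricted to well-supported
   conflict;
3. **parent assignment of recent hybrids**: placement of a putative
   hybrid's mitochondrial markers (maternal side) and cloned nuclear
   alleles (one per parent in an F1) onto a reference phylogeny.

A synthetic-data module generates multilocus datasets with known ground
truth (species tree, hybrid donors per locus, regrafted mitochondrial
genealogy) so the whole pipeline is testable end to end without external
data.

# The homoplasy excess test

For a focal removal set $i$ (a taxon, or a monophyletic group of up to 8
taxa), the test:

1. removes $i$ from the concatenated nuclear supermatrix;
2. infers `n_boot` bootstrap trees on the reduced matrix (columns resampled
   with replacement within each gene partition) and, for every reference
   node, records the percentage of bootstrap trees containing that node's
   bipartition — the observed support $BS_i$;
3. builds a null distribution by repeating step 2 for `n_null` random
   removals of the same size drawn from the non-focal, non-outgroup taxa;
4. flags the node when $BS_i$ falls above the *upper whisker* of the null:
   the highest null value within $1.5\,\mathrm{IQR}$ above the upper
   quartile, with quartiles computed as Tukey hinges.  The comparison is
   strict (`observed > whisker`), so a degenerate null with zero spread is
   only exceeded by a genuinely larger value.

Defaults are `n_boot = 100`, `n_null = 100`, groups up to size 8 — the
scale at which the test was originally applied.

## Node identity across taxon subsets

After a removal the reference node no longer exists verbatim, so "the
support of node $k$" needs a definition.  We use bipartition restriction:
both the reference split and every replicate tree's splits are intersected
with the same surviving taxon set before matching; a split whose
restriction leaves fewer than two taxa on either side is *undefined* for
that replicate and contributes nothing.  Observed and null values for a
node therefore always use identical split semantics, and `run_het()`
accepts a reference tree built on a subset of the supermatrix taxa (the
validation experiments exploit this to track the generating species tree's
nodes while the injected hybrid is still present in the matrix).

## Quartiles, whiskers and tie handling

Quartiles are Tukey hinges (the median of each half of the sorted sample,
the median included in both halves when the count is odd) because the
outlier rule is a boxplot rule; `quartile_method = "linear"` switches to
type-7 quantiles.  For the worked sample $\{50, 52, 55, 57, 60\}$ the
hinges are 52 and 57, the fence $57 + 1.5 \times 5 = 64.5$, the whisker 60;
an observed support of 61 is an outlier, 60 is not.  Nodes with fewer than
`min_null_valid = 5` defined null values are reported untestable rather
than tested against a meaningless sample.

## The null: fresh versus shared

The faithful design draws a fresh null per focal set (`shared_null =
FALSE`): replicate $r$ of size $n$ draws its removal from its own named
substream, redrawing only on collision with the focal set, so the null is
identical across focal sets unless a collision forces a redraw.  The
shared-null economy mode draws one pool per removal size and, for each
focal set, masks the replicates whose removal overlaps it; on large
designs this reduces tree inference by an order of magnitude.  Null group
removals are arbitrary random sets by default (`null_monophyletic = FALSE`)
— matching a null defined as "remove $n$ random species" — while focal
groups must be monophyletic in the reference tree.

# Desk-scale inference and the backend contract

Tree estimation inside the test is deliberately pluggable: any function
mapping a supermatrix to an `ape::phylo` on the same leaf set can serve as
the backend.  The built-in backend is JC69 distances (pairwise deletion of
`-`/`?`/`N`) followed by neighbour joining, with two numerical guards:
saturated pairs ($p \ge 3/4$, where the JC69 log diverges) are capped at 10
substitutions/site with a warning, and negative NJ branch lengths are
clamped to zero with the deficit moved to a sibling edge.  Bootstrap
support uses within-partition column resampling so every gene contributes
exactly its own length (`--bootstrap-scope global` resamples across the
whole matrix instead).  Consensus trees are extended majority rule: all
splits above 50% plus lower-frequency splits added greedily, in decreasing
frequency (ties broken lexicographically on the canonical split), while
compatible with everything already accepted.

Internally the bootstrap loop is pattern-compressed: per-pair mismatch
indicators are precomputed at variable sites, a bootstrap replicate is a
multinomial weight vector over columns, and all replicate distance
matrices of a removal fall out of one matrix product.  The draws are
identical to materialising `bootstrap_resample()`, which the unit tests
verify.

## A known limitation: distances linearise mosaic conflict

The homoplasy excess signal is a *character-level* phenomenon.  A distance
backend averages it away: the concatenated distance from a mosaic hybrid to
any other taxon is a locus-weighted average of the two parents' distances,
which is approximately realisable by attaching the hybrid along the path
between its parents.  Neighbour joining therefore tends to place the
hybrid stably instead of letting it destabilise replicates, and the
acceptance experiments show correspondingly conservative detection power,
while type-I behaviour stays well controlled.  Character-based backends
(parsimony, likelihood) express the conflict directly and can be plugged
in through the backend contract where their cost is acceptable; the
package keeps the distance backend as default because it is fast enough to
run the full jack-knife design in minutes and exact oracles exist for
every piece.

# Cytonuclear discordance

`compare_trees()` reports three layers: shared bipartitions with both
supports; *conflicts*, pairs of mutually incompatible bipartitions each
meeting `min_support` (default 95) in its own tree; and *unsupported*
incongruence, which is listed but never interpreted — absence of
resolution is not discordance, and weakly supported topological noise
should not be read as hybridisation.  For clades supported in both rooted
trees a relocation summary gives the clade with its two sister groups.
The 95 default maps the conventional 0.95 posterior-probability reporting
threshold onto the bootstrap scale; this is a configuration default, not a
claim that the two scales are equivalent.

# Parent assignment

The maternal parent is read from the placement of the hybrid's
concatenated mitochondrial markers; the paternal parent from the cloned
nuclear variant whose placement falls outside the maternal lineage.
Cloned sequences are first collapsed to unique variants (expecting two in
a true F1, one otherwise; more than two triggers a warning).  Placement is
by re-inference with bootstrap on reference-plus-query, and the reported
"nearest lineage" is the smallest reference clade sister to the query — a
deliberately honest output: an ambiguous placement comes back as a
multi-taxon clade with its support rather than a forced single taxon, and
placements below `min_support` are flagged inconclusive.  A sliding-window
recombination scan (window 100 bp, step 25 bp, minimum winning margin 3
informative sites — conservative defaults, all configurable) checks that a
clone is not itself a within-locus mosaic of the two parents.

# The synthetic-data generator

The generator emulates the shape of a multilocus dataset from a rapid
fish radiation:

* a pure-birth species tree (`rphylo`), `birth_rate = 12` per unit of
  expected substitutions/site, giving root-to-tip depths around 0.2–0.4
  for 16–41 taxa;
* seven nuclear genes of 954 bp by default (a ~6.7 kb nuclear matrix) and
  three mitochondrial genes sharing one genealogy, simulated independently
  per gene under JC69 (K2P/HKY available) with `phangorn::simSeq`;
* `mito_rate_multiplier = 2`: mitochondrial branch lengths are doubled,
  keeping the fastest mito pairs below ~0.6 expected substitutions/site —
  faster than nuclear, but inside the working range of the distance model
  (higher multipliers push deep pairs toward the JC69 ceiling and destroy
  mito node support, which no real dataset analysed this way would
  tolerate);
* hybrids: `mosaic` mode fixes each nuclear locus for one parent's allele
  (the maternal one with probability `maternal_locus_fraction`); `F1` mode
  emits both alleles per locus as clone records; in both modes every
  mitochondrial locus copies the maternal parent; `post_hybrid_branch`
  adds i.i.d. per-site divergence to every hybrid sequence;
* cytonuclear transfer: a monophyletic clade is pruned and regrafted as
  sister to a chosen taxon, and the resulting topology generates the mito
  partition.

What it does *not* emulate: incomplete lineage sorting (every non-hybrid
locus follows the species tree exactly), indels and alignment error
(alignments are gap-free), rate variation among sites and lineages, and
base-compositional heterogeneity.  Passing tests therefore demonstrate
correctness of the machinery and behaviour under clean coalescent-free
signal, not robustness to every property of real data.

# Validation experiments and problem sizes

The acceptance experiments (also exposed as exported functions) run at a
deliberate desk scale chosen so the full suite completes in minutes on one
CPU:

* **HET power and type-I**: 20 seeded 16-taxon datasets, seven 950 bp
  nuclear genes; one mosaic hybrid (`maternal_locus_fraction = 0.5`,
  `post_hybrid_branch = 0.01`) between a random closely related non-sister
  pair (patristic distance between 0.05 and the median pairwise distance —
  the regime in which natural hybridisation occurs); `n_boot = n_null =
  100`, singleton removals, shared null.  The reference node set is the
  generating species tree, so power is measured against the nodes the test
  is meant to guard; with an estimated consensus reference the hybrid can
  rewrite the consensus and hide the signal inside the reference itself.
* **Parent recovery**: 50 seeded F1 hybrids at inter-parent divergence
  ≥ 0.05 substitutions/site; maternal assignment from the three mito
  markers, paternal from the gene-1 clones.
* **Cytonuclear recovery**: 50 seeded transfers of a 2–4-taxon clade whose
  stem and attachment branches are long enough (≥ 0.01 substitutions/site)
  that both positions are resolvable at the 95% threshold, plus 50
  transfer-free controls that must report zero supported conflicts.
* **Exact oracles**: extended consensus against brute-force split
  counting; NJ against generating trees on additive matrices (n ≤ 8); the
  outlier rule against an independent sort-and-scan implementation.

`scripts/acceptance.R` recomputes all of these from scratch under a
caller-supplied seed.

# Reproducibility

Every stochastic stage derives its stream from one top-level seed through
named substreams (`derive_seed(seed, tag)`), so adding or reordering
stages never perturbs the others, identical configurations are
bit-identical (the pipeline manifest records an md5 digest per output
file), and any single null replicate can be regenerated in isolation.

```{r example}
library(phyloHET)

spec <- sim_spec(n_taxa = 16, n_nuclear_genes = 7, n_mito_genes = 3,
                 gene_length = 954, seed = 42)
tree <- simulate_species_tree(spec)
aln <- simulate_alignments(tree, spec)
ev <- hybrid_event("HYB", "T04", "T09", maternal_locus_fraction = 0.5,
                   mode = "mosaic", post_hybrid_branch = 0.01)
sm <- concatenate(inject_hybrid(aln, tree, ev, seed = 42)$alignments)

res <- run_het(sm, tree,
               het_config(n_boot = 100, n_null = 100, max_group_size = 1,
                          seed = 42, shared_null = TRUE))
res$flagged
```
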