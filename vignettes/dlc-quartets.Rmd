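---
title: "Quartets under duplication, loss and deep coalescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quartets under duplication, loss and deep coalescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlcquartet)
```

## The model

`dlcquartet` studies quartet-based species-tree inference when gene
families evolve under the three processes that shape most genomes: gene
duplication, gene loss and incomplete lineage sorting (ILS).  The
generative model is the two-stage duplication-loss-coalescence (DLCoal)
process:

1. **Duplication/loss stage.**  A birth-death process with duplication
   rate $\lambda$ and loss rate $\mu$ (events per coalescent unit) runs
   top-down along the branches of an ultrametric species tree, starting
   with a single lineage at the top of the planted root edge.  The pruned
   outcome is the *locus tree*.  A duplication is asymmetric: the mother
   copy continues the parental locus, while the daughter copy starts a
   novel locus.  We mark each daughter edge with a *duplication-point* at
   the duplication height.
2. **Bounded coalescent stage.**  One gene lineage starts at every extant
   locus-tree leaf and lineages sharing an edge coalesce at rate 1 per
   pair (times in coalescent units; leaves sit at time 0 and time
   increases rootward).  A novel locus is born as a *single* haploid copy,
   so all gene lineages descending from leaves below a duplication-point
   must have coalesced into one lineage below the duplication height.
   This constraint is what distinguishes the *bounded* multispecies
   coalescent (b-MSC) from the plain MSC.  Above the planted root edge,
   remaining lineages coalesce on an unbounded stem, so gene trees are
   always fully resolved.

The central quantity is the distribution of the quartet topology
(`ab|cd`, `ac|bd` or `ad|bc`) displayed by the gene tree for four genes
sampled from four distinct species, given the locus tree.  These
probabilities drive the statistical consistency of quartet-based
species-tree methods (ASTRAL-one and ASTRAL-multi) under DLCoal: the
species-tree quartet is always the strictly most probable gene-tree
quartet, so the dominant quartet converges to the species quartet as gene
families accumulate.

## Closed forms for four-leaf locus trees

Restricting the locus tree to four genes from distinct species leaves two
shapes, balanced `((a,b),(c,d))` and caterpillar `(((a,b),c),d)`, with
internal edge lengths $x$ (cherry edge) and $y$.  With
$g_{i,j}(x)$ the probability that $i$ lineages coalesce down to $j$
within time $x$ (the classical lineage-count law implemented by
`coal_prob()`), the cases are:

* **No duplication** — the plain MSC result
  $P[\text{match}] = 1 - \tfrac23 e^{-s}$ with $s = x + y$ (balanced) or
  $s = x$ (caterpillar).
* **Duplication on an internal edge below the root** (either cherry edge
  of the balanced shape, the cherry edge of the caterpillar, or a
  duplication-point immediately below the root vertex) — the bound forces
  the constrained cherry to coalesce on its own edge, so the matching
  quartet is certain.
* **Caterpillar, duplication on $Y$ at height $t$ above the
  `abc`-ancestor** — conditioning on "$a,b,c$ coalesced before the
  duplication", $P[\text{alt}] = \tfrac13 e^{-x} g_{3,1}(t)/D$ with
  $D = \sum_j g_{2,j}(x)\, g_{j+1,1}(t)$.
* **Duplication on the planted root edge at height $t$ above the root
  vertex** — conditioning on all four lineages coalescing before the
  duplication; e.g. for the balanced shape
  $P[\text{alt}] = \tfrac13 e^{-(x+y)} g_{4,1}(t)/D$ with
  $D = \sum_{j,k} g_{2,j}(x)\, g_{2,k}(y)\, g_{j+k,1}(t)$.

The denominators are computed by a lineage-count dynamic program
(`prob_all_coalesced()`) rather than nested quadrature: given $g$, the
sums are exact, with no integration error.  In every case the two
non-matching topologies have equal probability, the matching probability
is at least $1/3$, strictly exceeds the alternatives, and is
non-decreasing in $x$ (strictly increasing unless an internal-edge
duplication pins it at 1).

```{r closed-forms}
quartet_probs(case_params("balanced", "none", x = 0.5, y = 0.5))
quartet_probs(case_params("caterpillar", "dup_on_Y", x = 1, y = 1, t = 0.5))
```

### Geometry of the root-edge cases

The printed derivations leave the exact geometry of $t$ and $z$ implicit,
so the package fixes it as: $z$ is the absolute height of the
duplication-point and $t = z - h$ where $h$ is the height of the root
vertex of the restricted quartet (for the caterpillar $Y$-edge case, the
height of the `abc`-ancestor).  This reading was confirmed against an
independent Monte-Carlo oracle before being frozen; with any other
reading the simulated frequencies diverge from the closed forms well
beyond sampling error.

A duplication-point *exactly at* a junction (e.g. on $Y$ at the
`abc`-ancestor height, or on the root edge at the root vertex) would
condition on a zero-probability event; `classify_locus_case()` treats
these measure-zero configurations as errors rather than silently
reinterpreting them.

## Simulating the process

`sim_locus_tree()` implements the duplication/loss stage.  Extinct
subtrees are pruned, suppressed degree-2 nodes have their edge lengths
summed, and duplication-points migrate onto the merged edges (keeping
only the lowest per edge, which implies the others).  The number `l` of
locus lineages crossing the root speciation and the root-lineage index of
every extant copy are recorded, which is what the scenario analysis
conditions on.

`sim_gene_tree()` implements the bounded coalescent.  Bounds are enforced
by exact conditional sampling, organised per daughter locus:

* Any leaf, and any subtree whose top edge carries a bound, delivers
  exactly one lineage at the top of its edge with probability one.  A
  bounded edge whose children are all of this kind therefore has a
  deterministic entry count, and the coalescence times are drawn directly
  from the conditioned death process — no rejection at all.
* When the entry count $n$ is random, the sub-history is accepted with
  probability $g_{n,1}(s)/g_{2,1}(s)$ (a valid rejection envelope since
  $g_{n,1}$ decreases in $n$ and $n \ge 2$), and the coalescence path is
  then drawn from the death chain *conditioned* to reach one lineage
  within the remaining time $s$, step by step from truncated
  exponentials thinned by $g_{k-1,1}$ ratios.

This scheme's cost does not blow up when a duplication-point sits only a
sliver above a node — the regime in which naive resample-until-valid
rejection stalls, because its acceptance probability vanishes linearly
(or faster) in the sliver width.  A retry cap (default $10^6$) turns any
remaining pathological configuration into a diagnostic error rather than
a hang.  The daughter side at each duplication is chosen uniformly; by
exchangeability of the subsequent coalescent this does not affect any
distribution studied here.

## What the harness verifies

`check_closed_forms()` compares every closed-form case against
Monte-Carlo frequencies on the realised locus trees and reports
per-topology z-scores; `default_case_grid()` holds one or two parameter
cells per case, spanning weak ($x = 0.2$) to strong ($x = 1$) ILS with
duplication offsets $t \in \{0.3, 0.5, 1\}$.  The package's own test
suite runs this grid at $10^5$ replicates per cell and accepts cells
within 4 standard errors (a deliberately wide band, since ~30
case-topology combinations are examined jointly).

`scenario_check()` runs the full DLCoal process on a four-taxon species
tree, classifies each family by the partition of the four sampled genes
into root lineages, and checks the symmetries that drive the consistency
proof: the cross-clade index agreement $P[i_a = i_c \mid l] = 1/l$
exactly, the cherry-respecting partition `(ab,cd)` being at least as
frequent as the crossing one `(ac,bd)`, and the dominance of the matching
quartet within same-lineage strata.  Conditioning on `l` is by post-hoc
stratification — the simulator cannot fix `l` exogenously — which mirrors
the structure of the argument but is a weaker experimental control;
strata below a size floor are flagged inconclusive rather than dropped.

`convergence_experiment()` accumulates families and asks when the
dominant quartet (ASTRAL-one sampling or ASTRAL-multi tallying) settles
on the species quartet.  `infer_species_tree()` scores every unrooted
topology on up to 8 taxa by total displayed-quartet count — a transparent
exact stand-in for a constrained quartet-score search, which is all the
consistency statements require at desk scale.

```{r experiments, eval = FALSE}
sp <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1):1;")
conv <- convergence_experiment(sp, lam = 0.3, mu = 0.3,
                               gene_counts = c(50, 500, 5000),
                               n_datasets = 10, mode = "both", seed = 1)
ggplot2::autoplot(conv)
```

## Design choices and conventions

* **Time convention.**  Heights are absolute, leaves at 0, increasing
  rootward; duplication-point times are heights, not offsets along edges.
* **Newick dialect.**  Branch lengths are coalescent units;
  duplication-points are carried as NHX-style edge comments
  `[&&NHX:DUPTIME=<height>]` after the branch length, so standard parsers
  still read the topology.  The canonical writer orders children by the
  smallest leaf label below them and prints 10 significant digits, making
  parse/write round-trips bit-exact.
* **Root edge.**  The planted root edge is explicit.  The birth-death
  stage needs a finite root-edge length to start from (it is a required
  parameter); the coalescent above the root edge is unbounded unless a
  duplication-point bounds it.
* **Sampling conventions.**  One haploid gene copy per extant locus leaf;
  ASTRAL-one draws one copy per species once per gene tree (independent
  per-4-tuple resampling is available behind a flag for sensitivity
  checks); gene trees missing a species are skipped for that 4-tuple,
  matching the conditioning of the analysis.  Ties are always broken
  toward the fixed topology order `ab|cd < ac|bd < ad|bc`, and all
  experiment entry points take explicit seeds with derived per-family
  substreams, so every reported table is bit-reproducible.
* **Numerical guards.**  Probabilities are clipped to $[0,1]$ only within
  $10^{-12}$; larger violations raise errors.  Ultrametricity is checked
  (tolerance $10^{-6}$ relative) before any height is computed.

## Problem sizes and limitations

The default verification scales — $10^5$ Monte-Carlo replicates per
closed-form cell, 2,500 families per rate-grid cell, 20 replicates of
5,000 families for the convergence check, $10^4$ families for the
tally-ordering check — were chosen so the whole suite runs comfortably on a single
desktop core while keeping binomial standard errors small enough for the
4-SE bands to be informative.

The synthetic data emulate exactly the generative assumptions above:
ultrametric species trees, constant rates per branch, one sample per
locus, no hemiplasy, no population-size variation beyond what coalescent
units absorb, and no gene-flow.  Passing tests therefore validate the
implementation of this model, not the fidelity of the model to any real
clade.  Closed forms exist only for four-leaf locus trees; larger loci
are handled by simulation.  The exhaustive species-tree search refuses
more than 8 taxa by design.
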