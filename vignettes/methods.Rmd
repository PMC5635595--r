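---
title: "Models and methods behind xenoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xenoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`xenoscan` reconstructs the history of a gene family — typically a fungal
secondary-metabolite megasynthase family such as the nonreducing polyketide
synthases — against a dated species tree, and asks how the genomic
neighborhood of the family's members (the accessory genes of a biosynthetic
cluster) co-evolved with that history. This vignette states the models,
the tunable parameters, the numerical choices, and the limits of what the
synthetic-data tests establish.

## The dated DTL parsimony model

A reconciliation embeds a rooted binary gene tree into a rooted binary
chronogram. Each internal gene node receives exactly one event:

* **speciation** (cost 0), at a species-tree node;
* **duplication** (cost Δ, default 4), inside a species branch;
* **transfer** (cost θ, profiled over 5…40), copying one child lineage onto
  a *different* species branch alive at the same time;
* gene-tree leaves map to their own species.

Losses (cost L, profiled over 1, 2, 3) are implied: whenever a lineage
passes a speciation node on one side only, the other side counts one loss.

"Alive at the same time" is made discrete by cutting the chronogram into
**time slices** at the distinct internal-node ages. Within a slice the set
of contemporaneous branches is constant, so for parsimony purposes every
within-slice position is equivalent and the state space is (gene node) ×
(species edge, slice). Transfers connect two edges of the same slice.
A virtual stem above the species root (its own top slice) lets duplications
predate the first speciation; without it the classical duplication–loss
solution for a family older than the root would be unreachable. The gene
root's event may be placed in any cell or at any species node — no losses
are charged above the root's event, since nothing in the data implies them.

The dynamic program runs over gene nodes in postorder and slices bottom-up;
each cell's options are the in-slice events, the speciation or loss-bypass
at the slice's bottom boundary, or continuation into the slice below. With
the root handled as a free event placement, each distinct reconciliation
(per-node event, location, and transfer recipient) is generated by exactly
one derivation, which is what makes counting correct.

### Exact counting and uniform sampling

Co-optimal reconciliations are astronomically numerous (a routine 30-taxon
family already has >10^6 optima), so summaries must not depend on an
arbitrary representative. The engine therefore counts optima in exact
arbitrary-precision integer arithmetic (base-1e9 limbs in C++; the `count`
return is also given as a decimal string) and samples optima uniformly by
backtracking with branch probabilities proportional to the exact
sub-counts. Probabilities are evaluated in double precision from the exact
counts; the relative error (~1e-15) is far below anything a chi-square
uniformity test at n = 10,000 could detect. The test suite verifies both
the counts and the sampling distribution against an independently
formulated brute-force enumerator on hundreds of random small instances.

Costs are compared with an absolute tie tolerance of 1e-9; event costs are
intended to be "nice" numbers (integers or simple fractions), as in the
profiling grid.

### Event support, transfer calls, robustness

`event_support()` reruns the sampler over the (θ, L) grid with Δ fixed and
records per-node event fractions. PRNG substreams are keyed on
(tree id, Δ, θ, L, seed), so enlarging a grid never changes existing cells.
A node is *called* as a transfer when its transfer fraction exceeds 0.5
(strictly) in some cell; the **top transfer cost** — the largest θ at which
the majority persists at the reporting loss cost (L = 1) — measures how
strongly the data demand a transfer. The **consistent** flag
operationalises robustness: majority support at two or more consecutive
grid θ values for *every* L, and, when several gene-tree topologies are
profiled, in every topology containing the node's bipartition (matched by
leaf set). Rationale: a transfer that is real shows up even when heavily
penalised, and does not depend on one loss-cost setting or one topology.

`summarize_events_on_species()` reduces samples to a per-branch
`duplications / losses / genes` table: modal event placement per gene node
for duplications, the modal per-branch loss count, and the modal number of
lineages crossing each branch's top boundary (a duplication inside a branch
adds copies below the crossing point, so the resident count rises only at
the next boundary). Ties in modal placements break toward the smallest
species postorder label.

`lca_dl_reconcile()` is the classical undated duplication–loss
reconciliation (LCA mapping). It is both a fast summary and the exact
θ → ∞ limit of the DTL model, which the tests exploit as a closed-form
oracle.

## Homolog clustering

The similarity graph keeps a protein pair only if hits pass in both
directions with E < 1e-10 and coverage of the longer sequence > 50%
(both bounds strict, matching the filter's wording). Edge weight is the
mean of −log10 E over the two directions, with E floored at 1e-200 to
avoid infinities. MCL uses standard expansion/inflation iterations on the
column-stochastic matrix; self-loop weight is each node's maximum incident
edge weight (conventional; isolated nodes get 1), entries below 1e-10 are
pruned each iteration, and convergence is declared when the largest
elementwise change falls below 1e-8. Clusters are the connected components
of the limit matrix's support, renumbered by decreasing size — so the
result is deterministic and invariant to node order. Inflation defaults to
1.4; `inflation_sweep()` reports silhouette width across {1.2, 1.4, 1.6,
2.0} so the setting can be justified on the data at hand rather than
asserted. Silhouette distances are 1 − w/w_max for edges and 1 for
non-edges; singleton clusters contribute 0.

## The clade-association scan

Every subtree with ≥ 5 leaves is crossed with every binary feature (CHG
presence in the ±20-gene window; exon-junction features use the identical
machinery). The two-sided Fisher exact test comes from `stats::fisher.test`
(the test suite checks it exhaustively against direct hypergeometric
enumeration for all tables with total ≤ 30); the odds ratio is the sample
odds ratio with a Haldane 0.5 correction when a cell is zero, so direction
is always reportable. Bonferroni multiplies by the *total* number of
subtree × feature tests — the stricter of the two readings of "total number
of tests", kept as the default deliberately.

Reporting mirrors nested-scan practice: a subtree is a **local minimum**
when its corrected P beats both its parent's and every eligible child's
(ties resolved toward the smaller subtree); the **reported** set is built
greedily by ascending corrected P among local minima at corrected P ≤ 1e-4,
skipping subtrees that share a leaf with an already-reported subtree for
that feature.

## Neighborhood retention

At each internal node, retention is the mean over all cross pairs (one leaf
from each child subtree) of |A ∩ B| / min(|A|, |B|), where A and B are the
CHG sets of the two neighborhoods. The `min` denominator is the default
(the statistic then reads "fraction of the smaller context that survived");
`mean` and `jaccard` are available and recorded in the output, since the
choice is a genuine free parameter.

**Depth** defaults to the node's height above its leaves (cherries 1, root
deepest). The alternative — edge count below the root — is offered but not
default, for a structural reason: under any hierarchical model of context
loss, leaves under a recent node have diverged less, so retention can only
fall toward ancient nodes. Only the height orientation lets "context decays
with depth" appear as a negative Pearson correlation, which is the sign
convention used in reporting.

Class comparisons (speciation vs duplication, transfer vs duplication) use
the two-sample Wilcoxon rank-sum test with the normal approximation (ties
are common in retention fractions); a class with fewer than two records
drops its comparison with a notice.

## The synthetic-data generator

The generator's defaults are the study conditions exercised everywhere:
a 30-taxon birth–death chronogram normalised to root age 1; 50 families;
DTL rates 0.21 / 0.06 / 0.37 per lineage per unit time, chosen once so that
a family accumulates on average about 2 duplications, 0.5 transfers and 3
losses over this tree scale; ±20-gene windows drawn from a 400-CHG pool;
retention probabilities 0.40 (speciation), 0.11 (duplication), 0.21
(transfer); similarity tables with within-family E log-uniform on
[1e-180, 1e-30] and coverage uniform on [0.6, 1], cross-family noise at
E ≥ 1e-8. These sizes keep the full pipeline in minutes on one CPU while
leaving each statistic enough events to be estimated.

Design details that matter for interpreting recovery tests:

* **Chronogram.** Forward simulation; with k lineages the next event waits
  an Exp(k(b+d)) time, stopping when the extant count first reaches n (plus
  one final waiting time), so pure-birth inter-node gaps keep their exact
  exponential law — which the test suite checks by Kolmogorov–Smirnov.
  Total extinction triggers a bounded resample.
* **Families.** A single lineage enters at the species root; transfers
  choose recipients uniformly among coexisting branches — deliberately the
  same model class the reconciler assumes, so recovery error measures the
  inference, not model mismatch. The truth registry flags which events
  survive pruning as bifurcations, since only those are visible to any
  reconciliation method.
* **Neighborhoods.** At each split one child inherits the parental context
  unchanged; the other retains each CHG with the event's retention
  probability and refills from the pool *excluding the parental set*, so a
  retained CHG is never re-drawn by chance. Consequently the expected
  cross-pair shared fraction at a single-split family equals the planted
  probability exactly — the configuration the retention-recovery test uses —
  while deeper trees compound the loss multiplicatively, which is what the
  depth-decay analysis measures. Real genomes violate several of these
  idealisations (tandem duplications, segmental rearrangements, shared
  background synteny), so passing recovery tests demonstrates the
  statistics are implemented and calibrated correctly, not that real
  retention values will be unbiased.
* **Gene structures.** Junctions live in alignment-column coordinates and
  evolve by per-branch loss and Poisson gain; gaps are placed only in
  non-junction columns (a fraction of which are made low-occupancy to
  exercise the 70% consensus threshold), so every emitted exon list
  reproduces its generating junctions through `cds_junctions()` exactly.
  Phase-0 junctions attach to the first residue of the downstream exon;
  phases 1–2 to the interrupted codon's residue.

## Numerical and boundary conventions

* Occupancy trimming keeps columns with non-gap fraction **≥** the
  threshold (gap-threshold semantics, boundary inclusive); gap characters
  are `-` and `.`, and `X` counts as occupied.
* External coordinates are 1-based inclusive (GFF3 dialect); internal
  arithmetic is 0-based (junction offsets, residues, ordinals).
* Postorder labelling (children in stored order, left before right) is the
  single canonical node naming for both trees; all reports use it.
* Annotation ordinals sort by start coordinate with gene-id tie-breaks, so
  window extraction is permutation-invariant.
* Ages within 1e-8 × root age merge into one slice boundary.

## Scope and limitations

The reconciler is a parsimony method: it reports cost-optimal embeddings
and their support under explicit costs, not probabilities; amalgamation
over tree posteriors is out of scope (multiple topologies are instead
reconciled independently and cross-checked in the consistency flag).
Species trees must be binary and dated; gene trees binary and rooted.
The association scan treats CHG membership as the unit of "same gene",
which overestimates true orthologous synteny — the retention numbers are
therefore upper bounds by construction, and should be read comparatively
(between event classes) rather than absolutely.
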