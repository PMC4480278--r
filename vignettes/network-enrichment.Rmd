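---
title: "Network-based enrichment with minimal connecting modules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based enrichment with minimal connecting modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netenrich)
```

## The model

`netenrich` associates every ontology term with a *function-specific
module* of the protein interaction network, then replaces annotation
membership with module membership in a classical Fisher
overrepresentation test. The underlying assumptions are the usual ones of
network biology: proteins participating in the same biological process
tend to interact, so the interaction paths that connect the proteins
annotated with a process are enriched for further participants of that
process. A module makes this concrete in four steps.

**Seeds.** The seed set of a term is the set of proteins *directly*
annotated with it. Direct rather than propagated annotation matters:
propagation would flood high-level terms with thousands of seeds and
modules would lose all specificity. Seeds absent from the network carry no
topological information but remain module members, so they still count in
enrichment overlaps.

**Shortest path network.** The SPN is the union of all shortest paths
between all seed pairs, computed on the unweighted, undirected simple
graph. We deliberately keep *every* shortest path (node `v` qualifies iff
`d(s,v) + d(v,t) = d(s,t)` for some pair), and only edges lying on such
paths — not the induced subgraph on the SPN's nodes, which could contain
shortcuts that never occur on a seed-pair geodesic. Seed pairs in
different components impose no constraint.

**Minimization.** The SPN is typically much larger than the seed set, and
most of its nodes are generic well-connected proteins. The minimal
connecting network is the smallest subgraph preserving all seed-pair
shortest distances — a Steiner-tree-like problem whose optimum is neither
unique nor tractable in general, so a ranked greedy heuristic is used.
Connecting nodes are sorted by the hierarchical key `(sc, ss, bc)`
ascending — seed centrality, maximum Lin similarity to the reference term,
seed-restricted betweenness — and processed from least to most important;
a node is deleted iff afterwards every connected seed pair still realizes
its *original full-network* distance. Because deletions only ever shrink
the graph, a node that is retained once can never become deletable later,
so a single pass yields a 1-minimal, distance-preserving module. Two
design points deserve a note:

* *Distances are always checked against the full network*, cached once
  per term. Re-checking against the shrinking SPN would let distances
  drift upward silently: each single deletion could preserve the current
  distances while the accumulated drift stretches a seed pair well beyond
  its original distance.
* *Ties are broken by ascending node identifier.* The optimum is not
  unique (a diamond of two equivalent connectors is the canonical case)
  and a deterministic tie-break makes module archives byte-reproducible,
  which the test suite asserts.

**Quality filter.** Modules whose connecting nodes are functionally
unrelated to the reference term — typically long chains through hub
proteins, arising for rare terms with scattered seeds — are discarded. The
filter compares the mean maximum semantic similarity (`ss`) of the
module's connecting nodes against the network-wide mean with a one-sided
Welch two-sample t-test at level `alpha`. Welch rather than the pooled
Student variant because the two groups differ wildly in size and variance;
one-sided because only *higher* similarity is evidence of a genuine
module. Modules with no connecting node are discarded outright, and a
single connecting node leaves the group variance undefined, so such
modules are rejected too (reported under a distinct label).

## Semantic similarity

Information content is `IC(t) = -ln(n_t / n)` with `n_t` the number of
proteins carrying `t` after propagating annotations to ancestors and `n`
the number of annotated proteins. The log base is irrelevant (it cancels
in Lin's ratio) and fixed to natural for reproducibility. Lin similarity
is `2·IC(MICA) / (IC(t1) + IC(t2))`, where the most informative common
ancestor ranges over the common ancestors *including the compared terms
themselves* (the standard convention). Degenerate cases: a zero
denominator (two zero-IC terms) and disjoint-root term pairs score 0;
terms annotating no protein have undefined IC and are excluded from
similarity and from enrichment backgrounds.

A protein's similarity to the reference term is the maximum Lin score over
its *direct* annotation terms. Maximizing over the propagated closure
instead would systematically inflate scores: whenever a direct term shares
an ancestor `a` with the reference term, `a` itself is in the closure and
`sim(a, ref) >= sim(direct, ref)` (same MICA, smaller denominator), so
every protein would be scored by the generic shared ancestor rather than
by what it is actually annotated to do. Unannotated proteins score 0
rather than being excluded, because connecting nodes may be unannotated
and must still be rankable. For the
IC background, proteins are counted through propagated annotations —
standard Resnik/Lin practice; the direct-count alternative would make
parent ICs incoherent with their children.

Only `is_a` and `part_of` relations define ancestry; `regulates`-type
edges are ignored at parse time.

## The enrichment tests

Both modes compute the hypergeometric upper tail
`P(X >= k)` for an overlap of `k` input proteins among `n` in a
background of `N` with `K` positives, via `stats::phyper` in log space
(the suite checks agreement with direct tail summation to 1e-10 relative
error). Only terms with `k >= 1` are tested. Bonferroni multiplies by the
number of tested terms by default; a `bonferroni = "universe"` switch
multiplies by all background terms instead, which is strictly more
conservative — multiplying by terms that could never have been tested only
inflates corrected p-values. Input proteins outside the background are
dropped from `n` with a logged message.

The non-redundant ranking removes results whose term is a strict ancestor
of another enriched term (keeping the most specific term on each path);
when comparing network against standard results, network terms ancestral
to standard hits are likewise dropped before any claim of added value.
Novelty (`is_new_term`) is judged against the *propagated* annotations of
the input proteins — the strictest notion: a term counts as new only if no
input protein carries it even implicitly.

The four comparison classes (`none_significant`, `same_terms`,
`net_more_known_terms`, `net_new_terms`) are assigned by precedence, with
novelty checked first among the surviving network-only terms.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` (quality filter) | 0.05 | level of the one-sided Welch t-test on connector similarity |
| `alpha` (enrichment) | 0.05 | threshold on Bonferroni-corrected p-values |
| `bonferroni` | `"tested"` | correction denominator: tested terms vs whole background |
| `dialect` | `"generic"` | edge-list format; `"string-actions"` parses the STRING actions header |

Identifier mapping (network id to annotation id) is optional; ambiguous
one-to-many mappings are dropped with a warning, and unmapped nodes keep
their identifiers.

## The synthetic generator

`generateFixture()` emulates the pipeline's inputs at desk scale so every
stage is testable without downloads. The default study conditions, chosen
once: a 300-node Erdős–Rényi background with edge probability 0.02 (mean
degree ~6, comfortably above the connectivity threshold), one *subject*
module of 12 proteins — 8 seeds and 4 connectors — plus four decoy modules
of the same shape, annotation noise rate 0.1, and recovery queries of
5 planted members (disease-panel sized: real curated disease sets run
from 2 to a few tens of proteins with a mean around 4). The decoys are
not an optional extra: a network-enrichment background consisting of a
single module is degenerate (`N = K` makes every p-value 1), so a
realistic universe needs modules beyond the subject term.

A planted module splits its seeds into two cliques, removes all direct
cross-clique edges, and bridges matched cross-clique seed pairs through
the connectors. Each connector is thereby on its pair's shortest paths *by
construction* (distance exactly 2, no direct edge), so ground truth is
assertable rather than probabilistic. Seeds are annotated with the planted
term; each connector gets its own single-protein sibling term under the
same parent, which gives connectors high Lin similarity to the reference
term (the quality filter's acceptance signal) without creating a second
buildable term. Background noise annotations come from a disjoint subtree
and thus score zero similarity to any planted term.

All randomness flows from one master seed through fixed substreams
(graph, annotations, queries), so fixtures regenerate bit-identically and
components can be varied independently.

What the generator does *not* emulate: the heavy-tailed degree
distribution of real interactomes (a preferential-attachment background is
available but not default), edge scores and action types, annotation
depth heterogeneity, and correlated multi-term annotation of real
proteins. Passing the recovery and type-I tests therefore demonstrates
the machinery's correctness and calibration under clean planted signal,
not performance on a real interactome.

## Numerical and degenerate-input choices

* Hop distances are exact integers; all distance-preservation checks use
  equality, never tolerance.
* Shortest-path counts for `bc` are computed by layered BFS with path
  counting (doubles; exact for the path counts that occur at these
  scales).
* Terms with fewer than two in-network seeds produce no seed pair and are
  reported as `too-few-seeds`; per-term failures in batch construction are
  logged, never fatal.
* Self-loop-only network nodes are dropped entirely at load time.
* Empty enrichment results are a valid answer (exit 0), distinguished
  from input errors (missing files, empty input set), which are fatal.
* Serialization is deterministic: sorted terms, sorted member lists, no
  timestamps; metadata carries version, parameters and input MD5s.

## Problem sizes used by the test suite

The suite works at deliberately small scales chosen to make exhaustive
oracles feasible: shortest-path-network equivalence is checked against
explicit path enumeration on 200 random graphs of up to 12 nodes;
greedy minimization is compared against the exact minimum
distance-preserving subgraph found by exhaustive subset search on 100
instances; Fisher tails are enumerated fully for backgrounds up to 40
(sampled up to 60); Lin similarity is compared with a brute-force
ancestor walk on over 100 random DAGs of up to 20 terms; recovery and
type-I calibration use 100 and 200 replicates of the default study
conditions. `scripts/acceptance.R` re-runs the recovery, type-I,
inflation and added-value computations from scratch and writes the
numbers as JSON.

## Known limitations

* Exact Steiner optimality is not attempted (and not unique anyway); the
  greedy result is only guaranteed distance-preserving and 1-minimal.
* Module construction cost is dominated by the per-term removal loop;
  very large seed sets on dense networks would need the caching
  strategies real-scale runs require.
* Directed interaction semantics are discarded by design; activation
  versus inhibition is invisible to the module topology.
* With multi-root ontologies, term pairs with disjoint roots score 0
  similarity — reasonable, but it means cross-namespace annotation adds
  no ranking signal.
* Bonferroni over tested terms is the least conservative defensible
  choice; users wanting strict family-wise control across the whole
  background should use `bonferroni = "universe"`.
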