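---
title: "Dendritic heat maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendritic heat maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

A dendritic heat map (DHM) displays one sequence set clustered at a whole
ladder of fractional-identity cutoffs at once. Each concentric ring is a heat
map of the clusters at one cutoff (0.75 innermost to 1.00 outermost, by
0.01); rings are angularly aligned so that a cluster's children at the next
stricter cutoff occupy exactly its angular range. Read radially, the figure
is a dendrogram: genotype divergence appears as clusters breaking apart
toward the rim. Read by colour, it is a heat map: each cluster is coloured by
the log-ratio of two phenotype-group abundances, so phenotype divergence can
be tracked across every level of clustering specificity simultaneously. This
vignette documents the model, the tunable parameters, and the design
decisions behind `dhmap`, in the order the pipeline runs.

```{r, message = FALSE}
library(dhmap)
```

## Sequence records and phenotype groups

All functions exchange plain tibbles with columns `id`, `bases`, `group`,
`count`, `events`. Two phenotype groups are supported. By default they are
derived from GC content: group 1 is GC ≤ 50%, group 2 is GC > 50%. The
boundary matters — a 100-mer with exactly 50 G/C is group 1 — so the rule is
evaluated in integer arithmetic (`2 * gc_count <= length`), never in floating
point. GC content is a deliberately artificial phenotype: it is cheap to
compute, it is mechanically coupled to genotype (mutations move it), and it
exercises the display. Real phenotypes (habitat, treatment, condition) enter
through a two-column id-to-group table (`read_group_map()`).

Ambiguity codes and gap characters are rejected rather than coerced, because
the identity semantics of non-ACGT characters are undefined in this model;
inputs should be cleaned upstream.

Identical sequences are dereplicated (`dereplicate()`) into one record with
an abundance count before clustering. This never changes any partition —
identical sequences co-cluster at every cutoff — but it shrinks the identity
matrix and keeps the group tallies abundance-weighted.

## The two simulated datasets

The built-in generators define the study conditions the package is tested
under; they are first-class, tested code, not fixtures.

**Mutation lineage** (`simulate_mutation_lineage()`): 100 copies of a single
ancestor with exactly 50% GC content, 100 bp each, mutated with one uniform
random base substitution per sequence per iteration for 15 iterations. Every
record at snapshot *m* carries exactly *m* substitution events; the same
position may be hit repeatedly, so Hamming distance to the ancestor is ≤ *m*.

**Population growth** (`simulate_population_growth()`): one ancestor, and at
each of 15 generations every sequence is replaced by an unchanged copy plus a
once-substituted copy, reaching 2^15 = 32768 sequences. One lineage never
mutates, so the ancestor survives in every snapshot.

**Group evening.** Both generators use rejection sampling to keep the two GC
groups comparably sized: a finished run whose group-count difference exceeds
the policy bound (20 sequences absolute for the lineage; 5% of the total for
growth) is discarded and re-run with seed + attempt-index, up to
`max_restarts` (default 1000). A difference exactly at the bound passes; only
strictly exceeding it restarts.

Two policy details were genuinely open and were decided as follows:

* *When to check.* The default is `check_at = "final"`. Checking every
  snapshot sounds stricter, but at iteration zero of the lineage all 100
  sequences sit in group 1 (difference 100), and after one substitution the
  ≤-boundary asymmetry leaves an expected imbalance near 33, so a
  from-iteration-zero check can never pass at the 20-sequence bound.
  `"every"` (which skips snapshot 0) and `"none"` remain available.
* *Growth ancestor composition.* The growth ancestor defaults to exactly 50%
  GC (`ancestor_gc = 0.5`, configurable to fully random). A random ancestor
  a few percent off the boundary biases every descendant's GC walk, and the
  5% evening bound then fails almost surely within any reasonable restart
  budget. With a balanced ancestor roughly one run in five passes at 12–15
  generations, which rejection sampling absorbs.

What the generators emulate — and do not. They produce equal-length, ungapped,
uniformly mutating sequences with no indels, no selection, no recombination,
no rate heterogeneity, and a phenotype mechanically tied to genotype. Passing
tests on these data therefore demonstrate the correctness of the clustering,
geometry and colour algebra, not robustness to alignment error, length
variation or realistic substitution processes. The theoretical endpoint of
unbounded substitution at fixed length is still informative: the number of
possible distinct sequences is exactly b^n (`endpoint_count()`, computed in
exact big-integer arithmetic), the limiting cluster distribution every
lineage drifts toward.

## Fractional identity and the guide order

Identity between equal-length sequences is the fraction of matching
positions. For unequal lengths (external data only) a global alignment with
fixed scores — match +1, mismatch −1, gap −2, no end-gap discount — is
computed and identity is matching columns over alignment columns, with a
diagonal-then-up traceback preference so the value is deterministic. This is
an internal definition, documented as such; it is not claimed to equal any
particular tool's percent-identity formula.

Ring arrangement needs a linear order in which similar sequences are
adjacent; progressive-alignment tools get this from their guide tree. `dhmap`
computes the order internally (`guide_order()`): the leaf order of a UPGMA
hierarchy on 1 − identity, with all ties broken deterministically (highest
identity first; ties to the lexicographically smallest index pair; at each
node the child holding the smallest original index comes first). For the
equal-length, ungapped data this package targets, the order serves exactly
the same arranging role as an alignment-derived one, and any difference
affects only within-ring arrangement, never cluster membership.

The divisive method additionally processes sequences in *staggered* order
(`staggered_order()`): first element of the guide order, then the last, then
the second, and so on. The most mutually distant sequences are seen first and
found centroids before any would-be satellite is assigned, avoiding the
misbinning that alignment-sorted input causes in greedy clustering.

## The four clustering ladders

All four methods share the cutoff ladder 0.75, 0.76, …, 1.00 and the same
boundary rule: an identity meeting the cutoff joins (≥, the "minimum
identity" reading of an identity threshold). All comparisons use a 1e-9
fuzz so that rational identities (k/L) meet cutoffs like 0.83 despite binary
floating point; the fuzz is far below the 1/L spacing of attainable values.

**Agglomerative (min / max / avg linkage).** The merge tree joins, at every
step, the pair of clusters with the highest linkage identity: the maximum
cross-pair identity for single linkage, the minimum for complete linkage,
the unweighted mean for average linkage (UPGMA). One tree is built and cut
at all 26 cutoffs. Because all three linkage criteria are monotone along the
merge sequence, cutting one tree is equivalent to 26 independent runs while
*guaranteeing* the ring-to-ring nesting the figure requires. Ties everywhere
resolve to the smallest index pair, so results are fully deterministic.

**Divisive (greedy centroid).** The loosest cutoff partitions the full set:
records are processed in staggered order, each joining the highest-identity
existing centroid if that identity meets the cutoff and otherwise founding a
new cluster (assignment is best-match over all current centroids, not
first-match; centroid ties go to the earliest-founded cluster). Each
subsequent ring re-partitions every cluster independently at the next
cutoff, using the global staggered order restricted to the cluster's members
— a per-cluster recomputed order is available (`recompute_order = TRUE`) but
restriction is the default, since re-deriving an order inside an
already-homogeneous cluster rarely changes anything and costs a sub-matrix
per cluster. Nesting holds by construction, and no all-pairs matrix is
needed by the clustering itself, which is what lets this method scale to the
growth dataset.

An observation worth recording: single linkage provably yields the coarsest
partitions (its clusters are the connected components of the ≥-cutoff graph,
and any avg/max merge implies at least one qualifying edge), and cluster
*counts* always order #min ≤ #avg ≤ #max in practice; but complete linkage
is **not** a refinement of average linkage cluster-for-cluster — on a few
cutoffs of the default lineage data a complete-linkage cluster straddles two
average-linkage clusters. The test suite asserts the refinement relations
that actually hold (avg and max each refine min) plus the count ordering,
rather than a cluster-wise avg ⊇ max nesting that is false in general.

## Radial geometry

The key wedge (default 12°, configurable; the convention here is angles
clockwise from 12 o'clock) is centred at 0° and the remaining 348° hold the
clusters. Base-ring spans are proportional to cluster weight — dereplicated
abundance by default, distinct-sequence counts via `width_by = "unique"` —
and each deeper ring splits every parent's span among its children in
proportion to child weight. Child weights sum to the parent's, so nesting is
exact, per-ring extents always sum to 360° minus the wedge, and a sequence's
angular interval can only narrow from centre to rim. Doubling all abundances
changes nothing (scale invariance). No minimum span exists in the geometry;
invisibly thin singleton sectors get a minimum stroke width (default
0.25 px) at render time only, so exported geometry stays exact. The wedge
also separates the two ends of the guide order — the most distantly related
clusters — which would otherwise sit confusingly side by side.

## The colour model

Each cluster's bin response is `r = log10((g1 + 1) / (g2 + 1))` of its group
abundances. The +1 smoothing keeps r finite when a group is absent; the log
keeps small clusters with strong skew visible next to large ones. Base 10 is
the package's choice (the ratio-to-scale quotient that determines colour is
base-invariant); exported values read as decades of imbalance.

A global scale `M = max |r|` — taken over every panel of a figure set when
several DHMs are shown together (`normalization_scale()`) — maps responses
to 23 categories: 0 (white) exactly when r = 0, otherwise
`sign(r) * min(11, floor(|r|/M * 11) + 1)`. Bin edges are half-open lower
bounds so that *only* exact neutrality is white; |r| = M lands on ±11. An
all-neutral map (M = 0) renders white rather than erroring. Colours come
from two 11-step light-to-dark ramps — reds toward group 1, blues toward
group 2 — interpolated linearly in RGB from near-white to #67001F and
#053061. These endpoints are Brewer-inspired substitutes chosen by this
package (the original figures' exact RGB values are not published); the
palette is fully overridable, and a validity check enforces 23 distinct
colours. The key wedge shows the two ±11 extremes.

## Output

`render_svg()` writes the figure directly as SVG 1.1 — one annular sector
per (ring, cluster), two wedge halves — with deterministic, byte-stable
output; `autoplot()` gives the same geometry as a ggplot. `export_circos()`
writes Circos-compatible karyotype/track/conf text files (one heat-map
track per ring, positions mapped into base-ring segment coordinates) for
users who prefer that renderer; the conf is a functional template, and
Circos itself is never invoked.

## Numerical and degenerate-input choices

* Identity/cutoff comparisons: ≥ with 1e-9 fuzz, as above.
* All tie-breaks (merge pair choice, centroid assignment, guide order,
  within-ring arrangement) resolve to smallest index / earliest founded, so
  every method is a deterministic function of its input and seed.
* Restart r of a simulation reseeds with `seed + r`; runs are bit-identical
  given (seed, policy).
* Degenerate inputs: a single record yields 26 one-cluster rings; an empty
  FASTA reads as an empty tibble; zero total abundance is an error at layout
  time; M = 0 renders all white; an exhausted restart budget is an error
  reporting attempts and the last observed imbalance.

## Problem sizes used in the checks

The shipped test suite exercises the full-size lineage dataset (100
sequences, snapshots through iteration 15, all four methods) and the growth
dataset truncated to generation 12 (4096 sequences, ~4000 unique) for the
centroid ladder — the all-pairs matrix and guide order are the quadratic and
cubic pieces, and generation 12 keeps the whole suite comfortably
desk-scale while still three orders of magnitude past the lineage data.
Linkage-oracle equivalence is verified against naive reference
implementations on 200 random instances of up to 10 sequences at every
cutoff, where exhaustive recomputation per step is feasible.

## Known limitations

* Identity for unequal lengths is a fixed-score global alignment; there is
  no affine gap model, no substitution matrix, and no claim of equivalence
  with USEARCH or alignment-tool identities.
* Exact all-pairs identity and the in-package UPGMA are desk-scale
  (thousands of unique sequences); there are no k-mer prefilters or
  streaming modes, and the agglomerative methods inherently need the full
  matrix. The divisive ladder itself scales further, but the guide order it
  uses for arrangement is still matrix-based.
* The simulators are idealizations (see above); conclusions about real
  community data require real inputs via FASTA and, usually, an external
  group map.
* Ring arrangement is a heuristic for visual adjacency; two equally valid
  orders can differ cosmetically (never in membership, spans within a
  parent, or colour).
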