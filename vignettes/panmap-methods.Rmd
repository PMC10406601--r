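---
title: "Multiscale pangenome graphs with panmap: models, parameters and design"
author: "panmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale pangenome graphs with panmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmap)
```

# The problem

Haplotype-resolved assemblies make previously inaccessible loci — tandem
repeat arrays, palindromic amplicons, megabase inversions, highly
polymorphic gene clusters — available as complete sequences, but comparing
dozens of such sequences at once is hard.  Base-level multiple alignment is
expensive and unreadable over complex rearrangements, and dot plots only
compare two sequences at a time.  `panmap` takes the sequence-sketching
route: it anchors every sequence with sparse, strand-symmetric minimizers,
builds a pangenome graph from the anchors alone (no base-level alignment),
relinearizes the tangled parts of that graph into *principal bundles*, and
projects every haplotype back onto the bundles as a linear, colorable
decomposition.  Two scalar metrics — a random-walk entropy and a
repetitiveness score — summarize graph complexity so that large panels of
loci can be screened quickly.

# Anchors: symmetric minimizers, hierarchically reduced

Every k-mer is hashed by the lexicographically smaller of its forward and
reverse-complement forms (an FNV-1a pass finished with a splitmix64-style
avalanche, truncated to 53 bits so hashes are exact in doubles).  A k-mer
and its reverse complement therefore always hash identically, which makes
every downstream structure strand-agnostic.  In each window of `w`
consecutive valid k-mers the smallest hash is kept (leftmost on ties);
k-mers overlapping non-ACGT characters are skipped, and a run of ambiguous
bases splits a sequence into independently scanned blocks.

Plain minimizers are still too dense for megabase-scale comparison, so the
selection is applied again — `levels - 1` times — to the *hash sequence* of
the previous level with window `r`.  The resulting sparse hierarchical
minimizers (SHIMMERs) thin out by roughly a factor of `(r + 1) / 2` per
level while remaining deterministic anchors of the underlying sequence.
Finally `min_span` suppresses anchor pile-ups in simple-sequence context.

Parameters, units, defaults and roles:

| parameter  | unit    | default | role |
|------------|---------|---------|------|
| `w`        | k-mers  | 80      | level-0 window; anchor density `~2/(w+1)` |
| `k`        | bases   | 56      | anchor specificity |
| `r`        | anchors | 4       | per-level reduction factor |
| `min_span` | bases   | 64      | minimum anchor spacing |
| `levels`   | count   | 2       | total hierarchy depth (2 = one reduction) |

Whole-library indexing uses `(80, 56, 4, 64)`; single-locus decompositions
in this package and its tools default to the denser `(48, 56, 8, 12)`.
Increasing `w` or `r` lengthens the sequence each graph vertex represents,
moving the analysis to coarser structure; decreasing them resolves finer
repeats.  With `r = 1` and `min_span = 0` the SHIMMER set is exactly the
plain minimizer set, which is how the implementation is audited against a
brute-force window-enumeration oracle in the test suite.

## The `min_span` heuristic

Thinning anchors to a minimum spacing admits several heuristics.  A greedy
left-to-right scan is the obvious one, but it is not strand-symmetric: the
survivors of a sequence and of its reverse complement can disagree over
long stretches, which in turn breaks the strand symmetry of every
downstream graph.  Because strand symmetry is the entire point of
symmetric minimizers, the default heuristic here removes, among all anchors
currently violating the spacing, the one with the largest hash, and
repeats until no violation remains.  Hashes and the gap structure are
mirror images under reverse complement, so the surviving multiset is
strand-invariant.  The greedy scan remains available as
`enforceMinSpan(..., method = "greedy")`.

# The MAP-graph

For sequences `S = {s_i}`, each vertex of the minimizer-anchored pangenome
graph is a tuple of neighboring SHIMMERs — a normalized pair key
`(min(hash), max(hash))` — holding every sequence fragment in `S` that
spans that pair.  The vertex weight `w_i` is the number of such fragments,
a proxy for conservation and copy number.  Edges connect pairs adjacent on
at least one sequence; each sequence is a path in the graph.  The graph is
bidirected: each edge endpoint records whether the traversal passes the
canonical vertex forward or flipped, and an edge observed in both
directions is stored once with summed support.  Two conservation laws are
asserted throughout the tests: the vertex weights sum to the total number
of observed pairs, and every input path is embedded edge-by-edge.

Serialization uses GFA v1 (`S` lines carry a representative fragment per
vertex, `L` lines carry endpoint orientations and `0M` overlaps) plus a
text sidecar with `K` (parameters), `C` (contigs) and `F` (fragments)
lines, so the graph and the provenance of every vertex re-parse exactly.

# Query by anchor chaining

A query sequence is reduced to its SHIMMER pairs; the pair hashmap yields
all database occurrences of each shared key (one anchor per query-pair x
target-occurrence combination, orientation = XOR of the two pair
orientations).  Within each (target, orientation) group a sparse dynamic
program finds maximum-cardinality chains monotone in both coordinates with
per-step gaps at most `max_gap` (100 kb default), ties resolved toward the
smaller total gap.  Chain spans within `merge_range_tol` (100 kb default)
are then unioned, which keeps one contiguous hit across a polymorphic
middle whose anchors cannot chain.  Queries should exceed roughly 20 kb at
default parameters so they contain enough anchors.  No base-level
refinement is attempted; the output is a hit table and the hit sequences,
ready for downstream alignment by other tools.

# Principal bundles

Tangled graph regions — repeats, palindromes, polymorphic clusters — are
relinearized in three steps:

1. **Weight-prioritized DFS.**  Starting from the globally heaviest
   unvisited vertex, depth-first traversal always descends into the
   heaviest unvisited neighbor (ties to the smaller vertex id, fixed for
   determinism).  The deep spine of each tree thus follows the paths most
   haplotypes share, while rare-haplotype bubbles hang off it as short
   branches.
2. **Branch pruning.**  DFS branches with fewer than `min_branch_size`
   vertices (default 8) whose leaf stopped at an already-visited vertex —
   i.e. a bubble or loop closing back on the spine — are deleted;
   branches ending at a true graph dead end are contig termini and are
   kept regardless of size.  Traversal and pruning iterate to a fixpoint.
   `min_cov` (default 0) removes low-weight vertices before the first
   traversal.
3. **Branching-vertex removal.**  On the undirected view, vertices with
   more than three incident edges are removed.  That literal rule alone
   does not guarantee simple paths (degree-3 vertices survive it), so a
   second pass removes any residual vertex of degree three or more; the
   postcondition — the remainder is a union of simple paths — is the
   contract, and the literal rule is available via
   `strict_simple_paths = FALSE`.  Isolated cycles are opened at their
   smallest vertex id.

Maximal simple paths are the principal bundles, ranked by vertex count;
each bundle is oriented so index 0 sits at the endpoint with the smaller
pair key.  Every contig's vertex path is then scanned for maximal runs of
consecutive same-bundle vertices with consistent direction; runs become
BED segments carrying the bundle id, vertex count, orientation, traversed
vertex range, and an `R`/`U` flag marking bundles that occur at least
twice on the contig.  Same-bundle, same-orientation segments within
`bundle_merge_distance` are merged only when their bundle vertex indices
continue in the run direction: fragments of one traversal interrupted by
a private variant resume at a later index and are rejoined, whereas a
second tandem copy wraps back to the bundle start and remains a separate
(`R`-flagged) segment.  Opposite orientations are never merged — adjacent
opposite-orientation segments are exactly how a palindrome manifests.
Segments shorter than `bundle_length_cutoff` are dropped.

## Choosing decomposition parameters

Two situations recur in practice and in this package's fixtures:

* **Deep panels** (many haplotypes): the backbone has weight near the
  panel size and SNP-induced detours are light; the defaults
  (`min_cov = 0`, `min_branch_size = 8`, cutoff 100, merge 1000) work as
  is.
* **Repeats within few sequences** (e.g. one contig carrying six copies of
  a palindromic unit): each copy's private SNPs spawn weight-1 detours
  that can run longer than any reasonable branch-size cutoff, because a
  single substitution can re-phase minimizer selection over
  `~(w + r x spacing)` bases.  Here `min_cov = 2` (a vertex supported
  once is noise when the unit occurs six times) and a segment cutoff at
  the scale of interest (1 kb for multi-kb units) give a clean single
  repeat bundle.

# Diffusion entropy and repetitiveness

For graph complexity we use the equilibrium of a random walk.  With `A`
the support-weighted adjacency (symmetrized as `A + t(A)`) and `D` the
diagonal weighted-degree matrix, the walk `M = A D^-1` is iterated from
the all-ones vector.  The implementation uses the *lazy* step
`v <- (v + A D^-1 v) / 2`: on bipartite graphs the pure iteration
oscillates forever, while the lazy walk converges to the same stationary
distribution `p_i = d_i / sum(d)` on every connected graph — a closed form
the tests exploit as an independent oracle.  By default the iteration
budget equals the vertex count `N`, which is cheap and adequate for
well-connected graphs; `max_iter` raises it when the exact limit is wanted
on slowly mixing chains.  `D` uses weighted degrees because `A` is defined
with sequence-support weights.  The distribution `P` yields

* the **diffusion entropy** `S = -sum(p_i log2 p_i)` in bits, between 0
  and `log2 N`, higher for bubblier (more polymorphic) graphs, and
* the **repetitiveness score**, the mean of the top `min(32, N)` entries
  of `N * P`, approximately the copy number of the most repeated region
  (1.0 on a regular cycle).

Haplotype comparison uses two complementary devices: a binary
haplotype-by-vertex matrix over the principal-bundle vertices (rows are
ready for a standard centered PCA), and a bundle-string distance — each
contig becomes a sequence of `(bundle, orientation)` tokens weighted by
segment length, pairwise similarity is the length-weighted longest common
subsequence (a sparse alignment of bundle strings; a weighted edit variant
is available via `method = "edit"`), and the distance
`1 - 2 W_lcs / (W_a + W_b)` feeds average-linkage clustering.  Average
linkage is a deliberate, undramatic default; the distance is a bounded
dissimilarity but not a metric (the triangle inequality is not asserted).
Merge heights become Newick branch lengths, and a text layout file drives
the dendrogram panel of the SVG renderer.

# The synthetic pangenome generator

Real pangenome panels are multi-gigabyte downloads; the generator builds
study-condition-sized stand-ins with planted, therefore known, structure.
A plan is a library of random DNA units plus per-haplotype compositions
(ordered unit tokens with orientations), a SNP rate, an indel rate and a
seed; haplotypes are concatenations of independently mutated (and possibly
reverse-complemented) unit copies, and a truth table records every planted
non-flank interval.  The same seed reproduces the FASTA byte-for-byte.

Shipped presets and what they emulate:

* `palindrome3` — one haplotype, three palindromic repeats
  (`U+ U-` three times) of a 16 kb unit between 30 kb flanks, SNP rate
  1e-3: an amylase-style nested palindrome.  Unit length sits deliberately
  high in the 5–20 kb design range: segment boundaries blur by ~0.5–1 kb
  at `(48, 56, 8, 12)` (junction vertices are removed as branching points,
  and anchor windows overhang copy boundaries), and the unit must dwarf
  that blur for per-copy truth overlap to stay above 0.9.
* `bubble` — eight haplotypes, shared flanks, one divergent 10 kb middle
  allele at frequency 6:2: a simple bubble with a high-weight backbone.
* `big_inversion` — two haplotypes where the second carries the two middle
  units inverted as a block: a segmental-duplication-style inversion.
* `two_cluster_mhc` — sixteen haplotypes, two structural alleles (distinct
  15 kb middles) times eight carriers at SNP rate 2e-3: a polymorphic
  locus with two haplotype groups, used for the PCA and dendrogram checks.

What the generator does **not** emulate: realistic mutation spectra,
indel-rich evolution, recombination, assembly errors, or panel depths in
the dozens.  Passing tests on these fixtures demonstrate the algorithms'
contracts (conservation laws, strand symmetry, recovery of planted
structure at the stated rates), not performance on real assemblies.

# Numerical and degenerate-input choices

* Window ties take the leftmost k-mer; DFS ties take the smaller vertex
  id; both fixed for determinism.
* Sequences shorter than `k`, or blocks with fewer than `w` valid k-mers,
  yield no anchors; sequences with fewer than two SHIMMERs are skipped
  (with a warning) by graph construction and produce empty query results.
* Isolated vertices keep only decayed initial mass in the diffusion
  iteration and are flagged in the result.
* Distances are clamped to `[0, 1]`; contigs with no bundle segments sit
  at distance 1 from everything and trigger a warning.
* All coordinates are 0-based half-open internally and in BED outputs.
* Problem sizes in the test-suite: fixtures of 0.1–1.2 Mb total, graphs
  of up to a few thousand vertices, 50 random graphs of up to 200 vertices
  for the stationary-distribution checks, and 100 random 2 kb sequences
  for the minimizer oracle audit.

# Known limitations

* The k-mer hash differs (necessarily — it is unpublished) from the
  original pangenome toolkit this design follows, so absolute vertex and
  edge counts of that tool are not bit-reproducible; all structural
  properties are hash-independent.
* Single-sample repeat decomposition is sensitive to substitution noise:
  hierarchical selection amplifies one SNP into a re-phased anchor stretch,
  so with only six copies of a unit the exact segment count can vary with
  the mutation seed.  Deep panels (the intended regime) vote this noise
  down through vertex weights; the fixture checks therefore pin the
  generator seed.
* The bundle distance is not a metric, and the PCA is a convenience
  projection with no attached significance claims.
* Query results are anchor-resolution homology calls, not alignments;
  flank repeats can produce spurious hits that the hit table's anchor
  counts and spans are meant to let the user filter.
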