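---
title: "Minimizer-graph assembly-guided scaffolding with mxscaff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimizer-graph assembly-guided scaffolding with mxscaff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxscaff)
```

## The problem

A draft genome assembly is often available only as a bag of contigs, while a
chromosome-scale assembly exists for the same species, a different
individual, or a close relative. When the two genomes are structurally
syntenic, the contiguous assembly can be used to order, orient and even
correct the draft: reference-guided scaffolding. `mxscaff` does this without
computing alignments. Both assemblies are reduced to *ordered minimizer
sketches*, and a shared graph over those sketches supplies the mapping
between them.

## The model

### Sketching

For a sequence and parameters $k$ (k-mer size) and $w$ (window size), every
window of $w$ consecutive k-mers contributes its minimum-hash k-mer — the
*minimizer* — to the sketch. The hash is strand-neutral: the k-mer and its
reverse complement are packed into 64-bit integers (2 bits per base), each
XORed with a fixed seed and passed through the splitmix64 finalizer, and the
smaller value wins. Ties inside a window go to the leftmost k-mer, and
consecutive windows that select the same k-mer collapse into one record, so
a sketch is a strictly position-increasing list of `(hash, pos, strand)`
records. K-mers covering an ambiguous base (anything outside ACGT) receive
an infinite hash: they can never be selected, and a window with no valid
k-mer contributes nothing. This stops runs of `N`s from generating identical
minimizers in unrelated sequences. Sequences are uppercased before hashing,
so soft-masking has no effect.

A sequence shorter than $k + w - 1$ has no complete window and yields an
empty sketch; this is the mechanism by which very short contigs end up
unplaced.

### Anchors and the minimizer graph

Only *anchor* minimizers become graph nodes: hashes that occur **exactly
once in every input assembly** (the target and each reference). Uniqueness
within an input gives an unambiguous node-to-coordinate mapping; presence in
all inputs makes edge weights comparable across the graph. This anchor
definition is the single largest interpretive choice in the package and is
isolated in `selectAnchors()` so alternative policies (e.g. "present in any
reference") can be swapped in. With several divergent references, requiring
presence in *all* of them thins the anchor set; the practical mitigation is
a smaller $w$.

Each input's sketches are filtered to the anchor set, and every pair of
anchors adjacent in some filtered sketch becomes an undirected edge. An edge
records the set of supporting inputs, and its weight is the sum of the
user-specified weights of those inputs. Reference weights should exceed the
target weight (defaults: target 1, reference 2) so that, wherever target and
reference order disagree, the reference's adjacency outweighs the target's —
this is what "fits" the draft to the reference structure.

### Filtering to linear paths

1. **Global threshold** — edges with weight below $n$ are removed. The
   default $n$ is the minimum reference weight, which keeps every
   reference-supported adjacency and discards adjacencies supported only by
   a lighter target.
2. **Branch resolution** — every node of degree > 2 is visited in sorted
   hash order. Thresholds iterate over the node's distinct incident weights
   in ascending order, removing incident edges below the threshold, and stop
   as soon as the degree drops below 3. If three or more incident edges tie
   at the node's maximum weight the postcondition is unreachable by
   thresholding, so all incident edges are removed and the node becomes
   isolated. Removals take effect immediately, so later nodes see earlier
   decisions; the fixed visiting order makes the result deterministic.
3. **Cycle breaking** — components that survive as simple cycles (possible
   when both assemblies agree on a circular arrangement of anchors) are
   opened at their minimum-weight edge, ties going to the lexicographically
   smallest hash pair.

The result has maximum degree 2 and no cycles: a set of simple paths.

### From paths to scaffolds

Path nodes are mapped to target coordinates through the anchor index.
Maximal blocks of consecutive nodes on one contig become *runs*; a block
whose positions are not strictly monotone is split at each monotonicity
break. Orientation is `+` if positions increase along the path, `-` if they
decrease. A block left with a single anchor has no orientation evidence and
is dropped (counted in the placement report) rather than guessed — a guessed
orientation would be a manufactured misassembly.

A contig whose anchors land in two or more runs is a putative misassembly.
In the default mode it is cut at the midpoint of the unanchored region
between adjacent used anchor intervals; the true breakpoint is unobservable
between anchors, and the midpoint bounds the worst-case displacement by half
the local anchor spacing. With `noCut = TRUE` nothing is cut: the contested
contig goes, whole, to the run holding the majority of its anchors (ties:
larger anchor span in target bases, then the earliest run in deterministic
path order), and is removed from the rest.

Finally each scaffold is flipped, if necessary, so that the majority of its
placed bases are forward-oriented. A scaffold and its reverse complement are
equivalent objects; the flip makes output deterministic and means a target
identical to its reference passes through forward and unchanged.

### Gap sizes

The gap between adjacent runs is estimated from the reference: the distance
between the two boundary anchors on the reference, minus the unanchored
target flanks on each side of the junction (computed orientation-aware, from
each anchor's start to its run's trailing or leading edge). Estimates are
clamped below at `minGap`; if the boundary anchors lie on different
reference sequences in every reference, the gap falls back to `minGap`.
With exact anchors the estimator is exact up to the clamp, and under
divergence its error is bounded by the anchor spacing, on the order of
$w + k$ bases.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 32 | k-mer size in bases (2–32; 32 packs exactly into 64 bits) |
| `w` | 1000 | window size in k-mers; ~2/(w+1) of k-mers are sampled, so `w` trades anchor density against speed and memory |
| weights | 1 / 2 | per-input emphasis; reference > target fits the draft to the reference |
| `n` | min reference weight | global edge weight floor |
| `minGap` | 20 | smallest emitted gap in bases; keeps junctions visibly gapped and coordinates valid |
| `noCut` | FALSE | disable misassembly cutting (preserves any real structural variation in the target) |

The conservative defaults suit mammalian-scale assemblies; the examples and
tests in this package use smaller `w` (40–250) because their genomes are
desk-scale (0.1–2 Mb). As a rule of thumb `w` should be at least several
times smaller than the contigs you hope to place: a contig needs at least
two minimizers to be ordered *and* oriented.

## The synthetic test bed

`generateFixture()` builds the study conditions used throughout the test
suite: uniform-random DNA chromosomes; a target obtained by fragmenting them
at random breakpoints (normal fragment lengths, truncated at 500 bp),
shuffling, reverse-complementing each fragment with probability 0.5;
optionally substituting bases at a fixed rate (`snpRate`, a proxy for
scaffolding against a diverged relative); optionally deleting spacers at
known loci (true gap sizes); and optionally joining fragments from different
chromosomes into chimeric contigs (true misassemblies). Every fragment's
source interval, orientation, order and following gap are recorded, and
`scoreScaffolds()` turns a run against such a fixture into junction
precision/recall, orientation accuracy, chimera-cut sensitivity, gap errors
and NG50 before/after.

The default problem sizes were chosen as the smallest that still exercise
chromosome-scale behaviour: 2 chromosomes × 1 Mb fragmented into ~50 pieces
for reconstruction and divergence runs, 2 × 0.5 Mb with 5 chimeras for the
correction runs, and 1 × 0.3 Mb with 100–2000 bp deletions for gap
estimation.

What uniform DNA does *not* emulate is as important as what it does: there
are no repeat families, so unique anchors are abundant and anchor filtering
is rarely stressed; there is no GC skew, no real gap size distribution, no
assembly base errors beyond point substitutions, and no structural variation
between target and reference other than what the generator plants. Passing
these tests demonstrates algorithmic correctness of sketching, graph
construction, filtering, translation, cutting and gap estimation — not
performance on repeat-rich real genomes, where anchor density inside recent
segmental duplications will drop and short contigs will go unplaced more
often.

## Numerical and design choices

* **Hash representation in R.** R has no native 64-bit integers, so hashes
  cross the C++/R boundary as 16-character lowercase hex strings. Fixed
  width means radix string order equals numeric order; every sort in the
  package uses `method = "radix"` so that ordering (and therefore
  tie-breaking) is locale-independent.
* **Hash ties inside a window** go to the leftmost k-mer. At 64 bits,
  cross-sequence collisions are astronomically rare; determinism is the only
  practical concern.
* **Degenerate inputs.** Empty assemblies warn and produce empty sketches;
  sequences below $k + w - 1$ sketch to nothing; an empty anchor set is a
  fatal, actionable error (smaller `w`/`k`, or a closer reference);
  all-tied branch nodes are isolated; negative gap estimates clamp to
  `minGap`.
* **Cut bookkeeping.** Cut coordinates are forced to be non-decreasing and
  inside `(0, len)`; a run squeezed to an empty interval (possible only with
  overlapping anchor intervals from a non-monotone translation) is dropped
  rather than emitted empty.
* **Base conservation** is an invariant, not an aspiration: every target
  base appears exactly once across placed runs and unplaced pieces, and the
  test suite audits it on every end-to-end fixture. When a cut contig has
  only some pieces placed, the remaining pieces are emitted unplaced rather
  than discarded.
* **Coordinates** are 0-based half-open everywhere inside the package and in
  the path file; the AGP writer converts to the format's 1-based inclusive
  convention at that boundary only.
* **AGP dialect.** Gap lines use `gap_type = "scaffold"`,
  `linkage = "yes"`, evidence `"align_genus"` — the standard values for
  reference-derived scaffold joins.

## Known limitations

* `k` is capped at 32 by the 2-bit packing (no rolling hash for larger k).
* Only one target per run; scaffolding is single-round.
* A contig contested between paths under `noCut` is resolved by an anchor
  majority vote; with several references there is no per-reference
  arbitration beyond the edge weights.
* Gap estimates use the first reference (in input order) on which both
  boundary anchors co-occur; other references are consulted only as
  fallbacks.
* The dot reader is a validator for this package's own writer, not a general
  Graphviz parser.

## A worked run

```{r example, eval = FALSE}
fx <- generateFixture(fixtureSpec(nChromosomes = 2, chromLength = 1000000,
                                  fragmentMean = 40000, fragmentSd = 10000,
                                  seed = 1))
res <- scaffoldAssemblies(fx$target, fx$reference, k = 24, w = 250)
res
scoreScaffolds(res, fx)[c("junction_recall", "orientation_accuracy",
                          "ng50_before", "ng50_after")]
writeScaffoldOutputs(res, "improved", agp = TRUE)
```
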