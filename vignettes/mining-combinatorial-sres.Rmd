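---
title: "Mining combinatorial splicing regulatory elements from score-ranked de Bruijn graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining combinatorial splicing regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sremine)
library(tibble)
```

## The problem

Whether an exon is included in a mature transcript is modulated by short
exonic sequences — enhancers (ESEs) bound by activating splicing factors and
silencers (ESSs) bound by repressors. Their action is combinatorial:
SF2/ASF-class activators and hnRNP-class repressors can bind adjacent or
even overlapping sequences, and the outcome depends on which elements
co-occur in the same exon. `sremine` takes a per-k-mer activity score (such
as a log enrichment index from a minigene inclusion screen, where positive
scores mark enhancing hexamers and negative scores silencing ones) plus a
set of exon sequences, and asks: *which groups of enhancer and silencer
elements — of possibly different lengths — reside together in an
unexpectedly large set of exons?*

## Model

All length-k DNA strings form the k-dimensional de Bruijn graph; two k-mers
are joined when they overlap by k−1 nucleotides, so a path of m vertices
spells one (m + k − 1)-nt sequence. This is what lets the method emit
elements longer than the scored k-mers without fixing a length beforehand.
Scores rank all 4^k k-mers (neutral k-mers are pinned to score 0: they carry
no measured effect, and letting a supplied nonzero value stand would smuggle
signal into the neutral class); the top R ranks induce the enhancer SRE
graph, the bottom R the silencer graph.

Occurrence is recorded in a sparse binary profile over a fixed exon window,
and the shared-exon operator T(·) — the intersection of per-k-mer supports —
is anti-monotone in the k-mer set. Both mining levels are exact searches
whose pruning relies only on that anti-monotonicity:

* **Level 1** enumerates every maximal α-cohesive connected induced
  subgraph (MCS) of each SRE graph: connected vertex sets S with
  |T(S)| ≥ α such that every one-vertex extension drops below α. Because
  every subset of a cohesive set is cohesive, depth-first growth from each
  single vertex, extending by any adjacent vertex and memoising visited
  vertex sets, visits every MCS; maximality is checked against *all*
  adjacent vertices, which by anti-monotonicity is equivalent to checking
  all supergraphs. Overlapping MCSs sharing vertices are deliberately all
  kept — they are distinct candidate elements sharing nucleotides — and no
  subsumption pruning is applied; nested maximal sets cannot occur.
* **Level 2** enumerates every collection M of ≥ β MCSs (enhancer and
  silencer MCSs mixed in one ID space) with |T(M)| ≥ θ, by ordered
  set-enumeration: members are added in increasing ID order, so each subset
  is generated exactly once, and a branch is cut as soon as |T(M)| < θ
  (subset-infrequency pruning). The conceptual tree is an implementation
  detail; the contract — verified against brute-force subset enumeration in
  the tests — is the enumerated set itself. All qualifying collections are
  reported, not only maximal ones; `maximal_only = TRUE` filters afterwards.

## Sequence-level filtering

Because level 1 keeps overlapping subgraphs, a collection's members may be
overlapping occurrences of what is really one longer element. Each member
subgraph is therefore spelled (all maximal simple paths, substring-subsumed
spellings dropped), the spelled elements are located in each shared exon
window (every offset, overlaps allowed), and same-type occurrences
overlapping by at least one nucleotide are transitively merged, the merged
sequence being read off the exon itself over the union span. Merging is
per-exon: the same collection can yield different element sets in different
exons, and each distinct per-exon multiset of (sequence, type) is
aggregated across exons and emitted when it keeps ≥ 2 elements and reaches
the same θ used for collection mining. A collection that always collapses
to a single long element is discarded — it is one SRE, not a set.
Enhancer–silencer overlaps are never merged: antagonistic factors genuinely
compete for overlapping sites, and conflating them would erase exactly the
signal of interest. Setting `merge_same_type = FALSE` emits the alternative
reading in which overlapping same-type occurrences are distinct co-occurring
elements; both interpretations are legitimate and the package exposes both.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 6 | k-mer length of the score table and graph |
| `R` | 400 | vertices per SRE graph (top/bottom of the ranking) |
| `alpha` | 1000 | minimum exon support of a cohesive subgraph |
| `theta` | 100 | minimum shared-exon count of a collection and of an emitted set |
| `beta` | 2 | minimum collection size |
| `window`, `window_end` | 50, `"first"` | exon window scanned for occurrences |
| `merge_same_type` | `TRUE` | merged vs. unmerged reading of same-type overlaps |

The defaults are the genome-scale settings of the analysis the package
implements (hundreds of thousands of exons): R = 400 matches the portion of
the hexamer screen with the strongest evidence, α = 1000 keeps elements with
a reasonable number of common exons, θ = 100 is deliberately small so that
downstream filtering sees all candidate groups, and β = 2 asks for at least
pairs. α and θ are independent thresholds. Raising α can only shrink the
MCS count (anti-monotonicity); the collection count responds
non-monotonically, since coarser MCSs can recombine into more collections.

## Numerical and design choices

* **Ties in ranking** are broken lexicographically (A < C < G < T); the
  ranking, and hence the whole pipeline, is deterministic for fixed inputs.
* **Self-loops** (homopolymers) exist in the de Bruijn graph and count
  toward its 4^(k+1) edges, but are ignored for connectivity and spelling —
  a self-loop neither connects a vertex to a neighbour nor terminates a
  traversal meaningfully.
* **Connectivity is undirected.** Co-occurrence of elements has no edge
  direction semantics; subgraph growth treats adjacency bidirectionally.
  Spelling, by contrast, follows edge direction, since only directed paths
  spell sequences.
* **Exons shorter than the window** contribute their full length; windows
  shorter than k simply contain no k-mer. Non-ACGT characters (N) in a
  window match nothing — a conservative choice that avoids phantom
  elements. Sequences are used as given (sense strand); no
  reverse-complement scanning.
* **Coordinates** are 1-based inclusive throughout.
* **All occurrences participate in merging.** When a spelled element occurs
  several times in one window, every occurrence enters the overlap merge
  and the exon's candidate set is read off the full merged layout; picking
  one occurrence would be arbitrary and irreproducible. A consequence is
  that an exon with a stray second occurrence of an element presents a
  different multiset and is aggregated separately.
* **MCS IDs** are assigned after mining by sorting vertex sets
  lexicographically, making level-2 enumeration independent of discovery
  order; in the combined table, enhancer MCSs precede silencer MCSs.

## What the synthetic generator emulates — and what it does not

`gen_score_table()` emulates a hexamer activity screen: ~1182 enhancer and
~1090 silencer labels (the size of the published screen it mirrors), scores
drawn as signed folded-normal values, neutrals at zero, and optional
"boost" k-mers pinned beyond the observed extremes so planted elements are
guaranteed inside the top-/bottom-R graphs. `gen_exons()` produces uniform
random ACGT windows and plants complete motif sets into exactly the chosen
number of exons at non-overlapping random positions, rejection-sampling
background exons so the planting contract is exact. This captures the
co-occurrence signal and the random-sequence null, but not real exonic base
composition, codon structure, motif positional bias, or correlated motif
families; passing the planted-recovery and negative-control tests therefore
demonstrates algorithmic correctness and statistical separability at the
simulated effect sizes, not performance on real exomes.

The packaged validation uses desk-scale study conditions: 5,000 windows of
50 nt with a planted enhancer+silencer pair in 150 exons, mined at
α = 100, θ = 100, β = 2, and a matched 5-seed random negative control —
sizes chosen so a single-workstation run reproduces the qualitative
behaviour of the genome-scale analysis (planted sets recovered, random
input yielding an empty final table). Oracle tests compare both mining
levels against exhaustive enumeration on instances of up to 12 vertices /
10 MCSs, where the 2^n subset space is fully checkable.

## Limitations

* The exact collection enumeration is exponential in the number of MCSs in
  the worst case; the α and θ thresholds are what keep real instances
  tractable. No approximate or closed-itemset mining is provided.
* Scores are taken as given; the package does not estimate them from raw
  sequencing data, and merged elements are not re-scored — a merged set is
  re-admitted purely by its exon support.
* Significance is assessed by the random-sequence control, not by an
  analytic null model; supports near θ should be interpreted with care.
* Single-process execution; genome-scale runs are minutes-scale but not
  parallelised.
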