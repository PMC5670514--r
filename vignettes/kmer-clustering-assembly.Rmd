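---
title: "Clustering the de Bruijn graph before assembly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering the de Bruijn graph before assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoneworm)
```

## The problem

De novo transcriptome assembly from RNA-Seq reads usually proceeds through a
de Bruijn graph: every distinct k-mer of the read set is a node, and two
k-mers are linked when they overlap by k−1 bases. Assemblers typically hold
the *entire* graph in one shared-memory table, which for complex
transcriptomes means hundreds of gigabytes of RAM. But a transcriptome is not
one connected graph: ideally it decomposes into one connected component per
gene (plus its isoforms), and each component can be assembled independently.

`zoneworm` makes that decomposition the first step. It clusters the k-mer
graph into its connected components ("zones"), then runs a greedy
highest-abundance contig builder — the classic Inchworm-style walk used by
Trinity's first stage — separately within each zone. Every graph stage is
expressed as map/collate/reduce cycles over hash-partitioned key/value
stores, the data-parallel idiom of MPI-based MapReduce libraries, so the
memory footprint per logical worker is bounded and results are provably
independent of how the data is partitioned or paged.

## The pipeline

Given reads and a k-mer length *k* (default 25, the conventional choice for
transcriptome assembly):

1. **K-mer counting** (`count_kmers`). Map emits one `(k-mer, 1)` pair per
   valid window of each read; windows containing `N` are skipped; collate
   groups by k-mer; reduce counts occurrences, giving node abundances *C*.
   Entries below `min_kmer_cov` are dropped. In double-stranded mode each
   window is folded to its canonical form (lexicographic minimum of the
   k-mer and its reverse complement) before counting.
2. **Edge extraction** (`extract_edges`). A second cycle emits one ordered
   pair per two *adjacent* read positions that both yield valid k-mers; the
   reduce count is the edge abundance *CE*. Only read-supported edges exist —
   no trial extensions are enumerated — and edges lose both endpoints'
   support when a node is removed by the abundance floor.
3. **Edge filtering** (`filter_edges`). An edge survives only if its *CE* is
   maximal among its source's outgoing (3′) edges *and* maximal among its
   target's incoming (5′) edges; ties at the maximum are all kept. Removing
   dominated branch edges splits what would otherwise be sprawling
   components into per-gene clusters of comparable size — the load-balancing
   property that matters when clusters are assembled in parallel.
4. **Clustering** (`find_connected_components`). Every node starts in its own
   zone (IDs 0..N−1 by lexicographic rank). Each sweep — map emits zones
   across edges in both directions plus each node's own zone, collate groups
   by node, reduce takes the minimum — lets a zone grow by one neighbour
   layer. Convergence is declared when a sweep changes nothing.
5. **Assembly** (`group_by_zone`, `assemble_cluster`). Two more cycles
   regroup (k-mer, abundance) pairs under their zone ID, yielding one
   abundance map per cluster. Within a cluster, the unused k-mer of highest
   abundance seeds a contig, which is extended 3′ then 5′ by repeatedly
   choosing the highest-abundance overlapping k-mer; constituent k-mers are
   then retired and seeding repeats until the cluster is consumed.

`run_pipeline()` composes the stages; the `zoneworm` command-line tool (in
`exec/`) exposes them as subcommands with TSV hand-offs (`kmer⇥count`,
`source⇥target⇥CE`, `kmer⇥zone`) so every intermediate is inspectable, and a
stage-wise run reproduces the single-run FASTA byte for byte.

## The engine and its guarantees

`mr_map()`, `mr_collate()` and `mr_reduce()` operate on stores whose pairs
are routed to `partition_owner(key) = FNV-1a32(key) mod n_workers` (offset
basis 2166136261, prime 16777619, over the key's bytes). The hash is fixed
and seed-independent, so partition contents are reproducible across runs and
platforms. Workers are logical: partitions are processed sequentially, in
order, which preserves the per-partition output contract that a concurrent
backend would have to honour.

A partition whose estimated size exceeds `pagesize` bytes spills excess
pages to disk and reads them back transparently; spill files are serialized
R pages under `spill_dir` (an internal format — no stable on-disk layout is
promised), deleted at pipeline end unless `keep_temp` is set. Two design
choices differ from a fully streaming out-of-core system and are deliberate
at desk scale: pages are cut when a store is materialized (after a pass
collects its emissions) rather than incrementally per pair, and collate
materializes one partition at a time, so the true memory bound is the
largest partition, not `pagesize`. The *logical* guarantees are unaffected
and are what the test suite enforces: the final content of any store, and
the pipeline's FASTA output, are identical for any `n_workers` and any
`pagesize` at least one pair's size.

Value order within a key/multivalue pair is declared unspecified; every
reducer in the package is order-insensitive (counts, minima, grouped sets).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 25 nt | k-mer length; larger k increases specificity, decreases sensitivity at low coverage |
| `mode` | `strand_specific` | `double_stranded` folds k-mers to canonical form for unstranded libraries |
| `min_kmer_cov` | 1 | abundance floor; 2+ removes most single-error k-mers |
| `min_contig_length` | 48 nt | shortest reported contig |
| `filter_rule` | `and` | endpoint-maximality combination (see below) |
| `n_workers` | 1 | logical partitions |
| `pagesize` | 1 GiB | per-partition bytes before spilling |

## Design choices where the design was open

**Endpoint rule of the edge filter.** A dominated edge can be judged from
its source's 3′ view, its target's 5′ view, or both. The default requires
maximality at *both* endpoints: it splits clusters most aggressively —
directly serving balanced cluster sizes — while always preserving each
node's best edge. The AND rule can delete a node's only outgoing edge when
that edge is dominated at its target; this is accepted, and the milder OR
variant (`filter_rule = "or"`, survive if maximal at either endpoint) is
available for comparison.

**Winner rule in clustering.** When two zones meet across an edge the
numerically smaller ID wins. This is deterministic, order-independent, and
makes the final label of each component equal to the minimum initial zone ID
of its members — a property the tests check directly.

**Plain layer propagation.** Zones grow by one neighbour layer per sweep;
convergence needs at most (component diameter) sweeps plus one confirming
sweep. Accelerated label-propagation schemes reassign whole zones per
iteration and converge in far fewer sweeps on large-diameter graphs; plain
propagation was chosen for its directness and testability, and is noted as
the thing to replace first if path-like graphs of very large diameter
dominate a workload.

**Greedy extension ranks by node abundance, not edge abundance.** Edges
exist to segregate clusters; the walk itself selects, among the ≤4 one-base
shifts of the terminal k-mer, the candidate with the highest *node*
abundance present in the cluster's own map — which implicitly honours the
filtered topology, since clustering decided which k-mers share a map.
Tie-breaks are lexicographic (appended base during extension, k-mer at
seeding), making assembly invariant to map iteration order.

**Loop guard.** Extension stops when the chosen candidate was already
appended during the current extension call; the seed itself is exempt, so a
self-overlapping k-mer (e.g. `AAA`) extends exactly once rather than not at
all or forever. A cluster-wide used-set prevents re-use across contigs:
every k-mer is consumed by exactly one contig attempt.

**Paired-end reads** are consumed as a flat stream — both mates contribute
k-mers independently and pairing information is unused, consistent with the
role of a first-stage contig builder. Reads shorter than k are skipped and
counted, not errors.

## The synthetic-data generator

`generate_transcripts()` draws uniform random ACGT sequences; with
`disjoint_spectra = TRUE` each transcript is redrawn until it has no internal
repeated k-mer and shares none with previously drawn transcripts, so the
graph has exactly one linear component per transcript. The default
end-to-end conditions used throughout the tests and the acceptance script
are 20 transcripts of 300 nt at k = 25 — small enough to assemble in
seconds, large enough that clustering runs hundreds of sweeps and the
spill machinery is genuinely exercised at small pagesizes.

`tile_reads()` emits every start position exactly once (error-free), making
perfect-recovery checks non-stochastic: the read spectrum equals the
transcript spectrum, each component is a simple path, and the single contig
per zone must equal its transcript character for character.
`simulate_reads()` draws uniform random start positions to a target mean
coverage (default 30×, a realistic bulk RNA-Seq depth for expressed genes;
read length 100 nt) and applies i.i.d. substitution errors. The error model
is substitution-only — sufficient to create the low-abundance erroneous
branches that `min_kmer_cov` and the edge filter are meant to remove —
and deliberately omits indels, coverage bias, fragment-size structure and
strand flips. Passing these tests therefore demonstrates the graph
machinery and the greedy walk, not robustness to every artefact of real
libraries.

Randomness goes through R's default Mersenne-Twister generator seeded
explicitly, so every fixture is reproducible from its integer seed.

**Recovery criterion under errors.** A transcript counts as recovered when
some contig, after trimming at most k−1 nt from each end, is an exact
substring of the transcript with matched length ≥ 99% of the transcript
length minus the 2(k−1) nt truncation allowance. Exact containment implies
100% identity over the match; the truncation budget absorbs the two effects
errors have at component boundaries — uncovered transcript ends under random
start positions, and short erroneous k-mer chains that greedy extension can
append past the last true k-mer (such a chain is at most k−1 bases before
the erroneous k-mers run out of read support).

## Numerical and degenerate-input behaviour

* Empty read files warn and flow through to an empty FASTA with zero counts.
* `N`-containing windows are skipped; an adjacent pair spanning an `N`
  contributes no edge.
* Self-loops (`AAA → AAA`) are legitimate edges and are counted per
  occurrence.
* The propagation sweep count is bounded by `max_iter` (default 10 000) as a
  safety net; the iteration is monotone (zone IDs never increase, their sum
  strictly decreases until the fixed point), so hitting the bound indicates
  a bug, not a data property.
* The uniformity of FNV-1a over short DNA strings is adequate for load
  balancing (verified empirically in the tests); it is not cryptographic and
  adversarial key sets could skew partitions.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated data:
50 random read sets of ≤100 reads for the counting and edge oracles, 100
random graphs for filter properties, 50 Erdős–Rényi graphs of ≤200 nodes
against an independent components oracle, and the 20×300 nt end-to-end
conditions above (≈4 000 tiling reads, ≈5 500 nodes) — sizes chosen so the
whole suite exercises every code path, including multi-page disk spill, in a
few minutes on one core.

## Known limitations

* Workers are logical; no concurrent or distributed backend is included. The
  partitioning contract (hash ownership, per-partition grouping) is the
  interface such a backend would implement.
* Collate's memory bound is the largest partition (see above).
* Double-stranded mode is functional (canonical folding, orientation-aware
  extension) but strand-specific mode is the primary tested path; palindromic
  k-mers and orientation conflicts within a cluster are not specially
  resolved.
* No isoform resolution: one greedy contig set per component, no bubble
  popping or path enumeration — downstream stages of a full assembler would
  take over from the per-cluster contigs.
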