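---
title: "clustx: methods, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clustx: methods, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

`clustx` performs a translated (BLASTX-style) local homology search of
short DNA reads against a protein database.  Reads of 100–300 bp are
translated in all six frames; each maximal stop-free run of at least
10 residues becomes a query segment; segments are aligned to database
proteins by seed-and-extend with affine-gap local scoring; hits are
ranked by Karlin–Altschul statistics.

The distinguishing component is the seeding stage.  All length-10
database windows are clustered in a reduced amino-acid alphabet during
preprocessing, and at search time the triangle inequality

> d(q, m) ≥ |D(q, r) − d(r, m)|

turns one computed distance per cluster (query to representative,
`D(q,r)`) plus precomputed member–representative distances `d(r,m)`
into a sound lower bound on every member's distance.  Members whose
bound exceeds the filter threshold are rejected without ever computing
their true distance; members within the threshold are extended.
Because the bound never exceeds the true distance, no member that an
exact-distance filter would accept is lost: the clustered filter's
pass set is a superset of the exact one, which the test suite asserts
against a brute-force oracle.

## Pipeline stages and their contracts

1. **Encoding** — residues map to integer codes 0–19 (alphabetical),
   X = 20 for anything non-canonical (including B, Z, J, U, O), 21 for
   the sequence delimiter.  Databases are stored as one flat code
   array with a delimiter before, between, and after sequences, so
   every stage can treat "delimiter reached" as a hard extension
   boundary.
2. **Reduced alphabet** — a fixed Murphy-style 10-group partition
   {A,S,T} {C} {D,N} {E,Q} {F,W,Y} {G} {H} {I,L,M,V} {K,R} {P}, plus
   an X group and a delimiter group.  The clustering metric is plain
   Hamming distance over these group ids: conservative substitutions
   count as matches, which is what makes distance-1 clusters capture
   biologically related windows.
3. **Index** — greedy first-fit clustering in position order
   (threshold `T_c`), then three tables: `B_e` maps a hash key to
   singleton representatives, `B_r` to non-singleton cluster ids,
   `B_m` holds members and their stored distances.  The hash key is
   the base-10 positional encoding of a window's first 5 group ids;
   windows whose key prefix contains the X or delimiter group are not
   indexed (X-rich regions only generate spurious seeds).
4. **Seeding** — every query position is seeded (stride 1).  Lookup
   uses the exact key plus, at radius 1, all 45 keys differing in one
   prefix position; this recovers the sensitivity that exact-key
   lookup loses when a substitution falls inside the key prefix.
5. **Ungapped extension** — X-dropoff walk in both directions from the
   10-column seed; stop when the running score drops more than `X_u`
   below the running maximum; shortest prefix on ties; keep segments
   scoring at least `S_u`.
6. **Chain filter** — per (query segment, subject): one survivor per
   diagonal band of half-width `band`, plus removal of segments whose
   query interval nests inside a stronger survivor's.  Greedy in score
   order with deterministic tie-breaks; idempotent; the global best
   segment always survives.
7. **Gapped extension** — anchored at the central column of the
   segment's best 11-residue window (leftmost on ties — robust to
   weak segment ends), a Gotoh affine-gap DP extends outward on each
   side, pruning any cell more than `X_g` below the best score seen.
   The score pass stores a single DP row plus the column-wise gap
   state — never the full matrix.  Traceback for reported hits re-runs
   the *identical* pruned DP with stored matrices, so the traced score
   equals the score-only result by construction; any discrepancy is
   raised as an internal error, never patched.
8. **Statistics** — E = K·m·n·exp(−λS) with m the query segment
   length and n the *whole* database's residue count (not the
   chunk's), making E-values, bit scores, and therefore ranks
   invariant under database chunking — asserted byte-for-byte in the
   acceptance suite.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `L` | 10 residues | window length for clustering and seeding |
| `T_c` | 1 (reduced-Hamming) | clustering radius at build time |
| `k_h` | 5 groups | hash-key prefix length (10^5 key space) |
| `T_f` | 2 (reduced-Hamming) | similarity filter threshold |
| `r_h` | 1 | key lookup neighborhood radius at search time |
| `gap_open`, `gap_extend` | 11, 1 | affine penalties; gap of length k costs 11 + k |
| `X_u` | 20 raw score | ungapped X-dropoff |
| `S_u` | 20 raw score | ungapped survival cutoff (sensitivity/speed knob) |
| `X_g` | 38 raw score | gapped X-dropoff |
| `band` | 16 diagonals | chain-filter band half-width |
| `lambda`, `K` | 0.267, 0.041 | gapped Karlin–Altschul constants for BLOSUM62 11/1 |
| `chunk_bytes` | 1e9 residues | database chunk capacity (working-memory heuristic) |
| `e_cut`, `max_targets` | 10, 100 | reporting threshold and per-query row cap |

The window length `L` = 10 is fixed by the method; the matrix, gap
penalties, X-dropoffs, and statistical constants follow BLAST
conventions for BLOSUM62/11/1, since the method itself prescribes
none.  `T_c`, `T_f`, `k_h` and `r_h` have no published values either;
the defaults were chosen once (coarse clusters, generous filter,
tractable key space, one-substitution lookup tolerance) and are
exposed on the CLI rather than revisited.

## What the simulator emulates — and what it does not

`simulate_dataset()` emulates the metagenomic setting the search is
meant for: proteins sampled i.i.d. from uniform amino-acid
frequencies; each read reverse-translated (uniform synonymous codon
choice) from a random 50-residue window of a random protein on a
random strand; DNA-level substitutions at 5% per base by default;
optional DNA-level indels and decoy reads.  The benchmark
configuration (seed 42, 200 proteins of 100–400 residues, 200 reads
of 150 bp, 5% substitutions, no indels) is the suite's stated world.

It does **not** model: real amino-acid composition or codon bias,
sequencing error profiles or quality values, database redundancy
(homologous families, paralogs), or frameshifts within a read (indel
reads are generated on request but, like BLASTX, the pipeline is not
frameshift-aware, so they are excluded from the agreement
denominator).  Consequently a green oracle-agreement test establishes
that the pipeline recovers clear homology signals at the stated
mutation load — not that its sensitivity matches any particular tool
on real data.  Two specific caveats:

* In an i.i.d. database nearly all windows are mutually distant, so
  most clusters are singletons and the measured reduction in distance
  evaluations is small (the acceptance test asserts strict reduction
  at identical output, not a magnitude).  On redundant real databases
  the same mechanism prunes much more; the synthetic world
  under-states the benefit by construction.
* Uniform residue frequencies make Karlin–Altschul constants for
  BLOSUM62 slightly conservative; E-values here are ranking devices,
  not calibrated p-values (no effective-length correction either — a
  documented divergence from NCBI BLAST).

## Numerical and degenerate-input choices

* All coordinates are 0-based half-open internally; conversion to
  1-based (and to nucleotide positions on the read, with
  qstart > qend on reverse frames) happens only in the writer.
* Integer scores throughout; the DP kernels use 64-bit accumulators
  with a saturating "−∞" sentinel, so no overflow at any realistic
  score.
* Ties: ungapped extension keeps the shortest best prefix; the gapped
  DP keeps the first best cell in sweep order (smallest query offset,
  then smallest database offset); the anchor window takes the leftmost
  maximum; chain-filter ties rank by smallest qstart then dstart;
  final ranking breaks bit-score ties by E-value, subject id, then
  coordinates — every stage is fully deterministic.
* Segments shorter than 11 residues anchor on their central column;
  an anchor directly against a delimiter yields a zero-length, zero
  delta extension.
* Empty inputs (no reads, no seedable window, a frame with no
  stop-free run) propagate as empty results, not errors.  A sequence
  larger than the chunk capacity, a missing chunk file, and an index
  header mismatch are hard errors naming the offender.

## Open design decisions (and why)

Several details are not recoverable from the method's published
description and were fixed here as package decisions:

* **Clustering algorithm and spaces** — single-pass greedy first-fit
  in position order over the reduced alphabet, candidates restricted
  to the window's exact hash key at build time.  Deterministic, linear
  in database size, and correct for any input order (no external
  pre-sorting of the database is assumed or required).
* **Two-sided bound** — |D(q,r) − d(r,m)| rather than the one-sided
  D(q,r) − d(r,m): tighter, still sound.
* **Stop codons split segments** rather than translating through with
  a penalty: avoids inventing a stop penalty, and segments below 10
  residues could never seed anyway.
* **Chain-filter rule** — the "bring similar extended seeds together"
  step is concretized as diagonal-band grouping plus query-interval
  containment; the band half-width is exposed.
* **Parallelism as a contract** — workers, batch budget, chunk count
  and prefetch are scheduling knobs whose effect on output must be
  nil; the serial path is the reference semantics and an 8-way toggle
  matrix asserts byte-identical output.  The query-length dispatch
  sort (a GPU load-balancing device upstream) is kept observable in
  the run log but cannot influence results.

## Known limitations

* Score-level, not letter-level, agreement with NCBI BLASTX output is
  the goal; composition-based statistics, SEG masking, effective
  search-space correction, and two-hit seeding are all out of scope.
* The member filter accepts on the lower bound alone (no exact
  verification step), faithfully to the method; this admits members
  whose true distance exceeds `T_f`.  Extension and the score cutoff
  discard these cheaply, and chunk-equivalence of the final output is
  asserted on the benchmark, but pathological databases could in
  principle surface borderline extra hits whose visibility depends on
  cluster composition.
* Index files are written per chunk with a versioned binary header;
  indexes are not portable across parameter changes (by design — the
  loader refuses mismatches) and not incremental.
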