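# clustx

Translated protein homology search with a clustered seed index.

`clustx` searches short DNA reads (FASTA/FASTQ) against a protein
database (FASTA) in all six reading frames, BLASTX-style, and reports
BLAST-tabular hits with Karlin–Altschul E-values.  It is aimed at the
metagenomic use case — hundreds of thousands of 100–300 bp shotgun
reads against a large protein reference — where exhaustive
Smith–Waterman search is far too slow and the speedup has to come from
the algorithm, not the hardware.

## The method

The pipeline is seed-and-extend with an algorithmic twist in the
seeding stage:

1. **Database subsequence clustering (preprocessing).**  Every
   delimiter-free window of length *L* = 10 of the database (stored as
   one delimiter-concatenated 5-bit-range code array) is projected
   into a 10-group reduced amino-acid alphabet and greedily clustered:
   a window joins the first cluster whose representative is within
   Hamming distance *T<sub>c</sub>* (default 1) in the reduced space,
   else founds its own cluster.  Member–representative distances
   *d(r,m)* are stored.  Three tables index the clusters: `B_e`
   (singleton representatives), `B_r` (non-singleton representatives)
   and `B_m` (members), keyed by a base-10 encoding of the window's
   5-group prefix.

2. **Seed search with triangle-inequality filtering.**  For each query
   window *q* only the distance to each candidate representative
   *D(q,r)* is computed.  For every member of that cluster the bound

   d(q,m) ≥ |D(q,r) − d(r,m)|

   is evaluated from stored data alone; the member seeds iff the lower
   bound is ≤ *T<sub>f</sub>* (default 2).  The bound is sound — no
   member with true distance ≤ *T<sub>f</sub>* is ever rejected — and
   saves one full distance computation per member.

3. **X-dropoff ungapped extension** of surviving seeds (stop when the
   running score falls more than *X<sub>u</sub>* = 20 below the best;
   keep segments scoring ≥ *S<sub>u</sub>* = 20), **chain filtering**
   (one survivor per diagonal band per subject, nested query intervals
   dropped), and **X-dropoff gapped extension** (affine gaps 11/1,
   *X<sub>g</sub>* = 38, score-only pass storing a single DP column,
   full-matrix traceback only for reported hits).

4. **E-values**: E = *K·m·n·e<sup>−λS</sup>* with gapped BLOSUM62
   constants λ = 0.267, K = 0.041, where *n* is always the whole
   database's residue count so results are invariant under database
   chunking.  The database streams in chunks (default capacity 1 GB of
   residues) through a deterministic two-phase batched scheduler:
   phase 1 = seeding + ungapped extension, phase 2 = chain filtering +
   gapped extension dispatched in query-length order.

## Worked example

```r
library(clustx)

dir <- tempfile()
d <- simulate_dataset(sim_config(), dir)   # 200 proteins, 200 reads of
                                           # 150 bp, 5% DNA substitutions
build_db(d$files[["proteins"]], file.path(dir, "db"))
hits <- run_search(d$reads, file.path(dir, "db"))
head(hits[, c("qseqid", "sseqid", "pident", "length", "evalue", "bitscore")], 5)
```

```
    qseqid   sseqid   pident length       evalue  bitscore
1 read0001 prot0190 93.87755     49 1.110208e-26 107.45652
2 read0002 prot0005 85.71429     28 1.702408e-11  56.22498
3 read0002 prot0005 88.88889     18 1.939741e-06  38.89099
4 read0003 prot0015 88.00000     50 6.735398e-24  98.21173
5 read0004 prot0091 92.00000     50 5.886828e-28 111.69371
```

read0001's 150 bp translate to a 50-residue segment; 49 of its columns
align to prot0190 at 93.9% identity with E ≈ 1e-26 — the simulator's
truth table confirms prot0190 is the source protein.  read0002 carries
a substitution that created a stop codon, so its frame is split into
two segments and two HSPs are reported.  Against the exact
Smith–Waterman oracle (`oracle_top_hits()`), the pipeline's best
subject agrees for 200/200 reads at E ≤ 1e-5
(`top_hit_agreement()` = 1.0).

The same search from the shell:

```sh
Rscript inst/cli/clustx.R db  --in proteins.fasta --out mydb
Rscript inst/cli/clustx.R aln --query reads.fastq --db mydb --out hits.tsv
```

`hits.tsv` is 12-column BLAST outfmt-6 (one `#` header line); query
coordinates are 1-based nucleotide positions on the read, with
qstart > qend on reverse frames.

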