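# dbgasm

A desk-scale de novo short-read genome assembler in R, built so that every
algorithmic stage is independently testable against known ground truth.

De novo assembly reconstructs a genome from millions of short (~100 bp)
paired-end reads without a reference. dbgasm implements the full modern
short-read pipeline at sizes where truth can be checked exactly:

* **k-mer spectrum error correction** — k-mer windows of a read are
  *trusted* when their canonical count clears a cutoff placed at the valley
  between the error and coverage peaks of the count histogram; reads are
  repaired by a fast unique-substitution search, escalating to a bounded
  deep search over joint substitutions scored by total window counts (ties
  are left ambiguous rather than guessed).
* **De Bruijn graph construction** — nodes are canonical k-mers, edges
  canonical (k+1)-mers, so the graph is strand-symmetric and deterministic.
  A *sparse* mode stores only every g-th k-mer along unbranched stretches
  (with the skipped bases as extensions) and is contractually equivalent to
  the dense graph in the sequences it spells.
* **Graph cleaning and contigs** — low-coverage edge filtering, tip
  clipping, bubble popping, then maximal unbranched paths as contigs
  (unitigs).
* **Iterative multi-k assembly** — clean at small k, rebuild at larger k
  with previous contigs injected as protected pseudo-reads, resolving
  repeats of length up to k_max − 2 without losing assembled sequence.
* **Hierarchical paired-end scaffolding** — link bundling with outlier
  trimming and support thresholds, rank-by-rank joining from short to long
  insert libraries, transitive link reduction, heterozygous contig-pair
  masking by depth and local topology, chimeric-junction rectification by
  larger-insert spanning evidence, and topology-based recovery of weakly
  supported links. Gap sizes are estimated as
  `avg_ins − d_a − d_b` from the mates' outer distances to the linked
  contig ends.
* **Gap closing** — iterative local assembly into each wildcard gap using
  cumulative read evidence across cycles (reads are never un-assigned),
  weighted per-base consensus with an ambiguity stop, and overlap-based
  closure validated against the gap estimate.
* **Simulator and evaluator** — a fully seeded truth-known generator
  (haploid/diploid genomes, exact repeat families, multiple insert-size
  libraries, substitution errors) and assembly metrics (N50/NG50, reference
  coverage by seeded exact-match chaining, structural-error counting).

It is aimed at method developers, students and reviewers who want an
assembler whose every stage can be read, instrumented and verified in an
afternoon — not at production genomes.

## Worked example

Simulate a 60 kb genome containing an exact 2 kb two-copy repeat, sequence
it with a 500 ± 20 bp paired-end library at 40× and a 5 kb ± 300 bp library
at 15× (0.5% substitution errors), and assemble:

```r
library(dbgasm)
genome <- simulate_genome(60000, gc = 0.5, repeats = list(c(2000, 2)),
                          seed = 1)
libs <- list(pe_library("short", 500, 20, "FR", rank = 1),
             pe_library("long",  5000, 300, "FR", rank = 2))
pe <- list(simulate_pe_library(genome, libs[[1]], 100, 40, 0.005, seed = 2),
           simulate_pe_library(genome, libs[[2]], 100, 15, 0.005, seed = 3))
res <- run_assembly(pe, libs, k = 31)

res$correction_summary
#>     unchanged     corrected uncorrectable     ambiguous
#>         20144         12080           776             0

res$contigs[, c("id", "length", "mean_coverage", "read_depth")]
#>       id length mean_coverage read_depth
#> 1:     1  53050      38.23033   55.32328
#> 2:     2   2193      29.95791   42.31646
#> 3:     3   2000      67.49010   93.10000
#> 4:     4    877      25.40544   33.86545
#> ...

n50_stats(nchar(res$scaffold_seqs$seq), genome_size = 60000)
#> <assembly_stats: 7 seqs, total 60199 bp, N50 55865, largest 55865, NG50 55865>

cov <- reference_coverage(res$scaffold_seqs, genome, max_insert = 5000)
#> reference coverage: 97.0%, structural errors: 0

res$gap_results[, c("scaffold_id", "gap_index", "est_gap", "status", "fill_len")]
#>    scaffold_id gap_index est_gap  status fill_len
#> 1:           1         1  1938.5 partial      207
```

Reading the output: 12,080 of ~33,000 reads carried correctable errors and
were repaired (none invented on clean reads — a tested invariant). At
k = 31 the 2 kb repeat collapses into a single double-depth contig (id 3,
~67× k-mer coverage vs ~38× elsewhere), fragmenting the assembly; the 5 kb
library then bridges the repeat locus, lifting the scaffold N50 to 55.9 kb
and 97% reference coverage with no structural errors. The bridged repeat
gap (estimated 1939 bp) is only partially filled: the gap closer's
ambiguity rule stops the consensus where reads from the two repeat copies
conflict, in preference to risking a wrong-copy fill.

A thin CLI over the same functions lives in `exec/dbgasm`:

```sh
Rscript exec/dbgasm simulate --genome-length 20000 --coverage 30 \
    --error-rate 0.003 --out-prefix sim --seed 5
Rscript exec/dbgasm all --config sim.cfg --kmer 31 --out-prefix asm
Rscript exec/dbgasm evaluate --reference sim_genome.fasta --out-prefix asm
```

Subcommands `correct`, `pregraph`, `contig`, `map`, `scaff`, `gapclose`
run the individual stages; `--kmer-range 21,51,10` switches contig building
to the multi-k plan, `--sparse`/`--sparse-g` to sparse graph construction,
and `--diploid` to the heterozygosity-aware pipeline.

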