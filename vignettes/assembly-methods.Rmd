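---
title: "Assembly methods in dbgasm: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly methods in dbgasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbgasm)
library(data.table)
```

dbgasm is a complete short-read de novo assembler built at desk scale: every
stage is an ordinary R function operating on inspectable objects, and a
truth-known simulator makes every algorithmic claim testable end to end.
This vignette explains the science behind each stage, the parameters that
matter, and the places where we made a design choice among several
defensible options.

## The de Bruijn graph model

Reads are decomposed into k-mers. Nodes of the graph are *canonical* k-mers
(the lexicographic minimum of a k-mer and its reverse complement), and an
edge is a canonical (k+1)-mer: the adjacency of two k-mers observed inside a
read. Storing edges as (k+1)-mers makes the graph strand-symmetric by
construction — walking an edge forward is the same lookup as walking its
reverse complement backward — and makes graph construction order-invariant
and deterministic. k is required to be odd so that no k-mer equals its own
reverse complement.

The choice of k trades repeat resolution against coverage: a window of
length k is sampled by `read_len - k + 1` positions per read, so large k
resolves repeats up to length `k - 1` but thins the effective coverage;
small k is robust at low coverage and lets sequencing errors be recognized
(an isolated error creates k low-multiplicity k-mers). The multi-k strategy
below uses both ends of this trade-off.

## Error correction by k-mer spectrum

The corrector classifies each k-mer window of a read as *trusted* or
*untrusted* by its count in the library-wide canonical spectrum. In `auto`
mode the trusted cutoff is placed at the first local minimum of the count
histogram between the error peak (counts near 1) and the coverage peak
(counts near the sequencing depth); a unimodal histogram falls back to a
cutoff of 2 with a warning. Trusted means `count >= cutoff`.

Two search modes repair reads, both substitution-only (the Illumina error
model this package targets):

* **fast** — scan windows left to right; at the first untrusted window, try
  the three alternative bases at every position covered only by untrusted
  windows, starting from the last base of the first untrusted window. An
  edit is accepted only when it is the *unique* substitution that makes all
  windows covering that position trusted. Repeats up to `max_edits` times
  (default 2).
* **deep** — a bounded depth-first search over joint substitutions at up to
  `max_edits` sites, exploring at most `budget` branches (default 64).
  Candidates that clear every window are ranked by the total spectrum count
  of their windows; the strictly best one is applied. Two candidates tying
  on that score leave the read unchanged with status `ambiguous` — this is
  what prevents reads inside near-identical repeat copies from being
  "corrected" toward the wrong copy.

A read that cannot be fully cleared is returned unchanged (`uncorrectable`)
rather than partially edited; `fast_then_deep` escalates only the reads fast
mode could not fix, so its corrected count dominates fast mode's by
construction. Quality strings are carried through but not used: the method
is k-mer-frequency driven.

A *spaced* k-mer scheme (two matched blocks separated by skipped positions,
default `block = ceiling(k/2), skip = 4`) is available as a corroboration
filter: when enabled, an accepted edit must also leave every spaced k-mer
covering the edited site trusted. Spaced seeds are insensitive to a
mismatch falling in the skipped gap, so they confirm an edit from partially
independent evidence. The exact combination rule of consecutive and spaced
seeds is an open design point; we chose a conservative veto (off by
default) and exposed the pattern as a parameter.

## Dense and sparse graph construction

`build_dbg()` stores every canonical k-mer. `build_sparse_dbg()` stores, along
every unbranched stretch, only every g-th k-mer as an *anchor* together with
the skipped bases as an extension string; anchors are forced at unitig
boundaries (branch or merge positions). The contract — and the core
equivalence test of the package — is that the spelled sequences of maximal
unbranched paths are identical between the sparse and dense graphs at equal
k, for every input and every g. The anchor count shrinks roughly as 1/g,
which is the memory argument for sparse construction at scale.

We derive anchors deterministically from the canonical k-mer and edge sets
rather than by greedy placement while streaming reads: greedy placement is
read-order dependent, and determinism plus spelled-sequence equivalence is
the contract everything downstream relies on. Group coverage is carried as
the mean k-mer multiplicity of the stretch; when the sparse graph is lowered
to its dense view for cleaning, per-k-mer multiplicities inside a group are
that rounded mean. This loses within-group multiplicity detail, which is
acceptable because cleaning decisions happen at junctions, where anchors are
exact.

## Graph cleaning

Three operations, each monotone (never adding nodes or edges), applied in
the order low-coverage filter, tip clipping, bubble popping:

* **`remove_low_coverage()`** deletes edges with multiplicity at or below
  `cutoff` (default 1) and any node that thereby loses all edges. At 30-40x
  coverage, isolated sequencing errors produce multiplicity 1-2 edges, so
  the default removes most error structure before topology-based cleaning.
* **`clip_tips()`** removes dead-end chains shorter than `max_tip_len`
  (default 2k) whose mean coverage is below their best sibling edge at the
  junction where they attach. Tips are the signature of errors near read
  ends.
* **`pop_bubbles()`** merges two parallel simple paths sharing a source and
  sink when their spelled sequences align within `max_divergence` (edit
  distance over the longer spelling). The lower-coverage path is folded
  into the higher-coverage one and its multiplicities are added; coverage
  ties break toward the lexicographically smaller spelling. A single-SNP
  bubble spells two branches of about `k + 1` bp differing at one base,
  i.e. divergence `1/(k+1)` (0.045 at k = 21, 0.031 at k = 31), so the
  default `max_divergence = 0.03` pops only longer, denser near-identities
  and leaves isolated heterozygous SNP bubbles intact at typical k.
  Branches longer than `max_path_len` (default 500 bp) are never
  considered, protecting haplotype-scale divergent regions.

Every tie-break in the package is lexicographic on spelled sequence:
determinism was preferred over faithfulness to any particular historic
behavior, because reproducibility is what makes the test suite meaningful.

## Multi-k contig assembly

`assemble_multik()` implements the iterative strategy: clean with a small k
(default plans start at 21), then rebuild at k' = k + step (step even, so k
stays odd), injecting the previous round's unitigs as pseudo-reads alongside
the reads. Edges supported only by pseudo-reads are *protected* from the
low-coverage filter and tip clipping, which guarantees that sequence already
assembled is never lost when window coverage at the larger k drops below
cleaning thresholds. Reads contribute k-mers whether or not they place on
the previous unitigs; spurious edges from unplaced reads carry no protection
and face the low-coverage filter, which at substitution-only error rates is
equivalent to threading placed reads explicitly and cheaper to compute.
Edge multiplicities are recomputed from the reads each round rather than
carried over, because the (k+1)-mer support of a window genuinely differs
between k values.

A degenerate plan (`k_min == k_max`) is bit-identical to the single-k
pipeline; an exact two-copy repeat of length L with unique flanks is
resolved whenever `k_min - 1 <= L < k_max - 1` on error-free data — both are
tested properties. Final contig depth is recomputed by mapping all reads
back (`contig_read_depth()`).

## Paired-end scaffolding

Read pairs whose mates place on different contigs yield links. For an FR
library, a mate on the + strand points its fragment rightward, fixing the
contig's orientation and linked end in the implied layout; the observed gap
is `avg_ins - d_a - d_b` with `d` the distance from each read's outermost
(5') base to the linked contig end. RF (outward-facing mate-pair) libraries
are normalized by flipping both strands at link creation, so all downstream
logic is library-agnostic. Same-contig pairs re-estimate the insert
distribution instead of producing links.

Links are bundled per (contig pair, orientation, rank); observations more
than 3 library standard deviations from the bundle median are discarded
before averaging. Bundles with fewer than `min_support` pairs (default 3,
the classic default for this family of assemblers) are kept as *weak
candidates*; minority orientations are recorded as conflicts.

Scaffolding proceeds rank by rank, short inserts first; each later rank
treats the scaffolds built so far as super-contigs by lifting bundles onto
scaffold ends. Within a rank, a direct link explained by a two-link chain
(gap within 3 pooled standard deviations, `sqrt(sd_a^2 + sd_b^2 + sd_c^2)`)
is transitively redundant and removed; scaffold ends with two or more
remaining candidates are ambiguous branchings and stay unjoined; the rest
are linearized, breaking would-be cycles at the weakest-support link. Gap
estimates keep their sign internally (negative estimates mean overlapping
contigs, resolved only by gap closing); rendering clamps every internal gap
to at least one `N`.

**Heterozygous contig pairs.** Two contigs are called allelic when their
depths fall in a window (default 0.3-0.7) around the modal depth of long
contigs, they share a neighbor on both flanks, and their lengths agree
within a factor 2. The higher-depth member is kept; the other is masked
from scaffolding (and emitted separately), with equal depths resolved
toward the smaller id. Two concretizations matter at desk scale. First,
"neighbor" includes unitig-graph adjacency (shared (k-1)-mer junctions at
contig ends) as well as bundle-graph adjacency, because under a
substitution-only heterozygosity model allelic fragments are bubble-scale —
shorter than the insert size — and anchor no paired-end bundles. Second, a
shared-junction pair whose sequences align within 10% divergence is
accepted even when a depth estimate drifts outside the window, provided
both depths sit below 0.85 of modal: depth estimates on sub-kilobase
fragments carry too much sampling noise for a fixed window alone, while
near-identity at half depth is exactly the allelic signature (full-depth
diverged duplications remain excluded). In the diploid pipeline
(`run_assembly(diploid = TRUE)`), contig-stage bubble popping is disabled so
allelic structure survives to this stage, and detection/masking is iterated
to fixpoint: after removing a dropped allele's exclusive k-mers from the
graph and re-extracting unitigs, previously fragmented allelic stretches
consolidate and their pairs become detectable in the next pass.

**Chimera rectification.** After each rank, every internal junction is
audited against all larger-insert bundles: pairs spanning the junction
(consistent orientation and layout distance) support it; if none span it
and a junction-adjacent contig has at least `min_support` higher-rank links
to contigs outside the scaffold, the junction is cut and the pieces re-enter
the next round. A junction with any consistent spanning support is never
cut. We re-run rectification after every rank rather than once at the end,
so a false join made with a short-insert library cannot block the longer
library's joins in the same region.

**Weak-link recovery.** A weak candidate is accepted (tagged `recovered`)
when the accepted bundle graph already implies the same layout through a
consistent two-link chain, or when it is the unique, conflict-free
candidate joining two dead scaffold ends.

## Gap closing

Wildcard gaps are filled by iterative local assembly. A read is assigned to
a gap when its placed mate implies, through the library insert distribution
(mate position +/- `avg_ins` +/- 3 sd), that the read lies inside the gap
interval; unplaced and soft-placed reads are eligible. Each cycle extends
both flanks inward by per-base weighted consensus: reads anchored by an
exact (k_fill - 1)-mer at the growing end vote for the next base, one vote
per read, with weight halved once a read has disagreed with the consensus.
A column whose runner-up weight exceeds 0.8 of the winner is ambiguous and
stops extension — the guard against filling a gap with the wrong copy of a
repeat. The gap closes when the two extensions overlap by at least `k_fill`
bases (default 25) with at most one mismatch, choosing the overlap most
consistent with the estimated gap; negative estimates test a direct flank
overlap first.

The central rule is *cumulative evidence*: votes come from every read
assigned in any cycle up to the current one, not only the reads reachable
this cycle. Reads are never un-assigned. The legacy cycle-local behavior is
retained behind `rule = "cycle_local"` purely so the test suite can
demonstrate the cumulative rule's advantage on engineered cross-cycle
conflicts. Fills are capped at `est_gap + 3 pooled sd + 2 read_len`
(`partial` beyond that); partial extensions replace wildcards they resolve,
so the assembly's total `N` count never increases across cycles.

## The simulator and what passing tests mean

`simulate_genome()` draws i.i.d. bases at a requested GC content and plants
exact repeat families at non-overlapping uniform positions;
`make_diploid()` adds i.i.d. heterozygous substitutions, optionally confined
to a region; `simulate_pe_library()` draws fragment lengths from a truncated
normal (`[2 read_len, 2 avg_ins]`), samples fragment starts uniformly, reads
inward (FR) or outward (RF), and plants i.i.d. substitution errors — with
complete per-read truth emitted. Everything is deterministic per seed.

Two deliberate idealizations: the first and last two fragments per
haplotype are pinned to the genome ends, because a finite linear genome
sampled uniformly leaves its terminal bases at vanishing depth — an edge
artifact of desk-scale genomes, not a property of assembly; and the error
model is substitution-only, matching the corrector's scope. Real data adds
indels, quality-correlated and GC-biased errors, PCR duplicates and
chimeric fragments; passing this suite therefore demonstrates algorithmic
correctness under the stated model, not field performance. Heterozygosity
by i.i.d. substitution at 2% produces bubble-scale allelic fragments rather
than the long haplotype contigs of real diploid assemblies, which is
precisely why the het-pair machinery documents the graph-topology and
similarity concretizations above.

## Evaluation

`n50_stats()` implements the standard N50/NG50 definitions (NG50 absent when
half the genome size is unreachable). `reference_coverage()` aligns
assemblies by exact 31-mer seeding with maximal ungapped extension, adequate
for the near-identical toy genomes it targets — a deliberate substitute for
a full aligner, and a documented limitation. Structural errors are counted
operationally: adjacent aligned blocks of one sequence that flip strand or
whose reference spacing disagrees with their query spacing by more than
twice the maximum insert size contribute one breakpoint each; an internal
inversion therefore counts two junctions (one per flank).

## Problem sizes

The test suite and the acceptance script run, end to end, on genomes of
5-100 kb at 15-40x coverage with two libraries (500 +/- 20 bp FR and
5 kb +/- 300 bp), read length 100 bp, substitution rate 0-0.5%, twenty
seeded replicates for the scaffolding and chimera properties — sizes at
which every stage's truth can be checked exactly while the whole suite runs
in minutes on one CPU.

```{r example, eval = FALSE}
genome <- simulate_genome(60000, gc = 0.5, repeats = list(c(300, 2)),
                          seed = 1)
libs <- list(pe_library("short", 500, 20, "FR", rank = 1),
             pe_library("long", 5000, 300, "FR", rank = 2))
pe <- lapply(libs, simulate_pe_library, genome = genome, read_len = 100,
             coverage = 20, error_rate = 0.005, seed = 2)
res <- run_assembly(pe, libs, k = 31)
n50_stats(nchar(res$scaffold_seqs$seq), genome_size = 60000)
reference_coverage(res$scaffold_seqs, genome)
```
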