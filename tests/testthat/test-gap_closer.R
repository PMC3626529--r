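test_that("conflict resolution follows cumulative weights and the
           ambiguity ratio", {
  expect_equal(resolve_conflict(c(A = 6, G = 1)), "A")
  expect_true(is.na(resolve_conflict(c(A = 5, G = 4.5))))  # 0.9 > 0.8
  expect_equal(resolve_conflict(c(C = 1)), "C")
  expect_error(resolve_conflict(numeric()), "at least one")
})

test_that("reads are assigned to gaps their placed mates imply", {
  # scaffold: two 2 kb contigs around a 300 bp gap; library 500 +/- 20
  g <- simulate_genome(4300, 0.5, seed = 41)
  gg <- g$haplotypes[1L]
  contigs <- data.table::data.table(
    id = 1:2, seq = c(substr(gg, 1, 2000), substr(gg, 2301, 4300)),
    length = 2000L)
  sc <- data.table::data.table(scaffold_id = 1L, part_index = 1:2,
                               contig_id = 1:2, orient = "+",
                               gap_after = c(300, NA))
  lib <- pe_library("short", 500, 20, "FR", 1)
  sim <- simulate_pe_library(g, lib, 100, 30, 0, seed = 42)
  tasks <- assign_reads_to_gaps(sc, contigs, list(sim), list(lib))
  expect_length(tasks, 1L)
  task <- tasks[[1L]]
  expect_gt(nrow(task$reads), 5L)
  expect_equal(task$est_gap, 300)
  # every assigned read truly originates near the gap interval [2000, 2300)
  tr <- sim$truth[match(task$reads$id, sim$truth$read_id)]
  expect_true(all(tr$true_start + 100 > 2000 - 3 * 20 - 100 &
                    tr$true_start < 2300 + 3 * 20 + 100))
  # distant reads are never assigned: mates placed 5 kb from the gap
  far <- sim$truth$read_id[sim$truth$true_start < 800]
  expect_false(any(far %in% task$reads$id))
})

test_that("extension without reads is a no-op", {
  task <- gap_task(1L, 1L, strrep("ACGT", 20), strrep("TTCA", 20), 100,
                   data.table::data.table(id = character(),
                                          seq = character()))
  out <- extend_cycle(task, 1L)
  expect_equal(out$left_ext, "")
  expect_equal(out$right_ext, "")
})

test_that("cumulative evidence outvotes cycle-local reads at conflict
           columns", {
  set.seed(43)
  flank <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
  tailseq <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                   collapse = "")
  good <- paste0(substr(flank, 31, 60), "G", tailseq)  # earlier-cycle reads
  bad <- paste0(substr(flank, 31, 60), "A", tailseq)   # current-cycle reads
  reads <- data.table::data.table(
    id = sprintf("r%d", 1:7),
    seq = c(rep(good, 5L), rep(bad, 2L)),
    cycle_first_seen = c(rep(1L, 5L), rep(2L, 2L)))
  mk <- function() gap_task(1L, 1L, flank, strrep("T", 30), 40, reads)
  cum <- extend_cycle(mk(), cycle = 2L, k_fill = 25L, rule = "cumulative")
  expect_equal(substr(cum$left_ext, 1L, 1L), "G")
  legacy <- extend_cycle(mk(), cycle = 2L, k_fill = 25L,
                         rule = "cycle_local")
  expect_equal(substr(legacy$left_ext, 1L, 1L), "A")
  # the cumulative rule matches the majority (true) base; the legacy rule
  # is strictly worse on this fixture
  expect_false(substr(legacy$left_ext, 1L, 1L) ==
                 substr(cum$left_ext, 1L, 1L))
})

ten_gap_fixture <- function(seed = 3L) {
  lay <- make_scaffold_fixture(seed)
  fx <- scaffold_fixture_bundles(lay, seed + 700L)
  sc <- build_scaffolds(lay$contigs, fx$bundles, fx$libs)
  list(lay = lay, fx = fx, sc = sc)
}

test_that("unique-sequence gaps close to the exact truth", {
  t <- ten_gap_fixture(3L)
  out <- close_gaps(t$sc, t$lay$contigs, t$fx$pe, t$fx$libs)
  expect_gte(sum(out$results$status == "closed"), 8L)
  # closed fills equal the true inter-contig sequence: the whole rendered
  # scaffold must match the genomic span exactly when all gaps close
  if (all(out$results$status == "closed")) {
    span <- substr(t$lay$genome$haplotypes[1L], 1L,
                   t$lay$starts[10L] + t$lay$lens[10L])
    expect_true(out$scaffolds$seq[1L] %in% c(span, revcomp(span)))
  }
  # flanks byte-stable: contig sequence outside gaps is untouched
  for (i in seq_len(10L)) {
    ctg <- t$lay$contigs$seq[i]
    expect_true(grepl(ctg, out$scaffolds$seq[1L], fixed = TRUE) ||
                  grepl(revcomp(ctg), out$scaffolds$seq[1L], fixed = TRUE))
  }
})

test_that("gap closing never increases the wildcard count", {
  t <- ten_gap_fixture(4L)
  before <- scaffold_seq(t$sc, t$lay$contigs)
  n_before <- sum(vapply(gregexpr("N", before$seq),
                         function(m) sum(m > 0L), 0L))
  out <- close_gaps(t$sc, t$lay$contigs, t$fx$pe, t$fx$libs, max_cycles = 3L)
  n_after <- sum(vapply(gregexpr("N", out$scaffolds$seq),
                        function(m) sum(m > 0L), 0L))
  expect_lte(n_after, n_before)
})

test_that("a gap inside a diverged two-copy repeat is never misjoined", {
  # two 600 bp repeat copies differing at one site; the gap contains copy 2.
  # reads from copy 1 vote the wrong base at the divergent column, so the
  # consensus must either stall (partial/open) or recover the exact truth
  g <- simulate_genome(8000, 0.5, seed = 44)
  gg <- g$haplotypes[1L]
  copy <- substr(gg, 3001, 3600)
  gg2 <- gg
  substr(gg2, 1001, 1600) <- copy            # copy 1 at [1000, 1600)
  mid <- substr(gg2, 3301, 3301)
  substr(gg2, 1301, 1301) <- setdiff(c("A", "C", "G", "T"), mid)[1L]
  genome <- structure(list(haplotypes = gg2,
                           repeat_annotations = data.table::data.table(),
                           variant_positions = data.table::data.table(),
                           seed = 44L), class = "genome_truth")
  contigs <- data.table::data.table(
    id = 1:2, seq = c(substr(gg2, 1, 2900), substr(gg2, 3701, 8000)),
    length = c(2900L, 4300L))
  sc <- data.table::data.table(scaffold_id = 1L, part_index = 1:2,
                               contig_id = 1:2, orient = "+",
                               gap_after = c(800, NA))
  lib <- pe_library("short", 500, 20, "FR", 1)
  sim <- simulate_pe_library(genome, lib, 100, 35, 0, seed = 45)
  out <- close_gaps(sc, contigs, list(sim), list(lib))
  truth_fill <- substr(gg2, 2901, 3700)
  if (out$results$status == "closed")
    expect_equal(out$results$fill_seq, truth_fill)
  else
    expect_true(out$results$status %in% c("partial", "open"))
})

test_that("scaffolds without gaps pass through byte-identical", {
  contigs <- data.table::data.table(id = 1L, seq = strrep("ACGT", 500),
                                    length = 2000L)
  sc <- data.table::data.table(scaffold_id = 1L, part_index = 1L,
                               contig_id = 1L, orient = "+",
                               gap_after = NA_real_)
  lib <- pe_library("short", 500, 20, "FR", 1)
  sim <- list(read1 = data.table::data.table(id = "p1/1", seq = strrep("ACGT", 25)),
              read2 = data.table::data.table(id = "p1/2", seq = strrep("ACGT", 25)),
              pairs = data.table::data.table(pair_id = "p1", read1_id = "p1/1",
                                             read2_id = "p1/2",
                                             library = "short"),
              library = "short")
  out <- close_gaps(sc, contigs, list(sim), list(lib))
  expect_equal(out$scaffolds$seq, strrep("ACGT", 500))
  expect_equal(nrow(out$results), 0L)
})
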