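test_that("dense graph construction matches hand enumeration", {
  g <- build_dbg("ACGTC", 3)
  # windows ACG, CGT, GTC canonicalize to ACG (x2) and GAC; edges are the
  # 4-mers ACGT (its own reverse complement) and CGTC (< GACG)
  expect_equal(g$nodes$kmer, c("ACG", "GAC"))
  expect_equal(g$nodes$count, c(2, 1))
  expect_equal(g$edges$kmer, sort(c("ACGT", "CGTC")))
  expect_equal(g$edges$count, c(1, 1))
})

test_that("graph multiplicities are additive and strand-symmetric", {
  one <- build_dbg("ACGTCAGGT", 5)
  two <- build_dbg(c("ACGTCAGGT", "ACGTCAGGT"), 5)
  expect_identical(two$nodes$kmer, one$nodes$kmer)
  expect_identical(two$edges$kmer, one$edges$kmer)
  expect_identical(two$nodes$count, 2 * one$nodes$count)
  expect_identical(two$edges$count, 2 * one$edges$count)
  rc <- build_dbg(c("ACGTCAGGT", revcomp("ACGTCAGGT")), 5)
  expect_identical(rc$edges$kmer, two$edges$kmer)
  expect_identical(rc$edges$count, two$edges$count)
})

test_that("even k is rejected at graph construction", {
  expect_error(build_dbg("ACGTACGT", 4), "odd")
})

test_that("sparse construction with g = 1 is isomorphic to the dense graph", {
  g <- simulate_genome(3000, 0.5, seed = 2)
  reads <- tiling_reads(g$haplotypes[1L], 60L)
  d <- build_dbg(reads, 21)
  s <- build_sparse_dbg(reads, 21, g = 1L)
  expect_equal(s$n_anchors, nrow(d$nodes))
  expect_true(all(s$anchors$ext %in% c("", s$anchors$ext[nchar(s$anchors$ext) == 1L])))
  lowered <- as_dense_dbg(s)
  expect_identical(sort(lowered$nodes$kmer), d$nodes$kmer)
  expect_identical(sort(lowered$edges$kmer), d$edges$kmer)
})

test_that("sparse and dense graphs spell identical unitig multisets", {
  for (seed in 1:4) {
    reps <- if (seed %% 2 == 0) list(c(2 * 21 + 5, 2)) else list()
    g <- simulate_genome(4000 + seed * 2000L, 0.5, repeats = reps,
                         seed = seed)
    reads <- tiling_reads(g$haplotypes[1L], 60L)
    dense_uni <- extract_unitigs(build_dbg(reads, 21))
    for (gg in c(2L, 4L, 8L)) {
      s <- build_sparse_dbg(reads, 21, gg)
      expect_identical(sort(extract_unitigs(s)$seq), sort(dense_uni$seq))
      # anchor compression: every g-th k-mer plus unitig-boundary corrections
      expect_lte(s$n_anchors,
                 ceiling(nrow(as_dense_dbg(s)$nodes) / gg) +
                   2L * nrow(dense_uni))
    }
  }
})

test_that("a low-coverage spur is clipped while the main path survives", {
  g <- simulate_genome(500, 0.5, seed = 6)
  main <- g$haplotypes[1L]
  reads <- tiling_reads(main, 40L)
  reads <- reads[rep(seq_len(nrow(reads)), 10L)]     # 10x multiplicity
  spur <- substr(main, 101, 125)
  substr(spur, 25, 25) <- setdiff(c("A", "C", "G", "T"),
                                  substr(spur, 25, 25))[1L]
  graph <- build_dbg(c(reads$seq, spur), 21)
  before <- extract_unitigs(graph)
  expect_gt(nrow(before), 1L)
  clipped <- clip_tips(graph, max_tip_len = 42L)
  after <- extract_unitigs(clipped)
  expect_equal(nrow(after), 1L)
  expect_true(after$seq[1L] %in% c(main, revcomp(main)))
})

test_that("graphs without dead ends or with long dead ends are untouched", {
  g <- simulate_genome(400, 0.5, seed = 7)
  lin <- build_dbg(tiling_reads(g$haplotypes[1L], 40L), 21)
  expect_identical(clip_tips(lin, 60L)$edges$kmer, lin$edges$kmer)
  # a dead-end branch longer than max_tip_len is retained
  branch <- paste0(substr(g$haplotypes[1L], 181, 200),
                   simulate_genome(120, 0.5, seed = 8)$haplotypes[1L])
  gb <- build_dbg(c(tiling_reads(g$haplotypes[1L], 40L)$seq, branch), 21)
  kept <- clip_tips(gb, max_tip_len = 50L)
  expect_gt(nrow(extract_unitigs(kept)), 1L)
})

test_that("bubble popping merges close parallel paths by coverage", {
  set.seed(9)
  A <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  B <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  X <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
  Y <- X
  substr(Y, 25, 25) <- setdiff(c("A", "C", "G", "T"), substr(Y, 25, 25))[1L]
  hi <- paste0(A, X, B)
  lo <- paste0(A, Y, B)
  reads <- c(rep(tiling_reads(hi, 40L)$seq, 25L),
             rep(tiling_reads(lo, 40L)$seq, 5L))
  graph <- build_dbg(reads, 21)
  expect_gt(nrow(extract_unitigs(graph)), 1L)
  # a single-SNP bubble at k = 21 spells two (k+1) bp branches differing at
  # one base, i.e. divergence 1/(k+1) ~ 0.045
  popped <- pop_bubbles(graph, max_divergence = 0.05)
  uni <- extract_unitigs(popped)
  expect_equal(nrow(uni), 1L)
  expect_true(uni$seq[1L] %in% c(hi, revcomp(hi)))    # higher coverage wins
  # merged multiplicities: the surviving path gains the loser's coverage,
  # lifting the path mean above the winner's own ~25x
  expect_gt(uni$mean_coverage[1L], 25)
})

test_that("equal-coverage bubbles resolve to the smaller spelled sequence", {
  set.seed(10)
  A <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  B <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  X <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  Y <- X
  substr(Y, 20, 20) <- setdiff(c("A", "C", "G", "T"), substr(Y, 20, 20))[1L]
  reads <- c(tiling_reads(paste0(A, X, B), 35L)$seq,
             tiling_reads(paste0(A, Y, B), 35L)$seq)
  popped <- pop_bubbles(build_dbg(reads, 21), 0.06)
  uni <- extract_unitigs(popped)
  expect_equal(nrow(uni), 1L)
  surv <- if (paste0(A, X, B) <= paste0(A, Y, B)) paste0(A, X, B)
          else paste0(A, Y, B)
  # tie-break is on the spelled branch sequences, equivalent here to the
  # lexicographically smaller full path
  expect_true(uni$seq[1L] %in% c(surv, revcomp(surv)))
})

test_that("divergent parallel paths are both retained", {
  set.seed(12)
  A <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  B <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  X <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  Y <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  reads <- c(tiling_reads(paste0(A, X, B), 35L)$seq,
             tiling_reads(paste0(A, Y, B), 35L)$seq)
  graph <- build_dbg(reads, 21)
  popped <- pop_bubbles(graph, 0.03)
  expect_identical(popped$edges$kmer, graph$edges$kmer)
})

test_that("low-coverage filtering removes error edges, keeps identity at 0", {
  g <- simulate_genome(800, 0.5, seed = 13)
  reads <- rep(tiling_reads(g$haplotypes[1L], 40L)$seq, 5L)
  err <- substr(g$haplotypes[1L], 301, 340)
  substr(err, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                 substr(err, 20, 20))[1L]
  graph <- build_dbg(c(reads, err), 21)
  expect_identical(remove_low_coverage(graph, 0L)$edges$kmer,
                   graph$edges$kmer)
  clean <- remove_low_coverage(graph, 1L)
  expect_lt(nrow(clean$edges), nrow(graph$edges))
  uni <- extract_unitigs(clip_tips(clean))
  expect_equal(nrow(uni), 1L)
  # cutoff at or above the maximum multiplicity empties the graph
  gone <- remove_low_coverage(graph, max(graph$edges$count))
  expect_equal(nrow(gone$edges), 0L)
})

test_that("cleaning operations never grow the graph", {
  for (seed in 1:3) {
    g <- simulate_genome(2000, 0.5, seed = seed)
    reads <- c(tiling_reads(g$haplotypes[1L], 40L)$seq,
               simulate_pe_library(g, pe_library("l", 300, 15, "FR", 1),
                                   50, 5, 0.01, seed = seed)$read1$seq)
    graph <- build_dbg(reads, 21)
    for (op in list(function(x) clip_tips(x),
                    function(x) pop_bubbles(x, 0.03),
                    function(x) remove_low_coverage(x, 1L))) {
      out <- op(graph)
      expect_lte(nrow(out$nodes), nrow(graph$nodes))
      expect_lte(nrow(out$edges), nrow(graph$edges))
    }
  }
})

test_that("a repeat-free genome reconstructs as one exact unitig", {
  g <- simulate_genome(5000, 0.5, seed = 17)
  uni <- extract_unitigs(build_dbg(tiling_reads(g$haplotypes[1L], 60L), 31))
  expect_equal(nrow(uni), 1L)
  expect_true(uni$seq[1L] %in% c(g$haplotypes[1L], revcomp(g$haplotypes[1L])))
})

test_that("an exact repeat longer than k-1 fragments the assembly", {
  g <- simulate_genome(6000, 0.5, repeats = list(c(80, 2)), seed = 18)
  uni <- extract_unitigs(build_dbg(tiling_reads(g$haplotypes[1L], 60L), 31))
  expect_gte(nrow(uni), 3L)
  gg <- paste0(g$haplotypes[1L], "NN", revcomp(g$haplotypes[1L]))
  for (s in uni$seq) expect_true(grepl(s, gg, fixed = TRUE))
})

test_that("assembling reverse-complemented input yields the same unitigs", {
  g <- simulate_genome(3000, 0.5, repeats = list(c(50, 2)), seed = 19)
  reads <- tiling_reads(g$haplotypes[1L], 50L)
  a <- extract_unitigs(build_dbg(reads$seq, 21))
  b <- extract_unitigs(build_dbg(revcomp(reads$seq), 21))
  expect_identical(a$seq, b$seq)
})

test_that("empty graphs extract empty unitig tables", {
  expect_warning(g <- build_dbg(character(), 21))
  expect_equal(nrow(extract_unitigs(g)), 0L)
})

test_that("GFA and unitig FASTA exports are well-formed", {
  g <- simulate_genome(2000, 0.5, seed = 20)
  graph <- build_dbg(tiling_reads(g$haplotypes[1L], 50L), 21)
  p <- tempfile(fileext = ".gfa")
  write_gfa(graph, p)
  lines <- readLines(p)
  expect_equal(lines[1L], "H\tVN:Z:1.0")
  expect_true(any(startsWith(lines, "S\t")))
  fa <- tempfile(fileext = ".fa")
  write_unitigs(extract_unitigs(graph), fa)
  expect_true(grepl("cov=", readLines(fa, n = 1L)))
})
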