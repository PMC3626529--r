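test_that("paired-end links derive gaps from the invariant formula", {
  # contig a: 1000 bp, read1 + at offset 850 -> d_a = 150
  # contig b: 1000 bp, read2 - ending at offset 50+100 -> d_b = 150
  contigs <- data.table::data.table(id = 1:2, length = 1000L)
  placements <- data.table::data.table(
    read_id = c("p1/1", "p1/2"), contig_id = c(1L, 2L),
    offset = c(850L, 50L), strand = c("+", "-"),
    mismatches = 0L, read_len = 100L)
  pairs <- data.table::data.table(pair_id = "p1", read1_id = "p1/1",
                                  read2_id = "p1/2", library = "lib")
  lib <- pe_library("lib", 500, 20, "FR", 1)
  links <- collect_pe_links(placements, pairs, list(lib), contigs)
  expect_equal(nrow(links), 1L)
  expect_equal(links$gap_obs, 500 - 150 - 150)
  expect_equal(links$orient, "++")
})

test_that("same-contig pairs feed insert re-estimation, not links", {
  contigs <- data.table::data.table(id = 1L, length = 2000L)
  placements <- data.table::data.table(
    read_id = c("p1/1", "p1/2", "p2/1"), contig_id = 1L,
    offset = c(200L, 600L, 300L), strand = c("+", "-", "+"),
    mismatches = 0L, read_len = 100L)
  pairs <- data.table::data.table(
    pair_id = c("p1", "p2"), read1_id = c("p1/1", "p2/1"),
    read2_id = c("p1/2", "p2/2"), library = "lib")
  lib <- pe_library("lib", 500, 20, "FR", 1)
  links <- collect_pe_links(placements, pairs, list(lib), contigs)
  expect_equal(nrow(links), 0L)                         # p2 mate unplaced
  expect_equal(attr(links, "insert_obs"), 600 + 100 - 200)
})

test_that("bundling averages concordant gaps and flags weak support", {
  mk <- function(gaps, orient = "++")
    data.table::data.table(contig_a = 1L, contig_b = 2L, orient = orient,
                           gap_obs = gaps, library = "lib", rank = 1L,
                           ins_sd = 20L,
                           read_pair_id = sprintf("p%d", seq_along(gaps)))
  b <- bundle_links(mk(c(190, 200, 210, 205, 195)), 3L)
  expect_equal(b$support, 5L)
  expect_equal(b$gap_mean, 200)
  expect_equal(b$status, "accepted")
  w <- bundle_links(mk(c(100, 120)), 3L)
  expect_equal(w$status, "weak")
  conf <- bundle_links(rbind(mk(c(10, 20, 15, 12)), mk(50, orient = "+-")),
                       3L)
  expect_equal(conf$status[conf$orient == "++"], "accepted")
  expect_equal(conf$support[conf$orient == "++"], 4L)
  expect_equal(conf$status[conf$orient == "+-"], "conflict")
})

test_that("gap outliers beyond 3 library sd are trimmed before averaging", {
  links <- data.table::data.table(
    contig_a = 1L, contig_b = 2L, orient = "++",
    gap_obs = c(200, 210, 190, 205, 800), library = "lib", rank = 1L,
    ins_sd = 20L, read_pair_id = sprintf("p%d", 1:5))
  b <- bundle_links(links, 3L)
  expect_equal(b$support, 4L)
  expect_equal(b$gap_mean, mean(c(200, 210, 190, 205)))
})

test_that("the ten-contig truth layout scaffolds perfectly with gaps in
           tolerance", {
  lay <- make_scaffold_fixture(3)
  fx <- scaffold_fixture_bundles(lay, 700)
  sc <- build_scaffolds(lay$contigs, fx$bundles, fx$libs)
  expect_true(scaffold_matches_truth(sc, lay))
  # every estimated gap within 3 * (lib sd / sqrt(support)) of truth
  one <- sc[sc$scaffold_id == 1L]
  flipped <- !identical(one$contig_id, lay$order)
  truth_gaps <- if (flipped) rev(lay$gaps) else lay$gaps
  for (i in seq_len(9L)) {
    pairkey <- sort(c(one$contig_id[i], one$contig_id[i + 1L]))
    bb <- fx$bundles[fx$bundles$contig_a == pairkey[1L] &
                       fx$bundles$contig_b == pairkey[2L] &
                       fx$bundles$status == "accepted"]
    tol <- max(3 * ifelse(bb$rank == 1L, 20, 300) / sqrt(bb$support))
    expect_lt(abs(one$gap_after[i] - truth_gaps[i]), tol + 1e-9)
  }
})

test_that("a single contig without bundles is a singleton scaffold", {
  contigs <- data.table::data.table(id = 1L, seq = "ACGTACGT", length = 8L)
  b <- bundle_links(data.table::data.table(
    contig_a = integer(), contig_b = integer(), orient = character(),
    gap_obs = numeric(), library = character(), rank = integer(),
    ins_sd = integer(), read_pair_id = character()), 3L)
  sc <- build_scaffolds(contigs, b, list())
  expect_equal(nrow(sc), 1L)
  expect_equal(scaffold_seq(sc, contigs)$seq, "ACGTACGT")
})

test_that("negative gap estimates render as the minimum wildcard run", {
  contigs <- data.table::data.table(id = 1:2,
                                    seq = c(strrep("A", 60), strrep("C", 60)),
                                    length = 60L)
  bundles <- data.table::data.table(
    contig_a = 1L, contig_b = 2L, orient = "++", support = 5L,
    gap_mean = -10, gap_sd = 5, rank = 1L, status = "accepted")
  sc <- build_scaffolds(contigs, bundles, list(), rectify = FALSE)
  expect_equal(sc$gap_after[1L], -10)               # signed estimate kept
  ss <- scaffold_seq(sc, contigs)
  expect_equal(nchar(ss$seq), 60L + 1L + 60L)       # one N wildcard
  expect_equal(sum(strsplit(ss$seq, "")[[1L]] == "N"), 1L)
})

test_that("scaffolds conserve contig content and never duplicate contigs", {
  lay <- make_scaffold_fixture(8)
  fx <- scaffold_fixture_bundles(lay, 900)
  masked <- 4L
  sc <- build_scaffolds(lay$contigs, fx$bundles, fx$libs, masked = masked)
  expect_false(masked %in% sc$contig_id)
  expect_equal(anyDuplicated(sc$contig_id), 0L)
  expect_equal(sort(sc$contig_id), setdiff(1:10, masked))
  lens <- lay$contigs$length[match(sc$contig_id, lay$contigs$id)]
  ss <- scaffold_seq(sc, lay$contigs)
  expect_equal(sum(nchar(gsub("N", "", ss$seq))), sum(lens))
})

test_that("heterozygous pairs are detected by depth and shared topology", {
  g0 <- simulate_genome(24000, 0.5, seed = 21)
  gd <- make_diploid(g0, 0.02, seed = 22, region = c(10000, 13000))
  lib <- pe_library("short", 500, 20, "FR", 1)
  sim <- simulate_pe_library(gd, lib, 100, 40, 0, seed = 23)
  reads <- rbind(sim$read1, sim$read2)
  uni <- assemble_contigs(reads, 31, bubble_divergence = 0)
  pl <- map_reads_to_contigs(reads, uni)
  links <- collect_pe_links(pl, sim$pairs, list(lib), uni)
  b <- bundle_links(links, 3L)
  het <- detect_het_pairs(uni, b, uni$mean_coverage, contig_k = 31L)
  expect_gt(nrow(het), 0L)
  dep <- setNames(uni$mean_coverage, uni$id)
  for (i in seq_len(nrow(het)))
    expect_gte(dep[[as.character(het$kept_id[i])]],
               dep[[as.character(het$dropped_id[i])]])
  # full-depth homozygous contigs are never flagged
  big <- uni$id[uni$length >= 5000L]
  expect_false(any(big %in% c(het$kept_id, het$dropped_id)))
})

test_that("equal-depth allelic pairs keep the smaller contig id", {
  contigs <- data.table::data.table(id = 1:4,
                                    length = c(5000L, 400L, 400L, 5000L))
  bundles <- data.table::data.table(
    contig_a = c(1L, 1L, 2L, 3L), contig_b = c(2L, 3L, 4L, 4L),
    orient = "++", support = 5L, gap_mean = 50, gap_sd = 10, rank = 1L,
    status = "accepted")
  depth <- c(40, 20, 20, 40)
  het <- detect_het_pairs(contigs, bundles, depth)
  expect_equal(het$kept_id, 2L)
  expect_equal(het$dropped_id, 3L)
})

test_that("chimeric junctions are cut only without spanning support", {
  g <- simulate_genome(60000, 0.5, seed = 31)
  starts <- c(0, 5200, 10400, 15600, 38000, 43200, 48400, 53600)
  seqs <- substring(g$haplotypes[1L], starts + 1L, starts + 5000L)
  contigs <- data.table::data.table(id = 1:8, seq = seqs, length = 5000L)
  libs <- list(pe_library("short", 500, 20, "FR", 1),
               pe_library("long", 5000, 300, "FR", 2))
  pe <- lapply(libs, function(L)
    simulate_pe_library(g, L, 100, 20, 0, seed = 131 + L$rank))
  all_reads <- data.table::rbindlist(lapply(pe, function(p)
    rbind(p$read1, p$read2)))
  pl <- map_reads_to_contigs(all_reads, contigs)
  pairs <- data.table::rbindlist(lapply(pe, function(p) p$pairs))
  b <- bundle_links(collect_pe_links(pl, pairs, libs, contigs), 3L)
  # false join 3|6 fuses the two distant regions
  chim <- data.table::data.table(scaffold_id = 1L, part_index = 1:4,
                                 contig_id = c(2L, 3L, 6L, 7L),
                                 orient = "+", gap_after = c(200, 200, 200, NA))
  out <- rectify_chimeras(chim, contigs, b[b$rank == 2L], libs)
  expect_equal(attr(out, "n_cut"), 1L)
  expect_equal(length(unique(out$scaffold_id)), 2L)
  halves <- split(out$contig_id, out$scaffold_id)
  expect_true(all(vapply(halves, function(h)
    all(h %in% c(2L, 3L)) || all(h %in% c(6L, 7L)), TRUE)))
  # without higher-rank bundles nothing changes
  none <- rectify_chimeras(chim, contigs, b[0L], libs)
  expect_identical(none$contig_id, chim$contig_id)
  expect_equal(attr(none, "n_cut"), 0L)
})

test_that("weak links recover through transitive paths or unique dead ends", {
  ctg <- data.table::data.table(id = 1:3, seq = strrep("A", 10),
                                length = c(4000L, 5000L, 4500L))
  sc <- data.table::data.table(scaffold_id = 1:3, part_index = 1L,
                               contig_id = 1:3, orient = "+",
                               gap_after = NA_real_)
  acc <- data.table::data.table(
    contig_a = c(1L, 2L), contig_b = c(2L, 3L), orient = "++",
    support = 5L, gap_mean = c(100, 120), gap_sd = 20, rank = 1L,
    status = "accepted")
  weak <- data.table::data.table(
    contig_a = 1L, contig_b = 3L, orient = "++", support = 2L,
    gap_mean = 100 + 5000 + 120, gap_sd = 40, rank = 1L, status = "weak")
  r <- recover_weak_links(sc, ctg, rbind(acc, weak))
  expect_equal(nrow(r$joins), 1L)
  expect_equal(r$joins$status, "recovered")
  # an isolated weak link between hubs with conflicting candidates: rejected
  weak2 <- data.table::data.table(
    contig_a = c(1L, 1L), contig_b = c(3L, 2L), orient = "++",
    support = 2L, gap_mean = c(150, 170), gap_sd = 40, rank = 1L,
    status = "weak")
  r2 <- recover_weak_links(sc, ctg, weak2)
  expect_equal(nrow(r2$joins), 0L)
  # a weak link duplicating an accepted join is ignored
  scj <- build_scaffolds(ctg, acc, list(), rectify = FALSE)
  dup <- data.table::data.table(
    contig_a = 1L, contig_b = 2L, orient = "++", support = 2L,
    gap_mean = 100, gap_sd = 40, rank = 1L, status = "weak")
  r3 <- recover_weak_links(scj, ctg, rbind(acc, dup))
  expect_equal(nrow(r3$joins), 0L)
})
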