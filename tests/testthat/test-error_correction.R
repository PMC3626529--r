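# synthetic spectrum whose count histogram we control exactly; k-mer
# identities are irrelevant to cutoff selection
fake_spectrum <- function(hist_counts) {
  counts <- rep(as.numeric(names(hist_counts)), times = hist_counts)
  structure(list(k = 21L,
                 kmer = sprintf("K%06d", seq_along(counts)),
                 count = counts, trusted_cutoff = NA_integer_),
            class = "kmer_spectrum")
}

test_that("auto cutoff lands in the valley between error and coverage peaks", {
  h <- c(`1` = 10000L, `2` = 500L, `3` = 40L, `20` = 900L, `21` = 1100L)
  sp <- set_trusted_cutoff(fake_spectrum(h), "auto")
  # brute-force oracle: first argmin of the histogram strictly between the
  # first local maximum and the highest later local maximum
  hh <- integer(21); hh[c(1, 2, 3, 20, 21)] <- c(10000L, 500L, 40L, 900L, 1100L)
  pad <- c(-Inf, hh, -Inf)
  peaks <- which(vapply(seq_along(hh), function(c)
    pad[c + 1] >= pad[c] && pad[c + 1] >= pad[c + 2] && hh[c] > 0, TRUE))
  cov_peak <- peaks[peaks > peaks[1]][which.max(hh[peaks[peaks > peaks[1]]])]
  between <- (peaks[1] + 1):(cov_peak - 1)
  oracle <- between[which.min(hh[between])]
  expect_equal(sp$trusted_cutoff, oracle)
  expect_gte(sp$trusted_cutoff, 1L)
})

test_that("fixed cutoff and degenerate-histogram fallbacks", {
  sp <- set_trusted_cutoff(fake_spectrum(c(`1` = 10L)), "fixed",
                           fixed_value = 3)
  expect_equal(sp$trusted_cutoff, 3L)
  empty <- structure(list(k = 21L, kmer = character(), count = numeric(),
                          trusted_cutoff = NA_integer_),
                     class = "kmer_spectrum")
  expect_error(set_trusted_cutoff(empty, "auto"), "non-empty")
  expect_warning(uni <- set_trusted_cutoff(
    fake_spectrum(c(`1` = 100L, `2` = 50L, `3` = 10L)), "auto"))
  expect_equal(uni$trusted_cutoff, 2L)
})

# small truth-known corrector fixture: error-free tiling coverage plus reads
# with planted substitutions
corrector_fixture <- function(genome_len = 6000L, k = 21L, seed = 5L) {
  g <- simulate_genome(genome_len, 0.5, seed = seed)
  reads <- tiling_reads(g$haplotypes[1L], 100L)
  reads <- reads[seq(1L, nrow(reads), by = 3L)]   # ~33x coverage
  sp <- set_trusted_cutoff(count_kmers(reads, k), "fixed", fixed_value = 3)
  list(genome = g, reads = reads, spectrum = sp)
}

test_that("fast mode repairs a single planted substitution exactly", {
  fx <- corrector_fixture()
  true_seq <- fx$reads$seq[100L]
  bad <- true_seq
  old <- substr(bad, 51, 51)
  new <- setdiff(c("A", "C", "G", "T"), old)[1L]
  substr(bad, 51, 51) <- new
  res <- correct_read_fast(bad, fx$spectrum)
  expect_equal(res$status, "corrected")
  expect_equal(res$seq, true_seq)
  expect_equal(res$edits$position, 50L)            # 0-based
  expect_equal(res$edits$old_base, new)
  expect_equal(res$edits$new_base, old)
  expect_lt(res$n_untrusted_after, res$n_untrusted_before)
})

test_that("a fully trusted read is returned unchanged", {
  fx <- corrector_fixture()
  res <- correct_read_fast(fx$reads$seq[20L], fx$spectrum)
  expect_equal(res$status, "unchanged")
  expect_equal(nrow(res$edits), 0L)
})

test_that("more isolated errors than max_edits yields uncorrectable", {
  fx <- corrector_fixture()
  bad <- fx$reads$seq[50L]
  for (p in c(10L, 50L, 90L)) {
    old <- substr(bad, p, p)
    substr(bad, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1L]
  }
  res <- correct_read_fast(bad, fx$spectrum, max_edits = 2L)
  expect_equal(res$status, "uncorrectable")
  expect_equal(res$seq, bad)  # reverted, not half-fixed
})

test_that("deep mode repairs two errors closer than k where fast cannot", {
  fx <- corrector_fixture()
  true_seq <- fx$reads$seq[70L]
  bad <- true_seq
  for (p in c(48L, 53L)) {    # 5 bp apart, within one k window
    old <- substr(bad, p, p)
    substr(bad, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1L]
  }
  fast <- correct_read_fast(bad, fx$spectrum)
  expect_true(fast$status %in% c("uncorrectable", "ambiguous"))
  deep <- correct_read_deep(bad, fx$spectrum, budget = 200L)
  expect_equal(deep$status, "corrected")
  expect_equal(deep$seq, true_seq)
  expect_equal(sort(deep$edits$position), c(47L, 52L))
})

test_that("deep mode with an exhausted branch budget is uncorrectable", {
  fx <- corrector_fixture()
  bad <- fx$reads$seq[70L]
  # plant at a position whose true base is T, observed A: the first explored
  # branch (C) fails and exhausts a budget of 1
  p <- which(strsplit(substr(bad, 40, 60), "")[[1L]] == "T")[1L] + 39L
  substr(bad, p, p) <- "A"
  res <- correct_read_deep(bad, fx$spectrum, budget = 1L)
  expect_true(res$status %in% c("uncorrectable", "ambiguous"))
  full <- correct_read_deep(bad, fx$spectrum, budget = 64L)
  expect_equal(full$status, "corrected")
})

test_that("an exact two-copy repeat differing at one site ties deep mode", {
  # genome: two identical repeat copies except one middle base; a read fully
  # inside copy 1 carrying a third base at that site can be repaired toward
  # either copy with identical window-count scores
  set.seed(13)
  core <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  copy1 <- core; substr(copy1, 60, 60) <- "A"
  copy2 <- core; substr(copy2, 60, 60) <- "C"
  flankL <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  flankM <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  flankR <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  genome <- paste0(flankL, copy1, flankM, copy2, flankR)
  reads <- tiling_reads(genome, 40L)
  sp <- set_trusted_cutoff(count_kmers(reads, 15L), "fixed", fixed_value = 2)
  read <- substr(genome, 101, 140)        # inside copy 1, covers site 60
  site <- 80 + 60 - 100                   # 1-based position within the read
  expect_equal(substr(read, site, site), "A")
  substr(read, site, site) <- "G"         # a third allele: true base ambiguous
  res <- correct_read_deep(read, sp, budget = 500L)
  expect_equal(res$status, "ambiguous")
  expect_equal(res$seq, read)
  # exhaustive verification of the tie: both candidate repairs clear every
  # window and score identically
  score <- function(b) {
    cand <- read; substr(cand, site, site) <- b
    w <- vapply(1:(nchar(cand) - 14L), function(i)
      spectrum_count(sp, substr(cand, i, i + 14L)), 0)
    if (any(w < sp$trusted_cutoff)) return(NA_real_)
    sum(w)
  }
  expect_equal(score("A"), score("C"))
  expect_false(is.na(score("A")))
})

test_that("library correction restores planted errors and never touches
           clean reads", {
  g <- simulate_genome(20000, 0.5, seed = 11)
  lib <- pe_library("l", 400, 20, "FR", 1)
  sim <- simulate_pe_library(g, lib, 100, 35, 0.005, seed = 12)
  reads <- rbind(sim$read1, sim$read2)
  sp <- set_trusted_cutoff(count_kmers(reads, 21), "auto")
  res <- correct_library(reads, sp, mode = "fast_then_deep")
  expect_equal(nrow(res$reads), nrow(reads))           # order and count kept
  expect_identical(res$reads$id, reads$id)
  expect_true(all(nchar(res$reads$seq) == nchar(reads$seq)))  # substitution-only

  err_reads <- unique(sim$errors$read_id)
  clean <- !reads$id %in% err_reads
  expect_identical(res$reads$seq[clean], reads$seq[clean])    # no false edits

  one_err <- names(which(table(sim$errors$read_id) == 1L))
  restored <- vapply(one_err, function(id) {
    tr <- sim$truth[sim$truth$read_id == id]
    res$reads$seq[match(id, res$reads$id)] == true_read_seq(g, tr, 100)
  }, TRUE)
  expect_gte(mean(restored), 0.95)

  fast <- correct_library(reads, sp, mode = "fast")
  expect_gte(res$summary[["corrected"]], fast$summary[["corrected"]])
})

test_that("error-free input leaves every read unchanged under auto cutoff", {
  g <- simulate_genome(15000, 0.5, seed = 14)
  lib <- pe_library("l", 400, 20, "FR", 1)
  sim <- simulate_pe_library(g, lib, 100, 35, 0, seed = 15)
  reads <- rbind(sim$read1, sim$read2)
  sp <- set_trusted_cutoff(count_kmers(reads, 21), "auto")
  res <- correct_library(reads, sp, mode = "fast_then_deep")
  expect_equal(res$summary[["corrected"]], 0L)
  expect_identical(res$reads$seq, reads$seq)
})

test_that("spaced-spectrum corroboration can veto corrections", {
  fx <- corrector_fixture()
  bad <- fx$reads$seq[30L]
  old <- substr(bad, 50, 50)
  substr(bad, 50, 50) <- setdiff(c("A", "C", "G", "T"), old)[1L]
  pat <- spaced_pattern(11L, 4L, 2L)
  ssp <- count_spaced_kmers(fx$reads, pat)
  ssp <- set_trusted_cutoff(ssp, "fixed", fixed_value = 3)
  ok <- correct_library(data.table::data.table(id = "r", seq = bad),
                        fx$spectrum, mode = "fast", spaced_spectrum = ssp)
  expect_equal(unname(ok$summary[["corrected"]]), 1L)
  # an absurd spaced cutoff rejects every corroboration
  ssp$trusted_cutoff <- 10000L
  veto <- correct_library(data.table::data.table(id = "r", seq = bad),
                          fx$spectrum, mode = "fast", spaced_spectrum = ssp)
  expect_equal(unname(veto$summary[["uncorrectable"]]), 1L)
  expect_identical(veto$reads$seq, bad)
})
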