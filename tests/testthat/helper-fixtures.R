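# Shared fixtures, all generated in code under fixed seeds.

# deterministic error-free tiling reads (every substring of length rl,
# stride 1): uniform coverage with no sampling holes
tiling_reads <- function(genome_seq, rl = 50L) {
  L <- nchar(genome_seq)
  starts <- 1:(L - rl + 1L)
  data.table::data.table(id = sprintf("t%05d", starts),
                         seq = substring(genome_seq, starts, starts + rl - 1L))
}

# a 10-contig truth layout cut from one genome, with shuffled ids and
# random stored orientations; gaps 60-250 bp so the short-insert library
# spans every junction
make_scaffold_fixture <- function(seed, genome_len = 42000L) {
  g <- simulate_genome(genome_len, 0.5, seed = seed)
  set.seed(seed + 999L)
  gaps <- sample(60:250, 9, replace = TRUE)
  lens <- sample(2000:3600, 10, replace = TRUE)
  stopifnot(sum(lens) + sum(gaps) <= genome_len)
  starts <- cumsum(c(0L, head(lens, -1L) + gaps))
  seqs <- substring(g$haplotypes[1L], starts + 1L, starts + lens)
  ori <- sample(c("+", "-"), 10, replace = TRUE)
  stored <- ifelse(ori == "-", revcomp(seqs), seqs)
  perm <- sample(10)
  contigs <- data.table::data.table(id = 1:10, seq = stored[perm],
                                    length = nchar(stored[perm]))
  list(genome = g, contigs = contigs,
       order = match(1:10, perm),      # contig ids in genome order
       ori = ori[perm],                # stored orientation relative to genome
       gaps = gaps, starts = starts, lens = lens)
}

# simulate both libraries of the scaffolding fixture and bundle the links
scaffold_fixture_bundles <- function(lay, seed, cov_short = 20, cov_long = 15) {
  libs <- list(pe_library("short", 500, 20, "FR", 1),
               pe_library("long", 5000, 300, "FR", 2))
  pe <- lapply(libs, function(L)
    simulate_pe_library(lay$genome, L, 100,
                        if (L$rank == 1L) cov_short else cov_long, 0,
                        seed = seed + L$rank))
  all_reads <- data.table::rbindlist(lapply(pe, function(p)
    rbind(p$read1, p$read2)))
  pl <- map_reads_to_contigs(all_reads, lay$contigs)
  pairs <- data.table::rbindlist(lapply(pe, function(p) p$pairs))
  links <- collect_pe_links(pl, pairs, libs, lay$contigs)
  list(libs = libs, pe = pe, links = links,
       bundles = bundle_links(links, 3L))
}

# does the scaffold part table reproduce the truth layout (up to whole
# scaffold reversal)?
scaffold_matches_truth <- function(sc, lay) {
  one <- sc[sc$scaffold_id == 1L]
  if (nrow(one) != 10L) return(FALSE)
  got <- one$contig_id
  fwd <- identical(got, lay$order)
  rev_ <- identical(got, rev(lay$order))
  if (!fwd && !rev_) return(FALSE)
  # orientation: contig stored "-" relative to genome must appear flipped
  truth_ori <- lay$ori[match(got, seq_len(10))]
  expect_ori <- if (fwd) ifelse(truth_ori == "-", "-", "+")
                else ifelse(truth_ori == "-", "+", "-")
  identical(one$orient, expect_ori)
}
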