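.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.sample_bases <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a truth-known genome
#'
#' Background bases are i.i.d. with the requested GC content; each repeat
#' family is generated once and planted at uniformly chosen non-overlapping
#' positions, so repeat copies are exact by construction. Identical seeds
#' yield identical bytes.
#'
#' @param length genome length in bp.
#' @param gc GC fraction (default 0.5).
#' @param repeats list of `c(copy_len, n_copies)` repeat families; their
#'   total planted length must stay below half the genome.
#' @param seed integer seed.
#' @return an object of class `genome_truth`: `haplotypes` (character
#'   vector of 1), `repeat_annotations` (data.table `start`, `end` 0-based
#'   half-open, `family`, `copy`), `variant_positions` (empty), `seed`.
#' @export
simulate_genome <- function(length, gc = 0.5, repeats = list(), seed = 1L) {
  total_rep <- sum(vapply(repeats, function(r) r[1L] * r[2L], 0))
  if (total_rep >= length / 2)
    stop("total repeat length must be below half the genome length")
  .with_seed(seed, {
    g <- .sample_bases(length, gc)
    ann <- list()
    occupied <- integer(0)
    for (fi in seq_along(repeats)) {
      cl <- repeats[[fi]][1L]; nc <- repeats[[fi]][2L]
      fam <- .sample_bases(cl, gc)
      for (ci in seq_len(nc)) {
        placed <- FALSE
        for (try in seq_len(1000L)) {
          s <- sample.int(length - cl + 1L, 1L) - 1L
          span <- s:(s + cl - 1L)
          if (!any(span %in% occupied)) {
            substr(g, s + 1L, s + cl) <- fam
            occupied <- c(occupied, span)
            ann[[base::length(ann) + 1L]] <- data.table(
              start = s, end = s + cl, family = fi, copy = ci)
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("could not place repeat copy without overlap")
      }
    }
    ann <- if (base::length(ann)) rbindlist(ann)
           else data.table(start = integer(), end = integer(),
                           family = integer(), copy = integer())
    structure(list(haplotypes = g, repeat_annotations = ann,
                   variant_positions = data.table(pos = integer(),
                                                  ref_base = character(),
                                                  alt_base = character()),
                   seed = seed),
              class = "genome_truth")
  })
}

#' @export
print.genome_truth <- function(x, ...) {
  cat(sprintf("<genome_truth: %d haplotype(s) of %d bp, %d repeat copies, %d variants>\n",
              length(x$haplotypes), nchar(x$haplotypes[1L]),
              nrow(x$repeat_annotations), nrow(x$variant_positions)))
  invisible(x)
}

#' Derive a diploid genome by planting heterozygous substitutions
#'
#' The second haplotype is a copy of the first with i.i.d. substitutions at
#' rate `het_rate`; every variant is recorded.
#'
#' @param genome a haploid `genome_truth`.
#' @param het_rate per-base substitution probability between haplotypes.
#' @param seed integer seed.
#' @param region optional `c(start, end)` (0-based half-open) restricting
#'   heterozygosity to one interval, emulating a locally divergent region in
#'   an otherwise homozygous genome.
#' @return the `genome_truth` with two haplotypes and `variant_positions`
#'   filled (`pos` 0-based, `ref_base`, `alt_base`).
#' @export
make_diploid <- function(genome, het_rate, seed = 1L, region = NULL) {
  stopifnot(inherits(genome, "genome_truth"),
            length(genome$haplotypes) == 1L)
  h1 <- genome$haplotypes[1L]
  L <- nchar(h1)
  .with_seed(seed, {
    pos <- which(runif(L) < het_rate)
    if (!is.null(region))
      pos <- pos[pos > region[1L] & pos <= region[2L]]
    h2 <- h1
    vars <- data.table(pos = integer(), ref_base = character(),
                       alt_base = character())
    if (length(pos)) {
      ref <- substring(h1, pos, pos)
      alt <- vapply(ref, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L),
        USE.NAMES = FALSE)
      for (i in seq_along(pos)) substr(h2, pos[i], pos[i]) <- alt[i]
      vars <- data.table(pos = pos - 1L, ref_base = ref, alt_base = alt)
    }
    genome$haplotypes <- c(h1, h2)
    genome$variant_positions <- vars
    genome
  })
}

#' Simulate a paired-end read library
#'
#' Fragment lengths are normal with the library's mean and sd, truncated to
#' `[2 * read_len, 2 * avg_ins]`; fragment start positions are uniform over
#' the genome, except that the first and last fragment of each haplotype
#' are pinned to the genome ends so terminal bases are always sampled (a
#' finite-genome edge correction, documented in the methods vignette).
#' Fragments come from either genomic strand with equal probability. FR
#' libraries read inward from the fragment ends; RF libraries read outward.
#' Substitution errors are i.i.d. per base at `error_rate`; full per-read
#' truth is emitted.
#'
#' @param genome a `genome_truth` (diploid genomes are sampled equally).
#' @param library a [pe_library()].
#' @param read_len read length in bp (default 100).
#' @param coverage total fold coverage; the pair count is
#'   `round(coverage * genome_len / (2 * read_len))`.
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return a list: `read1`/`read2` (data.tables `id`, `seq`), `truth`
#'   (per-read: `read_id`, `haplotype` 0/1, `true_start`, `strand`,
#'   `mate`), `errors` (`read_id`, `read_pos` 0-based, `true_base`,
#'   `observed_base`), `pairs` (`pair_id`, `read1_id`, `read2_id`,
#'   `library`), `library` (the name).
#' @export
simulate_pe_library <- function(genome, library, read_len = 100L,
                                coverage = 40, error_rate = 0, seed = 1L) {
  stopifnot(inherits(genome, "genome_truth"), inherits(library, "pe_library"))
  haps <- genome$haplotypes
  L <- nchar(haps[1L])
  n_pairs <- round(coverage * L / (2 * read_len))
  stopifnot(n_pairs >= 2L)
  .with_seed(seed, {
    hap <- if (length(haps) == 2L) sample(c(0L, 1L), n_pairs, replace = TRUE)
           else rep(0L, n_pairs)
    frag <- pmin(pmax(round(rnorm(n_pairs, library$avg_ins, library$ins_sd)),
                      2L * read_len), 2L * library$avg_ins)
    frag <- pmin(frag, L)
    start <- vapply(frag, function(f) sample.int(L - f + 1L, 1L) - 1L, 0L)
    # pin two fragments per haplotype to each genome end so terminal bases
    # are sampled at depth >= 2 rather than tailing off to zero
    for (h in unique(hap)) {
      idx <- which(hap == h)
      if (length(idx) >= 4L) {
        start[idx[1:2]] <- 0L
        n <- length(idx)
        start[idx[(n - 1L):n]] <- L - frag[idx[(n - 1L):n]]
      } else {
        start[idx[1L]] <- 0L
        start[idx[length(idx)]] <- L - frag[idx[length(idx)]]
      }
    }
    flip <- runif(n_pairs) < 0.5
    ids <- sprintf("%s_p%06d", library$name, seq_len(n_pairs))
    frag_seq <- substring(haps[hap + 1L], start + 1L, start + frag)
    frag_seq[flip] <- revcomp(frag_seq[flip])
    if (library$orientation == "FR") {
      r1 <- substring(frag_seq, 1L, read_len)
      r2 <- revcomp(substring(frag_seq, frag - read_len + 1L, frag))
    } else {
      r1 <- revcomp(substring(frag_seq, 1L, read_len))
      r2 <- substring(frag_seq, frag - read_len + 1L, frag)
    }
    # truth coordinates on the stored (plus) haplotype strand
    st1 <- ifelse(flip, "-", "+")
    st2 <- ifelse(flip, "+", "-")
    start1 <- ifelse(flip, start + frag - read_len, start)
    start2 <- ifelse(flip, start, start + frag - read_len)
    if (library$orientation == "RF") {
      st1 <- ifelse(st1 == "+", "-", "+")
      st2 <- ifelse(st2 == "+", "-", "+")
    }
    id1 <- paste0(ids, "/1"); id2 <- paste0(ids, "/2")
    errors <- data.table(read_id = character(), read_pos = integer(),
                         true_base = character(), observed_base = character())
    if (error_rate > 0) {
      e1 <- .plant_errors_vec(r1, error_rate, id1)
      e2 <- .plant_errors_vec(r2, error_rate, id2)
      r1 <- e1$seqs; r2 <- e2$seqs
      errors <- rbind(e1$err, e2$err)
    }
    truth <- data.table(
      read_id = c(id1, id2), haplotype = c(hap, hap),
      true_start = c(start1, start2), strand = c(st1, st2),
      mate = c(id2, id1))
    list(read1 = data.table(id = id1, seq = r1),
         read2 = data.table(id = id2, seq = r2),
         truth = truth, errors = errors,
         pairs = data.table(pair_id = ids, read1_id = id1, read2_id = id2,
                            library = library$name),
         library = library$name)
  })
}

.plant_errors_vec <- function(seqs, rate, ids) {
  L <- nchar(seqs[1L])
  n <- length(seqs)
  hit <- which(runif(n * L) < rate)
  err <- data.table(read_id = character(), read_pos = integer(),
                    true_base = character(), observed_base = character())
  if (!length(hit)) return(list(seqs = seqs, err = err))
  ri <- (hit - 1L) %/% L + 1L
  p <- (hit - 1L) %% L + 1L
  tb <- substring(seqs[ri], p, p)
  bases <- c("A", "C", "G", "T")
  ob <- vapply(tb, function(b) sample(setdiff(bases, b), 1L), character(1L),
               USE.NAMES = FALSE)
  for (j in seq_along(hit)) substr(seqs[ri[j]], p[j], p[j]) <- ob[j]
  err <- data.table(read_id = ids[ri], read_pos = p - 1L,
                    true_base = tb, observed_base = ob)
  list(seqs = seqs, err = err)
}

#' Reconstruct the true read sequence from truth records
#'
#' Reverses planted errors and extracts `(haplotype, true_start, strand)`;
#' the result must equal the genomic substring exactly (round-trip
#' identity used by the test-suite).
#'
#' @param genome the `genome_truth` the reads were simulated from.
#' @param truth one row of the simulation `truth` table.
#' @param read_len read length.
#' @return the true read sequence.
#' @export
true_read_seq <- function(genome, truth, read_len) {
  g <- genome$haplotypes[truth$haplotype + 1L]
  s <- substr(g, truth$true_start + 1L, truth$true_start + read_len)
  if (truth$strand == "-") s <- revcomp(s)
  s
}
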