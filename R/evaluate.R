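#' Assembly length statistics (N50 / NG50)
#'
#' `n50` is the largest length L such that sequences of length >= L sum to
#' at least half the assembly; `ng50` uses half the known genome size
#' instead and is `NA` when unreachable.
#'
#' @param lengths positive sequence lengths.
#' @param genome_size optional known genome size for NG50.
#' @return an object of class `assembly_stats`: `n_seqs`, `total_len`,
#'   `n50`, `ng50`, `largest`.
#' @export
n50_stats <- function(lengths, genome_size = NULL) {
  if (length(lengths) == 0L) stop("lengths must be non-empty")
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(s))
  total <- cum[length(cum)]
  n50 <- s[which(cum >= total / 2)[1L]]
  ng50 <- NA_real_
  if (!is.null(genome_size)) {
    hit <- which(cum >= genome_size / 2)
    if (length(hit)) ng50 <- s[hit[1L]]
  }
  structure(list(n_seqs = length(lengths), total_len = total,
                 n50 = n50, ng50 = ng50, largest = s[1L]),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("<assembly_stats: %d seqs, total %.0f bp, N50 %.0f, largest %.0f%s>\n",
              x$n_seqs, x$total_len, x$n50, x$largest,
              if (is.na(x$ng50)) "" else sprintf(", NG50 %.0f", x$ng50)))
  invisible(x)
}

.ref_seq <- function(reference) {
  if (inherits(reference, "genome_truth")) reference$haplotypes[1L]
  else as.character(reference)[1L]
}

#' Reference coverage by seeded exact-match chaining
#'
#' Each assembled sequence is aligned to the reference by exact 31-mer
#' seeding with maximal ungapped extension (both strands); coverage is the
#' fraction of reference positions covered by at least one aligned block of
#' `min_block` bp or more. A full aligner is deliberately not used: exact
#' chaining is adequate for the near-identical toy genomes this evaluator
#' targets.
#'
#' @param assembly character vector of sequences, or a data.table with
#'   `seq` (e.g. unitigs or rendered scaffolds).
#' @param reference a `genome_truth` or a single reference sequence.
#' @param min_block minimum counted block length (default 100 bp).
#' @param max_insert separation beyond which adjacent blocks of one
#'   sequence count as a structural breakpoint (default 1000 bp; see
#'   [count_structural_errors()]).
#' @return a list: `reference_coverage` (fraction), `structural_errors`
#'   (breakpoint count), `blocks` (per-sequence block matrices).
#' @export
reference_coverage <- function(assembly, reference, min_block = 100L,
                               max_insert = 1000L) {
  seqs <- if (is.data.frame(assembly)) assembly$seq else as.character(assembly)
  ref <- .ref_seq(reference)
  RL <- nchar(ref)
  if (length(seqs) == 0L)
    return(list(reference_coverage = 0, structural_errors = 0L,
                blocks = list()))
  blocks <- align_blocks_cpp(seqs, ref, 31L)
  covered <- logical(RL)
  n_err <- 0L
  for (bm in blocks) {
    if (nrow(bm) == 0L) next
    big <- bm[bm[, "q_end"] - bm[, "q_start"] >= min_block, , drop = FALSE]
    for (i in seq_len(nrow(big)))
      covered[(big[i, "r_start"] + 1L):big[i, "r_end"]] <- TRUE
    if (nrow(big) >= 2L) {
      ord <- order(big[, "q_start"])
      big <- big[ord, , drop = FALSE]
      for (i in seq_len(nrow(big) - 1L)) {
        a <- big[i, ]; b <- big[i + 1L, ]
        if (a["strand"] != b["strand"]) { n_err <- n_err + 1L; next }
        qgap <- b["q_start"] - a["q_end"]
        rgap <- if (a["strand"] == 1L) b["r_start"] - a["r_end"]
                else a["r_start"] - b["r_end"]
        if (abs(rgap - qgap) > 2L * max_insert) n_err <- n_err + 1L
      }
    }
  }
  list(reference_coverage = sum(covered) / RL, structural_errors = n_err,
       blocks = blocks)
}

#' Count structural errors against a reference
#'
#' Operational definition: for every assembled sequence, aligned blocks
#' (exact-match chains of at least `min_block` bp) are ordered along the
#' sequence, and each adjacent pair that is non-collinear — an orientation
#' flip, or reference loci farther apart than twice the maximum insert
#' size relative to their query spacing — counts as one structural error
#' junction.
#'
#' @inheritParams reference_coverage
#' @return integer breakpoint count.
#' @export
count_structural_errors <- function(assembly, reference, min_block = 100L,
                                    max_insert = 1000L) {
  reference_coverage(assembly, reference, min_block, max_insert)$structural_errors
}
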