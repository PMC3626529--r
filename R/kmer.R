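#' Reverse complement
#'
#' @param seq character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) revcomp_cpp(as.character(seq))

#' Canonical k-mer
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' k-mer and its reverse complement — the standard strand-collapsing
#' convention for de Bruijn graphs. K-mers containing `N` (or any non-ACGT
#' character) are rejected and returned as `NA`, which callers must skip.
#'
#' @param seq character vector of k-mers.
#' @return character vector of canonical k-mers (`NA` where rejected).
#' @export
canonical_kmer <- function(seq) canonical_cpp(as.character(seq))

#' Enumerate k-mer windows of a sequence
#'
#' One entry per position `0 .. nchar(seq) - k` whose window contains no `N`;
#' offsets are 0-based and strictly increasing. K-mers are reported as they
#' occur (not canonicalized).
#'
#' @param seq a single sequence.
#' @param k window size, `>= 3`.
#' @return a [data.table::data.table] with columns `offset` and `kmer`.
#' @export
kmerize <- function(seq, k) {
  stopifnot(length(seq) == 1L, k >= 3L)
  L <- nchar(seq)
  if (L < k) return(data.table(offset = integer(), kmer = character()))
  off <- 0:(L - k)
  km <- substring(seq, off + 1L, off + k)
  ok <- !grepl("N", km, fixed = TRUE)
  data.table(offset = off[ok], kmer = km[ok])
}

#' Count canonical k-mers over a read stream
#'
#' Builds a strand-canonical k-mer spectrum: querying a k-mer and its reverse
#' complement returns the same count. The result is deterministic and
#' invariant to the order of the input reads. The trusted/untrusted cutoff is
#' unset (`NA`) until [set_trusted_cutoff()] is applied.
#'
#' @param reads character vector of sequences, or a data.table with a `seq`
#'   column as returned by [read_sequences()].
#' @param k k-mer size, `>= 3`. Odd k is the norm (it rules out
#'   self-reverse-complement k-mers); even k is accepted here but rejected at
#'   graph construction.
#' @return an object of class `kmer_spectrum`: fields `k`, `kmer` (sorted
#'   canonical k-mers), `count`, `trusted_cutoff`.
#' @export
count_kmers <- function(reads, k) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  stopifnot(k >= 3L)
  if (length(seqs) && k > max(nchar(seqs))) {
    warning("k exceeds the maximum read length; spectrum is empty")
    seqs <- character()
  }
  res <- count_kmers_cpp(seqs, as.integer(k))
  structure(list(k = as.integer(k), kmer = res$kmer, count = res$count,
                 trusted_cutoff = NA_integer_),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("<kmer_spectrum k=%d: %d distinct k-mers, cutoff=%s>\n",
              x$k, length(x$kmer),
              if (is.na(x$trusted_cutoff)) "unset" else x$trusted_cutoff))
  invisible(x)
}

#' Query counts in a spectrum
#'
#' @param spectrum a `kmer_spectrum`.
#' @param kmers character vector of k-mers (any strand).
#' @return numeric vector of counts (0 where absent or containing `N`).
#' @export
spectrum_count <- function(spectrum, kmers) {
  ck <- canonical_cpp(as.character(kmers))
  idx <- match(ck, spectrum$kmer)
  out <- spectrum$count[idx]
  out[is.na(out)] <- 0
  out
}

#' Dump a spectrum as a two-column TSV
#'
#' @param spectrum a `kmer_spectrum`.
#' @param path output file.
#' @export
write_spectrum <- function(spectrum, path) {
  write.table(data.frame(kmer = spectrum$kmer, count = spectrum$count),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Spaced (gapped) k-mer pattern
#'
#' A pattern of `n_blocks` matched blocks of `block` consecutive positions,
#' separated by `skip` ignored positions. The total span on the sequence is
#' `n_blocks * block + (n_blocks - 1) * skip`; the extracted string has
#' length `n_blocks * block`. Used as an optional corroboration scheme in
#' error correction alongside consecutive k-mers.
#'
#' @param block matched positions per block, `>= 1`.
#' @param skip ignored positions between blocks, `>= 1` (0 is allowed and
#'   degenerates to a consecutive k-mer).
#' @param n_blocks number of blocks, `>= 2`.
#' @return an object of class `spaced_pattern` with a `span` field.
#' @export
spaced_pattern <- function(block, skip, n_blocks = 2L) {
  stopifnot(block >= 1L, skip >= 0L, n_blocks >= 2L)
  structure(list(block = as.integer(block), skip = as.integer(skip),
                 n_blocks = as.integer(n_blocks),
                 span = as.integer(n_blocks * block + (n_blocks - 1L) * skip)),
            class = "spaced_pattern")
}

#' Extract a spaced k-mer
#'
#' Concatenates the matched blocks of `pattern` starting at `offset`
#' (0-based), skipping `skip` bases between blocks.
#'
#' @param seq a single sequence.
#' @param offset 0-based start of the pattern span.
#' @param pattern a [spaced_pattern()].
#' @return the extracted string of length `n_blocks * block`, or `NA` when
#'   the span exceeds the sequence or a matched position is `N`.
#' @export
spaced_kmer <- function(seq, offset, pattern) {
  stopifnot(inherits(pattern, "spaced_pattern"), length(seq) == 1L)
  if (offset < 0L || offset + pattern$span > nchar(seq)) return(NA_character_)
  starts <- offset + (0:(pattern$n_blocks - 1L)) * (pattern$block + pattern$skip)
  parts <- substring(seq, starts + 1L, starts + pattern$block)
  out <- paste(parts, collapse = "")
  if (grepl("[^ACGT]", out)) return(NA_character_)
  out
}

#' Spaced-position coverage of a base
#'
#' All pattern offsets whose matched positions include base position `p`
#' (0-based) of a sequence of length `L`.
#'
#' @keywords internal
spaced_offsets_covering <- function(p, L, pattern) {
  offs <- 0:max(0L, L - pattern$span)
  offs <- offs[offs + pattern$span <= L]
  keep <- vapply(offs, function(o) {
    starts <- o + (0:(pattern$n_blocks - 1L)) * (pattern$block + pattern$skip)
    any(p >= starts & p < starts + pattern$block)
  }, logical(1L))
  offs[keep]
}

#' Count spaced k-mers over reads
#'
#' Canonical counting of the spaced extraction at every valid offset.
#'
#' @inheritParams count_kmers
#' @param pattern a [spaced_pattern()].
#' @return a `kmer_spectrum` whose `k` is the extracted length
#'   (`n_blocks * block`) and which carries the pattern as attribute.
#' @export
count_spaced_kmers <- function(reads, pattern) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  ext <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < pattern$span) return(character())
    offs <- 0:(L - pattern$span)
    v <- vapply(offs, function(o) {
      x <- spaced_kmer(s, o, pattern)
      if (is.na(x)) "" else x
    }, character(1L))
    v[nzchar(v)]
  }))
  k <- pattern$n_blocks * pattern$block
  res <- count_kmers_cpp(ext, as.integer(k))
  sp <- structure(list(k = as.integer(k), kmer = res$kmer, count = res$count,
                       trusted_cutoff = NA_integer_),
                  class = "kmer_spectrum")
  attr(sp, "pattern") <- pattern
  sp
}
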