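#' Set the trusted/untrusted count cutoff of a spectrum
#'
#' In `auto` mode the cutoff is placed at the first local minimum of the
#' count histogram between the error peak (the low-count mode produced by
#' sequencing errors) and the coverage peak (the mode at the sequencing
#' depth). K-mers with count at or above the cutoff are trusted. On a
#' unimodal histogram (no valley) the cutoff falls back to 2 with a warning.
#'
#' @param spectrum a `kmer_spectrum` from [count_kmers()].
#' @param mode `"auto"` or `"fixed"`.
#' @param fixed_value cutoff to use in fixed mode, `>= 1`.
#' @return the spectrum with `trusted_cutoff` set.
#' @export
set_trusted_cutoff <- function(spectrum, mode = c("auto", "fixed"),
                               fixed_value = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    stopifnot(!is.null(fixed_value), fixed_value >= 1)
    spectrum$trusted_cutoff <- as.integer(fixed_value)
    return(spectrum)
  }
  if (length(spectrum$kmer) == 0L)
    stop("auto cutoff requires a non-empty spectrum")
  cmax <- max(spectrum$count)
  h <- tabulate(spectrum$count, nbins = cmax)  # h[c] = #distinct k-mers with count c
  spectrum$trusted_cutoff <- .auto_cutoff(h)
  spectrum
}

# valley search on the count histogram; exported logic kept in one place so
# the brute-force oracle in the tests can target exactly this contract
.auto_cutoff <- function(h) {
  n <- length(h)
  if (n < 3L) { warning("count histogram too narrow; cutoff = 2"); return(2L) }
  hp <- c(-Inf, h, -Inf)
  is_peak <- vapply(seq_len(n), function(c) hp[c + 1L] >= hp[c] &&
                      hp[c + 1L] >= hp[c + 2L] && h[c] > 0, logical(1L))
  peaks <- which(is_peak)
  if (length(peaks) < 2L) {
    warning("unimodal count histogram (no valley); cutoff = 2")
    return(2L)
  }
  err_peak <- peaks[1L]
  later <- peaks[peaks > err_peak]
  cov_peak <- later[which.max(h[later])]
  if (cov_peak - err_peak < 2L) {
    warning("no valley between peaks; cutoff = 2")
    return(2L)
  }
  between <- (err_peak + 1L):(cov_peak - 1L)
  cutoff <- between[which.min(h[between])]   # first index achieving the min
  max(cutoff, 1L)
}

.status_levels <- c("unchanged", "corrected", "uncorrectable", "ambiguous")

.as_correction_result <- function(id, res, i) {
  e <- res$edits[[i]]
  structure(list(read_id = id,
                 status = .status_levels[res$status[i] + 1L],
                 seq = res$seq[i],
                 edits = data.table(position = e$position,
                                    old_base = e$old_base,
                                    new_base = e$new_base),
                 n_untrusted_before = res$n_untrusted_before[i],
                 n_untrusted_after = res$n_untrusted_after[i]),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("<correction_result %s: %s, %d edit(s), untrusted %d -> %d>\n",
              x$read_id, x$status, nrow(x$edits),
              x$n_untrusted_before, x$n_untrusted_after))
  invisible(x)
}

.check_spectrum_ready <- function(spectrum) {
  if (!inherits(spectrum, "kmer_spectrum")) stop("expected a kmer_spectrum")
  if (is.na(spectrum$trusted_cutoff))
    stop("trusted_cutoff is unset; call set_trusted_cutoff() first")
}

#' Correct a read by the fast single-site search
#'
#' Scans k-mer windows left to right; at the first untrusted window, each of
#' the three alternative bases is tried at every position covered only by
#' untrusted windows (the last base of the first untrusted window is tried
#' first). The unique substitution that makes all windows covering that
#' position trusted is accepted; the scan repeats up to `max_edits` times.
#' If the read cannot be fully cleared it is returned unchanged with status
#' `uncorrectable` (or `ambiguous` when several substitutions tied).
#'
#' @param read a single sequence, or a one-row data.frame with `id`/`seq`.
#' @param spectrum a `kmer_spectrum` with cutoff set.
#' @param max_edits maximum substitutions per read (default 2).
#' @return a `correction_result`: status, corrected sequence, edit list
#'   (0-based positions), untrusted-window counts before/after.
#' @export
correct_read_fast <- function(read, spectrum, max_edits = 2L) {
  .check_spectrum_ready(spectrum)
  id <- if (is.data.frame(read)) read$id[1L] else "read"
  s <- if (is.data.frame(read)) read$seq[1L] else as.character(read)
  res <- correct_reads_cpp(s, spectrum$k, spectrum$kmer, spectrum$count,
                           spectrum$trusted_cutoff, as.integer(max_edits),
                           0L, 64L)
  .as_correction_result(id, res, 1L)
}

#' Correct a read by the bounded deep multi-site search
#'
#' Bounded depth-first search over joint substitutions (up to `max_edits`
#' sites), exploring at most `budget` candidate branches. Candidates that
#' clear every window are scored by the total spectrum count of their
#' windows; the strictly best candidate is returned. Two candidates tying on
#' the full score yield status `ambiguous` and the read is left unchanged.
#'
#' @inheritParams correct_read_fast
#' @param budget maximum number of explored substitution branches, `>= 1`.
#' @return a `correction_result`.
#' @export
correct_read_deep <- function(read, spectrum, budget = 64L, max_edits = 2L) {
  .check_spectrum_ready(spectrum)
  stopifnot(budget >= 1L)
  id <- if (is.data.frame(read)) read$id[1L] else "read"
  s <- if (is.data.frame(read)) read$seq[1L] else as.character(read)
  res <- correct_reads_cpp(s, spectrum$k, spectrum$kmer, spectrum$count,
                           spectrum$trusted_cutoff, as.integer(max_edits),
                           1L, as.integer(budget))
  .as_correction_result(id, res, 1L)
}

#' Correct a read library
#'
#' Applies the fast and/or deep correction to every read, preserving input
#' order and read count (substitution-only: read lengths never change).
#' `fast_then_deep` applies the deep search only to reads the fast pass
#' could not fully clear, so its corrected count is never below the fast
#' pass's. When a spaced spectrum is supplied, an accepted edit must also
#' leave every spaced k-mer covering the edited site trusted, otherwise the
#' read reverts to `uncorrectable` (corroboration filter, off by default).
#'
#' @param reads data.table with `id` and `seq` columns (or character vector).
#' @param spectrum a `kmer_spectrum` with cutoff set.
#' @param mode `"fast"`, `"deep"` or `"fast_then_deep"`.
#' @param max_edits maximum substitutions per read.
#' @param budget deep-search branch budget.
#' @param drop_uncorrectable drop reads that remain uncorrectable (default
#'   keeps them unchanged).
#' @param spaced_spectrum optional `kmer_spectrum` from
#'   [count_spaced_kmers()] with its cutoff set.
#' @return a list: `reads` (corrected, same order), `results` (data.table of
#'   per-read status and edit counts), `summary` (counts per status).
#' @export
correct_library <- function(reads, spectrum,
                            mode = c("fast", "deep", "fast_then_deep"),
                            max_edits = 2L, budget = 64L,
                            drop_uncorrectable = FALSE,
                            spaced_spectrum = NULL) {
  mode <- match.arg(mode)
  .check_spectrum_ready(spectrum)
  dt <- if (is.data.frame(reads)) as.data.table(reads)
        else data.table(id = sprintf("read%d", seq_along(reads)),
                        seq = as.character(reads))
  mcode <- match(mode, c("fast", "deep", "fast_then_deep")) - 1L
  res <- correct_reads_cpp(dt$seq, spectrum$k, spectrum$kmer, spectrum$count,
                           spectrum$trusted_cutoff, as.integer(max_edits),
                           mcode, as.integer(budget))
  status <- .status_levels[res$status + 1L]
  out_seq <- res$seq

  if (!is.null(spaced_spectrum)) {
    pat <- attr(spaced_spectrum, "pattern")
    if (is.null(pat) || is.na(spaced_spectrum$trusted_cutoff))
      stop("spaced_spectrum must come from count_spaced_kmers() with a cutoff")
    for (i in which(status == "corrected")) {
      e <- res$edits[[i]]
      ok <- all(vapply(e$position, function(p) {
        offs <- spaced_offsets_covering(p, nchar(out_seq[i]), pat)
        if (!length(offs)) return(TRUE)
        sk <- vapply(offs, function(o) {
          x <- spaced_kmer(out_seq[i], o, pat)
          if (is.na(x)) "" else x
        }, character(1L))
        sk <- sk[nzchar(sk)]
        all(spectrum_count(spaced_spectrum, sk) >= spaced_spectrum$trusted_cutoff)
      }, logical(1L)))
      if (!ok) {
        status[i] <- "uncorrectable"
        out_seq[i] <- dt$seq[i]
      }
    }
  }

  results <- data.table(read_id = dt$id, status = status,
                        n_edits = vapply(res$edits, function(e)
                          length(e$position), 0L),
                        n_untrusted_before = res$n_untrusted_before,
                        n_untrusted_after = res$n_untrusted_after)
  results[status != "corrected", n_edits := 0L]
  out <- copy(dt)
  out[, seq := out_seq]
  keep <- if (drop_uncorrectable) status != "uncorrectable" else rep(TRUE, nrow(out))
  summary <- vapply(.status_levels, function(sv) sum(status == sv), 0L)
  list(reads = out[keep], results = results, summary = summary)
}
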