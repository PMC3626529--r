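#' Paired-end library description
#'
#' Metadata for one sequencing library: insert size distribution, read
#' orientation and the scaffolding rank that decides in which round its
#' paired-end links are used (smaller ranks, i.e. shorter inserts, first).
#'
#' @param name library name.
#' @param avg_ins mean insert (fragment) size in bp; must be positive.
#' @param ins_sd insert size standard deviation in bp (default 10% of
#'   `avg_ins`).
#' @param orientation `"FR"` (innie, short-insert paired-end) or `"RF"`
#'   (outie, long-insert mate-pair).
#' @param rank positive integer scaffolding rank; libraries sharing a rank are
#'   used in the same scaffolding round.
#' @param read_files character vector of read file paths (may be empty when
#'   reads are passed in memory).
#' @param max_read_len maximum read length in bp.
#' @return an object of class `pe_library`.
#' @export
pe_library <- function(name, avg_ins, ins_sd = NULL,
                       orientation = c("FR", "RF"), rank = 1L,
                       read_files = character(), max_read_len = 150L) {
  orientation <- match.arg(orientation)
  avg_ins <- as.integer(avg_ins)
  if (is.na(avg_ins) || avg_ins <= 0) stop("avg_ins must be a positive integer")
  rank <- as.integer(rank)
  if (is.na(rank) || rank < 1) stop("rank must be >= 1")
  if (is.null(ins_sd)) ins_sd <- max(1L, as.integer(round(0.1 * avg_ins)))
  structure(list(name = name, avg_ins = avg_ins, ins_sd = as.integer(ins_sd),
                 orientation = orientation, rank = rank,
                 read_files = read_files,
                 max_read_len = as.integer(max_read_len)),
            class = "pe_library")
}

#' @export
print.pe_library <- function(x, ...) {
  cat(sprintf("<pe_library %s: ins %d +/- %d bp, %s, rank %d, %d file(s)>\n",
              x$name, x$avg_ins, x$ins_sd, x$orientation, x$rank,
              length(x$read_files)))
  invisible(x)
}

# keys understood by the classic key=value library-config dialect
.config_known_keys <- c("avg_ins", "ins_sd", "reverse_seq", "asm_flags",
                        "rank", "q1", "q2", "f1", "f2", "q", "f", "p",
                        "name", "rd_len_cutoff", "map_len", "pair_num_cutoff")

#' Parse a library configuration file
#'
#' Reads the classic assembler configuration dialect: a global
#' `max_rd_len=` line followed by `[LIB]` blocks with `avg_ins`,
#' `reverse_seq` (0 = FR, 1 = RF), `rank` and read-file keys (`q1`/`q2` for
#' FASTQ pairs, `f1`/`f2` for FASTA). Assembly-phase flags such as
#' `asm_flags` are recorded but not interpreted. Unknown keys are ignored
#' with a warning.
#'
#' @param path path to the configuration file.
#' @return a list of [pe_library()] objects, sorted by `(rank, avg_ins)`
#'   ascending (stable).
#' @export
parse_library_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  max_rd_len <- 150L
  blocks <- list()
  cur <- NULL
  unknown <- character()
  push <- function() if (!is.null(cur)) blocks[[length(blocks) + 1L]] <<- cur
  for (ln in lines) {
    if (toupper(ln) == "[LIB]") { push(); cur <- list(); next }
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("cannot parse config line: ", ln)
    key <- kv[2]; val <- trimws(kv[3])
    if (is.null(cur)) {
      if (key == "max_rd_len") {
        max_rd_len <- .config_int(key, val)
      } else {
        unknown <- c(unknown, key)
      }
    } else {
      if (!(key %in% .config_known_keys)) { unknown <- c(unknown, key); next }
      cur[[key]] <- val
    }
  }
  push()
  if (length(unknown))
    warning("ignoring unknown config key(s): ",
            paste(unique(unknown), collapse = ", "))

  libs <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (is.null(b$avg_ins))
      stop("configuration error: [LIB] block ", i, " is missing avg_ins")
    avg_ins <- .config_int("avg_ins", b$avg_ins)
    ins_sd <- if (!is.null(b$ins_sd)) .config_int("ins_sd", b$ins_sd) else NULL
    rank <- if (!is.null(b$rank)) .config_int("rank", b$rank) else 1L
    rev_seq <- if (!is.null(b$reverse_seq)) .config_int("reverse_seq", b$reverse_seq) else 0L
    files <- unlist(b[intersect(names(b), c("q1", "q2", "f1", "f2", "q", "f", "p"))],
                    use.names = FALSE)
    name <- if (!is.null(b$name)) b$name else sprintf("lib%d", i)
    libs[[i]] <- pe_library(name, avg_ins, ins_sd,
                            orientation = if (rev_seq == 1L) "RF" else "FR",
                            rank = rank, read_files = as.character(files),
                            max_read_len = max_rd_len)
  }
  ord <- order(vapply(libs, `[[`, 1L, "rank"),
               vapply(libs, `[[`, 1L, "avg_ins"))
  libs[ord]
}

.config_int <- function(key, val) {
  if (!grepl("^-?[0-9]+$", val))
    stop("configuration error: non-integer value for ", key, ": ", val)
  as.integer(val)
}

#' Read sequences from FASTA or FASTQ
#'
#' Bases are uppercased and any character outside `A,C,G,T,N` is replaced by
#' `N` (a warning reports the replacement count). FASTQ records whose quality
#' string length differs from the sequence length raise a format error naming
#' the record.
#'
#' @param path input file.
#' @param format `"fasta"`, `"fastq"` or `"auto"` (detect from the leading
#'   character: `>` vs `@`).
#' @return a [data.table::data.table] with columns `id`, `seq` and `qual`
#'   (`NA` for FASTA).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- substr(readLines(path, n = 1L), 1L, 1L)
    format <- if (identical(first, ">")) "fasta" else "fastq"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    dt <- data.table(id = sub("\\s.*$", "", names(ss)),
                     seq = as.character(ss), qual = NA_character_)
  } else {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) %% 4L != 0L)
      stop("format error: FASTQ file has a truncated record at end of file")
    ids <- sub("\\s.*$", "", sub("^@", "", lines[seq(1L, length(lines), 4L)]))
    seqs <- lines[seq(2L, length(lines), 4L)]
    quals <- lines[seq(4L, length(lines), 4L)]
    bad <- which(nchar(seqs) != nchar(quals))
    if (length(bad))
      stop("format error: sequence/quality length mismatch in record ",
           ids[bad[1L]])
    dt <- data.table(id = ids, seq = seqs, qual = quals)
  }
  dt[, seq := toupper(seq)]
  n_bad <- sum(vapply(gregexpr("[^ACGTN]", dt$seq),
                      function(m) if (m[1L] == -1L) 0L else length(m), 0L))
  if (n_bad > 0L) {
    warning(n_bad, " base(s) outside {A,C,G,T,N} replaced by N")
    dt[, seq := gsub("[^ACGTN]", "N", seq)]
  }
  dt[]
}

#' Write sequences as 80-column wrapped FASTA
#'
#' @param records a data.frame with columns `id` and `seq`, or a named
#'   character vector of sequences.
#' @param path output file.
#' @return the path, invisibly. Round-trips losslessly through
#'   [read_sequences()].
#' @export
write_assembly <- function(records, path) {
  if (is.character(records)) {
    ids <- names(records); seqs <- unname(records)
  } else {
    ids <- as.character(records$id); seqs <- as.character(records$seq)
  }
  if (anyDuplicated(ids)) stop("duplicate record id: ",
                               ids[duplicated(ids)][1L])
  if (length(seqs) == 0L) { file.create(path); return(invisible(path)) }
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Write paired reads as two FASTQ files
#'
#' @param read1,read2 data.tables with `id` and `seq` (and optionally `qual`)
#'   columns.
#' @param prefix output prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq_pair <- function(read1, read2, prefix) {
  w <- function(dt, path) {
    qual <- if ("qual" %in% names(dt) && !all(is.na(dt$qual))) dt$qual
            else strrep("I", nchar(dt$seq))
    out <- as.vector(rbind(paste0("@", dt$id), dt$seq, "+", qual))
    writeLines(out, path)
    path
  }
  p1 <- w(read1, paste0(prefix, "_1.fastq"))
  p2 <- w(read2, paste0(prefix, "_2.fastq"))
  invisible(c(p1, p2))
}
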