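#' Resolve a consensus column from weighted base votes
#'
#' Returns the base with the highest cumulative weight. A read contributes
#' weight 1, halved to 0.5 once it has disagreed with the local consensus.
#' If the runner-up weight is within `ratio` of the top weight the column is
#' ambiguous (`NA`) and extension stops there.
#'
#' @param votes named numeric vector of per-base cumulative weights.
#' @param ratio ambiguity ratio (default 0.8).
#' @return the winning base, or `NA_character_` on ambiguity.
#' @export
resolve_conflict <- function(votes, ratio = 0.8) {
  if (length(votes) == 0L) stop("resolve_conflict requires at least one vote")
  votes <- sort(votes, decreasing = TRUE)
  if (length(votes) >= 2L && votes[2L] > ratio * votes[1L])
    return(NA_character_)
  names(votes)[1L]
}

#' Construct a gap-filling task
#'
#' @param scaffold_id,gap_index identify the gap.
#' @param left_flank,right_flank N-free scaffold sequence adjacent to the
#'   gap (left flank ends at the gap; right flank starts after it).
#' @param est_gap signed gap estimate in bp.
#' @param reads data.table with `id`, `seq`, `cycle_first_seen` (and
#'   optionally `mism`, the disagreement flag driving weight halving).
#' @return an object of class `gap_task`.
#' @export
gap_task <- function(scaffold_id, gap_index, left_flank, right_flank,
                     est_gap, reads) {
  reads <- as.data.table(reads)
  if (!"cycle_first_seen" %in% names(reads)) reads[, cycle_first_seen := 1L]
  if (!"mism" %in% names(reads)) reads[, mism := FALSE]
  reads <- unique(reads, by = "id")
  structure(list(scaffold_id = scaffold_id, gap_index = gap_index,
                 left_flank = left_flank, right_flank = right_flank,
                 est_gap = est_gap, reads = reads,
                 left_ext = "", right_ext = "", stalled = FALSE),
            class = "gap_task")
}

# (k-1)-mer -> next-base index over both read orientations; one row per
# occurrence, rid identifies the read
.read_next_index <- function(seqs, a) {
  rows <- vector("list", 2L * length(seqs))
  n <- 0L
  for (ori in 1:2) {
    ss <- if (ori == 1L) seqs else revcomp(seqs)
    for (i in seq_along(ss)) {
      s <- ss[[i]]
      L <- nchar(s)
      if (L < a + 1L) next
      off <- 1:(L - a)
      n <- n + 1L
      rows[[n]] <- data.table(kmer = substring(s, off, off + a - 1L),
                              nextb = substring(s, off + a, off + a),
                              rid = i)
    }
  }
  idx <- rbindlist(rows[seq_len(n)])
  if (nrow(idx) == 0L)
    idx <- data.table(kmer = character(), nextb = character(), rid = integer())
  idx <- unique(idx, by = c("kmer", "nextb", "rid"))
  setkey(idx, kmer)
  idx
}

# extend one sequence rightward by iterated weighted consensus
.extend_right <- function(cur, idx, reads, rule, cycle, k_fill, max_extend,
                          ratio = 0.8) {
  a <- k_fill - 1L
  ext <- character(0)
  mism <- reads$mism
  eligible <- if (rule == "cumulative") reads$cycle_first_seen <= cycle
              else reads$cycle_first_seen == cycle
  for (step in seq_len(max_extend)) {
    t <- substr(cur, nchar(cur) - a + 1L, nchar(cur))
    if (nchar(t) < a || grepl("N", t, fixed = TRUE)) break
    hits <- idx[.(t), nomatch = NULL]
    hits <- hits[eligible[hits$rid]]
    if (nrow(hits) == 0L) break
    hits <- unique(hits, by = "rid")        # one vote per read
    w <- ifelse(mism[hits$rid], 0.5, 1)
    votes <- tapply(w, hits$nextb, sum)
    base <- resolve_conflict(setNames(as.numeric(votes), names(votes)), ratio)
    if (is.na(base)) break
    mism[hits$rid[hits$nextb != base]] <- TRUE
    ext <- c(ext, base)
    cur <- paste0(cur, base)
  }
  list(ext = paste(ext, collapse = ""), mism = mism)
}

#' Run one extension cycle on a gap task
#'
#' Rebuilds the left and right flank extensions by weighted consensus using
#' every read assigned in cycles up to `cycle` (the cumulative rule;
#' `rule = "cycle_local"` is the legacy behavior that weighs only reads
#' first seen in the current cycle). Reads from `pool` whose sequence
#' anchors in the new extensions are assigned (with their mates) at
#' `cycle + 1`.
#'
#' @param task a [gap_task()].
#' @param cycle current cycle number (1-based).
#' @param k_fill consensus k-mer size (default 25).
#' @param rule `"cumulative"` or `"cycle_local"`.
#' @param max_extend per-side extension cap in bp.
#' @param pool optional data.table of unassigned candidate reads (`id`,
#'   `seq`, `mate_id`, `mate_seq`).
#' @return the updated `gap_task` (fields `left_ext`, `right_ext`, `reads`).
#' @export
extend_cycle <- function(task, cycle, k_fill = 25L,
                         rule = c("cumulative", "cycle_local"),
                         max_extend = 2000L, pool = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(task, "gap_task"))
  if (nrow(task$reads) == 0L) return(task)
  a <- k_fill - 1L
  idx <- .read_next_index(task$reads$seq, a)
  resL <- .extend_right(task$left_flank, idx, task$reads, rule, cycle,
                        k_fill, max_extend)
  task$reads$mism <- resL$mism
  resR <- .extend_right(revcomp(task$right_flank), idx, task$reads, rule,
                        cycle, k_fill, max_extend)
  task$reads$mism <- resR$mism
  old_l <- task$left_ext; old_r <- task$right_ext
  task$left_ext <- resL$ext
  task$right_ext <- revcomp(resR$ext)
  task$stalled <- identical(old_l, task$left_ext) &&
                  identical(old_r, task$right_ext)
  if (!is.null(pool) && nrow(pool)) {
    extseq <- paste(task$left_ext, task$right_ext)
    newly <- vapply(seq_len(nrow(pool)), function(i) {
      s <- pool$seq[i]
      if (nchar(s) < k_fill) return(FALSE)
      anyhit <- function(x) {
        if (nchar(x) < k_fill) return(FALSE)
        grepl(substr(s, 1L, k_fill), x, fixed = TRUE) ||
          grepl(substr(revcomp(s), 1L, k_fill), x, fixed = TRUE)
      }
      anyhit(task$left_ext) || anyhit(task$right_ext)
    }, logical(1L))
    if (any(newly)) {
      add <- rbind(
        data.table(id = pool$id[newly], seq = pool$seq[newly]),
        data.table(id = pool$mate_id[newly], seq = pool$mate_seq[newly]))
      add <- add[!add$id %in% task$reads$id]
      if (nrow(add)) {
        add[, `:=`(cycle_first_seen = cycle + 1L, mism = FALSE)]
        task$reads <- rbind(task$reads, add)
        task$stalled <- FALSE
      }
    }
  }
  task
}

.count_mism <- function(x, y) {
  # equal-length mismatch count
  sum(utf8ToInt(x) != utf8ToInt(y))
}

# try to splice the two flank extensions: overlap >= k_fill with <= 1
# mismatch, preferring the overlap most consistent with est_gap
.try_close <- function(task, k_fill, max_over_mm = 1L) {
  L <- paste0(task$left_flank, task$left_ext)
  R <- paste0(task$right_ext, task$right_flank)
  omax <- min(nchar(L), nchar(R))
  if (omax < k_fill) return(NULL)
  best <- NULL
  for (o in k_fill:omax) {
    sfx <- substr(L, nchar(L) - o + 1L, nchar(L))
    pfx <- substr(R, 1L, o)
    if (grepl("N", sfx, fixed = TRUE) || grepl("N", pfx, fixed = TRUE)) next
    mm <- .count_mism(sfx, pfx)
    if (mm > max_over_mm) next
    fill_len <- nchar(task$left_ext) + nchar(task$right_ext) - o
    score <- abs(fill_len - task$est_gap)
    if (is.null(best) || mm < best$mm || (mm == best$mm && score < best$score))
      best <- list(o = o, mm = mm, score = score, fill_len = fill_len)
  }
  if (is.null(best)) return(NULL)
  merged <- paste0(L, substr(R, best$o + 1L, nchar(R)))
  best$merged <- merged
  best
}

#' Close scaffold gaps by iterative local assembly
#'
#' Reads are assigned to gaps from mate placements (a read joins a gap when
#' its placed mate implies, through the library insert distribution, that
#' the read lies inside the gap interval). Each cycle rebuilds both flank
#' extensions from all reads assigned so far (the cumulative evidence
#' rule), then assigns newly reachable reads; a gap is closed when the two
#' extensions overlap by at least `k_fill` bases with at most one mismatch.
#' Negative gap estimates are tested for a direct flank overlap first.
#' Extension stops at ambiguous consensus columns, when no progress is made,
#' at `max_cycles`, or when the assembled fill exceeds
#' `est_gap + 3 * pooled_sd + 2 * read_len` (reported `partial`).
#'
#' @param scaffolds scaffold data.table from [build_scaffolds()].
#' @param contigs contig data.table (`id`, `seq`, `length`).
#' @param pe_libs list of paired libraries: each
#'   `list(read1 =, read2 =, library = <name>)` with `id`/`seq` tables.
#' @param libraries list of [pe_library()] objects.
#' @param max_cycles maximum assign/extend cycles (default 10).
#' @param k_fill consensus/closure k-mer size (default 25).
#' @param rule `"cumulative"` (default) or the legacy `"cycle_local"`.
#' @param mismatch_threshold placements with more mismatches count as
#'   soft-placed and stay eligible for gap assignment.
#' @param min_wildcard rendered minimum gap width (must match the value used
#'   to render scaffolds elsewhere).
#' @return a list: `scaffolds` (data.table `id`, `seq` with gaps filled),
#'   `results` (per-gap data.table: `scaffold_id`, `gap_index`, `est_gap`,
#'   `status` in closed/partial/open, `fill_len`, `final_gap`,
#'   `cycles_used`, `fill_seq`).
#' @export
close_gaps <- function(scaffolds, contigs, pe_libs, libraries,
                       max_cycles = 10L, k_fill = 25L,
                       rule = c("cumulative", "cycle_local"),
                       mismatch_threshold = 2L, min_wildcard = 1L) {
  rule <- match.arg(rule)
  stopifnot(max_cycles >= 1L)
  libmap <- setNames(libraries, vapply(libraries, `[[`, "", "name"))
  prep <- .prepare_gap_tasks(scaffolds, contigs, pe_libs, libmap,
                             mismatch_threshold, min_wildcard, k_fill)
  tasks <- prep$tasks
  results <- list()
  fills <- list()   # keyed "<sid>:<gap>"
  for (ti in seq_along(tasks)) {
    task <- tasks[[ti]]
    pool <- prep$pools[[as.character(task$scaffold_id)]]
    status <- "open"; cycles_used <- 0L; best <- NULL
    if (task$est_gap < 0) best <- .try_close(task, k_fill)
    if (is.null(best)) {
      max_sd <- if (length(libraries))
        max(vapply(libraries, `[[`, 1L, "ins_sd")) else 50L
      read_len <- if (nrow(task$reads)) max(nchar(task$reads$seq)) else 100L
      cap <- max(task$est_gap, 0) + 3 * max_sd + 2 * read_len
      for (cy in seq_len(max_cycles)) {
        task <- extend_cycle(task, cy, k_fill = k_fill, rule = rule,
                             pool = pool)
        cycles_used <- cy
        best <- .try_close(task, k_fill)
        if (!is.null(best)) break
        if (nchar(task$left_ext) + nchar(task$right_ext) > cap) break
        if (task$stalled) break
      }
    }
    if (!is.null(best)) {
      status <- "closed"
      fill_seq <- substr(best$merged, nchar(task$left_flank) + 1L,
                         nchar(best$merged) - nchar(task$right_flank))
      final_gap <- best$fill_len
    } else {
      status <- if (nchar(task$left_ext) + nchar(task$right_ext) > 0L)
        "partial" else "open"
      fill_seq <- ""
      final_gap <- task$est_gap - nchar(task$left_ext) - nchar(task$right_ext)
    }
    key <- paste0(task$scaffold_id, ":", task$gap_index)
    fills[[key]] <- list(status = status, fill_seq = fill_seq,
                         left_ext = task$left_ext, right_ext = task$right_ext,
                         merged = if (!is.null(best)) best$merged else NULL,
                         task = task)
    results[[ti]] <- data.table(
      scaffold_id = task$scaffold_id, gap_index = task$gap_index,
      est_gap = task$est_gap, status = status,
      fill_len = if (status == "closed") nchar(fill_seq) else
        nchar(task$left_ext) + nchar(task$right_ext),
      final_gap = final_gap, cycles_used = cycles_used,
      fill_seq = fill_seq)
  }
  res <- rbindlist(results)
  if (nrow(res) == 0L)
    res <- data.table(scaffold_id = integer(), gap_index = integer(),
                      est_gap = numeric(), status = character(),
                      fill_len = integer(), final_gap = numeric(),
                      cycles_used = integer(), fill_seq = character())
  out_seq <- .render_filled(scaffolds, contigs, fills, min_wildcard)
  list(scaffolds = out_seq, results = res)
}

# rebuild rendered scaffolds, substituting gap fills
.render_filled <- function(scaffolds, contigs, fills, min_wildcard) {
  cs <- setNames(contigs$seq, as.character(contigs$id))
  sc <- scaffolds[order(scaffold_id, part_index)]
  out <- sc[, .(seq = {
    pieces <- character(0)
    for (i in seq_len(.N)) {
      s <- cs[[as.character(contig_id[i])]]
      if (orient[i] == "-") s <- revcomp(s)
      pieces <- c(pieces, s)
      if (i < .N) {
        f <- fills[[paste0(scaffold_id[1L], ":", i)]]
        if (!is.null(f) && f$status == "closed" && nchar(f$fill_seq) >= 0L &&
            !is.null(f$merged) && f$task$est_gap >= 0) {
          pieces <- c(pieces, f$fill_seq)
        } else if (!is.null(f) && f$status == "closed") {
          # negative-gap closure: the merged junction may trim flank overlap
          pieces <- c(pieces, f$fill_seq)
        } else if (!is.null(f) && f$status == "partial") {
          nrun <- max(round(f$task$est_gap) - nchar(f$left_ext) -
                        nchar(f$right_ext), min_wildcard)
          pieces <- c(pieces, paste0(f$left_ext, strrep("N", nrun),
                                     f$right_ext))
        } else {
          pieces <- c(pieces,
                      strrep("N", max(round(gap_after[i]), min_wildcard)))
        }
      }
    }
    paste(pieces, collapse = "")
  }), by = "scaffold_id"]
  data.table(id = sprintf("scaffold_%d", out$scaffold_id), seq = out$seq)
}

# map all reads onto rendered scaffolds, derive gap intervals and per-gap
# read assignments plus per-scaffold candidate pools
.prepare_gap_tasks <- function(scaffolds, contigs, pe_libs, libmap,
                               mismatch_threshold, min_wildcard, k_fill) {
  sseqs <- scaffold_seq(scaffolds, contigs, min_wildcard)
  lens <- setNames(contigs$length, as.character(contigs$id))
  sc <- scaffolds[order(scaffold_id, part_index)]
  gaps <- sc[, {
    if (.N < 2L) data.table(gap_index = integer(), gs = numeric(),
                            ge = numeric(), est = numeric())
    else {
      pos <- 0; g <- list()
      for (i in seq_len(.N - 1L)) {
        pos <- pos + as.numeric(lens[[as.character(contig_id[i])]])
        w <- max(round(gap_after[i]), min_wildcard)
        g[[i]] <- data.table(gap_index = i, gs = pos, ge = pos + w,
                             est = as.numeric(gap_after[i]))
        pos <- pos + w
      }
      rbindlist(g)
    }
  }, by = "scaffold_id"]

  max_sd <- if (length(libmap)) max(vapply(libmap, `[[`, 1L, "ins_sd")) else 50L
  flank_len_of <- function(rl) 2L * max_sd + rl

  tasks <- list(); pools <- list()
  if (nrow(gaps) == 0L) return(list(tasks = tasks, pools = pools))

  assigned <- list()  # key -> data.table(id, seq)
  for (pl in pe_libs) {
    lib <- libmap[[pl$library]]
    r1 <- pl$read1; r2 <- pl$read2
    allr <- rbind(data.table(id = r1$id, seq = r1$seq),
                  data.table(id = r2$id, seq = r2$seq))
    pm <- map_reads_to_contigs(allr, data.table(id = seq_len(nrow(sseqs)),
                                                seq = sseqs$seq),
                               max_mismatch = mismatch_threshold)
    pmap <- pm[match(allr$id, pm$read_id)]
    placed <- !is.na(pmap$contig_id)
    n <- nrow(r1)
    look <- function(i) i               # r1 rows 1..n, r2 rows n+1..2n
    for (i in seq_len(n)) {
      for (side in 1:2) {
        mi <- if (side == 1L) i else n + i          # placed mate row
        pi <- if (side == 1L) n + i else i          # partner row
        if (!placed[mi]) next
        soft <- pmap$mismatches[pi] > mismatch_threshold
        if (placed[pi] && !isTRUE(soft)) next       # partner well placed
        sid <- pmap$contig_id[mi]
        off <- pmap$offset[mi]; st <- pmap$strand[mi]
        rl <- pmap$read_len[mi]
        pstart <- if (st == "+") off + lib$avg_ins - rl
                  else off + rl - lib$avg_ins
        lo <- pstart - 3 * lib$ins_sd - rl
        hi <- pstart + 3 * lib$ins_sd + rl
        gsel <- gaps[gaps$scaffold_id == sid & gaps$ge > lo & gaps$gs < hi]
        if (nrow(gsel) == 0L) next
        for (gi in seq_len(nrow(gsel))) {
          key <- paste0(sid, ":", gsel$gap_index[gi])
          assigned[[key]] <- rbind(assigned[[key]],
                                   data.table(id = allr$id[pi],
                                              seq = allr$seq[pi]))
        }
      }
    }
    # pool: pairs with an unplaced member, candidates for later cycles
    un1 <- !placed[seq_len(n)]; un2 <- !placed[n + seq_len(n)]
    cand <- un1 | un2
    if (any(cand)) {
      pool <- rbind(
        data.table(id = r1$id[cand], seq = r1$seq[cand],
                   mate_id = r2$id[cand], mate_seq = r2$seq[cand]),
        data.table(id = r2$id[cand], seq = r2$seq[cand],
                   mate_id = r1$id[cand], mate_seq = r1$seq[cand]))
      for (sid in unique(gaps$scaffold_id)) {
        k <- as.character(sid)
        pools[[k]] <- rbind(pools[[k]], pool)
      }
    }
  }
  for (k in names(pools)) pools[[k]] <- unique(pools[[k]], by = "id")

  for (gi in seq_len(nrow(gaps))) {
    sid <- gaps$scaffold_id[gi]
    key <- paste0(sid, ":", gaps$gap_index[gi])
    sseq <- sseqs$seq[sid]
    rds <- assigned[[key]]
    rl <- if (!is.null(rds) && nrow(rds)) max(nchar(rds$seq)) else 100L
    fl <- flank_len_of(rl)
    gs <- gaps$gs[gi]; ge <- gaps$ge[gi]
    lf <- substr(sseq, max(1L, gs - fl + 1L), gs)
    lf <- sub("^.*N", "", lf)
    rf <- substr(sseq, ge + 1L, min(nchar(sseq), ge + fl))
    rf <- sub("N.*$", "", rf)
    if (is.null(rds)) rds <- data.table(id = character(), seq = character())
    rds <- unique(rds, by = "id")
    tasks[[length(tasks) + 1L]] <- gap_task(sid, gaps$gap_index[gi], lf, rf,
                                            gaps$est[gi], rds)
  }
  list(tasks = tasks, pools = pools)
}

#' Assign reads to scaffold gaps
#'
#' Convenience wrapper around the assignment stage of [close_gaps()]: maps
#' all reads to the rendered scaffolds and returns one [gap_task()] per
#' internal gap, with reads whose placed mates imply membership of the gap
#' interval assigned at cycle 1.
#'
#' @inheritParams close_gaps
#' @return a list of `gap_task` objects.
#' @export
assign_reads_to_gaps <- function(scaffolds, contigs, pe_libs, libraries,
                                 mismatch_threshold = 2L, min_wildcard = 1L) {
  libmap <- setNames(libraries, vapply(libraries, `[[`, "", "name"))
  .prepare_gap_tasks(scaffolds, contigs, pe_libs, libmap,
                     mismatch_threshold, min_wildcard, 25L)$tasks
}
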