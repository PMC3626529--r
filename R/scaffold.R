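.flip <- function(s) ifelse(s == "+", "-", "+")

#' Collect paired-end links between contigs
#'
#' Pairs with both mates placed on different contigs in a library-consistent
#' relative orientation yield one link with an observed gap
#' `gap_obs = avg_ins - d_a - d_b`, where `d_a` is the distance from the
#' a-read's outermost (5') base to the linked end of contig a, and `d_b`
#' likewise on contig b. Pairs with both mates on one contig contribute to
#' insert-size re-estimation (returned as the `insert_obs` attribute); pairs
#' on one contig violating the library orientation are counted and dropped
#' (`n_orient_violations` attribute).
#'
#' @param placements placement data.table from [map_reads_to_contigs()]
#'   covering both mates of every pair.
#' @param pairs data.table with columns `pair_id`, `read1_id`, `read2_id`,
#'   `library`.
#' @param libraries list of [pe_library()] objects.
#' @param contigs contig data.table (`id`, `length`).
#' @return a data.table of links: `contig_a`, `contig_b` (normalized
#'   `contig_a < contig_b`), `orient` (two characters: layout senses of a
#'   and b), `gap_obs`, `library`, `rank`, `ins_sd`, `read_pair_id`.
#' @export
collect_pe_links <- function(placements, pairs, libraries, contigs) {
  libmap <- setNames(libraries, vapply(libraries, `[[`, "", "name"))
  m1 <- placements[match(pairs$read1_id, placements$read_id)]
  m2 <- placements[match(pairs$read2_id, placements$read_id)]
  clen <- setNames(contigs$length, as.character(contigs$id))

  links <- vector("list", nrow(pairs))
  insert_obs <- numeric(0)
  n_viol <- 0L
  for (i in seq_len(nrow(pairs))) {
    if (is.na(m1$contig_id[i]) || is.na(m2$contig_id[i])) next
    lib <- libmap[[pairs$library[i]]]
    s1 <- m1$strand[i]; s2 <- m2$strand[i]
    if (lib$orientation == "RF") { s1 <- .flip(s1); s2 <- .flip(s2) }
    if (m1$contig_id[i] == m2$contig_id[i]) {
      # innie orientation on one contig: forward read upstream of reverse read
      if (s1 != s2) {
        fwd <- if (s1 == "+") 1L else 2L
        off_f <- if (fwd == 1L) m1$offset[i] else m2$offset[i]
        off_r <- if (fwd == 1L) m2$offset[i] else m1$offset[i]
        rl_r <- if (fwd == 1L) m2$read_len[i] else m1$read_len[i]
        ins <- off_r + rl_r - off_f
        if (ins > 0) insert_obs <- c(insert_obs, ins) else n_viol <- n_viol + 1L
      } else n_viol <- n_viol + 1L
      next
    }
    a <- m1$contig_id[i]; b <- m2$contig_id[i]
    la <- clen[[as.character(a)]]; lb <- clen[[as.character(b)]]
    oa <- s1
    ob <- .flip(s2)
    xa <- if (s1 == "+") m1$offset[i] else m1$offset[i] + m1$read_len[i] - 1L
    xb <- if (s2 == "+") m2$offset[i] else m2$offset[i] + m2$read_len[i] - 1L
    da <- if (oa == "+") la - xa else xa + 1L
    db <- if (ob == "+") xb + 1L else lb - xb
    gap <- lib$avg_ins - da - db
    if (a > b) {
      tmp <- a; a <- b; b <- tmp
      o <- c(.flip(ob), .flip(oa))
    } else o <- c(oa, ob)
    links[[i]] <- data.table(contig_a = a, contig_b = b,
                             orient = paste0(o[1L], o[2L]),
                             gap_obs = gap, library = lib$name,
                             rank = lib$rank, ins_sd = lib$ins_sd,
                             read_pair_id = pairs$pair_id[i])
  }
  out <- rbindlist(links)
  if (nrow(out) == 0L)
    out <- data.table(contig_a = integer(), contig_b = integer(),
                      orient = character(), gap_obs = numeric(),
                      library = character(), rank = integer(),
                      ins_sd = integer(), read_pair_id = character())
  attr(out, "insert_obs") <- insert_obs
  attr(out, "n_orient_violations") <- n_viol
  out
}

#' Bundle links into aggregated paired-end evidence
#'
#' Links are grouped by (contig pair, orientation, rank). Observations
#' farther than 3 library standard deviations from the group's median are
#' discarded before averaging. Where orientations conflict for one pair, the
#' majority orientation keeps its status and the minority is marked
#' `conflict`. Bundles below `min_support` are kept as `weak` candidates
#' rather than discarded; the rest are `accepted`.
#'
#' @param links data.table from [collect_pe_links()].
#' @param min_support minimum distinct read pairs for acceptance (default 3).
#' @param gap_clamp optional lower clamp for `gap_mean` (e.g. `-(k - 1)`);
#'   the unclamped estimate drives nothing downstream once clamped.
#' @return a data.table of bundles: pair, `orient`, `support`, `gap_mean`,
#'   `gap_sd`, `rank`, `status` in `accepted`/`weak`/`conflict`.
#' @export
bundle_links <- function(links, min_support = 3L, gap_clamp = NULL) {
  if (nrow(links) == 0L)
    return(data.table(contig_a = integer(), contig_b = integer(),
                      orient = character(), support = integer(),
                      gap_mean = numeric(), gap_sd = numeric(),
                      rank = integer(), status = character()))
  b <- links[, {
    libsd <- max(ins_sd)
    keep <- abs(gap_obs - median(gap_obs)) <= 3 * libsd
    g <- gap_obs[keep]
    .(support = length(g), gap_mean = mean(g),
      gap_sd = if (length(g) >= 2L) max(sd(g), 1) else as.numeric(libsd))
  }, by = c("contig_a", "contig_b", "orient", "rank")]
  # orientation conflicts within a pair+rank: majority wins
  b[, status := "accepted"]
  b <- b[order(contig_a, contig_b, rank, -support, orient)]
  b[, status := {
    s <- rep("accepted", .N)
    if (.N > 1L) s[-1L] <- "conflict"
    s
  }, by = c("contig_a", "contig_b", "rank")]
  b[status == "accepted" & support < min_support, status := "weak"]
  if (!is.null(gap_clamp)) b[, gap_mean := pmax(gap_mean, gap_clamp)]
  b[]
}

#' Detect heterozygous contig pairs
#'
#' Two contigs form an allelic (heterozygous) pair when (a) both have read
#' depth within `depth_window` times the modal depth of long contigs
#' (>= 1 kb), (b) they share a common neighbor on both flanks in the
#' accepted bundle graph (allowing for the two alleles being stored in
#' opposite canonical orientations), and (c) their lengths are within
#' `len_ratio` of each other. The higher-depth member is kept and the other
#' masked from scaffolding; equal depth keeps the smaller contig id.
#'
#' @param contigs contig data.table (`id`, `length`).
#' @param bundles bundle data.table from [bundle_links()].
#' @param depth numeric per-contig read depth aligned with `contigs` rows
#'   (see [contig_read_depth()]).
#' @param depth_window fraction window around half the modal depth,
#'   default `c(0.3, 0.7)`.
#' @param len_ratio maximum length ratio between pair members (default 2).
#' @param contig_k optional assembly k: when given and `contigs` carries a
#'   `seq` column, contigs sharing a (k-1)-mer unitig-graph junction at
#'   their ends count as neighbors too. This is what makes bubble-scale
#'   allelic fragments detectable, since fragments shorter than the insert
#'   size anchor no paired-end bundles.
#' @return a data.table with columns `kept_id`, `dropped_id`.
#' @export
detect_het_pairs <- function(contigs, bundles, depth,
                             depth_window = c(0.3, 0.7), len_ratio = 2,
                             contig_k = NULL) {
  long <- depth[contigs$length >= 1000L & depth > 0]
  if (length(long) == 0L) long <- depth[depth > 0]
  mode_depth <- if (length(long) >= 3L) {
    d <- density(long)
    d$x[which.max(d$y)]
  } else median(long)
  in_win <- depth > depth_window[1L] * mode_depth &
            depth < depth_window[2L] * mode_depth
  # sequence-similarity fallback: allelic mates are near-identical, so a
  # shared-junction pair aligning within 10% divergence counts as long as
  # both sit clearly below full depth (depth estimates on sub-kilobase
  # fragments are too noisy for the window alone)
  sub_full <- depth < 0.85 * mode_depth
  have_seq <- "seq" %in% names(contigs)
  cand <- contigs$id[in_win | (have_seq & sub_full)]
  if (length(cand) < 2L) return(data.table(kept_id = integer(),
                                           dropped_id = integer()))
  win_of <- setNames(in_win, as.character(contigs$id))
  seq_of <- if (have_seq) setNames(contigs$seq, as.character(contigs$id))
            else NULL
  similar <- function(x, y) {
    if (is.null(seq_of)) return(FALSE)
    sx <- seq_of[[as.character(x)]]; sy <- seq_of[[as.character(y)]]
    d <- min(utils::adist(sx, sy), utils::adist(sx, revcomp(sy)))
    d / max(nchar(sx), nchar(sy)) <= 0.1
  }
  acc <- bundles[bundles$status == "accepted"]
  end_tab <- NULL
  if (!is.null(contig_k) && "seq" %in% names(contigs)) {
    a <- contig_k - 1L
    ok <- contigs$length >= a
    end_tab <- data.table(
      contig = rep(contigs$id[ok], 2L),
      end = rep(c("L", "R"), each = sum(ok)),
      key_km = canonical_kmer(c(substr(contigs$seq[ok], 1L, a),
                                substring(contigs$seq[ok],
                                          contigs$length[ok] - a + 1L))))
  }
  nbr <- function(cid, end) {
    aside <- acc[acc$contig_a == cid &
                   (substr(acc$orient, 1L, 1L) == "+") == (end == "R")]
    bside <- acc[acc$contig_b == cid &
                   (substr(acc$orient, 2L, 2L) == "+") == (end == "L")]
    out <- c(aside$contig_b, bside$contig_a)
    if (!is.null(end_tab)) {
      km <- end_tab$key_km[end_tab$contig == cid & end_tab$end == end]
      if (length(km))
        out <- c(out, end_tab$contig[end_tab$key_km %in% km &
                                       end_tab$contig != cid])
    }
    unique(out)
  }
  lens <- setNames(contigs$length, as.character(contigs$id))
  dep <- setNames(depth, as.character(contigs$id))
  pairs <- list(); used <- integer(0)
  cand <- sort(cand)
  for (i in seq_along(cand)) for (j in seq_along(cand)) {
    if (j <= i) next
    x <- cand[i]; y <- cand[j]
    if (x %in% used || y %in% used) next
    lx <- lens[[as.character(x)]]; ly <- lens[[as.character(y)]]
    if (max(lx, ly) > len_ratio * min(lx, ly)) next
    xl <- nbr(x, "L"); xr <- nbr(x, "R")
    yl <- nbr(y, "L"); yr <- nbr(y, "R")
    straight <- length(intersect(xl, yl)) > 0L && length(intersect(xr, yr)) > 0L
    flipped  <- length(intersect(xl, yr)) > 0L && length(intersect(xr, yl)) > 0L
    if (!(straight || flipped)) next
    depth_ok <- (win_of[[as.character(x)]] && win_of[[as.character(y)]]) ||
      similar(x, y)
    if (!depth_ok) next
    dx <- dep[[as.character(x)]]; dy <- dep[[as.character(y)]]
    kept <- if (dx > dy) x else if (dy > dx) y else min(x, y)
    dropped <- if (kept == x) y else x
    pairs[[length(pairs) + 1L]] <- data.table(kept_id = kept,
                                              dropped_id = dropped)
    used <- c(used, x, y)
  }
  out <- rbindlist(pairs)
  if (nrow(out) == 0L) out <- data.table(kept_id = integer(),
                                         dropped_id = integer())
  out
}

# per-contig layout coordinates using signed gap estimates
.scaffold_layout <- function(scaffolds, contigs) {
  lens <- setNames(contigs$length, as.character(contigs$id))
  sc <- copy(scaffolds)
  sc[, length_ := lens[as.character(contig_id)]]
  sc <- sc[order(scaffold_id, part_index)]
  sc[, `:=`(start = {
    g <- gap_after; g[is.na(g)] <- 0
    cumsum(c(0, head(length_ + g, -1L)))
  }), by = "scaffold_id"]
  sc[, end := start + length_]
  sc[, scaffold_len := max(end), by = "scaffold_id"]
  sc[]
}

# lift contig-level bundles to scaffold-end links
.lift_bundles <- function(bundles, layout) {
  if (nrow(bundles) == 0L) return(NULL)
  idx <- layout[match(bundles$contig_a, layout$contig_id)]
  idy <- layout[match(bundles$contig_b, layout$contig_id)]
  rows <- list()
  for (i in seq_len(nrow(bundles))) {
    if (is.na(idx$scaffold_id[i]) || is.na(idy$scaffold_id[i])) next
    if (idx$scaffold_id[i] == idy$scaffold_id[i]) next
    oa <- substr(bundles$orient[i], 1L, 1L)
    ob <- substr(bundles$orient[i], 2L, 2L)
    # a-side: does a's linked end point toward the scaffold's right?
    a_right <- (oa == "+") == (idx$orient[i] == "+")
    us <- if (a_right) "+" else "-"
    da <- if (a_right) idx$scaffold_len[i] - idx$end[i] else idx$start[i]
    b_left <- (ob == "+") == (idy$orient[i] == "+")
    vs <- if (b_left) "+" else "-"
    db <- if (b_left) idy$start[i] else idy$scaffold_len[i] - idy$end[i]
    u <- idx$scaffold_id[i]; v <- idy$scaffold_id[i]
    gap <- bundles$gap_mean[i] - da - db
    if (u > v) {
      tmp <- u; u <- v; v <- tmp
      o <- c(.flip(vs), .flip(us))
    } else o <- c(us, vs)
    rows[[length(rows) + 1L]] <- data.table(
      u = u, v = v, us = o[1L], vs = o[2L], gap = gap,
      sdv = bundles$gap_sd[i], support = bundles$support[i])
  }
  if (!length(rows)) return(NULL)
  agg <- rbindlist(rows)[, .(
    gap = sum(gap * support) / sum(support),
    sdv = max(min(sdv), 1), support = sum(support)),
    by = c("u", "v", "us", "vs")]
  agg[]
}

# drop edges explained by a two-edge chain through a third scaffold
.transitive_reduce <- function(edges, scaffold_lens) {
  if (is.null(edges) || nrow(edges) <= 2L) return(edges)
  dir <- rbind(
    data.table(from = edges$u, fs = edges$us, to = edges$v, ts = edges$vs,
               gap = edges$gap, sdv = edges$sdv, eid = seq_len(nrow(edges))),
    data.table(from = edges$v, fs = .flip(edges$vs), to = edges$u,
               ts = .flip(edges$us), gap = edges$gap, sdv = edges$sdv,
               eid = seq_len(nrow(edges))))
  redundant <- rep(FALSE, nrow(edges))
  for (i in seq_len(nrow(dir))) for (j in seq_len(nrow(dir))) {
    if (dir$to[i] != dir$from[j] || dir$ts[i] != dir$fs[j]) next
    if (dir$from[i] == dir$to[j]) next
    comp <- dir$gap[i] + scaffold_lens[[as.character(dir$to[i])]] + dir$gap[j]
    hit <- which(dir$from == dir$from[i] & dir$to == dir$to[j] &
                   dir$fs == dir$fs[i] & dir$ts == dir$ts[j])
    for (h in hit) {
      if (dir$eid[h] == dir$eid[i] || dir$eid[h] == dir$eid[j]) next
      tol <- 3 * sqrt(dir$sdv[h]^2 + dir$sdv[i]^2 + dir$sdv[j]^2)
      if (abs(dir$gap[h] - comp) <= tol) redundant[dir$eid[h]] <- TRUE
    }
  }
  edges[!redundant]
}

# join scaffolds along unambiguous end-to-end edges
.linearize <- function(scaffolds, edges, contigs) {
  if (is.null(edges) || nrow(edges) == 0L) return(scaffolds)
  # "out" end of u: R if us == "+"; "in" end of v: L if vs == "+"
  e_u <- paste0(edges$u, ":", ifelse(edges$us == "+", "R", "L"))
  e_v <- paste0(edges$v, ":", ifelse(edges$vs == "+", "L", "R"))
  cnt <- table(c(e_u, e_v))
  ambig <- names(cnt)[cnt >= 2L]
  ok <- !(e_u %in% ambig) & !(e_v %in% ambig)
  edges <- edges[ok]; e_u <- e_u[ok]; e_v <- e_v[ok]
  if (nrow(edges) == 0L) return(scaffolds)
  ord <- order(-edges$support, edges$u, edges$v)
  comp <- setNames(unique(scaffolds$scaffold_id),
                   as.character(unique(scaffolds$scaffold_id)))
  find <- function(x) {
    r <- x
    while (comp[[as.character(r)]] != r) r <- comp[[as.character(r)]]
    r
  }
  used_end <- character(0)
  kept <- logical(nrow(edges))
  for (i in ord) {
    if (e_u[i] %in% used_end || e_v[i] %in% used_end) next
    ru <- find(edges$u[i]); rv <- find(edges$v[i])
    if (ru == rv) next  # would close a cycle; weakest-first skipped by order
    comp[[as.character(ru)]] <- rv
    used_end <- c(used_end, e_u[i], e_v[i])
    kept[i] <- TRUE
  }
  edges <- edges[kept]
  if (nrow(edges) == 0L) return(scaffolds)

  # adjacency per scaffold end
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    ue <- paste0(edges$u[i], ":", ifelse(edges$us[i] == "+", "R", "L"))
    ve <- paste0(edges$v[i], ":", ifelse(edges$vs[i] == "+", "L", "R"))
    adj[[ue]] <- list(other = edges$v[i], other_sense = edges$vs[i],
                      gap = edges$gap[i])
    adj[[ve]] <- list(other = edges$u[i], other_sense = .flip(edges$us[i]),
                      gap = edges$gap[i])
  }
  sc_ids <- unique(scaffolds$scaffold_id)
  in_chain <- setNames(rep(FALSE, length(sc_ids)), as.character(sc_ids))
  chains <- list()
  for (s in sort(sc_ids)) {
    if (in_chain[[as.character(s)]]) next
    has_L <- !is.null(adj[[paste0(s, ":L")]])
    has_R <- !is.null(adj[[paste0(s, ":R")]])
    if (has_L && has_R) next        # interior; reached from a terminal
    if (!has_L && !has_R) {
      in_chain[[as.character(s)]] <- TRUE
      chains[[length(chains) + 1L]] <- list(ids = s, senses = "+",
                                            gaps = numeric(0))
      next
    }
    sense <- if (has_R) "+" else "-"   # walk leaves via the linked end
    ids <- s; senses <- sense; gaps <- numeric(0)
    in_chain[[as.character(s)]] <- TRUE
    cur <- s; cur_sense <- sense
    repeat {
      exit_end <- paste0(cur, ":", ifelse(cur_sense == "+", "R", "L"))
      nx <- adj[[exit_end]]
      if (is.null(nx) || in_chain[[as.character(nx$other)]]) break
      # adj keys are contig-fixed ends, so reaching this exit end implies the
      # walk direction matches the stored direction; the stored sense applies
      nsense <- nx$other_sense
      ids <- c(ids, nx$other); senses <- c(senses, nsense)
      gaps <- c(gaps, nx$gap)
      in_chain[[as.character(nx$other)]] <- TRUE
      cur <- nx$other; cur_sense <- nsense
    }
    chains[[length(chains) + 1L]] <- list(ids = ids, senses = senses,
                                          gaps = gaps)
  }
  for (s in sort(sc_ids))   # anything untouched (shouldn't happen): singleton
    if (!in_chain[[as.character(s)]]) {
      chains[[length(chains) + 1L]] <- list(ids = s, senses = "+",
                                            gaps = numeric(0))
      in_chain[[as.character(s)]] <- TRUE
    }

  parts <- list()
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    allp <- list()
    for (m in seq_along(ch$ids)) {
      p <- scaffolds[scaffolds$scaffold_id == ch$ids[m]]
      p <- p[order(p$part_index)]
      if (ch$senses[m] == "-") {
        g <- p$gap_after                # g1..g(n-1), NA
        p <- p[rev(seq_len(nrow(p)))]
        p[, orient := .flip(orient)]
        p[, gap_after := c(rev(head(g, -1L)), NA_real_)]
      }
      if (m < length(ch$ids)) p$gap_after[nrow(p)] <- ch$gaps[m]
      allp[[m]] <- p
    }
    pp <- rbindlist(allp)
    pp[, `:=`(scaffold_id = ci, part_index = seq_len(.N))]
    parts[[ci]] <- pp
  }
  out <- rbindlist(parts)
  out[, c("scaffold_id", "part_index", "contig_id", "orient", "gap_after"),
      with = FALSE]
}

#' Build scaffolds from bundles, rank by rank
#'
#' Library ranks are processed in ascending order (short inserts first).
#' Within a rank, accepted bundles are lifted onto the current scaffolds
#' (each round treats the scaffolds built so far as super-contigs),
#' transitively redundant links are removed (a direct link explained by a
#' two-link chain within 3 pooled standard deviations), ambiguous branchings
#' are left unjoined, and the remaining unambiguous end-to-end links are
#' linearized into longer scaffolds. After each rank, junctions are
#' re-checked against all larger-rank bundles and chimeric joins are cut
#' (see [rectify_chimeras()]). Gap estimates keep their sign internally;
#' rendering clamps them to at least `min_wildcard` N characters.
#'
#' @param contigs contig data.table (`id`, `seq`, `length`).
#' @param bundles bundle data.table from [bundle_links()] (all ranks,
#'   including weak/conflict rows; only `accepted` rows build joins).
#' @param libraries list of [pe_library()] objects.
#' @param min_support minimum bundle support used in this stage.
#' @param masked contig ids masked from scaffolding (e.g. dropped
#'   heterozygous mates); they appear in no scaffold.
#' @param rectify run chimera rectification after each rank (default TRUE).
#' @return scaffold data.table: `scaffold_id`, `part_index`, `contig_id`,
#'   `orient`, `gap_after` (signed bp estimate, `NA` after the last part).
#' @export
build_scaffolds <- function(contigs, bundles, libraries, min_support = 3L,
                            masked = integer(0), rectify = TRUE) {
  ids <- setdiff(contigs$id, masked)
  scaffolds <- data.table(scaffold_id = seq_along(ids), part_index = 1L,
                          contig_id = ids, orient = "+",
                          gap_after = NA_real_)
  acc <- bundles[bundles$status %in% c("accepted", "recovered") &
                   bundles$support >= min_support &
                   !(bundles$contig_a %in% masked) &
                   !(bundles$contig_b %in% masked)]
  if (nrow(acc) == 0L) return(.renumber_scaffolds(scaffolds, contigs))
  ranks <- sort(unique(acc$rank))
  for (r in ranks) {
    layout <- .scaffold_layout(scaffolds, contigs)
    edges <- .lift_bundles(acc[acc$rank == r], layout)
    slens <- setNames(layout[!duplicated(scaffold_id)]$scaffold_len,
                      as.character(layout[!duplicated(scaffold_id)]$scaffold_id))
    edges <- .transitive_reduce(edges, slens)
    scaffolds <- .linearize(scaffolds, edges, contigs)
    if (rectify && any(bundles$rank > r))
      scaffolds <- rectify_chimeras(scaffolds, contigs,
                                    bundles[bundles$rank > r], libraries,
                                    min_support = min_support)
  }
  .renumber_scaffolds(scaffolds, contigs)
}

.renumber_scaffolds <- function(scaffolds, contigs) {
  lens <- setNames(contigs$length, as.character(contigs$id))
  tot <- scaffolds[, .(tl = sum(lens[as.character(contig_id)]),
                       first = min(contig_id)), by = "scaffold_id"]
  tot <- tot[order(-tl, first)]
  newid <- setNames(seq_len(nrow(tot)), as.character(tot$scaffold_id))
  out <- copy(scaffolds)
  out[, scaffold_id := newid[as.character(scaffold_id)]]
  out <- out[order(scaffold_id, part_index)]
  out[, part_index := seq_len(.N), by = "scaffold_id"]
  out[]
}

#' Cut chimeric scaffold junctions
#'
#' For each internal junction of each scaffold, larger-insert bundles are
#' classified as spanning (linking a contig left of the junction to one
#' right of it, with orientation and distance consistent with the layout)
#' or as elsewhere-evidence (a junction-adjacent contig linked with at least
#' `min_support` pairs to a contig outside the scaffold). Junctions with
#' zero spanning support and non-zero elsewhere-evidence are cut; a
#' junction spanned by enough pairs is never cut. With no larger-insert
#' bundles the scaffolds are returned unchanged.
#'
#' @param scaffolds scaffold data.table.
#' @param contigs contig data.table.
#' @param higher_rank_bundles bundles from ranks strictly larger than the
#'   rank that built the candidate joins.
#' @param libraries list of [pe_library()] objects (for insert reach).
#' @param min_support support needed for elsewhere-evidence (default 3).
#' @return the (possibly split) scaffold data.table; attribute `n_cut`
#'   counts cut junctions.
#' @export
rectify_chimeras <- function(scaffolds, contigs, higher_rank_bundles,
                             libraries, min_support = 3L) {
  hb <- higher_rank_bundles[higher_rank_bundles$status != "conflict"]
  if (nrow(hb) == 0L) {
    attr(scaffolds, "n_cut") <- 0L
    return(scaffolds)
  }
  layout <- .scaffold_layout(scaffolds, contigs)
  max_sd <- max(vapply(libraries, `[[`, 1L, "ins_sd"))
  n_cut <- 0L
  cuts <- list()
  for (sid in unique(layout$scaffold_id)) {
    ly <- layout[layout$scaffold_id == sid][order(part_index)]
    if (nrow(ly) < 2L) next
    for (jx in seq_len(nrow(ly) - 1L)) {
      left_ids <- ly$contig_id[seq_len(jx)]
      right_ids <- ly$contig_id[(jx + 1L):nrow(ly)]
      span <- 0L
      for (bi in seq_len(nrow(hb))) {
        a <- hb$contig_a[bi]; b <- hb$contig_b[bi]
        al <- a %in% left_ids; bl <- b %in% left_ids
        ar <- a %in% right_ids; br <- b %in% right_ids
        if (!((al && br) || (ar && bl))) next
        pa <- ly[ly$contig_id == a]; pb <- ly[ly$contig_id == b]
        oa <- substr(hb$orient[bi], 1L, 1L); ob <- substr(hb$orient[bi], 2L, 2L)
        if (pa$start[1L] < pb$start[1L]) {
          consistent <- pa$orient[1L] == oa && pb$orient[1L] == ob
          exp_gap <- pb$start[1L] - pa$end[1L]
        } else {
          consistent <- pb$orient[1L] == .flip(ob) && pa$orient[1L] == .flip(oa)
          exp_gap <- pa$start[1L] - pb$end[1L]
        }
        tol <- 3 * hb$gap_sd[bi] + 3 * max_sd
        if (consistent && abs(exp_gap - hb$gap_mean[bi]) <= tol)
          span <- span + hb$support[bi]
      }
      if (span > 0L) next
      adj_ids <- c(ly$contig_id[jx], ly$contig_id[jx + 1L])
      elsewhere <- hb[(hb$contig_a %in% adj_ids &
                         !(hb$contig_b %in% ly$contig_id)) |
                      (hb$contig_b %in% adj_ids &
                         !(hb$contig_a %in% ly$contig_id))]
      if (sum(elsewhere$support) >= min_support) {
        n_cut <- n_cut + 1L
        cuts[[length(cuts) + 1L]] <- c(sid, jx)
      }
    }
  }
  if (!length(cuts)) {
    attr(scaffolds, "n_cut") <- 0L
    return(scaffolds)
  }
  out <- copy(scaffolds)
  out[, grp := 0L]
  for (cc in cuts) {
    sel <- out$scaffold_id == cc[1L] & out$part_index > cc[2L]
    out[sel, grp := grp + 1L]
  }
  out[, scaffold_id := as.integer(factor(paste(scaffold_id, grp)))]
  out[, grp := NULL]
  out <- out[order(scaffold_id, part_index)]
  out[, part_index := seq_len(.N), by = "scaffold_id"]
  out[, gap_after := c(head(gap_after, -1L), NA_real_), by = "scaffold_id"]
  out <- .renumber_scaffolds(out, contigs)
  attr(out, "n_cut") <- n_cut
  out
}

#' Recover weakly supported links by topology
#'
#' A weak candidate bundle (support below the acceptance threshold) is
#' accepted when the accepted bundle graph already implies the same layout
#' through a consistent two-link chain (same orientations, summed gap
#' within 3 pooled standard deviations), or when it is the unique candidate
#' joining two otherwise dead scaffold ends. Accepted joins are tagged
#' `recovered`; a weak link duplicating an existing join is ignored.
#'
#' @param scaffolds scaffold data.table after primary linearization.
#' @param contigs contig data.table.
#' @param bundles full bundle table (statuses `accepted` and `weak` used).
#' @return list with `joins` (recovered bundle rows) and `scaffolds`
#'   (with the recovered joins applied where both ends were free).
#' @export
recover_weak_links <- function(scaffolds, contigs, bundles) {
  acc <- bundles[bundles$status == "accepted"]
  weak <- bundles[bundles$status == "weak"]
  if (nrow(weak) == 0L)
    return(list(joins = weak, scaffolds = scaffolds))
  layout <- .scaffold_layout(scaffolds, contigs)
  dir_acc <- rbind(
    data.table(from = acc$contig_a, fs = substr(acc$orient, 1L, 1L),
               to = acc$contig_b, ts = substr(acc$orient, 2L, 2L),
               gap = acc$gap_mean, sdv = acc$gap_sd),
    data.table(from = acc$contig_b, fs = .flip(substr(acc$orient, 2L, 2L)),
               to = acc$contig_a, ts = .flip(substr(acc$orient, 1L, 1L)),
               gap = acc$gap_mean, sdv = acc$gap_sd))
  lens <- setNames(contigs$length, as.character(contigs$id))

  # which (contig, end) sits exposed at a scaffold end?
  ly <- layout[order(scaffold_id, part_index)]
  ends <- rbindlist(lapply(unique(ly$scaffold_id), function(s) {
    p <- ly[ly$scaffold_id == s]
    rbind(data.table(contig = p$contig_id[1L],
                     end = if (p$orient[1L] == "+") "L" else "R"),
          data.table(contig = p$contig_id[nrow(p)],
                     end = if (p$orient[nrow(p)] == "+") "R" else "L"))
  }))
  end_key <- paste0(ends$contig, ":", ends$end)

  accepted_rows <- integer(0)
  for (i in seq_len(nrow(weak))) {
    a <- weak$contig_a[i]; b <- weak$contig_b[i]
    oa <- substr(weak$orient[i], 1L, 1L); ob <- substr(weak$orient[i], 2L, 2L)
    # already joined (adjacent in one scaffold)?
    pa <- layout[layout$contig_id == a]; pb <- layout[layout$contig_id == b]
    if (nrow(pa) && nrow(pb) && pa$scaffold_id[1L] == pb$scaffold_id[1L]) next
    # (i) two-link chain a -> c -> b implying the same layout
    ok <- FALSE
    e1s <- dir_acc[dir_acc$from == a & dir_acc$fs == oa]
    if (nrow(e1s)) for (x in seq_len(nrow(e1s))) {
      c_id <- e1s$to[x]
      e2s <- dir_acc[dir_acc$from == c_id & dir_acc$fs == e1s$ts[x] &
                       dir_acc$to == b & dir_acc$ts == ob]
      if (!nrow(e2s)) next
      comp <- e1s$gap[x] + lens[[as.character(c_id)]] + e2s$gap[1L]
      tol <- 3 * sqrt(weak$gap_sd[i]^2 + e1s$sdv[x]^2 + e2s$sdv[1L]^2)
      if (abs(weak$gap_mean[i] - comp) <= tol) { ok <- TRUE; break }
    }
    # (ii) unique candidate between two dead ends
    if (!ok) {
      a_end <- paste0(a, ":", if (oa == "+") "R" else "L")
      b_end <- paste0(b, ":", if (ob == "+") "L" else "R")
      if (a_end %in% end_key && b_end %in% end_key) {
        competing <- weak[-i][(weak$contig_a[-i] %in% c(a, b)) |
                                (weak$contig_b[-i] %in% c(a, b))]
        acc_touch <- acc[(acc$contig_a %in% c(a, b)) |
                           (acc$contig_b %in% c(a, b))]
        if (nrow(competing) == 0L && nrow(acc_touch) == 0L) ok <- TRUE
      }
    }
    if (ok) accepted_rows <- c(accepted_rows, i)
  }
  joins <- weak[accepted_rows]
  if (nrow(joins)) {
    joins[, status := "recovered"]
    merged <- build_scaffolds(
      contigs[contigs$id %in% layout$contig_id],
      rbind(acc, joins), libraries = list(), min_support = 1L,
      rectify = FALSE)
    return(list(joins = joins, scaffolds = merged))
  }
  list(joins = joins, scaffolds = scaffolds)
}

#' Render scaffold sequences
#'
#' Internal gaps are rendered as runs of `N`: the rounded gap estimate
#' clamped to at least `min_wildcard` characters (negative estimates are
#' kept internally for gap closing but render as the minimum wildcard run).
#'
#' @param scaffolds scaffold data.table.
#' @param contigs contig data.table (`id`, `seq`).
#' @param min_wildcard minimum rendered gap length (default 1).
#' @return data.table with `id` (`scaffold_<n>`) and `seq`.
#' @export
scaffold_seq <- function(scaffolds, contigs, min_wildcard = 1L) {
  cs <- setNames(contigs$seq, as.character(contigs$id))
  out <- scaffolds[order(scaffold_id, part_index)][, .(seq = {
    pieces <- character(0)
    for (i in seq_len(.N)) {
      s <- cs[[as.character(contig_id[i])]]
      if (orient[i] == "-") s <- revcomp(s)
      pieces <- c(pieces, s)
      if (i < .N)
        pieces <- c(pieces, strrep("N", max(round(gap_after[i]), min_wildcard)))
    }
    paste(pieces, collapse = "")
  }), by = "scaffold_id"]
  data.table(id = sprintf("scaffold_%d", out$scaffold_id), seq = out$seq)
}

#' Export scaffolds as an AGP-like placement table
#'
#' @param scaffolds scaffold data.table.
#' @param contigs contig data.table.
#' @param path output TSV.
#' @export
write_scaffold_agp <- function(scaffolds, contigs, path) {
  layout <- .scaffold_layout(scaffolds, contigs)
  write.table(layout[, c("scaffold_id", "part_index", "contig_id", "orient",
                         "start", "end", "gap_after"), with = FALSE],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
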