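#' Build a dense de Bruijn graph from reads
#'
#' Nodes are the canonical k-mers of the reads; an edge (a canonical
#' (k+1)-mer) is recorded for every adjacent k-mer pair within a read, with
#' multiplicity equal to the number of supporting windows. The construction
#' is deterministic and invariant to read order, and the graph is
#' strand-symmetric by construction.
#'
#' @param reads character vector of sequences or a data.table with `seq`.
#' @param k odd k-mer size, `>= 3` (`>= 13` recommended for real use).
#' @return an object of class `dbg`: fields `k`, `nodes` (data.table
#'   `kmer`, `count`) and `edges` (data.table `kmer`, `count`, `protected`).
#' @export
build_dbg <- function(reads, k) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  k <- as.integer(k)
  if (k < 3L) stop("k must be >= 3")
  if (k %% 2L == 0L) stop("k must be odd (self-reverse-complement k-mers are not allowed)")
  res <- build_dbg_cpp(seqs, k)
  if (length(res$node_kmer) == 0L) warning("no valid k-mers; graph is empty")
  .new_dbg(k,
           data.table(kmer = res$node_kmer, count = res$node_count),
           data.table(kmer = res$edge_kmer, count = res$edge_count,
                      protected = rep(FALSE, length(res$edge_kmer))))
}

.new_dbg <- function(k, nodes, edges) {
  structure(list(k = as.integer(k), nodes = nodes, edges = edges),
            class = "dbg")
}

#' @export
print.dbg <- function(x, ...) {
  cat(sprintf("<dbg k=%d: %d nodes, %d edges>\n", x$k, nrow(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Build a sparse de Bruijn graph
#'
#' Along unbranched stretches only every g-th k-mer is stored as an anchor,
#' with the skipped bases kept as the anchor's extension string; anchors are
#' forced at branching or merging positions (unitig boundaries). The spelled
#' sequence set of the graph's maximal paths equals that of the dense graph
#' built from the same reads at the same k, which is the contract every
#' consumer relies on. Anchors are derived deterministically from the
#' canonical k-mer and edge sets, so the result is read-order invariant.
#'
#' @inheritParams build_dbg
#' @param g skip factor, `>= 1` (`g = 1` stores every k-mer and is
#'   node-for-node isomorphic to the dense graph).
#' @return an object of class `sparse_dbg`: fields `k`, `g`, `anchors`
#'   (data.table `anchor`, `ext`, `cov`), `junction_edges` (the (k+1)-mer
#'   edges joining unitig boundaries) and `n_anchors`.
#' @export
build_sparse_dbg <- function(reads, k, g = 4L) {
  g <- as.integer(g)
  stopifnot(g >= 1L)
  dense <- build_dbg(reads, k)
  uni <- extract_unitigs(dense)
  anchors <- vector("list", nrow(uni))
  path_nodes <- character(0)
  for (i in seq_len(nrow(uni))) {
    s <- uni$seq[i]
    n_km <- nchar(s) - k + 1L
    pos <- unique(c(seq(0L, n_km - 1L, by = g), n_km - 1L))
    km <- substring(s, pos + 1L, pos + k)
    nxt <- c(pos[-1L], nchar(s) - k + 1L)
    ext <- substring(s, pos + k + 1L, nxt + k)
    ext[length(ext)] <- ""
    anchors[[i]] <- data.table(unitig = i, anchor = km, ext = ext,
                               cov = uni$mean_coverage[i])
  }
  anchors <- rbindlist(anchors)
  # edges between unitig boundary k-mers: any dense edge not interior to a
  # single unitig path
  interior <- unlist(lapply(seq_len(nrow(uni)), function(i) {
    s <- uni$seq[i]
    if (nchar(s) < k + 1L) return(character())
    canonical_cpp(substring(s, 1:(nchar(s) - k), (k + 1L):nchar(s)))
  }))
  jedges <- dense$edges[!dense$edges$kmer %in% interior]
  structure(list(k = as.integer(k), g = g, anchors = anchors,
                 junction_edges = jedges, n_anchors = nrow(anchors)),
            class = "sparse_dbg")
}

#' @export
print.sparse_dbg <- function(x, ...) {
  cat(sprintf("<sparse_dbg k=%d g=%d: %d anchors, %d junction edges>\n",
              x$k, x$g, x$n_anchors, nrow(x$junction_edges)))
  invisible(x)
}

#' Lower a sparse graph to its equivalent dense view
#'
#' Re-expands anchors and extensions into the full canonical k-mer and edge
#' sets so cleaning and unitig extraction are written once against the dense
#' interface. Node and edge multiplicities along a group are the group's
#' mean coverage (rounded, at least 1); junction edges keep their exact
#' multiplicities.
#'
#' @param x a `sparse_dbg`.
#' @return a `dbg`.
#' @export
as_dense_dbg <- function(x) {
  if (inherits(x, "dbg")) return(x)
  stopifnot(inherits(x, "sparse_dbg"))
  k <- x$k
  # anchor[j] starts where ext[j-1] ends, so the spelled group sequence is
  # anchor[1] followed by every extension string
  per_uni <- x$anchors[, .(seq = paste0(anchor[1L], paste(ext, collapse = "")),
                           cov = cov[1L]), by = "unitig"]
  nodes <- list(); edges <- list()
  for (i in seq_len(nrow(per_uni))) {
    s <- per_uni$seq[i]
    m <- max(1, round(per_uni$cov[i]))
    km <- canonical_cpp(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
    nodes[[i]] <- data.table(kmer = km, count = m)
    if (nchar(s) >= k + 1L) {
      ek <- canonical_cpp(substring(s, 1:(nchar(s) - k), (k + 1L):nchar(s)))
      edges[[i]] <- data.table(kmer = ek, count = m)
    }
  }
  nodes <- rbindlist(nodes)
  nodes <- nodes[, .(count = max(count)), by = "kmer"]
  edges <- rbindlist(c(edges, list(x$junction_edges[, c("kmer", "count")])))
  edges <- edges[, .(count = max(count)), by = "kmer"]
  edges[, protected := FALSE]
  setorder(nodes, kmer); setorder(edges, kmer)
  .new_dbg(k, nodes, edges)
}

.as_dbg <- function(graph) {
  if (inherits(graph, "sparse_dbg")) as_dense_dbg(graph) else graph
}

.prot <- function(graph) {
  if ("protected" %in% names(graph$edges)) graph$edges$protected
  else rep(FALSE, nrow(graph$edges))
}

#' Clip short dead-end tips
#'
#' Dead-end chains (one endpoint with degree 0) whose spelled length is
#' shorter than `max_tip_len` and whose mean edge coverage is below the best
#' sibling edge at their attachment junction are deleted; applied
#' iteratively to fixpoint. Tips containing protected edges are retained.
#'
#' @param graph a `dbg` (or `sparse_dbg`, lowered first).
#' @param max_tip_len maximum spelled tip length in bp, `>= k` (default 2k).
#' @return the cleaned `dbg`.
#' @export
clip_tips <- function(graph, max_tip_len = NULL) {
  graph <- .as_dbg(graph)
  if (is.null(max_tip_len)) max_tip_len <- 2L * graph$k
  stopifnot(max_tip_len >= graph$k)
  res <- clip_tips_cpp(graph$nodes$kmer, graph$nodes$count,
                       graph$edges$kmer, graph$edges$count, .prot(graph),
                       graph$k, as.integer(max_tip_len))
  .new_dbg(graph$k,
           data.table(kmer = res$node_kmer, count = res$node_count),
           data.table(kmer = res$edge_kmer, count = res$edge_count,
                      protected = res$edge_protected))
}

#' Pop small bubbles
#'
#' Two parallel simple paths sharing a source and a sink whose spelled
#' sequences align within `max_divergence` (edit distance over the longer
#' length) are merged: the lower-coverage path is folded into the
#' higher-coverage one and its multiplicities added; coverage ties are
#' broken toward the lexicographically smaller spelled sequence. Paths
#' longer than `max_path_len` bp are never considered, which keeps long
#' haplotype-scale divergent regions intact.
#'
#' @param graph a `dbg` (or `sparse_dbg`).
#' @param max_divergence maximum per-base divergence between the two path
#'   spellings (typical `<= 0.1`; default 0.03). A value of 0 disables
#'   popping of non-identical paths.
#' @param max_path_len maximum spelled branch length considered (default
#'   500 bp).
#' @return the cleaned `dbg`.
#' @export
pop_bubbles <- function(graph, max_divergence = 0.03, max_path_len = 500L) {
  graph <- .as_dbg(graph)
  stopifnot(max_divergence >= 0, max_divergence <= 1)
  res <- pop_bubbles_cpp(graph$nodes$kmer, graph$nodes$count,
                         graph$edges$kmer, graph$edges$count, .prot(graph),
                         graph$k, max_divergence, as.integer(max_path_len))
  .new_dbg(graph$k,
           data.table(kmer = res$node_kmer, count = res$node_count),
           data.table(kmer = res$edge_kmer, count = res$edge_count,
                      protected = res$edge_protected))
}

#' Remove low-coverage edges
#'
#' Edges with multiplicity `<= cutoff` are removed (protected edges are
#' kept); nodes that thereby lose all incident edges are removed with them.
#' `cutoff = 0` is the identity.
#'
#' @param graph a `dbg` (or `sparse_dbg`).
#' @param cutoff non-negative multiplicity cutoff.
#' @return the filtered `dbg`.
#' @export
remove_low_coverage <- function(graph, cutoff = 1L) {
  graph <- .as_dbg(graph)
  stopifnot(cutoff >= 0)
  if (cutoff == 0L || nrow(graph$edges) == 0L) return(graph)
  keep <- graph$edges$count > cutoff | .prot(graph)
  ep_before <- edge_endpoints_cpp(graph$edges$kmer, graph$k)
  had_edge <- unique(c(ep_before$from, ep_before$to))
  edges <- graph$edges[keep]
  if (nrow(edges)) {
    ep_after <- edge_endpoints_cpp(edges$kmer, graph$k)
    has_edge <- unique(c(ep_after$from, ep_after$to))
  } else has_edge <- character()
  lost <- setdiff(had_edge, has_edge)
  nodes <- graph$nodes[!graph$nodes$kmer %in% lost]
  .new_dbg(graph$k, nodes, edges)
}

#' Extract unitigs
#'
#' Maximal unbranched paths of the graph, spelled into sequences and
#' reported once each in canonical orientation (the lexicographically
#' smaller of the sequence and its reverse complement). `mean_coverage` is
#' the mean edge multiplicity along the path (node count for single-k-mer
#' unitigs). Ordering is deterministic: length descending, then sequence
#' ascending.
#'
#' @param graph a `dbg` (or `sparse_dbg`).
#' @return a data.table with columns `id`, `seq`, `length`,
#'   `mean_coverage`, `in_degree_start`, `out_degree_end`.
#' @export
extract_unitigs <- function(graph) {
  graph <- .as_dbg(graph)
  if (nrow(graph$nodes) == 0L)
    return(data.table(id = integer(), seq = character(), length = integer(),
                      mean_coverage = numeric(), in_degree_start = integer(),
                      out_degree_end = integer()))
  res <- extract_unitigs_cpp(graph$nodes$kmer, graph$nodes$count,
                             graph$edges$kmer, graph$edges$count, graph$k)
  data.table(id = seq_along(res$seq), seq = res$seq,
             length = nchar(res$seq), mean_coverage = res$mean_coverage,
             in_degree_start = res$in_degree_start,
             out_degree_end = res$out_degree_end)
}

#' Dump a graph in GFA v1
#'
#' Unitigs become S lines; L lines carry the (k-1)-overlap connections
#' between unitig ends implied by the remaining edges.
#'
#' @param graph a `dbg` (or `sparse_dbg`).
#' @param path output file.
#' @export
write_gfa <- function(graph, path) {
  graph <- .as_dbg(graph)
  uni <- extract_unitigs(graph)
  k <- graph$k
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  for (i in seq_len(nrow(uni)))
    writeLines(sprintf("S\tu%d\t%s\tdp:f:%.2f", uni$id[i], uni$seq[i],
                       uni$mean_coverage[i]), con)
  if (nrow(uni) > 1L && nrow(graph$edges)) {
    ends <- rbindlist(lapply(seq_len(nrow(uni)), function(i) {
      s <- uni$seq[i]
      data.table(uid = uni$id[i],
                 kmer = c(substr(s, 1L, k), substr(s, nchar(s) - k + 1L, nchar(s))),
                 side = c("start", "end"))
    }))
    ep <- edge_endpoints_cpp(graph$edges$kmer, k)
    for (j in seq_len(nrow(graph$edges))) {
      e <- graph$edges$kmer[j]
      pre <- substr(e, 1L, k); suf <- substr(e, 2L, k + 1L)
      a <- ends[canonical_cpp(ends$kmer) == canonical_cpp(pre) & ends$side == "end"]
      b <- ends[canonical_cpp(ends$kmer) == canonical_cpp(suf) & ends$side == "start"]
      if (nrow(a) && nrow(b) && a$uid[1L] != b$uid[1L])
        writeLines(sprintf("L\tu%d\t+\tu%d\t+\t%dM", a$uid[1L], b$uid[1L],
                           k - 1L), con)
    }
  }
  invisible(path)
}

#' Write unitigs as FASTA with coverage headers
#'
#' @param unitigs data.table from [extract_unitigs()].
#' @param path output file.
#' @export
write_unitigs <- function(unitigs, path) {
  recs <- data.table(id = sprintf("unitig_%d cov=%.2f", unitigs$id,
                                  unitigs$mean_coverage),
                     seq = unitigs$seq)
  write_assembly(recs, path)
}
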