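#' Multi-k assembly plan
#'
#' @param k_min,k_max odd k-mer sizes with `k_min <= k_max`.
#' @param step even positive increment between rounds (even keeps k odd);
#'   default 8.
#' @return an object of class `multik_plan` with the per-round k values.
#' @export
multik_plan <- function(k_min, k_max, step = 8L) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max); step <- as.integer(step)
  if (k_min %% 2L == 0L || k_max %% 2L == 0L) stop("k_min and k_max must be odd")
  if (k_min > k_max) stop("k_min must be <= k_max")
  if (step <= 0L || step %% 2L != 0L) stop("step must be a positive even integer")
  ks <- seq(k_min, k_max, by = step)
  if (ks[length(ks)] != k_max) ks <- c(ks, k_max)
  structure(list(k_min = k_min, k_max = k_max, step = step, rounds = ks),
            class = "multik_plan")
}

#' Map reads to contigs by full-length ungapped placement
#'
#' For each read, the best full-length ungapped placement on either strand:
#' fewest mismatches, then smallest contig id, then smallest offset (ties
#' between strands resolve to `+`). Reads without a placement at
#' `<= max_mismatch` are omitted. Contigs are indexed by exact seeds;
#' with three seeds per read, any placement with `max_mismatch <= 2`
#' mismatches is guaranteed to be found for reads of at least
#' `3 * seed_len` bp.
#'
#' @param reads data.table with `id` and `seq`, or character vector.
#' @param contigs data.table with `id` and `seq` (e.g. from
#'   [extract_unitigs()]), or character vector.
#' @param max_mismatch maximum mismatches for a reported placement.
#' @param seed_len exact seed length (default 31, capped at the shortest
#'   read).
#' @return a data.table with columns `read_id`, `contig_id`, `offset`
#'   (0-based), `strand` (`"+"`/`"-"`), `mismatches`, `read_len`.
#' @export
map_reads_to_contigs <- function(reads, contigs, max_mismatch = 2L,
                                 seed_len = 31L) {
  rdt <- if (is.data.frame(reads)) as.data.table(reads)
         else data.table(id = sprintf("read%d", seq_along(reads)),
                         seq = as.character(reads))
  cdt <- if (is.data.frame(contigs)) as.data.table(contigs)
         else data.table(id = seq_along(contigs), seq = as.character(contigs))
  if (nrow(rdt) == 0L || nrow(cdt) == 0L)
    return(data.table(read_id = character(), contig_id = cdt$id[0],
                      offset = integer(), strand = character(),
                      mismatches = integer(), read_len = integer()))
  seed_len <- min(as.integer(seed_len), min(nchar(rdt$seq)))
  res <- map_reads_cpp(rdt$seq, cdt$seq, as.integer(max_mismatch), seed_len)
  data.table(read_id = rdt$id[res$read_idx],
             contig_id = cdt$id[res$contig_idx],
             offset = res$offset,
             strand = ifelse(res$strand > 0L, "+", "-"),
             mismatches = res$mismatches,
             read_len = nchar(rdt$seq[res$read_idx]))
}

#' Single-k contig assembly
#'
#' Build (dense or sparse) graph, remove low-coverage edges, clip tips, pop
#' bubbles, extract unitigs.
#'
#' @param reads reads (character vector or data.table with `seq`).
#' @param k odd k-mer size.
#' @param sparse build the graph sparsely with skip factor `g`.
#' @param g sparse skip factor (default 4).
#' @param cov_cutoff low-coverage edge cutoff (default 1).
#' @param max_tip_len maximum tip length (default `2 * k`).
#' @param bubble_divergence bubble-popping divergence (default 0.03; set to
#'   0 to keep haplotype bubbles for scaffold-stage resolution on diploid
#'   input).
#' @param max_bubble_len maximum bubble branch length (default 500 bp).
#' @return unitig data.table as from [extract_unitigs()].
#' @export
assemble_contigs <- function(reads, k, sparse = FALSE, g = 4L,
                             cov_cutoff = 1L, max_tip_len = NULL,
                             bubble_divergence = 0.03,
                             max_bubble_len = 500L) {
  graph <- if (sparse) build_sparse_dbg(reads, k, g) else build_dbg(reads, k)
  graph <- .as_dbg(graph)
  graph <- remove_low_coverage(graph, cov_cutoff)
  graph <- clip_tips(graph, max_tip_len)
  if (bubble_divergence > 0)
    graph <- pop_bubbles(graph, bubble_divergence, max_bubble_len)
  extract_unitigs(graph)
}

#' Iterative multi-k contig assembly
#'
#' Round 1 builds and cleans the graph at `k_min`. Each later round (k
#' increased by `step`) rebuilds the graph from the reads threaded against
#' the previous round's unitigs together with those unitigs injected as
#' pseudo-reads; edges supported only by pseudo-reads are protected from
#' error-removal cleaning so assembled sequence is never lost when read
#' coverage at the larger k drops below cleaning thresholds. Unplaced reads
#' still contribute k-mers but get no protection, so spurious edges they
#' create face the low-coverage filter. The final round's unitigs are
#' returned with per-contig mean read depth recomputed by
#' [map_reads_to_contigs()].
#'
#' @param reads reads (character vector or data.table with `id`, `seq`).
#' @param plan a [multik_plan()].
#' @param sparse,g sparse-graph options for every round.
#' @param max_mismatch read-threading placement tolerance (default 2).
#' @param cov_cutoff,max_tip_len,bubble_divergence,max_bubble_len cleaning
#'   parameters, as in [assemble_contigs()].
#' @param keep_rounds return intermediate unitigs of every round in the
#'   `rounds` attribute.
#' @return unitig data.table with an additional `read_depth` column.
#' @export
assemble_multik <- function(reads, plan, sparse = FALSE, g = 4L,
                            max_mismatch = 2L, cov_cutoff = 1L,
                            max_tip_len = NULL, bubble_divergence = 0.03,
                            max_bubble_len = 500L, keep_rounds = FALSE) {
  stopifnot(inherits(plan, "multik_plan"))
  rdt <- if (is.data.frame(reads)) as.data.table(reads)
         else data.table(id = sprintf("read%d", seq_along(reads)),
                         seq = as.character(reads))
  min_rl <- min(nchar(rdt$seq))
  if (plan$k_max >= min_rl)
    stop("plan error: k_max must be smaller than the minimum read length")

  uni <- assemble_contigs(rdt, plan$rounds[1L], sparse = sparse, g = g,
                          cov_cutoff = cov_cutoff, max_tip_len = max_tip_len,
                          bubble_divergence = bubble_divergence,
                          max_bubble_len = max_bubble_len)
  rounds <- list(uni)
  for (kk in plan$rounds[-1L]) {
    read_part <- build_dbg_cpp(rdt$seq, kk)
    pseudo_part <- build_dbg_cpp(uni$seq, kk)
    edges <- merge(
      data.table(kmer = read_part$edge_kmer, n_read = read_part$edge_count),
      data.table(kmer = pseudo_part$edge_kmer, n_pseudo = pseudo_part$edge_count),
      by = "kmer", all = TRUE)
    edges[is.na(edges)] <- 0
    edges[, `:=`(count = n_read + n_pseudo,
                 protected = n_read == 0 & n_pseudo > 0)]
    nodes <- merge(
      data.table(kmer = read_part$node_kmer, n_read = read_part$node_count),
      data.table(kmer = pseudo_part$node_kmer, n_pseudo = pseudo_part$node_count),
      by = "kmer", all = TRUE)
    nodes[is.na(nodes)] <- 0
    nodes[, count := n_read + n_pseudo]
    graph <- .new_dbg(kk, nodes[, c("kmer", "count")],
                      edges[, c("kmer", "count", "protected")])
    graph <- remove_low_coverage(graph, cov_cutoff)
    graph <- clip_tips(graph, max_tip_len)
    if (bubble_divergence > 0)
      graph <- pop_bubbles(graph, bubble_divergence, max_bubble_len)
    uni <- extract_unitigs(graph)
    rounds[[length(rounds) + 1L]] <- uni
  }
  uni[, read_depth := contig_read_depth(rdt, uni, max_mismatch = max_mismatch)]
  if (keep_rounds) attr(uni, "rounds") <- rounds
  uni[]
}

#' Per-contig mean read depth
#'
#' Depth of each contig as total placed read bases divided by contig
#' length, using best full-length placements.
#'
#' @param reads reads (data.table with `id`, `seq`, or character vector).
#' @param contigs unitig data.table (`id`, `seq`, `length`).
#' @param max_mismatch placement tolerance.
#' @return numeric vector of depths aligned with `contigs` rows.
#' @export
contig_read_depth <- function(reads, contigs, max_mismatch = 2L) {
  pl <- map_reads_to_contigs(reads, contigs, max_mismatch = max_mismatch)
  if (nrow(pl) == 0L) return(rep(0, nrow(contigs)))
  agg <- pl[, .(bases = sum(read_len)), by = "contig_id"]
  depth <- rep(0, nrow(contigs))
  idx <- match(agg$contig_id, contigs$id)
  depth[idx] <- agg$bases / contigs$length[idx]
  depth
}
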