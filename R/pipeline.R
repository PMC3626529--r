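#' Run the full assembly pipeline
#'
#' Error correction, contig assembly (single-k or multi-k, dense or sparse
#' graph), paired-end mapping, hierarchical scaffolding (heterozygous-pair
#' masking, chimera rectification, weak-link recovery) and gap closing, in
#' one call. Every stage's intermediate result is returned so each can be
#' inspected and tested.
#'
#' @param pe_libs list of simulated or parsed paired libraries: each
#'   `list(read1 =, read2 =, pairs =, library = <name>)`.
#' @param libraries list of [pe_library()] objects matching the `library`
#'   names in `pe_libs`.
#' @param k odd k-mer size for single-k assembly (ignored when `plan` is
#'   given).
#' @param plan optional [multik_plan()] for iterative multi-k assembly.
#' @param correct run spectrum-based error correction first (default TRUE).
#' @param correct_k correction k-mer size (default 21).
#' @param diploid treat input as diploid: keep haplotype bubbles at the
#'   contig stage (popping off) and resolve allelic contigs at the scaffold
#'   stage by depth (default FALSE).
#' @param sparse,g sparse-graph construction options.
#' @param min_support bundle acceptance support (default 3).
#' @param close run gap closing (default TRUE).
#' @param max_cycles gap-closing cycle cap.
#' @return a list with elements `reads` (post-correction),
#'   `correction_summary`, `contigs`, `depth`, `placements`, `links`,
#'   `bundles`, `het_pairs`, `masked`, `scaffolds` (part table),
#'   `scaffold_seqs` (rendered, gaps filled when `close = TRUE`),
#'   `gap_results`.
#' @export
run_assembly <- function(pe_libs, libraries, k = 31L, plan = NULL,
                         correct = TRUE, correct_k = 21L, diploid = FALSE,
                         sparse = FALSE, g = 4L, min_support = 3L,
                         close = TRUE, max_cycles = 10L) {
  correction_summary <- NULL
  if (correct) {
    allseq <- unlist(lapply(pe_libs, function(p) c(p$read1$seq, p$read2$seq)))
    spec <- count_kmers(allseq, correct_k)
    spec <- set_trusted_cutoff(spec, "auto")
    for (i in seq_along(pe_libs)) {
      c1 <- correct_library(pe_libs[[i]]$read1, spec, mode = "fast_then_deep")
      c2 <- correct_library(pe_libs[[i]]$read2, spec, mode = "fast_then_deep")
      pe_libs[[i]]$read1 <- c1$reads
      pe_libs[[i]]$read2 <- c2$reads
      correction_summary <- if (is.null(correction_summary))
        c1$summary + c2$summary else correction_summary + c1$summary + c2$summary
    }
  }
  all_reads <- rbindlist(lapply(pe_libs, function(p)
    rbind(p$read1[, c("id", "seq")], p$read2[, c("id", "seq")])))
  bubble_div <- if (diploid) 0 else 0.03
  pairs <- rbindlist(lapply(pe_libs, function(p) p$pairs))
  het <- data.table(kept_id = integer(), dropped_id = integer())
  het_dropped <- NULL
  masked <- integer(0)
  contigs <- if (!is.null(plan)) {
    assemble_multik(all_reads, plan, sparse = sparse, g = g,
                    bubble_divergence = bubble_div)
  } else {
    u <- assemble_contigs(all_reads, k, sparse = sparse, g = g,
                          bubble_divergence = bubble_div)
    u[, read_depth := contig_read_depth(all_reads, u)]
    u
  }
  if (diploid && is.null(plan)) {
    # detect allelic pairs on the bubble-preserving assembly, keep the
    # higher-depth member, and re-extract contigs from the graph with the
    # dropped allele's exclusive k-mers removed so the haplotypes merge.
    # Iterated to fixpoint: merging neighbors consolidates fragmented
    # allelic stretches, whose pairs only then become detectable.
    graph <- build_dbg(all_reads, k)
    graph <- remove_low_coverage(graph, 1L)
    graph <- clip_tips(graph)
    dropped_all <- list()
    for (pass in 1:10) {
      placements0 <- map_reads_to_contigs(all_reads, contigs)
      links0 <- collect_pe_links(placements0, pairs, libraries, contigs)
      bundles0 <- bundle_links(links0, min_support = min_support)
      het_pass <- detect_het_pairs(contigs, bundles0, contigs$mean_coverage,
                                   contig_k = k)
      if (nrow(het_pass) == 0L) break
      het <- rbind(het, het_pass)
      dropped_all[[pass]] <- contigs[contigs$id %in% het_pass$dropped_id,
                                     c("id", "seq", "length")]
      drop_km <- count_kmers(dropped_all[[pass]]$seq, k)$kmer
      keep_km <- count_kmers(
        contigs$seq[!contigs$id %in% het_pass$dropped_id], k)$kmer
      rm_km <- setdiff(drop_km, keep_km)
      graph$nodes <- graph$nodes[!graph$nodes$kmer %in% rm_km]
      ep <- edge_endpoints_cpp(graph$edges$kmer, k)
      graph$edges <- graph$edges[!(ep$from %in% rm_km | ep$to %in% rm_km)]
      contigs <- extract_unitigs(graph)
    }
    if (length(dropped_all)) {
      het_dropped <- rbindlist(dropped_all)
      contigs[, read_depth := contig_read_depth(all_reads, contigs)]
    }
  }
  placements <- map_reads_to_contigs(all_reads, contigs)
  links <- collect_pe_links(placements, pairs, libraries, contigs)
  k_used <- if (!is.null(plan)) plan$k_max else k
  bundles <- bundle_links(links, min_support = min_support,
                          gap_clamp = -(k_used - 1L))
  scaffolds <- build_scaffolds(contigs, bundles, libraries,
                               min_support = min_support, masked = masked)
  rec <- recover_weak_links(scaffolds, contigs, bundles)
  scaffolds <- rec$scaffolds
  gap_results <- NULL
  if (close) {
    gc_out <- close_gaps(scaffolds, contigs, pe_libs, libraries,
                         max_cycles = max_cycles)
    scaffold_seqs <- gc_out$scaffolds
    gap_results <- gc_out$results
  } else {
    scaffold_seqs <- scaffold_seq(scaffolds, contigs)
  }
  list(reads = pe_libs, correction_summary = correction_summary,
       contigs = contigs, depth = contigs$read_depth,
       placements = placements, links = links, bundles = bundles,
       het_pairs = het, het_dropped = het_dropped, masked = masked,
       scaffolds = scaffolds, scaffold_seqs = scaffold_seqs,
       gap_results = gap_results, recovered = rec$joins)
}
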