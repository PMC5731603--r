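# Shared fixture builders (all data is generated in code).

# A validated segment object without going through disassembly.
make_segment <- function(id, draft_id, start, end, sequence = NULL,
                         support = data.frame(read_id = "r0", read_start = 0,
                                              read_end = 1, strand = "+",
                                              draft_start = start,
                                              draft_end = end)) {
  if (is.null(sequence))
    sequence <- paste(rep("A", end - start), collapse = "")
  structure(list(segment_id = id, draft_id = draft_id, start = start,
                 end = end, sequence = sequence, support = support),
            class = "validated_segment")
}

# A scaffold_graph from explicit solid edges given as a data.frame with
# seg1, end1, seg2, end2, weight (support geometry optional).
make_graph <- function(segment_ids, solid = NULL) {
  g <- build_graph(segment_ids)
  if (!is.null(solid)) {
    if (is.null(solid$mean_gap)) solid$mean_gap <- 0
    if (is.null(solid$support)) solid$support <- I(rep(list(NULL), nrow(solid)))
    rownames(solid) <- NULL
    g$solid <- solid
  }
  g
}

# Small end-to-end simulation: genome -> structurally corrupted draft
# (no base errors) -> error-free reads -> truth-based aligned blocks.
make_sim <- function(genome_len = 100000, n_pieces = 5, min_piece_len = 10000,
                     coverage = 25, seed = 1) {
  genome <- stats::setNames(random_genome(genome_len, seed = seed), "ref")
  mut <- mutate_assembly(genome, mutation_config(
    n_pieces = n_pieces, min_piece_len = min_piece_len,
    ins_rate = 0, del_rate = 0, mis_rate = 0, revcomp_prob = 0.5,
    seed = seed + 1L))
  sim <- simulate_reads(genome, read_sim_config(
    coverage = coverage, residual_error_rate = 0, seed = seed + 2L))
  blocks <- truth_alignments(sim$truth, mut$layout, nchar(sim$reads))
  list(genome = genome, mut = mut, sim = sim, blocks = blocks)
}

random_blocks_table <- function(n = 20) {
  DL <- sample.int(10000, n)
  RL <- sample.int(5000, n)
  len <- sample(30:500, n, replace = TRUE)
  aligned_blocks(
    draft_id = sample(c("c1", "c2"), n, replace = TRUE),
    read_id = sprintf("r%03d", sample.int(50, n, replace = TRUE)),
    DL = DL, DR = DL + len, RL = RL, RR = RL + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    identity = round(runif(n, 0.9, 1), 4)
  )
}
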