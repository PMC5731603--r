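test_that("orient_path emits orientations by traversal direction", {
  # A tail->head, B tail->head: both forward
  p <- c("A:tail", "A:head", "B:tail", "B:head")
  expect_equal(orient_path(p)$orientation, c("+", "+"))
  expect_equal(orient_path(p)$segment_id, c("A", "B"))

  # A tail->head, B head->tail: B reverse complemented
  p <- c("A:tail", "A:head", "B:head", "B:tail")
  expect_equal(orient_path(p)$orientation, c("+", "-"))

  # reversing the walk flips order and orientations
  pr <- rev(p)
  o <- orient_path(pr, canonical = FALSE)
  expect_equal(o$segment_id, c("B", "A"))
  expect_equal(o$orientation, c("+", "-"))
  # canonical choice picks the direction starting at the smaller id
  expect_equal(orient_path(pr)$segment_id, c("A", "B"))
})

test_that("fill_gap selects the best-identity read and handles overlaps", {
  sup <- data.frame(seg1 = "A", end1 = "head", seg2 = "B", end2 = "tail",
                    read_id = c("r1", "r2"), gap = c(200, 200),
                    gap_start = c(100, 100), gap_end = c(300, 300),
                    strand1 = "+", strand2 = "+",
                    identity = c(0.95, 0.99), span = c(500, 400))
  edge <- data.frame(seg1 = "A", end1 = "head", seg2 = "B", end2 = "tail",
                     weight = 2, mean_gap = 200, support = I(list(sup)))
  reads <- c(r1 = random_genome(400, seed = 1),
             r2 = random_genome(400, seed = 2))
  fg <- fill_gap(edge[1, ], "A", "+", reads)
  expect_equal(fg$read_id, "r2")                 # higher identity wins
  expect_equal(fg$gap_seq, substr(reads[["r2"]], 101, 300))
  expect_equal(fg$trim, 0L)

  # left part emitted in reverse: the insert is reverse complemented
  fg2 <- fill_gap(edge[1, ], "A", "-", reads)
  expect_equal(fg2$gap_seq, revcomp(substr(reads[["r2"]], 101, 300)))

  # negative junction distance: no insert, trim on the right segment
  sup$gap <- -30
  edge$support <- I(list(sup))
  fg3 <- fill_gap(edge[1, ], "A", "+", reads)
  expect_equal(fg3$gap_seq, "")
  expect_equal(fg3$trim, 30L)

  # missing read is a lookup error
  expect_error(fill_gap(edge[1, ], "A", "+", reads["r1"]), "missing")
})

test_that("assemble_scaffolds reconstructs across gaps and overlaps", {
  truth <- random_genome(2400, seed = 31)
  # segA = truth[1..1000], segB = truth[1201..2400]; a read spans the gap
  segA <- make_segment("segA", "cA", 0, 1000, substr(truth, 1, 1000))
  segB <- make_segment("segB", "cB", 0, 1200, substr(truth, 1201, 2400))
  read <- substr(truth, 801, 1600)  # suffix(A) + 200 gap + prefix(B)
  sup <- data.frame(seg1 = "segA", end1 = "head", seg2 = "segB", end2 = "tail",
                    read_id = "r1", gap = 200, gap_start = 200, gap_end = 400,
                    strand1 = "+", strand2 = "+", identity = 1, span = 800)
  solid <- data.frame(seg1 = "segA", end1 = "head", seg2 = "segB",
                      end2 = "tail", weight = 1, mean_gap = 200,
                      support = I(list(sup)))
  g <- make_graph(c("segA", "segB"), solid)
  cov <- cover_from_matching(g)
  asm <- assemble_scaffolds(cov, list(segA, segB), c(r1 = read), g)
  expect_length(asm$sequences, 1)
  expect_identical(unname(asm$sequences[[1]]), truth)

  # overlapping segments: segB' = truth[971..2400], junction distance -30
  segB2 <- make_segment("segB", "cB", 0, 1430, substr(truth, 971, 2400))
  sup2 <- data.frame(seg1 = "segA", end1 = "head", seg2 = "segB",
                     end2 = "tail", read_id = "r1", gap = -30,
                     gap_start = 0, gap_end = 0,
                     strand1 = "+", strand2 = "+", identity = 1, span = 800)
  solid2 <- data.frame(seg1 = "segA", end1 = "head", seg2 = "segB",
                       end2 = "tail", weight = 1, mean_gap = -30,
                       support = I(list(sup2)))
  g2 <- make_graph(c("segA", "segB"), solid2)
  asm2 <- assemble_scaffolds(cover_from_matching(g2),
                             list(segA, segB2), c(r1 = read), g2)
  expect_identical(unname(asm2$sequences[[1]]), truth)
})

test_that("scaffold sequences are reverse-complement invariant across walks", {
  fx <- make_sim(genome_len = 60000, n_pieces = 3, min_piece_len = 8000,
                 coverage = 25, seed = 71)
  res <- run_pipeline(fx$mut$draft, fx$sim$reads, fx$blocks)
  for (i in seq_along(res$cover$paths)) {
    p <- res$cover$paths[[i]]
    cov_rev <- res$cover
    cov_rev$paths[[i]] <- rev(p)
    asm_rev <- assemble_scaffolds(cov_rev, res$segments, fx$sim$reads,
                                  res$graph)
    # canonicalization makes the reversed walk produce identical output
    expect_identical(sort(unname(asm_rev$sequences)),
                     sort(unname(res$scaffolds)))
  }
  # every validated segment appears in exactly one scaffold exactly once
  expect_setequal(res$layout$segment_id,
                  vapply(res$segments, function(s) s$segment_id, ""))
  expect_equal(anyDuplicated(res$layout$segment_id), 0)
})

test_that("evaluate_scaffolds counts oriented adjacencies against the truth", {
  truth <- data.frame(draft_id = c("p1", "p2", "p3"), ref_id = "ref",
                      ref_start = c(0, 1000, 2000),
                      ref_end = c(1000, 2000, 3000),
                      strand = c("+", "-", "+"), order_index = 0:2)
  segments <- list(make_segment("s1", "p1", 0, 1000),
                   make_segment("s2", "p2", 0, 1000),
                   make_segment("s3", "p3", 0, 1000))
  perfect <- data.frame(scaffold_id = "scaffold_1", part_index = 1:3,
                        segment_id = c("s1", "s2", "s3"),
                        orientation = c("+", "-", "+"),
                        gap_after = 0, trim_after = 0, fill_read = NA)
  res <- list(scaffolds = c(scaffold_1 = paste(rep("A", 3000), collapse = "")),
              layout = perfect, segments = segments)
  rep1 <- evaluate_scaffolds(res, truth)
  expect_equal(rep1$adjacency_precision, 1)
  expect_equal(rep1$adjacency_recall, 1)
  expect_equal(rep1$orientation_accuracy, 1)
  expect_equal(rep1$n50, 3000)

  # splitting at one true adjacency: recall drops by 1/2, precision stays 1
  split_layout <- perfect
  split_layout$scaffold_id <- c("scaffold_1", "scaffold_1", "scaffold_2")
  split_layout$part_index <- c(1, 2, 1)
  res2 <- list(scaffolds = c(scaffold_1 = paste(rep("A", 2000), collapse = ""),
                             scaffold_2 = paste(rep("A", 1000), collapse = "")),
               layout = split_layout, segments = segments)
  rep2 <- evaluate_scaffolds(res2, truth)
  expect_equal(rep2$adjacency_precision, 1)
  expect_equal(rep2$adjacency_recall, 0.5)

  # a wrong-orientation join is a false adjacency
  bad <- perfect
  bad$orientation <- c("+", "+", "+")    # p2 joined in the wrong orientation
  res3 <- list(scaffolds = res$scaffolds, layout = bad, segments = segments)
  rep3 <- evaluate_scaffolds(res3, truth)
  expect_equal(rep3$adjacency_precision, 0)
  expect_equal(rep3$orientation_accuracy, 0)

  # unknown segment ids are a consistency error
  bad2 <- perfect; bad2$segment_id[1] <- "nope"
  expect_error(evaluate_scaffolds(list(scaffolds = res$scaffolds,
                                       layout = bad2, segments = segments),
                                  truth), "unknown segment")
})

test_that("n50 is the standard halfway statistic", {
  expect_equal(rescaf:::n50(c(10000)), 10000)
  expect_equal(rescaf:::n50(c(5, 4, 3, 2, 1)), 4)   # 9 >= 15/2
  expect_equal(rescaf:::n50(integer(0)), 0L)
})

test_that("zero reads produce an empty result", {
  fx <- make_sim(genome_len = 40000, n_pieces = 2, min_piece_len = 8000,
                 coverage = 2, seed = 99)
  res <- run_pipeline(fx$mut$draft, fx$sim$reads[0], fx$blocks[0, ])
  expect_length(res$scaffolds, 0)
  expect_length(res$segments, 0)
})

test_that("the pipeline is a fixed point on an intact draft", {
  # error-free draft with no structural errors: scaffolds reproduce the
  # draft sequences up to end trimming
  genome <- setNames(random_genome(50000, seed = 111), "ref")
  mut <- mutate_assembly(genome, mutation_config(
    n_pieces = 1, min_piece_len = 10, ins_rate = 0, del_rate = 0,
    mis_rate = 0, revcomp_prob = 0, seed = 112))
  sim <- simulate_reads(genome, read_sim_config(coverage = 30,
                                                residual_error_rate = 0,
                                                seed = 113))
  blocks <- truth_alignments(sim$truth, mut$layout, nchar(sim$reads))
  res <- run_pipeline(mut$draft, sim$reads, blocks)
  expect_length(res$scaffolds, 1)
  sc <- unname(res$scaffolds[[1]])
  if (!grepl(sc, genome, fixed = TRUE)) sc <- revcomp(sc)
  expect_true(grepl(sc, genome, fixed = TRUE))
  expect_gte(nchar(sc), 0.99 * 50000)
})

test_that("AGP and report writers emit well-formed tables", {
  fx <- make_sim(genome_len = 60000, n_pieces = 3, min_piece_len = 8000,
                 coverage = 25, seed = 121)
  res <- run_pipeline(fx$mut$draft, fx$sim$reads, fx$blocks)
  fa <- withr::local_tempfile(fileext = ".agp")
  fs <- withr::local_tempfile(fileext = ".tsv")
  write_agp(res, res$segments, fa, fs)
  agp <- readLines(fa)
  expect_equal(agp[1], "##agp-version\t2.1")
  body <- read.table(text = agp[-1], sep = "\t")
  expect_true(all(body$V5 == "W"))
  expect_true(all(body$V3 >= body$V2))
  rep <- evaluate_scaffolds(res, fx$mut$layout)
  fr <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(rep, fr)
  tab <- read.table(fr, header = TRUE, sep = "\t")
  expect_true("adjacency_recall" %in% tab$metric)
})
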