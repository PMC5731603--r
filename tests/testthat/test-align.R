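test_that("parse_coords applies the coordinate and strand conventions", {
  f <- withr::local_tempfile(fileext = ".coords")
  writeLines(c("/path/ref.fa /path/qry.fa", "NUCMER", "",
               paste("[S1]", "[E1]", "[S2]", "[E2]", "[LEN 1]", "[LEN 2]",
                     "[% IDY]", "[TAGS]", sep = "\t"),
               paste(1, 100, 1, 100, 100, 100, "99.00", "refA", "read1", sep = "\t"),
               paste(501, 700, 210, 95, 200, 116, "97.50", "refA", "read2", sep = "\t")),
             f)
  b <- parse_coords(f)
  expect_equal(nrow(b), 2)
  expect_equal(unlist(b[1, c("DL", "DR", "RL", "RR")], use.names = FALSE),
               c(0L, 100L, 0L, 100L))
  expect_equal(b$strand[1], "+")
  expect_equal(b$identity[1], 0.99)
  # reverse-strand row "210 95" normalizes to forward coordinates
  expect_equal(unlist(b[2, c("DL", "DR", "RL", "RR")], use.names = FALSE),
               c(500L, 700L, 94L, 210L))
  expect_equal(b$strand[2], "-")
})

test_that("parse_coords rejects malformed rows and drops degenerate ones", {
  f <- withr::local_tempfile(fileext = ".coords")
  writeLines(c(paste(1, 100, 1, 100, 100, 100, "99.0", "r", "q", sep = "\t"),
               paste(5, 50, 8, sep = "\t")), f)
  expect_error(parse_coords(f), "line 2")
  writeLines(c(paste(1, 100, 1, 100, 100, 100, "99.0", "r", "q", sep = "\t"),
               paste(7, 7, 1, 50, 1, 50, "99.0", "r", "q", sep = "\t")), f)
  expect_message(b <- parse_coords(f), "degenerate")
  expect_equal(nrow(b), 1)
})

test_that("coords tables round-trip through write_coords / parse_coords", {
  withr::local_seed(421)
  for (rep in 1:5) {
    b <- random_blocks_table(25)
    f <- withr::local_tempfile(fileext = ".coords")
    write_coords(b, f)
    b2 <- parse_coords(f)
    expect_equal(b2$DL, b$DL)
    expect_equal(b2$DR, b$DR)
    expect_equal(b2$RL, b$RL)
    expect_equal(b2$RR, b$RR)
    expect_equal(b2$strand, b$strand)
    expect_equal(b2$draft_id, b$draft_id)
    expect_equal(b2$read_id, b$read_id)
    expect_equal(b2$identity, b$identity, tolerance = 1e-4)
  }
})

test_that("trim_overlaps cuts back the left ends of right-hand blocks", {
  # disjoint blocks unchanged
  b <- aligned_blocks("c", "r", DL = c(0, 200), DR = c(100, 300),
                      RL = c(0, 205), RR = c(100, 305))
  expect_equal(trim_overlaps(b), b)

  # draft overlap 10 > read overlap 5: both left ends advance by 10
  b <- aligned_blocks("c", "r", DL = c(0, 90), DR = c(100, 200),
                      RL = c(0, 95), RR = c(100, 210))
  t <- trim_overlaps(b)
  expect_equal(unlist(t[2, c("DL", "DR", "RL", "RR")], use.names = FALSE),
               c(100L, 200L, 105L, 210L))

  # containment: second block dropped
  b <- aligned_blocks("c", "r", DL = c(0, 40), DR = c(100, 80),
                      RL = c(0, 42), RR = c(100, 82))
  expect_equal(nrow(trim_overlaps(b)), 1)
})

test_that("trim_overlaps leaves no residual overlap on random chains", {
  withr::local_seed(77)
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    strand <- sample(c("+", "-"), 1)
    # offsets stay below the minimum block length so overlaps are partial
    len <- sample(50:200, k, replace = TRUE)
    DL <- cumsum(c(0, head(len, -1))) - sample(0:40, k, replace = TRUE)
    DL <- cummax(pmax(DL, 0))
    rlen <- sample(50:200, k, replace = TRUE)
    RLf <- cumsum(c(0, head(rlen, -1))) - sample(0:40, k, replace = TRUE)
    RLf <- cummax(pmax(RLf, 0))
    if (strand == "-") {
      tot <- max(RLf + rlen) + 10
      RL <- rev(tot - (RLf + rlen))
      RR <- rev(tot - RLf)
      RL <- RL[order(-seq_len(k))] # keep aligned with DL order
      RR <- RR[order(-seq_len(k))]
      # read coords must descend with DL for a minus chain
      RL <- sort(RL, decreasing = TRUE); RR <- RL + rev(rlen)
    } else {
      RL <- RLf; RR <- RLf + rlen
    }
    b <- aligned_blocks("c", "r", DL = DL, DR = DL + len,
                        RL = RL, RR = RR, strand = strand)
    t <- trim_overlaps(b)
    if (nrow(t) > 1) {
      g <- rescaf:::block_gaps(t)
      expect_true(all(g$g1 >= 0), info = paste("rep", rep))
      expect_true(all(g$g2 >= 0), info = paste("rep", rep))
    }
  }
})

test_that("needleman_wunsch basic identities", {
  expect_equal(needleman_wunsch("ACGT", "ACGT")$score, 4)
  expect_equal(needleman_wunsch("", "AC", keep_alignment = FALSE)$score, -2)
  a <- "ACGTACGTTG"
  expect_equal(needleman_wunsch(a, a)$score, nchar(a))
  # symmetry
  b <- "ACTTACGG"
  expect_equal(needleman_wunsch(a, b)$score, needleman_wunsch(b, a)$score)
  # length cap refusal
  long <- paste(rep("A", 5001), collapse = "")
  expect_error(needleman_wunsch(long, "A"), "cap")
})

test_that("needleman_wunsch matches independent oracles", {
  withr::local_seed(101)
  # plain recursion over all alignments, tiny strings
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(0:8, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(1:8, 1), TRUE), collapse = "")
    expect_equal(needleman_wunsch(a, b, keep_alignment = FALSE)$score,
                 nw_recursive(a, b), info = paste(a, b))
  }
  # memoized recursion, strings up to length 12
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(5:12, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(5:12, 1), TRUE), collapse = "")
    expect_equal(needleman_wunsch(a, b, keep_alignment = FALSE)$score,
                 nw_memo(a, b), info = paste(a, b))
  }
  # Biostrings as a third, library-grade oracle on longer strings
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(30:60, 1), TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 1,
                                         scoreOnly = TRUE)
    expect_equal(needleman_wunsch(a, b, keep_alignment = FALSE)$score, ref)
  }
})

test_that("build_segments assembles, closes gaps and splits on violations", {
  # single block covering the whole read
  reads <- c(r1 = random_genome(400, seed = 1))
  draft <- c(c1 = paste0(random_genome(100, seed = 2), reads[["r1"]],
                         random_genome(100, seed = 3)))
  b <- aligned_blocks("c1", "r1", DL = 100, DR = 500, RL = 0, RR = 400)
  segs <- build_segments(b, reads, draft)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$aligned_read_fraction, 1.0)

  # two blocks with equal flanking gaps g1 = g2 = 20: one closed gap
  b2 <- aligned_blocks("c1", "r1",
                       DL = c(100, 320), DR = c(300, 500),
                       RL = c(0, 220), RR = c(200, 400))
  segs <- build_segments(b2, reads, draft)
  expect_length(segs, 1)
  expect_equal(nrow(segs[[1]]$closed_gaps), 1)
  cg <- segs[[1]]$closed_gaps
  expect_equal(cg$draft_end - cg$draft_start, 20)
  expect_equal(cg$read_end - cg$read_start, 20)
  expect_equal(cg$score, 20)  # identical sequences: all matches
  expect_equal(segs[[1]]$aligned_read_fraction, 1.0)

  # blocks on opposite strands stay separate segments
  b3 <- rbind(aligned_blocks("c1", "r1", 100, 300, 0, 200, "+"),
              aligned_blocks("c1", "r1", 320, 500, 0, 180, "-"))
  class(b3) <- c("aligned_blocks", "data.frame")
  expect_length(build_segments(b3, reads, draft), 2)

  # read-order violation splits the chain
  b4 <- aligned_blocks("c1", "r1",
                       DL = c(100, 320), DR = c(300, 500),
                       RL = c(200, 0), RR = c(400, 180))
  expect_message(segs <- build_segments(b4, reads, draft), "read-order")
  expect_length(segs, 2)

  # missing ids error
  expect_error(build_segments(b, reads, c(other = "ACGT")), "draft id")
  expect_error(build_segments(b, c(other = "ACGT"), draft), "read id")
})

test_that("error-free simulated reads align at fraction 1.0", {
  fx <- make_sim(genome_len = 60000, n_pieces = 3, min_piece_len = 8000,
                 coverage = 3, seed = 55)
  segs <- build_segments(fx$blocks, fx$sim$reads, fx$mut$draft)
  # reads contained in a single piece must reach fraction 1
  by_read <- split(vapply(segs, function(s) s$aligned_read_fraction, 0),
                   vapply(segs, function(s) s$read_id, ""))
  full <- vapply(by_read, function(x) any(x == 1), TRUE)
  tr <- fx$sim$truth
  lay <- fx$mut$layout
  contained <- vapply(seq_len(nrow(tr)), function(i)
    any(tr$ref_start[i] >= lay$ref_start & tr$ref_end[i] <= lay$ref_end), TRUE)
  ids <- tr$read_id[contained & tr$read_id %in% names(full)]
  expect_true(all(full[ids]))
})
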