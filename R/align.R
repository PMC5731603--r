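#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Optimal global alignment under linear gap penalties with the scoring
#' scheme match = +1, mismatch = -1, gap = -1 (configurable).  Inputs longer
#' than `max_len` are refused to bound the quadratic cost; gap closing in
#' [build_segments()] leaves such gaps unclosed.
#'
#' @param a,b nucleotide strings over A/C/G/T/N.
#' @param match,mismatch,gap scoring parameters.
#' @param band optional band half-width on `|i - j|`; `NULL` (default) runs
#'   unbanded (exact) alignment.
#' @param max_len maximum sequence length accepted when unbanded.
#' @param keep_alignment return the aligned strings as well.
#' @return list with `score`, event counts (`n_match`, `n_mismatch`,
#'   `n_ins` = bases of `b` opposite a gap in `a`, `n_del` = bases of `a`
#'   opposite a gap in `b`) and, if requested, `aligned_a` / `aligned_b`.
#' @export
needleman_wunsch <- function(a, b, match = 1L, mismatch = -1L, gap = -1L,
                             band = NULL, max_len = 5000L,
                             keep_alignment = TRUE) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (is.null(band)) {
    if (nchar(a) > max_len || nchar(b) > max_len)
      stop(sprintf("sequence length exceeds the %d bp alignment cap", max_len))
    band <- max(nchar(a), nchar(b))
  }
  nw_align_cpp(toupper(a), toupper(b), as.integer(match),
               as.integer(-abs(mismatch)), as.integer(abs(gap)),
               as.integer(band), keep_alignment)
}

# Banded realignment of a corrupted sequence to its source, returning
# per-reference-base event rates.  The band is sized from the length
# difference plus a drift allowance for independent indels.
realign_rates <- function(source, mutated, indel_rate = 0.04) {
  n <- nchar(source); m <- nchar(mutated)
  # 6-sigma allowance for the insertion/deletion random walk plus slack;
  # the chance of the optimal path leaving this band is negligible
  band <- as.integer(abs(n - m) + ceiling(6 * sqrt(max(n, m) * indel_rate)) + 60)
  al <- nw_align_cpp(source, mutated, 1L, -1L, 1L, band, FALSE)
  c(ins = al$n_ins / n, del = al$n_del / n, mis = al$n_mismatch / n)
}

# Strand-aware draft/read gaps between consecutive blocks (sorted by DL).
# For minus-strand chains the read coordinates run backwards.
block_gaps <- function(blocks) {
  k <- nrow(blocks)
  if (k < 2) return(data.frame(g1 = numeric(0), g2 = numeric(0)))
  g1 <- blocks$DL[-1] - blocks$DR[-k]
  g2 <- if (blocks$strand[1] == "+") blocks$RL[-1] - blocks$RR[-k]
        else blocks$RL[-k] - blocks$RR[-1]
  data.frame(g1 = g1, g2 = g2)
}

#' Trim overlaps between consecutive aligned blocks
#'
#' For one (draft, read, strand) group sorted by draft start: whenever two
#' consecutive blocks overlap in draft or read coordinates, the left ends of
#' the right block are cut back.  Draft and read coordinates are advanced by
#' the same amount -- the larger of the two overlaps -- so the block diagonal
#' is preserved; blocks trimmed to nothing are dropped.
#'
#' @param blocks `aligned_blocks` rows for one (draft_id, read_id, strand)
#'   group, sorted by `DL`.
#' @return the trimmed `aligned_blocks` data.frame.
#' @export
trim_overlaps <- function(blocks) {
  if (nrow(blocks) < 2) return(blocks)
  minus <- blocks$strand[1] == "-"
  out <- blocks[0, ]
  for (i in seq_len(nrow(blocks))) {
    cur <- blocks[i, ]
    if (nrow(out) > 0) {
      prev <- out[nrow(out), ]
      ov_d <- prev$DR - cur$DL
      ov_r <- if (minus) cur$RR - prev$RL else prev$RR - cur$RL
      # read intervals that are disjoint but backwards are disorder (e.g. a
      # micro-inversion), not an overlap: leave the block intact so the
      # chain is split at this point downstream
      disjoint_r <- if (minus) cur$RL >= prev$RR else cur$RR <= prev$RL
      if (disjoint_r && ov_r > 0) {
        out <- rbind(out, cur)
        next
      }
      adv <- max(ov_d, ov_r, 0L)
      if (adv > 0) {
        cur$DL <- cur$DL + adv
        if (minus) cur$RR <- cur$RR - adv else cur$RL <- cur$RL + adv
      }
    }
    if (cur$DL < cur$DR && cur$RL < cur$RR) out <- rbind(out, cur)
  }
  rownames(out) <- NULL
  out
}

new_alignment_segment <- function(draft_id, read_id, strand, blocks,
                                  closed_gaps, read_len) {
  aligned <- sum(blocks$RR - blocks$RL) +
    (if (nrow(closed_gaps)) sum(closed_gaps$read_end - closed_gaps$read_start) else 0)
  structure(list(draft_id = draft_id, read_id = read_id, strand = strand,
                 blocks = blocks, closed_gaps = closed_gaps,
                 read_len = read_len,
                 aligned_read_fraction = aligned / read_len),
            class = "alignment_segment")
}

#' @export
print.alignment_segment <- function(x, ...) {
  cat(sprintf("<alignment_segment> %s ~ %s (%s): %d block(s), draft %d-%d, aligned %.3f of read\n",
              x$draft_id, x$read_id, x$strand, nrow(x$blocks),
              min(x$blocks$DL), max(x$blocks$DR), x$aligned_read_fraction))
  invisible(x)
}

#' Assemble per-(draft, read) alignment segments from aligned blocks
#'
#' Blocks are grouped by (draft sequence, read, strand), sorted by draft
#' start, overlap-trimmed, and consecutive small gaps are closed by global
#' alignment of the intervening draft and read substrings.  A gap whose side
#' exceeds `gap_cap`, or a read-order violation (read coordinates stepping
#' backwards, e.g. a micro-inversion), splits the chain into separate
#' segments.
#'
#' @param blocks an `aligned_blocks` data.frame.
#' @param reads,draft named character vectors (or `DNAStringSet`) with the
#'   read and draft sequences.
#' @param gap_cap per-side length cap for gap closing (default 5000).
#' @return list of `alignment_segment` objects.
#' @export
build_segments <- function(blocks, reads, draft, gap_cap = 5000L) {
  reads <- as_seq_vector(reads)
  draft <- as_seq_vector(draft)
  missing_r <- setdiff(unique(blocks$read_id), names(reads))
  if (length(missing_r))
    stop("read id(s) missing from FASTA: ", paste(head(missing_r, 3), collapse = ", "))
  missing_d <- setdiff(unique(blocks$draft_id), names(draft))
  if (length(missing_d))
    stop("draft id(s) missing from FASTA: ", paste(head(missing_d, 3), collapse = ", "))
  read_len <- nchar(reads)

  key <- paste(blocks$draft_id, blocks$read_id, blocks$strand, sep = "\r")
  segments <- list()
  empty_gaps <- data.frame(draft_start = integer(0), draft_end = integer(0),
                           read_start = integer(0), read_end = integer(0),
                           score = numeric(0))
  for (idx in split(seq_len(nrow(blocks)), key)) {
    grp <- blocks[idx, , drop = FALSE]
    grp <- grp[order(grp$DL, grp$RL), , drop = FALSE]
    grp <- trim_overlaps(grp)
    if (nrow(grp) == 0) next
    did <- grp$draft_id[1]; rid <- grp$read_id[1]; str <- grp$strand[1]

    # fast path: single block
    if (nrow(grp) == 1) {
      segments[[length(segments) + 1]] <-
        new_alignment_segment(did, rid, str, grp, empty_gaps, read_len[[rid]])
      next
    }

    gaps <- block_gaps(grp)
    # chain breaks: read-order violation or uncloseably large gap
    brk <- which(gaps$g2 < 0 | gaps$g1 > gap_cap | gaps$g2 > gap_cap)
    if (any(gaps$g2 < 0))
      message(sprintf("build_segments: read-order violation for %s ~ %s; chain split",
                      did, rid))
    if (any(gaps$g1 > gap_cap | gaps$g2 > gap_cap))
      message(sprintf("build_segments: gap above %d bp cap for %s ~ %s left unclosed; chain split",
                      gap_cap, did, rid))
    starts <- c(1L, brk + 1L)
    ends <- c(brk, nrow(grp))
    for (p in seq_along(starts)) {
      sub <- grp[starts[p]:ends[p], , drop = FALSE]
      closed <- empty_gaps
      if (nrow(sub) > 1) {
        sg <- block_gaps(sub)
        for (j in which(sg$g1 > 0 | sg$g2 > 0)) {
          ds <- sub$DR[j]; de <- sub$DL[j + 1]
          if (str == "+") { rs <- sub$RR[j]; re <- sub$RL[j + 1] }
          else            { rs <- sub$RR[j + 1]; re <- sub$RL[j] }
          dseq <- substr(draft[[did]], ds + 1L, de)
          rseq <- substr(reads[[rid]], rs + 1L, re)
          if (str == "-") rseq <- revcomp(rseq)
          sc <- if (nchar(dseq) == 0 && nchar(rseq) == 0) 0
                else needleman_wunsch(dseq, rseq, keep_alignment = FALSE)$score
          closed <- rbind(closed, data.frame(draft_start = ds, draft_end = de,
                                             read_start = rs, read_end = re,
                                             score = sc))
        }
      }
      segments[[length(segments) + 1]] <-
        new_alignment_segment(did, rid, str, sub, closed, read_len[[rid]])
    }
  }
  segments
}
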