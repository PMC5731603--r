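#' Validation thresholds for disassembly
#'
#' Three thresholds decide which alignment segments certify draft structure:
#' consecutive-block gap agreement (`max_gap_diff`, default 30 bases), the
#' fraction of the read that must align (`min_read_fraction`, default 0.99,
#' strict inequality), and the minimum overlap for merging validated regions
#' (`delta`, default 50 bases).
#'
#' @param max_gap_diff maximum allowed |g1 - g2| between the draft-side and
#'   read-side gap of consecutive blocks.
#' @param min_read_fraction aligned-read-fraction threshold (kept only if
#'   strictly larger).
#' @param delta minimum overlap (bases) for merging validated intervals.
#' @param consensus_mode `"simple"` (extract the draft substring) or
#'   `"consensus"` (per-column majority vote over supporting reads).
#' @param fraction_basis `"read"` compares the aligned fraction against the
#'   read length; `"smaller"` against the smaller of read and draft sequence
#'   (an optional relaxation for fragmented drafts).
#' @param min_support minimum number of supporting reads per validated
#'   segment (default 1).
#' @return an object of class `validation_config`.
#' @export
validation_config <- function(max_gap_diff = 30L, min_read_fraction = 0.99,
                              delta = 50L,
                              consensus_mode = c("simple", "consensus"),
                              fraction_basis = c("read", "smaller"),
                              min_support = 1L) {
  consensus_mode <- match.arg(consensus_mode)
  fraction_basis <- match.arg(fraction_basis)
  stopifnot(max_gap_diff >= 0, min_read_fraction > 0, min_read_fraction <= 1,
            delta >= 1, min_support >= 1)
  structure(list(max_gap_diff = as.integer(max_gap_diff),
                 min_read_fraction = min_read_fraction,
                 delta = as.integer(delta), consensus_mode = consensus_mode,
                 fraction_basis = fraction_basis,
                 min_support = as.integer(min_support)),
            class = "validation_config")
}

#' Decide whether an alignment segment certifies draft structure
#'
#' A segment is kept iff (i) every consecutive block pair has
#' `|g1 - g2| <= max_gap_diff`, where g1 / g2 are the draft-side and
#' read-side gap lengths, and (ii) the aligned read fraction is strictly
#' larger than `min_read_fraction`.
#'
#' @param seg an `alignment_segment` from [build_segments()].
#' @param cfg a [validation_config()].
#' @param draft_len optional draft sequence length, needed when
#'   `fraction_basis = "smaller"`.
#' @return list with `keep` (logical) and `reason` (`NA` if kept, else the
#'   first violated condition, `"gap-diff"` or `"read-fraction"`).
#' @export
validate_segment <- function(seg, cfg = validation_config(), draft_len = NULL) {
  gaps <- block_gaps(seg$blocks)
  if (nrow(gaps) > 0 && any(abs(gaps$g1 - gaps$g2) > cfg$max_gap_diff))
    return(list(keep = FALSE, reason = "gap-diff"))
  frac <- seg$aligned_read_fraction
  if (cfg$fraction_basis == "smaller" && !is.null(draft_len)) {
    aligned <- frac * seg$read_len
    frac <- aligned / min(seg$read_len, draft_len)
  }
  if (!(frac > cfg$min_read_fraction))
    return(list(keep = FALSE, reason = "read-fraction"))
  list(keep = TRUE, reason = NA_character_)
}

#' Merge validated draft intervals overlapping by at least delta
#'
#' Per draft sequence, the transitive closure of the "overlap >= delta"
#' relation is merged into single intervals (union of members).  Intervals
#' overlapping by fewer than delta bases stay separate: the untrusted thin
#' overlap is discarded by truncating the later interval at the earlier
#' one's end, so output intervals are pairwise disjoint.
#'
#' @param intervals data.frame with columns `draft_id`, `start`, `end`
#'   (0-based half-open) and `read_id` of the supporting read.
#' @param delta minimum trustworthy overlap in bases.
#' @return data.frame with `draft_id`, `start`, `end`, `n_support` and a
#'   list-column `reads` of supporting read ids.
#' @export
merge_segments <- function(intervals, delta = 50L) {
  out <- NULL
  for (did in unique(intervals$draft_id)) {
    iv <- intervals[intervals$draft_id == did, , drop = FALSE]
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    cs <- iv$start[1]; ce <- iv$end[1]; members <- list(iv$read_id[1])
    flush <- function(s, e, mem) {
      rbind(out, data.frame(draft_id = did, start = s, end = e,
                            n_support = length(unique(unlist(mem))),
                            reads = I(list(unique(unlist(mem))))))
    }
    if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
      s2 <- iv$start[i]; e2 <- iv$end[i]
      ov <- ce - s2
      if (ov >= delta) {          # trustworthy overlap: merge
        ce <- max(ce, e2)
        members[[length(members) + 1]] <- iv$read_id[i]
      } else if (e2 > ce) {       # separate; drop any thin overlap
        out <- flush(cs, ce, members)
        cs <- max(s2, ce); ce <- e2
        members <- list(iv$read_id[i])
      }                           # else: contained with untrusted overlap; drop
    }
    out <- flush(cs, ce, members)
  }
  if (is.null(out)) out <- data.frame(draft_id = character(0), start = integer(0),
                                      end = integer(0), n_support = integer(0),
                                      reads = I(list()))
  rownames(out) <- NULL
  out
}

#' Extract validated segments from the draft
#'
#' Simple mode extracts the draft substring verbatim.  Consensus mode
#' realigns each supporting read onto the interval (banded global alignment)
#' and takes a per-column majority vote over the read bases, with ties going
#' to the draft base and a gap majority deleting the column.
#'
#' @param draft named character vector of draft sequences.
#' @param merged merged intervals from [merge_segments()].
#' @param reads named character vector of read sequences.
#' @param kept_segments list of the kept `alignment_segment` objects (used
#'   for supporting-read geometry).
#' @param cfg a [validation_config()].
#' @return list of `validated_segment` objects: `segment_id`, `draft_id`,
#'   `start`, `end`, `sequence`, and a `support` data.frame (`read_id`,
#'   `read_start`, `read_end`, `strand`, `draft_start`, `draft_end`).
#' @export
extract_segments <- function(draft, merged, reads, kept_segments,
                             cfg = validation_config()) {
  draft <- as_seq_vector(draft)
  reads <- as_seq_vector(reads)
  seg_draft <- vapply(kept_segments, function(s) s$draft_id, "")
  out <- list()
  for (i in seq_len(nrow(merged))) {
    did <- merged$draft_id[i]
    s <- merged$start[i]; e <- merged$end[i]
    if (e > nchar(draft[[did]]) || s < 0)
      stop(sprintf("interval [%d,%d) outside draft sequence %s", s, e, did))
    support <- NULL
    for (seg in kept_segments[seg_draft == did]) {
      ds <- min(seg$blocks$DL); de <- max(seg$blocks$DR)
      if (min(de, e) - max(ds, s) <= 0) next
      support <- rbind(support, data.frame(
        read_id = seg$read_id,
        read_start = min(seg$blocks$RL), read_end = max(seg$blocks$RR),
        strand = seg$strand, draft_start = ds, draft_end = de))
    }
    if (is.null(support) || length(unique(support$read_id)) < cfg$min_support) next
    seq <- substr(draft[[did]], s + 1L, e)
    if (cfg$consensus_mode == "consensus")
      seq <- consensus_interval(seq, s, support, reads)
    out[[length(out) + 1]] <- structure(
      list(segment_id = NA_character_, draft_id = did, start = s, end = e,
           sequence = seq, support = support),
      class = "validated_segment")
  }
  # deterministic ids ordered by (draft_id, start)
  ord <- order(vapply(out, function(x) x$draft_id, ""),
               vapply(out, function(x) x$start, 0))
  out <- out[ord]
  for (k in seq_along(out)) out[[k]]$segment_id <- sprintf("seg_%03d", k)
  out
}

# Column-majority consensus of supporting reads over one draft interval.
# Each read's aligned portion is realigned to its own footprint clipped to
# the interval; votes are per draft column over {A,C,G,T,-}; ties keep the
# draft base; a '-' majority deletes the column.  Read insertions are
# ignored (no new columns are created).
consensus_interval <- function(refseq, offset, support, reads) {
  n <- nchar(refseq)
  counts <- matrix(0L, 5, n, dimnames = list(c(BASES, "-"), NULL))
  refchars <- strsplit(refseq, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(support))) {
    ds <- max(support$draft_start[i], offset)
    de <- min(support$draft_end[i], offset + n)
    if (de - ds <= 0) next
    target <- substr(refseq, ds - offset + 1L, de - offset)
    rseq <- substr(reads[[support$read_id[i]]],
                   support$read_start[i] + 1L, support$read_end[i])
    if (support$strand[i] == "-") rseq <- revcomp(rseq)
    # clip the read to the same relative footprint before realigning
    rel_s <- (ds - support$draft_start[i])
    rel_e <- nchar(rseq) - (support$draft_end[i] - de)
    if (rel_e - rel_s < 1) next
    rseq <- substr(rseq, rel_s + 1L, rel_e)
    band <- abs(nchar(target) - nchar(rseq)) + 200L
    al <- nw_align_cpp(target, rseq, 1L, -1L, 1L, band, TRUE)
    ta <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
    qa <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
    col <- (ds - offset) + cumsum(ta != "-")   # 1-based draft column
    keep <- ta != "-" & qa %in% c(BASES, "-")
    for (b in c(BASES, "-")) {
      sel <- keep & qa == b
      if (any(sel)) {
        tb <- tabulate(col[sel], nbins = n)
        counts[b, ] <- counts[b, ] + tb
      }
    }
  }
  best <- apply(counts, 2, max)
  call <- refchars
  for (j in which(best > 0)) {
    winners <- rownames(counts)[counts[, j] == best[j]]
    if (refchars[j] %in% winners) next      # tie or majority for the draft
    call[j] <- winners[1]
  }
  paste(call[call != "-"], collapse = "")
}

#' Disassemble a draft assembly into validated segments
#'
#' Runs the full disassembly stage: build alignment segments from the
#' aligned-block table, filter them by the validation thresholds, merge
#' overlapping validated regions, and extract the validated segments.
#'
#' @param blocks an `aligned_blocks` data.frame (read-to-draft alignments).
#' @param draft,reads named character vectors of sequences.
#' @param cfg a [validation_config()].
#' @return list with `segments` (validated segments), `kept` (kept alignment
#'   segments), `merged` (merged interval table) and `all_segments` (every
#'   alignment segment, used later for bridging).
#' @export
disassemble <- function(blocks, draft, reads, cfg = validation_config()) {
  segs <- build_segments(blocks, reads, draft)
  draft <- as_seq_vector(draft)
  reads <- as_seq_vector(reads)
  keep <- vapply(segs, function(s)
    validate_segment(s, cfg, draft_len = nchar(draft[[s$draft_id]]))$keep, TRUE)
  kept <- segs[keep]
  if (length(kept) == 0)
    return(list(segments = list(), kept = list(),
                merged = merge_segments(data.frame(draft_id = character(0),
                                                   start = integer(0), end = integer(0),
                                                   read_id = character(0))),
                all_segments = segs))
  intervals <- data.frame(
    draft_id = vapply(kept, function(s) s$draft_id, ""),
    start = vapply(kept, function(s) min(s$blocks$DL), 0),
    end = vapply(kept, function(s) max(s$blocks$DR), 0),
    read_id = vapply(kept, function(s) s$read_id, "")
  )
  merged <- merge_segments(intervals, cfg$delta)
  validated <- extract_segments(draft, merged, reads, kept, cfg)
  list(segments = validated, kept = kept, merged = merged, all_segments = segs)
}

#' @export
print.validated_segment <- function(x, ...) {
  cat(sprintf("<validated_segment> %s: %s:[%d,%d) %d bp, %d supporting read(s)\n",
              x$segment_id, x$draft_id, x$start, x$end, nchar(x$sequence),
              length(unique(x$support$read_id))))
  invisible(x)
}

#' Write validated segments as FASTA and BED
#'
#' FASTA headers are `segid draftid:start-end`; the BED file records the
#' 0-based half-open source intervals.
#'
#' @param segments list of `validated_segment` objects.
#' @param fasta_path,bed_path output paths (either may be `NULL` to skip).
#' @return invisibly, a named character vector of the segment sequences.
#' @export
write_segments <- function(segments, fasta_path = NULL, bed_path = NULL) {
  seqs <- setNames(vapply(segments, function(s) s$sequence, ""),
                   vapply(segments, function(s) s$segment_id, ""))
  if (!is.null(fasta_path)) {
    hdr <- vapply(segments, function(s)
      sprintf("%s %s:%d-%d", s$segment_id, s$draft_id, s$start, s$end), "")
    write_fasta(setNames(seqs, hdr), fasta_path)
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = vapply(segments, function(s) s$draft_id, ""),
                      start = vapply(segments, function(s) s$start, 0),
                      end = vapply(segments, function(s) s$end, 0),
                      name = names(seqs))
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(seqs)
}
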