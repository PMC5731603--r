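#' Orient the segments along an alternating path
#'
#' Walking a path, a segment traversed tail-to-head is emitted forward
#' (`+`), head-to-tail reverse complemented (`-`).  The two walk directions
#' give reverse-complementary scaffolds; the canonical direction is the one
#' whose first segment id is lexicographically smaller.
#'
#' @param path vertex sequence of one alternating path (from a
#'   `path_cover`).
#' @param canonical pick the canonical walk direction (default `TRUE`).
#' @return data.frame with `segment_id` and `orientation` (`+`/`-`) in walk
#'   order.
#' @export
orient_path <- function(path, canonical = TRUE) {
  stopifnot(length(path) %% 2 == 0)
  if (canonical) {
    first <- sub(":.*", "", path[1])
    last <- sub(":.*", "", path[length(path)])
    if (last < first) path <- rev(path)
  }
  entry <- path[seq(1, length(path), by = 2)]
  data.frame(segment_id = sub(":.*", "", entry),
             orientation = ifelse(grepl(":tail$", entry), "+", "-"),
             stringsAsFactors = FALSE)
}

#' Select the gap filler for one solid edge
#'
#' Picks the supporting read with the highest mean junction identity (ties:
#' longest junction span, then smallest read id) and returns either the
#' read subsequence spanning the junction, oriented to the scaffold forward
#' strand, or -- for a negative junction distance -- the number of bases to
#' trim from the start of the right-hand segment.
#'
#' @param edge one row of a `scaffold_graph` solid edge table (with its
#'   `support` bridges).
#' @param left_seg segment id of the left-hand scaffold part.
#' @param left_orient orientation (`+`/`-`) of the left-hand part.
#' @param reads named character vector of read sequences.
#' @return list with `read_id`, `gap_seq` (possibly "") and `trim` (bases to
#'   cut from the right-hand segment start).
#' @export
fill_gap <- function(edge, left_seg, left_orient, reads) {
  sup <- edge$support[[1]]
  if (is.null(sup) || nrow(sup) == 0)
    stop("solid edge has no supporting bridge geometry")
  best <- sup[order(-sup$identity, -sup$span, sup$read_id), , drop = FALSE][1, ]
  if (!(best$read_id %in% names(reads)))
    stop("supporting read missing from FASTA: ", best$read_id)
  if (best$gap <= 0)
    return(list(read_id = best$read_id, gap_seq = "", trim = as.integer(-best$gap)))
  gap_seq <- substr(reads[[best$read_id]], best$gap_start + 1L, best$gap_end)
  # the bridge's hit strand on the left segment, from whichever side of the
  # stored geometry matches it
  s_left <- if (best$seg1 == left_seg) best$strand1 else best$strand2
  forward <- (s_left == "+") == (left_orient == "+")
  if (!forward) gap_seq <- revcomp(gap_seq)
  list(read_id = best$read_id, gap_seq = gap_seq, trim = 0L)
}

#' Assemble scaffold sequences from a path cover
#'
#' Converts each alternating path into one scaffold: validated segments are
#' emitted in walk order with their orientations, and each junction is
#' filled with the best bridging read's subsequence (or an overlap trim for
#' negative junction distances).  Unbridged paths become standalone
#' single-segment scaffolds.  Scaffold ids are `scaffold_<k>` in descending
#' length order.
#'
#' @param cover a `path_cover`.
#' @param segments list of `validated_segment` objects.
#' @param reads named character vector of read sequences.
#' @param graph the `scaffold_graph` (defaults to the cover's graph).
#' @return list with `sequences` (named character vector) and `layout`
#'   data.frame (`scaffold_id`, `part_index`, `segment_id`, `orientation`,
#'   `gap_after`, `trim_after`, `fill_read`).
#' @export
assemble_scaffolds <- function(cover, segments, reads, graph = cover$graph) {
  reads <- as_seq_vector(reads)
  seg_seq <- setNames(vapply(segments, function(s) s$sequence, ""),
                      vapply(segments, function(s) s$segment_id, ""))
  k <- solid_keys(graph$solid)
  solid_set <- pairkey(k$v1, k$v2)
  seqs <- character(0)
  layout <- NULL
  for (p in seq_along(cover$paths)) {
    parts <- orient_path(cover$paths[[p]])
    path <- cover$paths[[p]]
    first <- sub(":.*", "", path[1])
    if (parts$segment_id[1] != first) path <- rev(path)
    seq <- ""
    for (i in seq_len(nrow(parts))) {
      s <- seg_seq[[parts$segment_id[i]]]
      if (parts$orientation[i] == "-") s <- revcomp(s)
      gap_seq <- ""; trim <- 0L; fill_read <- NA_character_
      if (i < nrow(parts)) {
        a <- path[2 * i]; b <- path[2 * i + 1]
        j <- match(pairkey(a, b), solid_set)
        if (is.na(j)) stop("internal error: path junction has no solid edge")
        fg <- fill_gap(graph$solid[j, , drop = FALSE],
                       parts$segment_id[i], parts$orientation[i], reads)
        gap_seq <- fg$gap_seq; trim <- fg$trim; fill_read <- fg$read_id
      }
      if (i > 1 && prev_trim > 0) {
        prev_trim <- min(prev_trim, nchar(s) - 1L)
        s <- substr(s, prev_trim + 1L, nchar(s))
      }
      seq <- paste0(seq, s, gap_seq)
      prev_trim <- trim
      layout <- rbind(layout, data.frame(
        scaffold_id = NA_character_, path_index = p, part_index = i,
        segment_id = parts$segment_id[i], orientation = parts$orientation[i],
        gap_after = nchar(gap_seq), trim_after = trim, fill_read = fill_read))
    }
    seqs <- c(seqs, seq)
  }
  ord <- order(-nchar(seqs), seq_along(seqs))
  ids <- sprintf("scaffold_%d", seq_along(seqs))
  names(seqs)[ord] <- ids
  layout$scaffold_id <- ids[match(layout$path_index, ord)]
  layout <- layout[order(match(layout$scaffold_id, ids), layout$part_index), ]
  rownames(layout) <- NULL
  list(sequences = seqs[ids], layout = layout[, c("scaffold_id", "part_index",
                                                  "segment_id", "orientation",
                                                  "gap_after", "trim_after",
                                                  "fill_read")])
}

#' Run the full disassemble-reassemble pipeline
#'
#' Composes [disassemble()], [find_bridging_reads()], [build_graph()],
#' [cover_from_matching()] and [assemble_scaffolds()].  Deterministic given
#' the inputs and configuration.
#'
#' @param draft named character vector (or FASTA path) of draft sequences.
#' @param reads named character vector (or FASTA path) of reads.
#' @param blocks `aligned_blocks` (or a coords file path) of read-to-draft
#'   alignments.
#' @param cfg a [validation_config()].
#' @param variant cycle-breaking variant for [cover_from_matching()].
#' @return list with `scaffolds` (named character vector), `layout`,
#'   `segments`, `graph`, `matching` and `cover`.
#' @export
run_pipeline <- function(draft, reads, blocks, cfg = validation_config(),
                         variant = c("relaxed", "iterative")) {
  variant <- match.arg(variant)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (is.character(draft) && length(draft) == 1 && file.exists(draft))
    draft <- read_fasta(draft)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fasta(reads)
  if (is.character(blocks)) blocks <- parse_coords(blocks)
  draft <- as_seq_vector(draft)
  reads <- as_seq_vector(reads)
  dis <- stage("disassemble", disassemble(blocks, draft, reads, cfg))
  if (length(dis$segments) == 0)
    return(list(scaffolds = character(0), layout = NULL,
                segments = list(), graph = NULL, matching = NULL, cover = NULL))
  bridges <- stage("scaffold_graph",
                   find_bridging_reads(blocks, dis$segments, cfg))
  graph <- stage("scaffold_graph", build_graph(dis$segments, bridges))
  matching <- stage("path_cover", max_weight_matching_solid(graph))
  cover <- stage("path_cover", cover_from_matching(graph, matching, variant))
  check_cover(cover, graph)
  asm <- stage("reassemble", assemble_scaffolds(cover, dis$segments, reads, graph))
  list(scaffolds = asm$sequences, layout = asm$layout,
       segments = dis$segments, graph = graph, matching = matching,
       cover = cover)
}

#' Evaluate scaffolds against the simulated truth layout
#'
#' Maps every scaffold part to its source piece on the reference (via the
#' validated segment's draft record) and scores the oriented adjacencies
#' between consecutive parts of different pieces against the true
#' neighbour relation of the pieces on the reference.  Stands in for
#' external reference-comparison tools.
#'
#' @param result a [run_pipeline()] result (needs `scaffolds`, `layout`,
#'   `segments`).
#' @param truth truth layout from [mutate_assembly()].
#' @return an `eval_report` list: `n_scaffolds`, `n50`,
#'   `adjacency_precision`, `adjacency_recall`, `orientation_accuracy`,
#'   plus the raw counts.
#' @export
evaluate_scaffolds <- function(result, truth) {
  lengths <- nchar(result$scaffolds)
  seg_tab <- data.frame(
    segment_id = vapply(result$segments, function(s) s$segment_id, ""),
    draft_id = vapply(result$segments, function(s) s$draft_id, "")
  )
  layout <- result$layout
  if (!is.null(layout) && !all(layout$segment_id %in% seg_tab$segment_id))
    stop("scaffold layout references unknown segment ids")
  if (!is.null(layout)) {
    piece <- seg_tab$draft_id[match(layout$segment_id, seg_tab$segment_id)]
    if (!all(piece %in% truth$draft_id))
      stop("draft ids in layout are missing from the truth layout")
  }
  truth <- truth[order(truth$ref_start), , drop = FALSE]
  n_true <- max(nrow(truth) - 1, 0)
  # true neighbours in reference order: piece i (+) followed by piece i+1 (+)
  succ <- setNames(c(truth$draft_id[-1], NA), truth$draft_id[-nrow(truth)])
  piece_strand <- setNames(truth$strand, truth$draft_id)

  tp <- 0L; fp <- 0L; correct_orient <- 0L; adjacent_pairs <- 0L
  recovered <- character(0)
  if (!is.null(layout)) for (sc in split(layout, layout$scaffold_id)) {
    sc <- sc[order(sc$part_index), , drop = FALSE]
    if (nrow(sc) < 2) next
    pc <- seg_tab$draft_id[match(sc$segment_id, seg_tab$segment_id)]
    # effective orientation on the reference: part orientation combined with
    # the piece's strand in the draft
    eff <- ifelse((sc$orientation == "+") == (piece_strand[pc] == "+"), "+", "-")
    for (i in seq_len(nrow(sc) - 1)) {
      a <- pc[i]; b <- pc[i + 1]
      if (a == b) {
        # two validated segments of one piece re-joined: correct iff the
        # internal order and orientation are preserved
        if (eff[i] != eff[i + 1]) fp <- fp + 1L
        next
      }
      ok_fwd <- !is.na(succ[a]) && succ[a] == b && eff[i] == "+" && eff[i + 1] == "+"
      ok_rev <- !is.na(succ[b]) && succ[b] == a && eff[i] == "-" && eff[i + 1] == "-"
      pair_adjacent <- (!is.na(succ[a]) && succ[a] == b) ||
                       (!is.na(succ[b]) && succ[b] == a)
      if (pair_adjacent) {
        adjacent_pairs <- adjacent_pairs + 1L
        if (ok_fwd || ok_rev) correct_orient <- correct_orient + 1L
      }
      if (ok_fwd || ok_rev) {
        tp <- tp + 1L
        recovered <- c(recovered, if (ok_fwd) paste(a, b) else paste(b, a))
      } else fp <- fp + 1L
    }
  }
  n_pred <- tp + fp
  structure(list(
    n_scaffolds = length(result$scaffolds),
    n50 = n50(lengths),
    adjacency_precision = if (n_pred > 0) tp / n_pred else NA_real_,
    adjacency_recall = if (n_true > 0) length(unique(recovered)) / n_true else NA_real_,
    orientation_accuracy = if (adjacent_pairs > 0) correct_orient / adjacent_pairs
                           else NA_real_,
    n_true_adjacencies = n_true, n_predicted = n_pred,
    true_positives = tp, false_positives = fp
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> %d scaffold(s), N50 %d bp\n",
                     "  adjacency precision %.3f | recall %.3f | orientation accuracy %.3f\n"),
              x$n_scaffolds, x$n50, x$adjacency_precision,
              x$adjacency_recall, x$orientation_accuracy))
  invisible(x)
}

#' Write an eval report as TSV
#'
#' @param report an `eval_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  df <- data.frame(metric = names(unclass(report)),
                   value = unlist(unclass(report), use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write scaffolds as AGP v2.1 with a gap-fill sidecar
#'
#' Validated segments are emitted as `W` component lines; filled gaps are
#' emitted as `W` lines whose component is the filling read, annotated with
#' the read interval in a sidecar TSV.
#'
#' @param asm result of [assemble_scaffolds()] (or [run_pipeline()]).
#' @param segments list of `validated_segment` objects.
#' @param agp_path AGP output file.
#' @param sidecar_path optional TSV describing gap fills.
#' @return `agp_path`, invisibly.
#' @export
write_agp <- function(asm, segments, agp_path, sidecar_path = NULL) {
  seg_len <- setNames(vapply(segments, function(s) nchar(s$sequence), 0L),
                      vapply(segments, function(s) s$segment_id, ""))
  lay <- if (!is.null(asm$layout)) asm$layout else asm
  lines <- c("##agp-version\t2.1")
  sidecar <- NULL
  for (sc in split(lay, lay$scaffold_id)) {
    sc <- sc[order(sc$part_index), , drop = FALSE]
    pos <- 0L; partno <- 0L
    for (i in seq_len(nrow(sc))) {
      len <- seg_len[[sc$segment_id[i]]]
      if (i > 1 && sc$trim_after[i - 1] > 0) len <- len - sc$trim_after[i - 1]
      partno <- partno + 1L
      lines <- c(lines, paste(sc$scaffold_id[i], pos + 1L, pos + len, partno,
                              "W", sc$segment_id[i], 1L, len,
                              sc$orientation[i], sep = "\t"))
      pos <- pos + len
      if (i < nrow(sc) && sc$gap_after[i] > 0) {
        partno <- partno + 1L
        lines <- c(lines, paste(sc$scaffold_id[i], pos + 1L,
                                pos + sc$gap_after[i], partno, "W",
                                sc$fill_read[i], 1L, sc$gap_after[i], "+",
                                sep = "\t"))
        sidecar <- rbind(sidecar, data.frame(
          scaffold_id = sc$scaffold_id[i], after_part = partno - 1L,
          fill_read = sc$fill_read[i], fill_len = sc$gap_after[i]))
        pos <- pos + sc$gap_after[i]
      }
    }
  }
  writeLines(lines, agp_path)
  if (!is.null(sidecar_path) && !is.null(sidecar))
    write.table(sidecar, sidecar_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(agp_path)
}
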