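vkey <- function(seg, end) paste0(seg, ":", end)

# canonical unordered vertex-pair key
pairkey <- function(v1, v2) {
  a <- pmin(v1, v2); b <- pmax(v1, v2)
  paste(a, b, sep = "|")
}

#' Find long reads bridging two validated segments
#'
#' A read bridges segments A and B when it has validated-quality alignments
#' (gap agreement within `cfg$max_gap_diff`; aligned fraction of the hit's
#' read span strictly above `cfg$min_read_fraction`) to a terminal window of
#' both segments, in compatible read order and orientation.  The terminal
#' window is the outermost `min(500, 20%)` of the segment.  Reads touching
#' k > 2 segments yield the k-1 consecutive pairwise bridges; reads hitting
#' no or one segment are ignored.
#'
#' Alignments are supplied as read-to-draft aligned blocks and are cropped to
#' each validated segment's draft interval, so no separate read-to-segment
#' alignment run is needed.
#'
#' @param blocks `aligned_blocks` of reads against the draft.
#' @param segments list of `validated_segment` objects.
#' @param cfg a [validation_config()].
#' @param terminal_window absolute cap of the terminal window in bases.
#' @return data.frame of bridge records: vertex ends (`seg1`, `end1`,
#'   `seg2`, `end2`), `read_id`, junction `gap` (read distance between the
#'   two hits; negative = overlap), the unaligned read interval
#'   (`gap_start`, `gap_end`), hit strands, mean `identity` and junction
#'   `span`.
#' @export
find_bridging_reads <- function(blocks, segments, cfg = validation_config(),
                                terminal_window = 500L) {
  if (length(segments) == 0 || nrow(blocks) == 0) return(empty_bridges())
  seg_tab <- data.frame(
    segment_id = vapply(segments, function(s) s$segment_id, ""),
    draft_id = vapply(segments, function(s) s$draft_id, ""),
    start = vapply(segments, function(s) s$start, 0),
    end = vapply(segments, function(s) s$end, 0)
  )
  hits <- NULL
  for (i in seq_len(nrow(seg_tab))) {
    b <- blocks[blocks$draft_id == seg_tab$draft_id[i], , drop = FALSE]
    if (nrow(b) == 0) next
    s <- seg_tab$start[i]; e <- seg_tab$end[i]
    ov_lo <- pmax(b$DL, s); ov_hi <- pmin(b$DR, e)
    sel <- which(ov_hi - ov_lo > 0)
    if (length(sel) == 0) next
    b <- b[sel, , drop = FALSE]
    ov_lo <- ov_lo[sel]; ov_hi <- ov_hi[sel]
    # crop read coordinates along the block diagonal
    lead <- ov_lo - b$DL; trail <- b$DR - ov_hi
    plus <- b$strand == "+"
    r_lo <- ifelse(plus, b$RL + lead, b$RL + trail)
    r_hi <- ifelse(plus, b$RR - trail, b$RR - lead)
    h <- data.frame(read_id = b$read_id, strand = b$strand,
                    segment_id = seg_tab$segment_id[i],
                    seg_len = e - s,
                    seg_lo = ov_lo - s, seg_hi = ov_hi - s,
                    read_lo = r_lo, read_hi = r_hi,
                    identity = b$identity)
    hits <- rbind(hits, h)
  }
  if (is.null(hits)) return(empty_bridges())

  # chain multi-block hits per (read, segment, strand)
  key <- paste(hits$read_id, hits$segment_id, hits$strand, sep = "\r")
  chained <- do.call(rbind, lapply(split(hits, key), function(h) {
    h <- h[order(h$seg_lo), , drop = FALSE]
    if (nrow(h) > 1) {
      g1 <- h$seg_lo[-1] - h$seg_hi[-nrow(h)]
      g2 <- if (h$strand[1] == "+") h$read_lo[-1] - h$read_hi[-nrow(h)]
            else h$read_lo[-nrow(h)] - h$read_hi[-1]
      if (any(abs(g1 - g2) > cfg$max_gap_diff) || any(g2 < -cfg$max_gap_diff))
        return(NULL)             # structurally inconsistent hit; not a bridge anchor
    }
    aligned <- sum(h$read_hi - h$read_lo)
    data.frame(read_id = h$read_id[1], strand = h$strand[1],
               segment_id = h$segment_id[1], seg_len = h$seg_len[1],
               seg_lo = min(h$seg_lo), seg_hi = max(h$seg_hi),
               read_lo = min(h$read_lo), read_hi = max(h$read_hi),
               identity = mean(h$identity),
               frac = aligned / (max(h$read_hi) - min(h$read_lo)))
  }))
  if (is.null(chained)) return(empty_bridges())
  chained <- chained[chained$frac > cfg$min_read_fraction, , drop = FALSE]

  bridges <- NULL
  for (h in split(chained, chained$read_id)) {
    if (nrow(h) < 2) next
    h <- h[order(h$read_lo), , drop = FALSE]
    for (j in seq_len(nrow(h) - 1)) {
      a <- h[j, ]; b <- h[j + 1, ]
      if (a$segment_id == b$segment_id) next
      wa <- min(terminal_window, floor(0.2 * a$seg_len))
      wb <- min(terminal_window, floor(0.2 * b$seg_len))
      # the junction-facing end of each hit, from strand and read order
      end_a <- if (a$strand == "+") "head" else "tail"
      end_b <- if (b$strand == "+") "tail" else "head"
      ok_a <- if (end_a == "head") a$seg_hi >= a$seg_len - wa else a$seg_lo <= wa
      ok_b <- if (end_b == "head") b$seg_hi >= b$seg_len - wb else b$seg_lo <= wb
      if (!ok_a || !ok_b) next
      bridges <- rbind(bridges, data.frame(
        seg1 = a$segment_id, end1 = end_a, seg2 = b$segment_id, end2 = end_b,
        read_id = a$read_id, gap = b$read_lo - a$read_hi,
        gap_start = a$read_hi, gap_end = b$read_lo,
        strand1 = a$strand, strand2 = b$strand,
        identity = (a$identity + b$identity) / 2,
        span = b$read_hi - a$read_lo))
    }
  }
  if (is.null(bridges)) return(empty_bridges())
  rownames(bridges) <- NULL
  bridges
}

empty_bridges <- function() {
  data.frame(seg1 = character(0), end1 = character(0),
             seg2 = character(0), end2 = character(0),
             read_id = character(0), gap = numeric(0),
             gap_start = numeric(0), gap_end = numeric(0),
             strand1 = character(0), strand2 = character(0),
             identity = numeric(0), span = numeric(0))
}

#' Build the breakpoint-style scaffold graph
#'
#' Every validated segment contributes two vertices -- its tail (5') and
#' head (3') end -- joined by an implicit weight-0 dashed edge.  Bridges
#' between the same unordered vertex pair with similar junction geometry
#' (gap lengths within `gap_tol` bases) are merged into one solid edge whose
#' weight is the number of distinct supporting reads.  If dissimilar
#' geometries survive between the same vertex pair, only the
#' largest-support geometry is kept (ties broken by larger median junction
#' identity, then lexicographic smallest read id).
#'
#' @param segments list of `validated_segment` objects (or a character
#'   vector of segment ids for weight-only graphs).
#' @param bridges bridge records from [find_bridging_reads()].
#' @param gap_tol geometry-similarity tolerance in bases.
#' @return an object of class `scaffold_graph`: `segments` data.frame
#'   (`segment_id`, `length`, `draft_id`) and `solid` edge data.frame
#'   (`seg1`, `end1`, `seg2`, `end2`, `weight`, `mean_gap`, list-column
#'   `support`).
#' @export
build_graph <- function(segments, bridges = empty_bridges(), gap_tol = 100L) {
  if (is.character(segments)) {
    seg_tab <- data.frame(segment_id = segments, length = NA_integer_,
                          draft_id = NA_character_)
  } else {
    seg_tab <- data.frame(
      segment_id = vapply(segments, function(s) s$segment_id, ""),
      length = vapply(segments, function(s) nchar(s$sequence), 0L),
      draft_id = vapply(segments, function(s) s$draft_id, "")
    )
  }
  solid <- NULL
  if (nrow(bridges) > 0) {
    pk <- pairkey(vkey(bridges$seg1, bridges$end1), vkey(bridges$seg2, bridges$end2))
    for (grp in split(bridges, pk)) {
      # cluster by junction gap; geometries within gap_tol are "similar"
      grp <- grp[order(grp$gap), , drop = FALSE]
      cl <- cumsum(c(1, diff(grp$gap) > gap_tol))
      clusters <- split(grp, cl)
      n_reads <- vapply(clusters, function(g) length(unique(g$read_id)), 0L)
      med_idy <- vapply(clusters, function(g) median(g$identity), 0)
      min_rid <- vapply(clusters, function(g) min(g$read_id), "")
      best <- order(-n_reads, -med_idy, min_rid)[1]
      win <- clusters[[best]]
      # one support unit per distinct read
      win <- win[!duplicated(win$read_id), , drop = FALSE]
      solid <- rbind(solid, data.frame(
        seg1 = win$seg1[1], end1 = win$end1[1],
        seg2 = win$seg2[1], end2 = win$end2[1],
        weight = nrow(win), mean_gap = mean(win$gap),
        support = I(list(win))))
    }
    rownames(solid) <- NULL
  }
  if (is.null(solid))
    solid <- data.frame(seg1 = character(0), end1 = character(0),
                        seg2 = character(0), end2 = character(0),
                        weight = numeric(0), mean_gap = numeric(0),
                        support = I(list()))
  structure(list(segments = seg_tab, solid = solid), class = "scaffold_graph")
}

#' @export
print.scaffold_graph <- function(x, ...) {
  cat(sprintf("<scaffold_graph> %d segments (%d vertices, %d dashed edges), %d solid edge(s), total weight %g\n",
              nrow(x$segments), 2 * nrow(x$segments), nrow(x$segments),
              nrow(x$solid), sum(x$solid$weight)))
  invisible(x)
}

#' Write / read a scaffold graph as a tab-separated edge list
#'
#' Columns: `v1_segment v1_end v2_segment v2_end kind weight mean_gap`.
#' Dashed edges are written explicitly with weight 0; support read lists are
#' not round-tripped.
#'
#' @param graph a `scaffold_graph`.
#' @param path file path.
#' @return `path` (write); a `scaffold_graph` without support lists (read).
#' @export
write_graph <- function(graph, path) {
  dashed <- data.frame(v1_segment = graph$segments$segment_id, v1_end = "tail",
                       v2_segment = graph$segments$segment_id, v2_end = "head",
                       kind = "dashed", weight = 0, mean_gap = NA_real_)
  solid <- data.frame(v1_segment = graph$solid$seg1, v1_end = graph$solid$end1,
                      v2_segment = graph$solid$seg2, v2_end = graph$solid$end2,
                      kind = "solid", weight = graph$solid$weight,
                      mean_gap = graph$solid$mean_gap)
  write.table(rbind(dashed, solid), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  dashed <- tab[tab$kind == "dashed", , drop = FALSE]
  solid <- tab[tab$kind == "solid", , drop = FALSE]
  g <- build_graph(dashed$v1_segment)
  if (nrow(solid) > 0)
    g$solid <- data.frame(seg1 = solid$v1_segment, end1 = solid$v1_end,
                          seg2 = solid$v2_segment, end2 = solid$v2_end,
                          weight = solid$weight, mean_gap = solid$mean_gap,
                          support = I(rep(list(NULL), nrow(solid))))
  g
}

#' Export a scaffold graph as GraphViz DOT
#'
#' @param graph a `scaffold_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dot <- function(graph, path) {
  lines <- c("graph scaffold {", "  node [shape=point];")
  for (s in graph$segments$segment_id)
    lines <- c(lines, sprintf("  \"%s\" -- \"%s\" [style=dashed, label=\"%s\"];",
                              vkey(s, "tail"), vkey(s, "head"), s))
  if (nrow(graph$solid) > 0)
    lines <- c(lines, sprintf("  \"%s\" -- \"%s\" [label=\"%g\"];",
                              vkey(graph$solid$seg1, graph$solid$end1),
                              vkey(graph$solid$seg2, graph$solid$end2),
                              graph$solid$weight))
  writeLines(c(lines, "}"), path)
  invisible(path)
}
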