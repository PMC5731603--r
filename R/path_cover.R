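## Maximum weighted alternating path cover.
##
## Vertices: two per segment ("seg:tail", "seg:head"); one weight-0 dashed
## edge per segment joins them; solid edges carry positive bridging-read
## support.  A cover is a set of vertex-disjoint alternating paths
## (dashed, solid, ..., dashed) using every vertex and every dashed edge
## exactly once; the objective is the total solid weight.

other_end <- function(v) {
  seg <- sub(":(tail|head)$", "", v)
  end <- sub("^.*:", "", v)
  vkey(seg, ifelse(end == "tail", "head", "tail"))
}

solid_keys <- function(solid) {
  list(v1 = vkey(solid$seg1, solid$end1), v2 = vkey(solid$seg2, solid$end2))
}

# union-find
uf_new <- function(keys) setNames(keys, keys)
uf_find <- function(uf, x) { while (uf[[x]] != x) x <- uf[[x]]; x }

# Exact maximum-weight matching over an edge table, by subset DP per
# connected component of the solid subgraph.
mwm_edges <- function(v1, v2, w) {
  n_e <- length(w)
  if (n_e == 0) return(list(idx = integer(0), weight = 0))
  verts <- unique(c(v1, v2))
  uf <- uf_new(verts)
  for (i in seq_len(n_e)) {
    r1 <- uf_find(uf, v1[i]); r2 <- uf_find(uf, v2[i])
    if (r1 != r2) uf[[r1]] <- r2
  }
  roots <- vapply(verts, function(x) uf_find(uf, x), "")
  sel <- integer(0)
  for (comp in split(verts, roots)) {
    in_comp <- v1 %in% comp
    eidx <- which(in_comp)
    if (length(eidx) == 0) next
    cv <- sort(unique(c(v1[eidx], v2[eidx])))
    k <- length(cv)
    if (k > 22)
      stop(sprintf("solid-edge component with %d vertices exceeds the exact matching limit (22)", k))
    W <- matrix(0, k, k, dimnames = list(cv, cv))
    for (i in eidx) {
      # parallel edges cannot occur post-merge, but keep the max defensively
      W[v1[i], v2[i]] <- max(W[v1[i], v2[i]], w[i])
      W[v2[i], v1[i]] <- W[v1[i], v2[i]]
    }
    partner <- mwm_dp_cpp(W)
    for (a in seq_len(k)) {
      b <- partner[a] + 1L
      if (b > a) {
        hit <- eidx[(v1[eidx] == cv[a] & v2[eidx] == cv[b]) |
                    (v1[eidx] == cv[b] & v2[eidx] == cv[a])]
        sel <- c(sel, hit[which.max(w[hit])])
      }
    }
  }
  list(idx = sort(sel), weight = sum(w[sel]))
}

# Decompose dashed edges + a set of matched solid edges into alternating
# paths and cycles.  Returns vertex sequences; paths start and end with a
# dashed edge, cycles are closed by a solid edge from last to first vertex.
cover_components <- function(segment_ids, v1, v2) {
  partner <- character(0)
  partner[v1] <- v2
  partner[v2] <- v1
  all_v <- c(vkey(segment_ids, "tail"), vkey(segment_ids, "head"))
  visited <- setNames(rep(FALSE, length(all_v)), all_v)
  paths <- list(); cycles <- list()
  # paths first: start from vertices with no solid partner
  starts <- all_v[!(all_v %in% names(partner))]
  for (s in starts) {
    if (visited[[s]]) next
    seq_v <- character(0)
    v <- s
    repeat {
      seq_v <- c(seq_v, v); visited[[v]] <- TRUE
      u <- other_end(v)                 # dashed edge
      seq_v <- c(seq_v, u); visited[[u]] <- TRUE
      nxt <- if (u %in% names(partner)) partner[[u]] else NA_character_
      if (is.na(nxt)) break
      v <- nxt                          # solid edge
    }
    paths[[length(paths) + 1]] <- seq_v
  }
  # remaining vertices sit on alternating cycles
  for (s in all_v) {
    if (visited[[s]]) next
    seq_v <- character(0)
    v <- s
    repeat {
      seq_v <- c(seq_v, v); visited[[v]] <- TRUE
      u <- other_end(v)
      seq_v <- c(seq_v, u); visited[[u]] <- TRUE
      v <- partner[[u]]                 # always defined on a cycle
      if (v == s) break
    }
    cycles[[length(cycles) + 1]] <- seq_v
  }
  list(paths = paths, cycles = cycles)
}

new_matching_result <- function(graph, idx, eligible_weight = NULL) {
  solid <- graph$solid
  k <- solid_keys(solid)
  comps <- cover_components(graph$segments$segment_id, k$v1[idx], k$v2[idx])
  cyc_edges <- lapply(comps$cycles, function(cy)
    idx[k$v1[idx] %in% cy & k$v2[idx] %in% cy])
  ki <- vapply(cyc_edges, length, 0L)
  structure(list(idx = idx, mstar = sum(solid$weight[idx]),
                 matched = solid[idx, , drop = FALSE],
                 paths = comps$paths, cycles = comps$cycles,
                 cycle_edges = cyc_edges, k = ki,
                 k_min = if (length(ki)) min(ki) else NA_integer_),
            class = "matching_result")
}

#' Maximum weighted matching over the solid edges
#'
#' Exact maximum-weight matching on the (general, non-bipartite) subgraph of
#' solid edges, computed by subset dynamic programming per connected
#' component.  Also reports the alternating cycles that appear once the
#' dashed edges are added to the matching, with their solid-edge counts
#' `k_i` and `k_min`.
#'
#' @param graph a `scaffold_graph`.
#' @param eligible optional logical vector flagging solid edges available to
#'   the matching (used by the iterative cycle-breaking variant).
#' @return a `matching_result`: matched edge indices `idx`, weight sum
#'   `mstar`, the induced `paths` / `cycles`, cycle solid-edge counts `k`
#'   and `k_min`.
#' @export
max_weight_matching_solid <- function(graph, eligible = NULL) {
  solid <- graph$solid
  ok <- solid$weight > 0
  if (!is.null(eligible)) ok <- ok & eligible
  k <- solid_keys(solid)
  res <- mwm_edges(k$v1[ok], k$v2[ok], solid$weight[ok])
  new_matching_result(graph, which(ok)[res$idx])
}

new_path_cover <- function(graph, idx) {
  k <- solid_keys(graph$solid)
  comps <- cover_components(graph$segments$segment_id, k$v1[idx], k$v2[idx])
  if (length(comps$cycles) > 0)
    stop("internal error: path cover construction produced a cycle")
  structure(list(paths = comps$paths,
                 total_weight = sum(graph$solid$weight[idx]),
                 solid_idx = idx, graph = graph),
            class = "path_cover")
}

#' @export
print.path_cover <- function(x, ...) {
  cat(sprintf("<path_cover> %d path(s), total solid weight %g\n",
              length(x$paths), x$total_weight))
  for (p in x$paths) {
    segs <- p[seq(1, length(p), by = 2)]
    cat("  ", paste(sub(":.*", "", segs), collapse = " - "), "\n")
  }
  invisible(x)
}

# smallest-weight solid edge of a cycle; ties by lexicographically smallest
# sorted vertex pair
cycle_min_edge <- function(solid, edge_idx) {
  w <- solid$weight[edge_idx]
  cand <- edge_idx[w == min(w)]
  if (length(cand) == 1) return(cand)
  keys <- pairkey(vkey(solid$seg1[cand], solid$end1[cand]),
                  vkey(solid$seg2[cand], solid$end2[cand]))
  cand[order(keys)[1]]
}

#' Build an alternating path cover from a maximum matching
#'
#' Adds the dashed edges to the matching; the resulting components are
#' alternating paths and cycles.  The `relaxed` variant (default) removes
#' the smallest-weight solid edge from each cycle once.  The `iterative`
#' variant instead marks the smallest-weight cycle edge ineligible and
#' re-runs the matching until no cycle remains, keeping the best acyclic
#' solution encountered (each round's cycle-broken matching is itself a
#' feasible cover, so the result is never worse than the relaxed variant).
#'
#' When cycles exist the output satisfies `ALG >= M* (k_min - 1) / k_min`;
#' without cycles `ALG = M*`.
#'
#' @param graph a `scaffold_graph`.
#' @param matching a `matching_result` from [max_weight_matching_solid()];
#'   computed if `NULL`.
#' @param variant `"relaxed"` or `"iterative"`.
#' @return a `path_cover`: vertex-sequence `paths`, `total_weight` (ALG) and
#'   the used solid edge indices `solid_idx`.
#' @export
cover_from_matching <- function(graph, matching = NULL,
                                variant = c("relaxed", "iterative")) {
  variant <- match.arg(variant)
  if (is.null(matching)) matching <- max_weight_matching_solid(graph)
  solid <- graph$solid
  if (variant == "relaxed") {
    drop <- vapply(matching$cycle_edges, function(e) cycle_min_edge(solid, e), 0L)
    return(new_path_cover(graph, setdiff(matching$idx, drop)))
  }
  # iterative: exclude min cycle edges and re-match until acyclic
  eligible <- rep(TRUE, nrow(solid))
  best_idx <- integer(0); best_w <- -Inf
  m <- matching
  for (round in seq_len(nrow(solid) + 1L)) {
    if (length(m$cycles) == 0) {
      if (m$mstar > best_w) { best_w <- m$mstar; best_idx <- m$idx }
      break
    }
    drop <- vapply(m$cycle_edges, function(e) cycle_min_edge(solid, e), 0L)
    cand <- setdiff(m$idx, drop)
    cand_w <- sum(solid$weight[cand])
    if (cand_w > best_w) { best_w <- cand_w; best_idx <- cand }
    eligible[drop] <- FALSE
    m <- max_weight_matching_solid(graph, eligible)
  }
  new_path_cover(graph, best_idx)
}

#' Exact maximum weighted alternating path cover (oracle)
#'
#' Exhaustive search over matchings on the solid edges whose union with the
#' dashed edges is acyclic (exactly the feasible covers), with
#' branch-and-bound pruning.  Limited to 8 segments; intended as a test
#' oracle, not for production use.
#'
#' @param graph a `scaffold_graph`.
#' @return a `path_cover` attaining the optimum OPT.
#' @export
brute_force_cover <- function(graph) {
  nseg <- nrow(graph$segments)
  if (nseg > 8)
    stop(sprintf("brute_force_cover refuses instances with more than 8 segments (got %d)", nseg))
  solid <- graph$solid
  ok <- which(solid$weight > 0)
  seg_index <- setNames(seq_len(nseg) - 1L, graph$segments$segment_id)
  to_v <- function(seg, end) 2L * seg_index[seg] + ifelse(end == "head", 1L, 0L)
  if (length(ok) == 0) return(new_path_cover(graph, integer(0)))
  ord <- ok[order(-solid$weight[ok])]
  em <- cbind(to_v(solid$seg1[ord], solid$end1[ord]),
              to_v(solid$seg2[ord], solid$end2[ord]))
  res <- bf_cover_cpp(nseg, em, solid$weight[ord])
  new_path_cover(graph, sort(ord[res$edges + 1L]))
}

#' Verify alternating-path-cover invariants
#'
#' Checks that every vertex and every dashed edge appears exactly once, that
#' edges strictly alternate dashed / solid, that paths start and end with a
#' dashed edge, and that every used solid edge exists in the graph.
#'
#' @param cover a `path_cover`.
#' @param graph the `scaffold_graph` it was computed on.
#' @return `TRUE` (invisibly); stops with a message on violation.
#' @export
check_cover <- function(cover, graph = cover$graph) {
  segs <- graph$segments$segment_id
  all_v <- c(vkey(segs, "tail"), vkey(segs, "head"))
  seen <- unlist(cover$paths)
  if (length(seen) != length(all_v) || anyDuplicated(seen) ||
      !setequal(seen, all_v))
    stop("cover violates the vertex-exactly-once constraint")
  k <- solid_keys(graph$solid)
  solid_set <- pairkey(k$v1, k$v2)
  used_w <- 0
  for (p in cover$paths) {
    if (length(p) %% 2 != 0) stop("path with an odd number of vertices")
    for (i in seq_len(length(p) - 1)) {
      a <- p[i]; b <- p[i + 1]
      if (i %% 2 == 1) {                    # must be a dashed edge
        if (other_end(a) != b) stop("expected dashed edge in path")
      } else {                              # must be an existing solid edge
        j <- match(pairkey(a, b), solid_set)
        if (is.na(j)) stop("path uses a non-existent solid edge")
        used_w <- used_w + graph$solid$weight[j]
      }
    }
  }
  if (abs(used_w - cover$total_weight) > 1e-9)
    stop("cover weight does not match its solid edges")
  invisible(TRUE)
}

#' Random scaffolding instance generator
#'
#' Adds each possible solid edge between vertices of distinct segments with
#' probability `edge_prob` and an integer weight uniform on
#' `[wmin, wmax]`.
#'
#' @param n_segments number of segments.
#' @param edge_prob solid edge probability.
#' @param wmin,wmax integer weight range.
#' @param seed integer seed (optional).
#' @return a `scaffold_graph`.
#' @export
random_scaffold_instance <- function(n_segments, edge_prob = 0.4,
                                     wmin = 1L, wmax = 10L, seed = NULL) {
  segs <- sprintf("s%02d", seq_len(n_segments))
  verts <- c(vapply(segs, vkey, "", end = "tail"),
             vapply(segs, vkey, "", end = "head"))
  vseg <- rep(segs, 2)
  with_seed(seed, {
    solid <- NULL
    nv <- length(verts)
    for (i in seq_len(nv - 1)) for (j in (i + 1):nv) {
      if (vseg[i] == vseg[j]) next
      if (runif(1) < edge_prob) {
        w <- wmin + sample.int(wmax - wmin + 1L, 1L) - 1L
        solid <- rbind(solid, data.frame(
          seg1 = vseg[i], end1 = sub("^.*:", "", verts[i]),
          seg2 = vseg[j], end2 = sub("^.*:", "", verts[j]),
          weight = w, mean_gap = 0, support = I(list(NULL))))
      }
    }
    g <- build_graph(segs)
    if (!is.null(solid)) { rownames(solid) <- NULL; g$solid <- solid }
    g
  })
}

#' Scaffolding instance from the Hamiltonian-path construction
#'
#' Given a simple undirected graph on `n` vertices, builds the scaffolding
#' instance with one segment per input vertex, solid edges of weight 1
#' duplicated on the tail side (`E`) and the head side (`E'`), and the usual
#' dashed edges.  The input graph has a Hamiltonian path iff the instance
#' admits an alternating path cover of weight >= n - 1.  Used as test
#' infrastructure.
#'
#' @param n number of vertices of the input graph.
#' @param edges two-column matrix of 1-based vertex pairs.
#' @return a `scaffold_graph`.
#' @export
hamiltonian_reduction <- function(n, edges) {
  stopifnot(n >= 2)
  segs <- sprintf("v%02d", seq_len(n))
  g <- build_graph(segs)
  if (length(edges) > 0 && nrow(edges) > 0) {
    solid <- rbind(
      data.frame(seg1 = segs[edges[, 1]], end1 = "tail",
                 seg2 = segs[edges[, 2]], end2 = "tail",
                 weight = 1, mean_gap = 0, support = I(rep(list(NULL), nrow(edges)))),
      data.frame(seg1 = segs[edges[, 1]], end1 = "head",
                 seg2 = segs[edges[, 2]], end2 = "head",
                 weight = 1, mean_gap = 0, support = I(rep(list(NULL), nrow(edges))))
    )
    rownames(solid) <- NULL
    g$solid <- solid
  }
  g
}

#' Write an alternating path cover as ordered, oriented segment lists
#'
#' One line per path: `path_id seg1:+ seg2:- ...`.
#'
#' @param cover a `path_cover`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cover <- function(cover, path) {
  lines <- vapply(seq_along(cover$paths), function(i) {
    parts <- orient_path(cover$paths[[i]])
    paste(c(sprintf("path_%03d", i),
            paste0(parts$segment_id, ":", parts$orientation)), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
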