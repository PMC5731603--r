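# Independent oracles used to cross-check the implementation.

# Global alignment score by plain recursion over all alignments (no DP).
# Only viable for very short strings.
nw_recursive <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  n <- nchar(a); m <- nchar(b)
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(n, m)
}

# Same optimum by memoized top-down recursion (fast enough for length 12).
nw_memo <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  n <- nchar(a); m <- nchar(b)
  memo <- matrix(NA_real_, n + 1, m + 1)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- if (i == 0 && j == 0) 0 else {
      best <- -Inf
      if (i > 0 && j > 0) {
        s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
        best <- max(best, rec(i - 1, j - 1) + s)
      }
      if (i > 0) best <- max(best, rec(i - 1, j) + gap)
      if (j > 0) best <- max(best, rec(i, j - 1) + gap)
      best
    }
    memo[i + 1, j + 1] <<- v
    v
  }
  rec(n, m)
}

# Maximum-weight matching by exhaustive recursion over vertices.
matching_enum <- function(v1, v2, w) {
  verts <- sort(unique(c(v1, v2)))
  rec <- function(free) {
    if (length(free) == 0) return(0)
    v <- free[1]
    best <- rec(free[-1])                       # v unmatched
    cand <- which((v1 == v & v2 %in% free) | (v2 == v & v1 %in% free))
    for (i in cand) {
      u <- if (v1[i] == v) v2[i] else v1[i]
      best <- max(best, w[i] + rec(setdiff(free[-1], u)))
    }
    best
  }
  rec(verts)
}

# Transitive-closure interval merging by explicit union-find on the
# pairwise "overlap >= delta" relation, then the same thin-overlap
# truncation between consecutive merged intervals.
merge_oracle <- function(intervals, delta) {
  out <- NULL
  for (did in unique(intervals$draft_id)) {
    iv <- intervals[intervals$draft_id == did, , drop = FALSE]
    n <- nrow(iv)
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
      ov <- min(iv$end[i], iv$end[j]) - max(iv$start[i], iv$start[j])
      if (ov >= delta) parent[find(i)] <- find(j)
    }
    roots <- vapply(seq_len(n), find, 0L)
    cl <- lapply(split(seq_len(n), roots), function(ix)
      c(start = min(iv$start[ix]), end = max(iv$end[ix])))
    m <- do.call(rbind, cl)
    m <- m[order(m[, "start"]), , drop = FALSE]
    # thin-overlap truncation; contained untrusted intervals are dropped
    res <- NULL
    for (i in seq_len(nrow(m))) {
      s <- m[i, "start"]; e <- m[i, "end"]
      if (!is.null(res)) {
        pe <- res$end[nrow(res)]
        if (e <= pe) next
        s <- max(s, pe)
      }
      res <- rbind(res, data.frame(draft_id = did, start = s, end = e))
    }
    out <- rbind(out, res)
  }
  rownames(out) <- NULL
  out
}

# Exhaustive Hamiltonian path search over all vertex permutations (n <= 7).
has_hamiltonian_path <- function(n, edges) {
  if (n == 1) return(TRUE)
  has_edge <- matrix(FALSE, n, n)
  if (length(edges) && nrow(edges)) {
    has_edge[edges] <- TRUE
    has_edge[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (p in perms(seq_len(n))) {
    if (all(has_edge[cbind(p[-n], p[-1])])) return(TRUE)
  }
  FALSE
}

random_simple_graph <- function(n, p = 0.4) {
  e <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p) e <- rbind(e, c(i, j))
  if (is.null(e)) e <- matrix(integer(0), 0, 2)
  e
}
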