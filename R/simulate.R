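#' Configuration for the structural assembly mutator
#'
#' The mutator emulates a structurally corrupted draft assembly: the genome is
#' cut into `n_pieces` contiguous pieces, the pieces are shuffled and randomly
#' reverse complemented, and each piece is then corrupted base-wise with
#' independent per-position insertion / deletion / mismatch events.
#'
#' @param n_pieces number of pieces N (the genome is cut N-1 times).
#' @param min_piece_len minimum piece length l in bases.
#' @param ins_rate,del_rate,mis_rate per-base event probabilities.
#' @param revcomp_prob probability that a piece is reverse complemented.
#' @param seed integer seed governing cutting, shuffling, orientation and
#'   base-level corruption.
#' @return an object of class `mutation_config`.
#' @export
mutation_config <- function(n_pieces = 50, min_piece_len = 10000,
                            ins_rate = 0.02, del_rate = 0.02, mis_rate = 0.02,
                            revcomp_prob = 0.5, seed = NULL) {
  stopifnot(
    is.finite(n_pieces), n_pieces >= 1,
    is.finite(min_piece_len), min_piece_len >= 1,
    ins_rate >= 0, del_rate >= 0, mis_rate >= 0,
    ins_rate + del_rate + mis_rate < 1,
    revcomp_prob >= 0, revcomp_prob <= 1
  )
  structure(list(n_pieces = as.integer(n_pieces),
                 min_piece_len = as.integer(min_piece_len),
                 ins_rate = ins_rate, del_rate = del_rate, mis_rate = mis_rate,
                 revcomp_prob = revcomp_prob, seed = seed),
            class = "mutation_config")
}

#' Cut a sequence into random contiguous pieces
#'
#' Iterative cutting rule: with `m` cuts still to go and `L` bases remaining
#' to the right of the previous cut, the next cut point is drawn uniformly
#' from `[l, floor(L/(m+1))]`, measured from the left end of the remaining
#' suffix.  This guarantees every piece is at least `l` bases.
#'
#' @param sequence a nucleotide string, or a bare integer length.
#' @param n_pieces number of pieces (>= 1).
#' @param min_piece_len minimum piece length l.
#' @param seed integer seed (optional).
#' @return data.frame with 0-based half-open columns `start`, `end` giving
#'   `n_pieces` ordered intervals that partition the sequence.
#' @export
cut_genome <- function(sequence, n_pieces, min_piece_len = 10000, seed = NULL) {
  L <- if (is.numeric(sequence)) as.integer(sequence) else nchar(sequence)
  n_pieces <- as.integer(n_pieces)
  l <- as.integer(min_piece_len)
  stopifnot(n_pieces >= 1, l >= 1)
  if (L < n_pieces * l)
    stop(sprintf("sequence of length %d cannot be cut into %d pieces of >= %d bases",
                 L, n_pieces, l))
  cuts <- with_seed(seed, {
    pos <- integer(0)
    offset <- 0L
    Lrem <- L
    if (n_pieces > 1) for (m in (n_pieces - 1L):1L) {
      hi <- as.integer(Lrem %/% (m + 1L))
      c_at <- l + sample.int(hi - l + 1L, 1L) - 1L
      pos <- c(pos, offset + c_at)
      offset <- offset + c_at
      Lrem <- Lrem - c_at
    }
    pos
  })
  bounds <- c(0L, cuts, L)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1])
}

# Corrupt a sequence base-wise: at each position at most one event -- insert a
# random base before it (ins), delete it (del), or substitute it with a
# different base (mis).  Returns the corrupted string with realized event
# counts attached as attribute "events".  Assumes RNG state is already set.
corrupt_sequence <- function(seq, ins_rate, del_rate, mis_rate) {
  n <- nchar(seq)
  if (n == 0 || (ins_rate + del_rate + mis_rate) == 0) {
    attr(seq, "events") <- c(ins = 0L, del = 0L, mis = 0L)
    return(seq)
  }
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  u <- runif(n)
  ins <- u < ins_rate
  del <- !ins & u < ins_rate + del_rate
  mis <- !ins & !del & u < ins_rate + del_rate + mis_rate
  out <- x
  if (any(mis)) {
    # substitute with one of the three other bases, uniformly
    alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                  nrow = 3)
    k <- sum(mis)
    out[mis] <- alt[cbind(sample.int(3L, k, replace = TRUE),
                          match(x[mis], BASES))]
  }
  ins_base <- rep(NA_character_, n)
  if (any(ins)) ins_base[ins] <- sample(BASES, sum(ins), replace = TRUE)
  out[del] <- NA_character_
  v <- as.vector(rbind(ins_base, out))
  v <- v[!is.na(v)]
  res <- paste(v, collapse = "")
  attr(res, "events") <- c(ins = sum(ins), del = sum(del), mis = sum(mis))
  res
}

#' Structurally corrupt a reference genome into a draft assembly
#'
#' Cuts the reference into pieces (see [cut_genome()]), permutes the pieces
#' uniformly at random, reverse complements each independently with
#' probability `revcomp_prob`, and corrupts each piece base-wise with the
#' configured insertion / deletion / mismatch rates.  The returned truth
#' layout records the pre-corruption provenance of every draft record.
#'
#' @param reference a single named nucleotide string (or `DNAStringSet` of
#'   length 1).
#' @param config a [mutation_config()].
#' @return list with elements
#'   * `draft`: named character vector of draft records in output order,
#'   * `layout`: data.frame (`draft_id`, `ref_id`, `ref_start`, `ref_end`,
#'     `strand`, `order_index`) with 0-based half-open source intervals that
#'     partition the reference,
#'   * `events`: data.frame of realized corruption event counts per piece.
#' @export
mutate_assembly <- function(reference, config = mutation_config()) {
  reference <- as_seq_vector(reference, fallback = "ref")
  stopifnot(length(reference) == 1, nchar(reference) >= 1)
  ref_id <- names(reference)
  refseq <- unname(reference)
  with_seed(config$seed, {
    iv <- cut_genome(refseq, config$n_pieces, config$min_piece_len, seed = NULL)
    n <- nrow(iv)
    perm <- sample.int(n)
    flip <- runif(n) < config$revcomp_prob
    draft_id <- sprintf("piece_%03d", seq_len(n))
    draft <- character(n)
    ev <- matrix(0L, n, 3, dimnames = list(NULL, c("ins", "del", "mis")))
    for (k in seq_len(n)) {
      src <- perm[k]
      s <- substr(refseq, iv$start[src] + 1L, iv$end[src])
      if (flip[k]) s <- revcomp(s)
      s <- corrupt_sequence(s, config$ins_rate, config$del_rate, config$mis_rate)
      ev[k, ] <- attr(s, "events")
      draft[k] <- as.character(s)
    }
    names(draft) <- draft_id
    layout <- data.frame(
      draft_id = draft_id, ref_id = ref_id,
      ref_start = iv$start[perm], ref_end = iv$end[perm],
      strand = ifelse(flip, "-", "+"),
      order_index = seq_len(n) - 1L
    )
    list(draft = draft, layout = layout,
         events = data.frame(draft_id = draft_id, ev,
                             src_len = iv$end[perm] - iv$start[perm]))
  })
}

#' Write / read a truth layout table
#'
#' Tab-separated with header: `draft_id ref_id ref_start ref_end strand
#' order_index`; coordinates 0-based half-open.
#'
#' @param layout a layout data.frame as returned by [mutate_assembly()].
#' @param path file path.
#' @return `path` (write) or the layout data.frame (read).
#' @export
write_layout <- function(layout, path) {
  write.table(layout, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
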