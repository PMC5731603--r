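BASES <- c("A", "C", "G", "T")

# Evaluate `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards.  All simulator entry points route their
# randomness through this so a seed fully determines their output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Reverse complement of a nucleotide string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a uniform random genome sequence
#'
#' @param length number of bases.
#' @param seed integer seed (optional).
#' @return a single character string over A/C/G/T.
#' @export
random_genome <- function(length, seed = NULL) {
  stopifnot(length >= 1)
  with_seed(seed, paste(sample(BASES, length, replace = TRUE), collapse = ""))
}

# Coerce sequence input (character vector, DNAString(Set)) to a named
# character vector; unnamed single sequences get the fallback name.
as_seq_vector <- function(x, fallback = "seq1") {
  if (inherits(x, "DNAString")) x <- Biostrings::DNAStringSet(x)
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    return(out)
  }
  x <- setNames(as.character(x), names(x))
  if (is.null(names(x))) {
    names(x) <- if (length(x) == 1) fallback else paste0("seq", seq_along(x))
  }
  x
}

#' Write sequences as multi-record FASTA
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output file.
#' @param width line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  seqs <- as_seq_vector(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = width)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

# standard N50 over a vector of lengths
n50 <- function(lengths) {
  if (length(lengths) == 0) return(0L)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  as.integer(s[which(cumsum(s) >= sum(s) / 2)[1]])
}
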