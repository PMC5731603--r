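## Read-length model -----------------------------------------------------
##
## Error-corrected long-read sets are bimodal in practice: correction trims
## and splits raw reads, leaving a population of short corrected fragments
## next to the full-length reads.  A single lognormal cannot reproduce the
## calibration statistics used here (mean 4070 bp, upper quartile 6231 bp):
## for any lognormal mean/Q3 = exp(s^2/2 - z75*s) >= 0.797, while the target
## ratio is 0.653.  We therefore model lengths as a two-component lognormal
## mixture (fragments + full-length), with the fragment component fixed and
## the mixture weight and full-length location solved so that the mixture
## mean and upper quartile hit the targets exactly.

FRAG_MEANLOG <- log(1200)
FRAG_SDLOG <- 0.6
FULL_SDLOG <- 0.35

#' Calibrate the read-length mixture to a target mean and upper quartile
#'
#' Solves for the fragment-component weight `w` and the full-length component
#' `meanlog` such that the two-component lognormal mixture has the requested
#' mean and 75th percentile.  The fragment component is fixed at
#' `meanlog = log(1200)`, `sdlog = 0.6`; the full-length `sdlog` is 0.35.
#'
#' @param mean_len target mean read length in bases.
#' @param q3_len target upper-quartile read length in bases.
#' @return list with mixture parameters `w`, `meanlog1`, `sdlog1`,
#'   `meanlog2`, `sdlog2`.
#' @export
calibrate_length_model <- function(mean_len = 4070, q3_len = 6231) {
  e1 <- exp(FRAG_MEANLOG + FRAG_SDLOG^2 / 2)
  mu2_of_w <- function(w) log((mean_len - w * e1) / (1 - w)) - FULL_SDLOG^2 / 2
  g <- function(w) {
    w * plnorm(q3_len, FRAG_MEANLOG, FRAG_SDLOG) +
      (1 - w) * plnorm(q3_len, mu2_of_w(w), FULL_SDLOG) - 0.75
  }
  w <- uniroot(g, c(0.05, 0.6), tol = 1e-10)$root
  list(w = w, meanlog1 = FRAG_MEANLOG, sdlog1 = FRAG_SDLOG,
       meanlog2 = mu2_of_w(w), sdlog2 = FULL_SDLOG)
}

# Defaults frozen from calibrate_length_model(4070, 6231); a unit test keeps
# these constants in sync with the solver.
DEFAULT_LENGTH_MODEL <- list(
  w = 0.4793336117, meanlog1 = 7.0900768358, sdlog1 = 0.6,
  meanlog2 = 8.7174290974, sdlog2 = 0.35
)

#' Sample read lengths from the default (or a given) length model
#'
#' Lengths are drawn from the two-component lognormal mixture, rounded to
#' integer bases, and truncated below at `min_len` by rejection.
#'
#' @param n number of lengths.
#' @param model mixture parameters (see [calibrate_length_model()]).
#' @param min_len minimum length in bases.
#' @param seed integer seed (optional).
#' @return integer vector of `n` read lengths.
#' @export
sample_read_lengths <- function(n, model = DEFAULT_LENGTH_MODEL,
                                min_len = 100, seed = NULL) {
  with_seed(seed, {
    out <- integer(0)
    while (length(out) < n) {
      k <- max(n - length(out), 16L)
      frag <- runif(k) < model$w
      len <- ifelse(frag,
                    rlnorm(k, model$meanlog1, model$sdlog1),
                    rlnorm(k, model$meanlog2, model$sdlog2))
      len <- as.integer(round(len))
      out <- c(out, len[len >= min_len])
    }
    out[seq_len(n)]
  })
}

#' Configuration for the long-read simulator
#'
#' @param coverage target fold coverage of the reference.
#' @param length_model read-length mixture parameters; defaults are
#'   calibrated so the length distribution has mean 4070 bp and upper
#'   quartile 6231 bp.
#' @param min_len minimum read length in bases.
#' @param residual_error_rate total residual error rate of the already
#'   error-corrected reads (split equally between insertion, deletion and
#'   mismatch); must be in [0, 0.05].
#' @param seed integer seed.
#' @return an object of class `read_sim_config`.
#' @export
read_sim_config <- function(coverage = 50, length_model = DEFAULT_LENGTH_MODEL,
                            min_len = 100, residual_error_rate = 0.005,
                            seed = NULL) {
  stopifnot(coverage > 0, min_len >= 1,
            residual_error_rate >= 0, residual_error_rate <= 0.05)
  structure(list(coverage = coverage, length_model = length_model,
                 min_len = as.integer(min_len),
                 residual_error_rate = residual_error_rate, seed = seed),
            class = "read_sim_config")
}

#' Simulate error-corrected long reads from a reference
#'
#' Read start positions are uniform over the reference, lengths come from the
#' mixture model (truncated at `min_len` and at the sequence end), each read
#' is reverse complemented with probability 0.5, and residual errors are
#' applied at `residual_error_rate` with an equal insertion / deletion /
#' mismatch split.  Reads are emitted until total bases reach
#' `coverage * reference length` (overshoot at most one read).
#'
#' @param reference a single named nucleotide string.
#' @param config a [read_sim_config()].
#' @return list with elements
#'   * `reads`: named character vector of read sequences,
#'   * `truth`: data.frame (`read_id`, `ref_id`, `ref_start`, `ref_end`,
#'     `strand`) with 0-based half-open source intervals.
#' @export
simulate_reads <- function(reference, config = read_sim_config()) {
  reference <- as_seq_vector(reference, fallback = "ref")
  stopifnot(length(reference) == 1)
  L <- nchar(reference)
  if (L < config$min_len)
    stop(sprintf("reference length %d is shorter than min_len %d", L, config$min_len))
  ref_id <- names(reference)
  refseq <- unname(reference)
  err <- config$residual_error_rate / 3
  with_seed(config$seed, {
    target <- config$coverage * L
    lens <- integer(0)
    while (sum(as.numeric(lens)) < target) {
      k <- max(16L, ceiling((target - sum(as.numeric(lens))) / 3000))
      lens <- c(lens, pmin(sample_read_lengths(k, config$length_model,
                                               config$min_len), L))
    }
    n <- which(cumsum(as.numeric(lens)) >= target)[1]
    lens <- lens[seq_len(n)]
    # uniform over feasible starts so the drawn length is fully used
    starts <- vapply(lens, function(len) sample.int(L - len + 1L, 1L) - 1L, 0L)
    ends <- starts + lens
    reads <- substring(refseq, starts + 1L, ends)
    minus <- runif(n) < 0.5
    if (any(minus)) reads[minus] <- revcomp(reads[minus])
    if (err > 0)
      reads <- vapply(reads, function(sq)
        as.character(corrupt_sequence(sq, err, err, err)), "", USE.NAMES = FALSE)
    strands <- ifelse(minus, "-", "+")
    ids <- sprintf("read_%05d", seq_along(reads))
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read_id = ids, ref_id = ref_id,
                            ref_start = starts, ref_end = ends,
                            strand = strands))
  })
}

#' Toy truth-based aligner: aligned blocks of simulated reads on a draft
#'
#' For simulated inputs with known provenance, computes the aligned-block
#' table a long-read aligner would produce by intersecting each read's source
#' interval on the reference with each draft piece's source interval, and
#' mapping the overlap into draft and read coordinates.  Intended as test
#' infrastructure: coordinates are exact only when neither the draft pieces
#' nor the reads carry simulated insertions / deletions (mismatch-only
#' corruption is fine since it does not shift coordinates).
#'
#' @param read_truth truth data.frame from [simulate_reads()].
#' @param layout truth layout from [mutate_assembly()].
#' @param read_len named integer vector of read lengths.
#' @param identity identity value to report for every block (fraction).
#' @param min_block minimum overlap length to emit a block (bases).
#' @return an `aligned_blocks` data.frame (see [parse_coords()]).
#' @export
truth_alignments <- function(read_truth, layout, read_len,
                             identity = 1.0, min_block = 30L) {
  ri <- IRanges::IRanges(start = read_truth$ref_start + 1L, end = read_truth$ref_end)
  pi_ <- IRanges::IRanges(start = layout$ref_start + 1L, end = layout$ref_end)
  ov <- IRanges::findOverlaps(ri, pi_, minoverlap = as.integer(min_block))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  if (length(qh) == 0) return(empty_blocks())
  # overlap interval on the reference, 0-based half-open
  os <- pmax(read_truth$ref_start[qh], layout$ref_start[sh])
  oe <- pmin(read_truth$ref_end[qh], layout$ref_end[sh])
  piece_len <- layout$ref_end[sh] - layout$ref_start[sh]
  # draft coordinates of the overlap within the piece
  plus_piece <- layout$strand[sh] == "+"
  DL <- ifelse(plus_piece, os - layout$ref_start[sh], layout$ref_end[sh] - oe)
  DR <- DL + (oe - os)
  # read coordinates of the overlap on the forward read strand
  plus_read <- read_truth$strand[qh] == "+"
  RL <- ifelse(plus_read, os - read_truth$ref_start[qh], read_truth$ref_end[qh] - oe)
  RR <- RL + (oe - os)
  strand <- ifelse(plus_piece == plus_read, "+", "-")
  blocks <- data.frame(
    draft_id = layout$draft_id[sh], read_id = read_truth$read_id[qh],
    DL = as.integer(DL), DR = as.integer(DR),
    RL = as.integer(RL), RR = as.integer(RR),
    strand = strand, identity = identity,
    stringsAsFactors = FALSE
  )
  class(blocks) <- c("aligned_blocks", "data.frame")
  blocks
}
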