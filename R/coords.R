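## Aligned-block tables (the tab-separated `show-coords -T` dialect):
## columns S1 E1 S2 E2 LEN1 LEN2 %IDY REF_ID QRY_ID, coordinates 1-based
## inclusive, reverse-strand rows carrying query start > end.  Internally
## blocks are 0-based half-open on the forward strands of both sequences.

empty_blocks <- function() {
  blocks <- data.frame(draft_id = character(0), read_id = character(0),
                       DL = integer(0), DR = integer(0),
                       RL = integer(0), RR = integer(0),
                       strand = character(0), identity = numeric(0),
                       stringsAsFactors = FALSE)
  class(blocks) <- c("aligned_blocks", "data.frame")
  blocks
}

#' Construct an aligned-block table
#'
#' @param draft_id,read_id sequence identifiers.
#' @param DL,DR draft coordinates, 0-based half-open.
#' @param RL,RR read coordinates on the forward read strand, 0-based
#'   half-open.
#' @param strand `"+"` or `"-"` (read orientation relative to the draft).
#' @param identity alignment identity as a fraction in [0, 1].
#' @return data.frame of class `aligned_blocks`.
#' @export
aligned_blocks <- function(draft_id, read_id, DL, DR, RL, RR,
                           strand = "+", identity = 1.0) {
  blocks <- data.frame(draft_id = draft_id, read_id = read_id,
                       DL = as.integer(DL), DR = as.integer(DR),
                       RL = as.integer(RL), RR = as.integer(RR),
                       strand = strand, identity = identity,
                       stringsAsFactors = FALSE)
  stopifnot(all(blocks$DL < blocks$DR), all(blocks$RL < blocks$RR),
            all(blocks$identity >= 0 & blocks$identity <= 1),
            all(blocks$strand %in% c("+", "-")))
  class(blocks) <- c("aligned_blocks", "data.frame")
  blocks
}

#' Parse an aligned-block (coords) table
#'
#' Reads the tab-separated dialect `S1 E1 S2 E2 LEN1 LEN2 %IDY REF_ID
#' QRY_ID` (header lines are skipped).  File coordinates are 1-based
#' inclusive; reverse-strand rows (query start > query end) are normalized to
#' forward-strand 0-based half-open coordinates with `strand = "-"`.
#'
#' @param path coords file.
#' @return data.frame of class `aligned_blocks` with columns `draft_id`,
#'   `read_id`, `DL`, `DR`, `RL`, `RR`, `strand`, `identity`.
#' @export
parse_coords <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(empty_blocks())
  first <- sub("\t.*$", "", lines)
  is_data <- grepl("^\\s*-?[0-9]+$", first)
  keep <- which(is_data)
  if (length(keep) == 0) return(empty_blocks())
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != 9))
    stop(sprintf("malformed coords row at line %d: expected 9 tab-separated fields, got %d",
                 keep[which(nf != 9)[1]], nf[nf != 9][1]))
  m <- do.call(rbind, rows)
  num <- suppressWarnings(apply(m[, 1:7, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 7)
  if (anyNA(num))
    stop(sprintf("malformed coords row at line %d: non-numeric coordinate field",
                 keep[which(rowSums(is.na(num)) > 0)[1]]))
  s1 <- num[, 1]; e1 <- num[, 2]; s2 <- num[, 3]; e2 <- num[, 4]
  zero <- (s1 >= e1) | (s2 == e2)
  if (any(zero)) {
    message(sprintf("parse_coords: dropping %d degenerate row(s) (start == end)",
                    sum(zero)))
  }
  ok <- !zero
  minus <- s2 > e2
  RL <- ifelse(minus, e2 - 1, s2 - 1)
  RR <- ifelse(minus, s2, e2)
  blocks <- data.frame(
    draft_id = m[, 8], read_id = m[, 9],
    DL = as.integer(s1 - 1), DR = as.integer(e1),
    RL = as.integer(RL), RR = as.integer(RR),
    strand = ifelse(minus, "-", "+"),
    identity = num[, 7] / 100,
    stringsAsFactors = FALSE
  )[ok, , drop = FALSE]
  rownames(blocks) <- NULL
  class(blocks) <- c("aligned_blocks", "data.frame")
  blocks
}

#' Write an aligned-block table in the coords dialect
#'
#' Inverse of [parse_coords()]: emits `S1 E1 S2 E2 LEN1 LEN2 %IDY REF_ID
#' QRY_ID` with 1-based inclusive coordinates and reverse-strand rows encoded
#' by a descending query interval.
#'
#' @param blocks an `aligned_blocks` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coords <- function(blocks, path) {
  minus <- blocks$strand == "-"
  out <- data.frame(
    S1 = blocks$DL + 1L, E1 = blocks$DR,
    S2 = ifelse(minus, blocks$RR, blocks$RL + 1L),
    E2 = ifelse(minus, blocks$RL + 1L, blocks$RR),
    LEN1 = blocks$DR - blocks$DL, LEN2 = blocks$RR - blocks$RL,
    IDY = sprintf("%.2f", blocks$identity * 100),
    REF = blocks$draft_id, QRY = blocks$read_id
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("[COORDS]", "NUCMER", "",
               paste(c("[S1]", "[E1]", "[S2]", "[E2]", "[LEN 1]", "[LEN 2]",
                       "[% IDY]", "[TAGS]", ""), collapse = "\t")), con)
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
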