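IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Parse a degenerate DNA motif into per-position base classes
#'
#' Motifs use single-letter IUPAC codes (`AGATY`) and/or bracket classes
#' (`AGAT[TC]`). The symbol `N` matches any of A/C/G/T but never the
#' sequence character N.
#'
#' @param motif Motif string.
#' @return List of character vectors, one per motif position.
#' @export
parse_iupac <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif))
    stop("motif must be a non-empty string")
  chars <- strsplit(toupper(motif), "")[[1]]
  classes <- list()
  i <- 1L
  pos <- 0L
  while (i <= length(chars)) {
    pos <- pos + 1L
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      members <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        if (chars[j] != ",") members <- c(members, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) stop("unclosed bracket class at position ", pos)
      if (!length(members) || !all(members %in% c("A", "C", "G", "T")))
        stop("invalid bracket class at position ", pos)
      classes[[pos]] <- unique(members)
      i <- j + 1L
    } else if (ch %in% names(IUPAC_CLASSES)) {
      classes[[pos]] <- IUPAC_CLASSES[[ch]]
      i <- i + 1L
    } else {
      stop(sprintf("invalid motif symbol '%s' at position %d", ch, pos))
    }
  }
  classes
}

#' Expand a degenerate motif into all concrete sequences
#'
#' @param motif Motif string (see [parse_iupac()]).
#' @return Character vector of concrete DNA strings; length equals the
#'   product of the per-position class sizes.
#' @export
#' @examples
#' expand_iupac("AAGAT[TC]TT")
expand_iupac <- function(motif) {
  classes <- parse_iupac(motif)
  grid <- do.call(expand.grid,
                  c(rev(classes),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  grid <- grid[, rev(seq_along(classes)), drop = FALSE]
  unique(do.call(paste0, grid))
}

motif_length <- function(motif) length(parse_iupac(motif))

#' Reverse complement of DNA strings
#'
#' @param x Character vector over A/C/G/T/N.
#' @return Reverse-complemented strings.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

sequence_windows <- function(seq, width) {
  n <- nchar(seq)
  if (n < width) return(character(0))
  substring(seq, seq_len(n - width + 1L), seq(width, n))
}

#' Count motif occurrences in one sequence
#'
#' Sliding-window exact degenerate matching at every position; overlapping
#' matches are counted by default (poly-TA motifs overlap heavily).
#' Windows containing N never match. With `strand_mode = "both"` the
#' reverse complement is scanned as well and positions of reverse-strand
#' matches are reported as the forward-strand start of the matched window.
#'
#' @param seq DNA string (upper case A/C/G/T/N).
#' @param motif Degenerate motif string.
#' @param strand_mode `"forward"` (default) or `"both"`.
#' @param count_overlaps Count overlapping occurrences (default `TRUE`);
#'   when `FALSE`, occurrences are taken greedily left to right without
#'   overlap, per strand.
#' @return List: `count`, `positions` (1-based forward-strand starts,
#'   sorted).
#' @export
#' @examples
#' count_occurrences("TATATATATA", "TATATATA")$count  # 2
count_occurrences <- function(seq, motif,
                              strand_mode = c("forward", "both"),
                              count_overlaps = TRUE) {
  strand_mode <- match.arg(strand_mode)
  words <- expand_iupac(motif)
  m <- nchar(words[1])
  scan1 <- function(s) {
    pos <- which(sequence_windows(s, m) %in% words)
    if (!count_overlaps && length(pos) > 1L) {
      keep <- pos[1]
      last <- pos[1]
      for (p in pos[-1]) if (p >= last + m) { keep <- c(keep, p); last <- p }
      pos <- keep
    }
    pos
  }
  seq <- toupper(seq)
  pos <- scan1(seq)
  if (strand_mode == "both") {
    rpos <- scan1(reverse_complement(seq))
    if (length(rpos)) pos <- c(pos, nchar(seq) - (rpos + m - 1L) + 1L)
  }
  pos <- sort(pos)
  list(count = length(pos), positions = pos)
}

# Occurrence and presence counts of a fixed set of same-length concrete
# words across a promoter set. Returns list(occ = named numeric vector of
# total occurrence counts, present = named numeric vector of number of
# promoters containing each word, total_bp, n_promoters).
tabulate_words <- function(promoters, words, width,
                           strand_mode = "forward") {
  occ <- numeric(length(words))
  present <- numeric(length(words))
  names(occ) <- names(present) <- words
  for (s in promoters) {
    w <- sequence_windows(s, width)
    if (strand_mode == "both")
      w <- c(w, sequence_windows(reverse_complement(s), width))
    idx <- match(w, words)
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      t1 <- tabulate(idx, nbins = length(words))
      occ <- occ + t1
      present <- present + (t1 > 0)
    }
  }
  list(occ = occ, present = present,
       total_bp = sum(nchar(promoters)), n_promoters = length(promoters))
}
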