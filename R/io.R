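#' Normalize gene identifiers
#'
#' Gene IDs (AGI locus codes such as `AT5G62920`, rice locus codes, probe
#' IDs) are compared case-insensitively throughout the pipeline: IDs are
#' trimmed and upper-cased on entry.
#'
#' @param x Character vector of gene identifiers.
#' @return Upper-cased, trimmed character vector.
#' @export
#' @examples
#' normalize_gene_id(c(" at5g62920 ", "At1G19050"))
normalize_gene_id <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (any(!nzchar(x) | is.na(x))) stop("empty or missing gene identifier")
  x
}

parse_ratio_number <- function(x) {
  # accepts dot or comma decimals; "" / NA / "NA" stay missing
  x <- trimws(x)
  miss <- is.na(x) | x == "" | toupper(x) == "NA"
  out <- suppressWarnings(as.numeric(gsub(",", ".", x, fixed = TRUE)))
  out[miss] <- NA_real_
  bad <- !miss & is.na(out)
  attr(out, "bad") <- which(bad)
  out
}

#' Read a per-experiment expression-ratio table
#'
#' Reads a table of per-gene treated-versus-control expression ratios (one
#' gene-ID column, one or more numeric ratio columns, e.g. one per
#' experiment x time point). Decimal commas, as printed in European
#' spreadsheet exports ("11,72"), are parsed transparently; all output uses
#' dot decimals. Missing cells stay missing.
#'
#' @param path Path to the table.
#' @param dialect `"tsv"` (default) or `"csv"` field separator.
#' @return A data.frame of class `"ratio_table"`: first column `gene_id`
#'   (normalized, unique), remaining columns numeric ratios.
#' @export
read_ratio_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("ratio table needs a gene-ID column and >= 1 ratio column")
  ids <- normalize_gene_id(raw[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate gene ID in ratio table: ", dup[1])
  vals <- lapply(seq(2L, ncol(raw)), function(j) {
    v <- parse_ratio_number(raw[[j]])
    bad <- attr(v, "bad")
    if (length(bad))
      stop(sprintf("non-numeric ratio '%s' at row %d, column '%s'",
                   raw[[j]][bad[1]], bad[1], names(raw)[j]))
    as.numeric(v)
  })
  out <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  out[names(raw)[-1]] <- vals
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Write a ratio table (dot decimals, TSV)
#'
#' @param x A `ratio_table` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratio_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, dec = ".")
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' Promoters are strand-oriented upstream windows (by convention the
#' -1000..-1 bp window 5'->3' toward the gene; the file itself carries no
#' coordinates). The record ID is the first whitespace-delimited token of
#' the header and must start with the gene identifier. Sequences are
#' upper-cased and must use only A, C, G, T, N; N never matches any motif
#' symbol during scanning.
#'
#' @param path FASTA file.
#' @return Named character vector of class `"promoter_set"` (ID -> sequence).
#' @export
read_fasta_promoters <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- normalize_gene_id(sub("\\s.*$", "", names(seqs)))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate promoter ID: ", dup[1])
  s <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", s)
  if (any(bad))
    stop("invalid sequence character in record ", ids[which(bad)[1]])
  if (any(!nzchar(s)))
    stop("empty sequence in record ", ids[which(!nzchar(s))[1]])
  names(s) <- ids
  structure(s, class = "promoter_set")
}

#' Write promoter sequences to FASTA
#'
#' @param x Named character vector of sequences (a `promoter_set`).
#' @param path Output path.
#' @param width Line width for wrapping. Default 70.
#' @return `path`, invisibly.
#' @export
write_fasta_promoters <- function(x, path, width = 70L) {
  stopifnot(!is.null(names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d sequences, lengths %d..%d bp\n",
              length(x), min(nchar(x)), max(nchar(x))))
  invisible(x)
}

HIT_COLUMNS <- c("query", "subject", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a 12-column tabular similarity hit table
#'
#' Reads pairwise similarity hits in the standard 12-column tabular format
#' (query, subject, %identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, E-value, bit score). Hits are ranked
#' per query by descending bit score, ties broken by ascending E-value then
#' lexicographic subject ID, giving a total order that is invariant to the
#' input row order.
#'
#' @param path Path to the tab-separated hit file (no header).
#' @return A data.frame of class `"hit_table"` with the 12 named columns,
#'   sorted by query and rank, plus a `rank` column.
#' @export
read_hit_table <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L || is.null(nf)) {
    out <- data.frame(matrix(nrow = 0, ncol = 12,
                             dimnames = list(NULL, HIT_COLUMNS)))
    out$rank <- integer(0)
    class(out) <- c("hit_table", "data.frame")
    return(out)
  }
  short <- which(nf < 12L)
  if (length(short))
    stop(sprintf("hit table line %d has %d column(s), expected 12",
                 short[1], nf[short[1]]))
  raw <- utils::read.delim(path, header = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  raw <- raw[, 1:12]
  names(raw) <- HIT_COLUMNS
  raw$query <- normalize_gene_id(raw$query)
  raw$subject <- normalize_gene_id(raw$subject)
  rank_hit_table(raw)
}

rank_hit_table <- function(df) {
  ord <- order(df$query, -df$bitscore, df$evalue, df$subject)
  df <- df[ord, , drop = FALSE]
  df$rank <- stats::ave(seq_len(nrow(df)), df$query,
                        FUN = seq_along)
  rownames(df) <- NULL
  class(df) <- c("hit_table", "data.frame")
  df
}
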