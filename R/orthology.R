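hits_for <- function(hits, gene, drop_self = TRUE) {
  h <- hits[hits$query == gene, , drop = FALSE]
  if (drop_self) h <- h[h$subject != gene, , drop = FALSE]
  h
}

top_reverse_hit <- function(reverse, subject) {
  h <- hits_for(reverse, subject, drop_self = TRUE)
  if (nrow(h) == 0L) NA_character_ else h$subject[1]
}

#' Iterative reciprocal-top-hit orthologs for one gene
#'
#' Walks the ranked forward hits (query species -> target species) of
#' `gene` in order. Each target-species subject is accepted while `gene` is
#' the top-ranked reverse hit of that subject; the walk stops at the first
#' subject for which it is not (`rule = "prefix"`, the default iterative
#' rule), so the result is always a prefix of the forward ranking. A
#' subject absent from the reverse table fails the reciprocal check and
#' stops the walk. `rule = "filter"` instead keeps every reciprocal subject
#' regardless of position (sensitivity-analysis variant). Self-hits
#' (identical query and subject IDs) are removed before ranking; "top hit"
#' means rank 1 after the bit-score / E-value / lexicographic tie-break.
#'
#' @param forward `hit_table` of query-species proteins vs the target
#'   species database.
#' @param reverse `hit_table` of target-species proteins vs the query
#'   species database.
#' @param gene Query gene ID; if absent from `forward`, the result is
#'   empty.
#' @param rule `"prefix"` (stop at first failure) or `"filter"` (keep all
#'   reciprocal hits).
#' @return Character vector of accepted target-species IDs in forward rank
#'   order.
#' @export
reciprocal_orthologs <- function(forward, reverse, gene,
                                 rule = c("prefix", "filter")) {
  rule <- match.arg(rule)
  gene <- normalize_gene_id(gene)
  fwd <- hits_for(forward, gene)
  if (nrow(fwd) == 0L) return(character(0))
  accepted <- character(0)
  for (s in fwd$subject) {
    top <- top_reverse_hit(reverse, s)
    ok <- !is.na(top) && top == gene
    if (ok) {
      accepted <- c(accepted, s)
    } else if (rule == "prefix") {
      break
    }
  }
  unique(accepted)
}

#' Build an ortholog map from reciprocal hit tables
#'
#' Applies [reciprocal_orthologs()] to every query (or a supplied subset)
#' of the forward table.
#'
#' @param forward,reverse `hit_table`s as in [reciprocal_orthologs()].
#' @param genes Optional character vector of query genes; default all
#'   queries in `forward`.
#' @param rule Passed to [reciprocal_orthologs()].
#' @param source Source tag recorded per pair. Default `"reciprocal"`.
#' @return Data.frame of class `"ortholog_map"`: `gene_id`, `ortholog`,
#'   `source`. Genes without orthologs are absent (no empty sets stored).
#' @export
build_ortholog_map <- function(forward, reverse, genes = NULL,
                               rule = c("prefix", "filter"),
                               source = "reciprocal") {
  rule <- match.arg(rule)
  if (is.null(genes)) genes <- unique(forward$query)
  else genes <- unique(normalize_gene_id(genes))
  pairs <- lapply(genes, function(g) {
    orth <- reciprocal_orthologs(forward, reverse, g, rule)
    if (length(orth) == 0L) return(NULL)
    data.frame(gene_id = g, ortholog = orth, source = source,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(pairs, list(empty_ortholog_map())))
  rownames(out) <- NULL
  class(out) <- c("ortholog_map", "data.frame")
  out
}

empty_ortholog_map <- function() {
  data.frame(gene_id = character(0), ortholog = character(0),
             source = character(0), stringsAsFactors = FALSE)
}

#' Read an ortholog pair list
#'
#' Two-column TSV (`gene_id`, `ortholog`), e.g. from an external orthology
#' service export.
#'
#' @param path Path to the TSV (header optional; detected by whether the
#'   first field parses as a header token `gene_id`).
#' @param source Source tag. Default `"external_list"`.
#' @return An `"ortholog_map"` data.frame.
#' @export
read_ortholog_pairs <- function(path, source = "external_list") {
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) && tolower(raw[1, 1]) == "gene_id")
    raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0L) {
    out <- empty_ortholog_map()
  } else {
    out <- data.frame(gene_id = normalize_gene_id(raw[[1]]),
                      ortholog = normalize_gene_id(raw[[2]]),
                      source = source, stringsAsFactors = FALSE)
    out <- out[!duplicated(out[c("gene_id", "ortholog")]), ]
    rownames(out) <- NULL
  }
  class(out) <- c("ortholog_map", "data.frame")
  out
}

#' Merge two ortholog maps and report their overlap
#'
#' Pairwise union of two ortholog sources; pairs found by both are tagged
#' `"both"`. The overlap fraction is `|pairs in both| / |pairs in union|`
#' (the published reciprocal-search vs service comparison reported ~20%).
#'
#' @param a,b `"ortholog_map"` data.frames.
#' @return List: `map` (merged `"ortholog_map"`), `overlap` (fraction, `NA`
#'   when both maps are empty).
#' @export
merge_sources <- function(a, b) {
  key <- function(m) paste(m$gene_id, m$ortholog, sep = "\r")
  ka <- key(a); kb <- key(b)
  all_keys <- union(ka, kb)
  if (length(all_keys) == 0L)
    return(list(map = empty_ortholog_map(), overlap = NA_real_))
  in_a <- all_keys %in% ka
  in_b <- all_keys %in% kb
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  out <- data.frame(
    gene_id = vapply(parts, `[`, "", 1L),
    ortholog = vapply(parts, `[`, "", 2L),
    source = ifelse(in_a & in_b, "both",
                    ifelse(in_a, a$source[match(all_keys, ka)],
                           b$source[match(all_keys, kb)])),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_id, out$ortholog), ]
  rownames(out) <- NULL
  class(out) <- c("ortholog_map", "data.frame")
  list(map = out, overlap = sum(in_a & in_b) / length(all_keys))
}
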