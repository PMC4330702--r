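#' Build a gene-list collection
#'
#' A named collection of gene sets (one per independent analysis), each
#' normalized and deduplicated, optionally with per-platform gene universes
#' for coverage statistics.
#'
#' @param lists Named list of character vectors of gene IDs.
#' @param universes Optional named list of character vectors (platform ->
#'   gene universe).
#' @return List of class `"gene_list_collection"` with elements `lists`,
#'   `universes`.
#' @export
gene_list_collection <- function(lists, universes = list()) {
  if (is.null(names(lists)) || any(!nzchar(names(lists))) ||
      anyDuplicated(names(lists)))
    stop("lists must have unique non-empty names")
  if (length(lists) > 8L) stop("at most 8 lists supported")
  lists <- lapply(lists, function(x) unique(normalize_gene_id(x)))
  universes <- lapply(universes, function(x) unique(normalize_gene_id(x)))
  structure(list(lists = lists, universes = universes),
            class = "gene_list_collection")
}

as_collection <- function(x) {
  if (inherits(x, "gene_list_collection")) x else gene_list_collection(x)
}

membership_matrix <- function(coll) {
  coll <- as_collection(coll)
  all_genes <- sort(unique(unlist(coll$lists, use.names = FALSE)))
  m <- vapply(coll$lists, function(s) all_genes %in% s,
              logical(length(all_genes)))
  m <- matrix(m, nrow = length(all_genes),
              dimnames = list(all_genes, names(coll$lists)))
  m
}

#' Venn partition of a gene-list collection
#'
#' Assigns every gene of the union to exactly one of the 2^n - 1 regions of
#' the n-set Venn diagram (the exact subset of lists containing it).
#'
#' @param coll A [gene_list_collection()] (or a plain named list of gene
#'   vectors) with >= 2 lists.
#' @return List of class `"overlap_partition"`: `regions` (named list,
#'   region label `"A+B"` -> member genes), `counts` (named integer
#'   vector over the same regions), `n_union`.
#' @export
#' @examples
#' p <- venn_partition(list(A = c("g1", "g2", "g3"), B = c("g2", "g3"),
#'                          C = "g3"))
#' p$counts[p$counts > 0]
venn_partition <- function(coll) {
  coll <- as_collection(coll)
  if (length(coll$lists) < 2L) stop("need at least 2 lists")
  m <- membership_matrix(coll)
  nm <- colnames(m)
  combos <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(nm, k, simplify = FALSE)), recursive = FALSE)
  labels <- vapply(combos, paste, "", collapse = "+")
  key <- apply(m, 1L, function(r) paste(nm[r], collapse = "+"))
  regions <- lapply(labels, function(l) rownames(m)[key == l])
  names(regions) <- labels
  counts <- lengths(regions)
  structure(list(regions = regions, counts = counts, n_union = nrow(m)),
            class = "overlap_partition")
}

#' Extract the k-of-n core set
#'
#' Genes present in at least `k` of the lists (the induced-core rule, e.g.
#' "in at least three of the four analyses"), or in exactly `k` lists when
#' `exact = TRUE` (the repressed-core rule, "found in only two independent
#' analyses").
#'
#' @param coll A [gene_list_collection()] or plain named list.
#' @param k Number of lists required.
#' @param exact If `TRUE`, require membership in exactly `k` lists.
#' @return Sorted character vector of gene IDs.
#' @export
core_set <- function(coll, k, exact = FALSE) {
  coll <- as_collection(coll)
  n <- length(coll$lists)
  if (!(k >= 1L && k <= n)) stop("k must lie in 1..", n)
  m <- membership_matrix(coll)
  cnt <- rowSums(m)
  keep <- if (exact) cnt == k else cnt >= k
  sort(rownames(m)[keep])
}

#' Fraction of a list's genes unique to it
#'
#' @param coll A [gene_list_collection()] or plain named list.
#' @param name Name of the list.
#' @return `|list \ union(others)| / |list|`, or `NA` for an empty list.
#' @export
unique_fraction <- function(coll, name) {
  coll <- as_collection(coll)
  if (!name %in% names(coll$lists)) stop("no list named ", name)
  this <- coll$lists[[name]]
  if (length(this) == 0L) return(NA_real_)
  others <- unique(unlist(coll$lists[setdiff(names(coll$lists), name)],
                          use.names = FALSE))
  length(setdiff(this, others)) / length(this)
}

#' Fraction of genes covered by a platform universe
#'
#' Mirrors cross-platform coverage statistics such as "61% of the regulated
#' genes also have a probe on the other array".
#'
#' @param genes Character vector of gene IDs.
#' @param universe Non-empty character vector (the platform's gene universe).
#' @return `|genes ∩ universe| / |genes|`, or `NA` for an empty gene set.
#' @export
platform_coverage <- function(genes, universe) {
  if (length(universe) == 0L) stop("universe must be non-empty")
  universe <- unique(normalize_gene_id(universe))
  if (length(genes) == 0L) return(NA_real_)
  genes <- unique(normalize_gene_id(genes))
  length(intersect(genes, universe)) / length(genes)
}

#' Write an overlap partition report
#'
#' @param partition An `"overlap_partition"` from [venn_partition()].
#' @param path Output TSV path (region, count, semicolon-joined members).
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(
    region = names(partition$regions),
    count = as.integer(partition$counts),
    members = vapply(partition$regions, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
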