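#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q(i) = min over j >= i of p(j) * m / j`, clipped to 1 and mapped back
#' to the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed,
#'   propagated).
#' @return q-values in the input order.
#' @export
#' @examples
#' bh_qvalues(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_qvalues <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

de_groups <- function(samples, group) {
  group <- as.character(group)
  if (!all(group %in% c("control", "treated")))
    stop("groups must be 'control' or 'treated'")
  g <- factor(group, levels = c("control", "treated"))
  if (any(table(g) < 2L))
    stop("each group needs >= 2 replicates")
  g
}

#' Differential-expression calling on a normalized expression matrix
#'
#' Two-group comparison of normalized log2 intensities: per-gene log2
#' fold-change (mean treated minus mean control), two-sided two-sample
#' t-test (equal-variance Student's t by default, matching spreadsheet
#' practice; Welch via `var_equal = FALSE`), Benjamini-Hochberg q-values
#' over all tested genes, and a significance call of at least `2`-fold
#' change (either direction) at `q <= 0.05` (config-driven).
#'
#' Degenerate genes (zero variance in both groups): equal means give
#' p = 1 by convention; unequal means with zero pooled variance give p = 0
#' (perfect separation).
#'
#' @param mat Numeric matrix, genes x samples, normalized log2 scale,
#'   finite values.
#' @param group Character/factor of `"control"`/`"treated"`, one per
#'   column of `mat`, each group with >= 2 replicates.
#' @param cfg A [pipeline_config()].
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @return Data.frame: `gene_id`, `log2fc`, `fold_change`, `p`, `q`,
#'   `significant`.
#' @export
differential_expression <- function(mat, group, cfg = pipeline_config(),
                                    var_equal = TRUE) {
  mat <- as.matrix(mat)
  if (!all(is.finite(mat))) stop("expression values must be finite")
  g <- de_groups(colnames(mat), group)
  a <- mat[, g == "control", drop = FALSE]
  b <- mat[, g == "treated", drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1L, stats::var); v2 <- apply(b, 1L, stats::var)
  if (var_equal) {
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se == 0
  p[zero & m1 == m2] <- 1
  p[zero & m1 != m2] <- 0
  log2fc <- m2 - m1
  fc <- 2^log2fc
  q <- bh_qvalues(p)
  gene_id <- rownames(mat)
  if (is.null(gene_id)) gene_id <- paste0("G", seq_len(nrow(mat)))
  data.frame(
    gene_id = normalize_gene_id(gene_id),
    log2fc = log2fc,
    fold_change = fc,
    p = p,
    q = q,
    significant = (fc >= cfg$induced_fold_cutoff |
                     fc <= cfg$repressed_fold_cutoff) & q <= cfg$q_cutoff,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Sanity gate for an expression dataset
#'
#' A dataset whose samples do not share the usual strong global correlation
#' structure (as with one published rice series that yielded no meaningful
#' data) is flagged for exclusion rather than silently processed.
#'
#' @param mat Genes x samples log2 matrix.
#' @param min_mean_cor Minimal mean pairwise Pearson correlation across
#'   samples. Default 0.7.
#' @return List: `pass` (logical), `mean_cor`, `reason` (string or `NA`).
#' @export
qc_expression_matrix <- function(mat, min_mean_cor = 0.7) {
  cm <- stats::cor(as.matrix(mat))
  mean_cor <- mean(cm[upper.tri(cm)])
  pass <- is.finite(mean_cor) && mean_cor >= min_mean_cor
  list(pass = pass, mean_cor = mean_cor,
       reason = if (pass) NA_character_ else
         sprintf("mean between-sample correlation %.3f below %.3f",
                 mean_cor, min_mean_cor))
}

#' Conserved-regulation join of a core set with cross-species DE results
#'
#' For each core-set gene: does it have at least one ortholog, and is any
#' ortholog significantly induced in at least one of the cross-species
#' datasets? Summary fractions mirror the published statistics (fraction of
#' core genes with an ortholog; among those, the fraction with a conserved
#' induction).
#'
#' @param core Character vector of core-set gene IDs.
#' @param orthomap An `"ortholog_map"` data.frame (see
#'   [build_ortholog_map()]) keyed by the core species' gene IDs.
#' @param de_list List of DE result data.frames (one per dataset) from
#'   [differential_expression()].
#' @return List: `table` (per-gene flags), `n_core`, `n_with_ortholog`,
#'   `n_conserved`, `frac_with_ortholog`, `frac_conserved` (NA when no gene
#'   has an ortholog).
#' @export
conserved_regulation <- function(core, orthomap, de_list) {
  core <- sort(unique(normalize_gene_id(core)))
  if (inherits(orthomap, "data.frame") && nrow(orthomap) > 0) {
    omap <- split(orthomap$ortholog, orthomap$gene_id)
  } else {
    omap <- list()
  }
  induced <- unique(unlist(lapply(de_list, function(de)
    de$gene_id[de$significant & de$log2fc > 0]), use.names = FALSE))
  has_orth <- vapply(core, function(g)
    length(omap[[g]]) > 0, logical(1))
  conserved <- vapply(core, function(g)
    length(intersect(omap[[g]], induced)) > 0, logical(1))
  n_with <- sum(has_orth)
  n_cons <- sum(conserved & has_orth)
  list(
    table = data.frame(gene_id = core, has_ortholog = has_orth,
                       conserved = conserved & has_orth,
                       row.names = NULL, stringsAsFactors = FALSE),
    n_core = length(core),
    n_with_ortholog = n_with,
    n_conserved = n_cons,
    frac_with_ortholog = if (length(core)) n_with / length(core) else NA_real_,
    frac_conserved = if (n_with > 0) n_cons / n_with else NA_real_
  )
}
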