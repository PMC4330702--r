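#' Round half away from zero
#'
#' Spreadsheet-style display rounding (6.945 -> 6.95 at 2 digits), as
#' opposed to base R's round-half-to-even. Used only for display columns;
#' all computation stays at full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(6.945, 7.145), 2)
round_half_away <- function(x, digits = 2L) {
  f <- 10^digits
  y <- abs(x) * f
  # relative epsilon absorbs binary representation error of decimal halves
  sign(x) * floor(y + 0.5 + pmax(abs(y), 1) * 1e-12) / f
}

#' Average expression ratios over time points and experiments
#'
#' Computes, for each gene, the arithmetic mean ratio per time point
#' (averaging over experiments) and the overall mean (arithmetic mean of
#' the per-time-point means). Means are taken on the linear ratio scale,
#' which is the convention that reproduces the derived average column of
#' published meta-analysis tables from the per-time-point columns. Missing
#' values are excluded from the respective mean; a gene with no values at
#' all is dropped with a message.
#'
#' @param table A `ratio_table` data.frame (see [read_ratio_table()]).
#' @param timepoints Character vector mapping each ratio column to a time
#'   point label. Default: each column is its own time point.
#' @return Data.frame with `gene_id`, one mean column per time point
#'   (`mean_<label>`), and `mean_ratio` (overall mean).
#' @export
average_ratios <- function(table, timepoints = NULL) {
  vals <- as.matrix(table[, -1, drop = FALSE])
  if (any(vals[!is.na(vals)] <= 0))
    stop("ratios must be positive")
  if (is.null(timepoints)) timepoints <- colnames(vals)
  if (length(timepoints) != ncol(vals))
    stop("timepoints must name every ratio column")
  tps <- unique(timepoints)
  per_tp <- sapply(tps, function(tp) {
    rowMeans(vals[, timepoints == tp, drop = FALSE], na.rm = TRUE)
  })
  per_tp <- matrix(per_tp, nrow = nrow(vals),
                   dimnames = list(NULL, tps))
  per_tp[is.nan(per_tp)] <- NA_real_
  overall <- rowMeans(per_tp, na.rm = TRUE)
  overall[is.nan(overall)] <- NA_real_
  keep <- !is.na(overall)
  if (any(!keep))
    message("dropping ", sum(!keep), " gene(s) with no ratio values: ",
            paste(utils::head(table$gene_id[!keep], 5), collapse = ", "))
  out <- data.frame(gene_id = table$gene_id[keep],
                    stringsAsFactors = FALSE)
  out[paste0("mean_", tps)] <- per_tp[keep, , drop = FALSE]
  out$mean_ratio <- overall[keep]
  out
}

#' Call induced / repressed genes from mean ratios
#'
#' Applies the fold-change cut-offs inclusively: mean ratio >= the induced
#' cut-off (default 2) calls "induced", <= the repressed cut-off (default
#' 0.5) calls "repressed", anything else "none".
#'
#' @param means Data.frame from [average_ratios()] (needs `gene_id`,
#'   `mean_ratio`).
#' @param cfg A [pipeline_config()].
#' @return Data.frame `gene_id`, `mean_ratio`, `direction` (factor with
#'   levels induced/repressed/none).
#' @export
call_regulation <- function(means, cfg = pipeline_config()) {
  dir <- ifelse(means$mean_ratio >= cfg$induced_fold_cutoff, "induced",
         ifelse(means$mean_ratio <= cfg$repressed_fold_cutoff,
                "repressed", "none"))
  data.frame(gene_id = means$gene_id,
             mean_ratio = means$mean_ratio,
             direction = factor(dir,
                                levels = c("induced", "repressed", "none")),
             stringsAsFactors = FALSE)
}

#' Default meta-analysis score (stand-in)
#'
#' Scores a gene's evidence of regulation across independent experiments as
#' the sum of absolute log2 ratios multiplied by the number of experiments
#' with at least a 2-fold change. This is a documented stand-in: the score
#' used to rank published meta-analysis tables is defined elsewhere and is
#' not reproduced here; [meta_score()] accepts any alternative scorer.
#'
#' @param ratios Numeric vector of per-experiment linear ratios.
#' @return A single score, or `NA` when fewer than 2 experiments have data.
#' @export
#' @examples
#' default_meta_score(c(2, 2))  # 4
default_meta_score <- function(ratios) {
  r <- ratios[!is.na(ratios)]
  if (length(r) < 2L) return(NA_real_)
  l <- abs(log2(r))
  sum(l) * sum(l >= 1)
}

#' Per-gene meta score over a ratio table
#'
#' @param table A `ratio_table` with one column per experiment (or use
#'   `experiments` to map columns to experiments; a gene's per-experiment
#'   ratio is then the mean over that experiment's columns).
#' @param experiments Optional character vector mapping ratio columns to
#'   experiment labels.
#' @param scorer Function from a per-experiment ratio vector to a score;
#'   default [default_meta_score()].
#' @return Data.frame `gene_id`, `meta_score`.
#' @export
meta_score <- function(table, experiments = NULL,
                       scorer = default_meta_score) {
  vals <- as.matrix(table[, -1, drop = FALSE])
  if (is.null(experiments)) experiments <- colnames(vals)
  if (length(experiments) != ncol(vals))
    stop("experiments must label every ratio column")
  exps <- unique(experiments)
  per_exp <- sapply(exps, function(e) {
    rowMeans(vals[, experiments == e, drop = FALSE], na.rm = TRUE)
  })
  per_exp <- matrix(per_exp, nrow = nrow(vals))
  per_exp[is.nan(per_exp)] <- NA_real_
  data.frame(gene_id = table$gene_id,
             meta_score = apply(per_exp, 1L, scorer),
             stringsAsFactors = FALSE)
}
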