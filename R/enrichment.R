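ratio_or_sentinel <- function(num, den) {
  # 0 target signal -> 0; positive target over zero control -> +Inf
  ifelse(num == 0, 0, ifelse(den == 0, Inf, num / den))
}

enrich_stats <- function(t_occ, c_occ, t_pres, c_pres,
                         n_t, n_c, bp_t, bp_c) {
  mean_lt <- bp_t / n_t
  mean_lc <- bp_c / n_c
  length_normalized <- abs(mean_lt - mean_lc) > 1e-9 * max(mean_lt, mean_lc)
  fold_occ <- if (length_normalized) {
    ratio_or_sentinel(t_occ / bp_t, c_occ / bp_c)
  } else {
    ratio_or_sentinel(t_occ / n_t, c_occ / n_c)
  }
  fold_pres <- ratio_or_sentinel(t_pres / n_t, c_pres / n_c)
  # one-sided exact test on the presence/absence 2x2 table:
  # P(X >= t_pres), X ~ hypergeometric(white = promoters with a hit,
  # draws = target-set size)
  p_pres <- stats::phyper(t_pres - 1, m = t_pres + c_pres,
                          n = (n_t - t_pres) + (n_c - c_pres),
                          k = n_t, lower.tail = FALSE)
  # per-occurrence binomial companion: each occurrence falls in the target
  # set with probability proportional to its share of scanned bases
  pr <- bp_t / (bp_t + bp_c)
  p_occ <- stats::pbinom(t_occ - 1, t_occ + c_occ, pr, lower.tail = FALSE)
  data.frame(
    target_occurrences = t_occ, control_occurrences = c_occ,
    target_promoters_with_hit = t_pres,
    control_promoters_with_hit = c_pres,
    fold_enrichment = fold_occ, fold_presence = fold_pres,
    p = p_pres, p_occurrence = p_occ,
    stringsAsFactors = FALSE
  )
}

#' Motif enrichment in a target vs a control promoter set
#'
#' Counts occurrences of a degenerate motif in both sets and reports
#' per-promoter fold enrichment (length-normalized per-base when the mean
#' window lengths differ), presence-based fold, and p-values. The primary
#' p is the one-sided exact test on the promoter presence/absence 2x2
#' table (hypergeometric tail); a per-occurrence binomial p is emitted
#' alongside. A motif absent from the control but present in the target
#' reports `fold_enrichment = Inf` with the presence p still computed.
#'
#' @param target,control `promoter_set`s (named character vectors), both
#'   non-empty.
#' @param motif Degenerate motif string.
#' @param cfg A [pipeline_config()] (supplies `strand_mode`).
#' @param count_overlaps Count overlapping occurrences (default `TRUE`).
#' @return One-row data.frame (an enrichment record): motif, occurrence
#'   and presence counts for both sets, `fold_enrichment` (occurrence
#'   based), `fold_presence`, `p` (presence exact test), `p_occurrence`.
#' @export
enrichment <- function(target, control, motif, cfg = pipeline_config(),
                       count_overlaps = TRUE) {
  if (length(target) == 0L || length(control) == 0L)
    stop("both promoter sets must be non-empty")
  counts_of <- function(set) {
    per <- lapply(set, count_occurrences, motif = motif,
                  strand_mode = cfg$strand_mode,
                  count_overlaps = count_overlaps)
    n <- vapply(per, `[[`, 0L, "count")
    list(occ = sum(n), pres = sum(n > 0), bp = sum(nchar(set)))
  }
  tg <- counts_of(target)
  ct <- counts_of(control)
  out <- enrich_stats(tg$occ, ct$occ, tg$pres, ct$pres,
                      length(target), length(control), tg$bp, ct$bp)
  cbind(data.frame(motif = motif, stringsAsFactors = FALSE), out)
}

screen_words <- function(words, target, control, cfg) {
  width <- nchar(words[1])
  tg <- tabulate_words(target, words, width, cfg$strand_mode)
  ct <- tabulate_words(control, words, width, cfg$strand_mode)
  out <- enrich_stats(tg$occ, ct$occ, tg$present, ct$present,
                      tg$n_promoters, ct$n_promoters,
                      tg$total_bp, ct$total_bp)
  out <- cbind(data.frame(motif = words, stringsAsFactors = FALSE), out)
  out$q <- bh_qvalues(out$p)
  out$selected <- out$fold_enrichment >= cfg$enrichment_fold_min &
    out$p <= cfg$enrichment_alpha
  rownames(out) <- NULL
  out
}

#' Exhaustive screen of octamers with a fixed central dinucleotide
#'
#' Tests every DNA octamer whose central positions 4-5 equal `center`
#' (default `"AT"`: 4^6 = 4096 motifs) for enrichment in the target
#' promoter set versus the control set. Selection follows the published
#' rule — fold enrichment >= `enrichment_fold_min` and raw p <=
#' `enrichment_alpha` — while Benjamini-Hochberg q-values over the full
#' screen are reported for transparency.
#'
#' @param target,control `promoter_set`s.
#' @param center Central dinucleotide (length 2; IUPAC codes allowed).
#' @param cfg A [pipeline_config()].
#' @return List: `full` (all records, ordered by p then motif),
#'   `selected` (rows passing the selection rule).
#' @export
octamer_screen <- function(target, control, center = "AT",
                           cfg = pipeline_config()) {
  if (motif_length(center) != 2L)
    stop("center must be a 2-bp motif")
  words <- expand_iupac(paste0("NNN", center, "NNN"))
  out <- screen_words(words, target, control, cfg)
  out <- out[order(out$p, -out$fold_enrichment, out$motif), ]
  rownames(out) <- NULL
  list(full = out, selected = out[out$selected, , drop = FALSE])
}

#' Screen every concrete motif derivable from a degenerate consensus
#'
#' Expands a consensus (for example a binding-site consensus derived from
#' protein-binding microarrays) and tests each concrete motif for
#' enrichment. In addition to the strict selection rule, a relaxed p band
#' `(alpha, relaxed_alpha]` is recorded (the source analysis reported
#' motifs "with a p-value between 0.05 and 0.06"): rows in the band that
#' meet the fold cut-off are flagged `relaxed_band` and included in the
#' returned selection, each carrying both flags.
#'
#' @param consensus Degenerate consensus motif string.
#' @param target,control `promoter_set`s.
#' @param cfg A [pipeline_config()].
#' @param relaxed_alpha Upper edge of the relaxed p band. Default 0.06.
#' @return List: `full` (all expanded motifs with `selected` and
#'   `relaxed_band` flags), `selected` (strict or relaxed-band rows).
#' @export
consensus_screen <- function(consensus, target, control,
                             cfg = pipeline_config(),
                             relaxed_alpha = 0.06) {
  words <- expand_iupac(consensus)
  out <- screen_words(words, target, control, cfg)
  out$relaxed_band <- !out$selected &
    out$fold_enrichment >= cfg$enrichment_fold_min &
    out$p > cfg$enrichment_alpha & out$p <= relaxed_alpha
  out <- out[order(out$p, -out$fold_enrichment, out$motif), ]
  rownames(out) <- NULL
  list(full = out,
       selected = out[out$selected | out$relaxed_band, , drop = FALSE])
}

#' Combined coverage and pooled enrichment of a motif list
#'
#' A target promoter is covered when at least one of the motifs hits it,
#' counted once regardless of how many motifs hit. The combined fold is
#' the pooled occurrence rate per target promoter over the pooled rate per
#' control promoter.
#'
#' @param motifs Non-empty character vector of (possibly degenerate)
#'   motifs.
#' @param target,control `promoter_set`s.
#' @param cfg A [pipeline_config()].
#' @return List: `coverage` (fraction of target promoters with >= 1 hit),
#'   `fold` (pooled occurrence fold), `n_target_with_hit`,
#'   `target_occurrences`, `control_occurrences`.
#' @export
combined_coverage <- function(motifs, target, control,
                              cfg = pipeline_config()) {
  if (length(motifs) == 0L) stop("need at least one motif")
  counts <- function(set) {
    per_prom <- vapply(set, function(s) {
      sum(vapply(motifs, function(m)
        count_occurrences(s, m, cfg$strand_mode)$count, 0L))
    }, 0L)
    per_prom
  }
  tg <- counts(target)
  ct <- counts(control)
  list(
    coverage = mean(tg > 0),
    fold = ratio_or_sentinel(sum(tg) / length(target),
                             sum(ct) / length(control)),
    n_target_with_hit = sum(tg > 0),
    target_occurrences = sum(tg),
    control_occurrences = sum(ct)
  )
}

#' Position frequency matrix and information content from motif hits
#'
#' Builds the position-frequency matrix underlying a sequence logo from
#' all occurrences of the supplied motifs in the target promoters
#' (occurrence-weighted), or directly from a character vector of
#' equal-length hit sequences. Per-column information content is
#' `2 - H(column)` bits (Shannon entropy, no small-sample correction).
#'
#' @param motifs_or_hits Character vector of motifs (scanned against
#'   `target`) or, when `target` is `NULL`, of concrete equal-length hit
#'   sequences.
#' @param target Optional `promoter_set` to scan.
#' @param cfg A [pipeline_config()].
#' @return Object of class `"pfm"`: `freq` (4 x L matrix, rows A/C/G/T,
#'   columns summing to 1), `info` (bits per column), `n_occurrences`.
#' @export
build_logo <- function(motifs_or_hits, target = NULL,
                       cfg = pipeline_config()) {
  if (is.null(target)) {
    hits <- toupper(motifs_or_hits)
  } else {
    hits <- unlist(lapply(motifs_or_hits, function(m) {
      words <- expand_iupac(m)
      width <- nchar(words[1])
      unlist(lapply(target, function(s) {
        w <- sequence_windows(s, width)
        if (cfg$strand_mode == "both")
          w <- c(w, sequence_windows(reverse_complement(s), width))
        w[w %in% words]
      }), use.names = FALSE)
    }), use.names = FALSE)
  }
  if (length(hits) == 0L) stop("no motif occurrences to build a logo from")
  if (length(unique(nchar(hits))) != 1L)
    stop("mixed lengths: all contributing sequences must be equally long")
  L <- nchar(hits[1])
  chars <- matrix(unlist(strsplit(hits, ""), use.names = FALSE),
                  nrow = length(hits), byrow = TRUE)
  freq <- vapply(seq_len(L), function(j) {
    tab <- table(factor(chars[, j], levels = c("A", "C", "G", "T")))
    as.numeric(tab) / length(hits)
  }, numeric(4))
  rownames(freq) <- c("A", "C", "G", "T")
  colnames(freq) <- seq_len(L)
  entropy <- apply(freq, 2L, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  structure(list(freq = freq, info = 2 - entropy,
                 n_occurrences = length(hits)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("pfm: %d positions from %d occurrences\n",
              ncol(x$freq), x$n_occurrences))
  print(round(x$freq, 3))
  cat("information (bits):", paste(round(x$info, 2), collapse = " "), "\n")
  invisible(x)
}

#' Plot a sequence logo from a position frequency matrix
#'
#' Letter heights scale with column frequency times column information
#' content, the conventional logo layout. Requires ggplot2.
#'
#' @param pfm A `"pfm"` object from [build_logo()].
#' @return A ggplot object.
#' @export
plot_logo <- function(pfm) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_logo requires ggplot2")
  L <- ncol(pfm$freq)
  df <- do.call(rbind, lapply(seq_len(L), function(j) {
    f <- sort(pfm$freq[, j])
    f <- f[f > 0]
    h <- f * pfm$info[j]
    data.frame(pos = j, base = names(f), height = h,
               y = cumsum(h) - h / 2, stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = pos, y = y, label = base,
                                   size = height, colour = base)) +
    ggplot2::geom_text(fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_size(range = c(2, 12)) +
    ggplot2::scale_colour_manual(values = c(A = "#109648", C = "#255C99",
                                            G = "#F7B32B", T = "#D62839")) +
    ggplot2::scale_x_continuous(breaks = seq_len(L)) +
    ggplot2::labs(x = "position", y = "bits") +
    ggplot2::theme_minimal()
}
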