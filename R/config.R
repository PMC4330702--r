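#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis chain in one validated
#' object. Defaults reproduce the study conditions of the cytokinin
#' meta-analysis: 2-fold induction / 0.5-fold repression cut-offs, q <= 0.05
#' for differential expression, the at-least-3-of-4 induced core rule and the
#' exactly-2 repressed core rule, 1000-bp promoter windows, and the
#' 2-fold / alpha = 0.05 motif-enrichment selection rule.
#'
#' @param induced_fold_cutoff Minimal mean linear ratio to call a gene
#'   induced (inclusive). Default 2.
#' @param repressed_fold_cutoff Maximal mean linear ratio to call a gene
#'   repressed (inclusive). Default 0.5.
#' @param q_cutoff FDR (Benjamini-Hochberg q) threshold for differential
#'   expression. Default 0.05.
#' @param core_k_induced Minimal number of lists a gene must appear in for
#'   the induced core set. Default 3.
#' @param core_k_repressed Exact number of lists for the repressed core set.
#'   Default 2.
#' @param promoter_window Nominal upstream window length in bp. Default 1000.
#' @param enrichment_alpha p-value threshold of the motif selection rule.
#' @param enrichment_fold_min Minimal fold enrichment of the selection rule.
#' @param strand_mode `"forward"` (default) or `"both"`: whether motif
#'   scanning also scans the reverse complement.
#' @param rng_seed Integer seed from which all randomness flows.
#'
#' @return A list of class `"pipeline_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config(q_cutoff = 0.01)
#' cfg$induced_fold_cutoff
pipeline_config <- function(induced_fold_cutoff = 2.0,
                            repressed_fold_cutoff = 0.5,
                            q_cutoff = 0.05,
                            core_k_induced = 3L,
                            core_k_repressed = 2L,
                            promoter_window = 1000L,
                            enrichment_alpha = 0.05,
                            enrichment_fold_min = 2.0,
                            strand_mode = c("forward", "both"),
                            rng_seed = 1L) {
  strand_mode <- match.arg(strand_mode)
  cfg <- list(
    induced_fold_cutoff = as.numeric(induced_fold_cutoff),
    repressed_fold_cutoff = as.numeric(repressed_fold_cutoff),
    q_cutoff = as.numeric(q_cutoff),
    core_k_induced = as.integer(core_k_induced),
    core_k_repressed = as.integer(core_k_repressed),
    promoter_window = as.integer(promoter_window),
    enrichment_alpha = as.numeric(enrichment_alpha),
    enrichment_fold_min = as.numeric(enrichment_fold_min),
    strand_mode = strand_mode,
    rng_seed = as.integer(rng_seed)
  )
  if (!(cfg$repressed_fold_cutoff > 0 && cfg$repressed_fold_cutoff < 1))
    stop("repressed_fold_cutoff must lie in (0, 1)")
  if (cfg$induced_fold_cutoff <= 1)
    stop("induced_fold_cutoff must exceed 1")
  if (!(cfg$q_cutoff > 0 && cfg$q_cutoff < 1))
    stop("q_cutoff must lie in (0, 1)")
  if (cfg$core_k_induced < 1L || cfg$core_k_repressed < 1L)
    stop("core-set k must be >= 1")
  if (cfg$promoter_window < 1L) stop("promoter_window must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' Accepts either YAML (`.yml`/`.yaml`) or flat `key=value` lines (one per
#' line, `#` comments allowed). Keys must be names of [pipeline_config()]
#' arguments; unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return A `"pipeline_config"` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    vals <- yaml::read_yaml(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    bad <- lengths(kv) != 2L
    if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
    vals <- lapply(kv, function(x) utils::type.convert(trimws(x[2]),
                                                       as.is = TRUE))
    names(vals) <- vapply(kv, function(x) trimws(x[1]), "")
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("ckpipe pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, x[[nm]]))
  invisible(x)
}
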