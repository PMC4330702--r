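#' Simulation specification
#'
#' One seeded specification drives every synthetic-data generator. The
#' defaults state the study conditions the pipeline was designed around:
#' four ratio experiments with two sampling times, 65 target and 103
#' control promoters of 1000 bp, an AT-rich (60%) promoter base
#' composition, 3-vs-3 expression designs, and an orthology topology in
#' which 62.5% of queries carry at least one reciprocal ortholog.
#'
#' @param seed Integer master seed; per-generator substreams are derived
#'   from it by stable labels, so adding a generator never shifts another
#'   generator's stream.
#' @param n_genes Number of genes in ratio tables / expression matrices.
#' @param n_datasets Number of independent ratio experiments.
#' @param n_timepoints Sampling times per ratio experiment.
#' @param de_fraction Fraction of genes with a planted effect.
#' @param effect_log2fc Planted effect size (log2 fold-change).
#' @param noise_sd_log2 Noise standard deviation on the log2 scale.
#' @param n_control,n_treated Replicates per group in expression matrices.
#' @param n_target_promoters,n_control_promoters Promoter-set sizes.
#' @param promoter_length Promoter window length (bp).
#' @param base_composition Named numeric (A, C, G, T) summing to 1.
#' @param planted_motifs List of `list(motif =, target_rate =,
#'   control_rate =)` entries; each promoter of a set receives one planted
#'   concrete instance of the motif with the set's Bernoulli rate.
#' @param ortholog_topology List: `n_queries`, `p_has_ortholog`,
#'   `max_orthologs` (reciprocal prefix length is uniform on
#'   1..max), `decoy` (append a reciprocity-breaking hit after the
#'   prefix).
#' @return List of class `"simulation_spec"`.
#' @export
simulation_spec <- function(seed = 1L,
                            n_genes = 200L,
                            n_datasets = 4L,
                            n_timepoints = 2L,
                            de_fraction = 0.1,
                            effect_log2fc = 1,
                            noise_sd_log2 = 0.2,
                            n_control = 3L,
                            n_treated = 3L,
                            n_target_promoters = 65L,
                            n_control_promoters = 103L,
                            promoter_length = 1000L,
                            base_composition = c(A = 0.3, C = 0.2,
                                                 G = 0.2, T = 0.3),
                            planted_motifs = list(),
                            ortholog_topology = list(n_queries = 65L,
                                                     p_has_ortholog = 0.625,
                                                     max_orthologs = 2L,
                                                     decoy = TRUE)) {
  stopifnot(length(base_composition) == 4L,
            abs(sum(base_composition) - 1) < 1e-9,
            de_fraction >= 0, de_fraction <= 1,
            noise_sd_log2 >= 0,
            n_control >= 2L, n_treated >= 2L)
  for (pm in planted_motifs) {
    stopifnot(is.character(pm$motif),
              pm$target_rate >= 0, pm$target_rate <= 1,
              pm$control_rate >= 0, pm$control_rate <= 1)
    if (motif_length(pm$motif) > promoter_length)
      stop("planted motif longer than promoter window")
  }
  names(base_composition) <- c("A", "C", "G", "T")
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_datasets = as.integer(n_datasets),
    n_timepoints = as.integer(n_timepoints),
    de_fraction = de_fraction, effect_log2fc = effect_log2fc,
    noise_sd_log2 = noise_sd_log2,
    n_control = as.integer(n_control), n_treated = as.integer(n_treated),
    n_target_promoters = as.integer(n_target_promoters),
    n_control_promoters = as.integer(n_control_promoters),
    promoter_length = as.integer(promoter_length),
    base_composition = base_composition,
    planted_motifs = planted_motifs,
    ortholog_topology = ortholog_topology
  ), class = "simulation_spec")
}

# stable per-generator substreams; keeps derived seeds below 2^31
sub_seed <- function(spec, label) {
  offsets <- c(promoters = 1L, gene_lists = 2L, ratios = 3L,
               expression = 4L, hits = 5L)
  if (!label %in% names(offsets)) stop("unknown generator label: ", label)
  (abs(spec$seed) %% 2000000L) * 1000L + offsets[[label]]
}

random_sequences <- function(n, len, composition) {
  vapply(seq_len(n), function(i)
    paste(sample(names(composition), len, replace = TRUE,
                 prob = composition), collapse = ""),
    "")
}

#' Generate target and control promoter sets with planted motifs
#'
#' Background sequence is i.i.d. per the spec's base composition; each
#' planted motif is inserted (overwriting background, so window length is
#' preserved) at one uniform random position in a Bernoulli-rate subset of
#' promoters of each set, as a concrete instance drawn uniformly from the
#' motif's expansion. The truth table records every insertion.
#'
#' @param spec A [simulation_spec()].
#' @return List: `target`, `control` (`promoter_set`s), `truth`
#'   (data.frame set/id/motif/instance/position).
#' @export
gen_promoters <- function(spec) {
  set.seed(sub_seed(spec, "promoters"))
  make_set <- function(n, prefix) {
    s <- random_sequences(n, spec$promoter_length, spec$base_composition)
    names(s) <- sprintf("%s%04d", prefix, seq_len(n))
    s
  }
  target <- make_set(spec$n_target_promoters, "TGT")
  control <- make_set(spec$n_control_promoters, "CTL")
  truth <- list()
  plant <- function(set, set_name, rate, motif) {
    words <- expand_iupac(motif)
    m <- nchar(words[1])
    hit <- stats::runif(length(set)) < rate
    for (i in which(hit)) {
      pos <- sample.int(nchar(set[i]) - m + 1L, 1L)
      inst <- sample(words, 1L)
      substr(set[i], pos, pos + m - 1L) <- inst
      truth[[length(truth) + 1L]] <<- data.frame(
        set = set_name, id = names(set)[i], motif = motif,
        instance = inst, position = pos, stringsAsFactors = FALSE)
    }
    set
  }
  for (pm in spec$planted_motifs) {
    target <- plant(target, "target", pm$target_rate, pm$motif)
    control <- plant(control, "control", pm$control_rate, pm$motif)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(set = character(0), id = character(0), motif = character(0),
               instance = character(0), position = integer(0),
               stringsAsFactors = FALSE)
  list(target = structure(target, class = "promoter_set"),
       control = structure(control, class = "promoter_set"),
       truth = truth)
}

default_region_counts <- function() {
  # emulates the published four-way Venn structure: 23 genes in all four
  # analyses, 65 in at least three, large single-platform fringes
  c("CATMA+ATH1_STRICT+ATH1_BROAD+RNASEQ" = 23L,
    "CATMA+ATH1_STRICT+ATH1_BROAD" = 11L,
    "CATMA+ATH1_STRICT+RNASEQ" = 11L,
    "CATMA+ATH1_BROAD+RNASEQ" = 10L,
    "ATH1_STRICT+ATH1_BROAD+RNASEQ" = 10L,
    "CATMA+ATH1_STRICT" = 8L, "CATMA+ATH1_BROAD" = 8L,
    "CATMA+RNASEQ" = 12L, "ATH1_STRICT+ATH1_BROAD" = 24L,
    "ATH1_STRICT+RNASEQ" = 10L, "ATH1_BROAD+RNASEQ" = 10L,
    "CATMA" = 160L, "ATH1_STRICT" = 40L, "ATH1_BROAD" = 40L,
    "RNASEQ" = 160L)
}

#' Generate overlapping gene lists with a controlled Venn structure
#'
#' Builds named gene lists whose Venn-region occupancies equal
#' `region_counts` exactly (region labels are `+`-joined list names). The
#' default structure emulates the published four-analysis comparison:
#' 23 genes present in all four lists and 65 in at least three.
#'
#' @param spec A [simulation_spec()] (provides the seed used to shuffle
#'   synthetic gene IDs over regions).
#' @param region_counts Named integer vector, region label -> gene count.
#' @return List: `collection` (a [gene_list_collection()]), `truth`
#'   (data.frame gene_id/region).
#' @export
gen_gene_lists <- function(spec, region_counts = default_region_counts()) {
  set.seed(sub_seed(spec, "gene_lists"))
  list_names <- unique(unlist(strsplit(names(region_counts), "+",
                                       fixed = TRUE)))
  total <- sum(region_counts)
  ids <- sample(sprintf("SYN%05d", seq_len(total)))
  region_of <- rep(names(region_counts), region_counts)
  lists <- lapply(list_names, function(nm) {
    in_region <- vapply(strsplit(region_of, "+", fixed = TRUE),
                        function(r) nm %in% r, logical(1))
    ids[in_region]
  })
  names(lists) <- list_names
  list(collection = gene_list_collection(lists),
       truth = data.frame(gene_id = ids, region = region_of,
                          stringsAsFactors = FALSE))
}

#' Generate per-experiment ratio tables with planted induced genes
#'
#' True induced genes get linear ratio `2^effect_log2fc`, all others 1.0,
#' each multiplied by independent log-normal noise
#' `exp(N(0, noise_sd_log2 * ln 2))` per dataset and time point.
#'
#' @param spec A [simulation_spec()].
#' @return List: `tables` (list of `ratio_table` data.frames, one per
#'   dataset, columns `t1..t<n_timepoints>`), `truth` (data.frame
#'   gene_id/induced).
#' @export
gen_ratio_tables <- function(spec) {
  set.seed(sub_seed(spec, "ratios"))
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  n_de <- round(spec$de_fraction * spec$n_genes)
  induced <- sort(sample(genes, n_de))
  base_ratio <- ifelse(genes %in% induced, 2^spec$effect_log2fc, 1.0)
  sd_ln <- spec$noise_sd_log2 * log(2)
  tables <- lapply(seq_len(spec$n_datasets), function(d) {
    tab <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
    for (tp in seq_len(spec$n_timepoints)) {
      tab[[paste0("t", tp)]] <-
        base_ratio * exp(stats::rnorm(spec$n_genes, 0, sd_ln))
    }
    class(tab) <- c("ratio_table", "data.frame")
    tab
  })
  names(tables) <- sprintf("expt%d", seq_len(spec$n_datasets))
  list(tables = tables,
       truth = data.frame(gene_id = genes, induced = genes %in% induced,
                          stringsAsFactors = FALSE))
}

#' Generate a normalized expression matrix with planted fold-changes
#'
#' Log2 values are gene baseline + planted group effect (treated samples
#' of planted genes) + Gaussian noise.
#'
#' @param spec A [simulation_spec()].
#' @param gene_ids Optional gene IDs (default `G0001..`); the first
#'   `round(de_fraction * n_genes)` sampled genes carry the effect.
#' @param planted Optional character vector naming the planted genes
#'   (overrides `de_fraction` sampling).
#' @return List: `mat` (genes x samples matrix), `group` (character
#'   vector), `truth` (data.frame gene_id/planted).
#' @export
gen_expression_matrix <- function(spec, gene_ids = NULL, planted = NULL) {
  set.seed(sub_seed(spec, "expression"))
  genes <- if (is.null(gene_ids)) sprintf("G%04d", seq_len(spec$n_genes))
           else normalize_gene_id(gene_ids)
  n <- length(genes)
  if (is.null(planted)) {
    planted <- sort(sample(genes, round(spec$de_fraction * n)))
  } else {
    planted <- normalize_gene_id(planted)
  }
  n_samp <- spec$n_control + spec$n_treated
  group <- rep(c("control", "treated"), c(spec$n_control, spec$n_treated))
  baseline <- stats::rnorm(n, 8, 1.5)
  mat <- matrix(stats::rnorm(n * n_samp, 0, spec$noise_sd_log2),
                nrow = n) + baseline
  mat[genes %in% planted, group == "treated"] <-
    mat[genes %in% planted, group == "treated"] + spec$effect_log2fc
  dimnames(mat) <- list(genes,
                        paste0(ifelse(group == "control", "C", "T"),
                               sequence(c(spec$n_control, spec$n_treated))))
  list(mat = mat, group = group,
       truth = data.frame(gene_id = genes, planted = genes %in% planted,
                          stringsAsFactors = FALSE))
}

blast_row <- function(query, subject, bitscore, evalue) {
  data.frame(query = query, subject = subject, pident = 85, length = 300,
             mismatch = 45, gapopen = 2, qstart = 1, qend = 300,
             sstart = 1, send = 300, evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

#' Generate reciprocal hit tables with a known ortholog structure
#'
#' For each query gene a prefix of 1..`max_orthologs` rice subjects is
#' constructed to satisfy the reciprocal-top-hit check; when `decoy` is
#' set, a lower-scoring subject whose reverse top hit is a different query
#' follows the prefix (breaking reciprocity at a known rank). Queries
#' drawn to have no ortholog get the decoy first.
#'
#' @param spec A [simulation_spec()] (`ortholog_topology` drives sizes).
#' @return List: `forward`, `reverse` (`hit_table`s), `truth` (an
#'   `"ortholog_map"` of the planted reciprocal pairs), `queries`.
#' @export
gen_hit_tables <- function(spec) {
  set.seed(sub_seed(spec, "hits"))
  topo <- spec$ortholog_topology
  queries <- sprintf("ATQ%04d", seq_len(topo$n_queries))
  other <- "ATDECOY0"
  fwd <- list(); rev <- list(); truth <- list()
  rice_i <- 0L
  for (q in queries) {
    has <- stats::runif(1) < topo$p_has_ortholog
    k <- if (has) sample.int(topo$max_orthologs, 1L) else 0L
    if (k > 0L) {
      rice <- sprintf("OSR%05d", rice_i + seq_len(k))
      rice_i <- rice_i + k
      for (j in seq_len(k)) {
        fwd[[length(fwd) + 1L]] <-
          blast_row(q, rice[j], 300 - 10 * j, 1e-80 * 10^j)
        rev[[length(rev) + 1L]] <- rbind(
          blast_row(rice[j], q, 280, 1e-75),
          blast_row(rice[j], other, 180, 1e-40))
        truth[[length(truth) + 1L]] <-
          data.frame(gene_id = q, ortholog = rice[j],
                     source = "reciprocal", stringsAsFactors = FALSE)
      }
    }
    if (isTRUE(topo$decoy)) {
      d <- sprintf("OSD%05d", rice_i + 1L)
      rice_i <- rice_i + 1L
      fwd[[length(fwd) + 1L]] <-
        blast_row(q, d, 300 - 10 * (k + 1L), 1e-80 * 10^(k + 1L))
      rev[[length(rev) + 1L]] <- rbind(
        blast_row(d, other, 280, 1e-75),
        blast_row(d, q, 180, 1e-40))
    }
  }
  truth <- do.call(rbind, c(truth, list(empty_ortholog_map())))
  class(truth) <- c("ortholog_map", "data.frame")
  list(forward = rank_hit_table(do.call(rbind, fwd)),
       reverse = rank_hit_table(do.call(rbind, rev)),
       truth = truth, queries = queries)
}
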