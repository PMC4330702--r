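test_that("generators are pure functions of the specification", {
  spec <- simulation_spec(seed = 71, planted_motifs = list(
    list(motif = "AAGAT[TC]TT", target_rate = 0.4, control_rate = 0.05)))
  a <- gen_promoters(spec); b <- gen_promoters(spec)
  expect_identical(a, b)
  path1 <- withr::local_tempfile(); path2 <- withr::local_tempfile()
  write_fasta_promoters(a$target, path1)
  write_fasta_promoters(b$target, path2)
  expect_identical(readLines(path1), readLines(path2))  # byte-identical

  expect_identical(gen_ratio_tables(spec), gen_ratio_tables(spec))
  expect_identical(gen_expression_matrix(spec), gen_expression_matrix(spec))
  expect_identical(gen_hit_tables(spec), gen_hit_tables(spec))
  expect_identical(gen_gene_lists(spec), gen_gene_lists(spec))

  # different seeds give different data
  expect_false(identical(gen_promoters(simulation_spec(seed = 72))$target,
                         a$target))
})

test_that("promoter base composition follows the specification", {
  spec <- simulation_spec(seed = 73,
                          base_composition = c(A = 0.3, C = 0.2,
                                               G = 0.2, T = 0.3),
                          n_control_promoters = 103)
  prom <- gen_promoters(spec)
  s <- paste(prom$control, collapse = "")
  at <- mean(strsplit(s, "")[[1]] %in% c("A", "T"))
  n <- nchar(s)
  expect_lt(abs(at - 0.6), 3 * sqrt(0.6 * 0.4 / n))  # 3 binomial SDs
  expect_equal(unique(nchar(prom$target)), spec$promoter_length)
})

test_that("planted motif truth tables describe real insertions", {
  pm <- list(list(motif = "AAGAT[TC]TT", target_rate = 0.5,
                  control_rate = 0.1))
  prom <- gen_promoters(simulation_spec(seed = 74, planted_motifs = pm))
  tr <- prom$truth
  expect_gt(nrow(tr), 0)
  for (i in seq_len(nrow(tr))) {
    set <- if (tr$set[i] == "target") prom$target else prom$control
    expect_equal(substr(set[[tr$id[i]]], tr$position[i],
                        tr$position[i] + nchar(tr$instance[i]) - 1L),
                 tr$instance[i])
    expect_true(tr$instance[i] %in% expand_iupac(tr$motif[i]))
  }
  # with no planting, scanning finds only background occurrences
  bg <- gen_promoters(simulation_spec(seed = 74, planted_motifs = list(
    list(motif = "AAGAT[TC]TT", target_rate = 0, control_rate = 0))))
  expect_equal(nrow(bg$truth), 0L)
  expect_error(gen_promoters(simulation_spec(
    seed = 1, promoter_length = 4,
    planted_motifs = list(list(motif = "AAGATTTT", target_rate = 1,
                               control_rate = 0)))),
    "longer than promoter")
})

test_that("ratio tables recover the planted effect size", {
  spec <- simulation_spec(seed = 75, n_genes = 200, n_datasets = 4,
                          de_fraction = 0.25, effect_log2fc = 1,
                          noise_sd_log2 = 0.2)
  rt <- gen_ratio_tables(spec)
  expect_length(rt$tables, 4)
  merged <- rt$tables[[1]]["gene_id"]
  cols <- list()
  for (nm in names(rt$tables))
    cols[[nm]] <- rowMeans(as.matrix(rt$tables[[nm]][, -1]))
  overall <- rowMeans(do.call(cbind, cols))
  induced_mean <- mean(overall[rt$truth$induced])
  expect_lt(abs(induced_mean - 2) / 2, 0.05)  # within 5% of 2.0
  baseline_mean <- mean(overall[!rt$truth$induced])
  expect_lt(abs(baseline_mean - 1), 0.05)

  noiseless <- gen_ratio_tables(simulation_spec(seed = 76,
                                                noise_sd_log2 = 0,
                                                effect_log2fc = 1.5))
  tab <- noiseless$tables[[1]]
  expect_true(all(tab$t1[noiseless$truth$induced] == 2^1.5))
  expect_true(all(tab$t1[!noiseless$truth$induced] == 1))
})

test_that("gene-list generation realizes the requested Venn structure", {
  spec <- simulation_spec(seed = 77)
  gl <- gen_gene_lists(spec)
  expect_equal(length(core_set(gl$collection, 3)), 65L)
  expect_equal(length(core_set(gl$collection, 4)), 23L)
  p <- venn_partition(gl$collection)
  expect_equal(sum(p$counts), nrow(gl$truth))
  counts <- default_region_counts()
  for (lbl in names(counts)) {
    members <- sort(strsplit(lbl, "+", fixed = TRUE)[[1]])
    match_lbl <- names(p$counts)[vapply(strsplit(names(p$counts), "+",
                                                 fixed = TRUE),
                                        function(x) identical(sort(x),
                                                              members),
                                        logical(1))]
    expect_equal(unname(p$counts[match_lbl]), unname(counts[[lbl]]))
  }

  custom <- gen_gene_lists(spec, c("A+B" = 5L, "A" = 3L, "B" = 2L))
  expect_equal(lengths(custom$collection$lists), c(A = 8L, B = 7L))
})

test_that("expression matrices carry the planted group effect", {
  spec <- simulation_spec(seed = 78, n_genes = 400, de_fraction = 0.05,
                          effect_log2fc = 2, noise_sd_log2 = 0.25)
  em <- gen_expression_matrix(spec)
  expect_equal(dim(em$mat), c(400L, 6L))
  planted <- em$truth$planted
  diffs <- rowMeans(em$mat[, em$group == "treated"]) -
    rowMeans(em$mat[, em$group == "control"])
  expect_equal(mean(diffs[planted]), 2, tolerance = 0.15)
  expect_equal(mean(diffs[!planted]), 0, tolerance = 0.05)
})
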