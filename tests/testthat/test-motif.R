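test_that("IUPAC expansion enumerates concrete motifs", {
  expect_setequal(expand_iupac("AAGAT[TC]TT"), c("AAGATTTT", "AAGATCTT"))
  expect_equal(length(expand_iupac("[ACT][AG][GT]AT[ACT][CT][ACGT]")), 288)
  expect_equal(expand_iupac("ACGT"), "ACGT")
  expect_setequal(expand_iupac("AGATY"), c("AGATT", "AGATC"))
  expect_equal(length(expand_iupac("NN")), 16)
  expect_error(parse_iupac("AC?T"), "position 3")
  expect_error(parse_iupac("A[CT"), "unclosed")
})

test_that("occurrence counting handles overlaps, strands and N", {
  expect_equal(count_occurrences("AAGATTTT", "AAGAT[TC]TT"),
               list(count = 1L, positions = 1L))
  expect_equal(count_occurrences("TATATATATA", "TATATATA")$positions,
               c(1L, 3L))
  expect_equal(count_occurrences("TATATATATA", "TATATATA",
                                 count_overlaps = FALSE)$count, 1L)
  expect_equal(count_occurrences("GGGGGGGG", "NNNATNNN")$count, 0L)
  # N in the sequence never matches, not even the motif symbol N
  expect_equal(count_occurrences("AANAT", "AANAT")$count, 0L)
  expect_equal(count_occurrences("AAAAT", "AANAT")$count, 1L)
  # reverse-strand scanning reports forward coordinates
  both <- count_occurrences("CCAAAATTCC", "AAGATTTT", strand_mode = "both")
  expect_equal(both$count, 0L)
  rc <- count_occurrences("AAAATCTT", "AAGAT[TC]TT", strand_mode = "both")
  expect_equal(rc, list(count = 1L, positions = 1L))  # AAGATTTT on reverse
})

test_that("scanning agrees with a character-comparison oracle", {
  set.seed(12)
  iupac <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  for (i in 1:200) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), sample(20:80, 1),
                        TRUE, prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
    motif <- paste(sample(iupac, sample(3:8, 1), TRUE), collapse = "")
    got <- count_occurrences(seq, motif)$count
    expect_equal(got, oracle_scan_count(seq, parse_iupac(motif)),
                 info = paste(seq, motif))
  }
})

test_that("every extended-motif occurrence embeds a core-motif occurrence", {
  set.seed(13)
  for (i in 1:1000) {
    seq <- paste(sample(c("A", "C", "G", "T"), 60, TRUE,
                        prob = c(0.35, 0.15, 0.15, 0.35)), collapse = "")
    n_ecrm <- count_occurrences(seq, "AAGAT[TC]TT")$count
    n_crm <- count_occurrences(seq, "AGAT[TC]")$count
    expect_lte(n_ecrm, n_crm)
  }
})

test_that("presence-based exact test matches closed form and the oracle", {
  t10 <- as_promoters(rep("GGAAGATTTTGG", 10))
  c10 <- as_promoters(rep("GGGGGGGGGGGG", 10))
  e <- enrichment(t10, c10, "AAGATTTT")
  expect_equal(e$p, 1 / choose(20, 10))
  expect_equal(e$fold_enrichment, Inf)  # zero control occurrences

  same <- enrichment(t10, t10, "AAGATTTT")
  expect_equal(same$fold_presence, 1)
  expect_equal(same$fold_enrichment, 1)

  none <- enrichment(c10, c10, "AAGATTTT")
  expect_equal(none$fold_enrichment, 0)
  expect_equal(none$p, 1)

  set.seed(14)
  for (i in 1:50) {
    n_t <- sample(2:30, 1); n_c <- sample(2:30, 1)
    a <- sample(0:n_t, 1); b <- sample(0:n_c, 1)
    p <- phyper(a - 1, a + b, (n_t - a) + (n_c - b), n_t,
                lower.tail = FALSE)
    expect_equal(p, oracle_hyper_p(a, b, n_t, n_c), tolerance = 1e-12)
  }
})

test_that("central-AT octamer counts conserve the number of AT windows", {
  set.seed(15)
  seqs <- as_promoters(random_dna(20, 300, prob = c(0.4, 0.1, 0.1, 0.4)))
  words <- expand_iupac("NNNATNNN")
  for (s in seqs) {
    windows <- substring(s, 1:(nchar(s) - 7), 8:nchar(s))
    n_at <- sum(substr(windows, 4, 5) == "AT")
    total <- sum(vapply(words, function(w)
      count_occurrences(s, w)$count, 0L))
    expect_equal(total, n_at)
  }
  # and the screen's tabulation agrees in aggregate
  ctl <- as_promoters(random_dna(5, 300), prefix = "C")
  scr <- octamer_screen(seqs, ctl)
  n_at_all <- sum(vapply(seqs, function(s) {
    w <- substring(s, 1:(nchar(s) - 7), 8:nchar(s))
    sum(substr(w, 4, 5) == "AT")
  }, 0))
  expect_equal(sum(scr$full$target_occurrences), n_at_all)
})

test_that("the octamer screen finds planted motifs and nothing on identity", {
  pm <- list(list(motif = "TTGATCCA", target_rate = 0.4,
                  control_rate = 0.05))
  prom <- gen_promoters(simulation_spec(seed = 16, planted_motifs = pm))
  scr <- octamer_screen(prom$target, prom$control)
  expect_true("TTGATCCA" %in% scr$selected$motif)
  expect_equal(nrow(scr$full), 4096)
  expect_true(all(scr$full$q >= scr$full$p - 1e-12))

  self <- octamer_screen(prom$target, prom$target)
  expect_equal(nrow(self$selected), 0L)  # fold identically 1
})

test_that("consensus screening selects planted variants and flags the band", {
  pm <- list(list(motif = "AAGATCTT", target_rate = 0.5,
                  control_rate = 0.03))
  prom <- gen_promoters(simulation_spec(seed = 17, planted_motifs = pm))
  scr <- consensus_screen("AAGAT[TC]TT", prom$target, prom$control)
  expect_true("AAGATCTT" %in% scr$selected$motif)
  expect_false("AAGATTTT" %in% scr$selected$motif)
  expect_true(all(c("selected", "relaxed_band") %in% names(scr$full)))

  # alpha = 1, fold_min = 0 lists every motif with >= 1 target hit as
  # selected (boundary of the rule); motifs with zero target hits never are
  cfg <- pipeline_config(enrichment_alpha = 0.9999,
                         enrichment_fold_min = 0)
  all_scr <- consensus_screen("AAGAT[TC]TT", prom$target, prom$control, cfg)
  expect_equal(all_scr$full$selected,
               all_scr$full$p <= 0.9999)
  zero <- consensus_screen("GGGGCCCC", prom$target, prom$control)
  expect_equal(nrow(zero$selected), 0L)
})

test_that("combined coverage counts promoters once and pools occurrences", {
  target <- as_promoters(c("AAGATTTTGG", "CCTATATATA", "GGGGGGGGGG"))
  control <- as_promoters(rep("GGGGGGGGGG", 4), prefix = "C")
  cc <- combined_coverage(c("AAGATTTT", "TATATATA"), target, control)
  expect_equal(cc$coverage, 2 / 3)
  expect_equal(cc$n_target_with_hit, 2L)
  expect_equal(cc$fold, Inf)

  single <- combined_coverage("AAGATTTT", target, control)
  e <- enrichment(target, control, "AAGATTTT")
  expect_equal(single$n_target_with_hit, e$target_promoters_with_hit)
  expect_error(combined_coverage(character(0), target, control),
               "at least one")
})

test_that("logos report base frequencies and information in bits", {
  uniform <- build_logo(c("AA", "CA", "GA", "TA"))
  # column built from equal base counts carries zero information
  expect_equal(unname(uniform$info), c(0, 2))

  pure <- build_logo(rep("AAGATTTT", 5))
  expect_equal(unname(pure$freq["A", 1]), 1)
  expect_equal(unname(pure$info), rep(2, 8))

  two <- build_logo(c("AT", "AA"))
  expect_equal(unname(two$freq["A", 1]), 1)
  expect_equal(unname(two$info), c(2, 1))
  expect_equal(colSums(two$freq), c("1" = 1, "2" = 1))

  expect_error(build_logo(c("AT", "AAA")), "mixed lengths")

  # scanning route: occurrences collected from the target promoters
  target <- as_promoters(c("GGAAGATTTTGG", "GGAAGATCTTGG"))
  pfm <- build_logo("AAGAT[TC]TT", target)
  expect_equal(pfm$n_occurrences, 2L)
  expect_equal(unname(pfm$freq["T", 6]), 0.5)
})
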