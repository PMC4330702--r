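# Shared fixtures and independent oracles used across test files.

# Six worked rows of the published top-25 induced-gene table:
# per-time-point average ratios and the printed overall average.
table1_rows <- data.frame(
  gene_id = c("AT5G62920", "AT1G19050", "AT4G29740",
              "AT5G47980", "AT1G53060", "AT5G08640"),
  symbol = c("ARR6", "ARR7", "CKX4", NA, NA, "FLS1"),
  ba15 = c(4.83, 11.72, 7.60, 2.00, 2.12, 3.80),
  ba120 = c(3.08, 8.94, 6.29, 12.29, 16.16, 6.57),
  printed_avg = c(3.96, 10.33, 6.95, 7.15, 9.14, 5.19),
  stringsAsFactors = FALSE
)

table1_ratio_table <- function() {
  tab <- data.frame(gene_id = table1_rows$gene_id,
                    BA15 = table1_rows$ba15,
                    BA120 = table1_rows$ba120,
                    stringsAsFactors = FALSE)
  class(tab) <- c("ratio_table", "data.frame")
  tab
}

# Write the same rows as a decimal-comma TSV, the way European
# spreadsheet exports print them.
write_table1_tsv <- function(path) {
  num <- function(x) sub(".", ",", format(x, nsmall = 2), fixed = TRUE)
  lines <- c("AGI\tBA15\tBA120",
             sprintf("%s\t%s\t%s", table1_rows$gene_id,
                     num(table1_rows$ba15), num(table1_rows$ba120)))
  writeLines(lines, path)
  path
}

as_promoters <- function(seqs, prefix = "P") {
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("%s%03d", prefix, seq_along(seqs))
  structure(toupper(seqs), class = "promoter_set")
}

random_dna <- function(n, len, prob = rep(0.25, 4)) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE, prob), collapse = ""),
    "")
}

# --- independent oracles -------------------------------------------------

# naive per-gene subset-membership core set
oracle_core_set <- function(lists, k, exact = FALSE) {
  lists <- lapply(lists, function(x) unique(toupper(x)))
  genes <- unique(unlist(lists))
  cnt <- vapply(genes, function(g)
    sum(vapply(lists, function(s) g %in% s, logical(1))), 0)
  sort(genes[if (exact) cnt == k else cnt >= k])
}

# O(m^2) min-over-suffix Benjamini-Hochberg
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    suffix <- seq(i, m)
    q[ord[i]] <- min(1, min(p[ord[suffix]] * m / suffix))
  }
  q
}

# brute-force hypergeometric upper tail by summation
oracle_hyper_p <- function(t_pres, c_pres, n_t, n_c) {
  white <- t_pres + c_pres
  black <- (n_t - t_pres) + (n_c - c_pres)
  ks <- seq(t_pres, min(n_t, white))
  sum(choose(white, ks) * choose(black, n_t - ks) /
        choose(white + black, n_t))
}

# regex-free character-by-character degenerate scan
oracle_scan_count <- function(seq, classes) {
  chars <- strsplit(seq, "")[[1]]
  m <- length(classes)
  n <- length(chars)
  if (n < m) return(0L)
  cnt <- 0L
  for (i in seq_len(n - m + 1L)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!(chars[i + j - 1L] %in% classes[[j]])) { ok <- FALSE; break }
    }
    if (ok) cnt <- cnt + 1L
  }
  cnt
}

# enumerate accept/stop prefixes of the reciprocal walk
oracle_reciprocal <- function(forward, reverse, gene) {
  fwd <- forward[forward$query == gene & forward$subject != gene, ]
  fwd <- fwd[order(-fwd$bitscore, fwd$evalue, fwd$subject), ]
  acc <- character(0)
  for (s in fwd$subject) {
    rv <- reverse[reverse$query == s & reverse$subject != s, ]
    rv <- rv[order(-rv$bitscore, rv$evalue, rv$subject), ]
    if (nrow(rv) > 0 && rv$subject[1] == gene) acc <- c(acc, s) else break
  }
  acc
}
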