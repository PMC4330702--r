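---
title: "Methods: cytokinin transcriptomics meta-analysis and promoter motif screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cytokinin transcriptomics meta-analysis and promoter motif screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckpipe)
```

## Scope and model

`ckpipe` implements the computational chain used to distil a robust core
set of cytokinin-regulated genes from heterogeneous transcriptomic
sources and to mine their promoters for candidate type-B response
regulator binding sites:

1. **Ratio meta-averaging** — per-gene treated/control expression ratios
   from several experiments and sampling times are averaged and
   thresholded into induced / repressed calls.
2. **k-of-n core sets** — regulated-gene lists from independent analyses
   (different platforms, different meta-analysis strategies) are
   intersected; genes supported by at least *k* of *n* lists form the
   core set.
3. **Differential expression** — normalized log2 expression matrices
   from a second species (rice) are tested gene-wise with a two-sample
   t-test, FDR-adjusted, and joined to the core set via orthology.
4. **Reciprocal-top-hit orthology** — an iterative walk over ranked
   similarity hits identifies orthologs.
5. **Promoter motif enrichment** — degenerate motifs, an exhaustive
   central-AT octamer space, and consensus-derived motif sets are scored
   for overrepresentation in target vs control promoters; selected
   motifs are summarized as a position-frequency-matrix logo.

Every input has a seeded synthetic generator, so the full chain is
testable without any downloads.

## Ratio averaging

Per-time-point means are arithmetic means *on the linear ratio scale*
over experiments, and the overall mean is the arithmetic mean of the
per-time-point means. Linear-scale averaging is deliberate: it is the
only convention that reproduces the derived average column of the
published top-induced-genes table from its per-time-point columns
(e.g. 4.83 and 3.08 average to 3.96 after display rounding). Missing
values are excluded from the respective mean; a gene with no data is
dropped with a message rather than propagated as `NaN`.

Display rounding is two decimals, *half away from zero*
(`round_half_away()`): spreadsheet-style rounding, needed because cells
like 6.945 print as 6.95. Base R's banker's rounding would disagree on
exactly these halves. A small relative epsilon absorbs the binary
representation error of decimal halves.

Regulation calls are inclusive: mean ratio ≥ 2.0 is induced, ≤ 0.5
repressed. The repressed cut-off is the one the source analyses state;
2.0 is its reciprocal and consistent with every published induced entry.

The per-gene `meta_score()` (sum of |log2 ratio| times the number of
experiments with ≥ 2-fold change) is a documented stand-in: the score
used to rank the published tables is defined in prior work and is not
reproduced here. It deliberately remains a plug-in (`scorer` argument)
and the package makes no claim that the default reproduces published
score columns.

## Core sets and overlap analysis

Gene lists are compared by normalized identifier only (upper-cased,
trimmed); no probe-to-gene remapping is attempted because the input
lists are already gene-level. `venn_partition()` assigns each union
member to exactly one of the `2^n - 1` regions; by construction the
region counts sum to the union size, which the tests assert as a
conservation property. The induced core rule is *at least k* (default
3 of 4); the repressed rule is *exactly k* (default 2), because no
repressed gene was found in more than two of the source analyses.
Because published overlap percentages have an ambiguous denominator
("all transcripts listed in the source datasets"), `unique_fraction()`
and the partition report expose the raw counts so either union-based or
per-list denominators can be formed.

## Differential expression

The caller computes `log2fc` as the difference of group means of the
(already normalized) log2 values and `fold_change = 2^log2fc` — a
log-mean fold change, not a ratio of linear means; the source analyses
do not state which they used, so the package picks one convention and
documents it. The default test is the equal-variance Student t
(spreadsheet default, matching how the original p-values were computed),
with Welch behind `var_equal = FALSE`. The per-gene t statistic is
evaluated in closed form for speed; the test suite checks it against
`stats::t.test` gene by gene, keeping implementation and oracle
separate. Degenerate rows: zero variance in both groups with equal
means gives p = 1 by convention; with different means, p = 0 (perfect
separation). `bh_qvalues()` applies Benjamini–Hochberg step-up FDR
adjustment (via `stats::p.adjust`; the test suite carries an O(m²)
min-over-suffix oracle). Significance requires both a ≥ 2-fold change
in either direction and q ≤ 0.05.

A dataset-level sanity gate (`qc_expression_matrix()`) flags matrices
whose samples lack the usual strong global correlation (default mean
pairwise Pearson r ≥ 0.7) — the failure mode of one published rice
series that produced no meaningful data — so such datasets are excluded
with a recorded reason instead of silently analyzed.

## Orthology

`reciprocal_orthologs()` interprets the iterative rule literally as a
*prefix walk with stop at first failure*: forward hits of a query are
visited in rank order (bit score desc, E-value asc, subject ID as final
tie-break — a total order, so shuffled input files rank identically),
and each subject is accepted while the query is that subject's
top-ranked reverse hit. The first failure stops the walk, so the result
is always a prefix of the forward ranking. The alternative
interpretation — keep every reciprocal subject regardless of position —
is available as `rule = "filter"` for sensitivity analysis. Self-hits
are removed before ranking; a subject missing from the reverse table
fails the check. IDs are treated as opaque: exact duplicates collapse,
and no transcript-to-locus mapping is attempted. A second ortholog
source is modeled as a plain pair list (`read_ortholog_pairs()`);
`merge_sources()` reports the pairwise overlap fraction
|both| / |union|.

## Promoter motif enrichment

Motifs are degenerate DNA words over the IUPAC alphabet with bracket
classes (`AAGAT[TC]TT`). Scanning is exact sliding-window matching of
the expanded word set — no position-weight scoring — because the method
being reproduced counts exact degenerate matches. Three scanning
choices matter and are fixed as defaults:

* **Strand:** forward-only by default. The motif lists being reproduced
  are reported as written, with no mention of reverse-complement
  counting; `strand_mode = "both"` is available.
* **Overlaps:** counted (default). Poly-TA motifs such as `TATATATA`
  overlap heavily; discarding overlaps would silently change counts.
* **N:** the sequence character N never matches anything, including the
  motif symbol N (which means "any of A/C/G/T").

Enrichment of a motif in a target promoter set vs a control set
reports both an occurrence-rate fold (per promoter; per base when the
mean window lengths differ) and a presence fold, with two p-values: the
primary one-sided exact test on the presence/absence 2×2 table
(hypergeometric tail) and a per-occurrence binomial companion. The
source analysis reports p-values without naming the test, so both
natural choices are emitted; selection uses the presence-based exact p.
A motif absent from the control set but present in the target reports
`fold = Inf` with the presence p still defined; a motif absent from the
target reports fold 0, p = 1.

The exhaustive screen enumerates all 4⁶ = 4096 octamers with a fixed
central `AT` and applies the published selection rule — fold ≥ 2 and
raw p ≤ 0.05, i.e. no multiple-testing gate, exactly as in the original
selection — while BH q-values over the full screen are always reported
alongside as an honesty column. A useful arithmetic invariant checked
by the tests: summed forward occurrence counts over all 4096 octamers
equal the number of AT-centred windows in the scanned set, because each
such window matches exactly one concrete octamer.

`consensus_screen()` expands a degenerate consensus (for instance the
288-member `[ACT][AG][GT]AT[ACT][CT][ACGT]` binding-site consensus) and
scores each concrete motif the same way. The original analysis listed
some motifs "with a p-value between 0.05 and 0.06"; the screen
therefore flags a relaxed band `(0.05, 0.06]` and the returned
selection contains strict passes and relaxed-band rows, each carrying
both flags, so downstream code can apply either standard.

`combined_coverage()` counts a target promoter once however many of the
selected motifs hit it, and pools occurrences for a combined fold.
`build_logo()` collects every occurrence of the selected motifs in the
target promoters (occurrence-weighted) into a position frequency
matrix; per-column information content is `2 − H` bits with no
small-sample correction, matching a plain frequencies-of-bases logo.

## Synthetic data: what it emulates and what it does not

The generators are pure functions of a `simulation_spec()`; one master
seed fans out to per-generator substreams by stable labels, so adding a
generator never shifts another's stream. Defaults state the study
conditions the pipeline was built around: four ratio experiments with
two sampling times; 65 target and 103 control promoters of 1000 bp;
an AT-rich (60% A+T) base composition typical of plant upstream
regions; 3-vs-3 expression designs with log2-scale Gaussian noise
(σ = 0.2–0.25, the within-condition spread typical of RMA-normalized
arrays); and an orthology topology in which 62.5% of queries carry a
reciprocal ortholog. The gene-list generator realizes a requested Venn
structure exactly; its default encodes the published four-analysis
comparison (23 genes in all four lists, 65 in at least three).

Planted motifs overwrite background at a uniform position, keeping the
window length fixed; ratio noise is log-normal,
`exp(N(0, σ·ln 2))`, so σ is in log2 units.

The generators emulate the *statistical structure* the analysis assumes
— i.i.d. background sequence, independent per-dataset noise, clean
group labels — not real data's correlated genomic background, dye and
probe effects, shared regulatory motifs between "unregulated" control
promoters, or phylogenetic structure among orthologs. Passing the
recovery suites therefore demonstrates that the pipeline detects the
signals it is designed for at the stated rates under its own model; it
does not certify the published biological folds, which depend on genome
promoter sequences and an unpublished control-set construction and are
deliberately not asserted.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale sizes chosen to estimate
each property stably: 20 random sequences for the conservation
invariant, all 2×2 presence tables with both set sizes ≤ 30 against a
summation oracle, m = 1000 for the FDR oracle, 100 seeded replicates
for planted-octamer recovery (presence 40% vs 5% at 65/103 promoters),
and 200–1000 genes for power and type-I calibration. Ties in hit
tables resolve deterministically (bit score, E-value, subject ID);
region labels join list names with `+` in input order; empty
edge-cases return typed empties or `NA` rather than errors wherever
the operation is well-defined on them.

## Known limitations

* The meta-score is a stand-in, not the published ranking statistic.
* Fold changes in the DE caller are log-mean based; analyses that used
  linear-mean folds will differ slightly for noisy genes.
* Motif statistics treat promoters as exchangeable units; no
  positional or clustering information enters the enrichment test
  (occurrence positions are, however, reported by `count_occurrences()`
  for downstream positional analyses).
* The orthology rule trusts the hit tables' scores; no alignment is
  performed, and paralog fan-outs beyond the reciprocal prefix are
  invisible to the prefix rule by design.
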