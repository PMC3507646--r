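---
title: "Measuring amino-acid substitution flexibility between transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring amino-acid substitution flexibility between transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matchratio)
```

## The model

`matchratio` compares the unigene sets of two related species at the
protein level. Every query unigene is translated in all six reading
frames and locally aligned (Smith–Waterman, affine gaps, BLOSUM62)
against the six frames of each subject; the best-scoring segment pair
stands in for the HSP a production translated-search tool would report.
Within that conserved region each column is classified as an identical
match (`i`), a homologous substitution (`h`, distinct residues with
BLOSUM62 score strictly positive — the "+" convention of protein-search
midlines), a non-similar mismatch (`m`), or a gap column (`g`). The
per-pair statistic is the identical match ratio `r = i / (i + h)`.

The model behind the statistic is deliberately minimal: conditional on a
column being a substitution the matrix decides whether it was
conservative, and `r` estimates the per-site probability that a conserved
position stayed identical rather than accepting a conservative
replacement. Mismatch and gap columns carry no information about that
choice and are excluded — gaps entirely, mismatches from the ratio but
not from the conserved-region span. The statistic assumes sites are
exchangeable within the region and ignores rate variation along the
protein; it is a ranking device, not an evolutionary rate estimate.

Ranked pairs are split into extremes: the lowest-ratio 15% form the
high-substitution ("conserved") class, the highest 15% the
low-substitution ("identical") class. Each selected gene maps to one
functional class via its best annotation hit, and each function is scored
by `log2(conserved_count / identical_count)`. No significance test is
attached — the tally is descriptive, and the package intentionally leaves
multiple-testing machinery out of scope.

## Thresholds and defaults

| parameter | default | units | role |
|---|---|---|---|
| `min_query_len_nt` | 600 | nt | minimum query unigene length |
| `max_evalue_pair` | 1e-30 | — | pair E-value ceiling (boundary retained) |
| `min_region_nt` | 80 | nt | minimum conserved-region span |
| `split_fraction` | 0.15 | — | fraction per side of the ranked list |
| `max_evalue_function` | 1e-10 | — | annotation ceiling, strict `<` |
| gap open / extend | 11 / 1 | score | affine penalties (gap of length L costs 11 + L) |
| lambda, K | 0.267, 0.041 | — | Karlin–Altschul constants for gapped BLOSUM62 |

The filter defaults are the published operating point of the comparison
this package re-implements; `run_config()` carries them plus the seed, and
`write_report()` stamps the snapshot into every output file so any result
is auditable. The gap penalties and E-value constants are the common
protein-search defaults — the original analysis delegated them to external
tools, so they are configurable here and every stage also accepts
raw-score reasoning in tests, which avoids depending on E-value
calibration.

Two rounding rules matter for reproducing printed arithmetic. Each side
of the split takes `floor(split_fraction * n)` genes — with 3,177 ranked
pairs at 15% this gives 476 + 476 = 952 selected genes, and no other
rounding reproduces that total. And the conserved-region length is
counted in nucleotides as `3 *` (non-gap alignment columns), so the 80-nt
floor means at least 27 aligned residue columns.

## Interpretation decisions

Several points were genuinely open and are fixed here as package policy:

* **Best HSP only.** One alignment per (query, subject) feeds the
  statistic; segments on either side of a stop codon compete as separate
  candidates rather than being summed. Stops terminate candidates and are
  never scored.
* **One-way best hit.** Each query pairs with its best-scoring subject
  (ties broken to the lexicographically smallest subject id); no
  reciprocal-best requirement is imposed.
* **One function per gene.** The best (smallest E-value) annotation wins;
  E-value ties resolve to the lexicographically first function name, so
  multi-domain genes are never fractionally assigned.
* **`X` and stop columns are mismatches.** BLOSUM62 rows for `X` are
  non-positive and stops are not residues, so neither can be `i` nor `h`;
  this keeps the ratio over genuine residue pairs.
* **All-one-class functions.** When a function's selected genes are all
  in one class the log2 odds is infinite; the row keeps a signed `Inf`
  plus an `all_one_class` flag (rendered "*" by `autoplot()`), and rows
  with both counts zero are dropped.
* **OR-rule direction.** "Passing the threshold" means `evalue <=
  ceiling`; one passing channel among several calls the gene present, and
  adding evidence can only turn calls on (a monotonicity the tests
  enforce).

## What the generators emulate

`simulate_homolog_pair()` draws an ancestral protein and a derived copy:
per codon site the residue is kept with `p_identical`, replaced by a
uniformly chosen conservative partner (BLOSUM62 > 0) with
`p_conservative`, and by a radical partner (score ≤ 0) with `p_radical`;
synonymous codons are chosen uniformly on both sides, and optional indels
operate on whole codons so frames never shift. The generator's site log
records every decision, making expected statistics computable without
re-alignment — the planted expectation of the identical match ratio is
simply `p_identical / (p_identical + p_conservative)`.

One BLOSUM62 fact shapes the design: cysteine, glycine and proline have
no positive off-diagonal score, hence no conservative partner. Ancestral
residues are therefore drawn from the 17 residues that have one, and the
substitution routine raises an error rather than silently skipping if a
conservative event ever lands on a partnerless residue. This slightly
restricts the simulated amino-acid composition but guarantees the planted
spectrum is exactly realizable.

Higher-level generators compose this primitive: `simulate_function_panel()`
plants per-function substitution regimes for enrichment recovery;
`simulate_target_datasets()` plants a presence/absence plan, adds random
coding decoys, and can fragment homologs into exon-like pieces joined by
random spacers to emulate genomic super contigs (only local segments then
align); `simulate_est_collection()` builds near-identical read clusters
(≤ 1% per-base mutation) with a skewed size profile for rarefaction and
depth-histogram tests.

What the generators do **not** emulate: codon-usage bias, realistic
substitution processes (no rate matrices, no dN/dS), indel length
distributions, sequencing error profiles, chimeric or mis-assembled
unigenes, and paralogy. Passing recovery tests therefore demonstrates
that the pipeline's bookkeeping and statistics are correct under the
stated model — not that real transcriptome comparisons are free of the
biases those phenomena introduce.

## Numerical and degenerate-input choices

* Alignment scores below or at zero yield the empty alignment (score 0);
  the tie-break in traceback is the alignment engine's deterministic
  choice, and only the rendered strings — never the score — could depend
  on it.
* Candidate segments shorter than `min_segment_aa` (default 8 residues)
  are skipped in translated search: such fragments cannot influence any
  E-value decision at the thresholds in use, and dropping them bounds the
  combination count.
* Ratios are kept at full precision everywhere; the two-decimal form
  (e.g. 0.78) is a display convention only.
* An alignment with `i + h = 0` has no ratio: the pair errors out of the
  statistic and is excluded upstream, never silently scored 0.
* Ambiguous codons translate to `X` unless every resolution agrees;
  RNA `U` maps to `T` on input.
* Doubling depth bins are `{1}`, `{2}`, then `(2^(k-1), 2^k]`, which
  partition the positive integers — property-tested rather than assumed.
* The rarefaction protocol draws one permutation per replicate and
  evaluates its prefixes on the size grid: a prefix is a uniform
  without-replacement sample, so the closed-form hypergeometric
  expectation applies unchanged, and each replicate's curve is
  non-decreasing under a consistent clusterer. The default grid is 20
  evenly spaced sizes; the clusterer is injectable, with a greedy
  single-linkage 95%-identity stand-in provided in place of assembly
  software.

## Test problem sizes

The recovery suites run at sizes chosen to give clean statistical
separation while keeping the whole suite quick on one core: 300-codon
pairs for ratio recovery (binomial SE ≈ 0.026 per pair at `p = 0.5`,
three-SE bands over 100 seeded pairs per target), 80-codon genes and 30
genes per function over 100 seeded runs for end-to-end sign recovery
(planted expected ratios 0.75 vs 0.95), 70-codon genes with decoys for
exact conservation-plan recovery at the 1e-10 ceiling, and a 20-cluster
collection with 20 replicates for the rarefaction comparison. The
enumeration oracle for alignment scores covers every peptide pair up to
length 2 over a four-letter alphabet exhaustively plus seeded random
pairs at lengths 3–5 — the full length-5 cross is astronomically larger
with no additional discriminating power per unit of compute.

## Known limitations

* The internal aligner is exact but unseeded (no k-mer heuristics), so it
  is meant for desk-scale panels; production-scale searches should feed
  results in through the tabular alignment format instead.
* E-values use fixed Karlin–Altschul constants without composition-based
  adjustment; they are consistent within a run but not comparable to a
  production tool's values at fine grain.
* The ontology roll-up consumes a user-supplied edge list; the package
  neither bundles nor fetches a full ontology.
* The transcript-concordance figure that excludes two subcategories from
  the published comparison is ambiguous about whether the exclusion
  applies to numerator or denominator; the summarizer reports raw
  per-dataset counts and leaves that reading to the user.
* Printed singleton and whole-set mean lengths in the packaged assembly
  summary are internally inconsistent with their printed totals; the
  recomputed `total_bases / n` is the quantity of record, and only the
  contig-class mean is used as a checked value.
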