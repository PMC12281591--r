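---
title: "Methods: bidirectional connectivity screening of transcriptomic signatures"
author: "sigscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidirectional connectivity screening of transcriptomic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Connectivity mapping asks which catalogued perturbations (typically
small-molecule compounds profiled in a LINCS L1000-style resource) produce a
transcriptional response resembling a query signature — for instance the
differential-expression profile of cells treated with an uncharacterized
extract. A perturbation whose induced expression changes align with the
query's is a candidate mimic, and its annotated targets become mechanistic
hypotheses for the query treatment.

`sigscreen` implements this screen, together with the supporting statistics
such a study runs around it: DEG selection, preranked GSEA and
over-representation analysis, Jaccard comparison of DEG sets, mean-rank
aggregation of transcription-factor enrichment libraries, footprint-based
pathway activities, and reporter metabolites.

## The screening statistic

Each library perturbation is summarized by two predefined gene sets: its `n`
most up-regulated and `n` most down-regulated genes by z-score
(`extreme_sets()`, default `n = 500`; selection is by z-score value, with an
optional strict-sign mode). The query DE table is ranked by log2 fold change
in descending order, and both sets are scored against that ranking by
preranked GSEA. The perturbation's connectivity score is the **summarized
NES**

    total_NES = NES_up − NES_down,

so a perturbation whose up genes crowd the top of the query ranking
(`NES_up > 0`) *and* whose down genes crowd the bottom (`NES_down < 0`) is
rewarded on both terms. Signatures are ranked by `total_NES` descending;
ties are broken by the sum of the two permutation p-values, then by compound
name. The per-direction p-values are BH-adjusted in two separate families
(all up-sets, all down-sets) across whatever library was screened; the
family size is recorded in the output header.

### Enrichment score

`enrichment_score()` is the weighted Kolmogorov–Smirnov running-sum
statistic: walking the ranked list, a gene-set member at position *i* adds
`|metric_i|^exponent / N_R` (with `N_R` the sum of `|metric|^exponent` over
the effective set, so hit increments total 1) and a non-member adds
`−1/(N − N_H)`. The enrichment score is the running-sum value of maximal
absolute deviation from zero; the sum returns to zero at the end of the
list. The leading edge is the members at or before the extremum (at or
after, for a negative score).

Numerical conventions, fixed for reproducibility:

* **Extremum ties.** When the maximal positive and negative deviations tie
  in magnitude — which happens for symmetric toy rankings — the positive
  peak is taken. The comparison uses a 1e-9 band so the choice cannot flip
  with summation order.
* **Weighting exponent** defaults to 1, the classic "weighted" preranked
  statistic; `exponent = 0` gives the unweighted KS form and tolerates
  zero metrics.
* **Degenerate inputs** are errors, not silent zeros: an empty effective
  set, a set covering the whole universe (the miss increment is undefined),
  and an all-zero-metric hit set with positive exponent.

### Permutation null and NES

Phenotype permutation does not exist for a preranked list, so the null is
gene-set (label) permutation: `n_perm` (default 1000; 500 in the screens
below) uniform random subsets of the same effective size, each scored like a
real set. Normalization is sign-stratified: with `S` the null scores sharing
the observed score's sign,

    NES = ES / mean(|S|),   p = (#{|s| ≥ |ES|} + 1) / (|S| + 1),

the `+1` correction keeping p in (0, 1]. If no null score shares the sign
(practically impossible at the default permutation count), the mean over the
whole null is used and p is floored at `1/(n_perm + 1)`, with a warning.

### Determinism and null sharing

Every random stream derives from a global seed and a stable string key
(`derive_seed()`). The permutation null for a given effective set size
depends only on the seed and that size, so one null per distinct size is
computed and shared across all signatures in a screen. Two consequences are
tested as invariants: screening a permuted library yields the identical
table, and a signature scored alone (`score_signature()`) reproduces its
rows from the full screen exactly.

### Query ranking scope

The screen ranks **all** genes of the query DE table, the
information-preserving reading; `degs_only = TRUE` restricts the ranking to
significant DEGs (`padj < alpha`) first, for the stricter convention. With a
genome-scale table both orderings put the same genes at the extremes, where
the extreme sets are scored.

## Supporting statistics

* **DEG selection** (`select_degs`): `padj < alpha` (default 0.05) and
  strictly signed log2FC; genes with log2FC exactly 0 fall in neither set.
* **ORA** (`ora_fisher`): one-sided upper-tail hypergeometric test of the
  interest/set overlap against the detected-gene background, BH across
  sets; `gene_ratio` is overlap / interest size.
* **Mean-rank aggregation** (`mean_rank_aggregate`): items missing from a
  ranking receive its length + 1 as penalty rank; mean-rank ties break by
  item id.
* **Pathway activities** (`progeny_scores`): `raw = Σ w_g · stat_g` over a
  pathway's footprint genes (`top_k_weights` keeps the 100
  largest-|weight| genes per pathway from a supplied weight table — the
  published footprint matrices are distributed elsewhere and are an input,
  not shipped data). The null permutes the statistic values over gene
  labels; `z = (raw − mean)/sd`, with a two-sided +1-corrected permutation
  p centred on the null mean. Null draws ignore the weights, so doubling
  all weights doubles `raw` and leaves `z` unchanged — a tested
  equivariance.
* **Reporter metabolites** (`reporter_metabolites`): per-gene
  `Z = Φ⁻¹(1 − p)` (p clamped to `[1e-15, 1 − 1e-15]`), per-metabolite
  `Z_agg = Σ Z / √k`, background-corrected against `n_samples`
  (default 10000) random size-k draws from the full gene list, one null per
  distinct k; upper-tail normal p on the corrected score. The aggregation
  is unsigned; directional variants are obtained by restricting the gene
  list to one DE direction before the call. A degenerate background
  (`sd = 0`, e.g. identical p-values everywhere) yields a corrected score
  of 0 with a warning rather than an error.
* **BH adjustment** (`bh_adjust`) validates its inputs and applies the
  standard step-up procedure via `stats::p.adjust`; the test suite checks
  it against an independent naive O(m²) implementation.

## The synthetic-data generator

The generators emulate the statistical structure the pipeline consumes —
not the upstream assay. `simulate_de_table()` plants
`round(n_genes · frac_de)` effect genes with true log2FC `|N(0, effect_sd²)|`
and a forced 50/50 sign split (so both query tails are populated), adds
`N(0, null_noise_sd²)` observation noise, and derives `stat`, exact normal
p-values and BH `padj` from the stated model; with `frac_de = 0` the
p-values are exactly uniform, which the suite verifies by KS test at level
0.01 over ten seeds at 5000 genes. `simulate_library()` standardizes the
true query log2FC to z-scale and builds mimics
(`a·z + N(0, noise_sd²)`), inverters (sign-flipped) and i.i.d. `N(0,1)`
decoys.

Default conditions — 2000 genes, 20% DE, `effect_sd = 1`,
`null_noise_sd = 0.25`, one mimic and one inverter at weight `a = 2` with
noise SD 0.5 among 20 decoys — are the package's standard validation
setting. `effect_sd = 1` gives a realistic spread of log2 fold changes
(most true effects within ±2); `null_noise_sd = 0.25` corresponds to a
well-powered experiment in which 1-unit fold changes are detected
comfortably but the null and alternative distributions still overlap.

What the generator does **not** model: count-level (negative binomial)
noise — the pipeline consumes DE tables, and only a minimal Poisson count
table is provided to exercise `filter_genes` — L1000 landmark-gene
imputation, batch effects, dose–response structure, and correlated genes.
Passing the planted-recovery tests therefore demonstrates that the screen
ranks genuinely correlated signatures above independent ones under Gaussian
noise; it does not certify performance against the correlation structure of
real expression data.

In `simulate_gene_sets()`, `frac_enriched` is the fraction of an enriched
set's members drawn from the target list; which sets are enriched is
controlled by `n_enriched` (default: the first set), a package convention.

## Validation design and problem sizes

The suite's deeper checks, all seeded and all at sizes chosen to keep a
full run around a quarter of a minute:

* enrichment scores against a brute-force loop oracle on all 1022
  non-trivial subsets of a 10-gene list, plus randomized cases and an
  independent cross-check against `fgsea::calcGseaStat`;
* permutation-p calibration on 200 random sets over a 2000-gene ranking
  (500 permutations) by KS uniformity at level 0.01;
* planted-structure recovery: 40 independent screens at the default
  conditions (n = 100, 500 permutations) requiring the mimic first and the
  inverter last in at least 95%, with decoys never rivalling the mimic;
* reporter recovery: 40 spiked-metabolite simulations (five neighbors with
  `Z ~ N(2,1)`, 2000 background draws) requiring the spike on top in at
  least 95%;
* self-similarity controls: a query screened against its own signed
  signature scores positive, against its negation negative, at every seed
  tried.

The worked top-ten table shipped in `inst/extdata/` additionally pins the
summarized-NES arithmetic (the rows whose printed per-direction values are
exact at six decimals) and the compound-redundancy counting of
`top_table()`.

## File formats and output precision

GCT is supported in dialect 1.2 only — the text dialect of level 5 z-score
exports — and 1.3 is rejected outright to keep the parser exact. Writers
emit deterministic column order, scores at 6-decimal fixed point and
p-values at 6 significant digits (fixed point would annihilate the
e-100-scale tail p-values connectivity screens produce). Gene identifiers
are matched case-sensitively and exactly throughout; identifier mapping is
data curation, out of scope.

## Known limitations

* NES values are comparable within a screen, not across screens with
  different rankings, set sizes or permutation counts.
* The gene-set permutation null ignores inter-gene correlation, as all
  preranked GSEA nulls do; p-values are anti-conservative on strongly
  correlated sets.
* The screen ranks signatures, not compounds; a compound profiled at
  several doses/times appears once per signature (summarized by
  `top_table`'s occurrence counts).
* BH families are per screened library; screening a filtered library
  changes adjusted p-values, not NES values.
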