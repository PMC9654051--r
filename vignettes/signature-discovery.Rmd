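---
title: "Deriving tissue-independent calorie-restriction signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving tissue-independent calorie-restriction signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crsignature)
```

`crsignature` implements a complete analysis chain for discovering a
tissue-independent transcriptomic signature of long-term calorie
restriction (CR) from bulk RNA-seq counts in a balanced two-diet,
four-tissue design, together with a synthetic-data generator that makes
every stage testable against known planted truth. This vignette is the
package's own account of the models, the tunable parameters, the
numerical choices, and where the design was genuinely open.

## The data model

The raw input is a genes × samples matrix of non-negative integer read
counts with per-gene exon lengths, plus sample metadata assigning each
library a diet (`control` or `CR`) and a tissue (hypothalamus,
amygdala, pituitary, adrenal). The design the package targets has five
libraries per diet per tissue — 40 in total — and all methods assume
both diets are present within every tissue, because every inference is
a within-tissue diet contrast or a pooled classification against diet.

## Differential expression

Counts for gene *g* in sample *j* are modelled as negative binomial
with mean `mu_gj` and dispersion `phi_g`, `Var = mu + phi * mu^2`. Per
tissue, the two-group GLM with log link is

```
log mu_gj = beta0_g + beta_g * diet_j + log s_j
```

where `s_j` are median-of-ratios size factors (geometric-mean
reference; upper-quartile fallback when no gene is nonzero everywhere,
a practical necessity for very sparse matrices). `beta_g` is the log
CR/control ratio; the reported fold change uses the signed convention
(`r` if `r >= 1`, `-1/r` otherwise), so a halving appears as −2.

**Dispersion.** `phi_g` is a per-gene method-of-moments estimate on
normalised counts with the sample variance pooled *within* diet groups,
truncated at zero. There is no shrinkage across genes: the estimator is
simple, transparent, and unbiased enough at the target design size; a
`shared_dispersion` switch replaces all `phi_g` by their median for
users who prefer borrowing strength.

**The Wald reference.** With a small-sample plug-in dispersion, the
naive Wald z against a standard normal is noticeably anticonservative
at n = 5 per group. The package therefore uses the quasi-likelihood
convention: the standard error is scaled by the Pearson-estimated
dispersion of the fitted GLM and the two-sided p-value comes from a t
reference with the residual degrees of freedom (n − 2). The package's
own null-simulation tests check that the empirical type-I error at
α = 0.05 stays in a narrow band around the nominal level under this
convention. Genes with all-zero counts in one group get a 0.5
pseudo-count on the normalised group means and a delta-method standard
error (same t reference), and are flagged; genes with zero counts
everywhere in a tissue are reported as `not_expressed` and excluded
from testing and FDR. p-values are Benjamini–Hochberg adjusted within
tissue.

## FPKM and the mined table

FPKM is computed from its definition,
`counts * 1e9 / (library_size * length_bp)`, with the library size
taken as each sample's total assigned counts and the annotated gene
length in the denominator — no effective-length correction, since the
pipeline starts from gene-level counts and no fragment-length model is
available. Genes whose arithmetic mean FPKM over *all* samples is
strictly below the threshold (default 5) are removed; a gene sitting
exactly at the threshold is kept. The mean is taken over the pooled
40-sample table rather than per tissue, because the object being
filtered is the pooled mined table itself.

The mined table has one row per sample and, as features, the kept
genes' FPKM values (columns sorted by gene id for determinism), a
categorical tissue attribute, and the binary diet class. Including
tissue as an ordinary feature is the crux of the design: if the
weighting ensemble ranks tissue near the bottom, diet response — not
tissue identity — is what drives the signature.

## The seven-model weighting ensemble

Five models are functions of the feature × class contingency table.
Numeric features are first discretized into equal-frequency bins
(default `n_bins = 5`, about eight samples per bin at the target
design; quantile edges, right-closed intervals, so heavy ties collapse
bins deterministically rather than splitting a value across bins).
With class entropy `H(C)` and bin entropy `H(B)` in bits:

* **information gain** `IG = H(C) − Σ_b p(b) H(C|b)`
* **gain ratio** `IG / H(B)` (0 when `H(B) = 0`)
* **symmetric uncertainty** `2 IG / (H(C) + H(B))`
* **Gini index** — the impurity reduction `Gini(C) − Σ_b p(b) Gini(C|b)`
* **chi-squared** — the raw Pearson statistic `Σ (O−E)²/E` over cells
  with positive expectation (the statistic, not its p-value, is the
  weight, matching the usual "weight by chi-squared" semantics)

The **rule** model is a OneR-style scorer: map each bin to its majority
class and take the rule's training accuracy minus the majority-class
baseline, floored at zero. This is an interpretation — rule-based
weighting operators in data-mining suites are not published formulas —
and is documented as such.

**ReliefF** rewards features that differ between a sample and its
nearest *misses* (other class) more than its nearest *hits* (same
class). Numeric features are min-max scaled to [0, 1]; `diff` is the
absolute scaled difference for numeric features and a 0/1 indicator
for categorical ones; inter-sample distance is the Manhattan sum of
diffs. The package uses `k = 5` neighbours per class and a full
deterministic pass over all samples (every sample visited once), with
neighbour ties broken by sample order. A sampled-iteration mode exists
for large tables but is not the default, precisely because determinism
is worth more than the modest speed-up at this design size. The unit
suite checks the vectorised implementation against an independent
quadratic-time reference at 1e-12.

Each model's raw weights are min-max normalised across features to
[0, 1] (a constant raw vector normalises to all zeros, with a
warning). The ranking statistic is the **sum of the seven normalised
weights**, in [0, 7]; ties are broken lexicographically by feature id
so rankings are reproducible. Reports additionally print weights
rounded to one decimal, which means a printed sum can differ from the
sum of the printed entries by up to one rounding unit — sums are
always computed from the unrounded values.

**Tissue-independence diagnostic.** The check reports the tissue
attribute's rank and sum and whether it falls in the bottom decile of
the ranking (rank/N ≥ 0.9). One structural fact is worth knowing: in a
perfectly balanced design every tissue bin is 50/50 in diet, so the
five contingency models and the rule model give the tissue attribute
*exactly* zero weight no matter what the genes do; only ReliefF can
lift it, which caps the tissue attribute's sum at 1.0. Adversarial
configurations (all diet effects confined to one tissue) therefore
raise tissue off the very bottom of the ranking — Relief's nearest
misses start crossing tissues — but cannot push its sum past 1, so the
bottom-decile flag is a coarse alarm, not a sensitive one. The warning
path is tested directly on constructed rankings.

## Posterior effect reporting

For a vector of posterior draws of one effect the package reports the
posterior median `E_M`, the shortest interval containing 95% of the
draws (sliding-window HDI over the sorted sample; the mass is
configurable), the probability of direction
`D_p = max(P(>0), P(<0))` with draws at zero split evenly, and the
proportion of the **full posterior** inside the region of practical
equivalence `±0.05 · SD(y)`. The effect is declared not practically
equivalent to zero when `ROPE_p < 0.025`. Three small choices are
deliberate: ROPE membership uses the closed interval (draws exactly on
a bound count as inside, conservative for the decision); `ROPE_p` is
computed on the full posterior rather than the HDI subset, with a
`rope_within_hdi` switch for the alternative convention; and the
summary refuses fewer than 100 draws by default, below which HDI and
tail proportions are too unstable to report. Model fitting is out of
scope — the functions consume draws from whatever sampler produced
them.

## Multivariate analysis of fold changes

The genes × tissues matrix of signed fold changes (top 40 genes by
best p-value; fold change 1 imputed where a gene is not expressed in a
tissue) feeds two summaries. PCA uses the column correlation matrix
(equivalently, standardised columns), with a deterministic sign
convention — each component's largest-magnitude loading is made
positive. Agglomerative clustering of tissues runs on Euclidean
distance with complete linkage by default (single and average
available), and each merge is reported on the percent-similarity scale
`100 · (1 − d/d_max)`, the convention of classical statistical
packages, so the final merge sits at exactly 0% and identical columns
join at 100%.

## The synthetic generator

The generator emulates the target study design, not any particular
dataset. Per gene: length uniform on 500–5000 bp; a log-normal baseline
rate (`meanlog = 1`, `sdlog = 1.5`), giving a long-tailed FPKM
distribution in which a realistic minority of genes falls under the
mean-FPKM < 5 filter at the default problem sizes; a per-tissue
log-normal multiplier (`sdlog = 0.5`) so tissues have genuinely
different expression profiles; NB dispersion 0.3, a typical bulk
RNA-seq magnitude. Per sample: a log-normal size factor
(`sdlog = 0.1`) so normalisation is exercised non-trivially, and an
expected depth of 2e6 fragments per library — proportionally matched
to real experiments (on the order of 1000 fragments per expressed
gene), so that count noise is dispersion-dominated rather than
shot-noise-dominated.

Planted truth comes in two flavours. *Signature* genes receive one
multiplicative diet fold (up or down, one sign per gene) in every
tissue; *tissue-dependent* genes draw an independent sign per tissue,
mimicking genes that respond up in one tissue and down in others. The
planted classes are assigned only to genes whose expected pooled mean
FPKM clears the filter threshold (conservatively assuming the gene is
down-regulated): the signature concept is defined on the post-filter
expressed gene set, and an "effect" planted on a gene the filter
removes would be unrecoverable by construction, turning recovery tests
into tests of the filter instead of the ranking.

What the generator does **not** emulate: batch effects beyond size
factors, gene–gene correlation, length-dependent count biases beyond
the linear length term, outlier samples, and read-level artefacts.
Passing recovery tests on this generator therefore demonstrates that
the pipeline's logic is sound under its stated model — not that real
tissue panels are as well-behaved.

## Problem sizes and test design

The test and acceptance workloads use 2000-gene matrices (10 planted
signature genes, effect fold 3, five seeds) for recovery runs and 2000
null genes for Wald calibration — sizes chosen so the full suite
completes in about a minute while keeping Monte-Carlo error small
relative to the asserted bands. Exhaustive oracle comparisons for the
contingency weights cover every 2×2 table with cells up to 6 and every
4×2 table with cells up to 2, plus a seeded random sweep of larger 4×2
tables; full enumeration of all 4×2 tables with cells up to 6 (about
5.8 million) would add hours of interpreted-loop time for no additional
coverage of code paths. All stochastic tests fix their seeds; the
pipeline derives one seed per stage from the master seed and the stage
name, so toggling stages never shifts another stage's random stream.

## Known limitations

* The weighting models operate on the pooled 40-sample table; strong
  tissue-specific baselines can dilute the contingency models' view of
  a genuine diet effect (ReliefF, being neighbourhood-based, is robust
  to this). This mirrors the behaviour of the mining workflow the
  package models, but users with severe tissue imbalance should
  inspect per-tissue DE results alongside the ensemble ranking.
* Exact numeric agreement with any particular commercial mining suite
  is not claimed: discretization, Relief neighbour counts and rule
  scoring differ between implementations, and only the aggregation
  arithmetic and qualitative behaviour are specified here.
* The DE module fits a single two-group contrast per tissue; it has no
  covariates, no multi-factor designs, and no empirical-Bayes
  dispersion shrinkage.
* `NE` (not expressed) means all-zero counts in every library of that
  tissue — not "filtered", which is a property of the mined table, not
  of the DE input.
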