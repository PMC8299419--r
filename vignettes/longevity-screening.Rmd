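---
title: "Screening strain omics panels for lifespan-correlated expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening strain omics panels for lifespan-correlated expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifecor)
```

## The screening problem

Recombinant-inbred mouse panels such as the BXD family pair a
reproducible genome per strain with a published median lifespan, and
public repositories hold transcriptomic and proteomic profiles of many
of these strains across tissues and sexes. That combination allows a
simple question to be asked at scale: which genes' expression levels
track how long a strain lives?

`lifecor` implements this screen as a pipeline of small, testable
stages:

1. **Match and rank.** Each dataset's strains are matched to a median
   lifespan table (spelling dialects such as `BXD-1` / `bxd 1` / `BXD1`
   are harmonized by case-folding and stripping separators) and ordered
   shortest- to longest-lived.
2. **Select the extremes.** By default the 4 shortest- and 4
   longest-lived matched strains enter the comparison (`tails` mode,
   `tail_size = 4`). The premise of extreme-phenotype sampling is that
   lifespan-determining genes change most between the ends of the
   ranking; the middle of the distribution mostly adds noise at these
   sample sizes. Datasets with too few matched strains (fewer than
   `2 * tail_size`) fall back to using every strain, as do datasets
   explicitly configured with `mode = "all"` — the shipped synthetic
   roster applies that to both liver datasets, which emulate the
   smaller liver cohorts.
3. **Score.** For every feature, the Pearson correlation `r` between
   expression and median lifespan over the selected strains, together
   with the slope of the univariate regression of lifespan (days) on
   expression. Pearson rather than Spearman is used deliberately:
   lifespan is a continuous, non-ordinal trait, and with eight
   observations the rank transform discards most of the information.
4. **Vet.** Features with `|r| >= 0.4` count as longevity-correlating,
   `|r| >= 0.7` as top hits. Both thresholds are configurable.
5. **Merge.** Hit sets are compared across datasets (pairwise overlap)
   and genes are ranked by *presence count* — the number of datasets
   in which the gene is both measured and passing — then by mean
   `|r|` over the passing datasets, then by gene id.
6. **Enrich.** Hit lists are tested against user-supplied GMT gene
   sets with the upper-tail hypergeometric probability and
   Benjamini–Hochberg adjustment.

## Choosing the |r| threshold

With `n` strains the smallest correlation significant at two-tailed
level `alpha` follows from the t-transform of `r`:

```
r_crit = t / sqrt(t^2 + n - 2),   t = qt(1 - alpha/2, df = n - 2)
```

`critical_r()` evaluates this. At `n = 32` and `alpha = 0.05` it gives
0.349, which motivates 0.4 as a conservative round default; at
`n = 12` it gives 0.576. Note one inconsistency a user of published
critical-r tables may meet: 0.349 is sometimes quoted against an
average sample size of 43, but the construction above yields 0.301 at
`n = 43` — 0.349 belongs to `n = 32`. The package reports the formula's
value and leaves the table attribution to the reader.

`critical_r()` is a diagnostic, not a filter: vetting is by `|r|`
only, with no p-value or FDR selection at the scoring stage. With
eight strains, roughly a third of pure-noise features exceed
`|r| = 0.4` (see the null calibration below), so the screen is a
high-recall first pass whose specificity comes from requiring
presence across many independent datasets, not from any single
dataset's cutoff.

## Missing data and undefined scores

Scoring is pairwise-complete per feature with a minimum of `min_obs =
6` observations (configurable). A feature with fewer complete pairs,
or constant over them, gets an *undefined marker* (`NA`), never a
silent zero — zero would spuriously fail the threshold while looking
like evidence of absence. Undefined features are excluded from hit
sets but still count as *measured* for cross-dataset bookkeeping: a
gene is "measured" in a dataset when its platform quantified it (it
has a score row), and "present" only when additionally `|r|` passes.
Genes unmeasured in a dataset are excluded from that dataset's
denominator rather than counted as failures.

## Normalization conventions

Expression values are expected as per-feature z-scores. Some
GeneNetwork exports use the "2z+8" convention (z-scores rescaled to
mean 8, SD 2); datasets declaring `two_z_plus_8` are mapped back via
`z = (x - 8) / 2` before scoring. Correlations are scale-invariant, so
this only matters for the slope, which is reported in days per SD of
expression once data are on the z scale. Data declared `other` are
refused rather than guessed at.

## Probe-to-gene collapse

Microarray platforms carry several probes per gene. Before
cross-dataset comparison, `collapse_features_to_genes()` keeps, per
gene, the probe with maximal `|r|` (sign retained from that probe;
ties broken by lexicographically smallest probe id; undefined probes
lose to any defined one). The rationale is to preserve the strongest
longevity signal per gene for the gene-level overlap analysis; mean-
or median-collapse would dilute a real signal carried by the one
probe that targets the expressed isoform. This rule is a package
decision — collapse conventions vary across studies — and is therefore
stated explicitly in the output metadata.

## Overlap definitions

The pairwise overlap of two hit sets is computed after restricting
both to the *shared measured universe* (genes quantified in both
datasets). Two fractions are reported:

- `fraction` — the Jaccard index `|A ∩ B| / |A ∪ B|`, the headline
  similarity of the two hit sets (diagonal = 1 by construction);
- `fraction_of_universe` — `|A ∩ B| / |shared universe|`, the share of
  commonly measured genes that are hits in both datasets.

The distinction matters for threshold sweeps: raising the threshold
shrinks both hit sets, so intersections, unions and
`fraction_of_universe` are non-increasing — but the Jaccard *ratio*
can increase when the union shrinks faster than the intersection
(shrink `A = {a, b}, B = {a}` to `A = B = {a}` and Jaccard jumps from
1/2 to 1). Property tests assert monotonicity for the quantities that
are mathematically monotone and treat Jaccard as a similarity, not a
monotone statistic.

"Average correlation value" in the shared-gene ranking means the mean
of `|r|` over passing datasets. A signed mean would cancel genuine
signal, because the same gene can correlate positively with lifespan
in one tissue and negatively in another; the signed per-dataset values
are preserved separately in the sign-pattern matrix, where an absent
entry is an explicit missing marker, never 0.

## The synthetic panel generator

Real BXD matrices are large external downloads; the package instead
validates against a generator whose ground truth is known exactly.
The default configuration (`synthetic_config()`) is the reference
study design used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `n_strains` | 40 | strains in the panel |
| `lifespan_range` | 450–900 days | uniform medians; over a twofold spread, as across real BXD strains |
| `n_datasets` | 8 | roster: adrenal m/f, kidney m/f, liver RNA f, liver protein f, bone m, eye combined |
| `strains_per_dataset` | 20 | sampled without replacement, so subsets overlap only partially |
| `n_features_per_dataset` | 500 | i.i.d. `N(0, noise_sd^2)` background sharing one `BG…` gene-id space |
| `planted` | 2 universal genes, `\|rho\| = 0.95` | tissue-specific sign patterns |
| `missing_rate` | 0 | optional missing-at-random injection |
| `tail_size` | 4 | tails used downstream |

A planted gene with target correlation `rho` is constructed as
`expr = rho * z_L + sqrt(1 - rho^2) * eps`, with `z_L` the
standardized lifespan over the dataset's strain subset and
`eps ~ N(0, 1)`: the standard bivariate-normal construction, under
which `rho` is the exact population correlation and the sampling
distribution of the empirical `r` is analytically known. `noise_sd`
scales only the background features; the planted noise term keeps unit
variance so the planted correlation is not diluted.

Lifespans are uniform because only the ordered medians matter to the
tails design and uniform draws maximize rank information; the range
realizes the documented greater-than-twofold spread between the
shortest- and longest-lived strains. One global seed expands into
per-dataset sub-seeds through a fixed affine-modular rule, so adding a
ninth dataset leaves the first eight bit-identical.

What the generator does **not** emulate: genetic relatedness between
strains (no kinship, no QTL structure — the screen itself never uses
genotypes), platform-specific intensity distributions, batch effects,
or correlated background genes. Passing the recovery tests therefore
shows the machinery is correct under a clean linear signal-plus-noise
model; it does not certify power or error rates on real arrays, where
background correlation inflates the number of co-passing genes.

## Null calibration and what the tests establish

With 8 selected strains, a pure-noise Gaussian feature passes
`|r| >= 0.4` with probability

```
p0 = 2 * P(T6 >= 0.4 * sqrt(6 / (1 - 0.16))) ≈ 0.326
```

The test suite checks (i) this fraction on 20,000 background features
to within ±0.02; (ii) that presence counts of background-only panels
follow `Bin(8, p0)`; and (iii) that in at least 95 of 100 replicate
panels the two planted universal genes attain presence count 8 and
the top two ranks — the recovery analogue of finding the same two
genes shared by all eight real datasets. Problem sizes (20,000
features for calibration, 100 panels of 8 × 502 × 20 for recovery)
were chosen so the full suite completes in well under a minute while
keeping Monte-Carlo error far below the asserted tolerances.

## Enrichment

`run_enrichment()` is a self-contained over-representation analysis:
each gene set is intersected with the universe, sets outside
`[min_set_size, max_set_size]` (defaults 5 and 500, conventional ORA
bounds) are skipped, and `P(X >= k)` is computed from the
hypergeometric distribution in log space. The universe should be the
genes measured in the dataset being enriched; when no measured
universe is available, the union of collection members is the
fallback. BH-adjusted values are reported alongside raw p-values; the
hypergeometric test is discrete and therefore conservative, so null
p-values are stochastically larger than uniform. This module is a
generic replacement for dedicated GO tooling: it knows nothing of
term ancestry or the GO DAG, and its results depend entirely on the
supplied GMT.

## Determinism and numerical conventions

- All TSV writers format doubles with 17 significant digits, so every
  write→read round trip is value-exact and identical configs + seed
  reproduce output files byte for byte.
- Correlations are clamped to `[-1, 1]` after the vectorized
  computation to absorb floating-point overshoot on exactly linear
  features.
- Ordering rules are total everywhere (lifespan ties by normalized
  strain id; `|r|` ties by feature id; ranking ties by presence, mean
  `|r|`, then gene id), so results are permutation-invariant and
  platform-stable.
- Strain name normalization is intentionally aggressive
  (case-insensitive, separator-stripping); distinct strains that
  differ only by separators would collide, which is the right trade
  for repository spelling noise but worth knowing for unusual naming
  schemes.

## Limitations

The screen inherits the limits of its design: with four strains per
tail, single-dataset hits are noisy by construction, and everything
rests on the published median lifespans being applicable to the
profiled cohorts. No multiple-testing correction is applied at the
scoring stage, no covariates (age at collection, diet, batch) are
modeled, and probe-collapse by max `|r|` slightly biases gene-level
`|r|` upward under the null. Cross-dataset presence counting treats
datasets as independent evidence, which overstates independence when
datasets share strains or experimental origin.
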