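---
title: "Benchmarking glycomics normalization by network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking glycomics normalization by network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glybench)
```

## The problem

High-throughput glycomics platforms — subclass-resolved IgG Fc glycopeptide
mass spectrometry, chromatographic total-IgG glycan profiling, and
mass-merged total-plasma glycan profiling — deliver abundance tables that
carry technical variation: per-sample differences in injected material
(dilution), instrument drift, additive baseline shifts. Normalization is
supposed to remove this variation, but the common options rest on different
and usually unverifiable assumptions, and the de facto standard, total-area
(TA) normalization, is a closure operation that provably distorts the
covariance structure of the data.

`glybench` scores a normalization by a *biological* criterion instead of a
purely statistical one. Glycans are synthesized by the stepwise addition of
single monosaccharides, so the true dependence structure of glycan
abundances should concentrate on single-step neighbours in the synthesis
pathway. A Gaussian graphical model (GGM) estimates exactly this kind of
structure from data: its edges are non-zero partial correlations, i.e.
pairwise associations conditioned on all other glycans. A normalization
that preserves biology should yield a GGM whose edges coincide with known
synthesis steps; a normalization that injects artifacts should not.

The pipeline is: normalize with a candidate strategy, fit a shrinkage GGM,
classify all glycan pairs against the reference pathway in a 2×2 table
(edge in both, GGM only, pathway only, neither), and summarize the overlap
by a one-sided Fisher's exact test p-value — lower means better. The
whole procedure is bootstrapped (samples resampled with replacement,
normalization parameters recomputed per replicate) and strategies are
ranked by the bootstrap median p-value.

## The strategy menu

Seven base methods are implemented, each an explicit assumption about the
technical variation:

* **Raw** — no correction (baseline for comparison).
* **Median** centering — a constant per-sample additive offset (default:
  each sample's median across glycans is subtracted; the per-glycan variant
  is available via `mode = "per_glycan"`).
* **TA** — per-sample division by the total signal; the closure operation.
* **Quotient** — probabilistic quotient: each sample is divided by the
  median ratio to a reference sample (the per-glycan median across
  samples), an estimate of the sample's dilution factor.
* **TAQuotient** — quotient applied after closure, in that fixed order.
* **Quantile** — per-glycan distributions forced onto the pooled
  rank-means (ties averaged).
* **Rank** — values replaced by within-glycan ranks across samples.

Every method except median centering (which produces non-positive values)
also has a natural-log variant, giving 13 strategies. On the
subclass-resolved glycopeptide platform each sample-dependent method
(quantile, rank, TA, quotient, TAQuotient, and their log forms) can also be
applied independently within each IgG subclass block, adding 10 more for 23
in total. `enumerate_strategies(platform)` produces exactly this menu;
`apply_strategy()` dispatches a single spec.

The closure artifact is not hypothetical: for compositional data the
covariance of each glycan with the row total is zero, which forces at least
one negative entry into every row of the covariance matrix. This holds for
every positive input matrix and is asserted as a property test over
hundreds of random draws.

## The network estimator

With p up to ~60 glycans and sometimes modest n, the sample correlation
matrix is noisy or ill-conditioned, so the GGM uses a shrinkage estimator:

1. **Shrinkage correlation.** `R* = λ I + (1 − λ) R`, with the analytic
   intensity `λ* = Σ Var̂(r_ij) / Σ r_ij²` over distinct pairs, where
   `Var̂(r_ij)` is the unbiased empirical variance of the standardized
   cross-products. `λ*` is clipped to [0, 1] (and set to 1 if all
   correlations vanish); `R*` is positive definite whenever `λ > 0`.
2. **Partial correlations.** The standardized negative inverse of `R*`.
3. **Empirical-null significance.** The off-diagonal partial correlations
   are modelled as mostly null with density
   `f0(r; κ) ∝ (1 − r²)^((κ−3)/2)`, where κ acts as an effective
   degrees-of-freedom parameter. κ is estimated by maximum likelihood with
   iterative tail exclusion: after an initial fit on all values, values
   beyond the fitted null's upper 5% tail are set aside and κ is refit with
   a truncated likelihood (the truncation probability enters the
   likelihood, keeping the estimate consistent for the null component).
   The plain MLE is markedly biased when a minority of real edges sits in
   the tails — in simulations with 10% contamination at |r| = 0.5 it can
   halve κ — whereas the truncated refit stays within a few percent of the
   true value, and remains identifiable because the truncation point sits
   at the null scale. A Fisher-z alternative (`method = "fisher_z"`) is
   provided, and is also the automatic fallback for networks with fewer
   than 10 pairs, where fitting a null distribution is meaningless.
4. **Edge selection.** Two-sided tail-area p-values
   (`P(|R| ≥ |r|)` has an incomplete-beta closed form under `f0`) are
   corrected by Benjamini–Hochberg across all p(p−1)/2 pairs, once per
   dataset, at FDR `q = 0.01` by default. Tail-area p-values plus BH are
   the literal reading of the published procedure; a local-fdr variant
   would be a natural alternative but is not implemented.

`infer_ggm()` composes these steps and returns a classed fit with `print`,
`summary`, `coef` (the partial-correlation matrix), `plot`, `simulate` and
`as.data.frame` methods. The estimator is deterministic and invariant to
sample order.

## Pathway priors

The reference pathway is rule-based: two glycans are joined when their
monosaccharide-class compositions (hexose, HexNAc, fucose, NeuAc) differ by
exactly one unit in exactly one class — one enzymatic addition. Working at
composition level is a deliberate simplification: isomer-level branch
resolution is not attempted, and the rule is auditable and reproducible.
A user-supplied explicit edge list (`read_pathway_edges()`) overrides the
rule when curated knowledge is available.

Three platform-specific constructions are provided:

* **Subclass-resolved glycopeptides** (`build_igg_fc_pathway()`): the same
  pathway is replicated within each IgG subclass; nodes are
  subclass-qualified labels. Cross-subclass edges between identical
  compositions are off by default — the biology replicates the pathway per
  subclass, but whether identical glycoforms on different subclasses
  should count as direct neighbours is not established, so it is a flag.
* **Chromatographic peaks**: each peak is approximated by its predominant
  structure and the structure-level rule applies.
* **Mass-merged profiles** (`build_mass_pathway()`): structures with equal
  mass are merged into one node (union of incident edges, self-loops
  dropped) and nodes whose mass was not measured are removed. Removal is
  read literally — edges through removed nodes are lost — because the
  alternative (bridging neighbours of a removed node with a direct edge)
  is equally defensible but not documented anywhere; both behaviours are
  available via `bridge_removed`. Mass matching uses residue-sum masses
  (constant offsets cancel in equality comparisons) with a ±0.5 Da
  tolerance, configurable.

Glycan names are parsed by `parse_composition()` in two dialects:
composition strings (`H5N4F1S1`) and short IgG names in both the G-style
(`G2FS1`) and Oxford (`FA2G2S1`) conventions, including high-mannose
(`M5`–`M9`).

## The synthetic-data generator

Because the deposited cohort data are an optional download, every claim the
package makes is testable on synthetic data with known ground truth.
The generator (`simulation_config()`, `sample_abundances()`,
`apply_artifacts()`) draws log-scale abundances from a multivariate normal
whose precision matrix has support exactly on the pathway edges (entry
−ρ·s at edges with random signs, diagonal loaded until safely positive
definite), adds optional linear age effects on the log scale, exponentiates
to positive abundances, and then contaminates with the two artifact types
the normalization menu targets: per-sample multiplicative dilution
`f_i ~ LogNormal(0, σ_d)` and per-sample additive offsets
`o_i ~ Normal(0, σ_o)`. Closure is never applied by the generator — TA is a
strategy under test, not a data property.

Defaults: edge partial correlation ρ = 0.3 (comfortably detectable at
cohort sample sizes without being unrealistically strong), log-scale sd
σ = 0.5 (a realistic biological coefficient of variation for glycan
abundances), ages uniform on 18–88 years (the range of the largest
subclass-resolved cohort), and platform shapes of 50 glycoforms (20/20/10
across IgG1, IgG2/3, IgG4), 24 peaks, or 61 masses. `generate_benchmark()`
emits the dataset, pathway and a JSON truth file (seed, edges, per-sample
dilution factors, age slopes) in the package's I/O formats.

What the generator does *not* emulate: batch structure, missing values
(the pipeline's complete-case filter is tested separately), peak-picking
noise, isomer mixtures within chromatographic peaks, and non-log-normal
marginals. Passing tests therefore demonstrate correctness of the
machinery and qualitative behaviour under the stated artifact model, not
performance guarantees on any particular real cohort.

## Bootstrap, ranking, determinism

`bootstrap_evaluate()` resamples samples with replacement B = 1000 times by
default (B = 100 is used in the package's own synthetic benchmark, which
is ample to separate strategies whose medians differ by orders of
magnitude), re-applies the normalization inside each replicate — the
quotient reference, quantile means and ranks are sample-set-dependent, so
re-normalizing is the faithful default; `renormalize = FALSE` gives the
normalize-once variant — and summarizes the replicate Fisher p-values by
the median and the 2.5/97.5 percentile interval. The Fisher test defaults
to the one-sided enrichment alternative: "lower p = higher overlap" is
only coherent for enrichment; a two-sided option exists.

Replicates in which a glycan becomes constant (so the correlation is
undefined) are skipped with a warning; more than 5% skips is an error.
Ties in the ranking are broken alphabetically by label, so rankings are
stable under permutation of the strategy list.

Randomness is controlled by a single seed expanded into per-strategy
streams keyed by the strategy label, so adding or removing a strategy
never perturbs the replicates of the others, and identical configuration
plus seed reproduces output files byte for byte (output files carry a
configuration hash in a header comment).

## Age-association secondary evaluation

As an independent check against a more conventional criterion,
`age_fraction()` regresses each glycan on age (OLS, two-sided t-test on
the slope), corrects across glycans by BH at FDR 0.01, and reports the
fraction of significant glycans; `weighted_average_fractions()` combines
cohorts by first averaging the replicated-platform group and then taking a
plain mean with each remaining cohort — no sample-size weights. Constant
glycan columns yield an undefined test and are counted as non-significant
with a warning.

## Numerical choices and degenerate inputs

* Natural log throughout (correlation-based results are base-invariant).
* Ties: average ranks and averaged quantile means — deterministic.
* κ optimization is performed on log(κ − 3) with κ capped at 1e7; an
  all-zero partial-correlation vector returns the cap with a warning.
* Non-positive row totals (TA), non-positive reference entries or dilution
  factors (quotient), non-positive values under log, constant columns
  under correlation, and GGM/pathway node-set mismatches all raise errors
  naming the offending sample, glycan or cell.
* The precision-matrix generator guarantees a smallest eigenvalue of at
  least 0.05 via diagonal loading followed by rescaling to unit diagonal,
  which preserves the zero pattern exactly.
* Problem sizes used in the package's own checks: oracle comparisons at
  p ≤ 8, FDR control over 500 null simulations at n = 80, p = 8,
  large-sample pathway recovery at n = 20000, and the headline benchmark
  at n = 300, B = 100 on the 50-glycoform panel.

## Known limitations

* The pathway prior is composition-level; isomers and branch positions are
  not resolved, and the predominant-structure approximation for
  chromatographic peaks ignores within-peak mixtures.
* Batch correction and missing-value imputation are out of scope; samples
  with missing values are excluded before normalization
  (`drop_incomplete_samples()`).
* The empirical-null tail-area test assumes a null majority of pairs; for
  very dense true networks the null fit would be biased conservative.
* Bootstrap medians are compared across strategies on the same resample
  seeds per strategy label; no formal test of the difference between
  strategies is attached to the ranking.

## A minimal run

```{r example, eval = FALSE}
pathway <- build_igg_fc_pathway(igg_glycoforms())
cfg <- simulation_config(pathway, n = 300, rho = 0.3, sigma = 0.5,
                         sigma_d = 0.5, seed = 1)
d <- apply_artifacts(sample_abundances(cfg), cfg)
d$platform <- "lc-esi-ms"

bench <- benchmark_normalizations(
  d, pathway,
  strategies = lapply(c("raw", "ta", "quotient"), normalization_spec),
  B = 100, seed = 1)
bench
plot(bench)
```
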