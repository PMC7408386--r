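# glybench

Benchmarking normalization methods for glycomics data by how well the
resulting correlation network recovers known glycan synthesis reactions.

## The problem

Glycomics abundance tables (IgG Fc glycopeptides, total-IgG glycan peaks,
total-plasma glycan masses) carry technical variation — sample dilution,
baseline offsets, instrument drift — and there is no consensus on how to
normalize them. Worse, the de facto standard, Total Area normalization,
is a *closure* operation: dividing each sample by its total forces the
normalized values to sum to one, which provably places at least one
negative entry in every row of the covariance matrix and thereby distorts
any downstream correlation analysis.

`glybench` evaluates a normalization by a biological measure of quality.
Glycans are synthesized by stepwise addition of single monosaccharides, so
the conditional-dependence structure of glycan abundances should
concentrate on single-step neighbours in the synthesis pathway. The
package:

1. applies a candidate normalization (the menu covers Raw, Median
   centering, Total Area, Probabilistic Quotient, TA+Quotient, Quantile,
   Rank, their log variants, and per-IgG-subclass variants — 13 strategies
   per platform, 23 on the subclass-resolved platform);
2. fits a Gaussian graphical model by shrinkage partial correlations
   (`R* = λI + (1−λ)R` with analytic `λ* = ΣVar̂(r_ij)/Σr_ij²`), with
   empirical-null tail-area edge p-values
   (`f0(r;κ) ∝ (1−r²)^((κ−3)/2)`, κ fit by robustified maximum
   likelihood) and Benjamini–Hochberg edge selection at FDR 0.01;
3. classifies all glycan pairs against a rule-based synthesis pathway
   prior (edge ⇔ compositions differ by exactly one monosaccharide) in a
   2×2 table and scores the overlap by a one-sided Fisher's exact test —
   lower p, better normalization;
4. bootstraps the whole pipeline (normalization parameters recomputed per
   replicate) and ranks strategies by the median overlap p-value, with an
   independent secondary ranking by the fraction of glycans significantly
   associated with age.

A synthetic-data generator with known pathway structure and known
technical artifacts (log-normal dilution factors, additive offsets) makes
every stage testable without any external data.

## Worked example

Simulate a 50-glycoform subclass-resolved panel (n = 300) whose partial
correlations follow the IgG Fc synthesis pathway, contaminate it with
per-sample dilution (σ_d = 0.5), and compare three strategies:

```r
library(glybench)

pathway <- build_igg_fc_pathway(igg_glycoforms())   # 50 nodes, 85 edges
cfg <- simulation_config(pathway, n = 300, rho = 0.3, sigma = 0.5,
                         sigma_d = 0.5, seed = 1)
d <- apply_artifacts(sample_abundances(cfg), cfg)
d$platform <- "lc-esi-ms"

bench <- benchmark_normalizations(
  d, pathway,
  strategies = list(normalization_spec("raw"),
                    normalization_spec("ta"),
                    normalization_spec("quotient", log = TRUE)),
  B = 100, seed = 1)
bench
#> <normalization benchmark> 3 strategies, B = 100, FDR q = 0.01
#>          label median_p   ci_low  ci_high rank
#> 1 Quotient log 3.84e-43 4.75e-62 6.30e-19    1
#> 2          Raw 6.11e-09 2.92e-15 6.94e-02    2
#> 3           TA 2.74e-04 3.37e-11 2.42e-01    3
```

Quotient-log wins by ~34 orders of magnitude of median overlap p-value: it
removes the injected dilution without the closure distortion, while TA —
although it also cancels dilution — pays for the compositional constraint
it imposes. A single fitted network shows why the overlap p-values are so
small:

```r
fit <- infer_ggm(log_transform(probabilistic_quotient(d))$abundance)
fit
#> <GGM> 50 nodes, 84 edges at FDR 0.01 (n = 300)
#>   shrinkage lambda = 0.1072, null kappa = 401.3
contingency_counts(fit, pathway)
#> <overlap> tp=81 fp=3 fn=4 tn=1137 (50 nodes)
```

Of the 84 selected edges, 81 are true synthesis steps (85 exist), and only
3 of the 1140 non-pathway pairs are selected.

Config-driven runs (`run_evaluation()`, `run_age_analysis()`, YAML or
JSON) and a thin command-line wrapper (`inst/scripts/glybench`) orchestrate
the same pipeline end to end with deterministic seeding; identical config
and seed reproduce output files byte for byte.

See the vignette `vignettes/normalization-benchmarking.Rmd` for the model,
its assumptions, parameter defaults, and known limitations.

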