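# bestcite

Robust Bayesian comparison of citation counts between groups of
publications — for bibliometricians, meta-researchers and anyone asking
whether one cohort of papers (say, those with reproducible computational
models) is cited more than another.

Citation counts are heavy-tailed: a few blockbuster papers can dominate a
group, and a classical t-test comparison is driven by exactly those
outliers. `bestcite` implements the BEST approach (Bayesian Estimation
Supersedes the t-Test). Each group *g* is modelled with a location-scale
Student-t likelihood,

    y_gi ~ t_nu(mu_g, sigma_g),

with a tail ("normality") parameter ν shared across groups, so outliers are
absorbed by heavy tails instead of distorting the means. Priors come from
the pooled data: μ_g ~ N(m, (10 s)²), σ_g ~ U(s/100, 100 s) and
ν ~ 1 + Exp(mean 29), with m and s the pooled mean and standard deviation.
The posterior (sampled by a C++ slice sampler, deterministic given a seed)
yields full distributions of the quantities decisions are made on:

* the difference of means μ₁ − μ₂ and of scales σ₁ − σ₂;
* the Cohen's d effect size per draw, d = (μ₁ − μ₂)/σ_pooled with
  σ_pooled = sqrt(((n₁−1)σ₁² + (n₂−1)σ₂²)/(n₁+n₂−2));
* 95% highest-density intervals (HDI), credibility masses above zero, and a
  four-way HDI/ROPE decision: reject equal means when the mean-difference
  HDI clears zero, accept them only when the effect-size HDI sits inside
  the region of practical equivalence (−0.2, 0.2), otherwise undecided.

Around the model sit bibliometric curation (Scopus / Web of Science /
Google Scholar averaging, imputation of sources missing from the stricter
databases at 62.87% of the Google Scholar count, journal-impact-factor
normalization, period filtering, deduplication), a hand-built Mann-Whitney
U companion test (exact p by enumeration for small samples, tie- and
continuity-corrected normal approximation otherwise), Shapiro-Wilk and
QQ/Kolmogorov-Smirnov distribution checks, split-chain PSRF / ESS
convergence diagnostics with prior and posterior predictive checks, and a
synthetic-study generator with a ground-truth manifest.

## Worked example

```r
library(bestcite)

# a synthetic study at the package's reference conditions:
# 111 vs 76 papers, true mean difference 3.4 citations, heavy tails
study <- generate_study(seed = 20260927)

run <- run_comparison(study$records, period = c(2013, 2020),
                      draws = 20000, chains = 4, warmup = 1000, seed = 1)
print(run)
```

```
Period 2013-2020
Robust comparison: REPRODUCIBLE (n1=111) vs NON_REPRODUCIBLE (n2=76)
  mean diff    mean     3.53  95% HDI (0.797, 6.39)  P(>0) = 99.2%
  sd diff      mean    0.661  95% HDI (-1.72, 3.02)  P(>0) = 71.4%
  effect size  mean    0.457  95% HDI (0.0824, 0.82)  P(>0) = 99.2%
  decision: REJECT_H0_GROUP1_HIGHER
Mann-Whitney U test (NORMAL_APPROX): U = 3390.5, n1 = 111, n2 = 76, p = 0.02272
  max PSRF = 1.0002, min ESS = 9607
```

Reading the output: the posterior mean of the citation difference is 3.53
(the generator's truth is 3.4) and its 95% HDI (0.80, 6.39) lies entirely
above zero, so the null hypothesis of equal means is rejected in favour of
the first group, with 99.2% of the posterior mass on a positive difference.
The scales do not differ credibly (the sd-difference HDI straddles zero),
the effect size is moderate (0.46), and the convergence diagnostics are
clean (split PSRF ≈ 1, effective sample size near the draw count). The
Mann-Whitney companion agrees here (p = 0.023).

Other entry points: `curate_citations()` (curation with an exclusion log),
`best_fit()` / `compare_groups()` (model level), `run_multi_period()`
(joint shared-tail model over several periods with a pairwise credibility
matrix), `mwu_test()`, `t_fit_check()`, `predictive_check()`,
`write_report()` (CSV/JSON report bundle with a run manifest), and
`run_from_config()` for YAML/JSON-driven runs. `reproduce_published_tables()`
reruns the four standard comparisons (full period, 2013–2020, JIF
normalized, benchmark group) on a user-supplied deposited dataset.

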