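# metabofract

Multifractal analysis of metabolic-rate time series in R.

Long flow-through respirometry records — hours of oxygen consumption
(VO2) sampled every second — fluctuate irregularly, and the *structure*
of those fluctuations carries physiological information that mean-level
summaries like basal metabolic rate (BMR) miss. This package is for
physiologists and behavioral ecologists who want to quantify that
structure and relate it to behavior: it implements the full chain from
raw respirometry channels to multifractal descriptors, surrogate-based
source attribution, recognition-index behavioral statistics, and an
integrative multivariate comparison of treatment groups.

## The method in brief

The analyzed series is the log-ratio increment series
`r(t) = log10(VO2(t+1)/VO2(t))`. Multifractal detrended fluctuation
analysis (MF-DFA) builds the profile `y_i = Σ_{k≤i}(r_k − r̄)`,
detrends it in `2⌊N/s⌋` segments of length `s` by a local polynomial,
and aggregates the detrended variances σ²(v, s) into

    F_q(s) = { (1/2Ns) Σ_v [σ²(v,s)]^(q/2) }^(1/q),

with logarithmic averaging at q = 0. The generalized Hurst exponent
h(q) is the slope of ln F_q(s) on ln s; `H = h(2)` is the classical
Hurst exponent and `Δh = h(q_min) − h(q_max)` the multifractality
range. From the Renyi exponents `τ(q) = q·h(q) − 1`, the Legendre
transform `α = dτ/dq`, `f(α) = qα − τ(q)` yields the singularity
spectrum with descriptors α₀, Δα, Δf and asymmetry B. Shuffle and
AAFT-surrogate versions of the series attribute the observed Δα to
long-range correlations versus heavy-tailed distributions through the
ratios Δα_shuff/Δα_orig and Δα_surr/Δα_orig. Group structure across
behavioral and physiological variables is tested by PCoA and PERMANOVA
on Manhattan dissimilarities.

Every estimator is validated against independent theory: binomial
cascades with closed-form `h(q) = 1/q − log2(p^q + (1−p)^q)/q`, exact
Davies–Harte fractional Gaussian noise, brute-force enumeration
oracles, and planted-truth synthetic studies.

## Worked example

A deterministic binomial cascade (p = 0.6, N = 2^16) has known
multifractal scaling, so it makes an auditable first analysis:

```r
library(metabofract)

x <- gen_binomial_cascade(0.6, 16)
fit <- mfdfa(x, scale_max = 2^13)
fit
#> Multifractal DFA fit
#>   series length 65536, detrend order 2, 20 scales [16, 8192], 41 q values in [-5, 5]
#>   H = h(2) = 0.9510   delta_h = 0.2800   median R^2 = 0.9877
```

Theory gives h(2) = 0.9717 for this cascade; the estimate 0.9510 is
within the expected finite-size bias, and across the whole q-grid the
maximum |h(q) − theory| is ≈ 0.033. The singularity spectrum and the
surrogate diagnostics:

```r
singularity_spectrum(fit)
#> Singularity spectrum: alpha0 = 1.0186, delta_alpha = 0.4875, delta_f = 0.0295, B = -0.029

multifractality_source(x, n_replicates = 19, seed = 1, scale_max = 2^13)
#> Multifractality source attribution
#>   delta_alpha: original 0.4875 | shuffled 0.1950 (sd 0.0161) | surrogate 0.4552 (sd 0.0674)
#>   shuffle ratio = 0.400   surrogate ratio = 0.934   (19 replicates)
#>   verdict: correlation-dominated
```

Shuffling collapses the spectrum width (ratio 0.40) while the AAFT
surrogate preserves it (0.93): the multifractality comes from
long-range correlations, exactly as the cascade construction dictates.
Δα = 0.4875 sits below the theoretical infinite-order bound
log2(0.6/0.4) = 0.585, as it must at finite q.

Published two-group tables reporting mean ± SEM can be audited
directly:

```r
t_from_summary(21.74, 3.66, 12, 7.86, 2.75, 12)  # time with a novel object, s
#> pooled t from summary statistics: t = 3.032, df = 22, p = 0.006124 (means 21.74 vs 7.86)
```

A complete synthetic study — 24 animals in two groups with planted
behavioral and multifractal contrasts, through respirometry, MF-DFA,
integration, PCoA and PERMANOVA — runs from one config:

```r
cfg <- default_run_config(seed = 1)
man <- run_all(cfg)      # writes stage CSVs + manifest.json to cfg$out_dir
man$results$permanova
#> PERMANOVA (Monte-Carlo permutation): pseudo-F(1, 22) = 10.69, p = 1e-04
```

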