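---
title: "Quantifying the multifractal complexity of metabolic rate time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the multifractal complexity of metabolic rate time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabofract)
```

## The problem

Long oxygen-consumption (VO2) records from flow-through respirometry —
hours of data at 1-second resolution — show irregular, non-stationary
fluctuations: clusters of large excursions separated by stretches of
small ones. A single summary such as basal metabolic rate (BMR) ignores
this temporal structure. Multifractal detrended fluctuation analysis
(MF-DFA) characterizes it: it asks how the size of fluctuations scales
with the window over which they are observed, separately for small and
large fluctuations, and compresses the answer into a handful of
descriptors (the Hurst exponent *H*, the multifractality range Δh, the
singularity-spectrum width Δα, its asymmetry *B*, the dominant exponent
α₀ and the amplitude Δf). In chronically stressed animals these
descriptors shift — the spectrum narrows and the signal becomes more
persistent — so they are candidate physiological markers of allostatic
load.

This vignette documents the models, the numerical choices, and what the
synthetic-data validation does and does not establish.

## From raw channels to increments

The open-flow VO2 equation (CO2 scrubbed before the analyzer) is

$$\mathrm{VO}_2 = FR \times 60 \times \frac{F_IO_2 - F_EO_2}{1 - F_IO_2}
\quad [\mathrm{mL\,O_2\,h^{-1}}],$$

implemented in `compute_vo2()`. Units are fixed to mL O2 h⁻¹ by the
factor 60; CSV headers carry units so files are self-describing.

BMR is read as "the mean over a 10-minute steady-state window". Steady
state is not defined operationally in most protocols, so
`extract_bmr()` makes it auditable: among all contiguous windows of
`window_s` seconds whose rolling coefficient of variation is below
`cv_threshold` (default 0.05, i.e. 5% relative spread), it returns the
one with the lowest mean. If no window qualifies the global
minimum-mean window is used and the result is flagged `unstable`
rather than silently accepted.

The series analyzed for multifractality is not VO2 itself but its
log-ratio increments, `r(t) = log10(VO2(t+1)/VO2(t))`
(`log_ratio_increments()`), which removes the multiplicative trend and
yields a dimensionless, approximately stationary series. Nonpositive
VO2 samples are an error naming the offending indices: dropping them
silently would corrupt the timing structure the analysis depends on.

## MF-DFA

`mfdfa()` follows the canonical recipe:

1. **Profile.** \(y_i = \sum_{k \le i} (x_k - \bar x)\).
2. **Segmentation.** At each scale *s* the profile is cut into
   \(N_s = \lfloor N/s \rfloor\) non-overlapping segments from the
   start *and* \(N_s\) from the end (2\(N_s\) total). The two-sided
   convention is a deliberate choice: \(\lfloor N/s \rfloor\) discards
   a tail, and discarding it asymmetrically would weight the record's
   beginning.
3. **Detrending.** Each segment is detrended by a least-squares
   polynomial of order *m* ∈ {1, 2, 3} (default 2), and the variance
   \(\sigma^2(v, s)\) of the residuals retained. Order 2 removes both
   local level and slow curvature, which matters for drifting
   physiological baselines; the order is a configuration knob because
   no single choice is right for every record.
4. **Fluctuation function.**
   \(F_q(s) = \{\tfrac{1}{2N_s}\sum_v [\sigma^2(v,s)]^{q/2}\}^{1/q}\),
   with the logarithmic average
   \(F_0(s) = \exp(\tfrac12\langle\ln\sigma^2\rangle)\) at \(q = 0\)
   where the power mean is undefined — the standard continuity-
   preserving treatment.
5. **Scaling.** \(h(q)\) is the OLS slope of \(\ln F_q(s)\) on
   \(\ln s\); \(H = h(2)\); \(\Delta h = h(q_{\min}) - h(q_{\max})\);
   \(\tau(q) = q\,h(q) - 1\).

Negative moments diverge if any segment variance is exactly zero, so
that case is an error naming the segment; it arises only for degenerate
(locally polynomial) inputs.

**q-grid.** Default −5…5 in steps of 0.25. Beyond |q| ≈ 5 the moments
are dominated by a handful of extreme segments and estimates become
noise; the grid must include q = 2 so that *H* is defined.

**Scales.** Default: 20 log-spaced scales from 16 to N/4. The lower
bound keeps at least ~13 residual degrees of freedom per segment after
quadratic detrending; the upper bound is the common DFA convention.
For the *high-|q|* moments specifically, the largest scales are the
weak point: at \(s = N/4\) only 8 segments exist and a ±5-order moment
estimated from 8 variances is unstable. Where closed-form recovery is
being tested (and in the pipeline default) we therefore cap scales at
N/8, which keeps ≥ 16 segments at the largest scale. On the
deterministic cascade benchmark below this reduces the worst-case h(q)
error from ~0.07 to ~0.03.

**Singularity spectrum.** `singularity_spectrum()` computes
\(\alpha = d\tau/dq\) by central finite differences (one-sided at the
grid ends) and \(f(\alpha) = q\alpha - \tau\). Differentiating τ once
numerically was preferred over the analytic form
\(\alpha = h + q\,dh/dq\) because it involves a single numerical
derivative with a simpler error budget; the two agree on the benchmark.
Descriptors: α₀ (α at the peak), Δα (width), Δf = f(α_min) − f(α_max)
(positive when the strongest fluctuations are the more probable
extreme), and asymmetry
\(B = [(\alpha_{\max}-\alpha_0) - (\alpha_0-\alpha_{\min})]/\Delta\alpha\).
*B* has no universally agreed definition; this normalized left/right
width difference (positive = right-skewed) is this package's documented
convention. A non-concave τ (spectrum not single-peaked) and a peak
exceeding the support dimension 1 by more than 0.05 are *flags*, not
errors — they indicate estimation trouble the analyst should see, on
data that may still be worth inspecting. A spectrum width below 1e-8 is
treated as a point spectrum with *B* = 0.

## Validation against closed-form theory

The binomial multiplicative cascade (`gen_binomial_cascade()`) has
exactly known scaling,

$$h(q) = \frac{1}{q} - \frac{\log_2\!\left(p^q + (1-p)^q\right)}{q},$$

(`theory_h_binomial()`), with the q → ±∞ spectrum width bound
\(\Delta\alpha_\infty = \log_2\frac{\max(p, 1-p)}{\min(p, 1-p)}\).
For p = 0.6 and N = 2¹⁶ the package recovers h(q) across q ∈ [−5, 5]
with a maximum error of about 0.03 (tolerance asserted: 0.05), and the
estimated Δα ≈ 0.49 stays below the theoretical bound 0.585, as it
must at finite |q|. Monofractal controls bracket the other regime:
white noise gives H ≈ 0.5 with Δh ≲ 0.03, and fractional Gaussian
noise with H = 0.8 (`gen_fgn()`, exact Davies–Harte circulant
embedding) is recovered within 0.05.

```{r cascade, eval = FALSE}
x <- gen_binomial_cascade(0.6, 16)
fit <- mfdfa(x, scale_max = 2^13)
max(abs(fit$hq - theory_h_binomial(fit$q, 0.6)))  # ~0.033
singularity_spectrum(fit)$delta_alpha             # ~0.49 < 0.585
```

## Attributing multifractality: shuffle and AAFT

Apparent multifractality has two canonical sources: long-range
correlations between small and large fluctuations, and a heavy-tailed
value distribution. `multifractality_source()` separates them:

* **Shuffling** (`shuffle_series()`) destroys all temporal order while
  conserving the value multiset exactly. If Δα collapses after
  shuffling, correlations carried the multifractality.
* **AAFT surrogates** (`aaft_surrogate()`) conserve the value multiset
  exactly and the linear power spectrum approximately while destroying
  nonlinear structure, via the classic single-pass algorithm
  (gaussianize by rank → randomize Fourier phases, drawn
  conjugate-symmetric with the DC and, for even lengths, Nyquist bins
  left real → rank-remap the original amplitudes). If Δα survives the
  surrogate, the distribution (or linear correlations) carried it.
  The single-pass variant, not iterated IAAFT, is implemented because
  it is the procedure the ratio diagnostics are defined for.

The diagnostics are the width ratios Δα_shuff/Δα_orig and
Δα_surr/Δα_orig. Defaults: 19 replicates of each kind (the classic
one-sided 5% rank-test count), replicate-mean widths, a ratio < 0.6
counting as "collapsed" and a ratio in [0.8, 1.2] as "preserved".
Verdicts: collapsed shuffle + preserved surrogate =
`correlation-dominated`; the converse = `fat-tail-dominated`; both
preserved = `none` (nothing attributable, e.g. monofractal noise);
anything else = `mixed`. On the p = 0.6 cascade the shuffle ratio is
≈ 0.40 (correlations dominate, as construction dictates), and for a
linear Gaussian AR(1) process the original width falls inside the
19-surrogate range, i.e. AAFT preserves it within replicate noise.
Single realizations of length 2¹⁴ or shorter can fall outside that
range through finite-size apparent multifractality; the package's
validation uses 2¹⁵.

## Behavioral statistics

Recognition indices are `RI = t_target / (t_target + t_reference)`
with 0.5 the indifference point. Group comparisons use the pooled
(Student) unpaired t with df = n₁ + n₂ − 2 — chosen because published
two-group tables with n = 12 per group report df = 22 throughout, which
identifies the pooled rather than the Welch test; Welch is available as
an option. `t_from_summary()` recomputes t from printed mean ± SEM
(SD = SEM·√n), which is how published tables are audited;
`t_from_raw()` is the same test from raw data. p-values are two-sided
and the sign convention is group 1 minus group 2. Significance stars
are two-tier: `*` p < 0.05, `**` p < 0.01.

## Integrative ordination

`integrate_animals()` joins behavioral measures, physiology (BMR, body
mass) and per-animal multifractal descriptors by animal id, refusing
mismatched or duplicated ids. Because the variables are
incommensurable (seconds, counts, mL O2 h⁻¹, dimensionless exponents),
they are z-scored by default before Manhattan distances are computed;
unstandardized distances are available by flag. Manhattan rather than
Euclidean distance weights every variable's deviation linearly and is
the convention this analysis chain follows.

`pcoa()` performs classical scaling (Gower double-centering +
eigendecomposition). Manhattan matrices are generally non-Euclidean, so
negative eigenvalues can appear; the policy is to *report* them and to
exclude them from the variance-explained denominator — variance shares
then refer to the representable (positive) part, which is the honest
denominator for a 2-D ordination plot.

`permanova()` implements the one-factor permutation test from first
principles on the distance matrix: SS_total = Σd²/n over all pairs,
within-group SS analogously, pseudo-F from the usual mean squares, and
p by label permutation with the add-one convention
p = (1 + #{F* ≥ F}) / (1 + n_perm), 9999 permutations by default (a
resolution of 10⁻⁴, well below conventional thresholds). Two-group
designs with at most 10,000 distinct label arrangements are enumerated
completely instead, with p = #{F* ≥ F}/n_arrangements; the
Monte-Carlo path is validated against that enumeration, and the
pseudo-F against `vegan::adonis2` when vegan is available.

## The synthetic study and what it shows

`run_all()` drives the whole chain from one configuration (an R list or
a YAML/JSON file): per-animal respirometry traces, increments, BMR,
MF-DFA, optional surrogate attribution, a behavioral table, the joined
feature matrix, PCoA and PERMANOVA, with every output written as CSV
plus a JSON manifest (parameters, derived seeds, file checksums,
warnings, stage status). One global seed is expanded into per-stage and
per-animal child seeds by a fixed integer-folding scheme
(`(s·31 + idx + 1) mod (2³¹−1)` per index level), so stages are
individually reproducible and no stream is reused.

The generator defaults define the emulated study: two groups of 12
animals; 9 h of VO2 at 1 s (length 2¹⁵ in the pipeline default — the
closest power of two below 32,400 samples, which keeps dyadic scale
grids clean); baseline 250 mL O2 h⁻¹ with 5% slow sinusoidal drift (a
nuisance term, not a circadian model); log10 increments of SD 0.002 so
the trace wanders visibly but stays physiological; cascade increments
with multiplier 0.65 for controls versus 0.58 for the treatment group,
reproducing the reported direction of the contrast (wider spectrum,
stronger multifractality in controls) without targeting any printed
width; and behavioral group means/SEMs taken from the published
reference summary shipped with the package
(`behavior_reference_summary()`). Body mass is drawn N(180, 15) g with
no group difference, matching the reported absence of a mass effect.
Validation runs and tests use shorter series (2¹²–2¹³) and reduced
q-grids; these sizes are stated in the tests themselves.

What passing this synthetic validation shows: the estimators recover
known scaling laws, the surrogate logic attributes planted sources
correctly, and a planted group contrast of realistic magnitude is
detected end to end (PERMANOVA p ≤ 0.05 in ≥ 90% of seeded
replicates, with clear first-axis separation). What it does not show:
real respirometry traces have washout dynamics, analyzer drift,
activity artifacts and crossovers in their scaling that the generator
deliberately omits — the generator's drift is a smooth nuisance term
and its increments are exactly scale-free. Published descriptor values
from real recordings also depend on unstated analysis settings
(q-grid, scale range, detrend order), so they are reproducible from
raw data only approximately; the package therefore validates against
closed-form theory and planted truths, not against printed descriptor
tables.

## Known limitations

* h(q) estimates beyond |q| ≈ 5 are moment-starved at any realistic
  record length; widen the q-grid only with much longer series.
* The finite-difference α inherits the q-grid resolution; Δα is
  therefore a lower bound on the asymptotic width (the cascade
  benchmark shows Δα ≈ 0.49 against an ∞-order bound of 0.585).
* AAFT preserves the spectrum of the gaussianized series, not of the
  original; for strongly non-Gaussian signals the surrogate spectrum is
  biased slightly white — one reason surrogate ratios near 1 should be
  read as a band, not a point.
* The BMR window search assumes the steady state is the *lowest* stable
  plateau; torpid or hypometabolic episodes would require a different
  criterion.
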