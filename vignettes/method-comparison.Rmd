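---
title: "Method comparison statistics: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Method comparison statistics: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methodcompare)
```

## The problem

When a new measurement method is cheaper or faster than the established
reference, the question is never whether the two correlate — almost any
two methods measuring the same quantity do — but whether they *agree*:
is the new method interchangeable with the old one without changing
clinical interpretation? Correlation cannot see a constant offset, and
ordinary regression assumes the reference is error-free, which is false
for two imperfect instruments. This package implements the standard
repertoire that addresses both problems: Bland–Altman absolute-agreement
analysis, scaled agreement indices (ICC, CCC), and errors-in-variables
and rank-based regression, tied together by an explicit
assumption-checking and method-selection layer.

Throughout, `x` is the reference method and `y` the test method, one row
per subject, same physical units.

## Bland–Altman analysis

The differences $d_i = y_i - x_i$ are summarised by their mean $\bar d$
(the bias) and standard deviation $s_d$; the limits of agreement
$\bar d \pm z_{0.975}\, s_d$ are the interval expected to contain about
95% of future differences. The analysis is meaningful when the $d_i$ are
approximately normal and unrelated to the measurement level
$m_i = (x_i + y_i)/2$; both conditions are checked by `run_assumptions()`
and surfaced as caveats (or, with `strict = TRUE`, as errors).

Interval conventions, chosen to reproduce published tables computed with
the mainstream implementations:

* LoA use the normal quantile $z = 1.959964$ at level 0.95 (a pure-$t$
  variant is available via `loa_quantile = "t"`);
* the CI of the bias uses $t_{n-1}\, s_d/\sqrt n$;
* the CI of each limit uses the classical approximation
  $\mathrm{Var}(\mathrm{LoA}) \approx 3 s_d^2 / n$ with $t_{n-1}$.

With this combination, `bland_altman_from_summary()` — which rebuilds
$s_d$ from a printed LoA width as $\text{width}/(2 \times 1.959964)$ —
reproduces the printed confidence intervals of the bundled n = 975
fetal-weight cohort table to the published rounding, which is the check
`scripts/acceptance.R` automates. One printed row of that table has an
LoA midpoint of −83.575 against a printed mean of −83.57; this is
rounding noise and the consistency checks use a ±0.01 tolerance.

The sign convention is fixed: differences are test − reference, so a
negative bias means the test method under-reads on average. The
interpretation sentence renders the limits in the clinical direction
("may read up to … more and … less than the reference").

## ICC and CCC

`compute_icc()` implements the McGraw–Wong grid. The two-way mean
squares come from the closed-form decomposition (between-subjects MSR,
between-methods MSC, residual MSE, within-subjects MSW); e.g. the
single-measurement consistency ICC is $(MSR - MSE)/(MSR + (k-1)MSE)$ and
the absolute-agreement form adds $k(MSC - MSE)/n$ to the denominator.
Confidence intervals use the exact F construction for the one-way and
consistency forms and the Satterthwaite approximation for absolute
agreement; average-measurement absolute intervals step the single bounds
up with Spearman–Brown. Two-way random and two-way mixed share all
numbers and differ only in interpretation scope, which the result object
records. The significance test against ICC = 0 is $F = MSR/MSE$ (two-way)
or $MSR/MSW$ (one-way) with $(n-1, (n-1)(k-1))$ or $(n-1, n(k-1))$ df.
The default design is two-way mixed / consistency / single — methods
fixed, subjects random, one measurement per subject-method cell — which
is the usual method-comparison layout.

`compute_ccc()` uses Lin's original biased ($1/n$) moment estimators;
an `"n-1"` flag exists because software ecosystems split on this (the
two agree as $n$ grows). The factorisation
$\rho_c = \rho \cdot C_b$ with $C_b = 2/(v + 1/v + u^2)$,
$v = s_x/s_y$, $u = (\bar x - \bar y)/\sqrt{s_x s_y}$, holds to
machine precision and is asserted in the tests; $|\rho_c| \le |\rho|$
always, with equality exactly when means and variances match. The CI is
the inverse Fisher-z interval with Lin's asymptotic variance.

Interpretation scales are data, not code: Koo–Li for the ICC and McBride
for the CCC by default, with boundary values taking the higher label.
Published applications sometimes imply a bare 0.95 cutoff between "high"
and "excellent/almost perfect"; an `"mcs_paper"` scale with that single
threshold ships alongside the standard ones, because no published scale
reproduces those labels exactly.

## Regression estimators

**OLS/WOLS.** Closed-form least squares with $t_{n-2}$ intervals. The
weighted variant defaults to $w_i = 1/x_i^2$, the proportional-error
weighting standard in method comparison; arbitrary positive weights are
accepted.

**Deming.** The errors-in-variables objective is
$\sum_i \left[ (x_i - \hat X_i)^2 + \lambda (y_i - \hat Y_i)^2 \right]$
subject to $\hat Y_i = a + b \hat X_i$. The user-facing parameter is
$\lambda = \mathrm{Var}(\varepsilon_x)/\mathrm{Var}(\varepsilon_y)$:
rescaling the objective by $1/\lambda$ shows the two definitions
coincide, because the maximum-likelihood weights are inverse error
variances. This mapping is the classic source of silent Deming bugs, so
the closed-form slope
$b = \big[(\lambda s_{yy} - s_{xx}) + \sqrt{(\lambda s_{yy} - s_{xx})^2
+ 4\lambda s_{xy}^2}\,\big] / (2\lambda s_{xy})$
is validated in the test suite against a numerical minimiser of the
objective itself. Limiting behaviour under this convention: $\lambda \to 0$
recovers OLS of y on x (all error attributed to y); $\lambda \to \infty$
recovers the inverse regression $s_{yy}/s_{xy}$; $\lambda = 1$ is
orthogonal regression and is checked against a spectral total-least-squares
oracle. $\lambda$ defaults to 1, since without replicate measurements the
error variance ratio cannot be estimated from the data.

**Weighted Deming.** Linnet's iterative reweighting for proportional
error: weights $1/\hat X_i^2$ from the current fitted true values
$\hat X_i = x_i + \lambda b (y_i - a - b x_i)/(1 + \lambda b^2)$,
iterated until the slope moves by less than $10^{-10}$ (cap 100
iterations; non-convergence is an error, as is any nonpositive fitted
level, since the weighting presumes positive measurements).

Deming-family CIs default to the leave-one-out jackknife with a
$t_{n-2}$ quantile; the analytic option uses the normal-theory
approximation $SE(b) = \sqrt{b^2 (s_{xx} s_{yy}/s_{xy}^2 - 1)/(n-2)}$.

**Passing–Bablok.** All $N = \binom{n}{2}$ pairwise slopes with the
original 1983 conventions: pairs identical in both coordinates are
dropped; x-ties with different y contribute $\pm\infty$ slopes; slopes
exactly $-1$ are discarded; and the median rank is shifted by
$K = \#\{S_{ij} < -1\}$, which makes the estimator invariant to
exchanging the axes. For even $N$ the two middle (shifted) order
statistics are averaged. The distribution-free CI places the bounds at
ranks $M_1 + K$ and $M_2 + K$ with $M_1 = \mathrm{round}((N - C_\gamma)/2)$,
$M_2 = N - M_1 + 1$, $C_\gamma = z_{(1+\gamma)/2}\sqrt{n(n-1)(2n+5)/18}$
(rank indices clamped to $[1, N]$ in extreme cases). The intercept is
$\mathrm{median}(y_i - b x_i)$ with its CI evaluated at the slope CI
endpoints. Because the $-1$-discard and $K$-shift rules do not commute
with unequal axis rescalings, Passing–Bablok is only equivariant under
equal scalings plus shifts; OLS and Theil–Sen are fully
affine-equivariant, and Deming is once $\lambda$ is rescaled by
$(b/d)^2$ — all of which the property tests exercise.

**Passing–Bablok for large datasets.** Enumerating $N$ pairs is
quadratic in $n$; the large mode computes the same estimator on a seeded
uniform subsample of $m = \min(N, 10^6)$ pairs (pairs are drawn by
linear index and decoded arithmetically, so the full set is never
materialised). When $m = N$ the point estimate is identical to the exact
mode; the CI uses normal-approximation binomial rank bounds
($\pm z\sqrt{m}/2$ around the shifted median rank) instead of the exact
Kendall construction. The subsampling error contract is tested: at
$n = 200$ with a fifth of the pairs retained, the slope stays within
0.01 of the exact estimate across seeds.

**Theil–Sen.** Median of the finite pairwise slopes (x-tied pairs
skipped), intercept $\mathrm{median}(y_i - b x_i)$, and the same rank CI
without the $K$ offset. The intercept convention deliberately replaces
the "substitute the median-slope pair" rule sometimes quoted, which is
ill-defined when the median averages two slopes.

**Bias flags and method selection.** Systematic bias ⇔ the intercept CI
excludes 0; proportional bias ⇔ the slope CI excludes 1 (the standard
convention; some texts state the reverse pairing, which contradicts
their own worked examples). `select_method()` encodes the decision
table: homoscedastic and outlier-free → {OLS, Deming}; heteroscedastic →
{WOLS, weighted Deming}; outliers present → {Passing–Bablok, Theil–Sen},
because weighting does not defuse gross outliers; above 5000 subjects
the subsampling Passing–Bablok substitutes for the exact one.

## Assumption engine defaults

* Normality: Shapiro–Wilk up to its implementation limit of n = 5000,
  then Lilliefors-corrected Kolmogorov–Smirnov (parameters are estimated,
  so the plain KS null would be anti-conservative).
* Association: Pearson when both $d$ and $m$ pass normality at the same
  α, Spearman otherwise; forceable.
* Breusch–Pagan: studentized (Koenker) variant by default — the default
  of the standard R implementation it wraps — original variant behind a
  flag; LM statistic referred to χ²₁.
* Mahalanobis: classical mean/covariance by default, cutoff
  $\sqrt{\chi^2_{2,0.975}}$; MCD-robust estimation optional for masking
  resistance. All α and quantile choices are exposed as options and
  recorded in the report.

These defaults are package decisions where the surrounding literature
is silent; they are flagged as such here rather than presented as
universal.

## Synthetic data

`generate_paired()` draws true values $t_i$ (default log-normal with
median 3300 and σ_log = 0.15 — a realistic term birth-weight
distribution, CV ≈ 15%), then
$x_i = t_i + \varepsilon_x$, $y_i = a + b t_i + \varepsilon_y$ with
constant-SD or proportional-CV noise, and optionally displaces a fixed
fraction of rows upward by a multiple of SD(y). Contamination is
shift-based rather than variance-inflating because shifted points are
what Mahalanobis screening and the rank-estimator robustness claims are
about. Ground truth (true values, noise draws, outlier mask) is always
returned so tests never re-derive it, and a seed is mandatory — there is
no implicit global RNG state. `generate_biometry()` draws BPD/HC/AC/FL
from a one-factor latent-size model clamped inside the Hadlock
plausibility envelope; it is a demo input generator, not a reproduction
of any cohort's joint distribution.

What passing simulation tests show — and what they do not: the generator
produces linear relationships with Gaussian noise and clean shift
outliers. Real clinical data add curvature, level-dependent skewness,
digit preference and correlated repeat measurements, none of which are
emulated; results on the synthetic suite certify the estimators'
numerics, not their behaviour under every real-data pathology.

## Problem sizes and numerical choices

The simulation studies run at sizes chosen to make Monte-Carlo error
small relative to the bands being checked: Passing–Bablok parameter
recovery uses 500 replicates of n = 200 (slope mean within ±0.01 of the
true 1.05; CI coverage in [92%, 98%]); the Breusch–Pagan null size uses
2000 replicates of n = 100 (empirical rate in [3.5%, 6.5%] at α = 0.05);
oracle-equivalence checks enumerate all pairwise slopes at n ≤ 30 where
brute force is exact. Weighted-Deming convergence tolerance is
$10^{-10}$ on the slope. JSON report serialisation uses 17 significant
digits so every double survives a write/read round trip bit-exactly.

## The Hadlock worked application

The five formulas are stored as frozen coefficient tables with their
source polynomial strings kept alongside for audit — transcription being
the only realistic failure mode for a pure polynomial. Units are fixed
(cm in, grams out). Within the plausibility envelope every formula is
strictly increasing in abdominal circumference (the dominant
coefficient), which the tests verify on a 0.5 cm grid; outside the
envelope the package warns and this monotonicity is not asserted. The
published n = 975 cohort summary tables (Bland–Altman, ICC/CCC,
Passing–Bablok/Theil–Sen coefficients) ship as plain-text data for
internal-consistency checking; the underlying raw cohort is not publicly
deposited, so those tables are inputs, not reproduction targets.

## Known limitations

* No repeated-measures Bland–Altman and no regression-based LoA for
  proportional bias; the caveat system points users at the rank
  regressions instead.
* No Bablok cusum linearity test; Kendall's τ ≤ 0 only triggers a
  warning.
* Deming λ must be supplied (default 1); the package does not estimate
  it from replicates.
* The large-dataset Passing–Bablok CI is a binomial approximation on the
  subsample, not the exact rank interval.
* Report export writes JSON and per-section CSV; xlsx export is not
  available in this build (xlsx *input* is supported).
* Interpretation labels are convention-dependent; both standard scales
  and the single-0.95-cutoff scale are provided, and the scale used is
  recorded in the result.
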