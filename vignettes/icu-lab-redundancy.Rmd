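---
title: "Quantifying redundancy in ICU laboratory tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying redundancy in ICU laboratory tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icuinfo)
```

## The question and the measures

A lab test that can be predicted — from the same patient's value yesterday,
or from a coupled test drawn the same morning — carries little *novel*
information, and repeating it buys little. `icuinfo` makes that statement
quantitative. For a discretized lab value $X$ the expected total
information is the entropy

$$H(X) = -\sum_i P(x_i)\,\log_2 P(x_i) \quad \text{(bits)},$$

the expected information shared with a second value $Y$ is the mutual
information

$$I(X;Y) = \sum_j \sum_i P(x_i, y_j)\,
  \log_2\!\frac{P(x_i, y_j)}{P(x_i)\,P(y_j)},$$

and the expected novel information left in $X$ once $Y$ is known is the
conditional entropy $H(X\mid Y) = H(X) - I(X;Y)$. All logarithms are base
2 and every result is labelled in bits; the $0\log_2 0 = 0$ convention is
applied by summing over occupied cells only.

Two designs use these measures. *Day-over-day*: $X$ is a variable on ICU
day $d+1$ and $Y$ the same variable, same patient, on day $d$, for the day
pairs (1,2) and (2,3); $H(X\mid Y)$ is then the novel information a repeat
test delivers. *Same-day pairs*: $X$ and $Y$ are two variables measured on
the same day, by default creatinine–BUN, bicarbonate–lactate,
sodium–chloride, and platelet–WBC. In both designs pairs are formed within
patient and pooled across the whole cohort into one joint distribution; a
per-patient joint is not estimable from one daily median per patient.

## Preprocessing

Raw measurements (typically 1–4 per patient-day) are collapsed to the
per-patient daily median. Per variable, daily values below the 1st or above
the 99th percentile are discarded as outliers; the surviving values are
discretized into 20 equal-width bins spanning their pooled minimum to
maximum, so the maximum achievable entropy is $\log_2 20 = 4.32$ bits.
Numerical conventions, each of which matters at the margins:

- **Quantile definition.** Percentiles use linear interpolation
  (`stats::quantile()` type 7). On small samples the 1st percentile depends
  noticeably on this choice, so it is fixed and documented.
- **Strict inequalities.** A value exactly equal to a percentile cutoff is
  retained; only values strictly below/above are discarded. A variable with
  fewer than two distinct values skips the filter with a warning.
- **Pooled edges.** Percentiles and bin edges are fit per variable pooled
  across days (not per day), so a bin index means the same thing on every
  day and day-wise entropies are directly comparable. `pooling = "per_day"`
  in `run_config()` flips this for sensitivity analysis.
- **Half-open bins.** `bin = floor((v - lower)/width)` with the final bin
  closed, so the maximum retained value lands in bin 19 rather than a
  phantom bin 20.
- **Paired-subset marginals.** For a decomposition, $H(X)$ and $H(Y)$ are
  computed from the joint's own margins — i.e. on the patients contributing
  to the pair — which makes $0 \le I \le \min(H_X, H_Y)$ and
  $H(X\mid Y) \ge 0$ hold exactly. The entropy over *all* patients with $X$
  available is reported alongside as `h_x_all_bits`, because the two
  denominators genuinely differ under attrition and neither is canonically
  "the" total; results tables carry both plus all counts.

The estimator is the plug-in (maximum-likelihood) one: empirical
frequencies substituted into the formulas, with no bias correction by
default. Its mutual-information bias is positive, approximately
$(B_x-1)(B_y-1)/(2N\ln 2)$ bits for $B_x \times B_y$ tables on $N$ pairs —
about 0.08 bits at $N \approx 3{,}300$ pairs and 20 bins, which is small
against the signals of interest here but not zero; the permutation-null
check below measures it directly. An optional Miller–Madow correction
(`correction = "miller_madow"`) adds $(m-1)/(2N\ln 2)$ to each entropy
($m$ = occupied cells) and recomputes $I = H_X + H_Y - H_{XY}$, clamped
into $[0, \min(H_X, H_Y)]$ so the decomposition identities survive.

## The synthetic cohort generator

Real ICU lab databases are access-controlled, so the package generates
cohorts with the statistical structure the analysis assumes:

- **Gaussian copula.** Each patient-day has a latent standard-normal vector
  with a configurable cross-correlation matrix; marginals are normal or
  log-normal (log-normal for the right-skewed tests: platelet, WBC,
  glucose, BUN, creatinine, lactate). Log-normal parameters are
  moment-inverted (`lognormal_params()`) from target natural-unit means and
  SDs typical of a large adult ICU cohort, e.g. sodium 138.6 [4.4] mEq/L
  and creatinine 1.4 [1.5] mg/dL on day 1.
- **AR(1) persistence.** Day $d$'s latent vector is
  $\rho_v z_{d-1} + \sqrt{1-\rho_v^2}\,\varepsilon_d$ per variable, with
  innovations re-coupled through the same cross-correlation. Defaults make
  creatinine (0.95), BUN and platelet (0.93) the most persistent variables
  and glucose (0.45) the least — the ordering the redundancy analysis
  should recover.
- **Coupling defaults.** Creatinine–BUN 0.80 and sodium–chloride 0.75
  (strong), bicarbonate–lactate −0.40 (moderate, negative: lactate consumes
  buffer), WBC–platelet 0.15 (weak). The default pairs occupy disjoint
  2×2 blocks, so the matrix is positive semi-definite by construction; any
  user-supplied matrix is eigenvalue-checked.
- **Attrition and missingness.** Patients drop out between days with
  monotone (discharge-like) dropout to 68% of the day-1 cohort on day 2 and
  46% on day 3; once gone they emit nothing. Each patient-day-variable is
  independently unmeasured with a per-variable missing rate — 0.59 for
  lactate (much the least frequently ordered test), 0.01 elsewhere.
- **Raw measurements.** Each retained patient-day-variable emits
  Uniform{1..4} raw values: the daily latent value plus Gaussian noise.
  Because additive noise could push a log-normal variable's tail below
  zero, noisy draws are floored at 1% of the latent value; default noise
  SDs are small fractions of each variable's spread, since only the daily
  median feeds the analysis. No within-day timestamps are generated — the
  analysis never uses them.

All defaults are tuned emulation targets, not measured constants. The
generator reproduces marginal shape, cross-sectional coupling, temporal
persistence, attrition, and missingness; it does **not** model treatment
effects, diurnal structure, clinician ordering behaviour, re-admission, or
outcome-dependent testing. Passing tests therefore demonstrate that the
pipeline measures the information structure it is pointed at — not that any
particular real ICU exhibits that structure.

## Design choices where the design was open

- Pairing excludes patients missing either member of a pair; patients with
  a single day still count in the all-available entropies. With monotone
  attrition this makes day-(1,2) pair counts at least day-(2,3) counts, a
  property the tests assert.
- In a day pair, $X$ is the *later* day, so `h_x_given_y_bits` is directly
  "novel information in day $d+1$ given day $d$".
- Determinism is a contract: one seed drives the whole generator through a
  fixed draw order, and the same (config, seed) yields a byte-identical
  CSV. The command-line `run` subcommand inherits this end-to-end.
- Degenerate inputs fail loudly and early: non-PSD correlation matrices are
  rejected naming the smallest eigenvalue, a variable with a single
  distinct value cannot be binned, fewer than two paired patients abort the
  comparison (skipped with a warning inside `run_full_analysis()`), and a
  value outside its fitted bin range signals that filtering and binning
  were fit on different data.

## Verification strategy and problem sizes

The test suite checks the estimators against hand-computed values (the
4.32-bit uniform, the 0.4690-bit biased coin, a 0.2781-bit 2×2 joint), an
independently coded brute-force oracle on 1000 random tables up to 20×20
(agreement within $10^{-12}$ bits), and the bivariate-Gaussian closed form
$-\tfrac12 \log_2(1-\rho^2)$ at $n = 10^5$ pairs, where the binned plug-in
estimate must land within 0.1 bits for $\rho \in \{0.3, 0.6, 0.9\}$ (at
$\rho = 0.9$ quantization loss dominates and the estimate sits just below
the closed form). Pipeline-level properties — permutation of patient
identity collapsing MI to the bias level, recovery of the configured
coupling and persistence orderings, chain identities, conservation of
counts — run on a 5000-patient, 3-day default cohort under a fixed seed;
5000 patients keeps Monte-Carlo error on pair MIs near 0.01 bits while the
whole suite runs in well under a minute. `scripts/acceptance.R` recomputes
the same quantities from scratch at an arbitrary seed.

## Limitations

Plug-in MI is biased upward at small pair counts; comparisons with very few
pairs (e.g. lactate on day 3) should be read against the
$(B_x-1)(B_y-1)/(2N\ln 2)$ yardstick or rerun with the Miller–Madow flag.
Only pairwise redundancy is measured — three-way and higher interactions
are out of scope. Equal-width binning concentrates skewed variables in few
bins, deflating their entropies relative to a quantile binning; that is a
deliberate, interpretable choice (bins are fixed spans of the measurement
scale) but not a neutral one. And redundancy in information content is not
clinical uselessness: a predictable test can still matter for an individual
patient.
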