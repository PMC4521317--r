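# icuinfo

Information-theoretic redundancy analysis of longitudinal ICU laboratory
tests.

Intensive-care patients are tested heavily: daily panels of hematocrit,
platelet count, WBC, glucose, bicarbonate, potassium, sodium, chloride, BUN,
creatinine, and lactate. Much of what those repeated tests report is
predictable — from the same patient's value the day before, or from a
physiologically coupled test drawn the same day. `icuinfo` quantifies that
predictability in bits, for clinical-informatics researchers and anyone
studying rational test-ordering policy.

## The model

Daily lab values are reduced to per-patient daily medians, trimmed at the
1st/99th percentiles, and discretized into 20 equal-width bins per variable.
On the binned values the package computes plug-in estimates of

- **entropy** — the expected total information in a test X on a given ICU
  day: `H(X) = -Σᵢ P(xᵢ) log₂ P(xᵢ)`, at most `log₂ 20 = 4.32` bits;
- **mutual information** — the expected redundant information shared by X
  and Y: `I(X;Y) = ΣⱼΣᵢ P(xᵢ,yⱼ) log₂[P(xᵢ,yⱼ) / (P(xᵢ)P(yⱼ))]`;
- **conditional entropy** — the expected novel information left in X once Y
  is known: `H(X|Y) = H(X) − I(X;Y)`.

Pairs (X, Y) are formed *within patient* — the same variable on consecutive
ICU days, or two variables on the same day — and pooled across the cohort
into a single joint distribution. Because real ICU lab databases are
access-controlled, the package ships a Gaussian-copula cohort generator
(skewed marginals, AR(1) day-to-day persistence, cross-variable coupling,
monotone attrition) so the entire pipeline runs with known ground truth.

## Worked example

```r
library(icuinfo)

sim <- default_icu_specs(n_patients = 2000, seed = 42)
obs <- simulate_cohort(sim$specs, sim$config)   # 110,260 raw measurements
fit <- run_full_analysis(obs)
fit
#> <icu_redundancy>
#>   67 comparisons (33 daily entropies, 22 day pairs, 12 variable pairs)
#>   20 bins per variable; max achievable entropy 4.32 bits

res <- tidy(fit)
res[res$comparison_type == "variable_pair" & res$day_x == 1,
    c("comparison_label", "h_x_bits", "h_y_bits", "mi_bits",
      "h_x_given_y_bits", "n_pairs")]
#>   comparison_label       h_x_bits h_y_bits mi_bits h_x_given_y_bits n_pairs
#> 1 creatinine-bun: day 1      3.17     3.46   0.654             2.52    1893
#> 2 hco3-lactate: day 1        4.06     3.48   0.364             3.70     752
#> 3 platelet-wbc: day 1        3.74     3.52   0.140             3.60    1882
#> 4 sodium-chloride: day 1     4.03     3.98   0.633             3.40    1886
```

Creatinine carries 3.17 bits of information on day 1, of which 0.654 bits
are redundant with the same patient's BUN — knowing BUN leaves only 2.52
bits of novel information in creatinine. The renal (creatinine–BUN) and
resuscitation-fluid (sodium–chloride) pairs are far more redundant than the
deliberately weakly coupled platelet–WBC pair (0.140 bits). Day-over-day,
persistent variables are mostly redundant with yesterday's value:

```r
res[res$comparison_type == "day_pair" &
      res$variable_x %in% c("creatinine", "glucose"),
    c("comparison_label", "h_x_bits", "mi_bits", "h_x_given_y_bits", "n_pairs")]
#>   comparison_label          h_x_bits mi_bits h_x_given_y_bits n_pairs
#> 1 creatinine: day 2 | day 1     3.15   1.37              1.78    1306
#> 2 creatinine: day 3 | day 2     3.16   1.40              1.76     859
#> 3 glucose: day 2 | day 1        3.91   0.353             3.55    1309
#> 4 glucose: day 3 | day 2        3.89   0.389             3.50     856
```

`autoplot(fit)` draws the stacked total/novel bars per variable and day;
`autoplot(fit, type = "pairs")` the asymmetric pair figure;
`render_report(fit, "report/")` writes the tidy CSV, both figures, and a
text summary. The same chain is scriptable from a shell:

```sh
exec/icuinfo run --output-dir report/ --seed 7 --n-patients 2000
```

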