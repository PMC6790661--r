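# psarank

Rank probabilities for the economic evaluation of multiple technology
appraisals.

## The problem

A probabilistic sensitivity analysis (PSA) runs a health-economic decision
model thousands of times under parameter uncertainty, producing paired cost
and QALY draws for each of J mutually exclusive options. At a
willingness-to-pay threshold λ the outcome of option j collapses to its net
monetary benefit, NB<sub>j</sub> = λQ<sub>j</sub> − C<sub>j</sub>, and the
conventional display of uncertainty is the cost-effectiveness acceptability
curve (CEAC): the probability that an option has the greatest net benefit,
as a function of λ.

With more than two options the CEAC shows only the probability of ranking
*first*. psarank computes the whole rank distribution and the presentation
suite built on it, for analysts who must explain PSA results to decision
makers:

* the **rank-probability matrix** P<sub>jr</sub> — the probability option j
  takes rank r by net benefit (rank 1 = best; column 1 is the CEAC) — and
  its **cumulative** version, drawn as rankograms and cumulative rankograms;
* **SUCRA** (the surface under the cumulative ranking,
  Σ<sub>r≤J−1</sub> P<sup>cum</sup><sub>jr</sub>/(J−1)), **mean rank**
  (Σ r·P<sub>jr</sub>) and **median rank with IQR** — descriptive summaries
  of each option's rank distribution;
* pairwise **first-order stochastic dominance** (FSD): option a dominates b
  when a's probability of being ranked r-th or better is at least b's at
  every r — a risk-attitude-free partial order over options;
* **CEAC/CEAF curves** over a λ grid (the acceptability frontier reports the
  CEAC value of the option with the greatest *mean* net benefit, which can
  lie below other options' CEACs);
* the mean-outcome **efficiency frontier** with strict and extended
  dominance, ICERs, and the λ interval on which each frontier option
  maximizes mean net benefit.

A Gaussian-copula **synthetic PSA generator** (`generate_psa()`) with
packaged scenarios makes every statistic testable end to end, including the
classic paradox in which an option *dominated on mean outcomes* still has
the highest probability of greatest net benefit (`paradox_scenario()`).

## Worked example

```r
library(psarank)
psa <- generate_psa(casestudy_scenario())   # stylized 7-option appraisal, n = 10,000
fit <- rank_analysis(psa, lambda = 20000)
fit
```

```
Rank analysis of net benefit at lambda = £20,000/QALY  (10000 simulations)

  (row 'P(rank 1)' is the CEAC at this threshold)
                        D       C       F       A       G       E       B
P(rank 1)             62%      6%     31%      0%      1%      0%      0%
P(rank 2)             34%     52%      8%      4%      2%      0%      0%
...
P(rank <= 4)         100%    100%     71%     93%     32%      5%      0%
...
SUCRA                 93%     76%     62%     58%     37%     21%      3%
Rank of mean NB         1       2       4       3       5       6       7
Mean rank             1.4     2.4     3.3     3.5     4.8     5.8     6.8
Median rank (IQR) 1 (1-2) 2 (2-3) 4 (1-5) 4 (3-4) 5 (4-5) 6 (5-6) 7 (7-7)

FSD (covering relation): C > A, E > B, D > C, A > E, F > E, G > E, D > F, C > G
Frontier: B -> D
```

Reading it: D is the clear winner — greatest mean net benefit, highest CEAC
(62%), and FSD-dominant over C and (transitively) everything except F's
crossing curve. F is the interesting column: it is **dominated** on mean
outcomes (see below) yet has a 31% probability of greatest net benefit —
and a wide IQR (1–5), i.e. a high chance of being best *and* a high chance
of ranking near the bottom. A CEAC alone would have shown F's 31% and hidden
the downside entirely.

```r
ce_frontier(psa)
```

```
 option mean_cost mean_qaly      status icer lambda_low lambda_high
      A  1100.370   2.80032   dominated   NA         NA          NA
      B     0.000   2.49995 on_frontier   NA      0.000    1711.964
      C   898.089   2.83021   dominated   NA         NA          NA
      D   599.589   2.85019 on_frontier 1712   1711.964         Inf
      E  1299.450   2.64994   dominated   NA         NA          NA
      F  1499.250   2.81972   dominated   NA         NA          NA
      G  2498.420   2.77930   dominated   NA         NA          NA
Frontier (by increasing mean QALYs): B -> D
```

`plot(fit, style = "cumulative")` draws the cumulative rankograms,
`ceac(psa)` / `plot(ceac(psa))` the acceptability curves with the frontier
overlay, and `rank_table(fit)` returns the full-precision table for export.

## Command line

A thin wrapper over the same functions (also installed at
`system.file("cli", "psarank", package = "psarank")`):

```sh
Rscript inst/cli/psarank simulate --config scenario.yaml --out psa.csv
Rscript inst/cli/psarank analyze  --psa psa.csv --lambda 20000 --out-dir out/
Rscript inst/cli/psarank curves   --psa psa.csv --lambda-max 100000 --out-dir out/
Rscript inst/cli/psarank rankogram --psa psa.csv --lambda 20000 --style cumulative --out-dir out/
```

Every figure has a CSV twin; exit codes are 0 (success), 2 (usage error),
3 (invalid data). PSA files are wide CSVs with paired `cost_<label>` /
`qaly_<label>` columns, one row per simulation.

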