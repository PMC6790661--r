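---
title: "Rank probabilities for multi-option cost-effectiveness analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank probabilities for multi-option cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psarank)
```

## The problem

A probabilistic sensitivity analysis (PSA) propagates parameter uncertainty
through a health-economic decision model by Monte Carlo simulation, yielding
paired cost and QALY draws for each of $J$ mutually exclusive options. At a
willingness-to-pay threshold $\lambda$ (currency per QALY) the bivariate
outcome collapses to the scalar net monetary benefit

$$NB_j = \lambda Q_j - C_j.$$

With only two options, the cost-effectiveness acceptability curve (CEAC) —
the probability that an option has the greatest net benefit, as a function of
$\lambda$ — summarises the decision uncertainty adequately. With several
options it reports only the probability of ranking *first* and hides the rest
of each option's rank distribution: an option can have a high chance of being
best *and* a high chance of being nearly worst, and two options with similar
CEAC values can have completely different downside risk. psarank computes the
full matrix of net-benefit rank probabilities and the presentation devices
built on it, so that a multiple technology appraisal can show decision makers
the whole picture.

## Statistics computed

Let $P_{jr}$ be the probability that option $j$ takes rank $r$ by net benefit
(rank 1 = greatest). Within each simulation the options are ranked by
descending net benefit; $P_{jr}$ is the fraction of simulations in which $j$
got rank $r$ (`rank_matrix()`). From it:

* **Cumulative rank probabilities** $P^{cum}_{jr} = \sum_{s \le r} P_{js}$
  (`cumulative()`), drawn as cumulative rankograms (`plot(fit,
  style = "cumulative")`).
* **SUCRA** $= \sum_{r=1}^{J-1} P^{cum}_{jr} / (J-1)$, the surface under the
  cumulative ranking: 1 for an option that always ranks first, 0 for one that
  always ranks last. The algebraic identity SUCRA
  $= (J - \bar r_j)/(J-1)$, with $\bar r_j = \sum_r r\,P_{jr}$ the mean rank,
  is enforced by a property test. SUCRA and the other unweighted rank
  aggregates (mean rank, median rank) are reported as *descriptive* measures
  only: an unweighted average over rank places carries no utility-theoretic
  weighting of those places and cannot by itself justify preferring one
  option to another.
* **Median rank and IQR**: for $q \in \{0.25, 0.5, 0.75\}$ the smallest rank
  $r$ with $P^{cum}_{jr} \ge q$ (`median_iqr()`), the standard lower quantile
  of a discrete distribution.
* **First-order stochastic dominance** (`fsd()`): option $a$ dominates $b$
  when $P^{cum}_{ar} \ge P^{cum}_{br}$ at every rank $r$, strictly somewhere.
  FSD ranks options without any assumption on the decision maker's risk
  attitude, but only partially — crossing cumulative curves are incomparable,
  which is itself informative.
* **CEAC and CEAF** (`ceac()`, `ceaf()`): the CEAC of $j$ at $\lambda$ is
  $P_{j1}$; the cost-effectiveness acceptability frontier reports, at each
  $\lambda$, the CEAC value of the option with the greatest *mean* net
  benefit. The two can disagree (below).
* **Efficiency frontier** (`ce_frontier()`): on mean outcomes, strictly
  dominated options (another option no costlier and no less effective, with
  one strict inequality) are removed, then extended dominance is applied by
  repeatedly deleting any option whose ICER against its frontier predecessor
  is not below its successor's ICER against it, until the ICER sequence is
  strictly increasing. This is the lower-left convex hull of the
  cost-effectiveness plane, implemented iteratively because the audit trail
  (who was removed, and why) is part of the output. Each frontier option
  receives the half-open $\lambda$ interval $[\lambda_{low}, \lambda_{high})$
  on which it maximizes mean net benefit; the breakpoints are exactly the
  frontier ICERs, and a threshold equal to an ICER is assigned to the more
  effective option.

`rank_analysis(psa, lambda)` computes all of the above and prints a single
rank table (probability block, cumulative block, SUCRA, rank of mean net
benefit, mean rank, median and IQR), ordered by ascending mean rank with the
best option first. Binomial Monte Carlo standard errors
$\sqrt{p(1-p)/n_{sims}}$ accompany every rank probability (`rank_prob_se()`)
so users can judge how many simulations their table is worth; this is an
extension beyond the usual presentation.

## The mean-NB / CEAC paradox

An option with the greatest mean net benefit need not be the most probable
winner, and a *dominated* option can top the CEAC. The mechanism requires
correlation between options and unequal net-benefit variances: when two
similar options are strongly positively correlated and close in mean net
benefit, they split the probability mass of "one of us wins" between them,
while a third, high-variance option — even one strictly dominated on means —
takes a plurality of simulations. `paradox_scenario()` packages a
three-option instance of this construction: X (cost 1200, QALYs
$\mathcal N(0.295, 0.15^2)$) is strictly dominated by Y (cost 1000, QALYs
$\mathcal N(0.300, 0.015^2)$); Z (cost 900, QALYs
$\mathcal N(0.294, 0.015^2)$) is Y's correlated shadow (Spearman 0.8 between
their QALYs). At $\lambda = 20{,}000$ the rank-1 probabilities are roughly
0.45 (X), 0.30 (Y), 0.25 (Z), while the frontier classifies X as dominated —
and X also carries the largest probability of ranking last, the signature of
a "promising but risky" option. The CEAF makes the disagreement visible: at
that threshold it reports Y's CEAC value, which lies well below the maximum
CEAC.

## The synthetic generator

Real PSA output comes from a decision model we do not reimplement
(cohort machinery, discounting and half-cycle correction are out of scope —
inputs to this package are already per-simulation totals). `generate_psa()`
instead draws from a Gaussian copula over all $2J$ cost/QALY dimensions:

1. latent multivariate normal draws with correlation
   $\rho = 2\sin(\pi\rho_S/6)$, the exact normal-score conversion from the
   scenario's target Spearman correlations $\rho_S$ (the latent matrix is
   eigendecomposed, with tiny negative eigenvalues from the conversion
   clamped to zero, so positive-semi-definite targets are handled);
2. probability-integral transform to uniforms;
3. moment-matched marginal quantile functions per dimension (normal,
   lognormal, gamma or beta, parameterised by mean and standard deviation —
   the parameterisation health economists actually elicit; a standard
   deviation of zero yields a degenerate constant, e.g. a zero-cost
   conservative-care arm).

Scenarios are deterministic in (configuration, seed): the generator seeds
the Mersenne-Twister with inversion sampling for normals and restores the
caller's RNG state afterwards, so identical configurations are bit-identical
across runs and platforms on the same R series, and the seed is echoed into
the output's provenance metadata.

What the copula emulates is the *joint distribution* of model outputs:
means, spreads, skewness (via the marginal families) and monotone
dependence. What it does not emulate is everything structural in a real
model — multimodality from discrete events, exact functional dependencies
between arms that share parameters, heavy tails beyond the chosen families.
Passing tests on generated data therefore validate the *statistics*, not any
particular clinical model.

`casestudy_scenario()` is a stylized seven-option appraisal shaped like a
varicose-veins multiple technology appraisal: a reference interventional
comparator (A), conservative care with no initial cost and the lowest QALYs
(B), a cheap and effective frontier winner (D), a high-variance dominated
"promising" therapy (F, QALY sd 0.15 against 0.04–0.06 elsewhere), and
further dominated competitors (C, E, G), with Spearman 0.8 between the QALYs
of the similar interventional options A, C, D. Its construction guarantees,
at the default 10,000 simulations, a two-option frontier anchored at the
zero-cost option, a dominated option with rank-1 probability above 0.2, and
at least one FSD-incomparable pair. The means and spreads were chosen once,
at design time, to sit many Monte Carlo standard errors away from every
classification boundary; they are plausible magnitudes for a surgical
intervention appraisal (costs in the hundreds to low thousands, QALYs near
2.5–2.9 per person over the model horizon), not a reproduction of any
published model's inputs.

## Numerical choices

* **Tie handling.** Tied net benefits get the minimum (competition) rank,
  the semantics of spreadsheet `RANK()` — relevant only for degenerate
  inputs, since ties have probability zero for continuous models. Under this
  rule a tie shares rank 1, so CEAC values can sum to slightly more than one;
  `ties = "random"` breaks ties uniformly instead, preserving double
  stochasticity in expectation. Competition ranking is the default because
  it is reproducible without a seed.
* **Quantile convention at rounding boundaries.** The smallest-rank-with-
  $P^{cum} \ge q$ rule is exact for full-precision matrices. Applied to a
  published table rounded to whole percent, a cumulative entry printed
  exactly at a quartile (e.g. 25%) cannot reveal which side of the boundary
  the unrounded value sat on; one such cell exists in the shipped case-study
  table and is documented where it is tested.
* **Row renormalization.** `cumulative()` and `mean_rank()` renormalize each
  probability row by its sum before use. For matrices produced by
  `rank_matrix()` this is a no-op; for whole-percent published rows (which
  can sum to 99–101%) it prevents the rounding error from leaking into the
  running sums, and the final cumulative column is pinned to exactly 1.
* **Constructor tolerances.** `rank_prob_matrix()` / `cum_rank_matrix()`
  validate with `tol = 1e-6` by default; the shipped case-study table is
  loaded with `tol = 0.02` to admit whole-percent rounding. Internal
  invariants (row sums, double stochasticity) are tested at `1e-12`.
* **Frontier ties.** Equal-QALY options keep only the cheapest; exactly
  coincident points are resolved by input order with a warning; mean-NB ties
  in `max_mean_nb()` break by lowest mean cost, then input order. Extended
  dominance removes on "ICER $\ge$ successor ICER", so collinear points
  count as extendedly dominated and the surviving ICER sequence is strictly
  increasing.
* **Default threshold grid.** `ceac()` uses 0 to 100,000 in steps of 500 —
  fine enough to localise frontier switches in the few-thousands range and
  CEAC crossovers in the tens of thousands — and is fully configurable.

## Verification design

Every statistic is checked against an independent oracle rather than against
itself: ranking against a per-simulation sort-and-tally loop; the frontier
against exact enumeration of all pairwise net-benefit breakpoints (an option
is on the frontier iff it uniquely maximizes mean net benefit on some open
threshold interval); the CEAC against the closed-form normal probability
$\Phi\!\left((\lambda\mu_d - \mu_c)/\mathrm{sd}(\lambda d - c)\right)$ for a
two-option jointly Gaussian scenario, within three binomial standard errors
at $10^6$ simulations; FSD against its partial-order axioms and its
monotonicity with SUCRA and mean rank; and the shipped seven-option table's
summary rows against recomputation from its probability blocks. Routine
property tests run at small sizes (up to $J = 7$, 500 simulations); the
targeted stochastic checks use $10^5$ draws for the paradox construction and
$10^6$ for the Gaussian closed form, sizes at which the assertions sit many
standard errors from their thresholds while the whole suite stays fast.

## Limitations

* Inputs are per-simulation totals; the package neither builds nor runs
  decision models, and performs no discounting or evidence synthesis.
* Rank statistics are computed per threshold; the FSD relation and rank
  table can change with $\lambda$, and the package makes no attempt to
  summarise across thresholds beyond the CEAC/CEAF curves.
* Only the mean-outcome frontier is computed, not per-draw probabilistic
  frontiers.
* The rank aggregates (SUCRA, mean/median rank) are descriptive; none is a
  decision rule, and the package deliberately provides no weighted rank
  score for preference-based choice.
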