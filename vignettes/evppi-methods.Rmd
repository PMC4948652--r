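---
title: "Single-step EVPPI estimation: models, approximations, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step EVPPI estimation: models, approximations, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voitools)
```

## The decision problem

`voitools` computes the expected value of perfect information (EVPI) and of
partial perfect information (EVPPI) for a cost-effectiveness model of fluid
resuscitation in children hospitalised with severe malaria.  Four strategies
are compared — no fluid (reference), albumin, saline, and gelofusine — on
incremental net monetary benefit.  For treatment $j$ with log-odds-ratio of
death $d_j$, the per-patient incremental net benefit is

$$
B_j(\theta) = \bigl(\operatorname{expit}(\alpha) -
\operatorname{expit}(\alpha + d_j)\bigr)
\Bigl(W q_M - C_H - p_L\,
\frac{p_B e^{d_S}}{1 + p_B e^{d_S}} (W q_S + C_S)\Bigr) - C^F_j ,
$$

where $\alpha$ is the baseline log-odds of death, $W$ the willingness to pay
per QALY, $q_M$ the quality-adjusted life expectancy of survivors free of
neurological sequelae (NS), $p_B$ the baseline NS risk, $d_S$ the shift in
NS log-odds among patients "saved" by treatment, $p_L$ the probability that
short-term NS persists, $q_S$ the QALY loss and $C_S$ the lifetime cost of
long-term NS, $C_H$ the hospital cost of survival, and $C^F_j$ the fluid
cost.  The same quantity is computed independently in
`outcome_net_benefit()` by enumerating the four patient outcomes (death,
NS-free survival, short- and long-term NS) with the saved-patient split; the
two agree to $10^{-9}$ dollars on random draws, which the test suite asserts.

With a draws-by-parameters table in hand, decision summaries follow:
`ceac()` (probability each arm is optimal), `switching_threshold()` (the
$W$ at which the arm with maximal mean net benefit changes; mean net benefit
is affine in $W$, so grid bracketing plus bisection finds the exact
crossing), and `evpi_curve()`.

For a focal subset $\phi$ of parameters, learning $\phi$ perfectly is worth

$$
\mathrm{EVPPI}(\phi) = E_\phi\Bigl[\max_j E_{\phi^C\mid\phi}
\bigl[B_j(\theta) - B_{j^*}(\theta)\bigr]\Bigr],
$$

with $j^*$ the arm maximising the unconditional mean net benefit.  The
package fixes $j^*$ once, from the full-sample means, and uses it for every
estimator; all single-step methods then differ only in how they approximate
the inner conditional expectation.

## Parameter uncertainty: a moment-matched reconstruction

The joint parameter distribution emulates an MCMC posterior from a Bayesian
evidence synthesis of three pilot studies.  The synthesis itself (and its
underlying data) is out of scope here; `posterior_spec()` reconstructs the
posterior from its published summaries instead:

* marginals — $\alpha \sim N(-1.07,\,0.11)$;
  $(d_\text{saline}, d_\text{albumin}, d_\text{gelofusine})$ normal with
  means $(-0.31, -2.34, -0.19)$ and variances $(0.51, 0.64, 1.81)$;
  $d_S \sim N(1.88,\,4.52)$; $p_B \sim \mathrm{Beta}(1, 9)$;
  $p_L \sim \mathrm{Beta}(1, 1)$; $q_M \sim N(19.99,\,24.97)$;
  $q_S \sim N(5,\,3.16^2)$ truncated below at 0 (its implied moments, mean
  5.38 and variance 7.94, match the reported posterior);
* dependence — a Gaussian copula whose correlation matrix carries the
  reported correlations within the jointly estimated block
  $(d_\text{saline}, d_\text{albumin}, d_\text{gelofusine}, d_S)$
  (0.64/0.44/0.51 among the effects; 0.25/0.27/0.27 with $d_S$); all other
  parameters are independent, being informed by separate data sources.
  Since that block's marginals are normal, the copula coincides with direct
  multivariate-normal sampling there.

Two reported summaries are internally inconsistent and were resolved as
follows.  First, the second moment printed for $p_B$ (0.04) matches neither
the Beta(1, 9) prior (variance 0.0082) nor its standard deviation (0.09);
the Beta(1, 9) prior is used because its 95% interval (0.6%–28.5%) matches
the printed interval exactly.  Second, the treatment labels attached to the
two stronger/weaker mortality effects conflict between the parameter tables
and the results narrative.  Only one assignment — albumin carrying the
$-2.34$ effect, saline the $-0.31$ effect — is consistent with the narrative
(albumin the only effect whose interval excludes zero; gelofusine optimal at
low thresholds, switching to albumin; saline never optimal) and with the
per-parameter value-of-information table.  The package adopts that
assignment and names the effect parameters by treatment (`d_albumin`,
`d_saline`, `d_gelofusine`) so each stays attached to its published moments.

**What the reconstruction does not capture.**  Moment matching with normal
marginals is exact only to second order: the true posterior of $d_S$
(variance 4.5, estimated from sparse pilot data) and of the effect block is
plausibly skewed, and skewness propagates nonlinearly through the
saved-patient NS probability.  Decision summaries near the switching
threshold are sensitive to these tails.  Reproduction of the published
value-of-information grid is therefore expected to be approximate — close
for estimators dominated by the linear economics ($q_M$, $q_S$, $p_L$
coefficients, EVPI) and looser for quantities driven by the tails of
$d_S$, $p_B$, and the gelofusine effect (variance 1.81).  Under the
reconstruction the gelofusine-to-albumin switch lands near \$239/QALY
rather than \$269, which also makes albumin (not gelofusine) the
maximal-mean arm at $W = 250$; $j^*$ is always computed from the sample, not
asserted.  Passing the reproduction checks therefore validates the
estimators *given* the reconstructed uncertainty, not the reconstruction
itself; the property tier (oracle comparisons below) is what validates the
estimators independently of it.

## The five single-step estimators

**Methods 1–2, mean plug-in (`cond_nb_plugin()`).**  When the nonfocal
parameters enter $B_j$ linearly (or multilinearly with mutual independence),
the conditional expectation is exactly $B_j$ with nonfocal parameters
replaced by their sample means.  Admissibility is looked up in a registry of
focal sets established for this model (`admissible_method()`) rather than
derived symbolically; an inadmissible request errors, naming the offending
parameters, instead of silently returning a biased estimate.

**Method 3, reparameterization (`cond_nb_reparam()`).**  For focal subsets
of $\{q_M, q_S, p_L\}$, $B_j$ is linear in the derived quantities
$\beta_{1,j} = \operatorname{expit}(\alpha) - \operatorname{expit}(\alpha +
d_j)$ and $\beta_{2,j} = \beta_{1,j}\, p_B e^{d_S}/(1 + p_B e^{d_S})$, whose
unconditional means are computed once over the full sample.

**Method 4, quantile-averaged Taylor series (`evppi_taylor()`).**  For the
focal sets $\{d_M, d_S\}$ and $\{\alpha, p_B\}$, the conditional
expectations of the expit terms are expanded around the mean of the single
nonfocal coordinate they contain ($\alpha$ and $\log p_B$, or each $d_j$
and $d_S$).  Rather than raising the expansion order, the nonfocal
distribution is split into equal-probability segments and order-2
expansions about the segment means are averaged (`segment_moments()`,
`taylor_expect()`); the first-order term vanishes by centring.  Defaults are
order 2 with 4 segments (interquartile means): on
$E[\operatorname{expit}(s + X)]$ with $X$ standard normal the 4-segment
order-2 approximation has roughly five-fold smaller worst-case error than a
single order-4 expansion over $s \in [-4, 4]$, and segment ladders 1→4→8
shrink the error monotonically — both properties are asserted against
Gauss–Hermite oracles in the tests.  Derivatives of the expit and
inverse-cloglog are supplied analytically to order 4; no numeric
differentiation is used.  Approximated probabilities falling outside
$[0, 1]$ are clipped and counted (`settings$clipped`) — the published
procedure is silent on this, and under the default model the count is zero.
For $\{\alpha, p_B\}$ the cross term couples the correlated pair
$(d_j, d_S)$; its expectation is factorised, neglecting those modest
(0.25–0.27) correlations, which is why only $\{d_M, d_S\}$ carries a
reproduction check.

**Method 5, restricted cubic splines (`evppi_spline()`).**  For a single
focal parameter correlated with the nonfocal set (any of $\alpha$, $p_B$,
$d_S$, $d_j$), the net benefit is decomposed per arm into the streams
$u_j = \beta_{1,j}$ and $v_j = \beta_{2,j}$ times economically linear
factors.  Each stream's conditional expectation given the focal parameter
is estimated by equal-count binning (`make_bins()`, default $M_B = 100$)
followed by ordinary least squares of the bin means on a restricted cubic
spline basis (`rcs_basis()`, default 10 equally spaced knots placed
strictly inside the observed range via `choose_knots()`).  Bin means of a
term against the focal parameter estimate its conditional expectation
whatever the dependence structure, so the correlations that defeat methods
1–4 are absorbed automatically; streams statistically independent of the
focal parameter (by the correlation-group structure of the spec) use their
overall means instead of a fit.  Design choices worth recording:

* the linear-tail and smoothness constraints are built into the basis
  (truncated-cube combinations), so any fitted coefficient vector satisfies
  them automatically rather than via side conditions;
* bin means are fitted unweighted — equal-count binning makes their
  sampling variances equal to first order;
* a termwise spline is fitted to *every* dependent stream, including the
  mortality term, rather than exploiting the factorisation
  $E[u_j \mid \alpha]$ available for some focal choices; the cross-method
  test (spline versus exact conditional after de-correlating $d_S$)
  validates this choice;
* estimates are knot-stable: moving from 10 to 6 knots changes case-study
  estimates above \$20 by less than 1%, asserted at $10^6$ draws.

**Nested baseline (`evppi_nested()`).**  The two-level estimator draws the
complement from its conditional law given the focal values — Gaussian
conditioning on the copula's latent scale (`conditional_sampler()`) — or
from its marginal when no cross-correlation exists (the complement is then
jointly resampled from the original draws, preserving its internal
dependence).  Ignoring an existing correlation is allowed but warned
against: on the correlated expit toy model it biases EVPPI downward by far
more than Monte Carlo error.  A finite inner sample biases nested estimates
upward (the max of noisy means); at 1000 inner draws the overshoot for
focal $q_M$ is a few percent, which `run_benchmark()` tabulates on a ladder
of sample sizes.

## Oracles

Every estimator is validated against deterministic quadrature on models
small enough to integrate exactly.  `gh_expectation()` (Gauss–Hermite,
node-doubling to $10^{-10}$) checks the Taylor formulas;
`quadrature_evppi()` computes EVPPI for two-arm toy models with jointly
normal parameters by Gauss–Hermite inner expectations and adaptive outer
quadrature — the outer integrand is kinked where the conditionally optimal
arm switches, so adaptive rules rather than fixed tensor grids are used
there.  `toy_suite()` ships four models (linear, product, independent
expit, correlated expit) matching the four approximation families.
Oracles live in the package, not only the tests, so custom models can be
validated the same way.

## Numerical and scale choices

* Default sample size $N_\theta = 10^6$ (the published analysis used
  $5 \times 10^6$; at $10^6$ the Monte Carlo standard errors of the dollar
  grid are \$1–6, well below the reconstruction uncertainty).  The test
  suite uses $10^5$–$10^6$ draws for reproduction checks and
  $10^4 \times 10^4$ for the nested-versus-plug-in agreement checks.
* Monte Carlo standard errors of single-step estimates are the standard
  errors of the per-draw regret; the $O(1/N)$ bias induced by the outer
  max is not corrected.
* Correlation matrices are repaired to the nearest positive semidefinite
  matrix by eigenvalue clipping; repairs that would move any entry by more
  than 0.01 abort instead.
* `pB` at the boundary of $[0,1]$ (measure-zero under Beta(1, 9)) uses the
  limiting formula values with a warning; ties in the argmax (measure-zero
  for continuous draws) break to the earliest arm.
* Seeded runs are reproducible bit for bit; every result row records its
  method, focal set, tuning settings, and sample size.

## Limitations

The admissibility registry is specific to this net-benefit function;
applying the package to another model means extending the registry (or
using the generic `evppi_single_step()` with a custom conditional).
Multivariate correlated focal sets beyond the registered ones have no
single-step method here — multivariate splines are deliberately out of
scope — and fall back to nested simulation.  And as emphasised above, the
case-study numbers inherit the moment-matched reconstruction: they
demonstrate the estimators, not a re-analysis of the underlying trial
evidence.
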