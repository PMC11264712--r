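---
title: "Value-based sequential trial design: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value-based sequential trial design: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decision problem

A randomised trial compares a new health technology *N* with the standard
*S* on cost-effectiveness grounds. Patients are randomised in pairs; for
pair *i* the incremental net monetary benefit is

$$X_i = \lambda\,(E_{iN} - E_{iS}) - (C_{iN} - C_{iS}),$$

where *E* is effectiveness in QALYs, *C* is follow-up cost and $\lambda$
is the payer's maximum willingness to pay per QALY. The $X_i$ are modelled
as $\mathrm{Normal}(\mu_X, \sigma_X^2)$ with $\sigma_X$ known, and beliefs
about $\mu_X$ carry a conjugate Normal prior with mean $\mu_0$ and
effective sample size $n_0 = \sigma_X^2/\sigma_0^2$. After $n$ observed
pairs the posterior is

$$\mu_n = \frac{n_0\mu_0 + n\bar{x}}{n_0 + n},
  \qquad \sigma_n^2 = \frac{\sigma_X^2}{n_0 + n}.$$

The design maximises the expected net benefit to the health-care system:
the reward of adopting the better technology for the $P$ patients affected
by the decision, net of any switching cost $I$ and of the cost of running
the trial. Because outcomes take $\Delta$ years to observe while
recruitment continues, there are always $\tau$ (recruitment rate $\times$
$\Delta$) *pipeline* pairs randomised but not yet observed. The trial has
three stages: recruitment before any outcome arrives (Stage I), recruiting
under interim monitoring (Stage II), and follow-up of the pipeline after
recruitment stops (Stage III). Adoption of *N* is recommended when
$P\mu_{\tilde n} > I$ at the end of Stage III; a tie keeps the standard
technology, matching the strict inequality of the adoption rule.

## The stopping boundary

At a Stage II epoch with $n$ pairs observed, stopping yields

$$G(\mu, n) = \mathbb{E}\left[\max(P\mu' - I,\, 0)\right],
  \qquad \mu' \sim \mathrm{Normal}\!\big(\mu,\, s(n,\tau)^2\big),$$

with the *preposterior* spread
$s(n,m) = \sigma_X\sqrt{m/\big((n_0+n)(n_0+n+m)\big)}$ describing how the
pipeline outcomes will move the posterior mean. $G$ has the closed form
$P[(\mu - I/P)\Phi(z) + s\,\phi(z)]$, $z = (\mu-I/P)/s$. Continuing costs
`c_pair` for one more pairwise allocation and moves the state to epoch
$n+1$, where the posterior mean shifts by a Gaussian increment with
standard deviation $s(n, 1)$. Backward induction from the terminal epoch
$n = T_{\max} - \tau$ gives the value function

$$V(n,\mu) = \max\Big(G(\mu, n),\; -c + \mathbb{E}\big[V(n+1, \mu')\big]\Big),$$

and the stopping boundary is the locus where the two branches cross.
`vb_design()` implements this and returns the boundary over all per-pair
epochs; `interim_schedule()` decides where it is actually consulted
(solver and schedule are deliberately separated, so the same boundary
serves fully sequential or blockwise monitoring).

Monitoring is blockwise in practice: the first interim occurs at 20
observed pairs (chained-equation imputation is unstable on 10 pairs — see
below), then every 10, with no decision at epochs where recruitment is
already complete ($n + \tau \ge T_{\max}$). A posterior mean exactly on
the boundary stops: "crossed" is ambiguous at equality and the inclusive
rule is conservative about sampling costs.

## Design selection: points A--D

Before the trial, the prior mean determines which design maximises
expected net benefit:

* beyond **A** (above) or **B** (below), deciding immediately beats any
  trial;
* between **C** (or **D**) and **A** (or **B**), a fixed one-stage trial
  of ENBS-optimal size is best;
* inside (**D**, **C**), the sequential design wins.

The package compares, as functions of $\mu_0$: no trial,
$\max(P\mu_0 - I, 0)$; the best one-stage design,
$\max_k \mathrm{ENBS}(k)$ from `one_stage_enbs()`; and the sequential
design's root value $V(0, \mu_0) - c\,\tau$ (Stage I recruitment is
committed before any outcome arrives, so its variable cost is charged to
the sequential design). With the reference parameters the sequential
region ends near ±£12,000 and the no-trial region begins near ±£16,000.

**Fixed costs and the design comparison.** Only variable sampling costs
enter the A--D comparison. Fixed research spend (set-up, close-down) is
committed largely irrespective of the stopping time and of which trial
design is run, so charging it to one design but not another would move
the thresholds by an amount the budget data cannot justify; charging the
pre-trial fixed spend to both trial designs would shrink the one-stage
region's outer threshold by roughly £2,000--£3,000. `cost_accounting()`
reports total spend including all fixed components; `one_stage_enbs()`
accepts an explicit `fixed_cost` for users who want a different
allocation.

## Reference parameters

| Quantity | Default | Units | Source of the default |
|---|---|---|---|
| $\lambda$ | 30,000 | £/QALY | UK payer convention |
| $P$ | 24,500 | patients | 2,450/year × 10-year horizon |
| $I$ | 0 | £ | no switching cost for a drug already in use |
| `c_pair` | 1,650 | £/pair | £204,581 variable spend / 124 pairs |
| $\Delta$ | 1 | years | 12-month economic endpoint |
| $\tau$ | 74 | pairs | 124 pairs / 611 days × 365 × $\Delta$ |
| $T_{\max}$ | 124 | pairs | the actual trial's sample size |
| $\sigma_X$ | 7,615 | £ | pooled SD of pairwise INMB |
| $\mu_0$, $n_0$ | 0, 2 | £, pairs | diffuse, equivocal prior |

`derive_design_params()` reproduces these from raw accrual and accounts
figures, and `vb_read_config()` reads them from a flat YAML file.

## Numerical choices

**Grid.** The value function lives on a uniform posterior-mean grid,
half-width £60,000 (comfortably beyond point A plus several prior SDs)
and step £50 by default. The expectation over the one-step Gaussian
increment is computed exactly for the piecewise-linear interpolant of the
value function (hat-function weights built from $\Phi$ and $\phi$), with
the value surface padded by the stopping reward beyond the grid edge —
valid because stopping is optimal far outside the boundary, and enforced
by an error if the boundary ever touches the edge.

**Grid convergence and long horizons.** For the 124- and 250-pair
designs, halving the step from £50 changes the boundary by well under
£100. For horizons of many hundreds of epochs a subtlety matters: once
the one-step increment SD $s(n,1) = \sigma_X/\sqrt{(n_0+n)(n_0+n+1)}$
falls below the grid step, the interpolant-exact rule effectively
over-diffuses (its smoothing is of order $s\cdot h$, not $s^2$), and the
error compounds across thousands of backward sweeps: coarse grids
systematically widen the late boundary, which inflates simulated expected
sample sizes and the fraction of trials recruiting to the maximum. The
shipped large-horizon analyses therefore use a £10 step, at which the
$T_{\max} = 1000$ boundary agrees with a £5-step solution to a few
pounds, and a Monte-Carlo policy evaluation (run in the test suite)
confirms the boundary attains the dynamic-programming root value within
Monte-Carlo error and is not beaten by any fixed stopping time.
Perturbing the boundary by ±30% changes expected net benefit by under
0.1% — the objective is extremely flat near the optimum, so small
numerical differences in the boundary have negligible economic cost but
visibly change operating characteristics such as the probability of
recruiting to the maximum. Comparisons of those statistics across
implementations are correspondingly sensitive to solver settings.

**Degenerate cases.** A prohibitive `c_pair` empties the continuation
region (the boundary is recorded as `NA`: stop everywhere); `m = 0`
pipeline information makes the stopping value collapse to
$\max(P\mu - I, 0)$; ties in the adoption rule keep the standard.

## Monitoring with missing data

Costs and utilities go missing in routine economic data collection. At
each interim the records of the pairs followed up so far are completed by
chained equations (`impute_interim()`): each incomplete variable is
regressed on arm, baseline covariates, arm-by-covariate interactions and
the other outcome fields; regression parameters are drawn from their
posterior (normal-draw method) each sweep; five imputations by default.
The newest block of pairs then yields five block means of derived INMB,
pooled by Rubin's rules (`rubins_pool()`), and the pooled block mean
enters the conjugate update weighted by block size. The posterior update
treats the sampling variance as the known $\sigma_X^2$ — the model's
known-variance assumption — while the Rubin total variance is carried for
diagnostics. With one imputation (complete data) pooling short-circuits
with zero between-imputation variance, and the whole pipeline reproduces
the complete-data analysis exactly.

Imputed utilities are censored to the EQ-5D value-set range
$[-0.594, 1]$. QALYs are the trapezoidal area under the utility curve at
0, 6 and 12 months (or 0 and 6 for the half-year endpoint); total cost is
the sum of the cost components. The trapezoid is a deliberate, isolated
choice (`derive_costs_and_qalys()`): real economic evaluations sometimes
use study-specific derivations, and replacing this one function adapts
the whole pipeline.

An interim on 10 pairs is refused (`data sparsity`) rather than silently
skipped: with so few complete rows the chained-equation draws are
numerically unstable, which is why the first interim sits at 20 pairs.

## The synthetic cohort generator

`generate_cohort()` draws patient-level records whose *derived* pairwise
INMB is calibrated — by construction, with a fixed-seed internal
moment-matching sample — to a Normal law with configurable mean (default
−£45) and SD (default £7,615), recruitment uniform over 611 days, and a
logistic-in-frailty MAR missingness mask. Frailty raises costs, lowers
utility, and interacts with the arm effect on costs, so complete-case
analyses of INMB are biased while multiple imputation (which sees frailty)
recovers the truth; this is verified in the test suite.

What the generator does *not* emulate: skewed, zero-inflated cost
distributions (its Gaussian cost components can go slightly negative —
read them as net resource-use deviations); centre-level clustering of
outcomes; informative (MNAR) missingness; and dose-level structure within
the new-technology arm. Passing tests on synthetic cohorts therefore
demonstrate the machinery — calibration, monitoring, imputation,
resampling — not robustness of the design to those real-data features.

**Simulation sizes.** The shipped analyses use 5,000 replicates for
operating characteristics (the acceptance script) and reduced counts with
3-Monte-Carlo-SE tolerances in the routine test suite; the vignette and
README report only numbers those runs actually produce.

## Known limitations

* The sampling SD $\sigma_X$ is treated as known; a normal-gamma
  (unknown-variance) extension is out of scope.
* Point estimates of E[INMB] are unadjusted group-mean differences;
  covariate-adjusted (regression) estimation is out of scope.
* The boundary solver's per-pair epochs assume one observation arrives
  per allocation made; strongly time-varying accrual would require
  re-deriving $\tau$ (an internal pilot is the practical remedy).
* No discounting of costs or QALYs within the follow-up year.
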