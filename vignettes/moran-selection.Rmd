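---
title: "Methods: Moran-model estimation of clonal selection coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Moran-model estimation of clonal selection coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moranselect)
```

## The model

A mutant clone (the motivating case: a truncating *CSF3R* mutation in the
hematopoietic stem cells of a severe congenital neutropenia patient) competes
with wildtype cells in a pool of constant size $N$. The mutant count $i$
follows a time-continuous Moran process: birth-death events replace one cell
by the offspring of another, the wildtype reproducing with weight $1 - s$,
$s \in [0, 1)$; in addition each wildtype cell mutates at rate $\mu$ per
generation. The transition intensities are

$$q_{i,i+1} = \frac{(N-i)\,i}{N} + \mu (N-i), \qquad
  q_{i,i-1} = \frac{i\,(1-s)(N-i)}{N}.$$

Time is counted in *generations* (one expected division per cell); calendar
time enters only through the assumed division rate $\lambda$ per year.
State $N$ (fixation) is absorbing. State $0$ is absorbing only when
$\mu = 0$: with recurrent mutation, transiently extinct clones are re-seeded,
which is why the chain is eventually fixed with probability one. For the
mutation-free chain the package also exposes the classical absorption
probability $[1-(1-s)^i]/[1-(1-s)^N]$ and the large-$N$ fixation-time
asymptotic $(2/s)\ln N$; the latter is known to be crude at moderate $N$ and
is provided for reference only, never used in estimation.

## Mean-field curve and the two-point estimator

Replacing the count by its expectation in the one-step conditional mean
yields the frequency ODE $\dot y = (1-y)\,y\,s + \mu(1-y)$, whose solution
(for $s > 0$, with $u = \mu/s$ and $\alpha_0 = (1-y_0)/(y_0+u)$) is

$$y(t) = \frac{1 - u\,\alpha_0 e^{-(\mu+s)(t-t_0)}}
              {1 + \alpha_0 e^{-(\mu+s)(t-t_0)}}.$$

This is a *mean-field approximation*, not the exact expectation of the
chain: the logistic term is nonlinear, so $E[y(X_t)] \ne y(E[X_t])$ in
general. The package therefore never asserts exact agreement with
simulation means; the test suite checks agreement within Monte-Carlo error
(200 replicates at $N = 10^4$ over 600 generations, pointwise within three
standard errors), and checks that the ensemble variance falls roughly as
$1/N$ between $N = 10^3$ and $N = 10^4$. Note $N$ does not appear in
$y(t)$ at all — it controls only the fluctuations around it.

Given frequencies $y_0, y_1$ observed $\Delta t$ years apart, inverting the
curve for each assumed $u = \mu/s$ gives

$$\hat s(u) = \frac{1}{1+u}\,
  \frac{\ln(\alpha_0/\alpha_1)}{\lambda\,\Delta t},
  \qquad \alpha_i = \frac{1-y_i}{y_i+u},$$

with implied mutation rate $u\,\hat s$. At $u = 0$ this is the change in
log-odds per generation. One observation pair identifies only this
trade-off curve, not $(s, \mu)$ jointly; the packaged reproduction and all
defaults use $u = 0$, and `tradeoff_curve()` sweeps the rest. For a growing
clone $\hat s(u)$ is strictly decreasing in $u$, so mutation allowances only
lower the estimate.

**Orientation of the logarithm.** Writing the inversion as
$\mu + s = \ln(\alpha_1/\alpha_0)/\Delta t$, with $\alpha$ decreasing in
$y$, would make every growing clone come out negative, contradicting the
relation $\alpha_1 = \alpha_0 e^{-(\mu+s)\Delta t}$ from which it is
derived — an apparent sign typo in the printed derivation this package
follows. The implementation uses $\ln(\alpha_0/\alpha_1)$, which is the
orientation consistent with that relation and with every published
per-patient value.

**Two conventions for the table's "alpha" columns.** The published
per-patient table tabulates the *odds* $y/(1-y)$ (e.g. $y = 0.24 \mapsto
0.32$), the reciprocal of Eq.-style $\alpha$ at $u = 0$. Estimate objects
carry both (`alpha0`/`alpha1` and `odds0`/`odds1`) explicitly.

**The leading-order trade-off intuition can mislead at low frequency.**
Treating only the $1/(1+u)$ prefactor, a 10% change in $\hat s$ needs
$u \approx 0.1$, i.e. an implied $\mu \approx 2\times 10^{-4}$ per
generation for the lowest estimates near $0.002$ — five orders of magnitude
above human per-nucleotide rates, which is why mutation is negligible for
these data. The exact curve shifts somewhat faster when $y_0$ is small
(there $u$ is not negligible against $y_0$ inside $\alpha_0$), so the
acceptance test asserts the directional claims: a shift of at least 10% at
implied $\mu \approx 2\times10^{-4}$, under 1% at $\mu = 10^{-6}$.

## Tunable parameters

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| $N$ | cells | — | HSC pool size; affects only fluctuations, not $y(t)$ or $\hat s$ |
| $s$ | per generation | — | the estimand; chain formulas require $0 \le s < 1$ |
| $\mu$ | per cell per generation (per nucleotide site) | 0 | per-site rates are used because specific mutation sites are modelled; a variant-multiplicity factor (several alternative truncating variants, at most ~10) can be folded into $\mu$ by the caller |
| $\lambda$ | divisions/year | 24 | 15-day HSC interdivision time; $\hat s \propto 1/\lambda$ exactly, `sensitivity_to_lambda()` sweeps it |
| $u=\mu/s$ | dimensionless | 0 | the published estimates assume $\mu = 0$ |
| `read_depth` | reads | `Inf` | synthetic noise model only (below) |

## Numerical choices

* `fixation_probability()` evaluates $\mathrm{expm1}(i\log(1-s))/\mathrm{expm1}(N\log(1-s))$,
  stable where the naive power underflows at large $N$, and returns the
  neutral limit $i/N$ exactly at $s = 0$ (the formula is continuous there).
* `mean_frequency()` at $s = 0$ switches to the exact pure-mutation solution
  $1-(1-y_0)e^{-\mu(t-t_0)}$, since $u = \mu/s$ is undefined; this keeps the
  curve total on the parameter space. The closed form is verified against
  adaptive Runge–Kutta integration of the ODE to $10^{-8}$ over a parameter
  grid including all simulated-comparison parameter sets, and the estimator
  inverts it to $10^{-10}$.
* The Gillespie simulator draws exponential holding times at total rate
  $q_{i,i+1}+q_{i,i-1}$ and picks the jump direction proportionally — the
  exact law of the chain, no approximation. Trajectories are stored sparsely
  (jump times + states); ensembles are sampled straight onto the requested
  time grid (right-continuous interpolation), so memory is independent of
  $N$. An event cap (default $10\,N\,t_{\max}$ plus a constant) guards
  against runaway parameter mistakes.
* Reproducibility: R's RNG drives the C++ loop; per-replicate seeds are
  spawned deterministically from one master seed, so ensembles are
  reproducible and replicate-order independent, and any single replicate can
  be regenerated in isolation.
* Initial counts from target frequencies use nearest-integer rounding
  $i_0 = \mathrm{round}(y_0 N)$.
* Estimation requires $y \in (0,1)$ strictly (odds and $\alpha$ are
  undefined at the boundary); boundary inputs are rejected with a
  validation error, never clamped.

## The synthetic-data generator

`synthetic_scenario()` / `generate_observation()` emulate exactly the
structure the estimator consumes: one true Moran trajectory under known
$(N, s, \mu)$, read at $t_0$ and $t_1 = t_0 + \lambda\,\Delta t$, optionally
through binomial sampling at a finite read depth standing in for
sequencing-limited variant-allele-frequency calls. The clinical sources
publish no measurement model, so the binomial depth model is this package's
own stand-in and defaults to `Inf` (noise-free) so that core validation
isolates process noise. Draws landing on 0 or 1 are rejected and redrawn
(with a recorded flag) because the estimator's domain is open; silent
clamping would bias recovery experiments. A trajectory absorbed at 0 under
$\mu = 0$ with infinite depth yields no usable observation and is signalled
explicitly.

`recovery_experiment()` runs generate→estimate cycles at $u = 0$ and reports
bias, RMSE and quantiles of $\hat s$. The validation suite uses $N = 10^4$,
$y_0 = 0.2$, intervals chosen so the expected endpoint is near $y = 0.5$
(log odds-ratio 4), 200 replicates per true $s \in \{0.01, 0.05\}$, asserting
the median within ±20% of truth; neutral scenarios ($s = 0$) are checked to
center at zero; and $\mu = 10^{-6}$ versus $\mu = 0$ is checked to be
statistically indistinguishable at that replicate count. Problem sizes
throughout the suite (replicate counts, grids, $N$) were chosen as the
smallest at which each property is sharply testable.

What passing these tests shows: the estimator is consistent with the model
that generated the data, with quantified sampling spread. What it does not
show: anything about model *mis*specification in real patients — ascertainment
bias (faster clones get sequenced sooner, visible as the negative
association between $\hat s$ and the observation interval in the packaged
data), non-constant HSC pool size during childhood, multi-clone receptor
competition, or sequencing error structure beyond binomial thinning.

## The packaged clinical dataset

`load_table1()` ships the 14 curated two-time-point records (three source
publications; only cases with an unambiguous monotone frequency trend),
together with the published odds and $\hat s$ values. `reproduce_table1()`
recomputes everything from the printed $y_0, y_1, \Delta t$: six records
(identifiers 4, 8, 9, 11, 13, 14) reproduce the published $\hat s$ exactly
at its 3-decimal printing, and the others are *flagged*, not matched — the
printed frequencies are rounded readings of source figures, so
recomputation from them cannot always reach the authors' unrounded
spreadsheet values (e.g. record 1 recomputes to 0.008 against a printed
0.002). The flags keep the discrepancy visible rather than silently
adopting either number. Rounding for comparison follows the table's
printing: $\hat s$ to 3 decimals, odds to 2.

`fig3_summary()` reports Pearson and Spearman associations between
$\hat s$ and the observation interval (the published claim is only a
"negative association", so both are given, with and without the single
negative-$\hat s$ record) and per-phase means (MDS, AML, unclassified — the
latter being the cases published only as "CN-MDS/AML").

## Known limitations

* The estimator uses exactly two time points; longitudinal series with more
  points are not pooled.
* No uncertainty intervals for $\hat s$ are produced (none exist for the
  published values either); the synthetic machinery quantifies sampling
  spread under the model instead.
* $(s, \mu)$ are not jointly identifiable from one observation pair — only
  the trade-off curve is.
* Constant $N$; the fetal/childhood expansion of the HSC pool is outside
  the model.
* Variance dynamics of the chain are simulated, not given in closed form.
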