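---
title: "Sequential sampling models of decision confidence: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential sampling models of decision confidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in **rtconf**, the
assumptions behind them, the numerical methods used to evaluate their
likelihoods, and the design decisions taken where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## The modeling problem

In a binary discrimination experiment a participant sees a stimulus of
identity $S \in \{-1, +1\}$ at difficulty level $l \in \{1..L\}$ and
produces, on every trial, a choice $R \in \{-1, +1\}$, a response time
$RT$, and a confidence rating $C \in \{1..K\}$. Sequential sampling
models treat the choice as the first passage of a noisy evidence
accumulation process and derive RT and confidence from the same episode,
so the three observables are fitted jointly via their full likelihood
$P(RT, C, R \mid \vartheta, S, l)$ rather than through summary
statistics.

All models share two components:

* **Confidence discretization.** A model-specific internal confidence
  variable $c$ is compared against response-specific thresholds
  $\theta_{R,1} \le \dots \le \theta_{R,K-1}$ (sentinels
  $\theta_{R,0} = -\infty$, $\theta_{R,K} = +\infty$), giving
  $C = \sum_i 1(c > \theta_{R,i}) + 1$. `sym_thetas` forces
  $\theta_{+1,k} = \theta_{-1,k}$.
* **Non-decision time.** $T_{ND} \sim U[t_0, t_0 + s_{t0}]$ adds
  encoding/motor time: $RT = T_{Dec} + T_{ND}$, or
  $RT = T_{Dec} + \tau + T_{ND}$ for models with a post-decisional
  accumulation period $\tau$ when choice and confidence are reported
  simultaneously (`simult_conf = TRUE`).

### Drift-diffusion family (dynaViTE, dynWEV, 2DSD, DDConf)

The decision process $X$ is a Wiener process with diffusion constant $s$
(fixed to 1 in fitting), drift drawn per trial from
$N(\nu, s_\nu^2)$ with $\nu = S d_l$, and relative start
$X(0)/a \sim U[z - s_z/2, z + s_z/2]$ between absorbing boundaries $0$
and $a$. After the boundary crossing, accumulation continues for $\tau$;
a parallel visibility process $V$ (drift $\sim N(\mu_V, \sigma_V^2)$ with
$\mu_V = d_l$, diffusion $s_V$) accrues difficulty evidence. Confidence
is

$$c = \frac{w R (X(T_{Dec}+\tau) - a z) + (1-w) V(T_{Dec}+\tau)}
           {(T_{Dec}+\tau)^{\lambda}}.$$

Special cases: dynWEV ($\lambda = 0$), 2DSD ($\lambda = 0, w = 1$; the
visibility process drops out of the likelihood entirely), DDConf
($w = 1, \tau = 0, \lambda = 0.5$). `dDDConf()` is implemented *exactly*
as the constrained dynaViTE density, so its thresholds live on the
$a\zeta_R/\sqrt{T}$ scale — a response-specific positive rescaling of
$1/\sqrt{T}$; this makes the pointwise special-case identity hold by
construction, and is observationally equivalent to thresholding
$1/\sqrt{T}$ because thresholds are free per response. $\lambda$ is
restricted to be non-negative (larger accumulation time can only
penalize confidence); negative values have no theoretical reading in
this family.

**Likelihood.** The first-passage density uses the truncated small-time
and large-time series with the minimal-terms switching rule; the series
truncation error is kept below $10^{-(p+1.5)}$ for precision argument
$p$. Drift variability does *not* require numeric integration: the drift
enters the first-passage density only through
$\exp(R \nu a \zeta/s^2 - \nu^2 t / 2s^2)$, so a normal drift
marginalizes in closed form, and the drift posterior given the
first-passage event $(t, R)$ is itself Gaussian. Conditional on
$(t, R, \nu)$ both evidence terms of $c$ are Gaussian, so the
probability of a confidence bin is a difference of normal CDFs. Only the
starting point ($s_z$) and the non-decision time ($s_{t0}$) are
integrated numerically.

### Wiener race models (IRM, IRMt, PCRM, PCRMt)

Two accumulators $(X_1, X_2)$ with unit diffusion, drifts
$(S d_l, -S d_l)$ and noise correlation $\rho$ race to thresholds $A$
and $B$. $\rho$ is restricted to $0$ (independent race) or $-0.5$
(partial feed-forward inhibition) — exactly the two values for which the
method of images gives closed-form first-passage densities: in
threshold-distance coordinates the wedge angle is $\arccos(-\rho)$,
i.e. $\pi/2$ (4 images) or $\pi/3$ (6 images, dihedral group $D_3$),
with drift absorbed into constant image weights
$\exp(c^\top (y_j - y_0))$, $c = \Sigma^{-1} m$. Confidence is the
balance of evidence $b$ (loser's distance to its own threshold),
time-dependent variants use
$c_{RMt} = w_X b + w_{RT}/\sqrt{T} + w_{Int}\, b/\sqrt{T}$ with
non-negative weights summing to 1 (exact zeros are admitted: the
time-independent models are the $(1,0,0)$ corner). Because $c_{RMt}$ is
increasing in $b$ at fixed $T$, a confidence bin maps to a $b$-interval
(clipped at 0, forced by $c_{RMt} \ge w_{RT}/\sqrt{T}$), and the
$b$-integral of the image solution is analytic — race likelihoods need
numeric integration only over $s_{t0}$. The degenerate corner
$w_X = w_{Int} = 0$ makes $c$ a function of $T$ alone and is handled as
an indicator times the full gap mass.

### Multiple-threshold log-normal race (MTLNR)

Ballistic accumulation: crossing times $T_i = D_i / V_i$ with log-normal
boundary distances and rates, so
$(\log T_1, \log T_2)$ is bivariate normal with means
$\mu_{di} - \mu_{vi}$ and covariance $\Sigma_d + \Sigma_v$ — the
covariance *adds* with a positive sign on the rate correlation, since
$\mathrm{cov}(-\log V_1, -\log V_2) = +\rho_v \sigma_{v1}\sigma_{v2}$;
this sign was validated against the exact log-normal sampling oracle,
which has no discretization error. Confidence is
$c = \log(T_{lose}/T_{win}) > 0$; its bin probability is a conditional
normal CDF difference given the winner's log time. The full
parameterization (`MTLNRfull`, 10 base parameters) is exposed in the
density layer and the precision benchmark; per-subject fitting uses the
identifiable restriction $\sigma_{d} = \rho_d = 0$, relabeling
$\sigma_{v1}, \sigma_{v2}, \rho_v$ as `s1`, `s2`, `rho` — the variance
parameters of the boundary-hitting times.

## Numerical integration and the precision argument

Starting-point and non-decision-time integrals use the midpoint
(rectangular) rule with equidistant support points. The step count per
dimension is $\lceil \kappa \cdot \mathrm{range} \cdot 10^{p/2}
\rceil$ (minimum 4, capped at 250 per dimension for the diffusion
family, 2000/4000 for race/MTLNR), so the quadratic error of the
midpoint rule makes the density error scale as $10^{-p}$. The constants
$\kappa$ (0.79 diffusion, 0.55 race, 1.6 MTLNR) were calibrated once
against precision-9 reference computations over sampled parameter sets
so that the mean absolute density error lands slightly *below*
$10^{-p}$ (about $10^{-(p+0.45)}$), and are frozen by a regression test
(log-error within $\pm 0.7$ of $-p$ for $p \in \{4,5,6\}$). Contrary to
an a-priori guess that the log-time curvature would force much smaller
steps, MTLNR needed only a mildly larger constant than the Wiener race
models. Defaults: precision 6 in direct density calls, 3 inside fitting
— at precision 3 a 600-trial likelihood evaluates in a few
milliseconds, which is what makes grid search plus restarted
optimization affordable.

## Fitting

Per subject and model, maximum likelihood with:

1. **Transforms** to an unconstrained space: log for positive
   parameters, logistic for $z$, $w$ and the $t_0 <$ min(RT) bound,
   conditional-logistic for $s_z$ given $z$, stick-breaking for the race
   weights, $\tanh$ for correlations, and first-threshold plus
   log-increments (minimum spacing $10^{-6}$) for the ordered
   thresholds.
2. **Grid search**: a deterministic product grid over data-driven
   anchors — boundary, variability and timing anchors crossed with a
   drift scale; the drift pattern across conditions comes from
   per-condition accuracy ($\Phi^{-1}$, clamped); $t_0$ anchors sit
   below the minimum observed RT; thresholds are placed at the observed
   rating proportions using a Gaussian approximation of the confidence
   variable at the median RT. The default budget is ~12,000 evaluations
   (`opts$grid_size`); the grid-adequacy property (best grid candidate
   within 20% of the generator's NLL on simulated data) is part of the
   test suite.
3. **Restarted Nelder–Mead** from the `n_starts` (default 5) best grid
   candidates, `n_restarts` (default 5) rounds of at most `max_evals`
   (default 5000) iterations each, warm-starting each round at the
   previous optimum.
4. **Unused rating categories** are detected from the data and not
   optimized: unused extreme categories get $\mp\infty$ sentinel
   thresholds, unused interior categories coincident thresholds (both
   maximize the likelihood), and the reported parameter count `k` is
   reduced accordingly.

Zero-density trials contribute a finite penalty of $-\log 10^{-300}$
per trial so the optimizer can recover from bad regions.
`restr_tau = "simult_conf"` bounds $\tau$ by min(RT) $- t_0$, since
Eq. $RT = T_{Dec} + \tau + T_{ND}$ requires positive decision time.
AIC $= 2\mathcal{L} + 2k$, BIC $= 2\mathcal{L} + k \log N$,
AICc $=$ AIC $+ 2k(k+1)/(N-k-1)$.

## Simulation

Path-based simulators (diffusion, race) use Euler–Maruyama with step
`delta` (default 0.001 s) **plus a Brownian-bridge correction** for
within-step boundary crossings: without it, the $O(\sqrt{\delta})$
first-passage bias at $\delta = 10^{-3}$ is several Monte-Carlo standard
errors at $n = 10^5$, which was established by comparing against
$\delta = 2\times 10^{-4}$ runs and the closed-form densities. The
post-decisional increment and the visibility evidence are drawn exactly
from their Gaussian laws; MTLNR is sampled exactly (no discretization at
all), which is why it serves as the sharpest simulator-vs-density
oracle. Trials that reach `maxrt` (default 15 s of decision time)
without a decision return `response = 0` with missing outcomes.

## Synthetic data: what the generator emulates, and what not

`sample_parameters()` draws generating parameter sets uniformly within
ranges chosen to emulate empirical fits of binary discrimination
experiments (RTs mostly under ~3 s; accuracies ~60–95% across levels;
e.g. $a \in [1, 2.5]$, $t_0 \in [0.2, 0.5]$ s, $s_{t0} \in [0.05,
0.3]$ s, drifts as a uniform first level plus uniform increments so
discriminability increases across levels). Exceptions to independent
uniform sampling: $s_z$ is uniform over its admissible range given $z$;
race boundaries are drawn as total separation and relative height; race
weights sequentially on the simplex. Confidence thresholds are placed at
quantiles of a simulated confidence variable at target rating
proportions (equal by default), so every category has mass.

A green recovery test therefore establishes that the fitting machinery
identifies parameters *within this stated world*: balanced designs,
stationary parameters, no lapses or contaminant RTs, no sequential
dependencies, no asymmetries between stimulus classes beyond the drift
sign. Real data violate several of these (the package deliberately
leaves outlier filtering to the user via `filter_rt_outliers()`), so
recovery results are a property of the procedure, not a guarantee for
any data set.

## Group-level model comparison

Log model evidence is approximated by $-IC/2$ (BIC by default — the
most conservative criterion at typical trial counts; AIC/AICc via
`measure`). `group_BMS_fit()` runs the standard variational Bayes
updates for a Dirichlet population model (prior $\alpha_0 = 1$ per
model, convergence at $10^{-8}$ on $\alpha$; the variational free
energy is non-decreasing and asserted as such). Exceedance
probabilities use the analytic Beta comparison for two models and $10^6$
Dirichlet samples otherwise; the Bayesian omnibus risk compares the
random-effects free energy against the equal-frequency null, and
$PEP = (1-BOR)\,EP + BOR/M$.

Two properties of the *algorithm* (as opposed to exact inference) are
worth knowing and are asserted in the tests in this form: with
identical evidences across models, BOR approaches 1 only as the number
of subjects grows (0.71 at $n = 8$, 0.92 at $n = 200$); and for a
single subject the mean-field updates are sparsity-promoting as
$\alpha_0 \to 0$ (winner-take-all), so the exact-inference limit
"posterior frequencies $\to$ IC weights" holds only in ranking, or
exactly for the responsibilities under a large symmetric prior.

## Recovery suites and scale

The shipped studies run at a desk scale by default — 10 parameter sets
× 100 trials per stimulus×condition cell at $L = 2$, $K = 3$, with a
reduced optimization budget (`recovery_presets()$scaled`) — and
reproduce the qualitative structure of the full-scale studies: drift
parameters recover well (CCC > 0.8 for 2DSD), starting-point
variability recovers poorly (CCC(drift) > CCC($s_z$) for dynaViTE), and
BIC classification cleanly separates diffusion-based from race-based
generators. The full-scale preset (50 sets, 500 trials/cell, $L = K =
5$) matches the head-line simulation settings and is configuration
only (`desk_scale = FALSE`): it takes CPU-days, not desk minutes. With
$L = 5$, $K = 5$ the free-parameter counts are 26 for dynaViTE, 21 for
IRMt/PCRMt and 22 for MTLNR when counting $2K$ rather than $2(K-1)$
thresholds; the package follows the $2(K-1)$ formulas throughout (11/6/7
base + $L$ + $2(K-1)$), which yields 24/19/20 — the discrepancy is in
the source material's recovery section, not in the formulas, and the
formulas are authoritative here.

## Known limitations

No collapsing boundaries, leakage, inhibition, or state-dependent
drift; no confidence response times for sequential report paradigms; no
lapse/contaminant mixture; no hierarchical estimation and no parameter
uncertainty measures (point estimates only); information criteria do
not account for functional model complexity. The CLI's config format is
JSON rather than YAML (no YAML parser in the dependency footprint; JSON
covers the same need).
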