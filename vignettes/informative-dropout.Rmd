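---
title: "Modelling longitudinal quality-of-life scores under informative dropout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal quality-of-life scores under informative dropout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qoldrop)
```

## The problem

A two-arm oncology trial collects a 0–100 quality-of-life dimension score
at planned visits (here months 0, 1.25, 3, 4, 6, 12, 24, 36). Returns thin
out over time, almost always monotonically: after a certain visit a
subject's scores are missing for good. When the decision to stop returning
questionnaires is driven by how the patient feels — i.e. by the score
itself, observed or not — the missingness is *informative* (MNAR) and a
likelihood analysis that ignores the dropout process is biased. This
package fits the four standard models for this situation to the same
dataset so their answers can be confronted, and ships a generator that
produces trials with known truth so each estimator can be checked by
parameter recovery rather than by faith.

All four models share one longitudinal sub-model, the random-coefficients
LMM

$$Y_i(t_j) = \beta_0 + \beta_1 t_j + \beta_2\,\mathrm{arm}_i\, t_j
  + b_{0i} + b_{1i} t_j + \varepsilon_i(t_j),$$

with $(b_{0i}, b_{1i}) \sim N(0, G)$ and $\varepsilon \sim N(0,\sigma^2)$.
$\beta_1$ is the control-arm slope (points/month) and $\beta_2$ the
difference between the arms' slopes, the treatment contrast of interest.
The mean has no main arm effect: randomization justifies a common baseline
mean, and arm enters through the slope only. Design matrices always use
the planned visit times, not the (slightly jittered) observed ones.

## The four estimators

**LMM** (`fit_lmm`). REML by default for the standalone fit, ML inside
the joint models (REML has no clean joint-likelihood analogue). The
variance components are optimized on a log-Cholesky scale — positive
definiteness of $G$ by construction, unconstrained smooth optimization —
with the fixed effects profiled out by GLS, so the optimizer works in four
dimensions regardless of the design. Wald inference uses the standard
normal; no small-sample degrees-of-freedom correction is applied.

**Selection model** (`fit_sm`). The joint density factorizes as
$f(Y)\,f(D\mid Y)$, with the discrete-time dropout hazard
$\mathrm{logit}\,P(D = j \mid D \ge j) = \psi_0 + \psi_1 Y(t_j) +
\psi_2 Y(t_{j+1})$ in the last observed and current (possibly unobserved)
score, per raw point on the 0–100 scale. A subject dropping after visit
$d < J$ contributes the observed-score normal density, the
stay-in probabilities for visits $1..d{-}1$, and the dropout probability
with the unobserved next score integrated out against its conditional
normal distribution given the history. That one-dimensional integral of a
logistic times a Gaussian is evaluated by Gauss–Hermite quadrature on the
conditional scale (30 nodes by default; doubling the rule changes the
log-likelihood by far less than the optimizer tolerance). Completers
contribute density and stay-in factors only; dropout is possible at every
non-final visit. Subjects observed only at baseline contribute
$f(y_1)$ times the integral term, as the likelihood structure forces.

The joint likelihood is maximized over all ten parameters with a scaled
quasi-Newton method. Two practical points deserve honesty. First, the
surface is often *bimodal* in $\psi_2$: a MAR-like mode near
$\psi_2 = 0$ can coexist with an informative one. The fitter therefore
explores a small set of $\psi_2$ starting values (0, ±0.04, with
$\psi_0$ offset so the implied marginal dropout rate is unchanged) with a
few coarse iterations each, then polishes the best candidate; the
observable MAR logistic fit (dropout on the last observed score) supplies
the base start. Second, the observed information can be near-singular —
the model is weakly identified when dropout is heavy — so standard errors
are returned only when the numerically differentiated Hessian inverts
(`hessian_ok`); simulation at trial-like dropout intensity shows the Wald
interval for $\psi_2$ undercovers (roughly 80% instead of 95% under MCAR
at $n = 250$), which is a known fragility of this model class and should
temper interpretation of borderline $\psi_2$ findings.

**Pattern-mixture model** (`fit_pmm`). The converse factorization
$f(D)\,f(Y\mid D)$: pattern probabilities are multinomial proportions
$\hat\pi_k = n_k/n$ with covariance $(\mathrm{diag}(\pi)-\pi\pi')/n$, and
within patterns the LMM carries pattern-specific fixed effects. The
default scheme for the eight-visit design groups last-available visits
{V0–V2}, {V3–V4}, {V5}, {V6–V7}: early treatment-phase dropouts, two
follow-up bands, and late dropouts merged with completers. The default
`variance_mode = "shared"` fits one model with pattern-indexed fixed
effects and common $(G, \sigma^2)$ — the natural reading of "an LMM with
pattern indicator variables" — while `"stratified"` refits per pattern as
a sensitivity analysis; whether variance components should be shared is
genuinely open, so both are provided.

Marginal effects are $\beta_l = \sum_k \beta_l^k \hat\pi_k$. The
delta-method variance $w'\Sigma_\beta w + \beta'\Sigma_\pi\beta$ (with
$w = \hat\pi$) treats the effect estimates and the proportions as
independent — $\hat\pi$ is a function of dropout counts only, $\hat\beta$
is conditional on pattern — a standard working assumption; against a
1,000-replicate nonparametric bootstrap of the whole pipeline it agrees
to about 12% relative difference in the test suite. Overall proportions
weight both slopes by default; arm-specific weighting
(`marginalize_pmm(fit, weights = "by_arm")`) is available because the two
weightings genuinely differ when dropout timing differs by arm, and with
overall weights the marginal slope is not, in general, reconstructible
from arm-wise summaries. Each pattern's straight line is extrapolated
beyond its own last visit when marginalizing — an explicit, untestable
assumption and the model's defining caveat: patterns estimated from one
or two early visits can dominate the marginal slope with very wide
intervals. Patterns observed in a single arm lose their interaction term
(treated as 0, with a warning); patterns without usable support are
dropped and the proportions renormalized.

**Shared-parameter model** (`fit_spm`). Scores and a continuous
time-to-dropout are conditionally independent given the random effects;
dropout follows the proportional-hazards model
$\lambda_i(t) = \lambda_0(t)\exp\{\gamma\,\mathrm{arm}_i + \alpha
Y_i^*(t)\}$ with the current-value association
$Y^*(t) = \beta_0 + b_0 + (\beta_1 + \beta_2\mathrm{arm} + b_1)t$ (the
error-free trajectory; current-slope or random-effects-only associations
are deliberately out of scope). The baseline hazard is piecewise constant
with knots at the interior visit times (months 1.25, 3, 4, 6, 12, 24 —
seven intervals, left-closed/right-open, estimated on the log scale for
positivity). Because $Y^*$ is linear in $t$, the cumulative hazard is
analytic per interval, $\xi_q e^{\gamma\,\mathrm{arm} + \alpha(\beta_0 +
b_0)}\,\Delta\,\frac{e^{\alpha s\Delta}-1}{\alpha s\Delta}
e^{\alpha s l}$ with $s$ the subject slope, handled by `expm1` with the
$\alpha s \to 0$ limit; the test suite verifies it against adaptive
quadrature to $10^{-8}$.

Each subject's likelihood is a two-dimensional integral over
$(b_0, b_1)$, evaluated by *pseudo-adaptive* Gauss–Hermite quadrature:
nodes are centered and scaled by the subject's empirical-Bayes posterior
mode and curvature from a preliminary REML LMM fit, held fixed during the
joint optimization. Nine nodes per dimension is the default; moving to
25 changes the log-likelihood by less than $10^{-4}$ on a typical
simulated trial. The inner loops, and an analytic gradient in the
optimizer coordinates, are compiled (Rcpp); the gradient is verified
against central finite differences in the tests. Initialization decouples
the processes (REML LMM; piecewise-exponential survival fit with
$\alpha = 0$); standard errors come from the observed information built
by differencing the analytic gradient, with the same `hessian_ok`
contract as the selection model.

*Event-time convention.* For observed trial data the dropout time is the
time of the last available visit, with completers censored at month 36 —
the only convention available when all we see is the visit grid
(`derive_dropout_times`). One should know that this coarsens a
continuous-time process: events are recorded up to one interval early and
exposure in the final interval is truncated, which inflates the
baseline-hazard levels and, when intervals are wide, the association
estimate (in simulation, roughly a factor two on $\alpha$ at trial-like
settings). For simulated trials the generator keeps the latent continuous
dropout time, and passing `dropout = sim_dropout_times(trial)` to
`fit_spm` fits the self-consistent exact-time likelihood; this is what
the parameter-recovery experiments use. Death is not distinguished from
questionnaire dropout, and there are no competing risks.

## The synthetic-trial generator

`sim_config()` fixes the study conditions; its defaults emulate the
motivating trial's structure: 130 subjects per arm, eight visits over 36
months, and trajectories with $\beta_0 = 60$, $\beta_1 = 0.5$,
$\beta_2 = -0.15$ — an intercept and a mild control-arm improvement of
the size reported for global health scores. No variance components are
reported for the motivating data, so the defaults are chosen once at
values a trialist would call realistic for 0–100 HRQoL dimensions:
between-subject intercept SD ≈ 17 points ($G_{11} = 300$), slope SD ≈ 0.7
points/month ($G_{22} = 0.5$, mildly negatively correlated with the
intercept), residual SD 10 points ($\sigma^2 = 100$). Dropout mechanisms:

* `mcar` — logistic with $\psi_1 = \psi_2 = 0$ ($\psi_0 = -0.55$, about a
  third of the at-risk subjects per visit, reaching ~90% cumulative
  dropout like the motivating data);
* `mar_dk` — dropout on the last observed score;
* `mnar_dk` — the published global-health dropout coefficients
  $(-0.808, -0.005, 0.005)$ as defaults;
* `mnar_spm` — continuous dropout times by piecewise-analytic inversion
  of the subject-specific cumulative hazard, censored at month 36, with
  the latent time stored;
* `pattern` — pattern labels drawn from given proportions with
  pattern-specific fixed-effect shifts.

Scores are generated unbounded; `truncate_scores = TRUE` clips to
[0, 100] *after* dropout as an opt-in robustness stressor, flagged on the
dataset, because the models assume Gaussian scores and recovery tests
should respect the models' own assumptions. Everything is reproducible
from the integer seed (R's default Mersenne–Twister stream). What the
generator does *not* emulate: item-level questionnaire structure, floor
and ceiling effects (unless truncation is switched on), intermittent
missingness, staggered entry, and death as a separate process — so a
green recovery suite says the estimators work when their assumptions
hold, not that real HRQoL data satisfy those assumptions.

Intermittent gaps in real data are handled by `monotonize()`: the
truncate-at-first-gap policy is this package's explicit convention (the
selection model is defined for monotone dropout only), not a recommended
scientific procedure.

## Numerical choices and scale

Convergence uses a relative log-likelihood tolerance of about $10^{-8}$
with box constraints keeping log-scale parameters finite; the LMM refits
from jittered starts if the first attempt fails. Percentages in
missingness summaries are rounded half-up to integers, with raw fractions
retained. The recovery experiments in `tests/testthat/test-acceptance.R`
use 100 replicates of 250–300 subjects — large enough that Monte-Carlo
error is a few percent of each target, small enough that the whole suite
fits in minutes; the mean-recovery checks are strict (two Monte-Carlo
standard errors), which makes them sensitive even to the ordinary
$O(1/n)$ bias of a maximum-likelihood estimator, and the selection-model
dropout coefficient sits at the edge of that band at these sample sizes.

## Known limitations

The selection model inherits its sensitivity to the normality of the
unobserved scores and its weak identification from the model class; the
pattern-mixture marginalization rests on linear extrapolation beyond
dropout; the shared-parameter model assumes conditional independence and
normal random effects, and its grid-time convention biases the hazard
scale as discussed above. None of the models can be validated against the
confidential motivating dataset; validation here is by construction:
exact decoupling identities, closed-form-versus-quadrature oracles, an
independent mixed-model implementation for the shared sub-model, and
parameter recovery under the generator's known truth.
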