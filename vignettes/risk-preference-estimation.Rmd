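---
title: "Estimating risk preferences across the lifespan: model, estimation and validation"
author: "riskspan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating risk preferences across the lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskspan)
```

## The behavioural model

The package targets a classic risky-choice design: on each trial a
participant chooses between a certain gain (by default $5) and a lottery
paying an amount $v$ with probability $p$ (and nothing otherwise). The 60
analysis trials cross 20 amounts spanning \$5–\$120 with three probability
levels (0.25, 0.5, 0.75).

Both options are valued by power-utility expected utility,

$$\mathrm{EU} = p \, v^{\alpha},$$

with the certain option evaluated through the same form at $p = 1$ (so
$\mathrm{EU}_{\text{safe}} = 5^{\alpha}$). The exponent $\alpha$ is the
risk-tolerance parameter: $\alpha = 1$ is risk neutrality over gains,
$\alpha < 1$ risk aversion, and larger $\alpha$ greater tolerance for
risk. Choice is stochastic through a logistic rule,

$$P_{\text{lottery}} =
  \frac{1}{1 + \exp\{-\sigma(\mathrm{EU}_{\text{lottery}} -
  \mathrm{EU}_{\text{safe}})\}},$$

where $\sigma > 0$ is the slope of the choice function: larger $\sigma$
means choices track the utility difference more deterministically.

Two conventions for $\sigma$ circulate in this literature. The package
defaults to the *slope* convention above ($\sigma$ multiplies the EU
difference), under which a fitted $\sigma \approx 1$ gives sensible choice
stochasticity at this task's utility scale; the *temperature* convention
($\sigma$ divides the difference) is available through the `convention`
argument of the likelihood and fitting functions, since the two are
reciprocal re-parameterizations.

### The covariate link

Scientific interest centres on how $\alpha$ varies across people, so
$\alpha$ is a linear function of participant covariates,

$$\alpha_i = \beta_0 + \textstyle\sum_k \beta_k x_{ik},$$

with five nested specifications: age only; right-posterior-parietal
grey-matter volume (rPPC GMV) only; age + rPPC GMV; rPPC GMV + global GMV;
and age + rPPC GMV + global GMV. Gender (0/1, female = 1) can be appended
to any of them. The link is kept *exactly* linear — positivity of
$\alpha$ is enforced by a floor (default 0.01) rather than, say, an
exponential transform, so that fitted coefficients are directly
interpretable as linear effects; the floor never binds in any default
configuration, and the fit records how often it does.

## Estimation

`fit_pooled()` maximizes the joint log-likelihood over
$(\beta_0, \ldots, \beta_k, \sigma)$ using all participants' choices at
once. Standard errors are clustered on participants with the score
sandwich $A^{-1} B A^{-1}$, where $A$ is the negative Hessian at the MLE
and $B$ sums outer products of *within-participant* score sums, scaled by
the small-sample factor $G/(G-1)$ for $G$ participants. This allows
arbitrary within-participant correlation of choice-level scores without
any random-effects assumption. (No additional degrees-of-freedom
correction is applied; with singleton clusters the estimator reduces to
the usual heteroskedasticity-robust sandwich up to $n/(n-1)$.) Wald
$z$-tests are two-tailed; the only one-tailed tests in the pipeline are
the model-free regression's, where the signs are predicted a priori.

Model comparison uses BIC $= k \ln(n) - 2\ln L$ with $n$ equal to the
number of *choice records* (the likelihood's observation count, the
~3,000-scale $n$), not the number of participants.

Numerical choices worth knowing:

* **Optimizer.** L-BFGS-B with the analytic gradient, box bounds on
  $\sigma$ ($[10^{-3}, 50]$), and five deterministic jittered restarts
  (fixed internal seed); ties are broken by likelihood, then by smaller
  parameter norm. Covariates enter on wildly different scales (years,
  ~0.35 a.u. regional GMV, ~600 a.u. global GMV), so each slope's search
  direction and jitter are scaled by the reciprocal of its covariate's
  standard deviation.
* **Guards.** Inside the likelihood $\alpha$ is boxed into
  $[\text{floor}, 20]$ — the cap only matters far from any plausible
  optimum, where $v^{\alpha}$ would overflow — and observed-choice
  probabilities are clipped at $10^{-12}$ before logging, with a counter.
  Non-finite objective or gradient values encountered during a wild
  restart are sanitized so the search can recover.
* **Degenerate inputs.** A dataset whose choices are all-lottery or
  all-safe is completely separated: the fit warns, flags the boundary and
  withholds the covariance rather than reporting one.

`fit_individual()` re-estimates $\alpha$ per participant by bounded
one-dimensional maximization ($\alpha \in [0.01, 4]$) with $\sigma$ held
at the pooled estimate of the corresponding population-level model —
Model 2's $\sigma$ for the $\alpha$-vs-GMV scatter, Model 3's for the
partial plots (configurable in `run_full_analysis()`). Participants who
always choose the certain option sit at the lower bound and are flagged.

`ols_one_tailed()` and `added_variable()` cover the model-free analysis:
an OLS of each participant's lottery-choice proportion on age and rPPC
GMV with one-tailed $p$-values in the predicted directions (negative for
age, positive for GMV), and Frisch–Waugh residualization so the partial
plots' slopes equal the multiple-regression coefficients exactly.

## The exclusion rule

Participants who chose a *dominated* lottery — one offering at most the
certain amount with probability below one — on strictly more than 50% of
dominated trials are excluded; such behaviour reveals a preference for
less money or task misunderstanding, and $\alpha$ is not estimable from
it. The denominator is dominated trials only: only there is the
preference demonstrable. The strictness matters (exactly half is kept)
and is pinned by tests.

## The synthetic cohort generator

No participant-level data accompany the study the package emulates, so
`generate_cohort()` provides cohorts with the same statistical structure,
making every estimation stage testable by parameter recovery. Defaults
are the study's printed conditions and are not tuning knobs:

| knob | default | rationale |
|---|---|---|
| participants | 52 | studied sample size |
| ages | mean 54.7, sd 22.1 on [18, 88] | printed demographics |
| age distribution | moment-matched scaled beta | bounded support with exact moment control; the shape is otherwise unreported |
| female fraction | 30/52 | printed composition |
| rPPC GMV | mean 0.35, sd 0.08 a.u. | see below |
| age–rPPC GMV correlation | −0.66 | printed correlation |
| global GMV | mean 600, sd 60 a.u.; age corr −0.45 | global decline is weaker than the focal regional decline; value unreported, chosen once |
| true link | $\alpha = 0.152 + 1.338\,\mathrm{GMV}$ | published GMV-model coefficients |
| true $\sigma$ | 0.986 | published slope |
| missingness | 1.38% per trial, independent | 43 of 3,120 trials missing in the study; mechanism unreported |

GMV enters in arbitrary units (it is a voxel-based-morphometry readout).
The default scale is an internal-consistency calibration: with the
age–GMV slope $r \cdot \mathrm{sd}_{\mathrm{GMV}} / \mathrm{sd}_{\text{age}}
= -0.66 \times 0.08 / 22.1 \approx -0.00239$ a.u./yr, the GMV
coefficient 1.338 implies an $\alpha$ drop of
$1.338 \times (-0.00239) \times 70 \approx -0.22$ across a 70-year span,
matching the age-only gradient $-0.003 \times 70 \approx -0.21$. GMV is
generated as a linear-in-age Gaussian with slope and residual sd chosen
so the population moments and the age correlation hit their targets
exactly.

What the generator does *not* emulate: heaping of ages, multimodal
cohorts, choice sequences with history dependence (fatigue, win-stay
behaviour), lapses or attention failures off the logistic model, and any
non-linear age–GMV relationship. Recovery tests passing therefore show
the estimator is correct *under the model*, not that the model is right
for any human sample. One visible consequence: under the logistic model
dominated choices occur more often than trained humans produce them, so a
default synthetic cohort loses a handful of participants to the exclusion
rule, where the original study lost 3 of 55.

## Validation strategy and problem sizes

The test suite validates each stage against an independent route:

* the pooled MLE against an exhaustive grid search on a 2-participant toy
  problem, and against Monte-Carlo recovery of the generating
  coefficients (1,000 participants for the age model, 5,000 for the GMV
  model — sizes at which the recovery tolerances of ±0.001 and ±0.1 are
  three or more Monte-Carlo standard errors wide);
* the clustered sandwich against the standard `sandwich::vcovCL`
  estimator on a clustered logistic GLM, against its closed-form
  reductions, and against a 400-replicate cluster bootstrap;
* interval calibration by 95% Wald coverage over 200 replicates at the
  studied size of 52 participants (accepted band 0.90–0.98);
* the generator's demographic calibration at n = 5,000, where sampling
  error on the age–GMV correlation is ~0.008;
* grid-independence of recovery, run on two different 20-amount spacings.

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_config(seed = 1))
report <- run_full_analysis(cohort$participants, cohort$records)
report
```

## Known limitations

* Inference relies on asymptotics in the number of clusters; at G = 52
  the $G/(G-1)$ correction leaves Wald intervals slightly liberal, which
  the coverage suite quantifies but does not correct. Cluster-bootstrap
  inference is deliberately out of scope as a primary method.
* The linear-with-floor link is non-smooth at the floor; all default and
  published-coefficient configurations stay strictly above it.
* Probability weighting, loss aversion, ambiguity attitudes and lapse
  parameters are intentionally outside the model.
* Individual fits from 60 binary choices are noisy (recovery to roughly
  ±0.15 in $\alpha$); they are display material, while inference rests on
  the pooled fits.
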