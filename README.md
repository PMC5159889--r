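# riskspan

Structural estimation of risk preferences from binary certain-versus-lottery
choices, built for lifespan studies that relate risk tolerance to age and to
grey-matter volume (GMV) covariates.

## The problem and the model

In the underlying task a participant repeatedly chooses between a certain
gain of $5 and a lottery paying an amount *v* ∈ [$5, $120] with probability
*p* ∈ {0.25, 0.5, 0.75} (60 trials: 20 amounts × 3 probabilities). Both
options are valued by power-utility expected utility

    EU = p · v^α,

where α is the risk-tolerance exponent (α = 1 risk-neutral, α < 1
risk-averse), and choice is stochastic through a logistic rule

    P(lottery) = 1 / (1 + exp(−σ · (EU_lottery − EU_safe))),

with σ the slope of the choice function. The scientific question — does
age itself, or age-related decline in right posterior parietal GMV, drive
increasing risk aversion across adulthood? — is posed by letting α vary
linearly with covariates, α = β₀ + Σ βₖ xₖ, across five nested models
(age; rPPC GMV; age + rPPC GMV; rPPC GMV + global GMV; all three), fit by
pooled maximum likelihood with standard errors clustered on participants
and compared by BIC. The pipeline also provides individual-level α fits
(σ fixed at the pooled estimate), a model-free OLS of each participant's
lottery-choice proportion with one-tailed tests in the predicted
directions, added-variable residualization for partial plots, and a
dominated-choice exclusion rule.

Because no participant-level data are publicly deposited for this design,
the package ships a calibrated synthetic-cohort generator
(`generate_cohort()`) reproducing the printed study conditions — 52 adults
aged 18–88 (mean 54.7, sd 22.1), GMV declining with age at r = −0.66,
published link coefficients as generating truth, 1.38% trial-level
missingness — so every stage is validated by parameter recovery.

## Worked example

```r
library(riskspan)
cohort <- generate_cohort(cohort_config(seed = 1))   # 52 synthetic adults
fit <- fit_pooled(cohort$records, cohort$participants,
                  covariates = "rppc_gmv")
fit
#> Pooled EU/logistic risk-preference fit
#>   observations: 3073, clustered on 52 participants
#>           Estimate Clustered SE       z Pr(>|z|)
#> intercept   0.2188       0.0277  7.9064        0
#> rppc_gmv    1.1237       0.0695 16.1751        0
#> sigma       1.0107       0.0660 15.3168        0
#>   logLik: -1304.15   BIC: 2632.4
```

The `rppc_gmv` row says each unit of regional GMV adds ≈1.12 to the
risk-tolerance exponent, with a participant-clustered SE and a Wald
z-test; the generating truth is 1.338, and across repeated 52-participant
cohorts the estimate scatters with a Monte-Carlo sd of ≈0.12, so this
draw sits about two sampling SDs low — 60 choices per participant is a
small-sample regime, which is exactly why inference clusters on
participants. `sigma` ≈ 1.01 is the choice-function slope. The full
pipeline — exclusion, all five models (plus gender variants), BIC
ranking, individual fits, partial plots, model-free regression — runs as

```r
report <- run_full_analysis(cohort$participants, cohort$records)
report$bic_table
#>    model log_likelihood k n_obs      bic rank
#> 1 Model1      -1197.514 3  2777 2418.816    5
#> 2 Model2      -1162.462 3  2777 2348.711    1
#> 3 Model3      -1160.057 4  2777 2351.830    2
#> 4 Model4      -1160.877 4  2777 2353.471    3
#> 5 Model5      -1159.607 5  2777 2358.860    4
```

(n_obs drops below 3,073 because a few simulated participants violate the
dominated-choice exclusion rule, as the stochastic choice model predicts.)
The GMV-only model ranks first here, as it should when GMV is the
generating truth. `write_report(report, "out/")` exports the tables;
`inst/cli/riskspan` wraps simulate / fit / analyze / recover as shell
verbs. See the vignette in `vignettes/` for the model's assumptions,
numerical choices and what recovery tests do and do not establish.

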