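# adtraj — adherence trajectory modeling from pharmacy claims

`adtraj` phenotypes longitudinal medication adherence from
administrative pharmacy claims. It was built around the workflow used to
study nintedanib adherence in older adults with idiopathic pulmonary
fibrosis, but every stage is generic claims methodology:

* **PDC engine** — daily supply calendars with stockpiling (overlapping
  supply carries forward), monthly proportion of days covered over
  30-day months, dichotomized adherence indicators (PDC ≥ 0.8), overall
  PDC.
* **Cohort filters** — sequential inclusion/exclusion rules on
  claims-shaped tables (age, continuous enrollment, diagnosis
  confirmation with the two-outpatient/14-day rule, baseline drug
  exclusions, institutional care, dual eligibility, survival) with an
  attrition report.
* **GBTM** — group-based trajectory models: a G-component mixture with
  multinomial-logit membership and, per group, a logistic polynomial (in
  standardized month) for the monthly adherence indicators. Estimated by
  EM with multiple restarts; BIC-guided specification search over the
  30-cell grid (1–5 groups × order 0–5) followed by per-group
  polynomial-order reduction under Wald significance and a ≥ 5 %
  minimum-group-share rule.
* **Diagnostics** — average posterior probability of assignment (APP),
  odds of correct classification (OCC), relative entropy, observed vs
  fitted trajectory tables, spaghetti-plot exports.
* **Membership regression** — fractional multinomial logit of the
  posterior membership probabilities on baseline covariates, with
  heteroskedasticity-robust (sandwich) standard errors and adjusted odds
  ratio tables.
* **Synthetic data** — a scenario-driven generator (latent trajectory
  groups, covariates, fills/enrollment/diagnosis tables) so the whole
  pipeline runs and is tested without restricted data.

The core model, for adherence indicator $y_{it}$ of patient $i$ in month
$t$:

$$P(y_i) = \sum_{g=1}^{G} \pi_g \prod_t p_{gt}^{y_{it}}(1-p_{gt})^{1-y_{it}},
\qquad \operatorname{logit} p_{gt} = \beta_{g0} + \beta_{g1} z_t + \dots + \beta_{gd_g} z_t^{d_g}.$$

## Worked example

```r
library(adtraj)

# Stockpiling: a refill at day 20 overlapping a day-0 fill is deferred,
# so days 0-59 are covered.
cal <- build_supply_calendar(day = c(0, 20), days_supply = c(30, 30))
sum(cal)
#> [1] 60
monthly_pdc(cal)[1:3]
#> [1] 1 1 0

# Five-group synthetic cohort emulating the published nintedanib
# adherence structure (n = 1798, 12 monthly indicators).
scn <- default_scenario("nintedanib5", seed = 42)
coh <- simulate_cohort(scn)
fit <- fit_gbtm(coh$panel, trajectory_spec(5, 3), starts = 5, seed = 7)
fit
#> Group-based trajectory model: G = 5, orders = (3, 3, 3, 3, 3)
#>   logL = -7681.5924  k = 24  BIC = -7771.5255  N = 1798
#>   pi: 0.1120 0.1385 0.2090 0.4331 0.1074
#>   best start 3 (converged)

model_diagnostics(fit, coh$panel)
#> Trajectory model adequacy:
#>  group     pi assigned    APP   OCC
#>      1 0.1120   0.1023 0.8731 54.59
#>      2 0.1385   0.1296 0.8551 36.70
#>      3 0.2090   0.2164 0.9196 43.28
#>      4 0.4331   0.4388 0.9813 68.84
#>      5 0.1074   0.1129 0.8628 52.25
#> Relative entropy: 0.8747
#> Pass flags: APP>=0.7 TRUE | OCC>5 TRUE | entropy>=0.7 TRUE
```

Reading the output: group 4 is the consistently-high-adherence group —
its estimated mixing probability 0.433 recovers the generating share
0.431 (the generator draws groups from the published proportions), and
group 3 (0.209) recovers the early-discontinuation share 0.215. All
groups clear the published adequacy thresholds: APP ≥ 0.7, OCC > 5, and
relative entropy ≥ 0.7.

The full two-stage specification search (30-model BIC grid, then
order reduction) is one call:

```r
sel <- select_model(coh$panel, starts = 3, seed = 11)
sel$winner_spec   # stage-1 winner: G = 5
sel$final_fit     # reduced per-group orders
```

The end-to-end pipeline (simulate → filters → PDC → selection →
diagnostics → membership regression), writing CSV/JSON artifacts plus a
manifest:

```r
run_pipeline(list(scenario = "nintedanib5", outdir = "out", seed = 1))
```

or from a shell:

```sh
Rscript -e 'adtraj::cli_main()' run --scenario nintedanib5 --outdir out --seed 1
```

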