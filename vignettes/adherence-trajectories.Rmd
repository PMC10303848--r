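---
title: "Modeling medication adherence trajectories from pharmacy claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling medication adherence trajectories from pharmacy claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adtraj)
```

## The problem

A single annual proportion of days covered (PDC) summarizes a patient's
medication adherence in one number and hides when, and how, adherence
changes. For chronic therapies such as antifibrotics in idiopathic
pulmonary fibrosis (IPF), the clinically interesting structure is
longitudinal: some patients stay adherent all year, some taper slowly,
some stop within a few months. `adtraj` implements the standard
claims-based workflow for recovering that structure:

1. build daily **supply calendars** from fill dates and days' supply, with
   stockpiling of overlapping supply;
2. compute **monthly PDC** over consecutive 30-day months and dichotomize
   at PDC ≥ 0.8;
3. fit **group-based trajectory models** (GBTM) to the 12 monthly
   indicators and select a specification;
4. check classification adequacy;
5. relate group-membership probabilities to baseline covariates with a
   **fractional multinomial logit**.

Because the motivating data (Medicare claims) cannot be redistributed,
the package ships a synthetic-cohort generator whose default scenario
reproduces the statistical structure of a published five-group nintedanib
adherence cohort, so every stage is testable end to end.

## The model

Let $y_{it} \in \{0,1\}$ indicate whether patient $i$ was adherent
(monthly PDC ≥ 0.8) in month $t = 1, \dots, 12$. The GBTM is a finite
mixture

$$
P(y_i) \;=\; \sum_{g=1}^{G} \pi_g \prod_{t=1}^{12}
p_{gt}^{\,y_{it}} (1 - p_{gt})^{1-y_{it}},
\qquad
\operatorname{logit} p_{gt} = \sum_{j=0}^{d_g} \beta_{gj} z_t^{\,j},
$$

where $\pi$ is an intercept-only multinomial-logit mixing distribution,
$z_t$ is the standardized month index ($z_t = (t - 6.5)/3.452$ for a
12-month panel), and $d_g \le 5$ is group $g$'s polynomial order.
Conditional on group, months are independent — the defining GBTM
assumption.

**Estimation.** EM: the E-step computes posterior membership
probabilities $\hat p_{ig} \propto \pi_g f_g(y_i)$; the M-step sets
$\pi_g$ to the mean posterior and refits each group's polynomial by a
posterior-weighted logistic solve on the aggregated month counts
(successes $\sum_i \hat p_{ig} y_{it}$ out of $\sum_i \hat p_{ig}$
trials per month — twelve observations, so each M-step is essentially
free). The published analysis used direct ML in commercial software; EM
reaches the same optimum and its monotone likelihood is easy to verify.

**Specification search.** Stage 1 fits the 30-cell grid (1–5 groups ×
common order 0–5) and keeps the best BIC,
$\mathrm{BIC} = \log L - \tfrac{k}{2}\log N$ with $N$ = patients (larger
is better; the patient-month convention is available as an option since
the original report does not state which was used). Stage 2 repeatedly
tests each group's highest-order coefficient (Wald, normal reference,
$\alpha = 0.05$); while any is non-significant the group with the
largest p-value is reduced by one order and the model refit — one change
per refit makes the trace deterministic. Orders floor at 0 (the
published rule would otherwise loop), and the smallest assigned group
must hold ≥ 5 % of the sample; on violation the search re-runs at
$G-1$, flagged, since the source states the constraint but not a remedy.

**Adequacy.** Average posterior probability of assignment
(APP$_g$ ≥ 0.7), odds of correct classification
$\mathrm{OCC}_g = \frac{\mathrm{APP}_g/(1-\mathrm{APP}_g)}{\pi_g/(1-\pi_g)} > 5$
(using estimated $\pi$, the standard convention; assigned shares are an
option), and relative entropy
$E = 1 - \sum_{ig}(-\hat p_{ig}\ln\hat p_{ig}) / (N \ln G) \ge 0.7$.

**Membership regression.** With posterior probabilities as fractional
outcomes $s_{ig}$ (rows on the simplex), the fractional multinomial
logit maximizes the quasi-log-likelihood
$\sum_i \sum_g s_{ig} \log \mu_{ig}(x_i'\gamma)$ with multinomial-logit
means and a reference group fixed at zero. Newton iterations with step
halving from a zero start converge fast (the objective is concave in
$\gamma$); inference uses the sandwich $A^{-1} B A^{-1}$ with per-patient
score outer products, robust to the heteroskedasticity fractional
outcomes necessarily have. Effects are reported as adjusted odds ratios
$e^{\gamma}$ with Wald intervals.

## Numerical choices

* **Linear-predictor clipping at ±12.** The index prescription carries at
  least 30 days of supply, so month 1 is structurally all-adherent in
  claims-derived panels and perfectly separated. Clipping bounds the
  likelihood; at $|{\pm}12|$ the fitted probability is within $6\times
  10^{-6}$ of its limit, so the bias is negligible.
* **Ridge $10^{-8}$** in each weighted logistic solve keeps separated
  M-steps full rank; its displacement of interior optima is below
  $10^{-10}$.
* **Restarts.** Default 10. Restarts cycle three initializations:
  equal-frequency bins of jittered adherence row sums (level), k-means on
  the 0/1 month patterns (shape), and random responsibilities. Row-sum
  binning alone proved insufficient: on some simulation seeds every such
  start entered the same inferior basin, which we detected because
  parameters built from the true labels had visibly higher likelihood.
* **Convergence**: relative log-likelihood change $< 10^{-7}$, max 500
  EM iterations; ties between equally good starts go to the earlier one.
* **Standard errors** come from the numerically differentiated observed
  information of the full mixture log-likelihood at the optimum
  (central differences, step $10^{-4}\max(1,|\theta_j|)$); a singular
  information matrix flags the affected Wald tests as non-significant
  rather than failing.
* **Stockpiling** uses full carry-forward — a fill's supply starts when
  accumulated supply runs out — the standard PDC convention; the source
  names stockpiling without fixing the rule, and no cap is applied since
  none is described. The pointer implementation is property-tested
  against a day-by-day pill-queue simulation.
* **Boundaries**: monthly PDC ≥ 0.8 is inclusive; the two-outpatient
  diagnosis gap "≥ 14 days" is inclusive at exactly 14; month $m$ covers
  days $[30(m-1), 30m)$; baseline is $[-360, -1]$ and follow-up
  $[0, 359]$ — one 30-day-month time base for both adherence and
  eligibility, since the study schematic says "one year" without day
  counts.

## The synthetic world

`default_scenario("nintedanib5")` encodes the published five-group
structure: mixing shares $(0.431, 0.119, 0.104, 0.132, 0.215)$
renormalized from printed percentages that sum to 100.1, and five fixed
trajectory coefficient vectors (registry constants, not estimates) whose
inverse-logit curves satisfy the qualitative descriptions: *high*
adherence near-constant at ≈ 0.97; *moderate* settling between 0.4 and
0.6 by month 3; *high-then-poor* high through month 7 then falling and
leveling near month 11; *delayed-poor* declining steadily then dropping
sharply after mid follow-up; *early-poor* near 0 from month 4. Cohort
size defaults to 1798, the published analytic sample.

Covariates (age, sex, deprivation index with a small missingness rate,
comorbidity and medication counts, utilization flags) are drawn from
marginal distributions matched to the published baseline table. They are
generated **independently of group** in the default scenario: the
published marginal shares are part of the stated world, and covariate
effects on membership would perturb them. Covariate-driven membership is
fully supported (`membership_coefs`) and exercised in tests with custom
scenarios; consequently the default pipeline's adjusted odds ratios are
near-null by construction, and the published AOR table is not a
reproduction target (it derives from restricted data).

What a green test establishes, and what it does not: recovery tests show
the estimator finds the generating mixture when the GBTM's own
assumptions hold (conditional independence within group, logistic
polynomial curves). Real claims exhibit serial dependence within
patients beyond group membership, drug switching, censoring by death,
and fill-timing irregularities the generator only partially mimics
(`markov_persistence` and `short_fill_prob` knobs exist for robustness
checks but default to 0, matching the model's assumptions). Claims
generation also forces month-1 adherence via the index fill, so
round-trip reconstruction is exact only from month 2 onward.

## Open design points we had to decide

* The source does not state whether the structurally all-adherent month 1
  entered estimation; it is included here (clipping handles the
  separation).
* BIC sign/N convention is unstated; both N conventions are implemented,
  patients being the default.
* The entropy formula is uncited; the standard normalized
  classification-entropy definition is used.
* The remedy for a min-share violation after order reduction is
  unstated; re-running at $G-1$ with a flag is this package's choice.
* Scenario files are plain-text JSON rather than YAML: no YAML parser is
  available in the supported dependency set, and JSON keeps the config
  equally inspectable.

## Limitations

Identification is up to label permutation (use `match_groups()` against
a known scenario); EM can in principle still miss the global optimum at
very low restart counts; standard errors are asymptotic and ignore the
two-stage nature of "assign then describe" workflows; and the cohort
filters operate on semantic flags (`IPF`, `SNF`, ...) rather than real
ICD/NDC vocabularies, which is deliberate — code-system parsing is out
of scope.
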