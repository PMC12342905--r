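---
title: "Modelling the cost of cardiovascular disease in the UK"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost of cardiovascular disease in the UK}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdcoi)
```

## The problem

Cardiovascular disease (CVD) is costed here from a societal perspective as
the sum of ten components over the four UK nations: seven direct components
(inpatient, outpatient, accident & emergency, primary care, medications,
medical devices, and long-term care split into post-stroke care and vascular
dementia) and three indirect ones (production losses to morbidity and to
mortality, and informal care). Five components are read straight from
published national statistics; five are modelled. The package implements the
full pipeline — ledger arithmetic, top-down apportionment, the modelled
components, and sensitivity analysis — with packaged published cost tables
and synthetic-data generators so that every stage is testable offline.

## The cost ledger

Every stage writes `money` amounts tagged with a price year into a
`cost_ledger` keyed by (component, nation, fiscal year). Amounts are doubles
carried at full precision; rounding happens only at report time
(`round_half_up`, since published tables round half up, while base R rounds
half to even). Arithmetic across price years is a hard error — amounts must
be re-expressed with `inflate()` against a GDP-deflator table first. Future
costs are discounted at the HM Treasury rate of 3.5% per annum
(`discount_factor`), and foreign-currency inputs convert at mid-year rates
(`convert_currency`). All packaged figures are in 2022 real terms.

One wrinkle worth knowing: the packaged tables are printed at penny
precision, so a UK total printed in the source can differ from the sum of
its four printed nation cells by up to a penny per cell. The additivity
tests therefore assert agreement within one penny per summed cell rather
than exact equality. Relatedly, the printed medications change since 2015
(15.3%) is not quite what the printed table cells give (15.2% at 1 dp); the
package reproduces the absolute fall (£348.3 mn) exactly and reports the
recomputed percentage, leaving the 0.1 pp discrepancy documented rather than
reconciled.

## Top-down apportionment

Aggregate NHS budgets and activity are attributed to CVD with a small set of
published shares, shipped as a versioned YAML registry
(`load_apportionment_rules()`) rather than hard-coded, because the
sensitivity analysis varies them: 17.9% of general-medicine activity, a 30%
stroke/TIA-to-neurology ratio, a 7.2% vascular-to-general-surgery ratio, a
12% hypertension proxy for primary-care consultations, and a 17% vascular
share of dementia. Fractional attributed counts stay fractional until
costing. Where both uncoded-consultation attribution and the generalist
share apply, coding attribution is applied first; the source is silent on
the order, and this choice is the documented one.

Wales reports only a gross circulatory secondary-care budget, so the Welsh
split is estimated: outpatient by England's outpatient-to-secondary ratio
(`wales_outpatient_share`), A&E from activity, and inpatient as the residual
(`wales_inpatient_residual`), which recomposes the budget exactly. Applying
England's 2021/22 ratio to the recomposed Welsh budget reproduces the
packaged Welsh outpatient cell only to about 0.6% — the published split used
year-specific unit-cost routes not fully specified in the main text — so the
cross-route consistency test asserts 1% rather than exact agreement.

## Post-stroke long-term care

Care-home use after stroke is modelled as a discrete-time Markov cohort.
The default state set is `{home, community, care_home, death}` (the pathway
narrative: discharge home directly or via early-supported-discharge and
community teams), configurable where audit data support more states.
Conventions, chosen for simplicity and stated so results are interpretable:

* annual cycles, no half-cycle correction;
* costs accrue at cycle start, so a trace over `n` cycles costs its first
  `n` rows and not the final occupancy;
* transition probabilities are maximum-likelihood row-normalised counts
  (`counts_to_probabilities`); an absorbing state may lack observed exits
  and becomes an identity row, any other zero row is an error.

Transition uncertainty uses Dirichlet rows with the observed counts as
concentration parameters — the conjugate posterior for multinomial
transitions and standard health-economics practice — implemented via
independent gamma draws so that never-observed transitions stay at exactly
zero. Vascular-dementia long-term care is not modelled dynamically: it is
the 17% share applied to an externally modelled total dementia social-care
cost (`vad_ltc_cost`).

The cohort propagation is verified against brute-force matrix powers to
1e-12 on three-state models, and the sampler against the Dirichlet mean over
10 000 draws.

## Informal care

The contribution at the heart of the indirect side is the average marginal
effect (AME) machinery. For a binary outcome (severe disability; receiving
in- or out-of-household help) a logistic regression is fitted and the AME of
the CVD flag is the sample mean of the discrete change in predicted
probability when the flag is switched, all other covariates at observed
values. For carer contact frequency a proportional-odds model
(`MASS::polr`) over `none < annually < monthly < weekly < daily` yields
per-category AMEs, which sum to zero across the full category set by
construction. Standard errors are delta-method: analytic gradients for the
logistic case, a central-difference Jacobian over the stacked
(coefficients, cutpoints) vector for the ordered case. Confidence intervals
use z = 1.96 exactly, and report at 4 decimal places — this reproduces the
majority of the published margin-table bounds exactly and all of them to
within one 4-dp ulp (the published bounds were computed from unrounded
margins; e.g. the severe-disability lower bound prints 0.1375 where the
rounded margin gives 0.1374).

The aggregate annual cost is a product:

    population over 50
    x CVD prevalence
    x AME(severe disability)
    x AME(requiring help)
    x sum over carers 1..3 and frequencies of
        AME(frequency) x contacts/year x hours/contact x hourly wage

with annualisation daily = 365, weekly = 52, monthly = 12, annually = 1.
Choices made where the source is silent, each of which is a modelling
convention rather than a published rule:

* "requiring help" combines the in-household and out-of-household margins
  additively (the result must stay a proportion; the constructor rejects
  anything outside [0, 1]);
* CVD prevalence is the respondent-level union of heart attack,
  hypertension and stroke flags, not the sum of three prevalences;
* carers of different frequencies for one respondent contribute additively
  through the inner sum; the per-term composition is attached to every
  result (`attr(x, "terms")`) so the factorisation is auditable;
* carer hours are valued at the average hourly wage for employed carers and
  the minimum wage otherwise, with siblings, spouses, friends and parents
  of respondents over 65 treated as retired (minimum wage).

A respondent-level brute force (composing the fitted per-respondent
probability changes and averaging up) agrees with the aggregate
product-of-averages formula to about 3% under the default generator. The
gap is real, not numerical: the disability and help deltas are positively
correlated across respondents (both rise with age and comorbidity), and the
product of averages drops that covariance. The property test bounds the
discrepancy at 5% and this is the honest statement of how far the aggregate
formula can be trusted against its own microdata.

PSA samples every margin independently from a normal centred on its
estimate with its standard error, truncated to [0, 1] by re-draw; no
correlation structure is imposed, matching the absence of a published one.

## Production losses

Mortality uses the human-capital approach: deaths by age band and sex are
valued at the present value of expected earnings (employment rate times
average wage per band) from the band's integer midpoint age — working-age
floor 15 — to retirement at 65, discounted at 3.5%. The year-of-death term
is counted undiscounted and discounting starts the following year; the
source says only "serially discounted", so this convention is stated
explicitly and verified against the geometric-series annuity closed form to
1e-8 on flat profiles. Employment rates and wages are held at the analysis
year for all future years. Morbidity is sickness days times the average
daily wage, plus benefit claims (weekly amount x claimants x weeks the
claim runs in the year, the operationalisation of "adjusted for the time
the claim had been in place"); disability-allowance dementia claims are
scaled by the 17% vascular share before costing.

## Sensitivity analysis

`one_way()` produces tornado entries — vary one parameter to its low/high
limit, report the signed % change of the total, sort by swing — and is
checked against the analytic |coefficient x range| ranking on linear
models. `run_psa()` draws all parameters independently (one seed, one
stream, draw order fixed by spec order, so runs are bit-reproducible) and
summarises trials with quartiles by linear interpolation between order
statistics (`stats::quantile` type 7; box-plot conventions matter, so the
choice is pinned here), with whiskers at the minimum and maximum.
`combine_extremes()` converts per-component PSA extremes into tornado
entries for an additive total.

## What the synthetic generators emulate — and what they do not

`gen_survey()` mirrors the structure of the ageing-survey microdata the
informal-care model needs: ages uniform on 51–90, a CVD flag drawn
independently of the other covariates at 50% prevalence (realistic for a
50+ population once hypertension is included), binary outcomes from
logistic models, carer frequencies from proportional-odds models with the
no-gaps carer-slot structure enforced, and gamma hours per contact (mean
4 h). Default coefficients put the true disability AME near 0.149 and the
first-carer daily AME near 0.125 — the magnitudes the published fits report
— and covariate effects are weak, consistent with the low pseudo-R² of
those fits. Every generator returns `(data, truth)`: the analytic AMEs
implied by its own coefficients over the generated covariates, so recovery
tests have an oracle without re-deriving it.

`gen_stroke_counts()` draws multinomial pathway counts around a known
transition matrix; `gen_labor_and_deaths()` produces age-increasing death
counts and hump-shaped employment/wage profiles at national scale.

What passing tests on these data do **not** show: the generators are
unweighted, impose no survey design, no missingness, no recall error, no
correlation between CVD and the covariates, and no attempt to match real
survey marginals beyond structure. Parameter recovery on synthetic data
demonstrates that the estimators are correct, not that the published
modelled totals (informal care £6.38 bn, etc.) are reproducible — those
depend on restricted microdata and are out of reach by construction. The
fixture-based identities are the part of the published results the package
reproduces exactly.

## Problem sizes and numerical tolerances

The test suite uses survey replicates of n = 4 000–20 000 (20 replicates
for CI-coverage checks, which pass at ≥ 80% coverage by a binomial bound at
n = 20), 1 000-trial PSAs, 10 000 Dirichlet draws for the sampler-mean
check, and 5–20-cycle cohorts — sizes at which each check is sharp while
the whole suite stays around a minute. Tolerances: 1e-12 for cohort algebra
against matrix powers, 1e-8 for the annuity closed form, 1e-9 relative for
inflation round trips, one penny per summed printed cell for table
additivity, and Monte-Carlo standard-error bounds for stochastic checks.

## Known limitations

* Transition probabilities are time-homogeneous; the stroke pathway is
  improving year on year, so the model is only valid near its data window.
* Heart-failure long-term care is excluded (no usable disposition data);
  the long-term-care total is conservative.
* The aggregate informal-care formula drops respondent-level covariance
  between its margin factors (measured ~3% here).
* Intangible (quality-of-life) costs are out of scope.
* Extrapolations from England (devices, A&E attribution, primary-care unit
  costs) inherit England's structure for the other nations.
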