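---
title: "Modelling survival trends with joinpoints: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling survival trends with joinpoints: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(joinsurv)
```

## The model

`joinsurv` analyzes grouped survival data by single calendar year of
diagnosis. Follow-up is discretized into annual intervals, interval $j$
covering $(j-1, j]$ years since diagnosis. The hazard of dying of the
disease for patients diagnosed in year $x$ is assumed proportional across
diagnosis years,

$$\lambda(t \mid x) = \lambda_0(t)\, e^{h(x)},$$

with one baseline hazard mass per interval, $\alpha_j = \log \lambda_{0j}$,
and a continuous piecewise-linear calendar effect

$$h(x) = \beta\,(x - a) + \sum_{k=1}^{K} \delta_k (x - \tau_k)^+,$$

where the $\tau_k$ are the joinpoints, $(u)^+ = \max(u, 0)$, and $a$ is an
anchor year used purely for numerical conditioning (the first diagnosis
year; every prediction and trend measure is invariant to it, which the test
suite asserts to $10^{-10}$). With $K = 0$ the model is an ordinary
proportional-hazards regression on diagnosis year. Net interval survival is
$s_j(x) = \exp\{-e^{\alpha_j + h(x)}\}$ and cumulative net survival
satisfies $S(t \mid x) = S_0(t)^{\exp h(x)}$, which equals the product of
the interval survivals exactly.

Three data modes are supported. *Relative* survival compares the cohort's
all-cause mortality with the expected mortality of a matched general
population: the model's net survival is multiplied by the supplied expected
interval survival $e_j(x)$ to give the all-cause interval death probability
$\pi = 1 - e_j(x)\, s_j(x)$ entering the likelihood. *Cause-specific* and
*overall* modes set $e \equiv 1$ and differ only in what the death counts
mean.

## Likelihood and estimation

Each (year, interval) cell contributes a grouped quasi-binomial term
$n^{\mathrm{eff}} \{ y \log \pi + (1 - y) \log (1 - \pi) \}$ with
$n^{\mathrm{eff}} = n - l/2$ the actuarial effective denominator (number at
risk minus half the losses) and $y$ the observed death fraction. The
denominators are non-integer and enter as prior weights; no rounding is
applied to the data. This is the canonical discrete-time realization of a
model that is linear on the log hazard scale: with a complementary log-log
link, $\operatorname{cloglog}(1 - e\,s) $ is exactly
$\alpha_j + h(x)$ when $e = 1$, and the relative-survival multiplier enters
as a per-cell modification of the link.

At fixed joinpoints the likelihood is maximized by Fisher-scoring IRLS
written directly against this likelihood (the per-cell expected-survival
multiplier makes the relative-survival link observation-specific, which the
`stats::family` machinery does not express; in cause-specific mode the
solution coincides with a weighted `cloglog` GLM, and the test suite uses
`glm.fit` as an independent cross-check, alongside a quasi-Newton maximizer
of the likelihood itself in relative mode). Safeguards: step-halving
whenever a scoring step would reduce the likelihood (at most 30 halvings),
and fitted probabilities clipped to $[10^{-12}, 1 - 10^{-12}]$ with a clip
counter reported on the fit. Convergence is declared when the score
equations are satisfied — maximum absolute score below $10^{-7}(|\ell|+1)$
— or, as a fallback, when the relative log-likelihood change stays below
$10^{-8}$ on three consecutive iterations; the cap is 100 iterations. The
covariance of the free parameters $(\alpha_1..\alpha_J, \beta,
\delta_1..\delta_K)$ is the inverse *observed* information (analytic
Hessian, validated against finite differences in the tests); joinpoint
locations are treated as fixed when computing standard errors.

Degenerate designs are refused rather than silently fitted: a fit needs at
least two diagnosis years per segment, and a rank-deficient design matrix
(collinear hinge columns) is an error naming the problem.

## Joinpoint search and model selection

Candidate joinpoints are integer calendar years within the fitted range.
The grid excludes `min_years_before_first` years at the start (default 3)
and `min_years_after_last` at the end (default 5), and enforces
`min_years_between` (default 2) between consecutive joinpoints. For each
$K$ up to `max_joinpoints` (at most 5) every admissible configuration is
fitted; the converged fit with the largest log-likelihood is retained, ties
broken deterministically toward the earliest configuration in lexicographic
order, so the search is reproducible and safely parallelizable in
principle. The final model minimizes

$$\mathrm{BIC} = -2\ell + p \log n \quad\text{or}\quad
  \mathrm{AIC} = -2\ell + 2p,$$

with $n$ the number of (year, interval) cells — the total number of
follow-up years over all diagnosis years — and $p = J + 1 + 2K$: each
joinpoint costs two parameters, its slope change and its searched location.
Counting the location is a deliberate choice (the selection literature for
segmented models varies here); it penalizes the search itself and makes BIC
more conservative, which matches its intended role as the parsimonious
default. BIC is the default criterion; AIC is reported alongside and can be
chosen instead — on the same ladder AIC never selects fewer joinpoints than
BIC, which the tests assert on simulated designs.

## Trend measures

For segment $m$ with slope $\beta^* = \beta + \sum_{k \le m}\delta_k$:

* **APC_D** $= 100\,(e^{\beta^*} - 1)$, the annual percent change in the
  conditional probability of cancer death. It is follow-up-free and
  constant within a segment; its SE is the delta-method form
  $100\, e^{\beta^*}\,\mathrm{se}(\beta^*)$.
* **AAC_S(t)**, the average of $S(t \mid x+1) - S(t \mid x)$ over the
  segment's diagnosis years, in percentage points. The average telescopes
  exactly to $100\,[S(t \mid x_{\mathrm{end}}) - S(t \mid
  x_{\mathrm{start}})]/(x_{\mathrm{end}} - x_{\mathrm{start}})$; the
  implementation uses the telescoped form and the tests assert the identity
  to $10^{-12}$. The SE propagates the analytic gradient of the telescoped
  expression through the parameter covariance, using
  $\partial \log S / \partial \alpha_j = -e^{\alpha_j} e^{h(x)}$ (for
  $j \le t$), $\partial \log S / \partial \beta = \log S \cdot (x - a)$ and
  $\partial \log S / \partial \delta_k = \log S \cdot (x - \tau_k)^+$. A
  central-finite-difference fallback (`se_method = "numeric"`, relative
  step $10^{-6}$) exists to validate the analytic gradient and for any
  future reparametrization. Arbitrary year windows are allowed, including
  windows beyond the data (they use the projected trend); a single-year
  window is rejected because an annual change is undefined on it.

Both measures carry 95% normal confidence intervals; a trend whose interval
spans zero is marked `ns`, otherwise `up`/`down` by sign. Within any
segment the two measures have opposite signs by construction. The report
table flags, without filtering, segments with AAC_S above one percentage
point or APC_D below −5 percent.

Projection extends the last segment's slope: because every hinge
$(x - \tau_k)^+$ is active past the last joinpoint, simply evaluating
$h(x)$ at $x$ beyond the data extends the final trend linearly with no
special casing. Projected values — future diagnosis years, and deeper
follow-up than a recent year has accrued — are flagged, and a caution is
emitted when the last joinpoint lies within five years of the last data
year, where extrapolation rests on a short final segment.

## The simulator

`sim_config()`/`simulate_table()` generate grouped tables from a known
joinpoint truth, so that every estimator in the package can be tested for
recovery without registry data. The walk per diagnosis year draws losses
$\sim \mathrm{Bin}(n, \text{loss\_prob})$, then deaths
$\sim \mathrm{Bin}(\mathrm{round}(n - l/2), \pi)$ over the half-loss
exposure — the same actuarial convention the estimator uses, so the
life-table estimator is unbiased for the generative interval survival (the
rounding of the non-integer exposure is the only approximation, of order
$1/n$). Defaults emulate a registry extract: diagnosis years 1975–2015,
ten annual intervals, relative mode with constant expected interval
survival 0.97 (a typical annual expected survival in an elderly cancer
population), 2% annual loss to follow-up, a first-year net survival of 0.80
flattening toward 0.97, and a single joinpoint in 1995 where a slow
improvement ($\beta = -0.005$) accelerates by $\delta = -0.03$ — the
mid-1990s acceleration pattern typical of sites transformed by new
therapies. An optional non-proportional switch multiplies $h(x)$ by a
factor for late intervals after a break year, reproducing the situation
where a treatment mainly benefits patients who have already survived some
years; `true_summaries()` refuses to report closed-form trend truths for
such configs since the generative process then lies outside the model
class. A `data_cutoff_year` truncates follow-up for recent diagnosis years,
giving the ragged tables registries actually deliver.

What the simulator does *not* emulate: age structure and age-standardized
relative survival, period/hybrid estimation, dependence between censoring
and prognosis, within-year seasonality, reporting delay, and
stage-migration artifacts. Passing recovery tests on these tables therefore
shows the estimator is correct for the model and sampling scheme, not that
the model fits any particular registry series — the residual diagnostics
(notably the interval-wise death-probability display) are the tool for the
latter.

## Study sizes used in the test suite

The suite's simulation studies use 20 diagnosis years with five follow-up
intervals. Oracle-agreement checks run at 2,000 diagnoses/year; joinpoint
recovery and CI calibration use 50 grid-search replicates and 200
fixed-joinpoint replicates at 5,000 diagnoses/year (selection over
$K \le 2$ for a one-joinpoint truth); the delta-method SE is validated
against a 200-replicate parametric bootstrap at 2,000/year. These sizes
give simulation noise well inside the asserted bands (e.g. binomial SE
$\approx 1.5\%$ on a 95% coverage estimate from 200 replicates) while
keeping the default test run to about a minute.

## Numerical choices and degenerate inputs

* Observed relative survival above 1 (common in real tables) is retained as
  data, never clamped; the fitted model is bounded in $(0, 1]$ by
  construction.
* An observed interval with everyone dying before the last follow-up
  interval flags the cohort with a warning (cumulative survival hits zero;
  the Greenwood SE is infinite there) but does not abort.
* Life-table coherence is enforced on read: the at-risk count of interval
  $j+1$ must equal interval $j$'s at-risk minus its deaths and losses;
  truncated tables are rejected with the offending cell named.
* The simulator requires an explicit seed, echoes it into its output
  metadata, and restores the caller's RNG state, so simulated fixtures
  cannot silently depend on session state.

## Limitations

The proportionality assumption — the calendar effect scales the baseline
hazard identically at every follow-up interval — is the model's main
restriction; when it fails, early- and late-interval death probabilities
show opposite-signed systematic residuals, and restricting `max_followup`
(to 2 or 5 years) both diagnoses and mitigates the problem at the cost of
only modelling short-term survival. Joinpoint locations are treated as
fixed in all covariances, so confidence intervals do not carry
location-search uncertainty. Joinpoints are restricted to integer years
within the data range. Covariates other than diagnosis year (age, stage as
model terms rather than strata) and joint inference across cohorts are out
of scope; cohorts are fitted independently.
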