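---
title: "Identifying non-medically indicated caesarean sections in claims data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying non-medically indicated caesarean sections in claims data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmics)
```

## The problem

Swiss hospital claims carry no code for a caesarean section performed
without medical indication (nmi CS): no DRG, no ICD-10-GM diagnosis, no
CHOP procedure identifies maternal-request sections directly. The
package implements a phenotyping strategy that approximates this group
from codes that *do* exist, and the analysis stages that sit on top of
it: descriptive group comparisons and a logistic regression of birth
mode on maternal and cantonal factors. Because the underlying national
discharge dataset (2014–2018, about 431,000 births) is restricted, a
seeded synthetic cohort generator reproduces its statistical structure
so that every stage is testable end to end.

## The selection algorithm

A discharge record is classified by a fixed cascade of gates:

1. DRG `O60D` → **SVB** (uncomplicated spontaneous vaginal birth);
2. DRG different from the year's low-complexity CS group
   (`O01F` 2014–2016, `O01G` 2017, `O01H` 2018) →
   **EXCLUDED_NON_TARGET_DRG**;
3. any coded diagnosis matching the exclusion patterns (conditions
   incompatible with vaginal birth, e.g. malpresentation `O32`,
   obstructed labour `O64`–`O66`, placenta praevia `O44`) →
   **EXCLUDED_DIAGNOSIS**;
4. any procedure matching the emergency-CS patterns →
   **EXCLUDED_EMERGENCY**;
5. otherwise → **NMI_CS**.

The first failing gate wins, so exclusion reasons are mutually
exclusive. The source flowchart does not pin down whether the diagnosis
or the emergency check runs first; the specific exclusion *reason* (not
NMI_CS membership) depends on that order, so we freeze
diagnosis-before-emergency and document it here. The diagnosis gate
scans all coded diagnoses, principal and secondary — the conservative
reading of "diagnoses that do not allow for vaginal birth".

Two pattern conventions: an entry without a dot (an ICD category such as
`O32`) or suffixed `*` is a prefix pattern; a fully dotted code matches
exactly. Codes are canonicalized to upper case with whitespace stripped;
dots are preserved because ICD-10-GM is conventionally dotted.

**The shipped exclusion lists are placeholders.** The official
diagnosis- and procedure-exclusion catalogues are not reproduced in the
public record, so `default_codebook()` ships a small, clearly labelled
stand-in set; the codebook is fully user-overridable from a YAML/JSON
file. What the package contributes — and what the tests establish — is
the *algorithm*: on synthetic records whose true channel is known by
construction, classification is exact, whatever lists are plugged in.

Records outside 2014–2018 are rejected: before 2014 the Swiss procedure
classification did not distinguish planned from emergency CS, so the
algorithm is undefined there.

## The annual summary conventions

`summarize_annual_counts()` reproduces the arithmetic conventions of the
published national table: percentages are rounded half-up at 2 decimals;
the Average row uses `floor(total / 5)` for count columns and the
arithmetic mean of the five *annual rounded percentages* (not the pooled
ratio — the two differ, e.g. 41.10 vs 41.05 for the SVB share) for
percentage columns; the Total row is column sums. The CS denominator
counts every `O01`-prefixed DRG, not only the year's candidate code.

## The regression model

For the cohort restricted to NMI_CS and SVB, the model is a plain
logistic regression

$$\operatorname{logit}\Pr(\text{nmi CS}) = \beta_0
 + \beta_{\text{age}[a]} + \beta_{\text{ins}[i]} + \beta_{\text{urb}[u]}
 + \beta_m \cdot \text{midwives} + \beta_s \cdot \text{staff}
 + \beta_y \cdot \text{income}/10{,}000,$$

with reference categories age 45–49, private insurance and rural
urbanity, midwives per 1,000 births and nursing staff per hospital bed
as cantonal rates, and income per capita in units of CHF 10,000. The
design matrix has 14 columns in a fixed, documented order
(`model_terms()`). The published coefficient table is headed "odds
ratio" but its entries are negative and its text speaks of log odds
ratios; all entries are treated as log-odds coefficients throughout.
The staffing covariate is defined per hospital *bed* (the quantified
definition), not per hospital. Living region is a descriptive variable
only and enters no regression.

Fitting is by iteratively reweighted least squares (Newton scoring)
written in the package, with:

* convergence when the maximum absolute score component falls below
  1e-8 or the relative log-likelihood change falls below 1e-10, capped
  at 50 iterations;
* step-halving when a Newton step would decrease the log-likelihood;
* rank checking up front (collinear columns are named in the error);
* separation detection both by coefficient divergence (|β| > 30) and by
  an exact check that the converged fit reproduces every outcome to
  within 1e-6 — the divergence heuristic alone misses separated
  problems whose Newton path plateaus at moderate coefficients;
* Wald standard errors from the inverse observed information, 95%
  intervals at ±1.959964·SE (matching the symmetric printed intervals;
  profile intervals are deliberately not used).

Discrimination is the ROC AUC in its rank-sum (Mann–Whitney) form with
midranks for ties, equivalent to the probability that a random case
outscores a random control, ties counting one half. The test suite
cross-checks the fit against `stats::glm` and the AUC against `pROC`;
those libraries are oracles only, never the implementation.

Descriptive statistics delegate the independent-samples t-test to
`stats::t.test`. Welch's unequal-variance form is the default — the
cantonal covariates plainly violate equal variances across groups — with
the pooled-variance form behind a flag, since the source analysis does
not state which variant it used. The Spearman correlation is the Pearson
correlation of midranks with a t-approximation p-value, implemented
directly (three lines) and cross-checked against base R.

## The synthetic cohort generator

The generator's defaults *are* the study conditions:

* **year weights**: proportional to the printed annual birth totals;
* **categorical marginals** (age category, insurance class, urbanity,
  living region): the printed group profiles pooled over both birth-mode
  groups, renormalised;
* **canton-year covariates**: 26 cantons × 5 years, each covariate
  normal, truncated at zero, with means at the pooled printed
  person-level means — 37.7 midwives per 1,000 births, 3.65 nursing
  staff per bed, CHF 37,200 income per capita;
* **generating coefficients**: the published fitted model
  (`published_birthmode_model()`).

The covariate dispersions are free parameters — the source reports no
cantonal spread — chosen once as realistic Swiss cantonal variation: SD
8 midwives per 1,000 births, 0.5 staff per bed, CHF 6,000 income. A
back-of-envelope check fixes the scale: these dispersions give a
linear-predictor SD of about 0.41, and for a logistic model with
normal-ish linear predictor the AUC is approximately Φ(σ/√2) ≈ 0.61,
consistent with the published discrimination of 0.625. The AUC
acceptance check is exactly this calibration statement, not an
independent reproduction.

Covariates are sampled independently except for one documented
dependency: income and insurance class are linked through a Gaussian
latent-threshold model. The insurance thresholds are the normal
quantiles of the configured class probabilities (so the marginal is
preserved by construction), the latent score mixes the standardized
cantonal income with fresh noise, and the latent correlation is solved
numerically (1-D integration plus root finding) so that the *population
Spearman grade correlation* between income and the ordinal insurance
class (mandatory = 0, semi-private = 1, private = 2) equals the
configured target, 0.155 by default. One subtlety matters for
validation: income is a cantonal covariate, so a cohort contains only
130 distinct income values, and the realized rank correlation
fluctuates with the canton draw itself (SD ≈ 0.01 regardless of cohort
size). The knob's calibration is therefore verified on a many-canton
configuration, where that cluster noise is negligible, at the strict
±0.02 tolerance; default-canton runs are checked with cluster-aware
bounds.

Ages are drawn uniformly within the sampled category — the analysis
only ever uses the category. Clean records get their DRG from the drawn
outcome; contamination channels (all defaulting to zero — the defaults
target the regression cohort, and the classifier tests switch them on
explicitly) produce emergency-flagged CS, diagnosis-excluded CS, and
other-DRG CS records whose covariates come from the same marginals.
Contaminant code assignments use a representative code for each
configured pattern.

When a target prevalence is requested (`intercept_calibration`), the
intercept shift δ is obtained by solving mean(plogis(η + δ)) = target
exactly by root finding rather than by the first-order offset
logit(p*) − logit(p̄); with a linear-predictor SD around 0.4 the
first-order shift is biased by roughly as much as the Monte-Carlo
tolerance it has to meet. Prevalence under the defaults is *not*
calibrated to the study's 5.9% — the real intercept/covariate joint
distribution is unknown, and transporting the fitted coefficients onto
independent marginals lands near 20%; the calibration flag exists for
experiments that need the study's rate.

All randomness flows from one top-level seed; sub-streams (contexts,
records) derive from it by a fixed affine map, and identical
configuration plus seed reproduces outputs bit for bit.

### What the generator does not emulate

No temporal trend (the real SVB counts fall over 2014–2018), no
hospital identifiers, no parity or any clinical variable, no regional
covariate geography (cantons are exchangeable), and covariate
independence beyond the single income–insurance link. Passing tests
therefore establish that the pipeline's arithmetic, classification and
estimation are correct under the stated generating process — not that
the placeholder code lists, or the model, capture the real clinical
phenomenon.

## Problem sizes and seeds

The analysis scripts run at 200,000 records; the parameter-recovery and
AUC checks at 400,000 (about 6 seconds end to end); property suites use
10,000–100,000 records and 200 replicate fits for interval coverage.
Fixed seeds make every reported number reproducible; the recovery
experiment at 400,000 records recovers all 14 generating coefficients
within 3 estimated standard errors, the income coefficient near 0.168
and the midwife-density coefficient near −0.019.

## Known limitations

* The exclusion lists are placeholders; results on real data depend
  entirely on supplying the genuine catalogues.
* Cantonal covariates are cluster-shared but standard errors are not
  cluster-adjusted — deliberately matching the source analysis, which
  fits a plain logistic model.
* The published midwife coefficient is printed as −0.019 in the table
  and −0.018 in the discussion; the table value is used.
* DRG cost weights are carried as an optional field but never analysed.
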