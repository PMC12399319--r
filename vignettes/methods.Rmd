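---
title: "Quantifying small-scale demographic asynchrony and its climate drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying small-scale demographic asynchrony and its climate drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A population spread over a small environmental gradient — here, dune zones
running from a lake shoreline (foredune) to the treeline (backdune) — can
be more stable in total than any of its parts, if the parts fluctuate out
of step. `dunesync` quantifies this *portfolio effect* for a zoned,
long-term census of a monocarpic perennial plant (seedling → vegetative
rosette, measured as ln taproot diameter in mm → one flowering episode →
death) and asks whether zone-specific responses to climate are what
desynchronizes the zones.

The pipeline has six stages, each usable on its own:

1. **Transitions** (`build_transitions`): plant-year records with fates.
2. **Vital rates** (`fit_vital_rate`): five mixed models with
   year-by-zone variation.
3. **IPMs** (`build_kernel`, `growth_rate`, `lambda_table`): zone- and
   year-specific asymptotic growth rates.
4. **Portfolio statistics** (`synchrony_phi`, `portfolio_effect`,
   `correlation_matrix`).
5. **Climate windows** (`scan_windows`, `randomization_test`): which
   variable, over which months, best predicts each rate.
6. **Attribution** (`zone1_correlations`, `coef_vs_corr_regression`):
   do per-zone climate slopes explain asynchrony with the foredune zone?

A synthetic census generator (`generate_population`) with retrievable
true parameters is the package's test bed.

## Transition scoring

Plants are tagged individuals, censused each year around 30 June.
Transition building encodes two field-protocol rules. A plant missing
for three or more consecutive years, and never seen again, is dead in
the first year it went missing; a plant missing fewer than three years
at the end of the series has an unresolved fate and contributes no final
transition (right-censoring). A plant re-found after a short gap was
alive throughout: gap years contribute survival records with unknown
sizes, and contribute nothing to the growth or size-dependent models —
we credit survival through the gap but never fabricate a size.

One consequence worth knowing: survival data from the last two
transition years are enriched for survivors (deaths there cannot yet be
confirmed). Parameter-recovery tests therefore fit on transitions whose
fates are fully scored (`year_t0` at least three years before the end).

## Vital-rate models

Five rates are modeled from the transitions, exactly one model each:

| rate | meaning                    | family           | size covariate |
|------|----------------------------|------------------|----------------|
| S1   | seedling survival          | Bernoulli(logit) | no             |
| S2   | plant survival             | Bernoulli(logit) | yes            |
| G    | growth (ln mm)             | Gaussian         | yes            |
| A    | flowering probability      | Bernoulli(logit) | yes            |
| D    | new-plant size (ln mm)     | Gaussian         | no             |

All five carry a random effect of the year-by-zone interaction *only* —
no separate year or zone main effects.  This is deliberate: separate
additive year and zone terms would pull zones that move in opposite
directions within a year toward a common year mean, understating exactly
the asynchrony the analysis is after.  For the size-dependent rates the
(year, zone) cells carry a correlated random intercept *and* random
ln-size slope; a slope-only structure cannot reproduce between-cell
level differences, so intercept-plus-slope is used.  Fitting goes
through `lme4` (Laplace approximation for the Bernoulli rates; Gaussian
rates by maximum likelihood, not REML, so that likelihoods are
comparable across fixed-effect structures).  The ln-size covariate is
centered on the rate data's mean for numerical stability and uncentered
again in all reported coefficients and predictions.  Seedling survival,
which has no individual-level covariate, is fitted on (year, zone)
binomial counts — the likelihood is the Bernoulli one up to an additive
constant, and fits are an order of magnitude faster.

Complete separation (all successes or all failures) is refused with an
error rather than silently returning a divergent coefficient.

Recruitment is not modeled but estimated directly:
`r_zone = sum_t seedlings(zone, t+1) / sum_t flowering(zone, t)`, pooled
over years because individual zone-years can have seedlings without any
flowering plants the year before (a seedbank or dispersal signal this
design cannot separate — recruitment is attributed to the zone's own
flowering plants).

## The integral projection model

Each (year, zone) cell gets a projection operator over the state
(seedling S, size-structured vegetative density n(z), reproductive A):

* seedlings survive with probability s1 and enter n at sizes drawn from
  the new-plant distribution d(z');
* vegetative plants of size z survive with s2(z), flower with a(z)
  (leaving n for A), or grow via a Gaussian kernel G(z', z);
* every reproductive plant dies after producing r recruits (monocarpy).

Discretization uses the midpoint rule over m = 200 equal bins on
`[L', U']`, where the observed size range `[L, U]` is extended by 20% of
the range on each side.  (The alternative reading — extending each
endpoint by 20% of its own value — is available as
`size_bounds(mode = "endpoint")`.)  The Gaussian growth and new-size
densities are discretized and each column renormalized to mass exactly
one: this is the truncation ("eviction") correction, and it makes the
column-mass identity — continuous-block column sums equal
`s2(z)(1 - a(z))` — hold to machine precision by construction, which the
tests assert at 1e-10.

λ is computed by iterating the kernel and tracking the total-population
growth ratio until successive ratios change by less than `tol`
(default 1e-8, capped at 1e5 iterations; non-convergence is an error,
never a silently returned value).  Tests cross-check the iterated λ
against a dense eigendecomposition, and against the exact 3×3 stage
matrix in the size-independent reduction.  Both the new-plant and growth
distributions are truncated to the mesh, at both bounds.  Cells missing
any vital-rate prediction yield no kernel and are reported as `NA`, not
imputed; zones without flowering plants in some years still get kernels
because recruitment is pooled.

## Synchrony and the portfolio effect

From the zone-by-year abundance matrix (all live plants, all stages):

* synchrony `phi = Var(N_total) / (sum_i sd(N_i))^2`, 1 for perfectly
  synchronous zones, 0 for perfectly compensating ones;
* Taylor scaling `log Var(N_i) = beta0 + z log E(N_i)` fitted by OLS
  across zones (natural logs);
* predicted total variance `exp(beta0 + z log E(N_total))`, and
  `PE = Var_pred / Var_obs` — PE above 1 means the total is steadier
  than its own mean-variance scaling predicts, i.e. a portfolio effect.

All variances use the sample (n−1) denominator.  The choice cancels in
the phi ratio but not in the Taylor/PE step, so it is fixed and stated.
Pairwise zone correlations (of per-cell vital-rate predictions, at the
mean size for survival and growth and one SD above it for flowering,
where variation is only visible among large plants; and of λ) use
Pearson r with two-sided t-based p-values, uncorrected per pair by
default (a `p_adjust` option exists).

## Sliding-window climate analysis

Monthly station values are standardized per calendar month against a
reference period (z-scores with the sample-SD denominator).  A candidate
window is a run of consecutive months, offsets 0..36 counted backwards
from the census date (30 June) of the transition's *second* year; all
`(open, close)` pairs give 703 windows, and each of the (by default)
four variables is tested one at a time — a drought index column can be
supplied as a fifth.  Each candidate model adds to the rate's fixed
structure a `zone + climate:zone` term — one climate slope per zone,
spanning the same space as main-effect-plus-interaction — with a random
intercept per transition year absorbing climate-independent year
variation.  Candidates compete on AICc (`AIC + 2k(k+1)/(n-k-1)`, k
counting all estimated parameters including variance components, n the
transition count) against a climate-free baseline.  Exact ties break
deterministically: shorter window, then more recent, then variable
order.  Non-converged or degenerate candidates (for example a constant
window covariate) are flagged and excluded from the minimum, never
crashed on.

Scan fits use `glmer`'s fast `nAGQ = 0` approximation for binomial
rates: the scan compares thousands of models on equal footing, and the
selection is driven by likelihood differences that this approximation
preserves; the final vital-rate fits use the full Laplace default.

The randomization test permutes the mapping between biological years and
climate years as whole blocks — record-level shuffling would destroy the
within-year dependence that the year random effect exists to absorb —
reruns the scan each time, and reports
`p = (1 + #{null best dAICc <= observed}) / (n_perm + 1)`.  This add-one
exceedance p is simpler than the sliding-window literature's calibrated
statistic and is deliberately so; it is the documented deviation of this
implementation.  When the scan data sit on a complete (year, zone) grid
(always true for aggregated seedling survival), permuting climate years
against fixed responses is re-expressed as permuting response blocks
against fixed designs, so every candidate's model structure is built
once and only a one-dimensional variance-parameter profile is
re-optimized per permutation — mathematically identical to a fresh fit
(the tests assert this equivalence) and about four times faster.  The
observed statistic is computed through the same engine as the nulls, so
the permutation comparison is exactly exchangeable.

## Attribution

If climate-by-zone interaction drives asynchrony, zones that respond to
climate most unlike Zone 1 should also track Zone 1 least.  The package
regresses the best scan model's per-zone climate slopes on each zone's
correlation with Zone 1 (per rate; Zone 1's own point, correlation 1, is
included by default and can be toggled).  Slopes are reported in the
per-zone parameterization, not as treatment contrasts.  Note the
expected *sign*: with a negative foredune slope grading to a positive
backdune slope, low-correlation zones have the most positive slopes, so
the fitted regression slope is negative whenever the reference zone's
own climate response is negative.  What is diagnostic is the
significance and strength of the association, not its sign, which simply
mirrors the reference zone's response.

## The synthetic generator

`generate_population` simulates tagged individuals forward through the
exact life cycle above.  Climate enters every rate's linear predictor as
(zone slope) × (mean anomaly of one variable over one window), plus a
year-level Gaussian deviate *shared across zones within a rate*.  The
sharing is deliberate: it mirrors the scan model's year random
intercept and makes climate the only zone-differential force, which the
attribution analysis needs as its ground truth.  Recruitment is Poisson
around `r × (flowering adults)`, giving integer seedling counts with the
right mean.  Anomalies inside the generator are computed by the same
standardization as the analysis, so the scan sees the generating scale.

Default parameters describe a quasi-stationary population of the size a
long-term dune monitoring plot carries: about 550–700 plants in census
years (roughly
26% seedlings, 7% flowering), initial densities graded 60..200 across
zones (dune zones differ in cover), seedling survival near 0.5,
new-plant sizes around ln 3.7 mm, growth equilibrating near ln 20 mm
taproot diameter, four seedlings per flowering plant, and seedling- and
plant-survival climate slopes grading from −1 (foredune) to +1
(backdune) logits per anomaly unit with a true precipitation window 8..4
months before the census.  Initial sizes are drawn from the new-plant
distribution (shifted up slightly, as standing plants are older),
truncated to positive ln-size; the real protocol never initializes a
plot this way, which is one of several honest differences listed below.

What the generator does *not* emulate: detection error (available
separately as `apply_detection_noise`), spatial structure within zones,
zone-specific year noise, herbivory, seed dormancy, and between-zone
dispersal.  Passing tests on generator output therefore validate the
estimation machinery under the stated statistical structure, not the
field realism of any particular dataset.

## Numerical and design choices

* **Convergence**: power iteration tolerance 1e-8 by default (tests use
  tighter tolerances when comparing against eigensolvers so that the
  comparison tolerance, not the stopping rule, binds).
* **Ties**: scan ties break to the shorter, more recent window with a
  logged message.
* **Degenerate inputs**: zero-variance zones, constant covariates,
  zero reference SDs with varying values, separation, unknown cells and
  empty populations raise errors naming the problem.  A calendar month
  whose reference SD is zero *and* whose values all equal the reference
  mean standardizes to anomaly 0 (the constant-series case) rather than
  erroring.
* **Problem sizes in the test suite**: the acceptance-style checks run
  100-replicate parameter recovery at ~3,000 transitions, a 50-replicate
  window-scan power study on the reduced 13-month grid, 200 null
  simulations of the randomization test at 99 permutations, and
  15-replicate attribution runs; these sizes give the binomial margins
  the assertions state while keeping a full run of the suite in the
  tens of minutes.
* **Coverage is assessed where the model is correct**: the recovery
  replicates switch year-level noise and climate slopes off, because the
  generator's shared year deviate deliberately violates the fitted
  model's independent-cell assumption (see above) — that misspecification
  is a property of the study design being emulated, not an estimator
  defect, and conflating the two would make the coverage test
  uninterpretable.

## Known limitations

* The Bernoulli scan models rely on `nAGQ = 0`; for final reporting of
  any single best model, refit with `fit_window_model(..., nAGQ = 1)`.
* AICc counts variance components as ordinary parameters, the standard
  small-sample convention, though their boundary-constrained nature
  makes this an approximation.
* The add-one randomization p has resolution `1/(n_perm + 1)`; with 99
  permutations the smallest attainable p is 0.01.
* Taylor scaling fitted across five zones rests on five points; its
  slope — and hence PE — carries wide sampling variation, which is
  visible across generator seeds and would be equally true of any real
  five-zone plot.
* The attribution regression's nominal p-value is anticonservative:
  per-zone climate slopes and zone-1 correlations are estimated from the
  same realized rate series, so their errors are correlated and, in null
  simulations, p < 0.05 occurs several times more often than 5% (the
  slope's *sign* stays symmetric under the null).  Treat the association
  as descriptive, or calibrate its p by simulation, before leaning on it.
* λ is asymptotic; transient dynamics and density dependence are out of
  scope, as are elasticities and stochastic growth rates.
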