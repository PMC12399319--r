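# dunesync

Small-scale demographic asynchrony, portfolio effects, and their climate
drivers, for zoned long-term censuses of a monocarpic perennial plant.

A population monitored across a handful of adjacent habitat zones — say,
five dune zones running from a lake shoreline to the treeline — can be
steadier in total than any single zone, provided the zones fluctuate out
of step. `dunesync` measures that stabilization and tests whether
zone-specific responses to climate cause it. It is aimed at plant
demographers with tagged-individual census data (one row per live plant
per year: id, zone, year, stage, size) and a nearby monthly climate
series.

## What it computes

**Demography.** Census tables become plant-year transitions (with the
"dead after three missing years" scoring rule and gap re-linking), which
feed five vital-rate mixed models — seedling survival S1, plant survival
S2, growth G, flowering probability A, new-plant size D — each with a
random effect of the year-by-zone interaction only, so zones may move in
opposite directions within a year. Sizes are ln taproot diameter (mm).
Recruitment r is the pooled ratio of seedlings to the previous year's
flowering plants, per zone.

**Population growth.** Per (year, zone), an integral projection model
with discrete seedling and reproductive stages and a size-structured
vegetative stage (midpoint rule, 200 bins, bounds extended 20% beyond
the observed size range, truncation-corrected Gaussian kernels):

    n(z', t1) = S(t0) s1 d(z') + ∫ s2(z) (1 − a(z)) G(z', z) n(z, t0) dz
    S(t1) = A(t0) r,   A(t1) = ∫ s2(z) a(z) n(z, t0) dz

λ comes from iterating the kernel to convergence.

**Portfolio statistics.** From zone-by-year abundances N_i:
synchrony φ = Var(ΣN_i) / (Σ sd(N_i))², Taylor scaling
log Var(N_i) = β0 + z log E(N_i) across zones, and the portfolio effect
PE = exp(β0 + z log E(N_total)) / Var(N_total): PE > 1 means the whole
is steadier than its parts predict.

**Climate windows.** Monthly anomalies (per-calendar-month z-scores) are
averaged over all 703 month-windows reaching up to 36 months before the
30 June census; for each vital rate and climate variable, models with
per-zone climate slopes (`size + zone + climate:zone + (1 | year)`)
compete on AICc against a climate-free baseline, and a year-block
randomization test guards against spurious support.

**Attribution.** Per-zone climate slopes from the best model are
regressed on each zone's correlation with Zone 1: a significant
association means climate-by-zone interaction explains part of the
asynchrony.

A fully parameterized individual-based generator
(`generate_population`) emulates the 17-year, 5-zone study design with
retrievable truth, and backs the package's recovery and calibration
tests.

## Worked example

Simulate the default synthetic study (17 years, 5 zones, seedling- and
plant-survival slopes grading from −1 to +1 across zones with a true
precipitation window 8..4 months before the census), then run every
stage:

```r
library(dunesync)

params  <- generator_params()
climate <- generate_climate(21, seed = 1, start_year = params$start_year - 4)
sim     <- generate_population(params, climate, seed = 2)

transitions <- build_transitions(sim$census)          # 8439 transitions
fits <- lapply(setNames(c("S1","S2","G","A","D"), c("S1","S2","G","A","D")),
               function(r) fit_vital_rate(transitions, r))
fits$S1
#> <vital_rate_fit S1 (binomial), n = 2388, 80 cells>
#> intercept
#> 0.1874763

lambdas <- lambda_table(fits, recruitment(sim$census), transitions, m = 200)
range(lambdas, na.rm = TRUE)                          # 0.882 .. 1.160

portfolio_effect(zone_abundance(sim$census))
#> phi = 0.501, Taylor beta0 = 1.950, z = 0.654, PE = 0.234
#>   predicted total variance 449.3 vs observed 1922

anoms <- lapply(setNames(c("prcp","tmean"), c("prcp","tmean")),
                function(v) monthly_anomalies(climate, v))
scan <- scan_windows(transitions, anoms, "S1", max_offset = 12)
scan
#> <window_scan S1: 182 candidates (0 failed), baseline AICc 440.32>
#> best: prcp, window open 9 close 2, dAICc -25.97

randomization_test(transitions, anoms["prcp"], "S1", n_perm = 99,
                   seed = 3, max_offset = 12)
#> <randomization test: observed dAICc -25.97, p = 0.02 (99 permutations)>

pts <- attribution_points(scan$best$zone_slopes,
                          zone1_correlations(cell_prediction_matrix(fits$S1)))
coef_vs_corr_regression(pts)[c("slope", "p_value")]
#> $slope   -3.71
#> $p_value  0.0026
```

Reading the output: seedling survival sits near invlogit(0.19) ≈ 0.55 on
average; per-cell λ values straddle 1 (a quasi-stationary population);
the scan correctly singles out precipitation in a window overlapping the
planted 8..4-month truth, with AICc support 26 units beyond the baseline
that year-randomization calls non-spurious (p = 0.02); and the per-zone
precipitation slopes are strongly associated with each zone's
correlation to Zone 1 (negative slope, because Zone 1's own response is
negative) — climate-by-zone interaction explains part of the asynchrony.
The synchrony index φ = 0.50 is moderate: the generator's year-level
noise is shared across zones by design, so only climate desynchronizes
them. `run_pipeline(run_config(...))` chains all of the above and writes
per-stage CSVs plus a JSON summary.

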