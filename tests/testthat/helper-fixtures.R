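## Shared fixtures, built in code and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

## A mid-sized simulated census shared by several test files.
shared_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    p <- generator_params(n_years = 10, init_per_zone = 60)
    clim <- generate_climate(14, seed = 101, start_year = p$start_year - 4L)
    sim <- generate_population(p, clim, seed = 102)
    .fixture_cache$sim <- list(params = p, climate = clim, sim = sim,
                               transitions = build_transitions(sim$census))
  }
  .fixture_cache$sim
}

## A random valid kernel component set (draws from the caller's RNG state).
random_kernel_components <- function(m = 50L, bounds = c(0, 4)) {
  h <- (bounds[2] - bounds[1]) / m
  mesh <- bounds[1] + (seq_len(m) - 0.5) * h
  list(
    s1 = runif(1, 0.2, 0.9),
    s2 = plogis(runif(1, -1, 1) + runif(1, 0.2, 1) * mesh),
    a = plogis(runif(1, -6, -2) + runif(1, 0.5, 2) * mesh),
    g_mean = runif(1, 0.2, 0.8) + runif(1, 0.6, 1.05) * mesh,
    g_sd = runif(1, 0.1, 0.4),
    d_mean = runif(1, 0.8, 1.8),
    d_sd = runif(1, 0.2, 0.5),
    r = runif(1, 0.5, 5)
  )
}

## Hand-built census for transition-rule tests.
tiny_census <- function() {
  data.frame(
    plant_id = c(1, 1,            # vegetative -> flowering
                 2, 2, 2,         # seedling -> vegetative -> vegetative
                 3,               # vegetative, then absent >= 3 years
                 4, 4,            # vegetative with a 1-year gap, re-found
                 5),              # seedling in final year (no transition)
    zone = c(1, 1, 1, 1, 1, 2, 2, 2, 1),
    year = c(2010, 2011,
             2010, 2011, 2012,
             2012,
             2010, 2012,
             2016),
    stage = c("vegetative", "flowering",
              "seedling", "vegetative", "vegetative",
              "vegetative",
              "vegetative", "vegetative",
              "seedling"),
    size = c(2.1, NA, NA, 1.4, 1.9, 2.5, 2.0, 2.3, NA)
  )
}
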