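## Individual-based synthetic census generator.
##
## Emulates a 17-year, 5-zone demographic census of a monocarpic perennial
## (seedling -> vegetative rosette measured as ln taproot diameter ->
## one-time flowering -> death).  Vital rates respond to the mean anomaly
## of one climate variable over one fixed window through zone-specific
## slopes, plus a year-level Gaussian deviate shared across zones, so that
## climate is the sole *zone-differential* driver of asynchrony.  All true
## parameters and the per-(year, zone) realized rates are returned for
## parameter-recovery tests.

#' Parameters of the synthetic census generator
#'
#' Returns the default generator configuration, with any field overridden
#' by name.  Defaults describe a stable population of a few hundred plants
#' per zone whose seedling survival, plant survival and growth respond to
#' the precipitation anomaly of a fixed absolute window with slopes grading
#' from negative in Zone 1 (foredune) to positive in Zone `n_zones`
#' (backdune); flowering depends on size only.
#'
#' @param ... Named overrides of any default field:
#' \describe{
#'   \item{n_zones, n_years, init_per_zone, start_year}{Design: number of
#'     zones (5), census years (17), initial plants per zone (a scalar or
#'     per-zone vector; the default grades 60..200 across zones, as zone
#'     densities differ along a dune gradient, split roughly 55\%
#'     vegetative, 35\% seedlings, 10\% flowering), first census year
#'     (2006).}
#'   \item{true_variable, true_window}{The climate driver: variable name in
#'     the climate table and the [window_spec()] over which its anomaly is
#'     averaged (default `prcp` over offsets 8..4 before the 30 June census
#'     of the transition's second year).}
#'   \item{s1_intercepts, s1_climate_slopes}{Seedling survival: per-zone
#'     logit intercepts and per-zone slopes per anomaly unit.}
#'   \item{s2_intercepts, s2_size_slope, s2_climate_slopes}{Plant survival:
#'     per-zone logit intercepts, common ln-size slope, per-zone climate
#'     slopes.}
#'   \item{growth_intercept, growth_size_slope, growth_climate_slopes,
#'     growth_resid_sd}{Gaussian growth of ln taproot diameter.}
#'   \item{flower_intercept, flower_size_slope}{Flowering probability
#'     (logit scale, size-dependent, climate-independent).}
#'   \item{newsize_mean, newsize_sd}{Size distribution (ln mm) of plants in
#'     the year after they were seedlings.}
#'   \item{recruit_rate}{Per-zone expected seedlings per flowering adult.}
#'   \item{year_noise_sd}{Named vector of year-level latent SDs for rates
#'     `s1, s2, g, a, d`; the year deviate is shared across zones.}
#' }
#' @return A list of class `generator_params`.
#' @examples
#' p <- generator_params(n_years = 8, init_per_zone = 40)
#' p$s1_climate_slopes
#' @export
generator_params <- function(...) {
  p <- list(
    n_zones = 5L,
    n_years = 17L,
    init_per_zone = c(60L, 130L, 200L, 160L, 100L),
    start_year = 2006L,
    true_variable = "prcp",
    true_window = window_spec(8, 4),
    s1_intercepts = rep(0, 5),
    s1_climate_slopes = seq(-1, 1, length.out = 5),
    s2_intercepts = rep(0.6, 5),
    s2_size_slope = 0.8,
    s2_climate_slopes = seq(-0.8, 0.8, length.out = 5),
    growth_intercept = 0.55,
    growth_size_slope = 0.85,
    growth_climate_slopes = seq(-0.08, 0.08, length.out = 5),
    growth_resid_sd = 0.18,
    flower_intercept = -7,
    flower_size_slope = 2.0,
    newsize_mean = 1.3,
    newsize_sd = 0.35,
    recruit_rate = rep(4, 5),
    year_noise_sd = c(s1 = 0.4, s2 = 0.3, g = 0.05, a = 0.3, d = 0.08)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    stop_dunesync("unknown generator parameter(s): ",
                  paste(unknown, collapse = ", "))
  }
  p[names(dots)] <- dots
  nz <- p$n_zones
  for (f in c("init_per_zone", "s1_intercepts", "s1_climate_slopes",
              "s2_intercepts", "s2_climate_slopes", "growth_climate_slopes",
              "recruit_rate")) {
    if (length(p[[f]]) == 1L) p[[f]] <- rep(p[[f]], nz)
    if (length(p[[f]]) != nz) {
      stop_dunesync(sprintf("%s must have length 1 or n_zones (%d)", f, nz))
    }
  }
  if (p$growth_resid_sd <= 0 || p$newsize_sd <= 0) {
    stop_dunesync("growth_resid_sd and newsize_sd must be > 0")
  }
  if (any(p$recruit_rate < 0)) stop_dunesync("recruit_rate must be >= 0")
  if (any(p$year_noise_sd < 0)) stop_dunesync("year_noise_sd must be >= 0")
  needed <- c("s1", "s2", "g", "a", "d")
  if (!all(needed %in% names(p$year_noise_sd))) {
    stop_dunesync("year_noise_sd must be named for rates: ",
                  paste(needed, collapse = ", "))
  }
  class(p) <- "generator_params"
  p
}

#' Default seasonal climate parameters for the synthetic station
#'
#' Monthly means and SDs for total precipitation (mm) and minimum, mean and
#' maximum air temperature (deg C) with a Great Lakes-like seasonal cycle.
#' Only the anomaly structure matters downstream; the absolute values are
#' cosmetic.
#'
#' @return A named list, one element per variable, each with `mean` and
#'   `sd` vectors of length 12.
#' @export
default_climate_params <- function() {
  tmean <- c(-6, -5, 0, 7, 13, 18, 21, 20, 16, 9, 3, -3)
  list(
    prcp  = list(mean = c(45, 40, 55, 70, 80, 85, 75, 80, 90, 85, 75, 55),
                 sd = rep(25, 12)),
    tmin  = list(mean = tmean - 5, sd = rep(2.2, 12)),
    tmean = list(mean = tmean,     sd = rep(2.0, 12)),
    tmax  = list(mean = tmean + 5, sd = rep(2.4, 12))
  )
}

#' Generate a synthetic monthly station series
#'
#' Each variable is its seasonal monthly mean plus independent Gaussian
#' noise.  The series should start at least three years before the first
#' census transition so that 36-month windows can be resolved.
#'
#' @param n_years_with_burnin Number of calendar years to generate.
#' @param seed Optional RNG seed; the same seed reproduces the same table.
#' @param params Seasonal means/SDs per variable, as
#'   [default_climate_params()].
#' @param start_year First calendar year of the series.
#' @return Data frame with columns `year`, `month`, and one column per
#'   variable.
#' @examples
#' clim <- generate_climate(5, seed = 42)
#' subset(clim, month == 1)
#' @export
generate_climate <- function(n_years_with_burnin, seed = NULL,
                             params = default_climate_params(),
                             start_year = 2003L) {
  if (n_years_with_burnin < 1) stop_dunesync("need at least one year")
  for (v in names(params)) {
    if (any(params[[v]]$sd <= 0)) {
      stop_dunesync("non-positive seasonal SD for variable ", v)
    }
    if (length(params[[v]]$mean) != 12L || length(params[[v]]$sd) != 12L) {
      stop_dunesync("seasonal mean/sd for ", v, " must have length 12")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  years <- seq.int(start_year, length.out = n_years_with_burnin)
  out <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
  n <- nrow(out)
  for (v in names(params)) {
    out[[v]] <- params[[v]]$mean[out$month] +
      stats::rnorm(n, 0, params[[v]]$sd[out$month])
  }
  rownames(out) <- NULL
  out
}

## The five stage labels used throughout.
STAGES <- c("seedling", "vegetative", "flowering")

#' Simulate an individual-based census
#'
#' Runs the generator forward from an initial population.  Each transition
#' year `t0 -> t1`: a vegetative plant survives with probability
#' `invlogit(s2)`, then flowers at `t1` with probability `invlogit(a)`
#' (flowering plants die after the `t1` census: monocarpy) or grows to a
#' Normal new size; a seedling survives with probability `invlogit(s1)` and
#' receives a Normal first measured size; flowering adults at `t0` produce
#' `Poisson(r_zone * A_zone)` seedlings at `t1`.  Climate enters every
#' linear predictor as (zone slope) x (mean anomaly of `true_variable` over
#' `true_window`, anchored at the 30 June census of `t1`), plus a year-level
#' Gaussian deviate shared across zones.
#'
#' @param params A [generator_params()] object.
#' @param climate Monthly climate table covering at least
#'   `[start_year - 3, start_year + n_years - 1]`.
#' @param seed Optional RNG seed.
#' @return A list of class `census_sim`:
#' \describe{
#'   \item{census}{Data frame `plant_id, zone, year, stage, size` (size in
#'     ln mm, present iff vegetative).}
#'   \item{latent}{Per-(year, zone, rate) data frame with the at-risk count
#'     `n`, the `realized` frequency/mean and the `expected` value under
#'     the latent linear predictor.}
#'   \item{anomaly}{Per transition-year `t0` the window-mean anomaly used.}
#'   \item{params}{The generating parameters.}
#' }
#' @examples
#' p <- generator_params(n_years = 6, init_per_zone = 30)
#' clim <- generate_climate(10, seed = 1, start_year = p$start_year - 4)
#' sim <- generate_population(p, clim, seed = 1)
#' table(sim$census$stage)
#' @export
generate_population <- function(params, climate, seed = NULL) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  years <- seq.int(p$start_year, length.out = p$n_years)
  need_first <- offset_to_month(years[2], p$true_window$open)$year
  if (min(climate$year) > need_first || max(climate$year) < max(years)) {
    stop_dunesync(sprintf(
      "climate must cover %d..%d (covers %d..%d)", need_first, max(years),
      min(climate$year), max(climate$year)))
  }
  if (sum(p$init_per_zone) < 1) stop_dunesync("empty initial population")
  if (!is.null(seed)) set.seed(seed)

  anoms <- monthly_anomalies(climate, p$true_variable)
  nz <- p$n_zones

  ## initial population: mostly vegetative, some seedlings, a few flowering
  n_veg0 <- round(0.55 * p$init_per_zone)
  n_sdl0 <- round(0.35 * p$init_per_zone)
  n_flw0 <- p$init_per_zone - n_veg0 - n_sdl0
  zone <- rep(seq_len(nz), times = p$init_per_zone)
  stage <- unlist(lapply(seq_len(nz), function(z)
    rep(c("vegetative", "seedling", "flowering"),
        c(n_veg0[z], n_sdl0[z], n_flw0[z]))))
  n0 <- length(zone)
  live <- data.frame(
    plant_id = seq_len(n0), zone = zone, stage = stage,
    size = ifelse(stage == "vegetative",
                  rtnorm_lower(n0, p$newsize_mean + 0.6, p$newsize_sd + 0.15),
                  NA_real_)
  )
  next_id <- n0 + 1L

  census <- vector("list", p$n_years)
  latent <- list()
  anomaly_used <- numeric(p$n_years - 1L)

  for (t in seq_len(p$n_years)) {
    yr <- years[t]
    census[[t]] <- data.frame(plant_id = live$plant_id, zone = live$zone,
                              year = yr, stage = live$stage, size = live$size)
    if (t == p$n_years) break

    x <- window_mean(anoms, yr + 1L, p$true_window)
    anomaly_used[t] <- x
    eps <- stats::rnorm(5, 0, p$year_noise_sd[c("s1", "s2", "g", "a", "d")])
    names(eps) <- c("s1", "s2", "g", "a", "d")

    is_sdl <- live$stage == "seedling"
    is_veg <- live$stage == "vegetative"
    is_flw <- live$stage == "flowering"

    ## vegetative fates
    veg <- live[is_veg, ]
    eta_s2 <- p$s2_intercepts[veg$zone] + p$s2_size_slope * veg$size +
      p$s2_climate_slopes[veg$zone] * x + eps["s2"]
    surv_v <- stats::rbinom(nrow(veg), 1L, stats::plogis(eta_s2)) == 1L
    vs <- veg[surv_v, ]
    eta_a <- p$flower_intercept + p$flower_size_slope * vs$size + eps["a"]
    flw <- stats::rbinom(nrow(vs), 1L, stats::plogis(eta_a)) == 1L
    grower <- vs[!flw, ]
    mu_g <- p$growth_intercept + p$growth_size_slope * grower$size +
      p$growth_climate_slopes[grower$zone] * x + eps["g"]
    new_size <- mu_g + stats::rnorm(nrow(grower), 0, p$growth_resid_sd)

    ## seedling fates
    sdl <- live[is_sdl, ]
    eta_s1 <- p$s1_intercepts[sdl$zone] + p$s1_climate_slopes[sdl$zone] * x +
      eps["s1"]
    surv_s <- stats::rbinom(nrow(sdl), 1L, stats::plogis(eta_s1)) == 1L
    ss <- sdl[surv_s, ]
    d_size <- rtnorm_lower(nrow(ss), p$newsize_mean + eps["d"], p$newsize_sd)

    ## recruitment from this year's flowering adults
    a_count <- tabulate(live$zone[is_flw], nbins = nz)
    n_rec <- stats::rpois(nz, p$recruit_rate * a_count)
    rec_zone <- rep(seq_len(nz), n_rec)
    rec_ids <- seq.int(next_id, length.out = length(rec_zone))
    next_id <- next_id + length(rec_zone)

    ## latent bookkeeping (per year t0, zone)
    zf <- factor(veg$zone, levels = seq_len(nz))
    zs <- factor(sdl$zone, levels = seq_len(nz))
    zvs <- factor(vs$zone, levels = seq_len(nz))
    zgr <- factor(grower$zone, levels = seq_len(nz))
    zss <- factor(ss$zone, levels = seq_len(nz))
    cell <- function(rate, n, realized, expected) {
      data.frame(year = yr, zone = seq_len(nz), rate = rate, n = n,
                 realized = realized, expected = expected)
    }
    n_s1 <- tabulate(zs, nz)
    n_d <- tabulate(zss, nz)
    latent[[length(latent) + 1L]] <- rbind(
      cell("s1", n_s1, ifelse(n_s1 > 0, n_d / n_s1, NA),
           stats::plogis(p$s1_intercepts + p$s1_climate_slopes * x + eps["s1"])),
      cell("s2", tabulate(zf, nz),
           ifelse(tabulate(zf, nz) > 0,
                  tabulate(factor(veg$zone[surv_v], seq_len(nz)), nz) /
                    tabulate(zf, nz), NA),
           as.numeric(tapply(stats::plogis(eta_s2), zf, mean))),
      cell("a", tabulate(zvs, nz),
           ifelse(tabulate(zvs, nz) > 0,
                  tabulate(factor(vs$zone[flw], seq_len(nz)), nz) /
                    tabulate(zvs, nz), NA),
           as.numeric(tapply(stats::plogis(eta_a), zvs, mean))),
      cell("g", tabulate(zgr, nz),
           as.numeric(tapply(new_size, zgr, mean)),
           as.numeric(tapply(mu_g, zgr, mean))),
      cell("d", n_d,
           as.numeric(tapply(d_size, zss, mean)),
           rep(p$newsize_mean + eps["d"], nz))
    )

    ## assemble next year's population
    live <- rbind(
      data.frame(plant_id = grower$plant_id, zone = grower$zone,
                 stage = rep("vegetative", nrow(grower)), size = new_size),
      data.frame(plant_id = vs$plant_id[flw], zone = vs$zone[flw],
                 stage = rep("flowering", sum(flw)),
                 size = rep(NA_real_, sum(flw))),
      data.frame(plant_id = ss$plant_id, zone = ss$zone,
                 stage = rep("vegetative", nrow(ss)), size = d_size),
      data.frame(plant_id = rec_ids, zone = rec_zone,
                 stage = rep("seedling", length(rec_ids)),
                 size = rep(NA_real_, length(rec_ids)))
    )
    if (nrow(live) == 0L) {
      census <- census[seq_len(t)]
      break
    }
  }

  census <- do.call(rbind, census)
  census <- census[order(census$plant_id, census$year), ]
  rownames(census) <- NULL
  structure(list(census = census,
                 latent = do.call(rbind, latent),
                 anomaly = data.frame(year_t0 = years[seq_along(anomaly_used)],
                                      anomaly = anomaly_used),
                 params = p),
            class = "census_sim")
}

#' Delete vegetative census records to emulate detection failure
#'
#' Each vegetative record is independently dropped with probability
#' `miss_prob`; seedling and flowering records, and the plant's underlying
#' fate, are untouched.  Used to exercise the transition builder's
#' gap-relinking and dead-after-three-missing-years rules.
#'
#' @param census A census data frame.
#' @param miss_prob Probability in `[0, 1)` of missing a vegetative record.
#' @param seed Optional RNG seed.
#' @return The census with some vegetative rows removed.
#' @export
apply_detection_noise <- function(census, miss_prob, seed = NULL) {
  if (miss_prob < 0 || miss_prob >= 1) stop_dunesync("need 0 <= miss_prob < 1")
  if (miss_prob == 0) return(census)
  if (!is.null(seed)) set.seed(seed)
  veg <- which(census$stage == "vegetative")
  drop <- veg[stats::runif(length(veg)) < miss_prob]
  if (length(drop)) census <- census[-drop, ]
  rownames(census) <- NULL
  census
}
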