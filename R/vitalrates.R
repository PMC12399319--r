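## Vital-rate mixed models.
##
## Five rates are modeled from the transition table, all with a random
## effect of the year-by-zone interaction only (no separate year or zone
## terms), so that zones are free to move in opposite directions within a
## year:
##   S1  seedling survival        Bernoulli-logit, intercept only
##   D   new-plant size (ln mm)   Gaussian, intercept only
##   S2  plant survival           Bernoulli-logit, ln-size fixed effect
##   G   growth (ln mm)           Gaussian, ln-size fixed effect
##   A   flowering probability    Bernoulli-logit, ln-size fixed effect
## Size-dependent rates carry a correlated random intercept and random
## size slope per (year, zone) cell; size-independent rates a random
## intercept.  The size covariate is centered on the rate data's mean for
## numerical stability; centering is undone in all reported predictions.

RATES <- c("S1", "S2", "G", "A", "D")

rate_family <- function(rate) {
  switch(rate, S1 = , S2 = , A = "binomial", G = , D = "gaussian",
         stop_dunesync("unknown rate: ", rate))
}

rate_has_size <- function(rate) rate %in% c("S2", "G", "A")

## Extract the analysis rows and response for one rate.
rate_data <- function(transitions, rate) {
  tr <- transitions
  d <- switch(rate,
    S1 = {
      s <- tr[tr$stage_t0 == "seedling", ]
      s$resp <- s$survived_t1
      s
    },
    D = {
      s <- tr[tr$stage_t0 == "seedling" & tr$survived_t1 == 1L &
                !is.na(tr$size_t1), ]
      s$resp <- s$size_t1
      s
    },
    S2 = {
      s <- tr[tr$stage_t0 == "vegetative" & !is.na(tr$size_t0), ]
      s$resp <- s$survived_t1
      s
    },
    A = {
      s <- tr[tr$stage_t0 == "vegetative" & !is.na(tr$size_t0) &
                tr$survived_t1 == 1L, ]
      s$resp <- s$flowered_t1
      s
    },
    G = {
      s <- tr[tr$stage_t0 == "vegetative" & tr$survived_t1 == 1L &
                tr$flowered_t1 == 0L & !is.na(tr$size_t0) &
                !is.na(tr$size_t1), ]
      s$resp <- s$size_t1
      s
    },
    stop_dunesync("unknown rate: ", rate))
  d$year <- factor(d$year_t0)
  d$zone <- factor(d$zone)
  d$cell <- interaction(d$year, d$zone, drop = TRUE, sep = ":")
  d
}

#' Fit one vital-rate mixed model
#'
#' Fits the rate's generalized linear mixed model with a random effect of
#' the year-by-zone interaction (random intercept for S1 and D; correlated
#' random intercept and ln-size slope for S2, G and A), via [lme4::glmer()]
#' / [lme4::lmer()] (Gaussian fits use ML, not REML).  Seedling survival is
#' fitted on (year, zone)-aggregated binomial counts, which has the same
#' likelihood as the Bernoulli form.
#'
#' @param transitions A [build_transitions()] table.
#' @param rate One of `"S1", "S2", "G", "A", "D"`.
#' @return An object of class `vital_rate_fit`: list with the rate id,
#'   family, fixed `coefficients` (on the uncentered ln-size scale),
#'   per-cell random effects (`ranef`), `center` (size centering constant),
#'   `sigma` (residual SD, Gaussian rates), `cells`, `model`, `converged`,
#'   `logLik` and `n`.
#' @details Bernoulli rates whose observed responses are all successes or
#'   all failures are refused (complete separation: the MLE is infinite).
#' @examples
#' \donttest{
#' p <- generator_params(n_years = 8, init_per_zone = 60)
#' clim <- generate_climate(12, seed = 1, start_year = p$start_year - 4)
#' sim <- generate_population(p, clim, seed = 2)
#' tr <- build_transitions(sim$census)
#' fit <- fit_vital_rate(tr, "S1")
#' fit$coefficients
#' }
#' @export
fit_vital_rate <- function(transitions, rate) {
  rate <- match.arg(rate, RATES)
  d <- rate_data(transitions, rate)
  if (nlevels(d$cell) < 2L) {
    stop_dunesync("need >= 2 (year, zone) cells with data for rate ", rate)
  }
  fam <- rate_family(rate)
  if (fam == "binomial" && length(unique(d$resp)) < 2L) {
    stop_dunesync("complete separation for rate ", rate,
                  ": all responses are ", d$resp[1])
  }
  center <- if (rate_has_size(rate)) mean(d$size_t0) else 0
  d$size_c <- if (rate_has_size(rate)) d$size_t0 - center else 0

  converged <- TRUE
  note <- withCallingHandlers({
    fit <- if (rate == "S1") {
      agg <- stats::aggregate(cbind(succ = resp, fail = 1 - resp) ~
                                year + zone + cell, data = d, FUN = sum)
      lme4::glmer(cbind(succ, fail) ~ 1 + (1 | cell), data = agg,
                  family = stats::binomial())
    } else if (rate == "D") {
      lme4::lmer(resp ~ 1 + (1 | cell), data = d, REML = FALSE)
    } else if (fam == "binomial") {
      lme4::glmer(resp ~ size_c + (size_c | cell), data = d,
                  family = stats::binomial())
    } else {
      lme4::lmer(resp ~ size_c + (size_c | cell), data = d, REML = FALSE)
    }
    NULL
  }, warning = function(w) {
    if (grepl("converge|singular", conditionMessage(w), ignore.case = TRUE)) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    }
  })

  re <- lme4::ranef(fit)$cell
  names(re) <- c("intercept", "size_slope")[seq_len(ncol(re))]
  cells <- unique(d[, c("year", "zone", "cell")])
  fx <- lme4::fixef(fit)
  ## report the intercept on the uncentered size scale
  coef_out <- c(intercept = unname(fx[1]) -
                  if (rate_has_size(rate)) unname(fx["size_c"]) * center else 0)
  if (rate_has_size(rate)) coef_out["size_slope"] <- unname(fx["size_c"])

  structure(list(
    rate = rate, family = fam, model = fit,
    coefficients = coef_out, fixef = fx, center = center,
    ranef = re, cells = cells,
    sigma = if (fam == "gaussian") stats::sigma(fit) else NA_real_,
    size_mean = if (rate_has_size(rate)) mean(d$size_t0) else NA_real_,
    size_sd = if (rate_has_size(rate)) stats::sd(d$size_t0) else NA_real_,
    converged = converged,
    logLik = stats::logLik(fit),
    n = nrow(d)
  ), class = "vital_rate_fit")
}

#' @export
print.vital_rate_fit <- function(x, ...) {
  cat(sprintf("<vital_rate_fit %s (%s), n = %d, %d cells%s>\n", x$rate,
              x$family, x$n, nrow(x$cells),
              if (x$converged) "" else ", NOT converged"))
  print(x$coefficients)
  invisible(x)
}

#' Cell-level mean prediction on the response scale
#'
#' Evaluates the fixed effects plus the (year, zone) cell's conditional
#' random effects at a given ln-size, applying the inverse link.
#'
#' @param fit A [fit_vital_rate()] object.
#' @param year,zone Cell labels (coerced to character); vectors recycle.
#' @param size ln taproot diameter (mm); ignored for S1 and D.  Defaults
#'   to the rate data's mean size.
#' @return Numeric vector of predictions (probabilities for Bernoulli
#'   rates, ln-mm means for Gaussian rates).
#' @export
predict_cell <- function(fit, year, zone, size = NULL) {
  stopifnot(inherits(fit, "vital_rate_fit"))
  key <- paste(year, zone, sep = ":")
  i <- match(key, rownames(fit$ranef))
  if (anyNA(i)) {
    stop_dunesync("unknown (year, zone) cell(s): ",
                  paste(unique(key[is.na(i)]), collapse = ", "))
  }
  if (rate_has_size(fit$rate)) {
    if (is.null(size)) size <- fit$size_mean
    sc <- size - fit$center
    eta <- fit$fixef[1] + fit$ranef$intercept[i] +
      (fit$fixef["size_c"] + fit$ranef$size_slope[i]) * sc
  } else {
    eta <- fit$fixef[1] + fit$ranef$intercept[i]
  }
  eta <- unname(eta)
  if (fit$family == "binomial") stats::plogis(eta) else eta
}

#' Matrix of cell predictions (zones x years)
#'
#' Convenience wrapper around [predict_cell()] evaluating every fitted
#' (year, zone) cell at a common size: the rate data's mean size by
#' default, or one SD above it (`size_at = "mean_plus_sd"`) as used for
#' flowering probability, where variation is only visible for large
#' plants.
#'
#' @param fit A [fit_vital_rate()] object.
#' @param size_at `"mean"`, `"mean_plus_sd"`, or a number (ln mm).
#' @return Numeric matrix with zones as rows and years as columns; cells
#'   absent from the data are `NA`.
#' @export
cell_prediction_matrix <- function(fit, size_at = "mean") {
  size <- if (is.numeric(size_at)) size_at
  else switch(size_at,
              mean = fit$size_mean,
              mean_plus_sd = fit$size_mean + fit$size_sd,
              stop_dunesync("size_at must be 'mean', 'mean_plus_sd' or a number"))
  years <- sort(unique(as.character(fit$cells$year)))
  zones <- sort(unique(as.character(fit$cells$zone)))
  mat <- matrix(NA_real_, length(zones), length(years),
                dimnames = list(zone = zones, year = years))
  cc <- fit$cells
  mat[cbind(match(as.character(cc$zone), zones),
            match(as.character(cc$year), years))] <-
    predict_cell(fit, as.character(cc$year), as.character(cc$zone), size)
  mat
}

#' Pooled zone-specific recruitment
#'
#' Seedlings per reproductive adult, pooled over years within each zone:
#' `r_zone = sum_t seedlings(zone, t+1) / sum_t flowering(zone, t)`.
#' Pooling avoids dividing by zero in zone-years without flowering plants.
#'
#' @param census Census data frame.
#' @return Named numeric vector, one element per zone.
#' @export
recruitment <- function(census) {
  validate_census(census)
  zones <- sort(unique(census$zone))
  years <- sort(unique(census$year))
  if (length(years) < 2L) stop_dunesync("need >= 2 census years")
  t0s <- years[-length(years)]
  r <- vapply(zones, function(z) {
    sub <- census[census$zone == z, ]
    adults <- sum(sub$stage == "flowering" & sub$year %in% t0s)
    seedl <- sum(sub$stage == "seedling" & sub$year %in% (t0s + 1L))
    if (adults == 0L) {
      stop_dunesync("zone ", z, " has no flowering adults in any t0 year; ",
                    "recruitment is undefined")
    }
    seedl / adults
  }, numeric(1))
  names(r) <- zones
  r
}
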