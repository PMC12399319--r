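test_that("transition building encodes the field-protocol rules", {
  tr <- build_transitions(tiny_census())

  ## vegetative -> flowering: survived and flowered
  t1 <- tr[tr$plant_id == 1, ]
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$survived_t1, 1L)
  expect_equal(t1$flowered_t1, 1L)
  expect_equal(t1$size_t0, 2.1)

  ## seedling -> vegetative: an S1 success carrying the new-plant size
  t2 <- tr[tr$plant_id == 2 & tr$year_t0 == 2010, ]
  expect_equal(t2$stage_t0, "seedling")
  expect_equal(t2$survived_t1, 1L)
  expect_equal(t2$size_t1, 1.4)

  ## absent >= 3 years and never seen again: dead in first missing year
  t3 <- tr[tr$plant_id == 3, ]
  expect_equal(t3$year_t0, 2012)
  expect_equal(t3$survived_t1, 0L)

  ## re-found after a gap: survival credited through the gap, sizes NA
  t4 <- tr[tr$plant_id == 4, ]
  expect_equal(t4$year_t0, c(2010, 2011, 2012))
  expect_equal(t4$survived_t1, c(1L, 1L, 0L))
  expect_equal(t4$observed_t0, c(TRUE, FALSE, TRUE))
  expect_true(is.na(t4$size_t0[2]))
  expect_equal(t4$size_t1[2], 2.3)

  ## final-year record yields no transition; and plant 5 is in the final
  ## census year
  expect_equal(nrow(tr[tr$plant_id == 5, ]), 0L)
})

test_that("a recently missing plant is censored, not scored dead", {
  cen <- data.frame(plant_id = 1, zone = 1, year = 2020,
                    stage = "vegetative", size = 2)
  ## absent 2021-2022 only: fate unresolved
  expect_error(build_transitions(cen, last_census_year = 2022),
               "no transitions")
  ## absent 2021-2023: dead
  tr <- build_transitions(cen, last_census_year = 2023)
  expect_equal(tr$survived_t1, 0L)
})

test_that("census violations are rejected", {
  dup <- data.frame(plant_id = c(1, 1), zone = 1, year = c(2010, 2010),
                    stage = "vegetative", size = c(2, 2))
  expect_error(build_transitions(dup), "duplicate")
  zombie <- data.frame(plant_id = c(1, 1), zone = 1, year = c(2010, 2011),
                       stage = c("flowering", "vegetative"), size = c(NA, 2))
  expect_error(build_transitions(zombie), "monocarpy")
  revert <- data.frame(plant_id = c(1, 1), zone = 1, year = c(2010, 2011),
                       stage = c("vegetative", "seedling"), size = c(2, NA))
  expect_error(build_transitions(revert), "reverts")
})

test_that("gap handling survives detection noise end to end", {
  fx <- shared_sim()
  noisy <- apply_detection_noise(fx$sim$census, 0.08, seed = 55)
  tr <- build_transitions(noisy)
  ## some gap transitions exist and carry survival through the gap
  gaps <- tr[!tr$observed_t0, ]
  expect_gt(nrow(gaps), 0)
  expect_true(all(gaps$survived_t1 == 1L))
  expect_true(all(is.na(gaps$size_t0)))
})

test_that("surviving-seedling transitions equal new-plant size observations", {
  fx <- shared_sim()
  tr <- fx$transitions
  years <- sort(unique(tr$year_t0))
  for (y in years) {
    s1_surv <- sum(tr$stage_t0 == "seedling" & tr$year_t0 == y &
                     tr$survived_t1 == 1L)
    d_obs <- sum(tr$stage_t0 == "seedling" & tr$year_t0 == y &
                   !is.na(tr$size_t1))
    expect_identical(s1_surv, d_obs)
  }
})

test_that("intercept-only rates are recovered on zero-variance data", {
  ## seedling survival 0.5 with no year/zone heterogeneity
  set.seed(77)
  n <- 5000
  cells <- expand.grid(year = 2001:2010, zone = 1:5)
  idx <- sample(nrow(cells), n, replace = TRUE)
  tr <- data.frame(plant_id = seq_len(n), zone = cells$zone[idx],
                   year_t0 = cells$year[idx], stage_t0 = "seedling",
                   size_t0 = NA_real_,
                   survived_t1 = rbinom(n, 1, 0.5), flowered_t1 = 0L,
                   size_t1 = NA_real_, observed_t0 = TRUE)
  tr$size_t1[tr$survived_t1 == 1] <- rnorm(sum(tr$survived_t1), 1.3, 0.35)
  fit <- fit_vital_rate(tr, "S1")
  se <- sqrt(vcov(fit$model)[1, 1])
  expect_lt(abs(fit$coefficients["intercept"] - 0), 2 * se + 0.01)

  ## new-plant size recovered too
  fd <- fit_vital_rate(tr, "D")
  expect_lt(abs(fd$coefficients["intercept"] - 1.3), 0.05)
})

test_that("Gaussian growth recovers slope and residual SD", {
  set.seed(78)
  n <- 3000
  cells <- expand.grid(year = 2001:2010, zone = 1:5)
  idx <- sample(nrow(cells), n, replace = TRUE)
  size0 <- runif(n, 1, 3.5)
  tr <- data.frame(plant_id = seq_len(n), zone = cells$zone[idx],
                   year_t0 = cells$year[idx], stage_t0 = "vegetative",
                   size_t0 = size0, survived_t1 = 1L, flowered_t1 = 0L,
                   size_t1 = 0.5 + 0.9 * size0 + rnorm(n, 0, 0.1),
                   observed_t0 = TRUE)
  fit <- fit_vital_rate(tr, "G")
  V <- as.matrix(vcov(fit$model))
  expect_lt(abs(fit$coefficients["size_slope"] - 0.9),
            2 * sqrt(V[2, 2]) + 0.005)
  expect_lt(abs(fit$sigma - 0.1) / 0.1, 0.10)
})

test_that("complete separation is refused, not silently fitted", {
  tr <- data.frame(plant_id = 1:100, zone = rep(1:2, 50),
                   year_t0 = rep(2001:2005, each = 20),
                   stage_t0 = "seedling", size_t0 = NA_real_,
                   survived_t1 = 1L, flowered_t1 = 0L, size_t1 = 1.5,
                   observed_t0 = TRUE)
  expect_error(fit_vital_rate(tr, "S1"), "separation")
})

test_that("cell predictions equal hand-evaluated linear predictors", {
  fx <- shared_sim()
  f2 <- fit_vital_rate(fx$transitions, "S2")
  cell <- fx$transitions[fx$transitions$stage_t0 == "vegetative", ][1, ]
  y <- as.character(cell$year_t0); z <- as.character(cell$zone)
  key <- paste(y, z, sep = ":")
  size <- 2.2
  eta <- f2$fixef[1] + f2$ranef[key, "intercept"] +
    (f2$fixef["size_c"] + f2$ranef[key, "size_slope"]) * (size - f2$center)
  expect_equal(predict_cell(f2, y, z, size), unname(plogis(eta)))
  expect_error(predict_cell(f2, "1900", z), "unknown")

  ## Gaussian intercept-only prediction is fixed + cell intercept exactly
  fd <- fit_vital_rate(fx$transitions, "D")
  key2 <- rownames(fd$ranef)[3]
  parts <- strsplit(key2, ":")[[1]]
  expect_equal(predict_cell(fd, parts[1], parts[2]),
               unname(fd$fixef[1] + fd$ranef[key2, "intercept"]))
})

test_that("count-weighted Bernoulli cell predictions track the raw rate", {
  fx <- shared_sim()
  tr <- fx$transitions
  f1 <- fit_vital_rate(tr, "S1")
  d <- tr[tr$stage_t0 == "seedling", ]
  raw <- mean(d$survived_t1)
  pred <- predict_cell(f1, as.character(d$year_t0), as.character(d$zone))
  expect_lt(abs(mean(pred) - raw), 0.05)
})

test_that("recruitment pools seedlings over flowering adults by zone", {
  cen <- rbind(
    data.frame(plant_id = 1:5, zone = 1, year = 2010, stage = "flowering",
               size = NA),
    data.frame(plant_id = 6:15, zone = 1, year = 2011, stage = "seedling",
               size = NA),
    data.frame(plant_id = 16, zone = 1, year = 2011, stage = "flowering",
               size = NA),
    data.frame(plant_id = 17, zone = 1, year = 2012, stage = "vegetative",
               size = 2)
  )
  ## seedlings (10, 0) over flowering (5, 1) pooled: 10/6
  expect_equal(unname(recruitment(cen)), 10 / 6)

  ## no seedlings ever: r = 0
  cen2 <- cen[cen$stage != "seedling", ]
  expect_equal(unname(recruitment(cen2)), 0)

  ## no flowering adults: undefined
  cen3 <- cen[cen$stage != "flowering", ]
  expect_error(recruitment(cen3), "undefined")
})

test_that("recruitment estimate sits inside Poisson bounds of the truth", {
  fx <- shared_sim()
  r_hat <- recruitment(fx$sim$census)
  cen <- fx$sim$census
  years <- sort(unique(cen$year)); t0s <- years[-length(years)]
  for (z in c(1, 5)) {
    adults <- sum(cen$zone == z & cen$stage == "flowering" & cen$year %in% t0s)
    truth <- fx$params$recruit_rate[z]
    ## 99.5% Poisson interval on the pooled count
    expect_lt(abs(r_hat[[as.character(z)]] - truth),
              2.8 * sqrt(truth / adults))
  }
})
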