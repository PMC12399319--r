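test_that("window enumeration count follows the triangular formula", {
  expect_equal(nrow(enumerate_windows(36)), 703L)
  expect_equal(nrow(enumerate_windows(0)), 1L)
  expect_equal(nrow(enumerate_windows(2)), 6L)
  for (k in 0:36) {
    expect_equal(nrow(enumerate_windows(k)), (k + 1) * (k + 2) / 2)
  }
  w <- enumerate_windows(3)
  expect_true(all(w$close <= w$open))
  expect_false(any(duplicated(w)))
  expect_error(enumerate_windows(-1), ">= 0")
})

test_that("window covariates equal directly computed window means", {
  clim <- generate_climate(12, seed = 41, start_year = 2004)
  an <- monthly_anomalies(clim, "prcp")
  windows <- enumerate_windows(6)
  W <- dunesync:::window_covariates(an, 2010:2013, windows)
  for (j in c(1, 10, 25)) {
    for (y in c(2010, 2013)) {
      expect_equal(unname(W[as.character(y), j]),
                   window_mean(an, y + 1, window_spec(windows$open[j],
                                                      windows$close[j])))
    }
  }
})

test_that("the small-sample correction vanishes for large n", {
  expect_equal(dunesync:::aicc_value(100, 8, 1e6), 100, tolerance = 1e-3)
  expect_gt(dunesync:::aicc_value(100, 8, 30), 100 + 2)
  ## n <= k + 1 is off the valid range
  expect_equal(dunesync:::aicc_value(100, 8, 9), Inf)
})

test_that("candidate and baseline models differ by one slope per zone", {
  fx <- shared_sim()
  an <- monthly_anomalies(fx$climate, "prcp")
  base <- baseline_model(fx$transitions, "S1")
  wf <- fit_window_model(fx$transitions, an, "S1", window_spec(8, 4),
                         baseline_aicc = base$aicc)
  k_cand <- attr(logLik(wf$fit), "df")
  k_base <- attr(logLik(base$fit), "df")
  expect_equal(k_cand - k_base, 5L)
  expect_equal(length(wf$zone_slopes), 5L)
  ## deterministic: same data, same AICc
  wf2 <- fit_window_model(fx$transitions, an, "S1", window_spec(8, 4),
                          baseline_aicc = base$aicc)
  expect_identical(wf$aicc, wf2$aicc)
})

test_that("a constant climate covariate is flagged, not crashed on", {
  fx <- shared_sim()
  clim0 <- fx$climate
  an0 <- monthly_anomalies(clim0, "prcp")
  an0$anomaly[] <- 0
  wf <- fit_window_model(fx$transitions, an0, "S1", window_spec(3, 0))
  expect_false(wf$converged)
  expect_true(is.na(wf$aicc))
  expect_match(wf$message, "constant")
})

test_that("null climate slopes stay within their standard errors", {
  ## climate-free generator: fitted per-zone slopes should sit within 2 SE
  ## of zero almost always
  nrep <- 40
  n_par <- 0; n_cover <- 0
  for (i in seq_len(nrep)) {
    p <- generator_params(n_years = 8, init_per_zone = 50,
                          s1_climate_slopes = 0, s2_climate_slopes = 0,
                          growth_climate_slopes = 0)
    clim <- generate_climate(12, seed = 7000 + i, start_year = p$start_year - 4L)
    sim <- generate_population(p, clim, seed = 8000 + i)
    tr <- build_transitions(sim$census)
    an <- monthly_anomalies(clim, "prcp")
    wf <- fit_window_model(tr, an, "S1", window_spec(8, 4), nAGQ = 1L)
    if (!wf$converged || is.null(wf$fit)) next
    V <- as.matrix(vcov(wf$fit))
    ses <- sqrt(diag(V)[grepl("clim", colnames(V))])
    n_par <- n_par + length(wf$zone_slopes)
    n_cover <- n_cover + sum(abs(wf$zone_slopes) <= 2 * ses)
  }
  expect_gt(n_cover / n_par, 0.9)
})

test_that("a strong planted effect beats the baseline decisively", {
  nrep <- 8; wins <- 0
  for (i in seq_len(nrep)) {
    p <- generator_params(n_years = 12, init_per_zone = 80,
                          s1_climate_slopes = seq(-2, 2, length.out = 5))
    clim <- generate_climate(16, seed = 8100 + i, start_year = p$start_year - 4L)
    sim <- generate_population(p, clim, seed = 8200 + i)
    tr <- build_transitions(sim$census)
    an <- monthly_anomalies(clim, "prcp")
    wf <- fit_window_model(tr, an, "S1", p$true_window)
    wins <- wins + (wf$delta_aicc < -10)
  }
  expect_gte(wins, 6)
})

test_that("without climate effects the baseline is rarely beaten by much", {
  nrep <- 15; ok <- 0
  for (i in seq_len(nrep)) {
    p <- generator_params(n_years = 9, init_per_zone = 50,
                          s1_climate_slopes = 0, s2_climate_slopes = 0,
                          growth_climate_slopes = 0)
    clim <- generate_climate(13, seed = 8300 + i, start_year = p$start_year - 4L)
    sim <- generate_population(p, clim, seed = 8400 + i)
    tr <- build_transitions(sim$census)
    an <- list(prcp = monthly_anomalies(clim, "prcp"))
    sc <- scan_windows(tr, an, "S1", max_offset = 2)
    ok <- ok + (sc$baseline_aicc <= sc$best$aicc + 2)
  }
  expect_gt(ok / nrep, 0.5)
})

test_that("exact AICc ties break to the shortest, most recent window", {
  ## a climate table whose values depend only on year makes every window
  ## mean identical, so all candidates tie exactly
  fx <- shared_sim()
  clim <- fx$climate
  yr_val <- rnorm(length(unique(clim$year)))
  names(yr_val) <- sort(unique(clim$year))
  clim$flat <- yr_val[as.character(clim$year)]
  an <- monthly_anomalies(clim, "flat")
  expect_message(
    sc <- scan_windows(fx$transitions, list(flat = an), "S1", max_offset = 1),
    "tie"
  )
  expect_equal(sc$best$window$open, 0L)
  expect_equal(sc$best$window$close, 0L)
})

test_that("scan output is complete and ordered deterministically", {
  fx <- shared_sim()
  an <- list(prcp = monthly_anomalies(fx$climate, "prcp"),
             tmean = monthly_anomalies(fx$climate, "tmean"))
  sc <- scan_windows(fx$transitions, an, "S1", max_offset = 3)
  expect_equal(nrow(sc$results), 2 * 10)
  expect_setequal(unique(sc$results$variable), c("prcp", "tmean"))
  expect_true(all(c("slope_zone1", "slope_zone5") %in% names(sc$results)))
  ## rescan reproduces the selection (no RNG involved)
  sc2 <- scan_windows(fx$transitions, an, "S1", max_offset = 3)
  expect_identical(sc$results$aicc, sc2$results$aicc)
  expect_identical(sc$best$window, sc2$best$window)
})

test_that("randomization p has the add-one resolution and is reproducible", {
  fx <- shared_sim()
  an <- list(prcp = monthly_anomalies(fx$climate, "prcp"))
  rt <- randomization_test(fx$transitions, an, "S1", n_perm = 19, seed = 91,
                           max_offset = 1)
  expect_gte(rt$p, 1 / 20)
  expect_lte(rt$p, 1)
  expect_equal(length(rt$null), 19)
  rt2 <- randomization_test(fx$transitions, an, "S1", n_perm = 19, seed = 91,
                            max_offset = 1)
  expect_identical(rt$p, rt2$p)
  expect_error(randomization_test(fx$transitions, an, "S1", n_perm = 0),
               "n_perm")
})

test_that("fast block-permutation path matches fresh refits exactly", {
  fx <- shared_sim()
  an <- list(prcp = monthly_anomalies(fx$climate, "prcp"))
  set.seed(91)
  obs <- scan_windows(fx$transitions, an, "S1", max_offset = 1)
  d <- obs$sd_obj$data
  years <- sort(unique(as.character(d$year)))
  ny <- length(years)
  W <- dunesync:::window_covariates(an$prcp, as.integer(years),
                                    enumerate_windows(1))
  nulls <- numeric(4)
  ## one identity evaluation mirrors the fast path's observed statistic
  for (b in seq_len(4)) {
    perm <- sample.int(ny)
    best <- Inf
    for (j in 1:3) {
      Wp <- W[perm, , drop = FALSE]
      rownames(Wp) <- years
      sd2 <- obs$sd_obj
      sd2$data$clim <- Wp[as.character(d$year), j]
      r <- dunesync:::fit_scan_model(sd2, TRUE, 0L)
      if (!is.na(r$aicc) && r$aicc < best) best <- r$aicc
    }
    nulls[b] <- best - obs$baseline_aicc
  }
  set.seed(91)
  rt <- randomization_test(fx$transitions, an, "S1", n_perm = 4,
                           max_offset = 1)
  expect_equal(rt$null, nulls, tolerance = 1e-3)
})

test_that("strong planted effects yield the smallest possible p", {
  p <- generator_params(n_years = 12, init_per_zone = 80,
                        s1_climate_slopes = seq(-2, 2, length.out = 5))
  clim <- generate_climate(16, seed = 93, start_year = p$start_year - 4L)
  sim <- generate_population(p, clim, seed = 94)
  tr <- build_transitions(sim$census)
  an <- list(prcp = monthly_anomalies(clim, "prcp"))
  rt <- randomization_test(tr, an, "S1", n_perm = 19, seed = 95,
                           max_offset = 8)
  expect_equal(rt$p, 1 / 20)
})
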