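## Sliding-window climate-driver selection.
##
## For one vital rate, every candidate model pairs one climate variable
## with one absolute window of whole months before the census; the
## window-mean anomaly enters the rate's model as a per-zone slope
## (`zone + climate:zone` fixed effects, random intercept per transition
## year t0), and candidates compete on AICc against a climate-free
## baseline with the same random structure.  A year-randomization test
## reruns the scan with biological years remapped to climate years as
## whole blocks, building a null distribution of best-candidate support.

#' Enumerate absolute candidate windows
#'
#' All `(open, close)` pairs with `0 <= close <= open <= max_offset`,
#' ordered by `open` then `close`; a 37-month range (`max_offset = 36`)
#' yields 703 windows.
#'
#' @param max_offset Largest month offset before the census month.
#' @return Data frame with integer columns `open` and `close`.
#' @examples
#' nrow(enumerate_windows(36))  # 703
#' @export
enumerate_windows <- function(max_offset = 36L) {
  max_offset <- as.integer(max_offset)
  if (is.na(max_offset) || max_offset < 0L) {
    stop_dunesync("max_offset must be >= 0")
  }
  out <- do.call(rbind, lapply(0:max_offset, function(o)
    data.frame(open = o, close = 0:o)))
  out[order(out$open, out$close), c("open", "close")]
}

## Window-mean anomalies for every (transition year t0, window): matrix
## with one row per t0 year and one column per window, anchored at June of
## t1 = t0 + 1.
window_covariates <- function(anoms, years_t0, windows, anchor_month = 6L) {
  years_t0 <- sort(unique(as.integer(years_t0)))
  max_off <- max(windows$open)
  ## per t0 year, anomalies at offsets 0..max_off back from June of t1
  offs <- vapply(years_t0, function(y0) {
    mm <- offset_to_month(y0 + 1L, 0:max_off, anchor_month)
    key <- anoms$year * 12L + anoms$month
    idx <- match(mm$year * 12L + mm$month, key)
    if (anyNA(idx)) {
      stop_dunesync("anomaly series does not cover offsets 0..", max_off,
                    " for census year ", y0 + 1L)
    }
    anoms$anomaly[idx]
  }, numeric(max_off + 1L))
  ## offs is (max_off+1) x n_years; cumulative sums give window means
  if (is.null(dim(offs))) offs <- matrix(offs, nrow = 1L)
  cs <- apply(offs, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
  W <- matrix(NA_real_, length(years_t0), nrow(windows),
              dimnames = list(years_t0, NULL))
  for (j in seq_len(nrow(windows))) {
    o <- windows$open[j]; cl <- windows$close[j]
    tot <- cs[o + 1L, ] - if (cl > 0L) cs[cl, ] else 0
    W[, j] <- tot / (o - cl + 1L)
  }
  W
}

## Assemble the per-rate modeling frame for the scan. S1 is aggregated to
## (year, zone) binomial counts: same likelihood up to a constant that is
## identical for baseline and all candidates, so AICc differences are
## unaffected, and fits are much faster.
prepare_scan_data <- function(transitions, rate) {
  d <- rate_data(transitions, rate)
  has_size <- rate_has_size(rate)
  if (has_size) {
    d$size_c <- d$size_t0 - mean(d$size_t0)
  }
  n_units <- nrow(d)
  aggregated <- rate == "S1"
  if (aggregated) {
    d <- stats::aggregate(cbind(succ = resp, fail = 1 - resp) ~ year + zone,
                          data = d, FUN = sum)
    d$year <- droplevels(d$year)
    d$zone <- droplevels(d$zone)
    ## complete the (year, zone) grid with zero-trial rows: these are
    ## likelihood-neutral but keep every year block's composition equal,
    ## which the randomization test's block-permutation fast path needs
    full <- expand.grid(year = levels(d$year), zone = levels(d$zone),
                        stringsAsFactors = TRUE)
    d <- merge(full, d, by = c("year", "zone"), all.x = TRUE)
    d$succ[is.na(d$succ)] <- 0
    d$fail[is.na(d$fail)] <- 0
    d <- d[order(d$year, d$zone), ]
    rownames(d) <- NULL
  }
  if (nlevels(droplevels(d$year)) < 2L) {
    stop_dunesync("need >= 2 distinct transition years for rate ", rate)
  }
  list(data = d, rate = rate, family = rate_family(rate),
       has_size = has_size, aggregated = aggregated, n_units = n_units)
}

scan_control <- function() {
  list(glmer = lme4::glmerControl(calc.derivs = FALSE),
       lmer = lme4::lmerControl(calc.derivs = FALSE))
}

## Fit one scan model (baseline if `climate = FALSE`). Returns list(fit,
## aicc, converged, message).
fit_scan_model <- function(sd_obj, climate = TRUE, nAGQ = 0L) {
  d <- sd_obj$data
  rhs <- c(if (sd_obj$has_size) "size_c", "zone",
           if (climate) "clim:zone", "(1 | year)")
  lhs <- if (sd_obj$aggregated) "cbind(succ, fail)" else "resp"
  form <- stats::as.formula(paste(lhs, "~", paste(rhs, collapse = " + ")))
  if (climate && (!("clim" %in% names(d)) || stats::sd(d$clim) == 0)) {
    return(list(fit = NULL, aicc = NA_real_, converged = FALSE,
                message = "constant climate covariate"))
  }
  converged <- TRUE
  msg <- NULL
  ctrl <- scan_control()
  fit <- tryCatch(
    withCallingHandlers({
      if (sd_obj$family == "binomial") {
        lme4::glmer(form, data = d, family = stats::binomial(),
                    nAGQ = nAGQ, control = ctrl$glmer)
      } else {
        lme4::lmer(form, data = d, REML = FALSE, control = ctrl$lmer)
      }
    }, warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
        msg <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }
    }),
    error = function(e) {
      converged <<- FALSE
      msg <<- conditionMessage(e)
      NULL
    })
  list(fit = fit,
       aicc = if (is.null(fit)) NA_real_ else aicc(fit, sd_obj$n_units),
       converged = converged, message = msg)
}

extract_zone_slopes <- function(fit) {
  fx <- lme4::fixef(fit)
  slopes <- fx[grepl("clim", names(fx))]
  names(slopes) <- sub("clim", "", gsub(":", "", names(slopes)))
  slopes
}

#' Climate-free baseline model for one vital rate
#'
#' Same fixed structure as the candidates minus all climate terms
#' (`size + zone` fixed effects where applicable, random intercept per
#' transition year), fitted by ML.
#'
#' @param transitions A [build_transitions()] table.
#' @param rate One of `"S1", "S2", "G", "A", "D"`.
#' @param nAGQ Integration setting for binomial fits (see
#'   [lme4::glmer()]); 0 uses the fast penalized-least-squares
#'   approximation used throughout the scan.
#' @return List with `aicc`, `fit`, `converged`, `n`.
#' @export
baseline_model <- function(transitions, rate, nAGQ = 0L) {
  sd_obj <- prepare_scan_data(transitions, rate)
  res <- fit_scan_model(sd_obj, climate = FALSE, nAGQ = nAGQ)
  if (is.null(res$fit)) {
    stop_dunesync("baseline model failed for rate ", rate, ": ", res$message)
  }
  list(aicc = res$aicc, fit = res$fit, converged = res$converged,
       n = sd_obj$n_units)
}

#' Fit one candidate climate-window model
#'
#' The rate's model with fixed effects `size (where applicable) + zone +
#' climate:zone` — one climate slope per zone, testing climate's role in
#' zone asynchrony — and a random intercept per transition year; the
#' climate covariate is the window-mean anomaly of one variable.
#'
#' @param transitions A [build_transitions()] table.
#' @param anoms An [monthly_anomalies()] series.
#' @param rate Vital-rate id.
#' @param window A [window_spec()].
#' @param baseline_aicc Optional baseline AICc; computed if missing.
#' @param anchor_month Census month (default June).
#' @param nAGQ See [baseline_model()].
#' @return List of class `window_fit` with `rate`, `variable`, `window`,
#'   `aicc`, `delta_aicc`, `zone_slopes`, `coefficients`, `converged`,
#'   `n`, `fit`.
#' @export
fit_window_model <- function(transitions, anoms, rate, window,
                             baseline_aicc = NULL, anchor_month = 6L,
                             nAGQ = 0L) {
  sd_obj <- prepare_scan_data(transitions, rate)
  wdf <- data.frame(open = window$open, close = window$close)
  W <- window_covariates(anoms, as.integer(as.character(sd_obj$data$year)),
                         wdf, anchor_month)
  sd_obj$data$clim <- W[as.character(sd_obj$data$year), 1L]
  if (is.null(baseline_aicc)) {
    baseline_aicc <- fit_scan_model(sd_obj, climate = FALSE, nAGQ = nAGQ)$aicc
  }
  res <- fit_scan_model(sd_obj, climate = TRUE, nAGQ = nAGQ)
  structure(list(
    rate = rate, variable = attr(anoms, "variable"), window = window,
    aicc = res$aicc, delta_aicc = res$aicc - baseline_aicc,
    zone_slopes = if (!is.null(res$fit)) extract_zone_slopes(res$fit),
    coefficients = if (!is.null(res$fit)) lme4::fixef(res$fit),
    converged = res$converged, message = res$message,
    n = sd_obj$n_units, fit = res$fit
  ), class = "window_fit")
}

#' Sliding-window scan for one vital rate
#'
#' Fits every (variable, window) candidate, one variable at a time, and
#' selects the AICc minimizer among converged candidates.  Exact AICc ties
#' are broken deterministically: shorter window first, then the more
#' recent (smaller `close`), then variable order; ties are reported with a
#' message.
#'
#' @param transitions A [build_transitions()] table.
#' @param anoms_list Named list of [monthly_anomalies()] series, one per
#'   climate variable.
#' @param rate Vital-rate id.
#' @param max_offset Scan depth in months (default 36, i.e. 703 windows
#'   per variable).
#' @param anchor_month Census month (default June).
#' @param nAGQ See [baseline_model()].
#' @param keep_fits Keep every fitted candidate (memory-heavy; needed by
#'   the fast randomization path, which sets it internally).
#' @return Object of class `window_scan`: list with `results` (one row per
#'   candidate: variable, open, close, aicc, delta_aicc, converged, and
#'   per-zone slopes), `best` (a `window_fit`), `baseline_aicc`,
#'   `n_failed`, `rate`, `n`.
#' @export
scan_windows <- function(transitions, anoms_list, rate, max_offset = 36L,
                         anchor_month = 6L, nAGQ = 0L, keep_fits = FALSE) {
  if (inherits(anoms_list, "anomaly_series")) {
    anoms_list <- stats::setNames(list(anoms_list), attr(anoms_list, "variable"))
  }
  windows <- enumerate_windows(max_offset)
  sd_obj <- prepare_scan_data(transitions, rate)
  years <- as.integer(as.character(sort(unique(sd_obj$data$year))))
  base <- fit_scan_model(sd_obj, climate = FALSE, nAGQ = nAGQ)
  if (is.null(base$fit)) {
    stop_dunesync("baseline model failed for rate ", rate, ": ", base$message)
  }

  nz <- nlevels(sd_obj$data$zone)
  res_rows <- vector("list", length(anoms_list) * nrow(windows))
  fits <- if (keep_fits) vector("list", length(res_rows))
  k <- 0L
  yr_chr <- as.character(sd_obj$data$year)
  for (v in names(anoms_list)) {
    W <- window_covariates(anoms_list[[v]], years, windows, anchor_month)
    for (j in seq_len(nrow(windows))) {
      k <- k + 1L
      sd_obj$data$clim <- W[yr_chr, j]
      r <- fit_scan_model(sd_obj, climate = TRUE, nAGQ = nAGQ)
      slopes <- if (!is.null(r$fit)) extract_zone_slopes(r$fit) else
        rep(NA_real_, nz)
      res_rows[[k]] <- c(list(variable = v, open = windows$open[j],
                              close = windows$close[j], aicc = r$aicc,
                              delta_aicc = r$aicc - base$aicc,
                              converged = r$converged),
                         as.list(stats::setNames(unname(slopes),
                                                 paste0("slope_zone",
                                                        levels(sd_obj$data$zone)))))
      if (keep_fits) fits[[k]] <- r$fit
    }
  }
  results <- do.call(rbind, lapply(res_rows, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  ok <- which(results$converged & is.finite(results$aicc))
  if (!length(ok)) stop_dunesync("all candidate models failed for rate ", rate)
  o <- ok[order(results$aicc[ok],
                results$open[ok] - results$close[ok],
                results$close[ok],
                match(results$variable[ok], names(anoms_list)))]
  besti <- o[1L]
  tied <- ok[results$aicc[ok] == results$aicc[besti]]
  if (length(tied) > 1L) {
    message("window scan: ", length(tied),
            " candidates tied on AICc; tie broken by window length, ",
            "recency, then variable order")
  }
  best <- list(rate = rate, variable = results$variable[besti],
               window = window_spec(results$open[besti], results$close[besti]),
               aicc = results$aicc[besti],
               delta_aicc = results$delta_aicc[besti],
               zone_slopes = unlist(results[besti, grepl("^slope_zone",
                                                         names(results))]),
               converged = TRUE, n = sd_obj$n_units)
  class(best) <- "window_fit"
  structure(list(results = results, best = best, baseline_aicc = base$aicc,
                 n_failed = sum(!results$converged), rate = rate,
                 n = sd_obj$n_units, variables = names(anoms_list),
                 max_offset = max_offset,
                 fits = if (keep_fits) fits,
                 baseline_fit = if (keep_fits) base$fit,
                 sd_obj = sd_obj),
            class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<window_scan %s: %d candidates (%d failed), baseline AICc %.2f>\n",
    x$rate, nrow(x$results), x$n_failed, x$baseline_aicc))
  cat(sprintf("best: %s, window open %d close %d, dAICc %.2f\n",
              b$variable, b$window$open, b$window$close, b$delta_aicc))
  invisible(x)
}

#' Year-randomization test of the best scan model
#'
#' Permutes the mapping between biological years and climate years as
#' whole blocks (all of a year's records move together, preserving the
#' within-year dependence that the year random effect absorbs), reruns the
#' full scan per permutation, and compares the observed best
#' AICc-improvement over baseline with the permutation distribution:
#' `p = (1 + #\{null <= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams scan_windows
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional RNG seed.
#' @return Object of class `randomization_result`: list with `p`,
#'   `observed` best delta-AICc, vector `null` of permuted best
#'   delta-AICc, `n_perm`, and the observed `scan`.
#' @details When the rate's scan data aggregate to one row per (year,
#'   zone) on a complete year-by-zone grid, permutations reuse the
#'   observed candidate model structures with block-permuted responses
#'   (lme4's modular interface), which is mathematically identical to
#'   remapping climate years and refitting — the designs do not change,
#'   and the climate-free baseline's likelihood is invariant under the
#'   block permutation.  Otherwise each permutation refits from scratch.
#' @export
randomization_test <- function(transitions, anoms_list, rate, n_perm = 1000L,
                               seed = NULL, max_offset = 36L,
                               anchor_month = 6L, nAGQ = 0L) {
  if (n_perm < 1L) stop_dunesync("n_perm must be >= 1")
  if (inherits(anoms_list, "anomaly_series")) {
    anoms_list <- stats::setNames(list(anoms_list), attr(anoms_list, "variable"))
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- scan_windows(transitions, anoms_list, rate, max_offset,
                      anchor_month, nAGQ)
  sd_obj <- obs$sd_obj
  d <- sd_obj$data
  years <- sort(unique(as.character(d$year)))
  ny <- length(years)
  if (ny < 2L) stop_dunesync("need >= 2 distinct years")

  grid_ok <- sd_obj$aggregated && nAGQ == 0L &&
    nrow(d) == ny * nlevels(droplevels(d$zone)) &&
    !is.unsorted(order(d$year, d$zone))
  null_delta <- numeric(n_perm)

  if (grid_ok) {
    ## fast path: permute response year-blocks against the fixed designs.
    ## Biological year b is mapped to climate year perm[b]; with rows
    ## sorted (year, zone) on a complete grid, the design row for climate
    ## year c must carry the response of biological year inv[c].  The
    ## designs are unchanged under permutation, so each candidate's model
    ## structure is prepared once (lme4 modular API) and only the response
    ## is swapped; with a single scalar random-effect parameter the
    ## profiled deviance is optimized in one dimension.  This reproduces
    ## glmer's nAGQ = 0 deviance exactly.
    resp <- cbind(d$succ, d$fail)
    nz <- nrow(d) / ny
    row_year <- rep(seq_len(ny), each = nz)
    zone_rank <- rep(seq_len(nz), ny)
    windows <- enumerate_windows(max_offset)
    Ws <- lapply(anoms_list, window_covariates,
                 years_t0 = as.integer(years), windows = windows,
                 anchor_month = anchor_month)
    yr_chr <- as.character(d$year)
    ctrl <- scan_control()$glmer
    keep <- which(obs$results$converged & is.finite(obs$results$aicc))
    gfs <- vector("list", length(keep))
    ks <- integer(length(keep))
    for (q in seq_along(keep)) {
      i <- keep[q]
      j <- which(windows$open == obs$results$open[i] &
                   windows$close == obs$results$close[i])
      d$clim <- Ws[[obs$results$variable[i]]][yr_chr, j]
      gfs[[q]] <- lme4::glFormula(
        cbind(succ, fail) ~ zone + clim:zone + (1 | year), data = d,
        family = stats::binomial(), control = ctrl)
      ks[q] <- ncol(gfs[[q]]$X) + 1L
    }
    best_under <- function(newresp) {
      best <- Inf
      for (q in seq_along(gfs)) {
        gf <- gfs[[q]]
        gf$fr[[1L]] <- newresp
        devfun <- do.call(lme4::mkGlmerDevfun, c(gf, list(control = ctrl)))
        dev <- stats::optimize(devfun, c(0, 15), tol = 1e-6)$objective
        ac <- aicc_value(dev + 2 * ks[q], ks[q], sd_obj$n_units)
        if (ac < best) best <- ac
      }
      best - obs$baseline_aicc
    }
    ## observed statistic through the same engine as the nulls, so the
    ## permutation comparison is exactly exchangeable
    observed_stat <- best_under(resp)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(ny)
      inv <- order(perm)
      src <- (inv[row_year] - 1L) * nz + zone_rank
      null_delta[b] <- best_under(resp[src, , drop = FALSE])
    }
  } else {
    ## general path: remap climate years as blocks and refit from scratch
    windows <- enumerate_windows(max_offset)
    yrs_int <- as.integer(years)
    Ws <- lapply(anoms_list, window_covariates, years_t0 = yrs_int,
                 windows = windows, anchor_month = anchor_month)
    yr_chr <- as.character(d$year)
    observed_stat <- obs$best$delta_aicc
    for (b in seq_len(n_perm)) {
      perm <- sample.int(ny)
      best <- Inf
      for (v in names(anoms_list)) {
        Wp <- Ws[[v]][perm, , drop = FALSE]
        rownames(Wp) <- years
        for (j in seq_len(nrow(windows))) {
          sd_obj$data$clim <- Wp[yr_chr, j]
          r <- fit_scan_model(sd_obj, climate = TRUE, nAGQ = nAGQ)
          if (!is.na(r$aicc) && r$aicc < best) best <- r$aicc
        }
      }
      null_delta[b] <- best - obs$baseline_aicc
    }
  }

  structure(list(
    p = (1 + sum(null_delta <= observed_stat)) / (n_perm + 1),
    observed = observed_stat, null = null_delta, n_perm = n_perm,
    scan = obs
  ), class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "<randomization test: observed dAICc %.2f, p = %.4g (%d permutations)>\n",
    x$observed, x$p, x$n_perm))
  invisible(x)
}
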