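#' @keywords internal
#' @importFrom lme4 GHrule
"_PACKAGE"

## Small shared helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dunesync <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

## Sample from a Normal truncated below at `lower` via inverse-CDF.
rtnorm_lower <- function(n, mean, sd, lower = 0) {
  plo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, plo, 1)
  stats::qnorm(pmin(u, 1 - 1e-16), mean, sd)
}

## Small-sample corrected AIC. `n` is the number of independent response
## units (Bernoulli trials for aggregated binomial fits), `k` the number of
## estimated parameters including variance components.
aicc_value <- function(aic, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

## AICc of a fitted (merMod or lm-like) model; k from the logLik df
## attribute so variance components are counted.
aicc <- function(fit, n = stats::nobs(fit)) {
  ll <- stats::logLik(fit)
  aicc_value(stats::AIC(fit), attr(ll, "df"), n)
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_dunesync(sprintf("%s is missing column(s): %s", what,
                          paste(missing, collapse = ", ")))
  }
  invisible(df)
}
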