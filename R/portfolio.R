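## Synchrony and portfolio-effect statistics on zone-by-year series.
##
## Input is a numeric matrix with zones in rows and years in columns —
## abundances from [zone_abundance()], or per-cell vital-rate predictions,
## or lambda values.  All variances use the sample (n-1) denominator; the
## synchrony index is a ratio so the choice cancels there, but it does not
## in the Taylor / portfolio-effect calculations, where it is therefore
## fixed and documented.  Logarithms are natural.

check_zone_year <- function(mat, min_zones = 2L, min_years = 3L) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (nrow(mat) < min_zones) stop_dunesync("need >= ", min_zones, " zones")
  if (ncol(mat) < min_years) stop_dunesync("need >= ", min_years, " years")
  invisible(mat)
}

#' Population-level synchrony index
#'
#' `phi = Var(sum_i N_i) / (sum_i sd(N_i))^2`, where the numerator is the
#' temporal variance of the whole-population series and the denominator
#' the squared sum of the zone SDs.  1 means perfect synchrony; values
#' near 0 mean compensating (asynchronous) zones and hence a stronger
#' portfolio effect.
#'
#' @param mat Zone-by-year numeric matrix.
#' @return Scalar in `[0, 1]`.
#' @examples
#' m <- rbind(c(1, 2, 3), c(3, 2, 1))
#' synchrony_phi(m)  # exactly compensating: 0
#' @export
synchrony_phi <- function(mat) {
  check_zone_year(mat)
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) {
    stop_dunesync("zone(s) with zero temporal variance: ",
                  paste(rownames(mat)[sds == 0] %||% which(sds == 0),
                        collapse = ", "))
  }
  stats::var(colSums(mat)) / sum(sds)^2
}

#' Taylor mean-variance scaling fit
#'
#' Ordinary least squares of `log(Var(N_i))` on `log(E(N_i))` across zones
#' (natural logs): the temporal mean-variance scaling relationship with
#' intercept `beta0` and slope `z`.
#'
#' @param mat Zone-by-year numeric matrix; all zone means and variances
#'   must be positive, and at least 3 zones are required for a residual
#'   degree of freedom.
#' @return List with `beta0`, `z`, and the underlying `lm` fit.
#' @export
taylor_fit <- function(mat) {
  check_zone_year(mat, min_zones = 3L)
  mz <- rowMeans(mat)
  vz <- apply(mat, 1, stats::var)
  if (any(mz <= 0)) stop_dunesync("zone temporal mean(s) must be > 0")
  if (any(vz <= 0)) stop_dunesync("zone temporal variance(s) must be > 0")
  if (stats::sd(log(mz)) == 0) {
    stop_dunesync("degenerate regression: all zone means identical")
  }
  fit <- stats::lm(log(vz) ~ log(mz))
  list(beta0 = unname(stats::coef(fit)[1]), z = unname(stats::coef(fit)[2]),
       fit = fit)
}

#' Portfolio effect from zone-by-year abundances
#'
#' Two-step mean-variance procedure: fit the Taylor scaling across zones,
#' predict the total-population variance from the total's temporal mean,
#' `Var_pred = exp(beta0 + z log(E(N_total)))`, and take
#' `PE = Var_pred / Var_obs`.  PE above 1 is evidence for asynchrony-driven
#' stabilization of the total.
#'
#' @param mat Zone-by-year numeric matrix of abundances.
#' @return An object of class `portfolio_stats`: list with `phi`, `beta0`,
#'   `z`, `var_pred_total`, `var_obs_total` and `pe`.
#' @export
portfolio_effect <- function(mat) {
  tf <- taylor_fit(mat)
  total <- colSums(mat)
  var_obs <- stats::var(total)
  var_pred <- exp(tf$beta0 + tf$z * log(mean(total)))
  structure(list(phi = synchrony_phi(mat),
                 beta0 = tf$beta0, z = tf$z,
                 var_pred_total = var_pred, var_obs_total = var_obs,
                 pe = var_pred / var_obs),
            class = "portfolio_stats")
}

#' @export
print.portfolio_stats <- function(x, ...) {
  cat(sprintf("phi = %.3f, Taylor beta0 = %.3f, z = %.3f, PE = %.3f\n",
              x$phi, x$beta0, x$z, x$pe))
  cat(sprintf("  predicted total variance %.4g vs observed %.4g\n",
              x$var_pred_total, x$var_obs_total))
  invisible(x)
}

#' Pairwise zone correlation matrix with significance tests
#'
#' Pearson correlations of each pair of zone series across years, with
#' two-sided p-values from [stats::cor.test()].  Pairs are computed on
#' their shared non-missing years.  No multiple-testing correction is
#' applied by default, matching per-pair reporting conventions.
#'
#' @param mat Zone-by-year numeric matrix (NAs allowed).
#' @param p_adjust Method for [stats::p.adjust()] (`"none"` by default).
#' @return List with matrices `r` and `p` (zones x zones) and `n` pairs of
#'   shared years.
#' @export
correlation_matrix <- function(mat, p_adjust = "none") {
  check_zone_year(mat)
  nz <- nrow(mat)
  r <- p <- n <- matrix(NA_real_, nz, nz,
                        dimnames = list(rownames(mat), rownames(mat)))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(nz - 1L)) for (j in (i + 1L):nz) {
    ok <- !is.na(mat[i, ]) & !is.na(mat[j, ])
    if (sum(ok) < 3L) stop_dunesync("zones ", i, " and ", j,
                                    " share fewer than 3 years")
    if (stats::sd(mat[i, ok]) == 0 || stats::sd(mat[j, ok]) == 0) {
      stop_dunesync("constant series in zone pair (", i, ", ", j, ")")
    }
    ct <- stats::cor.test(mat[i, ok], mat[j, ok])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
    n[i, j] <- n[j, i] <- sum(ok)
  }
  if (p_adjust != "none") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = p_adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  list(r = r, p = p, n = n)
}
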