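## Attribution of asynchrony to climate-by-zone interactions.
##
## If zones desynchronize because they respond to climate with different
## slopes, then a zone's climate coefficient should covary with how
## strongly its vital-rate series tracks the reference (foredune) zone:
## zones most unlike Zone 1 in climate response should correlate least
## with Zone 1.  The test regresses per-zone climate slopes from the best
## scan model on each zone's correlation with Zone 1.

#' Correlation of each zone's series with Zone 1
#'
#' Pearson correlation of every zone's year-series of cell predictions
#' (or lambda values) with the first zone's, over shared non-missing
#' years.
#'
#' @param mat Zone-by-year numeric matrix; row 1 (or the row named by
#'   `reference`) is the reference zone.
#' @param reference Reference zone row name or index (default first row).
#' @return Named numeric vector of correlations, one per zone (the
#'   reference zone's own entry is 1).
#' @export
zone1_correlations <- function(mat, reference = 1L) {
  check_zone_year(mat)
  ref <- mat[reference, ]
  vapply(seq_len(nrow(mat)), function(i) {
    ok <- !is.na(ref) & !is.na(mat[i, ])
    if (sum(ok) < 3L) stop_dunesync("zone ", i, " shares fewer than 3 years ",
                                    "with the reference zone")
    if (stats::sd(mat[i, ok]) == 0 || stats::sd(ref[ok]) == 0) {
      stop_dunesync("constant series for zone ", i)
    }
    stats::cor(ref[ok], mat[i, ok])
  }, numeric(1)) |> stats::setNames(rownames(mat))
}

#' Assemble attribution points for one vital rate
#'
#' Pairs each zone's climate coefficient (per-zone slope from a
#' [fit_window_model()] / [scan_windows()] best model) with its
#' correlation to Zone 1.
#'
#' @param zone_slopes Named per-zone climate slopes (names are zone
#'   labels, or in the scan's `slope_zoneZ` order).
#' @param correlations Per-zone correlations with Zone 1
#'   ([zone1_correlations()]).
#' @param rate Optional rate label carried through.
#' @return Data frame with columns `rate`, `zone`, `coef`, `corr`.
#' @export
attribution_points <- function(zone_slopes, correlations, rate = NA) {
  if (length(zone_slopes) != length(correlations)) {
    stop_dunesync("slopes and correlations must have one entry per zone")
  }
  data.frame(rate = rate,
             zone = names(correlations) %||% seq_along(correlations),
             coef = unname(zone_slopes), corr = unname(correlations))
}

#' Regress climate coefficients on Zone-1 correlations
#'
#' Least-squares fit of the per-zone climate coefficient on the zone's
#' correlation with Zone 1, with the two-sided p-value for the slope.  The
#' reference zone's own point (correlation 1) is included by default.
#'
#' @param points An [attribution_points()] data frame (columns `coef`,
#'   `corr`), or anything coercible.
#' @param include_reference Keep the reference zone's own point
#'   (`corr == 1`)?
#' @return List with `slope`, `intercept`, `p_value`, `r_squared`, `n` and
#'   the `lm` fit.
#' @export
coef_vs_corr_regression <- function(points, include_reference = TRUE) {
  pts <- as.data.frame(points)
  assert_columns(pts, c("coef", "corr"), "attribution points")
  if (!include_reference) pts <- pts[pts$corr != 1, ]
  if (nrow(pts) < 3L) stop_dunesync("need >= 3 points")
  if (stats::sd(pts$corr) == 0) {
    stop_dunesync("degenerate regression: zero variance in correlations")
  }
  fit <- stats::lm(coef ~ corr, data = pts)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = sm$coefficients["corr", "Pr(>|t|)"],
       r_squared = sm$r.squared, n = nrow(pts), fit = fit)
}
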