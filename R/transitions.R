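## Plant-year transition building.
##
## Converts a long-format census (one row per live tagged plant per year)
## into one record per plant per year t0, carrying the plant's fate at t1.
## Two field-protocol rules are encoded here:
##   * a plant absent for three or more consecutive years and never seen
##     again is scored dead in the first year it went missing;
##   * a plant re-found after a shorter gap is credited with survival
##     through the gap, with unknown (NA) sizes in the gap years.

validate_census <- function(census) {
  assert_columns(census, c("plant_id", "zone", "year", "stage", "size"),
                 "census table")
  bad_stage <- setdiff(unique(census$stage), STAGES)
  if (length(bad_stage)) {
    stop_dunesync("unknown stage value(s): ", paste(bad_stage, collapse = ", "))
  }
  dup <- duplicated(census[, c("plant_id", "year")])
  if (any(dup)) {
    stop_dunesync("duplicate (plant_id, year) record(s), e.g. plant ",
                  census$plant_id[dup][1])
  }
  invisible(census)
}

#' Build plant-year transition records from a census table
#'
#' For every plant and every year `t0` in which it was (or is presumed)
#' alive as a seedling or vegetative plant, emits one record with its fate
#' at `t1 = t0 + 1`: `survived_t1`, `flowered_t1`, and `size_t1` when it
#' was measured as vegetative at `t1`.
#'
#' @param census Census data frame (`plant_id, zone, year, stage, size`).
#' @param last_census_year Final census year; defaults to the maximum year
#'   in the table.  Needed to distinguish death from right-censoring.
#' @return Data frame of class `transition_table` with columns `plant_id`,
#'   `zone`, `year_t0`, `stage_t0`, `size_t0`, `survived_t1`,
#'   `flowered_t1`, `size_t1`, `observed_t0` (FALSE for presumed-alive gap
#'   years).
#' @details
#' Fate scoring at the end of a plant's record (flowering excepted, which
#' terminates the record by monocarpy): if at least three census years
#' follow its last sighting, the plant is dead in the first missing year
#' (`survived_t1 = 0` in its last transition); with one or two remaining
#' years its fate is unresolved and no final transition is emitted.
#' Gap years between sightings yield `survived_t1 = 1` transitions with
#' missing sizes; a seedling re-found later is presumed vegetative from the
#' year after it was a seedling.
#' @examples
#' cen <- data.frame(plant_id = 1, zone = 1, year = 2010:2011,
#'                   stage = c("vegetative", "flowering"),
#'                   size = c(2.1, NA))
#' build_transitions(cen, last_census_year = 2022)
#' @export
build_transitions <- function(census, last_census_year = max(census$year)) {
  validate_census(census)
  census <- census[order(census$plant_id, census$year), ]
  ids <- unique(census$plant_id)
  idx <- split(seq_len(nrow(census)), census$plant_id)[as.character(ids)]

  acc <- list(plant_id = vector("list", length(ids)),
              zone = vector("list", length(ids)),
              year_t0 = vector("list", length(ids)),
              stage_t0 = vector("list", length(ids)),
              size_t0 = vector("list", length(ids)),
              survived_t1 = vector("list", length(ids)),
              flowered_t1 = vector("list", length(ids)),
              size_t1 = vector("list", length(ids)),
              observed_t0 = vector("list", length(ids)))
  for (i in seq_along(ids)) {
    rows <- census[idx[[i]], ]
    yrs <- rows$year
    stg <- rows$stage
    n <- length(yrs)
    if (any(stg[-n] == "flowering")) {
      stop_dunesync("plant ", ids[i],
                    " has records after a flowering record (monocarpy)")
    }
    first_veg <- match("vegetative", stg)
    if (!is.na(first_veg) && first_veg < n &&
        any(stg[(first_veg + 1L):n] == "seedling")) {
      stop_dunesync("plant ", ids[i], " reverts from vegetative to seedling")
    }

    ## every year from first sighting to the year before the last sighting
    ## is a survived transition (gap years presumed vegetative, size NA)
    t0s <- if (yrs[n] > yrs[1]) yrs[1]:(yrs[n] - 1L) else integer(0)
    surv <- rep(1L, length(t0s))
    ## after the last non-flowering sighting: dead if >= 3 missing census
    ## years remain, otherwise right-censored (no final transition)
    if (stg[n] != "flowering" && last_census_year - yrs[n] >= 3L) {
      t0s <- c(t0s, yrs[n])
      surv <- c(surv, 0L)
    }
    if (!length(t0s)) next
    oi <- match(t0s, yrs)
    observed <- !is.na(oi)
    ti <- match(t0s + 1L, yrs)
    acc$plant_id[[i]] <- rep(ids[i], length(t0s))
    acc$zone[[i]] <- rep(rows$zone[1], length(t0s))
    acc$year_t0[[i]] <- t0s
    acc$stage_t0[[i]] <- ifelse(observed, stg[oi], "vegetative")
    acc$size_t0[[i]] <- ifelse(observed, rows$size[oi], NA_real_)
    acc$survived_t1[[i]] <- surv
    acc$flowered_t1[[i]] <- as.integer(!is.na(ti) & stg[ti] == "flowering")
    acc$size_t1[[i]] <- ifelse(!is.na(ti) & stg[ti] == "vegetative",
                               rows$size[ti], NA_real_)
    acc$observed_t0[[i]] <- observed
  }
  tr <- data.frame(lapply(acc, function(x) unlist(x, use.names = FALSE)))
  if (!nrow(tr)) {
    stop_dunesync("no transitions could be built from this census")
  }
  class(tr) <- c("transition_table", "data.frame")
  tr
}

#' Zone-by-year abundance matrix
#'
#' Counts all live tagged plants (seedlings, vegetative and flowering) per
#' zone and census year.
#'
#' @param census Census data frame.
#' @return Integer matrix, zones in rows, years in columns, with dimnames.
#' @export
zone_abundance <- function(census) {
  validate_census(census)
  tab <- table(zone = census$zone, year = census$year)
  mat <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = list(zone = rownames(tab), year = colnames(tab)))
  mat
}
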