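#' @keywords internal
check_fips <- function(fips, what = "county_fips") {
  fips <- as.character(fips)
  bad <- !grepl("^[0-9]{5}$", fips)
  if (any(bad)) {
    stop(sprintf(
      "invalid %s (must be 5 digits, zero-padded): %s",
      what, paste(utils::head(unique(fips[bad]), 10), collapse = ", ")
    ), call. = FALSE)
  }
  fips
}

#' Aggregate county-level pill and population records to spatial units
#'
#' Sums annual county pill counts over the study window within each spatial
#' unit (commuting zone or CBSA) defined by a county-to-unit crosswalk, and
#' computes each unit's mean annual population (counties are summed within
#' each year first, then years are averaged). Units containing at least one
#' county in an excluded state (by default the non-contiguous states Alaska
#' and Hawaii) are dropped entirely.
#'
#' @param pills data.frame with columns `county_fips`, `year`, `pills`
#'   (non-negative counts of dosage units).
#' @param pops data.frame with columns `county_fips`, `year`, `population`
#'   (positive person counts). Every county of every retained unit must have
#'   a population for every window year; missing values are a hard error,
#'   never imputed.
#' @param xwalk data.frame with columns `county_fips`, `unit_id`,
#'   `unit_kind` (one of `"CZ"`, `"CBSA_METRO"`, `"CBSA_MICRO"`), `state`
#'   (two-letter postal code). Each county may map to at most one unit.
#' @param excluded_states character vector of state codes whose units are
#'   dropped (default `c("AK", "HI")`).
#' @param window integer vector of calendar years (default `2006:2014`).
#'
#' @return A unit table: data.frame with columns `unit_id`, `pills_total`,
#'   `pop_mean`, `region` (NA until [assign_region()]), `stratum`
#'   (`"metro"`/`"micro"` for CBSA kinds, NA for CZs), `n_counties`,
#'   sorted by `unit_id`. Attribute `dropped_units` records excluded-state
#'   units and their pill totals so mass can be audited.
#' @seealso [assign_region()], [log_log_data()]
#' @export
aggregate_to_units <- function(pills, pops, xwalk,
                               excluded_states = c("AK", "HI"),
                               window = 2006:2014) {
  stopifnot(is.data.frame(pills), is.data.frame(pops), is.data.frame(xwalk))
  if (length(window) == 0) stop("empty study window", call. = FALSE)
  need <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s is missing column(s): %s", name,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(pills, c("county_fips", "year", "pills"), "pills")
  need(pops, c("county_fips", "year", "population"), "pops")
  need(xwalk, c("county_fips", "unit_id", "unit_kind", "state"), "xwalk")

  pills$county_fips <- check_fips(pills$county_fips)
  pops$county_fips <- check_fips(pops$county_fips)
  xwalk$county_fips <- check_fips(xwalk$county_fips)
  if (any(pills$pills < 0)) stop("negative pill counts", call. = FALSE)
  if (any(pops$population <= 0)) stop("non-positive populations", call. = FALSE)
  if (anyDuplicated(xwalk$county_fips)) {
    dup <- unique(xwalk$county_fips[duplicated(xwalk$county_fips)])
    stop(sprintf("crosswalk maps county to more than one unit: %s",
                 paste(utils::head(dup, 10), collapse = ", ")), call. = FALSE)
  }

  pills <- pills[pills$year %in% window, , drop = FALSE]
  pops <- pops[pops$year %in% window, , drop = FALSE]

  missing_xwalk <- setdiff(unique(pills$county_fips), xwalk$county_fips)
  if (length(missing_xwalk)) {
    stop(sprintf("counties in pill data absent from crosswalk: %s",
                 paste(utils::head(sort(missing_xwalk), 20), collapse = ", ")),
         call. = FALSE)
  }

  # drop whole units touching an excluded state
  excl_units <- unique(xwalk$unit_id[xwalk$state %in% excluded_states])
  kept <- !(xwalk$unit_id %in% excl_units)
  xw_kept <- xwalk[kept, , drop = FALSE]

  # every county of every retained unit needs a population in every window year
  key <- function(f, y) paste(f, y, sep = "|")
  have_pop <- key(pops$county_fips, pops$year)
  want <- expand.grid(county_fips = unique(xw_kept$county_fips),
                      year = window, stringsAsFactors = FALSE)
  miss_pop <- !(key(want$county_fips, want$year) %in% have_pop)
  if (any(miss_pop)) {
    off <- want[miss_pop, , drop = FALSE]
    stop(sprintf(
      "missing population for %d county-year(s), e.g. %s",
      nrow(off),
      paste(utils::head(sprintf("%s/%d", off$county_fips, off$year), 10),
            collapse = ", ")
    ), call. = FALSE)
  }

  unit_of <- stats::setNames(xw_kept$unit_id, xw_kept$county_fips)
  p_kept <- pills[pills$county_fips %in% xw_kept$county_fips, , drop = FALSE]
  pills_by_unit <- tapply(p_kept$pills, unit_of[p_kept$county_fips], sum)

  pop_kept <- pops[pops$county_fips %in% xw_kept$county_fips, , drop = FALSE]
  # sum counties within (unit, year), then average over years
  uy <- rowsum(pop_kept$population,
               group = key(unit_of[pop_kept$county_fips], pop_kept$year))
  uy_unit <- sub("\\|.*$", "", rownames(uy))
  pop_mean <- tapply(uy[, 1], uy_unit, mean)

  ids <- sort(unique(xw_kept$unit_id))
  kind_of <- tapply(xw_kept$unit_kind, xw_kept$unit_id, function(k) k[[1]])
  stratum <- c(CZ = NA_character_, CBSA_METRO = "metro",
               CBSA_MICRO = "micro")[as.character(kind_of[ids])]
  n_counties <- tapply(xw_kept$county_fips, xw_kept$unit_id, length)

  units <- data.frame(
    unit_id = ids,
    pills_total = as.numeric(ifelse(is.na(pills_by_unit[ids]), 0,
                                    pills_by_unit[ids])),
    pop_mean = as.numeric(pop_mean[ids]),
    region = NA_character_,
    stratum = unname(stratum),
    n_counties = as.integer(n_counties[ids]),
    stringsAsFactors = FALSE
  )
  rownames(units) <- NULL

  if (length(excl_units)) {
    p_excl <- pills[!(pills$county_fips %in% xw_kept$county_fips), ,
                    drop = FALSE]
    xw_all <- stats::setNames(xwalk$unit_id, xwalk$county_fips)
    dropped <- data.frame(
      unit_id = sort(excl_units),
      pills_total = as.numeric(tapply(
        p_excl$pills, xw_all[p_excl$county_fips], sum
      )[sort(excl_units)]),
      stringsAsFactors = FALSE
    )
    dropped$pills_total[is.na(dropped$pills_total)] <- 0
    message(sprintf("dropped %d unit(s) touching excluded state(s): %s",
                    length(excl_units),
                    paste(excluded_states, collapse = ", ")))
    attr(units, "dropped_units") <- dropped
  } else {
    attr(units, "dropped_units") <- data.frame(unit_id = character(0),
                                               pills_total = numeric(0))
  }
  units
}

#' Attach a census region to each spatial unit
#'
#' Assigns each unit the region of the state contributing the largest mean
#' population to it. Single-state units reduce to a direct lookup. When a
#' unit spans states in different regions, population within the unit is
#' summed by region and the largest wins; an exact tie goes to the
#' alphabetically first region, with a warning.
#'
#' @param units unit table from [aggregate_to_units()].
#' @param xwalk the crosswalk used to build `units`.
#' @param pops county population records used to build `units`.
#' @param state_region_map named character vector state -> region; default
#'   [census_region_map()].
#' @param window years over which mean populations are taken.
#' @return `units` with the `region` column filled.
#' @export
assign_region <- function(units, xwalk, pops,
                          state_region_map = census_region_map(),
                          window = 2006:2014) {
  stopifnot(is.data.frame(units), "unit_id" %in% names(units))
  xw <- xwalk[xwalk$unit_id %in% units$unit_id, , drop = FALSE]
  unmapped <- setdiff(unique(xw$state), names(state_region_map))
  if (length(unmapped)) {
    stop(sprintf("state(s) not covered by the region map: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  pops <- pops[pops$year %in% window, , drop = FALSE]
  mean_pop <- tapply(pops$population, pops$county_fips, mean)
  xw$mpop <- as.numeric(mean_pop[xw$county_fips])
  if (anyNA(xw$mpop)) {
    stop("county in crosswalk lacks population records", call. = FALSE)
  }
  xw$region <- unname(state_region_map[xw$state])

  pick <- vapply(split(xw, xw$unit_id), function(d) {
    by_reg <- tapply(d$mpop, d$region, sum)
    top <- names(by_reg)[by_reg == max(by_reg)]
    if (length(top) > 1) {
      warning(sprintf(
        "unit %s: region tie (%s); taking alphabetically first",
        d$unit_id[[1]], paste(sort(top), collapse = " vs ")
      ), call. = FALSE)
    }
    sort(top)[[1]]
  }, character(1))

  units$region <- unname(pick[units$unit_id])
  units
}

#' Read a unit table from CSV
#'
#' Expects a header row with at least `unit_id`, `pills_total`, `pop_mean`,
#' `region`, `stratum`; unknown extra columns are preserved. Validation
#' failures name the offending data row.
#'
#' @param path path to a CSV file.
#' @return unit table data.frame.
#' @export
read_units_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(unit_id = "character"))
  need <- c("unit_id", "pills_total", "pop_mean", "region", "stratum")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("units CSV %s missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (col in c("pills_total", "pop_mean")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric %s at row %d of %s", col, bad[[1]], path),
           call. = FALSE)
    }
    df[[col]] <- v
  }
  neg <- which(df$pills_total < 0)
  if (length(neg)) {
    stop(sprintf("negative pills_total at row %d of %s", neg[[1]], path),
         call. = FALSE)
  }
  if (anyDuplicated(df$unit_id)) {
    stop("duplicate unit_id in units CSV", call. = FALSE)
  }
  df$region <- as.character(df$region)
  df$stratum <- as.character(df$stratum)
  df
}

#' Write a unit table to CSV
#'
#' Counts are written as integers and `pop_mean` at full double precision
#' (17 significant digits), so a write/read round trip reproduces the table
#' exactly.
#'
#' @param units unit table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_units_csv <- function(units, path) {
  out <- units
  out$pills_total <- sprintf("%.0f", round(units$pills_total))
  out$pop_mean <- sprintf("%.17g", units$pop_mean)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}
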