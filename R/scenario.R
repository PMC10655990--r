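# Scenario definitions and time-varying socioeconomic drivers: named policy
# scenario presets, management-intensity priors, ownership conversion, land
# reform completion, and the market-pressure ramp on harvest willingness.

#' Harvest decision and permitting parameters
#'
#' The single source of tunables for the harvest engine. Defaults are the
#' REAL-scenario values: yearly base clear-cutting probabilities by
#' management intensity and ownership, the linear age adjustment that
#' doubles a base probability 20 years past maturity (capped at 1), the
#' total-cutover area limits by management type, the limited-management
#' quiet period, and the state harvest machinery (quota, cluster radius,
#' maturity offsets).
#'
#' `limited_doubling_horizon` optionally gives limited-management (class
#' A/B) stands a different doubling horizon than the general 20 years; by
#' default they share it.
#'
#' @param ... named overrides of any default listed below.
#' @return a list of class `harvest_params`.
#' @export
default_harvest_params <- function(...) {
  p <- list(
    cutprob_int = 0.385,
    cutprob_nonint = 0.055,
    cutprob_nonint_2050 = 0.13,
    cutprob_state = 1,
    cutprob_classA = 0.2,
    cutprob_classB = 0.1,
    cutprob_state_AB = 0.05,
    doubling_horizon = 20,
    limited_doubling_horizon = NULL,
    clearcut_age = 6L,
    limit_alvar = 20000,
    limit_riparian = 20000,
    limit_bog = 50000,
    limit_general = 70000,
    quiet_years = 5L,
    state_quota = 120000000,
    state_radius = 1000,
    state_offset = 10,
    state_offset_hpi = 20,
    regen_flip = 0.05,
    p_int_juridical = 0.95,
    p_int_physical = 0.35,
    second_layer_rate = 0.01
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    abort(paste0("unknown harvest parameter(s): ",
                 paste(unknown, collapse = ", ")))
  }
  p[names(dots)] <- dots
  probs <- unlist(p[c("cutprob_int", "cutprob_nonint", "cutprob_nonint_2050",
                      "cutprob_state", "cutprob_classA", "cutprob_classB",
                      "cutprob_state_AB", "regen_flip",
                      "p_int_juridical", "p_int_physical")])
  stopifnot(all(probs >= 0 & probs <= 1),
            all(unlist(p[c("limit_alvar", "limit_riparian",
                           "limit_bog", "limit_general")]) > 0))
  structure(p, class = "harvest_params")
}

#' Build a named scenario configuration
#'
#' Six scenario presets differ in starting condition (whether clear-cuts
#' missed by the outdated canopy scans are simulated in before year one),
#' ownership conversion from non-intensive to intensive management, market
#' pressure (a linear ramp of the non-intensive base cutting probability),
#' and governance laxity (20% larger allowable total cutover areas):
#'
#' * `DEFa` - recorded clear-cuts only; no conversion; base probabilities
#'   0.35 (intensive) / 0.05 (non-intensive).
#' * `DEFb` - as `DEFa` with the simulated extra clear-cuts and the
#'   calibrated probabilities 0.385 / 0.055.
#' * `MODa`, `MODb` - the `a`/`b` starting conditions plus a yearly 2.8%
#'   conversion of eligible non-intensive units to intensive.
#' * `GOV` - `DEFb` with all area limits multiplied by 1.2.
#' * `REAL` - `MODb` plus the market-pressure ramp of the non-intensive
#'   base probability to 0.13 by 2050.
#'
#' @param name scenario name.
#' @param start_year,end_year simulation horizon (calendar years).
#' @param ... overrides forwarded to [default_harvest_params()].
#' @return a list of class `scenario_config` with elements `name`,
#'   `start_year`, `end_year`, `harvest` (the harvest params with area
#'   limits already scaled by `area_multiplier`), `area_multiplier`,
#'   `conversion_rate`, `market_pressure`, `extra_clearcuts`,
#'   `maturity_table`.
#' @examples
#' build_scenario("GOV")$harvest$limit_general  # 84000
#' @export
build_scenario <- function(name = c("REAL", "DEFa", "DEFb", "MODa", "MODb", "GOV"),
                           start_year = 2022L, end_year = 2050L, ...) {
  name <- match.arg(name)
  hp <- switch(name,
    DEFa = default_harvest_params(cutprob_int = 0.35, cutprob_nonint = 0.05, ...),
    MODa = default_harvest_params(cutprob_int = 0.35, cutprob_nonint = 0.05, ...),
    default_harvest_params(...)
  )
  mult <- if (name == "GOV") 1.2 else 1
  for (lim in c("limit_alvar", "limit_riparian", "limit_bog", "limit_general")) {
    hp[[lim]] <- hp[[lim]] * mult
  }
  structure(list(
    name = name,
    start_year = as.integer(start_year),
    end_year = as.integer(end_year),
    harvest = hp,
    area_multiplier = mult,
    conversion_rate = if (name %in% c("MODa", "MODb", "REAL")) 0.028 else 0,
    market_pressure = name == "REAL",
    extra_clearcuts = name %in% c("DEFb", "MODb", "GOV", "REAL"),
    maturity_table = default_maturity_table()
  ), class = "scenario_config")
}

#' Assign management intensity to private cadastral units
#'
#' Each private unit is drawn intensively managed with the owner-type prior
#' (juridical 0.95, physical 0.35 by default); state units are not
#' applicable. Uses the current RNG stream; seed before calling for
#' reproducibility.
#'
#' @param x a `landscape`.
#' @param config a `scenario_config`.
#' @return the `landscape` with `units$intensity` redrawn.
#' @export
assign_intensity <- function(x, config = build_scenario("REAL")) {
  un <- x$units
  hp <- config$harvest
  p <- ifelse(un$owner_type == "juridical", hp$p_int_juridical,
              ifelse(un$owner_type == "physical", hp$p_int_physical, NA_real_))
  draw <- runif(nrow(un))
  un$intensity <- ifelse(un$owner_type == "state", "not_applicable",
                         ifelse(draw < p, "INT", "nonINT"))
  x$units <- un
  x
}

#' Convert non-intensive units to intensive management
#'
#' Each year a fraction (default 2.8%) of the remaining eligible private
#' non-intensively managed cadastral units switches to intensive
#' management. Eligibility requires at least one registered, non-strict
#' stand with age above its maturity threshold. The converted count is the
#' banker's rounding of rate x eligible (unbiased in the long run).
#'
#' @param x a `landscape`.
#' @param config a `scenario_config` (its `conversion_rate` is used).
#' @return the `landscape` with converted units and logged
#'   `intensity_change` events.
#' @export
convert_ownership <- function(x, config = build_scenario("REAL")) {
  rate <- config$conversion_rate
  if (rate <= 0) return(x)
  st <- x$stands
  ypm <- years_past_maturity(x, config$maturity_table)
  mature_ok <- !is.na(ypm) & ypm > 0 & st$registered & st$zone != "strict"
  units_with_mature <- unique(st$unit[mature_ok])
  un <- x$units
  eligible <- un$id[un$intensity == "nonINT" &
                      un$owner_type %in% c("physical", "juridical") &
                      un$id %in% units_with_mature]
  n_conv <- round(rate * length(eligible))
  if (n_conv == 0 || !length(eligible)) return(x)
  picked <- eligible[sample.int(length(eligible), min(n_conv, length(eligible)))]
  x$units$intensity[x$units$id %in% picked] <- "INT"
  unit_area <- rowsum(st$area, st$unit)
  x$events <- bind_rows(x$events, tibble(
    stand_id = NA_integer_, year = x$year, event = "intensity_change",
    area_m2 = unit_area[match(picked, as.integer(rownames(unit_area))), 1]))
  x
}

#' Register previously unregistered stands (land reform completion)
#'
#' The initially unregistered stand count is spread linearly over the
#' simulation horizon so that by the final year all forest land is
#' registered (and thereby harvestable). Selection within a year is a
#' seeded random sample of the remaining unregistered stands.
#'
#' @param x a `landscape`.
#' @param config a `scenario_config`.
#' @return the `landscape` with newly registered stands and logged
#'   `registered` events.
#' @export
include_unregistered <- function(x, config = build_scenario("REAL")) {
  if (is.null(x$reg_schedule)) {
    x$reg_schedule <- list(n0 = sum(!x$stands$registered),
                           start = x$year)
  }
  n0 <- x$reg_schedule$n0
  if (n0 == 0) return(x)
  unreg <- which(!x$stands$registered)
  if (!length(unreg)) return(x)
  horizon <- config$end_year - config$start_year
  per_year <- if (horizon > 0) round(n0 / horizon) else length(unreg)
  if (x$year >= config$end_year) per_year <- length(unreg)
  k <- min(per_year, length(unreg))
  if (k <= 0) return(x)
  picked <- unreg[sample.int(length(unreg), k)]
  x$stands$registered[picked] <- TRUE
  x$events <- bind_rows(x$events, tibble(
    stand_id = x$stands$id[picked], year = x$year, event = "registered",
    area_m2 = x$stands$area[picked]))
  x
}

#' Market-pressure ramp of the non-intensive base cutting probability
#'
#' In the REAL scenario the yearly base clear-cutting probability of
#' non-intensively managed private stands rises linearly from its start
#' value (0.055 in 2022) to 0.13 by 2050.
#'
#' @param year calendar year (vectorised).
#' @param config a `scenario_config`.
#' @return the interpolated base probability.
#' @examples
#' interpolate_nonint_cutprob(2036, build_scenario("REAL"))  # 0.0925
#' @export
interpolate_nonint_cutprob <- function(year, config = build_scenario("REAL")) {
  hp <- config$harvest
  f <- (pmin(pmax(year, config$start_year), config$end_year) - config$start_year) /
    (config$end_year - config$start_year)
  hp$cutprob_nonint + f * (hp$cutprob_nonint_2050 - hp$cutprob_nonint)
}
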