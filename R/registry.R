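# Registry refresh: canopy-summary based detection of unrecorded
# clear-cuts, time-decay extrapolation of cuts the scans could not yet see,
# and composition imputation for stands without a described overstory.

#' Default height-growth parameters
#'
#' Expected stand height follows a saturating curve
#' `h = h_max * prod_factor * (1 - exp(-k * age))` per species, with the
#' productivity factor 1.1 / 1.0 / 0.85 for classes 1/2/3. The values are a
#' documented synthetic default, not statutory growth tables; supply your
#' own via the `params` argument of [expected_height()].
#'
#' @return a tibble `(species, h_max, k)`.
#' @export
default_height_params <- function() {
  tibble(species = c("pine", "spruce", "birch", "aspen"),
         h_max = c(30, 32, 26, 28),
         k = c(0.025, 0.022, 0.035, 0.030))
}

#' Expected stand height from species, age and productivity
#'
#' @param species character vector of species codes.
#' @param age stand ages in years.
#' @param productivity_class integer class (1 = best).
#' @param params height-curve parameters, see [default_height_params()].
#' @return expected heights in metres (0 at age 0, monotone increasing,
#'   saturating).
#' @examples
#' expected_height("pine", 80, 2)  # about 25.9 m
#' @export
expected_height <- function(species, age, productivity_class,
                            params = default_height_params()) {
  idx <- match(species, params$species)
  if (anyNA(idx)) {
    abort(paste0("unknown species: ",
                 paste(unique(species[is.na(idx)]), collapse = ", ")))
  }
  pf <- c(1.1, 1.0, 0.85)[pmin(pmax(productivity_class, 1L), 3L)]
  params$h_max[idx] * pf * (1 - exp(-params$k[idx] * age))
}

#' Detect an unrecorded clear-cut from canopy-height percentiles
#'
#' A stand is flagged as clear-cut since its last registry description when
#' (1) the 50th percentile of canopy height is less than half of both the
#' 90th percentile and the expected stand height, or (2) the height
#' distribution is very uneven: the relative spread
#' `(p90 - p50) / p90` exceeds `unevenness` (partially cut stands or
#' clear-cuts with many retention trees).
#'
#' @param summaries data frame with columns `p50`, `p90` (metres).
#' @param expected expected stand heights (m), recycled to rows.
#' @param unevenness relative-spread threshold of rule (2).
#' @return logical vector, `TRUE` where a clear-cut is detected.
#' @examples
#' detect_clearcut(data.frame(p50 = 5, p90 = 20), expected = 25)  # TRUE
#' @export
detect_clearcut <- function(summaries, expected, unevenness = 0.7) {
  p50 <- summaries$p50
  p90 <- summaries$p90
  rule1 <- p50 < 0.5 * p90 & p50 < 0.5 * expected
  spread <- (p90 - p50) / pmax(p90, 1e-9)
  rule2 <- spread > unevenness
  rule1 | rule2
}

#' Add clear-cuts missed by the outdated canopy scans
#'
#' The scans cover the country in yearly regions, so the additional
#' clear-cut rates they reveal decay with scan age. The linear trend of the
#' per-scan-year rates is extrapolated to the target date: stands scanned
#' in older years carry a shortfall equal to the rate gap to the newest
#' scan, and even the newest scan misses the months between scanning and
#' the target date (`partial_year` times the annual slope). The implied
#' count per scan-year region is drawn (seeded) from the eligible stands
#' there -- mature, registered, outside strict protection -- and those are
#' flagged clear-cut (age 0) before the first simulated year.
#'
#' @param x a `landscape`.
#' @param rates named vector of additional clear-cut rates by scan year.
#' @param partial_year fraction of a scan year elapsed between the newest
#'   scan and the target date.
#' @param config a `scenario_config` (for the maturity table).
#' @return the updated `landscape` with the extra cuts applied and logged.
#' @export
simulate_missing_clearcuts <- function(x,
                                       rates = c("2019" = 0.068,
                                                 "2020" = 0.076,
                                                 "2021" = 0.084),
                                       partial_year = 0.5,
                                       config = build_scenario("REAL")) {
  yrs <- as.integer(names(rates))
  slope <- if (length(yrs) > 1) {
    unname(stats::coef(stats::lm(rates ~ yrs))[2])
  } else 0
  latest <- rates[[which.max(yrs)]]
  st <- x$stands
  ypm <- years_past_maturity(x, config$maturity_table)
  eligible <- !is.na(ypm) & ypm >= 0 & st$registered & st$zone != "strict"
  to_cut <- integer()
  for (k in seq_along(yrs)) {
    in_region <- st$scan_year == yrs[k]
    gap <- (latest - rates[[k]]) + partial_year * slope
    n_extra <- round(gap * sum(in_region))
    if (n_extra <= 0) next
    pool <- which(in_region & eligible)
    if (!length(pool)) next
    to_cut <- c(to_cut, pool[sample.int(length(pool), min(n_extra, length(pool)))])
  }
  if (!length(to_cut)) return(x)
  reset <- x$upper$stand %in% to_cut
  x$upper$age[reset] <- 0
  x$upper$stock[reset] <- x$upper$share[reset]
  x$second <- x$second[!x$second$stand %in% to_cut, ]
  x$stands$ysc[to_cut] <- 0L
  # these cuts happened before the target date, so they are logged to the
  # year preceding the first simulated one
  x$events <- bind_rows(x$events, tibble(
    stand_id = x$stands$id[to_cut], year = x$year - 1L, event = "clearcut",
    area_m2 = x$stands$area[to_cut]))
  x
}

#' Impute a missing overstory composition from similar stands
#'
#' Stands without any composition data are assigned the overstory of a
#' similar registered stand -- same site type, nearest centroid -- and a
#' regeneration mode drawn with probability 0.2 artificial (planted) and
#' 0.8 natural. Stands that already have a composition are left unchanged.
#'
#' @param x a `landscape`.
#' @param stand_ids stands to impute (default: all without an upper layer).
#' @param p_artificial probability of artificial regeneration.
#' @return the updated `landscape`.
#' @export
impute_missing_composition <- function(x, stand_ids = NULL,
                                       p_artificial = 0.2) {
  have <- unique(x$upper$stand)
  if (is.null(stand_ids)) {
    stand_ids <- setdiff(x$stands$id, have)
  } else {
    stand_ids <- setdiff(stand_ids, have)  # guard: composition present
  }
  if (!length(stand_ids)) return(x)
  st <- x$stands
  donors_all <- intersect(which(st$registered), have)
  if (!length(donors_all)) abort("empty donor pool: no registered stand has a composition")
  new_rows <- vector("list", length(stand_ids))
  modes <- ifelse(runif(length(stand_ids)) < p_artificial, "planted", "natural")
  for (k in seq_along(stand_ids)) {
    i <- stand_ids[k]
    cand <- donors_all[st$site[donors_all] == st$site[i] & donors_all != i]
    if (!length(cand)) cand <- donors_all[donors_all != i]
    if (!length(cand)) abort("empty donor pool for stand with missing composition")
    d2 <- (st$cx[cand] - st$cx[i])^2 + (st$cy[cand] - st$cy[i])^2
    don <- cand[which.min(d2)]
    rows <- x$upper[x$upper$stand == don, ]
    rows$stand <- i
    new_rows[[k]] <- rows
  }
  x$upper <- arrange(bind_rows(x$upper, new_rows), .data$stand)
  x$stands$regen_mode[stand_ids] <- modes
  x
}
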