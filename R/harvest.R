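# The harvest engine: the annual clear-cutting decision ("does the owner
# want to harvest, and is it allowed?"), sequential permitting under the
# adjacency rules, two-step cuts, state forest harvesting under a quota,
# and the annual iteration / multi-seed scenario driver.

#' Age-adjusted annual cutting probability
#'
#' The base probability rises linearly with years past the minimum felling
#' age so that exceeding it by `horizon` years (default 20) doubles the
#' base, capped at 1. Stands below the felling age get probability 0.
#'
#' @param base base yearly probability in `[0, 1]`.
#' @param years_past_maturity years past the minimum felling age (may be
#'   negative).
#' @param horizon years past maturity at which the base doubles.
#' @return the adjusted probability (vectorised).
#' @examples
#' age_adjusted_probability(0.385, 20)   # 0.77
#' age_adjusted_probability(0.385, -3)   # 0
#' @export
age_adjusted_probability <- function(base, years_past_maturity, horizon = 20) {
  ifelse(is.na(years_past_maturity) | years_past_maturity < 0, 0,
         pmin(1, base * (1 + years_past_maturity / horizon)))
}

#' Unit-level permit application probability from per-stand probabilities
#'
#' The owner-level probability of applying for a harvest permit is the
#' equal-weight mean of the age-adjusted per-stand probabilities over
#' stands with nonzero probability (immature and strictly protected stands
#' are omitted); 0 when no stand qualifies.
#'
#' @param adjusted numeric vector of age-adjusted per-stand probabilities.
#' @return the application probability.
#' @examples
#' application_probability(c(0.3, 0, 0.77, 0))  # 0.535
#' @export
application_probability <- function(adjusted) {
  pos <- adjusted[adjusted > 0]
  if (!length(pos)) 0 else mean(pos)
}

#' Per-stand adjusted probabilities and the unit application probability
#'
#' Computes the age-adjusted yearly cutting probability of every stand of a
#' private cadastral unit under a scenario configuration (base probability
#' from the unit's management intensity, capped class A/B overrides, zeroed
#' for strict protection, unregistered or immature stands) and averages the
#' nonzero ones.
#'
#' @param x a `landscape`.
#' @param unit_id a private cadastral unit id.
#' @param config a `scenario_config`.
#' @param year calendar year used for the market-pressure ramp (defaults to
#'   the landscape year).
#' @return the unit's application probability.
#' @export
unit_application_probability <- function(x, unit_id,
                                         config = build_scenario("REAL"),
                                         year = x$year) {
  un <- x$units
  owner <- un$owner_type[match(unit_id, un$id)]
  if (is.na(owner)) abort(paste("unknown cadastral unit", unit_id))
  if (owner == "state") {
    abort("state units do not apply for permits; see state_forest_harvest()")
  }
  padj <- stand_adjusted_probabilities(x, config, year)
  application_probability(padj[x$stands$unit == unit_id])
}

# Vector of age-adjusted per-stand probabilities for the whole landscape
# (0 for state stands, which are handled by the state machinery).
stand_adjusted_probabilities <- function(x, config, year = x$year) {
  st <- x$stands
  hp <- config$harvest
  n <- nrow(st)
  ypm <- years_past_maturity(x, config$maturity_table)
  owner <- x$units$owner_type[match(st$unit, x$units$id)]
  intens <- x$units$intensity[match(st$unit, x$units$id)]
  base_nonint <- if (isTRUE(config$market_pressure)) {
    interpolate_nonint_cutprob(year, config)
  } else hp$cutprob_nonint
  base <- ifelse(intens == "INT", hp$cutprob_int, base_nonint)
  base[st$zone == "classA"] <- pmin(hp$cutprob_classA, base[st$zone == "classA"])
  base[st$zone == "classB"] <- pmin(hp$cutprob_classB, base[st$zone == "classB"])
  horizon <- rep(hp$doubling_horizon, n)
  hl <- hp$limited_doubling_horizon %||% hp$doubling_horizon
  horizon[st$zone %in% c("classA", "classB")] <- hl
  padj <- age_adjusted_probability(base, ypm, horizon)
  padj[st$zone == "strict" | !st$registered | owner == "state"] <- 0
  padj
}

#' Total connected cutover area around a candidate stand
#'
#' Flood-fills the stand adjacency graph from the candidate, traversing
#' only stands currently counting as clear-cut (weighted age below the
#' threshold); the candidate itself is counted as if already cut. The
#' summed area is what the adjacency criterion compares with the
#' management-type limit, so neighbours' neighbours are reached through
#' connected young stands.
#'
#' @param x a `landscape`.
#' @param stand_id candidate stand id.
#' @param threshold age (years) below which a stand counts as a clear-cut.
#' @return total cutover area in m^2.
#' @export
clearcut_cluster_area <- function(x, stand_id, threshold = 6) {
  age <- stand_ages(x)
  young <- !is.na(age) & age < threshold
  members <- flood_cluster(x$adjacency, young, stand_id)
  sum(x$stands$area[members])
}

# Iterative flood fill over `young` stands starting at s (s always
# included). Returns member indices.
flood_cluster <- function(adj, young, s) {
  inclust <- rep(FALSE, length(adj))
  inclust[s] <- TRUE
  stack <- s
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (young[w] && !inclust[w]) {
        inclust[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  which(inclust)
}

#' Decide a clear-cut permit for a candidate stand
#'
#' Applies the management-type-specific allowance rule against the
#' connected cutover area: general and bog management compare the cluster
#' with their area limit, with a single-stand exemption for stands larger
#' than the limit on their own; alvar and riparian management additionally
#' allow over-limit stands as two-step cuts; limited management checks only
#' that no neighbouring stand was clear-cut within the quiet period.
#' Strictly protected stands must never reach this point.
#'
#' @param x a `landscape`.
#' @param stand_id candidate stand id.
#' @param config a `scenario_config`.
#' @return a list with `decision` (`"allowed"`, `"denied"`,
#'   `"allowed_two_step"`) and `reason` (`NA` or the denial reason).
#' @export
permit_clearcut <- function(x, stand_id, config = build_scenario("REAL")) {
  hp <- config$harvest
  age <- stand_ages(x)
  young <- !is.na(age) & age < hp$clearcut_age
  permit_decision(x$adjacency, x$stands$area, x$stands$mgmt, x$stands$ysc,
                  young, stand_id, hp)
}

# Shared permit rule used by the exported wrapper and the engine.
permit_decision <- function(adj, area, mgmt, ysc, young, s, hp) {
  m <- mgmt[s]
  if (m == "no_management") {
    abort("strictly protected stand reached the permitting step")
  }
  if (m == "limited") {
    nb <- adj[[s]]
    blocked <- length(nb) && any(!is.na(ysc[nb]) & ysc[nb] < hp$quiet_years)
    if (blocked) return(list(decision = "denied", reason = "quiet_period"))
    return(list(decision = "allowed", reason = NA_character_))
  }
  limit <- switch(m, alvar = hp$limit_alvar, riparian = hp$limit_riparian,
                  bog = hp$limit_bog, general = hp$limit_general)
  if (!is.finite(limit)) return(list(decision = "allowed", reason = NA_character_))
  two_step_type <- m %in% c("alvar", "riparian")
  if (two_step_type && area[s] > limit) {
    child_area <- min(limit, area[s] / 2)
    members <- flood_cluster(adj, young, s)
    clust <- child_area + sum(area[members[members != s]])
    if (clust <= limit) {
      return(list(decision = "allowed_two_step", reason = NA_character_))
    }
    return(list(decision = "denied", reason = "adjacency"))
  }
  members <- flood_cluster(adj, young, s)
  total <- sum(area[members])
  if (total <= limit) return(list(decision = "allowed", reason = NA_character_))
  if (!two_step_type && area[s] > limit && length(members) == 1L) {
    return(list(decision = "allowed", reason = NA_character_))
  }
  list(decision = "denied", reason = "adjacency")
}

## ---------------------------------------------------------------------------
## internal mutable engine

make_engine <- function(x, config, year = x$year) {
  st <- x$stands
  hp <- config$harvest
  eng <- new.env(parent = emptyenv())
  eng$n <- nrow(st)
  for (nm in c("area", "cx", "cy", "x0", "x1", "y0", "y1", "unit", "zone",
               "site", "mgmt", "prod", "hpi", "registered", "scan_year",
               "regen_mode", "ysc", "similar_natural", "similar_planted")) {
    assign(nm, st[[nm]], envir = eng)
  }
  eng$adj <- x$adjacency
  age <- stand_age_vec(x$upper, eng$n)
  eng$ypm <- age - maturity_vec(x$upper, st$prod, config$maturity_table, eng$n)
  eng$young <- !is.na(age) & age < hp$clearcut_age
  eng$cut_now <- rep(FALSE, eng$n)
  eng$flip <- rep(FALSE, eng$n)
  eng$processed <- rep(FALSE, eng$n)
  eng$owner <- x$units$owner_type[match(st$unit, x$units$id)]
  eng$splits <- list()
  eng$cut_order <- integer()
  eng$hp <- hp
  eng$counts <- list(applications = 0L, units_applied = 0L, allowed = 0L,
                     denied_adjacency = 0L, denied_quiet = 0L, two_step = 0L,
                     area_private = 0, area_state = 0)
  eng
}

engine_cut <- function(eng, s, state_cut = FALSE) {
  eng$young[s] <- TRUE
  eng$ysc[s] <- 0L
  eng$cut_now[s] <- TRUE
  eng$cut_order <- c(eng$cut_order, s)
  eng$flip[s] <- runif(1L) < eng$hp$regen_flip
  if (state_cut) {
    eng$counts$area_state <- eng$counts$area_state + eng$area[s]
  } else {
    eng$counts$area_private <- eng$counts$area_private + eng$area[s]
  }
  invisible(eng)
}

# Split an over-limit alvar/riparian stand into a harvested child (keeps the
# parent's id) and a residual child (new id). Children inherit the parent's
# neighbours and are adjacent to each other; the rectangle, when present, is
# split along its longer side so geometry stays exact.
engine_split <- function(eng, s) {
  m <- eng$mgmt[s]
  limit <- switch(m, alvar = eng$hp$limit_alvar, riparian = eng$hp$limit_riparian)
  child_area <- min(limit, eng$area[s] / 2)
  resid_area <- eng$area[s] - child_area
  t <- eng$n + 1L
  f <- child_area / eng$area[s]
  # geometry
  x0 <- eng$x0[s]; x1 <- eng$x1[s]; y0 <- eng$y0[s]; y1 <- eng$y1[s]
  cx_t <- eng$cx[s]; cy_t <- eng$cy[s]
  if (!is.na(x0)) {
    if ((x1 - x0) >= (y1 - y0)) {
      xm <- x0 + f * (x1 - x0)
      eng$x1[s] <- xm
      x0_t <- xm; x1_t <- x1; y0_t <- y0; y1_t <- y1
    } else {
      ym <- y0 + f * (y1 - y0)
      eng$y1[s] <- ym
      x0_t <- x0; x1_t <- x1; y0_t <- ym; y1_t <- y1
    }
    eng$cx[s] <- (eng$x0[s] + eng$x1[s]) / 2
    eng$cy[s] <- (eng$y0[s] + eng$y1[s]) / 2
    cx_t <- (x0_t + x1_t) / 2
    cy_t <- (y0_t + y1_t) / 2
  } else {
    x0_t <- x1_t <- y0_t <- y1_t <- NA_real_
  }
  old_nb <- eng$adj[[s]]
  eng$area[s] <- child_area
  # append the residual child
  eng$area <- c(eng$area, resid_area)
  eng$cx <- c(eng$cx, cx_t); eng$cy <- c(eng$cy, cy_t)
  eng$x0 <- c(eng$x0, x0_t); eng$x1 <- c(eng$x1, x1_t)
  eng$y0 <- c(eng$y0, y0_t); eng$y1 <- c(eng$y1, y1_t)
  for (nm in c("unit", "zone", "site", "mgmt", "prod", "hpi", "registered",
               "scan_year", "regen_mode", "similar_natural",
               "similar_planted", "owner")) {
    assign(nm, c(get(nm, envir = eng), get(nm, envir = eng)[s]), envir = eng)
  }
  eng$ysc <- c(eng$ysc, NA_integer_)
  eng$ypm <- c(eng$ypm, eng$ypm[s])
  eng$young <- c(eng$young, FALSE)
  eng$cut_now <- c(eng$cut_now, FALSE)
  eng$flip <- c(eng$flip, FALSE)
  eng$processed <- c(eng$processed, TRUE)  # residual waits for later years
  eng$adj[[t]] <- sort(c(old_nb, s))
  eng$adj[[s]] <- sort(c(old_nb, t))
  for (nb in old_nb) eng$adj[[nb]] <- sort(c(eng$adj[[nb]], t))
  eng$n <- t
  eng$splits[[length(eng$splits) + 1L]] <- c(s, t)
  eng$counts$two_step <- eng$counts$two_step + 1L
  t
}

# Process one candidate stand through permit + execution.
engine_try_cut <- function(eng, s, state_cut = FALSE) {
  res <- permit_decision(eng$adj, eng$area, eng$mgmt, eng$ysc, eng$young,
                         s, eng$hp)
  if (res$decision == "allowed") {
    eng$counts$allowed <- eng$counts$allowed + 1L
    engine_cut(eng, s, state_cut)
  } else if (res$decision == "allowed_two_step") {
    engine_split(eng, s)
    eng$counts$allowed <- eng$counts$allowed + 1L
    engine_cut(eng, s, state_cut)
  } else if (identical(res$reason, "quiet_period")) {
    eng$counts$denied_quiet <- eng$counts$denied_quiet + 1L
  } else {
    eng$counts$denied_adjacency <- eng$counts$denied_adjacency + 1L
  }
  res$decision
}

# Private permitting passes in the fixed management-type sequence. `apps`
# is the integer vector of applied stand indices.
engine_private_phase <- function(eng, apps) {
  eng$counts$applications <- length(apps)
  for (m in c("alvar", "riparian", "limited", "bog", "general")) {
    cand <- apps[eng$mgmt[apps] == m]
    if (!length(cand)) next
    uu <- unique(eng$unit[cand])
    uu <- uu[sample.int(length(uu))]  # seeded random unit order per year
    for (u in uu) {
      ss <- cand[eng$unit[cand] == u]
      ss <- ss[order(-eng$area[ss], ss)]  # largest stand first
      for (s in ss) {
        if (eng$cut_now[s]) next
        engine_try_cut(eng, s, state_cut = FALSE)
      }
    }
  }
  invisible(eng)
}

# State harvesting: repeatedly pick the largest harvestable cluster (sum of
# eligible state stand areas within the cluster radius of a focal stand)
# and cut its members through the ordinary permits, until the yearly quota
# is reached or no eligible stands remain.
engine_state_phase <- function(eng) {
  hp <- eng$hp
  state <- eng$owner == "state"
  offset <- ifelse(eng$hpi, hp$state_offset_hpi, hp$state_offset)
  elig <- state & eng$registered & eng$zone != "strict" &
    !is.na(eng$ypm) & eng$ypm >= offset
  # willingness: unrestricted state stands always willing at cutprob 1;
  # class A/B stands get stand-level Bernoulli draws
  ab <- eng$zone %in% c("classA", "classB")
  idx <- which(elig)
  if (length(idx)) {
    willing <- rep(TRUE, length(idx))
    draws <- runif(length(idx))
    p <- ifelse(ab[idx], hp$cutprob_state_AB, hp$cutprob_state)
    willing <- draws < p
    elig[idx] <- willing
  }
  eng$elig_state <- elig
  quota <- hp$state_quota
  repeat {
    e <- which(eng$elig_state[seq_len(eng$n)] & !eng$processed & !eng$cut_now)
    if (!length(e) || quota <= 0) break
    if (length(e) == 1L) {
      focal_i <- 1L
      members <- e
    } else {
      d2 <- outer(eng$cx[e], eng$cx[e], "-")^2 + outer(eng$cy[e], eng$cy[e], "-")^2
      within <- d2 <= hp$state_radius^2
      scores <- as.vector(within %*% eng$area[e])
      focal_i <- order(-scores, e)[1L]
      members <- e[within[focal_i, ]]
    }
    members <- members[order(-eng$area[members], members)]
    for (s in members) {
      if (quota <= 0) break
      dec <- engine_try_cut(eng, s, state_cut = TRUE)
      if (dec %in% c("allowed", "allowed_two_step")) {
        quota <- quota - eng$area[s]  # after a split this is the cut child
      }
    }
    eng$processed[members] <- TRUE
    # appended residual children carry elig_state implicitly FALSE
    if (length(eng$elig_state) < eng$n) {
      eng$elig_state <- c(eng$elig_state,
                          rep(FALSE, eng$n - length(eng$elig_state)))
    }
  }
  invisible(eng)
}

# Rebuild a landscape object from the engine, apply the batched composition
# updates for cuts and splits, and log events.
engine_finalize <- function(eng, x, year) {
  n <- eng$n
  up0 <- x$upper
  sec0 <- x$second
  up <- up0
  sec <- sec0
  # duplicate compositions for split residual children (pre-cut parent rows)
  if (length(eng$splits)) {
    dup_u <- lapply(eng$splits, function(pr) {
      rows <- up0[up0$stand == pr[1], ]
      if (nrow(rows)) rows$stand <- pr[2]
      rows
    })
    dup_s <- lapply(eng$splits, function(pr) {
      rows <- sec0[sec0$stand == pr[1], ]
      if (nrow(rows)) rows$stand <- pr[2]
      rows
    })
    up <- bind_rows(up, dup_u)
    sec <- bind_rows(sec, dup_s)
  }
  cutids <- which(eng$cut_now)
  if (length(cutids)) {
    # regeneration-mode transitions: copy composition from the stored
    # similar stand of the target mode, when available
    flips <- cutids[eng$flip[cutids]]
    for (s in flips) {
      target <- if (eng$regen_mode[s] == "planted") "natural" else "planted"
      ref <- if (target == "natural") eng$similar_natural[s] else eng$similar_planted[s]
      if (!is.na(ref)) {
        rows <- up0[up0$stand == ref, ]
        if (nrow(rows)) {
          rows$stand <- s
          up <- bind_rows(up[up$stand != s, ], rows)
        }
      }
      eng$regen_mode[s] <- target
    }
    reset <- up$stand %in% cutids
    up$age[reset] <- 0
    up$stock[reset] <- up$share[reset]
    sec <- sec[!sec$stand %in% cutids, ]
  }
  x$stands <- tibble(
    id = seq_len(n), area = eng$area, cx = eng$cx, cy = eng$cy,
    x0 = eng$x0, x1 = eng$x1, y0 = eng$y0, y1 = eng$y1,
    unit = eng$unit, zone = eng$zone, site = eng$site, mgmt = eng$mgmt,
    prod = eng$prod, hpi = eng$hpi, registered = eng$registered,
    scan_year = eng$scan_year, regen_mode = eng$regen_mode, ysc = eng$ysc,
    similar_natural = eng$similar_natural, similar_planted = eng$similar_planted
  )
  x$adjacency <- eng$adj
  x$upper <- arrange(up, .data$stand)
  x$second <- arrange(sec, .data$stand)
  if (length(eng$cut_order)) {
    x$events <- bind_rows(x$events, tibble(
      stand_id = eng$cut_order, year = year, event = "clearcut",
      area_m2 = eng$area[eng$cut_order]))
  }
  x$counters <- bind_rows(x$counters, as_tibble(c(list(year = year), eng$counts)))
  x
}

#' Run the state forest harvesting step in isolation
#'
#' Draws state harvest willingness, determines the largest harvestable
#' clusters (eligible state stands within the cluster radius of a focal
#' stand, past maturity by the state offsets) and cuts them through the
#' ordinary permits until the yearly quota is reached. Exposed separately
#' for inspection; [run_year()] calls the same machinery.
#'
#' @param x a `landscape`.
#' @param config a `scenario_config`.
#' @return the updated `landscape` (ages are not advanced).
#' @export
state_forest_harvest <- function(x, config = build_scenario("REAL")) {
  eng <- make_engine(x, config)
  engine_state_phase(eng)
  engine_finalize(eng, x, x$year)
}

#' Simulate one year of the landscape model
#'
#' One annual iteration, in order: scenario drivers (ownership conversion,
#' land-reform registration, the market-pressure ramp), harvest willingness
#' draws (one Bernoulli per private cadastral unit at its application
#' probability; on success the owner applies for all eligible stands;
#' stand-level draws for state class A/B stands), sequential private
#' permitting in the fixed management-type order (alvar, riparian, limited,
#' bog, general; units in seeded random order; largest stand first within a
#' unit; every executed cut constrains the next permit), state forest
#' harvesting under the quota, and finally aging plus the second-layer
#' transfer. Uses the current RNG stream.
#'
#' @param x a `landscape`.
#' @param config a `scenario_config`.
#' @return the landscape advanced by one year.
#' @export
run_year <- function(x, config = build_scenario("REAL")) {
  stopifnot(inherits(x, "landscape"), inherits(config, "scenario_config"))
  hp <- config$harvest
  year <- x$year
  ## scenario drivers
  if (config$conversion_rate > 0) x <- convert_ownership(x, config)
  x <- include_unregistered(x, config)
  ## willingness
  padj <- stand_adjusted_probabilities(x, config, year)
  st <- x$stands
  owner <- x$units$owner_type[match(st$unit, x$units$id)]
  private <- owner != "state"
  pos <- padj > 0 & private
  apps <- integer()
  n_units_applied <- 0L
  if (any(pos)) {
    sums <- rowsum(padj[pos], st$unit[pos])
    cnts <- rowsum(rep(1, sum(pos)), st$unit[pos])
    uids <- as.integer(rownames(sums))
    uprob <- sums[, 1] / cnts[, 1]
    ord <- order(uids)
    uids <- uids[ord]; uprob <- uprob[ord]
    success <- runif(length(uids)) < uprob
    applied_units <- uids[success]
    n_units_applied <- length(applied_units)
    apps <- which(pos & st$unit %in% applied_units)
  }
  ## sequential permitting and execution
  eng <- make_engine(x, config, year)
  eng$counts$units_applied <- n_units_applied
  engine_private_phase(eng, apps)
  engine_state_phase(eng)
  x <- engine_finalize(eng, x, year)
  ## aging and succession
  x <- advance_ages(x)
  x <- transfer_second_layer(x, hp$second_layer_rate)
  x$year <- year + 1L
  x
}

#' Run a multi-year, multi-seed scenario
#'
#' Runs independent seeded replicates of the scenario: each replicate
#' redraws the management-intensity assignment (a dominant source of
#' between-run variation), optionally applies the simulated extra
#' clear-cuts of starting condition "b", and iterates [run_year()]. Per
#' year it records cut areas and the broad age-class area shares; pass
#' `metrics_fn` to add custom per-year columns.
#'
#' @param x the initial `landscape`.
#' @param config a `scenario_config`.
#' @param seeds integer vector of replicate seeds.
#' @param n_years number of annual iterations (default: the scenario
#'   horizon).
#' @param reassign_intensity redraw unit intensities per replicate.
#' @param metrics_fn optional `function(landscape)` returning a one-row
#'   data frame of extra per-year metrics.
#' @param keep_final keep the final `landscape` of each replicate.
#' @return an object of class `scenario_run` with elements `trajectories`
#'   (tibble: seed, year, area_cut_m2, n_cuts, share_young, share_old80,
#'   share_old100, ...), `config`, `seeds`, and optionally `final_states`.
#' @export
run_scenario <- function(x, config = build_scenario("REAL"),
                         seeds = 1:3,
                         n_years = config$end_year - config$start_year,
                         reassign_intensity = TRUE,
                         metrics_fn = NULL,
                         keep_final = FALSE) {
  stopifnot(n_years >= 1)
  traj <- list()
  finals <- list()
  for (sd in seeds) {
    set.seed(sd)
    y <- x
    if (reassign_intensity) y <- assign_intensity(y, config)
    if (isTRUE(config$extra_clearcuts)) y <- simulate_missing_clearcuts(y, config = config)
    for (t in seq_len(n_years)) {
      y <- run_year(y, config)
      yr <- y$year - 1L
      age <- stand_ages(y)
      tot <- sum(y$stands$area)
      cuts <- y$events[y$events$year == yr & y$events$event == "clearcut", ]
      row <- tibble(
        seed = sd, year = yr,
        area_cut_m2 = sum(cuts$area_m2), n_cuts = nrow(cuts),
        share_young = sum(y$stands$area[!is.na(age) & age < 20]) / tot,
        share_old80 = sum(y$stands$area[!is.na(age) & age >= 80]) / tot,
        share_old100 = sum(y$stands$area[!is.na(age) & age >= 100]) / tot)
      if (!is.null(metrics_fn)) row <- bind_rows(cbind(row, metrics_fn(y)))
      traj[[length(traj) + 1L]] <- row
    }
    if (keep_final) finals[[as.character(sd)]] <- y
  }
  structure(list(
    trajectories = bind_rows(traj),
    config = config,
    seeds = seeds,
    final_states = if (keep_final) finals else NULL
  ), class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  tr <- x$trajectories
  cat("<scenario_run>", x$config$name, "-", length(x$seeds), "seed(s),",
      length(unique(tr$year)), "years\n")
  print(glance(x))
  invisible(x)
}

## ---------------------------------------------------------------------------
## calibration helpers

#' Analytic cumulative probability of harvest since maturation
#'
#' Without harvest constraints, a stand with yearly base probability `base`
#' and the linear age adjustment is cut within `years` years of maturation
#' with probability `1 - prod(1 - min(1, base * (1 + t/horizon)))` over
#' `t = 0, ..., years - 1`. This closed form backs the calibration of the
#' base probabilities against stated time-to-cut targets.
#'
#' @param base base yearly probability.
#' @param years number of years since maturation.
#' @param horizon doubling horizon of the age adjustment.
#' @return cumulative cut probability.
#' @examples
#' time_to_cut_cdf(0.385, 3)  # about 0.79
#' @export
time_to_cut_cdf <- function(base, years, horizon = 20) {
  t <- seq_len(years) - 1
  1 - prod(1 - pmin(1, base * (1 + t / horizon)))
}

#' Monte-Carlo cumulative cut fraction since maturation
#'
#' Simulates independent stand trajectories (no harvest constraints, one
#' stand per owner) under the yearly age-adjusted Bernoulli decision and
#' returns the fraction cut within `years` years. Cross-checks
#' [time_to_cut_cdf()].
#'
#' @param base base yearly probability.
#' @param years number of years since maturation.
#' @param n number of simulated stands.
#' @param horizon doubling horizon.
#' @return the empirical cumulative cut fraction.
#' @export
simulate_time_to_cut <- function(base, years, n = 1e5, horizon = 20) {
  alive <- rep(TRUE, n)
  for (t in seq_len(years) - 1) {
    p <- min(1, base * (1 + t / horizon))
    a <- which(alive)
    alive[a] <- runif(length(a)) >= p
  }
  1 - mean(alive)
}

#' The four-stand worked example landscape
#'
#' A single intensively managed cadastral unit of four mutually adjacent
#' stands: a strictly protected stand (3 ha, 10 years past maturity), a
#' limited-management class A stand (3 ha, 30 years past), an immature
#' unrestricted stand (2 ha, 5 years short of maturity) and a mature
#' unrestricted stand (2 ha, 20 years past). Useful for tracing the
#' application-probability arithmetic and the permitting rules by hand.
#'
#' @return a `landscape`.
#' @export
worked_example_landscape <- function() {
  # pure pine, productivity class 2 -> minimum felling age 100
  ages <- c(110, 130, 95, 120)
  stands <- tibble(
    id = 1:4, area = c(3, 3, 2, 2) * 1e4,
    cx = c(0, 100, 0, 100), cy = c(0, 0, 100, 100),
    unit = 1L,
    zone = c("strict", "classA", "unrestricted", "unrestricted"),
    site = "mineral", prod = 2L)
  stands$mgmt <- assign_management_type(stands$zone, stands$site)
  edges <- expand.grid(from = 1:4, to = 1:4)
  edges <- edges[edges$from < edges$to, ]
  upper <- tibble(stand = 1:4, species = "pine", share = 1,
                  age = ages, stock = 1)
  units <- tibble(id = 1L, owner_type = "juridical", intensity = "INT")
  new_landscape(stands, units, upper, adjacency = edges, year = 2022L)
}
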