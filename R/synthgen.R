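# Synthetic landscape generator: seeded landscapes with the statistical
# structure of the study system (zoning fractions, site prevalences,
# ownership mix, multi-stand cadastral units), plus synthetic canopy-height
# summaries used by the registry-refresh detector.

#' Parameters of the synthetic landscape generator
#'
#' Defaults emulate the modelled forest estate: mean stand area of about
#' 1.15 ha (2.3 Mha over ~2 M stands), 12.9% strictly protected and 12.3%
#' restricted-management area, alvar and bog site prevalences of 2.0% and
#' 13.6%, and 10% of the land not yet registered (hence not harvestable
#' until the land reform completes). Restricted area is split between
#' waterbody restriction and limited-management classes in proportion to
#' their reported prevalences (5.1% vs 6.8%); limited-management stands are
#' assigned class A or B with equal probability.
#'
#' @param n_stands number of stands.
#' @param mean_stand_area mean stand area in m^2.
#' @param fraction_strict,fraction_restricted target area fractions of the
#'   strict and restricted zones.
#' @param fraction_waterbody_of_restricted share of the restricted zone
#'   under waterbody restriction (the rest is limited management).
#' @param prevalence_alvar,prevalence_bog target site-type fractions.
#' @param state_fraction fraction of cadastral units that are state owned.
#' @param juridical_fraction fraction of *private* units owned by juridical
#'   persons (companies); the rest belong to physical persons.
#' @param unit_sizes,unit_size_probs distribution of stands per cadastral
#'   unit (contiguous units are grown to a size drawn from it).
#' @param age_breaks,age_weights piecewise-uniform stand age distribution:
#'   ages are drawn uniformly within `[age_breaks[k], age_breaks[k+1])`
#'   with probability `age_weights[k]`. The default mixes a recent
#'   clear-cut cohort, mid-aged managed forest and an old tail.
#' @param p_planted probability that a stand regenerated artificially.
#' @param p_second_layer probability that a stand older than 60 years
#'   carries a described second layer before the second-layer rules run.
#' @param settlement_density settlements per km^2 (drives the heightened
#'   public interest flag within `hpi_distance` metres).
#' @param hpi_distance distance to a settlement below which state stands
#'   are of heightened public interest (m).
#' @param fraction_unregistered fraction of stands not in the registry.
#' @param blob_size mean size (stands) of the spatially clustered blobs
#'   used for zones, sites and unregistered land.
#' @param seed integer seed making generation fully reproducible.
#' @return a list of class `synth_params`.
#' @export
synth_params <- function(n_stands = 1000L,
                         mean_stand_area = 11500,
                         fraction_strict = 0.129,
                         fraction_restricted = 0.123,
                         fraction_waterbody_of_restricted = 0.051 / 0.119,
                         prevalence_alvar = 0.020,
                         prevalence_bog = 0.136,
                         state_fraction = 0.5,
                         juridical_fraction = 0.3,
                         unit_sizes = 1:6,
                         unit_size_probs = c(0.15, 0.2, 0.25, 0.2, 0.12, 0.08),
                         age_breaks = c(0, 6, 20, 60, 90, 140),
                         age_weights = c(0.08, 0.17, 0.40, 0.20, 0.15),
                         p_planted = 0.2,
                         p_second_layer = 0.35,
                         settlement_density = 0.05,
                         hpi_distance = 1000,
                         fraction_unregistered = 0.10,
                         blob_size = 20,
                         seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$n_stands >= 1,
            p$fraction_strict >= 0, p$fraction_restricted >= 0,
            p$fraction_strict + p$fraction_restricted <= 1,
            all(p$unit_size_probs >= 0),
            length(p$age_weights) == length(p$age_breaks) - 1)
  if (max(p$unit_sizes) > p$n_stands) {
    abort("infeasible params: a cadastral unit cannot exceed n_stands")
  }
  structure(p, class = "synth_params")
}

#' Generate a synthetic landscape
#'
#' Builds a jittered rectangular tessellation of `n_stands` stands (areas
#' sum exactly to the landscape extent, adjacency is the planar 4-neighbour
#' grid), grows contiguous cadastral units, assigns restriction zones,
#' site types and unregistered land as spatially clustered blobs hitting
#' their target fractions, draws ages and layered species compositions,
#' links similar natural/planted reference stands, and applies the
#' second-layer initialisation rules so the landscape is ready to simulate.
#'
#' @param params a [synth_params()] list.
#' @param seed optional override of `params$seed`.
#' @return a valid `landscape` ([validate_landscape()] returns zero rows).
#' @export
generate_landscape <- function(params = synth_params(), seed = NULL) {
  stopifnot(inherits(params, "synth_params"))
  if (!is.null(seed)) params$seed <- seed
  set.seed(params$seed)
  n <- as.integer(params$n_stands)

  ## --- tessellation: jittered global grid lines -------------------------
  ny <- max(1L, floor(sqrt(n)))
  while (n %% ny != 0L) ny <- ny - 1L
  nx <- n %/% ny
  side <- sqrt(params$mean_stand_area)
  jitter1 <- function(k, total) {
    w <- runif(k, 0.7, 1.3)
    w / sum(w) * total
  }
  widths <- jitter1(nx, nx * side)
  heights <- jitter1(ny, ny * side)
  xs <- c(0, cumsum(widths))
  ys <- c(0, cumsum(heights))
  col <- rep(seq_len(nx), times = ny)
  row <- rep(seq_len(ny), each = nx)
  x0 <- xs[col]; x1 <- xs[col + 1L]
  y0 <- ys[row]; y1 <- ys[row + 1L]
  area <- (x1 - x0) * (y1 - y0)
  cx <- (x0 + x1) / 2; cy <- (y0 + y1) / 2
  extent <- c(nx * side, ny * side)

  id_at <- function(r, c) (r - 1L) * nx + c
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    r <- row[i]; c <- col[i]
    nb <- integer()
    if (c > 1L) nb <- c(nb, id_at(r, c - 1L))
    if (c < nx) nb <- c(nb, id_at(r, c + 1L))
    if (r > 1L) nb <- c(nb, id_at(r - 1L, c))
    if (r < ny) nb <- c(nb, id_at(r + 1L, c))
    adj[[i]] <- sort(nb)
  }

  ## --- contiguous cadastral units by BFS growth -------------------------
  unit_of <- integer(n)
  next_unit <- 0L
  unassigned_order <- sample.int(n)
  for (s in unassigned_order) {
    if (unit_of[s] != 0L) next
    next_unit <- next_unit + 1L
    target <- sample(params$unit_sizes, 1L, prob = params$unit_size_probs)
    members <- s
    unit_of[s] <- next_unit
    frontier <- adj[[s]]
    while (length(members) < target) {
      frontier <- frontier[unit_of[frontier] == 0L]
      if (!length(frontier)) break
      pick <- frontier[[sample.int(length(frontier), 1L)]]
      unit_of[pick] <- next_unit
      members <- c(members, pick)
      frontier <- unique(c(frontier[frontier != pick], adj[[pick]]))
    }
  }
  n_units <- next_unit

  ## --- spatially clustered blob assignment ------------------------------
  grow_blobs <- function(eligible, target_n) {
    chosen <- logical(n)
    remaining <- target_n
    free <- eligible
    while (remaining > 0L && any(free)) {
      seed_s <- which(free)
      seed_s <- seed_s[[sample.int(length(seed_s), 1L)]]
      size <- min(remaining, 1L + stats::rgeom(1L, 1 / params$blob_size))
      blob <- seed_s
      chosen[seed_s] <- TRUE; free[seed_s] <- FALSE
      frontier <- adj[[seed_s]]
      while (length(blob) < size) {
        frontier <- frontier[free[frontier]]
        if (!length(frontier)) break
        pick <- frontier[[sample.int(length(frontier), 1L)]]
        chosen[pick] <- TRUE; free[pick] <- FALSE
        blob <- c(blob, pick)
        frontier <- unique(c(frontier[frontier != pick], adj[[pick]]))
      }
      remaining <- remaining - length(blob)
    }
    chosen
  }

  zone <- rep("unrestricted", n)
  strict_sel <- grow_blobs(rep(TRUE, n), round(params$fraction_strict * n))
  zone[strict_sel] <- "strict"
  restr_sel <- grow_blobs(!strict_sel, round(params$fraction_restricted * n))
  water <- restr_sel & (runif(n) < params$fraction_waterbody_of_restricted)
  zone[restr_sel] <- ifelse(water[restr_sel], "waterbody",
                            ifelse(runif(sum(restr_sel)) < 0.5, "classA", "classB"))

  site <- rep("mineral", n)
  bog_sel <- grow_blobs(rep(TRUE, n), round(params$prevalence_bog * n))
  site[bog_sel] <- "bog"
  alvar_sel <- grow_blobs(!bog_sel, round(params$prevalence_alvar * n))
  site[alvar_sel] <- "alvar"

  registered <- !grow_blobs(rep(TRUE, n), round(params$fraction_unregistered * n))

  ## --- ownership and intensity ------------------------------------------
  owner <- ifelse(runif(n_units) < params$state_fraction, "state",
                  ifelse(runif(n_units) < params$juridical_fraction,
                         "juridical", "physical"))
  units <- tibble(
    id = seq_len(n_units),
    owner_type = owner,
    intensity = ifelse(owner == "state", "not_applicable",
                       ifelse(runif(n_units) <
                                ifelse(owner == "juridical", 0.95, 0.35),
                              "INT", "nonINT"))
  )

  ## --- ages, productivity, composition ----------------------------------
  k <- length(params$age_weights)
  cls <- sample.int(k, n, replace = TRUE, prob = params$age_weights)
  age <- floor(runif(n, params$age_breaks[cls], params$age_breaks[cls + 1L]))
  prod <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.5, 0.2))
  regen_mode <- ifelse(runif(n) < params$p_planted, "planted", "natural")

  dominant_by_site <- list(
    alvar = c(pine = 0.8, spruce = 0.1, birch = 0.1, aspen = 0),
    bog = c(pine = 0.7, birch = 0.25, spruce = 0.05, aspen = 0),
    mineral = c(pine = 0.35, spruce = 0.3, birch = 0.25, aspen = 0.1),
    other = c(pine = 0.25, spruce = 0.25, birch = 0.35, aspen = 0.15)
  )
  upper_list <- vector("list", n)
  for (i in seq_len(n)) {
    w <- dominant_by_site[[site[i]]]
    n_sp <- sample(1:3, 1L, prob = c(0.4, 0.4, 0.2))
    sp <- sample(names(w), n_sp, prob = w + 1e-6)
    sh <- rexp(n_sp) + 0.2
    sh <- sh / sum(sh)
    comp_age <- pmax(0, age[i] + if (n_sp > 1) c(0, sample(-5:5, n_sp - 1L, TRUE)) else 0)
    vol_ha <- pmin(350, 3 * comp_age)
    upper_list[[i]] <- data.frame(
      stand = i, species = sp, share = sh, age = comp_age,
      stock = sh * vol_ha * area[i] / 1e4)
  }
  upper <- as_tibble(do.call(rbind, upper_list))
  wage <- stand_age_vec(upper, n)

  has_second <- wage >= 60 & runif(n) < params$p_second_layer
  second <- tibble(
    stand = which(has_second), species = "spruce", share = 1,
    age = pmax(5, floor(wage[has_second] / 3)),
    stock = 30 * area[has_second] / 1e4)

  ## --- settlements and heightened public interest ------------------------
  n_settl <- stats::rpois(1L, params$settlement_density * prod(extent) / 1e6)
  settlements <- tibble(x = runif(n_settl, 0, extent[1]),
                        y = runif(n_settl, 0, extent[2]))
  hpi <- rep(FALSE, n)
  if (n_settl > 0) {
    for (j in seq_len(n_settl)) {
      d2 <- (cx - settlements$x[j])^2 + (cy - settlements$y[j])^2
      hpi <- hpi | d2 <= params$hpi_distance^2
    }
  }

  ## --- lidar scan year by region (vertical thirds) -----------------------
  scan_year <- 2019L + pmin(2L, floor(3 * cx / extent[1]))

  ## --- similar-stand references (same site type, nearest centroid) -------
  sim_nat <- nearest_of_mode(cx, cy, site, regen_mode, "natural")
  sim_pla <- nearest_of_mode(cx, cy, site, regen_mode, "planted")

  stands <- tibble(
    id = seq_len(n), area = area, cx = cx, cy = cy,
    x0 = x0, x1 = x1, y0 = y0, y1 = y1,
    unit = unit_of, zone = zone, site = site,
    mgmt = assign_management_type(zone, site),
    prod = as.integer(prod), hpi = hpi, registered = registered,
    scan_year = scan_year, regen_mode = regen_mode,
    ysc = ifelse(age < 6, as.integer(age), NA_integer_),
    similar_natural = sim_nat, similar_planted = sim_pla
  )

  x <- new_landscape(stands, units, upper, second, adjacency = adj,
                     year = 2022L, extent = extent, settlements = settlements)
  x$stands$mgmt <- stands$mgmt
  x$params <- params
  apply_second_layer_rules(x)
}

# For each stand, the nearest other stand of the same site type whose
# regeneration mode is `mode` (used as donor for post-harvest regeneration
# transitions and for composition imputation). Chunked distance search.
nearest_of_mode <- function(cx, cy, site, mode, target_mode, chunk = 500L) {
  n <- length(cx)
  out <- rep(NA_integer_, n)
  for (s in unique(site)) {
    targets <- which(site == s)
    cand <- which(site == s & mode == target_mode)
    if (!length(cand)) next
    for (start in seq(1L, length(targets), by = chunk)) {
      tt <- targets[start:min(start + chunk - 1L, length(targets))]
      d2 <- outer(cx[tt], cx[cand], "-")^2 + outer(cy[tt], cy[cand], "-")^2
      d2[cbind(match(intersect(tt, cand), tt),
               match(intersect(tt, cand), cand))] <- Inf  # exclude self
      out[tt] <- cand[max.col(-d2, ties.method = "first")]
    }
  }
  out
}

#' Synthetic canopy-height summaries
#'
#' Builds per-stand 50th/90th percentile canopy-height summaries as a test
#' fixture for the clear-cut detector: intact stands get `p50` near their
#' expected height with `p90` slightly above; stands listed in `cut_ids`
#' (unrecorded clear-cuts) get a near-zero `p50` with sparse tall retention
#' returns driving a high `p90`.
#'
#' @param x a `landscape`.
#' @param cut_ids stand ids to treat as secretly clear-cut.
#' @param noise_sd measurement noise (m) added to the percentiles.
#' @param height_params height-curve parameters, see [expected_height()].
#' @return a tibble `(stand_id, p50, p90, scan_year)`.
#' @export
generate_canopy_summaries <- function(x, cut_ids = integer(),
                                      noise_sd = 0.5,
                                      height_params = default_height_params()) {
  st <- x$stands
  n <- nrow(st)
  h <- expected_stand_height(x, height_params)
  cut <- st$id %in% cut_ids
  p50 <- h + rnorm(n, 0, noise_sd)
  p90 <- p50 + 0.12 * h + abs(rnorm(n, 0, noise_sd / 2))
  p50[cut] <- pmin(2, abs(rnorm(sum(cut), 0.5, noise_sd / 2)))
  p90[cut] <- pmax(0.8 * h[cut] + rnorm(sum(cut), 0, noise_sd), p50[cut])
  p50 <- pmax(0, p50)
  p90 <- pmax(p50, p90)
  tibble(stand_id = st$id, p50 = p50, p90 = p90, scan_year = st$scan_year)
}

# Expected height of each stand from its dominant species, weighted age and
# productivity class.
expected_stand_height <- function(x, height_params = default_height_params()) {
  st <- x$stands
  up <- x$upper
  dom <- up %>%
    group_by(.data$stand) %>%
    slice(which.max(.data$share)) %>%
    ungroup()
  sp <- rep(NA_character_, nrow(st))
  sp[dom$stand] <- dom$species
  age <- stand_ages(x)
  out <- rep(0, nrow(st))
  ok <- !is.na(sp)
  out[ok] <- expected_height(sp[ok], age[ok], st$prod[ok], height_params)
  out
}
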