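# Core landscape state: domain vocabulary, the landscape container,
# management-type assignment and structural validation.

#' Category levels used throughout the model
#'
#' Restriction zones follow the national protection categories: strict
#' protection (no harvesting), limited-management classes A and B, waterbody
#' shore/bank restriction, and unrestricted land. Site types collapse the
#' national site-type catalogue to the four classes that drive distinct
#' harvest rules. Management types are derived from zone and site in a fixed
#' priority order (see [assign_management_type()]).
#'
#' @name standscape-levels
#' @keywords internal
NULL

zone_levels <- c("unrestricted", "strict", "classA", "classB", "waterbody")
site_levels <- c("alvar", "bog", "mineral", "other")
mgmt_levels <- c("no_management", "alvar", "limited", "riparian", "bog", "general")
owner_levels <- c("state", "physical", "juridical")
species_pool <- c("pine", "spruce", "birch", "aspen")

#' Assign the operative management type of a stand
#'
#' Management types are assigned from restriction zone and forest site type
#' in a fixed priority order: strict protection always wins, then alvar
#' sites, then limited-management classes A/B, then waterbody restriction,
#' then bog sites; everything else is general management. A stand matching
#' several rules takes the highest-priority one, so e.g. a peatland stand
#' inside a waterbody restriction is managed as riparian, not bog.
#'
#' @param zone character vector of restriction zones
#'   (`unrestricted`, `strict`, `classA`, `classB`, `waterbody`).
#' @param site character vector of site types
#'   (`alvar`, `bog`, `mineral`, `other`).
#' @return character vector of management types, one of `no_management`,
#'   `alvar`, `limited`, `riparian`, `bog`, `general`.
#' @examples
#' assign_management_type("strict", "bog")       # no_management
#' assign_management_type("waterbody", "bog")    # riparian
#' assign_management_type("unrestricted", "mineral")
#' @export
assign_management_type <- function(zone, site) {
  bad_zone <- !zone %in% zone_levels
  if (any(bad_zone)) {
    abort(paste0("unknown restriction zone code(s): ",
                 paste(unique(zone[bad_zone]), collapse = ", ")))
  }
  bad_site <- !site %in% site_levels
  if (any(bad_site)) {
    abort(paste0("unknown site type code(s): ",
                 paste(unique(site[bad_site]), collapse = ", ")))
  }
  out <- rep("general", length(zone))
  out[site == "bog"] <- "bog"
  out[zone == "waterbody"] <- "riparian"
  out[zone %in% c("classA", "classB")] <- "limited"
  out[site == "alvar"] <- "alvar"
  out[zone == "strict"] <- "no_management"
  out
}

#' Share-weighted mean age of a stand layer
#'
#' The stand age used against the minimum felling age is the weighted mean
#' of the per-species component ages, weighted by their share of the layer.
#'
#' @param layer a data frame with columns `share` and `age` (one row per
#'   species component). Shares are expected to sum to 1.
#' @return the weighted mean age in years.
#' @examples
#' weighted_stand_age(data.frame(share = c(0.75, 0.25), age = c(40, 80)))
#' @export
weighted_stand_age <- function(layer) {
  if (is.null(layer) || nrow(layer) == 0) {
    abort("no overstory: cannot compute a stand age from an empty layer")
  }
  sum(layer$share * layer$age)
}

#' Construct a landscape object from component tables
#'
#' The landscape is the full mutable world of the simulation: a stand table,
#' a cadastral-unit table, the layered species compositions in long format,
#' a symmetric stand adjacency structure, the calendar year, and an
#' append-only event log. Most users will obtain one from
#' [generate_landscape()] or [read_landscape_csv()]; this constructor exists
#' for building small landscapes programmatically (tests, worked examples).
#'
#' @param stands tibble with one row per stand. Required columns: `id`
#'   (integer), `area` (m^2), `cx`, `cy` (planar metric centroid), `unit`
#'   (cadastral unit id), `zone`, `site`. Optional columns (defaulted when
#'   missing): `prod` (productivity class, integer, 1 = best), `hpi`,
#'   `registered`, `scan_year`, `regen_mode`, `ysc` (years since clear-cut,
#'   `NA` when unknown), `similar_natural`, `similar_planted`, and the
#'   rectangle geometry `x0`, `x1`, `y0`, `y1` (needed only for the
#'   geometry-based metrics).
#' @param units tibble with columns `id`, `owner_type`
#'   (`state`/`physical`/`juridical`) and optionally `intensity`
#'   (`INT`/`nonINT`/`not_applicable`).
#' @param upper,second long composition tables with columns `stand`,
#'   `species`, `share`, `age` and optionally `stock` (m^3). `second` may be
#'   `NULL` or empty.
#' @param adjacency either a two-column data frame of undirected edges
#'   (`from`, `to`, stand ids) or a list of integer neighbour vectors
#'   indexed by stand id.
#' @param year starting calendar year.
#' @param extent optional `c(width, height)` of the landscape in metres.
#' @param settlements optional tibble of settlement points (`x`, `y`).
#' @return an object of class `landscape`.
#' @export
new_landscape <- function(stands, units, upper, second = NULL,
                          adjacency = NULL, year = 2022L,
                          extent = NULL, settlements = NULL) {
  stands <- as_tibble(stands)
  req <- c("id", "area", "cx", "cy", "unit", "zone", "site")
  missing_cols <- setdiff(req, names(stands))
  if (length(missing_cols)) {
    abort(paste0("stand table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(stands)
  stands$id <- as.integer(stands$id)
  defaults <- list(
    prod = 2L, hpi = FALSE, registered = TRUE, scan_year = 2021L,
    regen_mode = "natural", ysc = NA_integer_,
    similar_natural = NA_integer_, similar_planted = NA_integer_,
    x0 = NA_real_, x1 = NA_real_, y0 = NA_real_, y1 = NA_real_
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(stands)) stands[[nm]] <- rep(defaults[[nm]], n)
  }
  stands$ysc <- as.integer(stands$ysc)
  if (!identical(stands$id, seq_len(n))) {
    abort("stand ids must be the consecutive integers 1..n (row order)")
  }
  if (!"mgmt" %in% names(stands)) {
    stands$mgmt <- assign_management_type(stands$zone, stands$site)
  }

  units <- as_tibble(units)
  units$id <- as.integer(units$id)
  if (!"intensity" %in% names(units)) {
    units$intensity <- ifelse(units$owner_type == "state",
                              "not_applicable", "nonINT")
  }

  adj <- as_adjacency_list(adjacency, n)

  fix_comp <- function(tab) {
    if (is.null(tab) || nrow(as.data.frame(tab)) == 0) {
      return(tibble(stand = integer(), species = character(),
                    share = double(), age = double(), stock = double()))
    }
    tab <- as_tibble(tab)
    if (!"stock" %in% names(tab)) tab$stock <- tab$share
    tab$stand <- as.integer(tab$stand)
    tab[, c("stand", "species", "share", "age", "stock")]
  }

  structure(
    list(
      year = as.integer(year),
      stands = stands,
      units = units,
      upper = fix_comp(upper),
      second = fix_comp(second),
      adjacency = adj,
      extent = extent,
      settlements = settlements,
      events = empty_events(),
      counters = tibble(),
      reg_schedule = NULL
    ),
    class = "landscape"
  )
}

empty_events <- function() {
  tibble(stand_id = integer(), year = integer(),
         event = character(), area_m2 = double())
}

# Normalise the two accepted adjacency encodings to a list of integer
# neighbour vectors indexed by stand id.
as_adjacency_list <- function(adjacency, n) {
  if (is.null(adjacency)) {
    return(rep(list(integer()), n))
  }
  if (is.data.frame(adjacency)) {
    from <- as.integer(adjacency[[1]])
    to <- as.integer(adjacency[[2]])
    adj <- rep(list(integer()), n)
    both <- split(c(to, from), c(from, to))
    idx <- as.integer(names(both))
    adj[idx] <- lapply(both, function(v) sort(unique(v)))
    return(adj)
  }
  stopifnot(is.list(adjacency))
  adjacency <- lapply(adjacency, as.integer)
  if (length(adjacency) < n) {
    adjacency <- c(adjacency, rep(list(integer()), n - length(adjacency)))
  }
  adjacency
}

#' Share-weighted stand ages for every stand
#'
#' @param x a `landscape`.
#' @return a numeric vector indexed by stand id (`NA` for stands without an
#'   upper layer).
#' @export
stand_ages <- function(x) {
  stand_age_vec(x$upper, nrow(x$stands))
}

stand_age_vec <- function(upper, n) {
  out <- rep(NA_real_, n)
  if (nrow(upper)) {
    s <- rowsum(upper$share * upper$age, upper$stand)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  # snap float drift from share sums (1 - 1e-16) back to the integer ages
  # it perturbs, so threshold comparisons (clear-cut age, class edges)
  # behave as the integer-age semantics dictate
  near <- !is.na(out) & abs(out - round(out)) < 1e-9
  out[near] <- round(out[near])
  out
}

#' Validate the structural invariants of a landscape
#'
#' Checks the container invariants: symmetric and irreflexive adjacency,
#' layer shares summing to one, positive stand areas, known zone and site
#' codes, and every stand mapping to an existing cadastral unit. Violations
#' are returned as data, not raised as errors.
#'
#' @param x a `landscape`.
#' @param tol numeric tolerance on layer share sums.
#' @return a tibble with columns `stand_id`, `check`, `detail`; zero rows
#'   when the landscape is valid.
#' @export
validate_landscape <- function(x, tol = 1e-9) {
  st <- x$stands
  out <- list()
  bad <- which(!st$zone %in% zone_levels)
  if (length(bad)) {
    out[[length(out) + 1L]] <- tibble(stand_id = st$id[bad], check = "zone",
                                      detail = paste("unknown zone", st$zone[bad]))
  }
  bad <- which(!st$site %in% site_levels)
  if (length(bad)) {
    out[[length(out) + 1L]] <- tibble(stand_id = st$id[bad], check = "site",
                                      detail = paste("unknown site", st$site[bad]))
  }
  bad <- which(!(st$area > 0))
  if (length(bad)) {
    out[[length(out) + 1L]] <- tibble(stand_id = st$id[bad], check = "area",
                                      detail = "non-positive area")
  }
  bad <- which(!st$unit %in% x$units$id)
  if (length(bad)) {
    out[[length(out) + 1L]] <- tibble(stand_id = st$id[bad], check = "unit",
                                      detail = "stand maps to no cadastral unit")
  }
  # adjacency symmetry / irreflexivity
  adj <- x$adjacency
  for (i in seq_along(adj)) {
    nb <- adj[[i]]
    if (any(nb == i)) {
      out[[length(out) + 1L]] <- tibble(stand_id = i, check = "adjacency",
                                        detail = "stand adjacent to itself")
    }
    back <- vapply(nb, function(j) i %in% adj[[j]], logical(1))
    if (length(nb) && any(!back)) {
      out[[length(out) + 1L]] <- tibble(
        stand_id = i, check = "adjacency",
        detail = paste("neighbour", paste(nb[!back], collapse = ","),
                       "does not list the stand back"))
    }
  }
  # share sums per layer
  for (layer in c("upper", "second")) {
    tab <- x[[layer]]
    if (!nrow(tab)) next
    s <- rowsum(tab$share, tab$stand)
    off <- abs(s[, 1] - 1) > tol
    if (any(off)) {
      out[[length(out) + 1L]] <- tibble(
        stand_id = as.integer(rownames(s))[off], check = paste0(layer, "_shares"),
        detail = paste("shares sum to", signif(s[off, 1], 6)))
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(stand_id = integer(), check = character(), detail = character())
}

#' @export
print.landscape <- function(x, ...) {
  st <- x$stands
  cat("<landscape> year", x$year, "-", nrow(st), "stands,",
      nrow(x$units), "cadastral units\n")
  cat("  total area:", format(sum(st$area) / 1e4, big.mark = ","), "ha\n")
  zl <- table(st$zone)
  cat("  zones:", paste(names(zl), as.integer(zl), sep = "=", collapse = " "), "\n")
  cat("  events logged:", nrow(x$events), "\n")
  invisible(x)
}

#' Plot a landscape coloured by stand age
#'
#' Requires rectangle geometry (synthetic landscapes carry it).
#'
#' @param object a `landscape`.
#' @param fill one of `"age"`, `"zone"`, `"mgmt"`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.landscape <- function(object, fill = c("age", "zone", "mgmt"), ...) {
  fill <- match.arg(fill)
  st <- object$stands
  if (all(is.na(st$x0))) {
    abort("landscape has no rectangle geometry to plot")
  }
  st$age <- stand_ages(object)
  ggplot2::ggplot(st) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$x0, xmax = .data$x1, ymin = .data$y0, ymax = .data$y1,
      fill = .data[[fill]])) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = fill) +
    ggplot2::theme_minimal()
}

#' Write / read a landscape as plain CSV tables
#'
#' The on-disk format is a directory of four CSV files: `stands.csv`
#' (stand attributes incl. rectangle geometry), `units.csv`, `upper.csv`
#' and `second.csv` (long composition tables), and `edges.csv` (undirected
#' adjacency). Events are written to `events.csv` when present.
#'
#' @param x a `landscape`.
#' @param path directory to write into (created if needed).
#' @return `write_landscape_csv` returns `path` invisibly;
#'   `read_landscape_csv` returns a `landscape`.
#' @export
write_landscape_csv <- function(x, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$stands, file.path(path, "stands.csv"), row.names = FALSE)
  utils::write.csv(x$units, file.path(path, "units.csv"), row.names = FALSE)
  utils::write.csv(x$upper, file.path(path, "upper.csv"), row.names = FALSE)
  utils::write.csv(x$second, file.path(path, "second.csv"), row.names = FALSE)
  edges <- adjacency_edges(x$adjacency)
  utils::write.csv(edges, file.path(path, "edges.csv"), row.names = FALSE)
  if (nrow(x$events)) {
    utils::write.csv(x$events, file.path(path, "events.csv"), row.names = FALSE)
  }
  meta <- data.frame(key = c("year", "extent_x", "extent_y"),
                     value = c(x$year,
                               if (is.null(x$extent)) NA else x$extent[1],
                               if (is.null(x$extent)) NA else x$extent[2]))
  utils::write.csv(meta, file.path(path, "meta.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape_csv
#' @export
read_landscape_csv <- function(path) {
  rd <- function(f) as_tibble(utils::read.csv(file.path(path, f)))
  stands <- rd("stands.csv")
  meta <- rd("meta.csv")
  year <- as.integer(meta$value[meta$key == "year"])
  ext <- as.numeric(meta$value[meta$key %in% c("extent_x", "extent_y")])
  if (anyNA(ext)) ext <- NULL
  x <- new_landscape(
    stands = stands, units = rd("units.csv"),
    upper = rd("upper.csv"), second = rd("second.csv"),
    adjacency = rd("edges.csv"), year = year, extent = ext)
  ev <- file.path(path, "events.csv")
  if (file.exists(ev)) x$events <- as_tibble(utils::read.csv(ev))
  x
}

adjacency_edges <- function(adj) {
  from <- rep.int(seq_along(adj), lengths(adj))
  to <- unlist(adj, use.names = FALSE)
  keep <- from < to
  data.frame(from = from[keep], to = to[keep])
}
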