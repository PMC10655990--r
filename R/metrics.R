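# Landscape output metrics: age-class composition, patch building, patch
# size distributions, edge areas, and incidence-function (Hanski)
# connectivity aggregated on a regular grid.

#' Age-class composition of the forest area
#'
#' Area shares of stand-age classes, optionally stratified by protection
#' zone (pooled to strict / restricted / production), management type, or
#' ownership. Shares sum to one within each stratum.
#'
#' @param x a `landscape`.
#' @param class_edges inner age-class breaks in years (classes are
#'   `[0, e1), [e1, e2), ..., [ek, Inf)`).
#' @param stratify `NULL` or one of `"zone"`, `"management"`, `"ownership"`.
#' @return a tibble `(stratum, age_class, area_m2, share)`.
#' @export
age_class_composition <- function(x, class_edges = c(20, 80),
                                  stratify = NULL) {
  st <- x$stands
  age <- stand_ages(x)
  breaks <- c(0, class_edges, Inf)
  cls <- cut(age, breaks = breaks, right = FALSE, include.lowest = TRUE)
  stratum <- if (is.null(stratify)) {
    rep("all", nrow(st))
  } else if (stratify == "zone") {
    ifelse(st$zone == "strict", "strict",
           ifelse(st$zone == "unrestricted", "production", "restricted"))
  } else if (stratify == "management") {
    st$mgmt
  } else if (stratify == "ownership") {
    x$units$owner_type[match(st$unit, x$units$id)]
  } else {
    abort("stratify must be NULL, 'zone', 'management' or 'ownership'")
  }
  tab <- tibble(stratum = stratum, age_class = cls, area = st$area) %>%
    filter(!is.na(.data$age_class)) %>%
    group_by(.data$stratum, .data$age_class, .drop = FALSE) %>%
    summarise(area_m2 = sum(.data$area), .groups = "drop_last") %>%
    mutate(share = {
      tot <- sum(.data$area_m2)
      if (tot > 0) .data$area_m2 / tot else rep(0, dplyr::n())
    }) %>%
    ungroup()
  tab[tab$stratum %in% unique(stratum), ]
}

#' Group stands of similar age into patches
#'
#' Connected components of the stand adjacency graph restricted to stands
#' whose weighted age falls in `age_range` (`[lo, hi)`; use `c(80, Inf)`
#' for old forest, `c(0, 20)` for early-successional patches). Patch area
#' is the member sum, the centroid the area-weighted member centroid, and
#' the equivalent radius that of a circle of the patch area.
#'
#' @param x a `landscape`.
#' @param age_range numeric `c(lo, hi)`, lower inclusive, upper exclusive.
#' @return a tibble `(patch_id, n_stands, area_m2, cx, cy, radius_m,
#'   stand_ids)` with `stand_ids` a list column.
#' @export
build_patches <- function(x, age_range = c(80, Inf)) {
  age <- stand_ages(x)
  keep <- which(!is.na(age) & age >= age_range[1] & age < age_range[2])
  if (!length(keep)) {
    return(tibble(patch_id = integer(), n_stands = integer(),
                  area_m2 = double(), cx = double(), cy = double(),
                  radius_m = double(), stand_ids = list()))
  }
  edges <- adjacency_edges(x$adjacency)
  sub <- edges[edges$from %in% keep & edges$to %in% keep, ]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(sub$from), to = as.character(sub$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(keep)))
  comp <- igraph::components(g)
  member <- comp$membership[as.character(keep)]
  st <- x$stands
  area <- st$area[keep]
  patch <- tibble(stand = keep, patch_id = as.integer(member), area = area,
                  wx = st$cx[keep] * area, wy = st$cy[keep] * area) %>%
    group_by(.data$patch_id) %>%
    summarise(n_stands = n(), area_m2 = sum(.data$area),
              cx = sum(.data$wx) / sum(.data$area),
              cy = sum(.data$wy) / sum(.data$area),
              stand_ids = list(.data$stand), .groups = "drop") %>%
    mutate(radius_m = sqrt(.data$area_m2 / pi),
           patch_id = row_number())
  patch[, c("patch_id", "n_stands", "area_m2", "cx", "cy", "radius_m",
            "stand_ids")]
}

#' One term of the incidence-function connectivity index
#'
#' `exp(-a * d) * S^b` with the edge-to-edge distance `d` in kilometres and
#' the neighbouring patch area `S` in square metres.
#'
#' @param S neighbouring patch area in m^2.
#' @param d distance in km.
#' @param a distance-decay parameter (per km).
#' @param b area exponent.
#' @return the contribution of the neighbouring patch (vectorised).
#' @examples
#' hanski_term(10000, 0)        # 100
#' hanski_term(1e6, 2)          # exp(-1) * 1000
#' @export
hanski_term <- function(S, d, a = 0.5, b = 0.5) {
  exp(-a * d) * S^b
}

#' Incidence-function connectivity of every patch
#'
#' For each focal patch, sums [hanski_term()] over all other patches whose
#' edge-to-edge distance is within the search radius. Patches are treated
#' as circles around their centroids (radius from area), so the
#' edge-to-edge distance is `max(0, ||c_i - c_j|| - r_i - r_j)`; the focal
#' patch itself is excluded.
#'
#' @param patches a patch table from [build_patches()].
#' @param a,b incidence-function parameters.
#' @param radius_km neighbourhood search radius in km (edge-to-edge).
#' @return `patches` with a `connectivity` column added.
#' @export
patch_connectivity <- function(patches, a = 0.5, b = 0.5, radius_km = 10) {
  n <- nrow(patches)
  conn <- numeric(n)
  if (n > 1) {
    dc <- sqrt(outer(patches$cx, patches$cx, "-")^2 +
                 outer(patches$cy, patches$cy, "-")^2)
    dee <- (dc - outer(patches$radius_m, patches$radius_m, "+")) / 1000
    dee[dee < 0] <- 0
    decay <- exp(-a * dee)
    decay[dee > radius_km] <- 0
    diag(decay) <- 0
    conn <- as.vector(decay %*% (patches$area_m2^b))
  }
  patches$connectivity <- conn
  patches
}

#' Edge area and edge proportion of patches
#'
#' The edge of a patch is its area within `edge_distance` metres of open
#' land (the landscape exterior) or of stands up to `open_age` years old
#' (clear-cuts and early-successional stands). Computed exactly for the
#' rectangle geometry of synthetic landscapes by eroding each member
#' rectangle on its exposed sides; requires geometry.
#'
#' @param x a `landscape` with rectangle geometry.
#' @param patches a patch table from [build_patches()].
#' @param edge_distance edge depth in metres.
#' @param open_age age (years) up to which a neighbouring stand counts as
#'   open.
#' @return `patches` with `edge_m2` and `edge_prop` columns added.
#' @export
edge_area <- function(x, patches, edge_distance = 30, open_age = 20) {
  st <- x$stands
  if (all(is.na(st$x0))) {
    abort("edge_area needs rectangle geometry; this landscape has none")
  }
  age <- stand_ages(x)
  open <- !is.na(age) & age <= open_age
  eps <- 1e-6
  edge_of_member <- function(s, members) {
    nb <- x$adjacency[[s]]
    w <- st$x1[s] - st$x0[s]
    h <- st$y1[s] - st$y0[s]
    side_exposed <- function(side_nb) {
      if (!length(side_nb)) return(TRUE)      # landscape exterior = open land
      any(open[side_nb])
    }
    yov <- pmin(st$y1[nb], st$y1[s]) - pmax(st$y0[nb], st$y0[s])
    xov <- pmin(st$x1[nb], st$x1[s]) - pmax(st$x0[nb], st$x0[s])
    left <- nb[abs(st$x1[nb] - st$x0[s]) < eps & yov > eps]
    right <- nb[abs(st$x0[nb] - st$x1[s]) < eps & yov > eps]
    bottom <- nb[abs(st$y1[nb] - st$y0[s]) < eps & xov > eps]
    top <- nb[abs(st$y0[nb] - st$y1[s]) < eps & xov > eps]
    eL <- side_exposed(left); eR <- side_exposed(right)
    eB <- side_exposed(bottom); eT <- side_exposed(top)
    inner <- max(0, w - edge_distance * (eL + eR)) *
      max(0, h - edge_distance * (eB + eT))
    w * h - inner
  }
  patches$edge_m2 <- vapply(patches$stand_ids, function(members) {
    sum(vapply(members, edge_of_member, numeric(1), members = members))
  }, numeric(1))
  patches$edge_prop <- ifelse(patches$area_m2 > 0,
                              patches$edge_m2 / patches$area_m2, 0)
  patches
}

#' Connectivity aggregated on a regular grid
#'
#' Overlays a square grid (default 10 x 10 km cells) on the landscape and
#' aggregates the patch connectivity indices into each cell. The default
#' aggregation is the area-weighted mean over the patches overlapping the
#' cell, with weights equal to the patch area inside the cell;
#' `agg = "sum"` instead sums the indices weighted by the fraction of each
#' patch inside the cell. Cells without any patch get 0.
#'
#' @param x a `landscape` with rectangle geometry and a known extent.
#' @param patches a patch table with a `connectivity` column (see
#'   [patch_connectivity()]).
#' @param cell_size cell side in metres.
#' @param agg `"mean"` (area-weighted mean) or `"sum"`.
#' @return a tibble `(cell_ix, cell_iy, x0, y0, connectivity,
#'   patch_area_m2)` covering the full grid.
#' @export
grid_connectivity <- function(x, patches, cell_size = 10000,
                              agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  st <- x$stands
  if (all(is.na(st$x0))) {
    abort("grid_connectivity needs rectangle geometry")
  }
  if (!"connectivity" %in% names(patches)) {
    patches <- patch_connectivity(patches)
  }
  extent <- x$extent %||% c(max(st$x1, na.rm = TRUE), max(st$y1, na.rm = TRUE))
  ncx <- max(1L, ceiling(extent[1] / cell_size))
  ncy <- max(1L, ceiling(extent[2] / cell_size))
  acc <- list()
  for (p in seq_len(nrow(patches))) {
    for (s in patches$stand_ids[[p]]) {
      ix0 <- max(0L, floor(st$x0[s] / cell_size))
      ix1 <- min(ncx - 1L, floor((st$x1[s] - 1e-9) / cell_size))
      iy0 <- max(0L, floor(st$y0[s] / cell_size))
      iy1 <- min(ncy - 1L, floor((st$y1[s] - 1e-9) / cell_size))
      for (ix in ix0:ix1) for (iy in iy0:iy1) {
        ov <- max(0, min(st$x1[s], (ix + 1) * cell_size) - max(st$x0[s], ix * cell_size)) *
          max(0, min(st$y1[s], (iy + 1) * cell_size) - max(st$y0[s], iy * cell_size))
        if (ov > 0) {
          acc[[length(acc) + 1L]] <- tibble(
            patch = p, ix = ix, iy = iy, w = ov)
        }
      }
    }
  }
  grid <- tidyr::expand_grid(cell_ix = 0:(ncx - 1L), cell_iy = 0:(ncy - 1L))
  grid$x0 <- grid$cell_ix * cell_size
  grid$y0 <- grid$cell_iy * cell_size
  if (!length(acc)) {
    grid$connectivity <- 0
    grid$patch_area_m2 <- 0
    return(grid)
  }
  wtab <- bind_rows(acc) %>%
    group_by(.data$patch, .data$ix, .data$iy) %>%
    summarise(w = sum(.data$w), .groups = "drop")
  wtab$conn <- patches$connectivity[wtab$patch]
  wtab$patch_total <- patches$area_m2[wtab$patch]
  cells <- wtab %>%
    group_by(.data$ix, .data$iy) %>%
    summarise(
      connectivity = if (.env$agg == "mean") {
        sum(.data$w * .data$conn) / sum(.data$w)
      } else {
        sum(.data$conn * .data$w / .data$patch_total)
      },
      patch_area_m2 = sum(.data$w), .groups = "drop")
  out <- left_join(grid, cells, by = c(cell_ix = "ix", cell_iy = "iy"),
                   suffix = c("", ".y"))
  out$connectivity[is.na(out$connectivity)] <- 0
  out$patch_area_m2[is.na(out$patch_area_m2)] <- 0
  out
}

#' Patch size distribution
#'
#' Totals of patch area by size bin (default: below 1 ha, 1-10 ha, above
#' 10 ha). Bin totals sum to the total patch area.
#'
#' @param patches a patch table from [build_patches()].
#' @param breaks_ha inner bin edges in hectares.
#' @return a tibble `(size_bin, n_patches, total_area_ha)`.
#' @export
patch_size_distribution <- function(patches, breaks_ha = c(1, 10)) {
  ha <- patches$area_m2 / 1e4
  bin <- cut(ha, breaks = c(0, breaks_ha, Inf), right = FALSE,
             include.lowest = TRUE)
  tibble(size_bin = bin, ha = ha) %>%
    group_by(.data$size_bin, .drop = FALSE) %>%
    summarise(n_patches = n(), total_area_ha = sum(.data$ha),
              .groups = "drop")
}
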