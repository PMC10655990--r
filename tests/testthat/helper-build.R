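# Programmatic fixtures: small rectangle-grid landscapes with explicit
# ages, and independent brute-force oracles for graph operations.

make_grid_landscape <- function(nx, ny, ages, cell = 100,
                                zone = "unrestricted", site = "mineral",
                                owner = "physical", intensity = "INT",
                                units_per_stand = TRUE, prod = 2L,
                                year = 2022L, adjacency = TRUE,
                                species = "pine") {
  n <- nx * ny
  stopifnot(length(ages) == n)
  col <- rep(seq_len(nx), times = ny)
  row <- rep(seq_len(ny), each = nx)
  x0 <- (col - 1) * cell; x1 <- col * cell
  y0 <- (row - 1) * cell; y1 <- row * cell
  unit <- if (units_per_stand) seq_len(n) else rep(1L, n)
  stands <- tibble::tibble(
    id = seq_len(n), area = (x1 - x0) * (y1 - y0),
    cx = (x0 + x1) / 2, cy = (y0 + y1) / 2,
    x0 = x0, x1 = x1, y0 = y0, y1 = y1,
    unit = unit,
    zone = rep(zone, length.out = n),
    site = rep(site, length.out = n),
    prod = rep(as.integer(prod), length.out = n),
    ysc = ifelse(ages < 6, as.integer(ages), NA_integer_))
  adj <- NULL
  if (adjacency) {
    id_at <- function(r, c) (r - 1L) * nx + c
    adj <- lapply(seq_len(n), function(i) {
      r <- row[i]; c <- col[i]
      nb <- integer()
      if (c > 1) nb <- c(nb, id_at(r, c - 1L))
      if (c < nx) nb <- c(nb, id_at(r, c + 1L))
      if (r > 1) nb <- c(nb, id_at(r - 1L, c))
      if (r < ny) nb <- c(nb, id_at(r + 1L, c))
      sort(nb)
    })
  }
  uid <- unique(unit)
  units <- tibble::tibble(
    id = uid,
    owner_type = rep(owner, length.out = length(uid)),
    intensity = ifelse(rep(owner, length.out = length(uid)) == "state",
                       "not_applicable",
                       rep(intensity, length.out = length(uid))))
  upper <- tibble::tibble(stand = seq_len(n), species = species, share = 1,
                          age = ages, stock = 1)
  new_landscape(stands, units, upper, adjacency = adj, year = year,
                extent = c(nx * cell, ny * cell))
}

# Independent BFS connected components over a kept-vertex subset.
# Returns a list of sorted integer vectors (the components), sorted by
# their smallest member.
bfs_components_oracle <- function(adj, keep) {
  keep_set <- rep(FALSE, length(adj))
  keep_set[keep] <- TRUE
  seen <- rep(FALSE, length(adj))
  comps <- list()
  for (s in keep) {
    if (seen[s]) next
    comp <- integer()
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) {
        if (keep_set[w] && !seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, integer(1)))]
}

# Brute-force cutover cluster area: candidate s counted as cut, traversal
# only through stands whose age is below the threshold.
cluster_area_oracle <- function(adj, area, age, s, threshold = 6) {
  young <- !is.na(age) & age < threshold
  young[s] <- TRUE
  comp <- bfs_components_oracle(adj, which(young))
  hit <- comp[[which(vapply(comp, function(cc) s %in% cc, logical(1)))]]
  sum(area[hit])
}

# Brute-force double-loop incidence-function connectivity.
connectivity_oracle <- function(patches, a = 0.5, b = 0.5, radius_km = 10) {
  n <- nrow(patches)
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dc <- sqrt((patches$cx[i] - patches$cx[j])^2 +
                   (patches$cy[i] - patches$cy[j])^2)
      d <- max(0, dc - patches$radius_m[i] - patches$radius_m[j]) / 1000
      if (d <= radius_km) {
        out[i] <- out[i] + exp(-a * d) * patches$area_m2[j]^b
      }
    }
  }
  out
}

# Adjacency oracle replaying the within-year cut sequence from the ordered
# event log: immediately after every executed general/bog cut, the
# young-stand cluster containing it must respect that cut's type limit,
# unless the cut stand forms the cluster alone (the oversized-stand
# exemption). `x` is the year-end landscape (ages already advanced), `yr`
# the simulated year just completed.
adjacency_violations_oracle <- function(x, yr, hp, threshold = 6) {
  st <- x$stands
  cuts <- x$events$stand_id[x$events$year == yr & x$events$event == "clearcut"]
  if (!length(cuts)) return(0L)
  pre_age <- stand_ages(x) - 1          # ages at the start of the year
  young <- !is.na(pre_age) & pre_age < threshold
  young[cuts] <- FALSE                  # cut stands were mature beforehand
  bad <- 0L
  for (s in cuts) {
    young[s] <- TRUE                    # the cut just executed
    m <- st$mgmt[s]
    if (!m %in% c("general", "bog")) next
    limit <- if (m == "general") hp$limit_general else hp$limit_bog
    comp <- bfs_components_oracle(x$adjacency, which(young))
    cc <- comp[[which(vapply(comp, function(v) s %in% v, logical(1)))]]
    if (length(cc) >= 2 && sum(st$area[cc]) > limit + 1e-6) bad <- bad + 1L
  }
  bad
}
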