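# Succession: annual aging, second-layer dynamics, and the minimum felling
# age (maturity) machinery.

#' Default minimum felling age table
#'
#' The legal minimum felling age is a matrix of species and
#' site-productivity class. The statutory values are not shipped here; this
#' synthetic default is clearly non-normative and exists so the model runs
#' out of the box. Real values can be supplied as a CSV with columns
#' `species`, `productivity_class`, `min_age` via [read_maturity_table()].
#' Entries are monotone non-increasing in productivity: better sites
#' (class 1) reach the felling age earlier or at the same age.
#'
#' @return a tibble `(species, productivity_class, min_age)`.
#' @export
default_maturity_table <- function() {
  tibble(
    species = rep(c("pine", "spruce", "birch", "aspen"), each = 3),
    productivity_class = rep(1:3, times = 4),
    min_age = c(90, 100, 110,   # pine
                80, 90, 100,    # spruce
                60, 70, 80,     # birch
                40, 50, 60)     # aspen
  )
}

#' @rdname default_maturity_table
#' @param path CSV file with columns `species`, `productivity_class`, `min_age`.
#' @export
read_maturity_table <- function(path) {
  tab <- as_tibble(utils::read.csv(path))
  stopifnot(all(c("species", "productivity_class", "min_age") %in% names(tab)))
  tab
}

#' Minimum felling age of a stand
#'
#' For mixed stands the lookup aggregates by the share-weighted mean of the
#' per-species minimum felling ages at the stand's productivity class (the
#' statutory matrix addresses pure compositions; the mixing rule is a
#' documented model choice).
#'
#' @param composition data frame with columns `species` and `share`.
#' @param productivity_class integer productivity class (1 = best).
#' @param table a maturity table, see [default_maturity_table()].
#' @return minimum felling age in years.
#' @export
maturity_age <- function(composition, productivity_class,
                         table = default_maturity_table()) {
  if (is.null(composition) || nrow(composition) == 0) {
    abort("no overstory: maturity age undefined for an empty layer")
  }
  key <- paste(composition$species, productivity_class)
  idx <- match(key, paste(table$species, table$productivity_class))
  if (anyNA(idx)) {
    abort(paste0("no maturity table entry for: ",
                 paste(unique(key[is.na(idx)]), collapse = ", ")))
  }
  sum(composition$share * table$min_age[idx])
}

# Vectorised maturity ages for all stands (NA where the upper layer is
# empty). Errors on table keys that are genuinely missing.
maturity_vec <- function(upper, prod, table, n) {
  out <- rep(NA_real_, n)
  if (!nrow(upper)) return(out)
  key <- paste(upper$species, prod[upper$stand])
  idx <- match(key, paste(table$species, table$productivity_class))
  if (anyNA(idx)) {
    abort(paste0("no maturity table entry for: ",
                 paste(unique(key[is.na(idx)]), collapse = ", ")))
  }
  s <- rowsum(upper$share * table$min_age[idx], upper$stand)
  out[as.integer(rownames(s))] <- s[, 1]
  near <- !is.na(out) & abs(out - round(out)) < 1e-9
  out[near] <- round(out[near])
  out
}

#' Years past the minimum felling age, per stand
#'
#' @param x a `landscape`.
#' @param table maturity table.
#' @return numeric vector indexed by stand id (negative when immature,
#'   `NA` without an upper layer).
#' @export
years_past_maturity <- function(x, table = default_maturity_table()) {
  n <- nrow(x$stands)
  stand_age_vec(x$upper, n) - maturity_vec(x$upper, x$stands$prod, table, n)
}

#' Advance every stand by one year
#'
#' All component ages in both layers increase by one; years since clear-cut
#' increase by one where tracked. Stand count and total area are conserved.
#'
#' @param x a `landscape`.
#' @return the aged `landscape` (year is advanced by [run_year()], not here).
#' @export
advance_ages <- function(x) {
  x$upper$age <- x$upper$age + 1
  x$second$age <- x$second$age + 1
  x$stands$ysc <- x$stands$ysc + 1L
  x
}

#' Transfer second-layer stock into the overstory
#'
#' Each year a fixed fraction (default 1%) of every second-layer
#' component's stock is added to the matching overstory component (created
#' if absent, inheriting the second-layer component's age); the second
#' layer itself is unchanged. Overstory shares are renormalised to the new
#' stock proportions.
#'
#' @param x a `landscape`.
#' @param rate fraction of second-layer stock transferred per year.
#' @return the updated `landscape`.
#' @export
transfer_second_layer <- function(x, rate = 0.01) {
  if (rate == 0 || nrow(x$second) == 0) return(x)
  up <- x$upper
  sec <- x$second
  add <- sec
  add$stock <- rate * sec$stock
  key_up <- paste(up$stand, up$species)
  key_add <- paste(add$stand, add$species)
  hit <- match(key_add, key_up)
  # existing components: bump stock
  ex <- !is.na(hit)
  if (any(ex)) up$stock[hit[ex]] <- up$stock[hit[ex]] + add$stock[ex]
  # new components enter the overstory at the second-layer age
  if (any(!ex)) {
    up <- bind_rows(up, tibble(
      stand = add$stand[!ex], species = add$species[!ex],
      share = 0, age = add$age[!ex], stock = add$stock[!ex]))
  }
  # renormalise shares to stock proportions within affected stands
  affected <- unique(add$stand)
  sel <- up$stand %in% affected
  tot <- rowsum(up$stock[sel], up$stand[sel])
  denom <- tot[match(up$stand[sel], as.integer(rownames(tot))), 1]
  up$share[sel] <- ifelse(denom > 0, up$stock[sel] / denom, up$share[sel])
  x$upper <- up
  x
}

#' Initialise second layers from the registry-age rules
#'
#' Applied once before simulation: stands younger than 60 years are deemed
#' to lack a second layer (any recorded one is dropped); stands older than
#' 90 years without a described second layer are deemed not to produce one;
#' 60-90 year-old stands without one are assigned a copy of the second
#' layer of the nearest stand within 1 km that is older than 90 years and
#' has one (no donor, no second layer). Idempotent.
#'
#' @param x a `landscape`.
#' @param donor_radius donor search radius in metres.
#' @return the updated `landscape`.
#' @export
apply_second_layer_rules <- function(x, donor_radius = 1000) {
  n <- nrow(x$stands)
  age <- stand_age_vec(x$upper, n)
  has_sec <- seq_len(n) %in% x$second$stand
  # rule 1: < 60 years -> no second layer
  drop <- which(has_sec & !is.na(age) & age < 60)
  if (length(drop)) {
    x$second <- x$second[!x$second$stand %in% drop, ]
    has_sec[drop] <- FALSE
  }
  # rule 3: 60-90 without a second layer -> copy from nearest old donor
  need <- which(!has_sec & !is.na(age) & age >= 60 & age <= 90)
  donors <- which(has_sec & !is.na(age) & age > 90)
  if (length(need) && length(donors)) {
    st <- x$stands
    copies <- vector("list", length(need))
    for (k in seq_along(need)) {
      i <- need[k]
      d2 <- (st$cx[donors] - st$cx[i])^2 + (st$cy[donors] - st$cy[i])^2
      j <- which.min(d2)
      if (d2[j] <= donor_radius^2) {
        don <- x$second[x$second$stand == donors[j], ]
        don$stand <- i
        copies[[k]] <- don
      }
    }
    copies <- copies[!vapply(copies, is.null, logical(1))]
    if (length(copies)) x$second <- bind_rows(x$second, copies)
  }
  # rule 2 (> 90 without) needs no action: nothing assigns them one
  x$second <- arrange(x$second, .data$stand)
  x
}
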