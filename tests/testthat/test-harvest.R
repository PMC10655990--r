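test_that("the age adjustment doubles the base at the horizon and caps at one", {
  expect_equal(age_adjusted_probability(0.385, 20), 0.77)
  expect_equal(age_adjusted_probability(0.385, -3), 0)
  expect_equal(age_adjusted_probability(0.6, 40), 1)
  expect_equal(age_adjusted_probability(0.2, 0), 0.2)
  # vectorised
  expect_equal(age_adjusted_probability(c(0.385, 0.385, 0.6), c(20, -3, 40)),
               c(0.77, 0, 1))
})

test_that("the unit application probability is the mean over nonzero stand probabilities", {
  expect_equal(application_probability(c(0.3, 0, 0.77, 0)), 0.535)
  expect_equal(application_probability(c(0, 0, 0)), 0)
  expect_equal(application_probability(0.4), 0.4)

  W <- worked_example_landscape()
  # under the stated doubling rule the class A stand adjusts 0.2 -> 0.5
  expect_equal(unit_application_probability(W, 1), mean(c(0.5, 0.77)))
  # a slower adjustment for limited-management stands reproduces the
  # printed example value 0.3, hence the unit mean 0.535
  cfg <- build_scenario("REAL", limited_doubling_horizon = 60)
  expect_equal(unit_application_probability(W, 1, cfg), 0.535)

  # all stands immature -> probability 0, never applies
  L <- make_grid_landscape(2, 1, ages = c(50, 60), units_per_stand = FALSE)
  expect_equal(unit_application_probability(L, 1), 0)
  # single eligible stand returns its own probability
  L1 <- make_grid_landscape(1, 1, ages = 100)
  cfg04 <- build_scenario("REAL", cutprob_int = 0.4)
  expect_equal(unit_application_probability(L1, 1, cfg04), 0.4)
  # state units are not permit applicants
  Ls <- make_grid_landscape(1, 1, ages = 100, owner = "state")
  expect_error(unit_application_probability(Ls, 1), "state")
})

test_that("unit willingness draws occur at the computed application probability", {
  W <- worked_example_landscape()
  cfg <- build_scenario("REAL", limited_doubling_horizon = 60)
  set.seed(101)
  applied <- vapply(1:4000, function(i) {
    run_year(W, cfg)$counters$units_applied[1]
  }, integer(1))
  expect_lt(abs(mean(applied) - 0.535), 0.03)
})

test_that("cutover cluster areas flood-fill through connected young stands", {
  # isolated mature 3 ha candidate
  L <- make_grid_landscape(1, 1, ages = 120, cell = sqrt(30000))
  expect_equal(clearcut_cluster_area(L, 1), 30000)
  # chain: candidate 3 ha - young 3 ha - young 2 ha
  st <- tibble::tibble(
    id = 1:3, area = c(30000, 30000, 20000),
    cx = c(0, 200, 400), cy = 0, unit = 1:3,
    zone = "unrestricted", site = "mineral")
  L2 <- new_landscape(st, tibble::tibble(id = 1:3, owner_type = "physical"),
                      upper = tibble::tibble(stand = 1:3, species = "pine",
                                             share = 1, age = c(120, 2, 3)),
                      adjacency = data.frame(from = c(1, 2), to = c(2, 3)))
  expect_equal(clearcut_cluster_area(L2, 1), 80000)
  expect_equal(clearcut_cluster_area(L2, 1),
               cluster_area_oracle(L2$adjacency, L2$stands$area,
                                   stand_ages(L2), 1))
  # worked example: after cutting the 3 ha stand, the 2 ha neighbour's
  # cluster totals 5 ha, below the 7 ha general limit
  W <- worked_example_landscape()
  W$upper$age[W$upper$stand == 2] <- 0
  expect_equal(clearcut_cluster_area(W, 4), 50000)
  expect_lte(clearcut_cluster_area(W, 4),
             default_harvest_params()$limit_general)
})

test_that("permits apply the management-type rules against the cluster area", {
  cfg <- build_scenario("REAL")
  # general stand, cluster within the limit
  st <- tibble::tibble(
    id = 1:3, area = c(30000, 30000, 20000),
    cx = c(0, 200, 400), cy = 0, unit = 1:3,
    zone = "unrestricted", site = "mineral")
  mk <- function(ages, areas = c(30000, 30000, 20000)) {
    s <- st; s$area <- areas
    new_landscape(s, tibble::tibble(id = 1:3, owner_type = "physical"),
                  upper = tibble::tibble(stand = 1:3, species = "pine",
                                         share = 1, age = ages),
                  adjacency = data.frame(from = c(1, 2), to = c(2, 3)))
  }
  L <- mk(c(120, 2, 120))  # candidate + one young 3 ha neighbour = 6 ha
  expect_identical(permit_clearcut(L, 1, cfg)$decision, "allowed")
  # young chain pushes the cluster to 8 ha > 7 ha
  L2 <- mk(c(120, 2, 3))
  res <- permit_clearcut(L2, 1, cfg)
  expect_identical(res$decision, "denied")
  expect_identical(res$reason, "adjacency")
  # 9 ha stand alone: the stand-itself-larger exemption
  L3 <- mk(c(120, 120, 120), areas = c(90000, 30000, 20000))
  expect_identical(permit_clearcut(L3, 1, cfg)$decision, "allowed")
  # but not when connected young cuts join the cluster
  L4 <- mk(c(120, 4, 120), areas = c(90000, 30000, 20000))
  expect_identical(permit_clearcut(L4, 1, cfg)$decision, "denied")
  # strictly protected stands must never be permitted
  L5 <- mk(c(120, 120, 120))
  L5$stands$zone[1] <- "strict"
  L5$stands$mgmt[1] <- "no_management"
  expect_error(permit_clearcut(L5, 1, cfg), "protected")
})

test_that("limited management only checks the five-year neighbour condition", {
  cfg <- build_scenario("REAL")
  L <- make_grid_landscape(2, 1, ages = c(130, 3), zone = c("classA", "unrestricted"))
  L$stands$ysc[2] <- 3L  # neighbour cut three years ago
  res <- permit_clearcut(L, 1, cfg)
  expect_identical(res$decision, "denied")
  expect_identical(res$reason, "quiet_period")
  # five or more years ago: allowed
  L$stands$ysc[2] <- 5L
  L$upper$age[L$upper$stand == 2] <- 5
  expect_identical(permit_clearcut(L, 1, cfg)$decision, "allowed")
})

test_that("over-limit alvar and riparian stands are cut in two steps", {
  cfg <- build_scenario("REAL", cutprob_int = 1)
  # single 3 ha riparian stand (limit 2 ha), its own intensive unit
  st <- tibble::tibble(id = 1L, area = 30000, cx = 150, cy = 50,
                       x0 = 0, x1 = 300, y0 = 0, y1 = 100,
                       unit = 1L, zone = "waterbody", site = "mineral")
  L <- new_landscape(st, tibble::tibble(id = 1L, owner_type = "juridical",
                                        intensity = "INT"),
                     upper = tibble::tibble(stand = 1L, species = "pine",
                                            share = 1, age = 120),
                     extent = c(300, 100))
  expect_identical(permit_clearcut(L, 1, cfg)$decision, "allowed_two_step")
  # at the limit: an ordinary permit, no split
  Lsmall <- L
  Lsmall$stands$area <- 20000
  expect_identical(permit_clearcut(Lsmall, 1, cfg)$decision, "allowed")

  set.seed(7)
  L1 <- run_year(L, cfg)
  expect_identical(nrow(L1$stands), 2L)
  expect_equal(sort(L1$stands$area), c(15000, 15000))  # equal halves
  expect_equal(sum(L1$stands$area), 30000)             # area conserved
  expect_identical(L1$adjacency[[1]], 2L)              # children adjacent
  expect_identical(L1$adjacency[[2]], 1L)
  cut1 <- L1$events[L1$events$event == "clearcut", ]
  expect_identical(cut1$stand_id, 1L)
  expect_equal(cut1$area_m2, 15000)
  # geometry stays rectangular and exact
  expect_equal((L1$stands$x1 - L1$stands$x0) * (L1$stands$y1 - L1$stands$y0),
               L1$stands$area)

  # the residual is blocked while the first child counts as a clear-cut
  for (i in 1:5) L1 <- run_year(L1, cfg)
  expect_identical(nrow(L1$events[L1$events$event == "clearcut", ]), 1L)
  L1 <- run_year(L1, cfg)  # first child now aged 6
  cuts <- L1$events[L1$events$event == "clearcut", ]
  expect_identical(cuts$stand_id, c(1L, 2L))
  expect_identical(cuts$year, c(2022L, 2028L))
})

test_that("regeneration mode flips with probability 0.05 at execution", {
  n <- 10000
  L <- make_grid_landscape(100, 100, ages = rep(120, n), adjacency = FALSE,
                           owner = "juridical", intensity = "INT")
  cfg <- build_scenario("DEFb", cutprob_int = 1)
  set.seed(17)
  L1 <- run_year(L, cfg)
  expect_equal(sum(L1$events$event == "clearcut"), n)
  flipped <- mean(L1$stands$regen_mode != L$stands$regen_mode)
  expect_lt(abs(flipped - 0.05), 0.007)
  # with transition probability zero the composition is identical, ages 0
  set.seed(17)
  L2 <- run_year(L, build_scenario("DEFb", cutprob_int = 1, regen_flip = 0))
  expect_identical(L2$stands$regen_mode, L$stands$regen_mode)
  expect_equal(unname(stand_ages(L2)), rep(1, n))  # 0 at cut, +1 at year end
})

test_that("a regeneration flip copies the similar stand of the target mode", {
  st <- tibble::tibble(id = 1:2, area = 10000, cx = c(0, 500), cy = 0,
                       unit = c(1L, 2L), zone = "unrestricted", site = "mineral",
                       regen_mode = c("natural", "planted"),
                       similar_planted = c(2L, NA), similar_natural = c(NA, 1L))
  L <- new_landscape(st, tibble::tibble(id = 1:2, owner_type = "juridical",
                                        intensity = "INT"),
                     upper = tibble::tibble(stand = 1:2,
                                            species = c("pine", "spruce"),
                                            share = 1, age = c(120, 10)))
  cfg <- build_scenario("DEFb", cutprob_int = 1, regen_flip = 1)
  set.seed(1)
  L1 <- run_year(L, cfg)
  expect_identical(L1$stands$regen_mode[1], "planted")
  expect_identical(L1$upper$species[L1$upper$stand == 1], "spruce")
  expect_equal(L1$upper$age[L1$upper$stand == 1], 1)  # reset, then aged
})

test_that("state harvest processes the largest willing cluster first, under the quota", {
  # two spatial clusters of mature state stands: 9 ha total vs 4 ha total
  st <- tibble::tibble(
    id = 1:5, area = c(30000, 30000, 30000, 20000, 20000),
    cx = c(0, 300, 600, 9000, 9300), cy = 0,
    unit = 1L, zone = "unrestricted", site = "mineral")
  mk <- function(quota) {
    L <- new_landscape(st, tibble::tibble(id = 1L, owner_type = "state"),
                       upper = tibble::tibble(stand = 1:5, species = "pine",
                                              share = 1, age = 115))
    list(L = L, cfg = build_scenario("REAL", state_quota = quota))
  }
  z <- mk(quota = 120000000)
  set.seed(2)
  L1 <- state_forest_harvest(z$L, z$cfg)
  ev <- L1$events[L1$events$event == "clearcut", ]
  expect_identical(ev$stand_id[1:3], c(1L, 2L, 3L))  # 9 ha cluster first
  expect_setequal(ev$stand_id, 1:5)                  # quota far from binding
  # zero quota: no state cuts
  z0 <- mk(quota = 0)
  set.seed(2)
  L0 <- state_forest_harvest(z0$L, z0$cfg)
  expect_identical(nrow(L0$events), 0L)
  # a single eligible stand is cut exactly
  st1 <- st[1, ]
  Ls <- new_landscape(st1, tibble::tibble(id = 1L, owner_type = "state"),
                      upper = tibble::tibble(stand = 1L, species = "pine",
                                             share = 1, age = 115))
  set.seed(2)
  Ls1 <- state_forest_harvest(Ls, build_scenario("REAL"))
  expect_identical(Ls1$events$stand_id, 1L)
})

test_that("state eligibility honours the maturity offsets and HPI rule", {
  mk <- function(age, hpi) {
    st <- tibble::tibble(id = 1L, area = 30000, cx = 0, cy = 0, unit = 1L,
                         zone = "unrestricted", site = "mineral", hpi = hpi)
    new_landscape(st, tibble::tibble(id = 1L, owner_type = "state"),
                  upper = tibble::tibble(stand = 1L, species = "pine",
                                         share = 1, age = age))
  }
  cfg <- build_scenario("REAL")
  set.seed(1)
  # 9 years past maturity: below the 10-year state offset
  expect_identical(nrow(state_forest_harvest(mk(109, FALSE), cfg)$events), 0L)
  expect_identical(nrow(state_forest_harvest(mk(110, FALSE), cfg)$events), 1L)
  # HPI stands wait for 20 years past maturity
  expect_identical(nrow(state_forest_harvest(mk(115, TRUE), cfg)$events), 0L)
  expect_identical(nrow(state_forest_harvest(mk(120, TRUE), cfg)$events), 1L)
})

test_that("sequential permitting lets only one of two adjacent over-limit stands go", {
  # two adjacent 4 ha general stands in one willing unit: either alone is
  # fine, together they would form an 8 ha > 7 ha cutover
  L <- make_grid_landscape(2, 1, ages = c(120, 120), cell = 200,
                           units_per_stand = FALSE, owner = "juridical")
  cfg <- build_scenario("REAL", cutprob_int = 1)
  set.seed(3)
  L1 <- run_year(L, cfg)
  cuts <- L1$events[L1$events$event == "clearcut", ]
  expect_identical(nrow(cuts), 1L)
  expect_identical(L1$counters$denied_adjacency, 1L)
  # the other follows once the first stops counting as a clear-cut
  for (i in 1:6) L1 <- run_year(L1, cfg)
  expect_identical(nrow(L1$events[L1$events$event == "clearcut", ]), 2L)
})

test_that("a year with zero willingness only ages the landscape", {
  L <- make_grid_landscape(3, 1, ages = c(30, 40, 50))
  cfg <- build_scenario("DEFb")
  set.seed(5)
  L1 <- run_year(L, cfg)
  expect_identical(nrow(L1$events), 0L)
  expect_equal(stand_ages(L1), c(31, 41, 51))
  expect_identical(L1$year, L$year + 1L)
})

test_that("identical seeds give identical years; different seeds differ", {
  L <- generate_landscape(synth_params(n_stands = 300, seed = 44))
  cfg <- build_scenario("REAL")
  set.seed(5); A <- run_year(L, cfg)
  set.seed(5); B <- run_year(L, cfg)
  expect_identical(A, B)
  set.seed(6); C <- run_year(L, cfg)
  expect_false(identical(A$events, C$events))
})
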