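test_that("world generation is deterministic for a fixed config", {
  cfg <- world_config(1, 2, c(80L, 120L), seed = 3)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$zones, w2$zones)
  expect_identical(w1$zone_marginals, w2$zone_marginals)
  expect_identical(w1$buildings, w2$buildings)
  expect_identical(w1$truth$persons, w2$truth$persons)
})

test_that("all world aggregates are mutually consistent", {
  w <- tw()
  # zone marginals sum to zone populations
  zm_tot <- tapply(w$zone_marginals$count, w$zone_marginals$zone_id, sum)
  expect_equal(as.integer(zm_tot[w$zones$zone_id]), w$zones$population)
  # municipal cross-tab sums to the municipal population
  expect_identical(sum(w$crosstab$count), sum(w$zones$population))
  # grid cell populations sum to zone populations
  g_tot <- tapply(w$grid$population, w$grid$zone_id, sum)
  expect_equal(as.integer(g_tot[w$zones$zone_id]), w$zones$population)
  # household-type counts match the latent truth
  tt <- table(w$truth$households$zone_id, w$truth$households$type)
  expect_equal(w$zones$hh_couple,
               as.integer(tt[w$zones$zone_id, "couple"]))
  expect_equal(w$zones$hh_single,
               as.integer(tt[w$zones$zone_id, "single"]))
  # employee/student/car controls match the truth
  expect_identical(sum(w$zones$n_employees), sum(w$truth$persons$employment))
  expect_identical(sum(w$zones$n_students), sum(w$truth$persons$studenthood))
  expect_identical(sum(w$zones$n_cars), sum(w$truth$households$n_cars))
  # income counts partition the population
  expect_identical(sum(w$income_counts$count), sum(w$zones$population))
})

test_that("configuration validation rejects bad settings", {
  expect_error(world_config(n_municipalities = 0), class = "actipop_config_error")
  expect_error(world_config(persons_per_zone_range = c(100L, 50L)),
               class = "actipop_config_error")
  expect_error(world_config(building_density = c(workplace = 5L)),
               class = "actipop_config_error")
  expect_error(behaviour_params(p_work = c(employed = 1.5, nonemployed = 0)),
               class = "actipop_config_error")
  expect_error(behaviour_params(gravity_beta = list(
    W = c(Car = -1, CarPassenger = 1, PublicTransport = 1, Bike = 1, Walking = 1),
    S = c(Car = 1, CarPassenger = 1, PublicTransport = 1, Bike = 1, Walking = 1),
    O = c(Car = 1, CarPassenger = 1, PublicTransport = 1, Bike = 1, Walking = 1))),
    class = "actipop_config_error")
})

test_that("survey diaries respect the stated duration distributions", {
  s <- tsurv()
  di <- s$diary
  durs <- di$end_h - di$start_h
  w_tot <- tapply(durs[di$purpose == "W"], di$respondent_id[di$purpose == "W"], sum)
  # work durations are truncated normal(8, 1) on [2, 12]
  expect_true(all(w_tot >= 2 & w_tot <= 12))
  expect_lt(abs(mean(w_tot) - 8), 3 * 1 / sqrt(length(w_tot)))
  # every diary closes the 24 h day: episode time + travel time = 24
  tot <- tapply(durs, di$respondent_id, sum)
  expect_true(all(tot <= 24 + 1e-9))
  # purposes limited to the four activity types, first/last episode is home
  expect_true(all(di$purpose %in% c("H", "W", "S", "O")))
  first <- di[!duplicated(di$respondent_id), ]
  expect_true(all(first$purpose == "H"))
})

test_that("degenerate participation probabilities are honoured", {
  w <- generate_world(world_config(1, 2, c(80L, 120L), seed = 5))
  p <- behaviour_params(p_work = c(employed = 1, nonemployed = 0),
                        p_school = c(student = 0, nonstudent = 0),
                        p_other = 0)
  s <- generate_survey(w, 150, params = p, seed = 6)
  sets <- tapply(s$diary$purpose, s$diary$respondent_id,
                 function(v) paste(sort(unique(v)), collapse = ""))
  emp <- s$persons$employment[match(as.integer(names(sets)),
                                    s$persons$respondent_id)]
  expect_true(all(sets[emp == 1] == "HW"))
  expect_true(all(sets[emp == 0] == "H"))
})

test_that("survey rejects a non-positive respondent count", {
  expect_error(generate_survey(tw(), 0), class = "actipop_config_error")
})

test_that("attraction masses sum building footprints by usage", {
  b <- data.frame(building_id = 1:4,
                  usage_type = c("workplace", "workplace", "school", "other"),
                  x = 0, y = 0, footprint_area = c(10, 20, 5, 7),
                  zone_id = c("A", "B", "A", "A"))
  m <- attraction_masses(b, c("A", "B"))
  expect_equal(m$W, c(A = 10, B = 20))
  expect_equal(m$S, c(A = 5, B = 0))
  expect_equal(m$O, c(A = 7, B = 0))
})

test_that("OD matrices are mass-conserving gravity expectations", {
  w <- tw()
  od <- generate_od_matrices(w)
  expect_true(all(od$flow >= 0))
  # every (purpose, mode) slice totals one trip per inhabitant
  sl <- tapply(od$flow, paste(od$purpose, od$mode), sum)
  expect_true(all(abs(sl - sum(w$zones$population)) < 1e-6))
  # no CarPassenger slice (regional models carry network modes only)
  expect_false("CarPassenger" %in% od$mode)
  # origin totals are proportional to zone population
  work_car <- od[od$purpose == "work" & od$mode == "Car", ]
  o_tot <- tapply(work_car$flow, work_car$origin, sum)[w$zones$zone_id]
  expect_equal(as.numeric(o_tot / sum(o_tot)),
               w$zones$population / sum(w$zones$population),
               tolerance = 1e-9)
})

test_that("OD destination shares approach attraction shares as beta -> 0", {
  w <- tw()
  eps <- 1e-8
  p <- behaviour_params(gravity_beta = list(
    W = c(Car = eps, CarPassenger = eps, PublicTransport = eps,
          Bike = eps, Walking = eps),
    S = c(Car = eps, CarPassenger = eps, PublicTransport = eps,
          Bike = eps, Walking = eps),
    O = c(Car = eps, CarPassenger = eps, PublicTransport = eps,
          Bike = eps, Walking = eps)))
  od <- generate_od_matrices(w, params = p)
  work_car <- od[od$purpose == "work" & od$mode == "Car", ]
  one_o <- work_car[work_car$origin == w$zones$zone_id[1], ]
  m <- attraction_masses(w$buildings, w$zones$zone_id)$W
  expect_equal(one_o$flow[match(w$zones$zone_id, one_o$destination)] /
                 sum(one_o$flow),
               as.numeric(m / sum(m)), tolerance = 1e-4)
})
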