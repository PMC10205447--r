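test_that("virtual zone weights follow grid population shares", {
  zones <- data.frame(zone_id = c("A", "B"))
  grid <- data.frame(cell_id = c("c1", "c2", "c3", "c4"),
                     zone_id = c("A", "A", "B", "B"),
                     x0 = c(0, 1000, 0, 1000), y0 = 0, size = 1000,
                     population = c(75, 25, 0, 0))
  expect_warning(vz <- build_virtual_zones(zones, grid),
                 class = "actipop_data_warning")
  expect_equal(vz$population_weight[vz$zone_id == "A"], c(0.75, 0.25))
  # zero-population zone falls back to uniform weights
  expect_equal(vz$population_weight[vz$zone_id == "B"], c(0.5, 0.5))
})

test_that("home placement assigns residential buildings or errors", {
  w <- tw()
  vz <- build_virtual_zones(w$zones, w$grid)
  hh <- data.frame(HId = 1:20, size = rep(1:4, 5),
                   zone_id = w$zones$zone_id[1])
  out <- assign_home_buildings(hh, vz, w$buildings, seed = 1)
  expect_false(any(is.na(out$building_id)))
  bt <- w$buildings$usage_type[match(out$building_id, w$buildings$building_id)]
  expect_true(all(bt %in% c("detached_house", "apartment")))
  bz <- w$buildings$zone_id[match(out$building_id, w$buildings$building_id)]
  expect_true(all(bz == w$zones$zone_id[1]))
  # a zone with no residential stock is a placement error
  no_res <- w$buildings[w$buildings$usage_type == "workplace", ]
  expect_error(assign_home_buildings(hh, vz, no_res),
               class = "actipop_placement_error")
})

test_that("gravity fitting matches observed mean distances", {
  w <- tw()
  masses <- attraction_masses(w$buildings, w$zones$zone_id)
  fit <- suppressWarnings(fit_gravity(tsurv()$trips, w$zones, masses))
  expect_s3_class(fit, "gravity_fit")
  expect_true(all(fit$beta > 0))
  expect_true(all(abs(fit$residual) < 1e-6))
  expect_true(all(fit$n_trips >= 20))
  # every purpose also carries the pooled-mode fallback row
  expect_true(all(c("W", "O") %in% fit$purpose[fit$mode == "(all)"]))
})

test_that("an unreachable observed mean raises a fit error", {
  w <- tw()
  masses <- attraction_masses(w$buildings, w$zones$zone_id)
  trips <- data.frame(purpose = "W", mode = "Car",
                      origin_zone = w$zones$zone_id[1],
                      distance_km = 100)[rep(1, 30), ]
  expect_error(suppressWarnings(fit_gravity(trips, w$zones, masses)),
               class = "actipop_fit_error")
})

test_that("OD probabilities are normalized and honour precedence", {
  w <- tw()
  masses <- attraction_masses(w$buildings, w$zones$zone_id)
  gravity <- suppressWarnings(fit_gravity(tsurv()$trips, w$zones, masses))
  ids <- w$zones$zone_id
  od <- data.frame(origin = rep(ids[1:2], each = 2),
                   destination = rep(ids[1:2], 2),
                   mode = "Car", purpose = "work",
                   flow = c(10, 30, 5, 5))
  # pad the remaining origins so no OD row is empty
  pad <- expand.grid(origin = ids[3:4], destination = ids,
                     stringsAsFactors = FALSE)
  pad$mode <- "Car"; pad$purpose <- "work"; pad$flow <- 1
  probs <- build_od_probabilities(w$zones, masses, od = rbind(od, pad),
                                  gravity = gravity)
  for (k in names(probs)) {
    expect_equal(unname(rowSums(probs[[k]])), rep(1, length(ids)))
  }
  # supplied OD takes precedence over gravity for (W, Car)
  expect_equal(unname(probs[["W|Car"]][ids[1], ids[1:2]]), c(0.25, 0.75))
  src <- attr(probs, "source")
  expect_identical(src$source[src$key == "W|Car"], "od")
  # school destinations always come from gravity
  expect_true(all(grepl("gravity", src$source[grepl("^S\\|", src$key)])))
})

test_that("an all-zero OD origin row is a data error", {
  w <- tw()
  masses <- attraction_masses(w$buildings, w$zones$zone_id)
  ids <- w$zones$zone_id
  od <- expand.grid(origin = ids, destination = ids, stringsAsFactors = FALSE)
  od$mode <- "Car"; od$purpose <- "work"
  od$flow <- ifelse(od$origin == ids[2], 0, 1)
  expect_error(build_od_probabilities(w$zones, masses, od = od),
               class = "actipop_data_error")
})

test_that("a large deterrence rate concentrates probability on the nearest zone", {
  w <- tw()
  masses <- attraction_masses(w$buildings, w$zones$zone_id)
  gravity <- expand.grid(purpose = c("W", "S", "O"),
                         mode = MODES, stringsAsFactors = FALSE)
  gravity$beta <- 49
  gravity$residual <- 0
  gravity$n_trips <- 100L
  probs <- build_od_probabilities(w$zones, masses, gravity = gravity)
  dmat <- as.matrix(dist(cbind(w$zones$centroid_x, w$zones$centroid_y))) / 1000
  P <- probs[["W|Car"]]
  for (i in seq_along(w$zones$zone_id)) {
    expect_identical(unname(which.max(P[i, ])), unname(which.min(dmat[i, ])))
    expect_gt(max(P[i, ]), 0.999)
  }
})

test_that("tour modes follow the model and the car constraint", {
  persons <- data.frame(PId = 1:40, HId = 1:40)
  hh <- data.frame(HId = 1:40, n_cars = rep(c(0L, 2L), 20))
  sch <- data.frame(PId = rep(1:40, each = 3), activity_id = rep(1:3, 40),
                    purpose = rep(c("H", "W", "H"), 40),
                    gap_after = 0.5)
  # degenerate model: everyone bikes
  bike <- choice_model_constant(c(Bike = 1))
  out <- assign_modes(persons, hh, sch, bike, seed = 1)
  expect_true(all(is.na(out$mode[out$activity_id == 1])))
  expect_true(all(out$mode[out$activity_id > 1] == "Bike"))
  # carless households never draw Car
  half <- choice_model_constant(c(Car = 0.5, Walking = 0.5))
  out2 <- assign_modes(persons, hh, sch, half, seed = 2)
  carless <- persons$PId[hh$n_cars[match(persons$HId, hh$HId)] == 0]
  expect_false(any(out2$mode[out2$PId %in% carless] == "Car", na.rm = TRUE))
})

test_that("travel-time quantiles steer destination distance", {
  w <- tw()
  masses <- attraction_masses(w$buildings, w$zones$zone_id)
  gravity <- suppressWarnings(fit_gravity(tsurv()$trips, w$zones, masses))
  probs <- build_od_probabilities(w$zones, masses, gravity = gravity)
  home_z <- w$zones$zone_id[1]
  res_b <- w$buildings[w$buildings$zone_id == home_z &
                         w$buildings$usage_type == "apartment", ]
  persons <- data.frame(PId = 1:2, HId = 1:2, zone = home_z)
  hh <- data.frame(HId = 1:2, building_id = res_b$building_id[1])
  sch <- data.frame(PId = rep(1:2, each = 2), activity_id = rep(1:2, 2),
                    purpose = rep(c("H", "W"), 2),
                    start_h = 0, end_h = 12,
                    gap_after = c(0.2, NA, 2, NA),
                    mode = c(NA, "Car", NA, "Car"))
  out <- assign_zones_and_buildings(persons, hh, sch, probs, w, seed = 1)
  dmat <- as.matrix(dist(cbind(w$zones$centroid_x, w$zones$centroid_y))) / 1000
  oi <- match(home_z, w$zones$zone_id)
  d1 <- dmat[oi, match(out$zone[out$PId == 1 & out$activity_id == 2],
                       w$zones$zone_id)]
  d2 <- dmat[oi, match(out$zone[out$PId == 2 & out$activity_id == 2],
                       w$zones$zone_id)]
  # shorter travel time never maps to a farther zone
  expect_lte(d1, d2)
  # the top-quantile agent lands in the farthest zone
  expect_equal(d2, max(dmat[oi, ]))
  # work activities take place in workplaces
  expect_true(all(out$building_type[out$purpose == "W"] == "workplace"))
})

test_that("located schedules are complete and home-consistent", {
  loc <- tw_loc()
  sch <- loc$schedules
  expect_false(any(is.na(sch$zone)))
  expect_false(any(is.na(sch$building_id)))
  expect_false(any(is.na(sch$x)) || any(is.na(sch$y)))
  # all home episodes of one agent share one building
  hb <- tapply(sch$building_id[sch$purpose == "H"],
               sch$PId[sch$purpose == "H"],
               function(v) length(unique(v)))
  expect_true(all(hb == 1L))
  # coordinates lie inside the assigned zone
  w <- tw()
  zi <- match(sch$zone, w$zones$zone_id)
  expect_true(all(sch$x >= w$zones$x0[zi] & sch$x <= w$zones$x1[zi] |
                    sch$relocated))
  expect_true(all(sch$y >= w$zones$y0[zi] & sch$y <= w$zones$y1[zi] |
                    sch$relocated))
})
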