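test_that("js_distance matches its closed form and bounds", {
  expect_identical(js_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_distance(c(1, 0), c(0, 1)), 1)
  # direct formula oracle on hand-built vectors
  p <- c(1, 0); q <- c(0.5, 0.5)
  expect_lt(abs(js_distance(p, q) - oracle_js(p, q)), 1e-12)
  p2 <- c(0.2, 0.5, 0.3); q2 <- c(0.6, 0.1, 0.3)
  expect_lt(abs(js_distance(p2, q2) - oracle_js(p2, q2)), 1e-12)
  expect_true(js_distance(p2, q2) >= 0 && js_distance(p2, q2) <= 1)
  # symmetry
  expect_equal(js_distance(p2, q2), js_distance(q2, p2))
})

test_that("js_distance validates its inputs", {
  expect_error(js_distance(c(1, 0), c(0.5, 0.5, 0)),
               class = "actipop_input_error")
  expect_error(js_distance(c(1.2, -0.2), c(0.5, 0.5)),
               class = "actipop_input_error")
  expect_error(js_distance(c(0.7, 0.7), c(0.5, 0.5)),
               class = "actipop_input_error")
})

test_that("sample-based JS distance vanishes for identical samples", {
  x <- runif(500, 0, 24)
  expect_identical(js_distance_samples(x, x), 0)
  expect_gt(js_distance_samples(rep(2, 100), rep(20, 100)), 0.99)
})

test_that("marginal report is exact on a perfect population", {
  w <- tw()
  fh <- tw_synth()
  rep <- marginal_diff_report(fh$persons, w)
  g <- rep$detail[rep$detail$attribute == "gender", ]
  expect_true(all(g$pct_diff == 0))
  a <- rep$detail[rep$detail$attribute == "age_group", ]
  expect_true(all(a$pct_diff == 0))
  expect_equal(rep$summary$share_within_0.5[rep$summary$attribute == "gender"], 1)
  # one row per (zone, attribute, category)
  expect_identical(nrow(g), nrow(w$zones) * 2L)
  expect_false(any(duplicated(paste(rep$detail$zone_id, rep$detail$attribute,
                                    rep$detail$category))))
})

test_that("percentage differences are plain arithmetic; missing zones flagged", {
  w <- tw()
  fh <- tw_synth()
  p <- fh$persons
  # drop one male from zone 1 and the whole of zone 2
  z1 <- w$zones$zone_id[1]; z2 <- w$zones$zone_id[2]
  drop1 <- which(p$zone == z1 & p$gender == "Male")[1]
  p2 <- p[-drop1, ]
  p2 <- p2[p2$zone != z2, ]
  rep <- marginal_diff_report(p2, w)
  tgt <- sum(w$zone_marginals$count[w$zone_marginals$zone_id == z1 &
                                      w$zone_marginals$gender == "Male"])
  row <- rep$detail[rep$detail$zone_id == z1 & rep$detail$attribute == "gender" &
                      rep$detail$category == "Male", ]
  expect_equal(row$pct_diff, -1 / tgt * 100)
  expect_true(all(rep$detail$missing[rep$detail$zone_id == z2]))
  expect_false(any(rep$detail$missing[rep$detail$zone_id == z1]))
})

test_that("the person table round-trips losslessly", {
  p <- data.frame(PId = 1:3, HId = c(1L, 1L, 2L),
                  gender = c("Male", "Female", "Female"),
                  age = c(40L, 38L, 9L),
                  marital_status = c("couple", "couple", "age<18"),
                  employment = c(1L, 0L, 0L), studenthood = c(0L, 1L, 1L),
                  income_class = c("High", "Low", "No"),
                  n_cars = c(2L, 2L, 2L), zone = "Z001",
                  municipality = "M01", stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".csv")
  write_person_table(p, f)
  hdr <- readLines(f, n = 1)
  expect_match(hdr, "\"Marital status\"", fixed = TRUE)
  expect_identical(read_person_table(f), p)
  # snake_case headers round-trip too
  write_person_table(p, f, snake_case = TRUE)
  expect_match(readLines(f, n = 1), "marital_status", fixed = TRUE)
  expect_identical(read_person_table(f), p)
  unlink(f)
})

test_that("person table vocabulary and columns are enforced", {
  p <- data.frame(PId = 1L, HId = 1L, gender = "Man", age = 30L,
                  marital_status = "single", employment = 0L,
                  studenthood = 0L, income_class = "Low", n_cars = 0L,
                  zone = "Z001", municipality = "M01")
  expect_error(write_person_table(p, tempfile()),
               class = "actipop_validation_error")
  f <- tempfile(fileext = ".csv")
  writeLines(c("PId,Gender", "1,Male"), f)
  expect_error(read_person_table(f), class = "actipop_validation_error")
  unlink(f)
})

test_that("the household table parses published-style rows", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("HId,Type,Size,Number of children,Number of cars",
               "1,couple,2,0,0"), f)
  hh <- read_household_table(f)
  expect_identical(hh$type, "couple")
  expect_identical(hh$size, 2L)
  expect_identical(hh$n_children_under6, 0L)
  expect_identical(hh$n_cars, 0L)
  # invalid size and type are validation errors
  writeLines(c("HId,Type,Size,Number of children,Number of cars",
               "1,couple,0,0,0"), f)
  expect_error(read_household_table(f), class = "actipop_validation_error")
  writeLines(c("HId,Type,Size,Number of children,Number of cars",
               "1,commune,3,0,0"), f)
  expect_error(read_household_table(f), class = "actipop_validation_error")
  unlink(f)
})

test_that("the activity table round-trips through clock time", {
  sch <- data.frame(PId = c(1L, 1L, 1L), activity_id = 1:3,
                    purpose = c("H", "W", "H"),
                    start_h = c(0, 8, 16.8), end_h = c(7.2, 16, 24),
                    mode = c(NA, "Car", "Car"),
                    building_id = c(11L, 12L, 11L),
                    building_type = c("apartment", "workplace", "apartment"),
                    x = c(100.5, 2000.1, 100.5), y = c(50.5, 900.9, 50.5),
                    zone = "Z001", stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".csv")
  write_activity_table(sch, f)
  raw <- read.csv(f, check.names = FALSE)
  # times serialize as clock hours with one decimal (3 AM day start)
  expect_identical(sprintf("%.1f", raw[["Activity Start Time"]]),
                   c("3.0", "11.0", "19.8"))
  expect_identical(raw[["Activity Purpose"]], c("Home", "Work", "Home"))
  expect_identical(raw[["Building Type"]],
                   c("Apartment", "Other", "Apartment"))
  back <- read_activity_table(f)
  expect_equal(back$start_h, sch$start_h, tolerance = 1e-9)
  expect_equal(back$end_h, sch$end_h, tolerance = 1e-9)
  expect_identical(back$purpose, sch$purpose)
  expect_identical(back$mode, sch$mode)
  expect_identical(back$building_id, sch$building_id)
  unlink(f)
})

test_that("activity vocabulary errors carry the offending row", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(paste("PId,Activity ID,Activity Purpose,Activity Start Time,",
                     "Activity End Time,Travel Mode,Building ID,Building Type,",
                     "Point X,Point Y,DeSO", sep = ""),
               "1,1,Gym,3.0,11.0,Car,5,Apartment,1.0,2.0,Z001"), f)
  err <- tryCatch(read_activity_table(f), error = identity)
  expect_s3_class(err, "actipop_validation_error")
  expect_match(conditionMessage(err), "Gym")
  expect_match(conditionMessage(err), "row 1")
  unlink(f)
})

test_that("world, survey, and OD files round-trip", {
  w <- tw()
  d <- file.path(tempdir(), "world_rt")
  write_world(w, d)
  w2 <- read_world(d, w$config)
  expect_equal(w2$zones, w$zones)
  expect_equal(w2$zone_marginals, w$zone_marginals)
  expect_equal(w2$crosstab[order(w2$crosstab$gender, w2$crosstab$age_group,
                                 w2$crosstab$civil_status), "count"],
               w$crosstab[order(w$crosstab$gender, w$crosstab$age_group,
                                w$crosstab$civil_status), "count"])
  expect_equal(w2$buildings, w$buildings)
  expect_equal(w2$params$gravity_beta, w$params$gravity_beta)

  s <- tsurv()
  write_survey(s, d)
  s2 <- read_survey(d, params = s$params)
  expect_equal(s2$persons, s$persons)
  expect_equal(s2$diary$start_h, s$diary$start_h, tolerance = 1e-3)
  expect_equal(s2$diary$end_h, s$diary$end_h, tolerance = 1e-3)
  expect_identical(s2$diary$purpose, s$diary$purpose)
  expect_equal(s2$trips, s$trips)

  od <- generate_od_matrices(w)
  f <- file.path(d, "od.csv")
  write_od(od, f)
  od2 <- read_od(f)
  expect_equal(od2$flow, od$flow, tolerance = 1e-9)
  bad <- od; bad$flow[1] <- -1
  write.csv(as.data.frame(bad), f, row.names = FALSE)
  expect_error(read_od(f), class = "actipop_validation_error")
  unlink(d, recursive = TRUE)
})
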