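# Minimal hand-built survey: two respondents per participation set with
# known duration tuples, for exact matching tests.
fake_survey <- function(persons, diary) {
  structure(list(persons = persons, diary = diary,
                 trips = data.frame(), params = NULL),
            class = "actipop_survey")
}

diary_rows <- function(id, purposes, durations) {
  ends <- cumsum(durations)
  data.frame(respondent_id = id, episode = seq_along(purposes),
             purpose = purposes, start_h = ends - durations, end_h = ends,
             access_mode = NA_character_, stringsAsFactors = FALSE)
}

test_that("participation sets are the eight home-anchored subsets", {
  s <- participation_sets()
  expect_length(s, 8L)
  expect_true(all(substr(s, 1, 1) == "H"))
  expect_true(all(c("H", "HW", "HS", "HO", "HWS", "HWO", "HSO", "HWSO") %in% s))
})

test_that("participation assignment rejects non home-anchored models", {
  m <- choice_model_constant(c(WS = 1))
  expect_error(assign_participation(data.frame(x = 1), m),
               class = "actipop_input_error")
  ok <- choice_model_constant(c(HW = 0.5, H = 0.5))
  out <- assign_participation(data.frame(x = 1:50), ok, seed = 1)
  expect_true(all(out %in% c("HW", "H")))
})

test_that("duration/travel-time classes respect the participation set", {
  dcm <- build_duration_class_model(tsurv())
  part <- c("H", "HW", "HWO", "HWSO")
  cl <- assign_duration_and_traveltime_classes(part, dcm, seed = 1)
  expect_identical(cl$set, part)
  # classes exist exactly for the participating types
  expect_true(is.na(cl$class_W[1]) && !is.na(cl$class_H[2]))
  expect_true(!is.na(cl$class_W[2]) && is.na(cl$class_S[2]))
  # home-only days have zero travel time
  expect_identical(cl$tt_lower[1], 0)
  expect_identical(cl$tt_upper[1], 0)
  # travel-time bounds come from the class breaks
  expect_true(all(cl$tt_lower %in% c(0, 0.5, 1, 2)))
  expect_true(all(cl$tt_upper %in% c(0, 0.5, 1, 2, 4)))
})

test_that("sampled durations satisfy the daily time budget", {
  dcm <- build_duration_class_model(tsurv())
  part <- rep(c("HW", "HO", "HWO", "H"), each = 50)
  cl <- assign_duration_and_traveltime_classes(part, dcm, seed = 2)
  du <- sample_durations(cl, dcm, seed = 3)
  tot <- du$t_H + du$t_W + du$t_S + du$t_O
  lo <- 24 - cl$tt_upper
  hi <- 24 - cl$tt_lower
  non_home <- part != "H"
  expect_true(all(tot[non_home & !du$fallback] >= lo[non_home & !du$fallback]))
  expect_true(all(tot[non_home & !du$fallback] < hi[non_home & !du$fallback]))
  expect_true(all(tot[!non_home] == 24))
  # absent types get zero duration
  expect_true(all(du$t_S[part %in% c("HW", "HO", "HWO", "H")] == 0))
  expect_true(all(du$t_W[part == "HO"] == 0))
})

test_that("sequence matching minimizes duration distance with id tie-break", {
  persons <- data.frame(respondent_id = 1:3, gender = "Male", age = 30,
                        employment = 1L, studenthood = 0L,
                        stringsAsFactors = FALSE)
  diary <- rbind(diary_rows(1L, c("H", "W", "H"), c(7, 8, 7)),   # (H=14, W=8)
                 diary_rows(2L, c("H", "W", "H"), c(5, 3, 5)),   # (H=10, W=3)
                 diary_rows(3L, c("H", "W", "H"), c(7, 8, 7)))   # = donor 1
  s <- fake_survey(persons, diary)
  q <- data.frame(gender = "Male", age = 30, employment = 1L, studenthood = 0L)
  # distance to donor 1: sqrt(1 + 1) = sqrt(2); to donor 2: sqrt(25 + 36)
  du <- data.frame(t_H = 15, t_W = 9, t_S = 0, t_O = 0)
  m <- match_sequence(q, "HW", du, s)
  expect_identical(m$donor_id, 1L)          # donor 3 is identical: lower id wins
  expect_identical(m$sequences[[1]], c("H", "W", "H"))
  expect_false(m$fallback)
})

test_that("attribute filters relax from the last criterion, gender kept", {
  persons <- data.frame(respondent_id = 1:2,
                        gender = c("Male", "Female"), age = c(30, 30),
                        employment = c(1L, 1L), studenthood = c(0L, 0L),
                        stringsAsFactors = FALSE)
  diary <- rbind(diary_rows(1L, c("H", "W", "H"), c(7, 8, 7)),
                 diary_rows(2L, c("H", "W", "H"), c(5, 10, 5)))
  s <- fake_survey(persons, diary)
  # male, 70, not employed: no donor matches all filters, but relaxing down
  # to gender alone keeps donor 1 only -- even though donor 2's durations
  # are closer to the query
  q <- data.frame(gender = "Male", age = 70, employment = 0L, studenthood = 0L)
  du <- data.frame(t_H = 10, t_W = 10, t_S = 0, t_O = 0)
  m <- match_sequence(q, "HW", du, s)
  expect_identical(m$donor_id, 1L)
})

test_that("a donorless participation set falls back to a canonical sequence", {
  persons <- data.frame(respondent_id = 1L, gender = "Male", age = 30,
                        employment = 1L, studenthood = 0L)
  s <- fake_survey(persons, diary_rows(1L, c("H", "W", "H"), c(7, 8, 7)))
  q <- data.frame(gender = "Male", age = 30, employment = 1L, studenthood = 0L)
  du <- data.frame(t_H = 12, t_W = 0, t_S = 6, t_O = 0)
  m <- match_sequence(q, "HS", du, s)
  expect_true(m$fallback)
  expect_identical(m$sequences[[1]], c("H", "S", "H"))
  expect_true(is.na(m$donor_id))
})

test_that("schedule construction reproduces the worked example", {
  # H-W-H day, 8 h work, 14.5 h home, travel-time class (1, 2] h:
  # travel = 24 - 22.5 = 1.5 h split over two gaps of 0.75 h; the home stay
  # splits into two 7.25 h halves around the 3 AM boundary
  sch <- anchor_and_build_schedule(c("H", "W", "H"),
                                   c(H = 14.5, W = 8, S = 0, O = 0),
                                   c(1, 2))
  expect_equal(sch$start_h, c(0, 8, 16.75))
  expect_equal(sch$end_h, c(7.25, 16, 24))
  expect_equal(sch$gap_after, c(0.75, 0.75, NA))
  # in clock hours: day starts at 3.0, work runs 11.0-19.0
  expect_equal(clock_from_internal(sch$start_h), c(3, 11, 19.75))
  expect_equal(clock_from_internal(sch$end_h[2]), 19)
})

test_that("schedules tile the day and split instances equally", {
  sch <- anchor_and_build_schedule(c("H", "W", "O", "H"),
                                   c(H = 13, W = 8, S = 0, O = 2), c(0.5, 1))
  expect_equal(sch$end_h[4], 24)
  expect_equal(sum(sch$end_h - sch$start_h) + sum(sch$gap_after, na.rm = TRUE),
               24)
  durs <- sch$end_h - sch$start_h
  expect_equal(durs[1], durs[4])                       # equal H halves
  # an anchor model reapportions the boundary-spanning halves only
  sch2 <- anchor_and_build_schedule(c("H", "W", "H"),
                                    c(H = 14, W = 8, S = 0, O = 0), c(1, 2),
                                    anchor_model = function(type, slot) 5)
  d2 <- sch2$end_h - sch2$start_h
  expect_equal(d2[1], 5)
  expect_equal(d2[3], 9)
  expect_equal(d2[1] + d2[3], 14)
})

test_that("degenerate schedules behave", {
  one <- anchor_and_build_schedule("H", c(H = 24, W = 0, S = 0, O = 0), c(0, 0))
  expect_identical(nrow(one), 1L)
  expect_equal(one$end_h - one$start_h, 24)
  expect_error(anchor_and_build_schedule(c("H", "W"),
                                         c(H = 12, W = 10, S = 0, O = 0),
                                         c(1, 2)),
               class = "actipop_input_error")
})

test_that("generated schedules are internally consistent at scale", {
  res <- tw_acts()
  sch <- res$schedules
  # per-person tiling of the 24 h day
  tile <- tapply(seq_len(nrow(sch)), sch$PId, function(ii) {
    sum(sch$end_h[ii] - sch$start_h[ii]) + sum(sch$gap_after[ii], na.rm = TRUE)
  })
  expect_true(all(abs(tile - 24) < 1e-9))
  # episode totals equal the sampled per-type durations
  for (a in c("H", "W")) {
    per <- tapply(sch$end_h[sch$purpose == a] - sch$start_h[sch$purpose == a],
                  sch$PId[sch$purpose == a], sum)
    want <- res$durations[[paste0("t_", a)]][
      match(as.integer(names(per)), tw_attr()$persons$PId)]
    expect_true(all(abs(per - want) < 1e-9))
  }
  # first and last episode of every person is home
  firsts <- sch[!duplicated(sch$PId), ]
  lasts <- sch[!duplicated(sch$PId, fromLast = TRUE), ]
  expect_true(all(firsts$purpose == "H"))
  expect_true(all(lasts$purpose == "H"))
})
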