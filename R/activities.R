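# Stage 2: daily activity schedules.
#
# Internal timeline: hours since 3 AM, in [0, 24). The day starts and ends
# at 3 AM (the time with the fewest people in motion), so the first and last
# entries of a sequence are the two halves of the episode spanning the day
# boundary. Serialization converts to clock hours.

TT_CLASS_BREAKS <- c(0, 0.5, 1, 2, 4)
DUR_CLASS_LEVELS <- c("low", "moderate", "high")

clock_from_internal <- function(h) (h + 3) %% 24
internal_from_clock <- function(h) (h - 3) %% 24

#' Participation sets containing home
#' @return Character vector of the 8 subsets of {H, W, S, O} containing H.
#' @export
participation_sets <- function() .participation_sets()

# Participation-set label for a diary's purposes.
.diary_set <- function(purposes) {
  .set_label("W" %in% purposes, "S" %in% purposes, "O" %in% purposes)
}

#' Train the activity-participation model from a survey
#'
#' A choice model over the 8 home-containing participation subsets,
#' conditioned on socio-demographics.
#' @param survey An `actipop_survey`.
#' @param seed Integer seed.
#' @return A `choice_model`.
#' @export
train_participation_model <- function(survey, seed = 1L) {
  sets <- tapply(survey$diary$purpose, survey$diary$respondent_id, .diary_set)
  df <- survey$persons
  df$set <- as.character(sets[as.character(df$respondent_id)])
  train_choice_model(df, c("age", "gender", "employment", "studenthood"),
                     "set", seed = seed)
}

#' Assign activity participation sets
#'
#' Samples one home-containing subset of {H, W, S, O} per person from the
#' choice model. Home membership is guaranteed by the choice set itself.
#'
#' @param persons Completed persons data.frame.
#' @param model A `choice_model` whose choice set is a subset of
#'   [participation_sets()].
#' @param seed Integer seed.
#' @return Character vector of participation-set labels (e.g. `"HWO"`).
#' @export
assign_participation <- function(persons, model, seed = NULL) {
  bad <- setdiff(model$choice_set, participation_sets())
  if (length(bad)) {
    stopf("model choice set contains non home-anchored sets: %s",
          paste(bad, collapse = ", "), class = "actipop_input_error")
  }
  P <- predict_probs(model, persons)
  with_seed(seed, model$choice_set[sample_rows(P)])
}

# ---- duration & travel-time classes ----------------------------------------

# Empirical per-type duration tertiles and the survey's joint distribution of
# (duration-class combination, travel-time class) per participation set.
#' Build the duration/travel-time class sampler from a survey
#'
#' Duration classes (low / moderate / high) are the empirical tertiles of
#' the survey's per-type activity durations. For every participation set the
#' joint distribution of the per-type class combination and the travel-time
#' class is tabulated, preserving cross-type correlation.
#'
#' @param survey An `actipop_survey`.
#' @return A list of class `duration_class_model` with the tertile cutpoints,
#'   the per-set joint tables, and per-(type, class) hourly histograms.
#' @export
build_duration_class_model <- function(survey) {
  di <- survey$diary
  durs <- di$end_h - di$start_h
  # total duration per respondent per type
  key <- paste(di$respondent_id, di$purpose)
  tot <- tapply(durs, key, sum)
  rid <- as.integer(sub(" .*", "", names(tot)))
  typ <- sub(".* ", "", names(tot))
  cut_points <- lapply(ACTIVITY_TYPES, function(a) {
    v <- tot[typ == a]
    if (length(v) < 3) return(c(-Inf, Inf))
    stats::quantile(v, c(1 / 3, 2 / 3), names = FALSE)
  })
  names(cut_points) <- ACTIVITY_TYPES
  class_of <- function(a, d) {
    DUR_CLASS_LEVELS[1L + (d > cut_points[[a]][1]) + (d > cut_points[[a]][2])]
  }

  # per-respondent: set label, class combo, travel-time class
  resp_ids <- unique(di$respondent_id)
  set_lab <- tapply(di$purpose, di$respondent_id, .diary_set)[as.character(resp_ids)]
  combos <- character(length(resp_ids))
  ttcls <- integer(length(resp_ids))
  tt_breaks <- TT_CLASS_BREAKS
  for (i in seq_along(resp_ids)) {
    r <- resp_ids[i]
    sel <- rid == r
    parts <- sort(typ[sel])
    combos[i] <- paste(vapply(parts, function(a) {
      paste0(a, ":", class_of(a, tot[rid == r & typ == a]))
    }, character(1)), collapse = "|")
    day_tt <- 24 - sum(tot[sel])
    ttcls[i] <- max(1L, findInterval(day_tt, tt_breaks, left.open = TRUE))
    ttcls[i] <- min(ttcls[i], length(tt_breaks) - 1L)
  }
  joint <- split(paste(combos, ttcls, sep = "@"), as.character(set_lab))
  joint <- lapply(joint, function(v) table(v) / length(v))

  # class-conditional hourly histograms (1 h bins) per activity type
  hist_tab <- list()
  for (a in ACTIVITY_TYPES) {
    v <- tot[typ == a]
    cl <- vapply(v, function(d) class_of(a, d), character(1))
    for (cc in DUR_CLASS_LEVELS) {
      h <- floor(pmin(v[cl == cc], 23.999))
      hist_tab[[paste(a, cc)]] <- table(factor(h, levels = 0:23))
    }
  }
  structure(list(cut_points = cut_points, joint = joint, hist = hist_tab,
                 tt_breaks = tt_breaks),
            class = "duration_class_model")
}

#' Assign duration classes and a travel-time class
#'
#' Draws, per person, one realization of the joint (per-type duration class
#' combination, travel-time range class) distribution learned from survey
#' respondents with the same participation set — a single categorical draw
#' over the combinations, preserving cross-type class correlation.
#'
#' @param participation Character vector of participation-set labels.
#' @param model A `duration_class_model`.
#' @param seed Integer seed.
#' @return data.frame with one row per person: `set`, per-type class columns
#'   `class_H` .. `class_O` (NA for absent types), `tt_lower`, `tt_upper`.
#' @export
assign_duration_and_traveltime_classes <- function(participation, model,
                                                   seed = NULL) {
  with_seed(seed, {
    n <- length(participation)
    out <- data.frame(set = participation,
                      class_H = NA_character_, class_W = NA_character_,
                      class_S = NA_character_, class_O = NA_character_,
                      tt_lower = NA_real_, tt_upper = NA_real_,
                      stringsAsFactors = FALSE)
    br <- model$tt_breaks
    for (s in unique(participation)) {
      ii <- which(participation == s)
      jt <- model$joint[[s]]
      if (is.null(jt)) {         # set unseen in the survey: flat fallback
        types <- strsplit(s, "")[[1]]
        combo <- paste(paste0(sort(types), ":moderate"), collapse = "|")
        draw <- rep(paste0(combo, "@2"), length(ii))
      } else {
        draw <- names(jt)[sample.int(length(jt), length(ii), replace = TRUE,
                                     prob = as.numeric(jt))]
      }
      combo <- sub("@.*", "", draw)
      tti <- as.integer(sub(".*@", "", draw))
      out$tt_lower[ii] <- br[tti]
      out$tt_upper[ii] <- br[tti + 1L]
      for (a in ACTIVITY_TYPES) {
        m <- regmatches(combo, regexpr(paste0(a, ":[a-z]+"), combo))
        has <- grepl(paste0(a, ":"), combo)
        cl <- rep(NA_character_, length(ii))
        cl[has] <- sub(".*:", "", m)
        out[[paste0("class_", a)]][ii] <- cl
      }
    }
    # stay-at-home days have zero travel by definition
    home_only <- participation == "H"
    out$tt_lower[home_only] <- 0
    out$tt_upper[home_only] <- 0
    out
  })
}

#' Sample activity durations under the daily time budget
#'
#' Draws each participating type's duration from its class-conditional
#' hourly histogram (1 h bins, uniform within the bin) and accepts the tuple
#' when total activity time lands in the feasible band
#' `24 - tt_upper <= sum(t) < 24 - tt_lower` implied by the travel-time
#' class. After `max_tries` rejections the last draw is rescaled
#' proportionally onto the midpoint of the band and flagged.
#'
#' @param classes data.frame from [assign_duration_and_traveltime_classes()].
#' @param model A `duration_class_model` (for the histograms).
#' @param max_tries Rejection budget per person.
#' @param seed Integer seed.
#' @return data.frame: `t_H`, `t_W`, `t_S`, `t_O` (hours; 0 for absent
#'   types), `fallback` (logical).
#' @export
sample_durations <- function(classes, model, max_tries = 100L, seed = NULL) {
  with_seed(seed, {
    n <- nrow(classes)
    res <- matrix(0, n, 4, dimnames = list(NULL, ACTIVITY_TYPES))
    fallback <- rep(FALSE, n)
    lo <- 24 - classes$tt_upper
    hi <- 24 - classes$tt_lower
    home_only <- classes$set == "H"
    res[home_only, "H"] <- 24

    pending <- which(!home_only)
    draw_one <- function(a, cl, k) {
      hist <- model$hist[[paste(a, cl)]]
      if (is.null(hist) || sum(hist) == 0) {
        return(stats::runif(k, 0.5, 10))     # no donors in this class: flat draw
      }
      bins <- sample.int(24, k, replace = TRUE, prob = as.numeric(hist)) - 1L
      bins + stats::runif(k)
    }
    tries <- 0L
    while (length(pending) && tries < max_tries) {
      tries <- tries + 1L
      for (a in ACTIVITY_TYPES) {
        cl <- classes[[paste0("class_", a)]][pending]
        for (cc in DUR_CLASS_LEVELS) {
          sel <- which(!is.na(cl) & cl == cc)
          if (length(sel)) {
            res[pending[sel], a] <- draw_one(a, cc, length(sel))
          }
        }
        res[pending[is.na(cl)], a] <- 0
      }
      tot <- rowSums(res[pending, , drop = FALSE])
      ok <- tot >= lo[pending] & tot < hi[pending]
      pending <- pending[!ok]
    }
    if (length(pending)) {                    # proportional-rescale fallback
      mid <- (lo[pending] + hi[pending]) / 2
      tot <- rowSums(res[pending, , drop = FALSE])
      res[pending, ] <- res[pending, , drop = FALSE] * (mid / tot)
      fallback[pending] <- TRUE
    }
    out <- as.data.frame(res)
    names(out) <- paste0("t_", ACTIVITY_TYPES)
    out$fallback <- fallback
    out
  })
}

# ---- sequence matching -----------------------------------------------------

# Donor summary used by match_sequence: one row per respondent with their
# participation set, duration tuple and socio-demographics.
.donor_table <- function(survey) {
  di <- survey$diary
  durs <- di$end_h - di$start_h
  key <- paste(di$respondent_id, di$purpose)
  tot <- tapply(durs, key, sum)
  rid <- as.integer(sub(" .*", "", names(tot)))
  typ <- sub(".* ", "", names(tot))
  ids <- sort(unique(di$respondent_id))
  D <- matrix(0, length(ids), 4, dimnames = list(NULL, ACTIVITY_TYPES))
  for (a in ACTIVITY_TYPES) {
    sel <- typ == a
    D[match(rid[sel], ids), a] <- tot[sel]
  }
  sets <- tapply(di$purpose, di$respondent_id, .diary_set)[as.character(ids)]
  sp <- survey$persons[match(ids, survey$persons$respondent_id), ]
  seqs <- split(di$purpose[order(di$respondent_id, di$episode)],
                di$respondent_id[order(di$respondent_id, di$episode)])
  list(ids = ids, durations = D, sets = as.character(sets),
       gender = sp$gender, age = sp$age,
       employment = sp$employment, studenthood = sp$studenthood,
       sequences = seqs[as.character(ids)])
}

CANONICAL_SEQUENCES <- list(
  H = c("H"),
  HW = c("H", "W", "H"), HS = c("H", "S", "H"), HO = c("H", "O", "H"),
  HWO = c("H", "W", "O", "H"), HWS = c("H", "W", "S", "H"),
  HSO = c("H", "S", "O", "H"), HWSO = c("H", "W", "S", "O", "H"))

#' Match donor activity sequences by socio-demographics and duration
#'
#' For each person: candidate donors are survey respondents with the same
#' participation set, filtered by agreement on gender, 10-year age band,
#' employment, and studenthood; filters are relaxed one at a time from the
#' last (studenthood first, gender last) until candidates remain. The winner
#' minimizes the Euclidean distance between activity-duration tuples
#' (`t_H`, `t_W`, `t_S`, `t_O`); ties break to the smallest respondent id,
#' and the winner's activity sequence is copied verbatim. Persons whose
#' participation set has no donor at all fall back to a canonical sequence
#' and are flagged.
#'
#' @param persons Persons data.frame (gender, age, employment, studenthood).
#' @param participation Participation-set labels per person.
#' @param durations data.frame from [sample_durations()].
#' @param survey An `actipop_survey`.
#' @return list with `sequences` (list of character vectors), `donor_id`
#'   (matched respondent id or NA), `fallback` (logical).
#' @export
match_sequence <- function(persons, participation, durations, survey) {
  if (!nrow(survey$persons)) {
    stopf("survey is empty", class = "actipop_input_error")
  }
  don <- .donor_table(survey)
  n <- nrow(persons)
  seqs <- vector("list", n)
  donor_id <- rep(NA_integer_, n)
  fallback <- rep(FALSE, n)
  A <- as.matrix(durations[, paste0("t_", ACTIVITY_TYPES)])
  p_band <- persons$age %/% 10L
  d_band <- don$age %/% 10L

  for (s in unique(participation)) {
    in_set <- which(don$sets == s)
    ppl <- which(participation == s)
    if (!length(in_set)) {
      for (i in ppl) {
        seqs[[i]] <- CANONICAL_SEQUENCES[[s]]
        fallback[i] <- TRUE
      }
      next
    }
    # group people by the attribute signature so the relaxation and the
    # candidate set are resolved once per group
    sig <- paste(persons$gender[ppl], p_band[ppl],
                 persons$employment[ppl], persons$studenthood[ppl])
    for (g in unique(sig)) {
      gi <- ppl[sig == g]
      one <- gi[1]
      crit <- list(
        gender = don$gender[in_set] == persons$gender[one],
        ageband = d_band[in_set] == p_band[one],
        employment = don$employment[in_set] == persons$employment[one],
        studenthood = don$studenthood[in_set] == persons$studenthood[one])
      for (keep in length(crit):0) {
        mask <- rep(TRUE, length(in_set))
        for (k in seq_len(keep)) mask <- mask & crit[[k]]
        if (any(mask)) break
      }
      cand <- in_set[mask]
      # order candidates by respondent id so which.min realizes the tie rule
      cand <- cand[order(don$ids[cand])]
      Dc <- don$durations[cand, , drop = FALSE]
      for (i in gi) {
        d2 <- colSums((t(Dc) - A[i, ])^2)
        w <- which.min(d2)
        donor_id[i] <- don$ids[cand[w]]
        seqs[[i]] <- as.character(don$sequences[[cand[w]]])
      }
    }
  }
  list(sequences = seqs, donor_id = donor_id, fallback = fallback)
}

# ---- schedule construction -------------------------------------------------

#' Build a timed daily schedule from a sequence and durations
#'
#' Each activity type's total duration is split equally among its instances
#' in the sequence (the first and last entries are the two halves of the
#' 3 AM-spanning episode and count as separate instances). The total travel
#' time, `24 - sum(durations)`, is split equally across the gaps between
#' consecutive episodes. Episodes tile the 3 AM-anchored day exactly: the
#' first starts at the day boundary and the last ends on it. An optional
#' anchor model reapportions the boundary-spanning type's duration between
#' its first and last instance.
#'
#' @param sequence Character vector over {H, W, S, O}; first and last entries
#'   must agree (the boundary-spanning type).
#' @param durations Named numeric `c(H=, W=, S=, O=)` total hours per type.
#' @param tt_class Numeric pair `c(lower, upper)`; the implied travel time
#'   must fall in `(lower, upper]` (guaranteed when the durations satisfy
#'   the daily time budget).
#' @param anchor_model Optional function `(type, slot_total)` returning the
#'   duration of the first (morning) instance; default splits equally.
#' @param seed Integer seed (used only by a stochastic anchor model).
#' @return data.frame of class `actipop_schedule`: `activity_id`, `purpose`,
#'   `start_h`, `end_h` (internal hours since 3 AM), `gap_after` (travel
#'   time following the episode, NA for the last).
#' @export
anchor_and_build_schedule <- function(sequence, durations, tt_class,
                                      anchor_model = NULL, seed = NULL) {
  m <- length(sequence)
  if (m > 1L && sequence[1] != sequence[m]) {
    stopf("sequence must start and end with the boundary-spanning type",
          class = "actipop_input_error")
  }
  tot <- sum(durations)
  tt <- 24 - tot
  if (m == 1L) {
    out <- data.frame(activity_id = 1L, purpose = sequence, start_h = 0,
                      end_h = 24, gap_after = NA_real_)
    class(out) <- c("actipop_schedule", "data.frame")
    return(out)
  }
  if (tt < -1e-9) {
    stopf("durations exceed the 24 h day by %.3f h", -tt,
          class = "actipop_feasibility_error")
  }
  counts <- table(factor(sequence, levels = ACTIVITY_TYPES))
  ep <- as.numeric(durations[sequence] / as.integer(counts[sequence]))
  if (!is.null(anchor_model)) {
    a <- sequence[1]
    slot <- ep[1] + ep[m]
    first <- with_seed(seed, anchor_model(a, slot))
    first <- min(max(first, 1e-6), slot - 1e-6)
    ep[1] <- first
    ep[m] <- slot - first
  }
  gap <- tt / (m - 1)
  starts <- cumsum(c(0, ep[-m] + gap))
  out <- data.frame(activity_id = seq_len(m), purpose = sequence,
                    start_h = starts, end_h = starts + ep,
                    gap_after = c(rep(gap, m - 1), NA_real_))
  class(out) <- c("actipop_schedule", "data.frame")
  out
}

#' Generate activity schedules for a whole population
#'
#' Runs the full activity-generation stage: participation, joint duration /
#' travel-time classes, budget-constrained durations, donor sequence
#' matching, and schedule construction.
#'
#' @param persons Completed persons (with advanced attributes).
#' @param survey An `actipop_survey`.
#' @param seed Integer seed.
#' @param max_tries Rejection budget for duration sampling.
#' @return list: `schedules` (long data.frame with `PId`, `activity_id`,
#'   `purpose`, `start_h`, `end_h`, `gap_after`), `durations`, `classes`,
#'   `participation`, `donor_id`, `fallback_durations`,
#'   `fallback_sequence`.
#' @export
generate_activities <- function(persons, survey, seed = 1L, max_tries = 100L) {
  pm <- train_participation_model(survey, seed = derive_seed(seed, 11))
  participation <- assign_participation(persons, pm,
                                        seed = derive_seed(seed, 12))
  dcm <- build_duration_class_model(survey)
  classes <- assign_duration_and_traveltime_classes(participation, dcm,
                                                    seed = derive_seed(seed, 13))
  durations <- sample_durations(classes, dcm, max_tries = max_tries,
                                seed = derive_seed(seed, 14))
  matched <- match_sequence(persons, participation, durations, survey)
  rows <- vector("list", nrow(persons))
  for (i in seq_len(nrow(persons))) {
    dur <- c(H = durations$t_H[i], W = durations$t_W[i],
             S = durations$t_S[i], O = durations$t_O[i])
    sch <- anchor_and_build_schedule(matched$sequences[[i]], dur,
                                     c(classes$tt_lower[i], classes$tt_upper[i]))
    sch$PId <- persons$PId[i]
    rows[[i]] <- sch
  }
  schedules <- do.call(rbind, rows)
  schedules <- schedules[, c("PId", "activity_id", "purpose", "start_h",
                             "end_h", "gap_after")]
  rownames(schedules) <- NULL
  list(schedules = schedules, durations = durations, classes = classes,
       participation = participation, donor_id = matched$donor_id,
       fallback_durations = durations$fallback,
       fallback_sequence = matched$fallback)
}
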