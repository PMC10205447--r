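# Stage 1: synthesize agents with basic attributes and form households.

CIVIL_LEVELS <- c("age<18", "couple", "single")

#' Synthesize one zone's agents with basic attributes
#'
#' Estimates the zone-level joint distribution of gender, age group, and
#' civil status by fitting the municipal cross-tabulation to the zone's
#' observed gender-by-age marginal with IPF (the zone-level civil-status
#' margin is not observed; it is implied by the municipal conditional
#' distribution), integerizes the fit within each gender-age cell so the
#' observed marginals are matched exactly, then instantiates one person per
#' unit with an integer age drawn uniformly within the band (restricted to
#' under/over 18 as the civil status dictates).
#'
#' @param zone_id Zone to synthesize.
#' @param world An `actipop_world` (supplies marginals and the municipal
#'   cross-tab).
#' @param tol,max_iter IPF controls.
#' @param seed Integer seed.
#' @param pid_start First person id to assign.
#' @return data.frame of persons with basic attributes: `PId`, `gender`,
#'   `age`, `age_group`, `marital_status`, `zone`, `municipality` (household
#'   and advanced attributes are filled by later stages).
#' @export
synthesize_persons <- function(zone_id, world, tol = 1e-6, max_iter = 1000L,
                               seed = NULL, pid_start = 1L) {
  zm <- world$zone_marginals
  zm <- zm[zm$zone_id == zone_id, ]
  if (!nrow(zm)) stopf("unknown zone: %s", zone_id, class = "actipop_input_error")
  mun <- world$zones$municipality_id[match(zone_id, world$zones$zone_id)]
  ct <- world$crosstab
  ct <- ct[ct$municipality_id == mun, ]
  breaks <- world$config$age_breaks
  labs <- age_band_labels(breaks)
  genders <- c("Male", "Female")

  # seed array: municipal gender x age x civil counts
  seed_arr <- array(0, dim = c(2, length(labs), 3),
                    dimnames = list(genders, labs, CIVIL_LEVELS))
  seed_arr[cbind(match(ct$gender, genders), match(ct$age_group, labs),
                 match(ct$civil_status, CIVIL_LEVELS))] <- ct$count
  zone_ga <- matrix(0, 2, length(labs), dimnames = list(genders, labs))
  zone_ga[cbind(match(zm$gender, genders), match(zm$age_group, labs))] <- zm$count

  # flatten (gender, age) into one axis so the observed 2-way marginal is a
  # single IPF target; the civil axis target is the municipally implied one
  seed2 <- matrix(seed_arr, nrow = 2 * length(labs), ncol = 3)
  row_target <- as.vector(zone_ga)
  scaled <- seed2 * ifelse(rowSums(seed2) > 0, row_target / pmax(rowSums(seed2), 1e-300), 0)
  col_target <- colSums(scaled)
  fit <- ipf_fit(seed2, list(row_target, col_target), tol = tol,
                 max_iter = max_iter)

  with_seed(seed, {
    # integerize each (gender, age) row separately: axis totals stay exact
    counts <- fit$table
    for (r in seq_len(nrow(counts))) {
      counts[r, ] <- integerize(fit$table[r, ])
    }
    g_ix <- rep(seq_along(genders), times = length(labs))
    a_ix <- rep(seq_along(labs), each = length(genders))
    rows <- list()
    for (r in seq_len(nrow(counts))) {
      for (cc in seq_len(3)) {
        k <- counts[r, cc]
        if (k == 0) next
        civ <- CIVIL_LEVELS[cc]
        rng <- if (civ == "age<18") {
          band_age_range(labs[a_ix[r]], breaks, lo = 0L, hi = 17L)
        } else {
          band_age_range(labs[a_ix[r]], breaks, lo = 18L)
        }
        if (rng[1] > rng[2]) rng <- band_age_range(labs[a_ix[r]], breaks)
        ages <- sample(rng[1]:rng[2], k, replace = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          gender = genders[g_ix[r]], age = as.integer(ages),
          age_group = labs[a_ix[r]], marital_status = civ,
          stringsAsFactors = FALSE)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gender = character(), age = integer(), age_group = character(),
                 marital_status = character(), stringsAsFactors = FALSE)
    # hard rule: the under-18 civil status iff the age is under 18
    out$marital_status[out$age < 18] <- "age<18"
    out$marital_status[out$age >= 18 & out$marital_status == "age<18"] <- "single"
    out <- cbind(PId = seq.int(pid_start, length.out = nrow(out)), out)
    out$zone <- zone_id
    out$municipality <- mun
    rownames(out) <- NULL
    out
  })
}

#' Synthesize all zones of a world
#'
#' @param world An `actipop_world`.
#' @param seed Integer seed.
#' @inheritParams synthesize_persons
#' @return data.frame of persons with basic attributes across all zones.
#' @export
synthesize_population <- function(world, seed = 1L, tol = 1e-6,
                                  max_iter = 1000L) {
  pid <- 1L
  out <- vector("list", nrow(world$zones))
  for (i in seq_len(nrow(world$zones))) {
    zid <- world$zones$zone_id[i]
    p <- synthesize_persons(zid, world, tol = tol, max_iter = max_iter,
                            seed = derive_seed(seed, i), pid_start = pid)
    pid <- pid + nrow(p)
    out[[i]] <- p
  }
  do.call(rbind, out)
}

#' Form households from synthesized persons
#'
#' Per zone: couple-status persons are split into two gender groups; the
#' first is sorted ascending by age, the second ascending by an age proxy
#' (own age plus a seeded normal offset, default mean -2 y, sd 4 y), and the
#' groups are matched one-to-one in rank order up to the zone's couple
#' target. Single-status adults fill single households up to the zone
#' target. Children (under 18) join the household whose closest adult
#' minimizes the parent-child age difference, subject to the difference
#' lying in `[child_gap_min, child_gap_max]`; ties go to the lower household
#' id. All leftovers are pooled into 'other' households of 2-6 members.
#'
#' @param persons data.frame from [synthesize_persons()] (possibly many zones).
#' @param zone_household_counts data.frame with `zone_id`, `single`, `couple`,
#'   `other` household targets (e.g. built from a world's zones table).
#' @param seed Integer seed.
#' @param proxy_mean,proxy_sd Age-proxy offset distribution (years).
#' @param child_gap_min,child_gap_max Feasible parent-child age difference.
#' @param other_size_range Size range for 'other' households.
#' @return list with `households` (HId, type, size, n_children_under6,
#'   n_cars) and `persons` (input plus `HId`).
#' @export
form_households <- function(persons, zone_household_counts, seed = 1L,
                            proxy_mean = -2, proxy_sd = 4,
                            child_gap_min = 18, child_gap_max = 50,
                            other_size_range = c(2L, 6L)) {
  with_seed(seed, {
    persons$HId <- NA_integer_
    hh_rows <- list()
    hid <- 0L
    for (zid in unique(persons$zone)) {
      zi <- which(persons$zone == zid)
      pz <- persons[zi, ]
      tz <- zone_household_counts[zone_household_counts$zone_id == zid, ]
      if (!nrow(tz)) {
        stopf("no household targets for zone %s", zid,
              class = "actipop_input_error")
      }
      assign_hid <- function(pids, type) {
        hid <<- hid + 1L
        persons$HId[match(pids, persons$PId)] <<- hid
        hh_rows[[length(hh_rows) + 1L]] <<-
          list(HId = hid, type = type, zone_id = zid)
        hid
      }

      # --- couples ---------------------------------------------------------
      cp <- pz[pz$marital_status == "couple", ]
      g1 <- cp[cp$gender == "Male", ]
      g2 <- cp[cp$gender == "Female", ]
      g1 <- g1[order(g1$age, g1$PId), ]
      proxy <- g2$age + stats::rnorm(nrow(g2), proxy_mean, proxy_sd)
      g2 <- g2[order(proxy, g2$PId), ]
      n_pairs <- min(nrow(g1), nrow(g2), tz$couple)
      if (tz$couple > min(nrow(g1), nrow(g2))) {
        warnf("zone %s: couple target %d exceeds available pairs %d; capped",
              zid, tz$couple, min(nrow(g1), nrow(g2)),
              class = "actipop_feasibility_warning")
      }
      if (n_pairs > 0) {
        for (i in seq_len(n_pairs)) {
          assign_hid(c(g1$PId[i], g2$PId[i]), "couple")
        }
      }

      # --- singles ---------------------------------------------------------
      sg <- pz[pz$marital_status == "single", ]
      n_single <- min(nrow(sg), tz$single)
      if (tz$single > nrow(sg)) {
        warnf("zone %s: single target %d exceeds available persons %d; capped",
              zid, tz$single, nrow(sg), class = "actipop_feasibility_warning")
      }
      if (n_single > 0) {
        pick <- sample(sg$PId, n_single)
        for (pid in pick) assign_hid(pid, "single")
      }

      # --- children: smallest feasible parent-child age gap ----------------
      kids <- pz[pz$marital_status == "age<18", ]
      zone_hids <- vapply(hh_rows, function(h) h$HId, integer(1))
      zone_types <- vapply(hh_rows, function(h) h$type, character(1))
      zone_of <- vapply(hh_rows, function(h) h$zone_id, character(1))
      local_h <- zone_hids[zone_of == zid & zone_types %in% c("couple", "single")]
      if (nrow(kids) && length(local_h)) {
        adults <- persons[!is.na(persons$HId) & persons$HId %in% local_h, ]
        for (ki in order(kids$PId)) {
          gap <- adults$age - kids$age[ki]
          ok <- gap >= child_gap_min & gap <= child_gap_max
          if (!any(ok)) next
          cand <- adults[ok, ]
          cgap <- gap[ok]
          best <- order(cgap, cand$HId)[1]
          persons$HId[match(kids$PId[ki], persons$PId)] <- cand$HId[best]
        }
      }

      # --- leftovers into 'other' households -------------------------------
      left <- persons$PId[persons$zone == zid & is.na(persons$HId)]
      if (length(left)) {
        left <- sample(left)
        while (length(left)) {
          k <- sample(other_size_range[1]:other_size_range[2], 1)
          k <- min(k, length(left))
          assign_hid(left[seq_len(k)], "other")
          left <- left[-seq_len(k)]
        }
      }
    }

    hh <- data.frame(HId = vapply(hh_rows, function(h) h$HId, integer(1)),
                     type = vapply(hh_rows, function(h) h$type, character(1)),
                     zone_id = vapply(hh_rows, function(h) h$zone_id, character(1)),
                     stringsAsFactors = FALSE)
    sz <- table(factor(persons$HId, levels = hh$HId))
    hh$size <- as.integer(sz)
    kid6 <- table(factor(persons$HId[persons$age < 6], levels = hh$HId))
    hh$n_children_under6 <- as.integer(kid6)
    hh$n_cars <- NA_integer_
    list(households = hh, persons = persons)
  })
}
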