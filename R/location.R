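# Stage 3: homes into buildings via virtual zones, OD probability matrices
# (supplied OD matrices first, gravity fit as fallback), tour modes,
# travel-time-rank-coupled destination zones, and activity buildings.

ACTIVITY_USAGE <- c(W = "workplace", S = "school", O = "other")
RESIDENTIAL_TYPES <- c("detached_house", "apartment")

#' Build virtual zones from the zone-grid overlay
#'
#' One virtual zone per non-empty intersection of a statistical zone with a
#' population grid cell; its weight is the cell's share of the zone's grid
#' population (uniform, with a warning, when the whole zone has zero grid
#' population).
#'
#' @param zones Zones table (with extents).
#' @param grid Grid table (`cell_id`, `zone_id`, `x0`, `y0`, `size`,
#'   `population`).
#' @return data.frame: `vz_id`, `zone_id`, `cell_id`, `x0`, `y0`, `size`,
#'   `population_weight`.
#' @export
build_virtual_zones <- function(zones, grid) {
  vz <- grid[grid$zone_id %in% zones$zone_id, ]
  tot <- tapply(vz$population, vz$zone_id, sum)[vz$zone_id]
  zero <- tot == 0
  if (any(zero)) {
    warnf("zone(s) %s have zero grid population; using uniform weights",
          paste(unique(vz$zone_id[zero]), collapse = ", "),
          class = "actipop_data_warning")
    cnt <- table(vz$zone_id)[vz$zone_id]
    vz$population_weight <- as.numeric(ifelse(zero, 1 / as.numeric(cnt),
                                              vz$population / pmax(tot, 1)))
  } else {
    vz$population_weight <- as.numeric(vz$population / tot)
  }
  vz$vz_id <- paste0(vz$zone_id, "/", vz$cell_id)
  rownames(vz) <- NULL
  vz[, c("vz_id", "zone_id", "cell_id", "x0", "y0", "size",
         "population_weight")]
}

#' Place households into residential buildings
#'
#' Each household is assigned a virtual zone by population weight, then a
#' residential building type — detached house with probability increasing in
#' household size through a logistic model — and finally a concrete building
#' of that type, uniformly within the virtual zone (falling back to the
#' whole parent zone when the virtual zone holds none of that type, then to
#' the other residential type).
#'
#' @param households Households with `zone_id`.
#' @param virtual_zones From [build_virtual_zones()].
#' @param buildings Building register.
#' @param size_model Numeric `c(intercept, slope)` of the logistic
#'   P(detached | size) on household size; `slope > 0` makes larger
#'   households likelier to live in detached houses.
#' @param seed Integer seed.
#' @return `households` with `building_id` added.
#' @export
assign_home_buildings <- function(households, virtual_zones, buildings,
                                  size_model = c(-2.5, 1.0), seed = NULL) {
  res <- buildings[buildings$usage_type %in% RESIDENTIAL_TYPES, ]
  missing_z <- setdiff(unique(households$zone_id), unique(res$zone_id))
  if (length(missing_z)) {
    stopf("zone(s) without residential buildings: %s",
          paste(missing_z, collapse = ", "), class = "actipop_placement_error")
  }
  with_seed(seed, {
    households$building_id <- NA_integer_
    p_det <- stats::plogis(size_model[1] + size_model[2] * households$size)
    for (zid in unique(households$zone_id)) {
      hi <- which(households$zone_id == zid)
      vz <- virtual_zones[virtual_zones$zone_id == zid, ]
      vzi <- sample.int(nrow(vz), length(hi), replace = TRUE,
                        prob = vz$population_weight)
      bz <- res[res$zone_id == zid, ]
      in_cell <- function(b, v) b$x >= v$x0 & b$x < v$x0 + v$size &
        b$y >= v$y0 & b$y < v$y0 + v$size
      for (k in seq_along(hi)) {
        h <- hi[k]
        v <- vz[vzi[k], ]
        want <- if (stats::runif(1) < p_det[h]) "detached_house" else "apartment"
        cand <- bz[bz$usage_type == want & in_cell(bz, v), ]
        if (!nrow(cand)) cand <- bz[bz$usage_type == want, ]      # parent zone
        if (!nrow(cand)) cand <- bz                               # other type
        households$building_id[h] <- cand$building_id[sample.int(nrow(cand), 1)]
      }
    }
    households
  })
}

#' Fit gravity deterrence rates from survey trips
#'
#' For each (purpose, mode) with at least `min_trips` trips, finds the
#' deterrence rate beta of the destination-choice kernel
#' `P(j | i) ~ mass_j * exp(-beta * d_ij)` whose origin-weighted mean trip
#' distance matches the survey's observed mean, by monotone 1-D root
#' finding. Distances are straight-line between zone centroids, in km.
#'
#' @param trips data.frame with `purpose`, `mode`, `origin_zone` and either
#'   `destination_zone` or `distance_km`.
#' @param zones Zones table with centroids.
#' @param masses Attraction masses per activity type, as from
#'   [attraction_masses()].
#' @param min_trips Minimum trips per (purpose, mode) cell.
#' @return data.frame of class `gravity_fit`: `purpose`, `mode`, `beta`,
#'   `residual` (mean-distance gap at the root), `n_trips`.
#' @export
fit_gravity <- function(trips, zones, masses, min_trips = 20L) {
  dmat <- zone_distance_matrix(zones)
  if (!"distance_km" %in% names(trips)) {
    trips$distance_km <- dmat[cbind(match(trips$origin_zone, zones$zone_id),
                                    match(trips$destination_zone, zones$zone_id))]
  }
  out <- list()
  for (pur in intersect(names(masses), unique(trips$purpose))) {
    mass <- masses[[pur]]
    # "(all)" pools every mode of the purpose: the fallback when a
    # (purpose, mode) cell is too sparse to fit on its own
    for (mode in c(unique(trips$mode[trips$purpose == pur]), "(all)")) {
      tr <- if (mode == "(all)") trips[trips$purpose == pur, ] else
        trips[trips$purpose == pur & trips$mode == mode, ]
      if (nrow(tr) < min_trips) next
      obs <- mean(tr$distance_km)
      ocount <- table(factor(tr$origin_zone, levels = zones$zone_id))
      oi <- which(ocount > 0)
      w <- as.numeric(ocount[oi])
      model_mean <- function(beta) {
        mm <- vapply(oi, function(i) {
          k <- mass * exp(-beta * dmat[i, ])
          sum(k * dmat[i, ]) / sum(k)
        }, numeric(1))
        sum(w * mm) / sum(w)
      }
      f <- function(lb) model_mean(exp(lb)) - obs
      lo <- log(1e-4); hi <- log(50)
      if (f(lo) < 0 || f(hi) > 0) {
        # a single mode's noisy observed mean can fall outside the kernel's
        # reachable range; skip it so the pooled fit covers the slice, and
        # only fail when the purpose as a whole cannot be fitted
        if (mode != "(all)") {
          warnf("gravity fit for (%s, %s): observed mean distance %.2f km is outside the model's reachable range [%.2f, %.2f]; falling back to the pooled fit",
                pur, mode, obs, model_mean(exp(hi)), model_mean(exp(lo)),
                class = "actipop_fit_warning")
          next
        }
        stopf("gravity fit for (%s, %s): observed mean distance %.2f km is outside the model's reachable range [%.2f, %.2f]",
              pur, mode, obs, model_mean(exp(hi)), model_mean(exp(lo)),
              class = "actipop_fit_error")
      }
      root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)
      out[[length(out) + 1L]] <- data.frame(
        purpose = pur, mode = mode, beta = exp(root$root),
        residual = model_mean(exp(root$root)) - obs,
        n_trips = nrow(tr), stringsAsFactors = FALSE)
    }
  }
  fit <- do.call(rbind, out)
  class(fit) <- c("gravity_fit", "data.frame")
  fit
}

#' Build origin-destination probability matrices
#'
#' One row-normalized destination distribution per (origin zone, activity
#' purpose, mode). Supplied OD matrices take precedence: their trip purposes
#' map onto activity types (work to W; business, other and private to O;
#' school trips have no OD purpose, so school destinations always come from
#' the gravity kernel over school-building masses). Any (purpose, mode)
#' slice without OD data falls back to the gravity fit.
#'
#' @param zones Zones table.
#' @param masses Attraction masses from [attraction_masses()].
#' @param od Optional long OD data.frame (`origin`, `destination`, `mode`,
#'   `purpose`, `flow`).
#' @param gravity Optional `gravity_fit`.
#' @return list of class `od_probability`: matrices keyed `"<purpose>|<mode>"`
#'   (origins x destinations, rows summing to 1), plus a `source` table.
#' @export
build_od_probabilities <- function(zones, masses, od = NULL, gravity = NULL) {
  ids <- zones$zone_id
  dmat <- zone_distance_matrix(zones)
  purpose_map <- c(work = "W", business = "O", other = "O", private = "O")
  out <- list()
  src <- list()
  for (act in c("W", "S", "O")) {
    for (mode in MODES) {
      key <- paste(act, mode, sep = "|")
      M <- NULL
      if (act != "S" && !is.null(od)) {
        sel <- od$mode == mode & purpose_map[od$purpose] == act
        if (any(sel)) {
          sl <- od[sel, ]
          M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
          agg <- stats::aggregate(flow ~ origin + destination, data = sl, sum)
          M[cbind(match(agg$origin, ids), match(agg$destination, ids))] <- agg$flow
          zero_rows <- rowSums(M) == 0
          if (any(zero_rows)) {
            stopf("OD slice (%s, %s): origin(s) %s have zero total flow",
                  act, mode, paste(ids[zero_rows], collapse = ", "),
                  class = "actipop_data_error")
          }
          src[[key]] <- "od"
        }
      }
      if (is.null(M)) {
        beta <- NULL
        src[[key]] <- "gravity"
        if (!is.null(gravity)) {
          g <- gravity[gravity$purpose == act & gravity$mode == mode, ]
          if (!nrow(g)) {   # sparse cell: pooled-mode fit for the purpose
            g <- gravity[gravity$purpose == act & gravity$mode == "(all)", ]
            src[[key]] <- "gravity_pooled"
          }
          if (nrow(g)) beta <- g$beta[1]
        }
        if (is.null(beta)) {
          stopf("no OD data and no gravity fit for (%s, %s)", act, mode,
                class = "actipop_data_error")
        }
        M <- sweep(exp(-beta * dmat), 2, masses[[act]], `*`)
      }
      out[[key]] <- M / rowSums(M)
    }
  }
  structure(out, class = "od_probability",
            source = data.frame(key = names(src),
                                source = unlist(src, use.names = FALSE)))
}

#' Train the tour-mode choice model from a survey
#'
#' The target is each respondent's main (most frequent) diary access mode,
#' conditioned on socio-demographics and car availability.
#' @param survey An `actipop_survey`.
#' @param seed Integer seed.
#' @return A `choice_model` over the five modes (those observed).
#' @export
train_mode_model <- function(survey, seed = 1L) {
  di <- survey$diary[!is.na(survey$diary$access_mode), ]
  main <- tapply(di$access_mode, di$respondent_id, function(v) {
    tb <- sort(table(v), decreasing = TRUE)
    names(tb)[1]
  })
  df <- survey$persons[match(as.integer(names(main)),
                             survey$persons$respondent_id), ]
  df$mode <- as.character(main)
  df$has_car <- as.integer(df$n_cars > 0)
  train_choice_model(df, c("age", "gender", "employment", "has_car"),
                     "mode", seed = seed)
}

#' Assign travel modes to every trip
#'
#' Draws one main tour mode per agent from the choice model (conditioned on
#' socio-demographics and household car availability); driving is
#' structurally unavailable to agents in carless households. All of an
#' agent's trips use the tour mode unless a per-trip walk substitution
#' fires.
#'
#' @param persons Completed persons.
#' @param households Households (for car availability).
#' @param schedules Long schedule table from [generate_activities()].
#' @param mode_model A `choice_model` over modes.
#' @param walk_substitution Per-trip probability of replacing the tour mode
#'   by walking (0 disables; tour purity is the default).
#' @param seed Integer seed.
#' @return `schedules` with a `mode` column (NA on each person's first
#'   episode, the mode used to access every later one).
#' @export
assign_modes <- function(persons, households, schedules, mode_model,
                         walk_substitution = 0, seed = NULL) {
  hh_cars <- households$n_cars[match(persons$HId, households$HId)]
  hh_cars[is.na(hh_cars)] <- 0L
  df <- persons
  df$has_car <- as.integer(hh_cars > 0)
  P <- predict_probs(mode_model, df)
  full <- matrix(0, nrow(persons), length(MODES),
                 dimnames = list(NULL, MODES))
  full[, colnames(P)] <- P
  full[df$has_car == 0, "Car"] <- 0       # no vehicle, no driving
  full <- full / rowSums(full)
  with_seed(seed, {
    tour <- MODES[sample_rows(full)]
    names(tour) <- as.character(persons$PId)
    schedules$mode <- NA_character_
    later <- schedules$activity_id > 1L
    schedules$mode[later] <- tour[as.character(schedules$PId[later])]
    if (walk_substitution > 0) {
      sub <- later & stats::runif(nrow(schedules)) < walk_substitution
      schedules$mode[sub] <- "Walking"
    }
    schedules
  })
}

#' Assign destination zones and buildings to every activity
#'
#' Non-home activities get a destination zone by inverse-CDF over the
#' origin's destination distribution with destinations ordered by increasing
#' distance, evaluated at the agent's travel-time quantile among all
#' same-mode trips in the run — longer travel times map to farther zones.
#' Consecutive activities chain (each trip starts from the previous
#' activity's zone). A building of the purpose-appropriate usage type is
#' then drawn within the zone with probability proportional to footprint
#' area (nearest zone holding one, flagged, if the zone has none). Home
#' episodes reuse the household's building.
#'
#' @param persons,households Completed tables (homes already placed).
#' @param schedules Schedule table with modes.
#' @param od_probs From [build_od_probabilities()].
#' @param world The `actipop_world` (zones, buildings).
#' @param seed Integer seed.
#' @return `schedules` completed with `zone`, `building_id`,
#'   `building_type`, `x`, `y`, and a `relocated` flag for
#'   building-fallback rows.
#' @export
assign_zones_and_buildings <- function(persons, households, schedules,
                                       od_probs, world, seed = NULL) {
  zones <- world$zones
  ids <- zones$zone_id
  dmat <- zone_distance_matrix(zones)
  bld <- world$buildings
  home_bld <- households$building_id[match(persons$HId, households$HId)]
  names(home_bld) <- as.character(persons$PId)
  home_zone <- persons$zone
  names(home_zone) <- as.character(persons$PId)

  # travel-time quantile of every trip within its mode
  trip <- schedules$activity_id > 1L
  tt <- schedules$gap_after[match(paste(schedules$PId, schedules$activity_id - 1L),
                                  paste(schedules$PId, schedules$activity_id))]
  qtl <- rep(NA_real_, nrow(schedules))
  for (m in unique(schedules$mode[trip])) {
    sel <- which(trip & !is.na(schedules$mode) & schedules$mode == m)
    r <- rank(tt[sel], ties.method = "average")
    qtl[sel] <- r / length(sel)
  }

  # precompute per-(purpose|mode, origin) the distance ordering + CDF
  order_cache <- new.env(parent = emptyenv())
  dest_at_quantile <- function(origin_i, key, q) {
    ck <- paste(key, origin_i)
    ent <- order_cache[[ck]]
    if (is.null(ent)) {
      p <- od_probs[[key]][origin_i, ]
      o <- order(dmat[origin_i, ], ids)           # increasing distance
      cdf <- cumsum(p[o])
      ent <- list(o = o, cdf = cdf)
      order_cache[[ck]] <- ent
    }
    j <- which(ent$cdf >= q - 1e-12)[1]
    if (is.na(j)) j <- length(ent$o)
    ent$o[j]
  }

  with_seed(seed, {
    schedules$zone <- NA_character_
    schedules$building_id <- NA_integer_
    schedules$relocated <- FALSE
    ord <- order(schedules$PId, schedules$activity_id)
    schedules <- schedules[ord, ]
    qtl <- qtl[ord]
    cur_zone <- NA_character_
    cur_pid <- NA_integer_
    for (r in seq_len(nrow(schedules))) {
      pid <- schedules$PId[r]
      if (!identical(pid, cur_pid)) {
        cur_pid <- pid
        cur_zone <- home_zone[[as.character(pid)]]
      }
      act <- schedules$purpose[r]
      if (act == "H") {
        schedules$zone[r] <- home_zone[[as.character(pid)]]
        schedules$building_id[r] <- home_bld[[as.character(pid)]]
        cur_zone <- schedules$zone[r]
        next
      }
      key <- paste(act, schedules$mode[r], sep = "|")
      oi <- match(cur_zone, ids)
      di <- dest_at_quantile(oi, key, qtl[r])
      dz <- ids[di]
      usage <- ACTIVITY_USAGE[[act]]
      cand <- bld[bld$zone_id == dz & bld$usage_type == usage, ]
      if (!nrow(cand)) {
        # nearest zone holding a suitable building
        have <- unique(bld$zone_id[bld$usage_type == usage])
        hz <- have[which.min(dmat[di, match(have, ids)])]
        cand <- bld[bld$zone_id == hz & bld$usage_type == usage, ]
        dz <- hz
        schedules$relocated[r] <- TRUE
      }
      pick <- cand$building_id[sample.int(nrow(cand), 1,
                                          prob = cand$footprint_area)]
      schedules$zone[r] <- dz
      schedules$building_id[r] <- pick
      cur_zone <- dz
    }
    bi <- match(schedules$building_id, bld$building_id)
    schedules$building_type <- bld$usage_type[bi]
    schedules$x <- bld$x[bi]
    schedules$y <- bld$y[bi]
    rownames(schedules) <- NULL
    schedules
  })
}

#' Run the full location and mode assignment stage
#'
#' @param persons,households Completed tables.
#' @param schedules From [generate_activities()].
#' @param world The `actipop_world`.
#' @param survey An `actipop_survey` (mode model and gravity trips).
#' @param od Optional supplied OD matrices (take precedence over gravity).
#' @param seed Integer seed.
#' @return list: completed `schedules`, `households` (with buildings),
#'   `od_probs`, `gravity` fit, `virtual_zones`.
#' @export
assign_locations <- function(persons, households, schedules, world, survey,
                             od = NULL, seed = 1L) {
  vz <- build_virtual_zones(world$zones, world$grid)
  households <- assign_home_buildings(households, vz, world$buildings,
                                      seed = derive_seed(seed, 21))
  masses <- attraction_masses(world$buildings, world$zones$zone_id)
  gravity <- fit_gravity(survey$trips, world$zones, masses)
  od_probs <- build_od_probabilities(world$zones, masses, od = od,
                                     gravity = gravity)
  mm <- train_mode_model(survey, seed = derive_seed(seed, 22))
  schedules <- assign_modes(persons, households, schedules, mm,
                            seed = derive_seed(seed, 23))
  schedules <- assign_zones_and_buildings(persons, households, schedules,
                                          od_probs, world,
                                          seed = derive_seed(seed, 24))
  list(schedules = schedules, households = households, od_probs = od_probs,
       gravity = gravity, virtual_zones = vz)
}
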