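# Toy-region fixture generator.
#
# Builds a fully self-consistent miniature study region: a latent ground-truth
# micro-population is generated household by household, and every aggregate
# input the pipeline consumes (zone marginals, municipal cross-tabulations,
# grid populations, building register, OD matrices, travel-survey diaries) is
# tallied from that same micro-population. Aggregates are therefore exactly
# consistent with each other by construction, and the behavioural parameters
# used to simulate diaries are persisted so parameter-recovery tests can
# assert against known truth.

MODES <- c("Car", "CarPassenger", "PublicTransport", "Bike", "Walking")
ACTIVITY_TYPES <- c("H", "W", "S", "O")
INCOME_CLASSES <- c("No", "Low", "Lower-middle", "Upper-middle", "High")
OD_PURPOSES <- c("work", "business", "other", "private")
HH_TYPES <- c("single", "couple", "other")

#' Behavioural ground-truth parameters for the toy region
#'
#' Defines the data-generating process for survey diaries and OD matrices:
#' activity-participation probabilities by employment/studenthood status,
#' truncated-normal activity duration distributions (hours), per-trip travel
#' time, a multinomial mode-utility model (distance in km), and gravity
#' deterrence rates per activity purpose and mode (1/km).
#'
#' @param p_work Probability that an employed (resp. non-employed) person has
#'   a work activity in their day.
#' @param p_school Same for students / non-students and school.
#' @param p_other Probability of an "other" activity for anyone.
#' @param duration_distributions Named list per activity type:
#'   `c(mean, sd, lo, hi)` in hours.
#' @param trip_time Per-trip travel time distribution `c(mean, sd, lo, hi)`.
#' @param mode_utility List with `intercepts` and `dist_coef`, one value per
#'   mode; utilities are `intercept + dist_coef * distance_km` and modes are
#'   drawn by softmax. Car is unavailable to carless households.
#' @param gravity_beta Named list per activity purpose (W, S, O) of named
#'   per-mode deterrence rates (1/km), all > 0.
#' @return A list of class `behaviour_params`.
#' @export
behaviour_params <- function(p_work = c(employed = 0.85, nonemployed = 0.03),
                             p_school = c(student = 0.85, nonstudent = 0.01),
                             p_other = 0.45,
                             duration_distributions = list(
                               H = c(mean = 13, sd = 2.5, lo = 6,    hi = 20),
                               W = c(mean = 8,  sd = 1,   lo = 2,    hi = 12),
                               S = c(mean = 6,  sd = 1,   lo = 2,    hi = 10),
                               O = c(mean = 2,  sd = 1,   lo = 0.25, hi = 6)),
                             trip_time = c(mean = 0.4, sd = 0.2, lo = 0.1, hi = 1.5),
                             mode_utility = list(
                               intercepts = c(Car = 1.0, CarPassenger = -1.0,
                                              PublicTransport = -0.3, Bike = 0.2,
                                              Walking = 0.8),
                               dist_coef = c(Car = -0.05, CarPassenger = -0.08,
                                             PublicTransport = -0.07, Bike = -0.35,
                                             Walking = -0.8)),
                             gravity_beta = list(
                               W = c(Car = 0.30, CarPassenger = 0.35,
                                     PublicTransport = 0.35, Bike = 0.60,
                                     Walking = 1.20),
                               S = c(Car = 0.50, CarPassenger = 0.50,
                                     PublicTransport = 0.55, Bike = 0.80,
                                     Walking = 1.40),
                               O = c(Car = 0.40, CarPassenger = 0.40,
                                     PublicTransport = 0.45, Bike = 0.70,
                                     Walking = 1.30))) {
  p <- list(p_work = p_work, p_school = p_school, p_other = p_other,
            duration_distributions = duration_distributions,
            trip_time = trip_time, mode_utility = mode_utility,
            gravity_beta = gravity_beta)
  probs <- c(p_work, p_school, p_other)
  if (any(probs < 0 | probs > 1)) {
    stopf("participation probabilities must lie in [0, 1]",
          class = "actipop_config_error")
  }
  if (any(unlist(gravity_beta) <= 0)) {
    stopf("gravity_beta rates must be > 0", class = "actipop_config_error")
  }
  structure(p, class = "behaviour_params")
}

#' Configuration of the toy region
#'
#' @param n_municipalities Number of municipalities.
#' @param zones_per_municipality Zones per municipality.
#' @param persons_per_zone_range Min/max inhabitants per zone. The default
#'   mirrors small statistical areas of 700--2,700 inhabitants; toy worlds may
#'   set it smaller for fast tests.
#' @param grid_cell_size Grid cell edge in metres.
#' @param zone_cells Number of grid cells per zone edge (zones are square
#'   blocks of whole cells, so zone-by-grid intersection is exact).
#' @param building_density Named vector: buildings per zone by usage type.
#' @param age_breaks Lower bounds of age bands (last band open-ended).
#' @param behaviour Ground-truth `behaviour_params`.
#' @param seed Integer seed; a fixed seed yields byte-identical fixtures.
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_municipalities = 1L,
                         zones_per_municipality = 2L,
                         persons_per_zone_range = c(700L, 2700L),
                         grid_cell_size = 1000,
                         zone_cells = 2L,
                         building_density = c(detached_house = 40L, apartment = 20L,
                                              workplace = 12L, school = 2L,
                                              other = 10L),
                         age_breaks = seq(0L, 95L, by = 5L),
                         behaviour = behaviour_params(),
                         seed = 1L) {
  if (n_municipalities < 1L) {
    stopf("n_municipalities must be >= 1", class = "actipop_config_error")
  }
  if (zones_per_municipality < 1L) {
    stopf("zones_per_municipality must be >= 1", class = "actipop_config_error")
  }
  if (length(persons_per_zone_range) != 2L ||
      persons_per_zone_range[1] > persons_per_zone_range[2] ||
      persons_per_zone_range[1] < 1L) {
    stopf("persons_per_zone_range must be an increasing positive pair",
          class = "actipop_config_error")
  }
  need <- c("detached_house", "apartment", "workplace", "school", "other")
  if (!all(need %in% names(building_density))) {
    stopf("building_density must name all of: %s", paste(need, collapse = ", "),
          class = "actipop_config_error")
  }
  if (building_density[["detached_house"]] + building_density[["apartment"]] < 1L) {
    stopf("building_density: every zone needs at least one residential building",
          class = "actipop_config_error")
  }
  structure(list(n_municipalities = as.integer(n_municipalities),
                 zones_per_municipality = as.integer(zones_per_municipality),
                 persons_per_zone_range = as.integer(persons_per_zone_range),
                 grid_cell_size = grid_cell_size,
                 zone_cells = as.integer(zone_cells),
                 building_density = building_density,
                 age_breaks = as.integer(age_breaks),
                 behaviour = behaviour,
                 seed = as.integer(seed)),
            class = "world_config")
}

# ---- ground-truth micro-population -----------------------------------------

# One household worth of true persons; returns a data.frame.
.rand_household <- function(type) {
  if (type == "couple") {
    age1 <- round(rtruncnorm(1, 45, 15, 18, 95))
    age2 <- round(max(18, age1 + stats::rnorm(1, -2, 4)))
    ages <- c(age1, age2)
    genders <- c("Male", "Female")
    civil <- c("couple", "couple")
    n_kids <- if (min(ages) < 50) stats::rpois(1, 0.9) else 0L
  } else if (type == "single") {
    ages <- round(rtruncnorm(1, 50, 18, 18, 95))
    genders <- sample(c("Male", "Female"), 1)
    civil <- "single"
    n_kids <- if (ages >= 25 && ages <= 50 && stats::runif(1) < 0.2)
      sample(1:2, 1) else 0L
  } else {
    k <- sample(2:4, 1)
    ages <- round(rtruncnorm(k, 32, 10, 18, 95))
    genders <- sample(c("Male", "Female"), k, replace = TRUE)
    civil <- rep("single", k)
    n_kids <- 0L
  }
  if (n_kids > 0) {
    ref <- min(ages)
    kid_hi <- max(0L, min(17L, ref - 19L))
    kid_ages <- sample(0:max(kid_hi, 0L), n_kids, replace = TRUE)
    ages <- c(ages, kid_ages)
    genders <- c(genders, sample(c("Male", "Female"), n_kids, replace = TRUE))
    civil <- c(civil, rep("age<18", n_kids))
  }
  data.frame(age = as.integer(ages), gender = genders, civil_status = civil,
             stringsAsFactors = FALSE)
}

.true_statuses <- function(df) {
  n <- nrow(df)
  emp <- rep(0L, n)
  adultworking <- df$age >= 18 & df$age <= 66
  emp[adultworking] <- stats::rbinom(sum(adultworking), 1, 0.75)
  old <- df$age > 66
  emp[old] <- stats::rbinom(sum(old), 1, 0.05)
  stud <- rep(0L, n)
  kid <- df$age >= 6 & df$age <= 18
  stud[kid] <- stats::rbinom(sum(kid), 1, 0.95)
  young <- df$age >= 19 & df$age <= 25
  stud[young] <- stats::rbinom(sum(young), 1, 0.45)
  adult <- df$age > 25
  stud[adult] <- stats::rbinom(sum(adult), 1, 0.03)
  df$employment <- emp
  df$studenthood <- stud
  # income class: children mostly "No"; employed adults skew upwards
  pr <- matrix(0, n, 5, dimnames = list(NULL, INCOME_CLASSES))
  pr[df$age < 16, ] <- matrix(rep(c(0.97, 0.03, 0, 0, 0), each = sum(df$age < 16)),
                              ncol = 5)
  grown <- df$age >= 16
  pr[grown & emp == 1L, ] <- matrix(rep(c(0.02, 0.10, 0.28, 0.32, 0.28),
                                        each = sum(grown & emp == 1L)), ncol = 5)
  pr[grown & emp == 0L, ] <- matrix(rep(c(0.30, 0.40, 0.20, 0.07, 0.03),
                                        each = sum(grown & emp == 0L)), ncol = 5)
  df$income_class <- INCOME_CLASSES[sample_rows(pr)]
  df
}

#' Generate the toy region
#'
#' Generates a latent ground-truth micro-population and tallies every
#' aggregate input from it, so all emitted tables are exactly consistent:
#' zone gender-by-age marginals sum to municipal cross-tab marginals, grid
#' populations sum to zone populations, and household-type counts match the
#' true households.
#'
#' @param config A [world_config()].
#' @return A list of class `actipop_world` with elements `zones`,
#'   `zone_marginals`, `crosstab` (municipal gender x age x civil counts),
#'   `income_counts`, `children_by_hhtype`, `grid`, `buildings`, `truth`
#'   (latent persons/households), `params`, and `config`.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  with_seed(config$seed, .generate_world_impl(config))
}

.generate_world_impl <- function(config) {
  n_zones <- config$n_municipalities * config$zones_per_municipality
  cell <- config$grid_cell_size
  zc <- config$zone_cells
  ncol_z <- ceiling(sqrt(n_zones))
  breaks <- config$age_breaks

  zones <- data.frame(
    zone_id = sprintf("Z%03d", seq_len(n_zones)),
    municipality_id = sprintf("M%02d",
                              rep(seq_len(config$n_municipalities),
                                  each = config$zones_per_municipality)),
    stringsAsFactors = FALSE)
  col <- (seq_len(n_zones) - 1L) %% ncol_z
  row <- (seq_len(n_zones) - 1L) %/% ncol_z
  zones$x0 <- col * zc * cell
  zones$y0 <- row * zc * cell
  zones$x1 <- zones$x0 + zc * cell
  zones$y1 <- zones$y0 + zc * cell
  zones$centroid_x <- (zones$x0 + zones$x1) / 2
  zones$centroid_y <- (zones$y0 + zones$y1) / 2

  # --- latent micro-population, built household by household -----------------
  persons_list <- vector("list", n_zones)
  hh_list <- vector("list", n_zones)
  hid0 <- 0L
  pid0 <- 0L
  for (z in seq_len(n_zones)) {
    target <- sample(config$persons_per_zone_range[1]:config$persons_per_zone_range[2], 1)
    plist <- list()
    hrows <- list()
    tot <- 0L
    while (tot < target) {
      type <- sample(HH_TYPES, 1, prob = c(0.55, 0.38, 0.07))
      hh <- .rand_household(type)
      hid0 <- hid0 + 1L
      hh$true_hid <- hid0
      hh$zone_id <- zones$zone_id[z]
      plist[[length(plist) + 1L]] <- hh
      hrows[[length(hrows) + 1L]] <- data.frame(
        true_hid = hid0, type = type, size = nrow(hh),
        zone_id = zones$zone_id[z], stringsAsFactors = FALSE)
      tot <- tot + nrow(hh)
    }
    pz <- do.call(rbind, plist)
    hz <- do.call(rbind, hrows)
    # household cars: scale with number of adults
    n_adults <- tapply(pz$age >= 18, pz$true_hid, sum)[as.character(hz$true_hid)]
    hz$n_cars <- pmin(stats::rbinom(nrow(hz), size = pmax(n_adults, 1L), prob = 0.55), 3L)
    pz$n_cars <- hz$n_cars[match(pz$true_hid, hz$true_hid)]
    # home grid cell within the zone
    cells_per_zone <- zc * zc
    cell_idx <- sample.int(cells_per_zone, nrow(hz), replace = TRUE)
    hz$cell_ix <- (cell_idx - 1L) %% zc
    hz$cell_iy <- (cell_idx - 1L) %/% zc
    pz$cell_ix <- hz$cell_ix[match(pz$true_hid, hz$true_hid)]
    pz$cell_iy <- hz$cell_iy[match(pz$true_hid, hz$true_hid)]
    persons_list[[z]] <- pz
    hh_list[[z]] <- hz
  }
  true_persons <- do.call(rbind, persons_list)
  true_persons <- .true_statuses(true_persons)
  true_persons$person_id <- seq_len(nrow(true_persons))
  true_hh <- do.call(rbind, hh_list)
  true_persons$municipality_id <-
    zones$municipality_id[match(true_persons$zone_id, zones$zone_id)]
  true_persons$age_group <- age_band_of(true_persons$age, breaks)

  # --- aggregates tallied from the truth -------------------------------------
  labs <- age_band_labels(breaks)
  zone_marginals <- as.data.frame(
    table(zone_id = true_persons$zone_id,
          gender = true_persons$gender,
          age_group = factor(true_persons$age_group, levels = labs)),
    responseName = "count", stringsAsFactors = FALSE)

  zones$population <- as.integer(
    table(factor(true_persons$zone_id, levels = zones$zone_id)))
  httab <- table(factor(true_hh$zone_id, levels = zones$zone_id),
                 factor(true_hh$type, levels = HH_TYPES))
  zones$hh_single <- as.integer(httab[, "single"])
  zones$hh_couple <- as.integer(httab[, "couple"])
  zones$hh_other <- as.integer(httab[, "other"])
  zones$n_employees <- as.integer(tapply(true_persons$employment,
    factor(true_persons$zone_id, levels = zones$zone_id), sum))
  zones$n_students <- as.integer(tapply(true_persons$studenthood,
    factor(true_persons$zone_id, levels = zones$zone_id), sum))
  zones$n_cars <- as.integer(tapply(true_hh$n_cars,
    factor(true_hh$zone_id, levels = zones$zone_id), sum))

  crosstab <- as.data.frame(
    table(municipality_id = true_persons$municipality_id,
          gender = true_persons$gender,
          age_group = factor(true_persons$age_group, levels = labs),
          civil_status = factor(true_persons$civil_status,
                                levels = c("age<18", "couple", "single"))),
    responseName = "count", stringsAsFactors = FALSE)

  income_counts <- as.data.frame(
    table(municipality_id = true_persons$municipality_id,
          income_class = factor(true_persons$income_class, levels = INCOME_CLASSES)),
    responseName = "count", stringsAsFactors = FALSE)

  kids <- true_persons[true_persons$age < 6, ]
  kid_type <- true_hh$type[match(kids$true_hid, true_hh$true_hid)]
  kid_mun <- zones$municipality_id[match(kids$zone_id, zones$zone_id)]
  children_by_hhtype <- as.data.frame(
    table(municipality_id = factor(kid_mun, levels = unique(zones$municipality_id)),
          household_type = factor(kid_type, levels = HH_TYPES)),
    responseName = "count", stringsAsFactors = FALSE)

  # grid: one row per cell of every zone, population tallied from the truth
  grid_list <- lapply(seq_len(n_zones), function(z) {
    ix <- rep(0:(zc - 1L), times = zc)
    iy <- rep(0:(zc - 1L), each = zc)
    data.frame(cell_id = sprintf("%s_C%d", zones$zone_id[z], seq_len(zc * zc)),
               zone_id = zones$zone_id[z],
               x0 = zones$x0[z] + ix * cell,
               y0 = zones$y0[z] + iy * cell,
               size = cell, ix = ix, iy = iy, stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, grid_list)
  key_g <- paste(grid$zone_id, grid$ix, grid$iy)
  key_p <- paste(true_persons$zone_id, true_persons$cell_ix, true_persons$cell_iy)
  grid$population <- as.integer(table(factor(key_p, levels = key_g)))
  grid$ix <- grid$iy <- NULL

  # building register
  dens <- config$building_density
  area_mu <- c(detached_house = log(150), apartment = log(800),
               workplace = log(1200), school = log(2000), other = log(500))
  bld_list <- lapply(seq_len(n_zones), function(z) {
    types <- rep(names(dens), times = dens)
    n <- length(types)
    data.frame(usage_type = types,
               x = round(stats::runif(n, zones$x0[z], zones$x1[z]), 1),
               y = round(stats::runif(n, zones$y0[z], zones$y1[z]), 1),
               footprint_area = round(exp(stats::rnorm(n, area_mu[types], 0.35)), 1),
               zone_id = zones$zone_id[z], stringsAsFactors = FALSE)
  })
  buildings <- do.call(rbind, bld_list)
  buildings <- buildings[, c("usage_type", "x", "y", "footprint_area", "zone_id")]
  buildings <- cbind(building_id = seq_len(nrow(buildings)), buildings)
  rownames(buildings) <- NULL
  rownames(true_persons) <- NULL
  rownames(true_hh) <- NULL

  structure(list(zones = zones, zone_marginals = zone_marginals,
                 crosstab = crosstab, income_counts = income_counts,
                 children_by_hhtype = children_by_hhtype,
                 grid = grid, buildings = buildings,
                 truth = list(persons = true_persons, households = true_hh),
                 params = config$behaviour, config = config),
            class = "actipop_world")
}

#' @export
print.actipop_world <- function(x, ...) {
  cat(sprintf("Toy region: %d municipalities, %d zones, %d inhabitants, %d buildings\n",
              length(unique(x$zones$municipality_id)), nrow(x$zones),
              sum(x$zones$population), nrow(x$buildings)))
  invisible(x)
}

# ---- survey ----------------------------------------------------------------

.participation_sets <- function() {
  c("H", "HW", "HS", "HO", "HWS", "HWO", "HSO", "HWSO")
}

.set_label <- function(w, s, o) {
  paste0("H", ifelse(w, "W", ""), ifelse(s, "S", ""), ifelse(o, "O", ""))
}

.sequence_for_set <- function(set) {
  # canonical daily orderings per participation set; a second pattern adds
  # mild variety where it exists
  pats <- switch(set,
    H = list(c("H")),
    HW = list(c("H", "W", "H")),
    HS = list(c("H", "S", "H")),
    HO = list(c("H", "O", "H")),
    HWO = list(c("H", "W", "O", "H"), c("H", "W", "H", "O", "H")),
    HWS = list(c("H", "W", "S", "H"), c("H", "S", "W", "H")),
    HSO = list(c("H", "S", "O", "H")),
    HWSO = list(c("H", "W", "S", "O", "H"), c("H", "S", "W", "O", "H")))
  pats[[sample.int(length(pats), 1)]]
}

#' Simulate a travel survey on the toy region
#'
#' Respondents are drawn from the region's latent micro-population; their
#' activity diaries are simulated from the ground-truth behavioural
#' parameters: participation by employment/studenthood status, truncated
#' normal durations, per-trip travel times, softmax mode choice given a
#' gravity-drawn destination, all on the 3 AM-anchored day.
#'
#' @param world An `actipop_world`.
#' @param n_respondents Number of respondents (>= 1).
#' @param params Ground truth `behaviour_params`; defaults to the world's.
#' @param seed Integer seed.
#' @return A list of class `actipop_survey` with `persons`, `diary` (long,
#'   internal hours since 3 AM), `trips` (purpose, mode, origin/destination
#'   zone, distance km), and `params` (the ground truth used).
#' @export
generate_survey <- function(world, n_respondents, params = world$params,
                            seed = 1L) {
  stopifnot(inherits(world, "actipop_world"))
  if (!is.numeric(n_respondents) || n_respondents < 1) {
    stopf("n_respondents must be >= 1", class = "actipop_config_error")
  }
  with_seed(seed, .generate_survey_impl(world, as.integer(n_respondents), params))
}

.generate_survey_impl <- function(world, n, params) {
  tp <- world$truth$persons
  idx <- sample.int(nrow(tp), n, replace = TRUE)
  persons <- data.frame(respondent_id = seq_len(n),
                        age = tp$age[idx], gender = tp$gender[idx],
                        civil_status = tp$civil_status[idx],
                        employment = tp$employment[idx],
                        studenthood = tp$studenthood[idx],
                        income_class = tp$income_class[idx],
                        n_cars = tp$n_cars[idx],
                        home_zone = tp$zone_id[idx],
                        stringsAsFactors = FALSE)

  dd <- params$duration_distributions
  zones <- world$zones
  dmat <- zone_distance_matrix(zones)
  masses <- attraction_masses(world$buildings, zones$zone_id)

  diary_rows <- list()
  trip_rows <- list()
  for (i in seq_len(n)) {
    p <- persons[i, ]
    pw <- if (p$employment == 1) params$p_work[["employed"]] else params$p_work[["nonemployed"]]
    ps <- if (p$studenthood == 1) params$p_school[["student"]] else params$p_school[["nonstudent"]]
    has_w <- stats::runif(1) < pw
    has_s <- stats::runif(1) < ps
    has_o <- stats::runif(1) < params$p_other
    set <- .set_label(has_w, has_s, has_o)
    seqv <- .sequence_for_set(set)
    m <- length(seqv)
    if (m == 1L) {
      diary_rows[[i]] <- data.frame(respondent_id = i, episode = 1L,
                                    purpose = "H", start_h = 0, end_h = 24,
                                    access_mode = NA_character_,
                                    stringsAsFactors = FALSE)
      next
    }
    # non-home durations keep their exact ground-truth distributions;
    # the home stay absorbs the remainder so the day closes at 24 h
    durs <- vapply(ACTIVITY_TYPES, function(a) {
      if (a %in% seqv && a != "H") {
        d <- dd[[a]]
        rtruncnorm(1, d[["mean"]], d[["sd"]], d[["lo"]], d[["hi"]])
      } else 0
    }, numeric(1))
    tt <- params$trip_time
    gaps <- rtruncnorm(m - 1L, tt[["mean"]], tt[["sd"]], tt[["lo"]], tt[["hi"]])
    durs[["H"]] <- 24 - sum(gaps) - sum(durs)
    if (durs[["H"]] < 4) {           # rare: clamp and shrink the rest
      excess <- 4 - durs[["H"]]
      nh <- setdiff(seqv, "H")
      durs[nh] <- durs[nh] * (1 - excess / sum(durs[nh]))
      durs[["H"]] <- 4
    }
    kcount <- table(factor(seqv, levels = ACTIVITY_TYPES))
    ep_dur <- durs[seqv] / as.integer(kcount[seqv])
    starts <- cumsum(c(0, head(ep_dur, -1) + gaps))
    ends <- starts + ep_dur

    # gravity destination + softmax mode for each non-home arrival
    o_zone <- p$home_zone
    oi <- match(o_zone, zones$zone_id)
    modes_out <- rep(NA_character_, m)
    for (j in 2:m) {
      act <- seqv[j]
      if (act == "H") {
        # return home: reuse the outbound mode of the tour so far
        prev <- modes_out[!is.na(modes_out)]
        modes_out[j] <- if (length(prev)) prev[length(prev)] else "Walking"
        o_zone <- p$home_zone
        oi <- match(o_zone, zones$zone_id)
        next
      }
      mode_betas <- params$gravity_beta[[act]]
      # draw mode first from utilities at the expected nearby distance,
      # then the destination from that mode's gravity kernel
      d_near <- pmax(dmat[oi, ], 0.5)
      util <- params$mode_utility$intercepts[MODES] +
        params$mode_utility$dist_coef[MODES] * mean(d_near)
      avail <- MODES
      if (p$n_cars == 0) avail <- setdiff(avail, "Car")
      u <- util[avail]
      prb <- exp(u - max(u)); prb <- prb / sum(prb)
      mode <- sample(avail, 1, prob = prb)
      modes_out[j] <- mode
      beta <- mode_betas[[mode]]
      w <- masses[[act]] * exp(-beta * dmat[oi, ])
      di <- sample.int(nrow(zones), 1, prob = w)
      trip_rows[[length(trip_rows) + 1L]] <- data.frame(
        respondent_id = i, purpose = act, mode = mode,
        origin_zone = o_zone, destination_zone = zones$zone_id[di],
        distance_km = dmat[oi, di], stringsAsFactors = FALSE)
      o_zone <- zones$zone_id[di]
      oi <- di
    }
    diary_rows[[i]] <- data.frame(respondent_id = i, episode = seq_len(m),
                                  purpose = seqv, start_h = starts, end_h = ends,
                                  access_mode = modes_out, stringsAsFactors = FALSE)
  }
  diary <- do.call(rbind, diary_rows)
  trips <- if (length(trip_rows)) do.call(rbind, trip_rows) else
    data.frame(respondent_id = integer(), purpose = character(),
               mode = character(), origin_zone = character(),
               destination_zone = character(), distance_km = numeric())
  rownames(diary) <- NULL
  rownames(trips) <- NULL
  structure(list(persons = persons, diary = diary, trips = trips,
                 params = params),
            class = "actipop_survey")
}

#' @export
print.actipop_survey <- function(x, ...) {
  cat(sprintf("Travel survey: %d respondents, %d diary episodes, %d trips\n",
              nrow(x$persons), nrow(x$diary), nrow(x$trips)))
  invisible(x)
}

#' Zone attraction masses by activity type
#'
#' Sums building footprint areas per zone for the usage type that serves each
#' activity purpose (W: workplaces, S: schools, O: other buildings).
#'
#' @param buildings Building register data.frame.
#' @param zone_ids Character vector of all zone ids (defines output order).
#' @return Named list (W, S, O) of named numeric vectors over zones.
#' @export
attraction_masses <- function(buildings, zone_ids) {
  usage_for <- c(W = "workplace", S = "school", O = "other")
  out <- lapply(usage_for, function(u) {
    b <- buildings[buildings$usage_type == u, ]
    m <- tapply(b$footprint_area, factor(b$zone_id, levels = zone_ids), sum)
    m[is.na(m)] <- 0
    as.numeric(m)
  })
  for (k in names(out)) names(out[[k]]) <- zone_ids
  out
}

#' Generate OD matrices for the toy region
#'
#' Flows follow a gravity process with the world's ground-truth deterrence
#' rates: `flow(i, j) ~ pop_i * mass_j * exp(-beta * d_ij)`, scaled so each
#' (purpose, mode) slice totals one trip per inhabitant. Matrices are emitted
#' for the four trip purposes (work, business, other, private) and the four
#' network modes (no CarPassenger slice, as in regional transport models).
#'
#' @param world An `actipop_world`.
#' @param params `behaviour_params` carrying `gravity_beta`; defaults to the
#'   world's ground truth.
#' @param seed Unused (flows are deterministic expectations); kept for
#'   interface symmetry.
#' @return Long data.frame of class `actipop_od`: origin, destination, mode,
#'   purpose, flow.
#' @export
generate_od_matrices <- function(world, params = world$params, seed = NULL) {
  stopifnot(inherits(world, "actipop_world"))
  zones <- world$zones
  if (any(is.na(zones$centroid_x)) || any(is.na(zones$centroid_y))) {
    stopf("zones lack centroids", class = "actipop_data_error")
  }
  dmat <- zone_distance_matrix(zones)
  masses <- attraction_masses(world$buildings, zones$zone_id)
  purpose_map <- c(work = "W", business = "O", other = "O", private = "O")
  od_modes <- setdiff(MODES, "CarPassenger")
  rows <- list()
  for (pur in OD_PURPOSES) {
    act <- purpose_map[[pur]]
    for (mode in od_modes) {
      beta <- params$gravity_beta[[act]][[mode]]
      K <- sweep(exp(-beta * dmat), 2, masses[[act]], `*`)  # K[i,j] = mass_j e^{-b d_ij}
      flow <- zones$population * K / rowSums(K)
      flow <- flow * (sum(zones$population) / sum(flow))
      n <- nrow(zones)
      rows[[length(rows) + 1L]] <- data.frame(
        origin = rep(zones$zone_id, each = n),
        destination = rep(zones$zone_id, times = n),
        mode = mode, purpose = pur,
        flow = as.vector(t(flow)), stringsAsFactors = FALSE)
    }
  }
  od <- do.call(rbind, rows)
  rownames(od) <- NULL
  class(od) <- c("actipop_od", "data.frame")
  od
}
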