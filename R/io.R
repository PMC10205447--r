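# Readers and writers for the three published table schemas and the fixture
# CSVs. Published headers are reproduced verbatim (including spaces);
# `snake_case = TRUE` writes machine-friendly headers instead. All files are
# UTF-8 CSVs with `.` decimal separators; times and coordinates carry one
# decimal place.

PERSON_COLUMNS <- c("PId", "HId", "Gender", "Age", "Marital status",
                    "Employment status", "Studenthood status", "Income class",
                    "Number of cars", "DeSO", "Municipality")
HOUSEHOLD_COLUMNS <- c("HId", "Type", "Size", "Number of children",
                       "Number of cars")
ACTIVITY_COLUMNS <- c("PId", "Activity ID", "Activity Purpose",
                      "Activity Start Time", "Activity End Time",
                      "Travel Mode", "Building ID", "Building Type",
                      "Point X", "Point Y", "DeSO")

GENDER_LEVELS <- c("Male", "Female")
PURPOSE_LABELS <- c(H = "Home", W = "Work", S = "School", O = "Other")
BUILDING_LABELS <- c(detached_house = "Detached house", apartment = "Apartment",
                     workplace = "Other", school = "Other", other = "Other")
BUILDING_TYPE_LEVELS <- c("Detached house", "Apartment", "Other")

.snake <- function(x) gsub(" ", "_", tolower(x))

.check_vocab <- function(values, allowed, column, allow_na = FALSE) {
  bad <- !(values %in% allowed)
  if (allow_na) bad <- bad & !is.na(values)
  if (any(bad)) {
    stopf("column '%s': invalid value '%s' at row %d (allowed: %s)",
          column, values[which(bad)[1]], which(bad)[1],
          paste(allowed, collapse = ", "), class = "actipop_validation_error")
  }
  invisible(TRUE)
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
}

.read_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}

.require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stopf("%s: missing column(s): %s", basename(path),
          paste(miss, collapse = ", "), class = "actipop_validation_error")
  }
}

#' Write the Person table
#'
#' @param persons Internal persons data.frame (`PId`, `HId`, `gender`,
#'   `age`, `marital_status`, `employment`, `studenthood`, `income_class`,
#'   `n_cars`, `zone`, `municipality`).
#' @param path Output CSV path.
#' @param snake_case Write machine-friendly headers instead of the published
#'   ones.
#' @export
write_person_table <- function(persons, path, snake_case = FALSE) {
  .check_vocab(persons$gender, GENDER_LEVELS, "Gender")
  .check_vocab(persons$marital_status, CIVIL_LEVELS, "Marital status")
  .check_vocab(persons$income_class, INCOME_CLASSES, "Income class")
  out <- data.frame(persons$PId, persons$HId, persons$gender, persons$age,
                    persons$marital_status, persons$employment,
                    persons$studenthood, persons$income_class,
                    persons$n_cars, persons$zone, persons$municipality,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- if (snake_case) .snake(PERSON_COLUMNS) else PERSON_COLUMNS
  .write_csv(out, path)
  invisible(path)
}

#' Read the Person table
#'
#' Validates the column inventory and every categorical vocabulary, and
#' returns the internal representation.
#' @param path CSV path (published or snake_case headers).
#' @return Internal persons data.frame.
#' @export
read_person_table <- function(path) {
  df <- .read_csv(path)
  if (all(.snake(PERSON_COLUMNS) %in% names(df))) {
    names(df)[match(.snake(PERSON_COLUMNS), names(df))] <- PERSON_COLUMNS
  }
  .require_columns(df, PERSON_COLUMNS, path)
  .check_vocab(df$Gender, GENDER_LEVELS, "Gender")
  .check_vocab(df[["Marital status"]], CIVIL_LEVELS, "Marital status")
  .check_vocab(df[["Income class"]], INCOME_CLASSES, "Income class")
  .check_vocab(df[["Employment status"]], 0:1, "Employment status")
  .check_vocab(df[["Studenthood status"]], 0:1, "Studenthood status")
  data.frame(PId = as.integer(df$PId), HId = as.integer(df$HId),
             gender = df$Gender, age = as.integer(df$Age),
             marital_status = df[["Marital status"]],
             employment = as.integer(df[["Employment status"]]),
             studenthood = as.integer(df[["Studenthood status"]]),
             income_class = df[["Income class"]],
             n_cars = as.integer(df[["Number of cars"]]),
             zone = df$DeSO, municipality = df$Municipality,
             stringsAsFactors = FALSE)
}

#' Write the Household table
#' @param households Internal households data.frame.
#' @inheritParams write_person_table
#' @export
write_household_table <- function(households, path, snake_case = FALSE) {
  .check_vocab(households$type, HH_TYPES, "Type")
  out <- data.frame(households$HId, households$type, households$size,
                    households$n_children_under6, households$n_cars,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- if (snake_case) .snake(HOUSEHOLD_COLUMNS) else HOUSEHOLD_COLUMNS
  .write_csv(out, path)
  invisible(path)
}

#' Read the Household table
#' @param path CSV path.
#' @return Internal households data.frame.
#' @export
read_household_table <- function(path) {
  df <- .read_csv(path)
  if (all(.snake(HOUSEHOLD_COLUMNS) %in% names(df))) {
    names(df)[match(.snake(HOUSEHOLD_COLUMNS), names(df))] <- HOUSEHOLD_COLUMNS
  }
  .require_columns(df, HOUSEHOLD_COLUMNS, path)
  .check_vocab(df$Type, HH_TYPES, "Type")
  if (any(df$Size < 1)) {
    stopf("column 'Size': household size < 1 at row %d", which(df$Size < 1)[1],
          class = "actipop_validation_error")
  }
  data.frame(HId = as.integer(df$HId), type = df$Type,
             size = as.integer(df$Size),
             n_children_under6 = as.integer(df[["Number of children"]]),
             n_cars = as.integer(df[["Number of cars"]]),
             stringsAsFactors = FALSE)
}

#' Write the Activity-travel table
#'
#' Serializes internal 3 AM-anchored hours as decimal clock hours with one
#' decimal place; coordinates with one decimal place.
#' @param schedules Completed schedule table (internal columns `PId`,
#'   `activity_id`, `purpose`, `start_h`, `end_h`, `mode`, `building_id`,
#'   `building_type`, `x`, `y`, `zone`).
#' @inheritParams write_person_table
#' @export
write_activity_table <- function(schedules, path, snake_case = FALSE) {
  .check_vocab(schedules$purpose, names(PURPOSE_LABELS), "Activity Purpose")
  .check_vocab(schedules$mode, MODES, "Travel Mode", allow_na = TRUE)
  btype <- schedules$building_type
  btype <- ifelse(btype %in% names(BUILDING_LABELS),
                  BUILDING_LABELS[btype], btype)
  .check_vocab(btype, BUILDING_TYPE_LEVELS, "Building Type")
  out <- data.frame(
    schedules$PId, schedules$activity_id,
    PURPOSE_LABELS[schedules$purpose],
    sprintf("%.1f", clock_from_internal(schedules$start_h)),
    sprintf("%.1f", clock_from_internal(schedules$end_h)),
    ifelse(is.na(schedules$mode), "", schedules$mode),
    schedules$building_id, btype,
    sprintf("%.1f", schedules$x), sprintf("%.1f", schedules$y),
    schedules$zone, stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- if (snake_case) .snake(ACTIVITY_COLUMNS) else ACTIVITY_COLUMNS
  .write_csv(out, path)
  invisible(path)
}

#' Read the Activity-travel table
#' @param path CSV path.
#' @return Internal schedule data.frame (times converted back to hours since
#'   3 AM; purposes to {H, W, S, O}).
#' @export
read_activity_table <- function(path) {
  df <- .read_csv(path)
  if (all(.snake(ACTIVITY_COLUMNS) %in% names(df))) {
    names(df)[match(.snake(ACTIVITY_COLUMNS), names(df))] <- ACTIVITY_COLUMNS
  }
  .require_columns(df, ACTIVITY_COLUMNS, path)
  .check_vocab(df[["Activity Purpose"]], unname(PURPOSE_LABELS),
               "Activity Purpose")
  mode <- df[["Travel Mode"]]
  mode[mode == ""] <- NA_character_
  .check_vocab(mode, MODES, "Travel Mode", allow_na = TRUE)
  .check_vocab(df[["Building Type"]], BUILDING_TYPE_LEVELS, "Building Type")
  inv_purpose <- stats::setNames(names(PURPOSE_LABELS), PURPOSE_LABELS)
  start_h <- internal_from_clock(as.numeric(df[["Activity Start Time"]]))
  end_h <- internal_from_clock(as.numeric(df[["Activity End Time"]]))
  end_h[end_h <= start_h] <- 24                # day-closing episode
  data.frame(PId = as.integer(df$PId),
             activity_id = as.integer(df[["Activity ID"]]),
             purpose = unname(inv_purpose[df[["Activity Purpose"]]]),
             start_h = start_h, end_h = end_h, mode = mode,
             building_id = as.integer(df[["Building ID"]]),
             building_type = df[["Building Type"]],
             x = as.numeric(df[["Point X"]]), y = as.numeric(df[["Point Y"]]),
             zone = df$DeSO, stringsAsFactors = FALSE)
}

# ---- fixture CSV round-trip ------------------------------------------------

#' Write all toy-region input CSVs to a directory
#'
#' Emits `zones.csv`, `zone_marginals.csv`, `crosstabs.csv`, `grid.csv`,
#' `buildings.csv`, and `params.yaml` (the persisted ground-truth
#' behavioural parameters).
#' @param world An `actipop_world`.
#' @param dir Output directory (created if needed).
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_csv(world$zones, file.path(dir, "zones.csv"))
  .write_csv(world$zone_marginals, file.path(dir, "zone_marginals.csv"))
  ct <- world$crosstab
  ct$table <- "gender_age_civil"
  ic <- world$income_counts
  ic$table <- "income"
  ch <- world$children_by_hhtype
  ch$table <- "children_by_hhtype"
  all_cols <- c("municipality_id", "table", "gender", "age_group",
                "civil_status", "income_class", "household_type", "count")
  pad <- function(df) {
    for (cc in setdiff(all_cols, names(df))) df[[cc]] <- ""
    df[, all_cols]
  }
  .write_csv(rbind(pad(ct), pad(ic), pad(ch)), file.path(dir, "crosstabs.csv"))
  .write_csv(world$grid, file.path(dir, "grid.csv"))
  .write_csv(world$buildings, file.path(dir, "buildings.csv"))
  yaml::write_yaml(.params_to_list(world$params), file.path(dir, "params.yaml"))
  invisible(dir)
}

.params_to_list <- function(p) {
  list(p_work = as.list(p$p_work), p_school = as.list(p$p_school),
       p_other = p$p_other,
       duration_distributions = lapply(p$duration_distributions, as.list),
       trip_time = as.list(p$trip_time),
       mode_utility = lapply(p$mode_utility, as.list),
       gravity_beta = lapply(p$gravity_beta, as.list))
}

.params_from_list <- function(l) {
  behaviour_params(
    p_work = unlist(l$p_work), p_school = unlist(l$p_school),
    p_other = l$p_other,
    duration_distributions = lapply(l$duration_distributions, unlist),
    trip_time = unlist(l$trip_time),
    mode_utility = lapply(l$mode_utility, unlist),
    gravity_beta = lapply(l$gravity_beta, unlist))
}

#' Read a toy region back from its CSV directory
#'
#' @param dir Directory written by [write_world()].
#' @param config Optional `world_config` (age bands etc.); defaults to the
#'   standard configuration.
#' @return An `actipop_world` (without the latent truth tables).
#' @export
read_world <- function(dir, config = world_config()) {
  zones <- .read_csv(file.path(dir, "zones.csv"))
  zm <- .read_csv(file.path(dir, "zone_marginals.csv"))
  ctall <- .read_csv(file.path(dir, "crosstabs.csv"))
  ct <- ctall[ctall$table == "gender_age_civil",
              c("municipality_id", "gender", "age_group", "civil_status", "count")]
  ic <- ctall[ctall$table == "income",
              c("municipality_id", "income_class", "count")]
  ch <- ctall[ctall$table == "children_by_hhtype",
              c("municipality_id", "household_type", "count")]
  grid <- .read_csv(file.path(dir, "grid.csv"))
  buildings <- .read_csv(file.path(dir, "buildings.csv"))
  params <- if (file.exists(file.path(dir, "params.yaml"))) {
    .params_from_list(yaml::read_yaml(file.path(dir, "params.yaml")))
  } else config$behaviour
  structure(list(zones = zones, zone_marginals = zm, crosstab = ct,
                 income_counts = ic, children_by_hhtype = ch, grid = grid,
                 buildings = buildings, truth = NULL, params = params,
                 config = config),
            class = "actipop_world")
}

#' Write a simulated survey to CSVs
#'
#' Diary times are serialized as clock hours (3 AM-anchored day).
#' @param survey An `actipop_survey`.
#' @param dir Output directory.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_csv(survey$persons, file.path(dir, "survey_persons.csv"))
  di <- survey$diary
  di$start_h <- round(clock_from_internal(di$start_h), 4)
  di$end_h <- round(clock_from_internal(di$end_h), 4)
  .write_csv(di, file.path(dir, "survey_diary.csv"))
  .write_csv(survey$trips, file.path(dir, "survey_trips.csv"))
  invisible(dir)
}

#' Read a survey from CSVs
#' @param dir Directory written by [write_survey()].
#' @param params Ground-truth parameters to attach (optional).
#' @return An `actipop_survey`.
#' @export
read_survey <- function(dir, params = NULL) {
  persons <- .read_csv(file.path(dir, "survey_persons.csv"))
  di <- .read_csv(file.path(dir, "survey_diary.csv"))
  di$access_mode[di$access_mode == ""] <- NA_character_
  di$start_h <- internal_from_clock(di$start_h)
  di$end_h <- internal_from_clock(di$end_h)
  di$end_h[di$end_h <= di$start_h] <- 24
  trips <- .read_csv(file.path(dir, "survey_trips.csv"))
  structure(list(persons = persons, diary = di, trips = trips,
                 params = params),
            class = "actipop_survey")
}

#' Write OD matrices to CSV
#' @param od An `actipop_od` long data.frame.
#' @param path Output CSV.
#' @export
write_od <- function(od, path) {
  .write_csv(as.data.frame(od), path)
  invisible(path)
}

#' Read OD matrices from CSV
#' @param path CSV with columns origin, destination, mode, purpose, flow.
#' @return An `actipop_od` data.frame.
#' @export
read_od <- function(path) {
  od <- .read_csv(path)
  .require_columns(od, c("origin", "destination", "mode", "purpose", "flow"),
                   path)
  if (any(od$flow < 0)) {
    stopf("OD flows must be non-negative (row %d)", which(od$flow < 0)[1],
          class = "actipop_validation_error")
  }
  class(od) <- c("actipop_od", "data.frame")
  od
}
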