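# End-to-end pipeline: each stage reads its predecessor's CSVs from the
# output directory and writes its own, so stages are independently
# re-runnable. Every output table passes its own reader's validation before
# the stage reports success.

#' Default pipeline configuration
#'
#' @param n_municipalities,zones_per_municipality,persons_per_zone_range,seed
#'   Toy-region settings (see [world_config()]).
#' @param n_respondents Survey size.
#' @return Nested configuration list.
#' @export
default_config <- function(n_municipalities = 1L, zones_per_municipality = 4L,
                           persons_per_zone_range = c(700L, 900L),
                           n_respondents = 1500L, seed = 1L) {
  list(world = list(n_municipalities = n_municipalities,
                    zones_per_municipality = zones_per_municipality,
                    persons_per_zone_range = persons_per_zone_range),
       survey = list(n_respondents = n_respondents),
       attributes = list(car_aggregate = "max"),
       activities = list(max_tries = 100L),
       seed = seed)
}

#' Read a pipeline configuration file (YAML)
#' @param path Config file path.
#' @return Configuration list merged over the defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stopf("config file not found: %s", path, class = "actipop_config_error")
  }
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(cfg[[k]])) {
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else cfg[[k]] <- user[[k]]
  }
  cfg
}

.world_config_from <- function(cfg, seed) {
  world_config(n_municipalities = cfg$world$n_municipalities,
               zones_per_municipality = cfg$world$zones_per_municipality,
               persons_per_zone_range = unlist(cfg$world$persons_per_zone_range),
               seed = seed)
}

.log <- function(fmt, ...) message(sprintf(paste0("[actipop] ", fmt), ...))

#' Pipeline stage: generate fixtures
#'
#' Writes the toy-region input CSVs, the simulated survey, and the OD
#' matrices into `out`.
#' @param cfg Configuration list.
#' @param seed Integer seed.
#' @param out Output directory.
#' @export
stage_fixtures <- function(cfg, seed, out) {
  wc <- .world_config_from(cfg, seed)
  world <- generate_world(wc)
  write_world(world, out)
  survey <- generate_survey(world, cfg$survey$n_respondents,
                            seed = derive_seed(seed, 2))
  write_survey(survey, out)
  od <- generate_od_matrices(world)
  write_od(od, file.path(out, "od.csv"))
  # the latent truth is an in-memory diagnostic, not a pipeline input
  .log("fixtures: %d zones, %d inhabitants, %d respondents, %d buildings",
       nrow(world$zones), sum(world$zones$population),
       nrow(survey$persons), nrow(world$buildings))
  invisible(world)
}

.load_world <- function(cfg, out) read_world(out, .world_config_from(cfg, 0L))

#' Pipeline stage: population synthesis (basic attributes + households)
#' @inheritParams stage_fixtures
#' @export
stage_synthesize <- function(cfg, seed, out) {
  world <- .load_world(cfg, out)
  persons <- synthesize_population(world, seed = derive_seed(seed, 3))
  targets <- data.frame(zone_id = world$zones$zone_id,
                        single = world$zones$hh_single,
                        couple = world$zones$hh_couple,
                        other = world$zones$hh_other)
  fh <- form_households(persons, targets, seed = derive_seed(seed, 4))
  .write_csv(fh$persons, file.path(out, "persons_basic.csv"))
  hh <- fh$households
  write_household_table(hh, file.path(out, "households.csv"))
  .write_csv(hh[, c("HId", "zone_id")], file.path(out, "household_zones.csv"))
  stopifnot(nrow(read_household_table(file.path(out, "households.csv"))) == nrow(hh))
  .log("synthesize: %d persons, %d households", nrow(fh$persons), nrow(hh))
  invisible(fh)
}

#' Pipeline stage: advanced attributes
#' @inheritParams stage_fixtures
#' @export
stage_attributes <- function(cfg, seed, out) {
  world <- .load_world(cfg, out)
  survey <- read_survey(out)
  persons <- .read_csv(file.path(out, "persons_basic.csv"))
  households <- read_household_table(file.path(out, "households.csv"))
  hz <- .read_csv(file.path(out, "household_zones.csv"))
  households$zone_id <- hz$zone_id[match(households$HId, hz$HId)]
  res <- assign_advanced_attributes(persons, households, survey, world,
                                    seed = derive_seed(seed, 5),
                                    car_aggregate = cfg$attributes$car_aggregate)
  write_person_table(res$persons, file.path(out, "persons.csv"))
  write_household_table(res$households, file.path(out, "households.csv"))
  stopifnot(nrow(read_person_table(file.path(out, "persons.csv"))) ==
              nrow(res$persons))
  .log("attributes: %d employed, %d students",
       sum(res$persons$employment), sum(res$persons$studenthood))
  invisible(res)
}

#' Pipeline stage: activity generation
#' @inheritParams stage_fixtures
#' @export
stage_activities <- function(cfg, seed, out) {
  survey <- read_survey(out)
  persons <- read_person_table(file.path(out, "persons.csv"))
  res <- generate_activities(persons, survey, seed = derive_seed(seed, 6),
                             max_tries = cfg$activities$max_tries)
  .write_csv(res$schedules, file.path(out, "schedules_raw.csv"))
  .log("activities: %d episodes for %d persons (%d duration fallbacks, %d sequence fallbacks)",
       nrow(res$schedules), nrow(persons), sum(res$fallback_durations),
       sum(res$fallback_sequence))
  invisible(res)
}

#' Pipeline stage: location and mode assignment
#' @inheritParams stage_fixtures
#' @export
stage_locate <- function(cfg, seed, out) {
  world <- .load_world(cfg, out)
  survey <- read_survey(out)
  persons <- read_person_table(file.path(out, "persons.csv"))
  households <- read_household_table(file.path(out, "households.csv"))
  hz <- .read_csv(file.path(out, "household_zones.csv"))
  households$zone_id <- hz$zone_id[match(households$HId, hz$HId)]
  schedules <- .read_csv(file.path(out, "schedules_raw.csv"))
  od <- read_od(file.path(out, "od.csv"))
  res <- assign_locations(persons, households, schedules, world, survey,
                          od = od, seed = derive_seed(seed, 7))
  write_activity_table(res$schedules, file.path(out, "activities.csv"))
  utils::write.csv(as.data.frame(res$gravity), file.path(out, "gravity_fit.csv"),
                   row.names = FALSE)
  src <- attr(res$od_probs, "source")
  utils::write.csv(src, file.path(out, "od_probabilities_source.csv"),
                   row.names = FALSE)
  stopifnot(nrow(read_activity_table(file.path(out, "activities.csv"))) ==
              nrow(res$schedules))
  .log("locate: %d activity rows, %d relocated buildings",
       nrow(res$schedules), sum(res$schedules$relocated))
  invisible(res)
}

#' Pipeline stage: evaluation report
#' @inheritParams stage_fixtures
#' @export
stage_evaluate <- function(cfg, seed, out) {
  world <- .load_world(cfg, out)
  survey <- read_survey(out)
  persons <- read_person_table(file.path(out, "persons.csv"))
  rep <- marginal_diff_report(persons, world)
  utils::write.csv(rep$detail, file.path(out, "report.csv"), row.names = FALSE)
  utils::write.csv(rep$summary, file.path(out, "report_summary.csv"),
                   row.names = FALSE)
  # duration-distribution similarity vs the survey, per activity type
  acts <- read_activity_table(file.path(out, "activities.csv"))
  di <- survey$diary
  js <- vapply(ACTIVITY_TYPES, function(a) {
    gen <- acts$end_h[acts$purpose == a] - acts$start_h[acts$purpose == a]
    ref <- di$end_h[di$purpose == a] - di$start_h[di$purpose == a]
    if (!length(gen) || !length(ref)) return(NA_real_)
    js_distance_samples(gen, ref)
  }, numeric(1))
  utils::write.csv(data.frame(activity = ACTIVITY_TYPES, js_distance = js),
                   file.path(out, "js_durations.csv"), row.names = FALSE)
  .log("evaluate: gender within 0.5%%: %.0f%%; JS(durations): %s",
       100 * rep$summary$share_within_0.5[rep$summary$attribute == "gender"],
       paste(sprintf("%s=%.3f", ACTIVITY_TYPES, js), collapse = " "))
  invisible(list(report = rep, js = js))
}

#' Run the full pipeline
#'
#' Runs fixtures, synthesize, attributes, activities, locate, and evaluate
#' in order, all into one output directory. A resolved copy of the
#' configuration is written next to the outputs for provenance.
#'
#' @param config Configuration list (see [default_config()]) or a YAML path.
#' @param seed Integer master seed; every stage derives its own stream.
#' @param out Output directory.
#' @return Invisibly, the evaluation result.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L, out) {
  cfg <- if (is.character(config)) read_config(config) else config
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg$seed <- seed
  yaml::write_yaml(cfg, file.path(out, "config_resolved.yaml"))
  stage_fixtures(cfg, seed, out)
  stage_synthesize(cfg, seed, out)
  stage_attributes(cfg, seed, out)
  stage_activities(cfg, seed, out)
  stage_locate(cfg, seed, out)
  res <- stage_evaluate(cfg, seed, out)
  invisible(res)
}
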