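# Shared, memoized test fixtures. testthat sources helpers once per run, so
# expensive fixtures (worlds, surveys, pipeline stages) are built at most
# once and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# Small region for unit tests: 4 zones, ~150-220 inhabitants each.
tw <- function() fixture("tw",
  generate_world(world_config(1, 4, c(150L, 220L), seed = 42)))

tsurv <- function() fixture("ts", generate_survey(tw(), 600, seed = 7))

tw_synth <- function() fixture("tw_synth", {
  w <- tw()
  persons <- synthesize_population(w, seed = 13)
  targets <- data.frame(zone_id = w$zones$zone_id,
                        single = w$zones$hh_single,
                        couple = w$zones$hh_couple,
                        other = w$zones$hh_other)
  suppressWarnings(form_households(persons, targets, seed = 14))
})

tw_attr <- function() fixture("tw_attr", {
  fh <- tw_synth()
  assign_advanced_attributes(fh$persons, fh$households, tsurv(), tw(), seed = 15)
})

tw_acts <- function() fixture("tw_acts",
  generate_activities(tw_attr()$persons, tsurv(), seed = 16))

tw_loc <- function() fixture("tw_loc", {
  at <- tw_attr()
  suppressWarnings(assign_locations(at$persons, at$households,
                                    tw_acts()$schedules, tw(), tsurv(),
                                    od = generate_od_matrices(tw()),
                                    seed = 17))
})

# Larger region for the property-based suite: 10 zones of ~1000 inhabitants.
acc_world <- function() fixture("acc_world",
  generate_world(world_config(1, 10, c(950L, 1050L), seed = 11)))

acc_survey <- function() fixture("acc_survey",
  generate_survey(acc_world(), 2500, seed = 12))

acc_synth <- function() fixture("acc_synth", {
  w <- acc_world()
  persons <- synthesize_population(w, seed = 13)
  targets <- data.frame(zone_id = w$zones$zone_id,
                        single = w$zones$hh_single,
                        couple = w$zones$hh_couple,
                        other = w$zones$hh_other)
  suppressWarnings(form_households(persons, targets, seed = 14))
})

acc_attr <- function() fixture("acc_attr", {
  fh <- acc_synth()
  assign_advanced_attributes(fh$persons, fh$households, acc_survey(),
                             acc_world(), seed = 15)
})

acc_acts <- function() fixture("acc_acts",
  generate_activities(acc_attr()$persons, acc_survey(), seed = 16))

acc_loc <- function() fixture("acc_loc", {
  at <- acc_attr()
  suppressWarnings(assign_locations(at$persons, at$households,
                                    acc_acts()$schedules, acc_world(),
                                    acc_survey(),
                                    od = generate_od_matrices(acc_world()),
                                    seed = 17))
})
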