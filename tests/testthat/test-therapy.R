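test_that("norepinephrine starts only after an unresponsive fluid
           challenge of at least an hour", {
  low_map <- make_sample(map_mmHg = 50)
  after_90min <- therapy_state(minutes_on_fluid_resuscitation = 90,
                               time_h = 18)
  after_30min <- therapy_state(minutes_on_fluid_resuscitation = 30,
                               time_h = 18)
  expect_true("start_norepinephrine" %in%
                evaluate_triggers(low_map, after_90min))
  expect_false("start_norepinephrine" %in%
                 evaluate_triggers(low_map, after_30min))
  # MAP exactly at the trigger counts ("decreased to 55 mmHg")
  expect_true("start_norepinephrine" %in%
                evaluate_triggers(make_sample(map_mmHg = 55), after_90min))
  expect_false("start_norepinephrine" %in%
                 evaluate_triggers(make_sample(map_mmHg = 56), after_90min))
  # already running -> no new start action
  running <- therapy_state(norepinephrine_ug_kg_min = 0.05,
                           minutes_on_fluid_resuscitation = 120,
                           time_h = 18)
  expect_false("start_norepinephrine" %in%
                 evaluate_triggers(low_map, running))
})

test_that("furosemide fires on oliguria despite fluids or on elevated
           ELWI, and repeats when refractory", {
  fluids <- therapy_state(minutes_on_fluid_resuscitation = 60, time_h = 18)
  oliguric <- make_sample(urine_output_ml_kg_h = 0.1)
  expect_true("give_furosemide" %in% evaluate_triggers(oliguric, fluids))
  # no fluids running: oliguria alone does not trigger
  expect_false("give_furosemide" %in%
                 evaluate_triggers(oliguric, therapy_state(time_h = 18)))
  # ELWI pathway works without fluids
  wet <- make_sample(elwi_ml_kg = 12)
  expect_true("give_furosemide" %in%
                evaluate_triggers(wet, therapy_state(time_h = 18)))
  # refractory after one dose an hour ago: repeat
  dosed <- therapy_state(furosemide_cum_mg = 10,
                         minutes_on_fluid_resuscitation = 120,
                         time_h = 18, last_furosemide_time_h = 17)
  prev <- make_sample(time_h = 17, urine_output_ml_kg_h = 0.1,
                      elwi_ml_kg = 12)
  now <- make_sample(urine_output_ml_kg_h = 0.1, elwi_ml_kg = 12)
  expect_true("give_furosemide" %in%
                evaluate_triggers(now, dosed, previous = prev))
  # responsive (urine more than doubled): hold the repeat dose
  improved <- make_sample(urine_output_ml_kg_h = 0.22, elwi_ml_kg = 12)
  prev_low <- make_sample(time_h = 17, urine_output_ml_kg_h = 0.1,
                          elwi_ml_kg = 13.5)
  expect_false("give_furosemide" %in%
                 evaluate_triggers(improved, dosed, previous = prev_low))
})

test_that("no action fires on a sample inside all target ranges", {
  healthy <- make_sample(ci_L_min_m2 = 3.8, hr_bpm = 95, elwi_ml_kg = 7)
  expect_length(evaluate_triggers(healthy, therapy_state(time_h = 18)), 0)
})

test_that("fluid boluses are indicated below the SVI target range", {
  low_svi <- make_sample(ci_L_min_m2 = 2.8, hr_bpm = 130)  # SVI ~21.5
  expect_true("give_fluid_bolus" %in%
                evaluate_triggers(low_svi, therapy_state(time_h = 18)))
})

test_that("trigger evaluation is deterministic and validates timestamps", {
  s <- make_sample(map_mmHg = 50, urine_output_ml_kg_h = 0.1,
                   elwi_ml_kg = 12, ci_L_min_m2 = 2.5, hr_bpm = 140)
  st <- therapy_state(minutes_on_fluid_resuscitation = 90, time_h = 18)
  expect_identical(evaluate_triggers(s, st), evaluate_triggers(s, st))
  mismatched <- therapy_state(time_h = 17)
  expect_error(evaluate_triggers(s, mismatched), "different times")
})

test_that("therapy policies validate their thresholds", {
  expect_error(therapy_policy(map_norepi_trigger_mmHg = -5))
  expect_error(therapy_policy(svi_target_range = c(45, 35)), "ordered")
  pol <- therapy_policy(map_norepi_trigger_mmHg = 60)
  expect_equal(pol$map_norepi_trigger_mmHg, 60)
})

test_that("event logs reconstruct per-hour therapy states", {
  events <- tibble::tibble(
    animal_id = "a",
    time_h = c(6, 16, 17, 17, 18),
    drug = c("crystalloid", "crystalloid", "norepinephrine", "furosemide",
             "furosemide"),
    dose = c(15, 15, 0.05, 10, 10),
    units = c("ml_kg", "ml_kg", "ug_kg_min", "mg", "mg"))
  times <- tibble::tibble(animal_id = "a", time_h = c(16, 17, 18, 20))
  st <- therapy_state_table(events, times)
  expect_equal(st$norepinephrine_ug_kg_min, c(0, 0.05, 0.05, 0.05))
  expect_equal(st$furosemide_cum_mg, c(0, 10, 20, 20))
  # maintenance fluids at 6 h do not start the resuscitation clock
  expect_equal(st$minutes_on_fluid_resuscitation, c(0, 60, 120, 240))
})
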