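test_that("respiration scores follow the printed PaO2/FiO2 thresholds", {
  expect_identical(score_respiration(c(450, 400, 250, 50)),
                   c(0L, 0L, 2L, 4L))
  expect_identical(score_respiration(c(399.99, 300, 299.99, 200, 100,
                                       99.99)),
                   c(1L, 1L, 2L, 2L, 3L, 4L))
  expect_error(score_respiration(-1), "pao2_fio2")
  expect_error(score_respiration(NaN))
})

test_that("cardiovascular scoring uses the pig MAP bands with vasopressor
           precedence", {
  expect_identical(score_cardiovascular(80, therapy_state()), 0L)
  expect_identical(score_cardiovascular(75, therapy_state()), 0L)
  expect_identical(score_cardiovascular(70, therapy_state()), 1L)
  expect_identical(score_cardiovascular(60, therapy_state()), 2L)
  low_dose <- therapy_state(norepinephrine_ug_kg_min = 0.05)
  high_dose <- therapy_state(norepinephrine_ug_kg_min = 0.2)
  expect_identical(score_cardiovascular(60, low_dose), 3L)
  expect_identical(score_cardiovascular(60, high_dose), 4L)
  # any vasopressor dominates a normal pressure
  expect_identical(score_cardiovascular(90, high_dose), 4L)
  expect_error(score_cardiovascular(0, therapy_state()))
})

test_that("human-mode cardiovascular thresholds differ where the table
           prints italic values", {
  # MAP 72: abnormal for pigs (cutoff 75), normal for humans (cutoff 70)
  expect_identical(score_cardiovascular(72, therapy_state(), "pig"), 1L)
  expect_identical(score_cardiovascular(72, therapy_state(), "human"), 0L)
  dop_low <- therapy_state(dopamine_ug_kg_min = 3)
  dop_high <- therapy_state(dopamine_ug_kg_min = 20)
  dob <- therapy_state(dobutamine_ug_kg_min = 5)
  expect_identical(score_cardiovascular(80, dop_low, "human"), 2L)
  expect_identical(score_cardiovascular(80, dob, "human"), 2L)
  expect_identical(score_cardiovascular(80, dop_high, "human"), 4L)
})

test_that("renal scoring combines urine bands with furosemide precedence", {
  expect_identical(score_renal(c(0.6, 0.5, 0.4, 0.2), therapy_state()),
                   c(0L, 0L, 1L, 2L))
  expect_identical(score_renal(0.1, therapy_state(furosemide_cum_mg = 10)),
                   3L)
  expect_identical(score_renal(0.1, therapy_state(furosemide_cum_mg = 20)),
                   4L)
  expect_identical(score_renal(1.0, therapy_state(furosemide_cum_mg = 20)),
                   4L)
})

test_that("liver and coagulation scores follow the laboratory bands", {
  expect_identical(score_liver(c(15, 20, 25, 50, 150, 250)),
                   c(0L, 0L, 1L, 2L, 3L, 4L))
  expect_identical(score_coagulation(c(250, 200, 180, 120, 80, 30)),
                   c(0L, 0L, 1L, 2L, 3L, 4L))
  # human platelet bands are shifted one category down
  expect_identical(score_coagulation(180, mode = "human"), 0L)
  expect_identical(score_coagulation(120, mode = "human"), 1L)
})

test_that("compute_psofa sums the five independent domain calls", {
  res <- compute_psofa(make_sample(map_mmHg = 70, pao2_fio2 = 250,
                                   urine_output_ml_kg_h = 0.4,
                                   bilirubin_umol_L = 25,
                                   platelets_1e9_L = 180))
  expect_identical(res$total_3d, 4L)   # 2 + 1 + 1
  expect_identical(res$total_5d, 6L)   # + 1 + 1
  expect_false(res$three_domain_only)

  best <- compute_psofa(make_sample())
  expect_identical(best$total_3d, 0L)
  expect_identical(best$total_5d, 0L)

  worst <- compute_psofa(
    make_sample(map_mmHg = 40, pao2_fio2 = 50, urine_output_ml_kg_h = 0.05,
                bilirubin_umol_L = 300, platelets_1e9_L = 20),
    therapy_state(norepinephrine_ug_kg_min = 0.3, furosemide_cum_mg = 30))
  expect_identical(worst$total_3d, 12L)
  expect_identical(worst$total_5d, 20L)
})

test_that("missing laboratory values flag a 3-domain-only result instead of
           imputing zeros", {
  res <- compute_psofa(make_sample(bilirubin_umol_L = NA))
  expect_true(res$three_domain_only)
  expect_true(is.na(res$total_5d))
  expect_false(is.na(res$total_3d))
  expect_error(compute_psofa(list(time_h = 1)), "missing")
  expect_error(compute_psofa(make_sample(map_mmHg = NA)), "map")
})

test_that("score_timeseries averages hourly totals and rejects empty
           windows", {
  traj <- make_trajectory(16:24, map_mmHg = 70, pao2_fio2 = 250,
                          urine_output_ml_kg_h = 0.4,
                          bilirubin_umol_L = 25, platelets_1e9_L = 180)
  ts <- score_timeseries(traj)
  expect_equal(nrow(ts$scores), 9)
  expect_equal(ts$animal_summary$mean_5d, 6)

  # a staircase of hourly totals 0..8 -> unrounded mean 4.0
  traj2 <- make_trajectory(16:24)
  traj2$map_mmHg <- c(90, 90, 90, 90, 90, 70, 60, 60, 60)
  traj2$pao2_fio2 <- c(450, 350, 250, 150, 50, 50, 50, 50, 50)
  traj2$urine_output_ml_kg_h <- c(1, 1, 1, 1, 1, 1, 1, 0.4, 0.2)
  ts2 <- score_timeseries(traj2)
  expect_identical(ts2$scores$total_3d, 0:8)
  expect_equal(ts2$animal_summary$mean_3d, 4)

  expect_error(score_timeseries(traj, window = c(30, 40)), "window")
})

test_that("per-hour medians are taken across animals", {
  a <- make_trajectory(16:18, animal_id = "a", map_mmHg = 90)
  b <- make_trajectory(16:18, animal_id = "b", map_mmHg = 70)
  c <- make_trajectory(16:18, animal_id = "c", map_mmHg = 60)
  ts <- score_timeseries(dplyr::bind_rows(a, b, c))
  expect_equal(ts$hourly_median$median_3d, rep(1, 3))
  expect_equal(ts$hourly_median$n_animals, rep(3, 3))
})

test_that("monitoring invariants are enforced", {
  expect_error(monitoring_sample(time_h = -1), "time_h")
  expect_error(monitoring_sample(sao2_fraction = 1.2), "sao2")
  expect_error(monitoring_sample(pao2_fio2 = 300, pao2_mmHg = 95,
                                 fio2_fraction = 0.21), "inconsistent")
  ok <- monitoring_sample(pao2_mmHg = 94.5, fio2_fraction = 0.21)
  expect_true(is.na(ok$pao2_fio2))  # derivation happens at scoring time
})
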