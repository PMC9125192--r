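test_that("the same seed reproduces the cohort exactly", {
  cfg <- cohort_config(n_animals = 12, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$monitoring, b$monitoring)
  expect_identical(a$therapy_events, b$therapy_events)
  expect_identical(a$animals, b$animals)
  expect_identical(a$hemoculture, b$hemoculture)
})

test_that("generated values respect the monitoring invariants", {
  coh <- generate_cohort(cohort_config(n_animals = 20, seed = 5))
  mon <- coh$monitoring
  expect_true(all(mon$time_h >= 0))
  expect_true(all(mon$sao2_fraction >= 0 & mon$sao2_fraction <= 1))
  expect_true(all(mon$svo2_fraction <= mon$sao2_fraction))
  num_cols <- vapply(mon, is.numeric, logical(1))
  expect_true(all(as.matrix(mon[, num_cols]) >= 0))
  expect_equal(mon$pao2_fio2, mon$pao2_mmHg / mon$fio2_fraction)
  # validation round-trip through the scoring-layer checks
  expect_silent(psofa:::validate_monitoring(mon))
})

test_that("template quotas reproduce the study flow", {
  coh <- generate_cohort(cohort_config(seed = 99))  # default 36 animals
  counts <- table(coh$animals$template)
  expect_equal(unname(counts["sham"]), 9)
  expect_equal(unname(counts["non_responder"]), 5)
  expect_equal(unname(counts["fulminant"]), 3)
  expect_equal(unname(counts["sepsis"]), 10)
  expect_equal(unname(counts["septic_shock"]), 9)
  # fulminant animals stop before the monitoring window
  ful <- coh$animals$animal_id[coh$animals$template == "fulminant"]
  last <- tapply(coh$monitoring$time_h, coh$monitoring$animal_id, max)
  expect_true(all(last[ful] <= 15))
  expect_true(all(last[setdiff(names(last), ful)] == 24))
})

test_that("shock-template animals score above sepsis-template animals in
           every seed", {
  for (seed in 1:5) {
    coh <- generate_cohort(cohort_config(n_animals = 30, seed = seed))
    rec <- score_recovery(coh)
    med <- tapply(rec$per_animal$mean_5d, rec$per_animal$template, median)
    expect_gt(med[["septic_shock"]], med[["sepsis"]])
  }
})

test_that("zero coupling decouples the recovered correlation from the
           inoculum load", {
  rs <- vapply(1:4, function(seed) {
    coh <- generate_cohort(cohort_config(n_animals = 60, sham_fraction = 0,
                                         severity_coupling = 0,
                                         seed = seed))
    score_recovery(coh)$r
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.25)
})

test_that("vasopressor and diuretic states arise endogenously in shock
           trajectories", {
  coh <- generate_cohort(cohort_config(n_animals = 30, seed = 21))
  shock <- coh$animals$animal_id[coh$animals$template == "septic_shock"]
  ev <- coh$therapy_events
  for (id in shock) {
    mine <- ev[ev$animal_id == id, ]
    expect_true("norepinephrine" %in% mine$drug)
    expect_true("furosemide" %in% mine$drug)
    # norepinephrine starts only inside the monitoring window
    expect_true(min(mine$time_h[mine$drug == "norepinephrine"]) >= 16)
  }
  sham <- coh$animals$animal_id[coh$animals$template == "sham"]
  expect_false(any(ev$drug[ev$animal_id %in% sham] == "norepinephrine"))
})

test_that("perturb transforms single parameters and validates the result", {
  cfg <- cohort_config(n_animals = 10, severity_coupling = 0.5)
  same <- perturb(cfg, "severity_coupling", 0)
  expect_equal(same$severity_coupling, 0.5)
  up <- perturb(cfg, "severity_coupling", 0.3)
  expect_equal(up$severity_coupling, 0.8)
  expect_error(perturb(cfg, "n_animals", -20), "n_animals")
  expect_error(perturb(cfg, "not_a_parameter", 1), "Unknown")
})

test_that("cohort configuration validates its fields", {
  expect_error(cohort_config(n_animals = 1), "n_animals")
  expect_error(cohort_config(severity_coupling = -1), "severity_coupling")
  expect_error(cohort_config(cfu_log10_range = c(9, 5)), "ordered")
})
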