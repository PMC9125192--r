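# Build a flat trajectory with a given score profile plus its score table.
classify_case <- function(total_target = 0, lactate = 1.2, norepi = 0,
                          map = 90) {
  # reach the requested total via respiration (0-4) plus coagulation (+1)
  pf <- c(450, 350, 250, 150, 50)[min(total_target, 4) + 1]
  plt <- if (total_target > 4) 180 else 350
  traj <- make_trajectory(16:24, map_mmHg = map, pao2_fio2 = pf,
                          platelets_1e9_L = plt, lactate_mmol_L = lactate)
  therapy <- if (norepi > 0) {
    tibble::tibble(animal_id = "pig001", time_h = 17,
                   drug = "norepinephrine", dose = norepi,
                   units = "ug_kg_min")
  } else NULL
  scores <- score_timeseries(traj, therapy)$scores
  classify_animal(scores, traj, therapy)
}

test_that("sepsis requires both the score and the lactate criterion", {
  expect_equal(as.character(classify_case(3, lactate = 2.5)$label), "sepsis")
  expect_equal(as.character(classify_case(1, lactate = 1.0)$label),
               "non_responder")
  # score >= 2 but lactate below threshold -> not sepsis
  expect_equal(as.character(classify_case(3, lactate = 1.0)$label),
               "non_responder")
  # lactate high but score below threshold -> not sepsis
  expect_equal(as.character(classify_case(1, lactate = 3)$label),
               "non_responder")
})

test_that("septic shock is sepsis plus vasopressor dependence at
           allocation", {
  res <- classify_case(8, lactate = 3, norepi = 0.1, map = 65)
  expect_equal(as.character(res$label), "septic_shock")
  expect_match(res$criteria_met, "vasopressor_dependent")
  expect_match(res$criteria_met, "psofa_ge2")
  expect_match(res$criteria_met, "lactate_ge2")
  # same severity without the vasopressor is sepsis
  expect_equal(as.character(classify_case(8, lactate = 3)$label), "sepsis")
})

test_that("animals qualifying only after the allocation hour are labelled
           at the first qualifying time", {
  traj <- make_trajectory(16:24, lactate_mmol_L = 2.5)
  traj$pao2_fio2 <- c(rep(450, 6), rep(250, 3))  # deteriorates at 22 h
  scores <- score_timeseries(traj)$scores
  res <- classify_animal(scores, traj)
  expect_equal(as.character(res$label), "sepsis")
  expect_equal(res$decision_time_h, 22)
})

test_that("saline controls pass through as sham", {
  res <- classify_animal(NULL, make_trajectory(), inoculated = FALSE)
  expect_equal(as.character(res$label), "sham")
})

test_that("fulminant flag needs the full conjunction of early
           deteriorations", {
  flat <- dplyr::bind_rows(make_sample(time_h = 0),
                           make_sample(time_h = 6))
  expect_false(flag_fulminant(flat)$flag)

  crash <- dplyr::bind_rows(
    monitoring_sample(time_h = 0, lactate_mmol_L = 1.2,
                      bilirubin_umol_L = 8, svo2_fraction = 0.70,
                      albumin_g_L = 35),
    monitoring_sample(time_h = 6, lactate_mmol_L = 4, bilirubin_umol_L = 16,
                      svo2_fraction = 0.48, albumin_g_L = 24))
  expect_true(flag_fulminant(crash)$flag)

  lactate_only <- crash
  lactate_only$bilirubin_umol_L[2] <- 9
  lactate_only$svo2_fraction[2] <- 0.70
  lactate_only$albumin_g_L[2] <- 35
  expect_false(flag_fulminant(lactate_only)$flag)

  flagged <- flat
  flagged$acute_failure <- c(FALSE, TRUE)
  expect_true(flag_fulminant(flagged)$flag)
})

test_that("a trajectory ending before allocation must be fulminant", {
  early <- dplyr::bind_rows(make_sample(time_h = 0), make_sample(time_h = 6))
  early$animal_id <- "pig001"
  expect_error(classify_animal(NULL, early), "allocation")
})

test_that("labels partition a synthetic cohort and shock implies the
           sepsis criteria", {
  for (seed in c(11, 12)) {
    coh <- generate_cohort(cohort_config(n_animals = 24, seed = seed))
    labels <- classify_cohort(coh$monitoring, coh$therapy_events,
                              coh$animals)
    expect_equal(nrow(labels), 24)
    expect_equal(anyDuplicated(labels$animal_id), 0)
    expect_false(any(is.na(labels$label)))
    shock <- labels[labels$label == "septic_shock", ]
    expect_true(all(grepl("psofa_ge2", shock$criteria_met)))
    expect_true(all(grepl("lactate_ge2", shock$criteria_met)))
  }
})

test_that("raising every domain score of a sepsis trajectory never demotes
           the label", {
  base <- classify_case(2, lactate = 2.5)
  expect_equal(as.character(base$label), "sepsis")
  for (tot in 3:5) {
    worse <- classify_case(tot, lactate = 2.5)
    expect_true(as.character(worse$label) %in% c("sepsis", "septic_shock"))
  }
})
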