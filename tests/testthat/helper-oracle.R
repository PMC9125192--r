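# Independent chain-of-ifs transcription of the pig-mode scoring table,
# kept deliberately separate from the package's vectorised engine so the
# two can disagree.

oracle_respiration <- function(pf) {
  if (pf >= 400) 0L else if (pf >= 300) 1L else if (pf >= 200) 2L
  else if (pf >= 100) 3L else 4L
}

oracle_cardiovascular <- function(map, norepi) {
  if (norepi > 0.1) 4L else if (norepi > 0) 3L
  else if (map < 65) 2L else if (map < 75) 1L else 0L
}

oracle_renal <- function(urine, furo) {
  if (furo > 10) 4L else if (furo > 0) 3L
  else if (urine < 0.25) 2L else if (urine < 0.5) 1L else 0L
}

oracle_liver <- function(bili) {
  if (bili > 204) 4L else if (bili > 101) 3L else if (bili > 32) 2L
  else if (bili > 20) 1L else 0L
}

oracle_coagulation <- function(plt) {
  if (plt < 50) 4L else if (plt < 100) 3L else if (plt < 150) 2L
  else if (plt < 200) 1L else 0L
}

# Values straddling every printed threshold by a small epsilon.
straddle <- function(cuts, eps = 1e-6) {
  c(cuts - eps, cuts, cuts + eps)
}

# A healthy monitoring row with selective overrides.
make_sample <- function(...) {
  args <- list(time_h = 18, map_mmHg = 90, pao2_fio2 = 450,
               urine_output_ml_kg_h = 1, bilirubin_umol_L = 8,
               platelets_1e9_L = 350, lactate_mmol_L = 1.2)
  over <- list(...)
  args[names(over)] <- over
  do.call(monitoring_sample, args)
}

# A flat multi-hour trajectory for one animal built from one row template.
make_trajectory <- function(times = 16:24, animal_id = "pig001", ...) {
  rows <- lapply(times, function(t) make_sample(time_h = t, ...))
  df <- dplyr::bind_rows(rows)
  df$animal_id <- animal_id
  df
}
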