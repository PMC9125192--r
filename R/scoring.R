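#' pSOFA domain scores
#'
#' Score the five organ-dysfunction domains of the pig-specific Sequential
#' Organ Failure Assessment (pSOFA). Each domain maps a physiological or
#' laboratory measurement (plus, for the cardiovascular and renal domains,
#' the supportive-therapy state) to an integer score 0--4. The pig-adapted
#' thresholds differ from the human SOFA in the cardiovascular domain
#' (mean arterial pressure above 75 mmHg is normal, reflecting the
#' blood-pressure-lowering effect of anesthesia) and the coagulation domain
#' (platelet counts up to 200 x 10^9 L^-1 are normal, reflecting the broader
#' porcine platelet range); `mode = "human"` selects the conventional human
#' thresholds instead.
#'
#' Threshold conventions: categories are half-open and the healthy ("0")
#' category is closed at its printed boundary, so a PaO2/FiO2 ratio of
#' exactly 400, a MAP of exactly 75 mmHg, urine output of exactly
#' 0.5 mL kg^-1 h^-1, bilirubin of exactly 20 umol L^-1 and platelets of
#' exactly 200 x 10^9 L^-1 all score 0. Vasopressor- and diuretic-based
#' scores (3--4) take precedence over the measurement-based pathway: the
#' reported domain score is the maximum of the two.
#'
#' @param pao2_fio2 PaO2/FiO2 ratio (dimensionless, PaO2 in mmHg, FiO2 as a
#'   fraction).
#' @param map_mmHg Mean arterial pressure (mmHg).
#' @param urine_output_ml_kg_h Hourly diuresis (mL kg^-1 h^-1).
#' @param bilirubin_umol_L Plasma total bilirubin (umol L^-1).
#' @param platelets_1e9_L Platelet count (x 10^9 L^-1).
#' @param therapy A [therapy_state()] carrying the norepinephrine dose rate
#'   (ug kg^-1 min^-1), cumulative furosemide dose (mg) and, for human-mode
#'   scoring, optional dopamine/epinephrine/dobutamine dose rates.
#' @param mode `"pig"` (default) for the pig-adapted thresholds, `"human"`
#'   for the conventional human SOFA thresholds.
#' @return An integer vector of scores in `0:4`.
#' @examples
#' score_respiration(c(450, 400, 250, 50))
#' score_cardiovascular(80, therapy_state())
#' score_cardiovascular(60, therapy_state(norepinephrine_ug_kg_min = 0.2))
#' score_renal(0.1, therapy_state(furosemide_cum_mg = 20))
#' score_liver(c(15, 25, 250))
#' score_coagulation(c(250, 80))
#' @name psofa_domains
NULL

#' @rdname psofa_domains
#' @export
score_respiration <- function(pao2_fio2) {
  check_numeric(pao2_fio2, "pao2_fio2", min = 0)
  4L - findInterval(pao2_fio2, c(100, 200, 300, 400))
}

#' @rdname psofa_domains
#' @export
score_cardiovascular <- function(map_mmHg, therapy = therapy_state(),
                                 mode = c("pig", "human")) {
  mode <- match.arg(mode)
  check_numeric(map_mmHg, "map_mmHg", min = 0, strict_min = TRUE)
  nor <- therapy$norepinephrine_ug_kg_min
  check_numeric(nor, "norepinephrine_ug_kg_min", min = 0)
  if (mode == "pig") {
    map_score <- (map_mmHg < 75) + (map_mmHg < 65)
    drug_score <- ifelse(nor > 0.1, 4L, ifelse(nor > 0, 3L, 0L))
  } else {
    dop <- therapy$dopamine_ug_kg_min %||% 0
    epi <- therapy$epinephrine_ug_kg_min %||% 0
    dob <- therapy$dobutamine_ug_kg_min %||% 0
    check_numeric(dop, "dopamine_ug_kg_min", min = 0)
    check_numeric(epi, "epinephrine_ug_kg_min", min = 0)
    check_numeric(dob, "dobutamine_ug_kg_min", min = 0)
    map_score <- as.integer(map_mmHg < 70)
    s4 <- dop > 15 | epi > 0.1 | nor > 0.1
    s3 <- !s4 & (dop > 5 | (epi > 0 & epi <= 0.1) | (nor > 0 & nor <= 0.1))
    s2 <- !s4 & !s3 & ((dop > 0 & dop <= 5) | dob > 0)
    drug_score <- 4L * s4 + 3L * s3 + 2L * s2
  }
  as.integer(pmax(map_score, drug_score))
}

#' @rdname psofa_domains
#' @export
score_renal <- function(urine_output_ml_kg_h, therapy = therapy_state()) {
  check_numeric(urine_output_ml_kg_h, "urine_output_ml_kg_h", min = 0)
  furo <- therapy$furosemide_cum_mg
  check_numeric(furo, "furosemide_cum_mg", min = 0)
  urine_score <- (urine_output_ml_kg_h < 0.5) + (urine_output_ml_kg_h < 0.25)
  drug_score <- ifelse(furo > 10, 4L, ifelse(furo > 0, 3L, 0L))
  as.integer(pmax(urine_score, drug_score))
}

#' @rdname psofa_domains
#' @export
score_liver <- function(bilirubin_umol_L) {
  check_numeric(bilirubin_umol_L, "bilirubin_umol_L", min = 0)
  findInterval(bilirubin_umol_L, c(20, 32, 101, 204), left.open = TRUE)
}

#' @rdname psofa_domains
#' @export
score_coagulation <- function(platelets_1e9_L, mode = c("pig", "human")) {
  mode <- match.arg(mode)
  check_numeric(platelets_1e9_L, "platelets_1e9_L", min = 0)
  cuts <- if (mode == "pig") c(50, 100, 150, 200) else c(20, 50, 100, 150)
  4L - findInterval(platelets_1e9_L, cuts)
}

#' Construct a single animal-hour monitoring sample
#'
#' A light validating constructor for one row of hourly monitoring data.
#' All arguments are optional except that scoring downstream requires the
#' three online domains (respiration, MAP, urine output). `pao2_fio2` is
#' derived from `pao2_mmHg / fio2_fraction` when absent and both parts are
#' present; when all three are supplied they must agree.
#'
#' @param time_h Hours since inoculation (>= 0).
#' @param map_mmHg,pao2_fio2,urine_output_ml_kg_h Online 3-domain inputs.
#' @param bilirubin_umol_L,platelets_1e9_L Laboratory 5-domain inputs.
#' @param lactate_mmol_L Venous lactate (mmol L^-1).
#' @param pao2_mmHg,fio2_fraction,sao2_fraction,svo2_fraction Blood-gas
#'   quantities; fractions must lie in `[0, 1]`.
#' @param hb_g_dL,co_L_min,ci_L_min_m2,cvp_mmHg,hr_bpm Hemodynamic inputs.
#' @param ast_U_L,alt_U_L,creatinine_umol_L,albumin_g_L,wbc_1e9_L,elwi_ml_kg
#'   Further laboratory / thermodilution values.
#' @param tnfa,il10,bet,hmgb1 Plasma biomarker concentrations (assay units).
#' @return A one-row tibble.
#' @export
monitoring_sample <- function(time_h = 0, map_mmHg = NA, pao2_fio2 = NA,
                              urine_output_ml_kg_h = NA,
                              bilirubin_umol_L = NA, platelets_1e9_L = NA,
                              lactate_mmol_L = NA, pao2_mmHg = NA,
                              fio2_fraction = NA, sao2_fraction = NA,
                              svo2_fraction = NA, hb_g_dL = NA,
                              co_L_min = NA, ci_L_min_m2 = NA, cvp_mmHg = NA,
                              hr_bpm = NA, ast_U_L = NA, alt_U_L = NA,
                              creatinine_umol_L = NA, albumin_g_L = NA,
                              wbc_1e9_L = NA, elwi_ml_kg = NA, tnfa = NA,
                              il10 = NA, bet = NA, hmgb1 = NA) {
  out <- tibble::tibble(
    time_h = as.numeric(time_h), map_mmHg = as.numeric(map_mmHg),
    pao2_fio2 = as.numeric(pao2_fio2),
    urine_output_ml_kg_h = as.numeric(urine_output_ml_kg_h),
    bilirubin_umol_L = as.numeric(bilirubin_umol_L),
    platelets_1e9_L = as.numeric(platelets_1e9_L),
    lactate_mmol_L = as.numeric(lactate_mmol_L),
    pao2_mmHg = as.numeric(pao2_mmHg),
    fio2_fraction = as.numeric(fio2_fraction),
    sao2_fraction = as.numeric(sao2_fraction),
    svo2_fraction = as.numeric(svo2_fraction),
    hb_g_dL = as.numeric(hb_g_dL), co_L_min = as.numeric(co_L_min),
    ci_L_min_m2 = as.numeric(ci_L_min_m2), cvp_mmHg = as.numeric(cvp_mmHg),
    hr_bpm = as.numeric(hr_bpm), ast_U_L = as.numeric(ast_U_L),
    alt_U_L = as.numeric(alt_U_L),
    creatinine_umol_L = as.numeric(creatinine_umol_L),
    albumin_g_L = as.numeric(albumin_g_L), wbc_1e9_L = as.numeric(wbc_1e9_L),
    elwi_ml_kg = as.numeric(elwi_ml_kg), tnfa = as.numeric(tnfa),
    il10 = as.numeric(il10), bet = as.numeric(bet), hmgb1 = as.numeric(hmgb1)
  )
  validate_monitoring(out)
}

validate_monitoring <- function(df) {
  check_numeric(df$time_h, "time_h", min = 0)
  for (f in c("fio2_fraction", "sao2_fraction", "svo2_fraction")) {
    if (f %in% names(df)) check_numeric(df[[f]], f, allow_na = TRUE,
                                        min = 0, max = 1)
  }
  nonneg <- intersect(
    c("pao2_fio2", "map_mmHg", "urine_output_ml_kg_h", "bilirubin_umol_L",
      "platelets_1e9_L", "lactate_mmol_L", "pao2_mmHg", "hb_g_dL",
      "co_L_min", "ci_L_min_m2", "hr_bpm", "ast_U_L", "alt_U_L",
      "creatinine_umol_L", "albumin_g_L", "wbc_1e9_L", "elwi_ml_kg",
      "tnfa", "il10", "bet", "hmgb1"),
    names(df))
  for (f in nonneg) check_numeric(df[[f]], f, allow_na = TRUE, min = 0)
  if (all(c("pao2_fio2", "pao2_mmHg", "fio2_fraction") %in% names(df))) {
    have <- !is.na(df$pao2_fio2) & !is.na(df$pao2_mmHg) &
      !is.na(df$fio2_fraction) & df$fio2_fraction > 0
    implied <- df$pao2_mmHg[have] / df$fio2_fraction[have]
    if (any(abs(implied - df$pao2_fio2[have]) > pmax(1, 0.01 * implied))) {
      stop("`pao2_fio2` is inconsistent with pao2_mmHg / fio2_fraction.",
           call. = FALSE)
    }
  }
  df
}

# Fill pao2_fio2 from its parts where missing.
complete_pf_ratio <- function(df) {
  if (!"pao2_fio2" %in% names(df)) df$pao2_fio2 <- NA_real_
  if (all(c("pao2_mmHg", "fio2_fraction") %in% names(df))) {
    fill <- is.na(df$pao2_fio2) & !is.na(df$pao2_mmHg) &
      !is.na(df$fio2_fraction) & df$fio2_fraction > 0
    df$pao2_fio2[fill] <- df$pao2_mmHg[fill] / df$fio2_fraction[fill]
  }
  df
}

#' Compute a full pSOFA result for one animal-hour
#'
#' Combines the five domain scores into the 3-domain total (respiration +
#' cardiovascular + renal; range 0--12) and the 5-domain total (plus liver
#' and coagulation; range 0--20). The three online domains are required;
#' if either laboratory domain (bilirubin, platelets) is missing the result
#' is flagged `three_domain_only` and the 5-domain total is `NA` — missing
#' laboratory values are never imputed as score 0.
#'
#' @param sample A one-row data frame (see [monitoring_sample()]) or a named
#'   list with at least `pao2_fio2` (or `pao2_mmHg` + `fio2_fraction`),
#'   `map_mmHg` and `urine_output_ml_kg_h`.
#' @param therapy A [therapy_state()].
#' @param mode `"pig"` or `"human"` threshold set.
#' @return A one-row tibble with the five domain scores, `total_3d`,
#'   `total_5d` and the `three_domain_only` flag.
#' @examples
#' compute_psofa(monitoring_sample(time_h = 18, map_mmHg = 70, pao2_fio2 = 250,
#'                                 urine_output_ml_kg_h = 0.4,
#'                                 bilirubin_umol_L = 25, platelets_1e9_L = 180))
#' @export
compute_psofa <- function(sample, therapy = therapy_state(),
                          mode = c("pig", "human")) {
  mode <- match.arg(mode)
  df <- complete_pf_ratio(tibble::as_tibble(as.list(sample)))
  need <- c("pao2_fio2", "map_mmHg", "urine_output_ml_kg_h")
  missing3 <- vapply(need, function(f) !f %in% names(df) || is.na(df[[f]]),
                     logical(1))
  if (all(missing3)) {
    stop("All three online domain inputs (PaO2/FiO2, MAP, urine output) ",
         "are missing; nothing to score.", call. = FALSE)
  }
  if (any(missing3)) {
    stop("Online domain input(s) missing: ",
         paste(need[missing3], collapse = ", "), call. = FALSE)
  }
  resp <- score_respiration(df$pao2_fio2)
  card <- score_cardiovascular(df$map_mmHg, therapy, mode)
  renal <- score_renal(df$urine_output_ml_kg_h, therapy)
  bili <- if ("bilirubin_umol_L" %in% names(df)) df$bilirubin_umol_L else NA
  plt <- if ("platelets_1e9_L" %in% names(df)) df$platelets_1e9_L else NA
  three_only <- is.na(bili) || is.na(plt)
  liver <- if (is.na(bili)) NA_integer_ else score_liver(bili)
  coag <- if (is.na(plt)) NA_integer_ else score_coagulation(plt, mode)
  total3 <- resp + card + renal
  tibble::tibble(
    time_h = if ("time_h" %in% names(df)) df$time_h else NA_real_,
    respiration = resp, cardiovascular = card, renal = renal,
    liver = liver, coagulation = coag,
    total_3d = total3,
    total_5d = if (three_only) NA_integer_ else total3 + liver + coag,
    three_domain_only = three_only,
    mode = mode
  )
}

#' Score an hourly monitoring time series
#'
#' Applies the pSOFA scoring engine to every in-window animal-hour of a tidy
#' monitoring table (one row per animal-hour), joining in the supportive
#' therapy state, and summarises the result per animal (unrounded arithmetic
#' mean of hourly totals) and per hour (median across animals). The default
#' window is the invasive-monitoring period 16--24 h after inoculation.
#'
#' @param monitoring Tidy data frame, one row per animal-hour, columns named
#'   as in [monitoring_sample()]; an `animal_id` column is optional for a
#'   single animal.
#' @param therapy Either `NULL` (no supportive therapy), a per-animal-hour
#'   state table (columns `animal_id`, `time_h`, `norepinephrine_ug_kg_min`,
#'   `furosemide_cum_mg`, ...), or a therapy event log (columns `animal_id`,
#'   `time_h`, `drug`, `dose`, `units`) which is converted with
#'   [therapy_state_table()].
#' @param window Numeric length-2, inclusive scoring window in hours.
#' @param mode `"pig"` or `"human"` threshold set.
#' @return A list of class `psofa_timeseries` with elements `scores`
#'   (per animal-hour), `animal_summary` (per-animal means) and
#'   `hourly_median` (per-hour medians across animals).
#' @export
score_timeseries <- function(monitoring, therapy = NULL, window = c(16, 24),
                             mode = c("pig", "human")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(monitoring))
  if (length(window) != 2L || window[1] > window[2]) {
    stop("`window` must be an ordered pair of hours.", call. = FALSE)
  }
  df <- complete_pf_ratio(monitoring)
  if (!"animal_id" %in% names(df)) df$animal_id <- "animal1"
  df <- validate_monitoring(df)
  if (is.unsorted(df$time_h[df$animal_id == df$animal_id[1]])) {
    df <- dplyr::arrange(df, .data$animal_id, .data$time_h)
  }
  df <- df[df$time_h >= window[1] & df$time_h <= window[2], , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("No samples fall inside the scoring window [",
         window[1], ", ", window[2], "] h.", call. = FALSE)
  }

  states <- resolve_therapy(therapy, df)
  st_col <- function(f) if (f %in% names(states)) states[[f]] else 0
  nor <- states$norepinephrine_ug_kg_min
  furo <- states$furosemide_cum_mg

  scores <- tibble::tibble(
    animal_id = df$animal_id,
    time_h = df$time_h,
    respiration = score_respiration(df$pao2_fio2),
    cardiovascular = score_cardiovascular(
      df$map_mmHg,
      list(norepinephrine_ug_kg_min = nor,
           dopamine_ug_kg_min = st_col("dopamine_ug_kg_min"),
           epinephrine_ug_kg_min = st_col("epinephrine_ug_kg_min"),
           dobutamine_ug_kg_min = st_col("dobutamine_ug_kg_min")),
      mode),
    renal = score_renal(df$urine_output_ml_kg_h,
                        list(furosemide_cum_mg = furo))
  )
  bili <- if ("bilirubin_umol_L" %in% names(df)) df$bilirubin_umol_L else NA
  plt <- if ("platelets_1e9_L" %in% names(df)) df$platelets_1e9_L else NA
  scores$liver <- ifelse(is.na(bili), NA_integer_,
                         score_liver(tidyr::replace_na(bili, 0)))
  scores$coagulation <- ifelse(is.na(plt), NA_integer_,
                               score_coagulation(tidyr::replace_na(plt, 0),
                                                 mode))
  scores$total_3d <- scores$respiration + scores$cardiovascular + scores$renal
  scores$three_domain_only <- is.na(scores$liver) | is.na(scores$coagulation)
  scores$total_5d <- ifelse(scores$three_domain_only, NA_integer_,
                            scores$total_3d + scores$liver +
                              scores$coagulation)
  scores$mode <- mode

  animal_summary <- scores |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(
      n_hours = dplyr::n(),
      mean_3d = mean(.data$total_3d),
      mean_5d = if (any(.data$three_domain_only)) NA_real_
                else mean(.data$total_5d),
      three_domain_only = any(.data$three_domain_only),
      .groups = "drop")

  hourly_median <- scores |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(
      n_animals = dplyr::n(),
      median_3d = stats::median(.data$total_3d),
      median_5d = stats::median(.data$total_5d),
      .groups = "drop")

  structure(list(scores = scores, animal_summary = animal_summary,
                 hourly_median = hourly_median, window = window, mode = mode),
            class = "psofa_timeseries")
}

#' @export
print.psofa_timeseries <- function(x, ...) {
  cat(sprintf("pSOFA time series: %d animal(s), window %g-%g h, mode %s\n",
              nrow(x$animal_summary), x$window[1], x$window[2], x$mode))
  print(x$animal_summary, ...)
  invisible(x)
}

# Align a therapy argument (NULL, state table, or event log) with the
# monitoring rows, returning one state per monitoring row.
resolve_therapy <- function(therapy, df) {
  zero <- tibble::tibble(
    norepinephrine_ug_kg_min = rep(0, nrow(df)),
    furosemide_cum_mg = 0, crystalloid_ml_kg_h = 0,
    minutes_on_fluid_resuscitation = 0)
  if (is.null(therapy) || nrow(therapy) == 0L) return(zero)
  stopifnot(is.data.frame(therapy))
  if ("drug" %in% names(therapy)) {
    therapy <- therapy_state_table(
      therapy, times = unique(df[, c("animal_id", "time_h")]))
  }
  if (!"animal_id" %in% names(therapy)) therapy$animal_id <- df$animal_id[1]
  key <- paste(df$animal_id, df$time_h)
  idx <- match(key, paste(therapy$animal_id, therapy$time_h))
  out <- zero
  for (f in setdiff(names(therapy), c("animal_id", "time_h"))) {
    vals <- therapy[[f]][idx]
    out[[f]] <- ifelse(is.na(vals), 0, vals)
  }
  out
}
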