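#' Supportive-therapy state
#'
#' The drug/fluid state of one animal at one time point, as consumed by the
#' cardiovascular and renal pSOFA domains and by [evaluate_triggers()].
#' The optional dopamine/epinephrine/dobutamine rates exist only for
#' human-mode cardiovascular scoring.
#'
#' @param norepinephrine_ug_kg_min Current norepinephrine dose rate
#'   (ug kg^-1 min^-1).
#' @param furosemide_cum_mg Cumulative furosemide dose within the monitoring
#'   window (mg).
#' @param crystalloid_ml_kg_h Current crystalloid infusion rate
#'   (mL kg^-1 h^-1).
#' @param minutes_on_fluid_resuscitation Minutes of ongoing goal-directed
#'   crystalloid resuscitation.
#' @param dopamine_ug_kg_min,epinephrine_ug_kg_min,dobutamine_ug_kg_min
#'   Optional dose rates for human-mode scoring.
#' @param time_h Optional time stamp (hours since inoculation).
#' @param last_furosemide_time_h Optional time of the most recent furosemide
#'   dose, used for the refractoriness check.
#' @return A named list of class `therapy_state`.
#' @export
therapy_state <- function(norepinephrine_ug_kg_min = 0,
                          furosemide_cum_mg = 0,
                          crystalloid_ml_kg_h = 0,
                          minutes_on_fluid_resuscitation = 0,
                          dopamine_ug_kg_min = 0,
                          epinephrine_ug_kg_min = 0,
                          dobutamine_ug_kg_min = 0,
                          time_h = NA_real_,
                          last_furosemide_time_h = NA_real_) {
  st <- list(norepinephrine_ug_kg_min = norepinephrine_ug_kg_min,
             furosemide_cum_mg = furosemide_cum_mg,
             crystalloid_ml_kg_h = crystalloid_ml_kg_h,
             minutes_on_fluid_resuscitation = minutes_on_fluid_resuscitation,
             dopamine_ug_kg_min = dopamine_ug_kg_min,
             epinephrine_ug_kg_min = epinephrine_ug_kg_min,
             dobutamine_ug_kg_min = dobutamine_ug_kg_min,
             time_h = time_h,
             last_furosemide_time_h = last_furosemide_time_h)
  for (f in setdiff(names(st), c("time_h", "last_furosemide_time_h"))) {
    check_numeric(st[[f]], f, min = 0)
  }
  structure(st, class = "therapy_state")
}

#' Goal-directed supportive-therapy policy
#'
#' Trigger thresholds and target ranges for the in-window supportive
#' therapy: norepinephrine is started when MAP has fallen to the trigger
#' value and at least `min_fluid_minutes_before_norepi` minutes of
#' crystalloid resuscitation have failed to restore it; furosemide (one
#' `furosemide_bolus_mg` bolus, repeatable when refractory) is given for
#' oliguria despite fluids or for an elevated extravascular lung water
#' index; fluid boluses aim at the physiological stroke-volume-index
#' target range.
#'
#' @param map_norepi_trigger_mmHg MAP at/below which norepinephrine is
#'   indicated (default 55 mmHg).
#' @param min_fluid_minutes_before_norepi Minimum minutes of unresponsive
#'   crystalloid resuscitation before a vasopressor is started (default 60).
#' @param urine_furosemide_trigger Oliguria threshold, strictly below which
#'   furosemide is indicated despite fluids (default 0.25 mL kg^-1 h^-1).
#' @param elwi_furosemide_trigger Extravascular lung water index above which
#'   furosemide is indicated (default 10 mL kg^-1).
#' @param furosemide_bolus_mg Single furosemide bolus (default 10 mg iv).
#' @param svi_target_range Stroke volume index target
#'   (default 35--45 mL beat^-1 m^-2).
#' @param cvp_range Central venous pressure guidance range (5--8 mmHg).
#' @param fluid_bolus_ml_kg Crystalloid bolus size (15 mL kg^-1).
#' @param glucose_range_mmol_L Venous glucose guidance range (4.1--5.6).
#' @param ppv_range_pct Pulse pressure variation guidance range (8--12%).
#' @param norepi_start_dose Starting norepinephrine rate
#'   (0.05 ug kg^-1 min^-1; titration doubles the rate each unresponsive
#'   hour — a simulator assumption, not a protocol quantity).
#' @param refractory_tolerance Relative improvement in urine output or ELWI
#'   below which a furosemide dose is considered unresponsive (default 0.1).
#' @return A named list of class `therapy_policy`.
#' @export
therapy_policy <- function(map_norepi_trigger_mmHg = 55,
                           min_fluid_minutes_before_norepi = 60,
                           urine_furosemide_trigger = 0.25,
                           elwi_furosemide_trigger = 10,
                           furosemide_bolus_mg = 10,
                           svi_target_range = c(35, 45),
                           cvp_range = c(5, 8),
                           fluid_bolus_ml_kg = 15,
                           glucose_range_mmol_L = c(4.1, 5.6),
                           ppv_range_pct = c(8, 12),
                           norepi_start_dose = 0.05,
                           refractory_tolerance = 0.1) {
  pol <- list(map_norepi_trigger_mmHg = map_norepi_trigger_mmHg,
              min_fluid_minutes_before_norepi = min_fluid_minutes_before_norepi,
              urine_furosemide_trigger = urine_furosemide_trigger,
              elwi_furosemide_trigger = elwi_furosemide_trigger,
              furosemide_bolus_mg = furosemide_bolus_mg,
              svi_target_range = svi_target_range,
              cvp_range = cvp_range,
              fluid_bolus_ml_kg = fluid_bolus_ml_kg,
              glucose_range_mmol_L = glucose_range_mmol_L,
              ppv_range_pct = ppv_range_pct,
              norepi_start_dose = norepi_start_dose,
              refractory_tolerance = refractory_tolerance)
  scalars <- c("map_norepi_trigger_mmHg", "min_fluid_minutes_before_norepi",
               "urine_furosemide_trigger", "elwi_furosemide_trigger",
               "furosemide_bolus_mg", "fluid_bolus_ml_kg",
               "norepi_start_dose")
  for (f in scalars) check_scalar(pol[[f]], f, min = 0, strict_min = TRUE)
  for (f in c("svi_target_range", "cvp_range", "glucose_range_mmol_L",
              "ppv_range_pct")) {
    rng <- pol[[f]]
    if (length(rng) != 2L || rng[1] >= rng[2]) {
      stop(sprintf("`%s` must be an ordered pair.", f), call. = FALSE)
    }
  }
  structure(pol, class = "therapy_policy")
}

#' Evaluate supportive-therapy triggers at one time point
#'
#' Deterministically maps one monitoring sample plus the current therapy
#' state to the set of indicated actions:
#' * `start_norepinephrine` — MAP at/below the trigger despite at least the
#'   minimum duration of crystalloid resuscitation, and no norepinephrine
#'   running yet;
#' * `give_furosemide` — urine output strictly below the oliguria trigger
#'   despite ongoing fluids, or ELWI above its trigger; repeatable when the
#'   previous dose was unresponsive (urine/ELWI improved by less than the
#'   refractoriness tolerance);
#' * `give_fluid_bolus` — stroke volume index below the target range.
#'
#' @param sample One monitoring row (list or one-row data frame).
#' @param therapy The current [therapy_state()]; if both carry `time_h`
#'   they must agree.
#' @param policy A [therapy_policy()].
#' @param previous Optional monitoring row from one hour earlier, used for
#'   the furosemide refractoriness check.
#' @return Character vector (possibly empty) of action identifiers.
#' @examples
#' evaluate_triggers(monitoring_sample(time_h = 18, map_mmHg = 50,
#'                                     urine_output_ml_kg_h = 1),
#'                   therapy_state(minutes_on_fluid_resuscitation = 90))
#' @export
evaluate_triggers <- function(sample, therapy = therapy_state(),
                              policy = therapy_policy(), previous = NULL) {
  s <- as.list(sample)
  if (!is.na(therapy$time_h %||% NA) && !is.na(s$time_h %||% NA) &&
      therapy$time_h != s$time_h) {
    stop("Monitoring sample and therapy state are at different times (",
         s$time_h, " vs ", therapy$time_h, " h).", call. = FALSE)
  }
  actions <- character()

  fluids_ongoing <- (therapy$crystalloid_ml_kg_h %||% 0) > 0 ||
    (therapy$minutes_on_fluid_resuscitation %||% 0) > 0

  # Vasopressor: hypotension unresponsive to >= the minimum fluid challenge.
  map <- s$map_mmHg %||% NA
  if (!is.na(map) &&
      map <= policy$map_norepi_trigger_mmHg &&
      (therapy$minutes_on_fluid_resuscitation %||% 0) >=
        policy$min_fluid_minutes_before_norepi &&
      (therapy$norepinephrine_ug_kg_min %||% 0) == 0) {
    actions <- c(actions, "start_norepinephrine")
  }

  # Diuretic: oliguria despite fluids, or fluid overload by ELWI.
  urine <- s$urine_output_ml_kg_h %||% NA
  elwi <- s$elwi_ml_kg %||% NA
  oliguria <- !is.na(urine) && fluids_ongoing &&
    urine < policy$urine_furosemide_trigger
  overload <- !is.na(elwi) && elwi > policy$elwi_furosemide_trigger
  if (oliguria || overload) {
    repeat_ok <- TRUE
    last_dose <- therapy$last_furosemide_time_h %||% NA
    if (!is.null(previous) && !is.na(last_dose) && !is.na(s$time_h %||% NA) &&
        s$time_h - last_dose <= 1) {
      p <- as.list(previous)
      tol <- policy$refractory_tolerance
      urine_improved <- !is.na(urine) && !is.na(p$urine_output_ml_kg_h %||% NA) &&
        urine > (1 + tol) * p$urine_output_ml_kg_h
      elwi_improved <- !is.na(elwi) && !is.na(p$elwi_ml_kg %||% NA) &&
        elwi < (1 - tol) * p$elwi_ml_kg
      # Responsive to the previous dose: hold off on repeating it.
      if (urine_improved || elwi_improved) repeat_ok <- FALSE
    }
    if (repeat_ok) actions <- c(actions, "give_furosemide")
  }

  # Fluids: SVI below the goal-directed target range.
  svi_val <- if (!is.na(s$ci_L_min_m2 %||% NA) && !is.na(s$hr_bpm %||% NA) &&
                 (s$hr_bpm %||% 0) > 0) {
    svi(s$ci_L_min_m2, s$hr_bpm)
  } else NA_real_
  if (!is.na(svi_val) && svi_val < policy$svi_target_range[1]) {
    actions <- c(actions, "give_fluid_bolus")
  }
  actions
}

#' Reconstruct per-hour therapy states from an event log
#'
#' Converts a tidy therapy event log (`animal_id`, `time_h`, `drug`, `dose`,
#' `units`) into the per-animal-hour state table the scoring engine
#' consumes. Norepinephrine events set the current dose rate (the most
#' recent event at or before each time applies); furosemide doses
#' accumulate; a crystalloid event covers the following hour at the bolus
#' rate, and the resuscitation clock counts minutes since the first
#' crystalloid event at or after `resuscitation_from_h`.
#'
#' @param events Therapy event log data frame.
#' @param times Data frame of (`animal_id`, `time_h`) rows at which states
#'   are wanted.
#' @param resuscitation_from_h Events before this hour (maintenance fluids)
#'   do not start the resuscitation clock (default 16).
#' @return Tibble with one state row per requested animal-hour.
#' @export
therapy_state_table <- function(events, times, resuscitation_from_h = 16) {
  stopifnot(is.data.frame(times),
            all(c("animal_id", "time_h") %in% names(times)))
  need <- c("animal_id", "time_h", "drug", "dose")
  if (!is.null(events) && nrow(events) > 0 &&
      !all(need %in% names(events))) {
    stop("Therapy event log must have columns ",
         paste(need, collapse = ", "), ".", call. = FALSE)
  }
  out <- lapply(seq_len(nrow(times)), function(i) {
    id <- times$animal_id[i]
    t <- times$time_h[i]
    ev <- if (is.null(events) || nrow(events) == 0) events else
      events[events$animal_id == id & events$time_h <= t, , drop = FALSE]
    nor_ev <- ev[ev$drug == "norepinephrine", , drop = FALSE]
    nor <- if (nrow(nor_ev)) nor_ev$dose[which.max(nor_ev$time_h)] else 0
    furo_ev <- ev[ev$drug == "furosemide", , drop = FALSE]
    furo <- sum(furo_ev$dose)
    last_furo <- if (nrow(furo_ev)) max(furo_ev$time_h) else NA_real_
    cry_ev <- ev[ev$drug == "crystalloid", , drop = FALSE]
    rate <- if (nrow(cry_ev) && any(cry_ev$time_h > t - 1)) {
      max(cry_ev$dose[cry_ev$time_h > t - 1])
    } else 0
    resus <- cry_ev$time_h[cry_ev$time_h >= resuscitation_from_h]
    minutes <- if (length(resus)) 60 * (t - min(resus)) else 0
    tibble::tibble(animal_id = id, time_h = t,
                   norepinephrine_ug_kg_min = nor,
                   furosemide_cum_mg = furo,
                   crystalloid_ml_kg_h = rate,
                   minutes_on_fluid_resuscitation = max(0, minutes),
                   last_furosemide_time_h = last_furo)
  })
  dplyr::bind_rows(out)
}
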