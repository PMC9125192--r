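#' Severity classification policy
#'
#' Operationalises the Sepsis-3-adapted allocation rules: sepsis requires a
#' total pSOFA score of at least 2 together with lactate of at least
#' 2 mmol L^-1 at the allocation time (default 18 h after inoculation);
#' septic shock additionally requires vasopressor support to maintain MAP
#' at the 65 mmHg target despite adequate fluid resuscitation. Animals
#' whose trajectory ends before the invasive-monitoring window are screened
#' with the fulminant early-deterioration rule: at the early check time
#' (default 6 h), lactate and bilirubin elevated above baseline by the
#' configured multiples AND venous oxygen saturation and albumin depressed
#' below baseline by the configured fractions (or explicit acute
#' respiratory/circulatory failure flags).
#'
#' @param allocation_time_h Hour at which sepsis/septic shock are decided
#'   (default 18).
#' @param score_basis `"5d"` (default) or `"3d"` total used for the
#'   score >= 2 criterion; when the 5-domain total is unavailable the
#'   3-domain total is used and flagged.
#' @param sofa_threshold Score criterion (default 2).
#' @param lactate_threshold_mmol_L Lactate criterion (default 2).
#' @param map_target_mmHg Vasopressor MAP target (default 65).
#' @param end_of_observation_h Last hour scanned for late-qualifying
#'   animals (default 24).
#' @param strict_lactate_clause If `TRUE`, septic shock additionally
#'   requires the lactate criterion despite resuscitation (stricter
#'   Sepsis-3 reading); the default keeps the vasopressor clause only.
#' @param fulminant_check_h Early check time for the fulminant rule
#'   (default 6).
#' @param fulminant_lactate_fold,fulminant_bilirubin_fold Baseline
#'   multiples (defaults 2 and 1.5).
#' @param fulminant_svo2_drop,fulminant_albumin_drop Fractional drops below
#'   baseline (defaults 0.2 and 0.2).
#' @return A named list of class `classification_policy`.
#' @export
classification_policy <- function(allocation_time_h = 18,
                                  score_basis = c("5d", "3d"),
                                  sofa_threshold = 2,
                                  lactate_threshold_mmol_L = 2,
                                  map_target_mmHg = 65,
                                  end_of_observation_h = 24,
                                  strict_lactate_clause = FALSE,
                                  fulminant_check_h = 6,
                                  fulminant_lactate_fold = 2,
                                  fulminant_bilirubin_fold = 1.5,
                                  fulminant_svo2_drop = 0.2,
                                  fulminant_albumin_drop = 0.2) {
  score_basis <- match.arg(score_basis)
  pol <- list(allocation_time_h = allocation_time_h,
              score_basis = score_basis,
              sofa_threshold = sofa_threshold,
              lactate_threshold_mmol_L = lactate_threshold_mmol_L,
              map_target_mmHg = map_target_mmHg,
              end_of_observation_h = end_of_observation_h,
              strict_lactate_clause = isTRUE(strict_lactate_clause),
              fulminant_check_h = fulminant_check_h,
              fulminant_lactate_fold = fulminant_lactate_fold,
              fulminant_bilirubin_fold = fulminant_bilirubin_fold,
              fulminant_svo2_drop = fulminant_svo2_drop,
              fulminant_albumin_drop = fulminant_albumin_drop)
  for (f in c("allocation_time_h", "sofa_threshold",
              "lactate_threshold_mmol_L", "map_target_mmHg",
              "end_of_observation_h", "fulminant_check_h",
              "fulminant_lactate_fold", "fulminant_bilirubin_fold")) {
    check_scalar(pol[[f]], f, min = 0, strict_min = TRUE)
  }
  check_scalar(pol$fulminant_svo2_drop, "fulminant_svo2_drop", min = 0,
               max = 1)
  check_scalar(pol$fulminant_albumin_drop, "fulminant_albumin_drop",
               min = 0, max = 1)
  structure(pol, class = "classification_policy")
}

severity_levels <- c("sham", "non_responder", "sepsis", "septic_shock",
                     "fulminant")

#' Flag a fulminant early septic reaction
#'
#' Evaluates the humane-endpoint screening rule on the early (<= 15 h)
#' trajectory of one animal: relative to the baseline (earliest) sample,
#' lactate and bilirubin must be elevated by the configured multiples AND
#' venous oxygen saturation and albumin depressed by the configured
#' fractions at the early check time; an explicit `acute_failure` flag
#' column (respiratory/circulatory collapse) also triggers the rule.
#'
#' @param samples Monitoring rows for one animal with `time_h <= 15`
#'   (later rows are ignored), including a baseline row.
#' @param policy A [classification_policy()].
#' @return List with `flag` (logical) and `reasons` (character).
#' @export
flag_fulminant <- function(samples, policy = classification_policy()) {
  stopifnot(is.data.frame(samples))
  early <- samples[samples$time_h <= 15, , drop = FALSE]
  if (nrow(early) == 0L) return(list(flag = FALSE, reasons = character()))
  base <- early[which.min(early$time_h), , drop = FALSE]
  reasons <- character()
  if ("acute_failure" %in% names(early) &&
      any(early$acute_failure %in% TRUE)) {
    return(list(flag = TRUE, reasons = "acute_failure_flag"))
  }
  chk <- early[which.min(abs(early$time_h - policy$fulminant_check_h)), ,
               drop = FALSE]
  if (chk$time_h == base$time_h) {
    return(list(flag = FALSE, reasons = character()))
  }
  rel_up <- function(f, fold) {
    !is.na(chk[[f]]) && !is.na(base[[f]]) && base[[f]] > 0 &&
      chk[[f]] >= fold * base[[f]]
  }
  rel_down <- function(f, drop) {
    !is.na(chk[[f]]) && !is.na(base[[f]]) && base[[f]] > 0 &&
      chk[[f]] <= (1 - drop) * base[[f]]
  }
  conds <- c(
    lactate_rise = rel_up("lactate_mmol_L", policy$fulminant_lactate_fold),
    bilirubin_rise = rel_up("bilirubin_umol_L",
                            policy$fulminant_bilirubin_fold),
    svo2_fall = rel_down("svo2_fraction", policy$fulminant_svo2_drop),
    albumin_fall = rel_down("albumin_g_L", policy$fulminant_albumin_drop))
  if (all(conds)) {
    list(flag = TRUE, reasons = names(conds))
  } else {
    list(flag = FALSE, reasons = names(conds)[conds])
  }
}

#' Classify one animal's severity
#'
#' Applies the group-allocation rules to one animal's score and monitoring
#' trajectory. Saline controls pass through as `sham`. Inoculated animals
#' whose trajectory ends before the allocation time must satisfy the
#' fulminant rule (otherwise the trajectory is rejected as incomplete).
#' Surviving animals are evaluated at the allocation time: `septic_shock`
#' when the sepsis criteria hold and the animal is vasopressor-dependent;
#' `sepsis` when total pSOFA >= 2 and lactate >= 2 mmol L^-1 without
#' vasopressor dependence; animals meeting the criteria only later in the
#' observation window are labelled at the first qualifying hour;
#' `non_responder` when neither criterion is met through the end of
#' observation.
#'
#' @param scores Per-hour score table for the animal (from
#'   [score_timeseries()]`$scores`), or `NULL` for an early-terminated
#'   animal.
#' @param samples The animal's monitoring rows (all hours).
#' @param therapy Therapy state table or event log for the animal (used for
#'   vasopressor dependence); `NULL` means no vasopressor support.
#' @param policy A [classification_policy()].
#' @param inoculated `FALSE` for saline controls.
#' @return One-row tibble: `label`, `decision_time_h`, `criteria_met`.
#' @export
classify_animal <- function(scores, samples, therapy = NULL,
                            policy = classification_policy(),
                            inoculated = TRUE) {
  if (!inoculated) {
    return(label_row("sham", policy$allocation_time_h, "saline_control"))
  }
  stopifnot(is.data.frame(samples))
  t_alloc <- policy$allocation_time_h
  t_last <- max(c(samples$time_h,
                  if (!is.null(scores)) scores$time_h else numeric()))
  if (t_last < t_alloc) {
    ff <- flag_fulminant(samples, policy)
    if (ff$flag) {
      return(label_row("fulminant", max(samples$time_h),
                       paste(ff$reasons, collapse = ";")))
    }
    stop("Trajectory ends at ", t_last, " h, before the allocation time (",
         t_alloc, " h), without meeting the fulminant rule.", call. = FALSE)
  }
  if (is.null(scores) || nrow(scores) == 0L) {
    stop("Score trajectory required for an animal surviving to allocation.",
         call. = FALSE)
  }

  nor_at <- function(t) {
    if (is.null(therapy) || nrow(therapy) == 0L) return(0)
    th <- therapy
    if ("drug" %in% names(th)) {
      ev <- th[th$drug == "norepinephrine" & th$time_h <= t, , drop = FALSE]
      if (nrow(ev) == 0L) return(0)
      return(ev$dose[which.max(ev$time_h)])
    }
    if (!"norepinephrine_ug_kg_min" %in% names(th)) return(0)
    val <- nearest_time(th$time_h, th$norepinephrine_ug_kg_min, t)
    if (is.na(val)) 0 else val
  }
  total_at <- function(t) {
    i <- which.min(abs(scores$time_h - t))
    tot <- if (policy$score_basis == "5d" && !is.na(scores$total_5d[i])) {
      scores$total_5d[i]
    } else scores$total_3d[i]
    tot
  }
  lact_at <- function(t) nearest_time(samples$time_h, samples$lactate_mmol_L, t)
  map_at <- function(t) nearest_time(samples$time_h, samples$map_mmHg, t)

  eval_hour <- function(t) {
    tot <- total_at(t)
    lac <- lact_at(t)
    nor <- nor_at(t)
    sofa_ok <- !is.na(tot) && tot >= policy$sofa_threshold
    lact_ok <- !is.na(lac) && lac >= policy$lactate_threshold_mmol_L
    sepsis_ok <- sofa_ok && lact_ok
    vaso <- !is.na(nor) && nor > 0
    shock_ok <- sepsis_ok && vaso &&
      (!policy$strict_lactate_clause || lact_ok)
    crits <- c(if (sofa_ok) sprintf("psofa_ge%g", policy$sofa_threshold),
               if (lact_ok) sprintf("lactate_ge%g",
                                    policy$lactate_threshold_mmol_L),
               if (vaso) "vasopressor_dependent",
               if (vaso && !is.na(map_at(t)) &&
                   map_at(t) >= policy$map_target_mmHg) "map_maintained")
    list(sepsis = sepsis_ok, shock = shock_ok, criteria = crits)
  }

  at_alloc <- eval_hour(t_alloc)
  if (at_alloc$shock) {
    return(label_row("septic_shock", t_alloc,
                     paste(at_alloc$criteria, collapse = ";")))
  }
  if (at_alloc$sepsis) {
    return(label_row("sepsis", t_alloc,
                     paste(at_alloc$criteria, collapse = ";")))
  }
  later <- sort(unique(scores$time_h[scores$time_h > t_alloc &
                                       scores$time_h <=
                                         policy$end_of_observation_h]))
  for (t in later) {
    res <- eval_hour(t)
    if (res$shock) {
      return(label_row("septic_shock", t, paste(res$criteria,
                                                collapse = ";")))
    }
    if (res$sepsis) {
      return(label_row("sepsis", t, paste(res$criteria, collapse = ";")))
    }
  }
  label_row("non_responder", policy$end_of_observation_h,
            "criteria_unmet_through_observation")
}

label_row <- function(label, time, criteria) {
  tibble::tibble(
    label = factor(label, levels = severity_levels),
    decision_time_h = time,
    criteria_met = criteria)
}

#' Classify every animal of a cohort
#'
#' Convenience wrapper running [score_timeseries()] and [classify_animal()]
#' over a whole cohort.
#'
#' @param monitoring Cohort monitoring table (must contain `animal_id`).
#' @param therapy Therapy event log or state table for the cohort.
#' @param animals Data frame with `animal_id` and `group` (`"sham"` or
#'   inoculated) columns; if `NULL`, every animal is treated as inoculated.
#' @param policy A [classification_policy()].
#' @param mode Scoring threshold set, `"pig"` or `"human"`.
#' @return Tibble with one row per animal: `animal_id`, `label`,
#'   `decision_time_h`, `criteria_met`.
#' @export
classify_cohort <- function(monitoring, therapy = NULL, animals = NULL,
                            policy = classification_policy(),
                            mode = "pig") {
  stopifnot(is.data.frame(monitoring), "animal_id" %in% names(monitoring))
  ids <- unique(monitoring$animal_id)
  sham_ids <- if (!is.null(animals)) {
    animals$animal_id[animals$group == "sham"]
  } else character()
  out <- lapply(ids, function(id) {
    mon <- monitoring[monitoring$animal_id == id, , drop = FALSE]
    th <- if (is.null(therapy)) NULL else
      therapy[therapy$animal_id == id, , drop = FALSE]
    sc <- NULL
    if (max(mon$time_h) >= policy$allocation_time_h) {
      sc <- score_timeseries(mon, th,
                             window = c(policy$allocation_time_h - 2,
                                        policy$end_of_observation_h),
                             mode = mode)$scores
    }
    res <- classify_animal(sc, mon, th, policy,
                           inoculated = !(id %in% sham_ids))
    res$animal_id <- id
    res
  })
  dplyr::bind_rows(out)[, c("animal_id", "label", "decision_time_h",
                            "criteria_met")]
}
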