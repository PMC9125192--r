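#' Systemic oxygen delivery, consumption and extraction
#'
#' Computes oxygen delivery `DO2 = CO x (1.38 x Hb x SaO2 + 0.003 x PaO2)`,
#' oxygen consumption `VO2 = CO x (1.38 x Hb x (SaO2 - SvO2) + 0.003 x PaO2)`
#' and the extraction fraction `ExO2 = VO2 / DO2`. The default
#' `units_mode = "literal"` multiplies the terms exactly as written
#' (CO in L min^-1, Hb in g dL^-1, saturations as fractions, PaO2 in mmHg);
#' `"ml_per_min"` additionally applies the conventional factor 10 for the
#' dL-to-L conversion so that DO2/VO2 come out in mL O2 min^-1.
#' `extraction = "literal_inverse"` returns DO2/VO2 instead of the
#' physiological extraction fraction.
#'
#' @param co Cardiac output (L min^-1), > 0.
#' @param hb Hemoglobin (g dL^-1), > 0.
#' @param sao2,svo2 Arterial and mixed/central venous oxygen saturations as
#'   fractions in `[0, 1]`, with `svo2 <= sao2`.
#' @param pao2 Arterial oxygen tension (mmHg), >= 0.
#' @param units_mode `"literal"` (default) or `"ml_per_min"`.
#' @param extraction `"fraction"` (VO2/DO2, default) or `"literal_inverse"`.
#' @return A tibble with columns `do2`, `vo2`, `exo2`, `units_mode`.
#' @examples
#' oxygen_profile(co = 4, hb = 10, sao2 = 0.98, svo2 = 0.68, pao2 = 95)
#' @export
oxygen_profile <- function(co, hb, sao2, svo2, pao2,
                           units_mode = c("literal", "ml_per_min"),
                           extraction = c("fraction", "literal_inverse")) {
  units_mode <- match.arg(units_mode)
  extraction <- match.arg(extraction)
  check_numeric(co, "co", min = 0, strict_min = TRUE)
  check_numeric(hb, "hb", min = 0, strict_min = TRUE)
  check_numeric(sao2, "sao2", min = 0, max = 1)
  check_numeric(svo2, "svo2", min = 0, max = 1)
  check_numeric(pao2, "pao2", min = 0)
  if (any(svo2 > sao2)) {
    stop("`svo2` exceeds `sao2`: negative oxygen extraction is not valid.",
         call. = FALSE)
  }
  k <- if (units_mode == "ml_per_min") 10 else 1
  do2 <- k * co * (1.38 * hb * sao2 + 0.003 * pao2)
  vo2 <- k * co * (1.38 * hb * (sao2 - svo2) + 0.003 * pao2)
  exo2 <- if (extraction == "fraction") vo2 / do2 else do2 / vo2
  tibble::tibble(do2 = do2, vo2 = vo2, exo2 = exo2, units_mode = units_mode)
}

#' Systemic vascular resistance index
#'
#' `SVRI = (MAP - CVP) / flow`, with the flow argument taken literally:
#' pass the cardiac index for an indexed resistance or the raw cardiac
#' output for the unindexed form.
#'
#' @param map_mmHg Mean arterial pressure (mmHg), must exceed `cvp_mmHg`.
#' @param cvp_mmHg Central venous pressure (mmHg).
#' @param flow Cardiac output (L min^-1) or cardiac index (L min^-1 m^-2),
#'   > 0.
#' @return Numeric resistance (mmHg min L^-1, per m^2 if `flow` is indexed).
#' @examples
#' svri(90, 5, 4)
#' @export
svri <- function(map_mmHg, cvp_mmHg, flow) {
  check_numeric(map_mmHg, "map_mmHg")
  check_numeric(cvp_mmHg, "cvp_mmHg")
  check_numeric(flow, "flow", min = 0, strict_min = TRUE)
  if (any(map_mmHg <= cvp_mmHg)) {
    stop("`map_mmHg` must exceed `cvp_mmHg`.", call. = FALSE)
  }
  (map_mmHg - cvp_mmHg) / flow
}

#' Stroke volume index
#'
#' `SVI = CI / HR`, scaled by 1000 so the result is in mL beat^-1 m^-2 and
#' directly comparable with the goal-directed target range
#' (35--45 mL beat^-1 m^-2).
#'
#' @param ci Cardiac index (L min^-1 m^-2), > 0.
#' @param hr Heart rate (beats min^-1), > 0.
#' @return Stroke volume index (mL beat^-1 m^-2).
#' @examples
#' svi(3.5, 100)
#' @export
svi <- function(ci, hr) {
  check_numeric(ci, "ci", min = 0, strict_min = TRUE)
  check_numeric(hr, "hr", min = 0, strict_min = TRUE)
  1000 * ci / hr
}

#' De Ritis ratio
#'
#' `AST / ALT`; values above ~1 with rising AST suggest mixed hepatic and
#' non-hepatic (kidney, heart, muscle) cell injury.
#'
#' @param ast Aspartate aminotransferase (U L^-1), >= 0.
#' @param alt Alanine aminotransferase (U L^-1), > 0.
#' @return Numeric ratio.
#' @examples
#' de_ritis(80, 40)
#' @export
de_ritis <- function(ast, alt) {
  check_numeric(ast, "ast", min = 0)
  check_numeric(alt, "alt", min = 0, strict_min = TRUE)
  ast / alt
}

#' Proportion of perfused vessels
#'
#' Computes the sublingual microcirculatory PPV from a precomputed vessel
#' segment table: 100 x (total length of segments with measurable flow) /
#' (total length of all detected segments). When a `quarter` column is
#' present (the analysis convention of splitting each video into four
#' quarters), the per-quarter PPVs are averaged.
#'
#' @param segments Data frame with columns `length_um` (> 0) and `perfused`
#'   (logical or 0/1), optionally `quarter`.
#' @return PPV as a percentage.
#' @examples
#' ppv(data.frame(length_um = c(800, 200), perfused = c(1, 0)))
#' @export
ppv <- function(segments) {
  stopifnot(is.data.frame(segments))
  if (nrow(segments) == 0L) {
    stop("Empty vessel segment table.", call. = FALSE)
  }
  if (!all(c("length_um", "perfused") %in% names(segments))) {
    stop("`segments` needs columns `length_um` and `perfused`.",
         call. = FALSE)
  }
  check_numeric(segments$length_um, "length_um", min = 0, strict_min = TRUE)
  perf <- as.logical(segments$perfused)
  if (any(is.na(perf))) stop("`perfused` must be logical or 0/1.",
                             call. = FALSE)
  one <- function(len, p) 100 * sum(len[p]) / sum(len)
  if ("quarter" %in% names(segments)) {
    by_q <- split(seq_len(nrow(segments)), segments$quarter)
    mean(vapply(by_q, function(i) one(segments$length_um[i], perf[i]),
                numeric(1)))
  } else {
    one(segments$length_um, perf)
  }
}

#' Append derived oxygen-transport and hemodynamic columns
#'
#' Adds `do2`, `vo2`, `exo2`, `svri`, `svi_ml_beat_m2` and `de_ritis`
#' columns to a monitoring or score table wherever the inputs are present
#' (rows with missing inputs get `NA`).
#'
#' @param df Data frame carrying monitoring columns (see
#'   [monitoring_sample()]).
#' @inheritParams oxygen_profile
#' @return `df` with the derived columns appended.
#' @export
append_derived <- function(df, units_mode = "literal") {
  get <- function(f) if (f %in% names(df)) df[[f]] else rep(NA_real_, nrow(df))
  co <- get("co_L_min"); hb <- get("hb_g_dL")
  sao2 <- get("sao2_fraction"); svo2 <- get("svo2_fraction")
  pao2 <- get("pao2_mmHg")
  ok <- !is.na(co) & !is.na(hb) & !is.na(sao2) & !is.na(svo2) & !is.na(pao2) &
    co > 0 & hb > 0 & svo2 <= sao2
  df$do2 <- df$vo2 <- df$exo2 <- NA_real_
  if (any(ok)) {
    prof <- oxygen_profile(co[ok], hb[ok], sao2[ok], svo2[ok], pao2[ok],
                           units_mode = units_mode)
    df$do2[ok] <- prof$do2; df$vo2[ok] <- prof$vo2; df$exo2[ok] <- prof$exo2
  }
  map <- get("map_mmHg"); cvp <- get("cvp_mmHg"); ci <- get("ci_L_min_m2")
  hr <- get("hr_bpm")
  ok <- !is.na(map) & !is.na(cvp) & !is.na(ci) & map > cvp & ci > 0
  df$svri <- NA_real_
  df$svri[ok] <- (map[ok] - cvp[ok]) / ci[ok]
  ok <- !is.na(ci) & !is.na(hr) & ci > 0 & hr > 0
  df$svi_ml_beat_m2 <- NA_real_
  df$svi_ml_beat_m2[ok] <- svi(ci[ok], hr[ok])
  ast <- get("ast_U_L"); alt <- get("alt_U_L")
  ok <- !is.na(ast) & !is.na(alt) & alt > 0
  df$de_ritis <- NA_real_
  df$de_ritis[ok] <- ast[ok] / alt[ok]
  df
}
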