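#' Synthetic minipig cohort configuration
#'
#' Parameters of the synthetic fecal-peritonitis cohort generator. The
#' defaults emulate the study design the scoring pipeline targets: 36
#' animals of which a quarter are saline shams; a log-uniform inoculum load
#' spanning 10^5.8--10^10.2 total CFU; a latent severity that increases
#' with log10 CFU at slope `severity_coupling` plus Gaussian noise;
#' non-responder and fulminant trajectory templates at quota fractions 5/27
#' and 3/27 of the inoculated animals; sepsis / septic-shock templates for
#' the remainder (split at the latent-severity median); TNF-alpha peaking
#' at 6 h, IL-10 at 16 h, and bET/HMGB1 rising only in the shock template
#' over 16--24 h; leucopenia at 16 h and persistent lactate >= 2 with
#' vasopressor-dependent hypotension only in the shock template; a late
#' (20--24 h) bilirubin rise in shock templates only.
#'
#' @param n_animals Cohort size (>= 2; default 36).
#' @param sham_fraction Fraction of saline controls (default 0.25).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param cfu_log10_range Log10 range of the total inoculum CFU
#'   (default 5.8--10.2).
#' @param severity_coupling Slope of latent severity on log10 CFU
#'   (>= 0; default 1).
#' @param severity_noise_sd SD of the latent-severity noise (default 0.4).
#' @param nonresponder_fraction,fulminant_fraction Template quota fractions
#'   of the inoculated animals (defaults 5/27 and 3/27).
#' @param noise Named list of per-variable noise scales (log-SD for
#'   multiplicative noise; absolute SD for the saturation fractions).
#' @param band_thresholds CFU severity-band boundaries (see
#'   [severity_band()]).
#' @param times Trajectory time grid in hours (default 0, 6, 12, then
#'   hourly 16--24).
#' @param inoculum_volume_ml Suspension volume (200 mL).
#' @param biomarker_timing Named list recording the emulated biomarker
#'   kinetics (TNF-alpha peak hour, IL-10 peak hour, first hour of the
#'   shock-only bET/HMGB1 rise).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_animals = 36, sham_fraction = 0.25, seed = NULL,
                          cfu_log10_range = c(5.8, 10.2),
                          severity_coupling = 1, severity_noise_sd = 0.4,
                          nonresponder_fraction = 5 / 27,
                          fulminant_fraction = 3 / 27,
                          noise = default_noise(),
                          band_thresholds = c(1.34e7, 4e8, 8e9),
                          times = c(0, 6, 12, 16:24),
                          inoculum_volume_ml = 200,
                          biomarker_timing = list(tnfa_peak_h = 6,
                                                  il10_peak_h = 16,
                                                  shock_rise_from_h = 16)) {
  cfg <- list(n_animals = n_animals, sham_fraction = sham_fraction,
              seed = seed, cfu_log10_range = cfu_log10_range,
              severity_coupling = severity_coupling,
              severity_noise_sd = severity_noise_sd,
              nonresponder_fraction = nonresponder_fraction,
              fulminant_fraction = fulminant_fraction,
              noise = utils::modifyList(default_noise(), noise),
              band_thresholds = band_thresholds, times = sort(times),
              inoculum_volume_ml = inoculum_volume_ml,
              biomarker_timing = biomarker_timing)
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  check_scalar(cfg$n_animals, "n_animals", min = 2)
  if (cfg$n_animals != round(cfg$n_animals)) {
    stop("`n_animals` must be an integer.", call. = FALSE)
  }
  check_scalar(cfg$sham_fraction, "sham_fraction", min = 0, max = 1)
  check_scalar(cfg$severity_coupling, "severity_coupling", min = 0)
  check_scalar(cfg$severity_noise_sd, "severity_noise_sd", min = 0)
  check_scalar(cfg$nonresponder_fraction, "nonresponder_fraction",
               min = 0, max = 1)
  check_scalar(cfg$fulminant_fraction, "fulminant_fraction", min = 0,
               max = 1)
  if (length(cfg$cfu_log10_range) != 2L ||
      cfg$cfu_log10_range[1] >= cfg$cfu_log10_range[2]) {
    stop("`cfu_log10_range` must be an ordered pair.", call. = FALSE)
  }
  check_numeric(cfg$times, "times", min = 0)
  structure(cfg, class = "cohort_config")
}

default_noise <- function() {
  list(map = 0.03, hr = 0.03, ci = 0.04, co = 0.04, cvp = 0.08, pf = 0.05,
       hb = 0.03, urine = 0.10, bili = 0.08, plt = 0.06, lact = 0.06,
       ast = 0.08, alt = 0.08, creat = 0.05, alb = 0.04, wbc = 0.10,
       elwi = 0.05, tnfa = 0.15, il10 = 0.15, bet = 0.15, hmgb1 = 0.15,
       sao2 = 0.01, svo2 = 0.01)
}

#' Perturb one generator parameter
#'
#' Pure configuration transform for sensitivity sweeps: adds `delta` to a
#' single numeric scalar parameter and re-validates.
#'
#' @param config A [cohort_config()].
#' @param parameter Name of a numeric scalar field (e.g.
#'   `"severity_coupling"`, `"n_animals"`).
#' @param delta Numeric increment.
#' @return A new validated `cohort_config`.
#' @export
perturb <- function(config, parameter, delta) {
  stopifnot(inherits(config, "cohort_config"))
  ok <- c("n_animals", "sham_fraction", "severity_coupling",
          "severity_noise_sd", "nonresponder_fraction",
          "fulminant_fraction", "inoculum_volume_ml")
  if (!is.character(parameter) || length(parameter) != 1L ||
      !parameter %in% ok) {
    stop("Unknown perturbable parameter: ", parameter, call. = FALSE)
  }
  check_scalar(delta, "delta")
  config[[parameter]] <- config[[parameter]] + delta
  validate_cohort_config(config)
}

# Piecewise-linear trajectory anchors per template. Each variable carries a
# time vector `t` and mild/severe anchor values; an animal's curve is the
# interpolation of mild + u * (severe - mild), u in [0, 1]. Anchor values
# are package defaults placed inside the qualitative ranges the templates
# emulate (see the methods vignette); they are not measured data.
cohort_templates <- function() {
  v <- function(t, mild, severe = mild) list(t = t, mild = mild,
                                             severe = severe)
  t6 <- c(0, 6, 12, 16, 20, 24)
  t7 <- c(0, 6, 12, 16, 17, 20, 24)
  t3 <- c(0, 6, 12)
  list(
    sham = list(
      map = v(t6, c(90, 90, 90, 88, 88, 87)),
      hr = v(t6, c(90, 90, 92, 95, 95, 96)),
      ci = v(t6, rep(3.5, 6)), co = v(t6, rep(4.0, 6)),
      cvp = v(t6, rep(6, 6)),
      pf = v(t6, c(450, 450, 445, 440, 435, 430)),
      fio2 = v(t6, rep(0.21, 6)),
      sao2 = v(t6, rep(0.97, 6)), svo2 = v(t6, rep(0.70, 6)),
      hb = v(t6, rep(10, 6)),
      urine = v(t6, c(1.2, 1.2, 1.1, 1.1, 1.0, 1.0)),
      bili = v(t6, rep(8, 6)),
      plt = v(t6, c(350, 345, 340, 335, 320, 300)),
      lact = v(t6, rep(1.2, 6)),
      ast = v(t6, rep(40, 6)), alt = v(t6, rep(45, 6)),
      creat = v(t6, rep(90, 6)),
      alb = v(t6, c(35, 35, 34, 33, 32, 31)),
      wbc = v(t6, rep(15, 6)), elwi = v(t6, rep(7, 6)),
      tnfa = v(t6, rep(40, 6)), il10 = v(t6, rep(25, 6)),
      bet = v(t6, rep(0.8, 6)), hmgb1 = v(t6, rep(2, 6))),
    non_responder = list(
      map = v(t6, c(90, 88, 87, 86, 85, 84), c(90, 87, 85, 84, 83, 82)),
      hr = v(t6, c(90, 95, 100, 102, 104, 105)),
      ci = v(t6, c(3.5, 3.7, 3.9, 4.0, 4.1, 4.2)),
      co = v(t6, c(4.0, 4.2, 4.4, 4.5, 4.6, 4.6)),
      cvp = v(t6, rep(6, 6)),
      pf = v(t6, c(450, 440, 430, 420, 415, 410),
             c(450, 430, 415, 405, 400, 395)),
      fio2 = v(t6, rep(0.21, 6)),
      sao2 = v(t6, rep(0.96, 6)),
      svo2 = v(t6, c(0.70, 0.68, 0.66, 0.65, 0.64, 0.64)),
      hb = v(t6, rep(10.3, 6)),
      urine = v(t6, c(1.2, 1.1, 1.0, 0.95, 0.90, 0.85)),
      bili = v(t6, c(8, 9, 10, 10, 11, 12)),
      plt = v(t6, c(350, 340, 320, 300, 285, 270)),
      lact = v(t6, c(1.2, 1.4, 1.45, 1.5, 1.5, 1.5)),
      ast = v(t6, c(40, 45, 48, 50, 52, 55)), alt = v(t6, rep(45, 6)),
      creat = v(t6, c(90, 95, 98, 100, 102, 105)),
      alb = v(t6, c(35, 33, 31, 29, 28, 26)),
      wbc = v(t6, c(15, 13, 12, 11, 11, 12)),
      elwi = v(t6, rep(7.5, 6)),
      tnfa = v(t6, c(40, 150, 120, 100, 80, 70),
               c(40, 220, 180, 150, 120, 100)),
      il10 = v(t6, c(25, 60, 80, 100, 80, 60)),
      bet = v(t6, rep(0.9, 6)), hmgb1 = v(t6, rep(2.2, 6))),
    sepsis = list(
      map = v(t6, c(90, 85, 82, 78, 76, 70), c(90, 82, 78, 72, 70, 66)),
      hr = v(t6, c(90, 105, 110, 115, 118, 120),
             c(90, 112, 118, 124, 128, 130)),
      ci = v(t6, c(3.5, 3.4, 3.3, 3.3, 3.2, 3.1),
             c(3.5, 3.3, 3.2, 3.1, 3.0, 2.9)),
      co = v(t6, c(4.0, 3.9, 3.8, 3.8, 3.7, 3.6),
             c(4.0, 3.8, 3.6, 3.5, 3.4, 3.3)),
      cvp = v(t6, rep(6, 6)),
      pf = v(t6, c(450, 420, 380, 330, 320, 310),
             c(450, 400, 340, 260, 245, 235)),
      fio2 = v(t6, rep(0.30, 6)),
      sao2 = v(t6, c(0.97, 0.96, 0.95, 0.94, 0.94, 0.93),
               c(0.97, 0.95, 0.94, 0.92, 0.92, 0.91)),
      svo2 = v(t6, c(0.70, 0.66, 0.63, 0.60, 0.58, 0.57),
               c(0.70, 0.64, 0.60, 0.56, 0.54, 0.53)),
      hb = v(t6, c(10, 10.2, 10.4, 10.6, 10.7, 10.8)),
      urine = v(t6, c(1.2, 0.9, 0.7, 0.45, 0.42, 0.40),
                c(1.2, 0.8, 0.6, 0.35, 0.33, 0.30)),
      bili = v(t6, c(8, 9, 10, 11, 12, 13), c(8, 10, 11, 13, 15, 18)),
      plt = v(t6, c(350, 330, 300, 260, 230, 200),
              c(350, 320, 280, 210, 180, 155)),
      lact = v(t6, c(1.2, 1.8, 2.1, 2.4, 2.5, 2.6),
               c(1.2, 2.1, 2.5, 3.0, 3.1, 3.2)),
      ast = v(t6, c(40, 50, 60, 65, 70, 75), c(40, 60, 75, 85, 95, 105)),
      alt = v(t6, c(45, 47, 49, 50, 52, 53)),
      creat = v(t6, c(90, 100, 110, 115, 120, 125),
                c(90, 110, 130, 145, 150, 155)),
      alb = v(t6, c(35, 33, 30, 28, 27, 26), c(35, 32, 29, 27, 25, 24)),
      wbc = v(t6, c(15, 9, 6, 5, 6, 8), c(15, 8, 5, 4, 5, 7)),
      elwi = v(t6, c(7, 7.5, 8, 8.5, 9, 9.2),
               c(7, 7.7, 8.3, 8.8, 9.3, 9.5)),
      tnfa = v(t6, c(40, 400, 300, 220, 180, 150),
               c(40, 800, 550, 380, 300, 250)),
      il10 = v(t6, c(25, 80, 120, 160, 120, 80),
               c(25, 120, 200, 300, 220, 150)),
      bet = v(t6, c(0.8, 0.9, 1.0, 1.1, 1.1, 1.2),
              c(0.8, 1.0, 1.1, 1.3, 1.3, 1.4)),
      hmgb1 = v(t6, c(2, 2.2, 2.4, 2.6, 2.7, 2.8),
                c(2, 2.4, 2.7, 3.0, 3.1, 3.2))),
    septic_shock = list(
      map = v(t7, c(90, 80, 70, 58, 52, 48, 45),
              c(90, 75, 65, 54, 48, 44, 42)),
      hr = v(t7, c(90, 110, 120, 125, 130, 135, 140),
             c(90, 120, 130, 135, 140, 145, 150)),
      ci = v(t7, c(3.5, 3.2, 3.0, 2.8, 2.7, 2.6, 2.5),
             c(3.5, 3.0, 2.8, 2.5, 2.4, 2.3, 2.2)),
      co = v(t7, c(4.0, 3.6, 3.4, 3.2, 3.1, 3.0, 2.9),
             c(4.0, 3.4, 3.1, 2.9, 2.8, 2.7, 2.6)),
      cvp = v(t7, rep(7, 7)),
      pf = v(t7, c(450, 380, 300, 230, 215, 200, 185),
             c(450, 350, 260, 180, 165, 150, 140)),
      fio2 = v(t7, rep(0.35, 7)),
      sao2 = v(t7, c(0.97, 0.95, 0.93, 0.91, 0.90, 0.89, 0.88),
               c(0.97, 0.94, 0.91, 0.88, 0.87, 0.86, 0.85)),
      svo2 = v(t7, c(0.70, 0.62, 0.56, 0.52, 0.50, 0.48, 0.45),
               c(0.70, 0.58, 0.52, 0.47, 0.45, 0.43, 0.40)),
      hb = v(t7, c(10, 10.5, 11, 11.3, 11.5, 11.6, 11.8)),
      urine = v(t7, c(1.2, 0.7, 0.45, 0.22, 0.18, 0.15, 0.12),
                c(1.2, 0.6, 0.35, 0.16, 0.12, 0.10, 0.08)),
      bili = v(t7, c(8, 10, 13, 15, 16, 28, 35),
               c(8, 12, 16, 20, 22, 42, 70)),
      plt = v(t7, c(350, 300, 240, 160, 150, 120, 90),
              c(350, 280, 200, 110, 100, 70, 45)),
      lact = v(t7, c(1.2, 2.5, 3.0, 3.5, 3.6, 4.2, 4.5),
               c(1.2, 3.2, 4.0, 4.8, 5.0, 5.8, 6.5)),
      ast = v(t7, c(40, 70, 95, 120, 125, 140, 150),
              c(40, 90, 120, 150, 158, 180, 200)),
      alt = v(t7, c(45, 50, 55, 57, 57, 60, 62)),
      creat = v(t7, c(90, 110, 140, 160, 165, 185, 200),
                c(90, 130, 170, 200, 208, 225, 240)),
      alb = v(t7, c(35, 32, 29, 26, 25, 24, 23),
              c(35, 30, 27, 24, 23, 22, 21)),
      wbc = v(t7, c(15, 7, 5, 4, 4, 4.5, 5),
              c(15, 6, 4, 3, 3, 3.5, 4)),
      elwi = v(t7, c(7, 8, 9, 10.5, 10.8, 11.2, 11.8),
               c(7, 8.5, 9.8, 11.2, 11.5, 12.2, 13)),
      tnfa = v(t7, c(40, 700, 550, 420, 400, 340, 300),
               c(40, 1400, 1050, 800, 760, 620, 550)),
      il10 = v(t7, c(25, 130, 200, 280, 275, 220, 160),
               c(25, 200, 320, 500, 490, 380, 280)),
      bet = v(t7, c(0.8, 1.0, 1.5, 2.5, 2.7, 3.5, 4.0),
              c(0.8, 1.2, 2.2, 4.0, 4.3, 5.5, 6.5)),
      hmgb1 = v(t7, c(2, 3, 5, 8, 8.5, 10, 11),
                c(2, 4, 8, 13, 14, 17, 20))),
    fulminant = list(
      map = v(t3, c(90, 62, 50), c(90, 55, 42)),
      hr = v(t3, c(90, 140, 150), c(90, 150, 160)),
      ci = v(t3, c(3.5, 2.6, 2.2)), co = v(t3, c(4.0, 3.0, 2.6)),
      cvp = v(t3, rep(7, 3)),
      pf = v(t3, c(450, 250, 180), c(450, 200, 140)),
      fio2 = v(t3, rep(0.30, 3)),
      sao2 = v(t3, c(0.97, 0.90, 0.86)),
      svo2 = v(t3, c(0.70, 0.50, 0.42), c(0.70, 0.46, 0.38)),
      hb = v(t3, c(10, 12.5, 13)),
      urine = v(t3, c(1.2, 0.3, 0.15)),
      bili = v(t3, c(8, 18, 26), c(8, 24, 34)),
      plt = v(t3, c(350, 180, 120)),
      lact = v(t3, c(1.2, 4.5, 6.0), c(1.2, 6.5, 8.5)),
      ast = v(t3, c(40, 110, 160)), alt = v(t3, c(45, 52, 58)),
      creat = v(t3, c(90, 150, 200)),
      alb = v(t3, c(35, 23, 20), c(35, 21, 17)),
      wbc = v(t3, c(15, 4, 3)), elwi = v(t3, c(7, 10, 12)),
      tnfa = v(t3, c(40, 1500, 1200), c(40, 2100, 1700)),
      il10 = v(t3, c(25, 150, 250)),
      bet = v(t3, c(0.8, 2.0, 3.5)), hmgb1 = v(t3, c(2, 6, 10)))
  )
}

# Interpolate one template variable at `times` for severity u.
template_curve <- function(tmpl_var, u, times) {
  vals <- tmpl_var$mild + u * (tmpl_var$severe - tmpl_var$mild)
  approx(tmpl_var$t, vals, xout = times, rule = 2)$y
}

#' Generate a synthetic minipig sepsis cohort
#'
#' Draws a cohort under a [cohort_config()]: each inoculated animal gets a
#' log-uniform total inoculum CFU and a latent severity
#' `severity_coupling x (log10 CFU - min) + noise`; trajectory templates
#' (non-responder, sepsis, septic shock, fulminant) are assigned by
#' latent-severity rank with deterministic quota counts for the
#' non-responder and fulminant templates and a median split of the
#' remainder; within-template severity scales the piecewise-linear anchor
#' curves, and multiplicative lognormal measurement noise is applied. The
#' in-window supportive-therapy rules ([evaluate_triggers()]) are applied
#' hour by hour so vasopressor/diuretic states arise endogenously: a
#' running norepinephrine infusion holds observed MAP at the 65 mmHg
#' target and doubles each hour the unsupported pressure remains at or
#' below the trigger. Fulminant animals are terminated between 6 and 15 h.
#' Output is deterministic for a fixed seed.
#'
#' @param config A [cohort_config()].
#' @param policy A [therapy_policy()] used inside the simulation loop.
#' @return A list of class `psofa_cohort`: `animals` (identity, inoculum
#'   load, latent severity, true template), `monitoring` (one row per
#'   animal-hour), `therapy_events` (event log), `microbiology` (inoculum
#'   plate counts), `hemoculture` (18-h blood-culture loads), and the
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            policy = therapy_policy()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_animals
  n_sham <- round(n * config$sham_fraction)
  n_inoc <- n - n_sham
  if (n_inoc < 1) stop("Configuration leaves no inoculated animals.",
                       call. = FALSE)
  ids <- sprintf("pig%03d", seq_len(n))
  sham_ids <- ids[seq_len(n_sham)]
  inoc_ids <- setdiff(ids, sham_ids)

  r <- config$cfu_log10_range
  log10_cfu <- runif(n_inoc, r[1], r[2])
  s <- config$severity_coupling * (log10_cfu - r[1]) +
    rnorm(n_inoc, 0, config$severity_noise_sd)

  n_nr <- round(n_inoc * config$nonresponder_fraction)
  n_ful <- round(n_inoc * config$fulminant_fraction)
  if (n_nr + n_ful > n_inoc) {
    stop("Template quota fractions exceed the inoculated cohort.",
         call. = FALSE)
  }
  ord <- order(s)
  template <- rep("sepsis", n_inoc)
  if (n_nr > 0) template[ord[seq_len(n_nr)]] <- "non_responder"
  if (n_ful > 0) template[ord[seq(n_inoc - n_ful + 1, n_inoc)]] <- "fulminant"
  mid <- which(template == "sepsis")
  if (length(mid) > 1) {
    n_shock <- floor(length(mid) / 2)
    if (n_shock > 0) {
      shock_idx <- mid[order(s[mid], decreasing = TRUE)[seq_len(n_shock)]]
      template[shock_idx] <- "septic_shock"
    }
  }
  u <- numeric(n_inoc)
  for (tp in unique(template)) {
    i <- which(template == tp)
    u[i] <- if (length(i) == 1L) 0.5 else
      (rank(s[i], ties.method = "first") - 1) / (length(i) - 1)
  }

  total_cfu <- 10^log10_cfu
  animals <- tibble::tibble(
    animal_id = ids,
    group = c(rep("sham", n_sham), rep("fecal", n_inoc)),
    template = c(rep("sham", n_sham), template),
    log10_cfu = c(rep(NA_real_, n_sham), log10_cfu),
    total_cfu = c(rep(NA_real_, n_sham), total_cfu),
    latent_severity = c(rep(NA_real_, n_sham), s),
    severity_u = c(rep(0.5, n_sham), u))
  animals$band <- factor(NA, levels = levels(severity_band(1)),
                         ordered = TRUE)
  inoc_rows <- animals$group == "fecal"
  animals$band[inoc_rows] <- severity_band(animals$total_cfu[inoc_rows],
                                           config$band_thresholds)

  tmpl <- cohort_templates()
  mon_list <- vector("list", n)
  ev_list <- vector("list", n)
  for (i in seq_len(n)) {
    res <- simulate_animal(animals$animal_id[i], animals$template[i],
                           animals$severity_u[i], config, policy, tmpl)
    mon_list[[i]] <- res$monitoring
    ev_list[[i]] <- res$events
  }
  monitoring <- dplyr::bind_rows(mon_list)
  therapy_events <- dplyr::bind_rows(ev_list)

  microbiology <- inoculum_plate_counts(animals[inoc_rows, ], config)
  hemoculture <- hemoculture_table(animals[inoc_rows, ])

  structure(list(animals = animals, monitoring = monitoring,
                 therapy_events = therapy_events,
                 microbiology = microbiology, hemoculture = hemoculture,
                 config = config),
            class = "psofa_cohort")
}

#' @export
print.psofa_cohort <- function(x, ...) {
  cat(sprintf("Synthetic minipig cohort: %d animals (%d sham), %d rows\n",
              nrow(x$animals), sum(x$animals$group == "sham"),
              nrow(x$monitoring)))
  print(table(x$animals$template), ...)
  invisible(x)
}

# One animal's trajectory plus endogenous therapy events.
simulate_animal <- function(id, template, u, config, policy, tmpl) {
  tt <- tmpl[[template]]
  nz <- config$noise
  times <- config$times
  if (template == "fulminant") {
    term <- 15 - 9 * u       # humane endpoint between 6 and 15 h
    times <- times[times <= max(6, term)]
  }
  m <- length(times)
  val <- function(var) template_curve(tt[[var]], u, times)
  mnoise <- function(x, sd) x * exp(rnorm(length(x), 0, sd))

  map_raw <- mnoise(val("map"), nz$map)
  hr <- mnoise(val("hr"), nz$hr)
  ci <- mnoise(val("ci"), nz$ci)
  co <- mnoise(val("co"), nz$co)
  cvp <- mnoise(val("cvp"), nz$cvp)
  pf <- mnoise(val("pf"), nz$pf)
  fio2 <- val("fio2")
  sao2 <- pmin(1, pmax(0, val("sao2") + rnorm(m, 0, nz$sao2)))
  svo2 <- pmin(sao2 - 0.005, pmax(0, val("svo2") + rnorm(m, 0, nz$svo2)))
  hb <- mnoise(val("hb"), nz$hb)
  urine <- mnoise(val("urine"), nz$urine)
  bili <- mnoise(val("bili"), nz$bili)
  plt <- mnoise(val("plt"), nz$plt)
  lact <- mnoise(val("lact"), nz$lact)
  ast <- mnoise(val("ast"), nz$ast)
  alt <- mnoise(val("alt"), nz$alt)
  creat <- mnoise(val("creat"), nz$creat)
  alb <- mnoise(val("alb"), nz$alb)
  wbc <- mnoise(val("wbc"), nz$wbc)
  elwi <- mnoise(val("elwi"), nz$elwi)
  tnfa <- mnoise(val("tnfa"), nz$tnfa)
  il10 <- mnoise(val("il10"), nz$il10)
  bet <- mnoise(val("bet"), nz$bet)
  hmgb1 <- mnoise(val("hmgb1"), nz$hmgb1)

  events <- list()
  add_event <- function(t, drug, dose, units) {
    events[[length(events) + 1L]] <<-
      tibble::tibble(animal_id = id, time_h = t, drug = drug, dose = dose,
                     units = units)
  }
  # Protocol maintenance fluids at 6 and 12 h for every surviving animal.
  for (t in c(6, 12)) {
    if (t <= max(times)) add_event(t, "crystalloid",
                                   policy$fluid_bolus_ml_kg, "ml_kg")
  }

  map_obs <- map_raw
  nor_dose <- 0
  furo_cum <- 0
  first_resus <- NA_real_
  last_furo <- NA_real_
  window_idx <- which(times >= 16)
  for (k in window_idx) {
    t <- times[k]
    if (nor_dose > 0) {
      # The infusion holds MAP at the target; titrate up while the
      # unsupported pressure stays at/below the trigger.
      map_obs[k] <- max(map_raw[k], policy$map_norepi_trigger_mmHg + 10)
      if (map_raw[k] <= policy$map_norepi_trigger_mmHg) {
        nor_dose <- min(1, 2 * nor_dose)
        add_event(t, "norepinephrine", nor_dose, "ug_kg_min")
      }
    }
    minutes <- if (is.na(first_resus)) 0 else 60 * (t - first_resus)
    state <- therapy_state(
      norepinephrine_ug_kg_min = nor_dose,
      furosemide_cum_mg = furo_cum,
      crystalloid_ml_kg_h = 0,
      minutes_on_fluid_resuscitation = minutes,
      time_h = t, last_furosemide_time_h = last_furo)
    sample <- list(time_h = t, map_mmHg = map_obs[k],
                   urine_output_ml_kg_h = urine[k], elwi_ml_kg = elwi[k],
                   ci_L_min_m2 = ci[k], hr_bpm = hr[k])
    actions <- evaluate_triggers(sample, state, policy)
    if ("give_fluid_bolus" %in% actions) {
      add_event(t, "crystalloid", policy$fluid_bolus_ml_kg, "ml_kg")
      if (is.na(first_resus)) first_resus <- t
    }
    if ("start_norepinephrine" %in% actions) {
      nor_dose <- policy$norepi_start_dose
      add_event(t, "norepinephrine", nor_dose, "ug_kg_min")
      map_obs[k] <- max(map_raw[k], policy$map_norepi_trigger_mmHg + 10)
    }
    if ("give_furosemide" %in% actions) {
      furo_cum <- furo_cum + policy$furosemide_bolus_mg
      last_furo <- t
      add_event(t, "furosemide", policy$furosemide_bolus_mg, "mg")
    }
  }

  monitoring <- tibble::tibble(
    animal_id = id, time_h = times, map_mmHg = map_obs,
    pao2_fio2 = pf, pao2_mmHg = pf * fio2, fio2_fraction = fio2,
    urine_output_ml_kg_h = urine, bilirubin_umol_L = bili,
    platelets_1e9_L = plt, lactate_mmol_L = lact,
    sao2_fraction = sao2, svo2_fraction = svo2, hb_g_dL = hb,
    co_L_min = co, ci_L_min_m2 = ci, cvp_mmHg = cvp, hr_bpm = hr,
    ast_U_L = ast, alt_U_L = alt, creatinine_umol_L = creat,
    albumin_g_L = alb, wbc_1e9_L = wbc, elwi_ml_kg = elwi,
    tnfa = tnfa, il10 = il10, bet = bet, hmgb1 = hmgb1)
  list(monitoring = monitoring,
       events = if (length(events)) dplyr::bind_rows(events) else
         tibble::tibble(animal_id = character(), time_h = numeric(),
                        drug = character(), dose = numeric(),
                        units = character()))
}

# Retrospective viable plate counts consistent with each inoculum load.
inoculum_plate_counts <- function(inoc_animals, config) {
  cfu_ml <- inoc_animals$total_cfu / config$inoculum_volume_ml
  dil_pow <- pmax(0, ceiling(log10(cfu_ml * 0.1 / 150)))
  dilution <- 10^dil_pow
  colonies <- round(cfu_ml * 0.1 / dilution)
  tibble::tibble(sample_id = inoc_animals$animal_id,
                 colonies = colonies, dilution_factor = dilution,
                 plated_ml = 0.1)
}

# 18-h blood-culture loads, lognormal around a severity-proportional mean;
# fulminant animals are terminated before sampling.
hemoculture_table <- function(inoc_animals) {
  alive <- inoc_animals[inoc_animals$template != "fulminant", , drop = FALSE]
  log10_cfu_ml <- -1.5 + 0.9 * alive$latent_severity +
    rnorm(nrow(alive), 0, 0.3)
  tibble::tibble(animal_id = alive$animal_id, time_h = 18,
                 cfu_per_ml = 10^log10_cfu_ml,
                 positive = log10_cfu_ml > 0)
}

#' Recover the CFU-severity correlation from a synthetic cohort
#'
#' Scores a generated cohort and computes the Spearman correlation between
#' log10 inoculum CFU and each inoculated animal's mean pSOFA total. For
#' animals reaching the invasive-monitoring window the mean is taken over
#' the in-window hours; animals terminated early at the humane endpoint
#' contribute the mean over their available post-induction hours.
#'
#' @param cohort A `psofa_cohort` from [generate_cohort()].
#' @param basis `"5d"` (default) or `"3d"` totals.
#' @param window Scoring window for surviving animals (default 16--24 h).
#' @return List with `r` (Spearman coefficient), `n`, and the `per_animal`
#'   tibble.
#' @export
score_recovery <- function(cohort, basis = c("5d", "3d"),
                           window = c(16, 24)) {
  basis <- match.arg(basis)
  stopifnot(inherits(cohort, "psofa_cohort"))
  inoc <- cohort$animals[cohort$animals$group == "fecal", , drop = FALSE]
  mon <- cohort$monitoring[cohort$monitoring$animal_id %in%
                             inoc$animal_id, , drop = FALSE]
  col <- if (basis == "5d") "mean_5d" else "mean_3d"
  last_t <- tapply(mon$time_h, mon$animal_id, max)
  in_window_ids <- names(last_t)[last_t >= window[1]]
  early_ids <- setdiff(unique(mon$animal_id), in_window_ids)

  parts <- list()
  if (length(in_window_ids)) {
    ts <- score_timeseries(mon[mon$animal_id %in% in_window_ids, ],
                           cohort$therapy_events, window = window)
    parts$surv <- ts$animal_summary[, c("animal_id", col)]
  }
  if (length(early_ids)) {
    ts <- score_timeseries(mon[mon$animal_id %in% early_ids, ],
                           cohort$therapy_events, window = c(0.5, 15))
    parts$early <- ts$animal_summary[, c("animal_id", col)]
  }
  means <- dplyr::bind_rows(parts)
  per_animal <- dplyr::inner_join(
    inoc[, c("animal_id", "log10_cfu", "template")], means, by = "animal_id")
  r <- spearman_cor(per_animal$log10_cfu, per_animal[[col]],
                    band = FALSE)$r
  list(r = r, n = nrow(per_animal), per_animal = per_animal)
}
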