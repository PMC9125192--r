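#' Read a tidy monitoring CSV
#'
#' One row per animal-hour, UTF-8, header required, columns named as in
#' [monitoring_sample()] plus `animal_id`. Schema violations are reported
#' with the offending column names.
#'
#' @param path CSV path.
#' @return Validated tibble.
#' @export
read_monitoring <- function(path) {
  df <- read_checked(path, c("animal_id", "time_h"))
  df <- complete_pf_ratio(df)
  validate_monitoring(df)
}

#' Read a therapy event log CSV
#'
#' Columns `animal_id`, `time_h`, `drug`, `dose` (plus optional `units`).
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_therapy_log <- function(path) {
  read_checked(path, c("animal_id", "time_h", "drug", "dose"))
}

read_checked <- function(path, required) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("Cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) {
    stop("Schema error in ", path, ": no data rows.", call. = FALSE)
  }
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("Schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), ".", call. = FALSE)
  }
  df
}

#' Write the cohort tables of a synthetic cohort to disk
#'
#' Emits `monitoring.csv`, `therapy_events.csv`, `microbiology.csv`,
#' `hemoculture.csv`, `animals.csv` and a `manifest.json` recording the
#' configuration, seed and a configuration hash.
#'
#' @param cohort A `psofa_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "psofa_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$monitoring, file.path(dir, "monitoring.csv"))
  readr::write_csv(cohort$therapy_events,
                   file.path(dir, "therapy_events.csv"))
  readr::write_csv(cohort$microbiology, file.path(dir, "microbiology.csv"))
  readr::write_csv(cohort$hemoculture, file.path(dir, "hemoculture.csv"))
  animals <- cohort$animals
  animals$band <- as.character(animals$band)
  readr::write_csv(animals, file.path(dir, "animals.csv"))
  invisible(write_manifest(dir, "simulate", cohort$config,
                           cohort$config$seed,
                           inputs = character()))
}

write_manifest <- function(dir, stage, config, seed, inputs) {
  cfg <- unclass(config)
  manifest <- list(
    stage = stage,
    package = "psofa",
    version = as.character(utils::packageVersion("psofa")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = cfg,
    config_hash = rlang::hash(cfg),
    inputs = as.list(inputs))
  jsonlite::write_json(manifest,
                       file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  manifest
}

#' Group-wise hourly summaries and rank tests
#'
#' Assembles the analysis tables of the severity pipeline: per-group
#' hourly medians with 25th/75th percentiles for the score totals,
#' between-group Kruskal-Wallis + Dunn tests per hour, and the Spearman
#' correlation tables relating log10 inoculum CFU, log10 hemoculture CFU
#' and selected biomarkers to the pSOFA scores.
#'
#' @param scores Per animal-hour score table (from
#'   [score_timeseries()]`$scores` or the score CSV).
#' @param labels Per-animal label table (from [classify_cohort()]).
#' @param monitoring Monitoring table (for biomarkers).
#' @param microbiology Inoculum plate-count table (`sample_id`, `colonies`,
#'   `dilution_factor`, `plated_ml`), or `NULL`.
#' @param hemoculture Blood-culture table (`animal_id`, `cfu_per_ml`), or
#'   `NULL`.
#' @param inoculum_volume_ml Suspension volume for total-CFU conversion.
#' @return List of tibbles: `group_summary`, `group_tests`,
#'   `correlations`.
#' @export
analyze_cohort <- function(scores, labels, monitoring,
                           microbiology = NULL, hemoculture = NULL,
                           inoculum_volume_ml = 200) {
  stopifnot(is.data.frame(scores), is.data.frame(labels))
  lab <- labels[, c("animal_id", "label")]
  sc <- dplyr::inner_join(scores, lab, by = "animal_id")

  q25 <- function(x) unname(quantile(x, 0.25, na.rm = TRUE))
  q75 <- function(x) unname(quantile(x, 0.75, na.rm = TRUE))
  group_summary <- sc |>
    tidyr::pivot_longer(dplyr::all_of(c("total_3d", "total_5d")),
                        names_to = "score", values_to = "value") |>
    dplyr::group_by(.data$label, .data$time_h, .data$score) |>
    dplyr::summarise(n = sum(!is.na(.data$value)),
                     median = median(.data$value, na.rm = TRUE),
                     p25 = q25(.data$value), p75 = q75(.data$value),
                     .groups = "drop")

  test_rows <- list()
  for (t in sort(unique(sc$time_h))) {
    sub <- sc[sc$time_h == t & !is.na(sc$total_3d), ]
    tab <- table(sub$label[!is.na(sub$label)])
    tab <- tab[tab >= 2]
    if (length(tab) < 2) next
    sub <- sub[sub$label %in% names(tab), ]
    kw <- tryCatch(
      kruskal_wallis_dunn(sub$total_3d, as.character(sub$label)),
      warning = function(w) NULL)
    if (is.null(kw)) next
    test_rows[[length(test_rows) + 1L]] <- tibble::tibble(
      time_h = t, H = kw$H, df = kw$df, p_value = kw$p_value,
      n_significant_pairs = sum(kw$dunn$p_adj < 0.05))
  }
  group_tests <- dplyr::bind_rows(test_rows)

  per_animal <- sc |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(mean_3d = mean(.data$total_3d),
                     mean_5d = mean(.data$total_5d), .groups = "drop")

  cors <- list()
  add_cor <- function(name, x, y) {
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) >= 3 && length(unique(x[keep])) > 1 &&
        length(unique(y[keep])) > 1) {
      ct <- spearman_cor(x[keep], y[keep], band = FALSE)
      cors[[length(cors) + 1L]] <<- tibble::tibble(
        comparison = name, r = ct$r, n = ct$n, p_value = ct$p_value)
    }
  }
  if (!is.null(microbiology) && nrow(microbiology)) {
    mb <- plate_counts_to_cfu(microbiology)
    mb$total_cfu <- mb$cfu_per_ml * inoculum_volume_ml
    mrg <- dplyr::inner_join(
      per_animal, mb[, c("sample_id", "total_cfu")],
      by = c(animal_id = "sample_id"))
    mrg <- mrg[mrg$total_cfu > 0, ]
    add_cor("log10_inoculum_cfu_vs_mean_3d", log10(mrg$total_cfu),
            mrg$mean_3d)
    add_cor("log10_inoculum_cfu_vs_mean_5d", log10(mrg$total_cfu),
            mrg$mean_5d)
  }
  if (!is.null(hemoculture) && nrow(hemoculture)) {
    mrg <- dplyr::inner_join(per_animal,
                             hemoculture[, c("animal_id", "cfu_per_ml")],
                             by = "animal_id")
    mrg <- mrg[mrg$cfu_per_ml > 0, ]
    add_cor("log10_hemoculture_cfu_vs_mean_3d", log10(mrg$cfu_per_ml),
            mrg$mean_3d)
    add_cor("log10_hemoculture_cfu_vs_mean_5d", log10(mrg$cfu_per_ml),
            mrg$mean_5d)
  }
  if (!is.null(monitoring)) {
    final_t <- max(scores$time_h)
    sc24 <- sc[sc$time_h == final_t, c("animal_id", "total_3d", "total_5d")]
    bm <- function(var, t) {
      sub <- monitoring[abs(monitoring$time_h - t) < 0.5,
                        c("animal_id", var)]
      names(sub)[2] <- "biomarker"
      dplyr::inner_join(sc24, sub, by = "animal_id")
    }
    if ("tnfa" %in% names(monitoring)) {
      d <- bm("tnfa", 6)
      add_cor("tnfa_6h_vs_total_5d_24h", d$biomarker, d$total_5d)
    }
    for (v in c("il10", "bet", "hmgb1")) {
      if (v %in% names(monitoring)) {
        d <- bm(v, 16)
        add_cor(paste0(v, "_16h_vs_total_5d_24h"), d$biomarker, d$total_5d)
      }
    }
  }
  list(group_summary = group_summary, group_tests = group_tests,
       correlations = dplyr::bind_rows(cors))
}

#' Run one stage of the severity pipeline
#'
#' File-based pipeline over the package's functions, re-runnable from any
#' intermediate CSV (no hidden state). Stages:
#' * `simulate` — generate a synthetic cohort into `out_dir`;
#' * `score` — read `monitoring.csv` (+ optional `therapy_events.csv`)
#'   from `in_dir`, write `scores.csv` with derived oxygen/hemodynamic
#'   columns appended;
#' * `classify` — read scores, monitoring and therapy, write `labels.csv`
#'   with the criteria audit trail;
#' * `analyze` — read scores, labels and microbiology tables, write
#'   `group_summary.csv`, `group_tests.csv` and `correlations.csv`.
#' Every stage writes a `manifest_<stage>.json` recording configuration,
#' seed and input files.
#'
#' @param stage One of `"simulate"`, `"score"`, `"classify"`, `"analyze"`.
#' @param in_dir Directory holding the stage inputs (not needed for
#'   `simulate`).
#' @param out_dir Output directory (default `in_dir`).
#' @param config A [cohort_config()] (simulate only).
#' @param seed Integer seed applied to the configuration (simulate only).
#' @param mode Scoring threshold set, `"pig"` or `"human"`.
#' @param window Scoring window (hours).
#' @param policy A [classification_policy()] (classify only).
#' @return Invisibly, the paths written.
#' @export
run_pipeline <- function(stage = c("simulate", "score", "classify",
                                   "analyze"),
                         in_dir = NULL, out_dir = in_dir,
                         config = cohort_config(), seed = NULL,
                         mode = "pig", window = c(16, 24),
                         policy = classification_policy()) {
  stage <- match.arg(stage)
  if (is.null(out_dir)) stop("`out_dir` is required.", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()

  if (stage == "simulate") {
    if (!is.null(seed)) config$seed <- seed
    cohort <- generate_cohort(config)
    write_cohort(cohort, out_dir)
    written <- file.path(out_dir,
                         c("monitoring.csv", "therapy_events.csv",
                           "microbiology.csv", "hemoculture.csv",
                           "animals.csv"))
  } else if (stage == "score") {
    mon_path <- file.path(in_dir, "monitoring.csv")
    monitoring <- read_monitoring(mon_path)
    th_path <- file.path(in_dir, "therapy_events.csv")
    therapy <- if (file.exists(th_path)) read_therapy_log(th_path) else NULL
    ts <- score_timeseries(monitoring, therapy, window = window,
                           mode = mode)
    scored <- dplyr::left_join(
      ts$scores,
      append_derived(monitoring)[, c("animal_id", "time_h", "do2", "vo2",
                                     "exo2", "svri", "svi_ml_beat_m2",
                                     "de_ritis")],
      by = c("animal_id", "time_h"))
    out <- file.path(out_dir, "scores.csv")
    readr::write_csv(scored, out)
    readr::write_csv(ts$animal_summary,
                     file.path(out_dir, "animal_summary.csv"))
    write_manifest(out_dir, "score", list(mode = mode, window = window),
                   seed, inputs = mon_path)
    written <- out
  } else if (stage == "classify") {
    monitoring <- read_monitoring(file.path(in_dir, "monitoring.csv"))
    th_path <- file.path(in_dir, "therapy_events.csv")
    therapy <- if (file.exists(th_path)) read_therapy_log(th_path) else NULL
    an_path <- file.path(in_dir, "animals.csv")
    animals <- if (file.exists(an_path)) {
      read_checked(an_path, c("animal_id", "group"))
    } else NULL
    labels <- classify_cohort(monitoring, therapy, animals, policy,
                              mode = mode)
    labels$label <- as.character(labels$label)
    out <- file.path(out_dir, "labels.csv")
    readr::write_csv(labels, out)
    write_manifest(out_dir, "classify", unclass(policy), seed,
                   inputs = file.path(in_dir, "monitoring.csv"))
    written <- out
  } else {
    scores <- read_checked(file.path(in_dir, "scores.csv"),
                           c("animal_id", "time_h", "total_3d"))
    labels <- read_checked(file.path(in_dir, "labels.csv"),
                           c("animal_id", "label"))
    monitoring <- read_monitoring(file.path(in_dir, "monitoring.csv"))
    mb_path <- file.path(in_dir, "microbiology.csv")
    microbiology <- if (file.exists(mb_path)) {
      read_checked(mb_path, c("sample_id", "colonies", "dilution_factor"))
    } else NULL
    hc_path <- file.path(in_dir, "hemoculture.csv")
    hemoculture <- if (file.exists(hc_path)) {
      read_checked(hc_path, c("animal_id", "cfu_per_ml"))
    } else NULL
    res <- analyze_cohort(scores, labels, monitoring, microbiology,
                          hemoculture)
    for (nm in names(res)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      readr::write_csv(res[[nm]], p)
      written <- c(written, p)
    }
    write_manifest(out_dir, "analyze", list(), seed,
                   inputs = file.path(in_dir, "scores.csv"))
  }
  invisible(written)
}
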