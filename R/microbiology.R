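#' Viable count from a dilution plate
#'
#' Standard viable plate count: `CFU mL^-1 = colonies x dilution_factor /
#' plated_volume_ml`. Zero colonies give 0 CFU mL^-1 and should be treated
#' as below the detection limit of the plated dilution.
#'
#' @param colonies Colony count on the plate (>= 0).
#' @param dilution_factor Fold dilution of the plated sample (>= 1).
#' @param plated_volume_ml Plated volume (default 0.1 mL per the protocol).
#' @return CFU mL^-1 (numeric, vectorised).
#' @examples
#' cfu_from_plate(62, 1e4)           # 6.2e6 CFU/mL
#' @export
cfu_from_plate <- function(colonies, dilution_factor, plated_volume_ml = 0.1) {
  check_numeric(colonies, "colonies", min = 0)
  check_numeric(dilution_factor, "dilution_factor", min = 1)
  check_numeric(plated_volume_ml, "plated_volume_ml", min = 0,
                strict_min = TRUE)
  colonies * dilution_factor / plated_volume_ml
}

#' Convert a plate-count table to CFU concentrations
#'
#' @param counts Data frame with columns `colonies`, `dilution_factor` and
#'   optionally `plated_ml` (default 0.1).
#' @return The input with `cfu_per_ml` and `below_detection` columns added.
#' @export
plate_counts_to_cfu <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("colonies", "dilution_factor") %in% names(counts)))
  vol <- if ("plated_ml" %in% names(counts)) counts$plated_ml else 0.1
  counts$cfu_per_ml <- cfu_from_plate(counts$colonies,
                                      counts$dilution_factor, vol)
  counts$below_detection <- counts$colonies == 0
  tibble::as_tibble(counts)
}

#' Inoculum severity band
#'
#' Maps the total microbial load of the inducer inoculum to the observed
#' severity bands: loads under 1.34e7 CFU did not produce a septic
#' reaction (`sub_septic`), loads above 4e8 CFU made sepsis/septic shock
#' likely (`sepsis_likely`), and loads above 8e9 CFU produced a fulminant
#' deterioration (`fulminant`); the range in between is `indeterminate`.
#' Boundary values fall in the lower band.
#'
#' @param total_cfu Total CFU in the inoculum (> 0), vectorised.
#' @param thresholds Numeric length-3 band boundaries (ascending).
#' @return Ordered factor with levels `sub_septic < indeterminate <
#'   sepsis_likely < fulminant`.
#' @examples
#' severity_band(c(1e6, 1e9, 1.2e10))
#' @export
severity_band <- function(total_cfu,
                          thresholds = c(1.34e7, 4e8, 8e9)) {
  check_numeric(total_cfu, "total_cfu", min = 0, strict_min = TRUE)
  stopifnot(length(thresholds) == 3L, !is.unsorted(thresholds))
  lev <- c("sub_septic", "indeterminate", "sepsis_likely", "fulminant")
  idx <- 1L + (total_cfu >= thresholds[1]) + (total_cfu > thresholds[2]) +
    (total_cfu > thresholds[3])
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Inoculum microbial profile
#'
#' Bundles the concentration, total load and severity band of a
#' sepsis-inducing fecal suspension.
#'
#' @param cfu_per_ml Microbial concentration of the suspension (CFU mL^-1).
#' @param volume_ml Suspension volume (default 200 mL).
#' @param species Optional character vector of species labels.
#' @inheritParams severity_band
#' @return A tibble with `cfu_per_ml`, `total_cfu`, `severity_band` and a
#'   `species` list-column.
#' @export
inoculum_profile <- function(cfu_per_ml, volume_ml = 200, species = NULL,
                             thresholds = c(1.34e7, 4e8, 8e9)) {
  check_numeric(cfu_per_ml, "cfu_per_ml", min = 0, strict_min = TRUE)
  check_scalar(volume_ml, "volume_ml", min = 0, strict_min = TRUE)
  total <- cfu_per_ml * volume_ml
  tibble::tibble(
    cfu_per_ml = cfu_per_ml,
    total_cfu = total,
    severity_band = severity_band(total, thresholds),
    species = if (is.null(species)) list(character())
              else list(as.character(species))
  )
}
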