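#' Spearman rank correlation with regression band
#'
#' Rank correlation as used throughout the severity analyses: mid-ranks for
#' ties, a t-approximation for the p-value, and an exact permutation null
#' for small samples (`n <= exact_n_max`). A least-squares regression line
#' of `y` on `x` with a pointwise 95% confidence band is attached for
#' plotting alongside the coefficient.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, neither constant.
#' @param exact_n_max Largest `n` for which the exact permutation p-value is
#'   computed (default 9).
#' @param band Logical; compute the regression line and confidence band
#'   (default `TRUE`; switch off in simulation loops).
#' @return An object of class `psofa_cor`: a list with `r`, `n`, `p_value`,
#'   `method`, `slope`, `intercept` and (optionally) a `band` tibble
#'   (`x`, `fit`, `lwr`, `upr`).
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_cor <- function(x, y, exact_n_max = 9, band = TRUE) {
  check_numeric(x, "x")
  check_numeric(y, "y")
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length.",
                           call. = FALSE)
  if (n < 3) stop("Need at least 3 pairs.", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("Spearman correlation is undefined for a constant vector.",
         call. = FALSE)
  }
  r <- cor(rx, ry)
  if (n <= exact_n_max) {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2))
    rho_perm <- apply(perms, 1L, function(p) {
      ryp <- ry[p]
      sum(rxc * (ryp - mean(ryp))) / (denom * sqrt(sum((ryp - mean(ryp))^2)))
    })
    p_value <- mean(abs(rho_perm) >= abs(r) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p_value <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  fit <- lm(y ~ x)
  out <- list(r = r, n = n, p_value = p_value, method = method,
              slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]))
  if (band) {
    grid <- data.frame(x = seq(min(x), max(x), length.out = 50))
    ci <- predict(fit, newdata = grid, interval = "confidence", level = 0.95)
    out$band <- tibble::tibble(x = grid$x, fit = ci[, "fit"],
                               lwr = ci[, "lwr"], upr = ci[, "upr"])
  }
  structure(out, class = "psofa_cor")
}

#' @export
print.psofa_cor <- function(x, ...) {
  cat(sprintf("Spearman r = %.3f (n = %d, p = %.4g, %s)\n",
              x$r, x$n, x$p_value, x$method))
  invisible(x)
}

# All permutations of 1..n as a matrix (n! rows). Used for the exact
# Spearman null; n is capped to keep this enumerable.
all_permutations <- function(n) {
  if (n > 9) stop("Exact enumeration is limited to n <= 9.", call. = FALSE)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    blk <- nrow(sub)
    out[row:(row + blk - 1L), ] <- cbind(sub, n)[, append(seq_len(n - 1L),
                                                          n, after = pos - 1L)]
    row <- row + blk
  }
  out
}

# Tie-corrected Dunn z-tests on the pooled ranks of k groups.
dunn_pairwise <- function(values, groups, p_adjust = "none") {
  N <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  levs <- unique(groups)
  mean_rank <- vapply(levs, function(g) mean(rk[groups == g]), numeric(1))
  n_g <- vapply(levs, function(g) sum(groups == g), numeric(1))
  cmb <- utils::combn(seq_along(levs), 2)
  z <- apply(cmb, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    (mean_rank[i] - mean_rank[j]) /
      sqrt(var_base * (1 / n_g[i] + 1 / n_g[j]))
  })
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(
    group1 = as.character(levs[cmb[1, ]]),
    group2 = as.character(levs[cmb[2, ]]),
    z = z, p = p,
    p_adj = stats::p.adjust(p, method = p_adjust),
    adjustment = p_adjust)
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Between-group analysis of ranks: the tie-corrected Kruskal-Wallis H
#' statistic with chi-square p-value, followed by Dunn's pairwise z-tests
#' on the pooled ranks. The default reports Dunn's raw z-test p-values
#' (no multiple-comparison adjustment, mirroring classic rank-based
#' post-hoc software); `p_adjust = "bonferroni"` or `"holm"` are available
#' and the choice is recorded in the output.
#'
#' @param values Numeric vector of observations, or a list of per-group
#'   numeric vectors (in which case `groups` is ignored).
#' @param groups Grouping vector parallel to `values`.
#' @param p_adjust Multiplicity adjustment for the Dunn p-values
#'   (`"none"`, `"bonferroni"`, `"holm"`, ...; passed to
#'   [stats::p.adjust()]).
#' @return List with `H`, `df`, `p_value`, `dunn` (pairwise tibble) and
#'   `degenerate` (TRUE when all observations are tied).
#' @examples
#' kruskal_wallis_dunn(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
#' @export
kruskal_wallis_dunn <- function(values, groups = NULL, p_adjust = "none") {
  if (is.list(values) && !is.data.frame(values)) {
    groups <- rep(names(values) %||% seq_along(values),
                  lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  check_numeric(values, "values")
  groups <- as.character(groups)
  stopifnot(length(groups) == length(values))
  tab <- table(groups)
  if (length(tab) < 2) stop("Need at least 2 groups.", call. = FALSE)
  if (any(tab < 2)) stop("Each group needs at least 2 observations.",
                         call. = FALSE)
  if (length(unique(values)) == 1L) {
    warning("All observations are tied; rank statistics are degenerate.")
    return(list(H = 0, df = length(tab) - 1L, p_value = 1,
                dunn = dunn_degenerate(names(tab), p_adjust),
                degenerate = TRUE))
  }
  kw <- kruskal.test(values, factor(groups))
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value,
       dunn = dunn_pairwise(values, groups, p_adjust),
       degenerate = FALSE)
}

dunn_degenerate <- function(levs, p_adjust) {
  cmb <- utils::combn(levs, 2)
  tibble::tibble(group1 = cmb[1, ], group2 = cmb[2, ], z = 0, p = 1,
                 p_adj = 1, adjustment = p_adjust)
}

#' Friedman test with Dunn-type contrasts against baseline
#'
#' Within-group (repeated-measures) analysis of ranks: the Friedman
#' chi-square statistic across repeated time points, followed by Dunn-type
#' z contrasts of each time point against the baseline (first) column,
#' using within-block ranks and the standard variance `k(k+1)/(6n)`.
#'
#' @param y Matrix or data frame, one row per subject (block), one column
#'   per repeated time point; the first column is the baseline.
#' @param p_adjust Multiplicity adjustment for the contrast p-values.
#' @return List with `chisq`, `df`, `p_value` and a `contrasts` tibble.
#' @export
friedman_dunn <- function(y, p_adjust = "none") {
  y <- as.matrix(y)
  if (!is.numeric(y)) stop("`y` must be numeric.", call. = FALSE)
  n <- nrow(y); k <- ncol(y)
  if (n < 2 || k < 2) {
    stop("Need at least 2 blocks and 2 repeated time points.", call. = FALSE)
  }
  if (length(unique(as.vector(y))) == 1L) {
    warning("All observations are tied; rank statistics are degenerate.")
    cols <- colnames(y) %||% paste0("t", seq_len(k))
    return(list(chisq = 0, df = k - 1L, p_value = 1,
                contrasts = tibble::tibble(
                  time = cols[-1], baseline = cols[1], z = 0, p = 1,
                  p_adj = 1, adjustment = p_adjust)))
  }
  fr <- friedman.test(y)
  rks <- t(apply(y, 1, rank))
  mean_rank <- colMeans(rks)
  se <- sqrt(k * (k + 1) / (6 * n))
  z <- (mean_rank[-1] - mean_rank[1]) / se
  p <- 2 * pnorm(-abs(z))
  cols <- colnames(y) %||% paste0("t", seq_len(k))
  list(chisq = unname(fr$statistic), df = unname(fr$parameter),
       p_value = fr$p.value,
       contrasts = tibble::tibble(time = cols[-1], baseline = cols[1],
                                  z = unname(z), p = unname(p),
                                  p_adj = stats::p.adjust(p, p_adjust),
                                  adjustment = p_adjust))
}

#' Survival-based sample-size estimate
#'
#' Schoenfeld's event count for a two-arm log-rank comparison,
#' `d = (z[1-a/2] + z[1-b])^2 / (p (1-p) (ln HR)^2)` with allocation
#' fraction `p` of subjects in the experimental arm, converted to group
#' sizes when per-arm event probabilities are supplied. All assumptions are
#' echoed in the output; the event-probability assumption is deliberately
#' an input because published designs rarely pin it down.
#'
#' @param hazard_ratio Presumed true hazard ratio (> 0, != 1).
#' @param power Target power `1 - beta` (default 0.9).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param allocation_fraction Fraction of subjects in the experimental arm
#'   (default 0.5).
#' @param event_prob_experimental,event_prob_control Optional per-arm event
#'   probabilities used to convert events to subjects.
#' @return List with `events_required` (integer), `events_raw`, the echoed
#'   assumptions, and (when event probabilities are given) `n_total`,
#'   `n_experimental`, `n_control`.
#' @examples
#' survival_sample_size(0.2, power = 0.9, alpha = 0.05,
#'                      allocation_fraction = 0.25)
#' @export
survival_sample_size <- function(hazard_ratio, power = 0.9, alpha = 0.05,
                                 allocation_fraction = 0.5,
                                 event_prob_experimental = NULL,
                                 event_prob_control = NULL) {
  check_scalar(hazard_ratio, "hazard_ratio", min = 0, strict_min = TRUE)
  if (hazard_ratio == 1) {
    stop("`hazard_ratio` = 1: no effect to power against.", call. = FALSE)
  }
  check_scalar(power, "power", min = 0, strict_min = TRUE)
  check_scalar(alpha, "alpha", min = 0, strict_min = TRUE)
  if (power >= 1 || alpha >= 1) {
    stop("`power` and `alpha` must lie in (0, 1).", call. = FALSE)
  }
  p <- allocation_fraction
  check_scalar(p, "allocation_fraction", min = 0, strict_min = TRUE)
  if (p >= 1) stop("`allocation_fraction` must lie in (0, 1).", call. = FALSE)
  d <- (qnorm(1 - alpha / 2) + qnorm(power))^2 /
    (p * (1 - p) * log(hazard_ratio)^2)
  out <- list(events_raw = d, events_required = ceiling(d),
              hazard_ratio = hazard_ratio, power = power, alpha = alpha,
              allocation_fraction = p)
  if (!is.null(event_prob_experimental) && !is.null(event_prob_control)) {
    check_scalar(event_prob_experimental, "event_prob_experimental",
                 min = 0, strict_min = TRUE, max = 1)
    check_scalar(event_prob_control, "event_prob_control",
                 min = 0, max = 1)
    mean_event <- p * event_prob_experimental +
      (1 - p) * event_prob_control
    if (mean_event <= 0) {
      stop("Event probabilities imply no expected events.", call. = FALSE)
    }
    n_total <- ceiling(out$events_required / mean_event)
    out$n_total <- n_total
    out$n_experimental <- ceiling(p * n_total)
    out$n_control <- n_total - out$n_experimental
    out$event_prob_experimental <- event_prob_experimental
    out$event_prob_control <- event_prob_control
  }
  out
}
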