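test_that("Spearman coefficient matches the rank definition and base R", {
  res <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(res$r, 0.8)  # 1 - 6*4/(5*24), frozen from the rank formula
  expect_equal(res$r,
               unname(cor(1:5, c(2, 1, 4, 3, 5), method = "spearman")))
  expect_equal(spearman_cor(1:6, (1:6)^3)$r, 1)
  expect_equal(spearman_cor(1:6, -(1:6)^3)$r, -1)
  expect_error(spearman_cor(1:5, rep(2, 5)), "constant")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("the exact permutation p-value agrees with base R's exact
           Spearman test", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  y <- c(2, 1, 4, 3, 7, 5, 6)
  ours <- spearman_cor(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = TRUE))
  expect_equal(ours$method, "exact permutation")
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Spearman r is invariant under strictly monotone transforms", {
  set.seed(7)
  x <- rnorm(40)
  y <- x + rnorm(40)
  r0 <- spearman_cor(x, y, band = FALSE)$r
  expect_equal(spearman_cor(exp(x), y, band = FALSE)$r, r0)
  expect_equal(spearman_cor(x, y^3 + 5, band = FALSE)$r, r0)
})

test_that("the regression band brackets the fitted line", {
  set.seed(8)
  x <- 1:20
  y <- 2 * x + rnorm(20)
  res <- spearman_cor(x, y)
  expect_equal(res$slope, unname(coef(lm(y ~ x))[2]))
  expect_true(all(res$band$lwr <= res$band$fit))
  expect_true(all(res$band$upr >= res$band$fit))
})

test_that("Kruskal-Wallis + Dunn behave on identical, separated and
           two-group data", {
  same <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
               c = c(1, 2, 3, 4, 5))
  res <- kruskal_wallis_dunn(same)
  expect_lt(res$H, 1e-10)
  expect_false(any(res$dunn$p < 0.05))

  set.seed(9)
  sep <- list(a = rnorm(10), b = rnorm(10, 20), c = rnorm(10, 40))
  res2 <- kruskal_wallis_dunn(sep)
  expect_lt(res2$p_value, 1e-4)
  expect_true(all(res2$dunn$p < 0.05))

  # two groups: H equals the squared Mann-Whitney z statistic
  g1 <- c(1.2, 3.4, 2.2, 5.1, 4.4, 6.3)
  g2 <- c(7.7, 8.1, 2.9, 9.4, 10.2, 11.5)
  res3 <- kruskal_wallis_dunn(list(a = g1, b = g2))
  U <- sum(rank(c(g1, g2))[seq_along(g1)]) - length(g1) *
    (length(g1) + 1) / 2
  z <- (U - length(g1) * length(g2) / 2) /
    sqrt(length(g1) * length(g2) * (length(g1) + length(g2) + 1) / 12)
  expect_equal(res3$H, z^2, tolerance = 1e-10)

  expect_warning(kruskal_wallis_dunn(list(a = c(1, 1), b = c(1, 1))),
                 "tied")
  expect_error(kruskal_wallis_dunn(list(a = 1:5)), "2 groups")
})

test_that("Dunn p-value adjustment choice is recorded and applied", {
  set.seed(10)
  g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  raw <- kruskal_wallis_dunn(g, p_adjust = "none")
  bonf <- kruskal_wallis_dunn(g, p_adjust = "bonferroni")
  expect_equal(raw$dunn$adjustment[1], "none")
  expect_equal(bonf$dunn$p_adj, pmin(1, raw$dunn$p * 3))
})

test_that("Friedman analysis with baseline contrasts matches base R's
           omnibus statistic", {
  set.seed(11)
  y <- matrix(rnorm(40), nrow = 8) + rep(c(0, 0, 1, 2, 3), each = 8)
  dim(y) <- c(8, 5)
  colnames(y) <- paste0("h", c(0, 6, 12, 18, 24))
  res <- friedman_dunn(y)
  expect_equal(res$chisq, unname(friedman.test(y)$statistic))
  expect_equal(nrow(res$contrasts), 4)
  # strong late shifts separate from baseline
  expect_lt(res$contrasts$p[4], 0.01)
  expect_error(friedman_dunn(y[1, , drop = FALSE]), "blocks")
})

test_that("the Schoenfeld event count reproduces the study's design
           numbers and limiting behaviour", {
  des <- survival_sample_size(0.2, power = 0.9, alpha = 0.05,
                              allocation_fraction = 0.25)
  expect_equal(des$events_required, 22)
  expect_equal(des$events_raw,
               (qnorm(0.975) + qnorm(0.9))^2 /
                 (0.25 * 0.75 * log(0.2)^2))

  # HR -> 1 diverges
  expect_gt(survival_sample_size(0.999)$events_raw, 1e6)
  expect_error(survival_sample_size(1), "hazard_ratio")

  # symmetric allocation minimises the required events at fixed HR
  grid <- seq(0.1, 0.9, by = 0.05)
  events <- vapply(grid, function(p)
    survival_sample_size(0.2, allocation_fraction = p)$events_raw,
    numeric(1))
  expect_equal(grid[which.min(events)], 0.5)

  # event probabilities convert events to group sizes
  des2 <- survival_sample_size(0.2, allocation_fraction = 0.75,
                               event_prob_experimental = 0.2,
                               event_prob_control = 0.05)
  expect_true(des2$n_experimental + des2$n_control == des2$n_total)
})

test_that("Kruskal-Wallis H is invariant under monotone transforms", {
  set.seed(12)
  g <- rep(c("a", "b", "c"), each = 7)
  x <- rnorm(21) + as.integer(factor(g))
  h1 <- kruskal_wallis_dunn(x, g)$H
  h2 <- kruskal_wallis_dunn(exp(x), g)$H
  expect_equal(h1, h2)
})
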