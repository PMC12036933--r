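# explicit sums-of-squares oracle for the balanced two-group mixed design;
# computed entirely from cell means and marginal means
ss_oracle <- function(df) {
  wide <- tidyr::pivot_wider(df, names_from = "population", values_from = "value")
  vals <- as.matrix(wide[, c(3, 4)])
  g <- wide$group
  n_per <- table(g)
  grand <- mean(vals)
  subj_mean <- rowMeans(vals)
  grp_mean <- tapply(subj_mean, g, mean)
  pop_mean <- colMeans(vals)
  cell_mean <- rbind(colMeans(vals[g == names(n_per)[1], , drop = FALSE]),
                     colMeans(vals[g == names(n_per)[2], , drop = FALSE]))
  ss_group <- 2 * sum(as.vector(n_per) * (grp_mean - grand)^2)
  ss_subj <- 2 * sum((subj_mean - grp_mean[g])^2)
  ss_pop <- sum(nrow(vals) * (pop_mean - grand)^2)
  ss_cells <- sum(as.vector(n_per) * (cell_mean - grand)^2)
  ss_int <- ss_cells - ss_group - ss_pop
  ss_tot <- sum((vals - grand)^2)
  ss_err_w <- ss_tot - ss_group - ss_subj - ss_pop - ss_int
  df_group <- 1; df_subj <- nrow(vals) - 2; df_pop <- 1; df_int <- 1
  list(
    F_group = (ss_group / df_group) / (ss_subj / df_subj),
    F_pop = (ss_pop / df_pop) / (ss_err_w / df_subj),
    F_int = (ss_int / df_int) / (ss_err_w / df_subj)
  )
}

test_that("independent t-test is pooled Student with df = n1 + n2 - 2", {
  r0 <- t_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  r <- t_independent(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$df, 4)
  expect_equal(r$statistic, -3 / sqrt(1 * (1 / 3 + 1 / 3)), tolerance = 1e-12)
  expect_equal(r$statistic, -3.674, tolerance = 1e-3)
  expect_equal(r$direction, -1)

  set.seed(5)
  r2 <- t_independent(rnorm(6), rnorm(7))
  expect_equal(r2$df, 11)

  expect_error(t_independent(c(1, 1), c(2, 2)), "degenerate-variance")
})

test_that("paired t-test uses the difference vector with df = n - 1", {
  x <- c(3, 4, 5, 6)
  expect_equal(t_paired(x, x)$statistic, 0)

  set.seed(6)
  y <- x + 2 + rnorm(4, sd = 0.5)
  r <- t_paired(y, x)
  d <- y - x
  expect_equal(r$statistic, mean(d) / (sd(d) / sqrt(4)), tolerance = 1e-12)
  expect_equal(r$df, 3)

  set.seed(7)
  expect_equal(t_paired(rnorm(7), rnorm(7))$df, 6)
  expect_error(t_paired(c(1, 2), c(0, 1)), "degenerate-variance")
})

test_that("mixed ANOVA matches the explicit sums-of-squares oracle", {
  # balanced toy dataset, both factors active
  set.seed(31)
  n <- 8
  df <- expand.grid(bird_id = sprintf("b%d", 1:n),
                    population = c("P1", "P2"), stringsAsFactors = FALSE)
  df$group <- rep(rep(c("g1", "g2"), each = n / 2), 2)
  df$value <- 10 + (df$group == "g2") * 1.5 + (df$population == "P2") * 3 +
    (df$group == "g2") * (df$population == "P2") * 0.8 +
    rnorm(nrow(df), sd = 1) + rep(rnorm(n, sd = 0.7), 2)

  got <- mixed_anova_2x2(df)
  want <- ss_oracle(df)
  expect_equal(got$F[got$effect == "group"], want$F_group, tolerance = 1e-9)
  expect_equal(got$F[got$effect == "population"], want$F_pop, tolerance = 1e-9)
  expect_equal(got$F[got$effect == "group:population"], want$F_int,
               tolerance = 1e-9)
  expect_equal(got$df2[got$effect == "group"], n - 2)
})

test_that("mixed ANOVA degenerate and constructed cases behave", {
  df0 <- expand.grid(bird_id = sprintf("b%d", 1:6),
                     population = c("P1", "P2"), stringsAsFactors = FALSE)
  df0$group <- rep(rep(c("g1", "g2"), each = 3), 2)
  df0$value <- 5
  got0 <- mixed_anova_2x2(df0)
  expect_equal(got0$F, c(0, 0, 0))

  # pure within-population shift, no group effect
  set.seed(32)
  df1 <- df0
  df1$value <- 10 + (df1$population == "P2") * 4 + rnorm(nrow(df1), sd = 0.3)
  got1 <- mixed_anova_2x2(df1)
  expect_gt(got1$p_value[got1$effect == "group"], 0.01)
  expect_gt(got1$F[got1$effect == "population"], 50)

  # missing within-level value is an error, not imputed
  expect_error(mixed_anova_2x2(df0[-1, ]), "every bird")
})

test_that("BH step-up matches hand-computed adjustments", {
  r1 <- bh_fdr(0.03)
  expect_equal(r1$p_adjusted, 0.03)

  r4 <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r4$p_adjusted, c(0.04, 0.04, 0.04, 0.04))
  expect_true(all(r4$reject))

  r2 <- bh_fdr(c(0.001, 0.9))
  expect_equal(r2$p_adjusted, c(0.002, 0.9))

  expect_equal(nrow(bh_fdr(numeric(0))), 0)

  # monotone in rank; rejections form a prefix of the sorted list
  set.seed(8)
  p <- runif(20)^2
  r <- bh_fdr(p)
  o <- order(p)
  expect_true(all(diff(r$p_adjusted[o]) >= -1e-12))
  rej_sorted <- r$reject[o]
  expect_true(all(diff(rej_sorted) <= 0))
})

test_that("OLS regression recovers exact fits and matches the r-to-t identity", {
  x <- 1:10
  r <- ols_regress(x, 2 * x + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)

  set.seed(9)
  x2 <- rnorm(13); y2 <- rnorm(13)
  r2 <- ols_regress(x2, y2)
  rho <- cor(x2, y2)
  t_from_r <- rho * sqrt(11 / (1 - rho^2))
  expect_equal(2 * pt(-abs(t_from_r), df = 11), r2$p_value, tolerance = 1e-12)

  expect_error(ols_regress(c(1, 2), c(1, 2)), "at least 3")
  expect_error(ols_regress(rep(1, 5), rnorm(5)), "degenerate predictor")
})

test_that("tests are invariant to bird order within groups", {
  set.seed(10)
  x <- rnorm(6); y <- rnorm(7)
  r1 <- t_independent(x, y)
  r2 <- t_independent(sample(x), sample(y))
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})
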