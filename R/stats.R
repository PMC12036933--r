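#' Group-comparison statistics
#'
#' The statistical battery applied to per-bird summaries: two-tailed
#' independent t-tests (pooled variance, so 6 vs 7 birds gives df = 11),
#' post-hoc paired t-tests, a 2 (treatment group) x 2 (neuron population)
#' mixed ANOVA with the population factor repeated within bird,
#' Benjamini-Hochberg FDR correction over each family of morphology
#' comparisons, and ordinary least-squares regressions of experimental
#' covariates on outcomes. The analysis unit is always the bird: cell-level
#' measurements are averaged per bird before any test.
#'
#' @name group_stats
NULL

test_result <- function(statistic, df, p_value, direction) {
  tibble::tibble(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), direction = direction)
}

#' Two-tailed independent t-test (pooled variance)
#'
#' Student's t-test with pooled variance and df = n1 + n2 - 2. `direction` is
#' the sign of mean(x) - mean(y); by convention x is the statin group, so a
#' negative direction means the measure is lower in treated birds.
#'
#' @param x,y numeric per-bird values for the two groups (each length >= 2).
#' @return one-row tibble: `statistic`, `df`, `p_value`, `direction`.
#' @export
t_independent <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) != mean(y)) stop("degenerate-variance condition: zero variance with unequal means")
    return(test_result(0, length(x) + length(y) - 2L, 1, 0))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  test_result(tt$statistic, tt$parameter, tt$p.value, sign(mean(x) - mean(y)))
}

#' Two-tailed paired t-test
#'
#' t-test on within-bird differences, df = n - 1.
#'
#' @param x,y matched per-bird values (equal length >= 2).
#' @return one-row tibble: `statistic`, `df`, `p_value`, `direction`.
#' @export
t_paired <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) != 0) stop("degenerate-variance condition: constant nonzero paired differences")
    return(test_result(0, length(d) - 1L, 1, 0))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  test_result(tt$statistic, tt$parameter, tt$p.value, sign(mean(d)))
}

#' Two-group, two-population mixed ANOVA
#'
#' Sums-of-squares decomposition for a design with one between-subjects factor
#' (treatment group) and one within-subjects factor (neuron population,
#' measured twice in the same birds). The group effect is tested against the
#' between-bird error stratum; the population effect and the group x
#' population interaction against the bird x population stratum.
#'
#' @param data data frame with columns `bird_id`, `group` (2 levels),
#'   `population` (2 levels), `value`; every bird must contribute both
#'   population levels (no imputation).
#' @return tibble with one row per effect (`group`, `population`,
#'   `group:population`): `df1`, `df2`, `F`, `p_value`.
#' @export
mixed_anova_2x2 <- function(data) {
  data <- as.data.frame(data)
  stopifnot(all(c("bird_id", "group", "population", "value") %in% names(data)))
  data$bird_id <- factor(data$bird_id)
  data$group <- factor(data$group)
  data$population <- factor(data$population)
  if (nlevels(data$group) != 2 || nlevels(data$population) != 2) {
    stop("both factors must have exactly two levels")
  }
  tab <- table(data$bird_id, data$population)
  if (any(tab != 1)) stop("every bird must contribute exactly one value per population level")

  fit <- stats::aov(value ~ group * population + Error(bird_id / population),
                    data = data)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: bird_id"]][[1L]])
  within <- as.data.frame(sm[["Error: bird_id:population"]][[1L]])
  pick <- function(strat, term) {
    i <- match(term, trimws(rownames(strat)))
    err <- grep("Residuals", rownames(strat))
    ss <- strat[i, "Sum Sq"]; df1 <- strat[i, "Df"]
    ss_e <- strat[err, "Sum Sq"]; df2 <- strat[err, "Df"]
    if (ss < 1e-12 * max(1, ss_e)) {          # no effect variance: F defined as 0
      return(c(df1 = df1, df2 = df2, F = 0, p_value = 1))
    }
    Fv <- (ss / df1) / (ss_e / df2)
    c(df1 = df1, df2 = df2, F = Fv, p_value = stats::pf(Fv, df1, df2, lower.tail = FALSE))
  }
  res <- rbind(group = pick(between, "group"),
               population = pick(within, "population"),
               `group:population` = pick(within, "group:population"))
  tibble::tibble(effect = rownames(res), tibble::as_tibble(res))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values (`stats::p.adjust(method = "BH")`) and rejection
#' flags at the given FDR level.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return tibble with `p_raw`, `p_adjusted`, `reject`, in input order.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) {
    return(tibble::tibble(p_raw = double(), p_adjusted = double(), reject = logical()))
  }
  stopifnot(all(p_values >= 0 & p_values <= 1))
  adj <- stats::p.adjust(p_values, method = "BH")
  tibble::tibble(p_raw = p_values, p_adjusted = adj, reject = adj <= alpha)
}

#' Ordinary least-squares regression of an outcome on one covariate
#'
#' Fits `y ~ x` per bird and reports the slope, intercept, r^2 and the
#' two-tailed t-test p-value on the slope.
#'
#' @param x covariate per bird (not constant; >= 3 points).
#' @param y outcome per bird.
#' @return one-row tibble: `slope`, `intercept`, `r_squared`, `p_value`.
#' @export
ols_regress <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 points for regression")
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0) stop("degenerate predictor: covariate is constant")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  co <- sm$coefficients
  p <- if (nrow(co) < 2 || sm$sigma == 0) {
    if (sm$sigma == 0) 0 else NA_real_   # exact fit: slope determined without error
  } else co["x", "Pr(>|t|)"]
  tibble::tibble(slope = co["x", "Estimate"],
                 intercept = co["(Intercept)", "Estimate"],
                 r_squared = sm$r.squared, p_value = p)
}
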