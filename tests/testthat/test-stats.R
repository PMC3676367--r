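test_that("balanced two-way ANOVA degrees of freedom follow the trial dimensions", {
  set.seed(1)
  df <- expand.grid(genotype = sprintf("G%03d", 1:192), day = 1:3, rep = 1:2)
  df$value <- rnorm(nrow(df))
  tab <- anova_twoway(df)
  expect_equal(tab$df, c(191L, 2L, 382L, 576L))
  # SS decomposition conserves total SS; df sum to N - 1
  total <- sum((df$value - mean(df$value))^2)
  expect_equal(sum(tab$ss), total, tolerance = 1e-9)
  expect_equal(sum(tab$df), nrow(df) - 1L)
})

test_that("constant data give zero sums of squares everywhere", {
  df <- expand.grid(genotype = c("A", "B"), day = 1:2, rep = 1:2)
  df$value <- 7
  expect_equal(anova_twoway(df)$ss, rep(0, 4))
})

test_that("two-way sums of squares match the brute-force summation oracle", {
  set.seed(42)
  df <- expand.grid(genotype = c("A", "B"), day = c("d1", "d2"), rep = 1:2)
  df$value <- c(3.1, 5.2, 4.4, 4.8, 2.9, 6.1, 5.0, 4.2)
  tab <- anova_twoway(df)
  oracle <- oracle_twoway_ss(df)
  expect_equal(tab$ss, unname(oracle), tolerance = 1e-9)
  # F p-values against an independent beta-CDF route
  expect_equal(tab$p[1:3],
               oracle_f_p(tab$f[1:3], tab$df[1:3], tab$df[4]),
               tolerance = 1e-6)
})

test_that("unbalanced tables fall back to sequential SS with a note", {
  set.seed(3)
  df <- expand.grid(genotype = c("A", "B", "C"), day = 1:2, rep = 1:2)
  df$value <- rnorm(nrow(df))
  df <- df[-1, ]   # drop one plot
  expect_message(tab <- anova_twoway(df), "sequential")
  expect_equal(sum(tab$df), nrow(df) - 1L)
  # sequential SS still conserve the total
  expect_equal(sum(tab$ss), sum((df$value - mean(df$value))^2),
               tolerance = 1e-9)
})

test_that("single-replicate cells leave no error term and are rejected", {
  df <- expand.grid(genotype = c("A", "B"), day = 1:2)
  df$value <- rnorm(4)
  expect_error(anova_twoway(df), "error term")
})

test_that("ANOVA on daily genotype means has days-as-replicates df", {
  set.seed(4)
  m <- matrix(rnorm(192 * 3), 192, 3)
  res <- anova_on_means(m)
  expect_equal(res$table$df, c(191L, 384L))
  expect_error(anova_on_means(m[, 1, drop = FALSE]), "2 days")
})

test_that("zero within-genotype spread means genotypes explain all variation", {
  m <- matrix(rep(1:5, 3), 5, 3)
  expect_equal(anova_on_means(m)$variance_explained, 100)
})

test_that("random labels give between-genotype MS close to within-genotype MS", {
  set.seed(5)
  ratios <- replicate(50, {
    m <- matrix(rnorm(96 * 3), 96, 3)
    tab <- anova_on_means(m)$table
    tab$ms[1] / tab$ms[2]
  })
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("the LSD follows the t-based formula", {
  # large df: normal limit
  expect_equal(lsd(2, 10^6, 2, 0.05), qnorm(0.975) * sqrt(2), tolerance = 1e-3)
  expect_error(lsd(2, 100, 2, 1.0), "alpha")
  expect_error(lsd(-1, 100, 2, 0.05), "ms_error")
  # t quantile cross-checked by root finding on the t CDF
  got <- lsd(0.0836, 572, 6, 0.05)
  t_oracle <- uniroot(function(q) pt(q, 572) - 0.975, c(1, 3), tol = 1e-10)$root
  expect_equal(got, t_oracle * sqrt(2 * 0.0836 / 6), tolerance = 1e-6)
})

test_that("the randomisation test is deterministic and its p-value bounded", {
  set.seed(6)
  m <- matrix(rnorm(48 * 3), 48, 3, dimnames = list(sprintf("G%02d", 1:48), NULL))
  a <- monte_carlo_randomization(m, n_reps = 99, seed = 11)
  b <- monte_carlo_randomization(m, n_reps = 99, seed = 11)
  expect_identical(a[c("p_value", "null_f", "null_range")],
                   b[c("p_value", "null_f", "null_range")])
  expect_gte(a$p_value, 1 / 100)
  expect_lte(a$p_value, 1)
  expect_error(monte_carlo_randomization(m, n_reps = 0, seed = 1), "n_reps")
})

test_that("strong genotype effects are detected against the randomisation null", {
  set.seed(7)
  eff <- rnorm(96, 0, 0.4)
  m <- matrix(eff + rnorm(96 * 3, 0, 0.15), 96, 3,
              dimnames = list(sprintf("G%02d", 1:96), NULL))
  res <- monte_carlo_randomization(m, n_reps = 199, seed = 12)
  expect_equal(res$p_value, 1 / 200)     # observed F beats every null F
  expect_gt(res$observed_range, res$apparent_lsd)
})

test_that("randomisation p-values are uniform on null data", {
  pvals <- vapply(1:200, function(i) {
    set.seed(6000 + i)
    m <- matrix(rnorm(48 * 3), 48, 3,
                dimnames = list(sprintf("G%02d", 1:48), NULL))
    monte_carlo_randomization(m, n_reps = 199, seed = 7000 + i)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  rej <- mean(pvals <= 0.05)
  expect_lt(abs(rej - 0.05), 2 * sqrt(0.05 * 0.95 / 200) + 1e-12)
})

test_that("Spearman's rho handles monotone, reversed and tied data", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, -(1:10)), -1)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:4, 1:5), "equal length")
  set.seed(8)
  for (i in 1:20) {
    x <- sample(1:5, 12, replace = TRUE)   # heavy ties
    y <- sample(1:5, 12, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y), tolerance = 1e-9)
    # and against the standard implementation
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-9)
  }
})

test_that("extreme-subset selection reduces to the full set at k = n/2", {
  set.seed(9)
  m <- matrix(rnorm(20 * 2), 20, 2,
              dimnames = list(sprintf("G%02d", 1:20), c("o1", "o2")))
  full <- spearman_rho(m[, 1], m[, 2])
  res <- extreme_subset_rho(m, k = 10)
  expect_equal(sort(res$genotypes), sort(rownames(m)))
  expect_equal(res$rho["o1", "o2"], full)
  # identical occasions are perfectly rank-consistent
  m2 <- cbind(o1 = m[, 1], o2 = m[, 1])
  expect_equal(extreme_subset_rho(m2, k = 5)$rho["o1", "o2"], 1)
  expect_error(extreme_subset_rho(m, k = 0), "k")
  expect_error(extreme_subset_rho(m, k = 11), "exceeds")
})

test_that("extreme subsets are at least as rank-consistent as the full set", {
  set.seed(10)
  gain <- replicate(30, {
    eff <- rnorm(60, 0, 1)
    m <- cbind(o1 = eff + rnorm(60, 0, 0.8), o2 = eff + rnorm(60, 0, 0.8))
    rownames(m) <- sprintf("G%02d", 1:60)
    extreme_subset_rho(m, k = 10)$rho["o1", "o2"] - spearman_rho(m[, 1], m[, 2])
  })
  expect_gt(mean(gain), 0)
})

test_that("occasion correlation matrices are symmetric with unit diagonal", {
  set.seed(11)
  m <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  cm <- correlation_matrix(m)
  expect_equal(diag(cm), c(a = 1, b = 1, c = 1))
  expect_equal(cm, t(cm))
  # duplicated occasion correlates perfectly
  cm2 <- correlation_matrix(cbind(m, a2 = m[, "a"]))
  expect_equal(cm2["a", "a2"], 1)
  # independent occasions decorrelate as n grows
  big <- matrix(rnorm(2000 * 2), 2000, 2, dimnames = list(NULL, c("x", "y")))
  expect_lt(abs(correlation_matrix(big)["x", "y"]), 0.08)
})

test_that("day means correlate better across days than single occasions do", {
  set.seed(12)
  eff <- rnorm(96, 0, 0.4)
  occ <- sapply(1:8, function(i) eff + rnorm(96, 0, 0.3))
  colnames(occ) <- paste0("t", rep(1:4, 2), "_d", rep(1:2, each = 4))
  days <- rep(c("day1", "day2"), each = 4)
  cm <- correlation_matrix(occ, days = days)
  cross <- cm[paste0("t", 1:4, "_d1"), paste0("t", 1:4, "_d2")]
  expect_gte(cm["day1_Mean", "day2_Mean"], stats::median(cross))
})

test_that("stepwise selection finds an exact predictor and stops", {
  set.seed(13)
  X <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  res <- forward_stepwise(X$b * 2 + 1, X)
  expect_equal(res$steps$term, "b")
  expect_equal(res$steps$r2_cum, 1, tolerance = 1e-9)
})

test_that("orthogonal predictors contribute additive r-squared", {
  n <- 32
  X <- data.frame(a = rep(c(-1, 1), each = n / 2),
                  b = rep(c(-1, 1), times = n / 2))
  set.seed(14)
  y <- 0.8 * X$a + 0.5 * X$b + rnorm(n, 0, 0.4)
  r2a <- summary(lm(y ~ a, X))$r.squared
  r2b <- summary(lm(y ~ b, X))$r.squared
  res <- forward_stepwise(y, X)
  expect_equal(max(res$steps$r2_cum), r2a + r2b, tolerance = 1e-9)
})

test_that("the selection path matches the exhaustive enumeration oracle", {
  set.seed(15)
  for (i in 1:10) {
    X <- data.frame(t = rnorm(12), m = rnorm(12), h = rnorm(12))
    y <- 1.5 * X$t + 0.8 * X$m + rnorm(12, 0, 0.6)
    res <- forward_stepwise(y, X)
    expect_identical(res$steps$term, oracle_forward_path(y, X))
  }
  # a 5-point hand-built case
  X5 <- data.frame(t = c(1, 2, 3, 4, 5), m = c(2, 1, 2, 1, 2),
                   h = c(5, 3, 4, 1, 2))
  y5 <- c(2.0, 3.9, 6.1, 8.0, 9.9)
  res5 <- forward_stepwise(y5, X5)
  expect_identical(res5$steps$term, oracle_forward_path(y5, X5))
})

test_that("cumulative r-squared is monotone and bounded by the full model", {
  set.seed(16)
  for (i in 1:10) {
    X <- data.frame(a = rnorm(25), b = rnorm(25), c = rnorm(25), d = rnorm(25))
    y <- as.matrix(X) %*% runif(4, -1, 1) + rnorm(25)
    res <- forward_stepwise(y[, 1], X, alpha_enter = 0.5)
    if (nrow(res$steps) > 1) {
      expect_true(all(diff(res$steps$r2_cum) >= -1e-12))
    }
    if (nrow(res$steps) > 0) {
      expect_lte(max(res$steps$r2_cum), res$full_model_r2 + 1e-12)
    }
  }
})

test_that("collinear candidates are skipped with a warning", {
  set.seed(17)
  X <- data.frame(a = rnorm(20))
  X$b <- 2 * X$a          # exact copy, rank-deficient together
  X$c <- rnorm(20)
  y <- X$a + 0.5 * X$c + rnorm(20, 0, 0.1)
  expect_warning(res <- forward_stepwise(y, X), "collinear")
  expect_false("b" %in% res$steps$term && "a" %in% res$steps$term)
})
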