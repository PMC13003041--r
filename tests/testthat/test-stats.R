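test_that("Mann-Whitney U matches pair counting and printed statistics", {
  r <- mann_whitney(c(3, 3, 3, 2, 2), c(2, 2, 2, 1, 1))
  expect_equal(r$statistic, 22)
  expect_equal(round(r$p_value, 3), 0.041)

  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$statistic, 4.5)

  set.seed(51)
  for (i in 1:20) {
    x <- sample(1:6, 5, replace = TRUE)   # ties likely
    y <- sample(1:6, 5, replace = TRUE)
    expect_equal(mann_whitney(x, y)$statistic, oracle_U(x, y))
    # U_x + U_y = n_x n_y under midranks
    expect_equal(mann_whitney(x, y)$statistic +
                   mann_whitney(y, x)$statistic, 25)
  }

  # invariance under strictly monotone transforms of the pooled data
  x <- c(0.3, 1.2, 2.2, 5); y <- c(0.1, 1.7, 2.9)
  expect_equal(mann_whitney(exp(x), exp(y))$statistic,
               mann_whitney(x, y)$statistic)
  expect_equal(mann_whitney(exp(x), exp(y))$p_value,
               mann_whitney(x, y)$p_value)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney type-I error is calibrated under the null", {
  set.seed(52)
  reps <- 5000
  rej <- mean(replicate(reps, {
    mann_whitney(rnorm(10), rnorm(10))$p_value < 0.05
  }))
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("Shapiro-Wilk W reproduces known values", {
  pooled <- c(3, 3, 3, 2, 2, 2, 2, 2, 1, 1)
  r <- shapiro_wilk(pooled)
  expect_equal(round(r$statistic, 3), 0.833)
  # permutation-invariant, in (0, 1]
  r2 <- shapiro_wilk(rev(pooled))
  expect_equal(r2$statistic, r$statistic)
  expect_true(r$statistic > 0 && r$statistic <= 1)

  q <- qnorm((1:10 - 0.5) / 10)    # near-perfect normal sample
  expect_gt(shapiro_wilk(q)$statistic, 0.98)
  expect_lt(shapiro_wilk(c(1, 1, 1, 1, 5))$statistic, 0.8)
  expect_error(shapiro_wilk(c(2, 2, 2)), "zero-variance")
  expect_error(shapiro_wilk(1:60), "between 3 and 50")
})

test_that("two-way ANOVA matches the balanced closed-form decomposition", {
  set.seed(53)
  d <- expand.grid(rep_i = 1:5, group = c("a53t", "empty"),
                   sex = c("M", "F"))
  d$y <- rnorm(nrow(d), mean = 10 + 2 * (d$group == "a53t") +
                 1 * (d$sex == "M"))
  got <- two_way_anova(d, "y")
  ref <- oracle_balanced_anova(d$y, d$group, d$sex)
  expect_equal(got$group$statistic, ref$F_a, tolerance = 1e-10)
  expect_equal(got$sex$statistic, ref$F_b, tolerance = 1e-10)
  expect_equal(got$`group:sex`$statistic, ref$F_ab, tolerance = 1e-10)
  # balanced decomposition is exhaustive
  expect_equal(sum(ref$ss[c("a", "b", "ab", "res")]), ref$ss["tot"],
               ignore_attr = TRUE)
  # F is invariant under affine transforms of the response
  d$y2 <- 3 * d$y - 100
  got2 <- two_way_anova(d, "y2")
  expect_equal(got2$group$statistic, got$group$statistic, tolerance = 1e-10)
})

test_that("Type II F values agree with an established implementation", {
  set.seed(56)
  d <- expand.grid(rep_i = 1:6, group = c("a53t", "empty"),
                   sex = c("M", "F"))
  d$y <- rnorm(nrow(d), 5 + (d$group == "a53t") + 0.5 * (d$sex == "M"))
  d <- d[-c(1, 2, 8), ]   # unbalance the design so the SS types differ
  got <- two_way_anova(d, "y")
  ref <- car::Anova(lm(y ~ group * sex, d), type = 2)
  expect_equal(got$group$statistic, ref["group", "F value"],
               tolerance = 1e-10)
  expect_equal(got$sex$statistic, ref["sex", "F value"], tolerance = 1e-10)
  expect_equal(got$`group:sex`$statistic, ref["group:sex", "F value"],
               tolerance = 1e-10)

  d$w <- rnorm(nrow(d), 20, 2)
  ga <- ancova(d, "y", "group", "w")
  ra <- car::Anova(lm(y ~ group + w, d), type = 2)
  expect_equal(ga$statistic, ra["group", "F value"], tolerance = 1e-10)
  expect_equal(ga$p_value, ra["group", "Pr(>F)"], tolerance = 1e-10)
})

test_that("ANOVA handles exact null terms and degenerate inputs", {
  # additive cell means with symmetric residuals: interaction SS exactly 0
  d <- expand.grid(rep_i = 1:2, group = c("g1", "g2"), sex = c("M", "F"))
  d$y <- 10 + 2 * (d$group == "g2") + ifelse(d$rep_i == 1, 1, -1)
  got <- two_way_anova(d, "y")
  expect_equal(got$`group:sex`$ss, 0, tolerance = 1e-12)
  expect_equal(got$sex$ss, 0, tolerance = 1e-12)

  d$y <- 7
  got0 <- two_way_anova(d, "y")
  expect_equal(got0$group$ss, 0, tolerance = 1e-12)
  expect_equal(got0$sex$ss, 0, tolerance = 1e-12)

  d2 <- d[d$group == "g1" | d$sex == "M", ]
  expect_error(two_way_anova(d2, "y"), "empty design cell")

  d$y <- abs(rnorm(nrow(d))) + 1
  logged <- two_way_anova(d, "y", transform = "log")
  expect_true(any(grepl("log", logged$group$notes)))
})

test_that("ANCOVA adjusts the group effect for the covariate", {
  # response exactly equal to the covariate: adjusted group SS is 0
  set.seed(54)
  d <- data.frame(group = rep(c("a", "b"), each = 4),
                  w = rnorm(8, 20, 2))
  d$y <- d$w
  expect_equal(ancova(d, "y", "group", "w")$ss, 0, tolerance = 1e-12)

  # textbook small case against an explicit least-squares oracle
  d$y <- c(5, 6, 7, 8, 9, 10, 11, 12) + 0.5 * d$w
  got <- ancova(d, "y", "group", "w")
  X_full <- cbind(1, d$group == "b", d$w)
  X_red <- cbind(1, d$w)
  rss <- function(X, y) {
    b <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% b)^2)
  }
  ss_group <- rss(X_red, d$y) - rss(X_full, d$y)
  F_ref <- ss_group / (rss(X_full, d$y) / (nrow(d) - 3))
  expect_equal(got$statistic, F_ref, tolerance = 1e-10)
  expect_equal(got$df, c(1, 5))

  # a covariate uncorrelated with the group barely changes the group F
  set.seed(55)
  big <- data.frame(group = rep(c("a", "b"), each = 400))
  big$w <- rnorm(800)
  big$y <- rnorm(800, mean = 2 * (big$group == "b"))
  f_ancova <- ancova(big, "y", "group", "w")$statistic
  f_anova <- summary(aov(y ~ group, big))[[1]]$`F value`[1]
  expect_lt(abs(f_ancova - f_anova) / f_anova, 0.05)

  d$wc <- rep(5, 8)
  expect_error(ancova(d, "y", "group", "wc"), "non-constant")
})

test_that("power calculation reproduces the design's group size", {
  p <- power_sample_size(1.5, 0.05, 0.80)
  expect_equal(round(p$n_approx, 2), 7.94)
  expect_equal(p$n, 8)

  expect_equal(power_sample_size(100)$n, 1)  # large-effect floor

  p1 <- power_sample_size(1.0)
  expect_equal(round(p1$n_approx, 1), 16.7)
  # the exact noncentral-t solution achieves the target power
  n <- ceiling(p1$n_exact)
  df <- 2 * n - 2
  pw <- 1 - pt(qt(0.975, df), df, ncp = 1 * sqrt(n / 2)) +
    pt(qt(0.025, df), df, ncp = 1 * sqrt(n / 2))
  expect_gte(pw, 0.80)
  expect_error(power_sample_size(-1))
})
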