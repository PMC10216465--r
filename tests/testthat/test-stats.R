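test_that("paired t matches the hand difference-based formula", {
  x <- c(0.31, 0.28, 0.40, 0.35, 0.22, 0.30)
  y <- c(0.25, 0.30, 0.33, 0.30, 0.20, 0.24)
  out <- paired_t(x, y, labels = c("weighted", "binary"))
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(out$statistic, t_hand, tolerance = 1e-12)
  expect_equal(out$df1, 5)
  expect_equal(out$p, 2 * pt(-abs(t_hand), 5), tolerance = 1e-12)
  expect_match(out$effect, "weighted vs binary")
})

test_that("zero-variance differences are a hard error", {
  x <- c(1, 2, 3)
  expect_error(paired_t(x, x), "zero variance")
  expect_error(paired_t(x, x + 2), "zero variance")
})

test_that("one-way repeated ANOVA: no level effect gives F = 0", {
  m <- matrix(rnorm(6), 6, 1)[, c(1, 1, 1)] # identical columns per case
  out <- rm_anova_1way(m)
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1)
})

test_that("with two levels sphericity is trivial and epsilon is 1", {
  set.seed(21)
  m <- matrix(rnorm(16), 8, 2)
  out <- rm_anova_1way(m)
  expect_equal(out$epsilon, 1)
  expect_equal(out$df1, 1)
  expect_equal(out$df2, 7)
})

test_that("F and epsilon match the car multivariate oracle", {
  skip_if_not_installed("car")
  set.seed(22)
  m <- matrix(rnorm(24, mean = rep(c(0, 0.5, 1), each = 8)), 8, 3)
  out <- rm_anova_1way(m)
  idata <- data.frame(cond = factor(paste0("c", 1:3)))
  fit <- lm(m ~ 1)
  av <- suppressWarnings(summary(
    car::Anova(fit, idata = idata, idesign = ~cond, type = 3),
    multivariate = FALSE
  ))
  f_car <- av$univariate.tests["cond", "F value"]
  eps_car <- av$pval.adjustments["cond", "GG eps"]
  p_car <- av$pval.adjustments["cond", "Pr(>F[GG])"]
  expect_equal(out$statistic, unname(f_car), tolerance = 1e-8)
  expect_equal(out$epsilon, unname(eps_car), tolerance = 1e-8)
  expect_equal(out$p, unname(p_car), tolerance = 1e-8)
})

test_that("two-way repeated ANOVA matches car for every effect", {
  skip_if_not_installed("car")
  set.seed(23)
  n <- 7
  a <- 3
  b <- 4
  arr <- array(rnorm(n * a * b), c(n, a, b)) +
    rep(seq(0, 1, length.out = a), each = n) # factor A effect
  out <- rm_anova_2way(arr, effects = c("interval", "method"))
  wide <- matrix(arr, n, a * b) # column order: A fastest, then B
  idata <- expand.grid(interval = factor(paste0("i", 1:a)), method = factor(paste0("m", 1:b)))
  fit <- lm(wide ~ 1)
  av <- suppressWarnings(summary(
    car::Anova(fit, idata = idata, idesign = ~ interval * method, type = 3),
    multivariate = FALSE
  ))
  f_car <- av$univariate.tests[, "F value"]
  eps_car <- av$pval.adjustments[, "GG eps"]
  expect_equal(out$statistic[1], unname(f_car["interval"]), tolerance = 1e-8)
  expect_equal(out$statistic[2], unname(f_car["method"]), tolerance = 1e-8)
  expect_equal(out$statistic[3], unname(f_car["interval:method"]), tolerance = 1e-8)
  expect_equal(out$epsilon[1], unname(eps_car["interval"]), tolerance = 1e-8)
  expect_equal(out$epsilon[2], unname(eps_car["method"]), tolerance = 1e-8)
  expect_equal(out$epsilon[3], unname(eps_car["interval:method"]), tolerance = 1e-8)
})

test_that("two-way ANOVA has the expected uncorrected interaction structure", {
  set.seed(24)
  arr <- array(rnorm(7 * 3 * 4), c(7, 3, 4))
  out <- rm_anova_2way(arr)
  # corrected dfs are epsilon times (6, 36)
  expect_equal(out$df1[3] / out$epsilon[3], 6, tolerance = 1e-12)
  expect_equal(out$df2[3] / out$epsilon[3], 36, tolerance = 1e-12)
  const_a <- array(rep(rnorm(7 * 4), each = 1), c(7, 3, 4))
  for (i in 1:3) const_a[, i, ] <- const_a[, 1, ] # constant in factor A
  out2 <- rm_anova_2way(const_a)
  expect_equal(out2$statistic[1], 0)
})

test_that("under an additive model interaction p-values are well calibrated", {
  set.seed(25)
  ps <- replicate(200, {
    arr <- array(rnorm(8 * 3 * 3, sd = 0.3), c(8, 3, 3)) +
      rep(rnorm(8), times = 9) # case effects, no interaction
    rm_anova_2way(arr)$p[3]
  })
  expect_lt(mean(ps < 0.05), 0.09) # GG correction is mildly conservative
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.65)
})

test_that("Bonferroni adjustment caps and preserves order", {
  expect_equal(posthoc_bonferroni(0.01, 3), 0.03)
  expect_equal(posthoc_bonferroni(0.5, 3), 1)
  set.seed(26)
  p <- runif(10)
  adj <- posthoc_bonferroni(p, 10)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_equal(adj, pmin(1, p * 10))
})

test_that("nodal method ANOVA has between-groups structure and matches an SS oracle", {
  set.seed(27)
  sizes <- c(rep(90, 4), rep(264, 4))
  methods <- paste0("m", 1:8)
  df <- purrr::map2_dfr(methods, sizes, function(m, s) {
    tibble::tibble(method = m, icc = rnorm(s, mean = match(m, methods) / 10))
  })
  out <- nodal_method_anova(df)
  expect_equal(out$df1, 7)
  expect_equal(out$df2, 1408)
  grand <- mean(df$icc)
  ss_b <- sum(tapply(df$icc, df$method, function(x) length(x) * (mean(x) - grand)^2))
  ss_w <- sum((df$icc - ave(df$icc, df$method))^2)
  f_oracle <- (ss_b / 7) / (ss_w / 1408)
  expect_equal(out$statistic, f_oracle, tolerance = 1e-10)
  expect_error(nodal_method_anova(tibble::tibble(method = c("a", "b"), icc = c(1, 1))), "identical")
})
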