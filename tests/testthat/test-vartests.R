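test_that("Levene's F matches an independently coded ANOVA on deviations", {
  g1 <- c(1, 2, 3, 4); g2 <- c(2, 4, 6, 8)
  res <- levene_f(list(a = g1, b = g2))

  # independent oracle: explicit sums of squares on |x - group mean|
  dev <- c(abs(g1 - mean(g1)), abs(g2 - mean(g2)))
  grp <- rep(c("a", "b"), each = 4)
  gm <- tapply(dev, grp, mean)
  ssb <- sum(4 * (gm - mean(dev))^2)
  ssw <- sum((dev - gm[grp])^2)
  f_oracle <- (ssb / 1) / (ssw / 6)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(res$p_value, pf(f_oracle, 1, 6, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_false(res$degenerate)

  # cross-check against R's own linear-model ANOVA
  fit <- anova(lm(dev ~ grp))
  expect_equal(res$statistic, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p_value, fit$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("Levene handles degenerate and null configurations explicitly", {
  # groups (1,3) and (0,4): all within-group deviations constant -> F
  # degenerate, reported as p -> 0 with the flag set
  res <- levene_f(list(a = c(1, 3), b = c(0, 4)))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 0)
  expect_equal(res$statistic, Inf)

  # two identical groups -> F = 0, p = 1
  res2 <- levene_f(list(a = c(1, 5, 2), b = c(1, 5, 2)))
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)

  expect_error(levene_f(list(a = 1:3)), ">= 2 groups")
  expect_error(levene_f(list(a = 1:3, b = 2)), ">= 2 values")
})

test_that("Levene invariances and the two-group t-statistic identity hold", {
  set.seed(20)
  a <- rnorm(12, 5, 1); b <- rnorm(15, 5, 3)
  base <- levene_f(list(a = a, b = b))
  shifted <- levene_f(list(a = a + 7, b = b))
  scaled <- levene_f(list(a = 3 * a, b = 3 * b))
  expect_equal(base$statistic, shifted$statistic, tolerance = 1e-10)
  expect_equal(base$statistic, scaled$statistic, tolerance = 1e-10)

  # with center = mean and two groups, F equals the squared pooled-variance
  # t statistic on the absolute deviations
  dev_a <- abs(a - mean(a)); dev_b <- abs(b - mean(b))
  tt <- t.test(dev_a, dev_b, var.equal = TRUE)
  expect_equal(base$statistic, unname(tt$statistic)^2, tolerance = 1e-10)

  # median centering (Brown-Forsythe) is available and differs in general
  bf <- levene_f(list(a = a, b = b), center = "median")
  expect_false(isTRUE(all.equal(bf$statistic, base$statistic)))
})

test_that("distribution comparisons match the textbook Welch computation", {
  a <- c(3.1, 2.8, 3.5, 3.0, 2.9)
  b <- c(3.8, 4.1, 3.9, 4.3)
  res <- compare_distributions(a, b, method = "t")
  # Welch by hand
  se <- sqrt(var(a) / 5 + var(b) / 4)
  tstat <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 4)^2 / 3)
  expect_equal(res$statistic, tstat, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-10)

  expect_equal(compare_distributions(c(1, 1), c(1, 1))$p_value, 1)
  set.seed(21)
  x <- rnorm(50); y <- rnorm(50) + 10
  expect_lt(compare_distributions(x, y)$p_value, 1e-10)

  res_a <- compare_distributions(a, b, method = "anova")
  fit <- anova(lm(c(a, b) ~ rep(c("a", "b"), c(5, 4))))
  expect_equal(res_a$statistic, fit$`F value`[1], tolerance = 1e-10)
})

test_that("the parental-expectation model has the stated degenerate and null behavior", {
  # both parents constant: every simulated CV is 0, so mean = max = 0
  pa <- matrix(5, 3, 4, dimnames = list(paste0("t", 1:3), NULL))
  res <- parental_expectation_model(pa, pa, n_lines = 50, n_models = 20,
                                    seed = 30)
  expect_equal(res$model_mean, 0)
  expect_equal(res$model_max, 0)

  # self-consistency: RIL CVs actually drawn from the parental mixture fall
  # inside the model envelope
  set.seed(31)
  n_traits <- 8; k <- 4; n_lines <- 120
  pa2 <- matrix(rnorm(n_traits * k, 100, 10), n_traits, k,
                dimnames = list(paste0("t", 1:n_traits), NULL))
  pb2 <- matrix(rnorm(n_traits * k, 100, 18), n_traits, k,
                dimnames = list(paste0("t", 1:n_traits), NULL))
  obs_cv <- sapply(1:n_traits, function(t) {
    vapply(1:n_lines, function(i) {
      src <- if (runif(1) < 0.5) pa2[t, ] else pb2[t, ]
      compute_cv(sample(src, k, replace = TRUE))
    }, numeric(1))
  })
  res2 <- parental_expectation_model(pa2, pb2, n_lines = n_lines,
                                     n_models = 300, observed_cv = obs_cv,
                                     seed = 32)
  expect_false(isTRUE(res2$exceeds))
  expect_gte(res2$observed, min(res2$model_sds) * 0.8)

  # swapping the parents leaves the model envelope statistically unchanged
  res3 <- parental_expectation_model(pb2, pa2, n_lines = n_lines,
                                     n_models = 300, seed = 33)
  expect_lt(abs(res3$model_mean - res2$model_mean),
            5 * sd(res2$model_sds) / sqrt(300) +
              5 * sd(res3$model_sds) / sqrt(300))

  # unusable traits are skipped with a message
  pa3 <- rbind(pa2, bad = c(-10, -9, -11, -10))
  pb3 <- rbind(pb2, bad = c(1, 2, 3, 4))
  expect_message(
    parental_expectation_model(pa3, pb3, n_lines = 20, n_models = 5,
                               seed = 34),
    "skipping")
})
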