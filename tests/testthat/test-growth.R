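test_that("vbgm_predict evaluates the growth equation", {
  expect_equal(vbgm_predict(40, 0.2, -1, age = -1), 0)   # exponent zero at t0
  expect_equal(vbgm_predict(41.59, 0.11, -4.86, age = 2),
               41.59 * (1 - exp(-0.11 * (2 + 4.86))), tolerance = 1e-12)
  expect_equal(round(vbgm_predict(41.59, 0.11, -4.86, age = 2), 2), 22.03)
  # monotone approach to the asymptote
  ages <- seq(0, 80, by = 0.5)
  pred <- vbgm_predict(38, 0.15, -3, ages)
  expect_true(all(diff(pred) > 0))
  expect_lt(38 - vbgm_predict(38, 0.15, -3, 200), 1e-10)
  expect_error(vbgm_predict(38, -0.1, -3, 1), "positive")
})

test_that("noiseless data identify the generating parameters exactly", {
  ages <- seq(0.5, 12, by = 0.5)
  lens <- vbgm_predict(38.85, 0.15, -3.66, ages)
  fit <- fit_vbgm(ages, lens)
  expect_equal(unname(fit$coef),
               c(38.85, 0.15, -3.66), tolerance = 1e-6)
  expect_equal(fit$df, length(ages) - 3)
})

test_that("degenerate designs are refused", {
  expect_error(fit_vbgm(c(1, 2), c(10, 12)), "at least 4")
  expect_error(fit_vbgm(rep(3, 6), rnorm(6, 20)), "distinct ages")
})

test_that("the fitted curve beats the generating truth in RSS on a sample", {
  set.seed(8)
  for (i in 1:10) {
    d <- gen_vbgm_data(120)
    fit <- fit_vbgm(d$age, d$len)
    rss_truth <- sum((d$len - vbgm_predict(38.85, 0.15, -3.66, d$age))^2)
    expect_lte(fit$rss, rss_truth + 1e-8)
  }
})

test_that("the profiled Gaussian log-likelihood matches the closed form", {
  set.seed(9)
  d <- gen_vbgm_data(200)
  fit <- fit_vbgm(d$age, d$len)
  expect_equal(fit$logLik, gauss_logl(fit$rss, fit$n), tolerance = 1e-10)
})

test_that("bootstrap CIs are deterministic under a fixed seed and collapse
           to points on noiseless data", {
  set.seed(10)
  d <- gen_vbgm_data(150)
  fit <- fit_vbgm(d$age, d$len)
  b1 <- bootstrap_vbgm(fit, B = 100, seed = 42)
  b2 <- bootstrap_vbgm(fit, B = 100, seed = 42)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$ci["linf", 1] <= fit$coef["linf"],
              fit$coef["linf"] <= b1$ci["linf", 2])

  ages <- seq(0.5, 12, by = 0.25)
  clean <- fit_vbgm(ages, vbgm_predict(38.85, 0.15, -3.66, ages))
  bc <- bootstrap_vbgm(clean, B = 100, seed = 1)
  expect_lt(diff(bc$ci["linf", ]), 1e-3)
})

test_that("the model lattice is complete, nested and correctly sized", {
  set.seed(12)
  d <- gen_vbgm_data(240)
  g <- rep(c("a", "b", "c"), each = 80)
  cg <- compare_growth(d$age, d$len, g)
  expect_equal(nrow(cg$models), 8)
  # parameter counts for 3 groups: 9, 7, 7, 7, 5, 5, 5, 3
  expect_setequal(cg$models$m, c(9, 7, 7, 7, 5, 5, 5, 3))
  # nesting monotonicity of logL within optimiser tolerance
  full_ll <- cg$models$logLik[cg$models$model == "full"]
  expect_true(all(cg$models$logLik <= full_ll + 1e-6))
  coin_ll <- cg$models$logLik[cg$models$model == "coincident"]
  expect_true(all(cg$models$logLik >= coin_ll - 1e-6))
  expect_true(all(cg$comparisons$chisq >= 0))
  expect_true(all(cg$comparisons$df > 0))
})

test_that("identical groups lead to the coincident curve", {
  set.seed(130)
  d <- gen_vbgm_data(300)
  g <- rep(c("x", "y"), each = 150)
  cg <- compare_growth(d$age, d$len, g)
  expect_equal(cg$selected, "coincident")
  p0 <- cg$comparisons$p[cg$comparisons$test == "coincident vs full"]
  expect_gt(p0, 0.05)
  # 2-group lattice parameter counts: 6, 5, 5, 5, 4, 4, 4, 3
  expect_setequal(cg$models$m, c(6, 5, 5, 5, 4, 4, 4, 3))
})

test_that("model selection is invariant to group label permutation", {
  set.seed(14)
  d <- gen_vbgm_data(240)
  # real K/t0 differences between groups
  g <- rep(c("a", "b", "c"), each = 80)
  d$len <- d$len + ifelse(g == "b", 2.5, ifelse(g == "c", -2.5, 0)) *
    (d$age / 12)
  cg1 <- compare_growth(d$age, d$len, g)
  relabel <- c(a = "c", b = "a", c = "b")[g]
  cg2 <- compare_growth(d$age, d$len, relabel)
  expect_equal(cg1$selected, cg2$selected)
  expect_equal(cg1$models$logLik[order(cg1$models$model)],
               cg2$models$logLik[order(cg2$models$model)], tolerance = 1e-4)
})

test_that("a strong single-parameter group difference is recovered", {
  set.seed(15)
  ages <- runif(360, 0.5, 12)
  g <- rep(c("a", "b", "c"), each = 120)
  k_true <- c(a = 0.10, b = 0.15, c = 0.22)[g]
  lens <- 38.85 * (1 - exp(-k_true * (ages + 3.66))) + rnorm(360, 0, 1.0)
  cg <- compare_growth(ages, lens, g)
  expect_true(grepl("k", cg$selected))
})

test_that("phi-prime and lifespan match arbitrary-precision evaluation", {
  expect_equal(growth_performance(1, 10), 2)
  expect_equal(growth_performance(0.15, 38.85),
               log10(0.15) + 2 * log10(38.85), tolerance = 1e-12)
  expect_equal(lifespan(3, 0), 1)
  expect_equal(lifespan(0.11, -4.86), 3 / 0.11 - 4.86, tolerance = 1e-12)
  expect_error(growth_performance(-1, 10), "positive")
  expect_error(lifespan(0, 1), "positive")
})
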