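test_that("marginal increment matches hand arithmetic and edge cases", {
  expect_equal(marginal_increment(10, 10, 8), 0)    # annulus on the edge
  expect_equal(marginal_increment(10, 8, 6), 1)     # equal spacing
  expect_equal(marginal_increment(10, 9, 7), 0.5)
  expect_error(marginal_increment(10, 8, 8), "degenerate")
  expect_error(marginal_increment(10, 7, 8), "ordering")
})

test_that("marginal increment is scale-invariant", {
  set.seed(31)
  for (i in 1:25) {
    rim1 <- runif(1, 0.5, 2); ri <- rim1 + runif(1, 0.1, 2)
    R <- ri + runif(1, 0, 1); c <- runif(1, 0.1, 50)
    expect_equal(marginal_increment(c * R, c * ri, c * rim1),
                 marginal_increment(R, ri, rim1), tolerance = 1e-12)
  }
})

test_that("mia_series finds the deposition window the generator imposed", {
  pop <- generate_population(population_config(seed = 3))
  rd <- pop$readings
  rd <- rd[!is.na(rd$penultimate_annulus_mm), ]
  rd$mia <- marginal_increment(rd$otolith_radius_mm, rd$last_annulus_mm,
                               rd$penultimate_annulus_mm)
  out <- mia_series(rd, group_by = "site")
  dep <- out$deposition
  # Celestun deposits Feb-Mar, the other two sites Jul-Sep
  expect_true(all(dep$month[dep$group == "Celestun"] %in% 2:3))
  expect_true(all(dep$month[dep$group != "Celestun"] %in% 7:9))
})

test_that("degenerate mia_series cells are reported, not dropped", {
  one <- data.frame(mia = 0.4, month = 7, annuli = 3)
  out <- mia_series(one, group_by = "annuli")
  expect_equal(out$series$sd_mia, 0)
  expect_true(out$series$sd_undefined)
  two <- data.frame(mia = c(0.4, 0.4), month = 7, annuli = 3)
  expect_equal(mia_series(two, "annuli")$series$sd_mia, 0)
})

test_that("APE and CV match hand arithmetic and the agreement zero-case", {
  same <- matrix(rep(c(3, 5, 7), each = 2), ncol = 2, byrow = TRUE)
  out <- ape_cv(same)
  expect_equal(out$ape_pct, 0)
  expect_equal(out$cv_pct, 0)

  out <- ape_cv(rbind(c(9, 11)))
  expect_equal(out$ape_pct, 10)
  expect_equal(out$cv_pct, 100 * sqrt(2) / 10, tolerance = 1e-10)

  expect_error(ape_cv(matrix(1:3, ncol = 1)), "two readers")
  expect_error(ape_cv(rbind(c(0, 0))), "undefined")
})

test_that("CV tracks the analytic expectation of a known noise model", {
  # reads = true age + iid N(0, 0.5); E[CV_j] ~ 100 * c4 * sigma / age
  set.seed(77)
  n <- 1000; true_age <- rep(10, n); sigma <- 0.5
  reads <- matrix(rnorm(3 * n, true_age, sigma), ncol = 3)
  out <- ape_cv(reads)
  # E[sd] of 3 iid normals = sigma * sqrt(2/2) * gamma(3/2)/gamma(1)
  expected <- 100 * sigma * sqrt(pi) / 2 / 10
  expect_lt(abs(out$cv_pct - expected), 1)
})

test_that("precision_report treats the automatic count as an extra reader", {
  readers <- rbind(c(3, 3), c(5, 5), c(7, 7))
  auto <- c(3, 5, 9)
  rep <- precision_report(readers, auto_counts = auto, consensus = c(3, 5, 7))
  expect_equal(rep$ape_between_readers_pct, 0)
  expect_gt(rep$ape_global_pct, 0)
  expect_gt(rep$ape_automatic_pct, 0)
})

test_that("fractional age follows the calendar and the edge rule", {
  # capture on the birthdate anniversary: zero elapsed fraction
  expect_equal(fractional_age(3, as.Date("2008-05-01")), 3)
  # May 1 -> Jul 31 is 91 days; opaque edge in window: no bump
  expect_equal(fractional_age(3, as.Date("2008-07-31"), edge_opaque = TRUE),
               3 + 91 / 365.25, tolerance = 1e-12)
  # in the deposition window without an opaque edge: one year added
  expect_equal(fractional_age(2, as.Date("2008-08-15"), edge_opaque = FALSE),
               3 + 106 / 365.25, tolerance = 1e-12)
  # outside the window the edge state is irrelevant
  expect_equal(fractional_age(2, as.Date("2008-03-15"), edge_opaque = FALSE),
               2 + as.numeric(as.Date("2008-03-15") - as.Date("2007-05-01")) /
                 365.25, tolerance = 1e-12)
})

test_that("fractional age is non-decreasing in capture date at fixed annuli", {
  dates <- seq(as.Date("2008-05-01"), as.Date("2009-04-30"), by = "day")
  ages <- fractional_age(4, dates, edge_opaque = TRUE)
  expect_true(all(diff(ages) >= 0))
})
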