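test_that("allometric screening classifies size, site and inert variables", {
  set.seed(41)
  n <- 300
  group <- factor(rep(c("a", "b", "c"), each = n / 3))
  fl <- runif(n, 17, 39)
  site_exp <- c(a = 1.1, b = 1.45, c = 1.8)[group]  # site-specific allometry
  tab <- data.frame(
    size_only = 0.17 * fl^1.4235 * rlnorm(n, 0, sqrt(log(1 + 0.1^2))),
    inert = rlnorm(n, log(5), 0.1),
    interacting = 0.05 * fl^site_exp * rlnorm(n, 0, 0.1)
  )
  out <- classify_and_correct(tab, fl, group)
  dec <- out$decisions
  expect_equal(dec$state[dec$variable == "size_only"], "corrected")
  expect_equal(dec$state[dec$variable == "inert"], "kept")
  expect_equal(dec$state[dec$variable == "interacting"],
               "removed_site_x_length")
  # recovered common slope close to the generating exponent
  expect_equal(dec$b[dec$variable == "size_only"], 1.4235, tolerance = 0.05)
  # the correction removes the size correlation it targets
  adj <- out$corrected$size_only
  slope_fit <- summary(lm(log(adj) ~ log(fl)))$coefficients
  expect_lt(abs(slope_fit["log(fl)", "Estimate"]),
            2 * slope_fit["log(fl)", "Std. Error"])
})

test_that("percentage indices are arcsine-transformed before screening", {
  set.seed(420)
  n <- 120
  group <- factor(rep(c("a", "b"), each = n / 2))
  fl <- runif(n, 17, 39)
  tab <- data.frame(OsA_SAA_pct = 100 * plogis(rnorm(n, -0.5, 0.2)))
  out <- classify_and_correct(tab, fl, group)
  expect_equal(out$decisions$state, "kept")
  # surviving values are on the arcsine scale (radians, < pi/2)
  expect_true(all(out$corrected$OsA_SAA_pct < pi / 2))
  expect_equal(out$corrected$OsA_SAA_pct,
               asin(sqrt(tab$OsA_SAA_pct / 100)))
  expect_error(arcsine_pct(120), "0, 100")
})

test_that("non-positive variables are excluded with a reason", {
  group <- factor(rep(c("a", "b"), each = 10))
  tab <- data.frame(ok = runif(20, 1, 2), bad = c(-1, runif(19, 1, 2)))
  out <- classify_and_correct(tab, runif(20, 17, 39), group)
  expect_equal(out$decisions$state[out$decisions$variable == "bad"],
               "excluded_nonpositive")
  expect_false("bad" %in% names(out$corrected))
})

test_that("normalisation gives zero-mean unit-SD columns and flags collinearity", {
  set.seed(43)
  tab <- data.frame(x = rnorm(50, 10, 2), y = rnorm(50), z = rep(1, 50))
  tab$x2 <- tab$x * 3 + 0.001 * rnorm(50)
  expect_warning(scaled <- normalize_shape(tab), "constant")
  expect_equal(unname(colMeans(scaled)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(scaled, 2, sd)), rep(1, 3), tolerance = 1e-12)
  pairs <- attr(scaled, "collinear_pairs")
  expect_true(any(pairs$var1 == "x" & pairs$var2 == "x2"))
})

test_that("PCoA of two points puts them at +-d/2 with all the variance", {
  x <- rbind(c(0, 0), c(3, 4))   # distance 5
  ord <- shape_pcoa(x)
  expect_equal(unname(sort(ord$coordinates[, 1])), c(-2.5, 2.5),
               tolerance = 1e-10)
  expect_equal(ord$variance_pct[1], 100, tolerance = 1e-8)
})

test_that("PCoA coincides with PCA on Euclidean input", {
  set.seed(44)
  x <- scale(matrix(rnorm(20 * 8), 20, 8))
  ord <- shape_pcoa(x)
  pca <- prcomp(x, center = TRUE, scale. = FALSE)
  for (axis in 1:3) {
    expect_equal(abs(ord$coordinates[, axis]), abs(pca$x[, axis]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # axis variance percentages non-increasing; trace preserved
  expect_true(all(diff(ord$variance_pct) <= 1e-10))
  expect_equal(ord$trace, sum(pca$sdev^2) * (nrow(x) - 1), tolerance = 1e-8)
  # centroid of the coordinates at the origin
  expect_equal(unname(colMeans(ord$coordinates)),
               rep(0, ncol(ord$coordinates)), tolerance = 1e-10)
})

test_that("a variable equal to the axis scores contributes 100%", {
  set.seed(45)
  x <- scale(matrix(rnorm(30 * 4), 30, 4))
  ord <- shape_pcoa(x)
  x2 <- cbind(x, probe = ord$coordinates[, 1])
  ord2 <- shape_pcoa(x2)
  ct <- ord2$contributions
  expect_gt(ct$axis1[ct$variable == "probe"], 99.9)
})

test_that("variable selection applies the either-axis threshold", {
  ord <- structure(list(contributions = tibble::tibble(
    variable = c("v1", "v2", "v3"),
    axis1 = c(95.3, 79.9, 10),
    axis2 = c(5, 40, 87.2))), class = "shape_pcoa")
  expect_setequal(select_variables(ord), c("v1", "v3"))
  expect_setequal(select_variables(ord, threshold = 0), c("v1", "v2", "v3"))
  expect_warning(sel <- select_variables(ord, threshold = 99.9), "keeping all")
  expect_equal(sel, c("v1", "v2", "v3"))
})

test_that("PERMANOVA is label-order invariant, seeded, and attains the
           minimum p under extreme separation", {
  set.seed(46)
  x <- rbind(matrix(rnorm(15 * 4), 15, 4),
             matrix(rnorm(15 * 4, mean = 50), 15, 4))
  labels <- rep(c("near", "far"), each = 15)
  out <- shape_permanova(x, labels, n_perm = 99, seed = 5)
  expect_equal(out$p[out$level == "overall"], 1 / (99 + 1))
  out2 <- shape_permanova(x, labels, n_perm = 99, seed = 5)
  expect_equal(out$f, out2$f)
  expect_equal(out$p, out2$p)
  # permuting the row order leaves the observed F unchanged
  perm <- sample(30)
  out3 <- shape_permanova(x[perm, ], labels[perm], n_perm = 99, seed = 5)
  expect_equal(out3$f[out3$level == "overall"],
               out$f[out$level == "overall"], tolerance = 1e-10)
  expect_error(shape_permanova(x, rep("one", 30)), "2 label levels")
})

test_that("betadisper returns centroid distances with the right geometry", {
  x <- rbind(c(0, 0), c(4, 0),          # group A: distance 4 apart
             c(1, 1), c(1, 1), c(1, 1)) # group B: coincident
  labels <- c("A", "A", "B", "B", "B")
  out <- shape_betadisper(x, labels)
  s <- out$summary
  expect_equal(s$mean_dist[s$group == "A"], 2, tolerance = 1e-10)
  expect_equal(s$mean_dist[s$group == "B"], 0, tolerance = 1e-10)
  expect_equal(s$n, c(2L, 3L))
})
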