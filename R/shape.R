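# Otolith-shape workflow: allometric size correction driven by ANCOVA
# slope-homogeneity screening, normalisation, principal coordinates
# analysis, PERMANOVA and dispersion (betadisper) for stock discrimination.

#' Names of the standard otolith and sulcus acusticus shape variables
#'
#' Nine otolith morphometrics and seven shape indices for the sagitta, six
#' morphometrics and two percentage indices for the sulcus acusticus.
#'
#' @return named list with `otolith`, `sulcus` and `percent` (the two
#'   indices expressed as percentages).
#' @export
shape_variable_names <- function() {
  list(
    otolith = c("A", "MaxD", "MinD", "P", "Rl", "Rw", "Al", "Aw", "EA",
                "RE", "R", "E", "Fi", "As", "RAs", "AAs"),
    sulcus = c("SAl", "SAA", "Osl", "OsA", "Cl", "CA",
               "OsA_SAA_pct", "Osl_SAl_pct"),
    percent = c("OsA_SAA_pct", "Osl_SAl_pct")
  )
}

#' Arcsine square-root transform for percentage indices
#'
#' `asin(sqrt(p / 100))`, mapping 0-100% onto 0-pi/2. Applied to
#' percentage-scale indices before allometric screening and normalisation.
#'
#' @param p percentages in \[0, 100\].
#' @return transformed values (radians).
#' @export
arcsine_pct <- function(p) {
  if (any(p < 0 | p > 100, na.rm = TRUE)) stop("percentages must be in [0, 100]")
  asin(sqrt(p / 100))
}

#' Allometric screening and size correction of shape variables
#'
#' Removes the effect of fish size on otolith shape variables before
#' multivariate analysis. Per variable, an ANCOVA with homogeneity-of-slopes
#' test is run on the log-log model `log(V) ~ log(FL) * group`:
#'
#' * a significant slope-by-group interaction, or a significant group main
#'   effect alongside a significant size effect, means the variable
#'   confounds site and size — it is **removed**;
#' * otherwise a significant size slope alone means the variable is
#'   **corrected** multiplicatively, `V_adj = V * (FL_ref / FL)^b`, with `b`
#'   the common within-group log-log slope and `FL_ref` the grand mean FL;
#' * otherwise the variable is **kept** unchanged.
#'
#' Percentage indices are arcsine-square-root transformed first and handled
#' on that scale throughout.
#'
#' @param table data frame of positive shape variables (one column per
#'   variable, one row per otolith).
#' @param fl fork length (cm) per otolith.
#' @param group grouping factor (fishing site).
#' @param alpha significance level for the ANCOVA terms.
#' @param percent_vars column names on a percentage scale; defaults to the
#'   intersection of `shape_variable_names()$percent` with the columns.
#' @return list with `decisions` (tibble: variable, state, b, p_interaction,
#'   p_group, p_fl) and `corrected` (tibble of the surviving, size-adjusted
#'   variables, percentage indices on the arcsine scale).
#' @export
classify_and_correct <- function(table, fl, group, alpha = 0.05,
                                 percent_vars = NULL) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (is.null(percent_vars)) {
    percent_vars <- intersect(shape_variable_names()$percent, names(table))
  }
  fl_ref <- mean(fl)
  logfl <- log(fl)

  decisions <- list()
  corrected <- list()
  for (v in names(table)) {
    val <- table[[v]]
    if (v %in% percent_vars) val <- arcsine_pct(val)
    if (any(is.na(val)) || any(val <= 0)) {
      decisions[[v]] <- tibble(variable = v, state = "excluded_nonpositive",
                               b = NA_real_, p_interaction = NA_real_,
                               p_group = NA_real_, p_fl = NA_real_)
      next
    }
    fit <- lm(log(val) ~ logfl * group)
    an <- anova(fit)
    p_fl <- an["logfl", "Pr(>F)"]
    p_group <- an["group", "Pr(>F)"]
    p_int <- an["logfl:group", "Pr(>F)"]
    if (p_int < alpha || (p_group < alpha && p_fl < alpha)) {
      state <- "removed_site_x_length"; b <- NA_real_
    } else if (p_fl < alpha) {
      state <- "corrected"
      b <- coef(lm(log(val) ~ logfl + group))[["logfl"]]
      corrected[[v]] <- val * (fl_ref / fl)^b
    } else {
      state <- "kept"; b <- NA_real_
      corrected[[v]] <- val
    }
    decisions[[v]] <- tibble(variable = v, state = state, b = b,
                             p_interaction = p_int, p_group = p_group,
                             p_fl = p_fl)
  }
  list(decisions = dplyr::bind_rows(decisions),
       corrected = as_tibble(corrected))
}

#' Normalise shape variables to a common scale
#'
#' Centres each variable to zero mean and unit sample SD. Constant columns
#' are dropped with a warning. A collinearity screen reports (but does not
#' drop) variable pairs with `|r| >= 0.9` in the `collinear_pairs`
#' attribute.
#'
#' @param table data frame or matrix of numeric variables.
#' @return numeric matrix of scaled variables with attribute
#'   `collinear_pairs` (data frame: var1, var2, r).
#' @export
normalize_shape <- function(table) {
  x <- as.matrix(table)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant variable(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  scaled <- scale(x)
  r <- cor(scaled)
  idx <- which(abs(r) >= 0.9 & upper.tri(r), arr.ind = TRUE)
  attr(scaled, "collinear_pairs") <- data.frame(
    var1 = colnames(r)[idx[, 1]], var2 = colnames(r)[idx[, 2]],
    r = r[idx])
  scaled
}

#' Principal coordinates analysis of a shape matrix
#'
#' Metric multidimensional scaling on the Euclidean distance matrix (Gower
#' double-centering of -D^2/2 followed by eigendecomposition; coordinates
#' are eigenvectors scaled by the square root of their eigenvalue). On
#' Euclidean input this coincides with PCA of the data matrix. Negative
#' eigenvalues — numerically impossible for truly Euclidean input — are
#' clipped to zero with a warning. The contribution of each variable to an
#' axis is `100 * r^2` between the variable and the axis scores.
#'
#' @param x numeric matrix (otoliths x variables), typically the output of
#'   [normalize_shape()].
#' @return object of class `shape_pcoa`: list with `eigenvalues`,
#'   `coordinates` (otoliths x axes), `variance_pct` (per axis),
#'   `contributions` (tibble: variable, axis1, axis2, in %), `trace`.
#' @export
shape_pcoa <- function(x) {
  x <- as.matrix(x)
  d <- dist(x)
  pc <- ape::pcoa(d)
  ev <- pc$values$Eigenvalues
  if (any(ev < -sqrt(.Machine$double.eps) * max(abs(ev)))) {
    warning("negative eigenvalues clipped to zero")
  }
  ev <- pmax(ev, 0)
  coords <- pc$vectors
  keep <- seq_len(ncol(coords))
  variance_pct <- 100 * ev[keep] / sum(ev)
  contributions <- tibble(
    variable = colnames(x),
    axis1 = 100 * as.vector(cor(x, coords[, 1]))^2,
    axis2 = if (ncol(coords) >= 2) 100 * as.vector(cor(x, coords[, 2]))^2
            else NA_real_
  )
  structure(list(
    eigenvalues = ev[keep], coordinates = coords,
    variance_pct = variance_pct, contributions = contributions,
    trace = sum(ev)
  ), class = "shape_pcoa")
}

#' @export
print.shape_pcoa <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "otoliths,",
      length(x$eigenvalues), "axes\n")
  cat("variance explained (first axes, %):",
      paste(round(head(x$variance_pct, 4), 2), collapse = ", "), "\n")
  invisible(x)
}

#' Select shape variables by ordination contribution
#'
#' Variables whose contribution (`100 * r^2` with the axis scores) reaches
#' the threshold on either of the first two axes. An empty selection falls
#' back to all variables with a warning.
#'
#' @param ordination a `shape_pcoa` object.
#' @param threshold contribution threshold in percent (default 80).
#' @return character vector of selected variable names.
#' @export
select_variables <- function(ordination, threshold = 80) {
  ct <- ordination$contributions
  sel <- ct$variable[ct$axis1 >= threshold |
                       (!is.na(ct$axis2) & ct$axis2 >= threshold)]
  if (!length(sel)) {
    warning("no variable reaches the contribution threshold; keeping all")
    sel <- ct$variable
  }
  sel
}

#' PERMANOVA on otolith shape
#'
#' Permutation-based multivariate analysis of variance on the Euclidean
#' distance matrix: an overall test of the factor plus one row per level
#' testing that level against the rest (one-vs-rest). The pseudo-F is the
#' among/within mean-square ratio of the distance partition; the p-value is
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)` under whole-row label
#' permutation.
#'
#' @param x numeric matrix of (corrected, scaled) shape variables.
#' @param labels grouping factor.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return tibble with columns `level` (`"overall"` or the level tested
#'   one-vs-rest), `df`, `ss`, `n`, `f`, `p`, `n_perm`, `seed`.
#' @export
shape_permanova <- function(x, labels, n_perm = 999, seed = 1) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2) stop("need at least 2 label levels")
  if (any(table(labels) < 2)) stop("every level needs at least 2 members")
  x <- as.matrix(x)
  d <- dist(x)

  run_one <- function(fac, level_name) {
    set.seed(seed)
    dat <- data.frame(fac = fac)
    res <- vegan::adonis2(d ~ fac, data = dat, permutations = n_perm)
    tibble(level = level_name, df = res$Df[1], ss = res$SumOfSqs[1],
           n = length(fac), f = res$F[1], p = res$`Pr(>F)`[1],
           n_perm = n_perm, seed = seed)
  }
  rows <- list(run_one(labels, "overall"))
  for (l in levels(labels)) {
    rows[[length(rows) + 1]] <-
      run_one(factor(labels == l, levels = c(FALSE, TRUE)), l)
  }
  dplyr::bind_rows(rows)
}

#' Group dispersion around centroids (betadisper)
#'
#' Homogeneity-of-dispersion analysis: for each group, the centroid in
#' principal-coordinate space and the mean distance of members to it.
#'
#' @param x numeric matrix of (corrected, scaled) shape variables.
#' @param labels grouping factor.
#' @return list with `summary` (tibble: group, n, mean_dist) and
#'   `centroids` (matrix, groups x axes), plus the underlying
#'   `vegan::betadisper` object as `fit`.
#' @export
shape_betadisper <- function(x, labels) {
  labels <- droplevels(factor(labels))
  empty <- setdiff(levels(factor(labels)), unique(as.character(labels)))
  if (length(empty)) warning("omitting empty group(s): ",
                             paste(empty, collapse = ", "))
  bd <- vegan::betadisper(dist(as.matrix(x)), labels, type = "centroid")
  mean_dist <- tapply(bd$distances, bd$group, mean)
  list(
    summary = tibble(group = names(mean_dist),
                     n = as.integer(table(bd$group)[names(mean_dist)]),
                     mean_dist = as.numeric(mean_dist)),
    centroids = bd$centroids,
    fit = bd
  )
}
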