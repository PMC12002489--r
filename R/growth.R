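# Von Bertalanffy growth modelling: nonlinear least-squares fitting,
# bootstrap uncertainty, hierarchical likelihood-ratio comparison of growth
# curves among groups, and derived life-history quantities.

#' Predict mean length at age under the von Bertalanffy growth model
#'
#' `L(t) = L_inf * (1 - exp(-K * (t - t0)))`. Defined for all real ages;
#' predictions below zero (ages well before `t0`) are returned as-is.
#'
#' @param linf asymptotic mean length (cm).
#' @param k growth coefficient (1/year), must be positive.
#' @param t0 hypothetical age at zero length (year).
#' @param age age in years (vectorised).
#' @return predicted fork length (cm).
#' @export
#' @examples
#' vbgm_predict(38.85, 0.15, -3.66, age = 5)
vbgm_predict <- function(linf, k, t0, age) {
  if (any(k <= 0)) stop("k must be positive")
  linf * (1 - exp(-k * (age - t0)))
}

# Gaussian log-likelihood with the error variance profiled out at RSS/n.
.gauss_logl <- function(rss, n) -(n / 2) * (log(2 * pi) + log(rss / n) + 1)

#' Fit the von Bertalanffy growth model
#'
#' Nonlinear least squares (Levenberg-Marquardt) on age-length pairs, with
#' multiple jittered starts before declaring non-convergence: the VBGM
#' surface is notoriously flat in the `L_inf`-`K` direction, and single-start
#' fits can stall on poorly conditioned samples.
#'
#' @param age ages in years (fractional ages, not raw annuli counts).
#' @param length lengths (cm).
#' @param start optional named vector `c(linf=, k=, t0=)`; defaults to
#'   `linf = 1.1 * max(length)`, `k = 0.2`, `t0 = -1`.
#' @param n_starts number of jittered restarts to attempt on failure.
#' @return an object of class `vbgm_fit`: list with `coef` (linf, k, t0),
#'   `se`, `vcov`, `n`, `df` (= n - 3), `rss`, `logLik` (Gaussian, profiled
#'   variance), `converged`, and the data used.
#' @export
fit_vbgm <- function(age, length, start = NULL, n_starts = 5) {
  ok <- !is.na(age) & !is.na(length)
  age <- age[ok]; length <- length[ok]
  n <- length(age)
  if (n < 4) stop("need at least 4 age-length pairs")
  if (length(unique(age)) < 3) stop("degenerate design: need >= 3 distinct ages")
  if (is.null(start)) {
    start <- c(linf = 1.1 * max(length), k = 0.2, t0 = -1)
  }
  start <- start[c("linf", "k", "t0")]
  dat <- data.frame(age = age, len = length)

  attempt <- function(s) {
    tryCatch(
      minpack.lm::nlsLM(
        len ~ linf * (1 - exp(-k * (age - t0))), data = dat,
        start = as.list(s),
        lower = c(linf = 1e-6, k = 1e-6, t0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- attempt(start)
  tries <- 0
  while (is.null(fit) && tries < n_starts) {
    tries <- tries + 1
    jit <- start * exp(rnorm(3, 0, 0.2))
    jit["t0"] <- start[["t0"]] - abs(rnorm(1, 0, 1))
    fit <- attempt(jit)
  }
  if (is.null(fit)) {
    stop("VBGM fit failed to converge after ", n_starts, " restarts (n = ",
         n, ", age range ", paste(round(range(age), 2), collapse = "-"), ")")
  }
  est <- coef(fit)
  rss <- sum(resid(fit)^2)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  structure(list(
    coef = c(linf = unname(est["linf"]), k = unname(est["k"]),
             t0 = unname(est["t0"])),
    se = sqrt(diag(vc)), vcov = vc,
    n = n, df = n - 3L, rss = rss, logLik = .gauss_logl(rss, n),
    converged = TRUE, age = age, length = length
  ), class = "vbgm_fit")
}

#' @export
print.vbgm_fit <- function(x, ...) {
  cat("von Bertalanffy growth fit (n =", x$n, ")\n")
  est <- rbind(estimate = x$coef, se = x$se)
  print(round(est, 4))
  cat("RSS:", format(x$rss, digits = 6),
      " logLik:", format(x$logLik, digits = 6), "\n")
  if (!is.null(x$ci)) {
    cat("bootstrap 95% CI:\n"); print(round(x$ci, 3))
  }
  invisible(x)
}

#' Bootstrap percentile confidence intervals for VBGM parameters
#'
#' Resamples (age, length) pairs with replacement, refits, and takes the
#' 2.5/97.5 percentiles of each parameter. Non-converged replicates are
#' dropped and counted.
#'
#' @param fit a `vbgm_fit` object.
#' @param B number of bootstrap iterations (>= 100).
#' @param seed integer seed; required for reproducibility.
#' @param strict if `TRUE`, more than 20% non-convergence is an error
#'   instead of a warning.
#' @return the fit with added elements `ci` (matrix 3 x 2), `boot`
#'   (replicate parameter matrix) and `n_failed`.
#' @export
bootstrap_vbgm <- function(fit, B = 999, seed = 1, strict = FALSE) {
  stopifnot(inherits(fit, "vbgm_fit"), B >= 100)
  set.seed(seed)
  n <- fit$n
  reps <- matrix(NA_real_, B, 3, dimnames = list(NULL, names(fit$coef)))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_fit <- tryCatch(
      fit_vbgm(fit$age[idx], fit$length[idx], start = fit$coef, n_starts = 2),
      error = function(e) NULL)
    if (!is.null(rep_fit)) reps[b, ] <- rep_fit$coef
  }
  failed <- sum(is.na(reps[, 1]))
  if (failed > 0.2 * B) {
    msg <- sprintf("%d/%d bootstrap replicates failed to converge", failed, B)
    if (strict) stop(msg) else warning(msg)
  }
  ok <- reps[stats::complete.cases(reps), , drop = FALSE]
  fit$ci <- t(apply(ok, 2, quantile, probs = c(0.025, 0.975)))
  fit$boot <- ok
  fit$n_failed <- failed
  fit$seed <- seed
  fit
}

# ---- multi-group lattice ---------------------------------------------------

# Fit a VBGM where the parameters named in `vary` take group-specific values
# and the rest are shared. Parameters are packed into one vector and the RSS
# is minimised with Levenberg-Marquardt on the residual vector.
.fit_vbgm_grouped <- function(age, len, group, vary, start_by_group) {
  g <- nlevels(group)
  gi <- as.integer(group)
  len_par <- function(p) if (p %in% vary) g else 1L
  shape <- c(linf = len_par("linf"), k = len_par("k"), t0 = len_par("t0"))
  unpack <- function(par) {
    i <- 0
    out <- list()
    for (p in names(shape)) {
      out[[p]] <- par[i + seq_len(shape[p])]
      i <- i + shape[p]
    }
    out
  }
  pred <- function(par) {
    pr <- unpack(par)
    linf <- if (shape["linf"] > 1) pr$linf[gi] else pr$linf
    k <- if (shape["k"] > 1) pr$k[gi] else pr$k
    t0 <- if (shape["t0"] > 1) pr$t0[gi] else pr$t0
    linf * (1 - exp(-pmax(k, 1e-8) * (age - t0)))
  }
  start <- unlist(lapply(names(shape), function(p) {
    v <- start_by_group[, p]
    if (shape[p] > 1) v else mean(v)
  }))
  out <- minpack.lm::nls.lm(
    par = start, fn = function(par) len - pred(par),
    control = minpack.lm::nls.lm.control(maxiter = 400))
  rss <- sum(out$fvec^2)
  n <- length(len)
  list(par = unpack(out$par), m = sum(shape), rss = rss,
       logLik = .gauss_logl(rss, n), n = n, df = n - sum(shape),
       converged = out$info %in% 1:4, vary = vary)
}

#' Hierarchical likelihood-ratio comparison of growth curves among groups
#'
#' Fits the full lattice of nested von Bertalanffy models over a grouping
#' factor — all three parameters group-specific, the three models with two
#' group-specific parameters, the three with one, and the coincident model
#' with all parameters shared (up to eight curves) — and compares them with
#' likelihood-ratio chi-squared tests, `X2 = 2 * (logL_full - logL_reduced)`
#' on `df = delta(m)` degrees of freedom (equivalently `n * log(RSS_red /
#' RSS_full)` under the profiled Gaussian likelihood).
#'
#' Selection walks from the most complex model downwards: the full model is
#' compared with each two-parameter model; reductions not rejected at
#' `alpha` are preferred as more parsimonious (ties broken by the highest
#' log-likelihood), and the walk recurses until every further reduction is
#' rejected or the coincident curve is reached. The comparison of the
#' coincident curve against the full model, and against any one-parameter
#' model visited, is also reported.
#'
#' @param age,length age-length data (years, cm).
#' @param group grouping factor (e.g. sex or fishing site), >= 2 levels.
#' @param alpha significance level for the selection walk.
#' @return an object of class `growth_lattice`: list with `models` (tibble:
#'   model, m, df, rss, logLik), `comparisons` (tibble: test, m, df_model,
#'   chisq, df, p), `selected` (model name), `fits` (named list of fitted
#'   parameter sets) and `n`.
#' @export
compare_growth <- function(age, length, group, alpha = 0.05) {
  ok <- !is.na(age) & !is.na(length) & !is.na(group)
  age <- age[ok]; len <- length[ok]
  group <- droplevels(factor(group[ok]))
  g <- nlevels(group)
  if (g < 2) stop("need at least 2 groups")

  start_by_group <- t(vapply(levels(group), function(l) {
    fit_vbgm(age[group == l], len[group == l])$coef
  }, numeric(3)))
  colnames(start_by_group) <- c("linf", "k", "t0")

  vary_sets <- list(
    full = c("linf", "k", "t0"),
    `linf.k` = c("linf", "k"), `linf.t0` = c("linf", "t0"),
    `k.t0` = c("k", "t0"),
    linf = "linf", k = "k", t0 = "t0",
    coincident = character(0)
  )
  fits <- lapply(vary_sets, function(v)
    .fit_vbgm_grouped(age, len, group, v, start_by_group))

  models <- tibble(
    model = names(fits),
    m = vapply(fits, `[[`, numeric(1), "m"),
    df = vapply(fits, `[[`, numeric(1), "df"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik")
  )

  comparisons <- list()
  add_cmp <- function(full, red) {
    chisq <- max(0, 2 * (fits[[full]]$logLik - fits[[red]]$logLik))
    df <- fits[[full]]$m - fits[[red]]$m
    row <- tibble(test = paste(red, "vs", full),
                  m = fits[[red]]$m, df_model = fits[[red]]$df,
                  chisq = chisq, df = df,
                  p = pchisq(chisq, df, lower.tail = FALSE))
    comparisons[[length(comparisons) + 1]] <<- row
    row$p
  }

  # coincident vs full: the global test of any group difference
  add_cmp("full", "coincident")

  nested_in <- function(model) {
    v <- vary_sets[[model]]
    names(vary_sets)[vapply(vary_sets, function(w)
      length(w) == length(v) - 1 && all(w %in% v), logical(1))]
  }
  current <- "full"
  repeat {
    subs <- nested_in(current)
    if (!length(subs)) break
    ps <- vapply(subs, function(s) add_cmp(current, s), numeric(1))
    keep <- subs[ps > alpha]
    if (!length(keep)) break
    current <- keep[which.max(models$logLik[match(keep, models$model)])]
  }
  # confirm any intermediate selection against the coincident curve
  if (!current %in% c("full", "coincident")) {
    p0 <- add_cmp(current, "coincident")
    if (p0 > alpha) current <- "coincident"
  }

  structure(list(
    models = models,
    comparisons = dplyr::bind_rows(comparisons),
    selected = current,
    fits = lapply(fits, `[`, c("par", "m", "rss", "logLik", "vary")),
    n = length(len), groups = levels(group), alpha = alpha
  ), class = "growth_lattice")
}

#' @export
print.growth_lattice <- function(x, ...) {
  cat("Growth-curve comparison over groups:",
      paste(x$groups, collapse = ", "), "(n =", x$n, ")\n\nModels:\n")
  print(as.data.frame(x$models), row.names = FALSE, digits = 6)
  cat("\nLikelihood-ratio tests:\n")
  print(as.data.frame(x$comparisons), row.names = FALSE, digits = 4)
  cat("\nSelected model:", x$selected, "\n")
  invisible(x)
}

#' Growth performance index
#'
#' `phi' = log10(K) + 2 * log10(L_inf)`, comparable across populations of a
#' species.
#'
#' @param k growth coefficient (1/year).
#' @param linf asymptotic length (cm).
#' @return phi-prime (dimensionless, base-10 log scale).
#' @export
#' @examples
#' growth_performance(0.15, 38.85)
growth_performance <- function(k, linf) {
  if (any(k <= 0) || any(linf <= 0)) stop("k and linf must be positive")
  log10(k) + 2 * log10(linf)
}

#' Lifespan from growth parameters
#'
#' Age at which ~95% of the asymptotic length is reached:
#' `t_max = 3/K + t0`.
#'
#' @param k growth coefficient (1/year).
#' @param t0 age at zero length (year).
#' @return lifespan in years.
#' @export
#' @examples
#' lifespan(0.11, -4.86)  # 22.41
lifespan <- function(k, t0) {
  if (any(k <= 0)) stop("k must be positive")
  3 / k + t0
}
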