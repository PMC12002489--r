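# Age at maturity (logistic ogive) and natural mortality estimators.

#' Fit a logistic maturity ogive and estimate age at 50% maturity
#'
#' Binomial GLM with logit link of maturity state on age;
#' `A50 = -beta0 / beta1`. Uncertainty by percentile bootstrap over fish,
#' resampling (age, maturity) pairs jointly.
#'
#' Complete separation (a threshold age below which no fish is mature and
#' above which all are) leaves the slope unbounded; the fit is then flagged
#' and `A50` is reported as the midpoint of the separating gap, with the
#' bootstrap CI computed the same way per replicate.
#'
#' @param age ages in years.
#' @param mature logical or 0/1 maturity state.
#' @param B bootstrap replicates (default 999).
#' @param seed integer seed for the bootstrap.
#' @return object of class `maturity_ogive`: list with `beta0`, `beta1`,
#'   `a50`, `ci` (percentile 95%), `separation` flag, `n`, `boot` (replicate
#'   A50s) and the fitted `glm` (NULL under separation).
#' @export
fit_maturity <- function(age, mature, B = 999, seed = 1) {
  ok <- !is.na(age) & !is.na(mature)
  age <- age[ok]; mature <- as.integer(as.logical(mature[ok]))
  n <- length(age)
  if (n < 10) stop("need at least 10 fish")
  if (length(unique(mature)) < 2) {
    stop("single class: both mature and immature fish are required")
  }

  a50_once <- function(a, m) {
    sep <- max(a[m == 0]) < min(a[m == 1])
    if (sep) {
      return(list(a50 = (max(a[m == 0]) + min(a[m == 1])) / 2,
                  beta0 = NA_real_, beta1 = NA_real_, sep = TRUE, fit = NULL))
    }
    fit <- suppressWarnings(glm(m ~ a, family = binomial("logit")))
    b <- coef(fit)
    list(a50 = -b[[1]] / b[[2]], beta0 = b[[1]], beta1 = b[[2]],
         sep = FALSE, fit = fit)
  }
  point <- a50_once(age, mature)
  if (point$sep) {
    warning("complete separation: A50 reported as the separating-gap midpoint")
  }

  set.seed(seed)
  boot <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(mature[idx])) < 2) next
    boot[b] <- a50_once(age[idx], mature[idx])$a50
  }
  boot <- boot[!is.na(boot)]
  structure(list(
    beta0 = point$beta0, beta1 = point$beta1, a50 = point$a50,
    ci = quantile(boot, c(0.025, 0.975), names = FALSE),
    separation = point$sep, n = n, B = B, seed = seed,
    boot = boot, fit = point$fit
  ), class = "maturity_ogive")
}

#' @export
print.maturity_ogive <- function(x, ...) {
  cat("Logistic maturity ogive (n =", x$n, ")\n")
  cat(sprintf("A50 = %.2f years (95%% CI %.2f-%.2f, B = %d)\n",
              x$a50, x$ci[1], x$ci[2], x$B))
  if (x$separation) cat("note: complete separation; A50 from gap midpoint\n")
  invisible(x)
}

#' Natural mortality from maximum age
#'
#' Longevity-based estimator `M = 4.899 * t_max^(-0.916)` (1/year).
#'
#' @param t_max lifespan in years (> 0).
#' @return natural mortality rate (1/year).
#' @export
#' @examples
#' mortality_from_tmax(22.41)  # ~0.28
mortality_from_tmax <- function(t_max) {
  if (any(t_max <= 0)) stop("t_max must be positive")
  4.899 * t_max^(-0.916)
}

#' Natural mortality at age from growth parameters
#'
#' Length-at-age based estimator
#' `ln M = 0.55 - 1.61 ln(FL) + 1.44 ln(L_inf) + ln(K)`, with FL the
#' VBGM-predicted fork length at the given age. Strictly decreasing in age:
#' predation pressure relaxes as fish outgrow their predators.
#'
#' @param age age in years (vectorised).
#' @param linf,k,t0 VBGM parameters (or pass a `vbgm_fit` as `fit`).
#' @param fit optional `vbgm_fit`; overrides `linf`, `k`, `t0`.
#' @return natural mortality rate (1/year) per age.
#' @export
mortality_at_age <- function(age, linf, k, t0, fit = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "vbgm_fit"))
    linf <- fit$coef[["linf"]]; k <- fit$coef[["k"]]; t0 <- fit$coef[["t0"]]
  }
  fl <- vbgm_predict(linf, k, t0, age)
  if (any(fl <= 0)) {
    stop("non-positive predicted length at age ",
         paste(age[fl <= 0], collapse = ", "))
  }
  exp(0.55 - 1.61 * log(fl) + 1.44 * log(linf) + log(k))
}
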