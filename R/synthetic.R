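# Synthetic population generator: produces linked individual-level tables
# (fish records, otolith readings, shape variables) with the statistical
# structure the analysis pipeline assumes, so every stage can be exercised
# and tested without raw survey data. Defaults emulate the yellowtail
# snapper populations of the three Yucatan fishing sites: site-specific
# growth truth and age structure, logistic maturity by age, annulus radii
# from a saturating radius-at-age map with the edge increment tied to the
# deposition season, and allometrically scaled shape variables with site
# effects on the size-independent ones.

.default_shape_model <- function() {
  # typical value at FL = 28 cm, allometric exponent b, per-site multipliers
  # (Celestun, DzilamDeBravo, RioLagartos), and lognormal noise CV.
  # role: removed = correlates with both site and size; corrected = size
  # only; kept = size-free (some carry the site signal that PCoA recovers).
  def <- function(v28, b, mult = c(1, 1, 1), cv = 0.10, role = "kept") {
    list(a = v28 / 28^b, b = b, mult = mult, cv = cv, role = role)
  }
  list(
    A    = def(20, 1.4235, role = "corrected"),
    MaxD = def(7, 0.1767, role = "corrected"),
    MinD = def(4, 0.60, mult = c(1, 1.06, 1.10), role = "removed"),
    P    = def(18, 0.5842, role = "corrected"),
    Rl   = def(1.5, 0, mult = c(1, 1.10, 1.12)),
    Rw   = def(0.8, 0.55, mult = c(1, 1.07, 1.12), role = "removed"),
    Al   = def(1.0, 0),
    Aw   = def(0.6, 0),
    EA   = def(0.9, 0.80, mult = c(1, 1.08, 1.14), role = "removed"),
    RE   = def(0.62, 0, mult = c(1, 1.04, 0.97), cv = 0.04),
    R    = def(1.35, 0.0102, cv = 0.04, role = "corrected"),
    E    = def(17, 0.4316, role = "corrected"),
    Fi   = def(1.9, 0.0008, cv = 0.02, role = "corrected"),
    As   = def(1.6, 0, mult = c(1, 0.96, 1.05), cv = 0.05),
    RAs  = def(0.55, 0, cv = 0.08),
    AAs  = def(0.60, 0.35, mult = c(1, 1.05, 1.09), cv = 0.08,
               role = "removed"),
    SAl  = def(5.5, 0.50, mult = c(1, 1.06, 1.09), role = "removed"),
    SAA  = def(6.0, 0, mult = c(1, 1.12, 1.16)),
    Osl  = def(2.6, 0.0708, role = "corrected"),
    OsA  = def(2.4, 0.70, mult = c(1, 1.08, 1.12), role = "removed"),
    Cl   = def(3.0, 0.55, mult = c(1, 1.06, 1.10), role = "removed"),
    CA   = def(3.2, 0, mult = c(1, 1.10, 1.15)),
    OsA_SAA_pct = list(base = 38, b = 0, mult = c(1, 1, 1), sd_logit = 0.15,
                       role = "kept", percent = TRUE),
    Osl_SAl_pct = list(base = 52, b = 0.25, mult = c(1, 1.05, 1.08),
                       sd_logit = 0.15, role = "removed", percent = TRUE)
  )
}

#' Configuration for the synthetic population generator
#'
#' Bundles every parameter the generator draws from. Site defaults follow
#' the published growth truth and age composition of the three Yucatan
#' fishing sites; the remaining rates are realistic values for an otolith
#' ageing study of a demersal snapper.
#'
#' @param n_per_site named integer vector, fish collected per site.
#' @param n_shape_per_site named integer vector, otoliths entering the
#'   shape analysis per site.
#' @param length_sd additive Gaussian SD of length about the growth curve
#'   (cm).
#' @param maturity list with per-sex logit-scale `c(beta0, beta1)`; the
#'   defaults put A50 at 1.3 years for females and 0.8 for males.
#' @param birthdate theoretical birthdate, `"MM-DD"`.
#' @param p_broken,p_illegible probabilities that an otolith is broken in
#'   processing / illegible.
#' @param p_read_error per-reader probability of a miscount (+-1 annulus);
#'   `p_auto_error` likewise for the automatic count.
#' @param p_reread_agree probability that an initial reader disagreement is
#'   resolved by the consensus re-read.
#' @param radius `c(rmax, rk, rt0)` of the saturating otolith radius-at-age
#'   map (mm).
#' @param shape_model per-variable allometric model; see the package source
#'   for the structure. Defaults cover the 24 standard variables.
#' @param seed integer seed; the generator is deterministic given the
#'   config.
#' @return a list of class `population_config`.
#' @export
population_config <- function(
    n_per_site = c(Celestun = 528, DzilamDeBravo = 449, RioLagartos = 472),
    n_shape_per_site = c(Celestun = 179, DzilamDeBravo = 158,
                         RioLagartos = 159),
    length_sd = 1.5,
    maturity = list(female = c(beta0 = -5.2, beta1 = 4.0),
                    male = c(beta0 = -3.6, beta1 = 4.5)),
    birthdate = "05-01",
    p_broken = 0.059, p_illegible = 0.15,
    p_read_error = 0.08, p_auto_error = 0.10, p_reread_agree = 0.7,
    radius = c(rmax = 4.5, rk = 0.25, rt0 = -2),
    shape_model = .default_shape_model(),
    seed = 1) {
  sites <- list(
    Celestun = list(
      vbgm = c(linf = 41.59, k = 0.11, t0 = -4.86),
      age_weights = c(9, 13, 213, 76, 17, 4, 3, 1, 0, 2, 0, 0, 0),
      deposition = 2:3),
    DzilamDeBravo = list(
      vbgm = c(linf = 38.36, k = 0.16, t0 = -3.25),
      age_weights = c(0, 1, 53, 82, 46, 70, 47, 23, 10, 33, 10, 11, 5),
      deposition = 7:9),
    RioLagartos = list(
      vbgm = c(linf = 40.28, k = 0.12, t0 = -4.99),
      age_weights = c(0, 0, 65, 125, 51, 60, 28, 13, 6, 20, 11, 14, 2),
      deposition = 7:9)
  )
  for (s in names(sites)) {
    w <- sites[[s]]$age_weights
    if (all(w == 0)) stop("config error: zero-weight age distribution for ", s)
    sites[[s]]$age_weights <- w / sum(w)
  }
  if (any(n_per_site <= 0)) stop("config error: non-positive sample size")
  structure(list(
    sites = sites, n_per_site = n_per_site,
    n_shape_per_site = n_shape_per_site, length_sd = length_sd,
    maturity = maturity, birthdate = birthdate,
    p_broken = p_broken, p_illegible = p_illegible,
    p_read_error = p_read_error, p_auto_error = p_auto_error,
    p_reread_agree = p_reread_agree,
    radius = radius, shape_model = shape_model, seed = seed
  ), class = "population_config")
}

.radius_at_age <- function(age, radius) {
  radius[["rmax"]] * (1 - exp(-radius[["rk"]] * (age - radius[["rt0"]])))
}

#' Generate a synthetic linked population
#'
#' Draws, per site: ages from the configured age distribution; uniform
#' capture dates over a two-year window and fractional ages relative to the
#' theoretical birthdate; lengths from the site growth curve plus Gaussian
#' noise (truncated positive); maturity from the per-sex logistic ogive;
#' annulus radii from the monotone radius-at-age map, with the edge
#' increment proportional to the fraction of the ring-year elapsed since
#' the deposition window so the marginal-increment minimum falls inside
#' that window; reader counts with independent miscount errors and a
#' consensus/rejection protocol; and shape variables scaled allometrically
#' with site multipliers and multiplicative lognormal noise (percentage
#' indices via a logistic-normal model).
#'
#' @param config a [population_config()].
#' @return list of class `synthetic_population` with tibbles `fish`
#'   (includes the generating truth `age_true`), `readings` and `shape`.
#'   Deterministic given `config$seed`.
#' @export
generate_population <- function(config = population_config()) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  start_date <- as.Date("2008-01-01")
  n_days <- as.integer(as.Date("2009-12-31") - start_date)

  fish_rows <- list(); read_rows <- list()
  fid0 <- 0
  for (s in names(config$sites)) {
    site_cfg <- config$sites[[s]]
    n <- config$n_per_site[[s]]
    ids <- sprintf("F%05d", fid0 + seq_len(n)); fid0 <- fid0 + n
    annuli <- sample(0:12, n, replace = TRUE, prob = site_cfg$age_weights)
    capture <- start_date + sample.int(n_days + 1, n, replace = TRUE) - 1
    month <- as.integer(format(capture, "%m"))

    # fraction of a year since the most recent birthdate anniversary
    yr <- as.integer(format(capture, "%Y"))
    anniv <- as.Date(paste0(yr, "-", config$birthdate))
    shift <- capture < anniv
    anniv[shift] <- as.Date(paste0(yr - 1, "-", config$birthdate))[shift]
    age <- annuli + as.numeric(capture - anniv) / 365.25

    p <- site_cfg$vbgm
    fl <- vbgm_predict(p[["linf"]], p[["k"]], p[["t0"]], age) +
      rnorm(n, 0, config$length_sd)
    fl <- pmax(fl, 5)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    mat_p <- vapply(seq_len(n), function(i) {
      cf <- config$maturity[[sex[i]]]
      plogis(cf[["beta0"]] + cf[["beta1"]] * age[i])
    }, numeric(1))
    mature <- rbinom(n, 1, mat_p) == 1

    tl <- fl * runif(n, 1.04, 1.10)
    sl <- fl * runif(n, 0.85, 0.92)
    ww <- 0.020 * fl^3 * rlnorm(n, 0, 0.08)
    gw <- ww * runif(n, 0.88, 0.95)
    ow <- 6e-5 * fl^2.2 * rlnorm(n, 0, 0.15)

    fish_rows[[s]] <- tibble(
      fish_id = ids, site = s, sex = sex,
      maturity = ifelse(mature, "mature", "immature"),
      capture_date = capture, fl_cm = fl, tl_cm = tl, sl_cm = sl,
      ww_g = ww, gw_g = gw, ow_g = ow,
      annuli = annuli, age_true = age
    )

    # ring-year fraction since the start of the deposition window
    m_start <- min(site_cfg$deposition)
    gfrac <- (((month - m_start) %% 12) + runif(n)) / 12
    r_last <- ifelse(annuli >= 1, .radius_at_age(annuli, config$radius), NA)
    r_pen <- ifelse(annuli >= 2, .radius_at_age(annuli - 1, config$radius), NA)
    spacing <- ifelse(annuli >= 2, r_last - r_pen, NA)
    R <- ifelse(annuli >= 2, r_last + gfrac * spacing,
                .radius_at_age(pmax(age, 0.2), config$radius))
    # every window-month capture carries a freshly deposited ring in this
    # construction, so its opaque zone is at the edge; shortly after the
    # window the zone is still visible
    edge_opaque <- month %in% site_cfg$deposition | gfrac < 0.25

    r1 <- annuli + sample(c(-1, 1), n, TRUE) * rbinom(n, 1, config$p_read_error)
    r2 <- annuli + sample(c(-1, 1), n, TRUE) * rbinom(n, 1, config$p_read_error)
    r1 <- pmax(r1, 0); r2 <- pmax(r2, 0)
    auto <- pmax(annuli + sample(c(-1, 1), n, TRUE) *
                   rbinom(n, 1, config$p_auto_error), 0)
    agree <- r1 == r2
    resolved <- agree | (rbinom(n, 1, config$p_reread_agree) == 1)
    consensus <- ifelse(resolved, annuli, NA_integer_)
    broken <- rbinom(n, 1, config$p_broken) == 1
    illegible <- rbinom(n, 1, config$p_illegible) == 1
    unreadable <- (!resolved | illegible) & !broken

    read_rows[[s]] <- tibble(
      fish_id = ids, site = s, month = month,
      reader1 = r1, reader2 = r2, auto = auto,
      consensus_annuli = consensus,
      otolith_radius_mm = R, last_annulus_mm = r_last,
      penultimate_annulus_mm = r_pen,
      edge_opaque = edge_opaque,
      broken = broken, unreadable = unreadable
    )
  }
  fish <- dplyr::bind_rows(fish_rows)
  readings <- dplyr::bind_rows(read_rows)

  # shape subsample: intact otoliths only
  shape_rows <- list()
  site_index <- setNames(seq_along(config$sites), names(config$sites))
  for (s in names(config$sites)) {
    pool <- which(fish$site == s & !readings$broken)
    n_s <- min(config$n_shape_per_site[[s]], length(pool))
    take <- sample(pool, n_s)
    fl <- fish$fl_cm[take]
    vars <- lapply(names(config$shape_model), function(v) {
      mdl <- config$shape_model[[v]]
      mult <- mdl$mult[site_index[[s]]]
      if (isTRUE(mdl$percent)) {
        eta <- qlogis(mdl$base / 100) + mdl$b * log(fl / 28) + log(mult) +
          rnorm(n_s, 0, mdl$sd_logit)
        100 * plogis(eta)
      } else {
        sdlog <- sqrt(log(1 + mdl$cv^2))
        mdl$a * fl^mdl$b * mult * rlnorm(n_s, 0, sdlog)
      }
    })
    names(vars) <- names(config$shape_model)
    shape_rows[[s]] <- tibble(fish_id = fish$fish_id[take], site = s,
                              fl_cm = fl, !!!vars)
  }
  structure(list(fish = fish, readings = readings,
                 shape = dplyr::bind_rows(shape_rows),
                 config = config),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat("Synthetic population:", nrow(x$fish), "fish,",
      nrow(x$shape), "shape otoliths, seed", x$config$seed, "\n")
  print(table(x$fish$site))
  invisible(x)
}

#' Expand an age-length key into individual records
#'
#' Each cell count becomes that many records with fork length at the bin
#' midpoint and age equal to the column age class — the standard device for
#' refitting a growth curve from a published key when the raw measurements
#' are unavailable.
#'
#' @param key tibble as returned by [snapper_age_length_key()] (columns
#'   `ll`, `ul`, `age`, `n`).
#' @return tibble with one row per fish: `age` (years), `fl_cm` (bin
#'   midpoint).
#' @export
#' @examples
#' nrow(expand_age_length_key(snapper_age_length_key("all")))  # 1124
expand_age_length_key <- function(key) {
  stopifnot(all(c("ll", "ul", "age", "n") %in% names(key)),
            all(key$n >= 0), all(key$n == round(key$n)))
  key <- key[key$n > 0, , drop = FALSE]
  tibble(
    age = rep(key$age, key$n),
    fl_cm = rep((key$ll + key$ul) / 2, key$n)
  )
}
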