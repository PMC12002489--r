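# End-to-end orchestration with flat-file (CSV) handoff between stages and
# a JSON run manifest, so any stage is independently re-runnable and every
# output is a pure function of (inputs, config, seed).

#' Run the full analysis pipeline on a synthetic population
#'
#' Stages: `simulate` (generate and write the population tables), `age`
#' (QC filter, precision statistics, marginal-increment series, fractional
#' ages), `growth` (VBGM per site and pooled, with the hierarchical
#' growth-curve comparison), `maturity` (per-sex ogives), `mortality`
#' (both estimators on an age ladder), `shape` (allometric correction,
#' PCoA, variable selection, PERMANOVA, betadisper) and `report` (derived
#' life-history table). Stage outputs are CSVs under `out_dir`; a JSON
#' manifest records the seed, stage timings and a digest of every file
#' written.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [population_config()]; its seed drives every stage.
#' @param stages character vector of stages to run (in the canonical
#'   order); `"all"` runs everything.
#' @param n_perm permutations for the PERMANOVA stage.
#' @param boot_B bootstrap replicates for maturity and growth CIs.
#' @return list with the in-memory stage results and the `manifest`.
#' @export
run_pipeline <- function(out_dir, config = population_config(),
                         stages = "all", n_perm = 999, boot_B = 199) {
  all_stages <- c("simulate", "age", "growth", "maturity", "mortality",
                  "shape", "report")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  results <- list()
  timings <- list()
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  need <- function(stage) {
    if (is.null(results[[stage]])) {
      stop("stage dependency missing: run '", stage, "' first")
    }
    results[[stage]]
  }
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    results[[stage]] <<- expr
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  if ("simulate" %in% stages) tick("simulate", {
    pop <- generate_population(config)
    emit(pop$fish, "fish")
    emit(pop$readings, "readings")
    emit(pop$shape, "shape")
    pop
  })

  if ("age" %in% stages) tick("age", {
    pop <- need("simulate")
    qc <- qc_filter(pop$readings)
    emit(qc$report, "qc_report")
    kept <- qc$retained
    prec <- precision_report(cbind(kept$reader1, kept$reader2),
                             auto_counts = kept$auto,
                             consensus = kept$consensus_annuli)
    emit(prec, "precision")
    two_plus <- kept[!is.na(kept$penultimate_annulus_mm), , drop = FALSE]
    two_plus$mia <- marginal_increment(two_plus$otolith_radius_mm,
                                       two_plus$last_annulus_mm,
                                       two_plus$penultimate_annulus_mm)
    two_plus$increment_mm <- two_plus$otolith_radius_mm - two_plus$last_annulus_mm
    two_plus$annuli <- two_plus$consensus_annuli
    mia <- mia_series(two_plus[!is.na(two_plus$annuli), ], group_by = "site")
    emit(mia$series, "mia_series")
    emit(mia$deposition, "mia_deposition")
    aged <- pop$fish[match(kept$fish_id, pop$fish$fish_id), ]
    aged <- aged[!is.na(kept$consensus_annuli), ]
    kept_ok <- kept[!is.na(kept$consensus_annuli), ]
    # deposition windows differ by site; use each site's own window
    aged$fractional_age <- NA_real_
    for (s in names(config$sites)) {
      i <- kept_ok$site == s
      aged$fractional_age[i] <- fractional_age(
        kept_ok$consensus_annuli[i], aged$capture_date[i],
        edge_opaque = kept_ok$edge_opaque[i], birthdate = config$birthdate,
        deposition_window = config$sites[[s]]$deposition)
    }
    emit(aged[, c("fish_id", "site", "sex", "maturity", "fl_cm",
                  "fractional_age")], "aged_fish")
    list(qc = qc, precision = prec, mia = mia, aged = aged)
  })

  if ("growth" %in% stages) tick("growth", {
    aged <- need("age")$aged
    fits <- lapply(split(aged, aged$site), function(d)
      fit_vbgm(d$fractional_age, d$fl_cm))
    fits$all <- fit_vbgm(aged$fractional_age, aged$fl_cm)
    params <- dplyr::bind_rows(lapply(names(fits), function(g) {
      f <- fits[[g]]
      tibble(group = g, linf = f$coef[["linf"]], k = f$coef[["k"]],
             t0 = f$coef[["t0"]], n = f$n, rss = f$rss, logLik = f$logLik)
    }))
    emit(params, "growth_params")
    lattice <- compare_growth(aged$fractional_age, aged$fl_cm, aged$site)
    emit(lattice$models, "growth_models")
    emit(lattice$comparisons, "growth_comparisons")
    list(fits = fits, params = params, lattice = lattice)
  })

  if ("maturity" %in% stages) tick("maturity", {
    aged <- need("age")$aged
    ogives <- lapply(split(aged, aged$sex), function(d) {
      if (length(unique(d$maturity)) < 2) return(NULL)
      fit_maturity(d$fractional_age, d$maturity == "mature",
                   B = boot_B, seed = seed)
    })
    ogives <- Filter(Negate(is.null), ogives)
    tab <- dplyr::bind_rows(lapply(names(ogives), function(s) {
      o <- ogives[[s]]
      tibble(sex = s, a50 = o$a50, ci_lo = o$ci[1], ci_hi = o$ci[2],
             beta0 = o$beta0, beta1 = o$beta1, n = o$n)
    }))
    emit(tab, "maturity")
    list(ogives = ogives, table = tab)
  })

  if ("mortality" %in% stages) tick("mortality", {
    growth <- need("growth")
    ladder <- dplyr::bind_rows(lapply(names(growth$fits), function(g) {
      f <- growth$fits[[g]]
      tmax <- lifespan(f$coef[["k"]], f$coef[["t0"]])
      ages <- seq(1, max(2, floor(tmax)))
      tibble(group = g, age = ages,
             m_at_age = mortality_at_age(ages, fit = f),
             t_max = tmax, m_tmax = mortality_from_tmax(tmax))
    }))
    emit(ladder, "mortality")
    ladder
  })

  if ("shape" %in% stages) tick("shape", {
    pop <- need("simulate")
    sh <- pop$shape
    vars <- sh[, setdiff(names(sh), c("fish_id", "site", "fl_cm"))]
    cc <- classify_and_correct(vars, sh$fl_cm, sh$site)
    emit(cc$decisions, "shape_decisions")
    scaled <- normalize_shape(cc$corrected)
    ord <- shape_pcoa(scaled)
    emit(ord$contributions, "shape_contributions")
    sel <- select_variables(ord)
    scaled_sel <- scaled[, sel, drop = FALSE]
    ord_sel <- shape_pcoa(scaled_sel)
    set.seed(seed)
    perm <- shape_permanova(scaled_sel, sh$site, n_perm = n_perm, seed = seed)
    emit(perm, "permanova")
    disp <- shape_betadisper(scaled_sel, sh$site)
    emit(disp$summary, "betadisper")
    list(decisions = cc$decisions, ordination = ord,
         ordination_selected = ord_sel, selected = sel,
         permanova = perm, dispersion = disp)
  })

  if ("report" %in% stages) tick("report", {
    growth <- need("growth")
    report <- dplyr::bind_rows(lapply(names(growth$fits), function(g) {
      f <- growth$fits[[g]]
      tmax <- lifespan(f$coef[["k"]], f$coef[["t0"]])
      tibble(group = g,
             linf = f$coef[["linf"]], k = f$coef[["k"]], t0 = f$coef[["t0"]],
             phi_prime = growth_performance(f$coef[["k"]], f$coef[["linf"]]),
             t_max = tmax, m_tmax = mortality_from_tmax(tmax))
    }))
    emit(report, "life_history")
    report
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("otostock")),
    seed = seed,
    stages = stages,
    timings_s = timings,
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  list(results = results, manifest = manifest,
       manifest_path = manifest_path)
}
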