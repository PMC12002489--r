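# otostock

Age-based life history and otolith shape analysis for describing the
population structure of exploited fish — built around the yellowtail
snapper (*Ocyurus chrysurus*) fishery of the Yucatán shelf, southern Gulf
of México, and usable for any otolith ageing / otolith morphometry study
with the same design.

The package is aimed at fisheries scientists who have (or can simulate)
individual-level records — fork length, capture date, otolith annuli
counts and radial measurements, maturity state, and otolith morphometric
variables — and want the full chain from raw readings to stock-structure
conclusions as reproducible, tested code.

## What it computes

**Ageing.** Marginal increment analysis validates annual ring deposition:
`MIA = (R - r_i) / (r_i - r_{i-1})` with `R` the otolith radius and `r_i`,
`r_{i-1}` the last and penultimate annulus radii; the calendar month with
the minimum mean MIA per group marks the deposition window. Reading
precision uses the Beamish–Fournier average percent error and the Chang
coefficient of variation. Fractional ("biological") age adds to the annuli
count the fraction of a year since the theoretical birthdate (May 1 by
default), with one year added for fish captured in the deposition window
whose otolith edge lacks an opaque zone.

**Growth.** Von Bertalanffy growth model
`L(t) = L∞ (1 − e^{−K (t − t0)})` fitted by nonlinear least squares with
multi-start Levenberg–Marquardt, percentile bootstrap CIs, and the
hierarchical likelihood-ratio framework that compares up to eight nested
growth curves over a grouping factor (all parameters shared → all
group-specific), `X² = 2 (logL_full − logL_reduced)`.

**Derived life history.** Growth performance `φ′ = log10 K + 2 log10 L∞`;
lifespan `t_max = 3/K + t0`; natural mortality both from longevity,
`M = 4.899 t_max^{−0.916}`, and from length at age,
`ln M = 0.55 − 1.61 ln FL + 1.44 ln L∞ + ln K`; age at 50% maturity from a
binomial-logit GLM with a 999-replicate bootstrap CI.

**Otolith shape.** ANCOVA-based allometric screening (variables
confounding site and size are removed; size-only variables corrected by
`V · (FL_ref / FL)^b` with the common within-group log–log slope `b`),
normalisation, principal coordinates analysis on the Euclidean matrix,
selection of variables contributing ≥ 80% to either of the first two axes,
PERMANOVA (overall and one-vs-rest per level), and betadisper centroid
dispersion.

**Synthetic data.** `generate_population()` draws a linked, deterministic
population (fish records, otolith readings, shape table) whose truth
follows the published site-specific growth, age structure, maturity and
deposition windows, so the whole pipeline is testable without the raw
survey data. Published age–length keys and growth parameters ship as
in-package reference tables.

## Worked example

```r
library(otostock)

# refit growth from the bundled all-fish age-length key (bin midpoints)
rec <- expand_age_length_key(snapper_age_length_key("all"))
fit <- fit_vbgm(rec$age, rec$fl_cm)
print(fit)
#> von Bertalanffy growth fit (n = 1124 )
#>             linf      k      t0
#> estimate 38.3895 0.1648 -3.6228
#> se        0.5202 0.0088  0.1935
#> RSS: 2204.14  logLik: -1973.36
```

The binned refit lands within ~1% of the published L∞ of 38.85 cm and
within the binning error of K = 0.15 yr⁻¹. Derived life history from the
bundled site parameters:

```r
gp <- snapper_growth_params()
site <- gp[gp$group == "Celestun", ]
tmax <- lifespan(site$k, site$t0)
cat("Celestun: t_max =", round(tmax, 2), "years;",
    "M =", round(mortality_from_tmax(tmax), 2), "1/yr\n")
#> Celestun: t_max = 22.41 years; M = 0.28 1/yr
```

`t_max = 22.41` years says Celestún fish need ~22 years to approach 95% of
their asymptotic length at their slow local growth rate (K = 0.11 yr⁻¹),
and the longevity-based natural mortality is 0.28 yr⁻¹. The full pipeline
on a synthetic survey:

```r
pop <- generate_population(population_config(seed = 42))
print(pop)
#> Synthetic population: 1449 fish, 496 shape otoliths, seed 42
#>
#>      Celestun DzilamDeBravo   RioLagartos
#>           528           449           472

res <- run_pipeline("out", population_config(seed = 42))
res$results$report          # phi', t_max, M per site and pooled
res$results$shape$permanova # site discrimination from otolith shape
```

## Vignette

`vignettes/stock-structure-methods.Rmd` documents the models, their
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, and the numerical
choices (starts, tolerances, tie-breaks, degenerate-input handling).
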