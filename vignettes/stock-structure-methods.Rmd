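---
title: "Methods: age-based life history and otolith shape for stock structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-based life history and otolith shape for stock structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otostock)
```

# The problem

Exploited fish populations that look homogeneous in landings statistics
can hide site-level structure: different growth rates, lifespans, natural
mortality and otolith morphology across fishing grounds. otostock
implements the standard analysis chain for detecting such structure from
otolith data — ageing, growth modelling, derived demography, and
multivariate otolith-shape discrimination — as a tested pipeline. The
reference system is the yellowtail snapper fishery at three Yucatán ports
(Celestún, Dzilam de Bravo, Río Lagartos).

# Ageing

**Marginal increment.** `marginal_increment()` returns the dimensionless
ratio (R − r_i)/(r_i − r_{i−1}). The ratio is scale-invariant, so it is
comparable across otoliths of different absolute size; its seasonal
minimum marks the annulus-deposition window. Because workers sometimes
plot the *absolute* edge increment R − r_i (mm) instead, `mia_series()`
summarises both when the absolute increment column is supplied, and labels
them distinctly rather than guessing which one a given figure shows.

**Precision.** `ape_cv()` implements the Beamish–Fournier average percent
error and the Chang coefficient of variation, averaged over fish. Both are
zero exactly when all readers agree everywhere; fish with a zero mean read
are excluded and counted, since the relative error is undefined there. The
automatic (image-analysis) count is treated as an ordinary extra reader
for the global statistics; its dedicated APE is computed pairwise against
the consensus age.

**Fractional age.** `fractional_age()` adds to the annuli count the
fraction of a year elapsed since the most recent birthdate anniversary
(default May 1, the spawning-season midpoint). The year length is fixed at
365.25 days — the analysis does not need calendar precision beyond that,
and it avoids leap-year branches. The edge rule adds one year for fish
captured inside the deposition window whose otolith edge lacks an opaque
zone, anticipating the imminent ring. The window defaults to July–September
but is an argument, because deposition timing varies by site (February–
March at Celestún); `run_pipeline()` passes each site its own window.

**Reader reconciliation.** Exact agreement is accepted; one re-read pass
may resolve a disagreement; persistent disagreement rejects the otolith.
This is the policy the QC bookkeeping (`qc_filter()`) expects upstream:
counts always satisfy retained = collected − broken − unreadable/discordant.

# Growth

The von Bertalanffy model L(t) = L∞(1 − e^{−K(t−t0)}) is fitted by least
squares under additive Gaussian length error with constant variance — the
assumption implicit in unweighted nonlinear least squares. Ages entering
the fit are fractional ages, not raw annuli counts. Fitting uses
Levenberg–Marquardt with starts L∞ = 1.1·max(L), K = 0.2, t0 = −1, and up
to five jittered restarts before declaring failure: the RSS surface is
flat along the L∞–K ridge, and restarts rescue occasional stalls on
resampled data. The log-likelihood is the Gaussian form with the error
variance profiled out, logL = −(n/2)(ln 2π + ln(RSS/n) + 1).

**Group comparison.** `compare_growth()` fits the full lattice of nested
models over a grouping factor: all three parameters group-specific (m = 3g
mean parameters), the three two-parameter and three one-parameter
intermediates, and the coincident curve (m = 3). Likelihood-ratio tests
use X² = 2·ΔlogL, df = Δm, which equals n·ln(RSS_red/RSS_full) under the
profiled likelihood; both forms are available for cross-checking. The
selection walk starts at the full model and prefers any non-rejected
reduction (α = 0.05) as more parsimonious, breaking ties among equally
parsimonious candidates by the highest log-likelihood, and recursing until
every further reduction is rejected; an intermediate selection is finally
confirmed against the coincident curve. All comparison rows are reported,
not just the path taken, so the full table can be inspected when the
walk's intermediate p-values are close to α.

**Bootstrap.** `bootstrap_vbgm()` resamples fish (age–length pairs)
jointly, refits, and reports percentile 2.5/97.5 intervals. Non-converged
replicates are dropped and counted; more than 20% failures raises a
warning (an error in strict mode). Fixed seeds reproduce intervals
bit-identically.

**Derived quantities.** φ′ = log10 K + 2 log10 L∞ (base-10 logs) and
t_max = 3/K + t0 are exact closed forms of the fitted parameters.
Parameters are reported unrounded internally; printed reports round to
2 dp (parameters, t_max, M) and 1 dp (φ′), the conventional presentation.

# Demography

**Maturity.** `fit_maturity()` is a binomial-logit GLM of maturity on age;
A50 = −β0/β1. The 95% CI is a percentile bootstrap over individuals
(default B = 999). Complete separation — all immature fish younger than
all mature fish — leaves the MLE unbounded; the fit is then flagged and
A50 is taken as the midpoint of the separating gap, which is the only
age-location information the data carry in that case. Per-site ogives are
only meaningful where both classes occur at the site; early-maturing
populations can have sites with no immature fish at all.

**Natural mortality.** Two estimators are provided and deliberately not
reconciled: the longevity form M = 4.899·t_max^{−0.916}, and the
length-at-age form ln M = 0.55 − 1.61 ln FL + 1.44 ln L∞ + ln K with FL
the VBGM prediction at the requested age. They answer different questions
(a single population-level rate vs an age schedule) and need not agree
numerically; reports show each as computed from the fitted parameters.

# Otolith shape

**Allometric screening.** Each variable is tested on the log–log ANCOVA
log V ~ log FL × group with sequential sums of squares. A significant
slope-by-group interaction, or a significant group effect alongside a
significant size effect, removes the variable: its site signal cannot be
separated from size structure among sites. A significant size slope alone
triggers the multiplicative correction V·(FL_ref/FL)^b, with b the common
within-group slope from log V ~ log FL + group and FL_ref the grand mean
fork length of the shape sample — the standard allometric normalisation;
the choice of FL_ref only rescales variables uniformly and cannot affect
downstream group tests. Everything else is kept unchanged. Percentage
indices are arcsine-square-root transformed (arcsin √(p/100)) first and
handled on that scale throughout. Note a consequence of sequential SS:
a size-independent variable whose site shifts happen to align with the
sites' size ordering shows a marginal size correlation and is removed —
conservative, and consistent with treating size–site confounding as
non-attributable.

**Ordination.** `normalize_shape()` scales to zero mean/unit SD and
reports (never auto-drops) collinear pairs at |r| ≥ 0.9. `shape_pcoa()`
performs PCoA on the Euclidean distance matrix; on such input it coincides
with PCA of the scaled data, which the tests exploit as an independent
oracle. Negative eigenvalues are clipped at zero with a warning. The
"contribution" of a variable to an axis is operationalised as 100·r²
between the variable and the axis scores, and `select_variables()` keeps
variables reaching 80% on either of the first two axes (an empty selection
falls back to all variables with a warning). Two-axis variance is
reported both before and after selection, since the two are legitimately
different summaries.

**Tests.** `shape_permanova()` reports the overall factor test plus one
row per level tested one-vs-rest — a reading of the per-level table layout
common in this literature; the p-value convention includes the observed
statistic, p = (1 + #{F_perm ≥ F_obs})/(1 + n_perm), with 999 permutations
and a recorded seed by default. `shape_betadisper()` reports group
centroids and the mean member-to-centroid distance.

# The synthetic generator

`generate_population()` emulates the statistical structure the analysis
assumes: site-specific VBGM truth and age composition (taken from the
bundled reference tables), uniform capture dates over a two-year window,
additive Gaussian length noise (SD 1.5 cm — a typical residual scale for
length-at-age in snappers), per-sex logistic maturity (A50 = 1.3 yr
females, 0.8 yr males), annulus radii from a saturating radius-at-age map
with the edge increment proportional to the ring-year fraction elapsed
since the site's deposition window, two human readers plus an automatic
reader with independent miscount errors, QC flags at realistic rates
(5.9% broken, 15% illegible), and shape variables scaled allometrically
with site multipliers and ~10% lognormal noise (percentage indices via a
logistic-normal model). Everything is deterministic given the config seed.

What it does **not** emulate: gear selectivity and size-truncated
sampling, environmental covariates, between-variable correlation beyond
what shared FL induces (shape noise is independent per variable), otolith
weight–age coupling, and within-window deposition timing — in this
construction every window-month capture already carries its fresh ring,
so the ageing edge rule is exercised by direct unit tests rather than by
the simulated pipeline. Passing end-to-end tests on this generator
therefore demonstrates the estimators' correctness under the stated
model, not robustness to real-data pathologies.

# Numerical choices and test scales

Optimiser tolerance for the nesting-monotonicity invariant is 1e−6 logL
units. Simulation-based test sizes were chosen to give tight binomial
bands at modest runtime: 200 replicates of n = 500 for parameter-recovery
bias, 1000 null replicates (n = 300, three groups) for the LRT type-I
error, 200 outer replicates with B = 199 for bootstrap coverage, 400
replicates for PERMANOVA null uniformity, and n = 2000 for A50 recovery.
The bundled age–length keys expand at bin midpoints; the young-of-the-year
class is coded as age 0, the literal value of the key's age classes.

# Known limitations

Only the von Bertalanffy model is implemented (no Gompertz/Schnute
alternatives); growth error is additive Gaussian (no lognormal option);
the LRT relies on the chi-squared asymptotics, slightly anticonservative
below ~50 fish per group; and the shape workflow assumes the morphometric
variables are already extracted — image processing is out of scope.
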