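# Bundled reference tables for yellowtail snapper (Ocyurus chrysurus) from
# three artisanal fishing sites on the Yucatan shelf, southern Gulf of Mexico:
# published age-length keys (counts of aged fish per fork-length bin and age
# class) and von Bertalanffy parameter estimates by sex and site. These are
# in-package fixtures so derived life-history quantities and scaled-down
# refits can be computed without access to the raw survey data.

# 12 contiguous fork-length bins, 16.00-42.18 cm, width 2.18 cm (approx).
.alk_lower <- c(16.00, 18.18, 20.36, 22.55, 24.73, 26.91, 29.09, 31.27,
                33.45, 35.64, 37.82, 40.00)
.alk_upper <- c(18.18, 20.36, 22.55, 24.73, 26.91, 29.09, 31.27, 33.45,
                35.64, 37.82, 40.00, 42.18)
.alk_ages <- 0:12

.alk_counts <- list(
  females = rbind(
    c(4, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(2, 6, 3, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(1, 1, 50, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(1, 0, 96, 20, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 9, 76, 7, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 1, 34, 37, 25, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, 1, 1, 42, 45, 17, 0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 0, 1, 4, 5, 8, 29, 3, 0, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 3, 8, 4, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 9, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 3),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)),
  males = rbind(
    c(1, 1, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(1, 7, 8, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 49, 3, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 100, 26, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 11, 102, 6, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, 24, 58, 33, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 1, 33, 28, 6, 2, 1, 0, 0, 0),
    c(0, 0, 0, 0, 0, 1, 1, 9, 6, 21, 3, 0, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 6, 0, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 6, 1),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 3, 1),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1)),
  Celestun = rbind(
    c(7, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(2, 11, 16, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 70, 6, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 118, 33, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 9, 29, 3, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, 8, 13, 3, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 1, 1, 3, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 0, 0, 0, 1, 0, 2, 0, 0, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)),
  DzilamDeBravo = rbind(
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 20, 3, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 26, 10, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 7, 40, 2, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, 29, 39, 20, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 5, 46, 43, 10, 1, 0, 0, 0, 0),
    c(0, 0, 0, 0, 0, 4, 4, 13, 9, 31, 0, 0, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 2, 9, 2, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 6, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 2, 5),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0)),
  RioLagartos = rbind(
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 14, 4, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 45, 11, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 6, 92, 8, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, 18, 43, 29, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 0, 30, 26, 7, 1, 2, 0, 0, 0),
    c(0, 0, 0, 0, 0, 1, 2, 6, 5, 16, 5, 0, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 2, 6, 6, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 6, 1),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 2, 0),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1))
)

#' Reference age-length keys for yellowtail snapper
#'
#' Counts of aged fish per fork-length bin (cm) and age class (years), by sex
#' (`"females"`, `"males"`) or fishing site (`"Celestun"`, `"DzilamDeBravo"`,
#' `"RioLagartos"`). `"all"` returns the females + males key (the full aged
#' sample of 1,124 otoliths).
#'
#' @param group one of `"all"`, `"females"`, `"males"`, `"Celestun"`,
#'   `"DzilamDeBravo"`, `"RioLagartos"`.
#' @return a tibble with columns `ll`, `ul` (bin bounds, FL cm), `age`
#'   (years; the 0 class is young-of-the-year), `n` (count) and `group`.
#' @seealso [expand_age_length_key()] to turn a key into individual records.
#' @export
#' @examples
#' key <- snapper_age_length_key("Celestun")
#' sum(key$n)  # 338 aged fish
snapper_age_length_key <- function(group = c("all", "females", "males",
                                             "Celestun", "DzilamDeBravo",
                                             "RioLagartos")) {
  group <- match.arg(group)
  counts <- if (group == "all") {
    .alk_counts$females + .alk_counts$males
  } else {
    .alk_counts[[group]]
  }
  tibble(
    ll = rep(.alk_lower, times = length(.alk_ages)),
    ul = rep(.alk_upper, times = length(.alk_ages)),
    age = rep(.alk_ages, each = length(.alk_lower)),
    n = as.integer(counts[cbind(rep(seq_along(.alk_lower), length(.alk_ages)),
                                rep(seq_along(.alk_ages),
                                    each = length(.alk_lower)))]),
    group = group
  )
}

#' Reference von Bertalanffy growth parameters
#'
#' Published parameter estimates (fork length, cm) for yellowtail snapper in
#' the southern Gulf of Mexico, for pooled sexes, each sex, and each of the
#' three Yucatan fishing sites.
#'
#' @return a tibble with columns `group`, `linf` (cm), `k` (1/year), `t0`
#'   (year) and sample size `n`.
#' @export
snapper_growth_params <- function() {
  tibble(
    group = c("all", "females", "males",
              "Celestun", "DzilamDeBravo", "RioLagartos"),
    linf = c(38.85, 39.58, 38.14, 41.59, 38.36, 40.28),
    k = c(0.15, 0.14, 0.16, 0.11, 0.16, 0.12),
    t0 = c(-3.66, -3.97, -3.36, -4.86, -3.25, -4.99),
    n = c(1124L, 560L, 564L, 338L, 391L, 395L)
  )
}
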