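# Shared helpers for building small in-code fixtures.

# age-length sample from a known VBGM truth with Gaussian length noise
gen_vbgm_data <- function(n, linf = 38.85, k = 0.15, t0 = -3.66, sd = 1.5,
                          age_range = c(0.5, 12)) {
  age <- runif(n, age_range[1], age_range[2])
  len <- linf * (1 - exp(-k * (age - t0))) + rnorm(n, 0, sd)
  data.frame(age = age, len = len)
}

# independent profiled-variance Gaussian log-likelihood (closed form)
gauss_logl <- function(rss, n) -(n / 2) * (log(2 * pi) + log(rss / n) + 1)

# ten valid fish rows in the default file layout
fixture_fish_rows <- function() {
  data.frame(
    fish_id = sprintf("X%02d", 1:10),
    site = rep(c("Celestun", "DzilamDeBravo", "RioLagartos"), length.out = 10),
    sex = rep(c("female", "male"), 5),
    maturity = rep(c("mature", "immature"), 5),
    capture_date = as.character(as.Date("2008-03-01") + seq(0, 270, 30)),
    fl_cm = seq(18, 36, 2),
    tl_cm = seq(18, 36, 2) * 1.07,
    sl_cm = seq(18, 36, 2) * 0.9,
    ww_g = seq(100, 800, length.out = 10),
    gw_g = seq(90, 720, length.out = 10),
    ow_g = seq(0.05, 0.12, length.out = 10)
  )
}
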