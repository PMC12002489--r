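# Otolith ageing: marginal increment analysis, reader precision, and
# fractional (biological) age assignment.

#' Marginal increment ratio
#'
#' Edge growth since the last annulus scaled by the last complete
#' inter-annulus distance: `(R - r_i) / (r_i - r_im1)`. Dimensionless and
#' scale-invariant; 0 exactly when the last annulus lies on the otolith edge.
#'
#' @param R otolith radius, centre to edge (mm).
#' @param r_i radius of the last (outermost) annulus (mm).
#' @param r_im1 radius of the penultimate annulus (mm).
#' @return the marginal increment ratio (vectorised).
#' @export
#' @examples
#' marginal_increment(10, 9, 7)  # 0.5
marginal_increment <- function(R, r_i, r_im1) {
  if (any(r_i == r_im1, na.rm = TRUE)) {
    stop("degenerate annulus spacing: r_i == r_im1")
  }
  ok <- is.na(R) | is.na(r_i) | is.na(r_im1) |
    (r_im1 > 0 & r_im1 < r_i & r_i <= R)
  if (!all(ok)) stop("radius ordering violated: need 0 < r_im1 < r_i <= R")
  (R - r_i) / (r_i - r_im1)
}

#' Monthly marginal-increment series
#'
#' Tabulates the marginal increment by calendar month within groups (annuli
#' count or fishing site) and reports, per group, the month(s) attaining the
#' minimum mean — the inferred annulus-deposition window. Both the
#' dimensionless ratio (`mia`) and, when a `increment_mm` column is present,
#' the absolute edge increment R - r_i in mm are summarised; the two are
#' distinct quantities and are labelled as such.
#'
#' @param aged data frame with columns `mia`, `month` (1-12) and the
#'   grouping column; optionally `increment_mm`.
#' @param group_by name of the grouping column, `"annuli"` or `"site"` (any
#'   column present is accepted).
#' @return list with `series` (tibble: group, month, n, mean_mia, sd_mia and,
#'   if available, mean/sd of the absolute increment; cells with a single
#'   observation report `sd_mia = 0` and `sd_undefined = TRUE`) and
#'   `deposition` (tibble: group, minimum-mean month(s)).
#' @export
mia_series <- function(aged, group_by = "annuli") {
  stopifnot(group_by %in% names(aged), all(c("mia", "month") %in% names(aged)))
  aged <- aged[!is.na(aged$mia) & !is.na(aged$month), , drop = FALSE]
  if (!nrow(aged)) stop("no records with both mia and month")
  has_abs <- "increment_mm" %in% names(aged)

  key <- interaction(aged[[group_by]], aged$month, drop = TRUE)
  series <- do.call(rbind, lapply(split(aged, key), function(d) {
    out <- data.frame(
      group = d[[group_by]][1], month = d$month[1], n = nrow(d),
      mean_mia = mean(d$mia),
      sd_mia = if (nrow(d) > 1) sd(d$mia) else 0,
      sd_undefined = nrow(d) == 1
    )
    if (has_abs) {
      out$mean_increment_mm <- mean(d$increment_mm)
      out$sd_increment_mm <- if (nrow(d) > 1) sd(d$increment_mm) else 0
    }
    out
  }))
  series <- as_tibble(series[order(series$group, series$month), ])

  deposition <- do.call(rbind, lapply(split(series, series$group), function(s) {
    data.frame(group = s$group[1],
               month = s$month[s$mean_mia == min(s$mean_mia)])
  }))
  list(series = series, deposition = as_tibble(deposition))
}

#' Ageing precision: average percent error and coefficient of variation
#'
#' Beamish-Fournier average percent error and Chang coefficient of
#' variation over repeated age reads. Per fish j with reads x_1j..x_Rj and
#' mean x-bar_j: `APE_j = (100/R) * sum_i |x_ij - xbar_j| / xbar_j` and
#' `CV_j = 100 * sd_j / xbar_j`; both are averaged over fish. Fish with a
#' zero mean read (uninformative denominators) are excluded and counted.
#'
#' @param counts numeric matrix, fish in rows, readers in columns. Rows with
#'   any missing read are excluded.
#' @return list with `ape_pct`, `cv_pct`, `n_used`, `n_excluded`.
#' @export
#' @examples
#' ape_cv(rbind(c(9, 11)))  # APE 10, CV ~14.14
ape_cv <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least two readers")
  complete <- stats::complete.cases(counts)
  counts <- counts[complete, , drop = FALSE]
  if (!nrow(counts)) stop("no fish with all readers present")
  m <- rowMeans(counts)
  usable <- m > 0
  x <- counts[usable, , drop = FALSE]
  mu <- m[usable]
  if (!nrow(x)) stop("all fish have zero mean age read; APE/CV undefined")
  ape_j <- 100 / ncol(x) * rowSums(abs(x - mu) / mu)
  cv_j <- 100 * apply(x, 1, sd) / mu
  list(ape_pct = mean(ape_j), cv_pct = mean(cv_j),
       n_used = nrow(x), n_excluded = sum(!usable) + sum(!complete))
}

#' Full reading-precision report
#'
#' Combines the precision statistics reported for an ageing study: global
#' APE and CV over all count columns (human readers plus the automatic
#' count, treated as an ordinary extra reader), APE between the human
#' readers only, and the APE of the automatic count against the consensus
#' age.
#'
#' @param reader_counts matrix fish x human readers.
#' @param auto_counts optional numeric vector, automatic count per fish.
#' @param consensus optional numeric vector, consensus age per fish
#'   (required for the automatic-vs-consensus APE).
#' @return tibble with `ape_global_pct`, `ape_between_readers_pct`,
#'   `ape_automatic_pct`, `cv_global_pct` (NA where inputs are absent).
#' @export
precision_report <- function(reader_counts, auto_counts = NULL,
                             consensus = NULL) {
  reader_counts <- as.matrix(reader_counts)
  all_counts <- if (is.null(auto_counts)) reader_counts else
    cbind(reader_counts, auto = auto_counts)
  global <- ape_cv(all_counts)
  between <- ape_cv(reader_counts)
  auto <- if (!is.null(auto_counts) && !is.null(consensus)) {
    ape_cv(cbind(auto_counts, consensus))$ape_pct
  } else NA_real_
  tibble(
    ape_global_pct = global$ape_pct,
    ape_between_readers_pct = between$ape_pct,
    ape_automatic_pct = auto,
    cv_global_pct = global$cv_pct
  )
}

#' Fractional (biological) age
#'
#' Adds to the annuli count the fraction of a year elapsed between the most
#' recent theoretical birthdate anniversary and the capture date (year
#' length 365.25 d). For fish captured during the annulus-deposition window
#' whose otolith edge lacks an opaque zone, one year is added on the
#' assumption that the new annulus is about to deposit.
#'
#' @param annuli non-negative integer annuli count (vectorised).
#' @param capture_date `Date` (or ISO-8601 string) of capture.
#' @param edge_opaque logical, opaque zone present at the otolith edge.
#' @param birthdate theoretical birthdate as `"MM-DD"`; default May 1, the
#'   mid-point of the species' spawning season.
#' @param deposition_window integer months (1-12) of annulus deposition;
#'   default July-September.
#' @return fractional age in years.
#' @export
#' @examples
#' fractional_age(3, as.Date("2008-07-31"), edge_opaque = TRUE)  # ~3.249
fractional_age <- function(annuli, capture_date, edge_opaque = FALSE,
                           birthdate = "05-01", deposition_window = 7:9) {
  capture_date <- as.Date(capture_date)
  if (any(is.na(capture_date))) stop("unparseable capture_date")
  if (any(annuli < 0)) stop("annuli must be non-negative")
  n <- max(length(annuli), length(capture_date), length(edge_opaque))
  annuli <- rep_len(annuli, n)
  capture_date <- rep_len(capture_date, n)
  edge_opaque <- rep_len(edge_opaque, n)

  yr <- as.integer(format(capture_date, "%Y"))
  anniv <- as.Date(paste0(yr, "-", birthdate))
  anniv[capture_date < anniv] <- as.Date(paste0(yr - 1, "-", birthdate))[capture_date < anniv]
  frac <- as.numeric(capture_date - anniv) / 365.25
  age <- annuli + frac
  month <- as.integer(format(capture_date, "%m"))
  bump <- month %in% deposition_window & !edge_opaque
  age[bump] <- age[bump] + 1
  age
}
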