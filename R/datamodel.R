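# Domain tables and tabular I/O. One row of the fish table is one sampled
# individual; otolith readings and shape variables live in companion tables
# keyed by fish_id. All files are plain comma-separated UTF-8 with a header
# row; dates ISO-8601; lengths cm, radii mm, weights g.

#' Default column schema for the individual fish table
#'
#' Maps the canonical field names used throughout the package to the column
#' names found in a CSV file. Override entries to adapt to a foreign layout.
#'
#' @param ... named overrides, e.g. `fl_cm = "fork_length"`.
#' @return named character vector mapping canonical name -> file column.
#' @export
fish_schema <- function(...) {
  schema <- c(
    fish_id = "fish_id", site = "site", sex = "sex", maturity = "maturity",
    capture_date = "capture_date", fl_cm = "fl_cm", tl_cm = "tl_cm",
    sl_cm = "sl_cm", ww_g = "ww_g", gw_g = "gw_g", ow_g = "ow_g"
  )
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(schema))
    if (length(bad)) stop("unknown schema fields: ", paste(bad, collapse = ", "))
    schema[names(overrides)] <- overrides
  }
  schema
}

.mandatory_fields <- c("fish_id", "site", "fl_cm")

#' Read an individual fish table from CSV
#'
#' Parses and validates one row per fish. Rows violating the record
#' invariants (non-positive fork length, length ordering TL >= FL >= SL,
#' unparseable date or number, capture date outside the study window) are
#' collected into a rejection report with a reason, never dropped silently.
#' Unknown sex/maturity are allowed and left for per-analysis exclusion.
#'
#' @param path CSV file path.
#' @param schema column mapping from [fish_schema()].
#' @param study_window length-2 Date vector; capture dates outside it are
#'   rejected. `NULL` disables the check.
#' @return list with `records` (tibble of valid rows, canonical names) and
#'   `rejections` (tibble with `fish_id`, `row`, `reason`).
#' @export
read_fish_table <- function(path, schema = fish_schema(),
                            study_window = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- schema[.mandatory_fields][!schema[.mandatory_fields] %in% names(raw)]
  if (length(missing_cols)) {
    stop("mandatory column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  validate_fish_records(raw, schema = schema, study_window = study_window)
}

#' Validate a data frame of fish records
#'
#' Same invariant checks as [read_fish_table()] applied to an in-memory
#' data frame (with file-layout column names per `schema`).
#'
#' @inheritParams read_fish_table
#' @param data data frame of raw rows.
#' @return list with `records` and `rejections` tibbles.
#' @export
validate_fish_records <- function(data, schema = fish_schema(),
                                  study_window = NULL) {
  present <- schema[schema %in% names(data)]
  canon <- data[, present, drop = FALSE]
  names(canon) <- names(present)

  n <- nrow(canon)
  reason <- rep(NA_character_, n)
  note <- function(idx, msg) {
    new <- idx & is.na(reason)
    reason[new] <<- msg
  }

  num_fields <- intersect(c("fl_cm", "tl_cm", "sl_cm", "ww_g", "gw_g", "ow_g"),
                          names(canon))
  for (f in num_fields) {
    val <- suppressWarnings(as.numeric(canon[[f]]))
    bad <- !is.na(canon[[f]]) & canon[[f]] != "" & is.na(val)
    note(bad, paste0("unparseable number: ", f))
    canon[[f]] <- val
  }
  if ("capture_date" %in% names(canon)) {
    d <- as.Date(as.character(canon$capture_date), format = "%Y-%m-%d")
    bad <- !is.na(canon$capture_date) & canon$capture_date != "" & is.na(d)
    note(bad, "unparseable date: capture_date")
    canon$capture_date <- d
    if (!is.null(study_window)) {
      out <- !is.na(d) & (d < study_window[1] | d > study_window[2])
      note(out, "invariant: capture_date within study window")
    }
  }
  note(is.na(canon$fl_cm) | canon$fl_cm <= 0, "invariant: fl_cm>0")
  if (all(c("tl_cm", "fl_cm") %in% names(canon))) {
    bad <- !is.na(canon$tl_cm) & !is.na(canon$fl_cm) & canon$tl_cm < canon$fl_cm
    note(bad, "invariant: tl_cm>=fl_cm")
  }
  if (all(c("sl_cm", "fl_cm") %in% names(canon))) {
    bad <- !is.na(canon$sl_cm) & !is.na(canon$fl_cm) & canon$sl_cm > canon$fl_cm
    note(bad, "invariant: fl_cm>=sl_cm")
  }

  keep <- is.na(reason)
  rejections <- tibble(
    fish_id = if ("fish_id" %in% names(canon)) as.character(canon$fish_id[!keep]) else NA_character_,
    row = which(!keep),
    reason = reason[!keep]
  )
  list(records = as_tibble(canon[keep, , drop = FALSE]),
       rejections = rejections)
}

#' Write an individual fish table to CSV
#'
#' Inverse of [read_fish_table()]: writing then re-reading a valid table is
#' the identity on all typed fields.
#'
#' @param records tibble of fish records (canonical column names).
#' @param path output CSV path.
#' @param schema column mapping; canonical names are renamed to the file
#'   layout before writing.
#' @return `path`, invisibly.
#' @export
write_fish_table <- function(records, path, schema = fish_schema()) {
  out <- records
  present <- intersect(names(out), names(schema))
  names(out)[match(present, names(out))] <- schema[present]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Quality-control filter for otolith readings
#'
#' Pure bookkeeping over upstream QC flags: otoliths broken during
#' processing, and otoliths that were illegible or on which independent
#' readers remained discordant after reconciliation, are dropped; everything
#' else is retained. Counts always satisfy
#' `retained = collected - broken - unreadable_or_discordant`.
#'
#' @param readings data frame with one row per otolith, logical columns
#'   `broken` and `unreadable` (illegible or persistently discordant).
#'   Missing flags are treated as `FALSE`.
#' @return list with `retained` (the surviving rows) and `report` (tibble
#'   with `collected`, `broken`, `unreadable_or_discordant`, `retained`).
#' @export
qc_filter <- function(readings) {
  broken <- if ("broken" %in% names(readings)) isTRUE_vec(readings$broken) else rep(FALSE, nrow(readings))
  unread <- if ("unreadable" %in% names(readings)) isTRUE_vec(readings$unreadable) else rep(FALSE, nrow(readings))
  unread <- unread & !broken  # a broken otolith is counted once, as broken
  keep <- !broken & !unread
  report <- tibble(
    collected = nrow(readings),
    broken = sum(broken),
    unreadable_or_discordant = sum(unread),
    retained = sum(keep)
  )
  stopifnot(report$retained ==
              report$collected - report$broken - report$unreadable_or_discordant)
  list(retained = readings[keep, , drop = FALSE], report = report)
}

#' QC report from plain counts
#'
#' @param collected,broken,unreadable_or_discordant non-negative counts.
#' @return tibble as in [qc_filter()].
#' @export
#' @examples
#' qc_report(1499, 88, 287)$retained  # 1124
qc_report <- function(collected, broken, unreadable_or_discordant) {
  stopifnot(collected >= broken + unreadable_or_discordant)
  tibble(
    collected = collected, broken = broken,
    unreadable_or_discordant = unreadable_or_discordant,
    retained = collected - broken - unreadable_or_discordant
  )
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Validate an otolith reading table
#'
#' Checks the radial-measurement invariant 0 < r_{i-1} < r_i <= R where the
#' annulus radii are present.
#'
#' @param readings data frame with columns `otolith_radius_mm`,
#'   `last_annulus_mm`, `penultimate_annulus_mm` (the latter two may be NA).
#' @return tibble of violations (`row`, `reason`); zero rows when clean.
#' @export
validate_readings <- function(readings) {
  R <- readings$otolith_radius_mm
  ri <- readings$last_annulus_mm
  rim1 <- readings$penultimate_annulus_mm
  bad_order <- (!is.na(ri) & !is.na(R) & ri > R) |
    (!is.na(rim1) & !is.na(ri) & rim1 >= ri) |
    (!is.na(rim1) & rim1 <= 0)
  tibble(row = which(bad_order),
         reason = "invariant: 0 < r_{i-1} < r_i <= R")
}
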