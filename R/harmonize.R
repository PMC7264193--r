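# Record-processing pipeline: trait derivation, quality filters, and
# season/decade binning, with a per-step audit trail.
#
# Records are plain data.frames with (at least) the columns
#   record_id, source, decimalLongitude, decimalLatitude, year, month, day,
#   sex, life_stage, body_mass (g), total_length (mm), tail_length (mm)
# plus derived columns hb_length, season, decade_bin, and filter_flags.

# ---- audit log ----------------------------------------------------------

audit_new <- function() {
  data.frame(step = character(), n_in = integer(),
             n_removed = integer(), n_out = integer())
}

audit_add <- function(audit, step, n_in, n_removed) {
  rbind(audit, data.frame(step = step, n_in = as.integer(n_in),
                          n_removed = as.integer(n_removed),
                          n_out = as.integer(n_in - n_removed)))
}

#' Serialize an audit log to JSON
#'
#' @param audit the audit data.frame produced by [run_pipeline()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
audit_to_json <- function(audit, path = NULL) {
  js <- jsonlite::toJSON(audit, dataframe = "rows", auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# ---- trait derivation ---------------------------------------------------

#' Derive head-body length from total and tail length
#'
#' Head-body (HB) length is total length minus tail length. It is set only
#' where both measurements are present; anatomically impossible (non-positive)
#' derivations are left missing and flagged `"negative_hb"` rather than
#' propagated.
#'
#' @param records a record data.frame.
#' @return the records with an `hb_length` column (mm) and updated
#'   `filter_flags`.
#' @export
derive_hb_length <- function(records) {
  if (!"filter_flags" %in% names(records))
    records$filter_flags <- character(nrow(records))
  hb <- records$total_length - records$tail_length
  neg <- !is.na(hb) & hb <= 0
  records$filter_flags[neg] <- paste0(records$filter_flags[neg], ";negative_hb")
  hb[neg] <- NA_real_
  records$hb_length <- hb
  records
}

# ---- filters ------------------------------------------------------------

#' Remove records with body mass below the adult floor
#'
#' Known adult mass ranges imply records lighter than the floor are
#' unambiguous juveniles. Strictly-below-floor records are removed; records
#' with missing mass are untouched (they may still carry an HB length).
#'
#' @param records a record data.frame.
#' @param floor mass floor in grams (default 9).
#' @return `list(records, removed, n_removed)`.
#' @export
filter_mass_floor <- function(records, floor = 9) {
  stopifnot(floor > 0)
  drop <- !is.na(records$body_mass) & records$body_mass < floor
  list(records = records[!drop, , drop = FALSE],
       removed = records[drop, , drop = FALSE],
       n_removed = sum(drop))
}

#' Remove records explicitly labelled as juveniles
#'
#' Only records whose life stage is labelled `"juvenile"` are filtered;
#' `"unknown"` stages are retained.
#'
#' @param records a record data.frame.
#' @param include_juveniles if `TRUE`, nothing is removed.
#' @return `list(records, removed, n_removed)`.
#' @export
filter_lifestage <- function(records, include_juveniles = FALSE) {
  if (include_juveniles) {
    return(list(records = records, removed = records[0, , drop = FALSE],
                n_removed = 0L))
  }
  ls <- tolower(trimws(as.character(records$life_stage)))
  drop <- !is.na(ls) & ls == "juvenile"
  list(records = records[!drop, , drop = FALSE],
       removed = records[drop, , drop = FALSE],
       n_removed = sum(drop))
}

# Number of days in a month, Gregorian.
days_in_month <- function(year, month) {
  dim <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  out <- dim[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  out[!is.na(month) & month == 2L & leap] <- 29L
  out
}

#' Remove records with unusable collection dates
#'
#' Removes records missing month or day, records dated 1 January (which
#' frequently stand in for year-only reporting), records collected before
#' the anchor year, and impossible calendar dates.
#'
#' @param records a record data.frame.
#' @param min_year earliest admissible collection year (default 1895).
#' @return `list(records, removed, n_removed)`.
#' @export
filter_dates <- function(records, min_year = 1895) {
  y <- records$year; m <- records$month; d <- records$day
  bad <- is.na(m) | is.na(d) | is.na(y)
  bad <- bad | (!is.na(m) & !is.na(d) & m == 1 & d == 1)
  bad <- bad | (!is.na(y) & y < min_year)
  impossible <- !is.na(m) & !is.na(d) &
    (m < 1 | m > 12 | d < 1 | d > ifelse(m >= 1 & m <= 12,
                                         days_in_month(y, pmin(pmax(m, 1), 12)), 0))
  bad <- bad | impossible
  list(records = records[!bad, , drop = FALSE],
       removed = records[bad, , drop = FALSE],
       n_removed = sum(bad))
}

#' Remove records with missing or ambiguous sex
#'
#' Retains only records whose sex resolves (case-insensitively) to
#' `"female"` or `"male"`. Trailing question marks or any other token
#' (`"undetermined"`, `"unknown"`, empty) count as ambiguous and are removed.
#'
#' @param records a record data.frame.
#' @return `list(records, removed, n_removed)`; retained records have
#'   `sex` normalized to `"female"`/`"male"`.
#' @export
filter_sex <- function(records) {
  sx <- tolower(trimws(as.character(records$sex)))
  keep <- !is.na(sx) & sx %in% c("female", "male")
  records$sex[keep] <- sx[keep]
  list(records = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE],
       n_removed = sum(!keep))
}

# ---- binning ------------------------------------------------------------

#' Assign a season from month and day
#'
#' Seasons follow fixed equinox/solstice boundaries:
#' Spring = Mar 20 to Jun 20, Summer = Jun 21 to Sep 21,
#' Fall = Sep 22 to Dec 20, Winter = Dec 21 to Mar 19.
#'
#' @param month,day integer vectors (a valid calendar date).
#' @return character vector of `"Spring"`, `"Summer"`, `"Fall"`, `"Winter"`.
#' @export
assign_season <- function(month, day) {
  if (any(is.na(month) | is.na(day) | month < 1 | month > 12 | day < 1 | day > 31))
    stop("assign_season requires valid month/day values")
  key <- month * 100 + day  # e.g. Mar 20 -> 320
  out <- rep(NA_character_, length(key))
  out[key >= 320 & key <= 620] <- "Spring"
  out[key >= 621 & key <= 921] <- "Summer"
  out[key >= 922 & key <= 1220] <- "Fall"
  out[key >= 1221 | key <= 319] <- "Winter"
  out
}

#' Assign a decade bin from collection year
#'
#' Bins are ten-year increments anchored at 1895: bin *k* covers years
#' `[1895 + 10(k-1), 1904 + 10(k-1)]`. Years 1895--2019 fall into 13 bins,
#' the last (2015 onward) truncated to 2015--2019.
#'
#' @param year integer vector, all `>= 1895`.
#' @return integer bin index (1--13 for 1895--2019).
#' @export
assign_decade <- function(year) {
  if (any(is.na(year) | year < 1895)) stop("assign_decade requires years >= 1895")
  as.integer(floor((year - 1895) / 10)) + 1L
}

#' Label for a decade bin
#'
#' @param bin integer bin index from [assign_decade()].
#' @return character like `"1895-1904"` (the 13th bin is `"2015-2019"`).
#' @export
decade_label <- function(bin) {
  start <- 1895 + 10 * (bin - 1)
  end <- ifelse(bin == 13L, 2019, start + 9)
  sprintf("%d-%d", start, end)
}

# ---- outliers -----------------------------------------------------------

#' Flag and remove trait-measurement outliers
#'
#' For each measurement (body mass, tail length, total length), the mean and
#' standard deviation are computed once over the current dataset; a record
#' with any measurement outside mean +/- k*SD is removed. The pass is single
#' (non-iterative): statistics are not recomputed after removals. A
#' measurement with zero or undefined SD removes nothing.
#'
#' @param records a record data.frame.
#' @param k SD multiplier (default 3).
#' @param measurements columns to screen.
#' @return `list(records, removed, n_removed)`.
#' @export
flag_outliers <- function(records, k = 3,
                          measurements = c("body_mass", "tail_length", "total_length")) {
  stopifnot(k > 0)
  drop <- rep(FALSE, nrow(records))
  for (mcol in intersect(measurements, names(records))) {
    x <- records[[mcol]]
    mu <- mean(x, na.rm = TRUE)
    sdev <- sd(x, na.rm = TRUE)
    if (!is.finite(sdev) || sdev == 0) next
    drop <- drop | (!is.na(x) & abs(x - mu) > k * sdev)
  }
  list(records = records[!drop, , drop = FALSE],
       removed = records[drop, , drop = FALSE],
       n_removed = sum(drop))
}

# ---- full pipeline ------------------------------------------------------

#' Run the full record-harmonization pipeline
#'
#' Deterministic ordered application of the quality filters:
#' coordinate presence, dates, sex, life stage, HB-length derivation, then
#' per-trait dataset assembly (mass floor and a single outlier pass applied
#' to the mass and HB datasets separately), season/decade assignment, the
#' optional temporal cut (collection year >= 1945), and the optional
#' exclusion of the live-capture NEON source.
#'
#' @param records a record data.frame (see [simulate_records()] for the
#'   column contract).
#' @param config list with elements `include_juveniles` (default `FALSE`),
#'   `include_neon` (default `TRUE`), `temporal` (default `FALSE`),
#'   `floor` (default 9 g), `k` (default 3 SD). Unknown keys are an error.
#' @param log_path optional JSON-lines log file.
#' @return `list(mass = <data.frame>, hb = <data.frame>, audit = <data.frame>)`.
#'   The audit chains: records out of one step are the records into the next,
#'   with the two trait datasets audited on separate branches after the
#'   shared steps.
#' @export
run_pipeline <- function(records, config = list(), log_path = NULL) {
  defaults <- list(include_juveniles = FALSE, include_neon = TRUE,
                   temporal = FALSE, floor = 9, k = 3)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)

  audit <- audit_new()
  step <- function(name, res, n_in) {
    audit <<- audit_add(audit, name, n_in, res$n_removed)
    log_jsonl(log_path, stage = "harmonize", step = name,
              n_in = n_in, n_removed = res$n_removed)
    res$records
  }

  r <- records
  # coordinate presence (manual georeferencing is out of scope)
  has_xy <- !is.na(r$decimalLongitude) & !is.na(r$decimalLatitude)
  audit <- audit_add(audit, "coordinates", nrow(r), sum(!has_xy))
  r <- r[has_xy, , drop = FALSE]

  r <- step("dates", filter_dates(r), nrow(r))
  r <- step("sex", filter_sex(r), nrow(r))
  r <- step("lifestage", filter_lifestage(r, cfg$include_juveniles), nrow(r))
  r <- derive_hb_length(r)

  # season/decade binning on the shared survivors
  r$season <- assign_season(r$month, r$day)
  r$decade_bin <- assign_decade(r$year)
  r$decade <- decade_label(r$decade_bin)

  finish <- function(d, trait) {
    if (cfg$temporal) {
      drop <- d$year < 1945
      audit <<- audit_add(audit, paste0(trait, "_temporal_1945"), nrow(d), sum(drop))
      d <- d[!drop, , drop = FALSE]
    }
    if (!cfg$include_neon) {
      drop <- d$source == "NEON"
      audit <<- audit_add(audit, paste0(trait, "_drop_neon"), nrow(d), sum(drop))
      d <- d[!drop, , drop = FALSE]
    }
    d
  }

  # mass branch
  m <- r[!is.na(r$body_mass), , drop = FALSE]
  audit <- audit_add(audit, "mass_present", nrow(r), nrow(r) - nrow(m))
  m <- step("mass_floor", filter_mass_floor(m, cfg$floor), nrow(m))
  m <- step("mass_outliers",
            flag_outliers(m, cfg$k, c("body_mass", "tail_length", "total_length")),
            nrow(m))
  m <- finish(m, "mass")

  # HB branch
  h <- r[!is.na(r$hb_length), , drop = FALSE]
  audit <- audit_add(audit, "hb_present", nrow(r), nrow(r) - nrow(h))
  h <- step("hb_outliers",
            flag_outliers(h, cfg$k, c("body_mass", "tail_length", "total_length")),
            nrow(h))
  h <- finish(h, "hb")

  list(mass = m, hb = h, audit = audit)
}
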