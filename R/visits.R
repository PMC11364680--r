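# Visit-table schema, month-resolution dates, delimited IO and validation.

#' Columns of a screening visit table
#'
#' Required columns for a visit table, in canonical order. `diagnosis_date`
#' is recognised as an optional extra column (cancer visits only); any other
#' column is ignored with a warning on read.
#'
#' @format Character vector of column names.
#' @export
visit_columns <- c("visit_id", "woman_id", "visit_date", "ai_score", "birads",
                   "reader_detected", "is_cancer_visit", "detection_mode")

detection_modes <- c("screen_detected", "interval", "missed", "none")

#' Parse dates at month resolution
#'
#' Screening timelines in this package are kept at month resolution: any
#' day-of-month information is dropped and dates are stored as the first of
#' the month. Accepts `Date` vectors or strings in `"YYYY-MM"` or
#' `"YYYY-MM-DD"` form.
#'
#' @param x Date vector or character vector.
#' @return `Date` vector, first day of each month.
#' @export
#' @examples
#' as_month(c("2015-03", "2015-03-17"))
as_month <- function(x) {
  if (inherits(x, "Date")) {
    return(as.Date(format(x, "%Y-%m-01")))
  }
  x <- as.character(x)
  ym <- grepl("^\\d{4}-\\d{2}$", x)
  x[ym] <- paste0(x[ym], "-01")
  out <- as.Date(x)
  if (anyNA(out) && !all(is.na(x))) {
    bad <- which(is.na(out) & !is.na(x))[1L]
    stop_validation(sprintf("unparseable date %s at position %d",
                            dQuote(x[bad]), bad))
  }
  as.Date(format(out, "%Y-%m-01"))
}

#' Whole months between two month-resolution dates
#'
#' @param later,earlier `Date` vectors (coerced to month resolution).
#' @return Integer vector of month differences (`later - earlier`).
#' @export
#' @examples
#' months_between(as.Date("2018-01-01"), as.Date("2015-07-01")) # 30
months_between <- function(later, earlier) {
  later <- as_month(later)
  earlier <- as_month(earlier)
  lt <- as.POSIXlt(later)
  et <- as.POSIXlt(earlier)
  as.integer(12L * (lt$year - et$year) + (lt$mon - et$mon))
}

#' Add whole months to a month-resolution date
#' @param date `Date` vector.
#' @param months Integer vector of months to add (recycled).
#' @return `Date` vector at month resolution.
#' @export
add_months <- function(date, months) {
  date <- as_month(date)
  n <- if (length(date) == 0 || length(months) == 0) 0L
       else max(length(date), length(months))
  date <- rep_len(date, n)
  months <- rep_len(as.integer(months), n)
  if (n == 0L) return(date)
  lt <- as.POSIXlt(date)
  lt$mon <- lt$mon + months
  as.Date(format(as.Date(lt), "%Y-%m-01"))
}

#' Validate a visit table
#'
#' Checks the schema and the record-level invariants: AI scores in
#' \[0, 100\], BI-RADS in 0..5, a recognised detection mode,
#' `detection_mode == "none"` exactly for non-cancer visits, and reader
#' outcomes consistent with the detection mode (screen-detected cancers were
#' recalled by the readers; interval and missed cancers were not).
#'
#' @param visits A data frame with the columns in [visit_columns].
#' @return `visits` (as a tibble), invisibly usable downstream.
#' @export
validate_visits <- function(visits) {
  missing_cols <- setdiff(visit_columns, names(visits))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("visit table is missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  visits <- tibble::as_tibble(visits)
  visits$visit_date <- as_month(visits$visit_date)
  if ("diagnosis_date" %in% names(visits)) {
    visits$diagnosis_date <- suppressWarnings(as_month(visits$diagnosis_date))
  }
  bad <- which(!is.finite(visits$ai_score) | visits$ai_score < 0 |
                 visits$ai_score > 100)
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "ai_score out of [0, 100] at row %d (value %s)", bad[1L],
      format(visits$ai_score[bad[1L]])))
  }
  bad <- which(!(visits$birads %in% 0:5))
  if (length(bad) > 0) {
    stop_validation(sprintf("birads outside {0..5} at row %d (value %s)",
                            bad[1L], format(visits$birads[bad[1L]])))
  }
  bad <- which(!(visits$detection_mode %in% detection_modes))
  if (length(bad) > 0) {
    stop_validation(sprintf("unknown detection_mode %s at row %d",
                            dQuote(visits$detection_mode[bad[1L]]), bad[1L]))
  }
  mismatch <- which((visits$detection_mode == "none") != !visits$is_cancer_visit)
  if (length(mismatch) > 0) {
    stop_validation(sprintf(
      "detection_mode/is_cancer_visit mismatch at row %d", mismatch[1L]))
  }
  bad <- which(visits$detection_mode %in% c("interval", "missed") &
                 visits$reader_detected)
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "interval/missed cancer marked reader_detected at row %d", bad[1L]))
  }
  bad <- which(visits$detection_mode == "screen_detected" &
                 !visits$reader_detected)
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "screen-detected cancer without reader_detected at row %d", bad[1L]))
  }
  visits
}

#' Read a screening visit table from a delimited file
#'
#' Expects a header row with the columns in [visit_columns] (plus optional
#' `diagnosis_date`); unknown extra columns are dropped with a warning. All
#' rows are validated against the visit invariants and row order is
#' preserved.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter (default comma).
#' @return A tibble of validated visit records.
#' @seealso [write_visits()], [validate_visits()]
#' @export
read_visits <- function(path, delim = ",") {
  if (!file.exists(path)) {
    stop_schema(sprintf("visit file not found: %s", path))
  }
  raw <- utils::read.csv(path, sep = delim, stringsAsFactors = FALSE,
                         check.names = FALSE)
  known <- c(visit_columns, "diagnosis_date")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
    raw <- raw[, setdiff(names(raw), extra), drop = FALSE]
  }
  missing_cols <- setdiff(visit_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("visit table is missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  raw$visit_id <- as.character(raw$visit_id)
  raw$woman_id <- as.character(raw$woman_id)
  raw$ai_score <- as.numeric(raw$ai_score)
  raw$birads <- as.integer(raw$birads)
  raw$reader_detected <- as.logical(raw$reader_detected)
  raw$is_cancer_visit <- as.logical(raw$is_cancer_visit)
  raw$detection_mode <- as.character(raw$detection_mode)
  if ("diagnosis_date" %in% names(raw)) {
    raw$diagnosis_date[raw$diagnosis_date %in% c("", "NA")] <- NA
  }
  validate_visits(raw)
}

#' Write a screening visit table to a delimited file
#'
#' Dates are written at month resolution (`YYYY-MM`); AI scores are written
#' with full double precision so that write-then-read round-trips exactly.
#'
#' @param visits Visit table (validated before writing).
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path, delim = ",") {
  visits <- validate_visits(visits)
  out <- as.data.frame(visits)
  out$visit_date <- format(out$visit_date, "%Y-%m")
  if ("diagnosis_date" %in% names(out)) {
    out$diagnosis_date <- ifelse(is.na(out$diagnosis_date), NA,
                                 format(out$diagnosis_date, "%Y-%m"))
  }
  out$ai_score <- sprintf("%.17g", out$ai_score)
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Dichotomize BI-RADS assessments into reader-positive/negative
#'
#' BI-RADS 1 and 2 are negative (routine screening); 0, 3, 4 and 5 are
#' positive (recall / further assessment), following the standard screening
#' dichotomization.
#'
#' @param birads Integer vector of BI-RADS categories in 0..5.
#' @return Logical vector, `TRUE` = reader-positive.
#' @export
#' @examples
#' dichotomize_birads(c(0, 1, 2, 3, 4, 5))
dichotomize_birads <- function(birads) {
  bad <- which(!(birads %in% 0:5))
  if (length(bad) > 0) {
    stop_validation(sprintf("birads outside {0..5} at position %d (value %s)",
                            bad[1L], format(birads[bad[1L]])))
  }
  !(birads %in% c(1L, 2L))
}
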