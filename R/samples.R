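# Sample records, study window filtering and meteorological seasons.
#
# A sample record is one measurement by one actor (e.g. the agency "EA" or
# the citizen-science programme "FWW") at one site and date. Laboratory
# actors report a continuous nitrate-N concentration in mg/L; field-kit
# actors report a category label. Exactly one of the two is present per
# record, matching `value_kind`.

SAMPLE_COLUMNS <- c("actor", "site_id", "x", "y", "timestamp", "determinand",
                    "value", "value_kind", "waterbody_class")

SEASONS <- c("spring", "summer", "autumn", "winter")

#' Define an inclusive study window
#'
#' @param start,end inclusive window bounds, coercible to \code{Date}. The
#'   defaults span 1 March 2013 to 31 December 2015 (spring 2013 through
#'   winter 2015).
#' @return object of class \code{study_window}.
#' @export
study_window <- function(start = "2013-03-01", end = "2015-12-31") {
  start <- tryCatch(as.Date(start), error = function(e) NA)
  end <- tryCatch(as.Date(end), error = function(e) NA)
  if (is.na(start) || is.na(end)) stop("study window bounds must be valid dates")
  if (start > end) stop("study window start must not be after its end")
  structure(list(start = start, end = end), class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat("Study window:", format(x$start), "to", format(x$end), "(inclusive)\n")
  invisible(x)
}

#' Assign meteorological seasons to dates
#'
#' Meteorological convention: Mar-May spring, Jun-Aug summer, Sep-Nov autumn,
#' Dec-Feb winter.
#'
#' @param dates a \code{Date} vector (or coercible).
#' @return character vector over \code{"spring"}, \code{"summer"},
#'   \code{"autumn"}, \code{"winter"}.
#' @seealso \code{\link{season_year}} for the season-year label.
#' @export
assign_season <- function(dates) {
  dates <- as.Date(dates)
  m <- as.integer(format(dates, "%m"))
  SEASONS[ifelse(m %in% 3:5, 1L,
          ifelse(m %in% 6:8, 2L,
          ifelse(m %in% 9:11, 3L, 4L)))]
}

#' Season-year label of a date
#'
#' Winter belongs to the year of its December: January and February carry the
#' previous year's label, so "winter 2015" runs December 2015 through
#' February 2016 (and is truncated at 31 December 2015 by the default study
#' window).
#'
#' @param dates a \code{Date} vector (or coercible).
#' @return integer vector of season years.
#' @export
season_year <- function(dates) {
  dates <- as.Date(dates)
  m <- as.integer(format(dates, "%m"))
  y <- as.integer(format(dates, "%Y"))
  ifelse(m <= 2L, y - 1L, y)
}

#' Read sample records from a delimited text file
#'
#' Rows that cannot be parsed (bad date, non-numeric continuous value,
#' unknown \code{value_kind} or \code{waterbody_class}, non-finite
#' coordinates) are rejected with a row-level reason and reported via a
#' warning; they are never silently dropped. A continuous value written with
#' a below-detection-limit flag \code{"<x"} is read as \code{x}.
#'
#' @param path path to the file.
#' @param dialect \code{"csv"} (comma) or \code{"tsv"} (tab).
#' @return data frame of parsed records with columns \code{actor},
#'   \code{site_id}, \code{x}, \code{y}, \code{timestamp} (Date),
#'   \code{determinand}, \code{value} (numeric; \code{NA} for categorical
#'   records), \code{category} (character; \code{NA} for continuous records),
#'   \code{value_kind}, \code{waterbody_class}. Rejected rows are attached as
#'   the \code{rejected} attribute (data frame with \code{row} and
#'   \code{reason}).
#' @export
read_samples <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("sample file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  missing_cols <- setdiff(SAMPLE_COLUMNS, names(raw))
  if (length(missing_cols) > 0L)
    stop("sample file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  parse_sample_rows(raw)
}

parse_sample_rows <- function(raw) {
  n <- nrow(raw)
  reasons <- character(n)
  ts <- suppressWarnings(as.Date(raw$timestamp, format = "%Y-%m-%d"))
  # tolerate ISO timestamps with a time-of-day part: truncate to the date
  with_time <- is.na(ts) & grepl("^\\d{4}-\\d{2}-\\d{2}[T ]", raw$timestamp)
  ts[with_time] <- suppressWarnings(
    as.Date(substr(raw$timestamp[with_time], 1, 10), format = "%Y-%m-%d"))
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  kind <- raw$value_kind
  wclass <- raw$waterbody_class

  value <- rep(NA_real_, n)
  category <- rep(NA_character_, n)
  cont <- !is.na(kind) & kind == "continuous"
  # "<x" below-detection-limit flags are read as x
  vtxt <- sub("^<\\s*", "", raw$value)
  value[cont] <- suppressWarnings(as.numeric(vtxt[cont]))
  category[!cont] <- raw$value[!cont]

  reasons[is.na(ts)] <- "unparseable timestamp"
  reasons[reasons == "" & (is.na(x) | is.na(y) | !is.finite(x) | !is.finite(y))] <-
    "non-finite coordinates"
  reasons[reasons == "" & !(kind %in% c("continuous", "categorical"))] <-
    "value_kind must be 'continuous' or 'categorical'"
  reasons[reasons == "" & cont & (is.na(value) | value < 0)] <-
    "unparseable or negative continuous value"
  reasons[reasons == "" & !cont & (is.na(category) | category == "")] <-
    "empty category label"
  reasons[reasons == "" & !(wclass %in% c("running", "still"))] <-
    "waterbody_class must be 'running' or 'still'"

  ok <- reasons == ""
  out <- data.frame(actor = raw$actor[ok], site_id = raw$site_id[ok],
                    x = x[ok], y = y[ok], timestamp = ts[ok],
                    determinand = raw$determinand[ok],
                    value = value[ok], category = category[ok],
                    value_kind = kind[ok], waterbody_class = wclass[ok],
                    stringsAsFactors = FALSE)
  rejected <- data.frame(row = which(!ok), reason = reasons[!ok],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0L)
    warning(nrow(rejected), " row(s) rejected while reading samples (see ",
            "attr(, 'rejected')); first reason: ", rejected$reason[1L],
            call. = FALSE)
  attr(out, "rejected") <- rejected
  out
}

#' Write sample records to CSV
#'
#' Inverse of \code{\link{read_samples}}: continuous records write their
#' numeric value, categorical records their label, into the single
#' \code{value} column of the schema.
#'
#' @param samples data frame as returned by \code{\link{read_samples}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_samples <- function(samples, path) {
  value_txt <- ifelse(samples$value_kind == "continuous",
                      vapply(samples$value, format_number, character(1)),
                      samples$category)
  out <- data.frame(actor = samples$actor, site_id = samples$site_id,
                    x = vapply(samples$x, format_number, character(1)),
                    y = vapply(samples$y, format_number, character(1)),
                    timestamp = format(samples$timestamp, "%Y-%m-%d"),
                    determinand = samples$determinand,
                    value = value_txt,
                    value_kind = samples$value_kind,
                    waterbody_class = samples$waterbody_class,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_number <- function(v) {
  if (is.na(v)) return("")
  format(v, scientific = FALSE, trim = TRUE, digits = 15)
}

#' Restrict sample records to a study window
#'
#' Keeps exactly the records with \code{start <= timestamp <= end},
#' preserving order. Idempotent.
#'
#' @param samples sample data frame.
#' @param window a \code{\link{study_window}}.
#' @return filtered data frame.
#' @export
filter_window <- function(samples, window = study_window()) {
  stopifnot(inherits(window, "study_window"))
  keep <- samples$timestamp >= window$start & samples$timestamp <= window$end
  samples[keep, , drop = FALSE]
}
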