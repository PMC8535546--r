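#' Parse raw workout-session logs
#'
#' Reads session records from a CSV or JSON source. Both dialects carry the
#' four canonical fields `user_id`, `start_time` (ISO-8601 timestamp),
#' `duration_s` (seconds) and `finished`; extra fields are ignored. Records
#' with missing or unparseable fields are *kept* (with `NA` in the offending
#' column) so that [clean_sessions()] can count and remove them.
#'
#' @param source path to a file, a connection, or a character vector of
#'   literal text (for JSON, the document; for CSV, one element per line).
#' @param format `"csv"` or `"json"`.
#' @return A `data.frame` with columns `user_id` (character), `start_time`
#'   (character, as supplied), `duration_s` (numeric) and `finished`
#'   (logical).
#' @seealso [clean_sessions()], [build_daily_series()]
#' @export
#' @examples
#' txt <- c("user_id,start_time,duration_s,finished",
#'          "u1,2021-03-01T10:00:00,300,true",
#'          "u1,2021-03-02T10:00:00,150,YES")
#' parse_sessions(txt, "csv")
parse_sessions <- function(source, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- tryCatch(
      read.csv(text_or_path(source), stringsAsFactors = FALSE,
               colClasses = "character"),
      error = function(e) stop("malformed CSV stream: ", conditionMessage(e),
                               call. = FALSE)
    )
  } else {
    doc <- if (is.character(source) && length(source) == 1L &&
               !grepl("[\\[{]", source)) {
      paste(readLines(source, warn = FALSE), collapse = "\n")
    } else if (inherits(source, "connection")) {
      paste(readLines(source, warn = FALSE), collapse = "\n")
    } else {
      paste(source, collapse = "\n")
    }
    df <- tryCatch(
      jsonlite::fromJSON(doc, simplifyDataFrame = TRUE),
      error = function(e) stop("malformed JSON stream: ", conditionMessage(e),
                               call. = FALSE)
    )
    if (!is.data.frame(df)) stop("JSON source must be an array of objects",
                                 call. = FALSE)
  }
  for (fld in c("user_id", "start_time", "duration_s", "finished"))
    if (is.null(df[[fld]])) df[[fld]] <- NA
  out <- data.frame(
    user_id    = as.character(df$user_id),
    start_time = as.character(df$start_time),
    duration_s = suppressWarnings(as.numeric(df$duration_s)),
    finished   = parse_finished(df$finished),
    stringsAsFactors = FALSE
  )
  out
}

# CSV helper: decide whether `source` is inline text or a path/connection
text_or_path <- function(source) {
  if (is.character(source) && (length(source) > 1L || grepl(",", source[1])))
    return(textConnection(paste(source, collapse = "\n")))
  source
}

# finished flags accepted: true/false, 1/0, YES/NO (case-insensitive)
parse_finished <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "1", "yes")] <- TRUE
  out[x %in% c("false", "0", "no")] <- FALSE
  out
}

#' Clean session records
#'
#' Removes exact duplicates (identical `user_id`, `start_time`, `duration_s`
#' triples), records with missing or negative duration, records whose
#' timestamp cannot be parsed to a calendar date and, optionally, unfinished
#' sessions. Cleaning never fails: it filters, preserving input order, and
#' reports how many records were dropped via the `"removed"` attribute.
#'
#' @param records data.frame of session records from [parse_sessions()].
#' @param finished_only drop sessions whose `finished` flag is not `TRUE`?
#'   Defaults to `TRUE`: the clustering features are defined over *completed*
#'   sessions, but the raw logs also carry unfinished ones.
#' @return The filtered data.frame, with attribute `removed` (integer count).
#' @export
clean_sessions <- function(records, finished_only = TRUE) {
  n0 <- nrow(records)
  keep <- !duplicated(records[, c("user_id", "start_time", "duration_s")])
  keep <- keep & !is.na(records$duration_s) & records$duration_s >= 0
  keep <- keep & !is.na(session_date(records$start_time))
  if (finished_only)
    keep <- keep & !is.na(records$finished) & records$finished
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- n0 - nrow(out)
  out
}

# Calendar date of a timestamp: its own date component, no timezone math.
session_date <- function(x) {
  d <- suppressWarnings(as.Date(substr(as.character(x), 1L, 10L),
                                format = "%Y-%m-%d"))
  d
}

#' Daily accumulated workout-seconds series
#'
#' Constructs one user's fixed-length daily series: day `d` holds the sum of
#' that user's session durations on calendar date `anchor + (d - 1)`, where
#' the anchor is the date of the user's first retained session. Days without
#' sessions, and days beyond the last session, are zero.
#'
#' @param records cleaned session records (see [clean_sessions()]).
#' @param user_id the user to aggregate.
#' @param period_days series length in days (default 120: 90 training days
#'   followed by a 30-day held-out window).
#' @return A `daily_series` object.
#' @export
build_daily_series <- function(records, user_id, period_days = 120L) {
  stopifnot(period_days >= 1)
  rec <- records[records$user_id == user_id, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no anchor: user '", user_id, "' has no retained sessions",
         call. = FALSE)
  dates <- session_date(rec$start_time)
  anchor <- min(dates)
  idx <- as.integer(dates - anchor) + 1L
  values <- numeric(period_days)
  in_window <- idx >= 1L & idx <= period_days
  for (i in which(in_window))
    values[idx[i]] <- values[idx[i]] + rec$duration_s[i]
  daily_series(user_id, values, anchor = anchor)
}

#' Construct a daily series object
#'
#' @param user_id user identifier.
#' @param values non-negative numeric vector of daily accumulated workout
#'   seconds (length 120 for the standard 90/30 split).
#' @param anchor optional anchor date (day 1).
#' @return A `daily_series`: list with `user_id`, `values`, `anchor`.
#' @export
daily_series <- function(user_id, values, anchor = NULL) {
  values <- as.numeric(values)
  if (any(is.na(values)) || any(values < 0))
    stop("daily series values must be non-negative and non-missing",
         call. = FALSE)
  structure(list(user_id = user_id, values = values, anchor = anchor),
            class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  n <- length(x$values)
  cat("Daily workout series: user", x$user_id, "-", n, "days,",
      sum(x$values > 0), "active,", round(sum(x$values)), "s total\n")
  invisible(x)
}

#' @export
length.daily_series <- function(x) length(x$values)

#' Split a 120-day series into training and held-out windows
#'
#' Days 1-90 train the system; days 91-120 are the held-out fourth month.
#' The concatenation of the two windows reproduces the input exactly.
#'
#' @param series a `daily_series` of length 120 (or a plain 120-vector).
#' @return `list(train = <90 values>, test = <30 values>)`.
#' @export
split_windows <- function(series) {
  v <- if (inherits(series, "daily_series")) series$values else as.numeric(series)
  if (length(v) != 120L)
    stop("split_windows expects a 120-day series, got length ", length(v),
         call. = FALSE)
  list(train = v[1:90], test = v[91:120])
}
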